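## Image / mask I/O and dataset assembly. Images are PNG (TIFF also
## accepted when the tiff package is available); masks are single-channel
## PNG with 0 = background and 255 = aphid on disk, mapped to {0, 1} in
## memory.

readImageFile <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      stopIf(!requireNamespace("tiff", quietly = TRUE),
             "reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE] # drop alpha
  img
}

#' Read / write binary masks as PNG
#'
#' Masks are stored as single-channel PNG with the pinned encoding
#' 0 = background, 255 = aphid; in memory they are integer matrices in
#' `{0, 1}`. Reading tolerates any grayscale PNG by thresholding at 0.5.
#'
#' @param path PNG file path.
#' @param mask integer matrix in `{0, 1}`.
#' @return `readMaskPng()`: integer matrix; `writeMaskPng()`: `path`,
#'   invisibly.
#' @export
readMaskPng <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(m > 0.5), nrow(m), ncol(m))
}

#' @rdname readMaskPng
#' @export
writeMaskPng <- function(mask, path) {
  stopIf(!all(mask %in% c(0L, 1L)), "mask values must be 0/1")
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

## Bilinear (images) and nearest-neighbour (masks) resizing.
resizeImage <- function(img, size) {
  d <- dim(img)
  if (d[1L] == size && d[2L] == size) return(img)
  Rh <- bilinearMatrix(size, d[1L])
  Rw <- t(bilinearMatrix(size, d[2L]))
  out <- array(0, c(size, size, d[3L]))
  for (ch in seq_len(d[3L])) out[, , ch] <- Rh %*% img[, , ch] %*% Rw
  out
}

resizeMask <- function(mask, size) {
  d <- dim(mask)
  if (d[1L] == size && d[2L] == size) return(mask)
  ri <- pmin(pmax(round(seq(1, d[1L], length.out = size)), 1L), d[1L])
  ci <- pmin(pmax(round(seq(1, d[2L], length.out = size)), 1L), d[2L])
  mask[ri, ci, drop = FALSE]
}

#' Load image/mask pairs from directories
#'
#' Matches images to masks by file stem, loads them (PNG, or TIFF with the
#' tiff package; masks must be PNG), optionally resizes (bilinear for
#' images, nearest-neighbour for masks) and reports orphans -- images
#' without a mask or masks without an image.
#'
#' @param imageDir,maskDir directories containing the images and masks.
#' @param size optional square target size (e.g. 480 or 1024).
#' @param onOrphan `"warn"` (skip with a warning, default) or `"error"`.
#' @return list of segmentation samples (`image`, `mask`, `id`,
#'   `provenance = "original"`); orphan stems are attached as attribute
#'   `"orphans"`.
#' @export
loadPairs <- function(imageDir, maskDir, size = NULL,
                      onOrphan = c("warn", "error")) {
  onOrphan <- match.arg(onOrphan)
  stopIf(!dir.exists(imageDir), "image directory not found: ", imageDir)
  stopIf(!dir.exists(maskDir), "mask directory not found: ", maskDir)
  imgs <- list.files(imageDir, pattern = "\\.(png|tif|tiff)$",
                     ignore.case = TRUE)
  msks <- list.files(maskDir, pattern = "\\.png$", ignore.case = TRUE)
  istem <- tools::file_path_sans_ext(imgs)
  mstem <- tools::file_path_sans_ext(msks)
  common <- intersect(istem, mstem)
  orphans <- c(setdiff(istem, mstem), setdiff(mstem, istem))
  if (length(orphans)) {
    msg <- paste("unmatched image/mask stems:",
                 paste(orphans, collapse = ", "))
    if (onOrphan == "error") stop(msg, call. = FALSE) else warning(msg)
  }
  if (length(common) == 0L) {
    warning("no matched image/mask pairs found")
    return(structure(list(), orphans = orphans))
  }
  samples <- lapply(common, function(st) {
    img <- readImageFile(file.path(imageDir, imgs[match(st, istem)]))
    msk <- readMaskPng(file.path(maskDir, msks[match(st, mstem)]))
    stopIf(!all(dim(img)[1:2] == dim(msk)),
           "image and mask dimensions differ for stem ", st)
    if (!is.null(size)) {
      img <- resizeImage(img, size)
      msk <- resizeMask(msk, size)
    }
    list(image = img, mask = msk, id = st, provenance = "original")
  })
  structure(samples, orphans = orphans)
}

#' Write a dataset manifest
#'
#' CSV with one row per sample: `id`, `imagePath`, `maskPath`, `split`,
#' `provenance`.
#'
#' @param samples list of segmentation samples.
#' @param path output CSV path.
#' @param split character vector (recycled) labelling each sample.
#' @param imagePath,maskPath character vectors of file locations
#'   (defaults derive from the ids).
#' @return `path`, invisibly.
#' @export
writeManifest <- function(samples, path, split = "train",
                          imagePath = NULL, maskPath = NULL) {
  ids <- vapply(samples, `[[`, "", "id")
  df <- data.frame(
    id = ids,
    imagePath = imagePath %||% paste0("images/", ids, ".png"),
    maskPath = maskPath %||% paste0("masks/", ids, ".png"),
    split = rep_len(split, length(samples)),
    provenance = vapply(samples, `[[`, "", "provenance"),
    stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Predict masks and overlays for a set of images
#'
#' Runs inference on each image, writes the arg-max mask
#' (`<id>_mask.png`, 0/255 encoding) and a red-overlay visualisation
#' (`<id>_overlay.png`) in which pixels outside the predicted foreground
#' are the unmodified source pixels.
#'
#' @param model a [FeswUNet-class].
#' @param images list of `(H, W, 3)` arrays or image file paths; spatial
#'   dims must be divisible by 16. Unreadable files are reported and
#'   skipped.
#' @param outDir output directory (created if needed).
#' @param alpha overlay blend strength for foreground pixels.
#' @return invisible data frame with `id`, `maskPath`, `overlayPath`,
#'   `foregroundFraction` (NA rows mark skipped inputs).
#' @export
predictMasks <- function(model, images, outDir, alpha = 0.5) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(images), function(i) {
    src <- images[[i]]
    id <- if (is.character(src)) tools::file_path_sans_ext(basename(src))
          else sprintf("image%03d", i)
    img <- tryCatch(if (is.character(src)) readImageFile(src) else src,
                    error = function(e) {
                      warning("skipping ", id, ": ", conditionMessage(e))
                      NULL
                    })
    if (is.null(img))
      return(data.frame(id = id, maskPath = NA, overlayPath = NA,
                        foregroundFraction = NA))
    logits <- predictLogits(model, img)
    pred <- argmaxClasses(asBatch(logits))[, , 1L]
    over <- img
    fg <- pred == 1L
    over[, , 1L][fg] <- (1 - alpha) * over[, , 1L][fg] + alpha
    over[, , 2L][fg] <- (1 - alpha) * over[, , 2L][fg]
    over[, , 3L][fg] <- (1 - alpha) * over[, , 3L][fg]
    mp <- file.path(outDir, paste0(id, "_mask.png"))
    op <- file.path(outDir, paste0(id, "_overlay.png"))
    writeMaskPng(pred, mp)
    png::writePNG(over, op)
    data.frame(id = id, maskPath = mp, overlayPath = op,
               foregroundFraction = mean(fg), stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}

#' Write a metric report to JSON and CSV
#'
#' @param metrics list from [computeMetrics()] / [evaluateModel()].
#' @param jsonPath,csvPath output paths (either may be `NULL` to skip).
#' @return invisible list of written paths.
#' @export
writeMetricReport <- function(metrics, jsonPath = NULL, csvPath = NULL) {
  flat <- metrics[c("mIoU", "mPA", "accuracy", "mF1")]
  if (!is.null(metrics$fps)) flat$fps <- metrics$fps
  if (!is.null(jsonPath))
    jsonlite::write_json(flat, jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(csvPath))
    write.csv(as.data.frame(flat), csvPath, row.names = FALSE)
  invisible(list(json = jsonPath, csv = csvPath))
}
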