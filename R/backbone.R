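## Backbone assembly: parameter initialisation, forward pass, reverse-mode
## backward pass and parameter accounting for the full encoder-decoder.
##
## Parameters live in a flat named list ("enc3.conv1.W", "ema.w3",
## "feam1.alpha2", ...); buffers (batch-norm running statistics) use the
## same naming. The forward pass threads buffers through and returns them
## (they change in training mode); the backward pass accumulates gradients
## into a flat list keyed identically to the parameters, which is what the
## Adam step consumes.

heConv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout) * sqrt(2 / (k * k * cin)),
        c(k, k, cin, cout))
}

#' Build a FESW-UNet model from a configuration
#'
#' Instantiates all layers described by the configuration: five
#' double-convolution encoder stages (each conv + batch norm + ReLU), the
#' chosen downsampler between stages (max-pooling or HWD), optional SimAM
#' after every encoder stage, optional EMA on the bottleneck, optional FEAM
#' blocks on the deepest skip connections, 2x2 transposed-convolution
#' upsampling with skip concatenation, and a final 1x1 classifier.
#' Convolution weights use He-normal initialisation; FEAM spectral weights
#' start at the identity (`alpha = 1, beta = 0`) unless configured
#' otherwise.
#'
#' @param config a [FeswConfig-class] (see [feswConfig()]).
#' @param seed optional integer; when given, initialisation runs under a
#'   private RNG stream so identical seeds give identical models.
#' @return a [FeswUNet-class] model.
#' @examples
#' m <- buildModel(feswConfig(downsample = "maxpool", simam = FALSE,
#'                            ema = FALSE, feamCount = 0L), seed = 1)
#' nParameters(m)
#' @export
buildModel <- function(config, seed = NULL) {
  stopIf(!is(config, "FeswConfig"), "'config' must be a FeswConfig")
  validObject(config)
  init <- function() buildParams(config)
  pb <- if (is.null(seed)) init() else withSeed(seed, init())
  new("FeswUNet", config = config, params = pb$params, buffers = pb$buffers)
}

buildParams <- function(config) {
  w <- config@widths
  p <- list()
  buf <- list()
  addBn <- function(name, ch) {
    p[[paste0(name, ".gamma")]] <<- rep(1, ch)
    p[[paste0(name, ".beta")]] <<- numeric(ch)
    buf[[paste0(name, ".mean")]] <<- numeric(ch)
    buf[[paste0(name, ".var")]] <<- rep(1, ch)
  }
  addConv <- function(name, k, cin, cout, bias) {
    p[[paste0(name, ".W")]] <<- heConv(k, cin, cout)
    if (bias) p[[paste0(name, ".b")]] <<- numeric(cout)
  }
  ## encoder stages
  cin <- config@inChannels
  for (i in 1:5) {
    pre <- sprintf("enc%d", i)
    addConv(paste0(pre, ".conv1"), 3L, cin, w[i], config@convBias)
    addBn(paste0(pre, ".bn1"), w[i])
    addConv(paste0(pre, ".conv2"), 3L, w[i], w[i], config@convBias)
    addBn(paste0(pre, ".bn2"), w[i])
    cin <- w[i]
  }
  ## downsamplers (HWD heads carry parameters; max-pooling has none)
  if (config@downsample == "hwd") {
    for (i in 1:4) {
      pre <- sprintf("down%d", i)
      addConv(paste0(pre, ".conv"), 1L, 4L * w[i], w[i], config@hwdBias)
      addBn(paste0(pre, ".bn"), w[i])
    }
  }
  if (config@ema) {
    e <- emaInit(w[5L], config@emaGroups)
    for (nm in names(e)) p[[paste0("ema.", nm)]] <- e[[nm]]
  }
  if (config@feamCount > 0L) {
    for (j in seq_len(config@feamCount)) {
      ch <- w[5L - j] # deepest skip first: 512, 256, 128, 64
      f <- feamInit(config@feamScales[[j]], ch,
                    reduction = config@feamGateReduction,
                    init = config@feamInit)
      for (s in seq_along(f$alpha)) {
        p[[sprintf("feam%d.alpha%d", j, s)]] <- f$alpha[[s]]
        p[[sprintf("feam%d.beta%d", j, s)]] <- f$beta[[s]]
      }
      for (nm in names(f$gate))
        p[[sprintf("feam%d.gate.%s", j, nm)]] <- f$gate[[nm]]
    }
  }
  ## decoder: upsample + double conv, deepest level first
  for (lev in 4:1) {
    upre <- sprintf("up%d", lev)
    cinUp <- if (lev == 4L) w[5L] else w[lev + 1L]
    p[[paste0(upre, ".W")]] <- array(
      rnorm(4L * w[lev] * cinUp) * sqrt(2 / (4 * cinUp)),
      c(2L, 2L, w[lev], cinUp))
    if (config@upBias) p[[paste0(upre, ".b")]] <- numeric(w[lev])
    dpre <- sprintf("dec%d", lev)
    addConv(paste0(dpre, ".conv1"), 3L, 2L * w[lev], w[lev], config@convBias)
    addBn(paste0(dpre, ".bn1"), w[lev])
    addConv(paste0(dpre, ".conv2"), 3L, w[lev], w[lev], config@convBias)
    addBn(paste0(dpre, ".bn2"), w[lev])
  }
  addConv("final", 1L, w[1L], config@classes, TRUE)
  list(params = p, buffers = buf)
}

## conv (+ optional bias) + BN + ReLU, threading flat buffers. In
## inference mode the batch-norm affine (from running statistics) and the
## ReLU are folded into the convolution kernel's output pass.
cbrForward <- function(x, p, buf, convName, bnName, training) {
  w <- p[[paste0(convName, ".W")]]
  b <- p[[paste0(convName, ".b")]] %||% numeric(dim(w)[4L])
  if (!training) {
    a <- p[[paste0(bnName, ".gamma")]] /
      sqrt(buf[[paste0(bnName, ".var")]] + 1e-5)
    sh <- p[[paste0(bnName, ".beta")]] - buf[[paste0(bnName, ".mean")]] * a
    y <- convForward(x, w, b, postA = a, postB = sh, relu = TRUE)
    return(list(y = y, buf = buf, cache = NULL))
  }
  z <- convForward(x, w, b)
  bn <- bnForward(z, p[[paste0(bnName, ".gamma")]],
                  p[[paste0(bnName, ".beta")]],
                  list(mean = buf[[paste0(bnName, ".mean")]],
                       var = buf[[paste0(bnName, ".var")]]),
                  training)
  buf[[paste0(bnName, ".mean")]] <- bn$buffers$mean
  buf[[paste0(bnName, ".var")]] <- bn$buffers$var
  list(y = reluForward(bn$y), buf = buf,
       cache = list(x = x, z = bn$y, bn = bn$cache))
}

cbrBackward <- function(dy, p, cache, convName, bnName, genv, needDx = TRUE) {
  dz <- reluBackward(cache$z, dy)
  bb <- bnBackward(cache$bn, dz)
  addGrad(genv, paste0(bnName, ".gamma"), bb$dgamma)
  addGrad(genv, paste0(bnName, ".beta"), bb$dbeta)
  cv <- convBackward(cache$x, p[[paste0(convName, ".W")]], bb$dx, needDx)
  addGrad(genv, paste0(convName, ".W"), cv$dw)
  if (!is.null(p[[paste0(convName, ".b")]]))
    addGrad(genv, paste0(convName, ".b"), cv$db)
  if (needDx) cv$dx else NULL
}

addGrad <- function(genv, name, g) {
  if (is.null(genv[[name]])) genv[[name]] <- g
  else genv[[name]] <- genv[[name]] + g
}

feamView <- function(p, j, config) {
  nS <- length(config@feamScales[[j]])
  list(alpha = lapply(seq_len(nS), function(s)
         p[[sprintf("feam%d.alpha%d", j, s)]]),
       beta = lapply(seq_len(nS), function(s)
         p[[sprintf("feam%d.beta%d", j, s)]]),
       gate = list(W1 = p[[sprintf("feam%d.gate.W1", j)]],
                   b1 = p[[sprintf("feam%d.gate.b1", j)]],
                   W2 = p[[sprintf("feam%d.gate.W2", j)]],
                   b2 = p[[sprintf("feam%d.gate.b2", j)]]))
}

## Full forward pass. x: (H, W, C, N). Returns logits, updated buffers and
## (optionally) all caches needed by feswBackward.
feswForward <- function(config, p, buf, x, training = FALSE,
                        keepCache = FALSE) {
  d <- dim(x)
  stopIf(d[1L] %% 16L != 0L || d[2L] %% 16L != 0L,
         "input spatial dimensions must be divisible by 16 ",
         "(four 2x downsampling stages); got ", d[1L], "x", d[2L])
  stopIf(d[3L] != config@inChannels,
         "input has ", d[3L], " channels; config expects ",
         config@inChannels)
  w <- config@widths
  cache <- list(enc = vector("list", 5L), down = vector("list", 4L),
                feam = vector("list", config@feamCount))
  skips <- vector("list", 4L)
  h <- x
  for (i in 1:5) {
    if (i > 1L) {
      if (config@downsample == "maxpool") {
        mp <- maxpoolForward(h)
        h <- mp$y
        if (keepCache) cache$down[[i - 1L]] <- mp$cache
      } else {
        pre <- sprintf("down%d", i - 1L)
        hw <- hwdApply(h, list(W = p[[paste0(pre, ".conv.W")]],
                               b = p[[paste0(pre, ".conv.b")]] %||%
                                 numeric(w[i - 1L]),
                               gamma = p[[paste0(pre, ".bn.gamma")]],
                               beta = p[[paste0(pre, ".bn.beta")]]),
                       list(mean = buf[[paste0(pre, ".bn.mean")]],
                            var = buf[[paste0(pre, ".bn.var")]]),
                       training)
        buf[[paste0(pre, ".bn.mean")]] <- hw$buffers$mean
        buf[[paste0(pre, ".bn.var")]] <- hw$buffers$var
        h <- hw$y
        if (keepCache) cache$down[[i - 1L]] <- hw$cache
      }
    }
    pre <- sprintf("enc%d", i)
    c1 <- cbrForward(h, p, buf, paste0(pre, ".conv1"), paste0(pre, ".bn1"),
                     training)
    buf <- c1$buf
    c2 <- cbrForward(c1$y, p, buf, paste0(pre, ".conv2"), paste0(pre, ".bn2"),
                     training)
    buf <- c2$buf
    h <- c2$y
    sa <- NULL
    if (config@simam) {
      sa <- h # pre-attention activations, needed for the backward pass
      h <- h * simamWeights(h, config@simamLambda)
    }
    if (keepCache) cache$enc[[i]] <- list(c1 = c1$cache, c2 = c2$cache,
                                          simamIn = sa)
    if (i < 5L) skips[[i]] <- h
  }
  if (config@ema) {
    em <- emaApply(h, emaParams(p), config@emaGroups)
    if (keepCache) cache$ema <- em$cache
    h <- em$y
  }
  ## FEAM on the deepest `feamCount` skips (block j -> encoder stage 5 - j)
  if (config@feamCount > 0L) {
    for (j in seq_len(config@feamCount)) {
      lev <- 5L - j
      fa <- feamApply(skips[[lev]], feamView(p, j, config),
                      keepCache = keepCache)
      skips[[lev]] <- fa$y
      if (keepCache) cache$feam[[j]] <- fa$cache
    }
  }
  cache$dec <- vector("list", 4L)
  for (lev in 4:1) {
    upre <- sprintf("up%d", lev)
    up <- convTransposeForward(h, p[[paste0(upre, ".W")]],
                               p[[paste0(upre, ".b")]] %||% numeric(w[lev]))
    skip <- skips[[lev]]
    cat <- array(0, c(dim(up)[1:2], 2L * w[lev], dim(up)[4L]))
    cat[, , seq_len(w[lev]), ] <- skip
    cat[, , w[lev] + seq_len(w[lev]), ] <- up
    dpre <- sprintf("dec%d", lev)
    c1 <- cbrForward(cat, p, buf, paste0(dpre, ".conv1"),
                     paste0(dpre, ".bn1"), training)
    buf <- c1$buf
    c2 <- cbrForward(c1$y, p, buf, paste0(dpre, ".conv2"),
                     paste0(dpre, ".bn2"), training)
    buf <- c2$buf
    if (keepCache) cache$dec[[lev]] <- list(upIn = h, c1 = c1$cache,
                                            c2 = c2$cache)
    h <- c2$y
  }
  logits <- convForward(h, p[["final.W"]], p[["final.b"]])
  if (keepCache) cache$finalIn <- h
  list(logits = logits, buffers = buf, cache = cache)
}

emaParams <- function(p) {
  list(w1 = p[["ema.w1"]], b1 = p[["ema.b1"]], w3 = p[["ema.w3"]],
       b3 = p[["ema.b3"]], gamma = p[["ema.gamma"]], beta = p[["ema.beta"]])
}

## Full backward pass; returns flat gradient list matching names(p).
feswBackward <- function(config, p, cache, dlogits) {
  w <- config@widths
  genv <- new.env(parent = emptyenv())
  fb <- convBackward(cache$finalIn, p[["final.W"]], dlogits, needDx = TRUE)
  addGrad(genv, "final.W", fb$dw)
  addGrad(genv, "final.b", fb$db)
  dh <- fb$dx
  dskips <- vector("list", 4L)
  for (lev in 1:4) {
    dpre <- sprintf("dec%d", lev)
    d2 <- cbrBackward(dh, p, cache$dec[[lev]]$c2, paste0(dpre, ".conv2"),
                      paste0(dpre, ".bn2"), genv)
    dcat <- cbrBackward(d2, p, cache$dec[[lev]]$c1, paste0(dpre, ".conv1"),
                        paste0(dpre, ".bn1"), genv)
    dskips[[lev]] <- dcat[, , seq_len(w[lev]), , drop = FALSE]
    dup <- dcat[, , w[lev] + seq_len(w[lev]), , drop = FALSE]
    upre <- sprintf("up%d", lev)
    tb <- convTransposeBackward(cache$dec[[lev]]$upIn,
                                p[[paste0(upre, ".W")]], dup)
    addGrad(genv, paste0(upre, ".W"), tb$dw)
    if (!is.null(p[[paste0(upre, ".b")]]))
      addGrad(genv, paste0(upre, ".b"), tb$db)
    dh <- tb$dx
  }
  ## dh now flows into the bottleneck output (after EMA); dskips into the
  ## (possibly FEAM-processed) skip tensors.
  if (config@feamCount > 0L) {
    for (j in seq_len(config@feamCount)) {
      lev <- 5L - j
      fv <- feamView(p, j, config)
      bf <- feamBackward(fv, cache$feam[[j]], dskips[[lev]])
      dskips[[lev]] <- bf$dx
      for (s in seq_along(bf$grads$alpha)) {
        addGrad(genv, sprintf("feam%d.alpha%d", j, s), bf$grads$alpha[[s]])
        addGrad(genv, sprintf("feam%d.beta%d", j, s), bf$grads$beta[[s]])
      }
      for (nm in names(bf$grads$gate))
        addGrad(genv, sprintf("feam%d.gate.%s", j, nm), bf$grads$gate[[nm]])
    }
  }
  if (config@ema) {
    eb <- emaBackward(emaParams(p), cache$ema, dh)
    for (nm in names(eb$grads)) addGrad(genv, paste0("ema.", nm),
                                        eb$grads[[nm]])
    dh <- eb$dx
  }
  for (i in 5:1) {
    ec <- cache$enc[[i]]
    ## skips branch off after SimAM, so dskips[[i]] was already merged into
    ## dh when the downsampler of stage i+1 was reversed.
    if (config@simam)
      dh <- simamBackward(ec$simamIn, dh, config@simamLambda)
    pre <- sprintf("enc%d", i)
    d2 <- cbrBackward(dh, p, ec$c2, paste0(pre, ".conv2"),
                      paste0(pre, ".bn2"), genv)
    dh <- cbrBackward(d2, p, ec$c1, paste0(pre, ".conv1"),
                      paste0(pre, ".bn1"), genv, needDx = i > 1L)
    if (i > 1L) {
      if (config@downsample == "maxpool") {
        dh <- maxpoolBackward(cache$down[[i - 1L]], dh)
      } else {
        dpre <- sprintf("down%d", i - 1L)
        hb <- hwdBackward(list(W = p[[paste0(dpre, ".conv.W")]]),
                          cache$down[[i - 1L]], dh)
        addGrad(genv, paste0(dpre, ".conv.W"), hb$grads$W)
        if (!is.null(p[[paste0(dpre, ".conv.b")]]))
          addGrad(genv, paste0(dpre, ".conv.b"), hb$grads$b)
        addGrad(genv, paste0(dpre, ".bn.gamma"), hb$grads$gamma)
        addGrad(genv, paste0(dpre, ".bn.beta"), hb$grads$beta)
        dh <- hb$dx
      }
      ## the stage output feeding this downsampler is also the skip source
      dh <- dh + dskips[[i - 1L]]
    }
  }
  grads <- as.list(genv)
  grads[names(p)[names(p) %in% names(grads)]]
}
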