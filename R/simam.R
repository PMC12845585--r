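#' Per-neuron minimum-energy map (SimAM)
#'
#' Computes the closed-form minimum of the SimAM linear-separability energy
#' for every neuron of a single channel plane. For neuron value `t` the
#' energy is
#' \deqn{e^*_t = \frac{4(\sigma_t^2 + \lambda)}{(t - \mu_t)^2 + 2\sigma_t^2
#'   + 2\lambda}}
#' where \eqn{\mu_t} and \eqn{\sigma_t^2} are the mean and (population)
#' variance of the *other* `M - 1` neurons of the plane, i.e. the deviation
#' of each neuron from its own neighbourhood. With these leave-one-out
#' statistics the formula is the exact minimiser of the canonical two-target
#' energy (target +1 for the neuron, -1 for its neighbours, ridge penalty
#' \eqn{\lambda w^2}), which the test suite verifies by brute-force numeric
#' minimisation. A constant plane has energy exactly 2 everywhere.
#'
#' Low energy marks neurons that stand out from their surroundings; the
#' attention weight used by [simamApply()] is `sigmoid(1 / e)`.
#'
#' @param plane numeric matrix (a single channel of a feature map) with at
#'   least 2 elements.
#' @param lambda positive regularisation scalar (default `1e-4`).
#' @return numeric matrix of energies, same shape as `plane`, all values
#'   strictly positive; the regularisation used is attached as attribute
#'   `"lambda"`.
#' @seealso [simamApply()]
#' @examples
#' e <- simamEnergy(matrix(rnorm(25), 5), lambda = 1e-4)
#' stopifnot(all(e > 0))
#' all(abs(simamEnergy(matrix(3, 4, 4)) - 2) < 1e-12) # constant plane
#' @export
simamEnergy <- function(plane, lambda = 1e-4) {
  stopIf(!is.numeric(plane) || length(plane) < 2L,
         "'plane' must be numeric with at least 2 elements")
  stopIf(!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0,
         "'lambda' must be a positive scalar")
  M <- length(plane)
  st <- simamStats(as.vector(plane), M)
  e <- 4 * (st$v + lambda) / (st$d^2 + 2 * st$v + 2 * lambda)
  e <- array(e, dim(plane) %||% length(plane))
  attr(e, "lambda") <- lambda
  e
}

## Leave-one-out mean/variance and deviation for every element of a plane
## (vectorised; `x` a numeric vector of length M >= 2).
simamStats <- function(x, M) {
  s1 <- sum(x)
  s2 <- sum(x * x)
  mu <- (s1 - x) / (M - 1)
  v <- pmax(((s2 - x * x) - (M - 1) * mu^2) / (M - 1), 0)
  list(mu = mu, v = v, d = x - mu, s1 = s1, s2 = s2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply SimAM attention to a feature map
#'
#' Re-weights a feature map with the sigmoid of the inverse energy map,
#' independently per channel: `X' = sigmoid(1/E) * X`. The operation has no
#' learnable parameters; inserting it into a model leaves the parameter
#' count unchanged. Attention weights lie strictly in (0, 1), so the output
#' never exceeds the input in magnitude, and a constant channel of value `v`
#' maps to `sigmoid(0.5) * v` (about `0.62246 v`).
#'
#' @param x feature map, numeric array `(H, W, C)` or batch `(H, W, C, N)`
#'   with `H * W >= 2`.
#' @param lambda positive regularisation scalar passed to the energy.
#' @return array of the same shape as `x`.
#' @export
simamApply <- function(x, lambda = 1e-4) {
  nd <- length(dim(x))
  stopIf(!(nd %in% c(3L, 4L)), "'x' must be an (H,W,C) or (H,W,C,N) array")
  stopIf(lambda <= 0, "'lambda' must be positive")
  x3 <- nd == 3L
  x <- asBatch(x)
  y <- x * simamWeights(x, lambda)
  if (x3) dim(y) <- dim(y)[1:3]
  y
}

## Attention weights sigmoid(1/e*) for every neuron of a batch, vectorised
## over channels and samples.
simamWeights <- function(x, lambda) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  stopIf(hw < 2L, "SimAM needs at least 2 spatial positions per channel")
  M <- hw
  s1 <- broadcastCN(planeSums(x), hw)
  s2 <- broadcastCN(planeSums(x * x), hw)
  mu <- (s1 - x) / (M - 1)
  v <- pmax(((s2 - x * x) - (M - 1) * mu^2) / (M - 1), 0)
  dd <- x - mu
  ginv <- (dd^2 + 2 * v + 2 * lambda) / (4 * (v + lambda)) # = 1 / e*
  array(sigmoid(ginv), d)
}

## Exact reverse-mode gradient of y = x * sigmoid(g(x)) where g is the
## inverse-energy map with leave-one-out statistics. Every output depends on
## every input of its plane through the plane sums S1 = sum(x), S2 = sum(x^2);
## writing g_t = G(t, S1, S2) the vector-Jacobian product needs only the
## plane-wise sums of c_t dG/dS1 and c_t dG/dS2 (c_t = dy_t x_t a_t (1-a_t)).
simamBackward <- function(x, dy, lambda) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  M <- hw
  s1 <- broadcastCN(planeSums(x), hw)
  s2 <- broadcastCN(planeSums(x * x), hw)
  mu <- (s1 - x) / (M - 1)
  v <- ((s2 - x * x) - (M - 1) * mu^2) / (M - 1)
  v <- pmax(v, 0)
  dd <- x - mu
  den <- 4 * (v + lambda)
  num <- dd^2 + 2 * v + 2 * lambda
  g <- num / den
  a <- sigmoid(g)
  cc <- dy * x * a * (1 - a)
  dgd <- 2 * dd / den
  dgv <- (2 * den - 4 * num) / den^2
  ## total derivatives of d and v w.r.t. (t, S1, S2)
  G1 <- dgd * (M / (M - 1)) + dgv * (-2 * dd / (M - 1))
  G2 <- dgd * (-1 / (M - 1)) + dgv * (-2 * mu / (M - 1))
  G3 <- dgv / (M - 1)
  sum2 <- broadcastCN(planeSums(array(cc * G2, d)), hw)
  sum3 <- broadcastCN(planeSums(array(cc * G3, d)), hw)
  array(a * dy + cc * G1 + sum2 + 2 * x * sum3, d)
}
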