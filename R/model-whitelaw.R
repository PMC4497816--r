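# ---------------------------------------------------------------------------
# Whitelaw model: Hebbian weight dynamics driven by circular retinal waves,
# chemospecific adhesion, lateral SC smoothing, and ordered dual
# normalization (SC first, then RGC).
# ---------------------------------------------------------------------------

#' Chemospecific adhesion matrix
#'
#' \eqn{M_{ij} = R_A(r_i)[\max_k L_A(s_k) - L_A(s_j)] + R_B(r_i) L_B(s_j)}:
#' the A system enters repulsively (adhesion highest where ephrin-A is
#' lowest) and the B system attractively; all entries are nonnegative, as
#' required by the Hebbian update.
#'
#' @param substrate a [build_substrate()] object.
#' @return dense `n_r` x `n_sc` matrix.
#' @export
adhesion_matrix <- function(substrate) {
  r <- substrate$retina; s <- substrate$sc
  outer(r$R_A, max(s$L_A) - s$L_A) + outer(r$R_B, s$L_B)
}

#' Retinal wave activity centred on one RGC
#'
#' RGCs within radius `r_r` of RGC `q` (including `q`) are active with a
#' common level `2 / |neigh|`, normalizing the summed retinal activity of
#' every wave to exactly 2.
#'
#' @param q wave-centre RGC index.
#' @param substrate the substrate.
#' @param r_r wave radius.
#' @return activity vector of length `n_r`.
#' @export
wave_activity <- function(q, substrate, r_r = 0.07) {
  r <- substrate$retina
  d2 <- (r$x - r$x[q])^2 + (r$y - r$y[q])^2
  nb <- d2 <= r_r^2
  x <- numeric(substrate$n_r)
  x[nb] <- 2 / sum(nb)
  x
}

# precompute the epoch-invariant structures: adhesion, the wave matrix XR
# (row q = activity vector of wave q) and the SC smoothing matrix S
# (row j = k/|neigh(s_j)| over neigh(s_j))
.whitelaw_precompute <- function(substrate, r_r, r_sc, k) {
  r <- substrate$retina; s <- substrate$sc
  n_r <- substrate$n_r; n_sc <- substrate$n_sc
  dr2 <- outer(r$x, r$x, "-")^2 + outer(r$y, r$y, "-")^2
  nbR <- dr2 <= r_r^2
  XR <- Matrix::Matrix(nbR * (2 / rowSums(nbR)), sparse = TRUE)
  ds2 <- outer(s$x, s$x, "-")^2 + outer(s$y, s$y, "-")^2
  nbS <- ds2 <= r_sc^2
  S <- Matrix::Matrix(nbS * (k / rowSums(nbS)), sparse = TRUE)
  list(M1 = adhesion_matrix(substrate) + 1, XR = XR, S = S,
       n_r = n_r, n_sc = n_sc)
}

# one epoch given precomputed structures; returns list(W, delta)
.whitelaw_epoch_fast <- function(W, pre, dt, mu, w_min) {
  # y^I for every wave centre at once: row q of YI is W^T x^(q)
  YI <- as.matrix(pre$XR %*% W)          # n_r x n_sc
  Y <- as.matrix(YI %*% Matrix::t(pre$S)) # lateral smoothing, row q = y^(q)
  A <- as.matrix(Matrix::crossprod(pre$XR, Y)) # sum_q x^(q) y^(q)^T
  v <- colSums(Y)                         # sum_q y^(q)
  dW <- dt * (pre$M1 * A - mu * matrix(v, pre$n_r, pre$n_sc, byrow = TRUE))
  W <- W + dW
  W[W < w_min] <- 0
  # normalization: per SC neuron first, then per RGC (order is essential for
  # the knock-in double map)
  cs <- colSums(W)
  nz <- cs > 0
  if (any(nz)) W[, nz] <- W[, nz] * rep(pre$n_r / cs[nz], each = pre$n_r)
  rs <- rowSums(W)
  nzr <- rs > 0
  if (any(nzr)) W[nzr, ] <- W[nzr, ] * (pre$n_sc / rs[nzr])
  list(W = W, delta = sum(abs(dW)), n_thresholded = sum(W == 0))
}

#' One Whitelaw epoch
#'
#' Sweeps every RGC once as wave centre, accumulating the Hebbian update
#' \eqn{\Delta W_{ij} = \Delta t\,[(M_{ij}+1) x_i y_j - \mu y_j]} over the
#' epoch and applying it once; then zeroes entries below `w_min` and
#' normalizes totals per SC neuron (to `n_r`) followed by per RGC (to
#' `n_sc`). Zero columns/rows are skipped by the normalization.
#'
#' @param W current weight matrix.
#' @param substrate the substrate.
#' @param dt integration time step.
#' @param mu weight decay rate.
#' @param r_r,r_sc retinal wave and SC interaction radii.
#' @param k lateral proportionality constant.
#' @param w_min threshold below which weights are zeroed.
#' @return the updated weight matrix.
#' @export
whitelaw_epoch <- function(W, substrate, dt = 1e-4, mu = 0.1, r_r = 0.07,
                           r_sc = 0.0289, k = 0.5, w_min = 1e-5) {
  pre <- .whitelaw_precompute(substrate, r_r, r_sc, k)
  .whitelaw_epoch_fast(W, pre, dt, mu, w_min)$W
}

#' Run the Whitelaw model
#'
#' Starts fully connected with all weights 1 and iterates [whitelaw_epoch()]
#' dynamics. The number of epochs is a convergence choice (monitored via the
#' per-epoch total weight change); the dynamics themselves are
#' deterministic given the substrate.
#'
#' @param substrate a [build_substrate()] object.
#' @param n_epochs number of epochs.
#' @param dt time step per wave activation.
#' @param mu weight decay rate.
#' @param r_r,r_sc retinal wave and SC interaction radii.
#' @param k lateral proportionality constant (the induced SC activity is
#'   scaled below the retinal input level).
#' @param w_min minimum synapse strength.
#' @param seed stored for provenance (the dynamics draw no random numbers).
#' @return a [connection_state()] with continuous weights.
#' @export
run_whitelaw <- function(substrate, n_epochs = 500, dt = 1e-4, mu = 0.1,
                         r_r = 0.07, r_sc = 0.0289, k = 0.5, w_min = 1e-5,
                         seed = 1) {
  stopifnot(inherits(substrate, "substrate"))
  pre <- .whitelaw_precompute(substrate, r_r, r_sc, k)
  W <- matrix(1, substrate$n_r, substrate$n_sc)
  delta <- numeric(n_epochs); nthr <- numeric(n_epochs)
  for (ep in seq_len(n_epochs)) {
    res <- .whitelaw_epoch_fast(W, pre, dt, mu, w_min)
    W <- res$W
    delta[ep] <- res$delta; nthr[ep] <- res$n_thresholded
  }
  connection_state(
    W, "whitelaw",
    params = list(dt = dt, mu = mu, r_r = r_r, r_sc = r_sc, k = k,
                  w_min = w_min, n_epochs = n_epochs),
    log = data.frame(epoch = seq_len(n_epochs), sum_abs_dW = delta,
                     n_zero = nthr),
    seed = seed, w_min = w_min)
}
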