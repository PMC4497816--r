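# ---------------------------------------------------------------------------
# Gierer model: potential-descent movement of a fixed number of terminals per
# RGC over the SC Delaunay graph, with bounded competition.
# ---------------------------------------------------------------------------

#' Gierer potential at an SC neuron
#'
#' \eqn{p(r_i, s_j) = R_A(r_i) L_A(s_j) - R_B(r_i) L_B(s_j) + c(s_j)}:
#' the A system is repulsive (potential grows with concentration), the B
#' system attractive, and `c` is the local competition level.
#'
#' @param substrate a [build_substrate()] object.
#' @param i RGC index (may be a vector).
#' @param j SC neuron index (same length as `i`, or one of the two scalar).
#' @param c competition levels per SC neuron (default all zero).
#' @return potential values.
#' @export
gierer_potential <- function(substrate, i, j, c = rep(0, substrate$n_sc)) {
  r <- substrate$retina; s <- substrate$sc
  r$R_A[i] * s$L_A[j] - r$R_B[i] * s$L_B[j] + c[j]
}

#' One Gierer epoch (reference implementation)
#'
#' Visits every terminal once in a fresh random order; a terminal moves to
#' the Delaunay neighbour of its current SC neuron with the lowest potential
#' if that potential is strictly lower than at its current position (ties
#' among equally minimal neighbours broken uniformly at random). After the
#' sweep the competition level is advanced by one explicit-Euler step of
#' \eqn{dc/dt = \epsilon \rho - \eta c} with unit time step, where
#' \eqn{\rho} is the terminal count per SC neuron.
#'
#' This R implementation defines the per-epoch semantics and serves as the
#' readable reference; [run_gierer()] uses an equivalent compiled core.
#'
#' @param state list with `assign` (integer matrix `n_term` x `n_r` of SC
#'   indices), `c` (competition per SC neuron), and `adjacency` (list of
#'   neighbour index vectors).
#' @param substrate the substrate.
#' @param eps,eta competition growth and decay rates.
#' @return the updated state (with `rho` and `moves` fields refreshed).
#' @export
gierer_epoch <- function(state, substrate, eps = 0.005, eta = 0.1) {
  assign <- state$assign
  c_lev <- state$c
  adj <- state$adjacency
  r <- substrate$retina; s <- substrate$sc
  n_term <- nrow(assign); n_r <- ncol(assign)
  ord <- sample.int(n_term * n_r)
  moves <- 0L
  for (t in ord) {
    i <- ((t - 1L) %/% n_term) + 1L
    slot <- ((t - 1L) %% n_term) + 1L
    j <- assign[slot, i]
    p_cur <- r$R_A[i] * s$L_A[j] - r$R_B[i] * s$L_B[j] + c_lev[j]
    nb <- adj[[j]]
    if (length(nb) == 0) next
    p_nb <- r$R_A[i] * s$L_A[nb] - r$R_B[i] * s$L_B[nb] + c_lev[nb]
    p_min <- min(p_nb)
    if (p_min < p_cur) {
      cand <- nb[p_nb == p_min]
      pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1)] else cand
      assign[slot, i] <- pick
      moves <- moves + 1L
    }
  }
  rho <- tabulate(assign, nbins = substrate$n_sc)
  c_lev <- c_lev + eps * rho - eta * c_lev
  state$assign <- assign
  state$c <- c_lev
  state$rho <- rho
  state$moves <- moves
  state
}

#' Run the Gierer model
#'
#' Initializes each RGC with `n_term` terminals on uniformly random SC
#' neurons and iterates [gierer_epoch()] dynamics for `n_epochs` epochs
#' (compiled core). Competition starts at zero.
#'
#' @param substrate a [build_substrate()] object.
#' @param n_epochs number of epochs (default 10000, at which full-scale maps
#'   have converged as judged by the \eqn{c \to (\epsilon/\eta)\rho} gauge).
#' @param n_term terminals per RGC.
#' @param eps,eta competition growth and decay rates.
#' @param c_update competition discretization. `"continuous"` (default)
#'   integrates \eqn{dc/dt = \epsilon\rho - \eta c} exactly between terminal
#'   examinations (the terminal count \eqn{\rho} is piecewise constant, so
#'   the ODE has a closed-form solution on each interval); one epoch still
#'   advances time by 1. `"epoch"` freezes `c` during the sweep and applies
#'   a single Euler step per epoch; at the reference parameter values this
#'   variant is dynamically unstable (terminals of all RGCs make identical
#'   decisions against the stale competition field and aggregate into a
#'   single travelling blob), and is retained for comparison only.
#' @param seed RNG seed.
#' @return a [connection_state()] with integer weights
#'   \eqn{W_{ij} = } number of terminals of RGC `i` on SC neuron `j`
#'   (so every row sums to `n_term`); auxiliary state holds the final
#'   competition levels and terminal assignment.
#' @export
run_gierer <- function(substrate, n_epochs = 10000, n_term = 16,
                       eps = 0.005, eta = 0.1,
                       c_update = c("continuous", "epoch"), seed = 1) {
  stopifnot(inherits(substrate, "substrate"))
  c_update <- match.arg(c_update)
  set.seed(seed)
  dl <- delaunay(substrate$sc$x, substrate$sc$y)
  csr <- .adjacency_csr(dl$edges, substrate$n_sc)
  init <- sample.int(substrate$n_sc, substrate$n_r * n_term,
                     replace = TRUE) - 1L
  res <- gierer_run_cpp(substrate$retina$R_A, substrate$retina$R_B,
                        substrate$sc$L_A, substrate$sc$L_B,
                        csr$ptr, csr$idx, n_term, eps, eta, n_epochs,
                        init, rep(0, substrate$n_sc),
                        continuous = c_update == "continuous")
  assign <- res$assign + 1L
  i_idx <- rep(seq_len(substrate$n_r), each = n_term)
  W <- Matrix::sparseMatrix(i = i_idx, j = assign, x = 1,
                            dims = c(substrate$n_r, substrate$n_sc))
  connection_state(
    W, "gierer",
    params = list(n_term = n_term, eps = eps, eta = eta,
                  n_epochs = n_epochs),
    log = data.frame(epoch = seq_len(n_epochs), moves = res$moves,
                     c_deviation = res$c_deviation),
    aux = list(c = res$c, rho = res$rho,
               assign = matrix(assign, nrow = n_term)),
    seed = seed)
}
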