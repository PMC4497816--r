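# ---------------------------------------------------------------------------
# Willshaw marker-induction model: retinal receptor profiles are carried into
# the SC through the synaptic weights ("induced markers") and drive plastic
# SC ligand fields T^A, T^B; weights grow with the receptor/marker
# similarity under presynaptic normalization.
# ---------------------------------------------------------------------------

#' Laplacian neighbour graph for the marker diffusion
#'
#' Delaunay triangulation of the SC neuron positions with sliver shortcut
#' edges pruned via [prune_sliver_edges()].
#'
#' @param substrate the substrate.
#' @param min_angle pruning threshold in degrees.
#' @return list with `edges` (two-column integer matrix) and `adjacency`
#'   (list of neighbour vectors).
#' @export
willshaw_graph <- function(substrate, min_angle = 10) {
  dl <- delaunay(substrate$sc$x, substrate$sc$y)
  edges <- prune_sliver_edges(dl$triangles, substrate$sc$x, substrate$sc$y,
                              min_angle)
  list(edges = edges, adjacency = .adjacency(edges, substrate$n_sc))
}

#' Induced markers at SC neurons
#'
#' \eqn{I^X_j = \sum_k W_{kj} R_X(r_k) / \sum_k W_{kj}}: the weighted mean
#' of the presynaptic receptor densities. SC neurons with zero afferent
#' weight are flagged (`NA` here; the simulation core carries the previous
#' value forward).
#'
#' @param W weight matrix.
#' @param substrate the substrate.
#' @return list with vectors `IA`, `IB` and logical `zero_afferent`.
#' @export
induced_markers <- function(W, substrate) {
  cs <- colSums(W)
  IA <- as.numeric(crossprod(W, substrate$retina$R_A)) / cs
  IB <- as.numeric(crossprod(W, substrate$retina$R_B)) / cs
  zero <- cs == 0
  IA[zero] <- NA_real_; IB[zero] <- NA_real_
  list(IA = IA, IB = IB, zero_afferent = zero)
}

#' One marker production/diffusion step (reference implementation)
#'
#' \eqn{\Delta T^A = (\sigma(1 - \zeta I^A T^A) + \delta \nabla^2 T^A)\Delta t},
#' \eqn{\Delta T^B = (\sigma(I^B - T^B) + \delta \nabla^2 T^B)\Delta t}, with
#' the graph Laplacian \eqn{\nabla^2 T_j = \sum_{n \in nbrs(j)} (T_n - T_j)}.
#'
#' @param TA,TB current marker fields.
#' @param IA,IB induced markers.
#' @param adjacency neighbour list from [willshaw_graph()].
#' @param sigma,delta,zeta,dt parameters.
#' @return list with updated `TA`, `TB`.
#' @export
marker_step <- function(TA, TB, IA, IB, adjacency, sigma = 0.05,
                        delta = 0.01, zeta = 1, dt = 0.1) {
  lap <- function(T) vapply(seq_along(T), function(j) {
    nb <- adjacency[[j]]
    if (length(nb) == 0) 0 else sum(T[nb] - T[j])
  }, numeric(1))
  dTA <- (sigma * (1 - zeta * IA * TA) + delta * lap(TA)) * dt
  dTB <- (sigma * (IB - TB) + delta * lap(TB)) * dt
  list(TA = TA + dTA, TB = TB + dTB)
}

#' Receptor/marker similarity
#'
#' \eqn{\Phi_{ij} = \exp(-[(\zeta R_A(r_i) T^A_j - 1)^2 +
#' (R_B(r_i) - T^B_j)^2] / 2\kappa^2)}; maximal (=1) at a perfect match
#' \eqn{\zeta R_A T^A = 1,\; R_B = T^B}.
#'
#' @param substrate the substrate.
#' @param TA,TB marker fields.
#' @param zeta,kappa parameters.
#' @return dense `n_r` x `n_sc` matrix.
#' @export
willshaw_similarity <- function(substrate, TA, TB, zeta = 1, kappa = 0.0504) {
  r <- substrate$retina
  exp(-(outer(zeta * r$R_A, TA, function(p, q) (p * q - 1)^2) +
          outer(r$R_B, TB, function(p, q) (p - q)^2)) / (2 * kappa^2))
}

#' One weight update step (reference implementation)
#'
#' \eqn{W_{ij} \leftarrow (W_{ij} + \theta \Delta t \Phi_{ij}) /
#' \sum_k (W_{ik} + \theta \Delta t \Phi_{ik})}; per-RGC weight sums are
#' exactly 1 after the step.
#'
#' @param W weight matrix.
#' @param Phi similarity matrix from [willshaw_similarity()].
#' @param theta,dt parameters.
#' @return updated weight matrix.
#' @export
weight_step <- function(W, Phi, theta = 0.1, dt = 0.1) {
  W2 <- W + theta * dt * Phi
  W2 / rowSums(W2)
}

#' Run the Willshaw (marker induction) model
#'
#' Initial weights are independent uniform draws from `[0, 1e-4]`; the
#' plastic SC markers start at the standard ligand gradients
#' (\eqn{T^A = L_A}, \eqn{T^B = L_B}), which also provides the weak
#' orientation bias (for the TKO genotype the `K`-scaled gradient itself is
#' the bias). Each step applies, in order: induced markers, marker
#' production/diffusion, weight update.
#'
#' @param substrate a [build_substrate()] object.
#' @param n_steps number of steps (the reference full-scale runs use 48000).
#' @param dt integration time step.
#' @param sigma,delta induced-marker source and diffusion strengths.
#' @param theta weight update speed.
#' @param zeta scale of the marker/ligand interaction.
#' @param kappa sharpness of the receptor-ligand comparison.
#' @param w_min analysis threshold for weights.
#' @param min_angle Laplacian-graph edge pruning threshold (degrees).
#' @param seed RNG seed (initial weights).
#' @return a [connection_state()] with continuous weights (per-RGC sums 1);
#'   auxiliary state holds the final marker fields `TA`, `TB`.
#' @export
run_willshaw <- function(substrate, n_steps = 48000, dt = 0.1, sigma = 0.05,
                         delta = 0.01, theta = 0.1, zeta = 1, kappa = 0.0504,
                         w_min = 0.001, min_angle = 10, seed = 1) {
  stopifnot(inherits(substrate, "substrate"))
  set.seed(seed)
  W0 <- matrix(runif(substrate$n_r * substrate$n_sc, 0, 1e-4),
               substrate$n_r, substrate$n_sc)
  g <- willshaw_graph(substrate, min_angle)
  csr <- .adjacency_csr(g$edges, substrate$n_sc)
  res <- willshaw_run_cpp(substrate$retina$R_A, substrate$retina$R_B, W0,
                          substrate$sc$L_A, substrate$sc$L_B,
                          csr$ptr, csr$idx, sigma, delta, theta, zeta,
                          kappa, dt, n_steps)
  connection_state(
    res$W, "willshaw",
    params = list(dt = dt, sigma = sigma, delta = delta, theta = theta,
                  zeta = zeta, kappa = kappa, w_min = w_min,
                  min_angle = min_angle, n_steps = n_steps),
    log = data.frame(step = res$log_step, sum_abs_dT = res$log_sum_abs_dT),
    aux = list(TA = res$TA, TB = res$TB, graph = g),
    seed = seed, w_min = w_min)
}
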