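# ---------------------------------------------------------------------------
# Quantitative map evaluation: strongest-target mapping, virtual injections
# (segregation), cross-validated KDE contours, lattice analysis, collapse
# points, projection histograms, SC coverage.
# ---------------------------------------------------------------------------

#' Strongest-connection point mapping
#'
#' For each RGC with a nonzero weight row, pairs its retinal position with
#' the position of the SC neuron receiving its strongest connection. Ties
#' at the row maximum (routine for binary synapse counts) are broken by
#' taking, among the tied SC neurons, the one nearest the row's
#' weight-centroid position — the centre of the termination zone — which is
#' deterministic and does not privilege storage order. RGCs with all-zero
#' rows are excluded and counted.
#'
#' @param state a `connection_state` or a weight matrix.
#' @param substrate the substrate the weights were computed on.
#' @return an object of class `point_mapping`: data frame with columns `i`
#'   (RGC index), `rx`, `ry` (retina), `sx`, `sy` (SC), `j` (SC index) and
#'   `isl2`; attribute `n_unmapped` counts excluded RGCs.
#' @export
strongest_mapping <- function(state, substrate) {
  W <- if (inherits(state, "connection_state")) state$W else state
  W <- as.matrix(W)
  stopifnot(nrow(W) == substrate$n_r, ncol(W) == substrate$n_sc)
  sx <- substrate$sc$x; sy <- substrate$sc$y
  rmax <- apply(W, 1, max)
  mapped <- which(rmax > 0)
  j <- vapply(mapped, function(i) {
    row <- W[i, ]
    cand <- which(row == max(row))
    if (length(cand) == 1L) return(cand)
    nz <- row > 0
    cx <- sum(row[nz] * sx[nz]) / sum(row[nz])
    cy <- sum(row[nz] * sy[nz]) / sum(row[nz])
    cand[which.min((sx[cand] - cx)^2 + (sy[cand] - cy)^2)]
  }, integer(1))
  out <- data.frame(i = mapped,
                    rx = substrate$retina$x[mapped],
                    ry = substrate$retina$y[mapped],
                    sx = substrate$sc$x[j],
                    sy = substrate$sc$y[j],
                    j = j,
                    isl2 = substrate$retina$isl2[mapped])
  attr(out, "n_unmapped") <- substrate$n_r - length(mapped)
  attr(out, "ml_extent") <- substrate$ml_extent
  class(out) <- c("point_mapping", "data.frame")
  out
}

# --- segment intersection -------------------------------------------------

# strict proper intersection of segments (vectorized over rows)
.segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o <- function(px, py, qx, qy, rx, ry)
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  o1 <- o(ax, ay, bx, by, cx, cy)
  o2 <- o(ax, ay, bx, by, dx, dy)
  o3 <- o(cx, cy, dx, dy, ax, ay)
  o4 <- o(cx, cy, dx, dy, bx, by)
  (o1 * o2 < 0) & (o3 * o4 < 0)
}

# farthest-point sampling of k approximately equidistant centers;
# deterministic: starts from the point nearest the centroid
.farthest_points <- function(x, y, k) {
  n <- length(x)
  stopifnot(k <= n)
  d0 <- (x - mean(x))^2 + (y - mean(y))^2
  sel <- integer(k)
  sel[1] <- which.min(d0)
  mind <- (x - x[sel[1]])^2 + (y - y[sel[1]])^2
  for (m in seq_len(k - 1)) {
    sel[m + 1] <- which.max(mind)
    mind <- pmin(mind, (x - x[sel[m + 1]])^2 + (y - y[sel[m + 1]])^2)
  }
  sel
}

#' Lattice analysis of a point-to-point map
#'
#' Places `n_centers` approximately equidistant centre nodes over the mapped
#' retinal extent (farthest-point sampling); each centre's SC node is the
#' centroid of the strongest-target positions of RGCs within `radius` of the
#' centre. The Delaunay lattice on the retinal centres is projected into the
#' SC; edge pairs that cross there mark local map distortions, and nodes are
#' removed greedily (most crossing-involved first; ties by larger summed
#' crossing-edge length, then lower index) until the remaining submap is
#' crossing-free.
#'
#' Reported measures: percentage of nodes that retained all their lattice
#' edges, percentage of edges retained, AP and ML polarity (percentage of
#' connected node pairs of the full lattice whose SC order matches the
#' canonical map orientation: temporal to anterior, ventral to medial), and
#' the mean absolute orientation difference (degrees) between SC edges and
#' canonically transferred retinal edges.
#'
#' @param mapping a [strongest_mapping()] (or fixture) `point_mapping`.
#' @param n_centers number of centre nodes.
#' @param radius retinal circle radius around each centre (units of the
#'   retinal diameter, which is 1).
#' @param max_empty_frac error if more than this fraction of centres capture
#'   no RGC.
#' @return an object of class `lattice_result` (a list); see Details.
#' @export
lattice_analysis <- function(mapping, n_centers = 100, radius = 0.07,
                             max_empty_frac = 0.2) {
  stopifnot(nrow(mapping) >= n_centers)
  ml <- attr(mapping, "ml_extent")
  if (is.null(ml)) ml <- 1
  ctr <- .farthest_points(mapping$rx, mapping$ry, n_centers)
  cx <- mapping$rx[ctr]; cy <- mapping$ry[ctr]
  # SC node = centroid of strongest targets of RGCs within the circle
  nx <- numeric(n_centers); ny <- numeric(n_centers)
  n_in <- integer(n_centers)
  for (m in seq_len(n_centers)) {
    inside <- (mapping$rx - cx[m])^2 + (mapping$ry - cy[m])^2 <= radius^2
    n_in[m] <- sum(inside)
    if (n_in[m] > 0) {
      nx[m] <- mean(mapping$sx[inside]); ny[m] <- mean(mapping$sy[inside])
    } else nx[m] <- ny[m] <- NA_real_
  }
  if (mean(n_in < 1) > max_empty_frac)
    stop("insufficient coverage: more than ", round(100 * max_empty_frac),
         "% of lattice centres capture no RGC")
  ok <- n_in >= 1
  cx <- cx[ok]; cy <- cy[ok]; nx <- nx[ok]; ny <- ny[ok]
  nn <- sum(ok)

  dl <- delaunay(cx, cy)
  ed <- prune_sliver_edges(dl$triangles, cx, cy)
  ne <- nrow(ed)

  # all crossing edge pairs in the SC (computed once; removals only delete)
  pair_i <- rep(seq_len(ne), times = ne) ; pair_j <- rep(seq_len(ne), each = ne)
  keep <- pair_i < pair_j
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  a <- ed[pair_i, 1]; b <- ed[pair_i, 2]; c <- ed[pair_j, 1]; d <- ed[pair_j, 2]
  share <- a == c | a == d | b == c | b == d
  cr <- .segments_cross(nx[a], ny[a], nx[b], ny[b],
                        nx[c], ny[c], nx[d], ny[d]) & !share
  cross_pairs <- cbind(pair_i[cr], pair_j[cr])

  # greedy node removal until crossing-free
  removed <- logical(nn)
  edge_alive <- rep(TRUE, ne)
  pairs_alive <- rep(TRUE, nrow(cross_pairs))
  edge_len <- sqrt((nx[ed[, 1]] - nx[ed[, 2]])^2 +
                     (ny[ed[, 1]] - ny[ed[, 2]])^2)
  while (any(pairs_alive)) {
    cp <- cross_pairs[pairs_alive, , drop = FALSE]
    ce <- unique(c(cp))                       # edges involved in crossings
    # per-node: number of live crossing pairs its edges take part in
    cnt <- numeric(nn); len <- numeric(nn)
    for (e in ce) {
      m <- sum(cp == e)                       # pair involvements of edge e
      for (v in ed[e, ]) {
        cnt[v] <- cnt[v] + m
        len[v] <- len[v] + edge_len[e] * m
      }
    }
    worst <- which(cnt == max(cnt))
    if (length(worst) > 1) worst <- worst[order(-len[worst], worst)][1]
    removed[worst] <- TRUE
    dead_e <- which(ed[, 1] == worst | ed[, 2] == worst)
    edge_alive[dead_e] <- FALSE
    pairs_alive <- pairs_alive &
      !(cross_pairs[, 1] %in% dead_e | cross_pairs[, 2] %in% dead_e)
  }
  # node retains all its edges iff itself and all its neighbours survive
  nb_ok <- vapply(seq_len(nn), function(v) {
    if (removed[v]) return(FALSE)
    nbs <- c(ed[ed[, 1] == v, 2], ed[ed[, 2] == v, 1])
    all(!removed[nbs])
  }, logical(1))

  # polarity over the full lattice, against the canonical orientation
  dNT <- cx[ed[, 1]] - cx[ed[, 2]]
  dDV <- cy[ed[, 1]] - cy[ed[, 2]]
  dAP <- nx[ed[, 1]] - nx[ed[, 2]]
  dML <- ny[ed[, 1]] - ny[ed[, 2]]
  ap_ok <- dNT * dAP < 0
  ml_ok <- dDV * dML < 0
  # orientation difference: SC edge vs canonically transferred retinal edge
  # (both axes flip; ML compared in units of the SC ML extent)
  va <- atan2(dML / ml, dAP)
  vb <- atan2(-dDV, -dNT)
  dang <- abs((va - vb + pi) %% (2 * pi) - pi) * 180 / pi

  structure(list(
    n_centers = n_centers, n_nodes = nn,
    centers = cbind(x = cx, y = cy), sc_nodes = cbind(x = nx, y = ny),
    edges = ed, removed = removed, edge_retained = edge_alive,
    nodes_pct = 100 * sum(nb_ok) / nn,
    edges_pct = 100 * sum(edge_alive) / ne,
    ap_polarity = 100 * mean(ap_ok),
    ml_polarity = 100 * mean(ml_ok),
    orientation_diff = mean(dang),
    n_crossings = nrow(cross_pairs)
  ), class = "lattice_result")
}

#' @export
print.lattice_result <- function(x, ...) {
  cat(sprintf(paste0("<lattice_result> nodes %.1f%%, edges %.1f%%, ",
                     "AP polarity %.1f%%, ML polarity %.1f%%, ",
                     "orientation diff %.1f deg\n"),
              x$nodes_pct, x$edges_pct, x$ap_polarity, x$ml_polarity,
              x$orientation_diff))
  invisible(x)
}

#' Segregation of two virtual retrograde injections
#'
#' Labels the RGCs whose strongest SC target lies within `radius` of each
#' injection centre (retrograde transport), then reports the fraction of
#' labelled RGCs whose nearest labelled neighbour in the retina carries the
#' same label: 1 for two completely segregated projections, 0.5 for two
#' overlapping projections.
#'
#' RGCs labelled by both injections (overlapping injection sites) are
#' assigned to the nearer centre; exact ties are resolved by a seeded fair
#' coin, so two coincident injections label each RGC with one of the two
#' colours at random and segregate at chance (0.5).
#'
#' @param mapping a `point_mapping`.
#' @param centers 2 x 2 matrix (rows = the two SC injection centres).
#' @param radius injection radius in SC units.
#' @param seed seed for resolving exactly tied dual labels.
#' @return segregation fraction in `[0, 1]`.
#' @export
segregation <- function(mapping, centers, radius = 0.05, seed = 1) {
  stopifnot(nrow(centers) == 2)
  d1 <- (mapping$sx - centers[1, 1])^2 + (mapping$sy - centers[1, 2])^2
  d2 <- (mapping$sx - centers[2, 1])^2 + (mapping$sy - centers[2, 2])^2
  in1 <- d1 <= radius^2; in2 <- d2 <= radius^2
  lab <- integer(nrow(mapping))
  lab[in1 & !in2] <- 1L
  lab[in2 & !in1] <- 2L
  both <- which(in1 & in2)
  if (length(both)) {
    set.seed(seed)
    nearer <- ifelse(d1[both] < d2[both], 1L,
                     ifelse(d2[both] < d1[both], 2L,
                            sample(c(1L, 2L), length(both), replace = TRUE)))
    lab[both] <- nearer
  }
  if (sum(lab == 1L) < 2 || sum(lab == 2L) < 2)
    stop("too few labelled RGCs (need at least 2 per injection)")
  keep <- lab > 0
  px <- mapping$rx[keep]; py <- mapping$ry[keep]; lab <- lab[keep]
  n <- length(px)
  same <- logical(n)
  for (q in seq_len(n)) {
    d2 <- (px - px[q])^2 + (py - py[q])^2
    d2[q] <- Inf
    same[q] <- lab[which.min(d2)] == lab[q]
  }
  mean(same)
}

# --- kernel density estimation with cross-validated bandwidth -------------

# leave-one-out log-likelihood of a Gaussian KDE at bandwidth k, given the
# pairwise squared distance matrix (weights optional, normalized)
.kde_cv_loglik <- function(k, D2, w = NULL) {
  n <- nrow(D2)
  K <- exp(-D2 / (2 * k^2))
  diag(K) <- 0
  if (is.null(w)) {
    fi <- rowSums(K) / ((n - 1) * 2 * pi * k^2)
    if (any(fi <= 0)) return(-Inf)
    sum(log(fi))
  } else {
    sw <- sum(w)
    fi <- as.numeric(K %*% w)
    denom <- (sw - w) * 2 * pi * k^2
    pos <- w > 0
    if (any(fi[pos] <= 0)) return(-Inf)
    sum((w[pos] / sw) * log(fi[pos] / denom[pos]))
  }
}

#' Cross-validated KDE bandwidth
#'
#' Maximizes the leave-one-out log-likelihood
#' \eqn{L(k) = \sum_i \log \hat f_i(r_i, k)} by scalar optimization.
#'
#' @param x,y point coordinates.
#' @param w optional nonnegative weights.
#' @param interval search interval for `k`.
#' @param floor lower bound applied if the optimum degenerates (coincident
#'   points); flagged in the result.
#' @return list with `bandwidth` and `flagged`.
#' @export
kde_bandwidth <- function(x, y, w = NULL, interval = c(5e-4, 0.5),
                          floor = 1e-3) {
  D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  if (length(x) < 2 || max(D2) == 0)   # single or fully coincident points
    return(list(bandwidth = floor, flagged = TRUE))
  opt <- optimize(function(k) .kde_cv_loglik(k, D2, w), interval,
                  maximum = TRUE)
  k <- opt$maximum
  flagged <- FALSE
  if (!is.finite(opt$objective) || k < floor) {
    k <- max(k, floor)
    flagged <- TRUE
  }
  list(bandwidth = k, flagged = flagged)
}

# KDE evaluated on a grid masked to an outline; returns the percentage of
# the outline area needed to enclose `percentile`% of the total density mass
.contour_area <- function(px, py, w, outline, percentile, grid_n = 100,
                          bandwidth = NULL) {
  if (is.null(bandwidth)) {
    bw <- kde_bandwidth(px, py, w)
  } else bw <- list(bandwidth = bandwidth, flagged = FALSE)
  k <- bw$bandwidth
  gx <- seq(min(outline[, 1]), max(outline[, 1]), length.out = grid_n)
  gy <- seq(min(outline[, 2]), max(outline[, 2]), length.out = grid_n)
  G <- expand.grid(x = gx, y = gy)
  inside <- in_polygon(G$x, G$y, outline)
  if (is.null(w)) w <- rep(1, length(px))
  dens <- numeric(nrow(G))
  # accumulate per data point (memory-light for 10^4 grid cells)
  for (q in seq_along(px)) {
    dens <- dens + w[q] *
      exp(-((G$x - px[q])^2 + (G$y - py[q])^2) / (2 * k^2))
  }
  dens <- dens / (sum(w) * 2 * pi * k^2)
  di <- dens[inside]
  o <- order(di, decreasing = TRUE)
  cum <- cumsum(di[o]) / sum(di)
  ncell <- which(cum >= percentile / 100)[1]
  if (is.na(ncell)) ncell <- length(di)
  list(area_pct = 100 * ncell / sum(inside), bandwidth = k,
       flagged = bw$flagged,
       total_mass_inside = sum(di) / sum(dens))
}

#' KDE contour analysis of labelled retinal points
#'
#' Gaussian kernel density estimate on a 100 x 100 grid over the retina,
#' with the bandwidth maximizing the leave-one-out cross-validated
#' log-likelihood; returns the percentage of retinal area inside the contour
#' that encloses the top `percentile` percent of the total labelling.
#'
#' @param x,y labelled retinal positions (at least 3).
#' @param percentile contour mass percentage (e.g. 95).
#' @param grid_n grid resolution per axis.
#' @param outline region outline (default the unit-diameter retina).
#' @return list with `area_pct`, `bandwidth`, `flagged`.
#' @export
kde_contour <- function(x, y, percentile = 95, grid_n = 100,
                        outline = retina_outline()) {
  stopifnot(length(x) >= 3)
  .contour_area(x, y, NULL, outline, percentile, grid_n)
}

#' SC coverage of the synaptic weight distribution
#'
#' Percentage of SC area containing `mass` of the total synaptic weight.
#' The default method exploits that the SC neurons are themselves a uniform
#' spatial sample of the SC: the area fraction equals the smallest fraction
#' of SC neurons (taken in decreasing order of afferent weight) that holds
#' `mass` of the weight. A uniform innervation gives ~`100 * mass`, weight
#' spread uniformly over half the SC gives ~`100 * mass / 2`, and a single
#' innervated neuron gives ~`100 / n_sc`. `method = "kde"` instead applies
#' the weighted KDE/contour machinery of [kde_contour()]; its
#' cross-validated bandwidth smooths the support outward, which inflates
#' the area by roughly a bandwidth-times-perimeter term.
#'
#' @param state a `connection_state` or weight matrix.
#' @param substrate the substrate.
#' @param mass weight fraction to enclose (default 0.99).
#' @param method `"neurons"` (default) or `"kde"`.
#' @return list with `area_pct` (plus `bandwidth` and `flagged` for the KDE
#'   method).
#' @export
sc_coverage <- function(state, substrate, mass = 0.99,
                        method = c("neurons", "kde")) {
  method <- match.arg(method)
  W <- if (inherits(state, "connection_state")) threshold_weights(state)$W
       else state
  wj <- as.numeric(Matrix::colSums(W))
  stopifnot(sum(wj) > 0)
  if (method == "neurons") {
    o <- order(wj, decreasing = TRUE)
    cum <- cumsum(wj[o]) / sum(wj)
    n_needed <- which(cum >= mass)[1]
    return(list(area_pct = 100 * n_needed / length(wj)))
  }
  use <- wj > 0
  .contour_area(substrate$sc$x[use], substrate$sc$y[use], wj[use],
                substrate$sc_outline, 100 * mass)
}

#' Collapse-point detection by binned 2-means clustering
#'
#' Restricts the mapping to the central third of the orthogonal (DV) retinal
#' axis, divides the NT axis into `n_bins` equal bins, and clusters each
#' bin's AP termination coordinates with 2-means. The bin holds two
#' distinct termination zones if all of the following hold:
#' \itemize{
#'   \item the distance between the cluster means exceeds `sd_factor` pooled
#'     (within-cluster) standard deviations;
#'   \item the smaller cluster holds at least `min_frac` of the bin's
#'     neurons;
#'   \item the split is a genuine density valley: fewer than `valley_frac`
#'     of the bin's points fall in the middle half of the interval between
#'     the two cluster means (a unimodal bin puts 25-30% of its mass there,
#'     two separated bands essentially none — a 2-means split of unimodal
#'     data always passes the first two conditions, so this is what decides
#'     bimodality).
#' }
#' The clustering for bin `b` pools the bin with its `window` neighbours on
#' each side (labels are assigned to the central bin): at 50 bins and
#' desk-scale populations a single bin holds only ~10-20 RGCs, too few for
#' the valley statistic to be reliable (one stray point flips the call).
#' The collapse point is the nasal/temporal boundary minimizing label
#' misclassification (doubles nasal, singles temporal), shifted nasally by
#' `window` bins to undo the smearing of a sharp transition by the pooling
#' window; maps whose usable bins are >90% single report `"no_split"` (no
#' duplication anywhere), while maps that stay double in all but at most
#' one bin report `"no_merge"` (the two maps never resolvably join).
#'
#' @param mapping a `point_mapping`.
#' @param n_bins number of NT bins.
#' @param band retinal DV interval to keep (central third by default).
#' @param sd_factor distinctness threshold in pooled SDs.
#' @param min_frac minimum fraction of the bin in the smaller cluster.
#' @param valley_frac maximum fraction of points between the modes (at
#'   least one point is always tolerated).
#' @param ratio_distinct separation (in pooled SDs) beyond which the split
#'   counts as bimodal regardless of the valley count; a 2-means split of
#'   unimodal data reaches ~2.2-4, well below this.
#' @param window number of neighbouring bins pooled on each side for the
#'   clustering.
#' @param min_bin_n pooled bins with fewer points are skipped.
#' @param seed seed for the k-means restarts.
#' @return an object of class `collapse_result`: list with `collapse_pct`
#'   (`NA` unless `status == "collapse"`), `status`, and a per-bin table.
#' @export
collapse_point <- function(mapping, n_bins = 50, band = c(1 / 3, 2 / 3),
                           sd_factor = 1.5, min_frac = 0.05,
                           valley_frac = 0.10, ratio_distinct = 4.5,
                           window = 1, min_bin_n = 8, seed = 1) {
  m <- mapping[mapping$ry >= band[1] & mapping$ry <= band[2], ]
  if (nrow(m) < 2 * min_bin_n) stop("insufficient data for collapse analysis")
  set.seed(seed)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(m$rx, edges, rightmost.closed = TRUE), 1),
              n_bins)
  tab <- data.frame(bin = seq_len(n_bins),
                    center_pct = 100 * (edges[-1] + edges[-(n_bins + 1)]) / 2,
                    n = 0L, n_window = 0L, n_clusters = NA_integer_,
                    separation = NA_real_, pooled_sd = NA_real_,
                    valley = NA_real_, ap1 = NA_real_, ap2 = NA_real_)
  for (bb in seq_len(n_bins)) {
    idx <- which(bin >= bb - window & bin <= bb + window)
    tab$n[bb] <- sum(bin == bb)
    tab$n_window[bb] <- length(idx)
    if (length(idx) < min_bin_n) next
    ap <- m$sx[idx]
    if (length(unique(ap)) < 2) {
      tab$n_clusters[bb] <- 1L
      next
    }
    km <- kmeans(matrix(ap), centers = 2, nstart = 5)
    mu <- sort(km$centers[, 1])
    sep <- mu[2] - mu[1]
    pooled <- sqrt(sum(km$withinss) / max(1, length(ap) - 2))
    small <- min(km$size) / length(ap)
    n_valley <- sum(ap > mu[1] + sep / 4 & ap < mu[2] - sep / 4)
    # bimodality: either an (essentially) empty valley between the modes,
    # or a separation far above the ~2.2-4 pooled SDs that a 2-means split
    # of unimodal data produces
    bimodal <- n_valley <= max(1, valley_frac * length(ap)) ||
      sep > ratio_distinct * pooled
    distinct <- sep > sd_factor * pooled && small >= min_frac && bimodal
    tab$n_clusters[bb] <- if (distinct) 2L else 1L
    tab$separation[bb] <- sep
    tab$pooled_sd[bb] <- pooled
    tab$valley[bb] <- n_valley / length(ap)
    tab$ap1[bb] <- mu[1]; tab$ap2[bb] <- mu[2]
  }
  usable <- which(!is.na(tab$n_clusters))
  if (length(usable) == 0) stop("insufficient data: no usable NT bin")
  lab <- tab$n_clusters[usable]           # 1 = single, 2 = double
  frac_double <- mean(lab == 2L)
  if (frac_double <= 0.1) {
    status <- "no_split"; collapse_pct <- NA_real_
  } else if (frac_double > 0.96) {
    # merges confined to the last bin (or none at all) are not resolvable
    status <- "no_merge"; collapse_pct <- NA_real_
  } else {
    status <- "collapse"
    # boundary b: bins nasal of b should be double, temporal single;
    # pick the cut minimizing misclassified bins (nasal-most on ties)
    err <- vapply(seq_len(length(usable) + 1), function(cut) {
      sum(lab[seq_len(cut - 1)] == 1L) +
        sum(lab[seq(cut, length(lab))[seq_len(length(lab) - cut + 1)]] == 2L)
    }, numeric(1))
    cut <- which.min(err)
    cut_bin <- if (cut > length(usable)) usable[length(usable)]
               else usable[cut]
    cut_bin <- max(1L, cut_bin - window)   # undo window smearing
    collapse_pct <- tab$center_pct[cut_bin]
  }
  structure(list(collapse_pct = collapse_pct, status = status, bins = tab),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat("<collapse_result>", x$status,
      if (!is.na(x$collapse_pct)) sprintf("at %.1f%% NT", x$collapse_pct),
      "\n")
  invisible(x)
}

#' Projection histogram along an axis pair
#'
#' 2D histogram of the mapping along NT -> AP (or DV -> ML), restricted to
#' the central third of the orthogonal retinal axis.
#'
#' @param mapping a `point_mapping`.
#' @param axes `"NT_AP"` or `"DV_ML"`.
#' @param nbins bins per axis.
#' @param band orthogonal-axis interval to keep.
#' @return matrix of counts (rows = retinal bins, cols = SC bins).
#' @export
projection_histogram <- function(mapping, axes = c("NT_AP", "DV_ML"),
                                 nbins = 50, band = c(1 / 3, 2 / 3)) {
  axes <- match.arg(axes)
  ml <- attr(mapping, "ml_extent"); if (is.null(ml)) ml <- 1
  if (axes == "NT_AP") {
    m <- mapping[mapping$ry >= band[1] & mapping$ry <= band[2], ]
    u <- m$rx; v <- m$sx
  } else {
    m <- mapping[mapping$rx >= band[1] & mapping$rx <= band[2], ]
    u <- m$ry; v <- m$sy / ml
  }
  bu <- pmin(pmax(ceiling(u * nbins), 1), nbins)
  bv <- pmin(pmax(ceiling(v * nbins), 1), nbins)
  H <- matrix(0L, nbins, nbins)
  for (q in seq_along(bu)) H[bu[q], bv[q]] <- H[bu[q], bv[q]] + 1L
  H
}
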