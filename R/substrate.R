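#' @useDynLib retinosim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize kmeans runif rbinom sd dist setNames
#' @importFrom utils write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Gradient parameterization
#
# Each Eph/ephrin subtype is an exponential profile along one normalized axis
# coordinate x in [0,1]:  G(x) = max(0, G0 + G1 * exp(-G2 * |x - G3|)).
# Subtype profiles are summed per system (EphA, EphB, ephrin-A, ephrin-B) and
# the sum is scaled so that each wild-type summed gradient peaks at 1; the
# same scale constants are reused for every genotype, so knock-ins peak above
# 1 and knock-outs below 1.
# ---------------------------------------------------------------------------

#' Gradient profile parameters
#'
#' Bundles the four parameters of an exponential expression profile
#' \eqn{G(x) = \max(0, G_0 + G_1 e^{-G_2 |x - G_3|})} for one Eph/ephrin
#' subtype along a normalized axis.
#'
#' @param G0,G1,G2,G3 profile parameters; `G2` must be nonnegative.
#' @return an object of class `gradient_params`.
#' @export
gradient_params <- function(G0, G1, G2, G3) {
  stopifnot(is.numeric(G0), is.numeric(G1), is.numeric(G2), is.numeric(G3),
            G2 >= 0)
  structure(list(G0 = G0, G1 = G1, G2 = G2, G3 = G3),
            class = "gradient_params")
}

#' Evaluate one gradient profile
#'
#' @param params a [gradient_params()] object.
#' @param x positions along the axis, in `[0, 1]`.
#' @return nonnegative concentrations, same length as `x`.
#' @export
eval_gradient <- function(params, x) {
  stopifnot(inherits(params, "gradient_params"), all(x >= 0 & x <= 1))
  pmax(0, params$G0 + params$G1 * exp(-params$G2 * abs(x - params$G3)))
}

# Subtype tables. Retinal EphA runs along the nasotemporal axis (x = 0 nasal,
# 1 temporal), EphB along dorsoventral; SC ephrin-A along anteroposterior
# (x = 0 anterior), ephrin-B along mediolateral (x = 0 medial).
.gradient_tables <- function() {
  list(
    EphA = list(
      EphA4 = gradient_params(1.05, 0,    0,   1),
      EphA5 = gradient_params(0,    0.85, 1.8, 1),
      EphA6 = gradient_params(0,    1.64, 2.9, 1)
    ),
    EphB = list(
      EphB = gradient_params(0, 1, 1, 1)
    ),
    ephrinA = list(
      ephrinA2 = gradient_params(-0.06, 0.35, 2, 0.8),
      ephrinA3 = gradient_params(0.05,  0,    0, 1),
      ephrinA5 = gradient_params(-0.1,  0.9,  3, 1)
    ),
    ephrinB = list(
      ephrinB = gradient_params(0, 1, 1, 0)
    )
  )
}

# EphA3 knocked into Isl2+ RGCs: flat profile, G0 = 1.86 (ki/ki), 0.93 (ki/+)
.epha3_params <- function(homozygous) {
  gradient_params(if (homozygous) 1.86 else 0.93, 0, 0, 1)
}

#' Summed (unscaled) wild-type gradient of one system
#'
#' @param system one of `"EphA"`, `"EphB"`, `"ephrinA"`, `"ephrinB"`.
#' @param x axis positions in `[0, 1]`.
#' @return summed subtype concentrations at `x`.
#' @export
summed_gradient <- function(system = c("EphA", "EphB", "ephrinA", "ephrinB"),
                            x) {
  system <- match.arg(system)
  subtypes <- .gradient_tables()[[system]]
  Reduce(`+`, lapply(subtypes, eval_gradient, x = x))
}

#' Wild-type peak normalization constants
#'
#' Peak of each summed wild-type gradient over a dense grid; all genotypes
#' are scaled by these constants so the wild-type summed gradients peak at 1.
#'
#' @param n grid resolution.
#' @return named numeric vector of peaks for the four systems.
#' @export
wt_peaks <- function(n = 100001) {
  grid <- seq(0, 1, length.out = n)
  vapply(c("EphA", "EphB", "ephrinA", "ephrinB"),
         function(s) max(summed_gradient(s, grid)), numeric(1))
}

# cached at first use (profile parameters are fixed)
.peaks_cache <- new.env(parent = emptyenv())
.wt_peaks <- function() {
  if (is.null(.peaks_cache$p)) .peaks_cache$p <- wt_peaks()
  .peaks_cache$p
}

# ---------------------------------------------------------------------------
# Structure outlines
# ---------------------------------------------------------------------------

#' Retinal outline: circle of diameter 1
#' @param n number of polygon vertices.
#' @return matrix of polygon vertices (closed implicitly).
#' @export
retina_outline <- function(n = 360) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = 0.5 + 0.5 * cos(th), y = 0.5 + 0.5 * sin(th))
}

#' Superior colliculus outline
#'
#' A fixed smooth convex-ish blob, longer along the anteroposterior axis than
#' mediolaterally, normalized to unit AP extent. The exact traced outline of
#' the SC is not recoverable, and the analysis is outline-agnostic; a circle
#' can be used instead via `shape = "circle"`.
#'
#' @param n number of polygon vertices.
#' @param shape `"blob"` (default) or `"circle"`.
#' @return matrix of polygon vertices with `x` (AP) in `[0,1]`.
#' @export
sc_outline <- function(n = 360, shape = c("blob", "circle")) {
  shape <- match.arg(shape)
  if (shape == "circle") return(retina_outline(n))
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  # egg-like ellipse, slightly wider posteriorly
  a <- 0.5; b <- 0.36
  xr <- a * cos(th) * (1 + 0.07 * cos(th))
  yr <- b * sin(th) * (1 + 0.10 * cos(th))
  x <- xr - min(xr); y <- yr - min(yr)
  sc <- max(x)  # normalize AP extent to 1
  cbind(x = x / sc, y = y / sc)
}

#' Test points for inclusion in a polygon
#'
#' Even-odd ray-casting rule.
#' @param x,y point coordinates.
#' @param poly polygon vertex matrix (columns x, y).
#' @return logical vector.
#' @export
in_polygon <- function(x, y, poly) {
  nx <- nrow(poly)
  j <- c(nx, seq_len(nx - 1))
  inside <- rep(FALSE, length(x))
  for (k in seq_len(nx)) {
    xi <- poly[k, 1]; yi <- poly[k, 2]
    xj <- poly[j[k], 1]; yj <- poly[j[k], 2]
    crosses <- ((yi > y) != (yj > y)) &
      (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# ---------------------------------------------------------------------------
# Neuron placement: uniform rejection sampling with a minimum spacing
# ---------------------------------------------------------------------------

#' Place neurons with a minimum-distance constraint
#'
#' Samples positions uniformly over the outline's bounding box expanded by
#' `buffer` so that points just outside the structure still constrain spacing
#' (avoiding inflated edge density); buffer points are discarded at the end.
#' A candidate is rejected if any previously accepted point (inside or
#' outside) lies within `exclusion`. Placement terminates with an error after
#' `1000 * count` rejections in total.
#'
#' @param count number of points required inside the outline.
#' @param outline polygon vertex matrix, e.g. [retina_outline()].
#' @param exclusion minimum pairwise distance.
#' @param seed integer RNG seed.
#' @param buffer width of the sampling margin outside the bounding box
#'   (default `3 * exclusion`).
#' @return matrix with columns `x`, `y` of exactly `count` points.
#' @export
place_neurons <- function(count, outline, exclusion, seed = NULL,
                          buffer = 3 * exclusion) {
  stopifnot(count >= 1, exclusion >= 0)
  if (!is.null(seed)) set.seed(seed)
  xlim <- range(outline[, 1]) + c(-buffer, buffer)
  ylim <- range(outline[, 2]) + c(-buffer, buffer)
  cap <- max(count * 4L, 64L)
  px <- numeric(cap); py <- numeric(cap)
  n_acc <- 0L; n_inside <- 0L; n_rej <- 0L
  inside <- logical(cap)
  excl2 <- exclusion^2
  while (n_inside < count) {
    if (n_rej >= 1000 * count)
      stop("packing infeasible: rejection budget (1000 * count) exhausted")
    cx <- runif(1, xlim[1], xlim[2])
    cy <- runif(1, ylim[1], ylim[2])
    if (n_acc > 0L) {
      d2 <- (px[seq_len(n_acc)] - cx)^2 + (py[seq_len(n_acc)] - cy)^2
      if (min(d2) < excl2) { n_rej <- n_rej + 1L; next }
    }
    n_acc <- n_acc + 1L
    if (n_acc > cap) {
      cap <- cap * 2L
      px <- c(px, numeric(cap / 2)); py <- c(py, numeric(cap / 2))
      inside <- c(inside, logical(cap / 2))
    }
    px[n_acc] <- cx; py[n_acc] <- cy
    ins <- in_polygon(cx, cy, outline)
    inside[n_acc] <- ins
    if (ins) n_inside <- n_inside + 1L
  }
  keep <- which(inside[seq_len(n_acc)])
  cbind(x = px[keep], y = py[keep])
}

# ---------------------------------------------------------------------------
# Genotypes
# ---------------------------------------------------------------------------

#' Genotype specification
#'
#' @param name one of `"wild_type"`, `"isl2_epha3_ki_ki"`,
#'   `"isl2_epha3_ki_het"`, `"tko"`, `"math5"`.
#' @param K weak-gradient scale for the TKO genotype: the SC ephrin-A profile
#'   is replaced by `K` times the wild-type profile (`K = 0`: complete
#'   knock-out). Must be in `[0, 1]`.
#' @param isl2_fraction expected fraction of Isl2+ RGCs for the knock-in
#'   genotypes (salt-and-pepper, independent per RGC).
#' @return an object of class `genotype_spec`.
#' @export
genotype_spec <- function(name = c("wild_type", "isl2_epha3_ki_ki",
                                   "isl2_epha3_ki_het", "tko", "math5"),
                          K = 0, isl2_fraction = 0.4) {
  name <- match.arg(name)
  stopifnot(K >= 0, K <= 1, isl2_fraction > 0, isl2_fraction < 1)
  structure(list(
    name = name,
    K = K,
    isl2_fraction = isl2_fraction,
    population_fraction = if (name == "math5") 0.1 else 1.0,
    epha3 = switch(name,
                   isl2_epha3_ki_ki = .epha3_params(TRUE),
                   isl2_epha3_ki_het = .epha3_params(FALSE),
                   NULL)
  ), class = "genotype_spec")
}

#' @export
print.genotype_spec <- function(x, ...) {
  cat("<genotype_spec>", x$name,
      if (x$name == "tko") sprintf("(K = %g)", x$K) else "",
      sprintf("[pop. fraction %g]", x$population_fraction), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Substrate assembly
# ---------------------------------------------------------------------------

#' Build the initial conditions for one simulation
#'
#' Places RGCs in the unit-diameter retina and SC neurons in the SC outline,
#' samples the summed, wild-type-scaled gradients at the neuron positions,
#' and applies genotype modifications: EphA3 added to Isl2+ RGCs (knock-ins),
#' ephrin-A replaced by `K` times the wild-type profile (TKO), or the RGC
#' population reduced to 10% (Math5).
#'
#' @param genotype a [genotype_spec()] or a genotype name.
#' @param n_r,n_sc numbers of RGCs and SC neurons (before the Math5
#'   population reduction).
#' @param d_r,d_sc exclusion distances in retina and SC.
#' @param seed master seed for this substrate (placement and Isl2 labelling
#'   use deterministic sub-streams).
#' @param sc_shape outline shape passed to [sc_outline()].
#' @return an object of class `substrate`: list with data frames `retina`
#'   (`x`, `y`, `R_A`, `R_B`, `isl2`) and `sc` (`x`, `y`, `L_A`, `L_B`),
#'   outlines, counts, and metadata.
#' @export
build_substrate <- function(genotype = "wild_type", n_r = 2000, n_sc = 2000,
                            d_r = 0.0139, d_sc = 0.0119, seed = 1,
                            sc_shape = "blob") {
  if (is.character(genotype)) genotype <- genotype_spec(genotype)
  stopifnot(inherits(genotype, "genotype_spec"))
  seeds <- seed_streams(seed, 3)

  n_r_eff <- max(1L, as.integer(round(n_r * genotype$population_fraction)))
  rout <- retina_outline()
  sout <- sc_outline(shape = sc_shape)
  rpos <- place_neurons(n_r_eff, rout, d_r, seed = seeds[1])
  spos <- place_neurons(n_sc, sout, d_sc, seed = seeds[2])

  peaks <- .wt_peaks()

  # retinal receptors: EphA along NT (x), EphB along DV (y)
  R_A <- summed_gradient("EphA", rpos[, "x"]) / peaks["EphA"]
  R_B <- summed_gradient("EphB", rpos[, "y"]) / peaks["EphB"]

  set.seed(seeds[3])
  isl2 <- if (!is.null(genotype$epha3)) {
    as.logical(rbinom(n_r_eff, 1, genotype$isl2_fraction))
  } else rep(FALSE, n_r_eff)
  if (!is.null(genotype$epha3)) {
    R_A <- R_A + isl2 * eval_gradient(genotype$epha3, rpos[, "x"]) /
      peaks["EphA"]
  }

  # SC ligands: ephrin-A along AP (x / AP extent = x), ephrin-B along ML
  ml_extent <- max(sout[, 2])
  ap_coord <- spos[, "x"]
  ml_coord <- spos[, "y"] / ml_extent
  L_A <- summed_gradient("ephrinA", ap_coord) / peaks["ephrinA"]
  if (genotype$name == "tko") L_A <- genotype$K * L_A
  L_B <- summed_gradient("ephrinB", ml_coord) / peaks["ephrinB"]

  structure(list(
    retina = data.frame(x = rpos[, "x"], y = rpos[, "y"],
                        R_A = as.numeric(R_A), R_B = as.numeric(R_B),
                        isl2 = isl2),
    sc = data.frame(x = spos[, "x"], y = spos[, "y"],
                    L_A = as.numeric(L_A), L_B = as.numeric(L_B)),
    n_r = n_r_eff, n_sc = as.integer(n_sc),
    d_r = d_r, d_sc = d_sc,
    retina_outline = rout, sc_outline = sout,
    ml_extent = ml_extent,
    genotype = genotype, seed = seed
  ), class = "substrate")
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("<substrate> %s: %d RGCs, %d SC neurons (seed %s)\n",
              x$genotype$name, x$n_r, x$n_sc, format(x$seed)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Seeds and serialization
# ---------------------------------------------------------------------------

#' Deterministically split a master seed into sub-stream seeds
#'
#' @param master integer master seed.
#' @param n number of sub-seeds.
#' @return integer vector of `n` seeds, all below 2^31.
#' @export
seed_streams <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Serialize a substrate to a directory of CSV tables + JSON metadata
#' @param substrate a `substrate`.
#' @param path directory to create.
#' @export
write_substrate <- function(substrate, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write.csv(substrate$retina, file.path(path, "retina.csv"), row.names = FALSE)
  write.csv(substrate$sc, file.path(path, "sc.csv"), row.names = FALSE)
  write.csv(as.data.frame(substrate$retina_outline),
            file.path(path, "retina_outline.csv"), row.names = FALSE)
  write.csv(as.data.frame(substrate$sc_outline),
            file.path(path, "sc_outline.csv"), row.names = FALSE)
  meta <- list(n_r = substrate$n_r, n_sc = substrate$n_sc,
               d_r = substrate$d_r, d_sc = substrate$d_sc,
               ml_extent = substrate$ml_extent, seed = substrate$seed,
               genotype = substrate$genotype[c("name", "K", "isl2_fraction",
                                               "population_fraction")])
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a substrate written by [write_substrate()]
#' @param path directory.
#' @return a `substrate`.
#' @export
read_substrate <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  gt <- genotype_spec(meta$genotype$name, K = meta$genotype$K,
                      isl2_fraction = meta$genotype$isl2_fraction)
  structure(list(
    retina = read.csv(file.path(path, "retina.csv")),
    sc = read.csv(file.path(path, "sc.csv")),
    n_r = meta$n_r, n_sc = meta$n_sc, d_r = meta$d_r, d_sc = meta$d_sc,
    retina_outline = as.matrix(read.csv(file.path(path, "retina_outline.csv"))),
    sc_outline = as.matrix(read.csv(file.path(path, "sc_outline.csv"))),
    ml_extent = meta$ml_extent, genotype = gt, seed = meta$seed
  ), class = "substrate")
}

#' Delaunay triangulation of a 2D point set
#'
#' Bowyer--Watson incremental triangulation. Used for the SC neighbour
#' graphs and the lattice analysis.
#'
#' @param x,y point coordinates.
#' @return list with integer matrix `triangles` (rows of vertex indices) and
#'   `edges` (unique undirected edges, two columns).
#' @export
delaunay <- function(x, y) {
  delaunay_cpp(as.numeric(x), as.numeric(y))
}

#' Delaunay edges with sliver shortcuts removed
#'
#' Near-degenerate (sliver) triangles along the convex hull contribute long
#' shortcut edges that distort neighbour graphs and projected lattices. For
#' every triangle containing an angle below `min_angle` degrees, its longest
#' edge is dropped.
#'
#' @param tri triangle index matrix from [delaunay()].
#' @param x,y point coordinates.
#' @param min_angle threshold in degrees.
#' @return two-column matrix of retained unique edges.
#' @export
prune_sliver_edges <- function(tri, x, y, min_angle = 10) {
  thr <- min_angle * pi / 180
  ekey <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
  drop <- character(0)
  for (t in seq_len(nrow(tri))) {
    v <- tri[t, ]
    ang <- numeric(3); len2 <- numeric(3)
    for (m in 1:3) {
      op <- v[m]; a <- v[(m %% 3) + 1]; b <- v[((m + 1) %% 3) + 1]
      u1 <- c(x[a] - x[op], y[a] - y[op])
      u2 <- c(x[b] - x[op], y[b] - y[op])
      ang[m] <- acos(pmin(1, pmax(-1, sum(u1 * u2) /
                                    sqrt(sum(u1^2) * sum(u2^2)))))
      len2[m] <- (x[a] - x[b])^2 + (y[a] - y[b])^2  # edge opposite vertex m
    }
    if (min(ang) < thr) {
      m <- which.max(len2)
      a <- v[(m %% 3) + 1]; b <- v[((m + 1) %% 3) + 1]
      drop <- c(drop, ekey(a, b))
    }
  }
  # unique edges over all triangles
  e <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  e[!(ekey(e[, 1], e[, 2]) %in% drop), , drop = FALSE]
}

# adjacency list (list of integer vectors) from a Delaunay edge matrix
.adjacency <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}
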