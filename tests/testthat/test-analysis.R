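test_that("strongest mapping selects the argmax target and excludes empties", {
  s <- tiny_wt()
  W <- matrix(0, s$n_r, s$n_sc)
  W[1, 5] <- 2; W[1, 9] <- 1
  W[2, 3] <- 0.5
  mp <- strongest_mapping(W, s)
  expect_equal(nrow(mp), 2L)
  expect_equal(mp$j, c(5L, 3L))
  expect_equal(attr(mp, "n_unmapped"), s$n_r - 2L)
  expect_equal(mp$sx, s$sc$x[c(5, 3)])
})

test_that("lattice analysis reproduces the fixture oracles", {
  s <- medium_wt()
  la <- lattice_analysis(make_mapping("identity", s))
  expect_equal(la$nodes_pct, 100)
  expect_equal(la$edges_pct, 100)
  expect_gt(la$ap_polarity, 95)     # snap-to-neuron noise on near-vertical
  expect_gt(la$ml_polarity, 95)     # edges keeps polarity just below 100
  expect_lt(la$orientation_diff, 8)

  lr <- lattice_analysis(make_mapping("random", s, seed = 3))
  expect_equal(lr$ap_polarity, 50, tolerance = 0.12)
  expect_equal(lr$ml_polarity, 50, tolerance = 0.12)
  expect_lt(lr$nodes_pct, 20)       # tiny ordered submap

  lm <- lattice_analysis(make_mapping("mirrored", s))
  expect_lt(lm$ap_polarity, 5)      # orientation violated ...
  expect_equal(lm$edges_pct, 100)   # ... without any crossing edges
  expect_gt(lm$ml_polarity, 95)
})

test_that("the retained lattice submap is audited crossing-free", {
  s <- medium_wt()
  la <- lattice_analysis(make_mapping("noisy", s, noise = 0.1, seed = 2))
  expect_gt(sum(la$removed), 0)     # heavy noise forces removals
  keep <- la$edge_retained
  ed <- la$edges[keep, , drop = FALSE]
  nx <- la$sc_nodes[, 1]; ny <- la$sc_nodes[, 2]
  ne <- nrow(ed)
  crossings <- 0
  for (a in seq_len(ne - 1)) {
    for (b in seq((a + 1), ne)) {
      if (length(intersect(ed[a, ], ed[b, ])) > 0) next
      if (retinosim:::.segments_cross(
        nx[ed[a, 1]], ny[ed[a, 1]], nx[ed[a, 2]], ny[ed[a, 2]],
        nx[ed[b, 1]], ny[ed[b, 1]], nx[ed[b, 2]], ny[ed[b, 2]]))
        crossings <- crossings + 1
    }
  }
  expect_equal(crossings, 0)
})

test_that("segregation distinguishes separated from overlapping injections", {
  s <- medium_wt()
  id <- make_mapping("identity", s)
  # anterior vs posterior injections label disjoint retinal regions
  expect_equal(segregation(id, rbind(c(0.25, 0.2), c(0.75, 0.5)), 0.05), 1)
  # coincident injections label one cloud with random colours
  sg <- segregation(id, rbind(c(0.5, 0.35), c(0.5, 0.35)), 0.06)
  expect_equal(sg, 0.5, tolerance = 0.2)
  # label symmetry: swapping the two centres leaves the value unchanged
  c1 <- rbind(c(0.4, 0.3), c(0.6, 0.35))
  expect_equal(segregation(id, c1, 0.05), segregation(id, c1[2:1, ], 0.05))
  expect_error(segregation(id, rbind(c(-5, -5), c(0.5, 0.35)), 0.01),
               "too few")
})

test_that("KDE bandwidth and contours behave like a density estimate", {
  set.seed(12)
  # integral over the grid approximates 1
  x <- runif(80, 0.3, 0.7); y <- runif(80, 0.3, 0.7)
  bw <- kde_bandwidth(x, y)
  gx <- seq(0, 1, length.out = 100)
  G <- expand.grid(x = gx, y = gx)
  dens <- rowSums(vapply(seq_along(x), function(q)
    exp(-((G$x - x[q])^2 + (G$y - y[q])^2) / (2 * bw$bandwidth^2)),
    numeric(nrow(G)))) / (length(x) * 2 * pi * bw$bandwidth^2)
  expect_equal(sum(dens) * (gx[2] - gx[1])^2, 1, tolerance = 0.05)

  # a tight cluster occupies less area than dispersed points
  tight <- kde_contour(0.5 + rnorm(60, 0, 0.02), 0.5 + rnorm(60, 0, 0.02),
                       percentile = 95)
  wide <- kde_contour(runif(60), runif(60), percentile = 95)
  expect_lt(tight$area_pct, wide$area_pct)

  # CV bandwidth lands within a factor-2 band of the Silverman reference
  # for isotropic Gaussian draws (averaged over repeats)
  ratios <- vapply(1:5, function(r) {
    xs <- rnorm(100, 0.5, 0.08); ys <- rnorm(100, 0.5, 0.08)
    silverman <- 1.06 * 0.08 * 100^(-1 / 5)
    kde_bandwidth(xs, ys)$bandwidth / silverman
  }, numeric(1))
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 2)

  # coincident points trigger the bandwidth floor flag
  fl <- kde_bandwidth(rep(0.5, 5), rep(0.5, 5))
  expect_true(fl$flagged)
})

test_that("SC coverage matches analytic uniform-density expectations", {
  s <- medium_wt()
  # synaptic weight uniform over the whole SC encloses ~99% of the area
  Wu <- matrix(1, 2, s$n_sc)
  expect_equal(sc_coverage(Wu, s, mass = 0.99)$area_pct, 99,
               tolerance = 0.001)
  # uniform over the anterior half: 0.99 * half the area
  anterior <- s$sc$x < stats::median(s$sc$x)
  Wh <- rbind(as.numeric(anterior), as.numeric(anterior))
  expect_equal(sc_coverage(Wh, s, mass = 0.99)$area_pct, 49.5,
               tolerance = 0.01)
  # all weight on one neuron: coverage collapses toward zero
  W1 <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 1,
                             dims = c(s$n_r, s$n_sc))
  expect_lt(sc_coverage(W1, s)$area_pct, 1)
  # the KDE route agrees up to its boundary smoothing
  expect_equal(sc_coverage(Wh, s, method = "kde")$area_pct, 49.5,
               tolerance = 0.15)
})

test_that("collapse detection recovers constructed merge points", {
  s <- medium_wt()
  expect_equal(collapse_point(make_mapping("identity", s))$status, "no_split")
  expect_equal(collapse_point(make_mapping("duplicated", s))$status,
               "no_merge")
  cp7 <- collapse_point(make_mapping("merged_at", s, merge_at = 0.7))
  expect_equal(cp7$status, "collapse")
  expect_equal(cp7$collapse_pct, 70, tolerance = 0.05) # within ~one bin
  cp5 <- collapse_point(make_mapping("merged_at", s, merge_at = 0.5))
  expect_equal(cp5$collapse_pct, 50, tolerance = 0.06)
  expect_error(collapse_point(make_mapping("identity", s)[1:5, ]),
               "insufficient")
})

test_that("projection histograms concentrate where the map sends mass", {
  s <- medium_wt()
  H <- projection_histogram(make_mapping("identity", s), "NT_AP", nbins = 20)
  # identity in canonical orientation: mass on the anti-diagonal
  anti <- sum(vapply(1:20, function(b) H[b, 21 - b], numeric(1)))
  expect_gt(anti / sum(H), 0.5)
  Hd <- projection_histogram(make_mapping("duplicated", s), "NT_AP",
                             nbins = 20)
  # two parallel ridges: rows with two occupied bands
  mid <- Hd[10, ]
  expect_gte(sum(mid > 0.1 * max(mid)), 2)
  Hr <- projection_histogram(make_mapping("random", s, seed = 5), "NT_AP",
                             nbins = 10)
  expect_lt(max(colSums(Hr)) / sum(Hr), 0.25)  # roughly uniform columns
})

test_that("analysis operations are deterministic given mapping and seed", {
  s <- medium_wt()
  mp <- make_mapping("merged_at", s, seed = 4)
  expect_identical(collapse_point(mp, seed = 2)$collapse_pct,
                   collapse_point(mp, seed = 2)$collapse_pct)
  la1 <- lattice_analysis(mp); la2 <- lattice_analysis(mp)
  expect_identical(la1$nodes_pct, la2$nodes_pct)
})
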