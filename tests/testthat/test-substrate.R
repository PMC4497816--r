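test_that("gradient profiles evaluate per their closed form", {
  # flat EphA4 profile: G1 = 0 makes the exponential term vanish
  epha4 <- gradient_params(1.05, 0, 0, 1)
  expect_equal(eval_gradient(epha4, c(0, 0.3, 1)), rep(1.05, 3))
  # exponential term equals G1 at x = G3
  epha5 <- gradient_params(0, 0.85, 1.8, 1)
  expect_equal(eval_gradient(epha5, 1), 0.85)
  # independent hand computation, including the max(0, .) clip
  ea2 <- gradient_params(-0.06, 0.35, 2, 0.8)
  expect_equal(eval_gradient(ea2, 0), max(0, -0.06 + 0.35 * exp(-1.6)))
  ea5 <- gradient_params(-0.1, 0.9, 3, 1)
  expect_equal(eval_gradient(ea5, 0), max(0, -0.1 + 0.9 * exp(-3)))
  expect_true(all(eval_gradient(ea5, seq(0, 1, 0.01)) >= 0))
  expect_error(gradient_params(0, 1, -1, 0))
})

test_that("summed wild-type gradients are peak-normalized to 1 and monotone", {
  grid <- seq(0, 1, length.out = 2001)
  peaks <- wt_peaks(100001)
  for (sys in c("EphA", "EphB", "ephrinA", "ephrinB")) {
    scaled <- summed_gradient(sys, grid) / peaks[[sys]]
    expect_lte(max(scaled), 1 + 1e-9)
    expect_gte(max(scaled), 1 - 1e-4)  # peak lies on/near the test grid
  }
  # EphA nondecreasing nasal -> temporal; ephrin-A nondecreasing A -> P
  expect_true(all(diff(summed_gradient("EphA", grid)) >= -1e-12))
  expect_true(all(diff(summed_gradient("ephrinA", grid)) >= -1e-12))
})

test_that("neuron placement respects count, outline and exclusion distance", {
  p1 <- place_neurons(1, retina_outline(), 0.1, seed = 1)
  expect_equal(nrow(p1), 1L)
  expect_true(in_polygon(p1[1, 1], p1[1, 2], retina_outline()))

  p <- place_neurons(400, retina_outline(), 0.0139, seed = 2)
  expect_equal(nrow(p), 400L)
  expect_gte(min(dist(p)), 0.0139)
  expect_true(all(in_polygon(p[, 1], p[, 2], retina_outline())))

  # area argument: only a handful of points with 0.5 spacing fit a unit disc
  expect_error(place_neurons(50, retina_outline(), 0.5, seed = 3),
               "packing infeasible")
})

test_that("genotype substrates implement the gradient modifications", {
  s <- small_wt(300, seed = 5)
  expect_lte(max(s$retina$R_A), 1)
  expect_gte(max(s$retina$R_A), 0.95)   # temporal-most RGC near the peak
  expect_false(any(s$retina$isl2))

  ki <- build_substrate("isl2_epha3_ki_ki", n_r = 2000, n_sc = 50, seed = 6)
  expect_gt(max(ki$retina$R_A), 1)      # knock-in exceeds the WT peak
  expect_equal(mean(ki$retina$isl2), 0.4, tolerance = 0.1)
  # EphA3 is flat, so Isl2+ cells sit above Isl2- cells at matched positions
  het <- build_substrate("isl2_epha3_ki_het", n_r = 500, n_sc = 50, seed = 6)
  expect_gt(max(het$retina$R_A), 1)
  expect_lt(max(het$retina$R_A), max(ki$retina$R_A))

  tko0 <- build_substrate(genotype_spec("tko", K = 0), n_r = 50, n_sc = 300,
                          seed = 7)
  expect_true(all(tko0$sc$L_A == 0))
  tkoK <- build_substrate(genotype_spec("tko", K = 0.1), n_r = 50, n_sc = 300,
                          seed = 7)
  wt <- build_substrate("wild_type", n_r = 50, n_sc = 300, seed = 7)
  expect_equal(tkoK$sc$L_A, 0.1 * wt$sc$L_A)
  expect_lt(max(tkoK$sc$L_A), 1)

  m5 <- build_substrate("math5", n_r = 2000, n_sc = 50, seed = 8)
  expect_equal(m5$n_r, 200L)
  expect_error(genotype_spec("unknown_genotype"))
})

test_that("substrates are reproducible and round-trip through serialization", {
  a <- small_wt(150, seed = 9)
  b <- small_wt(150, seed = 9)
  expect_identical(a$retina, b$retina)
  expect_identical(a$sc, b$sc)

  path <- file.path(tempdir(), "sub_roundtrip")
  write_substrate(a, path)
  r <- read_substrate(path)
  expect_equal(r$retina$x, a$retina$x)
  expect_equal(r$sc$L_A, a$sc$L_A)
  expect_equal(r$genotype$name, "wild_type")
  unlink(path, recursive = TRUE)
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(42)
  for (n in c(10, 40)) {
    x <- runif(n); y <- runif(n)
    dl <- delaunay(x, y)
    expect_gte(nrow(dl$triangles), 1)
    for (t in seq_len(nrow(dl$triangles))) {
      v <- dl$triangles[t, ]
      ax <- x[v[1]]; ay <- y[v[1]]; bx <- x[v[2]]; by <- y[v[2]]
      cx <- x[v[3]]; cy <- y[v[3]]
      d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
      ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
               (cx^2 + cy^2) * (ay - by)) / d
      uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
               (cx^2 + cy^2) * (bx - ax)) / d
      r2 <- (ax - ux)^2 + (ay - uy)^2
      others <- setdiff(seq_len(n), v)
      d2 <- (x[others] - ux)^2 + (y[others] - uy)^2
      expect_true(all(d2 >= r2 * (1 - 1e-9)))
    }
  }
})

test_that("sliver pruning drops hull shortcuts but keeps interior edges", {
  # a square grid has no angles below 45 degrees: nothing pruned
  g <- expand.grid(x = 0:4, y = 0:4)
  dl <- delaunay(g$x + 0.001 * sin(seq_len(25)), g$y)
  pruned <- prune_sliver_edges(dl$triangles, g$x + 0.001 * sin(seq_len(25)),
                               g$y)
  expect_equal(nrow(pruned), nrow(dl$edges))
  # three nearly collinear points beside a triangle: the long chord goes
  x <- c(0, 1, 2, 1); y <- c(0, 0.01, 0, 1)
  dl2 <- delaunay(x, y)
  pr2 <- prune_sliver_edges(dl2$triangles, x, y)
  expect_false(any(pr2[, 1] == 1 & pr2[, 2] == 3))
})

test_that("seed streams are deterministic, distinct, and leave the RNG alone", {
  s1 <- seed_streams(123, 5)
  s2 <- seed_streams(123, 5)
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 5L)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(seed_streams(1, 3)); after <- runif(1)
  expect_identical(before, after)
})
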