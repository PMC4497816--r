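test_that("induced markers are weight-weighted means of receptor densities", {
  s <- tiny_wt()
  n_r <- s$n_r; n_sc <- s$n_sc
  # single afferent: the induced marker equals that RGC's receptor level
  W <- matrix(0, n_r, n_sc)
  W[7, 1] <- 0.3
  im <- induced_markers(W, s)
  expect_equal(im$IA[1], s$retina$R_A[7])
  expect_equal(im$IB[1], s$retina$R_B[7])
  expect_true(im$zero_afferent[2])
  expect_true(is.na(im$IA[2]))
  # uniform weights: plain mean; always a convex combination
  W2 <- matrix(1, n_r, n_sc)
  im2 <- induced_markers(W2, s)
  expect_equal(im2$IA, rep(mean(s$retina$R_A), n_sc))
  W3 <- matrix(runif(n_r * n_sc), n_r, n_sc)
  im3 <- induced_markers(W3, s)
  expect_true(all(im3$IA >= min(s$retina$R_A) - 1e-12))
  expect_true(all(im3$IA <= max(s$retina$R_A) + 1e-12))
})

test_that("marker dynamics have the stated fixed points and ODE solution", {
  adj <- list(2L, c(1L, 3L), 2L)     # 3-node path graph
  # fixed points: zeta * IA * TA = 1 and TB = IB give zero change on a
  # spatially uniform field (Laplacian of a constant vanishes)
  TA <- rep(2, 3); IA <- rep(0.5, 3)
  TB <- rep(0.7, 3); IB <- rep(0.7, 3)
  st <- marker_step(TA, TB, IA, IB, adj, sigma = 0.05, delta = 0.01,
                    zeta = 1, dt = 0.1)
  expect_equal(st$TA, TA)
  expect_equal(st$TB, TB)
  # delta = 0, constant IB: TB relaxes exponentially at rate sigma
  TB2 <- c(0, 0, 0); IBc <- rep(1, 3)
  sigma <- 0.05; dt <- 0.1
  for (t in 1:200) {
    TB2 <- marker_step(rep(1, 3), TB2, rep(1, 3), IBc, adj, sigma = sigma,
                       delta = 0, zeta = 1, dt = dt)$TB
  }
  expect_equal(TB2, rep(1 - (1 - sigma * dt)^200, 3), tolerance = 1e-10)
  # graph Laplacian conserves total marker on a degree-regular graph
  ring <- lapply(1:6, function(j) c(((j - 2) %% 6) + 1L, (j %% 6) + 1L))
  T0 <- runif(6)
  st2 <- marker_step(T0, T0, rep(0, 6), T0, ring, sigma = 0, delta = 0.01,
                     zeta = 1, dt = 0.1)
  expect_equal(sum(st2$TA), sum(T0))
})

test_that("similarity peaks at a perfect match and weight rows normalize", {
  s <- tiny_wt()
  TA <- 1 / pmax(s$retina$R_A[1], 1e-9) + numeric(s$n_sc)  # match RGC 1
  Phi <- willshaw_similarity(s, TA, TB = s$retina$R_B[1] + numeric(s$n_sc))
  expect_equal(Phi[1, ], rep(1, s$n_sc))
  expect_true(all(Phi <= 1))
  # kappa -> Inf washes out all specificity
  Phi2 <- willshaw_similarity(s, TA, TB = rep(0, s$n_sc), kappa = 1e6)
  expect_true(all(abs(Phi2 - 1) < 1e-9))
  W <- matrix(runif(s$n_r * s$n_sc, 0, 1e-4), s$n_r, s$n_sc)
  W2 <- weight_step(W, Phi)
  expect_equal(unname(rowSums(W2)), rep(1, s$n_r))
})

test_that("the compiled core reproduces the R reference steps", {
  s <- small_wt(40, seed = 61)
  set.seed(8)
  W0 <- matrix(runif(s$n_r * s$n_sc, 0, 1e-4), s$n_r, s$n_sc)
  g <- willshaw_graph(s)
  n_steps <- 5
  res <- retinosim:::willshaw_run_cpp(
    s$retina$R_A, s$retina$R_B, W0, s$sc$L_A, s$sc$L_B,
    retinosim:::.adjacency_csr(g$edges, s$n_sc)$ptr,
    retinosim:::.adjacency_csr(g$edges, s$n_sc)$idx,
    0.05, 0.01, 0.1, 1, 0.0504, 0.1, n_steps, exp_floor = -745)
  W <- W0
  TA <- s$sc$L_A; TB <- s$sc$L_B
  lastIA <- rep(0, s$n_sc); lastIB <- rep(0, s$n_sc)
  for (t in seq_len(n_steps)) {
    im <- induced_markers(W, s)
    IA <- ifelse(im$zero_afferent, lastIA, im$IA)
    IB <- ifelse(im$zero_afferent, lastIB, im$IB)
    lastIA <- IA; lastIB <- IB
    mk <- marker_step(TA, TB, IA, IB, g$adjacency)
    TA <- mk$TA; TB <- mk$TB
    W <- weight_step(W, willshaw_similarity(s, TA, TB))
  }
  expect_equal(res$TA, TA, tolerance = 1e-10)
  expect_equal(res$TB, TB, tolerance = 1e-10)
  expect_equal(res$W, W, tolerance = 1e-9)
})

test_that("weights stay presynaptically normalized across a run", {
  s <- small_wt(60, seed = 62)
  v <- run_willshaw(s, n_steps = 300, seed = 2)
  expect_equal(unname(rowSums(v$W)), rep(1, s$n_r), tolerance = 1e-9)
})

test_that("induction regrows markers in the ephrin-A knock-out", {
  s <- build_substrate(genotype_spec("tko", K = 0), n_r = 60, n_sc = 60,
                       seed = 63)
  expect_true(all(s$sc$L_A == 0))       # initial T^A = 0 everywhere
  v <- run_willshaw(s, n_steps = 500, seed = 3)
  expect_gt(min(v$aux$TA), 0)           # sigma term regrows the marker
})

test_that("a wild-type Willshaw run is topographic in canonical orientation", {
  s <- small_wt(200, seed = 64)
  v <- run_willshaw(s, n_steps = 4000, seed = 4)
  mp <- strongest_mapping(threshold_weights(v), s)
  expect_lt(cor(mp$rx, mp$sx), -0.8)
  expect_lt(cor(mp$ry, mp$sy), -0.8)
})
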