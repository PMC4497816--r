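test_that("the adhesion matrix is nonnegative with the stated structure", {
  s <- tiny_wt()
  M <- adhesion_matrix(s)
  expect_true(all(M >= 0))
  expect_equal(dim(M), c(s$n_r, s$n_sc))
  # at the SC neuron attaining max L_A the A-term bracket vanishes
  jmax <- which.max(s$sc$L_A)
  expect_equal(M[, jmax], s$retina$R_B * s$sc$L_B[jmax])
  # an RGC with no EphA contributes only the attractive B term
  s2 <- s; s2$retina$R_A[1] <- 0
  M2 <- adhesion_matrix(s2)
  expect_equal(M2[1, ], s2$retina$R_B[1] * s2$sc$L_B)
})

test_that("wave activity sums to exactly 2 with uniform member levels", {
  s <- small_wt(120, seed = 51)
  for (q in c(1, 17, 120)) {
    x <- wave_activity(q, s, r_r = 0.07)
    expect_equal(sum(x), 2)
    act <- x[x > 0]
    expect_equal(length(unique(act)), 1L)      # uniform within the wave
    expect_gt(x[q], 0)                         # centre is included
  }
  # an isolated centre carries the whole wave
  xiso <- wave_activity(1, s, r_r = 1e-9)
  expect_equal(xiso[1], 2)
  expect_equal(sum(xiso > 0), 1L)
})

test_that("one epoch matches the hand-computed Hebbian accumulation", {
  # 3 RGCs / 3 SC neurons, M = 0, waves isolated to each RGC: the epoch
  # update reduces to dW = dt * (x y^T summed over waves - mu * 1 v^T)
  s <- tiny_wt()
  s$retina <- s$retina[1:3, ]; s$sc <- s$sc[1:3, ]
  s$n_r <- 3L; s$n_sc <- 3L
  s$retina$x <- c(0.1, 0.5, 0.9); s$retina$y <- rep(0.5, 3)
  s$sc$x <- c(0.1, 0.5, 0.9); s$sc$y <- rep(0.2, 3)
  s$retina$R_A <- 0; s$retina$R_B <- 0   # adhesion M = 0
  s$sc$L_A <- 0; s$sc$L_B <- 0
  W <- matrix(c(1, 2, 0, 0, 1, 0, 1, 0, 3), 3, 3, byrow = TRUE)
  dt <- 0.01; mu <- 0.1; k <- 0.5
  W2 <- whitelaw_epoch(W, s, dt = dt, mu = mu, r_r = 0.05, r_sc = 0.05,
                       k = k, w_min = 0)
  # waves: x^(q) = 2 e_q; y^I = W^T x = 2 W[q, ]; y = k * y^I (isolated SC)
  A <- matrix(0, 3, 3); v <- numeric(3)
  for (q in 1:3) {
    x <- 2 * (seq_len(3) == q)
    y <- k * as.numeric(crossprod(W, x))
    A <- A + outer(x, y)
    v <- v + y
  }
  Wexp <- W + dt * ((0 + 1) * A - mu * matrix(v, 3, 3, byrow = TRUE))
  Wexp[Wexp < 0] <- 0                  # w_min clipping (here w_min = 0)
  # then the ordered normalization: columns to n_r, rows to n_sc
  cs <- colSums(Wexp); nz <- cs > 0
  Wexp[, nz] <- Wexp[, nz] * rep(3 / cs[nz], each = 3)
  rs <- rowSums(Wexp)
  Wexp <- Wexp * (3 / rs)
  expect_equal(W2, Wexp, tolerance = 1e-12)
})

test_that("normalization order and invariants hold over a short run", {
  s <- small_wt(100, seed = 52)
  w <- run_whitelaw(s, n_epochs = 30, seed = 1)
  expect_true(all(w$W >= 0))
  expect_equal(unname(rowSums(w$W)), rep(s$n_sc, s$n_r), tolerance = 1e-9)
  # the first-stage (column) normalization is subsequently distorted by the
  # row stage, but column sums must stay near n_r (mass is balanced)
  expect_equal(mean(colSums(w$W)), s$n_r, tolerance = 0.05)
})

test_that("a wild-type Whitelaw run refines toward the canonical topography", {
  s <- small_wt(220, seed = 53)
  w <- run_whitelaw(s, n_epochs = 250, seed = 1)
  mp <- strongest_mapping(threshold_weights(w), s)
  expect_lt(cor(mp$rx, mp$sx), -0.6)
  expect_lt(cor(mp$ry, mp$sy), -0.6)
})
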