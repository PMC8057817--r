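# Rotational channels, low-rank factorization and amplification theory.

test_that("rotational-channel connectivities have the predicted spectra", {
  set.seed(21)
  B <- qr.Q(qr(matrix(rnorm(12 * 2), 12)))
  b <- rotational_channel_bank(1, 7, B)
  J <- build_connectivity(b)
  ev <- eigen(J, only.values = TRUE)$values
  nz <- ev[Mod(ev) > 1e-8]
  expect_equal(sort(Im(nz)), c(-sqrt(7), sqrt(7)), tolerance = 1e-10)
  expect_lt(max(abs(Re(nz))), 1e-10)
  # balanced channel: antisymmetric, symmetric part identically zero
  bb <- rotational_channel_bank(2, 2, B)
  Jb <- build_connectivity(bb)
  expect_equal(Jb, -t(Jb), tolerance = 1e-12)
  expect_lt(max(abs(eigen((Jb + t(Jb)) / 2, only.values = TRUE)$values)),
            1e-12)
})

test_that("a 20-channel bank on 1000 units has dense rank 40", {
  set.seed(22)
  B <- qr.Q(qr(matrix(rnorm(1000 * 40), 1000)))
  b <- rotational_channel_bank(1, 7, B)
  J <- build_connectivity(b)
  d <- svd(J, nu = 0, nv = 0)$d
  expect_equal(sum(d > 1e-8 * d[1]), 40)
})

test_that("non-orthogonal channel bases are rejected with a report", {
  B <- cbind(c(1, 0, 0, 0), c(0.6, 0.8, 0, 0))
  expect_error(rotational_channel_bank(1, 7, B), "not orthonormal")
})

test_that("the amplification criterion matches special cases and sampling", {
  # unit-rank with orthogonal patterns, ||u|| = 3
  u <- c(3, 0, 0, 0); v <- c(0, 1, 0, 0)
  ac <- amplification_criterion(tcrossprod(u, v))
  expect_equal(ac$lambda_max_sym, 1.5, tolerance = 1e-12)
  expect_true(ac$amplified)
  # rank-2 channel: lambda_max_sym = |d2 - d1| / 2
  for (d2 in c(3, 7)) {
    b <- rotational_channel_bank(1, d2, diag(6)[, 1:2])
    expect_equal(amplification_criterion(build_connectivity(b))$lambda_max_sym,
                 (d2 - 1) / 2, tolerance = 1e-10)
  }
  # random networks: flag agrees with an optimization oracle over unit states
  set.seed(23)
  for (lam in c(0.8, 1.25)) {
    J <- random_connectivity_with_sym(50, lam, seed = 23 + round(100 * lam))
    ac <- amplification_criterion(J)
    g <- sampled_max_growth(J)
    expect_equal(ac$amplified, g > 0)
  }
})

test_that("unit-rank stability and amplification thresholds are exact", {
  mkuv <- function(nu, ct) {
    v <- c(1, 0, 0)
    u <- nu * (ct * v + sqrt(1 - ct^2) * c(0, 1, 0))
    list(u = u, v = v)
  }
  # orthogonal patterns: threshold 2
  p <- mkuv(1, 0)
  expect_equal(unit_rank_conditions(p$u, p$v)$amplification_threshold, 2)
  # aligned patterns: threshold 1 but stability forbids amplification
  p <- mkuv(0.9, 1)
  res <- unit_rank_conditions(p$u, p$v)
  expect_equal(res$amplification_threshold, 1)
  expect_true(res$stable)
  expect_false(res$amplified)
  # cos(theta) = 0.25: threshold 1.6, cross-checked by bisection on
  # lambda_max(J_S) = 1
  p <- mkuv(1, 0.25)
  thr <- unit_rank_conditions(p$u, p$v)$amplification_threshold
  expect_equal(thr, 1.6, tolerance = 1e-12)
  f <- function(nu) {
    q <- mkuv(nu, 0.25)
    amplification_criterion(tcrossprod(q$u, q$v))$lambda_max_sym - 1
  }
  lo <- 1; hi <- 3
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal((lo + hi) / 2, thr, tolerance = 1e-6)
  # antiparallel patterns: threshold undefined, flagged
  res2 <- unit_rank_conditions(c(-2, 0, 0), c(1, 0, 0))
  expect_false(res2$threshold_defined)
  expect_true(is.na(res2$amplification_threshold))
})

test_that("the overlap matrix carries the nonzero spectrum of the dense J", {
  # rank-2 channel form
  b <- rotational_channel_bank(1, 7, diag(8)[, 1:2])
  lrc <- low_rank_connectivity(U = cbind(1 * b$basis[, 2], -7 * b$basis[, 1]),
                               V = b$basis[, 1:2])
  expect_equal(lr_overlap_matrix(lrc), rbind(c(0, -7), c(1, 0)),
               tolerance = 1e-12)
  # all-orthogonal patterns: zero overlap matrix, nilpotent dense J
  set.seed(24)
  Q <- qr.Q(qr(matrix(rnorm(10 * 4), 10)))
  lrc2 <- low_rank_connectivity(U = 2 * Q[, 1:2], V = Q[, 3:4])
  expect_equal(lr_overlap_matrix(lrc2), matrix(0, 2, 2), tolerance = 1e-12)
  J2 <- as_dense(lrc2)
  expect_lt(max(abs(J2 %*% J2)), 1e-12)
  # random rank-4 instance: overlap eigenvalues equal dense eigenvalues
  set.seed(25)
  J4 <- matrix(rnorm(30 * 4), 30) %*% t(matrix(rnorm(30 * 4), 30)) / 10
  lrc4 <- low_rank_connectivity(J4)
  expect_equal(lrc4$rank, 4)
  ev_ov <- sort(Mod(eigen(lr_overlap_matrix(lrc4), only.values = TRUE)$values))
  ev_d <- eigen(J4, only.values = TRUE)$values
  ev_d <- sort(Mod(ev_d[Mod(ev_d) > 1e-8]))
  expect_equal(ev_ov, ev_d, tolerance = 1e-10)
})

test_that("canonical factorization reproduces the dense matrix", {
  set.seed(26)
  J <- matrix(rnorm(20 * 3), 20) %*% t(matrix(rnorm(20 * 3), 20)) / 5
  lrc <- low_rank_connectivity(J)
  expect_equal(as_dense(lrc), J, tolerance = 1e-10)
  expect_equal(colSums(lrc$V^2), rep(1, lrc$rank), tolerance = 1e-12)
  # sign convention: largest-magnitude entry of each V column is positive
  for (k in seq_len(lrc$rank)) {
    expect_gt(lrc$V[which.max(abs(lrc$V[, k])), k], 0)
  }
})

test_that("closed-form channel trajectories equal dense propagation", {
  set.seed(27)
  B <- qr.Q(qr(matrix(rnorm(30 * 6), 30)))
  b <- rotational_channel_bank(c(1, 2, 0.5), c(7, 5, 9), B)
  r0 <- rnorm(30); r0 <- r0 / sqrt(sum(r0^2))
  dec <- initial_state_decomposition(b, r0 = r0)
  ts <- seq(0, 2, by = 0.05)
  cf <- closed_form_trajectory(b, dec, ts)
  pr <- propagate(build_connectivity(b), r0, ts)
  expect_lt(max(abs(cf$values - pr$values)), 1e-8)
})

test_that("norms follow the closed form for states along v1 and z_perp", {
  d1 <- 1; d2 <- 7
  b <- rotational_channel_bank(d1, d2, diag(10)[, 1:2])
  ts <- seq(0, 2, by = 0.01)
  # r0 = v1: never amplified, norm below exp(-t)
  dec1 <- initial_state_decomposition(b, alpha1 = 1)
  n1 <- distance_from_baseline(closed_form_trajectory(b, dec1, ts))
  w <- b$omega[1]
  expect_equal(n1^2,
               exp(-2 * ts) * (1 + (d1 / d2 - 1) * sin(w * ts)^2),
               tolerance = 1e-10)
  expect_true(all(n1[-1] < exp(-ts[-1]) + 1e-12))
  # beta = 1: pure exponential decay along z_perp
  dec2 <- initial_state_decomposition(b, beta = 1, z_perp = diag(10)[, 5])
  n2 <- distance_from_baseline(closed_form_trajectory(b, dec2, ts))
  expect_equal(n2, exp(-ts), tolerance = 1e-12)
})

test_that("balanced channels never amplify for any initial state", {
  set.seed(28)
  B <- qr.Q(qr(matrix(rnorm(14 * 4), 14)))
  b <- rotational_channel_bank(3, 3, B)
  for (rep in 1:5) {
    r0 <- rnorm(14); r0 <- r0 / sqrt(sum(r0^2))
    dec <- initial_state_decomposition(b, r0 = r0)
    n <- distance_from_baseline(
      closed_form_trajectory(b, dec, seq(0, 2, by = 0.05)))
    expect_equal(n, exp(-seq(0, 2, by = 0.05)), tolerance = 1e-10)
  }
})

test_that("initial-state amplification conditions behave as derived", {
  b <- rotational_channel_bank(1, 7, diag(8)[, 1:2])
  # fully orthogonal state only decays
  res <- initial_state_condition(
    b, initial_state_decomposition(b, beta = 1, z_perp = diag(8)[, 5]),
    t_star = 0.3)
  expect_false(res$satisfied)
  expect_equal(res$margin, 1 - exp(0.6), tolerance = 1e-12)
  # state along v2 of an amplified channel is amplified at the peak
  dec2 <- initial_state_decomposition(b, alpha2 = 1)
  res2 <- initial_state_condition(b, dec2)
  expect_true(res2$satisfied)
  # alpha2 component below the bound fails the condition
  bound <- res2$alpha2_sq_bound
  a2 <- sqrt(bound * 0.8)
  dec3 <- initial_state_decomposition(b, alpha1 = sqrt(1 - a2^2),
                                      alpha2 = a2)
  res3 <- initial_state_condition(b, dec3, t_star = res2$t_star)
  expect_false(res3$satisfied)
})

test_that("implicit symmetric-part eigenvalues match the dense solver", {
  set.seed(29)
  for (rep in 1:5) {
    N <- sample(10:40, 1); R <- sample(2:6, 1)
    J <- matrix(rnorm(N * R), N) %*% t(matrix(rnorm(N * R), N)) / N
    lrc <- low_rank_connectivity(J)
    implicit <- lowrank_sym_eigs(lrc)
    direct <- eigen((J + t(J)) / 2, symmetric = TRUE,
                    only.values = TRUE)$values
    direct <- direct[abs(direct) > 1e-10]
    expect_equal(sort(implicit[abs(implicit) > 1e-10]), sort(direct),
                 tolerance = 1e-8)
  }
})

test_that("initial-peak correlation vanishes as the delta ratio grows", {
  set.seed(30)
  B <- qr.Q(qr(matrix(rnorm(16 * 4), 16)))
  cors <- vapply(c(2, 10, 100), function(ratio) {
    b <- rotational_channel_bank(1, ratio, B)
    dec <- initial_state_decomposition(b, alpha2 = c(0.8, 0.6))
    tr <- closed_form_trajectory(b, dec,
                                 seq(0, 3, length.out = 3000))
    abs(initial_peak_correlation(tr))
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
  expect_lt(cors[3], 0.02)
})

test_that("channel banks round-trip through YAML", {
  set.seed(32)
  B <- qr.Q(qr(matrix(rnorm(10 * 4), 10)))
  b <- rotational_channel_bank(c(1, 2), c(7, 5), B)
  path <- tempfile(fileext = ".yaml")
  write_bank_yaml(b, path)
  back <- read_bank_yaml(path)
  expect_equal(back$delta1, b$delta1)
  expect_equal(back$delta2, b$delta2)
  expect_equal(back$basis, b$basis, tolerance = 1e-12)
})
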