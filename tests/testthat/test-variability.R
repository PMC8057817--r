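# Single-trial variance structure, variability amplification and the
# shuffle contrast separating recurrent from single-cell mechanisms.

test_that("variance along directions matches its definition", {
  set.seed(101)
  T_ <- 6; N <- 20
  vals <- array(0, c(5, T_, N))
  sig <- matrix(rnorm(T_ * N), T_)
  for (tr in 1:5) vals[tr, , ] <- sig
  tt <- trial_tensor(vals, seq(0, 0.5, by = 0.1), rep("a", 5))
  d <- rnorm(N); d <- d / sqrt(sum(d^2))
  expect_equal(variance_along(tt, d, 0), 0)
  expect_error(variance_along(tt, rep(0, N), 0), "nonzero")
  # isotropic initial noise: C(0) = s^2 I, any direction gives ~ s^2
  set.seed(102)
  s <- 0.3; ntr <- 4000
  vals2 <- array(rnorm(ntr * 2 * N, 0, s), c(ntr, 2, N))
  tt2 <- trial_tensor(vals2, c(0, 0.1), rep("a", ntr))
  for (i in 1:3) {
    d <- rnorm(N); d <- d / sqrt(sum(d^2))
    expect_equal(variance_along(tt2, d, 0), s^2, tolerance = 0.1)
  }
})

test_that("propagated noise variance follows the propagator singular values", {
  set.seed(103)
  N <- 24
  B <- qr.Q(qr(matrix(rnorm(N * 2), N)))
  b <- rotational_channel_bank(1, 7, B)
  J <- build_connectivity(b)
  fit <- structure(list(J = J, lambda = 0, rank = NULL, pc_basis = NULL,
                        center = rep(0, N), cv_r2 = NA_real_),
                   class = "network_fit")
  r0 <- B[, 2]
  s <- 0.1
  ts <- seq(0, 1.2, by = 0.1)
  tt <- generate_single_trials(fit, r0, s^2, n_trials = 4000, times = ts,
                               seed = 104)
  ad <- amplified_direction(tt)
  # Pt at the peak time
  Pt <- as.matrix(Matrix::expm(Matrix::Matrix((J - diag(N)) * ad$t_star)))
  sv <- svd(Pt)
  # variance along the amplified direction vs the closed form
  # sum(a_k^2 s_k^4) / sum(a_k^2 s_k^2) with a_k the components of r0 on
  # the propagator's right singular vectors
  a <- as.numeric(crossprod(sv$v, r0))
  pred_ampl <- s^2 * sum(a^2 * sv$d^4) / sum(a^2 * sv$d^2)
  obs <- variance_along(tt, ad$direction, ad$t_star)
  expect_equal(obs, pred_ampl, tolerance = 0.1)
  # empirical covariance at t* approaches s^2 Pt Pt'
  idx <- ad$index
  X <- matrix(tt$values[, idx, ], dim(tt$values)[1], N)
  Chat <- cov(X)
  expect_lt(norm(Chat - s^2 * tcrossprod(Pt), "F") /
              norm(s^2 * tcrossprod(Pt), "F"), 0.15)
})

test_that("empirical covariance converges to the propagated form as 1/sqrt(n)", {
  set.seed(105)
  N <- 12
  J <- matrix(rnorm(N^2), N) / sqrt(N) * 0.5
  fit <- structure(list(J = J, pc_basis = NULL, center = rep(0, N)),
                   class = "network_fit")
  Pt <- as.matrix(Matrix::expm(Matrix::Matrix((J - diag(N)) * 0.5)))
  target <- 0.04 * tcrossprod(Pt)
  errs <- vapply(c(400, 6400), function(n) {
    tt <- generate_single_trials(fit, rnorm(N), 0.04, n_trials = n,
                                 times = c(0, 0.25, 0.5), seed = 106)
    X <- matrix(tt$values[, 3, ], n, N)
    norm(cov(X) - target, "F")
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2)  # ~1/sqrt(n) with 16x more trials
})

test_that("the amplified direction approaches -v1 for strong rotation", {
  set.seed(107)
  N <- 30
  B <- qr.Q(qr(matrix(rnorm(N * 2), N)))
  b <- rotational_channel_bank(1, 60, B)
  J <- build_connectivity(b)
  fit <- structure(list(J = J, pc_basis = NULL, center = rep(0, N)),
                   class = "network_fit")
  tt <- generate_single_trials(fit, B[, 2], 1e-4, n_trials = 5,
                               times = seq(0, 0.5, by = 0.01), seed = 108)
  ad <- amplified_direction(tt)
  expect_gt(abs(sum(ad$direction * B[, 1])), 0.98)
  # stability of the direction under trial subsampling
  ds <- cached_fixture("network_small")
  ad_full <- amplified_direction(ds$tensor, "1")
  idx <- which(ds$tensor$stimulus == "1")[1:19]
  sub <- trial_tensor(ds$tensor$values[c(idx, which(ds$tensor$stimulus != "1")[1]), , ],
                      ds$tensor$times, rep("1", 20))
  ad_sub <- amplified_direction(sub, "1")
  angle <- acos(min(1, abs(sum(ad_full$direction * ad_sub$direction))))
  expect_lt(angle, 10 * pi / 180)
})

test_that("VA is below one for pure decay and large along amplified modes", {
  set.seed(109)
  N <- 15
  fitd <- structure(list(J = diag(0.2, N), pc_basis = NULL,
                         center = rep(0, N)), class = "network_fit")
  ttd <- generate_single_trials(fitd, rnorm(N), 0.01, n_trials = 200,
                                times = seq(0, 1, by = 0.1), seed = 110)
  d <- rnorm(N); d <- d / sqrt(sum(d^2))
  # decaying dynamics peak at t = 0, so VA relative to any later time is
  # below one
  expect_lte(variability_amplification(ttd, d), 1)
  expect_lt(variance_along(ttd, d, 0.5) / variance_along(ttd, d, 0), 1)
  # network fixture: VA(ampl) >> 1, VA(rand) = O(1)
  ds <- cached_fixture("network_small")
  ad <- amplified_direction(ds$tensor, "1")
  va_a <- variability_amplification(ds$tensor, ad$direction, "1")
  set.seed(111)
  va_r <- mean(replicate(10, {
    d <- rnorm(dim(ds$tensor$values)[3])
    variability_amplification(ds$tensor, d / sqrt(sum(d^2)), "1")
  }))
  expect_gt(va_a, 2)
  expect_lt(va_r, 2)
})

test_that("trial shuffling preserves marginals and destroys correlations", {
  set.seed(112)
  ntr <- 20; T_ <- 4; N <- 100
  # planted correlated noise across neurons
  shared <- array(rnorm(ntr * T_), c(ntr, T_))
  vals <- array(rnorm(ntr * T_ * N, 0, 0.3), c(ntr, T_, N)) +
    outer(shared, rep(1, N))
  tt <- trial_tensor(vals, seq(0, 0.3, by = 0.1), rep("a", ntr))
  sh <- shuffle_trials(tt, seed = 113)
  # per-neuron per-time histograms exactly preserved
  for (n in c(1, 50)) for (ti in 1:T_) {
    expect_equal(sort(sh$values[, ti, n]), sort(tt$values[, ti, n]))
  }
  # off-diagonal covariance magnitude shrinks at least 5x
  od <- function(x) {
    C <- cov(matrix(x[, 1, ], ntr, N))
    mean(abs(C[row(C) != col(C)]))
  }
  expect_gt(od(tt$values) / od(sh$values), 5)
  # determinism under a fixed seed
  expect_identical(shuffle_trials(tt, seed = 113)$values, sh$values)
})

test_that("model-generated single trials have the predicted structure", {
  set.seed(114)
  N <- 10
  J <- matrix(rnorm(N^2), N) / sqrt(N) * 0.4
  fit <- structure(list(J = J, pc_basis = NULL, center = rep(0, N)),
                   class = "network_fit")
  # zero covariance: every trial equals the mean trajectory
  tt0 <- generate_single_trials(fit, rnorm(N), 0, n_trials = 3,
                                times = c(0, 0.2, 0.4), seed = 115)
  expect_equal(tt0$values[1, , ], tt0$values[3, , ], tolerance = 1e-12)
  # indefinite covariance is rejected
  bad <- diag(N); bad[1, 1] <- -1
  expect_error(generate_single_trials(fit, rnorm(N), bad, 3,
                                      c(0, 0.1), seed = 1),
               "semidefinite")
  # single-cell model: diagonal covariance s^2 L_i(t)^2
  ds <- cached_fixture("single_cell_small")
  resp <- trial_average(ds$tensor)
  scf <- fit_single_cell(resp, keep_frac = 1)
  s <- 0.2
  ttc <- generate_single_trials(scf, scf$ranges[, 1], s^2 * diag(nrow(scf$B)),
                                n_trials = 3000,
                                times = scf$times, seed = 116)
  L <- single_cell_filters(scf)
  ti <- 5
  X <- matrix(ttc$values[, ti, ], 3000)
  Chat <- cov(X)
  expect_equal(unname(diag(Chat)), unname(s^2 * L[, ti]^2), tolerance = 0.15)
  expect_lt(mean(abs(Chat[row(Chat) != col(Chat)])),
            0.05 * s^2 * mean(L[, ti]^2) + 1e-4)
})

test_that("the VA contrast separates network from single-cell data", {
  nd <- cached_fixture("network_small")
  van <- va_contrast(nd$tensor, n_direction_samples = 10,
                     n_subsamples = 20, n_shuffles = 30, seed = 117)
  expect_gte(mean(van$per_stimulus$p_value < 0.05), 0.75)
  expect_true(all(van$per_stimulus$delta_va_real >
                    van$per_stimulus$delta_va_shuffled))
  expect_lt(van$p_value_pooled, 0.15)  # floor of the n=4 signed-rank test
  sc <- cached_fixture("single_cell_small")
  vas <- va_contrast(sc$tensor, n_direction_samples = 10,
                     n_subsamples = 20, n_shuffles = 30, seed = 118)
  # diagonal covariance: shuffling changes nothing systematically; single
  # realizations of VA still scatter, so the comparison is on the mean
  expect_gt(min(vas$per_stimulus$p_value), 0.05)
  expect_gt(vas$p_value_pooled, 0.05)
  rel <- abs(mean(vas$per_stimulus$va_amplified) -
               mean(vas$per_stimulus$va_amplified_shuffled)) /
    mean(vas$per_stimulus$va_amplified)
  expect_lt(rel, 0.5)
})
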