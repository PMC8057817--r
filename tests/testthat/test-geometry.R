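# Dimensionality curves, cross-validated PCA, subspace overlaps and the
# shuffle-based significance controls.

test_that("cumulative variance saturates at the true dimensionality", {
  set.seed(71)
  N <- 40
  Q <- qr.Q(qr(matrix(rnorm(N * 5), N)))
  resp <- trajectory(matrix(rnorm(30 * 5), 30) %*% t(Q),
                     seq(0, 2.9, by = 0.1))
  cv <- cumulative_variance(resp)
  expect_equal(cv[5], 1, tolerance = 1e-10)
  expect_lt(cv[4], 1 - 1e-6)
  expect_true(all(diff(cv) >= -1e-12))
  expect_error(cumulative_variance(list()), "trajectory|empty")
})

test_that("16 orthogonal 5-dim responses span exactly 80 components", {
  set.seed(72)
  N <- 120
  Q <- qr.Q(qr(matrix(rnorm(N * 80), N)))
  resp <- lapply(1:16, function(s) {
    co <- qr.Q(qr(matrix(rnorm(10 * 5), 10)))  # equal variance per dim
    trajectory(co %*% t(Q[, (s - 1) * 5 + 1:5]), seq(0, 0.9, by = 0.1))
  })
  cv <- cumulative_variance(resp)
  ev <- attr(cv, "eigenvalues")
  expect_equal(sum(ev > 1e-10 * ev[1]), 80)
  expect_equal(cv[80], 1, tolerance = 1e-10)
})

test_that("isotropic noise yields a linear cumulative-variance curve", {
  set.seed(73)
  N <- 10
  resp <- trajectory(matrix(rnorm(2000 * N), 2000),
                     seq(0.001, 2, by = 0.001))
  cv <- cumulative_variance(resp)
  expect_lt(max(abs(as.numeric(cv) - seq_len(N) / N)), 0.05)
})

test_that("cvPCA equals ordinary PCA on noiseless repeated trials", {
  set.seed(74)
  T_ <- 8; N <- 25
  sig <- matrix(rnorm(T_ * N), T_)
  vals <- array(0, c(4, T_, N))
  for (tr in 1:4) vals[tr, , ] <- sig
  tt <- trial_tensor(vals, seq(0, 0.7, by = 0.1), rep("a", 4))
  sp <- cvpca_spectrum(tt, n_components = 5)
  expect_equal(as.numeric(sp), attr(sp, "naive")[1:5], tolerance = 1e-10)
  expect_error(cvpca_spectrum(trial_tensor(vals[1, , , drop = FALSE],
                                           seq(0, 0.7, by = 0.1), "a")),
               "two trials")
})

test_that("cvPCA is unbiased at the null while naive PCA is not", {
  set.seed(75)
  T_ <- 8; N <- 40; ntr <- 12
  means_cv <- replicate(30, {
    vals <- array(rnorm(ntr * T_ * N), c(ntr, T_, N))
    tt <- trial_tensor(vals, seq(0, 0.7, by = 0.1), rep("a", ntr))
    sp <- cvpca_spectrum(tt, n_components = 3, max_pairs = 20)
    c(cv = mean(sp), naive = mean(attr(sp, "naive")))
  })
  expect_lt(abs(mean(means_cv["cv", ])), 0.5)
  expect_gt(mean(means_cv["naive", ]), 2)
})

test_that("subspace overlap matches a direct optimization oracle", {
  set.seed(76)
  N <- 200
  mkresp <- function() {
    Q <- qr.Q(qr(matrix(rnorm(N * 5), N)))
    trajectory(matrix(rnorm(12 * 5), 12) %*% t(Q), seq(0, 1.1, by = 0.1))
  }
  r1 <- mkresp(); r2 <- mkresp()
  ov <- subspace_overlap(r1, r2, k = 5)
  # oracle: alternating maximization of u.v over the two 5-dim spans
  Q1 <- svd(sweep(r1$values, 2, colMeans(r1$values)))$v[, 1:5]
  Q2 <- svd(sweep(r2$values, 2, colMeans(r2$values)))$v[, 1:5]
  a <- rnorm(5); a <- a / sqrt(sum(a^2))
  for (i in 1:200) {
    b <- crossprod(Q2, Q1 %*% a); b <- b / sqrt(sum(b^2))
    a <- crossprod(Q1, Q2 %*% b); a <- a / sqrt(sum(a^2))
  }
  oracle <- as.numeric(t(Q1 %*% a) %*% (Q2 %*% b))
  expect_equal(ov, oracle, tolerance = 1e-6)
  # identical and orthogonal extremes
  expect_equal(subspace_overlap(r1, r1, k = 5), 1, tolerance = 1e-10)
  set.seed(77)
  Q <- qr.Q(qr(matrix(rnorm(N * 10), N)))
  ra <- trajectory(matrix(rnorm(12 * 5), 12) %*% t(Q[, 1:5]),
                   seq(0, 1.1, by = 0.1))
  rb <- trajectory(matrix(rnorm(12 * 5), 12) %*% t(Q[, 6:10]),
                   seq(0, 1.1, by = 0.1))
  expect_lt(subspace_overlap(ra, rb, k = 5, center = FALSE), 1e-10)
  expect_error(subspace_overlap(ra, rb, k = 50), "components")
})

test_that("subspace overlap is symmetric and rotation invariant", {
  set.seed(78)
  N <- 50
  r1 <- trajectory(matrix(rnorm(10 * N), 10), seq(0, 0.9, by = 0.1))
  r2 <- trajectory(matrix(rnorm(10 * N), 10), seq(0, 0.9, by = 0.1))
  expect_equal(subspace_overlap(r1, r2, 3), subspace_overlap(r2, r1, 3),
               tolerance = 1e-12)
  R <- qr.Q(qr(matrix(rnorm(N^2), N)))
  r1r <- trajectory(r1$values %*% R, r1$times)
  r2r <- trajectory(r2$values %*% R, r2$times)
  expect_equal(subspace_overlap(r1r, r2r, 3), subspace_overlap(r1, r2, 3),
               tolerance = 1e-10)
})

test_that("planted cluster structure appears in the overlap matrix", {
  ds <- cached_fixture("two_orthogonal_channels")
  resp <- trial_average(ds$tensor)
  os <- overlap_structure(resp, k = 2)
  v <- os$overlaps$values
  expect_gt(min(v["1", "2"], v["3", "4"]), 0.8)
  expect_lt(max(v["1", "3"], v["1", "4"], v["2", "3"]), 0.3)
  expect_gt(os$structure_correlation, 0.8)
  # subtracting the initial-state component keeps the block structure
  os2 <- overlap_structure(resp, k = 2, subtract_initial = TRUE)
  expect_gt(os2$overlaps$values["1", "2"], 0.6)
  expect_gt(os2$structure_correlation, 0.8)
  # identical responses give overlap 1 everywhere
  os3 <- overlap_structure(list(a = resp[[1]], b = resp[[1]]), k = 2)
  expect_equal(os3$overlaps$values, matrix(1, 2, 2,
               dimnames = list(c("a", "b"), c("a", "b"))), tolerance = 1e-10)
})

test_that("label-shuffle control flags planted orthogonality", {
  ds <- cached_fixture("two_orthogonal_channels")
  om <- significance_controls(ds$tensor, "overlap", "label_shuffle",
                              n_resamples = 40, k = 2, seed = 81)
  # orthogonal pair (different channels) strongly significant
  expect_lt(om$p_values["1", "3"], 0.05)
  expect_true(all(diag(is.na(om$p_values))))
})

test_that("split-half control flags orthogonal but not identical pairs", {
  ds <- cached_fixture("two_orthogonal_channels")
  om <- significance_controls(ds$tensor, "overlap", "split_half",
                              n_resamples = 25, k = 2, seed = 82)
  expect_lt(om$p_values["1", "3"], 0.05)
  # two labels drawn from one stimulus distribution are not distinguished
  set.seed(87)
  sig <- trial_average(ds$tensor)[["1"]]$values
  T_ <- nrow(sig); N <- ncol(sig)
  vals <- array(0, c(40, T_, N))
  for (tr in 1:40) vals[tr, , ] <- sig + matrix(rnorm(T_ * N, 0, 0.05),
                                                T_, N)
  ttn <- trial_tensor(vals, ds$tensor$times, rep(c("a", "b"), each = 20))
  omn <- significance_controls(ttn, "overlap", "split_half",
                               n_resamples = 25, k = 2, seed = 88)
  expect_gt(omn$p_values["a", "b"], 0.05)
})

test_that("controls are calibrated under their nulls", {
  # identical stimulus distributions: label-shuffle p approximately uniform
  set.seed(83)
  pvals <- replicate(25, {
    vals <- array(rnorm(24 * 6 * 15), c(24, 6, 15))
    tt <- trial_tensor(vals, seq(0, 0.5, by = 0.1),
                       rep(c("a", "b"), each = 12))
    significance_controls(tt, "overlap", "label_shuffle",
                          n_resamples = 19, k = 2,
                          seed = sample.int(1e6, 1))$p_values[1, 2]
  })
  expect_gte(mean(pvals), 0.25)
  expect_lte(mean(pvals <= 0.05), 0.2)
  # one-resample boundary case
  ds <- cached_fixture("two_orthogonal_channels")
  om1 <- significance_controls(ds$tensor, "overlap", "label_shuffle",
                               n_resamples = 1, k = 2, seed = 84)
  expect_true(all(om1$p_values[!is.na(om1$p_values)] %in% c(0, 1)))
  # split-half needs an even trial count
  vals <- array(rnorm(6 * 4 * 8), c(6, 4, 8))
  tt3 <- trial_tensor(vals, seq(0, 0.3, by = 0.1), rep(c("a", "b"), each = 3))
  expect_error(significance_controls(tt3, "overlap", "split_half"),
               "even")
})

test_that("initial/peak-state controls detect rotational dynamics", {
  ds <- cached_fixture("two_orthogonal_channels")
  res <- significance_controls(ds$tensor, "initial_peak_correlation",
                               "label_shuffle", n_resamples = 40, seed = 85)
  expect_true(all(res$p_value < 0.05))
  expect_true(all(abs(res$statistic) < 0.6))
})

test_that("overlap matrices round-trip through CSV with p-values", {
  set.seed(86)
  v <- crossprod(qr.Q(qr(matrix(rnorm(9), 3))))
  om <- overlap_matrix(abs(v), labels = c("a", "b", "c"),
                       p_values = matrix(0.5, 3, 3),
                       control_tag = "label_shuffle")
  path <- tempfile(fileext = ".csv")
  write_overlap_csv(om, path)
  back <- read_overlap_csv(path)
  expect_equal(unname(back$values), unname(om$values), tolerance = 1e-10)
  expect_equal(back$labels, om$labels)
  expect_equal(unname(back$p_values), unname(om$p_values))
})
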