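#' Across-trial variance along a state-space direction
#'
#' \eqn{\mathrm{var}(z_0; t) = z_0^\top C(t) z_0}, the across-trial
#' variance of the activity projected on the unit direction `z0` at a given
#' time.
#'
#' @param tt a [trial_tensor()] restricted to one stimulus (or pass
#'   `stimulus`).
#' @param direction unit vector of length equal to the neuron count.
#' @param t time (seconds); the nearest grid time is used.
#' @param stimulus optional stimulus label to restrict to.
#' @return scalar variance.
#' @export
variance_along <- function(tt, direction, t, stimulus = NULL) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  direction <- as.numeric(direction)
  .assert(sqrt(sum(direction^2)) > 0, "direction must be nonzero")
  direction <- .unit(direction)
  idx <- if (is.null(stimulus)) seq_len(dim(tt$values)[1]) else
    which(tt$stimulus == stimulus)
  .assert(length(idx) >= 2, "need at least two trials")
  ti <- which.min(abs(tt$times - t))
  proj <- matrix(tt$values[idx, ti, ], length(idx)) %*% direction
  stats::var(as.numeric(proj))
}

#' Amplified direction of a trial-averaged response
#'
#' Unit vector along the trial-averaged population state at the time when
#' its norm peaks: the direction into which the transient dynamics
#' amplify activity.
#'
#' @param tt a [trial_tensor()].
#' @param stimulus optional stimulus label.
#' @return list with `direction` (unit vector), `t_star` (seconds) and
#'   `index`.
#' @export
amplified_direction <- function(tt, stimulus = NULL) {
  idx <- if (is.null(stimulus)) seq_len(dim(tt$values)[1]) else
    which(tt$stimulus == stimulus)
  avg <- .avg_from_trials(tt, idx)
  pk <- peak_state(avg)
  .assert(sqrt(sum(pk$state^2)) > 0, "trial-averaged activity is all zero")
  list(direction = .unit(pk$state), t_star = pk$t_peak, index = pk$index)
}

#' Variability amplification along a direction
#'
#' Ratio of the across-trial variance along `direction` at the peak time of
#' the trial-averaged norm and at the initial time:
#' \eqn{VA(z_0) = \mathrm{var}(z_0; t^*)/\mathrm{var}(z_0; 0)}. Recurrent
#' amplification predicts VA much larger than 1 along the amplified
#' direction and of order 1 along random directions.
#'
#' @param tt a [trial_tensor()].
#' @param direction unit vector.
#' @param stimulus optional stimulus label.
#' @param t_star peak time; defaults to the trial-averaged norm peak of
#'   this tensor/stimulus.
#' @return scalar VA.
#' @export
variability_amplification <- function(tt, direction, stimulus = NULL,
                                      t_star = NULL) {
  t_star <- t_star %||% amplified_direction(tt, stimulus)$t_star
  v0 <- variance_along(tt, direction, tt$times[1], stimulus)
  .assert(v0 > 0, "zero variance at the initial time; VA undefined")
  variance_along(tt, direction, t_star, stimulus) / v0
}

#' Shuffle trial labels independently per neuron
#'
#' Destroys across-neuron noise correlations while preserving every
#' neuron's marginal statistics exactly: for each neuron (and stimulus) the
#' trial labels are permuted independently. The covariance matrix of the
#' shuffled responses retains only the diagonal of the original.
#'
#' @param tt a [trial_tensor()].
#' @param seed RNG seed.
#' @return a [trial_tensor()] of the same shape.
#' @export
shuffle_trials <- function(tt, seed = 1) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  set.seed(seed)
  vals <- tt$values
  d <- dim(vals)
  for (s in unique(tt$stimulus)) {
    idx <- which(tt$stimulus == s)
    for (n in seq_len(d[3])) {
      vals[idx, , n] <- vals[idx[sample(length(idx))], , n]
    }
  }
  trial_tensor(vals, tt$times, tt$stimulus, tt$session)
}

#' Generate model-based single-trial responses
#'
#' Draws single-trial initial conditions from a Gaussian with mean `r0` and
#' the given covariance, and propagates each through the fitted model: the
#' network model evolves each initial state with the fitted connectivity;
#' the single-cell model scales each neuron's filter by its perturbed
#' range.
#'
#' @param fit a `network_fit` or `single_cell_fit`.
#' @param r0 mean initial state in the fit's own space (PC space for a
#'   network fit; per-neuron ranges for a single-cell fit).
#' @param covariance symmetric positive semidefinite covariance of the
#'   initial states (scalar shorthand for isotropic `cov * I`).
#' @param n_trials number of trials to generate.
#' @param times time grid starting at 0 (seconds = model time units here).
#' @param seed RNG seed.
#' @param stimulus stimulus label for the output tensor.
#' @return a [trial_tensor()] of simulated trials.
#' @export
generate_single_trials <- function(fit, r0, covariance, n_trials, times,
                                   seed = 1, stimulus = "stim1") {
  r0 <- as.numeric(r0)
  D <- length(r0)
  if (length(covariance) == 1) covariance <- diag(covariance, D)
  covariance <- as.matrix(covariance)
  .assert(all(dim(covariance) == D), "covariance has wrong shape")
  .assert(max(abs(covariance - t(covariance))) < 1e-8,
          "covariance must be symmetric")
  ec <- eigen(covariance, symmetric = TRUE)
  .assert(min(ec$values) > -1e-8 * max(abs(ec$values), 1),
          "covariance must be positive semidefinite")
  lam <- pmax(ec$values, 0)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_trials * D), n_trials, D)
  inits <- sweep(Z %*% (t(ec$vectors) * sqrt(lam)), 2, r0, `+`)
  # note: rows of t(ec$vectors) scaled by sqrt(lam) gives cov = V diag(lam) V'
  T_ <- length(times)
  vals <- array(0, c(n_trials, T_, D))
  if (inherits(fit, "network_fit")) {
    for (tr in seq_len(n_trials)) {
      vals[tr, , ] <- propagate(fit$J, inits[tr, ], times)$values
    }
  } else if (inherits(fit, "single_cell_fit")) {
    L <- single_cell_filters(fit, times)  # neurons x T
    .assert(nrow(L) == D, "r0 length must match the kept neuron count")
    for (tr in seq_len(n_trials)) {
      vals[tr, , ] <- t(inits[tr, ] * L)
    }
  } else stop("unsupported fit class", call. = FALSE)
  trial_tensor(vals, times, rep(stimulus, n_trials))
}

# Across-trial variance of each column of a projection matrix.
.col_vars <- function(M) {
  n <- nrow(M)
  (colSums(M^2) - n * colMeans(M)^2) / (n - 1)
}

#' Variability-amplification contrast with shuffle control
#'
#' For each stimulus, computes the variability amplification along the
#' amplified direction and along random directions, on the real data and on
#' trial-shuffled data (per-neuron trial-label permutation), over repeated
#' subsamples of 90% of the cells. The discriminating statistic is
#' \eqn{\Delta VA = VA(ampl) - VA(rand)}: recurrent dynamics predict
#' \eqn{\Delta VA(\mathrm{real}) > \Delta VA(\mathrm{shuffle})}, while a
#' single-cell mechanism (diagonal covariance) predicts no difference.
#'
#' The primary per-stimulus p-value is an exact one-sided permutation
#' p-value: the subsample-averaged \eqn{\Delta VA} of the real data is
#' ranked within the \eqn{\Delta VA} values of the independent trial-label
#' shuffles, which are exchangeable with the real data when the
#' across-trial covariance is diagonal. A two-sided t-test of
#' \eqn{\Delta VA(real)} against the shuffle-averaged
#' \eqn{\Delta VA(shuffle)} across subsamples is also reported
#' (`p_value_ttest`), but note that subsamples of one dataset are strongly
#' dependent, which makes that test anticonservative. When several stimuli
#' are present a pooled two-sided Wilcoxon signed-rank test across stimuli
#' is added.
#'
#' @param tt a [trial_tensor()].
#' @param n_direction_samples random directions averaged per subsample
#'   (default 20).
#' @param n_subsamples subsamples of 90% of the cells (default 50).
#' @param n_shuffles independent trial-label shuffles (default 50; the
#'   smallest attainable permutation p is `1/(n_shuffles + 1)`).
#' @param subsample_frac fraction of cells per subsample (default 0.9).
#' @param seed RNG seed.
#' @return object of class `va_result`: data frame `per_stimulus` (columns
#'   `stimulus`, `va_amplified`, `va_random`, `va_amplified_shuffled`,
#'   `va_random_shuffled`, `delta_va_real`, `delta_va_shuffled`,
#'   `p_value` (permutation), `p_value_ttest`), pooled `p_value_pooled`
#'   (Wilcoxon, `NA` for a single stimulus), `n_subsamples`, `n_shuffles`,
#'   `seed`.
#' @export
va_contrast <- function(tt, n_direction_samples = 20, n_subsamples = 50,
                        n_shuffles = 50, subsample_frac = 0.9, seed = 1) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  set.seed(seed)
  stimuli <- unique(tt$stimulus)
  N <- dim(tt$values)[3]
  K <- n_direction_samples
  rows <- list()
  for (s in stimuli) {
    idx <- which(tt$stimulus == s)
    ntr <- length(idx)
    ad <- amplified_direction(tt, s)
    X0 <- matrix(tt$values[idx, 1, ], ntr, N)
    Xp <- matrix(tt$values[idx, ad$index, ], ntr, N)
    # one column per (subsample, direction); VA is scale invariant, so
    # restriction to a subsample is implemented by zeroing dropped cells
    D <- matrix(0, N, n_subsamples * (K + 1))
    for (b in seq_len(n_subsamples)) {
      sub <- sample(N, max(2, round(subsample_frac * N)))
      block <- matrix(0, N, K + 1)
      block[sub, 1] <- ad$direction[sub]
      block[sub, -1] <- stats::rnorm(length(sub) * K)
      D[, (b - 1) * (K + 1) + seq_len(K + 1)] <- block
    }
    va_of <- function(A0, Ap) {
      va <- .col_vars(Ap %*% D) / .col_vars(A0 %*% D)
      matrix(va, K + 1, n_subsamples)  # row 1: amplified; rows 2..: random
    }
    va_real <- va_of(X0, Xp)
    dva_real <- va_real[1, ] - colMeans(va_real[-1, , drop = FALSE])
    dva_sh <- matrix(0, n_shuffles, n_subsamples)
    va_sh_parts <- matrix(0, n_shuffles, 2)
    for (j in seq_len(n_shuffles)) {
      X0s <- X0; Xps <- Xp
      for (n in seq_len(N)) {
        pi_n <- sample(ntr)
        X0s[, n] <- X0[pi_n, n]
        Xps[, n] <- Xp[pi_n, n]
      }
      va_s <- va_of(X0s, Xps)
      dva_sh[j, ] <- va_s[1, ] - colMeans(va_s[-1, , drop = FALSE])
      va_sh_parts[j, ] <- c(mean(va_s[1, ]), mean(va_s[-1, ]))
    }
    stat_real <- mean(dva_real)
    stat_sh <- rowMeans(dva_sh)
    p_perm <- (1 + sum(stat_sh >= stat_real)) / (n_shuffles + 1)
    dva_sh_by_sub <- colMeans(dva_sh)
    p_t <- tryCatch(stats::t.test(dva_real, dva_sh_by_sub)$p.value,
                    error = function(e) NA_real_)
    rows[[s]] <- data.frame(stimulus = s,
                            va_amplified = mean(va_real[1, ]),
                            va_random = mean(va_real[-1, ]),
                            va_amplified_shuffled = mean(va_sh_parts[, 1]),
                            va_random_shuffled = mean(va_sh_parts[, 2]),
                            delta_va_real = stat_real,
                            delta_va_shuffled = mean(stat_sh),
                            p_value = p_perm,
                            p_value_ttest = p_t)
  }
  per_stimulus <- do.call(rbind, rows)
  rownames(per_stimulus) <- NULL
  p_pooled <- if (length(stimuli) >= 2) {
    stats::wilcox.test(per_stimulus$delta_va_real,
                       per_stimulus$delta_va_shuffled,
                       paired = TRUE)$p.value
  } else NA_real_
  structure(list(per_stimulus = per_stimulus, p_value_pooled = p_pooled,
                 n_subsamples = n_subsamples, n_shuffles = n_shuffles,
                 seed = seed),
            class = "va_result")
}

#' @export
print.va_result <- function(x, ...) {
  cat(sprintf("<va_result: %d stimuli, %d subsamples>\n",
              nrow(x$per_stimulus), x$n_subsamples))
  print(x$per_stimulus, digits = 3)
  invisible(x)
}
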