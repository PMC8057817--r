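#' Cumulative variance explained by principal components
#'
#' Stacks the supplied responses over time (and stimuli), centers them
#' around the joint mean over times and stimuli, and returns the cumulative
#' fraction of variance explained by the first M principal components, for
#' all M.
#'
#' @param responses a [trajectory()] or list of trajectories.
#' @return numeric vector `cumvar` (nondecreasing, ending at 1), with
#'   attribute `"eigenvalues"` carrying the covariance eigenvalues.
#' @export
cumulative_variance <- function(responses) {
  if (inherits(responses, "trajectory")) responses <- list(responses)
  .assert(length(responses) >= 1, "empty input")
  X <- do.call(rbind, lapply(responses, function(r) r$values))
  X <- sweep(X, 2, colMeans(X))
  d2 <- svd(X, nu = 0, nv = 0)$d^2 / nrow(X)
  .assert(sum(d2) > 0, "responses have no variance")
  out <- cumsum(d2) / sum(d2)
  attr(out, "eigenvalues") <- d2
  out
}

# Per-trial mean-centered response matrix (TC x N) for cvPCA: responses to
# all stimuli from one trial index, centered over times and stimuli.
.trial_matrix <- function(tt, trial_index, stimuli) {
  rows <- lapply(stimuli, function(s) {
    idx <- which(tt$stimulus == s)[trial_index]
    matrix(tt$values[idx, , ], dim(tt$values)[2], dim(tt$values)[3])
  })
  X <- do.call(rbind, rows)
  sweep(X, 2, colMeans(X))
}

#' Cross-validated PCA spectrum
#'
#' Estimates the stimulus-related variance spectrum by computing, for every
#' ordered pair of distinct trials, the covariance of a test trial's
#' responses with the principal components of a training trial:
#' \eqn{\lambda_i = \frac{1}{C} u_i^{\top} X^{(test)\top} X^{(train)} u_i},
#' averaged over pairs. Because trial-to-trial noise is independent between
#' trials, noise variance cancels in expectation and the spectrum estimates
#' the signal-only eigenvalues, unlike naive PCA which adds the noise
#' variance to every component.
#'
#' @param tt a [trial_tensor()] with at least two trials per stimulus.
#' @param n_components number of leading components to report (default
#'   all).
#' @param max_pairs optional cap on the number of ordered trial pairs used
#'   (pairs are then subsampled deterministically).
#' @return numeric vector of cross-validated eigenvalues, with attribute
#'   `"naive"` carrying the ordinary PCA spectrum of the trial-averaged
#'   pairs (same normalization, 1/C).
#' @export
cvpca_spectrum <- function(tt, n_components = NULL, max_pairs = NULL) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  ntr <- trials_per_stimulus(tt)
  .assert(ntr >= 2, "cvPCA needs at least two trials per stimulus")
  stimuli <- unique(tt$stimulus)
  C <- length(stimuli)
  N <- dim(tt$values)[3]
  pairs <- expand.grid(train = seq_len(ntr), test = seq_len(ntr))
  pairs <- pairs[pairs$train != pairs$test, ]
  if (!is.null(max_pairs) && nrow(pairs) > max_pairs) {
    pairs <- pairs[round(seq(1, nrow(pairs), length.out = max_pairs)), ]
  }
  tmats <- lapply(seq_len(ntr), function(i) .trial_matrix(tt, i, stimuli))
  k <- min(n_components %||% N, nrow(tmats[[1]]), N)
  acc <- numeric(k)
  acc_naive <- numeric(k)
  for (p in seq_len(nrow(pairs))) {
    Xtr <- tmats[[pairs$train[p]]]
    Xte <- tmats[[pairs$test[p]]]
    sv <- svd(Xtr, nv = k)
    U <- sv$v[, seq_len(k), drop = FALSE]
    a <- (Xtr %*% U) ; b <- (Xte %*% U)
    acc <- acc + colSums(a * b) / C
    acc_naive <- acc_naive + colSums(a * a) / C
  }
  out <- acc / nrow(pairs)
  attr(out, "naive") <- acc_naive / nrow(pairs)
  out
}

# Top-K principal directions (N x K orthonormal) of one response.
.pc_directions <- function(values, k, center = TRUE) {
  if (center) values <- sweep(values, 2, colMeans(values))
  sv <- svd(values, nv = min(k, min(dim(values))))
  .assert(ncol(sv$v) >= k,
          sprintf("requested %d components but only %d available", k,
                  ncol(sv$v)))
  sv$v[, seq_len(k), drop = FALSE]
}

#' Subspace overlap between two responses
#'
#' Cosine of the smallest principal angle between the K-dimensional
#' principal subspaces of two responses: the largest singular value of
#' \eqn{Q(s_1)^\top Q(s_2)}, where the Q's hold the top-K principal
#' components as columns. 0 means orthogonal response subspaces, 1 aligned.
#'
#' @param resp1,resp2 [trajectory()] objects in the same neuron space.
#' @param k number of principal components per response (default 5).
#' @param center center each response over time before PCA (default TRUE).
#' @return scalar in \[0, 1\].
#' @export
subspace_overlap <- function(resp1, resp2, k = 5, center = TRUE) {
  .assert(ncol(resp1$values) == ncol(resp2$values),
          "responses live in different spaces")
  Q1 <- .pc_directions(resp1$values, k, center)
  Q2 <- .pc_directions(resp2$values, k, center)
  max(svd(crossprod(Q1, Q2), nu = 0, nv = 0)$d)
}

#' Overlap matrix
#'
#' Container for a stimulus-by-stimulus matrix of subspace (or
#' connectivity) overlaps, with optional p-values from a significance
#' control.
#'
#' @param values symmetric numeric matrix in \[0, 1\].
#' @param labels stimulus labels.
#' @param p_values optional matching matrix of p-values.
#' @param control_tag label of the control that produced `p_values`.
#' @return object of class `overlap_matrix`.
#' @export
overlap_matrix <- function(values, labels = NULL, p_values = NULL,
                           control_tag = NULL) {
  values <- as.matrix(values)
  .assert(nrow(values) == ncol(values), "overlap matrix must be square")
  .assert(max(abs(values - t(values))) < 1e-8,
          "overlap matrix must be symmetric")
  labels <- labels %||% rownames(values) %||%
    paste0("stim", seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels, p_values = p_values,
                 control_tag = control_tag),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat(sprintf("<overlap_matrix: %d stimuli%s>\n", nrow(x$values),
              if (is.null(x$p_values)) "" else
                sprintf(", p-values from %s control", x$control_tag)))
  print(round(x$values, 3))
  invisible(x)
}

# Pearson correlation between the off-diagonal entries of two square
# matrices.
.offdiag_cor <- function(a, b) {
  m <- row(a) != col(a)
  if (stats::sd(a[m]) == 0 || stats::sd(b[m]) == 0) return(NA_real_)
  stats::cor(a[m], b[m])
}

#' Pairwise subspace-overlap structure across stimuli
#'
#' Computes all pairwise subspace overlaps between per-stimulus responses,
#' the correlation matrix of their initial states, and the linear
#' correlation between the two matrices' off-diagonal entries. When
#' `subtract_initial` is set, the component of each response along its own
#' initial state is projected out before computing overlaps, so the
#' comparison with the initial-state structure is not trivially induced by
#' the initial condition itself.
#'
#' @param responses named list of [trajectory()] objects.
#' @param k components per stimulus (default 5).
#' @param subtract_initial project each response off its own initial-state
#'   direction first (default FALSE).
#' @return list with `overlaps` (an [overlap_matrix()]),
#'   `initial_correlations` (S x S matrix of initial-state cosines) and
#'   `structure_correlation` (scalar).
#' @export
overlap_structure <- function(responses, k = 5, subtract_initial = FALSE) {
  .assert(length(responses) >= 2, "need at least two stimuli")
  labels <- names(responses) %||% paste0("stim", seq_along(responses))
  S <- length(responses)
  r0 <- vapply(responses, function(r) .unit(r$values[1, ]),
               numeric(ncol(responses[[1]]$values)))
  work <- responses
  if (subtract_initial) {
    work <- lapply(seq_len(S), function(i) {
      v <- responses[[i]]$values
      u <- r0[, i]
      trajectory(v - (v %*% u) %*% t(u), responses[[i]]$times)
    })
  }
  ov <- diag(1, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    ov[i, j] <- ov[j, i] <- subspace_overlap(work[[i]], work[[j]], k)
  }
  ic <- crossprod(r0)
  dimnames(ic) <- list(labels, labels)
  list(overlaps = overlap_matrix(ov, labels),
       initial_correlations = ic,
       structure_correlation = .offdiag_cor(ov, ic))
}

# trial-averaged trajectory from explicit trial indices of one stimulus
.avg_from_trials <- function(tt, idx) {
  m <- apply(tt$values[idx, , , drop = FALSE], c(2, 3), mean)
  trajectory(m, tt$times)
}

# initial/peak correlation of a trial-averaged response, with peak index
# fixed externally (or recomputed when NULL)
.ipc_stat <- function(traj, peak_index = NULL) {
  i <- peak_index %||% peak_state(traj)$index
  a <- traj$values[1, ]; b <- traj$values[i, ]
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Shuffle-based significance controls for orthogonality statistics
#'
#' Two null hypotheses are addressed. The `label_shuffle` control tests
#' whether low overlaps (or low initial/peak correlations) could arise from
#' the high dimensionality of the state space: stimulus labels are permuted
#' across trials, the statistic is recomputed per resample, and the
#' lower-tail fraction of shuffles below the observed value is returned as
#' the p-value. The `split_half` control tests whether low values are an
#' artifact of trial-to-trial variability: the observed statistic is
#' recomputed from disjoint 10-trial averages, compared against the
#' within-stimulus statistic between two disjoint half-averages by a
#' two-tailed t-test; for stimulus pairs the conservative maximum of the
#' two per-stimulus p-values is reported, and only where the observed mean
#' is below both within-stimulus means.
#'
#' @param tt a [trial_tensor()] (split-half requires an even trial count).
#' @param statistic `"overlap"` (pairwise subspace overlaps) or
#'   `"initial_peak_correlation"` (per stimulus).
#' @param control `"label_shuffle"` or `"split_half"`.
#' @param n_resamples resamples per test (default 100).
#' @param k components per response for overlaps (default 5).
#' @param seed RNG seed.
#' @return for `"overlap"`: an [overlap_matrix()] with `p_values`; for
#'   `"initial_peak_correlation"`: a data frame with one row per stimulus
#'   (`statistic`, `p_value`).
#' @export
significance_controls <- function(tt,
                                  statistic = c("overlap",
                                                "initial_peak_correlation"),
                                  control = c("label_shuffle",
                                              "split_half"),
                                  n_resamples = 100, k = 5, seed = 1) {
  statistic <- match.arg(statistic)
  control <- match.arg(control)
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  set.seed(seed)
  ntr <- trials_per_stimulus(tt)
  stimuli <- unique(tt$stimulus)
  S <- length(stimuli)
  half <- ntr %/% 2
  if (control == "split_half") {
    .assert(ntr %% 2 == 0, "split-half control needs an even trial count")
  }
  idx_of <- lapply(stimuli, function(s) which(tt$stimulus == s))
  names(idx_of) <- stimuli

  if (statistic == "overlap") {
    avg <- trial_average(tt)
    real <- matrix(1, S, S, dimnames = list(stimuli, stimuli))
    pv <- matrix(NA_real_, S, S, dimnames = list(stimuli, stimuli))
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      real[i, j] <- real[j, i] <-
        subspace_overlap(avg[[i]], avg[[j]], k)
    }
    if (control == "label_shuffle") {
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        pool <- c(idx_of[[i]], idx_of[[j]])
        sh <- vapply(seq_len(n_resamples), function(r) {
          perm <- sample(pool)
          subspace_overlap(.avg_from_trials(tt, perm[seq_len(ntr)]),
                           .avg_from_trials(tt, perm[ntr + seq_len(ntr)]),
                           k)
        }, numeric(1))
        pv[i, j] <- pv[j, i] <- mean(sh < real[i, j])
      }
    } else {
      shuffle_s <- lapply(seq_len(S), function(i) {
        vapply(seq_len(n_resamples), function(r) {
          perm <- sample(idx_of[[i]])
          subspace_overlap(.avg_from_trials(tt, perm[seq_len(half)]),
                           .avg_from_trials(tt, perm[half + seq_len(half)]),
                           k)
        }, numeric(1))
      })
      for (i in seq_len(S - 1)) for (j in (i + 1):S) {
        reals <- vapply(seq_len(n_resamples), function(r) {
          subspace_overlap(
            .avg_from_trials(tt, sample(idx_of[[i]], half)),
            .avg_from_trials(tt, sample(idx_of[[j]], half)), k)
        }, numeric(1))
        if (mean(reals) < mean(shuffle_s[[i]]) &&
            mean(reals) < mean(shuffle_s[[j]])) {
          p1 <- stats::t.test(reals, shuffle_s[[i]])$p.value
          p2 <- stats::t.test(reals, shuffle_s[[j]])$p.value
          pv[i, j] <- pv[j, i] <- max(p1, p2)
        } else pv[i, j] <- pv[j, i] <- 1
      }
    }
    return(overlap_matrix(real, stimuli, p_values = pv,
                          control_tag = control))
  }

  # initial_peak_correlation
  out <- data.frame(stimulus = stimuli, statistic = NA_real_,
                    p_value = NA_real_)
  for (i in seq_len(S)) {
    avg <- .avg_from_trials(tt, idx_of[[i]])
    pk <- peak_state(avg)$index
    real <- .ipc_stat(avg, pk)
    out$statistic[i] <- real
    if (control == "label_shuffle") {
      # pool per-trial initial and peak states, reassign the two labels
      init <- matrix(tt$values[idx_of[[i]], 1, ], ntr)
      peak <- matrix(tt$values[idx_of[[i]], pk, ], ntr)
      both <- rbind(init, peak)
      sh <- vapply(seq_len(n_resamples), function(r) {
        perm <- sample(2 * ntr)
        a <- colMeans(both[perm[seq_len(ntr)], , drop = FALSE])
        b <- colMeans(both[perm[ntr + seq_len(ntr)], , drop = FALSE])
        sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
      }, numeric(1))
      out$p_value[i] <- mean(sh < real)
    } else {
      reals <- vapply(seq_len(n_resamples), function(r) {
        .ipc_stat(.avg_from_trials(tt, sample(idx_of[[i]], half)), pk)
      }, numeric(1))
      shs <- vapply(seq_len(n_resamples), function(r) {
        perm <- sample(idx_of[[i]])
        a <- .avg_from_trials(tt, perm[seq_len(half)])$values
        b <- .avg_from_trials(tt, perm[half + seq_len(half)])$values
        mean(vapply(seq_len(nrow(a)), function(ti) {
          na <- sqrt(sum(a[ti, ]^2)); nb <- sqrt(sum(b[ti, ]^2))
          if (na == 0 || nb == 0) return(0)
          sum(a[ti, ] * b[ti, ]) / (na * nb)
        }, numeric(1)))
      }, numeric(1))
      out$p_value[i] <- if (mean(reals) < mean(shs))
        stats::t.test(reals, shs)$p.value else 1
    }
  }
  out
}
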