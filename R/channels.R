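#' Per-stimulus transient-channel decomposition
#'
#' Fits the reduced-rank network model to the response of each stimulus
#' independently (all fits share one PC basis built from the joint
#' responses), and factorizes each fitted connectivity canonically. If the
#' global connectivity consists of independent low-rank coding channels,
#' these per-stimulus fits recover mutually orthogonal channels whose sum
#' reconstructs the jointly fitted matrix.
#'
#' @param responses named list of [trajectory()] objects (neuron space).
#' @param lambda ridge penalty for the per-stimulus fits (default 5).
#' @param rank rank bound per stimulus (default 5).
#' @param n_pc shared number of principal components (default 100, the
#'   fixed count used for channel analyses).
#' @param var_threshold variance threshold for the PC count (default 1:
#'   the count is fixed by `n_pc` alone, since truncating below the
#'   dynamics' dimensionality entangles the per-stimulus fits).
#' @return object of class `channel_set`: list with `channels` (named list
#'   of [low_rank_connectivity()]), `fits` (the network fits), `pc_basis`,
#'   `center`, `design` (the joint design used for scoring).
#' @export
fit_channels <- function(responses, lambda = 5, rank = 5, n_pc = 100,
                         var_threshold = 1) {
  joint <- build_design(responses, n_pc = n_pc,
                        var_threshold = var_threshold)
  channels <- list(); fits <- list()
  for (s in names(joint$responses_pc)) {
    sub <- build_design(joint$responses_pc[s], n_pc = NULL)
    # responses are already centered + projected; re-centering within the
    # single-stimulus design is avoided by restoring the joint rows
    rows <- which(joint$stimulus_of_row == s)
    sub$X <- joint$X[rows, , drop = FALSE]
    sub$Xdot <- joint$Xdot[rows, , drop = FALSE]
    sub$stimulus_of_row <- joint$stimulus_of_row[rows]
    fit <- fit_reduced_rank(sub, lambda, rank)
    fit$pc_basis <- joint$pc_basis
    fit$center <- joint$center
    fits[[s]] <- fit
    channels[[s]] <- low_rank_connectivity(fit$J, rank = rank)
  }
  structure(list(channels = channels, fits = fits,
                 pc_basis = joint$pc_basis, center = joint$center,
                 design = joint),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set: %d stimuli, ambient dim %d>\n",
              length(x$channels), nrow(x$channels[[1]]$U)))
  invisible(x)
}

#' Connectivity overlaps between transient channels
#'
#' Principal-angle cosine between the orthonormalized right connectivity
#' patterns of each pair of per-stimulus channels. Orthogonal coding
#' channels give near-zero off-diagonal overlaps.
#'
#' @param cs a [fit_channels()] object.
#' @return an [overlap_matrix()].
#' @export
connectivity_overlap <- function(cs) {
  .assert(inherits(cs, "channel_set"), "expected a channel_set")
  .assert(length(cs$channels) >= 2, "need at least two stimuli")
  labels <- names(cs$channels)
  # orthonormalize the right patterns U of each channel
  Qs <- lapply(cs$channels, function(ch) svd(ch$U)$u)
  S <- length(Qs)
  ov <- diag(1, S)
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    ov[i, j] <- ov[j, i] <-
      max(svd(crossprod(Qs[[i]], Qs[[j]]), nu = 0, nv = 0)$d)
  }
  overlap_matrix(ov, labels)
}

# In-design r2 of a fixed connectivity (no refitting).
.fixed_J_r2 <- function(design, J) {
  pred <- design$X %*% (t(J) - diag(ncol(design$X)))
  .r2_score(design$Xdot, pred)
}

# Cross-validation-style per-chunk r2 of a fixed connectivity.
.fixed_J_fold_r2 <- function(design, J, k_folds = 10) {
  folds <- .cv_folds(design$stimulus_of_row, k_folds)
  vapply(folds, function(rows)
    .fixed_J_r2(.design_rows(design, rows), J), numeric(1))
}

#' Test whether the full connectivity is a sum of independent channels
#'
#' Compares the goodness of fit of the jointly fitted connectivity
#' (`J_full`) with the sum of the per-stimulus channels (`J_sum`) and with
#' a shuffle control in which the entries of `J_sum` are permuted uniformly
#' at random. Scores are coefficient-of-determination values per
#' cross-validation chunk of the joint design.
#'
#' @param cs a [fit_channels()] object.
#' @param full_fit a `network_fit` fitted on all stimuli jointly (same PC
#'   basis); if `NULL`, one is fitted with `lambda_full`, `rank_full`.
#' @param lambda_full,rank_full hyperparameters for the joint fit when
#'   `full_fit` is missing (defaults 2 and 70, capped at the dimension).
#' @param n_shuffles number of entry-permutation controls (default 100).
#' @param k_folds chunks for scoring (default 10).
#' @param seed RNG seed for the shuffles.
#' @return list with `r2_full`, `r2_sum`, `r2_shuffle` (vector), `J_sum`,
#'   and the per-fold scores `fold_r2_full`, `fold_r2_sum`.
#' @export
sum_channels_test <- function(cs, full_fit = NULL, lambda_full = 2,
                              rank_full = 70, n_shuffles = 100,
                              k_folds = 10, seed = 1) {
  .assert(inherits(cs, "channel_set"), "expected a channel_set")
  design <- cs$design
  if (is.null(full_fit)) {
    full_fit <- fit_reduced_rank(design, lambda_full,
                                 min(rank_full, ncol(design$X)))
  }
  J_sum <- Reduce(`+`, lapply(cs$channels, as_dense))
  fold_full <- .fixed_J_fold_r2(design, full_fit$J, k_folds)
  fold_sum <- .fixed_J_fold_r2(design, J_sum, k_folds)
  set.seed(seed)
  r2_shuffle <- vapply(seq_len(n_shuffles), function(i) {
    Jp <- matrix(sample(as.vector(J_sum)), nrow(J_sum), ncol(J_sum))
    .fixed_J_r2(design, Jp)
  }, numeric(1))
  list(r2_full = mean(fold_full), r2_sum = mean(fold_sum),
       r2_shuffle = r2_shuffle, J_sum = J_sum,
       fold_r2_full = fold_full, fold_r2_sum = fold_sum)
}
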