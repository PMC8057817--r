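# Bin trial activity into non-overlapping windows of bin_width seconds.
# Returns list(centers, array trials x bins x neurons).
.bin_trials <- function(tt, bin_width) {
  edges <- seq(min(tt$times), max(tt$times) + 1e-9, by = bin_width)
  if (utils::tail(edges, 1) < max(tt$times)) {
    edges <- c(edges, utils::tail(edges, 1) + bin_width)
  }
  bin_of <- findInterval(tt$times, edges, rightmost.closed = TRUE)
  keep <- sort(unique(bin_of))
  d <- dim(tt$values)
  out <- array(0, c(d[1], length(keep), d[3]))
  centers <- numeric(length(keep))
  for (i in seq_along(keep)) {
    idx <- which(bin_of == keep[i])
    centers[i] <- mean(tt$times[idx])
    out[, i, ] <- apply(tt$values[, idx, , drop = FALSE], c(1, 3), mean)
  }
  list(centers = centers, values = out)
}

# Leave-one-out accuracy per bin for a trials x bins x neurons array split
# into two classes by `is1`. Classifier: w = c1 - c2, b = (c1 + c2)/2,
# sign of w'(x - b); ties broken at random.
.loo_binned <- function(binned, is1) {
  d <- dim(binned)
  i1 <- which(is1); i2 <- which(!is1)
  n <- length(i1)
  acc <- matrix(0, d[2], 1)
  for (b in seq_len(d[2])) {
    Xb <- matrix(binned[, b, ], d[1], d[3])
    correct <- 0L
    for (f in seq_len(n)) {
      c1 <- colMeans(Xb[i1[-f], , drop = FALSE])
      c2 <- colMeans(Xb[i2[-f], , drop = FALSE])
      w <- c1 - c2; bb <- (c1 + c2) / 2
      y1 <- sum(w * (Xb[i1[f], ] - bb))
      y2 <- sum(w * (Xb[i2[f], ] - bb))
      if (y1 == 0) y1 <- stats::rnorm(1)
      if (y2 == 0) y2 <- stats::rnorm(1)
      correct <- correct + (y1 > 0) + (y2 < 0)
    }
    acc[b] <- correct / (2 * n)
  }
  as.numeric(acc)
}

#' Time-resolved pairwise stimulus decoding
#'
#' Trains, in every time bin, a nearest-class-mean linear classifier on the
#' trial-averaged population vectors of two stimuli and evaluates it with
#' leave-one-out cross-validation: each fold holds out one trial of each
#' stimulus, trains the decoder \eqn{w = c_1 - c_2}, \eqn{b = (c_1+c_2)/2}
#' on the remaining trials and classifies the held-out vectors by the sign
#' of \eqn{w^\top(x - b)}.
#'
#' @param tt a [trial_tensor()] containing exactly the two stimuli to
#'   classify (or use `stimuli` to select them).
#' @param stimuli length-2 character vector of stimulus labels.
#' @param bin_width bin width in seconds (default 0.05).
#' @param seed seed for tie-breaking.
#' @return object of class `decoder_timecourse`: data frame `timecourse`
#'   (`time`, `accuracy`, `se`), plus `bin_width`.
#' @export
loo_accuracy <- function(tt, stimuli = NULL, bin_width = 0.05, seed = 1) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  stimuli <- stimuli %||% unique(tt$stimulus)
  .assert(length(stimuli) == 2, "decoding is defined for stimulus pairs")
  keep <- tt$stimulus %in% stimuli
  .assert(sum(tt$stimulus == stimuli[1]) ==
            sum(tt$stimulus == stimuli[2]),
          "classes must have equal trial counts")
  .assert(sum(keep) >= 4, "need at least two trials per stimulus")
  sub <- trial_tensor(tt$values[keep, , , drop = FALSE], tt$times,
                      tt$stimulus[keep], tt$session)
  set.seed(seed)
  bn <- .bin_trials(sub, bin_width)
  acc <- .loo_binned(bn$values, sub$stimulus == stimuli[1])
  n_folds <- sum(sub$stimulus == stimuli[1])
  se <- sqrt(pmax(acc * (1 - acc), 0) / (2 * n_folds))
  structure(list(timecourse = data.frame(time = bn$centers,
                                         accuracy = acc, se = se),
                 bin_width = bin_width, stimuli = stimuli),
            class = "decoder_timecourse")
}

#' Chance level of the pairwise decoder
#'
#' Repeats the leave-one-out decoding after shuffling stimulus labels
#' across trials independently at each time bin, and summarizes the
#' resulting chance accuracy. The summary (`chance_mean`, `chance_sd`) is
#' taken over time bins of the shuffle-averaged course by default, or over
#' shuffles per bin with `summary = "shuffle"`.
#'
#' @inheritParams loo_accuracy
#' @param n_shuffles number of label shuffles (default 20).
#' @param summary `"time"` or `"shuffle"`.
#' @return list with `chance_mean`, `chance_sd`, `per_bin` (data frame of
#'   per-bin mean/sd over shuffles), `n_shuffles`.
#' @export
chance_course <- function(tt, stimuli = NULL, bin_width = 0.05,
                          n_shuffles = 20, seed = 1,
                          summary = c("time", "shuffle")) {
  summary <- match.arg(summary)
  stimuli <- stimuli %||% unique(tt$stimulus)
  .assert(length(stimuli) == 2, "decoding is defined for stimulus pairs")
  keep <- tt$stimulus %in% stimuli
  sub <- trial_tensor(tt$values[keep, , , drop = FALSE], tt$times,
                      tt$stimulus[keep], tt$session)
  set.seed(seed)
  bn <- .bin_trials(sub, bin_width)
  d <- dim(bn$values)
  lab1 <- sub$stimulus == stimuli[1]
  acc <- matrix(0, n_shuffles, d[2])
  for (r in seq_len(n_shuffles)) {
    shuffled <- bn$values
    for (b in seq_len(d[2])) {
      shuffled[, b, ] <- shuffled[sample(d[1]), b, ]
    }
    acc[r, ] <- .loo_binned(shuffled, lab1)
  }
  per_bin <- data.frame(time = bn$centers, mean = colMeans(acc),
                        sd = apply(acc, 2, stats::sd))
  if (summary == "time") {
    list(chance_mean = mean(per_bin$mean), chance_sd = stats::sd(per_bin$mean),
         per_bin = per_bin, n_shuffles = n_shuffles)
  } else {
    list(chance_mean = mean(acc), chance_sd = stats::sd(as.numeric(acc)),
         per_bin = per_bin, n_shuffles = n_shuffles)
  }
}
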