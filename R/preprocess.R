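#' Gaussian smoothing and baseline subtraction
#'
#' Convolves every neuron/trial time series with a Gaussian kernel (standard
#' deviation in seconds; the auditory-cortex recordings use 32 ms at a
#' 31.5 Hz frame rate) and subtracts, per neuron and trial, the mean
#' activity over a pre-stimulus baseline window. Edges are handled with
#' reflection padding, which avoids boundary transients on short OFF
#' windows.
#'
#' @param tt a [trial_tensor()].
#' @param kernel_sd Gaussian kernel standard deviation in seconds; 0 skips
#'   smoothing.
#' @param baseline_window length-2 vector (seconds) delimiting the baseline
#'   period, half-open `[start, stop)`; `NULL` skips baseline subtraction.
#' @return a [trial_tensor()] of the same shape.
#' @export
smooth_and_baseline <- function(tt, kernel_sd = 0.032,
                                baseline_window = NULL) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  vals <- tt$values
  d <- dim(vals)
  if (kernel_sd > 0) {
    dt <- stats::median(diff(tt$times))
    half <- ceiling(4 * kernel_sd / dt)
    .assert(half < d[2],
            "smoothing kernel is wider than the recording window")
    kern <- stats::dnorm(seq(-half, half) * dt, sd = kernel_sd)
    kern <- kern / sum(kern)
    smooth1 <- function(x) {
      padded <- c(rev(x[seq_len(half) + 1]), x,
                  rev(x[d[2] - seq_len(half)]))
      as.numeric(stats::filter(padded, kern, sides = 2))[half + seq_len(d[2])]
    }
    for (tr in seq_len(d[1])) {
      vals[tr, , ] <- apply(matrix(vals[tr, , ], d[2], d[3]), 2, smooth1)
    }
  }
  if (!is.null(baseline_window)) {
    idx <- which(tt$times >= baseline_window[1] &
                   tt$times < baseline_window[2])
    .assert(length(idx) > 0, "baseline window contains no samples")
    .assert(max(tt$times[idx]) <= 0,
            "baseline window must precede stimulus offset")
    for (tr in seq_len(d[1])) {
      # mean over baseline frames, one value per neuron
      base <- colMeans(matrix(vals[tr, idx, ], length(idx), d[3]))
      vals[tr, , ] <- sweep(matrix(vals[tr, , ], d[2], d[3]), 2, base)
    }
  }
  trial_tensor(vals, tt$times, tt$stimulus, tt$session)
}

#' Pool sessions into a pseudo-population
#'
#' Concatenates the neuron axes of several simultaneously analyzed sessions
#' recorded under the same stimulus protocol, after aligning trials by
#' stimulus label (trials within a stimulus are matched by order of
#' occurrence). Session provenance is retained per neuron.
#'
#' @param sessions list of [trial_tensor()] objects with identical time
#'   grids and stimulus sets.
#' @return a pooled [trial_tensor()].
#' @export
build_pseudopopulation <- function(sessions) {
  .assert(is.list(sessions) && length(sessions) >= 1,
          "need at least one session")
  if (length(sessions) == 1) return(sessions[[1]])
  ref <- sessions[[1]]
  stim_ref <- sort(unique(ref$stimulus))
  ntr <- trials_per_stimulus(ref)
  for (s in sessions) {
    .assert(isTRUE(all.equal(s$times, ref$times)),
            "sessions have mismatched time grids")
    .assert(identical(sort(unique(s$stimulus)), stim_ref),
            "sessions have mismatched stimulus sets")
    .assert(trials_per_stimulus(s) == ntr,
            "sessions have mismatched trial counts")
  }
  # canonical trial order: stimuli sorted, trials in order of appearance
  order_of <- function(s) {
    unlist(lapply(stim_ref, function(st) which(s$stimulus == st)))
  }
  n_neurons <- vapply(sessions, function(s) dim(s$values)[3], integer(1))
  vals <- array(0, c(ntr * length(stim_ref), length(ref$times),
                     sum(n_neurons)))
  off <- 0L
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    vals[, , off + seq_len(n_neurons[i])] <-
      s$values[order_of(s), , , drop = FALSE]
    off <- off + n_neurons[i]
  }
  session <- unlist(lapply(seq_along(sessions), function(i) {
    lab <- unique(sessions[[i]]$session)
    rep(if (length(lab) == 1) lab else sprintf("session%02d", i),
        n_neurons[i])
  }))
  trial_tensor(vals, ref$times, rep(stim_ref, each = ntr), session)
}

#' Extract the OFF-response window
#'
#' Crops the time axis to the half-open interval `[start, stop)` in seconds
#' relative to stimulus offset (the standard window runs from 50 ms before
#' to 300 ms after offset). Optionally resamples the cropped window to a
#' fixed number of equally spaced time points by linear interpolation.
#'
#' @param tt a [trial_tensor()].
#' @param start,stop window bounds in seconds.
#' @param resample_to optional integer; if given, the window is linearly
#'   resampled to this many time points.
#' @return a [trial_tensor()].
#' @export
extract_off_window <- function(tt, start = -0.05, stop = 0.30,
                               resample_to = NULL) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  idx <- which(tt$times >= start & tt$times < stop)
  .assert(length(idx) > 0, "requested window contains no samples")
  out <- trial_tensor(tt$values[, idx, , drop = FALSE], tt$times[idx],
                      tt$stimulus, tt$session)
  if (!is.null(resample_to)) {
    new_times <- seq(min(out$times), max(out$times),
                     length.out = resample_to)
    d <- dim(out$values)
    vals <- array(0, c(d[1], resample_to, d[3]))
    for (tr in seq_len(d[1])) {
      vals[tr, , ] <- apply(matrix(out$values[tr, , ], d[2], d[3]), 2,
                            function(x) {
                              stats::approx(out$times, x, new_times)$y
                            })
    }
    out <- trial_tensor(vals, new_times, out$stimulus, out$session)
  }
  out
}

#' Forward-difference derivative of a trajectory
#'
#' Estimates the velocity of a trajectory as
#' \eqn{\dot X(t_i) = (X(t_{i+1}) - X(t_i)) / (t_{i+1} - t_i)}, the
#' estimator used when regressing velocities on states. The output has one
#' row fewer than the input and is aligned with the left time point of each
#' interval; nonuniform grids use the actual per-interval spacing.
#'
#' @param traj a [trajectory()].
#' @return list with `xdot` (a [trajectory()] of derivatives) and `x` (the
#'   left-aligned state trajectory with matching rows).
#' @export
estimate_derivative <- function(traj) {
  .assert(inherits(traj, "trajectory"), "expected a trajectory")
  T_ <- nrow(traj$values)
  .assert(T_ >= 2, "need at least two time points")
  dt <- diff(traj$times)
  .assert(all(dt > 0), "duplicate time stamps")
  xd <- diff(traj$values) / dt
  keep <- seq_len(T_ - 1)
  list(xdot = trajectory(xd, traj$times[keep], traj$space_tag),
       x = trajectory(traj$values[keep, , drop = FALSE], traj$times[keep],
                      traj$space_tag))
}
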