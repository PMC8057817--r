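#' Trial-resolved population activity tensor
#'
#' Stores single-trial population activity as a trials x time x neurons
#' array, with a shared time axis (seconds, t = 0 at stimulus offset), a
#' stimulus label per trial and a session label per neuron. All analyses in
#' the package consume this container: multiple stimuli live in one tensor
#' and are distinguished by the per-trial labels, with equal trial counts
#' per stimulus.
#'
#' @param values numeric array, trials x time x neurons.
#' @param times numeric vector of time stamps in seconds.
#' @param stimulus vector of stimulus labels, one per trial.
#' @param session optional vector of session labels, one per neuron.
#' @return object of class `trial_tensor`.
#' @export
trial_tensor <- function(values, times, stimulus, session = NULL) {
  values <- as.array(values)
  .assert(length(dim(values)) == 3,
          "values must be a 3-d array (trials x time x neurons)")
  times <- as.numeric(times)
  .assert(dim(values)[2] == length(times),
          "time axis length must match `times`")
  .assert(all(diff(times) > 0), "`times` must be strictly increasing")
  stimulus <- as.character(stimulus)
  .assert(length(stimulus) == dim(values)[1],
          "need one stimulus label per trial")
  counts <- table(stimulus)
  .assert(length(unique(counts)) == 1,
          "every stimulus must have the same number of trials")
  session <- as.character(session %||% rep("s1", dim(values)[3]))
  .assert(length(session) == dim(values)[3],
          "need one session label per neuron")
  structure(list(values = values, times = times, stimulus = stimulus,
                 session = session),
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<trial_tensor: %d trials x %d times x %d neurons, %d stimuli, %d sessions>\n",
    d[1], d[2], d[3], length(unique(x$stimulus)),
    length(unique(x$session))))
  invisible(x)
}

#' Number of trials per stimulus
#' @param tt a [trial_tensor()].
#' @return integer scalar.
#' @export
trials_per_stimulus <- function(tt) {
  as.integer(sum(tt$stimulus == tt$stimulus[1]))
}

#' Trial-averaged responses per stimulus
#'
#' Averages the tensor across trials within each stimulus, yielding one
#' [trajectory()] (time x neurons) per stimulus.
#'
#' @param tt a [trial_tensor()].
#' @param stimuli subset of stimulus labels (default all, in order of first
#'   appearance).
#' @return named list of trajectories.
#' @export
trial_average <- function(tt, stimuli = NULL) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  stimuli <- stimuli %||% unique(tt$stimulus)
  out <- lapply(stimuli, function(s) {
    idx <- which(tt$stimulus == s)
    .assert(length(idx) > 0, sprintf("unknown stimulus '%s'", s))
    m <- apply(tt$values[idx, , , drop = FALSE], c(2, 3), mean)
    trajectory(m, tt$times)
  })
  names(out) <- stimuli
  out
}

#' Restrict a trial tensor to a subset of neurons
#' @param tt a [trial_tensor()].
#' @param neurons integer indices of neurons to keep.
#' @return a [trial_tensor()].
#' @export
subset_neurons <- function(tt, neurons) {
  trial_tensor(tt$values[, , neurons, drop = FALSE], tt$times,
               tt$stimulus, tt$session[neurons])
}
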