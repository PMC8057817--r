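# Plain-text serialization: every container round-trips through CSV plus a
# JSON (or YAML) sidecar carrying axes and labels.

#' Write / read a trial tensor
#'
#' Serializes a [trial_tensor()] as `<prefix>_values.csv` (long format:
#' trial, time_index, neuron, value) plus `<prefix>_meta.json` carrying the
#' time axis and the stimulus/session labels. The round trip is lossless up
#' to double formatting.
#'
#' @param tt a [trial_tensor()].
#' @param prefix path prefix (directory must exist).
#' @return `prefix`, invisibly.
#' @export
write_trial_tensor <- function(tt, prefix) {
  .assert(inherits(tt, "trial_tensor"), "expected a trial_tensor")
  d <- dim(tt$values)
  long <- data.frame(trial = rep(seq_len(d[1]), times = d[2] * d[3]),
                     time_index = rep(rep(seq_len(d[2]), each = d[1]),
                                      times = d[3]),
                     neuron = rep(seq_len(d[3]), each = d[1] * d[2]),
                     value = as.vector(tt$values))
  utils::write.csv(long, paste0(prefix, "_values.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(times = tt$times, stimulus = tt$stimulus,
                            session = tt$session, dim = d),
                       paste0(prefix, "_meta.json"), digits = NA)
  invisible(prefix)
}

#' @rdname write_trial_tensor
#' @export
read_trial_tensor <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"),
                              simplifyVector = TRUE)
  long <- utils::read.csv(paste0(prefix, "_values.csv"))
  vals <- array(long$value[order(long$neuron, long$time_index,
                                 long$trial)],
                meta$dim)
  trial_tensor(vals, meta$times, meta$stimulus, meta$session)
}

#' Write / read a trajectory as CSV
#'
#' One row per time point; first column `time`, remaining columns the
#' dimensions. The space tag travels in a comment-free sidecar-less way via
#' the column prefix (`n` for neuron space, `pc` for PC space).
#'
#' @param traj a [trajectory()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  .assert(inherits(traj, "trajectory"), "expected a trajectory")
  pre <- if (traj$space_tag == "pc") "pc" else "n"
  df <- data.frame(time = traj$times, traj$values)
  names(df) <- c("time", paste0(pre, seq_len(ncol(traj$values))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  tag <- if (grepl("^pc", names(df)[2])) "pc" else "neuron"
  trajectory(as.matrix(df[, -1, drop = FALSE]), df$time, space_tag = tag)
}

#' Write / read an overlap matrix as CSV
#'
#' The matrix is written with a label header row and column; a companion
#' `<path base>_pvalues.csv` with the same layout is written when p-values
#' are present.
#'
#' @param om an [overlap_matrix()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_overlap_csv <- function(om, path) {
  .assert(inherits(om, "overlap_matrix"), "expected an overlap_matrix")
  utils::write.csv(data.frame(label = om$labels, om$values,
                              check.names = FALSE),
                   path, row.names = FALSE)
  if (!is.null(om$p_values)) {
    pv <- om$p_values
    dimnames(pv) <- list(om$labels, om$labels)
    utils::write.csv(data.frame(label = om$labels, pv,
                                check.names = FALSE),
                     sub("\\.csv$", "_pvalues.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_overlap_csv
#' @export
read_overlap_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- as.character(df$label)
  vals <- as.matrix(df[, -1, drop = FALSE])
  pv_path <- sub("\\.csv$", "_pvalues.csv", path)
  pv <- NULL
  if (file.exists(pv_path)) {
    pv <- as.matrix(utils::read.csv(pv_path,
                                    check.names = FALSE)[, -1,
                                                         drop = FALSE])
    dimnames(pv) <- list(labels, labels)
  }
  overlap_matrix(vals, labels, p_values = pv)
}

#' Human-readable YAML summary of a channel bank
#'
#' Writes the per-channel amplitudes and frequencies plus the orthonormal
#' basis (as a nested list) to YAML; [read_bank_yaml()] reconstructs the
#' bank.
#'
#' @param bank a [rotational_channel_bank()].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_bank_yaml <- function(bank, path) {
  .assert(inherits(bank, "rotational_channel_bank"),
          "expected a rotational_channel_bank")
  yaml::write_yaml(list(n = bank$n, n_channels = bank$n_channels,
                        delta1 = as.numeric(bank$delta1),
                        delta2 = as.numeric(bank$delta2),
                        omega = as.numeric(bank$omega),
                        basis = apply(bank$basis, 2, as.numeric,
                                      simplify = FALSE)),
                   path, precision = 15)
  invisible(path)
}

#' @rdname write_bank_yaml
#' @export
read_bank_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  basis <- do.call(cbind, y$basis)
  rotational_channel_bank(y$delta1, y$delta2, basis)
}
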