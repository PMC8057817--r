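#' The 16-stimulus ramping-sound design
#'
#' Enumerates the stimulus set used throughout: the full cross of ramp
#' direction (UP with rising intensity, DOWN with falling), carrier
#' frequency (8 kHz pure tone or white noise), duration (1 or 2 s) and
#' intensity modulation (50-85 or 60-85 dB, reversed for DOWN ramps),
#' numbered 1-16 with all UP stimuli first.
#'
#' @return data frame with columns `stimulus`, `direction`, `frequency`,
#'   `duration_s`, `modulation_db`.
#' @export
enumerate_stimulus_set <- function() {
  up <- expand.grid(modulation_db = c("50-85", "60-85"),
                    duration_s = c(1, 2),
                    frequency = c("8kHz", "WN"),
                    stringsAsFactors = FALSE)
  down <- expand.grid(modulation_db = c("85-50", "85-60"),
                      duration_s = c(1, 2),
                      frequency = c("8kHz", "WN"),
                      stringsAsFactors = FALSE)
  out <- rbind(cbind(direction = "UP", up),
               cbind(direction = "DOWN", down))
  out <- out[, c("direction", "frequency", "duration_s", "modulation_db")]
  data.frame(stimulus = seq_len(nrow(out)), out,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters of the emulated recordings. Defaults follow the
#' simulated-network regime used for the rotational-channel analyses (1000
#' units, 20 rank-2 channels with \eqn{\Delta_1 = 1}, \eqn{\Delta_2 = 7})
#' and the recording statistics of the pooled dataset (16 stimuli, 20
#' trials, 31.5 Hz frames, OFF window from -50 ms to +300 ms, 13 sessions
#' of 180 +/- 72 neurons rescaled to the population size).
#'
#' @param n_neurons population size.
#' @param n_channels number of rank-2 rotational channels.
#' @param delta1,delta2 channel amplitudes (recycled).
#' @param n_stimuli number of stimuli (at most 16; labels follow
#'   [enumerate_stimulus_set()]).
#' @param n_trials trials per stimulus.
#' @param init_noise_sd standard deviation `s` of the isotropic Gaussian
#'   trial-to-trial noise on the initial state.
#' @param obs_noise_sd observation noise added to every sample (default 0:
#'   the models place noise only in the initial condition).
#' @param frame_rate_hz sampling rate.
#' @param window OFF window in seconds relative to offset.
#' @param time_constant network time constant in seconds (maps data time to
#'   model time).
#' @param n_sessions,session_size_mean,session_size_sd session layout;
#'   sizes are drawn from this normal law and rescaled to sum to
#'   `n_neurons`.
#' @param stimulus_channel integer vector mapping each stimulus to its
#'   channel (default: stimulus s drives channel s, recycled).
#' @param cluster_cosine across-stimulus correlation of initial states for
#'   stimuli mapped to the same channel entry via `clusters`.
#' @param clusters optional list of integer vectors; stimuli within one
#'   vector share the leading member's channel with cosine
#'   `cluster_cosine`.
#' @param resample_to optional time-point count for window resampling.
#' @param seed RNG seed.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_neurons = 1000, n_channels = 20,
                             delta1 = 1, delta2 = 7, n_stimuli = 16,
                             n_trials = 20, init_noise_sd = 0.1,
                             obs_noise_sd = 0, frame_rate_hz = 31.5,
                             window = c(-0.05, 0.30),
                             time_constant = 0.1, n_sessions = 13,
                             session_size_mean = 180,
                             session_size_sd = 72,
                             stimulus_channel = NULL,
                             cluster_cosine = 0.8, clusters = NULL,
                             resample_to = NULL, seed = 1) {
  .assert(2 * n_channels <= n_neurons,
          "need at least two dimensions per channel")
  .assert(init_noise_sd >= 0 && obs_noise_sd >= 0,
          "noise sds must be nonnegative")
  cfg <- list(n_neurons = n_neurons, n_channels = n_channels,
              delta1 = rep_len(delta1, n_channels),
              delta2 = rep_len(delta2, n_channels),
              n_stimuli = n_stimuli, n_trials = n_trials,
              init_noise_sd = init_noise_sd,
              obs_noise_sd = obs_noise_sd,
              frame_rate_hz = frame_rate_hz, window = window,
              time_constant = time_constant, n_sessions = n_sessions,
              session_size_mean = session_size_mean,
              session_size_sd = session_size_sd,
              stimulus_channel = stimulus_channel %||%
                (((seq_len(n_stimuli) - 1) %% n_channels) + 1),
              cluster_cosine = cluster_cosine, clusters = clusters,
              resample_to = resample_to, seed = seed)
  class(cfg) <- "generator_config"
  cfg
}

# frame grid of the OFF window in seconds
.window_times <- function(cfg) {
  dt <- 1 / cfg$frame_rate_hz
  ts <- seq(cfg$window[1], cfg$window[2] - 1e-9, by = dt)
  if (!is.null(cfg$resample_to)) {
    ts <- seq(cfg$window[1], max(ts), length.out = cfg$resample_to)
  }
  ts
}

# draw session sizes summing to n
.session_sizes <- function(cfg) {
  raw <- pmax(10, round(stats::rnorm(cfg$n_sessions,
                                     cfg$session_size_mean,
                                     cfg$session_size_sd)))
  sizes <- pmax(2, round(raw * cfg$n_neurons / sum(raw)))
  while (sum(sizes) != cfg$n_neurons) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] + sign(cfg$n_neurons - sum(sizes))
  }
  sizes
}

#' Generate a network-model dataset with ground truth
#'
#' Builds a bank of mutually orthogonal rank-2 rotational channels on a
#' random orthonormal basis, assigns each stimulus an initial state along
#' its channel's amplified input direction \eqn{v^{(2;k)}} (stimulus
#' clusters share channels at a configurable cosine), draws per-trial
#' initial states with isotropic Gaussian noise, propagates them with the
#' network dynamics, and splits neurons into sessions. Model time is mapped
#' to data time by the configured network time constant.
#'
#' @param cfg a [generator_config()].
#' @return list with `tensor` (a [trial_tensor()]; times in seconds,
#'   t = 0 at the window start used as the propagation origin) and
#'   `ground_truth` (bank, dense connectivity `J`, `initial_states`
#'   (stimuli x neurons), `stimulus_channel`, `times_model`, `seed`).
#' @export
generate_network_dataset <- function(cfg = generator_config()) {
  .assert(inherits(cfg, "generator_config"), "expected a generator_config")
  set.seed(cfg$seed)
  basis <- .random_orthonormal(cfg$n_neurons, 2 * cfg$n_channels)
  bank <- rotational_channel_bank(cfg$delta1, cfg$delta2, basis)
  J <- build_connectivity(bank)
  chan <- rep_len(cfg$stimulus_channel, cfg$n_stimuli)
  # clusters: every member state mixes a shared amplified direction (the
  # lead member's channel) with a private one, so all pairwise cosines
  # within a cluster equal cluster_cosine; the lead's private direction is
  # taken from a spare (unassigned) channel
  shared_ch <- rep(NA_integer_, cfg$n_stimuli)
  private_ch <- chan
  if (!is.null(cfg$clusters)) {
    spare <- setdiff(seq_len(cfg$n_channels), chan)
    for (cl in cfg$clusters) {
      lead <- cl[1]
      .assert(length(spare) >= 1,
              "clusters need one spare channel per cluster for the lead")
      shared_ch[cl] <- chan[lead]
      private_ch[lead] <- spare[1]
      spare <- spare[-1]
    }
  }
  v2 <- function(k) bank$basis[, 2 * k]
  r0 <- matrix(0, cfg$n_stimuli, cfg$n_neurons)
  for (s in seq_len(cfg$n_stimuli)) {
    if (is.na(shared_ch[s])) {
      r0[s, ] <- v2(chan[s])
    } else {
      r0[s, ] <- sqrt(cfg$cluster_cosine) * v2(shared_ch[s]) +
        sqrt(1 - cfg$cluster_cosine) * v2(private_ch[s])
    }
  }
  times <- .window_times(cfg)
  times_model <- (times - times[1]) / cfg$time_constant
  ntr <- cfg$n_trials
  vals <- array(0, c(ntr * cfg$n_stimuli, length(times), cfg$n_neurons))
  A <- J - diag(cfg$n_neurons)
  inits <- matrix(0, cfg$n_neurons, ntr * cfg$n_stimuli)
  for (s in seq_len(cfg$n_stimuli)) {
    for (tr in seq_len(ntr)) {
      inits[, (s - 1) * ntr + tr] <-
        r0[s, ] + stats::rnorm(cfg$n_neurons, 0, cfg$init_noise_sd)
    }
  }
  batch <- .propagate_batch(A, inits, times_model)
  for (i in seq_len(ntr * cfg$n_stimuli)) vals[i, , ] <- batch[, , i]
  if (cfg$obs_noise_sd > 0) {
    vals <- vals + array(stats::rnorm(length(vals), 0, cfg$obs_noise_sd),
                         dim(vals))
  }
  sizes <- .session_sizes(cfg)
  session <- rep(sprintf("session%02d", seq_along(sizes)), sizes)
  tensor <- trial_tensor(vals, times,
                         rep(as.character(seq_len(cfg$n_stimuli)),
                             each = ntr), session)
  list(tensor = tensor,
       ground_truth = list(bank = bank, J = J, initial_states = r0,
                           stimulus_channel = chan,
                           times_model = times_model, seed = cfg$seed))
}

#' Generate a single-cell-model dataset with ground truth
#'
#' Each neuron carries one temporal filter (a random mixture of Gaussian
#' bumps, normalized to unit dynamic range) shared across stimuli, and a
#' per-stimulus firing-rate range with configurable across-stimulus
#' correlation. Single trials perturb the range with isotropic Gaussian
#' noise, so the across-trial covariance is diagonal at every time.
#'
#' @param cfg a [generator_config()] (channel fields are ignored).
#' @param n_bumps bumps mixed per filter (default 3).
#' @param range_correlation across-stimulus correlation of the ranges
#'   (default 0.5).
#' @return list with `tensor` and `ground_truth` (`filters` neurons x
#'   time, `ranges` neurons x stimuli, `seed`).
#' @export
generate_single_cell_dataset <- function(cfg = generator_config(),
                                         n_bumps = 3,
                                         range_correlation = 0.5) {
  .assert(inherits(cfg, "generator_config"), "expected a generator_config")
  set.seed(cfg$seed + 1L)
  times <- .window_times(cfg)
  T_ <- length(times)
  N <- cfg$n_neurons
  centers <- stats::runif(N * n_bumps, min(times), max(times))
  widths <- stats::runif(N * n_bumps, 0.02, 0.08)
  weights <- matrix(stats::rnorm(N * n_bumps), N)
  L <- matrix(0, N, T_)
  for (b in seq_len(n_bumps)) {
    cb <- centers[(b - 1) * N + seq_len(N)]
    wb <- widths[(b - 1) * N + seq_len(N)]
    L <- L + weights[, b] * exp(-sweep(outer(rep(1, N), times), 1, cb)^2 /
                                  (2 * wb^2))
  }
  rng <- apply(L, 1, function(x) abs(max(x) - min(x)))
  rng[rng == 0] <- 1
  L <- L / rng
  rho <- range_correlation
  common <- stats::rnorm(N)
  ranges <- vapply(seq_len(cfg$n_stimuli), function(s) {
    # firing-rate ranges are magnitudes; |N(0,1)| keeps the configurable
    # across-stimulus correlation while staying nonnegative
    abs(sqrt(rho) * common + sqrt(1 - rho) * stats::rnorm(N)) + 0.1
  }, numeric(N))
  ntr <- cfg$n_trials
  vals <- array(0, c(ntr * cfg$n_stimuli, T_, N))
  for (s in seq_len(cfg$n_stimuli)) {
    for (tr in seq_len(ntr)) {
      pert <- ranges[, s] + stats::rnorm(N, 0, cfg$init_noise_sd)
      vals[(s - 1) * ntr + tr, , ] <- t(pert * L)
    }
  }
  if (cfg$obs_noise_sd > 0) {
    vals <- vals + array(stats::rnorm(length(vals), 0, cfg$obs_noise_sd),
                         dim(vals))
  }
  sizes <- .session_sizes(cfg)
  session <- rep(sprintf("session%02d", seq_along(sizes)), sizes)
  tensor <- trial_tensor(vals, times,
                         rep(as.character(seq_len(cfg$n_stimuli)),
                             each = ntr), session)
  list(tensor = tensor,
       ground_truth = list(filters = L, ranges = ranges, seed = cfg$seed))
}

#' Small deterministic fixture datasets
#'
#' A registry of tiny, seeded datasets used for fast tests and examples.
#' `"two_orthogonal_channels"`: 4 stimuli on two orthogonal rotational
#' channels (two correlated pairs), 40 neurons. `"single_cell_small"`:
#' 4-stimulus single-cell dataset, 50 neurons. `"network_small"`: 4
#' stimuli on 4 orthogonal channels, 60 neurons.
#'
#' @param name fixture name.
#' @return the generator output (list with `tensor`, `ground_truth`).
#' @export
make_fixture <- function(name) {
  registry <- c("two_orthogonal_channels", "single_cell_small",
                "network_small")
  if (!name %in% registry) {
    stop(sprintf("unknown fixture '%s'; available: %s", name,
                 paste(registry, collapse = ", ")), call. = FALSE)
  }
  switch(name,
    two_orthogonal_channels = generate_network_dataset(generator_config(
      n_neurons = 40, n_channels = 6, n_stimuli = 4, n_trials = 20,
      init_noise_sd = 0.05, n_sessions = 2, seed = 424243,
      stimulus_channel = c(1, 3, 2, 4),
      clusters = list(c(1, 2), c(3, 4)), cluster_cosine = 0.9)),
    network_small = generate_network_dataset(generator_config(
      n_neurons = 60, n_channels = 4, n_stimuli = 4, n_trials = 20,
      init_noise_sd = 0.05, n_sessions = 2, seed = 424244)),
    single_cell_small = generate_single_cell_dataset(generator_config(
      n_neurons = 50, n_channels = 2, n_stimuli = 4, n_trials = 20,
      init_noise_sd = 0.05, n_sessions = 2, seed = 424245)))
}
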