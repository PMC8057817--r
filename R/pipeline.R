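#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages (simulate, preprocess, fit, geometry,
#' channels, variability, decode, surrogate) on a synthetic dataset
#' described by a single hierarchical configuration (a YAML file path or an
#' equivalent nested list), writing versioned CSV/JSON outputs, a log with
#' every derived seed, and a machine-readable `summary.json`. All
#' randomness flows from one master seed through named substreams, so
#' reruns with the same configuration are reproducible.
#'
#' Configuration keys (all optional except `generator`): `seed` (master
#' seed), `stages` (character vector; default all), `generator` (`kind`
#' `"network"` or `"single_cell"` plus [generator_config()] fields, or
#' `fixture` naming a [make_fixture()] entry), `preprocess` (`kernel_sd`,
#' `window`), `fit` (`lambda`, `rank`, `n_pc`, `k_folds`), `geometry`
#' (`k`, `n_resamples`), `channels` (`lambda`, `rank`, `lambda_full`,
#' `rank_full`, `n_shuffles`), `variability` (`n_subsamples`,
#' `n_direction_samples`), `decode` (`stimuli`, `bin_width`,
#' `n_shuffles`), `surrogate` (`kind`, `n`).
#'
#' @param config YAML file path or nested list.
#' @param out_dir output directory (created if missing).
#' @return the run directory path, invisibly; `summary.json` inside holds
#'   the headline numbers of every executed stage.
#' @export
run_pipeline <- function(config, out_dir = tempfile("offdyn_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  .assert(is.list(config), "config must be a list or a YAML path")
  .assert(!is.null(config$generator),
          "config must contain a `generator` stanza")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "preprocess", "fit",
                                 "geometry", "channels", "variability",
                                 "decode", "surrogate")
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("offdyn pipeline run, master seed %d\n", seed),
      file = log_path)
  summary <- list(seed = seed, stages = stages)

  # --- simulate ------------------------------------------------------
  gen <- config$generator
  gseed <- .substream_seed(seed, "simulate")
  logf("stage simulate: seed %d", gseed)
  if (!is.null(gen$fixture)) {
    ds <- make_fixture(gen$fixture)
  } else {
    kind <- gen$kind %||% "network"
    gen_args <- gen[setdiff(names(gen), c("kind", "fixture"))]
    gen_args$seed <- gseed
    cfg <- do.call(generator_config, gen_args)
    ds <- if (kind == "network") generate_network_dataset(cfg) else
      generate_single_cell_dataset(cfg)
  }
  tt <- ds$tensor
  write_trial_tensor(tt, file.path(out_dir, "dataset"))
  summary$simulate <- list(n_neurons = dim(tt$values)[3],
                           n_trials = dim(tt$values)[1],
                           n_times = dim(tt$values)[2],
                           n_stimuli = length(unique(tt$stimulus)))
  if (!"simulate" %in% stages) stages <- union(stages, "simulate")

  # --- preprocess ----------------------------------------------------
  if ("preprocess" %in% stages) {
    pp <- config$preprocess %||% list()
    if (!is.null(pp$kernel_sd) && pp$kernel_sd > 0) {
      tt <- smooth_and_baseline(tt, kernel_sd = pp$kernel_sd)
    }
    if (!is.null(pp$window)) {
      tt <- extract_off_window(tt, pp$window[1], pp$window[2])
    }
    summary$preprocess <- list(n_times = dim(tt$values)[2])
  }
  responses <- trial_average(tt)

  # --- fit -----------------------------------------------------------
  fit <- NULL; design <- NULL
  if ("fit" %in% stages) {
    fc <- config$fit %||% list()
    design <- build_design(responses, n_pc = fc$n_pc %||% 100)
    lambda <- fc$lambda %||% 1
    rank <- fc$rank
    fit <- if (is.null(rank)) fit_ridge(design, lambda) else
      fit_reduced_rank(design, lambda, rank)
    cv <- crossval_r2(design, lambda, rank,
                      k_folds = fc$k_folds %||% 10)
    fit$cv_r2 <- cv$mean_r2; fit$fold_r2 <- cv$fold_r2
    sc <- predict_and_score(fit, responses)
    utils::write.csv(data.frame(fold = seq_along(cv$fold_r2),
                                r2 = cv$fold_r2),
                     file.path(out_dir, "fit_cv.csv"), row.names = FALSE)
    summary$fit <- list(lambda = lambda, rank = rank,
                        cv_r2 = cv$mean_r2, r2 = sc$r2,
                        n_pc = ncol(design$X))
    logf("stage fit: cv_r2 %.4f", cv$mean_r2)
  }

  # --- geometry ------------------------------------------------------
  if ("geometry" %in% stages) {
    gc_ <- config$geometry %||% list()
    k <- gc_$k %||% 5
    os <- overlap_structure(responses, k = k, subtract_initial = TRUE)
    write_overlap_csv(os$overlaps,
                      file.path(out_dir, "subspace_overlaps.csv"))
    cum <- cumulative_variance(responses)
    utils::write.csv(data.frame(component = seq_along(cum),
                                cumvar = as.numeric(cum)),
                     file.path(out_dir, "cumulative_variance.csv"),
                     row.names = FALSE)
    summary$geometry <- list(
      k = k, structure_correlation = os$structure_correlation,
      mean_offdiag_overlap =
        mean(os$overlaps$values[row(os$overlaps$values) !=
                                  col(os$overlaps$values)]))
  }

  # --- channels ------------------------------------------------------
  if ("channels" %in% stages && length(responses) >= 2) {
    cc <- config$channels %||% list()
    D_max <- if (!is.null(design)) ncol(design$X) else
      min(dim(responses[[1]]$values))
    cs <- fit_channels(responses, lambda = cc$lambda %||% 5,
                       rank = min(cc$rank %||% 5, D_max),
                       n_pc = cc$n_pc %||% 100)
    sct <- sum_channels_test(
      cs, lambda_full = cc$lambda_full %||% 2,
      rank_full = cc$rank_full %||% 70,
      n_shuffles = cc$n_shuffles %||% 50,
      seed = .substream_seed(seed, "channels"))
    co <- connectivity_overlap(cs)
    write_overlap_csv(co, file.path(out_dir, "connectivity_overlaps.csv"))
    utils::write.csv(
      data.frame(quantity = c("r2_full", "r2_sum", "r2_shuffle_q50",
                              "r2_shuffle_q95"),
                 value = c(sct$r2_full, sct$r2_sum,
                           stats::median(sct$r2_shuffle),
                           stats::quantile(sct$r2_shuffle, 0.95))),
      file.path(out_dir, "sum_channels.csv"), row.names = FALSE)
    summary$channels <- list(r2_full = sct$r2_full, r2_sum = sct$r2_sum,
                             r2_shuffle_median =
                               stats::median(sct$r2_shuffle))
  }

  # --- variability ---------------------------------------------------
  if ("variability" %in% stages) {
    vc <- config$variability %||% list()
    va <- va_contrast(tt,
                      n_direction_samples = vc$n_direction_samples %||% 20,
                      n_subsamples = vc$n_subsamples %||% 50,
                      seed = .substream_seed(seed, "variability"))
    utils::write.csv(va$per_stimulus,
                     file.path(out_dir, "va_contrast.csv"),
                     row.names = FALSE)
    summary$variability <- list(
      mean_delta_va_real = mean(va$per_stimulus$delta_va_real),
      mean_delta_va_shuffled = mean(va$per_stimulus$delta_va_shuffled),
      p_value_pooled = va$p_value_pooled)
    logf("stage variability: seed %d",
         .substream_seed(seed, "variability"))
  }

  # --- decode --------------------------------------------------------
  if ("decode" %in% stages && length(unique(tt$stimulus)) >= 2) {
    dc <- config$decode %||% list()
    pair <- dc$stimuli %||% utils::head(unique(tt$stimulus), 2)
    dec <- loo_accuracy(tt, pair, bin_width = dc$bin_width %||% 0.05,
                        seed = .substream_seed(seed, "decode"))
    ch <- chance_course(tt, pair, bin_width = dc$bin_width %||% 0.05,
                        n_shuffles = dc$n_shuffles %||% 10,
                        seed = .substream_seed(seed, "decode_chance"))
    out <- dec$timecourse
    out$chance_mean <- ch$chance_mean
    out$chance_sd <- ch$chance_sd
    utils::write.csv(out, file.path(out_dir, "decoder_timecourse.csv"),
                     row.names = FALSE)
    summary$decode <- list(peak_accuracy = max(out$accuracy),
                           chance_mean = ch$chance_mean)
  }

  # --- surrogate -----------------------------------------------------
  if ("surrogate" %in% stages && !is.null(design)) {
    sc_ <- config$surrogate %||% list()
    Z <- array(0, c(nrow(design$responses_pc[[1]]$values),
                    ncol(design$X), length(design$responses_pc)))
    for (i in seq_along(design$responses_pc)) {
      Z[, , i] <- design$responses_pc[[i]]$values
    }
    ms <- marginal_stats(Z)
    sur <- generate_surrogates(ms, kind = sc_$kind %||% "TKC",
                               n = sc_$n %||% 5,
                               seed = .substream_seed(seed, "surrogate"))
    cmp <- surrogate_fit_comparison(Z, sur, design$times,
                                    lambda = config$fit$lambda %||% 1)
    utils::write.csv(cmp, file.path(out_dir, "surrogate_fits.csv"),
                     row.names = FALSE)
    summary$surrogate <- list(
      r2_real = cmp$cv_r2[cmp$dataset == "real"],
      r2_surrogate_mean = mean(cmp$cv_r2[cmp$dataset != "real"]))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Collect the tables written by a pipeline run
#'
#' Reads the summary and every stage CSV of a completed [run_pipeline()]
#' directory back into R; missing stage outputs are noted rather than
#' failing.
#'
#' @param run_dir directory returned by [run_pipeline()].
#' @return list with `summary` and one entry per table (`NULL` plus a note
#'   in `missing` for absent stages).
#' @export
pipeline_report <- function(run_dir) {
  .assert(dir.exists(run_dir), "run directory does not exist")
  sp <- file.path(run_dir, "summary.json")
  .assert(file.exists(sp), "run has no summary.json (incomplete run?)")
  out <- list(summary = jsonlite::read_json(sp, simplifyVector = TRUE),
              missing = character(0))
  tables <- c(fit_cv = "fit_cv.csv",
              subspace_overlaps = "subspace_overlaps.csv",
              cumulative_variance = "cumulative_variance.csv",
              connectivity_overlaps = "connectivity_overlaps.csv",
              sum_channels = "sum_channels.csv",
              va_contrast = "va_contrast.csv",
              decoder_timecourse = "decoder_timecourse.csv",
              surrogate_fits = "surrogate_fits.csv")
  for (nm in names(tables)) {
    p <- file.path(run_dir, tables[[nm]])
    if (file.exists(p)) {
      out[[nm]] <- if (grepl("overlaps", nm)) read_overlap_csv(p) else
        utils::read.csv(p, check.names = FALSE)
    } else {
      out$missing <- c(out$missing, nm)
    }
  }
  out
}
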