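#' Regression design for network-model fitting
#'
#' Assembles the state/velocity regression used to estimate the effective
#' connectivity of the linear network model \eqn{\dot X = X(J - I)}. The
#' trial-averaged responses to each stimulus are stacked over time, the data
#' are centered jointly over times and stimuli, optionally reduced by PCA,
#' and velocities are estimated by forward differences aligned with the
#' left time point.
#'
#' @param responses named list of [trajectory()] objects (one per
#'   stimulus), all in the same space and on the same time grid.
#' @param n_pc number of principal components to keep; the effective count
#'   is the smaller of `n_pc` and the number of components reaching
#'   `var_threshold` of the variance. `NULL` disables PCA reduction.
#' @param var_threshold fraction of variance the retained components must
#'   reach (default 0.9).
#' @return object of class `regression_design` with fields `X`, `Xdot`,
#'   `stimulus_of_row`, `pc_basis`, `center`, `times`, `responses_pc`.
#' @export
build_design <- function(responses, n_pc = 100, var_threshold = 0.9) {
  .assert(is.list(responses) && length(responses) >= 1,
          "need at least one response trajectory")
  .assert(all(vapply(responses, inherits, logical(1), "trajectory")),
          "responses must be trajectories")
  if (is.null(names(responses)) || any(names(responses) == "")) {
    names(responses) <- paste0("stim", seq_along(responses))
  }
  times <- responses[[1]]$times
  for (r in responses) {
    .assert(isTRUE(all.equal(r$times, times)),
            "responses must share one time grid")
  }
  grand <- do.call(rbind, lapply(responses, function(r) r$values))
  center <- colMeans(grand)
  centered <- sweep(grand, 2, center)
  pc_basis <- NULL
  if (!is.null(n_pc)) {
    sv <- svd(centered)
    var_exp <- cumsum(sv$d^2) / sum(sv$d^2)
    k90 <- which(var_exp >= var_threshold)[1]
    k <- min(n_pc, k90, length(sv$d))
    pc_basis <- sv$v[, seq_len(k), drop = FALSE]
    # The dynamics have their fixed point at baseline (0), not at the
    # time/stimulus mean, so activity is projected uncentered; the mean
    # direction is appended to the basis so that no state component the
    # trajectories actually visit is lost to the centering.
    b0 <- center - pc_basis %*% crossprod(pc_basis, center)
    nb0 <- sqrt(sum(b0^2))
    if (nb0 > 1e-10 * max(sqrt(sum(center^2)), 1)) {
      pc_basis <- cbind(pc_basis, b0 / nb0)
    }
  }
  proj <- function(m) {
    if (is.null(pc_basis)) m else m %*% pc_basis
  }
  responses_pc <- lapply(responses, function(r) {
    trajectory(proj(r$values), r$times,
               if (is.null(pc_basis)) r$space_tag else "pc")
  })
  Xs <- list(); Xds <- list(); labs <- character(0)
  for (s in names(responses_pc)) {
    der <- estimate_derivative(responses_pc[[s]])
    Xs[[s]] <- der$x$values
    Xds[[s]] <- der$xdot$values
    labs <- c(labs, rep(s, nrow(der$x$values)))
  }
  structure(list(X = do.call(rbind, Xs), Xdot = do.call(rbind, Xds),
                 stimulus_of_row = labs, pc_basis = pc_basis,
                 center = center, times = times,
                 responses_pc = responses_pc),
            class = "regression_design")
}

# Subset a design to a set of rows (used by cross-validation).
.design_rows <- function(design, rows) {
  structure(list(X = design$X[rows, , drop = FALSE],
                 Xdot = design$Xdot[rows, , drop = FALSE],
                 stimulus_of_row = design$stimulus_of_row[rows],
                 pc_basis = design$pc_basis, center = design$center,
                 times = design$times,
                 responses_pc = design$responses_pc),
            class = "regression_design")
}

# Ridge solution in the printed (row-state) convention:
# J* = I + (X'X + lambda I)^-1 X' Xdot. Returns the dynamical-convention
# connectivity, i.e. the transpose, so that rdot = -r + J r reproduces the
# fitted velocities.
.ridge_raw <- function(X, Xdot, lambda) {
  D <- ncol(X)
  G <- crossprod(X) + lambda * diag(D)
  if (lambda == 0) {
    ok <- tryCatch({solve(G); TRUE}, error = function(e) FALSE)
    if (!ok || rcond(G) < 1e-14) {
      stop(paste0("normal equations are singular at lambda = 0; ",
                  "use a small positive ridge penalty"), call. = FALSE)
    }
  }
  A <- solve(G, crossprod(X, Xdot))
  diag(D) + A
}

#' Ridge-regression estimate of the network connectivity
#'
#' Minimizes \eqn{\lVert\dot X - X(J - I)\rVert^2 +
#' \lambda\lVert J - I\rVert^2} over the connectivity. The returned
#' connectivity is stored in the dynamical convention
#' (\eqn{\dot r = -r + Jr}), so it can be passed directly to
#' [propagate()].
#'
#' @param design a [build_design()] object.
#' @param lambda nonnegative ridge penalty.
#' @return object of class `network_fit` with fields `J`, `lambda`, `rank`
#'   (`NULL` for unconstrained), `pc_basis`, `center`, `cv_r2` (filled by
#'   [crossval_r2()]).
#' @export
fit_ridge <- function(design, lambda) {
  .assert(inherits(design, "regression_design"), "expected a design")
  .assert(lambda >= 0, "lambda must be nonnegative")
  Jrow <- .ridge_raw(design$X, design$Xdot, lambda)
  structure(list(J = t(Jrow), lambda = lambda, rank = NULL,
                 pc_basis = design$pc_basis, center = design$center,
                 cv_r2 = NA_real_, fold_r2 = NULL),
            class = "network_fit")
}

#' Reduced-rank ridge estimate of the network connectivity
#'
#' Solves the ridge problem under a rank constraint on `J`: the ridge
#' solution is projected on the leading `R` right singular vectors of
#' \eqn{X_\lambda J^*_\lambda} (the augmented design times the ridge
#' solution), which is the exact solution of the reduced-rank ridge
#' problem.
#'
#' @inheritParams fit_ridge
#' @param rank rank bound `R`, between 1 and the state dimension.
#' @return a `network_fit` whose connectivity has rank at most `R`.
#' @export
fit_reduced_rank <- function(design, lambda, rank) {
  .assert(inherits(design, "regression_design"), "expected a design")
  D <- ncol(design$X)
  .assert(rank >= 1 && rank <= D,
          sprintf("rank must be between 1 and %d", D))
  Jrow <- .ridge_raw(design$X, design$Xdot, lambda)
  Xlam <- rbind(design$X, sqrt(lambda) * diag(D))
  sv <- svd(Xlam %*% Jrow)
  V <- sv$v[, seq_len(rank), drop = FALSE]
  Jr <- Jrow %*% tcrossprod(V)
  structure(list(J = t(Jr), lambda = lambda, rank = rank,
                 pc_basis = design$pc_basis, center = design$center,
                 cv_r2 = NA_real_, fold_r2 = NULL),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat(sprintf("<network_fit: %d dims, lambda = %g, rank = %s, cv R2 = %s>\n",
              nrow(x$J), x$lambda,
              if (is.null(x$rank)) "full" else x$rank,
              if (is.na(x$cv_r2)) "unset" else sprintf("%.3f", x$cv_r2)))
  invisible(x)
}

# Contiguous K-chunk fold assignment per stimulus; returns a list of row
# index vectors, one per fold.
.cv_folds <- function(stimulus_of_row, k_folds) {
  folds <- vector("list", k_folds)
  for (s in unique(stimulus_of_row)) {
    rows <- which(stimulus_of_row == s)
    .assert(length(rows) >= k_folds,
            sprintf("stimulus '%s' has fewer rows (%d) than folds (%d)",
                    s, length(rows), k_folds))
    # contiguous chunks; remainder goes to the last chunk
    cuts <- floor(seq(0, length(rows), length.out = k_folds + 1))
    for (i in seq_len(k_folds)) {
      folds[[i]] <- c(folds[[i]], rows[(cuts[i] + 1):cuts[i + 1]])
    }
  }
  folds
}

#' Cross-validated goodness of fit of a network model
#'
#' K-fold cross-validation in which each stimulus's rows are partitioned
#' into contiguous temporal chunks; fold i holds out the i-th chunk of
#' every stimulus, the model is refitted on the remainder and held-out
#' velocities are predicted. Returns the coefficient of determination on
#' the held-out derivative predictions.
#'
#' @param design a [build_design()] object.
#' @param lambda ridge penalty.
#' @param rank rank bound, or `NULL` for unconstrained ridge.
#' @param k_folds number of folds (default 10).
#' @return list with `mean_r2` and `fold_r2`.
#' @export
crossval_r2 <- function(design, lambda, rank = NULL, k_folds = 10) {
  folds <- .cv_folds(design$stimulus_of_row, k_folds)
  fold_r2 <- vapply(folds, function(test_rows) {
    train <- .design_rows(design, setdiff(seq_len(nrow(design$X)),
                                          test_rows))
    fit <- if (is.null(rank)) fit_ridge(train, lambda) else
      fit_reduced_rank(train, lambda, rank)
    Xte <- design$X[test_rows, , drop = FALSE]
    pred <- Xte %*% (t(fit$J) - diag(ncol(Xte)))
    .r2_score(design$Xdot[test_rows, , drop = FALSE], pred)
  }, numeric(1))
  list(mean_r2 = mean(fold_r2), fold_r2 = fold_r2)
}

#' Hyperparameter selection for reduced-rank ridge fits
#'
#' The cross-validated goodness of fit as a function of the rank saturates
#' rather than peaking; the selected rank `R*` is therefore the smallest
#' rank whose best-over-lambda CV score reaches a fixed fraction
#' (`plateau_frac`, default 0.95) of the plateau level across the grid,
#' and `lambda*` maximizes the CV score at `R*`.
#'
#' @param design a [build_design()] object.
#' @param lambda_grid,rank_grid candidate values.
#' @param k_folds folds for [crossval_r2()].
#' @param plateau_frac fraction of the plateau defining saturation.
#' @return list with `lambda`, `rank`, `r2_table` (rank x lambda matrix of
#'   mean CV scores) and `saturated` flag.
#' @export
select_hyperparameters <- function(design, lambda_grid, rank_grid,
                                   k_folds = 10, plateau_frac = 0.95) {
  .assert(length(lambda_grid) >= 1 && length(rank_grid) >= 1,
          "grids must be nonempty")
  rank_grid <- sort(unique(rank_grid))
  tab <- matrix(NA_real_, length(rank_grid), length(lambda_grid),
                dimnames = list(rank = rank_grid, lambda = lambda_grid))
  for (i in seq_along(rank_grid)) {
    for (j in seq_along(lambda_grid)) {
      tab[i, j] <- crossval_r2(design, lambda_grid[j], rank_grid[i],
                               k_folds)$mean_r2
    }
  }
  curve <- apply(tab, 1, max)
  plateau <- max(curve)
  saturated <- TRUE
  if (plateau <= 0) {
    warning("CV score never positive; returning largest grid rank")
    r_star_i <- length(rank_grid)
    saturated <- FALSE
  } else {
    hit <- which(curve >= plateau_frac * plateau)
    if (length(hit) == 0) {
      warning("non-saturating rank curve; returning largest grid rank")
      r_star_i <- length(rank_grid)
      saturated <- FALSE
    } else r_star_i <- hit[1]
  }
  j_star <- which.max(tab[r_star_i, ])
  list(lambda = lambda_grid[j_star], rank = rank_grid[r_star_i],
       r2_table = tab, saturated = saturated)
}

#' Continuous-time spectrum of a fitted connectivity
#'
#' The forward-difference regression estimates the one-step flow map
#' \eqn{(P_{\Delta t} - I)/\Delta t} rather than the generator itself, so
#' eigenvalues of the fitted connectivity are biased at coarse sampling.
#' This helper inverts the discretization per eigenvalue,
#' \eqn{\lambda_J = 1 + \log(1 + \Delta t\,(\mu - 1))/\Delta t} for each
#' eigenvalue \eqn{\mu} of the fitted matrix, recovering the
#' continuous-time connectivity spectrum exactly in the noiseless case
#' (valid while \eqn{|\mathrm{Im}\,\lambda\,\Delta t| < \pi}).
#'
#' @param fit a `network_fit` (or a bare connectivity matrix).
#' @param dt sampling interval of the data the fit was computed from, in
#'   the same time units as the fit.
#' @return complex vector of corrected connectivity eigenvalues.
#' @export
connectivity_spectrum <- function(fit, dt) {
  J <- if (inherits(fit, "network_fit")) fit$J else .check_connectivity(fit)
  mu <- eigen(J, only.values = TRUE)$values
  1 + log(1 + dt * (mu - 1)) / dt
}
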