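#' Population activity trajectory
#'
#' A trajectory stores the time course of population activity relative to
#' baseline as a time-by-dimensions matrix, together with its time stamps in
#' seconds. Time zero conventionally marks stimulus offset. Trajectories can
#' live in the raw neuron space or in a reduced principal-component space;
#' the `space_tag` records which.
#'
#' @param values numeric matrix, time points in rows, dimensions in columns.
#' @param times strictly increasing numeric vector of time stamps (seconds),
#'   one per row of `values`.
#' @param space_tag `"neuron"` or `"pc"`.
#' @param time_scale optional scalar carrying the data-time to model-time
#'   conversion (model time units per second); default 1.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(values, times, space_tag = c("neuron", "pc"),
                       time_scale = 1) {
  space_tag <- match.arg(space_tag)
  values <- as.matrix(values)
  times <- as.numeric(times)
  .assert(nrow(values) == length(times),
          "row count of `values` must equal length of `times`")
  .assert(length(times) == 0 || all(diff(times) > 0),
          "`times` must be strictly increasing")
  .assert(all(is.finite(values)), "trajectory values must be finite")
  structure(list(values = values, times = times, space_tag = space_tag,
                 time_scale = time_scale),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d time points x %d dimensions (%s space)>\n",
              nrow(x$values), ncol(x$values), x$space_tag))
  invisible(x)
}

.check_connectivity <- function(J) {
  J <- as.matrix(J)
  .assert(nrow(J) == ncol(J), "connectivity must be a square matrix")
  .assert(all(is.finite(J)), "connectivity must have finite entries")
  J
}

#' Propagate linear network dynamics from an initial state
#'
#' Integrates the autonomous linear rate dynamics
#' \eqn{\tau \dot r = -r + J r} (time constant fixed to one) from the initial
#' state `r0`, i.e. evaluates the propagator \eqn{\exp(t(J - I))} applied to
#' `r0` at each requested time. The computation diagonalizes \eqn{J - I}
#' once; if the eigendecomposition does not reconstruct the matrix to high
#' accuracy (defective or badly conditioned cases) it falls back to a dense
#' matrix exponential at each grid time. Grids need not be uniform.
#'
#' @param conn square connectivity matrix `J`.
#' @param r0 initial state vector, one entry per network unit.
#' @param times nonnegative, strictly increasing time grid starting at 0 (in
#'   units of the network time constant).
#' @param space_tag passed to [trajectory()].
#' @return a [trajectory()] whose row at time `t` is
#'   \eqn{\exp(t(J-I)) r_0}; the row at `t = 0` is `r0` itself.
#' @export
propagate <- function(conn, r0, times, space_tag = "neuron") {
  J <- .check_connectivity(conn)
  r0 <- as.numeric(r0)
  .assert(length(r0) == nrow(J),
          sprintf("length of r0 (%d) must match connectivity size (%d)",
                  length(r0), nrow(J)))
  times <- as.numeric(times)
  .assert(length(times) >= 1 && abs(times[1]) < 1e-12,
          "time grid must start at 0")
  A <- J - diag(nrow(J))
  vals <- .propagate_matrix(A, r0, times)
  vals[1, ] <- r0  # exact at t = 0
  trajectory(vals, times, space_tag = space_tag)
}

# Batch propagation of xdot = A x from columns of R0 (N x m), evaluated by
# exact matrix exponentials over each grid interval (one Pade expm per
# distinct step size, chained by the semigroup property). Returns an array
# length(times) x N x m.
.propagate_batch <- function(A, R0, times) {
  n <- nrow(A)
  m <- ncol(R0)
  out <- array(0, c(length(times), n, m))
  out[1, , ] <- R0
  cache <- list()
  X <- R0
  if (length(times) > 1) for (i in 2:length(times)) {
    dt <- times[i] - times[i - 1]
    key <- sprintf("%.15g", dt)
    if (is.null(cache[[key]])) {
      cache[[key]] <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
    }
    X <- cache[[key]] %*% X
    out[i, , ] <- X
  }
  out
}

# Core propagation of xdot = A x. Returns length(times) x N matrix.
.propagate_matrix <- function(A, r0, times) {
  matrix(.propagate_batch(A, matrix(r0, ncol = 1), times),
         length(times), nrow(A))
}

#' Distance of a trajectory from baseline
#'
#' Euclidean norm of the population state at every time point; the central
#' diagnostic for transient amplification (a norm that rises above its
#' initial value before decaying).
#'
#' @param traj a [trajectory()].
#' @return numeric vector of per-time norms.
#' @export
distance_from_baseline <- function(traj) {
  .assert(inherits(traj, "trajectory"), "expected a trajectory")
  .assert(nrow(traj$values) > 0, "empty trajectory")
  sqrt(rowSums(traj$values^2))
}

#' Peak of a transient response
#'
#' Finds the grid time at which the distance from baseline is maximal (ties
#' broken toward the earliest time) and returns that time together with the
#' population state there.
#'
#' @param traj a [trajectory()].
#' @return list with `t_peak` (seconds), `state` (numeric vector) and
#'   `index` (row index of the peak).
#' @export
peak_state <- function(traj) {
  d <- distance_from_baseline(traj)
  i <- which.max(d)
  list(t_peak = traj$times[i], state = traj$values[i, ], index = i)
}

#' Correlation between initial and peak state
#'
#' Cosine of the angle between the state at the first grid time and the
#' state at the peak of the distance from baseline. In amplified rotational
#' channels this correlation approaches zero when the initial condition lies
#' along the amplified input directions.
#'
#' @param traj a [trajectory()].
#' @return scalar in \[-1, 1\].
#' @export
initial_peak_correlation <- function(traj) {
  .assert(inherits(traj, "trajectory"), "expected a trajectory")
  r0 <- traj$values[1, ]
  pk <- peak_state(traj)$state
  n0 <- sqrt(sum(r0^2)); np <- sqrt(sum(pk^2))
  .assert(n0 > 0 && np > 0,
          "initial-peak correlation undefined for zero-norm states")
  sum(r0 * pk) / (n0 * np)
}
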