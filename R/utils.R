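# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Draw an N x k matrix with orthonormal columns (Haar-distributed given the
# RNG state).
.random_orthonormal <- function(n, k) {
  .assert(k <= n, "cannot draw more orthonormal columns than rows")
  qr.Q(qr(matrix(stats::rnorm(n * k), n, k)))[, seq_len(k), drop = FALSE]
}

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  .assert(nv > 0, "cannot normalize a zero vector")
  v / nv
}

# Largest eigenvalue of the symmetric part (J + J^T)/2.
.lambda_max_sym <- function(J) {
  max(eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

# Coefficient of determination of predictions against a reference, computed
# over all entries jointly (1 - SS_res / SS_tot about the reference column
# means).
.r2_score <- function(reference, prediction) {
  reference <- as.matrix(reference)
  prediction <- as.matrix(prediction)
  mu <- colMeans(reference)
  ss_tot <- sum(sweep(reference, 2, mu)^2)
  ss_res <- sum((reference - prediction)^2)
  if (ss_tot == 0) return(if (ss_res == 0) 1 else -Inf)
  1 - ss_res / ss_tot
}

# Derive a bounded substream seed from a master seed and a stage name, so
# that all pipeline randomness flows from a single integer.
.substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}
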