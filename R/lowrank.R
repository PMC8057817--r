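#' Low-rank connectivity factorization
#'
#' Represents a connectivity matrix \eqn{J = U V^\top} through its right
#' pattern matrix `U` (columns set the directions explored by the evoked
#' dynamics) and left pattern matrix `V` (unit-norm columns selecting the
#' initial states that engage each mode). The canonical factorization of an
#' arbitrary matrix uses the SVD, \eqn{J = \hat U S V^\top} with
#' \eqn{U = \hat U S}, so left patterns are orthonormal and right patterns
#' carry the mode amplitudes. The sign of each column of `V` is fixed so
#' that its largest-magnitude entry is positive.
#'
#' @param J square matrix to factorize, or `NULL` when `U`/`V` are given.
#' @param U,V explicit pattern matrices (V columns must be unit norm).
#' @param rank number of modes retained when factorizing `J`; defaults to
#'   the numerical rank (singular values above `tol`).
#' @param tol relative singular-value tolerance for the numerical rank.
#' @return object of class `low_rank_connectivity` with fields `U`, `V`,
#'   `rank`.
#' @export
low_rank_connectivity <- function(J = NULL, U = NULL, V = NULL, rank = NULL,
                                  tol = 1e-10) {
  if (!is.null(J)) {
    J <- .check_connectivity(J)
    sv <- svd(J)
    r <- rank %||% sum(sv$d > tol * max(sv$d, 1e-300))
    .assert(r >= 1, "matrix is numerically zero; no low-rank factorization")
    U <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r)
    V <- sv$v[, seq_len(r), drop = FALSE]
  } else {
    U <- as.matrix(U); V <- as.matrix(V)
    .assert(nrow(U) == nrow(V) && ncol(U) == ncol(V),
            "U and V must have matching shapes")
    cn <- sqrt(colSums(V^2))
    .assert(all(abs(cn - 1) < 1e-10), "columns of V must have unit norm")
    r <- ncol(U)
  }
  # deterministic sign convention: largest-|entry| of each V column positive
  for (k in seq_len(r)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  structure(list(U = U, V = V, rank = r), class = "low_rank_connectivity")
}

#' Dense matrix of a low-rank connectivity
#' @param lrc a [low_rank_connectivity()].
#' @return the N x N matrix `U V^T`.
#' @export
as_dense <- function(lrc) {
  .assert(inherits(lrc, "low_rank_connectivity"),
          "expected a low_rank_connectivity")
  tcrossprod(lrc$U, lrc$V)
}

#' Overlap matrix of a low-rank connectivity
#'
#' The matrix of scalar products between left and right connectivity
#' vectors, \eqn{V^\top U}. Its nonzero eigenvalues coincide with the
#' nonzero eigenvalues of the dense connectivity, so the R x R overlap
#' matrix fully determines the low-dimensional dynamics.
#'
#' @param lrc a [low_rank_connectivity()].
#' @return an R x R matrix.
#' @export
lr_overlap_matrix <- function(lrc) {
  .assert(inherits(lrc, "low_rank_connectivity"),
          "expected a low_rank_connectivity")
  crossprod(lrc$V, lrc$U)
}

#' Bank of rank-2 rotational channels
#'
#' A rotational channel is the rank-2 connectivity
#' \eqn{J_2 = \Delta_1 v^{(2)} v^{(1)\top} - \Delta_2 v^{(1)} v^{(2)\top}}
#' built on two orthonormal vectors; its nonzero eigenvalues are purely
#' imaginary, \eqn{\pm i\omega} with \eqn{\omega = \sqrt{\Delta_1\Delta_2}},
#' so each channel rotates activity between its two directions while overall
#' stability is guaranteed. A bank is a superposition of K mutually
#' orthogonal channels.
#'
#' @param delta1,delta2 positive scalars (recycled to `n_channels`).
#' @param basis N x 2K matrix whose columns are mutually orthonormal;
#'   columns `2k-1` and `2k` are \eqn{v^{(1;k)}} and \eqn{v^{(2;k)}}.
#' @param tol orthonormality tolerance.
#' @return object of class `rotational_channel_bank`.
#' @export
rotational_channel_bank <- function(delta1, delta2, basis, tol = 1e-8) {
  basis <- as.matrix(basis)
  .assert(ncol(basis) %% 2 == 0, "basis must have an even number of columns")
  K <- ncol(basis) / 2
  .assert(2 * K <= nrow(basis),
          "need ambient dimension at least twice the number of channels")
  delta1 <- rep_len(delta1, K); delta2 <- rep_len(delta2, K)
  .assert(all(delta1 >= 0) && all(delta2 >= 0), "deltas must be nonnegative")
  G <- crossprod(basis)
  off <- max(abs(G - diag(ncol(basis))))
  if (off > tol) {
    stop(sprintf(paste0("channel basis is not orthonormal: maximum Gram ",
                        "deviation %.2e exceeds tolerance %.2e"), off, tol),
         call. = FALSE)
  }
  degenerate <- delta1 == 0 | delta2 == 0
  if (any(degenerate)) {
    warning("bank contains degenerate (feedforward) channels with omega = 0")
  }
  structure(list(delta1 = delta1, delta2 = delta2, basis = basis,
                 n_channels = K, n = nrow(basis),
                 omega = sqrt(delta1 * delta2), degenerate = degenerate),
            class = "rotational_channel_bank")
}

#' Dense connectivity of a channel bank
#'
#' Sums the rank-2 blocks
#' \eqn{\Delta_1^{(k)} v^{(2;k)} v^{(1;k)\top} -
#'      \Delta_2^{(k)} v^{(1;k)} v^{(2;k)\top}} over channels.
#'
#' @param bank a [rotational_channel_bank()].
#' @return N x N connectivity matrix.
#' @export
build_connectivity <- function(bank) {
  .assert(inherits(bank, "rotational_channel_bank"),
          "expected a rotational_channel_bank")
  J <- matrix(0, bank$n, bank$n)
  for (k in seq_len(bank$n_channels)) {
    v1 <- bank$basis[, 2 * k - 1]; v2 <- bank$basis[, 2 * k]
    J <- J + bank$delta1[k] * tcrossprod(v2, v1) -
      bank$delta2[k] * tcrossprod(v1, v2)
  }
  J
}

#' Amplification criterion for a linear network
#'
#' A linear network \eqn{\dot r = (J - I) r} can transiently amplify some
#' initial condition if and only if the largest eigenvalue of the symmetric
#' part \eqn{J_S = (J + J^\top)/2} exceeds one; stability requires all
#' eigenvalues of `J` to have real part below one.
#'
#' @param conn square connectivity matrix.
#' @return list with `lambda_max_sym`, logical `amplified`, logical
#'   `stable`.
#' @export
amplification_criterion <- function(conn) {
  J <- .check_connectivity(conn)
  lms <- .lambda_max_sym(J)
  re_max <- max(Re(eigen(J, only.values = TRUE)$values))
  list(lambda_max_sym = lms, amplified = lms > 1, stable = re_max < 1)
}

#' Stability and amplification conditions for a unit-rank network
#'
#' For \eqn{J = u v^\top} with `v` unit norm, the only nonzero eigenvalue is
#' \eqn{\lambda = \lVert u\rVert \cos\theta} where \eqn{\theta} is the angle
#' between the patterns. The dynamics are stable iff
#' \eqn{\cos\theta < 1/\lVert u\rVert} and amplified iff
#' \eqn{\lVert u\rVert > 2/(\cos\theta + 1)}.
#'
#' @param u right connectivity vector.
#' @param v left connectivity vector (unit norm).
#' @return list with `lambda`, `cos_theta`, `stable`,
#'   `amplification_threshold` (critical norm of `u`; `NA` and flagged
#'   `threshold_defined = FALSE` at \eqn{\cos\theta = -1}) and `amplified`.
#' @export
unit_rank_conditions <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  .assert(length(u) == length(v), "u and v must have equal length")
  .assert(abs(sqrt(sum(v^2)) - 1) < 1e-10, "v must have unit norm")
  nu <- sqrt(sum(u^2))
  .assert(nu > 0, "u must be nonzero")
  ct <- sum(u * v) / nu
  lambda <- nu * ct
  defined <- ct > -1 + 1e-12
  thr <- if (defined) 2 / (ct + 1) else NA_real_
  list(lambda = lambda, cos_theta = ct, stable = ct < 1 / nu,
       amplification_threshold = thr, threshold_defined = defined,
       amplified = defined && nu > thr)
}

#' Decomposition of an initial state on a channel bank
#'
#' Expresses a state as
#' \eqn{r_0 = \sum_k (\alpha_1^{(k)} v^{(1;k)} + \alpha_2^{(k)} v^{(2;k)})
#'      + \beta z^{(\perp)}} with \eqn{z^{(\perp)}} orthogonal to all
#' channel planes.
#'
#' @param bank a [rotational_channel_bank()].
#' @param r0 state vector (length N), or `NULL` to build directly from
#'   coefficients.
#' @param alpha1,alpha2,beta,z_perp explicit coefficients when `r0` is not
#'   given.
#' @return object of class `initial_state_decomposition` with fields
#'   `alpha1`, `alpha2`, `beta`, `z_perp`.
#' @export
initial_state_decomposition <- function(bank, r0 = NULL, alpha1 = NULL,
                                        alpha2 = NULL, beta = 0,
                                        z_perp = NULL) {
  .assert(inherits(bank, "rotational_channel_bank"),
          "expected a rotational_channel_bank")
  K <- bank$n_channels
  if (!is.null(r0)) {
    r0 <- as.numeric(r0)
    .assert(length(r0) == bank$n, "state length must match bank dimension")
    co <- as.numeric(crossprod(bank$basis, r0))
    alpha1 <- co[seq(1, 2 * K, by = 2)]
    alpha2 <- co[seq(2, 2 * K, by = 2)]
    resid <- r0 - bank$basis %*% co
    beta <- sqrt(sum(resid^2))
    z_perp <- if (beta > 1e-12) as.numeric(resid) / beta else rep(0, bank$n)
  } else {
    alpha1 <- rep_len(alpha1 %||% 0, K)
    alpha2 <- rep_len(alpha2 %||% 0, K)
    if (is.null(z_perp)) {
      .assert(beta == 0, "z_perp must be supplied when beta != 0")
      z_perp <- rep(0, bank$n)
    } else {
      z_perp <- .unit(as.numeric(z_perp))
      .assert(max(abs(crossprod(bank$basis, z_perp))) < 1e-8,
              "z_perp must be orthogonal to all channel planes")
    }
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2, beta = beta,
                 z_perp = z_perp),
            class = "initial_state_decomposition")
}

#' Reconstruct the state of a decomposition
#' @param bank a [rotational_channel_bank()].
#' @param decomp an [initial_state_decomposition()].
#' @return state vector of length N.
#' @export
compose_state <- function(bank, decomp) {
  K <- bank$n_channels
  co <- numeric(2 * K)
  co[seq(1, 2 * K, by = 2)] <- decomp$alpha1
  co[seq(2, 2 * K, by = 2)] <- decomp$alpha2
  as.numeric(bank$basis %*% co + decomp$beta * decomp$z_perp)
}

#' Closed-form trajectory of a rotational channel bank
#'
#' Evaluates the analytic solution of the linear dynamics for a
#' superposition of orthogonal rank-2 rotational channels: within channel k,
#' \deqn{r_k(t) = e^{-t}[v^{(1;k)}(\alpha_1\cos\omega t -
#'   \sqrt{\Delta_2/\Delta_1}\,\alpha_2\sin\omega t) +
#'   v^{(2;k)}(\alpha_2\cos\omega t +
#'   \sqrt{\Delta_1/\Delta_2}\,\alpha_1\sin\omega t)]}
#' plus the decaying orthogonal component \eqn{e^{-t}\beta z^{(\perp)}}.
#' Degenerate channels (\eqn{\omega = 0}) fall back to matrix-exponential
#' propagation of their rank-2 block.
#'
#' @param bank a [rotational_channel_bank()].
#' @param decomp an [initial_state_decomposition()] consistent with `bank`.
#' @param times time grid starting at 0.
#' @return a [trajectory()].
#' @export
closed_form_trajectory <- function(bank, decomp, times) {
  .assert(inherits(bank, "rotational_channel_bank"),
          "expected a rotational_channel_bank")
  .assert(inherits(decomp, "initial_state_decomposition"),
          "expected an initial_state_decomposition")
  .assert(length(decomp$alpha1) == bank$n_channels,
          "decomposition inconsistent with bank")
  times <- as.numeric(times)
  .assert(abs(times[1]) < 1e-12, "time grid must start at 0")
  vals <- exp(-times) %o% (decomp$beta * decomp$z_perp)
  for (k in seq_len(bank$n_channels)) {
    v1 <- bank$basis[, 2 * k - 1]; v2 <- bank$basis[, 2 * k]
    a1 <- decomp$alpha1[k]; a2 <- decomp$alpha2[k]
    if (bank$degenerate[k]) {
      Jk <- bank$delta1[k] * tcrossprod(v2, v1) -
        bank$delta2[k] * tcrossprod(v1, v2)
      vals <- vals + propagate(Jk, a1 * v1 + a2 * v2, times)$values
      next
    }
    w <- bank$omega[k]
    g <- sqrt(bank$delta2[k] / bank$delta1[k])
    c1 <- a1 * cos(w * times) - g * a2 * sin(w * times)
    c2 <- a2 * cos(w * times) + (1 / g) * a1 * sin(w * times)
    vals <- vals + exp(-times) * (c1 %o% v1 + c2 %o% v2)
  }
  trajectory(vals, times)
}

#' Amplification condition on the initial state of a channel bank
#'
#' For a bank with peak time `t_star`, the response is amplified
#' (\eqn{\lVert r(t^*)\rVert > 1} for a unit-norm initial state) when
#' \deqn{\sum_k \sqrt{\Delta_1/\Delta_2}\,\alpha_1^{(k)2} +
#'       \sqrt{\Delta_2/\Delta_1}\,\alpha_2^{(k)2} + \beta^2 > e^{2t^*}.}
#' The returned margin is the left-hand side minus \eqn{e^{2t^*}}. When
#' `beta = 0` and the deltas are channel independent the bound on the
#' total \eqn{v^{(2)}} component,
#' \eqn{\sum_k \alpha_2^{(k)2} > (\sqrt{\Delta_2/\Delta_1}e^{2t^*} - 1) /
#' (\Delta_2^2/\Delta_1^2 - 1)}, is also reported.
#'
#' @param bank a [rotational_channel_bank()].
#' @param decomp an [initial_state_decomposition()].
#' @param t_star peak time; default: numerically computed peak time of the
#'   closed-form trajectory (exact in all parameter regimes, unlike the
#'   asymptotic \eqn{\omega t^* = \pi/2} rule).
#' @return list with `satisfied`, `margin`, `t_star`, and (when defined)
#'   `alpha2_sq_bound` with the observed `alpha2_sq_total`.
#' @export
initial_state_condition <- function(bank, decomp, t_star = NULL) {
  if (is.null(t_star)) {
    tmax <- if (all(bank$omega == 0)) 5 else pi / min(bank$omega[bank$omega > 0])
    grid <- seq(0, max(tmax, 1e-3), length.out = 2000)
    t_star <- peak_state(closed_form_trajectory(bank, decomp, grid))$t_peak
  }
  .assert(t_star >= 0, "t_star must be nonnegative")
  ratio1 <- sqrt(bank$delta1 / bank$delta2)
  ratio2 <- sqrt(bank$delta2 / bank$delta1)
  lhs <- sum(ratio1 * decomp$alpha1^2 + ratio2 * decomp$alpha2^2) +
    decomp$beta^2
  margin <- lhs - exp(2 * t_star)
  out <- list(satisfied = margin > 0, margin = margin, t_star = t_star)
  if (abs(decomp$beta) < 1e-12 &&
      length(unique(round(bank$delta1, 12))) == 1 &&
      length(unique(round(bank$delta2, 12))) == 1 &&
      bank$delta1[1] != bank$delta2[1]) {
    d1 <- bank$delta1[1]; d2 <- bank$delta2[1]
    out$alpha2_sq_bound <- (sqrt(d2 / d1) * exp(2 * t_star) - 1) /
      (d2^2 / d1^2 - 1)
    out$alpha2_sq_total <- sum(decomp$alpha2^2)
  }
  out
}

#' Nonzero eigenvalues of the symmetric part of a low-rank connectivity
#'
#' Computes the nonzero eigenvalues of \eqn{J_S = (UV^\top + VU^\top)/2}
#' through the implicit rank-2R condition: values \eqn{\lambda_S} solving
#' \eqn{\det[B(\lambda_S)B(\lambda_S)^\top - S^2] = 0} with
#' \eqn{B(\lambda_S) = U^\top V - 2\lambda_S I} and
#' \eqn{S^2 = \mathrm{diag}(\lVert u^{(r)}\rVert^2)}, i.e. by
#' eigendecomposing the equivalent 2R x 2R block matrix. Used as an
#' independent cross-check of the dense eigensolver.
#'
#' @param lrc a [low_rank_connectivity()].
#' @return numeric vector of the 2R nonzero eigenvalues of the symmetric
#'   part (descending).
#' @export
lowrank_sym_eigs <- function(lrc) {
  .assert(inherits(lrc, "low_rank_connectivity"),
          "expected a low_rank_connectivity")
  R <- lrc$rank
  # 2 lambda_S are the nonzero eigenvalues of [[V^T U, I], [S^2, U^T V]]
  VtU <- crossprod(lrc$V, lrc$U)
  S2 <- crossprod(lrc$U)  # equals diag(||u(r)||^2) in the canonical factorization
  M <- rbind(cbind(VtU, diag(R)), cbind(S2, t(VtU)))
  ev <- eigen(M, only.values = TRUE)$values
  sort(Re(ev) / 2, decreasing = TRUE)
}
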