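# Apply a matrix to one mode of a 3-d array: returns the array with
# dimension `mode` transformed by M (rows of M index the new coordinate).
.mode_multiply <- function(Z, M, mode) {
  d <- dim(Z)
  perm <- c(mode, setdiff(1:3, mode))
  Zm <- aperm(Z, perm)
  dm <- dim(Zm)
  Zm <- matrix(Zm, dm[1])
  out <- M %*% Zm
  out <- array(out, c(nrow(M), dm[2], dm[3]))
  aperm(out, order(perm))
}

# Marginal mean removal: iteratively subtract the per-slice means along
# each mode until all three marginal mean sums vanish.
.remove_marginal_means <- function(Z, tol = 1e-10, max_sweeps = 100) {
  Zb <- Z
  for (sweep_i in seq_len(max_sweeps)) {
    m1 <- apply(Zb, 1, mean); Zb <- sweep(Zb, 1, m1)
    m2 <- apply(Zb, 2, mean); Zb <- sweep(Zb, 2, m2)
    m3 <- apply(Zb, 3, mean); Zb <- sweep(Zb, 3, m3)
    err <- max(abs(apply(Zb, 1, mean)), abs(apply(Zb, 2, mean)),
               abs(apply(Zb, 3, mean)))
    if (err < tol * max(1, max(abs(Z)))) {
      return(list(Zbar = Zb, converged = TRUE, sweeps = sweep_i))
    }
  }
  warning("marginal mean removal did not converge")
  list(Zbar = Zb, converged = FALSE, sweeps = max_sweeps)
}

#' Marginal means and covariances of an activity tensor
#'
#' Decomposes a times x dimensions x stimuli tensor `Z` into a mean tensor
#' `M` (built by iterative marginal-mean removal, so that all three
#' marginal mean sums of the centered tensor vanish) and the marginal
#' covariances of the centered tensor across times (`sigma_t`), neural
#' dimensions (`sigma_k`) and stimuli (`sigma_c`).
#'
#' @param Z numeric array T x K x C.
#' @param tol convergence tolerance for mean removal (default 1e-10).
#' @param max_sweeps sweep cap (default 100).
#' @return object of class `marginal_stats` with fields `M`, `sigma_t`,
#'   `sigma_k`, `sigma_c`, `dim`, `total_ss`, `converged`.
#' @export
marginal_stats <- function(Z, tol = 1e-10, max_sweeps = 100) {
  Z <- as.array(Z)
  .assert(length(dim(Z)) == 3, "Z must be a 3-d array (T x K x C)")
  .assert(all(dim(Z) > 0), "empty tensor")
  rm <- .remove_marginal_means(Z, tol, max_sweeps)
  Zb <- rm$Zbar
  M <- Z - Zb
  d <- dim(Z)
  mat_t <- matrix(Zb, d[1])                         # T x (K*C)
  mat_k <- matrix(aperm(Zb, c(2, 1, 3)), d[2])      # K x (T*C)
  mat_c <- matrix(aperm(Zb, c(3, 1, 2)), d[3])      # C x (T*K)
  structure(list(M = M, sigma_t = tcrossprod(mat_t),
                 sigma_k = tcrossprod(mat_k),
                 sigma_c = tcrossprod(mat_c), dim = d,
                 total_ss = sum(Zb^2), converged = rm$converged),
            class = "marginal_stats")
}

#' Maximum-entropy-style surrogate tensors
#'
#' Generates Gaussian surrogate tensors whose marginal statistics match the
#' data: every surrogate has the data's mean tensor, and the marginal
#' covariances along the constrained axes equal the data's marginal
#' covariances in expectation. The noise has Kronecker-separable covariance
#' built from the eigendecompositions of the constrained marginal
#' covariances; unconstrained axes receive isotropic factors with trace
#' matched to the data, the maximum-entropy choice given no constraint.
#' Three families mirror increasing structure: `"T"` constrains only the
#' time covariance, `"TK"` time and dimension, `"TKC"` all three.
#'
#' @param stats a [marginal_stats()] object.
#' @param kind `"T"`, `"TK"` or `"TKC"`.
#' @param n number of surrogates.
#' @param seed RNG seed.
#' @return list of `n` arrays of the data's shape.
#' @export
generate_surrogates <- function(stats, kind = c("TKC", "TK", "T"), n,
                                seed = 1) {
  .assert(inherits(stats, "marginal_stats"), "expected marginal_stats")
  kind <- match.arg(kind)
  if (n == 0) return(list())
  d <- stats$dim
  ss <- stats$total_ss
  .assert(ss > 0, "tensor has no variance around its marginal means")
  constrained <- list(t = TRUE, k = kind %in% c("TK", "TKC"),
                      c = kind == "TKC")
  sig <- list(stats$sigma_t, stats$sigma_k, stats$sigma_c)
  Q <- vector("list", 3); lam <- vector("list", 3)
  for (i in 1:3) {
    if (constrained[[i]]) {
      e <- eigen(sig[[i]], symmetric = TRUE)
      .assert(min(e$values) > -1e-8 * max(e$values),
              "marginal covariance is not positive semidefinite")
      Q[[i]] <- e$vectors
      lam[[i]] <- pmax(e$values, 0) / ss^(2 / 3)
    } else {
      Q[[i]] <- diag(d[i])
      lam[[i]] <- rep(ss^(1 / 3) / d[i], d[i])
    }
  }
  set.seed(seed)
  lapply(seq_len(n), function(j) {
    G <- array(stats::rnorm(prod(d)), d)
    G <- sweep(G, 1, sqrt(lam[[1]]), `*`)
    G <- sweep(G, 2, sqrt(lam[[2]]), `*`)
    G <- sweep(G, 3, sqrt(lam[[3]]), `*`)
    noise <- .mode_multiply(G, Q[[1]], 1)
    noise <- .mode_multiply(noise, Q[[2]], 2)
    noise <- .mode_multiply(noise, Q[[3]], 3)
    stats$M + noise
  })
}

# Convert a T x K x C tensor to a named list of trajectories (K-dim),
# using the supplied times.
.tensor_to_responses <- function(Z, times) {
  d <- dim(Z)
  out <- lapply(seq_len(d[3]), function(c) {
    trajectory(matrix(Z[, , c], d[1], d[2]), times, space_tag = "pc")
  })
  names(out) <- paste0("stim", seq_len(d[3]))
  out
}

#' Compare network-model fit quality on real versus surrogate data
#'
#' Fits the network model (cross-validated ridge) to the real tensor and to
#' each surrogate, returning the CV goodness of fit per dataset. A fit that
#' is significantly better on the real data than on surrogates matched for
#' marginal covariances indicates dynamical structure beyond those
#' correlations.
#'
#' @param Z real tensor T x K x C (e.g. PC-space responses).
#' @param surrogates list of tensors from [generate_surrogates()], possibly
#'   of several kinds (pass a named list of lists to tag kinds).
#' @param times time stamps of the T axis.
#' @param lambda ridge penalty (default 1).
#' @param rank optional rank bound.
#' @param k_folds CV folds (default 10).
#' @return data frame with columns `dataset`, `kind`, `cv_r2`.
#' @export
surrogate_fit_comparison <- function(Z, surrogates, times, lambda = 1,
                                     rank = NULL, k_folds = 10) {
  score <- function(tensor) {
    des <- build_design(.tensor_to_responses(tensor, times), n_pc = NULL)
    crossval_r2(des, lambda, rank, k_folds)$mean_r2
  }
  if (length(surrogates) > 0 && is.list(surrogates[[1]]) &&
      !is.array(surrogates[[1]])) {
    kinds <- rep(names(surrogates),
                 vapply(surrogates, length, integer(1)))
    surrogates <- do.call(c, unname(surrogates))
  } else {
    kinds <- rep("surrogate", length(surrogates))
  }
  out <- data.frame(dataset = c("real", sprintf("surrogate%03d",
                                                seq_along(surrogates))),
                    kind = c("real", kinds),
                    cv_r2 = c(score(Z),
                              vapply(surrogates, score, numeric(1))))
  rownames(out) <- NULL
  out
}
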