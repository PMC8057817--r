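# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_fixture(name)
  }
  .fixture_cache[[name]]
}

# Random stable connectivity with a prescribed largest symmetric-part
# eigenvalue (used by amplification tests).
random_connectivity_with_sym <- function(n, lambda_sym, seed) {
  set.seed(seed)
  J <- matrix(rnorm(n^2), n) / sqrt(n)
  lms <- max(eigen((J + t(J)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values)
  J * lambda_sym / lms
}

# Best achievable initial growth rate of ||r|| over the unit sphere,
# estimated by random sampling followed by ascent refinement of the best
# candidate (power iteration on a positively shifted symmetric part).
sampled_max_growth <- function(J, n_samples = 10000, refine = TRUE) {
  n <- nrow(J)
  S <- (J + t(J)) / 2
  U <- matrix(rnorm(n * n_samples), n)
  U <- sweep(U, 2, sqrt(colSums(U^2)), `/`)
  g <- colSums(U * (S %*% U))
  best <- U[, which.max(g)]
  if (refine) {
    shift <- max(g) + 1
    for (i in 1:3000) {
      cand <- c(S %*% best) + shift * best
      best <- cand / sqrt(sum(cand^2))
    }
    max(max(g), sum(best * (S %*% best))) - 1
  } else max(g) - 1
}
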