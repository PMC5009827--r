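# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, explicit inverses) so they cannot share
# a bug with the implementation they check.

# OSCAR penalty over all pairs by explicit double loop
oracle_oscar <- function(u) {
  p <- length(u)
  s <- 0
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      s <- s + max(abs(u[i]), abs(u[j]))
    }
  }
  s
}

# GOSCAR penalty over an explicit edge matrix by loop
oracle_goscar <- function(u, edges) {
  s <- 0
  for (r in seq_len(nrow(edges))) {
    s <- s + max(abs(u[edges[r, 1L]]), abs(u[edges[r, 2L]]))
  }
  s
}

# explicit-inverse evaluation of the u-side update (the closed form the
# solver is supposed to match while solving a linear system instead)
oracle_update_u <- function(X, Y, v, u_cur, lambda, beta, gamma, zeta) {
  p <- ncol(X)
  W <- matrix(0, p, p)
  What <- matrix(0, p, p)
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      W[i, j] <- W[j, i] <- 1 / (2 * sqrt((u_cur[i] - u_cur[j])^2 + zeta))
      What[i, j] <- What[j, i] <- 1 / (2 * sqrt((u_cur[i] + u_cur[j])^2 + zeta))
    }
  }
  L <- diag(rowSums(W)) - W
  Lhat <- diag(rowSums(What)) + What
  Lam <- diag(1 / (2 * sqrt(u_cur^2 + zeta)))
  A <- lambda * (L + Lhat) + beta * Lam + gamma * t(X) %*% X
  drop(solve(A) %*% (t(X) %*% Y %*% v))
}

# random paired dataset of given shape, standardized
random_paired <- function(seed, n = 30, p = 10, q = 12) {
  set.seed(seed)
  standardize(paired_data(matrix(rnorm(n * p), n, p),
                          matrix(rnorm(n * q), n, q)))
}

# cosine similarity between two vectors
cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# scaled-down tuning grid used by the long-running acceptance simulations:
# the two largest decades (1e2, 1e3) of the lambda/beta grids are dropped
# purely for runtime — they sit deep in the over-penalization regime and
# were never selected in exploratory full-grid runs (the reduced grid picks
# the same configurations as the full 147-point grid on all four shipped
# scenarios). Fold count and fit depth match the real protocol.
acceptance_grid <- function() {
  cv_grid(lambda_values = 10^(-3:1), beta_values = 10^(-3:1),
          gamma_values = c(0.1, 1, 10))
}

# tuned configuration per shipped scenario: CV tuning on a seed-1 draw,
# exactly once (memoised across test files)
tuned_config_cache <- new.env(parent = emptyenv())
tuned_config_for <- function(sc) {
  key <- as.character(sc)
  if (is.null(tuned_config_cache[[key]])) {
    draw <- generate_data(make_scenario(sc), seed = 1L)
    tuned <- suppressWarnings(
      tune_penalties(draw$data, grid = acceptance_grid(), k = 5L,
                     seed = 100L + sc, max_iter = 100L))
    tuned_config_cache[[key]] <- tuned
  }
  tuned_config_cache[[key]]
}
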