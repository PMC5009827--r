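# Graph-OSCAR penalty and the reweighting matrices used by the alternating
# solver. The penalty on a loading vector u over edge set E is
#   sum_{(i,j) in E} max{|u_i|, |u_j|}
# which, via max{a,b} = (|a-b| + |a+b|)/2 for a,b >= 0, splits into a fused
# (difference) part and a "signless" (sum) part. Each part is handled by an
# iteratively reweighted quadratic: the difference part through a graph
# Laplacian L = D - W and the sum part through its signless analog
# Lhat = Dhat + What.

# p above which dense W/What matrices are refused; edge-wise assembly for
# larger problems is not needed at the scales this package targets.
.dense_cap <- 5000L

#' Graph-OSCAR penalty value
#'
#' Computes \eqn{\sum_{(i,j) \in E} \max(|u_i|, |u_j|)} over the edges of a
#' feature graph. On a complete graph this is the OSCAR penalty over all
#' feature pairs. The equivalent half-decomposition
#' \eqn{\frac12 \sum |u_i - u_j| + \frac12 \sum |u_i + u_j|} is available for
#' cross-checking via `form = "split"`.
#'
#' @param u numeric loading vector, length `graph$n_features`.
#' @param graph a [feature_graph()].
#' @param form `"max"` (default) or `"split"`; both compute the same value up
#'   to floating-point round-off.
#' @return a non-negative scalar.
#' @examples
#' goscar_norm(c(3, -1), feature_graph(2, rbind(c(1, 2)))) # 3
#' @export
goscar_norm <- function(u, graph, form = c("max", "split")) {
  stopifnot_graph(graph)
  form <- match.arg(form)
  if (length(u) != graph$n_features) {
    stop(sprintf("length(u) = %d but graph has %d features",
                 length(u), graph$n_features))
  }
  e <- graph$edges
  if (nrow(e) == 0L) return(0)
  ui <- u[e[, 1L]]
  uj <- u[e[, 2L]]
  if (form == "max") {
    sum(pmax(abs(ui), abs(uj)))
  } else {
    0.5 * sum(abs(ui - uj)) + 0.5 * sum(abs(ui + uj))
  }
}

# Build the derived matrices (row-sum diagonals, Laplacian and signless
# Laplacian) from dense symmetric W, What plus the element-wise diagonal.
make_goscar_weights <- function(W, What, lambda_diag, graph, zeta) {
  d <- rowSums(W)
  dhat <- rowSums(What)
  structure(list(
    W = W, W_hat = What,
    D = diag(d, nrow = length(d)), D_hat = diag(dhat, nrow = length(dhat)),
    L = diag(d, nrow = length(d)) - W,
    L_hat = diag(dhat, nrow = length(dhat)) + What,
    lambda_diag = lambda_diag,
    graph = graph, zeta = zeta
  ), class = "goscar_weights")
}

dense_weight_matrix <- function(graph, values) {
  p <- graph$n_features
  if (p > .dense_cap) {
    stop(sprintf("dense weight matrices limited to %d features", .dense_cap))
  }
  W <- matrix(0, p, p)
  e <- graph$edges
  if (nrow(e) > 0L) {
    W[e] <- values
    W[e[, c(2L, 1L), drop = FALSE]] <- values
  }
  W
}

#' Initial reweighting state
#'
#' All pair weights start at 1/2 (off the diagonal, on graph edges only);
#' the element-wise diagonal entries are initialized from the starting
#' loading `u0` through the same smoothed rule the solver uses at every
#' iteration, \eqn{\Lambda_{kk} = 1 / (2 \sqrt{u_k^2 + \zeta})}.
#'
#' @param graph a [feature_graph()].
#' @param u0 initial loading; defaults to a vector of ones.
#' @param zeta smoothing constant, a small positive number.
#' @return a `goscar_weights` object holding `W`, `W_hat`, the row-sum
#'   diagonals `D`, `D_hat`, the Laplacian `L = D - W`, the signless
#'   `L_hat = D_hat + W_hat`, and `lambda_diag`.
#' @export
init_weights <- function(graph, u0 = NULL, zeta = 1e-10) {
  stopifnot_graph(graph)
  check_zeta(zeta)
  p <- graph$n_features
  if (is.null(u0)) u0 <- rep(1, p)
  if (length(u0) != p) stop("length(u0) must equal graph$n_features")
  W <- dense_weight_matrix(graph, rep(0.5, nrow(graph$edges)))
  lam <- 1 / (2 * sqrt(u0^2 + zeta))
  make_goscar_weights(W, W, lam, graph, zeta)
}

#' Recompute reweighting matrices from the current loading
#'
#' The solver's half-quadratic surrogate replaces each absolute value
#' \eqn{|x|} by \eqn{\sqrt{x^2 + \zeta}}; its quadratic majorizer carries the
#' weights
#' \eqn{w_{ij} = 1/(2\sqrt{(u_i-u_j)^2+\zeta})},
#' \eqn{\hat w_{ij} = 1/(2\sqrt{(u_i+u_j)^2+\zeta})} and
#' \eqn{\Lambda_{kk} = 1/(2\sqrt{u_k^2+\zeta})}. Smoothing is applied
#' uniformly to every weight (not only at exact zeros) so the surrogate is
#' differentiable everywhere; as \eqn{\zeta \to 0} it recovers the exact
#' penalty.
#'
#' @inheritParams init_weights
#' @param u current loading vector.
#' @return a `goscar_weights` object; all entries finite, `L` and `L_hat`
#'   positive semidefinite.
#' @export
reweight <- function(u, graph, zeta = 1e-10) {
  stopifnot_graph(graph)
  check_zeta(zeta)
  if (length(u) != graph$n_features) {
    stop("length(u) must equal graph$n_features")
  }
  e <- graph$edges
  ui <- u[e[, 1L]]
  uj <- u[e[, 2L]]
  w <- 1 / (2 * sqrt((ui - uj)^2 + zeta))
  what <- 1 / (2 * sqrt((ui + uj)^2 + zeta))
  W <- dense_weight_matrix(graph, w)
  What <- dense_weight_matrix(graph, what)
  lam <- 1 / (2 * sqrt(u^2 + zeta))
  make_goscar_weights(W, What, lam, graph, zeta)
}

check_zeta <- function(zeta) {
  if (length(zeta) != 1L || !is.finite(zeta) || zeta <= 0) {
    stop("`zeta` must be a single positive number")
  }
  invisible(zeta)
}

#' @export
print.goscar_weights <- function(x, ...) {
  cat(sprintf("goscar_weights: %d features, %d edges, zeta = %g\n",
              x$graph$n_features, nrow(x$graph$edges), x$zeta))
  invisible(x)
}
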