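# The alternating GOSC-SCCA solver. Each half-step solves a Laplacian-
# regularized positive (semi)definite linear system obtained by reweighting
# the graph-OSCAR and l1 terms around the current iterate:
#   (lambda (L + Lhat) + beta Lambda + gamma M'M) w = M'N other
# with (M, N) = (X, Y) for the u side and (Y, X) for the v side. Monotone
# decrease of the objective follows from the half-quadratic majorization.

#' Solver configuration
#'
#' Bundles the six penalty weights of the Lagrangian objective with the
#' numerical knobs of the alternating solver.
#'
#' @param lambda1,lambda2 graph-OSCAR penalty weights for u and v (>= 0).
#' @param beta1,beta2 l1 penalty weights for u and v (>= 0). They enter the
#'   objective as beta/2 * ||.||_1.
#' @param gamma1,gamma2 weights of the quadratic variate-norm terms
#'   gamma/2 * ||Xu||^2 and gamma/2 * ||Yv||^2; must be > 0 for the linear
#'   systems to be well-posed.
#' @param zeta smoothing constant for the reweighting rules (> 0). Default
#'   1e-10.
#' @param tau convergence tolerance on the max absolute change of each
#'   loading between iterations. Default 1e-5.
#' @param max_iter iteration cap. Default 100.
#' @param init `"ones"` (deterministic, default) or `"random"` (seeded).
#' @param seed integer seed used when `init = "random"`.
#' @param rescale `"per_iteration"` (default; each updated loading is scaled
#'   so its variate has unit norm, stabilizing scale across iterations) or
#'   `"final"` (raw updates throughout, loadings scaled once at the end;
#'   this is the mode under which the objective trace is provably monotone).
#' @return an object of class `scca_config`.
#' @export
scca_config <- function(lambda1 = 1, lambda2 = 1, beta1 = 1, beta2 = 1,
                        gamma1 = 1, gamma2 = 1, zeta = 1e-10, tau = 1e-5,
                        max_iter = 100L, init = c("ones", "random"),
                        seed = 1L, rescale = c("per_iteration", "final")) {
  init <- match.arg(init)
  rescale <- match.arg(rescale)
  pen <- c(lambda1 = lambda1, lambda2 = lambda2, beta1 = beta1,
           beta2 = beta2, gamma1 = gamma1, gamma2 = gamma2)
  if (any(!is.finite(pen)) || any(pen < 0)) {
    stop("penalty weights must be finite and non-negative")
  }
  if (gamma1 <= 0 || gamma2 <= 0) {
    stop("gamma1 and gamma2 must be strictly positive")
  }
  check_zeta(zeta)
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive")
  if (!is.finite(max_iter) || max_iter < 1) stop("`max_iter` must be >= 1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 beta1 = beta1, beta2 = beta2,
                 gamma1 = gamma1, gamma2 = gamma2,
                 zeta = zeta, tau = tau, max_iter = as.integer(max_iter),
                 init = init, seed = as.integer(seed), rescale = rescale),
            class = "scca_config")
}

#' @export
print.scca_config <- function(x, ...) {
  cat(sprintf(paste0("scca_config: lambda = (%g, %g), beta = (%g, %g), ",
                     "gamma = (%g, %g)\n  zeta = %g, tau = %g, ",
                     "max_iter = %d, init = %s, rescale = %s\n"),
              x$lambda1, x$lambda2, x$beta1, x$beta2, x$gamma1, x$gamma2,
              x$zeta, x$tau, x$max_iter, x$init, x$rescale))
  invisible(x)
}

default_graphs <- function(data, graphs = NULL) {
  if (is.null(graphs)) {
    graphs <- list(u = NULL, v = NULL)
  }
  if (is.null(graphs$u)) graphs$u <- complete_graph(ncol(data$X))
  if (is.null(graphs$v)) graphs$v <- complete_graph(ncol(data$Y))
  stopifnot_graph(graphs$u)
  stopifnot_graph(graphs$v)
  if (graphs$u$n_features != ncol(data$X)) {
    stop("u-side graph size does not match ncol(X)")
  }
  if (graphs$v$n_features != ncol(data$Y)) {
    stop("v-side graph size does not match ncol(Y)")
  }
  graphs
}

#' Lagrangian objective of GOSC-SCCA
#'
#' Evaluates
#' \deqn{-u' X' Y v + \lambda_1 \|u\|_{GOSCAR} + \lambda_2 \|v\|_{GOSCAR}
#'   + \frac{\beta_1}{2}\|u\|_1 + \frac{\beta_2}{2}\|v\|_1
#'   + \frac{\gamma_1}{2}\|Xu\|_2^2 + \frac{\gamma_2}{2}\|Yv\|_2^2.}
#' With `smoothed = TRUE` every absolute value inside the penalties is
#' replaced by \eqn{\sqrt{x^2 + \zeta}}, giving the surrogate the solver
#' actually minimizes (identical to the exact value as \eqn{\zeta \to 0}).
#'
#' @param u,v loading vectors.
#' @param data standardized [paired_data()].
#' @param config an [scca_config()].
#' @param graphs list with `feature_graph` elements `u` and `v`; `NULL`
#'   means complete graphs on both sides.
#' @param smoothed evaluate the zeta-smoothed surrogate instead of the exact
#'   objective.
#' @return scalar objective value.
#' @export
scca_objective <- function(u, v, data, config, graphs = NULL,
                           smoothed = FALSE) {
  stopifnot(inherits(data, "paired_data"), inherits(config, "scca_config"))
  graphs <- default_graphs(data, graphs)
  if (length(u) != ncol(data$X) || length(v) != ncol(data$Y)) {
    stop("loading lengths must match ncol(X) and ncol(Y)")
  }
  Xu <- data$X %*% u
  Yv <- data$Y %*% v
  if (smoothed) {
    z <- config$zeta
    sabs <- function(x) sqrt(x^2 + z)
    pen_goscar <- function(w, g) {
      e <- g$edges
      if (nrow(e) == 0L) return(0)
      0.5 * sum(sabs(w[e[, 1L]] - w[e[, 2L]])) +
        0.5 * sum(sabs(w[e[, 1L]] + w[e[, 2L]]))
    }
    gu <- pen_goscar(u, graphs$u)
    gv <- pen_goscar(v, graphs$v)
    l1u <- sum(sabs(u))
    l1v <- sum(sabs(v))
  } else {
    gu <- goscar_norm(u, graphs$u)
    gv <- goscar_norm(v, graphs$v)
    l1u <- sum(abs(u))
    l1v <- sum(abs(v))
  }
  -sum(Xu * Yv) +
    config$lambda1 * gu + config$lambda2 * gv +
    config$beta1 / 2 * l1u + config$beta2 / 2 * l1v +
    config$gamma1 / 2 * sum(Xu^2) + config$gamma2 / 2 * sum(Yv^2)
}

# Symmetric positive (semi)definite solve with escalating diagonal jitter.
# Cholesky first; on failure add eps * mean(diag) * I with eps escalating
# 1e-10 -> 1e-8 -> 1e-6, then give up.
solve_spd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (!is.null(ch)) {
    return(list(x = backsolve(ch, forwardsolve(t(ch), b)), jitter = 0))
  }
  md <- mean(diag(A))
  if (!is.finite(md) || md <= 0) md <- 1
  for (eps in c(1e-10, 1e-8, 1e-6)) {
    Aj <- A + diag(eps * md, nrow(A))
    ch <- tryCatch(chol(Aj), error = function(e) NULL)
    if (!is.null(ch)) {
      warning(sprintf("system matrix not positive definite; %g jitter added",
                      eps * md), call. = FALSE)
      return(list(x = backsolve(ch, forwardsolve(t(ch), b)), jitter = eps * md))
    }
  }
  stop(sprintf(paste0("linear system is singular even after jitter ",
                      "escalation (dim %d, mean diag %g)"), nrow(A), md))
}

#' One half-step of the alternating solver
#'
#' Solves the reweighted linear system for one side given the other side's
#' current loading. The weights must have been rebuilt (via [reweight()])
#' from the current value of the side being updated.
#'
#' @param side `"u"` or `"v"`.
#' @param data standardized [paired_data()].
#' @param other_loading current loading of the opposite side (v when
#'   updating u, u when updating v).
#' @param weights a `goscar_weights` object for this side's graph.
#' @param config an [scca_config()].
#' @return the updated loading vector.
#' @export
update_loading <- function(side = c("u", "v"), data, other_loading, weights,
                           config) {
  side <- match.arg(side)
  stopifnot(inherits(data, "paired_data"), inherits(config, "scca_config"),
            inherits(weights, "goscar_weights"))
  if (side == "u") {
    M <- data$X; N <- data$Y
    lambda <- config$lambda1; beta <- config$beta1; gamma <- config$gamma1
  } else {
    M <- data$Y; N <- data$X
    lambda <- config$lambda2; beta <- config$beta2; gamma <- config$gamma2
  }
  if (ncol(M) != weights$graph$n_features) {
    stop("weights graph size does not match the side being updated")
  }
  if (length(other_loading) != ncol(N)) {
    stop("other_loading length does not match the opposite side")
  }
  A <- lambda * (weights$L + weights$L_hat) +
    diag(beta * weights$lambda_diag, ncol(M)) +
    gamma * crossprod(M)
  b <- crossprod(M, N %*% other_loading)
  sol <- solve_spd(A, b)
  drop(sol$x)
}

scale_to_unit_variate <- function(w, M) {
  nrm <- sqrt(sum((M %*% w)^2))
  if (nrm > 1e-12) w / nrm else w
}

init_loading <- function(p, M, init, seed, offset = 0L) {
  if (init == "ones") {
    w <- rep(1, p)
  } else {
    set.seed(seed + offset)
    w <- stats::rnorm(p)
  }
  scale_to_unit_variate(w, M)
}

#' Fit GOSC-SCCA
#'
#' Alternates reweighting and linear-system updates for u and v until the
#' maximum absolute change of both loadings between successive iterations
#' falls below `config$tau`, or `config$max_iter` is reached. The objective
#' is recorded after every full iteration; the reported loadings are rescaled
#' so that the canonical variates Xu and Yv have unit norm, and the training
#' correlation cor(Xu, Yv) is attached.
#'
#' @param data a [paired_data()]; standardized internally if not already.
#' @param graphs optional list with `feature_graph` elements `u` and `v`;
#'   `NULL` gives complete graphs (group-pursuit mode).
#' @param config an [scca_config()].
#' @param u0,v0 optional initial loadings (override `config$init`).
#' @return an object of class `scca_fit` with elements `u`, `v`,
#'   `objective_trace` (exact objective per iteration),
#'   `objective_trace_smoothed` (the zeta-smoothed surrogate, monotone under
#'   `rescale = "final"`), `n_iter`, `converged`, `train_correlation`,
#'   `config`, and feature names.
#' @export
gosc_scca <- function(data, graphs = NULL, config = scca_config(),
                      u0 = NULL, v0 = NULL) {
  stopifnot(inherits(data, "paired_data"), inherits(config, "scca_config"))
  if (!data$standardized) data <- standardize(data)
  graphs <- default_graphs(data, graphs)
  X <- data$X; Y <- data$Y
  p <- ncol(X); q <- ncol(Y)
  u <- if (is.null(u0)) init_loading(p, X, config$init, config$seed, 0L) else
    as.numeric(u0)
  v <- if (is.null(v0)) init_loading(q, Y, config$init, config$seed, 1L) else
    as.numeric(v0)
  if (length(u) != p || length(v) != q) {
    stop("initial loadings have the wrong length")
  }
  per_iter <- identical(config$rescale, "per_iteration")
  trace_exact <- numeric(0)
  trace_smooth <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  for (it in seq_len(config$max_iter)) {
    u_prev <- u; v_prev <- v
    wu <- reweight(u, graphs$u, config$zeta)
    u <- update_loading("u", data, v, wu, config)
    if (per_iter) u <- scale_to_unit_variate(u, X)
    wv <- reweight(v, graphs$v, config$zeta)
    v <- update_loading("v", data, u, wv, config)
    if (per_iter) v <- scale_to_unit_variate(v, Y)
    obj <- scca_objective(u, v, data, config, graphs)
    if (!is.finite(obj)) {
      stop("objective became non-finite; check penalties and data scaling")
    }
    trace_exact <- c(trace_exact, obj)
    trace_smooth <- c(trace_smooth,
                      scca_objective(u, v, data, config, graphs,
                                     smoothed = TRUE))
    n_iter <- it
    if (max(abs(u - u_prev)) <= config$tau &&
        max(abs(v - v_prev)) <= config$tau) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("no convergence after %d iterations (tau = %g)",
                    config$max_iter, config$tau), call. = FALSE)
  }
  u_out <- scale_to_unit_variate(u, X)
  v_out <- scale_to_unit_variate(v, Y)
  fit <- structure(list(
    u = stats::setNames(u_out, data$x_features),
    v = stats::setNames(v_out, data$y_features),
    u_raw = u, v_raw = v,
    objective_trace = trace_exact,
    objective_trace_smoothed = trace_smooth,
    n_iter = n_iter, converged = converged,
    train_correlation = canonical_correlation(u_out, v_out, X, Y),
    config = config
  ), class = "scca_fit")
  fit
}

#' @export
print.scca_fit <- function(x, ...) {
  cat(sprintf(paste0("scca_fit: %d iterations, converged = %s\n",
                     "  train correlation = %.4f, final objective = %.6g\n",
                     "  nonzero |loading| > 1e-6: u %d/%d, v %d/%d\n"),
              x$n_iter, x$converged, x$train_correlation,
              utils::tail(x$objective_trace, 1L),
              sum(abs(x$u) > 1e-6), length(x$u),
              sum(abs(x$v) > 1e-6), length(x$v)))
  invisible(x)
}

#' Canonical correlation of a loading pair
#'
#' Pearson correlation between the projected variates `X_eval %*% u` and
#' `Y_eval %*% v`. Evaluation matrices must be standardized with the
#' statistics of the training data. Following the convention that a failed
#' estimate is reported rather than raised, the function returns `NaN`
#' (with attribute `failure` describing why) when a loading is all zero or a
#' projected variate has zero variance.
#'
#' @param u,v loading vectors.
#' @param X_eval,Y_eval evaluation matrices (n x p, n x q).
#' @return correlation in \[-1, 1\], or `NaN` on failure.
#' @export
canonical_correlation <- function(u, v, X_eval, Y_eval) {
  X_eval <- as.matrix(X_eval); Y_eval <- as.matrix(Y_eval)
  if (length(u) != ncol(X_eval) || length(v) != ncol(Y_eval)) {
    stop("loading lengths must match the evaluation matrices")
  }
  if (nrow(X_eval) != nrow(Y_eval)) stop("evaluation matrices must be aligned")
  fail <- function(reason) structure(NaN, failure = reason)
  if (all(u == 0) || all(v == 0)) return(fail("all-zero loading"))
  a <- drop(X_eval %*% u)
  b <- drop(Y_eval %*% v)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(fail("zero-variance projection"))
  }
  stats::cor(a, b)
}
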