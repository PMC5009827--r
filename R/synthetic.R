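# Synthetic paired data with known ground truth. The generator follows a
# latent-factor design: a latent score z_i ~ N(0, 1) per sample, row means
# z_i * u (resp. z_i * v), and noise drawn from a covariance kernel
# (Sigma)_jk = exp(-|u_j - u_k|) so that features sharing a true loading are
# strongly correlated. To exercise the sign-directionality problem, the signs
# of half of the first nonzero group are flipped in both the loadings and
# the corresponding data columns, which leaves the canonical variate X u
# unchanged while making naive sign-of-correlation heuristics fail.

#' Specify one block of equal-valued true loadings
#' @param indices feature indices of the block (1-based).
#' @param value the shared nonzero loading value.
#' @return list usable inside `u_groups`/`v_groups` of [make_scenario()].
#' @export
group_spec <- function(indices, value) {
  list(indices = as.integer(indices), value = as.numeric(value))
}

loading_from_groups <- function(p, groups, what) {
  w <- numeric(p)
  seen <- integer(0)
  if (length(groups) == 0L) {
    stop(sprintf("%s must have at least one nonzero group", what))
  }
  for (g in groups) {
    idx <- g$indices
    if (any(idx < 1L | idx > p)) {
      stop(sprintf("%s group indices out of range [1, %d]", what, p))
    }
    if (any(idx %in% seen)) {
      stop(sprintf("%s groups overlap", what))
    }
    if (length(g$value) != 1L || !is.finite(g$value) || g$value == 0) {
      stop(sprintf("%s group values must be single nonzero numbers", what))
    }
    w[idx] <- g$value
    seen <- c(seen, idx)
  }
  w
}

swap_indices <- function(groups, swap_fraction) {
  first <- groups[[which.min(vapply(groups, function(g) min(g$indices),
                                    integer(1)))]]
  k <- floor(length(first$indices) * swap_fraction)
  if (k == 0L) return(integer(0))
  sort(first$indices)[seq_len(k)]
}

#' Define a synthetic ground-truth scenario
#'
#' Either selects one of the four shipped default scenarios (all with n = 80,
#' p = 100, q = 120 but distinct group layouts and signal scales; scenario 4
#' is the high-SNR one), or builds a custom scenario from explicit group
#' specifications. The true loadings are piecewise constant: each group is a
#' block of feature indices sharing one nonzero value; features outside all
#' groups have loading zero. A fraction (default one half) of the first
#' nonzero group on each side has its sign flipped, in the loading and the
#' corresponding data columns alike; the stored `u_true`/`v_true` are the
#' post-swap truths a correct method should recover.
#'
#' The shipped layouts emulate the kind of block-sparse truths used in the
#' simulation literature; they are this package's own choices, not a
#' replication of any published (graphically shown) pattern.
#'
#' @param scenario integer 1-4 selecting a shipped default, or `NULL` to
#'   build a custom scenario.
#' @param n,p,q dimensions (custom scenarios).
#' @param u_groups,v_groups lists of `list(indices =, value =)` blocks
#'   (custom scenarios); blocks must be disjoint and values nonzero.
#' @param swap_fraction fraction of the first nonzero group whose signs are
#'   flipped; `floor(group size * swap_fraction)` features are swapped.
#' @return an object of class `synthetic_scenario`.
#' @export
make_scenario <- function(scenario = NULL, n = 80, p = 100, q = 120,
                          u_groups = NULL, v_groups = NULL,
                          swap_fraction = 0.5) {
  if (!is.null(scenario)) {
    scenario <- as.integer(scenario)
    defaults <- list(
      `1` = list(
        u = list(group_spec(1:15, 1.0), group_spec(41:55, 1.5)),
        v = list(group_spec(1:20, 1.0), group_spec(61:75, -1.2))
      ),
      `2` = list(
        u = list(group_spec(1:10, 0.8), group_spec(31:40, -0.8),
                 group_spec(61:70, 0.8)),
        v = list(group_spec(1:12, 0.7), group_spec(41:52, 0.9),
                 group_spec(81:92, -0.7))
      ),
      `3` = list(
        u = list(group_spec(1:25, 1.2)),
        v = list(group_spec(1:30, 1.0), group_spec(71:90, -0.6))
      ),
      `4` = list(
        u = list(group_spec(1:15, 2.0), group_spec(51:65, -2.0)),
        v = list(group_spec(1:18, 2.0), group_spec(61:78, 2.0))
      )
    )
    if (is.na(scenario) || scenario < 1L || scenario > 4L) {
      stop("`scenario` must be 1, 2, 3 or 4")
    }
    sel <- defaults[[scenario]]
    u_groups <- sel$u
    v_groups <- sel$v
    n <- 80; p <- 100; q <- 120
  }
  if (swap_fraction < 0 || swap_fraction > 1) {
    stop("`swap_fraction` must lie in [0, 1]")
  }
  u_pre <- loading_from_groups(p, u_groups, "u")
  v_pre <- loading_from_groups(q, v_groups, "v")
  u_swap <- swap_indices(u_groups, swap_fraction)
  v_swap <- swap_indices(v_groups, swap_fraction)
  u_true <- u_pre; u_true[u_swap] <- -u_true[u_swap]
  v_true <- v_pre; v_true[v_swap] <- -v_true[v_swap]
  structure(list(
    scenario = scenario, n = as.integer(n), p = as.integer(p),
    q = as.integer(q),
    u_groups = u_groups, v_groups = v_groups,
    swap_fraction = swap_fraction,
    u_swap_idx = u_swap, v_swap_idx = v_swap,
    u_pre = u_pre, v_pre = v_pre,
    u_true = u_true, v_true = v_true
  ), class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scenario%s: n = %d, p = %d, q = %d\n",
                     "  nonzero: u %d (%d sign-swapped), v %d (%d sign-swapped)\n"),
              if (is.null(x$scenario)) "" else paste0(" ", x$scenario),
              x$n, x$p, x$q,
              sum(x$u_true != 0), length(x$u_swap_idx),
              sum(x$v_true != 0), length(x$v_swap_idx)))
  invisible(x)
}

# Symmetric square-root factor R (so that crossprod-style G %*% R has
# covariance S). Cholesky when S is positive definite; eigen fallback for
# the singular case (identical loadings give exactly unit correlation).
cov_factor <- function(S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) return(R)
  ed <- eigen(S, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    stop("covariance kernel is not positive semidefinite")
  }
  diag(sqrt(pmax(ed$values, 0))) %*% t(ed$vectors)
}

exp_abs_kernel <- function(w) {
  S <- exp(-abs(outer(w, w, "-")))
  S
}

#' Draw a synthetic paired dataset
#'
#' Samples a latent vector z ~ N(0, I_n), then rows
#' `X[i, ] ~ N(z_i * u, Sigma_x)` with `(Sigma_x)_jk = exp(-|u_j - u_k|)`
#' (pre-swap u; same construction for Y with v), and finally applies the
#' sign swap to the selected loadings and the matching data columns on both
#' sides. Because loading and column signs flip together, `X %*% u` is
#' bit-identical before and after the swap. Fully reproducible for a fixed
#' seed.
#'
#' @param scenario a [make_scenario()] object.
#' @param seed integer seed.
#' @return an object of class `synthetic_draw` with elements `data`
#'   (unstandardized [paired_data()]), `z` (latent scores) and `scenario`.
#' @export
generate_data <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(as.integer(seed))
  n <- scenario$n; p <- scenario$p; q <- scenario$q
  z <- stats::rnorm(n)
  Rx <- cov_factor(exp_abs_kernel(scenario$u_pre))
  Ry <- cov_factor(exp_abs_kernel(scenario$v_pre))
  X <- tcrossprod(z, scenario$u_pre) +
    matrix(stats::rnorm(n * p), n, p) %*% Rx
  Y <- tcrossprod(z, scenario$v_pre) +
    matrix(stats::rnorm(n * q), n, q) %*% Ry
  X[, scenario$u_swap_idx] <- -X[, scenario$u_swap_idx]
  Y[, scenario$v_swap_idx] <- -Y[, scenario$v_swap_idx]
  structure(list(
    data = paired_data(X, Y,
                       sample_ids = paste0("s", seq_len(n)),
                       x_features = paste0("x", seq_len(p)),
                       y_features = paste0("y", seq_len(q))),
    z = z, scenario = scenario, seed = as.integer(seed)
  ), class = "synthetic_draw")
}

#' @export
print.synthetic_draw <- function(x, ...) {
  cat(sprintf("synthetic_draw: seed %d of\n", x$seed))
  print(x$scenario)
  invisible(x)
}
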