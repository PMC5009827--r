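# Nested cross-validation and method comparison. The outer folds estimate
# generalization; hyperparameters are tuned by inner cross-validation on the
# FIRST outer training set only and then reused for every remaining outer
# fold (a time-saving protocol). Standardization statistics are always
# computed on training rows and applied to held-out rows, never the reverse.

#' Hyperparameter grid
#'
#' Default grids follow common practice for this model family: lambda and
#' beta from seven decades 1e-3..1e3 and gamma from the small set
#' \{0.1, 1, 10\} (the fit is not very sensitive to gamma). With
#' `coupling = "tied"` (default) the two sides share parameters
#' (lambda1 = lambda2, beta1 = beta2, gamma1 = gamma2), giving
#' 7 x 7 x 3 = 147 candidates; `"free"` crosses all six axes.
#'
#' @param lambda_values,beta_values,gamma_values positive candidate values;
#'   sorted ascending internally.
#' @param coupling `"tied"` or `"free"`.
#' @return an object of class `cv_grid`.
#' @export
cv_grid <- function(lambda_values = 10^(-3:3), beta_values = 10^(-3:3),
                    gamma_values = c(0.1, 1, 10),
                    coupling = c("tied", "free")) {
  coupling <- match.arg(coupling)
  chk <- function(v, nm) {
    if (length(v) < 1L || any(!is.finite(v)) || any(v <= 0)) {
      stop(sprintf("`%s` must be positive and finite", nm))
    }
    sort(unique(as.numeric(v)))
  }
  structure(list(lambda_values = chk(lambda_values, "lambda_values"),
                 beta_values = chk(beta_values, "beta_values"),
                 gamma_values = chk(gamma_values, "gamma_values"),
                 coupling = coupling),
            class = "cv_grid")
}

#' Enumerate a hyperparameter grid
#'
#' Deterministic enumeration: all axes ascending, lambda-major (lambda varies
#' slowest, gamma fastest). Under tied coupling each row carries one lambda,
#' beta and gamma shared by both sides.
#'
#' @param grid a [cv_grid()].
#' @return a data.frame with columns lambda1, lambda2, beta1, beta2, gamma1,
#'   gamma2, one row per candidate configuration.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "cv_grid"))
  if (grid$coupling == "tied") {
    g <- expand.grid(gamma = grid$gamma_values, beta = grid$beta_values,
                     lambda = grid$lambda_values, KEEP.OUT.ATTRS = FALSE)
    data.frame(lambda1 = g$lambda, lambda2 = g$lambda,
               beta1 = g$beta, beta2 = g$beta,
               gamma1 = g$gamma, gamma2 = g$gamma)
  } else {
    g <- expand.grid(gamma2 = grid$gamma_values, gamma1 = grid$gamma_values,
                     beta2 = grid$beta_values, beta1 = grid$beta_values,
                     lambda2 = grid$lambda_values,
                     lambda1 = grid$lambda_values, KEEP.OUT.ATTRS = FALSE)
    g[, c("lambda1", "lambda2", "beta1", "beta2", "gamma1", "gamma2")]
  }
}

make_folds <- function(n, k, seed) {
  if (n < 2L * k) stop(sprintf("need n >= 2k samples (n = %d, k = %d)", n, k))
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

subset_paired <- function(data, rows) {
  paired_data(data$X[rows, , drop = FALSE], data$Y[rows, , drop = FALSE],
              sample_ids = data$sample_ids[rows],
              x_features = data$x_features, y_features = data$y_features)
}

config_with <- function(base, row) {
  scca_config(lambda1 = row$lambda1, lambda2 = row$lambda2,
              beta1 = row$beta1, beta2 = row$beta2,
              gamma1 = row$gamma1, gamma2 = row$gamma2,
              zeta = base$zeta, tau = base$tau, max_iter = base$max_iter,
              init = base$init, seed = base$seed, rescale = base$rescale)
}

fit_and_score <- function(train, test, graphs, config) {
  std <- standardize(train)
  fit <- suppressWarnings(gosc_scca(std, graphs, config))
  tr <- as.numeric(fit$train_correlation)
  te <- NaN
  if (!is.null(test)) {
    std_te <- standardize(test, stats = attr(std, "stats"))
    te <- as.numeric(canonical_correlation(fit$u, fit$v, std_te$X, std_te$Y))
  }
  list(fit = fit, train = tr, test = te)
}

#' Tune penalties by k-fold cross-validation
#'
#' Scores every candidate of the grid by `k`-fold cross-validation on the
#' supplied (training) data: mean held-out canonical correlation with `NaN`
#' scores excluded, a candidate whose scores are all `NaN` being
#' disqualified. Ties are broken toward larger penalties (the later point in
#' the ascending lambda-major enumeration). This is the inner stage of
#' [run_nested_cv()], exposed separately so a tuned configuration can be
#' reused across repeated simulations the way the cross-validation protocol
#' reuses the first fold's parameters.
#'
#' @inheritParams run_nested_cv
#' @param max_iter iteration cap for the tuning fits.
#' @return list with `selected` (one grid row), `index`, `config` (a full
#'   [scca_config()]), and `scores` (mean validation correlation per
#'   candidate).
#' @export
tune_penalties <- function(data, graphs = NULL, grid = cv_grid(), k = 5L,
                           seed = 1L, base_config = scca_config(),
                           max_iter = base_config$max_iter) {
  stopifnot(inherits(data, "paired_data"), inherits(grid, "cv_grid"))
  k <- as.integer(k)
  candidates <- enumerate_grid(grid)
  inner_base <- base_config
  inner_base$max_iter <- as.integer(max_iter)
  folds <- make_folds(nrow(data$X), k, seed)
  scores <- numeric(nrow(candidates))
  for (ci in seq_len(nrow(candidates))) {
    cfg <- config_with(inner_base, candidates[ci, ])
    sc <- vapply(seq_len(k), function(f) {
      tr <- subset_paired(data, which(folds != f))
      te <- subset_paired(data, which(folds == f))
      fit_and_score(tr, te, graphs, cfg)$test
    }, numeric(1))
    ok <- !is.nan(sc) & !is.na(sc)
    scores[ci] <- if (any(ok)) mean(sc[ok]) else -Inf
  }
  if (all(!is.finite(scores))) {
    stop("every candidate configuration failed during tuning")
  }
  idx <- max(which(scores == max(scores))) # ties -> larger penalties
  list(selected = candidates[idx, ], index = idx,
       config = config_with(base_config, candidates[idx, ]),
       scores = scores)
}

#' Nested k-fold cross-validation
#'
#' Splits the samples into `k` outer folds (seeded, unstratified). On the
#' first outer training set only, every grid candidate is scored by inner
#' `k`-fold cross-validation via [tune_penalties()]; the winner is then
#' reused for all outer folds (the protocol's time-saving shortcut). Each
#' outer fold is standardized with its own training statistics, fit, and
#' scored on its held-out samples.
#'
#' @param data an unstandardized [paired_data()].
#' @param graphs optional feature graphs (see [gosc_scca()]).
#' @param grid a [cv_grid()].
#' @param k number of outer (and inner) folds; default 5.
#' @param seed integer seed controlling both fold assignments.
#' @param base_config an [scca_config()] supplying the non-penalty solver
#'   settings.
#' @param inner_max_iter iteration cap used during inner tuning only
#'   (defaults to `base_config$max_iter`); lowering it speeds up tuning
#'   without affecting the final per-fold fits.
#' @return an object of class `cv_result`: fold assignments, the enumerated
#'   grid with inner scores, the selected configuration, a per-fold
#'   data.frame of train/test correlations, their NaN-excluded means and the
#'   failure counts.
#' @export
run_nested_cv <- function(data, graphs = NULL, grid = cv_grid(), k = 5L,
                          seed = 1L, base_config = scca_config(),
                          inner_max_iter = base_config$max_iter) {
  stopifnot(inherits(data, "paired_data"), inherits(grid, "cv_grid"))
  k <- as.integer(k)
  n <- nrow(data$X)
  folds <- make_folds(n, k, seed)
  candidates <- enumerate_grid(grid)

  # --- inner tuning on the first outer training set only
  first_train_rows <- which(folds != 1L)
  inner_data <- subset_paired(data, first_train_rows)
  tuned <- tune_penalties(inner_data, graphs, grid, k, seed + 1L,
                          base_config, max_iter = inner_max_iter)
  inner_mean <- tuned$scores
  selected_idx <- tuned$index
  selected <- tuned$selected
  sel_config <- tuned$config

  # --- outer evaluation with the selected configuration
  per_fold <- data.frame(fold = seq_len(k), train_cor = NA_real_,
                         test_cor = NA_real_, converged = NA, n_iter = NA_integer_)
  for (f in seq_len(k)) {
    tr <- subset_paired(data, which(folds != f))
    te <- subset_paired(data, which(folds == f))
    sc <- fit_and_score(tr, te, graphs, sel_config)
    per_fold$train_cor[f] <- sc$train
    per_fold$test_cor[f] <- sc$test
    per_fold$converged[f] <- sc$fit$converged
    per_fold$n_iter[f] <- sc$fit$n_iter
  }
  mean_no_nan <- function(x) if (any(!is.nan(x))) mean(x[!is.nan(x)]) else NaN
  structure(list(
    folds = folds, k = k, seed = as.integer(seed),
    grid = cbind(candidates, inner_mean_cor = inner_mean),
    selected_index = selected_idx,
    selected = selected, config = sel_config,
    per_fold = per_fold,
    mean_train = mean_no_nan(per_fold$train_cor),
    mean_test = mean_no_nan(per_fold$test_cor),
    n_failed_train = sum(is.nan(per_fold$train_cor)),
    n_failed_test = sum(is.nan(per_fold$test_cor))
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(paste0("cv_result (%d folds, seed %d): mean train = %.3f, ",
                     "mean test = %.3f (%d NaN fold(s))\n",
                     "  selected: lambda = (%g, %g), beta = (%g, %g), ",
                     "gamma = (%g, %g)\n"),
              x$k, x$seed, x$mean_train, x$mean_test, x$n_failed_test,
              x$selected$lambda1, x$selected$lambda2, x$selected$beta1,
              x$selected$beta2, x$selected$gamma1, x$selected$gamma2))
  invisible(x)
}

#' Paired comparison of per-fold scores
#'
#' Two-sided paired t-test between two methods' per-fold correlations, the
#' test used to decide whether a method is "not significantly worse than the
#' best". Pairs with a `NaN`/`NA` in either vector are dropped. Degenerate
#' cases are handled in closed form: identical scores give p = 1, constant
#' nonzero differences give p = 0, and fewer than two usable pairs make the
#' comparison unavailable (`NA` with attribute `available = FALSE`).
#'
#' @param fold_scores_a,fold_scores_b equal-length numeric vectors.
#' @return two-sided p-value, with attributes `t` and `df`.
#' @export
compare_methods <- function(fold_scores_a, fold_scores_b) {
  if (length(fold_scores_a) != length(fold_scores_b)) {
    stop("fold score vectors must have equal length")
  }
  ok <- is.finite(fold_scores_a) & is.finite(fold_scores_b)
  a <- fold_scores_a[ok]
  b <- fold_scores_b[ok]
  m <- length(a)
  if (m < 2L) {
    return(structure(NA_real_, available = FALSE,
                     reason = "fewer than two usable score pairs"))
  }
  d <- a - b
  s <- stats::sd(d)
  if (s == 0) {
    p <- if (mean(d) == 0) 1 else 0
    return(structure(p, available = TRUE,
                     t = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
                     df = m - 1L))
  }
  tstat <- mean(d) / (s / sqrt(m))
  structure(2 * stats::pt(-abs(tstat), df = m - 1L), available = TRUE,
            t = tstat, df = m - 1L)
}
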