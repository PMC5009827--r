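test_that("standardize centers and unit-norms columns, and is idempotent", {
  M <- cbind(a = c(1, 2, 3), b = c(5, 1, 0))
  pd <- paired_data(M, M[, 1, drop = FALSE])
  std <- standardize(pd)
  expect_equal(std$X[, "a"], c(-1, 0, 1) / sqrt(2), ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(std$X))), 1e-10)
  expect_lt(max(abs(sqrt(colSums(std$X^2)) - 1)), 1e-10)

  again <- standardize(std)
  expect_lt(max(abs(again$X - std$X)), 1e-12)
  expect_lt(max(abs(again$Y - std$Y)), 1e-12)

  bad <- paired_data(cbind(ok = c(1, 2, 3), flat = c(5, 5, 5)), M)
  expect_error(standardize(bad), "flat")
})

test_that("paired_data rejects misaligned or non-finite input", {
  expect_error(paired_data(matrix(1:6, 3), matrix(1:8, 4)), "aligned")
  expect_error(paired_data(matrix(c(1, NA, 3, 4), 2), matrix(1:4, 2)),
               "finite")
  expect_error(paired_data(matrix(1:4, 2), matrix(c(1, Inf, 3, 4), 2)),
               "finite")
})

test_that("scca_config validates its parameters", {
  expect_error(scca_config(tau = -1), "tau")
  expect_error(scca_config(gamma1 = 0), "gamma")
  expect_error(scca_config(lambda1 = -0.5), "non-negative")
  expect_error(scca_config(zeta = 0), "zeta")
  expect_error(scca_config(max_iter = 0), "max_iter")
})

test_that("objective: zero point, sign symmetry, term-wise oracle", {
  pd <- random_paired(1)
  cfg <- scca_config(lambda1 = 0.7, lambda2 = 0.3, beta1 = 0.2, beta2 = 0.9,
                     gamma1 = 1.5, gamma2 = 0.8)
  p <- ncol(pd$X); q <- ncol(pd$Y)

  expect_identical(scca_objective(rep(0, p), rep(0, q), pd, cfg), 0)

  set.seed(2)
  u <- rnorm(p); v <- rnorm(q)
  expect_equal(scca_objective(u, v, pd, cfg),
               scca_objective(-u, -v, pd, cfg), tolerance = 1e-12)

  # independent term-by-term recomputation with the brute-force oracle
  expected <- -drop(t(u) %*% t(pd$X) %*% pd$Y %*% v) +
    cfg$lambda1 * oracle_oscar(u) + cfg$lambda2 * oracle_oscar(v) +
    cfg$beta1 / 2 * sum(abs(u)) + cfg$beta2 / 2 * sum(abs(v)) +
    cfg$gamma1 / 2 * sum((pd$X %*% u)^2) + cfg$gamma2 / 2 * sum((pd$Y %*% v)^2)
  expect_equal(scca_objective(u, v, pd, cfg), expected, tolerance = 1e-10)
})

test_that("update_loading agrees with the explicit-inverse oracle", {
  for (seed in 1:10) {
    pd <- random_paired(seed)
    set.seed(seed + 100)
    u_cur <- rnorm(ncol(pd$X))
    v <- rnorm(ncol(pd$Y))
    cfg <- scca_config(lambda1 = 0.4, beta1 = 0.6, gamma1 = 1.2, zeta = 1e-10)
    w <- reweight(u_cur, complete_graph(ncol(pd$X)), cfg$zeta)
    got <- update_loading("u", pd, v, w, cfg)
    want <- oracle_update_u(pd$X, pd$Y, v, u_cur, 0.4, 0.6, 1.2, 1e-10)
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("update_loading with zero penalties reduces to least squares", {
  pd <- random_paired(3, n = 30, p = 8, q = 5)
  cfg <- scca_config(lambda1 = 0, beta1 = 0, gamma1 = 1)
  set.seed(4)
  v <- rnorm(5)
  w <- reweight(rep(1, 8), complete_graph(8), cfg$zeta)
  got <- update_loading("u", pd, v, w, cfg)
  want <- drop(solve(crossprod(pd$X)) %*% crossprod(pd$X, pd$Y %*% v))
  expect_lt(max(abs(got - want)), 1e-8)
})

test_that("rank-deficient system activates the jitter path", {
  set.seed(5)
  X <- matrix(rnorm(20 * 3), 20, 3)
  X <- cbind(X, X[, 1] + X[, 2]) # exactly collinear fourth column
  Y <- matrix(rnorm(20 * 4), 20, 4)
  pd <- standardize(paired_data(X, Y))
  cfg <- scca_config(lambda1 = 0, beta1 = 0, gamma1 = 1)
  w <- reweight(rep(1, 4), complete_graph(4), cfg$zeta)
  expect_warning(
    got <- update_loading("u", pd, rnorm(4), w, cfg),
    "jitter"
  )
  expect_true(all(is.finite(got)))
})

test_that("fit: duplicated datasets give self-correlation near 1", {
  set.seed(6)
  X <- matrix(rnorm(40 * 6), 40, 6)
  pd <- paired_data(X, X)
  cfg <- scca_config(lambda1 = 1e-4, lambda2 = 1e-4, beta1 = 1e-4,
                     beta2 = 1e-4, gamma1 = 1, gamma2 = 1)
  fit <- gosc_scca(pd, config = cfg)
  expect_true(fit$converged)
  expect_equal(as.numeric(fit$train_correlation), 1, tolerance = 1e-6)
})

test_that("fit: sign-pair symmetry of initialization", {
  pd <- random_paired(7, n = 25, p = 6, q = 7)
  cfg <- scca_config(lambda1 = 0.2, lambda2 = 0.2, beta1 = 0.2, beta2 = 0.2,
                     rescale = "final", max_iter = 30)
  set.seed(8)
  u0 <- rnorm(6); v0 <- rnorm(7)
  f1 <- suppressWarnings(gosc_scca(pd, config = cfg, u0 = u0, v0 = v0))
  f2 <- suppressWarnings(gosc_scca(pd, config = cfg, u0 = -u0, v0 = -v0))
  expect_equal(unname(f1$u), -unname(f2$u), tolerance = 1e-10)
  expect_equal(unname(f1$v), -unname(f2$v), tolerance = 1e-10)
  expect_equal(f1$objective_trace, f2$objective_trace, tolerance = 1e-10)
})

test_that("lasso limit: lambda = 0 removes the graph penalty exactly", {
  pd <- random_paired(9, n = 20, p = 5, q = 6)
  cfg <- scca_config(lambda1 = 0, lambda2 = 0, beta1 = 0.5, beta2 = 0.5)
  fit <- suppressWarnings(gosc_scca(pd, config = cfg))
  u <- unname(fit$u); v <- unname(fit$v)
  # objective with complete graphs equals the objective with empty graphs
  # bit-for-bit: the GOSCAR contribution is exactly zero
  full <- scca_objective(u, v, pd, cfg)
  empty <- list(u = feature_graph(5), v = feature_graph(6))
  expect_identical(full, scca_objective(u, v, pd, cfg, graphs = empty))
  expect_identical(cfg$lambda1 * goscar_norm(u, complete_graph(5)), 0)
})

test_that("zeta limit: smoothed objective insensitive to zeta below 1e-10", {
  pd <- random_paired(10, n = 25, p = 8, q = 9)
  set.seed(11)
  u <- rnorm(8); v <- rnorm(9)
  o1 <- scca_objective(u, v, pd, scca_config(zeta = 1e-10), smoothed = TRUE)
  o2 <- scca_objective(u, v, pd, scca_config(zeta = 1e-14), smoothed = TRUE)
  expect_lt(abs(o1 - o2) / abs(o2), 1e-4)
})

test_that("fixed-point residual of the stationarity equations at convergence", {
  # rescale = "final" so the converged iterate is a genuine fixed point of
  # the unscaled update maps
  pd <- random_paired(12, n = 40, p = 12, q = 14)
  cfg <- scca_config(lambda1 = 0.3, lambda2 = 0.3, beta1 = 0.3, beta2 = 0.3,
                     rescale = "final", max_iter = 200)
  fit <- suppressWarnings(gosc_scca(pd, config = cfg))
  expect_true(fit$converged)
  u <- fit$u_raw; v <- fit$v_raw
  gu <- complete_graph(12); gv <- complete_graph(14)
  wu <- reweight(u, gu, cfg$zeta); wv <- reweight(v, gv, cfg$zeta)
  res_u <- -crossprod(pd$X, pd$Y %*% v) +
    cfg$lambda1 * (wu$L + wu$L_hat) %*% u +
    cfg$beta1 * wu$lambda_diag * u +
    cfg$gamma1 * crossprod(pd$X) %*% u
  res_v <- -crossprod(pd$Y, pd$X %*% u) +
    cfg$lambda2 * (wv$L + wv$L_hat) %*% v +
    cfg$beta2 * wv$lambda_diag * v +
    cfg$gamma2 * crossprod(pd$Y) %*% v
  expect_lt(max(abs(res_u)), 10 * cfg$tau)
  expect_lt(max(abs(res_v)), 10 * cfg$tau)
})

test_that("canonical_correlation: NaN conventions and the textbook formula", {
  set.seed(13)
  X <- matrix(rnorm(20 * 4), 20, 4)
  Y <- matrix(rnorm(20 * 5), 20, 5)

  nan <- canonical_correlation(rep(0, 4), rnorm(5), X, Y)
  expect_true(is.nan(nan))
  expect_match(attr(nan, "failure"), "zero")

  u <- rnorm(4)
  expect_equal(canonical_correlation(u, u, X, X), 1.0, tolerance = 1e-12)

  v <- rnorm(5)
  a <- drop(X %*% u); b <- drop(Y %*% v)
  manual <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(as.numeric(canonical_correlation(u, v, X, Y)), manual,
               tolerance = 1e-12)

  expect_error(canonical_correlation(rnorm(3), v, X, Y), "length")
})
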