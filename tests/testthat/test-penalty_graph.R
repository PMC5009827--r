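test_that("feature_graph validates and normalizes its edge set", {
  g <- feature_graph(4, rbind(c(1, 2), c(2, 1), c(4, 3), c(3, 4)))
  expect_equal(n_edges(g), 2L)
  expect_true(all(g$edges[, 1] < g$edges[, 2]))

  expect_equal(n_edges(complete_graph(4)), 6L)
  for (p in c(2L, 5L, 9L)) {
    expect_equal(n_edges(complete_graph(p)), p * (p - 1L) / 2L)
  }

  expect_error(feature_graph(3, rbind(c(1, 1))), "self-loop")
  expect_error(feature_graph(3, rbind(c(0, 2))), "indices")
  expect_error(feature_graph(3, rbind(c(1, 4))), "indices")
  expect_equal(n_edges(feature_graph(5)), 0L)
})

test_that("goscar_norm: trivial cases and the half-decomposition identity", {
  expect_identical(goscar_norm(c(0, 0, 0), complete_graph(3)), 0)

  g1 <- feature_graph(2, rbind(c(1, 2)))
  expect_equal(goscar_norm(c(3, -1), g1), 3)
  expect_equal(goscar_norm(c(3, -1), g1, form = "split"),
               0.5 * (abs(3 - (-1)) + abs(3 + (-1))))

  expect_error(goscar_norm(c(1, 2, 3), g1), "length")

  # max form vs split form on random vectors and random subgraphs
  set.seed(42)
  for (rep in 1:50) {
    p <- sample(2:10, 1)
    u <- rnorm(p, sd = sample(c(0.01, 1, 100), 1))
    g <- complete_graph(p)
    a <- goscar_norm(u, g)
    b <- goscar_norm(u, g, form = "split")
    expect_lt(abs(a - b), 1e-12 * (1 + a))
    # random subgraph vs brute-force loop oracle
    keep <- sample(c(TRUE, FALSE), n_edges(g), replace = TRUE)
    gs <- feature_graph(p, g$edges[keep, , drop = FALSE])
    expect_equal(goscar_norm(u, gs), oracle_goscar(u, gs$edges),
                 tolerance = 1e-13)
  }
})

test_that("complete-graph GOSCAR equals the OSCAR pairwise oracle", {
  set.seed(7)
  for (rep in 1:100) {
    p <- sample(2:10, 1)
    u <- rnorm(p)
    expect_equal(goscar_norm(u, complete_graph(p)), oracle_oscar(u),
                 tolerance = 1e-13)
  }
})

test_that("init_weights matches the 1/2 initialization and row-sum identities", {
  g2 <- complete_graph(2)
  w2 <- init_weights(g2)
  expect_equal(w2$W[1, 2], 0.5)
  expect_equal(w2$W_hat[1, 2], 0.5)
  expect_equal(diag(w2$W), c(0, 0))

  g3 <- complete_graph(3)
  w3 <- init_weights(g3)
  expect_equal(diag(w3$D), rep(1.0, 3))
  expect_equal(drop(w3$L %*% rep(1, 3)), rep(0, 3))

  empty <- feature_graph(4)
  we <- init_weights(empty)
  expect_true(all(we$W == 0) && all(we$W_hat == 0))
  expect_true(all(we$L == 0) && all(we$L_hat == 0))
})

test_that("reweight implements the smoothed weight rules", {
  g <- feature_graph(2, rbind(c(1, 2)))
  zeta <- 1e-14 # effectively the zero-smoothing limit
  w <- reweight(c(1, 0.5), g, zeta)
  expect_equal(w$W[1, 2], 1 / (2 * 0.5), tolerance = 1e-10)
  expect_equal(w$W_hat[1, 2], 1 / (2 * 1.5), tolerance = 1e-10)
  expect_equal(w$lambda_diag[2], 1 / (2 * 0.5), tolerance = 1e-10)

  # equal entries: smoothing keeps the weight finite at 1/(2 sqrt(zeta))
  zeta <- 1e-10
  w <- reweight(c(0.7, 0.7), g, zeta)
  expect_equal(w$W[1, 2], 1 / (2 * sqrt(zeta)))
  expect_true(is.finite(w$W[1, 2]))

  # Lambda_kk strictly decreasing in |u_k|
  lam <- reweight(c(0, 0.25, 0.5, 1, 2), feature_graph(5), zeta)$lambda_diag
  expect_true(all(diff(lam) < 0))

  expect_error(reweight(c(1, 2), g, zeta = 0), "zeta")
  expect_error(reweight(c(1, 2), g, zeta = -1), "zeta")
})

test_that("reweight output satisfies the Laplacian and PSD invariants", {
  set.seed(11)
  for (rep in 1:10) {
    p <- sample(3:12, 1)
    u <- rnorm(p)
    g <- if (rep %% 2 == 0) complete_graph(p) else {
      cg <- complete_graph(p)
      keep <- sample(c(TRUE, FALSE), n_edges(cg), replace = TRUE, prob = c(.6, .4))
      feature_graph(p, cg$edges[keep, , drop = FALSE])
    }
    w <- reweight(u, g, 1e-10)
    expect_equal(w$W, t(w$W))
    expect_equal(w$W_hat, t(w$W_hat))
    # entries vanish off-graph
    off <- matrix(TRUE, p, p)
    off[w$graph$edges] <- FALSE
    off[w$graph$edges[, c(2, 1), drop = FALSE]] <- FALSE
    expect_true(all(w$W[off & upper.tri(off)] == 0))
    # exact row sums
    expect_equal(diag(w$D), rowSums(w$W))
    expect_equal(diag(w$D_hat), rowSums(w$W_hat))
    expect_equal(drop(w$L %*% rep(1, p)), rep(0, p), tolerance = 1e-12)
    expect_gte(min(eigen(w$L, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_gte(min(eigen(w$L_hat, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    expect_true(all(w$lambda_diag > 0))

    # quadratic-form identities behind the convergence argument
    e <- g$edges
    qf_L <- sum(w$W[e] * (u[e[, 1]] - u[e[, 2]])^2)
    qf_Lhat <- sum(w$W_hat[e] * (u[e[, 1]] + u[e[, 2]])^2)
    expect_equal(drop(t(u) %*% w$L %*% u), qf_L,
                 tolerance = 1e-10 * (1 + abs(qf_L)))
    expect_equal(drop(t(u) %*% w$L_hat %*% u), qf_Lhat,
                 tolerance = 1e-10 * (1 + abs(qf_Lhat)))
  }
})
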