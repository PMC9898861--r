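test_that("the penalized path has the fully-penalized and unpenalized limits", {
  set.seed(10)
  X <- nondegenerate_binary(60, 3)
  y <- rbinom(60, 1, plogis(-0.5 + X[, 1]))
  if (length(unique(y)) < 2) y[1:2] <- 0:1
  path <- lasso_logistic_path(y, X)
  # largest penalty: all slopes zero, intercept at the null model
  expect_true(all(path$beta[, 1] == 0))
  expect_equal(path$a0[1], qlogis(mean(y)), tolerance = 1e-6)
  expect_equal(path$df[1], 0)
  # log-likelihood is nondecreasing as the penalty relaxes
  expect_true(all(diff(path$loglik) > -1e-6))
  # near-zero penalty matches the unpenalized MLE
  fit0 <- lasso_logistic_path(y, X, lambda = c(0.05, 1e-10))
  mle <- glm(y ~ X, family = binomial)
  expect_equal(fit0$a0[2], unname(coef(mle)[1]), tolerance = 1e-4)
  expect_equal(unname(fit0$beta[, 2]), unname(coef(mle)[-1]), tolerance = 1e-4)
  # degenerate outcomes are refused with guidance
  expect_error(lasso_logistic_path(rep(0, 60), X), "degenerate")
})

test_that("path solutions match an independent proximal-gradient solver", {
  set.seed(11)
  for (rep in 1:4) {
    n <- sample(20:50, 1)
    p <- sample(2:4, 1)
    X <- nondegenerate_binary(n, p, prob = 0.4)
    y <- rbinom(n, 1, plogis(-0.3 + 0.8 * X[, 1]))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    lam <- 0.05
    path <- lasso_logistic_path(y, X, lambda = c(0.3, lam))
    oracle <- ista_lasso_logistic(y, X, lam)
    expect_equal(path$a0[2], oracle$a0, tolerance = 1e-4)
    expect_equal(unname(path$beta[, 2]), oracle$beta, tolerance = 1e-4)
  }
})

test_that("EBIC evaluates its formula and penalizes model size monotonically", {
  # gamma = 0, k = 0 reduces to the deviance
  expect_equal(ebic(-50, 0, 100, 8, gamma = 0), 100)
  expect_equal(ebic(-100, 3, 335, 8, gamma = 0.25),
               200 + 3 * log(335) + 1.5 * log(8))
  expect_equal(ebic(-100, 3, 335, 8, gamma = 0.25), 220.5615, tolerance = 1e-4)
  # strictly increasing in k at fixed log-likelihood
  ks <- 0:8
  expect_true(all(diff(ebic(-100, ks, 335, 8, gamma = 0.25)) > 0))
  expect_error(ebic(-10, -1, 100, 5), "nonnegative")
})

test_that("node selection minimizes EBIC with ties broken toward sparsity", {
  # single-predictor toy where the empty model wins on EBIC
  set.seed(12)
  X <- cbind(rbinom(40, 1, 0.5), rbinom(40, 1, 0.5))
  fit <- fit_elasso_node(X, 1)
  path <- lasso_logistic_path(X[, 1], X[, 2, drop = FALSE])
  scores <- ebic(path$loglik, path$df, 40, 1)
  k_best <- path$df[which.min(scores)]
  expect_equal(sum(fit$coef != 0), unname(k_best))
  # degenerate node: zero coefficients and a warning, not an error
  Xd <- cbind(rep(0L, 30), rbinom(30, 1, 0.5), rbinom(30, 1, 0.5))
  expect_warning(fd <- fit_elasso_node(Xd, 1), "degenerate")
  expect_true(all(fd$coef == 0))
  expect_true(fd$degenerate)
})

test_that("AND/OR assembly follows the rule definitions", {
  D <- matrix(0, 3, 3)
  D[1, 2] <- 2            # 1 regressed on 2: nonzero one way only
  D[2, 3] <- 2; D[3, 2] <- 3   # both ways nonzero
  W_and <- symptomnet:::assemble_weights(D, "AND")
  W_or <- symptomnet:::assemble_weights(D, "OR")
  expect_equal(W_and[1, 2], 0)          # AND kills one-sided edges
  expect_equal(W_or[1, 2], 2)           # OR keeps them at the nonzero value
  expect_equal(W_and[2, 3], 2.5)        # both nonzero: arithmetic mean
  expect_equal(W_or[2, 3], 2.5)
  expect_identical(W_and, t(W_and))
  expect_true(all(diag(W_and) == 0))
})

test_that("estimated networks are symmetric, sparse, and AND is nested in OR", {
  sc <- default_scenario("pgsi")
  pan <- generate_two_wave(sc$ising, sc$clpn, n = 335, seed = 31)
  X <- panel_wave(pan, 1)
  net_and <- suppressWarnings(estimate_ising(X, rule = "AND"))
  net_or <- suppressWarnings(estimate_ising(X, rule = "OR"))
  expect_identical(net_and$weights, t(net_and$weights))
  expect_true(all(diag(net_and$weights) == 0))
  ut <- upper.tri(net_and$weights)
  expect_lt(mean(net_and$weights[ut] != 0), 1)   # sparse output
  # AND edges are a subset of OR edges on the same node-wise fits
  expect_true(all(net_or$weights[net_and$weights != 0] != 0))
  # degenerate nodes are kept with zero edges and flagged
  Xd <- cbind(X[, 1:8], 0L)
  netd <- suppressWarnings(estimate_ising(Xd))
  expect_true(netd$degenerate[9])
  expect_true(all(netd$weights[9, ] == 0))
})

test_that("null data yield almost no false edges at large n", {
  null <- default_scenario("null")
  set.seed(32)
  false_edges <- replicate(15, {
    X <- sample_ising(null$ising, 2000)
    net <- suppressWarnings(estimate_ising(X))
    sum(net$weights[upper.tri(net$weights)] != 0)
  })
  expect_lt(mean(false_edges), 1.5)
})

test_that("chain couplings are recovered at large n", {
  strong <- default_scenario("strong")
  set.seed(33)
  hits <- replicate(10, {
    X <- sample_ising(strong$ising, 2000)
    net <- suppressWarnings(estimate_ising(X))
    chain <- net$weights[cbind(1:8, 2:9)]
    all(chain != 0)
  })
  expect_gte(mean(hits), 0.9)
})
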