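test_that("exact Ising enumeration matches hand-normalized probabilities", {
  # independent fair coins: uniform over the four states
  en <- enumerate_ising(ising_parameters(c(0, 0), matrix(0, 2, 2)))
  expect_equal(en$prob, rep(0.25, 4))
  # a single coupling of log(2) reweights only the (1,1) state
  W <- matrix(c(0, log(2), log(2), 0), 2)
  en2 <- enumerate_ising(ising_parameters(c(0, 0), W))
  expect_equal(en2$prob, c(1, 1, 1, 2) / 5)
  # probabilities normalize for arbitrary parameters
  set.seed(1)
  for (p in c(3, 5)) {
    Wr <- random_weight_matrix(p)
    en3 <- enumerate_ising(ising_parameters(rnorm(p), Wr))
    expect_true(all(en3$prob >= 0))
    expect_equal(sum(en3$prob), 1, tolerance = 1e-12)
  }
  expect_error(enumerate_ising(ising_parameters(rep(0, 21), matrix(0, 21, 21))),
               "p <= 20")
})

test_that("zero couplings factorize the joint into independent Bernoullis", {
  set.seed(2)
  tau <- rnorm(4)
  en <- enumerate_ising(ising_parameters(tau, matrix(0, 4, 4)))
  marg <- plogis(tau)
  expected <- apply(en$states, 1, function(x) prod(ifelse(x == 1, marg, 1 - marg)))
  expect_equal(en$prob, unname(expected), tolerance = 1e-12)
})

test_that("exact sampler reproduces the enumerated distribution", {
  par0 <- ising_parameters(rep(0, 3), matrix(0, 3, 3))
  x <- sample_ising(par0, 10000, seed = 11)
  expect_true(all(colMeans(x) > 0.48 & colMeans(x) < 0.52))
  # same seed, same sample
  expect_identical(x, sample_ising(par0, 10000, seed = 11))
  # pairwise moments agree with enumeration within 3 MC standard errors
  set.seed(3)
  par1 <- ising_parameters(rnorm(6, -0.5), random_weight_matrix(6))
  en <- enumerate_ising(par1)
  n <- 20000
  x1 <- sample_ising(par1, n, seed = 12)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      exact <- sum(en$prob[en$states[, i] == 1 & en$states[, j] == 1])
      emp <- mean(x1[, i] & x1[, j])
      se <- sqrt(exact * (1 - exact) / n)
      expect_lt(abs(emp - exact), 3 * se + 1e-8)
    }
  }
})

test_that("Gibbs sampler agrees with exact enumeration on moments", {
  set.seed(4)
  par1 <- ising_parameters(rnorm(5, -0.3), random_weight_matrix(5, signed = FALSE))
  en <- enumerate_ising(par1)
  n <- 3000
  x <- sample_ising(par1, n, seed = 13, method = "gibbs",
                    burnin = 500, thin = 10)
  for (i in 1:5) {
    exact <- sum(en$prob[en$states[, i] == 1])
    se <- sqrt(exact * (1 - exact) / n)   # iid bound; thinning keeps
    expect_lt(abs(mean(x[, i]) - exact), 5 * se + 1e-8)  # autocorrelation mild
  }
})

test_that("two-wave generation follows the conditional logistic model", {
  p <- 4
  ising <- ising_parameters(rep(qlogis(0.3), p), matrix(0, p, p))
  # with B = 0 the wave-2 marginal is exactly plogis(alpha)
  clpn0 <- crosslag_parameters(rep(qlogis(0.05), p), matrix(0, p, p))
  pan <- generate_two_wave(ising, clpn0, n = 20000, seed = 21)
  w2 <- panel_wave(pan, 2)
  expect_true(all(abs(colMeans(w2) - 0.05) < 0.006))
  # a single cross-lagged effect creates the implied odds ratio
  B <- matrix(0, p, p); B[2, 4] <- 2
  clpn1 <- crosslag_parameters(rep(qlogis(0.05), p), B)
  pan2 <- generate_two_wave(ising, clpn1, n = 40000, seed = 22)
  w1 <- panel_wave(pan2, 1); w2 <- panel_wave(pan2, 2)
  p1 <- mean(w2[w1[, 2] == 1, 4]); p0 <- mean(w2[w1[, 2] == 0, 4])
  odds_ratio <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_equal(log(odds_ratio), 2, tolerance = 0.15)
  # determinism under seed
  pan3 <- generate_two_wave(ising, clpn1, n = 100, seed = 5)
  pan4 <- generate_two_wave(ising, clpn1, n = 100, seed = 5)
  expect_identical(pan3$responses, pan4$responses)
  # dimension mismatch rejected
  expect_error(generate_two_wave(ising, crosslag_parameters(0, matrix(0, 1, 1)), 10),
               "mismatch")
})

test_that("built-in scenarios have the advertised structure", {
  null <- default_scenario("null")
  expect_true(all(null$ising$couplings == 0))
  expect_true(all(null$clpn$coefficients == 0))
  # under the null, wave-1 symptoms are independent by construction
  en <- enumerate_ising(null$ising)
  marg <- plogis(null$ising$thresholds)
  expect_equal(en$prob,
               unname(apply(en$states, 1, function(x)
                 prod(ifelse(x == 1, marg, 1 - marg)))),
               tolerance = 1e-12)

  sc <- default_scenario("pgsi")
  expect_equal(sc$n, 335L)
  # exact marginals sit inside the low-prevalence design band
  m <- symptomnet:::ising_marginals(sc$ising)
  expect_true(all(m >= 0.02 & m <= 0.08))
  # couplings sparse, positive, symmetric
  W <- sc$ising$couplings
  expect_identical(W, t(W))
  expect_true(all(W >= 0))
  expect_lt(mean(W[upper.tri(W)] != 0), 0.5)
  # cross-lagged drivers are symptoms 2 and 6 (plus autoregression)
  B <- sc$clpn$coefficients
  off <- B; diag(off) <- 0
  expect_setequal(which(rowSums(off != 0) > 0), c(2L, 6L))
  # empirical wave-1 prevalences stay in a plausible band across seeds
  set.seed(30)
  rates <- replicate(25, colMeans(panel_wave(
    generate_two_wave(sc$ising, sc$clpn, 335), 1)))
  expect_true(all(rates >= 0.01 - 1e-9 & rates <= 0.12 + 1e-9))

  strong <- default_scenario("strong")
  Wc <- strong$ising$couplings
  expect_true(all(Wc[cbind(1:8, 2:9)] == 2))
  expect_error(default_scenario("nope"))
})

test_that("scenario parameters survive a JSON round trip", {
  sc <- default_scenario("pgsi")
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario_json(sc, path)
  sc2 <- read_scenario_json(path)
  expect_equal(sc2$ising$thresholds, sc$ising$thresholds)
  expect_equal(sc2$ising$couplings, sc$ising$couplings, ignore_attr = TRUE)
  expect_equal(sc2$clpn$coefficients, sc$clpn$coefficients, ignore_attr = TRUE)
  expect_equal(sc2$n, sc$n)
})
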