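test_that("CSV round-trip preserves a two-wave panel and validates input", {
  df <- data.frame(pg1_w1 = c(0, 1, 2), pg2_w1 = c(0, 0, 3),
                   pg1_w2 = c(1, 0, 0), pg2_w2 = c(0, 2, 1),
                   sex = c("f", "m", "f"))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  pan <- read_panel(path, scale = "ordinal", n_items = 2, n_waves = 2)
  expect_s3_class(pan, "symptom_panel")
  expect_equal(dim(pan), c(3L, 2L, 2L))
  expect_equal(panel_wave(pan, 1), cbind(item1 = c(0, 1, 2), item2 = c(0, 0, 3)))
  expect_equal(pan$covariates$sex, c("f", "m", "f"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_panel(pan, out)
  pan2 <- read_panel(out, scale = "ordinal", n_items = 2, n_waves = 2)
  expect_equal(pan2$responses, pan$responses)

  # out-of-range ordinal value is rejected
  bad <- df; bad$pg1_w1[1] <- 4
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_panel(path, scale = "ordinal", n_items = 2, n_waves = 2),
               "range")
  # duplicate IDs are rejected
  df$id <- c(1, 1, 2)
  write.csv(df, path, row.names = FALSE)
  expect_error(read_panel(path, scale = "ordinal", n_items = 2, n_waves = 2,
                          id_col = "id"), "duplicate")
})

test_that("PGSI scoring sums items and risk categories follow the cut points", {
  expect_equal(score_pgsi(rep(0, 9)), 0)
  expect_equal(as.character(classify_risk(0)), "non_problematic")
  expect_equal(score_pgsi(c(1, 1, 1, 0, 0, 0, 0, 0, 0)), 3)
  expect_equal(as.character(classify_risk(3)), "moderate_risk")
  expect_equal(score_pgsi(rep(3, 9)), 27)
  expect_equal(as.character(classify_risk(c(2, 7, 8, 27))),
               c("low_risk", "moderate_risk", "severe", "severe"))
  expect_error(classify_risk(-1))
  expect_error(classify_risk(28))
  # total and monotone over the whole domain
  cats <- classify_risk(0:27)
  expect_false(anyNA(cats))
  expect_true(all(diff(as.integer(cats)) >= 0))
  # scoring refuses binary-scale panels
  pan <- symptom_panel(matrix(rbinom(27, 1, 0.3), 3, 9), scale = "binary")
  expect_error(score_pgsi(pan), "ordinal")
})

test_that("dichotomization maps 1-3 to 1 and is idempotent", {
  m <- matrix(c(0, 1, 2, 3, 0, 0, 1, 3, 2), 3, 3)
  pan <- symptom_panel(m, scale = "ordinal")
  bin <- dichotomize(pan)
  expect_equal(bin$scale, "binary")
  expect_equal(panel_wave(bin, 1), (m > 0) * 1L,
               ignore_attr = TRUE)
  expect_message(bin2 <- dichotomize(bin), "already binary")
  expect_equal(bin2$responses, bin$responses)
  # all-zero panel is a fixed point
  z <- symptom_panel(matrix(0L, 4, 3), scale = "ordinal")
  expect_true(all(panel_wave(dichotomize(z), 1) == 0))
})

test_that("prevalence percentages are 100 * count / n with exact counts", {
  # one symptom endorsed by 19 of 335, risk categories from totals
  resp <- matrix(0L, 335, 9)
  resp[1:19, 2] <- 1L            # 19 endorse symptom 2 -> 5.67%
  resp[1:36, 1] <- 1L            # 36 low-risk persons -> 299 non-problematic
  pan <- symptom_panel(resp, scale = "ordinal")
  tab <- prevalence_table(pan)
  sym2 <- tab[tab$measure == "symptom" & tab$label == pgsi_items()[2], ]
  expect_equal(sym2$count, 19L)
  expect_equal(round(sym2$pct, 2), 5.67)
  nonprob <- tab[tab$measure == "risk_category" &
                   tab$label == "non_problematic", ]
  expect_equal(nonprob$count, 299L)
  expect_equal(round(nonprob$pct, 2), 89.25)
  # zero-endorsement symptom reports 0
  sym5 <- tab[tab$measure == "symptom" & tab$label == pgsi_items()[5], ]
  expect_equal(sym5$pct, 0)
  # counts equal binary column sums
  cnts <- tab$count[tab$measure == "symptom"]
  expect_equal(cnts, unname(colSums(panel_wave(dichotomize(pan), 1))))
})

test_that("Cronbach's alpha matches its covariance formula and simulation", {
  # identical items are perfectly consistent
  x <- cbind(rnorm(20), 0)
  x[, 2] <- x[, 1]
  expect_equal(cronbach_alpha(x), 1)
  # direct evaluation on a constructed covariance
  expect_equal(cronbach_alpha(covmat = matrix(c(1, 0.5, 0.5, 1), 2)), 2 / 3)
  # independent items give alpha near zero
  set.seed(42)
  z <- matrix(rnorm(10000 * 4), ncol = 4)
  expect_lt(abs(cronbach_alpha(z)), 0.05)
  # degenerate input errors
  expect_error(cronbach_alpha(matrix(1, 5, 2)), "variance")
})

test_that("dependent t test matches hand computation and controls type I error", {
  x1 <- c(0, 1, 3, 0)
  x2 <- x1 + c(1, 0, -1, 2)
  res <- paired_t(x1, x2)
  expect_equal(res$mean_diff, 0.5)
  expect_equal(res$statistic, 0.5 / (sd(c(1, 0, -1, 2)) / 2), tolerance = 1e-10)
  expect_equal(res$statistic, 0.7746, tolerance = 1e-4)
  expect_equal(res$df, 3L)
  # identical waves: trivially no change
  same <- paired_t(c(1, 2, 3, 5), c(1, 2, 3, 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # constant nonzero shift leaves t undefined
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  # type-I error at the nominal level under a true null
  set.seed(7)
  rej <- mean(replicate(2000, {
    a <- rnorm(335); b <- 0.3 * a + rnorm(335)  # same mean, dependent
    paired_t(a, b)$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("McNemar statistics follow the discordant-pair formulas", {
  mk <- function(b, cc) {
    # build paired vectors with b 0->1 and cc 1->0 transitions
    b1 <- c(rep(0, b), rep(1, cc), rep(0, 5), rep(1, 5))
    b2 <- c(rep(1, b), rep(0, cc), rep(0, 5), rep(1, 5))
    mcnemar_paired(b1, b2)
  }
  sym <- mk(5, 5)
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p.value, 1)
  res <- mk(10, 2)
  expect_equal(res$statistic, 64 / 12, tolerance = 1e-12)
  expect_equal(res$p.binomial, 158 / 4096, tolerance = 1e-12)
  # swapping b and c leaves chi-squared unchanged
  expect_equal(mk(2, 10)$statistic, res$statistic)
  expect_equal(res$cohen_g, 10 / 12 - 0.5)
  # no discordant pairs: chi-squared undefined, binomial p = 1
  none <- mcnemar_paired(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_true(is.na(none$statistic))
  expect_equal(none$p.binomial, 1)
})
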