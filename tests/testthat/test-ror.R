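# Reporting odds ratios: point estimates, Woolf intervals, continuity
# correction, and agreement with an independent cross-product oracle.

test_that("symmetric tables give ROR 1 with a CI straddling 1", {
  r <- ror(10, 10, 10, 10)
  expect_equal(r$ror, 1)
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
  expect_false(r$corrected)
})

test_that("estimate and Woolf CI match an independent recomputation", {
  r <- ror(20, 80, 10, 90)
  expect_equal(r$ror, 2.25)
  # recompute the log-normal interval from first principles
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 10 + 1 / 90)
  z <- qnorm(0.975)
  expect_equal(r$ci_low, exp(log(2.25) - z * se), tolerance = 1e-12)
  expect_equal(r$ci_high, exp(log(2.25) + z * se), tolerance = 1e-12)
})

test_that("zero cells trigger the Haldane-Anscombe correction with finite CI", {
  r <- ror(0, 10, 5, 5)
  expect_true(r$corrected)
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
  expect_equal(r$ror, (0.5 / 10.5) / (5.5 / 5.5))
  expect_error(ror(0, 0, 5, 5), "margin")
})

test_that("ROR matches the direct cross-product on all 2x2 tables with cells 1..6", {
  g <- expand.grid(a = 1:6, b = 1:6, c = 1:6, d = 1:6)
  r <- ror(g$a, g$b, g$c, g$d)
  oracle <- (g$a * g$d) / (g$b * g$c)
  expect_equal(r$ror, oracle, tolerance = 1e-12)
  expect_false(any(r$corrected))
  expect_true(all(r$ci_low <= r$ror & r$ror <= r$ci_high))
})

test_that("swapping comparator inverts the ROR and its interval", {
  r1 <- ror(20, 80, 10, 90)
  r2 <- ror(10, 90, 20, 80)
  expect_equal(r2$ror, 1 / r1$ror, tolerance = 1e-12)
  expect_equal(r2$ci_low, 1 / r1$ci_high, tolerance = 1e-12)
  expect_equal(r2$ci_high, 1 / r1$ci_low, tolerance = 1e-12)
})

test_that("scaling all cells preserves the ROR and narrows the CI", {
  r1 <- ror(5, 15, 10, 20)
  r5 <- ror(25, 75, 50, 100)
  expect_equal(r5$ror, r1$ror, tolerance = 1e-12)
  expect_lt(r5$ci_high - r5$ci_low, r1$ci_high - r1$ci_low)
})

test_that("ror_profile equals per-pair 2x2 computations over the whole table", {
  withr::local_seed(99)
  O <- rand_table(26, 6)
  tab <- as_contingency_table(O)
  n <- sum(O)
  for (d in seq_len(ncol(O))) {
    prof <- ror_profile(tab, colnames(O)[d])
    for (i in seq_len(nrow(O))) {
      a <- O[i, d]
      b <- sum(O[, d]) - a
      c <- sum(O[i, ]) - a
      dd <- n - a - b - c
      expect_equal(prof$ror[i], (a / b) / (c / dd), tolerance = 1e-12)
    }
  }
})

test_that("uniform tables give flat profiles; lone-drug SOCs get corrected", {
  tab <- as_contingency_table(matrix(1, 2, 2))
  expect_equal(ror_profile(tab, "c1")$ror, c(1, 1))

  O <- matrix(c(5, 0, 3, 4, 6, 2), 3, 2,
              dimnames = list(c("s1", "s2", "s3"), c("d1", "d2")))
  prof <- ror_profile(as_contingency_table(O), "d2")
  expect_true(prof$corrected[2])  # s2 reported only for d2
})

test_that("outcome odds ratios recover planted rates and flat rates give 1", {
  rec <- make_records(drug = rep(c("a", "b"), each = 4),
                      soc = "Gastr",
                      seriousness = rep(c("serious", "non_serious"), 4))
  expect_equal(outcome_or(rec, "a", "serious")$ror, 1)

  cfg <- two_archetype_config(n_total = 50000, seed = 4L)
  sim <- simulate_icsr(cfg)
  # planted fatal odds ratio: drug1 0.124 vs rest 0.08
  truth <- (0.124 / 0.876) / (0.08 / 0.92)
  r <- outcome_or(sim$records, "drug1", "fatal")
  expect_true(r$ci_low <= truth && truth <= r$ci_high)
})

test_that("not_specified seriousness can be excluded instead of counted negative", {
  rec <- make_records(drug = rep(c("a", "b"), each = 3),
                      soc = "Gastr",
                      seriousness = c("serious", "not_specified", "non_serious",
                                      "serious", "serious", "non_serious"))
  neg <- outcome_or(rec, "a", "serious", not_specified = "negative")
  exc <- outcome_or(rec, "a", "serious", not_specified = "exclude")
  expect_equal(neg$b, 2)
  expect_equal(exc$b, 1)
})
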