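# Contingency tables, margin-product expectations, indexed residuals and
# the per-drug descriptive summaries.

test_that("build_table counts reactions and keeps margins consistent", {
  rec <- make_records(drug = c("a", "a", "b", "b"),
                      soc = c("Gastr", "Nerv", "Gastr", "Nerv"))
  tab <- build_table(rec)
  expect_equal(unname(tab$counts), matrix(1L, 2, 2))
  expect_equal(tab$n, 4)
  expect_equal(unname(tab$row_totals), c(2, 2))

  expect_error(build_table(rec[0, ]), "empty")

  one <- build_table(make_records(drug = "a", soc = c("Gastr", "Nerv", "Gastr")))
  expect_equal(ncol(one$counts), 1)
  expect_equal(unname(one$col_totals), one$n)
})

test_that("synthetic table margins equal an independent groupby recount", {
  sim <- simulate_icsr(synthetic_config(seed = 3L))
  tab <- build_table(sim$records, drugs = oac_drugs(), socs = soc_codes())
  # independent recount via xtabs on the raw records
  oracle <- as.matrix(xtabs(~ soc + drug, sim$records))
  expect_equal(as.vector(tab$counts[rownames(oracle), colnames(oracle)]),
               as.vector(oracle))
  expect_equal(unname(tab$col_totals),
               unname(as.vector(table(factor(sim$records$drug,
                                             levels = oac_drugs())))))
  expect_equal(tab$n, nrow(sim$records))
})

test_that("independence tables yield all-zero indexed residuals", {
  rm <- indexed_residuals(matrix(c(2, 3, 4, 6), 2))  # rank-1: O = R*C/n
  expect_equal(unname(rm$residual), matrix(0, 2, 2))
})

test_that("expected counts follow the margin product and residuals match hand values", {
  O <- matrix(c(10, 20, 30, 40), 2)  # rows: socs, cols: drugs
  rm <- indexed_residuals(O)
  expect_equal(rm$expected[1, 1], 40 * 30 / 100)
  expect_equal(unname(rm$expected),
               outer(rowSums(O), colSums(O)) / sum(O))
  expect_equal(rm$residual[1, 1], 100 * (10 - 12) / 12)
  expect_equal(format_residuals(rm)[1, 2], -16.7)
  # column sums of E reproduce the drug totals
  expect_equal(unname(colSums(rm$expected)), unname(colSums(O)))
  # conservation
  expect_equal(sum(rm$expected), sum(O), tolerance = 1e-12)
})

test_that("zero observed cells give exactly -100% and bound all residuals", {
  O <- matrix(c(0, 5, 4, 3, 2, 6), 3)
  rm <- indexed_residuals(O)
  expect_identical(rm$residual[1, 1], -100)
  expect_true(all(rm$residual >= -100))
  expect_equal(unname(rm$residual == -100), unname(O == 0))
})

test_that("residual row-consistency identity holds on random tables", {
  withr::local_seed(42)
  for (rep in 1:20) {
    O <- rand_table(5, 4)
    rm <- indexed_residuals(O)
    n <- sum(O)
    for (j in seq_len(ncol(O))) {
      lhs <- sum((colSums(O)[j] / n) * rowSums(O) * (1 + rm$residual[, j] / 100))
      expect_equal(lhs, unname(colSums(O)[j]), tolerance = 1e-9)
    }
  }
})

test_that("zero-margin rows are dropped with a warning, empty tables error", {
  O <- matrix(c(3, 0, 2, 5, 0, 1), 3)
  expect_warning(rm <- indexed_residuals(O), "zero-margin")
  expect_equal(nrow(rm$residual), 2)
  expect_error(suppressWarnings(indexed_residuals(matrix(0, 2, 2))))
})

test_that("summarize collapses cases and matches table margins at reaction level", {
  rec <- make_records(drug = "a", soc = c("Gastr", "Nerv"),
                      icsr_id = "case-1", outcome = "fatal")
  s_icsr <- summarize_reports(rec, axis = "outcome", unit = "icsr")
  expect_equal(s_icsr$n[s_icsr$drug == "a" & s_icsr$level == "fatal"], 1L)
  s_adr <- summarize_reports(rec, axis = "outcome", unit = "adr")
  expect_equal(s_adr$n[s_adr$drug == "a" & s_adr$level == "fatal"], 2L)

  sim <- simulate_icsr(synthetic_config(seed = 5L))
  tab <- build_table(sim$records, drugs = oac_drugs())
  s <- summarize_reports(sim$records, axis = "seriousness", unit = "adr")
  totals <- tapply(s$n[s$drug != "Total"], s$drug[s$drug != "Total"], sum)
  expect_equal(as.vector(totals[oac_drugs()]), unname(tab$col_totals))
})

test_that("planted seriousness probability is recovered within 1% at n = 10,000", {
  cfg <- synthetic_config(
    drugs = c(a = 10000L, b = 10000L),
    archetypes = list(p = baseline_soc_mass_for_test()),
    assignment = c(a = "p", b = "p"),
    seriousness_prob = c(a = 0.9, b = 0.9),
    fatal_prob = c(a = 0.1, b = 0.1),
    seed = 2L
  )
  s <- summarize_reports(simulate_icsr(cfg)$records,
                         axis = "seriousness", unit = "adr")
  share <- s$pct[s$drug == "a" & s$level == "serious"] / 100
  expect_lt(abs(share - 0.9), 0.01)
})

test_that("the aggregate fixtures reproduce the published shares", {
  ser <- fixture_shares(oac_adr_counts(), "seriousness")
  expect_equal(ser$pct[ser$drug == "rivaroxaban" & ser$level == "serious"], 95.5)
  out <- fixture_shares(oac_adr_counts(), "outcome", denominator = "adr")
  expect_equal(out$pct[out$drug == "dabigatran" & out$level == "fatal"], 12.4)
})
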