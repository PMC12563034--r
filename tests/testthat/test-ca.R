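# Correspondence analysis: inertia accounting, coordinates, contributions,
# biplot scaling, dimension retention and variable selection.

test_that("independence tables have zero total inertia", {
  fit <- fit_ca(matrix(c(2, 3, 4, 6), 2))  # rank-1: O = R*C/n
  expect_equal(fit$total_inertia, 0, tolerance = 1e-12)
  expect_equal(unname(fit$sv), 0, tolerance = 1e-9)
})

test_that("total inertia equals Pearson chi-square over n on random tables", {
  withr::local_seed(1)
  for (rep in 1:50) {
    O <- rand_table(sample(3:8, 1), sample(3:6, 1))
    fit <- fit_ca(O)
    expect_equal(fit$total_inertia, chisq_stat(O) / sum(O),
                 tolerance = 1e-9)
  }
  # and against the stats engine's statistic on one table
  O <- rand_table(4, 4)
  expect_equal(fit_ca(O)$total_inertia,
               unname(suppressWarnings(chisq.test(O)$statistic)) / sum(O),
               tolerance = 1e-9)
})

test_that("per-dimension contributions sum to one for rows and columns", {
  withr::local_seed(2)
  O <- rand_table(6, 5)
  fit <- fit_ca(O)
  expect_equal(unname(colSums(fit$row_contrib)), rep(1, length(fit$sv)),
               tolerance = 1e-9)
  expect_equal(unname(colSums(fit$col_contrib)), rep(1, length(fit$sv)),
               tolerance = 1e-9)
})

test_that("row principal coordinates reproduce chi-square profile distances", {
  withr::local_seed(3)
  O <- rand_table(4, 3)
  fit <- fit_ca(O)
  n <- sum(O)
  prof <- O / rowSums(O)
  cmass <- colSums(O) / n
  for (i in 1:3) for (j in (i + 1):4) {
    chi_d <- sqrt(sum((prof[i, ] - prof[j, ])^2 / cmass))
    eu_d <- sqrt(sum((fit$row_coord[i, ] - fit$row_coord[j, ])^2))
    expect_equal(eu_d, chi_d, tolerance = 1e-9)
  }
})

test_that("transition formula and mass-weighted orthogonality hold", {
  withr::local_seed(4)
  O <- rand_table(7, 5)
  fit <- fit_ca(O)
  P <- O / sum(O)
  r <- rowSums(P)
  F_from_G <- sweep((P / r) %*% fit$col_coord, 2, fit$sv, `/`)
  expect_equal(unname(F_from_G), unname(fit$row_coord), tolerance = 1e-9)
  K <- length(fit$sv)
  for (k in 1:(K - 1)) for (l in (k + 1):K) {
    expect_equal(sum(r * fit$row_coord[, k] * fit$row_coord[, l]), 0,
                 tolerance = 1e-9)
  }
})

test_that("principal inertias match an independent eigensolver on 3x3 tables", {
  withr::local_seed(5)
  for (rep in 1:20) {
    O <- rand_table(3, 3)
    fit <- fit_ca(O)
    P <- O / sum(O)
    r <- rowSums(P); c <- colSums(P)
    S <- (P - outer(r, c)) / sqrt(outer(r, c))
    ev <- eigen(S %*% t(S), symmetric = TRUE)$values
    expect_equal(unname(fit$inertia), sort(ev, decreasing = TRUE)[1:2],
                 tolerance = 1e-9)
  }
})

test_that("singular values agree with the MASS correspondence cross-check", {
  skip_if_not_installed("MASS")
  withr::local_seed(6)
  O <- rand_table(5, 4)
  fit <- fit_ca(O)
  cc <- MASS::corresp(O, nf = 3)
  expect_equal(unname(fit$sv), unname(cc$cor), tolerance = 1e-8)
})

test_that("biplot vectors carry contribution scaling", {
  withr::local_seed(7)
  fit <- fit_ca(rand_table(6, 4))
  expect_equal(unname(fit$biplot^2), unname(fit$row_contrib),
               tolerance = 1e-12)
})

test_that("dimension retention applies the average-inertia rule with a floor of 2", {
  mock <- structure(list(
    sv = sqrt(c(0.6, 0.3, 0.1, 0, 0)),
    inertia = c(0.6, 0.3, 0.1, 0, 0),
    inertia_share = c(0.6, 0.3, 0.1, 0, 0)
  ), class = "ca_result")
  expect_equal(retain_dimensions(mock), 2)  # criterion 1/5 = 0.2

  mock$inertia_share <- rep(0.2, 5)  # uniform spectrum: nothing exceeds
  expect_equal(retain_dimensions(mock), 2)

  mock$inertia_share <- c(0.4, 0.3, 0.25, 0.05, 0)
  expect_equal(retain_dimensions(mock), 3)
})

test_that("variable selection uses the reciprocal threshold and ranks the driver first", {
  withr::local_seed(8)
  # one SOC concentrated in one drug, everything else uniform
  O <- matrix(10, 8, 4)
  O[1, 1] <- 60
  rownames(O) <- paste0("soc", 1:8); colnames(O) <- paste0("d", 1:4)
  fit <- fit_ca(O)
  sel <- select_variables(fit, top_n = 5)
  expect_equal(sel$threshold, 1 / 8)
  expect_equal(sel$top[1], "soc1")
  expect_true("soc1" %in% sel$selected)

  # uniform table: zero inertia, nothing selected
  flat <- fit_ca(matrix(10, 6, 4))
  sel_flat <- select_variables(flat, dims = 2, top_n = 3)
  expect_equal(length(sel_flat$selected), 0)

  expect_warning(select_variables(fit, top_n = 100), "clamped")
})

test_that("aggregated contributions match a direct inertia-weighted recomputation", {
  withr::local_seed(9)
  O <- rand_table(6, 5)
  fit <- fit_ca(O)
  sel <- select_variables(fit, dims = 2, top_n = 3)
  lam <- fit$inertia[1:2]
  agg <- (fit$row_contrib[, 1] * lam[1] + fit$row_contrib[, 2] * lam[2]) /
    sum(lam)
  expect_equal(sel$contributions$contribution,
               unname(sort(agg, decreasing = TRUE)), tolerance = 1e-12)
})

test_that("identical drug columns coincide; planted clusters separate", {
  O <- matrix(c(10, 20, 30, 10, 20, 30, 40, 5, 15), 3,
              dimnames = list(paste0("s", 1:3), c("a", "b", "c")))
  fit <- fit_ca(O)
  rank <- profile_distance_ranking(fit, dims = 2)
  expect_equal(rank$distance[1], 0, tolerance = 1e-9)
  expect_setequal(c(rank$drug_a[1], rank$drug_b[1]), c("a", "b"))

  sim <- simulate_icsr(two_archetype_config(n_total = 12000, seed = 10L))
  tab <- drop_zero_margins(build_table(apply_filters(sim$records),
                                       drugs = names(sim$truth$assignment)))
  fit2 <- fit_ca(tab)
  rank2 <- profile_distance_ranking(fit2, dims = 2)
  same <- sim$truth$assignment[rank2$drug_a] == sim$truth$assignment[rank2$drug_b]
  expect_lt(max(rank2$distance[same]), min(rank2$distance[!same]))
})

test_that("single retained dimension ranks pairs by dm1 separation", {
  withr::local_seed(11)
  O <- rand_table(5, 4)
  fit <- fit_ca(O)
  rank1 <- profile_distance_ranking(fit, dims = 1)
  gaps <- abs(outer(fit$col_coord[, 1], fit$col_coord[, 1], `-`))
  expect_equal(rank1$distance, sort(gaps[upper.tri(gaps)]), tolerance = 1e-12)
})

test_that("zero margins and degenerate shapes are rejected", {
  O <- matrix(c(1, 0, 2, 0, 3, 0), 2)
  expect_error(fit_ca(rbind(O, 0)), "zero-margin")
  expect_error(fit_ca(matrix(1:3, 3, 1)), "2 x 2")
})
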