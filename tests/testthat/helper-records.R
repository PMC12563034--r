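# Builders for small in-code fixtures.

make_records <- function(drug, soc, outcome = "unknown",
                         seriousness = "serious", icsr_id = NULL,
                         age_band = "65_85", sex = "F", country = "") {
  n <- max(lengths(list(drug, soc, outcome, seriousness)))
  if (is.null(icsr_id)) icsr_id <- sprintf("case-%03d", seq_len(n))
  tibble::tibble(
    icsr_id = rep_len(icsr_id, n),
    drug = rep_len(drug, n),
    soc = rep_len(soc, n),
    seriousness = rep_len(seriousness, n),
    outcome = rep_len(outcome, n),
    age_band = rep_len(age_band, n),
    sex = rep_len(sex, n),
    country = rep_len(country, n)
  )
}

# random strictly positive count matrix with named dims
rand_table <- function(I, J, max_count = 30) {
  m <- matrix(sample.int(max_count, I * J, replace = TRUE), I, J)
  dimnames(m) <- list(paste0("soc", seq_len(I)), paste0("drug", seq_len(J)))
  m
}

# uniform SOC profile over the packaged vocabulary
baseline_soc_mass_for_test <- function() {
  socs <- soc_codes()
  stats::setNames(rep(1 / length(socs), length(socs)), socs)
}

# Pearson chi-square statistic computed cell by cell, independent of fit_ca
chisq_stat <- function(m) {
  n <- sum(m)
  E <- outer(rowSums(m), colSums(m)) / n
  sum((m - E)^2 / E)
}
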