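# Reporting odds ratios: the disproportionality statistic contrasting how
# often a drug-event pair is reported against all other drugs in the
# analysis set.

#' Reporting odds ratio of a 2x2 report-count table
#'
#' Cross-product odds ratio `ROR = (a/b) / (c/d)` of the 2x2 table
#'
#' |              | target drug | other drugs |
#' |--------------|-------------|-------------|
#' | target event | a           | c           |
#' | other events | b           | d           |
#'
#' with a Woolf (log-normal) confidence interval
#' `exp(log ROR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero,
#' the Haldane-Anscombe continuity correction adds 0.5 to all four cells and
#' the result is flagged `corrected`. Vectorized over the four cells.
#'
#' @param a,b,c,d Non-negative counts (recycled to a common length).
#' @param alpha Significance level for the `1 - alpha` interval (default
#'   0.05, i.e. a 95% CI).
#' @return A tibble with columns `a`, `b`, `c`, `d`, `ror`, `ci_low`,
#'   `ci_high`, `corrected`.
#' @export
#' @examples
#' ror(20, 80, 10, 90)
ror <- function(a, b, c, d, alpha = 0.05) {
  cells <- vctrs_recycle(a, b, c, d)
  a <- unname(cells[[1]]); b <- unname(cells[[2]])
  c <- unname(cells[[3]]); d <- unname(cells[[4]])
  if (any(c(a, b, c, d) < 0)) {
    stop("ror: counts must be non-negative", call. = FALSE)
  }
  if (any(a + b == 0) || any(c + d == 0)) {
    stop("ror: a margin is entirely zero (no exposure on one side)",
         call. = FALSE)
  }
  corrected <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  shift <- ifelse(corrected, 0.5, 0)
  a2 <- a + shift; b2 <- b + shift; c2 <- c + shift; d2 <- d + shift
  est <- (a2 / b2) / (c2 / d2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  z <- stats::qnorm(1 - alpha / 2)
  tibble::tibble(
    a = a, b = b, c = c, d = d,
    ror = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se),
    corrected = corrected
  )
}

# minimal common-length recycling without a vctrs dependency
vctrs_recycle <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x else rep(x, length.out = n)
  })
}

#' ROR profile of one drug across all SOCs
#'
#' For each SOC the 2x2 table contrasts the target drug's reports in that
#' SOC against its other reports, and likewise for all other drugs pooled:
#' `a = O[i, j]`, `b = C_j - a`, `c = R_i - a`, `d = n - R_i - C_j + a`.
#'
#' @param table A `contingency_table`.
#' @param drug A column label of `table`.
#' @param alpha Significance level passed to [ror()].
#' @param sort Order rows by descending ROR? Default `FALSE` (table row
#'   order).
#' @return A tibble with columns `drug`, `soc`, `a`, `b`, `c`, `d`, `ror`,
#'   `ci_low`, `ci_high`, `corrected`.
#' @export
ror_profile <- function(table, drug, alpha = 0.05, sort = FALSE) {
  table <- as_contingency_table(table)
  if (!(drug %in% table$drugs)) {
    stop("ror_profile: unknown drug '", drug, "'", call. = FALSE)
  }
  a <- table$counts[, drug]
  b <- table$col_totals[drug] - a
  c <- table$row_totals - a
  d <- table$n - table$row_totals - table$col_totals[drug] + a
  out <- ror(a, b, c, d, alpha = alpha)
  out <- dplyr::bind_cols(tibble::tibble(drug = drug, soc = table$socs), out)
  if (sort) out <- dplyr::arrange(out, dplyr::desc(.data$ror))
  out
}

#' Drug-level odds ratio of a serious or fatal outcome
#'
#' Contrasts the odds of a predicate-positive reaction (serious, or fatal)
#' for one drug against all other drugs pooled, at reaction level.
#' Reactions with `not_specified` seriousness count as non-serious by
#' default (`not_specified = "negative"`); `"exclude"` drops them instead.
#'
#' @param records A validated ADR record tibble covering at least two drugs.
#' @param drug The target drug label.
#' @param predicate `"serious"` or `"fatal"`.
#' @param alpha Significance level passed to [ror()].
#' @param not_specified How `not_specified` seriousness is treated:
#'   `"negative"` (default) or `"exclude"`. Ignored for `"fatal"`.
#' @return A one-row tibble as returned by [ror()].
#' @export
outcome_or <- function(records, drug, predicate = c("serious", "fatal"),
                       alpha = 0.05,
                       not_specified = c("negative", "exclude")) {
  predicate <- match.arg(predicate)
  not_specified <- match.arg(not_specified)
  if (!(drug %in% records$drug)) {
    stop("outcome_or: drug '", drug, "' not present", call. = FALSE)
  }
  if (predicate == "serious") {
    if (not_specified == "exclude") {
      records <- records[records$seriousness != "not_specified", , drop = FALSE]
    }
    pos <- records$seriousness == "serious"
  } else {
    pos <- records$outcome == "fatal"
  }
  tgt <- records$drug == drug
  ror(a = sum(pos & tgt), b = sum(!pos & tgt),
      c = sum(pos & !tgt), d = sum(!pos & !tgt), alpha = alpha)
}
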