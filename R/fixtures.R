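# Packaged aggregate fixtures: the public EudraVigilance oral-anticoagulant
# counts (cases and reactions up to March 2019, adrreports.eu view) and the
# corresponding indexed-residual reference tables. These are the printed
# aggregate surfaces the pipeline reproduces and tests against.

read_fixture <- function(file, col_types) {
  path <- system.file("extdata", file, package = "pvprofile", mustWork = TRUE)
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Aggregate ICSR counts for the oral-anticoagulant analysis set
#'
#' Per-drug individual case safety report (ICSR) totals and their sex and
#' age-band breakdowns, as published in the public aggregated view of
#' EudraVigilance for warfarin, acenocumarol, dabigatran, rivaroxaban,
#' apixaban and edoxaban (reports up to March 2019). Case totals sum to
#' 244,149.
#'
#' @return A long tibble with columns `drug`, `variable` (`icsr`, `sex`,
#'   `age`), `level`, `count`.
#' @export
oac_icsr_counts <- function() {
  read_fixture("ev_oac_icsr_counts.csv", "cccd")
}

#' Aggregate ADR counts for the oral-anticoagulant analysis set
#'
#' Per-drug suspected adverse reaction (ADR) totals and their seriousness
#' and outcome breakdowns from the same public aggregate; reaction totals
#' sum to 431,354. Note that the published outcome rows of some drugs sum
#' to more than the drug's ADR total (an ADR may carry several outcome
#' annotations in the source); the fixture preserves the published counts
#' verbatim.
#'
#' @return A long tibble with columns `drug`, `variable` (`adr`,
#'   `seriousness`, `outcome`), `level`, `count`.
#' @export
oac_adr_counts <- function() {
  read_fixture("ev_oac_adr_counts.csv", "cccd")
}

#' Published indexed-residual reference tables
#'
#' The published one-decimal indexed-residual percentages for the
#' oral-anticoagulant drug-by-SOC tables, overall and restricted to fatal
#' reactions (after the confounder exclusions of [filter_spec()]). Useful
#' as a comparison surface for [indexed_residuals()] output and to derive
#' realistic per-drug SOC profiles for the synthetic generator.
#'
#' @param outcome `"overall"` or `"fatal"`.
#' @return A tibble with a `soc` column and one numeric column per drug.
#' @export
oac_residual_reference <- function(outcome = c("overall", "fatal")) {
  outcome <- match.arg(outcome)
  read_fixture(sprintf("ev_oac_residuals_%s.csv", outcome),
               readr::cols(soc = readr::col_character(),
                           .default = readr::col_double()))
}

#' Percentage shares of an aggregate fixture axis
#'
#' Computes per-drug percentage shares (against each drug's own total, plus
#' a pooled `"Total"` drug) for one variable of an aggregate count fixture,
#' using the same share-and-rounding rules as [summarize_reports()].
#'
#' @param counts A long count tibble as returned by [oac_icsr_counts()] or
#'   [oac_adr_counts()].
#' @param variable Which `variable` value to summarize (e.g. `"seriousness"`,
#'   `"outcome"`, `"age"`, `"icsr"`).
#' @param denominator Optional `variable` whose per-drug totals serve as the
#'   percentage denominator. By default each drug's denominator is the sum
#'   of its own levels; the published outcome rows can carry several
#'   annotations per reaction and over-sum the reaction totals, so outcome
#'   shares are quoted against the `"adr"` totals
#'   (`denominator = "adr"`).
#' @return A tibble with columns `drug`, `level`, `n`, `pct`.
#' @export
#' @examples
#' shares <- fixture_shares(oac_adr_counts(), "seriousness")
#' shares[shares$drug == "rivaroxaban" & shares$level == "serious", ]
fixture_shares <- function(counts, variable, denominator = NULL) {
  df <- counts[counts$variable == variable, c("drug", "level", "count")]
  if (nrow(df) == 0) {
    stop("fixture_shares: no rows with variable '", variable, "'",
         call. = FALSE)
  }
  names(df)[names(df) == "count"] <- "n"
  if (is.null(denominator)) {
    return(add_shares(df))
  }
  den <- counts[counts$variable == denominator, c("drug", "count")]
  if (nrow(den) == 0) {
    stop("fixture_shares: no rows with denominator variable '",
         denominator, "'", call. = FALSE)
  }
  den_map <- c(stats::setNames(den$count, den$drug), Total = sum(den$count))
  df <- dplyr::bind_rows(
    df,
    dplyr::summarise(dplyr::group_by(df, .data$level),
                     n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(drug = "Total")
  )
  dplyr::mutate(df,
                pct = unname(round_half_up(100 * .data$n /
                                             den_map[.data$drug], 1)))
}

#' Across-drug shares of per-drug totals
#'
#' Shares of the grand total held by each drug, e.g. each drug's share of
#' all cases in the analysis set. Complements [fixture_shares()], whose
#' percentages are within-drug.
#'
#' @param counts A long count tibble ([oac_icsr_counts()] /
#'   [oac_adr_counts()]).
#' @param variable The totals variable, `"icsr"` or `"adr"`.
#' @return A tibble with columns `drug`, `n`, `pct` (half-up, one decimal).
#' @export
fixture_drug_shares <- function(counts, variable = c("icsr", "adr")) {
  variable <- match.arg(variable)
  df <- counts[counts$variable == variable, c("drug", "count")]
  names(df)[names(df) == "count"] <- "n"
  dplyr::mutate(df, pct = round_half_up(100 * .data$n / sum(.data$n), 1))
}
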