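# Controlled vocabularies for SOC-level spontaneous-report data.

#' MedDRA system organ class vocabulary
#'
#' Returns the controlled vocabulary of system organ class (SOC) short codes
#' used throughout the package, together with the full MedDRA SOC names.
#' The vocabulary covers the 26 SOC codes that appear in drug-by-SOC
#' aggregate tables plus `"Soc"` (social circumstances), which the default
#' analysis filters remove.
#'
#' @param include_social Keep the `"Soc"` (social circumstances) entry?
#'   Default `TRUE`.
#' @return A tibble with columns `code` and `name`; `code` is unique.
#' @export
#' @examples
#' soc_vocabulary()
soc_vocabulary <- function(include_social = TRUE) {
  path <- system.file("extdata", "soc_vocabulary.csv", package = "pvprofile",
                      mustWork = TRUE)
  voc <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  if (!include_social) {
    voc <- voc[voc$code != "Soc", , drop = FALSE]
  }
  voc
}

#' @rdname soc_vocabulary
#' @export
soc_codes <- function(include_social = TRUE) {
  soc_vocabulary(include_social = include_social)$code
}

#' Closed enumeration levels of an ADR record
#'
#' The categorical levels used by the public aggregated view of a
#' spontaneous-reporting database: seriousness, outcome, age band and sex.
#' Values outside these sets are coerced to `not_specified` on read.
#'
#' @return A named list of character vectors.
#' @export
adr_levels <- function() {
  list(
    seriousness = c("serious", "non_serious", "not_specified"),
    outcome     = c("fatal", "not_recovered", "not_specified", "recovered",
                    "recovered_with_sequelae", "recovering", "unknown"),
    age_band    = c("under_18", "18_64", "65_85", "over_85", "not_specified"),
    sex         = c("F", "M", "not_specified")
  )
}

#' Default oral anticoagulant analysis set
#'
#' The six oral anticoagulants of the packaged EudraVigilance aggregate
#' fixtures: two vitamin K antagonists and four direct (novel) oral
#' anticoagulants.
#'
#' @return Character vector of drug labels.
#' @export
oac_drugs <- function() {
  c("warfarin", "acenocumarol", "dabigatran",
    "rivaroxaban", "apixaban", "edoxaban")
}
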