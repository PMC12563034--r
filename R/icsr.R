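# ICSR line-list data model: readers, writers, validation and the
# confounder-exclusion filters applied before disproportionality and
# correspondence analysis.

line_list_columns <- function() {
  c("icsr_id", "drug", "soc", "seriousness", "outcome",
    "age_band", "sex", "country")
}

# Coerce one enum column: values outside the closed level set (including
# empty strings and NA) become "not_specified", with a single warning
# naming the column and the offending values.
coerce_enum <- function(x, levels, column) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  bad <- !(x %in% levels)
  if (any(bad)) {
    shown <- unique(x[bad])
    shown <- shown[shown != ""]
    if (length(shown) > 0) {
      warning(sprintf("column '%s': %d value(s) outside {%s} coerced to not_specified: %s",
                      column, sum(bad), paste(levels, collapse = ", "),
                      paste(utils::head(shown, 5), collapse = ", ")),
              call. = FALSE)
    }
    x[bad] <- "not_specified"
  }
  x
}

# Shared validator turning a raw data frame into a validated ADR record
# tibble. One row = one suspected reaction; several rows may share an
# icsr_id (one case, several reactions).
as_adr_records <- function(df, drugs = NULL, socs = soc_codes()) {
  lv <- adr_levels()
  df <- tibble::as_tibble(df)

  id <- as.character(df$icsr_id)
  if (any(is.na(id) | id == "")) {
    stop("validation error: icsr_id must be non-empty for every row", call. = FALSE)
  }

  soc <- as.character(df$soc)
  unknown_soc <- setdiff(unique(soc), socs)
  if (length(unknown_soc) > 0) {
    stop("validation error: unknown SOC code(s): ",
         paste(unknown_soc, collapse = ", "), call. = FALSE)
  }

  drug <- as.character(df$drug)
  if (!is.null(drugs)) {
    unknown_drug <- setdiff(unique(drug), drugs)
    if (length(unknown_drug) > 0) {
      stop("validation error: unknown drug name(s): ",
           paste(unknown_drug, collapse = ", "),
           " (drug labels define the analysis columns and are never coerced)",
           call. = FALSE)
    }
  }

  country <- if ("country" %in% names(df)) as.character(df$country) else ""
  country[is.na(country)] <- ""

  tibble::tibble(
    icsr_id     = id,
    drug        = drug,
    soc         = soc,
    seriousness = coerce_enum(df$seriousness, lv$seriousness, "seriousness"),
    outcome     = coerce_enum(df$outcome, lv$outcome, "outcome"),
    age_band    = coerce_enum(df$age_band, lv$age_band, "age_band"),
    sex         = coerce_enum(df$sex, lv$sex, "sex"),
    country     = country
  )
}

#' Read an ICSR line list from CSV
#'
#' One row per suspected adverse drug reaction (ADR); reactions belonging to
#' the same individual case safety report share an `icsr_id`. Expected
#' columns are `icsr_id, drug, soc, seriousness, outcome, age_band, sex,
#' country` (comma-separated, UTF-8, header mandatory); `schema` remaps
#' non-standard headers. Enumerated fields outside their closed level sets
#' are coerced to `not_specified` with a warning; unknown SOC codes, empty
#' case ids and (when `drugs` is given) unknown drug names are errors.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping standard column
#'   names to the file's column names, e.g. `c(icsr_id = "CaseID")`.
#' @param drugs Optional character vector of admissible drug labels; rows
#'   with other drug names raise an error rather than being coerced.
#' @param socs Admissible SOC codes (default: the packaged vocabulary).
#' @return A tibble of validated ADR records, one row per reaction.
#' @seealso [write_line_list()], [apply_filters()]
#' @export
read_line_list <- function(path, schema = NULL, drugs = NULL,
                           socs = soc_codes()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  std <- line_list_columns()
  lookup <- stats::setNames(std, std)
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    lookup[names(schema)] <- unname(schema)
  }
  mandatory <- setdiff(std, "country")
  missing <- mandatory[!(lookup[mandatory] %in% names(raw))]
  if (length(missing) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(sprintf("'%s' (expected header '%s')", missing, lookup[missing]),
               collapse = ", "),
         call. = FALSE)
  }
  present <- std[lookup[std] %in% names(raw)]
  df <- raw[, lookup[present], drop = FALSE]
  names(df) <- present
  as_adr_records(df, drugs = drugs, socs = socs)
}

#' Write an ICSR line list to CSV
#'
#' Inverse of [read_line_list()]: writes the standard eight columns so that
#' reading the file back reproduces the records field-by-field.
#'
#' @param records A validated ADR record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_line_list <- function(records, path) {
  readr::write_csv(records[, line_list_columns()], path, progress = FALSE)
  invisible(path)
}

#' Exclusion filters for confounder-prone SOC categories
#'
#' The analysis removes reaction categories judged confounder-prone before
#' profiling: social circumstances (`"Soc"`, which holds conditions such as
#' 'elderly' or 'economic problem') from every analysis, and, for the
#' fatal-outcome analysis, additional SOCs whose fatal reports are
#' implausible as drug effects (ear and eye disorders, investigations,
#' surgical procedures, product issues).
#'
#' @param excluded_socs_overall SOC codes removed from every analysis.
#' @param excluded_socs_fatal SOC codes additionally removed from the
#'   fatal-only analysis.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(excluded_socs_overall = "Soc",
                        excluded_socs_fatal = c("Ear", "Eye", "Inv",
                                                "Surg", "Product")) {
  known <- soc_codes()
  bad <- setdiff(c(excluded_socs_overall, excluded_socs_fatal), known)
  if (length(bad) > 0) {
    stop("filter_spec: unknown SOC code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(excluded_socs_overall = unique(excluded_socs_overall),
         excluded_socs_fatal = unique(excluded_socs_fatal)),
    class = "filter_spec"
  )
}

#' Apply the confounder-exclusion filters to ADR records
#'
#' With `fatal_only = FALSE`, removes records whose SOC is in the overall
#' exclusion set. With `fatal_only = TRUE`, keeps only records with a fatal
#' outcome and applies both the overall and the fatal exclusion sets. Row
#' order of the survivors is preserved, and the operation is idempotent.
#'
#' @param records A validated ADR record tibble.
#' @param spec A [filter_spec()].
#' @param fatal_only Restrict to fatal-outcome reactions?
#' @return The filtered record tibble (possibly empty).
#' @export
apply_filters <- function(records, spec = filter_spec(), fatal_only = FALSE) {
  stopifnot(inherits(spec, "filter_spec"))
  if (fatal_only) {
    drop_socs <- union(spec$excluded_socs_overall, spec$excluded_socs_fatal)
    keep <- records$outcome == "fatal" & !(records$soc %in% drop_socs)
  } else {
    keep <- !(records$soc %in% spec$excluded_socs_overall)
  }
  records[keep, , drop = FALSE]
}
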