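# Drug-by-SOC contingency tables, margin-product expected counts, indexed
# residuals and per-drug descriptive summary tables.

#' Build a SOC-by-drug contingency table from ADR records
#'
#' Counts reactions (not cases): `O[i, j]` is the number of ADR records
#' with SOC `i` and drug `j`. SOCs index rows and drugs index columns.
#'
#' @param records A validated ADR record tibble (non-empty).
#' @param drugs Ordered drug labels defining the columns; defaults to the
#'   sorted drugs present. Records with drugs outside this set are an error.
#' @param socs Ordered SOC codes defining the rows; defaults to the sorted
#'   SOCs present.
#' @return A `contingency_table`: list with `counts` (integer matrix),
#'   `row_totals`, `col_totals`, `n`, `socs`, `drugs`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   icsr_id = as.character(1:4), drug = c("a", "a", "b", "b"),
#'   soc = c("Gastr", "Nerv", "Gastr", "Nerv"),
#'   seriousness = "serious", outcome = "unknown",
#'   age_band = "65_85", sex = "F", country = ""
#' )
#' build_table(rec)
build_table <- function(records, drugs = NULL, socs = NULL) {
  if (nrow(records) == 0) {
    stop("build_table: empty record set (no degenerate table allowed)",
         call. = FALSE)
  }
  if (is.null(drugs)) drugs <- sort(unique(records$drug))
  if (is.null(socs)) socs <- sort(unique(records$soc))
  bad_drug <- setdiff(unique(records$drug), drugs)
  if (length(bad_drug) > 0) {
    stop("build_table: record drug(s) outside the analysis set: ",
         paste(bad_drug, collapse = ", "), call. = FALSE)
  }
  bad_soc <- setdiff(unique(records$soc), socs)
  if (length(bad_soc) > 0) {
    stop("build_table: record SOC(s) outside the analysis set: ",
         paste(bad_soc, collapse = ", "), call. = FALSE)
  }
  counts <- table(factor(records$soc, levels = socs),
                  factor(records$drug, levels = drugs))
  counts <- matrix(as.integer(counts), nrow = length(socs),
                   dimnames = list(soc = socs, drug = drugs))
  new_contingency_table(counts)
}

new_contingency_table <- function(counts) {
  structure(
    list(counts = counts,
         row_totals = rowSums(counts),
         col_totals = colSums(counts),
         n = sum(counts),
         socs = rownames(counts),
         drugs = colnames(counts)),
    class = "contingency_table"
  )
}

#' Coerce a count matrix to a contingency table
#'
#' @param x A non-negative numeric matrix with SOCs (or any row entities) as
#'   rows and drugs as columns, or an existing `contingency_table`.
#' @return A `contingency_table`.
#' @export
as_contingency_table <- function(x) {
  if (inherits(x, "contingency_table")) return(x)
  x <- as.matrix(x)
  if (any(x < 0) || any(!is.finite(x))) {
    stop("as_contingency_table: counts must be finite and non-negative",
         call. = FALSE)
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("r", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  new_contingency_table(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("SOC x drug contingency table: %d SOCs x %d drugs, n = %s reactions\n",
              nrow(x$counts), ncol(x$counts), format(x$n, big.mark = ",")))
  print(x$counts)
  invisible(x)
}

#' Drop zero-margin rows and columns
#'
#' Rows (SOCs) or columns (drugs) with a zero total carry no information for
#' residual or correspondence analysis and are removed with a warning; a
#' fatal-only table can lose entire SOCs this way.
#'
#' @param table A `contingency_table`.
#' @return A `contingency_table` with strictly positive margins.
#' @export
drop_zero_margins <- function(table) {
  table <- as_contingency_table(table)
  keep_r <- table$row_totals > 0
  keep_c <- table$col_totals > 0
  if (!all(keep_r) || !all(keep_c)) {
    dropped <- c(table$socs[!keep_r], table$drugs[!keep_c])
    warning("dropping zero-margin row(s)/column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    table <- new_contingency_table(
      table$counts[keep_r, keep_c, drop = FALSE])
  }
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0 || table$n == 0) {
    stop("indexed_residuals: table empty after dropping zero margins",
         call. = FALSE)
  }
  table
}

#' Indexed residuals against margin-product expectations
#'
#' For each drug-SOC cell the expected count under independence is
#' `E[i,j] = R_i * C_j / n` (row total times column total over the grand
#' total), and the indexed residual is the relative deviation
#' `r[i,j] = 100 * (O - E) / E`, a signed percentage. A zero observed count
#' with positive margins yields exactly -100%; positive values mean the
#' drug-SOC pair is reported more often than its margins predict.
#'
#' @param table A `contingency_table` or count matrix. Zero-margin rows or
#'   columns are dropped with a warning before computation.
#' @return A `residual_matrix`: list with `observed`, `expected`,
#'   `residual` (percent), `socs`, `drugs`, `n`.
#' @export
indexed_residuals <- function(table) {
  table <- drop_zero_margins(as_contingency_table(table))
  expected <- outer(table$row_totals, table$col_totals) / table$n
  residual <- 100 * (table$counts - expected) / expected
  structure(
    list(observed = table$counts, expected = expected, residual = residual,
         socs = table$socs, drugs = table$drugs, n = table$n),
    class = "residual_matrix"
  )
}

#' @export
print.residual_matrix <- function(x, ...) {
  cat(sprintf("Indexed residuals (%% deviation from expected), %d SOCs x %d drugs\n",
              nrow(x$residual), ncol(x$residual)))
  print(format_residuals(x))
  invisible(x)
}

# Round half away from zero (commercial rounding); base round() is
# round-half-even, which table exports must not use.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format indexed residuals as a one-decimal percentage table
#'
#' @param x A `residual_matrix`.
#' @return A data frame with a `soc` column and one signed one-decimal
#'   percentage column per drug (half-up rounding).
#' @export
format_residuals <- function(x) {
  stopifnot(inherits(x, "residual_matrix"))
  out <- as.data.frame(round_half_up(x$residual, 1))
  cbind(soc = x$socs, out, row.names = NULL)
}

# Attach per-drug percentage shares (against each drug's own total) plus a
# pooled "Total" drug to a long count table.
add_shares <- function(df) {
  df <- dplyr::bind_rows(
    df,
    dplyr::summarise(dplyr::group_by(df, .data$level),
                     n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(drug = "Total")
  )
  dplyr::mutate(dplyr::group_by(df, .data$drug),
                pct = round_half_up(100 * .data$n / sum(.data$n), 1)) |>
    dplyr::ungroup()
}

#' Per-drug descriptive summary of a categorical axis
#'
#' Tallies records per drug along one categorical axis, either at reaction
#' level (`unit = "adr"`) or collapsed to one row per case
#' (`unit = "icsr"`, using each case's first record for its attributes).
#' Percentages are computed against each drug's own total (plus a pooled
#' `"Total"` drug) and rounded half-up to one decimal.
#'
#' @param records A validated ADR record tibble.
#' @param axis One of `"sex"`, `"age"`, `"seriousness"`, `"outcome"`,
#'   `"country"`.
#' @param unit Counting unit: `"adr"` (reactions) or `"icsr"` (cases).
#' @return A tibble with columns `drug`, `level`, `n`, `pct`.
#' @export
summarize_reports <- function(records,
                              axis = c("sex", "age", "seriousness",
                                       "outcome", "country"),
                              unit = c("adr", "icsr")) {
  axis <- match.arg(axis)
  unit <- match.arg(unit)
  col <- switch(axis, sex = "sex", age = "age_band",
                seriousness = "seriousness", outcome = "outcome",
                country = "country")
  if (unit == "icsr") {
    records <- dplyr::slice_head(
      dplyr::group_by(records, .data$drug, .data$icsr_id), n = 1) |>
      dplyr::ungroup()
  }
  counts <- dplyr::count(records, drug = .data$drug, level = .data[[col]])
  # make absent levels explicit zeros so table shapes are stable
  lv <- adr_levels()[[col]]
  if (!is.null(lv)) {
    counts <- tidyr::complete(counts,
                              drug = unique(records$drug),
                              level = lv, fill = list(n = 0L))
  }
  add_shares(counts)
}
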