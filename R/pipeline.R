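# End-to-end orchestration: read -> filter -> summarize -> contingency ->
# residuals -> ROR profiles -> correspondence analysis (overall and
# fatal-only), with CSV exports and a hashed manifest for reproducibility.

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

write_stage_csv <- function(df, outdir, file) {
  path <- file.path(outdir, file)
  readr::write_csv(df, path, progress = FALSE)
  path
}

analysis_outputs <- function(records, drugs, label, alpha, top_n, outdir) {
  files <- character(0)
  if (nrow(records) == 0) {
    message("pipeline: no records for the ", label, " analysis; skipping")
    return(files)
  }
  table <- with_stage(paste0("contingency (", label, ")"), {
    drop_zero_margins(build_table(records, drugs = drugs))
  })
  message(sprintf("pipeline: %s table %d SOCs x %d drugs, n = %d",
                  label, length(table$socs), length(table$drugs), table$n))

  files <- c(files, with_stage(paste0("residuals (", label, ")"), {
    write_stage_csv(format_residuals(indexed_residuals(table)),
                    outdir, sprintf("residuals_%s.csv", label))
  }))

  files <- c(files, with_stage(paste0("ror (", label, ")"), {
    prof <- dplyr::bind_rows(lapply(table$drugs, function(d) {
      ror_profile(table, d, alpha = alpha)
    }))
    write_stage_csv(prof[, c("drug", "soc", "ror", "ci_low", "ci_high",
                             "corrected")],
                    outdir, sprintf("ror_%s.csv", label))
  }))

  if (length(table$socs) >= 2 && length(table$drugs) >= 2) {
    files <- c(files, with_stage(paste0("ca (", label, ")"), {
      fit <- fit_ca(table)
      dims <- retain_dimensions(fit)
      sel <- select_variables(fit, dims = dims, top_n = top_n)
      c(write_stage_csv(ca_coordinates(fit, dims = max(dims, 2)),
                        outdir, sprintf("ca_%s_coordinates.csv", label)),
        write_stage_csv(ca_inertia(fit),
                        outdir, sprintf("ca_%s_inertia.csv", label)),
        write_stage_csv(sel$contributions,
                        outdir, sprintf("ca_%s_top_variables.csv", label)))
    }))
  }
  files
}

#' Run the full safety-profiling pipeline
#'
#' Executes, on one ICSR line list, the complete analysis: descriptive
#' summaries (sex and age at case level, seriousness and outcome at
#' reaction level, computed before any exclusion), confounder filtering,
#' SOC-by-drug contingency tables with indexed residuals, per-drug ROR
#' profiles, and correspondence analysis with contribution-biplot
#' coordinates — each twice, overall and restricted to fatal reactions.
#' Every artifact is written as CSV and listed, with its MD5 hash, in
#' `manifest.json`; identical inputs and configuration yield identical
#' hashes.
#'
#' @param records A validated ADR record tibble, or a path to a line-list
#'   CSV readable by [read_line_list()].
#' @param outdir Output directory (created if absent).
#' @param drugs Ordered drug labels defining the analysis columns; default:
#'   drugs present in the data.
#' @param filters A [filter_spec()].
#' @param alpha Significance level for ROR confidence intervals.
#' @param exclude_socs Optional extra SOC codes removed before a sensitivity
#'   re-fit of the overall correspondence analysis (written as
#'   `ca_sensitivity_*` files); the main analyses are unchanged.
#' @param top_n Number of top SOC variables reported per analysis.
#' @return Invisibly, a tibble manifest with columns `file`, `md5`.
#' @export
run_pipeline <- function(records, outdir, drugs = NULL,
                         filters = filter_spec(), alpha = 0.05,
                         exclude_socs = character(0), top_n = 5) {
  if (is.character(records) && length(records) == 1) {
    records <- with_stage("read", read_line_list(records, drugs = drugs))
  }
  if (nrow(records) == 0) {
    stop("pipeline stage 'validate' failed: empty record set", call. = FALSE)
  }
  if (is.null(drugs)) drugs <- sort(unique(records$drug))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  # descriptive summaries on the unfiltered data (totals before exclusion)
  files <- c(files, with_stage("summarize", {
    unlist(lapply(
      list(c("sex", "icsr"), c("age", "icsr"),
           c("seriousness", "adr"), c("outcome", "adr")),
      function(ax) {
        write_stage_csv(summarize_reports(records, axis = ax[1],
                                          unit = ax[2]),
                        outdir, sprintf("summary_%s.csv", ax[1]))
      }))
  }))

  rec_overall <- with_stage("filter (overall)", {
    apply_filters(records, filters, fatal_only = FALSE)
  })
  message(sprintf("pipeline: overall filter kept %d of %d reactions",
                  nrow(rec_overall), nrow(records)))
  rec_fatal <- with_stage("filter (fatal)", {
    apply_filters(records, filters, fatal_only = TRUE)
  })
  message(sprintf("pipeline: fatal filter kept %d of %d reactions",
                  nrow(rec_fatal), nrow(records)))

  files <- c(files,
             analysis_outputs(rec_overall, drugs, "overall", alpha, top_n,
                              outdir),
             analysis_outputs(rec_fatal, drugs, "fatal", alpha, top_n,
                              outdir))

  if (length(exclude_socs) > 0) {
    files <- c(files, with_stage("ca (sensitivity)", {
      rec_sens <- rec_overall[!(rec_overall$soc %in% exclude_socs), ,
                              drop = FALSE]
      tab <- drop_zero_margins(build_table(rec_sens, drugs = drugs))
      fit <- fit_ca(tab)
      dims <- retain_dimensions(fit)
      c(write_stage_csv(ca_coordinates(fit, dims = max(dims, 2)),
                        outdir, "ca_sensitivity_coordinates.csv"),
        write_stage_csv(ca_inertia(fit), outdir,
                        "ca_sensitivity_inertia.csv"))
    }))
  }

  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
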