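# Synthetic ICSR line-list generator. Emulates the statistical structure
# the analysis assumes — per-drug report volumes, multinomial SOC profiles
# with planted similarity clusters, seriousness/outcome and demographic
# distributions — so the whole pipeline is testable offline with known
# ground truth.

# Baseline SOC reporting mass for an anticoagulant-like portfolio:
# gastrointestinal and nervous system disorders dominate (together ~30% of
# reactions, as in the aggregate source), a small social-circumstances mass
# exercises the exclusion filter, the rest decays over the usual
# pharmacovigilance suspects. Normalized on use.
baseline_soc_mass <- function() {
  m <- c(
    Gastr = 0.170, Nerv = 0.133, Genrl = 0.085, `Inj&P` = 0.075,
    Vasc = 0.070, Inv = 0.065, Resp = 0.055, Musc = 0.045, Skin = 0.042,
    Psych = 0.038, Card = 0.038, Renal = 0.032, Infec = 0.030,
    Blood = 0.028, Surg = 0.025, Metab = 0.022, Eye = 0.018,
    Hepato = 0.015, Neopl = 0.014, Ear = 0.010, Immun = 0.008,
    Repro = 0.008, Endo = 0.005, Preg = 0.004, Product = 0.004,
    Cong = 0.003, Soc = 0.004
  )
  m / sum(m)
}

normalize_prob <- function(p, what) {
  if (any(p < 0) || any(!is.finite(p))) {
    stop("synthetic_config: ", what, " must be finite and non-negative",
         call. = FALSE)
  }
  s <- sum(p)
  if (s <= 0) stop("synthetic_config: ", what, " sums to zero", call. = FALSE)
  p / s
}

#' Configuration for the synthetic ICSR generator
#'
#' The default configuration mirrors the packaged oral-anticoagulant
#' aggregate at 1/100 scale (about 4,300 reactions in 2,400 cases, so tests
#' run in seconds): per-drug reaction volumes, seriousness and fatality
#' probabilities and demographic distributions are taken from the aggregate
#' fixtures, and each drug's SOC archetype is derived by tilting a baseline
#' SOC mass by the drug's published indexed residuals
#' (`profile ~ mass * (1 + residual/100)`). Supplying explicit
#' `archetypes`/`assignment` plants similarity clusters instead.
#'
#' @param drugs Named integer vector: target reaction volume `n_d` per drug
#'   (all >= 1).
#' @param archetypes List of named probability vectors over `soc_levels`
#'   (each normalized to sum to one).
#' @param assignment Character/integer vector mapping each drug to an
#'   archetype (names or indices into `archetypes`), same length as
#'   `drugs`.
#' @param alpha Cluster tightness in `[0, 1]`: each drug samples SOCs from
#'   `alpha * archetype + (1 - alpha) * global mean archetype`. `alpha = 1`
#'   gives pure archetypes, `alpha = 0` one shared profile (drug and SOC
#'   independent).
#' @param seriousness_prob Named per-drug probability a reaction is serious.
#' @param fatal_prob Named per-drug probability a reaction's outcome is
#'   fatal.
#' @param nonfatal_outcome_probs Named probability vector over the
#'   non-fatal outcome levels.
#' @param adrs_per_icsr List `(mean, max)`: reactions per case follow a
#'   geometric distribution on `{1, 2, ...}` with the given mean, truncated
#'   at `max`.
#' @param age_probs,sex_probs Named categorical distributions over the age
#'   band and sex levels.
#' @param country_probs Named categorical distribution over country codes.
#' @param soc_levels SOC codes the archetypes are defined over.
#' @param seed Default RNG seed for [simulate_icsr()].
#' @return A validated `synthetic_config` object.
#' @export
synthetic_config <- function(drugs = NULL,
                             archetypes = NULL,
                             assignment = NULL,
                             alpha = 1,
                             seriousness_prob = NULL,
                             fatal_prob = NULL,
                             nonfatal_outcome_probs = NULL,
                             adrs_per_icsr = list(mean = 1.77, max = 10),
                             age_probs = NULL,
                             sex_probs = NULL,
                             country_probs = c(FR = 0.3, IT = 0.25,
                                               DE = 0.25, UK = 0.2),
                             soc_levels = soc_codes(),
                             seed = 1L) {
  adr_fix <- oac_adr_counts()
  icsr_fix <- oac_icsr_counts()

  if (is.null(drugs)) {
    tot <- adr_fix[adr_fix$variable == "adr", ]
    drugs <- stats::setNames(pmax(1L, as.integer(round(tot$count / 100))),
                             tot$drug)
  }
  if (is.null(names(drugs)) || any(names(drugs) == "")) {
    stop("synthetic_config: drugs must be a named vector of volumes",
         call. = FALSE)
  }
  if (any(drugs < 1)) {
    stop("synthetic_config: every drug needs a reaction volume >= 1",
         call. = FALSE)
  }
  drugs <- stats::setNames(as.integer(drugs), names(drugs))

  if (is.null(archetypes)) {
    # one archetype per drug, tilted by the published residual table
    res <- oac_residual_reference("overall")
    base <- baseline_soc_mass()[soc_levels]
    if (any(is.na(base))) {
      stop("synthetic_config: default archetypes need the packaged SOC codes",
           call. = FALSE)
    }
    archetypes <- lapply(names(drugs), function(d) {
      tilt <- stats::setNames(rep(0, length(soc_levels)), soc_levels)
      if (d %in% names(res)) {
        tilt[res$soc] <- res[[d]] / 100
      }
      normalize_prob(base * pmax(1 + tilt, 0.01), paste0("archetype ", d))
    })
    names(archetypes) <- names(drugs)
    if (is.null(assignment)) assignment <- stats::setNames(names(drugs),
                                                           names(drugs))
  }
  if (is.null(assignment)) {
    if (length(archetypes) != length(drugs)) {
      stop("synthetic_config: provide an assignment when archetypes and drugs differ in number",
           call. = FALSE)
    }
    assignment <- stats::setNames(seq_along(drugs), names(drugs))
  }
  if (is.null(names(assignment))) names(assignment) <- names(drugs)
  if (!setequal(names(assignment), names(drugs))) {
    stop("synthetic_config: assignment must map every drug", call. = FALSE)
  }
  archetypes <- lapply(archetypes, function(p) {
    p <- p[soc_levels]
    if (any(is.na(p))) {
      stop("synthetic_config: archetypes must be named over soc_levels",
           call. = FALSE)
    }
    normalize_prob(p, "archetype")
  })
  ok <- vapply(archetypes,
               function(p) abs(sum(p) - 1) < 1e-12, logical(1))
  stopifnot(all(ok))

  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("synthetic_config: alpha must lie in [0, 1]", call. = FALSE)
  }

  fix_share <- function(variable, level, fixture) {
    sub <- fixture[fixture$variable == variable, ]
    tot <- tapply(sub$count, sub$drug, sum)
    lvl <- sub[sub$level == level, ]
    stats::setNames(lvl$count / tot[lvl$drug], lvl$drug)
  }
  if (is.null(seriousness_prob)) {
    seriousness_prob <- fix_share("seriousness", "serious", adr_fix)
  }
  if (is.null(fatal_prob)) {
    # outcome rows of the source can exceed the ADR total; use the fatal
    # count against the drug's ADR total, the unit the shares are quoted in
    tot <- adr_fix[adr_fix$variable == "adr", ]
    fat <- adr_fix[adr_fix$variable == "outcome" & adr_fix$level == "fatal", ]
    fatal_prob <- stats::setNames(
      fat$count / tot$count[match(fat$drug, tot$drug)], fat$drug)
  }
  for (nm in c("seriousness_prob", "fatal_prob")) {
    p <- get(nm)
    missing <- setdiff(names(drugs), names(p))
    if (length(missing) > 0) {
      stop("synthetic_config: ", nm, " missing for drug(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    if (any(p < 0 | p > 1)) {
      stop("synthetic_config: ", nm, " must lie in [0, 1]", call. = FALSE)
    }
  }

  lv <- adr_levels()
  if (is.null(nonfatal_outcome_probs)) {
    out <- adr_fix[adr_fix$variable == "outcome" & adr_fix$level != "fatal", ]
    tot <- tapply(out$count, out$level, sum)
    nonfatal_outcome_probs <- normalize_prob(
      stats::setNames(as.numeric(tot), names(tot)), "nonfatal_outcome_probs")
  }
  nonfatal_levels <- setdiff(lv$outcome, "fatal")
  if (!setequal(names(nonfatal_outcome_probs), nonfatal_levels)) {
    stop("synthetic_config: nonfatal_outcome_probs must cover exactly the non-fatal outcome levels",
         call. = FALSE)
  }
  nonfatal_outcome_probs <-
    normalize_prob(nonfatal_outcome_probs[nonfatal_levels],
                   "nonfatal_outcome_probs")

  fix_cat <- function(variable, levels) {
    sub <- icsr_fix[icsr_fix$variable == variable, ]
    tot <- tapply(sub$count, sub$level, sum)
    normalize_prob(stats::setNames(as.numeric(tot[levels]), levels), variable)
  }
  if (is.null(age_probs)) age_probs <- fix_cat("age", lv$age_band)
  if (is.null(sex_probs)) sex_probs <- fix_cat("sex", lv$sex)
  age_probs <- normalize_prob(age_probs[lv$age_band], "age_probs")
  sex_probs <- normalize_prob(sex_probs[lv$sex], "sex_probs")
  country_probs <- normalize_prob(country_probs, "country_probs")

  if (!is.list(adrs_per_icsr) || is.null(adrs_per_icsr$mean) ||
      is.null(adrs_per_icsr$max) || adrs_per_icsr$mean < 1 ||
      adrs_per_icsr$max < 1) {
    stop("synthetic_config: adrs_per_icsr needs mean >= 1 and max >= 1",
         call. = FALSE)
  }

  structure(
    list(drugs = drugs, archetypes = archetypes, assignment = assignment,
         alpha = alpha, seriousness_prob = seriousness_prob,
         fatal_prob = fatal_prob,
         nonfatal_outcome_probs = nonfatal_outcome_probs,
         adrs_per_icsr = adrs_per_icsr, age_probs = age_probs,
         sex_probs = sex_probs, country_probs = country_probs,
         soc_levels = soc_levels, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# truncated geometric on {1..max} with target untruncated mean
ricsr_sizes <- function(m, mean, max) {
  p <- min(1, 1 / mean)
  pmf <- p * (1 - p)^(0:(max - 1))
  sample.int(max, m, replace = TRUE, prob = pmf / sum(pmf))
}

#' Generate a synthetic ICSR line list with ground truth
#'
#' For each drug, cases are drawn until the drug's reaction volume `n_d` is
#' reached (the last case is trimmed so volumes are hit exactly). Case
#' attributes (age band, sex, country) are drawn once per case; each
#' reaction draws its SOC from the drug's mixed profile
#' `alpha * archetype + (1 - alpha) * mean archetype`, its seriousness from
#' the drug's Bernoulli rate, and a fatal outcome with the drug's fatality
#' probability (otherwise one of the non-fatal outcome levels). Output is
#' deterministic under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with `records` (a validated ADR record tibble) and
#'   `truth`: the realized SOC-by-drug count matrix (recounted during
#'   generation, independently of [build_table()]), the drug-to-archetype
#'   `assignment`, the mixed `profiles` actually sampled from, and realized
#'   per-drug `seriousness_rate` / `fatal_rate`.
#' @export
simulate_icsr <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(seed, {
    socs <- config$soc_levels
    arch <- do.call(cbind, config$archetypes)  # socs x archetypes
    global <- rowMeans(arch[, config$assignment[names(config$drugs)],
                            drop = FALSE])
    lv <- adr_levels()
    nonfatal <- names(config$nonfatal_outcome_probs)

    per_drug <- lapply(names(config$drugs), function(d) {
      n_d <- config$drugs[[d]]
      profile <- config$alpha * arch[, config$assignment[[d]]] +
        (1 - config$alpha) * global
      profile <- profile / sum(profile)

      sizes <- integer(0)
      while (sum(sizes) < n_d) {
        sizes <- c(sizes, ricsr_sizes(max(16L, ceiling(n_d / 2)),
                                      config$adrs_per_icsr$mean,
                                      config$adrs_per_icsr$max))
      }
      m <- which(cumsum(sizes) >= n_d)[1]
      sizes <- sizes[seq_len(m)]
      sizes[m] <- sizes[m] - (sum(sizes) - n_d)  # trim to exact volume
      sizes <- sizes[sizes > 0]
      m <- length(sizes)

      case_age <- sample(lv$age_band, m, replace = TRUE,
                         prob = config$age_probs)
      case_sex <- sample(lv$sex, m, replace = TRUE, prob = config$sex_probs)
      case_country <- sample(names(config$country_probs), m, replace = TRUE,
                             prob = config$country_probs)
      idx <- rep.int(seq_len(m), sizes)

      soc <- sample(socs, n_d, replace = TRUE, prob = profile)
      serious <- stats::rbinom(n_d, 1, config$seriousness_prob[[d]]) == 1
      fatal <- stats::rbinom(n_d, 1, config$fatal_prob[[d]]) == 1
      outcome <- ifelse(
        fatal, "fatal",
        sample(nonfatal, n_d, replace = TRUE,
               prob = config$nonfatal_outcome_probs))

      list(
        records = tibble::tibble(
          icsr_id = sprintf("%s-%06d", d, idx),
          drug = d,
          soc = soc,
          seriousness = ifelse(serious, "serious", "non_serious"),
          outcome = outcome,
          age_band = case_age[idx],
          sex = case_sex[idx],
          country = case_country[idx]
        ),
        counts = tabulate(match(soc, socs), nbins = length(socs)),
        profile = profile,
        seriousness_rate = mean(serious),
        fatal_rate = mean(fatal)
      )
    })
    names(per_drug) <- names(config$drugs)

    records <- dplyr::bind_rows(lapply(per_drug, `[[`, "records"))
    counts <- vapply(per_drug, `[[`, numeric(length(socs)), "counts")
    rownames(counts) <- socs
    truth <- list(
      counts = counts,
      assignment = config$assignment[names(config$drugs)],
      profiles = vapply(per_drug, `[[`, numeric(length(socs)), "profile"),
      seriousness_rate = vapply(per_drug, `[[`, numeric(1),
                                "seriousness_rate"),
      fatal_rate = vapply(per_drug, `[[`, numeric(1), "fatal_rate")
    )
    list(records = as_adr_records(records, drugs = names(config$drugs),
                                  socs = socs),
         truth = truth)
  })
}

#' Two-archetype cluster configuration
#'
#' Convenience constructor for the planted-cluster recovery setting: six
#' drugs split into two groups, each group sharing one of two SOC
#' archetypes built by tilting the baseline SOC mass in opposite
#' directions (group 1 over-reports investigations-like categories, group 2
#' gastrointestinal/nervous ones), `alpha = 1`, and about `n_total`
#' reactions split evenly.
#'
#' @param n_total Total reaction volume across the six drugs.
#' @param seriousness_prob,fatal_prob Per-drug probabilities; defaults
#'   plant one elevated drug each (`drug3` serious 0.95 vs 0.90, `drug1`
#'   fatal 0.124 vs 0.08).
#' @param seed RNG seed stored in the config.
#' @return A `synthetic_config`.
#' @export
two_archetype_config <- function(n_total = 24000,
                                 seriousness_prob = NULL,
                                 fatal_prob = NULL,
                                 seed = 1L) {
  drugs <- stats::setNames(rep(round(n_total / 6), 6), paste0("drug", 1:6))
  socs <- soc_codes()
  base <- baseline_soc_mass()[socs]
  up1 <- c("Inv", "Preg", "Inj&P", "Psych")    # VKA-like tilt
  up2 <- c("Gastr", "Nerv", "Card", "Renal")   # NOAC-like tilt
  a1 <- base; a1[up1] <- a1[up1] * 4; a1[up2] <- a1[up2] * 0.5
  a2 <- base; a2[up2] <- a2[up2] * 2.5; a2[up1] <- a2[up1] * 0.4
  if (is.null(seriousness_prob)) {
    seriousness_prob <- stats::setNames(c(0.90, 0.90, 0.95, 0.90, 0.90, 0.90),
                                        names(drugs))
  }
  if (is.null(fatal_prob)) {
    fatal_prob <- stats::setNames(c(0.124, 0.08, 0.08, 0.08, 0.08, 0.08),
                                  names(drugs))
  }
  synthetic_config(
    drugs = drugs,
    archetypes = list(A = a1 / sum(a1), B = a2 / sum(a2)),
    assignment = stats::setNames(c("A", "A", "A", "B", "B", "B"),
                                 names(drugs)),
    alpha = 1,
    seriousness_prob = seriousness_prob,
    fatal_prob = fatal_prob,
    seed = seed
  )
}
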