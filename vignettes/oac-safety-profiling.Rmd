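---
title: "Profiling oral-anticoagulant safety from SOC-level spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling oral-anticoagulant safety from SOC-level spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvprofile)
```

## The problem

Spontaneous reporting databases collect individual case safety reports
(ICSRs); each case carries one or more suspected adverse drug reactions
(ADRs) coded, at the coarsest MedDRA level, into 26 system organ classes
(SOCs) plus social circumstances. There is no exposure denominator, so
drugs are compared through their *reporting* patterns: does a drug
accumulate disproportionately many reports in a reaction category,
relative to the other drugs in the analysis set? `pvprofile` implements
the three standard lenses on a SOC-by-drug count table — indexed
residuals, reporting odds ratios, and correspondence analysis with
contribution biplots — together with the data model, exclusion filters, a
synthetic report generator and an orchestrating pipeline.

Two counting units coexist and are kept explicit everywhere: the ADR
(reaction; the unit of every contingency analysis) and the ICSR (case;
the unit of the demographic summaries). A case contributes one row per
reaction to the line list; `summarize_reports(unit = "icsr")` collapses
back to cases.

## Model and procedure

**Contingency table.** `build_table()` tallies reactions into `O[i, j]`
(SOC `i`, drug `j`) with margins `R_i`, `C_j` and grand total `n`.

**Indexed residuals.** Under row–column independence the expected count
is the margin product `E_ij = R_i C_j / n`. The indexed residual is the
*relative* deviation `100 (O_ij − E_ij)/E_ij`. The relative (not
absolute) form is forced by the published tables this package mirrors:
they print percentages and contain exact −100.0 entries, which only the
relative form produces (at `O = 0`). Residuals are bounded below by −100,
hit it iff the cell is empty, and satisfy the accounting identity
`Σ_i (C_j/n) R_i (1 + r_ij/100) = C_j` per drug.

**Reporting odds ratio.** For a drug–event pair, the 2×2 table `a, b, c,
d` contrasts the pair against the drug's other reactions and against all
other drugs pooled (the comparator is always *within* the analysis set).
`ROR = (a/b)/(c/d)` with the Woolf log-normal interval
`exp(log ROR ± z √(1/a + 1/b + 1/c + 1/d))`. The interval method is a
package choice — it is the field's standard for RORs and is cheap and
well behaved at these counts. Zero cells get the Haldane–Anscombe +0.5
added to all four cells, flagged `corrected`. Drug-level seriousness and
fatality odds ratios (`outcome_or()`) use the same machinery at reaction
level; reactions with unspecified seriousness count as non-serious by
default (configurable to `exclude`) so the positive class is
unambiguous.

**Correspondence analysis.** With `P = O/n`, row masses `r` and column
masses `c`, the standardized residual matrix
`S_ij = (P_ij − r_i c_j)/√(r_i c_j)` is factored by SVD. Squared singular
values λ_k partition the total inertia `χ²/n`; principal coordinates are
`F = D_r^{−1/2} U D_σ` (SOCs) and `G = D_c^{−1/2} V D_σ` (drugs), so
Euclidean distances between row coordinates reproduce chi-square profile
distances, and the contribution of a point to an axis is
`mass × coord² / λ = U²` (rows) or `V²` (columns).

**Contribution biplot.** Drugs are drawn as points in principal
coordinates and SOCs as vectors in contribution coordinates (standard
coordinates scaled by √mass, i.e. the columns of `U`), so a vector's
squared coordinate on an axis *is* its contribution to that axis — vector
length encodes importance directly. The source analyses name this biplot
type without fixing the algebra; this scaling is the one under which the
length-equals-contribution reading is exact, which is why it was chosen.

**Dimension retention.** A dimension is kept when its inertia share
exceeds the uniform share `1/K` (`K = min(I, J) − 1` nontrivial
dimensions), the usual average-inertia reading of the practice-paper rule
the field cites; the count is floored at two because the biplot display
is two-dimensional.

**Variable selection.** Per-SOC contributions are aggregated over the
retained dimensions with inertia weights
(`Σ_k λ_k ctr_ik / Σ_k λ_k`) — the multi-axis combination is not fixed by
the sources, and inertia weighting keeps the aggregate interpretable as
"share of the displayed association explained". SOCs above the
uniform-contribution threshold `1/I` (reciprocal of the number of SOC
variables analysed) are flagged; ties in the top-`n` ranking break
lexicographically on the SOC code.

**Exclusion filters.** `filter_spec()` removes social circumstances
(`Soc`) from every analysis and, for the fatal-only pass, additionally
the categories whose fatal reports are implausible as drug effects: ear
and eye disorders, investigations, surgical procedures, product issues.
The fatal list is configurable — the sources name these five as examples
rather than a closed enumeration, so the default fixes exactly those
five. The descriptive summaries are computed *before* exclusion by
default: that is the order that reproduces the published seriousness and
outcome totals; the pipeline exposes the filtered records if the other
order is wanted.

## Numerical and formatting choices

- Percentages in table exports are rounded half away from zero to one
  decimal (`round_half_up()`); raw values are kept internally. Base
  `round()` is round-half-even and would disagree with printed tables at
  `.x5` boundaries.
- Zero-margin rows/columns are dropped with a warning before residual or
  CA computation (fatal-only tables can lose whole SOCs); a table that
  becomes empty is an error, as is CA on anything smaller than 2×2.
- The SVD sign indeterminacy is fixed by making the largest-magnitude row
  loading of each dimension positive, so coordinates are reproducible
  across platforms.
- An exactly independent table has zero total inertia; inertia shares are
  then reported as zero and no variable passes the selection threshold.
- The published outcome rows of the aggregate fixture over-sum the
  per-drug reaction totals (a reaction can carry several outcome
  annotations in the source). The fixture keeps the published counts
  verbatim; fatal shares are therefore quoted against the reaction totals
  (`fixture_shares(..., denominator = "adr")`), the denominator under
  which the published percentages reproduce exactly.

## The synthetic generator

`synthetic_config()` describes an extract: per-drug reaction volumes,
one SOC archetype per cluster (probability vectors over the 27 codes), a
drug-to-archetype assignment, a mixing weight α (each drug samples from
`α·archetype + (1−α)·mean archetype`, so α = 0 makes drug and SOC
independent and α = 1 plants pure clusters), per-drug seriousness and
fatality probabilities, a truncated-geometric reactions-per-case
distribution, and categorical age/sex/country distributions.

The default configuration mirrors the packaged oral-anticoagulant
aggregate at 1/100 scale — about 4,300 reactions in 2,400 cases, so the
full pipeline runs in seconds: volumes, seriousness and fatality rates
and demographics come from the fixture tables; each drug's archetype is
the baseline SOC mass tilted by the drug's published residual column
(`profile ∝ mass·(1 + r/100)`). The baseline mass itself is a package
choice (the published aggregate does not include SOC totals): it makes
gastrointestinal plus nervous-system disorders ≈30 % of reactions, as in
the source, adds a small social-circumstances mass so the exclusion
filter has work to do, and decays over the remaining categories. The
reactions-per-case mean (1.77) matches the fixture's reactions-to-cases
ratio.

What the generator does *not* emulate — so what green tests do and do not
show: no duplicate or stimulated reporting, no under-reporting bias, no
country-specific reporting cultures, no SOC-specific fatality (outcome
depends on the drug only, so fatal-only tables inherit the overall
profile structure), one outcome per reaction (unlike the source's
multi-annotated outcomes), and no pharmacological realism (dose,
indication, co-medication). Passing recovery tests demonstrate that the
*methods* recover planted structure under clean sampling assumptions, not
that real extracts satisfy those assumptions.

`two_archetype_config()` is the planted-cluster setting used by the
recovery tests: six drugs split 3/3 over two archetypes (one tilted
toward investigations/pregnancy/injury/psychiatric categories, one toward
gastrointestinal/nervous/cardiac/renal), α = 1, ≈24,000 reactions, one
drug with elevated seriousness (0.95 vs 0.90) and one with elevated
fatality (0.124 vs 0.08).

## Problem sizes and verification

The test-suite sizes are the package's own trade-off between statistical
resolution and fast iteration: 100 random tables for the chi-square
inertia identity (tolerance 1e−9 relative), the exhaustive 1,296-table
grid (cells 1..6) for the ROR cross-product oracle, 20 seeds × 24,000
reactions for archetype separation and odds-ratio CI coverage, 20 seeds ×
6,000 reactions for the α = 0 independence check, and n = 20,000 per drug
for multinomial profile recovery, asserted against the analytic expected
total-variation bound `0.5 Σ_i √(2 p_i (1−p_i)/(π n))` rather than an ad
hoc constant. Independent oracles used in tests: `chisq.test`'s
statistic, a dense `eigen()` solver on 3×3 tables, `MASS::corresp`, and
first-principles recomputation of the Woolf interval.

## Known limitations

- Two published surfaces are not reproducible from the shipped
  aggregates: the two-dimensional inertia shares of the full
  oral-anticoagulant analysis and the drug-level seriousness/fatality
  odds ratios, both of which depend on the full drug-by-SOC count matrix
  (and, for the odds ratios, on an exclusion/unit convention the
  aggregate does not disclose — the published Table-level margins yield
  slightly different values under the standard 2×2 construction). The
  package covers these by property-based tests and by treating the
  published *shares* as the reproduction surface; the residual reference
  tables are shipped for qualitative comparison.
- SOC-level only: no preferred-term hierarchy, no signal-detection
  thresholds (PRR, IC/EBGM), no multiplicity adjustment, no
  de-duplication beyond case-id grouping, and no figure rendering — the
  pipeline emits coordinates and tables for a plotting layer.
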