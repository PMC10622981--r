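---
title: "Case/non-case disproportionality with a synthetic report generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case/non-case disproportionality with a synthetic report generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous-report pharmacovigilance databases collect individual case
safety reports (ICSRs): one report carries demographics, one or more drugs
with role codes (suspect, interacting, concomitant), and one or more adverse
events coded as MedDRA-style preferred terms (PTs). In a **case/non-case
design**, reports containing the event of interest are "cases" and all other
reports are the comparator, and the **reporting odds ratio**

$$\mathrm{ROR} = \frac{a\,d}{b\,c}$$

from the drug-by-event 2×2 table over reports (a = cases with the drug,
b = non-cases with the drug, c = cases without, d = non-cases without)
measures disproportionate reporting. It is not an incidence measure: it only
says that, among what got reported, the event travels with the drug more
often than independence predicts.

`rorcase` implements this design for a concrete study shape: neurocognitive
impairment (NCI) reported in females under endocrine therapies (aromatase
inhibitors, SERMs, SERDs) and CDK4/6 inhibitors, with age-adjusted
estimation, DSM-5 domain sub-outcomes, and four sensitivity analyses. The
real databases behind such studies are access-restricted, so the package
pairs the pipeline with a seeded synthetic ICSR generator whose ground-truth
odds ratios are known: every stage is testable, and estimator calibration
and parameter recovery are demonstrable, without any proprietary data.

## Case definition

The case set is resolved from a term dictionary (PT → HLT → HLGT → SOC, SMQ
memberships, a disease flag, and a PT → DSM-5 domain map) by a query that
names SMQ/HLGT groups plus explicit PT additions and removals:

* resolved set = (PTs of the named groups ∪ added PTs) − removed PTs −
  disease-flagged PTs;
* exclusions always win over inclusions;
* the disease flag implements the restriction to *symptom-level* terms: PTs
  denoting established neurological or psychiatric diseases (dementia,
  delirium, ...) never define a case, so the signal is not driven by
  disease reporting.

Case status is **report-level**: a report with three matching PTs is one
case. Each matching PT maps to exactly one of the six DSM-5 neurocognitive
domains (complex attention, executive function, language, learning and
memory, perceptual motor function, social cognition), and a report can
belong to several domain sub-outcomes at once. Licensed MedDRA/SMQ content
is not reproduced; the packaged dictionary is a synthetic fixture with the
same structure, and the query groups are data (`nci_query.yaml`), editable
without code changes. Whether a production query should match SMQ narrow or
broad scope is a dictionary concern: groups here are flat PT sets.

## Cohort restriction and accounting

The primary cohort filter mirrors the study design: females, report date
inside the study window (2014-01-01 to 2022-03-16, both endpoints
inclusive — the window is phrased "from ... until ..." and both boundary
dates carry reports), all three role codes accepted for drug attribution,
and non-missing age (the age-adjusted model cannot use age-missing reports,
so they are excluded from cases *and* non-cases alike). `apply_filters()`
returns the cohort with a flow table (input, per-filter removals,
remaining); the final cohort is order-independent but the per-step counts
are not, so the output states the order explicitly. Demographic summaries
are computed before the age restriction so the missing-age share stays
visible.

A report counts as exposed to a drug iff it mentions that drug with an
accepted role code. `build_table()` cross-classifies exposure × outcome
within each age class; the strata partition the cohort, which the tests
assert. Because published tables of this design are ambiguous about whether
"N drug" means exposed non-cases (b) or all exposed reports (a + b) — the
printed marginals are only arithmetically consistent with b — results carry
`n_observed` (a), `n_drug_b` (b) and `n_drug_total` (a + b) explicitly.

## Estimators

Three estimators share one result schema:

* **Crude** ROR with the Woolf interval,
  $\exp(\ln \mathrm{ROR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d})$. A zero cell
  triggers the Haldane–Anscombe 0.5 correction on all four cells, annotated
  in the result; the minimum-report rule makes this rare for reportable
  pairs.
* **Mantel–Haenszel** over the four known-age strata,
  $\sum_k a_k d_k / n_k \,/\, \sum_k b_k c_k / n_k$, with the
  Robins–Breslow–Greenland variance.
* **Logistic regression** (the primary method):
  $\operatorname{logit} P(\text{case}) = \beta_0 + \beta_1\,\text{exposed} +
  \gamma_{\text{age class}}$, reference class 45–64, adjusted ROR
  $= e^{\beta_1}$ with Wald 95% interval. The fit uses counts aggregated
  over the eight (age class × exposure) cells — a sufficient statistic for
  this model — so report-level and aggregated routes give identical
  estimates at a fraction of the cost, and the tests assert that identity.

The source study names only "adjusted for age" without the technique;
fitting logistic regression with categorical age and keeping
Mantel–Haenszel as a closed-form cross-check is standard pharmacovigilance
practice, and the suite enforces their agreement on homogeneous-OR data
(within 2% on confounded synthetic cohorts, to 10⁻⁶ on a single stratum,
where both collapse to the crude ROR). The published phrase "95%
credibility interval" is implemented as a frequentist 95% confidence
interval — no Bayesian model is described in the source, and the bounds
reproduce under the Woolf/Wald formulas. The critical value is carried as
z = 1.959964 so interval endpoints are reproducible bit-for-bit
(tolerance 10⁻⁹ on the log scale).

**Decision rules.** An ROR is only interpreted when at least five case
reports carry the drug (`min_count = 5`); below that the row is kept but
marked not calculable ("NC"), never dropped. A signal is the strict rule
`ci_low > 1`: a lower bound of exactly 1 is not a signal. Under the null
this one-sided rule fires at ≈2.5%, which the calibration test verifies
over 1,000 simulated null pairs. No multiplicity correction is applied
across the 9 drugs × 7 outcomes × 5 analyses, matching the design this
package implements; the long results schema carries everything needed to
apply one downstream.

## Analyses

`run_primary()` estimates the adjusted NCI ROR per drug with crude and MH
diagnostics attached. `run_domain_subgroups()` repeats the estimation for
each DSM-5 domain, where domain cases are reports with ≥1 PT of that domain
and *all* other cohort reports are the comparator (including cases of other
domains — this is what makes the published per-domain margins consistent).
`run_sensitivity()` implements four variants, each a single declared
modification of the primary design:

* **S1** restricts non-cases to reports mentioning an oncology-class drug
  (antineoplastic, AI, SERM, SERD, iCDK4/6 or immunotherapy), controlling
  confounding by the underlying cancer. Cases are all kept: the exposed
  cells cannot change (exposed reports carry the study drug, itself an
  oncology-class drug), and only c and d shrink — asserted in tests. The
  CDK4/6-inhibitor class is included in the oncology set because those
  drugs are antineoplastic agents even though the dictionary classes them
  separately.
* **S2** restricts to healthcare-professional reporters before labelling.
* **S3**, per endocrine-therapy drug, re-runs the analysis on the window
  from that drug's first report date up to *but excluding* the first report
  date of the CDK4/6-inhibitor class (the variant's purpose is the
  pre-combination era, so the day combination reporting begins is out).
  The variant is skipped with a diagnostic when the class has no reports.
* **S4** drops reports flagged with co-illnesses or co-treatments known to
  cause NCI; with zero flagged reports it reproduces the primary results
  exactly, which is also a test.

`run_study()` drives everything from a YAML or list configuration and
returns a bundle (long results, rendered views, flow, demographics,
metadata) with `tidy()`, `glance()` and `autoplot()` methods;
`write_study_bundle()` persists plain-text CSV/JSON artifacts. Percentages
in rendered summaries are rounded to the nearest integer; the blocks then
sum to 100 ± 1, and the metadata records the rounding rule.

## The synthetic generator

`generator_config()` describes a database; `generate_reports()` samples it
reproducibly (same config + seed ⇒ identical tibble, and identical JSONL
bytes). The generative model, per report:

1. **Demographics.** Age class from the configured mix — default
   (5, 29, 26, 23, 17)% over 18–44 / 45–64 / 65–74 / 75+ / missing, the
   age structure of a worldwide endocrine-therapy NCI case series — then a
   uniform age inside the band (75+ is truncated at 95). Sex, region
   (Americas-dominant), reporter mix and a uniform report date inside the
   window follow. Missing age is assigned independently of case status.
2. **Exposures.** Per drug, a Bernoulli draw with an age-class-specific
   probability; CDK4/6 inhibitors have market-entry dates inside the window
   and cannot appear earlier. Study-drug schedules multiply a base rate
   (0.02%–2% per drug, roughly the relative reporting volumes of the nine
   drugs; toremifene is deliberately rare so the not-calculable path is
   exercised naturally) by age multipliers (0.3, 0.7, 1.3, 1.8): exposure
   rises with age. Exposures are independent across drugs by default; an
   optional coupling parameter adds an endocrine-therapy co-prescription to
   CDK4/6-exposed reports to emulate combination therapy (off by default so
   generating odds ratios stay exactly interpretable per drug).
3. **Outcome.** Six independent per-domain Bernoulli draws with log-odds
   `qlogis(p_age × mix_d)` plus effect contributions. The baseline case
   probability rises with age — (0.8, 1.5, 2.6, 4.0)% across the four
   bands, ~2.5% overall — which, combined with the exposure schedule, makes
   age a genuine confounder: under the global null the pooled crude ROR
   sits around 1.19 while every within-stratum OR is 1. The domain mix
   (learning and memory 40%, complex attention 25%, language 12%,
   perceptual motor 12%, executive 8%, social cognition 3%) follows the
   relative domain frequencies such case series report.
4. **Effects.** An NCI-level effect multiplies the within-stratum odds of
   *every* domain draw for the exposed drug, so the any-NCI conditional
   odds ratio equals θ up to a rare-outcome approximation of order the
   baseline probability (≪ Monte-Carlo error here). A domain-level effect
   multiplies only its domain, so the domain sub-outcome has conditional OR
   exactly θ and the composite NCI OR is diluted towards 1 — both
   behaviours are verified by simulation in the tests.
5. **Events.** Each affected domain contributes one symptom PT (weighted
   so the first-listed PT dominates, e.g. memory impairment for learning
   and memory), with probability 0.2 of a second PT from the same domain.
   Non-cases draw a non-NCI PT; every report adds `Binomial(2, 0.15)`
   extra non-NCI PTs (the source gives no within-report PT-count
   distribution, so a small zero-inflated draw is used and documented
   here), and a small fraction carries a disease-flagged cognitive PT —
   which must *not* make it a case, exercising the exclusion. Events are
   deduplicated; no report is empty.
6. **Flags.** Seriousness 57% among cases (40% otherwise), treatment
   interruption in one-third of serious cases, confounder flags at 2%
   (co-illness) and 0.7% (co-treatment).

`ground_truth()` tabulates the configured effects (unconfigured pairs OR 1)
and the baseline case odds per age class, as the oracle for recovery tests.

**What the generator does not emulate:** duplicate reports across
countries, reporting waves and stimulated reporting, drug–drug masking
beyond the oncology co-mention, dose/temporal pharmacology, and realistic
correlation structure between co-mentioned drugs. Passing recovery tests
therefore show that the *estimators and plumbing* are correct under a known
model with deliberate age confounding, not that any real-data signal is
causal or unbiased.

## Problem sizes and numerical choices

The unit suite uses databases of 5,000–150,000 reports; parameter-recovery
checks use 300,000 reports and assert agreement within 3 Monte-Carlo
standard errors (taken from the fitted interval width, which matches the
estimator's sampling error). The acceptance script generates 4,000,000
reports so the Monte-Carlo standard error of each recovered adjusted ROR is
3–6% on the log scale; null-calibration uses 1,000 directly simulated
stratified null pairs pushed through the logistic estimator and signal
rules. Degenerate inputs are handled explicitly: empty cohorts warn and
yield all-zero tables; a drug absent from the cohort, constant outcome,
separation or non-convergence yield `computed = FALSE` with a diagnostic
note rather than an estimate; strata with no reports drop out of the MH
sums; the missing-age stratum never enters adjusted estimation.

## A worked example

```{r, eval = FALSE}
library(rorcase)

cfg <- generator_config(
  n_reports = 300000, seed = 1001,
  effects = tibble::tibble(
    drug_id = c("anastrozole", "letrozole", "palbociclib", "ribociclib"),
    outcome = "NCI",
    or = c(1.52, 1.37, 1.41, 0.73)))
reports <- generate_reports(cfg)

plan <- study_plan()
primary <- run_primary(reports, plan)
dplyr::filter(primary, method == "logistic_adjusted")

study <- run_study(list(generator = list(
  n_reports = 300000, seed = 1001,
  effects = list(list(drug_id = "letrozole", outcome = "NCI", or = 1.37)))))
glance(study)
autoplot(study)
```

## Known limitations

* The fixture dictionaries are synthetic stand-ins; real MedDRA/WHODrug
  content (and the exact production PT inclusion/exclusion lists, which
  live in licensed appendices) must be supplied as data by the user.
* Wald/Woolf intervals are first-order; for very sparse computed pairs
  (just past the minimum-report rule) exact intervals would be wider.
* The logistic adjustment assumes a homogeneous conditional OR across age
  strata; heterogeneity is not modelled (nor was it in the design this
  package implements), though per-stratum cells are exposed for inspection.
* No duplicate-report detection: the generator does not simulate
  duplicates, and real-data use should deduplicate upstream.
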