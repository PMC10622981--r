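# rorcase

Case/non-case disproportionality analysis of spontaneous adverse-event
reports, with a seeded synthetic report generator for validation.

## What this is for

Pharmacovigilance databases collect individual case safety reports (ICSRs):
demographics, drugs with role codes (suspect / interacting / concomitant),
and adverse events coded as MedDRA-style preferred terms (PTs). In a
case/non-case design, reports carrying the event of interest are "cases"
and all other reports the comparator, and the **reporting odds ratio**

    ROR = (a·d) / (b·c)

over the drug × event 2×2 table (a = cases with the drug, b = non-cases
with the drug, c = cases without, d = non-cases without) measures
disproportionate reporting. `rorcase` implements a complete study of this
shape — neurocognitive impairment (NCI) in females under endocrine
therapies and CDK4/6 inhibitors — as a reusable, tested pipeline:

* **Case definition**: SMQ/HLGT query resolution against a term
  dictionary, with disease-term exclusion (symptom-level cases only) and
  PT → DSM-5 neurocognitive-domain mapping; report-level case labels.
* **Cohort restriction**: sex, inclusive study window, role-code
  attribution, age availability, reporter type — with flow-chart
  accounting of every removal.
* **Estimation**: crude ROR (Woolf interval, Haldane–Anscombe correction
  for zero cells), Mantel–Haenszel age-adjusted ROR
  (Robins–Breslow–Greenland variance), and the primary logistic
  age-adjusted ROR `logit P(case) = β0 + β1·exposed + age-class terms`
  (adjusted ROR = exp(β1), Wald 95% CI), plus the ≥5-report rule and the
  strict `ci_low > 1` signal rule.
* **Analyses**: primary per-drug analysis, six DSM-5 domain subgroups, and
  four sensitivity variants (oncology-restricted non-cases, HCP reporters
  only, per-drug pre-CDK4/6 window, confounder-flag exclusion).
* **Synthetic data**: `generator_config()` / `generate_reports()` sample a
  VigiBase-like report stream with configurable demographic mixes,
  age-dependent exposures and baseline risks (deliberate age confounding),
  and known within-stratum conditional odds ratios per drug–outcome pair,
  so estimator calibration and parameter recovery are testable without
  access to a proprietary database.

Everything is tibble-in / tibble-out and pipe-friendly; fitted studies have
`tidy()`, `glance()` and `autoplot()` methods.

## Worked example

Generate a confounded synthetic database whose anastrozole, letrozole,
palbociclib and ribociclib within-age-stratum odds ratios are set to known
values, then run the primary age-adjusted analysis:

```r
library(rorcase)

cfg <- generator_config(
  n_reports = 300000, seed = 1001,
  effects = tibble::tibble(
    drug_id = c("anastrozole", "letrozole", "palbociclib", "ribociclib"),
    outcome = "NCI",
    or      = c(1.52, 1.37, 1.41, 0.73)))
reports <- generate_reports(cfg)

primary <- run_primary(reports, study_plan())
render_table1(primary)
#> # A tibble: 9 × 7
#>   drug        n_observed n_drug n_drug_total ror   ci_95       signal
#>   <chr>            <int>  <int>        <int> <chr> <chr>       <chr>
#> 1 anastrozole        152   2913         3065 1.69  (1.43-2.00) "*"
#> 2 letrozole          216   4704         4920 1.50  (1.30-1.72) "*"
#> 3 exemestane          71   2416         2487 0.94  (0.74-1.19) ""
#> 4 tamoxifen           83   2933         3016 0.90  (0.72-1.12) ""
#> 5 toremifene           0     37           37 NC    NC          ""
#> 6 fulvestrant         78   2871         2949 0.87  (0.69-1.09) ""
#> 7 palbociclib        170   4139         4309 1.32  (1.13-1.54) "*"
#> 8 ribociclib          28   1164         1192 0.77  (0.53-1.12) ""
#> 9 abemaciclib         33    916          949 1.17  (0.82-1.66) ""
```

Reading this: `n_observed` is the number of case reports carrying the drug
(cell a), `n_drug` the non-case reports with the drug (cell b),
`n_drug_total` their sum. The three configured positive effects are
recovered within Monte-Carlo error (at 300,000 reports the standard error
of a log adjusted ROR here is 6–12%) and flagged `*` because the interval's
lower bound exceeds 1; ribociclib (generating OR 0.73) is below the null
and correctly raises no signal; toremifene is so rarely reported that its
pair fails the ≥5-report rule and renders `NC` — the row is kept, never
dropped. The crude RORs (attached in the same results tibble) run ~0.2
higher than the adjusted ones: exposure and baseline risk both rise with
age in this design, and the adjustment removes exactly that confounding.

Whole studies run from a config (YAML file or list) and summarise/plot:

```r
study <- run_study(list(generator = list(
  n_reports = 50000, seed = 5,
  effects = list(list(drug_id = "letrozole", outcome = "NCI", or = 2))),
  sensitivity = list("S1", "S4")))
glance(study)
#> # A tibble: 1 × 5
#>   n_reports_in cohort_size n_cases n_pairs n_primary_signals
#> 1        50000       35413     924      81                 2
study$demographics$age
#> # A tibble: 5 × 3
#>   level       n   pct
#> 1 18-44    2164     5
#> 2 45-64   12450    29
#> 3 65-74   11131    26
#> 4 75+      9668    23
#> 5 missing  7129    17
autoplot(study)          # forest plot, faceted by analysis
write_study_bundle(study, "study_out/")   # CSV/JSON artifacts
```

See the vignette (`vignettes/disproportionality-methods.Rmd`) for the
model, the generator's assumptions, and every numerical choice.

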