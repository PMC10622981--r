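#' Define a cohort filter
#'
#' Restrictions applied to the report stream before disproportionality
#' analysis: sex, study window (inclusive on both ends), accepted drug role
#' codes for exposure attribution, age availability (required for the
#' age-adjusted model), optional reporter restriction, optional exclusion of
#' reports flagged with co-illnesses/co-treatments known to cause the
#' outcome, and an optional oncology restriction of non-cases (applied at
#' analysis stage, once case labels exist).
#'
#' @param sex Required sex value, or `NULL` for no restriction.
#' @param window Length-2 date vector, inclusive.
#' @param roles Role codes accepted for drug attribution (subset of
#'   suspect/interacting/concomitant; all three by default).
#' @param require_age Drop reports with missing age (needed by the adjusted
#'   analysis)?
#' @param reporter Optional required reporter type
#'   (e.g. `"healthcare_professional"`).
#' @param exclude_confounded Drop reports whose `nci_comorbidity` or
#'   `nci_cotreatment` flag is set?
#' @param noncase_restrict_oncology Restrict non-cases to oncology reports
#'   (carried on the filter for bookkeeping; enforced by
#'   [restrict_noncases_oncology()] during analysis).
#' @return A list of class `cohort_filter`.
#' @export
cohort_filter <- function(sex = "female",
                          window = as.Date(c("2014-01-01", "2022-03-16")),
                          roles = DRUG_ROLES,
                          require_age = TRUE,
                          reporter = NULL,
                          exclude_confounded = FALSE,
                          noncase_restrict_oncology = FALSE) {
  window <- as.Date(window)
  if (length(window) != 2 || window[1] > window[2]) {
    abort("window must be two dates with start <= end")
  }
  roles <- match.arg(roles, DRUG_ROLES, several.ok = TRUE)
  if (length(roles) == 0) abort("roles must be nonempty")
  structure(
    list(sex = sex, window = window, roles = roles,
         require_age = require_age, reporter = reporter,
         exclude_confounded = exclude_confounded,
         noncase_restrict_oncology = noncase_restrict_oncology),
    class = "cohort_filter"
  )
}

#' Apply cohort restrictions with flow accounting
#'
#' Filters the report stream and records how many reports each restriction
#' removed, in the declared order: study window, then sex, then reporter,
#' then confounder exclusion, then age availability. The final cohort is
#' order-independent; the per-step removal counts are not, and the flow
#' table states the order explicitly.
#'
#' @param reports A report tibble (labelled or not).
#' @param filter A [cohort_filter()].
#' @return The filtered cohort tibble, with the flow table attached as the
#'   `"flow"` attribute (retrieve with [flow_counts()]).
#' @export
apply_filters <- function(reports, filter) {
  steps <- list()
  keep <- reports
  note <- function(label, kept) {
    steps[[length(steps) + 1]] <<- tibble(
      filter = label, removed = nrow(keep) - nrow(kept),
      remaining = nrow(kept))
    keep <<- kept
  }
  note("window",
       keep[keep$date >= filter$window[1] & keep$date <= filter$window[2], ])
  if (!is.null(filter$sex)) {
    note(paste0("sex=", filter$sex), keep[keep$sex == filter$sex, ])
  }
  if (!is.null(filter$reporter)) {
    note(paste0("reporter=", filter$reporter),
         keep[keep$reporter == filter$reporter, ])
  }
  if (isTRUE(filter$exclude_confounded)) {
    note("exclude_confounded",
         keep[!(keep$nci_comorbidity | keep$nci_cotreatment), ])
  }
  if (isTRUE(filter$require_age)) {
    note("require_age", keep[!is.na(keep$age_years), ])
  }
  flow <- bind_rows(steps)
  flow <- bind_rows(
    tibble(filter = "input", removed = 0L, remaining = nrow(reports)),
    flow
  )
  if (nrow(keep) == 0) warn("cohort is empty after filtering")
  attr(keep, "flow") <- flow
  attr(keep, "roles") <- filter$roles
  keep
}

#' Flow-chart counts of a filtered cohort
#'
#' @param cohort Output of [apply_filters()].
#' @return A tibble with columns `filter`, `removed`, `remaining` (first row
#'   is the unfiltered input).
#' @export
flow_counts <- function(cohort) {
  fl <- attr(cohort, "flow")
  if (is.null(fl)) abort("no flow information: was this cohort filtered with apply_filters()?")
  fl
}

# report_ids exposed to drug_id under the accepted role codes; `mentions`
# lets callers reuse one drug_mentions() pass across many drugs/outcomes
exposed_ids <- function(reports, drug_id, roles = DRUG_ROLES,
                        mentions = NULL) {
  dm <- mentions %||% drug_mentions(reports)
  unique(dm$report_id[dm$drug_id == drug_id & dm$role %in% roles])
}

#' Build an age-stratified 2x2 table for one drug
#'
#' Cross-classifies the cohort by exposure to `drug_id` (any mention with an
#' accepted role code) and outcome status, within each age class:
#' `a` = outcome & exposed, `b` = no outcome & exposed, `c` = outcome &
#' unexposed, `d` = no outcome & unexposed. Strata partition the cohort, so
#' summed cells equal the cohort size.
#'
#' @param cohort A labelled, filtered report tibble.
#' @param drug_id Drug of interest (must exist in the cohort's mentions or
#'   the supplied dictionary-checked plan; unknown ids error).
#' @param roles Accepted role codes (defaults to the cohort's filter roles,
#'   else all three).
#' @param outcome Name of the logical outcome column (default `"is_case"`;
#'   use a `dom_*` column for a DSM-5 domain sub-outcome).
#' @param known_drugs Optional character vector of valid drug ids used to
#'   validate `drug_id` (e.g. the drug dictionary). When `NULL`, any id is
#'   accepted (a drug absent from all reports yields `a = b = 0`).
#' @param mentions Optional precomputed [drug_mentions()] table for the
#'   cohort, reused across repeated calls.
#' @return A tibble of class `strat_table`: columns `drug_id`, `stratum`
#'   (the five age classes), `a`, `b`, `c`, `d`; attributes `outcome` and
#'   `roles`.
#' @export
build_table <- function(cohort, drug_id, roles = NULL,
                        outcome = "is_case", known_drugs = NULL,
                        mentions = NULL) {
  if (!is.null(known_drugs) && !drug_id %in% known_drugs) {
    abort(paste0("unknown drug_id: ", drug_id))
  }
  if (!outcome %in% names(cohort)) {
    abort(paste0("no outcome column ", outcome,
                 ": label the cohort with label_reports() first"))
  }
  roles <- roles %||% attr(cohort, "roles") %||% DRUG_ROLES
  exp_ids <- exposed_ids(cohort, drug_id, roles, mentions = mentions)
  exposed <- cohort$report_id %in% exp_ids
  case <- cohort[[outcome]]
  stratum <- assign_age_class(cohort$age_years)
  cell <- factor(
    if_else(case & exposed, "a",
            if_else(!case & exposed, "b", if_else(case, "c", "d"))),
    levels = c("a", "b", "c", "d")
  )
  m <- table(stratum, cell)   # 5 age classes x 4 cells, zero-filled
  out <- tibble(
    drug_id = drug_id,
    stratum = factor(rownames(m), levels = AGE_CLASSES),
    a = as.integer(m[, "a"]), b = as.integer(m[, "b"]),
    c = as.integer(m[, "c"]), d = as.integer(m[, "d"])
  )
  attr(out, "outcome") <- outcome
  attr(out, "roles") <- roles
  class(out) <- c("strat_table", class(out))
  out
}

#' Pool a stratified table
#'
#' @param table A `strat_table`.
#' @param drop_missing_age Pool only the four known-age strata?
#' @return A one-row tibble with pooled `a`, `b`, `c`, `d`, `n_observed`
#'   (= a) and `n_drug_total` (= a + b).
#' @export
pool_table <- function(table, drop_missing_age = FALSE) {
  tab <- if (drop_missing_age) {
    table[table$stratum != "missing", , drop = FALSE]
  } else {
    table
  }
  out <- summarise(as_tibble(tab),
                   a = sum(.data$a), b = sum(.data$b),
                   c = sum(.data$c), d = sum(.data$d))
  out$n_observed <- out$a
  out$n_drug_total <- out$a + out$b
  out
}

#' Date of the first report mentioning a drug or class
#'
#' @param reports A report tibble.
#' @param drugs Character vector of drug ids (e.g. one drug, or every drug
#'   of a class).
#' @return The earliest report date among mentions, or `NA` (`Date`) when
#'   no report mentions any of the drugs.
#' @export
first_report_date <- function(reports, drugs) {
  dm <- drug_mentions(reports)
  ids <- unique(dm$report_id[dm$drug_id %in% drugs])
  if (length(ids) == 0) return(as.Date(NA))
  min(reports$date[reports$report_id %in% ids])
}
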