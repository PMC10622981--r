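#' Define a study plan
#'
#' Bundles everything the analysis stages need: the dictionaries, the case
#' query, the drugs of interest, the primary cohort filter, and the
#' minimum-report rule. Every sensitivity variant derives from the primary
#' filter by a single declared modification (see [run_sensitivity()]).
#'
#' @param term_dict,drug_dict Dictionaries; default to the packaged
#'   fixtures.
#' @param query A [case_query()]; defaults to the packaged
#'   neurocognitive-impairment query.
#' @param drugs Drugs of interest; default: every AI/SERM/SERD/iCDK46 drug
#'   in the drug dictionary (the nine study drugs with the packaged
#'   dictionary).
#' @param filter Primary [cohort_filter()] (female, window
#'   2014-01-01..2022-03-16 inclusive, all role codes, age required).
#' @param min_count Minimum observed reports for a calculable ROR.
#' @return A list of class `study_plan`.
#' @export
study_plan <- function(term_dict = NULL, drug_dict = NULL, query = NULL,
                       drugs = NULL, filter = cohort_filter(),
                       min_count = 5) {
  term_dict <- term_dict %||%
    load_term_dictionary(rorcase_example("term_dictionary.csv"))
  drug_dict <- drug_dict %||%
    load_drug_dictionary(rorcase_example("drug_dictionary.csv"))
  query <- query %||% load_case_query(rorcase_example("nci_query.yaml"))
  drugs <- drugs %||%
    drug_dict$drug_id[drug_dict$drug_class %in% c("AI", "SERM", "SERD", "iCDK46")]
  unknown <- setdiff(drugs, drug_dict$drug_id)
  if (length(unknown) > 0) {
    abort(paste0("study drugs absent from the drug dictionary: ",
                 paste(unknown, collapse = ", ")))
  }
  structure(
    list(term_dict = term_dict, drug_dict = drug_dict, query = query,
         drugs = drugs, filter = filter, min_count = min_count),
    class = "study_plan"
  )
}

# label + filter a report stream according to a plan; returns the labelled
# cohort (flow attached) with its drug-mentions table cached as an attribute
prepare_cohort <- function(reports, plan, filter = NULL) {
  case_set <- resolve_query(plan$term_dict, plan$query)
  labelled <- label_reports(reports, case_set, plan$term_dict)
  cohort <- apply_filters(labelled, filter %||% plan$filter)
  attr(cohort, "mentions") <- drug_mentions(cohort)
  cohort
}

# crude + MH + logistic rows for one drug/outcome on a prepared cohort
analyse_pair <- function(cohort, drug_id, outcome, plan, analysis) {
  mentions <- attr(cohort, "mentions")
  tab <- build_table(cohort, drug_id, roles = plan$filter$roles,
                     outcome = outcome, known_drugs = plan$drug_dict$drug_id,
                     mentions = mentions)
  res <- bind_rows(
    lr_adjusted_ror(cohort, drug_id, roles = plan$filter$roles,
                    outcome = outcome, mentions = mentions),
    mh_adjusted_ror(tab),
    crude_ror(tab)
  )
  res$analysis <- analysis
  apply_signal_rules(res, min_count = plan$min_count)
}

#' Run the primary age-adjusted analysis
#'
#' Labels, filters and analyses every drug of interest against the
#' composite NCI outcome. The logistic age-adjusted ROR is the primary
#' estimate; Mantel–Haenszel and crude results are attached as diagnostics
#' (same schema, `method` column distinguishes them). Drugs with fewer than
#' `min_count` observed cases keep their row with `computed = FALSE` — they
#' are never dropped.
#'
#' @param reports A report tibble.
#' @param plan A [study_plan()].
#' @return A long results tibble (drugs x methods) with the cohort flow
#'   table attached as attribute `"flow"`.
#' @export
run_primary <- function(reports, plan = study_plan()) {
  cohort <- prepare_cohort(reports, plan)
  res <- purrr::map(plan$drugs, \(d)
                    analyse_pair(cohort, d, "is_case", plan, "primary")) |>
    bind_rows()
  attr(res, "flow") <- flow_counts(cohort)
  res
}

#' Run the six DSM-5 domain subgroup analyses
#'
#' For each DSM-5 neurocognitive domain, cases are the cohort reports with
#' at least one PT mapped to that domain and non-cases are *all* other
#' cohort reports (including NCI cases of other domains). Each drug x
#' domain pair gets the same adjusted estimates and rules as the primary
#' analysis; pairs under the minimum-report rule come back
#' `computed = FALSE` (rendered "NC").
#'
#' @inheritParams run_primary
#' @return A long results tibble (drugs x domains x methods).
#' @export
run_domain_subgroups <- function(reports, plan = study_plan()) {
  cohort <- prepare_cohort(reports, plan)
  grid <- tidyr::expand_grid(drug = plan$drugs, domain = DSM5_DOMAINS)
  res <- purrr::map2(grid$drug, grid$domain, \(d, dom)
                     analyse_pair(cohort, d, domain_column(dom), plan,
                                  "domain_subgroup")) |>
    bind_rows()
  attr(res, "flow") <- flow_counts(cohort)
  res
}

#' Restrict non-cases to oncology reports
#'
#' Keeps every case, and keeps a non-case only when it mentions a drug of
#' an oncology class (antineoplastic, AI, SERM, SERD, iCDK46 or
#' immunotherapy) — the restriction that controls confounding by the
#' underlying breast cancer in the oncology-restricted sensitivity
#' analysis. Exposed cells (`a`, `b`) are untouched for any study drug,
#' because exposed reports mention the study drug itself.
#'
#' @param labelled_cohort A labelled cohort tibble.
#' @param drug_dict A drug dictionary.
#' @return The restricted cohort.
#' @export
restrict_noncases_oncology <- function(labelled_cohort, drug_dict) {
  onc_classes <- c("antineoplastic", "AI", "SERM", "SERD", "iCDK46",
                   "immunotherapy")
  onc_drugs <- drug_dict$drug_id[drug_dict$drug_class %in% onc_classes]
  dm <- attr(labelled_cohort, "mentions") %||% drug_mentions(labelled_cohort)
  onc_ids <- unique(dm$report_id[dm$drug_id %in% onc_drugs])
  keep <- labelled_cohort$is_case | labelled_cohort$report_id %in% onc_ids
  out <- labelled_cohort[keep, , drop = FALSE]
  attr(out, "roles") <- attr(labelled_cohort, "roles")
  fl <- attr(labelled_cohort, "flow")
  if (!is.null(fl)) {
    attr(out, "flow") <- bind_rows(fl, tibble(
      filter = "noncase_oncology_restrict",
      removed = nrow(labelled_cohort) - nrow(out), remaining = nrow(out)))
  }
  attr(out, "mentions") <- NULL
  out
}

#' Run a sensitivity analysis
#'
#' The four variants, each one declared modification of the primary design:
#'
#' * `S1` — non-cases restricted to oncology reports (cases all kept); see
#'   [restrict_noncases_oncology()].
#' * `S2` — reports restricted to healthcare-professional reporters.
#' * `S3` — per endocrine-therapy drug, the extraction window runs from that
#'   drug's first report date up to (but excluding) the first report date of
#'   the CDK4/6-inhibitor class, and only that drug is analysed: the
#'   pre-combination-era signal. Skipped with a diagnostic when the class
#'   has no reports.
#' * `S4` — reports flagged with co-illnesses (`nci_comorbidity`) or
#'   co-treatments (`nci_cotreatment`) known to cause the outcome are
#'   excluded. With no flagged reports this reproduces the primary results
#'   exactly.
#'
#' @inheritParams run_primary
#' @param variant One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @return A long results tibble; `analysis` column names the variant.
#' @export
run_sensitivity <- function(reports, plan = study_plan(),
                            variant = c("S1", "S2", "S3", "S4")) {
  variant <- match.arg(variant)
  analysis <- paste0("sensitivity_", variant)
  if (variant == "S1") {
    cohort <- prepare_cohort(reports, plan)
    cohort <- restrict_noncases_oncology(cohort, plan$drug_dict)
    attr(cohort, "mentions") <- drug_mentions(cohort)
    res <- purrr::map(plan$drugs, \(d)
                      analyse_pair(cohort, d, "is_case", plan, analysis)) |>
      bind_rows()
    attr(res, "flow") <- flow_counts(cohort)
    return(res)
  }
  if (variant == "S2") {
    f <- plan$filter
    f$reporter <- "healthcare_professional"
    cohort <- prepare_cohort(reports, plan, filter = f)
    res <- purrr::map(plan$drugs, \(d)
                      analyse_pair(cohort, d, "is_case", plan, analysis)) |>
      bind_rows()
    attr(res, "flow") <- flow_counts(cohort)
    return(res)
  }
  if (variant == "S4") {
    f <- plan$filter
    f$exclude_confounded <- TRUE
    cohort <- prepare_cohort(reports, plan, filter = f)
    res <- purrr::map(plan$drugs, \(d)
                      analyse_pair(cohort, d, "is_case", plan, analysis)) |>
      bind_rows()
    attr(res, "flow") <- flow_counts(cohort)
    return(res)
  }
  # S3: per-ET pre-iCDK4/6 window
  et_classes <- c("AI", "SERM", "SERD")
  class_of <- setNames(plan$drug_dict$drug_class, plan$drug_dict$drug_id)
  et_drugs <- plan$drugs[class_of[plan$drugs] %in% et_classes]
  icdk_drugs <- plan$drug_dict$drug_id[plan$drug_dict$drug_class == "iCDK46"]
  icdk_first <- first_report_date(reports, icdk_drugs)
  if (is.na(icdk_first)) {
    warn("S3 skipped: no CDK4/6-inhibitor reports to anchor the window")
    return(ror_result(character(0), character(0), character(0)) |>
             mutate(analysis = character(0)))
  }
  res <- purrr::map(et_drugs, function(d) {
    d_first <- first_report_date(reports, d)
    if (is.na(d_first) || d_first >= icdk_first) {
      out <- ror_result(d, "NCI", "logistic_adjusted",
                        note = "no pre-iCDK4/6 window for this drug")
      out$signal <- FALSE
      out$analysis <- analysis
      return(out)
    }
    f <- plan$filter
    # closed at the ET's first report, open at the iCDK4/6 class's first
    f$window <- c(d_first, icdk_first - 1L)
    cohort <- prepare_cohort(reports, plan, filter = f)
    analyse_pair(cohort, d, "is_case", plan, analysis)
  }) |> bind_rows()
  res
}
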