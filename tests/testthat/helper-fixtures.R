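# Shared fixtures: packaged dictionaries, a hand-built report constructor,
# and direct strat_table builders for estimator tests.

pkg_term_dict <- function() {
  load_term_dictionary(rorcase_example("term_dictionary.csv"))
}

pkg_drug_dict <- function() {
  load_drug_dictionary(rorcase_example("drug_dictionary.csv"))
}

pkg_query <- function() load_case_query(rorcase_example("nci_query.yaml"))

pkg_case_set <- function(dict = pkg_term_dict()) {
  resolve_query(dict, pkg_query())
}

# one hand-built report row; drugs/roles/events are plain character vectors
report_row <- function(report_id, age = 60, sex = "female",
                       date = "2018-06-01", drugs = "paracetamol",
                       roles = "suspect", events = "nausea",
                       reporter = "healthcare_professional",
                       region = "Americas", serious = FALSE,
                       interrupted = FALSE, comorbidity = FALSE,
                       cotreatment = FALSE) {
  tibble::tibble(
    report_id = report_id,
    date = as.Date(date),
    sex = sex,
    age_years = if (is.na(age)) NA_integer_ else as.integer(age),
    region = region,
    reporter = reporter,
    serious = serious,
    action_interrupted = interrupted,
    drug_id = list(as.character(drugs)),
    drug_role = list(rep_len(as.character(roles), length(drugs))),
    events = list(as.character(events)),
    nci_comorbidity = comorbidity,
    nci_cotreatment = cotreatment
  )
}

# build a strat_table directly from per-stratum cell counts; each of a, b,
# c, d is a vector over the supplied strata
mk_table <- function(a, b, c, d,
                     strata = c("18-44", "45-64", "65-74", "75+")[seq_along(a)],
                     drug = "drug_x", outcome = "is_case") {
  out <- tibble::tibble(
    drug_id = drug,
    stratum = factor(strata, levels = c("18-44", "45-64", "65-74", "75+",
                                        "missing")),
    a = as.integer(a), b = as.integer(b), c = as.integer(c), d = as.integer(d)
  )
  attr(out, "outcome") <- outcome
  class(out) <- c("strat_table", class(out))
  out
}

# a labelled 8-report cohort used by the build_table hand-count tests:
# 4 exposed reports (3 cases), 4 unexposed (1 case), all one age stratum
hand_cohort <- function(role = "suspect") {
  reports <- dplyr::bind_rows(
    report_row("e1", drugs = "letrozole", roles = role,
               events = "memory_impairment"),
    report_row("e2", drugs = "letrozole", roles = role, events = "amnesia"),
    report_row("e3", drugs = "letrozole", roles = role,
               events = "speech_disorder"),
    report_row("e4", drugs = "letrozole", roles = role, events = "nausea"),
    report_row("u1", events = "memory_impairment"),
    report_row("u2", events = "fatigue"),
    report_row("u3", events = "rash"),
    report_row("u4", events = "arthralgia")
  )
  label_reports(reports, pkg_case_set(), pkg_term_dict())
}
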