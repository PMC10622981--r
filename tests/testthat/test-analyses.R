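# a compact synthetic database shared by the orchestration tests
analyses_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      cfg <- generator_config(
        n_reports = 60000, seed = 101,
        effects = tibble::tibble(drug_id = "letrozole", outcome = "NCI",
                                 or = 2.2))
      db <<- generate_reports(cfg)
    }
    db
  }
})

test_that("the primary analysis reports every drug, computed or not", {
  res <- run_primary(analyses_db(), study_plan())
  lr <- dplyr::filter(res, method == "logistic_adjusted")
  expect_equal(nrow(lr), 9)
  expect_setequal(unique(res$method),
                  c("logistic_adjusted", "mantel_haenszel", "crude"))
  # toremifene is vanishingly rare in the default exposure mix: its row is
  # present but not calculable, never dropped
  tor <- dplyr::filter(lr, drug_id == "toremifene")
  expect_equal(nrow(tor), 1)
  expect_false(tor$computed)
  expect_false(tor$signal)
  # the configured letrozole effect is detected
  let <- dplyr::filter(lr, drug_id == "letrozole")
  expect_true(let$signal)
  se <- (log(let$ci_high) - log(let$ci_low)) / (2 * 1.959964)
  expect_lt(abs(log(let$ror) - log(2.2)), 3 * se)
})

test_that("domain subgroups use domain cases against all other reports", {
  dict <- pkg_term_dict()
  case_set <- pkg_case_set(dict)
  # fixture where the drug's only NCI events are language-mapped
  reports <- dplyr::bind_rows(
    report_row("l1", drugs = "fulvestrant", events = "aphasia"),
    report_row("l2", drugs = "fulvestrant", events = "speech_disorder"),
    report_row("l3", drugs = "fulvestrant", events = "dysarthria"),
    report_row("n1", drugs = "fulvestrant", events = "nausea"),
    purrr::map(1:6, \(i) report_row(paste0("u", i), events = "fatigue")) |>
      dplyr::bind_rows(),
    report_row("u7", events = "memory_impairment")
  )
  lab <- label_reports(reports, case_set, dict)
  coh <- apply_filters(lab, cohort_filter())
  lang <- pool_table(build_table(coh, "fulvestrant", outcome = "dom_language"))
  nci <- pool_table(build_table(coh, "fulvestrant", outcome = "is_case"))
  expect_equal(lang$n_observed, nci$n_observed)  # all its cases are language
  mem <- pool_table(build_table(coh, "fulvestrant",
                                outcome = "dom_learning_and_memory"))
  expect_equal(mem$n_observed, 0L)
  # non-cases for the language outcome include the memory case u7
  expect_equal(lang$a + lang$b + lang$c + lang$d, nrow(coh))

  # with single-domain reports the domain n_observed partition the NCI count
  doms <- vapply(c("dom_language", "dom_learning_and_memory",
                   "dom_complex_attention", "dom_executive_function",
                   "dom_perceptual_motor_function", "dom_social_cognition"),
                 \(o) pool_table(build_table(coh, "fulvestrant",
                                             outcome = o))$n_observed,
                 integer(1))
  expect_equal(sum(doms), nci$n_observed)

  # with a multi-domain report the domain counts sum to more than the cases
  multi <- dplyr::bind_rows(
    reports,
    report_row("l4", drugs = "fulvestrant",
               events = c("aphasia", "memory_impairment")))
  coh2 <- apply_filters(label_reports(multi, case_set, dict), cohort_filter())
  nci2 <- pool_table(build_table(coh2, "fulvestrant"))$n_observed
  doms2 <- vapply(names(doms), \(o)
                  pool_table(build_table(coh2, "fulvestrant",
                                         outcome = o))$n_observed,
                  integer(1))
  expect_gt(sum(doms2), nci2)
})

test_that("configured domain effects are recovered through run_domain_subgroups", {
  cfg <- generator_config(
    n_reports = 120000, seed = 111,
    effects = tibble::tibble(drug_id = "palbociclib", outcome = "language",
                             or = 2.74))
  res <- run_domain_subgroups(generate_reports(cfg), study_plan())
  lang <- dplyr::filter(res, method == "logistic_adjusted",
                        drug_id == "palbociclib", outcome == "language")
  expect_true(lang$computed)
  se <- (log(lang$ci_high) - log(lang$ci_low)) / (2 * 1.959964)
  expect_lt(abs(log(lang$ror) - log(2.74)), 3 * se)
  # sparse pairs are flagged not-calculable rather than dropped
  soc <- dplyr::filter(res, method == "logistic_adjusted",
                       outcome == "social cognition",
                       drug_id == "toremifene")
  expect_false(soc$computed)
})

test_that("S1 restricts only the unexposed non-case cells", {
  dict <- pkg_term_dict()
  case_set <- pkg_case_set(dict)
  # every exposed report carries the (oncology-class) study drug; half the
  # unexposed non-cases carry an oncology co-medication
  reports <- dplyr::bind_rows(
    report_row("e1", drugs = "anastrozole", events = "memory_impairment"),
    report_row("e2", drugs = "anastrozole", events = "amnesia"),
    report_row("e3", drugs = "anastrozole", events = "nausea"),
    report_row("c1", events = "cognitive_disorder"),
    report_row("n1", drugs = "capecitabine", events = "nausea"),
    report_row("n2", drugs = "paclitaxel", events = "fatigue"),
    report_row("n3", drugs = "paracetamol", events = "rash"),
    report_row("n4", drugs = "amlodipine", events = "fatigue")
  )
  lab <- label_reports(reports, case_set, dict)
  coh <- apply_filters(lab, cohort_filter())
  before <- pool_table(build_table(coh, "anastrozole"))
  coh1 <- restrict_noncases_oncology(coh, pkg_drug_dict())
  after <- pool_table(build_table(coh1, "anastrozole"))
  expect_equal(after$a, before$a)
  expect_equal(after$b, before$b)
  expect_equal(after$c, before$c)   # cases always kept
  expect_equal(after$d, before$d - 2L)  # n3, n4 removed
  fl <- flow_counts(coh1)
  expect_equal(fl$filter[nrow(fl)], "noncase_oncology_restrict")
  expect_equal(fl$removed[nrow(fl)], 2L)
})

test_that("S1 on generated data never touches exposed cells of study drugs", {
  plan <- study_plan()
  cohort <- rorcase:::prepare_cohort(analyses_db(), plan)
  restricted <- restrict_noncases_oncology(cohort, plan$drug_dict)
  for (d in c("anastrozole", "palbociclib", "tamoxifen")) {
    p0 <- pool_table(build_table(cohort, d))
    p1 <- pool_table(build_table(restricted, d))
    expect_equal(p1$a, p0$a)
    expect_equal(p1$b, p0$b)
    expect_lte(p1$d, p0$d)
  }
})

test_that("S2 keeps only healthcare-professional reports", {
  res2 <- run_sensitivity(analyses_db(), study_plan(), "S2")
  fl <- attr(res2, "flow")
  hcp_step <- fl[fl$filter == "reporter=healthcare_professional", ]
  expect_equal(nrow(hcp_step), 1)
  expect_gt(hcp_step$removed, 0)
  expect_equal(unique(res2$analysis), "sensitivity_S2")
})

test_that("S3 windows are closed at the ET start and open at the iCDK start", {
  dict <- pkg_term_dict()
  reports <- dplyr::bind_rows(
    report_row("t1", date = "2014-02-01", drugs = "tamoxifen",
               events = "memory_impairment"),
    report_row("t2", date = "2014-06-01", drugs = "tamoxifen",
               events = "amnesia"),
    report_row("t3", date = "2014-12-31", drugs = "tamoxifen",
               events = "nausea"),
    # first iCDK4/6 report: 2015-01-01; tamoxifen reports from that day on
    # fall outside the pre-combination window
    report_row("p1", date = "2015-01-01", drugs = "palbociclib",
               events = "nausea"),
    report_row("t4", date = "2015-01-01", drugs = "tamoxifen",
               events = "cognitive_disorder"),
    report_row("t5", date = "2016-01-01", drugs = "tamoxifen",
               events = "memory_impairment"),
    purrr::map(1:8, \(i) report_row(paste0("bg", i),
                                    date = "2014-07-01",
                                    events = "fatigue")) |>
      dplyr::bind_rows()
  )
  plan <- study_plan(drugs = c("tamoxifen", "palbociclib"))
  res <- run_sensitivity(reports, plan, "S3")
  # only ET drugs are analysed in S3
  expect_setequal(unique(res$drug_id), "tamoxifen")
  lr <- dplyr::filter(res, method == "logistic_adjusted")
  # window [2014-02-01, 2014-12-31]: t1..t3 in, t4/t5 and the iCDK day out
  expect_equal(lr$n_drug_total, 3L)
  expect_equal(lr$n_observed, 2L)
})

test_that("S3 is skipped when no iCDK4/6 reports exist", {
  reports <- dplyr::bind_rows(
    report_row("t1", drugs = "tamoxifen", events = "memory_impairment"),
    report_row("t2", events = "fatigue")
  )
  expect_warning(res <- run_sensitivity(reports, study_plan(), "S3"),
                 "S3 skipped")
  expect_equal(nrow(res), 0)
})

test_that("S4 with no flagged reports reproduces the primary results", {
  db <- analyses_db()
  db$nci_comorbidity <- FALSE
  db$nci_cotreatment <- FALSE
  plan <- study_plan()
  prim <- run_primary(db, plan)
  s4 <- run_sensitivity(db, plan, "S4")
  expect_equal(dplyr::select(s4, -"analysis"),
               dplyr::select(prim, -"analysis"), ignore_attr = TRUE)
})

test_that("sensitivity flows reconcile with the primary cohort", {
  db <- analyses_db()
  plan <- study_plan()
  prim_flow <- attr(run_primary(db, plan), "flow")
  s4_flow <- attr(run_sensitivity(db, plan, "S4"), "flow")
  # S4 applies one extra removal step; totals still conserve
  expect_equal(s4_flow$remaining[1], prim_flow$remaining[1])
  expect_equal(s4_flow$remaining[nrow(s4_flow)],
               s4_flow$remaining[1] - sum(s4_flow$removed))
})
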