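test_that("generator configs are validated before any sampling", {
  expect_error(generator_config(0), "n_reports")
  expect_error(
    generator_config(10, age_probs = c("18-44" = 0.5, "45-64" = 0.6,
                                       "65-74" = 0, "75+" = 0,
                                       "missing" = 0)),
    "age_probs")
  expect_error(
    generator_config(10, effects = tibble::tibble(
      drug_id = "letrozole", outcome = "NCI", or = -1)),
    "positive")
  expect_error(
    generator_config(10, effects = tibble::tibble(
      drug_id = "letrozole", outcome = "mood", or = 2)),
    "outcome")
})

test_that("identical config and seed reproduce identical output", {
  cfg <- generator_config(n_reports = 400, seed = 11)
  r1 <- generate_reports(cfg)
  r2 <- generate_reports(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  t1 <- withr::local_tempfile(fileext = ".jsonl")
  t2 <- withr::local_tempfile(fileext = ".jsonl")
  write_reports_jsonl(r1, t1)
  write_reports_jsonl(r2, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
  # different seed, different stream
  r3 <- generate_reports(generator_config(n_reports = 400, seed = 12))
  expect_false(identical(as.data.frame(r1), as.data.frame(r3)))
})

test_that("generated reports satisfy the structural invariants", {
  cfg <- generator_config(n_reports = 5000, seed = 21)
  reports <- generate_reports(cfg)
  expect_equal(nrow(reports), 5000)
  expect_invisible(validate_reports(reports,
                                    date_range = cfg$date_range))
  expect_true(all(lengths(reports$events) >= 1))
  dm <- drug_mentions(reports)
  expect_false(any(duplicated(dm[c("report_id", "drug_id", "role")])))
})

test_that("empirical age-class shares match the configured mix", {
  cfg <- generator_config(n_reports = 50000, seed = 31)
  reports <- generate_reports(cfg)
  shares <- prop.table(table(assign_age_class(reports$age_years)))
  target <- c("18-44" = 0.05, "45-64" = 0.29, "65-74" = 0.26,
              "75+" = 0.23, "missing" = 0.17)
  # binomial SE at n = 50,000 is ~0.2pp; 1.5pp is a generous envelope
  expect_true(all(abs(shares[names(target)] - target) < 0.015))
})

test_that("ground truth tabulates configured effects and defaults to OR 1", {
  cfg0 <- generator_config(n_reports = 10, seed = 1)
  gt0 <- ground_truth(cfg0)
  expect_true(all(gt0$effects$true_or == 1))

  cfg1 <- generator_config(n_reports = 10, seed = 1,
                           effects = tibble::tibble(
                             drug_id = "palbociclib", outcome = "NCI",
                             or = 1.41))
  gt1 <- ground_truth(cfg1)
  non_unit <- gt1$effects[gt1$effects$true_or != 1, ]
  expect_equal(nrow(non_unit), 1)
  expect_equal(non_unit$drug_id, "palbociclib")
  expect_equal(non_unit$true_or, 1.41)
  expect_equal(
    gt1$baseline_odds$case_odds,
    unname(cfg1$base_case_prob / (1 - cfg1$base_case_prob)))
})

test_that("single-stratum single-effect design recovers the generating OR", {
  # one age stratum, one configured effect: the empirical 2x2 odds ratio
  # converges to theta within 3 Monte-Carlo SEs at n = 200,000
  theta <- 2.0
  cfg <- generator_config(
    n_reports = 200000, seed = 41,
    age_probs = c("18-44" = 0, "45-64" = 1, "65-74" = 0, "75+" = 0,
                  "missing" = 0),
    effects = tibble::tibble(drug_id = "letrozole", outcome = "NCI",
                             or = theta))
  reports <- generate_reports(cfg)
  lab <- label_reports(reports, pkg_case_set(), pkg_term_dict())
  tab <- build_table(lab, "letrozole")
  res <- crude_ror(tab)
  se <- (log(res$ci_high) - log(res$ci_low)) / (2 * 1.959964)
  expect_lt(abs(log(res$ror) - log(theta)), 3 * se)
})

test_that("the confounded null separates crude from within-stratum ORs", {
  # default design: exposure and baseline case risk both rise with age;
  # all effects at OR 1
  cfg <- generator_config(n_reports = 150000, seed = 54)
  reports <- generate_reports(cfg)
  lab <- label_reports(reports, pkg_case_set(), pkg_term_dict())
  coh <- apply_filters(lab, cohort_filter(sex = NULL, require_age = TRUE))
  tab <- build_table(coh, "letrozole")
  crude <- crude_ror(tab)
  expect_gt(abs(crude$ror - 1), 0.1)
  # every within-stratum empirical OR stays near 1 (0.5-corrected cells so
  # sparse young strata cannot produce degenerate zeros)
  strata <- tab[tab$stratum != "missing", ]
  for (k in seq_len(nrow(strata))) {
    cells <- unlist(strata[k, c("a", "b", "c", "d")]) + 0.5
    or_k <- (cells[1] * cells[4]) / (cells[2] * cells[3])
    se_k <- sqrt(sum(1 / cells))
    expect_lt(abs(log(or_k)), 3 * se_k)
  }
  # and both adjusted estimators sit within Monte-Carlo error of 1
  for (res in list(mh_adjusted_ror(tab), lr_adjusted_ror_counts(tab))) {
    se <- (log(res$ci_high) - log(res$ci_low)) / (2 * 1.959964)
    expect_lt(abs(log(res$ror)), 3 * se)
  }
})

test_that("a domain-only effect dilutes the composite-outcome OR", {
  theta_dom <- 3
  cfg <- generator_config(
    n_reports = 150000, seed = 61,
    age_probs = c("18-44" = 0, "45-64" = 1, "65-74" = 0, "75+" = 0,
                  "missing" = 0),
    effects = tibble::tibble(drug_id = "palbociclib", outcome = "language",
                             or = theta_dom))
  reports <- generate_reports(cfg)
  lab <- label_reports(reports, pkg_case_set(), pkg_term_dict())
  dom <- crude_ror(build_table(lab, "palbociclib", outcome = "dom_language"))
  nci <- crude_ror(build_table(lab, "palbociclib", outcome = "is_case"))
  se_dom <- (log(dom$ci_high) - log(dom$ci_low)) / (2 * 1.959964)
  expect_lt(abs(log(dom$ror) - log(theta_dom)), 3 * se_dom)
  # composite NCI outcome: strictly between 1 and the domain OR
  expect_gt(nci$ror, 1)
  expect_lt(nci$ror, theta_dom)
})
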