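#' Build a synthetic-database generator configuration
#'
#' Describes a synthetic spontaneous-report database: demographic mixes,
#' per-drug age-class-specific exposure probabilities, per-age-class baseline
#' probabilities of a neurocognitive-impairment (NCI) case, a distribution of
#' cases over the six DSM-5 domains, and a list of true within-age-stratum
#' conditional odds ratios ("effects") linking drug exposure to the NCI
#' outcome or to a single domain sub-outcome. Downstream estimators are
#' validated by recovering these generating odds ratios.
#'
#' The default demographic mixes emulate a worldwide oncology
#' pharmacovigilance stream: age shares (5, 29, 26, 23, 17)% over
#' 18–44 / 45–64 / 65–74 / 75+ / missing, region concentrated in the
#' Americas, a mixed reporter population, and 57% seriousness among cases.
#' Default exposure and baseline-risk schedules rise with age in opposite
#' directions of magnitude (exposure multipliers 0.3–1.8, baseline case risk
#' 0.8%–4.0%), which makes age a genuine confounder: with all effects at
#' OR 1 the pooled crude odds ratio sits visibly above 1 while every
#' within-stratum odds ratio is null.
#'
#' @param n_reports Number of reports to generate.
#' @param seed Integer seed; identical config + seed reproduce the output
#'   byte for byte.
#' @param date_range Length-2 date vector (inclusive) over which report
#'   dates are uniform.
#' @param term_dict,drug_dict Dictionaries ([load_term_dictionary()],
#'   [load_drug_dictionary()]); default to the packaged fixtures.
#' @param age_probs Named probabilities over the five age classes.
#' @param sex_probs,region_probs,reporter_probs Named categorical mixes.
#' @param base_case_prob Named per-age-class baseline probability that a
#'   report is an NCI case (all domains combined), at null exposure.
#' @param domain_mix Named distribution of baseline case risk over the six
#'   DSM-5 domains (sums to 1).
#' @param drug_specs Tibble with one row per drug: `drug_id`, per-age-class
#'   exposure probabilities `p18_44`, `p45_64`, `p65_74`, `p75plus`,
#'   `pmissing`, and `available_from` (date before which exposure is zero).
#'   Defaults cover every drug in `drug_dict`.
#' @param effects Tibble with columns `drug_id`, `outcome` (`"NCI"` or one
#'   DSM-5 domain name), `or` (true conditional odds ratio, > 0). An
#'   NCI-level effect multiplies the within-stratum odds of every domain
#'   sub-outcome so the any-NCI conditional odds ratio equals `or` (up to a
#'   rare-outcome approximation); a domain-level effect multiplies only that
#'   domain's odds, so the domain sub-outcome has conditional odds ratio
#'   exactly `or` and the any-NCI odds ratio is diluted towards 1.
#' @param coupling_prob Probability that a CDK4/6-inhibitor-exposed report
#'   without an endocrine-therapy mention gains a co-prescribed endocrine
#'   therapy (combination-therapy coupling). Default 0: independent
#'   exposures.
#' @param onc_comention_prob Probability that a study-drug-exposed report
#'   also mentions an antineoplastic agent (oncology co-mention, used by the
#'   oncology-restricted sensitivity analysis).
#' @param serious_prob_case,serious_prob_noncase Seriousness probabilities.
#' @param interrupt_prob_serious_case Probability that treatment was
#'   interrupted on a serious case report.
#' @param comorbidity_prob,cotreatment_prob Probabilities of the
#'   NCI-confounder flags (co-illness / co-treatment known to cause NCI).
#' @param second_domain_pt_prob Probability that a case carries a second PT
#'   from an affected domain.
#' @param extra_event_prob Per-trial probability of the zero-inflated extra
#'   non-NCI event draw (each report adds `Binomial(2, p)` extra PTs on top
#'   of its guaranteed event).
#' @param disease_pt_prob Probability that a report additionally carries a
#'   disease-flagged PT from the neurocognitive hierarchy (these never make
#'   a report a case: the case definition excludes disease terms).
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_reports,
    seed = 1L,
    date_range = as.Date(c("2014-01-01", "2022-03-16")),
    term_dict = NULL,
    drug_dict = NULL,
    age_probs = c("18-44" = 0.05, "45-64" = 0.29, "65-74" = 0.26,
                  "75+" = 0.23, "missing" = 0.17),
    sex_probs = c(female = 0.85, male = 0.12, unknown = 0.03),
    region_probs = c(Americas = 0.75, Europe = 0.21, EMediterranean = 0.012,
                     Asia = 0.012, Africa = 0.009, other = 0.007),
    reporter_probs = c(healthcare_professional = 0.55, non_hcp = 0.40,
                       unknown = 0.05),
    base_case_prob = c("18-44" = 0.008, "45-64" = 0.015, "65-74" = 0.026,
                       "75+" = 0.040, "missing" = 0.025),
    domain_mix = c("complex attention" = 0.25, "executive function" = 0.08,
                   "language" = 0.12, "learning and memory" = 0.40,
                   "perceptual motor function" = 0.12,
                   "social cognition" = 0.03),
    drug_specs = NULL,
    effects = tibble(drug_id = character(), outcome = character(),
                     or = numeric()),
    coupling_prob = 0,
    onc_comention_prob = 0.40,
    serious_prob_case = 0.57,
    serious_prob_noncase = 0.40,
    interrupt_prob_serious_case = 1 / 3,
    comorbidity_prob = 0.02,
    cotreatment_prob = 0.007,
    second_domain_pt_prob = 0.20,
    extra_event_prob = 0.15,
    disease_pt_prob = 0.008) {
  term_dict <- term_dict %||%
    load_term_dictionary(rorcase_example("term_dictionary.csv"))
  drug_dict <- drug_dict %||%
    load_drug_dictionary(rorcase_example("drug_dictionary.csv"))
  drug_specs <- drug_specs %||% default_drug_specs(drug_dict, date_range[1])
  effects <- as_tibble(effects)
  cfg <- structure(
    list(
      n_reports = as.integer(n_reports), seed = as.integer(seed),
      date_range = as.Date(date_range),
      term_dict = term_dict, drug_dict = drug_dict,
      age_probs = age_probs, sex_probs = sex_probs,
      region_probs = region_probs, reporter_probs = reporter_probs,
      base_case_prob = base_case_prob, domain_mix = domain_mix,
      drug_specs = drug_specs, effects = effects,
      coupling_prob = coupling_prob,
      onc_comention_prob = onc_comention_prob,
      serious_prob_case = serious_prob_case,
      serious_prob_noncase = serious_prob_noncase,
      interrupt_prob_serious_case = interrupt_prob_serious_case,
      comorbidity_prob = comorbidity_prob,
      cotreatment_prob = cotreatment_prob,
      second_domain_pt_prob = second_domain_pt_prob,
      extra_event_prob = extra_event_prob,
      disease_pt_prob = disease_pt_prob
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Default per-drug exposure schedules
#'
#' Exposure probability per age class is `base * multiplier`, with
#' multipliers (0.3, 0.7, 1.3, 1.8, 1.0) over the five age classes for
#' breast-cancer study drugs (exposure rises with age, the confounding arm of
#' the design) and flat multipliers for background drugs. CDK4/6 inhibitors
#' carry market-entry dates inside the study window so pre-launch reports
#' are never exposed.
#'
#' @param drug_dict A drug dictionary.
#' @param window_start First database date (availability default).
#' @return A `drug_specs` tibble (see [generator_config()]).
#' @export
default_drug_specs <- function(drug_dict, window_start = as.Date("2014-01-01")) {
  base <- c(
    anastrozole = 0.012, letrozole = 0.020, exemestane = 0.010,
    tamoxifen = 0.012, toremifene = 0.0002, fulvestrant = 0.012,
    palbociclib = 0.020, ribociclib = 0.008, abemaciclib = 0.007,
    capecitabine = 0.015, paclitaxel = 0.015, trastuzumab = 0.010,
    pembrolizumab = 0.005, atezolizumab = 0.004,
    morphine = 0.010, lorazepam = 0.008, metformin = 0.020,
    amlodipine = 0.020, paracetamol = 0.030, levothyroxine = 0.015
  )
  study_classes <- c("AI", "SERM", "SERD", "iCDK46")
  launch <- c(palbociclib = "2015-02-03", ribociclib = "2017-03-13",
              abemaciclib = "2017-09-28")
  mult_study <- c(0.3, 0.7, 1.3, 1.8, 1.0)
  purrr::pmap(drug_dict[c("drug_id", "drug_class")], function(drug_id, drug_class) {
    b <- if (drug_id %in% names(base)) base[[drug_id]] else 0.01
    m <- if (drug_class %in% study_classes) mult_study else rep(1, 5)
    p <- b * m
    tibble(
      drug_id = drug_id,
      p18_44 = p[1], p45_64 = p[2], p65_74 = p[3], p75plus = p[4],
      pmissing = p[5],
      available_from = as.Date(
        if (drug_id %in% names(launch)) launch[[drug_id]] else
          as.character(window_start))
    )
  }) |> bind_rows()
}

validate_generator_config <- function(cfg) {
  if (is.na(cfg$n_reports) || cfg$n_reports < 1) {
    abort("n_reports must be at least 1")
  }
  if (cfg$date_range[1] > cfg$date_range[2]) abort("date_range start > end")
  check_mix <- function(p, what, levels) {
    if (!setequal(names(p), levels)) {
      abort(paste0(what, " must be named over: ", paste(levels, collapse = ", ")))
    }
    if (any(p < 0 | p > 1)) abort(paste0(what, " outside [0, 1]"))
    if (abs(sum(p) - 1) > 1e-8) abort(paste0(what, " must sum to 1"))
  }
  check_mix(cfg$age_probs, "age_probs", AGE_CLASSES)
  check_mix(cfg$sex_probs, "sex_probs", SEX_LEVELS)
  check_mix(cfg$region_probs, "region_probs", REGION_LEVELS)
  check_mix(cfg$reporter_probs, "reporter_probs", REPORTER_LEVELS)
  check_mix(cfg$domain_mix, "domain_mix", DSM5_DOMAINS)
  if (!setequal(names(cfg$base_case_prob), AGE_CLASSES) ||
      any(cfg$base_case_prob <= 0 | cfg$base_case_prob >= 1)) {
    abort("base_case_prob must be named over the age classes, in (0, 1)")
  }
  pcols <- c("p18_44", "p45_64", "p65_74", "p75plus", "pmissing")
  spec_p <- as.matrix(cfg$drug_specs[pcols])
  if (any(spec_p < 0 | spec_p > 1)) abort("drug exposure probability outside [0, 1]")
  if (anyDuplicated(cfg$drug_specs$drug_id)) abort("duplicate drug_id in drug_specs")
  unknown <- setdiff(cfg$drug_specs$drug_id, cfg$drug_dict$drug_id)
  if (length(unknown) > 0) {
    abort(paste0("drug_specs for drugs absent from the drug dictionary: ",
                 paste(unknown, collapse = ", ")))
  }
  if (nrow(cfg$effects) > 0) {
    if (any(!cfg$effects$outcome %in% c("NCI", DSM5_DOMAINS))) {
      abort("effect outcome must be \"NCI\" or one of the six DSM-5 domains")
    }
    if (any(cfg$effects$or <= 0)) abort("true conditional OR must be positive")
    if (any(!cfg$effects$drug_id %in% cfg$drug_specs$drug_id)) {
      abort("effect on a drug with no exposure spec")
    }
    if (anyDuplicated(cfg$effects[c("drug_id", "outcome")])) {
      abort("duplicate (drug_id, outcome) effect")
    }
  }
  scalars <- c("coupling_prob", "onc_comention_prob", "serious_prob_case",
               "serious_prob_noncase", "interrupt_prob_serious_case",
               "comorbidity_prob", "cotreatment_prob",
               "second_domain_pt_prob", "extra_event_prob", "disease_pt_prob")
  for (s in scalars) {
    v <- cfg[[s]]
    if (length(v) != 1 || v < 0 || v > 1) abort(paste0(s, " outside [0, 1]"))
  }
  invisible(cfg)
}

#' Tabulate the generating ground truth
#'
#' Deterministic tabulation of the configured effects over every
#' (drug, outcome) pair: configured pairs carry their generating
#' within-stratum conditional odds ratio, all others OR 1, plus the
#' per-age-class baseline case odds.
#'
#' @param config A `generator_config`.
#' @return A list with `effects` (tibble `drug_id`, `outcome`, `true_or`
#'   over all drugs x (NCI + six domains)) and `baseline_odds` (tibble
#'   `age_class`, `case_odds`).
#' @export
ground_truth <- function(config) {
  grid <- tidyr::expand_grid(
    drug_id = config$drug_specs$drug_id,
    outcome = c("NCI", DSM5_DOMAINS)
  )
  eff <- config$effects |>
    select(drug_id = "drug_id", outcome = "outcome", true_or = "or")
  out <- grid |>
    left_join(eff, by = c("drug_id", "outcome")) |>
    mutate(true_or = dplyr::coalesce(.data$true_or, 1))
  p <- config$base_case_prob[AGE_CLASSES]
  list(
    effects = out,
    baseline_odds = tibble(age_class = AGE_CLASSES,
                           case_odds = unname(p / (1 - p)))
  )
}

#' Generate a synthetic report stream
#'
#' Samples `n_reports` individual case safety reports under the generative
#' model of [generator_config()]: demographics and dates first, then per-drug
#' exposures with age-class-specific probabilities (zero before a drug's
#' availability date), then the outcome via six independent per-domain
#' logistic draws whose log-odds are the age-class baseline plus the
#' configured effect contributions of the report's exposures, then event PTs
#' (each affected domain contributes at least one symptom PT; every report
#' carries at least one event), drug role codes, seriousness and confounder
#' flags. The same configuration and seed always reproduce the identical
#' tibble.
#'
#' @param config A validated `generator_config`.
#' @return A report tibble (one row per report; `drug_id`, `drug_role` and
#'   `events` are list-columns of parallel character vectors) with
#'   attributes `date_range` and `generator_seed`.
#' @export
#' @examples
#' cfg <- generator_config(
#'   n_reports = 2000, seed = 42,
#'   effects = tibble::tibble(drug_id = "letrozole", outcome = "NCI", or = 2)
#' )
#' reports <- generate_reports(cfg)
#' dplyr::glimpse(reports[1:3, ])
generate_reports <- function(config) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_reports_impl(config))
}

generate_reports_impl <- function(cfg) {
  n <- cfg$n_reports
  dict <- cfg$term_dict
  ddict <- cfg$drug_dict

  ## demographics ------------------------------------------------------------
  age_idx <- sample.int(5L, n, replace = TRUE, prob = cfg$age_probs[AGE_CLASSES])
  amin <- c(18L, 45L, 65L, 75L, NA)
  amax <- c(44L, 64L, 74L, 95L, NA)
  age_years <- amin[age_idx] +
    as.integer(floor(runif(n) * (amax[age_idx] - amin[age_idx] + 1L)))
  sex <- sample(SEX_LEVELS, n, replace = TRUE, prob = cfg$sex_probs[SEX_LEVELS])
  region <- sample(REGION_LEVELS, n, replace = TRUE,
                   prob = cfg$region_probs[REGION_LEVELS])
  reporter <- sample(REPORTER_LEVELS, n, replace = TRUE,
                     prob = cfg$reporter_probs[REPORTER_LEVELS])
  ndays <- as.integer(cfg$date_range[2] - cfg$date_range[1]) + 1L
  date <- cfg$date_range[1] + (sample.int(ndays, n, replace = TRUE) - 1L)

  ## exposures ---------------------------------------------------------------
  specs <- cfg$drug_specs
  pmat <- as.matrix(specs[c("p18_44", "p45_64", "p65_74", "p75plus", "pmissing")])
  exposed_idx <- vector("list", nrow(specs))
  names(exposed_idx) <- specs$drug_id
  for (j in seq_len(nrow(specs))) {
    p <- pmat[j, age_idx]
    hit <- runif(n) < p & date >= specs$available_from[j]
    exposed_idx[[j]] <- which(hit)
  }
  class_of <- setNames(ddict$drug_class, ddict$drug_id)
  et_drugs <- specs$drug_id[class_of[specs$drug_id] %in% c("AI", "SERM", "SERD")]
  icdk_drugs <- specs$drug_id[class_of[specs$drug_id] == "iCDK46"]

  if (cfg$coupling_prob > 0 && length(icdk_drugs) > 0 && length(et_drugs) > 0) {
    any_et <- logical(n)
    for (d in et_drugs) any_et[exposed_idx[[d]]] <- TRUE
    any_icdk <- logical(n)
    for (d in icdk_drugs) any_icdk[exposed_idx[[d]]] <- TRUE
    cand <- which(any_icdk & !any_et)
    cand <- cand[runif(length(cand)) < cfg$coupling_prob]
    if (length(cand) > 0) {
      pick <- sample(et_drugs, length(cand), replace = TRUE)
      for (d in unique(pick)) {
        add <- cand[pick == d]
        add <- add[date[add] >= specs$available_from[specs$drug_id == d]]
        exposed_idx[[d]] <- sort(c(exposed_idx[[d]], add))
      }
    }
  }

  ## outcome: six per-domain logistic draws ----------------------------------
  base_p <- cfg$base_case_prob[AGE_CLASSES]
  mix <- cfg$domain_mix[DSM5_DOMAINS]
  logit_base <- qlogis(outer(base_p, mix))   # 5 age classes x 6 domains
  L <- logit_base[age_idx, , drop = FALSE]   # n x 6
  if (nrow(cfg$effects) > 0) {
    for (k in seq_len(nrow(cfg$effects))) {
      eff <- cfg$effects[k, ]
      cols <- if (eff$outcome == "NCI") seq_along(DSM5_DOMAINS) else
        match(eff$outcome, DSM5_DOMAINS)
      rows <- exposed_idx[[eff$drug_id]]
      L[rows, cols] <- L[rows, cols] + log(eff$or)
    }
  }
  Y <- matrix(runif(n * 6L), n, 6L) < plogis(L)
  is_case <- rowSums(Y) > 0L

  ## events ------------------------------------------------------------------
  nci_pool <- lapply(DSM5_DOMAINS, function(d) {
    sub <- dict[!dict$disease_flag & !is.na(dict$dsm5_domain) &
                  dict$dsm5_domain == d, ]
    # first-listed PT is the dominant symptom of the domain
    list(pt = sub$pt_code,
         w = if (nrow(sub) > 1) c(3, rep(1, nrow(sub) - 1)) else 1)
  })
  non_nci_pts <- dict$pt_code[is.na(dict$dsm5_domain) & !dict$disease_flag]
  disease_pts <- dict$pt_code[dict$disease_flag]

  ev_idx <- integer(0)
  ev_pt <- character(0)
  for (j in seq_along(DSM5_DOMAINS)) {
    rows <- which(Y[, j])
    if (length(rows) == 0) next
    pool <- nci_pool[[j]]
    pts <- sample(pool$pt, length(rows), replace = TRUE, prob = pool$w)
    ev_idx <- c(ev_idx, rows)
    ev_pt <- c(ev_pt, pts)
    second <- rows[runif(length(rows)) < cfg$second_domain_pt_prob]
    if (length(second) > 0) {
      ev_idx <- c(ev_idx, second)
      ev_pt <- c(ev_pt, sample(pool$pt, length(second), replace = TRUE,
                               prob = pool$w))
    }
  }
  noncase_rows <- which(!is_case)
  ev_idx <- c(ev_idx, noncase_rows)
  ev_pt <- c(ev_pt, sample(non_nci_pts, length(noncase_rows), replace = TRUE))
  n_extra <- rbinom(n, 2L, cfg$extra_event_prob)
  extra_rows <- rep(seq_len(n), n_extra)
  if (length(extra_rows) > 0) {
    ev_idx <- c(ev_idx, extra_rows)
    ev_pt <- c(ev_pt, sample(non_nci_pts, length(extra_rows), replace = TRUE))
  }
  dz_rows <- which(runif(n) < cfg$disease_pt_prob)
  if (length(dz_rows) > 0 && length(disease_pts) > 0) {
    ev_idx <- c(ev_idx, dz_rows)
    ev_pt <- c(ev_pt, sample(disease_pts, length(dz_rows), replace = TRUE))
  }
  o <- order(ev_idx, ev_pt)
  ev_idx <- ev_idx[o]
  ev_pt <- ev_pt[o]
  keep <- !duplicated(paste0(ev_idx, "\r", ev_pt))
  events <- unname(split(ev_pt[keep], factor(ev_idx[keep], levels = seq_len(n))))

  ## drug mentions -----------------------------------------------------------
  study_set <- specs$drug_id[class_of[specs$drug_id] %in%
                               c("AI", "SERM", "SERD", "iCDK46")]
  dm_idx <- integer(0)
  dm_drug <- character(0)
  dm_role <- character(0)
  any_study <- logical(n)
  for (d in specs$drug_id) {
    rows <- exposed_idx[[d]]
    if (length(rows) == 0) next
    if (d %in% study_set) {
      any_study[rows] <- TRUE
      roles <- sample(DRUG_ROLES, length(rows), replace = TRUE,
                      prob = c(0.80, 0.05, 0.15))
    } else {
      roles <- sample(DRUG_ROLES, length(rows), replace = TRUE,
                      prob = c(0.25, 0.05, 0.70))
    }
    dm_idx <- c(dm_idx, rows)
    dm_drug <- c(dm_drug, rep(d, length(rows)))
    dm_role <- c(dm_role, roles)
  }
  antineo <- ddict$drug_id[ddict$drug_class == "antineoplastic"]
  if (cfg$onc_comention_prob > 0 && length(antineo) > 0) {
    rows <- which(any_study)
    rows <- rows[runif(length(rows)) < cfg$onc_comention_prob]
    if (length(rows) > 0) {
      dm_idx <- c(dm_idx, rows)
      dm_drug <- c(dm_drug, sample(antineo, length(rows), replace = TRUE))
      dm_role <- c(dm_role, sample(DRUG_ROLES, length(rows), replace = TRUE,
                                   prob = c(0.3, 0.05, 0.65)))
    }
  }
  # every report names at least one drug
  bare <- setdiff(seq_len(n), unique(dm_idx))
  if (length(bare) > 0) {
    others <- ddict$drug_id[ddict$drug_class == "other"]
    if (length(others) == 0) others <- ddict$drug_id
    dm_idx <- c(dm_idx, bare)
    dm_drug <- c(dm_drug, sample(others, length(bare), replace = TRUE))
    dm_role <- c(dm_role, rep("suspect", length(bare)))
  }
  o <- order(dm_idx, dm_drug)
  dm_idx <- dm_idx[o]
  dm_drug <- dm_drug[o]
  dm_role <- dm_role[o]
  keep <- !duplicated(paste0(dm_idx, "\r", dm_drug))
  f <- factor(dm_idx[keep], levels = seq_len(n))
  drug_id <- unname(split(dm_drug[keep], f))
  drug_role <- unname(split(dm_role[keep], f))

  ## flags -------------------------------------------------------------------
  serious <- runif(n) < if_else(is_case, cfg$serious_prob_case,
                                cfg$serious_prob_noncase)
  action_interrupted <- runif(n) <
    if_else(serious & is_case, cfg$interrupt_prob_serious_case, 0.05)
  nci_comorbidity <- runif(n) < cfg$comorbidity_prob
  nci_cotreatment <- runif(n) < cfg$cotreatment_prob

  out <- tibble(
    report_id = sprintf("R%08d", seq_len(n)),
    date = date,
    sex = sex,
    age_years = age_years,
    region = region,
    reporter = reporter,
    serious = serious,
    action_interrupted = action_interrupted,
    drug_id = drug_id,
    drug_role = drug_role,
    events = events,
    nci_comorbidity = nci_comorbidity,
    nci_cotreatment = nci_cotreatment
  )
  attr(out, "date_range") <- cfg$date_range
  attr(out, "generator_seed") <- cfg$seed
  out
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config>\n")
  cat("  n_reports:", x$n_reports, "  seed:", x$seed, "\n")
  cat("  window:", format(x$date_range[1]), "to", format(x$date_range[2]), "\n")
  cat("  drugs with exposure specs:", nrow(x$drug_specs), "\n")
  if (nrow(x$effects) == 0) {
    cat("  effects: none (global null)\n")
  } else {
    cat("  effects:\n")
    for (k in seq_len(nrow(x$effects))) {
      cat(sprintf("    %s ~ %s: OR %.3g\n", x$effects$drug_id[k],
                  x$effects$outcome[k], x$effects$or[k]))
    }
  }
  invisible(x)
}
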