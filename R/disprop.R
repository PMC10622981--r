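# Critical value for 95% intervals, carried to full double precision so
# interval endpoints are reproducible bit-for-bit across implementations.
Z975 <- 1.959964

# one-row result skeleton shared by every estimator
ror_result <- function(drug_id, outcome, method, a = NA_integer_,
                       b = NA_integer_, point = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, computed = FALSE, note = NA_character_) {
  tibble(
    drug_id = drug_id,
    outcome = outcome,
    method = method,
    n_observed = as.integer(a),
    n_drug_b = as.integer(b),
    n_drug_total = as.integer(a) + as.integer(b),
    ror = point,
    ci_low = ci_low,
    ci_high = ci_high,
    computed = computed,
    signal = NA,
    note = note
  )
}

#' Crude reporting odds ratio
#'
#' Pools the stratified table and computes the classical case/non-case
#' reporting odds ratio `ROR = (a d) / (b c)` with the Woolf (log-normal)
#' 95% interval `exp(ln ROR +/- 1.959964 * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' When any cell is zero, 0.5 is added to all four cells
#' (Haldane–Anscombe) and the result is annotated.
#'
#' @param table A `strat_table` from [build_table()] (all strata are
#'   pooled, including missing age).
#' @return A one-row results tibble (see [apply_signal_rules()] for the
#'   signal column).
#' @export
crude_ror <- function(table) {
  p <- pool_table(table)
  drug <- table$drug_id[1]
  outc <- outcome_name(attr(table, "outcome"))
  if (p$a + p$b == 0) {
    return(ror_result(drug, outc, "crude", a = p$a, b = p$b,
                      note = "drug absent from cohort"))
  }
  cells <- c(p$a, p$b, p$c, p$d)
  note <- NA_character_
  if (any(cells == 0)) {
    cells <- cells + 0.5
    note <- "Haldane-Anscombe 0.5 correction (zero cell)"
  }
  lo <- log(cells[1]) + log(cells[4]) - log(cells[2]) - log(cells[3])
  se <- sqrt(sum(1 / cells))
  ror_result(drug, outc, "crude", a = p$a, b = p$b,
             point = exp(lo), ci_low = exp(lo - Z975 * se),
             ci_high = exp(lo + Z975 * se), computed = TRUE, note = note)
}

#' Mantel–Haenszel age-adjusted reporting odds ratio
#'
#' Stratifies over the four known-age classes (missing age excluded) and
#' combines with the Mantel–Haenszel estimator
#' `sum_k(a_k d_k / n_k) / sum_k(b_k c_k / n_k)`, with the
#' Robins–Breslow–Greenland variance for the 95% interval. Serves as the
#' closed-form cross-check for the primary logistic adjustment.
#'
#' @param table A `strat_table`.
#' @return A one-row results tibble.
#' @export
mh_adjusted_ror <- function(table) {
  drug <- table$drug_id[1]
  outc <- outcome_name(attr(table, "outcome"))
  tab <- as_tibble(table) |> filter(.data$stratum != "missing")
  nk <- tab$a + tab$b + tab$c + tab$d
  use <- nk > 0
  tab <- tab[use, , drop = FALSE]
  nk <- nk[use]
  p <- pool_table(table, drop_missing_age = TRUE)
  R <- tab$a * tab$d / nk
  S <- tab$b * tab$c / nk
  if (nrow(tab) == 0 || sum(R) == 0 || sum(S) == 0) {
    return(ror_result(drug, outc, "mantel_haenszel", a = p$a, b = p$b,
                      note = "degenerate strata: MH estimator undefined"))
  }
  P <- (tab$a + tab$d) / nk
  Q <- (tab$b + tab$c) / nk
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  lo <- log(sum(R) / sum(S))
  se <- sqrt(var_log)
  ror_result(drug, outc, "mantel_haenszel", a = p$a, b = p$b,
             point = exp(lo), ci_low = exp(lo - Z975 * se),
             ci_high = exp(lo + Z975 * se), computed = TRUE)
}

#' Logistic-regression age-adjusted reporting odds ratio
#'
#' The primary adjustment method: fits
#' `logit P(outcome) = b0 + b1 exposed + age-class indicators` (reference
#' class 45–64) on the known-age cohort, and reports `exp(b1)` with its Wald
#' 95% interval. The fit is performed on counts aggregated over the eight
#' (age class x exposure) cells, which is the same likelihood as the
#' report-level fit at a fraction of the cost. Non-convergence or complete
#' separation yield `computed = FALSE` with a diagnostic note.
#'
#' @param cohort A labelled cohort tibble.
#' @param drug_id Drug of interest.
#' @param roles Accepted role codes (defaults to the cohort's filter roles).
#' @param outcome Logical outcome column (default `"is_case"`).
#' @param mentions Optional precomputed [drug_mentions()] table.
#' @return A one-row results tibble with `method = "logistic_adjusted"`.
#' @export
lr_adjusted_ror <- function(cohort, drug_id, roles = NULL,
                            outcome = "is_case", mentions = NULL) {
  roles <- roles %||% attr(cohort, "roles") %||% DRUG_ROLES
  outc <- outcome_name(outcome)
  keep <- !is.na(cohort$age_years)
  sub <- cohort[keep, , drop = FALSE]
  exp_ids <- exposed_ids(cohort, drug_id, roles, mentions = mentions)
  exposed <- sub$report_id %in% exp_ids
  case <- sub[[outcome]]
  a <- sum(case & exposed)
  b <- sum(!case & exposed)
  if (a + b == 0) {
    return(ror_result(drug_id, outc, "logistic_adjusted", a = a, b = b,
                      note = "drug absent from known-age cohort"))
  }
  if (all(exposed) || sum(case) == 0 || all(case)) {
    return(ror_result(drug_id, outc, "logistic_adjusted", a = a, b = b,
                      note = "degenerate cohort: outcome or exposure constant"))
  }
  agg <- tibble(
    age_class = factor(assign_age_class(sub$age_years),
                       levels = AGE_CLASSES[1:4]),
    exposed = exposed,
    case = case
  ) |>
    group_by(.data$age_class, .data$exposed) |>
    summarise(n_case = sum(.data$case), n_non = sum(!.data$case),
              .groups = "drop")
  fit_lr_agg(agg, drug_id, outc, a, b)
}

#' Logistic age-adjusted ROR from a stratified count table
#'
#' The same logistic estimator as [lr_adjusted_ror()], fitted from the
#' per-stratum 2x2 counts instead of report-level data (the aggregated
#' counts are a sufficient statistic for the model, so the two routes give
#' identical estimates). Strata with missing age are excluded.
#'
#' @param table A `strat_table` from [build_table()], or any tibble with
#'   columns `stratum`, `a`, `b`, `c`, `d`.
#' @return A one-row results tibble with `method = "logistic_adjusted"`.
#' @export
lr_adjusted_ror_counts <- function(table) {
  drug <- if ("drug_id" %in% names(table)) table$drug_id[1] else NA_character_
  outc <- outcome_name(attr(table, "outcome"))
  tab <- as_tibble(table) |> filter(.data$stratum != "missing")
  a <- sum(tab$a)
  b <- sum(tab$b)
  if (a + b == 0) {
    return(ror_result(drug, outc, "logistic_adjusted", a = a, b = b,
                      note = "drug absent from known-age cohort"))
  }
  if (sum(tab$c) + sum(tab$d) == 0 || a + sum(tab$c) == 0 ||
      b + sum(tab$d) == 0) {
    return(ror_result(drug, outc, "logistic_adjusted", a = a, b = b,
                      note = "degenerate cohort: outcome or exposure constant"))
  }
  agg <- bind_rows(
    tibble(age_class = tab$stratum, exposed = TRUE,
           n_case = tab$a, n_non = tab$b),
    tibble(age_class = tab$stratum, exposed = FALSE,
           n_case = tab$c, n_non = tab$d)
  ) |>
    mutate(age_class = factor(as.character(.data$age_class),
                              levels = AGE_CLASSES[1:4])) |>
    filter(.data$n_case + .data$n_non > 0)
  fit_lr_agg(agg, drug, outc, a, b)
}

# weighted-binomial logistic fit on (age_class, exposed) cells; the exposure
# coefficient is the adjusted log ROR, reference age class 45-64
fit_lr_agg <- function(agg, drug_id, outc, a, b) {
  agg <- agg |>
    filter(!is.na(.data$age_class)) |>
    mutate(age_class = droplevels(.data$age_class))
  if ("45-64" %in% levels(agg$age_class)) {
    agg <- agg |> mutate(age_class = stats::relevel(.data$age_class,
                                                    ref = "45-64"))
  }
  form <- if (nlevels(agg$age_class) > 1) {
    cbind(n_case, n_non) ~ exposed + age_class
  } else {
    cbind(n_case, n_non) ~ exposed   # single stratum: no age term needed
  }
  fit <- tryCatch(
    suppressWarnings(glm(form, family = binomial(), data = agg)),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || !"exposedTRUE" %in% names(coef(fit))) {
    return(ror_result(drug_id, outc, "logistic_adjusted", a = a, b = b,
                      note = "logistic fit failed to converge"))
  }
  est <- coef(fit)[["exposedTRUE"]]
  se <- sqrt(diag(stats::vcov(fit)))[["exposedTRUE"]]
  if (!is.finite(est) || !is.finite(se) || se > 50) {
    return(ror_result(drug_id, outc, "logistic_adjusted", a = a, b = b,
                      note = "separation: exposure coefficient unstable"))
  }
  ror_result(drug_id, outc, "logistic_adjusted", a = a, b = b,
             point = exp(est), ci_low = exp(est - Z975 * se),
             ci_high = exp(est + Z975 * se), computed = TRUE)
}

outcome_name <- function(outcome) {
  if (is.null(outcome) || outcome == "is_case") "NCI"
  else if (startsWith(outcome, "dom_")) domain_from_column(outcome)
  else outcome
}

#' Apply minimum-report and signal rules
#'
#' Disproportionality results are only interpreted when at least
#' `min_count` case reports carry the drug: below that, the estimate is
#' suppressed (`computed = FALSE`, point and interval blanked, rendered
#' "NC"). For computed results the signal flag is the strict rule
#' `ci_low > 1`.
#'
#' @param results A results tibble (one or more rows).
#' @param min_count Minimum `n_observed` (default 5).
#' @return `results` with `computed` and `signal` finalised.
#' @export
apply_signal_rules <- function(results, min_count = 5) {
  suppressed <- results$computed & results$n_observed < min_count
  results |>
    mutate(
      computed = .data$computed & .data$n_observed >= min_count,
      note = if_else(suppressed,
                     sprintf("fewer than %d observed reports", min_count),
                     .data$note),
      ror = if_else(.data$computed, .data$ror, NA_real_),
      ci_low = if_else(.data$computed, .data$ci_low, NA_real_),
      ci_high = if_else(.data$computed, .data$ci_high, NA_real_),
      signal = .data$computed & !is.na(.data$ci_low) & .data$ci_low > 1
    )
}
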