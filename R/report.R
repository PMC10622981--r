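#' Run a complete study from a configuration
#'
#' End-to-end driver: obtain reports (either generated from a seeded
#' synthetic configuration or read from a JSONL file), label them with the
#' case query, run the primary analysis, the six DSM-5 domain subgroups and
#' the requested sensitivity variants, and collect rendered views, flow
#' counts, a demographics summary and run metadata into a study bundle.
#' Deterministic given the seed: rerunning an identical configuration
#' reproduces the results byte for byte.
#'
#' @param config Either a path to a YAML file or a list with elements:
#'   `reports_path` (JSONL) *or* `generator` (a list of
#'   [generator_config()] arguments, e.g. `n_reports`, `seed`, `effects` as
#'   a list of `{drug_id, outcome, or}` records); optional `term_dictionary`
#'   / `drug_dictionary` / `case_query` paths (packaged fixtures by
#'   default); optional `sensitivity` (subset of S1–S4; default all);
#'   optional `min_count`.
#' @return A list of class `nci_study`: `results` (combined long tibble),
#'   `table1`, `table2` (rendered views), `flow`, `demographics`,
#'   `metadata`.
#' @export
run_study <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  term_dict <- if (!is.null(config$term_dictionary)) {
    load_term_dictionary(config$term_dictionary)
  } else NULL
  drug_dict <- if (!is.null(config$drug_dictionary)) {
    load_drug_dictionary(config$drug_dictionary)
  } else NULL
  query <- if (!is.null(config$case_query)) {
    load_case_query(config$case_query)
  } else NULL
  plan <- study_plan(term_dict = term_dict, drug_dict = drug_dict,
                     query = query,
                     min_count = config$min_count %||% 5)
  seed <- NA_integer_
  if (!is.null(config$reports_path)) {
    reports <- read_reports_jsonl(config$reports_path)
  } else if (!is.null(config$generator)) {
    gen <- config$generator
    if (!is.null(gen$effects)) {
      gen$effects <- bind_rows(lapply(gen$effects, as_tibble))
    }
    gen$term_dict <- plan$term_dict
    gen$drug_dict <- plan$drug_dict
    cfg <- do.call(generator_config, gen)
    seed <- cfg$seed
    reports <- generate_reports(cfg)
  } else {
    abort("config needs either reports_path or a generator block")
  }

  primary <- run_primary(reports, plan)
  subgroups <- run_domain_subgroups(reports, plan)
  variants <- config$sensitivity %||% c("S1", "S2", "S3", "S4")
  sens <- purrr::map(variants, \(v) run_sensitivity(reports, plan, v)) |>
    bind_rows()
  results <- bind_rows(primary, subgroups, sens)

  cohort <- prepare_cohort(reports, plan)
  # demographics describe the study population before the age restriction,
  # so the missing-age share is visible alongside the four adult bands
  dem_filter <- plan$filter
  dem_filter$require_age <- FALSE
  dem_cohort <- prepare_cohort(reports, plan, filter = dem_filter)
  structure(
    list(
      results = results,
      table1 = render_table1(primary),
      table2 = render_table2(subgroups),
      flow = flow_counts(cohort),
      demographics = demographics_summary(dem_cohort),
      metadata = list(
        seed = seed,
        n_reports_in = nrow(reports),
        cohort_size = nrow(cohort),
        n_cases = sum(cohort$is_case),
        drugs = plan$drugs,
        window = format(plan$filter$window),
        roles = plan$filter$roles,
        min_count = plan$min_count,
        rounding = "percentages rounded to nearest integer",
        filter_order = flow_counts(cohort)$filter,
        package_version = as.character(utils::packageVersion("rorcase"))
      )
    ),
    class = "nci_study"
  )
}

fmt_or <- function(x) ifelse(is.na(x), "NC", sprintf("%.2f", x))

#' Render the primary results view
#'
#' One row per drug for the primary age-adjusted method, in the layout of a
#' disproportionality summary table: observed case reports with the drug
#' (`n_observed`), non-case reports with the drug (`n_drug`), total reports
#' with the drug, the adjusted ROR and its 95% interval (or "NC" when not
#' calculable), and the signal marker derived from the strict
#' lower-bound-above-1 rule. `n_drug` is the non-case count `b`, so
#' `n_drug = n_drug_total - n_observed`; both are reported to avoid
#' ambiguity.
#'
#' @param results A results tibble from [run_primary()].
#' @return A rendered tibble.
#' @export
render_table1 <- function(results) {
  results |>
    filter(.data$method == "logistic_adjusted") |>
    mutate(
      drug = .data$drug_id,
      n_drug = .data$n_drug_b,
      ror = fmt_or(.data$ror),
      ci_95 = if_else(.data$computed,
                      sprintf("(%.2f-%.2f)", .data$ci_low, .data$ci_high),
                      "NC"),
      signal = if_else(.data$computed & .data$signal, "*", "")
    ) |>
    select("drug", "n_observed", "n_drug", "n_drug_total", "ror",
           "ci_95", "signal")
}

#' Render the DSM-5 domain subgroup view
#'
#' Like [render_table1()] with a leading outcome column for the six
#' neurocognitive domains; pairs under the minimum-report rule render "NC".
#'
#' @param results A results tibble from [run_domain_subgroups()].
#' @return A rendered tibble.
#' @export
render_table2 <- function(results) {
  results |>
    filter(.data$method == "logistic_adjusted") |>
    mutate(
      subtype = .data$outcome,
      drug = .data$drug_id,
      n_drug = .data$n_drug_b,
      aror = fmt_or(.data$ror),
      ci_95 = if_else(.data$computed,
                      sprintf("(%.2f-%.2f)", .data$ci_low, .data$ci_high),
                      "NC"),
      signal = if_else(.data$computed & .data$signal, "*", "")
    ) |>
    arrange(.data$subtype, .data$drug) |>
    select("subtype", "drug", "n_observed", "n_drug", "n_drug_total",
           "aror", "ci_95", "signal")
}

#' Demographic summary of a cohort
#'
#' Share tables (counts and integer-rounded percentages) for age class,
#' region, reporter type and seriousness. After integer rounding the
#' percentages of each block sum to 100 +/- 1.
#'
#' @param cohort A (labelled) cohort tibble.
#' @return A named list of tibbles (`age`, `region`, `reporter`,
#'   `seriousness`), each with `level`, `n`, `pct`.
#' @export
demographics_summary <- function(cohort) {
  share <- function(x, levels) {
    tb <- table(factor(x, levels = levels))
    tibble(level = names(tb), n = as.integer(tb),
           pct = as.integer(round(100 * as.integer(tb) / sum(tb))))
  }
  list(
    age = share(as.character(assign_age_class(cohort$age_years)), AGE_CLASSES),
    region = share(cohort$region, REGION_LEVELS),
    reporter = share(cohort$reporter, REPORTER_LEVELS),
    seriousness = share(if_else(cohort$serious, "serious", "non_serious"),
                        c("serious", "non_serious"))
  )
}

#' Write a study bundle to disk
#'
#' Persists the bundle as plain-text artifacts: `results.csv` (combined
#' long results), `table1.csv`, `table2.csv`, `forest.csv` (drug, point,
#' interval, analysis — data for external forest plotting), `flow.json`,
#' `demographics.json` and `metadata.json`.
#'
#' @param study An `nci_study` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$results, file.path(dir, "results.csv"))
  readr::write_csv(study$table1, file.path(dir, "table1.csv"))
  readr::write_csv(study$table2, file.path(dir, "table2.csv"))
  forest <- study$results |>
    filter(.data$method == "logistic_adjusted", .data$computed) |>
    select(drug = "drug_id", outcome = "outcome", point = "ror",
           low = "ci_low", high = "ci_high", analysis = "analysis")
  readr::write_csv(forest, file.path(dir, "forest.csv"))
  jsonlite::write_json(study$flow, file.path(dir, "flow.json"),
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(study$demographics, file.path(dir, "demographics.json"),
                       dataframe = "rows", pretty = TRUE)
  jsonlite::write_json(study$metadata, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.nci_study <- function(x, ...) {
  cat("<nci_study>\n")
  cat("  cohort:", x$metadata$cohort_size, "reports,",
      x$metadata$n_cases, "cases\n")
  cat("  analyses:", paste(unique(x$results$analysis), collapse = ", "), "\n")
  sig <- x$results |>
    filter(.data$method == "logistic_adjusted",
           .data$analysis == "primary", .data$signal)
  cat("  primary signals:",
      if (nrow(sig) == 0) "none" else paste(sig$drug_id, collapse = ", "),
      "\n")
  invisible(x)
}

#' Tidy a study bundle
#'
#' @param x An `nci_study`.
#' @param ... Unused.
#' @return The combined long results tibble (one row per drug x outcome x
#'   method x analysis).
#' @method tidy nci_study
#' @export
tidy.nci_study <- function(x, ...) as_tibble(x$results)

#' One-row study summary
#'
#' @param x An `nci_study`.
#' @param ... Unused.
#' @return A one-row tibble: reports in, cohort size, case count, number of
#'   drug/outcome pairs analysed and number of primary signals.
#' @method glance nci_study
#' @export
glance.nci_study <- function(x, ...) {
  prim <- x$results |>
    filter(.data$method == "logistic_adjusted", .data$analysis == "primary")
  tibble(
    n_reports_in = x$metadata$n_reports_in,
    cohort_size = x$metadata$cohort_size,
    n_cases = x$metadata$n_cases,
    n_pairs = nrow(dplyr::distinct(x$results,
                                   .data$drug_id, .data$outcome,
                                   .data$analysis)),
    n_primary_signals = sum(prim$signal, na.rm = TRUE)
  )
}

#' Forest plot of disproportionality results
#'
#' Point estimates with 95% intervals on a log scale, one row per
#' drug/outcome, faceted by analysis; the dashed line marks the null. Only
#' computed results are drawn.
#'
#' @param results A results tibble (any of the `run_*` outputs, or
#'   `tidy(study)`).
#' @param method Which estimator to plot (default the primary logistic
#'   adjustment).
#' @return A ggplot object.
#' @export
plot_forest <- function(results, method = "logistic_adjusted") {
  dat <- results |>
    filter(.data$method == !!method, .data$computed) |>
    mutate(label = if_else(.data$outcome == "NCI", .data$drug_id,
                           paste0(.data$drug_id, ": ", .data$outcome)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ror, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high,
                                          colour = .data$signal)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey30",
                                            "TRUE" = "firebrick"),
                                 guide = "none") +
    ggplot2::facet_wrap(~analysis, scales = "free_y") +
    ggplot2::labs(x = "reporting odds ratio (95% CI, log scale)", y = NULL)
}

#' @rdname plot_forest
#' @param object An `nci_study` bundle.
#' @param ... Passed to [plot_forest()].
#' @method autoplot nci_study
#' @export
autoplot.nci_study <- function(object, ...) plot_forest(object$results, ...)
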