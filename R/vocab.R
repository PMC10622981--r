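#' Load a term dictionary
#'
#' Reads a CSV dictionary of MedDRA-style preferred terms (PTs) with their
#' hierarchy (HLT, HLGT, SOC), SMQ memberships, a disease flag, and an
#' optional DSM-5 neurocognitive domain. The dictionary defines the universe
#' of event codes a report may carry and is the substrate for case-definition
#' queries: the disease flag marks PTs that denote an established
#' neurological or psychiatric *disease* (excluded from symptom-level case
#' definitions), and `dsm5_domain` maps symptom PTs into one of the six DSM-5
#' neurocognitive domains.
#'
#' Required columns: `pt_code`, `pt_name`, `hlt`, `hlgt`, `soc`, `smqs`
#' (semicolon-joined SMQ names, may be empty), `disease_flag`
#' (logical), `dsm5_domain` (one of the six domain names, or empty for PTs
#' outside the neurocognitive query).
#'
#' @param path Path to a CSV file.
#' @return A tibble of class `term_dictionary` with `smqs` parsed into a
#'   list-column of character vectors.
#' @export
#' @examples
#' dict <- load_term_dictionary(rorcase_example("term_dictionary.csv"))
#' dplyr::count(dict, .data$dsm5_domain)
load_term_dictionary <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  needed <- c("pt_code", "pt_name", "hlt", "hlgt", "soc", "smqs",
              "disease_flag", "dsm5_domain")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("term dictionary is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- raw$pt_code[duplicated(raw$pt_code)]
  if (length(dup) > 0) {
    abort(paste0("duplicate pt_code in term dictionary: ",
                 paste(unique(dup), collapse = ", ")))
  }
  dict <- raw |>
    mutate(
      smqs = strsplit(dplyr::coalesce(.data$smqs, ""), ";", fixed = TRUE),
      smqs = purrr::map(.data$smqs, \(x) trimws(x[nzchar(trimws(x))])),
      disease_flag = parse_flag(.data$disease_flag, "disease_flag"),
      dsm5_domain = if_else(
        is.na(.data$dsm5_domain) | .data$dsm5_domain == "",
        NA_character_, .data$dsm5_domain
      )
    )
  bad <- dict |>
    filter(!is.na(.data$dsm5_domain), !.data$dsm5_domain %in% DSM5_DOMAINS)
  if (nrow(bad) > 0) {
    abort(paste0(
      "dsm5_domain outside the six DSM-5 neurocognitive domains for pt_code ",
      paste(bad$pt_code, collapse = ", "), " (found: ",
      paste(unique(bad$dsm5_domain), collapse = ", "), ")"
    ))
  }
  class(dict) <- c("term_dictionary", class(dict))
  dict
}

#' Write a term dictionary back to CSV
#'
#' Inverse of [load_term_dictionary()]: the written file reloads to the same
#' semantic content (SMQ lists re-joined with `;`).
#'
#' @param dict A `term_dictionary`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_term_dictionary <- function(dict, path) {
  out <- dict |>
    mutate(
      smqs = purrr::map_chr(.data$smqs, paste, collapse = ";"),
      dsm5_domain = dplyr::coalesce(.data$dsm5_domain, "")
    )
  readr::write_csv(as_tibble(out), path)
  invisible(path)
}

#' Load a drug dictionary
#'
#' Reads a CSV of drugs with therapeutic class and a flag for co-treatments
#' known to cause neurocognitive impairment. Classes: aromatase inhibitor
#' (`AI`), selective estrogen-receptor modulator (`SERM`) / degrader
#' (`SERD`), CDK4/6 inhibitor (`iCDK46`), `antineoplastic`, `immunotherapy`,
#' `other`.
#'
#' @param path Path to a CSV with columns `drug_id`, `name`, `drug_class`,
#'   `known_nci_cotreatment`.
#' @return A tibble of class `drug_dictionary`.
#' @export
load_drug_dictionary <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  needed <- c("drug_id", "name", "drug_class", "known_nci_cotreatment")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("drug dictionary is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- raw$drug_id[duplicated(raw$drug_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate drug_id in drug dictionary: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(raw$drug_class), DRUG_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("unknown drug_class: ", paste(bad, collapse = ", ")))
  }
  dict <- raw |>
    mutate(known_nci_cotreatment =
             parse_flag(.data$known_nci_cotreatment, "known_nci_cotreatment"))
  class(dict) <- c("drug_dictionary", class(dict))
  dict
}

parse_flag <- function(x, what) {
  out <- dplyr::case_match(tolower(as.character(x)),
    c("true", "t", "1", "yes") ~ TRUE,
    c("false", "f", "0", "no") ~ FALSE,
    .default = NA
  )
  if (anyNA(out)) abort(paste0("non-logical value in column ", what))
  out
}

#' Assign age classes
#'
#' Maps age in completed years to the four adult bands used for
#' stratification — 18–44, 45–64, 65–74, 75+ — or `"missing"` when age is
#' unavailable. The bands partition `[18, Inf)`; ages under 18 are a
#' validation error (the study population has no paediatric class).
#'
#' @param age_years Integer vector of ages, `NA` allowed.
#' @return A factor with levels `r paste(AGE_CLASSES, collapse = ", ")`.
#' @export
#' @examples
#' assign_age_class(c(44, 45, 70, NA))
assign_age_class <- function(age_years) {
  age_years <- as.numeric(age_years)
  if (any(age_years < 18, na.rm = TRUE)) {
    abort("age_years below 18: not a valid study report age")
  }
  if (any(age_years < 0, na.rm = TRUE)) abort("negative age_years")
  cls <- cut(age_years, breaks = c(18, 45, 65, 75, Inf), right = FALSE,
             labels = AGE_CLASSES[1:4])
  cls <- as.character(cls)
  cls[is.na(age_years)] <- "missing"
  factor(cls, levels = AGE_CLASSES)
}

#' Long view of drug mentions
#'
#' Unnests the per-report drug list-columns into one row per
#' (report, drug, role) mention.
#'
#' @param reports A report tibble (see [generate_reports()] for the schema).
#' @return A tibble with columns `report_id`, `drug_id`, `role`.
#' @export
drug_mentions <- function(reports) {
  lens <- lengths(reports$drug_id)
  tibble(
    report_id = rep(reports$report_id, lens),
    drug_id = unlist(reports$drug_id, use.names = FALSE),
    role = unlist(reports$drug_role, use.names = FALSE)
  )
}

#' Long view of event mentions
#'
#' @param reports A report tibble.
#' @return A tibble with columns `report_id`, `pt_code`, one row per
#'   reported event term.
#' @export
event_mentions <- function(reports) {
  lens <- lengths(reports$events)
  tibble(
    report_id = rep(reports$report_id, lens),
    pt_code = unlist(reports$events, use.names = FALSE)
  )
}

#' Validate a report tibble
#'
#' Structural checks on a set of individual case safety reports: required
#' columns, nonempty event lists, deduplicated (drug, role) pairs, known
#' categorical levels, adult ages, and (optionally) dates inside the declared
#' database range.
#'
#' @param reports A report tibble.
#' @param date_range Optional length-2 `Date` (or coercible) vector; when
#'   given, report dates must fall inside it (inclusive).
#' @return `reports`, invisibly, if valid; otherwise an error naming the
#'   offending report(s).
#' @export
validate_reports <- function(reports, date_range = NULL) {
  needed <- c("report_id", "date", "sex", "age_years", "region", "reporter",
              "serious", "action_interrupted", "drug_id", "drug_role",
              "events", "nci_comorbidity", "nci_cotreatment")
  missing_cols <- setdiff(needed, names(reports))
  if (length(missing_cols) > 0) {
    abort(paste0("reports are missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(reports$report_id)) abort("duplicate report_id")
  empty <- lengths(reports$events) == 0
  if (any(empty)) {
    abort(paste0("report(s) with no events: ",
                 paste(utils::head(reports$report_id[empty], 5),
                       collapse = ", ")))
  }
  dm <- drug_mentions(reports)
  dup <- dm[duplicated(dm), , drop = FALSE]
  if (nrow(dup) > 0) {
    abort(paste0("duplicated (drug_id, role) pair on report(s): ",
                 paste(utils::head(unique(dup$report_id), 5),
                       collapse = ", ")))
  }
  if (!all(dm$role %in% DRUG_ROLES)) abort("unknown drug role code")
  if (!all(reports$sex %in% SEX_LEVELS)) abort("unknown sex level")
  if (!all(reports$reporter %in% REPORTER_LEVELS)) abort("unknown reporter level")
  if (!all(reports$region %in% REGION_LEVELS)) abort("unknown region level")
  assign_age_class(reports$age_years)  # errors on under-18
  if (!is.null(date_range)) {
    date_range <- as.Date(date_range)
    bad <- reports$date < date_range[1] | reports$date > date_range[2]
    if (any(bad)) {
      abort(paste0("report date outside declared database range: ",
                   paste(utils::head(reports$report_id[bad], 5),
                         collapse = ", ")))
    }
  }
  invisible(reports)
}

#' Path to a packaged example/fixture file
#'
#' @param file File name under the package's `extdata/` (defaults to listing
#'   available files).
#' @return A file path, or a character vector of available files.
#' @export
rorcase_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "rorcase"))
  } else {
    p <- system.file("extdata", file, package = "rorcase")
    if (p == "") abort(paste0("no packaged file named ", file))
    p
  }
}
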