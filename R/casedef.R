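#' Build a case-definition query
#'
#' A case query names SMQ/HLGT groups to include, plus optional explicit
#' PT-level additions and removals. Resolution semantics (see
#' [resolve_query()]): exclusions always win over inclusions, and PTs
#' carrying the dictionary's disease flag are always removed, restricting
#' the case definition to symptom-level terms.
#'
#' @param included_groups Character vector of SMQ or HLGT names.
#' @param included_pts,excluded_pts Character vectors of PT codes.
#' @return A list of class `case_query`.
#' @export
case_query <- function(included_groups, included_pts = character(),
                       excluded_pts = character()) {
  structure(
    list(included_groups = as.character(included_groups),
         included_pts = as.character(included_pts),
         excluded_pts = as.character(excluded_pts)),
    class = "case_query"
  )
}

#' Load a case query from YAML
#'
#' @param path YAML file with keys `included_groups`, `included_pts`,
#'   `excluded_pts`. The packaged neurocognitive-impairment query is at
#'   `rorcase_example("nci_query.yaml")`.
#' @return A `case_query`.
#' @export
load_case_query <- function(path) {
  y <- yaml::read_yaml(path)
  case_query(
    included_groups = unlist(y$included_groups) %||% character(),
    included_pts = unlist(y$included_pts) %||% character(),
    excluded_pts = unlist(y$excluded_pts) %||% character()
  )
}

#' Resolve a case query against a term dictionary
#'
#' Returns the PT codes defining the case set: the union of all PTs whose
#' HLGT or SMQ membership matches an included group, plus explicit PT
#' additions, minus explicit PT removals, minus every PT flagged as a
#' disease term. Unknown group or PT names are an error.
#'
#' @param dict A `term_dictionary`.
#' @param query A `case_query`.
#' @return A character vector of PT codes (sorted, unique).
#' @export
#' @examples
#' dict <- load_term_dictionary(rorcase_example("term_dictionary.csv"))
#' query <- load_case_query(rorcase_example("nci_query.yaml"))
#' length(resolve_query(dict, query))
resolve_query <- function(dict, query) {
  smq_names <- unique(unlist(dict$smqs, use.names = FALSE))
  known_groups <- union(unique(dict$hlgt), smq_names)
  bad <- setdiff(query$included_groups, known_groups)
  if (length(bad) > 0) {
    abort(paste0("unknown group name(s) in query: ", paste(bad, collapse = ", ")))
  }
  bad_pt <- setdiff(c(query$included_pts, query$excluded_pts), dict$pt_code)
  if (length(bad_pt) > 0) {
    abort(paste0("unknown PT code(s) in query: ", paste(bad_pt, collapse = ", ")))
  }
  in_smq <- purrr::map_lgl(dict$smqs, \(s) any(s %in% query$included_groups))
  hit <- dict$hlgt %in% query$included_groups | in_smq
  pts <- union(dict$pt_code[hit], query$included_pts)
  pts <- setdiff(pts, query$excluded_pts)
  pts <- setdiff(pts, dict$pt_code[dict$disease_flag])
  sort(pts)
}

#' Label reports against a case set
#'
#' Marks each report as a case iff it carries at least one event PT in the
#' resolved case set (case status is report-level: a report with three
#' matching PTs is one case), and records which DSM-5 domains its matching
#' PTs map to. A report may belong to several domain sub-outcomes at once.
#'
#' @param reports A report tibble.
#' @param case_set Character vector of PT codes from [resolve_query()].
#' @param dict The `term_dictionary` supplying the PT-to-domain map.
#' @return `reports` with an added logical `is_case` column and one logical
#'   column per domain (`dom_complex_attention`, ..., `dom_social_cognition`).
#' @export
label_reports <- function(reports, case_set, dict) {
  ev <- event_mentions(reports)
  ev <- ev[ev$pt_code %in% case_set, , drop = FALSE]
  domain_of <- setNames(dict$dsm5_domain, dict$pt_code)
  ev$domain <- unname(domain_of[ev$pt_code])
  if (anyNA(ev$domain)) {
    orphan <- unique(ev$pt_code[is.na(ev$domain)])
    abort(paste0("case-set PT(s) with no DSM-5 domain in the dictionary: ",
                 paste(orphan, collapse = ", ")))
  }
  out <- reports
  out$is_case <- reports$report_id %in% unique(ev$report_id)
  for (d in DSM5_DOMAINS) {
    out[[domain_column(d)]] <-
      reports$report_id %in% unique(ev$report_id[ev$domain == d])
  }
  out
}

#' Export case labels
#'
#' Flattens labelled reports into the exportable label table: one row per
#' report with its case status and a `;`-joined list of affected DSM-5
#' domains.
#'
#' @param labelled Output of [label_reports()].
#' @return A tibble with columns `report_id`, `is_case`, `domains`.
#' @export
case_labels <- function(labelled) {
  cols <- vapply(DSM5_DOMAINS, domain_column, character(1))
  flags <- as.matrix(labelled[cols])
  tibble(
    report_id = labelled$report_id,
    is_case = labelled$is_case,
    domains = apply(flags, 1, \(r) paste(DSM5_DOMAINS[r], collapse = ";"))
  )
}
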