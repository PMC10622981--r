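#' Write reports as JSON Lines
#'
#' Serialises a report tibble to JSONL: one JSON object per line with fields
#' `report_id`, `date` (ISO-8601), `sex`, `age_years` (null when missing),
#' `region`, `reporter`, `serious`, `action_interrupted`,
#' `nci_comorbidity`, `nci_cotreatment`, `drugs` (array of
#' `{"drug_id":..., "role":...}` objects) and `events` (array of PT codes).
#' Output is deterministic: the same tibble always produces the same bytes.
#'
#' @param reports A report tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reports_jsonl <- function(reports, path) {
  esc <- function(x) {
    x <- gsub("\\", "\\\\", x, fixed = TRUE)
    gsub("\"", "\\\"", x, fixed = TRUE)
  }
  jstr <- function(x) paste0("\"", esc(x), "\"")
  jnum <- function(x) if_else(is.na(x), "null", as.character(x))
  jbool <- function(x) if_else(x, "true", "false")
  drugs_json <- purrr::map2_chr(reports$drug_id, reports$drug_role, \(d, r) {
    if (length(d) == 0) return("[]")
    paste0("[", paste0("{\"drug_id\":", jstr(d), ",\"role\":", jstr(r), "}",
                       collapse = ","), "]")
  })
  events_json <- purrr::map_chr(reports$events, \(e) {
    paste0("[", paste0(jstr(e), collapse = ","), "]")
  })
  lines <- paste0(
    "{\"report_id\":", jstr(reports$report_id),
    ",\"date\":", jstr(format(reports$date, "%Y-%m-%d")),
    ",\"sex\":", jstr(reports$sex),
    ",\"age_years\":", jnum(reports$age_years),
    ",\"region\":", jstr(reports$region),
    ",\"reporter\":", jstr(reports$reporter),
    ",\"serious\":", jbool(reports$serious),
    ",\"action_interrupted\":", jbool(reports$action_interrupted),
    ",\"nci_comorbidity\":", jbool(reports$nci_comorbidity),
    ",\"nci_cotreatment\":", jbool(reports$nci_cotreatment),
    ",\"drugs\":", drugs_json,
    ",\"events\":", events_json,
    "}"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read reports from JSON Lines
#'
#' Parses a JSONL report file written by [write_reports_jsonl()] (or any
#' file following the documented schema) back into a report tibble.
#'
#' @param path Input file path.
#' @return A report tibble.
#' @export
read_reports_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE,
                 simplifyDataFrame = TRUE)
  get_chr <- function(f) vapply(objs, \(o) as.character(o[[f]]), character(1))
  get_lgl <- function(f) vapply(objs, \(o) isTRUE(o[[f]]), logical(1))
  age <- vapply(objs, \(o) {
    a <- o[["age_years"]]
    if (is.null(a) || length(a) == 0 || is.na(a)) NA_integer_ else as.integer(a)
  }, integer(1))
  drugs <- lapply(objs, \(o) {
    d <- o[["drugs"]]
    if (is.null(d) || length(d) == 0) {
      list(id = character(0), role = character(0))
    } else if (is.data.frame(d)) {
      list(id = as.character(d$drug_id), role = as.character(d$role))
    } else {
      list(id = vapply(d, \(x) x$drug_id, character(1)),
           role = vapply(d, \(x) x$role, character(1)))
    }
  })
  tibble(
    report_id = get_chr("report_id"),
    date = as.Date(get_chr("date")),
    sex = get_chr("sex"),
    age_years = age,
    region = get_chr("region"),
    reporter = get_chr("reporter"),
    serious = get_lgl("serious"),
    action_interrupted = get_lgl("action_interrupted"),
    drug_id = lapply(drugs, `[[`, "id"),
    drug_role = lapply(drugs, `[[`, "role"),
    events = lapply(objs, \(o) as.character(o[["events"]])),
    nci_comorbidity = get_lgl("nci_comorbidity"),
    nci_cotreatment = get_lgl("nci_cotreatment")
  )
}
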