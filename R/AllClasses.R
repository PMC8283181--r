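# Central data containers.
#
# All quarter tables are stored as all-character data frames in the FAERS
# ASCII convention: "" is the missing token, dates are raw 4/6/8-digit
# tokens.  Parsing happens once, in assembleReports().

QUARTER_TABLES <- c("demo", "drug", "reac", "outc", "ther", "indi")

QUARTER_COLUMNS <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex", "occp_cod", "occr_country", "rept_yr"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt", "pt_cod"),
  outc = c("primaryid", "outc_cod"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' FAERSQuarter: one quarterly set of FAERS-style ASCII tables
#'
#' Holds the six report tables of a FAERS quarterly extract (demographics,
#' drugs, reactions, outcomes, therapy dates, indications) as raw character
#' data frames, exactly as read from or written to "$"-delimited files.
#'
#' @slot demo report-level demographics, one row per primaryid
#' @slot drug drug records with role codes
#' @slot reac reaction records (MedDRA preferred terms)
#' @slot outc outcome codes
#' @slot ther therapy start/end dates per drug sequence
#' @slot indi indications per drug sequence
#' @slot log named list of ingest metrics (orphan rows, bad date tokens)
#' @exportClass FAERSQuarter
setClass("FAERSQuarter",
  representation(demo = "data.frame", drug = "data.frame",
                 reac = "data.frame", outc = "data.frame",
                 ther = "data.frame", indi = "data.frame", log = "list"))

setValidity("FAERSQuarter", function(object) {
  msgs <- character(0)
  for (tab in QUARTER_TABLES) {
    df <- slot(object, tab)
    missing <- setdiff(QUARTER_COLUMNS[[tab]], names(df))
    if (length(missing))
      msgs <- c(msgs, sprintf("%s table lacks column(s): %s",
                              toupper(tab), paste(missing, collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  pid <- object@demo$primaryid
  for (tab in setdiff(QUARTER_TABLES, "demo")) {
    child <- slot(object, tab)$primaryid
    if (length(child) && !all(child %in% pid))
      msgs <- c(msgs, sprintf("%s rows reference primaryids absent from DEMO",
                              toupper(tab)))
  }
  bad_role <- setdiff(setdiff(unique(object@drug$role_cod), ""), ROLE_CODES)
  if (length(bad_role))
    msgs <- c(msgs, paste("unknown drug role code(s):",
                          paste(bad_role, collapse = ", ")))
  bad_outc <- setdiff(setdiff(unique(object@outc$outc_cod), ""), OUTCOME_CODES)
  if (length(bad_outc))
    msgs <- c(msgs, paste("unknown outcome code(s):",
                          paste(bad_outc, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' ReportSet: assembled safety reports
#'
#' Normalised, typed view of a quarter: one row per report in
#' \code{reports}, with child tables for drugs, reactions, outcomes and
#' indications keyed by \code{primary_id}.  Dates carry an explicit
#' precision (\code{"day"}, \code{"month"}, \code{"year"} or \code{NA});
#' day-level computations require day-level precision on both operands.
#'
#' @slot reports one row per safety report (demographics, parsed dates)
#' @slot drugs drug records with canonical ICI generic where recognised
#' @slot reactions lower-cased preferred terms
#' @slot outcomes outcome codes
#' @slot indications indication terms per drug sequence
#' @slot log named list of assembly metrics
#' @exportClass ReportSet
setClass("ReportSet",
  representation(reports = "data.frame", drugs = "data.frame",
                 reactions = "data.frame", outcomes = "data.frame",
                 indications = "data.frame", log = "list"))

REPORT_COLUMNS <- c("primary_id", "case_id", "case_version",
                    "receipt_date", "receipt_prec", "event_date",
                    "event_prec", "age_years", "sex", "region",
                    "reporter", "report_year")

setValidity("ReportSet", function(object) {
  msgs <- character(0)
  missing <- setdiff(REPORT_COLUMNS, names(object@reports))
  if (length(missing))
    msgs <- c(msgs, paste("reports table lacks column(s):",
                          paste(missing, collapse = ", ")))
  age <- object@reports$age_years
  if (length(age) && any(!is.na(age) & age < 0))
    msgs <- c(msgs, "age_years must be >= 0 when present")
  if (length(msgs)) msgs else TRUE
})

#' CaseCohort: the pericardial case set
#'
#' One row per deduplicated case satisfying the case definition (at least
#' one pericardial preferred term and at least one suspect ICI), carrying
#' regimen, fatality status, time to onset and its bin, and the grouped
#' indication.  \code{provenance} records the in/out counts of every
#' filtering step.
#'
#' @slot records one row per case
#' @slot provenance named list; \code{$steps} is a data frame of filter
#'   counts, monotone non-increasing
#' @exportClass CaseCohort
setClass("CaseCohort",
  representation(records = "data.frame", provenance = "list"))

CASE_COLUMNS <- c("case_id", "primary_id", "report_year", "sex",
                  "age_years", "age_group", "region", "reporter",
                  "indication_group", "regimen", "strategy", "therapy",
                  "fatal", "outcome_status", "outcome_display",
                  "tto_days", "tto_bin")

setValidity("CaseCohort", function(object) {
  msgs <- character(0)
  missing <- setdiff(CASE_COLUMNS, names(object@records))
  if (length(missing))
    msgs <- c(msgs, paste("records lack column(s):",
                          paste(missing, collapse = ", ")))
  if (length(msgs)) return(msgs)
  rec <- object@records
  if (nrow(rec)) {
    if (!is.logical(rec$fatal)) msgs <- c(msgs, "fatal must be logical")
    bad_bin <- !is.na(rec$tto_days) &
      (is.na(rec$tto_bin) | rec$tto_bin != binTto(rec$tto_days))
    if (any(bad_bin))
      msgs <- c(msgs, "tto_bin inconsistent with tto_days")
  }
  if (length(msgs)) msgs else TRUE
})

#' ContingencyTable: the 2x2 counts behind one drug-event comparison
#'
#' @slot a reports with the drug and the event
#' @slot b reports with the drug, without the event
#' @slot c reports with the event, without the drug (comparator frame)
#' @slot d reports with neither
#' @exportClass ContingencyTable
setClass("ContingencyTable",
  representation(a = "numeric", b = "numeric", c = "numeric", d = "numeric"))

setValidity("ContingencyTable", function(object) {
  cells <- c(object@a, object@b, object@c, object@d)
  if (length(cells) != 4 || anyNA(cells))
    return("all four cells must be single non-missing numbers")
  if (any(cells < 0)) return("cells must be non-negative")
  if (any(cells != round(cells))) return("cells must be whole counts")
  TRUE
})

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d non-negative integer report counts: drug+event,
#'   drug-only, event-only, neither
#' @return a \linkS4class{ContingencyTable}
#' @examples
#' contingencyTable(10, 90, 100, 9000)
#' @export
contingencyTable <- function(a, b, c, d) {
  new("ContingencyTable", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), d = as.numeric(d))
}

#' @describeIn contingencyTable the four cells as a named vector
#' @param x a \code{ContingencyTable}
#' @export
ctCells <- function(x) {
  stopifnot(is(x, "ContingencyTable"))
  c(a = x@a, b = x@b, c = x@c, d = x@d)
}
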