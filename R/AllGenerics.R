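#' Number of reports or cases in a container
#'
#' @param x a \linkS4class{FAERSQuarter}, \linkS4class{ReportSet} or
#'   \linkS4class{CaseCohort}
#' @return integer count
#' @export
setGeneric("nReports", function(x) standardGeneric("nReports"))

#' Report-level table of a ReportSet
#' @param x a \linkS4class{ReportSet}
#' @return data frame, one row per report
#' @export
setGeneric("reports", function(x) standardGeneric("reports"))

#' Case records of a CaseCohort
#' @param x a \linkS4class{CaseCohort}
#' @return data frame, one row per case
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Provenance metadata (filter-step counts, source, seed)
#' @param x a \linkS4class{CaseCohort}
#' @return named list
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' One of the six raw quarter tables
#' @param x a \linkS4class{FAERSQuarter}
#' @param name one of "demo", "drug", "reac", "outc", "ther", "indi"
#' @return character data frame
#' @export
setGeneric("quarterTable", function(x, name) standardGeneric("quarterTable"))

#' @rdname nReports
#' @export
setMethod("nReports", "FAERSQuarter", function(x) nrow(x@demo))

#' @rdname nReports
#' @export
setMethod("nReports", "ReportSet", function(x) nrow(x@reports))

#' @rdname nReports
#' @export
setMethod("nReports", "CaseCohort", function(x) nrow(x@records))

#' @rdname reports
#' @export
setMethod("reports", "ReportSet", function(x) x@reports)

#' @rdname records
#' @export
setMethod("records", "CaseCohort", function(x) x@records)

#' @rdname provenance
#' @export
setMethod("provenance", "CaseCohort", function(x) x@provenance)

#' @rdname quarterTable
#' @export
setMethod("quarterTable", "FAERSQuarter", function(x, name) {
  name <- match.arg(name, QUARTER_TABLES)
  slot(x, name)
})

setMethod("show", "FAERSQuarter", function(object) {
  cat("FAERSQuarter:", nrow(object@demo), "reports\n")
  for (tab in setdiff(QUARTER_TABLES, "demo"))
    cat(sprintf("  %s: %d rows\n", toupper(tab), nrow(slot(object, tab))))
  if (length(object@log))
    cat("  ingest log:",
        paste(names(object@log), unlist(object@log),
              sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ReportSet", function(object) {
  cat("ReportSet:", nrow(object@reports), "assembled reports\n")
  cat(sprintf("  drugs: %d | reactions: %d | outcomes: %d | indications: %d\n",
              nrow(object@drugs), nrow(object@reactions),
              nrow(object@outcomes), nrow(object@indications)))
})

setMethod("show", "CaseCohort", function(object) {
  rec <- object@records
  cat("CaseCohort:", nrow(rec), "cases\n")
  if (nrow(rec)) {
    cat(sprintf("  fatal: %d | non-fatal: %d | unknown outcome: %d\n",
                sum(rec$outcome_status == "fatal"),
                sum(rec$outcome_status == "non-fatal"),
                sum(rec$outcome_status == "unknown")))
    cat(sprintf("  with time to onset: %d\n", sum(!is.na(rec$tto_days))))
  }
})

setMethod("show", "ContingencyTable", function(object) {
  m <- matrix(c(object@a, object@c, object@b, object@d), 2, 2,
              dimnames = list(c("drug", "no drug"),
                              c("event", "no event")))
  cat("ContingencyTable (reports)\n")
  print(m)
})
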