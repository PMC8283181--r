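# Reading/writing FAERS-style "$"-delimited quarterly ASCII files and
# assembling them into typed safety reports.

quarterFileName <- function(tab) paste0(toupper(tab), ".txt")

#' Read a FAERS-style quarter from "$"-delimited ASCII files
#'
#' Expects a directory containing DEMO.txt, DRUG.txt, REAC.txt, OUTC.txt,
#' THER.txt and INDI.txt, each "$"-delimited with one header line (column
#' names matched case-insensitively).  Child rows whose primaryid does
#' not appear in DEMO are dropped and counted in the ingest log; date
#' tokens that fail to parse are counted and warned about but never
#' abort the read.
#'
#' @param path directory holding the six files
#' @return a \linkS4class{FAERSQuarter}
#' @seealso [writeQuarter()], [assembleReports()]
#' @export
readQuarter <- function(path) {
  if (!dir.exists(path)) inputError(paste("no such directory:", path))
  tabs <- list()
  log <- list(orphan_rows = 0L, unparseable_dates = 0L)
  for (tab in QUARTER_TABLES) {
    f <- file.path(path, quarterFileName(tab))
    if (!file.exists(f))
      inputError(paste("missing mandatory file:", quarterFileName(tab)))
    df <- utils::read.table(f, sep = "$", header = TRUE,
                            colClasses = "character", quote = "",
                            comment.char = "", check.names = FALSE,
                            blank.lines.skip = FALSE)
    names(df) <- tolower(names(df))
    unknown <- setdiff(names(df), QUARTER_COLUMNS[[tab]])
    if (length(unknown)) {
      warning(sprintf("%s: ignoring unknown column(s): %s",
                      quarterFileName(tab), paste(unknown, collapse = ", ")))
      df <- df[, setdiff(names(df), unknown), drop = FALSE]
    }
    for (col in setdiff(QUARTER_COLUMNS[[tab]], names(df)))
      df[[col]] <- character(nrow(df))
    df <- df[, QUARTER_COLUMNS[[tab]], drop = FALSE]
    tabs[[tab]] <- df
  }
  pid <- tabs$demo$primaryid
  for (tab in setdiff(QUARTER_TABLES, "demo")) {
    orphan <- !(tabs[[tab]]$primaryid %in% pid)
    if (any(orphan)) {
      log$orphan_rows <- log$orphan_rows + sum(orphan)
      tabs[[tab]] <- tabs[[tab]][!orphan, , drop = FALSE]
      rownames(tabs[[tab]]) <- NULL
    }
  }
  date_cols <- list(demo = c("fda_dt", "event_dt"),
                    ther = c("start_dt", "end_dt"))
  for (tab in names(date_cols)) for (col in date_cols[[tab]]) {
    parsed <- parseFaersDate(tabs[[tab]][[col]])
    log$unparseable_dates <- log$unparseable_dates +
      attr(parsed, "n_unparseable")
  }
  if (log$unparseable_dates > 0)
    warning(sprintf("%d date token(s) could not be parsed and become missing",
                    log$unparseable_dates))
  new("FAERSQuarter", demo = tabs$demo, drug = tabs$drug, reac = tabs$reac,
      outc = tabs$outc, ther = tabs$ther, indi = tabs$indi, log = log)
}

#' Write a FAERS-style quarter as "$"-delimited ASCII files
#'
#' Writes the six tables with one header line each, no quoting, so that
#' \code{readQuarter(writeQuarter(q))} reproduces \code{q}
#' field-for-field.  Output is byte-deterministic.
#'
#' @param quarter a \linkS4class{FAERSQuarter}
#' @param path output directory (created if needed)
#' @return \code{path}, invisibly
#' @export
writeQuarter <- function(quarter, path) {
  stopifnot(is(quarter, "FAERSQuarter"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) inputError(paste("cannot create directory:", path))
  for (tab in QUARTER_TABLES) {
    f <- file.path(path, quarterFileName(tab))
    df <- slot(quarter, tab)
    status <- try(utils::write.table(df, f, sep = "$", quote = FALSE,
                                     row.names = FALSE, na = "",
                                     eol = "\n", fileEncoding = "UTF-8"),
                  silent = TRUE)
    if (inherits(status, "try-error"))
      inputError(paste("cannot write file:", f))
  }
  invisible(path)
}

# earliest therapy start per (primaryid, drug_seq); day-precision starts
# take precedence over coarser ones so day-level TTO is never computed
# from a month- or year-anchored date
earliestTherapyStart <- function(ther) {
  if (!nrow(ther)) {
    return(data.frame(key = character(0), start_date = as.Date(character(0)),
                      start_prec = character(0), stringsAsFactors = FALSE))
  }
  parsed <- parseFaersDate(ther$start_dt)
  key <- paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r")
  prec_rank <- match(parsed$precision, c("day", "month", "year"))
  ord <- order(key, prec_rank, parsed$date, na.last = TRUE)
  first <- !duplicated(key[ord])
  idx <- ord[first]
  data.frame(key = key[idx], start_date = parsed$date[idx],
             start_prec = parsed$precision[idx], stringsAsFactors = FALSE)
}

#' Assemble a raw quarter into typed safety reports
#'
#' Joins the child tables onto the demographics by primaryid, parses all
#' dates with explicit precision, converts ages to years, maps occurrence
#' countries to reporting regions and reporter qualification codes to
#' reporter classes, lower-cases reaction terms, recognises ICI drug
#' names, and attaches the earliest therapy start date to each drug
#' record.  Degraded fields become missing; no report is dropped.
#'
#' @param quarter a \linkS4class{FAERSQuarter}
#' @return a \linkS4class{ReportSet}
#' @export
assembleReports <- function(quarter) {
  stopifnot(is(quarter, "FAERSQuarter"))
  demo <- quarter@demo
  receipt <- parseFaersDate(demo$fda_dt)
  event <- parseFaersDate(demo$event_dt)
  age <- ageToYears(demo$age, demo$age_cod)
  if (attr(age, "n_implausible") > 0)
    warning(sprintf("%d implausible age value(s) (>120y or negative) set missing",
                    attr(age, "n_implausible")))
  sex <- ifelse(toupper(demo$sex) == "F", "female",
         ifelse(toupper(demo$sex) == "M", "male", NA_character_))
  reporter_map <- c(MD = "health-professional", PH = "health-professional",
                    RN = "health-professional", HP = "health-professional",
                    OT = "health-professional",
                    CN = "non-health-professional",
                    LW = "non-health-professional")
  reporter <- unname(reporter_map[toupper(demo$occp_cod)])
  year <- suppressWarnings(as.integer(demo$rept_yr))
  year[!grepl("^[0-9]{4}$", demo$rept_yr)] <- NA_integer_
  fallback <- is.na(year) & !is.na(receipt$date)
  year[fallback] <- as.integer(format(receipt$date[fallback], "%Y"))

  rep_df <- data.frame(
    primary_id = demo$primaryid,
    case_id = demo$caseid,
    case_version = suppressWarnings(as.numeric(demo$caseversion)),
    receipt_date = receipt$date, receipt_prec = receipt$precision,
    event_date = event$date, event_prec = event$precision,
    age_years = as.numeric(age),
    sex = sex,
    region = countryToRegion(demo$occr_country),
    reporter = reporter,
    report_year = year,
    stringsAsFactors = FALSE)

  drug <- quarter@drug
  ici <- normalizeDrugName(drug$drugname)
  miss <- is.na(ici) & nzchar(drug$prod_ai)
  if (any(miss)) ici[miss] <- normalizeDrugName(drug$prod_ai[miss])
  starts <- earliestTherapyStart(quarter@ther)
  key <- paste(drug$primaryid, drug$drug_seq, sep = "\r")
  hit <- match(key, starts$key)
  drug_df <- data.frame(
    primary_id = drug$primaryid,
    drug_seq = drug$drug_seq,
    role = toupper(drug$role_cod),
    drug_raw = drug$drugname,
    ici = ici,
    start_date = starts$start_date[hit],
    start_prec = starts$start_prec[hit],
    stringsAsFactors = FALSE)

  reac <- quarter@reac
  pt <- tolower(gsub("\\s+", " ", trimws(reac$pt)))
  keep <- nzchar(pt)
  reac_df <- data.frame(primary_id = reac$primaryid[keep], pt = pt[keep],
                        stringsAsFactors = FALSE)

  outc_df <- data.frame(primary_id = quarter@outc$primaryid,
                        code = toupper(quarter@outc$outc_cod),
                        stringsAsFactors = FALSE)
  outc_df <- outc_df[nzchar(outc_df$code), , drop = FALSE]

  indi_df <- data.frame(primary_id = quarter@indi$primaryid,
                        drug_seq = quarter@indi$indi_drug_seq,
                        term = tolower(trimws(quarter@indi$indi_pt)),
                        stringsAsFactors = FALSE)
  indi_df <- indi_df[nzchar(indi_df$term), , drop = FALSE]

  log <- quarter@log
  log$reports_in <- nrow(demo)
  log$reports_out <- nrow(rep_df)
  new("ReportSet", reports = rep_df, drugs = drug_df, reactions = reac_df,
      outcomes = outc_df, indications = indi_df, log = log)
}
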