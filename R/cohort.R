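# Deduplication, regimen classification, time to onset and the
# pericardial case cohort.

#' Deduplicate safety reports by case id
#'
#' Spontaneous-report cases are revised over time, so one case id may
#' carry several versions.  Keeps exactly one report per case id: the
#' highest case version, ties broken by latest receipt date, then
#' highest primaryid.  The number of dropped versions is logged.
#'
#' @param rs a \linkS4class{ReportSet}
#' @return a \linkS4class{ReportSet} with one report per case id
#' @export
deduplicateReports <- function(rs) {
  stopifnot(is(rs, "ReportSet"))
  r <- rs@reports
  if (!nrow(r)) return(rs)
  pid_num <- suppressWarnings(as.numeric(r$primary_id))
  pid_rank <- if (anyNA(pid_num)) xtfrm(r$primary_id) else pid_num
  ord <- order(r$case_id, -xtfrm(r$case_version),
               -xtfrm(r$receipt_date), -pid_rank, na.last = TRUE)
  keep <- ord[!duplicated(r$case_id[ord])]
  kept <- r[sort(keep), , drop = FALSE]
  rownames(kept) <- NULL
  out <- rs
  out@reports <- kept
  pids <- kept$primary_id
  for (s in c("drugs", "reactions", "outcomes", "indications")) {
    df <- slot(out, s)
    df <- df[df$primary_id %in% pids, , drop = FALSE]
    rownames(df) <- NULL
    slot(out, s) <- df
  }
  out@log$dedup_dropped <- nrow(r) - nrow(kept)
  out
}

REGIMEN_COMBOS <- c("ipilimumab+nivolumab" = "ipilimumab+nivolumab",
                    "ipilimumab+pembrolizumab" = "ipilimumab+pembrolizumab",
                    "durvalumab+tremelimumab" = "tremelimumab+durvalumab")

MONO_STRATEGY <- c(nivolumab = "anti-PD-1 mono",
                   pembrolizumab = "anti-PD-1 mono",
                   cemiplimab = "anti-PD-1 mono",
                   atezolizumab = "anti-PD-L1 mono",
                   avelumab = "anti-PD-L1 mono",
                   durvalumab = "anti-PD-L1 mono",
                   ipilimumab = "anti-CTLA-4 mono",
                   tremelimumab = "anti-CTLA-4 mono")

regimenFromSuspectKey <- function(key) {
  # key: "+"-joined sorted generics, "" when no suspect ICI
  label <- rep(NA_character_, length(key))
  single <- key %in% names(MONO_STRATEGY)
  label[single] <- key[single]
  combo <- key %in% names(REGIMEN_COMBOS)
  label[combo] <- REGIMEN_COMBOS[key[combo]]
  multi <- !single & !combo & grepl("+", key, fixed = TRUE)
  label[multi] <- "other-multi-ICI"
  label
}

regimenStrategy <- function(label) {
  out <- unname(MONO_STRATEGY[label])
  out[label %in% REGIMEN_COMBOS] <- "combination"
  out[!is.na(label) & label == "other-multi-ICI"] <- "other"
  out
}

#' Classify the ICI regimen of one report
#'
#' A report's regimen is defined by the set of distinct ICI generics
#' among its suspect drugs (role PS or SS); concomitant or interacting
#' ICIs never contribute.  Exactly one suspect ICI gives that
#' monotherapy; the pairs ipilimumab+nivolumab, ipilimumab+pembrolizumab
#' and tremelimumab+durvalumab give the named combinations; any other
#' multi-ICI suspect set is "other-multi-ICI".
#'
#' @param suspects character vector of canonical ICI generics with
#'   suspect roles in one report
#' @return list with \code{label} and \code{strategy}
#' @examples
#' classifyRegimen(c("ipilimumab", "nivolumab"))
#' @export
classifyRegimen <- function(suspects) {
  suspects <- unique(suspects[!is.na(suspects)])
  if (!length(suspects))
    stop("report has no suspect ICI; regimen is undefined")
  key <- paste(sort(suspects), collapse = "+")
  label <- regimenFromSuspectKey(key)
  list(label = label, strategy = regimenStrategy(label))
}

# vectorised regimen classification: one row per report in rs
classifyRegimens <- function(rs) {
  r <- rs@reports
  d <- rs@drugs
  susp <- d[d$role %in% c("PS", "SS") & !is.na(d$ici),
            c("primary_id", "ici")]
  key <- rep(NA_character_, nrow(r))
  if (nrow(susp)) {
    sets <- vapply(split(susp$ici, susp$primary_id),
                   function(g) paste(sort(unique(g)), collapse = "+"),
                   character(1))
    key[match(names(sets), r$primary_id)] <- sets
  }
  label <- rep(NA_character_, nrow(r))
  has <- !is.na(key)
  label[has] <- regimenFromSuspectKey(key[has])
  data.frame(primary_id = r$primary_id, regimen = label,
             strategy = regimenStrategy(label), stringsAsFactors = FALSE)
}

#' Compute time to onset per report
#'
#' Time to onset is the whole-day interval from the earliest
#' day-precision therapy start date among suspect ICI drugs to the event
#' date.  It is missing when either operand is missing or coarser than
#' day precision; negative intervals are incorrect records and become
#' missing, counted in the \code{n_negative} attribute.
#'
#' @param rs a \linkS4class{ReportSet}
#' @return data frame with \code{primary_id} and \code{tto_days};
#'   attribute \code{n_negative} counts excluded incorrect records
#' @export
computeTto <- function(rs) {
  stopifnot(is(rs, "ReportSet"))
  r <- rs@reports
  d <- rs@drugs
  ok <- d$role %in% c("PS", "SS") & !is.na(d$ici) &
    !is.na(d$start_prec) & d$start_prec == "day"
  tto <- rep(NA_integer_, nrow(r))
  n_neg <- 0L
  if (any(ok)) {
    starts <- d[ok, c("primary_id", "start_date")]
    agg <- tapply(starts$start_date, starts$primary_id, min)
    start <- as.Date(agg[r$primary_id], origin = "1970-01-01")
    event_ok <- !is.na(r$event_prec) & r$event_prec == "day"
    val <- as.integer(r$event_date - start)
    val[!event_ok] <- NA_integer_
    neg <- !is.na(val) & val < 0
    n_neg <- sum(neg)
    val[neg] <- NA_integer_
    tto <- val
  }
  out <- data.frame(primary_id = r$primary_id, tto_days = tto,
                    stringsAsFactors = FALSE)
  attr(out, "n_negative") <- n_neg
  out
}

OUTCOME_DISPLAY <- c(DE = "death", LT = "life-threatening",
                     DS = "disability", HO = "hospitalization",
                     CA = "other serious", RI = "other serious",
                     OT = "other serious")
# mutually exclusive display precedence
OUTCOME_PRECEDENCE <- c("DE", "LT", "DS", "HO", "CA", "RI", "OT")

newCaseCohort <- function(records, provenance = list()) {
  new("CaseCohort", records = records, provenance = provenance)
}

emptyCaseRecords <- function() {
  data.frame(case_id = character(0), primary_id = character(0),
             report_year = integer(0), sex = character(0),
             age_years = numeric(0), age_group = character(0),
             region = character(0), reporter = character(0),
             indication_group = character(0), regimen = character(0),
             strategy = character(0), therapy = character(0),
             fatal = logical(0), outcome_status = character(0),
             outcome_display = character(0), tto_days = integer(0),
             tto_bin = character(0), stringsAsFactors = FALSE)
}

#' Build the pericardial case cohort
#'
#' Applies the case definition to deduplicated reports: a case must carry
#' at least one pericardial preferred term among its reactions and at
#' least one ICI among its suspect drugs.  Each case is annotated with
#' regimen and strategy, fatality status (outcome set contains DE), time
#' to onset and its bin, and the grouped indication.  Every filter step's
#' in/out counts are recorded in the provenance.
#'
#' @param rs a deduplicated \linkS4class{ReportSet}
#' @return a \linkS4class{CaseCohort} (possibly empty)
#' @export
buildCohort <- function(rs) {
  stopifnot(is(rs, "ReportSet"))
  r <- rs@reports
  steps <- data.frame(step = "reports in", n = nrow(r),
                      stringsAsFactors = FALSE)

  event_ids <- unique(rs@reactions$primary_id[isPericardialPT(rs@reactions$pt)])
  keep1 <- r$primary_id %in% event_ids
  steps <- rbind(steps, data.frame(step = "with pericardial PT",
                                   n = sum(keep1)))

  cls <- classifyRegimens(rs)
  keep2 <- keep1 & !is.na(cls$regimen)
  steps <- rbind(steps, data.frame(step = "with suspect ICI",
                                   n = sum(keep2)))

  if (!any(keep2)) {
    return(newCaseCohort(emptyCaseRecords(),
                         list(steps = steps, log = rs@log)))
  }

  idx <- which(keep2)
  pids <- r$primary_id[idx]

  tto <- computeTto(rs)
  tto_days <- tto$tto_days[match(pids, tto$primary_id)]

  oc <- rs@outcomes[rs@outcomes$primary_id %in% pids, , drop = FALSE]
  fatal_ids <- unique(oc$primary_id[oc$code == "DE"])
  any_out_ids <- unique(oc$primary_id)
  fatal <- pids %in% fatal_ids
  status <- ifelse(fatal, "fatal",
                   ifelse(pids %in% any_out_ids, "non-fatal", "unknown"))
  disp <- rep(NA_character_, length(pids))
  if (nrow(oc)) {
    rank <- match(oc$code, OUTCOME_PRECEDENCE)
    ord <- order(oc$primary_id, rank)
    top <- oc[ord, ][!duplicated(oc$primary_id[ord]), ]
    hit <- match(pids, top$primary_id)
    disp <- unname(OUTCOME_DISPLAY[top$code[hit]])
  }

  ind <- rs@indications[rs@indications$primary_id %in% pids, , drop = FALSE]
  ind_group <- rep("unknown or missing", length(pids))
  if (nrow(ind)) {
    g <- mapIndication(ind$term)
    agg <- vapply(split(g, ind$primary_id), reportIndicationGroup,
                  character(1))
    hit <- match(pids, names(agg))
    ind_group[!is.na(hit)] <- unname(agg[hit[!is.na(hit)]])
  }

  regimen <- cls$regimen[idx]
  strategy <- cls$strategy[idx]
  therapy <- ifelse(strategy == "combination", "combination",
             ifelse(strategy == "other", "other", "monotherapy"))

  rec <- data.frame(
    case_id = r$case_id[idx],
    primary_id = pids,
    report_year = r$report_year[idx],
    sex = r$sex[idx],
    age_years = r$age_years[idx],
    age_group = ageGroup(r$age_years[idx]),
    region = r$region[idx],
    reporter = r$reporter[idx],
    indication_group = ind_group,
    regimen = regimen,
    strategy = strategy,
    therapy = therapy,
    fatal = fatal,
    outcome_status = status,
    outcome_display = disp,
    tto_days = tto_days,
    tto_bin = binTto(tto_days),
    stringsAsFactors = FALSE)
  rownames(rec) <- NULL

  prov <- list(steps = steps, log = rs@log,
               n_negative_tto = attr(tto, "n_negative"))
  newCaseCohort(rec, prov)
}

#' Export a case cohort as CSV
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeCohortCsv <- function(cohort, path) {
  stopifnot(is(cohort, "CaseCohort"))
  utils::write.csv(cohort@records, path, row.names = FALSE, na = "")
  invisible(path)
}
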