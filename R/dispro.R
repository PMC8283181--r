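# Disproportionality statistics: reporting odds ratio with Woolf
# confidence interval, the Bayesian information component with its
# credibility lower bound, the signal criteria, and the comparison
# designs that replicate the per-regimen signal table.

Z_95 <- 1.959964

#' Reporting odds ratio with 95\% confidence interval
#'
#' ROR = (a*d)/(b*c) from the 2x2 report-count table, with the log-scale
#' normal (Woolf) interval exp(ln ROR +/- z*sqrt(1/a+1/b+1/c+1/d)).
#' When any cell is zero the Haldane-Anscombe continuity correction adds
#' 0.5 to every cell (estimate and interval), and the result is flagged
#' as corrected.
#'
#' @param tab a \linkS4class{ContingencyTable}
#' @param z normal quantile for the interval (default 1.959964, 95\%)
#' @return one-row data frame: \code{ror}, \code{ror025}, \code{ror975},
#'   \code{corrected}
#' @examples
#' computeRor(contingencyTable(10, 90, 100, 9000))
#' @export
computeRor <- function(tab, z = Z_95) {
  stopifnot(is(tab, "ContingencyTable"))
  cells <- ctCells(tab)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  a <- cells[["a"]]; b <- cells[["b"]]
  cc <- cells[["c"]]; d <- cells[["d"]]
  ror <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  data.frame(ror = ror,
             ror025 = exp(log(ror) - z * se),
             ror975 = exp(log(ror) + z * se),
             corrected = corrected)
}

#' Expected report count under independence
#'
#' N_expected = N_drug * N_event / N_total, the count expected for the
#' drug-event combination if drug and event reporting were independent.
#'
#' @param nDrug reports mentioning the drug
#' @param nEvent reports mentioning the event
#' @param nTotal reports in the comparison frame
#' @return numeric expected count
#' @examples
#' expectedCount(1000, 200, 100000)
#' @export
expectedCount <- function(nDrug, nEvent, nTotal) {
  if (any(nTotal <= 0)) configError("nTotal must be positive")
  if (any(nDrug > nTotal) || any(nEvent > nTotal))
    configError("margins cannot exceed nTotal")
  nDrug * nEvent / nTotal
}

#' Credibility lower bound of the information component
#'
#' Analytic approximation to the 2.5\% posterior quantile:
#' IC025 = IC - 3.3*(n+0.5)^(-1/2) - 2*(n+0.5)^(-3/2), with n the
#' observed count.  Isolated here so a posterior-simulation alternative
#' can be swapped in.
#'
#' @param nObserved observed report count
#' @param ic the information component point estimate
#' @return numeric lower bound
#' @export
icLowerBound <- function(nObserved, ic) {
  ic - 3.3 * (nObserved + 0.5)^(-0.5) - 2 * (nObserved + 0.5)^(-1.5)
}

#' Information component with credibility lower bound
#'
#' IC = log2((N_observed + 0.5)/(N_expected + 0.5)), the shrunken log2
#' observed/expected ratio of the BCPNN family; the built-in +0.5 makes
#' zero counts well defined without further correction.
#'
#' @param nObserved observed report counts (vectorised)
#' @param nExpected expected counts under independence
#' @return data frame with \code{ic} and \code{ic025}
#' @examples
#' computeIc(15, 7.25)   # ratio 15.5/7.75 = 2, so IC = 1
#' @export
computeIc <- function(nObserved, nExpected) {
  stopifnot(all(nObserved >= 0), all(nExpected >= 0))
  ic <- log2((nObserved + 0.5) / (nExpected + 0.5))
  data.frame(ic = ic, ic025 = icLowerBound(nObserved, ic))
}

#' Apply the signal criteria
#'
#' A ROR signal requires the lower 95\% bound above 1 with at least
#' \code{nMin} observed cases; an IC signal requires IC025 above zero.
#'
#' @param stats data frame with columns \code{n_observed}, \code{ror025}
#'   and (optionally) \code{ic025}
#' @param nMin minimum case count for the ROR criterion (default 3)
#' @return \code{stats} with logical columns \code{signal_ror} and
#'   \code{signal_ic} set (NA where the underlying statistic is absent)
#' @examples
#' classifySignal(data.frame(n_observed = 705, ror025 = 4.51, ic025 = 2.11))
#' @export
classifySignal <- function(stats, nMin = 3) {
  stopifnot(is.data.frame(stats),
            all(c("n_observed", "ror025") %in% names(stats)))
  if (!"ic025" %in% names(stats)) stats$ic025 <- NA_real_
  stats$signal_ror <- stats$ror025 > 1 & stats$n_observed >= nMin
  stats$signal_ic <- ifelse(is.na(stats$ic025), NA, stats$ic025 > 0)
  stats
}

#' Full signal statistics for one contingency table
#'
#' @param tab a \linkS4class{ContingencyTable}
#' @param ic compute the information component (full-database designs
#'   only; subgroup comparisons carry ROR alone)
#' @param nMin minimum case count for the ROR signal criterion
#' @return one-row data frame with observed/expected counts, ROR and IC
#'   statistics and signal flags
#' @export
signalStats <- function(tab, ic = TRUE, nMin = 3) {
  cells <- ctCells(tab)
  a <- cells[["a"]]
  n_total <- sum(cells)
  out <- data.frame(n_observed = a, n_expected = NA_real_,
                    ror = NA_real_, ror025 = NA_real_, ror975 = NA_real_,
                    ic = NA_real_, ic025 = NA_real_, corrected = FALSE)
  if (a == 0 || n_total == 0) {
    out$signal_ror <- NA
    out$signal_ic <- NA
    return(out)
  }
  r <- computeRor(tab)
  out$ror <- r$ror; out$ror025 <- r$ror025; out$ror975 <- r$ror975
  out$corrected <- r$corrected
  if (ic) {
    out$n_expected <- expectedCount(cells[["a"]] + cells[["b"]],
                                    cells[["a"]] + cells[["c"]], n_total)
    icv <- computeIc(a, out$n_expected)
    out$ic <- icv$ic; out$ic025 <- icv$ic025
  }
  classifySignal(out, nMin = nMin)
}

#' Define a drug/comparator comparison design
#'
#' A design selects target reports (by suspect-ICI status, monotherapy
#' drug, strategy or regimen label), a comparator (the full-database
#' remainder, or a named disjoint selector restricted to a two-group
#' frame), and the event set (default: the pericardial preferred terms).
#' IC is computed only against the full database; subgroup comparisons
#' carry ROR alone.
#'
#' @param name row label
#' @param targetType one of "ici" (any suspect ICI), "drug" (monotherapy
#'   regimen equal to a generic), "strategy", "regimen"
#' @param targetValue value(s) for the selector (unused for "ici")
#' @param comparatorType "database" or one of the selector types
#' @param comparatorValue value(s) for a named comparator
#' @param events character vector of preferred terms (lower case), or
#'   NULL for the pericardial case definition
#' @param nMin minimum-case rule for the ROR signal
#' @param type design category used in output tables ("total", "class",
#'   "drug", "combination", "comparison")
#' @return a \code{ComparisonDesign} (S3 list)
#' @export
comparisonDesign <- function(name, targetType, targetValue = NULL,
                             comparatorType = "database",
                             comparatorValue = NULL, events = NULL,
                             nMin = 3, type = "drug") {
  targetType <- match.arg(targetType, c("ici", "drug", "strategy", "regimen"))
  comparatorType <- match.arg(comparatorType,
                              c("database", "ici", "drug", "strategy",
                                "regimen"))
  if (comparatorType != "database" && is.null(comparatorValue))
    configError("named comparator requires comparatorValue")
  if (identical(targetType, comparatorType) &&
      length(intersect(targetValue, comparatorValue)))
    configError("target and comparator selectors must be disjoint")
  structure(list(name = name, targetType = targetType,
                 targetValue = targetValue,
                 comparatorType = comparatorType,
                 comparatorValue = comparatorValue,
                 events = events, nMin = nMin, type = type),
            class = "ComparisonDesign")
}

selectorFlag <- function(cls, type, value) {
  switch(type,
         ici = !is.na(cls$regimen),
         drug = !is.na(cls$regimen) & cls$regimen %in% value,
         regimen = !is.na(cls$regimen) & cls$regimen %in% value,
         strategy = !is.na(cls$strategy) & cls$strategy %in% value,
         stop("unknown selector type: ", type))
}

#' Build the 2x2 contingency table for a comparison design
#'
#' Each deduplicated report is classified once into exactly one cell.
#' With the full-database comparator, b/c/d are drawn from all non-target
#' reports; with a named comparator the frame is restricted to target and
#' comparator reports and all others are excluded.
#'
#' @param rs a deduplicated \linkS4class{ReportSet}
#' @param design a \code{ComparisonDesign}
#' @param .cls optional precomputed \code{classifyRegimens(rs)} result,
#'   reused across designs
#' @return a \linkS4class{ContingencyTable}
#' @export
buildContingency <- function(rs, design, .cls = NULL) {
  stopifnot(is(rs, "ReportSet"), inherits(design, "ComparisonDesign"))
  cls <- if (is.null(.cls)) classifyRegimens(rs) else .cls
  if (is.null(design$events)) {
    hit <- isPericardialPT(rs@reactions$pt)
  } else {
    hit <- rs@reactions$pt %in% tolower(design$events)
  }
  event_ids <- unique(rs@reactions$primary_id[hit])
  event <- cls$primary_id %in% event_ids
  tflag <- selectorFlag(cls, design$targetType, design$targetValue)
  if (design$comparatorType == "database") {
    cflag <- !tflag
  } else {
    cflag <- selectorFlag(cls, design$comparatorType, design$comparatorValue)
    cflag <- cflag & !tflag
  }
  contingencyTable(sum(tflag & event), sum(tflag & !event),
                   sum(cflag & event), sum(cflag & !event))
}

MONO_STRATEGIES <- c("anti-PD-1 mono", "anti-PD-L1 mono", "anti-CTLA-4 mono")

#' The default per-regimen design set
#'
#' Replicates the per-regimen signal-table layout: one full-database row
#' for all ICIs, one per target class, one per monotherapy drug and one
#' per named combination (ROR and IC), plus the four subgroup comparisons
#' (anti-PD-1 vs anti-CTLA-4, anti-PD-L1 vs anti-CTLA-4, anti-PD-1 vs
#' anti-PD-L1, combination vs monotherapy; ROR only).
#'
#' @param nMin minimum-case rule applied to every design
#' @return named list of \code{ComparisonDesign} objects
#' @export
defaultDesignSet <- function(nMin = 3) {
  d <- list()
  d[["Total ICIs"]] <- comparisonDesign("Total ICIs", "ici", type = "total")
  for (s in MONO_STRATEGIES) {
    nm <- sub(" mono", "", s)
    d[[nm]] <- comparisonDesign(nm, "strategy", s, type = "class")
  }
  for (g in iciDictionary()$generic)
    d[[g]] <- comparisonDesign(g, "drug", g, type = "drug")
  for (combo in unique(unname(REGIMEN_COMBOS)))
    d[[combo]] <- comparisonDesign(combo, "regimen", combo,
                                   type = "combination")
  d[["anti-PD-1 vs anti-CTLA-4"]] <- comparisonDesign(
    "anti-PD-1 vs anti-CTLA-4", "strategy", "anti-PD-1 mono",
    "strategy", "anti-CTLA-4 mono", type = "comparison")
  d[["anti-PD-L1 vs anti-CTLA-4"]] <- comparisonDesign(
    "anti-PD-L1 vs anti-CTLA-4", "strategy", "anti-PD-L1 mono",
    "strategy", "anti-CTLA-4 mono", type = "comparison")
  d[["anti-PD-1 vs anti-PD-L1"]] <- comparisonDesign(
    "anti-PD-1 vs anti-PD-L1", "strategy", "anti-PD-1 mono",
    "strategy", "anti-PD-L1 mono", type = "comparison")
  d[["combination vs monotherapy"]] <- comparisonDesign(
    "combination vs monotherapy", "strategy", "combination",
    "strategy", MONO_STRATEGIES, type = "comparison")
  for (nm in names(d)) d[[nm]]$nMin <- nMin
  d
}

#' Run the per-regimen signal table
#'
#' One row per comparison design.  Full-database rows carry ROR and IC
#' with both signal flags; subgroup comparisons carry ROR only (IC fields
#' absent); designs with zero observed cases are emitted with empty
#' statistics, never zeros.
#'
#' @param rs a deduplicated \linkS4class{ReportSet}
#' @param designs list of \code{ComparisonDesign}s
#'   (default \code{defaultDesignSet()})
#' @return data frame, one row per design
#' @export
runSignalTable <- function(rs, designs = defaultDesignSet()) {
  stopifnot(is(rs, "ReportSet"))
  cls <- classifyRegimens(rs)
  rows <- lapply(designs, function(des) {
    tab <- buildContingency(rs, des, .cls = cls)
    full_db <- des$comparatorType == "database"
    st <- signalStats(tab, ic = full_db, nMin = des$nMin)
    cbind(data.frame(design = des$name, type = des$type,
                     comparator = if (full_db) "database" else "subgroup",
                     stringsAsFactors = FALSE),
          st)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
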