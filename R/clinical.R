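# Descriptive and comparative clinical analyses of the case cohort:
# stratified fatality rates, time-to-onset summaries, fatal vs non-fatal
# group tests, and the characteristics table.

UNKNOWN_LABEL <- "unknown or missing"

#' Stratified fatality rates
#'
#' Fatal count, total count and percentage per stratum of a cohort
#' column.  The denominator is all cohort reports in the stratum,
#' including those with unknown outcome; the display percentage is
#' rounded to two decimals, full precision is kept in \code{pct_raw}.
#' Empty strata are omitted.
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @param by records column to stratify on (e.g. "region", "strategy")
#' @return data frame: \code{stratum}, \code{fatal}, \code{total},
#'   \code{pct}, \code{pct_raw}
#' @examples
#' fatalityRate(buildTable2Fixture(), "region")
#' @export
fatalityRate <- function(cohort, by) {
  stopifnot(is(cohort, "CaseCohort"))
  rec <- cohort@records
  if (!by %in% names(rec)) configError(paste("no such column:", by))
  g <- rec[[by]]
  g[is.na(g)] <- UNKNOWN_LABEL
  total <- table(g)
  fatal <- table(g[rec$fatal])
  strata <- names(total)
  f <- as.integer(fatal[strata]); f[is.na(f)] <- 0L
  t <- as.integer(total)
  raw <- ifelse(t > 0, f / t * 100, NA_real_)
  data.frame(stratum = strata, fatal = f, total = t,
             pct = round(raw, 2), pct_raw = raw,
             stringsAsFactors = FALSE, row.names = NULL)
}

quartiles <- function(x) {
  # linear-interpolation convention (stats::quantile type 7)
  stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
}

#' Time-to-onset summaries per group
#'
#' Median and quartiles (linear-interpolation convention) over
#' non-missing TTO values, with the standard bin counts.  Groups whose
#' TTO is entirely missing are omitted.
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @param by grouping: "all", or a records column such as "regimen",
#'   "strategy", "outcome_status"
#' @return data frame with \code{group}, \code{n}, \code{q1},
#'   \code{median}, \code{q3} and one count column per bin
#' @export
summarizeTto <- function(cohort, by = "all") {
  stopifnot(is(cohort, "CaseCohort"))
  rec <- cohort@records
  g <- if (identical(by, "all")) rep("all", nrow(rec)) else rec[[by]]
  if (is.null(g)) configError(paste("no such column:", by))
  ok <- !is.na(rec$tto_days) & !is.na(g)
  if (!any(ok)) {
    out <- data.frame(group = character(0), n = integer(0),
                      q1 = numeric(0), median = numeric(0),
                      q3 = numeric(0), stringsAsFactors = FALSE)
    for (b in TTO_BIN_LEVELS) out[[paste0("bin_", b)]] <- integer(0)
    return(out)
  }
  sp <- split(rec$tto_days[ok], g[ok])
  rows <- lapply(names(sp), function(nm) {
    v <- sp[[nm]]
    q <- quartiles(v)
    row <- data.frame(group = nm, n = length(v), q1 = q[1],
                      median = q[2], q3 = q[3], stringsAsFactors = FALSE)
    bins <- table(factor(binTto(v), levels = TTO_BIN_LEVELS))
    for (b in TTO_BIN_LEVELS) row[[paste0("bin_", b)]] <- as.integer(bins[[b]])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

groupTestResult <- function(test, statistic = NA_real_, p = NA_real_,
                            groups = character(0), n_used = NA_integer_,
                            n_excluded = NA_integer_, testable = TRUE,
                            note = "") {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p), groups = groups, n_used = n_used,
                 n_excluded = n_excluded, testable = testable,
                 note = note),
            class = "groupTest")
}

#' @export
print.groupTest <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("%s: untestable (%s)\n", x$test, x$note))
  } else {
    cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, excluded = %d)\n",
                x$test, x$statistic, x$p_value, x$n_used, x$n_excluded))
  }
  invisible(x)
}

chisqOnTable <- function(m, groups) {
  # rows/columns with zero margin are degenerate after exclusions
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2)
    return(groupTestResult("chi-square", groups = groups, testable = FALSE,
                           note = "degenerate table after exclusions"))
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  res <- groupTestResult("chi-square", ht$statistic, ht$p.value,
                         groups = groups, n_used = sum(m))
  res$expected_below_5 <- sum(ht$expected < 5)
  res
}

#' Compare fatal and non-fatal cases on one characteristic
#'
#' Categorical characteristics use the chi-square test (no continuity
#' correction) on the fatal-by-category table after dropping
#' unknown/missing rows and unknown-outcome reports.  Time to onset uses
#' the Mann-Whitney test.  Other continuous values (age) use the t test
#' when a Shapiro-Wilk pre-check (alpha 0.05) accepts normality in both
#' groups, otherwise Mann-Whitney.  Degenerate tables are flagged
#' untestable rather than erroring.
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @param characteristic records column: categorical (e.g. "region",
#'   "sex", "regimen") or continuous ("tto_days", "age_years")
#' @return a \code{groupTest} result (test name, statistic, p-value,
#'   groups, exclusion counts, testable flag)
#' @export
compareFatalNonfatal <- function(cohort, characteristic) {
  stopifnot(is(cohort, "CaseCohort"))
  rec <- cohort@records
  if (!characteristic %in% names(rec))
    configError(paste("no such column:", characteristic))
  known <- rec[rec$outcome_status %in% c("fatal", "non-fatal"), , drop = FALSE]
  groups <- c("fatal", "non-fatal")
  x <- known[[characteristic]]

  if (characteristic %in% c("tto_days", "age_years")) {
    ok <- !is.na(x)
    v <- x[ok]
    f <- known$fatal[ok]
    n_excluded <- sum(!ok) + (nrow(rec) - nrow(known))
    if (length(unique(f)) < 2 || length(v) < 3)
      return(groupTestResult("Mann-Whitney", groups = groups,
                             testable = FALSE, note = "fewer than two groups"))
    use_t <- FALSE
    if (characteristic == "age_years") {
      normal1 <- tryShapiro(v[f])
      normal2 <- tryShapiro(v[!f])
      use_t <- isTRUE(normal1) && isTRUE(normal2)
    }
    if (use_t) {
      ht <- stats::t.test(v[f], v[!f])
      return(groupTestResult("t", ht$statistic, ht$p.value, groups,
                             length(v), n_excluded))
    }
    ht <- suppressWarnings(stats::wilcox.test(v[f], v[!f]))
    return(groupTestResult("Mann-Whitney", ht$statistic, ht$p.value,
                           groups, length(v), n_excluded))
  }

  keep <- !is.na(x) & x != UNKNOWN_LABEL
  m <- table(known$outcome_status[keep], x[keep])
  n_excluded <- sum(!keep) + (nrow(rec) - nrow(known))
  res <- chisqOnTable(as.matrix(m), groups)
  res$n_excluded <- n_excluded
  res
}

#' Compare time to onset across regimens
#'
#' Kruskal-Wallis test of the non-missing TTO values across multiple
#' groups (two groups reduce to Mann-Whitney).
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @param by grouping column (default "regimen")
#' @param minPerGroup groups with fewer non-missing TTO values are
#'   excluded (default 1)
#' @return a \code{groupTest} result
#' @export
compareTtoAcrossGroups <- function(cohort, by = "regimen", minPerGroup = 1) {
  stopifnot(is(cohort, "CaseCohort"))
  rec <- cohort@records
  g <- rec[[by]]
  if (is.null(g)) configError(paste("no such column:", by))
  ok <- !is.na(rec$tto_days) & !is.na(g)
  v <- rec$tto_days[ok]
  g <- g[ok]
  sizes <- table(g)
  keep_groups <- names(sizes)[sizes >= minPerGroup]
  sel <- g %in% keep_groups
  v <- v[sel]; g <- factor(g[sel])
  if (nlevels(g) < 2)
    return(groupTestResult("Kruskal-Wallis", groups = levels(g),
                           testable = FALSE, note = "fewer than two groups"))
  if (nlevels(g) == 2) {
    ht <- suppressWarnings(stats::wilcox.test(v[g == levels(g)[1]],
                                              v[g == levels(g)[2]]))
    return(groupTestResult("Mann-Whitney", ht$statistic, ht$p.value,
                           levels(g), length(v), sum(!ok)))
  }
  ht <- stats::kruskal.test(v, g)
  groupTestResult("Kruskal-Wallis", ht$statistic, ht$p.value,
                  levels(g), length(v), sum(!ok))
}

tryShapiro <- function(v) {
  if (length(v) < 3 || length(v) > 5000 || length(unique(v)) < 3)
    return(FALSE)
  stats::shapiro.test(v)$p.value > 0.05
}

REGIMEN_LEVELS <- c("ipilimumab", "tremelimumab", "pembrolizumab",
                    "nivolumab", "cemiplimab", "atezolizumab", "avelumab",
                    "durvalumab", "ipilimumab+nivolumab",
                    "ipilimumab+pembrolizumab", "tremelimumab+durvalumab",
                    "other-multi-ICI")

CHARACTERISTIC_BLOCKS <- list(
  gender = list(column = "sex", levels = c("female", "male")),
  age_group = list(column = "age_group", levels = AGE_GROUP_LEVELS),
  report_year = list(column = "report_year", levels = NULL),
  region = list(column = "region",
                levels = c("Europe", "America", "Asia", "Oceania", "Africa")),
  indication = list(column = "indication_group",
                    levels = setdiff(INDICATION_PRIORITY, "unknown or missing")),
  outcome = list(column = "outcome_display",
                 levels = c("death", "life-threatening", "disability",
                            "hospitalization", "other serious")),
  reporter = list(column = "reporter",
                  levels = c("non-health-professional", "health-professional")),
  tto_bin = list(column = "tto_bin", levels = TTO_BIN_LEVELS),
  regimen = list(column = "regimen", levels = REGIMEN_LEVELS)
)

blockCounts <- function(values, levels) {
  vals <- as.character(values)
  vals[is.na(vals)] <- UNKNOWN_LABEL
  if (is.null(levels)) levels <- sort(unique(vals[vals != UNKNOWN_LABEL]))
  cats <- c(levels, UNKNOWN_LABEL)
  as.integer(table(factor(vals, levels = cats)))
}

#' Build the full characteristics table
#'
#' Counts and percentages per characteristic block (gender, age group,
#' reporting year, region, indication, outcome, reporter, TTO bin,
#' regimen) for the total, fatal and non-fatal columns, each percentage
#' against its column's cohort-level denominator (unknown rows included),
#' plus a fatal-vs-non-fatal test per block.  The within-30-days share of
#' documented-TTO cases uses the documented count as denominator and is
#' exposed separately via [summarizeTto()].
#'
#' @param cohort a \linkS4class{CaseCohort}
#' @return list of class \code{characteristicsTable}: \code{$table}
#'   (one row per block/category) and \code{$tests} (named list of
#'   \code{groupTest} results)
#' @export
buildCharacteristicsTable <- function(cohort) {
  stopifnot(is(cohort, "CaseCohort"))
  rec <- cohort@records
  n_total <- nrow(rec)
  n_fatal <- sum(rec$outcome_status == "fatal")
  n_nonfatal <- sum(rec$outcome_status == "non-fatal")
  pct <- function(n, d) if (d > 0) n / d * 100 else rep(0, length(n))

  rows <- list()
  for (blk in names(CHARACTERISTIC_BLOCKS)) {
    spec <- CHARACTERISTIC_BLOCKS[[blk]]
    v <- rec[[spec$column]]
    lv <- spec$levels
    if (is.null(lv)) {
      vals <- as.character(v); vals[is.na(vals)] <- UNKNOWN_LABEL
      lv <- sort(unique(vals[vals != UNKNOWN_LABEL]))
    }
    cats <- c(lv, UNKNOWN_LABEL)
    tot <- blockCounts(v, lv)
    fat <- blockCounts(v[rec$outcome_status == "fatal"], lv)
    non <- blockCounts(v[rec$outcome_status == "non-fatal"], lv)
    rows[[blk]] <- data.frame(
      block = blk, category = cats,
      total_n = tot, total_pct = pct(tot, n_total),
      fatal_n = fat, fatal_pct = pct(fat, n_fatal),
      nonfatal_n = non, nonfatal_pct = pct(non, n_nonfatal),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tests <- list()
  if (n_fatal > 0 && n_nonfatal > 0) {
    tests$gender <- compareFatalNonfatal(cohort, "sex")
    tests$age <- compareFatalNonfatal(cohort, "age_years")
    tests$report_year <- compareFatalNonfatal(cohort, "report_year")
    tests$region <- compareFatalNonfatal(cohort, "region")
    tests$indication <- compareFatalNonfatal(cohort, "indication_group")
    tests$reporter <- compareFatalNonfatal(cohort, "reporter")
    tests$tto <- compareFatalNonfatal(cohort, "tto_days")
    tests$therapy <- compareFatalNonfatal(cohort, "therapy")
    tests$strategy <- compareFatalNonfatal(cohort, "strategy")
  }
  structure(list(table = tab, tests = tests,
                 n_total = n_total, n_fatal = n_fatal,
                 n_nonfatal = n_nonfatal),
            class = "characteristicsTable")
}

#' @export
print.characteristicsTable <- function(x, ...) {
  cat(sprintf("Characteristics table: %d cases (%d fatal, %d non-fatal)\n",
              x$n_total, x$n_fatal, x$n_nonfatal))
  print(renderCharacteristicsTable(x))
  invisible(x)
}

#' Render a characteristics table as plain text
#'
#' Counts with percentages to two decimals; block p-values shown with
#' "NS" for p >= 0.05.
#'
#' @param x a \code{characteristicsTable}
#' @return character vector of lines
#' @export
renderCharacteristicsTable <- function(x) {
  stopifnot(inherits(x, "characteristicsTable"))
  tab <- x$table
  lines <- character(0)
  for (blk in unique(tab$block)) {
    tst <- x$tests[[blk]]
    ptxt <- ""
    if (!is.null(tst) && tst$testable && !is.na(tst$p_value))
      ptxt <- if (tst$p_value < 0.05) sprintf("p=%.3f", tst$p_value) else "NS"
    lines <- c(lines, sprintf("%s %s", blk, ptxt))
    sub <- tab[tab$block == blk, ]
    lines <- c(lines, sprintf("  %-38s %5d (%6.2f) %5d (%6.2f) %5d (%6.2f)",
                              sub$category, sub$total_n, sub$total_pct,
                              sub$fatal_n, sub$fatal_pct,
                              sub$nonfatal_n, sub$nonfatal_pct))
  }
  lines
}
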