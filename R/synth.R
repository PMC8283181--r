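# Synthetic FAERS-like database generator with a ground-truth ledger.
#
# The generator emulates the structures the pipeline consumes: case/version
# duplication, drug records with role codes and therapy start dates,
# reactions as MedDRA preferred terms, outcome codes, demographics with
# realistic missingness, and a configurable excess-reporting association
# between chosen drugs and the pericardial event set.  Associations are
# injected on the odds scale, so the true reporting odds ratio of a
# (suspect drug, pericardial set) pair equals the configured multiplier.

#' Default drug catalogue for the synthetic generator
#'
#' The eight ICIs plus common background drugs, each with an exposure
#' probability and the probability that an exposed drug is reported as
#' suspect.  Adjust exposure probabilities to set up calibration or
#' recovery studies.
#'
#' @return data frame with columns \code{name}, \code{exposureProb},
#'   \code{suspectProb}, \code{isICI}
#' @export
defaultDrugCatalogue <- function() {
  ici <- iciDictionary()
  data.frame(
    name = c(ici$generic,
             "carboplatin", "pemetrexed", "aspirin", "atorvastatin",
             "metformin"),
    exposureProb = c(0.015, 0.012, 0.001, 0.005, 0.001, 0.003, 0.006,
                     0.0005, 0.03, 0.02, 0.08, 0.05, 0.06),
    suspectProb = c(rep(0.9, 8), rep(0.2, 5)),
    isICI = c(rep(TRUE, 8), rep(FALSE, 5)),
    stringsAsFactors = FALSE)
}

BACKGROUND_PTS <- c("nausea", "fatigue", "diarrhoea", "rash", "pyrexia",
                    "dyspnoea", "anaemia", "headache", "vomiting",
                    "pruritus", "cough", "decreased appetite", "dizziness",
                    "arthralgia", "oedema peripheral")

defaultIndicationWeights <- function() {
  c("non-small cell lung cancer" = 0.40,
    "malignant melanoma" = 0.10,
    "renal cell carcinoma" = 0.06,
    "urothelial carcinoma" = 0.04,
    "hodgkin's disease" = 0.03,
    "gastric cancer" = 0.04,
    "squamous cell carcinoma of head and neck" = 0.02,
    "breast cancer" = 0.02,
    "ovarian cancer" = 0.03,
    "mesothelioma" = 0.015,
    "malignant neoplasm" = 0.03,
    "hepatocellular carcinoma" = 0.04,
    "plasma cell myeloma" = 0.02,
    "product used for unknown indication" = 0.075,
    "psoriasis" = 0.02)
}

#' Configure the synthetic database generator
#'
#' All defaults describe one realistic study condition: ICI exposure
#' rates of a fraction of a percent against common background drugs, a
#' 1\% per-report baseline probability of a pericardial preferred term,
#' demographics shaped like the published case series (age about
#' N(63, 10) truncated to [0, 120], mostly health-professional reporters,
#' Europe/America/Asia-dominated regions), log-normal time to onset with
#' median about 37 days, and 5\% injected duplicate case versions.
#'
#' @param nReports number of distinct cases to generate
#' @param seed RNG seed; the whole database is reproducible from it
#' @param drugs drug catalogue: data frame with \code{name},
#'   \code{exposureProb}, \code{suspectProb}, \code{isICI}
#' @param baselineEventProb per-report baseline probability of a
#'   pericardial preferred term
#' @param backgroundPtRate mean number of background reactions per report
#'   (at least one is always emitted)
#' @param association named list of odds multipliers: each multiplier
#'   inflates the pericardial event odds of reports where that drug is a
#'   suspect
#' @param duplicateRate fraction of cases re-emitted as a higher case
#'   version (only receipt date and version mutate)
#' @param demographics list: \code{sexWeights}, \code{ageMean},
#'   \code{ageSd}, \code{ageMissing}, \code{regionWeights},
#'   \code{reporterWeights}, \code{yearRange}
#' @param dates list: \code{eventMissing}, \code{startMissing},
#'   \code{startMonthPrec} (probability a start date is month-precision)
#' @param tto list \code{meanlog}, \code{sdlog}, or per-group lists
#'   \code{fatal}/\code{nonfatal}
#' @param fatality list \code{case} (fatality probability of pericardial
#'   ICI cases) and \code{background}
#' @param indicationWeights named weights for indication terms attached
#'   to suspect ICI drugs
#' @return validated \code{SynthConfig} (S3 list)
#' @export
synthConfig <- function(nReports = 10000, seed = 1,
                        drugs = defaultDrugCatalogue(),
                        baselineEventProb = 0.01,
                        backgroundPtRate = 1.5,
                        association = list(),
                        duplicateRate = 0.05,
                        demographics = list(),
                        dates = list(),
                        tto = list(meanlog = 3.6, sdlog = 1.0),
                        fatality = list(case = 0.17, background = 0.05),
                        indicationWeights = defaultIndicationWeights()) {
  demo_default <- list(
    sexWeights = c(female = 0.36, male = 0.54, missing = 0.10),
    ageMean = 63, ageSd = 10, ageMissing = 0.20,
    regionWeights = c(Europe = 0.37, America = 0.315, Asia = 0.285,
                      Oceania = 0.021, Africa = 0.003, missing = 0.006),
    reporterWeights = c("health-professional" = 0.783,
                        "non-health-professional" = 0.212,
                        missing = 0.005),
    yearRange = c(2015, 2019))
  dates_default <- list(eventMissing = 0.25, startMissing = 0.25,
                        startMonthPrec = 0.05)
  demographics <- utils::modifyList(demo_default, demographics)
  dates <- utils::modifyList(dates_default, dates)
  cfg <- structure(list(nReports = nReports, seed = seed, drugs = drugs,
                        baselineEventProb = baselineEventProb,
                        backgroundPtRate = backgroundPtRate,
                        association = association,
                        duplicateRate = duplicateRate,
                        demographics = demographics, dates = dates,
                        tto = tto, fatality = fatality,
                        indicationWeights = indicationWeights),
                   class = "SynthConfig")
  validateSynthConfig(cfg)
}

checkProb <- function(x, field) {
  if (is.null(x) || anyNA(x) || any(x < 0) || any(x > 1))
    configError(paste("invalid config field:", field,
                      "(probabilities must be in [0, 1])"))
  invisible(x)
}

validateSynthConfig <- function(cfg) {
  if (!inherits(cfg, "SynthConfig")) configError("not a SynthConfig")
  if (is.null(cfg$nReports) || is.na(cfg$nReports) || cfg$nReports < 1)
    configError("invalid config field: nReports (must be >= 1)")
  d <- cfg$drugs
  if (!is.data.frame(d) ||
      !all(c("name", "exposureProb", "suspectProb", "isICI") %in% names(d)))
    configError("invalid config field: drugs (need name/exposureProb/suspectProb/isICI)")
  checkProb(d$exposureProb, "drugs$exposureProb")
  checkProb(d$suspectProb, "drugs$suspectProb")
  checkProb(cfg$baselineEventProb, "baselineEventProb")
  checkProb(cfg$duplicateRate, "duplicateRate")
  checkProb(cfg$fatality$case, "fatality$case")
  checkProb(cfg$fatality$background, "fatality$background")
  checkProb(cfg$dates$eventMissing, "dates$eventMissing")
  checkProb(cfg$dates$startMissing, "dates$startMissing")
  checkProb(cfg$dates$startMonthPrec, "dates$startMonthPrec")
  checkProb(cfg$demographics$ageMissing, "demographics$ageMissing")
  for (w in c("sexWeights", "regionWeights", "reporterWeights"))
    checkProb(cfg$demographics[[w]], paste0("demographics$", w))
  if (length(cfg$association)) {
    mult <- unlist(cfg$association)
    if (anyNA(mult) || any(mult <= 0))
      configError("invalid config field: association (multipliers must be > 0)")
    unknown <- setdiff(names(cfg$association), d$name)
    if (length(unknown))
      configError(paste("invalid config field: association (unknown drug:",
                        paste(unknown, collapse = ", "), ")"))
  }
  cfg
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substring(x, 2))

ttoMeanlog <- function(cfg, fatal) {
  if (!is.null(cfg$tto$fatal)) {
    ifelse(fatal, cfg$tto$fatal$meanlog, cfg$tto$nonfatal$meanlog)
  } else rep(cfg$tto$meanlog, length(fatal))
}

ttoSdlog <- function(cfg, fatal) {
  if (!is.null(cfg$tto$fatal)) {
    ifelse(fatal, cfg$tto$fatal$sdlog, cfg$tto$nonfatal$sdlog)
  } else rep(cfg$tto$sdlog, length(fatal))
}

#' Generate a synthetic FAERS-like database with ground truth
#'
#' Samples drug exposures, roles and a pericardial event per report (the
#' event odds multiplied by the association map for suspect-exposed
#' drugs), emits the six quarter tables with configured missingness,
#' injects duplicate case versions that differ only in version and
#' receipt date, and returns a ledger with the per-report ground truth
#' (suspect set, event flag, true TTO and fatality, duplicate flag).
#' Fully reproducible from the seed.
#'
#' @param config a \code{SynthConfig}
#' @param dir optional directory: when given, the quarter is written as
#'   "$"-delimited files and the ledger as \code{ledger.csv}
#' @return list with \code{quarter} (\linkS4class{FAERSQuarter}) and
#'   \code{ledger} (data frame)
#' @export
generateDatabase <- function(config, dir = NULL) {
  config <- validateSynthConfig(config)
  set.seed(config$seed)
  n <- as.integer(config$nReports)
  cat <- config$drugs
  K <- nrow(cat)

  caseno <- 10000000 + seq_len(n)
  caseid <- as.character(caseno)
  primaryid <- paste0(caseid, "1")

  expo <- matrix(stats::runif(n * K), n, K) <
    matrix(cat$exposureProb, n, K, byrow = TRUE)
  none <- rowSums(expo) == 0
  if (any(none)) {
    fallback <- if (any(!cat$isICI)) which(!cat$isICI)[1] else 1L
    expo[none, fallback] <- TRUE
  }
  susp <- expo & (matrix(stats::runif(n * K), n, K) <
                    matrix(cat$suspectProb, n, K, byrow = TRUE))

  mult <- rep(1, n)
  for (nm in names(config$association)) {
    j <- match(nm, cat$name)
    mult[susp[, j]] <- mult[susp[, j]] * config$association[[nm]]
  }
  p0 <- config$baselineEventProb
  odds <- mult * p0 / (1 - p0)
  event <- stats::runif(n) < odds / (1 + odds)

  ici_cols <- which(cat$isICI)
  has_ici_susp <- rowSums(susp[, ici_cols, drop = FALSE]) > 0
  suspect_key <- rep("", n)
  idx_ici <- which(has_ici_susp)
  if (length(idx_ici)) {
    sub <- susp[idx_ici, ici_cols, drop = FALSE]
    nm <- cat$name[ici_cols]
    suspect_key[idx_ici] <- apply(sub, 1, function(row)
      paste(sort(nm[row]), collapse = "+"))
  }

  p_fatal <- ifelse(event & has_ici_susp, config$fatality$case,
                    config$fatality$background)
  fatal <- stats::runif(n) < p_fatal

  true_tto <- pmax(0L, as.integer(round(stats::rlnorm(
    n, ttoMeanlog(config, fatal), ttoSdlog(config, fatal)))))
  true_tto[!has_ici_susp] <- NA_integer_

  dm <- config$demographics
  yr0 <- as.Date(sprintf("%d-01-01", dm$yearRange[1]))
  yr1 <- as.Date(sprintf("%d-12-31", dm$yearRange[2]))
  start_date <- yr0 + sample.int(as.integer(yr1 - yr0) + 1L, n,
                                 replace = TRUE) - 1L
  event_date <- start_date +
    ifelse(is.na(true_tto),
           sample.int(200L, n, replace = TRUE), true_tto)
  receipt_date <- event_date + sample.int(60L, n, replace = TRUE)

  sex <- sampleCategories(n, dm$sexWeights)
  age_true <- pmin(120, pmax(0, stats::rnorm(n, dm$ageMean, dm$ageSd)))
  age_missing <- stats::runif(n) < dm$ageMissing
  unit <- sample(c("YR", "DY", "MON"), n, replace = TRUE,
                 prob = c(0.85, 0.10, 0.05))
  age_val <- ifelse(unit == "YR", as.character(round(age_true)),
             ifelse(unit == "DY", as.character(round(age_true * 365)),
                    as.character(round(age_true * 12))))
  age_val[age_missing] <- ""
  unit[age_missing] <- ""

  region <- sampleCategories(n, dm$regionWeights)
  cc <- extdataTable("country_regions.tsv")
  country <- rep("", n)
  for (rg in unique(region[!is.na(region)])) {
    idx <- which(!is.na(region) & region == rg)
    pool <- cc$country[cc$region == rg]
    country[idx] <- sample(pool, length(idx), replace = TRUE)
  }

  reporter <- sampleCategories(n, dm$reporterWeights)
  occp <- rep("", n)
  hp <- !is.na(reporter) & reporter == "health-professional"
  occp[hp] <- sample(c("MD", "PH", "OT"), sum(hp), replace = TRUE,
                     prob = c(0.5, 0.25, 0.25))
  nh <- !is.na(reporter) & reporter == "non-health-professional"
  occp[nh] <- sample(c("CN", "LW"), sum(nh), replace = TRUE,
                     prob = c(0.95, 0.05))

  ev_tok <- format(event_date, "%Y%m%d")
  ev_tok[stats::runif(n) < config$dates$eventMissing] <- ""

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    fda_dt = format(receipt_date, "%Y%m%d"), event_dt = ev_tok,
    age = age_val, age_cod = unit,
    sex = ifelse(is.na(sex), "", ifelse(sex == "female", "F", "M")),
    occp_cod = occp, occr_country = country,
    rept_yr = format(receipt_date, "%Y"),
    stringsAsFactors = FALSE)

  # drug rows, ordered by report then catalogue position
  hits <- which(t(expo))                 # t(): report-major order
  row_i <- (hits - 1L) %/% K + 1L
  col_j <- (hits - 1L) %% K + 1L
  n_per <- tabulate(row_i, nbins = n)
  drug_seq <- sequence(n_per)
  is_susp <- susp[cbind(row_i, col_j)]
  # first suspect drug of each report is PS, later suspects SS
  s_cum <- cumsum(is_susp)
  fp <- match(row_i, row_i)          # rows are report-major, so this is
  prior <- s_cum[fp] - is_susp[fp]   # the cumulative count before each report
  first_susp <- is_susp & (s_cum - prior) == 1
  role <- ifelse(is_susp, ifelse(first_susp, "PS", "SS"), "C")
  role[role == "C" & stats::runif(length(role)) < 0.02] <- "I"

  gen <- cat$name[col_j]
  is_ici_row <- cat$isICI[col_j]
  dict <- iciDictionary()
  brand <- stats::setNames(dict$brands, dict$generic)
  drugname <- toupper(gen)
  u <- stats::runif(length(gen))
  b <- brand[gen]
  use_brand <- is_ici_row & !is.na(b) & nzchar(b) & u < 0.35
  drugname[use_brand] <- toupper(b[use_brand])
  use_suffix <- is_ici_row & !use_brand & u > 0.55 & u < 0.70
  drugname[use_suffix] <- paste0(capitalize(gen[use_suffix]), " (10 mg/mL)")
  plain <- is_ici_row & !use_brand & !use_suffix
  drugname[plain] <- capitalize(gen[plain])

  drug <- data.frame(
    primaryid = primaryid[row_i], drug_seq = as.character(drug_seq),
    role_cod = role, drugname = drugname,
    prod_ai = ifelse(is_ici_row, toupper(gen), ""),
    stringsAsFactors = FALSE)

  # reactions: background terms for everyone, pericardial terms for events
  kbg <- pmax(1L, stats::rpois(n, config$backgroundPtRate))
  reac <- data.frame(
    primaryid = rep(primaryid, kbg),
    pt = capitalize(sample(BACKGROUND_PTS, sum(kbg), replace = TRUE)),
    stringsAsFactors = FALSE)
  if (any(event)) {
    plist <- pericardialTerms()$pt
    eidx <- which(event)
    pt1 <- sample(plist, length(eidx), replace = TRUE)
    extra <- stats::runif(length(eidx)) < 0.2
    reac <- rbind(reac,
                  data.frame(primaryid = primaryid[eidx],
                             pt = capitalize(pt1), stringsAsFactors = FALSE),
                  data.frame(primaryid = primaryid[eidx][extra],
                             pt = capitalize(sample(plist, sum(extra),
                                                    replace = TRUE)),
                             stringsAsFactors = FALSE))
  }
  reac$pt_cod <- ""
  reac <- reac[order(match(reac$primaryid, primaryid)), , drop = FALSE]
  rownames(reac) <- NULL

  # outcomes
  oc_codes <- rep("", n)
  oc_codes[fatal] <- "DE"
  nonfatal <- which(!fatal)
  oc_codes[nonfatal] <- sample(c("HO", "LT", "OT", "DS", "RI", ""),
                               length(nonfatal), replace = TRUE,
                               prob = c(0.32, 0.08, 0.22, 0.02, 0.01, 0.35))
  has_oc <- nzchar(oc_codes)
  outc <- data.frame(primaryid = primaryid[has_oc],
                     outc_cod = oc_codes[has_oc], stringsAsFactors = FALSE)
  extra_ho <- fatal & stats::runif(n) < 0.3
  if (any(extra_ho))
    outc <- rbind(outc, data.frame(primaryid = primaryid[extra_ho],
                                   outc_cod = "HO", stringsAsFactors = FALSE))
  outc <- outc[order(match(outc$primaryid, primaryid)), , drop = FALSE]
  rownames(outc) <- NULL

  # therapy and indication rows for suspect ICI drug records
  ici_susp_row <- is_susp & is_ici_row
  st_date <- start_date[row_i[ici_susp_row]]
  st_tok <- format(st_date, "%Y%m%d")
  u <- stats::runif(length(st_tok))
  st_tok[u < config$dates$startMonthPrec] <- format(
    st_date[u < config$dates$startMonthPrec], "%Y%m")
  st_tok[u > 1 - config$dates$startMissing] <- ""
  ther <- data.frame(primaryid = primaryid[row_i[ici_susp_row]],
                     dsg_drug_seq = as.character(drug_seq[ici_susp_row]),
                     start_dt = st_tok, end_dt = rep("", length(st_tok)),
                     stringsAsFactors = FALSE)

  iw <- config$indicationWeights
  indi <- data.frame(primaryid = primaryid[row_i[ici_susp_row]],
                     indi_drug_seq = as.character(drug_seq[ici_susp_row]),
                     indi_pt = capitalize(sample(names(iw), sum(ici_susp_row),
                                                 replace = TRUE, prob = iw)),
                     stringsAsFactors = FALSE)

  ledger <- data.frame(
    caseid = caseid, primaryid = primaryid, caseversion = 1L,
    duplicate = FALSE, suspects = suspect_key, pericardial = event,
    true_tto = true_tto, true_fatal = fatal, stringsAsFactors = FALSE)

  # duplicate injection: higher case versions, new receipt date only
  dup <- which(stats::runif(n) < config$duplicateRate)
  if (length(dup)) {
    dup_old <- primaryid[dup]
    dup_new <- paste0(caseid[dup], "2")
    d2 <- demo[dup, , drop = FALSE]
    d2$primaryid <- dup_new
    d2$caseversion <- "2"
    new_receipt <- receipt_date[dup] + sample.int(30L, length(dup),
                                                  replace = TRUE)
    d2$fda_dt <- format(new_receipt, "%Y%m%d")
    d2$rept_yr <- format(new_receipt, "%Y")
    demo <- rbind(demo, d2)
    remap <- stats::setNames(dup_new, dup_old)
    for (tabnm in c("drug", "reac", "outc", "ther", "indi")) {
      tb <- get(tabnm)
      sub <- tb[tb$primaryid %in% dup_old, , drop = FALSE]
      if (nrow(sub)) {
        sub$primaryid <- unname(remap[sub$primaryid])
        assign(tabnm, rbind(tb, sub))
      }
    }
    led2 <- ledger[dup, , drop = FALSE]
    led2$primaryid <- dup_new
    led2$caseversion <- 2L
    led2$duplicate <- TRUE
    ledger <- rbind(ledger, led2)
  }
  rownames(demo) <- rownames(ledger) <- NULL

  quarter <- new("FAERSQuarter", demo = demo, drug = drug, reac = reac,
                 outc = outc, ther = ther, indi = indi,
                 log = list(generated = n, duplicates = length(dup)))
  if (!is.null(dir)) {
    writeQuarter(quarter, dir)
    utils::write.csv(ledger, file.path(dir, "ledger.csv"),
                     row.names = FALSE, na = "")
  }
  list(quarter = quarter, ledger = ledger)
}

#' Contingency cells from the generator ledger
#'
#' Computes the same 2x2 cells as [buildContingency()], but from the
#' ground-truth ledger (after resolving duplicate case versions) instead
#' of the emitted files; the two must agree exactly for any registered
#' design with the default pericardial event set.
#'
#' @param ledger ledger data frame from [generateDatabase()]
#' @param design a \code{ComparisonDesign} (default pericardial events)
#' @return a \linkS4class{ContingencyTable}
#' @export
ledgerContingency <- function(ledger, design) {
  stopifnot(inherits(design, "ComparisonDesign"))
  if (!is.null(design$events))
    configError("ledger cells are defined for the pericardial event set only")
  ord <- order(ledger$caseid, -ledger$caseversion)
  final <- ledger[ord, ][!duplicated(ledger$caseid[ord]), , drop = FALSE]
  key <- final$suspects
  regimen <- rep(NA_character_, nrow(final))
  has <- nzchar(key)
  regimen[has] <- regimenFromSuspectKey(key[has])
  cls <- data.frame(primary_id = final$primaryid, regimen = regimen,
                    strategy = regimenStrategy(regimen),
                    stringsAsFactors = FALSE)
  event <- final$pericardial
  tflag <- selectorFlag(cls, design$targetType, design$targetValue)
  if (design$comparatorType == "database") {
    cflag <- !tflag
  } else {
    cflag <- selectorFlag(cls, design$comparatorType,
                          design$comparatorValue) & !tflag
  }
  contingencyTable(sum(tflag & event), sum(tflag & !event),
                   sum(cflag & event), sum(cflag & !event))
}

#' Generate a cohort with group-specific time to onset
#'
#' Directly samples a case cohort (no file round trip) with Bernoulli
#' fatality and log-normal TTO whose meanlog may differ between fatal and
#' non-fatal cases and between regimens, for power and type-I-error
#' studies of the TTO comparisons.
#'
#' @param n number of cases (0 gives a valid empty cohort)
#' @param meanlogNonfatal,meanlogFatal log-normal location by fatality
#' @param sdlog log-normal scale
#' @param fatalProb Bernoulli fatality probability
#' @param regimenWeights named sampling weights over regimen labels
#' @param regimenShift optional named meanlog shifts per regimen
#' @param seed RNG seed
#' @return a \linkS4class{CaseCohort}
#' @export
generateTtoCohort <- function(n, meanlogNonfatal = 3.6, meanlogFatal = 3.6,
                              sdlog = 1.0, fatalProb = 0.17,
                              regimenWeights = c(nivolumab = 1),
                              regimenShift = NULL, seed = 1) {
  set.seed(seed)
  if (n == 0) {
    return(newCaseCohort(emptyCaseRecords(),
                         list(steps = data.frame(step = "generated", n = 0L))))
  }
  regimen <- sample(names(regimenWeights), n, replace = TRUE,
                    prob = regimenWeights)
  fatal <- stats::runif(n) < fatalProb
  meanlog <- ifelse(fatal, meanlogFatal, meanlogNonfatal)
  if (!is.null(regimenShift)) {
    shift <- regimenShift[regimen]
    shift[is.na(shift)] <- 0
    meanlog <- meanlog + unname(shift)
  }
  tto <- pmax(0L, as.integer(round(stats::rlnorm(n, meanlog, sdlog))))
  strategy <- regimenStrategy(regimen)
  rec <- data.frame(
    case_id = sprintf("SIM%06d", seq_len(n)),
    primary_id = sprintf("SIM%06d1", seq_len(n)),
    report_year = NA_integer_, sex = NA_character_,
    age_years = NA_real_, age_group = NA_character_,
    region = NA_character_, reporter = NA_character_,
    indication_group = "unknown or missing",
    regimen = regimen, strategy = strategy,
    therapy = ifelse(strategy == "combination", "combination",
              ifelse(is.na(strategy) | strategy == "other", "other",
                     "monotherapy")),
    fatal = fatal,
    outcome_status = ifelse(fatal, "fatal", "non-fatal"),
    outcome_display = ifelse(fatal, "death", "other serious"),
    tto_days = tto, tto_bin = binTto(tto),
    stringsAsFactors = FALSE)
  newCaseCohort(rec, list(steps = data.frame(step = "generated", n = n),
                          seed = seed))
}
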