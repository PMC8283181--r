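# Case definition, deduplication, regimen classification, time to onset.

test_that("pericardial PT membership matches names and codes", {
  expect_true(isPericardialPT("Cardiac tamponade"))
  expect_true(isPericardialPT("10034487"))       # pericarditis constrictive
  expect_true(isPericardialPT("  pericardial   effusion "))
  expect_false(isPericardialPT("myocarditis"))
  expect_false(isPericardialPT("10000000"))
  expect_equal(sum(isPericardialPT(pericardialTerms()$pt)), 15L)
})

test_that("drug-name normalisation strips brands, dose text, suffixes", {
  expect_equal(normalizeDrugName("OPDIVO"), "nivolumab")
  expect_equal(normalizeDrugName("Nivolumab (10 mg/mL)"), "nivolumab")
  expect_equal(normalizeDrugName("KEYTRUDA 25 MG"), "pembrolizumab")
  expect_equal(normalizeDrugName("yervoy."), "ipilimumab")
  expect_true(is.na(normalizeDrugName("aspirin")))
  expect_true(is.na(normalizeDrugName("")))
  # vectorised
  expect_equal(normalizeDrugName(c("TECENTRIQ", "Imfinzi", "BAVENCIO")),
               c("atezolizumab", "durvalumab", "avelumab"))
})

test_that("the highest case version wins deduplication, with tie-breaks", {
  q <- makeQuarter(
    demo = rbind(demoRow("11", case = "C1", version = "1", fda = "20190101"),
                 demoRow("12", case = "C1", version = "2", fda = "20190301"),
                 demoRow("13", case = "C1", version = "3", fda = "20190201"),
                 demoRow("21", case = "C2", version = "1"),
                 demoRow("31", case = "C3", version = "1", fda = "20190101"),
                 demoRow("32", case = "C3", version = "1", fda = "20190501")),
    reac = do.call(rbind, lapply(c("11", "12", "13", "21", "31", "32"),
                                 reacRow, pt = "Nausea")))
  rs <- deduplicateReports(assembleReports(q))
  r <- reports(rs)
  expect_equal(sort(r$primary_id), c("13", "21", "32"))
  expect_equal(rs@log$dedup_dropped, 3L)
  # child tables are filtered consistently
  expect_setequal(unique(rs@reactions$primary_id), r$primary_id)
})

test_that("deduplication equals a brute-force group-by on injected duplicates", {
  g <- generateDatabase(synthConfig(nReports = 100, seed = 21,
                                    duplicateRate = 0.10))
  rs <- deduplicateReports(assembleReports(g$quarter))
  led <- g$ledger
  # brute force: per case id keep the max version
  brute <- vapply(split(led, led$caseid), function(grp)
    grp$primaryid[which.max(grp$caseversion)], character(1))
  expect_equal(nReports(rs), length(unique(led$caseid)))
  expect_setequal(reports(rs)$primary_id, unname(brute))
})

test_that("regimens classify by the suspect ICI set", {
  expect_equal(classifyRegimen("pembrolizumab"),
               list(label = "pembrolizumab", strategy = "anti-PD-1 mono"))
  expect_equal(classifyRegimen(c("ipilimumab", "nivolumab")),
               list(label = "ipilimumab+nivolumab", strategy = "combination"))
  expect_equal(classifyRegimen(c("nivolumab", "ipilimumab"))$label,
               "ipilimumab+nivolumab")  # order-invariant
  expect_equal(classifyRegimen(c("durvalumab", "tremelimumab"))$label,
               "tremelimumab+durvalumab")
  expect_equal(classifyRegimen(c("nivolumab", "pembrolizumab")),
               list(label = "other-multi-ICI", strategy = "other"))
  expect_equal(classifyRegimen("ipilimumab")$strategy, "anti-CTLA-4 mono")
  expect_equal(classifyRegimen("avelumab")$strategy, "anti-PD-L1 mono")
  expect_error(classifyRegimen(character(0)), "suspect")
})

test_that("time to onset needs day precision on both operands", {
  mk <- function(event, start) {
    q <- makeQuarter(demo = demoRow("1", event = event),
                     drug = drugRow("1"),
                     reac = reacRow("1", "Pericarditis"),
                     ther = therRow("1", start = start))
    computeTto(assembleReports(q))
  }
  expect_equal(mk("20190212", "20190101")$tto_days, 42L)
  expect_true(is.na(mk("20190401", "20190501")$tto_days))   # negative
  expect_equal(attr(mk("20190401", "20190501"), "n_negative"), 1L)
  expect_true(is.na(mk("20190212", "201901")$tto_days))     # month start
  expect_true(is.na(mk("201902", "20190101")$tto_days))     # month event
  expect_true(is.na(mk("20190212", "")$tto_days))
})

test_that("the earliest day-precision suspect start defines onset", {
  q <- makeQuarter(
    demo = demoRow("1", event = "20190301"),
    drug = rbind(drugRow("1", seq = "1", name = "OPDIVO"),
                 drugRow("1", seq = "2", name = "YERVOY", role = "SS"),
                 drugRow("1", seq = "3", name = "aspirin", role = "C")),
    reac = reacRow("1", "Cardiac tamponade"),
    ther = rbind(therRow("1", seq = "1", start = "20190201"),
                 therRow("1", seq = "2", start = "20190115"),
                 therRow("1", seq = "3", start = "20180101")))
  expect_equal(computeTto(assembleReports(q))$tto_days, 45L)
})

test_that("the cohort keeps pericardial cases with a suspect ICI only", {
  q <- makeQuarter(
    demo = rbind(demoRow("1"), demoRow("2"), demoRow("3"), demoRow("4")),
    drug = rbind(drugRow("1", name = "Nivolumab"),
                 drugRow("2", name = "Nivolumab", role = "C"),  # concomitant
                 drugRow("3", name = "aspirin"),
                 drugRow("4", name = "KEYTRUDA")),
    reac = rbind(reacRow("1", "Pericardial effusion"),
                 reacRow("2", "Pericarditis"),
                 reacRow("3", "Cardiac tamponade"),
                 reacRow("4", "Nausea")),
    outc = outcRow("1", "DE"))
  cohort <- buildCohort(deduplicateReports(assembleReports(q)))
  rec <- records(cohort)
  expect_equal(rec$primary_id, "1")
  expect_true(rec$fatal)
  expect_equal(rec$regimen, "nivolumab")
  steps <- provenance(cohort)$steps
  expect_true(all(diff(steps$n) <= 0))   # filters only shrink
})

test_that("a report with several pericardial PTs counts once", {
  q <- makeQuarter(
    demo = demoRow("1"),
    drug = drugRow("1"),
    reac = rbind(reacRow("1", "Pericarditis"),
                 reacRow("1", "Pericardial effusion"),
                 reacRow("1", "Cardiac tamponade")))
  expect_equal(nReports(buildCohort(assembleReports(q))), 1L)
})

test_that("the case definition is idempotent", {
  g <- generateDatabase(synthConfig(nReports = 3000, seed = 33,
                                    association = list(nivolumab = 4)))
  rs <- deduplicateReports(assembleReports(g$quarter))
  cohort <- buildCohort(rs)
  pids <- records(cohort)$primary_id
  rs2 <- rs
  rs2@reports <- rs@reports[rs@reports$primary_id %in% pids, ]
  for (s in c("drugs", "reactions", "outcomes", "indications")) {
    df <- slot(rs2, s)
    slot(rs2, s) <- df[df$primary_id %in% pids, ]
  }
  cohort2 <- buildCohort(rs2)
  rec1 <- records(cohort);  rec1 <- rec1[order(rec1$primary_id), ]
  rec2 <- records(cohort2); rec2 <- rec2[order(rec2$primary_id), ]
  rownames(rec1) <- rownames(rec2) <- NULL
  expect_equal(rec2, rec1)
})

test_that("strategies partition the cohort and bins sum to documented TTO", {
  g <- generateDatabase(synthConfig(nReports = 5000, seed = 34,
                                    association = list(nivolumab = 5,
                                                       ipilimumab = 3)))
  cohort <- buildCohort(deduplicateReports(assembleReports(g$quarter)))
  rec <- records(cohort)
  expect_gt(nrow(rec), 0)
  strat <- table(rec$strategy)
  expect_equal(sum(strat), nrow(rec))
  expect_true(all(names(strat) %in% c("anti-PD-1 mono", "anti-PD-L1 mono",
                                      "anti-CTLA-4 mono", "combination",
                                      "other")))
  bins <- table(rec$tto_bin)
  expect_equal(sum(bins), sum(!is.na(rec$tto_days)))
  # bin boundaries are closed on the printed endpoints
  expect_equal(binTto(c(0, 30, 31, 60, 61, 90, 91, 180, 181)),
               c("0-30", "0-30", "31-60", "31-60", "61-90", "61-90",
                 "91-180", "91-180", ">180"))
})

test_that("an empty cohort is valid, not an error", {
  q <- makeQuarter(demo = demoRow("1"), drug = drugRow("1", name = "aspirin"),
                   reac = reacRow("1", "Nausea"))
  cohort <- buildCohort(assembleReports(q))
  expect_s4_class(cohort, "CaseCohort")
  expect_equal(nReports(cohort), 0L)
})

test_that("indication terms map onto the reporting groups", {
  expect_equal(mapIndication(c("Non-small cell lung cancer",
                               "Malignant melanoma",
                               "Renal cell carcinoma",
                               "Product used for unknown indication",
                               "Psoriasis")),
               c("lung cancer", "melanoma", "tumors of urinary system",
                 "unknown or missing", "other indications"))
})
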