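# Disproportionality statistics: 2x2 construction, ROR, expected counts,
# IC and the signal criteria.

test_that("contingency cells classify each report exactly once", {
  rs <- assembleReports(contingencyQuarter())
  tab <- buildContingency(rs, comparisonDesign("ICIs", "ici"))
  expect_equal(ctCells(tab), c(a = 2, b = 3, c = 1, d = 4))
  expect_equal(sum(ctCells(tab)), nReports(rs))
})

test_that("named-regimen comparators restrict the frame to both groups", {
  rs <- assembleReports(contingencyQuarter())
  des <- comparisonDesign("nivolumab vs pembrolizumab", "drug", "nivolumab",
                          "drug", "pembrolizumab")
  tab <- buildContingency(rs, des)
  # nivolumab reports 101/102 (with event) and 103 (without); pembrolizumab
  # report 104 (without); everything else is outside the two-group frame
  expect_equal(ctCells(tab), c(a = 2, b = 1, c = 0, d = 1))
  expect_error(comparisonDesign("bad", "drug", "nivolumab",
                                "drug", "nivolumab"),
               "disjoint")
})

test_that("ROR point estimates and Woolf intervals match the closed form", {
  r <- computeRor(contingencyTable(10, 90, 100, 9000))
  expect_equal(r$ror, 10.0)
  expect_false(r$corrected)
  sym <- computeRor(contingencyTable(5, 5, 5, 5))
  expect_equal(sym$ror, 1.0)
  expect_lt(sym$ror025, 1); expect_gt(sym$ror975, 1)
  # frozen values computed independently before the module was written
  fr <- computeRor(contingencyTable(3, 97, 300, 99700))
  expect_equal(fr$ror, 10.27835051546392, tolerance = 1e-10)
  expect_equal(fr$ror025, 3.2398041955855783, tolerance = 1e-6)
  expect_equal(fr$ror975, 32.60829449590938, tolerance = 1e-6)
})

test_that("zero cells trigger the Haldane-Anscombe correction with a flag", {
  r <- computeRor(contingencyTable(3, 0, 10, 100))
  expect_true(r$corrected)
  expect_equal(r$ror, (3.5 * 100.5) / (0.5 * 10.5))
  expect_true(is.finite(r$ror025) && is.finite(r$ror975))
})

test_that("expected counts follow the margin product rule", {
  expect_equal(expectedCount(1000, 200, 100000), 2.0)
  expect_equal(expectedCount(0, 50, 1000), 0)
  expect_error(expectedCount(10, 10, 0), "nTotal")
  expect_error(expectedCount(20, 5, 10), "margins")
  # identity with the (a+b)(a+c)/N form on random tables
  tabs <- randomTables(50, seed = 99)
  with(tabs, expect_equal(expectedCount(a + b, a + c, a + b + c + d),
                          (a + b) * (a + c) / (a + b + c + d)))
})

test_that("IC identities hold exactly", {
  expect_identical(computeIc(15, 7.25)$ic, 1.0)   # 15.5/7.75 = 2
  expect_identical(computeIc(12, 12)$ic, 0.0)
  expect_identical(computeIc(0.5, 0.5)$ic, 0.0)
})

test_that("IC is monotone in the observed count and IC025 is always below", {
  e <- 17.3
  ics <- computeIc(0:400, e)
  expect_true(all(diff(ics$ic) > 0))
  expect_true(all(ics$ic025 < ics$ic))
  # decreasing in expected count with observed fixed
  ice <- computeIc(50, seq(1, 200, by = 0.5))
  expect_true(all(diff(ice$ic) < 0))
})

test_that("ROR and IC agree with the independent oracle on random tables", {
  tabs <- randomTables(200, seed = 7)
  for (i in seq_len(nrow(tabs))) {
    a <- tabs$a[i]; b <- tabs$b[i]; c <- tabs$c[i]; d <- tabs$d[i]
    got <- computeRor(contingencyTable(a, b, c, d))
    want <- oracleRor(a, b, c, d)
    expect_equal(got$ror, unname(want["ror"]), tolerance = 1e-10)
    expect_equal(got$ror025, unname(want["lo"]), tolerance = 1e-10)
    expect_equal(got$ror975, unname(want["hi"]), tolerance = 1e-10)
    nexp <- expectedCount(a + b, a + c, a + b + c + d)
    gotic <- computeIc(a, nexp)
    wantic <- oracleIc(a, nexp)
    expect_equal(gotic$ic, unname(wantic["ic"]), tolerance = 1e-10)
    expect_equal(gotic$ic025, unname(wantic["ic025"]), tolerance = 1e-10)
  }
})

test_that("signal criteria apply the interval bounds and the case minimum", {
  s <- classifySignal(data.frame(n_observed = c(705, 22, 2, 3, 10),
                                 ror025 = c(4.51, 0.84, 5.0, 1.01, 1.0),
                                 ic025 = c(2.11, -0.31, NA, NA, 0.0)))
  expect_equal(s$signal_ror, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(s$signal_ic, c(TRUE, FALSE, NA, NA, FALSE))
  # a stricter case minimum can be supplied
  s5 <- classifySignal(data.frame(n_observed = 3, ror025 = 2), nMin = 5)
  expect_false(s5$signal_ror)
})

test_that("the default signal table has the published layout", {
  drugs <- defaultDrugCatalogue()
  drugs$exposureProb[drugs$name == "nivolumab"] <- 0.05
  g <- generateDatabase(synthConfig(nReports = 8000, seed = 12,
                                    drugs = drugs,
                                    association = list(nivolumab = 5)))
  rs <- deduplicateReports(assembleReports(g$quarter))
  st <- runSignalTable(rs)
  expect_equal(as.vector(table(st$type)[c("total", "class", "drug",
                                          "combination", "comparison")]),
               c(1L, 3L, 8L, 3L, 4L))
  # subgroup comparisons carry ROR only
  comp <- st[st$type == "comparison", ]
  expect_true(all(is.na(comp$ic)) && all(is.na(comp$ic025)))
  expect_true(all(comp$comparator == "subgroup"))
  # zero-case rows are emitted with empty statistics, not zeros
  zero <- st[st$n_observed == 0, ]
  expect_gt(nrow(zero), 0)
  expect_true(all(is.na(zero$ror)) && all(is.na(zero$ic)))
  # the injected pair is flagged on its full-database row
  nivo <- st[st$design == "nivolumab", ]
  expect_true(nivo$signal_ror && nivo$signal_ic)
})
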