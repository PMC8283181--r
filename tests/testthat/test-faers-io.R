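# FAERS ASCII I/O: date parsing, file round trips, assembly rules.

test_that("date parser handles the 4/6/8-digit token truth table", {
  tokens <- c("20190212", "20190230", "201902", "201913", "2019", "0199",
              "", "garbage", "19000101", "21010101")
  p <- parseFaersDate(tokens)
  expect_equal(p$precision,
               c("day", NA, "month", NA, "year", NA, NA, NA, "day", "day"))
  expect_equal(p$date[1], as.Date("2019-02-12"))
  expect_equal(p$date[3], as.Date("2019-02-01"))
  expect_equal(p$date[5], as.Date("2019-01-01"))
  # empty tokens are missing but not unparseable; garbage ones are counted
  expect_equal(attr(p, "n_unparseable"), 4L)
})

test_that("write/read round-trips a seeded random quarter field-for-field", {
  g <- generateDatabase(synthConfig(nReports = 150, seed = 11))
  dir <- withr::local_tempdir()
  writeQuarter(g$quarter, dir)
  back <- suppressWarnings(readQuarter(dir))
  for (tab in c("demo", "drug", "reac", "outc", "ther", "indi"))
    expect_equal(quarterTable(back, tab), quarterTable(g$quarter, tab),
                 ignore_attr = TRUE)
})

test_that("writes are byte-deterministic", {
  g <- generateDatabase(synthConfig(nReports = 80, seed = 3))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeQuarter(g$quarter, d1)
  writeQuarter(g$quarter, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("an empty quarter writes six header-only files", {
  q <- makeQuarter()
  dir <- withr::local_tempdir()
  writeQuarter(q, dir)
  files <- list.files(dir)
  expect_setequal(files, c("DEMO.txt", "DRUG.txt", "REAC.txt",
                           "OUTC.txt", "THER.txt", "INDI.txt"))
  for (f in files) expect_length(readLines(file.path(dir, f)), 1L)
  expect_equal(nReports(readQuarter(dir)), 0L)
})

test_that("orphan child rows are dropped and counted, never kept", {
  q <- makeQuarter(demo = demoRow("1"), drug = drugRow("1"),
                   reac = reacRow("1", "Nausea"))
  dir <- withr::local_tempdir()
  writeQuarter(q, dir)
  # a drug row whose primaryid is absent from DEMO
  cat("999$1$PS$Nivolumab$\n", file = file.path(dir, "DRUG.txt"),
      append = TRUE)
  back <- readQuarter(dir)
  expect_equal(nrow(quarterTable(back, "drug")), 1L)
  expect_equal(back@log$orphan_rows, 1L)
})

test_that("a missing mandatory file errors naming the file", {
  g <- generateDatabase(synthConfig(nReports = 10, seed = 5))
  dir <- withr::local_tempdir()
  writeQuarter(g$quarter, dir)
  unlink(file.path(dir, "OUTC.txt"))
  expect_error(readQuarter(dir), "OUTC.txt")
})

test_that("unknown columns are ignored with a warning", {
  q <- makeQuarter(demo = demoRow("1"), reac = reacRow("1", "Nausea"))
  dir <- withr::local_tempdir()
  writeQuarter(q, dir)
  demo_lines <- readLines(file.path(dir, "DEMO.txt"))
  writeLines(paste0(demo_lines, c("$mystery", "$42")),
             file.path(dir, "DEMO.txt"))
  expect_warning(back <- readQuarter(dir), "mystery")
  expect_equal(nReports(back), 1L)
  expect_false("mystery" %in% names(quarterTable(back, "demo")))
})

test_that("ages convert to years by unit, with plausibility bounds", {
  expect_equal(ageToYears("730", "DY"), 2.0, ignore_attr = TRUE)
  expect_equal(ageToYears("63", "YR"), 63, ignore_attr = TRUE)
  expect_equal(ageToYears("6", "DEC"), 60, ignore_attr = TRUE)
  expect_equal(ageToYears("24", "MON"), 2, ignore_attr = TRUE)
  expect_true(is.na(ageToYears("63", "XX")))
  expect_true(is.na(ageToYears("63", "")))
  y <- ageToYears(c("150", "-2"), c("YR", "YR"))
  expect_true(all(is.na(y)))
  expect_equal(attr(y, "n_implausible"), 2L)
})

test_that("region mapping is total: known codes map, anything else is NA", {
  expect_equal(countryToRegion(c("JP", "US", "FR", "AU", "ZA")),
               c("Asia", "America", "Europe", "Oceania", "Africa"))
  expect_true(all(is.na(countryToRegion(c("", "XX", "ZZ")))))
})

test_that("assembly joins child rows, converts fields, keeps every report", {
  q <- makeQuarter(
    demo = rbind(demoRow("1", age = "730", age_cod = "DY", country = "JP",
                         occp = "CN"),
                 demoRow("2", age = "", age_cod = "", country = "",
                         occp = "", sex = "")),
    drug = rbind(drugRow("1", name = "OPDIVO"), drugRow("2", name = "aspirin")),
    reac = rbind(reacRow("1", "Pericardial  Effusion"), reacRow("2", "Nausea")),
    outc = rbind(outcRow("1", "HO"), outcRow("1", "DE")),
    ther = therRow("1", start = "20190101"))
  rs <- assembleReports(q)
  r <- reports(rs)
  expect_equal(nrow(r), 2L)
  expect_equal(r$age_years[1], 2.0)
  expect_equal(r$region, c("Asia", NA))
  expect_equal(r$reporter, c("non-health-professional", NA))
  expect_true(is.na(r$sex[2]))
  # reactions are lower-cased and whitespace-normalised
  expect_true("pericardial effusion" %in% rs@reactions$pt)
  # both outcome codes are retained; the death flag is resolved later
  expect_setequal(rs@outcomes$code[rs@outcomes$primary_id == "1"],
                  c("HO", "DE"))
  expect_equal(rs@drugs$ici[rs@drugs$primary_id == "1"], "nivolumab")
  expect_equal(rs@drugs$start_prec[rs@drugs$primary_id == "1"], "day")
  expect_equal(rs@log$reports_in, rs@log$reports_out)
})

test_that("year-precision event dates feed report_year but not day math", {
  q <- makeQuarter(
    demo = demoRow("1", event = "2019", fda = "20200301", yr = ""),
    drug = drugRow("1"),
    reac = reacRow("1", "Pericarditis"),
    ther = therRow("1", start = "20190101"))
  rs <- assembleReports(q)
  expect_equal(reports(rs)$event_prec, "year")
  expect_equal(reports(rs)$report_year, 2020L)  # falls back to receipt year
  expect_true(is.na(computeTto(rs)$tto_days))
})
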