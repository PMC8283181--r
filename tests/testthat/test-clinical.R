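# Clinical feature analyses: fatality rates, TTO summaries, group tests,
# the characteristics table.

test_that("fatality rates use the full stratum as denominator", {
  fx <- buildTable2Fixture()
  fr <- fatalityRate(fx, "region")
  asia <- fr[fr$stratum == "Asia", ]
  expect_equal(asia$fatal, 45L)
  expect_equal(asia$total, 201L)
  expect_equal(asia$pct, 22.39)
  # zero-fatality strata report 0.00, empty strata are omitted
  expect_false("Africa" %in% fr$stratum)
  fs <- fatalityRate(fx, "strategy")
  expect_equal(fs$pct[fs$stratum == "anti-CTLA-4 mono"], 31.82)
})

test_that("TTO summaries use linear-interpolation quartiles per group", {
  coh <- generateTtoCohort(3, fatalProb = 0)
  rec <- records(coh)
  rec$tto_days <- c(10L, 20L, 30L)
  rec$tto_bin <- binTto(rec$tto_days)
  coh2 <- perivig:::newCaseCohort(rec, provenance(coh))
  s <- summarizeTto(coh2, "all")
  expect_equal(s$median, 20)
  expect_equal(s$q1, 15); expect_equal(s$q3, 25)
  expect_equal(s$n, 3L)
  # all-missing groups are omitted
  rec$tto_days[] <- NA_integer_; rec$tto_bin[] <- NA_character_
  s0 <- summarizeTto(perivig:::newCaseCohort(rec, list()), "all")
  expect_equal(nrow(s0), 0L)
})

test_that("generated log-normal TTO medians land near the distribution median", {
  coh <- generateTtoCohort(400, meanlogNonfatal = 3.6, meanlogFatal = 3.6,
                           sdlog = 1.0, fatalProb = 0.17, seed = 5)
  s <- summarizeTto(coh, "all")
  expect_equal(s$n, 400L)
  expect_lt(abs(s$median - exp(3.6)) / exp(3.6), 0.15)
})

test_that("identical TTO samples give a Mann-Whitney p near 1", {
  coh <- generateTtoCohort(200, fatalProb = 0.5, seed = 9)
  rec <- records(coh)
  v <- rep(c(10L, 20L, 30L, 40L), 50)
  rec$tto_days <- v; rec$tto_bin <- binTto(v)
  res <- compareFatalNonfatal(perivig:::newCaseCohort(rec, list()),
                              "tto_days")
  expect_equal(res$test, "Mann-Whitney")
  expect_gt(res$p_value, 0.5)
})

test_that("group tests agree with hand-computed statistics on random inputs", {
  set.seed(41)
  for (i in 1:50) {
    nx <- sample(5:40, 1); ny <- sample(5:40, 1)
    x <- round(rlnorm(nx, 3.5, 1)); y <- round(rlnorm(ny, 3.7, 1))
    got <- suppressWarnings(stats::wilcox.test(x, y))$statistic
    expect_equal(unname(got), oracleMannWhitneyU(x, y), tolerance = 1e-8)
  }
  for (i in 1:50) {
    m <- matrix(sample(5:60, 6, TRUE), 2, 3)
    got <- suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic
    expect_equal(unname(got), oracleChisqStat(m), tolerance = 1e-8)
  }
})

test_that("fatal vs non-fatal comparisons pick the documented test", {
  fx <- buildTable2Fixture()
  reg <- compareFatalNonfatal(fx, "region")
  expect_equal(reg$test, "chi-square")
  expect_lt(reg$p_value, 0.05)
  tto <- compareFatalNonfatal(fx, "tto_days")
  expect_equal(tto$test, "Mann-Whitney")
  expect_lt(tto$p_value, 0.05)
  # unknown-outcome reports and unknown categories are excluded
  expect_gt(reg$n_excluded, 0)
})

test_that("degenerate tables are flagged untestable, not errors", {
  coh <- generateTtoCohort(50, fatalProb = 0, seed = 2)  # no fatal group
  res <- compareFatalNonfatal(coh, "regimen")
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
})

test_that("Kruskal-Wallis runs across regimens, Mann-Whitney for two", {
  coh <- generateTtoCohort(300, fatalProb = 0.2, seed = 8,
                           regimenWeights = c(nivolumab = .4,
                                              pembrolizumab = .3,
                                              ipilimumab = .3))
  res <- compareTtoAcrossGroups(coh, "regimen")
  expect_equal(res$test, "Kruskal-Wallis")
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  two <- generateTtoCohort(100, fatalProb = 0.2, seed = 8,
                           regimenWeights = c(nivolumab = .5,
                                              ipilimumab = .5))
  expect_equal(compareTtoAcrossGroups(two, "regimen")$test, "Mann-Whitney")
})

test_that("the characteristics table is internally consistent", {
  fx <- buildTable2Fixture()
  ch <- buildCharacteristicsTable(fx)
  tab <- ch$table
  # every block's total column sums to the cohort size
  for (blk in unique(tab$block))
    expect_equal(sum(tab$total_n[tab$block == blk]), 705L)
  # fatal + non-fatal + unknown-outcome equal the total in every block
  for (blk in unique(tab$block)) {
    sub <- tab[tab$block == blk, ]
    expect_equal(sum(sub$fatal_n) + sum(sub$nonfatal_n), 703L)
  }
  # percentages are recoverable: n / denominator * 100
  expect_equal(tab$total_pct, tab$total_n / 705 * 100)
  expect_equal(tab$fatal_pct, tab$fatal_n / 123 * 100)
  expect_equal(tab$nonfatal_pct, tab$nonfatal_n / 580 * 100)
})

test_that("an empty cohort yields zero counts without division errors", {
  coh <- generateTtoCohort(0)
  ch <- buildCharacteristicsTable(coh)
  expect_true(all(ch$table$total_n == 0))
  expect_true(all(is.finite(ch$table$total_pct)))
  expect_equal(nrow(summarizeTto(coh, "all")), 0L)
})

test_that("rendering shows NS for non-significant blocks", {
  fx <- buildTable2Fixture()
  lines <- renderCharacteristicsTable(buildCharacteristicsTable(fx))
  expect_true(any(grepl("^gender NS", lines)))
  expect_true(any(grepl("^region p=0", lines)))
})
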