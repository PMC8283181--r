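# Independent closed-form oracles, written as direct arithmetic over the
# formulas (different algebraic routes from the implementation) so that
# agreement is a genuine cross-check.

oracleRor <- function(a, b, c, d, z = 1.959964) {
  if (min(a, b, c, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  est <- (a / c) / (b / d)
  se <- sqrt(sum(1 / c(a, b, c, d)))
  c(ror = est, lo = est * exp(-z * se), hi = est * exp(z * se))
}

oracleIc <- function(nobs, nexp) {
  ic <- (log(nobs + 0.5) - log(nexp + 0.5)) / log(2)
  c(ic = ic,
    ic025 = ic - 3.3 / sqrt(nobs + 0.5) - 2 / sqrt(nobs + 0.5)^3)
}

# Mann-Whitney U computed from rank sums (the convention wilcox.test
# reports as W for the first sample)
oracleMannWhitneyU <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

# Pearson chi-square statistic from first principles
oracleChisqStat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# random 2x2 tables with all-positive cells
randomTables <- function(n, seed) {
  set.seed(seed)
  data.frame(a = sample(1:500, n, TRUE), b = sample(1:5000, n, TRUE),
             c = sample(1:5000, n, TRUE), d = sample(1:100000, n, TRUE))
}
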