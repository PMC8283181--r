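# Date tokens, age conversion, bins and small shared helpers.

#' Parse FAERS date tokens
#'
#' FAERS dates are 8-digit (YYYYMMDD), 6-digit (YYYYMM) or 4-digit (YYYY)
#' tokens.  Each token parses to a calendar date anchored at the first
#' day of its period, together with its precision; anything else
#' (including the empty token) is missing.  Day-level arithmetic must
#' only use day-precision dates.
#'
#' @param x character vector of raw tokens
#' @return data frame with columns \code{date} (Date) and
#'   \code{precision} ("day", "month", "year" or NA); attribute
#'   \code{n_unparseable} counts non-empty tokens that failed to parse
#' @examples
#' parseFaersDate(c("20190212", "201902", "2019", "", "garbage"))
#' @export
parseFaersDate <- function(x) {
  x <- trimws(as.character(x))
  n <- length(x)
  date <- rep(as.Date(NA), n)
  prec <- rep(NA_character_, n)

  i8 <- grepl("^[0-9]{8}$", x)
  if (any(i8)) {
    d <- as.Date(x[i8], format = "%Y%m%d")
    date[i8] <- d
    prec[i8][!is.na(d)] <- "day"
  }
  i6 <- grepl("^[0-9]{6}$", x)
  if (any(i6)) {
    d <- as.Date(paste0(x[i6], "01"), format = "%Y%m%d")
    date[i6] <- d
    prec[i6][!is.na(d)] <- "month"
  }
  i4 <- grepl("^[0-9]{4}$", x)
  if (any(i4)) {
    yr <- as.integer(x[i4])
    ok <- yr >= 1900 & yr <= 2100
    d <- as.Date(ifelse(ok, paste0(x[i4], "-01-01"), NA))
    date[i4] <- d
    prec[i4][!is.na(d)] <- "year"
  }
  out <- data.frame(date = date, precision = prec,
                    stringsAsFactors = FALSE)
  attr(out, "n_unparseable") <- sum(nzchar(x) & is.na(prec))
  out
}

# days per year deliberately 365 so whole-year ages expressed in days
# convert exactly (730 DY -> 2)
AGE_UNIT_FACTORS <- c(YR = 1, YEAR = 1, DEC = 10, MON = 1 / 12,
                      WK = 7 / 365, DY = 1 / 365, HR = 1 / (24 * 365))

#' Convert stated age values to years
#'
#' Units YR/DEC/MON/WK/DY/HR are converted arithmetically (decades are
#' ten years); unknown or absent units give missing.  Implausible results
#' (negative or above 120 years) are set to missing.
#'
#' @param value numeric or character age values
#' @param unit character unit codes
#' @return numeric years; attribute \code{n_implausible} counts values
#'   dropped by the plausibility rule
#' @examples
#' ageToYears(c("730", "63"), c("DY", "YR"))
#' @export
ageToYears <- function(value, unit) {
  v <- suppressWarnings(as.numeric(value))
  f <- AGE_UNIT_FACTORS[toupper(trimws(unit))]
  yrs <- v * unname(f)
  implausible <- !is.na(yrs) & (yrs < 0 | yrs > 120)
  yrs[implausible] <- NA_real_
  attr(yrs, "n_implausible") <- sum(implausible)
  yrs
}

#' Map ISO-3166 alpha-2 country codes to reporting regions
#'
#' North and South America are pooled into one "America" region, matching
#' the five-region reporting scheme (Europe/America/Asia/Oceania/Africa).
#' Unmapped or empty codes give missing, never an error.
#'
#' @param code character country codes
#' @return character region names or NA
#' @examples
#' countryToRegion(c("JP", "US", "FR", ""))
#' @export
countryToRegion <- function(code) {
  tab <- extdataTable("country_regions.tsv")
  map <- stats::setNames(tab$region, tab$country)
  unname(map[toupper(trimws(code))])
}

TTO_BIN_LEVELS <- c("0-30", "31-60", "61-90", "91-180", ">180")

#' Bin time-to-onset values
#'
#' Bins are the reporting scheme 0-30, 31-60, 61-90, 91-180 and >180
#' days, closed on both printed endpoints; missing stays missing.
#'
#' @param days integer days
#' @return character bin labels
#' @export
binTto <- function(days) {
  out <- rep(NA_character_, length(days))
  ok <- !is.na(days)
  d <- days[ok]
  out[ok] <- ifelse(d <= 30, "0-30",
             ifelse(d <= 60, "31-60",
             ifelse(d <= 90, "61-90",
             ifelse(d <= 180, "91-180", ">180"))))
  out
}

AGE_GROUP_LEVELS <- c("<18", "18-64", "65-84", ">=85")

ageGroup <- function(age_years) {
  out <- rep(NA_character_, length(age_years))
  ok <- !is.na(age_years)
  a <- age_years[ok]
  out[ok] <- ifelse(a < 18, "<18",
             ifelse(a < 65, "18-64",
             ifelse(a < 85, "65-84", ">=85")))
  out
}

# weighted category sampler used by the synthetic generator; "missing"
# weight names become NA values
sampleCategories <- function(n, weights) {
  vals <- names(weights)
  out <- sample(vals, n, replace = TRUE, prob = weights)
  out[out == "missing"] <- NA_character_
  out
}

fmtDate <- function(date, precision) {
  out <- character(length(date))
  day <- !is.na(precision) & precision == "day"
  mon <- !is.na(precision) & precision == "month"
  yr <- !is.na(precision) & precision == "year"
  out[day] <- format(date[day], "%Y%m%d")
  out[mon] <- format(date[mon], "%Y%m")
  out[yr] <- format(date[yr], "%Y")
  out
}
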