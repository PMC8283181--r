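# Case-definition assets: the pericardial preferred-term list and the
# ICI drug dictionary, both shipped as editable plain-text tables.

#' The pericardial-disorder preferred-term case definition
#'
#' The 15 MedDRA preferred terms (with 8-digit codes) treated as
#' pericardial disorders, from autoimmune pericarditis through
#' pericardial drainage.  Shipped as a plain-text asset so the case
#' definition can be inspected or extended.
#'
#' @return data frame with columns \code{pt} (lower-cased name) and
#'   \code{code}
#' @examples
#' nrow(pericardialTerms())
#' @export
pericardialTerms <- function() {
  tab <- extdataTable("pericardial_pts.tsv")
  stopifnot(nrow(tab) == 15, !anyDuplicated(tab$pt), !anyDuplicated(tab$code))
  tab
}

#' The ICI drug dictionary
#'
#' Generic and brand names of the eight FDA-approved immune checkpoint
#' inhibitors with their target class (PD-1, PD-L1 or CTLA-4).
#'
#' @return data frame with columns \code{generic}, \code{brands}
#'   (semicolon-separated, possibly empty) and \code{target}
#' @export
iciDictionary <- function() {
  tab <- extdataTable("ici_drugs.tsv")
  stopifnot(nrow(tab) == 8, all(tab$target %in% c("PD-1", "PD-L1", "CTLA-4")))
  tab
}

# name -> canonical generic lookup, cached
iciNameLookup <- function() {
  if (!is.null(.perivigCache$ici_lookup)) return(.perivigCache$ici_lookup)
  dict <- iciDictionary()
  keys <- toupper(dict$generic)
  vals <- dict$generic
  for (i in seq_len(nrow(dict))) {
    brands <- strsplit(dict$brands[i], ";", fixed = TRUE)[[1]]
    brands <- trimws(brands[nzchar(trimws(brands))])
    if (length(brands)) {
      keys <- c(keys, toupper(brands))
      vals <- c(vals, rep(dict$generic[i], length(brands)))
    }
  }
  lk <- stats::setNames(vals, keys)
  .perivigCache$ici_lookup <- lk
  lk
}

#' Test preferred terms against the pericardial case definition
#'
#' A term matches if its lower-cased, whitespace-normalised name, or its
#' 8-digit MedDRA code, is in the shipped 15-term list.
#'
#' @param pt character vector of preferred-term names or 8-digit codes
#' @return logical vector
#' @examples
#' isPericardialPT(c("Cardiac tamponade", "myocarditis", "10034487"))
#' @export
isPericardialPT <- function(pt) {
  tab <- pericardialTerms()
  x <- tolower(gsub("\\s+", " ", trimws(as.character(pt))))
  x %in% tab$pt | x %in% tab$code
}

# tokens stripped from verbatim drug strings before dictionary matching
DOSE_TOKEN_RE <- paste0(
  "^[0-9.,]+$|^[0-9.,]+(MG|ML|MCG|G|MGML)$|",
  "^(MG|ML|MCG|MGML|SOLUTION|INJECTION|CONCENTRATE|INFUSION|",
  "INTRAVENOUS|IV|VIAL|FOR)$")

#' Map verbatim drug names to canonical ICI generics
#'
#' Strips parenthetical suffixes, punctuation and dose text from the raw
#' string and matches the remainder case-insensitively against the
#' generic and brand names of the ICI dictionary.
#'
#' @param raw character vector of verbatim drug names
#' @return canonical generic names (lower case) or NA where the string is
#'   not a recognised ICI
#' @examples
#' normalizeDrugName(c("OPDIVO", "Nivolumab (10 mg/mL)", "aspirin"))
#' @export
normalizeDrugName <- function(raw) {
  x <- toupper(as.character(raw))
  x <- gsub("\\([^)]*\\)", " ", x)          # parenthetical suffixes
  x <- gsub("[^A-Z0-9]+", " ", x)            # punctuation -> spaces
  x <- trimws(gsub("\\s+", " ", x))
  lk <- iciNameLookup()
  out <- unname(lk[x])
  todo <- which(is.na(out) & nzchar(x) & grepl(" |[0-9]", x))
  if (length(todo)) {
    cleaned <- vapply(strsplit(x[todo], " ", fixed = TRUE), function(tok) {
      tok <- tok[!grepl(DOSE_TOKEN_RE, tok)]
      paste(tok, collapse = " ")
    }, character(1))
    out[todo] <- unname(lk[cleaned])
  }
  out
}

#' Map indication terms to indication groups
#'
#' Keyword mapping from free-text indication preferred terms onto the
#' twelve reporting groups used in the characteristics table (melanoma,
#' lung cancer, ..., other indications, unknown or missing).  The
#' keyword table is a shipped plain-text asset.
#'
#' @param terms character vector of indication terms (any case)
#' @return group label per term; unmatched non-empty terms give
#'   "other indications", empty terms "unknown or missing"
#' @export
mapIndication <- function(terms) {
  tab <- extdataTable("indication_groups.tsv")
  x <- tolower(trimws(as.character(terms)))
  out <- ifelse(nzchar(x), "other indications", "unknown or missing")
  # later rows never override earlier (more specific) ones
  for (i in rev(seq_len(nrow(tab)))) {
    hit <- nzchar(x) & grepl(tab$pattern[i], x)
    out[hit] <- tab$group[i]
  }
  out
}

INDICATION_PRIORITY <- c("melanoma", "lung cancer", "mesothelioma",
  "hematological cancer and lymphoma", "gastrointestinal cancer",
  "head and neck cancer", "breast cancer",
  "tumors of female reproductive organs", "tumors of urinary system",
  "non-specified malignant neoplasm", "other indications",
  "unknown or missing")

# one indication group per report: most specific group among its terms
reportIndicationGroup <- function(groups) {
  if (!length(groups)) return("unknown or missing")
  ord <- match(groups, INDICATION_PRIORITY)
  INDICATION_PRIORITY[min(ord, na.rm = TRUE)]
}
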