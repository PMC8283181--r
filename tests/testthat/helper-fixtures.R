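# Hand-built miniature quarters used across the unit tests.  Everything
# is constructed in code; no binary fixtures.

emptyTab <- function(tab) {
  cols <- perivig:::QUARTER_COLUMNS[[tab]]
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

makeQuarter <- function(demo = NULL, drug = NULL, reac = NULL,
                        outc = NULL, ther = NULL, indi = NULL) {
  fill <- function(df, tab) {
    if (is.null(df)) return(emptyTab(tab))
    cols <- perivig:::QUARTER_COLUMNS[[tab]]
    for (col in setdiff(cols, names(df))) df[[col]] <- ""
    df[, cols]
  }
  new("FAERSQuarter",
      demo = fill(demo, "demo"), drug = fill(drug, "drug"),
      reac = fill(reac, "reac"), outc = fill(outc, "outc"),
      ther = fill(ther, "ther"), indi = fill(indi, "indi"),
      log = list())
}

demoRow <- function(pid, case = pid, version = "1", fda = "20190601",
                    event = "20190201", age = "63", age_cod = "YR",
                    sex = "M", occp = "MD", country = "US", yr = "2019") {
  data.frame(primaryid = pid, caseid = case, caseversion = version,
             fda_dt = fda, event_dt = event, age = age, age_cod = age_cod,
             sex = sex, occp_cod = occp, occr_country = country,
             rept_yr = yr, stringsAsFactors = FALSE)
}

drugRow <- function(pid, seq = "1", role = "PS", name = "Nivolumab",
                    ai = "") {
  data.frame(primaryid = pid, drug_seq = seq, role_cod = role,
             drugname = name, prod_ai = ai, stringsAsFactors = FALSE)
}

reacRow <- function(pid, pt) {
  data.frame(primaryid = pid, pt = pt, pt_cod = "",
             stringsAsFactors = FALSE)
}

outcRow <- function(pid, code) {
  data.frame(primaryid = pid, outc_cod = code, stringsAsFactors = FALSE)
}

therRow <- function(pid, seq = "1", start = "20190101", end = "") {
  data.frame(primaryid = pid, dsg_drug_seq = seq, start_dt = start,
             end_dt = end, stringsAsFactors = FALSE)
}

indiRow <- function(pid, seq = "1", term = "Malignant melanoma") {
  data.frame(primaryid = pid, indi_drug_seq = seq, indi_pt = term,
             stringsAsFactors = FALSE)
}

# ten-report quarter realising the (2, 3, 1, 4) contingency layout:
# 2 suspect-ICI reports with a pericardial PT, 3 suspect-ICI without,
# 1 pericardial without ICI, 4 with neither
contingencyQuarter <- function() {
  pids <- as.character(101:110)
  demo <- do.call(rbind, lapply(pids, demoRow))
  drug <- rbind(
    drugRow("101"), drugRow("102", name = "OPDIVO"),
    drugRow("103"), drugRow("104", name = "Keytruda"),
    drugRow("105", name = "Ipilimumab"),
    drugRow("106", name = "aspirin"), drugRow("107", name = "aspirin"),
    drugRow("108", name = "metformin"), drugRow("109", name = "aspirin"),
    drugRow("110", name = "nivolumab", role = "C"))
  reac <- rbind(
    reacRow("101", "Pericardial effusion"),
    reacRow("102", "Cardiac tamponade"),
    reacRow("103", "Nausea"), reacRow("104", "Rash"),
    reacRow("105", "Fatigue"),
    reacRow("106", "Pericarditis"),
    reacRow("107", "Nausea"), reacRow("108", "Headache"),
    reacRow("109", "Rash"), reacRow("110", "Dizziness"))
  makeQuarter(demo = demo, drug = drug, reac = reac)
}

assembleQuarter <- function(q) assembleReports(q)
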