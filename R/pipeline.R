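# Run configuration, the end-to-end analysis pipeline and report
# bundling.  A thin command-line wrapper over these functions ships in
# inst/scripts/perivig-cli.R.

#' Build and validate a run configuration
#'
#' A run has exactly one input source: FAERS-style files
#' (\code{input = list(type = "files", path = ...)}), the synthetic
#' generator (\code{type = "generator"}, with \code{synth} holding
#' [synthConfig()] arguments), or the deterministic fixture cohort
#' (\code{type = "fixture"}).
#'
#' @param x named list, or path to a YAML file holding one
#' @return validated run configuration (class \code{RunConfig})
#' @export
runConfig <- function(x) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) configError(paste("no such config file:", x))
    x <- yaml::read_yaml(x)
  }
  if (!is.list(x)) configError("config must be a list or a YAML file path")
  defaults <- list(designs = "default", outputDir = "perivig-out",
                   seed = 1L, verbose = FALSE)
  cfg <- utils::modifyList(defaults, x)
  if (is.null(cfg$input) || is.null(cfg$input$type))
    configError("missing config field: input$type")
  cfg$input$type <- match.arg(cfg$input$type,
                              c("files", "generator", "fixture"))
  if (cfg$input$type == "files" && is.null(cfg$input$path))
    configError("missing config field: input$path")
  if (cfg$input$type == "generator" && is.null(cfg$input$synth$nReports))
    configError("missing config field: input$synth$nReports")
  class(cfg) <- "RunConfig"
  cfg
}

configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Generate a synthetic database to disk
#'
#' Wraps [generateDatabase()]: writes the six quarter files plus the
#' ground-truth ledger into the configured output directory.
#'
#' @param config a \code{RunConfig} (or list/path accepted by
#'   [runConfig()]) with \code{input$type == "generator"}
#' @return output directory, invisibly
#' @export
runGenerate <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else runConfig(config)
  if (cfg$input$type != "generator")
    configError("runGenerate requires input$type 'generator'")
  args <- cfg$input$synth
  args$seed <- if (!is.null(args$seed)) args$seed else cfg$seed
  scfg <- do.call(synthConfig, args)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  generateDatabase(scfg, dir = cfg$outputDir)
  invisible(cfg$outputDir)
}

resolveReportSet <- function(cfg) {
  switch(cfg$input$type,
    files = assembleReports(readQuarter(cfg$input$path)),
    generator = {
      args <- cfg$input$synth
      args$seed <- if (!is.null(args$seed)) args$seed else cfg$seed
      assembleReports(generateDatabase(do.call(synthConfig, args))$quarter)
    },
    fixture = NULL)
}

#' Run the full analysis pipeline and write the report bundle
#'
#' read -> deduplicate -> case cohort -> signal table -> characteristics
#' table -> TTO summaries.  Writes a CSV/JSON bundle (cohort, signal
#' table, characteristics, TTO summaries, summary JSON) plus a provenance
#' log with the in/out counts of every filter step, the seed and a config
#' hash.  An empty cohort yields a bundle of empty tables with a
#' prominent warning, not an error.
#'
#' @param config a \code{RunConfig} (or list/path accepted by
#'   [runConfig()])
#' @return named list of result objects (invisibly): \code{cohort},
#'   \code{signal_table}, \code{characteristics}, \code{tto_summary},
#'   \code{paths}
#' @export
runAnalyze <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else runConfig(config)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  out <- list()
  prov_lines <- c(sprintf("seed: %s", cfg$seed),
                  sprintf("config_hash: %s", configHash(cfg)),
                  sprintf("input: %s", cfg$input$type))

  if (cfg$input$type == "fixture") {
    cohort <- buildTable2Fixture()
    signal <- NULL
  } else {
    rs <- resolveReportSet(cfg)
    n0 <- nReports(rs)
    rs <- deduplicateReports(rs)
    cohort <- buildCohort(rs)
    signal <- if (identical(cfg$designs, "default"))
      runSignalTable(rs) else runSignalTable(rs, cfg$designs)
    prov_lines <- c(prov_lines,
                    sprintf("reports assembled: %d", n0),
                    sprintf("reports after deduplication: %d", nReports(rs)))
  }
  steps <- provenance(cohort)$steps
  prov_lines <- c(prov_lines,
                  sprintf("%s: %d", steps$step, steps$n))

  if (nReports(cohort) == 0)
    warning("empty case cohort: the bundle contains empty tables")

  chars <- buildCharacteristicsTable(cohort)
  tto_reg <- summarizeTto(cohort, "regimen")
  tto_fatal <- summarizeTto(cohort, "outcome_status")

  paths <- list()
  paths$cohort <- file.path(cfg$outputDir, "cohort.csv")
  writeCohortCsv(cohort, paths$cohort)
  if (!is.null(signal)) {
    paths$signal <- file.path(cfg$outputDir, "signal_table.csv")
    utils::write.csv(signal, paths$signal, row.names = FALSE, na = "")
  }
  paths$characteristics <- file.path(cfg$outputDir, "characteristics.csv")
  utils::write.csv(chars$table, paths$characteristics, row.names = FALSE)
  paths$tto <- file.path(cfg$outputDir, "tto_summary.csv")
  tagGroup <- function(df, g)
    cbind(grouping = rep(g, nrow(df)), df)
  utils::write.csv(rbind(tagGroup(tto_reg, "regimen"),
                         tagGroup(tto_fatal, "outcome_status")),
                   paths$tto, row.names = FALSE)

  tests <- lapply(chars$tests, function(t)
    list(test = t$test, statistic = t$statistic, p_value = t$p_value,
         testable = t$testable))
  summary <- list(n_cases = nReports(cohort),
                  n_fatal = chars$n_fatal, n_nonfatal = chars$n_nonfatal,
                  tests = tests)
  paths$summary <- file.path(cfg$outputDir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths$provenance <- file.path(cfg$outputDir, "provenance.txt")
  writeLines(prov_lines, paths$provenance)
  paths$rendering <- file.path(cfg$outputDir, "characteristics.txt")
  writeLines(renderCharacteristicsTable(chars), paths$rendering)

  invisible(list(cohort = cohort, signal_table = signal,
                 characteristics = chars,
                 tto_summary = list(regimen = tto_reg, fatal = tto_fatal),
                 paths = paths))
}
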