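#' Plan a submission
#'
#' Turns a validated configuration plus scenario into the dependency-ordered
#' list of steps the run will execute: sample registration, per-read-set
#' uploads, a virtual sample for a co-assembly, the assembly upload, then
#' per bin (and per MAG) a fresh virtual sample followed by the upload.
#' Levels covered by pre-existing accessions contribute no steps — their
#' accessions seed the ledger at execution time. The resulting plan is
#' topological by construction and checked before it is returned.
#'
#' @param scenario a [submission_scenario()].
#' @param config a [parse_config()] result.
#' @param report the [validate_config()] report for exactly this config and
#'   scenario; a report with ERRORs (or none at all) refuses to plan.
#' @return A tibble of class `submission_plan` with columns `step`, `kind`,
#'   `alias` (the alias the step produces an accession for), `payload`
#'   (list-column of step inputs) and `deps` (list-column of aliases or
#'   accessions the step needs resolved beforehand).
#' @export
plan_submission <- function(scenario, config, report) {
  if (missing(report) || !inherits(report, "validation_report")) {
    stop_magbroker("precondition",
      "plan_submission needs the validation report for this config")
  }
  if (report_has_errors(report)) {
    stop_magbroker("precondition",
      sprintf("configuration has %d validation ERROR(s); fix them before planning",
              sum(report$severity == "ERROR")))
  }
  has <- function(lv) scenario_has(scenario, lv)
  for (lv in scenario$levels) {
    n <- switch(lv, SAMPLES = nrow(config$samples), READS = nrow(config$read_sets),
                ASSEMBLY = if (is.null(config$assembly)) 0L else 1L,
                BINS = nrow(config$bins), MAGS = nrow(config$mags))
    if (n == 0) {
      stop_magbroker("precondition",
        sprintf("level %s requested but the configuration declares no records for it", lv))
    }
  }

  steps <- list()
  push <- function(kind, alias, payload, deps = character()) {
    steps[[length(steps) + 1L]] <<- tibble::tibble(
      kind = kind, alias = alias, payload = list(payload), deps = list(deps))
  }
  origin_samples <- assembly_origin_refs(config)

  if (has("SAMPLES")) {
    push("REGISTER_SAMPLES", NA_character_,
         list(aliases = config$samples$alias))
  }
  if (has("READS")) {
    for (i in seq_len(nrow(config$read_sets))) {
      rs <- config$read_sets[i, ]
      push("UPLOAD_READS", rs$alias, list(index = i), deps = rs$sample)
    }
  }
  coassembly <- has("ASSEMBLY") && length(origin_samples) > 1
  vs_assembly <- NULL
  if (coassembly) {
    vs_assembly <- paste0("vs_", config$assembly$name[1])
    push("REGISTER_VIRTUAL_SAMPLE", vs_assembly,
         list(target = "assembly"), deps = origin_samples)
  }
  if (has("ASSEMBLY")) {
    anchor <- if (coassembly) vs_assembly else origin_samples[1]
    push("UPLOAD_ASSEMBLY", config$assembly$name[1], list(),
         deps = c(anchor, config$assembly$runs[[1]]))
  }
  if (has("BINS")) {
    for (i in seq_len(nrow(config$bins))) {
      b <- config$bins[i, ]
      vs <- paste0("vs_", b$bin_id)
      push("REGISTER_VIRTUAL_SAMPLE", vs,
           list(target = "bin", index = i), deps = origin_samples)
      push("UPLOAD_BIN", b$bin_id, list(index = i), deps = vs)
    }
  }
  if (has("MAGS")) {
    for (i in seq_len(nrow(config$mags))) {
      m <- config$mags[i, ]
      vs <- paste0("vs_", m$bin_id)
      push("REGISTER_VIRTUAL_SAMPLE", vs,
           list(target = "mag", index = i), deps = origin_samples)
      push("UPLOAD_MAG", m$bin_id, list(index = i), deps = vs)
    }
  }
  plan <- dplyr::bind_rows(steps)
  plan$step <- seq_len(nrow(plan))
  plan <- plan[, c("step", "kind", "alias", "payload", "deps")]
  plan <- structure(plan, scenario = scenario,
                    class = c("submission_plan", class(tibble::tibble())))
  if (!plan_is_topological(plan, preexisting_accessions(scenario, config))) {
    stop_magbroker("precondition", "constructed plan is not topologically valid")
  }
  plan
}

# samples the assembly (and hence its bins/MAGs) derives from: declared
# assembly sample refs, else the pre-existing sample accessions
assembly_origin_refs <- function(config) {
  if (!is.null(config$assembly)) {
    refs <- config$assembly$samples[[1]]
    if (length(refs) > 0) return(refs)
  }
  if (length(config$sample_accessions) > 0) return(config$sample_accessions)
  config$samples$alias
}

preexisting_accessions <- function(scenario, config) {
  unique(c(unlist(scenario$preexisting, use.names = FALSE),
           config$sample_accessions,
           config$bin_accessions,
           config$assembly_accession[!is.na(config$assembly_accession)]))
}

#' Check the topological validity of a plan
#'
#' Every dependency of every step must be an accession literal, a
#' pre-existing accession, a sample alias registered by an earlier
#' `REGISTER_SAMPLES` step, or the alias produced by an earlier step.
#'
#' @param plan a [plan_submission()] result.
#' @param preexisting character vector of pre-existing accessions.
#' @param patterns accession pattern table.
#' @return `TRUE` or `FALSE`.
#' @export
plan_is_topological <- function(plan, preexisting = character(),
                                patterns = accession_patterns()) {
  produced <- character()
  for (i in seq_len(nrow(plan))) {
    deps <- plan$deps[[i]]
    ok <- vapply(deps, function(d) {
      d %in% produced || d %in% preexisting || is_accession(d, patterns = patterns)
    }, logical(1))
    if (!all(ok)) return(FALSE)
    produced <- c(produced,
                  if (plan$kind[i] == "REGISTER_SAMPLES") plan$payload[[i]]$aliases
                  else plan$alias[i])
  }
  TRUE
}
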