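#' Submission levels
#' @keywords internal
#' @noRd
SUBMISSION_LEVELS <- c("SAMPLES", "READS", "ASSEMBLY", "BINS", "MAGS")

#' Describe a submission scenario
#'
#' A scenario is the set of data levels to submit in one run, plus any
#' accessions of objects that were already deposited in an earlier study
#' (the study-extension path: e.g. submit only bins against known sample and
#' assembly accessions). Dependency rules are enforced at construction time:
#' reads need samples (fresh or pre-existing), and bins/MAGs need an assembly
#' (fresh or pre-existing) together with quality/taxonomy metadata.
#'
#' @param levels character vector, subset of
#'   `c("SAMPLES", "READS", "ASSEMBLY", "BINS", "MAGS")` (case-insensitive).
#' @param preexisting named list mapping a level to the accessions already
#'   assigned for it, e.g. `list(SAMPLES = c("ERS0000001"), ASSEMBLY = "ERZ0000001")`.
#' @return An object of class `submission_scenario`.
#' @examples
#' submission_scenario(c("samples", "reads"))
#' submission_scenario("bins",
#'   preexisting = list(SAMPLES = "ERS0000001", ASSEMBLY = "ERZ0000001"))
#' @export
submission_scenario <- function(levels, preexisting = list()) {
  levels <- toupper(as.character(levels))
  bad <- setdiff(levels, SUBMISSION_LEVELS)
  if (length(bad) > 0) {
    stop_magbroker("scenario", sprintf("unknown submission level(s): %s",
                                       paste(bad, collapse = ", ")))
  }
  if (length(levels) == 0) {
    stop_magbroker("scenario", "a scenario needs at least one submission level")
  }
  names(preexisting) <- toupper(names(preexisting))
  has_pre <- function(lv) length(preexisting[[lv]]) > 0
  if (any(c("BINS", "MAGS") %in% levels) &&
      !("ASSEMBLY" %in% levels) && !has_pre("ASSEMBLY")) {
    stop_magbroker("scenario", paste(
      "bins/MAGs need an assembly: add the ASSEMBLY level or supply a",
      "pre-existing assembly accession"))
  }
  if ("READS" %in% levels && !("SAMPLES" %in% levels) && !has_pre("SAMPLES")) {
    stop_magbroker("scenario", paste(
      "reads need samples: add the SAMPLES level or supply pre-existing",
      "sample accessions"))
  }
  if ("MAGS" %in% levels && !("BINS" %in% levels) && !has_pre("BINS")) {
    # MAGs are promoted bins; their quality/taxonomy metadata travel with the
    # bin metadata sections of the configuration.
    stop_magbroker("scenario", paste(
      "MAGs require bin-style quality/taxonomy metadata: include the BINS",
      "level or supply pre-existing bin accessions"))
  }
  structure(
    list(levels = unique(levels[order(match(levels, SUBMISSION_LEVELS))]),
         preexisting = preexisting),
    class = "submission_scenario")
}

#' @export
print.submission_scenario <- function(x, ...) {
  cat("<submission_scenario>\n  levels:", paste(x$levels, collapse = ", "), "\n")
  for (lv in names(x$preexisting)) {
    cat("  pre-existing", lv, ":", paste(x$preexisting[[lv]], collapse = ", "), "\n")
  }
  invisible(x)
}

scenario_has <- function(scenario, level) level %in% scenario$levels
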