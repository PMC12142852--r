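#' Generate a scenario-specific configuration template
#'
#' Builds a pre-filled YAML configuration form containing exactly the
#' sections the requested submission levels need: every mandatory field is
#' present with an explanatory comment and an example value, optional fields
#' appear as commented hints, and levels covered by pre-existing accessions
#' are replaced by accession-entry fields (pre-filled with the accessions
#' given in the scenario). Sections for unrequested levels are absent.
#'
#' @param scenario a [submission_scenario()].
#' @return A single character string of YAML template text.
#' @examples
#' cat(make_template(submission_scenario(c("samples", "reads"))))
#' @export
make_template <- function(scenario) {
  stopifnot(inherits(scenario, "submission_scenario"))
  schema <- config_field_schema()
  out <- c(
    "# Submission configuration.",
    "# Fill in every uncommented field; the comment above each field states what",
    "# is required and shows an example value. Additional fields may be added to",
    "# any record at your discretion and are carried along as extra attributes.",
    "")
  for (sec in sections_for_scenario(scenario)) {
    sch <- schema[[sec]]
    out <- c(out, paste0("# ", sch$comment))
    if (isTRUE(sch$list_section)) {
      out <- c(out, paste0(sec, ":"), render_record(sch$fields, indent = 4L,
                                                    first_prefix = "  - "))
    } else if (sec == "aux") {
      # the aux paths are part of the standard form whenever inference can
      # apply; blank out entries that do not apply
      aux_fields <- lapply(sch$fields, function(f) { f$mandatory <- TRUE; f })
      out <- c(out, "aux:", render_fields(aux_fields, indent = 2L))
    } else if (sec == "assembly") {
      out <- c(out, "assembly:", render_fields(sch$fields, indent = 2L))
    } else {
      out <- c(out, render_fields(sch$fields, indent = 0L,
                                  overrides = template_overrides(sec, scenario)))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

# Pre-existing accessions from the scenario are written into the
# accession-entry sections so the "extend a deposited study" form arrives
# already filled.
template_overrides <- function(section, scenario) {
  switch(section,
    sample_accessions   = list(sample_accessions = scenario$preexisting$SAMPLES),
    assembly_accession  = list(assembly_accession = scenario$preexisting$ASSEMBLY),
    bin_accessions      = list(bin_accessions = scenario$preexisting$BINS),
    list()
  )
}

render_record <- function(fields, indent, first_prefix) {
  lines <- render_fields(fields, indent = indent)
  # turn the first real key line into the list-item opener
  pad <- strrep(" ", indent)
  first_key <- which(!startsWith(str_trim(lines), "#"))[1]
  lines[first_key] <- paste0(first_prefix, substring(lines[first_key], indent + 1L))
  lines
}

render_fields <- function(fields, indent, overrides = list()) {
  pad <- strrep(" ", indent)
  unlist(lapply(fields, function(f) {
    value <- overrides[[f$key]] %||% f$example
    comment <- paste0(pad, "# ", f$comment)
    if (!f$mandatory && is.null(overrides[[f$key]])) {
      hint <- if (is.null(f$example)) "" else yaml_value(f$example)
      return(c(comment, paste0(pad, "# ", f$key, ": ", hint)))
    }
    c(comment, paste0(pad, f$key, ": ", yaml_value(value)))
  }))
}

yaml_value <- function(x) {
  if (is.null(x)) return("~")
  if (length(x) > 1) {
    return(paste0("[", paste(vapply(x, yaml_scalar, character(1)), collapse = ", "), "]"))
  }
  yaml_scalar(x)
}

yaml_scalar <- function(x) {
  if (is.numeric(x)) return(format(x, scientific = FALSE))
  x <- as.character(x)
  if (grepl("^[A-Za-z0-9][A-Za-z0-9 ._/()-]*$", x)) x else
    paste0('"', gsub('"', '\\\\"', x), '"')
}
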