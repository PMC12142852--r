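#' Parse a filled configuration
#'
#' Reads the single-document YAML configuration form into a structured
#' `submission_config`: the study reference plus tibbles of sample, read-set,
#' bin and MAG records, the optional assembly record, any pre-existing
#' accessions, and the aux file paths. Keys not in the field schema are
#' preserved per record in an `attributes` list-column (users may freely add
#' metadata fields; they are submitted as extra attributes).
#'
#' @param text configuration YAML as a single string, or a path to the file
#'   (detected by existence on disk / absence of newlines).
#' @return An object of class `submission_config`.
#' @seealso [make_template()], [validate_config()]
#' @export
parse_config <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  src_dir <- "."
  if (!grepl("\n", text) && file.exists(text)) {
    src_dir <- dirname(text)
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(
    yaml::yaml.load(text),
    error = function(e) {
      stop_magbroker("parse", paste0("malformed configuration: ", conditionMessage(e)))
    })
  if (is.null(doc) || !is.list(doc) || length(doc) == 0) {
    stop_magbroker("parse", "configuration is empty")
  }

  schema <- config_field_schema()
  aux <- doc[["aux"]] # nb: [[ everywhere — $ would partial-match key names
  cfg <- list(
    study = scalar_or_na(doc[["study"]]),
    samples = records_tibble(doc[["samples"]], schema$samples$fields, "samples"),
    sample_accessions = as.character(unlist(doc[["sample_accessions"]] %||% character())),
    read_sets = records_tibble(doc[["read_sets"]], schema$read_sets$fields, "read_sets"),
    assembly = if (is.null(doc[["assembly"]])) NULL else
      records_tibble(list(doc[["assembly"]]), schema$assembly$fields, "assembly"),
    assembly_accession = scalar_or_na(doc[["assembly_accession"]]),
    bins = records_tibble(doc[["bins"]], schema$bins$fields, "bins"),
    bin_accessions = as.character(unlist(doc[["bin_accessions"]] %||% character())),
    mags = records_tibble(doc[["mags"]], schema$mags$fields, "mags"),
    aux = list(
      quality_table = scalar_or_na(aux[["quality_table"]]),
      taxonomy_table = scalar_or_na(aux[["taxonomy_table"]]),
      alignment = scalar_or_na(aux[["alignment"]])
    ),
    dir = src_dir
  )
  structure(cfg, class = "submission_config")
}

scalar_or_na <- function(x) if (is.null(x)) NA_character_ else as.character(x)

# Materialize a list of YAML mappings into one tibble following the field
# schema; unknown keys land in the attributes list-column. Field paths in
# errors use dotted section.index.field notation with 0-based indices.
records_tibble <- function(records, fields, section) {
  keys <- vapply(fields, `[[`, character(1), "key")
  mandatory <- keys[vapply(fields, `[[`, logical(1), "mandatory")]
  list_valued <- c("files", "md5", "samples", "runs")
  rows <- purrr::imap(records %||% list(), function(rec, i) {
    if (!is.list(rec)) {
      stop_magbroker("field",
        sprintf("%s.%d: expected a key/value record", section, i - 1L),
        locus = sprintf("%s.%d", section, i - 1L))
    }
    for (k in mandatory) {
      if (!k %in% names(rec)) {
        stop_magbroker("field",
          sprintf("%s.%d.%s: mandatory field missing", section, i - 1L, k),
          locus = sprintf("%s.%d.%s", section, i - 1L, k))
      }
    }
    known <- intersect(names(rec), keys)
    extra <- rec[setdiff(names(rec), keys)]
    vals <- lapply(stats::setNames(keys, keys), function(k) {
      v <- rec[[k]]
      if (k %in% list_valued) list(as.character(unlist(v %||% character())))
      else if (is.null(v)) NA
      else v
    })
    tibble::as_tibble(c(vals, list(attributes = list(extra))))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    cols <- c(lapply(stats::setNames(keys, keys), function(k)
      if (k %in% list_valued) list() else character()),
      list(attributes = list()))
    out <- tibble::as_tibble(cols)
  }
  # numeric coercions where the schema implies numbers
  for (k in intersect(c("taxid", "completeness", "contamination", "coverage"),
                      names(out))) {
    out[[k]] <- suppressWarnings(as.numeric(out[[k]]))
  }
  out
}

#' @export
print.submission_config <- function(x, ...) {
  cat("<submission_config>\n")
  cat("  study:", x$study, "\n")
  cat(sprintf("  samples: %d  read_sets: %d  assembly: %s  bins: %d  mags: %d\n",
              nrow(x$samples), nrow(x$read_sets),
              if (is.null(x$assembly)) "none" else x$assembly$name[1],
              nrow(x$bins), nrow(x$mags)))
  invisible(x)
}
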