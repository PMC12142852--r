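#' Validate a configuration against a scenario
#'
#' Runs every pre-submission check and returns them all at once as a
#' validation report; nothing is thrown. A report containing at least one
#' ERROR blocks submission (see [plan_submission()]); WARNINGs never block.
#' Checks cover mandatory values, alias uniqueness, cross-reference
#' resolution, paired-layout file counts, existence/readability/nonemptiness
#' of every referenced file, format signatures on the first record of each
#' sequence/alignment file, aux-table coverage of bins and MAGs, and the
#' MIMAG high-quality bar for MAG candidates (advisory WARNING only).
#'
#' The function is pure: it reads referenced local files but never mutates
#' the config and never touches the network.
#'
#' @param config a [parse_config()] result.
#' @param scenario the [submission_scenario()] being submitted.
#' @param patterns accession pattern table, see [accession_patterns()].
#' @return A tibble of class `validation_report` with columns `severity`
#'   (`"ERROR"`/`"WARNING"`), `locus` (dotted field path, 0-based indices)
#'   and `message`.
#' @export
validate_config <- function(config, scenario, patterns = accession_patterns()) {
  stopifnot(inherits(config, "submission_config"),
            inherits(scenario, "submission_scenario"))
  iss <- list()
  add <- function(severity, locus, message) {
    iss[[length(iss) + 1L]] <<- tibble::tibble(
      severity = severity, locus = locus, message = message)
  }
  has <- function(lv) scenario_has(scenario, lv)

  ## study reference
  if (is.na(config$study) || !nzchar(config$study)) {
    add("ERROR", "study", "study accession is mandatory")
  } else if (!is_accession(config$study, "STUDY", patterns)) {
    add("ERROR", "study", sprintf("'%s' does not look like a study accession",
                                  config$study))
  }

  ## level sections present
  if (has("SAMPLES") && nrow(config$samples) == 0)
    add("ERROR", "samples", "SAMPLES level requested but no sample records given")
  if (has("READS") && nrow(config$read_sets) == 0)
    add("ERROR", "read_sets", "READS level requested but no read-set records given")
  if (has("ASSEMBLY") && is.null(config$assembly))
    add("ERROR", "assembly", "ASSEMBLY level requested but no assembly record given")
  if (has("BINS") && nrow(config$bins) == 0)
    add("ERROR", "bins", "BINS level requested but no bin records given")
  if (has("MAGS") && nrow(config$mags) == 0)
    add("ERROR", "mags", "MAGS level requested but no MAG records given")

  ## alias uniqueness across the whole config
  aliases <- c(config$samples$alias, config$read_sets$alias,
               if (!is.null(config$assembly)) config$assembly$name,
               config$bins$bin_id, config$mags$bin_id)
  for (a in unique(aliases[duplicated(aliases)])) {
    add("ERROR", "aliases", sprintf("alias '%s' is declared more than once", a))
  }

  ## per-record mandatory values and cross-references
  known_samples <- c(config$samples$alias, config$sample_accessions)
  known_runs <- config$read_sets$alias
  known_bins <- c(config$bins$bin_id, config$bin_accessions)

  check_nonempty <- function(tbl, section, keys) {
    for (i in seq_len(nrow(tbl))) for (k in keys) {
      v <- tbl[[k]][[i]]
      if (is.null(v) || all(is.na(v)) || (is.character(v) && !any(nzchar(v)))) {
        add("ERROR", sprintf("%s.%d.%s", section, i - 1L, k),
            "mandatory field is empty")
      }
    }
  }
  check_nonempty(config$samples, "samples", mandatory_fields("samples"))
  check_nonempty(config$read_sets, "read_sets", mandatory_fields("read_sets"))
  if (!is.null(config$assembly))
    check_nonempty(config$assembly, "assembly",
                   setdiff(mandatory_fields("assembly"), "runs"))
  check_nonempty(config$bins, "bins", mandatory_fields("bins"))
  check_nonempty(config$mags, "mags", mandatory_fields("mags"))

  for (i in seq_len(nrow(config$samples))) {
    taxid <- config$samples$taxid[i]
    if (!is.na(taxid) && (taxid <= 0 || taxid != round(taxid))) {
      add("ERROR", sprintf("samples.%d.taxid", i - 1L),
          "taxid must be a positive integer")
    }
  }

  check_ref <- function(ref, locus, pool, kind) {
    if (is.na(ref) || !nzchar(ref)) return(invisible())
    if (!(ref %in% pool) && !is_accession(ref, kind, patterns)) {
      add("ERROR", locus,
          sprintf("reference '%s' matches no declared alias and no %s accession pattern",
                  ref, kind))
    }
  }
  for (i in seq_len(nrow(config$read_sets))) {
    rs <- config$read_sets[i, ]
    check_ref(rs$sample, sprintf("read_sets.%d.sample", i - 1L),
              known_samples, "SAMPLE")
    files <- rs$files[[1]]
    layout <- toupper(rs$library_layout %||% "")
    if (!layout %in% c("SINGLE", "PAIRED")) {
      add("ERROR", sprintf("read_sets.%d.library_layout", i - 1L),
          "library_layout must be SINGLE or PAIRED")
    } else if ((layout == "PAIRED") != (length(files) == 2L)) {
      add("ERROR", sprintf("read_sets.%d.files", i - 1L),
          sprintf("%s layout requires exactly %d file(s), got %d",
                  layout, if (layout == "PAIRED") 2L else 1L, length(files)))
    }
  }
  if (!is.null(config$assembly)) {
    srefs <- config$assembly$samples[[1]]
    if (length(srefs) == 0)
      add("ERROR", "assembly.0.samples", "an assembly needs at least one sample reference")
    for (s in srefs) check_ref(s, "assembly.0.samples", known_samples, "SAMPLE")
    for (r in config$assembly$runs[[1]])
      check_ref(r, "assembly.0.runs", known_runs, "RUN")
    cov <- config$assembly$coverage[1]
    if (!is.na(cov) && cov < 0)
      add("ERROR", "assembly.0.coverage", "coverage must be nonnegative")
  }
  for (i in seq_len(nrow(config$mags))) {
    db <- config$mags$derived_bin[i]
    if (!is.na(db)) check_ref(db, sprintf("mags.%d.derived_bin", i - 1L),
                              known_bins, "ANALYSIS")
  }

  ## referenced files: uniqueness, existence, signatures
  file_fields <- collect_file_fields(config, scenario)
  dup_paths <- file_fields$path[duplicated(file_fields$path)]
  for (p in unique(dup_paths)) {
    add("ERROR", paste(file_fields$locus[file_fields$path == p], collapse = ","),
        sprintf("file '%s' is referenced by more than one record", p))
  }
  for (i in seq_len(nrow(file_fields))) {
    p <- resolve_path(config, file_fields$path[i])
    locus <- file_fields$locus[i]
    kind <- file_fields$kind[i]
    if (!file.exists(p)) {
      add("ERROR", locus, sprintf("file '%s' does not exist", file_fields$path[i]))
    } else if (file.access(p, 4) != 0) {
      add("ERROR", locus, sprintf("file '%s' is not readable", file_fields$path[i]))
    } else if (file.size(p) == 0) {
      add("ERROR", locus, sprintf("file '%s' is empty", file_fields$path[i]))
    } else {
      sig <- check_signature(p, kind)
      if (!is.na(sig)) add("ERROR", locus, sig)
    }
  }

  ## quality/taxonomy availability for bins and MAGs
  genome_tbl <- dplyr::bind_rows(
    if (has("BINS")) dplyr::mutate(config$bins, .section = "bins"),
    if (has("MAGS")) dplyr::mutate(config$mags, .section = "mags"))
  if (!is.null(genome_tbl) && nrow(genome_tbl) > 0) {
    qt <- aux_table(config, "quality_table", read_quality_table)
    tt <- aux_table(config, "taxonomy_table", read_taxonomy_table)
    for (i in seq_len(nrow(genome_tbl))) {
      g <- genome_tbl[i, ]
      locus <- sprintf("%s.%d", g$.section,
                       sum(genome_tbl$.section[seq_len(i)] == g$.section) - 1L)
      q <- genome_quality(g, qt)
      if (is.null(q)) {
        add("ERROR", paste0(locus, ".completeness"), sprintf(
          "no quality information for '%s': give completeness/contamination inline or in aux.quality_table",
          g$bin_id))
      } else if (g$.section == "mags" && classify_mimag(q$completeness, q$contamination) != "HIGH") {
        add("WARNING", locus, sprintf(
          "MAG '%s' (completeness %.1f%%, contamination %.1f%%) is below the MIMAG high-quality tier (>90%% complete, <5%% contaminated)",
          g$bin_id, q$completeness, q$contamination))
      }
      has_tax <- (!is.na(g$taxid) && !is.na(g$scientific_name)) ||
        (!is.na(g$lineage) && nzchar(g$lineage)) ||
        (!is.null(tt) && g$bin_id %in% tt$bin_id)
      if (!has_tax) {
        add("ERROR", paste0(locus, ".lineage"), sprintf(
          "no taxonomy source for '%s': give a lineage or taxid/scientific_name inline, or list it in aux.taxonomy_table",
          g$bin_id))
      }
      if (!is.na(g$coverage) && g$coverage < 0)
        add("ERROR", paste0(locus, ".coverage"), "coverage must be nonnegative")
      needs_cov <- is.na(g$coverage)
      if (needs_cov && is.na(config$aux$alignment)) {
        add("ERROR", paste0(locus, ".coverage"), sprintf(
          "coverage for '%s' must be given inline or inferable from aux.alignment",
          g$bin_id))
      }
    }
  }
  if (has("ASSEMBLY") && !is.null(config$assembly) &&
      is.na(config$assembly$coverage[1]) && is.na(config$aux$alignment)) {
    add("ERROR", "assembly.0.coverage",
        "assembly coverage must be given inline or inferable from aux.alignment")
  }

  report <- if (length(iss)) dplyr::bind_rows(iss) else
    tibble::tibble(severity = character(), locus = character(), message = character())
  structure(report, class = c("validation_report", class(tibble::tibble())))
}

#' Does a validation report contain blocking errors?
#' @param report a [validate_config()] result.
#' @return `TRUE` if any `ERROR`-severity issue is present.
#' @export
report_has_errors <- function(report) {
  any(report$severity == "ERROR")
}

resolve_path <- function(config, path) {
  if (grepl("^/", path) || file.exists(path)) path else file.path(config$dir, path)
}

# quality for one bin/MAG row: inline values win over the aux table
genome_quality <- function(g, qt) {
  if (!is.na(g$completeness) && !is.na(g$contamination)) {
    return(list(completeness = g$completeness, contamination = g$contamination))
  }
  if (!is.null(qt) && g$bin_id %in% qt$bin_id) {
    row <- qt[qt$bin_id == g$bin_id, ]
    return(list(completeness = row$completeness[1], contamination = row$contamination[1]))
  }
  NULL
}

aux_table <- function(config, field, reader) {
  p <- config$aux[[field]]
  if (is.na(p)) return(NULL)
  p <- resolve_path(config, p)
  if (!file.exists(p)) return(NULL)
  tryCatch(reader(p), error = function(e) NULL)
}

collect_file_fields <- function(config, scenario) {
  rows <- list()
  push <- function(path, locus, kind) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(path = path, locus = locus, kind = kind)
  }
  if (scenario_has(scenario, "READS")) {
    for (i in seq_len(nrow(config$read_sets))) {
      for (f in config$read_sets$files[[i]])
        push(f, sprintf("read_sets.%d.files", i - 1L), "fastq")
    }
  }
  if (scenario_has(scenario, "ASSEMBLY") && !is.null(config$assembly)) {
    push(config$assembly$fasta[1], "assembly.0.fasta", "fasta")
  }
  if (scenario_has(scenario, "BINS")) {
    for (i in seq_len(nrow(config$bins)))
      push(config$bins$fasta[i], sprintf("bins.%d.fasta", i - 1L), "fasta")
  }
  if (scenario_has(scenario, "MAGS")) {
    for (i in seq_len(nrow(config$mags)))
      push(config$mags$fasta[i], sprintf("mags.%d.fasta", i - 1L), "fasta")
  }
  for (f in c("quality_table", "taxonomy_table")) {
    if (!is.na(config$aux[[f]])) push(config$aux[[f]], paste0("aux.", f), "table")
  }
  if (!is.na(config$aux$alignment)) push(config$aux$alignment, "aux.alignment", "alignment")
  if (length(rows) == 0) {
    return(tibble::tibble(path = character(), locus = character(), kind = character()))
  }
  dplyr::bind_rows(rows)
}

# Cheap plausibility check on the first record only; full parsing happens
# where the content is actually consumed. Returns NA when fine, else a
# message.
check_signature <- function(path, kind) {
  if (kind == "fasta") {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) == 0 || !startsWith(first, ">"))
      return("file does not start with a FASTA record ('>')")
  } else if (kind == "fastq") {
    ln <- readLines(path, n = 4L, warn = FALSE)
    ok <- length(ln) == 4L && startsWith(ln[1], "@") && startsWith(ln[3], "+") &&
      nchar(ln[2]) == nchar(ln[4])
    if (!ok) return("first record is not 4-line FASTQ (@/seq/+/qual)")
  } else if (kind == "alignment") {
    con <- file(path, "rb"); on.exit(close(con))
    magic <- readBin(con, "raw", n = 2L)
    is_bgzf <- length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))
    if (!is_bgzf) {
      first <- readLines(path, n = 1L, warn = FALSE)
      if (length(first) == 0 || !startsWith(first, "@"))
        return("file is neither BAM (gzip magic) nor headered SAM ('@')")
    }
  }
  NA_character_
}

#' @export
print.validation_report <- function(x, ...) {
  ne <- sum(x$severity == "ERROR"); nw <- sum(x$severity == "WARNING")
  cat(sprintf("<validation_report: %d error(s), %d warning(s)>\n", ne, nw))
  NextMethod()
}
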