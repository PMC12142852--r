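#' Mandatory manifest keys per submission level
#'
#' The key tables follow public Webin manifest conventions; they are data,
#' so a different registry dialect can be accommodated by passing an amended
#' table to [build_manifest()] consumers. `FASTQ` may appear once or twice
#' (paired layout); every other mandatory key appears exactly once.
#'
#' @param level `"reads"`, `"assembly"`, `"bin"` or `"mag"`.
#' @return Character vector of mandatory KEYs.
#' @export
mandatory_manifest_keys <- function(level) {
  level <- match.arg(tolower(level), c("reads", "assembly", "bin", "mag"))
  if (level == "reads") {
    c("STUDY", "SAMPLE", "NAME", "PLATFORM", "INSTRUMENT", "LIBRARY_SOURCE",
      "LIBRARY_SELECTION", "LIBRARY_STRATEGY", "FASTQ")
  } else {
    c("STUDY", "SAMPLE", "ASSEMBLYNAME", "ASSEMBLY_TYPE", "COVERAGE",
      "PROGRAM", "PLATFORM", "MOLECULETYPE", "FASTA")
  }
}

assembly_type_for_level <- function(level) {
  switch(level,
    assembly = "primary metagenome",
    bin = "binned metagenome",
    mag = "Metagenome-Assembled Genome (MAG)",
    stop_magbroker("format", sprintf("no ASSEMBLY_TYPE for level '%s'", level)))
}

# one decimal place, round half to even
format_coverage <- function(fold) sprintf("%.1f", round(fold, 1))

#' Build the manifest for one uploadable item
#'
#' Assembles the ordered KEY/VALUE metadata block staged alongside an
#' uploaded file. Reference dependencies are resolved through the ledger:
#' the study accession always, the (virtual) sample accession for the item,
#' and optional run references. A missing dependency is an
#' unresolved-reference error naming the manifest key it would have filled.
#' `ASSEMBLY_TYPE` is fixed per level (`primary metagenome` /
#' `binned metagenome` / `Metagenome-Assembled Genome (MAG)`); `COVERAGE` is
#' formatted with one decimal place.
#'
#' @param level `"reads"`, `"assembly"`, `"bin"` or `"mag"`.
#' @param record one-row tibble (or list) of the item's config record.
#' @param ledger [accession_ledger()] with the item's dependencies.
#' @param study study accession or alias resolvable to one.
#' @param sample_ref alias/accession of the sample (virtual sample for
#'   bins/MAGs) the item is anchored to.
#' @param run_refs optional aliases/accessions of associated runs.
#' @param coverage optional [compute_coverage()] result, used when the
#'   record carries no explicit coverage value.
#' @param platform sequencing platform recorded for assembly-type manifests.
#' @return An object of class `manifest`: a tibble with columns `key`,
#'   `value` in serialization order.
#' @export
build_manifest <- function(level, record, ledger, study, sample_ref,
                           run_refs = NULL, coverage = NULL,
                           platform = "unspecified") {
  level <- match.arg(tolower(level), c("reads", "assembly", "bin", "mag"))
  record <- as.list(record)
  need <- function(ref, key, kind) {
    tryCatch(ledger_resolve(ledger, ref, kind), magbroker_error_unresolved = function(e) {
      stop_magbroker("unresolved",
        sprintf("manifest key %s: %s", key, conditionMessage(e)), key = key)
    })
  }
  study_acc <- if (is_accession(study, "STUDY")) study else
    need(study, "STUDY", "STUDY")
  sample_acc <- need(sample_ref, "SAMPLE", "SAMPLE")

  if (level == "reads") {
    files <- unlist(record$files)
    entries <- c(
      STUDY = study_acc, SAMPLE = sample_acc, NAME = scalar1(record$alias),
      PLATFORM = scalar1(record$platform), INSTRUMENT = scalar1(record$instrument),
      LIBRARY_SOURCE = scalar1(record$library_source),
      LIBRARY_SELECTION = scalar1(record$library_selection),
      LIBRARY_STRATEGY = scalar1(record$library_strategy))
    m <- tibble::tibble(key = names(entries), value = unname(entries))
    m <- dplyr::bind_rows(m, tibble::tibble(key = rep("FASTQ", length(files)),
                                            value = files))
  } else {
    cov <- record$coverage
    cov <- if (!is.null(cov) && length(cov) == 1 && !is.na(cov)) as.numeric(cov)
           else if (!is.null(coverage)) coverage$fold else NULL
    if (is.null(cov)) {
      stop_magbroker("unresolved",
        "manifest key COVERAGE: no coverage value given and none inferred",
        key = "COVERAGE")
    }
    name <- scalar1(record$name %||% record$bin_id)
    program <- scalar1(record$program %||% record$binning_software)
    moltype <- scalar1(record$molecule_type %||% "genomic DNA")
    entries <- c(
      STUDY = study_acc, SAMPLE = sample_acc, ASSEMBLYNAME = name,
      ASSEMBLY_TYPE = assembly_type_for_level(level),
      COVERAGE = format_coverage(cov), PROGRAM = program,
      PLATFORM = platform, MOLECULETYPE = moltype,
      FASTA = scalar1(record$fasta))
    m <- tibble::tibble(key = names(entries), value = unname(entries))
    if (length(run_refs) > 0) {
      runs <- vapply(run_refs, function(r) need(r, "RUN_REF", "RUN"), character(1))
      m <- dplyr::bind_rows(m, tibble::tibble(key = "RUN_REF",
                                              value = paste(runs, collapse = ",")))
    }
  }
  new_manifest(m, level)
}

scalar1 <- function(x) {
  x <- unlist(x)
  if (is.null(x) || length(x) == 0 || is.na(x[1])) NA_character_ else as.character(x[1])
}

new_manifest <- function(tbl, level) {
  if (any(is.na(tbl$value) | !nzchar(tbl$value))) {
    bad <- tbl$key[is.na(tbl$value) | !nzchar(tbl$value)]
    stop_magbroker("unresolved",
      sprintf("manifest key(s) without a value: %s", paste(bad, collapse = ", ")),
      key = bad[1])
  }
  if (any(grepl("\t", tbl$value, fixed = TRUE))) {
    stop_magbroker("format", "manifest values must not contain tab characters")
  }
  counts <- table(tbl$key)
  multi <- setdiff(names(counts[counts > 1]), "FASTQ")
  if (length(multi) > 0) {
    stop_magbroker("format", sprintf("manifest key(s) repeated: %s",
                                     paste(multi, collapse = ", ")))
  }
  structure(tbl, level = level, class = c("manifest", class(tibble::tibble())))
}

#' Serialize / parse a manifest
#'
#' The wire format is one `KEY<TAB>VALUE` line per entry, UTF-8, LF line
#' endings. `parse_manifest(serialize_manifest(m))` reproduces `m` exactly.
#'
#' @param manifest a [build_manifest()] result.
#' @return `serialize_manifest()`: a single string. `parse_manifest()`: a
#'   `manifest` tibble.
#' @export
serialize_manifest <- function(manifest) {
  paste0(paste(manifest$key, manifest$value, sep = "\t", collapse = "\n"), "\n")
}

#' @rdname serialize_manifest
#' @param text manifest text.
#' @param level optional level tag to attach.
#' @export
parse_manifest <- function(text, level = NULL) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- stringr::str_split_fixed(lines, "\t", 2)
  new_manifest(tibble::tibble(key = parts[, 1], value = parts[, 2]),
               level %||% "unknown")
}

#' Stage an item for upload
#'
#' Creates the per-item staging directory `<workdir>/<level>/<alias>/`,
#' copies the item's data files into it, rewrites the manifest's file
#' entries to the staged locations, and writes the manifest beside them.
#' Re-staging the same item overwrites its own directory cleanly
#' (byte-identical results for identical inputs); a non-empty directory that
#' was not produced by a previous staging is refused.
#'
#' @param alias item alias (directory name).
#' @param level submission level tag (directory component).
#' @param files character vector of data file paths (must exist).
#' @param manifest the item's [build_manifest()] result.
#' @param workdir staging root (created if needed).
#' @return A list of class `staged_item`: `staging_dir`, `manifest_path`,
#'   `data_files` (staged paths), `level`, `alias`.
#' @export
stage_item <- function(alias, level, files, manifest, workdir) {
  missing <- files[!file.exists(files)]
  if (length(missing) > 0) {
    stop_magbroker("staging", sprintf("data file(s) not found: %s",
                                      paste(missing, collapse = ", ")))
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(workdir) || file.access(workdir, 2) != 0) {
    stop_magbroker("staging", sprintf("staging root '%s' is not writable", workdir))
  }
  dest <- file.path(workdir, tolower(level), alias)
  if (dir.exists(dest)) {
    contents <- list.files(dest)
    if (length(contents) > 0 && !"manifest.txt" %in% contents) {
      stop_magbroker("staging",
        sprintf("'%s' exists, is non-empty and is not a previous staging directory",
                dest))
    }
    unlink(dest, recursive = TRUE)
  }
  dir.create(dest, recursive = TRUE)
  staged <- file.path(dest, basename(files))
  ok <- file.copy(files, staged, overwrite = TRUE)
  if (!all(ok)) {
    stop_magbroker("staging", sprintf("failed to copy into '%s'", dest))
  }
  # manifest file entries point at the staged copies
  m2 <- manifest
  file_keys <- m2$key %in% c("FASTA", "FASTQ")
  m2$value[file_keys] <- basename(m2$value[file_keys])
  manifest_path <- file.path(dest, "manifest.txt")
  writeLines(sub("\n$", "", serialize_manifest(m2)), manifest_path, useBytes = TRUE)
  structure(list(staging_dir = dest, manifest_path = manifest_path,
                 data_files = staged, level = tolower(level), alias = alias),
            class = "staged_item")
}
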