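#' Deterministic mock registry
#'
#' An in-process stand-in for the registry's submission, taxonomy and upload
#' endpoints so the entire workflow runs and is testable offline (the
#' development-service role). Accessions are issued sequentially per object
#' kind with the same prefixes and zero-padded 7-digit counters the real
#' accession patterns describe, so ledger validation is exercised for real;
#' identical call sequences always yield identical receipts. An alias is
#' never issued two accessions: resubmitting one yields a failure receipt.
#'
#' @param fixture_path taxonomy registry table served by
#'   [mock_taxonomy_query()]; defaults to the bundled fixture.
#' @return An environment of class `mock_registry` holding the mutable
#'   service state (per-kind counters, issued accessions, taxonomy records).
#' @export
mock_registry <- function(fixture_path = default_registry_path()) {
  state <- new.env(parent = emptyenv())
  state$counters <- c(SAMPLE = 0L, RUN = 0L, ANALYSIS = 0L)
  state$issued <- tibble::tibble(alias = character(), kind = character(),
                                 accession = character())
  state$taxonomy <- read_taxon_records(fixture_path)
  state$calls <- 0L          # submission-service calls (register/upload)
  state$taxonomy_calls <- 0L # taxonomy queries, counted separately
  class(state) <- "mock_registry"
  state
}

accession_prefix <- c(SAMPLE = "ERS", RUN = "ERR", ANALYSIS = "ERZ")

next_accession <- function(state, kind) {
  state$counters[[kind]] <- state$counters[[kind]] + 1L
  sprintf("%s%07d", accession_prefix[[kind]], state$counters[[kind]])
}

#' Submit a sample-set document to the mock registry
#'
#' Emulates the registry's XML submission endpoint: parses the document,
#' assigns the next sequential sample accession per alias, and returns a
#' receipt XML string. Problems (malformed payload, resubmitted alias) come
#' back as failure receipts, never as exceptions — a server answers, it does
#' not throw.
#'
#' @param state a [mock_registry()].
#' @param xml_text sample-set XML.
#' @return Receipt XML as a string.
#' @export
mock_register <- function(state, xml_text) {
  state$calls <- state$calls + 1L
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) NULL)
  if (is.null(doc) || xml2::xml_name(doc) != "SAMPLE_SET") {
    return(receipt_xml(FALSE, messages = list(c("ERROR",
      "payload is not a well-formed SAMPLE_SET document"))))
  }
  aliases <- xml2::xml_attr(xml2::xml_find_all(doc, "./SAMPLE"), "alias")
  if (length(aliases) == 0 || anyNA(aliases)) {
    return(receipt_xml(FALSE, messages = list(c("ERROR",
      "document contains no SAMPLE elements with aliases"))))
  }
  dup <- aliases[aliases %in% state$issued$alias]
  if (length(dup) > 0) {
    return(receipt_xml(FALSE, messages = lapply(dup, function(a)
      c("ERROR", sprintf("object with alias '%s' already exists", a)))))
  }
  rows <- lapply(aliases, function(a) {
    acc <- next_accession(state, "SAMPLE")
    state$issued <- dplyr::bind_rows(state$issued, tibble::tibble(
      alias = a, kind = "SAMPLE", accession = acc))
    c("SAMPLE", a, acc)
  })
  receipt_xml(TRUE, assignments = rows)
}

receipt_xml <- function(success, assignments = list(), messages = list()) {
  doc <- xml2::xml_new_root("RECEIPT",
                            success = if (success) "true" else "false")
  for (a in assignments) {
    xml2::xml_add_child(doc, a[1], alias = a[2], accession = a[3])
  }
  if (length(messages) > 0) {
    wrap <- xml2::xml_add_child(doc, "MESSAGES")
    for (m in messages) xml2::xml_add_child(wrap, m[1], m[2])
  }
  as.character(doc)
}

#' Query the mock taxonomy endpoint
#'
#' Returns exact-name matches first, then superstring matches (names
#' containing the query), mirroring suggestion-style endpoints — the
#' resolver is expected to filter the latter out.
#'
#' @param state a [mock_registry()].
#' @param name scientific-name query.
#' @return Tibble of matching taxon records.
#' @export
mock_taxonomy_query <- function(state, name) {
  rec <- state$taxonomy
  exact <- rec[rec$scientific_name == name, ]
  super <- rec[rec$scientific_name != name &
                 grepl(name, rec$scientific_name, fixed = TRUE), ]
  dplyr::bind_rows(exact, super)
}

#' @export
query_taxon.mock_registry <- function(client, name) {
  client$taxonomy_calls <- client$taxonomy_calls + 1L
  mock_taxonomy_query(client, name)
}

#' Upload a staged item to the mock uploader
#'
#' Emulates the manifest-driven upload path: validates that the staged
#' manifest carries every mandatory key for its level and that the files it
#' names exist in the staging directory, then issues the next sequential
#' RUN (reads) or ANALYSIS (assembly/bin/MAG) accession. Failures are
#' returned as failed [parse_receipt()]-shaped receipts, never thrown.
#'
#' @param state a [mock_registry()].
#' @param staged a [stage_item()] result.
#' @return A `receipt` object.
#' @export
mock_upload <- function(state, staged) {
  state$calls <- state$calls + 1L
  fail <- function(msg) {
    structure(list(success = FALSE,
                   assignments = tibble::tibble(kind = character(),
                                                alias = character(),
                                                accession = character()),
                   messages = tibble::tibble(severity = "ERROR", text = msg)),
              class = "receipt")
  }
  if (!file.exists(staged$manifest_path)) {
    return(fail("staging directory has no manifest"))
  }
  m <- tryCatch(parse_manifest(paste(readLines(staged$manifest_path, warn = FALSE),
                                     collapse = "\n"), staged$level),
                error = function(e) NULL)
  if (is.null(m)) return(fail("manifest is unreadable"))
  missing <- setdiff(mandatory_manifest_keys(staged$level), m$key)
  if (length(missing) > 0) {
    return(fail(sprintf("manifest lacks mandatory key(s): %s",
                        paste(missing, collapse = ", "))))
  }
  data_values <- m$value[m$key %in% c("FASTA", "FASTQ")]
  absent <- data_values[!file.exists(file.path(staged$staging_dir, data_values))]
  if (length(absent) > 0) {
    return(fail(sprintf("staged file(s) missing: %s", paste(absent, collapse = ", "))))
  }
  if (staged$alias %in% state$issued$alias) {
    return(fail(sprintf("object with alias '%s' already exists", staged$alias)))
  }
  kind <- if (staged$level == "reads") "RUN" else "ANALYSIS"
  acc <- next_accession(state, kind)
  state$issued <- dplyr::bind_rows(state$issued, tibble::tibble(
    alias = staged$alias, kind = kind, accession = acc))
  structure(list(success = TRUE,
                 assignments = tibble::tibble(kind = kind, alias = staged$alias,
                                              accession = acc),
                 messages = tibble::tibble(severity = character(),
                                           text = character())),
            class = "receipt")
}
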