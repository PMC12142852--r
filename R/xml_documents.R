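#' Build a sample-set XML document
#'
#' Serializes sample records (physical or virtual) to the registry's
#' sample-set XML: one `SAMPLE` element per record carrying the alias, the
#' title, the taxon (`TAXON_ID` + `SCIENTIFIC_NAME`) and every attribute as
#' a `SAMPLE_ATTRIBUTE` `TAG`/`VALUE` pair, in input order. Element and
#' attribute order is canonical so serialized documents are byte-stable.
#'
#' @param samples tibble with columns `alias`, `title`, `taxid`,
#'   `scientific_name` and an `attributes` list-column of named values.
#' @return A single string of XML text.
#' @export
build_sample_set <- function(samples) {
  if (NROW(samples) == 0) {
    stop_magbroker("empty_set", "refusing to build a sample set with no samples")
  }
  dup <- unique(samples$alias[duplicated(samples$alias)])
  if (length(dup) > 0) {
    stop_magbroker("conflict", sprintf("duplicate sample alias(es): %s",
                                       paste(dup, collapse = ", ")))
  }
  doc <- xml2::xml_new_root("SAMPLE_SET")
  for (i in seq_len(NROW(samples))) {
    s <- xml2::xml_add_child(doc, "SAMPLE", alias = samples$alias[i])
    xml2::xml_add_child(s, "TITLE", samples$title[i])
    nm <- xml2::xml_add_child(s, "SAMPLE_NAME")
    xml2::xml_add_child(nm, "TAXON_ID", as.character(as.integer(samples$taxid[i])))
    xml2::xml_add_child(nm, "SCIENTIFIC_NAME", samples$scientific_name[i])
    attrs <- samples$attributes[[i]]
    if (length(attrs) > 0) {
      wrap <- xml2::xml_add_child(s, "SAMPLE_ATTRIBUTES")
      for (k in names(attrs)) {
        a <- xml2::xml_add_child(wrap, "SAMPLE_ATTRIBUTE")
        xml2::xml_add_child(a, "TAG", k)
        xml2::xml_add_child(a, "VALUE", as.character(attrs[[k]]))
      }
    }
  }
  as.character(doc)
}

#' Build a virtual sample for a derived object
#'
#' Bins, MAGs and co-assemblies are not physical samples, yet the registry
#' anchors each of them to a sample object. This builds that virtual sample:
#' it carries the resolved environmental taxon, the completeness /
#' contamination scores and binning software when available, and a
#' `sample derived from` attribute listing the accessions of the physical
#' origin samples (comma-separated for co-assemblies), resolved through the
#' ledger. Attribute names follow the public binned-metagenome checklist
#' vocabulary.
#'
#' @param alias alias for the virtual sample.
#' @param title sample title.
#' @param assignment the [taxonomy_assignment()] for the object.
#' @param origin_refs aliases or accessions of the physical samples the
#'   object derives from.
#' @param ledger [accession_ledger()] used to resolve `origin_refs`.
#' @param quality optional list with `completeness` and `contamination`.
#' @param binning_software optional software string.
#' @param extra optional named list of further attributes.
#' @return A one-row tibble suitable for [build_sample_set()].
#' @export
build_virtual_sample <- function(alias, title, assignment, origin_refs, ledger,
                                 quality = NULL, binning_software = NULL,
                                 extra = list()) {
  stopifnot(inherits(assignment, "taxonomy_assignment"), length(origin_refs) >= 1)
  origins <- vapply(origin_refs, function(r) ledger_resolve(ledger, r, "SAMPLE"),
                    character(1), USE.NAMES = FALSE)
  attrs <- list()
  if (!is.null(quality)) {
    attrs[["completeness score"]] <- format(quality$completeness)
    attrs[["contamination score"]] <- format(quality$contamination)
  }
  if (!is.null(binning_software) && !is.na(binning_software)) {
    attrs[["binning software"]] <- binning_software
  }
  attrs[["sample derived from"]] <- paste(origins, collapse = ",")
  attrs <- c(attrs, extra)
  tibble::tibble(alias = alias, title = title,
                 taxid = assignment$taxid,
                 scientific_name = assignment$scientific_name,
                 attributes = list(attrs))
}

#' Parse a registry receipt
#'
#' Receipts are the XML responses the registry returns after a submission;
#' they carry a success flag, assigned accessions, and messages. Every
#' accession-bearing child element becomes an assignment (object kind from
#' the element name); `MESSAGES` children are collected with their severity.
#'
#' @param xml_text receipt XML as a string.
#' @return A list of class `receipt`: `success` (logical), `assignments`
#'   (tibble `kind`, `alias`, `accession`), `messages` (tibble `severity`,
#'   `text`).
#' @export
parse_receipt <- function(xml_text) {
  force(xml_text) # evaluate the argument outside the parse tryCatch
  doc <- tryCatch(xml2::read_xml(xml_text), error = function(e) {
    stop_magbroker("parse", paste0("malformed receipt XML: ", conditionMessage(e)))
  })
  if (xml2::xml_name(doc) != "RECEIPT") {
    stop_magbroker("format", sprintf("expected a RECEIPT root, found <%s>",
                                     xml2::xml_name(doc)))
  }
  success_attr <- xml2::xml_attr(doc, "success")
  if (is.na(success_attr)) {
    stop_magbroker("format", "receipt lacks the success attribute")
  }
  success <- tolower(success_attr) == "true"
  kids <- xml2::xml_children(doc)
  rows <- list(); msgs <- list()
  for (k in kids) {
    nm <- xml2::xml_name(k)
    if (nm == "MESSAGES") {
      for (m in xml2::xml_children(k)) {
        msgs[[length(msgs) + 1L]] <- tibble::tibble(
          severity = toupper(xml2::xml_name(m)), text = xml2::xml_text(m))
      }
    } else {
      acc <- xml2::xml_attr(k, "accession")
      if (!is.na(acc)) {
        alias <- xml2::xml_attr(k, "alias")
        if (is.na(alias) || !nzchar(alias) || !nzchar(acc)) {
          stop_magbroker("format",
            sprintf("receipt %s element needs nonempty alias and accession", nm))
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = nm, alias = alias, accession = acc)
      }
    }
  }
  assignments <- bind_or_empty(rows, tibble::tibble(
    kind = character(), alias = character(), accession = character()))
  if (!success && nrow(assignments) > 0) {
    stop_magbroker("format", "failed receipt must not carry assignments")
  }
  structure(list(success = success, assignments = assignments,
                 messages = bind_or_empty(msgs, tibble::tibble(
                   severity = character(), text = character()))),
            class = "receipt")
}

#' @export
print.receipt <- function(x, ...) {
  cat(sprintf("<receipt: %s, %d assignment(s), %d message(s)>\n",
              if (x$success) "success" else "FAILURE",
              nrow(x$assignments), nrow(x$messages)))
  invisible(x)
}
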