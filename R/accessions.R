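#' Accession pattern table
#'
#' Regular expressions describing the accession shapes of the four object
#' kinds the workflow tracks. They follow public ENA conventions (ERS/SAMEA
#' samples, ERR runs, ERZ analyses, PRJ/ERP studies). The table is data, not
#' hard-coded logic: pass a modified copy wherever a `patterns` argument is
#' accepted to adapt the broker to another registry dialect. The bundled mock
#' registry issues accessions with exactly these shapes so ledger validation
#' is exercised for real.
#'
#' @return Named character vector of anchored regular expressions with names
#'   `SAMPLE`, `RUN`, `ANALYSIS`, `STUDY`.
#' @examples
#' grepl(accession_patterns()["SAMPLE"], "SAMEA123456")
#' @export
accession_patterns <- function() {
  c(
    SAMPLE   = "^(ERS|SAMEA)\\d+$",
    RUN      = "^ERR\\d+$",
    ANALYSIS = "^ERZ\\d+$",
    STUDY    = "^(PRJ[EDN][A-Z]\\d+|ERP\\d+)$"
  )
}

#' Does a string look like an accession?
#'
#' @param x character vector to test.
#' @param kind one of `"SAMPLE"`, `"RUN"`, `"ANALYSIS"`, `"STUDY"`, or `NULL`
#'   to accept any kind.
#' @param patterns pattern table, see [accession_patterns()].
#' @return logical vector.
#' @export
is_accession <- function(x, kind = NULL, patterns = accession_patterns()) {
  pats <- if (is.null(kind)) patterns else patterns[kind]
  vapply(x, function(s) any(vapply(pats, grepl, logical(1), x = s)), logical(1),
         USE.NAMES = FALSE)
}

#' Create an empty accession ledger
#'
#' The ledger is the single source of truth for accessions assigned during a
#' run: every registry receipt feeds it, and every downstream document
#' (virtual samples, manifests) resolves its references through it. It is a
#' tibble with one row per assigned accession plus an attached pattern table.
#'
#' @param patterns accession pattern table, see [accession_patterns()].
#' @return An object of class `accession_ledger`: a tibble with columns
#'   `alias`, `kind`, `accession`, `step`.
#' @examples
#' accession_ledger() |> ledger_add("s1", "SAMPLE", "ERS0000001")
#' @export
accession_ledger <- function(patterns = accession_patterns()) {
  led <- tibble::tibble(
    alias = character(), kind = character(),
    accession = character(), step = integer()
  )
  structure(led, patterns = patterns,
            class = c("accession_ledger", class(led)))
}

#' Record a newly assigned accession
#'
#' Appends one entry. Aliases are write-once: re-adding an alias is a
#' conflict, and the accession must match the pattern configured for its
#' object kind. `step` defaults to the next insertion index so the insertion
#' order is always reconstructible from the ledger itself.
#'
#' @param ledger an [accession_ledger()].
#' @param alias unique alias the object was submitted under.
#' @param kind object kind: `"SAMPLE"`, `"RUN"` or `"ANALYSIS"`.
#' @param accession accession string assigned by the registry.
#' @param step optional step index (defaults to insertion order).
#' @return The ledger with one more row.
#' @export
ledger_add <- function(ledger, alias, kind, accession, step = NULL) {
  stopifnot(inherits(ledger, "accession_ledger"))
  patterns <- attr(ledger, "patterns")
  kind <- match.arg(kind, c("SAMPLE", "RUN", "ANALYSIS", "STUDY"))
  if (alias %in% ledger$alias) {
    stop_magbroker("conflict",
      sprintf("alias '%s' already holds accession %s; ledger entries are never overwritten",
              alias, ledger$accession[ledger$alias == alias]),
      alias = alias)
  }
  if (!grepl(patterns[[kind]], accession)) {
    stop_magbroker("format",
      sprintf("accession '%s' does not match the %s pattern '%s'",
              accession, kind, patterns[[kind]]),
      accession = accession, kind = kind)
  }
  step <- as.integer(step %||% (nrow(ledger) + 1L))
  out <- dplyr::bind_rows(ledger, tibble::tibble(
    alias = alias, kind = kind, accession = accession, step = step))
  structure(out, patterns = patterns,
            class = c("accession_ledger", class(tibble::tibble())))
}

#' Resolve an alias or accession literal to an accession
#'
#' Configuration fields that reference other objects accept either an alias
#' declared in the same run or an accession of something already deposited
#' (the study-extension path). Disambiguation: a known alias wins; otherwise
#' a string matching an accession pattern passes through unchanged; anything
#' else is an unresolved reference.
#'
#' @inheritParams ledger_add
#' @param ref alias or accession literal.
#' @param kind optional object kind to restrict the pass-through pattern.
#' @return The accession string.
#' @export
ledger_resolve <- function(ledger, ref, kind = NULL) {
  stopifnot(inherits(ledger, "accession_ledger"), is.character(ref),
            length(ref) == 1L)
  hit <- which(ledger$alias == ref)
  if (length(hit) == 1L) return(ledger$accession[hit])
  if (is_accession(ref, kind, attr(ledger, "patterns"))) return(ref)
  stop_magbroker("unresolved",
    sprintf("reference '%s' is neither a known alias nor an accession%s",
            ref, if (is.null(kind)) "" else sprintf(" of kind %s", kind)),
    ref = ref)
}

#' @export
print.accession_ledger <- function(x, ...) {
  cat(sprintf("<accession_ledger: %d entries>\n", nrow(x)))
  NextMethod()
}
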