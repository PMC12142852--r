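CANONICAL_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
GTDB_PREFIXES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species")

#' Parse a classification string into a ranked lineage
#'
#' Accepts the GTDB prefix dialect (`d__...;p__...;...;s__...`) or a plain
#' semicolon-separated list of names assigned positionally domain-to-species.
#' Empty ranks are allowed anywhere (e.g. a family-level classification with
#' an empty genus). GTDB polyphyletic suffixes of the form `_A` ... `_Z` on a
#' name's trailing token are stripped (registry records use the base names),
#' and each strip is recorded as a normalization note.
#'
#' @param raw classification string.
#' @return An object of class `ranked_lineage`: a list with `ranks` (named
#'   character vector over the 7 canonical ranks, `""` where unclassified),
#'   `dialect` (`"GTDB"` or `"plain"`) and `notes` (character vector of
#'   normalizations applied).
#' @examples
#' parse_lineage("d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__;s__")
#' @export
parse_lineage <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  ranks <- stats::setNames(rep("", 7L), CANONICAL_RANKS)
  notes <- character()
  parts <- str_trim(strsplit(raw, ";", fixed = TRUE)[[1]])
  gtdb <- any(grepl("^[dpcofgs]__", parts))
  if (gtdb) {
    for (p in parts) {
      if (!nzchar(p)) next
      m <- str_match(p, "^([a-z])__(.*)$")
      if (is.na(m[1, 1]) || !(m[1, 2] %in% names(GTDB_PREFIXES))) {
        stop_magbroker("dialect",
          sprintf("unrecognized rank prefix in lineage token '%s'", p))
      }
      ranks[[GTDB_PREFIXES[[m[1, 2]]]]] <- m[1, 3]
    }
  } else {
    if (length(parts) > 7L) {
      stop_magbroker("dialect",
        sprintf("plain lineage has %d fields; at most the 7 canonical ranks are supported",
                length(parts)))
    }
    ranks[seq_along(parts)] <- parts
  }
  # strip GTDB polyphyletic suffixes (_A ... _Z on the trailing token)
  for (r in CANONICAL_RANKS) {
    stripped <- sub("_[A-Z]$", "", ranks[[r]])
    if (stripped != ranks[[r]]) {
      notes <- c(notes, sprintf("%s '%s' normalized to '%s' (polyphyletic suffix)",
                                r, ranks[[r]], stripped))
      ranks[[r]] <- stripped
    }
  }
  structure(list(ranks = ranks, dialect = if (gtdb) "GTDB" else "plain",
                 notes = notes),
            class = "ranked_lineage")
}

#' Serialize a ranked lineage back to the GTDB prefix dialect
#'
#' @param lineage a [parse_lineage()] result.
#' @return A single classification string (`d__...;p__...;...;s__...`).
#' @export
format_lineage <- function(lineage) {
  stopifnot(inherits(lineage, "ranked_lineage"))
  paste(paste0(names(GTDB_PREFIXES)[match(CANONICAL_RANKS, GTDB_PREFIXES)],
               "__", lineage$ranks),
        collapse = ";")
}

#' @export
print.ranked_lineage <- function(x, ...) {
  set <- x$ranks[nzchar(x$ranks)]
  cat("<ranked_lineage>", if (length(set)) paste(names(set), set, sep = "=",
                                                 collapse = "; ") else "(empty)", "\n")
  invisible(x)
}

lowest_rank <- function(lineage) {
  set <- which(nzchar(lineage$ranks))
  if (length(set) == 0) return(NULL)
  CANONICAL_RANKS[max(set)]
}
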