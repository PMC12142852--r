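#' Read a CheckM-style bin quality table
#'
#' Parses a tab-separated table of per-bin completeness and contamination
#' percentages. Header matching is case-insensitive and accepts the common
#' synonyms different tools emit for the bin-identifier column (`Bin Id`,
#' `Name`, `user_genome`, `genome`). Values are percentages.
#'
#' @param path path to the tab-separated table.
#' @return A tibble with columns `bin_id`, `completeness`, `contamination`,
#'   one row per data row.
#' @export
read_quality_table <- function(path) {
  tbl <- read_tsv_quiet(path)
  id_col <- match_header(tbl, c("bin id", "bin_id", "name", "user_genome", "genome"))
  comp_col <- match_header(tbl, c("completeness", "completeness (%)"))
  cont_col <- match_header(tbl, c("contamination", "contamination (%)"))
  out <- tibble::tibble(
    bin_id = as.character(tbl[[id_col]]),
    completeness = as.numeric(tbl[[comp_col]]),
    contamination = as.numeric(tbl[[cont_col]])
  )
  bad <- which(is.na(out$completeness) | out$completeness < 0 | out$completeness > 100)
  if (length(bad) > 0) {
    stop_magbroker("range",
      sprintf("row %d ('%s'): completeness must be within [0, 100]",
              bad[1], out$bin_id[bad[1]]), row = bad[1])
  }
  bad <- which(is.na(out$contamination) | out$contamination < 0)
  if (length(bad) > 0) {
    stop_magbroker("range",
      sprintf("row %d ('%s'): contamination must be nonnegative",
              bad[1], out$bin_id[bad[1]]), row = bad[1])
  }
  out
}

#' Read a GTDB-Tk-style classification table
#'
#' Parses a tab-separated table mapping genome/bin identifiers to raw
#' classification strings. The strings are preserved verbatim (including
#' empty cells); turning them into ranked lineages and taxon assignments is
#' the job of [parse_lineage()] and the taxonomy resolver, which report their
#' own failures.
#'
#' @param path path to the tab-separated table.
#' @return A tibble with columns `bin_id`, `classification`.
#' @export
read_taxonomy_table <- function(path) {
  tbl <- read_tsv_quiet(path)
  id_col <- match_header(tbl, c("user_genome", "bin id", "bin_id", "name", "genome"))
  cls_col <- match_header(tbl, c("classification", "lineage", "taxonomy"))
  out <- tibble::tibble(
    bin_id = as.character(tbl[[id_col]]),
    classification = dplyr::coalesce(as.character(tbl[[cls_col]]), "")
  )
  dup <- unique(out$bin_id[duplicated(out$bin_id)])
  if (length(dup) > 0) {
    stop_magbroker("conflict",
      sprintf("duplicate genome identifier(s) in classification table: %s",
              paste(dup, collapse = ", ")))
  }
  out
}

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) {
    stop_magbroker("io", sprintf("table '%s' does not exist", path))
  }
  readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                  progress = FALSE, show_col_types = FALSE)
}

match_header <- function(tbl, synonyms) {
  hits <- which(tolower(names(tbl)) %in% synonyms)
  if (length(hits) == 0) {
    stop_magbroker("header",
      sprintf("no column matching any of [%s]; found columns: %s",
              paste(synonyms, collapse = ", "),
              paste(names(tbl), collapse = ", ")))
  }
  hits[1]
}

#' MIMAG quality tier of a bin
#'
#' Classifies completeness/contamination pairs into the MIMAG genome-quality
#' tiers: `HIGH` for >90% complete and <5% contaminated, `MEDIUM` for >=50%
#' complete and <10% contaminated, otherwise `LOW`. The MIMAG high-quality
#' tier additionally requires rRNA/tRNA presence, which needs gene calling
#' and is out of scope here; the tier returned is therefore the
#' completeness/contamination component only, which is why submission uses
#' it advisorily (a WARNING, never an ERROR).
#'
#' @param completeness completeness percent in `[0, 100]` (vectorized).
#' @param contamination contamination percent `>= 0` (vectorized).
#' @return Character vector of `"HIGH"`, `"MEDIUM"` or `"LOW"`.
#' @examples
#' classify_mimag(c(95, 50, 10), c(2, 9.9, 40))
#' @export
classify_mimag <- function(completeness, contamination) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0))
  dplyr::case_when(
    completeness > 90 & contamination < 5 ~ "HIGH",
    completeness >= 50 & contamination < 10 ~ "MEDIUM",
    .default = "LOW"
  )
}
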