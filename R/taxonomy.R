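#' Candidate environmental taxon names for a lineage
#'
#' Derives the "uncultured ..." organism-level names a classification should
#' be submitted under, from the lowest classified rank only (no silent
#' walk-up to higher ranks — demoting the rank changes the scientific
#' claim). The rule table, most specific first:
#'
#' * species `S` -> `S`, then `uncultured S`
#' * genus `G` -> `uncultured G sp.`
#' * family/order/class/phylum `N` -> `uncultured N bacterium` (domain
#'   Bacteria) or `uncultured N archaeon` (domain Archaea)
#' * domain only -> `uncultured bacterium` / `uncultured archaeon`
#'
#' So a genome classified at family level as Enterobacteriaceae with an
#' empty genus yields `uncultured Enterobacteriaceae bacterium`. Only
#' Bacteria and Archaea are covered; other domains fail explicitly.
#'
#' @param lineage a [parse_lineage()] result.
#' @return A tibble with columns `name` (query string) and `rank` (the rank
#'   the candidate was derived from), ordered most specific first.
#' @examples
#' candidate_names(parse_lineage("d__Bacteria;f__Enterobacteriaceae"))
#' @export
candidate_names <- function(lineage) {
  stopifnot(inherits(lineage, "ranked_lineage"))
  low <- lowest_rank(lineage)
  if (is.null(low)) {
    stop_magbroker("empty_lineage", "all ranks are empty; cannot derive a taxon name")
  }
  domain <- lineage$ranks[["domain"]]
  if (!domain %in% c("Bacteria", "Archaea")) {
    stop_magbroker("dialect",
      sprintf("environmental name rules cover Bacteria and Archaea only, not '%s'",
              domain))
  }
  adjective <- if (domain == "Bacteria") "bacterium" else "archaeon"
  name <- lineage$ranks[[low]]
  cand <- switch(low,
    species = {
      genus <- lineage$ranks[["genus"]]
      binomial <- if (nzchar(genus) && !startsWith(name, paste0(genus, " ")))
        paste(genus, name) else name
      c(binomial, paste("uncultured", binomial))
    },
    genus = paste("uncultured", name, "sp."),
    domain = paste("uncultured", adjective),
    paste("uncultured", name, adjective)
  )
  tibble::tibble(name = cand, rank = low)
}

#' Taxonomy query clients
#'
#' A taxonomy client answers scientific-name queries with matching registry
#' records. Implementations satisfy one contract — `query_taxon(client,
#' name)` returns a tibble with columns `taxid`, `scientific_name`, `rank`,
#' `submittable` (possibly zero rows) and is deterministic for a fixed
#' registry state. `fixture_taxonomy_client()` serves the bundled
#' tab-separated registry table offline; [mock_registry()] exposes the same
#' fixture through the mock service.
#'
#' @param path tab-separated registry table with columns `taxid`,
#'   `scientific_name`, `rank`, `submittable`; defaults to the fixture
#'   bundled with the package (a small synthetic registry excerpt carrying
#'   the genuine public identifiers for the names it contains).
#' @return An object with class `taxonomy_client`.
#' @export
fixture_taxonomy_client <- function(path = default_registry_path()) {
  records <- read_taxon_records(path)
  structure(list(records = records), class = c("fixture_taxonomy_client",
                                               "taxonomy_client"))
}

default_registry_path <- function() {
  system.file("extdata", "taxonomy_registry_synthetic.tsv", package = "magbroker",
              mustWork = TRUE)
}

read_taxon_records <- function(path) {
  tbl <- read_tsv_quiet(path)
  need <- c("taxid", "scientific_name", "rank", "submittable")
  missing <- setdiff(need, tolower(names(tbl)))
  if (length(missing) > 0) {
    stop_magbroker("header", sprintf("registry table lacks column(s): %s",
                                     paste(missing, collapse = ", ")))
  }
  names(tbl) <- tolower(names(tbl))
  out <- tibble::tibble(
    taxid = as.integer(tbl$taxid),
    scientific_name = tbl$scientific_name,
    rank = tbl$rank,
    submittable = tolower(tbl$submittable) %in% c("true", "yes", "1")
  )
  dup <- duplicated(out[c("taxid", "scientific_name")])
  if (any(dup)) {
    stop_magbroker("conflict", "registry table has duplicate (taxid, name) records")
  }
  out
}

#' Query a taxonomy client
#' @param client a taxonomy client (see [fixture_taxonomy_client()]).
#' @param name scientific-name query string.
#' @return Tibble of matching records: `taxid`, `scientific_name`, `rank`,
#'   `submittable`. Exact matches sort before superstring matches.
#' @export
query_taxon <- function(client, name) UseMethod("query_taxon")

#' @export
query_taxon.fixture_taxonomy_client <- function(client, name) {
  rec <- client$records
  exact <- rec[rec$scientific_name == name, ]
  super <- rec[rec$scientific_name != name &
                 grepl(name, rec$scientific_name, fixed = TRUE), ]
  dplyr::bind_rows(exact, super)
}

#' Resolve candidate names to a submittable taxon
#'
#' Tries the candidate names in order; the first one with exactly one
#' submittable registry record whose name equals the query (case-sensitive;
#' suggestion-style superstring matches are filtered out) wins. If no
#' candidate resolves, a failure object carrying all tried names is returned
#' — resolution failure is data, not an exception. Client transport errors
#' (`magbroker_error_transport`) do propagate: they are retriable and must
#' not be mistaken for "no such taxon".
#'
#' @param candidates a [candidate_names()] tibble (columns `name`, `rank`).
#' @param client a taxonomy client.
#' @return A `taxonomy_assignment` (fields `scientific_name`, `taxid`,
#'   `source = "RESOLVED"`, `rank_used`) or a `taxonomy_failure` (field
#'   `tried`).
#' @export
resolve_taxonomy <- function(candidates, client) {
  stopifnot(nrow(candidates) > 0)
  for (i in seq_len(nrow(candidates))) {
    name <- candidates$name[i]
    hits <- query_taxon(client, name)
    hits <- hits[hits$scientific_name == name & hits$submittable, , drop = FALSE]
    if (nrow(hits) == 1L) {
      return(taxonomy_assignment(name, hits$taxid[1], source = "RESOLVED",
                                 rank_used = candidates$rank[i]))
    }
  }
  structure(list(tried = candidates$name), class = "taxonomy_failure")
}

#' Construct a taxonomy assignment
#' @param scientific_name resolved environmental scientific name.
#' @param taxid positive integer taxon identifier.
#' @param source `"RESOLVED"` (from the registry) or `"USER"` (manual
#'   override in the configuration).
#' @param rank_used rank the name was derived from, or `"NONE"`.
#' @return An object of class `taxonomy_assignment`.
#' @export
taxonomy_assignment <- function(scientific_name, taxid,
                                source = c("RESOLVED", "USER"),
                                rank_used = "NONE") {
  source <- match.arg(source)
  taxid <- as.integer(taxid)
  if (is.na(taxid) || taxid <= 0) {
    stop_magbroker("format", "taxid must be a positive integer")
  }
  structure(list(scientific_name = scientific_name, taxid = taxid,
                 source = source, rank_used = rank_used),
            class = "taxonomy_assignment")
}

#' Resolve taxonomy for every bin and MAG
#'
#' Applies the candidate-name rules and registry resolution to each genome
#' record. Manual overrides bypass the client entirely (`source = "USER"`).
#' Failures are aggregated, never raised one by one: the caller gets the
#' complete list of problematic bins in one pass, and the orchestrator
#' refuses to submit anything while that list is nonempty.
#'
#' @param genomes tibble with columns `bin_id` and `lineage` (raw
#'   classification string; may be `NA` for override-only rows).
#' @param client a taxonomy client.
#' @param overrides named list mapping `bin_id` to a [taxonomy_assignment()].
#' @return A list with `assignments` (tibble: `bin_id`, `scientific_name`,
#'   `taxid`, `source`, `rank_used`) and `failures` (tibble: `bin_id`,
#'   `tried`, `message`).
#' @export
resolve_all <- function(genomes, client, overrides = list()) {
  assignments <- list(); failures <- list()
  for (i in seq_len(NROW(genomes))) {
    id <- genomes$bin_id[i]
    if (!is.null(overrides[[id]])) {
      ov <- overrides[[id]]
      assignments[[length(assignments) + 1L]] <- tibble::tibble(
        bin_id = id, scientific_name = ov$scientific_name, taxid = ov$taxid,
        source = "USER", rank_used = ov$rank_used)
      next
    }
    res <- tryCatch({
      lin <- parse_lineage(genomes$lineage[i] %|NA|% "")
      resolve_taxonomy(candidate_names(lin), client)
    }, magbroker_error_empty_lineage = function(e) failure_of(e),
       magbroker_error_dialect = function(e) failure_of(e))
    if (inherits(res, "taxonomy_assignment")) {
      assignments[[length(assignments) + 1L]] <- tibble::tibble(
        bin_id = id, scientific_name = res$scientific_name, taxid = res$taxid,
        source = res$source, rank_used = res$rank_used)
    } else {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        bin_id = id, tried = paste(res$tried, collapse = "; "),
        message = res$message %||% sprintf(
          "no submittable exact-match taxon for any of: %s",
          paste(res$tried, collapse = "; ")))
    }
  }
  list(
    assignments = bind_or_empty(assignments,
      tibble::tibble(bin_id = character(), scientific_name = character(),
                     taxid = integer(), source = character(),
                     rank_used = character())),
    failures = bind_or_empty(failures,
      tibble::tibble(bin_id = character(), tried = character(),
                     message = character()))
  )
}

failure_of <- function(e) {
  structure(list(tried = character(), message = conditionMessage(e)),
            class = "taxonomy_failure")
}

bind_or_empty <- function(rows, empty) {
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}

`%|NA|%` <- function(x, y) if (is.null(x) || is.na(x)) y else x
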