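#' Configure service endpoints
#'
#' Bundles the three service contracts a run talks to: `register` (takes a
#' sample-set XML string, returns receipt XML), `uploader` (takes a
#' [stage_item()] result, returns a `receipt`), and `taxonomy_client`
#' (answers [query_taxon()]). `DEVELOPMENT` is the default mode — the
#' registry's test side, where submissions are validated but not published.
#' `PRODUCTION` requires the explicit `accept_production` opt-in and is
#' unreachable without it.
#'
#' @param register function(xml_text) -> receipt XML.
#' @param uploader function(staged_item) -> `receipt`.
#' @param taxonomy_client a taxonomy client, see [fixture_taxonomy_client()].
#' @param mode `"DEVELOPMENT"` (default) or `"PRODUCTION"`.
#' @param accept_production must be `TRUE` to select `PRODUCTION`.
#' @return A list of class `service_endpoints`.
#' @export
service_endpoints <- function(register, uploader, taxonomy_client,
                              mode = c("DEVELOPMENT", "PRODUCTION"),
                              accept_production = FALSE) {
  mode <- match.arg(mode)
  if (mode == "PRODUCTION" && !isTRUE(accept_production)) {
    stop_magbroker("production_optin",
      "PRODUCTION mode needs the explicit accept_production opt-in")
  }
  structure(list(register = register, uploader = uploader,
                 taxonomy_client = taxonomy_client, mode = mode),
            class = "service_endpoints")
}

#' Endpoints backed by one mock registry
#' @param registry a [mock_registry()].
#' @inheritParams service_endpoints
#' @return A `service_endpoints` whose three contracts all talk to `registry`.
#' @export
mock_endpoints <- function(registry = mock_registry(), mode = "DEVELOPMENT",
                           accept_production = FALSE) {
  service_endpoints(
    register = function(xml) mock_register(registry, xml),
    uploader = function(staged) mock_upload(registry, staged),
    taxonomy_client = registry,
    mode = mode, accept_production = accept_production)
}

#' Execute a submission plan
#'
#' Runs the plan step by step against the endpoints, parsing every receipt
#' and adding its accessions to the ledger before any dependent step runs.
#' Pre-existing accessions seed the ledger first. A nonempty taxonomy
#' failure list refuses to start — nothing is submitted while any bin is
#' unresolved (the halt property). Coverage still unset after configuration
#' is inferred from the aux alignment map (assembly-wide, then per bin
#' restricted to the bin's contigs) before the first upload. The first
#' failed receipt aborts the run; the returned report lists completed steps
#' and the accessions assigned up to the abort. With `dry_run = TRUE`,
#' inference, document generation and staging all happen but no service call
#' is made and the ledger stays empty. Transport failures are retried 3
#' times with backoff, then re-raised with the step index; receipt-level
#' failures are never retried.
#'
#' @param plan a [plan_submission()] result.
#' @param config the matching [parse_config()] result.
#' @param endpoints a [service_endpoints()].
#' @param resolution a [resolve_all()] result for the configured bins/MAGs
#'   (may be `NULL` when the plan has no bin/MAG steps).
#' @param dry_run logical.
#' @param workdir staging root directory.
#' @return A list of class `submission_run`: `success`, `ledger`, `report`
#'   (tibble `step`, `kind`, `alias`, `status`, `accession`, `message`),
#'   `staged` (list of `staged_item`s).
#' @export
execute_plan <- function(plan, config, endpoints, resolution = NULL,
                         dry_run = FALSE,
                         workdir = file.path(tempdir(), "magbroker-staging")) {
  stopifnot(inherits(plan, "submission_plan"),
            inherits(endpoints, "service_endpoints"))
  failures <- resolution$failures
  if (!is.null(failures) && nrow(failures) > 0) {
    stop_magbroker("halt",
      sprintf("taxonomy unresolved for %d bin(s)/MAG(s): %s; nothing was submitted",
              nrow(failures), paste(failures$bin_id, collapse = ", ")),
      failures = failures)
  }
  needs_assignments <- any(vapply(plan$payload, function(p)
    identical(p$target, "bin") || identical(p$target, "mag"), logical(1)))
  if (needs_assignments &&
      (is.null(resolution) || nrow(resolution$assignments) == 0)) {
    stop_magbroker("precondition",
      "plan contains bin/MAG steps but no taxonomy resolution was supplied")
  }

  scenario <- attr(plan, "scenario")
  ledger <- accession_ledger()
  for (lv in names(scenario$preexisting)) {
    kind <- switch(lv, SAMPLES = "SAMPLE", ASSEMBLY = "ANALYSIS",
                   BINS = "ANALYSIS", READS = "RUN", "ANALYSIS")
    for (acc in scenario$preexisting[[lv]]) {
      ledger <- ledger_add(ledger, acc, kind, acc, step = 0L)
    }
  }

  # document generation during a dry run resolves references against a
  # placeholder ledger (pattern-shaped dummy accessions for every alias the
  # plan would produce); the run ledger itself stays empty
  doc_ledger <- function() if (dry_run) dry_run_ledger(plan, ledger) else ledger

  covs <- infer_coverages(plan, config)
  report_rows <- list(); staged_items <- list()
  note <- function(step, kind, alias, status, accession = NA_character_,
                   message = NA_character_) {
    report_rows[[length(report_rows) + 1L]] <<- tibble::tibble(
      step = step, kind = kind, alias = alias, status = status,
      accession = accession, message = message)
  }
  run_result <- function(success) {
    structure(list(success = success, ledger = ledger,
                   report = bind_or_empty(report_rows, tibble::tibble(
                     step = integer(), kind = character(), alias = character(),
                     status = character(), accession = character(),
                     message = character())),
                   staged = staged_items),
              class = "submission_run")
  }

  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]; alias <- plan$alias[i]; payload <- plan$payload[[i]]
    step <- plan$step[i]
    log_msg("INFO", sprintf("step %d/%d [%s] %s (%s mode%s)", step, nrow(plan),
                            kind, alias %|NA|% "samples", endpoints$mode,
                            if (dry_run) ", dry run" else ""))
    if (kind == "REGISTER_SAMPLES") {
      xml <- build_sample_set(physical_samples_tbl(config))
      if (dry_run) { note(step, kind, alias, "DRY_RUN"); next }
      receipt <- parse_receipt(with_transport_retry(endpoints$register(xml),
                                                    step))
      if (!receipt$success) {
        note(step, kind, alias, "FAILED", message = receipt_message(receipt))
        return(run_result(FALSE))
      }
      for (j in seq_len(nrow(receipt$assignments))) {
        a <- receipt$assignments[j, ]
        ledger <- ledger_add(ledger, a$alias, "SAMPLE", a$accession, step = step)
        note(step, kind, a$alias, "DONE", accession = a$accession)
      }
    } else if (kind == "REGISTER_VIRTUAL_SAMPLE") {
      vs <- virtual_sample_row(payload, alias, config, resolution, covs,
                               doc_ledger())
      xml <- build_sample_set(vs)
      if (dry_run) { note(step, kind, alias, "DRY_RUN"); next }
      receipt <- parse_receipt(with_transport_retry(endpoints$register(xml),
                                                    step))
      if (!receipt$success) {
        note(step, kind, alias, "FAILED", message = receipt_message(receipt))
        return(run_result(FALSE))
      }
      a <- receipt$assignments[1, ]
      ledger <- ledger_add(ledger, a$alias, "SAMPLE", a$accession, step = step)
      note(step, kind, alias, "DONE", accession = a$accession)
    } else {
      staged <- stage_upload_step(kind, alias, payload, config, resolution,
                                  covs, doc_ledger(), workdir)
      staged_items[[length(staged_items) + 1L]] <- staged
      if (dry_run) { note(step, kind, alias, "DRY_RUN"); next }
      receipt <- with_transport_retry(endpoints$uploader(staged), step)
      if (!receipt$success) {
        note(step, kind, alias, "FAILED", message = receipt_message(receipt))
        return(run_result(FALSE))
      }
      a <- receipt$assignments[1, ]
      led_kind <- if (kind == "UPLOAD_READS") "RUN" else "ANALYSIS"
      ledger <- ledger_add(ledger, a$alias, led_kind, a$accession, step = step)
      note(step, kind, alias, "DONE", accession = a$accession)
    }
  }
  run_result(TRUE)
}

dry_run_ledger <- function(plan, seeded) {
  led <- seeded
  counters <- c(SAMPLE = 0L, RUN = 0L, ANALYSIS = 0L)
  dummy <- function(kind) {
    counters[[kind]] <<- counters[[kind]] + 1L
    sprintf("%s%07d", c(SAMPLE = "ERS", RUN = "ERR", ANALYSIS = "ERZ")[[kind]],
            counters[[kind]])
  }
  for (i in seq_len(nrow(plan))) {
    kind <- plan$kind[i]
    if (kind == "REGISTER_SAMPLES") {
      for (a in plan$payload[[i]]$aliases) {
        led <- ledger_add(led, a, "SAMPLE", dummy("SAMPLE"), step = plan$step[i])
      }
    } else {
      lk <- switch(kind, REGISTER_VIRTUAL_SAMPLE = "SAMPLE",
                   UPLOAD_READS = "RUN", "ANALYSIS")
      led <- ledger_add(led, plan$alias[i], lk, dummy(lk), step = plan$step[i])
    }
  }
  led
}

receipt_message <- function(receipt) {
  if (nrow(receipt$messages) == 0) return("service reported failure")
  paste(sprintf("%s: %s", receipt$messages$severity, receipt$messages$text),
        collapse = " | ")
}

with_transport_retry <- function(expr, step, times = 3L, backoff = 0.2) {
  expr <- substitute(expr)
  env <- parent.frame()
  for (attempt in seq_len(times)) {
    res <- tryCatch(eval(expr, env), magbroker_error_transport = function(e) e)
    if (!is_magbroker_error(res, "transport")) return(res)
    if (attempt < times) Sys.sleep(backoff * attempt)
  }
  stop_magbroker("transport",
    sprintf("step %d: transport failed after %d attempts: %s", step, times,
            conditionMessage(res)),
    step = step)
}

# physical sample records as a build_sample_set() input; collection date and
# location become checklist-named attributes, user extras are appended
physical_samples_tbl <- function(config) {
  s <- config$samples
  attrs <- purrr::pmap(list(s$collection_date, s$location, s$attributes),
                       function(cd, loc, extra) {
    c(list("collection date" = cd,
           "geographic location (country and/or sea)" = loc),
      extra)
  })
  tibble::tibble(alias = s$alias, title = s$title, taxid = s$taxid,
                 scientific_name = s$scientific_name, attributes = attrs)
}

genome_record <- function(config, payload) {
  tbl <- if (payload$target == "mag") config$mags else config$bins
  tbl[payload$index, ]
}

virtual_sample_row <- function(payload, alias, config, resolution, covs, ledger) {
  origin <- assembly_origin_refs(config)
  if (identical(payload$target, "assembly")) {
    asm <- config$assembly
    assignment <- taxonomy_assignment("metagenome", 256318L, source = "USER",
                                      rank_used = "NONE")
    return(build_virtual_sample(
      alias, sprintf("virtual sample for co-assembly %s", asm$name[1]),
      assignment, origin, ledger,
      extra = list("assembly software" = asm$program[1])))
  }
  g <- genome_record(config, payload)
  asg <- resolution$assignments[resolution$assignments$bin_id == g$bin_id, ]
  if (nrow(asg) == 0) {
    stop_magbroker("precondition",
      sprintf("no taxonomy assignment for '%s'", g$bin_id))
  }
  assignment <- taxonomy_assignment(asg$scientific_name[1], asg$taxid[1],
                                    source = asg$source[1],
                                    rank_used = asg$rank_used[1])
  qt <- aux_table(config, "quality_table", read_quality_table)
  build_virtual_sample(
    alias, sprintf("virtual sample for %s %s", payload$target, g$bin_id),
    assignment, origin, ledger,
    quality = genome_quality(g, qt),
    binning_software = g$binning_software)
}

stage_upload_step <- function(kind, alias, payload, config, resolution, covs,
                              ledger, workdir) {
  study <- config$study
  if (kind == "UPLOAD_READS") {
    rs <- config$read_sets[payload$index, ]
    manifest <- build_manifest("reads", rs, ledger, study, rs$sample)
    files <- vapply(rs$files[[1]], function(f) resolve_path(config, f),
                    character(1), USE.NAMES = FALSE)
    return(stage_item(alias, "reads", files, manifest, workdir))
  }
  platform <- if (nrow(config$read_sets) > 0) config$read_sets$platform[1]
              else "unspecified"
  if (kind == "UPLOAD_ASSEMBLY") {
    asm <- config$assembly
    origin <- assembly_origin_refs(config)
    anchor <- if (length(origin) > 1) paste0("vs_", asm$name[1]) else origin[1]
    manifest <- build_manifest("assembly", asm, ledger, study, anchor,
                               run_refs = asm$runs[[1]],
                               coverage = covs$assembly, platform = platform)
    return(stage_item(alias, "assembly", resolve_path(config, asm$fasta[1]),
                      manifest, workdir))
  }
  level <- if (kind == "UPLOAD_MAG") "mag" else "bin"
  g <- genome_record(config, list(target = level, index = payload$index))
  manifest <- build_manifest(level, g, ledger, study, paste0("vs_", g$bin_id),
                             coverage = covs$genomes[[g$bin_id]],
                             platform = platform)
  stage_item(alias, level, resolve_path(config, g$fasta[1]), manifest, workdir)
}

# coverage inference pass: assembly-wide first, then per bin/MAG restricted
# to the bin's contigs; anything with an explicit configured value is skipped
infer_coverages <- function(plan, config) {
  out <- list(assembly = NULL, genomes = list())
  alignment <- config$aux$alignment
  have_map <- !is.na(alignment)
  if (have_map) alignment <- resolve_path(config, alignment)
  kinds <- plan$kind
  if ("UPLOAD_ASSEMBLY" %in% kinds && !is.null(config$assembly) &&
      is.na(config$assembly$coverage[1])) {
    if (!have_map) {
      stop_magbroker("precondition",
        "assembly coverage is unset and no alignment map is configured")
    }
    out$assembly <- compute_coverage(alignment)
  }
  genome_steps <- which(kinds %in% c("UPLOAD_BIN", "UPLOAD_MAG"))
  for (i in genome_steps) {
    level <- if (kinds[i] == "UPLOAD_MAG") "mag" else "bin"
    g <- genome_record(config, list(target = level, index = plan$payload[[i]]$index))
    if (!is.na(g$coverage)) next
    if (!have_map) {
      stop_magbroker("precondition",
        sprintf("coverage for '%s' is unset and no alignment map is configured",
                g$bin_id))
    }
    contig_names <- names(Biostrings::fasta.seqlengths(resolve_path(config,
                                                                    g$fasta[1])))
    out$genomes[[g$bin_id]] <- compute_coverage(alignment,
                                                restrict_to = contig_names)
  }
  out
}

#' Write the accession summary file
#'
#' @param ledger the run's [accession_ledger()].
#' @param path output path.
#' @return The path, invisibly. The file is tab-separated with columns
#'   `alias`, `kind`, `accession`, `step`; an empty ledger yields a
#'   header-only file.
#' @export
write_summary <- function(ledger, path) {
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop_magbroker("io", sprintf("cannot write summary to '%s'", path))
  })
  on.exit(close(con))
  lines <- c("alias\tkind\taccession\tstep",
             sprintf("%s\t%s\t%s\t%d", ledger$alias, ledger$kind,
                     ledger$accession, ledger$step))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

log_msg <- function(level, msg) {
  levels <- c(DEBUG = 1L, INFO = 2L, WARN = 3L, ERROR = 4L)
  threshold <- toupper(getOption("magbroker.log_level", "WARN"))
  if (levels[[level]] >= (levels[[threshold]] %||% 3L)) {
    cat(sprintf("[%s] %s\n", level, msg), file = stderr())
  }
}

#' @export
print.submission_run <- function(x, ...) {
  cat(sprintf("<submission_run: %s, %d ledger entr%s>\n",
              if (x$success) "success" else "ABORTED", nrow(x$ledger),
              if (nrow(x$ledger) == 1) "y" else "ies"))
  invisible(x)
}
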