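# Shared fixtures and independent oracles, all built in code at test time.

`%||%` <- rlang::`%||%`

# run the whole pipeline on a toy dataset (validate -> resolve -> plan ->
# execute) against a mock registry
toy_run <- function(toy, scenario = toy_scenario(), registry = mock_registry(),
                    dry_run = FALSE, endpoints = NULL, workdir = NULL) {
  cfg <- parse_config(toy$config_path)
  rep <- validate_config(cfg, scenario)
  stopifnot(!report_has_errors(rep))
  res <- resolve_all(magbroker:::genomes_for_resolution(cfg, scenario), registry)
  plan <- plan_submission(scenario, cfg, rep)
  run <- execute_plan(plan, cfg, endpoints %||% mock_endpoints(registry),
                      resolution = res, dry_run = dry_run,
                      workdir = workdir %||% file.path(toy$dir, "staging"))
  list(cfg = cfg, rep = rep, res = res, plan = plan, run = run,
       registry = registry)
}

# toy dataset in a self-deleting temp dir
local_toy <- function(..., env = parent.frame()) {
  dir <- withr::local_tempdir(.local_envir = env)
  generate_toy_dataset(file.path(dir, "toy"), ...)
}

toy_scenario <- function() {
  submission_scenario(c("samples", "reads", "assembly", "bins"))
}

# Brute-force per-position depth oracle for fold coverage: parses the SAM
# text directly and walks every reference-consuming CIGAR operation
# position by position. Independent of the package's Rsamtools-based path.
oracle_coverage <- function(sam_path, restrict_to = NULL) {
  lines <- readLines(sam_path, warn = FALSE)
  sq <- lines[startsWith(lines, "@SQ")]
  lens <- integer()
  for (l in sq) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    nm <- sub("^SN:", "", f[startsWith(f, "SN:")])
    lens[[nm]] <- as.integer(sub("^LN:", "", f[startsWith(f, "LN:")]))
  }
  keep_refs <- if (is.null(restrict_to)) names(lens) else restrict_to
  depth <- lapply(lens[keep_refs], function(L) integer(L))
  for (l in lines[!startsWith(lines, "@")]) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 0x4) > 0 || bitwAnd(flag, 0x100) > 0 ||
        bitwAnd(flag, 0x800) > 0) next
    rname <- f[3]
    if (!rname %in% keep_refs) next
    pos <- as.integer(f[4])
    ops <- regmatches(f[6], gregexpr("\\d+[MIDNSHP=X]", f[6]))[[1]]
    at <- pos
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]$", "", op))
      type <- sub("^\\d+", "", op)
      if (type %in% c("M", "=", "X", "D", "N")) {
        if (type != "N") {
          depth[[rname]][at:(at + n - 1L)] <- depth[[rname]][at:(at + n - 1L)] + 1L
        }
        at <- at + n
      }
    }
  }
  aligned <- sum(vapply(depth, function(d) sum(as.numeric(d)), numeric(1)))
  list(aligned_bases = aligned, reference_length = sum(as.numeric(lens[keep_refs])),
       fold = aligned / sum(as.numeric(lens[keep_refs])))
}

# write a SAM file from a header spec and record lines
write_sam <- function(path, ref_lengths, records = character()) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), ref_lengths),
               records), path, useBytes = TRUE)
  path
}

sam_record <- function(qname, flag, rname, pos, cigar) {
  qlen <- sum(as.integer(
    sub("[A-Z=]$", "",
        regmatches(cigar, gregexpr("\\d+[MIS=X]", cigar))[[1]])))
  seq <- strrep("A", max(qlen, 1L))
  paste(qname, flag, rname, pos, 60L, cigar, "*", 0L, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

# randomized small SAM for property tests; mixes mapped/unmapped/secondary/
# supplementary records and M/D/I/S CIGAR shapes
random_sam <- function(path, seed) {
  set.seed(seed)
  n_refs <- sample(2:4, 1)
  lens <- stats::setNames(sample(60:200, n_refs, replace = TRUE),
                          sprintf("ctg%d", seq_len(n_refs)))
  n_rec <- sample(0:25, 1)
  recs <- character(n_rec)
  for (i in seq_len(n_rec)) {
    flag <- sample(c(0L, 0L, 0L, 16L, 4L, 256L, 2048L), 1)
    ref <- sample(names(lens), 1)
    shape <- sample(1:4, 1)
    m1 <- sample(10:30, 1)
    cigar <- switch(shape,
      sprintf("%dM", m1),
      sprintf("%dM%dD%dM", m1, sample(1:5, 1), sample(5:15, 1)),
      sprintf("%dS%dM", sample(1:8, 1), m1),
      sprintf("%dM%dI%dM", m1, sample(1:4, 1), sample(5:15, 1)))
    ref_span <- sum(as.integer(sub("[A-Z=]$", "", regmatches(cigar,
      gregexpr("\\d+[MDN=X]", cigar))[[1]])))
    max_pos <- lens[[ref]] - ref_span + 1L
    if (max_pos < 1L) { cigar <- "10M"; ref_span <- 10L; max_pos <- lens[[ref]] - 9L }
    recs[i] <- sam_record(sprintf("r%d", i), flag, ref,
                          sample.int(max_pos, 1), cigar)
  }
  write_sam(path, lens, recs)
  lens
}

# fill a scenario template with the toy dataset's values and write it next
# to the toy files so relative paths resolve
fill_template <- function(scenario, toy) {
  filled <- yaml::yaml.load(make_template(scenario))
  toy_cfg <- yaml::yaml.load(paste(readLines(toy$config_path), collapse = "\n"))
  for (key in c("study", "samples", "read_sets", "assembly", "bins", "mags", "aux")) {
    if (!is.null(filled[[key]]) && !is.null(toy_cfg[[key]])) {
      filled[[key]] <- toy_cfg[[key]]
    }
  }
  path <- file.path(toy$dir, "filled_config.yaml")
  writeLines(yaml::as.yaml(filled), path, useBytes = TRUE)
  path
}

# taxonomy client doubles
failing_client <- function() {
  structure(list(), class = c("failing_client", "taxonomy_client"))
}
query_taxon.failing_client <- function(client, name) {
  magbroker:::stop_magbroker("transport", "connection refused")
}
registerS3method("query_taxon", "failing_client", query_taxon.failing_client,
                 envir = asNamespace("magbroker"))

recording_client <- function(inner) {
  e <- new.env()
  e$inner <- inner
  e$queries <- character()
  class(e) <- c("recording_client", "taxonomy_client")
  e
}
query_taxon.recording_client <- function(client, name) {
  client$queries <- c(client$queries, name)
  query_taxon(client$inner, name)
}
registerS3method("query_taxon", "recording_client", query_taxon.recording_client,
                 envir = asNamespace("magbroker"))

# an uploader wrapper that fails (receipt-level) from the nth call on
failing_uploader_after <- function(registry, n) {
  count <- 0L
  function(staged) {
    count <<- count + 1L
    if (count >= n) {
      structure(list(success = FALSE,
                     assignments = tibble::tibble(kind = character(),
                                                  alias = character(),
                                                  accession = character()),
                     messages = tibble::tibble(severity = "ERROR",
                                               text = "upload rejected")),
                class = "receipt")
    } else {
      mock_upload(registry, staged)
    }
  }
}
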