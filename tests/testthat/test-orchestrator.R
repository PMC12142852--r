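test_that("the co-assembly scenario plans 11 dependency-ordered steps", {
  toy <- local_toy(seed = 7)
  cfg <- parse_config(toy$config_path)
  rep <- validate_config(cfg, toy_scenario())
  plan <- plan_submission(toy_scenario(), cfg, rep)
  # 1 sample registration + 2 read uploads + 1 co-assembly virtual sample +
  # 1 assembly upload + 3 x (virtual sample + bin upload)
  expect_equal(nrow(plan), 11L)
  expect_equal(plan$kind[1], "REGISTER_SAMPLES")
  expect_equal(sum(plan$kind == "UPLOAD_READS"), 2L)
  expect_equal(sum(plan$kind == "REGISTER_VIRTUAL_SAMPLE"), 4L)
  expect_equal(sum(plan$kind == "UPLOAD_BIN"), 3L)
  expect_true(plan_is_topological(plan))

  expect_error(plan_submission(toy_scenario(), cfg,
    structure(tibble::tibble(severity = "ERROR", locus = "x", message = "y"),
              class = c("validation_report", class(tibble::tibble())))),
    class = "magbroker_error_precondition")
})

test_that("plans stay topological across randomized scenario/record sizes", {
  set.seed(23)
  for (i in 1:12) {
    toy <- local_toy(seed = 100 + i, n_samples = sample(1:3, 1),
                     n_readpairs_per_sample = sample(1:2, 1),
                     n_bins = sample(1:4, 1), reads_per_set = 4L)
    levels <- c("samples", "reads", "assembly",
                if (runif(1) < 0.7) "bins")
    scen <- submission_scenario(levels)
    cfg <- parse_config(toy$config_path)
    rep <- validate_config(cfg, scen)
    plan <- plan_submission(scen, cfg, rep)
    expect_true(plan_is_topological(plan), info = paste("iteration", i))
    # each payload appears exactly once per level
    expect_false(any(duplicated(stats::na.omit(plan$alias))))
  }
})

test_that("extending a deposited study plans only bin steps and seeds the ledger", {
  toy <- local_toy(seed = 19)
  pre <- list(SAMPLES = c("ERS9000001", "ERS9000002"), ASSEMBLY = "ERZ9000001")
  scen <- submission_scenario("bins", preexisting = pre)
  # rewrite the toy config into extension form
  cfg_doc <- yaml::yaml.load(paste(readLines(toy$config_path), collapse = "\n"))
  cfg_doc$samples <- NULL; cfg_doc$read_sets <- NULL; cfg_doc$assembly <- NULL
  cfg_doc$sample_accessions <- pre$SAMPLES
  cfg_doc$assembly_accession <- pre$ASSEMBLY
  ext_path <- file.path(toy$dir, "extension.yaml")
  writeLines(yaml::as.yaml(cfg_doc), ext_path)
  toy$config_path <- ext_path

  out <- toy_run(toy, scenario = scen)
  expect_true(out$run$success)
  expect_true(all(out$plan$kind %in% c("REGISTER_VIRTUAL_SAMPLE", "UPLOAD_BIN")))
  # seeded pre-existing accessions (step 0) plus 2 per bin
  seeded <- out$run$ledger[out$run$ledger$step == 0L, ]
  expect_setequal(seeded$accession, unlist(pre))
  expect_equal(nrow(out$run$ledger), 3L + 2L * 3L)
  # bin virtual samples derive from the pre-existing sample accessions
  expect_match(
    out$run$report$status[out$run$report$kind == "REGISTER_VIRTUAL_SAMPLE"],
    "DONE", all = TRUE)
})

test_that("a full toy run yields one accession per object and a faithful summary", {
  toy <- local_toy(seed = 7)
  out <- toy_run(toy)
  run <- out$run
  expect_true(run$success)
  expect_equal(nrow(run$ledger), 12L)
  counts <- table(run$ledger$kind)
  expect_equal(unname(counts[["SAMPLE"]]), 6L) # 2 physical + 1 co-assembly + 3 bins
  expect_equal(unname(counts[["RUN"]]), 2L)
  expect_equal(unname(counts[["ANALYSIS"]]), 4L) # assembly + 3 bins

  sm <- file.path(toy$dir, "summary.tsv")
  write_summary(run$ledger, sm)
  rows <- readLines(sm)
  expect_equal(length(rows), 13L)
  expect_equal(rows[1], "alias\tkind\taccession\tstep")

  empty <- file.path(toy$dir, "empty.tsv")
  write_summary(accession_ledger(), empty)
  expect_equal(readLines(empty), "alias\tkind\taccession\tstep")
})

test_that("taxonomy failures halt the run before any service interaction", {
  toy <- local_toy(seed = 7, unresolvable_bin = TRUE)
  registry <- mock_registry()
  cfg <- parse_config(toy$config_path)
  rep <- validate_config(cfg, toy_scenario())
  res <- resolve_all(magbroker:::genomes_for_resolution(cfg, toy_scenario()),
                     registry)
  expect_equal(nrow(res$failures), 1L)
  plan <- plan_submission(toy_scenario(), cfg, rep)
  err <- tryCatch(
    execute_plan(plan, cfg, mock_endpoints(registry), resolution = res),
    magbroker_error_halt = function(e) e)
  expect_s3_class(err, "magbroker_error_halt")
  expect_match(conditionMessage(err), res$failures$bin_id[1], fixed = TRUE)
  expect_equal(registry$calls, 0L)
})

test_that("dry runs stage everything but call no service and assign nothing", {
  toy <- local_toy(seed = 13)
  registry <- mock_registry()
  out <- toy_run(toy, registry = registry, dry_run = TRUE,
                 workdir = file.path(toy$dir, "dry-staging"))
  expect_true(out$run$success)
  expect_equal(nrow(out$run$ledger), 0L)
  expect_equal(registry$calls, 0L)
  expect_gt(length(out$run$staged), 0L)
  for (st in out$run$staged) {
    expect_true(file.exists(st$manifest_path))
    expect_true(all(file.exists(st$data_files)))
  }
})

test_that("the first failed receipt aborts with accessions assigned so far", {
  toy <- local_toy(seed = 31)
  registry <- mock_registry()
  endpoints <- service_endpoints(
    register = function(xml) mock_register(registry, xml),
    uploader = failing_uploader_after(registry, 2L),
    taxonomy_client = registry)
  out <- toy_run(toy, registry = registry, endpoints = endpoints)
  run <- out$run
  expect_false(run$success)
  # samples (2) + first read upload succeeded; second upload was rejected
  expect_equal(nrow(run$ledger), 3L)
  expect_equal(sum(run$report$status == "FAILED"), 1L)
  expect_match(run$report$message[run$report$status == "FAILED"],
               "upload rejected")
  sm <- file.path(toy$dir, "aborted.tsv")
  write_summary(run$ledger, sm)
  expect_equal(length(readLines(sm)), 4L)
})

test_that("transport failures retry and then surface with the step index", {
  toy <- local_toy(seed = 37)
  registry <- mock_registry()
  attempts <- 0L
  endpoints <- service_endpoints(
    register = function(xml) {
      attempts <<- attempts + 1L
      magbroker:::stop_magbroker("transport", "connection reset")
    },
    uploader = function(staged) mock_upload(registry, staged),
    taxonomy_client = registry)
  err <- tryCatch(toy_run(toy, registry = registry, endpoints = endpoints),
                  magbroker_error_transport = function(e) e)
  expect_s3_class(err, "magbroker_error_transport")
  expect_equal(attempts, 3L)
  expect_equal(err$step, 1L)
})

test_that("two identical toy runs produce byte-identical summaries and manifests", {
  results <- lapply(1:2, function(i) {
    toy <- local_toy(seed = 7)
    out <- toy_run(toy, workdir = file.path(toy$dir, "staging"))
    sm <- file.path(toy$dir, "summary.tsv")
    write_summary(out$run$ledger, sm)
    manifests <- sort(list.files(file.path(toy$dir, "staging"),
                                 pattern = "manifest.txt", recursive = TRUE,
                                 full.names = TRUE))
    list(summary = readBin(sm, "raw", file.size(sm)),
         manifests = lapply(manifests, function(p)
           readBin(p, "raw", file.size(p))))
  })
  expect_identical(results[[1]]$summary, results[[2]]$summary)
  expect_identical(results[[1]]$manifests, results[[2]]$manifests)
})

test_that("PRODUCTION mode is unreachable without the explicit opt-in", {
  expect_error(mock_endpoints(mock_registry(), mode = "PRODUCTION"),
               class = "magbroker_error_production_optin")
  expect_no_error(mock_endpoints(mock_registry(), mode = "PRODUCTION",
                                 accept_production = TRUE))
  expect_equal(mock_endpoints(mock_registry())$mode, "DEVELOPMENT")
})
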