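test_that("the mock registry issues sequential accessions and refuses re-registration", {
  reg <- mock_registry()
  xml <- build_sample_set(tibble::tibble(
    alias = c("s1", "s2"), title = c("a", "b"), taxid = 256318L,
    scientific_name = "metagenome", attributes = list(list(), list())))
  r1 <- parse_receipt(mock_register(reg, xml))
  expect_true(r1$success)
  expect_equal(r1$assignments$accession, c("ERS0000001", "ERS0000002"))

  r2 <- parse_receipt(mock_register(reg, xml))
  expect_false(r2$success)
  expect_match(r2$messages$text, "already exists", all = FALSE)

  r3 <- parse_receipt(mock_register(reg, "<not-xml"))
  expect_false(r3$success)
  expect_equal(nrow(r3$assignments), 0L)
})

test_that("the mock taxonomy endpoint returns exact then superstring matches", {
  reg <- mock_registry()
  hits <- mock_taxonomy_query(reg, "uncultured Enterobacteriaceae bacterium")
  expect_equal(hits$taxid[1], 218034L)
  expect_true(hits$submittable[1])

  fam <- mock_taxonomy_query(reg, "Enterobacteriaceae")
  expect_true(543L %in% fam$taxid)
  expect_false(fam$submittable[fam$taxid == 543])
  # the superstring record (218034) follows the exact one
  expect_equal(fam$taxid[1], 543L)
  expect_true(218034L %in% fam$taxid)

  expect_equal(nrow(mock_taxonomy_query(reg, "no such taxon")), 0L)
})

test_that("the mock uploader validates manifests before issuing accessions", {
  dir <- withr::local_tempdir()
  reg <- mock_registry()
  fa <- file.path(dir, "bin_1.fasta")
  writeLines(c(">c1", "ACGT"), fa)
  led <- ledger_add(accession_ledger(), "vs_bin_1", "SAMPLE", "ERS0000001")
  m <- build_manifest("bin",
    list(bin_id = "bin_1", fasta = fa, binning_software = "x", coverage = 3.2),
    led, "PRJEB00001", "vs_bin_1")
  st <- stage_item("bin_1", "bin", fa, m, file.path(dir, "w"))

  ok <- mock_upload(reg, st)
  expect_true(ok$success)
  expect_match(ok$assignments$accession, "^ERZ\\d{7}$")

  # drop COVERAGE from the staged manifest -> failure naming the key
  lines <- readLines(st$manifest_path)
  writeLines(lines[!startsWith(lines, "COVERAGE")], st$manifest_path)
  st2 <- st; st2$alias <- "bin_other"
  bad <- mock_upload(reg, st2)
  expect_false(bad$success)
  expect_match(bad$messages$text, "COVERAGE")

  # empty staging dir -> failure, no accession
  empty <- structure(list(staging_dir = file.path(dir, "none"),
                          manifest_path = file.path(dir, "none", "manifest.txt"),
                          data_files = character(), level = "bin",
                          alias = "b9"), class = "staged_item")
  r <- mock_upload(reg, empty)
  expect_false(r$success)
  expect_equal(nrow(r$assignments), 0L)
})

test_that("identical call sequences yield identical mock receipts", {
  run_sequence <- function() {
    reg <- mock_registry()
    xml <- build_sample_set(tibble::tibble(
      alias = "s1", title = "a", taxid = 256318L,
      scientific_name = "metagenome", attributes = list(list())))
    c(mock_register(reg, xml), mock_register(reg, xml))
  }
  expect_identical(run_sequence(), run_sequence())
})

test_that("toy datasets are deterministic, well-partitioned and self-consistent", {
  base <- withr::local_tempdir()
  toy1 <- generate_toy_dataset(file.path(base, "a"), seed = 7)
  toy2 <- generate_toy_dataset(file.path(base, "b"), seed = 7)

  files1 <- sort(list.files(toy1$dir, recursive = TRUE))
  expect_identical(files1, sort(list.files(toy2$dir, recursive = TRUE)))
  for (f in files1) {
    expect_identical(
      readBin(file.path(toy1$dir, f), "raw", file.size(file.path(toy1$dir, f))),
      readBin(file.path(toy2$dir, f), "raw", file.size(file.path(toy2$dir, f))),
      label = f)
  }

  # bins partition disjoint subsets of the assembly contigs
  asm <- names(Biostrings::fasta.seqlengths(file.path(toy1$dir, "assembly.fasta")))
  bin_files <- list.files(file.path(toy1$dir, "bins"), full.names = TRUE)
  expect_length(bin_files, 3L)
  bin_contigs <- lapply(bin_files, function(f)
    names(Biostrings::fasta.seqlengths(f)))
  all_bc <- unlist(bin_contigs)
  expect_false(any(duplicated(all_bc)))
  expect_true(all(all_bc %in% asm))

  # config validates cleanly against the generator's own scenario
  rep <- validate_config(parse_config(toy1$config_path), toy_scenario())
  expect_equal(sum(rep$severity == "ERROR"), 0L)

  # quality table spans all three MIMAG tiers
  q <- read_quality_table(file.path(toy1$dir, "checkm_quality.tsv"))
  expect_setequal(classify_mimag(q$completeness, q$contamination),
                  c("HIGH", "MEDIUM", "LOW"))

  # the generated SAM agrees with the generator's own bookkeeping
  cov <- compute_coverage(file.path(toy1$dir, "alignment.sam"))
  expect_equal(cov$aligned_bases, sum(toy1$placed$width))
  expect_equal(cov$fold, toy1$expected_fold)

  # target collision is refused
  expect_error(generate_toy_dataset(toy1$dir, seed = 7),
               class = "magbroker_error_collision")
})
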