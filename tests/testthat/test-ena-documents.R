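sample_tbl <- function(n = 2) {
  tibble::tibble(
    alias = sprintf("s%d", seq_len(n)),
    title = sprintf("toy sample %d", seq_len(n)),
    taxid = 256318L, scientific_name = "metagenome",
    attributes = rep(list(list("collection date" = "2024-06-01",
                               "ph" = "7.2")), n))
}

test_that("sample-set XML carries every record and attribute, round-trippable", {
  xml <- build_sample_set(sample_tbl(2))
  doc <- xml2::read_xml(xml)
  nodes <- xml2::xml_find_all(doc, "./SAMPLE")
  expect_length(nodes, 2L)
  expect_equal(xml2::xml_attr(nodes, "alias"), c("s1", "s2"))
  expect_equal(xml2::xml_text(xml2::xml_find_first(nodes[[1]],
    ".//TAXON_ID")), "256318")
  tags <- xml2::xml_text(xml2::xml_find_all(nodes[[1]],
    ".//SAMPLE_ATTRIBUTE/TAG"))
  vals <- xml2::xml_text(xml2::xml_find_all(nodes[[1]],
    ".//SAMPLE_ATTRIBUTE/VALUE"))
  expect_true("ph" %in% tags)
  expect_equal(vals[tags == "ph"], "7.2")

  dup <- sample_tbl(2); dup$alias <- c("s1", "s1")
  expect_error(build_sample_set(dup), class = "magbroker_error_conflict")
  expect_error(build_sample_set(sample_tbl(0)),
               class = "magbroker_error_empty_set")
})

test_that("virtual samples carry taxon, quality and derived-from accessions", {
  led <- accession_ledger() |>
    ledger_add("s1", "SAMPLE", "ERS0000001") |>
    ledger_add("s2", "SAMPLE", "ERS0000002")
  asg <- taxonomy_assignment("uncultured Enterobacteriaceae bacterium",
                             218034, source = "RESOLVED", rank_used = "family")
  vs <- build_virtual_sample("vs_bin_1", "virtual sample for bin bin_1", asg,
                             origin_refs = "s1", ledger = led,
                             quality = list(completeness = 95.3,
                                            contamination = 2.1),
                             binning_software = "metabat2 v2.15")
  attrs <- vs$attributes[[1]]
  expect_equal(attrs[["sample derived from"]], "ERS0000001")
  expect_equal(attrs[["completeness score"]], "95.3")
  expect_equal(attrs[["contamination score"]], "2.1")
  expect_equal(attrs[["binning software"]], "metabat2 v2.15")
  expect_equal(vs$taxid, 218034L)

  # co-assembly: derived-from lists all origin accessions
  co <- build_virtual_sample("vs_asm", "t", asg, origin_refs = c("s1", "s2"),
                             ledger = led)
  expect_equal(co$attributes[[1]][["sample derived from"]],
               "ERS0000001,ERS0000002")

  expect_error(build_virtual_sample("v", "t", asg, "missing_alias", led),
               class = "magbroker_error_unresolved")
})

test_that("receipts parse into success state, assignments and messages", {
  ok <- parse_receipt(paste0(
    '<RECEIPT success="true">',
    '<SAMPLE alias="s1" accession="ERS0000001"/>',
    '<SAMPLE alias="s2" accession="ERS0000002"/>',
    "</RECEIPT>"))
  expect_true(ok$success)
  expect_equal(nrow(ok$assignments), 2L)
  expect_equal(ok$assignments$kind, c("SAMPLE", "SAMPLE"))
  expect_equal(nrow(ok$messages), 0L)

  bad <- parse_receipt(paste0(
    '<RECEIPT success="false"><MESSAGES>',
    "<ERROR>object with alias s1 already exists</ERROR>",
    "</MESSAGES></RECEIPT>"))
  expect_false(bad$success)
  expect_equal(nrow(bad$assignments), 0L)
  expect_equal(bad$messages$severity, "ERROR")

  # pure-validation responses: success with info only, no assignments
  info <- parse_receipt(
    '<RECEIPT success="true"><MESSAGES><INFO>validated</INFO></MESSAGES></RECEIPT>')
  expect_true(info$success)
  expect_equal(nrow(info$assignments), 0L)

  expect_error(parse_receipt("<RECEIPT"), class = "magbroker_error_parse")
  expect_error(parse_receipt("<RECEIPT><SAMPLE/></RECEIPT>"),
               class = "magbroker_error_format")
})

manifest_fixture <- function(fold = 12.34) {
  led <- ledger_add(accession_ledger(), "vs_bin_1", "SAMPLE", "ERS0000009")
  record <- list(bin_id = "bin_1", fasta = "bins/bin_1.fasta",
                 binning_software = "metabat2 v2.15", coverage = NA)
  build_manifest("bin", record, led, "PRJEB00001", "vs_bin_1",
                 coverage = structure(list(fold = fold),
                                      class = "coverage_stats"),
                 platform = "ILLUMINA")
}

test_that("manifests carry the level key tables with formatted values", {
  m <- manifest_fixture(12.34)
  expect_true(all(mandatory_manifest_keys("bin") %in% m$key))
  expect_equal(m$value[m$key == "COVERAGE"], "12.3")
  expect_equal(m$value[m$key == "ASSEMBLY_TYPE"], "binned metagenome")
  expect_equal(m$value[m$key == "SAMPLE"], "ERS0000009")

  # round-half-even on the one-decimal coverage format (12.25 is exactly
  # representable, so the half rounds to the even digit)
  expect_equal(manifest_fixture(12.25)$value[
    manifest_fixture(12.25)$key == "COVERAGE"], "12.2")
  expect_equal(manifest_fixture(12.36)$value[
    manifest_fixture(12.36)$key == "COVERAGE"], "12.4")

  # MAG and assembly level types
  led <- ledger_add(accession_ledger(), "vs_m", "SAMPLE", "ERS0000001")
  mag <- build_manifest("mag", list(bin_id = "m1", fasta = "m.fasta",
                                    binning_software = "x", coverage = 2),
                        led, "PRJEB00001", "vs_m")
  expect_equal(mag$value[mag$key == "ASSEMBLY_TYPE"],
               "Metagenome-Assembled Genome (MAG)")

  # paired read set: two FASTQ entries
  led2 <- ledger_add(accession_ledger(), "s1", "SAMPLE", "ERS0000002")
  rs <- list(alias = "r1", sample = "s1", platform = "ILLUMINA",
             instrument = "MiSeq", library_source = "METAGENOMIC",
             library_selection = "RANDOM", library_strategy = "WGS",
             files = list(c("a_1.fastq", "a_2.fastq")))
  rm <- build_manifest("reads", rs, led2, "PRJEB00001", "s1")
  expect_equal(sum(rm$key == "FASTQ"), 2L)
  expect_true(all(mandatory_manifest_keys("reads") %in% rm$key))

  # missing dependency names the manifest key
  err <- tryCatch(build_manifest("bin", list(bin_id = "b", fasta = "f",
                                             binning_software = "x",
                                             coverage = 1),
                                 accession_ledger(), "PRJEB00001", "vs_none"),
                  magbroker_error_unresolved = function(e) e)
  expect_match(conditionMessage(err), "SAMPLE")
})

test_that("manifest serialization round-trips and rejects embedded tabs", {
  m <- manifest_fixture()
  txt <- serialize_manifest(m)
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(all(vapply(lines, function(l)
    length(strsplit(l, "\t", fixed = TRUE)[[1]]) == 2L, logical(1))))
  back <- parse_manifest(txt, "bin")
  expect_equal(back$key, m$key)
  expect_equal(back$value, m$value)

  expect_error(
    magbroker:::new_manifest(tibble::tibble(key = "K", value = "a\tb"), "bin"),
    class = "magbroker_error_format")
})

test_that("staging is repeatable and refuses foreign directories", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "bin_1.fasta")
  writeLines(c(">c1", "ACGT"), fa)
  m <- manifest_fixture()
  work <- file.path(dir, "staging")

  st <- stage_item("bin_1", "bin", fa, m, work)
  expect_true(file.exists(st$manifest_path))
  expect_true(all(file.exists(st$data_files)))
  expect_equal(st$staging_dir, file.path(work, "bin", "bin_1"))
  staged_manifest <- readBin(st$manifest_path, "raw",
                             file.size(st$manifest_path))
  # manifest references only staged (basename) locations
  m2 <- parse_manifest(rawToChar(staged_manifest), "bin")
  expect_equal(m2$value[m2$key == "FASTA"], "bin_1.fasta")

  # re-staging reproduces byte-identical content
  st2 <- stage_item("bin_1", "bin", fa, m, work)
  expect_identical(readBin(st2$manifest_path, "raw",
                           file.size(st2$manifest_path)), staged_manifest)

  # a foreign non-empty directory is never clobbered
  foreign <- file.path(work, "bin", "bin_2")
  dir.create(foreign, recursive = TRUE)
  writeLines("precious", file.path(foreign, "notes.txt"))
  expect_error(stage_item("bin_2", "bin", fa, m, work),
               class = "magbroker_error_staging")

  expect_error(stage_item("bin_1", "bin", file.path(dir, "nope.fa"), m, work),
               class = "magbroker_error_staging")
})
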