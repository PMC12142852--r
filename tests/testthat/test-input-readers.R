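write_quality_fixture <- function(path, rows, header = "Bin Id\tCompleteness\tContamination") {
  writeLines(c(header, rows), path)
  path
}

test_that("quality tables parse across header dialects and enforce ranges", {
  dir <- withr::local_tempdir()
  p <- write_quality_fixture(file.path(dir, "q.tsv"),
    c("bin_1\t95.3\t2.1", "bin_2\t60\t4", "bin_3\t30\t15"))
  q <- read_quality_table(p)
  expect_equal(nrow(q), 3L)
  expect_equal(q$completeness[q$bin_id == "bin_1"], 95.3)
  expect_equal(q$contamination[q$bin_id == "bin_1"], 2.1)

  # CheckM-style and GTDB-Tk-style identifier headers both work
  p2 <- write_quality_fixture(file.path(dir, "q2.tsv"), "g1\t50\t1",
                              header = "user_genome\tcompleteness\tcontamination")
  expect_equal(read_quality_table(p2)$bin_id, "g1")

  expect_error(read_quality_table(write_quality_fixture(
    file.path(dir, "q3.tsv"), "bin_1\t105\t2")),
    class = "magbroker_error_range")
  expect_error(read_quality_table(write_quality_fixture(
    file.path(dir, "q4.tsv"), "bin_1\t90\t2",
    header = "Bin Id\tFoo\tContamination")),
    class = "magbroker_error_header")
})

test_that("classification tables keep raw strings verbatim and reject duplicates", {
  dir <- withr::local_tempdir()
  raw <- "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__;s__"
  p <- file.path(dir, "t.tsv")
  writeLines(c("user_genome\tclassification",
               paste0("b1\t", raw), "b2\t"), p)
  tt <- read_taxonomy_table(p)
  expect_equal(nrow(tt), 2L)
  expect_identical(tt$classification[tt$bin_id == "b1"], raw)
  expect_identical(tt$classification[tt$bin_id == "b2"], "")

  writeLines(c("user_genome\tclassification", "b1\tx", "b1\ty"), p)
  expect_error(read_taxonomy_table(p), class = "magbroker_error_conflict")
})

test_that("lineage parsing handles GTDB prefixes, empties, and suffix stripping", {
  lin <- parse_lineage(paste0("d__Bacteria;p__Pseudomonadota;",
    "c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__;s__"))
  expect_equal(lin$ranks[["family"]], "Enterobacteriaceae")
  expect_equal(lin$ranks[["genus"]], "")
  expect_equal(lin$dialect, "GTDB")

  only_domain <- parse_lineage("d__Bacteria")
  expect_equal(unname(only_domain$ranks[only_domain$ranks != ""]), "Bacteria")

  strip <- parse_lineage("d__Bacteria;g__Escherichia_B")
  expect_equal(strip$ranks[["genus"]], "Escherichia")
  expect_match(strip$notes, "polyphyletic", all = FALSE)

  plain <- parse_lineage("Bacteria;Pseudomonadota")
  expect_equal(plain$ranks[["phylum"]], "Pseudomonadota")
  expect_equal(plain$dialect, "plain")

  expect_error(parse_lineage("q__Strange;d__Bacteria"),
               class = "magbroker_error_dialect")
})

test_that("parse_lineage is idempotent on its own re-serialized output", {
  cases <- c(
    "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__;s__",
    "d__Archaea;g__Methanococcus_A",
    "d__Bacteria",
    "Bacteria;Bacillota;Bacilli",
    "d__Bacteria;s__Escherichia coli_B")
  for (raw in cases) {
    once <- parse_lineage(raw)
    twice <- parse_lineage(format_lineage(once))
    expect_identical(twice$ranks, once$ranks, label = raw)
  }
})

test_that("MIMAG tiers follow the completeness/contamination thresholds", {
  expect_equal(classify_mimag(95, 2), "HIGH")
  expect_equal(classify_mimag(50, 9.9), "MEDIUM")
  expect_equal(classify_mimag(10, 40), "LOW")
  # boundary semantics: >90 / <5 for HIGH, >=50 / <10 for MEDIUM
  expect_equal(classify_mimag(90, 2), "MEDIUM")
  expect_equal(classify_mimag(95, 5), "MEDIUM")
  expect_equal(classify_mimag(49.9, 2), "LOW")
  expect_equal(classify_mimag(60, 10), "LOW")
})

test_that("MIMAG classification is monotone in quality", {
  tier_rank <- c(LOW = 1L, MEDIUM = 2L, HIGH = 3L)
  set.seed(42)
  for (i in 1:200) {
    comp <- runif(1, 0, 100); cont <- runif(1, 0, 20)
    base <- tier_rank[[classify_mimag(comp, cont)]]
    better_comp <- min(100, comp + runif(1, 0, 100 - comp))
    better_cont <- max(0, cont - runif(1, 0, cont))
    expect_gte(tier_rank[[classify_mimag(better_comp, cont)]], base)
    expect_gte(tier_rank[[classify_mimag(comp, better_cont)]], base)
  }
})

test_that("coverage matches hand-computable cases", {
  dir <- withr::local_tempdir()
  # one 100-base read fully aligned to a 100-base contig -> fold 1.0
  p1 <- write_sam(file.path(dir, "one.sam"), c(c1 = 100L),
                  sam_record("r1", 0L, "c1", 1L, "100M"))
  cov1 <- compute_coverage(p1)
  expect_equal(cov1$fold, 1.0)
  expect_equal(cov1$aligned_bases, 100)

  # empty alignment with one 500 bp contig -> fold 0
  p2 <- write_sam(file.path(dir, "empty.sam"), c(c1 = 500L))
  cov2 <- compute_coverage(p2)
  expect_equal(cov2$fold, 0)
  expect_equal(cov2$aligned_bases, 0)

  # two contigs (100 + 300 bp), 200 aligned bases -> fold 0.5
  p3 <- write_sam(file.path(dir, "two.sam"), c(c1 = 100L, c2 = 300L),
                  c(sam_record("r1", 0L, "c1", 1L, "100M"),
                    sam_record("r2", 0L, "c2", 1L, "100M")))
  expect_equal(compute_coverage(p3)$fold, 0.5)

  # restriction to one contig changes both numerator and denominator
  cov_c2 <- compute_coverage(p3, restrict_to = "c2")
  expect_equal(cov_c2$aligned_bases, 100)
  expect_equal(cov_c2$reference_length, 300)

  expect_error(compute_coverage(p3, restrict_to = "c9"),
               class = "magbroker_error_reference")
  p4 <- file.path(dir, "nohdr.sam")
  writeLines(sam_record("r1", 0L, "c1", 1L, "10M"), p4)
  expect_error(compute_coverage(p4), class = "magbroker_error_format")
})

test_that("unmapped, secondary and supplementary records never count", {
  dir <- withr::local_tempdir()
  p <- write_sam(file.path(dir, "flags.sam"), c(c1 = 200L),
                 c(sam_record("r1", 0L, "c1", 1L, "50M"),
                   sam_record("r2", 4L, "c1", 1L, "50M"),
                   sam_record("r3", 256L, "c1", 1L, "50M"),
                   sam_record("r4", 2048L, "c1", 1L, "50M"),
                   sam_record("r5", 16L, "c1", 101L, "50M")))
  cov <- compute_coverage(p)
  expect_equal(cov$aligned_bases, 100) # r1 + reverse-strand r5 only
  o <- oracle_coverage(p)
  expect_equal(cov$aligned_bases, o$aligned_bases)
})

test_that("coverage is additive over concatenated record sets", {
  dir <- withr::local_tempdir()
  lens <- c(a = 150L, b = 90L)
  r1 <- c(sam_record("x1", 0L, "a", 1L, "40M"),
          sam_record("x2", 0L, "b", 11L, "20M5D10M"))
  r2 <- c(sam_record("y1", 0L, "a", 50L, "5S30M"),
          sam_record("y2", 0L, "b", 1L, "15M2I15M"))
  pa <- write_sam(file.path(dir, "a.sam"), lens, r1)
  pb <- write_sam(file.path(dir, "b.sam"), lens, r2)
  pab <- write_sam(file.path(dir, "ab.sam"), lens, c(r1, r2))
  expect_equal(compute_coverage(pab)$aligned_bases,
               compute_coverage(pa)$aligned_bases +
                 compute_coverage(pb)$aligned_bases)
})
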