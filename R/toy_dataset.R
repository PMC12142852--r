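#' Generate a seeded toy dataset with a pre-filled configuration
#'
#' Writes a miniature but complete metagenomics study under `dir`: per-sample
#' paired FASTQ read sets (random 100-base reads cut from the contigs), a
#' co-assembly FASTA of random contigs, bin FASTA files partitioning disjoint
#' contig subsets, a SAM aligning every read back to its source position
#' (so coverage is exactly computable from the generator's own bookkeeping),
#' a CheckM-style quality table spanning all three MIMAG tiers, a
#' GTDB-Tk-style classification table (including the family-level
#' Enterobacteriaceae case, plus one unresolvable lineage on an extra
#' non-bin row for failure-path experiments), and a filled configuration
#' that validates cleanly. All randomness is fixed by `seed`; the same call
#' produces byte-identical output.
#'
#' @param dir target directory; must not exist or be empty.
#' @param seed integer seed fixing all randomness.
#' @param n_samples number of samples (each with its own read sets).
#' @param n_readpairs_per_sample paired read sets per sample.
#' @param n_bins number of bins (each takes two assembly contigs).
#' @param n_mags how many of the bins are additionally promoted to MAGs.
#' @param unresolvable_bin if `TRUE`, the last bin's classification is
#'   replaced by a lineage absent from the bundled registry fixture, so
#'   taxonomy resolution fails for it (halt-path testing).
#' @param reads_per_set read pairs per read set.
#' @return A list: `dir`, `config_path`, `placed` (tibble of read
#'   placements: `contig`, `start`, `width`), `contig_lengths` (named),
#'   `bin_contigs` (named list), `expected_fold` (assembly-wide fold
#'   coverage from the bookkeeping).
#' @export
generate_toy_dataset <- function(dir, seed = 7L, n_samples = 2L,
                                 n_readpairs_per_sample = 1L, n_bins = 3L,
                                 n_mags = 0L, unresolvable_bin = FALSE,
                                 reads_per_set = 20L) {
  stopifnot(n_samples >= 1, n_readpairs_per_sample >= 1, n_bins >= 1,
            n_mags >= 0, n_mags <= n_bins)
  if (dir.exists(dir) && length(list.files(dir, all.files = TRUE,
                                           no.. = TRUE)) > 0) {
    stop_magbroker("collision", sprintf("target directory '%s' is not empty", dir))
  }
  set.seed(seed)
  dir.create(file.path(dir, "bins"), recursive = TRUE, showWarnings = FALSE)
  if (n_mags > 0) dir.create(file.path(dir, "mags"), showWarnings = FALSE)

  ## contigs and assembly
  n_contigs <- max(2L * n_bins + 2L, 6L)
  contig_len <- sample(300:600, n_contigs, replace = TRUE)
  names(contig_len) <- sprintf("contig_%d", seq_len(n_contigs))
  contigs <- Biostrings::DNAStringSet(vapply(contig_len, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1)))
  assembly_fa <- file.path(dir, "assembly.fasta")
  Biostrings::writeXStringSet(contigs, assembly_fa)

  ## bins partition disjoint contig pairs
  bin_ids <- sprintf("bin_%d", seq_len(n_bins))
  bin_contigs <- stats::setNames(lapply(seq_len(n_bins), function(i)
    names(contig_len)[c(2L * i - 1L, 2L * i)]), bin_ids)
  for (b in bin_ids) {
    Biostrings::writeXStringSet(contigs[bin_contigs[[b]]],
                                file.path(dir, "bins", paste0(b, ".fasta")))
  }
  mag_ids <- character(0)
  if (n_mags > 0) {
    mag_ids <- sprintf("mag_%d", seq_len(n_mags))
    for (i in seq_len(n_mags)) {
      Biostrings::writeXStringSet(contigs[bin_contigs[[bin_ids[i]]]],
                                  file.path(dir, "mags", paste0(mag_ids[i], ".fasta")))
    }
  }

  ## reads: 100-base substrings of contigs; bookkeeping drives the SAM and
  ## the closed-form coverage oracle
  read_len <- 100L
  placed <- list()
  sam_records <- character()
  read_sets <- list()
  for (s in seq_len(n_samples)) {
    for (r in seq_len(n_readpairs_per_sample)) {
      alias <- sprintf("reads_s%d_%d", s, r)
      seqs1 <- character(reads_per_set); seqs2 <- character(reads_per_set)
      for (k in seq_len(reads_per_set)) {
        for (mate in 1:2) {
          ci <- sample(which(contig_len >= read_len), 1L)
          start <- sample.int(contig_len[ci] - read_len + 1L, 1L)
          sq <- as.character(Biostrings::subseq(contigs[[ci]], start,
                                                start + read_len - 1L))
          qname <- sprintf("%s_read%d/%d", alias, k, mate)
          placed[[length(placed) + 1L]] <- tibble::tibble(
            qname = qname, contig = names(contig_len)[ci],
            start = start, width = read_len)
          sam_records <- c(sam_records, paste(
            qname, 0L, names(contig_len)[ci], start, 60L,
            sprintf("%dM", read_len), "*", 0L, 0L, sq,
            strrep("I", read_len), sep = "\t"))
          if (mate == 1) seqs1[k] <- sq else seqs2[k] <- sq
        }
      }
      f1 <- file.path(dir, paste0(alias, "_R1.fastq"))
      f2 <- file.path(dir, paste0(alias, "_R2.fastq"))
      write_fastq(stats::setNames(seqs1, sprintf("%s_read%d/1", alias,
                                                 seq_len(reads_per_set))), f1)
      write_fastq(stats::setNames(seqs2, sprintf("%s_read%d/2", alias,
                                                 seq_len(reads_per_set))), f2)
      read_sets[[alias]] <- list(sample = sprintf("sample_%d", s),
                                 files = basename(c(f1, f2)))
    }
  }
  placed <- dplyr::bind_rows(placed)

  sam_path <- file.path(dir, "alignment.sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contig_len), contig_len),
               sam_records), sam_path, useBytes = TRUE)

  ## quality table spanning the three MIMAG tiers
  tiers <- list(c(95.3, 2.1), c(60.0, 4.0), c(30.0, 15.0))
  q_ids <- c(bin_ids, mag_ids)
  q <- t(vapply(seq_along(q_ids), function(i) {
    # MAG rows mirror their source bin's quality; mag_i derives from bin_i
    j <- if (grepl("^mag_", q_ids[i])) as.integer(sub("mag_", "", q_ids[i])) else i
    unlist(tiers[[(j - 1L) %% 3L + 1L]])
  }, numeric(2)))
  quality_path <- file.path(dir, "checkm_quality.tsv")
  readr::write_tsv(tibble::tibble(`Bin Id` = q_ids, Completeness = q[, 1],
                                  Contamination = q[, 2]), quality_path)

  ## classification table: family-level Enterobacteriaceae case, a
  ## resolvable archaeal genus, a domain-only lineage, plus an unresolvable
  ## lineage on an extra non-bin row
  lineages <- c(
    paste0("d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;",
           "o__Enterobacterales;f__Enterobacteriaceae;g__;s__"),
    paste0("d__Archaea;p__Methanobacteriota;c__Methanococci;",
           "o__Methanococcales;f__Methanococcaceae;g__Methanococcus;s__"),
    "d__Bacteria")
  unresolvable <- "d__Bacteria;p__;c__;o__;f__Absentiaceae;g__;s__"
  cls <- vapply(seq_along(q_ids), function(i) {
    j <- if (grepl("^mag_", q_ids[i])) as.integer(sub("mag_", "", q_ids[i])) else i
    lineages[[(j - 1L) %% 3L + 1L]]
  }, character(1))
  if (unresolvable_bin) cls[n_bins] <- unresolvable
  taxonomy_path <- file.path(dir, "gtdbtk_classification.tsv")
  readr::write_tsv(tibble::tibble(
    user_genome = c(q_ids, "unbinned_example"),
    classification = c(cls, unresolvable)), taxonomy_path)

  ## filled configuration
  cfg <- list(
    study = "PRJEB00001",
    samples = lapply(seq_len(n_samples), function(s) list(
      alias = sprintf("sample_%d", s),
      title = sprintf("toy metagenome sample %d", s),
      scientific_name = "metagenome", taxid = 256318L,
      collection_date = "2024-06-01", location = "Germany")),
    read_sets = purrr::imap(read_sets, function(rs, alias) list(
      alias = alias, sample = rs$sample, platform = "ILLUMINA",
      instrument = "Illumina MiSeq", library_layout = "PAIRED",
      library_source = "METAGENOMIC", library_selection = "RANDOM",
      library_strategy = "WGS", files = rs$files)) |> unname(),
    assembly = list(
      name = "toy_coassembly", program = "megahit v1.2.9",
      samples = sprintf("sample_%d", seq_len(n_samples)),
      runs = names(read_sets), fasta = "assembly.fasta",
      molecule_type = "genomic DNA"),
    bins = lapply(bin_ids, function(b) list(
      bin_id = b, fasta = file.path("bins", paste0(b, ".fasta")),
      binning_software = "metabat2 v2.15")),
    aux = list(quality_table = "checkm_quality.tsv",
               taxonomy_table = "gtdbtk_classification.tsv",
               alignment = "alignment.sam")
  )
  if (n_mags > 0) {
    cfg$mags <- lapply(seq_len(n_mags), function(i) list(
      bin_id = mag_ids[i], fasta = file.path("mags", paste0(mag_ids[i], ".fasta")),
      binning_software = "metabat2 v2.15", derived_bin = bin_ids[i]))
  }
  config_path <- file.path(dir, "config.yaml")
  writeLines(yaml::as.yaml(cfg), config_path, useBytes = TRUE)

  list(dir = dir, config_path = config_path, placed = placed,
       contig_lengths = contig_len, bin_contigs = bin_contigs,
       expected_fold = sum(placed$width) / sum(contig_len))
}

write_fastq <- function(named_seqs, path) {
  x <- Biostrings::DNAStringSet(unname(named_seqs))
  names(x) <- names(named_seqs)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(named_seqs))))
}
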