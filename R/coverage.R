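#' Fold coverage from an alignment map
#'
#' Computes fold coverage — aligned reference-consuming bases divided by
#' total reference length — from a SAM or BAM file. Counted records are
#' mapped, primary, non-supplementary alignments; per record the
#' reference-consuming CIGAR operations (M/=/X/D) contribute. With
#' `restrict_to`, only alignments to the named references are counted and
#' only those references' lengths enter the denominator (per-bin coverage
#' from an assembly-wide map). Coordinate sorting is not required.
#'
#' @param alignment_path path to a SAM or BAM file whose header declares
#'   reference lengths.
#' @param restrict_to optional character vector of reference (contig) names;
#'   must be a subset of the header references.
#' @return A list of class `coverage_stats` with `aligned_bases`,
#'   `reference_length` and `fold = aligned_bases / reference_length`.
#' @export
compute_coverage <- function(alignment_path, restrict_to = NULL) {
  if (!file.exists(alignment_path)) {
    stop_magbroker("io", sprintf("alignment '%s' does not exist", alignment_path))
  }
  bam <- as_bam(alignment_path)
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (length(targets) == 0) {
    stop_magbroker("format",
      sprintf("alignment '%s' declares no reference sequences in its header",
              alignment_path))
  }
  if (!is.null(restrict_to)) {
    unknown <- setdiff(restrict_to, names(targets))
    if (length(unknown) > 0) {
      stop_magbroker("reference",
        sprintf("restrict_to names unknown contig(s): %s",
                paste(unknown, collapse = ", ")))
    }
    targets <- targets[restrict_to]
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(flag = flag))
  keep <- as.character(GenomicAlignments::seqnames(ga)) %in% names(targets)
  aligned <- sum(GenomicAlignments::cigarWidthAlongReferenceSpace(
    GenomicAlignments::cigar(ga)[keep]))
  ref_len <- sum(as.numeric(targets))
  structure(list(aligned_bases = as.numeric(aligned),
                 reference_length = ref_len,
                 fold = as.numeric(aligned) / ref_len),
            class = "coverage_stats")
}

# SAM input is converted to a temporary BAM once; BAM passes through.
as_bam <- function(path) {
  con <- file(path, "rb")
  magic <- readBin(con, "raw", n = 2L)
  close(con)
  if (length(magic) == 2L && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    return(path)
  }
  dest <- tempfile(fileext = "")
  tryCatch(
    Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
    error = function(e) {
      stop_magbroker("format",
        sprintf("'%s' could not be read as SAM: %s", path, conditionMessage(e)))
    })
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("<coverage_stats: %.0f aligned bases / %.0f bp = %.3f fold>\n",
              x$aligned_bases, x$reference_length, x$fold))
  invisible(x)
}
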