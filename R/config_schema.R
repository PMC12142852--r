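# Field schema driving both template generation and parsing. Each field
# carries the inline help comment and the example value the template shows;
# `mandatory` fields must be present after filling. Keys not listed here are
# preserved as free extra attributes of the enclosing record.

fld <- function(key, comment, example, mandatory = TRUE) {
  list(key = key, comment = comment, example = example, mandatory = mandatory)
}

config_field_schema <- function() {
  list(
    study = list(
      comment = "Accession of the registered study (project) this submission extends.",
      fields = list(
        fld("study", "Study accession, e.g. assigned when the project was registered.",
            "PRJEB00001")
      )
    ),
    samples = list(
      comment = "One record per biological sample. Extra keys become sample attributes.",
      list_section = TRUE,
      fields = list(
        fld("alias", "Unique sample alias within this study.", "sample_1"),
        fld("title", "Short human-readable sample title.", "anaerobic digester sludge, reactor 1"),
        fld("scientific_name", "Scientific name of the sampled metagenome taxon.", "metagenome"),
        fld("taxid", "Taxonomy identifier matching scientific_name.", 256318L),
        fld("collection_date", "ISO-8601 collection date, or the keyword 'missing'.", "2024-06-01"),
        fld("location", "Geographic origin (country/sea), or the keyword 'missing'.", "Germany")
      )
    ),
    sample_accessions = list(
      comment = "Accessions of already-deposited samples this submission builds on.",
      accession_entry = TRUE,
      fields = list(
        fld("sample_accessions", "List the previously assigned sample accessions.",
            c("ERS0000001", "ERS0000002"))
      )
    ),
    read_sets = list(
      comment = "One record per sequencing read set (run).",
      list_section = TRUE,
      fields = list(
        fld("alias", "Unique read-set alias.", "reads_1"),
        fld("sample", "Alias (above) or accession of the sample the reads derive from.", "sample_1"),
        fld("platform", "Sequencing platform.", "ILLUMINA"),
        fld("instrument", "Instrument model.", "Illumina MiSeq"),
        fld("library_layout", "SINGLE or PAIRED.", "PAIRED"),
        fld("library_source", "Library source.", "METAGENOMIC"),
        fld("library_selection", "Library selection method.", "RANDOM"),
        fld("library_strategy", "Library strategy.", "WGS"),
        fld("files", "1 (SINGLE) or 2 (PAIRED) FASTQ paths.",
            c("reads_1_R1.fastq", "reads_1_R2.fastq")),
        fld("md5", "Optional per-file MD5 checksums, same order as files.",
            NULL, mandatory = FALSE)
      )
    ),
    assembly = list(
      comment = "The (co-)assembly to submit.",
      fields = list(
        fld("name", "Assembly name.", "coassembly_1"),
        fld("program", "Assembler name and version.", "megahit v1.2.9"),
        fld("samples", "Aliases or accessions of all samples assembled (>1 marks a co-assembly).",
            c("sample_1", "sample_2")),
        fld("runs", "Optional aliases or accessions of the read sets assembled.",
            c("reads_1", "reads_2"), mandatory = FALSE),
        fld("fasta", "Path to the assembly FASTA.", "assembly.fasta"),
        fld("molecule_type", "Molecule type.", "genomic DNA"),
        fld("coverage", "Fold coverage; omit to infer it from the alignment map.",
            NULL, mandatory = FALSE)
      )
    ),
    assembly_accession = list(
      comment = "Accession of the already-deposited assembly the bins derive from.",
      accession_entry = TRUE,
      fields = list(
        fld("assembly_accession", "Previously assigned assembly (analysis) accession.",
            "ERZ0000001")
      )
    ),
    bins = list(
      comment = "One record per contig bin. Quality, taxonomy and coverage are read from the aux tables/alignment unless given inline.",
      list_section = TRUE,
      fields = list(
        fld("bin_id", "Unique bin identifier, matching the aux table rows.", "bin_1"),
        fld("fasta", "Path to the bin FASTA.", "bins/bin_1.fasta"),
        fld("binning_software", "Binning software name and version.", "metabat2 v2.15"),
        fld("completeness", "Optional completeness percent (overrides the quality table).",
            NULL, mandatory = FALSE),
        fld("contamination", "Optional contamination percent (overrides the quality table).",
            NULL, mandatory = FALSE),
        fld("lineage", "Optional classification string (overrides the taxonomy table).",
            NULL, mandatory = FALSE),
        fld("taxid", "Optional manual taxon id (with scientific_name, bypasses resolution).",
            NULL, mandatory = FALSE),
        fld("scientific_name", "Optional manual scientific name for the taxid above.",
            NULL, mandatory = FALSE),
        fld("coverage", "Optional fold coverage; omit to infer from the alignment map.",
            NULL, mandatory = FALSE)
      )
    ),
    bin_accessions = list(
      comment = "Accessions of already-deposited bins the MAGs derive from.",
      accession_entry = TRUE,
      fields = list(
        fld("bin_accessions", "Previously assigned bin (analysis) accessions.",
            c("ERZ0000002"))
      )
    ),
    mags = list(
      comment = "One record per metagenome-assembled genome (MAG); fields as for bins.",
      list_section = TRUE,
      fields = list(
        fld("bin_id", "Unique MAG identifier, matching the aux table rows.", "mag_1"),
        fld("fasta", "Path to the MAG FASTA.", "mags/mag_1.fasta"),
        fld("binning_software", "Binning software name and version.", "metabat2 v2.15"),
        fld("derived_bin", "Optional id or accession of the source bin.",
            NULL, mandatory = FALSE),
        fld("completeness", "Optional completeness percent (overrides the quality table).",
            NULL, mandatory = FALSE),
        fld("contamination", "Optional contamination percent (overrides the quality table).",
            NULL, mandatory = FALSE),
        fld("lineage", "Optional classification string (overrides the taxonomy table).",
            NULL, mandatory = FALSE),
        fld("taxid", "Optional manual taxon id (with scientific_name, bypasses resolution).",
            NULL, mandatory = FALSE),
        fld("scientific_name", "Optional manual scientific name for the taxid above.",
            NULL, mandatory = FALSE),
        fld("coverage", "Optional fold coverage; omit to infer from the alignment map.",
            NULL, mandatory = FALSE)
      )
    ),
    aux = list(
      comment = "Third-party result files consumed during inference.",
      fields = list(
        fld("quality_table", "Tab-separated completeness/contamination table (CheckM-style).",
            "checkm_quality.tsv", mandatory = FALSE),
        fld("taxonomy_table", "Tab-separated classification table (GTDB-Tk-style).",
            "gtdbtk_classification.tsv", mandatory = FALSE),
        fld("alignment", "SAM/BAM of reads mapped to the assembly, for coverage inference.",
            "alignment.sam", mandatory = FALSE)
      )
    )
  )
}

# Which schema sections a scenario's template contains, in order. Levels
# covered by pre-existing accessions get accession-entry sections instead of
# full metadata sections.
sections_for_scenario <- function(scenario) {
  has <- function(lv) scenario_has(scenario, lv)
  pre <- function(lv) length(scenario$preexisting[[lv]]) > 0
  secs <- "study"
  if (has("SAMPLES")) secs <- c(secs, "samples")
  else if (pre("SAMPLES")) secs <- c(secs, "sample_accessions")
  if (has("READS")) secs <- c(secs, "read_sets")
  if (has("ASSEMBLY")) secs <- c(secs, "assembly")
  else if (pre("ASSEMBLY")) secs <- c(secs, "assembly_accession")
  if (has("BINS")) secs <- c(secs, "bins")
  else if (pre("BINS")) secs <- c(secs, "bin_accessions")
  if (has("MAGS")) secs <- c(secs, "mags")
  if (any(c("ASSEMBLY", "BINS", "MAGS") %in% scenario$levels)) secs <- c(secs, "aux")
  secs
}

mandatory_fields <- function(section) {
  sch <- config_field_schema()[[section]]
  keys <- vapply(sch$fields, `[[`, character(1), "key")
  keys[vapply(sch$fields, `[[`, logical(1), "mandatory")]
}
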