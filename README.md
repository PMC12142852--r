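# magbroker

Submitting a genome-resolved metagenomics study to an INSDC archive such as
the European Nucleotide Archive means depositing many interdependent
objects — samples, sequencing runs, a (co-)assembly, binned contigs, and
metagenome-assembled genomes (MAGs) — each with its own metadata form,
submission route (XML API vs tab-separated Webin-style manifests), and
accessions that must be carried into every downstream step. Done by hand
this is slow and error-prone, and it is one reason published studies often
lack their processed data layers.

`magbroker` automates that workflow for R users. From a single YAML
configuration it:

* generates scenario-specific configuration templates containing only the
  fields the chosen data levels need (`make_template()`), including the
  study-extension path where already-deposited accessions replace metadata
  sections;
* validates metadata, cross-references and referenced files before anything
  is submitted (`validate_config()`);
* infers **fold coverage** from SAM/BAM alignment maps,
  `fold = aligned reference-consuming bases (CIGAR M/=/X/D) / reference length`,
  assembly-wide and per bin (`compute_coverage()`);
* classifies bins against the MIMAG completeness/contamination tiers
  (`classify_mimag()`: HIGH iff completeness > 90% and contamination < 5%,
  MEDIUM iff completeness ≥ 50% and contamination < 10%);
* derives **environmental organism-level taxonomy** from GTDB-Tk-style
  classifications and resolves it to submittable taxon identifiers
  (`candidate_names()`, `resolve_taxonomy()`). A bin classified at family
  level as *Enterobacteriaceae* (taxid 543, a rank record that cannot be
  submitted) resolves to *uncultured Enterobacteriaceae bacterium*
  (taxid 218034). Unresolvable bins halt the submission with a complete
  problem list;
* serializes sample-set XML (including *virtual samples* that anchor bins,
  MAGs and co-assemblies, with `sample derived from` references), builds
  per-item Webin-style manifests, stages upload bundles, parses receipts,
  and tracks every assigned accession in a ledger that drives downstream
  references (`plan_submission()`, `execute_plan()`, `write_summary()`);
* ships a deterministic mock registry, uploader and taxonomy service plus a
  seeded toy-dataset generator, so the entire pipeline runs and is testable
  offline (`mock_registry()`, `generate_toy_dataset()`).

## Worked example

```r
library(magbroker)

toy  <- generate_toy_dataset("toy", seed = 7)   # 2 samples, 2 paired read
                                                # sets, co-assembly, 3 bins
scen <- submission_scenario(c("samples", "reads", "assembly", "bins"))
cfg  <- parse_config(toy$config_path)
rep  <- validate_config(cfg, scen)              # zero ERRORs

reg  <- mock_registry()                         # offline development registry
res  <- resolve_all(
  tibble::tibble(bin_id = cfg$bins$bin_id,
                 lineage = read_taxonomy_table("toy/gtdbtk_classification.tsv")$
                   classification[1:3]),
  reg)
plan <- plan_submission(scen, cfg, rep)         # 11 dependency-ordered steps
run  <- execute_plan(plan, cfg, mock_endpoints(reg), resolution = res,
                     workdir = "staging")
run$ledger
```

```
<accession_ledger: 12 entries>
# A tibble: 12 × 4
   alias             kind     accession   step
   <chr>             <chr>    <chr>      <int>
 1 sample_1          SAMPLE   ERS0000001     1
 2 sample_2          SAMPLE   ERS0000002     1
 3 reads_s1_1        RUN      ERR0000001     2
 4 reads_s2_1        RUN      ERR0000002     3
 5 vs_toy_coassembly SAMPLE   ERS0000003     4
 6 toy_coassembly    ANALYSIS ERZ0000001     5
 7 vs_bin_1          SAMPLE   ERS0000004     6
 8 bin_1             ANALYSIS ERZ0000002     7
 9 vs_bin_2          SAMPLE   ERS0000005     8
10 bin_2             ANALYSIS ERZ0000003     9
11 vs_bin_3          SAMPLE   ERS0000006    10
12 bin_3             ANALYSIS ERZ0000004    11
```

Twelve accessions: two physical samples, two runs, one virtual sample for
the co-assembly, the assembly analysis, and a fresh virtual sample plus an
analysis per bin. Coverage was inferred from the generated alignment map:

```r
compute_coverage("toy/alignment.sam")
#> <coverage_stats: 8000 aligned bases / 3784 bp = 2.114 fold>
```

The taxonomy resolution behind `res` reproduces the canonical family-level
case:

```r
lin <- parse_lineage("d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Enterobacterales;f__Enterobacteriaceae;g__;s__")
candidate_names(lin)$name
#> [1] "uncultured Enterobacteriaceae bacterium"
resolve_taxonomy(candidate_names(lin), fixture_taxonomy_client())$taxid
#> [1] 218034
```

The same workflow is available from a shell via the bundled entry point
(`inst/cli/magbroker`): `magbroker makecfg --samples --reads -o config.yaml`
to obtain a template, then
`magbroker submit --config=config.yaml --samples --reads ...` (exit code 0
on success, 1 on validation/taxonomy/submission failure, 2 on usage
errors; `--production` additionally requires `--i-accept-production`).

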