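---
title: "Brokering metagenomics submissions: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brokering metagenomics submissions: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magbroker)
```

## The problem

A genome-resolved metagenomics study produces a layered dataset: physical
samples, sequencing runs, one or more (co-)assemblies, binned contigs, and
the high-quality subset of bins promoted to metagenome-assembled genomes
(MAGs). Archives accept these through different routes — sample objects as
XML documents through a submission API, file-bearing objects through
tab-separated manifests — and every object must reference the accessions of
the objects it depends on. Derived objects (bins, MAGs, co-assemblies) are
additionally anchored to *virtual samples*: registry sample objects created
not for physical material but to carry the derived object's taxon, quality
scores and a `sample derived from` reference to its physical origins.

`magbroker` models this as a pipeline of five stages: configuration
(template, parse, validate), inference (coverage, MIMAG tier, environmental
taxonomy), document generation (sample XML, manifests, staging), planning
(a topologically ordered step list), and execution (service calls, receipt
parsing, accession ledger). This vignette records the scientific and design
decisions behind each stage.

## Configuration model

The configuration is one YAML document per study. A *scenario* — the set of
levels to submit (`SAMPLES`, `READS`, `ASSEMBLY`, `BINS`, `MAGS`) plus any
accessions already deposited — determines which sections the template
contains; levels covered by pre-existing accessions are replaced by
accession-entry fields, which is how a deposited study is extended. YAML
was chosen because the form must be hand-editable with inline comments;
every mandatory field in a template is preceded by a comment stating what
is required and showing an example value, and templates are themselves
parseable (pre-filled forms).

Two conventions matter:

* **Missing-value keyword.** `collection_date` and `location` accept the
  INSDC missing-value keyword `missing`, so "declared missing" is
  distinguishable from "forgot to fill in".
* **Open records.** Keys outside the field schema are preserved as extra
  attributes of their record and submitted as such; users may enrich
  metadata at will without schema changes.

Validation is pure (it reads referenced files but mutates nothing and never
touches a network) and exhaustive rather than fail-fast: all problems come
back in one report with dotted field-path loci (`read_sets.0.files`;
indices are 0-based so loci match the list positions users see in the
file). File checks verify existence, readability, non-emptiness and a
format signature on the first record only — a full parse at validation time
would be redundant with the consuming stage and makes validation O(1) per
file. A MAG candidate below the MIMAG high-quality bar yields a WARNING,
never an ERROR: tier shortfalls are a scientific judgement call, not a
structural defect.

## Coverage

The archives ask for a fold-coverage value per assembly, bin and MAG. The
definition used here is

> fold = (aligned reference-consuming bases) / (total reference length)

where a record contributes the widths of its CIGAR `M`, `=`, `X` and `D`
operations, and only mapped, primary, non-supplementary records count.
Deletions consume reference and are counted; insertions and clips do not.
This equals the mean per-position depth, which is exactly what the test
suite's independent oracle computes position by position. Per-bin coverage
restricts both numerator and denominator to the bin's contigs, supporting
either a bin-restricted alignment or an assembly-wide map (the `restrict_to`
argument); coverage supplied explicitly in the configuration is never
overridden. SAM and BAM are both accepted (SAM is converted once via
Rsamtools); coordinate sorting is not required.

## MIMAG tiers

`classify_mimag()` implements the completeness/contamination component of
the MIMAG genome-quality tiers: HIGH iff completeness > 90 and
contamination < 5; MEDIUM iff completeness ≥ 50 and contamination < 10 (and
not HIGH); LOW otherwise. The full MIMAG high-quality definition also
requires rRNA/tRNA presence; that needs gene calling by external tools and
is deliberately out of scope, which is one reason the tier is advisory
here. The function is monotone — improving either statistic can never lower
the tier — and the suite property-tests this.

## Environmental taxonomy

Classification pipelines output *rank* taxonomies (e.g. family
*Enterobacteriaceae*, taxid 543), but uncultivated genomes must be
deposited under *environmental organism-level* taxa (e.g. *uncultured
Enterobacteriaceae bacterium*, taxid 218034). The resolver derives
candidate names from the **lowest classified rank only**:

| lowest rank | candidate name(s), most specific first |
|---|---|
| species *S* | *S*, then `uncultured S` |
| genus *G* | `uncultured G sp.` |
| family/order/class/phylum *N* | `uncultured N bacterium` / `uncultured N archaeon` |
| domain only | `uncultured bacterium` / `uncultured archaeon` |

The adjective follows the domain (Bacteria/Archaea); other domains fail
explicitly rather than being guessed at. GTDB polyphyletic suffixes
(`_A` … `_Z` on a trailing token) are stripped before lookup, because
registry records carry base names; each strip is recorded as a
normalization note. Three further rules are deliberate:

* **No rank walk-up.** If the lowest rank's candidates fail, the resolver
  does not silently retry at a higher rank — demoting the rank changes the
  scientific claim. The remedy is user action: a manual
  `taxid`/`scientific_name` override in the configuration, or requesting a
  new taxon identifier from the registry.
* **Exact, submittable matches only.** A candidate resolves only to a
  registry record whose name equals the query case-sensitively and that is
  flagged submittable. Suggestion-style superstring matches and rank
  records (like taxid 543) are filtered out, preventing
  similar-but-wrong assignments.
* **Failures are aggregated.** `resolve_all()` returns the complete list
  of unresolvable bins at once, and the orchestrator refuses to submit
  *anything* while that list is nonempty. A partially submitted study whose
  remaining bins can never be resolved is worse than a halted one; partial
  submission of the resolvable subset is noted as possible future work.

Transport failures of the taxonomy service are a distinct, retriable error
class — they must never be mistaken for "no such taxon".

## Documents, manifests, staging

Sample-set XML uses a canonical element/attribute order so generated
documents are byte-stable and can be golden-file tested. Virtual samples
carry the resolved taxon, `completeness score`, `contamination score`,
`binning software` and `sample derived from` attributes, following public
binned-metagenome checklist vocabulary; for a co-assembly the derived-from
value lists all origin sample accessions comma-separated.

Manifests are ordered `KEY<TAB>VALUE` lines (UTF-8, LF). The mandatory key
tables per level follow public Webin conventions — reads: `STUDY, SAMPLE,
NAME, PLATFORM, INSTRUMENT, LIBRARY_SOURCE, LIBRARY_SELECTION,
LIBRARY_STRATEGY, FASTQ` (×1 or ×2); assembly-type levels: `STUDY, SAMPLE,
ASSEMBLYNAME, ASSEMBLY_TYPE, COVERAGE, PROGRAM, PLATFORM, MOLECULETYPE,
FASTA`, optional `RUN_REF`. `ASSEMBLY_TYPE` is fixed per level (`primary
metagenome`, `binned metagenome`, `Metagenome-Assembled Genome (MAG)`), and
`COVERAGE` is printed with one decimal place (R's round-half-to-even on the
stored binary value). Staging copies each item's data files into
`<workdir>/<level>/<alias>/` beside its serialized manifest; copying (with
the manifest rewritten to staged locations) was preferred over linking as
the safe default, and re-staging an item reproduces its directory
byte-identically while a foreign non-empty directory is refused.

## Planning and execution

The plan orders steps samples → reads → co-assembly virtual sample →
assembly → per-bin (virtual sample, upload) → per-MAG (virtual sample,
upload); levels covered by pre-existing accessions contribute no steps but
seed the ledger. **Each MAG gets its own fresh virtual sample** rather than
reusing its source bin's: every derived object is anchored independently.
This choice changes the accession arithmetic, so it is stated explicitly —
a full run assigns `n_samples + n_read_sets + [co-assembly] + 1 +
2·n_bins + 2·n_mags` accessions. The study accession is configuration data
(the study is registered beforehand; study registration is out of scope)
and is never a ledger entry.

Execution adds every receipt's accessions to the ledger before any
dependent step runs; aliases are write-once and accessions are validated
against per-kind patterns (`(ERS|SAMEA)\d+`, `ERR\d+`, `ERZ\d+`,
`(PRJ[EDN][A-Z]\d+|ERP\d+)` by default — a configurable table, since the
registry never prints its grammar). The first failed receipt aborts the
run and the summary then contains exactly the accessions assigned before
the abort; there is no resumability in this version because the
accession-extension path (re-run remaining levels against the assigned
accessions) already covers recovery. Transport errors are retried three
times with linear backoff; receipt-level rejections are never retried.
`DEVELOPMENT` mode is the default; `PRODUCTION` is unreachable without an
explicit opt-in flag. A dry run performs inference, document generation and
staging — resolving references against pattern-shaped placeholder
accessions — but makes no service call and leaves the ledger empty.

## The mock services and the toy generator

The bundled mock registry emulates the development service in-process:
sequential per-kind accessions with zero-padded 7-digit counters (so ledger
pattern validation is exercised for real), failure receipts for duplicate
aliases and malformed payloads (a server answers; it does not throw), a
manifest-validating uploader, and a taxonomy endpoint returning exact
matches before superstring matches. The taxonomy fixture is a small
synthetic registry excerpt; the identifiers for the names it contains
(543, 218034, 77133, 115547, 562) are the genuine public ones, while its
decoy rows (a submittable superstring of *uncultured bacterium*, a
non-submittable environmental name, an absent family) exist to exercise
the resolver's filters. Service contracts are plain functions, so tests
inject recording and failing doubles at the transport boundary.

`generate_toy_dataset()` emulates the full input surface at toy scale: the
default `(seed = 7, n_samples = 2, n_readpairs_per_sample = 1, n_bins = 3)`
reproduces the canonical co-assembly scenario (two samples, two paired read
sets, one co-assembly, three bins — 11 plan steps, 12 accessions). Contigs
are uniform-random 300–600 bp sequences; reads are 100 bp substrings placed
uniformly at recorded positions, so the generator's own bookkeeping is a
closed-form coverage oracle for the SAM it writes; the quality table spans
all three MIMAG tiers; the classification table contains the family-level
*Enterobacteriaceae* case, a resolvable archaeal genus, a domain-only
lineage, and an unresolvable lineage kept on an extra non-bin row so the
default dataset completes while `unresolvable_bin = TRUE` injects it into a
real bin for halt-path testing. What the toy data does **not** emulate:
realistic genome composition, read error profiles, paired-end flag
semantics in the SAM (mates are placed independently), service latency or
authentication. Passing tests therefore demonstrate the workflow's
correctness — ordering, conservation, formatting, halting — not robustness
to messy real-world classifier output.

## Numerical and degenerate-input choices

* Coverage arithmetic is integer numerator / integer denominator; equality
  with the oracle is exact, not tolerance-based.
* `fold = 0` iff no bases aligned; an alignment file without reference
  declarations is a format error, not zero coverage.
* Quality percentages are range-checked on read (`[0, 100]` completeness,
  `≥ 0` contamination) with row loci.
* Empty classifications parse to an all-empty lineage and fail resolution
  with an explicit empty-lineage error — at the resolver, not the reader,
  so tables remain inspectable verbatim.
* An empty sample set refuses to serialize; an empty ledger writes a
  header-only summary.
* Problem sizes in the test suite (toy datasets of 2–3 samples, ≤ 4 bins,
  20 read pairs per set; 50 randomized alignment files for the coverage
  property) were chosen as the smallest sizes that still exercise every
  code path, keeping the whole suite near twenty seconds on one core.

## Known limitations

* Bacteria and Archaea only in the environmental-name rules; Eukaryota and
  viral bins fail resolution explicitly.
* MIMAG rRNA/tRNA criteria are not evaluated (no gene calling).
* No partial submission when some bins fail taxonomy; the run halts.
* No live-service transport is bundled: the production/development split is
  modelled, but real network submission requires plugging an uploader and
  register function into `service_endpoints()`.
* The mock services are in-process contracts; no HTTP layer is emulated.
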