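---
title: "Methods: long-amplicon variant calling for single-gene diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-amplicon variant calling for single-gene diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longamp)
```

## The analysis problem

Single-gene diagnostic sequencing by long-amplicon nanopore runs works on
a simple design: a gene of clinical interest (the motivating case is
*LDLR* in familial hypercholesterolemia) is PCR-amplified in a handful of
long fragments covering the promoter and every exon, the equimolar pool
is sequenced on a nanopore device, and reads are mapped back to the
gene-local reference rather than a whole genome. Diagnosis then rests on
four quantities computed per candidate variant: the **variant
frequency** (percentage of covering reads supporting the alternate
allele, which doubles as the zygosity statistic), the **strand bias**
(share of alternate support on the majority strand), a **significance
value** against a background error model, and the **match status**
against a catalog of previously recorded variants.

`longamp` implements this computational half of the workflow end to end,
plus a read simulator that generates nanopore-like data from known
diploid genotypes so that every stage can be validated against a truth
table without access to sequencing data.

## Gene model and coordinates

A `gene_model` holds the gene-forward reference sequence, ordered exon
intervals, and CDS intervals whose concatenation is the coding sequence.
All coordinates are **1-based inclusive**, the R/Bioconductor (IRanges)
convention, used consistently from file import to report; the only
0-based dialect encountered (BED) is converted at the import boundary
and every file's dialect is declared by the caller, never guessed.
Minus-strand genes are expected to be supplied as gene-forward
sequences (the natural orientation of RefSeqGene-style records), with
the `strand` flag recording the original orientation.

Coding/genomic conversion is by precomputed lookup in both directions,
so `genomic_to_cds()` and `cds_to_genomic()` are exact inverses on
coding positions — a property the test suite asserts over every coding
position of the example gene.

### HGVS and protein consequences

`parse_hgvs_c()` supports exonic substitutions, deletions, insertions
and delins. Intronic offset notation (`c.123+5G>A`) is rejected with an
explicit error rather than mis-parsed: diagnostic reports in this
setting concern exonic variants, and silently mangling an offset would
be worse than refusing it.

`predict_consequence()` applies a variant to the coding sequence and
compares translations. For frameshifts, the reported `TerN` offset
follows the HGVS convention: the first altered residue counts as
position 1 and `N` is the position of the new stop in the shifted
frame. (Informal phrasings such as "a stop N codons downstream of the
deletion" are ambiguous about whether the altered residue itself is
counted; we implement the strict HGVS reading.) Because a shifted frame
usually runs past the original stop codon, the stop scan continues into
the exonic 3' UTR sequence. A frameshift that reaches the end of the
transcript without a stop is reported as an extension with the offset
absent. In-frame indels are labelled `inframe_delins` and handled
structurally, though they do not occur in the validation genotypes.

## The read simulator

`simulate_reads()` emulates the data-generating process of the
workflow, not the physics of the device:

* every read is a **full-length copy of one amplicon** — the protocol
  sequences intact long amplicons, and per-fragment coverage uniformity
  is the feature worth emulating; fragment-length distributions and
  chimeras are deliberately out of scope;
* each read draws its haplotype uniformly from the two, its amplicon
  proportionally to the panel weights (equimolar by default), and its
  strand 50/50, with reverse-strand reads emitted
  reverse-complemented;
* errors are injected per base: substitutions at `substitution_rate`,
  indels at `indel_rate`, with the indel rate multiplied by
  `tandem_context_multiplier` inside homopolymer/tandem-repeat context —
  the signature nanopore failure mode of unresolvable repeat lengths —
  and an optional `strand_error_asymmetry` factor on reverse-strand
  reads, the mechanism that produces strand-biased artifact calls in
  real data;
* quality strings are constant placeholders; no downstream stage may
  read them, mirroring a pipeline that applies no reported quality
  threshold.

The defaults (substitution 0.02, indel 0.03, multiplier 5 per base) are
documented placeholders of a mid-accuracy long-read run; published
studies do not report per-base rates for this protocol, so the rates
are parameters, not measurements. The repeat-context definition is
**shared with the filter module** (`tandem_runs()`): a single detector
decides both where the simulator inflates errors and which indel calls
the filter excludes, keeping the two in structural agreement.

What passing simulation-based tests shows, therefore, is that the
pipeline correctly recovers genotypes under an error process with the
right broad shape (uniform substitutions, repeat-concentrated indels,
strand asymmetry); it cannot certify performance against device-specific
effects the simulator does not model (basecaller context biases, signal
artifacts, read truncation).

## Alignment and pileup

Full-length amplicon reads have a known target, so the mapper is a
**built-in semi-global aligner** (free gaps at the reference ends, unit
edit costs) rather than an external long-read mapper; an adapter could
delegate to one, but no test requires it. Implementation details that
matter:

* both orientations are tried and the smaller edit distance wins, ties
  broken toward forward for determinism;
* a read is located first by exact 16-mer seeding at a few offsets,
  which fixes orientation and restricts the dynamic program to a padded
  reference window; if seeding fails or the seeded alignment misses the
  identity floor, the full-reference DP in both orientations is the
  fallback, so seeding is a pure optimization;
* alignments below an identity floor of 0.70 are reported unmapped —
  nanopore-like error rates of up to ~15% leave a wide margin;
* identical read sequences are aligned once and carried with a
  multiplicity weight (in error-free simulations every read is one of a
  handful of exact amplicon copies).

The pileup records per-position, per-strand counts of A/C/G/T and
deletions, with insertions keyed to the column left of the insertion
point — matching the left-alignment normalization used everywhere else.
Depth is defined as base plus deletion counts over both strands, and
the test suite asserts this conservation on random noisy read sets. The
aligner's edit distances are checked against two independent oracles: a
plain dynamic-programming matrix in R and the free-end-gap mode of
Biostrings' aligner.

## Variant calling

At every column with depth ≥ `min_depth` (default 100), each
non-reference allele with frequency ≥ `min_frequency` percent (default
20) yields one call; adjacent deletion-called columns merge into single
events and all indels are left-aligned. The defaults sit far below the
frequencies of real diploid variants (≥ ~30%) and far above the
per-allele error frequencies the simulator produces, and both are
config-exposed.

The significance value is the upper-tail binomial probability of the
observed alternate support at a per-base null error rate (default
0.05): the simplest defensible null that reproduces the observed
behaviour of "p ≈ 0 for true variants at high depth". It is monotone
decreasing in support and equals 1 at zero support. No numerical
agreement with any proprietary caller's statistic is claimed or sought.

## Exclusion filters and zygosity

Filters run in the order strand bias → tandem-repeat indels →
zygosity classification.

**Strand bias.** `100 × max(fwd, rev) / (fwd + rev)`, ranging 50–100.
Because bias varies with the surrounding sequence, only the extreme is
excluded: calls at exactly 100% (single-strand support). Everything
below is retained.

**Tandem-repeat indels.** Indel calls whose left-aligned event overlaps
a tandem run are flagged and excluded; substitutions never are. A
tandem run is a homopolymer of ≥ 3 bases, or a repeat of a 2–4 nt unit
with ≥ 2 copies spanning ≥ 6 nt — thresholds that are unstated in the
motivating work and therefore config-exposed. The accompanying
`fisher_tandem_test()` justifies the exclusion: variants from two
unrelated samples (e.g. a healthy control and a patient) are
cross-tabulated as (tandem indel vs other) × (called in both samples vs
sample-specific), and a one-sided hypergeometric tail tests whether
tandem indels are enriched for recurrence — the signature of a
systematic sequencing artifact rather than genotype. The 2×2
construction is interpretive (the source workflow does not spell it
out), so the printed p-value of any particular dataset is not a
reproduction target; only the qualitative enrichment is.

**Zygosity.** Heterozygous for frequencies in [30, 70] (band edges
inclusive, adopting the published rule of thumb), homozygous at ≥ 80,
ambiguous in between. Observed diploid frequencies cluster near 50 and
near 90–100, so both bands carry wide margins; the 80% floor is the
midpoint policy for the gap and, like the band, config-exposed.
Overlapping band configurations are rejected at configuration time.

## Annotation and reporting

Calls surviving the filters are annotated with region (promoter / UTR /
intron / CDS / downstream), exon label, HGVS c. and p. descriptions,
and matched against a recorded-variant catalog by exact
(position, ref, alt) identity **after left-alignment on both sides**,
which makes matching invariant to how an indel in repeat context was
written. Clinical significance and predictor labels (SIFT-style
columns) are carried verbatim from the catalog and never computed; a
novel variant is reported as "not recorded". The per-sample report
enforces the count identities recorded + novel = total and
CDS + non-CDS = total.

`run_pipeline()` composes the whole chain from one declarative config
(YAML or list) with every threshold surfaced, logs per-stage counts so
the report's accounting is auditable, and is deterministic given config
and seed. A thin command-line front end (`inst/cli/longamp.R`) exposes
`simulate`, `run`, `panel-check` and `report` subcommands.

## Numerical and design notes

* Ties in the aligner's dynamic program prefer diagonal, then read
  insertion, then reference deletion; alignment end ties toward the
  leftmost reference column. These choices only matter for degenerate
  equal-cost paths and are fixed for determinism.
* Pure indels are normalized by the classic left-shift; substitutions
  and delins pass through unchanged.
* The Fisher tail is summed from `stats::dhyper`; the independent test
  oracle enumerates tables from binomial coefficients, and agreement
  with `stats::fisher.test(alternative = "greater")` is asserted to
  1e-9 over all 2×2 tables with margins ≤ 30.
* `example_gene_model()` provides two deterministic, fully synthetic
  genes (no real locus): a ~2 kb six-exon gene with a 900 nt ORF,
  designed repeat stretches and a five-amplicon panel, and a ~360 nt
  single-exon "mini" gene for high-replicate studies.

### Problem sizes used in validation

The simulation studies run at deliberately compact sizes: the
heterozygous-band study uses 1,000 replicates of a depth-1,000
error-free simulation on the mini gene (the published read budget of
50,000 reads per sample exists to guarantee coverage above ~900; at
depth 1,000 the binomial spread of a heterozygous frequency,
SD ≈ 1.6 percentage points, is already the regime of interest); the
tandem-enrichment study uses two samples of 800 reads on the standard
gene with the context multiplier raised to 8 so that artifact calls sit
well above the 20% calling threshold in both samples, making the
recurrence pattern — not threshold noise — the tested signal; end-to-end
truth-recovery runs use 700–1,500 reads. One 50,000-read simulation
verifies the equimolar multinomial draw at the published scale.

## Known limitations

* Single gene model per run; multi-gene panels, transcript databases
  and splice-site effects are out of scope (the design does not
  preclude extension to other genes — any `gene_model` works).
* No phasing from reads: compound heterozygosity is expressed in the
  simulator's truth, but the caller reports two heterozygous variants
  without trans/cis inference.
* No base-quality weighting (simulated qualities are placeholders) and
  no structural-variant or copy-number inference.
* Catalog verdicts are carried, never computed; the package makes no
  pathogenicity judgements.
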