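---
title: "Species-level bacterial profiling from 16S-ITS-23S amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Species-level bacterial profiling from 16S-ITS-23S amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itsprofiler)
```

## The problem and the method

Profiling bacterial communities from 16S rRNA gene amplicons rarely resolves
species: the gene is too conserved. The internal transcribed spacer (ITS)
between the 16S and 23S rRNA genes is far more variable, so amplicons that
anchor in the conserved 3' end of the 16S and the conserved 5' part of the
23S — and therefore span the whole spacer — carry enough signal for
(sub)species assignment while keeping the cost profile of a marker-gene
assay.

`itsprofiler` implements that idea as a self-contained chain:

1. **Reference construction.** 16S-ITS-23S loci are extracted from annotated
   genomes (`pair_loci()`, `extract_loci()`), species labels are reconciled
   against a whole-genome ANI matrix (`ani_correct()`), and the degenerate
   universal primer pair (`uni_its_primers()`: forward
   `KRGGRYKAAGTCGTAACAAG`, reverse `TTTTCRYCTTTCCCTCACGG`) is applied by in
   silico PCR (`amplify()`) to produce one database entry per predicted
   amplicon (`build_reference()`).
2. **Read processing.** Only the forward (R1) read is used; it begins with
   the forward primer by construction. Reads are retained when the primer
   prefix matches (IUPAC-aware, `primer_max_mm = 0`), mean Phred quality
   exceeds 20, and no homopolymer run exceeds 7 bases (`filter_reads()`).
   Retained reads are dereplicated at 100% identity into ASVs; a variant
   must reach 2 copies in at least one sample (`dereplicate()`).
3. **Classification.** Each ASV is assigned by consensus over its accepted
   alignment hits (`classify_asv()`): candidates ranked by shared k-mers,
   aligned query-global with free end gaps on the reference, accepted at
   identity ≥ 0.90 up to 10 hits, and assigned to the deepest rank where
   more than half of the accepted hits agree.
4. **Profiling and diversity.** Reads are aggregated into per-sample
   relative-abundance profiles with an explicit `Unassigned` bucket
   (`profile_samples()`), and summarized by subsampled rarefaction, Shannon
   diversity and Bray-Curtis/Jaccard distances (`rarefy_observed()`,
   `alpha_metrics()`, `beta_matrix()`).
5. **Benchmarking.** Artificial communities with known composition are drawn
   from the reference itself (`make_community()`), scored against their
   expected profiles (`evaluate_profile()`, `genus_agreement()`), and
   subjected to the read-length truncation experiment
   (`truncation_experiment()`).

## Parameters that matter

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `primer_max_mm` | 0 | Mismatches tolerated in the read's primer prefix. Strict by default: amplicon R1 reads begin with the primer, so any mismatch indicates a sequencing artefact. |
| `min_mean_quality` | 20 | Mean read Phred quality, strict `>`. Interpreted as a per-read mean — a per-base rule at Q20 would discard nearly all real reads. |
| `max_homopolymer` | 7 | Longest tolerated homopolymer run (nt); runs of 8+ fail. |
| `min_count` | 2 | Per-sample ASV copy minimum; singleton-everywhere variants are noise under exact dereplication. |
| `min_identity` | 0.90 | Hit acceptance identity. General-purpose consensus classifiers default to 0.80, but species discrimination on the ITS needs a tighter bound; 0.80 remains available via `classifier_params()`. |
| `min_consensus` | 0.51 | Strict majority over accepted hits, evaluated on cumulative rank prefixes; an absent rank counts as disagreement. |
| `max_accepts` / `candidate_pool` | 10 / 50 | Accepted-hit cap and k-mer prefilter pool. On databases where off-target species sit below `min_identity`, the prefilter is exact (verified against brute force in the tests). |
| `max_spacer` | 3000 nt | 16S-23S pairing cap; ribosomal spacers beyond this are implausible and usually indicate annotation errors. |
| ANI `threshold` | 95% | The conventional bacterial species boundary. |

## Numerical and algorithmic choices

**Primer matching.** IUPAC codes are 4-bit sets; a target base matches when
its set is a subset of the primer base's set, so an `N` in the target counts
as a mismatch unless the primer position is at least as degenerate — a
conservative convention for coverage censuses. Coordinates are 1-based
inclusive everywhere. Reverse primers are stored 5'→3' as synthesized and
matched as their reverse complement (IUPAC-aware complementation, R↔Y,
K↔M, B↔V, D↔H). Tied hits are all reported, ordered by
(mismatches, start, strand). The printed primer positions on the reference
organism span 21 nt for 20-nt primers; this package fixes the 3'-end
coordinates (16S 1504, 23S 480) as authoritative, giving sites 1485-1504
and 461-480.

**Alignment identity.** The query (a read-length fragment) is aligned
globally with free end gaps on the reference
(`Biostrings::pairwiseAlignment`, type `"global-local"`; match +1,
mismatch −1, gap open −2, gap extend −1). Identity is matches over
alignment columns spanned by the query, gaps counted as mismatches. Ties in
k-mer rank or identity are broken by lexicographic entry id, making
classification deterministic.

**ANI correction.** The data source states only that an ANI matrix is used
to correct taxonomic assignments; the concrete rule here is this package's
design. Each species label elects a representative (maximal mean ANI to
co-labelled genomes, lexicographic tie-break); every genome is relabelled
to the lineage of its highest-ANI representative provided that ANI ≥ 95%,
otherwise its species is cleared and the genus kept. The operation is
deterministic, order-invariant and idempotent on well-separated species
blocks, and exact label recovery on block-structured matrices with planted
mislabels is asserted in the tests.

**Locus pairing.** The pairing rule (nearest downstream same-strand 23S
within the spacer cap, each 23S claimed once, closest 16S winning) is the
operon-structure default; the data source does not state one. Unpaired and
competing genes are dropped with warnings.

**Dereplication instead of denoising.** Exact (100% identity) dereplication
with the 2-copy rule stands in for error-model denoising and chimera
removal by an external tool. This is a documented divergence: on real data
a denoiser merges erroneous reads into their parent ASVs, whereas exact
dereplication leaves them as (mostly singleton, hence removed) variants.

**Degenerate inputs.** Empty FASTQ input errors at the filter stage; an
empty dereplication input yields an empty table; an empty sample column
yields an empty profile flagged in `empty_samples` with classified
fractions reported as 0; a reference build where no locus amplifies errors
with advice to raise the mismatch allowance.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` builds genomes whose ribosomal operons are
`[16S stub][species-specific ITS][23S stub]`, embedded on either strand
with per-genome primer-site mismatch counts drawn from a configurable
distribution, alongside a block-structured ANI matrix, a 7-rank taxonomy
(with optional planted mislabels) and a ground-truth manifest of every
planted coordinate.

The geometry mirrors the real locus: the forward-primer site ends 38 nt
before the 16S 3' end and the reverse binding site ends 480 nt into the
23S, so fixture amplicons are `58 + ITS + 480` nt; with the default ITS
range of 200-800 nt this reproduces a realistic amplicon length scale
(roughly 0.7-1.3 kb). The default mismatch distribution
(89.7% / 8.2% / 1.0% / 1.1% for 0/1/2/≥3 mismatches) matches the census
reported for universal primers against large rRNA databases. The 16S/23S
stubs are fixed pseudo-conserved scaffolds of 300/500 nt, not full-length
genes: primer-site context is all the downstream code consumes.

Fixtures deliberately idealize several things, so passing tests bound what
they show about real data: ITS sequences are random and unique per species
(real spacers share tRNA islands and repeats, and vary between operons of
one genome); sequencing errors are uniform substitutions at constant Q37
with no indels or chimeras; conserved regions are identical across taxa
rather than merely similar. Consequently the perfect species recovery
demonstrated on fixtures is a correctness check of the machinery, not an
accuracy claim for real communities, where reference coverage dominates
performance.

A practical consequence of the geometry is visible in the truncation
experiment: with 58 conserved bases ahead of the spacer, 75-bp reads retain
only 17 discriminating bases, and off-target references can reach the 0.90
identity bound through gapped alignments, truncating assignments above the
species rank — short reads lose species resolution while ≥150-bp reads
keep it, matching the qualitative behaviour reported for this assay.

## Problem sizes used in the shipped checks

The package's own acceptance checks run, per seed: a 50-species community
of 50,000 error-free 250-bp forward reads (classification, profiling, and
the 250/200/150/100/75-bp truncation series with `min_count = 1`); a
300-genome primer-coverage census under the default mismatch distribution;
a 1,000-sequence zero-mismatch search cross-validated against exhaustive
expansion search; a ≤200-entry database classified with and without the
k-mer prefilter; an 8-species × 4-genome ANI matrix with ~10% planted
mislabels; and 10,000 simulated reads at a 1% substitution rate. These
sizes were chosen to exercise every stage at a scale where the expected
outcomes are exactly known.

The reference-organism coordinate check uses bundled *synthetic* stand-ins
for the K-12 rRNA genes (`inst/extdata/synthetic_K12_*.fasta`): a 1542-nt
16S whose real conserved 3' segment places the forward-primer 3' end at
position 1504, and a 2904-nt 23S with the reverse binding site ending at
position 480; the remainder of both sequences is random and they are
labelled synthetic in name and headers.

## Known limitations

- No denoising or chimera handling (see above); no paired-end merging — the
  method is forward-read-only by design.
- No rRNA gene prediction: annotations are consumed (GFF3), not computed.
- No thermodynamic PCR model; in silico PCR is site matching under a
  mismatch budget with length bounds (defaults 100-3000 nt).
- Classification quality is bounded by reference coverage; taxa absent from
  the database can at best land in `Unassigned` or a shallower rank.
- Phylogenetic diversity metrics (e.g. UniFrac) are out of scope — the
  method builds no tree.
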