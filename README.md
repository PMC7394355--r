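# itsprofiler

Species-level taxonomic profiling of bacterial communities from amplicons of
the 16S–23S internal transcribed spacer (ITS).

## The problem

16S rRNA gene profiling is cheap but rarely resolves bacterial *species*:
the gene is too conserved. The ribosomal spacer between the 16S and 23S
genes is far more variable. Amplifying it with a universal degenerate primer
pair anchored in conserved ribosomal regions — forward
`5'-KRGGRYKAAGTCGTAACAAG-3'` at the 3' end of the 16S, reverse
`5'-TTTTCRYCTTTCCCTCACGG-3'` in the 5' part of the 23S — yields amplicons
that span the whole spacer and support (sub)species assignment at
marker-gene cost. `itsprofiler` is a self-contained reimplementation of that
profiling chain for microbiome researchers who want to build the reference,
process reads, classify, and benchmark without external services.

## What it does

- **Reference building** — extract 16S-ITS-23S loci from annotated genomes
  (FASTA + GFF3), reconcile species labels against a whole-genome ANI matrix
  (representative-based relabelling at the 95% species boundary), and run in
  silico PCR with the degenerate primer pair to produce an amplicon database
  with 7-rank lineages.
- **Degenerate primer toolkit** — IUPAC-aware expansion, mismatch counting,
  site search on both strands, and per-reference coverage censuses binned as
  0 / 1 / 2 / ≥3 mismatches.
- **Read QC and ASVs** — forward-read-only filtering (primer prefix
  anchored at position 1, mean quality > 20, homopolymer runs ≤ 7), exact
  dereplication at 100% identity with a 2-copies-in-some-sample rule.
- **Consensus classification** — vsearch-style consensus over accepted
  alignment hits (query-global, free end gaps on the reference, identity
  ≥ 0.90, up to 10 accepts, strict-majority consensus per rank), assignment
  to the lowest possible taxonomic rank.
- **Benchmarking and diversity** — artificial communities with known
  expected profiles, read-length truncation experiments, recall /
  min-overlap accuracy / Bray-Curtis scoring, subsampled rarefaction
  curves, Shannon, and Bray-Curtis/Jaccard distance matrices.
- **Synthetic fixtures** — a generator that emits genomes with implanted
  ribosomal operons (controlled primer-site mismatches, species-specific
  ITS), block-structured ANI matrices and taxonomies with a full
  ground-truth manifest, so the entire chain is testable offline.

## Worked example

Build a reference from a synthetic fixture, generate an error-free mock
community, and run the profiling chain:

```r
library(itsprofiler)

fix <- generate_fixture(fixture_config(n_species = 8, genomes_per_species = 1,
                                       primer_site_mismatches = c("0" = 1),
                                       seed = 42))
db  <- build_reference(fixture_loci(fix))
db
#> <reference_db> 12 entries, 8 species; amplicon length 1034.2 +/- 185.1 nt

species <- sort(unique(lineage_at_rank(db$entries$lineage, "species")))
comm <- make_community(db, community_spec(species, rep(1/8, 8),
                       total_reads = 5000, read_len = 250, seed = 43))
fl  <- filter_reads(comm$reads, uni_its_primers()$fw, qc_params())
tab <- dereplicate(list(S1 = fl$reads), min_count = 2)
tab
#> <asv_table> 8 ASVs x 1 samples (5000 reads; 0 variants removed)

cls  <- classify_table(tab, db)
prof <- profile_samples(tab, cls)
obs  <- profile_at_rank(prof, "S1", "species")
evaluate_profile(obs, comm$expected, rank = "species")
#> <eval_report> rank=species: taxon recall 1.000, read accuracy 1.000, Bray-Curtis 0.000

head(obs, 3)
#> d__Bacteria;p__Phylum_1;c__Class_1;o__Order_1;f__Family_1;g__Genus_1;s__Species_001
#>                                                                              0.1228
#> d__Bacteria;p__Phylum_1;c__Class_1;o__Order_1;f__Family_1;g__Genus_1;s__Species_002
#>                                                                              0.1194
#> d__Bacteria;p__Phylum_1;c__Class_1;o__Order_1;f__Family_1;g__Genus_2;s__Species_003
#>                                                                              0.1252
```

The 12 database entries cover 8 species because some genomes carry two
operon copies (both retained — multi-operon copies are real signal for the
consensus classifier). All 5,000 error-free reads pass QC, dereplicate into
one ASV per species, and classify back to their source species: recall 1.0,
read-level accuracy 1.0, Bray-Curtis distance 0 against the community's
known composition.

A file-based run of the same chain (filter → dereplicate → classify →
profile → diversity) is available through `run_pipeline()` /
`pipeline_config()`, and as subcommands of the thin CLI at
`inst/cli/itsprofiler.R` (`fixture`, `build-db`, `pcr`, `filter`, `derep`,
`classify`, `pipeline`, `benchmark`, `rarefy`).

## Notes

- The reference-organism primer-coordinate check uses bundled *synthetic*
  stand-ins for the K-12 rRNA genes
  (`inst/extdata/synthetic_K12_*.fasta`); see the methods vignette
  (`vignettes/its-profiling.Rmd`) for what is real (the conserved primer
  context and coordinates) and what is random in those files.
- Exact dereplication stands in for error-model denoising; divergences and
  limitations are documented in the vignette.
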