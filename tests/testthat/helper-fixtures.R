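# Shared in-code fixtures for the test suite.

FW_ALLELE <- "TGGGGTGAAGTCGTAACAAG"            # one expansion of UNI_ITS_fw
RV_SITE <- "CCGTGAGGGAAAGGTGAAAA"              # revcomp of an UNI_ITS_rv expansion

# A small perfect-site fixture database: unique ITS per species, all primer
# sites exact, built through the real locus-extraction + in silico PCR path.
make_test_db <- function(n_species = 6, genomes_per_species = 1,
                         seed = 11, ...) {
  fix <- generate_fixture(fixture_config(
    n_species = n_species, genomes_per_species = genomes_per_species,
    primer_site_mismatches = c("0" = 1), seed = seed, ...))
  list(fix = fix, db = build_reference(fixture_loci(fix)))
}

# The constructed 10-read QC FASTQ: 7 clean reads (3 copies of one variant,
# 2 of a second, 2 singletons), plus one homopolymer read, one mean-Q15 read
# and one primer-less read.
make_qc_reads <- function() {
  body <- function(tail) paste0(strrep("ACGT", 40), tail)
  clean <- function(tail) paste0(FW_ALLELE, body(tail))
  q30 <- function(s) strrep("?", nchar(s))     # Phred 30
  seqs <- c(rep(clean("TGCA"), 3), rep(clean("GATC"), 2),
            clean("CTAG"), clean("AGTC"),
            paste0(FW_ALLELE, strrep("ACGT", 20), "AAAAAAAA",
                   strrep("TGCA", 20)),        # 8-bp homopolymer
            clean("TTCA"),                     # will carry mean Q15
            paste0("CATG", body("GGCA")))      # primer-less
  qual <- q30(seqs)
  qual[9] <- strrep("0", nchar(seqs[9]))       # Phred 15
  data.frame(id = sprintf("r%02d", seq_along(seqs)), seq = seqs, qual = qual,
             stringsAsFactors = FALSE)
}
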