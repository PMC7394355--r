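make_ann <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(contig = "c1", gene = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               stringsAsFactors = FALSE)
  }))
}

test_that("16S/23S pairing extracts the spacer between adjacent genes", {
  set.seed(2)
  genome <- c(c1 = random_acgt(1, 6000))
  ann <- make_ann(list("16S", 100, 1641, "+"), list("23S", 2100, 5004, "+"))
  loci <- pair_loci(ann, genome, genome_id = "g1")
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$start_ITS, 1642L)
  expect_identical(loci$end_ITS, 2099L)
  expect_identical(nchar(loci$seq_ITS), 458L)
  expect_identical(loci$seq_ITS, substr(genome[["c1"]], 1642, 2099))
})

test_that("pairing requires same strand and bounded spacer", {
  set.seed(3)
  genome <- c(c1 = random_acgt(1, 10000))
  # strand mismatch
  ann <- make_ann(list("16S", 100, 1641, "+"), list("23S", 2100, 5004, "-"))
  expect_warning(loci <- pair_loci(ann, genome), "dropped")
  expect_identical(nrow(loci), 0L)
  # spacer above the cap
  ann2 <- make_ann(list("16S", 100, 1600, "+"), list("23S", 5101, 8000, "+"))
  expect_warning(loci2 <- pair_loci(ann2, genome, max_spacer = 3000))
  expect_identical(nrow(loci2), 0L)
  expect_identical(nrow(suppressWarnings(
    pair_loci(ann2, genome, max_spacer = 3500))), 1L)
})

test_that("minus-strand operons are re-oriented to sense", {
  set.seed(6)
  op16 <- random_acgt(1, 200); its <- random_acgt(1, 90); op23 <- random_acgt(1, 300)
  plus <- paste0(op16, its, op23)
  genome <- c(c1 = paste0("ACGTACGTAC", revcomp(plus), "TTGGCCAATT"))
  # on the plus strand the 23S comes first
  ann <- make_ann(list("23S", 11, 310, "-"), list("16S", 401, 600, "-"))
  loci <- pair_loci(ann, genome, genome_id = "g")
  expect_identical(nrow(loci), 1L)
  expect_identical(loci$seq_16S, op16)
  expect_identical(loci$seq_ITS, its)
  expect_identical(loci$seq_23S, op23)
})

test_that("annotations outside the genome raise an error", {
  genome <- c(c1 = strrep("ACGT", 100))
  ann <- make_ann(list("16S", 100, 2000, "+"))
  expect_error(pair_loci(ann, genome), "bounds")
})

test_that("ANI correction relabels against block representatives", {
  # two clean species blocks: nothing changes
  lin <- c(g1 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g2 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g3 = "d__B;p__P;c__C;o__O;f__F;g__G;s__B",
           g4 = "d__B;p__P;c__C;o__O;f__F;g__G;s__B")
  ani <- matrix(80, 4, 4, dimnames = list(names(lin), names(lin)))
  ani[1:2, 1:2] <- 98; ani[3:4, 3:4] <- 98; diag(ani) <- 100
  res <- ani_correct(lin, ani)
  expect_identical(res$lineages, lin)
  expect_identical(nrow(res$changes), 0L)

  # g2 actually belongs to species B (hand-checkable 4-genome case)
  ani2 <- ani
  ani2["g2", c("g1")] <- ani2["g1", "g2"] <- 91
  ani2["g2", c("g3", "g4")] <- ani2[c("g3", "g4"), "g2"] <- 98
  res2 <- ani_correct(lin, ani2, threshold = 95)
  expect_match(res2$lineages[["g2"]], "s__B$")
  expect_identical(res2$changes$genome_id, "g2")
  # unchanged genomes keep their labels
  expect_identical(res2$lineages[c("g1", "g3", "g4")],
                   lin[c("g1", "g3", "g4")])

  # idempotence
  res3 <- ani_correct(res2$lineages, ani2, threshold = 95)
  expect_identical(res3$lineages, res2$lineages)
  expect_identical(nrow(res3$changes), 0L)
})

test_that("ANI correction clears species with no link at threshold", {
  lin <- c(g1 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g2 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g5 = "d__B;p__P;c__C;o__O;f__F;g__H;s__X")
  ani <- matrix(80, 3, 3, dimnames = list(names(lin), names(lin)))
  ani[1:2, 1:2] <- 98; diag(ani) <- 100
  # g5 represents its own singleton species: keeps its label
  res <- ani_correct(lin, ani)
  expect_identical(res$lineages, lin)
  # but with its species label removed it cannot re-acquire one
  lin2 <- lin
  lin2["g5"] <- "d__B;p__P;c__C;o__O;f__F;g__H;s__"
  res2 <- ani_correct(lin2, ani)
  expect_identical(lineage_depth(res2$lineages[["g5"]]), 6L)
})

test_that("ANI correction is invariant to genome input order", {
  lin <- c(g1 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g2 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A",
           g3 = "d__B;p__P;c__C;o__O;f__F;g__G;s__B")
  ani <- matrix(82, 3, 3, dimnames = list(names(lin), names(lin)))
  ani[1:2, 1:2] <- 97; diag(ani) <- 100
  a <- ani_correct(lin, ani)
  b <- ani_correct(lin[c(3, 1, 2)], ani)
  expect_identical(a$lineages[names(lin)], b$lineages[names(lin)])
})

test_that("ANI correction requires every genome in the matrix", {
  lin <- c(g1 = "d__B;p__P;c__C;o__O;f__F;g__G;s__A")
  ani <- matrix(100, 1, 1, dimnames = list("gX", "gX"))
  expect_error(ani_correct(lin, ani), "g1")
})

test_that("reference building reproduces hand-computed length statistics", {
  set.seed(8)
  # constant flanks: 16S contributes 20 nt (primer at its 3' end), 23S 780 nt
  flank16 <- paste0(random_acgt(1, 280), FW_ALLELE)
  flank23 <- paste0(random_acgt(1, 760), RV_SITE, random_acgt(1, 40))
  its <- vapply(c(300, 400, 500), function(l) random_acgt(1, l), "")
  loci <- data.frame(
    genome_id = paste0("g", 1:3), locus_index = 1L, contig = "c",
    strand = "+", start_16S = 1L, end_16S = 300L, start_ITS = 301L,
    end_ITS = 300L + c(300L, 400L, 500L), start_23S = 0L, end_23S = 0L,
    seq_16S = flank16, seq_ITS = its, seq_23S = flank23,
    lineage = sprintf("d__B;p__P;c__C;o__O;f__F;g__G;s__S%d", 1:3),
    stringsAsFactors = FALSE)
  db <- build_reference(loci, max_mm = 0)
  expect_identical(nrow(db$entries), 3L)
  expect_identical(sort(nchar(db$entries$sequence)), c(1100L, 1200L, 1300L))
  expect_equal(db$stats$mean, 1200)
  expect_equal(db$stats$sd, 100)   # n-1 denominator
  expect_identical(db$stats$n, 3L)
})

test_that("loci without a reverse site contribute nothing; failure errors", {
  set.seed(12)
  locus <- data.frame(
    genome_id = "g1", locus_index = 1L, contig = "c", strand = "+",
    start_16S = 1L, end_16S = 300L, start_ITS = 301L, end_ITS = 700L,
    start_23S = 0L, end_23S = 0L,
    seq_16S = paste0(random_acgt(1, 280), FW_ALLELE),
    seq_ITS = random_acgt(1, 400),
    seq_23S = random_acgt(1, 500),     # no reverse-primer site
    lineage = "d__B;p__P;c__C;o__O;f__F;g__G;s__S",
    stringsAsFactors = FALSE)
  expect_error(build_reference(locus, max_mm = 0), "max_mm")
})

test_that("duplicate amplicons from separate operons are both retained", {
  res <- make_test_db(n_species = 2, seed = 21,
                      operons_per_genome = c(2, 2))
  db <- res$db
  expect_identical(nrow(db$entries), 4L)
  expect_identical(anyDuplicated(db$entries$entry_id), 0L)
  # two identical sequences per genome (operon copies)
  expect_identical(as.integer(table(db$entries$sequence)), c(2L, 2L))
})

test_that("reference databases round-trip through FASTA + taxonomy", {
  res <- make_test_db(n_species = 3, seed = 31)
  prefix <- file.path(withr::local_tempdir(), "db")
  write_reference_db(res$db, prefix)
  back <- read_reference_db(paste0(prefix, ".fasta"), paste0(prefix, ".tax.tsv"))
  expect_identical(back$entries$sequence, res$db$entries$sequence)
  expect_identical(back$entries$lineage, res$db$entries$lineage)
  expect_equal(back$stats$mean, res$db$stats$mean)
})
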