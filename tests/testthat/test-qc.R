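test_that("read filtering applies the printed rules with reason precedence", {
  reads <- make_qc_reads()
  fw <- uni_its_primers()$fw
  fl <- filter_reads(reads, fw, qc_params())
  expect_identical(fl$ledger$retained, 7L)
  expect_identical(unname(fl$ledger$discarded),
                   c(1L, 1L, 1L))   # primer, quality, homopolymer
  # conservation
  expect_identical(fl$ledger$input,
                   fl$ledger$retained + sum(fl$ledger$discarded))
  # a read failing primer AND quality is counted under primer
  reads2 <- reads
  reads2$qual[10] <- strrep("0", nchar(reads2$seq[10]))
  fl2 <- filter_reads(reads2, fw, qc_params())
  expect_identical(unname(fl2$ledger$discarded["primer"]), 1L)
  expect_identical(unname(fl2$ledger$discarded["quality"]), 1L)
})

test_that("quality threshold is strict and mean-based", {
  fw <- uni_its_primers()$fw
  seq <- paste0(FW_ALLELE, strrep("ACGT", 30))
  mk <- function(q) data.frame(id = "r", seq = seq,
                               qual = strrep(intToUtf8(q + 33), nchar(seq)),
                               stringsAsFactors = FALSE)
  expect_identical(filter_reads(mk(21), fw, qc_params())$ledger$retained, 1L)
  expect_identical(filter_reads(mk(20), fw, qc_params())$ledger$retained, 0L)
})

test_that("homopolymer rule: runs longer than the cap fail, equal runs pass", {
  fw <- uni_its_primers()$fw
  mk <- function(run) {
    s <- paste0(FW_ALLELE, strrep("ACGT", 10), strrep("A", run),
                strrep("TGCA", 10))
    data.frame(id = "r", seq = s, qual = strrep("?", nchar(s)),
               stringsAsFactors = FALSE)
  }
  expect_identical(filter_reads(mk(7), fw, qc_params())$ledger$retained, 1L)
  expect_identical(filter_reads(mk(8), fw, qc_params())$ledger$retained, 0L)
})

test_that("primer anchoring at mm=0 equals the expansion-prefix oracle", {
  fw <- uni_its_primers()$fw
  set.seed(23)
  ex <- expand_degenerate(fw)
  seqs <- c(paste0(sample(ex, 10, TRUE), random_acgt(10, 100)),
            random_acgt(10, 120))
  reads <- data.frame(id = paste0("r", 1:20), seq = seqs,
                      qual = strrep("?", nchar(seqs)),
                      stringsAsFactors = FALSE)
  fl <- filter_reads(reads, fw, qc_params())
  oracle <- substr(seqs, 1, 20) %in% ex &
    !grepl("A{8,}|C{8,}|G{8,}|T{8,}", seqs)
  expect_identical(sort(fl$reads$id), sort(reads$id[oracle]))
})

test_that("primer trimming removes the anchored prefix when requested", {
  fw <- uni_its_primers()$fw
  s <- paste0(FW_ALLELE, strrep("ACGT", 25))
  reads <- data.frame(id = "r", seq = s, qual = strrep("?", nchar(s)),
                      stringsAsFactors = FALSE)
  fl <- filter_reads(reads, fw, qc_params(trim_primer = TRUE))
  expect_identical(fl$reads$seq, strrep("ACGT", 25))
})

test_that("dereplication enforces the per-sample minimum copy rule", {
  # 3 copies of S1 + 1 copy of S2 in one sample
  tab <- dereplicate(list(A = c(rep("AAACCC", 3), "GGGTTT")), min_count = 2)
  expect_identical(nrow(tab$counts), 1L)
  expect_identical(unname(tab$sequences), "AAACCC")
  expect_identical(unname(tab$counts[1, "A"]), 3L)
  expect_identical(tab$removed$sequence, "GGGTTT")
  # kept when reaching 2 in at least one sample; per-sample counts preserved
  tab2 <- dereplicate(list(A = "ACGTAA", B = rep("ACGTAA", 2)), min_count = 2)
  expect_identical(unname(tab2$counts[1, ]), c(1L, 2L))
  # conservation: retained reads = ASV reads + removed-ASV reads
  tab3 <- dereplicate(list(A = c(rep("AAACCC", 3), "GGGTTT", "TTTAAA")),
                      min_count = 2)
  expect_identical(unname(tab3$ledger$input_reads["A"]),
                   as.integer(sum(tab3$counts[, "A"]) +
                              tab3$ledger$removed_reads[["A"]]))
})

test_that("dereplication is order-invariant and column-consistent", {
  reads <- c("ACGTAC", "ACGTAC", "TTGGCC", "TTGGCC", "TTGGCC")
  a <- dereplicate(list(S1 = reads, S2 = reads), min_count = 2)
  b <- dereplicate(list(S1 = rev(reads), S2 = sample(reads)), min_count = 2)
  expect_identical(a$counts, b$counts)
  expect_identical(unname(a$counts[, "S1"]), unname(a$counts[, "S2"]))
  # ordering: by total abundance, then sequence
  expect_identical(unname(a$sequences[1]), "TTGGCC")
})

test_that("empty input yields an empty table, not an error", {
  tab <- dereplicate(list(A = character(0)), min_count = 2)
  expect_identical(nrow(tab$counts), 0L)
})
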