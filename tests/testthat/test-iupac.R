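test_that("degenerate expansion enumerates exactly the matching sequences", {
  expect_identical(expand_degenerate("ACGT"), "ACGT")
  expect_setequal(expand_degenerate("AY"), c("AC", "AT"))

  fw <- uni_its_primers()$fw
  ex <- expand_degenerate(fw)
  # cardinality = product of per-position degeneracies (five 2-fold positions)
  expect_length(ex, 2^5)
  expect_false(anyDuplicated(ex) > 0)
  # every member matches the primer position-wise; every non-member 20-mer
  # probe built by breaking one fixed position does not
  for (e in ex) expect_identical(mismatch_count(fw$sequence, e), 0L)
  broken <- ex[1]
  substr(broken, 10, 10) <- setdiff(c("A","C","G","T"),
                                    substr(broken, 10, 10))[1]
  expect_gt(mismatch_count(fw$sequence, broken), 0)

  expect_error(expand_degenerate("ACX"), "position 3")
})

test_that("mismatch counting follows the IUPAC subset rule", {
  expect_identical(mismatch_count("AY", "AC"), 0L)
  expect_identical(mismatch_count("AY", "AG"), 1L)
  expect_identical(mismatch_count("KRGG", "TAGG"), 0L)
  # ambiguous target counts as mismatch unless its set is within the primer's
  expect_identical(mismatch_count("AY", "AN"), 1L)
  expect_identical(mismatch_count("AN", "AY"), 0L)
  expect_error(mismatch_count("ACG", "AC"), "lengths differ")
})

test_that("mismatch_count is zero iff the window is an expansion member", {
  set.seed(4)
  ex <- expand_degenerate("KRGGRY")
  for (w in random_acgt(200, 6)) {
    expect_identical(mismatch_count("KRGGRY", w) == 0L, w %in% ex)
  }
})

test_that("find_primer locates constructed sites and reports them sorted", {
  fw <- uni_its_primers()$fw
  hit <- find_primer(paste0("CCC", FW_ALLELE, "TTT"), fw)
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, 4L)
  expect_identical(hit$end, 23L)
  expect_identical(hit$mismatches, 0L)

  expect_identical(nrow(find_primer(strrep("A", 100), fw)), 0L)

  # two sites with different mismatch counts: ordered by (mismatches, start)
  one_mm <- FW_ALLELE
  substr(one_mm, 12, 12) <- "A"   # fixed position 12 is C in the primer
  two <- paste0(one_mm, strrep("T", 30), FW_ALLELE)
  hits <- find_primer(two, fw, max_mismatches = 1)
  expect_identical(hits$mismatches, c(0L, 1L))
  expect_identical(hits$start, c(51L, 1L))
})

test_that("reverse primers are searched as their reverse complement", {
  rv <- uni_its_primers()$rv
  s <- paste0(strrep("CA", 20), RV_SITE, strrep("GT", 20))
  hit <- find_primer(s, rv)
  expect_identical(hit$start, 41L)
  expect_identical(hit$end, 60L)
  expect_identical(hit$strand, "+")
  # the primer itself (as printed) sits on the minus strand
  both <- find_primer(revcomp(s), rv, search_both_strands = TRUE)
  expect_true(any(both$strand == "-"))
})

test_that("zero-mismatch search equals the expansion exact-search oracle", {
  fw <- uni_its_primers()$fw
  set.seed(9)
  for (i in 1:40) {
    s <- random_acgt(1, 600)
    if (i %% 2 == 0) {   # plant an expansion at a random position
      pos <- sample(1:(600 - 20), 1)
      substr(s, pos, pos + 19) <- sample(expand_degenerate(fw), 1)
    }
    got <- find_primer(s, fw, max_mismatches = 0)
    expect_identical(got$start, oracle_exact_sites(s, fw))
  }
})

test_that("hit sets grow monotonically with the mismatch allowance", {
  fw <- uni_its_primers()$fw
  set.seed(17)
  for (s in random_acgt(10, 400)) {
    prev <- character(0)
    for (k in 0:3) {
      h <- find_primer(s, fw, max_mismatches = k)
      cur <- paste(h$start, h$strand)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("coverage census bins minimum mismatch counts per reference", {
  fw <- uni_its_primers()$fw
  mm_site <- function(m) {
    s <- FW_ALLELE
    fixed <- c(3, 4, 8, 9, 10)   # non-degenerate primer positions
    for (p in fixed[seq_len(m)]) {
      substr(s, p, p) <- setdiff(c("A","C","G","T"), substr(s, p, p))[1]
    }
    paste0(strrep("CT", 30), s, strrep("GA", 30))
  }
  refs <- c(vapply(rep(0, 7), mm_site, ""), vapply(rep(1, 2), mm_site, ""),
            mm_site(3))
  names(refs) <- paste0("ref", seq_along(refs))
  cov <- coverage_report(refs, fw)
  expect_equal(unname(cov$fractions), c(0.7, 0.2, 0, 0.1))
  expect_identical(sum(cov$histogram), 10L)
  expect_equal(sum(cov$fractions), 1)

  # single reference equal to a primer expansion
  cov1 <- coverage_report(c(r = expand_degenerate(fw)[1]), fw)
  expect_equal(unname(cov1$fractions), c(1, 0, 0, 0))

  expect_error(coverage_report(character(0), fw), "empty")
})

test_that("coverage reports round-trip through their on-disk form", {
  fw <- uni_its_primers()$fw
  refs <- c(a = paste0("CCC", FW_ALLELE, "GGG"), b = strrep("ACGT", 20))
  cov <- coverage_report(refs, fw)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_coverage_report(cov, tsv, json)
  back <- utils::read.table(tsv, header = TRUE, sep = "\t")
  expect_identical(back$best_mismatches, cov$per_reference$best_mismatches)
  js <- jsonlite::read_json(json)
  expect_equal(unlist(js$fractions), unlist(as.list(cov$fractions)))
})

test_that("primers read from FASTA keep IUPAC codes and orientation", {
  path <- system.file("extdata", "uni_its_primers.fasta",
                      package = "itsprofiler")
  primers <- read_primers(path)
  expect_identical(primers$UNI_ITS_fw$sequence, "KRGGRYKAAGTCGTAACAAG")
  expect_identical(primers$UNI_ITS_rv$orientation, "reverse")
})
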