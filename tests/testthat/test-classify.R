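test_that("pairwise identity matches hand values and the ungapped oracle", {
  set.seed(26)
  a <- random_acgt(1, 100)
  expect_equal(pairwise_identity(a, a)$identity, 1)
  b <- a
  substr(b, 40, 40) <- setdiff(c("A", "C", "G", "T"), substr(a, 40, 40))[1]
  expect_equal(pairwise_identity(b, a)$identity, 0.99)

  # a query that is a fragment of the reference aligns end-gap free
  ref <- random_acgt(1, 900)
  expect_equal(pairwise_identity(substr(ref, 1, 150), ref)$identity, 1)
  expect_equal(pairwise_identity(substr(ref, 301, 500), ref)$identity, 1)

  # substitution-only cases agree with the sliding-window oracle
  for (i in 1:10) {
    q <- substr(ref, 101, 250)
    pos <- sample(150, 3)
    for (p in pos) {
      substr(q, p, p) <- setdiff(c("A", "C", "G", "T"), substr(q, p, p))[1]
    }
    expect_equal(pairwise_identity(q, ref)$identity,
                 oracle_ungapped_identity(q, ref))
  }
})

test_that("a single-base deletion costs one gap column", {
  set.seed(27)
  ref <- random_acgt(1, 100)
  q <- paste0(substr(ref, 1, 49), substr(ref, 51, 100))  # delete base 50
  res <- pairwise_identity(q, ref)
  expect_equal(res$columns, 100)
  expect_equal(res$identity, 0.99)
})

test_that("consensus classification truncates at the agreement depth", {
  res <- make_test_db(n_species = 4, seed = 51)
  db <- res$db
  # an ASV identical to one entry, no other species within min_identity
  entry <- db$entries[1, ]
  cl <- classify_asv(substr(entry$sequence, 1, 250), db)
  expect_identical(cl$status, "assigned")
  expect_identical(cl$depth, 7L)
  expect_identical(cl$lineage, entry$lineage)
  expect_equal(cl$best_identity, 1)

  # two accepted hits in the same genus but different species -> genus
  lin <- c("d__B;p__P;c__C;o__O;f__F;g__G;s__X",
           "d__B;p__P;c__C;o__O;f__F;g__G;s__Y")
  seq <- paste0(FW_ALLELE, strrep("ACGTG", 60), RV_SITE)
  near <- seq
  substr(near, 150, 150) <- "T"
  tiny <- structure(list(
    entries = data.frame(entry_id = c("e1", "e2"),
                         sequence = c(seq, near), lineage = lin,
                         genome_id = c("g1", "g2"), locus_index = 1L,
                         fw_mismatches = 0L, rv_mismatches = 0L,
                         stringsAsFactors = FALSE),
    stats = list(), params = list()), class = "reference_db")
  cl2 <- classify_asv(seq, tiny, classifier_params())
  expect_identical(cl2$n_accepted_hits, 2L)
  expect_identical(cl2$depth, 6L)
  expect_match(cl2$lineage, "g__G;s__$")

  # below the identity threshold -> unassigned
  far <- random_acgt(1, 300, seed = 3)
  cl3 <- classify_asv(far, db)
  expect_identical(cl3$status, "unassigned")
  expect_identical(cl3$n_accepted_hits, 0L)
})

test_that("consensus handles absent ranks as disagreement", {
  lins <- c("d__B;p__P;c__C;o__O;f__F;g__G;s__X",
            "d__B;p__P;c__C;o__O;f__F;g__G;s__X",
            "d__B;p__P;c__C;o__O;f__F;g__;s__")
  cons <- itsprofiler:::consensus_lineage(lins, 0.51)
  expect_identical(cons$depth, 7L)   # 2/3 >= 0.51 at species
  cons2 <- itsprofiler:::consensus_lineage(lins, 0.7)
  expect_identical(cons2$depth, 5L)  # species/genus agreement only 2/3 < 0.7
})

test_that("k-mer prefilter equals brute-force classification on small DBs", {
  res <- make_test_db(n_species = 10, genomes_per_species = 2, seed = 61)
  db <- res$db
  spec <- community_spec(
    unique(lineage_at_rank(db$entries$lineage, "species")),
    rep(0.1, 10), total_reads = 400, read_len = 250, seed = 5)
  comm <- make_community(db, spec)
  tab <- dereplicate(list(S1 = comm$reads), min_count = 1)
  a <- classify_table(tab, db, brute_force = FALSE)
  b <- classify_table(tab, db, brute_force = TRUE)
  expect_identical(a, b)
})

test_that("classification is deterministic under tie-prone inputs", {
  # two identical entries with the same lineage: stable accepted order
  lin <- "d__B;p__P;c__C;o__O;f__F;g__G;s__X"
  s <- paste0(FW_ALLELE, strrep("ACGTG", 50), RV_SITE)
  db <- structure(list(
    entries = data.frame(entry_id = c("b", "a"), sequence = s, lineage = lin,
                         genome_id = "g", locus_index = 1L,
                         fw_mismatches = 0L, rv_mismatches = 0L,
                         stringsAsFactors = FALSE),
    stats = list(), params = list()), class = "reference_db")
  cl <- classify_asv(s, db)
  expect_identical(cl$accepted$entry_id, c("a", "b"))
})

test_that("profiles aggregate reads by lineage with an Unassigned bucket", {
  counts <- matrix(c(60L, 40L), 2, 1,
                   dimnames = list(c("ASV_00001", "ASV_00002"), "S1"))
  tab <- structure(list(
    sequences = c(ASV_00001 = "AAA", ASV_00002 = "CCC"),
    counts = counts, removed = data.frame(), ledger = list()),
    class = "asv_table")
  cls <- data.frame(
    asv_id = c("ASV_00001", "ASV_00002"),
    lineage = c("d__B;p__P;c__C;o__O;f__F;g__G;s__X",
                "d__B;p__P;c__C;o__O;f__F;g__G;s__"),
    depth = c(7L, 6L), best_identity = 1, n_hits = 1L,
    status = "assigned", stringsAsFactors = FALSE)
  prof <- profile_samples(tab, cls)
  expect_equal(unname(prof$classified_fraction["S1", "species"]), 0.6)
  expect_equal(unname(prof$classified_fraction["S1", "genus"]), 1.0)
  sp <- profile_at_rank(prof, "S1", "species")
  expect_equal(unname(sp[["Unassigned"]]), 0.4)
  expect_equal(sum(sp), 1)
  gen <- profile_at_rank(prof, "S1", "genus")
  expect_equal(length(gen), 1L)
  expect_equal(unname(gen[[1]]), 1)

  # an ASV missing from the classifications is an error
  expect_error(profile_samples(tab, cls[1, , drop = FALSE]), "ASV_00002")
})

test_that("empty sample columns are flagged with zero fractions", {
  counts <- matrix(c(5L, 0L), 1, 2,
                   dimnames = list("ASV_00001", c("S1", "S2")))
  tab <- structure(list(sequences = c(ASV_00001 = "AAA"), counts = counts,
                        removed = data.frame(), ledger = list()),
                   class = "asv_table")
  cls <- data.frame(asv_id = "ASV_00001",
                    lineage = "d__B;p__P;c__C;o__O;f__F;g__G;s__X",
                    depth = 7L, best_identity = 1, n_hits = 1L,
                    status = "assigned", stringsAsFactors = FALSE)
  prof <- profile_samples(tab, cls)
  expect_identical(prof$empty_samples, "S2")
  expect_equal(unname(prof$classified_fraction["S2", "species"]), 0)
  expect_length(profile_at_rank(prof, "S2", "species"), 0)
})
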