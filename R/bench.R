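# Artificial-community benchmarking: generate read sets with known expected
# profiles from the reference database, run read-length truncation
# experiments, and score observed against expected profiles.

#' Specify an artificial community
#'
#' @param lineages species-level lineage strings.
#' @param abundances positive relative abundances summing to 1 (tolerance
#'   1e-9).
#' @param total_reads number of reads to draw (default 50000).
#' @param read_len forward-read length (default 250).
#' @param seed RNG seed.
#' @return a `community_spec` object.
#' @export
community_spec <- function(lineages, abundances, total_reads = 50000,
                           read_len = 250, seed = 1) {
  stopifnot(length(lineages) == length(abundances))
  if (any(abundances <= 0)) stopf("abundances must be positive")
  if (abs(sum(abundances) - 1) > 1e-9) {
    stopf("abundances must sum to 1 (got %.12f)", sum(abundances))
  }
  if (anyDuplicated(lineages)) stopf("duplicated lineages in community spec")
  structure(list(lineages = format_lineage(parse_lineage(lineages)),
                 abundances = abundances, total_reads = total_reads,
                 read_len = read_len, seed = seed),
            class = "community_spec")
}

#' Generate an artificial community read set with its expected profile
#'
#' Reads are drawn multinomially over species according to the specified
#' abundances; each read's template entry is chosen uniformly among the
#' species' database entries, and the read is the first `read_len` bases of
#' the amplicon (forward orientation, so it begins with the forward primer
#' region), with substitution errors at `error_rate`.
#'
#' @param db a `reference_db`.
#' @param spec a [community_spec()].
#' @param error_rate per-base substitution probability (default 0).
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `expected`
#'   (species-rank `taxon_profile` of the realized per-species read
#'   proportions — the ground truth of the generated read set; it converges
#'   to the specified abundances as `total_reads` grows).
#' @export
make_community <- function(db, spec, error_rate = 0) {
  stopifnot(inherits(db, "reference_db"), inherits(spec, "community_spec"))
  db_species <- lineage_at_rank(db$entries$lineage, "species")
  entry_sets <- lapply(spec$lineages, function(l) which(db_species == l))
  absent <- !vapply(entry_sets, function(x) length(x) > 0, logical(1))
  if (any(absent)) {
    stopf("species absent from reference database: %s",
          paste(spec$lineages[absent], collapse = ", "))
  }
  with_seed(spec$seed, {
    n_per <- as.vector(stats::rmultinom(1, spec$total_reads, spec$abundances))
    chunks <- lapply(seq_along(entry_sets), function(i) {
      n <- n_per[i]
      if (n == 0) return(NULL)
      idx <- entry_sets[[i]]
      picks <- if (length(idx) == 1) rep(idx, n) else
        sample(idx, n, replace = TRUE)
      seqs <- substr(db$entries$sequence[picks], 1, spec$read_len)
      data.frame(species = i, seq = seqs, stringsAsFactors = FALSE)
    })
    reads <- do.call(rbind, chunks)
    if (error_rate > 0) {
      reads$seq <- add_substitutions(reads$seq, error_rate)
    }
    reads <- data.frame(
      id = sprintf("read_%d", seq_len(nrow(reads))),
      seq = reads$seq,
      qual = strrep("F", nchar(reads$seq)),
      stringsAsFactors = FALSE)
    # ground truth of THIS read set: the realized multinomial draw
    expected <- structure(
      stats::setNames(n_per / sum(n_per),
                      spec$lineages)[radix_order(spec$lineages)],
      sample = "expected", rank = "species", class = "taxon_profile")
    list(reads = reads, expected = expected)
  })
}

# independent per-base substitutions on a character vector of reads
add_substitutions <- function(seqs, rate) {
  lens <- nchar(seqs)
  for (i in seq_along(seqs)) {
    hit <- which(stats::runif(lens[i]) < rate)
    for (p in hit) {
      orig <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), orig), 1)
    }
  }
  seqs
}

#' Score an observed profile against an expected profile
#'
#' Profiles are compared at a rank: taxon-level recall is the fraction of
#' expected taxa detected (abundance > 0) in the observed profile; read-level
#' accuracy is the min-overlap statistic `sum_i min(observed_i, expected_i)`
#' over matching taxa (equivalent to 1 - Bray-Curtis on normalized
#' profiles); the Bray-Curtis distance is taken over the union of taxa
#' (including any `Unassigned` mass).
#'
#' @param observed,expected `taxon_profile` objects (or named abundance
#'   vectors) at a comparable rank.
#' @param rank rank label recorded in the report.
#' @return object of class `eval_report`: list with `rank`, `taxon_recall`,
#'   `read_accuracy`, `bray_curtis` and a `confusion` data.frame (one row per
#'   expected taxon: expected vs observed abundance and detection flag).
#' @export
evaluate_profile <- function(observed, expected, rank = "species") {
  obs <- drop_class(observed)
  exp <- drop_class(expected)
  if (length(exp) == 0) stopf("empty expected profile")
  obs <- obs / max(sum(obs), .Machine$double.eps)
  exp <- exp / sum(exp)
  exp_taxa <- names(exp)[names(exp) != "Unassigned"]
  detected <- exp_taxa[exp_taxa %in% names(obs)[obs > 0]]
  taxa <- sort(union(names(obs), names(exp)))
  ov <- stats::setNames(numeric(length(taxa)), taxa)
  ev <- ov
  ov[names(obs)] <- obs
  ev[names(exp)] <- exp
  confusion <- data.frame(
    expected_taxon = exp_taxa,
    expected_abundance = unname(ev[exp_taxa]),
    observed_abundance = unname(ov[exp_taxa]),
    observed = ifelse(exp_taxa %in% detected, exp_taxa, "Unassigned/absent"),
    stringsAsFactors = FALSE)
  structure(list(
    rank = rank,
    taxon_recall = length(detected) / length(exp_taxa),
    read_accuracy = sum(pmin(ov, ev)[taxa != "Unassigned"]),
    bray_curtis = sum(abs(ov - ev)) / sum(ov + ev),
    confusion = confusion
  ), class = "eval_report")
}

drop_class <- function(x) {
  y <- as.numeric(x)
  names(y) <- names(x)
  y
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> rank=%s: taxon recall %.3f, ",
                     "read accuracy %.3f, Bray-Curtis %.3f\n"),
              x$rank, x$taxon_recall, x$read_accuracy, x$bray_curtis))
  invisible(x)
}

#' Genus-level agreement between two profiles
#'
#' Fraction of genus-classified reads in `profile_1` whose genus appears in
#' the detected-genus set (abundance > 0) of `profile_2`. Used to compare a
#' profile against one produced by an independent method.
#'
#' @param profile_1 genus-rank `taxon_profile` (or named abundance/count
#'   vector; `Unassigned` is excluded from the denominator).
#' @param profile_2 genus-rank `taxon_profile`, named vector, or a character
#'   vector of detected genus lineages.
#' @param threshold detection threshold on `profile_2` abundances (default 0,
#'   i.e. presence).
#' @return fraction in `[0, 1]`; 0 when `profile_2` detects nothing.
#' @export
genus_agreement <- function(profile_1, profile_2, threshold = 0) {
  p1 <- drop_class(profile_1)
  p1 <- p1[names(p1) != "Unassigned"]
  if (length(p1) == 0 || sum(p1) == 0) {
    stopf("profile_1 contains no genus-classified reads")
  }
  g2 <- if (is.character(profile_2)) profile_2 else {
    p2 <- drop_class(profile_2)
    names(p2)[p2 > threshold & names(p2) != "Unassigned"]
  }
  sum(p1[names(p1) %in% g2]) / sum(p1)
}

#' Run the read-length truncation experiment
#'
#' Truncates a community read set to each length, runs QC, dereplication,
#' classification and profiling, and records the species-level classified
#' read fraction per length.
#'
#' @param reads community reads data.frame.
#' @param db a `reference_db`.
#' @param lengths read lengths to test (default `c(250, 200, 150, 100, 75)`).
#' @param fw forward primer.
#' @param qc a [qc_params()] block.
#' @param params a [classifier_params()] block.
#' @param min_count dereplication minimum copy number (default 2).
#' @param sample_id sample label.
#' @return data.frame with columns `read_len`, `species_classified_fraction`,
#'   `n_asvs`, `retained_reads`.
#' @export
truncation_experiment <- function(reads, db,
                                  lengths = c(250, 200, 150, 100, 75),
                                  fw = uni_its_primers()$fw,
                                  qc = qc_params(),
                                  params = classifier_params(),
                                  min_count = 2, sample_id = "S1") {
  rows <- lapply(lengths, function(L) {
    tr <- truncate_reads(reads, L)
    fl <- filter_reads(tr, fw, qc)
    tab <- dereplicate(stats::setNames(list(fl$reads), sample_id),
                       min_count = min_count)
    cls <- classify_table(tab, db, params)
    prof <- profile_samples(tab, cls)
    data.frame(read_len = L,
               species_classified_fraction =
                 unname(prof$classified_fraction[sample_id, "species"]),
               n_asvs = nrow(tab$counts),
               retained_reads = unname(sum(tab$counts[, sample_id])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
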