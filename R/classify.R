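# Consensus alignment classifier.
#
# Each ASV is compared against the reference database: candidate entries are
# ranked by shared k-mer count, the top candidates are aligned (global on the
# query, free end gaps on the reference, since reads are fragments of full
# amplicons), hits at or above the identity threshold are accepted up to
# max_accepts, and the assignment is the deepest taxonomic rank on which a
# fraction >= min_consensus of the accepted hits agree — the semantics of
# consensus classifiers in the vsearch/QIIME tradition.

#' Classifier parameter block
#'
#' @param min_identity minimum pairwise identity for an accepted hit
#'   (default 0.90; species discrimination on the ITS calls for a tighter
#'   default than the 0.80 used by general-purpose consensus classifiers).
#' @param max_accepts maximum number of accepted hits (default 10).
#' @param min_consensus fraction of accepted hits that must agree at a rank
#'   (default 0.51; must exceed 0.5).
#' @param kmer_size k-mer length for the candidate prefilter (default 8).
#' @param candidate_pool number of top k-mer candidates aligned (default 50).
#' @return a `classifier_params` list.
#' @export
classifier_params <- function(min_identity = 0.90, max_accepts = 10,
                              min_consensus = 0.51, kmer_size = 8,
                              candidate_pool = 50) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_consensus > 0.5, min_consensus <= 1,
            max_accepts >= 1, kmer_size >= 1, candidate_pool >= 1)
  structure(list(min_identity = min_identity, max_accepts = max_accepts,
                 min_consensus = min_consensus, kmer_size = kmer_size,
                 candidate_pool = candidate_pool),
            class = "classifier_params")
}

#' Pairwise identity of a query fragment against a reference
#'
#' Global alignment of the query with free end gaps on the reference (the
#' query is typically a read-length fragment of a longer amplicon). Identity
#' is matches over alignment columns spanned by the query, with gap columns
#' counted as mismatches. Scoring: match +1, mismatch -1, gap open -2,
#' gap extend -1.
#'
#' @param query,reference nucleotide strings.
#' @return list with `identity`, `matches`, `columns` and alignment `score`.
#' @export
pairwise_identity <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) stopf("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global-local",
    substitutionMatrix = .nuc_mat(), gapOpening = 2, gapExtension = 1)
  cols <- nchar(as.character(Biostrings::pattern(aln)))  # columns incl. gaps
  m <- Biostrings::nmatch(aln)
  list(identity = m / cols, matches = m, columns = cols,
       score = Biostrings::score(aln))
}

.nuc_env <- new.env(parent = emptyenv())
.nuc_mat <- function() {
  if (is.null(.nuc_env$mat)) {
    .nuc_env$mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .nuc_env$mat
}

# k-mer index of database entries: list of unique k-mer character vectors
kmer_set <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

db_kmer_index <- function(db, k) {
  lapply(db$entries$sequence, kmer_set, k = k)
}

#' Classify one ASV against the reference database
#'
#' Candidates are ranked by shared k-mer count (ties by entry id); the top
#' `candidate_pool` are aligned, hits with identity >= `min_identity` are
#' ordered by (identity, entry id) and accepted up to `max_accepts`; the
#' consensus lineage is the deepest rank at which a fraction >=
#' `min_consensus` of accepted hits share the same rank prefix (an absent
#' rank counts as disagreement). With `brute_force = TRUE` the k-mer
#' prefilter is bypassed and every entry is aligned.
#'
#' @param asv nucleotide string.
#' @param db a `reference_db`.
#' @param params a [classifier_params()] block.
#' @param brute_force align against every entry (default FALSE).
#' @param kmer_index precomputed [db] k-mer index (internal optimisation).
#' @return object of class `its_classification`: list with `lineage`,
#'   `depth`, `status` (`"assigned"`/`"unassigned"`), `n_accepted_hits`,
#'   `best_identity` and `accepted` (data.frame of accepted hits).
#' @export
classify_asv <- function(asv, db, params = classifier_params(),
                         brute_force = FALSE, kmer_index = NULL) {
  stopifnot(inherits(db, "reference_db"))
  if (nrow(db$entries) == 0) stopf("empty reference database")
  ids <- db$entries$entry_id
  if (brute_force) {
    cand <- radix_order(ids)
  } else {
    if (is.null(kmer_index)) kmer_index <- db_kmer_index(db, params$kmer_size)
    q <- kmer_set(asv, params$kmer_size)
    shared <- vapply(kmer_index, function(s) as.numeric(sum(q %in% s)),
                     numeric(1))
    cand <- radix_order(-shared, ids)
    cand <- cand[seq_len(min(params$candidate_pool, length(cand)))]
  }
  idents <- vapply(cand, function(i) {
    pairwise_identity(asv, db$entries$sequence[i])$identity
  }, numeric(1))
  qual <- idents >= params$min_identity
  hit_idx <- cand[qual]
  hit_id <- idents[qual]
  ord <- radix_order(-hit_id, ids[hit_idx])
  ord <- ord[seq_len(min(params$max_accepts, length(ord)))]
  accepted <- data.frame(entry_id = ids[hit_idx][ord],
                         lineage = db$entries$lineage[hit_idx][ord],
                         identity = hit_id[ord], stringsAsFactors = FALSE)
  if (nrow(accepted) == 0) {
    return(structure(list(lineage = format_lineage(matrix("", 1, 7)),
                          depth = 0L, status = "unassigned",
                          n_accepted_hits = 0L, best_identity = NA_real_,
                          accepted = accepted),
                     class = "its_classification"))
  }
  cons <- consensus_lineage(accepted$lineage, params$min_consensus)
  structure(list(lineage = cons$lineage, depth = cons$depth,
                 status = "assigned",
                 n_accepted_hits = nrow(accepted),
                 best_identity = max(accepted$identity),
                 accepted = accepted),
            class = "its_classification")
}

# Deepest rank whose modal (non-empty) cumulative prefix is shared by a
# fraction >= min_consensus of the lineages.
consensus_lineage <- function(lineages, min_consensus) {
  m <- parse_lineage(lineages)
  n <- length(lineages)
  best_depth <- 0L
  best_prefix <- rep("", 7)
  for (d in 1:7) {
    vals <- apply(m[, 1:d, drop = FALSE], 1, paste, collapse = ";")
    vals[!nzchar(m[, d])] <- NA          # absent rank: disagreement
    tab <- table(vals, useNA = "no")
    if (length(tab) == 0) break
    top <- max(tab)
    if (top / n >= min_consensus) {
      winner <- sort(names(tab)[tab == top])[1]
      best_depth <- d
      best_prefix <- c(strsplit(winner, ";", fixed = TRUE)[[1]],
                       rep("", 7 - d))
    } else break
  }
  list(lineage = format_lineage(matrix(best_prefix, 1, 7)),
       depth = best_depth)
}

#' @export
print.its_classification <- function(x, ...) {
  cat(sprintf("<its_classification> %s (depth %d, %d hits, best id %.3f)\n  %s\n",
              x$status, x$depth, x$n_accepted_hits,
              ifelse(is.na(x$best_identity), 0, x$best_identity), x$lineage))
  invisible(x)
}

#' Classify every ASV in a table
#'
#' @param table an `asv_table`.
#' @param db a `reference_db`.
#' @param params a [classifier_params()] block.
#' @param brute_force bypass the k-mer prefilter (default FALSE).
#' @return data.frame with one row per ASV: `asv_id`, `lineage`, `depth`,
#'   `best_identity`, `n_hits`, `status`.
#' @export
classify_table <- function(table, db, params = classifier_params(),
                           brute_force = FALSE) {
  stopifnot(inherits(table, "asv_table"))
  idx <- if (brute_force) NULL else db_kmer_index(db, params$kmer_size)
  rows <- lapply(names(table$sequences), function(id) {
    cl <- classify_asv(table$sequences[[id]], db, params,
                       brute_force = brute_force, kmer_index = idx)
    data.frame(asv_id = id, lineage = cl$lineage, depth = cl$depth,
               best_identity = ifelse(is.na(cl$best_identity), NA_real_,
                                      cl$best_identity),
               n_hits = cl$n_accepted_hits, status = cl$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate classified ASVs into per-sample taxonomic profiles
#'
#' Per sample, reads are aggregated by assigned lineage; relative abundances
#' sum to 1 including an `Unassigned` bucket. The per-rank classified
#' fraction is the share of the sample's ASV-table reads whose assignment
#' reaches that rank.
#'
#' @param table an `asv_table`.
#' @param classifications output of [classify_table()] covering every ASV in
#'   `table`.
#' @return object of class `taxon_profiles`: list with `profiles` (named list
#'   of per-sample named abundance vectors over full assigned lineages, plus
#'   `Unassigned`), `classified_fraction` (matrix sample x rank), `reads`
#'   (per-sample totals) and `empty_samples` (flagged zero-read samples).
#' @export
profile_samples <- function(table, classifications) {
  stopifnot(inherits(table, "asv_table"))
  missing <- setdiff(rownames(table$counts), classifications$asv_id)
  if (length(missing)) {
    stopf("ASV(s) missing from classifications: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  cl <- classifications[match(rownames(table$counts), classifications$asv_id), ]
  samples <- colnames(table$counts)
  totals <- colSums(table$counts)
  profiles <- list()
  frac <- matrix(0, nrow = length(samples), ncol = 7,
                 dimnames = list(samples, TAX_RANKS))
  for (s in samples) {
    cnt <- table$counts[, s]
    if (totals[s] == 0) {
      profiles[[s]] <- stats::setNames(numeric(0), character(0))
      next
    }
    key <- ifelse(cl$status == "assigned" & cl$depth > 0,
                  cl$lineage, "Unassigned")
    ab <- tapply(cnt, key, sum) / totals[s]
    profiles[[s]] <- ab[radix_order(names(ab))]
    for (d in 1:7) {
      frac[s, d] <- sum(cnt[cl$depth >= d]) / totals[s]
    }
  }
  structure(list(profiles = profiles, classified_fraction = frac,
                 reads = totals, empty_samples = names(totals)[totals == 0]),
            class = "taxon_profiles")
}

#' @export
print.taxon_profiles <- function(x, ...) {
  cat(sprintf("<taxon_profiles> %d sample(s)\n", length(x$profiles)))
  cat("species-level classified fraction:\n")
  print(round(stats::setNames(x$classified_fraction[, "species"],
                              rownames(x$classified_fraction)), 4))
  invisible(x)
}

#' Collapse a sample profile to a taxonomic rank
#'
#' Lineages are truncated at `rank`; reads whose assignment does not reach
#' the rank fall into `Unassigned`.
#'
#' @param profiles a `taxon_profiles` object.
#' @param sample sample id.
#' @param rank rank name or index (1-7).
#' @return object of class `taxon_profile`: named numeric abundance vector
#'   (sums to 1) with attributes `sample` and `rank`.
#' @export
profile_at_rank <- function(profiles, sample, rank) {
  stopifnot(inherits(profiles, "taxon_profiles"))
  d <- rank_index(rank)
  p <- profiles$profiles[[sample]]
  if (is.null(p)) stopf("unknown sample '%s'", sample)
  as_taxon_profile(p, d, sample)
}

as_taxon_profile <- function(p, d, sample = NA_character_) {
  if (length(p) == 0) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     sample = sample, rank = TAX_RANKS[d],
                     class = "taxon_profile"))
  }
  keys <- names(p)
  assigned <- keys != "Unassigned"
  newkey <- keys
  if (any(assigned)) {
    lin <- lineage_at_rank(keys[assigned], d)
    deep_enough <- lineage_depth(keys[assigned]) >= d
    newkey[assigned] <- ifelse(deep_enough, lin, "Unassigned")
  }
  ab <- tapply(unname(p), newkey, sum)
  out <- stats::setNames(as.numeric(ab), names(ab))
  out <- out[radix_order(names(out))]
  structure(out, sample = sample, rank = TAX_RANKS[d],
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat(sprintf("<taxon_profile> sample=%s rank=%s, %d taxa\n",
              attr(x, "sample"), attr(x, "rank"), length(x)))
  y <- sort(unclass(x), decreasing = TRUE)
  print(round(utils::head(y, 10), 4))
  invisible(x)
}
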