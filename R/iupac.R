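# Degenerate (IUPAC) primer representation and site search.
#
# A target base matches a primer base when the target's base set is a subset
# of the primer's set; an ambiguous target base (e.g. N) therefore counts as a
# mismatch unless the primer position is at least as degenerate. This is the
# conservative convention used for the primer coverage census.

#' Construct a degenerate primer
#'
#' @param name short identifier.
#' @param sequence oligonucleotide over the IUPAC alphabet
#'   (`ACGTRYSWKMBDHVN`); stored uppercase.
#' @param orientation `"forward"` or `"reverse"`. Reverse primers are stored
#'   5'->3' as synthesized; site finding matches their reverse complement
#'   against the target strand.
#' @return an object of class `iupac_primer`.
#' @examples
#' iupac_primer("UNI_ITS_fw", "KRGGRYKAAGTCGTAACAAG", "forward")
#' @export
iupac_primer <- function(name, sequence, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stopf("primer '%s' has an empty sequence", name)
  iupac_encode(sequence)  # validates, errors name the offending position
  structure(
    list(name = name, sequence = sequence, orientation = orientation),
    class = "iupac_primer"
  )
}

#' @export
print.iupac_primer <- function(x, ...) {
  cat(sprintf("<iupac_primer> %s (%s) 5'-%s-3' [%d nt, %d expansions]\n",
              x$name, x$orientation, x$sequence, nchar(x$sequence),
              n_expansions(x$sequence)))
  invisible(x)
}

n_expansions <- function(seq) {
  prod(vapply(IUPAC_SETS[strsplit(toupper(seq), "")[[1]]], length, 1L))
}

#' The universal bacterial ITS primer pair
#'
#' The degenerate primer pair targeting the conserved 3' end of the 16S rRNA
#' gene (UNI_ITS_fw) and a conserved region in the 5' part of the 23S rRNA
#' gene (UNI_ITS_rv), so that the predicted amplicon spans the 16S-23S
#' internal transcribed spacer.
#'
#' @return list with elements `fw` and `rv`, both `iupac_primer` objects.
#' @export
uni_its_primers <- function() {
  list(
    fw = iupac_primer("UNI_ITS_fw", "KRGGRYKAAGTCGTAACAAG", "forward"),
    rv = iupac_primer("UNI_ITS_rv", "TTTTCRYCTTTCCCTCACGG", "reverse")
  )
}

#' Expand a degenerate primer into all concrete sequences
#'
#' @param primer an `iupac_primer` or a plain IUPAC string.
#' @return character vector of all ACGT sequences matching the primer; its
#'   length is the product of the per-position degeneracies.
#' @export
expand_degenerate <- function(primer) {
  seq <- primer_sequence(primer)
  iupac_encode(seq)  # validate
  sets <- IUPAC_SETS[strsplit(seq, "")[[1]]]
  grid <- do.call(expand.grid,
                  c(rev(unname(sets)), list(stringsAsFactors = FALSE)))
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste, collapse = ""))
}

primer_sequence <- function(primer) {
  if (inherits(primer, "iupac_primer")) primer$sequence else toupper(primer)
}

#' Count IUPAC-aware mismatches between two equal-length windows
#'
#' A position matches when the target base's set is a subset of the primer
#' base's set; ambiguous target bases count as mismatches otherwise.
#'
#' @param primer_window IUPAC string.
#' @param target_window nucleotide string of the same length.
#' @return non-negative integer mismatch count.
#' @export
mismatch_count <- function(primer_window, target_window) {
  p <- iupac_encode(primer_sequence(primer_window))
  t <- iupac_encode(target_window)
  if (length(p) != length(t)) {
    stopf("window lengths differ (%d vs %d)", length(p), length(t))
  }
  sum(bitwAnd(t, p) != t)
}

# Mismatch counts of `pattern_codes` against every window of `seq_codes`;
# returns integer vector of length n - L + 1 (empty when the sequence is
# shorter than the pattern).
mm_profile <- function(seq_codes, pattern_codes) {
  n <- length(seq_codes)
  L <- length(pattern_codes)
  if (n < L) return(integer(0))
  out <- integer(n - L + 1L)
  for (j in seq_len(L)) {
    tw <- seq_codes[j:(n - L + j)]
    out <- out + (bitwAnd(tw, pattern_codes[j]) != tw)
  }
  out
}

#' Locate primer binding sites on a sequence
#'
#' Reports every window whose IUPAC-aware mismatch count is within
#' `max_mismatches`. Forward primers are matched as stored; reverse primers
#' are matched as their reverse complement, so a `+` strand hit of a reverse
#' primer is the primer's binding site on the given strand. With
#' `search_both_strands = TRUE` the reverse complement of the effective
#' pattern is searched as well and reported with strand `-`; coordinates are
#' always 1-based inclusive on the given sequence.
#'
#' @param sequence nucleotide string, or a named character vector /
#'   `Biostrings::DNAStringSet` of several references.
#' @param primer an `iupac_primer`.
#' @param max_mismatches maximum mismatches per window (default 0).
#' @param search_both_strands also scan the opposite strand (default FALSE).
#' @return data.frame with columns `reference_id`, `start`, `end`, `strand`,
#'   `mismatches`, sorted by (mismatches, start, strand); zero rows when no
#'   site is found.
#' @export
find_primer <- function(sequence, primer, max_mismatches = 0,
                        search_both_strands = FALSE) {
  stopifnot(inherits(primer, "iupac_primer"))
  seqs <- as_named_sequences(sequence)
  if (any(!nzchar(seqs))) stopf("empty sequence supplied to find_primer")
  pattern <- if (primer$orientation == "forward") primer$sequence
             else revcomp(primer$sequence)
  pat_fwd <- iupac_encode(pattern)
  pat_rev <- iupac_encode(revcomp(pattern))
  L <- length(pat_fwd)
  res <- lapply(names(seqs), function(id) {
    codes <- iupac_encode(seqs[[id]])
    hit_rows(id, codes, pat_fwd, pat_rev, L, max_mismatches,
             search_both_strands)
  })
  out <- do.call(rbind, res)
  out <- out[radix_order(out$mismatches, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

hit_rows <- function(id, codes, pat_fwd, pat_rev, L, max_mm, both) {
  mk <- function(mm, strand) {
    keep <- which(mm <= max_mm)
    data.frame(reference_id = rep(id, length(keep)),
               start = keep, end = keep + L - 1L,
               strand = rep(strand, length(keep)),
               mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  out <- mk(mm_profile(codes, pat_fwd), "+")
  if (both) out <- rbind(out, mk(mm_profile(codes, pat_rev), "-"))
  out
}

as_named_sequences <- function(sequence) {
  if (inherits(sequence, "DNAStringSet")) {
    sequence <- stats::setNames(as.character(sequence), names(sequence))
  }
  sequence <- toupper(sequence)
  if (is.null(names(sequence))) {
    names(sequence) <- if (length(sequence) == 1) "seq" else
      paste0("seq", seq_along(sequence))
  }
  as.list(sequence)
}

#' Primer coverage census over a reference collection
#'
#' For each reference the minimum mismatch count over all windows (both
#' strands) is computed and binned into `{0, 1, 2, >=cap}`; bin fractions are
#' taken over all references. This reproduces the style of census used to
#' assess the taxonomic coverage of a universal primer against an rRNA
#' database.
#'
#' @param references named character vector or `DNAStringSet` (non-empty).
#' @param primer an `iupac_primer`.
#' @param cap lower edge of the open top bin (default 3, i.e. `>=3`).
#' @return object of class `coverage_report`: list with `per_reference`
#'   (data.frame `reference_id`, `best_mismatches`), `histogram` (integer
#'   counts per bin), `fractions` (bin fractions summing to 1) and `cap`.
#' @export
coverage_report <- function(references, primer, cap = 3) {
  if (length(references) == 0) stopf("empty reference collection")
  seqs <- as_named_sequences(references)
  stopifnot(inherits(primer, "iupac_primer"))
  pattern <- if (primer$orientation == "forward") primer$sequence
             else revcomp(primer$sequence)
  pat_fwd <- iupac_encode(pattern)
  pat_rev <- iupac_encode(revcomp(pattern))
  best <- vapply(seqs, function(s) {
    codes <- iupac_encode(s)
    mm <- c(mm_profile(codes, pat_fwd), mm_profile(codes, pat_rev))
    if (length(mm) == 0) length(pat_fwd) else min(mm)
  }, integer(1))
  bins <- pmin(best, cap)
  labels <- c(as.character(seq(0, cap - 1)), paste0(">=", cap))
  hist <- vapply(seq(0, cap), function(b) sum(bins == b), integer(1))
  names(hist) <- labels
  structure(
    list(
      per_reference = data.frame(reference_id = names(seqs),
                                 best_mismatches = unname(best),
                                 stringsAsFactors = FALSE),
      histogram = hist,
      fractions = hist / length(seqs),
      cap = cap
    ),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d references\n", nrow(x$per_reference)))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Write a coverage report to disk
#'
#' @param report a `coverage_report`.
#' @param tsv path for the per-reference TSV.
#' @param json optional path for the JSON bin-fraction summary.
#' @return invisibly, the report.
#' @export
write_coverage_report <- function(report, tsv, json = NULL) {
  stopifnot(inherits(report, "coverage_report"))
  utils::write.table(report$per_reference, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(histogram = as.list(report$histogram),
           fractions = as.list(report$fractions)),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}

#' Read primers from a FASTA file
#'
#' Headers are primer names; sequences may contain IUPAC codes. Orientation
#' is inferred from a `_rv`/`_rev`/`_R` name suffix (reverse), defaulting to
#' forward.
#'
#' @param path FASTA file.
#' @return named list of `iupac_primer` objects.
#' @export
read_primers <- function(path) {
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(nm) {
    ori <- if (grepl("(_rv|_rev|_R)$", nm)) "reverse" else "forward"
    iupac_primer(nm, seqs[[nm]], ori)
  })
  stats::setNames(out, names(seqs))
}
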