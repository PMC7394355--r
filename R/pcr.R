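# In silico PCR: amplicon prediction for a degenerate primer pair, and
# error-model read simulation from predicted amplicons.

#' Predict amplicons of a primer pair on a template
#'
#' Every forward-primer hit on the sense strand is combined with every
#' downstream reverse-primer binding site (the reverse primer matched as its
#' reverse complement); the spanned region, inclusive of both primer-binding
#' sites, is emitted when its length falls within `[min_len, max_len]`.
#' Nested and overlapping products are all reported.
#'
#' @param template nucleotide string (or named length-1 vector).
#' @param fw,rv forward / reverse `iupac_primer`s.
#' @param max_mm maximum IUPAC-aware mismatches per primer site (default 0).
#' @param min_len,max_len product length bounds (defaults 100 and 3000).
#' @return data.frame with columns `template_id`, `start`, `end`, `length`,
#'   `fw_mismatches`, `rv_mismatches`, `sequence`; zero rows when nothing
#'   amplifies.
#' @export
amplify <- function(template, fw, rv, max_mm = 0, min_len = 100,
                    max_len = 3000) {
  seqs <- as_named_sequences(template)
  if (length(seqs) != 1) stopf("amplify() expects a single template")
  id <- names(seqs)
  s <- seqs[[1]]
  if (!nzchar(s)) stopf("empty template")
  fw_hits <- find_primer(s, fw, max_mismatches = max_mm)
  rv_hits <- find_primer(s, rv, max_mismatches = max_mm)
  empty <- data.frame(template_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      fw_mismatches = integer(), rv_mismatches = integer(),
                      sequence = character(), stringsAsFactors = FALSE)
  if (nrow(fw_hits) == 0 || nrow(rv_hits) == 0) return(empty)
  combos <- merge(fw_hits, rv_hits, by = NULL,
                  suffixes = c("_fw", "_rv"))
  combos <- combos[combos$start_rv > combos$end_fw, , drop = FALSE]
  len <- combos$end_rv - combos$start_fw + 1L
  keep <- len >= min_len & len <= max_len
  combos <- combos[keep, , drop = FALSE]
  len <- len[keep]
  if (nrow(combos) == 0) return(empty)
  out <- data.frame(
    template_id = id,
    start = combos$start_fw,
    end = combos$end_rv,
    length = len,
    fw_mismatches = combos$mismatches_fw,
    rv_mismatches = combos$mismatches_rv,
    sequence = substring(s, combos$start_fw, combos$end_rv),
    stringsAsFactors = FALSE
  )
  out <- out[radix_order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate forward (R1) reads from an amplicon
#'
#' Each read is the first `min(read_len, amplicon length)` bases of the
#' amplicon sense strand, so R1 begins with the forward-primer region, with
#' independent per-base substitution errors at `error_rate`. Qualities are a
#' constant Q37; no indels are simulated.
#'
#' @param amplicon amplicon sequence (character) or one row of [amplify()]
#'   output.
#' @param read_len target read length (default 250).
#' @param n number of reads.
#' @param error_rate per-base substitution probability (default 0).
#' @param seed optional integer; when given, results are reproducible and the
#'   caller's RNG state is left untouched.
#' @param id_prefix prefix for read identifiers.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
simulate_reads <- function(amplicon, read_len = 250, n = 1, error_rate = 0,
                           seed = NULL, id_prefix = "read") {
  if (is.data.frame(amplicon)) amplicon <- amplicon$sequence[1]
  stopifnot(is.character(amplicon), length(amplicon) == 1)
  if (read_len < 1) stopf("read_len must be >= 1")
  if (n <= 0) stopf("n must be positive")
  if (error_rate < 0 || error_rate > 1) stopf("error_rate must be in [0, 1]")
  run <- function() {
    L <- min(read_len, nchar(amplicon))
    base <- substr(amplicon, 1, L)
    seqs <- rep(base, n)
    if (error_rate > 0) {
      hit <- which(stats::runif(n * L) < error_rate)
      if (length(hit)) {
        read_i <- (hit - 1L) %/% L + 1L
        pos <- (hit - 1L) %% L + 1L
        orig <- substring(base, pos, pos)
        for (k in seq_along(hit)) {
          alt <- sample(setdiff(c("A", "C", "G", "T"), orig[k]), 1)
          substr(seqs[read_i[k]], pos[k], pos[k]) <- alt
        }
      }
    }
    data.frame(id = sprintf("%s_%d", id_prefix, seq_len(n)),
               seq = seqs, qual = strrep("F", L), stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Truncate reads to a fixed length
#'
#' Sequence and quality strings are cut to their first `L` bases; shorter
#' reads pass through unchanged. Idempotent.
#'
#' @param reads data.frame with `seq` and `qual` columns.
#' @param L truncation length (>= 1).
#' @return the truncated reads data.frame.
#' @export
truncate_reads <- function(reads, L) {
  if (L < 1) stopf("L must be >= 1")
  reads$seq <- substr(reads$seq, 1, L)
  reads$qual <- substr(reads$qual, 1, L)
  reads
}
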