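# Independent oracles used to verify the package's primitives.

# Exact-search oracle for degenerate primer matching at zero mismatches:
# the union of fixed-string matches of every concrete expansion.
oracle_exact_sites <- function(sequence, pattern_iupac) {
  hits <- integer(0)
  for (e in expand_degenerate(pattern_iupac)) {
    m <- gregexpr(e, sequence, fixed = TRUE)[[1]]
    if (m[1] != -1) hits <- c(hits, as.integer(m))
  }
  sort(unique(hits))
}

# Ungapped sliding-window identity oracle: the best identity of the query
# placed at every offset of the reference without gaps. Valid as an oracle
# for alignments whose optimum is ungapped (substitution-only test cases).
oracle_ungapped_identity <- function(query, reference) {
  qc <- strsplit(query, "")[[1]]
  rc <- strsplit(reference, "")[[1]]
  L <- length(qc)
  n <- length(rc)
  stopifnot(n >= L)
  best <- 0
  for (off in 0:(n - L)) {
    best <- max(best, sum(qc == rc[(off + 1):(off + L)]) / L)
  }
  best
}

# Hand Bray-Curtis on two named abundance vectors over the union of names.
oracle_bray_curtis <- function(x, y) {
  taxa <- union(names(x), names(y))
  xv <- ifelse(taxa %in% names(x), x[taxa], 0)
  yv <- ifelse(taxa %in% names(y), y[taxa], 0)
  sum(abs(xv - yv)) / sum(xv + yv)
}

random_acgt <- function(n, len, seed = NULL) {
  draw <- function() {
    vapply(rep(len, n), function(l)
      paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
      character(1))
  }
  if (is.null(seed)) draw() else itsprofiler:::with_seed(seed, draw())
}
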