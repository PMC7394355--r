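# Internal helpers shared across modules.

# IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

IUPAC_LETTERS <- names(IUPAC_BITS)

# Concrete bases contained in each IUPAC code.
IUPAC_SETS <- lapply(IUPAC_BITS, function(b) {
  c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) != 0L]
})

#' @noRd
iupac_encode <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- unname(IUPAC_BITS[chars])
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop("invalid IUPAC character '", chars[bad], "' at position ", bad,
         call. = FALSE)
  }
  codes
}

#' Reverse complement of IUPAC nucleotide strings
#'
#' Complements degenerate codes correctly (R<->Y, K<->M, B<->V, D<->H).
#'
#' @param x character vector of nucleotide strings (IUPAC alphabet).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  flipped <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  vapply(strsplit(flipped, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Random ACGT strings; n strings of the given length(s).
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic string ordering independent of locale.
radix_order <- function(...) order(..., method = "radix")

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# sample() without the scalar-first-argument trap
sample1 <- function(x) x[sample.int(length(x), 1)]

# n draws from the inclusive integer range r = c(lo, hi)
sample_range <- function(r, n) {
  vals <- seq(r[1], r[2])
  vals[sample.int(length(vals), n, replace = TRUE)]
}
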