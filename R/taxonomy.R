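# Seven-rank taxonomy lineages in the QIIME-style string dialect
# "d__X;p__X;c__X;o__X;f__X;g__X;s__X".

TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
TAX_PREFIXES <- c(d = "d__", p = "p__", c = "c__", o = "o__", f = "f__",
                  g = "g__", s = "s__")

#' Parse lineage strings into a rank matrix
#'
#' Lineages are semicolon-separated, rank-prefixed strings
#' (`d__...;p__...;...;s__...`). Ranks are filled prefix-wise: the first empty
#' rank truncates everything deeper, so a lineage can never have, say, a
#' species without a genus.
#'
#' @param x character vector of lineage strings.
#' @return character matrix with one row per lineage and the seven canonical
#'   rank columns (`domain` ... `species`); empty string marks an absent rank.
#' @export
parse_lineage <- function(x) {
  out <- matrix("", nrow = length(x), ncol = 7,
                dimnames = list(NULL, TAX_RANKS))
  parts <- strsplit(x, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[nzchar(p)]
    for (tok in p) {
      pref <- substr(tok, 1, 3)
      j <- match(pref, paste0(names(TAX_PREFIXES), "__"))
      if (is.na(j)) stopf("unparseable lineage token '%s' in '%s'", tok, x[i])
      out[i, j] <- substring(tok, 4)
    }
    # prefix-fill normalization: truncate at the first absent rank
    empty <- which(!nzchar(out[i, ]))
    if (length(empty) && empty[1] <= 7) out[i, seq(empty[1], 7)] <- ""
  }
  out
}

#' Format a rank matrix back into lineage strings
#'
#' @param m character matrix as produced by [parse_lineage()].
#' @param depth truncate to this many ranks (default 7).
#' @return character vector of canonical lineage strings.
#' @export
format_lineage <- function(m, depth = 7) {
  if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  m <- m[, seq_len(7), drop = FALSE]
  if (depth < 7) m[, seq(depth + 1, 7)] <- ""
  apply(m, 1, function(r) {
    paste0(paste0(names(TAX_PREFIXES), "__"), r, collapse = ";")
  })
}

#' Depth of a lineage (deepest filled rank)
#'
#' @param x character vector of lineage strings.
#' @return integer vector; 0 for an entirely empty lineage.
#' @export
lineage_depth <- function(x) {
  m <- parse_lineage(x)
  apply(m, 1, function(r) {
    nz <- which(nzchar(r))
    if (length(nz)) max(nz) else 0L
  })
}

#' Truncate lineage strings at a rank
#'
#' @param x character vector of lineage strings.
#' @param rank one of `"domain"`, ..., `"species"`, or an integer 1-7.
#' @return character vector of lineage strings with deeper ranks emptied.
#' @export
lineage_at_rank <- function(x, rank) {
  d <- rank_index(rank)
  format_lineage(parse_lineage(x), depth = d)
}

rank_index <- function(rank) {
  if (is.numeric(rank)) {
    d <- as.integer(rank)
    if (d < 1 || d > 7) stopf("rank index must be in 1..7, got %d", d)
    return(d)
  }
  d <- match(match.arg(rank, TAX_RANKS), TAX_RANKS)
  d
}

# value of lineage at exactly rank d ("" when absent)
rank_value <- function(x, d) parse_lineage(x)[, d]
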