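# Alpha diversity (observed ASVs, Shannon) with subsampling-based
# rarefaction, and beta diversity on count tables.

#' Rarefaction curve of observed ASVs
#'
#' Classic rarefaction: at each depth `d` up to the sample total, `d` reads
#' are drawn without replacement `n_subsamples` times and the number of
#' distinct ASVs observed is recorded. Depths beyond the sample total are
#' reported as the total distinct count and flagged saturated.
#'
#' @param counts named non-negative integer vector (one sample).
#' @param depths ascending depths; default 10 evenly spaced points up to
#'   `min(10000, sum(counts))`.
#' @param n_subsamples repetitions per depth (default 10).
#' @param seed RNG seed (default 1); results are bit-reproducible.
#' @param sample_id label stored with the curve.
#' @return data.frame of class `rarefaction_curve` with columns `sample`,
#'   `depth`, `mean`, `sd`, `saturated`.
#' @export
rarefy_observed <- function(counts, depths = NULL, n_subsamples = 10,
                            seed = 1, sample_id = "sample") {
  if (any(counts < 0)) stopf("negative counts")
  stopifnot(n_subsamples >= 1)
  total <- sum(counts)
  if (is.null(depths)) {
    depths <- unique(round(seq(1, min(10000, total), length.out = 10)))
  }
  if (is.unsorted(depths)) stopf("depths must be sorted ascending")
  counts <- counts[counts > 0]
  if (is.null(names(counts))) names(counts) <- paste0("ASV", seq_along(counts))
  pool <- rep(names(counts), counts)
  distinct <- length(counts)
  with_seed(seed, {
    rows <- lapply(depths, function(d) {
      if (d >= total) {
        return(data.frame(sample = sample_id, depth = d, mean = distinct,
                          sd = 0, saturated = TRUE))
      }
      obs <- vapply(seq_len(n_subsamples), function(i) {
        length(unique(sample(pool, d, replace = FALSE)))
      }, numeric(1))
      data.frame(sample = sample_id, depth = d, mean = mean(obs),
                 sd = stats::sd(obs), saturated = FALSE)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("rarefaction_curve", class(out))
    out
  })
}

#' Alpha diversity metrics
#'
#' @param counts non-negative numeric vector of ASV counts.
#' @return list with `observed` (number of non-zero ASVs) and `shannon`
#'   (Shannon index, natural log).
#' @export
alpha_metrics <- function(counts) {
  if (any(counts < 0)) stopf("negative counts")
  if (sum(counts) == 0) stopf("all-zero count vector")
  list(observed = sum(counts > 0),
       shannon = unname(vegan::diversity(counts, index = "shannon")))
}

#' Pairwise beta-diversity matrix
#'
#' Bray-Curtis on raw counts (`sum |x - y| / sum (x + y)`) or Jaccard on
#' presence/absence sets.
#'
#' @param table an `asv_table` or an ASV x sample count matrix.
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return symmetric distance matrix (samples x samples, zero diagonal).
#' @export
beta_matrix <- function(table, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  counts <- if (inherits(table, "asv_table")) table$counts else table
  if (ncol(counts) < 2) stopf("need at least 2 samples")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stopf("sample(s) with zero total reads: %s",
          paste(colnames(counts)[zero], collapse = ", "))
  }
  x <- t(counts)                       # vegan wants samples as rows
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(x, method = "bray")
  } else {
    vegan::vegdist(x, method = "jaccard", binary = TRUE)
  }
  as.matrix(d)
}

#' Write rarefaction curves / distance matrices
#'
#' @param x a `rarefaction_curve` data.frame or a distance matrix.
#' @param path output TSV path.
#' @export
write_diversity <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.table(cbind(sample = rownames(x), as.data.frame(x)), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
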