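# Assembly of the ITS reference database: in silico PCR of every ribosomal
# locus with the universal primer pair, one database entry per predicted
# amplicon. Duplicate amplicon sequences from different operons are retained
# deliberately: multiple operon copies are real signal for the consensus
# classifier.

#' Build the ITS reference database from ribosomal loci
#'
#' Runs [amplify()] on the concatenated 16S+ITS+23S sequence of every locus
#' and collects one entry per predicted amplicon, carrying the locus's
#' (possibly ANI-corrected) lineage. Length statistics use the sample
#' standard deviation (n-1 denominator).
#'
#' @param loci a `ribosomal_loci` data.frame from [pair_loci()] /
#'   [extract_loci()].
#' @param fw,rv the primer pair (defaults: [uni_its_primers()]).
#' @param max_mm maximum primer mismatches (default 2).
#' @param min_len,max_len amplicon length bounds.
#' @return object of class `reference_db`: list with `entries` (data.frame
#'   `entry_id`, `sequence`, `lineage`, `genome_id`, `locus_index`,
#'   `fw_mismatches`, `rv_mismatches`), `stats` (`mean`, `sd`, `n` of entry
#'   lengths) and `params` (build provenance).
#' @export
build_reference <- function(loci, fw = uni_its_primers()$fw,
                            rv = uni_its_primers()$rv, max_mm = 2,
                            min_len = 100, max_len = 3000) {
  if (nrow(loci) == 0) stopf("no loci supplied")
  rows <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    template <- paste0(l$seq_16S, l$seq_ITS, l$seq_23S)
    names(template) <- paste0(l$genome_id, "|", l$locus_index)
    amps <- amplify(template, fw, rv, max_mm = max_mm,
                    min_len = min_len, max_len = max_len)
    if (nrow(amps) == 0) return(NULL)
    data.frame(
      entry_id = sprintf("%s|%s|amp%d", l$genome_id, l$locus_index,
                         seq_len(nrow(amps))),
      sequence = amps$sequence,
      lineage = l$lineage,
      genome_id = l$genome_id,
      locus_index = l$locus_index,
      fw_mismatches = amps$fw_mismatches,
      rv_mismatches = amps$rv_mismatches,
      stringsAsFactors = FALSE
    )
  })
  entries <- do.call(rbind, rows)
  if (is.null(entries) || nrow(entries) == 0) {
    stopf("no locus yielded an amplicon; consider raising max_mm (was %d)",
          max_mm)
  }
  rownames(entries) <- NULL
  len <- nchar(entries$sequence)
  structure(
    list(
      entries = entries,
      stats = list(mean = mean(len), sd = stats::sd(len), n = length(len)),
      params = list(fw = fw$sequence, rv = rv$sequence, max_mm = max_mm,
                    min_len = min_len, max_len = max_len,
                    n_loci = nrow(loci))
    ),
    class = "reference_db"
  )
}

#' @export
print.reference_db <- function(x, ...) {
  sp <- unique(rank_value(x$entries$lineage, 7))
  cat(sprintf(
    "<reference_db> %d entries, %d species; amplicon length %.1f +/- %.1f nt\n",
    nrow(x$entries), sum(nzchar(sp)), x$stats$mean, x$stats$sd))
  invisible(x)
}

#' Write / read a reference database
#'
#' The on-disk form is a FASTA of amplicon sequences (entry ids as headers),
#' a two-column taxonomy TSV, and a JSON build manifest.
#'
#' @param db a `reference_db`.
#' @param prefix path prefix; writes `<prefix>.fasta`, `<prefix>.tax.tsv`
#'   and `<prefix>.manifest.json`.
#' @return invisibly, the paths written.
#' @export
write_reference_db <- function(db, prefix) {
  stopifnot(inherits(db, "reference_db"))
  paths <- c(fasta = paste0(prefix, ".fasta"),
             taxonomy = paste0(prefix, ".tax.tsv"),
             manifest = paste0(prefix, ".manifest.json"))
  write_fasta(stats::setNames(db$entries$sequence, db$entries$entry_id),
              paths["fasta"])
  write_taxonomy(stats::setNames(db$entries$lineage, db$entries$entry_id),
                 paths["taxonomy"])
  jsonlite::write_json(c(db$params, db$stats), paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' @rdname write_reference_db
#' @param fasta,taxonomy paths of the FASTA and taxonomy TSV files.
#' @export
read_reference_db <- function(fasta, taxonomy) {
  seqs <- read_fasta(fasta)
  tax <- read_taxonomy(taxonomy)
  missing <- setdiff(names(seqs), names(tax))
  if (length(missing)) {
    stopf("entries missing from taxonomy: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  ids <- names(seqs)
  parts <- strsplit(ids, "|", fixed = TRUE)
  len <- nchar(unname(seqs))
  structure(
    list(
      entries = data.frame(
        entry_id = ids,
        sequence = unname(seqs),
        lineage = unname(tax[ids]),
        genome_id = vapply(parts, `[`, "", 1),
        locus_index = vapply(parts, function(p) p[min(2, length(p))], ""),
        fw_mismatches = NA_integer_, rv_mismatches = NA_integer_,
        stringsAsFactors = FALSE),
      stats = list(mean = mean(len), sd = stats::sd(len), n = length(len)),
      params = list()
    ),
    class = "reference_db"
  )
}
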