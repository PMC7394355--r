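# Readers and writers for the plain-text formats the pipeline consumes:
# FASTA, FASTQ (optionally gzipped), GFF3 rRNA annotations, taxonomy TSV,
# ANI matrix TSV, count-table TSV and community-spec TSV.

#' Read a (multi-)FASTA file
#'
#' @param path FASTA file, optionally gzipped.
#' @return named character vector, sequences uppercased, names taken from the
#'   first whitespace-delimited header token.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stopf("failed to parse FASTA '%s': %s",
                                          path, conditionMessage(e)))
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path (`.gz` suffix triggers compression).
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a reads data.frame
#'
#' @param path FASTQ file, optionally gzipped.
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 strings).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stopf("failed to parse FASTQ '%s': %s",
                              path, conditionMessage(e)))
  qual <- as.character(S4Vectors::mcols(x)$qualities)
  seqs <- toupper(as.character(x))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stopf("FASTQ record %d in '%s': sequence and quality lengths differ",
          bad[1], path)
  }
  data.frame(id = sub("\\s.*$", "", names(x)), seq = unname(seqs),
             qual = unname(qual), stringsAsFactors = FALSE)
}

#' Write a reads data.frame to FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` columns.
#' @param path output path (`.gz` suffix triggers compression).
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stopf("sequence/quality length mismatch at record %d",
          which(nchar(reads$seq) != nchar(reads$qual))[1])
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read rRNA gene annotations from GFF3
#'
#' Keeps features of type `rRNA` whose `product` attribute mentions 16S or
#' 23S (an explicit `gene=16S`/`gene=23S` attribute is also honoured).
#'
#' @param path GFF3 file.
#' @return data.frame with columns `contig`, `gene` (`"16S"`/`"23S"`),
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @export
read_rrna_gff <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stopf("failed to parse GFF3 '%s': %s",
                                           path, conditionMessage(e)))
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "rRNA"]
  meta <- S4Vectors::mcols(gr)
  gene <- rep(NA_character_, length(gr))
  if ("gene" %in% names(meta)) {
    g <- as.character(meta$gene)
    gene[grepl("16S", g)] <- "16S"
    gene[grepl("23S", g)] <- "23S"
  }
  if ("product" %in% names(meta)) {
    p <- as.character(meta$product)
    gene[is.na(gene) & grepl("16S", p)] <- "16S"
    gene[is.na(gene) & grepl("23S", p)] <- "23S"
  }
  keep <- !is.na(gene)
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr))[keep],
    gene = gene[keep],
    start = GenomicRanges::start(gr)[keep],
    end = GenomicRanges::end(gr)[keep],
    strand = as.character(GenomicRanges::strand(gr))[keep],
    stringsAsFactors = FALSE
  )
}

#' Sanity-check rRNA annotation lengths
#'
#' Flags annotations whose span is implausible for the annotated gene.
#'
#' @param ann annotation data.frame as from [read_rrna_gff()].
#' @param len_16S,len_23S acceptable length ranges.
#' @return `ann` with a logical `plausible` column; a warning lists offenders.
#' @export
check_rrna_annotations <- function(ann, len_16S = c(1200, 1800),
                                   len_23S = c(2300, 3500)) {
  len <- ann$end - ann$start + 1L
  lim <- ifelse(ann$gene == "16S", list(len_16S), list(len_23S))
  ok <- vapply(seq_len(nrow(ann)), function(i) {
    r <- lim[[i]]
    len[i] >= r[1] && len[i] <= r[2]
  }, logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " annotation(s) with implausible length", call. = FALSE)
  }
  ann$plausible <- ok
  ann
}

#' Read a taxonomy table
#'
#' Two tab-separated columns: identifier and QIIME-style lineage string.
#' Lineages are normalized by the prefix-fill rule (the first empty rank
#' truncates all deeper ranks).
#'
#' @param path TSV file (no header).
#' @return named character vector of canonical lineage strings.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("id", "lineage"))
  stats::setNames(format_lineage(parse_lineage(df$lineage)), df$id)
}

#' Write a taxonomy table
#' @param lineages named character vector of lineage strings.
#' @param path output TSV path.
#' @export
write_taxonomy <- function(lineages, path) {
  utils::write.table(
    data.frame(id = names(lineages), lineage = unname(lineages)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ANI matrix
#'
#' Square tab-separated matrix with genome identifiers in the first row and
#' column. Validated for range, unit diagonal and symmetry (tolerance 0.1
#' percentage points).
#'
#' @param path TSV file.
#' @return numeric matrix with genome ids as dimnames.
#' @export
read_ani <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  validate_ani(m)
}

validate_ani <- function(m) {
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stopf("ANI matrix must be square with matching row/column ids")
  }
  if (any(m < 0 | m > 100)) stopf("ANI values must lie in [0, 100]")
  if (any(abs(diag(m) - 100) > 1e-6)) stopf("ANI diagonal must equal 100")
  if (max(abs(m - t(m))) > 0.1) stopf("ANI matrix asymmetric beyond 0.1")
  m
}

#' Write an ANI matrix
#' @param m numeric matrix with genome ids as dimnames.
#' @param path output TSV path.
#' @export
write_ani <- function(m, path) {
  utils::write.table(cbind(genome = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an ASV count table
#'
#' Rows are ASV identifiers, columns samples.
#'
#' @param path TSV file.
#' @return integer matrix.
#' @export
read_counts <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts integer matrix (ASV x sample).
#' @export
write_counts <- function(counts, path) {
  utils::write.table(cbind(asv_id = rownames(counts), as.data.frame(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a community specification
#'
#' Two tab-separated columns: species lineage string and relative abundance.
#'
#' @param path TSV file (no header).
#' @param ... passed on to [community_spec()].
#' @return a `community_spec` object.
#' @export
read_community_spec <- function(path, ...) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("lineage", "abundance"))
  community_spec(df$lineage, df$abundance, ...)
}
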