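# Extraction of 16S-ITS-23S ribosomal loci from annotated genome sequences.
#
# Bacterial rRNA operons carry the 16S gene, the internal transcribed spacer
# and the 23S gene in that order on the operon's sense strand. Each annotated
# 16S gene is therefore paired with the nearest downstream 23S gene on the
# same strand and contig; the spacer between them is the ITS.

#' Pair annotated 16S/23S genes into ribosomal loci
#'
#' For `+` strand operons the nearest 23S starting after the 16S end is
#' taken; for `-` strand operons the nearest 23S ending before the 16S start
#' (downstream in operon orientation). The spacer length must be in
#' `(0, max_spacer]`. A 23S gene is assigned to at most one 16S (the closest
#' one wins); unpaired genes are dropped with a warning. Extracted segments
#' are reverse-complemented to sense orientation for `-` strand operons.
#'
#' @param annotations data.frame with columns `contig`, `gene`
#'   (`"16S"`/`"23S"`), `start`, `end`, `strand` — all from one genome.
#' @param genome named character vector of contig sequences (or a single
#'   unnamed sequence).
#' @param genome_id identifier recorded in the output (default `"genome"`).
#' @param lineage lineage string attached to every locus (default empty).
#' @param max_spacer maximum ITS length (default 3000).
#' @return data.frame of class `ribosomal_loci` with one row per locus:
#'   identifiers, plus-strand coordinates of the three segments, strand, and
#'   the sense-oriented sequences `seq_16S`, `seq_ITS`, `seq_23S`.
#' @export
pair_loci <- function(annotations, genome, genome_id = "genome",
                      lineage = format_lineage(matrix("", 1, 7)),
                      max_spacer = 3000) {
  contigs <- as_named_sequences(genome)
  if (is.null(names(contigs)) || length(names(contigs)) == 0) {
    names(contigs) <- unique(annotations$contig)[1]
  }
  ann <- annotations
  if (!all(c("contig", "gene", "start", "end", "strand") %in% names(ann))) {
    stopf("annotations must have contig/gene/start/end/strand columns")
  }
  for (i in seq_len(nrow(ann))) {
    ctg <- ann$contig[i]
    if (!ctg %in% names(contigs)) stopf("contig '%s' not in genome", ctg)
    if (ann$start[i] < 1 || ann$end[i] > nchar(contigs[[ctg]])) {
      stopf("annotation %d (%s %s:%d-%d) outside genome bounds",
            i, ann$gene[i], ctg, ann$start[i], ann$end[i])
    }
  }
  s16 <- ann[ann$gene == "16S", , drop = FALSE]
  s23 <- ann[ann$gene == "23S", , drop = FALSE]
  pairs <- list()
  for (i in seq_len(nrow(s16))) {
    a <- s16[i, ]
    cand <- s23[s23$contig == a$contig & s23$strand == a$strand, , drop = FALSE]
    if (a$strand == "+") {
      cand <- cand[cand$start > a$end, , drop = FALSE]
      spacer <- cand$start - a$end - 1L
    } else {
      cand <- cand[cand$end < a$start, , drop = FALSE]
      spacer <- a$start - cand$end - 1L
    }
    ok <- spacer > 0 & spacer <= max_spacer
    cand <- cand[ok, , drop = FALSE]
    spacer <- spacer[ok]
    if (nrow(cand) == 0) next
    j <- which.min(spacer)
    pairs[[length(pairs) + 1L]] <- list(s16 = a, s23 = cand[j, ],
                                        spacer = spacer[j])
  }
  if (length(pairs) < nrow(s16)) {
    warning(nrow(s16) - length(pairs),
            " 16S gene(s) without a pairable downstream 23S were dropped",
            call. = FALSE)
  }
  # each 23S claimed at most once; closest 16S wins
  if (length(pairs) > 1) {
    key <- vapply(pairs, function(p)
      paste(p$s23$contig, p$s23$start, p$s23$end), character(1))
    sp <- vapply(pairs, function(p) as.numeric(p$spacer), numeric(1))
    ord <- order(sp)
    keep <- logical(length(pairs))
    keep[ord] <- !duplicated(key[ord])
    if (any(!keep)) {
      warning(sum(!keep), " 16S gene(s) competed for the same 23S; ",
              "only the closest was kept", call. = FALSE)
    }
    pairs <- pairs[keep]
  }
  rows <- lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    a <- p$s16; b <- p$s23
    ctg <- contigs[[a$contig]]
    if (a$strand == "+") {
      its_start <- a$end + 1L; its_end <- b$start - 1L
      seg <- c(substr(ctg, a$start, a$end),
               substr(ctg, its_start, its_end),
               substr(ctg, b$start, b$end))
    } else {
      its_start <- b$end + 1L; its_end <- a$start - 1L
      seg <- revcomp(c(substr(ctg, a$start, a$end),
                       substr(ctg, its_start, its_end),
                       substr(ctg, b$start, b$end)))
    }
    data.frame(
      genome_id = genome_id, locus_index = k, contig = a$contig,
      strand = a$strand,
      start_16S = a$start, end_16S = a$end,
      start_ITS = its_start, end_ITS = its_end,
      start_23S = b$start, end_23S = b$end,
      seq_16S = seg[1], seq_ITS = seg[2], seq_23S = seg[3],
      lineage = lineage, stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), locus_index = integer(),
               contig = character(), strand = character(),
               start_16S = integer(), end_16S = integer(),
               start_ITS = integer(), end_ITS = integer(),
               start_23S = integer(), end_23S = integer(),
               seq_16S = character(), seq_ITS = character(),
               seq_23S = character(), lineage = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("ribosomal_loci", class(out))
  out
}

#' Extract ribosomal loci for a set of genomes
#'
#' Convenience wrapper running [pair_loci()] per genome and attaching
#' per-genome lineages.
#'
#' @param genomes named list; each element a named character vector of contig
#'   sequences.
#' @param annotations data.frame with a `genome_id` column plus the
#'   [pair_loci()] annotation columns.
#' @param lineages named character vector of lineage strings per genome.
#' @param max_spacer maximum ITS length (default 3000).
#' @return a `ribosomal_loci` data.frame over all genomes.
#' @export
extract_loci <- function(genomes, annotations, lineages, max_spacer = 3000) {
  out <- lapply(names(genomes), function(g) {
    ann <- annotations[annotations$genome_id == g, , drop = FALSE]
    if (nrow(ann) == 0) return(NULL)
    pair_loci(ann, genomes[[g]], genome_id = g,
              lineage = unname(lineages[g]), max_spacer = max_spacer)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ribosomal_loci", class(out)[class(out) != "ribosomal_loci"])
  out
}
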