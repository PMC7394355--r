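# Synthetic fixture generator.
#
# Emulates the statistical structure of the inputs the pipeline consumes:
# annotated genomes whose ribosomal operons carry the forward-primer site
# with a controlled mismatch count, species-specific ITS sequences,
# block-structured ANI matrices, 7-rank taxonomies, and (optionally)
# mislabelled genomes. The 16S/23S segments are fixed pseudo-conserved
# scaffolds rather than full-length genes: primer-site context is all the
# downstream code consumes. Every planted coordinate, site and mismatch
# count is recorded in a ground-truth manifest.
#
# Geometry mirrors the real locus: the forward-primer site ends 38 nt before
# the 16S 3' end and the reverse-primer binding site ends 480 nt into the
# 23S, so a predicted amplicon is 58 + ITS + 480 nt.

FIX_16S_LEN <- 300L
FIX_23S_LEN <- 500L
FIX_FW_END_OFFSET <- 38L   # nt of 16S following the fw site
FIX_RV_END <- 480L         # rv binding-site 3' end within the 23S

#' Fixture generator configuration
#'
#' @param n_species number of species.
#' @param genomes_per_species genomes per species (default 1).
#' @param operons_per_genome inclusive range of operon copies (default
#'   `c(1, 2)`).
#' @param its_length inclusive range of the species-specific ITS length
#'   (default `c(200, 800)`).
#' @param primer_site_mismatches named probability vector over planted
#'   forward-primer mismatch counts; names are counts (`"3"` meaning >= 3,
#'   planted as exactly 3). Default is the census observed for universal
#'   primers against large rRNA databases:
#'   `c("0" = 0.897, "1" = 0.082, "2" = 0.010, "3" = 0.011)`.
#' @param ani_within,ani_between ANI ranges (percent) within / between
#'   species blocks (defaults 96-99 and 75-90).
#' @param minus_strand_prob probability that an operon is embedded on the
#'   minus strand (default 0.25).
#' @param mislabel_fraction fraction of genomes whose species label is
#'   swapped to another species (ground truth kept in the manifest;
#'   default 0).
#' @param seed RNG seed; regeneration with the same seed is byte-identical.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(n_species = 20, genomes_per_species = 1,
                           operons_per_genome = c(1, 2),
                           its_length = c(200, 800),
                           primer_site_mismatches =
                             c("0" = 0.897, "1" = 0.082,
                               "2" = 0.010, "3" = 0.011),
                           ani_within = c(96, 99), ani_between = c(75, 90),
                           minus_strand_prob = 0.25,
                           mislabel_fraction = 0, seed = 1) {
  stopifnot(n_species >= 1, genomes_per_species >= 1)
  if (its_length[1] < 1 || its_length[2] < its_length[1]) {
    stopf("invalid its_length range")
  }
  if (abs(sum(primer_site_mismatches) - 1) > 1e-9) {
    stopf("primer_site_mismatches probabilities must sum to 1")
  }
  if (operons_per_genome[2] < operons_per_genome[1] ||
      operons_per_genome[1] < 1) {
    stopf("invalid operons_per_genome range")
  }
  stopifnot(ani_within[1] <= ani_within[2], ani_between[1] <= ani_between[2],
            ani_between[2] < ani_within[1],
            mislabel_fraction >= 0, mislabel_fraction < 1)
  structure(list(n_species = n_species,
                 genomes_per_species = genomes_per_species,
                 operons_per_genome = operons_per_genome,
                 its_length = its_length,
                 primer_site_mismatches = primer_site_mismatches,
                 ani_within = ani_within, ani_between = ani_between,
                 minus_strand_prob = minus_strand_prob,
                 mislabel_fraction = mislabel_fraction, seed = seed),
            class = "fixture_config")
}

#' Generate a synthetic fixture with known ground truth
#'
#' @param config a [fixture_config()].
#' @param dir optional directory; when given, `genomes.fasta`,
#'   `annotations.gff3`, `taxonomy.tsv`, `ani.tsv` and `manifest.json` are
#'   written there.
#' @return list with `genomes` (named list: genome id -> named contig
#'   vector), `annotations` (data.frame with `genome_id`, `contig`, `gene`,
#'   `start`, `end`, `strand`), `taxonomy` (named lineage vector, including
#'   any planted mislabels), `ani` (matrix), `manifest` (ground truth) and
#'   `config`.
#' @export
generate_fixture <- function(config = fixture_config(), dir = NULL) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(config$seed, generate_fixture_impl(config, dir))
}

generate_fixture_impl <- function(config, dir) {
  fw <- uni_its_primers()$fw
  rv <- uni_its_primers()$rv
  fw_codes <- iupac_encode(fw$sequence)
  L <- length(fw_codes)

  # shared pseudo-conserved scaffolds
  s16 <- random_dna(1, FIX_16S_LEN)
  s23 <- random_dna(1, FIX_23S_LEN)
  fw_start <- FIX_16S_LEN - FIX_FW_END_OFFSET - L + 1L   # 243
  fw_end <- fw_start + L - 1L                            # 262
  rv_start <- FIX_RV_END - nchar(rv$sequence) + 1L       # 461
  fw_allele <- one_expansion(fw$sequence)
  rv_site <- revcomp(one_expansion(rv$sequence))
  substr(s16, fw_start, fw_end) <- fw_allele
  substr(s23, rv_start, FIX_RV_END) <- rv_site

  # species-level truth
  sp_ids <- seq_len(config$n_species)
  its_len <- sample_range(config$its_length, config$n_species)
  its_seqs <- random_dna(config$n_species, its_len)
  lineages <- fixture_lineages(config$n_species)

  non_degenerate <- which(vapply(IUPAC_SETS[strsplit(fw$sequence, "")[[1]]],
                                 length, 1L) == 1)

  genomes <- list()
  ann <- list()
  manifest_genomes <- list()
  true_species <- character(0)
  mm_counts <- c()
  for (i in sp_ids) {
    for (k in seq_len(config$genomes_per_species)) {
      gid <- sprintf("sp%03d_g%d", i, k)
      m <- as.integer(sample(names(config$primer_site_mismatches), 1,
                             prob = config$primer_site_mismatches))
      site <- fw_allele
      mm_pos <- integer(0)
      if (m > 0) {
        mm_pos <- sort(sample(non_degenerate, m))
        for (p in mm_pos) {
          allowed <- setdiff(c("A", "C", "G", "T"),
                             IUPAC_SETS[[substr(fw$sequence, p, p)]])
          substr(site, p, p) <- sample(allowed, 1)
        }
      }
      g16 <- s16
      substr(g16, fw_start, fw_end) <- site
      operon <- paste0(g16, its_seqs[i], s23)
      n_op <- sample_range(config$operons_per_genome, 1)
      pads <- random_dna(n_op + 1, 120)
      seq_parts <- character(0)
      pos <- 0L
      op_rows <- list()
      op_manifest <- list()
      for (o in seq_len(n_op)) {
        seq_parts <- c(seq_parts, pads[o])
        pos <- pos + nchar(pads[o])
        minus <- stats::runif(1) < config$minus_strand_prob
        emb <- if (minus) revcomp(operon) else operon
        op_start <- pos + 1L
        op_len <- nchar(operon)
        if (minus) {
          # plus-strand order: 23S, ITS, 16S
          c23 <- c(op_start, op_start + FIX_23S_LEN - 1L)
          c16 <- c(op_start + op_len - FIX_16S_LEN, op_start + op_len - 1L)
        } else {
          c16 <- c(op_start, op_start + FIX_16S_LEN - 1L)
          c23 <- c(op_start + op_len - FIX_23S_LEN, op_start + op_len - 1L)
        }
        strand <- if (minus) "-" else "+"
        op_rows[[o]] <- data.frame(
          genome_id = gid, contig = gid,
          gene = c("16S", "23S"),
          start = c(c16[1], c23[1]), end = c(c16[2], c23[2]),
          strand = strand, stringsAsFactors = FALSE)
        op_manifest[[o]] <- list(strand = strand, start = op_start,
                                 end = op_start + op_len - 1L)
        seq_parts <- c(seq_parts, emb)
        pos <- pos + op_len
      }
      seq_parts <- c(seq_parts, pads[n_op + 1])
      genomes[[gid]] <- stats::setNames(paste(seq_parts, collapse = ""), gid)
      ann[[gid]] <- do.call(rbind, op_rows)
      true_species[gid] <- lineages[i]
      mm_counts[gid] <- m
      manifest_genomes[[gid]] <- list(
        species = unname(lineages[i]),
        planted_mismatches = m,
        mismatch_positions = mm_pos,
        fw_site = site,
        n_operons = n_op,
        operons = op_manifest,
        expected_amplicon = paste0(
          substr(g16, fw_start, FIX_16S_LEN), its_seqs[i],
          substr(s23, 1, FIX_RV_END))
      )
    }
  }
  annotations <- do.call(rbind, ann)
  rownames(annotations) <- NULL

  gids <- names(genomes)
  species_of <- match(true_species, lineages)
  nA <- length(gids)
  ani <- matrix(0, nA, nA, dimnames = list(gids, gids))
  for (a in seq_len(nA)) {
    ani[a, a] <- 100
    if (a < nA) for (b in seq((a + 1), nA)) {
      rng <- if (species_of[a] == species_of[b]) config$ani_within
             else config$ani_between
      v <- round(stats::runif(1, rng[1], rng[2]), 2)
      ani[a, b] <- v
      ani[b, a] <- v
    }
  }

  taxonomy <- true_species
  mislabelled <- character(0)
  n_mis <- floor(config$mislabel_fraction * nA)
  if (n_mis > 0 && config$n_species > 1) {
    mislabelled <- sample(gids, n_mis)
    for (g in mislabelled) {
      other <- sample1(setdiff(sp_ids, species_of[match(g, gids)]))
      taxonomy[g] <- lineages[other]
    }
  }

  manifest <- list(
    config = unclass(config),
    scaffold_16S = s16, scaffold_23S = s23,
    fw_site_coords = c(start = fw_start, end = fw_end),
    rv_site_coords = c(start = rv_start, end = FIX_RV_END),
    species = stats::setNames(as.list(its_seqs), lineages),
    genomes = manifest_genomes,
    true_taxonomy = as.list(true_species),
    mislabelled = mislabelled,
    planted_mismatch_counts = as.list(mm_counts)
  )
  out <- list(genomes = genomes, annotations = annotations,
              taxonomy = taxonomy, ani = ani, manifest = manifest,
              config = config)
  if (!is.null(dir)) write_fixture(out, dir)
  out
}

# one concrete expansion of a degenerate primer (deterministic: first
# lexicographic expansion at fully conserved positions, random at degenerate
# ones)
one_expansion <- function(seq) {
  sets <- IUPAC_SETS[strsplit(toupper(seq), "")[[1]]]
  paste(vapply(sets, function(s) if (length(s) == 1) s else sample(s, 1), ""),
        collapse = "")
}

fixture_lineages <- function(n) {
  sp <- seq_len(n)
  genus <- ceiling(sp / 2)
  family <- ceiling(genus / 2)
  ord <- ceiling(family / 2)
  cls <- ceiling(ord / 2)
  phylum <- ceiling(cls / 2)
  sprintf(
    "d__Bacteria;p__Phylum_%d;c__Class_%d;o__Order_%d;f__Family_%d;g__Genus_%d;s__Species_%03d",
    phylum, cls, ord, family, genus, sp)
}

write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(vapply(fix$genomes, unname, ""), file.path(dir, "genomes.fasta"))
  gr <- GenomicRanges::GRanges(
    seqnames = fix$annotations$contig,
    ranges = IRanges::IRanges(fix$annotations$start, fix$annotations$end),
    strand = fix$annotations$strand)
  gr$type <- "rRNA"
  gr$source <- "itsprofiler_fixture"
  gr$product <- paste0(fix$annotations$gene, " ribosomal RNA")
  rtracklayer::export(gr, file.path(dir, "annotations.gff3"), format = "gff3")
  write_taxonomy(fix$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_ani(fix$ani, file.path(dir, "ani.tsv"))
  jsonlite::write_json(fix$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ribosomal loci of a generated fixture
#'
#' Convenience wrapper: [extract_loci()] on a [generate_fixture()] result
#' using its (possibly mislabelled) taxonomy.
#'
#' @param fix a fixture list.
#' @param corrected_lineages optional named lineage vector (e.g. after
#'   [ani_correct()]) overriding the fixture taxonomy.
#' @return a `ribosomal_loci` data.frame.
#' @export
fixture_loci <- function(fix, corrected_lineages = NULL) {
  lin <- corrected_lineages %||% fix$taxonomy
  extract_loci(fix$genomes, fix$annotations, lin)
}
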