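# End-to-end pipeline runner: filter -> dereplicate -> classify -> profile
# -> diversity, with every resolved parameter logged next to the outputs.

#' Pipeline configuration
#'
#' Flat key-value configuration covering every stage. Unknown keys are
#' rejected; every run writes a resolved copy of the configuration next to
#' its outputs.
#'
#' @param fastq named character vector: sample id -> FASTQ path.
#' @param reference_fasta,reference_taxonomy reference database files (see
#'   [write_reference_db()]).
#' @param output_dir output directory (created if needed).
#' @param min_mean_quality,max_homopolymer,primer_max_mm,trim_primer QC
#'   parameters, see [qc_params()].
#' @param min_count dereplication minimum copy number (default 2).
#' @param min_identity,max_accepts,min_consensus,kmer_size,candidate_pool
#'   classifier parameters, see [classifier_params()].
#' @param rarefaction_subsamples subsamplings per rarefaction depth
#'   (default 10).
#' @param seed RNG seed for the diversity stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(fastq, reference_fasta, reference_taxonomy,
                            output_dir,
                            min_mean_quality = 20, max_homopolymer = 7,
                            primer_max_mm = 0, trim_primer = FALSE,
                            min_count = 2,
                            min_identity = 0.90, max_accepts = 10,
                            min_consensus = 0.51, kmer_size = 8,
                            candidate_pool = 50,
                            rarefaction_subsamples = 10, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a key=value file
#'
#' @param path flat `key=value` text file; keys must be [pipeline_config()]
#'   arguments (`fastq` as comma-separated `sample:path` pairs).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    stopf("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  }
  args <- stats::setNames(as.list(vals), keys)
  if ("fastq" %in% keys) {
    pairs <- strsplit(strsplit(args$fastq, ",")[[1]], ":", fixed = TRUE)
    args$fastq <- stats::setNames(vapply(pairs, `[`, "", 2),
                                  vapply(pairs, `[`, "", 1))
  }
  numeric_keys <- c("min_mean_quality", "max_homopolymer", "primer_max_mm",
                    "min_count", "min_identity", "max_accepts",
                    "min_consensus", "kmer_size", "candidate_pool",
                    "rarefaction_subsamples", "seed")
  for (k in intersect(keys, numeric_keys)) args[[k]] <- as.numeric(args[[k]])
  if ("trim_primer" %in% keys) args$trim_primer <- as.logical(args$trim_primer)
  do.call(pipeline_config, args)
}

#' Run the full profiling pipeline
#'
#' Stages run in order: primer-anchored filtering, exact dereplication into
#' ASVs, consensus classification, per-sample taxonomic profiling, and
#' alpha/beta diversity. All outputs, the QC ledger, the resolved
#' configuration and a log are written to `config$output_dir`. Reruns with
#' identical configuration and seeds are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0("[%s] ", fmt, "\n"), "itsprofiler", ...),
        file = log_path, append = TRUE)
  }
  unlink(log_path)
  jsonlite::write_json(resolved_config(config),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA)

  for (p in c(config$fastq, config$reference_fasta,
              config$reference_taxonomy)) {
    if (!file.exists(p)) stopf("input stage: missing input file '%s'", p)
  }
  fw <- uni_its_primers()$fw
  qc <- qc_params(config$min_mean_quality, config$max_homopolymer,
                  config$primer_max_mm, config$trim_primer)
  cp <- classifier_params(config$min_identity, config$max_accepts,
                          config$min_consensus, config$kmer_size,
                          config$candidate_pool)
  db <- read_reference_db(config$reference_fasta, config$reference_taxonomy)
  logf("reference database: %d entries", nrow(db$entries))

  # filter
  filtered <- list()
  ledger <- list()
  for (s in names(config$fastq)) {
    reads <- read_fastq(config$fastq[[s]])
    if (nrow(reads) == 0) stopf("filter stage: sample '%s' has no reads", s)
    fl <- filter_reads(reads, fw, qc)
    if (nrow(fl$reads) == 0) {
      stopf("filter stage: sample '%s' retained no reads", s)
    }
    filtered[[s]] <- fl$reads
    ledger[[s]] <- fl$ledger
    logf("filter %s: %d -> %d reads (primer %d, quality %d, homopolymer %d)",
         s, fl$ledger$input, fl$ledger$retained,
         fl$ledger$discarded["primer"], fl$ledger$discarded["quality"],
         fl$ledger$discarded["homopolymer"])
  }
  jsonlite::write_json(ledger, file.path(out_dir, "qc_ledger.json"),
                       auto_unbox = TRUE, digits = NA)

  # dereplicate
  tab <- dereplicate(filtered, min_count = config$min_count)
  logf("dereplicate: %d ASVs, %d variants removed (min_count %d)",
       nrow(tab$counts), nrow(tab$removed), config$min_count)
  write_fasta(tab$sequences, file.path(out_dir, "asvs.fasta"))
  write_counts(tab$counts, file.path(out_dir, "asv_counts.tsv"))

  # classify
  cls <- classify_table(tab, db, cp)
  utils::write.table(cls, file.path(out_dir, "classifications.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("classify: %d/%d ASVs assigned", sum(cls$status == "assigned"),
       nrow(cls))

  # profile
  prof <- profile_samples(tab, cls)
  for (d in c(2, 6, 7)) {
    rows <- lapply(names(prof$profiles), function(s) {
      p <- profile_at_rank(prof, s, d)
      if (length(p) == 0) return(NULL)
      data.frame(sample = s, taxon = names(p),
                 relative_abundance = as.numeric(p),
                 stringsAsFactors = FALSE)
    })
    utils::write.table(do.call(rbind, rows),
                       file.path(out_dir,
                                 sprintf("profile_%s.tsv", TAX_RANKS[d])),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(classified_fraction = as.data.frame(prof$classified_fraction),
         reads = as.list(prof$reads)),
    file.path(out_dir, "classified_fractions.json"),
    auto_unbox = TRUE, digits = NA)

  # diversity
  curves <- do.call(rbind, lapply(colnames(tab$counts), function(s) {
    rarefy_observed(tab$counts[, s],
                    n_subsamples = config$rarefaction_subsamples,
                    seed = config$seed, sample_id = s)
  }))
  write_diversity(curves, file.path(out_dir, "rarefaction.tsv"))
  alpha <- do.call(rbind, lapply(colnames(tab$counts), function(s) {
    a <- alpha_metrics(tab$counts[, s])
    data.frame(sample = s, observed_asvs = a$observed, shannon = a$shannon)
  }))
  write_diversity(alpha, file.path(out_dir, "alpha_diversity.tsv"))
  if (ncol(tab$counts) >= 2) {
    write_diversity(beta_matrix(tab, "bray_curtis"),
                    file.path(out_dir, "beta_bray_curtis.tsv"))
    write_diversity(beta_matrix(tab, "jaccard"),
                    file.path(out_dir, "beta_jaccard.tsv"))
  }
  logf("pipeline complete: outputs in %s", out_dir)
  invisible(list(asv_table = tab, classifications = cls, profiles = prof,
                 ledger = ledger, rarefaction = curves, alpha = alpha))
}

resolved_config <- function(config) {
  cfg <- unclass(config)
  cfg$fastq <- as.list(cfg$fastq)
  cfg
}
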