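# ANI-based correction of species labels.
#
# Whole-genome average nucleotide identity (ANI) >= ~95% is the conventional
# boundary of a bacterial species. Genome collections carry occasional
# mislabelled species assignments; before building the reference database,
# labels are reconciled against the ANI matrix: each species label elects a
# representative genome, and every genome is relabelled to the species of
# the representative it is most similar to, provided that similarity crosses
# the species threshold.

#' Correct species labels using an ANI matrix
#'
#' For every species label, the representative is the member genome with the
#' highest mean ANI to the other members (ties broken by lexicographic
#' genome id; a single-member species represents itself). Each genome is then
#' relabelled to the lineage of the representative with which it shares the
#' highest ANI, provided that ANI is at least `threshold`; a genome linked to
#' no representative at `threshold` keeps its lineage up to genus but has its
#' species (and the rest of the lineage below genus) cleared. The operation
#' is deterministic and idempotent on well-separated species blocks.
#'
#' @param lineages named character vector: genome id -> lineage string.
#' @param ani numeric ANI matrix (percent, symmetric, diagonal 100) whose
#'   dimnames cover every genome in `lineages`.
#' @param threshold species boundary in percent ANI (default 95).
#' @return list with `lineages` (corrected named vector) and `changes`
#'   (data.frame `genome_id`, `old`, `new`, `reason`; zero rows when nothing
#'   changed).
#' @export
ani_correct <- function(lineages, ani, threshold = 95) {
  ani <- validate_ani(ani)
  missing <- setdiff(names(lineages), rownames(ani))
  if (length(missing)) {
    stopf("genome(s) missing from ANI matrix: %s",
          paste(missing, collapse = ", "))
  }
  genomes <- names(lineages)
  lin_mat <- parse_lineage(unname(lineages))
  species <- format_lineage(lin_mat)           # canonical full strings
  sp_label <- lin_mat[, "species"]

  labelled <- genomes[nzchar(sp_label)]
  reps <- character(0)                         # representative genome per label
  for (lab in sort(unique(species[nzchar(sp_label)]))) {
    members <- sort(genomes[species == lab])
    if (length(members) == 1) {
      reps[lab] <- members
    } else {
      mean_ani <- vapply(members, function(g) {
        mean(ani[g, setdiff(members, g)])
      }, numeric(1))
      reps[lab] <- members[which.max(mean_ani)]  # which.max: first = lexicographic tie-break
    }
  }

  new_lineages <- lineages
  changes <- list()
  if (length(reps)) {
    rep_labels <- names(reps)                  # sorted: deterministic tie-break
    for (g in genomes) {
      link <- vapply(reps, function(r) ani[g, r], numeric(1))
      best <- which.max(link)
      if (link[best] >= threshold) {
        new <- rep_labels[best]
        if (new != species[match(g, genomes)]) {
          changes[[length(changes) + 1L]] <- data.frame(
            genome_id = g, old = species[match(g, genomes)], new = new,
            reason = sprintf("ANI %.2f to representative %s",
                             link[best], reps[best]),
            stringsAsFactors = FALSE)
        }
        new_lineages[g] <- new
      } else {
        m <- parse_lineage(species[match(g, genomes)])
        new <- format_lineage(m, depth = 6)    # clear species, keep genus
        if (new != species[match(g, genomes)]) {
          changes[[length(changes) + 1L]] <- data.frame(
            genome_id = g, old = species[match(g, genomes)], new = new,
            reason = sprintf("no representative at ANI >= %g", threshold),
            stringsAsFactors = FALSE)
        }
        new_lineages[g] <- new
      }
    }
  }
  changes <- if (length(changes)) do.call(rbind, changes) else
    data.frame(genome_id = character(), old = character(), new = character(),
               reason = character(), stringsAsFactors = FALSE)
  list(lineages = new_lineages, changes = changes)
}
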