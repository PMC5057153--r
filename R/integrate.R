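# Dual-assay integration: combine RNA-seq and Pol II ChIP-seq calls into
# net-transcriptional-regulation classes and the initiation-vs-elongation
# archetype, then rank the regulated set for selectivity.

#' Joint class from the three per-gene calls
#'
#' Pure rule table over (rna, beyond-PPR, PPR) calls:
#' * `transcription_up`   — rna `up` and beyond-PPR `up` (coordinate
#'   increase in transcript and productive polymerase);
#' * `transcription_down` — rna `down` and beyond-PPR `down`;
#' * `rna_only_up` / `rna_only_down` — rna called, beyond-PPR `ns`
#'   (post-transcriptional candidates);
#' * `chip_only` — beyond-PPR called, rna `ns`;
#' * `none` — neither called, and also the discordant corner (rna and
#'   beyond-PPR called in opposite directions), which has no coherent net
#'   transcriptional reading.
#'
#' @param rna_call,beyond_call Character vectors in `{up, down, ns}`.
#' @return Character vector of joint classes.
#' @export
joint_class <- function(rna_call, beyond_call) {
  out <- rep("none", length(rna_call))
  out[rna_call == "up" & beyond_call == "up"] <- "transcription_up"
  out[rna_call == "down" & beyond_call == "down"] <- "transcription_down"
  out[rna_call == "up" & beyond_call == "ns"] <- "rna_only_up"
  out[rna_call == "down" & beyond_call == "ns"] <- "rna_only_down"
  out[rna_call == "ns" & beyond_call != "ns"] <- "chip_only"
  out
}

#' Initiation-vs-elongation archetype from the ChIP calls
#'
#' `elongation_regulated` whenever the beyond-PPR call is not `ns`
#' (polymerase throughput over the body changed); `initiation_only` when
#' binding rose in the PPR while the beyond-PPR signal stayed flat (paused
#' polymerase without pause release); otherwise `unclassified`.
#'
#' @param ppr_call,beyond_call Character vectors in `{up, down, ns}`.
#' @return Character vector of archetypes.
#' @export
chip_archetype <- function(ppr_call, beyond_call) {
  out <- rep("unclassified", length(ppr_call))
  out[ppr_call == "up" & beyond_call == "ns"] <- "initiation_only"
  out[beyond_call != "ns"] <- "elongation_regulated"
  out
}

#' Integrate RNA-seq and ChIP-seq differential tables
#'
#' Joins the three classified tables on their shared gene set and attaches
#' the joint class and archetype. The result is sorted by RNA effect,
#' descending — the ordering used for regulated-gene listings. The
#' scatter/joint logic uses beyond-PPR ChIP effects; full-body effects can
#' be carried alongside via `chip_full` but are never conflated with the
#' beyond-PPR axis.
#'
#' @param rna,chip_beyond,chip_ppr Classified tables from
#'   [classify_volcano()] (columns `gene_id`, `effect`, `se`, `p`, `call`).
#' @param chip_full Optional classified full-gene-body table, carried as
#'   extra columns.
#' @return `data.frame` with per-assay effects/calls, `joint_class` and
#'   `archetype`, one row per shared gene.
#' @export
integrate_assays <- function(rna, chip_beyond, chip_ppr, chip_full = NULL) {
  shared <- Reduce(intersect, list(rna$gene_id, chip_beyond$gene_id,
                                   chip_ppr$gene_id))
  if (!length(shared)) stop("no genes shared between the assay tables")
  pick <- function(tbl, prefix) {
    tbl <- tbl[match(shared, tbl$gene_id), ]
    out <- tbl[, c("effect", "se", "p", "call")]
    names(out) <- paste0(prefix, "_", names(out))
    out
  }
  rec <- cbind(data.frame(gene_id = shared, stringsAsFactors = FALSE),
               pick(rna, "rna"), pick(chip_beyond, "chip_beyond"),
               pick(chip_ppr, "chip_ppr"))
  if (!is.null(chip_full)) rec <- cbind(rec, pick(chip_full, "chip_full"))
  rec$joint_class <- joint_class(rec$rna_call, rec$chip_beyond_call)
  rec$archetype <- chip_archetype(rec$chip_ppr_call, rec$chip_beyond_call)
  rec <- rec[order(-rec$rna_effect, rec$gene_id), ]
  rownames(rec) <- NULL
  rec
}

#' Selectivity report: who is the maximum responder?
#'
#' Ranks the transcriptionally upregulated genes by RNA effect and by
#' beyond-PPR ChIP effect and flags whether one gene is maximal on both
#' axes — the signature of a single dominant target. Ties are broken
#' lexicographically by `gene_id` for determinism. Also attaches the
#' Shannon information-content summary for the regulated-set size (see
#' [information_bits()]).
#'
#' @param records Output of [integrate_assays()].
#' @param total_genes Genome-wide protein-coding gene count `G` for the
#'   information calculus (default 24000).
#' @param per_tf_target Typical number of genes targeted by one
#'   transcription factor (default 1000, i.e. 4.5 bits per factor).
#' @return List of class `selectivity_report`: `regulated` (gene ids by
#'   descending RNA effect), `top_rna`, `top_chip`, `both_axes_max`,
#'   `n_transcription_up`, `n_transcription_down`, and `information` (see
#'   [selectivity_information()]).
#' @export
selectivity_report <- function(records, total_genes = 24000,
                               per_tf_target = 1000) {
  up <- records[records$joint_class == "transcription_up", ]
  n_down <- sum(records$joint_class == "transcription_down")
  if (!nrow(up)) {
    warning("no transcription_up genes; selectivity flag is FALSE")
    return(structure(list(regulated = character(0), top_rna = NA_character_,
                          top_chip = NA_character_, both_axes_max = FALSE,
                          n_transcription_up = 0L,
                          n_transcription_down = n_down,
                          information = selectivity_information(
                            total_genes, max(1L, n_down), per_tf_target)),
                     class = "selectivity_report"))
  }
  ord_rna <- up[order(-up$rna_effect, up$gene_id), ]
  ord_chip <- up[order(-up$chip_beyond_effect, up$gene_id), ]
  top_rna <- ord_rna$gene_id[1]
  top_chip <- ord_chip$gene_id[1]
  m <- nrow(up) + n_down
  structure(list(
    regulated = ord_rna$gene_id,
    top_rna = top_rna,
    top_chip = top_chip,
    both_axes_max = identical(top_rna, top_chip),
    n_transcription_up = nrow(up),
    n_transcription_down = n_down,
    information = selectivity_information(total_genes, m, per_tf_target)
  ), class = "selectivity_report")
}

#' @export
print.selectivity_report <- function(x, ...) {
  cat("selectivity_report:", x$n_transcription_up, "transcription_up,",
      x$n_transcription_down, "transcription_down\n")
  cat("  max responder (RNA):", x$top_rna,
      " (ChIP beyond-PPR):", x$top_chip, "\n")
  cat("  single gene maximal on both axes:", x$both_axes_max, "\n")
  cat(sprintf("  bits to specify the regulated set: %.1f (single gene: %.1f)\n",
              x$information$bits_set, x$information$bits_single))
  invisible(x)
}
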