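# End-to-end orchestration: simulate (or load) -> quantify -> differential
# -> integrate -> sequence features -> information content -> report.
# Machine-readable outputs are TSV/JSON on disk; the console summary goes
# through message() so stdout stays clean.

#' Pipeline parameter block
#'
#' Analysis-side knobs, separate from the simulation config: PPR length,
#' pseudocount, significance level, metagene bin count, ARE pattern class,
#' smORF codon bounds, and the genome-wide gene count used by the
#' information calculus.
#'
#' @param ppr_len Promoter-proximal region length in bp (default 400).
#' @param pseudocount Pseudocount for log ratios (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param body_bins Metagene body bins (default 100).
#' @param are_class ARE pattern class for [scan_ares()].
#' @param smorf_bounds Length-2 codon bounds for [find_smorfs()].
#' @param total_genes Genome-wide protein-coding count for
#'   [selectivity_information()].
#' @param per_tf_target Typical targets per transcription factor.
#' @param chip_normalize Normalize ChIP occupancy to per-million of the
#'   gene-body library size before ratio computation. Default `FALSE`
#'   (raw occupancy, assuming depth-matched libraries): dividing by the
#'   gene-body total absorbs the near-global promoter-proximal increase
#'   that is itself the signal of interest, inverting the full-body median
#'   shift. Set `TRUE` when libraries differ in depth.
#' @return Named list of parameters.
#' @export
pipeline_params <- function(ppr_len = 400L, pseudocount = 0.5, alpha = 0.05,
                            body_bins = 100L,
                            are_class = "clustered",
                            smorf_bounds = c(10L, 100L),
                            total_genes = 24000,
                            per_tf_target = 1000,
                            chip_normalize = FALSE) {
  stopifnot(ppr_len > 0, pseudocount >= 0, alpha > 0, alpha < 1,
            body_bins > 0, length(smorf_bounds) == 2)
  list(ppr_len = as.integer(ppr_len), pseudocount = pseudocount,
       alpha = alpha, body_bins = as.integer(body_bins),
       are_class = are_class, smorf_bounds = as.integer(smorf_bounds),
       total_genes = total_genes, per_tf_target = per_tf_target,
       chip_normalize = isTRUE(chip_normalize))
}

#' Run the integrated RNA-seq / Pol II ChIP-seq pipeline
#'
#' Runs the full analysis on a simulated experiment (or a pre-built
#' experiment list of the same shape): TPM normalization, occupancy
#' quantification with the PPR split, empirical control:control
#' thresholds, per-assay volcano classification, dual-assay integration,
#' selectivity ranking with the information-content summary, ARE
#' enrichment among mRNA-upregulated genes, smORF detection in lncRNAs,
#' and condition-level metagene profiles. Identical `(config, seed)` give
#' byte-identical outputs.
#'
#' @param config A [sim_config()] (used when `experiment` is `NULL`).
#' @param out_dir Optional directory for TSV/JSON outputs; created if
#'   needed. `NULL` skips writing.
#' @param params A [pipeline_params()] list.
#' @param experiment Optional pre-built experiment (as returned by
#'   [simulate_experiment()]) to analyse instead of simulating; supply
#'   exactly one of `config` / `experiment` semantics — when `experiment`
#'   is given, `config` is ignored with a warning if also non-default.
#' @return Invisibly, a list with every intermediate: `experiment`, `tpm`,
#'   `occupancy`, `thresholds`, `diff` (rna / chip_full / chip_beyond /
#'   chip_ppr), `integration`, `selectivity`, `are`, `smorfs`, `metagene`,
#'   `summary` (named numeric tallies).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         params = pipeline_params(), experiment = NULL) {
  if (is.null(experiment)) {
    experiment <- simulate_experiment(config)
  } else if (!missing(config)) {
    warning("experiment supplied; config argument ignored")
  }
  genes <- experiment$genes
  truth <- experiment$truth

  # --- RNA side: TPM on the expressed set -------------------------------
  counts <- filter_expressed(experiment$rna$counts)
  expr <- compute_tpm(counts, stats::setNames(gene_length(genes),
                                              genes$gene_id))
  tpm <- expr$tpm

  # --- ChIP side: per-million occupancy matrices ------------------------
  tracks <- experiment$chip$tracks
  occ_full <- occupancy_matrix(tracks, genes, "full",
                               ppr_len = params$ppr_len,
                               normalize = params$chip_normalize)
  occ_ppr <- occupancy_matrix(tracks, genes, "ppr",
                              ppr_len = params$ppr_len,
                              normalize = params$chip_normalize)
  occ_beyond <- occupancy_matrix(tracks, genes, "beyond",
                                 ppr_len = params$ppr_len,
                                 normalize = params$chip_normalize)

  expressed <- intersect(rownames(tpm),
                         rownames(filter_expressed(occ_full)))
  tpm <- tpm[expressed, , drop = FALSE]
  occ_full <- occ_full[expressed, , drop = FALSE]
  occ_ppr <- occ_ppr[expressed, , drop = FALSE]
  # genes no longer than the PPR have no beyond-PPR signal by construction;
  # they are excluded from the beyond-PPR differential
  long_enough <- expressed[gene_length(genes)[match(expressed,
                                                    genes$gene_id)] >
                           params$ppr_len]
  occ_beyond <- occ_beyond[long_enough, , drop = FALSE]

  # --- thresholds from control:control pairs ----------------------------
  rna_cc <- make_cc_pairs(experiment$rna$design, "rna")
  chip_cc <- make_cc_pairs(experiment$chip$design, "chip")
  thr <- list(
    rna = empirical_threshold(tpm, rna_cc, params$pseudocount, params$alpha),
    chip_full = empirical_threshold(occ_full, chip_cc, params$pseudocount,
                                    params$alpha),
    chip_ppr = empirical_threshold(occ_ppr, chip_cc, params$pseudocount,
                                   params$alpha),
    chip_beyond = empirical_threshold(occ_beyond, chip_cc,
                                      params$pseudocount, params$alpha)
  )

  # --- per-assay differential tables ------------------------------------
  diff <- list(
    rna = classify_volcano(
      differential_test(tpm, experiment$rna$design, "rna",
                        params$pseudocount), thr$rna),
    chip_full = classify_volcano(
      differential_test(occ_full, experiment$chip$design, "chip",
                        params$pseudocount), thr$chip_full),
    chip_ppr = classify_volcano(
      differential_test(occ_ppr, experiment$chip$design, "chip",
                        params$pseudocount), thr$chip_ppr),
    chip_beyond = classify_volcano(
      differential_test(occ_beyond, experiment$chip$design, "chip",
                        params$pseudocount), thr$chip_beyond)
  )

  # --- integration and selectivity --------------------------------------
  integration <- integrate_assays(diff$rna, diff$chip_beyond, diff$chip_ppr,
                                  chip_full = diff$chip_full)
  selectivity <- selectivity_report(integration,
                                    total_genes = params$total_genes,
                                    per_tf_target = params$per_tf_target)

  # --- ARE enrichment among mRNA-upregulated transcripts ----------------
  utr_ids <- names(experiment$seqs)[endsWith(names(experiment$seqs),
                                             "_utr3")]
  utr_genes <- sub("_utr3$", "", utr_ids)
  hits <- scan_ares(experiment$seqs[utr_ids],
                    pattern_class = params$are_class)
  are_labels <- stats::setNames(utr_genes %in%
                                  sub("_utr3$", "", hits$sequence_id),
                                utr_genes)
  up_genes <- intersect(diff$rna$gene_id[diff$rna$call == "up"], utr_genes)
  bg_genes <- intersect(setdiff(diff$rna$gene_id, up_genes), utr_genes)
  are <- if (length(up_genes) && length(bg_genes)) {
    are_enrichment(up_genes, bg_genes, are_labels)
  } else NULL

  # --- smORFs in lncRNAs ------------------------------------------------
  lnc_ids <- names(experiment$seqs)[endsWith(names(experiment$seqs), "_lnc")]
  smorfs <- if (length(lnc_ids)) {
    find_smorfs(experiment$seqs[lnc_ids],
                params$smorf_bounds[1], params$smorf_bounds[2])
  } else NULL

  # --- metagene ---------------------------------------------------------
  conditions <- stats::setNames(experiment$chip$design$condition,
                                experiment$chip$design$sample_id)
  metagene <- metagene_profile(tracks, genes, conditions,
                               body_bins = params$body_bins,
                               normalize = params$chip_normalize)

  summary_counts <- c(
    expressed = length(expressed),
    rna_up = sum(diff$rna$call == "up"),
    rna_down = sum(diff$rna$call == "down"),
    chip_beyond_up = sum(diff$chip_beyond$call == "up"),
    chip_beyond_down = sum(diff$chip_beyond$call == "down"),
    transcription_up = sum(integration$joint_class == "transcription_up"),
    transcription_down = sum(integration$joint_class == "transcription_down"),
    median_full_ratio = ratio_median(diff$chip_full$effect),
    median_beyond_ratio = ratio_median(diff$chip_beyond$effect)
  )

  result <- list(experiment = experiment,
                 tpm = expr, occupancy = list(full = occ_full, ppr = occ_ppr,
                                              beyond = occ_beyond),
                 thresholds = thr, diff = diff, integration = integration,
                 selectivity = selectivity, are = are, smorfs = smorfs,
                 metagene = metagene, summary = summary_counts)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tpm_df <- data.frame(gene_id = rownames(result$tpm$tpm),
                       result$tpm$tpm, check.names = FALSE)
  write_tsv(tpm_df, file.path(out_dir, "tpm.tsv"))
  occ <- result$occupancy
  occ_long <- do.call(rbind, lapply(names(occ), function(region) {
    m <- occ[[region]]
    data.frame(gene_id = rep(rownames(m), ncol(m)),
               sample = rep(colnames(m), each = nrow(m)),
               region = region, value = as.vector(m),
               stringsAsFactors = FALSE)
  }))
  write_tsv(occ_long, file.path(out_dir, "occupancy.tsv"))
  for (nm in names(result$diff)) {
    write_tsv(result$diff[[nm]],
              file.path(out_dir, paste0("differential_", nm, ".tsv")))
  }
  write_tsv(result$integration, file.path(out_dir, "integration.tsv"))
  write_tsv(result$metagene, file.path(out_dir, "metagene.tsv"))
  if (!is.null(result$smorfs)) {
    write_tsv(result$smorfs, file.path(out_dir, "smorfs.tsv"))
  }
  sel <- result$selectivity
  report <- list(
    top_rna = sel$top_rna, top_chip = sel$top_chip,
    both_axes_max = sel$both_axes_max,
    n_transcription_up = sel$n_transcription_up,
    n_transcription_down = sel$n_transcription_down,
    information = sel$information,
    summary = as.list(result$summary)
  )
  if (!is.null(result$are)) {
    report$are <- list(table = as.vector(result$are$table),
                       prop_up = result$are$prop_up,
                       prop_bg = result$are$prop_bg,
                       odds_ratio = result$are$odds_ratio,
                       p_two_sided = result$are$p_two_sided,
                       p_greater = result$are$p_greater)
  }
  jsonlite::write_json(report, file.path(out_dir, "selectivity_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    "pipeline summary",
    sprintf("  expressed genes: %d", result$summary[["expressed"]]),
    sprintf("  rna up/down: %d/%d", result$summary[["rna_up"]],
            result$summary[["rna_down"]]),
    sprintf("  chip beyond-PPR up/down: %d/%d",
            result$summary[["chip_beyond_up"]],
            result$summary[["chip_beyond_down"]]),
    sprintf("  transcription up/down: %d/%d",
            result$summary[["transcription_up"]],
            result$summary[["transcription_down"]]),
    sprintf("  median log2 ratio, full body: %.3f",
            result$summary[["median_full_ratio"]]),
    sprintf("  median log2 ratio, beyond-PPR: %.3f",
            result$summary[["median_beyond_ratio"]]),
    sprintf("  max responder both axes: %s (%s)",
            sel$both_axes_max, sel$top_rna)
  )
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(out_dir)
}
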