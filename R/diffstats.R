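# Per-gene differential statistics and the dual-criterion volcano
# classification: a gene is called only if it clears BOTH an empirical
# fold-change threshold (2 x SEcc, derived from control:control pairs) and
# a t-test significance gate. Strict inequalities on both gates favour
# false negatives over false positives.

#' Expressed-gene filter
#'
#' Keeps genes quantified above `min_value` in every sample of the matrix,
#' echoing the restriction to genes with successful measurements in all
#' samples.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param min_value Exclusive lower bound (default 0, i.e. nonzero
#'   everywhere).
#' @return The row-subset matrix.
#' @export
filter_expressed <- function(mat, min_value = 0) {
  mat[apply(mat > min_value, 1, all), , drop = FALSE]
}

#' Default control:control pairings from a design table
#'
#' Forms same-condition sample pairs used to derive the empirical
#' fold-change threshold: vehicle replicates are paired in order
#' (1:2, 3:4, ...) for RNA, and all pairwise vehicle combinations are used
#' for ChIP (three vehicle samples give three pairs). Deterministic, so a
#' fixed design always yields the same threshold.
#'
#' @param design Design `data.frame`.
#' @param assay `"rna"` or `"chip"`.
#' @param max_pairs Cap on the number of pairs (default 3, matching the
#'   three control:control comparisons used to set the threshold).
#' @return List of length-2 character vectors of sample ids.
#' @export
make_cc_pairs <- function(design, assay = c("rna", "chip"), max_pairs = 3L) {
  assay <- match.arg(assay)
  validate_design(design)
  veh <- design$sample_id[design$assay == assay &
                          design$condition == "vehicle"]
  if (assay == "rna") {
    n <- length(veh) %/% 2L
    pairs <- lapply(seq_len(n), function(i) veh[c(2L * i - 1L, 2L * i)])
  } else {
    if (length(veh) < 2) stop("need >= 2 vehicle chip samples for cc pairs")
    cmb <- utils::combn(veh, 2, simplify = FALSE)
    pairs <- cmb
  }
  utils::head(pairs, max_pairs)
}

#' Empirical fold-change threshold from control:control pairs
#'
#' For each same-condition pair, the per-gene
#' `log2((a + pseudocount) / (b + pseudocount))` ratios are computed and
#' their standard deviation taken across genes; `SEcc` is the median of the
#' pair SDs and the ratio threshold is `2 * SEcc` (an empirical 95% band
#' for random variation between biological replicates).
#'
#' @param mat Gene-by-sample matrix of normalized quantifications (TPM or
#'   per-million occupancy), restricted to the expressed set.
#' @param cc_pairs List of length-2 character vectors of column names; at
#'   least one pair. A pair of identical samples is allowed (SD 0).
#' @param pseudocount Added before the log (default 0.5).
#' @param alpha Significance level carried alongside (default 0.05).
#' @return List of class `threshold_spec`: `alpha`, `se_cc`,
#'   `ratio_threshold`, `pair_sds`.
#' @export
empirical_threshold <- function(mat, cc_pairs, pseudocount = 0.5,
                                alpha = 0.05) {
  if (!length(cc_pairs)) stop("at least one control:control pair required")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  mat <- as.matrix(mat)
  pair_sds <- vapply(cc_pairs, function(p) {
    if (length(p) != 2 || !all(p %in% colnames(mat))) {
      stop("each cc pair must name two columns of mat")
    }
    r <- log2((mat[, p[1]] + pseudocount) / (mat[, p[2]] + pseudocount))
    stats::sd(r)
  }, numeric(1))
  se_cc <- stats::median(pair_sds)
  structure(list(alpha = alpha, se_cc = se_cc,
                 ratio_threshold = 2 * se_cc, pair_sds = pair_sds),
            class = "threshold_spec")
}

# vectorised row-wise Welch two-sample t on log2 values
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se <- sqrt(vx / nx + vy / ny)
  eff <- my - mx
  t <- eff / se
  df <- se^4 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  degenerate <- se == 0
  t[degenerate & eff == 0] <- 0
  p[degenerate & eff == 0] <- 1
  p[degenerate & eff != 0] <- 0
  list(effect = eff, se = se, t = t, p = p, df = df)
}

#' Per-gene differential test between dDAVP and vehicle
#'
#' RNA assay: Welch two-sample t-test on `log2(value + pseudocount)`
#' comparing all dDAVP samples to all vehicle samples; the effect is the
#' difference of group means (mean log2 ratio). ChIP assay (default
#' paired): the per-pair `log2((ddavp + pc) / (vehicle + pc))` ratios are
#' computed per gene and a one-sample t-test asks whether their mean
#' differs from zero — matching how a three-pair design reports
#' `effect +/- SE, n = 3`. An unpaired ChIP variant (Welch, as for RNA) is
#' selectable.
#'
#' @param mat Gene-by-sample matrix of normalized quantifications.
#' @param design Design table covering the columns of `mat`.
#' @param assay `"rna"` or `"chip"`.
#' @param pseudocount Added before the log (default 0.5).
#' @param paired For ChIP only: paired one-sample test (default `TRUE`).
#' @return `data.frame` with columns `gene_id`, `effect`, `se`, `t`, `p`,
#'   `n` (pairs for paired ChIP, per-group size otherwise).
#' @export
differential_test <- function(mat, design, assay = c("rna", "chip"),
                              pseudocount = 0.5, paired = TRUE) {
  assay <- match.arg(assay)
  validate_design(design)
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("non-finite values in quantification matrix")
  design <- design[design$assay == assay &
                   design$sample_id %in% colnames(mat), ]
  veh <- design$sample_id[design$condition == "vehicle"]
  dda <- design$sample_id[design$condition == "ddavp"]
  if (assay == "chip" && paired) {
    pairs <- sort(unique(design$pair_id))
    if (length(pairs) < 2) stop("paired chip test needs >= 2 pairs")
    ratios <- vapply(pairs, function(pid) {
      v <- design$sample_id[design$pair_id == pid &
                            design$condition == "vehicle"]
      d <- design$sample_id[design$pair_id == pid &
                            design$condition == "ddavp"]
      log2((mat[, d] + pseudocount) / (mat[, v] + pseudocount))
    }, numeric(nrow(mat)))
    ratios <- matrix(ratios, nrow = nrow(mat))
    n <- length(pairs)
    eff <- rowMeans(ratios)
    sdr <- sqrt(rowSums((ratios - eff)^2) / (n - 1))
    se <- sdr / sqrt(n)
    t <- eff / se
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
    degenerate <- se == 0
    t[degenerate & eff == 0] <- 0
    p[degenerate & eff == 0] <- 1
    p[degenerate & eff != 0] <- 0
    out <- data.frame(gene_id = rownames(mat), effect = eff, se = se,
                      t = t, p = p, n = n, stringsAsFactors = FALSE)
  } else {
    if (length(veh) < 2 || length(dda) < 2) {
      stop("need >= 2 samples per condition")
    }
    lx <- log2(mat[, veh, drop = FALSE] + pseudocount)
    ly <- log2(mat[, dda, drop = FALSE] + pseudocount)
    w <- welch_rows(lx, ly)
    out <- data.frame(gene_id = rownames(mat), effect = w$effect,
                      se = w$se, t = w$t, p = w$p,
                      n = min(length(veh), length(dda)),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Dual-criterion volcano classification
#'
#' A gene is called `up` only when `effect > ratio_threshold` AND
#' `p < alpha` (both strict); `down` mirrors with
#' `effect < -ratio_threshold`; anything else, including effects exactly at
#' the threshold, is `ns`.
#'
#' @param table Output of [differential_test()].
#' @param thresholds A `threshold_spec` from [empirical_threshold()], or a
#'   list with `alpha` and `ratio_threshold`.
#' @param adjust Optional multiple-testing correction applied to `p` before
#'   gating (`"none"`, the default — the fold-change gate is the second
#'   criterion — or `"BH"`).
#' @return `table` with a `call` column in `{up, down, ns}` (and `p_adj`
#'   when `adjust != "none"`).
#' @export
classify_volcano <- function(table, thresholds, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  thr <- thresholds$ratio_threshold
  alpha <- thresholds$alpha
  if (is.null(thr) || is.null(alpha)) {
    stop("thresholds must carry ratio_threshold and alpha")
  }
  p <- table$p
  if (adjust == "BH") {
    table$p_adj <- stats::p.adjust(p, method = "BH")
    p <- table$p_adj
  }
  call <- rep("ns", nrow(table))
  call[table$effect > thr & p < alpha] <- "up"
  call[table$effect < -thr & p < alpha] <- "down"
  table$call <- call
  table
}

#' Median log2 ratio
#'
#' Exact sample median (mean of the two central order statistics for even
#' n) of a set of log2 ratios, e.g. the per-gene full-body or beyond-PPR
#' occupancy ratios summarized under volcano histograms.
#'
#' @param x Numeric vector; non-finite values are dropped.
#' @return Scalar median.
#' @export
ratio_median <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("no finite ratios to take a median of")
  stats::median(x)
}
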