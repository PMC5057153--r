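# Per-gene quantities: TPM expression, gene-body Pol II occupancy with the
# promoter-proximal split at +400 bp, and metagene profiles (flank - scaled
# body - flank).

#' Transcripts-per-million normalization
#'
#' For each sample, `rate_g = count_g / length_g` and
#' `TPM_g = 1e6 * rate_g / sum(rate)`. Each TPM column sums to one million
#' by construction, making samples of different depth directly comparable.
#'
#' @param counts Nonnegative gene-by-sample count matrix with rownames.
#' @param lengths Positive gene lengths in bp, recycled against the rows of
#'   `counts` (named vectors are matched by rowname).
#' @return A list of class `expression_matrix` with elements `tpm`,
#'   `counts`, `lengths`.
#' @examples
#' m <- matrix(c(100, 100), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' compute_tpm(m, c(1000, 4000))$tpm  # 800000, 200000
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have gene rownames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts)) {
    stop("lengths must match the rows of counts")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("gene lengths must be positive")
  }
  zero_cols <- colSums(counts) == 0
  if (any(zero_cols)) {
    stop("all-zero sample(s), TPM undefined: ",
         paste(colnames(counts)[zero_cols], collapse = ", "))
  }
  rate <- counts / lengths
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  structure(list(tpm = tpm, counts = counts, lengths = lengths),
            class = "expression_matrix")
}

# Per-gene depth sums for full body / PPR / beyond-PPR, computed with one
# cumulative sum per chromosome. PPR is anchored at the TSS in transcription
# direction: the first `ppr_len` bases on the plus strand, the last
# `ppr_len` on the minus strand. Genes no longer than ppr_len count wholly
# as PPR (beyond = 0).
region_sums <- function(track, genes, ppr_len = 400L) {
  stopifnot(inherits(track, "coverage_track"))
  validate_gene_models(genes)
  ppr_len <- as.integer(ppr_len)
  full <- ppr <- numeric(nrow(genes))
  for (ch in unique(genes$chrom)) {
    if (!ch %in% names(track$depth)) {
      stop("chromosome ", ch, " absent from coverage track")
    }
    idx <- which(genes$chrom == ch)
    v <- track$depth[[ch]]
    if (any(genes$end[idx] > length(v)) || any(genes$start[idx] < 0)) {
      stop("gene outside coverage track bounds on ", ch)
    }
    cs <- c(0, cumsum(v))
    # sum over 0-based half-open [a, b) is cs[b + 1] - cs[a + 1]
    s <- genes$start[idx]; e <- genes$end[idx]
    full[idx] <- cs[e + 1L] - cs[s + 1L]
    plen <- pmin(ppr_len, e - s)
    ppr_start <- ifelse(genes$strand[idx] == "+", s, e - plen)
    ppr[idx] <- cs[ppr_start + plen + 1L] - cs[ppr_start + 1L]
  }
  data.frame(gene_id = genes$gene_id, full = full, ppr = ppr,
             beyond = full - ppr, stringsAsFactors = FALSE)
}

#' Gene-body occupancy split at the promoter-proximal region
#'
#' Sums per-base depth over the full gene body, over the promoter-proximal
#' region (PPR; the first `ppr_len` bp downstream of the TSS, strand-aware)
#' and over the remainder ("beyond-PPR"). `full = ppr + beyond` always; for
#' genes of length `<= ppr_len` the whole body is PPR and `beyond = 0`.
#'
#' @param track A `coverage_track`.
#' @param gene A single-row gene-model `data.frame`.
#' @param ppr_len PPR length in bp (default 400).
#' @return Named numeric vector `c(full, ppr, beyond)`.
#' @export
region_occupancy <- function(track, gene, ppr_len = 400L) {
  if (nrow(gene) != 1) stop("region_occupancy expects a single gene row")
  s <- region_sums(track, gene, ppr_len)
  c(full = s$full, ppr = s$ppr, beyond = s$beyond)
}

#' Occupancy table over many genes and samples
#'
#' @param tracks Named list of `coverage_track` objects (one per sample).
#' @param genes Gene-model table.
#' @param ppr_len PPR length in bp.
#' @return Long-format `data.frame` with columns `gene_id`, `sample`,
#'   `full`, `ppr`, `beyond`, plus the per-sample normalization factor
#'   `library_size`.
#' @export
occupancy_table <- function(tracks, genes, ppr_len = 400L) {
  if (is.null(names(tracks))) stop("tracks must be a named list")
  out <- lapply(names(tracks), function(sm) {
    s <- region_sums(tracks[[sm]], genes, ppr_len)
    s$sample <- sm
    s$library_size <- tracks[[sm]]$library_size
    s
  })
  out <- do.call(rbind, out)
  out[, c("gene_id", "sample", "full", "ppr", "beyond", "library_size")]
}

#' Gene-by-sample occupancy matrix for one region
#'
#' Convenience reshaping of [occupancy_table()] used by the differential
#' layer. With `normalize = TRUE` each column is divided by the sample's
#' library size (total depth over gene bodies) and rescaled to
#' depth-per-million, mirroring the total-count normalization applied to
#' the RNA side.
#'
#' @param tracks Named list of `coverage_track`s.
#' @param genes Gene-model table.
#' @param region `"full"`, `"ppr"` or `"beyond"`.
#' @param ppr_len PPR length in bp.
#' @param normalize Divide by library size and scale to per-million?
#' @return Numeric matrix, genes x samples.
#' @export
occupancy_matrix <- function(tracks, genes, region = c("full", "ppr", "beyond"),
                             ppr_len = 400L, normalize = TRUE) {
  region <- match.arg(region)
  mat <- vapply(names(tracks), function(sm) {
    s <- region_sums(tracks[[sm]], genes, ppr_len)
    v <- s[[region]]
    if (normalize) {
      if (tracks[[sm]]$library_size <= 0) stop("library_size must be positive")
      v <- v / tracks[[sm]]$library_size * 1e6
    }
    v
  }, numeric(nrow(genes)))
  rownames(mat) <- genes$gene_id
  mat
}

# Profile of one gene on one (already normalized) depth list:
# upstream flank (per-bp), body rescaled to body_bins, downstream flank,
# oriented TSS -> EAG (minus-strand genes are reversed).
gene_profile <- function(depth, gene, body_bins, flank) {
  v <- depth[[gene$chrom]]
  L <- gene$end - gene$start
  n <- length(v)
  grab <- function(a, b) {  # 0-based half-open window, zero-padded
    out <- numeric(b - a)
    lo <- max(a, 0L); hi <- min(b, n)
    if (hi > lo) out[(lo - a + 1L):(hi - a)] <- v[(lo + 1L):hi]
    out
  }
  left <- grab(gene$start - flank, gene$start)
  body <- v[(gene$start + 1L):gene$end]
  right <- grab(gene$end, gene$end + flank)
  bin <- floor((seq_len(L) - 1L) * body_bins / L) + 1L
  body_binned <- as.vector(rowsum(body, bin)) / tabulate(bin, body_bins)
  prof <- c(left, body_binned, right)
  if (gene$strand == "-") prof <- rev(prof)
  prof
}

#' Metagene occupancy profile
#'
#' Averages normalized Pol II depth over many genes after rescaling each
#' gene body to a fixed number of bins, flanked by fixed-length per-bp
#' windows upstream of the TSS and downstream of the EAG. Minus-strand
#' genes are reversed so every profile reads TSS to EAG. Profiles are
#' averaged across genes, then across the samples of each condition.
#'
#' @param tracks Named list of `coverage_track`s.
#' @param genes Gene-model table; genes shorter than `body_bins` bp are
#'   skipped with a warning.
#' @param conditions Named character vector mapping sample names to
#'   condition labels.
#' @param body_bins Number of bins the gene body is rescaled to (default
#'   100).
#' @param flank Flank length in bp (default 1000), taken per-bp.
#' @param normalize Divide each sample's depth by its library size (scaled
#'   to per-million) before averaging.
#' @return `data.frame` with columns `condition`, `position` (1-based index
#'   along flank + body + flank), `zone` (`upstream`/`body`/`downstream`)
#'   and `depth`.
#' @export
metagene_profile <- function(tracks, genes, conditions, body_bins = 100L,
                             flank = 1000L, normalize = TRUE) {
  validate_gene_models(genes)
  if (is.null(names(tracks)) || !all(names(tracks) %in% names(conditions))) {
    stop("every track needs a condition label")
  }
  body_bins <- as.integer(body_bins); flank <- as.integer(flank)
  short <- gene_length(genes) < body_bins
  if (any(short)) {
    warning(sum(short), " gene(s) shorter than body_bins skipped")
    genes <- genes[!short, , drop = FALSE]
  }
  if (!nrow(genes)) stop("no genes long enough for the requested body_bins")
  nbin <- 2L * flank + body_bins
  out <- list()
  for (cond in unique(conditions[names(tracks)])) {
    samples <- names(tracks)[conditions[names(tracks)] == cond]
    # average (normalized) depth across the condition's samples
    depth <- NULL
    for (sm in samples) {
      d <- tracks[[sm]]$depth
      if (normalize) {
        if (tracks[[sm]]$library_size <= 0) stop("library_size must be positive")
        d <- lapply(d, function(v) v / tracks[[sm]]$library_size * 1e6)
      }
      depth <- if (is.null(depth)) d else {
        mapply(`+`, depth, d[names(depth)], SIMPLIFY = FALSE)
      }
    }
    depth <- lapply(depth, function(v) v / length(samples))
    acc <- numeric(nbin)
    for (i in seq_len(nrow(genes))) {
      acc <- acc + gene_profile(depth, genes[i, ], body_bins, flank)
    }
    out[[cond]] <- data.frame(
      condition = cond,
      position = seq_len(nbin),
      zone = rep(c("upstream", "body", "downstream"),
                 c(flank, body_bins, flank)),
      depth = acc / nrow(genes),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
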