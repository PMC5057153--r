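#' Construct a gene-model table
#'
#' A gene model is a strand-aware interval from the transcription start site
#' (TSS) to the end of the annotated gene (EAG). Coordinates are 0-based,
#' half-open throughout the package; GTF input (1-based, inclusive) is
#' converted on ingest by [read_annotation()]. One interval per gene: isoform
#' structure is out of scope, matching analyses that quantify whole gene
#' bodies.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param chrom Chromosome / contig name per gene.
#' @param strand `"+"` or `"-"` per gene. The TSS is `start` on the plus
#'   strand and `end - 1` on the minus strand; the EAG is the opposite
#'   extremity.
#' @param start,end Integer 0-based half-open interval bounds, `end > start`.
#' @param biotype One of `"protein_coding"`, `"lncRNA"`, `"pseudogene"`,
#'   `"other"` (recycled if scalar).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `biotype`, validated by [validate_gene_models()].
#' @examples
#' g <- gene_models("geneA", "chr1", "+", 100, 600)
#' gene_tss(g)  # 100
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        biotype = "protein_coding") {
  genes <- data.frame(
    gene_id = as.character(gene_id),
    chrom   = as.character(chrom),
    strand  = as.character(strand),
    start   = as.integer(start),
    end     = as.integer(end),
    biotype = as.character(biotype),
    stringsAsFactors = FALSE
  )
  validate_gene_models(genes)
  genes
}

#' Validate a gene-model table
#'
#' Checks the structural invariants of a gene-model `data.frame`: required
#' columns, `end > start`, strand in `{+,-}`, known biotypes, and unique
#' `gene_id`.
#'
#' @param genes A gene-model `data.frame` as built by [gene_models()].
#' @return `genes`, invisibly, if valid; otherwise an error is raised.
#' @export
validate_gene_models <- function(genes) {
  required <- c("gene_id", "chrom", "strand", "start", "end", "biotype")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    stop("gene-model table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (any(genes$end <= genes$start)) {
    bad <- genes$gene_id[genes$end <= genes$start]
    stop("end must exceed start (0-based half-open); offending gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(genes$start < 0)) stop("start coordinates must be >= 0")
  ok_bio <- c("protein_coding", "lncRNA", "pseudogene", "other")
  if (!all(genes$biotype %in% ok_bio)) {
    stop("biotype must be one of: ", paste(ok_bio, collapse = ", "))
  }
  invisible(genes)
}

#' Transcription start site and end of annotated gene
#'
#' @param genes Gene-model `data.frame`.
#' @return Integer vector of 0-based positions: for `gene_tss()` the first
#'   transcribed base; for `gene_eag()` the last transcribed base.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

#' @rdname gene_tss
#' @export
gene_eag <- function(genes) {
  ifelse(genes$strand == "+", genes$end - 1L, genes$start)
}

#' @rdname gene_tss
#' @export
gene_length <- function(genes) genes$end - genes$start

#' Construct a per-base coverage track
#'
#' A coverage track stores strandless per-base read depth for each
#' chromosome, plus a library size defined as the total summed depth over
#' all annotated gene bodies (the normalization denominator used for
#' occupancy ratios). Pol II ChIP fragments are unstranded, so depth carries
#' no strand; strand only matters downstream when orienting the
#' promoter-proximal region.
#'
#' @param depth Named list, one nonnegative numeric vector of per-base
#'   depths per chromosome.
#' @param genes Optional gene-model table used to compute `library_size`
#'   (sum of per-base depth over every gene body). If omitted the library
#'   size is the total depth over all chromosomes.
#' @return An object of class `coverage_track` with elements `depth`,
#'   `chrom_lengths` and `library_size`.
#' @export
coverage_track <- function(depth, genes = NULL) {
  if (is.null(names(depth)) || anyDuplicated(names(depth))) {
    stop("depth must be a list with unique chromosome names")
  }
  depth <- lapply(depth, as.numeric)
  if (any(vapply(depth, function(v) any(v < 0), logical(1)))) {
    stop("coverage depths must be nonnegative")
  }
  track <- structure(
    list(depth = depth,
         chrom_lengths = vapply(depth, length, integer(1)),
         library_size = NA_real_),
    class = "coverage_track"
  )
  track$library_size <- if (is.null(genes)) {
    sum(vapply(depth, sum, numeric(1)))
  } else {
    compute_library_size(track, genes)
  }
  track
}

#' Total depth over annotated gene bodies
#'
#' @param track A `coverage_track`.
#' @param genes Gene-model table; genes must lie within the track.
#' @return Scalar library size.
#' @export
compute_library_size <- function(track, genes) {
  validate_gene_models(genes)
  sums <- region_sums(track, genes, ppr_len = 1L)
  sum(sums$full)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track:", length(x$depth), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bases,",
      "library_size =", signif(x$library_size, 6), "\n")
  invisible(x)
}

#' Construct / validate an experiment-design table
#'
#' @param sample_id Character sample identifiers (unique).
#' @param assay `"rna"` or `"chip"` per sample.
#' @param condition `"vehicle"` or `"ddavp"` per sample.
#' @param pair_id Integer pair labels for ChIP samples (each pair holds one
#'   vehicle and one ddavp sample); `NA` for RNA samples, which need no
#'   pairing.
#' @return A validated `data.frame` with the four columns.
#' @export
experiment_design <- function(sample_id, assay, condition, pair_id = NA) {
  design <- data.frame(
    sample_id = as.character(sample_id),
    assay = as.character(assay),
    condition = as.character(condition),
    pair_id = as.integer(pair_id),
    stringsAsFactors = FALSE
  )
  validate_design(design)
  design
}

#' @rdname experiment_design
#' @param design A design `data.frame`.
#' @export
validate_design <- function(design) {
  required <- c("sample_id", "assay", "condition", "pair_id")
  if (!all(required %in% names(design))) {
    stop("design table needs columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (!all(design$assay %in% c("rna", "chip"))) {
    stop("assay must be 'rna' or 'chip'")
  }
  if (!all(design$condition %in% c("vehicle", "ddavp"))) {
    stop("condition must be 'vehicle' or 'ddavp'")
  }
  chip <- design[design$assay == "chip", ]
  if (nrow(chip)) {
    if (anyNA(chip$pair_id)) stop("chip samples must carry a pair_id")
    tab <- table(chip$pair_id, chip$condition)
    if (!all(dim(tab) == c(nrow(tab), 2)) || !all(tab == 1)) {
      stop("each chip pair_id must hold exactly one vehicle and one ddavp sample")
    }
  }
  invisible(design)
}
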