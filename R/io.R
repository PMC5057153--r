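# Readers and writers for the standard interchange formats: GTF/BED
# annotations, bedGraph coverage, FASTA sequences, TSV design tables.
# Parsing is delegated to rtracklayer / Biostrings; these wrappers enforce
# the package's coordinate convention (0-based half-open) and contracts.

guess_annotation_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gtf", "gff")) return("gtf")
  if (ext %in% c("bed", "bed12")) return("bed")
  stop("cannot guess annotation format from extension '", ext,
       "'; pass format = 'gtf' or 'bed'")
}

#' Read a gene annotation (GTF or BED)
#'
#' GTF rows with feature type `gene` become one gene model each; 1-based
#' inclusive GTF coordinates are converted to the internal 0-based half-open
#' convention (start minus one). BED input is already 0-based half-open and
#' is taken verbatim; BED carries no biotype, so genes read from BED get
#' biotype `"other"` unless the optional `itemRgb`-free extra column is
#' absent. Round-tripping with [write_annotation()] therefore preserves all
#' fields for GTF only.
#'
#' @param path Path to a GTF or BED file.
#' @param format `"auto"` (by extension), `"gtf"` or `"bed"`.
#' @return A gene-model `data.frame` (see [gene_models()]).
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") format <- guess_annotation_format(path)
  check_annotation_lines(path, format)
  gr <- rtracklayer::import(path, format = format)
  md <- S4Vectors::mcols(gr)
  if (format == "gtf") {
    if ("type" %in% names(md)) {
      keep <- as.character(md$type) == "gene"
      gr <- gr[keep]
      md <- S4Vectors::mcols(gr)
    }
    if (!"gene_id" %in% names(md)) stop("GTF lacks gene_id attributes")
    ids <- as.character(md$gene_id)
    biotype <- if ("gene_biotype" %in% names(md)) {
      as.character(md$gene_biotype)
    } else "other"
  } else {
    if (!"name" %in% names(md)) stop("BED lacks a name column")
    ids <- as.character(md$name)
    biotype <- "other"
  }
  biotype[is.na(biotype)] <- "other"
  biotype[!biotype %in% c("protein_coding", "lncRNA", "pseudogene")] <- "other"
  gene_models(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based
    end = GenomicRanges::end(gr),
    biotype = biotype
  )
}

# cheap structural pre-scan so malformed rows fail with a line number
check_annotation_lines <- function(path, format) {
  lines <- readLines(path, warn = FALSE)
  data_lines <- which(!grepl("^(#|track|browser)", lines) & nzchar(lines))
  min_fields <- if (format == "gtf") 9L else 4L
  for (i in data_lines) {
    n <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (n < min_fields) {
      stop("malformed ", format, " row at line ", i, ": expected >= ",
           min_fields, " tab-separated fields, found ", n)
    }
  }
  invisible(TRUE)
}

#' Write a gene annotation
#'
#' @param genes Gene-model `data.frame`.
#' @param path Output path.
#' @param format `"gtf"` (keeps biotype, 1-based on disk) or `"bed"`
#'   (BED6; 0-based on disk, biotype dropped).
#' @export
write_annotation <- function(genes, path, format = c("gtf", "bed")) {
  format <- match.arg(format)
  validate_gene_models(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  if (format == "gtf") {
    S4Vectors::mcols(gr)$source <- "txpause"
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$gene_id <- genes$gene_id
    S4Vectors::mcols(gr)$gene_biotype <- genes$biotype
  } else {
    S4Vectors::mcols(gr)$name <- genes$gene_id
    S4Vectors::mcols(gr)$score <- 0L
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Read a bedGraph coverage file into a per-base track
#'
#' bedGraph intervals (0-based half-open on disk) are expanded to per-base
#' depth vectors. Intervals must be non-overlapping within a chromosome and
#' depths nonnegative. The library size is computed against `genes` when
#' given (total depth over gene bodies), else over the whole track.
#'
#' @param path bedGraph file; an empty file yields an all-zero track.
#' @param genes Optional gene-model table (also used to size chromosomes).
#' @param chrom_lengths Optional named integer vector declaring chromosome
#'   lengths; intervals beyond a declared length are an error.
#' @return A [coverage_track()].
#' @export
read_coverage <- function(path, genes = NULL, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(data_lines)) {
    lens <- coverage_chrom_lengths(NULL, genes, chrom_lengths)
    if (!length(lens)) stop("empty bedGraph and no genes/chrom_lengths to size the track")
    depth <- lapply(lens, function(n) numeric(n))
    return(coverage_track(depth, genes = genes))
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- as.numeric(S4Vectors::mcols(gr)$score)
  if (any(!is.finite(score))) stop("non-finite coverage value in ", path)
  if (any(score < 0)) stop("negative coverage value in ", path)
  iv <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 0-based half-open
    end = GenomicRanges::end(gr),
    score = score,
    stringsAsFactors = FALSE
  )
  lens <- coverage_chrom_lengths(iv, genes, chrom_lengths)
  if (!is.null(chrom_lengths)) {
    for (ch in unique(iv$chrom)) {
      if (!ch %in% names(lens)) stop("chromosome ", ch, " not in chrom_lengths")
      if (any(iv$end[iv$chrom == ch] > lens[[ch]])) {
        stop("bedGraph interval beyond declared length of ", ch)
      }
    }
  }
  depth <- lapply(lens, function(n) numeric(n))
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping bedGraph intervals on ", ch)
    }
    v <- depth[[ch]]
    for (k in seq_len(nrow(sub))) {
      v[(sub$start[k] + 1L):sub$end[k]] <- sub$score[k]
    }
    depth[[ch]] <- v
  }
  coverage_track(depth, genes = genes)
}

coverage_chrom_lengths <- function(iv, genes, chrom_lengths) {
  if (!is.null(chrom_lengths)) {
    return(vapply(chrom_lengths, as.integer, integer(1)))
  }
  ends <- integer(0)
  if (!is.null(iv)) {
    ends <- tapply(iv$end, iv$chrom, max)
  }
  if (!is.null(genes)) {
    gends <- tapply(genes$end, genes$chrom, max)
    for (ch in names(gends)) {
      ends[ch] <- max(ends[ch], gends[ch] + 1000L, na.rm = TRUE)
    }
  }
  out <- as.integer(ends)
  names(out) <- names(ends)
  out
}

#' Write a coverage track as bedGraph
#'
#' Zero-depth runs are omitted, so write/read round-trips reproduce the
#' per-base arrays exactly (given matching chromosome lengths).
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  chroms <- character(0); starts <- integer(0); ends <- integer(0)
  scores <- numeric(0)
  for (ch in names(track$depth)) {
    r <- rle(track$depth[[ch]])
    stop_ <- cumsum(r$lengths)
    start_ <- stop_ - r$lengths  # 0-based
    keep <- r$values != 0
    chroms <- c(chroms, rep(ch, sum(keep)))
    starts <- c(starts, start_[keep])
    ends <- c(ends, stop_[keep])
    scores <- c(scores, r$values[keep])
  }
  if (length(chroms)) {
    gr <- GenomicRanges::GRanges(
      seqnames = chroms,
      ranges = IRanges::IRanges(start = starts + 1L, end = ends),
      score = scores
    )
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    writeLines(character(0), path)
  }
  invisible(path)
}

#' Read nucleotide sequences from FASTA
#'
#' Sequences are upper-cased and RNA `U` is mapped to `T` on read, so ARE
#' scanning and ORF finding always operate on the DNA alphabet
#' `{A,C,G,T,N}`. Duplicate headers and empty records are errors.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_sequences <- function(path) {
  raw <- Biostrings::readBStringSet(path)
  if (anyDuplicated(names(raw))) {
    stop("duplicate FASTA header in ", path, ": ",
         names(raw)[duplicated(names(raw))][1])
  }
  s <- toupper(as.character(raw))
  s <- chartr("U", "T", s)
  if (any(nchar(s) == 0)) {
    stop("empty sequence record in ", path, ": ", names(s)[nchar(s) == 0][1])
  }
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop("non-ACGTN/U symbol in sequence ", names(s)[bad][1])
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(raw)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A `DNAStringSet` or named character vector.
#' @param path Output path.
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read / write an experiment-design TSV
#'
#' The on-disk format is a tab-separated table with header columns
#' `sample_id`, `assay`, `condition`, `pair_id` (empty pair_id for RNA
#' samples).
#'
#' @param path TSV path.
#' @return A validated design `data.frame`.
#' @export
read_design <- function(path) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"pair_id" %in% names(design)) design$pair_id <- NA_integer_
  design$pair_id <- suppressWarnings(as.integer(design$pair_id))
  validate_design(design)
  design
}

#' @rdname read_design
#' @param design Design `data.frame`.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
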