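# Sequence features: AU-rich element (ARE) scanning of 3'-UTRs, exact
# enrichment testing, and small open reading frame (smORF) detection in
# long non-coding RNAs. All scanning is sense-strand only: the inputs are
# mRNA-sense sequences, so the reverse complement is never searched.

are_pattern_classes <- c(
  clustered = "WWTTTATTTAWW",   # ATTTA core in an A/T-rich 12-nt context
  pentamer_repeat = "ATTTATTTA", # overlapping pentamer repeat (stricter)
  pentamer = "ATTTA"             # bare core (loosest)
)

as_dna_set <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) return(seqs)
  if (inherits(seqs, "DNAString")) {
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- "seq1"
    return(out)
  }
  s <- toupper(as.character(seqs))
  s <- chartr("U", "T", s)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) stop("non-ACGTN symbol in sequence ",
                     if (!is.null(names(s))) names(s)[bad][1] else which(bad)[1])
  if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
  Biostrings::DNAStringSet(s)
}

#' Scan sequences for AU-rich elements
#'
#' Searches mRNA-sense sequences (DNA alphabet; `U` accepted and mapped to
#' `T`) for ARE motifs. The default `"clustered"` class is the
#' `WWTTTATTTAWW` framework (`W` = A or T): the ATTTA core pentamer inside
#' an A/T-rich context. `"pentamer_repeat"` requires the overlapping
#' repeat `ATTTATTTA`; `"pentamer"` matches the bare core. All overlapping
#' matches are reported. Every reported match contains the ATTTA core.
#'
#' @param seqs `DNAStringSet` or named character vector of sequences
#'   (typically 3'-UTRs).
#' @param pattern_class One of `"clustered"` (default),
#'   `"pentamer_repeat"`, `"pentamer"`.
#' @return `data.frame` with columns `sequence_id`, `offset` (0-based),
#'   `pattern_class`, `match`; zero rows when nothing matches.
#' @export
scan_ares <- function(seqs, pattern_class = c("clustered", "pentamer_repeat",
                                              "pentamer")) {
  pattern_class <- match.arg(pattern_class)
  seqs <- as_dna_set(seqs)
  pattern <- are_pattern_classes[[pattern_class]]
  hits <- Biostrings::vmatchPattern(pattern, seqs, fixed = FALSE)
  out <- lapply(seq_along(seqs), function(i) {
    m <- hits[[i]]
    if (!length(m)) return(NULL)
    data.frame(
      sequence_id = names(seqs)[i],
      offset = IRanges::start(m) - 1L,
      pattern_class = pattern_class,
      match = as.character(Biostrings::extractAt(seqs[[i]], m)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(0), offset = integer(0),
                      pattern_class = character(0), match = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Fisher's exact test on a 2x2 table by hypergeometric summation
#'
#' With margins fixed, the count `a` in the top-left cell follows a
#' hypergeometric distribution. The one-sided P sums the tail at or beyond
#' the observed `a`; the two-sided P sums the probabilities of all tables
#' whose probability does not exceed that of the observed table (with a
#' `1e-7` relative tolerance for floating-point ties). The odds ratio is
#' the sample estimate `ad / bc`.
#'
#' @param a,b,c_,d Cell counts: rows are the two groups, columns
#'   with/without the feature.
#' @return List of class `fisher_result`: `table`, `odds_ratio`,
#'   `p_two_sided`, `p_greater`, `p_less`.
#' @export
fisher_exact <- function(a, b, c_, d) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers")
  }
  if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) {
    stop("empty margin: every row and column sum must be positive")
  }
  m <- a + c_        # column-1 total (feature present)
  n <- b + d         # column-2 total
  k <- a + b         # row-1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p_greater <- sum(probs[support >= a])
  p_less <- sum(probs[support <= a])
  p_two <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(
    table = matrix(c(a, c_, b, d), 2, 2,
                   dimnames = list(group = c("group1", "group2"),
                                   feature = c("present", "absent"))),
    odds_ratio = (a * d) / (b * c_),
    p_two_sided = p_two,
    p_greater = p_greater,
    p_less = p_less
  ), class = "fisher_result")
}

#' ARE enrichment among upregulated transcripts
#'
#' Builds the 2x2 table (with-ARE vs without, upregulated vs background)
#' and applies [fisher_exact()]. The background is the not-upregulated
#' expressed set; the two id sets must be disjoint.
#'
#' @param upregulated_ids,background_ids Character vectors of transcript
#'   ids (disjoint).
#' @param are_labels Named logical vector: does each transcript's 3'-UTR
#'   carry an ARE? Must cover both id sets.
#' @return A `fisher_result` with extra elements `prop_up` and `prop_bg`
#'   (fraction ARE-positive in each set).
#' @export
are_enrichment <- function(upregulated_ids, background_ids, are_labels) {
  if (length(intersect(upregulated_ids, background_ids))) {
    stop("upregulated and background sets must be disjoint")
  }
  missing_ids <- setdiff(c(upregulated_ids, background_ids),
                         names(are_labels))
  if (length(missing_ids)) {
    stop("are_labels missing for ", length(missing_ids), " transcript(s)")
  }
  a <- sum(are_labels[upregulated_ids])
  b <- length(upregulated_ids) - a
  c_ <- sum(are_labels[background_ids])
  d <- length(background_ids) - c_
  res <- fisher_exact(a, b, c_, d)
  res$prop_up <- a / (a + b)
  res$prop_bg <- c_ / (c_ + d)
  res
}

#' @export
print.fisher_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.3f; P two-sided %.4g, greater %.4g, less %.4g\n",
              x$odds_ratio, x$p_two_sided, x$p_greater, x$p_less))
  invisible(x)
}

#' Find small open reading frames
#'
#' Scans the three forward frames of each sequence for ORFs running from an
#' ATG to the first in-frame stop codon (a stop is required). Every
#' in-frame ATG opens its own candidate — nested starts are reported
#' separately. Length is counted in codons excluding the stop and must lie
#' within `[min_codons, max_codons]` inclusive. Peptides use the standard
#' genetic code.
#'
#' @param seqs `DNAStringSet` or named character vector (e.g. lncRNA
#'   transcripts).
#' @param min_codons,max_codons Inclusive codon-length bounds (defaults 10
#'   and 100, a common smORF convention).
#' @return `data.frame` with columns `transcript_id`, `frame` (0-2),
#'   `start`, `end` (0-based half-open, stop codon included in the span),
#'   `n_codons`, `peptide`.
#' @export
find_smorfs <- function(seqs, min_codons = 10L, max_codons = 100L) {
  if (min_codons < 1 || max_codons < min_codons) {
    stop("need 1 <= min_codons <= max_codons")
  }
  seqs <- as_dna_set(seqs)
  code <- Biostrings::GENETIC_CODE
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (i in seq_along(seqs)) {
    s <- as.character(seqs[[i]])
    n <- nchar(s)
    for (frame in 0:2) {
      n_codons <- (n - frame) %/% 3
      if (n_codons < 2) next
      starts_at <- frame + 3 * (seq_len(n_codons) - 1) + 1
      codons <- substring(s, starts_at, starts_at + 2)
      atg_idx <- which(codons == "ATG")
      stop_idx <- which(codons %in% stops)
      for (ai in atg_idx) {
        si <- stop_idx[stop_idx > ai]
        if (!length(si)) next
        si <- si[1]
        len <- si - ai  # codons excluding the stop
        if (len < min_codons || len > max_codons) next
        pep <- paste(code[codons[ai:(si - 1)]], collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = names(seqs)[i],
          frame = frame,
          start = frame + 3L * (ai - 1L),
          end = frame + 3L * si,
          n_codons = len,
          peptide = pep,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      n_codons = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
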