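# Independent brute-force oracles, kept deliberately naive: these recompute
# expected values by direct enumeration / per-base loops, independent of the
# package's vectorised implementations.

# Fisher exact P values by explicit enumeration of all 2x2 tables with the
# observed margins, probabilities from lchoose().
oracle_fisher <- function(a, b, c_, d) {
  r1 <- a + b; c1 <- a + c_; N <- a + b + c_ + d
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  logp <- lchoose(c1, ks) + lchoose(N - c1, r1 - ks) - lchoose(N, r1)
  probs <- exp(logp)
  p_obs <- probs[ks == a]
  list(
    p_greater = sum(probs[ks >= a]),
    p_less = sum(probs[ks <= a]),
    p_two_sided = min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  )
}

# six-line brute-force ORF translator: walks every position, reads codons
# one by one until a stop, translates via a hand-written lookup
oracle_orfs <- function(s, min_codons, max_codons) {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (i in seq_len(nchar(s) - 2)) {
    if (substr(s, i, i + 2) != "ATG") next
    j <- i; pep <- ""
    repeat {
      if (j + 2 > nchar(s)) { pep <- NULL; break }
      cod <- substr(s, j, j + 2)
      if (cod %in% c("TAA", "TAG", "TGA")) break
      pep <- paste0(pep, code[[cod]])
      j <- j + 3
    }
    if (is.null(pep)) next
    n_cod <- nchar(pep)
    if (n_cod >= min_codons && n_cod <= max_codons) {
      out[[length(out) + 1]] <- data.frame(
        start = i - 1L, end = j + 2L, n_codons = n_cod, peptide = pep,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# per-bin means by an explicit loop over equal genomic sub-intervals
oracle_bin_body <- function(v, bins) {
  L <- length(v)
  out <- numeric(bins)
  for (b in seq_len(bins)) {
    lo <- which(floor((seq_len(L) - 1) * bins / L) + 1 == b)
    out[b] <- mean(v[lo])
  }
  out
}

# per-base region sums by direct indexing (no cumulative sums)
oracle_region_sums <- function(depth_vec, start, end, strand, ppr_len) {
  body <- depth_vec[(start + 1):end]
  L <- end - start
  plen <- min(ppr_len, L)
  ppr <- if (strand == "+") sum(body[1:plen]) else sum(body[(L - plen + 1):L])
  c(full = sum(body), ppr = ppr, beyond = sum(body) - ppr)
}

random_track <- function(chrom_len = 5000, n_runs = 40, seed = NULL,
                         genes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- numeric(chrom_len)
  for (k in seq_len(n_runs)) {
    a <- sample.int(chrom_len - 50, 1)
    w <- sample.int(50, 1)
    v[a:(a + w)] <- round(stats::runif(1, 0, 20), 2)
  }
  coverage_track(list(chr1 = v), genes = genes)
}
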