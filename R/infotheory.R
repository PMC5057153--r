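# Shannon information-content calculus for regulatory selectivity: the
# information needed to single out M regulated genes among G, the
# information conveyed by one transcription factor's binding, and the
# minimum number of independently binding factors implied.

#' Information required to specify a regulated gene set
#'
#' `log2(G / M)` bits, where `G` is the total number of protein-coding
#' genes and `M` the number of regulated genes (or, for a transcription
#' factor, its number of high-affinity binding targets). Specifying a
#' single gene among 24000 takes `log2(24000) = 14.6` bits; the less
#' selective the regulation (larger `M`), the fewer bits required. Returned
#' at full precision — rounding for presentation is the caller's concern.
#'
#' @param G Total gene count, `G >= M`.
#' @param M Regulated / targeted gene count, `M >= 1`.
#' @return Bits, `log2(G / M)`.
#' @examples
#' round(information_bits(24000, 1), 1)   # 14.6
#' round(information_bits(24000, 35), 1)  # 9.4
#' @export
information_bits <- function(G, M) {
  if (length(G) != 1 || length(M) != 1 || !is.finite(G) || !is.finite(M)) {
    stop("G and M must be finite scalars")
  }
  if (M < 1) stop("M must be >= 1")
  if (M > G) stop("M must not exceed G")
  log2(G / M)
}

#' Minimum number of independent transcription factors
#'
#' If each independently binding factor conveys `per_tf_bits` of
#' information, selecting a target set that requires `required_bits` needs
#' at least `ceiling(required_bits / per_tf_bits)` factors. The ceiling
#' convention is used because a fractional factor cannot bind; note that a
#' quotient just above an integer (e.g. 9.4 / 4.5 = 2.09) therefore rounds
#' up, even where a looser "at least floor" reading is sometimes quoted —
#' [selectivity_information()] reports both conventions.
#'
#' @param required_bits Information required for the target set, > 0.
#' @param per_tf_bits Information conveyed per factor, > 0.
#' @return Integer count of factors.
#' @examples
#' min_tf_count(14.6, 4.5)  # 4
#' @export
min_tf_count <- function(required_bits, per_tf_bits) {
  if (!is.finite(required_bits) || required_bits <= 0) {
    stop("required_bits must be positive")
  }
  if (!is.finite(per_tf_bits) || per_tf_bits <= 0) {
    stop("per_tf_bits must be positive")
  }
  as.integer(ceiling(required_bits / per_tf_bits))
}

#' Full selectivity information summary
#'
#' Bundles the bits needed to specify one gene among `G`, the bits for the
#' observed regulated set of size `M`, the bits conveyed by a typical
#' transcription factor targeting `per_tf_target` genes, and the implied
#' minimum factor counts under both the ceiling and the floor conventions.
#'
#' @param G Total protein-coding gene count.
#' @param M Regulated-set size (`>= 1`).
#' @param per_tf_target Targets per typical transcription factor.
#' @return Named list: `G`, `M`, `bits_single`, `bits_set`, `per_tf_bits`,
#'   `min_tfs_single_ceiling`, `min_tfs_single_floor`,
#'   `min_tfs_set_ceiling`, `min_tfs_set_floor`.
#' @export
selectivity_information <- function(G = 24000, M = 1, per_tf_target = 1000) {
  bits_single <- information_bits(G, 1)
  bits_set <- information_bits(G, M)
  per_tf_bits <- information_bits(G, per_tf_target)
  list(
    G = G, M = M,
    bits_single = bits_single,
    bits_set = bits_set,
    per_tf_bits = per_tf_bits,
    min_tfs_single_ceiling = min_tf_count(bits_single, per_tf_bits),
    min_tfs_single_floor = as.integer(floor(bits_single / per_tf_bits)),
    min_tfs_set_ceiling = if (bits_set > 0) {
      min_tf_count(bits_set, per_tf_bits)
    } else 0L,
    min_tfs_set_floor = as.integer(floor(bits_set / per_tf_bits))
  )
}
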