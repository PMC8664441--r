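#' Convert a count matrix to per-column state frequencies
#'
#' Divides each column by its total read depth. Zero-depth columns stay
#' all-zero (the stated convention, so that uncovered positions carry no
#' signal).
#'
#' @param counts 6 x n matrix of non-negative read counts.
#' @return 6 x n frequency matrix; every nonzero column sums to 1.
#' @export
column_frequencies <- function(counts) {
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  sweep(counts, 2, depth, "/")
}

#' Per-position polarization weight from the grandparental likelihood-ratio test
#'
#' For one reference position, tests whether the two grandparents' read counts
#' were drawn from the same multinomial distribution or from two different
#' ones. The statistic is `G = 2 (lnL_separate - lnL_pooled)` with multinomial
#' maximum-likelihood estimates; its significance `Sig` is the upper-tail
#' chi-square p-value with `df = (number of states with nonzero pooled count)
#' - 1`. The polarization weight is `1 - Sig`. Positions where the test is
#' undefined (zero depth in either grandparent, or a single observed state)
#' get `Sig = 1`, weight 0.
#'
#' @param counts_bv,counts_bb non-negative 6-vectors of grandparental read
#'   counts at the position.
#' @return list with `G`, `df`, `sig` and `weight`.
#' @export
position_weight <- function(counts_bv, counts_bb) {
  w <- polarity_weights(matrix(counts_bv, ncol = 1), matrix(counts_bb, ncol = 1))
  list(G = w$G[1], df = w$df[1], sig = w$sig[1], weight = w$weight[1])
}

# vectorized over columns; x, y are 6 x n matrices
polarity_weights <- function(x, y) {
  xlog <- function(k, p) ifelse(k > 0, k * log(p), 0)
  nx <- colSums(x)
  ny <- colSums(y)
  fx <- sweep(x, 2, pmax(nx, 1), "/")
  fy <- sweep(y, 2, pmax(ny, 1), "/")
  pooled <- sweep(x + y, 2, pmax(nx + ny, 1), "/")
  lnl_sep <- colSums(xlog(x, fx)) + colSums(xlog(y, fy))
  lnl_pool <- colSums(xlog(x, pooled)) + colSums(xlog(y, pooled))
  G <- pmax(2 * (lnl_sep - lnl_pool), 0)
  df <- colSums(x + y > 0) - 1L
  sig <- rep(1, ncol(x))
  ok <- df >= 1L & nx > 0 & ny > 0
  sig[ok] <- pchisq(G[ok], df = df[ok], lower.tail = FALSE)
  list(G = G, df = df, sig = sig, weight = 1 - sig)
}

#' Build the weighted polarized matrix M_p
#'
#' Subtracts the second taxon's frequency matrix from the first's and
#' multiplies every column by its polarization weight. Positive entries mark
#' sequence states associated with the first (Bv) source, negative entries
#' states associated with the second (Bb) source; all entries lie in
#' `[-1, 1]`.
#'
#' @param freq_bv,freq_bb 6 x n frequency matrices (see
#'   [column_frequencies()]).
#' @param weights length-n vector of weights in `[0, 1]`.
#' @param source provenance label, `"initial_F0"` or `"updated_clusters"`.
#' @return an object of class `polarized_matrix`: list with `values` (6 x n),
#'   `weights` and `source`.
#' @export
build_polarized_matrix <- function(freq_bv, freq_bb, weights,
                                   source = "initial_F0") {
  stopifnot(all(dim(freq_bv) == dim(freq_bb)), length(weights) == ncol(freq_bv))
  values <- sweep(freq_bv - freq_bb, 2, weights, "*")
  structure(list(values = values, weights = weights, source = source),
            class = "polarized_matrix")
}

#' Polarize a locus from two source count matrices
#'
#' Convenience wrapper: computes both frequency matrices, the per-position
#' likelihood-ratio weights and the weighted polarized matrix in one step.
#'
#' @param counts_bv,counts_bb 6 x n count matrices for the Bv and Bb sources
#'   (the two grandparents initially; pooled axis clusters after the update).
#' @param source provenance label stored on the result.
#' @return a `polarized_matrix`.
#' @export
polarize <- function(counts_bv, counts_bb, source = "initial_F0") {
  w <- polarity_weights(counts_bv, counts_bb)
  build_polarized_matrix(column_frequencies(counts_bv),
                         column_frequencies(counts_bb),
                         w$weight, source = source)
}

#' Score one sample against a polarized matrix
#'
#' Multiplies the sample's raw count matrix elementwise by `M_p`. The summed
#' positive entries, normalized by the number of informative columns (weight
#' > 0), give the Bv score; the absolute summed negative entries give the Bb
#' score. The two scores express the average weighted read coverage of
#' sequence states associated with each grandparental taxon, so samples scale
#' with coverage and low-coverage samples sit near the origin.
#'
#' @param counts 6 x n count matrix for the sample.
#' @param mp a `polarized_matrix`.
#' @return list with `v_score`, `b_score`, `radius` and `angle` (degrees in
#'   `[0, 90]`; 0 = pure Bv axis).
#' @export
score_sample <- function(counts, mp) {
  m <- sum(mp$weights > 0)
  if (m == 0) return(list(v_score = 0, b_score = 0, radius = 0, angle = NA_real_))
  v <- sum(counts * pmax(mp$values, 0)) / m
  b <- sum(counts * pmax(-mp$values, 0)) / m
  r <- sqrt(v^2 + b^2)
  ang <- if (r > 0) atan2(b, v) * 180 / pi else NA_real_
  list(v_score = v, b_score = b, radius = r, angle = ang)
}

#' Score many samples against a polarized matrix
#'
#' @param counts_list named list of 6 x n count matrices.
#' @param mp a `polarized_matrix`.
#' @return data.frame with one row per sample: `sample_id`, `v_score`,
#'   `b_score`, `radius`, `angle`.
#' @export
score_samples <- function(counts_list, mp) {
  m <- sum(mp$weights > 0)
  ids <- names(counts_list)
  if (m == 0) {
    return(data.frame(sample_id = ids, v_score = 0, b_score = 0, radius = 0,
                      angle = NA_real_, stringsAsFactors = FALSE))
  }
  pos <- pmax(mp$values, 0)
  neg <- pmax(-mp$values, 0)
  v <- vapply(counts_list, function(cc) sum(cc * pos), numeric(1)) / m
  b <- vapply(counts_list, function(cc) sum(cc * neg), numeric(1)) / m
  r <- sqrt(v^2 + b^2)
  data.frame(sample_id = ids, v_score = v, b_score = b, radius = r,
             angle = ifelse(r > 0, atan2(b, v) * 180 / pi, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}
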