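#' Distance between two segments
#'
#' Number of binary feature dimensions on which two +1/-1 vectors differ
#' (Hamming distance; the rectilinear distance in the feature hypercube).
#'
#' @param a,b +1/-1 vectors of equal length.
#' @return integer distance.
#' @export
segment_distance <- function(a, b) {
  if (length(a) != length(b)) stop_pg("segment vectors differ in length")
  sum(a != b)
}

# All pairwise Hamming distances of a +/-1 matrix (s x s), via the inner
# product identity <a,b> = k - 2 d(a,b).
hamming_matrix <- function(m) {
  (ncol(m) - tcrossprod(m)) / 2
}

#' Count minimal pairs
#'
#' The number of unordered segment pairs at distance exactly one: the
#' edges of the feature hypercube occupied at both endpoints. This is the
#' raw local-symmetry quantity N_mp, always computed on a reduced
#' (contrastive) representation.
#'
#' @param mat s x k matrix of +1/-1 rows.
#' @return integer count, at most s(s-1)/2.
#' @export
count_minimal_pairs <- function(mat) {
  d <- hamming_matrix(mat)
  sum(d[upper.tri(d)] == 1)
}

#' Feature imbalance sum
#'
#' For each dimension, the absolute difference between the number of
#' segments carrying + and the number carrying -, summed over dimensions:
#' the raw global-symmetry quantity N_im. Zero means every dimension
#' splits the inventory exactly in half.
#'
#' @param mat s x k matrix of +1/-1 rows.
#' @return integer sum; each column contributes |column sum|, which has
#'   the parity of s.
#' @export
imbalance_sum <- function(mat) {
  sum(abs(colSums(mat)))
}

#' Raw geometry of a reduced inventory
#'
#' @param mat s x k matrix of +1/-1 rows (an inventory projected onto one
#'   irreducible feature subset).
#' @return list with `s`, `k`, `n_mp`, `n_im`.
#' @export
geometry_summary <- function(mat) {
  check_pm1_matrix(mat, "reduced inventory")
  list(s = nrow(mat), k = ncol(mat),
       n_mp = count_minimal_pairs(mat), n_im = imbalance_sum(mat))
}

#' Economy score
#'
#' Econ = (s - (p + 1)) / (2^p - (p + 1)): how fully an inventory of s
#' segments occupies the 2^p cells its p contrastive dimensions define,
#' shifted so that the sparsest inventory attainable with p irreducible
#' dimensions (s = p + 1) scores 0 and the saturated hypercube (s = 2^p)
#' scores 1. p is the median size of the inventory's irreducible feature
#' subsets and may be fractional (even-count median); the formula is then
#' applied with real exponentiation.
#'
#' For p = 1 the denominator vanishes (the only inventory is two segments
#' on one dimension) and the score is undefined: `NA` is returned and such
#' inventories are dropped from economy analyses.
#'
#' @param s integer segment count, s >= 2.
#' @param p real median contrastive dimension, p >= 1.
#' @return real in \[0, 1\], or `NA_real_` when undefined (p = 1).
#' @export
economy_score <- function(s, p) {
  if (s < 2) stop_pg("economy_score: s must be >= 2")
  if (p < 1) stop_pg("economy_score: p must be >= 1")
  if (p == round(p) && s > 2^p) {
    stop_pg("economy_score: impossible inventory (s = %d > 2^%d)", s, p)
  }
  den <- 2^p - (p + 1)
  if (abs(den) < 1e-12) return(NA_real_)
  val <- (s - (p + 1)) / den
  if (val < -1e-9 || val > 1 + 1e-9) {
    stop_pg("economy_score: value %.4f outside [0, 1] for s = %d, p = %g (invalid pair)",
            val, s, p)
  }
  min(max(val, 0), 1)
}
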