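# Size-matched random control inventories. Four families:
#   segment_freq    — attested feature combinations, drawn with
#                     probability proportional to the number of languages
#                     containing each combination
#   segment_uniform — attested combinations, drawn uniformly
#   feature_freq    — every feature value of every segment an independent
#                     biased coin with the pooled empirical +1 probability
#   feature_uniform — independent fair coins
# Segment controls always draw from the pool of the matched subsystem;
# duplicates are rejected and redrawn (inventories are sets), which for
# segment controls is equivalent to successive weighted sampling without
# replacement.

CONTROL_KINDS <- c("segment_freq", "segment_uniform",
                   "feature_freq", "feature_uniform")

#' Generate one random segment-control inventory
#'
#' @param size target inventory size.
#' @param pool a [combo_frequencies()] object for the matched subsystem.
#' @param kind `"segment_freq"` (probability proportional to combination
#'   frequency) or `"segment_uniform"`.
#' @param seed integer seed; the draw is deterministic given it.
#' @return matrix of `size` distinct +1/-1 rows, all from the attested
#'   pool.
#' @export
gen_segment_control <- function(size, pool, kind = c("segment_freq", "segment_uniform"),
                                seed = NULL) {
  kind <- match.arg(kind)
  n_pool <- nrow(pool$combos)
  if (n_pool < size) {
    stop_pg("pool has %d combinations, fewer than target size %d", n_pool, size)
  }
  w <- if (kind == "segment_freq") pool$counts else rep(1, n_pool)
  idx <- with_seed(seed, sample.int(n_pool, size, replace = FALSE, prob = w))
  pool$combos[idx, , drop = FALSE]
}

#' Generate one random feature-control inventory
#'
#' Every feature value of every segment is an independent coin flip —
#' +1 with the given per-feature probability — without regard for whether
#' the resulting vector is an attested segment. Segments identical to a
#' previously drawn one are rejected and resampled.
#'
#' @param size target inventory size.
#' @param K feature count.
#' @param plus_prob per-feature probability of +1: a length-K vector
#'   (frequency-matched controls) or a scalar 0.5 (uniform controls).
#' @param seed integer seed.
#' @return matrix of `size` distinct +1/-1 rows.
#' @export
gen_feature_control <- function(size, K, plus_prob = 0.5, seed = NULL) {
  if (size > 2^K) stop_pg("cannot draw %d distinct segments from 2^%d cells", size, K)
  if (length(plus_prob) == 1) plus_prob <- rep(plus_prob, K)
  if (length(plus_prob) != K) stop_pg("plus_prob must have length 1 or K")
  if (any(plus_prob <= 0) || any(plus_prob >= 1)) {
    stop_pg("plus_prob values must lie strictly in (0, 1)")
  }
  with_seed(seed, {
    rows <- matrix(numeric(0), nrow = 0, ncol = K)
    guard <- 0L
    while (nrow(rows) < size) {
      draw <- ifelse(stats::runif(K) < plus_prob, 1, -1)
      dup <- nrow(rows) > 0 && any(colSums(t(rows) != draw) == 0)
      if (!dup) rows <- rbind(rows, draw)
      guard <- guard + 1L
      if (guard > 10000L * size) {
        stop_pg("feature-control rejection sampling failed to find %d distinct segments",
                size)
      }
    }
    dimnames(rows) <- NULL
    rows
  })
}

#' Generate a full size-matched control database
#'
#' One control inventory per natural inventory, with the same subsystem
#' tag and exactly the same size, generated by the requested family. The
#' controls then flow through the same contrastive-search / geometry /
#' rank-normalization path as the naturals, including the omission
#' bookkeeping.
#'
#' @param naturals list of `encoded_inventory` objects.
#' @param kind one of `r paste(CONTROL_KINDS, collapse = ", ")`.
#' @param pool [combo_frequencies()] for the matched subsystem (segment
#'   kinds; also supplies `plus_prob` and K for feature kinds unless
#'   overridden).
#' @param plus_prob optional explicit per-feature +1 probabilities
#'   (feature kinds).
#' @param seed integer seed; control i uses a derived stream, so the
#'   database is reproducible as a whole.
#' @return list of `encoded_inventory` objects, ids suffixed with the
#'   control kind.
#' @export
build_control_database <- function(naturals, kind = CONTROL_KINDS, pool,
                                   plus_prob = NULL, seed = 1) {
  kind <- match.arg(kind)
  K <- ncol(naturals[[1]]$matrix)
  if (kind %in% c("feature_freq", "feature_uniform")) {
    if (is.null(plus_prob)) {
      plus_prob <- if (kind == "feature_uniform") rep(0.5, K) else pool$plus_prob
    }
    # empirical probabilities can be degenerate on rare features; clip
    plus_prob <- pmin(pmax(plus_prob, 1 / (2 * 10^4)), 1 - 1 / (2 * 10^4))
  }
  lapply(seq_along(naturals), function(i) {
    nat <- naturals[[i]]
    si <- derive_seed(seed, i)
    m <- switch(kind,
      segment_freq = gen_segment_control(nat$s, pool, "segment_freq", si),
      segment_uniform = gen_segment_control(nat$s, pool, "segment_uniform", si),
      feature_freq = gen_feature_control(nat$s, K, plus_prob, si),
      feature_uniform = gen_feature_control(nat$s, K, plus_prob, si)
    )
    rownames(m) <- NULL
    encoded_inventory(paste(nat$language_id, kind, sep = "."),
                      nat$subsystem, m)
  })
}
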