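# Independent oracles used across the suite. Deliberately naive: plain
# loops over power sets, all-pairs counts, explicit orbit enumeration.

# Random encoded inventory: s distinct +/-1 rows on K features.
random_inventory <- function(s, K) {
  stopifnot(s <= 2^K)
  m <- matrix(numeric(0), 0, K)
  while (nrow(m) < s) {
    m <- unique(rbind(m, matrix(sample(c(-1, 1), K * s, replace = TRUE),
                                ncol = K)))
  }
  m[seq_len(s), , drop = FALSE]
}

# All irreducible sufficient subsets by filtering the full power set.
naive_specs <- function(mat) {
  K <- ncol(mat)
  suff <- function(cols) {
    if (length(cols) == 0) return(nrow(mat) < 2)
    anyDuplicated(mat[, cols, drop = FALSE]) == 0
  }
  out <- list()
  for (code in seq_len(2^K - 1)) {
    cols <- which(bitwAnd(code, bitwShiftL(1L, 0:(K - 1))) != 0)
    if (!suff(cols)) next
    irred <- TRUE
    for (j in cols) {
      if (suff(setdiff(cols, j))) { irred <- FALSE; break }
    }
    if (irred) out[[length(out) + 1]] <- cols
  }
  out
}

spec_key <- function(specs) sort(vapply(specs, function(x) paste(sort(x), collapse = ","), ""))

# Edge count of the induced hypercube subgraph via an explicit adjacency
# matrix (independent of the inner-product trick used by the package).
naive_minimal_pairs <- function(mat) {
  s <- nrow(mat)
  adj <- 0L
  for (i in seq_len(s - 1)) {
    for (j in (i + 1):s) {
      if (sum(mat[i, ] != mat[j, ]) == 1) adj <- adj + 1L
    }
  }
  adj
}

# AUC by brute-force pair counting.
naive_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# Full orbit of a configuration under column permutation + per-column
# sign flip + row reordering, as a set of sorted-row string keys.
orbit_keys <- function(mat) {
  k <- ncol(mat)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(rest) c(v[i], rest))
    }))
  }
  keys <- character(0)
  for (pm in perms(seq_len(k))) {
    for (f in 0:(2^k - 1)) {
      flips <- ifelse(bitwAnd(f, bitwShiftL(1L, 0:(k - 1))) != 0, -1, 1)
      img <- sweep(mat[, pm, drop = FALSE], 2, flips, "*")
      key <- paste(sort(apply(img, 1, paste, collapse = ",")), collapse = "|")
      keys <- c(keys, key)
    }
  }
  unique(keys)
}

# A tiny natural-looking feature table on 3 features for io tests.
tiny_feature_system <- function() {
  m <- rbind(
    p = c(-1, -1, -1), b = c(-1, -1, -1),     # p/b share an encoding
    t = c(-1, -1, 1), a = c(1, 1, 1),
    i = c(1, 1, -1), u = c(1, -1, -1)
  )
  colnames(m) <- c("syllabic", "sonorant", "continuant")
  feature_system(c("syllabic", "sonorant", "continuant"), m)
}
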