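# Geometrically distinct configurations and attainable-value tables.
#
# Two inventories have the same geometry when one can be mapped onto the
# other by reordering feature dimensions, flipping the polarity of any
# dimension, and reordering segments — the symmetries of the binary
# hypercube. N_mp and N_im are invariant under exactly these operations,
# so rank tables of attainable values are built over geometrically
# distinct configurations only.

#' Canonical key of a configuration
#'
#' Produces a key equal for two s x k +1/-1 matrices iff they are related
#' by row permutation, column permutation, and per-column sign flips. The
#' matrix is encoded as a vertex-colored graph — one node per segment, two
#' nodes per column (one per polarity, each segment linked to the polarity
#' node matching its value) and one pairing node per column tying the two
#' polarity nodes together — whose color-preserving automorphisms are
#' exactly the hypercube symmetries; the key is a serialization of the
#' BLISS canonical form of that graph.
#'
#' @param mat s x k matrix of +1/-1.
#' @return character key (includes s and k).
#' @export
canonical_form <- function(mat) {
  check_pm1_matrix(mat, "configuration")
  s <- nrow(mat); k <- ncol(mat)
  # vertices: 1..s rows | s+1..s+2k column-polarity | s+2k+1..s+3k pairing
  colplus <- s + 2 * seq_len(k) - 1
  colminus <- s + 2 * seq_len(k)
  pairv <- s + 2 * k + seq_len(k)
  ei <- rep(seq_len(s), k)
  ej <- integer(s * k)
  for (j in seq_len(k)) {
    idx <- (j - 1) * s + seq_len(s)
    ej[idx] <- ifelse(mat[, j] > 0, colplus[j], colminus[j])
  }
  edges <- rbind(
    cbind(ei, ej),
    cbind(colplus, pairv),
    cbind(colminus, pairv)
  )
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  colors <- c(rep(1L, s), rep(2L, 2 * k), rep(3L, k))
  cp <- igraph::canonical_permutation(g, colors = colors)
  lab <- cp$labeling
  el <- cbind(pmin(lab[edges[, 1]], lab[edges[, 2]]),
              pmax(lab[edges[, 1]], lab[edges[, 2]]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  paste0(s, "x", k, "|", paste(el[, 1], el[, 2], sep = "-", collapse = ","))
}

# 0/1 vertex matrix of the k-cube, vertex v (1-based) = binary digits of
# v-1; returns +1/-1 matrix 2^k x k.
cube_vertices <- function(k) {
  v <- 0:(2^k - 1)
  m <- sapply(seq_len(k), function(j) bitwAnd(bitwShiftR(v, j - 1L), 1L))
  if (!is.matrix(m)) m <- matrix(m, ncol = k)
  2 * m - 1
}

# All vertex permutations of the k-cube induced by column permutations
# and per-column sign flips (the full hypercube symmetry group, order
# 2^k k!). Returns a (2^k k!) x 2^k matrix of 1-based vertex images.
# Only used for small k, where it makes orbit computation cheap.
cube_group <- function(k) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], perms(v[-i]))
    }))
  }
  pm <- perms(seq_len(k))
  verts <- 0:(2^k - 1)
  bits <- sapply(seq_len(k), function(j) bitwAnd(bitwShiftR(verts, j - 1L), 1L))
  if (!is.matrix(bits)) bits <- matrix(bits, ncol = k)
  pw <- 2^(seq_len(k) - 1)
  out <- matrix(0L, nrow = nrow(pm) * 2^k, ncol = 2^k)
  row <- 0L
  for (pi_ in seq_len(nrow(pm))) {
    pb <- bits[, pm[pi_, ], drop = FALSE]
    base <- as.integer(pb %*% pw)
    for (f in 0:(2^k - 1)) {
      row <- row + 1L
      out[row, ] <- bitwXor(base, f) + 1L
    }
  }
  out
}

# Irreducibility of a full configuration on its k columns: every column
# must carry at least one minimal pair (removing a column merges two rows
# iff they differed only there). Also rules out constant columns.
config_irreducible <- function(mat) {
  d <- hamming_matrix(mat)
  one <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
  if (nrow(one) == 0) return(FALSE)
  covered <- logical(ncol(mat))
  for (r in seq_len(nrow(one))) {
    j <- which(mat[one[r, 1], ] != mat[one[r, 2], ])
    covered[j] <- TRUE
  }
  all(covered)
}

#' Enumerate or sample geometrically distinct irreducible configurations
#'
#' For a given inventory size s and dimension k, produces configurations
#' of s distinct hypercube vertices that are irreducible (every dimension
#' is needed: each carries at least one minimal pair), deduplicated by
#' [canonical_form()]. When the raw subset count C(2^k, s) is at most
#' `budget` the enumeration is exhaustive; otherwise seeded random
#' sampling collects up to `sample_size` distinct configurations. The
#' sampler mixes uniform draws of s distinct vertices with a constructive
#' draw (a random dimension-spanning chain of k+1 vertices completed with
#' random vertices, irreducible by construction) so that sparse regimes
#' where uniform draws are almost never irreducible still yield
#' configurations.
#'
#' @param s inventory size, 2 <= s <= 2^k.
#' @param k dimension count.
#' @param budget switchover: exhaustive iff C(2^k, s) <= budget.
#' @param sample_size target number of distinct configurations in
#'   sampling mode.
#' @param seed integer seed (sampling mode).
#' @param max_attempts sampling attempt cap.
#' @param mode force `"exhaustive"` or `"sampled"` (default `"auto"`).
#' @return list with `configs` (list of s x k matrices), `stats`
#'   (data.frame of `n_mp`, `n_im` per configuration) and `provenance`.
#' @export
enumerate_geometries <- function(s, k, budget = 2e5, sample_size = 1e4,
                                 seed = 1, max_attempts = 30 * sample_size,
                                 mode = c("auto", "exhaustive", "sampled")) {
  mode <- match.arg(mode)
  if (s < 2) stop_pg("s must be >= 2")
  if (s > 2^k) stop_pg("impossible configuration: s = %d > 2^%d", s, k)
  n_raw <- if (k <= 40) lchoose(2^k, s) else Inf
  exhaustive <- if (mode == "auto") is.finite(n_raw) && n_raw <= log(budget) else
    mode == "exhaustive"
  if (mode == "exhaustive" && (!is.finite(n_raw) || n_raw > log(1e7))) {
    stop_pg("exhaustive enumeration infeasible for s = %d, k = %d", s, k)
  }

  # Deduplication by canonical form, with a cheap invariant fingerprint
  # (distance histogram, minimal-pair degrees, column imbalances) so the
  # graph canonicalization is only computed when two configurations
  # collide on all invariants.
  configs <- list()
  nmp <- integer(0); nim <- integer(0)
  canon_cache <- list()
  fp_index <- new.env(hash = TRUE, parent = emptyenv())
  config_fp <- function(m) {
    d <- hamming_matrix(m)
    du <- d[upper.tri(d)]
    paste(paste(tabulate(du + 1L, nbins = ncol(m) + 1L), collapse = ","),
          paste(sort(rowSums(d == 1)), collapse = ","),
          paste(sort(abs(colSums(m))), collapse = ","), sep = ";")
  }
  canon_of <- function(i) {
    if (is.null(canon_cache[[i]])) canon_cache[[i]] <<- canonical_form(configs[[i]])
    canon_cache[[i]]
  }
  add_config <- function(m) {
    fp <- config_fp(m)
    prev <- fp_index[[fp]]
    key <- NULL
    if (!is.null(prev)) {
      key <- canonical_form(m)
      for (i in prev) if (canon_of(i) == key) return(FALSE)
    }
    idx <- length(configs) + 1L
    configs[[idx]] <<- m
    if (!is.null(key)) canon_cache[[idx]] <<- key else
      canon_cache[idx] <<- list(NULL)
    fp_index[[fp]] <- c(prev, idx)
    g <- geometry_summary(m)
    nmp[[idx]] <<- g$n_mp
    nim[[idx]] <<- g$n_im
    TRUE
  }

  if (exhaustive) {
    verts <- cube_vertices(k)
    subsets <- utils::combn(2^k, s)
    if (k <= 5) {
      # orbit dedup under the explicit hypercube symmetry group: the
      # orbit id is the minimum, over group elements, of the occupancy
      # bitmask of the image subset
      G <- cube_group(k)
      P2 <- 2^(0:(2^k - 1))
      nbr <- sapply(seq_len(k), function(j) bitwXor(0:(2^k - 1), bitwShiftL(1L, j - 1L)) + 1L)
      if (!is.matrix(nbr)) nbr <- matrix(nbr, ncol = k)
      bits01 <- (verts + 1) / 2
      seen_orbits <- new.env(hash = TRUE, parent = emptyenv())
      occ <- logical(2^k)
      for (ci in seq_len(ncol(subsets))) {
        sub <- subsets[, ci]
        occ[sub] <- TRUE
        col_edges <- colSums(matrix(occ[nbr[sub, ]], nrow = s))
        occ[sub] <- FALSE
        if (any(col_edges == 0)) next
        oid <- format(min(rowSums(matrix(P2[G[, sub]], nrow = nrow(G)))),
                      digits = 22)
        if (!is.null(seen_orbits[[oid]])) next
        seen_orbits[[oid]] <- TRUE
        idx <- length(configs) + 1L
        configs[[idx]] <- verts[sub, , drop = FALSE]
        nmp[[idx]] <- sum(col_edges) / 2
        nim[[idx]] <- sum(abs(2 * colSums(bits01[sub, , drop = FALSE]) - s))
      }
    } else {
      for (ci in seq_len(ncol(subsets))) {
        m <- verts[subsets[, ci], , drop = FALSE]
        if (config_irreducible(m)) add_config(m)
      }
    }
    prov <- list(mode = "exhaustive", n_raw = ncol(subsets), seed = NULL)
  } else {
    if (s < k + 1) {
      # an irreducible configuration needs s >= k + 1 rows
      return(list(configs = list(),
                  stats = data.frame(n_mp = integer(0), n_im = integer(0)),
                  provenance = list(mode = "sampled", n_attempts = 0, seed = seed)))
    }
    small_space <- k <= 20
    verts <- if (small_space) cube_vertices(k) else NULL
    seen_subsets <- new.env(hash = TRUE, parent = emptyenv())
    attempts <- 0L
    with_seed(seed, {
      while (length(configs) < sample_size && attempts < max_attempts) {
        attempts <- attempts + 1L
        constructive <- stats::runif(1) < 0.3
        if (constructive) {
          base <- matrix(sample(c(-1, 1), k, replace = TRUE), nrow = 1)
          chain <- matrix(0, nrow = k + 1, ncol = k)
          chain[1, ] <- base
          ord <- sample.int(k)
          for (t in seq_len(k)) {
            chain[t + 1, ] <- chain[t, ]
            chain[t + 1, ord[t]] <- -chain[t + 1, ord[t]]
          }
          m <- chain
          while (nrow(m) < s) {
            extra <- matrix(sample(c(-1, 1), k * (s - nrow(m)),
                                   replace = TRUE), ncol = k)
            m <- unique(rbind(m, extra))
          }
          m <- m[seq_len(s), , drop = FALSE]
        } else if (small_space) {
          m <- verts[sample.int(2^k, s), , drop = FALSE]
        } else {
          m <- unique(matrix(sample(c(-1, 1), k * (s + 8), replace = TRUE),
                             ncol = k))
          if (nrow(m) < s) next
          m <- m[seq_len(s), , drop = FALSE]
        }
        skey <- paste(apply(m[do.call(order, as.data.frame(m)), , drop = FALSE],
                            1, paste, collapse = ""), collapse = "|")
        if (!is.null(seen_subsets[[skey]])) next
        seen_subsets[[skey]] <- TRUE
        if (config_irreducible(m)) add_config(m)
      }
    })
    prov <- list(mode = "sampled", n_attempts = attempts, seed = seed)
  }
  prov$n_configs <- length(configs)
  list(configs = configs,
       stats = data.frame(n_mp = nmp, n_im = nim),
       provenance = prov)
}

sk_key <- function(s, k) paste(s, k, sep = ":")
skm_key <- function(s, k, mp) paste(s, k, mp, sep = ":")

#' Build attainable-value tables for rank normalization
#'
#' For every (s, k) pair appearing among the attested variant
#' representations, collects the distinct attainable values of N_mp —
#' and, within each (s, k, N_mp) cell, of N_im — over the union of the
#' attested variants and the enumerated/sampled geometrically distinct
#' configurations of [enumerate_geometries()]. Attested values are always
#' unioned in, so every observed statistic is rankable; cells where an
#' attested value had to be added beyond the enumeration are flagged
#' `attested-augmented` in the provenance.
#'
#' @param attested data.frame with columns `s`, `k`, `n_mp`, `n_im` — one
#'   row per variant representation of every inventory to be scored (see
#'   [variant_stats()]).
#' @param budget,sample_size,max_attempts passed to [enumerate_geometries()].
#' @param seed integer seed; each (s, k) key gets a derived stream.
#' @return object of class `rank_table` with elements `mp` (named list
#'   keyed "s:k" of ascending N_mp values), `im` (keyed "s:k:n_mp"),
#'   `provenance`, and `pool` (data.frame of the distinct enumerated
#'   configurations' `s`, `k`, `n_mp`, `n_im`, used for decorrelation
#'   diagnostics).
#' @export
build_rank_tables <- function(attested, budget = 2e5, sample_size = 1e4,
                              seed = 1, max_attempts = 30 * sample_size) {
  stopifnot(all(c("s", "k", "n_mp", "n_im") %in% colnames(attested)))
  keys <- unique(attested[, c("s", "k")])
  mp <- list(); im <- list(); prov <- list()
  pool <- vector("list", nrow(keys))
  for (r in seq_len(nrow(keys))) {
    s <- keys$s[r]; k <- keys$k[r]
    att <- attested[attested$s == s & attested$k == k, , drop = FALSE]
    en <- enumerate_geometries(s, k, budget = budget,
                               sample_size = sample_size,
                               seed = derive_seed(seed, r),
                               max_attempts = max_attempts)
    pool[[r]] <- if (nrow(en$stats) > 0) {
      data.frame(s = s, k = k, en$stats)
    } else NULL
    kk <- sk_key(s, k)
    mp_vals <- sort(unique(c(att$n_mp, en$stats$n_mp)))
    mp[[kk]] <- mp_vals
    aug <- length(setdiff(att$n_mp, en$stats$n_mp)) > 0
    for (mv in mp_vals) {
      im_att <- att$n_im[att$n_mp == mv]
      im_en <- en$stats$n_im[en$stats$n_mp == mv]
      im[[skm_key(s, k, mv)]] <- sort(unique(c(im_att, im_en)))
      if (length(setdiff(im_att, im_en)) > 0) aug <- TRUE
    }
    prov[[kk]] <- c(en$provenance,
                    list(attested_augmented = aug, n_attested = nrow(att)))
  }
  structure(
    list(mp = mp, im = im, provenance = prov,
         pool = do.call(rbind, pool[!vapply(pool, is.null, logical(1))])),
    class = "rank_table"
  )
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Rank table: %d (s,k) keys, %d (s,k,N_mp) cells, pool of %d distinct geometries\n",
              length(x$mp), length(x$im),
              if (is.null(x$pool)) 0L else nrow(x$pool)))
  invisible(x)
}

#' Serialize / restore a rank table
#'
#' @param table a `rank_table`.
#' @param path JSON file path.
#' @return `read_rank_table()` returns a `rank_table`.
#' @export
write_rank_table <- function(table, path) {
  jsonlite::write_json(
    list(mp = table$mp, im = table$im, provenance = table$provenance,
         pool = table$pool),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_rank_table
#' @export
read_rank_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(mp = lapply(x$mp, as.numeric), im = lapply(x$im, as.numeric),
         provenance = x$provenance,
         pool = if (is.null(x$pool)) NULL else as.data.frame(x$pool)),
    class = "rank_table"
  )
}

#' Local-symmetry score of one variant representation
#'
#' Converts a raw minimal-pair count into its rank among the attainable
#' values for the variant's size and dimension, normalized to \[0, 1\]
#' (rank 1 = smallest value maps to 0, the largest to 1). When only one
#' value is attainable the score carries no information and `NA` is
#' returned (the variant is omitted from local-symmetry analyses).
#'
#' @param n_mp raw minimal-pair count.
#' @param s,k the variant's size and dimension.
#' @param table a `rank_table` covering the key (tables must be built
#'   from a pool including this variant).
#' @return real in \[0, 1\], or `NA_real_` when the value list has
#'   length 1.
#' @export
loc_score <- function(n_mp, s, k, table) {
  vals <- table$mp[[sk_key(s, k)]]
  if (is.null(vals)) stop_pg("no rank-table entry for (s = %d, k = %d); build tables first", s, k)
  if (length(vals) == 1) return(NA_real_)
  r <- match(n_mp, vals)
  if (is.na(r)) stop_pg("N_mp = %d not in the attainable list for (s = %d, k = %d)", n_mp, s, k)
  (r - 1) / (length(vals) - 1)
}

#' Global-symmetry score of one variant representation
#'
#' Rank-normalizes a raw imbalance sum among the values attainable for
#' the variant's size, dimension and minimal-pair count, ranking in
#' descending order so that the most imbalanced attainable configuration
#' scores 0 and the most balanced scores 1. `NA` when only one value is
#' attainable.
#'
#' @param n_im raw imbalance sum.
#' @param s,k,n_mp the conditioning key.
#' @param table a `rank_table`.
#' @return real in \[0, 1\] or `NA_real_`.
#' @export
glob_score <- function(n_im, s, k, n_mp, table) {
  vals <- table$im[[skm_key(s, k, n_mp)]]
  if (is.null(vals)) {
    stop_pg("no rank-table entry for (s = %d, k = %d, N_mp = %d); build tables first",
            s, k, n_mp)
  }
  if (length(vals) == 1) return(NA_real_)
  r <- match(n_im, vals)
  if (is.na(r)) {
    stop_pg("N_im = %d not in the attainable list for (s = %d, k = %d, N_mp = %d)",
            n_im, s, k, n_mp)
  }
  rd <- length(vals) - r + 1  # descending rank: largest n_im -> 1
  (rd - 1) / (length(vals) - 1)
}

#' Per-variant raw statistics of an inventory
#'
#' @param specs a `spec_set` for the inventory.
#' @param inv the matching `encoded_inventory`.
#' @return data.frame with one row per variant representation: `s`, `k`,
#'   `n_mp`, `n_im`.
#' @export
variant_stats <- function(specs, inv) {
  m <- inv$matrix
  do.call(rbind, lapply(specs$specs, function(cols) {
    red <- m[, cols, drop = FALSE]
    g <- geometry_summary(red)
    data.frame(s = g$s, k = g$k, n_mp = g$n_mp, n_im = g$n_im)
  }))
}

#' Score one inventory (Econ, Loc, Glob)
#'
#' Econ is computed from the inventory size and the median contrastive
#' dimension p. Loc and Glob are medians, over the variant
#' representations, of the per-variant rank-normalized scores, each
#' computed against the variant's own (s, k) — variants whose score is
#' fully determined (single attainable value) are left out of the median,
#' and the statistic is omitted entirely when every variant is
#' determined.
#'
#' @param specs a `spec_set`.
#' @param inv the matching `encoded_inventory`.
#' @param table a `rank_table` built over a pool including this
#'   inventory's variants.
#' @return one-row data.frame: `id`, `subsystem`, `s`, `p`, `n_variants`,
#'   `econ`, `loc`, `glob`, and omission reasons (`NA` when defined).
#' @export
score_inventory <- function(specs, inv, table) {
  vs <- variant_stats(specs, inv)
  p <- specs$p
  econ <- economy_score(inv$s, p)
  econ_reason <- if (is.na(econ)) "p_equals_1" else NA_character_
  locs <- mapply(loc_score, vs$n_mp, vs$s, vs$k, MoreArgs = list(table = table))
  globs <- mapply(glob_score, vs$n_im, vs$s, vs$k, vs$n_mp,
                  MoreArgs = list(table = table))
  loc <- if (all(is.na(locs))) NA_real_ else stats::median(locs[!is.na(locs)])
  glob <- if (all(is.na(globs))) NA_real_ else stats::median(globs[!is.na(globs)])
  data.frame(
    id = specs$id, subsystem = inv$subsystem, s = inv$s, p = p,
    n_variants = specs$n_variants,
    econ = econ, loc = loc, glob = glob,
    econ_omit = econ_reason,
    loc_omit = if (is.na(loc)) "single_attainable_value" else NA_character_,
    glob_omit = if (is.na(glob)) "single_attainable_value" else NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Score a database of inventories
#'
#' @param spec_sets list of `spec_set` objects.
#' @param invs matching list of `encoded_inventory` objects.
#' @param table a `rank_table`.
#' @return data.frame with one row per inventory (see [score_inventory()]).
#' @export
score_database <- function(spec_sets, invs, table) {
  stopifnot(length(spec_sets) == length(invs))
  do.call(rbind, Map(score_inventory, spec_sets, invs,
                     MoreArgs = list(table = table)))
}

#' Pairwise correlations of Econ, Loc and Glob over a rank table
#'
#' Computes the Pearson correlations between the three statistics over
#' the distinct rank-table entries: Econ vs Loc over one entry per
#' attainable (s, k, N_mp) value, and the two Glob correlations over one
#' entry per attainable (s, k, N_mp, N_im) value. At this granularity
#' the rank-normalized scores have mean 1/2 within every stratum by
#' construction, so all three correlations are zero up to floating
#' point; the function exists to verify that the implementation actually
#' delivers this design property. (Over raw geometry multiplicities —
#' see [pooled_geometry_scores()] — the statistics need not be
#' uncorrelated, since strata differ in how geometries distribute over
#' attainable values.)
#'
#' @param table a `rank_table`.
#' @return named numeric vector: `econ_loc`, `econ_glob`, `loc_glob`.
#' @export
decorrelation_check <- function(table) {
  mp_entries <- do.call(rbind, lapply(names(table$mp), function(kk) {
    sk <- as.integer(strsplit(kk, ":", fixed = TRUE)[[1]])
    vals <- table$mp[[kk]]
    if (length(vals) < 2) return(NULL)
    data.frame(s = sk[1], k = sk[2], n_mp = vals)
  }))
  im_entries <- do.call(rbind, lapply(names(table$im), function(kk) {
    skm <- as.integer(strsplit(kk, ":", fixed = TRUE)[[1]])
    vals <- table$im[[kk]]
    if (length(vals) < 2) return(NULL)
    data.frame(s = skm[1], k = skm[2], n_mp = skm[3], n_im = vals)
  }))
  econ_mp <- mapply(economy_score, mp_entries$s, mp_entries$k)
  loc_mp <- mapply(loc_score, mp_entries$n_mp, mp_entries$s, mp_entries$k,
                   MoreArgs = list(table = table))
  ok <- !is.na(econ_mp) & !is.na(loc_mp)
  r_el <- stats::cor(econ_mp[ok], loc_mp[ok])
  econ_im <- mapply(economy_score, im_entries$s, im_entries$k)
  loc_im <- mapply(loc_score, im_entries$n_mp, im_entries$s, im_entries$k,
                   MoreArgs = list(table = table))
  glob_im <- mapply(glob_score, im_entries$n_im, im_entries$s, im_entries$k,
                    im_entries$n_mp, MoreArgs = list(table = table))
  ok_eg <- !is.na(econ_im) & !is.na(glob_im)
  ok_lg <- !is.na(loc_im) & !is.na(glob_im)
  c(econ_loc = r_el,
    econ_glob = stats::cor(econ_im[ok_eg], glob_im[ok_eg]),
    loc_glob = stats::cor(loc_im[ok_lg], glob_im[ok_lg]))
}

#' Econ/Loc/Glob over the pooled distinct geometries
#'
#' Scores every geometrically distinct configuration in a rank table's
#' pool with the three statistics (each configuration taken as its own
#' single-variant inventory with p = k), dropping omitted values. By
#' construction of the rank normalization these three scores should be
#' mutually (close to) uncorrelated over the pool.
#'
#' @param table a `rank_table` with a non-empty pool.
#' @return data.frame with columns `econ`, `loc`, `glob` (rows with any
#'   omitted statistic removed).
#' @export
pooled_geometry_scores <- function(table) {
  pool <- table$pool
  if (is.null(pool) || nrow(pool) == 0) stop_pg("rank table has no pool")
  econ <- mapply(economy_score, pool$s, pool$k)
  loc <- mapply(loc_score, pool$n_mp, pool$s, pool$k,
                MoreArgs = list(table = table))
  glob <- mapply(glob_score, pool$n_im, pool$s, pool$k, pool$n_mp,
                 MoreArgs = list(table = table))
  df <- data.frame(econ = econ, loc = loc, glob = glob)
  df[stats::complete.cases(df), , drop = FALSE]
}
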