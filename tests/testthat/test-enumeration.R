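test_that("canonical form identifies exactly the hypercube-symmetry orbits", {
  set.seed(31)
  # same orbit -> same key, for explicit transforms
  for (trial in 1:15) {
    K <- sample(2:4, 1); s <- sample(2:min(6, 2^K), 1)
    m <- random_inventory(s, K)
    key <- canonical_form(m)
    m2 <- m[sample(s), rev(seq_len(K)), drop = FALSE]     # rows + column order
    expect_identical(canonical_form(m2), key)
    m3 <- m; m3[, 1] <- -m3[, 1]                          # polarity flip
    expect_identical(canonical_form(m3), key)
  }
  # equal keys <=> same orbit, against brute-force orbit enumeration
  for (trial in 1:10) {
    K <- sample(2:3, 1)
    s <- sample(2:min(5, 2^K), 1)
    a <- random_inventory(s, K); b <- random_inventory(s, K)
    same_orbit <- paste(sort(apply(b, 1, paste, collapse = ",")),
                        collapse = "|") %in% orbit_keys(a)
    expect_equal(canonical_form(a) == canonical_form(b), same_orbit)
  }
  # the two 2-segment geometries on k = 2 are distinct
  d1 <- rbind(c(1, 1), c(-1, 1))    # distance 1 (reducible, but keyable)
  d2 <- rbind(c(1, 1), c(-1, -1))   # distance 2
  expect_false(canonical_form(d1) == canonical_form(d2))
})

test_that("hypercube identities: unique saturated geometry, N_mp/N_im ranges", {
  e83 <- enumerate_geometries(8, 3)
  expect_equal(length(e83$configs), 1)
  expect_equal(e83$stats$n_mp, 12)
  expect_equal(e83$stats$n_im, 0)
  e21 <- enumerate_geometries(2, 1)
  expect_equal(length(e21$configs), 1)
  e84 <- enumerate_geometries(8, 4)
  expect_equal(range(e84$stats$n_mp), c(4, 10))
  expect_setequal(e84$stats$n_im[e84$stats$n_mp == 10], c(8, 10, 12))
  expect_error(enumerate_geometries(9, 3), "impossible")
})

test_that("every enumerated configuration is irreducible with distinct rows", {
  for (sk in list(c(5, 3), c(6, 4), c(10, 4))) {
    en <- enumerate_geometries(sk[1], sk[2])
    for (m in en$configs) {
      expect_equal(anyDuplicated(m), 0)
      # the full feature set must itself be an irreducible spec
      expect_true(any(vapply(find_specs_exact(m)$specs,
                             function(cc) length(cc) == ncol(m), logical(1))))
      # direct check: every column carries a minimal pair
      d <- phonogeom:::hamming_matrix(m)
      pairs <- which(d == 1 & upper.tri(d), arr.ind = TRUE)
      cols <- unique(unlist(lapply(seq_len(nrow(pairs)), function(r) {
        which(m[pairs[r, 1], ] != m[pairs[r, 2], ])
      })))
      expect_setequal(cols, seq_len(ncol(m)))
    }
  }
})

test_that("sampled enumeration reproduces exhaustive attainable values on small keys", {
  for (sk in list(c(4, 3), c(6, 3), c(8, 3), c(6, 4), c(7, 4))) {
    s <- sk[1]; k <- sk[2]
    ex <- enumerate_geometries(s, k, mode = "exhaustive")
    sm <- enumerate_geometries(s, k, mode = "sampled", sample_size = 5000,
                               max_attempts = 60000, seed = 7)
    expect_setequal(unique(sm$stats$n_mp), unique(ex$stats$n_mp))
    for (mv in unique(ex$stats$n_mp)) {
      expect_setequal(unique(sm$stats$n_im[sm$stats$n_mp == mv]),
                      unique(ex$stats$n_im[ex$stats$n_mp == mv]))
    }
  }
})

test_that("rank tables union attested values and score by normalized rank", {
  att <- data.frame(s = 8, k = 4, n_mp = c(4, 10, 10), n_im = c(24, 8, 12))
  tab <- build_rank_tables(att, seed = 2)
  vals <- tab$mp[["8:4"]]
  expect_equal(vals, sort(unique(vals)))
  expect_equal(range(vals), c(4, 10))
  expect_equal(loc_score(4, 8, 4, tab), 0)
  expect_equal(loc_score(10, 8, 4, tab), 1)
  # glob ranks descend: most imbalanced -> 0, most balanced -> 1
  expect_equal(tab$im[["8:4:10"]], c(8, 10, 12))
  expect_equal(glob_score(12, 8, 4, 10, tab), 0)
  expect_equal(glob_score(10, 8, 4, 10, tab), 0.5)
  expect_equal(glob_score(8, 8, 4, 10, tab), 1)
  # single attainable value -> omitted
  att2 <- data.frame(s = 8, k = 3, n_mp = 12, n_im = 0)
  tab2 <- build_rank_tables(att2, seed = 2)
  expect_true(is.na(loc_score(12, 8, 3, tab2)))
  expect_true(is.na(glob_score(0, 8, 3, 12, tab2)))
  # unknown key or value -> error
  expect_error(loc_score(5, 9, 4, tab), "no rank-table entry")
  expect_error(loc_score(11, 8, 4, tab), "not in the attainable list")
})

test_that("loc is increasing in N_mp and glob decreasing in N_im within strata", {
  att <- data.frame(s = 8, k = 4, n_mp = 6, n_im = 8)
  tab <- build_rank_tables(att, seed = 3)
  mp_vals <- tab$mp[["8:4"]]
  locs <- vapply(mp_vals, loc_score, numeric(1), s = 8, k = 4, table = tab)
  expect_true(all(diff(locs) > 0))
  for (mv in mp_vals) {
    iv <- tab$im[[phonogeom:::skm_key(8, 4, mv)]]
    if (length(iv) < 2) next
    globs <- vapply(iv, glob_score, numeric(1), s = 8, k = 4, n_mp = mv,
                    table = tab)
    expect_true(all(diff(globs) < 0))
    expect_true(all(globs >= 0 & globs <= 1))
  }
})

test_that("rank tables serialize to JSON and back", {
  att <- data.frame(s = c(8, 6), k = c(4, 3), n_mp = c(6, 5), n_im = c(8, 4))
  tab <- build_rank_tables(att, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_rank_table(tab, path)
  tab2 <- read_rank_table(path)
  expect_equal(tab2$mp, tab$mp)
  expect_equal(tab2$im, tab$im)
  expect_equal(loc_score(6, 8, 4, tab2), loc_score(6, 8, 4, tab))
})

test_that("inventory scoring takes medians over variants with omission rules", {
  # the saturated 3-cube: econ 1, loc and glob omitted (fully determined)
  cube <- phonogeom:::cube_vertices(3)
  inv <- encoded_inventory("cube", "whole", cube)
  specs <- find_specs_exact(inv)
  att <- variant_stats(specs, inv)
  tab <- build_rank_tables(att, seed = 5)
  sc <- score_inventory(specs, inv, tab)
  expect_equal(sc$econ, 1)
  expect_true(is.na(sc$loc)); expect_true(is.na(sc$glob))
  expect_equal(sc$loc_omit, "single_attainable_value")
  # two-segment inventory: p = 1, econ undefined
  two <- encoded_inventory("two", "whole", rbind(c(1, 1), c(-1, 1)))
  sp2 <- find_specs_exact(two)
  tab2 <- build_rank_tables(variant_stats(sp2, two), seed = 5)
  sc2 <- score_inventory(sp2, two, tab2)
  expect_true(is.na(sc2$econ))
  expect_equal(sc2$econ_omit, "p_equals_1")
  # median over two defined variant scores
  fake_specs <- structure(list(id = "x", specs = list(c(1, 2), c(3, 4)),
                               sizes = c(2, 2), p = 2, exact = TRUE,
                               n_variants = 2), class = "spec_set")
  m <- rbind(c(1, 1, 1, 1), c(-1, 1, -1, 1), c(-1, -1, 1, -1))
  invx <- encoded_inventory("x", "whole", m)
  attx <- rbind(variant_stats(fake_specs, invx),
                data.frame(s = 3, k = 2, n_mp = c(0, 1, 2, 3),
                           n_im = c(3, 1, 1, 3)))
  tabx <- build_rank_tables(attx, seed = 6)
  scx <- score_inventory(fake_specs, invx, tabx)
  vs <- variant_stats(fake_specs, invx)
  per <- vapply(seq_len(2), function(i) loc_score(vs$n_mp[i], 3, 2, tabx),
                numeric(1))
  expect_equal(scx$loc, median(per))
})
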