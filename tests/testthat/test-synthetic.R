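test_that("synthetic feature systems have the requested shape and weights", {
  cfg <- synth_config(K = 6, pool_size = 30, zipf_exponent = 1.2, seed = 10)
  fs <- gen_feature_system(cfg)
  expect_equal(dim(fs$matrix), c(30, 6))
  expect_equal(anyDuplicated(fs$matrix), 0)
  w <- attr(fs, "weights")
  expect_equal(length(w), 30)
  expect_true(all(diff(w) <= 0))          # Zipf weights decay in pool order
  expect_equal(sum(w), 1)
  # zipf_exponent 0 gives equal weights; full-cube pool is the cube
  fs0 <- gen_feature_system(synth_config(K = 3, pool_size = 8,
                                         zipf_exponent = 0, seed = 1))
  expect_true(all(attr(fs0, "weights") == 1 / 8))
  expect_setequal(apply(fs0$matrix, 1, paste, collapse = ","),
                  apply(phonogeom:::cube_vertices(3), 1, paste, collapse = ","))
  # scale of a large typological database is reachable
  big <- gen_feature_system(synth_config(K = 23, pool_size = 688, seed = 2))
  expect_equal(dim(big$matrix), c(688, 23))
  expect_equal(anyDuplicated(big$matrix), 0)
})

test_that("databases are reproducible and sizes respect the size law", {
  cfg <- synth_config(K = 7, pool_size = 50, n_languages = 40,
                      size_range = c(3, 15), seed = 21)
  db1 <- gen_database(cfg)
  db2 <- gen_database(cfg)
  expect_identical(db1$fs$matrix, db2$fs$matrix)
  expect_identical(lapply(db1$inventories, `[[`, "segments"),
                   lapply(db2$inventories, `[[`, "segments"))
  expect_equal(length(db1$inventories), 40)
  sizes <- lengths(lapply(db1$inventories, `[[`, "segments"))
  expect_true(all(sizes >= 3 & sizes <= 15))
})

test_that("written databases round-trip through the io parsers", {
  cfg <- synth_config(K = 5, pool_size = 20, n_languages = 10,
                      size_range = c(3, 8), seed = 33, duplicate_rate = 0.3)
  db <- gen_database(cfg)
  dir <- withr::local_tempdir()
  write_database(db, dir)
  fs2 <- parse_feature_table(file.path(dir, "features.tsv"))
  invs2 <- parse_inventory_table(file.path(dir, "inventories.csv"))
  expect_identical(fs2$matrix, db$fs$matrix)
  expect_identical(lapply(invs2, `[[`, "segments"),
                   lapply(db$inventories, `[[`, "segments"))
})

test_that("duplicate injection hits the recorded languages and only those", {
  cfg <- synth_config(K = 8, pool_size = 60, n_languages = 60,
                      size_range = c(3, 10), duplicate_rate = 0.25, seed = 9)
  db <- gen_database(cfg)
  res <- filter_encodable(db$inventories, db$fs)
  expect_setequal(res$rejected, db$truth$duplicated_language_ids)
  # rate is in the right ballpark (binomial 3-sigma around 0.25)
  phat <- length(res$rejected) / 60
  expect_lt(abs(phat - 0.25), 3 * sqrt(0.25 * 0.75 / 60))
})

test_that("with zero betas generation matches the segment-control law", {
  # same pool, same weights: the first draw of gen_language must follow
  # the same distribution as a weighted segment control draw
  cfg <- synth_config(K = 4, pool_size = 2, n_languages = 1,
                      size_range = c(2, 2), zipf_exponent = 1, seed = 1)
  fs <- gen_feature_system(cfg)
  w <- attr(fs, "weights")                 # weights 1 : 1/2, ratio 2:1
  n <- 3000
  set.seed(42)
  firsts <- vapply(seq_len(n), function(i) {
    gen_language(cfg, fs, size = 2)$segments[1]
  }, "")
  phat <- mean(firsts == rownames(fs$matrix)[1])
  ci <- binom.test(sum(firsts == rownames(fs$matrix)[1]), n,
                   p = w[1])$conf.int
  expect_true(w[1] >= ci[1] && w[1] <= ci[2])
})

test_that("a strong minimal-pair bias drives languages toward cube-dense sets", {
  # on the full 3-cube pool with equal weights, beta_loc >> 0 makes an
  # 4-segment language carry far more minimal pairs than unbiased draws
  cfg0 <- synth_config(K = 3, pool_size = 8, zipf_exponent = 0,
                       size_range = c(4, 4), beta_loc = 0, seed = 5)
  cfgb <- synth_config(K = 3, pool_size = 8, zipf_exponent = 0,
                       size_range = c(4, 4), beta_loc = 8, seed = 5)
  fs <- gen_feature_system(cfg0)
  set.seed(11)
  mp0 <- mean(vapply(1:150, function(i) {
    iv <- gen_language(cfg0, fs, size = 4)
    count_minimal_pairs(fs$matrix[iv$segments, ])
  }, numeric(1)))
  set.seed(11)
  mpb <- mean(vapply(1:150, function(i) {
    iv <- gen_language(cfgb, fs, size = 4)
    count_minimal_pairs(fs$matrix[iv$segments, ])
  }, numeric(1)))
  expect_gt(mpb, mp0 + 0.5)
  # in the greedy limit the 4-segment set approaches the 4 edges of a face
  expect_gt(mpb, 3.5)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(K = 3, pool_size = 9), "exceeds")
  expect_error(synth_config(beta_loc = -1), "betas")
  expect_error(synth_config(duplicate_rate = 2), "duplicate_rate")
})
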