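test_that("feature tables round-trip through write and parse", {
  fs <- tiny_feature_system()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(fs, path)
  fs2 <- parse_feature_table(path)
  expect_identical(fs2$features, fs$features)
  expect_identical(fs2$matrix, fs$matrix)
  # and a large synthetic system survives the round trip
  big <- gen_feature_system(synth_config(K = 23, pool_size = 120, seed = 4))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(big, path2)
  big2 <- parse_feature_table(path2)
  expect_identical(big2$matrix, big$matrix)
  expect_equal(length(big2$features), 23)
})

test_that("parse errors identify the offending cell or label", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("segment\tf1\tf2", "a\t+\t-", "b\t0\t+"), path)
  expect_error(parse_feature_table(path), "unknown feature value '0'.*'b'.*'f1'")
  writeLines(c("segment\tf1", "a\t+", "a\t-"), path)
  expect_error(parse_feature_table(path), "duplicate segment label")
})

test_that("the smallest valid table parses", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("segment,f1", "a,+", "b,-"), path)
  fs <- parse_feature_table(path)
  expect_equal(dim(fs$matrix), c(2, 1))
  expect_equal(unname(fs$matrix[, 1]), c(1, -1))
})

test_that("subsystem extraction filters by the rule and partitions with its complement", {
  fs <- tiny_feature_system()
  inv <- language_inventory("L1", c("p", "t", "a", "i", "u"))
  rules <- default_subsystem_rules()
  vow <- extract_subsystem(inv, rules$vowel, fs)
  con <- extract_subsystem(inv, rules$consonant, fs)
  expect_setequal(vow$segments, c("a", "i", "u"))
  expect_setequal(con$segments, c("p", "t"))
  expect_equal(vow$subsystem, "vowel")
  # empty conjunction is the identity
  whole <- extract_subsystem(inv, rules$whole, fs)
  expect_setequal(whole$segments, inv$segments)
  # vowel + consonant partition every whole inventory of a synthetic db
  db <- gen_database(synth_config(K = 6, pool_size = 40, n_languages = 15,
                                  size_range = c(3, 12), seed = 8))
  for (iv in db$inventories) {
    v <- extract_subsystem(iv, rules$vowel, db$fs)
    cns <- extract_subsystem(iv, rules$consonant, db$fs)
    got <- c(if (!is.null(v)) v$segments, if (!is.null(cns)) cns$segments)
    expect_setequal(got, iv$segments)
  }
})

test_that("encodability filter rejects duplicate encodings per subsystem and is idempotent", {
  fs <- tiny_feature_system()
  bad <- language_inventory("Lbad", c("p", "b", "a"))   # p/b share a vector
  good <- language_inventory("Lok", c("p", "t", "a"))
  res <- filter_encodable(list(bad, good), fs)
  expect_equal(res$rejected, "Lbad")
  expect_equal(length(res$inventories), 1)
  expect_equal(res$inventories[[1]]$language_id, "Lok")
  expect_equal(res$inventories[[1]]$s, 3)
  # but Lbad survives for the vowel subsystem, where p and b are absent
  rules <- default_subsystem_rules()
  vow <- extract_subsystem(bad, rules$vowel, fs)
  expect_error(filter_encodable(list(vow), fs)$inventories, NA)
  # single-segment subsystems are dropped as undersized, not rejected
  resv <- filter_encodable(list(vow), fs)
  expect_equal(resv$undersized, "Lbad")
  # idempotence: re-encoding survivors changes nothing
  surv <- lapply(res$inventories, function(e) {
    language_inventory(e$language_id, rownames(e$matrix), e$subsystem)
  })
  res2 <- filter_encodable(surv, fs)
  expect_equal(length(res2$inventories), length(res$inventories))
  expect_equal(res2$rejected, character(0))
  for (e in res2$inventories) expect_equal(anyDuplicated(e$matrix), 0)
})

test_that("combo frequencies count languages per combination and pool feature values", {
  m1 <- rbind(c(1, 1), c(-1, 1))
  m2 <- rbind(c(1, 1), c(-1, -1))
  e1 <- encoded_inventory("L1", "whole", m1)
  e2 <- encoded_inventory("L2", "whole", m2)
  cf <- combo_frequencies(list(e1, e2))
  expect_equal(cf$n_languages, 2)
  key <- apply(cf$combos, 1, paste, collapse = ",")
  expect_equal(cf$counts[key == "1,1"], 2L)       # shared combo in both
  expect_equal(sum(cf$counts), 4L)                # sum over distinct combos/lang
  expect_equal(unname(cf$plus_prob), c(0.5, 0.75))
  expect_error(combo_frequencies(list()), "empty")
  # single language on K=1 with both values: +1 probability one half
  e3 <- encoded_inventory("L3", "whole", matrix(c(1, -1), ncol = 1))
  expect_equal(unname(combo_frequencies(list(e3))$plus_prob), 0.5)
})
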