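test_that("AUC equals brute-force pair counting, with ties at one half", {
  expect_equal(auc(c(1, 1, 1), c(1, 1)), 0.5)
  expect_equal(auc(c(0.9, 0.8), c(0.5, 0.1)), 1)
  expect_equal(auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  set.seed(88)
  for (trial in 1:25) {
    n1 <- sample(1:50, 1); n2 <- sample(1:50, 1)
    pos <- sample(seq(0, 1, 0.05), n1, replace = TRUE)
    neg <- sample(seq(0, 1, 0.05), n2, replace = TRUE)
    expect_equal(auc(pos, neg), naive_auc(pos, neg))
    # complement symmetry and monotone invariance
    expect_equal(auc(pos, neg) + auc(neg, pos), 1)
    expect_equal(auc(exp(3 * pos), exp(3 * neg)), auc(pos, neg))
  }
  expect_error(auc(numeric(0), 1), "empty")
})

test_that("bootstrap intervals are deterministic, ordered, and collapse under separation", {
  pos <- rnorm(100, 2); neg <- rnorm(100, 0)
  b1 <- bootstrap_auc_ci(pos, neg, n_boot = 300, seed = 9)
  b2 <- bootstrap_auc_ci(pos, neg, n_boot = 300, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$ci_high)
  expect_true(b1$ci_low >= 0 && b1$ci_high <= 1)
  sep <- bootstrap_auc_ci(101:300, 1:100, n_boot = 200, seed = 2)
  expect_equal(sep$ci_low, 1); expect_equal(sep$ci_high, 1)
  expect_error(bootstrap_auc_ci(pos, neg, n_boot = 0), "n_boot")
})

test_that("bootstrap interval covers the true null AUC at roughly the nominal rate", {
  set.seed(321)
  hits <- vapply(1:120, function(r) {
    pos <- rnorm(60); neg <- rnorm(60)
    b <- bootstrap_auc_ci(pos, neg, n_boot = 200, seed = r)
    b$ci_low <= 0.5 && b$ci_high >= 0.5
  }, logical(1))
  # 95% nominal; binomial 3-sigma band around 0.95 for 120 replicates
  expect_gte(mean(hits), 0.85)
})

test_that("summaries report group means and oriented AUC comparisons", {
  set.seed(55)
  groups <- list(
    natural = data.frame(econ = runif(50, 0.4, 1), loc = runif(50, 0.5, 1),
                         glob = runif(50)),
    segment_freq = data.frame(econ = runif(50, 0, 0.6), loc = runif(50, 0, 0.5),
                              glob = runif(50))
  )
  sm <- summarize_scores(groups, n_boot = 200, seed = 4)
  expect_setequal(unique(sm$means$group), names(groups))
  expect_equal(nrow(sm$comparisons), 3)   # one comparison x three statistics
  loc_row <- sm$comparisons[sm$comparisons$statistic == "loc", ]
  expect_gt(loc_row$auc, 0.5)
  # swapped roles give the complementary AUC
  swapped <- summarize_scores(list(natural = groups$segment_freq,
                                   segment_freq = groups$natural),
                              n_boot = 200, seed = 4)
  expect_equal(swapped$comparisons$auc, 1 - sm$comparisons$auc)
  # omitted scores are excluded per statistic, not listwise
  groups$natural$glob[1:10] <- NA
  sm2 <- summarize_scores(groups, n_boot = 50, seed = 1)
  m <- sm2$means
  expect_equal(m$n_omitted[m$group == "natural" & m$statistic == "glob"], 10)
  expect_equal(m$n[m$group == "natural" & m$statistic == "loc"], 50)
})

test_that("external-set comparison draws size-matched natural subsamples", {
  set.seed(77)
  naturals <- data.frame(score = runif(120), size = sample(3:8, 120, TRUE))
  # external set drawn from the same law: AUC distribution centred near 0.5
  ext <- data.frame(score = runif(25), size = sample(3:8, 25, TRUE))
  r <- compare_external_set(ext, naturals, n_draws = 400, seed = 10)
  expect_true(r$ci_low < 0.5 && r$ci_high > 0.5)
  r2 <- compare_external_set(ext, naturals, n_draws = 400, seed = 10)
  expect_identical(r, r2)
  # external scores far below the naturals: interval near [1, 1]
  low <- data.frame(score = ext$score - 10, size = ext$size)
  rlow <- compare_external_set(low, naturals, n_draws = 100, seed = 3)
  expect_equal(rlow$ci_low, 1)
  # unmatched sizes are an error
  bad <- data.frame(score = 0.5, size = 99)
  expect_error(compare_external_set(bad, naturals, n_draws = 10, seed = 1),
               "no natural inventory of size")
})
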