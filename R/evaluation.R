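# ROC/AUC comparison of score distributions.

#' Area under the ROC curve
#'
#' Probability that a randomly chosen score from `pos` exceeds a randomly
#' chosen score from `neg`, ties counted one half — the rank-sum (Mann-
#' Whitney) formulation, identical to the trapezoidal area under the ROC
#' curve over all thresholds.
#'
#' @param pos,neg non-empty numeric vectors of scores.
#' @return real in \[0, 1\].
#' @export
auc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  n1 <- length(pos); n2 <- length(neg)
  if (n1 == 0 || n2 == 0) stop_pg("auc: empty score sample")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' Resamples each group independently with replacement `n_boot` times and
#' reports the percentile interval of the resampled AUCs.
#'
#' @param pos,neg numeric score vectors.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level interval level (default 0.95).
#' @param seed integer seed; the interval is deterministic given it.
#' @return list with `auc`, `ci_low`, `ci_high`, `n_boot`, `level`,
#'   `seed`.
#' @export
bootstrap_auc_ci <- function(pos, neg, n_boot = 1000, level = 0.95, seed = 1) {
  if (n_boot < 1) stop_pg("n_boot must be >= 1")
  if (level <= 0 || level >= 1) stop_pg("level must be in (0, 1)")
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  point <- auc(pos, neg)
  qs <- with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      auc(pos[sample.int(length(pos), replace = TRUE)],
          neg[sample.int(length(neg), replace = TRUE)])
    }, numeric(1))
    stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, type = 7)
  })
  list(auc = point, ci_low = qs[1], ci_high = qs[2],
       n_boot = n_boot, level = level, seed = seed)
}

#' Summarize score distributions across groups
#'
#' Produces the two building blocks of a results table for one subsystem:
#' per-statistic group means (with the count of omitted inventories) and
#' pairwise AUC bootstrap intervals for a set of named comparisons. The
#' AUC is oriented as P(second group > first group), so values above 0.5
#' mean the second-listed group scores higher. Intervals containing 0.5
#' are flagged `"ns"`, intervals entirely below 0.5 are flagged
#' `"reversed"`, others `""`.
#'
#' @param groups named list of score data.frames (columns `econ`, `loc`,
#'   `glob`, as returned by [score_database()]).
#' @param comparisons list of 2-element character vectors
#'   `c(lower, higher)` naming groups to compare; defaults to the
#'   standard natural-vs-control and control-vs-control contrasts present
#'   in `groups`.
#' @param statistics which statistics to summarize.
#' @param n_boot,level,seed bootstrap settings.
#' @return list with data.frames `means` and `comparisons`.
#' @export
summarize_scores <- function(groups,
                             comparisons = NULL,
                             statistics = c("econ", "loc", "glob"),
                             n_boot = 1000, level = 0.95, seed = 1) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  if (is.null(comparisons)) {
    candidates <- list(
      c("segment_freq", "natural"),
      c("segment_uniform", "segment_freq"),
      c("feature_uniform", "feature_freq"),
      c("segment_uniform", "feature_uniform")
    )
    comparisons <- Filter(function(p) all(p %in% names(groups)), candidates)
  }
  means <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(statistics, function(st) {
      v <- groups[[g]][[st]]
      data.frame(group = g, statistic = st,
                 mean = mean(v, na.rm = TRUE),
                 n = sum(!is.na(v)), n_omitted = sum(is.na(v)),
                 stringsAsFactors = FALSE)
    }))
  }))
  comp <- do.call(rbind, lapply(seq_along(comparisons), function(ci) {
    pair <- comparisons[[ci]]
    do.call(rbind, lapply(statistics, function(st) {
      lo <- groups[[pair[1]]][[st]]; hi <- groups[[pair[2]]][[st]]
      if (all(is.na(lo)) || all(is.na(hi))) {
        # a statistic can be omitted for every inventory of a group
        # (e.g. fully determined Loc in very small subsystems)
        return(data.frame(comparison = paste(pair[1], "<", pair[2]),
                          statistic = st, auc = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          flag = "undefined", stringsAsFactors = FALSE))
      }
      b <- bootstrap_auc_ci(hi, lo, n_boot = n_boot, level = level,
                            seed = derive_seed(seed, ci))
      flag <- if (b$ci_low <= 0.5 && b$ci_high >= 0.5) "ns"
              else if (b$ci_high < 0.5) "reversed" else ""
      data.frame(comparison = paste(pair[1], "<", pair[2]), statistic = st,
                 auc = b$auc, ci_low = b$ci_low, ci_high = b$ci_high,
                 flag = flag, stringsAsFactors = FALSE)
    }))
  }))
  list(means = means, comparisons = comp)
}

#' Compare an external inventory set against size-matched natural draws
#'
#' For each of `n_draws` rounds, draws a subsample of natural inventories
#' whose size multiset matches the external set's (one uniformly chosen
#' natural of the same size per external inventory), computes the AUC of
#' natural vs. external scores, and reports the percentile interval of
#' the resulting AUC distribution.
#'
#' @param external data.frame with columns `score`, `size` for the
#'   external inventories.
#' @param naturals data.frame with columns `score`, `size` for the
#'   natural inventories.
#' @param n_draws number of size-matched subsamples (default 10000).
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @return list with `ci_low`, `ci_high`, `median`, `n_draws`, `seed`.
#' @export
compare_external_set <- function(external, naturals, n_draws = 10000,
                                 level = 0.95, seed = 1) {
  stopifnot(all(c("score", "size") %in% colnames(external)),
            all(c("score", "size") %in% colnames(naturals)))
  ext <- external[!is.na(external$score), , drop = FALSE]
  nat <- naturals[!is.na(naturals$score), , drop = FALSE]
  by_size <- split(seq_len(nrow(nat)), nat$size)
  need <- unique(ext$size)
  missing_sz <- setdiff(as.character(need), names(by_size))
  if (length(missing_sz) > 0) {
    stop_pg("no natural inventory of size(s) %s to match the external set",
            paste(missing_sz, collapse = ", "))
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      idx <- vapply(as.character(ext$size), function(sz) {
        cand <- by_size[[sz]]
        if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
      }, integer(1))
      auc(nat$score[idx], ext$score)
    }, numeric(1))
  })
  qs <- stats::quantile(aucs, c((1 - level) / 2, 0.5, 1 - (1 - level) / 2),
                        names = FALSE)
  list(ci_low = qs[1], median = qs[2], ci_high = qs[3],
       n_draws = n_draws, level = level, seed = seed)
}
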