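#' Construct a feature system
#'
#' A feature system is the global encoding of a segment database: an
#' ordered set of binary feature names and, for every segment label, a
#' vector of feature values coded +1 (the "+" value) or -1 (the "-"
#' value). Several labels may share one feature combination (real
#' databases transcribe more sounds than the feature system can tell
#' apart); such collisions are handled per language by
#' [filter_encodable()].
#'
#' @param features character vector of feature names (length K >= 1).
#' @param segment_matrix numeric matrix of +1/-1 with one row per segment
#'   label (rownames) and one column per feature.
#' @return An object of class `feature_system` with elements `features`
#'   and `matrix`.
#' @export
feature_system <- function(features, segment_matrix) {
  features <- as.character(features)
  if (length(features) < 1) stop_pg("need at least one feature")
  check_pm1_matrix(segment_matrix, "segment_matrix")
  if (ncol(segment_matrix) != length(features)) {
    stop_pg("segment_matrix must have %d columns", length(features))
  }
  labels <- rownames(segment_matrix)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop_pg("segment_matrix must have unique rownames (segment labels)")
  }
  colnames(segment_matrix) <- features
  structure(
    list(features = features, matrix = segment_matrix),
    class = "feature_system"
  )
}

#' @export
print.feature_system <- function(x, ...) {
  cat(sprintf(
    "Feature system: %d segments x %d features (%d distinct combinations)\n",
    nrow(x$matrix), length(x$features),
    nrow(unique(x$matrix))
  ))
  invisible(x)
}

#' Parse a segment-by-feature table
#'
#' Reads a delimited text file whose first column holds segment labels and
#' whose remaining columns hold binary feature values. Only the symbols in
#' `symbols` are legal cell values; anything else is a hard parse error
#' naming the offending cell, because silently coercing an unexpected
#' value would corrupt every downstream geometry.
#'
#' @param path path to a TSV/CSV file with a header row of feature names.
#' @param sep field separator; defaults to tab for `.tsv` files and comma
#'   otherwise.
#' @param symbols named integer vector mapping cell symbols to +1/-1. The
#'   default accepts ASCII and Unicode minus signs.
#' @return A [feature_system()].
#' @export
parse_feature_table <- function(path, sep = NULL,
                                symbols = c("+" = 1L, "-" = -1L,
                                            "−" = -1L, "–" = -1L)) {
  if (!file.exists(path)) stop_pg("file not found: %s", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  if (ncol(raw) < 2) stop_pg("feature table needs a label column and >= 1 feature")
  labels <- raw[[1]]
  if (anyDuplicated(labels)) {
    stop_pg("duplicate segment label(s): %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  feats <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  coded <- symbols[vals]
  bad <- which(is.na(coded))
  if (length(bad) > 0) {
    b <- bad[1]
    r <- ((b - 1) %% nrow(vals)) + 1
    co <- ((b - 1) %/% nrow(vals)) + 1
    stop_pg("unknown feature value '%s' for segment '%s', feature '%s'",
            vals[r, co], labels[r], feats[co])
  }
  m <- matrix(as.numeric(coded), nrow = nrow(vals), ncol = ncol(vals))
  rownames(m) <- labels
  feature_system(feats, m)
}

#' Write a feature system to disk
#'
#' Inverse of [parse_feature_table()]: writes labels in the first column
#' ("segment") and "+"/"-" cells, so that a written system parses back to
#' an identical structure.
#'
#' @param fs a [feature_system()].
#' @param path output file; `.tsv` implies tab separation.
#' @export
write_feature_table <- function(fs, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  sym <- ifelse(fs$matrix > 0, "+", "-")
  df <- data.frame(segment = rownames(fs$matrix), sym, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("segment", fs$features)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a language inventory
#'
#' @param language_id language identifier.
#' @param segments character vector of segment labels (set semantics;
#'   duplicates are an error).
#' @param subsystem one of `"whole"`, `"consonant"`, `"stop_affricate"`,
#'   `"vowel"` (or any tag produced by a subsystem rule).
#' @return An object of class `language_inventory`.
#' @export
language_inventory <- function(language_id, segments, subsystem = "whole") {
  segments <- as.character(segments)
  if (length(segments) < 1) stop_pg("inventory for %s is empty", language_id)
  if (anyDuplicated(segments)) {
    stop_pg("duplicate segment label(s) in inventory %s", language_id)
  }
  structure(
    list(language_id = as.character(language_id), subsystem = subsystem,
         segments = segments),
    class = "language_inventory"
  )
}

#' Parse a long-format inventory table
#'
#' @param path CSV with columns `language_id` and `segment_label`.
#' @return list of [language_inventory()] objects (subsystem `"whole"`),
#'   in order of first appearance of each language.
#' @export
parse_inventory_table <- function(path) {
  if (!file.exists(path)) stop_pg("file not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("language_id", "segment_label")
  if (!all(need %in% colnames(df))) {
    stop_pg("inventory table must have columns: %s", paste(need, collapse = ", "))
  }
  ids <- unique(df$language_id)
  lapply(ids, function(id) {
    language_inventory(id, unique(df$segment_label[df$language_id == id]))
  })
}

#' Write inventories in long format
#'
#' @param invs list of [language_inventory()] objects.
#' @param path output CSV path.
#' @export
write_inventory_table <- function(invs, path) {
  df <- do.call(rbind, lapply(invs, function(iv) {
    data.frame(language_id = iv$language_id, segment_label = iv$segments,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Subsystem extraction rules
#'
#' A subsystem rule is a named conjunction of (feature, required sign)
#' conditions. The shipped defaults pick out vowels as \[+syllabic\],
#' consonants as \[-syllabic\], and stops/affricates as \[-syllabic,
#' -sonorant, -continuant\]; they are plain data and can be replaced by
#' the caller when a database uses different class definitions.
#'
#' @param name subsystem tag.
#' @param conditions named numeric vector of required signs (+1/-1) keyed
#'   by feature name; may be empty (the rule is then the identity).
#' @return An object of class `subsystem_rule`.
#' @export
subsystem_rule <- function(name, conditions = numeric(0)) {
  if (length(conditions) > 0) {
    if (is.null(names(conditions)) || any(names(conditions) == "")) {
      stop_pg("conditions must be a named vector of +1/-1 signs")
    }
    if (!all(conditions %in% c(-1, 1))) stop_pg("condition signs must be +1/-1")
  }
  structure(list(name = name, conditions = conditions),
            class = "subsystem_rule")
}

#' @rdname subsystem_rule
#' @export
default_subsystem_rules <- function() {
  list(
    whole = subsystem_rule("whole"),
    consonant = subsystem_rule("consonant", c(syllabic = -1)),
    stop_affricate = subsystem_rule(
      "stop_affricate",
      c(syllabic = -1, sonorant = -1, continuant = -1)
    ),
    vowel = subsystem_rule("vowel", c(syllabic = 1))
  )
}

#' Extract a subsystem from a whole inventory
#'
#' Keeps the segments whose feature values satisfy every condition of the
#' rule. An empty conjunction returns the whole inventory retagged. The
#' result may be empty, in which case `NULL` is returned and the caller
#' drops the language for that subsystem.
#'
#' @param inv a [language_inventory()].
#' @param rule a [subsystem_rule()].
#' @param fs the [feature_system()] resolving the labels.
#' @return A [language_inventory()] tagged with the rule's name, or `NULL`
#'   if no segment satisfies the rule.
#' @export
extract_subsystem <- function(inv, rule, fs) {
  missing_lab <- setdiff(inv$segments, rownames(fs$matrix))
  if (length(missing_lab) > 0) {
    stop_pg("unresolvable segment label(s) in %s: %s", inv$language_id,
            paste(missing_lab, collapse = ", "))
  }
  keep <- inv$segments
  if (length(rule$conditions) > 0) {
    miss_f <- setdiff(names(rule$conditions), fs$features)
    if (length(miss_f) > 0) {
      stop_pg("rule '%s' references unknown feature(s): %s", rule$name,
              paste(miss_f, collapse = ", "))
    }
    sub <- fs$matrix[inv$segments, names(rule$conditions), drop = FALSE]
    ok <- colSums(t(sub) == rule$conditions) == length(rule$conditions)
    keep <- inv$segments[ok]
  }
  if (length(keep) == 0) return(NULL)
  language_inventory(inv$language_id, keep, rule$name)
}

#' Apply the encodability filter and encode inventories
#'
#' A language is encodable in the feature system, for a given subsystem,
#' exactly when no two of its segments in that subsystem share a feature
#' vector; languages violating this are removed (their statistics would
#' depend on sounds the encoding cannot distinguish). Filtering is applied
#' independently per subsystem, so a language rejected for its whole
#' inventory can survive for, say, its vowels. Inventories that end up
#' with fewer than two segments are also dropped, since every geometric
#' statistic is undefined below s = 2.
#'
#' @param invs list of [language_inventory()] objects (one subsystem).
#' @param fs the [feature_system()].
#' @return list with `inventories` (list of `encoded_inventory`: fields
#'   `language_id`, `subsystem`, `matrix` with s distinct +1/-1 rows),
#'   `rejected` (ids with duplicate encodings) and `undersized` (ids with
#'   s < 2).
#' @export
filter_encodable <- function(invs, fs) {
  out <- list(); rejected <- character(0); undersized <- character(0)
  for (iv in invs) {
    missing_lab <- setdiff(iv$segments, rownames(fs$matrix))
    if (length(missing_lab) > 0) {
      stop_pg("unresolvable segment label(s) in %s: %s", iv$language_id,
              paste(missing_lab, collapse = ", "))
    }
    m <- fs$matrix[iv$segments, , drop = FALSE]
    if (anyDuplicated(m) > 0) {
      rejected <- c(rejected, iv$language_id)
    } else if (nrow(m) < 2) {
      undersized <- c(undersized, iv$language_id)
    } else {
      out[[length(out) + 1]] <- encoded_inventory(iv$language_id,
                                                  iv$subsystem, m)
    }
  }
  list(inventories = out, rejected = rejected, undersized = undersized)
}

#' Construct an encoded inventory
#'
#' @param language_id language identifier.
#' @param subsystem subsystem tag.
#' @param matrix s x K matrix of +1/-1 with pairwise-distinct rows
#'   (rownames = segment labels, optional).
#' @return object of class `encoded_inventory`.
#' @export
encoded_inventory <- function(language_id, subsystem, matrix) {
  check_pm1_matrix(matrix, "inventory matrix")
  if (nrow(matrix) < 2) stop_pg("encoded inventory needs s >= 2")
  if (anyDuplicated(matrix) > 0) stop_pg("encoded inventory rows must be distinct")
  structure(
    list(language_id = as.character(language_id), subsystem = subsystem,
         matrix = matrix, s = nrow(matrix)),
    class = "encoded_inventory"
  )
}

#' Pooled feature-combination and feature-value frequencies
#'
#' Computes, over a set of encoded inventories of one subsystem, (a) the
#' number of languages containing each attested feature combination (set
#' semantics per language), which drives the frequency-matched random
#' segment controls, and (b) the pooled per-feature probability of the +
#' value across all segment tokens, which drives the frequency-matched
#' random feature controls. Both are computed from the raw encodings, not
#' from reduced (contrastive) representations.
#'
#' @param invs non-empty list of `encoded_inventory` objects.
#' @return object of class `combo_freqs`: `combos` (distinct combination
#'   matrix), `counts` (languages containing each combo), `plus_prob`
#'   (per-feature +1 probability over segment tokens), `n_languages`.
#' @export
combo_frequencies <- function(invs) {
  if (length(invs) == 0) stop_pg("combo_frequencies: empty input")
  keys_per_lang <- lapply(invs, function(iv) {
    apply(iv$matrix, 1, function(r) paste(r, collapse = ""))
  })
  all_keys <- unlist(keys_per_lang, use.names = FALSE)
  uk <- unique(all_keys)
  counts <- integer(length(uk)); names(counts) <- uk
  for (kk in keys_per_lang) {
    u <- unique(kk)
    counts[u] <- counts[u] + 1L
  }
  big <- do.call(rbind, lapply(invs, function(iv) iv$matrix))
  combos <- big[match(uk, all_keys), , drop = FALSE]
  rownames(combos) <- NULL
  plus_prob <- colMeans(big == 1)
  structure(
    list(combos = combos, counts = unname(counts), plus_prob = plus_prob,
         n_languages = length(invs)),
    class = "combo_freqs"
  )
}
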