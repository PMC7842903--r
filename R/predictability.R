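# Derivation of lexical and morphosyntactic probabilities from either
# probability source (cloze response sets or corpus model distributions),
# the logit transform, and the comparison analyses: correlations, the
# cumulative-correlation curve, and per-class summary tables.

#' Logit transform used for all probability predictors
#'
#' `q = 0.5 * ln(p / (1 - p))`. Strictly increasing, zero at `p = 0.5`,
#' antisymmetric around it.
#'
#' @param p Probability strictly inside (0, 1).
#' @return Logit value.
#' @export
logitTransform <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must be strictly inside (0, 1)")
  }
  0.5 * log(p / (1 - p))
}

#' @param q Logit value.
#' @rdname logitTransform
#' @export
invLogitTransform <- function(q) stats::plogis(2 * q)

#' Probability-source entries
#'
#' A source entry carries the probability mass function over candidate
#' continuations for one stimulus position, from either a cloze response set
#' (response shares, with the per-word number of guesses retained for
#' smoothing) or a corpus model distribution (with any truncated tail mass
#' treated as non-matching).
#'
#' @param responses Character vector of cloze responses for one word.
#' @return A list with `kind`, `mass`, and smoothing metadata.
#' @export
clozeEntry <- function(responses) {
  n <- length(responses)
  if (n < 1L) stop("response set must be non-empty")
  responses <- normalizeResponse(responses)
  mass <- table(responses) / n
  list(kind = "cloze", mass = setNames(as.numeric(mass), names(mass)),
       n_guesses = n)
}

#' @param dist A `prob_distribution` (or a named numeric vector of
#'   probabilities, taken as-is with zero tail mass).
#' @rdname clozeEntry
#' @export
corpusEntry <- function(dist) {
  if (inherits(dist, "prob_distribution")) {
    list(kind = "corpus", mass = dist$mass, tail_mass = dist$tail_mass)
  } else {
    list(kind = "corpus", mass = dist, tail_mass = max(0, 1 - sum(dist)))
  }
}

.CORPUS_FLOOR <- 1e-9

# keep an aggregated probability strictly inside (0, 1), using the cloze
# smoothing rule or the corpus floor depending on the source
.bound_source_prob <- function(p, entry) {
  if (entry$kind == "cloze") {
    n <- entry$n_guesses
    min(max(p, smoothZero(n)), .cap_one(n))
  } else {
    min(max(p, .CORPUS_FLOOR), 1 - .CORPUS_FLOOR)
  }
}

# vectorized candidate matching over the lexicon: which forms in `forms`
# have an analysis whose (class, value) signature matches the target's
.matching_forms <- function(forms, target_analyses, lexicon,
                            feature = NULL) {
  tab <- lexicon$tab
  known <- forms %in% names(lexicon$index)
  if (is.null(feature)) {
    classes <- unique(target_analyses$word_class)
    ok_forms <- unique(tab$form[tab$word_class %in% classes])
    (forms %in% ok_forms) | (!known & "other" %in% classes)
  } else {
    tv <- target_analyses[!is.na(target_analyses[[feature]]), ]
    pairs <- unique(paste(tv$word_class, tv[[feature]]))
    keep <- !is.na(tab[[feature]]) &
      paste(tab$word_class, tab[[feature]]) %in% pairs
    forms %in% unique(tab$form[keep])  # unknown forms carry no features
  }
}

#' Word-class probability of a target
#'
#' Sums the probability mass of all candidate continuations whose analysis
#' set shares a word class with the target (permissive over ambiguity), then
#' bounds the result away from 0 and 1 with the source's smoothing rule
#' (cloze: `1/(2n)` and `1 - 1/(2n)`; corpus: floor `1e-9`).
#'
#' @param entry A [clozeEntry()] or [corpusEntry()].
#' @param target_analyses Analysis set of the target word (>= 1 row).
#' @param lexicon A `morph_lexicon` used to tag candidate forms.
#' @return Probability strictly inside (0, 1).
#' @export
classProbability <- function(entry, target_analyses, lexicon) {
  stopifnot(nrow(target_analyses) >= 1L)
  m <- .matching_forms(names(entry$mass), target_analyses, lexicon)
  .bound_source_prob(sum(entry$mass[m]), entry)
}

#' Morphological-feature probability of a target
#'
#' Sums the mass of candidates that match the target on `feature`
#' (class-conditioned and permissive, see [featureMatch()]). The denominator
#' is the total candidate mass, not the mass within the target's word class;
#' set `renormalize = TRUE` to divide by the class-matching mass instead.
#'
#' @inheritParams classProbability
#' @param feature Feature name; the target must define it in >= 1 analysis.
#' @param renormalize Renormalize within the target's word class?
#' @return Probability strictly inside (0, 1).
#' @export
featureProbability <- function(entry, target_analyses, feature, lexicon,
                               renormalize = FALSE) {
  stopifnot(nrow(target_analyses) >= 1L)
  if (!feature %in% names(morphFeatures())) {
    stop("unknown feature name: ", feature)
  }
  if (all(is.na(target_analyses[[feature]]))) {
    stop("target does not define feature '", feature, "'")
  }
  m <- .matching_forms(names(entry$mass), target_analyses, lexicon, feature)
  p <- sum(entry$mass[m])
  if (renormalize) {
    cls <- .matching_forms(names(entry$mass), target_analyses, lexicon)
    denom <- sum(entry$mass[cls])
    p <- if (denom > 0) p / denom else 0
  }
  .bound_source_prob(p, entry)
}

#' Correlate cloze and corpus logit probabilities
#'
#' Pearson correlations are computed on logit-transformed values; Spearman is
#' rank-based, so either scale may be passed. Under `zero_policy = "drop"`,
#' pairs whose cloze probability was smoothed from zero are removed;
#' `"smooth"` keeps them.
#'
#' @param q_cloze,q_corpus Numeric vectors of logit-transformed
#'   probabilities.
#' @param method `"pearson"` or `"spearman"`.
#' @param zero_policy `"drop"` or `"smooth"`.
#' @param smoothed Logical vector flagging cloze-smoothed records (required
#'   for `"drop"`).
#' @return Correlation coefficient.
#' @export
correlatePredictability <- function(q_cloze, q_corpus,
                                    method = c("pearson", "spearman"),
                                    zero_policy = c("drop", "smooth"),
                                    smoothed = NULL) {
  method <- match.arg(method)
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(q_cloze) == length(q_corpus))
  if (zero_policy == "drop") {
    if (is.null(smoothed)) stop("zero_policy 'drop' needs 'smoothed' flags")
    keep <- !as.logical(smoothed)
    q_cloze <- q_cloze[keep]
    q_corpus <- q_corpus[keep]
  }
  if (length(q_cloze) < 3L) stop("need >= 3 pairs after policy application")
  stats::cor(q_cloze, q_corpus, method = method)
}

#' Cumulative correlation curve over cloze-probability thresholds
#'
#' For each threshold `t`, the Pearson correlation (on logits, smoothed zeros
#' dropped) over all words with raw cloze probability below `t`. Thresholds
#' leaving fewer than 3 pairs are omitted.
#'
#' @param p_cloze Raw cloze probabilities.
#' @param q_cloze,q_corpus Logit-transformed probabilities.
#' @param smoothed Logical cloze-smoothing flags.
#' @param thresholds Increasing grid inside (0, 1].
#' @return Data frame with columns `threshold`, `pearson`, `n`.
#' @export
cumulativeCorrelationCurve <- function(p_cloze, q_cloze, q_corpus, smoothed,
                                       thresholds = seq(0.1, 1, by = 0.1)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  out <- lapply(thresholds, function(t) {
    sel <- !smoothed & p_cloze < t
    if (sum(sel) < 3L) return(NULL)
    data.frame(threshold = t,
               pearson = stats::cor(q_cloze[sel], q_corpus[sel]),
               n = sum(sel))
  })
  do.call(rbind, out)
}

.CONTENT_CLASSES <- c("noun", "verb_finite", "verb_infinitive",
                      "adjective", "adverb", "numeral")
.FUNCTION_CLASSES <- c("personal_pronoun", "preposition", "conjunction",
                       "particle")

#' Per-class summary of cloze and corpus probabilities
#'
#' Means, standard errors, and per-class Pearson correlations (on logits) of
#' a probability column pair, with content-word, function-word and overall
#' rollups.
#'
#' @param tab Data frame with columns `word_class` and the two probability
#'   columns.
#' @param cloze_col,corpus_col Names of the probability columns to summarize.
#' @return Data frame with one row per class plus rollup rows.
#' @export
summarizeByClass <- function(tab, cloze_col = "p_class_cloze",
                             corpus_col = "p_class_corpus") {
  one <- function(rows, label) {
    pc <- tab[[cloze_col]][rows]
    pm <- tab[[corpus_col]][rows]
    r <- if (length(pc) >= 3L && stats::sd(pc) > 0 && stats::sd(pm) > 0) {
      stats::cor(logitTransform(pc), logitTransform(pm))
    } else NA_real_
    data.frame(group = label, n_words = length(pc),
               mean_cloze = mean(pc),
               se_cloze = if (length(pc) > 1L) stats::sd(pc) / sqrt(length(pc)) else 0,
               mean_corpus = mean(pm),
               se_corpus = if (length(pm) > 1L) stats::sd(pm) / sqrt(length(pm)) else 0,
               pearson = r, stringsAsFactors = FALSE)
  }
  classes <- intersect(c(.CONTENT_CLASSES, .FUNCTION_CLASSES, "other"),
                       unique(tab$word_class))
  rows <- lapply(classes, function(cl) one(tab$word_class == cl, cl))
  roll <- list()
  if (any(tab$word_class %in% .CONTENT_CLASSES)) {
    roll <- c(roll, list(one(tab$word_class %in% .CONTENT_CLASSES,
                             "all_content_words")))
  }
  if (any(tab$word_class %in% .FUNCTION_CLASSES)) {
    roll <- c(roll, list(one(tab$word_class %in% .FUNCTION_CLASSES,
                             "all_function_words")))
  }
  roll <- c(roll, list(one(tab$word_class %in%
                             c(.CONTENT_CLASSES, .FUNCTION_CLASSES),
                           "all_words")))
  do.call(rbind, c(rows, roll))
}

# features coded for each target class
.target_features <- function(analyses) {
  cls <- analyses$word_class
  if ("noun" %in% cls) {
    c("gender", "number", "case")
  } else if ("verb_finite" %in% cls) {
    f <- c("tense", "number", "person", "gender")
    f[vapply(f, function(x) any(!is.na(analyses[[x]])), logical(1))]
  } else {
    character(0)
  }
}

#' Per-word predictability table from both sources
#'
#' For every stimulus word, derives the lexical, word-class, and
#' morphological-feature probabilities (with their logits) from the cloze
#' responses and from a corpus distribution provider. Feature probabilities
#' are coded for noun targets (gender, number, case) and finite-verb targets
#' (tense, number, and person or gender depending on tense).
#'
#' @param stimuli Stimulus data frame (`sentence_id`, `position`, `form`,
#'   `is_first`, `is_last`).
#' @param responses Cloze response data frame (see [aggregateCloze()]), or
#'   `NULL` to skip the cloze source.
#' @param provider A distribution provider (see [nextDistribution()]), or
#'   `NULL` to skip the corpus source.
#' @param lexicon A `morph_lexicon`.
#' @param renormalize Passed to [featureProbability()].
#' @return Data frame, one row per stimulus word, with `p_*`/`q_*` columns
#'   per source, the target's word class and tense, and the cloze smoothing
#'   flag.
#' @export
predictabilityTable <- function(stimuli, responses = NULL, provider = NULL,
                                lexicon, renormalize = FALSE) {
  feats <- names(morphFeatures())
  out <- vector("list", nrow(stimuli))
  resp_key <- if (!is.null(responses)) {
    paste(responses$sentence_id, responses$position)
  }
  for (i in seq_len(nrow(stimuli))) {
    form <- tolower(stimuli$form[i])
    analyses <- analyze(form, lexicon)
    tf <- .target_features(analyses)
    row <- list(sentence_id = stimuli$sentence_id[i],
                position = stimuli$position[i],
                target = form,
                word_class = analyses$word_class[1L],
                target_tense = analyses$tense[1L],
                is_first = as.logical(stimuli$is_first[i]),
                is_last = as.logical(stimuli$is_last[i]))
    sources <- list()
    if (!is.null(responses)) {
      resp <- responses$response[resp_key ==
                                   paste(row$sentence_id, row$position)]
      if (length(resp) == 0L) {
        stop("no cloze responses for sentence ", row$sentence_id,
             " position ", row$position)
      }
      entry <- clozeEntry(resp)
      rec <- lexicalProbability(resp, form)
      row$n_guesses <- rec$n_guesses
      row$smoothed <- rec$smoothed
      row$p_cloze <- rec$p_lexical
      sources$cloze <- entry
    }
    if (!is.null(provider)) {
      dist <- if (inherits(provider, "table_provider")) {
        nextDistribution(provider, sentence_id = row$sentence_id,
                         position = row$position)
      } else if (is.function(provider)) {
        provider(NULL, row$sentence_id, row$position)
      } else {
        ctx <- stimuli$form[stimuli$sentence_id == row$sentence_id &
                              stimuli$position < row$position]
        nextDistribution(provider, tolower(ctx))
      }
      entry <- corpusEntry(dist)
      p <- entry$mass[form]
      row$p_corpus <- .bound_source_prob(if (is.na(p)) 0 else p, entry)
      sources$corpus <- entry
    }
    for (src in names(sources)) {
      entry <- sources[[src]]
      row[[paste0("q_", src)]] <-
        logitTransform(.bound_source_prob(row[[paste0("p_", src)]], entry))
      pc <- classProbability(entry, analyses, lexicon)
      row[[paste0("p_class_", src)]] <- pc
      row[[paste0("q_class_", src)]] <- logitTransform(pc)
      for (f in feats) {
        val <- if (f %in% tf) {
          featureProbability(entry, analyses, f, lexicon,
                             renormalize = renormalize)
        } else NA_real_
        row[[paste0("p_", f, "_", src)]] <- val
        row[[paste0("q_", f, "_", src)]] <-
          if (is.na(val)) NA_real_ else logitTransform(val)
      }
    }
    out[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
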