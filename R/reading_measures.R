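# Fixation-duration measures (SFD, FFD, GD, TT) from fixation-level records,
# the word-exclusion rules, and assembly of the per-(participant, word)
# analysis table with all predictors.

#' Fixation-duration measures for one trial
#'
#' From the fixation sequence of a single (participant, sentence) trial,
#' derives per word: first fixation duration (FFD, the duration of the first
#' fixation on the word), gaze duration (GD, the sum of the maximal initial
#' run of consecutive fixations on the word — first pass ends at the first
#' fixation on any other word, regardless of direction), total reading time
#' (TT, the sum of all fixations on the word), and single fixation duration
#' (SFD, defined iff the word received exactly one fixation in the whole
#' trial, in which case SFD = FFD = GD = TT). Unfixated words have all
#' measures undefined.
#'
#' @param fixations Data frame for one trial, sorted by `fixation_index`,
#'   with columns `fixation_index`, `word_position`, `duration_ms`, and
#'   optionally `landing_char` and `saccade_amp_char`.
#' @param n_words Number of words in the sentence (defaults to the largest
#'   fixated position).
#' @return Data frame with one row per word position: `position`, `fixated`,
#'   `n_fixations`, `SFD`, `FFD`, `GD`, `TT`, `landing_first`,
#'   `saccade_amp_first`.
#' @examples
#' fx <- data.frame(fixation_index = 1:3, word_position = c(1, 1, 2),
#'                  duration_ms = c(200, 250, 100))
#' computeMeasures(fx)
#' @export
computeMeasures <- function(fixations, n_words = NULL) {
  if (nrow(fixations) > 0L) {
    if (is.unsorted(fixations$fixation_index, strictly = TRUE)) {
      stop("fixations must be sorted by strictly increasing fixation_index")
    }
    if (any(fixations$duration_ms <= 0)) {
      stop("fixation durations must be positive")
    }
  }
  if (is.null(n_words)) n_words <- max(fixations$word_position, 0L)
  has_land <- "landing_char" %in% names(fixations)
  has_amp <- "saccade_amp_char" %in% names(fixations)
  out <- data.frame(position = seq_len(n_words), fixated = FALSE,
                    n_fixations = 0L, SFD = NA_real_, FFD = NA_real_,
                    GD = NA_real_, TT = NA_real_,
                    landing_first = NA_real_, saccade_amp_first = NA_real_)
  wp <- fixations$word_position
  for (w in unique(wp)) {
    idx <- which(wp == w)
    first <- idx[1L]
    # first-pass window: maximal initial run of consecutive fixations
    run_len <- 1L
    while (first + run_len <= nrow(fixations) &&
           wp[first + run_len] == w) {
      run_len <- run_len + 1L
    }
    dur <- fixations$duration_ms
    out$fixated[w] <- TRUE
    out$n_fixations[w] <- length(idx)
    out$FFD[w] <- dur[first]
    out$GD[w] <- sum(dur[first:(first + run_len - 1L)])
    out$TT[w] <- sum(dur[idx])
    if (length(idx) == 1L) out$SFD[w] <- dur[first]
    if (has_land) out$landing_first[w] <- fixations$landing_char[first]
    if (has_amp) out$saccade_amp_first[w] <- fixations$saccade_amp_char[first]
  }
  out
}

#' Fixation-duration measures for a full fixation table
#'
#' @param fixations Data frame with columns `participant_id`, `sentence_id`,
#'   `fixation_index`, `word_position`, `duration_ms`, and optionally
#'   `landing_char`, `saccade_amp_char`.
#' @param stimuli Stimulus data frame, used to supply each sentence's length.
#' @return Data frame with one row per (participant, sentence, position).
#' @export
computeMeasuresAll <- function(fixations, stimuli) {
  sent_len <- tapply(stimuli$position, stimuli$sentence_id, max)
  trials <- split(fixations,
                  list(fixations$participant_id, fixations$sentence_id),
                  drop = TRUE)
  out <- lapply(trials, function(tr) {
    tr <- tr[order(tr$fixation_index), , drop = FALSE]
    m <- computeMeasures(tr,
                         n_words = sent_len[[as.character(tr$sentence_id[1L])]])
    m$participant_id <- tr$participant_id[1L]
    m$sentence_id <- tr$sentence_id[1L]
    m
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Word-exclusion rules
#'
#' The correlation stage drops sentence-initial words (no context for them in
#' the cloze task); the eyetracking stage drops both sentence-initial words
#' (forced first fixation position) and sentence-final words (wrap-up
#' effects).
#'
#' @param stimuli Stimulus data frame with `is_first`/`is_last` flags.
#' @param stage `"correlation"` or `"eyetracking"`.
#' @return The included subset of `stimuli`.
#' @export
applyExclusions <- function(stimuli, stage = c("correlation", "eyetracking")) {
  stage <- match.arg(stage)
  keep <- !as.logical(stimuli$is_first)
  if (stage == "eyetracking") keep <- keep & !as.logical(stimuli$is_last)
  stimuli[keep, , drop = FALSE]
}

#' Log word frequency with a zero floor
#'
#' Base-10 logarithm of frequency per million, flooring zero (and missing)
#' counts at 0.5 per million.
#'
#' @param per_million Numeric frequency-per-million values.
#' @return `log10(pmax(per_million, 0.5))`.
#' @export
logFrequency <- function(per_million) {
  per_million[is.na(per_million)] <- 0
  log10(pmax(per_million, 0.5))
}

# heuristic base-form flag: nominative-singular noun reading, infinitive, or
# a featureless class
.is_base_form <- function(form, lexicon) {
  a <- analyze(form, lexicon)
  any((a$word_class == "noun" & !is.na(a$case) & a$case == "nom" &
         !is.na(a$number) & a$number == "sg") |
        a$word_class %in% c("verb_infinitive", "adverb", "preposition",
                            "conjunction", "particle", "other"))
}

#' Assemble the per-(participant, word) analysis table
#'
#' Joins fixation measures, predictability records, and word frequencies into
#' one row per (participant, dependent word). Dependent words are the
#' eyetracking-stage inclusions (neither sentence-initial nor final);
#' neighbour predictors (`*_m1`, `*_p1`) use the raw adjacent positions, so
#' excluded words still serve as neighbours. Word lengths are centered and
#' scaled over the included rows only; probability predictors enter as
#' logits.
#'
#' @param measures Output of [computeMeasuresAll()].
#' @param predictability Output of [predictabilityTable()] covering every
#'   stimulus position (including sentence-initial words, which are needed as
#'   neighbours).
#' @param frequencies Data frame with columns `form` and `per_million`.
#' @param stimuli Stimulus data frame; an optional logical `is_base` column
#'   overrides the lexicon-based base-form heuristic.
#' @param lexicon Optional `morph_lexicon` for the base-form flag when
#'   `stimuli$is_base` is absent.
#' @return Data frame with dependent measures (`SFD`, `FFD`, `GD`, `TT`),
#'   predictor columns, and grouping ids (`participant_id`, `sentence_id`,
#'   `word_uid`).
#' @export
buildAnalysisTable <- function(measures, predictability, frequencies,
                               stimuli, lexicon = NULL) {
  stim <- stimuli
  stim$form <- tolower(stim$form)
  stim$len <- nchar(stim$form)
  fr <- setNames(frequencies$per_million, tolower(frequencies$form))
  stim$log_freq <- logFrequency(unname(fr[stim$form]))
  if (!"is_base" %in% names(stim)) {
    if (is.null(lexicon)) {
      stop("either stimuli$is_base or a lexicon must be supplied")
    }
    stim$is_base <- vapply(stim$form, .is_base_form, logical(1),
                           lexicon = lexicon)
  }
  skey <- paste(stim$sentence_id, stim$position)
  pkey <- paste(predictability$sentence_id, predictability$position)

  q_cols <- grep("^q_", names(predictability), value = TRUE)
  pred_at <- function(sid, pos, col) {
    j <- match(paste(sid, pos), pkey)
    predictability[[col]][j]
  }
  stim_at <- function(sid, pos, col) {
    j <- match(paste(sid, pos), skey)
    stim[[col]][j]
  }

  included <- applyExclusions(stim, "eyetracking")
  mkey <- paste(measures$sentence_id, measures$position)
  rows <- measures[mkey %in% paste(included$sentence_id, included$position) &
                     measures$fixated, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no fixated included words")

  sid <- rows$sentence_id
  tab <- data.frame(participant_id = rows$participant_id,
                    sentence_id = sid,
                    position = rows$position,
                    word_uid = paste(sid, rows$position, sep = ":"),
                    SFD = rows$SFD, FFD = rows$FFD, GD = rows$GD,
                    TT = rows$TT,
                    sacc_amp = rows$saccade_amp_first,
                    landing = rows$landing_first,
                    stringsAsFactors = FALSE)
  for (off in c(m1 = -1L, n = 0L, p1 = 1L)) {
    suf <- names(which(c(m1 = -1L, n = 0L, p1 = 1L) == off))
    pos <- rows$position + off
    tab[[paste0("len_", suf)]] <- stim_at(sid, pos, "len")
    tab[[paste0("freq_", suf)]] <- stim_at(sid, pos, "log_freq")
    for (qc in q_cols) {
      tab[[paste0(qc, "_", suf)]] <- pred_at(sid, pos, qc)
    }
  }
  tab$is_base <- as.numeric(stim_at(sid, rows$position, "is_base"))
  tab$target_class_n <- pred_at(sid, rows$position, "word_class")
  tab$target_tense_n <- pred_at(sid, rows$position, "target_tense")

  # lexical neighbour logits must exist for every included row
  lex_q <- intersect(c("q_cloze", "q_corpus"), q_cols)
  for (qc in lex_q) {
    for (suf in c("m1", "n", "p1")) {
      col <- paste0(qc, "_", suf)
      if (anyNA(tab[[col]])) {
        bad <- tab$word_uid[which(is.na(tab[[col]]))[1L]]
        stop("missing predictor ", col, " for word ", bad)
      }
    }
  }
  # center and scale word length over included rows only
  for (suf in c("m1", "n", "p1")) {
    col <- paste0("len_", suf)
    tab[[col]] <- as.numeric(scale(tab[[col]]))
    if (anyNA(tab[[col]])) tab[[col]][is.na(tab[[col]])] <- 0  # constant case
  }
  rownames(tab) <- NULL
  tab
}

#' Read / write fixation tables
#'
#' Tab-separated UTF-8 with columns `participant_id`, `sentence_id`,
#' `fixation_index`, `word_position`, `duration_ms`, `landing_char`,
#' `saccade_amp_char`. Word positions are 1-based within the sentence;
#' landing positions are 0-based character offsets from word start.
#'
#' @param path File path.
#' @return A data frame.
#' @export
readFixations <- function(path) {
  utils::read.delim(path, fileEncoding = "UTF-8")
}

#' @param fixations Fixation data frame.
#' @rdname readFixations
#' @export
writeFixations <- function(fixations, path) {
  utils::write.table(fixations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write stimulus tables
#'
#' Tab-separated UTF-8 with columns `sentence_id`, `position`, `form`,
#' `is_first`, `is_last` (and optionally `is_base`).
#'
#' @param path File path.
#' @return A data frame.
#' @export
readStimuli <- function(path) {
  utils::read.delim(path, fileEncoding = "UTF-8",
                    colClasses = c(form = "character"))
}

#' @param stimuli Stimulus data frame.
#' @rdname readStimuli
#' @export
writeStimuli <- function(stimuli, path) {
  utils::write.table(stimuli, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
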