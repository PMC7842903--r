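# Aggregation of cumulative cloze-task responses into per-word lexical
# probabilities with zero smoothing and a symmetric cap at 1.

#' Smoothing value for zero cloze counts
#'
#' A target that no respondent guessed receives probability
#' `1 / (2 * n_guesses)` instead of zero, keeping the logit transform finite.
#'
#' @param n_guesses Number of guesses collected for the word (>= 1).
#' @return Probability in (0, 0.5].
#' @examples
#' smoothZero(20)   # 0.025
#' @export
smoothZero <- function(n_guesses) {
  if (length(n_guesses) != 1L || is.na(n_guesses) || n_guesses < 1) {
    stop("n_guesses must be >= 1")
  }
  1 / (2 * n_guesses)
}

# symmetric cap so a unanimous response set stays inside (0, 1)
.cap_one <- function(n_guesses) 1 - 1 / (2 * n_guesses)

#' Normalize a typed cloze response
#'
#' Lower-casing plus Unicode NFC. Typo correction is assumed to have happened
#' upstream.
#'
#' @param x Character vector of responses.
#' @return Normalized character vector.
#' @export
normalizeResponse <- function(x) {
  stringi::stri_trans_nfc(tolower(trimws(x)))
}

#' Lexical cloze probability of a target word
#'
#' The probability is the share of responses that match the target form
#' orthographically (a full match). Zero counts are smoothed to
#' `1/(2 n)` ([smoothZero()]); unanimous sets are capped symmetrically at
#' `1 - 1/(2 n)` so the logit transform stays finite.
#'
#' @param responses Character vector of normalized responses (>= 1).
#' @param target_form Target word form.
#' @return List with `p_lexical`, `smoothed` (`TRUE` iff the raw match count
#'   was zero), and `n_guesses`.
#' @examples
#' lexicalProbability(c("driver", "driver", "driver", "pedestrian"), "driver")
#' @export
lexicalProbability <- function(responses, target_form) {
  n <- length(responses)
  if (n < 1L) stop("response set must be non-empty")
  target_form <- normalizeResponse(target_form)
  hits <- sum(normalizeResponse(responses) == target_form)
  if (hits == 0L) {
    list(p_lexical = smoothZero(n), smoothed = TRUE, n_guesses = n)
  } else {
    list(p_lexical = min(hits / n, .cap_one(n)), smoothed = FALSE,
         n_guesses = n)
  }
}

#' Aggregate a cloze response table into per-word records
#'
#' @param responses Data frame with columns `participant_id`, `sentence_id`,
#'   `position`, `response` (the cumulative cloze response TSV layout).
#' @param stimuli Data frame with columns `sentence_id`, `position`, `form`,
#'   `is_first`, `is_last`.
#' @param include_first Keep records for sentence-initial words? They are
#'   dropped by default (respondents had no context for them); the analysis
#'   table builder re-requests them as neighbour predictors.
#' @return Data frame with one row per stimulus word: `sentence_id`,
#'   `position`, `target`, `n_guesses`, `p_lexical`, `smoothed`.
#' @export
aggregateCloze <- function(responses, stimuli, include_first = FALSE) {
  need <- c("participant_id", "sentence_id", "position", "response")
  if (!all(need %in% names(responses))) {
    stop("responses must have columns: ", paste(need, collapse = ", "))
  }
  stim <- stimuli
  if (!include_first) stim <- stim[!as.logical(stim$is_first), , drop = FALSE]
  key_r <- paste(responses$sentence_id, responses$position)
  out <- vector("list", nrow(stim))
  for (i in seq_len(nrow(stim))) {
    sel <- key_r == paste(stim$sentence_id[i], stim$position[i])
    resp <- responses$response[sel]
    if (length(resp) == 0L) {
      stop("no cloze responses for sentence ", stim$sentence_id[i],
           " position ", stim$position[i])
    }
    rec <- lexicalProbability(resp, stim$form[i])
    out[[i]] <- data.frame(sentence_id = stim$sentence_id[i],
                           position = stim$position[i],
                           target = stim$form[i],
                           n_guesses = rec$n_guesses,
                           p_lexical = rec$p_lexical,
                           smoothed = rec$smoothed,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Read / write cloze tables
#'
#' Tab-separated UTF-8 files: the response table has columns
#' `participant_id`, `sentence_id`, `position`, `response`; the record table
#' written by [aggregateCloze()] has `sentence_id`, `position`, `target`,
#' `n_guesses`, `p_lexical`, `smoothed`.
#'
#' @param path File path.
#' @return A data frame.
#' @export
readClozeResponses <- function(path) {
  utils::read.delim(path, fileEncoding = "UTF-8",
                    colClasses = c(response = "character"))
}

#' @param records Data frame of cloze records.
#' @rdname readClozeResponses
#' @export
writeClozeRecords <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
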