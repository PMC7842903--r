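# Morphological analyses of word forms: representation, lexicon lookup, and
# the class/feature matching rules used when aggregating probability mass over
# candidate continuations.

#' Word classes recognised by the package
#'
#' The inventory distinguishes nouns, finite verbs, infinitives, adjectives,
#' adverbs, numerals, personal pronouns, prepositions, conjunctions and
#' particles; `"other"` is the designated fallback class for forms outside the
#' lexicon.
#'
#' @return Character vector of word-class labels.
#' @export
wordClasses <- function() {
  c("noun", "verb_finite", "verb_infinitive", "adjective", "adverb",
    "numeral", "personal_pronoun", "preposition", "conjunction",
    "particle", "other")
}

#' Morphological features and their value inventories
#'
#' Six core cases are used; secondary cases must be mapped onto these by the
#' lexicon builder.
#'
#' @return Named list mapping feature name to its permitted values.
#' @export
morphFeatures <- function() {
  list(gender = c("m", "f", "n"),
       number = c("sg", "pl"),
       case   = c("nom", "gen", "dat", "acc", "ins", "loc"),
       tense  = c("past", "present", "future"),
       person = c("1", "2", "3"))
}

.feature_names <- function() names(morphFeatures())

# Features a word class may carry. Finite verbs always allow tense and number;
# person is licensed only in present/future, gender only in past.
.allowed_features <- function(word_class, tense = NA_character_) {
  switch(word_class,
         noun = c("gender", "number", "case"),
         verb_finite = {
           extra <- character(0)
           if (!is.na(tense)) {
             extra <- if (tense == "past") "gender" else "person"
           }
           c("tense", "number", extra)
         },
         character(0))
}

#' Construct a single morphological analysis
#'
#' An analysis is a word class plus a partial feature map. Feature keys are
#' restricted by word class: nouns carry gender/number/case; finite verbs carry
#' tense and number, plus person in present/future tense or gender in past
#' tense; all other classes carry no features.
#'
#' @param word_class One of [wordClasses()].
#' @param gender,number,case,tense,person Feature values or `NA` (undefined).
#' @return One-row data frame with columns `word_class`, `gender`, `number`,
#'   `case`, `tense`, `person`.
#' @examples
#' morphAnalysis("noun", gender = "m", number = "sg", case = "nom")
#' @export
morphAnalysis <- function(word_class, gender = NA, number = NA, case = NA,
                          tense = NA, person = NA) {
  if (!is.character(word_class) || length(word_class) != 1L ||
      !word_class %in% wordClasses()) {
    stop("unknown word class: ", paste(word_class, collapse = ", "))
  }
  vals <- list(gender = gender, number = number, case = case,
               tense = tense, person = person)
  vals <- lapply(vals, function(v) {
    v <- as.character(v)
    if (length(v) != 1L) stop("feature values must be scalars")
    v
  })
  inv <- morphFeatures()
  defined <- names(vals)[!vapply(vals, is.na, logical(1))]
  for (f in defined) {
    if (!vals[[f]] %in% inv[[f]]) {
      stop("invalid value '", vals[[f]], "' for feature '", f, "'")
    }
  }
  allowed <- .allowed_features(word_class, vals$tense)
  bad <- setdiff(defined, allowed)
  if (length(bad) > 0L) {
    stop("feature(s) not permitted for class '", word_class, "': ",
         paste(bad, collapse = ", "))
  }
  data.frame(word_class = word_class, gender = vals$gender,
             number = vals$number, case = vals$case, tense = vals$tense,
             person = vals$person, stringsAsFactors = FALSE)
}

#' Combine analyses into an analysis set
#'
#' @param ... One-row analysis data frames from [morphAnalysis()], or data
#'   frames of such rows.
#' @return Data frame, one row per analysis.
#' @export
morphAnalysisSet <- function(...) {
  parts <- list(...)
  if (length(parts) == 0L) stop("an analysis set must contain >= 1 analysis")
  do.call(rbind, parts)
}

.unknown_analysis <- function() morphAnalysis("other")

#' Build a morphological lexicon
#'
#' A lexicon maps lower-cased word forms to non-empty sets of analyses. Lookup
#' of an absent form never fails: it returns the designated unknown analysis
#' (class `"other"`, no features).
#'
#' @param tab Data frame with columns `form`, `word_class`, `gender`,
#'   `number`, `case`, `tense`, `person` (`NA` or `""` = undefined), one row
#'   per analysis.
#' @return Object of class `morph_lexicon`.
#' @seealso [readLexicon()], [analyze()]
#' @export
morphLexicon <- function(tab) {
  need <- c("form", "word_class", "gender", "number", "case", "tense", "person")
  if (!all(need %in% names(tab))) {
    stop("lexicon table must have columns: ", paste(need, collapse = ", "))
  }
  tab <- tab[, need]
  tab$form <- tolower(trimws(as.character(tab$form)))
  for (f in .feature_names()) {
    v <- as.character(tab[[f]])
    v[!is.na(v) & v == ""] <- NA_character_
    tab[[f]] <- v
  }
  if (any(tab$form == "")) stop("empty word form in lexicon")
  # validate every row through the analysis constructor
  for (i in seq_len(nrow(tab))) {
    morphAnalysis(tab$word_class[i], tab$gender[i], tab$number[i],
                  tab$case[i], tab$tense[i], tab$person[i])
  }
  idx <- split(seq_len(nrow(tab)), tab$form)
  structure(list(tab = tab, index = idx), class = "morph_lexicon")
}

#' @export
print.morph_lexicon <- function(x, ...) {
  cat("morph_lexicon:", length(x$index), "forms,", nrow(x$tab), "analyses\n")
  invisible(x)
}

#' Read / write a lexicon TSV
#'
#' Tab-separated UTF-8, columns `form`, `word_class`, `gender`, `number`,
#' `case`, `tense`, `person`; empty string means the feature is undefined;
#' one row per analysis; forms are lower-cased.
#'
#' @param path File path.
#' @return `readLexicon` returns a `morph_lexicon`.
#' @export
readLexicon <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character",
                           fileEncoding = "UTF-8")
  morphLexicon(tab)
}

#' @param lexicon A `morph_lexicon`.
#' @rdname readLexicon
#' @export
writeLexicon <- function(lexicon, path) {
  tab <- lexicon$tab
  for (f in .feature_names()) tab[[f]][is.na(tab[[f]])] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up the analyses of a word form
#'
#' Deterministic for a fixed lexicon; ambiguous forms return all their
#' analyses; absent forms return the unknown analysis (`"other"`, no
#' features).
#'
#' @param form Word-form string (non-empty after trimming).
#' @param lexicon A `morph_lexicon`.
#' @return Data frame of analyses (>= 1 row).
#' @export
analyze <- function(form, lexicon) {
  stopifnot(inherits(lexicon, "morph_lexicon"))
  form <- tolower(trimws(form))
  if (length(form) != 1L || is.na(form) || form == "") {
    stop("form must be a non-empty string")
  }
  rows <- lexicon$index[[form]]
  if (is.null(rows)) return(.unknown_analysis())
  lexicon$tab[rows, -1L, drop = FALSE]
}

#' Word-class match between two analysis sets
#'
#' True iff some candidate analysis and some target analysis share a word
#' class. Morphological ambiguity is counted permissively: any analysis of
#' either side may support the match.
#'
#' @param candidate,target Non-empty analysis sets (data frames as returned by
#'   [analyze()]).
#' @return Logical scalar.
#' @export
classMatch <- function(candidate, target) {
  stopifnot(nrow(candidate) >= 1L, nrow(target) >= 1L)
  any(candidate$word_class %in% target$word_class)
}

#' Feature match between two analysis sets
#'
#' True iff some candidate analysis and some target analysis define `feature`
#' with the same value *and* share a word class: feature identity across word
#' classes does not count (a noun's "sg" never matches a verb's "sg").
#' Ambiguity is permissive, as in [classMatch()].
#'
#' @inheritParams classMatch
#' @param feature One of `"gender"`, `"number"`, `"case"`, `"tense"`,
#'   `"person"`.
#' @return Logical scalar.
#' @export
featureMatch <- function(candidate, target, feature) {
  if (!is.character(feature) || length(feature) != 1L ||
      !feature %in% .feature_names()) {
    stop("unknown feature name: ", paste(feature, collapse = ", "))
  }
  stopifnot(nrow(candidate) >= 1L, nrow(target) >= 1L)
  ck <- candidate[!is.na(candidate[[feature]]), c("word_class", feature)]
  tk <- target[!is.na(target[[feature]]), c("word_class", feature)]
  if (nrow(ck) == 0L || nrow(tk) == 0L) return(FALSE)
  any(paste(ck$word_class, ck[[feature]]) %in%
        paste(tk$word_class, tk[[feature]]))
}
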