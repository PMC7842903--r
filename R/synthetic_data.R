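# Seeded synthetic datasets with known ground truth: a morph-tagged lexicon,
# a first-order generative chain over it (whose exact conditional
# distributions are stored as ground truth), cumulative cloze samples with a
# shortness bias, corpus distributions distorted by Dirichlet resampling, and
# lognormal fixation sequences generated from a known coefficient vector.
# All randomness flows from one root seed via named substreams so stages can
# be regenerated independently.

.substream <- function(seed, k) {
  (as.integer(seed) %% 100000000L) * 17L + k
}

.default_class_mix <- function() {
  c(noun = 0.37, verb_finite = 0.16, verb_infinitive = 0.04,
    adjective = 0.14, adverb = 0.05, numeral = 0.01,
    personal_pronoun = 0.06, preposition = 0.10, conjunction = 0.05,
    particle = 0.02)
}

.gen_forms <- function(n, seed) {
  set.seed(seed)
  cons <- c("b", "d", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  forms <- character(0)
  while (length(forms) < n) {
    k <- n - length(forms)
    nsyl <- sample(1:5, 2L * k, replace = TRUE,
                   prob = c(0.15, 0.3, 0.3, 0.15, 0.1))
    new <- vapply(nsyl, function(s) {
      paste0(paste0(sample(cons, s, replace = TRUE),
                    sample(vow, s, replace = TRUE)), collapse = "")
    }, character(1))
    forms <- unique(c(forms, new))
  }
  forms[seq_len(n)]
}

.random_analysis <- function(word_class) {
  inv <- morphFeatures()
  switch(word_class,
         noun = morphAnalysis("noun", gender = sample(inv$gender, 1L),
                              number = sample(inv$number, 1L),
                              case = sample(inv$case, 1L)),
         verb_finite = {
           tense <- sample(inv$tense, 1L)
           if (tense == "past") {
             morphAnalysis("verb_finite", tense = tense,
                           number = sample(inv$number, 1L),
                           gender = sample(inv$gender, 1L))
           } else {
             morphAnalysis("verb_finite", tense = tense,
                           number = sample(inv$number, 1L),
                           person = sample(inv$person, 1L))
           }
         },
         morphAnalysis(word_class))
}

#' Generate a synthetic morphological lexicon
#'
#' Every form receives one analysis; with probability `ambiguity_rate` a
#' second analysis is added (a different case for nouns, a different word
#' class otherwise). Class frequencies follow `class_mix`.
#'
#' @param n_forms Number of distinct word forms.
#' @param ambiguity_rate Probability of a second analysis, in `[0, 1]`.
#' @param class_mix Named probability vector over word classes.
#' @param seed Integer seed.
#' @return A `morph_lexicon`.
#' @export
makeLexicon <- function(n_forms = 500L, ambiguity_rate = 0.1,
                        class_mix = .default_class_mix(), seed = 1L) {
  if (length(class_mix) == 0L) stop("class_mix must be non-empty")
  if (ambiguity_rate < 0 || ambiguity_rate > 1) {
    stop("ambiguity_rate must be in [0, 1]")
  }
  forms <- .gen_forms(n_forms, .substream(seed, 1L))
  set.seed(.substream(seed, 2L))
  classes <- sample(names(class_mix), n_forms, replace = TRUE,
                    prob = class_mix)
  rows <- vector("list", n_forms)
  inv <- morphFeatures()
  for (i in seq_len(n_forms)) {
    a <- .random_analysis(classes[i])
    a$form <- forms[i]
    if (stats::runif(1) < ambiguity_rate) {
      b <- if (classes[i] == "noun") {
        morphAnalysis("noun", gender = a$gender, number = a$number,
                      case = sample(setdiff(inv$case, a$case), 1L))
      } else {
        .random_analysis(sample(setdiff(names(class_mix), classes[i]), 1L))
      }
      b$form <- forms[i]
      a <- rbind(a, b)
    }
    rows[[i]] <- a
  }
  tab <- do.call(rbind, rows)
  morphLexicon(tab[, c("form", "word_class", "gender", "number", "case",
                       "tense", "person")])
}

# first-order chain over the lexicon's forms; conditional distributions are
# sparse Dirichlet draws, peaked enough that targets get realistic cloze mass
.make_chain <- function(forms, seed, n_succ = 12L, alpha = 0.4) {
  set.seed(seed)
  rdirichlet1 <- function(k, a) {
    g <- stats::rgamma(k, shape = a)
    g <- pmax(g, 1e-12)
    g / sum(g)
  }
  init_forms <- sort(sample(forms, min(40L, length(forms))))
  init <- setNames(rdirichlet1(length(init_forms), alpha), init_forms)
  succ <- lapply(forms, function(f) {
    s <- sort(sample(forms, min(n_succ, length(forms))))
    setNames(rdirichlet1(length(s), alpha), s)
  })
  names(succ) <- forms
  list(init = init, succ = succ)
}

#' Generate stimuli and their true next-word distributions
#'
#' Sentences are sampled from a seeded first-order generative chain over the
#' lexicon; the chain's exact conditional distribution at every position is
#' returned as ground truth. Sentence lengths are uniform over
#' `length_range` (default 5-13 words, mean 9) unless `lengths` is given.
#'
#' @param lexicon A `morph_lexicon`.
#' @param n_sentences Number of sentences (default 144).
#' @param length_range Two-element integer range within `[2, 20]`.
#' @param lengths Optional explicit sentence lengths (overrides sampling).
#' @param chain Optional pre-built chain (a list with `init` and `succ`
#'   named probability vectors); by default a fresh one is drawn from the
#'   lexicon.
#' @param seed Integer seed.
#' @return List with `stimuli` (data frame), `truth` (per sentence, a list of
#'   named probability vectors, one per position), and `chain`.
#' @export
makeStimuliAndTruth <- function(lexicon, n_sentences = 144L,
                                length_range = c(5L, 13L), lengths = NULL,
                                chain = NULL, seed = 1L) {
  stopifnot(length_range[1] >= 2L, length_range[2] <= 20L)
  forms <- names(lexicon$index)
  if (is.null(chain)) chain <- .make_chain(forms, .substream(seed, 3L))
  set.seed(.substream(seed, 4L))
  if (is.null(lengths)) {
    lengths <- sample(length_range[1]:length_range[2], n_sentences,
                      replace = TRUE)
  }
  stopifnot(length(lengths) == n_sentences)
  stim <- vector("list", n_sentences)
  truth <- vector("list", n_sentences)
  for (s in seq_len(n_sentences)) {
    len <- lengths[s]
    words <- character(len)
    dists <- vector("list", len)
    for (p in seq_len(len)) {
      d <- if (p == 1L) chain$init else chain$succ[[words[p - 1L]]]
      dists[[p]] <- d
      words[p] <- sample(names(d), 1L, prob = d)
    }
    stim[[s]] <- data.frame(sentence_id = s, position = seq_len(len),
                            form = words,
                            is_first = seq_len(len) == 1L,
                            is_last = seq_len(len) == len,
                            stringsAsFactors = FALSE)
    truth[[s]] <- dists
  }
  list(stimuli = do.call(rbind, stim), truth = truth, chain = chain)
}

#' Sample a training corpus from a generative chain
#'
#' @param chain Chain from [makeStimuliAndTruth()].
#' @param n_sentences Number of sentences.
#' @param length_range Sentence length range.
#' @param seed Integer seed.
#' @return List of token vectors.
#' @export
makeCorpus <- function(chain, n_sentences = 1000L, length_range = c(5L, 13L),
                       seed = 1L) {
  set.seed(.substream(seed, 5L))
  lens <- sample(length_range[1]:length_range[2], n_sentences, replace = TRUE)
  lapply(lens, function(len) {
    words <- character(len)
    for (p in seq_len(len)) {
      d <- if (p == 1L) chain$init else chain$succ[[words[p - 1L]]]
      words[p] <- sample(names(d), 1L, prob = d)
    }
    words
  })
}

#' Word frequencies per million from a corpus
#'
#' @param corpus List of token vectors.
#' @return Data frame with columns `form`, `per_million`.
#' @export
makeFrequencies <- function(corpus) {
  toks <- unlist(corpus)
  tab <- table(toks)
  data.frame(form = names(tab),
             per_million = as.numeric(tab) / length(toks) * 1e6,
             stringsAsFactors = FALSE)
}

#' Sample cumulative cloze responses from the ground truth
#'
#' Each respondent guess is drawn from the true next-word distribution
#' reweighted by `exp(-bias * word length)` (respondents avoid long words)
#' and renormalized. The number of guesses per word is sampled in
#' `[20, 151]` with mean about 47, matching a typical cumulative cloze
#' collection.
#'
#' @param stimuli,truth From [makeStimuliAndTruth()].
#' @param bias Non-negative shortness-preference weight (0 = unbiased).
#' @param n_guesses Optional fixed number of guesses per word (overrides
#'   sampling; may exceed the usual bounds for convergence checks).
#' @param seed Integer seed.
#' @return Response data frame (`participant_id`, `sentence_id`, `position`,
#'   `response`).
#' @export
sampleCloze <- function(stimuli, truth, bias = 0.3, n_guesses = NULL,
                        seed = 1L) {
  set.seed(.substream(seed, 6L))
  out <- vector("list", nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    s <- stimuli$sentence_id[i]
    p <- stimuli$position[i]
    d <- truth[[s]][[p]]
    w <- d * exp(-bias * nchar(names(d)))
    w <- w / sum(w)
    n <- if (is.null(n_guesses)) {
      min(151L, 20L + stats::rnbinom(1L, size = 4, mu = 27))
    } else n_guesses
    guesses <- sample(names(w), n, replace = TRUE, prob = w)
    out[[i]] <- data.frame(participant_id = sprintf("g%03d", seq_len(n)),
                           sentence_id = s, position = p,
                           response = guesses, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Distort true distributions into corpus-provider records
#'
#' Each true distribution is perturbed by Dirichlet resampling with
#' parameters `concentration * p`: the larger the concentration, the closer
#' the provider is to the truth (emulating language-model estimation error).
#' Output records pass the distribution normalization invariants and can be
#' wrapped with [tableProvider()] or written with [writeProviderJsonl()].
#'
#' @param stimuli,truth From [makeStimuliAndTruth()].
#' @param concentration Positive concentration of the perturbation.
#' @param top_k Truncate each distribution to its `top_k` heaviest words,
#'   accounting for the remainder as `tail_mass`.
#' @param seed Integer seed.
#' @return List of provider records.
#' @export
distortDistribution <- function(stimuli, truth, concentration = 50,
                                top_k = 5000L, seed = 1L) {
  if (concentration <= 0) stop("concentration must be > 0")
  set.seed(.substream(seed, 7L))
  out <- vector("list", nrow(stimuli))
  for (i in seq_len(nrow(stimuli))) {
    s <- stimuli$sentence_id[i]
    p <- stimuli$position[i]
    d <- truth[[s]][[p]]
    g <- stats::rgamma(length(d), shape = concentration * d)
    g <- pmax(g, 1e-12)
    mass <- setNames(g / sum(g), names(d))
    if (length(mass) > top_k) {
      keep <- order(-mass)[seq_len(top_k)]
      tail_mass <- sum(mass[-keep])
      mass <- mass[sort(keep)]
    } else {
      tail_mass <- 0
    }
    out[[i]] <- list(sentence_id = s, position = p, mass = mass,
                     tail_mass = tail_mass)
  }
  out
}

#' Simulate fixation sequences with known coefficients
#'
#' A generative mirror of the hierarchical lognormal analysis model: per
#' word, the linear predictor is `intercept + sum(beta * x) + participant +
#' sentence + word intercepts`; the first-pass duration is lognormal around
#' it. Words may be skipped (probability increasing with predictability),
#' refixated once in first pass (the total first-pass time is then split
#' 60/40 into two fixations), and revisited in a later regression pass
#' (which adds total-time but not gaze-duration mass). Landing positions are
#' uniform within the word; the incoming saccade amplitude is the character
#' distance from the previous fixation. Skip and refixation links are fixed
#' logistic scaffolding, not empirical claims.
#'
#' @param stimuli Stimulus data frame.
#' @param word_predictors Data frame aligned on (`sentence_id`, `position`)
#'   carrying the predictor columns named in `beta` (a name `q_cloze_n`
#'   refers to column `q_cloze` at the current word; `_m1`/`_p1` suffixes to
#'   the neighbours).
#' @param beta Named coefficient vector on the log-duration scale (default:
#'   lexical logit probability slope -0.05 per logit unit).
#' @param intercept Log-duration intercept (default `log(225)` ms).
#' @param varcomp Standard deviations of the participant, sentence and word
#'   varying intercepts and of the residual, on the log scale.
#' @param n_participants Number of simulated readers.
#' @param skip_link,refix_link Logistic intercept/slope pairs on the skip
#'   and refixation probabilities as functions of the word's `q_cloze`.
#' @param regress_prob Probability of a later revisit to a fixated word.
#' @param seed Integer seed.
#' @return Fixation data frame (see [readFixations()] for the layout).
#' @export
simulateReading <- function(stimuli, word_predictors,
                            beta = c(q_cloze_n = -0.05),
                            intercept = log(225),
                            varcomp = c(participant = 0.12, sentence = 0.06,
                                        word = 0.05, residual = 0.35),
                            n_participants = 30L,
                            skip_link = c(a = -2.2, b = 0.35),
                            refix_link = c(a = -1.1, b = -0.2),
                            regress_prob = 0.12, seed = 1L) {
  stopifnot(all(varcomp >= 0))
  set.seed(.substream(seed, 8L))
  wp_key <- paste(word_predictors$sentence_id, word_predictors$position)
  x_at <- function(sid, pos, col) {
    v <- word_predictors[[col]][match(paste(sid, pos), wp_key)]
    if (is.null(word_predictors[[col]])) stop("predictor column missing: ", col)
    ifelse(is.na(v), 0, v)
  }
  # resolve beta names to (column, offset)
  parse_beta <- function(nm) {
    if (grepl("_m1$", nm)) list(col = sub("_m1$", "", nm), off = -1L)
    else if (grepl("_p1$", nm)) list(col = sub("_p1$", "", nm), off = 1L)
    else if (grepl("_n$", nm)) list(col = sub("_n$", "", nm), off = 0L)
    else list(col = nm, off = 0L)
  }
  terms <- lapply(names(beta), parse_beta)
  for (t in terms) {
    if (is.null(word_predictors[[t$col]])) {
      stop("beta names must match predictor columns; missing: ", t$col)
    }
  }
  stim_split <- split(stimuli, stimuli$sentence_id)
  u_s <- stats::rnorm(length(stim_split), 0, varcomp["sentence"])
  names(u_s) <- names(stim_split)
  wuid <- paste(stimuli$sentence_id, stimuli$position, sep = ":")
  u_w <- stats::rnorm(length(wuid), 0, varcomp["word"])
  names(u_w) <- wuid
  u_p <- stats::rnorm(n_participants, 0, varcomp["participant"])

  rows <- list()
  for (pp in seq_len(n_participants)) {
    pid <- sprintf("s%03d", pp)
    for (sid in names(stim_split)) {
      sent <- stim_split[[sid]]
      len <- nrow(sent)
      offsets <- cumsum(c(0, nchar(sent$form) + 1L))[seq_len(len)]
      q <- x_at(sent$sentence_id, sent$position, "q_cloze")
      eta <- rep(intercept, len) + u_p[pp] + u_s[sid] +
        u_w[paste(sid, sent$position, sep = ":")]
      for (j in seq_along(terms)) {
        eta <- eta + beta[j] *
          x_at(sent$sentence_id, sent$position + terms[[j]]$off,
               terms[[j]]$col)
      }
      skip <- stats::runif(len) <
        stats::plogis(skip_link["a"] + skip_link["b"] * q)
      skip[1L] <- FALSE  # the initial fixation point forces a first fixation
      fix_pos <- integer(0); fix_dur <- numeric(0); fix_land <- numeric(0)
      revisit <- integer(0)
      for (w in seq_len(len)) {
        if (skip[w]) next
        t1 <- exp(eta[w] + stats::rnorm(1, 0, varcomp["residual"]))
        two <- stats::runif(1) <
          stats::plogis(refix_link["a"] + refix_link["b"] * q[w])
        land <- sample.int(nchar(sent$form[w]), if (two) 2L else 1L,
                           replace = TRUE) - 1L
        if (two) {
          fix_pos <- c(fix_pos, w, w)
          fix_dur <- c(fix_dur, 0.6 * t1, 0.4 * t1)
          fix_land <- c(fix_land, land)
        } else {
          fix_pos <- c(fix_pos, w)
          fix_dur <- c(fix_dur, t1)
          fix_land <- c(fix_land, land)
        }
        if (stats::runif(1) < regress_prob) revisit <- c(revisit, w)
      }
      # a revisit to the very last fixated word would be consecutive with
      # its first pass and silently extend gaze duration
      if (length(fix_pos) > 0L) {
        revisit <- revisit[revisit != fix_pos[length(fix_pos)]]
      }
      for (w in revisit) {
        fix_pos <- c(fix_pos, w)
        fix_dur <- c(fix_dur,
                     0.5 * exp(eta[w] + stats::rnorm(1, 0,
                                                     varcomp["residual"])))
        fix_land <- c(fix_land, sample.int(nchar(sent$form[w]), 1L) - 1L)
      }
      if (length(fix_pos) == 0L) next
      char_pos <- offsets[fix_pos] + fix_land
      amp <- c(offsets[fix_pos[1L]] + fix_land[1L],
               abs(diff(char_pos)))
      rows[[length(rows) + 1L]] <-
        data.frame(participant_id = pid,
                   sentence_id = sent$sentence_id[1L],
                   fixation_index = seq_along(fix_pos),
                   word_position = fix_pos,
                   duration_ms = fix_dur,
                   landing_char = fix_land,
                   saccade_amp_char = amp,
                   stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate a complete synthetic bundle
#'
#' Produces mutually consistent lexicon, training corpus, stimuli with
#' ground-truth distributions, cloze responses, distorted corpus-provider
#' records, word frequencies, and fixation records, all derived from one
#' root seed via fixed substreams (regeneration with the same seed is
#' byte-identical). When `out_dir` is given, the bundle is also written as
#' plain-text files (`lexicon.tsv`, `corpus.txt`, `stimuli.tsv`,
#' `responses.tsv`, `provider.jsonl`, `frequencies.tsv`, `fixations.tsv`,
#' `ground_truth.json`).
#'
#' @param seed Root seed.
#' @param n_sentences,n_participants Bundle size (defaults: 144-sentence
#'   stimulus set; 30 readers).
#' @param n_forms Lexicon size.
#' @param ambiguity_rate Lexicon ambiguity rate.
#' @param cloze_bias Shortness-preference weight of the cloze sampler.
#' @param concentration Corpus-distortion concentration.
#' @param beta,varcomp Duration-generation truth (see [simulateReading()]).
#' @param corpus_sentences Training-corpus size in sentences.
#' @param out_dir Optional output directory.
#' @return List with all bundle components and the ground-truth parameters.
#' @export
makeBundle <- function(seed = 1L, n_sentences = 144L, n_participants = 30L,
                       n_forms = 400L, ambiguity_rate = 0.1,
                       cloze_bias = 0.3, concentration = 50,
                       beta = c(q_cloze_n = -0.05),
                       varcomp = c(participant = 0.12, sentence = 0.06,
                                   word = 0.05, residual = 0.35),
                       corpus_sentences = 1000L, out_dir = NULL) {
  lexicon <- makeLexicon(n_forms = n_forms, ambiguity_rate = ambiguity_rate,
                         seed = seed)
  st <- makeStimuliAndTruth(lexicon, n_sentences = n_sentences, seed = seed)
  corpus <- makeCorpus(st$chain, n_sentences = corpus_sentences, seed = seed)
  frequencies <- makeFrequencies(corpus)
  responses <- sampleCloze(st$stimuli, st$truth, bias = cloze_bias,
                           seed = seed)
  provider_records <- distortDistribution(st$stimuli, st$truth,
                                          concentration = concentration,
                                          seed = seed)
  predictability <- predictabilityTable(st$stimuli, responses,
                                        tableProvider(provider_records),
                                        lexicon)
  fixations <- simulateReading(st$stimuli, predictability, beta = beta,
                               varcomp = varcomp,
                               n_participants = n_participants, seed = seed)
  bundle <- list(seed = seed, lexicon = lexicon, stimuli = st$stimuli,
                 truth = st$truth, chain = st$chain, corpus = corpus,
                 frequencies = frequencies, responses = responses,
                 provider_records = provider_records,
                 predictability = predictability, fixations = fixations,
                 ground_truth = list(beta = as.list(beta),
                                     varcomp = as.list(varcomp),
                                     cloze_bias = cloze_bias,
                                     concentration = concentration,
                                     n_sentences = n_sentences,
                                     n_participants = n_participants))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLexicon(lexicon, file.path(out_dir, "lexicon.tsv"))
    writeLines(vapply(corpus, paste, character(1), collapse = " "),
               file.path(out_dir, "corpus.txt"), useBytes = TRUE)
    writeStimuli(st$stimuli, file.path(out_dir, "stimuli.tsv"))
    utils::write.table(responses, file.path(out_dir, "responses.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    writeProviderJsonl(provider_records,
                       file.path(out_dir, "provider.jsonl"))
    utils::write.table(frequencies, file.path(out_dir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    writeFixations(fixations, file.path(out_dir, "fixations.tsv"))
    gt <- bundle$ground_truth
    gt$truth <- lapply(st$truth, function(sd) lapply(sd, as.list))
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}
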