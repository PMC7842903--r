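# Shared fixtures and independent oracles used across the test files.

# --- brute-force interpolated Kneser-Ney oracle ---------------------------
# Recomputes every count by scanning the corpus on each call; completely
# independent of the package's count-table implementation.
kn_oracle <- function(corpus, order, discount, context, w, vocab_cap = Inf) {
  toks <- unlist(corpus)
  freq <- table(toks)
  ord <- order(-as.numeric(freq), names(freq))
  keep <- names(freq)[ord][seq_len(min(length(freq), vocab_cap))]
  map <- function(t) ifelse(t %in% keep | t == "<s>", t, "<unk>")
  sents <- lapply(corpus, function(s) c(rep("<s>", order - 1L), map(s)))
  v_out <- length(unique(c(sort(keep), "<unk>")))

  grams <- function(k) {
    out <- list()
    for (s in sents) {
      for (e in order:length(s)) out[[length(out) + 1L]] <- s[(e - k + 1L):e]
    }
    out
  }
  gram_types <- function(k) unique(grams(k))

  p <- function(k, ctx, w) {
    if (k == 0L) return(1 / v_out)
    if (k == order) {
      g <- grams(k)
      items <- if (k == 1L) g else
        Filter(function(x) identical(x[seq_len(k - 1L)], ctx), g)
    } else {
      tt <- gram_types(k + 1L)
      suff <- lapply(tt, function(x) x[-1L])
      items <- if (k == 1L) suff else
        Filter(function(x) identical(x[seq_len(k - 1L)], ctx), suff)
    }
    den <- length(items)
    low_ctx <- if (k <= 1L) character(0) else ctx[-1L]
    if (den == 0L) return(p(k - 1L, low_ctx, w))
    lasts <- vapply(items, function(x) x[k], character(1))
    cnt <- sum(lasts == w)
    n1 <- length(unique(lasts))
    max(cnt - discount, 0) / den +
      (discount * n1 / den) * p(k - 1L, low_ctx, w)
  }

  ctx <- map(as.character(context))
  padded <- c(rep("<s>", order - 1L), ctx)
  ctx_use <- if (order == 1L) character(0) else
    padded[(length(padded) - order + 2L):length(padded)]
  p(order, ctx_use, map(w))
}

# --- hand-built morphological lexicon -------------------------------------
test_lexicon <- function() {
  r <- function(form, wc, g = NA, n = NA, cs = NA, t = NA, p = NA) {
    data.frame(form = form, word_class = wc, gender = g, number = n,
               case = cs, tense = t, person = p, stringsAsFactors = FALSE)
  }
  morphLexicon(rbind(
    r("driver", "noun", "m", "sg", "nom"),
    r("car", "noun", "f", "sg", "acc"),
    r("cars", "noun", "f", "pl", "nom"),
    r("rot", "noun", "m", "sg", "nom"),
    r("rot", "noun", "m", "sg", "acc"),    # nominative/accusative ambiguity
    r("quickly", "adverb"),
    r("big", "adjective"),
    r("runs", "verb_finite", n = "sg", t = "present", p = "3"),
    r("ran", "verb_finite", g = "m", n = "sg", t = "past"),
    r("run", "verb_infinitive"),
    r("and", "conjunction"),
    r("on", "preposition")
  ))
}

# random unambiguous lexicon over generated forms (for property tests)
random_unambiguous_lexicon <- function(n_forms = 30L, seed = 1L) {
  makeLexicon(n_forms = n_forms, ambiguity_rate = 0, seed = seed)
}

# a small shared synthetic bundle, built once per test run
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- makeBundle(seed = 11, n_sentences = 30, n_participants = 12,
                           n_forms = 250, corpus_sentences = 250)
    }
    cache
  }
})

shared_analysis_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      b <- shared_bundle()
      meas <- computeMeasuresAll(b$fixations, b$stimuli)
      cache <<- buildAnalysisTable(meas, b$predictability, b$frequencies,
                                   b$stimuli, b$lexicon)
    }
    cache
  }
})

# rebuild an analysis table from re-simulated fixations on a bundle
resimulated_table <- function(bundle, beta, n_participants, seed, ...) {
  fx <- simulateReading(bundle$stimuli, bundle$predictability, beta = beta,
                        n_participants = n_participants, seed = seed, ...)
  meas <- computeMeasuresAll(fx, bundle$stimuli)
  buildAnalysisTable(meas, bundle$predictability, bundle$frequencies,
                     bundle$stimuli, bundle$lexicon)
}
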