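lex <- test_lexicon()

test_that("logit transform identities", {
  expect_equal(logitTransform(0.5), 0)
  expect_equal(logitTransform(0.1), 0.5 * log(1 / 9))
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(logitTransform(p), -logitTransform(1 - p))  # antisymmetry
  expect_true(all(diff(logitTransform(p)) > 0))            # monotone
  grid <- seq(1e-4, 1 - 1e-4, length.out = 1000)
  expect_equal(invLogitTransform(logitTransform(grid)), grid,
               tolerance = 1e-12)
  expect_error(logitTransform(0), "inside")
  expect_error(logitTransform(1), "inside")
})

test_that("class probability sums matching candidate mass", {
  # {driver .5, car .25 (nouns), quickly .25 (adverb)}, noun target -> 0.75
  entry <- clozeEntry(c(rep("driver", 2), "car", "quickly"))
  target <- analyze("cars", lex)
  expect_equal(classProbability(entry, target, lex), 0.75)
  # all candidates in the target's class -> capped below 1
  all_noun <- clozeEntry(c("driver", "car", "rot", "driver"))
  expect_equal(classProbability(all_noun, target, lex), 1 - 1 / 8)
  # corpus source: same mass function, capped with the corpus floor
  ce <- corpusEntry(c(driver = 0.5, car = 0.25, quickly = 0.25))
  expect_equal(classProbability(ce, target, lex), 0.75)
})

test_that("feature probability is class-conditioned with permissive ambiguity", {
  # half of the noun mass is accusative; accusative noun target
  entry <- corpusEntry(c(car = 0.3, driver = 0.3, big = 0.4))
  acc_target <- analyze("car", lex)
  expect_equal(featureProbability(entry, acc_target, "case", lex), 0.3)
  # renormalized within the noun mass instead of the total
  expect_equal(featureProbability(entry, acc_target, "case", lex,
                                  renormalize = TRUE), 0.5)
  # ambiguous nom/acc candidate counts fully toward either case target
  amb <- corpusEntry(c(rot = 0.6, quickly = 0.4))
  expect_equal(featureProbability(amb, acc_target, "case", lex), 0.6)
  expect_equal(featureProbability(amb, analyze("rot", lex), "case", lex), 0.6)
  expect_error(featureProbability(entry, analyze("quickly", lex), "case",
                                  lex), "does not define")
})

test_that("cloze and corpus entries with the same mass function agree", {
  for (s in 1:100) {
    tlex <- makeLexicon(n_forms = 25, ambiguity_rate = 0.2, seed = s)
    forms <- names(tlex$index)
    set.seed(s)
    picked <- sample(forms, 6)
    counts <- as.numeric(stats::rmultinom(1, 40, rep(1 / 6, 6)))
    keep <- counts > 0
    resp <- rep(picked[keep], counts[keep])
    entry_c <- clozeEntry(resp)
    entry_m <- corpusEntry(entry_c$mass)
    target <- analyze(sample(picked, 1), tlex)
    pc <- classProbability(entry_c, target, tlex)
    pm <- classProbability(entry_m, target, tlex)
    # identical in the interior; both sources only differ at the 0/1 bounds
    if (pc > smoothZero(40) && pc < 1 - smoothZero(40)) {
      expect_equal(pm, pc, tolerance = 1e-12)
    }
    for (f in names(morphFeatures())) {
      if (all(is.na(target[[f]]))) next
      pfc <- featureProbability(entry_c, target, f, tlex)
      pfm <- featureProbability(entry_m, target, f, tlex)
      if (pfc > smoothZero(40) && pfc < 1 - smoothZero(40)) {
        expect_equal(pfm, pfc, tolerance = 1e-12)
      }
    }
  }
})

test_that("class mass conserves: sums to 1 unambiguous, >= 1 under ambiguity", {
  entry <- corpusEntry(c(driver = 0.4, big = 0.3, quickly = 0.2,
                         runs = 0.1))
  classes <- c("noun", "adjective", "adverb", "verb_finite")
  total <- sum(vapply(classes, function(cl) {
    m <- predread:::.matching_forms(names(entry$mass),
                                    morphAnalysis(cl), lex)
    sum(entry$mass[m])
  }, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-9)
  # ambiguous candidate double-counts permissively
  amb <- corpusEntry(c(rot = 1))  # one form, but try noun via two cases
  by_case <- vapply(c("nom", "acc"), function(cs) {
    featureProbability(amb, morphAnalysis("noun", gender = "m",
                                          number = "sg", case = cs),
                       "case", lex)
  }, numeric(1))
  expect_gte(sum(by_case), 1)
})

test_that("class probability dominates the target's raw lexical probability", {
  for (s in 1:20) {
    tlex <- random_unambiguous_lexicon(n_forms = 20, seed = s)
    forms <- names(tlex$index)
    set.seed(s)
    resp <- sample(forms, 30, replace = TRUE)
    target_form <- sample(unique(resp), 1)
    entry <- clozeEntry(resp)
    p_lex <- lexicalProbability(resp, target_form)$p_lexical
    p_cls <- classProbability(entry, analyze(target_form, tlex), tlex)
    expect_gte(p_cls + 1e-12, min(p_lex, 1 - smoothZero(30)))
  }
})

test_that("correlations follow textbook behaviour and drop policy", {
  set.seed(5)
  q1 <- rnorm(10)
  expect_equal(correlatePredictability(q1, 2 * q1 + 1, "pearson", "smooth"), 1)
  q2 <- rnorm(10)
  expect_equal(correlatePredictability(q1, q2, "spearman", "smooth"),
               correlatePredictability(q1, exp(q2), "spearman", "smooth"))
  # hand computation on a fixed 10-pair table
  x <- c(0.2, -1.1, 0.4, 1.3, -0.6, 0.0, 2.1, -0.3, 0.8, -1.7)
  y <- c(0.1, -0.9, 0.6, 1.0, -0.2, 0.3, 1.8, -0.5, 0.4, -1.2)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(correlatePredictability(x, y, "pearson", "smooth"), r_hand)
  sm <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(correlatePredictability(x, y, "pearson", "drop", smoothed = sm),
               cor(x[1:5], y[1:5]))
  expect_error(correlatePredictability(x[1:2], y[1:2], "pearson", "smooth"),
               ">= 3")
  expect_error(correlatePredictability(x, y, "pearson", "drop"), "smoothed")
})

test_that("cumulative correlation curve limits and shape", {
  set.seed(8)
  n <- 60
  p_cloze <- runif(n, 0.02, 0.9)
  q_cloze <- logitTransform(p_cloze)
  # noise grows with predictability: correlation must fall as the
  # threshold rises
  q_corpus <- q_cloze + rnorm(n, 0, 0.05 + 1.5 * p_cloze)
  smoothed <- rep(FALSE, n)
  curve <- cumulativeCorrelationCurve(p_cloze, q_cloze, q_corpus, smoothed,
                                      thresholds = c(0.01, 0.25, 0.5, 1))
  # threshold below the minimum cloze p leaves no pairs: point omitted
  expect_false(0.01 %in% curve$threshold)
  expect_gt(curve$pearson[curve$threshold == 0.25],
            curve$pearson[curve$threshold == 1])
  # the full-set point equals the plain drop-policy correlation
  expect_equal(curve$pearson[curve$threshold == 1],
               correlatePredictability(q_cloze, q_corpus, "pearson", "drop",
                                       smoothed = smoothed))
})

test_that("per-class summary reproduces hand averages and rollups", {
  tab <- data.frame(
    word_class = c("noun", "noun", "noun", "adjective", "preposition",
                   "conjunction"),
    p_class_cloze = c(0.8, 0.6, 0.7, 0.4, 0.5, 0.5),
    p_class_corpus = c(0.7, 0.5, 0.6, 0.3, 0.4, 0.6))
  s <- summarizeByClass(tab)
  noun <- s[s$group == "noun", ]
  expect_equal(noun$mean_cloze, 0.7)
  expect_equal(noun$se_cloze, sd(c(0.8, 0.6, 0.7)) / sqrt(3))
  expect_equal(s$n_words[s$group == "all_content_words"], 4L)
  expect_equal(s$n_words[s$group == "all_function_words"], 2L)
  expect_equal(s$mean_cloze[s$group == "all_words"], mean(tab$p_class_cloze))
  # single-word class and tied values report SE 0
  expect_equal(s$se_cloze[s$group == "adjective"], 0)
  two <- summarizeByClass(data.frame(word_class = c("noun", "noun"),
                                     p_class_cloze = c(0.5, 0.5),
                                     p_class_corpus = c(0.4, 0.4)))
  expect_equal(two$se_cloze[two$group == "noun"], 0)
})

test_that("the predictability table carries aligned source columns", {
  b <- shared_bundle()
  pred <- b$predictability
  expect_equal(nrow(pred), nrow(b$stimuli))
  expect_true(all(c("q_cloze", "q_corpus", "q_class_cloze",
                    "q_class_corpus") %in% names(pred)))
  expect_true(all(is.finite(pred$q_cloze)))
  expect_true(all(is.finite(pred$q_corpus)))
  # feature columns defined exactly for noun / finite-verb targets
  nouns <- pred$word_class == "noun"
  expect_true(all(!is.na(pred$p_case_cloze[nouns])))
  expect_true(all(is.na(pred$p_case_cloze[pred$word_class == "adverb"])))
  expect_true(all(pred$p_class_cloze > 0 & pred$p_class_cloze < 1))
})
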