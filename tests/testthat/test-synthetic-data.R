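test_that("lexicon generation honours ambiguity and class mix", {
  lex0 <- makeLexicon(n_forms = 60, ambiguity_rate = 0, seed = 3)
  counts <- table(lex0$tab$form)
  expect_true(all(counts == 1L))
  expect_equal(length(lex0$index), 60L)

  lex_n <- makeLexicon(n_forms = 40, ambiguity_rate = 0,
                       class_mix = c(noun = 1), seed = 3)
  expect_true(all(lex_n$tab$word_class == "noun"))
  expect_error(makeLexicon(class_mix = numeric(0)), "non-empty")
  expect_error(makeLexicon(ambiguity_rate = 2), "ambiguity_rate")

  # determinism
  lex_a <- makeLexicon(n_forms = 50, ambiguity_rate = 0.3, seed = 9)
  lex_b <- makeLexicon(n_forms = 50, ambiguity_rate = 0.3, seed = 9)
  expect_identical(lex_a$tab, lex_b$tab)
})

test_that("stimuli follow the requested lengths and store exact truth", {
  lex <- random_unambiguous_lexicon(40, seed = 2)
  st <- makeStimuliAndTruth(lex, n_sentences = 40, seed = 5)
  lens <- tapply(st$stimuli$position, st$stimuli$sentence_id, max)
  expect_true(all(lens >= 5 & lens <= 13))
  expect_gt(mean(lens), 7)
  expect_lt(mean(lens), 11)
  # truth distributions are normalized and condition on the previous word
  for (s in 1:3) {
    for (p in seq_along(st$truth[[s]])) {
      d <- st$truth[[s]][[p]]
      expect_equal(sum(d), 1, tolerance = 1e-9)
      if (p > 1) {
        prev <- st$stimuli$form[st$stimuli$sentence_id == s &
                                  st$stimuli$position == p - 1]
        expect_identical(d, st$chain$succ[[prev]])
      }
    }
  }
  # a degenerate chain (deterministic successors) gives point-mass truth
  forms <- names(lex$index)
  succ <- lapply(seq_along(forms), function(i) {
    setNames(1, forms[(i %% length(forms)) + 1L])
  })
  names(succ) <- forms
  chain <- list(init = setNames(1, forms[1]), succ = succ)
  st_d <- makeStimuliAndTruth(lex, n_sentences = 3, chain = chain, seed = 1)
  expect_true(all(vapply(unlist(st_d$truth, recursive = FALSE), length,
                         integer(1)) == 1L))
  st2 <- makeStimuliAndTruth(lex, n_sentences = 40, seed = 5)
  expect_identical(st2$stimuli, st$stimuli)
})

test_that("cloze sampling converges to the truth and shows the length bias", {
  lex <- random_unambiguous_lexicon(30, seed = 4)
  st <- makeStimuliAndTruth(lex, n_sentences = 2, seed = 4)
  for (s in 1:10) {
    resp <- sampleCloze(st$stimuli[1:3, ], st$truth, bias = 0,
                        n_guesses = 5000, seed = s)
    for (i in 1:3) {
      d <- st$truth[[1]][[i]]
      emp <- table(resp$response[resp$position == i]) / 5000
      tv <- sum(abs(unname(emp[names(d)]) - d), na.rm = TRUE) / 2 +
        sum(d[!names(d) %in% names(emp)]) / 2
      expect_lt(tv, 0.05)
    }
  }
  # a positive shortness bias strictly reduces mean guessed length
  mean_len <- function(bias, s) {
    r <- sampleCloze(st$stimuli, st$truth, bias = bias, n_guesses = 300,
                     seed = s)
    mean(nchar(r$response))
  }
  for (s in 1:5) expect_lt(mean_len(1, s), mean_len(0, s))
  # point-mass truth: all guesses identical
  forms <- names(lex$index)
  succ <- lapply(forms, function(f) setNames(1, forms[1]))
  names(succ) <- forms
  st_d <- makeStimuliAndTruth(lex, n_sentences = 2,
                              chain = list(init = setNames(1, forms[2]),
                                           succ = succ), seed = 1)
  r <- sampleCloze(st_d$stimuli, st_d$truth, bias = 0.5, n_guesses = 25,
                   seed = 1)
  expect_true(all(tapply(r$response, paste(r$sentence_id, r$position),
                         function(x) length(unique(x))) == 1L))
})

test_that("distorted distributions stay normalized and approach truth", {
  lex <- random_unambiguous_lexicon(30, seed = 6)
  st <- makeStimuliAndTruth(lex, n_sentences = 5, seed = 6)
  recs <- distortDistribution(st$stimuli, st$truth, concentration = 50,
                              seed = 2)
  for (r in recs) {
    d <- probDistribution(r$mass, r$tail_mass)  # validates invariants
    expect_equal(sum(d$mass) + d$tail_mass, 1, tolerance = 1e-8)
  }
  tight <- distortDistribution(st$stimuli, st$truth, concentration = 1e6,
                               seed = 2)
  dev <- max(vapply(seq_along(tight), function(i) {
    s <- st$stimuli$sentence_id[i]; p <- st$stimuli$position[i]
    max(abs(tight[[i]]$mass - st$truth[[s]][[p]]))
  }, numeric(1)))
  expect_lt(dev, 1e-2)
  recs2 <- distortDistribution(st$stimuli, st$truth, concentration = 50,
                               seed = 2)
  expect_identical(recs, recs2)
  expect_error(distortDistribution(st$stimuli, st$truth, concentration = 0),
               "concentration")
})

test_that("with zero variance and zero slopes, gaze durations equal the intercept", {
  b <- shared_bundle()
  fx <- simulateReading(b$stimuli, b$predictability,
                        beta = c(q_cloze_n = 0), intercept = log(200),
                        varcomp = c(participant = 0, sentence = 0, word = 0,
                                    residual = 0),
                        n_participants = 2, seed = 1)
  m <- computeMeasuresAll(fx, b$stimuli)
  expect_equal(unique(round(log(m$GD[m$fixated]), 10)), log(200))
})

test_that("a negative probability slope shows up as monotone tercile means", {
  b <- shared_bundle()
  for (s in 1:10) {
    fx <- simulateReading(b$stimuli, b$predictability,
                          beta = c(q_cloze_n = -0.4),
                          n_participants = 12, seed = 700 + s)
    m <- computeMeasuresAll(fx, b$stimuli)
    key <- paste(b$predictability$sentence_id, b$predictability$position)
    q <- b$predictability$q_cloze[match(paste(m$sentence_id, m$position),
                                        key)]
    ter <- cut(q, quantile(q, c(0, 1 / 3, 2 / 3, 1)), include.lowest = TRUE,
               labels = c("lo", "mid", "hi"))
    means <- tapply(log(m$GD), ter, mean, na.rm = TRUE)
    expect_true(means[["lo"]] > means[["mid"]],
                label = paste("seed", s, "lo>mid"))
    expect_true(means[["mid"]] > means[["hi"]],
                label = paste("seed", s, "mid>hi"))
  }
})

test_that("simulated trials always satisfy the measure ordering", {
  b <- shared_bundle()
  m <- computeMeasuresAll(b$fixations, b$stimuli)
  fx <- m[m$fixated, ]
  expect_true(all(fx$FFD <= fx$GD + 1e-9 & fx$GD <= fx$TT + 1e-9))
  expect_true(all(b$fixations$duration_ms > 0))
  expect_true(all(b$fixations$landing_char >= 0))
  expect_true(all(b$fixations$saccade_amp_char >= 0))
})

test_that("bundle regeneration with the same seed is byte-identical", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  makeBundle(seed = 5, n_sentences = 6, n_participants = 3, n_forms = 80,
             corpus_sentences = 40, out_dir = dir_a)
  makeBundle(seed = 5, n_sentences = 6, n_participants = 3, n_forms = 80,
             corpus_sentences = 40, out_dir = dir_b)
  files <- list.files(dir_a)
  expect_setequal(files, list.files(dir_b))
  for (f in files) {
    expect_identical(unname(tools::md5sum(file.path(dir_a, f))),
                     unname(tools::md5sum(file.path(dir_b, f))),
                     label = f)
  }
  # a different seed changes the data
  dir_c <- withr::local_tempdir()
  makeBundle(seed = 6, n_sentences = 6, n_participants = 3, n_forms = 80,
             corpus_sentences = 40, out_dir = dir_c)
  expect_false(identical(
    unname(tools::md5sum(file.path(dir_a, "stimuli.tsv"))),
    unname(tools::md5sum(file.path(dir_c, "stimuli.tsv")))))
})

test_that("bundle files round-trip through the package readers", {
  dir <- withr::local_tempdir()
  b <- makeBundle(seed = 8, n_sentences = 5, n_participants = 3,
                  n_forms = 80, corpus_sentences = 40, out_dir = dir)
  stim <- readStimuli(file.path(dir, "stimuli.tsv"))
  expect_equal(nrow(stim), nrow(b$stimuli))
  lex <- readLexicon(file.path(dir, "lexicon.tsv"))
  expect_equal(length(lex$index), length(b$lexicon$index))
  fx <- readFixations(file.path(dir, "fixations.tsv"))
  expect_equal(nrow(fx), nrow(b$fixations))
  tp <- readProviderJsonl(file.path(dir, "provider.jsonl"))
  d <- nextDistribution(tp, sentence_id = b$stimuli$sentence_id[2],
                        position = b$stimuli$position[2])
  expect_equal(sum(d$mass) + d$tail_mass, 1, tolerance = 1e-8)
  corp <- readCorpus(file.path(dir, "corpus.txt"))
  expect_equal(length(corp), 40L)
  resp <- readClozeResponses(file.path(dir, "responses.tsv"))
  expect_true(all(c("participant_id", "sentence_id", "position",
                    "response") %in% names(resp)))
})
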