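# Corpus-based next-word probability: an interpolated Kneser-Ney n-gram
# reference model, a pluggable distribution-provider interface (for external
# models such as neural LMs, exchanged as serialized distributions), and the
# accuracy/perplexity evaluation harness.

.SEP <- "\x1f"
.BOS <- "<s>"
.UNK <- "<unk>"

#' Tokenize raw sentence text
#'
#' Lower-cases, splits punctuation into separate tokens, then splits on
#' whitespace. Punctuation tokens are retained (so positions are preserved)
#' and excluded later during evaluation.
#'
#' @param x Character vector, one sentence per element.
#' @return List of character token vectors, one per sentence.
#' @export
tokenizeText <- function(x) {
  x <- tolower(x)
  x <- gsub("([[:punct:]]+)", " \\1 ", x)
  lapply(strsplit(trimws(x), "[[:space:]]+"), function(t) t[t != ""])
}

#' Is a token pure punctuation?
#'
#' @param tokens Character vector.
#' @return Logical vector.
#' @export
isPunct <- function(tokens) grepl("^[[:punct:]]+$", tokens)

#' Read a corpus file (UTF-8, one sentence per line)
#'
#' @param path File path.
#' @return List of token vectors.
#' @export
readCorpus <- function(path) {
  tokenizeText(readLines(path, encoding = "UTF-8", warn = FALSE))
}

.as_token_list <- function(corpus) {
  if (is.character(corpus)) corpus <- tokenizeText(corpus)
  corpus <- corpus[lengths(corpus) > 0L]
  corpus
}

# keys are prefixed so the empty context "" is a legal environment name
.env_get <- function(e, key, default = 0) {
  v <- e[[paste0(".", key)]]
  if (is.null(v)) default else v
}

.env_from <- function(keys, values) {
  e <- new.env(parent = emptyenv(), size = max(29L, length(keys)))
  keys <- paste0(".", keys)
  for (i in seq_along(keys)) e[[keys[i]]] <- values[i]
  e
}

# aggregate (ctx, w) pairs into a count data frame
.aggregate_grams <- function(ctx, w, n = NULL) {
  key <- paste(ctx, w, sep = .SEP)
  if (is.null(n)) {
    tab <- table(key)
  } else {
    tab <- tapply(n, key, sum)
  }
  keys <- names(tab)
  sep_pos <- regexpr(paste0(.SEP, "[^", .SEP, "]*$"), keys)
  data.frame(ctx = substr(keys, 1L, sep_pos - 1L),
             w = substr(keys, sep_pos + 1L, nchar(keys)),
             n = as.numeric(tab), stringsAsFactors = FALSE)
}

#' Train an interpolated Kneser-Ney n-gram model
#'
#' Absolute discounting with a single fixed discount at every order,
#' continuation counts for all lower-order distributions, and a final
#' interpolation with the uniform distribution over the output vocabulary so
#' that every probability is strictly positive. Types beyond the `vocab_cap`
#' most frequent (frequency ties broken lexicographically) are mapped to a
#' single unknown bucket `<unk>`.
#'
#' @param corpus List of character token vectors (or a character vector of raw
#'   sentences, which is tokenized with [tokenizeText()]). Must be non-empty.
#' @param order Model order, `1 <= order <= 7`.
#' @param discount Absolute discount in (0, 1); default 0.75.
#' @param vocab_cap Maximum vocabulary size (default unlimited).
#' @return Object of class `ngram_model`.
#' @examples
#' m <- trainNgram(list(c("a", "b", "a", "b", "a", "c")), order = 2)
#' nextDistribution(m, "a")
#' @export
trainNgram <- function(corpus, order = 5L, discount = 0.75, vocab_cap = Inf) {
  corpus <- .as_token_list(corpus)
  if (length(corpus) == 0L) stop("corpus must be non-empty")
  if (order < 1L || order > 7L) stop("order must be between 1 and 7")
  if (discount <= 0 || discount >= 1) stop("discount must be in (0, 1)")

  freq <- table(unlist(corpus))
  types <- names(freq)
  # deterministic cap: by descending frequency, ties lexicographic
  ord <- order(-as.numeric(freq), types)
  keep <- types[ord][seq_len(min(length(types), vocab_cap))]
  vocab <- sort(keep)
  out_vocab <- unique(c(vocab, .UNK))

  mapped <- lapply(corpus, function(s) ifelse(s %in% vocab, s, .UNK))
  padded <- lapply(mapped, function(s) c(rep(.BOS, order - 1L), s))

  # raw k-gram counts (grams always end at a real token)
  raw <- vector("list", order)
  for (k in seq_len(order)) {
    ctx_all <- character(0); w_all <- character(0)
    for (p in padded) {
      ends <- order:length(p)
      w_all <- c(w_all, p[ends])
      if (k == 1L) {
        ctx_all <- c(ctx_all, rep("", length(ends)))
      } else {
        ctx_all <- c(ctx_all, vapply(ends, function(e) {
          paste(p[(e - k + 1L):(e - 1L)], collapse = .SEP)
        }, character(1)))
      }
    }
    raw[[k]] <- .aggregate_grams(ctx_all, w_all)
  }

  # numerators: raw counts at the top level, continuation type counts below
  num_df <- vector("list", order)
  num_df[[order]] <- raw[[order]]
  if (order > 1L) {
    for (k in seq_len(order - 1L)) {
      hi <- raw[[k + 1L]]
      # drop the leftmost token of the higher-order context
      pos <- regexpr(.SEP, hi$ctx, fixed = TRUE)
      new_ctx <- ifelse(pos > 0L, substr(hi$ctx, pos + 1L, nchar(hi$ctx)), "")
      num_df[[k]] <- .aggregate_grams(new_ctx, hi$w, n = rep(1, nrow(hi)))
    }
  }

  num <- vector("list", order)
  den <- vector("list", order)
  n1p <- vector("list", order)
  for (k in seq_len(order)) {
    df <- num_df[[k]]
    num[[k]] <- .env_from(paste(df$ctx, df$w, sep = .SEP), df$n)
    dsum <- tapply(df$n, df$ctx, sum)
    den[[k]] <- .env_from(names(dsum), as.numeric(dsum))
    ncnt <- table(df$ctx)
    n1p[[k]] <- .env_from(names(ncnt), as.numeric(ncnt))
  }

  structure(list(order = as.integer(order), discount = discount,
                 vocab = vocab, out_vocab = out_vocab,
                 V_out = length(out_vocab),
                 num = num, den = den, n1p = n1p, num_df = num_df),
            class = "ngram_model")
}

#' @export
print.ngram_model <- function(x, ...) {
  cat("Interpolated Kneser-Ney", paste0(x$order, "-gram"), "model\n")
  cat("  vocabulary:", length(x$vocab), "types (+ <unk>)\n")
  cat("  discount:", x$discount, "\n")
  invisible(x)
}

# P(w | ctx_tokens) at level k; ctx_tokens has length k-1 (may contain <s>)
.kn_prob <- function(model, ctx_tokens, w, k = model$order) {
  if (k == 0L) return(1 / model$V_out)
  ctx <- if (k == 1L) "" else paste(ctx_tokens, collapse = .SEP)
  d <- model$discount
  denom <- .env_get(model$den[[k]], ctx)
  sub_ctx <- if (k <= 1L) character(0) else ctx_tokens[-1L]
  if (denom == 0) return(.kn_prob(model, sub_ctx, w, k - 1L))
  cnt <- .env_get(model$num[[k]], paste(ctx, w, sep = .SEP))
  n1 <- .env_get(model$n1p[[k]], ctx)
  max(cnt - d, 0) / denom +
    (d * n1 / denom) * .kn_prob(model, sub_ctx, w, k - 1L)
}

# normalize and pad a raw context for an n-gram model
.prep_context <- function(model, context) {
  context <- as.character(context)
  context <- ifelse(context %in% model$vocab | context == .BOS,
                    context, .UNK)
  padded <- c(rep(.BOS, model$order - 1L), context)
  if (model$order == 1L) character(0) else
    padded[(length(padded) - model$order + 2L):length(padded)]
}

#' Construct a probability distribution over next words
#'
#' @param mass Named numeric vector of word probabilities in (0, 1].
#' @param tail_mass Probability mass outside the stored words (after top-K
#'   truncation); `sum(mass) + tail_mass` must be 1 within 1e-8.
#' @param context_id Optional reference to the sentence prefix.
#' @return Object of class `prob_distribution`.
#' @export
probDistribution <- function(mass, tail_mass = 0, context_id = NULL) {
  if (is.null(names(mass)) || any(names(mass) == "")) {
    stop("mass must be a named vector")
  }
  if (any(mass <= 0)) stop("all stored probabilities must be > 0")
  tot <- sum(mass) + tail_mass
  if (tot > 1 + 1e-8) stop("probability mass sums to ", tot, " > 1")
  structure(list(mass = mass, tail_mass = tail_mass, context_id = context_id),
            class = "prob_distribution")
}

#' @export
print.prob_distribution <- function(x, ...) {
  top <- utils::head(sort(x$mass, decreasing = TRUE), 5L)
  cat("prob_distribution over", length(x$mass), "words (tail mass",
      format(x$tail_mass, digits = 4), ")\n")
  print(round(top, 4))
  invisible(x)
}

#' Next-word distribution given a context
#'
#' Dispatches on the provider: an [trainNgram()] model, an ARPA backoff model
#' from [readArpa()], or a serialized-distribution table from
#' [tableProvider()]. N-gram models use longest-suffix backoff when the
#' context exceeds `order - 1` tokens; sentence starts are handled by padding,
#' so the context may be empty.
#'
#' @param provider A probability provider.
#' @param context Character vector of preceding tokens (may be empty).
#' @param ... Passed to methods; `tableProvider` lookups need `sentence_id`
#'   and `position`.
#' @return A `prob_distribution`.
#' @export
nextDistribution <- function(provider, context = character(0), ...) {
  UseMethod("nextDistribution")
}

#' @export
nextDistribution.ngram_model <- function(provider, context = character(0), ...) {
  ctx <- .prep_context(provider, context)
  p <- vapply(provider$out_vocab, function(w) .kn_prob(provider, ctx, w),
              numeric(1))
  probDistribution(p, tail_mass = 0)
}

# single-word probability, used by the evaluation harness
.provider_word_prob <- function(dist, w) {
  p <- dist$mass[w]
  if (is.na(p)) p <- if (dist$tail_mass > 0) dist$tail_mass else 1e-12
  unname(p)
}

.argmax_word <- function(dist) {
  m <- max(dist$mass)
  # deterministic tie-break: lexicographically smallest word form
  min(sort(names(dist$mass)[dist$mass == m]))[1]
}

#' Serialized distribution provider
#'
#' Wraps a list of per-position distribution records (as produced by an
#' external model, e.g. a neural LM) into a provider keyed on
#' `(sentence_id, position)`.
#'
#' @param records List of records, each a list with elements `sentence_id`,
#'   `position`, `mass` (named numeric), and `tail_mass`.
#' @return Object of class `table_provider`.
#' @seealso [readProviderJsonl()]
#' @export
tableProvider <- function(records) {
  e <- new.env(parent = emptyenv())
  for (r in records) {
    key <- paste(r$sentence_id, r$position, sep = ":")
    e[[key]] <- probDistribution(unlist(r$mass),
                                 tail_mass = r$tail_mass %||% 0,
                                 context_id = key)
  }
  structure(list(env = e, n = length(records)), class = "table_provider")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param sentence_id,position Lookup key for table providers.
#' @rdname nextDistribution
#' @export
nextDistribution.table_provider <- function(provider, context = character(0),
                                            sentence_id, position, ...) {
  key <- paste(sentence_id, position, sep = ":")
  d <- provider$env[[key]]
  if (is.null(d)) stop("no stored distribution for ", key)
  d
}

#' Read / write distribution providers as JSON-lines
#'
#' One record per line with fields `sentence_id`, `position`, `mass`
#' (word-to-probability map, top-K truncated), and `tail_mass`.
#'
#' @param path File path.
#' @return `readProviderJsonl` returns a `table_provider`.
#' @export
readProviderJsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- lapply(lines, function(l) {
    r <- jsonlite::fromJSON(l)
    list(sentence_id = r$sentence_id, position = r$position,
         mass = unlist(r$mass), tail_mass = r$tail_mass %||% 0)
  })
  tableProvider(records)
}

#' @param records List of provider records (see [tableProvider()]).
#' @rdname readProviderJsonl
#' @export
writeProviderJsonl <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (r in records) {
    line <- jsonlite::toJSON(list(sentence_id = r$sentence_id,
                                  position = r$position,
                                  mass = as.list(r$mass),
                                  tail_mass = r$tail_mass %||% 0),
                             auto_unbox = TRUE, digits = NA)
    writeLines(line, con, useBytes = TRUE)
  }
  invisible(path)
}

#' Evaluate a provider on held-out sentences
#'
#' Accuracy is the share of scored tokens for which the target is the argmax
#' of the provider's distribution (ties broken by the lexicographically
#' smallest form); perplexity is `exp(-mean(log p(target)))`. Sentence-initial
#' tokens and punctuation tokens are never scored. For n-gram models,
#' out-of-vocabulary targets are scored as the unknown bucket.
#'
#' @param provider An `ngram_model`, `arpa_model`, `table_provider`, or a
#'   function `(context, sentence_id, position) -> prob_distribution`.
#' @param test_corpus List of token vectors (or raw character sentences).
#' @param ids Sentence identifiers (needed for table providers); defaults to
#'   `seq_along(test_corpus)`.
#' @return List with elements `accuracy`, `perplexity`, `n_evaluated`.
#' @export
evaluateModel <- function(provider, test_corpus, ids = NULL) {
  test_corpus <- .as_token_list(test_corpus)
  if (length(test_corpus) == 0L) stop("test corpus must be non-empty")
  if (is.null(ids)) ids <- seq_along(test_corpus)
  logp <- numeric(0)
  hits <- logical(0)
  for (i in seq_along(test_corpus)) {
    toks <- test_corpus[[i]]
    if (length(toks) < 2L) next
    for (pos in 2L:length(toks)) {
      target <- toks[pos]
      if (isPunct(target)) next
      dist <- if (inherits(provider, "table_provider")) {
        nextDistribution(provider, sentence_id = ids[i], position = pos)
      } else if (is.function(provider)) {
        provider(toks[seq_len(pos - 1L)], ids[i], pos)
      } else {
        nextDistribution(provider, toks[seq_len(pos - 1L)])
      }
      if (inherits(provider, c("ngram_model", "arpa_model")) &&
          !target %in% provider$vocab) {
        target <- .UNK
      }
      logp <- c(logp, log(.provider_word_prob(dist, target)))
      hits <- c(hits, .argmax_word(dist) == target)
    }
  }
  if (length(logp) == 0L) stop("nothing to evaluate")
  list(accuracy = mean(hits),
       perplexity = exp(-mean(logp)),
       n_evaluated = length(logp))
}

#' Unigram word-class baseline
#'
#' Class mass proportional to token counts, with morphologically ambiguous
#' tokens counted permissively (one count for every class among a token's
#' analyses). Used to score the mean class probability a context-free
#' baseline would assign to a stimulus set.
#'
#' @param forms Character vector of corpus tokens.
#' @param lexicon A `morph_lexicon`.
#' @return Named numeric vector of per-class probabilities (shares of the
#'   token count; sums to 1 when the lexicon is unambiguous, may exceed 1
#'   under ambiguity).
#' @export
unigramClassBaseline <- function(forms, lexicon) {
  if (length(forms) == 0L) stop("tagged corpus must be non-empty")
  counts <- setNames(numeric(length(wordClasses())), wordClasses())
  for (f in forms) {
    for (cl in unique(analyze(f, lexicon)$word_class)) {
      counts[cl] <- counts[cl] + 1
    }
  }
  counts / length(forms)
}

# ---------------------------------------------------------------------------
# ARPA export / import

.split_key <- function(key) strsplit(key, .SEP, fixed = TRUE)[[1]]

#' Write an n-gram model in ARPA format
#'
#' The listed probabilities are the full interpolated Kneser-Ney values and
#' the backoff weights are the interpolation weights, so a backoff evaluation
#' of the exported file reproduces the model's probabilities exactly (up to
#' printed precision). Context-only entries (grams ending in the padding
#' symbol) are written with the conventional dummy probability of -99.
#'
#' @param model An `ngram_model`.
#' @param path Output file.
#' @export
writeArpa <- function(model, path) {
  order <- model$order
  d <- model$discount
  entries <- vector("list", order)
  for (k in seq_len(order)) {
    keys <- paste(model$num_df[[k]]$ctx, model$num_df[[k]]$w, sep = .SEP)
    keys <- sub(paste0("^", .SEP), "", keys)  # level-1 keys have empty ctx
    if (k == 1L) keys <- unique(c(keys, model$out_vocab))
    if (k < order) {
      # contexts of the level above must be listed to carry backoff weights
      ctxs <- unique(model$num_df[[k + 1L]]$ctx)
      ctxs <- ctxs[ctxs != ""]
      keys <- unique(c(keys, ctxs))
    }
    entries[[k]] <- sort(keys)
  }
  lines <- c("\\data\\",
             sprintf("ngram %d=%d", seq_len(order), lengths(entries)), "")
  for (k in seq_len(order)) {
    lines <- c(lines, sprintf("\\%d-grams:", k))
    for (key in entries[[k]]) {
      toks <- .split_key(key)
      w <- toks[length(toks)]
      ctx <- toks[-length(toks)]
      lp <- if (w == .BOS) -99 else
        log10(.kn_prob(model, ctx, w, k))
      fields <- c(sprintf("%.10g", lp), paste(toks, collapse = " "))
      if (k < order) {
        denom <- .env_get(model$den[[k + 1L]], key)
        if (denom > 0) {
          bow <- d * .env_get(model$n1p[[k + 1L]], key) / denom
          fields <- c(fields, sprintf("%.10g", log10(bow)))
        }
      }
      lines <- c(lines, paste(fields, collapse = "\t"))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "\\end\\")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read an ARPA backoff model
#'
#' @param path ARPA file.
#' @return Object of class `arpa_model`, usable with [nextDistribution()] and
#'   [evaluateModel()].
#' @export
readArpa <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lp <- new.env(parent = emptyenv())
  bw <- new.env(parent = emptyenv())
  order <- 0L
  k <- 0L
  vocab <- character(0)
  for (line in lines) {
    line <- trimws(line)
    if (line == "" || line == "\\data\\" || line == "\\end\\") next
    if (grepl("^ngram \\d+=", line)) next
    m <- regmatches(line, regexec("^\\\\(\\d+)-grams:$", line))[[1]]
    if (length(m) == 2L) {
      k <- as.integer(m[2])
      order <- max(order, k)
      next
    }
    fields <- strsplit(line, "\t")[[1]]
    toks <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
    key <- paste(toks, collapse = .SEP)
    lp[[key]] <- as.numeric(fields[1])
    if (length(fields) >= 3L) bw[[key]] <- as.numeric(fields[3])
    if (k == 1L && toks[1] != .BOS) vocab <- c(vocab, toks[1])
  }
  structure(list(order = order, lp = lp, bw = bw, vocab = sort(vocab)),
            class = "arpa_model")
}

.arpa_prob <- function(model, ctx_tokens, w) {
  key <- paste(c(ctx_tokens, w), collapse = .SEP)
  v <- model$lp[[key]]
  if (!is.null(v)) return(10^v)
  if (length(ctx_tokens) == 0L) return(1e-99)
  bow <- model$bw[[paste(ctx_tokens, collapse = .SEP)]]
  (if (is.null(bow)) 1 else 10^bow) * .arpa_prob(model, ctx_tokens[-1L], w)
}

#' @export
nextDistribution.arpa_model <- function(provider, context = character(0), ...) {
  context <- as.character(context)
  context <- ifelse(context %in% provider$vocab | context == .BOS,
                    context, .UNK)
  padded <- c(rep(.BOS, provider$order - 1L), context)
  ctx <- if (provider$order == 1L) character(0) else
    padded[(length(padded) - provider$order + 2L):length(padded)]
  p <- vapply(provider$vocab, function(w) .arpa_prob(provider, ctx, w),
              numeric(1))
  probDistribution(p, tail_mass = max(0, 1 - sum(p)))
}

#' @export
print.arpa_model <- function(x, ...) {
  cat("ARPA backoff model, order", x$order, ",",
      length(x$vocab), "vocabulary entries\n")
  invisible(x)
}
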