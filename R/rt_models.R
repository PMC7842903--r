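# Hierarchical lognormal models of fixation durations: tiered predictor
# sets, penalized-likelihood fitting with varying intercepts for
# participants, sentences and words, k-fold goodness-of-fit comparison, and
# the residual-complementarity analysis.

.DEPENDENTS <- c("SFD", "FFD", "GD", "TT")
.TIERS <- c("baseline", "word_class", "noun_features",
            "verb_features_present_future", "verb_features_past")

.shared_predictors <- function() {
  c("len_m1", "len_n", "len_p1", "freq_m1", "freq_n", "freq_p1",
    "sacc_amp", "landing", "is_base")
}

#' Predictor set of a model tier
#'
#' Tiers are strictly nested: each tier includes all predictors of the tiers
#' above it. The shared block is word length and log frequency for the
#' previous, current and upcoming words, the incoming saccade amplitude, the
#' landing position, and the base-form flag. The baseline tier adds the
#' lexical logit probabilities of the three words; the word-class tier adds
#' the class probabilities of the current and upcoming words; the feature
#' tiers add the morphological probabilities of the current word (gender,
#' case, number for nouns; tense plus person and number for present/future
#' verbs; tense plus gender and number for past-tense verbs).
#'
#' @param tier One of `"baseline"`, `"word_class"`, `"noun_features"`,
#'   `"verb_features_present_future"`, `"verb_features_past"`.
#' @param source `"cloze"` or `"corpus"`.
#' @return Character vector of column names in the analysis table.
#' @export
tierPredictors <- function(tier = .TIERS, source = c("cloze", "corpus")) {
  tier <- match.arg(tier)
  source <- match.arg(source)
  q <- function(stem, suf) paste0("q_", stem, source, "_", suf)
  preds <- c(.shared_predictors(),
             q("", "m1"), q("", "n"), q("", "p1"))
  if (tier == "baseline") return(preds)
  preds <- c(preds, q("class_", "n"), q("class_", "p1"))
  if (tier == "word_class") return(preds)
  feats <- switch(tier,
                  noun_features = c("gender", "case", "number"),
                  verb_features_present_future = c("tense", "person", "number"),
                  verb_features_past = c("tense", "gender", "number"))
  c(preds, paste0("q_", feats, "_", source, "_n"))
}

#' Specify one duration model
#'
#' @param dependent One of `"SFD"`, `"FFD"`, `"GD"`, `"TT"`.
#' @param tier Model tier, see [tierPredictors()].
#' @param source Probability source, `"cloze"` or `"corpus"`.
#' @param predictors Optional explicit predictor column list overriding the
#'   tier set (used e.g. for permutation controls).
#' @return Object of class `duration_model_spec`.
#' @export
durationModelSpec <- function(dependent = .DEPENDENTS, tier = .TIERS,
                              source = c("cloze", "corpus"),
                              predictors = NULL) {
  dependent <- match.arg(dependent)
  tier <- match.arg(tier)
  source <- match.arg(source)
  if (is.null(predictors)) predictors <- tierPredictors(tier, source)
  structure(list(dependent = dependent, tier = tier, source = source,
                 predictors = predictors),
            class = "duration_model_spec")
}

# rows of the table usable under a spec: positive dependent, complete
# predictors, and the tier's word-class restriction
.valid_rows <- function(table, spec) {
  ok <- !is.na(table[[spec$dependent]]) & table[[spec$dependent]] > 0
  for (p in spec$predictors) {
    if (is.null(table[[p]])) stop("predictor column missing: ", p)
    ok <- ok & !is.na(table[[p]])
  }
  ok <- ok & switch(spec$tier,
    noun_features = table$target_class_n == "noun",
    verb_features_present_future =
      table$target_class_n == "verb_finite" &
      table$target_tense_n %in% c("present", "future"),
    verb_features_past =
      table$target_class_n == "verb_finite" &
      !is.na(table$target_tense_n) & table$target_tense_n == "past",
    TRUE)
  ok & !is.na(ok)
}

.GROUPS <- c("participant_id", "sentence_id", "word_uid")

# fit log(y) ~ predictors + varying intercepts, dropping constant predictors
# and single-level grouping factors
.fit_lmm <- function(y_log, dat, predictors) {
  keep <- predictors[vapply(predictors,
                            function(p) stats::sd(dat[[p]]) > 0, logical(1))]
  dropped <- setdiff(predictors, keep)
  groups <- character(0)
  for (g in .GROUPS) {
    if (length(unique(dat[[g]])) > 1L) {
      groups <- c(groups, g)
    } else {
      warning("grouping factor '", g,
              "' has a single level; dropped (degenerate fit)")
    }
  }
  dat$.y <- y_log
  rhs <- c(if (length(keep) > 0L) keep else "1",
           sprintf("(1 | %s)", groups))
  if (length(groups) == 0L) {
    fit <- stats::lm(stats::reformulate(rhs, response = ".y"), data = dat)
    s <- summary(fit)$coefficients
    sigma <- summary(fit)$sigma
    vc <- numeric(0)
    fitted_v <- stats::fitted(fit)
  } else {
    fit <- lme4::lmer(stats::reformulate(rhs, response = ".y"), data = dat,
                      REML = TRUE,
                      control = lme4::lmerControl(calc.derivs = FALSE,
                                                  check.conv.singular =
                                                    "ignore"))
    s <- stats::coef(summary(fit))
    sigma <- stats::sigma(fit)
    vc <- unlist(lapply(lme4::VarCorr(fit), function(m) m[1, 1]))
    fitted_v <- stats::fitted(fit)
  }
  est <- s[, "Estimate"]
  se <- s[, "Std. Error"]
  coefs <- data.frame(term = rownames(s), estimate = unname(est),
                      se = unname(se),
                      lower = unname(est - stats::qnorm(0.975) * se),
                      upper = unname(est + stats::qnorm(0.975) * se),
                      stringsAsFactors = FALSE)
  if (length(dropped) > 0L) {
    coefs <- rbind(coefs,
                   data.frame(term = dropped, estimate = 0, se = NA_real_,
                              lower = NA_real_, upper = NA_real_))
  }
  list(model = fit, coefficients = coefs, sigma = sigma, varcomp = vc,
       fitted = fitted_v, dropped = dropped, groups = groups)
}

#' Fit a hierarchical lognormal fixation-duration model
#'
#' The model is `log(duration) ~ fixed effects + (1 | participant) +
#' (1 | sentence) + (1 | word) + noise`, estimated by restricted maximum
#' likelihood. Returns coefficient estimates with 95% intervals, variance
#' components, per-row log-scale residuals, and pointwise lognormal
#' predictive density contributions.
#'
#' @param table Analysis table from [buildAnalysisTable()].
#' @param dependent,tier,source,predictors See [durationModelSpec()]; a
#'   ready-made spec may be passed as `spec`.
#' @param spec Optional `duration_model_spec` overriding the other arguments.
#' @param seed Integer seed (the REML fit is deterministic; the seed is
#'   recorded for provenance).
#' @return Object of class `duration_fit`.
#' @export
fitDurationModel <- function(table, dependent = "GD", tier = "baseline",
                             source = "cloze", predictors = NULL,
                             spec = NULL, seed = 1L) {
  if (is.null(spec)) {
    spec <- durationModelSpec(dependent, tier, source, predictors)
  }
  set.seed(seed)
  rows <- which(.valid_rows(table, spec))
  if (length(rows) == 0L) stop("no usable rows for this model spec")
  dat <- table[rows, , drop = FALSE]
  if (any(dat[[spec$dependent]] <= 0)) stop("non-positive durations")
  y <- log(dat[[spec$dependent]])
  f <- .fit_lmm(y, dat, spec$predictors)
  # marginal residuals (fixed effects only) are the downstream dependent:
  # conditional residuals would have the word varying intercepts absorb the
  # word-level variance the complementarity analysis probes
  mu_marg <- if (inherits(f$model, "lm")) f$fitted else
    stats::predict(f$model, re.form = NA)
  res <- y - mu_marg
  lpd <- stats::dnorm(y, f$fitted, f$sigma, log = TRUE) - y
  structure(list(spec = spec, coefficients = f$coefficients,
                 sigma = f$sigma, varcomp = f$varcomp,
                 residuals = res, residuals_conditional = y - f$fitted,
                 lpd = lpd, rows = rows,
                 n = length(rows), model = f$model, groups = f$groups,
                 dropped = f$dropped, seed = seed),
            class = "duration_fit")
}

#' @export
print.duration_fit <- function(x, ...) {
  cat("Hierarchical lognormal model:", x$spec$dependent, "~",
      x$spec$tier, "tier,", x$spec$source, "probabilities\n")
  cat("  n =", x$n, " sigma =", round(x$sigma, 4), "\n")
  cat("  varying-intercept variances:",
      paste(names(x$varcomp), round(x$varcomp, 4), collapse = ", "), "\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  invisible(x)
}

# out-of-fold lognormal log predictive density
.holdout_lpd <- function(fitted_lmm, test_dat, y_test) {
  mu <- if (inherits(fitted_lmm$model, "lm")) {
    stats::predict(fitted_lmm$model, newdata = test_dat)
  } else {
    stats::predict(fitted_lmm$model, newdata = test_dat,
                   allow.new.levels = TRUE)
  }
  stats::dnorm(y_test, mu, fitted_lmm$sigma, log = TRUE) - y_test
}

#' Compare two duration models by k-fold cross-validation
#'
#' Rows are partitioned into `k` seeded random folds; each model is refitted
#' on the training folds and scored by its out-of-fold lognormal predictive
#' density. The difference is reported on the information-criterion
#' (deviance, -2 * elpd) scale as `delta_ic = IC_A - IC_B` together with the
#' raw elpd difference: negative `delta_ic` means model A fits better. The
#' standard error comes from the pointwise contributions and `|ratio| >= 2`
#' is flagged significant.
#'
#' @param table Analysis table.
#' @param spec_a,spec_b `duration_model_spec`s sharing the same dependent.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return Object of class `kfold_comparison` with `delta_ic`, `se`, `ratio`,
#'   `significant`, `delta_elpd`, and the per-model elpd totals.
#' @export
compareKfold <- function(table, spec_a, spec_b, k = 10L, seed = 1L) {
  stopifnot(inherits(spec_a, "duration_model_spec"),
            inherits(spec_b, "duration_model_spec"))
  if (spec_a$dependent != spec_b$dependent) {
    stop("both specs must share the same dependent measure")
  }
  rows <- which(.valid_rows(table, spec_a) & .valid_rows(table, spec_b))
  n <- length(rows)
  if (k < 2L || k > n) stop("k must be between 2 and the number of rows")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  dat <- table[rows, , drop = FALSE]
  y <- log(dat[[spec_a$dependent]])
  lpd_a <- lpd_b <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    fa <- .fit_lmm(y[tr], dat[tr, , drop = FALSE], spec_a$predictors)
    fb <- .fit_lmm(y[tr], dat[tr, , drop = FALSE], spec_b$predictors)
    lpd_a[te] <- .holdout_lpd(fa, dat[te, , drop = FALSE], y[te])
    lpd_b[te] <- .holdout_lpd(fb, dat[te, , drop = FALSE], y[te])
  }
  elpd_a <- sum(lpd_a)
  elpd_b <- sum(lpd_b)
  d <- -2 * (lpd_a - lpd_b)
  delta_ic <- sum(d)
  se <- sqrt(n * stats::var(d))
  ratio <- if (se > 0) delta_ic / se else 0
  structure(list(delta_ic = delta_ic, se = se, ratio = ratio,
                 significant = abs(ratio) >= 2,
                 delta_elpd = elpd_a - elpd_b,
                 elpd_a = elpd_a, elpd_b = elpd_b, n = n, k = k,
                 seed = seed,
                 spec_a = spec_a, spec_b = spec_b),
            class = "kfold_comparison")
}

#' @export
print.kfold_comparison <- function(x, ...) {
  cat("k-fold comparison (k =", x$k, ", n =", x$n, ")\n")
  cat(sprintf("  delta IC (A - B) = %.2f  SE = %.2f  ratio = %.2f%s\n",
              x$delta_ic, x$se, x$ratio,
              if (x$significant) "  *" else ""))
  invisible(x)
}

#' Complementary predictor columns for the residual analysis
#'
#' For a model fitted with one probability source, the complementary set is
#' the *other* source's predictors of the same tier: the three lexical
#' logits for the baseline tier, plus the two class logits for the
#' word-class tier (five), plus the three feature logits for the feature
#' tiers (eight).
#'
#' @param tier Model tier.
#' @param other_source The complementary source.
#' @return Character vector of column names.
#' @export
complementaryColumns <- function(tier, other_source) {
  tierPredictors(tier, other_source)[-seq_along(.shared_predictors())]
}

#' Residual-complementarity analysis
#'
#' Regresses the log-scale residuals of a fitted model on the complementary
#' source's probability predictors, keeping the same varying-intercept
#' structure. A predictor is "reliable" iff its 95% interval excludes zero.
#' Constant complementary predictors are flagged and reported with a zero
#' estimate and degenerate interval.
#'
#' @param fit A `duration_fit`.
#' @param table The analysis table the fit was computed from.
#' @param columns Complementary predictor columns; defaults to
#'   [complementaryColumns()] for the fit's tier and the opposite source.
#' @return Data frame with one row per predictor: `term`, `estimate`, `se`,
#'   `lower`, `upper`, `reliable`, `constant`.
#' @export
residualComplementarity <- function(fit, table, columns = NULL) {
  stopifnot(inherits(fit, "duration_fit"))
  if (is.null(columns)) {
    other <- setdiff(c("cloze", "corpus"), fit$spec$source)
    columns <- complementaryColumns(fit$spec$tier, other)
  }
  dat <- table[fit$rows, , drop = FALSE]
  for (col in columns) {
    if (is.null(dat[[col]])) stop("complementary column missing: ", col)
    if (anyNA(dat[[col]])) stop("complementary column has NAs: ", col)
  }
  if (length(fit$residuals) != nrow(dat)) {
    stop("residuals are not aligned with the table rows")
  }
  f <- .fit_lmm(fit$residuals, dat, columns)
  out <- f$coefficients
  out$constant <- out$term %in% f$dropped
  out$reliable <- !out$constant & !is.na(out$lower) &
    (out$lower > 0 | out$upper < 0)
  out$reliable[out$term == "(Intercept)"] <- NA
  out
}
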