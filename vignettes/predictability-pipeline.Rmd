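---
title: "Estimating word predictability from cloze and corpus sources and modelling fixation durations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating word predictability from cloze and corpus sources and modelling fixation durations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predread)
```

## The problem

Reading experiments routinely control for how predictable each word is from
its left context. Two families of estimates exist. *Cloze probabilities* come
from human respondents who type the most likely continuation of a sentence
prefix; the probability of a word is the share of respondents who produced
it. *Corpus-based probabilities* come from language models trained on large
text corpora. `predread` implements both routes for a morphologically rich
language setting — alongside the word form itself (*lexical* predictability)
it derives the predictability of the word's class and of individual
morphological features (gender, number, case for nouns; tense, number, and
person or gender for finite verbs) — and then quantifies how much of the
variance in eye-fixation durations each probability source explains.

## Probability derivation

**Cloze aggregation.** For a word with $n$ guesses, the lexical probability
is the share of orthographic full matches. Because a zero probability has no
logit, zeros are replaced by $1/(2n)$; symmetrically, unanimous sets are
capped at $1 - 1/(2n)$. The cap is our design choice: the smoothing rule is
stated only for zeros, but the logit transform is undefined at 1 as well,
and the symmetric bound is the minimal fix. Sentence-initial words have no
context in the cumulative cloze task, so they are excluded from the
correlation analyses; they are still aggregated internally because the
duration models need them as *neighbour* predictors.

**Corpus distributions.** The reference model is an interpolated Kneser–Ney
n-gram model (single fixed discount, default $d = 0.75$, the standard
textbook setting) with a final interpolation against the uniform
distribution over the output vocabulary, which guarantees strictly positive
probabilities that sum to one. Vocabulary can be capped to the most frequent
types (frequency ties broken lexicographically for determinism); rarer types
fall into a single `<unk>` bucket. External models — e.g. neural LMs — enter
through a serialized-distribution interface (JSON-lines keyed by sentence
and position, top-$K$ truncated with an explicit tail mass). ARPA
export/import is provided; the exported file lists full interpolated
probabilities with the interpolation weights as backoff weights, so a
backoff evaluation reproduces the model exactly.

**Morphosyntactic probabilities.** The word-class probability of a target is
the total candidate mass whose analyses share a word class with the target;
feature probabilities additionally require an equal feature value *within a
shared class* (a noun's "singular" never matches a verb's "singular" —
feature identity across classes is linguistically meaningless here, and
noun and verb features are summarised separately). Morphological ambiguity
is resolved permissively: any analysis on either side may support a match,
with no mass splitting. Feature probabilities are computed over the *total*
candidate mass by default, not renormalized within the target's class; this
is the single most result-sensitive choice, so `renormalize = TRUE` is
available as a flag. Aggregated class/feature probabilities reuse the cloze
smoothing/capping rule on the cloze side and a $10^{-9}$ floor on the
corpus side (whose truncated tail mass is treated as non-matching).

**Transforms and comparisons.** All probabilities enter analyses through the
logit transform $q = 0.5\,\ln(p/(1-p))$. The 0.5 factor is stated for the
corpus probabilities; we apply it to the cloze side too so the two sources
live on the same scale (a monotone rescaling that leaves correlations and
model comparisons unaffected). Pearson correlations are computed on logits
only, with a `drop` policy that removes smoothed-zero records and a
`smooth` policy that keeps them; Spearman is rank-based and includes
smoothed zeros. The cumulative-correlation curve reports the Pearson
coefficient over all words whose raw cloze probability falls below each
threshold, omitting points with fewer than three pairs.

## Fixation measures

From fixation-level records the package derives, per word and trial: first
fixation duration (FFD), gaze duration (GD), total reading time (TT), and
single fixation duration (SFD, defined only when the word was fixated
exactly once in the trial, in which case all four coincide). "Before the
eyes left the word" is interpreted as the standard first-pass convention:
the gaze-duration window is the maximal initial run of consecutive
fixations on the word, ended by a fixation on *any* other word, regardless
of direction. Refixations after a regression contribute to TT only.
Durations are in milliseconds, word positions 1-based, landing positions
0-based characters from word start.

Word exclusions operate in two stages: the correlation stage drops
sentence-initial words; the eyetracking stage drops initial and final
words. At the published stimulus scale (144 sentences, 1,362 words) these
rules leave 1,218 and 1,074 words respectively. Exclusion applies to the
dependent word only — neighbour predictors use the raw adjacent positions.

## The hierarchical lognormal models

Each duration measure is modelled as
$\log y \sim X\beta + u_{\text{participant}} + u_{\text{sentence}} +
u_{\text{word}} + \varepsilon$, i.e. a lognormal likelihood with varying
intercepts (no varying slopes). Predictor tiers are strictly nested:

1. *shared*: centred/scaled word length and $\log_{10}$ frequency for words
   $n-1$, $n$, $n+1$; incoming saccade amplitude; landing position;
   base-form flag;
2. *baseline*: + lexical logits of $n-1$, $n$, $n+1$;
3. *word class*: + class logits of $n$ and $n+1$;
4. *features*: + the current word's feature logits, in separate models for
   nouns (gender, case, number), present/future verbs (tense, person,
   number — person is marked only in these tenses) and past-tense verbs
   (tense, gender, number).

Estimation is restricted maximum likelihood via `lme4`; the contract
deliberately fixes only the *surface* (estimates, 95% intervals, log-scale
residuals, pointwise predictive densities), not the estimation machinery,
and REML point estimates with Wald intervals honour it deterministically.
Zero-frequency floors are $0.5$ per million; constant predictors are
dropped from a fit and reported with zero estimates; grouping factors with
a single level are dropped with a warning (degenerate fit).

**Model comparison.** Two models for the same measure are compared by
10-fold cross-validation: rows are partitioned into seeded random folds
(the fold structure is a design choice; the source analysis does not state
whether folds respect grouping), each model is refitted per fold, and the
out-of-fold lognormal log predictive density is accumulated. The difference
is reported both as a raw expected-log-predictive-density difference and on
the deviance ($-2\times$) information-criterion scale, with a standard
error from the pointwise contributions; $|\Delta IC / SE| \ge 2$ is flagged
as a significant difference. Random effects of unseen grouping levels are
predicted at zero.

**Residual complementarity.** To test whether the two probability sources
explain the same variance, the residuals of a model fitted with one source
become the dependent variable of a second model containing the *other*
source's predictors of the same tier (three lexical logits at baseline,
five columns at the word-class tier, eight at the feature tiers), with the
same varying-intercept structure. A predictor is "reliable" iff its 95%
interval excludes zero. Two residual-definition choices were genuinely
open:

* *scale* — we use log-scale residuals, consistent with the lognormal
  likelihood;
* *conditional vs marginal* — we use marginal residuals
  ($\log y - X\hat\beta$, fixed effects only). With tens of observations
  per word, the word intercept's BLUP in a conditional residual would
  absorb essentially all word-level variance, making the analysis blind to
  any word-level complementary signal by construction; marginal residuals
  keep that variance visible while the residual model's own varying
  intercepts still account for the grouping structure.

## The synthetic-data generator

The generator produces a complete, seeded, mutually consistent bundle so
that every stage is testable without external data:

* a morph-tagged lexicon (default 400 forms; 10% of forms receive a second
  analysis; class mix follows a written-language distribution with 37%
  nouns and 14% adjectives, matching the class shares a context-free
  baseline would see);
* stimuli sampled from a first-order generative chain over the lexicon
  whose exact conditional distributions are stored as ground truth (a
  richer grammar would preclude exact oracle queries); sentence lengths
  uniform on 5–13 words (mean 9), 144 sentences by default;
* cumulative cloze guesses drawn from the true distribution reweighted by
  $\exp(-\text{bias} \cdot \text{word length})$ (respondents' documented
  avoidance of long words; default bias 0.3), 20–151 guesses per word with
  mean about 47;
* corpus-provider records obtained by Dirichlet resampling of the truth
  with concentration 50 (the model is a consistently *distorted* view of
  the same distribution — infinite concentration recovers the truth
  exactly);
* fixation sequences generated from the lognormal model itself with a known
  coefficient vector (default: lexical-logit slope $\beta_q = -0.05$ per
  logit unit, intercept $\log 225$ ms, intercept SDs 0.12/0.06/0.05 for
  participants/sentences/words, residual SD 0.35 — values typical of
  log-duration analyses). Skipping probability increases with
  predictability and refixation probability decreases with it, via fixed
  logistic links; these links, the 60/40 refixation split and the
  regression-revisit probability (0.12) are test scaffolding, not
  empirical claims. Revisits never target the last fixated word, which
  would silently extend the first-pass run.

All randomness flows from one root seed through fixed named substreams, so
stages can be regenerated independently and byte-identically.

What the generator does *not* emulate: real lexical statistics (Zipfian
frequencies, orthographic neighbourhoods), long-distance syntactic or
semantic dependencies, parafoveal preview, oculomotor error, or
participant-level strategy differences. Green tests therefore certify the
*machinery* — probability bookkeeping, measure extraction, estimation and
comparison logic — not the substantive conclusions one would draw from real
reading data.

## Validation problem sizes

The test suite validates statistical behaviour at deliberately chosen
sizes: slope recovery and null calibration use the default bundle of 30
participants × 50 sentences (about 10,000 analysis rows), where the
designed $\beta_q = -0.05$ is estimated with a standard error near 0.008;
the two-source separation scenarios use 40 participants so that the
residual-complementarity effect (whose magnitude is attenuated by the
shared-signal fraction of the two sources) sits near four standard errors —
a size picked by power analysis so that the scenario discriminates reliably.
K-fold machinery checks run at 15 participants × 40 sentences with five
folds. Oracle equivalence for the Kneser–Ney implementation is checked
against a brute-force reference on random corpora of up to 300 tokens and
order ≤ 3, to $10^{-10}$.

## Numerical choices and edge cases

* Tokenization lower-cases, splits punctuation into separate tokens, and
  splits on whitespace; punctuation and sentence-initial tokens are never
  scored in evaluation. Accuracy argmax ties break to the
  lexicographically smallest form.
* Distribution invariants: each stored mass is strictly positive and
  `sum(mass) + tail_mass = 1` within $10^{-8}$.
* Perplexity is $\exp(-\text{mean}\ \log p(\text{target}))$; a provider
  that does not cover a target is scored at its tail mass (or a $10^{-12}$
  floor), which only matters for deliberately incomplete providers.
* Out-of-vocabulary targets of an n-gram model are scored as `<unk>`.
* Empty response sets, non-positive durations, unknown feature names,
  unsorted fixation indices and missing predictor columns raise immediate
  errors naming the offending unit.

## Known limitations

* The lexicon is a static table; context-free ambiguity is preserved rather
  than resolved in context, and the six core cases must be mapped by the
  lexicon builder.
* No neural language model is trained here; external models participate
  only through the serialized-distribution interface.
* Wald intervals are first-order approximations; with very small group
  counts they can undercover, which is why the calibration checks run at
  realistic group sizes.
* Lemma-level lexical matching (as opposed to exact orthographic matching)
  is out of scope.
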