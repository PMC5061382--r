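---
title: "Modelling noun compound plausibility: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling noun compound plausibility: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`ncplaus` models human plausibility judgements of two-noun compounds
("school bus" is plausible, "saddle olive" is not) from corpus-derived,
compositionally constructed meaning representations. The pipeline has four
stages:

1. **Semantic space.** A window-based distributional semantic space is built
   from a lemmatized, sentence-segmented corpus: raw co-occurrence counts in
   a ±2-token within-sentence window, positive pointwise mutual information
   (PPMI) weighting, and reduction to `d` non-negative latent dimensions by
   non-negative matrix factorization (NMF).
2. **Composition.** Compound vectors are derived from constituent
   representations. The default is the *lexical function* method: each
   modifier noun is represented as a `d x (d+1)` matrix (transform plus
   intercept) estimated by ridge regression from observed phrase vectors of
   corpus-attested compounds with that modifier. Additive, multiplicative
   and full-additive (`c = A m + B h`) composition are available as
   alternatives.
3. **Measures.** Five plausibility measures are computed per item — head
   proximity `cos(c, h)`, modifier proximity `cos(c, m)`, constituent
   similarity `cos(m, h)`, neighbourhood density (mean cosine to the k = 20
   nearest single-word neighbours), and vector entropy — together with
   lexical covariates (letter lengths, Laplace-transformed log frequencies of
   both constituents and of the pair in both orders, pointwise mutual
   information between the constituents, and positional family sizes).
4. **Analysis.** Ratings are modelled with Gaussian generalized additive
   models (GAMs, via `mgcv`): a baseline of linear covariate effects plus
   random intercepts for modifier and head lemmata is pruned by Wald tests
   and verified by likelihood-ratio tests (LRTs); measure terms are then
   added stepwise (penalized smooths and tensor-product interaction
   smooths), and the final model is stress-tested by outlier-removal refits,
   tensor-versus-linear comparisons, and non-negative-proximity refits.

Every stage can be exercised on seeded synthetic data with known ground
truth; the package treats the synthetic generators as first-class, tested
code.

## The semantic space

**Counting.** The window is flat (no distance weighting) and never crosses a
sentence boundary. Designated bigrams — the training compounds — are counted
as if they were a single token occupying two positions: their window extends
`half_window` tokens beyond either end of the two-token span, and the member
tokens are not their own context. Member tokens still count as ordinary
occurrences of the corresponding single-word targets, so the space carries
both a compound row and its constituents' rows.

**PPMI.** `max(0, log p(a,b) - log p(a) - log p(b))` with natural
logarithms; marginals are the row and column sums of the same count matrix
(rather than corpus-level unigram totals — the two differ at corpus edges
and the matrix-internal choice keeps the weighting self-contained). The log
base only rescales a linear covariate downstream.

**NMF.** No suitable factorization routine ships with the package's
dependency set, so the package implements seeded multiplicative updates
(Lee–Seung) on the Frobenius objective: uniform random initialization scaled
to the data, convergence when the relative objective change falls below
`1e-4` (floor-guarded near zero), iteration cap 500. Seed, tolerance,
iteration count and achieved relative reconstruction error are recorded in
the space's provenance, making runs exactly reproducible. The reduction is
rank-monotone in reconstruction error, which the test suite checks. A
singular-value-decomposition variant is deliberately out of scope.

**Tie-breaking.** Vocabulary truncation at rank `n_content` breaks frequency
ties alphabetically, and nearest-neighbour queries break cosine ties by row
order, so all downstream quantities are reproducible across platforms.

## Composition

**Training sets.** Candidate training pairs are adjacent token bigrams whose
first token is a designated modifier. Pairs with corpus frequency below 20,
and pairs that are themselves analysis items, are excluded; modifiers with
fewer than 50 distinct surviving pairs are dropped entirely (their items are
marked uncomposable and excluded from the models, with reasons logged).
Training pairs enter the regression once per type, not weighted by token
frequency, matching the "distinct pairs" notion of the filters.

**Estimation.** The lexical function minimizes
`sum_i ||p_i - M [h_i; 1]||^2 + lambda ||M||_F^2` in closed form via the
regularized normal equations. The intercept column is included for the
lexical function (the `d x (d+1)` parameterization names one) and omitted
for the full-additive model (its definition has none). Because the number of
training pairs per modifier is often below `d + 1`, an unregularized fit is
ill-posed; the default `lambda` is selected per modifier by generalized
cross-validation over the log grid `1e-6 ... 1e2` and recorded in the fit
diagnostics. Observed phrase vectors are rows of the *same* reduced space
(bigram rows pass through PPMI and NMF alongside single words), so composed
and observed vectors are commensurable.

**Negative entries.** Trained composition can produce negative vector
entries. They are retained; only the entropy measure clips them (to zero,
with a warning), since it needs a probability normalization.

## Measures

Entropy is implemented exactly as the nonstandard printed form
`log(n) - (1/n) sum p_i log p_i` (after normalizing the clipped vector to
the simplex): it attains its maximum at the uniform vector and decreases for
peaked vectors, which is the contrast the measure is meant to capture; the
1/n factor only compresses the scale. Neighbourhood density does not exclude
an item's own constituents from the neighbourhood by default (a switch is
provided). The pair-frequency covariates use the item's own constituent
order and its reversal separately; the PMI covariate uses the ordered-bigram
probability of the item's own order, with +1 smoothing so unattested pairs
stay finite. Frequencies default to the training corpus itself; any external
unigram/bigram table (e.g. a subtitle-corpus export) can be substituted via
`read_frequency_table()`.

The Laplace transform is `log(count + 1)` on raw counts, not per-million
normalized counts; with a single backing corpus the difference is an
additive constant absorbed by the model intercept.

## The GAM analysis

**Baseline.** Candidates enter as linear effects only (keeping the baseline
simple); random intercepts for modifier and head lemmata are always
retained. A collinearity screen first removes any candidate correlated above
.6 with an already-retained one (family sizes are typically screened out
against the log frequencies, which is the situation the threshold is
calibrated to). Wald pruning is iterative — drop the least significant term
with p >= .05, refit, repeat — rather than single-pass; the trace records
every decision, so the difference is auditable. The pruned model is then
counter-checked by LRTs in both directions (re-adding dropped terms must not
help; removing kept terms must hurt), re-admitting a dropped term if the
LRT contradicts the Wald decision.

**Likelihoods.** All selection comparisons are fitted with marginal
likelihood (`method = "ML"`): REML likelihoods are not comparable between
models that differ in fixed structure. Standalone fits default to REML.
LRTs between models differing in penalized smooths have no exact reference
distribution; the package offers two approximations. The *edf* reference
(difference in effective degrees of freedom, floored at 0.5) is used for the
criticism comparisons; in a 100-replicate calibration it proved mildly
anti-conservative for adding a penalized null smooth (8% rejection at
nominal 5%), because the fitted edf understates the complexity actually
searched over when the smoothing parameter is estimated. The *coefficient
count* reference (the full basis dimension of the added terms) is an upper
bound and therefore conservative; the stepwise acceptance rule uses it, for
the reason given below. On tables of 500 rows or more the fits use
`mgcv::bam`, which produces the same penalized fits at a fraction of the
cost; below that, plain `gam`.

**Stepwise selection.** Phase one offers penalized smooth main effects of
the not-yet-included measures and tensor-product interactions among included
measures (interactions are only offered once their lower-order effects are
in the model); phase two, entered when phase one stops, offers tensor
interactions of included measures with log pair frequency — familiarity
modulation is tested after the measure effects are established. A candidate
is accepted if its LRT against the current model has p < .05 and its AIC
improves; among several such candidates the lowest AIC wins. When a tensor
term is accepted, the main-effect smooths (and linear terms) of its two
variables are absorbed into it, since a tensor-product smooth spans its
marginal bases. Only smooth mains are offered (not separate linear mains):
the thin-plate null space already contains the linear effect, so offering
both would double the multiplicity of every selection step without
enlarging the model space.

Smooths use 5 basis functions per variable (and per tensor margin) —
enough for the saturating/peaked shapes plausibility surfaces show, small
enough to keep selection stable at a few hundred to a few thousand items;
this is exposed as `k_main` / `k_tensor`.

**Selection inflation and the acceptance df.** A stepwise procedure that
tests several candidates per step has a family-wise spurious-inclusion
probability far above the per-test level: with roughly five null candidates
live across the stopping steps of a typical run, even exactly calibrated
5% tests admit at least one spurious measure term in about a quarter of
runs (1 − 0.95^5). A selection rule should control the inclusion error of
the whole scan, which is why the acceptance LRT deliberately uses the
conservative coefficient-count reference: a candidate only enters when its
likelihood gain would survive being charged for every basis function it
brings, which in simulation keeps spurious measure terms out of ~95% of
runs while leaving the power to detect the planted effects essentially
untouched (their statistics exceed either threshold by an order of
magnitude). The criticism stage then stress-tests whatever was admitted.

**Criticism.** (1) Rows whose residual exceeds 2.5 residual SDs are removed
and the same specification refitted; term significance and both
deviance-explained values are recorded. (2) Each tensor term is compared by
LRT against a model replacing it with main-effect smooths plus a linear
product interaction of the same two variables — the test of whether the
non-linearity earns its keep. (3) The model is refitted on rows with
non-negative modifier and head proximity (negative cosines having no clean
interpretation), recording significance and repeating the linearity
comparison. Refits below 50 rows abort with a diagnostic rather than
reporting unstable statistics.

## Synthetic data

The corpus generator is a topic-mixture model chosen because its expected
co-occurrence structure is analytically known: it is the package's test
harness, not a claim about English. Each lemma has a latent topic profile;
ordinary sentences sample a topic and draw words from its distribution, so
co-occurrence reflects topic proximity. With the configured rate a sentence
instead embeds a "modifier head" bigram, and its remaining words are drawn
from the distribution obtained by pushing the head's topic mixture through
the modifier's planted column-stochastic transform — making observed phrase
vectors approximate a planted linear map of head vectors, which is exactly
the structure the lexical-function regression assumes. The ledger records
the planted transforms, the per-pair context distributions, and the unigram
and bigram counts of the emitted corpus, so filter decisions can be checked
against ground truth exactly.

Default scale: 500 lemma types, 8 topics, 30,000 sentences of 3 + Poisson(6)
tokens, 6 modifiers, 40 head nouns with a 1/rank sampling skew (so pair
frequencies straddle the frequency filter), compound rate .15, and 60
attested item pairs plus their reversals. These sizes make a full pipeline
run a matter of minutes on one CPU while leaving every filter and fit
non-trivial. One consequence worth stating plainly: the full-corpus training
filters (20 occurrences, 50 distinct pairs per modifier) are arithmetically
unsatisfiable at this scale — 50 pairs of frequency 20 require 1000 compound
tokens per modifier, while .15 × 30000 / 6 = 750 exist — so the synthetic
pipeline preset scales the filters to (10, 10), which the skewed head
distribution comfortably straddles; the fidelity defaults for real corpora
remain (20, 50).
What the generator does *not* emulate: Zipfian unigram statistics beyond the
head-noun skew, polysemy, syntax, and part-of-speech structure — so passing
tests demonstrate the correctness of the machinery on data satisfying the
model's assumptions, not performance on English.

The ratings generator draws
`rating = clamp(surface(measures) + b_modifier + b_head + noise, 0, 4)` with
Gaussian random intercepts (SD 0.2) and residual noise (SD 0.35), roughly
the signal-to-noise regime of averaged human rating studies on a 0–4 scale.
The default surface `1.3 + 1.6 HP exp(-(MP - 0.55)^2 / (2 * 0.18^2))` is a
ridge rising in head proximity whose height is peaked at medium modifier
proximity — high plausibility needs a clear head contribution and a
clear-but-not-redundant modifier one. Its interaction content is of the
same order as its main effects (about 0.3 SD of the linear predictor), the
regime in which rating studies report such interactions; it is genuinely
non-additive and non-bilinear, so a tensor-product smooth can represent it
and neither additive mains nor a linear product can. The recovery and
criticism simulations use it.

Part-of-speech filtering of real corpora is out of scope: synthetic corpora
carry no POS tags, so the vocabulary builder accepts an optional stop-list /
suffix filter instead of a tagger — a stated fidelity deviation from
pipelines built on tagged corpora.

## Problem sizes used in the shipped checks

The validation suite uses: 50 random 8x6 matrices for the PPMI oracle; 20
random corpora of up to 200 sentences for the counting oracle; planted-map
recovery at d = 10 with 50 noiseless pairs; the default 30k-sentence corpus
for filter fidelity; 200 replicates of n = 100 for the type-I calibration of
a linear term; and 20 seeded replicates of n = 1500 items for stepwise
recovery and criticism power. These sizes were chosen so the whole suite
runs on a single CPU in well under half an hour while keeping Monte Carlo
error small relative to the bounds being checked.

## Known limitations

- The NMF solution is unique only up to scaling/permutation (and sometimes
  less); downstream quantities are cosine-based and the seed is fixed, so
  results are reproducible, but individual dimensions are not interpretable
  across runs with different seeds.
- The synthetic generator plants its modifier transforms on context
  *distributions*; PPMI and NMF are nonlinear, so the planted linearity does
  not carry exactly into the reduced space. In the generator's own topic
  coordinates, held-out composition reproduces the planted map essentially
  exactly; through the full pipeline, composed vectors track their observed
  phrase rows only approximately (cosines around .4–.8 at test scale,
  plateauing with corpus size), and the tests assert the discriminative
  property — composed vectors are far closer to their own observed rows than
  to mismatched ones — rather than near-identity.
- LRT p-values between penalized fits are approximations; the stepwise
  procedure inherits their selection inflation (see above).
- The covariate PMI and frequency measures default to the training corpus;
  with small corpora they are noisy and +1 smoothing biases PMI toward zero.
- Family sizes count distinct adjacent-bigram types, which in unfiltered
  corpora includes non-compound adjacencies; with POS-tagged input a
  noun-noun restriction would be tighter.
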