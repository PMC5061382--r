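# ncplaus

Noun compounds — two nouns adjoined into a single concept — vary enormously
in how plausible they feel: *school bus* is unremarkable, *moon colonist*
takes a moment's thought, *saddle olive* is nearly uninterpretable. `ncplaus` is an R
package for researchers in psycholinguistics and cognitive science who want
to model human plausibility judgements of such compounds from
corpus-derived, compositionally constructed meaning representations, and to
find out *which* properties of the composed meaning carry the judgement.

## What the package computes

**Semantic space.** From a lemmatized, sentence-segmented corpus the package
builds a distributional semantic space: co-occurrence counts in a ±2-token
within-sentence window, positive pointwise mutual information weighting

```
PPMI(a,b) = max(0, log p(a,b) − log p(a) − log p(b))
```

and reduction to *d* non-negative dimensions by non-negative matrix
factorization. Word similarity is the cosine,
`cos(a,b) = Σ aᵢbᵢ / (‖a‖‖b‖)`.

**Composition.** A compound vector *c* is derived from its modifier *m* and
head *h*. The default is the *lexical function* method: each modifier is an
estimated matrix **M** (d × (d+1), transform plus intercept) applied to the
head vector, `c = M·[h; 1]`, learned by ridge regression from observed
phrase vectors of corpus-attested compounds with that modifier (pairs
attested ≥ 20 times; modifiers with ≥ 50 distinct training pairs; analysis
items excluded from training). Additive (`m + h`), multiplicative (`m ⊙ h`)
and full-additive (`c = A·m + B·h`) composition are also provided.

**Plausibility measures.** Per item: head proximity `cos(c,h)`, modifier
proximity `cos(c,m)`, constituent similarity `cos(m,h)`, neighbourhood
density (mean cosine to the k = 20 nearest words), vector entropy; plus
lexical covariates (letter lengths, Laplace log frequencies of constituents
and of the pair in both orders, constituent PMI, family sizes).

**Analysis.** Ratings are modelled with Gaussian GAMs (`mgcv`): a
Wald-pruned, LRT-verified baseline of linear covariates with random
intercepts for modifier and head; stepwise addition of penalized smooth
measure terms and tensor-product interactions (accepted at α = .05 with a
conservative reference df, lowest AIC among significant candidates); and
model criticism — 2.5-SD outlier refits, tensor-versus-linear LRTs, and
non-negative-proximity refits.

Seeded synthetic generators (a topic-mixture corpus with planted
per-modifier linear transforms, and a ratings model with a known smooth
surface, random intercepts and noise) make every stage testable against
ground truth.

## Worked example

Simulate 1,500 rated items whose ratings follow a planted interaction
surface — a ridge rising in head proximity, peaked at medium modifier
proximity — plus random constituent intercepts and noise, then let the
stepwise procedure find the structure:

```r
library(ncplaus)

tab <- simulate_measure_table(1500, seed = 7)
tab <- generate_ratings(ratings_config(surface = "te_hp_mp", seed = 7), tab)

base <- fit_gam(tab, model_spec("rating", random = c("modifier", "head")),
                method = "ML")
sw <- stepwise_select(tab, base, c("head_proximity", "modifier_proximity",
                                   "constituent_similarity",
                                   "neighbourhood_density", "entropy"))
print(sw$trace)
#> step 1 [phase 1]: 5 candidates; accepted s(modifier_proximity) (AIC 2201.14 -> 1742.06)
#> step 2 [phase 1]: 4 candidates; accepted s(head_proximity) (AIC 1742.06 -> 1361.48)
#> step 3 [phase 1]: 4 candidates; accepted te(head_proximity,modifier_proximity) (AIC 1361.48 -> 1248.44)
#> step 4 [phase 1]: 3 candidates; stop (no significant candidate)
#> step 5 [phase 2]: 2 candidates; stop (no significant candidate)
print(sw$model)
#> model_spec: rating ~ te(head_proximity,modifier_proximity) + re(modifier) + re(head)
#>   n = 1500, method = ML, AIC = 1248.44, deviance explained = 0.626
```

The procedure first admits smooth main effects of the two proximities, then
replaces them with their tensor-product interaction (the planted term), and
admits none of the three null measures. Model criticism confirms the
interaction is not an artefact of outliers and genuinely non-linear:

```r
criticize_model(tab, sw$model)
#> criticism_report
#>  outlier refit: 17 rows removed; all terms significant: TRUE; deviance explained 0.626 -> 0.641
#>  tensor vs linear te(head_proximity,modifier_proximity): LRT = 111.92 (df 3.17), p = 5.97e-24
#>  non-negative-proximity refit: 0 rows removed; all terms significant: TRUE
```

The corpus side works the same way from plain text: `read_corpus()` →
`build_vocabulary()` → `count_cooccurrences()` → `ppmi()` →
`reduce_dimensions()` → `extract_training_pairs()` →
`train_lexical_functions()` → `assemble_item_table()`. `run_pipeline()`
(or `inst/scripts/run_pipeline.R` from a shell) chains all stages with
provenance logging; `pipeline_config(synthetic = TRUE)` runs it end to end
on generated data. The desk-checkable similarity example — two word vectors
counted against the contexts *sky*, *night*, *shine* —

```r
cosine(c(2, 5, 3), c(3, 1, 5))
#> [1] 0.7129052
```

i.e. .71 at two decimals: *moon* and *sun* are distributionally similar.

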