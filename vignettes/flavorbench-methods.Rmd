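---
title: "Methods: from beer chemistry to flavor and appreciation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from beer chemistry to flavor and appreciation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`flavorbench` implements a complete flavoromics analysis: from a beers ×
chemical-properties concentration matrix and accompanying sensory data to
benchmarked predictive models, model dissection, and in-silico spiking
recommendations. This vignette documents the statistical model behind each
stage, the parameters that matter, the design decisions that were genuinely
open, and what the synthetic-data generator does and does not emulate.

## The modeling problem

The data of interest are triplets over a shared set of beers:

- a predictor matrix $X$ (beers × chemical properties; concentrations in
  mg/L or assay units, plus style, ABV and optionally price metadata);
- trained-panel intensity scores on a 7-point scale, long format
  (beer, taster, session, attribute);
- consumer reviews with five numeric sub-scores (appearance, aroma, taste,
  palate, overall) and optional free text.

The goal is a regression map from $X$ to beer-level sensory responses
$y$ — either panel attribute z-scores or per-beer mean consumer scores —
followed by an attribution analysis asking *which compounds drive the
predictions*, and an intervention step that turns the attribution into
compound additions for a real beer.

## Chemistry preprocessing

Concentration data are heavy-tailed: many volatiles are near their
detection limit in most beers and high in a few styles. Preprocessing
therefore works per property:

1. **Log-transform selection.** A property is log-transformed when the
   Shapiro–Wilk test rejects normality of the raw values
   ($p < 0.05$) *and* does not reject it on the log scale — i.e. when the
   shape looks log-normal rather than normal. Testing both scales is a
   deliberate disambiguation of the looser phrase "log-transform the
   log-normal properties": testing only the raw scale would also flag
   shapes that the log transform does not fix. Both thresholds are
   configurable (`alpha`, default 0.05). Logs use $\log(x+\varepsilon)$
   with $\varepsilon$ = half the smallest positive observed value of that
   property, so below-detection zeros remain usable.
2. **Imputation.** Missing cells (rare in practice, ~0.1% in the kind of
   dataset this package targets) are replaced by the per-property mean of
   observed values. A fully missing property is an error, not a silent
   zero column.
3. **Stratified split.** Beers are split 70/30 into train and test within
   each style, using largest-remainder rounding so the global counts are
   exactly `round(n × frac)` (175/75 for a 250-beer set). Styles with a
   single beer land in train.
4. **Standardization.** Per-property mean/SD are fit on the training block
   only and applied to test beers and to any counterfactual (spiked) rows.
   Constant properties are centered with the scale forced to 1, with a
   warning.

The fitted `flv_transform` state bundles all of this (log flags, epsilons,
imputation means, centers, scales), so a raw concentration row — including
a spiked variant of a real beer — maps deterministically into model space.

Correlation analyses use Spearman's rank correlation with midrank tie
handling and pairwise-complete observations; imputing before correlating
would bias $\rho$. P-values use the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$.

## Trained panel

Tasters use the scale differently (compression, offset), so raw scores are
z-scored **per taster over all of that taster's ratings** — the scaling is
scoped to the taster, not to taster × attribute, because the bias being
removed is the person's scale use, and per-attribute scoping would erase
genuine between-attribute intensity differences. Sample (n−1) SDs are used
because per-taster counts are modest. Beer × attribute profiles are means
over whichever (taster, session) ratings exist; absent panelists reduce the
per-cell n, nothing is imputed.

Panel consistency is quantified by serving a subset of beers (12 by
default) in two sessions and running a one-way ANOVA per repeated beer ×
attribute with session as the factor; the headline number is the fraction
of tests with $p > 0.05$. The grouping (per beer × attribute rather than
pooled) is a design choice: it matches how a panel leader would ask "did
*this* beer score differently *on this attribute* across sessions?", and
under a true null it calibrates to $1-\alpha$ (checked by simulation in the
test suite at 400–2000 tests). Cells with zero variance everywhere leave
the F statistic undefined and are counted as consistent, flagged.

## Consumer reviews

Filtering keeps a review iff both of two independent language detectors
call it English (the detector outputs are part of the record; the choice of
detectors is pluggable) and its rater has at least `min_reviews` (default
100) English-consensus reviews. Activity is counted within the corpus at
hand — a platform-wide count is not observable offline — and on the
language-filtered subset, which makes the operation idempotent.

Sub-scores are centered and scaled per rater (n−1 SD; single-review or
constant raters contribute 0, with a warning) and averaged per beer.

Text mining runs through a fixed pipeline: lowercase → protect beer-context
proper terms ('Chimay', 'Lambic', ...) → slang/misspelling map → tokenize →
drop numbers and punctuation → collapse synonym groups
('floral'/'flower'/'flowery') → suffix-based lemmatization/stemming. The
order is pinned because the steps do not commute (stemming before synonym
collapse would miss group variants). The stemmer is a small rule-based one
(plural, -ing/-ed, -ity suffixes): the vocabulary of interest is a closed
sensory lexicon, so a full morphological stemmer would add dependency
weight without changing the tokens that matter. The shipped lexicon is an
illustrative default aligned with the synthetic generator; real corpora
should supply their own via `read_lexicon()`.

Sentence aspects (appearance, aroma, taste, palate, overall, irrelevant)
are predicted by a regularized multinomial logistic model on bag-of-words
counts of normalized tokens — a linear classifier is the standard baseline
for small labeled sets of short sentences, and sentences with entirely
unseen vocabulary fall back to the intercepts (class priors) instead of
failing. TFIDF enrichment then concatenates each beer's aroma/taste
sentences into one document and scores the lexicon terms with
$tf \times (\ln\frac{1+N}{1+df} + 1)$, the smoothed idf variant — pinned
explicitly because "TFIDF" alone underdetermines the formula.

## The benchmark

Ten regression families are compared: linear regression and lasso with
first-order interaction features ($x_i x_j$, $i<j$, built after
standardization and never re-standardized, so product terms stay
interpretable on the z-scale), PLS regression, AdaBoost.R2, extra trees,
gradient boosting, random forest, XGBoost, RBF-kernel support vector
regression, and a single-hidden-layer neural network. Hyperparameters are
chosen by five-fold cross-validated grid search maximizing mean R²; the
default grids are modest, desk-scale ones (trees: 100/300 estimators,
depth 3/6, learning rate 0.05/0.1; lasso: a log-spaced λ grid; PLSR:
2–20 components; SVR: C and γ log grids; ANN: width 8–32, decay 0.1/1).

Evaluation reports per-descriptor test R², a multi-output R² defined as the
uniform average of per-descriptor R² (an explicit choice; when models are
fit per attribute there is no canonical joint statistic), and the average
rank: per descriptor, models are ranked 1..M by test R² with midranks on
ties, and ranks are averaged per model. R² may be negative — a model worse
than predicting the test-set mean.

Two diagnostic experiments are built in: `stability_runs()` repeats
split + fit + Shapley dissection across seeds and tallies top-k feature
frequencies, and `augmented_experiments()` probes dataset provenance
(stacking two target sources, optionally with a binary source identifier)
and explicit style one-hot features.

## Dissection

For tree ensembles, feature importance comes from two angles:

- **MDI** (mean decrease in impurity), normalized to sum to 1, with
  lexicographic tie-breaks for reproducibility.
- **Shapley attributions** via the exact path-dependent TreeSHAP
  algorithm, implemented in C++ **in double precision** over the parsed
  trees. The implementation returns, alongside the attribution matrix, the
  double-precision evaluation of the ensemble itself, and local accuracy
  ($base + \sum_j \phi_{ij} = f(x_i)$) holds to 1e-6 on every sample — the
  boosting library's own single-precision attribution path is kept as an
  independent cross-check in the tests, not as the implementation. Split
  comparisons cast to single precision to mirror the library's traversal
  exactly. Aggregate importance is the mean absolute attribution
  (configurable to max), the convention behind the usual summary-plot
  ordering. Non-tree models fall back to a seeded Monte Carlo permutation
  estimate over a background sample.

Partial dependence clamps one or two features to a grid of equally spaced
quantiles (robust to the long right tails of concentration data; a uniform
grid over the range would spend most points where no beers live) and
averages predictions over the sample. `importance_correlation_overlap()`
compares the top-k Shapley features against the top-k by $|\rho|$ with the
target — the model-vs-conventional-statistics comparison; interaction-driven
compounds appear in the former but not the latter.

Which sample set to attribute (train, test, all) is not canonical; the
default is the training set, configurable, since that is the distribution
the trees' cover statistics describe.

## Spiking

Style-typical targets are computed on **ethanol-normalized** concentrations
(mg/L per % ABV): dividing by ABV keeps flavor balanced relative to beer
strength. Beers under 0.5% ABV — including 0.0% beers, which the workflow
must support — are normalized against that floor, flagged; the operation is
otherwise undefined at zero. Two target statistics are supported behind an
explicit flag, the 95th percentile (default; linear interpolation between
order statistics) and the mean, because both conventions are in live use
for "bring it up to style-typical" interventions; reports always name the
statistic. Plans are non-negative by construction
($addition = \max(0, target - current)$): a spiking experiment can add but
never remove. Predicted uplift applies the additions to the **raw**
concentrations and pushes both rows through the training preprocessing
state, so the counterfactual respects the log transforms.

Tasting validation uses the exact two-sided binomial test at null
proportion $\frac12$ (the sum of tail probabilities not exceeding
$P(k)$): with panels of 13–25 assessors, normal approximations are not
appropriate.

## The synthetic generator

The generator's defaults define a 250-beer study across 22 styles whose
composition mirrors the market structure such studies sample (Blond 12.4%,
Tripel 11.2%, rare styles at 1–2%, a non/low-alcohol group that exercises
the ABV floor), with 100 compounds across five origin classes.

**Chemistry** is a Gaussian copula with log-normal marginals: a latent
multivariate normal with correlation $r = 2\sin(\pi\rho_s/6)$ realizes
target Spearman correlations $\rho_s$ exactly in expectation, and
per-style additive log-shifts plant the familiar style signatures (iso-alpha
acids in hoppy styles, lactic/acetic acid in sours, dark color in stouts,
depleted esters in non/low-alcohol beers). Within-origin base correlations
(yeast 0.5, wild 0.5, hops 0.35, malt 0.3) are overridden for specific
pairs — yeast esters and alcohols correlate strongly (ethanol–ethyl acetate
0.72), bittering acids are nearly independent of aroma terpenoids and
anti-correlated with the sour-beer acids. All blocks and the assembled
matrix are validated positive semi-definite; a violating block is a named
error, never a silent projection. Note that style shifts add between-style
correlation on top of the copula targets, so empirical correlations on the
full mixed-style set can exceed the within-style targets — exactly as in
real data, where style structure inflates marginal correlations.

**Sensory surfaces** are sums of Hill terms
$2\big(\frac{x^h}{K^h+x^h}-\frac12\big)$ with $h=2$ and $K$ at the global
compound median — saturating responses that reproduce the
threshold/plateau behavior visible in partial dependence on real sensory
data — plus standardized-log linear terms (used for ethanol), planted
pairwise interactions, and antagonistic masking couplings (sweetness
suppressed by bitterness, coupling −0.45). Three appreciation drivers are
planted: ethyl acetate and lactic acid (saturating) and ethyl phenyl
acetate (linear). Ethanol is deliberately *not* a planted driver, yet
rank-correlates 0.72 with ethyl acetate — so the dissection stage faces the
same co-correlation trap that real studies report, and indeed tends to rank
ethanol highly.

**Panel scores** map latents onto the 7-point scale through per-taster
scale and bias (log-normal scale, SD 0.15; bias SD 0.4), taster noise
(SD 0.5), and a beer-level perceptual noise (SD 0.3) that is constant
across sessions — it represents unmodeled matrix effects, attenuates
chemistry–sensory correlations toward realistic levels, and by
construction does not degrade the repeated-session consistency analysis.
Scores are clipped to [1, 7] but not discretized, so the zero-noise limit
equals the response surface exactly.

**Reviews** scale the corpus down to ~40 reviews per beer (the platform
scale of ~900 per beer would dominate test runtime without changing any
property being tested; the methods are count-agnostic). The overall score
adds style biases (lagers and non/low-alcohol rated harshly, strong ales
favorably), a price bias on standardized log price, per-rater bias/scale
and review noise (SD 1.2). Rater activity is heavy-tailed: a small
prolific pool sits above the 100-review filter, a long tail below it. A
configurable 10% of reviews are non-English (or get disagreeing detector
labels). Texts are template sentences with gold aspect labels retained, and
sensory-term usage probabilities increase with the matching latent
attribute, giving free supervision for the classifier and a real signal for
TFIDF enrichment.

**What the generator does not emulate:** instrument noise and batch
effects (assumed corrected upstream), chromatogram-level structure,
realistic English prose, taster demographics, temporal drift in review
behavior, and conformity bias toward earlier ratings. Tests passing on
synthetic bundles therefore demonstrate that the *pipeline machinery* is
correct and that planted signal of realistic strength is recoverable — not
that any particular real dataset satisfies the generator's assumptions.
One visible consequence: the synthetic trained-panel appreciation is far
more predictable than real panel appreciation tends to be, because human
hedonic judgments carry idiosyncratic variance the generator does not
model.

## Numerical choices

- Log offsets: $\varepsilon$ = half the minimum positive value, per
  property.
- PSD validation tolerance: smallest eigenvalue ≥ −1e−8; Cholesky with a
  1e−10 diagonal guard.
- TreeSHAP: double-precision path algorithm; split comparisons cast to
  float to match the library's traversal; local accuracy asserted at 1e−6.
- Ranking ties: midranks for statistics, lexicographic order for
  reproducible feature lists.
- Percentiles: linear interpolation between order statistics (type 7).
- Seeds: one user seed fans out to per-stage seeds deterministically;
  regeneration is byte-identical.
- ABV floor for ethanol normalization: 0.5% v/v, flagged when used.

## Problem sizes in the test suite

The suite exercises the full default study (250 beers × 100 compounds,
16 tasters, ~12,000 reviews), 100 stability iterations of the boosted
model for planted-driver recovery, copula fidelity at n = 1000, a
2000-test null calibration for the consistency ANOVA at the invariant
level and a 400-test variant in the module tests, and exhaustive Shapley
enumeration at p ≤ 8. These sizes are chosen so the planted effects are
comfortably identifiable at study-realistic signal-to-noise.

## Known limitations

- Gradient boosting concentrates importance on one member of a correlated
  group; co-correlated compounds get artificially low MDI and Shapley
  scores. The dissection output is a ranking of *predictive* features, not
  a causal claim — interventions need validation tastings, which is why the
  spiking module carries its own binomial test machinery.
- Saturating models cannot express "too much of a good thing": predicted
  appreciation plateaus instead of declining at extreme concentrations, so
  spiking plans should stay within style-typical ranges (the p95 target
  enforces this).
- The aggregate-attribute recipes (total esters, caloric value, ...) are
  configuration-defined weighted sums; shipped defaults are placeholders
  for study-specific formulas.
- AdaBoost.R2 and the TreeSHAP kernel are in-package implementations;
  both are property-tested against independent oracles (weighted-median
  behavior, exhaustive enumeration, the boosting library's attribution
  path).
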