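---
title: "Methods: a bootstrap-aggregated logistic model tree for mitochondrial missense variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a bootstrap-aggregated logistic model tree for mitochondrial missense variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apogee)
```

## The problem

Only 13 proteins are encoded by the human mitochondrial genome, yet
missense variants in them cause a disproportionate share of
mitochondrial disease (LHON, MELAS-spectrum encephalomyopathies,
maternally inherited deafness). Dozens of in-silico pathogenicity
predictors score such variants, but they disagree with each other
badly, largely because almost all of them were trained on nuclear
genes. `apogee` implements a *meta-predictor*: a classifier whose
inputs are the outputs of the upstream predictors, trained on a
curated corpus of mitochondrial variants with known status, and whose
output is an explicit probability of pathogenicity together with the
decision rule that produced it.

## The model

### Logistic model tree

The learner is a two-class logistic model tree (LMT). A binary
decision tree partitions the space of predictor scores into disjoint
regions $S_t$; each leaf $t$ carries an additive logistic model $f_t$
over a subset $V_t$ of the predictors, so the full model is

$$f(x) = \sum_{t \in T} f_t(x)\, I(x \in S_t),$$

with exactly one indicator active per instance. Classes are coded
$y = +1$ for neutral and $y = -1$ for pathogenic. Each leaf model
consists of two class functions $F_{\mathrm{neutral}}$ and
$F_{\mathrm{pathogenic}}$ constrained to sum to zero, and the
posterior is the softmax

$$P(Y = y_j \mid x) = \frac{e^{F_j(x)}}{\sum_k e^{F_k(x)}},\qquad
\sum_k F_k(x) = 0 .$$

(Some published statements of this posterior carry a spurious "$1+$"
in the denominator, which cannot normalize under the sum-to-zero
constraint; the canonical softmax is used here.) Internally the
package stores only $F = F_{\mathrm{neutral}}$, so the constraint
holds identically rather than approximately, and
$P(\mathrm{neutral}\mid x) = 1/(1 + e^{-2F(x)})$.

### LogitBoost at the leaves

Leaf models are fitted by two-class LogitBoost. Each iteration
computes working responses $z_i = (y^*_i - p_i)/(p_i(1-p_i))$ and
weights $w_i = p_i(1-p_i)$ from the current probabilities
($y^* \in \{0,1\}$, 1 = neutral), fits a one-variable weighted
least-squares regression per candidate predictor, and adds the best
one (minimum weighted SSE) to $F$ with a factor of $1/2$. The
stagewise selection is what makes $V_t$ a proper subset of the
predictors: variables never chosen keep a zero coefficient.

Numerical choices:

* probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  working-response computation, and posterior outputs are clamped to
  the same open interval so downstream accumulators never see exact 0
  or 1;
* if the half-step on the selected variable would *increase* the
  training log-loss, the step is halved (down to $1/2^{12}$ of the
  Newton step) and, failing that, the next-best variable by SSE is
  tried; boosting stops when no single-variable step improves the
  loss. The training log-loss is therefore monotone non-increasing by
  construction, and at the stopping point the model is a
  coordinate-wise optimum of the (convex) logistic loss — on small
  problems it agrees with an independently fitted logistic regression
  to numerical precision;
* no hard cap is placed on the working responses: a cap shifts the
  fixed point of the coordinate updates away from the maximum
  likelihood estimate, and the step-halving rule already provides the
  stability a cap would buy.

### Tree induction

Splits are binary and axis-aligned, chosen by information gain on the
class labels; candidate thresholds are midpoints between consecutive
distinct sorted values. Ties in gain (within $10^{-12}$) break toward
the lower feature index, then the most balanced child sizes, then the
lower threshold. The balance preference matters for symmetric
multi-modal data (an XOR-like arrangement of clusters makes *every*
axis split have zero marginal gain, and a lowest-threshold rule would
degenerate to peeling single points); for generic continuous data ties
are vanishingly rare and the rule is inert.

Recursion stops at a pure node (majority fraction $\ge$
`purity_stop`, default 1.0), an undersized node (fewer than
`min_node_size` = 15 instances), the depth cap (`max_depth`, default
unlimited), or when no candidate split exists; an impure node with no
usable split simply becomes a leaf. Each child's LogitBoost model is
warm-started from its parent's, so deep leaves refine rather than
refit. Points equal to a split threshold route left ($\le$).

The per-node iteration count defaults to a fixed 30 (the fast mode);
`lmt_control(cv_folds = 5)` instead picks the count once at the root
by stratified cross-validated log-loss over up to
`max_boost_iterations`. The fixed default is the package's choice: a
100-member bootstrap ensemble with root-level cross-validation in
every member costs roughly two orders of magnitude more fitting work
for little gain at these sample sizes, and the ensemble averaging
itself regularizes the members.

## The bootstrap ensemble

The training corpus is unbalanced (223 pathogenic vs 641 neutral
variants), so a plain fit would under-serve the pathogenic class. The
ensemble instead draws, in each of 100 iterations, $m =
\mathrm{round}(0.7 \times 223) = 156$ pathogenic indices *with
replacement* and the same number of neutral indices — a class-balanced
bootstrap. The probability that a given variant enters a given
iteration is $1 - (1 - 1/n)^m$: 50% for a pathogenic variant
($n = 223$) and 22% for a neutral one ($n = 641$), to the nearest
percent.

```{r inclusion}
m <- round(0.7 * 223)
round(100 * expected_inclusion_frequency(223, m))
round(100 * expected_inclusion_frequency(641, m))
```

Per iteration, an LMT is fitted to the in-bag sample and the
out-of-bag (OOB) variants are scored; each variant accumulates one
probability per iteration in which it was out-of-bag. The final OOB
estimate is the *mean* of those probabilities, and the call is
pathogenic iff the mean strictly exceeds 0.5 (a mean of exactly 0.5
is neutral). A variant never out-of-bag — practically impossible at
100 iterations but handled anyway — receives the mean over all member
models and a `never_oob` flag. New variants are scored by the mean
over all members.

Missing predictor scores are imputed per member: column means (zeros
for dichotomized columns) fitted on that member's in-bag rows only,
never on out-of-bag rows, so OOB estimates stay honest. The master
seed deterministically spawns one sub-seed per iteration (plus spares
consumed by redraws of degenerate samples, which the balanced scheme
makes impossible in practice), and the whole run is bit-reproducible
from the master seed.

## Feature harmonization

Upstream predictors publish incommensurable outputs; the feature
layer normalizes them:

* **Numeric thresholds** (strictly greater in the harmful direction;
  equality is neutral): CADD phred > 12, MToolBox disease score >
  0.4311, COVEC weighted-majority score > 0 (a score of exactly 0 is
  neutral).
* **Categorical maps**, total over each predictor's published
  categories, with an unmapped category a hard error naming predictor
  and category. PolyPhen-2 ships in two variants — A maps "possibly
  damaging" to neutral, B maps it to harmful — because both
  conventions are used in evaluation tables. MutationAssessor maps
  low/neutral to neutral and medium/high to harmful.
* **Significance pairs**: harmful iff p-value < 0.05 *and* FDR < 0.2,
  both strict; a missing member of the pair makes the call missing.
* **Coevolution summaries**: from a symmetric matrix of
  mutual-information Z-scores, pairs with Z strictly above 6.5 are
  coevolving; each site reports the fraction of partners above the
  cut (denominator $L-1$) and the mean Z over those partners only —
  undefined, not zero, when a site has no supra-threshold partner, so
  the mean is never diluted below the cut.

Dichotomized calls encode harmful = 1, neutral = 0. Raw numeric
scores pass through unchanged. Both representations can feed the
learner because the original description does not fix which one did;
the default keeps numerics raw and dichotomizes only categorical
predictors.

## Evaluation suite

With pathogenic as the positive class: specificity TN/(FP+TN),
sensitivity TP/(TP+FN), accuracy (TP+TN)/N, precision TP/(TP+FP), FDR
FP/(TP+FP) (the complement of precision — not a multiple-testing
quantity), Matthews correlation coefficient, and the
misclassification rate MCR = 100(FP+FN)/N. All denominators use N =
the variants actually predicted; calls of "no prediction" are excluded
before counting, which is what makes published per-predictor rows with
different coverage comparable. Zero denominators yield `NaN` rather
than errors (MCC's zero denominator yields 0, the common convention).
Full precision is kept internally; display rounding is half away from
zero at 2 decimals. ROC curves sweep the distinct probability values
as thresholds and integrate by the trapezoid rule, which equals the
Mann–Whitney concordant-pair statistic with ties counted half.

## The synthetic generator

`generate_dataset()` emulates the one structure the classifier
assumes: a two-class table with class-conditional score distributions
and per-predictor missingness. Numeric predictors are class-conditional
normals; categorical predictors are class-conditional Bernoulli
harmful-call rates; missing cells are independent Bernoulli draws per
column. Defaults are fixed to the study conditions: 223 pathogenic and
641 neutral rows, a panel of seven numeric scores with class means one
pooled SD apart plus three dichotomous callers (individually weak,
informative in aggregate, as real panels are), and missingness on
three columns (15%, 12%, 3%) mirroring the coverage gaps of real
predictor tables.

What the generator does *not* emulate: the correlation structure among
real predictors (real scores are highly redundant; synthetic columns
are independent given the class), heavy-tailed score distributions,
and gene-specific effects. Passing tests on synthetic data therefore
demonstrate that the machinery recovers signal that is present and
fabricates none that is absent — not that real-data accuracies are
reproduced.

One honesty property deserves a note: with identical class
distributions (no signal), a classifier trained on *balanced*
bootstrap samples converges to chance-level calls near probability
0.5, so its accuracy tends toward ~0.5 rather than toward the
majority-class rate. The property tests assert near-zero MCC and
accuracy not exceeding the majority rate, which is what
balanced-bootstrap honesty actually implies.

## Missense enumeration

`enumerate_missense()` evaluates every single-nucleotide substitution
at every coding position under the vertebrate mitochondrial genetic
code (NCBI table 2) and emits a record wherever the amino acid
changes. Overlapping genes (ATP8/ATP6, ND4L/ND4) are evaluated
independently, one record per gene. Stop gains and losses count as
amino-acid changes by default (`include_stop = FALSE` excludes them)
because the headline count of possible mitochondrial missense changes
does not document its convention. Reverse-strand genes (ND6) report
plus-strand alleles. Frame lengths not divisible by 3 after the
annotated `codon_start` adjustment are an error, so annotations with
incomplete stop codons must say so explicitly.

## Problem sizes and determinism

The test suite and the worked examples run at desk scale: ensembles of
100 members on 864-row synthetic tables (seconds on one core),
property checks on toy sets of tens of points, Monte-Carlo checks at
20,000 draws. Every stochastic step is seeded, the ensemble is
bit-reproducible from its master seed, and model JSON serialization
writes doubles at 17 significant digits so a round trip is exact.

## Known limitations

* Two-class only; no multi-class machinery.
* No cost-complexity pruning beyond the stopping rules; whether the
  original implementation pruned its trees is not reported.
* Coevolution matrices are consumed precomputed; mutual information
  is not recalculated from alignments.
* The `.632`/`.632+` bootstrap error estimators are out of scope; OOB
  aggregation is the plain leave-one-out bootstrap.
* Concordance between predictors is percent agreement over jointly
  called variants; chance-corrected agreement (kappa) is not
  implemented.
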