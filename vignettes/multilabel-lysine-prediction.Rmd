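---
title: "Predicting concurrent lysine modifications: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting concurrent lysine modifications: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lysmod)
```

## The problem

A single lysine residue can carry several post-translational modifications
over its lifetime — acetylation (A), crotonylation (C), methylation (M) and
succinylation (S) frequently co-occur at the same site, and their crosstalk
matters biologically. `lysmod` treats site prediction as a *multi-label*
problem: given the sequence neighborhood of a lysine, predict the full set
of modification types observed at that site, rather than running four
independent binary predictors.

Only 11 of the 15 non-empty combinations of the four types are admissible
categories (A, C, M, S, AC, AM, AS, CM, ACM, ACS, ACMS); the remaining four
(CS, MS, AMS, CMS) are too rare in curated data to form usable classes and
are rejected at ingest with a logged count. Each category maps to a 4-bit
label vector in (A, C, M, S) order, e.g. AC = (1, 1, 0, 0).

## Pipeline

### Windowing

Each annotated site yields a 49-residue window: the central lysine plus 24
flanking residues on each side. Annotation positions are 1-based and must
point at a K. Sites within 24 residues of a terminus are padded with `X` —
the convention treats padding as information-free filler: `X`-containing
triads contribute to no frequency count and encode to feature value 0.
Dropping terminal-proximal sites instead would silently bias the dataset
against short proteins. Non-standard residues (B, J, O, U, Z) are likewise
normalized to `X` with a warning rather than discarding the window.

Duplicate windows (identical 49-mers) are collapsed to one record; when
duplicates disagree on category, the modification sets are unioned, because
a category is defined by the full set of modifications observed at a site.
If the union falls outside the 11 admissible categories the window is
dropped with a warning — keeping either conflicting half would assert an
annotation we cannot arbitrate.

Homology reduction is deliberately out of scope: the pipeline expects FASTA
input that has already been redundancy-reduced (e.g. with CD-HIT at a 0.4
identity threshold) and only performs exact-duplicate removal itself.

### Propensity encoding

The encoder scores each of the 46 overlapping triads (3-residue words) of
the 48-residue context (central K removed). For category $t$, $F_t[i, j]$
is the frequency of triad $i$ at position $j$ among that category's
training contexts, and $FF_t[i, j]$ the same frequency over the union of
the other 10 categories. With $F = \tfrac{1}{11}\sum_t F_t$ and
$FF = \tfrac{1}{11}\sum_t FF_t$, the propensity matrix is $F - FF$: entry
$(i, j)$ is positive where triad $i$ at position $j$ is, on average,
enriched in single categories relative to their complements. A window is
encoded as the 46-vector of matrix entries at its own (triad, position)
pairs; all values lie in $[-1, 1]$.

Triads index rows through the positional formula over the alphabet
`A C D E F G H I K L M N P Q R S T V W Y` (ranks 0–19):
$\mathrm{row} = r_1 \cdot 20^2 + r_2 \cdot 20 + r_3 + 1$, a bijection onto
1..8000. For example `AGA` → 101 and `GAT` → 2017.

Two conventions are worth stating. First, the matrices are fitted on the
*training split only* and frozen into the model artifact — fitting on all
data would leak test information through the encoder. Second, per-class
frequencies always use the number of sequences as denominator; columns over
padded positions therefore sum to less than 1, which is accepted and keeps
the interpretation "fraction of training windows" intact. On padding-free
data every column of $F$ and $FF$ sums to 1 and of $F - FF$ to 0 (checked
to 1e-9 in the tests).

### Majority-class undersampling

Real training sets are dominated by acetyl-only sites — the reference
training distribution 9279:710:600:454:561:252:360:88:153:454:73 puts over
71% of all windows in one category. Training directly on such data lets
the majority gradient swamp the rare categories. The sampler replaces the
majority category's $N$ feature vectors by $k = \max(1,
\mathrm{round}(rN))$ prototypes — the centroids of a mini-batch k-means
clustering — where the undersampling ratio $r$ is the post- to
pre-sampling count ratio ($r = 0.1$ by default). Centroids are used
directly as synthetic samples ("soft" prototypes) carrying the majority
label; they are means of real points and so always lie inside the
majority class's bounding box. All other categories pass through untouched.

Mini-batch k-means follows the standard scheme: $k$ initial centers drawn
from the data; per iteration a batch of $b$ points (default 1024, capped at
$n$) is assigned to nearest centers and every touched center is replaced by
the mean of its batch members. Two points were genuinely open and decided
here: the center update uses the plain batch mean (not the count-decayed
per-center learning rate of some variants) because that is the simplest
reading of the update rule, and centers receiving no batch points are
re-seeded to a random data point. Ties in assignment break to the
lowest-index center. On small inputs with $b = n$ the algorithm's
distortion is within 5% of full-batch Lloyd's (tested against
`stats::kmeans(algorithm = "Lloyd")` over 10 seeds).

Rounding of $k$ (and of split counts) is round-half-up, so the reference
$N = 9279$ at $r = 0.1$ keeps exactly 928 prototypes.

### Classifier

The classifier is a small 1-D CNN: four (convolution → ReLU → max-pool)
blocks and one fully connected layer with four sigmoid outputs, one
probability per modification type. Only the layer counts are inherent to
the design; the remaining hyperparameters are this implementation's
conventions, all exposed in `classifier_config()`:

| parameter | default | note |
|---|---|---|
| channels | 16, 32, 64, 128 | length shrinks 46 → 23 → 11 → 5 → 2 |
| kernel / padding | 3 / 1 | length-preserving convolutions |
| pool width & stride | 2 | remainder positions dropped |
| optimizer / lr | Adam / 1e-3 | |
| epochs / batch | 100 / 64 | |
| threshold | 0.5 | boundary-inclusive |

Training minimizes binary cross-entropy,
$-\tfrac{1}{N}\sum_i [y_i \log \hat y_i + (1-y_i)\log(1-\hat y_i)]$,
averaged over samples and the four labels; probabilities are clamped to
$[10^{-7}, 1-10^{-7}]$ in the loss for numerical safety. With a
zero-initialized output layer every output is $\sigma(0) = 0.5$ and the
loss is exactly $\ln 2$, a useful self-check. Prediction thresholds each
probability at 0.5 (inclusive); the all-zero pattern is reported as "no
modification predicted" rather than forced to a label. Weight
initialization and batch order derive from the config seed, so training is
deterministic on a fixed platform. Max-pool ties break to the earliest
position. The forward/backward passes are compiled (RcppArmadillo); the
gradients are verified against central finite differences in development.

### Evaluation

Five set-based metrics compare the true label set $Y$ and predicted set
$Y^*$ per sample, averaged over $n$ samples ($M = 4$):
Aiming $|Y \cap Y^*|/|Y^*|$, Coverage $|Y \cap Y^*|/|Y|$, Accuracy
$|Y \cap Y^*|/|Y \cup Y^*|$, Absolute-True (exact-match indicator) and
Absolute-False $(|Y \cup Y^*| - |Y \cap Y^*|)/M$. The formulas never
confront an empty prediction; here a sample with $Y^* = \emptyset$
contributes 0 to Aiming (maximal penalty), the other metrics follow their
formulas with a zero intersection, and the count of empty predictions is
reported. Absolute-True ≤ Accuracy holds per sample and is asserted on
every report. Per-category exact-match tables over the 11 categories
complement the global metrics; their sample-size-weighted mean equals
Absolute-True exactly.

Cross-validation stratifies folds by the 11 categories (the natural choice
for an 11-way imbalanced label structure). Everything fitted from data —
propensity matrices, prototypes, classifier — is computed inside each
training fold; undersampling is never applied to held-out data. The ratio
sweep (`ratio_sweep()`) repeats CV across undersampling ratios with a
shared fold assignment and tabulates per-category exact-match rates, one
row per ratio and one column per category.

## The synthetic benchmark

`default_imbalanced_spec()` generates windows whose 48 context residues are
i.i.d. uniform over the 20 standard amino acids, with one distinct strong
motif per category: category $t$ plants its tripled letter (K excluded) at
context position $4(t-1)+3$ with probability 0.9. Category counts follow
the reference training ratio above, scaled by 1/10 with a floor of 8 per
category so 5-fold stratification stays feasible. The planted structure —
class-specific positional triad enrichment — is exactly the statistic the
propensity encoder is built to detect, so the benchmark exercises every
stage end to end, and its planted frequency is itself tested
($p + (1-p)/20^3$ at 3 standard errors, $n = 2000$).

Choices made once and kept: uniform background (no claim of biological
realism — the goal is exercising the math, not mimicking proteome
composition), enrichment 0.9 (strong but leaving a 10% unmarked fraction,
so classes are not trivially separable), motifs only in the context, never
across the central K.

What the benchmark does *not* model: real amino-acid composition, homology
structure between windows, correlated or overlapping motifs between
categories, and the much weaker signal of real modification sites. Passing
the synthetic experiments therefore demonstrates the pipeline's mechanics
and the direction of the undersampling effect, not attainable accuracy on
curated data.

At this scale (about 1,300 windows, the package's default experiment size)
a 5-fold CV run takes seconds per fold on one CPU. The imbalance dynamics
reproduce the qualitative behavior seen on real data: without
undersampling, the rarest categories (CM with 9 windows, ACMS with 8) are
frequently predicted at exact-match rate 0, and moving the ratio from 1.0
to 0.1 recovers them while the majority category degrades only mildly.

## Known limitations

- The encoder captures positional triad composition only; no physicochemical
  properties, PSSMs or learned embeddings.
- A CNN over a 46-vector has a limited receptive field for long-range
  dependencies between distant context positions.
- Real-data headline numbers require the curated modification database the
  original datasets were drawn from; this package ships no data and makes
  no accuracy claims beyond what its own tests compute.
- The model artifact is this package's own serialization; it does not read
  or write other tools' feature or weight formats.
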