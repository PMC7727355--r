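---
title: "Modeling incremental semantic constraint with searchlight RSA: methods and design choices"
author: "blendRSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling incremental semantic constraint with searchlight RSA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blendRSA)
```

## The scientific problem

As a listener hears a sentence unfold — a subject noun phrase (SNP, "the
experienced walker"), then a verb ("chose"), then a complement noun (CN,
"path") — each word constrains the interpretation of the words still to
come. blendRSA implements a pipeline for quantifying those constraints and
locating their neural signature in source-space electrophysiological
(EMEG) recordings:

1. **What is predicted.** Sentence-completion norms give the conditional
   probability $P(\mathrm{word} \mid \mathrm{context})$ of each
   continuation word at two points: after the SNP (study 1, verbs) and
   after the SNP + verb (study 2, complement nouns).
2. **What those predictions mean.** A topic model trained on syntactically
   sliced co-occurrence counts assigns each word a distribution over
   latent semantic topics. The *semantic blend*
   $$\mathrm{blend} = P(\mathrm{topic} \mid \mathrm{context}) =
     \sum_{\mathrm{word}} P(\mathrm{topic} \mid \mathrm{word})\,
     P(\mathrm{word} \mid \mathrm{context})$$
   summarizes the predicted semantics as a single distribution over
   topics.
3. **How strong the constraint is.** The dispersion-corrected entropy
   $$H(P) = \sum_i w_i \left[-P_i \log P_i\right]$$
   measures the uncertainty of a blend, with per-topic weights $w_i$ equal
   to the mean pairwise cosine distance among the topic's preferred words
   (its within-topic semantic dispersion). The cosine distance between the
   predicted-CN blend and the heard CN's own topic distribution gives a
   *mismatch* index of how well the prediction was met.
4. **Where and when the brain tracks it.** A spatiotemporal searchlight
   representational similarity analysis relates the trial-by-trial
   structure of these metrics (model RDMs: absolute metric differences) to
   the trial-by-trial structure of neural patterns (data RDMs: 1 − Pearson
   within each 10 mm / 30 ms searchlight), using rank-based partial
   Spearman correlation with nuisance covariates partialled out, a
   one-sample group t-map, and cluster-level sign-flip permutation
   inference.

No real recordings ship with the package. A fully seeded synthetic-data
generator emulates every input — including a controllable
representational effect injected into the source epochs — so the entire
pipeline is validated against known ground truth.

## Corpus semantics

**Local mutual information.** Raw co-occurrence counts conflate
association with lexical frequency. The package weights each cell as
$w_{ct} = n_{ct}\,\log\!\big(n_{ct} N /(r_c\, s_t)\big)$, the count times
its pointwise mutual information (natural log), with negative and
undefined values clamped to zero. Clamping keeps the weights usable as
scaled token counts for topic-model training; it is the standard LMI
definition.

**LDA by collapsed Gibbs sampling.** Each context word is one "document"
whose tokens are its target words, replicated proportionally to the LMI
weight times a scale factor (default 10, rounded). The sampler is written
in C++ with a private, seeded RNG, so training is bitwise reproducible and
independent of R's RNG state. Posterior means are Dirichlet-smoothed:
$\hat\theta_{dk} \propto n_{dk} + \alpha$ for context–topic rows,
$\hat\phi_{kw} \propto n_{kw} + \beta$ for topic–target rows, and the
topic prior $\propto n_k + \alpha$ (strictly positive by construction).
Defaults are common LDA practice — $\alpha = 50/K$, $\beta = 0.01$, 1000
sweeps — and every hyperparameter is exposed in the training
configuration. Two axes serve different roles: a context word's topic
distribution is its document row; a target word's is the Bayes inversion
$P(k \mid w) \propto \hat\phi_{kw}\, \hat p(k)$. Both are available
because either reading of "a word's topic distribution" is defensible;
the blend formulas use the context axis for intervening words (predicted
verbs constraining CNs) and the target axis for predicted target words.

## Constraint metrics

**Blends** drop out-of-vocabulary words and renormalize the remaining
weights, which preserves the simplex without inventing topic vectors for
unknown words. A blend with no resolvable word is an error, not a silent
zero.

**Dispersion weights** use the `topK = 20` most probable target words per
topic (the notion of "preferred words" is inherently a top-$k$ choice;
20 balances stability against dragging in near-zero-probability words,
and the value is configuration-exposed). A topic with fewer than two
nonzero-probability words gets weight 0 with a warning. The sign
convention follows the formula as written — more dispersed topics
contribute *more* — with an `invert` flag for the opposite reading, since
"linearly combining" dispersion with entropy does not by itself fix the
sign of the manipulation.

**Entropy is in nats.** The log base only rescales all trials by a
constant, which leaves absolute-difference model RDMs proportional and
every rank-based model fit unchanged, so nothing downstream depends on
this choice.

**Mismatch** is the plain cosine distance between two simplex vectors and
therefore lies in $[0, 1]$ for non-negative inputs. Mismatch tables are
restricted to stimuli whose heard complement word is an identified object
noun, because the model needs the target CN; under the default synthetic
design about 64% of stimuli (128 of 200) qualify, which mirrors the
DO/PP share of the modeled stimulus set.

## Searchlight RSA

**Geometry.** A searchlight centered at vertex $v$ and sample $t$
contains every vertex within 10 mm (Euclidean distance in a single
template space — the standard choice for source grids; geodesic distance
is out of scope) and every sample within 30 ms, truncated at the epoch
edges. At the default 100 Hz sampling this is a ±3-sample window.

**Data RDMs** flatten each trial's member amplitudes to one vector and
take 1 − Pearson, so they are invariant to per-trial affine amplitude
scaling. A zero-variance trial vector has no defined correlation; its
pairs are set to the maximal "no shared pattern" distance of 1, with a
warning. Each searchlight's RDM is computed from the concatenated member
amplitudes, not from member averages, so fine-grained pattern structure
within the searchlight contributes.

**Partial Spearman fits.** Lower-triangle vectors of the data, model and
covariate RDMs are tie-average rank-transformed; model and data ranks are
residualized on the covariate ranks plus an intercept by least squares;
the fit is the Pearson correlation of the residuals. With no covariates
this is exactly classical Spearman's $\rho$. Two covariates are always
partialled out in scheduled runs: the log lexical frequency of the
epoch's alignment word (absolute-difference RDM) and the repetition of
the SNP + verb combination (0/1 grouping RDM). A covariate that exhausts
the model's rank variance yields a defined fit of 0 with a warning rather
than NaN.

**Performance.** The per-center loop (windowed Pearson statistics via
cumulative sums, ranking, residualization) is compiled C++; the R-level
`dataRDM` + `partialSpearman` pair is the reference implementation, and
the test suite verifies the two routes agree at sampled centers to 1e-8.
Distances are clamped to the $[0, 2]$ contract in both routes so that
exact ties (e.g. two-feature windows with correlation ±1) rank
identically.

## Group statistics

Per center, subject fits are tested against zero with a one-sample
one-tailed t (positive direction — the model fit is predicted positive;
testing the negative direction is a configuration option, off by
default). The cluster-forming threshold is the Student-t quantile at
$1 - 0.01$ with $n-1$ degrees of freedom; supra-threshold points are
clustered by mesh-edge adjacency at the same sample and same-vertex
adjacency across neighboring samples, and each cluster is scored by its
summed t ("mass"). Undefined centers (zero across-subject variance)
count as sub-threshold.

The permutation null multiplies each subject's *whole* fit map by an
independent random sign — whole-map flips preserve the spatial covariance
of the maps under the null — and records the maximum cluster mass per
permutation (0 when nothing survives). Corrected p-values use the add-one
estimator $p = (1 + \#\{\mathrm{null} \ge \mathrm{mass}\})/(1 + n_{perm})$,
so p is never exactly 0 and the observed labeling is not otherwise added
to the null. With fewer than 5 subjects the null has at most $2^n$
distinct values and the function warns. Reports tier clusters as
significant ($p \le 0.05$), marginal ($0.05 < p \le 0.06$), or ns.

## The analysis schedule

Each model is tested only in the epochs where its constraint is
hypothesized to operate: the two SNP-based entropy models in the
subject-noun and verb epochs, the SNP + verb entropy model in the verb
and complement-noun epochs, and the mismatch model only in the
complement-noun epoch (it needs the heard CN). `analysisPlan()` expands
to these 6 entropy runs plus the mismatch run; `validateAnalysisPlan()`
rejects any other pairing. `runPlan()` derives each run's permutation
seed deterministically from the plan seed and writes a JSON manifest, so
re-running a plan reproduces every output byte for byte.

## The synthetic-data generator

The generator's defaults encode the study design the package models:
200 sentences in repetition groups of 4 sharing the SNP + verb
combination; word durations drawn from the modeled set's statistics
(subject noun 432 ± 142 ms, verb 422 ± 111 ms, complement word
401 ± 115 ms) with uniqueness points at 80% of word duration; completion
studies of 24 (stage 1) and 31 (stage 2) responses per stimulus; 100
topics; 0–600 ms epochs; a fixed complement-type mixture allocating
exactly ~64% of stimuli a true complement noun. Complement types are
allocated by largest-remainder quota rather than independent sampling
because the mixture is a design property of a stimulus set, not a random
variable.

**Completions.** Each stimulus draws a latent constraint distribution
over topics (Dirichlet, concentration 0.5); stage-1 verb responses are
multinomial draws from the induced word distribution, and stage-2 CN
responses come from the same latent distribution *sharpened* by raising
it to the power `stage2Sharpening` (default 2) and renormalizing. The
stage-1 → stage-2 entropy reduction therefore holds by construction when
sharpening exceeds 1 and is absent at exactly 1, giving a matched null
control.

**Source epochs.** The mesh is a random geometric graph (uniform points
in a 100 mm box, symmetric k-nearest-neighbor edges): sufficient for
every geometry-dependent computation (radii, adjacency, clustering) while
making no claim to cortical realism. Outside the injection the data are
iid Gaussian noise plus a smooth background shared by all trials. Inside
the injected vertex set and time window, trial $t$ receives
$\mathrm{effectSize}\,[\cos\theta_t\, u_1 + \sin\theta_t\, u_2]$, where
$u_1, u_2$ are fixed orthogonal mean-zero unit-RMS patterns and
$\theta_t$ maps the trial's true metric value affinely into $[0, \pi/2]$.
Because $1-\cos$ is monotone there, the Pearson distance between
noiseless injected trials is a strictly increasing function of the
absolute metric difference — the model RDM is recoverable by
construction. The angular code matters: patterns differing only in gain
have Pearson distance 0, so an amplitude-coded injection would be
invisible to a correlation-distance data RDM. Signal is shared across
subjects; noise is per-subject.

**What passing does and does not show.** The generator produces white
noise with a smooth common background on a random graph. Real source
estimates have strong spatial and temporal autocorrelation, inter-subject
anatomical variability, and artifact structure none of which is emulated;
calibration and recovery results on synthetic data validate the
*statistics and plumbing* of the pipeline, not its behavior on real
recordings.

## Validation design and problem sizes

The test suite validates four kinds of guarantee, at sizes chosen to be
informative at desk scale:

* **Closed forms and algebra** — uniform-blend entropy $\ln 100$, blend
  simplex conservation over 1000 random mixtures, cosine geometry.
* **Dual-route oracles** — the compiled partial-Spearman path against a
  brute-force rank-residualization oracle (200 random RDM triples, max
  deviation ≤ 1e-10), and compiled cluster labeling against a plain BFS
  connected-components oracle (50 random 30-vertex × 20-sample maps,
  exact agreement).
* **Statistical calibration** — 100 independent null datasets (200
  vertices, 61 samples, 40 trials, 12 subjects, CFT p = 0.01, 200
  permutations each): the fraction producing any cluster with corrected
  p ≤ 0.05 must lie in the exact binomial 95% band [0.017, 0.112] around
  the nominal 0.05.
* **Ground-truth recovery** — 20 datasets with the injection at effect
  size 0.8, which places the per-subject mean fit inside the injection
  near 0.15: detection (a significant cluster overlapping the injection)
  in at least 80% of datasets, with mean Dice overlap ≥ 0.5 among
  detections; and the entropy-reduction contrast, rejecting at p < 0.01
  under sharpening 2 over 100 stimuli while staying null at sharpening 1
  in ≥ 90% of 20 seeds.

The entropy-reduction blocks use a 6-topic corpus with cross-block noise
rate 1 and LDA $\alpha = 0.1$. The small $\alpha$ matters: the stage-1
blend reads smoothed context-topic rows while the stage-2 blend reads
Bayes-inverted target distributions, and heavy document-topic smoothing
would flatten the former systematically relative to the latter,
confounding the stage comparison with an axis artifact. With $\alpha$
small both axes are comparably sharp and the null control at
sharpening 1 is clean. The cross-block noise keeps the dispersion weights
away from the degenerate all-zero case that a perfectly separable corpus
produces (where every topic's preferred words share one distribution).

## Numerical choices and degenerate inputs

* Probability sums are enforced to 1e-9 by class validity; completion
  distributions renormalize exactly.
* Rank ties use average ranks everywhere (matching base R `rank`).
* Data-RDM entries are clamped to $[0, 2]$ in both computation routes so
  FP noise cannot split exact ties.
* A constant metric vector is a degenerate model RDM and errors early;
  a zero-variance residual in the partial correlation returns 0 with a
  warning rather than propagating NaN.
* Seeds: every stochastic operation takes an explicit seed; generator
  sub-seeds are derived arithmetically from the master seed so that
  stimuli, corpus, completions and epochs are independently reproducible.
* Persistence is plain text (TSV matrices at 17 significant digits plus
  JSON sidecars), which round-trips doubles bit-exactly and keeps every
  artifact diffable.

## Known limitations

* The LDA sampler is single-chain collapsed Gibbs without convergence
  diagnostics; for the identifiable block corpora used in validation this
  is ample, but real corpus work would want longer chains and multiple
  restarts.
* Spatial distance is Euclidean, not geodesic; on folded cortical
  surfaces nearby-in-space vertices can be far along the sheet.
* The permutation test assumes subject exchangeability under sign
  flipping, i.e. symmetric per-subject fit distributions under the null.
* Searchlight data RDMs are simple correlation distances; cross-validated
  estimators (e.g. crossnobis) are out of scope.
* The mismatch model requires an identified complement noun, so its RDM
  covers a subset of trials by design.
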