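---
title: "Methods: nest-centroid clustering, recursive Gap partitioning, and confirmatory LDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nest-centroid clustering, recursive Gap partitioning, and confirmatory LDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncpart)
```

## The problem and the model

Delimiting insect species from continuous morphometric data is a
clustering problem with one unusual asset: specimens arrive grouped into
nest samples, and nestmates (workers of one colony, usually sisters) are
far more alike than conspecifics at large. `ncpart` exploits this by
using nests — not species guesses — as the grouping variable of a linear
discriminant analysis, which makes the whole hypothesis-forming stage
free of prior species assumptions.

Formally, for specimens \(x_i \in \mathbb{R}^p\) (raw trait values in
µm) grouped into \(G\) nests, we estimate the pooled within-nest
covariance \(S_W\) (denominator \(n - G\)) and the between-nest scatter
of the nest means, and retain **all** \(\min(G-1, p)\) eigenvectors of
\(S_W^{-1}B\) ("cumulative" LDA — no truncation, because no variance
cutoff is given by the protocol). Scores are sphered: loadings are scaled
so the pooled within-nest covariance of the scores is the identity.
Euclidean distance in score space is therefore a Mahalanobis-type
distance with respect to within-nest variation — this convention matters
because every downstream distance depends on it, and it is the reason
the dendrogram is invariant (up to rotation/sign) under any invertible
linear remixing of the traits, a property the test suite checks
explicitly.

Nest centroids (mean score vector per nest) become the clustering units:
pairwise Euclidean distances feed an agglomerative dendrogram (Ward on
Euclidean distances, i.e. `ward.D2`; average, complete and single
linkage are available), with leaves ordered lexicographically so tied
merges are deterministic.

## Choosing the number of clusters: Gap + recursion

The Gap statistic compares \(\log W_k\) — the log pooled within-cluster
sum of squares around centroids, equivalently
\(\sum_r D_r / (2 n_r)\) over pairwise squared distances — with its
expectation over \(B\) reference datasets drawn uniformly over the
data's bounding box in the PCA-rotated frame (a plain feature-range box
is available as an option; the rotated box is more faithful for the
elongated clouds LD scores produce). The estimate is
\[
\hat k = \min\{k : \mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}\},
\qquad s_k = \mathrm{sd}_k\sqrt{1 + 1/B},
\]
with \(\mathrm{sd}_k\) the population SD of the reference
\(\log W^*_k\) values (population, not sample, so the degenerate
\(B = 1\) case yields \(s_k = 0\) rather than `NA`).

PART applies this recursively: if \(\hat k > 1\), split (with the same
base clusterer — a cut of the Ward tree, or Lloyd k-means with ten
restarts keeping the best dispersion) and re-optimize on every subset
with at least \(2 \cdot \texttt{minSize}\) cases. Final clusters smaller
than `minSize` are labelled `OUTLIER`. The recursion trace is kept on
the result so every split decision is auditable.

A known property of the one-SE selection rule deserves honesty: it
compares *adjacent* k only, starting at k = 1, so a local dip in the gap
curve (typically when the best 2-split is uninformative even though a
deeper split is excellent) stops the recursion early. Our implementation
agrees exactly with the canonical `cluster::clusGap` +
`maxSE(method = "Tibs2001SEmax")` on such profiles. The acceptance suite
measures the practical consequence: on synthetic eight-species data the
three most similar species are sometimes left merged even though k-means
at the true k would separate them almost perfectly. We deliberately did
not switch to a more aggressive selection rule (e.g. `firstSEmax`),
because the one-SE rule is the one the protocol specifies.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `linkage` | `ward` | — | Compact, even-sized clusters on Euclidean LD distances; `average` offered for reproducing alternative trees |
| `kmax` | 15 | clusters | ≈ 2× the plausible species count; recursion caps it at ⌊subset/minSize⌋ |
| `minSize` | 3 | nests | smallest defensible species hypothesis (≥ 3 nest samples); drives both the 2·minSize stopping rule and outlier labelling |
| `B` | 1000 | reference sets | the protocol's bootstrap count; tests scale down to 100 (SE of the gap, not its mean, is affected) |
| `ridge` | 0 | fraction of mean diag(S_W) | opt-in regularization for singular within-group scatter (tiny nests, collinear traits) |
| `prior` | equal | — | species hypotheses should not be weighted by how many specimens happened to be collected |
| `rho` | 0.3 | variance fraction | nest effect in the generator: nestmates more homogeneous than the species, value chosen once as biologically plausible ("often sisters"), configurable |

## Confirmation and wildcards

Hypotheses are imposed only on samples classified congruently by both
PART variants (labels matched by Hungarian assignment on the contingency
table); everything else — incongruent or outlier — is a wildcard.
Labeled specimens are evaluated by leave-one-out cross-validation of a
pooled-covariance Gaussian LDA (implemented in the package; verified
against `MASS::lda(CV = TRUE)` to 1e-6 posterior agreement in the test
suite). Wildcards are assigned from the classifier trained on all
labeled specimens and excluded from the confusion matrix. The
confirmation runs once; no iterative relabeling, because the protocol
describes a single confirmation pass.

Raw µm traits (minus the screened and partially scored ones) are the
default feature set; whether the original confirmation used raw traits
or ratios is unstated, so a ratio route is available by passing a ratio
table instead.

## Ratio extraction for keys

"Classification power" of a ratio between two taxa is operationalized as
LOOCV percent correct of a 1-D (or, for ratio pairs, 2-D) LDA on the
specimen-level ratio — the protocol's confirmatory machinery turned on a
single dimension. The full multivariate-ratio machinery (isometric size
axis, allometry correction) is *not* implemented; the package's
exhaustive ratio search plus LDA power is an operational surrogate that
reproduces the outputs keys actually print (ratio identity, per-class
mean [min, max], percent correct). Ratios are reported in the
orientation that gives the first class the larger mean, matching the
"longer/shorter" phrasing of couplets. Reduced discriminant functions
use the class-means-midpoint-at-zero intercept and unit pooled
within-class score variance, so the sign of the score is the
determination and class score means are symmetric about zero.

## What the generator emulates — and what a green test does not establish

`simulate_dataset()` draws, per specimen, head size CS from a truncated
normal and each trait ratio from a truncated normal whose variance is
split between a nest-level random effect (fraction ρ, shared by
nestmates) and specimen noise; traits are ratio × CS (CL and CWb are
reconstructed from CS and the head-shape ratio so the CS identity holds
exactly; the postocular distance uses its printed denominator CL).
Truncation is by resampling, which preserves approximate normality at
the small coefficients of variation involved.

Deliberate simplifications, and their consequences:

- **Ratios are independent given CS** (no cross-trait shape covariance;
  an optional equicorrelation knob exists). Real morphometric data have
  correlated shape deviations, which LDA exploits; independence is
  therefore conservative, and synthetic classification success slightly
  *understates* what the method achieves on comparable real data. This
  is visible in the acceptance suite: confirmatory LOOCV on the
  synthetic eight-species world is typically 97–99%, not the 100% the
  real revision reports.
- **No CW**: the published ratio table carries no parameters for head
  width including eyes, so the generator cannot emit it, and the frozen
  printed four-trait discriminant (`d4_printed()`) can only be evaluated
  on user-supplied real measurements.
- **No geography, no allometric curvature, no queens/males.**

A green synthetic test therefore establishes that the pipeline's
machinery is correct and that parameter recovery works under honest
noise; it does not certify performance on real measurement error,
allometry, or collector bias.

## Numerical choices

- Within-group scatter eigendecomposition with a relative tolerance of
  1e-10 decides singularity; the error message points at the `ridge`
  option rather than silently regularizing.
- Axis signs are fixed by making each axis's largest-magnitude loading
  positive; merge ties in the dendrogram are broken toward the
  lexicographically smallest pair of ids.
- Congruence matching uses a Hungarian solver (tested against exhaustive
  permutation search); ties yield a deterministic optimal mapping.
- `part`, `gap_statistic` and `simulate_dataset` accept a `seed` and are
  byte-identical across reruns given it; they restore the caller's RNG
  state on exit.

## Known limitations

- The one-SE Gap rule can merge genuinely distinct but adjacent
  clusters (see above); inspect the recursion trace and the dendrogram
  before accepting a cluster count.
- Partially scored characters (clypeal depression, pronotal spine
  distance) are excluded from multivariate stages by default and only
  enter pairwise diagnostics on explicit request.
- The error-variance screen needs classes with ≥ 3 specimens; with
  nests of 1–2 it is recorded as skipped rather than blocking the run.
- With two base clusterers only; no silhouette/prediction-strength
  alternatives, by design.
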