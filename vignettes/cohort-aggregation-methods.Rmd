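---
title: "Methods: measuring cohort similarity and aggregating cohorts into super-cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring cohort similarity and aggregating cohorts into super-cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cancer-detection classifiers for H&E histopathology are usually trained
either per cohort (one model per cancer type, expensive to build and
maintain) or universally (one model on everything, typically worse than the
specialized models because morphologically unrelated tissue is pooled).
Between those extremes sits a family of configurations: partition the
cohorts into $S$ *super-cohorts*, pool slides within each group, and train
one detection model per group. This package implements the full analysis
that chooses such a partition from data:

1. quantify pairwise morphological similarity between cohorts from the
   behaviour of patch classifiers,
2. cluster the cohorts hierarchically from those similarity matrices,
3. train one detection model per super-cohort for each candidate $S$, and
4. select configurations whose detection performance stays above a
   confidence bound of the fully specialized reference while reducing total
   training time.

Because the original corpus is whole-slide imagery that cannot ship with a
package, a first-class synthetic generator replaces it: cohorts of small RGB
texture patches grouped into slides, whose pairwise similarity follows a
*planted* hierarchy that the downstream analysis can be scored against.

## Similarity metrics

Four $N \times N$ matrices are built, all on validation slides (test slides
are reserved for the final partition evaluation):

* **Detection transfer $C$**: $v_{ij}$ is the slide-level AUROC on target
  cohort $i$ of the cancer-detection model trained on source cohort $j$,
  averaged over the five resampled sub-datasets. Rows are targets, columns
  sources.
* **Discrimination confusion $D_n, D_p, D_g$**: a multi-class patch model is
  trained to predict a patch's cohort of origin using only negative slides
  ($D_n$), only positive slides ($D_p$), or both ($D_g$); $v_{ij}$ is the
  mean predicted probability of cohort $j$ over patches drawn from cohort
  $i$, so each row sums to one. Cohorts that are hard to tell apart show
  large mutual confusion. This is the finite-sample view of the
  H-divergence from domain adaptation: the harder two distributions are to
  discriminate, the smaller their divergence, and `hdivergence_proxy()`
  exposes the standard $2(1 - 2\hat\varepsilon)$ map from a pairwise
  discrimination error rate.

Confidences are pooled at the patch level (mean softmax over all sampled
patches) rather than per-slide-then-per-cohort; a patch budget of 100
patches per evaluation slide reproduces the published evaluation sizes at
full scale, and the desk profile samples each slide's available patches.
Matrix orientation follows the Methods convention (rows = origin/target
$i$, columns = predicted/source $j$); the orientation strings are carried on
the object because the figure captions in the source literature are
ambiguous for the discrimination matrices.

## Slide-level inference

Patch models emit class probabilities; a slide's confidence for class $y$
is the channel-wise sum $\hat p_y = \sum_{\text{patches}} p_y$, and the
slide decision is the likelihood-ratio test
$\hat y = \mathbf{1}\{\hat p_1 / \hat p_0 \ge \eta\}$. For ROC/AUROC the
package ranks slides by the threshold-free score
$\hat p_1 / (\hat p_0 + \hat p_1)$, a strictly increasing transform of the
ratio, so the ranking-based ROC coincides with the exhaustive $\eta$ sweep
(property-tested). AUROC is computed in rank (Mann–Whitney) form with ties
credited $1/2$; the tie convention is a package choice.

## Dataset preparation

Each cohort contributes five resampled *sub-datasets* of 36 training slides
(18 positive, 18 negative) and 36 held-out slides, under three criteria:
train and held-out sets share no patient; per patient at most one positive
and one negative slide enter a sub-dataset; the held-out set is halved into
validation and test with equal classes (stratified within cohort — the
halving rule is stated only as "equal classes", so stratification is the
package's resolution). Sampling is independent across sub-datasets, so a
slide may recur between sub-datasets but never within one. The counting
identities these rules imply (4,320 slide slots for a 12-cohort corpus;
216/432 discrimination training slides per sub-dataset; 54,000 and 108,000
evaluation patches) are reproduced exactly by the acceptance suite for any
cohort count.

## Patch model and training protocol

The published experiments use a ResNet-50 V2 on 224×224 patches; the
architecture there is a scale choice, not a methodological one, and is out
of scope here. The package's patch model is a one-hidden-layer softmax
network over eleven deterministic image summaries (per-channel means and
standard deviations, horizontal/vertical luminance gradient energy,
coarse block-contrast, luminance skewness and kurtosis), with the hidden
activations serving as the penultimate-layer features used for embeddings.
What is preserved exactly is the *training protocol*:

* Adam, batch size 32;
* an epoch is a fixed number of iterations, not a data pass — 1,000
  iterations (32,000 patches) in the paper profile;
* validation accuracy measured each epoch on a fixed random patch sample
  (6,400 in the paper profile);
* early stopping when the best validation accuracy has not improved for 5
  consecutive epochs;
* augmentation per training patch: 90° rotations and horizontal flips
  (exact index permutations), then brightness (±64/255), saturation
  (±0.25) and hue (±0.04) jitter in HSV space, multiplicative contrast
  (±0.75) about the patch mean, clipped to [0, 1]. Hue/saturation jitter is
  defined in HSV and contrast about the per-patch mean — the cited
  augmentation recipe names bounds but no formulas, so the conventional
  definitions are used.
* every patch inherits its slide's label; the generator's latent per-patch
  cancer state is never visible to training, so positive-slide labels are
  noisy exactly as in slide-level supervision.

### Desk profile

The `"desk"` training profile keeps every rule but rescales the sizes so
the full analysis runs on one CPU in minutes: 50 iterations per epoch, 512
validation patches, at most 30 epochs. Two further desk-scale adjustments
are deliberate deviations from the full-scale values, made because the
model class changes: the Adam learning rate is $10^{-2}$ (the published
$10^{-3}$ is tuned to a deep CNN; the small feature network does not
approach saturation within 30 epochs at that rate), and the minimum
improvement counted by early stopping is 0.002 — one patch in 512 — because
with small validation samples a strict zero tolerance lets sampling noise
reset the patience clock indefinitely. The `"paper"` profile retains
$10^{-3}$, tolerance 0, and the full-scale sizes.

## The synthetic generator

`generate_planted_hierarchy()` fixes a rooted binary merge tree over the
cohorts (the stand-in for the unknown true relatedness). Cohort texture
parameters $\theta$ (RGB means, spatial-frequency band, blob density, blob
contrast) evolve by Brownian motion along this tree, so
$E\|\theta_i-\theta_j\|^2$ is proportional to the cophenetic distance — the
*planted similarity*, property-tested via Spearman correlation > 0.8 over
200 draws. Cancer shifts a patch's texture by `cancer_effect` along a unit
`cancer_direction` that mixes a shared global component
(`shared_cancer_weight`) with a cohort-private component; the private
components are themselves diffused along the tree so that *how* cancer
perturbs a cohort's texture also resembles its neighbours. Without that,
detection models would transfer between twins no better than between
strangers and no detection-based tree could recover the planted structure.

Patches are 32×32 RGB textures: smoothed Gaussian noise fields (bandwidth
set by $\theta$), Poisson-placed disc "blobs" with signed contrast, and iid
pixel noise, clipped to [0, 1]. Every slide additionally sits at its own
offset from the cohort centre (`slide_jitter`, default 0.2 in theta units),
shared by all its patches — the synthetic analogue of inter-patient
heterogeneity. Positive slides carry
`round(tumor_fraction * patches_per_slide)` latent-cancer patches
(`tumor_fraction` defaults to 0.7; tumor purity is not reported in the
source corpus, and a value strictly inside (0, 1) keeps the noisy-label
limitation exercisable). Defaults — 40 positive and 40 negative slides per
cohort, 16 patches per slide, `sigma_walk` 1, `cancer_effect` 1,
`shared_cancer_weight` 0.25, `slide_jitter` 0.2 — are the desk-scale study
conditions, chosen once: enough slides to satisfy the 36+36 sub-dataset
demand, and a heterogeneity level at which detection transfer degrades
with tree distance while remaining near-perfect for a model on its own
cohort.

The slide-level heterogeneity is load-bearing for the detection similarity
matrix, not cosmetic. AUROC is a rank statistic, so a mismatched model
whose decision direction is even weakly aligned with a target cohort's
cancer shift ranks that cohort's slides perfectly — without heterogeneity,
cross-cohort transfer saturates at 1.0 for roughly half of all cohort
pairs (the chance-alignment probability of low-dimensional directions) and
the transfer matrix carries no tree signal. Per-slide offsets inject
rank noise that only a well-aligned (morphologically matched) model
overcomes, so transfer AUROC grades with parameter distance as it does for
real cohorts. An alternative `direction_groups` layout that plants
near-orthogonal cancer directions per tree group is also provided; it
guarantees distinct cancer morphology in parameter space, but the texture
map's nonlinearity means parameter-space orthogonality does not carry to
feature space, and heterogeneity proved the more faithful and more robust
mechanism.

What the generator deliberately does **not** emulate: H&E stain physics,
realistic tissue morphology, scanner artefacts, inter-patient heterogeneity
within a cohort, or whole-slide spatial context. Tests passing on this
corpus demonstrate that the *analysis machinery* behaves as specified under
a known ground truth — not that the biological conclusions transfer to any
real cohort.

The acceptance fixture plants six cohorts as three tight pairs
(`planted_pairs_layout(6, pair_height = 0.01, step = 2)` with the default
generation conditions): within-pair parameter distance is an order of
magnitude below the between-pair distance, realizing the strong-separation
regime in which a correct implementation recovers the pairs from all four
similarity matrices. The discrimination-based trees do so essentially
always; the detection-based tree, built from only $N$ AUROC columns, is
the noisiest of the four and is allowed one miss across the five fixture
seeds.

## Aggregation and selection

`build_dendrogram()` applies Ward's minimum-variance method
(`stats::hclust`, `ward.D2`) to Euclidean distances between the similarity
matrix's *column* vectors; the test suite cross-checks it against a
from-scratch agglomeration that recomputes the Ward objective at every
merge. Cutting the tree at $S$ groups (`cutree`) yields the super-cohort
partition; $S = 1$ is the universal configuration and $S = N$ the
cohort-specific one, and both are *exact* specializations: one engine
trains every group model, with the model seed derived from the sorted
member-cohort signature and sub-dataset index, so the $S = N$ sweep entry
is bit-identical to the separately trained single-cohort models.

Training time is measured in epochs, never wall-clock:
$t(T) = \sum_{s \in T} \bar t(f_s)$, the sum over super-cohorts of mean
epochs across the five sub-dataset trials. A partition evaluation scores
each cohort's test slides with its group's model, averages per-cohort AUROC
over sub-datasets, and reports the grand mean with a 95% Student-$t$
halfwidth across the $N$ per-cohort means (the source is ambiguous about
whether the interval is over cohorts, trials, or both; per-cohort means are
used, matching the displayed per-cohort intervals).

`select_partitions()` gates candidates on the *lower* 95% bound of the
cohort-specific reference — one-sided, following the explicit
"better than the 95% lower CI" selection wording; the looser two-sided
"within the interval" reading is available behind a flag. Among qualifiers
it reports the minimum-training-time choice and the best-performance
choice, breaking ties toward smaller $S$ and then lexicographic matrix
kind. Ward ties (exactly equal merge costs occur only for duplicated
columns) resolve by `hclust`'s deterministic ordering.

## Numerical and engineering choices

* Patch pixel data lives in one matrix with one flat patch per column
  (channel blocks R, G, B, each column-major within the image), so a patch
  is contiguous in memory; the augmentation chain and the feature
  statistics are compiled kernels (Rcpp) operating in single passes.
* Geometric augmentation is exact (integer permutations); an identity draw
  bypasses the photometric path entirely so composition tests hold bitwise.
* Feature standardization uses moments of (a sample of) the raw training
  patches; degenerate features get a floor of $10^{-8}$ on the scale.
* `p̂_0 = p̂_1 = 0` cannot arise from normalized patch rows but is guarded
  as an error; AUROC requires both classes and errors otherwise.
* All randomness flows from one master seed through named substreams
  (hierarchy, parameters, each slide, split sampling, weight init, batch
  order, matrix patch sampling), so every artifact is reproducible from
  `(config, seed)` and sub-streams are independent of evaluation order.

## Problem sizes

The shipped tests and the acceptance script run the six-cohort fixture (480
slides, 7,680 patches of 32×32) with the desk profile: roughly 45 patch
models per seed for the four similarity matrices, plus the $S \in \{1,3,6\}$
sweep at one seed, a few minutes each on one CPU. Unit tests use 2–4 cohort
corpora with 8×8 patches. The paper-scale profile (12 cohorts, ResNet-scale
patch counts) is expressible through the same configuration objects but is
not exercised by the shipped tests.

## Known limitations

* The patch model is intentionally small; its absolute AUROCs are not
  comparable to published full-scale numbers, only the *relations* between
  configurations (specialized ≥ grouped ≥ universal, time savings from
  fewer models) are meaningful here.
* Discrimination-based similarity is estimated from few validation slides
  per cohort at desk scale; with weak planted separation the detection
  based tree is the noisiest of the four, which mirrors its construction
  from only $N$ AUROC columns.
* The synthetic corpus has exchangeable patients within a cohort; the
  patient-exclusivity machinery is therefore only stress-tested through the
  optional paired-patient mode.
* `embed_features()` is decorative (UMAP via uwot when present, PCA
  otherwise); no downstream computation consumes the embedding.
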