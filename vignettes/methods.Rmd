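---
title: "Methods: semantic and social content analysis for naturalistic fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic and social content analysis for naturalistic fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(natsemsoc)
```

This vignette is the package's account of its model and procedure: what each
stage computes, the assumptions behind it, the tunable parameters with their
defaults and rationale, what the synthetic-data generator does and does not
emulate, and the numerical and design choices made where the procedure left
room for them. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Word-level predictors

Unique transcript words are scored on twelve psycholinguistic properties:
number of letters, number of phonemes, phonological and orthographic
neighbourhood sizes, word frequency, concreteness, semantic neighbourhood
density, semantic diversity, emotional valence, arousal, dominance, and
socialness (a 1–5 rating of how much a word describes inter-personal
behaviour). Three exclusion rules shape the word table: closed-class words
are dropped (they carry grammatical rather than conceptual load);
high-frequency words are dropped, implemented as a configurable frequency
quantile cutoff with default 0.95 because no specific stop-list is
canonical — a quantile rule is reproducible across corpora; and words
missing more than 10 of the 12 properties are dropped as effectively
un-normable.

Socialness for words without a norm entry is extrapolated from word
embeddings: the 10 normed words with the highest cosine similarity are
located (ties broken lexicographically for determinism), negative
similarities are clipped to zero — negative weights could push a weighted
mean outside the 1–5 rating scale — and the similarity-weighted mean of
their ratings is returned. The output is therefore always bounded by the
neighbour ratings. If every neighbour similarity is non-positive the
unweighted neighbour mean is used, with a warning.

Remaining missingness is handled by chained-equation multiple imputation
with predictive mean matching (PMM): each incomplete property is regressed
on all others, and each missing cell receives the observed value of one of
the 5 donors whose predictions are closest. PMM keeps imputations inside the
observed support (a count can never be imputed negative). Defaults are 10
cycles and m = 5 completed datasets; the whole procedure is a deterministic
function of its seed. Imputation is impossible when a property has fewer
than two observed values, and that is reported as an error rather than
guessed around.

Each completed dataset enters a PCA on standardized properties (the
correlation matrix — the properties have incommensurate units, so a
covariance PCA would be dominated by whichever property has the largest
numeric scale) with varimax rotation of the first k = 4 components. The
factor count is fixed at four rather than chosen by an eigenvalue rule
because the downstream analysis is defined in terms of four named factors
(Word Length, Semantic Flexibility, Emotional Strength, Social Impact);
names are attached by which marker properties carry each rotated component's
loading mass. Factor order and sign are arbitrary in any single fit, so
before averaging across imputations each solution is aligned to the first by
maximal absolute loading congruence, greedily matched, and signed so each
factor's largest-magnitude loading is positive. The averaged rotation matrix
is projected back to the nearest orthogonal matrix (SVD), preserving the
orthogonality invariant to numerical precision. Scores use the regression
method on standardized data — the conventional default when no scoring
method is prescribed — and are averaged over imputations. Emotional Strength
is replaced by its absolute value so it indexes emotional versus neutral
content rather than valence direction.

## Event-level predictors

Events are contiguous, non-overlapping segments of a movie with semantic and
social content each rated 1–10. Two rubric constraints are machine-checkable
and enforced by `validate_events`: ratings live in [1, 10], and no event may
carry 9 or 10 on both scales at once (the top of the scale encodes the
scene's single primary purpose). Events shorter than 3 s are merged into the
subsequent event, with the pair's ratings averaged; a short event at the end
of a movie has no successor, so it merges backward — the forward rule is
simply undefined there. Runs of consecutive short events are resolved by
iterating the single-pass rule until stable. Merged ratings are kept
real-valued rather than re-rounded to the integer scale: rounding would
discard information and no rounding rule is canonical. Total rated time is
conserved exactly.

Inter-rater reliability uses Krippendorff's alpha in the coincidence-matrix
formulation, tolerant of missing ratings. The measurement level defaults to
interval — the 1–10 ratings are treated as numeric — with ordinal available;
the interval choice is the weaker assumption to disagree with for equally
spaced scales and makes alpha directly comparable to intraclass measures.
Alpha below 0.75 sets a revision flag; the consensus re-rating itself is a
human act and is represented only by that flag plus the ability to read a
rating-override file.

Words are assigned to events by onset using half-open intervals
[onset, onset + duration): a word exactly at an event boundary belongs to
the next event, and no word can be double-counted. Word durations are
ignored for membership — transcript durations are noisy and all window sums
are onset-based.

## Event-bounded sliding-window time courses

Within each event, windows of 5 s slide every 1 s, anchored at the event's
onset; a window is clipped at the event end, so events shorter than 5 s get
a single shorter window and a final sub-second portion still gets a
(slightly shorter) window rather than being discarded. No window ever spans
an event boundary, so word scores from different events are never mixed. The
window value is the sum (not the mean) of word values with onsets in the
window; sums track the total quantity of content, which matters in movies
where stretches with no speech are common.

Windows containing no scored words are removed from factor-score series
rather than zero-filled: the scores are mean-centered, so a literal zero
would assert "words of average score are present", which is wrong for an
empty window. Content-word count series keep their zeros — a count of zero
is a real observation. Factor series are then residualized, per movie, on
the total word count per window (ordinary least squares with intercept), so
the residual series is exactly orthogonal to word quantity within each
movie; per-movie fitting is used because speech-rate regimes differ between
films and each subject watched a single film. Constant counts make the
regression degenerate; the residuals then reduce to mean-centered values,
with a warning.

## Subject-level GLMs

The hemodynamic response is modelled by a double-gamma kernel with a 5 s
peak, 15 s undershoot, 1:6 undershoot ratio, unit peak, truncated at 32 s —
a standard canonical form, fully configurable since nothing in the procedure
depends on its exact shape. Convolution happens on a 0.1 s oversampled grid
(window starts are at integer seconds but event onsets are sub-second) and
is then sampled at the TR grid. TR defaults to 1 s and is configurable.

Word-level predictors enter as parametric modulators: window values are
mean-centered over the retained windows and placed as impulses at window
start times (the start is the convention chosen; centers or ends would shift
everything by a constant lag absorbed by the HRF's breadth). Centering
decorrelates "content intensity" from "stimulus present". Event-level
predictors use a duration-modulated model with three regressors: an
unmodulated boxcar spanning every event (onset, duration), the boxcar scaled
by the mean-centered rating of interest, and the boxcar scaled by the
mean-centered other rating as a nuisance. The explicit baseline is required:
without it the modulated regressor would confound rating variation with the
mere presence of events.

The voxelwise fit is OLS inside the brain mask with polynomial drift columns
of configurable order; the default is order 0 (intercept only) because the
pipeline assumes detrended, motion-censored input — a censor vector is
accepted and censored volumes are dropped from the fit. Rank-deficient
designs are refused with the collinear columns named. Residual spatial
smoothness is estimated per axis from the lag-one autocorrelation of
standardized residuals under a Gaussian autocorrelation model and reported
as the voxel-width-composed FWHM, sqrt(FWHM_kernel² + voxel²): with that
convention unsmoothed white noise reports approximately one voxel width, and
the null-field simulator below can recover the kernel exactly by inverting
the composition.

## Group inference

The group map fits, at each voxel, an intercept-only linear mixed model to
the subject statistic values with a random intercept of movie, by profiled
REML. With one observation per subject per voxel, a subject random intercept
is not separately identifiable and is absorbed into the residual — this
preserves the movie-level dependence that matters for generalizing across
stimuli while remaining estimable. The fixed effect is converted to z via
the t distribution with movies − 1 degrees of freedom when the movie
variance is positive (the intercept is effectively estimated from movie
means), and n − 1 when the variance component collapses to zero, in which
case the statistic equals the one-sample t. This df choice is deliberately
conservative for small movie counts. Voxels with zero variance are capped at
|z| = 40 with a warning rather than returned infinite. Each content type is
analysed in its own model, matching how the results are reported, rather
than as levels of one multi-factor model.

Cluster-extent FWE correction is Monte-Carlo: Gaussian white-noise fields
are smoothed to the estimated group smoothness (median of subject FWHM
estimates — the median resists the occasional unstable subject estimate),
thresholded at the cluster-forming quantile (p < 0.01, applied bisided:
positive and negative supra-threshold voxels form separate clusters under
faces-only NN = 1 connectivity, with positive clusters the reported ones),
and the (1 − FWE p) quantile of the max-cluster-size distribution gives the
minimum cluster size. The simulator uses a pure Gaussian kernel rather than
a long-tailed autocorrelation model; that is a simplification, stated
openly, adequate for fields whose smoothness was itself induced by Gaussian
kernels — as in the synthetic data — and conservative or liberal in unknown
directions for heavy-tailed real noise. Both the FWE p < 0.05 and the strict
p < 0.01 variants are computed. Fields are simulated with padding so edge
voxels are not artificially rough, and n_sim ≥ 1000 is recommended for
production (tests use fewer).

## Overlap analysis

Subject-level maps are thresholded with subject-specific cluster-size
thresholds derived from each subject's own residual smoothness (a subject
with smoother residuals needs a larger cluster to reach the same FWE
level); the Monte-Carlo thresholds are memoized on rounded smoothness so
near-identical subjects do not pay repeatedly. Overlap between two content
types is quantified by overlapping-voxel count and Dice coefficient, with
fewer than 10 overlapping voxels treated as functionally zero. Normalized
statistical overlap maps divide each thresholded map by its maximum t
(positive-cluster convention enforced) and multiply the two conditions'
maps, so the product is supported exactly on the intersection and large
values mean a strong response in both conditions. The group random-effects
analysis of these overlap images uses the same mixed model; because the
inputs are non-negative with many zeros, testing against zero is
anti-conservative, and the result map carries that caveat in its metadata.
The binary-overlap alternative (aggregating thresholded intersections) is
deliberately not the default: it answers "where did anyone overlap", not
"where is overlap consistent".

## The synthetic-data generator

The generator is a first-class module, not a test fixture: it emits every
input the pipeline reads (norm tables, social norms, embeddings in word2vec
text format, event CSVs, transcript TSVs, 4D NIfTI) with complete ground
truth, and its defaults encode the study conditions the pipeline expects.

* **Lexicon** (`gen_lexicon`): properties are loadings × latents + noise
  from four orthogonal latent factors, with loading magnitudes calibrated so
  a varimax-rotated PCA on large samples recovers a variance split of
  approximately 29/17/16/11%; columns are then mapped to realistic scales
  (counts rounded non-negative, socialness clipped into [1, 5] — clipping
  affects ~1% of draws, a negligible distortion). Missingness is MCAR at a
  configurable rate (default 0.1, error at ≥ 0.5).
* **Embeddings** (`gen_embeddings`): words are placed near a one-dimensional
  manifold parameterized by socialness plus isotropic noise, so cosine
  neighbourhoods are enriched for similar socialness — the property the
  extrapolation step needs, and nothing more.
* **Events** (`gen_events`): log-normal durations (median ≈ 16 s) clipped to
  [4, 131] s plus ~4% short (< 3 s) pre-merge events; integer ratings arise
  from latent Gaussians correlated with log duration, with the dual-9/10
  exclusion enforced by demoting the weaker rating to 8.
* **Transcripts** (`gen_transcript`): per-event word counts are Poisson with
  a sub-linear duration term (exponent 0.75) and rating-driven modulation,
  calibrated so the duration/semantic/social versus word-count correlations
  fall in 0.55–0.86 / 0.40–0.76 / 0.32–0.56 in expectation. These
  calibration targets are bands, not hard constraints — single movies can
  fall outside them, as real movies do.
* **BOLD** (`gen_bold`): the pipeline's own forward model, y = Σ βᵣ xᵣ +
  AR(1) noise (default coefficient 0.3) with spatially smoothed innovations
  (default 4 mm FWHM at 2 mm voxels) and active-region beta maps recorded in
  the truth object. Default desk-scale grid 16×16×16; production sizes are
  configurable.

What the generator does **not** emulate: physiological noise structure
(cardiac/respiratory aliasing, heavy-tailed artifacts), motion, spatial
inhomogeneity of smoothness, anatomically structured signal, inter-subject
anatomical variability, or any actual film content. Passing tests therefore
demonstrate the pipeline's statistical correctness and calibration under its
own assumptions — they do not certify performance on real data, where the
noise model is known to be optimistic.

## Problem sizes and numerical choices

The test and acceptance workloads use deliberately small problem sizes —
grids of 10–16 voxels per axis, 18–40 events per movie, 2–4 movies, 3–5
subjects per movie, a few hundred Monte-Carlo fields per threshold — chosen
as the smallest sizes at which the statistical properties under test are
stable; production analyses simply scale the same code up. Other numerical
choices: ties in embedding similarity break lexicographically; the varimax
uses Kaiser row normalization; REML optimizes the variance ratio on a log
scale over [1e-8, 1e4] with a boundary check at zero; z values are capped at
±40; cluster-size thresholds are the smallest k with simulated
P(max ≥ k) ≤ FWE p, which inherits the usual conservatism of discrete
cluster sizes; and all generators and analyses are bit-reproducible given
their seeds.

## Known limitations

The mixed model's movies − 1 degrees of freedom are honest but conservative
for designs with very few movies; two-movie designs have df = 1 and little
group-level power. The Gaussian-kernel null-field model underestimates
cluster sizes under long-tailed spatial autocorrelation, as documented for
real fMRI noise. The imputation engine assumes approximately linear
conditional relations between properties. The socialness extrapolation
inherits whatever biases the embedding space carries. None of these
limitations affect the internal consistency checks the package ships with,
but all of them matter when interpreting real-data results.
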