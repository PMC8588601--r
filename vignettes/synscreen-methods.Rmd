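---
title: "SynScreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SynScreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

SynScreen implements the computational analytics of a multi-stage
drug-repurposing screen built around a *C. elegans* model of
α-synuclein-mediated dopaminergic dysfunction: (i) quantification of the
coiler motor phenotype from multi-worm video, (ii) literature-based
ranking of candidate compounds against a set of known actives, and
(iii) RT-QuIC seeding-positivity calling with group comparison. This
vignette explains the models behind each stage, the parameters that
matter, what the synthetic-data generators do and do not emulate, and
the design choices made where the design was genuinely open.

```{r setup, message = FALSE}
library(SynScreen)
```

## 1. Coiler phenotyping from multi-worm video

### The shape statistic

Coiling — a worm holding its body in a closed, round posture — is
scored per animal per frame through the dimensionless circularity of
its silhouette,

$$\mathrm{circ} = \frac{4\pi A}{P^2},$$

with $A$ the body area and $P$ the perimeter, both in pixel units. A
perfect circle gives 1; elongated shapes approach 0. Normal sinusoidal
crawling sits near 0.2, an omega turn near 0.5, and coiling runs from
about 0.6 to almost 1. A frame counts as coiled when circularity
**strictly exceeds 0.6**; the population *coiler score* is the
percentage of tracked worm-frames above that cut-off, pooled across the
animals of a recording. A per-animal averaging mode exists
(`coilerScore(..., perAnimal = TRUE)`) because pooling versus averaging
is not documented for the original scoring; with equal frame counts per
animal the two coincide.

### Segmentation and the perimeter estimator

Frames are thresholded automatically (Otsu's between-class-variance
criterion on a 256-bin histogram, dark worms on light agar; polarity is
a flag), labelled into connected components (EBImage), and filtered by
area: components outside $[0.25, 2.5] \times$ the nominal worm
silhouette area are discarded, the oversized ones counted as worm–worm
collisions for that frame. Dropping ambiguous collision blobs, rather
than attempting to split them, is a deliberate convention; the pooled
coiler score is robust to it because collisions are posture-agnostic to
first order (the residual bias is measured in the tests and stays
below one percentage point).

The perimeter uses a 4-direction Crofton (intercept-count) estimator
computed from $2\times2$ pixel-configuration counts, not a
boundary-pixel count: pixel counting biases $P$ upward by ~10–20% and
would depress every circularity. With the Crofton estimator,
rasterized discs of radius ≥ 15 px score in $[0.95, 1]$, and the
discrete statistic is scale-invariant within 2% across dilation factors
1–4 (both asserted in the tests). Values are clipped at 1, the
continuous supremum.

Two conventions required a decision because a coiled worm encloses a
hole:

* **Area** is the body area only — the enclosed hole is *not* filled
  into $A$.
* **Perimeter** is the *outer contour only* — the inner (hole) contour
  is excluded, implemented by hole-filling before the Crofton count.
  An Euler-number gate ($4E = n_1 - n_3 - 2n_d$ over configuration
  counts) detects which components actually have holes so the filling
  step only runs on those.

This annulus reading keeps tight coils above the 0.6 cut-off: a closed
loop of body length $L$ and width $w$ has
$\mathrm{circ} \approx 4\pi L w / (2\pi R)^2 \approx 2w/R$ with outer
radius $R \approx L/2\pi + w/2 \approx 0.73$ for the default geometry,
whereas counting the inner contour would roughly halve it. Both
conventions sit behind `segConfig()` flags.

### Tracking and behavioral endpoints

Detections are linked frame-to-frame by greedy nearest-neighbour
assignment, gated at `maxDisp` (default twice the expected per-frame
displacement) with tracks closed after `maxGap = 2` missed frames.
Optimal (Hungarian) assignment was deliberately not used: the
population endpoints — pooled coiler score and duration-weighted speed
— are invariant to identity swaps during close encounters, which is
exactly where greedy and optimal assignment differ.

Per-track speed is path length over tracked time; the population speed
weights each track by its duration, which is identically total path
length over total tracked time. Scores are normalized to a control
group as a ratio to the control mean (`normalizeToControl`): severe
coiler mutants reaching normalized scores above 100 are only consistent
with a fold-change reading, not a subtraction.

## 2. The worm-recording generator

`simulateWormRecording()` renders each worm as a filled band of width
`wormWidth` around a posture-specific midline, stamped as discs of
radius `wormWidth/2` at ~1 px arc-length spacing:

* *sinusoidal*: an undulating open curve (two body waves, amplitude
  $L/12$), truncated to arc length $L$;
* *turn*: 70% of the body closed into a loop with the remaining 30% as
  a tangent tail — the rendered silhouette lands near circularity 0.5,
  matching the omega-turn regime;
* *coil*: a slightly over-wrapped closed loop (1.1 turns), landing near
  0.7–0.8.

Worms are dark (intensity 0.2) on a light background (0.9) with
Gaussian pixel noise $\sigma = 0.02$, so segmentation is exercised
nontrivially. They advance at `meanSpeed` with per-frame heading noise
and reflect at the arena edge — the reflecting boundary stands in for
the chemorepellent ring that confines real recordings. Worms closer
than one body length are pushed apart and deflect away from each
other, extending the non-overlapping placement rule to the dynamics.
This choice keeps silhouettes disjoint: the native recordings run at
~3.5% arena occupancy, where worm–worm occlusion is a negligible part
of the measurement, whereas a desk-scale arena at the same animal
count would otherwise spend several percent of worm-frames in merged
blobs and bias the pooled score through posture-dependent occlusion
(compact coils collide less than extended crawlers). The avoidance
dynamics restore the native regime — occlusion-free scoring — at
tractable frame sizes; the collision-dropping filter remains in place
and is exercised by its own unit tests. Posture is an independent
per-frame draw from (`coilProb`, `turnProb`); a geometric dwell-time
option exists (`dwell`) but defaults to 1 frame because no dwell-time
statistics were available to calibrate it — that default is a
convention, not an inferred value.

Defaults mirror the population-recording design the pipeline targets:
10 animals, 2 frames/s, a 1936 × 1456 px arena, a 100 × 10 px adult
silhouette, 20 px/s crawling. The generator reproduces the three
circularity regimes and known per-frame postures; it does **not**
emulate realistic undulatory mechanics, self-occlusion, egg/debris
clutter, or illumination gradients — so passing tests certify the
*measurement pipeline* (segmentation → shape → tracking → scoring), not
robustness to those real-world nuisances.

### Problem sizes used in the recovery studies

The parameter-recovery suite runs 10 worms × 720 frames (a 6-minute
recording at 2 fps) for coil probabilities {0.01, 0.05, 0.2} × 20
seeds, on a 480 × 360 px arena with 60 × 6 px worms. The scaled-down
arena is the package's own choice: circularity is scale-invariant, the
posture bands are re-verified at this geometry by the test suite
(sinusoidal below 0.4, omega turns inside (0.4, 0.6], coils above 0.6
over more than 100 random rendered frames), and the smaller frames
keep the 43,200-frame study tractable. With avoidance dynamics
keeping silhouettes disjoint, the pipeline recovers the realized coil
fraction essentially exactly, so the remaining error against
`coilProb` × 100 is binomial posture sampling: bias stays well within
1 percentage point and per-run errors within 3 binomial standard
errors. Speed recovery on low-tortuosity runs (no coils/turns, heading
noise 0.15 rad/frame) is within 10%, and in practice within ~3%,
because midlines are re-centred so the rendered centroid tracks the
simulated position.

## 3. Literature ranking by graph diffusion

Documents are tokenized by lowercase whitespace splitting (a bigram
option exists; no natural-language processing is attempted). A
vocabulary of the top-`K` corpus terms (default 20,000, ties broken
lexicographically) feeds TF-IDF document vectors:

$$w(t, d) = \frac{\mathrm{count}(t,d)}{\mathrm{len}(d)}
  \cdot \ln\frac{1+N}{1+\mathrm{df}(t)},$$

length-normalized tf and add-one-smoothed idf (raw-count tf and
unsmoothed idf are switches). Each entity's **centroid** is the
arithmetic mean of its documents' vectors; pairwise **similarity** is
cosine on centroids, truncated at zero (TF-IDF centroids are
nonnegative, so the guard is defensive), with zero centroids isolated
(similarity 0 to everything, including themselves).

The ranking step is a **random walk with restart** on the
row-normalized similarity matrix $W$:

$$s \leftarrow \alpha e + (1-\alpha) W^{\top} s,$$

with restart mass $e$ uniform over the known set and $\alpha = 0.15$,
iterated from $s = e$ to an L1 tolerance of $10^{-10}$. The original
platform's diffusion algorithm is proprietary and unspecified; RWR is
adopted as the canonical published graph-diffusion ranking method, and
the direct linear solve $(I - (1-\alpha)W^{\top})s = \alpha e$ serves
as the test oracle (agreement within $10^{-8}$ L∞ on graphs of up to
50 nodes). Scores are conserved (sum to 1); rows without similarity
mass get a self-loop so conservation survives isolated nodes. Dense
diffusion is the default; whether the original platform sparsified to
a kNN graph first is unknown, so no sparsification is applied.

**Leave-one-out validation** removes each known entity in turn, ranks
it among the candidates under the remaining knowns, and records its
score and rank. ROC and precision–recall curves treat the held-out
knowns as positives and the never-known candidates — scored once under
the full known set, so each negative has exactly one score — as
negatives; a one-tailed rank-sum test asks whether known scores exceed
candidate scores. On a fully topic-separated synthetic corpus every
held-out known ranks first and the LOO AUC is 1; on a null corpus
(separation 0) the mean AUC over 5 seeds is asserted inside
$[0.35, 0.65]$ — the *mean* rather than each seed, because with ~15
positives the sampling SD of a null AUC is ≈ 0.08 and single seeds
legitimately stray outside the band.

The corpus generator plants a shared topic (the first tenth of the
vocabulary) into known and planted-positive entities at mixing weight
`topicSeparation`, leaving other candidates on the background
distribution; its default scale (15 known / 620 candidates) mirrors the
screen design. It emits explicit token streams, not natural-language
abstracts, and makes no attempt to model Medline-scale retrieval — the
original corpus-scale performance figures are out of scope here.

## 4. RT-QuIC positivity calling

Plates are wells × timepoints ThT fluorescence tables (reads every 45
minutes to 60 hours by default), held in a `SummarizedExperiment`
subclass with the well map (sample, replicate, background flag, group)
as row annotation. The caller:

1. **Threshold** — mean + 5 SD (sample SD, $n-1$) of the diluent wells,
   pooled over all their timepoints. Pooling is a convention (the
   alternative, per-timepoint thresholds, is behind a flag); with the
   default background model (mean 1200, SD 400 rfu) the threshold sits
   near 3200 rfu.
2. **Replicate call** — positive iff the reading at the *endpoint* (the
   last timepoint at or before 60 h) strictly exceeds the threshold.
   Max-over-time calling exists but is non-default; an endpoint read
   exactly at the threshold is negative.
3. **Sample call** — positive iff ≥ 1 of its (default 4) replicates is
   positive.
4. **Curves** — per positive sample, the mean over its positive
   replicates at each timepoint; per negative sample, the mean over its
   negative replicates.
5. **Group comparison** — a 2 × 2 positives table and a two-sided
   Fisher exact p-value.

The plate generator gives non-seeding wells i.i.d. Gaussian background
and seeded wells a logistic rise of amplitude `seededAmplitude`
(log-normal ±10% per replicate) after `lagTime`; with zero amplitude
and zero SD every reading is exactly the background mean, which pins
the strict-inequality endpoint behavior. It does not model lag-time
dispersion between replicates, drift, or evaporation artifacts.

## 5. Statistics

The two tests whose conventions the pipeline depends on are
implemented in-package and cross-checked against independent oracles
in the test suite:

* `fisherExactTwoSided` — the point-probability (Fisher) two-sided
  definition: sum the hypergeometric probabilities of all
  margin-preserving tables no more probable than the observed one
  (with a $1+10^{-7}$ relative guard against floating-point ties).
  Verified against exhaustive enumeration for all tables with total
  ≤ 25 and against `stats::fisher.test`. A zero margin returns 1 with
  a warning.
* `wilcoxonRankSumGreater` — exact by enumeration of rank assignments
  when $n+m \le 12$ (the crossover balances runtime against
  exactness), otherwise a normal approximation with tie correction and
  0.5 continuity correction; exact and approximate p agree within 0.02
  at $n = m = 10$ over 100 seeded draws.
* `rocAuc` / `precisionRecall` — threshold sweeps grouping tied scores
  into one step; trapezoidal AUC (equivalently Mann–Whitney with 0.5
  tie credit) and step-sum average precision
  $\sum_k (R_k - R_{k-1}) P_k$.

## 6. Numerical and degenerate-input choices

* Circularity requires $A, P > 0$ and is clipped at 1; posture
  classification rejects values outside $(0, 1]$.
* An empty frame or a frame with no surviving component yields an empty
  detection table, not an error; empty documents give zero TF-IDF
  vectors with a warning; a degenerate control group (mean 0) is an
  error directing the user to report raw scores.
* RWR non-convergence within 10,000 iterations is an error reporting
  the residual; an isolated known set produces tied candidate scores
  and a warning. Candidate ties in rankings break lexicographically.
* All generators take explicit seeds and restore the caller's RNG
  state; equal seed and configuration reproduce byte-identical
  recordings, corpora and plates. Pixel noise uses an xorshift128+
  stream seeded from R's RNG (so `set.seed` still governs it) with the
  Marsaglia polar transform — exact Gaussian, chosen for rendering
  throughput.

## 7. Known limitations

* The coiler pipeline drops collision blobs rather than resolving
  them, so extremely crowded arenas bias the score downward; track
  identities are not guaranteed through encounters (by design).
* The synthetic worm is a geometric band, not a biomechanical model;
  omega-turn circularity (~0.5) emerges from the rendered loop + tail
  construction, and real intermediate postures will populate the
  0.4–0.6 band more densely than the generator does.
* The literature module ranks token distributions; it cannot capture
  semantics beyond term co-occurrence, and results at Medline scale
  are expressly out of scope.
* The RT-QuIC caller implements endpoint positivity only — lag time,
  $T_{50}$ and slope kinetics are not estimated.
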