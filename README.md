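# SynScreen

Analytics for a multi-stage drug-repurposing screen built around a
*C. elegans* model of α-synuclein-mediated dopaminergic dysfunction.
The package implements, as tested reusable components, the three
computational stages of such a screen:

1. **Coiler phenotyping** — segment crawling worms in multi-worm video,
   score each silhouette's circularity
   `circ = 4πA/P²` (area *A*, perimeter *P*, pixel units; 1 = perfect
   circle), classify posture with the coiling cut-off at
   circularity > 0.6 (strict), link detections into per-animal tracks,
   and report the population **coiler score** (percentage of tracked
   frames above the cut-off) and the duration-weighted average speed,
   optionally normalized to a control group as fold-of-control.
2. **Literature ranking** — TF-IDF document vectors over a bounded
   vocabulary, entity centroids by averaging, cosine similarity, and
   candidate ranking by **random walk with restart** on the similarity
   graph (`s ← αe + (1−α)Wᵀs`, restart uniform on the known set,
   α = 0.15), with leave-one-out validation (ROC/AUC,
   precision–recall, one-tailed rank-sum).
3. **RT-QuIC positivity calling** — threshold = pooled background mean
   + 5 SD, replicate positive iff its 60 h endpoint strictly exceeds
   the threshold, sample positive iff ≥ 1 of 4 replicates is, mean
   kinetic curves per sample, and a two-sided Fisher exact group
   comparison.

Seeded synthetic-data generators (worm recordings with per-frame
ground-truth postures, topic-structured corpora, RT-QuIC plates)
make every stage testable end-to-end without external data.

## Worked example

Simulate a 2-minute population recording (10 worms, 2 fps) with an 8%
per-frame coil probability, run it through the full pipeline, and
compare against ground truth:

```r
library(SynScreen)

cfg <- wormSimConfig(nWorms = 10, nFrames = 240, arena = c(480, 360),
    wormLength = 60, wormWidth = 6, coilProb = 0.08, turnProb = 0.05,
    meanSpeed = 12, seed = 7)
res <- simulateAndSegment(cfg)                 # render + segment, streamed
tracks <- linkTracks(res$detections, maxDisp = 20, fps = 2)
populationResult(tracks)
#>   n_tracks coiler_score_pct mean_speed_px_s frames_used frames_dropped
#> 1       10         8.166667        11.72976        2400             0
100 * trueCoilFraction(res$truth)
#> [1] 8.166667
```

The pipeline recovers the realized coil fraction exactly on this
recording (8.17%; its difference from `coilProb` × 100 = 8 is binomial
posture sampling), with one track per worm over all 2400 worm-frames,
and the duration-weighted speed recovers the configured 12 px/s.
`frames_dropped` counts worm–worm collision blobs discarded by the
area filter (none occur here because simulated worms avoid each
other).

RT-QuIC calling on a simulated two-group plate (7 vehicle-like samples
with 4/7 truly seeding, 8 treated-like samples with none):

```r
plate <- simulateRtQuicPlate(rtquicSimConfig(
    nSamplesPerGroup = c(vehicle = 7, treated = 8),
    fracSeeded = c(4/7, 0), seed = 7))
calls <- rtquicCall(plate)
calls
#> RtQuicCalls: threshold 3194.8 rfu; 4/15 samples positive
groupContingency(sampleCalls(calls))
#> $table
#>         positive negative
#> treated        0        8
#> vehicle        4        3
#> $fisherP
#> [1] 0.02564103
```

The threshold lands near 3200 rfu for the default background model,
the groups call 4/7 (57%) versus 0/8 positive, and the Fisher exact
p-value (0.026) prints as 0.03 at two decimals.

Literature ranking on a topic-structured corpus with 4 planted
positives among 40 candidates:

```r
co <- simulateCorpus(corpusSimConfig(nKnown = 8, nCandidates = 40,
    docsPerEntity = 3, vocabSize = 300, topicSeparation = 0.9,
    nPlantedPositives = 4, docLength = 80, seed = 7))
loo <- looValidate(co, K = 300)
c(auc = loo$auc, ap = loo$averagePrecision)
#>       auc        ap
#> 0.9781250 0.9040179
head(candidateRanking(loo$fullRanking), 4)
#>   rank   entity      score
#> 1    1 candP_03 0.02508091
#> 2    2 candP_02 0.02486480
#> 3    3 candP_01 0.02485390
#> 4    4 candP_04 0.02461449
```

All four planted positives rank at the top of the candidate list.

## Package layout

* `R/` — S4 classes (`FrameStack`, `Corpus`, `RtQuicPlate`,
  `WormTracks`, `RankedList`, `RtQuicCalls`) and the stage functions.
* `src/` — Rcpp kernels for frame rendering and per-label shape
  features.
* `vignettes/synscreen-methods.Rmd` — the models, parameter choices
  and design decisions in detail.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
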