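---
title: "Methods: interphase FISH amplification analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interphase FISH amplification analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interfish)
```

## The problem

Focal oncogene amplification comes in two cytogenetically distinct forms:
extrachromosomal DNA (ecDNA), which appears in interphase FISH as many
small dispersed puncta, and homogeneously staining regions (HSR), which
appear as a few large contiguous blobs. Distinguishing the two from
interphase images matters because ecDNA segregates randomly at mitosis and
drives faster copy-number evolution. `interfish` provides the quantitative
half of that analysis: deterministic foci detection and per-nucleus
copy-number statistics, preprocessing (patching, rescaling, instance
splitting), quality gates, per-nucleus classification with sample-level
aggregation, and a maximum-likelihood estimator of fluorescent-tagging
accuracy in deliberately mixed EC/HSR populations.

## Preprocessing

Each nucleus in a segmented field is cropped to its bounding box and
resized (bilinear) to a 256 x 256 patch. Bounding boxes larger than the
patch are tiled by non-overlapping 256-pixel windows, with the final
window anchored at the bounding-box edge; the window stride is a package
convention (the underlying protocol specifies only that a sliding window
is used), and per-window predictions are merged by mean posterior
(`combine_window_predictions()`), another stated convention. Bounding
boxes are half-open and 0-based in all reporting. Nuclei touching the
image border are flagged rather than dropped, because only the tagging
analysis must exclude them (their maximum RFP intensity may be clipped).

Channel rescaling maps DAPI to [0, 1] by its own patch maximum and maps
the target and centromeric probes jointly by their shared maximum, so the
relative brightness of target versus centromere — informative for
distinguishing focal amplification from aneuploidy — is preserved. The RFP
channel is never rescaled; tagging thresholds operate on the raw 0-255
scale.

The robustness-testing distortions are fixed: shrink to 0.8x, enlarge to
1.2x, rotate 45 degrees, contrast down/up 40%. Contrast is defined here as
linear scaling about the 8-bit midpoint 127.5 with clipping (the protocol
does not pin down a contrast operator); rotation keeps the original extent
with zero fill, which preserves the central disk exactly under a
rotate/un-rotate round trip.

## Instance splitting by minimum cut

Touching nuclei inflate foci counts, so before stat-FISH the binary
segmentation is refined into instances. The pipeline is:

1. **L1 distance transform** of the mask, with the image border counted as
   background (nuclei clipped at borders are flagged anyway).
2. **Centre detection**: local maxima of the distance map over the
   8-neighbourhood, keeping only maxima deeper than 10 px. A connected
   plateau of equal values is a single centre only when no pixel of the
   plateau has a strictly greater neighbour, and collapses to its
   lexicographically smallest pixel (ties are not addressed by the
   protocol; this rule is deterministic).
3. **Min cut**: for components larger than 1.25x the median component area
   with two or more centres, the minimum number of 4-connectivity
   pixel-graph edges separating the two deepest centres is computed by
   max-flow with unit edge capacities. Each centre's *terminal* is its
   core region — the 4-connected component of pixels deeper than 10 px
   containing it — contracted through high-capacity super edges. If the
   cut is at most the flow limit (60 edges), the cut edges are removed and
   the sides relabeled; pieces still holding several centres are split
   again. Cuts remove adjacencies, never pixels.

The core-region terminals are a deliberate design choice. With single-pixel
terminals the min cut can never exceed 4 (a pixel has degree at most 4 in
the 4-connectivity graph), which would make a flow limit of 60
meaningless and would let every two-centre component split by isolating
one centre pixel. Treating the deep core as the centre makes the cut run
through the neck between nuclei, reproduces neck-width cut sizes, and
leaves the flow limit as a genuine gate: centres whose cores merge through
a thick neck are declared inseparable and the component stays whole. The
flow limit is read as a cap on the cut size, not an iteration bound.

## stat-FISH foci detection

An isolated FISH focus is modelled as an isotropic 2-D Gaussian of
standard deviation sigma on a locally constant background,
`v ~ c g + d 1` over an n x n neighbourhood. Orthogonalizing the Gaussian
kernel against the constant vector,
`g_perp = (g - mean(g) 1) / ||g - mean(g) 1||`, makes the projection
`c = v . g_perp` exactly zero on any constant region regardless of
brightness, so the detector responds to *peakedness*, not brightness. A
pixel is a focus candidate when

* its projection response reaches `c_min`, and
* its raw intensity reaches `b_min`,

and candidates are grouped into 8-connected components, of which those
with at least `s_min` pixels are foci. The 8-connectivity choice for foci
(versus 4-connectivity for the pixel graph, as specified there) is a
package convention.

Defaults: `sigma = 1.5` px with an n = 9 window (covering +/- 3 sigma);
`b_min = 50` on the 8-bit scale, interpreted on whatever scale the channel
is supplied in (divide by 255 for rescaled patches); `s_min = 2` px to
suppress single-pixel noise; `c_min = 15`, which is three times the
response standard deviation under the default background noise (SD 5 —
`g_perp` has unit norm, so the response to i.i.d. noise keeps its SD);
`calibrate_c_min()` recomputes this for other backgrounds. The convolution
zero-pads to a same-size response, and pixels within half a kernel width
of the patch border are excluded from candidacy, where padding would bias
the response — this matches a valid-region convolution on all interior
pixels.

The per-nucleus summary is the copy-number signal: the percentage of
nucleus area covered by foci pixels. Image-level mean and *population*
variance of that signal feed the heuristic classifier; co-occurrence
between two probe channels counts foci whose pixel components overlap in
at least one pixel (a focus overlapping several partners counts once).
Statistical significance of co-occurrence against a chance model is out
of scope; only the counts are reported.

## Quality gates

* **Target quality score** `Q = h1/h2`: the target channel is binned into
  50 equal-width buckets over [0, 256) (so 255 falls in bin 49); `h1` is
  the highest histogram peak among bins 0-24, `h2` among bins 25-49, with
  peaks defined by comparison to neighbouring bins (plateaus count once,
  at their left edge; edge bins compare to their single neighbour).
  `Q < 0.2` marks low quality — probe bleeding pushes background mass
  rightward, shrinking the left peak relative to the right. `Q = 0.2`
  passes, reading the cut-off literally. When a side has no peak, Q is
  undefined and the image fails with a recorded reason.
* **Per-nucleus target gate**: nuclei with mean rescaled target signal
  below 0.05 are excluded (boundary inclusive: exactly 0.05 keeps).
* **Centromeric image gate**: Pearson kurtosis (`m4/m2^2`) of per-nucleus
  mean centromeric intensity; above 3 the centromeric branch is disabled
  for the image. Pearson kurtosis is used because the cut-off of exactly 3
  is the normal reference value under that definition (a property the test
  suite checks on large normal samples).
* **Per-nucleus centromeric gate**: maximum raw centromeric intensity
  below 10 (0-255) disables the centromeric branch for that nucleus.

## Classification and aggregation

The deterministic baseline calls an image HSR-like iff the image-level
mean copy-number signal is below 10 *and* its variance below 64 (strict
inequalities), EC-like otherwise; `threshold_grid_search()` reproduces the
accuracy-maximizing grid scan with ties broken toward the smallest
cut-offs.

The neural harness is a compact feed-forward softmax network on
block-averaged patch features (8 x 8 blocks of the DAPI and target
channels), trained full-batch with hand-written Adam on cross-entropy.
What it preserves from the full-scale training procedure is the loop
semantics: patience-based early stopping (7 epochs) monitoring validation
loss for the three-class model and validation AUC for the binary model
(equal-AUC checkpoints with lower loss refresh the weights without
resetting the patience clock); learning rates 1e-4 / 5e-4; and per-epoch
balanced sampling drawing equal expected weight from every
tissue-by-label stratum. It is a lightweight classifier for testing that
loop at laptop scale, not a reimplementation of a deep dense-block
architecture, and no attempt is made to reproduce published accuracy
tables.

The centromeric branch's binary call gates the target-only prediction:
`no-focal-amp` forces `no-amp` (signal without focal amplification is
aneuploidy), `focal-amp` restricts the call to the better of EC-amp /
HSR-amp, and an absent gate passes the target-only call through.

Sample-level calls bootstrap the per-cell hard labels: 100 iterations of
10 cells drawn uniformly *with replacement* (the protocol does not state
with/without; with-replacement is the standard bootstrap and is flagged as
a convention), majority vote per draw with ties broken uniformly at random
under the iteration's RNG stream. The class-fraction rule is applied in
order: no-amp at >= 80%, else HSR-amp at >= 80%, else EC-amp at >= 50%,
else heterogeneous; the stricter 80% gates are tested first, matching the
order in which the rule is stated. Heterogeneity between two samples is a
Pearson chi-square on the 2 x k table of class counts, dropping classes
empty in both samples before computing `df = k - 1`.

## Tagging-accuracy maximum likelihood

In the mixed-population experiment, a truly EC-amplified line carries a
nuclear RFP tag and is mixed 1:1 with an untagged, truly HSR-amplified
line. Tagging is imperfect; the estimand x is the number of true EC-amp
nuclei among the Nh untagged ones. With class-conditional prediction
probabilities (ph, pe) for true EC-amp and (qh, qe) for true HSR-amp
measured on the pure lines, the probability of observing ch HSR-predicted
untagged nuclei is

    P(ch | x) = sum_{ah=0}^{x} C(x, ah) C(Nh - x, ch - ah)
                ph^ah pe^(x-ah) qh^(ch-ah) qe^(ce+ah-x)

and under a uniform prior on 0 <= x <= Nh the estimate is the integer
argmax. Evaluation is in log space with log-gamma binomials (Nh in the
hundreds overflows direct binomials); terms with invalid combinatorial
arguments vanish, `0 * log(0)` counts as 0, and argmax ties resolve to the
smallest x — when the two pure lines are indistinguishable (ph = qh) the
likelihood is exactly flat by a Vandermonde identity and the estimator
returns 0 rather than an arbitrary interior value. The test suite verifies
the sum against exhaustive enumeration over all class assignments and
prediction outcomes on small pools, and that the likelihood normalizes
over all (ch, ce) outcomes to 1 within 1e-9.

Derived quantities: untagged fraction `x_hat / (Ne + x_hat)` and tagging
accuracy `1 -` that fraction, reported as percentages rounded to two
decimals. Boundary handling of the intensity thresholds follows the stated
wording on each side: a nucleus is *tagged* when its maximum RFP intensity
strictly exceeds 10, while the centromeric QC gate excludes at strictly
below 10.

The goodness-of-fit check builds expected counts for the four categories
(tag status x predicted class) from x_hat and refers the Pearson statistic
to chi-square with 3 degrees of freedom (categories minus one, the
convention this analysis is reported with).
Simulation shows this reference is conservative: with the tag-status
margins fixed the observed counts have two free dimensions and fitting x
consumes one, so the statistic at the estimated x is calibrated against
chi-square with 1 df (the suite checks Kolmogorov distance < 0.15 over 150
simulated experiments). The reported p-value therefore errs toward not
rejecting the model.

## Synthetic fixtures

The generator exists so every module is testable with known ground truth.
EC-amp nuclei receive Poisson(30) Gaussian puncta (sigma 1.5 px, amplitude
200) with centres at least `4 sigma + 1` px apart; HSR-amp nuclei receive
1-2 contiguous bright regions each covering 5-15% of the nucleus;
no-amp nuclei receive 2-4 puncta; every nucleus has two centromeric
puncta; EC-amp nuclei are RFP-tagged with probability 0.95 (emulating a
~95%-pure sorted line). Nuclei are ellipses (field semi-axes 24-40 px)
with smooth DAPI texture and additive Gaussian noise (SD 5). These
defaults were chosen once so that the three classes are separable by the
mean < 10 / variance < 64 heuristic and are not tuned thereafter. Field
images place nuclei on a jittered grid (guaranteeing any requested count
places); overlap mode sets every even-indexed nucleus against its
predecessor so fused components exercise the splitter. Small nuclei can
saturate the packing limit of the separation constraint, in which case the
truth records both requested and placed counts and the image stays
consistent with the placed set.

What the generator does *not* emulate: optical point-spread functions,
chromatic aberration, tissue-section texture, uneven illumination, or
segmentation errors. Passing tests therefore demonstrate algorithmic
correctness on idealized data, not end-to-end performance on real
microscopy.

## Problem sizes and numerical choices

The test suite runs at deliberately modest scale: 50 synthetic EC patches
for planted-spot recovery; 20 random two-lobe masks (fused components
under 2,000 px) for the min-cut/oracle comparison, with an independent
Edmonds-Karp implementation as the oracle; 10,000 bootstrap iterations
against a closed-form binomial reference; 100 simulated tagging
experiments of 500 nuclei for estimator bias; and a 20-patch toy set that
a tiny network must fit exactly. Orthogonality and normalization
identities are asserted at 1e-9; kernel degeneracy (sigma so large the
Gaussian is numerically constant over its window) is an error rather than
a silent zero filter.

## Known limitations

* The heuristic classifier is intentionally crude; on real data it is a
  complement to, not a replacement for, a learned model.
* The min-cut splitter assumes nucleus cores deeper than 10 px; very small
  or very flat nuclei produce no centres and are never split.
* The neural harness trains on downsampled global features and cannot
  capture fine spatial texture; it validates the training loop, not
  image-classification performance.
* Co-occurrence counting reports overlap counts only, with no null model.
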