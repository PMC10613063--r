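---
title: "Decoding natural-movie frames from population spiking: models and methods"
author: "popdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding natural-movie frames from population spiking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A head-fixed mouse on a running wheel watches a 30-s natural movie, many
times, while spiking activity is recorded simultaneously from units across
visual cortex, thalamus, midbrain and hippocampus. Binning spikes into 1-s
windows aligned to movie onset turns each repeat into 30 population vectors,
one per movie frame. Three questions drive the package:

1. **Decoding** — how well can the presented frame be read out from the
   population vector, and how does this differ across brain regions?
2. **Behavioural state** — locomotion modulates visual responses; what
   happens to a decoder trained in one locomotion state and tested in
   another?
3. **Encoding and reconstruction** — how do stimulus and running speed
   jointly drive single-unit rates, and what does the decoder itself "see"
   (its receptive field) when we project its weights back through the
   activity onto the movie pixels?

Everything runs on synthetic sessions from the bundled generator, so the
full pipeline is testable without downloading any recordings. An adapter
for real exported sessions is the on-disk container of
`read_session()`/`write_session()`: anything translated into that container
(counts, region labels, speed, blocks) flows through every stage unchanged.

## Session model

A `session_recording` holds `counts[unit, repeat, bin]` (nonnegative
integers, 1-s bins; bin *b* shows frame *b*), per-unit region labels, a
`repeats x bins` running-speed trace (cm/s), and the presentation block of
each repeat (first half = block 1). Frames, bins, units and repeats are
1-based everywhere a user sees them.

Invalid intervals (NaN speed or counts) are removed by
`clean_invalid_intervals()`, which drops whole repeats rather than single
bins: every decoding sample is a (repeat, frame) cell and train/test splits
operate on repeats, so partial repeats would unbalance classes between
splits.

## The synthetic generator

The generator is the package's statement of the statistical structure the
analyses assume. Per unit, repeat and bin, the Poisson rate is

    base(f)        = baseline_rate + tuning_weights[f]
    none           rate = base(f)
    additive       rate = base(f) + strength * speed      (independent modulation)
    multiplicative rate = base(f) * (1 + strength * speed) (gain scaling)

with `speed` the cm/s value in that bin. Negative rates (possible with
negative additive strengths) are clipped at 0 and the number of clipped
cells is recorded in the session's ground truth.

**Tuning.** Region archetypes give units circular-Gaussian tuning bumps
over the 30-frame cycle with evenly spread, jittered preferred frames:
V1-like (baseline 1, amplitude 30, width 1.5 frames), dLGN-like (2, 6, 2),
APN-like (3, 1.5, 3) and CA1-like (5, 0, —, untuned). The amplitudes were
chosen once so that a 20-unit V1-like population separates even adjacent
frames nearly perfectly while CA1-like sits at chance, reproducing the
qualitative regional ordering; dLGN-like (mean pairwise accuracy ~0.95) is
the workhorse for experiments that need headroom below ceiling.

**Locomotion.** Each repeat draws a latent state: high with probability
`speed_state_fraction` (the count `round(fraction * R)` is exact, the
assignment random). Repeat base speeds are lognormal — low state median
0.5 cm/s (sdlog 0.5), high state median 8 cm/s (sdlog 0.35) — with
multiplicative per-bin jitter (sdlog 0.25). Pooled speeds are bimodal with
one mode on each side of the conventional 2 cm/s threshold. The source
figures do not tabulate the empirical speed distribution, so these are the
package's own choice of a realistic wheel-running profile; they are fully
configurable in `simulation_config()`.

What the generator deliberately does **not** emulate: spike-time structure
within bins, correlated (non-Poisson) variability, adaptation across
repeats, eye movements and pupil state. Passing tests therefore demonstrate
the pipeline's correctness and the qualitative logic of the analyses, not
quantitative agreement with any real recording.

## Decoding

`train_test_binary()` fits a soft-margin linear-kernel SVM (`e1071::svm`,
cost 1, raw unstandardized counts; both configurable) to distinguish two
frames from the selected units' counts. Splits are at the repeat level: 80%
of repeats train, the held-out repeats test, averaged over (default 10)
random splits. `pairwise_accuracy_matrix()` evaluates all F(F−1)/2 = 435
unordered pairs and summarizes by the mean of one triangle, diagonal
excluded. On the diagonal (same frame vs itself) a diagnostic null —
random halving of that frame's repeats — lands at the 50% chance level.

`train_multiclass()` implements one-vs-all over the 30 frames: 30 binary
SVMs, each frame against the other 29 pooled (1:29 label ratio). The
hyperplanes are extracted into an explicit weight matrix `W` (oriented so
larger scores mean "this class") because the reconstruction stage needs
them; prediction takes the argmax score, ties to the lowest class index.

**Chance levels.** `chance_level()` reports 50% for binary decoding and,
for the one-vs-all scheme, the constant `(1/F)^2` (1/900 ≈ 0.11% at F = 30)
obtained by multiplying the probability that a single classifier's positive
class is the true frame by the probability of selecting that classifier.
The empirical null of an uninformed argmax rule is instead `1/F`
(`empirical = TRUE`), and permutation tests in the suite confirm synthetic
null sessions land at 1/30, not 1/900. Both constants are reported side by
side by `multiclass_accuracy()`; users comparing observed accuracies to
chance should use the empirical one.

## Behavioural-state splits

Repeats are labelled H (mean speed ≥ 2 cm/s) or L. A condition "XY" trains
on state X and tests on state Y. The test set is the ⌈0.2 R⌉ repeats with
the *most extreme* mean speeds in the test-state direction; the training
set is everything else. Screening is strict: every test repeat must carry
the test-state label and every train repeat the train-state label,
otherwise the session is ineligible for that condition (the narrowest rule
that guarantees pure-state training and testing). In consequence the four
conditions demand different session compositions: H-L needs exactly-16H/4L
sessions at R = 20, H-H needs all-H sessions, and so on — which is how the
acceptance experiments generate their session groups (state fractions 1.0,
0.0, 0.8, 0.2 for H-H, L-L, H-L, L-H).

**Study conditions and what they show.** The frozen conditions are 20
dLGN-like 20-unit sessions per condition, additive strength 0.3
spikes/bin/(cm/s) or multiplicative gain 0.05 /cm/s (≈1.4× at a typical
8 cm/s run), accuracy summarized over 20 random frame pairs per session.
Under additive modulation, train-L/test-H transfers poorly (mean Δ vs
control ≈ −0.04): the decoder never saw the behavioural offset it meets at
test time. Train-H/test-L, however, sits near zero rather than clearly
negative, and the reason is instructive: with Poisson counts the additive
locomotion offset raises rates and therefore noise *without* raising the
tuning contrast, so the low-state test set is intrinsically less noisy than
the high-state training data, and this easiness gain offsets the transfer
loss. A mild gain (multiplicative) leaves all four conditions within noise
of control. Matched conditions (H-H, L-L) stay within noise of control in
both modes.

## The encoding model

Per unit, activity is the full flattened trace (repeat after repeat),
min-max normalized to [0, 1]; speed is min-max normalized per session.
Stage 1 fits a gaussian-family, log-link GLM of activity on the 30 one-hot
frame indicators (no separate intercept — the indicators span every
sample); the preferred frame is the largest coefficient, ties to the lowest
index. Stage 2 fits intercept + preferred-frame indicator + speed + their
product. The log link keeps every fitted rate positive; normalized
activities of exactly 0 are offset by 1e-6 beforehand. Fitting is IRLS
(`stats::glm.fit`) started from a least-squares fit on the log scale, with
a BFGS fallback on the identical least-squares objective if IRLS fails;
the test suite checks IRLS against an independent optimizer to 1e-4
relative error. Fit quality is `evaluate_fit()`: MSE and the Pearson
correlation between actual and fitted traces (flagged 0 when either trace
is constant). `population_interaction_analysis()` splits units at the
median absolute interaction coefficient — the split rule is the package's
choice — and compares the CC distributions of the two groups with a
Mann-Whitney U test.

**Reading the interaction coefficient.** The interaction lives on the
*log-rate* scale, and this changes what "no interaction" means. A pure
multiplicative gain `rate * (1 + s v)` is *additive* on the log scale
(`log rate + log(1 + s v)`) and is absorbed by the speed main effect: its
exact log-scale interaction is zero (empirically a small positive residue
survives, because least squares on the response scale weights the shared
`log(1 + s v)` curvature differently in the two indicator groups). An
additive rate offset `rate + s v`, by contrast, *is* an interaction on the
log scale — `log(base(f) + s v)` shifts tuned and untuned bins by different
log-amounts — and recovers as a clearly negative coefficient. So under a
log link the mapping between generator mode and interaction size is the
reverse of what an identity-scale reading of the model equation suggests;
interpreting a narrow interaction distribution as evidence for independent
(additive) rather than gain modulation is only valid on the identity
scale. The package implements the log link as specified and leaves the
interpretation to the analyst, with this caveat documented.

## Decoder receptive fields

`compute_drf()` forms dRF = W · A · M: decoder weights (classes × units),
class-averaged activity (units × frames, `class_activity_matrix()`), movie
pixels (frames × pixels), yielding one reconstructed image per class.
Similarity (`image_similarity()`) is the pixelwise Pearson correlation;
reconstruction-vs-actual entries are reported as absolute values — a
linear decoder is agnostic to the sign of its projection — with the signed
matrix retained for diagnostics; zero-variance images give flagged-0
entries.

One practical subtlety: each one-vs-all classifier assigns a large common
negative score to all non-target classes (negatives sit far below the
margin when counts are unbounded), so the raw triple product is dominated
by a large multiple of the *global mean frame* and the diagonal similarity
loses class specificity. `compute_drf(center_units = TRUE)` subtracts each
unit's mean class-response from its row of A, which is algebraically
identical to removing each classifier's mean score across classes and
leaves the discriminative structure intact. `compute_drf()` defaults to
the plain formula; `cross_block_experiment()` defaults to the centred
projection. With centring, matched-block dLGN-like sessions reconstruct at
mean diagonal correlation ≈ 0.55–0.6.

`cross_block_experiment()` trains the decoder on block 1 (50% of repeats)
and builds A from block 2. The high-vs-low behavioural-change contrast
uses strongly additively modulated sessions (strength 1.0 spikes/bin per
cm/s) with block states (L, L) vs (L, H): the constant part of the offset
centres out, and it is the within-state speed fluctuations — absent from
the training block — that degrade the mismatched reconstruction. Groups
are compared with a paired t-test.

Because absolute correlations have a positive bias, and more so when movie
frames are temporally correlated (the synthetic movie's adjacent-frame
correlation ≈ 0.8 mirrors a real movie's band-diagonal similarity), the
no-information floor of the mean diagonal |CC| is ≈ 0.3, not 0. Null
checks therefore compare the diagonal against the off-diagonal background
(no class specificity) rather than against zero.

## Numerical choices

* Control 80/20 splits use `floor(0.2 R)` test repeats (minimum 1);
  condition splits use `ceiling(0.2 R)`; both guard the float boundary
  (`0.2 * 20` must be 4).
* All argmax tie-breaks go to the lowest index (preferred frames,
  multi-class prediction).
* Every stochastic step takes a seed; compound experiments derive logged
  sub-seeds with `derive_seeds()`, and identical config + seed reproduces
  sessions and reports bit-exactly.
* `minmax_normalize()` of a constant vector returns zeros with a warning;
  correlations of constant traces are flagged 0; GLM zero activities are
  offset by 1e-6; zero-variance speed raises an ill-conditioned-design
  error in stage 2.
* Session containers are plain CSV + JSON; speeds are written at 17
  significant digits so `read_session(write_session(s))` is bit-exact.

## Problem sizes used by the test and acceptance suites

Sessions of 20 units × 20 repeats × 30 frames throughout; 435 frame pairs
with 10 split randomizations for null accuracy matrices (3 for the region
ordering); 20 sessions per behavioural condition with 20 sampled pairs
each; 100 units for preferred-frame recovery and 50 per mode for the
interaction analysis; 20 session pairs for the cross-block contrast. These
sizes put every Monte-Carlo estimate's standard error comfortably inside
the asserted tolerances while keeping a full run in minutes on one core.

## Limitations

* Poisson independence across units and bins: no shared gain fluctuations
  or noise correlations, which in real data limit decoding and couple to
  behavioural state.
* The one-vs-all weight extraction assumes a linear kernel; no nonlinear
  decoders are provided.
* The behavioural covariate is running speed alone (no pupil, whisking,
  or arousal indices).
* Real-data ingestion is limited to the documented session container;
  NWB/Allen-SDK parsing, spike sorting and atlas registration are out of
  scope.
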