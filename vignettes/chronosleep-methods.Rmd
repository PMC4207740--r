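---
title: "Models and methods behind chronosleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chronosleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

chronosleep quantifies mouse sleep architecture and EEG spectral features
from epoch-scored polysomnography, screens cortical gene expression for
day/night regulation, and models seed-gene subnetworks — the analysis chain
of a two-genotype circadian phenotyping study in which one genotype shows an
attenuated diurnal modulation of sleep. Because such studies rarely deposit
raw recordings, the package ships a seeded synthetic-cohort generator that
reproduces the statistical structure the analyses assume, so every stage is
testable end to end. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic data do and do not
establish about real recordings.

## Vigilance-state model

Scored sleep is a hypnogram: one label per 4-s epoch over WAKE, NREM and REM
plus an artifact flag. The generator drives states with a first-order Markov
chain. This is the minimal structure that reproduces bout alternation;
the field has no agreed generative model for mouse hypnograms, and no
bout-length statistics were available to calibrate against, so the default
transition matrix was chosen once for physiological plausibility:

```{r}
default_transition_matrix()
```

Its stationary distribution is roughly 55% wake, 36% NREM and 9% REM with
bout durations of a few minutes, typical for adult mice. Direct WAKE to REM
transitions are forbidden (they do not occur in healthy mice).

Diurnal sleep propensity enters multiplicatively: at epoch time $t$ (ZT
hours) every off-diagonal transition probability *into* a sleep state is
scaled by

$$m(t) = 1 + A \cos\!\left(\frac{2\pi (t - \phi)}{24}\right),$$

with the row renormalized. The phase $\phi$ defaults to ZT6 so that sleep
propensity peaks mid-light, as in nocturnal rodents. The depth $A$ is the
group-level parameter of interest: the WT-like group uses $A = 0.4$, the
mutant-like group $A = 0.15$, which attenuates the light–dark amplitude of
all three states while leaving 24-h totals essentially unchanged — the
defining phenotype the analysis chain must detect. Scaling transitions into
both NREM and REM means REM expression is modulated directly as well as via
NREM availability.

Artifact flags are drawn independently per epoch (default probability 0.02)
and only exclude epochs from spectral averaging; the state label, and hence
the time budget, is untouched. This mirrors standard scoring practice, where
artifact epochs still receive a vigilance label.

## Homeostat (Process S)

Slow-wave activity (SWA; mean 0.5–4 Hz NREM EEG power) tracks homeostatic
sleep pressure. The generator carries a latent pressure variable $S \in
[0, 1]$ per animal:

* during WAKE and REM: $S \leftarrow \min(1,\; S + \Delta t/\tau_\text{rise})$,
* during NREM: $S \leftarrow S\, e^{-\Delta t/\tau_\text{decay}}$,

with $\Delta t$ one epoch, $\tau_\text{rise} = 18$ h and
$\tau_\text{decay} = 4$ h — rise much slower than decay, as in the
two-process framework. NREM delta amplitude is affine in $S$
(`delta_gain * (0.5 + S)`), so enforced wakefulness produces the classic SWA
rebound whose direction the acceptance checks verify. The taus are design
choices, not fits; only the *direction* and rough magnitude of the rebound
are asserted anywhere.

## Signal synthesis

Every epoch receives a pink-noise (1/f) floor — synthesized by passing white
noise through the classic 3-pole pinking filter, whose $|H(f)|^2 f$ response
is flat to about 10% over 0.25–100 Hz at the default 256 Hz sampling rate —
plus a state component:

* **NREM**: 0.5–4 Hz band-limited noise, gain `delta_gain * (0.5 + S)`;
* **REM**: narrowband theta, realized as white noise band-passed (4th-order
  Butterworth) to `theta_center_frequency ± theta_bandwidth/2`. A filtered
  stochastic oscillation, not a sinusoid, so theta-peak estimation is a
  nontrivial recovery problem. Defaults: centers 7.2 Hz (WT-like) and 7.6 Hz
  (mutant-like), matching the theta-peak separation such studies report, with
  a 0.75 Hz bandwidth so the spectral peak is localized between adjacent
  0.5 Hz bins;
* **WAKE**: broadband white noise.

Component gains (`delta_gain`, `theta_gain` 1.5, `wake_gain` 1) were chosen
once so that the state-conditional spectra are delta- and theta-dominated,
as real NREM and REM EEG are; the EMG channel is white noise with RMS
ordered WAKE > NREM > REM, and artifact epochs receive a high-amplitude
burst. All noise is drawn from a single seeded stream per animal; per-animal
substreams are keyed by (master seed, group, animal index) so enlarging a
cohort never changes existing animals.

Sleep deprivation by gentle handling is modelled as per-epoch enforcement:
inside the window (default ZT0–6 of day 2) each epoch is independently
forced to WAKE with probability `sd_efficiency` (default 0.97, the
efficiency such protocols achieve).

## Spectral estimation

The analysis grid is 0.5–20 Hz at 0.5 Hz spacing. A 4-s epoch at 256 Hz
natively yields 0.25 Hz resolution, so the 0.5 Hz grid is obtained by a
declared Welch scheme: two non-overlapping 2-s Hann-windowed segments,
periodogram-transformed and averaged (`method = "welch"`). The commercial
acquisition software behind such studies does not document its windowing;
ours is stated, not inferred, and `method = "fft4s"` (single 4-s
periodogram, adjacent-bin averaging) is available for sensitivity checks.
Power is one-sided density; a full-band option satisfies Parseval with the
Hann power correction to 1e-6, which the tests assert.

Conventions, fixed once:

* band edges are inclusive at both ends — SWA averages 8 bins (0.5…4.0 Hz),
  the theta search spans 11 bins (5.0…10.0 Hz);
* theta peak frequency is the grid argmax over 5–10 Hz, ties broken toward
  the lower frequency; Methods-style 5–10 Hz governs even where results
  prose mentions 5–9 Hz;
* SWA is normalized per animal to the mean over the chronologically last 900
  artifact-free NREM epochs of the baseline light period (ZT0–12); fewer
  qualifying epochs is an error, though the window may be explicitly reduced
  (logged). The normalization identity — the reference window itself
  averaging to 100.0 within 1e-9 — is asserted;
* SWA time-course bins need at least 10 artifact-free NREM epochs
  (no published rule exists; 10 keeps bin noise below a few percent);
  thinner bins are flagged missing, never zero;
* ZT blocks are implemented as strict half-open intervals (L1 = ZT0–6,
  L2 = 6–12, D1 = 12–18, D2 = 18–24); published block labels that overlap
  (e.g. a "ZT17–24" D2) are treated as typographical and not reproduced.

## Sleep architecture metrics

State percentages are epoch counts over total epochs per half-open bin,
with 12-h L/D and 24-h aggregates. The light–dark amplitude is reported as
the *signed difference in percentage points*, `state%(L) − state%(D)`; a
normalized variant `(L − D) / ((L + D)/2)` sits behind `normalized = TRUE`
because the usual "relative L–D difference" phrasing does not pin down the
formula. The signed difference is the default since it keeps the ANOVA on
the percentage scale of the time-course figures.

The half-max activity time — the interpolated ZT at which nocturnal wheel
running first falls below 50% of its smoothed peak — uses a 3-bin centered
circular moving average by default (18-min bins); smoothing is needed
because Poisson bin noise otherwise creates spurious early crossings, and
3 bins is the narrowest symmetric window.

## Day/night expression screen

Per gene, ZT16 vs ZT4 on the log2 scale within a genotype; a gene passes at
linear fold-change strictly greater than 1.5 *and* BH-adjusted p below 0.05.
The default test moderates each gene's pooled variance toward the
across-gene mean with a fixed prior of 4 df — the variance-moderation
strategy standard for small-replicate array designs, and the one that makes
the planted-effect recovery target (≥90% at a 1.5 log2 effect, 0.25 noise
SD, n = 4/group) attainable; a plain Welch t-test (`method = "welch"`) is
available and is used for the permutation-null calibration checks, where its
exactly uniform null p-values matter more than power. Fold changes are
computed in log2 and reported on both scales with direction retained. The
genotype comparison reports, per gene, the ratio of mutant to WT fold-change
on both the log2 scale (which equals the generator's attenuation factor in
expectation) and the linear scale, plus the WT-only/shared/mutant-only
partition of the pass lists.

The synthetic design plants a `+1.5` log2 night effect in 20 genes (named
after canonical activity-induced and clock transcripts so the network demo
has meaningful identifiers), attenuated by a factor 0.3 in the mutant-like
group — reproducing the qualitative signature of many genes passing in the
WT screen and almost none in the mutant screen at the same cut-offs.

## Seed-gene networks and enrichment

`shortest_path_network()` implements the most stringent shortest-path rule:
seeds, their direct edges, and — with at most one intermediate step — every
non-seed node lying on a seed–connector–seed path, plus exactly the edges of
those paths. Connector–connector edges are *not* retained, since only
admitted seed-pair paths justify membership; this is documented because
proprietary implementations are ambiguous on the point. Edges are undirected
by default (curated interaction databases mix directed and undirected
semantics); the opt-in directed mode requires a directionally consistent
seed → v → seed path through two distinct seeds. Identifiers are
case-normalized, with an optional synonym map for protein-name inputs.

Enrichment is the hypergeometric upper tail $P(X \ge k)$ for the overlap
between the model's genes and each term set, BH-adjusted across terms. The
default universe is the graph's node set and can be overridden (e.g. all
assayed genes). The bundled edge list and GMT under `inst/extdata/` are
hand-written *synthetic* stand-ins for proprietary pathway databases — they
let the pipeline demo run, and are labelled accordingly.

## Test statistics

`two_way_anova()` is a fixed-effects full-factorial fit with Type II sums of
squares (classical partition when balanced), reported with the note that
repeated-measures corrections are *not* applied — time is treated as a
between factor, matching the effect/interaction structure such studies
report. `bonferroni_posthoc()` runs per-level two-sample t-tests (Welch by
default, since percentage data rarely have equal variances; pooled variance
by flag) and multiplies p by the level count, capped at 1.
`mann_whitney_u()` enumerates all group assignments exactly — including tied
data via mid-ranks — up to 16 total observations, and above that uses the
normal approximation with tie and continuity corrections; its type-I error
at $\alpha = 0.05$ is verified to sit in [0.035, 0.065] over 2000 null
replicates.

Degenerate inputs are defined, not accidental: all-constant ANOVA data give
F = 0 and p = 1; a gene with zero variance and equal means gives p = 1;
post-hoc levels with fewer than 2 observations per group are flagged rather
than fatal.

## Problem sizes and reproducibility

All randomness flows from explicit seeds; every generator is bit-reproducible
given (config, seed). The test and acceptance workloads use: 21600-epoch
(24-h) hypnograms for architecture properties; 1800 REM epochs (2 h) at
256 Hz for theta-peak recovery at centers 6.0–8.5 Hz; and, for the
sleep-deprivation rebound, 20 replicates of two-day recordings synthesized
at 128 Hz — the 0.5 Hz analysis grid is unchanged (2-s Welch segments), and
the band structure of the synthesis is rate-independent, so the lower rate
is purely a simulation-size choice. The pipeline demo runs 4 animals per
group for one day.

## What passing tests do and do not show

The generator emulates diurnally modulated state occupancy, homeostatic SWA
dynamics, narrowband REM theta, nocturnal wheel running and planted
day/night transcripts. It does not emulate: scorer disagreement or
state-transition ambiguity; EEG nonstationarity within epochs (spindles,
K-complex-like events) or electrode drift; bout-duration heavy tails;
correlated noise across genes; or realistic pathway topology. Passing the
suite therefore establishes that the *estimators and decision rules are
implemented correctly and recover known ground truth under the stated
statistical structure* — not that the defaults are calibrated to any
particular real mouse line. Parameters were chosen once for plausibility and
are not fitted to published recordings.
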