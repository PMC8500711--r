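---
title: "Methods: amygdala-hippocampus spike-train analysis under predatory risk"
author: "riskforage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amygdala-hippocampus spike-train analysis under predatory risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskforage)
```

# The experimental setting

The package analyzes simultaneous single-unit recordings from the basal
amygdala (BA) and the dorsal hippocampus (dHPC) of rats foraging on a
linear nest-corridor apparatus: the animal waits in a nest (corridor axis
x < 0), a gateway at x = 0 opens, and the animal runs out to a food pellet
at x = 125 cm. In **threat** sessions a robot predator surges toward the
animal whenever it comes within about 25 cm of the pellet (x around 100
cm), driving it back to the nest; **pre-threat** and **post-threat**
sessions bracket this experience. A recording day therefore yields three
sessions of 8--10 trials with tracking at 30 frames/s, an event log
(gate openings, pellet procurements, robot surges or photostimulations)
and spike trains for every isolated unit.

The scientific question the pipeline addresses is how amygdala threat
coding interacts with hippocampal spatial coding: dHPC place cells with
fields far from the nest ("distal" cells) remap under threat, and the
claim under test is that remapping is selective for place cells whose
spiking *synchronizes* with robot-responsive BA cells in the seconds
around the threat encounter.

# Analysis stages

## Sessions, epochs and behavior

Sessions are S4 objects (`Session`, `Tracking`, `EventLog`, `SpikeTrain`)
with validity checks (sorted spike times, no duplicates at 0.1 ms, event
invariants), read and written as plain CSV tables plus a DCF manifest
(`readSession()`, `writeSession()`). Two bookkeeping rules matter
downstream:

* **Surge refractory rule** (`filterSurgeEvents()`): threat events within
  10 s of the previously kept one are excluded so event-locked responses
  never overlap. The boundary is inclusive (a gap of exactly 10 s is
  kept); the convention is ours, the sources of the rule being silent on
  the boundary.
* **Epochs** (`makeEpochs()`): the synchrony analysis is restricted to
  2.5 s windows immediately before/after a surge or a pellet procurement,
  half-open `[start, end)`.

`behaviorMetrics()` summarizes each session: success rate (procured /
attempted trials), outbound latency (gate opening to procurement, or to
the robot trigger in threat sessions), path length and mean speed.

## Place fields and stability

Rate maps (`computeRateMap()`) use 4 cm pixels, Gaussian smoothing of
counts and occupancy with sigma = 1 pixel, and rates defined on visited
pixels only. A pixel counts as visited with at least 0.2 s of dwell; rates
on barely-sampled pixels are estimation noise and inflate the Skaggs
information (see *Numerical choices*). All maps of a recording day are
truncated at the **foraging limit**, the maximum x reached during the
threat session, so map comparisons only cover territory sampled in every
session; cells whose pre-threat peak lies beyond the limit are excluded.

Inclusion (`qualifiesAsPlaceCell()`) requires a minimum inter-spike
interval of 1 ms, a smoothed peak rate above 2 Hz in some session, and
Skaggs spatial information above 1.0 bits/s in some session, computed on
unsmoothed rates as

$$I = \sum_i p_i \lambda_i \log_2 (\lambda_i / \bar\lambda), \qquad
\bar\lambda = \sum_i p_i \lambda_i,$$

with $p_i$ the occupancy fraction of pixel $i$. Included cells are
classified by the pre-threat peak location: **nest** (x < 0), **proximal**
(0--25 cm, closed interval) or **distal** (beyond 25 cm).

Map stability between two sessions is measured two ways: a pixel-by-pixel
Pearson correlation over jointly visited pixels converted to a Fisher
Z' (`atanh` of r clipped at 1 - 1e-7), and the absolute distance between
the two peak locations on the corridor axis. Whether smoothed or raw maps
enter the correlation is configurable; smoothed is the default.

## Event responses of BA units

`computePeth()` builds peri-event time histograms in 500 ms bins over
[-5, +10] s, averaged over events and expressed in Hz, Z-scored against
the seven baseline bins [-5, -1.5) s. A unit is **Robot**-responsive
when some bin exceeds |Z| = 3 in the robot-approaching window ([-1.5, 0)
s) or the robot-triggered window ([0, 3) s); **Pellet**-responsive when
the same holds in [-1.5, 2) s around procurement; both gives
**RobotPellet**, neither **NonResponsive**. Pellet and non-responsive
units together form the *nonRobot* group used in the linkage;
RobotPellet units are excluded there. Window membership is decided by the
bin start; Z is identical in rate or count units under this binning.

**Calibration choice.** The empirical SD of seven baseline bins is a
noisy scale estimate: its fluctuations give per-bin Z statistics
t-like tails and would flag roughly a third of homogeneous Poisson units
as responsive. The package therefore floors the baseline SD at the SD
expected from Poisson counting at the baseline mean rate,
$\sqrt{\bar r / (0.5\,n_{\text{events}})}$; with the floor, fewer than
10% of homogeneous units are flagged at 50 events while strongly driven
units (gain 4+) are still recovered essentially always. The pure
empirical SD is available with `sdFloor = "zero_only"`.

Putative interneurons are split from pyramidal cells by a Ward
agglomerative 2-cluster cut on standardized spike width and mean rate
(`splitPyramidalInterneuron()`); the wider-spike cluster is pyramidal.
The cut is accepted only when the two-cluster solution is genuinely
separated (mean silhouette at least 0.5) — forcing k = 2 onto a
homogeneous population would otherwise invent interneurons. Interneurons
are excluded from the linkage analyses.

## Epoch-restricted synchrony

Cross-correlograms (`rawCcg()`) use the BA unit as reference, 10 ms bins
spanning +/-500 ms with edges at multiples of 10 ms (lag 0 is an edge, so
no bin straddles zero: a peak in [-10, 0) ms is dHPC-leading, in [0, 10)
ms BA-leading). Only same-trial spike pairs inside the 2.5 s epochs are
counted.

The stimulus-locked component is removed with a **shift predictor**
(`shiftPredictor()`): 100 trial shuffles, each a uniformly drawn
fixed-point-free permutation pairing reference trial i with target trial
pi(i), lags computed after aligning the two windows' starts; the mean
shuffled correlogram is subtracted from the raw one. Per-bin Z scores use
the mean and SD of the corrected correlogram over all +/-500 ms bins
(about 100 bins, of which 80 lie outside the test window; restricting the
normalization to those 80 is available via `zNormalization`). A pair is
**significant** when the peak Z exceeds 3, the peak bin falls inside the
+/-100 ms testing window, and both units fire above 0.1 Hz within the
epochs. `pairScreen()` runs every BA x dHPC pair across the four epoch
labels.

Under these conditions (10 trials x 2.5 s, 5 Hz units) about 5--10% of
truly independent pairs are flagged — the discreteness of low counts and
the estimated normalization make the peak statistic slightly heavy-tailed
— which is why the linkage below relies on group contrasts rather than
individual pairs.

## Theta-band spectra

`spikePsd()` bins spikes at 2 ms inside event-centered windows (+/-2.5 s
around surges; +/-2.5 s around procurements in pre/post sessions),
subtracts the window mean, and Welch-averages Hann-tapered 2.5 s segments
with 50% overlap. Band fractions are percentages of the total power over
[1, 50) Hz with half-open bands: delta [1, 4), theta [6, 10), beta
[12, 30), gamma [30, 50). On the 0.4 Hz Welch grid the half-open theta
band covers 10 of 122 in-range frequencies, so a flat (Poisson) spectrum
carries a theta fraction of ~8.2% — the bandwidth ratio 4/49 — which is
the null the theta analyses are compared against. Note that a spike
train's spectral floor scales with its rate, so an 8 Hz rate modulation
of depth d on a unit of rate r raises the theta fraction by roughly
$r d^2 / (2 \times 49\,\mathrm{Hz})$ relative to that floor: slow units
need strong modulation to show a clear theta excess.

## Linkage: synchrony class vs remapping

`buildLinkage()` labels each included place cell per epoch as
**Robot**-paired (at least one significant pair with a Robot-class
pyramidal BA unit), **nonRobot**-paired (significant partners are Pellet
or non-responsive units only) or unpaired. A cell paired with both kinds
counts as Robot-paired (dominance rule; an exclusive mode drops such
cells). Nest and proximal cells are pooled into `nest_proximal`.

`stabilityByPairing()` contrasts the pre-vs-threat Fisher Z' between
Robot- and nonRobot-paired cells within each class; a
Kolmogorov--Smirnov (Lilliefors) normality pre-test selects a Welch t or
a Wilcoxon rank-sum test. `stabilityVsPosition()` regresses both
stability metrics on the pre-threat peak location.
`speedControl()` checks that Z' does not simply track locomotion changes
in the cell's field region (peak +/-15 cm, about one field sigma), and
`rateComparisons()` that epoch firing rates do not differ between the
contrasted groups — the two standard confounds for this design.

# The synthetic cohort

Real recordings are not required anywhere: `simConfig()` /
`makeCohort()` generate a full three-session day with known ground truth.
The generator is deliberately a *script*, not a behavioral model — the
analyses need realistic occupancy, event timing and coupled spike trains,
not decision-making:

* **Trajectory**: per trial, a bounded random walk inside the nest
  (15 s), gate opening, a constant-speed outbound run (25 cm/s; threat
  trials may pause once), then either procurement at 125 cm and return
  (35 cm/s) or, in threat trials, a robot surge on first crossing 100 cm
  followed by a 60 cm/s flight. Threat-trial success probability defaults
  to 0, matching the behavioral collapse the design assumes. Lateral y is
  smooth bounded noise (+/-5 cm) so 2-D maps are non-degenerate.
* **dHPC units**: inhomogeneous Poisson by thinning with
  $\lambda(t) = b + (p - b)\exp(-(x(t)-c)^2/2\sigma^2)$ (defaults: peak
  12 Hz, baseline 0.8 Hz, sigma 10 cm); during threat the center is
  displaced by `threat_shift` and an optional 8 Hz modulation applied.
* **BA units**: baseline Poisson (4 Hz) with multiplicative event-locked
  gain (default 5, latency 0.1 s, decay 1.5 s) on robot and/or pellet
  events.
* **Synchrony injection**: per in-epoch BA spike, with probability
  `excess` a dHPC spike is inserted at the chosen lag (+/-5 ms jitter).
* All trains respect a 2 ms refractory period — without it Poisson
  trains would fail the 1 ms inter-spike-interval inclusion criterion
  that real sorted units satisfy.

Randomness is split into per-cell streams derived from the cohort seed,
so adding a cell never changes another cell's spikes and every output is
bit-reproducible. Positions, times and spikes are generated directly at
their on-disk precision (0.001 cm, 1e-6 s, 0.1 ms), so sessions
round-trip exactly through the CSV files.

The default "paper-like" cohort (`defaultSimConfig()`) has 10 nest, 4
proximal and 20 distal cells and 6 BA cells (2 robot-excited, 2
pellet-excited, 2 non-responsive). Half the distal cells receive
pre-surge synchrony (lag +30 ms, excess 0.3) with robot BA cells *and* a
30 cm threat-phase field shift; the other half receive synchrony with
nonRobot BA cells and stay stable; nest cells are paired half/half and
all stay stable. Remapping and pairing assignments are interleaved across
field positions so neither is confounded with distance from the nest. The
shift is directed toward the nest so the displaced field stays inside the
threat-session foraging limit; only the shift magnitude enters the
analyses. Population sizes are a desk-scale compromise: large enough that
group contrasts survive the ~10% chance-pair rate under the dominance
rule, far smaller than a real multi-day data set.

## What the simulator does not emulate

Theta phase precession, speed-rate coupling within fields, bursting and
spike-sorting artifacts, overdispersion of real firing, session-boundary
drift, and any learning dynamics. Passing recovery tests therefore shows
the *estimators* are correct and calibrated on their assumed generative
family, not that real recordings satisfy those assumptions.

# Numerical choices and degenerate inputs

* Pixel size 4 cm, smoothing sigma 1 pixel, minimum occupancy 0.2 s per
  visited pixel; all configurable. The plug-in Skaggs estimator has a
  positive sampling bias of roughly $K/(2\ln 2\, T)$ bits/s for $K$
  visited pixels and $T$ seconds of tracking (~0.1--0.2 bits/s at 10
  trials), which the occupancy threshold reduces but does not remove;
  the 1.0 bits/s inclusion threshold sits well above it for tuned cells.
* Correlations use pixels visited in both maps; zero-filling unvisited
  pixels would inflate r. Fewer than 10 common pixels yields an NA with
  a warning. Peak ties break toward smaller x.
* CCG and PSD binning applies a 1 ns epsilon at bin edges: spike times
  live on a 0.1 ms grid and bin edges on 10 ms / 2 ms grids, so the
  epsilon resolves floating-point jitter without ever moving a true lag
  across a boundary.
* A corrected correlogram with zero SD is flagged `degenerate` (never
  significant); pairs below the 0.1 Hz epoch-rate floor are flagged
  `rate_fail`; single-trial epochs cannot form a shift predictor and are
  flagged `no_epochs`.
* Two-group contrasts fall back to a t-test when groups are too small
  for the normality pre-test (n < 5) and return p = 1 on constant data.

# Problem sizes

The shipped tests validate the pipeline at desk scale, chosen to finish
comfortably on one CPU: 100 randomized correlogram instances for the
brute-force oracle; 200 independent and 30 injected pairs for the
specificity/sensitivity checks; 60-cell cohorts for remapping recovery;
50 units per class for PETH recovery; 20 seeded cohorts for the headline
linkage pattern; 20 theta-modulated cells. The same quantities are
recomputed from scratch by `scripts/acceptance.R`.
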