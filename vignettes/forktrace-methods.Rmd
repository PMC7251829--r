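---
title: "Mapping replication forks from nanopore BrdU signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping replication forks from nanopore BrdU signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(forktrace)
```

## The measurement

During DNA replication, nascent strands synthesized in the presence of
5-bromo-2'-deoxyuridine (BrdU) carry the analog in place of thymidine.  A
nanopore reads native single strands, and BrdU perturbs the ionic current:
at hexamer contexts with a T at the center of a pentamer, the current shift
between successive plateaus is displaced positively relative to the
thymidine-only expectation.  After resquiggling (aligning the raw current
to the reference, one mean current $m_i$ per reference base $N_i$), the
per-transition shifts $\delta_i = m_i - m_{i+1}$ therefore carry a readable
record of where, and how much, BrdU was incorporated.

A brief BrdU pulse followed by a thymidine chase converts this record into
replication dynamics: incorporation rises steeply from ~0 to the pulse
peak (60–80%) as the intracellular BrdUTP/dTTP ratio jumps, then decays
shallowly toward ~10% during the chase.  The asymmetry of each labeled
track — steep on the side where the fork was at pulse onset, shallow in
the direction of travel — encodes fork direction on a single molecule.
Midpoints between two diverging (converging) fork starts on one read are
per-molecule initiation (termination) events.

## Signal model and normalization

The expected shift for each of the $4^6 = 4096$ hexamers is tabulated in a
transition matrix, estimated separately for thymidine ($TM_T$) and BrdU
($TM_B$) contexts as the per-hexamer mean of observed shifts.  Per-read
drift is removed by the affine fit
$(\alpha_0, \beta_0) = \arg\min \sum_i (\alpha\delta_i + \beta -
\delta^{(e)}_i)^2$, solved in closed form (ordinary least squares),
using only transitions whose hexamer has no T at the center of either
pentamer, so that the fit is blind to BrdU content.  Reads whose minimized
mean squared distance exceeds 0.25 are discarded; the published rule says
"quadratic optimized distance" without fixing mean versus sum, and the
mean is implemented because it makes the cutoff independent of read
length (the cutoff is exposed as a parameter).  Reference estimation is
two-step — bootstrap matrix from raw reads, re-fit, re-estimate from
normalized survivors, average replicates — and the resulting frame is
identifiable only up to the ensemble's common affine drift, which is why
the recovery tests align affinely before comparing.

Reads with fewer than 50 usable drift-fit transitions are rejected: with
two free parameters the fit is unstable below that; the choice is ours
(the source method is silent).  Hexamers never observed are imputed with
the global mean shift and flagged, so expected-shift lookups have no
holes.

## BrdU calling

**Transition-matrix caller.**  At every hexamer with a T at position 3,
the observed (normalized) shift is compared with $\delta^T$ and
$\delta^B$.  If $|\delta^T - \delta^B| \le 0.4$ the site is indeterminate
(X); otherwise the nearer expectation wins (B or T).  An exactly
equidistant observation is conservatively X rather than randomly assigned.
Calls are smoothed into a content profile as the sliding fraction
$B/(B+T)$ over 30 consecutive called sites (X excluded from numerator and
denominator), each value anchored at the center of its site window — an
even window, so the anchor is the mean of the two central site
coordinates.

**Convolutional estimator.**  A small 1-D convnet maps a window of 96
transitions — five channels: one-hot base plus normalized shift — to the
fraction of substituted T sites: three convolutional layers (32 filters,
kernel 5, 'same' padding, ReLU), 4× max-pooling after the first two
(hence the window must be a multiple of 16), then a shared dense+sigmoid
head applied at each of the 6 remaining positions and averaged, which
keeps the output in $[0,1]$ by construction.  Training minimizes mean
squared error (the loss is not stated in the source method; MSE is the
natural choice for a fraction target and is configurable) with plain SGD:
learning rate 0.1, multiplicative decay $10^{-6}$ per update, momentum
0.9, 90/10 train/validation split, early stopping after 5 epochs without
validation improvement, best weights kept.  Labels are per-window copies
of the cohort-level content.  An optional second pass cleans BrdU-rich
cohorts: per-read predicted contents are split 2-means and, when the two
modes are more than 0.15 apart, the lower mode (parental thymidine
strands contaminating a substituted sample) is dropped and training
restarts.  A fixed threshold at half the label is not used because a
small, partially memorizing network biases contaminant predictions
upward; the mode split is robust to that compression.  At inference,
windows slide by 10 transitions (plus a final window flush with the read
end) and each full 10-transition segment receives the mean over windows
containing it.

The estimator is implemented in base R matrix algebra (im2col
convolutions with explicit backpropagation); it is deliberately small and
fully seeded, so training runs are reproducible to the last bit.

## Track detection, orientation, scoring

Reads shorter than 5 kb are excluded.  Reads with no track are removed by
two filters: a minimal signal amplitude on the smoothed profile (0.4 for
the convolutional path, 0.5 for the TM path) and a minimal standard
deviation of the BrdU signal (0.115 CNN, 0.3 TM).  For the TM path the sd
filter is applied to the per-site B/T call indicator rather than the
30-site smoothed profile: a smoothed fraction profile with the pulse-chase
shape (peak 0.6–0.8 decaying to ~0.1) is mathematically bounded to sd
well below 0.3, whereas on the binary call scale 0.3 corresponds to at
least ~10% B calls — a clean separator between BrdU-free reads (miscall
rate well under that) and track-bearing reads.  The convolutional
threshold stays on the smoothed profile.  The standalone
`filter_reads()` operation keeps the literal profile-sd semantics for
both methods.

The surviving profile is rescaled per read to $[0,1]$ (min to 0, max
to 1) and simplified with the Ramer–Douglas–Peucker algorithm using the
vertical deviation, which at genomic abscissa scales is numerically the
perpendicular one and is invariant to the coordinate units.  The
tolerance must sit above the intrinsic sampling noise of the profile: a
30-site fraction at intermediate content has binomial sd ≈ 0.09
(≈ 0.12 rescaled), and the simplification retains extreme excursions, so
the default is 0.5 for the TM path (~4× the noise scale; pulse features
span ~1.0 rescaled and survive) and 0.25 for the smoother convolutional
profiles.  One geometry needs a smaller tolerance: a chimeric
(step-shaped) profile has maximal chord deviation of only half its
amplitude, so the precision experiment runs at 0.2 — both choices are
plain function arguments.

Run structure on the simplified polyline uses a hysteresis (zigzag)
filter: a counter-movement smaller than `swing_tol` (default: the 0.26
downward amplitude threshold, the smallest shift the rules care about)
does not end a rising or falling run.  A track is a rising run with total
rise > 0.44 followed, possibly after a plateau, by a falling run with
total fall > 0.26.  Slopes are chord slopes between the 25% and 75%
amplitude crossings of each run, robust to shallow approach stretches;
flanking minima are the run pivots.

Orientation: if the rise is more than 1.5× steeper than the fall
(magnitudes), the track points rightward; mirrored, leftward; otherwise
the flanking minima decide (the chase leaves the trailing flank more than
0.075 above the pre-pulse baseline).  One additional gate reflects the
biology: a genuine fork start rises out of DNA that was unreplicated
during the pulse, so the pulse-side flank must lie at or below 0.15
(rescaled); noise bumps riding on the chase decay are flanked by elevated
signal on both sides and are left unoriented by this rule.

The fork-start coordinate is the mid-rise crossing — where the steep run
crosses halfway between its flanking minimum and the peak.  The 30-site
boxcar smoothing, anchored centrally, spreads any underlying step
symmetrically, so the mid-rise point is an unbiased localizer, whereas
the base-of-rise breakpoint is systematically early by half the smoothing
span (hundreds of nucleotides).

Scores (the source method names but never defines them; these
reconstructions are documented as such):

* `Ascore`: signed fork asymmetry — the steep/shallow slope-magnitude
  ratio, positive rightward, negative leftward.  `|Ascore| > 2` is then a
  stricter version of the 1.5 orientation ratio.
* `Jscore`: the starting-jump amplitude in pre-rescale units divided by
  the read's off-track residual standard deviation; `Jscore > 1` means
  the jump exceeds the noise floor.  Pre-rescale units keep the score
  comparable across reads with different rescale factors.

## Event calling

Initiation: a consecutive (leftward, rightward) diverging pair, both
high-confidence (`|Ascore| > 2`, `Jscore > 1`), fork starts at least 1 kb
apart, and mean rescaled profile between the fork starts at most 0.14
(CNN) / 0.12 (TM) — DNA between diverging fork starts replicated before
the pulse carries no BrdU.  The plateau mean is taken over the full
inter-fork interval.  The event midpoint is the mean of the two fork
starts.  Termination: a consecutive (rightward, leftward) converging
high-confidence pair; the same ceiling applies at the fork starts, and it
is evaluated at the flanking minima (the base of each rise), because at
the mid-rise localizer the signal is ~half-peak by construction.
"Consecutive" is read conservatively: any intervening detected track,
oriented or not, voids the pair.  Events from the two calling paths are
pooled by greedy nearest-pair matching per read and type within 2 kb
(ties by smaller distance, then leftmost); shared pairs count once.

## Genome-wide profiles

RFD is (rightward − leftward) / total track coverage, computed on a
100-nt internal grid (an explicit memory/runtime approximation of the
1-nt definition) and smoothed with a centered 1-kb running mean.
Uncovered bins are explicitly missing, never 0 — RFD = 0 is meaningful.
Running means shrink to the available window at chromosome edges, exclude
missing values, and leave a bin missing when less than half its window is
defined.  OEM at position $x$ is the rightward-fork fraction in
$(x, x+10\,\mathrm{kb}]$ minus that in $(x-10\,\mathrm{kb}, x]$; the
window order is fixed so initiation zones are positive and termination
zones negative, matching how negative-OEM segments are used.  The
initiation-minus-termination density counts events in non-overlapping
5-kb bins smoothed with a 10-kb running mean.  Profile comparisons use
Spearman rank correlation over bins defined in both signals.

## Event analysis

Clustering is single-linkage chaining per chromosome: neighboring events
closer than the clustering limit (mIED, default 1.5 kb; strict
inequality, documented and tested at the boundary) share a cluster;
dimension $d$ is the member count, width the span of the outmost members,
and the median point the interpolated median (for even $d$ the midpoint
of the central pair).  Dimension classes default to $d = 1$, 2–4, 5–12,
> 12.  Randomization keeps per-chromosome counts and redraws positions
uniformly i.i.d., without collision or annotation avoidance.  Distances
to annotations are midpoint-to-center.  Overlap fractions resize both
sets to 2 kb around their midpoints first.  PWM scanning uses weight-sum
scoring with the match threshold defined as a fraction (default 0.8) of
the maximum attainable score — note this differs from conventions that
scale relative to the minimum score; both coincide when column minima are
zero, which the cross-check test exploits.  Timing tracks are binned to
1 kb and min–max normalized to $[0,1]$ (start/end of S phase) on load.

## The simulator and what passing tests mean

The simulator generates every input the pipeline consumes, from the
transition matrices down to whole-genome read populations, under a single
integer seed.

* Matrices: thymidine expectations are standard normal across hexamers;
  a fraction (default 12.5%, i.e. 512 of 4096) of hexamers with a central
  T is displaced positively by `shift_gap` × U(0.8, 1.2) (well clear of
  the 0.4 calling threshold — callable sites are by definition clearly
  separated); other centrally-T hexamers receive a sub-threshold nudge.
  The informative subset is biased toward GC-rich flanking contexts so
  that, in the AT-rich simulated genome, callable sites occur every
  ~15–20 nt — matching the observed ~18-nt spacing of B/T call sites,
  which a uniform draw would triple.
* Noise: i.i.d. Gaussian per transition (sd 0.15 by default, ~0.4% naive
  miscall rate); the simplest model consistent with per-pentamer current
  distributions.  The distribution is an assumption, not a claim about
  pore physics.
* Pulse-chase shape: logistic rise over 300 nt to a per-molecule peak
  drawn from U(0.6, 0.8), exponential decay over 5,000 nt (about 3
  minutes of intracellular BrdUTP/dTTP decay at a yeast fork speed of
  1.5 kb/min) to a chase floor of 0.10 that persists to the end of
  labeling.  Rise and decay shapes are configurable; the asymmetry is the
  orientation signal, so the config requires rise < decay.
* Whole-genome runs: each read is an independent cell; origins fire with
  their efficiencies at uniform times before the pulse, forks move at
  constant speed, late origins can be passively replicated (the
  equal-speed nearest-arrival formula handles this exactly), and BrdU
  probability is the pulse-chase time course evaluated at each position's
  replication time.  Per-read ground truth (track extents, orientations,
  event midpoints) travels with the reads.
* Chimeric reads: probability steps from the chase floor to the pulse
  peak at a known coordinate, blurred symmetrically (logistic centered on
  the transition) over the rise length.

What the simulator does **not** emulate: raw pA-level current and event
segmentation (simulation starts at per-base mean currents, where the
method operates), basecalling and alignment errors, per-pore or
per-flowcell batch structure beyond the per-read affine drift,
non-uniform genome composition beyond GC content, replication-timing
programs (firing times are uniform before the pulse), and fork stalling
or variable fork speed.  Passing tests therefore demonstrate the
correctness and internal consistency of the algorithms under the stated
generative model, not performance on any particular real flowcell.

## Problem sizes and determinism

The test-suite and acceptance-script problem sizes are desk scale, chosen
so the full suite runs in minutes on one CPU while leaving clear
statistical margins: 500 BrdU-free reads for the zero-false-positive
check, 300 chimeric reads for precision, 500 reads per condition for
matrix recovery, five cohorts of 60 × 2-kb reads for content-estimator
recovery (the published training used 4,000 reads per sample), and a
2 × 300-kb genome with 5 origins and 2,000 reads for the end-to-end
consistency checks.  All randomness flows from explicit integer seeds;
every simulated artifact records its configuration.

## Known limitations

* The Ascore/Jscore formulas are reconstructions; absolute score values
  are not comparable with other implementations, only the gates
  (`|Ascore| > 2`, `Jscore > 1`) are.
* With 30-site windows, the irreducible binomial noise of a fraction at
  intermediate content sets the floor for detectable amplitudes; the
  simplification tolerance trades false swings against sensitivity to
  small genuine shifts, and features below ~0.5 rescaled amplitude are
  invisible to the pulse-track path at its default tolerance.
* Events are strictly per-molecule; no multi-read consensus calling.
* The per-read min–max rescaling ties all thresholds to each read's
  realized amplitude; reads whose peaks are clipped by read ends behave
  slightly differently from fully spanned tracks.
* Coordinate mirroring maps a divergent pair to a divergent pair, so the
  left/right symmetry test checks that mirrored profiles give mirrored
  tracks with flipped orientations and same-type events at mirrored
  midpoints.
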