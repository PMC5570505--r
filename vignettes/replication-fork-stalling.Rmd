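---
title: "Measuring replication fork stalling and kinetics from dual-pulse combing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring replication fork stalling and kinetics from dual-pulse combing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replifork)
```

## The measurement

DNA combing stretches single DNA molecules on a glass surface so that
replication tracks can be measured by immunofluorescence. Cells in
mid-S phase are pulse-labeled with CldU for 5 minutes (detected in red)
and chased with IdU for 10 minutes (green). Reading a combed fiber left
to right gives an ordered sequence of red, green and unlabeled tracks
with lengths in kb (calibrated against co-combed lambda DNA, 48.502 kb).
Only fibers longer than 120 kb are analyzed; shorter ones are kept but
flagged, so exclusions stay auditable.

The simple pattern taxonomy is: a red-then-green track (RG) is a
rightward-moving fork and GR a leftward one; green-red-green (GRG) is an
origin that fired during the first pulse; an isolated green track is an
origin that fired during the chase; red-green-red (RGR) is a termination
during the chase; an isolated red track is, at face value, a
termination during the first pulse. `replication_kinetics(mode =
"naive")` applies exactly this taxonomy.

## Stall evidence lives at red gap-edges

A fork that stops and does not resume is detectable only if it stops
before the chase begins and stays stopped: it leaves a red track end
facing unlabeled DNA. The state of that unlabeled gap decides the
reading. If the far side of the gap is a green track tip, an active fork
was still moving into the gap, so the gap was unreplicated and the red
edge must be a stalled fork: red-unlabeled-green (RUG) and its mirror
GUR are unambiguous single stalls. Green-unlabeled-green (GUG) is the
signature of two unstalled forks. A red-red gap (RUR) is ambiguous:
either the gap was replicated before labeling (two forks diverging from
an interior origin, no stalls) or it was never replicated and both
inbound forks stalled -- two stalls, jointly or not at all; mixed
readings are geometrically impossible. Red edges facing a fiber end
have no context and are free candidates.

The dataset-level *apparent stall rate* pools every informative
junction:

$$ s = \frac{RUG + GUR}{RUG + GUR + GUG}. $$

The definite stalls stay in the denominator because each stall is the
loss of one fork: a pulse-1 origin with one stalled fork appears as GR
or RG and should be scored 50% stalled, one stalled fork where there
should be two.

## Probabilistic resolution of ambiguous patterns

`enumerate_interpretations()` groups labeled segments linked through
red-red gaps and enumerates every geometrically consistent assignment
of stalls to red gap-edges. Each distinct count signature (origins,
terminations, forks per pulse, stalls) is one interpretation. An
interpretation requiring $k$ stalls beyond the definite ones gets
weight $s^k$; the minimal-stall interpretation takes the remaining
$1 - \sum s^k$ (floored at zero and renormalized if $s$ is large, which
keeps weights a probability vector for any $s \in [0,1]$). A red-red
gap therefore carries its two-stall reading with weight $s^2$ -- at
$s = 0.10$, a 1% chance -- and an isolated red track has exactly three
readings weighted $1 - s - s^2$ (termination), $s$ (stalled elongating
fork, either direction) and $s^2$ (origin with both forks stalled).
Mixed readings of a shared red-red gap (one tail, one stalled head) are
excluded, and no stall is ever assigned to a green edge. Stalled forks
count toward pulse-1 forks but not pulse-2.

Expected per-fiber counts are weight-averaged over each group
(`expected_event_counts()`); the test suite checks them against an
independent brute-force enumeration on randomized fibers.

From the expected counts:

* **stalls/kb** = expected stalls / unlabeled kb of the fiber;
* **stall rate** = expected stalls / expected pulse-1 forks;
* **origin firing rate** = expected origins / unlabeled kb / 15 min
  (the summed pulse time), with per-pulse rates over 5 and 10 min
  respectively -- dimensional consistency decides the per-pulse
  denominators, which the counting rules leave open;
* **fork density** (per pulse and total) = expected forks / unlabeled
  kb; in naive mode origins and terminations count twice and
  unidirectional forks once, verbatim from the taxonomy.

"Unlabeled kb" deliberately conflates DNA replicated before the pulses
with unreplicated DNA; the assay cannot distinguish them.

Fork rate is the green track length of every green track continuing
from a red one (two samples per GRG), divided by the 10-minute chase.
The distribution is binned (default 0.1 kb/min) and least-squares fit
with a Gaussian; the fitted mean is the estimate, which is what makes
the measurement robust to the left tail contributed by forks that
stalled or terminated mid-chase and to the right tail of fused tracks
(below). Fewer than 30 samples, or a non-converging fit, falls back to
the sample mean with a warning. Sister-fork asymmetry is the
longer/shorter green ratio of simple GRG origins. Dataset comparisons
use Welch's unequal-variance t-test on per-fiber values (per-sample for
fork rate); "t test" alone underdetermines the variant, and unequal
variances are the safe assumption for treated-vs-untreated fibers.
Dataset means and SDs are unweighted across fibers; the fork-weighted
pooled stall rate is reported alongside because the aggregation choice
is not determined by the measurement definition.

Lesion densities come from gel-quantified intact-molecule fractions
under a Poisson model, $\lambda = -\ln(f)/L$ per kb
(`poisson_lesion_density()`), with helpers for nick-spacing ranges and
expected lesion encounters per fork.

## The simulator

`simulate_fibers()` generates datasets with full ground truth. A linear
genome (default 25 Mb, about one dataset's worth of combed DNA)
replicates in continuous time: origins fire as a Poisson process over
unreplicated DNA at `origin_rate_per_mb_min` (default 2.3/Mb/min,
the measured fission-yeast mid-S rate), forks move at per-fork speeds
drawn from a truncated normal (default mean 0.91 kb/min, CV 0.1), stall
spontaneously per kb traversed, and at Poisson-placed lesions either
stall permanently (`p_stall_per_lesion`) or pause
(`pause_min_per_lesion`). Stalled forks never restart within the
window. Labeling starts 10 minutes into the simulation so pre-pulse
replicated unlabeled regions exist (these create the RUR ambiguity);
DNA replicated in minutes 10-15 is red, 15-25 green. The molecule is
then cut at Poisson points (mean fragment 450 kb), measured with 2%
multiplicative length noise, and fibers under 120 kb are flagged
excluded. A stall is flagged *detectable* in the ground truth iff it
begins before the chase starts; stalls during the chase only shorten
green tracks and are read as slower forks.

The default spontaneous stall rate (0.022 per kb traversed) was
calibrated once so that the true detectable stall fraction is about
0.14 -- the spontaneous level reported for untreated cells -- averaged
over three 25-Mb replicates. Damage presets set lesion densities of
1/kb (`mms_like`, with 0.3-min pauses and a small per-lesion stall
probability: frequent mild lesions), 1/25 kb (`nqo_like`, rarer bulky
lesions stalling 5% of encounters) and 1/50 kb (`bleo_like`, rare
severe breaks); their per-lesion severities are effective values chosen
to reproduce the qualitative regimes, not measured constants.

Numerical choices: integration uses a 0.05-min step (pulse boundaries
must be step-aligned, so label snapshots are exact); a fork hitting a
lesion forfeits the remainder of its step, which adds at most one step
to a pause; collision points interpolate linearly between the two
boundary positions; optical resolution (default 2 kb) is applied before
measurement noise. The resolution rule removes what cannot be
*separated*: sub-resolution unlabeled gaps vanish into a neighboring
track, sub-resolution end slivers are trimmed, and a sub-resolution
labeled track merges into an adjacent labeled track -- but an isolated
labeled punctum flanked by unlabeled DNA is kept, because fluorescence
detects bright spots well below the resolution limit; deleting them
would silently erase every late-firing chase origin.

## What passing tests do and do not show

The simulator reproduces the features the estimators rely on --
pattern geometry, stall detectability windows, fragmentation,
resolution merging, measurement noise -- but not fixed origin
positions, checkpoint feedback on origin firing, fork restart, or
dNTP-pool coupling between origin number and fork speed. Recovery
results therefore validate the estimator logic under the stated
generative model, not the biology of any particular dataset.

Measured properties of the method under the untreated operating point
(25-Mb datasets, three replicates in the acceptance suite):

* Gaussian-fit fork rate recovers the true speed within a few percent
  even though the raw sample mean is biased high by track fusion.
* The stall-corrected total origin firing rate runs ~10% low: chase
  origins whose green tracks fuse seamlessly with a converging
  neighbor are invisible in principle, and the probabilistic credit for
  stall-disrupted origins (at rate $s$) does not fully offset it.
* The estimated stall rate tracks the true detectable fraction within
  a few points near 0.14, but runs high at heavy stall burden
  (~0.4): $s$ is a junction-conditional quantity, survivor-biased
  upward because terminations destroy GUG evidence while stall
  junctions persist, so using it as the per-fork stall probability
  overstates ambiguous-event stalls. The treated/untreated *ratios*,
  which is how the measurements are used, are much less affected.
* End-exclusion (dropping the first and last labeled event per fiber)
  changes stall rate by well under 0.05 and fork rate by under 5%,
  matching the artifact-control reanalysis it models.

Test problem sizes are a deliberate compromise: unit tests use 3-12 Mb
genomes, the acceptance suite uses full 25-Mb datasets (about 45 fibers
each) for recovery and a 1000-fiber randomized corpus for the
enumeration oracle.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_fibers(sim_config(seed = 1))
fit <- replication_kinetics(sim$fibers)
print(fit)
#> <replication_kinetics> 51 fibers (23.7 Mb), 19 excluded; mode = probabilistic
#>   origin firing rate: 2.13 +/- 0.82 origins/Mb/min
#>   fork rate:          0.89 kb/min (Gaussian fit; sample mean 0.95, n = 469)
#>   stall rate:         20.1% +/- 8.6% (s_apparent = 0.324)
sim$truth$summary$detectable_stall_fraction
#> [1] 0.15
```

## Known limitations

* Stalls masked before measurement (a converging fork consumes the
  entire gap next to a stalled fork) are undetectable by construction;
  the ground truth records them as `masked`.
* The apparent stall rate is an approximation, not an estimate of the
  per-fork stall probability; all ambiguous-event corrections inherit
  its upward survivorship bias.
* Genomic positions of stalls are not inferred against a reference,
  and stalls during the chase are interpreted as slow forks, as the
  labeling design dictates.
* Fibers with no unlabeled DNA or no pulse-1 forks drop out of the
  per-kb and stall-rate aggregates respectively, with warnings.
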