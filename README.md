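# replifork

Analysis of dual-pulse labeled DNA combing data for replication
kinetics, with rigorous identification of stalled replication forks.

Cells in mid-S phase are pulse-labeled with CldU (red, 5 min) and
chased with IdU (green, 10 min); combed single DNA molecules then carry
ordered red/green/unlabeled tracks. From per-fiber track tables this
package computes origin firing rates, per-pulse fork densities,
Gaussian-fit fork rates, sister-fork asymmetry, and — its core — fork
stall statistics. A fork that stalls before the chase and never resumes
leaves a red track end facing an unlabeled gap: red–unlabeled–green
(RUG/GUR) junctions are unambiguous single stalls, green–unlabeled–green
(GUG) is the no-stall signature, and red–unlabeled–red (RUR) is
ambiguous. The apparent stall rate

s = (RUG + GUR) / (RUG + GUR + GUG)

is pooled across the dataset, and every ambiguous pattern is resolved by
enumerating its geometrically consistent readings, weighting a reading
that needs *k* extra stalls by *s*<sup>*k*</sup> (an RUR gap carries its
two-stall reading with weight *s*²; the minimal-stall reading takes the
remainder). Expected stalls per kb of unreplicated DNA and the fork
stall rate (expected stalls over expected first-pulse forks, stalled
forks included in the denominator) follow from the weight-averaged
counts, and origin/fork-density estimates are corrected for
stall-disrupted patterns. A Poisson model turns gel-quantified
intact-fragment fractions into lesion densities (λ = −ln f / L).

A stochastic simulator (`simulate_fibers()`) generates labeled fibers
with full ground truth — origin firing over unreplicated DNA, per-fork
speeds, spontaneous and lesion-induced stalls and pauses, fragmentation,
optical-resolution merging, measurement noise — so every estimator is
validated by parameter recovery.

Written for researchers analyzing single-molecule replication (fiber /
combing / spreading) experiments, and usable as a testbed for pattern
interpretation schemes.

## Worked example

```r
library(replifork)

sim <- simulate_fibers(sim_config(seed = 1))   # ~25 Mb, untreated defaults
fit <- replication_kinetics(sim$fibers)
print(fit)
#> <replication_kinetics> 51 fibers (23.7 Mb), 19 excluded; mode = probabilistic
#>   origin firing rate: 2.13 +/- 0.82 origins/Mb/min
#>   fork rate:          0.89 kb/min (Gaussian fit; sample mean 0.95, n = 469)
#>   stall rate:         20.1% +/- 8.6% (s_apparent = 0.324)

sim$truth$summary$detectable_stall_fraction
#> [1] 0.15
```

The origin firing rate (2.13 origins/Mb/min) and fork rate (0.89
kb/min) recover the generating parameters (2.3 and 0.91); the fitted
fork rate is preferred over the sample mean (0.95), which is inflated by
fused green tracks. The apparent stall rate (0.324) is the
junction-level quantity used to weight ambiguous patterns; the per-fiber
stall rate (20.1%) tracks the true detectable stall fraction (15.0% in
this dataset's ground truth). Comparing an MMS-like dataset (one lesion
per kb, short pauses, rare permanent stalls) against this one:

```r
mms <- simulate_fibers(mms_like(sim_config(seed = 2)))
cmp <- compare_kinetics(replication_kinetics(mms$fibers), fit,
                        metrics = c("fork_rate", "stall_rate"))
cmp[, c("metric", "ratio", "p_value")]
#>       metric     ratio      p_value
#> 1  fork_rate 0.7522036 6.428230e-19
#> 2 stall_rate 1.7529094 8.207114e-10
```

Forks slow to 75% of the untreated speed and stalling nearly doubles,
the frequent-mild-lesion regime.

Real data enter through `read_fibers()`: a TSV with columns
`dataset_id  fiber_id  track_index  label (R/G/U)  length_kb` (see
`?read_fibers`; `pixels_to_kb()` converts pixel measurements against a
lambda standard). A thin command-line wrapper with `simulate`,
`analyze`, `compare` and `lesions` subcommands is installed at
`inst/scripts/replifork-cli.R`.

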