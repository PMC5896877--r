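---
title: "Models and methods behind icmsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind icmsmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icmsmap)
```

## The experiment icmsmap models

Intracortical microstimulation (ICMS) through microelectrode arrays
implanted in primary somatosensory cortex (S1) can elicit conscious
sensations in people with spinal cord injury. In the percept-mapping
paradigm this package models, a participant receives one-second trains of
biphasic, charge-balanced, cathodic-leading pulses on a single electrode
per trial and reports, on cue, whether a sensation was felt and — if so —
its body location (receptive field), quality (a single-word descriptor
such as *squeeze* or *rightward movement*), intensity on a 1–10 scale, and
perceived duration (*short*, *medium*, *long*). Descriptors divide
percepts into two modalities: **cutaneous** (touch-like) and
**proprioceptive** (movement/position-like). Catch trials — identical cues
with no stimulation — estimate the false-positive rate.

Two designs are supported. The primary amplitude-mapping design
(Experiment 1) evaluates every stimulable electrode at eight amplitudes
(20, 30, 40, 60, 70, 80, 90, 100 µA) at a fixed 150 Hz, in blocks of a
pseudorandom electrode subset with three replicates per
electrode-amplitude pair and 10% interleaved catch trials. The
parameter-wide design (Experiment 2) crosses five electrodes with five
amplitudes (20–100 µA) and six frequencies (50–300 Hz), two replicates of
every triple per day over three days, so each triple accrues six
replicates and each amplitude-frequency combination 30 pooled
stimulations.

The central scientific question the analysis pipeline addresses: does
stimulus *amplitude* (rather than frequency) control which modality a
percept takes? The package's statistics reproduce that analysis chain on
simulated (or schema-compatible real) session tables.

## Charge safety

Charge per phase is `amplitude (µA) × phase width (µs) / 1000` nC, with a
hard ceiling of 20 nC per phase — the value reached at 100 µA and 200 µs.
`charge_per_phase()` and `stim_params()` refuse parameter sets above the
ceiling; the schedule builders validate their amplitude sets before
emitting a single trial.

## Scheduling under the adjacency constraint

Within a block, no two consecutive stimulation trials may use the same or
adjacent electrodes. We interpret adjacency conservatively as the
8-neighbourhood (Chebyshev distance 1, diagonals included) on the 7×7
array grid, and never across arrays. Because one stimulator delivers one
electrode per trial, "concurrently" is operationalized as *consecutively*;
catch trials deliver no current and are exempt.

No construction algorithm is prescribed by the protocol, so
`build_exp1_block()` uses randomized sequential construction: the next
electrode is drawn uniformly among feasible electrodes carrying the
largest remaining trial load (keeping loads balanced so no pocket of
mutually adjacent electrodes is left for the end), the amplitude uniformly
among that electrode's remaining levels, with bounded restarts on dead
ends. A subset dominated by one adjacency clique can be genuinely
unschedulable; the block builder then raises a scheduling error, and
`build_exp1_schedule()` responds by re-drawing its random partition of the
array (bounded retries). Everything is deterministic under a seed, and an
independent linear-scan checker (`count_adjacency_violations()`) is used
in the tests rather than trusting the constructor.

The catch count is `round(0.10 × stimulation trials)`; the 10% is taken of
the stimulation-trial count so it is computable before interleaving, and
catch positions are drawn uniformly among all slots.

## The generative model of percept reports

`simulate_experiment()` replaces the study's raw per-trial data with
draws from an explicit generative model. Per electrode (from
`make_electrode_population()`):

* `responsive ~ Bernoulli(0.48)` — only responsive electrodes can ever
  yield a report, and catch trials never do, so the simulated catch
  false-positive rate is structurally zero.
* Detection: `P(report) = clip(p_base + 0.002·A, 0, 1)` with
  `p_base ~ Beta(mean 0.526, concentration 25)`. A linear-and-clipped
  psychometric stand-in is used deliberately: the study reports only a
  weak dependence of detectability on amplitude, and no threshold-curve
  shape is available to fit. The defaults put the pooled report rate near
  381/1229 ≈ 0.31 of non-catch trials.
* Modality: `P(proprioceptive | report) = plogis(b0e + 0.03·A)` with a
  per-electrode intercept `b0e ~ N(−4.5, 2.5)`. The positive amplitude
  slope skews proprioceptive percepts toward higher amplitudes; frequency
  enters nowhere, making the frequency null true by construction. The
  intercept spread makes a realistic share of electrodes effectively
  unimodal; the mean and spread were chosen (via the logistic-normal
  marginal) so the pooled proprioceptive fraction sits near 79/381 ≈ 0.21
  and roughly 40% of responsive electrodes are cutaneous-only.
* Intensity: `round(2.0 + 0.02·A + ε)`, `ε ~ N(0, 1.9)`, clipped to the
  1–10 scale. The latent slope and the implied mean of 2.4 at 20 µA are
  the study's printed calibration values. Note that clipping at the scale
  floor attenuates the *fitted* slope to ≈ 0.017 — a deliberate,
  documented consequence of rating-scale censoring, not a bug.
* Duration: categorical with weights 225:122:12 (short:medium:long), and
  a 22/381 chance that no duration is recorded.
* Receptive field: each electrode has a home (region, plane) cell drawn
  from its array's somatotopic weights — the medial array favours the
  anterior upper arm (weight 0.46), the lateral array the posterior
  forearm (0.51) — and reports that cell with probability 0.90 plus the
  array-level weights for the remainder. The concentration 0.90 was set so
  that roughly half of responsive electrodes report a fully consistent
  region or plane, matching the study's 24/46.
* Impedance: per-electrode baseline `lognormal(log 40, 0.35)` kΩ (typical
  SIROF-tip magnitudes), identical for responsive and non-responsive
  electrodes, with multiplicative per-session jitter (sdlog 0.05) — so
  impedance carries no information about any percept outcome, making the
  impedance control tests null by construction.

All randomness flows from one master seed through named streams
(`derive_seed(seed, "population")`, `"responses"`, `"impedance"`, ...), so
components can be re-run independently yet the whole simulation is
bit-reproducible.

### What the generator does and does not emulate

The simulator reproduces the *statistical summary structure* of the
study's data: responsive fraction, report counts, modality composition and
its amplitude dependence, intensity calibration, duration mix, receptive
field somatotopy and consistency, impedance nulls, and zero catch false
positives. It does not model biophysics (current spread, charge
integration), day-to-day percept drift, spatial continuity of receptive
fields beyond categorical weights, or sequential dependence beyond what
the design induces. Two known infidelities: proprioceptive-only electrodes
are rarer in simulation (~2% of responsive electrodes versus 6/46 ≈ 13%)
because every responsive electrode accrues ~15 reports under the full
design, and per-amplitude report counts are more even than the study's
21–93 range. Passing tests therefore certify the pipeline's behaviour on
data with this structure, not on every pathology real data may show.

## Statistical core

The tests the pipeline needs are implemented in the package and checked
against brute-force oracles (and against the reference implementations in
base R) to 1e-10 in the test suite:

* **Kruskal–Wallis** with average ranks and the tie-correction divisor
  `1 − Σ(t³−t)/(N³−N)` — mandatory here because amplitudes take eight
  discrete values, so samples are heavily tied. p-values come from the
  χ² approximation with k−1 df; the result also carries `N − k` so the
  `(k−1, N−k)` display convention used in reports is recoverable.
* **Pearson correlation** with the exact t-transform p-value.
* **Two-sample Kolmogorov–Smirnov** via ECDF merge, asymptotic Kolmogorov
  p-value with the standard effective-n refinement.
* **Dunn–Šidák correction** `1 − (1−p)^m`, used across per-amplitude
  trial-history tests.
* **First-order polynomial fits** in closed form, and a plain **Gaussian
  KDE** with Silverman's rule-of-thumb bandwidth for amplitude and
  bootstrap-slope distributions.

Degenerate inputs are reported, not papered over: a constant sample yields
H = 0, p = 1 for the rank test; zero-variance correlations raise an error
(surfaced as a `no-variance` record by the pipeline); a constant KDE
sample asks for an explicit bandwidth.

## Resampling procedures

**Modality bootstrap.** Reports are unevenly distributed over amplitudes,
which could bias the apparent amplitude-modality relationship. The
bootstrap redraws 15 reports per amplitude (10,000 iterations), computes
per-amplitude percentages of each modality, and fits a line per iteration;
the slope distributions (percentage points per µA) and their KDEs are the
de-biased effect summary. Draws are *with replacement* — the standard
bootstrap, which also tolerates pools smaller than 15; a
without-replacement mode exists behind a flag for pools that support it.
Because a resample's modality count at one amplitude depends on the pool
only through its proportion, counts are drawn directly from the binomial
(or hypergeometric) distribution — draw-for-draw equivalent and fully
vectorized. Cutaneous and proprioceptive percentages are complementary, so
the two slope samples are exact mirrors; both are reported for plotting
symmetry.

**Trial-history null.** Whether a report is more likely after a hit than
after a miss is tested against a shuffle null: detection outcomes are
permuted within (session, amplitude) strata — holding per-stratum hit
counts fixed, the granularity at which the empirical distributions are
estimated — and the conditional report proportions after hits and after
misses are recomputed 10,000 times. The empirical conditionals are
compared with the 5th–95th percentile range of the shuffle distribution,
and a companion Kruskal–Wallis test compares the three conditions (all
trials, after hit, after miss) per amplitude with Dunn–Šidák correction.
First trials of a session have no predecessor and are excluded; catch
trials are excluded from conditioning by default (they deliver no
stimulus) but can be included as forced-miss predecessors via a flag.

Two numerical choices matter here. The within-range flag is computed from
the empirical value's add-one percentile rank among the shuffle draws,
counting ties on both sides, rather than by comparing against
interpolated sample quantiles: a permutation distribution of proportions
is discrete, interpolated quantiles can cut into a boundary atom, and
only the rank form keeps the probability of falling outside at or below
10% under exchangeability (the reported `hit_lo`/`hit_hi` quantile
columns are for plotting). And the conditional distributions are most
informative per experimental session: pooling conditionals across
sessions mixes proportions with different denominators, which thins out
the exact ties that make the range criterion conservative. The
calibration tests therefore evaluate the envelope on single-session
datasets, the unit at which the distributions are estimated.

One subtlety the simulator exposed: under the *default* heterogeneous
configuration the adjacency constraint plus between-electrode detection
differences induces a genuine (negative) lag-1 dependence — a hit tells
you the previous electrode was a good one, and the constraint forbids
reusing it. The envelope check is therefore validated on sessions with a
homogeneous detection probability, where outcomes really are i.i.d.
within strata; on heterogeneous data the procedure is measuring a real
design-induced effect, and that is the correct behaviour.

## Analysis conventions

* Percentiles interpolate linearly between order statistics; modes on
  discrete values take the smallest value among ties.
* "Mostly cutaneous/proprioceptive" for mixed electrodes means a strict
  majority; exact ties are their own class.
* Intensity normalization is min–max per session day,
  `(x − min)/(max − min)`, chosen as the evident intent of mapping ratings
  onto 0–1; the literal variant `(x − min)/max` is available via
  `normalization = "literal"`. Sessions with constant intensity cannot be
  normalized and are flagged and excluded from the variability analysis.
* The per-electrode "likelihood of elicited percepts" used in the
  impedance correlation is the electrode's detected/non-catch trial ratio
  pooled over days.
* The descriptor table pools descriptors beyond a cumulative 90% coverage
  threshold into `"other"`.
* The SD-versus-amplitude intensity correlation is computed per amplitude
  pooled over sessions; a per-session-per-amplitude alternative would be a
  straightforward variant but is not implemented.

## Problem sizes and reproducibility

Defaults follow the study protocol: full Experiment-1 schedules
(96 × 8 × 3 stimulation trials + 10% catch), 10,000 bootstrap iterations,
10,000 permutations. The test suite exercises the same code at reduced
sizes chosen for quick iteration (hundreds of permutations, tens of
replicate seeds); the acceptance script averages 50 full Experiment-1
replicates. Every stochastic stage takes an explicit seed, and seeded runs
are bit-reproducible end to end (schedules, sessions, resampling,
serialized CSVs).

## Known limitations

* The linear-clipped psychometric function is a stand-in, not an
  inference; real detection thresholds are sigmoid in amplitude.
* Electrode-subset size per block (default 8) and the exact catch-count
  base are not specified by the protocol; both are configurable.
* The KS p-value is asymptotic; at the per-electrode sample sizes used
  here (≈ 48 + 50) that is adequate, but very small fixtures should not
  lean on its tail accuracy.
* Reported `n` for conditional trial-history proportions can be very
  small at rarely-hit amplitudes; envelopes widen accordingly, and
  undefined conditionals (no hit or no miss predecessors) are flagged
  rather than imputed.
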