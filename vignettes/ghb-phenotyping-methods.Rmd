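---
title: "Methods: quantifying oral GHB self-administration and addiction-like phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying oral GHB self-administration and addiction-like phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ghbsa)
```

## The measurement problem

Oral GHB self-administration is measured through three very different kinds
of raw record: daily bottle weighings in the home cage, timestamped lever
and head-entry events in operant boxes, and frame-indexed tracking
coordinates in memory and anxiety assays. Each carries its own conventions
and edge cases (evaporation, cue timeouts, rats sitting on the objects they
are supposed to explore). This vignette documents how `ghbsa` defines each
derived quantity, the tunable parameters that matter, what the cohort
simulator does and does not emulate, and where we made genuinely open
design choices.

## Home-cage intake

A bottle reading is a (start mass, end mass) pair. We treat dilute aqueous
GHB as density 1.00 g/mL, so grams lost equal millilitres drunk, and a
concentration of c % w/v equals 10c mg/mL. Daily dose is therefore

$$\mathrm{dose} = \frac{\Delta m \,[\mathrm{g}] \times 10c}{\mathrm{bw}\,[\mathrm{kg}]} \quad [\mathrm{mg/kg}].$$

Body weight is measured weekly; daily doses use linear interpolation
between weighings, held flat outside the first and last measurement.
Negative mass losses (handling error) are clamped to zero with a warning.
Preference over any window is the drug share of total fluid,
$100\,\Sigma d/(\Sigma d + \Sigma w)$; we adopt the fraction form (rather
than drug/water) because preference is conventionally reported as a
percentage of total intake. Intake over the access period is summarised by
the trapezoidal AUC over the day index, with missing days linearly
interpolated and logged. An acute dose above 87.5 mg/kg (strict
inequality) is flagged as pharmacologically relevant. A 10-min drinking bin
is called a binge when it exceeds the session mean by more than 2 SD *and*
exceeds 10 s of drinking in absolute terms; both thresholds are
configurable because "a distinct peak" is not otherwise defined.

**Evaporation.** By default no evaporation correction is applied: measured
loss is taken as consumption. When sentinel readings (bottles in an
unoccupied cage, `animal_id == "sentinel"`) are present,
`homecage_intake(..., evaporation_correction = TRUE)` subtracts the mean
daily sentinel loss from every bottle before converting to volumes. With
the simulator's default half-normal spillage (SD 0.5 g per bottle per
day), the uncorrected daily dose carries an upward bias of roughly
0.4 g × 10c / bw — about 10 % at 7 % w/v in a 350 g rat — so analyses that
compare recovered to configured intake enable the correction.

## Operant schedule replay

Replay is a pure function of (event log, schedule). The semantics:

- Active presses outside cue-timeout windows advance a ratio counter; on
  reaching the requirement, a presentation starts. The dipper (10 s) and
  the cue light (15 s) both start at the completing press, so the cue
  window contains the dipper window.
- Presses during the cue timeout are recorded (they appear in `alp` and
  `timeout_presses`) but never advance the counter — they have no
  programmed consequences. Because the intended tally convention of
  published totals is ambiguous, both `alp` and `alp_excluding_timeout`
  are emitted.
- A presentation counts as *consumed* when at least one head entry falls
  inside its dipper window; a configurable grace period (default 0 s)
  can extend that window. Head entries at other times are recorded but
  unused.
- Under PR, the requirement for reward $n$ is
  $\mathrm{round}(5e^{0.2n}-5)$, floored at 1 — the canonical progression
  1, 2, 4, 6, 9, 12, 15, 20, 25, 32, … The breakpoint is the requirement
  of the last completed presentation.
- Under NR, presses are recorded and nothing is ever presented.

Acquisition follows the three-session rule: an animal is excluded after
any three consecutive sessions without a reward (checked first), acquired
after any three consecutive sessions with at least one reward, otherwise
in progress.

Session dose is `consumed × reward_volume × 10c / bw_kg`; the habit ratio
divides NR active presses by the last reinforced FR4 session's active
presses before the NR session; quinine resistance is the trapezoidal AUC
of session dose against quinine dose (g/L) over the ascending series 0,
0.1, 0.3, 1.0 g/L.

## Severity classification

The four addiction-like measures (intake AUC, PR active presses, habit
ratio, quinine AUC) are z-normalised against the cohort using the sample
SD (n − 1); the spec of "the standard deviation of the whole group" does
not fix a denominator, and we chose the sample form used by default in
every mainstream statistics package. All four leave-one-out triples are
summed per animal, and the top quartile of each combination is flagged.
Quartile size is `floor(q·n)` (3 of 12); `floor` rather than `ceiling`
generalises the 3-of-12 case to cohorts not divisible by four. Ties at the
quartile cutoff — possible with discrete measures — are broken by the
higher raw (unnormalised) triple total, then lexicographic animal id, and
every tie-break is logged in the result's metadata. Consistency is the
number of combinations (0–4) in which an animal is flagged. Animals with
any missing measure are dropped from all four computations, never
imputed.

The > 2 SD outlier rule (candidate included in mean and SD) is applied,
as an exclusion, only to analyses involving the motivation measure (the
correlation set) — not to the severity table itself. Note an arithmetic
consequence of including the candidate: with sample SD the largest
attainable deviation is $(n-1)/\sqrt{n}$ SD, so no point can be flagged at
$k = 2$ in groups of five or fewer; the rule only has power at realistic
cohort sizes.

## Assay scoring

NOR exploration counts frames where the nose is within 8 px of the object
centre (inclusive — "within" is read inclusively) *and* the body centre is
outside the object disk, divided by the frame rate; a trial with more than
10 % missing nose coordinates raises a data-quality error rather than a
silent estimate. The 8-px threshold depends on unreported image
resolution, so it is a parameter with 8 as default, recorded in results
metadata. DI is $(t_{novel}-t_{old})/(t_{novel}+t_{old})$, undefined (NA,
with a warning) when total exploration is zero. EPM frames are assigned by
body centre (the standard convention) to rectangular open/closed/centre
zones; frames outside every zone are assigned to the nearest zone and
counted. Open-arm latency defaults to trial duration when the animal never
enters. Behavior events are counted in half-open 10-min bins
$[kw, (k+1)w)$, so totals are conserved for any width.

## The cohort simulator

The simulator's defaults are the study conditions: 40 animals, half
female, half drug-exposed, 84 access days at 7 % w/v; male/female daily
dose presets 809.7 / 660.6 mg/kg with between-day CV 0.25 (the reported
between-animal spreads bracket this at roughly 0.28 and 0.14; a single CV
is configured and 0.25 is the male-leaning midpoint, since the latent
trait adds further between-animal spread); preference presets 20 % (male)
and 15 % (female); quinine series 0/0.1/0.3/1.0 g/L in 2 % solution.

**Susceptibility.** A quarter of drug animals (Bernoulli per animal) are
"prone": their latent trait is drawn as $0.5 + 0.5\,\mathrm{Beta}(2,2)$
versus $0.5\,\mathrm{Beta}(2,2)$ otherwise. The trait links
multiplicatively (log-linear gains) to daily intake, operant press rate,
NR persistence and quinine IC50 (0.4 g/L for prone vs 0.1 g/L baseline,
Hill coefficient 2 — calibrated so most animals stop responding by
0.3 g/L and all by 1.0 g/L while prone animals persist at 0.1–0.3). The
intake link is normalised by its *analytic* expectation under the
Beta-mixture, not by the realised cohort mean: the configured preset is
then the expected cohort mean while every animal's records stay
independent of who else is in the cohort — adding animals never perturbs
existing records, because every random quantity is drawn from a substream
keyed by (seed, animal id, context).

**Noise model.** Daily intended dose is lognormal around the animal's
mean; water volume follows the animal's preference target with 20 %
multiplicative noise; each bottle loses an additional half-normal
(SD 0.5 g) evaporation/spillage mass, and two sentinel bottles per day
record that loss alone. With all noise disabled the consumed volume is
exactly recoverable from the reading pair.

**Operant sessions.** Active presses are a Poisson process (baseline
0.004 presses/s, between-animal CV 0.35, susceptibility gain 0.8 —
calibrated so 3-h FR4 active-press totals span roughly 13–67 with
occasional high responders); the generator runs its own independent
schedule bookkeeping while emitting events, and the replay engine must
reproduce its tallies exactly — a generator/engine cross-check exercised
in the tests. Head entries follow 90 % of presentations inside the dipper
window. The simulated sequence is the full design: 7×FR1, 7×FR2,
7×FR4 (30 min), 3×FR4 (1 h), 3×FR4 (3 h, 7 %), 7×FR4 (3 h, 2 %), PR, NR,
a reminder FR4, then the quinine series.

**Assays.** NOR trials realise a per-animal true DI (baseline 0.35 ± 0.05
individual variation; drug males lose 0.35 in the post phase, pushing
their expected DI to zero) by per-frame placement of the nose in the
scoring zone of one object, with 1 %-per-object sitting frames that
exercise the body-centre exclusion and wander frames rejected from the
scoring zones so the intended dwell bookkeeping is exact. EPM trajectories
are zone bouts (exponential dwell, mean 5 s) realising a latent closed-arm
fraction (mean 0.55, SD 0.12), starting in the centre. Baseline anxiety is
generated independent of intake — the null relationship the regression
found — and behavior streams carry stable aberrant-behavior rates with no
withdrawal syndrome, plus binge-structured drinking events for drug
animals.

**What the simulator does not emulate:** within-day drinking
microstructure beyond coarse binge windows, pharmacokinetics (no blood
concentration model), pose-level motion or video, behavioral
classification (event streams are taken as classified), escalation over
weeks, and any correlation between baseline anxiety and intake. Passing
parameter-recovery tests therefore shows the analysis is a consistent
estimator of the quantities the generator encodes — not that real data
satisfy the generator's independence assumptions.

## Statistics

The correlation set computes two-sided Pearson correlations for the six
unordered pairs of the four measures (Pearson, since the published
analysis presents r with a regression line and confidence band;
two-sidedness is our recording of an unstated choice) and flags
significance at $\alpha/6 = 0.0083$. The motivation outlier exclusion is
applied before correlating. The anxiety regression is OLS of intake AUC on
baseline closed-arm fraction with a two-sided slope test. Group
comparisons (t tests, ANOVA families) are deliberately left to standard
facilities and reported descriptively; they are not part of the tested
core.

## Numerical and design choices

- PR requirement rounding: nearest integer, floored at 1.
- Dipper and cue windows both anchored at the completing press.
- Quartile size `floor(q·n)`; tie-break raw-total-then-id, logged.
- Sample SD everywhere a denominator is unstated.
- Degenerate inputs fail loudly with typed errors (`ghbsa_data_error`,
  `ghbsa_usage_error`, `ghbsa_config_error`) naming the offending field or
  measure; undefined ratios (zero reinforced responding, zero total
  exploration, zero total fluid) return NA with a warning rather than
  an error.
- Problem sizes in the test-suite simulations (cohorts of 4–20 animals,
  84 access days, 500 null replicates for the family-wise error check,
  1000 Monte-Carlo draws for link monotonicity and the quinine midpoint)
  were chosen to give sampling error comfortably inside the tested
  tolerances.

## Interface notes

Every analysis function takes a data frame first and returns a tibble, so
steps chain with the pipe; fitted/classified objects (`ghbsa_severity`,
`ghbsa_correlation_set`, `ghbsa_anxiety_regression`) provide `tidy()`,
`glance()` and `autoplot()` methods. The pipeline verbs
(`simulate_cohort()`, `homecage_intake()`, `replay_sessions()`,
`severity_table()`, `score_nor_trials()`, `score_epm_trials()`,
`correlation_set()`, `run_pipeline()`, `build_report()`) together with
`write_cohort()`/`read_cohort()` CSV round-tripping are the package's
interface; no shell wrapper is shipped because the expected user drives
the analysis from R.

```{r example}
cfg <- cohort_config(n_animals = 8, n_days_homecage = 28, seed = 1,
                     nor_trial_duration = 60, epm_trial_duration = 60,
                     behavior_session_duration = 1800)
ds <- simulate_cohort(cfg)
an <- run_pipeline(ds, evaporation_correction = TRUE)
an
glance(an$severity)
```

## Known limitations

Severity quartiles are unstable in small cohorts (a one-animal change can
move the cutoff); the simulator's frame-i.i.d. NOR placement has no
temporal bout structure, so dwell-time *autocorrelation* is absent; the
evaporation correction assumes sentinel bottles share the cage
environment; and the habit ratio inherits Poisson noise from both of its
session counts, which inflates its spread at low response rates.
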