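---
title: "Modeling directed signaling in BOLD networks with latent inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling directed signaling in BOLD networks with latent inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldnet)
```

## The model

`boldnet` analyzes regional fMRI BOLD time series with a directed linear
signaling model (structural and physiological modeling, SAPM). A network
is a set of regions, directed edges along which signaling is possible,
and *latent inputs* — unobserved external drives entering the network at
designated regions. Each connection carries two weightings:

* **D** — a nonnegative fraction partitioning a region's total input
  among its incoming connections. D values sum to 1 over each region's
  inputs.
* **B** — a signed factor describing how an incoming signal is converted
  into the region's output signaling. Positive B is excitatory (more
  input, more output), negative B inhibitory.
* **DB = D × B** — their product, the reported connectivity statistic.

Writing $S_{output}$ for the vector of regional output signals,
$M_{output}$ for the matrix holding DB on the edges, $\Lambda$ for the
latent DB block and $U$ for the latent time courses, the output
signaling is the self-consistent fixed point

$$S_{output} = (I - M_{output})^{-1}\,\Lambda\,U,$$

which exists whenever the spectral radius of $M_{output}$ is below 1 (a
dissipative network; the solver refuses anything else). The observable —
the model's prediction of the BOLD signal, which tracks a region's
metabolic demand and hence its *input* — is

$$S_{input} = M_{input}\,S_{output} + D_{lat}\,U,$$

with $M_{input}$ holding D on the edges and $D_{lat}$ the latent D
block. Everything is linear: doubling the latents doubles the
prediction exactly.

### Identifiability choices

D and B are not separately identifiable from time series, so the
engine fixes D by uniform row-normalization — each incoming connection
of a region receives `1/indegree` — and estimates B; DB is the reported
statistic. Because each latent also drives its target region's input
directly through the $D_{lat} U$ term, the latent time courses' scale
and sign are pinned by the data; no arbitrary normalization is applied
(an earlier design normalized fitted latents to unit variance, which
demonstrably corrupted the optimum and was removed).

Not every weighting is recoverable even then.
`connection_identifiability()` classifies each connection:

* **sink** — the target region has no outgoing edges, so its output
  signal (the only place this B enters) reaches no observable. The B is
  fixed at 0 during fitting and DB reported `NA`.
* **degenerate** — the connection lies in an exact trade-off direction
  of the gain map, typically because several of a region's inputs have
  collinear output signals (they descend from the same latent chain).
  These are estimated and reported, but individual values scatter along
  the flat direction; only combinations are meaningful.
* **identified** — everything else. Simulation checks in the test suite
  show these recover essentially exactly from noise-free data and with
  group-mean errors of a few hundredths from noisy data.

Very small networks (a 3-region cycle, short rings) additionally admit
column-space trade-offs that the gain-map analysis does not see: with
$K$ latents the data constrain only $\sim(R-K)K$ directions, so
closed-loop recovery demands networks, like the bundled 14-region brain
model, where that budget comfortably exceeds the parameter count.

## Fitting

`fit_sapm()` minimizes the summed squared difference between observed
(run-averaged, mean-centered) courses and $S_{input}$ over the B vector
and the latent time courses. The latents enter linearly, so they are
profiled out exactly — solved by linear least squares inside every
objective evaluation — and the B vector is updated by quasi-Newton
(BFGS) steps with an analytic gradient (the envelope theorem makes the
fixed-latent gradient exact for the profiled objective). The optimizer
runs from `n_restarts = 5` seeded random initializations, keeps the
best objective, and records a checkpoint trace that is non-increasing
by construction. A spectral-radius barrier (`rho_max = 0.95`) keeps
iterates in the dissipative regime. Convergence is declared when the
relative objective change drops below `tol = 1e-6` (or the objective
reaches the data's numerical floor); fits are bit-reproducible under a
fixed seed.

Per-region fit quality is summarized as
$R^2_r = 1 - SS_{resid,r}/SS_{total,r}$, the proportion of variance in
each sub-region course explained by the network model.

## Sub-regions

Each anatomical region is partitioned into 5 sub-regions by k-means on
standardized voxel time courses (`cluster_region()`), not on spatial
coordinates: the downstream use of a sub-region is time-course fitting,
and "approximately equal volume" is monitored by a balance warning
rather than enforced (k-means cannot guarantee it). One sub-region per
region enters the network fit; `search_subregions()` finds the
combination with least fit error by greedy coordinate descent — the
only well-defined descent on a categorical grid: from a seeded random
combination, sweep regions in canonical order trying all sub-regions
with the others fixed, keep strict improvements (ties keep the
incumbent), and stop when a full sweep improves nothing. Multi-start
(default 10) guards against local minima; on instances small enough to
enumerate, the multi-start search returns the exhaustive optimum. Each
candidate is evaluated by a full re-fit; a light fitting configuration
(1–3 restarts) keeps this affordable, and reliable candidate comparison
needs at least 2–3 restarts on noisy data. The winning combination is
frozen (`freeze_combination()`) and fingerprinted so all downstream
analyses — including a second network sharing regions — use the same
sub-regions or fail loudly.

## Significance against null simulations

Group-average DB values are not tested against zero: fits to pure-noise
data produce structurally biased DB values (the optimizer extracts the
dominant noise direction; on small networks the latent-edge B under the
null sits far from 0). `generate_null()` therefore fits the model to
replicated i.i.d. standard-normal time courses of matching dimensions
and `connection_ttest()` runs a Welch two-sample T-test of the
participants' DB values against the null sample, two-tailed, with
Welch–Satterthwaite degrees of freedom. Family-wise error is controlled
by Bonferroni: `fwe_threshold(alpha, m) = alpha/m`, which reproduces
the printed uncorrected thresholds 0.05/32 = 0.0015625 and
0.05/52 ≈ 0.00096.

Two sizing notes, chosen as the package's defaults at desk scale:

* The null-mean uncertainty scales as $sd_{null}/\sqrt{reps}$ and the
  null sd per connection can exceed 1, so detecting a group effect with
  sem ≈ 0.02 needs hundreds to thousands of replicates. The reference
  analysis used 10,000; `generate_null()` defaults to 1,000, and the
  calibration/power checks in the test suite use 400.
* `type1_calibration()` validates the whole chain: simulated null
  families tested at nominal α = 0.05 yield an empirical family-wise
  error around 0.02–0.05 (Bonferroni is conservative under the
  dependence between connections fitted from the same data).

## Time-course features

`mask_initial_volumes()` replaces the first points of each run (3 for
the brain acquisition, 2 for brainstem/cord) with the first subsequent
value — replaced, not removed, to preserve elapsed time.
`to_percent_signal_change()` uses the within-run mean as baseline, so
prepared courses are mean-zero.

The *initial rise* — the pre-stimulus signal increase over roughly the
first 40 s of a run — is measured as the mean over a plateau window
minus the value at the first retained volume. The plateau window
defaults to [40, 60) s: it ends before the 60-s inform cue so the rise
is not conflated with the cue response. Both sign conventions are
reported (`initial_rise` positive for a rise; `starting_point`, the
mean-centered first value, negative for a rise, matching the published
scatter-plot axis). Stimulation onset/offset responses are the maximum
over 15 s after the event minus the mean over the 10 s before it —
standard hemodynamic latency, configurable. `align_baselines()` shifts
one course vertically onto another's starting value for group overlay
plots.

## Group statistics

`ancova()` fits `value ~ group * covariate` and reports F-tests for the
group main effect, covariate main effect and interaction, with Type II
sums of squares by default (each term adjusted for the others;
appropriate for the unbalanced groups here; Type I available). Per-group
R² is the squared within-group Pearson correlation. Uncorrected
p-values are reported with the Bonferroni family threshold annotated,
never re-thresholded silently — mirroring the dual-threshold reporting
convention (effects listed at p < 0.01 with the family-wise cutoff
marked). `correlate()` and `two_group_compare()` (Welch, e.g. for
medication subgroups) round out the layer.

## Pupillometry

Pupil-area traces (pixel units, 500 Hz) carry white- and black-screen
reference segments at both ends of each trial; these are used only for
QC (black > task > white ordering), since results are reported in raw
pixel units. `repair_blinks()` marks samples below half the local
running median (floored by the whole-trace median, so long dropouts are
caught) as missing, linearly interpolates gaps up to 300 ms, and flags
trials with >50% missing as unusable. `group_mean_area()` averages
per-trial task means within groups; with the reference group means of
1920 and 1540 pixel units the percent difference is 24.7% — the
"approximately 25%" worked example. `average_trace()` resamples trials
to a common paradigm clock by linear interpolation before pointwise
averaging.

## The synthetic-data generator

No imaging data ships with the package; `sim_config()` +
`simulate_bold()` generate studies with the structure the analysis
assumes:

* **Paradigm** (`make_paradigm()`): 4.5-min runs; inform cue at 1 min;
  in Pain runs a 30-s stimulation block (10 contacts, onsets every 3 s)
  from 2 min. Brain TR 2 s → 135 volumes; brainstem/cord TR 6.75 s →
  40 volumes, 200 volumes per condition over 5 runs.
* **Latents**: event-locked components at the inform cue and
  stimulation onset/offset, convolved with a gamma-shaped hemodynamic
  kernel (peak 5 s — a standard BOLD convention; the width is
  configurable), plus a smooth stochastic fluctuation that keeps the
  latents linearly independent. This transient part is standardized to
  unit variance; a saturating initial-rise component
  $a(1 - e^{-t/\tau})$ with $\tau = 40/3$ s (~95% saturation by 40 s)
  is added afterwards so its configured amplitude (% signal change)
  is preserved rather than absorbed into the normalization.
* **Groups**: fibromyalgia-like (`FM`, 20 participants) and healthy
  control-like (`HC`, 17) — the sizes of the complete brain datasets in
  the reference study — with 5 runs per condition. The FM-like group's
  initial-rise amplitude is doubled (`group_multiplier = 2`), the
  generator's encoding of the observation that the rise is about twice
  as large in that group.
* **Truth**: default DB values are the published FM-group Pain-condition
  group averages for the connections named in the group-connectivity
  tables, with modest positive values on the two anatomy-completion
  edges; D defaults to the same uniform split the fitting engine uses,
  making closed-loop recovery well posed.
* **Noise**: i.i.d. Gaussian per volume (sd 0.2% signal change by
  default). Temporally autocorrelated noise is deliberately out of
  scope: the emulated pipeline removes physiological noise upstream.
* **Voxels** (`simulate_voxels()`): each sub-region contributes voxels
  equal to its course plus independent noise, with ground-truth labels
  for clustering checks. **Pupil traces** (`simulate_pupil()`):
  group-specific baselines (1920/1540 pixel units), run-start and
  stimulation dilations with equal peak across groups, reference
  segments, optional blink dropouts.

Everything is deterministic under the configured seed, and noise-free
output satisfies the forward equations to machine precision (a
cross-module test). What the generator does *not* emulate — spatial
structure, motion, physiological noise, scanner drift, nonlinear
hemodynamics — bounds what passing tests show about real data: they
validate the analysis chain's correctness and calibration, not its
robustness to artifacts the out-of-scope preprocessing would remove.

## Numerical and design notes

* The printed form of the output equation ("S_output = M_output
  S_output") is degenerate on its own; the latent-driven fixed point
  above is the only self-consistent linear reading in which latent
  inputs generate nonzero signaling.
* The brain fixture encodes the connections named in the published
  tables and text plus two canonical-anatomy edges (VTA→NAcc,
  Hypo→VTA) supplied so every region receives input, as the model
  requires; the brainstem/cord fixture completes its published
  connections with standard descending pain-modulation anatomy. Users
  with the exact figure topology can supply it as JSON
  (`load_network()`).
* Fit target is the run-averaged course per participant and condition;
  per-run fitting is available by passing single-run data.
* Candidate evaluation inside the sub-region search re-fits the model
  fully per candidate (no shortcut), cost-bounded at desk scale.
* Degenerate inputs fail fast with named errors: non-integer volume
  counts, stimulation beyond the run, non-finite time courses,
  zero-variance regions (flagged `NA` R²), singular ANCOVA designs,
  unknown pipeline-configuration keys.
* Problem sizes used by the packaged checks (chosen once as desk-scale
  defaults): 20 simulated studies for recovery, 400-replicate nulls,
  200 null families for calibration, 500 simulations for the
  interaction-p uniformity check, 25 replicate studies pooled over both
  conditions for the initial-rise ratio.

## A worked example

```{r example, eval = FALSE}
library(boldnet)

net <- brain_network()
paradigm <- make_paradigm("Pain", TR = 2)

# a small synthetic study at the generator's defaults
cfg <- sim_config(net, n_participants = c(FM = 4, HC = 4), n_runs = 2,
                  seed = 1)
tc <- simulate_bold(cfg, paradigm)

# fit one participant/condition and inspect
fit <- fit_sapm(dplyr::filter(tc, participant == "FM01"), net)
tidy(fit)       # per-connection D, B, DB with identifiability status
glance(fit)     # fit error, mean R^2, convergence
autoplot(fit)   # DB bar chart

# per-participant fits -> null-calibrated significance
pdb <- fit_sapm_groups(tc, net)
null <- generate_null(net, paradigm$n_volumes, reps = 200)
connection_ttest(dplyr::filter(pdb, group == "FM")[, c("connection", "DB")],
                 null)

# features and group statistics
feats <- timecourse_features(mask_initial_volumes(tc, 3), paradigm,
                             n_masked = 3)
```

Or run the whole chain end to end with `run_pipeline()` on a YAML
configuration (see `inst/extdata/demo_config.yaml`).

## Limitations

The model is a first-order linear approximation of signaling across a
hand-specified network: it omits within-region signaling, nonlinear and
time-varying coupling, and hemodynamic deconvolution, and its
conclusions are conditional on the network topology supplied. The
identifiability analysis tells you which weightings that topology can
support; treat `degenerate`-flagged estimates as combinations, not
individual effects. Null simulations at desk scale (hundreds of
replicates) leave visible null-mean uncertainty; use the full 10,000
when compute allows.
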