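---
title: "Methods: famine stimulus-response analysis in glucose-limited chemostats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: famine stimulus-response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Background and scope

Large industrial bioreactors mix imperfectly: cells circulating through
a fed-batch vessel repeatedly traverse zones where glucose is locally
exhausted, so famine — not balanced limitation — can dominate a cell's
environment. Stimulus-response experiments (SRE) reproduce this at
bench scale: an aerobic, glucose-limited chemostat of *Saccharomyces
cerevisiae* is run to a reference steady state (RS), the feed is then
stopped once for 2 minutes (the non-adapted response), and finally a
periodic 2-min-off / 7-min-on feed regime is applied until a dynamic
steady state (DS) establishes the adapted response.

`famineSRE` implements the quantitative layer of such an experiment:

1. simulation of extracellular glucose and biomass under continuous or
   intermittent feeding, with metabolic-regime classification and
   residence statistics (`simulate_chemostat`, `classify_regime`,
   `regime_residence`, `semilog_slope`, `minimum_glucose`);
2. identification and inversion of off-gas sensor dynamics and
   gas-phase mole balancing (`identify_sensor_model`,
   `convolve_sensor`, `deconvolve_signal`, `gas_transfer_rates`);
3. biomass-specific rates, yields, elemental recoveries and ATP-demand
   estimates with replicate statistics (`specific_rates`,
   `recoveries`, `qatp_estimate`, `welch_compare`);
4. energy/redox charge ratios and the classical-MDS relaxation
   trajectory of intracellular metabolite panels (`energy_charge`,
   `reduction_charges`, `minmax_normalize`, `classical_mds`,
   `relaxation_metrics`);
5. a seeded synthetic-data generator with known ground truth
   (`generate_sre_dataset`), because no machine-readable raw dataset
   accompanies the study design the package emulates.

The numbered scripts under `analysis/` run these stages as a
reproducible narrative; `run_pipeline()` executes the full chain on a
dataset directory.

## Chemostat model

The well-mixed balances for extracellular glucose $C_s$
(µmol L⁻¹) and biomass $X$ (g L⁻¹) under feed flow $F(t)$ in working
volume $V$ (harvest balanced, $F_{out} = F$) are

$$\frac{dC_s}{dt} = \frac{F(t)}{V}\,(C_{s,feed} - C_s) - q_s(C_s)\,X,
\qquad
\frac{dX}{dt} = (\mu - F(t)/V)\,X,$$

with hyperbolic uptake $q_s = q_{max} C_s/(K_M + C_s)$ and
yield-coupled growth $\mu = Y_{xs}(q_s - m_s)M_{glc}$. Integration is
a fixed-step explicit 4th-order Runge–Kutta scheme (via `deSolve`,
`method = "rk4"`); each constant-feed segment of the schedule is
integrated separately so feed switches always coincide with grid
nodes. Glucose is clipped at zero after each segment and uptake is
evaluated on the clipped value; the system is non-stiff at these
parameters and `dt = 1 s` keeps the continuous steady state within
0.5% of the closed-form Monod solution (tested).

Regimes follow fixed thresholds on extracellular glucose: overflow
metabolism above 207 µmol L⁻¹, starvation (maintenance demands no
longer covered) below 53 µmol L⁻¹, limitation in between. Both
boundaries count as limitation, matching the strict inequalities in
which the thresholds are usually quoted. `regime_residence` assigns
each sampling interval the regime of its left endpoint — no
interpolation, so constructed square waves give exact fractions.

### Kinetic defaults

Published uptake parameters for this operating point are not part of
the packaged inputs, so the defaults are chosen once from two
constraints a practitioner would impose: the steady state sits at
$C_s^\* = K_M/10$ (the regime reported for high-affinity hexose
transport under these conditions), and the yield is the measured
0.494 g g⁻¹ at $D = 0.1\,h^{-1}$. The first constraint fixes
$q_{max} = 11\,q_{req} \approx 12.4$ mmol g⁻¹ h⁻¹ regardless of
$K_M$; $K_M = 1000$ µmol L⁻¹ then puts $C_s^\* \approx 100$ µmol L⁻¹,
inside the limitation window. With these defaults a 2-min feed stop
depletes glucose to a few µmol L⁻¹ — consistent with the observation
that full hyperbolic kinetics overpredict short-term starvation depth
(experiments find minima around 22 µmol L⁻¹, about what the simulator
produces when uptake is scaled to 60%, cf. `analysis/01`).

`semilog_slope` reports the depletion slope of $\ln C_s$ both per
second and per minute. Printed depletion slopes for such transitions
are ambiguous in their time base (values quoted "per second" are only
mutually consistent on a per-minute reading); the package therefore
never hard-codes a literature slope and always returns both scales
with the $R^2$ of the fit.

## Off-gas sensor model and deconvolution

Long tubing and foam traps between fermenter and gas sensors act as
mixing chambers. Each channel is modelled as one lumped
first-order-plus-delay element (`sensor_model`): a transport delay
followed by a lag with time constant $\tau$. A single apparent time
constant per sensor is identifiable from one step experiment, which is
how such trains are characterized in practice; sensor cells themselves
are in the $\tau \approx 55$ s class, while the full train can show
delays of minutes.

**Forward model.** `convolve_sensor` applies the exact discrete
solution of the lag for piecewise-linear input (first-order hold):
with $a = e^{-\Delta t/\tau}$ and $c = (\tau/\Delta t)(1-a)$,
$y_k = a y_{k-1} + (1-a)x_{k-1} + (1-c)(x_k - x_{k-1})$. Unlike the
zero-order-hold form this introduces no spurious half-sample phase
lag, and $\tau \to 0$ reduces to the identity.

**Identification.** `identify_sensor_model` takes the delay as the
time from the applied step to the first *sustained* departure beyond
3× the baseline noise (three consecutive samples, so an isolated noise
excursion cannot trigger detection), then fits $\tau$ by least squares
to the exact discrete step response of the forward model, with a small
continuous time-origin refinement. Identification is therefore exact
on its own forward model, and recovers $\tau$ within a few percent at
0.5% additive noise (tested).

**Inversion.** `deconvolve_signal` offers two inverses of the same
model:

* `smoothed_derivative` (default): the continuous-time inverse
  $\hat x(t) = y(t+delay) + \tau\,y'(t+delay)$ with the derivative
  from a moving local quadratic fit. The default window is 3 points:
  at 1-min logging a 5-point window spans 5 min, longer than the 2-min
  feed-off phase of the 9-min cycle, and visibly clips the cycle
  trough; the window must stay shorter than the fastest process phase
  being resolved. This estimator is noise-robust but a centered
  derivative has zero gain at the Nyquist frequency, so features one
  sample wide are attenuated even noiselessly.
* `exact`: algebraic forward-substitution inverse of the first-order
  hold filter. It reconstructs noiseless signals exactly — including
  square waves — but amplifies measurement noise near the Nyquist
  frequency (the inverse has a slowly decaying alternating mode).

The pipeline uses the smoothed-derivative inverse for phase means
(where both estimators are unbiased) and the exact inverse combined
with cycle-synchronous folding (`cycle_waveform`) for cycle
amplitudes: the repeated 9-min cycles are averaged sample-wise, which
suppresses the amplified noise as $1/\sqrt{n_{cycles}}$ while the
coherent cycle shape — and hence the amplitude — is preserved. This
mirrors how repeatable cycle amplitudes are actually reported from
such experiments (many cycles, replicate vessels).

**Mole balance.** `gas_transfer_rates` converts outlet mole fractions
to volumetric rates through the inert-gas balance
$F_{out} = F_{in}(1-y_{O_2,in}-y_{CO_2,in})/(1-y_{O_2}-y_{CO_2})$,
with the molar volume at normal conditions (0 °C, 1 atm,
22.414 NL mol⁻¹) configurable. Inert moles are conserved by
construction. Dissolved-gas dynamics and humidity/pressure corrections
are out of scope.

## Physiology: rates, recoveries, ATP demand

`specific_rates` computes $q_{glc} = D(C_{s,feed} -
C_{s,res})/(X\,M_{glc})$ and divides volumetric gas rates by biomass;
uptake rates are stored as positive magnitudes and rendered with a
leading minus in reports. The identity $q_{glc}\,Y_{xs}\,M_{glc} = D$
at vanishing residual glucose is kept exactly and used as a
self-consistency test.

`recoveries` closes three balances on specific rates, with biomass
formation entering as $D/M_{Cmol}$:

* carbon: $(q_{CO_2} + r_X + q_{other})/(6\,q_{glc})$;
* nitrogen: $0.2\,r_X / q_{NH_3}$ for the default composition;
* available electrons: $(\gamma_X r_X + 4\,q_{O_2})/(4 \cdot 6\,
  q_{glc})$, using degrees of reduction $\gamma(C,H,O,N) =
  (4C + H - 2O - 3N)/C$ with ammonia as nitrogen source
  ($\gamma_{glc} = 4$, $\gamma_X = 4.2$ for CH₁.₈O₀.₅N₀.₂). The
  $\gamma_N = -3$ convention is the package default and configurable
  through the composition object.

The biomass composition defaults to the standard yeast C-mol formula
CH₁.₈O₀.₅N₀.₂ (24.63 g C-mol⁻¹, i.e. ≈0.041 mol C g⁻¹, close to the
0.04 mol C g⁻¹ round figure used for storage-carbon arithmetic in
`storage_carbon_yield_effect`).

`qatp_estimate` uses a deliberately minimal respiratory accounting:
$q_{ATP} = 2\,q_{glc} + 2\,(P/O)\,q_{O_2}$ — substrate-level
phosphorylation at 2 ATP per glucose plus oxidative phosphorylation at
the given P/O ratio (default 1.08) per oxygen atom. Both coefficients
are explicit arguments and are returned with the estimate, because
published ATP-demand changes for this experiment class depend on the
exact accounting used and cannot be reproduced from rounded rate
tables alone; the package always discloses the formula next to the
number rather than tuning coefficients to match a quoted percentage.

`welch_compare` implements the two-sided Welch test with Satterthwaite
degrees of freedom and labels changes with $p > 0.05$ as "n.s.". When
only mean ± sd ± n summaries are available (the usual situation with
published tables), `replicates_from_moments` reconstructs a
deterministic replicate set with exactly the requested sample moments
({m−s, m, m+s} for n = 3); this makes the test reproducible without
access to raw replicates. Degenerate input (zero variance in both
groups, equal means) returns $p = 1$.

## Metabolome: charges and MDS trajectory

Charges are simple ratio statistics on pool sizes in µmol g⁻¹ dry
matter: the adenylate energy charge
$AEC = (ATP + \tfrac12 ADP)/(ATP+ADP+AMP)$, and the catabolic and
anabolic reduction charges $NADH/(NADH+NAD^+)$ and
$NADPH/(NADPH+NADP^+)$. All are invariant to common rescaling of the
pools and bounded in [0, 1]. `axp_normalize` applies per-species
cross-method factors (defaults ATP 2.71, ADP 1.88, AMP 1.21) that
rescale HILIC-quantified adenylates to a reference method; factors are
configuration, not constants.

The relaxation trajectory uses min–max normalization per metabolite
over the included sample set (constant columns map to 0 by documented
convention), the Euclidean distance matrix between samples, and
classical (Torgerson) scaling: $B = -\tfrac12 J D^{(2)} J$,
eigendecomposition, coordinates from the top-$k$ eigenvectors scaled
by $\sqrt{\lambda}$, $k = 2$. Eigenvector signs are inherently
arbitrary; the package fixes them deterministically (first
non-negligible loading of each axis made positive) so repeated runs
are bit-identical. If fewer than $k$ eigenvalues are positive, fewer
axes are returned with a warning. The implementation is tested against
`stats::cmdscale` as an independent oracle and against
distance-preservation on planar configurations.

Published metabolite panels for this experiment class disagree on
whether 28 or 29 metabolites enter the MDS; the package therefore
takes an explicit inclusion list (`config$metabolome$include`) instead
of hard-coding a count. Replicates are collapsed to per-cell means
before normalization (replicate counts may differ between series);
charge uncertainties, where needed, propagate by the first-order delta
method from replicate means.

`relaxation_metrics` reports embedded distances to two anchors — the
pre-perturbation reference and a designated attractor sample — plus a
monotone-convergence flag over a chosen suffix, which distinguishes a
converging spiral (non-adapted relaxation) from a closed cycle
(adapted limit behavior).

## Synthetic data generator

`generate_sre_dataset` emulates the experimental design, not the
measurement physics:

* **Operating point.** 1.7 L working volume, 22.5 g L⁻¹ glucose feed,
  2.83 mL min⁻¹ continuous feed (D ≈ 0.1 h⁻¹), 0.8 NL min⁻¹ aeration;
  intermittent phase at 3.64 mL min⁻¹ for 7 of every 9 min, which
  preserves the cycle-averaged dilution rate.
* **Phases.** 1 h of reference steady state; one 2-min feed stop with
  30 min of tracked recovery; then 333 nine-minute cycles of the
  intermittent regime — five residence times at D = 0.1 h⁻¹, the
  operation time after which a dynamic steady state is conventionally
  assumed. Tests that only exercise structure use shorter phases
  explicitly.
* **Gas truth.** Volumetric O₂/CO₂ rates are derived from the
  simulated uptake stoichiometrically: all non-assimilated glucose
  carbon leaves as CO₂ and oxygen closes the electron balance, so
  carbon, nitrogen and electron recoveries are exactly 100% in the
  noiseless bundle by construction. At the default yield this
  reproduces specific rates in the observed range
  (q_O₂ ≈ 2.2 q_glc, q_CO₂ ≈ 2.4 q_glc). Mole fractions follow by
  inverting the inert-gas balance, then sensor smearing (default
  delay 180 s, τ = 120 s per channel — the "apparent constants of
  minutes" regime of a real sensor train) and noise at 1-min logging.
* **Metabolite panels.** Each metabolite relaxes by piecewise
  first-order kinetics: decay toward a famine level during the feed
  stop, recovery toward the steady level afterwards, plus an optional
  damped excursion anchored at famine onset for the AMP/ADP/IMP
  overshoot shape. Pool levels use published steady-state values where
  available (ATP 8.12 → 3.56 µmol g⁻¹ over the feed stop, NADH 0.17,
  catabolic charge ≈ 0.046, NADPH/NADP⁺ ≈ 1.28, AEC ≈ 0.90, AMP peak
  ≈ 3.9-fold) and order-of-magnitude placeholders documented as
  synthetic otherwise (`default_metabolite_specs`). These are shape
  emulations, not kinetic models — rate laws and regulation are
  deliberately out of scope.
* **Noise.** Multiplicative Gaussian per observation, truncated at
  zero (concentrations and fractions are positive; reported scatter is
  roughly proportional): 0.2% on gas fractions, 5% on metabolite
  observations, 0.5% on feed-rate readings, 1% on biomass. Triplicate
  panels and process measurements. The ground truth is a pure function
  of the scenario: the same seed reproduces the bundle bit-exactly and
  different seeds change only the noise.

What passing tests on this generator do **not** show: recovery of real
LC-MS/MS quantification biases, biological replicate structure beyond
i.i.d. multiplicative noise, overflow-metabolite excretion (none is
modelled, matching the respiratory operating point), or the absolute
accuracy of the placeholder pool levels.

## Numerical choices and degenerate inputs

* Time is internally in seconds, concentrations in µmol L⁻¹, specific
  rates in mmol g⁻¹ h⁻¹; glucose molar mass 180.16 g mol⁻¹.
* `dt = 1 s` default; intermittent schedules require switch times to
  be integer multiples of `dt` (errors otherwise rather than
  interpolating events).
* Deconvolution of the last `delay` seconds of a record is
  unobservable; the tail is held at the last reconstructed value and
  excluded from round-trip error metrics.
* `classify_regime` rejects negative glucose; `energy_charge` and
  `reduction_charges` reject all-zero pools; `welch_compare` returns
  $p = 1$ for identical zero-variance groups; `minmax_normalize` maps
  constant columns to 0; `classical_mds` warns and truncates when $k$
  exceeds the positive-eigenvalue count.
* Full-pipeline determinism (same inputs and config → byte-identical
  report files) is asserted in the test suite.

## Problem sizes

The test suite runs shortened generator phases (0.5 h reference, ≤ 10
cycles) for structural checks and one full-length scenario (1 h + 32
min + 333 cycles at 1-s resolution, ≈ 55 h of simulated process) for
the end-to-end parameter-recovery checks; `scripts/acceptance.R`
repeats the full-length recovery on three independently seeded vessels
in about half a minute on one CPU.

## Known limitations

* The sensor train is one lumped mixing chamber per channel; a chain
  of chambers (higher-order response) is not identified or inverted.
* No statistical reconciliation of redundant measurements: recoveries
  report closure, they do not redistribute residuals.
* The ATP-demand estimate is an accounting identity on two rates, not
  a metabolic model; growth-coupled corrections are not included.
* Lifelines of cells in a large vessel are consumed (as time series),
  never generated — hydrodynamics is out of scope.
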