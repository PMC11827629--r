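---
title: "Models and methods behind aptakinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aptakinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptakinetics)
```

`aptakinetics` implements a complete computational chain for decoding
aptamer–protein binding kinetics from single-molecule FRET (smFRET) time
traces and for translating those kinetics into predicted biosensor
performance. This vignette is the package's own account of the underlying
models, the estimators, the numerical choices, and their known limits.

## 1. The two-state binding model

A surface-immobilized protein is visited transiently by a fluorescently
labeled aptamer at concentration $c$. The hidden process is a two-state
alternating renewal process:

* unbound dwell times $\tau_{ub} \sim \mathrm{Exp}(k_{on} c)$,
* bound dwell times $\tau_b \sim \mathrm{Exp}(k_{off})$,

from which the kinetic constants follow as
$k_{off} = 1/\bar\tau_b$, $k_{on} = 1/(\bar\tau_{ub}\, c)$ and
$K_d = k_{off}/k_{on}$. Memorylessness of the exponential is what makes the
truncation corrections below exact.

`simulate_state_path()` draws this process with the initial state taken
from the stationary occupancy $k_{on}c/(k_{on}c + k_{off})$, so the path
carries no startup transient; the first and last dwells are censored by the
observation window and flagged as such downstream, which makes the choice
of initial state irrelevant for estimation.

## 2. The synthetic trace generator

`render_trace()` converts a state path into donor/acceptor intensity
series the way a camera would: each frame (default exposure 0.1 s)
integrates the bound occupancy *exactly* over its interval — partial frames
carry intermediate intensity. Midpoint sampling would instead produce a
small occupancy-dependent bias in apparent dwell lengths, which is why
exact integration is used. A frame with bound fraction $f$ emits
$f \cdot I_{tot}$ total intensity, split as acceptor
$= E \cdot f \cdot I_{tot}$, donor $= (1-E) f I_{tot}$, where $E$ is the
molecule's FRET efficiency. Both channels then receive a constant
background and additive homoscedastic Gaussian noise.

Defaults are the study conditions the package models: 5 nM aptamer, 600-s
movies of 6000 frames, and ensembles of a few hundred molecules per field
of view. Two labeling chemistries are emulated through the per-molecule
FRET draw:

* `fixed_2pca` — site-specific N-terminal labeling: $E_{mol} \sim$
  Normal(0.38, 0.14) truncated to $[0,1]$;
* `heterogeneous_nhs` — lysine (NHS-ester) labeling with variable
  fluorophore position: $E_{mol} \sim$ Uniform(0.2, 0.8).

Donor-only events (the population at $E \approx 0$ in real histograms)
arise from two modeled photophysical mechanisms: a fraction of molecules
(default 10%) carries no active acceptor, and an optional single
irreversible acceptor bleach time $\sim \mathrm{Exp}(\lambda_{bleach})$
(default off in kinetic studies). Both force $E = 0$ while leaving total
intensity unchanged, so they shape the FRET histogram without disturbing
the dwell-time kinetics.

The camera gain, background level and noise are not quantities the study
reports; the defaults (total intensity 1000, background 100, noise SD 100,
i.e. a signal-to-noise ratio of 10) were fixed once at values typical of
EM-CCD TIRF recordings, at which threshold misclassification is a
sub-$10^{-3}$ per-frame event and contributes negligibly to the kinetic
estimates.

**What the generator does not emulate:** spot detection and hotspot
pairing (the pipeline starts from extracted traces), spectral cross-talk
and donor leakage, intensity blinking, heterogeneous per-molecule rates,
and drift. Passing recovery tests on these synthetic ensembles therefore
demonstrates correctness of the estimators under the stated model, not
robustness to every artifact of real recordings.

## 3. Trace analysis

Segmentation follows the classic total-intensity recipe:

1. **Threshold** (`threshold_total_intensity`): 1-D two-state K-means on
   donor + acceptor; the threshold is the midpoint of the two cluster
   centers. Centers are initialized at the 10th/90th percentiles, which
   makes the clustering deterministic (K-means with random restarts is
   not). A trace whose center gap does not exceed three times the
   within-cluster robust noise (residual MAD) is flagged "no binding"; a
   global MAD would wrongly flag strongly bimodal traces, because the MAD
   of a balanced two-level signal is of the order of the gap itself.
2. **Segmentation** (`segment_trace`): maximal runs above threshold
   become candidate events; only runs of more than three consecutive
   frames (`min_frames = 4`, the strict reading of that phrase) are kept
   as binding segments. The inclusive reading is available as
   `min_frames = 3`. Candidates of every length are retained alongside,
   because the *unbound* dwell analysis needs them (Section 4).
3. **Event FRET** (`event_fret`): per-frame $E = I_A/(I_A + I_D)$ on
   background-subtracted intensities, averaged over the segment and
   clipped to $[0,1]$. The per-trace background is the per-channel median
   of below-threshold frames — the study does not state its background
   handling, and this estimator is robust to the bound fraction.
4. **QC** (`qc_filter`): molecules with fewer than 10 surviving events are
   rejected, with counts reported.

FRET populations are classified with a Gaussian mixture model
(`fit_fret_populations`, via `mclust`): models with 1–3 unequal-variance
components are fitted and the count is chosen by BIC. The mixture is used
as a *classifier*: components with mean below the donor-only cut (default
0.15, which sits between the donor-only peak at 0 and the 2PCA peak at
0.38) define the donor-only population, and the function reports both the
raw component parameters and the empirical weight/mean/SD of each
classified population. The fit carries `mclust`'s conjugate prior on the
variances: clipping at $E = 0$ gives donor-only events a point mass at
exactly zero, on which an unregularized mixture likelihood degenerates.

A known accuracy limit: clipped donor-only events form a spike at 0 plus a
positive tail; the tail (roughly $E$ in 0.03–0.12) is partly assigned to
the FRET population and pulls its classified mean down by about 0.01 at a
10% acceptor-dark fraction. Together with molecule-level sampling of
$E_{mol}$ (SE $0.14/\sqrt{n_{mol}}$), recovered peak positions should be
read with an accuracy of roughly $\pm 0.02$ at a few hundred molecules.

## 4. Dwell-time kinetics

`extract_dwells()` converts segmentations into dwell samples:

* **Bound dwells** come from the filtered segments. A run of $n$ frames is
  scored as $(n - 0.5)\,\Delta$ (half-frame continuity correction,
  toggleable): averaged over the uniform phase of the event relative to
  the frame grid, an event observed over $n$ majority-bound exposures has
  expected true duration close to $n\Delta$, and the $-0.5\Delta$ pairs
  with the truncation point below. Dwells touching the first or last frame
  are censored and excluded (the censored fraction is reported); at 600-s
  traces and second-scale dwells the censored fraction is below 1%, which
  is why plain exclusion was preferred over Kaplan–Meier machinery.
* **Unbound dwells** are the gaps between consecutive *candidate* runs.
  Using only the length-filtered segments (the literal alternative,
  `gap_source = "segments"`) would bridge every discarded short binding
  event, summing several true unbound dwells into one and inflating
  $\bar\tau_{ub}$ by roughly $1/P(\tau_b > t_{min})$ — a 10–20% bias at
  the faster measured $k_{off}$ values, large enough to break parameter
  recovery. A discarded event is still evidence that the unbound state
  ended.

`fit_exponential()` is a left-truncated exponential maximum-likelihood
fit: by memorylessness $E[X \mid X > t] = t + 1/\lambda$, so the MLE of
the mean is simply the sample mean above the truncation point minus that
point, with standard error $\hat\mu/\sqrt{n}$. Default truncation points
are $(n_{min} - 0.5)\Delta$ for bound dwells (the shortest surviving
segment under the half-frame correction) and $\Delta/2$ for unbound ones
(gaps shorter than half a frame are never detected). MLE on the dwell
list, rather than least squares on a binned histogram, is unbiased under
the segment length filter; a count-weighted histogram fit is provided for
comparison (`method = "histogram"`). Residual frame-discretization bias is
of order $\lambda\Delta/2$ — under 5% whenever the mean dwell exceeds ten
frames.

`kinetic_rates()` applies the reciprocal definitions; $K_d = k_{off}/k_{on}$
holds per replicate by construction, and `summarize_replicates()` reports
mean ± sample SD across replicates (flagged undefined for a single
replicate). Replicate $K_d$ values are averaged after forming the ratio
per replicate, not recomputed from rounded averaged rates.

## 5. The flow-cell transport simulator

`run_scenario()` models analyte capture in a shallow QCM flow chamber
(height 0.64 mm, length 11.1 mm): advection–diffusion of the analyte

$$\partial_t c + u(y)\,\partial_x c = D \nabla^2 c,$$

under fully developed plane Poiseuille flow
$u(y) = 6U(y/H)(1 - y/H)$, coupled at the sensor (bottom) wall to Langmuir
binding

$$\frac{dB}{dt} = k_{on} c_w (\Gamma_{max} - B) - k_{off} B,
\qquad D\,\partial_n c = -\frac{dB}{dt},$$

with Dirichlet inlet (analyte for the first 100 s, then buffer until
300 s), convective outflow, and a no-flux top wall. The diffusion
coefficient default ($8.76\times10^{-11}\,$m²/s) is the literature value
for thrombin in water, and the receptor density default
($\Gamma_{max} = 2.3\times10^{-7}$ mol/m²) is the immobilized aptamer
surface concentration used in the study's simulations.

Geometry reduction: the cylindrical chamber is modeled as a 2-D slice
along the flow, with effective width $W = \pi d/4$ chosen so $W H$ equals
the disc's mean cross-sectional area — this preserves mean residence time
and wall shear, which are what the transport-limitation trends depend on.
Full 3-D hydrodynamics with the 1-mm ports is deliberately out of scope,
as is any Navier–Stokes solve (the flow is prescribed).

Discretization: finite volumes, first-order upwind advection,
second-order central diffusion, backward Euler in time. The transport
operator is constant, so its sparse LU factorization is computed once and
reused every step. The wall reaction is advanced by operator splitting:
per column, backward Euler on the Langmuir ODE with local mass exchange
$h\,\dot c_w = -\dot B$ reduces to a scalar quadratic solved in closed
form, conserving bulk + surface mass exactly. Global mass balance
(inflow − outflow − accumulation) is tracked every step from the implicit
solution and closes to direct-solver precision ($\sim 10^{-13}$
relative); runs abort if the residual exceeds $10^{-3}$. The wall cell is
2 µm high with geometric coarsening upward, resolving the ~70 µm
concentration boundary layer. Defaults are a 256 × 64 grid and
$\Delta t = 0.05$ s (reduced automatically if the advective CFL number
exceeds 2); property tests verify first-order error decay under joint
grid/step refinement and agreement with the closed-form Langmuir curve
(`well_mixed_reference`) to better than 1% in the well-mixed limit.

Sweep conventions: one-axis sweeps (`sweep_scenario`) report the capture
rate (least-squares slope of $B(t)$ over the association phase), peak and
final $B$, and release fraction. The $k_{on}$ sweep is run at
$k_{off} = 0.01$ s⁻¹: at $k_{off} = 1$ s⁻¹ the capture window is dominated
by the approach to the (low) Langmuir equilibrium, which would confound
the transport-limitation property the sweep probes. The $k_{off}$ sweep is
run at $k_{on} = 10^8$ M⁻¹s⁻¹.

**A physical limit worth knowing.** With the stated parameters the surface
is deeply adsorption-dominated: the Lévêque mass-transfer coefficient is
$k_c \approx 7\times10^{-7}$ m/s while $k_{on}\Gamma_{max}$ reaches
$2\times10^{-2}$ m/s, so a molecule released from the surface rebinds
almost surely before escaping, and the *apparent* release rate is
$k_{off}/(1 + k_{on}\Gamma_{max}/k_c)$ — orders of magnitude below
$k_{off}$. Under this model, fast-$k_{off}$ scenarios retain rather than
release their captured analyte within 300 s, and the sensitivity ranking
across aptamers is set by $K_d$ (apparent release $\propto K_d k_c /
\Gamma_{max}$) rather than by $k_{off}$ alone. Reported simulated
behaviors that require weak rebinding (near-complete release at
$k_{off} = 1$ s⁻¹; a sensitivity margin of NU172 over RE31, whose $K_d$ is
slightly lower) are not reproduced by this solver at the stated
$\Gamma_{max}$ and $k_{on}$; the corresponding acceptance checks are left
failing by design rather than weakened, and the discrepancy is analyzed
here. All remaining trends — mass-transport-limited onset vs flow rate,
strict linearity in concentration, insensitivity to $k_{on}$ over
$10^6$–$10^8$ M⁻¹s⁻¹, ordering of peak and retention by $k_{off}$, and
NU172/RE31 outperforming HD1 — are reproduced.

## 6. QCM signal processing

`sauerbrey_mass()` converts frequency shifts to areal mass with the
crystal sensitivity constant $C = 17.7$ ng Hz⁻¹ cm⁻² (5 MHz AT-cut
crystal); mass uptake lowers frequency. `smooth_and_baseline()` applies
the study's 100-sample centered moving average and subtracts the mean over
a user-marked pre-capture interval. `capture_slope()` is the windowed
difference estimator: frequency averaged over 30 s before the capture
onset and again over the 30 s ending 5 min later, divided by the elapsed
time — robust to both white noise and slow drift, and invariant to
constant offsets. `sensitivity_fit()` regresses capture slopes on
concentration over the flagged linear range (sub-LOQ points are excluded
but reported); `dissociation_and_regeneration()` normalizes the initial
rinse-phase slope by the captured signal and compares capture cycles for
regeneration recovery. Phase boundaries are user-annotated by default
(instrument phases are marked manually in practice); onset detection from
the data alone is deliberately not guessed at.

`synthesize_qcm()` closes the loop for testing: it converts a simulated
$B(t)$ to a frequency trace ($1$ mol/m² $\times M$ g/mol $= 10^5 M$
ng/cm²), adds drift and Gaussian noise, and is the basis of round-trip
tests that recover programmed capture slopes to within a few percent at
0.1 Hz noise. The analyte molar mass default (36.7 kDa, human
alpha-thrombin) is a literature constant exposed as an argument, not
hard-coded into the analysis.

## 7. Reproducibility and problem sizes

All randomness flows from explicit integer seeds (one per ensemble,
recorded in trace manifests; `run_pipeline()` logs every stage and its
counts). Frame indices are 0-based with half-open segment spans; times are
seconds; concentrations are molar internally with nM accepted at config
boundaries; transport runs in strict SI with bench units (nM, µl/min, mm)
converted at the `transport_scenario()` boundary.

The test suite runs reduced problem sizes chosen so every stochastic check
sits several standard errors inside its tolerance: kinetic recoveries use
100 molecules × 600 s per replicate (the acceptance script uses the full
300), transport trend sweeps use a 96 × 24 grid with $\Delta t = 0.1$ s
(the mass-balance check runs the full 256 × 64 grid), and convergence
checks use 60-s horizons.
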