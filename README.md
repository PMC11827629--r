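# aptakinetics

Decode aptamer–protein binding kinetics from single-molecule FRET (smFRET)
time traces, and translate those kinetics into predicted flow-cell
biosensor performance.

The package is aimed at single-molecule biophysicists and biosensor
developers working with transient-binding assays: a surface-immobilized,
acceptor-labeled protein (the motivating system is human alpha-thrombin)
is visited repeatedly by a donor-labeled aptamer (HD1, RE31, NU172 bind
thrombin's exosite I), and each visit appears as a high-intensity,
FRET-positive episode in a per-molecule fluorescence trace.

## What it computes

**Kinetics from dwell times.** Binding is modeled as a two-state
alternating renewal process with exponential dwells. From segmented
traces,

- `k_off = 1 / tau_b` (mean bound dwell),
- `k_on = 1 / (tau_ub * c)` (mean unbound dwell at aptamer concentration
  `c`),
- `K_d = k_off / k_on`,

with mean ± SD across replicate ensembles. Segmentation follows the
standard total-intensity recipe (two-state K-means threshold, events
longer than three frames kept, molecules with fewer than 10 events
rejected), and dwell means come from a left-truncated exponential MLE that
is unbiased under the event length filter. FRET populations
(`E = I_A / (I_A + I_D)` per event) are classified with a BIC-selected
Gaussian mixture, separating the donor-only population (absent or bleached
acceptor, `E ~ 0`) from genuine FRET events.

**Ground-truthed simulation.** `simulate_ensemble()` generates complete
synthetic fields of view — exponential state paths, exact frame
integration at 0.1-s exposure, per-molecule FRET heterogeneity (narrow
site-specific 0.38 ± 0.14 vs broad lysine-labeled 0.2–0.8), acceptor-dark
and bleaching photophysics, camera noise — with the ground truth returned
alongside, so every downstream estimator is testable without instrument
data.

**Flow-cell transport.** `run_scenario()` solves the 2-D
advection–diffusion equation for analyte in a shallow sensor chamber
(prescribed Poiseuille flow) coupled to Langmuir surface binding
`dB/dt = k_on c_w (Gamma_max - B) - k_off B` at the sensor wall
(finite volumes, implicit time stepping, mass balance tracked to solver
precision), reproducing the mass-transport-limited behavior of
quartz-crystal-microbalance (QCM) sensing: onset controlled by flow,
response linear in concentration, near-insensitivity to `k_on`, strong
sensitivity to `k_off`.

**QCM signal processing.** Sauerbrey conversion
(`17.7 ng Hz^-1 cm^-2`), moving-average smoothing and baselining, 5-min
windowed capture slopes, concentration sensitivity fits, normalized
dissociation rates and regeneration recovery, plus a synthetic QCM trace
generator driven by the transport solver.

## Worked example

Simulate an RE31-like ensemble (k_on = 1.1e8 1/M/s, k_off = 0.3 1/s at
5 nM aptamer), recover the kinetics over three replicates, and classify
the FRET populations:

```r
library(aptakinetics)

cfg <- trace_sim_config(k_on = 1.1e8, c = 5e-9, k_off = 0.3,
                        n_frames = 6000, seed = 7)
ens <- simulate_ensemble(cfg, 100)
ens
#> <fret_ensemble> 100 molecules, 6000 frames at 0.1 s

reps <- lapply(1:3, function(r) {
  cfg$seed <- 7 + r
  estimate_kinetics(simulate_ensemble(cfg, 100))
})
summarize_replicates(reps)
#> <kinetic_summary> 3 replicate(s)
#>   k_off = 0.296 ± 0.0024 1/s
#>   k_on  = 1.08e+08 ± 7.2e+04 1/M/s
#>   K_d   = 2.73 ± 0.021 nM

est <- estimate_kinetics(ens)
ev <- qc_filter(est$analysis$events)$events
fit_fret_populations(ev$mean_fret)
#> <fret_population_model> fitted on 10357 events
#> mixture components:
#>   weight    mean      sd      label
#> 1 0.0579 0.00126 0.00393 donor_only
#> 2 0.2819 0.33303 0.07583 fret_event
#> 3 0.6602 0.39383 0.16241 fret_event
#> classified populations:
#>        label weight    mean      sd
#> 1 donor_only 0.0591 0.00127 0.00287
#> 2 fret_event 0.9409 0.37611 0.14440
```

The recovered rates sit on the programmed ground truth (0.3 1/s and
1.1e8 1/M/s) to within a few percent — the residual offsets are the
documented frame-discretization and sub-frame-event biases — and the
classified FRET-event population recovers the programmed 0.38 peak with
the donor-only population (6% of events here) separated out at E ≈ 0.

Predict sensor behavior for the same aptamer in a 40 µl/min flow cell:

```r
sc <- transport_scenario(flow_ul_min = 40, c_in_nM = 10,
                         k_on = 1.1e8, k_off = 0.3)
resp <- run_scenario(sc)          # 300 s: 100 s capture, then rinse
capture_rate(resp, window = 100)  # mol m^-2 s^-1 during association
qcm <- synthesize_qcm(resp, noise_sd = 0.1)
capture_slope(smooth_and_baseline(qcm, window = 100), onset = 0)  # Hz/min
```

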