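# sptkin

Two-color single-particle tracking colocalization kinetics for membrane
receptors.

## The problem

Fast dual-color TIRF imaging of single membrane proteins (a receptor in one
spectral channel, its co-receptor in the other) produces per-cell trajectory
sets at surface densities of ~0.4–0.6 molecules/µm², 400 frames at 33 ms per
frame, with ~20 nm localization and registration error. At those densities,
molecules are frequently within any practical search radius *by chance*, so
apparent colocalization conflates true binding with random proximity.

`sptkin` implements the full analysis chain that separates the two:

* affine inter-channel **registration** from bead fiducials
  (`fit_registration`, `apply_registration`);
* **track repair**: greedy relinking of dropout-split segments
  (`link_segments`) and gap interpolation (`interpolate_gaps`);
* **diffusion**: time-averaged MSD and diffusion coefficients
  (`compute_tamsd`, `estimate_d`), and probability-level **confinement
  classification** with per-cell confinement proportions
  (`classify_confinement`, `confinement_proportions`);
* frame-wise one-to-one **colocalization detection** with the strict
  `f + 1` extension rule and right-censoring (`detect_colocalizations`);
* **random-colocalization deconvolution**: the observed colocalization-time
  distribution is modelled as the convolution of the true interaction-time
  distribution with a measured random-proximity null, inverted by
  Lucy–Richardson iteration (`null_distribution`, `deconvolve_dwells`);
* **kinetics**: censored exponential (geometric-at-frame-resolution)
  dissociation fit and density-normalized association constant,
  `kon = N_true / Σ_fields (T · N_A · ρ_B)` in µm² molecule⁻¹ s⁻¹, with
  percentile bootstrap CIs over cells (`estimate_koff`, `estimate_kon`,
  `estimate_kinetics`);
* **co-confinement vs co-diffusion** classification of interaction events
  (`classify_interaction_state`);
* **stepwise photobleaching** cluster sizing by BIC change-point
  segmentation, ≤ 15 steps (`fit_steps`, `cluster_size_distribution`);
* **BRET** plate corrections: double-baseline ΔBRET kinetics and
  acceptor-titration net BRET (`delta_bret`, `net_bret`).

Because raw imaging data of this kind are rarely shared, the package also
contains a ground-truthed stochastic **simulator** of the whole observation
process — reversible 1:1 binding between two diffusing species on a periodic
membrane patch, static confinement zones, localization noise, registration
offsets, detection dropout, multi-fluorophore bleaching traces, and BRET
plates (`simulate_field`, `calibrate_binding_hazard`,
`simulate_photobleaching_traces`, `simulate_bret_plate`). Every analysis
stage is validated by parameter recovery against the simulator's truth logs.
See the methods vignette (`vignettes/sptkin-methods.Rmd`) for the model, the
parameter choices, and what the validation does and does not establish.

## Worked example

Simulate a small condition (4 cells) with true dissociation rate
0.64 s⁻¹ and a hazard calibrated to an association target of
0.3 µm² molecule⁻¹ s⁻¹, plus a non-interacting control pair for the null,
then run the estimator chain:

```r
library(sptkin)
null <- control_null(4, seed = 990)          # random-colocalization kernel
r <- recovery_experiment("wnt16b-late-like", n_cells = 4, seed = 7,
                         null = null, n_boot = 100)
r$kinetics
#> <kinetics_estimate>
#>   kon : 0.323 um^2 molecule^-1 s^-1 (95% CI 0.311 - 0.343)
#>   koff: 0.708 s^-1 (95% CI 0.68 - 0.736); mean dwell 1.41 s
#>   4 cells, 720 events (53 censored), 466.4 true events
r$kon_truth
#> [1] 0.315
```

Reading the output: from 720 observed colocalization events (53 of them
right-censored at the movie or track end), deconvolution against the null
attributes ~466 to true binding; the censored dwell fit returns
`koff = 0.71 s⁻¹` against a true simulated 0.64 s⁻¹ (mean interaction time
1.41 s vs true 1.56 s), and the density-normalized association constant
0.32 µm² molecule⁻¹ s⁻¹ against the simulation's truth-log 0.315 — both
within the small-sample scatter of 4 cells; the acceptance suite runs the
same experiment at 25 cells per condition.

The same stages are scriptable from the command line via
`inst/cli/sptkin` (`simulate`, `link`, `register`, `colocalize`, `steps`,
`bret-delta`, `run`).

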