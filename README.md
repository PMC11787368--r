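# TrackKinetics

Chromatin-binding kinetics of nuclear proteins from live-cell
single-molecule tracking.

Transcription factors bind chromatin both unspecifically (sub-second
encounters with DNA, cofactors or nuclear structures) and specifically
(minutes-long engagement of target sequences). Time-lapse single-molecule
imaging measures how long individual molecules stay bound, but the raw
survival times mix dissociation with photobleaching and span four orders
of magnitude. TrackKinetics implements the full inference chain from
per-cell track tables to:

- **dissociation-rate spectra** — survival-time histograms recorded under
  several frame-cycle times (0.1–6.4 s at fixed 50 ms exposure) are
  inverted globally by a regularized inverse Laplace transformation. The
  observed survival of a binding class with dissociation rate *k* under
  cycle time Δt is S(t) = exp(−k·t − a·t/Δt), where *a* is the per-frame
  photobleaching number shared by all conditions; varying Δt separates
  *a* (per frame) from *k* (per second). Both event amplitudes A^e (how
  often a class binds) and state amplitudes A^s ∝ A^e/k (snapshot
  occupancy) are reported, with 80 %-resampling uncertainties.
- **binding classes** — the spectrum is partitioned at 0.01 s⁻¹; the
  state-weighted mean rates give the specific and unspecific residence
  times τ_s = 1/k_d and τ_u = 1/k_off,u.
- **bound fractions** — cumulative jump-distance distributions from fast
  continuous movies (11.7 ms frames, first five jumps per track, gap
  jumps discarded) are fitted with 2- or 3-component Brownian mixtures
  P(r) = 1 − Σᵢ Aᵢ·exp(−r²/(4·Dᵢ·Δt)); the slowest amplitude is the
  overall bound fraction f_b, split into p_u and p_s by the state
  spectrum (p_b,l = f_b·A^s_l).
- **the three-state target-search model** — free ⇌ unspecific ⇌ specific
  with a direct free ⇌ specific edge. From (p_f, p_u, p_s, k_off,u, k_d)
  and one closure (the ratio k_off,s/k_d, conventionally 0.0705), the
  solver returns all microscopic rates via flux balance
  (k*_on,u = p_u/p_f·k_off,u, k*_on,s = p_s/p_f·k_off,s) and detailed
  balance, and the target-site search time
  τ_search = (k*_on,u + k_off,u + k_u−s) /
  (k*_on,s·k_off,u + (k*_on,s + k*_on,u)·k_u−s), validated against exact
  stochastic (Gillespie) first-passage simulation.
- **effective in vivo energy landscapes** — state energies
  ΔG = −ln(p_bound/p_f) in k_B·T at nuclear binding-site concentrations,
  relative transition barriers from the kinetic rates, and variant ΔΔG
  comparisons with Gaussian error propagation.
- **cellular-scale quantities** — nuclear volumes under both ellipsoid
  conventions, copy-number → concentration conversion, and the effective
  in vivo dissociation constant K_d = k_d·[sites]·τ_search.

A synthetic-data generator emulates the entire measurement process
(multi-exponential binding mixtures, per-frame bleaching, track-length
censoring, Brownian mixtures with localization error, three-state
continuous-time Markov chains), so every stage is testable without any
experimental download.

## Worked example

```r
library(TrackKinetics)

cfg <- pipelineConfig(nEvents = 8000, nTracks = 3000,
                      nSpectrumResamples = 0, nDiffusionResamples = 0,
                      seed = 42)
rep <- runPipeline(cfg)
rep
#> VariantReport: WT
#> BindingClasses at threshold 0.01 1/s
#>   specific:   k_d = 0.003779 1/s, tau_s = 264.6 s
#>   unspecific: k_off,u = 1.099 1/s, tau_u = 0.9103 s
#> BindingFractions: p_f = 0.615, p_u = 0.291, p_s = 0.094 (f_b = 0.385)
#>   tau_search = 2549 s
rep@landscape
#> EnergyLandscape (kB*T units)
#>   states:   dG_u = 0.746, dG_s = 1.877
#>   barriers (relative to kA = 1 1/s): f->u 0.652, u->s 7.434, f->s 10.108
```

The report says: molecules stay ~4.4 min at specific sites and ~0.9 s at
unspecific ones; 38.5 % of molecules are chromatin-bound at any instant;
an unbound molecule needs ~42 min to find a specific target site; and
although specific binding is long-lived, its state energy is *positive*
(+1.88 k_B·T above the free state) — binding is kinetically, not
thermodynamically, stable.

Cellular-scale arithmetic with published inputs:

```r
inVivoKd(1 / 247, 2270, 15111,
         ellipsoidVolume(c(12, 8, 3), "semi-axes")) * 1e9
#> [1] 191.157        # nM
concentrationFromCount(193718,
                       ellipsoidVolume(c(8, 8, 5), "diameters")) * 1e6
#> [1] 1.919864       # uM
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "TrackKinetics",
                               load_package = "installed")'
```

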