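# cbctiq

Simulation and image-quality analysis for megavoltage cone-beam CT
(MV-CBCT).

MV-CBCT systems image patients with the linac treatment beam and its
flat-panel portal imager. Their acquisition software exposes three knobs —
the gantry arc (a 200° *short scan* or a full 360°), the number of
projections (100–600, i.e. sampling rates of 0.5–2.0°/projection), and the
total exposure in monitor units (MU, with MU/projection rescaled so the
total is fixed). `cbctiq` rebuilds the standard QA experiment for these
protocols on synthetic data, end to end:

* **phantoms** — voxelized attenuation phantoms with ground-truth labels: a
  220 mm water cylinder (full or half filled, the latter providing a sharp
  water/air edge) and a pelvis-shaped slab with tissue-equivalent inserts
  of relative electron density 1.043, 1.117, 1.513 and 0.459
  (`mu = rED · mu_water`, Compton dominance at MV energies);
* **acquisition** — per-slice fan-beam forward projection (compiled ray
  tracing) and an exposure model with expected counts
  `fluence · MU/projection · exp(−∫μ dl)`, Poisson sampling, optional read
  noise, 16-bit saturation, and detector glare blur;
* **reconstruction** — flat-detector fan-beam filtered backprojection with
  cosine weighting, Parker short-scan redundancy weighting, and an apodized
  ramp filter (Hann at 0.8 Nyquist by default), plus display-thickness
  slice binning (4.8 mm);
* **metrics** — the classic phantom measures, each averaged over six
  consecutive display slabs and reported as mean ± SD:

  uniformity = [1 − |mean(center) − mean(periphery)| / (mean(water) −
  mean(air))] × 100,
  noise = stdev(water) / (mean(water) − mean(air)) × 100,
  CNR = |mean(insert) − mean(background)| / (½ [stdev(insert) +
  stdev(background)]),

  and spatial resolution via the edge chain ESF → LSF (derivative) →
  Gaussian fit → MTF(f) = exp(−2π²σ²f²) → f50;
* **logistics** — MU/projection, sampling rate, acquisition time from a
  gantry speed, and projection-file storage (truncated 10⁶-byte MB);
* **experiment driver** — `run_protocol_sweep()` runs a protocol list over
  the phantom set with hashed, reproducible seeds and renders summary
  tables (CSV) and figures (PNG).

## Worked example

```r
library(cbctiq)

protocols <- mvcbct_protocols()      # the nine study protocols
phantoms  <- sweep_phantoms()        # water, half-filled, pelvis

reports <- run_protocol_sweep(protocols[c("2", "9")], phantoms,
                              n_seeds = 4)
reports[["2"]]
#> iq_report, protocol 2
#>   uniformity: 99.80 +/- 0.15 %
#>   noise:      2.212 +/- 0.030 %
#>   CNR muscle:          1.82 +/- 0.17
#>   CNR trabecular_bone: 4.59 +/- 0.25
#>   CNR dense_bone:      13.06 +/- 1.06
#>   CNR lung_exhale:     12.72 +/- 0.29
#>   f50:        0.1132 +/- 0.0011 mm^-1
reports[["9"]]
#> iq_report, protocol 9
#>   uniformity: 99.68 +/- 0.24 %
#>   noise:      3.022 +/- 0.036 %
#>   CNR muscle:          1.32 +/- 0.20
#>   CNR trabecular_bone: 3.53 +/- 0.22
#>   CNR dense_bone:      11.53 +/- 1.06
#>   CNR lung_exhale:     11.25 +/- 0.45
#>   f50:        0.1137 +/- 0.0016 mm^-1
```

Protocol 2 is a full scan at 13.5 MU, protocol 9 the same geometry at
7.2 MU. Reading the output: uniformity is essentially 100% and identical
for both; noise rises from ~2.2% to ~3.0% — a ratio of 1.37, i.e. exactly
the inverse square root of the dose ratio √(13.5/7.2); every insert's CNR
drops correspondingly; and f50 (the frequency at 50% modulation, here
~0.11 mm⁻¹ ≈ 1.1 lp/cm) does not move, because resolution is set by the
detector and reconstruction filter, not by exposure. Sweeping all nine
protocols shows the study's null result: at fixed 13.5 MU, noise varies by
only ~0.1 percentage points and f50 by ~1% across arcs and sampling rates.

`render_report(reports, "out/")` writes the uniformity/noise,
CNR-vs-MU/projection and f50-vs-sampling-rate tables and figures. A thin
command-line front end is installed at `inst/cli/cbctiq`
(`cbctiq logistics`, `cbctiq sweep`). Protocol tables round-trip through
YAML; projections, phantoms and volumes through float TIFF + YAML
sidecars.

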