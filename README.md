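# radiocell

Single-cell multimodal radiography analysis in R: per-cell **dry mass**
from quantitative phase microscopy, **cell-cycle phase** from FUCCI
two-channel fluorescence, and decay-corrected **[18F]FDG counts per
minute** from radioluminescence microscopy — measured on the same field of
view of radiolabelled cells grown on a scintillator crystal. The package
is aimed at groups building or analysing combined phase/fluorescence/
radioluminescence microscopes who want a tested, scriptable pipeline from
raw-style images to a per-cell table and study-level statistics.

## What it computes

* **Dry mass** — an off-axis interferogram is demodulated (carrier
  sideband selection, 2-D least-squares phase unwrapping, polynomial
  background levelling) and each cell's mass follows from the phase
  integral

  m = λ/(2πα) ∬ Φ(x, y) dx dy,

  with λ = 0.633 µm and α = 0.18 mL/g ≡ 0.18 µm³/pg, so the integral over
  the segmented cell area gives picograms directly.
* **Cycle phase** — channels are normalised by their excitation
  backgrounds, thresholded, summed per cell, and classified by the FUCCI
  logic (red-only → G1, green-only → S/G2/M, both → G1/S, neither → M/G1),
  with explicit, recorded manual overrides.
* **Counts/min** — frames are dark-corrected; scintillation events are
  detected per frame, filtered by track morphology (length > 10 binned
  px → long; low spectral sharpness → diffuse; single saturated pixel →
  sensor hit; all three rejected), accumulated at their centres of
  gravity, integrated over PSF-dilated cell boundaries (σ = 12.5 µm;
  cells merged by the dilation are discarded), divided by live time and
  decay-corrected by 2^(Δt/110 min).
* **Statistics** — median/IQR summaries, exact and approximate two-tailed
  Mann-Whitney tests, one-way ANOVA, and Huber-weighted IRLS regression
  of counts on mass with adjusted R².

A seeded synthetic-data generator (`simulate_fov()`) emulates the full
acquisition — carrier-fringe interferograms, vignetted fluorescence pairs,
Poisson ionisation-track stacks with short/long/diffuse morphology, dark
frames — with ground truth attached, so every stage is testable by
parameter recovery.

## Worked example

```r
library(radiocell)

ds  <- simulate_fov(26, seed = 1,
                    acq = acq_config(n_frames = 1000, exposure_s = 0.2,
                                     n_dark_frames = 100))
res <- process_dataset(ds)
res
#> Pipeline result: 26 cells reported (0 merged-discarded); 4225 accepted events

rep <- run_report(res$cell_table)
rep
#> Report over 26 cells
#>   dry mass median 593.9 pg [439.9-658.5]
#>   counts/min median 64.3 [52.5-83.8]
#>   S/G2/M vs G1 uptake increase 85.8%
#>   counts ~ mass: slope 0.109, adjusted R^2 0.391, p 0.00037695

rep$summaries$counts_by_phase
#>    group  n   median       q1       q3
#> 1     G1  8 44.69668 38.61370 50.91189
#> 2   G1_S  5 71.93785 60.30084 75.64053
#> 3 S_G2_M 13 83.04590 65.06143 89.92231
```

Reading the output: the 26 simulated cells yield a dry-mass median of
594 pg and a counts/min median of 64; cells in S/G2/M take up roughly
twice the tracer of G1 cells (here +86% on the medians), while counts per
cell rise linearly with dry mass (robust slope 0.109 counts/min per pg,
adjusted R² 0.39, p < 0.001). `run_report(..., out_dir = )` additionally
writes a JSON report, the counts-vs-mass scatter with the robust fit and
its 95% confidence band, the mass-normalised scatter, and per-phase box
plots.

A thin command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/radiocell.R", package="radiocell"))')" \
  simulate --n-cells 26 --seed 1 --out dataset
# then: ... process --dataset dataset --out processed
```

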