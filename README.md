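# psitunnel

Multi-ligament knee reconstruction requires several bone tunnels in a single
distal femur, and the limited bone stock makes tunnel convergence a real
surgical risk. 3D-printed patient-specific instrumentation (PSI) — drill
guides whose cannulas encode the planned tunnel direction for one specific
bone — promises better adherence to the planned angulations than freehand
drilling by an experienced surgeon. `psitunnel` is an in-silico replica of
the cadaveric experiment that quantifies this: it plans the four femoral
tunnels (LCL and popliteal tendon laterally, MCL and POL medially), executes
them with simulated surgical error, recovers the result the way the real
study did (rigid ICP overlay of post-operative onto pre-operative bone), and
runs the study's statistics.

For biomechanics and surgical-planning researchers, the package provides:

* **Anatomical frames** — per-knee orthonormal ML/AP/SI triads built from
  bony landmarks, defining the axial and coronal planes in which tunnel
  angles are prescribed.
* **Tunnel planning** — a tunnel at axial angle α (anterior) and coronal
  angle β (proximal) has direction
  `normalize(ml + tan(α)·ap + tan(β)·si)`,
  the unique direction reading α and β off the axial and coronal CT planes
  simultaneously. Protocol defaults: LCL 30°/0° (∅8 × 25 mm),
  PT 30°/30° (∅8 × 25 mm), MCL and POL 30°/30° (∅7 × 25 mm).
* **Synthetic femurs** — watertight triangle meshes polygonized from an
  implicit blend of two condylar ellipsoids and a shaft cylinder, with
  on-surface ligament footprints and seeded per-specimen shape jitter.
* **Execution-error simulation** — per-ligament, per-technique error
  magnitudes drawn from log-normal distributions calibrated in closed form
  to published quartiles: `μ = ln(median)`, `σ = ln(Q3/Q1) / (2 z₀.₇₅)`.
* **Registration** — iterative closest point (vertex-to-surface
  correspondences + Kabsch/SVD rigid fits) to overlay the displaced, noised
  "post-operative" bone back onto the plan.
* **Accuracy endpoints** — angular deviation (the 3D angle between planned
  and achieved directions, `acos(d̂₁·d̂₂)`) and entry-point distance (mm,
  after overlay); tunnel-convergence checks via exact capped-cylinder
  (segment–segment) distance.
* **Statistics** — median [Q1–Q3] summaries, exact (fully enumerated)
  Mann–Whitney U tests for the study's small samples, and Levene variance
  tests.

## Worked example

```r
library(psitunnel)

# a full two-arm study: 2 knees per group, noiseless registration
rec <- simulate_study(n_knees_per_group = 2, seed = 11, noise_sd = 0,
                      resolution_mm = 4)
rec[1:4, c("knee_id", "group", "ligament",
           "angular_deviation_deg", "injected_angular_deg")]
#>   knee_id group ligament angular_deviation_deg injected_angular_deg
#> 1  psi_01   psi      LCL              5.249659            5.2454095
#> 2  psi_01   psi       PT              0.980009            0.9847814
#> 3  psi_01   psi      MCL             12.318656           12.3243841
#> 4  psi_01   psi      POL              3.119152            3.1162386
```

The measured deviations equal the injected ground truth to within
thousandths of a degree: with zero surface noise the ICP overlay is exactly
invertible, which is the pipeline's core correctness check. With the default
surface noise (`noise_sd = 0.79` mm) the mean ICP residual is ≈ 0.63 mm,
the overlay quality reported for the real CT scan pairs.

```r
res <- run_study(study_config(n_knees_per_group = 2, seed = 5,
                              resolution_mm = 4.5), outdir = tempfile())
res$comparisons[res$comparisons$stratum == "pooled", ]
#> outcome  stratum control med [IQR]  PSI med [IQR]      p(MW)  p(Lev)
#> angular  pooled   16.4 [14.0-21.9]   9.4 [5.9-13.6]    0.0499   0.552
#> entry    pooled    6.3 [5.2-9.8]     3.7 [2.9-4.4]     0.0207   0.00938
sum(res$collisions$collides)
#> [1] 0
```

Each run directory contains the per-tunnel records, the pooled and
per-ligament comparison table, pairwise tunnel-convergence reports (zero
collisions under the protocol angles, as observed in the study), the
registration log and a config echo.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch with the installed package, the distribution-level
summaries of the calibrated error models: the mean pooled median angular
deviation and entry-point distance of each study arm (1,000 simulated
studies of 5 knees × 4 ligaments per arm), and the 95th-percentile pooled
angular-deviation Mann–Whitney p-value over 200 simulated studies, writing
them as JSON.
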