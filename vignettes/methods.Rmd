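---
title: "Methods: in-silico evaluation of femoral tunnel drilling accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-silico evaluation of femoral tunnel drilling accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psitunnel)
```

## The problem being modelled

In multi-ligament knee reconstruction, four femoral tunnels are drilled at
the anatomical attachments of the LCL and popliteal tendon (lateral side)
and the MCL and POL (medial side). Because distal-femur bone stock is
limited, the prescribed tunnel angulations — e.g. LCL 30° anterior in the
axial plane and 0° in the coronal plane, PT/MCL/POL 30° anterior and 30°
proximal — exist to keep tunnels from converging. A cadaveric experiment
compared how accurately an experienced surgeon (freehand) versus a
3D-printed patient-specific guide (PSI) executes such a plan, measuring two
endpoints per tunnel after overlaying post-operative on pre-operative CT
reconstructions: the angular deviation between planned and achieved
trajectories and the distance between their entry points. `psitunnel`
rebuilds that entire computation — planning, execution error, overlay,
measurement, statistics — on synthetic bone, so every stage is testable
without the (unpublished) cadaver data.

## Anatomical frames

Tunnel angles are prescribed in a per-knee coordinate system defining the
axial and coronal planes. The original study delegates its construction to
cited methodology it does not reproduce, so this package fixes a
transparent surrogate behind the `landmark_set` interface:

* **SI** = normalized femoral shaft direction (proximal − distal),
* **ML** = inter-epicondylar direction orthogonalized against SI
  (Gram–Schmidt), sign-flipped to point *across the bone from the entry
  side* (medially for lateral-side tunnels and vice versa),
* **AP** = completes the triad, signed so the most anterior trochlear
  landmark is anterior,
* origin = the entry-side epicondyle.

Using per-side frames lets one convention ("anterior" and "proximal"
positive) serve both sides. With an anterior-positive AP axis on both
sides, the lateral-side triad of a right knee is left-handed and the
medial-side triad right-handed; orthonormality and |det| = 1 are enforced,
and all angle computations are handedness-agnostic. Left knees are handled
by sagittal mirroring (`mirror_landmarks()`); planned angles are invariant
under mirroring and under any rigid motion of the knee (both properties are
tested). Degenerate anatomy (epicondylar axis parallel to the shaft within
1e-6) is an explicit error. Whether the original study referenced angles to
the transepicondylar axis or another ML surrogate is unknowable from the
text; the reference axis is therefore whatever `landmark_set` supplies, and
alternative definitions can be swapped in through it.

## Angle composition: the projection convention

A tunnel at axial angle $\alpha$ and coronal angle $\beta$ has direction

$$\hat d \;=\; \mathrm{normalize}\!\left(\,\mathbf{ml} + \tan\alpha\,
\mathbf{ap} + \tan\beta\,\mathbf{si}\,\right),$$

the unique direction whose projections onto the axial and coronal planes
make angles $\alpha$ and $\beta$ with ML *simultaneously* — i.e. the angles
a reader would measure on axial and coronal CT slices. The alternative
sequential convention (rotate by $\alpha$ about SI, then elevate by
$\beta$) is implemented behind `convention = "sequential"`; the two differ
by 3.4° at 30°/30° (measured, see the planning tests), so the choice is
documented and configurable, with projection as default. The inverse map
(`angles_from_direction()`) is closed-form and exact to 1e-9 over
(−60°, 60°)²; directions with non-positive ML component (not into the
bone) are rejected.

## Synthetic femur

`generate_femur()` polygonizes an implicit field — the smooth (log-sum-exp,
blend 4 mm) union of two condylar ellipsoids and a capped shaft cylinder —
with marching tetrahedra (Rcpp; six tetrahedra per grid cube sharing the
main diagonal, edge-keyed vertex dedup). This guarantees a closed,
manifold surface whenever the solid stays inside the grid, which the
generator checks and reports. Defaults give an epicondylar width of ~82 mm
(adult range 70–90 mm is asserted in tests); per-specimen variability is a
seeded ±3% jitter of condyle/shaft dimensions applied *before* the global
`size_scale`, so rescaling a given specimen is exact similarity.

Footprints are placed by projecting literature-plausible seed points onto
the surface: LCL just postero-proximal to the lateral epicondyle, PT ~19 mm
antero-distal to it, MCL at the medial epicondyle, POL postero-proximal to
the MCL. Under the protocol angles these yield a minimum inter-tunnel wall
of ~2 mm (LCL–PT pair) — tight, as it is clinically, but collision-free on
every tested specimen, mirroring the study's observation of no tunnel
confluence in either arm.

What the generator does *not* emulate: real condylar surface detail
(trochlear groove geometry is only coarsely present), cortical/trabecular
interior, CT intensities, and segmentation artifacts. A green test
establishes the pipeline's geometric correctness, not anatomical realism
of the bone shape; anatomy enters the study's computation only through
footprint positions, surface curvature near them, and overall scale.

## Execution-error model

The study reports per-ligament accuracy as median [Q1–Q3]. A log-normal is
the minimal strictly-positive two-parameter family exactly identified by a
median and quartile ratio:

$$\mu = \ln(\mathrm{median}), \qquad
\sigma = \frac{\ln(Q3/Q1)}{2\,z_{0.75}}, \quad z_{0.75} = 0.67449.$$

A two-parameter family cannot match all three printed numbers unless the
printed quartiles are log-symmetric about the median (most rows nearly
are); the fitted quartiles are $\mathrm{median}\cdot(Q3/Q1)^{\pm 1/2}$,
which the Monte-Carlo calibration tests verify to 0.5% at $10^6$ draws.
The family is pluggable; the 16 shipped quartile specifications (2
techniques × 4 ligaments × 2 outcomes) live in
`inst/extdata/error_model_default.yaml`. Where the abstract and the pooled
table disagree on one control quartile (17.6 vs 17.7), the table is
followed.

`perturb_tunnel()` applies a drawn angular magnitude as a tilt about a
uniformly random azimuth (cone model) — the achieved deviation equals the
draw exactly — and a drawn entry displacement along a uniformly random
surface-tangent direction. The displaced entry is re-projected to the bone
surface with the tangent step length solved by secant iteration so the
final on-surface displacement equals the draw exactly; naive
project-after-step would shrink a 5 mm displacement by ~0.6 mm on a
20 mm-radius condyle and bias the calibrated quartiles. Angular and entry
errors are drawn independently, and independently across the four tunnels
of a knee: the study gives no correlation structure, so independence is the
assumption (a surgeon-skill or guide-seating common factor would induce
positive correlation this model does not represent).

## Post-operative manufacture and registration

`make_postop()` displaces the bone by a rigid transform (default bounds
15°, 8 mm — moderate repositioning between scans) and adds isotropic
Gaussian vertex noise. Isotropic rather than along-normal noise was chosen
for its closed-form checks (mean vertex displacement $\sigma\sqrt{8/\pi}$,
mean point-to-surface residual $\approx \sigma\sqrt{2/\pi}$); at these
magnitudes registration behaves equivalently. The default
`noise_sd = 0.79` mm is calibrated so the mean ICP residual is ≈ 0.63 mm,
the overlay quality the real study reports for its scan pairs; this is a
stated-world constant, fixed before any acceptance measurement.

`icp()` alternates vertex-to-surface nearest-point correspondence (exact
point-to-triangle, warm-start pruned, ≤ 5000 subsampled source vertices)
with Kabsch/SVD rigid fits (reflection-corrected). Initialization is
principal-axes + centroid alignment with the four proper-rotation sign
candidates scored on a 200-point probe. Defaults: `tol_mm = 1e-4` on the
mean-distance improvement, `max_iter = 100`; non-convergence warns, never
silently. The mean closest-point distance is non-increasing across
iterations (asserted in tests). The residual reported is the *mean*
closest-point distance — the study does not state whether its 0.63 mm is
mean or RMS; mean is documented here. On noiseless rigid copies the
recovered transform is exact to well under 0.1°/0.1 mm, and the full
pipeline then returns measured errors equal to the injected ones within
0.05°/0.05 mm — the package's core correctness surface.

## Accuracy endpoints

Angular deviation is the plain 3D angle $\arccos(\hat d_1\cdot\hat d_2)$.
The study describes measuring "in the plane where the deviation is
greatest": for two directions that plane is their span, and projection onto
any other plane can only shrink the angle (a projection is a contraction,
so the projected dot product can only grow relative to the vector norms);
hence the 3D angle *is* the maximal-plane angle. Directions are compared
signed — a reversed drill is 180°, not 0°. Entry distance is Euclidean,
after mapping the achieved tunnel through the registration transform.

## Convergence checking

Tunnels are capped cylinders (the protocol fixes 25 mm depth, and depth
matters for convergence), so the kernel is exact clamped segment–segment
distance; wall thickness is that distance minus the radii, and the default
collision threshold is 0 (touching). Opposite-side pairs are checked too.
The kernel is verified against a brute-force grid oracle to 0.01 mm on
1,000 random pairs, and simulated freehand error produces collisions at
least as often as PSI error under identical plans — the dispersion
ordering the study's results imply.

## Statistics

* `median_iqr()`: linear-interpolation quantiles (type 7) by default,
  Tukey hinges as the alternative; the convention is recorded in output.
* `mannwhitney_exact()`: U from rank sums (midranks under ties). With no
  ties and $\binom{n_a+n_b}{n_a} \le 4\times10^5$ the two-sided p is
  computed by full enumeration of labelings — for the study's 5 vs 5 this
  makes the printed values analytic facts: the minimum attainable p is
  $2/252 = 0.0079$ (printed 0.008, every per-ligament angular row), and
  $U = 6, 7$ give 0.222 and 0.310 (the entry-distance rows). Larger
  problems (the pooled 20 vs 20) use the normal approximation with tie and
  continuity corrections; the exact and approximate paths agree within
  0.02 at 10 vs 10. Two-sided p is $2\min(P_{\le}, P_{\ge})$ capped at 1.
* `levene_test()`: classic Levene (center = mean) by default because the
  study names the Levene test; `center = "median"` (Brown–Forsythe) is a
  switch. Zero within-group spread of the absolute deviations is an
  explicit failure, caught and reported as NA by `compare_study()`.

`compare_study()` emits the pooled (n = 20 vs 20) and per-ligament
(n = 5 vs 5) rows for both outcomes; strata with fewer than two
observations per group are omitted with a warning.

## Reproducibility

A master seed drives everything; `simulate_study()` spawns one substream
seed per knee so any knee is reproducible in isolation. Identical config +
seed reproduces records bit-for-bit (tested). Simulation sizes in the test
suite are scaled to desk hardware: coarse polygonization (4.5 mm) and
1–2 knees per group for pipeline tests; the distribution-level acceptance
computations use the full 1,000/200 replicates, which run in seconds.

## Known limitations

* The anatomical frame is a surrogate, not the study's exact (uncited
  in detail) construction; absolute angle values transfer only insofar as
  the ML reference agrees.
* Execution errors are independent across tunnels and between the angular
  and entry components; real errors likely correlate within a surgeon and
  a knee.
* The synthetic femur's realism is limited to scale, epicondylar
  geometry and footprint placement; collision *rates* under error depend
  on footprint separations that are configurable, literature-plausible
  defaults rather than measured anatomy.
* PSI guide geometry is descriptive only (`psi_guide_params()`); guide
  seating error is not modelled as a separate mechanism — it is part of
  the calibrated PSI error distributions.
* Tibial, cruciate and anterolateral tunnels — the other partners in
  clinically relevant collisions — are out of scope, as they were for the
  original experiment.
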