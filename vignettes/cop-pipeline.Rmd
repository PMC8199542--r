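---
title: "From resistive mat voltages to center-of-pressure agreement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From resistive mat voltages to center-of-pressure agreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copmat)
```

## The measurement problem

Postural stability is routinely quantified by the trajectory of the center of
pressure (CoP) — the point of application of the resultant vertical ground
reaction force — during quiet standing. The accepted instrument is a rigid
force platform; a far cheaper alternative is a pressure-sensitive mat (PSM):
a grid of piezoresistive cells at the crossings of row and column electrode
lines. `copmat` implements the full processing chain that turns raw scanned
voltages from such a mat into CoP sway statistics, and the evaluation design
that measures how well the mat agrees with a force platform across
processing choices.

Three instrument non-idealities shape the chain:

1. **Readout circuit.** A scan selects one row (tied to the supply through an
   offset resistor $R_0$) and one column (grounded), and digitizes the
   divider voltage. The multiplexers contribute a series resistance
   $R_\mathrm{mux}$ and the ADC loads the divider with its input impedance
   $R_\mathrm{ADC}$. The cell resistance follows exactly from
   $$V_x = V_{cc}\,\frac{Z}{R_0 + Z},\qquad
     Z = R_\mathrm{ADC} \parallel (R_\mathrm{mux} + R_x),$$
   inverted in closed form by `resistance_from_voltage()`. Defaults are the
   calibrated prototype values $R_0 = 2.2\,\mathrm{k\Omega}$,
   $R_\mathrm{mux} = 145\,\Omega$, $R_\mathrm{ADC} = 123\,\mathrm{k\Omega}$.
   $V_{cc}$ is taken as 3.3 V; only $V_x/V_{cc}$ enters the inversion, so
   this choice is inconsequential. $R_\mathrm{mux}$ is modeled as one lumped
   value (row plus column path), matching how a single constant is
   calibrated in practice.

2. **Crosstalk (the "ghost effect").** The current between the selected row
   and column does not only cross the addressed cell: it detours through
   every series path over other cells sharing those lines. A measurement is
   therefore the *equivalent* conductance of the whole resistor network —
   press three corners of a rectangle and the fourth appears pressed.
   `forward_equivalent_all()` computes this forward map by nodal analysis on
   the bipartite graph of row and column lines (unselected lines float, as
   the multiplexers disconnect them), and `remove_crosstalk()` inverts it to
   recover per-cell conductance.

3. **Sensor time response.** The piezoresistive material follows pressure
   with a first-order lag, calibrated at $\tau = 0.25$ s from a single-cell
   step experiment. Sampled at $T_s$, the sensor is the exponential smoother
   $x_k = a x_{k-1} + (1-a) u_k$, $a = e^{-T_s/\tau}$, whose *exact*
   discrete inverse is the two-coefficient FIR filter
   $$y_k = \frac{1}{1-a}\,x_k + \frac{a}{a-1}\,x_{k-1},$$
   implemented by `deconvolve_first_order()`. Because the lag acts as a
   low-pass filter, an uncorrected mat systematically *under-reports* sway
   amplitude — the reason mat-derived sway values run smaller than platform
   values, and the motivation for the `first_order` processing variant.

From the corrected frames, the CoP is the pressure-weighted centroid of the
cell centers (`compute_cop()`), and a trial is summarized by the population
(denominator-$N$) standard deviations of its medial–lateral and
anterior–posterior components, $\sigma_{ML}$ and $\sigma_{AP}$
(`sway_std()`).

## Inverting the crosstalk

Writing row and column lines as graph nodes and cells as conductances, the
measured equivalent conductance between row $a$ and column $b$ is
$1/R_\mathrm{eff}(a,b)$ with
$R_\mathrm{eff} = (e_a - e_b)^\top L^{+} (e_a - e_b)$, $L$ the weighted graph
Laplacian. One reduced-Laplacian inverse per connected component yields the
whole scan; isolated (zero-conductance) lines carry no current and are
eliminated rather than failing. Conductances below a floor (default
$10^{-9}$ S) are treated as exactly zero to keep floating nodes
well-conditioned.

The inversion is a projected Newton iteration. The Jacobian is analytic and
free once the Laplacian inverse is known: the sensitivity of a measurement
to cell $(p,q)$ is the squared per-unit voltage drop across that cell,
$\partial G_\mathrm{eff}/\partial g_{pq} = ((u_p - u_q)/R_\mathrm{eff})^2$.
Newton converges quadratically (typically 4–6 sweeps to $10^{-9}$ S) and —
unlike naive fixed-point "crosstalk subtraction", which is kept as
`method = "fixed_point"` — it remains stable when the crosstalk term exceeds
the direct-cell conductance. That regime is the rule, not the exception, for
a mat fully loaded by a foot: on simulated single-leg frames the ghost paths
contribute more equivalent conductance than the addressed cell itself, and
the fixed point oscillates without converging. Numerical policies:

* negative intermediate values are clamped to zero (conductance is
  physical);
* line-search progress is judged on the *sum of squared* residuals — on
  distorted (quantized) measurements the max residual is pinned by a few
  cells clamped at zero and would mask genuine progress elsewhere;
* the iteration stops at tolerance (max elementwise residual, default
  $10^{-9}$ S), at `max_iter` (default 100), or when three consecutive
  sweeps improve the fit by less than 0.1% — distorted measurements need
  not lie in the image of the forward map, so a residual floor is expected
  and the best iterate is returned, flagged `converged = FALSE`, never an
  error;
* each recording frame is inverted from scratch: warm-starting from the
  previous frame can pin the projected iteration to a stale active set of
  clamped cells and silently freeze the recovered blob.

## The synthetic study

Real validation data for this instrument — cohorts of humans standing
single-legged on a mat stacked on a force platform — cannot ship with a
package, so `copmat` carries a physics-based simulator whose every
distortion is the one the pipeline claims to remove. The defaults reproduce
the study conditions end to end: 42 subjects, two 60 s single-legged trials
(right leg, left leg) at 10 Hz on a 16×16 mat covering 32×32 cm (2 cm
pitch).

* **Sway**: each CoP axis is an AR(1) process rescaled so its realized
  population standard deviation equals the target *exactly* — ground truth
  is known by construction. The smoothness coefficient 0.95 at 10 Hz gives a
  ~2 s correlation time, typical of single-leg stance. Per-subject targets
  are log-normal, medians 0.7 cm (ML) and 1.1 cm (AP) — the neighbourhood of
  force-platform values for healthy adults in single-leg stance — with
  `sigma_sdlog = 0.3` matching the ~25–30% between-subject coefficient of
  variation such cohorts show. Setting `sigma_sdlog = 0` creates a perfectly
  homogeneous cohort, for which the agreement ICC must collapse toward zero
  (no true-score variance to explain).
* **Foot**: a single 2-D Gaussian blob (spreads 3 cm ML, 5 cm AP),
  renormalized so each frame's total equals the subject's weight
  (drawn from a normal of mean 74.3, SD 16.34 kg). Only the centroid and its
  temporal statistics matter downstream, so no anatomical silhouette is
  attempted — a deliberate simplification discussed under limitations.
* **Electronics**: conductance = $10^{-6}$ S baseline +
  $2\times10^{-5}$ S/N of cell load (the material's approximately
  proportional regime, scaled so a pressed cell sits near 1–2 kΩ where the
  divider is most sensitive); the sensor lag is applied to the per-cell
  conductance *before* the network scan — the time response lives in the
  material's pressure-to-conductance relation, upstream of the electrical
  readout; then the full-network equivalent map, the divider voltage, and
  12-bit quantization over $[0, V_{cc}]$.
* **Reference channel**: the true CoP plus 0.02 cm iid Gaussian noise
  (small relative to sway, as for a commercial platform), and a random
  integer start offset of up to 2 s planted on the mat channel because the
  instruments start independently — alignment is part of the pipeline, not
  an afterthought.

Trial-level seeds derive from one master seed; regeneration is
byte-identical.

## The evaluation harness

`run_variant_comparison()` reproduces the study design over a cohort. Per
trial, the voltage recording is processed under four variants — `raw`
(circuit inversion only, crosstalk left in), `base` (plus per-frame
crosstalk removal), `first_order` (plus exact lag deconvolution), and
`eight_by_eight` (base processing of every second row and column, emulating
a half-resolution mat; retained cells keep their physical coordinates) —
then aligned to the platform channel by maximizing the summed
cross-correlation of the mean-removed components over integer lags (ties
break toward the smallest magnitude, then negative; a peak correlation
below 0.5 is flagged as suspicious rather than silently accepted).
Alignment is computed once per trial from the base processing and shared
across variants, so variant differences reflect processing, not alignment
jitter. The first $\lceil 5\tau/T_s \rceil = 13$ samples of the overlap are
discarded (smoother start-up transient), and per-trial
$\sigma_{ML}/\sigma_{AP}$ pairs feed two agreement measures per variant,
trial, and metric:

* **ICC for absolute agreement** — two-way model, single measurement
  (ICC(A,1)): systematic offsets between instruments count as disagreement,
  $$\mathrm{ICC} = \frac{MS_R - MS_E}
    {MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)},\quad k = 2.$$
  This is the standard reading of "ICC for agreement" for two fixed
  instruments; a zero-total-variance table is signaled as undefined rather
  than given a number.
* **MAE** — mean absolute error, the platform value taken as truth.

On synthetic cohorts the report also carries recovery error against the
trials' built-in ground truth. Subjects whose trial fails any stage are
dropped pairwise with a logged count; nothing is imputed.

Because every simulated distortion is targeted by exactly one processing
stage, the variant ordering is a strong end-to-end check, and the test
suite asserts it on a seeded default cohort: removing crosstalk improves on
raw; deconvolving the sensor lag improves on base and cancels the downward
sway bias; halving the resolution costs agreement; and a homogeneous cohort
drives every ICC toward zero.

## Choices made where the design was open

* **Newton over fixed point** for the inversion (above): adopted after the
  fixed point proved non-contractive under realistic loads.
* **Lag placement in the simulator**: in the conductance domain, not on the
  digitized voltages — the material, not the ADC, is slow. Placing it after
  the readout would also make the smoothed maps inconsistent with *any*
  conductance grid and charge the inversion with noise the real instrument
  does not produce.
* **Deconvolution after crosstalk removal**, per cell, on the recovered
  grids — matching a reading of the processing chain in which the
  first-order correction derives from the base result. Since both the lag
  and its inverse act per cell and the inversion is near-exact, the order
  is immaterial in the clean limit.
* **Alignment sign convention**: a positive lag means the test channel is
  delayed. With the sensor lag left in (base processing), the recovered lag
  exceeds the planted start offset by the smoother's ~2-sample group delay;
  the shared-alignment policy makes this harmless across variants.
* **Centroid noise floor**: cells below 1% of a frame's maximum are zeroed
  before the centroid — crosstalk residue and quantization leave a nonzero
  background that would otherwise drag the CoP toward the grid center. An
  empty frame after flooring carries the previous CoP forward and is
  flagged; an empty first frame is an error.
* **Indexing**: the R API is 1-based like everything else in R; the frame
  file format stores cells in row-major order and is explicit about it.
* **Initial condition** $x_{-1} = 0$ for both the smoother and its inverse;
  the resulting start-up transient is why the harness discards the first 13
  samples. The discrete step response consequently reads
  $x_k = c(1 - e^{-(k+1)T_s/\tau})$: each sample reflects the response one
  full period after step onset, so `step_response()` timestamps samples at
  $t_k = (k+1)T_s$ and `fit_time_constant()` recovers $\tau$ exactly from
  noiseless data.

## Worked example

A miniature cohort (4 subjects, 20 s trials) exercises every stage in a few
seconds; the full study shape (42 subjects, 60 s) runs in a few minutes and
is what the package's acceptance checks use.

```{r example, eval = FALSE}
cohort <- simulate_cohort(cohort_config(n_subjects = 4, duration = 20,
                                        master_seed = 1))
report <- run_variant_comparison(cohort)
as.data.frame(report)
attr(report, "recovery")   # per-variant MAE against built-in ground truth
```

The same pipeline is scriptable from a shell through the thin CLI wrapper
(`system.file("cli", "copmat", package = "copmat")`): `simulate`, `process
--variant`, `stats`, `agree`, `variants`, and a seeded `demo`.

## What passing tests do and do not show

The simulator shares the real instrument's *structure* — network crosstalk,
divider readout, first-order lag, quantization, independent instrument
starts — but not every property of real data: the foot is one Gaussian blob
rather than a heel-and-metatarsal pressure pattern (which makes the
half-resolution penalty milder here than for real feet, since a wide smooth
blob survives 4 cm sampling almost unharmed); sway is AR(1) rather than
human, so its spectrum is only qualitatively right; the sensing material's
hysteresis, creep, and temperature drift are not modeled; and copper-trace
resistance and parasitic capacitance are ignored. Passing the end-to-end
checks therefore demonstrates that each processing stage removes the
distortion it targets and that the agreement machinery ranks processing
quality correctly — not that any particular ICC value will be attained on
human data. Absolute ICC levels on synthetic cohorts are generally higher
than a real study would produce, because the simulator's error budget is
exactly the part of reality the pipeline can invert.

One subtlety of the homogeneous-cohort check deserves spelling out. The
generator pins each trial's sway targets *exactly* on the full trial window,
but the harness normally scores an aligned, burn-in-trimmed subwindow — and
a subwindow's realized $\sigma$ wanders from realization to realization.
That wander is shared by the mat and the platform (they watch the same
trajectory), so it constitutes genuine true-score variance, and a
near-exact pipeline happily resolves it into a high ICC even though the
*targets* are identical. The check therefore scores the exact window the
targets are pinned on (no start offsets, no sensor lag, `burn_in = 0`),
which isolates the claim actually being tested: with zero true-score
variance the agreement ICC collapses to zero or below. (Negative values are
normal sampling behavior of ICC(A,1) when the error mean square exceeds
the subject mean square, so the meaningful bound is one-sided.)

Problem sizes used by the automated checks: the network oracle compares
against brute-force nodal analysis up to 3×3 over 100 seeded grids;
round-trip inversion runs up to 8×8; the cohort-level checks use the full
default study shape (42 subjects × 2 × 600 samples at 16×16), and the
homogeneous-cohort ICC collapse uses 12 subjects × 30 s.
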