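---
title: "Subspace-constrained reconstruction of 4D ASL angiography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subspace-constrained reconstruction of 4D ASL angiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dynamic angiography with arterial spin labeling (ASL) tags inflowing blood
magnetically at a neck labeling plane and follows the labeled bolus through
the brain vasculature with a long train of low-flip-angle readouts. With 3D
golden-ratio radial sampling the data can in principle be reframed at any
temporal resolution, down to one frame per repetition time (TR ~ 15 ms).
At that resolution each frame contains only a handful of spokes, far below
Nyquist, so conventional practice "bins" adjacent readouts into frames of
~100-200 ms, blurring fast inflow dynamics and biasing fitted hemodynamic
parameters.

`subangio` implements the alternative: a temporal subspace learned from an
angiographic kinetic model turns the ill-posed frame-by-frame problem into
a well-conditioned estimation of a small number of coefficient maps, so the
full series can be reconstructed at one frame per TR. The package contains
the whole chain - signal model, dictionary and SVD subspace, trajectory
generation, a gridding non-uniform FFT, locally-low-rank (LLR) regularized
reconstruction for both the subspace and the binning formulation, voxelwise
parameter fitting, and a single-vessel numerical phantom for end-to-end
validation.

## The kinetic signal model

The control-label difference signal of a voxel at time $t$ after labeling
onset is

$$S(t) = A \, \sin\alpha_i \int_{t-\delta t-\tau}^{t-\delta t}
  D(t_d)\, T(\delta t, t_d)\, R(t_d)\; dt_d$$

with

* $D(t_d) = \frac{s}{\Gamma(1+ps)} e^{-s t_d} (s t_d)^{ps}$ for $t_d>0$ -
  a gamma-variate dispersion kernel with sharpness $s$ (1/s) and
  time-to-peak $p$ (s). It integrates to one and peaks exactly at
  $t_d = p$.
* $T(\delta t, t_d) = e^{-(\delta t + t_d)/T_{1b}}$ - longitudinal
  relaxation of the inverted blood magnetization; $T_{1b}$ defaults to
  1.65 s, a standard arterial-blood value at 3 T (the value is
  configurable; published protocols rarely state it).
* $R(t_d) = \prod_{i=1}^{n} \cos\alpha_i$, $n = \lfloor t_d /
  \mathrm{TR}\rfloor$ capped at the number of pulses - attenuation of the
  labeled magnetization by the excitation train, taking literally the
  simplifying assumption that all labeled blood experiences all pulses
  before $t_d$.
* $A$ - an amplitude proportional to blood volume; $\delta t$ - the
  transit time from labeling plane to voxel.

Flip angles ramp quadratically, $\alpha_i = \alpha_{\min} +
(\alpha_{\max}-\alpha_{\min})\,((i-1)/(N-1))^2$, 3 to 12 degrees over
$N = 144$ readouts at TR 14.7 ms by default (total readout 2116.8 ms after
a 1.8 s labeling period). The monotone-increasing orientation of the
quadratic is a design choice; only the endpoints and "quadratic" are
conventionally specified. Signals are evaluated at excitation times
(echo-time offsets are not modelled). Labeling efficiency only rescales
the signal and is left out.

### Integration

$R(t_d)$ is constant on TR intervals and $D \cdot T$ is a gamma-form
integrand with shape $ps + 1$ and rate $s + 1/T_{1b}$, so the integral is
evaluated exactly (to special-function precision) as a sum of regularized
incomplete-gamma differences over TR intervals - `pgamma()` does the work.
A dense midpoint-quadrature path (`simulate_timecourse(method =
"quadrature")`) is retained as a slow reference, and the test suite checks
the two against each other (and against an independently assembled
quadrature oracle with a graded substitution at the $t_d = 0$ endpoint,
where $t_d^{ps}$ has unbounded derivatives) to $10^{-6}$ relative error
over randomized parameter draws. Batch simulation
(`simulate_timecourses()`) groups dictionary rows by transit time so the
incomplete-gamma evaluations vectorize across the $(s, p)$ grid; the full
64 000-entry dictionary builds in ~15 s.

## The temporal subspace

`parameter_grid()` spans $\delta t \in [0.1, 2]$ s, $s \in [1, 20]$ 1/s,
$p \in [0.001, 0.5]$ s with 40 equispaced samples per axis (64 000
curves); amplitude is excluded since scaling does not change the span.
Rows are not normalized before the SVD - amplitude variation across the
grid intentionally weights the basis; normalization is exposed as an
option. The first $K = 12$ right singular vectors form the default basis
$\Phi$: the number of unknowns then equals that of a 12-frame binned
reconstruction.

With this model and grid the 12-component basis captures 99.947% of the
dictionary energy (a 2.31% Frobenius relative error), computed by
`scripts/acceptance.R` and asserted in the test suite together with the
exact monotone decrease of the error in $K$. Typical curves re-expand with
~1.5% mean NRMSE; the worst corner of the grid (shortest transit times
combined with near-delta dispersion kernels) is poorly represented by any
12-dimensional linear basis, reaching ~33% - a known limitation of linear
subspace compression for this signal family.

## Sampling geometry

Spoke $m$ of the 3D golden-ratio ("kooshball") scheme has azimuth
$2\pi\,\mathrm{frac}(m\phi_1)$ and polar angle
$\arccos\,\mathrm{frac}(m\phi_2)$, where $\phi_1 = 1/\psi \approx 0.6823$,
$\phi_2 = 1/\psi^2 \approx 0.4656$ and $\psi$ is the real root of
$x^3 - x^2 - 1$. The fractional part is applied before the trigonometry
(the defining formulas omit it, but `arccos` requires it). Directions lie
on the upper hemisphere; spokes are full diameters through the k-space
origin, so coverage is effectively full-sphere. Readouts are sampled
uniformly from $-k_{\max}$ to $+k_{\max}$ at 0.5 cycles/voxel with
two-fold readout oversampling by default (samples per spoke is not a
protocol-published quantity; the default is declared, not inferred).

Repeat-first ordering assigns spoke $m(i,j) = (i-1)N_{rep} + j$ to
timepoint $i$, repeat $j$: each one-TR frame owns a contiguous golden-ratio
run, which makes every frame's coverage close to uniform (within ~1.5x the
ideal cap spacing in the antipodal metric) and statistically alike across
frames. Temporal binning groups `bin_size` adjacent timepoints; with 12
bins of 12 TRs the bin-center post-labeling delays run from 88.2 ms in
steps of 176.4 ms (441 ms for bin 3, 793.8 ms for bin 5, and so on).

## Non-uniform FFT

No R NUFFT library exists, so the package ships a standard Kaiser-Bessel
gridding transform (Rcpp kernels + base `fft()`): 2x oversampled grid,
width-6 kernel with the Beatty shape parameter, apodization computed by
numerical quadrature of the kernel's continuous Fourier transform, kernel
values from a dense lookup table. Accuracy against an explicit $O(n^2)$
non-uniform DFT on an $8^3$ grid is ~$6\times10^{-6}$ relative (width 4:
~$8\times10^{-4}$, still far below any regularization scale - desk-scale
reconstructions use width 4 for speed). Forward and adjoint are exact
adjoints by construction and the suite verifies the inner-product identity
to near machine precision.

## Reconstruction

Subspace mode solves

$$\hat\alpha = \arg\min_\alpha \|PF C \Phi \alpha - y\|_2^2 +
  \lambda \sum_i \|W_i(\alpha)\|_*$$

entirely in the subspace domain: because $F$ and $C$ act spatially and
$\Phi$ temporally, the operator order is commuted to $P\Phi FC$ and each
iteration costs one NUFFT per component and coil, with per-sample basis
weights precomputed - the 144-frame series is never materialized. The
binning baseline solves the same functional with per-bin frames as the
unknowns. The data-consistency term is implemented squared (the natural
choice for gradient-based solvers); published objectives often print the
unsquared norm.

* **LLR regularization**: non-overlapping $6^3$ patches, the patch matrix
  (voxels x components) soft-thresholded in its singular values - the
  exact proximal operator of the nuclear-norm sum under the partition.
  The default keeps one fixed partition for all iterations so the
  objective is a single well-defined function; a deterministic cyclic
  shift schedule is available (`shift_schedule = "cycle"`) to suppress
  blocking artifacts at the cost of a per-iteration-varying objective.
* **Solver, lambda > 0**: monotone accelerated proximal gradient
  (MFISTA-style): the candidate is rejected in favour of the previous
  iterate whenever the objective would increase, so the recorded trace is
  non-increasing by construction. The step size is $1/(1.05\,L)$ with $L$
  from eight power iterations on the normal operator. The momentum-point
  forward is formed from cached forwards by linearity, so each iteration
  costs exactly one forward and one adjoint.
* **Solver, lambda = 0**: conjugate gradients on the density-weighted
  normal equations (the CG-SENSE construction). For exactly
  model-consistent data any positive sample weighting leaves the solution
  unchanged, and compensating the radial density improves conditioning by
  orders of magnitude. This path exists for solver validation and
  fully-sampled use; regularized reconstructions use MFISTA.
* **Initialization**: adjoint of density-compensated data, least-squares
  scaled. **Scaling**: data are divided by their sort-based 95th-percentile
  magnitude (`scale_kspace()`), which is what makes a single
  regularization weight transferable across data sets; the defaults are
  5e-4 (subspace) and 1e-1 (binning) under that convention.
* **Multicoil path**: PCA coil compression to (by default) 8 virtual
  channels; sensitivity maps by an adaptive-combine (Walsh) estimate from
  the last two binned frames - density-compensated, radially
  Hamming-windowed gridding of each coil, then the dominant eigenvector of
  the box-smoothed coil covariance per voxel, phase-referenced to one
  fixed coil and unit root-sum-of-squares. The synthetic path simulates
  difference data directly; tag/control pairing and subtraction are an
  acquisition-side concern.

### A well-posedness caveat the phantom exposes

A one-voxel-wide vessel has an essentially flat spectrum in the plane
perpendicular to its axis, but radial spokes sample only the inscribed
k-space ball - about 21% of that planar spectral energy lies in the cube
corners, which the trajectory observes only through weak
interpolation-kernel couplings. Two consequences matter for validation:
least-squares recovery of the raw phantom is dominated by semi-convergence
(the tiny subspace-projection residual of the truth is amplified through
near-null modes), and no linear reconstruction can match the unfiltered
single-voxel truth to a few percent. The solver-recovery test therefore
simulates data from the Nyquist-ball-limited, basis-projected phantom - a
representable ground truth - and demands 2% vessel NRMSE, which the CG
path reaches in well under 100 iterations. Comparisons *between* methods
(subspace vs. binning) always use the same raw-phantom data for both arms,
so this caveat affects neither the orderings nor the parameter-error
comparisons.

## Parameter fitting

Voxelwise estimates of $(\delta t, s, p, A)$ come from dictionary matching
(cosine similarity against unit-amplitude entries, amplitude by
least-squares scaling) followed by bounded Levenberg-Marquardt refinement
(`minpack.lm`) on the magnitude timecourse. Bounds
($\delta t \in [0.05, 2.2]$ s, $s \in [0.5, 25]$ 1/s, $p \in [0.001,
0.6]$ s, $A \ge 0$) slightly exceed the dictionary ranges to avoid
boundary pile-up. A variational-Bayes engine used in the original workflow
is deliberately out of scope - the point estimates are what the
evaluations consume; posterior uncertainty is not reproduced. Binned
frames are fit against bin-averaged model curves (the forward model of
binning), which is how the characteristic step-wise overestimation of
transit time by binned reconstructions emerges. Noiseless self-consistency
(fit of a model-generated curve recovers the generator to 1%) holds across
randomized draws with the full 144-point train; with much shorter trains
many parameter combinations are simply unidentifiable, which is a property
of the experiment, not the optimizer.

The in-vivo-style fit mask (peak signal above a fraction of the
95th-percentile peak) assumes signal nearly everywhere; for the sparse
phantom the evaluation fits the vessel voxels explicitly (`mask =`),
mirroring how reconstructions of a simulated line are assessed along the
line.

## Evaluation and problem sizes

`psf_profile()` profiles the mid-vessel perpendicular plane at the frame
of peak vessel signal (normalized peak, FWHM by linear interpolation,
sidelobe = largest magnitude beyond 2 voxels); `timecourse_nrmse()`
reports per-voxel NRMSE against the truth RMS; `lambda_sweep()` runs
reconstruction + fitting per candidate weight on identical data.

Test and acceptance problem sizes were chosen once as the smallest scales
at which each property is meaningful: operator identities and solver
recovery on $8^3$ grids with 16-readout trains and 64 repeats (heavily
oversampled per frame); the subspace-vs-binning and weight-sweep
comparisons on a $24^3$ phantom with the full 144-readout train, 16
repeats, 48 samples per spoke, width-4 gridding and 40 MFISTA iterations;
the dictionary and its subspace always at the full 40^3 x 144 size. The
in-protocol geometry (1.13 mm, 200 x 200 x 125 mm FOV, ~176^3 matrix) is
reachable through the same API, just slower.

## What the phantom does and does not emulate

The generator reproduces the study conditions for the numerical
validation: a one-voxel line through the volume center with linear ramps
$\delta t: 0.25\to1.8$ s, $p: 0.1\to0.5$ s, $s: 1\to10$ 1/s, $A = 1$,
simulated with the same kinetic model and sampled by the same trajectory,
noiseless by default (noise is available, seeded and recorded). It does
not emulate vascular trees, partial-volume effects, motion, off-resonance,
trajectory infidelity, or background tissue signal - so green tests
demonstrate correctness of the machinery and the *direction* of the
subspace-vs-binning differences, not in vivo image quality.

## Known limitations

* The linear subspace represents extreme short-transit/sharp-dispersion
  signals poorly (see above); nonlinear compressions are out of scope.
* NIfTI output stores magnitudes (NIfTI-1 has no double-complex type);
  complex arrays round-trip exactly through the run-bundle binary format
  instead.
* The cone trajectory of the original acquisition family, Siemens raw-data
  parsing, and perfusion-signal reconstruction are out of scope; the
  radial protocol is the one modelled.
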