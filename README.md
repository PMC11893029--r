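# subangio

Ultra-high temporal resolution 4D angiography from arterial spin labeling
(ASL) data, reconstructed one frame per repetition time (TR ~ 15 ms)
through a model-derived temporal subspace.

ASL dynamic angiography labels inflowing blood at a neck plane and images
it with a long train of low-flip-angle readouts along 3D golden-ratio
radial spokes. At one-TR temporal resolution each frame holds only a few
spokes, so conventional reconstructions "bin" ~100-200 ms of readouts per
frame, blurring inflow dynamics and biasing fitted hemodynamics. This
package is for MR physicists and ASL methodologists who want the
subspace alternative as an inspectable, fully testable R implementation -
from the kinetic signal model to reconstructed 4D series and parameter
maps, with a synthetic single-vessel phantom standing in for scanner data.

## The method in brief

A voxel's control-label difference signal at time $t$ after labeling onset
is modelled as

$$S(t) = A\,\sin\alpha_i \int_{t-\delta t-\tau}^{t-\delta t}
  D(t_d)\,T(\delta t, t_d)\,R(t_d)\,dt_d,$$

where $D(t_d) = \frac{s}{\Gamma(1+ps)}e^{-st_d}(st_d)^{ps}$ is a
gamma-variate dispersion kernel (sharpness $s$, time-to-peak $p$),
$T = e^{-(\delta t + t_d)/T_{1b}}$ is blood $T_1$ decay, and
$R(t_d) = \prod_1^{\lfloor t_d/\mathrm{TR}\rfloor}\cos\alpha_i$ is RF
attenuation by the variable-flip-angle readout train. Simulating this
model over a 40x40x40 grid of $(\delta t, s, p)$ gives 64 000 curves whose
SVD yields an orthonormal temporal basis $\Phi$; keeping $K = 12$
components, the series $x \approx \Phi\alpha$ and reconstruction solves

$$\hat\alpha = \arg\min_\alpha\; \|P F C \Phi\alpha - y\|_2^2 +
  \lambda\sum_i \|W_i(\alpha)\|_*$$

by monotone accelerated proximal gradient descent with locally-low-rank
(LLR) patch regularization, entirely in the subspace domain (operator
order commuted to $P\Phi F C$, so no full time series is ever formed).
The temporal-binning baseline solves the same functional with binned
frames as unknowns. Voxelwise $(\delta t, s, p, A)$ are then estimated by
dictionary matching plus bounded Levenberg-Marquardt refinement.

See the methods vignette (`vignettes/subspace-angiography.Rmd`) for the
model conventions, solver details, numerical choices and limitations.

## Worked example

```r
library(subangio)

seq <- seq_params()   # TR 14.7 ms, 1.8 s labeling, 144 readouts, 3-12 deg
golden_means()
#>      phi1      phi2
#> 0.6823278 0.4655712

dict <- build_dictionary(parameter_grid(), seq)
sub  <- extract_subspace(dict, k = 12)
sub
#> temporal_subspace: 144 timepoints, 12 components
#>   energy captured by 12 components: 0.999468
relative_error(dict, sub)
#> [1] 2.306854
```

The two golden means are the azimuthal/polar angle increments of the 3D
radial trajectory; the 12-component basis captures 99.947% of the
dictionary's signal energy (a 2.31% Frobenius relative error).

```r
phantom  <- vessel_phantom(16)   # one-voxel vessel, linear kinetic ramps
sampling <- build_sampling(seq$n_readouts, n_repeats = 16, matrix_size = 16,
                           samples_per_spoke = 32)
series <- phantom_series(phantom, seq)
kdata  <- scale_kspace(simulate_kspace(series, sampling))
rec <- reconstruct_subspace(kdata, sampling, sub,
                            config = recon_config(lambda = 5e-4,
                                                  n_iterations = 40,
                                                  nufft_width = 4))
rec
#> recon_result (subspace): 40 iterations, final objective 29.678

fit_dict <- build_dictionary(parameter_grid(n_per_axis = 10), seq)
maps <- fit_volume(rec, seq, fit_dict, mask = phantom$voxels)
tab  <- vessel_fit_table(maps, phantom)
round(tab[c(4, 8, 12), c("position", "delta_t", "true_delta_t",
                         "sharpness", "true_sharpness")], 3)
#>    position delta_t true_delta_t sharpness true_sharpness
#> 4         4   0.549        0.560     2.988            2.8
#> 8         8   0.903        0.973     5.540            5.2
#> 12       12   1.205        1.387     9.787            7.6
```

Transit times recovered from the one-TR reconstruction track the ground
truth ramp along the vessel at this deliberately tiny scale (16^3 grid, 16
repeats); the test suite runs the same comparison at 24^3 against the
temporal-binning baseline, where the subspace reconstruction gives both
lower timecourse error and markedly smaller parameter biases.

A thin command-line front end wraps the same functions
(`inst/cli/subangio.R`, verbs `traj`, `dict`, `simulate`, `recon`, `fit`,
`eval`, each with `--config` and `-o`, writing a JSON sidecar of the
resolved configuration next to its outputs).

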