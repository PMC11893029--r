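# Fixtures shared across test files, built once per test run and cached.
.fx <- new.env(parent = emptyenv())
fixture <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

# A shortened readout train: full physics, 16 excitations, fast to simulate.
short_seq <- function() seq_params(n_readouts = 16L)

# Small-scale acquisition/reconstruction scene on an 8^3 grid with heavy
# per-frame oversampling (64 repeats), used by operator and solver tests.
small_scene <- function() {
  fixture("small_scene", function() {
    sq <- short_seq()
    n <- 8L
    samp <- build_sampling(sq$n_readouts, 64L, n, 16L)
    ph <- vessel_phantom(n, axis = 1L)
    ser <- phantom_series(ph, sq)
    dict <- build_dictionary(parameter_grid(n_per_axis = 8L), sq)
    sub <- extract_subspace(dict, 6L)
    plan <- nufft_plan(n, samp$coords)
    list(seq = sq, n = n, sampling = samp, phantom = ph, series = ser,
         dict = dict, subspace = sub, plan = plan)
  })
}

# The full-scale signal dictionary (40^3 entries, 144 timepoints) and its
# 12-component subspace; shared between subspace tests and acceptance.
full_dictionary <- function() {
  fixture("full_dictionary", function() {
    sq <- seq_params()
    dict <- build_dictionary(parameter_grid(), sq)
    sub <- extract_subspace(dict, 12L)
    list(seq = sq, dict = dict, subspace = sub)
  })
}

# The standard phantom run: single-vessel phantom at desk scale (24^3,
# 16 repeats, full 144-timepoint train), reconstructed with the subspace
# method (lambda 5e-4) and the temporal-binning baseline (lambda 1e-1)
# from identical k-space data.
standard_run <- function() {
  fixture("standard_run", function() {
    fd <- full_dictionary()
    sq <- fd$seq
    n <- 24L
    samp <- build_sampling(sq$n_readouts, 16L, n, 2L * n)
    ph <- vessel_phantom(n, axis = 1L)
    ser <- phantom_series(ph, sq)
    plan <- nufft_plan(n, samp$coords, width = 4L)
    kd <- scale_kspace(simulate_kspace(ser, samp, plan = plan))
    cfg_sub <- recon_config(lambda = 5e-4, n_iterations = 40L,
                            nufft_width = 4L)
    cfg_bin <- recon_config(lambda = 1e-1, n_iterations = 40L,
                            bin_size = 12L, nufft_width = 4L)
    rec_sub <- reconstruct_subspace(kd, samp, fd$subspace, config = cfg_sub,
                                    plan = plan)
    rec_bin <- reconstruct_binned(kd, samp, config = cfg_bin, plan = plan)
    fit_dict <- build_dictionary(parameter_grid(n_per_axis = 12L), sq)
    vessel_mask <- ph$voxels
    maps_sub <- fit_volume(rec_sub, sq, fit_dict, mask = vessel_mask)
    maps_bin <- fit_volume(rec_bin, sq, fit_dict, mask = vessel_mask,
                           bin_size = 12L)
    list(seq = sq, n = n, sampling = samp, phantom = ph, series = ser,
         kdata = kd, plan = plan, subspace = fd$subspace,
         fit_dict = fit_dict, rec_sub = rec_sub, rec_bin = rec_bin,
         maps_sub = maps_sub, maps_bin = maps_bin)
  })
}

# Mean absolute relative error of fitted vs true kinetic parameters over
# the fitted vessel voxels (delta_t, sharpness, time_to_peak).
vessel_param_error <- function(maps, phantom) {
  tab <- vessel_fit_table(maps, phantom)
  ok <- tab$mask & !is.na(tab$delta_t)
  rel <- function(est, truth) mean(abs(est[ok] - truth[ok]) / truth[ok])
  c(delta_t = rel(tab$delta_t, tab$true_delta_t),
    sharpness = rel(tab$sharpness, tab$true_sharpness),
    time_to_peak = rel(tab$time_to_peak, tab$true_time_to_peak))
}
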