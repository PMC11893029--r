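#' Sequence parameters for an ASL angiography readout train
#'
#' Describes the timing and excitation schedule of a single preparation
#' repeat: a (pseudo-continuous) labeling period of duration
#' `labeling_duration`, followed by a train of `n_readouts` low-flip-angle
#' excitations separated by `tr`. Flip angles vary quadratically between
#' `flip_min` and `flip_max` across the train (see
#' [quadratic_flip_schedule()]).
#'
#' @param tr Repetition time between successive excitations, in seconds.
#' @param labeling_duration Duration of the labeling period (tau), seconds.
#' @param n_readouts Number of excitations per preparation repeat.
#' @param flip_min,flip_max First and last flip angle of the quadratic
#'   schedule, degrees. Must satisfy `0 < flip_min <= flip_max < 90`.
#' @param t1_blood Longitudinal relaxation time of arterial blood, seconds.
#'   Default 1.65 s, a standard value for arterial blood at 3 T.
#' @param first_excitation_offset Delay from the end of labeling to the
#'   first excitation, seconds (default 0).
#'
#' @return An object of class `seq_params` (a named list).
#' @examples
#' sq <- seq_params()
#' excitation_times(sq)[1:3]
#' @export
seq_params <- function(tr = 0.0147,
                       labeling_duration = 1.8,
                       n_readouts = 144L,
                       flip_min = 3,
                       flip_max = 12,
                       t1_blood = 1.65,
                       first_excitation_offset = 0) {
  stopifnot(
    is.numeric(tr), length(tr) == 1L, tr > 0,
    is.numeric(labeling_duration), length(labeling_duration) == 1L,
    labeling_duration > 0,
    is.numeric(n_readouts), length(n_readouts) == 1L, n_readouts >= 1,
    n_readouts == round(n_readouts),
    is.numeric(flip_min), flip_min > 0,
    is.numeric(flip_max), flip_max < 90, flip_min <= flip_max,
    is.numeric(t1_blood), t1_blood > 0,
    is.numeric(first_excitation_offset), first_excitation_offset >= 0
  )
  structure(
    list(
      tr = tr,
      labeling_duration = labeling_duration,
      n_readouts = as.integer(n_readouts),
      flip_min = flip_min,
      flip_max = flip_max,
      t1_blood = t1_blood,
      first_excitation_offset = first_excitation_offset
    ),
    class = "seq_params"
  )
}

#' @export
print.seq_params <- function(x, ...) {
  cat("ASL angiography sequence parameters\n")
  cat(sprintf("  TR:                 %.4g ms\n", 1e3 * x$tr))
  cat(sprintf("  labeling duration:  %.4g s\n", x$labeling_duration))
  cat(sprintf("  readouts:           %d (total %.1f ms)\n",
              x$n_readouts, 1e3 * x$n_readouts * x$tr))
  cat(sprintf("  flip angles:        %g-%g deg (quadratic)\n",
              x$flip_min, x$flip_max))
  cat(sprintf("  blood T1:           %.3g s\n", x$t1_blood))
  invisible(x)
}

#' Quadratic variable flip-angle schedule
#'
#' Flip angle of excitation `i` (1-based) out of `N`:
#' `flip_min + (flip_max - flip_min) * ((i - 1) / (N - 1))^2`.
#' The schedule starts at `flip_min`, ends at `flip_max` and is
#' non-decreasing, compensating signal attenuation by earlier pulses.
#'
#' @param seq A [seq_params()] object.
#' @return Numeric vector of `n_readouts` flip angles in degrees.
#' @export
quadratic_flip_schedule <- function(seq) {
  stopifnot(inherits(seq, "seq_params"))
  n <- seq$n_readouts
  if (n == 1L) return(seq$flip_min)
  i <- seq_len(n)
  seq$flip_min + (seq$flip_max - seq$flip_min) * ((i - 1) / (n - 1))^2
}

#' Excitation times of the readout train
#'
#' Time of each excitation measured from the onset of labeling:
#' excitation `i` occurs at
#' `labeling_duration + first_excitation_offset + (i - 1) * tr`.
#'
#' @inheritParams quadratic_flip_schedule
#' @return Numeric vector of `n_readouts` times in seconds.
#' @export
excitation_times <- function(seq) {
  stopifnot(inherits(seq, "seq_params"))
  seq$labeling_duration + seq$first_excitation_offset +
    (seq_len(seq$n_readouts) - 1) * seq$tr
}

#' Read or write sequence parameters as a YAML config
#'
#' The YAML keys are `tr_s`, `labeling_duration_s`, `n_readouts`,
#' `flip_min_deg`, `flip_max_deg`, `t1b_s`, `first_excitation_offset_s`.
#' Missing optional keys fall back to the [seq_params()] defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_seq_config()` returns a `seq_params` object;
#'   `write_seq_config()` returns `path` invisibly.
#' @export
read_seq_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- seq_params()
  pick <- function(key, fallback) if (!is.null(cfg[[key]])) cfg[[key]] else fallback
  seq_params(
    tr = pick("tr_s", defaults$tr),
    labeling_duration = pick("labeling_duration_s", defaults$labeling_duration),
    n_readouts = pick("n_readouts", defaults$n_readouts),
    flip_min = pick("flip_min_deg", defaults$flip_min),
    flip_max = pick("flip_max_deg", defaults$flip_max),
    t1_blood = pick("t1b_s", defaults$t1_blood),
    first_excitation_offset = pick("first_excitation_offset_s",
                                   defaults$first_excitation_offset)
  )
}

#' @rdname read_seq_config
#' @param seq A [seq_params()] object to serialize.
#' @export
write_seq_config <- function(seq, path) {
  stopifnot(inherits(seq, "seq_params"))
  yaml::write_yaml(
    list(
      tr_s = seq$tr,
      labeling_duration_s = seq$labeling_duration,
      n_readouts = seq$n_readouts,
      flip_min_deg = seq$flip_min,
      flip_max_deg = seq$flip_max,
      t1b_s = seq$t1_blood,
      first_excitation_offset_s = seq$first_excitation_offset
    ),
    path
  )
  invisible(path)
}
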