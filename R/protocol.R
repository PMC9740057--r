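#' Acquisition protocol
#'
#' Bundle of sequence and contrast constants shared by the phantom simulator
#' and the fitting routines: repetition time and flip angles for the
#' variable-flip-angle (VFA) T1 series, echo times for the multi-echo T2
#' series, diffusion weightings, dynamic (DCE) frame structure and timing,
#' and the contrast-agent longitudinal relaxivity.
#'
#' The study protocol this mirrors uses 9 flip angles, 24 echo times, and a
#' dynamic series of 20 pre-contrast plus 80 post-contrast frames at 3.6 s
#' temporal resolution with a 0.1 mmol/kg Gd-DOTA dose.  The acquisition
#' parameter lists themselves are configurable; the defaults below are
#' conventional small-animal 3 T choices.
#'
#' @param tr_ms Repetition time of the spoiled-gradient-echo readout (ms).
#' @param flip_angles_deg Strictly increasing flip angles in (0, 90) degrees.
#' @param echo_times_ms Strictly increasing, positive echo times (ms).
#' @param b_values Diffusion weightings (s/mm^2), strictly increasing,
#'   conventionally including b = 0.
#' @param n_pre_frames,n_post_frames Number of dynamic frames before/after
#'   contrast injection.
#' @param frame_dt_s Temporal resolution of the dynamic series (s).
#' @param r1_relaxivity Contrast-agent longitudinal relaxivity
#'   (L mmol^-1 s^-1).  Default 3.5, typical for Gd-DOTA at 3 T.
#' @param ca_dose_mmol_per_kg Contrast-agent dose (mmol/kg body weight).
#' @param dce_flip_deg Flip angle of the dynamic SPGR readout (degrees).
#' @param dce_tr_ms Repetition time of the dynamic readout (ms).
#'
#' @return An object of class `acq_protocol` (a validated list).
#' @examples
#' p <- acq_protocol()
#' length(p$flip_angles_deg)  # 9
#' length(p$echo_times_ms)    # 24
#' @export
acq_protocol <- function(tr_ms = 15,
                         flip_angles_deg = c(2, 3, 4, 5, 7, 9, 12, 15, 20),
                         echo_times_ms = seq(10, 240, by = 10),
                         b_values = c(0, 1000),
                         n_pre_frames = 20L,
                         n_post_frames = 80L,
                         frame_dt_s = 3.6,
                         r1_relaxivity = 3.5,
                         ca_dose_mmol_per_kg = 0.1,
                         dce_flip_deg = 15,
                         dce_tr_ms = tr_ms) {
  p <- list(
    tr_ms = as.numeric(tr_ms),
    flip_angles_deg = as.numeric(flip_angles_deg),
    echo_times_ms = as.numeric(echo_times_ms),
    b_values = as.numeric(b_values),
    n_pre_frames = as.integer(n_pre_frames),
    n_post_frames = as.integer(n_post_frames),
    frame_dt_s = as.numeric(frame_dt_s),
    r1_relaxivity = as.numeric(r1_relaxivity),
    ca_dose_mmol_per_kg = as.numeric(ca_dose_mmol_per_kg),
    dce_flip_deg = as.numeric(dce_flip_deg),
    dce_tr_ms = as.numeric(dce_tr_ms)
  )
  class(p) <- "acq_protocol"
  validate_protocol(p)
}

#' @rdname acq_protocol
#' @param p An `acq_protocol` object.
#' @export
validate_protocol <- function(p) {
  stopifnot(inherits(p, "acq_protocol"))
  if (p$tr_ms <= 0) stop("tr_ms must be positive")
  fa <- p$flip_angles_deg
  if (length(fa) < 2 || any(diff(fa) <= 0))
    stop("flip_angles_deg must contain >= 2 strictly increasing angles")
  if (any(fa <= 0 | fa >= 90))
    stop("flip angles must lie strictly inside (0, 90) degrees")
  te <- p$echo_times_ms
  if (length(te) < 2 || any(te <= 0) || any(diff(te) <= 0))
    stop("echo_times_ms must be positive and strictly increasing")
  b <- p$b_values
  if (length(b) < 2 || any(b < 0) || any(diff(b) <= 0))
    stop("b_values must be non-negative and strictly increasing")
  if (p$n_pre_frames < 1 || p$n_post_frames < 1)
    stop("frame counts must be positive")
  if (p$frame_dt_s <= 0) stop("frame_dt_s must be positive")
  if (p$r1_relaxivity <= 0) stop("r1_relaxivity must be positive")
  if (p$ca_dose_mmol_per_kg <= 0) stop("ca_dose_mmol_per_kg must be positive")
  if (p$dce_flip_deg <= 0 || p$dce_flip_deg >= 90)
    stop("dce_flip_deg must lie strictly inside (0, 90) degrees")
  if (p$dce_tr_ms <= 0) stop("dce_tr_ms must be positive")
  invisible(p)
}

#' Dynamic frame times relative to contrast injection
#'
#' Injection happens at the start of frame `n_pre_frames + 1` (1-based);
#' each frame is stamped at its midpoint, so pre-contrast frames carry
#' negative times and the first post-contrast frame sits at `frame_dt_s / 2`.
#'
#' @param protocol An [acq_protocol()].
#' @return Numeric vector of length `n_pre_frames + n_post_frames` (s).
#' @export
frame_times <- function(protocol) {
  n <- protocol$n_pre_frames + protocol$n_post_frames
  (seq_len(n) - 1 - protocol$n_pre_frames) * protocol$frame_dt_s +
    protocol$frame_dt_s / 2
}

#' @export
print.acq_protocol <- function(x, ...) {
  cat("Acquisition protocol\n")
  cat(sprintf("  VFA: TR %.1f ms, %d flip angles (%s deg)\n", x$tr_ms,
              length(x$flip_angles_deg),
              paste(x$flip_angles_deg, collapse = ", ")))
  cat(sprintf("  Multi-echo: %d TEs, %.0f-%.0f ms\n",
              length(x$echo_times_ms), min(x$echo_times_ms),
              max(x$echo_times_ms)))
  cat(sprintf("  DWI: b = %s s/mm^2\n", paste(x$b_values, collapse = ", ")))
  cat(sprintf("  DCE: %d pre + %d post frames, dt %.1f s, flip %.0f deg\n",
              x$n_pre_frames, x$n_post_frames, x$frame_dt_s, x$dce_flip_deg))
  cat(sprintf("  CA: r1 %.2f L/mmol/s, dose %.2f mmol/kg\n",
              x$r1_relaxivity, x$ca_dose_mmol_per_kg))
  invisible(x)
}

#' Read/write an acquisition protocol as YAML
#'
#' @param protocol An [acq_protocol()].
#' @param path File path.
#' @return `read_protocol` returns an `acq_protocol`; `write_protocol`
#'   returns `path` invisibly.
#' @export
write_protocol <- function(protocol, path) {
  validate_protocol(protocol)
  yaml::write_yaml(unclass(protocol), path)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  do.call(acq_protocol, yaml::read_yaml(path))
}
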