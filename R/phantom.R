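#' Phantom ROI label map
#'
#' @param labels 3D integer array with values from [ROI_LABELS].
#' @param voxel_size_mm Isotropic voxel edge length (mm).
#' @return A `phantom_label_map` object.
#' @export
phantom_label_map <- function(labels, voxel_size_mm = 0.5) {
  stopifnot(length(dim(labels)) == 3)
  if (!all(labels %in% ROI_LABELS))
    stop("label map contains values outside the ROI dictionary")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 dictionary = ROI_LABELS),
            class = "phantom_label_map")
}

#' @export
print.phantom_label_map <- function(x, ...) {
  cat("Phantom label map", paste(dim(x$labels), collapse = " x "),
      sprintf("(%.2f mm voxels)\n", x$voxel_size_mm))
  print(table(factor(x$labels, levels = ROI_LABELS,
                     labels = names(ROI_LABELS))))
  invisible(x)
}

.ellipsoid_mask <- function(dims, center_frac, semi_frac) {
  cx <- center_frac * dims
  sx <- semi_frac * dims
  d1 <- ((seq_len(dims[1]) - cx[1]) / sx[1])^2
  d2 <- ((seq_len(dims[2]) - cx[2]) / sx[2])^2
  d3 <- ((seq_len(dims[3]) - cx[3]) / sx[3])^2
  outer(outer(d1, d2, `+`), d3, `+`) <= 1
}

#' Build the digital rat-head phantom
#'
#' Places three tissue regions on a voxel grid — an ellipsoidal brain with
#' an embedded intracranial tumor, and a separate extracranial (facial
#' muscle) tumor — and attaches the ground-truth tissue record of the
#' requested preset to each ROI.  Geometry is deterministic; `seed` is
#' recorded for provenance and used by downstream noise generation.
#'
#' @param grid_shape Integer vector of 3 grid dimensions.
#' @param preset_name One of [preset_names()].
#' @param seed Optional integer seed recorded in the result.
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @return List with `labels` (a [phantom_label_map()]), `ground_truth`
#'   (named list of [ground_truth_record()]s), `preset`, `seed`.
#' @examples
#' ph <- build_phantom(c(32, 32, 12), "extracranial_pre")
#' sort(unique(as.vector(ph$labels$labels)))  # 0 1 2 3
#' @export
build_phantom <- function(grid_shape = c(64, 64, 16),
                          preset_name = "extracranial_pre",
                          seed = NULL, voxel_size_mm = 0.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 12))
    stop("grid too small to place the phantom ROIs (need >= 12 per axis)")
  gt <- preset_ground_truth(preset_name)
  lab <- array(0L, grid_shape)
  brain <- .ellipsoid_mask(grid_shape, c(0.32, 0.50, 0.50),
                           c(0.24, 0.30, 0.34))
  intra <- .ellipsoid_mask(grid_shape, c(0.32, 0.50, 0.50),
                           c(0.10, 0.13, 0.18))
  extra <- .ellipsoid_mask(grid_shape, c(0.76, 0.50, 0.50),
                           c(0.12, 0.15, 0.22))
  lab[brain] <- ROI_LABELS[["brain"]]
  lab[intra] <- ROI_LABELS[["intracranial"]]
  lab[extra & !brain] <- ROI_LABELS[["extracranial"]]
  counts <- vapply(ROI_LABELS[-1], function(l) sum(lab == l), integer(1))
  if (any(counts < 8))
    stop("grid too small to place the phantom ROIs (an ROI came out empty)")
  list(labels = phantom_label_map(lab, voxel_size_mm),
       ground_truth = gt, preset = preset_name, seed = seed)
}

#' Expand per-ROI ground truth into voxel-wise parameter maps
#'
#' @param phantom Result of [build_phantom()].
#' @param quantity One of `"t1"`, `"t2"`, `"adc"`, `"ce_t1"`, `"m0"`.
#' @return A [parameter_map()] on the phantom grid (background voxels are
#'   zero and masked invalid).
#' @export
phantom_parameter_map <- function(phantom, quantity = c("t1", "t2", "adc",
                                                        "ce_t1", "m0")) {
  quantity <- match.arg(quantity)
  field <- switch(quantity, t1 = "t1_ms", t2 = "t2_ms",
                  adc = "adc_mm2_per_s", ce_t1 = "ce_t1_ms", m0 = "m0")
  units <- switch(quantity, t1 = "ms", t2 = "ms", ce_t1 = "ms",
                  adc = "mm2/s", m0 = "unitless")
  lab <- phantom$labels$labels
  lut <- numeric(4)
  for (roi in names(phantom$ground_truth)) {
    lut[ROI_LABELS[[roi]] + 1] <- phantom$ground_truth[[roi]][[field]]
  }
  vals <- array(lut[lab + 1L], dim(lab))
  parameter_map(vals, units, mask = lab > 0,
                provenance = list(source = "phantom", preset = phantom$preset,
                                  quantity = quantity))
}

# Rician magnitude noise: Gaussian noise of sd `sd` on two quadrature
# channels, the signal on one of them.  `gaussian` adds plain real noise,
# useful for debugging estimator bias separately from the Rician floor.
.add_noise <- function(x, sd, seed = NULL,
                       model = c("rician", "gaussian")) {
  model <- match.arg(model)
  if (sd < 0) stop("noise_sd must be non-negative")
  if (sd == 0) return(x)
  gen <- function() {
    if (model == "rician") {
      sqrt((x + stats::rnorm(length(x), 0, sd))^2 +
             stats::rnorm(length(x), 0, sd)^2)
    } else {
      x + stats::rnorm(length(x), 0, sd)
    }
  }
  y <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  array(y, dim(x))
}

# SPGR steady-state signal for unit M0.
.spgr_unit <- function(t1_ms, tr_ms, flip_deg) {
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_ms / t1_ms)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Simulate a variable-flip-angle SPGR series
#'
#' Forward-evaluates the spoiled-gradient-echo steady state
#' `S = M0 sin(a) (1 - E1) / (1 - E1 cos(a))`, `E1 = exp(-TR/T1)`, at every
#' protocol flip angle, optionally adding seed-controlled Rician noise.
#'
#' @param t1_map,m0_map 3D arrays (or [parameter_map()]s) of T1 (ms) and
#'   equilibrium magnetization; T1 must be positive wherever M0 > 0.
#' @param protocol An [acq_protocol()].
#' @param noise_sd Noise standard deviation per quadrature channel (signal
#'   units); 0 for noiseless.
#' @param seed Optional seed making the noise reproducible.
#' @param noise_model `"rician"` (magnitude) or `"gaussian"`.
#' @return A [signal_stack()] with one volume per flip angle.
#' @export
simulate_vfa_series <- function(t1_map, m0_map, protocol = acq_protocol(),
                                noise_sd = 0, seed = NULL,
                                noise_model = "rician") {
  t1 <- map_values(t1_map); m0 <- map_values(m0_map)
  stopifnot(identical(dim(t1), dim(m0)))
  if (any(m0 > 0 & t1 <= 0))
    stop("t1_map must be positive wherever m0_map > 0")
  angles <- protocol$flip_angles_deg
  vols <- vapply(angles, function(a) {
    s <- array(0, dim(t1))
    w <- m0 > 0
    s[w] <- m0[w] * .spgr_unit(t1[w], protocol$tr_ms, a)
    s
  }, FUN.VALUE = array(0, dim(t1)))
  vols <- .add_noise(array(vols, c(dim(t1), length(angles))), noise_sd,
                     seed, noise_model)
  signal_stack(vols, angles, axis = "flip_angle_deg", protocol = protocol)
}

#' Simulate a multi-echo spin-echo series
#'
#' Mono-exponential decay `S = S0 exp(-TE/T2)` at every protocol echo time.
#'
#' @param t2_map,s0_map 3D arrays (or [parameter_map()]s); T2 positive
#'   wherever S0 > 0.
#' @inheritParams simulate_vfa_series
#' @return A [signal_stack()] with one volume per echo time.
#' @export
simulate_multiecho_series <- function(t2_map, s0_map,
                                      protocol = acq_protocol(),
                                      noise_sd = 0, seed = NULL,
                                      noise_model = "rician") {
  t2 <- map_values(t2_map); s0 <- map_values(s0_map)
  stopifnot(identical(dim(t2), dim(s0)))
  if (any(s0 > 0 & t2 <= 0))
    stop("t2_map must be positive wherever s0_map > 0")
  tes <- protocol$echo_times_ms
  vols <- vapply(tes, function(te) {
    s <- array(0, dim(t2))
    w <- s0 > 0
    s[w] <- s0[w] * exp(-te / t2[w])
    s
  }, FUN.VALUE = array(0, dim(t2)))
  vols <- .add_noise(array(vols, c(dim(t2), length(tes))), noise_sd,
                     seed, noise_model)
  signal_stack(vols, tes, axis = "echo_time_ms", protocol = protocol)
}

#' Simulate a diffusion-weighted series
#'
#' Mono-exponential attenuation `S = S0 exp(-b * ADC)` per b-value.
#'
#' @param adc_map,s0_map 3D arrays (or [parameter_map()]s), ADC in mm^2/s.
#' @param b_values Diffusion weightings (s/mm^2); default from `protocol`.
#' @inheritParams simulate_vfa_series
#' @return A [signal_stack()] with one volume per b-value.
#' @export
simulate_dwi_series <- function(adc_map, s0_map, b_values = NULL,
                                protocol = acq_protocol(),
                                noise_sd = 0, seed = NULL,
                                noise_model = "rician") {
  adc <- map_values(adc_map); s0 <- map_values(s0_map)
  stopifnot(identical(dim(adc), dim(s0)))
  if (is.null(b_values)) b_values <- protocol$b_values
  vols <- vapply(b_values, function(b) s0 * exp(-b * adc),
                 FUN.VALUE = array(0, dim(adc)))
  vols <- .add_noise(array(vols, c(dim(adc), length(b_values))), noise_sd,
                     seed, noise_model)
  signal_stack(vols, b_values, axis = "b_value", protocol = protocol)
}

#' Simulate the dynamic contrast-enhanced series
#'
#' For every labelled ROI the tissue concentration follows its ground-truth
#' gamma-variate curve; the longitudinal rate is `R1(t) = 1/T10 + r1 C(t)`
#' and the signal is synthesized through the SPGR steady state at the
#' dynamic flip angle.  Pre-injection frames carry zero concentration;
#' injection happens at the start of frame `n_pre_frames + 1` and frames
#' are stamped at mid-frame (see [frame_times()]).
#'
#' @param label_map A [phantom_label_map()] (or 3D integer array).
#' @param ground_truth Named list of [ground_truth_record()]s covering every
#'   non-background label present.
#' @inheritParams simulate_vfa_series
#' @return A [dynamic_series()] with `n_pre_frames + n_post_frames` frames.
#' @export
simulate_dce_series <- function(label_map, ground_truth,
                                protocol = acq_protocol(),
                                noise_sd = 0, seed = NULL,
                                noise_model = "rician") {
  lab <- if (inherits(label_map, "phantom_label_map")) label_map$labels else
    label_map
  tt <- frame_times(protocol)
  n_frames <- length(tt)
  present <- setdiff(sort(unique(as.vector(lab))), 0L)
  sig <- matrix(0, nrow = 4, ncol = n_frames)  # rows: label 0..3
  for (l in present) {
    roi <- names(ROI_LABELS)[match(l, ROI_LABELS)]
    rec <- ground_truth[[roi]]
    if (is.null(rec))
      stop("missing ground truth for label ", l, " (", roi, ")")
    conc <- numeric(n_frames)
    post <- tt > 0
    conc[post] <- tissue_concentration_curve(rec$curve_params, tt[post])
    r10 <- 1 / rec$t1_ms                       # 1/ms
    r1t <- r10 + protocol$r1_relaxivity * conc / 1000
    sig[l + 1, ] <- rec$m0 *
      .spgr_unit(1 / r1t, protocol$dce_tr_ms, protocol$dce_flip_deg)
  }
  frames <- array(sig[as.vector(lab) + 1L, ], c(dim(lab), n_frames))
  frames <- .add_noise(frames, noise_sd, seed, noise_model)
  dynamic_series(frames, frame_times_s = tt,
                 n_pre_frames = protocol$n_pre_frames, protocol = protocol)
}
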