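#' Dynamic contrast-enhanced series
#'
#' @param frames 4D signal array, frame index last.
#' @param frame_times_s Per-frame mid-frame time relative to injection (s),
#'   strictly increasing; pre-injection frames are negative.
#' @param n_pre_frames Number of pre-injection frames.
#' @param protocol Optional [acq_protocol()] reference.
#' @return A `dynamic_series` object.
#' @export
dynamic_series <- function(frames, frame_times_s, n_pre_frames,
                           protocol = NULL) {
  stopifnot(length(dim(frames)) == 4)
  if (length(frame_times_s) != dim(frames)[4])
    stop("frame_times_s length must match the number of frames")
  if (any(diff(frame_times_s) <= 0))
    stop("frame_times_s must be strictly increasing")
  n_pre_frames <- as.integer(n_pre_frames)
  if (any(frame_times_s[seq_len(n_pre_frames)] >= 0))
    stop("pre-injection frames must carry negative times")
  structure(list(frames = frames, frame_times_s = frame_times_s,
                 n_pre_frames = n_pre_frames, protocol = protocol),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("Dynamic series %s: %d frames (%d pre + %d post), t = %.1f..%.1f s\n",
              paste(dim(x$frames)[1:3], collapse = " x "),
              dim(x$frames)[4], x$n_pre_frames,
              dim(x$frames)[4] - x$n_pre_frames,
              min(x$frame_times_s), max(x$frame_times_s)))
  invisible(x)
}

#' Pre-contrast baseline signal
#'
#' Per-voxel mean of the pre-injection frames, with the temporal standard
#' deviation as a quality-control map.
#'
#' @param series A [dynamic_series()].
#' @param mask Optional 3D logical mask.
#' @return List with `baseline` and `sd` [parameter_map()]s.
#' @export
estimate_baseline <- function(series, mask = NULL) {
  stopifnot(inherits(series, "dynamic_series"))
  npre <- series$n_pre_frames
  if (npre < 2) stop("need at least 2 pre-injection frames")
  dims <- dim(series$frames)[1:3]
  pre <- matrix(series$frames[, , , seq_len(npre)], prod(dims), npre)
  mu <- array(rowMeans(pre), dims)
  sdv <- array(sqrt(rowSums((pre - rowMeans(pre))^2) / (npre - 1)), dims)
  if (is.null(mask)) mask <- array(TRUE, dims)
  list(baseline = parameter_map(mu, "unitless", mask,
                                list(model = "pre_contrast_mean", n = npre)),
       sd = parameter_map(sdv, "unitless", mask,
                          list(model = "pre_contrast_sd", n = npre)))
}

#' Convert dynamic signal to contrast-agent concentration
#'
#' Inverts the SPGR steady-state equation frame by frame: the equilibrium
#' magnetization is calibrated from the measured pre-contrast baseline and
#' the supplied pre-contrast T1 (T10); each frame's signal is solved for
#' `E1`, hence `R1(t)`, and the concentration follows from
#' `C(t) = (R1(t) - 1/T10) / r1`.  Small negative concentrations from the
#' noise floor are carried signed, not clamped.  Frames whose signal
#' exceeds the SPGR saturation ceiling of a voxel are marked invalid (NA).
#'
#' A `"linear"` mode using the normalized enhancement
#' `C ~ (S - S0)/S0 / (r1 T10)` is provided for sensitivity analysis only.
#'
#' @param series A [dynamic_series()].
#' @param baseline_map Pre-contrast baseline signal ([estimate_baseline()]).
#' @param t10_map Pre-contrast T1 map (ms), positive on the mask.
#' @param protocol An [acq_protocol()]; supplies the dynamic flip angle,
#'   TR and relaxivity.
#' @param mask Optional 3D logical mask; defaults to the intersection of
#'   valid baseline and T10 voxels.
#' @param m0_map Optional externally known equilibrium magnetization; when
#'   given, a QC warning is raised if the SPGR-predicted baseline deviates
#'   from the measured one by more than 10% anywhere on the mask.
#' @param method `"spgr"` (full inversion, default) or `"linear"`.
#' @return A `concentration_series` list: `conc` (4D array, mmol/L),
#'   `times_s`, `n_pre_frames`, `mask`.
#' @export
signal_to_concentration <- function(series, baseline_map, t10_map,
                                    protocol = NULL, mask = NULL,
                                    m0_map = NULL,
                                    method = c("spgr", "linear")) {
  method <- match.arg(method)
  stopifnot(inherits(series, "dynamic_series"))
  if (is.null(protocol)) protocol <- series$protocol
  if (is.null(protocol)) stop("no acquisition protocol available")
  dims <- dim(series$frames)[1:3]
  sb <- map_values(baseline_map)
  t10 <- map_values(t10_map)
  stopifnot(identical(dim(sb), dims), identical(dim(t10), dims))
  if (is.null(mask)) {
    mask <- is.finite(sb) & sb > 0 & is.finite(t10) & t10 > 0
    if (inherits(t10_map, "parameter_map")) mask <- mask & t10_map$mask
  }
  if (any(t10[mask] <= 0)) stop("t10_map must be positive on the mask")
  a <- protocol$dce_flip_deg * pi / 180
  tr <- protocol$dce_tr_ms
  r1 <- protocol$r1_relaxivity
  idx <- which(mask)
  nfr <- dim(series$frames)[4]
  conc <- array(NA_real_, dim(series$frames))
  if (length(idx)) {
    S <- matrix(series$frames, prod(dims), nfr)[idx, , drop = FALSE]
    t10v <- t10[idx]; sbv <- sb[idx]
    m0 <- sbv / .spgr_unit(t10v, tr, protocol$dce_flip_deg)
    if (!is.null(m0_map)) {
      m0_ext <- map_values(m0_map)[idx]
      pred <- m0_ext * .spgr_unit(t10v, tr, protocol$dce_flip_deg)
      dev <- abs(pred - sbv) / sbv
      if (any(dev > 0.10))
        warning(sprintf(paste("baseline inconsistent with supplied M0/T10:",
                              "max deviation %.1f%% (> 10%%)"),
                        100 * max(dev)))
      m0 <- m0_ext
    }
    if (method == "spgr") {
      y <- S / (m0 * sin(a))
      e1 <- (1 - y) / (1 - y * cos(a))
      e1[e1 <= 0 | e1 >= 1] <- NA_real_  # beyond saturation ceiling
      r1t <- -log(e1) / tr               # 1/ms
      cm <- sweep(r1t, 1, 1 / t10v, `-`) * 1000 / r1
    } else {
      cm <- sweep(S, 1, sbv, `/`) - 1
      cm <- sweep(cm, 1, 1 / (r1 * t10v / 1000), `*`)
    }
    conc <- array(NA_real_, c(prod(dims), nfr))
    conc[idx, ] <- cm
    conc <- array(conc, c(dims, nfr))
  }
  structure(list(conc = conc, times_s = series$frame_times_s,
                 n_pre_frames = series$n_pre_frames, mask = mask,
                 protocol = protocol, method = method),
            class = "concentration_series")
}

#' ROI-mean concentration curve
#'
#' Averages the concentration over an ROI frame by frame and returns the
#' post-injection curve anchored at `C(0) = 0`.
#'
#' @param conc_series A `concentration_series` from
#'   [signal_to_concentration()].
#' @param labels A [phantom_label_map()] or 3D integer array.
#' @param roi_label ROI name (e.g. `"extracranial"`) or integer label.
#' @return A `concentration_curve` data frame with columns `times_s`,
#'   `conc_mM` and attribute `roi`.
#' @export
roi_concentration_curve <- function(conc_series, labels, roi_label) {
  lab <- if (inherits(labels, "phantom_label_map")) labels$labels else labels
  l <- if (is.character(roi_label)) ROI_LABELS[[roi_label]] else roi_label
  sel <- lab == l & conc_series$mask
  if (!any(sel)) stop("ROI '", roi_label, "' empty within the valid mask")
  dims <- dim(lab)
  nfr <- length(conc_series$times_s)
  M <- matrix(conc_series$conc, prod(dims), nfr)[which(sel), , drop = FALSE]
  mu <- colMeans(M)
  post <- conc_series$times_s > 0
  curve <- data.frame(times_s = c(0, conc_series$times_s[post]),
                      conc_mM = c(0, mu[post]))
  attr(curve, "roi") <- roi_label
  class(curve) <- c("concentration_curve", "data.frame")
  curve
}

# Trapezoidal integral of a sampled curve over [from, to] with linear
# interpolation at both window edges.
.trapz_window <- function(t, y, from, to) {
  if (to <= from) return(0)
  keep <- t > from & t < to
  ti <- c(from, t[keep], to)
  yi <- c(stats::approx(t, y, from, rule = 2)$y, y[keep],
          stats::approx(t, y, to, rule = 2)$y)
  sum(diff(ti) * (utils::head(yi, -1) + utils::tail(yi, -1)) / 2)
}

#' Area under the concentration curve
#'
#' Trapezoidal integral of a sampled concentration curve from `start_s` to
#' `window_s`, anchored at `C(0) = 0` when no sample at t = 0 is present,
#' with linear interpolation when a window edge falls between samples.
#' The result is reported in mmol/L * min.  The AUC30/AUC300 perfusion
#' surrogates are `auc(curve, 30)` and `auc(curve, 300)`.
#'
#' When the window extends beyond the last sample the integral is
#' truncated there; by default a warning is raised if the overshoot
#' exceeds one frame interval (`partial = "warn"`), which happens for the
#' 300 s window on an 80-frame, 3.6 s acquisition (288 s span).  Use
#' `partial = "error"` for strict behaviour or `"silent"` to suppress.
#'
#' @param curve A `concentration_curve` (or data frame with `times_s`,
#'   `conc_mM`), sorted by time.
#' @param window_s Upper window edge (s, > `start_s`).
#' @param start_s Lower window edge (s, default 0).
#' @param partial One of `"warn"`, `"silent"`, `"error"`.
#' @return Area in mmol/L * min.
#' @examples
#' curve <- data.frame(times_s = seq(0, 30, 1.5), conc_mM = 1)
#' auc(curve, 30)   # 0.5 mmol/L * min
#' @export
auc <- function(curve, window_s, start_s = 0,
                partial = c("warn", "silent", "error")) {
  partial <- match.arg(partial)
  if (window_s <= start_s) stop("window_s must exceed start_s")
  t <- curve$times_s; y <- curve$conc_mM
  if (is.unsorted(t, strictly = TRUE)) stop("curve must be sorted by time")
  if (min(t) > 0) { t <- c(0, t); y <- c(0, y) }
  last <- max(t)
  if (window_s > last) {
    dt <- if (length(t) > 1) stats::median(diff(t)) else Inf
    if (window_s - last > dt) {
      msg <- sprintf("window %.1f s exceeds last sample %.1f s; integral truncated",
                     window_s, last)
      if (partial == "error") stop(msg)
      if (partial == "warn") warning(msg)
    }
    window_s <- last
  }
  .trapz_window(t, y, start_s, window_s) / 60
}

#' Voxel-wise AUC map
#'
#' @param conc_series A `concentration_series`.
#' @param window_s Integration window (s).
#' @param partial Passed to [auc()] (default `"silent"`; the truncation
#'   warning would repeat per voxel).
#' @return A [parameter_map()] in mmol/L * min.
#' @export
auc_map <- function(conc_series, window_s, partial = "silent") {
  dims <- dim(conc_series$conc)[1:3]
  out <- array(NA_real_, dims)
  idx <- which(conc_series$mask)
  if (length(idx)) {
    nfr <- length(conc_series$times_s)
    M <- matrix(conc_series$conc, prod(dims), nfr)[idx, , drop = FALSE]
    post <- conc_series$times_s > 0
    tpost <- conc_series$times_s[post]
    vals <- apply(M[, post, drop = FALSE], 1, function(v) {
      if (anyNA(v)) return(NA_real_)
      auc(data.frame(times_s = tpost, conc_mM = v), window_s,
          partial = partial)
    })
    out[idx] <- vals
  }
  ok <- is.finite(out); ok[is.na(ok)] <- FALSE
  parameter_map(out, "mmol/L*min", ok,
                list(model = "trapezoid_auc", window_s = window_s))
}

#' T1 ratio map
#'
#' Voxel-wise post-contrast T1 divided by pre-contrast T1.  Values below 1
#' indicate contrast uptake; after vascular shutdown the ratio rises
#' toward 1.
#'
#' @param ce_t1_map Post-contrast T1 [parameter_map()] (or array).
#' @param pre_t1_map Pre-contrast T1 [parameter_map()] (or array).
#' @param mask Optional 3D logical mask.
#' @return A unitless [parameter_map()].
#' @export
t1_ratio <- function(ce_t1_map, pre_t1_map, mask = NULL) {
  ce <- map_values(ce_t1_map); pre <- map_values(pre_t1_map)
  stopifnot(identical(dim(ce), dim(pre)))
  ok <- is.finite(ce) & is.finite(pre) & pre > 0 & ce > 0
  if (inherits(ce_t1_map, "parameter_map")) ok <- ok & ce_t1_map$mask
  if (inherits(pre_t1_map, "parameter_map")) ok <- ok & pre_t1_map$mask
  if (!is.null(mask)) ok <- ok & mask
  vals <- array(NA_real_, dim(ce))
  vals[ok] <- ce[ok] / pre[ok]
  parameter_map(vals, "unitless", ok, list(model = "t1_ratio"))
}
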