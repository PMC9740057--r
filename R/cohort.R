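#' ROI summary statistics
#'
#' Mean, standard deviation and voxel count of a parameter map over one
#' ROI, using valid voxels only (invalid fits never propagate NaN into the
#' summary).
#'
#' @param map A [parameter_map()] (or 3D array).
#' @param labels A [phantom_label_map()] or 3D integer array on the same
#'   grid.
#' @param roi_label ROI name or integer label.
#' @return List with `mean`, `sd`, `n_voxels`.
#' @export
roi_summary <- function(map, labels, roi_label) {
  lab <- if (inherits(labels, "phantom_label_map")) labels$labels else labels
  vals <- map_values(map)
  stopifnot(identical(dim(vals), dim(lab)))
  l <- if (is.character(roi_label)) ROI_LABELS[[roi_label]] else roi_label
  roi <- lab == l
  if (!any(roi)) stop("ROI '", roi_label, "' is empty")
  ok <- roi & is.finite(vals)
  if (inherits(map, "parameter_map")) ok <- ok & map$mask
  v <- vals[ok]
  if (!length(v)) stop("no valid voxels in ROI '", roi_label, "'")
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
       n_voxels = length(v))
}

# 3D binary erosion with the 6-connected cross structuring element,
# iterated `iter` times; outside the volume counts as background.
.erode3d <- function(mask, iter = 1) {
  d <- dim(mask)
  shift <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else        { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (i in seq_len(iter)) {
    mask <- mask &
      shift(mask, 1, 1) & shift(mask, 1, -1) &
      shift(mask, 2, 1) & shift(mask, 2, -1) &
      shift(mask, 3, 1) & shift(mask, 3, -1)
  }
  mask
}

#' Split an ROI into core and periphery
#'
#' The rim is the ROI minus its morphological erosion (6-connected cross
#' kernel, `rim_width_voxels` iterations); the core is the erosion.  Rim
#' and core are disjoint and their union is the ROI.  Used to probe the
#' peripheral perfusion restoration seen after vascular-disrupting
#' treatment.
#'
#' @param labels A [phantom_label_map()] or 3D integer array.
#' @param roi_label ROI name or integer label.
#' @param rim_width_voxels Rim thickness in voxels (>= 1).
#' @return List of logical arrays `core` and `rim`.
#' @export
split_roi_periphery <- function(labels, roi_label, rim_width_voxels = 1) {
  if (rim_width_voxels < 1) stop("rim_width_voxels must be >= 1")
  lab <- if (inherits(labels, "phantom_label_map")) labels$labels else labels
  l <- if (is.character(roi_label)) ROI_LABELS[[roi_label]] else roi_label
  roi <- lab == l
  if (!any(roi)) stop("ROI '", roi_label, "' is empty")
  core <- .erode3d(roi, rim_width_voxels)
  if (!any(core))
    stop("rim width ", rim_width_voxels, " erodes ROI '", roi_label,
         "' to an empty core")
  list(core = core, rim = roi & !core)
}

#' Paired comparison of matched measurements
#'
#' Shapiro-Wilk normality test on the paired differences, then the paired
#' t-test (two-sided).  When normality is rejected the t result is still
#' reported with `normal = FALSE`, and a Wilcoxon signed-rank p-value is
#' attached as a sensitivity check.
#'
#' @param values_a,values_b Equal-length matched numeric vectors (n >= 3).
#' @param alpha Significance level used for the normality flag.
#' @param include_wilcoxon Attach the Wilcoxon signed-rank sensitivity
#'   p-value (default `TRUE`).
#' @return A `paired_comparison` list: `n`, `mean_a`, `mean_b`,
#'   `normality_p`, `normal`, `statistic` (t), `df`, `p_value`,
#'   `wilcoxon_p`, `test_used`.
#' @examples
#' paired_compare(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))$statistic  # 4.243
#' @export
paired_compare <- function(values_a, values_b, alpha = 0.05,
                           include_wilcoxon = TRUE) {
  if (length(values_a) != length(values_b))
    stop("values_a and values_b must have equal length")
  if (!all(is.finite(values_a)) || !all(is.finite(values_b)))
    stop("values must be finite")
  n <- length(values_a)
  if (n < 3) stop("need at least 3 pairs")
  d <- values_a - values_b
  sw_p <- if (stats::sd(d) == 0) NA_real_ else
    stats::shapiro.test(d)$p.value
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) { tstat <- 0; p <- 1 }
    else { tstat <- sign(mean(d)) * Inf; p <- 0 }
  } else {
    tt <- stats::t.test(values_a, values_b, paired = TRUE)
    tstat <- unname(tt$statistic); p <- tt$p.value
  }
  w_p <- NA_real_
  if (include_wilcoxon && any(d != 0)) {
    w_p <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE)$p.value)
  }
  structure(list(n = n, mean_a = mean(values_a), mean_b = mean(values_b),
                 normality_p = sw_p,
                 normal = is.na(sw_p) || sw_p >= alpha,
                 statistic = tstat, df = n - 1, p_value = p,
                 wilcoxon_p = w_p, test_used = "paired t"),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t: n = %d, mean A %.4g vs B %.4g, t(%d) = %.3f, p = %.4g%s\n",
              x$n, x$mean_a, x$mean_b, x$df, x$statistic, x$p_value,
              if (!x$normal) " [non-normal differences]" else ""))
  invisible(x)
}

#' Simulate a longitudinal ROI cohort
#'
#' Draws per-subject ROI summary values around the preset scene means with
#' a multiplicative Gaussian between-subject spread, producing the long
#' table consumed by [assemble_longitudinal()].  This emulates biological
#' inter-animal variability on top of the phantom ground truth; it does not
#' model within-subject measurement correlation across metrics.
#'
#' @param n_subjects Number of subjects.
#' @param metrics Metrics to draw (subset of `AUC30`, `AUC300`, `T1`,
#'   `CE_T1`, `T1_ratio`, `T2`, `ADC`).
#' @param timepoints Subset of `pre`, `1h`, `8h`, `24h`.
#' @param cv Between-subject coefficient of variation.
#' @param seed Optional seed.
#' @return A long `data.frame` with columns `subject`, `roi`, `timepoint`,
#'   `metric`, `value`, `n_voxels`, `sd`.
#' @export
simulate_roi_cohort <- function(n_subjects = 8,
                                metrics = c("AUC30", "AUC300", "T1", "CE_T1",
                                            "T1_ratio", "T2", "ADC"),
                                timepoints = c("pre", "1h", "8h", "24h"),
                                cv = 0.08, seed = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  timepoints <- match.arg(timepoints, several.ok = TRUE)
  truth_value <- function(rec, metric) {
    switch(metric,
           AUC30 = rec$auc30_true, AUC300 = rec$auc300_true,
           T1 = rec$t1_ms, CE_T1 = rec$ce_t1_ms,
           T1_ratio = rec$ce_t1_ms / rec$t1_ms,
           T2 = rec$t2_ms, ADC = rec$adc_mm2_per_s)
  }
  draw <- function() {
    rows <- list()
    for (tp in timepoints) {
      recs <- .scene_records(tp)
      for (roi in names(recs)) {
        for (m in metrics) {
          mu <- truth_value(recs[[roi]], m)
          val <- mu * (1 + stats::rnorm(n_subjects, 0, cv))
          rows[[length(rows) + 1]] <- data.frame(
            subject = sprintf("S%02d", seq_len(n_subjects)),
            roi = roi, timepoint = tp, metric = m, value = val,
            n_voxels = 100L, sd = abs(mu) * cv)
        }
      }
    }
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  rownames(out) <- NULL
  out
}

.one_comparison <- function(df_a, df_b, label_a, label_b, metric, alpha) {
  common <- intersect(df_a$subject, df_b$subject)
  dropped <- setdiff(union(df_a$subject, df_b$subject), common)
  if (length(dropped))
    warning("excluding subject(s) ", paste(dropped, collapse = ", "),
            " from ", metric, " ", label_a, " vs ", label_b,
            " (missing measurements)")
  if (length(common) < 3) {
    warning("fewer than 3 complete pairs for ", metric, " ", label_a,
            " vs ", label_b, "; test skipped")
    return(NULL)
  }
  a <- df_a$value[match(common, df_a$subject)]
  b <- df_b$value[match(common, df_b$subject)]
  pc <- paired_compare(a, b, alpha = alpha)
  data.frame(metric = metric, group_a = label_a, group_b = label_b,
             n = pc$n, mean_a = pc$mean_a, mean_b = pc$mean_b,
             normality_p = pc$normality_p, normal = pc$normal,
             statistic = pc$statistic, p_value = pc$p_value,
             wilcoxon_p = pc$wilcoxon_p, test_used = pc$test_used)
}

#' Assemble the longitudinal comparison set
#'
#' From a long ROI table (see [simulate_roi_cohort()] for the layout),
#' computes for every metric (a) intracranial vs extracranial paired
#' comparisons at each timepoint and (b) each post-treatment timepoint vs
#' pre-treatment within each ROI.  Subjects missing a timepoint are
#' excluded from the affected comparisons with a warning.  Raw two-sided
#' p-values are reported (as in the source analyses); a Holm-adjusted
#' column is added for transparency but not used for any flag.
#'
#' @param roi_table Long `data.frame` with columns `subject`, `roi`,
#'   `timepoint`, `metric`, `value` (a list of such tables is row-bound).
#' @param alpha Significance level for the normality flag.
#' @return List with `table` (the input, row-bound) and `comparisons`
#'   (one row per paired test, with `p_holm`).
#' @export
assemble_longitudinal <- function(roi_table, alpha = 0.05) {
  if (is.list(roi_table) && !is.data.frame(roi_table))
    roi_table <- do.call(rbind, roi_table)
  need <- c("subject", "roi", "timepoint", "metric", "value")
  if (!all(need %in% names(roi_table)))
    stop("roi_table must contain columns ",
         paste(need, collapse = ", "))
  tps <- intersect(c("pre", "1h", "8h", "24h"),
                   unique(roi_table$timepoint))
  out <- list()
  for (m in unique(roi_table$metric)) {
    dm <- roi_table[roi_table$metric == m, ]
    for (tp in tps) {  # site contrast at each timepoint
      res <- .one_comparison(
        dm[dm$roi == "intracranial" & dm$timepoint == tp, ],
        dm[dm$roi == "extracranial" & dm$timepoint == tp, ],
        paste0("intracranial_", tp), paste0("extracranial_", tp), m, alpha)
      out[[length(out) + 1]] <- res
    }
    if ("pre" %in% tps) {  # longitudinal contrast within each ROI
      for (roi in unique(dm$roi)) {
        for (tp in setdiff(tps, "pre")) {
          res <- .one_comparison(
            dm[dm$roi == roi & dm$timepoint == tp, ],
            dm[dm$roi == roi & dm$timepoint == "pre", ],
            paste0(roi, "_", tp), paste0(roi, "_pre"), m, alpha)
          out[[length(out) + 1]] <- res
        }
      }
    }
  }
  comparisons <- do.call(rbind, out)
  if (!is.null(comparisons) && nrow(comparisons))
    comparisons$p_holm <- stats::p.adjust(comparisons$p_value, "holm")
  list(table = roi_table, comparisons = comparisons)
}
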