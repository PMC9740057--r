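#' Pipeline run configuration
#'
#' Validated bag of settings for [run_simulate()] / [run_analyze()].
#' Unknown fields are rejected so a typo cannot silently disable a switch.
#'
#' @param out_dir Output directory.
#' @param presets Presets to simulate (see [preset_names()]); one phantom
#'   dataset is produced per preset.
#' @param grid_shape Phantom grid dimensions.
#' @param seed Integer seed recorded in every manifest and used for noise.
#' @param noise_sd Acquisition noise standard deviation (0 = noiseless).
#' @param protocol An [acq_protocol()].
#' @param voxelwise_maps Also write voxel-wise AUC maps.
#' @param rim_width_voxels Rim width for the core/periphery split.
#' @param alpha Significance level for comparisons.
#' @param n_subjects Cohort size for the longitudinal statistics stage.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, presets = preset_names(),
                       grid_shape = c(48, 48, 12), seed = 1L,
                       noise_sd = 0, protocol = acq_protocol(),
                       voxelwise_maps = TRUE, rim_width_voxels = 1,
                       alpha = 0.05, n_subjects = 8, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown config field(s): ", paste(names(extra), collapse = ", "))
  cfg <- list(out_dir = out_dir, presets = presets,
              grid_shape = as.integer(grid_shape), seed = as.integer(seed),
              noise_sd = noise_sd, protocol = protocol,
              voxelwise_maps = isTRUE(voxelwise_maps),
              rim_width_voxels = rim_width_voxels, alpha = alpha,
              n_subjects = as.integer(n_subjects))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
validate_run_config <- function(cfg) {
  known <- c("out_dir", "presets", "grid_shape", "seed", "noise_sd",
             "protocol", "voxelwise_maps", "rim_width_voxels", "alpha",
             "n_subjects")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config field(s): ", paste(extra, collapse = ", "))
  bad <- setdiff(cfg$presets, preset_names())
  if (length(bad)) stop("unknown preset(s): ", paste(bad, collapse = ", "))
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  validate_protocol(cfg$protocol)
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' The `protocol` block, if present, is passed to [acq_protocol()].
#'
#' @param path YAML file path.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$protocol)) y$protocol <- do.call(acq_protocol, y$protocol)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

.manifest_add <- function(files) {
  data.frame(file = basename(files), md5 = unname(tools::md5sum(files)),
             row.names = NULL)
}

#' Simulate a phantom dataset to disk
#'
#' For every configured preset, builds the phantom, forward-simulates the
#' VFA (pre- and post-contrast), multi-echo, diffusion and dynamic series,
#' and writes them as NIfTI together with the label map, ground-truth JSON,
#' protocol YAML and a checksum manifest.  Reruns with the same
#' configuration are byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a data frame manifest (file, md5) per preset.
#' @export
run_simulate <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifests <- list()
  for (preset in cfg$presets) {
    d <- file.path(cfg$out_dir, preset)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    ph <- build_phantom(cfg$grid_shape, preset, seed = cfg$seed)
    vox <- ph$labels$voxel_size_mm
    maps <- lapply(c(t1 = "t1", t2 = "t2", adc = "adc", ce_t1 = "ce_t1",
                     m0 = "m0"),
                   function(q) phantom_parameter_map(ph, q))
    sd <- cfg$noise_sd
    s <- cfg$seed
    write_volume(simulate_vfa_series(maps$t1, maps$m0, cfg$protocol, sd,
                                     s + 1), file.path(d, "vfa_pre.nii"), vox)
    write_volume(simulate_vfa_series(maps$ce_t1, maps$m0, cfg$protocol, sd,
                                     s + 2), file.path(d, "vfa_ce.nii"), vox)
    write_volume(simulate_multiecho_series(maps$t2, maps$m0, cfg$protocol,
                                           sd, s + 3),
                 file.path(d, "multiecho.nii"), vox)
    write_volume(simulate_dwi_series(maps$adc, maps$m0,
                                     protocol = cfg$protocol, noise_sd = sd,
                                     seed = s + 4),
                 file.path(d, "dwi.nii"), vox)
    write_volume(simulate_dce_series(ph$labels, ph$ground_truth,
                                     cfg$protocol, sd, s + 5),
                 file.path(d, "dce.nii"), vox)
    write_label_map(ph$labels, file.path(d, "labels.nii"))
    write_ground_truth(ph$ground_truth, file.path(d, "truth.json"))
    write_protocol(cfg$protocol, file.path(d, "protocol.yaml"))
    files <- file.path(d, c("vfa_pre.nii", "vfa_ce.nii", "multiecho.nii",
                            "dwi.nii", "dce.nii", "labels.nii",
                            "truth.json", "protocol.yaml"))
    mf <- .manifest_add(files)
    mf$preset <- preset
    mf$seed <- cfg$seed
    utils::write.csv(mf, file.path(d, "manifest.csv"), row.names = FALSE)
    manifests[[preset]] <- mf
  }
  invisible(do.call(rbind, manifests))
}

.analyze_preset_dir <- function(d, cfg) {
  protocol <- read_protocol(file.path(d, "protocol.yaml"))
  labels <- read_label_map(file.path(d, "labels.nii"))
  vfa_pre <- signal_stack(read_volume(file.path(d, "vfa_pre.nii")),
                          protocol$flip_angles_deg, "flip_angle_deg",
                          protocol)
  vfa_ce <- signal_stack(read_volume(file.path(d, "vfa_ce.nii")),
                         protocol$flip_angles_deg, "flip_angle_deg",
                         protocol)
  me <- signal_stack(read_volume(file.path(d, "multiecho.nii")),
                     protocol$echo_times_ms, "echo_time_ms", protocol)
  dwi <- signal_stack(read_volume(file.path(d, "dwi.nii")),
                      protocol$b_values, "b_value", protocol)
  dce_arr <- read_volume(file.path(d, "dce.nii"))
  # (the signal_stack constructors above already fail fast on a declared
  # angle/TE count that does not match the stored volumes)
  if (dim(dce_arr)[4] != protocol$n_pre_frames + protocol$n_post_frames)
    stop("protocol/series mismatch: ", dim(dce_arr)[4], " dynamic frames, ",
         protocol$n_pre_frames + protocol$n_post_frames, " declared")
  dce <- dynamic_series(dce_arr, frame_times(protocol),
                        protocol$n_pre_frames, protocol)
  mask <- labels$labels > 0
  refine <- cfg$noise_sd > 0
  t1f <- fit_t1_vfa(vfa_pre, mask = mask, refine = refine)
  cef <- fit_t1_vfa(vfa_ce, mask = mask, refine = refine)
  t2f <- fit_t2(me, mask = mask)
  adcf <- fit_adc(dwi, mask = mask)
  ratio <- t1_ratio(cef$t1, t1f$t1)
  bl <- estimate_baseline(dce, mask)
  conc <- signal_to_concentration(dce, bl$baseline, t1f$t1, protocol,
                                  mask = mask & t1f$t1$mask)
  rois <- c("brain", "intracranial", "extracranial")
  curves <- lapply(stats::setNames(rois, rois), function(r)
    roi_concentration_curve(conc, labels, r))
  metric_maps <- list(T1 = t1f$t1, CE_T1 = cef$t1, T1_ratio = ratio,
                      T2 = t2f$t2, ADC = adcf$adc)
  rows <- list()
  for (r in rois) {
    for (m in names(metric_maps)) {
      s <- roi_summary(metric_maps[[m]], labels, r)
      rows[[length(rows) + 1]] <- data.frame(
        roi = r, metric = m, value = s$mean, sd = s$sd,
        n_voxels = s$n_voxels)
    }
    for (w in c(30, 300)) {
      rows[[length(rows) + 1]] <- data.frame(
        roi = r, metric = paste0("AUC", w),
        value = auc(curves[[r]], w, partial = "silent"),
        sd = NA_real_, n_voxels = sum(labels$labels == ROI_LABELS[[r]]))
    }
  }
  out <- list(metrics = do.call(rbind, rows), curves = curves,
              maps = metric_maps, labels = labels)
  if (cfg$voxelwise_maps) {
    write_volume(auc_map(conc, 30), file.path(d, "auc30_map.nii"),
                 labels$voxel_size_mm)
    write_volume(auc_map(conc, 300), file.path(d, "auc300_map.nii"),
                 labels$voxel_size_mm)
  }
  out
}

#' Analyze a simulated (or externally supplied) dataset
#'
#' Runs relaxometry fitting, DCE concentration conversion and perfusion
#' metrics for every preset directory under the configured output
#' directory, writes per-preset ROI metric tables and concentration
#' curves, assembles the longitudinal comparison set from a simulated
#' cohort, and emits a plain-markdown report.  Header/protocol mismatches
#' (e.g. a declared frame count that does not match the series) fail fast.
#'
#' @param cfg A [run_config()] whose `out_dir` holds [run_simulate()]
#'   output.
#' @param stages Subset of `c("relaxometry", "dce", "stats", "histo")`;
#'   default all.
#' @return Invisibly, a list with `metrics` (per preset/ROI), `longitudinal`
#'   (cohort comparisons), `histology` (quantifier output), and the report
#'   path.
#' @export
run_analyze <- function(cfg, stages = c("relaxometry", "dce", "stats",
                                        "histo")) {
  validate_run_config(cfg)
  stages <- match.arg(stages, several.ok = TRUE)
  all_metrics <- list()
  if (any(c("relaxometry", "dce") %in% stages)) {
    for (preset in cfg$presets) {
      d <- file.path(cfg$out_dir, preset)
      if (!dir.exists(d)) stop("missing simulated dataset: ", d)
      res <- .analyze_preset_dir(d, cfg)
      res$metrics$preset <- preset
      utils::write.csv(res$metrics, file.path(d, "roi_metrics.csv"),
                       row.names = FALSE)
      write_curves(res$curves, file.path(d, "roi_curves.csv"))
      all_metrics[[preset]] <- res$metrics
    }
  }
  metrics <- if (length(all_metrics)) do.call(rbind, all_metrics) else NULL
  if (!is.null(metrics)) rownames(metrics) <- NULL
  longi <- NULL
  if ("stats" %in% stages) {
    cohort <- simulate_roi_cohort(n_subjects = cfg$n_subjects,
                                  seed = cfg$seed + 100)
    longi <- assemble_longitudinal(cohort, alpha = cfg$alpha)
    utils::write.csv(longi$comparisons,
                     file.path(cfg$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(longi$table, file.path(cfg$out_dir, "roi_table.csv"),
                     row.names = FALSE)
  }
  histo <- NULL
  if ("histo" %in% stages) {
    # one IHC-like field set per tumor site: positive fractions follow the
    # Ki67 presets, necrosis the H&E presets
    histo <- list(
      extracranial = quantify_histology(
        simulate_histology_fields(1000, 0.122, seed = cfg$seed + 200,
                                  necrosis_fraction = 0.862),
        marker = "Ki67"),
      intracranial = quantify_histology(
        simulate_histology_fields(1000, 0.323, seed = cfg$seed + 300,
                                  necrosis_fraction = 0.183),
        marker = "Ki67"))
    jsonlite::write_json(histo, file.path(cfg$out_dir, "histology.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report <- .write_report(cfg, metrics, longi, histo)
  invisible(list(metrics = metrics, longitudinal = longi, histology = histo,
                 report = report))
}

.write_report <- function(cfg, metrics, longi, histo) {
  path <- file.path(cfg$out_dir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Multiparametric MRI analysis report")
  w("")
  w("Seed: %d; noise sd: %g; grid: %s", cfg$seed, cfg$noise_sd,
    paste(cfg$grid_shape, collapse = "x"))
  if (!is.null(metrics)) {
    w("")
    w("## ROI metrics per preset")
    w("")
    w("| preset | roi | metric | value | n voxels |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(metrics)))
      w("| %s | %s | %s | %.6g | %d |", metrics$preset[i], metrics$roi[i],
        metrics$metric[i], metrics$value[i], metrics$n_voxels[i])
  }
  if (!is.null(longi) && !is.null(longi$comparisons)) {
    w("")
    w("## Paired comparisons (simulated cohort, n = %d)", cfg$n_subjects)
    w("")
    w("| metric | A | B | n | mean A | mean B | t | p | p (Holm) |")
    w("|---|---|---|---|---|---|---|---|---|")
    cp <- longi$comparisons
    for (i in seq_len(nrow(cp)))
      w("| %s | %s | %s | %d | %.4g | %.4g | %.3f | %.3g | %.3g |",
        cp$metric[i], cp$group_a[i], cp$group_b[i], cp$n[i], cp$mean_a[i],
        cp$mean_b[i], cp$statistic[i], cp$p_value[i], cp$p_holm[i])
  }
  if (!is.null(histo)) {
    w("")
    w("## Histology quantification")
    w("")
    for (site in names(histo)) {
      h <- histo[[site]]
      w("- %s: positive rate %.1f%%, necrosis %.1f%%, mean vessel area %.1f um^2 (%d vessels, %d cells)",
        site, h$positive_rate_pct, h$necrosis_fraction_pct,
        h$mean_vessel_area_um2, h$n_vessels, h$n_cells_total)
    }
  }
  path
}
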