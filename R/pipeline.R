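# Pipeline orchestration: YAML configuration, the end-to-end demo run, and
# stage logging. Every source of randomness flows from the single config
# seed; two runs with equal configs produce byte-identical CSV outputs.

#' Default pipeline configuration
#'
#' A small, fast, fully synthetic demonstration configuration: an ACR-like
#' phantom per scanner, a two-region diffusion ground truth, corrupted
#' rater maps for the fusion stage, and a multi-site measurement panel.
#' Grid sizes are kept deliberately small; the statistics scale, not the
#' geometry.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    phantom = list(grid_shape = c(64L, 64L, 11L),
                   voxel_size_mm = c(250 / 64, 250 / 64, 10),
                   cylinder_radius_mm = 95, signal_level = 100,
                   noise_sigma = 2, bias_amplitude = 0.05),
    acr = list(signal_area_mm2 = 400, background_area_mm2 = 182,
               uniformity_area_cm2 = 200),
    dwi = list(shape = c(10L, 10L, 4L), voxel_size_mm = c(2, 2, 2),
               s0 = 1000, noise_sigma = 0, n_b0 = 5L, n_dir = 30L, b = 1000),
    staple = list(n_raters = 4L, diag = 0.9, tol = 1e-6, max_iter = 100L),
    panel = list(
      true_values = c(wm_left = 240000, wm_right = 245000, icc = 1550000,
                      hippocampus = 4000, csf = 260000),
      scanner_ids = LETTERS[1:7],
      vendor_of = c(A = "Siemens", B = "Siemens", C = "Siemens",
                    D = "Philips", E = "Philips", F = "Philips", G = "GE"),
      sessions_per_scanner = c(A = 4L, B = 2L, C = 2L, D = 3L, E = 4L,
                               F = 7L, G = 4L),
      rescan_fraction = 0.3, inter_scanner_cv_pct = 3.3,
      intra_scanner_cv_pct = 1.1)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_mri("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = cfg$seed %||% 1L)
  for (section in names(cfg)) {
    if (section == "seed") next
    if (!section %in% names(base))
      stop_mri("unknown config section: %s", section)
    for (key in names(cfg[[section]])) {
      if (!key %in% names(base[[section]]))
        stop_mri("unknown config key: %s.%s", section, key)
      val <- cfg[[section]][[key]]
      if (!is.null(names(base[[section]][[key]])) && is.list(val))
        val <- unlist(val)
      base[[section]][[key]] <- val
    }
  }
  base
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  # yaml serialises named atomic vectors as plain sequences; convert them to
  # lists so names survive as mapping keys
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(named_to_list(unclass(config)), path)
  invisible(path)
}

stage_log <- function(stage, ...) msg("[%s] %s", stage, sprintf(...))

#' Run the full synthetic demonstration pipeline
#'
#' Executes simulate -> acr-qa -> fit-dti -> fuse -> roi-stats -> report on
#' synthetic inputs and writes all report CSVs under `out_dir`. Each stage
#' logs its parameters and outputs; reruns with an identical config are
#' byte-identical.
#'
#' @param config a `pipeline_config` (see [default_pipeline_config()]) or a
#'   YAML path.
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with the QA table, fusion result, repro table
#'   and the paths written.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  # -- ACR QA stage: one phantom per scanner -------------------------------
  ph <- config$phantom
  scanners <- config$panel$scanner_ids
  rois <- build_acr_rois(ph$grid_shape, ph$voxel_size_mm,
                         acr_roi_config(
                           signal_area_mm2 = config$acr$signal_area_mm2,
                           background_area_mm2 = config$acr$background_area_mm2,
                           uniformity_area_cm2 = config$acr$uniformity_area_cm2,
                           cylinder_radius_mm = ph$cylinder_radius_mm))
  qa <- do.call(rbind, lapply(seq_along(scanners), function(i) {
    spec <- acr_phantom_spec(grid_shape = ph$grid_shape,
                             voxel_size_mm = ph$voxel_size_mm,
                             cylinder_radius_mm = ph$cylinder_radius_mm,
                             signal_level = ph$signal_level,
                             noise_sigma = ph$noise_sigma,
                             bias_amplitude = ph$bias_amplitude,
                             seed = seed + i)
    acr_qa_result(gen_acr_phantom(spec), rois, scanner_id = scanners[i],
                  scan_date = sprintf("sim-%02d", i))
  }))
  qa_path <- file.path(out_dir, "acr_qa.csv")
  utils::write.csv(qa, qa_path, row.names = FALSE)
  stage_log("acr-qa", "%d phantoms -> %s", nrow(qa), qa_path)

  # -- DTI stage: known two-tensor ground truth, fit, ROI means ------------
  dw <- config$dwi
  shp <- as.integer(dw$shape)
  extent <- shp * dw$voxel_size_mm
  rois_dti <- gen_geometric_brain(
    shp,
    list(list(center_mm = extent * c(0.3, 0.5, 0.5),
              semiaxes_mm = extent * c(0.18, 0.3, 0.3), label = 1),
         list(center_mm = extent * c(0.72, 0.5, 0.5),
              semiaxes_mm = extent * c(0.18, 0.3, 0.3), label = 2)),
    dw$voxel_size_mm)
  D1 <- 1e-3 * diag(c(1.7, 0.2, 0.2))            # anisotropic, FA ~ 0.87
  D2 <- 1e-3 * diag(c(0.7, 0.7, 0.7))            # isotropic
  co <- uniform_tensor_field(D1, shp, dw$voxel_size_mm)$coefficients
  iso <- uniform_tensor_field(D2, shp, dw$voxel_size_mm)$coefficients
  sel <- rois_dti$data == 2L
  for (k in 1:6) {
    plane <- co[, , , k]
    plane[sel] <- iso[, , , k][sel]
    co[, , , k] <- plane
  }
  truth_tf <- tensor_field(co, dw$voxel_size_mm)
  scheme <- default_scheme(dw$n_b0, dw$n_dir, dw$b)
  dwi <- gen_dwi_series(truth_tf, dw$s0, scheme, dw$noise_sigma,
                        seed = seed + 101L)
  fit <- fit_tensor_field(dwi, mask = rois_dti$data > 0)
  fa_map <- compute_fa(fit)
  md_map <- compute_md(fit)
  dti_stats <- data.frame(
    label = names(roi_mean_scalar(fa_map, rois_dti)),
    mean_fa = as.numeric(roi_mean_scalar(fa_map, rois_dti)),
    mean_md = as.numeric(roi_mean_scalar(md_map, rois_dti)))
  dti_path <- file.path(out_dir, "dti_roi_stats.csv")
  utils::write.csv(dti_stats, dti_path, row.names = FALSE)
  stage_log("fit-dti", "%d ROIs, %d clamped eigenvalues -> %s",
            nrow(dti_stats), fit$n_clamped, dti_path)

  # -- Fusion stage: corrupted raters of the geometric truth ---------------
  st <- config$staple
  k_lab <- max(rois_dti$data) + 1L
  cm <- matrix((1 - st$diag) / (k_lab - 1), k_lab, k_lab)
  diag(cm) <- st$diag
  raters <- gen_rater_labelmaps(rois_dti,
                                rater_model(cm, st$n_raters,
                                            seed = seed + 202L))
  fus <- fuse_staple(raters, n_labels = k_lab, max_iter = st$max_iter,
                     tol = st$tol)
  perf <- do.call(rbind, lapply(seq_along(fus$rater_performance),
    function(r) {
      th <- fus$rater_performance[[r]]
      data.frame(rater = r,
                 true_label = rep(0:(k_lab - 1L), each = k_lab),
                 emitted_label = rep(0:(k_lab - 1L), times = k_lab),
                 probability = as.vector(t(th)))
    }))
  perf_path <- file.path(out_dir, "fusion_performance.csv")
  utils::write.csv(perf, perf_path, row.names = FALSE)
  stage_log("fuse", "%d raters, %d EM iterations -> %s",
            length(raters), fus$n_iterations, perf_path)

  # -- Panel + report stage ------------------------------------------------
  pn <- config$panel
  spec <- multisite_panel_spec(pn$true_values, pn$scanner_ids, pn$vendor_of,
                               pn$sessions_per_scanner, pn$rescan_fraction,
                               pn$inter_scanner_cv_pct,
                               pn$intra_scanner_cv_pct, seed = seed + 303L)
  panel <- gen_multisite_panel(spec)
  panel_path <- file.path(out_dir, "panel.csv")
  write_panel(panel, panel_path)
  table <- build_repro_table(panel)
  report_paths <- write_repro_report(table, out_dir)
  stage_log("report", "panel of %d rows -> %s", nrow(panel),
            paste(basename(report_paths), collapse = ", "))

  invisible(list(qa = qa, dti_stats = dti_stats, fusion = fus,
                 repro_table = table,
                 paths = c(qa_path, dti_path, perf_path, panel_path,
                           report_paths)))
}
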