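# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth. All generators are pure functions of their spec (seed
# included); randomness never leaks into or out of the caller's RNG state.

#' ACR-like phantom specification
#'
#' Describes a uniform cylinder phantom on an 11-slice axial grid, emulating
#' the ACR accreditation T1w protocol geometry (256 x 256 matrix, 250 mm
#' field of view, 5 mm slices at 10 mm centre spacing).
#'
#' @param grid_shape integer triple; in-plane matrix and slice count.
#' @param voxel_size_mm positive triple (mm); default 250/256 in-plane and
#'   10 mm slice centre-to-centre (5 mm slice + 5 mm gap).
#' @param cylinder_radius_mm phantom radius; default 95 mm (190 mm inner
#'   diameter cylinder, fits the 250 mm field of view).
#' @param signal_level mean in-phantom magnitude signal, arbitrary units.
#' @param noise_sigma Gaussian sigma per quadrature channel (>= 0).
#' @param bias_amplitude peak-to-trough multiplicative nonuniformity of the
#'   in-cylinder signal, in [0, 1): (max - min)/(max + min) of the bias field
#'   over the cylinder equals this value.
#' @param seed RNG seed.
#' @return An object of class `acr_phantom_spec`.
#' @export
acr_phantom_spec <- function(grid_shape = c(256L, 256L, 11L),
                             voxel_size_mm = c(250 / 256, 250 / 256, 10),
                             cylinder_radius_mm = 95,
                             signal_level = 100,
                             noise_sigma = 2,
                             bias_amplitude = 0,
                             seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (signal_level <= 0) stop_mri("signal_level must be positive")
  if (noise_sigma < 0) stop_mri("noise_sigma must be nonnegative")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop_mri("bias_amplitude must lie in [0, 1)")
  fov <- grid_shape[1:2] * voxel_size_mm[1:2]
  if (2 * cylinder_radius_mm > min(fov))
    stop_mri("cylinder (radius %g mm) does not fit the %g x %g mm field of view",
             cylinder_radius_mm, fov[1L], fov[2L])
  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 cylinder_radius_mm = cylinder_radius_mm,
                 signal_level = signal_level, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed)),
            class = "acr_phantom_spec")
}

# Squared in-plane distance (mm^2) of every voxel centre from the grid
# centre, as an nx x ny matrix.
inplane_r2 <- function(grid_shape, voxel_size_mm) {
  cx <- grid_shape[1L] * voxel_size_mm[1L] / 2
  cy <- grid_shape[2L] * voxel_size_mm[2L] / 2
  dx <- axis_coords(grid_shape[1L], voxel_size_mm[1L]) - cx
  dy <- axis_coords(grid_shape[2L], voxel_size_mm[2L]) - cy
  outer(dx^2, dy^2, "+")
}

# Radial bias profile: smoothstep in normalised squared radius, saturating
# at r = sqrt(0.65) * R so that the full bias range is realised well inside
# the uniformity disc (see the methods vignette). Returns multiplier in
# [1 - beta, 1] with beta chosen so the cylinder-wide (max-min)/(max+min)
# equals `amplitude`.
bias_field <- function(r2, radius_mm, amplitude) {
  if (amplitude == 0) return(array(1, dim(r2)))
  beta <- 2 * amplitude / (1 + amplitude)
  t <- pmin(1, (r2 / radius_mm^2) / 0.65)
  1 - beta * (t * t * (3 - 2 * t))
}

#' Generate a synthetic ACR-like phantom image
#'
#' Magnitude image of a uniform cylinder: Rician-distributed inside the
#' cylinder around `signal_level` times a smooth radial bias field, and
#' Rayleigh-distributed (pure noise magnitude) outside. With
#' `noise_sigma = 0` the image is exactly the noiseless signal.
#'
#' @param spec an [acr_phantom_spec()].
#' @return An [image_volume()].
#' @export
gen_acr_phantom <- function(spec) {
  stopifnot(inherits(spec, "acr_phantom_spec"))
  gs <- spec$grid_shape
  r2 <- inplane_r2(gs, spec$voxel_size_mm)
  inside <- r2 <= spec$cylinder_radius_mm^2
  slice_clean <- spec$signal_level *
    bias_field(r2, spec$cylinder_radius_mm, spec$bias_amplitude)
  slice_clean[!inside] <- 0
  clean <- array(slice_clean, dim = gs)   # identical slices along z
  data <- with_seed(spec$seed, {
    array(rician(as.vector(clean), spec$noise_sigma), dim = gs)
  })
  image_volume(data, spec$voxel_size_mm)
}

#' Generate a diffusion-weighted series from a known tensor field
#'
#' Clean signal per voxel and measurement is `s0 * exp(-b g' D g)`; Rician
#' corruption is applied with per-channel sigma `noise_sigma`
#' (`noise_sigma = 0` returns clean signals exactly).
#'
#' @param tensors a [tensor_field()] (ground truth; symmetric PSD per voxel).
#' @param s0 baseline (b = 0) signal, positive scalar.
#' @param scheme a [diffusion_scheme()].
#' @param noise_sigma per-channel noise sigma (>= 0).
#' @param seed RNG seed.
#' @return An [image_volume()] with 4D data (x, y, z, measurement) and a
#'   `scheme` attribute.
#' @export
gen_dwi_series <- function(tensors, s0, scheme, noise_sigma = 0, seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(scheme, "diffusion_scheme"))
  if (s0 <= 0) stop_mri("s0 must be positive")
  if (noise_sigma < 0) stop_mri("noise_sigma must be nonnegative")
  gs <- dim(tensors$coefficients)[1:3]
  n_meas <- length(scheme$bvals)
  # g' D g for all voxels x measurements: coefficients are Dxx Dxy Dxz Dyy
  # Dyz Dzz; quadratic form weights double the off-diagonal terms.
  co <- matrix(tensors$coefficients, ncol = 6L)
  g <- scheme$bvecs
  w <- rbind(g[1L, ]^2, 2 * g[1L, ] * g[2L, ], 2 * g[1L, ] * g[3L, ],
             g[2L, ]^2, 2 * g[2L, ] * g[3L, ], g[3L, ]^2)
  adc <- co %*% w                                   # voxels x measurements
  clean <- s0 * exp(-sweep(adc, 2L, scheme$bvals, "*"))
  noisy <- with_seed(seed, rician(as.vector(clean), noise_sigma))
  out <- image_volume(array(noisy, dim = c(gs, n_meas)),
                      tensors$voxel_size_mm)
  out$scheme <- scheme
  out
}

#' Rater confusion model
#'
#' @param confusion a K x K row-stochastic matrix (row = true label, column
#'   = emitted label) shared by all raters, or a list of one such matrix per
#'   rater.
#' @param n_raters number of raters (>= 0).
#' @param seed RNG seed.
#' @return An object of class `rater_model`.
#' @export
rater_model <- function(confusion, n_raters, seed = 1L) {
  if (is.matrix(confusion)) confusion <- rep(list(confusion), n_raters)
  if (n_raters > 0) {
    stopifnot(length(confusion) == n_raters)
    for (m in confusion) {
      if (!is.matrix(m) || nrow(m) != ncol(m))
        stop_mri("confusion matrices must be square")
      if (any(m < 0) || any(m > 1) || any(abs(rowSums(m) - 1) > 1e-12))
        stop_mri("confusion rows must be probabilities summing to 1")
    }
  }
  structure(list(confusion = confusion, n_raters = as.integer(n_raters),
                 seed = as.integer(seed)), class = "rater_model")
}

#' Generate corrupted rater label maps from a known truth
#'
#' Each rater's label at each voxel is drawn independently from the rater's
#' confusion-matrix row for the true label.
#'
#' @param truth a [label_map()] with labels in `0..K-1`.
#' @param model a [rater_model()] whose matrices are K x K.
#' @return A list of `n_raters` [label_map()] objects.
#' @export
gen_rater_labelmaps <- function(truth, model) {
  stopifnot(inherits(truth, "label_map"), inherits(model, "rater_model"))
  if (model$n_raters == 0L) return(list())
  k <- nrow(model$confusion[[1L]])
  tv <- as.vector(truth$data)
  if (any(tv >= k))
    stop_mri("truth contains label %d outside the %d-label confusion model",
             max(tv), k)
  with_seed(model$seed, {
    lapply(model$confusion, function(cm) {
      # inverse-CDF draw against the confusion row of each voxel's true label
      cum <- t(apply(cm, 1L, cumsum))
      u <- stats::runif(length(tv))
      emitted <- rowSums(u > cum[tv + 1L, , drop = FALSE])
      label_map(array(as.integer(emitted), dim = dim(truth$data)),
                truth$voxel_size_mm, labels = truth$labels)
    })
  })
}

#' Multi-site measurement panel specification
#'
#' Forward model for per-scan measurements across scanners: the value of
#' label j on scanner i, session s is `mu_j * (1 + delta_i + eps_is)`, where
#' `delta_i` is a scanner offset shared by all of that scanner's sessions
#' and `eps_is` is per-session noise, both expressed as fractions. The
#' between-scanner standard deviation is derived from the requested
#' inter-scanner CV by removing the within-scanner component
#' (`sqrt(max(inter^2 - intra^2, 0))`), because the inter-scanner CV as
#' measured over all scans pools both components.
#'
#' @param true_values named numeric vector, true value mu_j per label.
#' @param scanner_ids character vector of scanner identifiers.
#' @param vendor_of named character vector mapping scanner to vendor.
#' @param sessions_per_scanner named integer vector (>= 1 per scanner).
#' @param rescan_fraction proportion of sessions flagged as same-day
#'   rescans, in [0, 1].
#' @param inter_scanner_cv_pct,intra_scanner_cv_pct target CVs in percent.
#' @param seed RNG seed.
#' @return An object of class `multisite_panel_spec`.
#' @export
multisite_panel_spec <- function(true_values, scanner_ids, vendor_of,
                                 sessions_per_scanner,
                                 rescan_fraction = 0,
                                 inter_scanner_cv_pct = 3,
                                 intra_scanner_cv_pct = 1,
                                 seed = 1L) {
  stopifnot(length(true_values) >= 1L, all(true_values > 0),
            !is.null(names(true_values)))
  if (is.null(names(vendor_of)) || !all(scanner_ids %in% names(vendor_of)))
    stop_mri("every scanner needs a vendor")
  if (!all(scanner_ids %in% names(sessions_per_scanner)))
    stop_mri("every scanner needs a session count")
  if (any(sessions_per_scanner < 1L)) stop_mri("sessions_per_scanner >= 1")
  if (inter_scanner_cv_pct < 0 || intra_scanner_cv_pct < 0)
    stop_mri("CV inputs must be nonnegative")
  if (rescan_fraction < 0 || rescan_fraction > 1)
    stop_mri("rescan_fraction must lie in [0, 1]")
  if (intra_scanner_cv_pct > inter_scanner_cv_pct)
    msg("intra CV (%g%%) exceeds inter CV (%g%%): between-scanner variance clamped to 0",
        intra_scanner_cv_pct, inter_scanner_cv_pct)
  structure(list(true_values = true_values,
                 scanner_ids = as.character(scanner_ids),
                 vendor_of = vendor_of,
                 sessions_per_scanner = sessions_per_scanner,
                 rescan_fraction = rescan_fraction,
                 inter_scanner_cv_pct = inter_scanner_cv_pct,
                 intra_scanner_cv_pct = intra_scanner_cv_pct,
                 seed = as.integer(seed)),
            class = "multisite_panel_spec")
}

#' Generate a multi-site measurement panel
#'
#' @param spec a [multisite_panel_spec()].
#' @param metric metric name recorded in the panel (default "volume_mm3").
#' @return A `scan_panel` data frame with columns scanner_id, vendor,
#'   session_id, is_rescan, label, metric, value.
#' @export
gen_multisite_panel <- function(spec, metric = "volume_mm3") {
  stopifnot(inherits(spec, "multisite_panel_spec"))
  sd_intra <- spec$intra_scanner_cv_pct / 100
  sd_inter <- sqrt(max(spec$inter_scanner_cv_pct^2 -
                         spec$intra_scanner_cv_pct^2, 0)) / 100
  labels <- names(spec$true_values)
  with_seed(spec$seed, {
    rows <- lapply(spec$scanner_ids, function(sc) {
      n_sess <- spec$sessions_per_scanner[[sc]]
      delta <- stats::rnorm(1L, 0, sd_inter)
      do.call(rbind, lapply(seq_len(n_sess), function(s) {
        eps <- stats::rnorm(1L, 0, sd_intra)
        value <- spec$true_values * (1 + delta + eps)
        bad <- which(value <= 0)
        while (length(bad)) {          # resample pathological draws
          msg("resampling %d nonpositive values on scanner %s", length(bad), sc)
          value[bad] <- spec$true_values[bad] *
            (1 + delta + stats::rnorm(length(bad), 0, sd_intra))
          bad <- which(value <= 0)
        }
        data.frame(scanner_id = sc, vendor = spec$vendor_of[[sc]],
                   session_id = sprintf("%s_s%02d", sc, s),
                   is_rescan = s > ceiling(n_sess * (1 - spec$rescan_fraction)),
                   label = labels, metric = metric,
                   value = as.numeric(value), row.names = NULL)
      }))
    })
    panel <- do.call(rbind, rows)
    class(panel) <- c("scan_panel", "data.frame")
    panel
  })
}

#' Generate a geometric "brain" label map from ellipsoids
#'
#' Stand-in for an anatomical parcellation: each region is an ellipsoid;
#' a voxel takes the label of the last ellipsoid containing its centre,
#' with 0 as background.
#'
#' @param shape integer triple, grid size.
#' @param regions list of regions, each
#'   `list(center_mm = c(x,y,z), semiaxes_mm = c(a,b,c), label = L)`.
#' @param voxel_size_mm positive triple (mm).
#' @return A [label_map()].
#' @export
gen_geometric_brain <- function(shape, regions, voxel_size_mm = c(1, 1, 1)) {
  shape <- as.integer(shape)
  data <- array(0L, dim = shape)
  if (length(regions) == 0L) return(label_map(data, voxel_size_mm))
  labs <- vapply(regions, function(r) r$label, numeric(1L))
  if (anyDuplicated(labs[labs != 0]))
    msg("regions share a label; overlap resolves to the last one listed")
  xs <- axis_coords(shape[1L], voxel_size_mm[1L])
  ys <- axis_coords(shape[2L], voxel_size_mm[2L])
  zs <- axis_coords(shape[3L], voxel_size_mm[3L])
  extent <- shape * voxel_size_mm
  for (r in regions) {
    if (any(r$center_mm - r$semiaxes_mm < 0) ||
        any(r$center_mm + r$semiaxes_mm > extent))
      stop_mri("ellipsoid with label %d extends outside the grid", r$label)
    u <- outer(((xs - r$center_mm[1L]) / r$semiaxes_mm[1L])^2,
               ((ys - r$center_mm[2L]) / r$semiaxes_mm[2L])^2, "+")
    for (k in seq_along(zs)) {
      inside <- u + ((zs[k] - r$center_mm[3L]) / r$semiaxes_mm[3L])^2 <= 1
      data[, , k][inside] <- as.integer(r$label)
    }
  }
  label_map(data, voxel_size_mm)
}
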