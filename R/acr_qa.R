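# ACR-phantom quality assurance: ROI construction, SNR and percent integral
# uniformity. ROI placement is deterministic geometry concentric with the
# grid centre (the phantom generator centres the cylinder; a translation
# aligner is provided for off-centre scans).

#' ACR ROI geometry configuration
#'
#' Slice indices are 1-based, following the ACR accreditation convention
#' ("slices 6 through 10").
#'
#' @param signal_area_mm2 per-slice area of the central high-signal ROI.
#' @param signal_slices slices carrying the signal ROI.
#' @param background_area_mm2 per-slice area of the background (air) ROI.
#' @param background_slices slices carrying the background ROI.
#' @param uniformity_area_cm2 area of the large uniformity disc (cm^2);
#'   default 200 cm^2, standard ACR practice for the uniformity test.
#' @param uniformity_slice slice carrying the uniformity ROI.
#' @param cylinder_radius_mm phantom cylinder radius.
#' @return A list of class `acr_roi_config`.
#' @export
acr_roi_config <- function(signal_area_mm2 = 400,
                           signal_slices = 6:10,
                           background_area_mm2 = 182,
                           background_slices = 2:10,
                           uniformity_area_cm2 = 200,
                           uniformity_slice = 7L,
                           cylinder_radius_mm = 95) {
  stopifnot(signal_area_mm2 >= 0, background_area_mm2 >= 0,
            uniformity_area_cm2 >= 0, cylinder_radius_mm > 0)
  structure(list(signal_area_mm2 = signal_area_mm2,
                 signal_slices = as.integer(signal_slices),
                 background_area_mm2 = background_area_mm2,
                 background_slices = as.integer(background_slices),
                 uniformity_area_cm2 = uniformity_area_cm2,
                 uniformity_slice = as.integer(uniformity_slice),
                 cylinder_radius_mm = cylinder_radius_mm),
            class = "acr_roi_config")
}

# Logical in-plane disc of ~`n_vox` voxels nearest (by r^2) to a centre,
# restricted to `candidates`.
disc_mask <- function(r2, n_vox, candidates = NULL) {
  m <- matrix(FALSE, nrow(r2), ncol(r2))
  if (n_vox <= 0L) return(m)
  idx <- if (is.null(candidates)) seq_along(r2) else which(candidates)
  if (length(idx) < n_vox)
    stop_mri("grid too small for requested ROI area (%d of %d voxels available)",
             length(idx), n_vox)
  m[idx[order(r2[idx])[seq_len(n_vox)]]] <- TRUE
  m
}

#' Build the ACR signal / background / uniformity ROI masks
#'
#' The signal ROI is a centred disc on the configured slices; the
#' background ROI is a disc placed fully outside the cylinder (offset along
#' +x, midway between cylinder edge and field-of-view edge); the uniformity
#' ROI is a large centred region on its slice, built from the voxels
#' nearest the centre that are not already in the signal ROI, so the three
#' masks are pairwise disjoint. Per-slice areas match the configured
#' targets to within one voxel area.
#'
#' @param image_shape integer triple (expects the 11-slice ACR geometry).
#' @param voxel_size_mm positive triple (mm).
#' @param config an [acr_roi_config()].
#' @return A list of class `acr_roi_set` with logical arrays `signal_mask`,
#'   `background_mask`, `uniformity_mask`.
#' @export
build_acr_rois <- function(image_shape,
                           voxel_size_mm = c(250 / 256, 250 / 256, 10),
                           config = acr_roi_config()) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 3L, inherits(config, "acr_roi_config"))
  if (max(config$signal_slices, config$background_slices,
          config$uniformity_slice) > image_shape[3L])
    stop_mri("configured slices exceed the %d available", image_shape[3L])
  vox_area <- prod(voxel_size_mm[1:2])
  r2 <- inplane_r2(image_shape, voxel_size_mm)
  R <- config$cylinder_radius_mm
  inside <- r2 <= R^2

  n_sig <- as.integer(round(config$signal_area_mm2 / vox_area))
  sig2d <- disc_mask(r2, n_sig, candidates = inside)

  # background: disc centred midway between cylinder edge and FOV edge,
  # restricted to voxels strictly outside the cylinder (2-voxel buffer)
  fov_half <- min(image_shape[1:2] * voxel_size_mm[1:2]) / 2
  if (fov_half <= R) stop_mri("no background region outside the cylinder")
  bg_center_x <- image_shape[1L] * voxel_size_mm[1L] / 2 + (R + fov_half) / 2
  dx <- axis_coords(image_shape[1L], voxel_size_mm[1L]) - bg_center_x
  dy <- axis_coords(image_shape[2L], voxel_size_mm[2L]) -
    image_shape[2L] * voxel_size_mm[2L] / 2
  bg_r2 <- outer(dx^2, dy^2, "+")
  buffer <- 2 * max(voxel_size_mm[1:2])
  outside <- r2 > (R + buffer)^2
  n_bg <- as.integer(round(config$background_area_mm2 / vox_area))
  bg2d <- disc_mask(bg_r2, n_bg, candidates = outside)

  n_uni <- as.integer(round(config$uniformity_area_cm2 * 100 / vox_area))
  uni2d <- disc_mask(r2, n_uni, candidates = inside & !sig2d)

  blank <- array(FALSE, dim = image_shape)
  signal_mask <- blank
  signal_mask[, , config$signal_slices] <- sig2d
  background_mask <- blank
  background_mask[, , config$background_slices] <- bg2d
  uniformity_mask <- blank
  uniformity_mask[, , config$uniformity_slice] <- uni2d
  structure(list(signal_mask = signal_mask,
                 background_mask = background_mask,
                 uniformity_mask = uniformity_mask,
                 voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "acr_roi_set")
}

#' Signal-to-noise ratio of a phantom scan
#'
#' `mean(signal ROI) / sd(background ROI)` with the sample SD; the printed
#' magnitude-image formula is implemented literally, with no Rayleigh
#' correction of the background SD.
#'
#' @param image an [image_volume()].
#' @param rois an [acr_roi_set()] on the same grid.
#' @return SNR, dimensionless.
#' @export
compute_snr <- function(image, rois) {
  stopifnot(inherits(image, "image_volume"), inherits(rois, "acr_roi_set"))
  bg <- image$data[rois$background_mask]
  if (length(bg) < 2L) stop_mri("background ROI needs >= 2 voxels")
  sd_bg <- stats::sd(bg)
  if (sd_bg == 0) stop_mri("degenerate background: zero SD")
  mean(image$data[rois$signal_mask]) / sd_bg
}

# Nearest-rank percentile: the ceil(p * n)-th smallest value.
nearest_rank <- function(sorted_vals, p) {
  sorted_vals[max(1L, ceiling(p * length(sorted_vals)))]
}

#' Percent integral uniformity of a phantom scan
#'
#' Orders the uniformity-ROI intensities and takes the nearest-rank 5th
#' (low) and 95th (high) percentile voxels:
#' `IU = 100 * (1 - (high - low) / (high + low))`.
#'
#' @param image an [image_volume()].
#' @param rois an [acr_roi_set()].
#' @return IU in percent (<= 100; 100 means perfectly uniform).
#' @export
compute_iu <- function(image, rois) {
  stopifnot(inherits(image, "image_volume"), inherits(rois, "acr_roi_set"))
  vals <- sort(image$data[rois$uniformity_mask])
  if (length(vals) == 0L) stop_mri("empty uniformity ROI")
  lo <- nearest_rank(vals, 0.05)
  hi <- nearest_rank(vals, 0.95)
  if (hi + lo == 0) stop_mri("degenerate intensities: high + low = 0")
  100 * (1 - (hi - lo) / (hi + lo))
}

# Otsu's threshold on a 256-bin histogram; used only to find the phantom
# foreground for centre-of-mass alignment. Returns the threshold and the
# separability (between-class / total variance): near 1 for a bright object
# on dark background, markedly lower for unimodal pure noise.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(list(threshold = Inf, separability = 0))
  bins <- pmin(256L, 1L + floor((x - rng[1L]) / diff(rng) * 256))
  p <- tabulate(bins, 256L) / length(x)
  i <- seq_len(256L)
  omega <- cumsum(p)
  mu <- cumsum(p * i)
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  total_var <- sum(p * i^2) - mu_t^2
  list(threshold = rng[1L] + k / 256 * diff(rng),
       separability = if (total_var > 0) sigma_b[k] / total_var else 0)
}

#' Integer-voxel centre-of-mass alignment
#'
#' Plumbing stand-in for full rigid registration: translates `image` by the
#' integer voxel shift that aligns its foreground (above an Otsu-style
#' threshold) centre of mass with the reference's. No rotation, no
#' interpolation; vacated voxels are zero-filled.
#'
#' @param image,reference [image_volume()] objects on the same grid.
#' @return The shifted `image_volume`, with the applied shift in element
#'   `shift` (voxels).
#' @export
align_phantom <- function(image, reference) {
  stopifnot(inherits(image, "image_volume"),
            inherits(reference, "image_volume"))
  if (!identical(dim(image$data), dim(reference$data)))
    stop_mri("grid shape mismatch")
  com <- function(vol) {
    ot <- otsu_threshold(as.vector(vol$data))
    # Otsu on pure noise happily splits the noise distribution; demand a
    # genuinely bimodal image before trusting the foreground
    if (!is.finite(ot$threshold) || ot$separability < 0.85)
      stop_mri("empty foreground: no phantom detected (separability %.2f)",
               ot$separability)
    fg <- vol$data > ot$threshold
    w <- which(fg, arr.ind = TRUE)
    colMeans(w)
  }
  shift <- round(com(reference) - com(image))
  out <- array(0, dim = dim(image$data))
  d <- dim(image$data)
  src <- lapply(1:3, function(a) {
    s <- seq_len(d[a]) - shift[a]
    s
  })
  ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
  out[ok[[1L]], ok[[2L]], ok[[3L]]] <-
    image$data[src[[1L]][ok[[1L]]], src[[2L]][ok[[2L]]], src[[3L]][ok[[3L]]]]
  res <- image_volume(out, image$voxel_size_mm)
  res$shift <- as.integer(shift)
  res
}

#' ACR QA result for one scan
#'
#' @param image an [image_volume()].
#' @param rois an [acr_roi_set()]; default built for the image grid.
#' @param scanner_id,scan_date metadata carried into the result.
#' @return A one-row data frame: scanner_id, scan_date, snr, iu_pct.
#' @export
acr_qa_result <- function(image, rois = NULL, scanner_id = NA_character_,
                          scan_date = NA_character_) {
  if (is.null(rois))
    rois <- build_acr_rois(dim(image$data), image$voxel_size_mm)
  data.frame(scanner_id = scanner_id, scan_date = scan_date,
             snr = compute_snr(image, rois),
             iu_pct = compute_iu(image, rois))
}
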