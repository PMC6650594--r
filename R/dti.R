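# Single-tensor diffusion model: log-linear (weighted) least squares with
# IRLS Huber robustification, plus the FA/MD scalar maps.

#' Per-voxel diffusion tensor field
#'
#' @param coefficients numeric array (x, y, z, 6): unique tensor
#'   coefficients in the order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param voxel_size_mm positive triple (mm).
#' @param s0 optional 3D array of fitted baseline signals.
#' @param eigenvalues optional (x, y, z, 3) array, sorted descending.
#' @param n_clamped count of negative eigenvalues clamped to zero.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(coefficients, voxel_size_mm = c(1, 1, 1), s0 = NULL,
                         eigenvalues = NULL, n_clamped = 0L) {
  stopifnot(is.array(coefficients), length(dim(coefficients)) == 4L,
            dim(coefficients)[4L] == 6L)
  structure(list(coefficients = coefficients,
                 voxel_size_mm = as.numeric(voxel_size_mm), s0 = s0,
                 eigenvalues = eigenvalues, n_clamped = n_clamped),
            class = "tensor_field")
}

#' Build a spatially constant tensor field
#'
#' Convenience for simulations: replicate one 3 x 3 symmetric tensor over a
#' grid.
#'
#' @param D symmetric 3 x 3 matrix (mm^2/s).
#' @param shape integer triple.
#' @param voxel_size_mm positive triple (mm).
#' @return A [tensor_field()].
#' @export
uniform_tensor_field <- function(D, shape, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.matrix(D), all(dim(D) == 3L), max(abs(D - t(D))) < 1e-12)
  v <- c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  co <- aperm(array(v, dim = c(6L, shape)), c(2L, 3L, 4L, 1L))
  tensor_field(co, voxel_size_mm)
}

# Design matrix of the log-linearised model
#   ln S_k = ln S0 - b_k g_k' D g_k
# for parameters (ln S0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
dti_design <- function(scheme) {
  g <- scheme$bvecs
  b <- scheme$bvals
  X <- cbind(1,
             -b * g[1L, ]^2, -2 * b * g[1L, ] * g[2L, ],
             -2 * b * g[1L, ] * g[3L, ], -b * g[2L, ]^2,
             -2 * b * g[2L, ] * g[3L, ], -b * g[3L, ]^2)
  if (qr(X)$rank < 7L)
    stop_mri("scheme not well-posed: design matrix rank %d < 7", qr(X)$rank)
  X
}

# One voxel's fit on log signals. The plain path is weighted LS with
# weights s^2, the first-order variance correction for log-transformed
# data. The robust path starts from ordinary LS (so a gross outlier keeps a
# visible residual instead of buying leverage through its own weight) and
# iterates with weights = fitted-signal^2 times Huber weights at threshold
# c * MAD(residuals), c = 1.345. Returns c(lnS0, D[6]).
fit_voxel <- function(X, log_s, base_w, robust = TRUE,
                      max_iter = 50L, tol = 1e-10, huber_c = 1.345) {
  wls <- function(w) qr.coef(qr(X * sqrt(w)), log_s * sqrt(w))
  if (!robust) return(wls(base_w))
  beta <- qr.coef(qr(X), log_s)
  for (it in seq_len(max_iter)) {
    fitted <- as.vector(X %*% beta)
    r <- log_s - fitted
    s <- stats::mad(r)
    if (!is.finite(s) || s < 1e-12) break      # exact fit: nothing to reweight
    thr <- huber_c * s
    hub <- pmin(1, thr / pmax(abs(r), 1e-300))
    beta_new <- wls(exp(2 * pmin(fitted, 709 / 2)) * hub)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Fit a diffusion tensor in every masked voxel
#'
#' Solves the log-linearised single-tensor model by weighted least squares
#' (weights = squared signal) with iteratively reweighted robust fitting:
#' Huber weights at threshold `1.345 * MAD` of the working residuals, at
#' most `max_iter` iterations, stopping when the largest parameter change
#' falls below `tol`. Signals are floored at `1e-6 * max(signal)` before
#' the log. Eigenvalues are computed per voxel, sorted descending, and
#' negative values are clamped to zero with the clamp count recorded.
#'
#' @param dwi 4D [image_volume()] with a `scheme` element, as produced by
#'   [gen_dwi_series()], or any 4D volume if `scheme` is supplied.
#' @param mask 3D logical array (or `label_map` of 0/1); voxels outside are
#'   zero-filled. Default: all voxels.
#' @param scheme a [diffusion_scheme()]; defaults to `dwi$scheme`.
#' @param robust logical; `FALSE` gives the plain weighted LS fit (exposed
#'   for oracle comparisons).
#' @param max_iter,tol IRLS controls.
#' @return A [tensor_field()] with `s0`, `eigenvalues` and `n_clamped`.
#' @export
fit_tensor_field <- function(dwi, mask = NULL, scheme = dwi$scheme,
                             robust = TRUE, max_iter = 50L, tol = 1e-10) {
  stopifnot(inherits(dwi, "image_volume"), length(dim(dwi$data)) == 4L,
            inherits(scheme, "diffusion_scheme"))
  gs <- dim(dwi$data)[1:3]
  n_meas <- dim(dwi$data)[4L]
  if (n_meas != length(scheme$bvals))
    stop_mri("series has %d volumes but scheme has %d entries",
             n_meas, length(scheme$bvals))
  if (is.null(mask)) mask <- array(TRUE, dim = gs)
  if (inherits(mask, "image_volume")) mask <- mask$data != 0
  stopifnot(identical(dim(mask), gs))
  X <- dti_design(scheme)
  sig <- matrix(dwi$data, ncol = n_meas)      # voxels x measurements
  floor_val <- 1e-6 * max(sig)
  if (floor_val <= 0) stop_mri("all-zero series")
  idx <- which(as.vector(mask))
  co <- matrix(0, nrow = prod(gs), ncol = 6L)
  s0 <- numeric(prod(gs))
  ev <- matrix(0, nrow = prod(gs), ncol = 3L)
  n_clamped <- 0L
  n_skipped <- 0L
  for (v in idx) {
    s <- sig[v, ]
    if (all(s <= 0)) {
      n_skipped <- n_skipped + 1L
      next
    }
    s <- pmax(s, floor_val)
    beta <- fit_voxel(X, log(s), base_w = s^2, robust = robust,
                      max_iter = max_iter, tol = tol)
    co[v, ] <- beta[-1L]
    s0[v] <- exp(beta[1L])
    D <- matrix(beta[c(2, 3, 4, 3, 5, 6, 4, 6, 7)], 3L, 3L)
    lam <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
                decreasing = TRUE)
    n_clamped <- n_clamped + sum(lam < 0)
    ev[v, ] <- pmax(lam, 0)
  }
  if (n_skipped > 0L) msg("skipped %d all-zero voxels", n_skipped)
  if (n_clamped > 0L) msg("clamped %d negative eigenvalues to zero", n_clamped)
  tensor_field(array(co, dim = c(gs, 6L)), dwi$voxel_size_mm,
               s0 = array(s0, dim = gs),
               eigenvalues = array(ev, dim = c(gs, 3L)),
               n_clamped = n_clamped)
}

#' Mean diffusivity from eigenvalues
#'
#' `MD = (lambda1 + lambda2 + lambda3) / 3`, in mm^2/s.
#'
#' @param eigenvalues numeric triple, or an (x, y, z, 3) array, or a
#'   [tensor_field()].
#' @return Scalar, or a 3D array / [image_volume()] matching the input.
#' @export
compute_md <- function(eigenvalues) {
  if (inherits(eigenvalues, "tensor_field"))
    return(image_volume(compute_md(eigenvalues$eigenvalues),
                        eigenvalues$voxel_size_mm))
  if (is.array(eigenvalues) && length(dim(eigenvalues)) == 4L)
    return(apply(eigenvalues, 1:3, mean))
  stopifnot(length(eigenvalues) == 3L, all(is.finite(eigenvalues)))
  mean(eigenvalues)
}

fa_from_triple <- function(lam) {
  ss <- sum(lam^2)
  if (ss == 0) return(0)
  lbar <- mean(lam)
  sqrt(1.5 * sum((lam - lbar)^2) / ss)
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2 * sum((lambda_i - mean)^2) / sum(lambda_i^2))`, the
#' standard normalised eigenvalue dispersion: 0 for isotropic tensors, 1 in
#' the single-nonzero-eigenvalue limit. An all-zero triple returns 0 by
#' convention.
#'
#' @inheritParams compute_md
#' @return Scalar in [0, 1], or a 3D array / [image_volume()].
#' @export
compute_fa <- function(eigenvalues) {
  if (inherits(eigenvalues, "tensor_field"))
    return(image_volume(compute_fa(eigenvalues$eigenvalues),
                        eigenvalues$voxel_size_mm))
  if (is.array(eigenvalues) && length(dim(eigenvalues)) == 4L)
    return(apply(eigenvalues, 1:3, fa_from_triple))
  stopifnot(length(eigenvalues) == 3L, all(is.finite(eigenvalues)))
  fa_from_triple(eigenvalues)
}
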