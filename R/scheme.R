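#' Diffusion gradient scheme
#'
#' Pairs of (b-value, unit gradient direction). b is in s/mm^2; directions
#' must be unit norm for b > 0 and may be zero vectors at b = 0.
#'
#' @param bvals numeric vector of b-values (s/mm^2), length N.
#' @param bvecs 3 x N numeric matrix of gradient directions (FSL layout).
#' @return An object of class `diffusion_scheme` with elements `bvals` and
#'   `bvecs` (directions renormalised to unit length where b > 0).
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L || ncol(bvecs) != length(bvals))
    stop_mri("bvecs must be 3 x N with N = length(bvals)")
  if (any(bvals < 0)) stop_mri("b-values must be nonnegative")
  nrm <- sqrt(colSums(bvecs^2))
  dwi <- bvals > 0
  if (any(dwi & abs(nrm - 1) > 1e-3))
    stop_mri("non-unit gradient direction at b > 0 (|g| = %.4f)",
             nrm[which(dwi & abs(nrm - 1) > 1e-3)[1L]])
  bvecs[, dwi] <- sweep(bvecs[, dwi, drop = FALSE], 2L, nrm[dwi], "/")
  structure(list(bvals = bvals, bvecs = bvecs), class = "diffusion_scheme")
}

#' @export
print.diffusion_scheme <- function(x, ...) {
  cat(sprintf("<diffusion_scheme> %d measurements (%d b=0); b in [%g, %g]\n",
              length(x$bvals), sum(x$bvals == 0), min(x$bvals), max(x$bvals)))
  invisible(x)
}

# Deterministic, well-spread unit directions: golden-angle spiral on the
# upper hemisphere (antipodal symmetry makes the hemisphere sufficient for
# diffusion encoding).
spiral_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                              # uniform in z over (0, 1)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(1 - z^2)
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Default diffusion protocol
#'
#' b = 0 baselines followed by a single high-angular-resolution shell. The
#' default emulates a 5 x b=0 + 30 x b=1000 s/mm^2 clinical protocol; a
#' 6-baseline variant is available through `n_b0`.
#'
#' @param n_b0 number of b = 0 measurements (default 5).
#' @param n_dir number of unique gradient directions on the shell.
#' @param b shell b-value in s/mm^2.
#' @return A [diffusion_scheme()].
#' @export
default_scheme <- function(n_b0 = 5L, n_dir = 30L, b = 1000) {
  bvals <- c(rep(0, n_b0), rep(b, n_dir))
  bvecs <- cbind(matrix(0, 3L, n_b0), spiral_directions(n_dir))
  diffusion_scheme(bvals, bvecs)
}

#' Read an FSL-style bval/bvec pair
#'
#' @param bval_path whitespace-separated b-values, one row.
#' @param bvec_path whitespace-separated gradient components, three rows.
#' @return A [diffusion_scheme()].
#' @export
read_scheme <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- readLines(bvec_path)
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != 3L)
    stop_mri("bvec file must have 3 rows, got %d", length(rows))
  vals <- lapply(rows, function(r) scan(text = r, quiet = TRUE))
  if (any(lengths(vals) != length(bvals)))
    stop_mri("bval/bvec count mismatch: %d b-values vs %s direction columns",
             length(bvals), paste(unique(lengths(vals)), collapse = "/"))
  diffusion_scheme(bvals, do.call(rbind, vals))
}

#' Write an FSL-style bval/bvec pair
#'
#' @param scheme a [diffusion_scheme()].
#' @param bval_path,bvec_path output paths.
#' @return Invisibly, `c(bval_path, bvec_path)`.
#' @export
write_scheme <- function(scheme, bval_path, bvec_path) {
  stopifnot(inherits(scheme, "diffusion_scheme"))
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(scheme$bvecs, 1L, function(r)
    paste(format(r, trim = TRUE, digits = 15), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}
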