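# Multilabel STAPLE: EM estimation of a consensus segmentation and per-rater
# confusion (performance) matrices from candidate segmentations, with
# majority vote as baseline/initialiser.

#' Majority-vote label fusion
#'
#' Per-voxel modal label across raters; ties break toward the smallest
#' label index.
#'
#' @param raters nonempty list of [label_map()] objects on identical grids.
#' @return A [label_map()].
#' @export
fuse_majority <- function(raters) {
  if (length(raters) == 0L) stop_mri("empty rater list")
  ref <- raters[[1L]]
  for (r in raters) if (!same_grid(r, ref)) stop_mri("rater grid mismatch")
  D <- vapply(raters, function(r) as.vector(r$data),
              integer(length(ref$data)))
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)   # single-voxel grids
  k <- max(D) + 1L
  counts <- matrix(0L, nrow(D), k)
  for (j in seq_len(ncol(D)))
    counts[cbind(seq_len(nrow(D)), D[, j] + 1L)] <-
      counts[cbind(seq_len(nrow(D)), D[, j] + 1L)] + 1L
  mode_lab <- max.col(counts, ties.method = "first") - 1L
  label_map(array(mode_lab, dim = dim(ref$data)), ref$voxel_size_mm,
            labels = ref$labels)
}

#' STAPLE consensus label fusion
#'
#' Expectation-maximisation on the multilabel rater model: each rater r has
#' a K x K performance matrix `theta_r[l, m]` = P(rater emits m | true label
#' l). The E-step computes the per-voxel posterior over true labels,
#' `W(v, l) proportional to prior_l * prod_r theta_r[l, d_r(v)]`; the M-step
#' re-estimates each `theta_r[l, m]` as the posterior-weighted frequency of
#' emissions m under true label l. Initialisation: diagonal 0.99 with the
#' remainder spread uniformly off-diagonal; the prior defaults to the
#' raters' pooled label frequencies. Iteration stops when the largest change
#' in any theta entry drops below `tol`, or at `max_iter`.
#'
#' @param raters nonempty list of [label_map()] on identical grids, labels
#'   in `0..n_labels-1`.
#' @param n_labels number of labels K (>= 2); default `max label + 1`.
#' @param prior optional length-K probability vector over true labels.
#' @param max_iter,tol convergence controls.
#' @param exclude_unanimous_background drop voxels where every rater emits
#'   label 0 from the E/M computation (they are assigned label 0 directly).
#'   Default `FALSE`: all voxels participate.
#' @return A `fusion_result` list: `consensus` ([label_map()]),
#'   `rater_performance` (list of K x K matrices), `posterior` (voxels x K
#'   matrix), `prior`, `log_likelihood` (per-iteration trace),
#'   `n_iterations`, `converged`.
#' @export
fuse_staple <- function(raters, n_labels = NULL, prior = NULL,
                        max_iter = 100L, tol = 1e-6,
                        exclude_unanimous_background = FALSE) {
  if (length(raters) == 0L) stop_mri("empty rater list")
  ref <- raters[[1L]]
  for (r in raters) if (!same_grid(r, ref)) stop_mri("rater grid mismatch")
  D <- vapply(raters, function(r) as.vector(r$data),
              integer(length(ref$data)))
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  n_r <- ncol(D)
  if (is.null(n_labels)) n_labels <- max(D) + 1L
  k <- as.integer(n_labels)
  if (k < 2L) stop_mri("need at least 2 labels")
  if (max(D) >= k) stop_mri("rater label %d outside 0..%d", max(D), k - 1L)

  active <- rep(TRUE, nrow(D))
  if (exclude_unanimous_background)
    active <- rowSums(D != 0L) > 0L
  Da <- D[active, , drop = FALSE]
  n_v <- nrow(Da)

  if (is.null(prior)) {
    prior <- tabulate(as.vector(Da) + 1L, nbins = k) / length(Da)
  } else {
    stopifnot(length(prior) == k, all(prior >= 0), sum(prior) > 0)
    prior <- prior / sum(prior)
  }

  theta <- rep(list(matrix((1 - 0.99) / (k - 1), k, k) +
                      diag(0.99 - (1 - 0.99) / (k - 1), k)), n_r)
  # indicator matrices of each rater's decisions, voxels x K
  ind <- lapply(seq_len(n_r), function(r) {
    m <- matrix(0, n_v, k)
    m[cbind(seq_len(n_v), Da[, r] + 1L)] <- 1
    m
  })

  loglik <- numeric(0L)
  converged <- FALSE
  it <- 0L
  W <- NULL
  log_prior <- log(pmax(prior, 1e-300))
  while (it < max_iter) {
    it <- it + 1L
    # E-step in log space: logW[v, l] = log prior_l + sum_r log theta_r[l, d]
    logW <- matrix(log_prior, n_v, k, byrow = TRUE)
    for (r in seq_len(n_r))
      logW <- logW + log(pmax(t(theta[[r]])[Da[, r] + 1L, , drop = FALSE],
                              1e-300))
    mx <- apply(logW, 1L, max)
    Wu <- exp(logW - mx)
    rs <- rowSums(Wu)
    loglik <- c(loglik, sum(mx + log(rs)))
    W <- Wu / rs
    # M-step
    delta <- 0
    for (r in seq_len(n_r)) {
      num <- crossprod(W, ind[[r]])                 # K x K
      th_new <- num / pmax(rowSums(num), 1e-300)
      delta <- max(delta, max(abs(th_new - theta[[r]])))
      theta[[r]] <- th_new
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }

  cons_active <- max.col(W, ties.method = "first") - 1L
  consensus <- integer(nrow(D))
  consensus[active] <- cons_active
  post <- matrix(0, nrow(D), k)
  post[, 1L] <- 1                                    # excluded: background
  post[active, ] <- W
  structure(list(
    consensus = label_map(array(consensus, dim = dim(ref$data)),
                          ref$voxel_size_mm, labels = ref$labels),
    rater_performance = theta,
    posterior = post,
    prior = prior,
    log_likelihood = loglik,
    n_iterations = it,
    converged = converged
  ), class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %d raters, %d labels, %d EM iterations (%s)\n",
              length(x$rater_performance), ncol(x$posterior),
              x$n_iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}
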