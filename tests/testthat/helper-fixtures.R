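# Shared fixtures, all built in code.

# Rayleigh SD of |N(0,s) + i N(0,s)|: s * sqrt((4 - pi) / 2)
rayleigh_sd <- function(sigma) sigma * sqrt((4 - pi) / 2)

# Small multi-scanner panel spec with uncorrelated scanner/session effects.
toy_panel_spec <- function(inter = 3, intra = 1, n_scanners = 7L,
                           n_sessions = 20L, seed = 1L,
                           labels = c(a = 100, b = 5000)) {
  ids <- LETTERS[seq_len(n_scanners)]
  multisite_panel_spec(
    true_values = labels,
    scanner_ids = ids,
    vendor_of = stats::setNames(rep(c("V1", "V2"), length.out = n_scanners),
                                ids),
    sessions_per_scanner = stats::setNames(rep(n_sessions, n_scanners), ids),
    inter_scanner_cv_pct = inter, intra_scanner_cv_pct = intra,
    seed = seed)
}

# A 4 x 4 x 1 three-rater fixture in which exactly two raters agree at
# every voxel.
toy_raters_4x4 <- function() {
  truth <- c(0, 0, 1, 1,
             0, 1, 1, 0,
             1, 1, 0, 0,
             1, 0, 0, 1)
  flip <- function(v, at) { v[at] <- 1 - v[at]; v }
  r1 <- flip(truth, c(1, 6))
  r2 <- flip(truth, c(11, 16))
  r3 <- flip(truth, c(4, 9))
  lapply(list(r1, r2, r3), function(v)
    label_map(array(as.integer(v), c(4, 4, 1))))
}

# Brute-force multilabel STAPLE EM, written with explicit per-voxel loops
# and no shared code with the package implementation. Same conventions:
# diagonal-0.99 initialisation, pooled-frequency prior.
staple_oracle <- function(decision_mat, k, max_iter = 100, tol = 1e-6) {
  n_v <- nrow(decision_mat)
  n_r <- ncol(decision_mat)
  prior <- numeric(k)
  for (l in 0:(k - 1)) prior[l + 1] <- mean(decision_mat == l)
  theta <- lapply(seq_len(n_r), function(r) {
    m <- matrix((1 - 0.99) / (k - 1), k, k)
    diag(m) <- 0.99
    m
  })
  W <- matrix(0, n_v, k)
  for (iter in seq_len(max_iter)) {
    for (v in seq_len(n_v)) {
      for (l in seq_len(k)) {
        p <- prior[l]
        for (r in seq_len(n_r)) p <- p * theta[[r]][l, decision_mat[v, r] + 1]
        W[v, l] <- p
      }
      W[v, ] <- W[v, ] / sum(W[v, ])
    }
    delta <- 0
    for (r in seq_len(n_r)) {
      th <- matrix(0, k, k)
      for (l in seq_len(k)) {
        for (m in seq_len(k)) {
          num <- 0
          for (v in seq_len(n_v))
            if (decision_mat[v, r] == m - 1) num <- num + W[v, l]
          th[l, m] <- num
        }
        th[l, ] <- th[l, ] / sum(th[l, ])
      }
      delta <- max(delta, max(abs(th - theta[[r]])))
      theta[[r]] <- th
    }
    if (delta < tol) break
  }
  list(posterior = W, theta = theta,
       consensus = apply(W, 1, which.max) - 1)
}
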