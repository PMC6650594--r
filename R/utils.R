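#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state on exit.
# All generators route their randomness through this so that they are pure
# functions of their arguments (seed included).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample magnitude of a complex Gaussian with real mean `s` and per-channel
# sigma: Rician in signal, Rayleigh where s = 0. Vectorised over `s`.
rician <- function(s, sigma, n = length(s)) {
  if (sigma == 0) return(abs(s))
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

stop_mri <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

msg <- function(fmt, ...) message(sprintf("[mrirepro] %s", sprintf(fmt, ...)))
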