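# Internal numeric helpers shared across modules.

# Gaussian smoothing with edge renormalisation (kernel truncated at +/- 4 SD).
# Works on a vector or column-wise on a matrix; sd_samples <= 0 is a no-op.
gaussian_smooth <- function(x, sd_samples = 2) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], half), v, rep(v[n], half))
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(half + 1):(half + n)])
  }
  if (is.matrix(x)) apply(x, 2, smooth_vec) else smooth_vec(x)
}

# Local maxima with topographic prominence; thin wrapper over the C++ core.
find_peaks <- function(x, min_prominence = 0) {
  res <- find_peaks_cpp(as.numeric(x), min_prominence)
  data.frame(index = res$index, prominence = res$prominence)
}

# Derive a 32-bit sub-seed from a base seed and a string/int tag,
# deterministic across platforms.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(paste0(tag)) * (seq_along(utf8ToInt(paste0(tag))) %% 31 + 1))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
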