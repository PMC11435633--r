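#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream derivation: mixes a base seed with stream indices
# so that regenerating participant p / interval i in any order gives the same
# draws. Kept below 2^31 - 1 so it is always a valid set.seed() argument.
derive_seed <- function(base, ...) {
  idx <- c(...)
  m <- 2147483629
  h <- as.numeric(base) %% m
  for (v in idx) {
    h <- (h * 48271 + as.numeric(v) * 16807 + 11) %% m
  }
  as.integer(h)
}

# Run an expression under a local RNG state so library code never disturbs
# the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Hann window, 50% overlap) of a single
#' channel. Used by the session generator's self-checks and the GAN's
#' spectral-similarity diagnostics.
#'
#' @param x numeric vector, one channel.
#' @param fs sampling frequency in Hz.
#' @param nperseg segment length in samples (default `min(256, length(x))`).
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(256L, length(x))) {
  x <- as.numeric(x)
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  if (nperseg < 8L) stop_config("welch_psd: segment length %d too short", nperseg)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nperseg) - 1L) / (nperseg - 1L))  # Hann
  u <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)] * w
    sp <- abs(stats::fft(seg))^2
    acc <- acc + sp[seq_len(nf)]
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double interior bins
  if (nf > 2L) psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

#' Band power of a signal
#'
#' Integrates the Welch PSD over `[lo, hi)` Hz.
#'
#' @param x numeric vector.
#' @param fs sampling frequency in Hz.
#' @param band numeric length-2, band edges in Hz.
#' @param nperseg Welch segment length.
#' @return scalar band power.
#' @export
band_power <- function(x, fs, band, nperseg = min(256L, length(x))) {
  p <- welch_psd(x, fs, nperseg)
  sel <- p$freq >= band[1] & p$freq < band[2]
  df <- fs / nperseg
  sum(p$psd[sel]) * df
}

#' Canonical EEG frequency bands (Hz)
#'
#' theta 4-7, alpha 8-13, beta2 18-22, beta3 22-30, gamma 30-45.
#' @export
eeg_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 13), beta2 = c(18, 22),
       beta3 = c(22, 30), gamma = c(30, 45))
}
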