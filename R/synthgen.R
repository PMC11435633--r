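# Synthetic music-stimulus EEG sessions.
#
# The recordings this package was designed around are private, so the
# generator emulates the experimental protocol instead: 10 one-minute song
# presentations (5 per valence) separated by 10-s silences, recorded at
# 500 Hz on C3/C4/Pz, with class-dependent band-power signatures (frontal
# alpha asymmetry, beta-2/beta-3/gamma shifts).

#' Experimental protocol configuration
#'
#' Describes the stimulus timing and recording setup of one session:
#' `n_songs_per_valence` songs per emotional valence, each played for
#' `song_duration_s` seconds and followed by `silence_duration_s` seconds of
#' silence, sampled at `fs` Hz on the named channels.
#'
#' @param n_songs_per_valence songs per valence (default 5).
#' @param song_duration_s song length in seconds (default 60).
#' @param silence_duration_s inter-song silence in seconds (default 10).
#' @param fs sampling frequency in Hz (default 500).
#' @param channels ordered channel names (default C3, C4, Pz).
#' @param n_participants cohort size (default 20).
#' @return an object of class `protocol_config`.
#' @export
protocol_config <- function(n_songs_per_valence = 5L,
                            song_duration_s = 60,
                            silence_duration_s = 10,
                            fs = 500,
                            channels = c("C3", "C4", "Pz"),
                            n_participants = 20L) {
  if (song_duration_s <= 0 || silence_duration_s <= 0)
    stop_config("durations must be positive")
  if (fs <= 0) stop_config("sampling frequency must be positive")
  if (length(channels) < 1L || anyDuplicated(channels))
    stop_config("channel list must be non-empty and duplicate-free")
  if (n_songs_per_valence < 1L) stop_config("need at least one song per valence")
  structure(list(n_songs_per_valence = as.integer(n_songs_per_valence),
                 song_duration_s = song_duration_s,
                 silence_duration_s = silence_duration_s,
                 fs = fs,
                 channels = channels,
                 n_participants = as.integer(n_participants)),
            class = "protocol_config")
}

#' Class-dependent spectral signature specification
#'
#' Per-emotion relative band-power weights per channel. Rows are the
#' canonical bands ([eeg_bands()]), columns the protocol channels. The
#' defaults encode the physiology the classifier is meant to pick up:
#' positive valence shows stronger left-central (C3) alpha and suppressed
#' beta-2/beta-3/gamma; negative valence the mirrored alpha asymmetry with
#' elevated high-frequency power; neutral is spectrally flat.
#'
#' Within every band, each channel receives a mix of a channel-specific
#' oscillation and one source shared by all channels (fraction
#' `channel_mixing` of the band's power), mimicking the inter-channel
#' correlation that volume conduction produces in scalp EEG; the per-channel
#' band power is unaffected by the mixing.
#'
#' @param weights named list (one entry per emotion) of band-by-channel
#'   weight matrices; `NULL` for the defaults described above.
#' @param noise_std additive white-noise standard deviation in microvolts.
#' @param amplitude_uV baseline oscillation amplitude in microvolts.
#' @param n_components sinusoids per band.
#' @param channel_mixing fraction of each band's power drawn from the
#'   channel-shared source, in `[0, 1)` (default 0.45).
#' @param seed base RNG seed.
#' @return an object of class `class_spectrum_spec`.
#' @export
class_spectrum_spec <- function(weights = NULL, noise_std = 2,
                                amplitude_uV = 10, n_components = 8L,
                                channel_mixing = 0.45, seed = 1L) {
  bands <- names(eeg_bands())
  if (is.null(weights)) {
    mk <- function(theta, alpha, beta2, beta3, gamma) {
      m <- rbind(theta = theta, alpha = alpha, beta2 = beta2,
                 beta3 = beta3, gamma = gamma)
      colnames(m) <- c("C3", "C4", "Pz")
      m
    }
    weights <- list(
      positive = mk(theta = c(1.2, 1.2, 1.0),
                    alpha = c(1.8, 0.6, 1.0),
                    beta2 = c(0.40, 0.40, 0.40),
                    beta3 = c(0.30, 0.30, 0.30),
                    gamma = c(0.25, 0.25, 0.25)),
      negative = mk(theta = c(0.6, 0.6, 0.5),
                    alpha = c(0.6, 1.8, 1.0),
                    beta2 = c(1.5, 1.5, 1.2),
                    beta3 = c(1.3, 1.3, 1.1),
                    gamma = c(1.1, 1.1, 0.9)),
      neutral  = mk(theta = c(0.8, 0.8, 0.8),
                    alpha = c(0.8, 0.8, 0.8),
                    beta2 = c(0.8, 0.8, 0.8),
                    beta3 = c(0.8, 0.8, 0.8),
                    gamma = c(0.8, 0.8, 0.8)))
  }
  for (em in names(weights)) {
    w <- weights[[em]]
    if (!all(rownames(w) %in% bands))
      stop_config("unknown band in spectrum for '%s'", em)
    if (any(w < 0)) stop_config("band weights must be >= 0")
    if (all(w == 0)) stop_config("emotion '%s' needs at least one positive band weight", em)
  }
  if (noise_std < 0) stop_config("noise_std must be >= 0")
  if (channel_mixing < 0 || channel_mixing >= 1)
    stop_config("channel_mixing must lie in [0, 1)")
  structure(list(weights = weights, noise_std = noise_std,
                 amplitude_uV = amplitude_uV,
                 n_components = as.integer(n_components),
                 channel_mixing = channel_mixing,
                 seed = as.integer(seed)),
            class = "class_spectrum_spec")
}

#' Spectrum specification for a well-separated cohort
#'
#' A deliberately easy condition used to validate that the pipeline can
#' recover class structure end to end: each emotion occupies one dominant
#' frequency band (positive: alpha, negative: gamma, neutral: theta) with
#' a 40x weight margin over the off bands on every channel. Unlike the
#' physiologically motivated defaults of [class_spectrum_spec()], these
#' classes are separable from short windows by construction.
#'
#' @param noise_std white-noise standard deviation in microvolts (default 1).
#' @param seed base RNG seed.
#' @return a `class_spectrum_spec`.
#' @export
separable_spectrum_spec <- function(noise_std = 1, seed = 1L) {
  one_band <- function(b) {
    m <- matrix(0.05, 5, 3, dimnames = list(names(eeg_bands()),
                                            c("C3", "C4", "Pz")))
    m[b, ] <- 2
    m
  }
  class_spectrum_spec(weights = list(positive = one_band("alpha"),
                                     negative = one_band("gamma"),
                                     neutral = one_band("theta")),
                      noise_std = noise_std, seed = seed)
}

# Stimulus sequence of one session: songs in the published playing order
# (N, P, N, P, P, N, N, P, N, P), each followed by one silence.
protocol_sequence <- function(protocol) {
  valence_order <- c("negative", "positive", "negative", "positive", "positive",
                     "negative", "negative", "positive", "negative", "positive")
  n_each <- protocol$n_songs_per_valence
  # truncate/extend the canonical pattern to n_each songs per valence
  seq_out <- character(0)
  cnt <- c(negative = 0L, positive = 0L)
  i <- 1L
  while (any(cnt < n_each)) {
    v <- valence_order[((i - 1L) %% length(valence_order)) + 1L]
    if (cnt[[v]] < n_each) {
      seq_out <- c(seq_out, v)
      cnt[[v]] <- cnt[[v]] + 1L
    }
    i <- i + 1L
  }
  seq_out
}

# unit-power band-limited random-phase sinusoid mixture
band_component <- function(n, fs, band, n_components) {
  t <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  fr <- stats::runif(n_components, band[1], band[2])
  ph <- stats::runif(n_components, 0, 2 * pi)
  for (m in seq_len(n_components)) x <- x + sin(2 * pi * fr[m] * t + ph[m])
  x / sqrt(n_components)
}

# one interval, all channels: per band, a channel-shared source plus
# channel-specific sources, both scaled by the channel's band weight, are
# mixed so that the band power stays proportional to the weight while
# channels correlate by ~channel_mixing.
synth_interval_block <- function(n, fs, W, nch, spec) {
  X <- matrix(0, nch, n)
  m <- spec$channel_mixing
  bands <- eeg_bands()
  for (b in rownames(W)) {
    shared <- band_component(n, fs, bands[[b]], spec$n_components)
    for (ci in seq_len(nch)) {
      wb <- W[b, min(ci, ncol(W))]
      if (wb <= 0) next
      own <- band_component(n, fs, bands[[b]], spec$n_components)
      amp <- spec$amplitude_uV * sqrt(wb)
      X[ci, ] <- X[ci, ] + amp * (sqrt(1 - m) * own + sqrt(m) * shared)
    }
  }
  if (spec$noise_std > 0)
    X <- X + matrix(stats::rnorm(nch * n, 0, spec$noise_std), nch, n)
  X
}

#' Generate one synthetic EEG session
#'
#' Produces a multichannel recording following the protocol: each song
#' interval carries its valence label, each silence a neutral label.
#' Annotation intervals are 0-based half-open `[start, end)` sample ranges
#' that tile the whole session. Identical `(protocol, spectra,
#' participant_id)` including the spectrum specification's seed give bit-identical output; the
#' per-interval random streams are derived from `(seed, participant_id,
#' interval)` so they do not depend on generation order.
#'
#' @param protocol a [protocol_config()].
#' @param spectra a [class_spectrum_spec()].
#' @param participant_id integer id (0-based).
#' @return an object of class `emotion_session` with elements `signal`
#'   (channels x samples matrix, microvolts), `fs`, `annotations`
#'   (data.frame with label/start/end/piece_index), `participant_id`.
#' @export
generate_session <- function(protocol, spectra, participant_id = 0L) {
  stopifnot(inherits(protocol, "protocol_config"),
            inherits(spectra, "class_spectrum_spec"))
  fs <- protocol$fs
  song_n <- as.integer(round(protocol$song_duration_s * fs))
  sil_n <- as.integer(round(protocol$silence_duration_s * fs))
  valences <- protocol_sequence(protocol)
  n_songs <- length(valences)
  total_n <- n_songs * (song_n + sil_n)
  nch <- length(protocol$channels)

  sig <- matrix(0, nrow = nch, ncol = total_n,
                dimnames = list(protocol$channels, NULL))
  ann <- vector("list", 2L * n_songs)
  pos <- 0L
  piece <- 0L
  for (k in seq_len(n_songs)) {
    for (part in c("song", "silence")) {
      label <- if (part == "song") valences[k] else "neutral"
      len <- if (part == "song") song_n else sil_n
      piece <- piece + 1L
      w <- spectra$weights[[label]]
      seed_k <- derive_seed(spectra$seed, participant_id, piece)
      block <- with_seed(seed_k,
                         synth_interval_block(len, fs, w, nch, spectra))
      sig[, (pos + 1L):(pos + len)] <- block
      ann[[piece]] <- data.frame(label = label, start = pos, end = pos + len,
                                 piece_index = piece - 1L,
                                 stringsAsFactors = FALSE)
      pos <- pos + len
    }
  }
  annotations <- do.call(rbind, ann)
  structure(list(signal = sig, fs = fs, annotations = annotations,
                 participant_id = as.integer(participant_id)),
            class = "emotion_session")
}

#' Generate a cohort of synthetic sessions
#'
#' @param protocol a [protocol_config()].
#' @param spectra a [class_spectrum_spec()]; per-participant streams are
#'   derived from its seed, so participant `p` is identical whether generated
#'   alone or inside a cohort.
#' @param n_participants number of sessions (defaults to the protocol value).
#' @return list of `emotion_session`, participant ids `0..n-1`.
#' @export
generate_cohort <- function(protocol, spectra,
                            n_participants = protocol$n_participants) {
  if (n_participants < 1L) stop_config("n_participants must be >= 1")
  lapply(seq_len(n_participants) - 1L,
         function(p) generate_session(protocol, spectra, p))
}

#' @export
print.emotion_session <- function(x, ...) {
  cat(sprintf("<emotion_session> participant %d: %d channels x %d samples @ %g Hz, %d annotations\n",
              x$participant_id, nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$annotations)))
  invisible(x)
}

#' Write / read a session as text files
#'
#' `signal.csv` holds the channels-x-samples matrix (one row per channel);
#' `meta.json` the sampling rate, participant id and annotation table.
#'
#' @param session an `emotion_session`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(channel = rownames(session$signal), session$signal,
                              check.names = FALSE),
                   file.path(dir, "signal.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = session$fs,
                            participant_id = session$participant_id,
                            annotations = session$annotations),
                       file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  df <- utils::read.csv(file.path(dir, "signal.csv"), check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sig <- as.matrix(df[, -1, drop = FALSE])
  dimnames(sig) <- list(df$channel, NULL)
  structure(list(signal = sig, fs = meta$fs,
                 annotations = as.data.frame(meta$annotations),
                 participant_id = as.integer(meta$participant_id)),
            class = "emotion_session")
}
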