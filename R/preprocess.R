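# Preprocessing chain: channel selection, mid-song extraction, per-class
# stacking, fixed non-overlapping windowing, sample-budget bookkeeping and
# stratified split construction.

#' Select and reorder channels of a session
#'
#' @param session an `emotion_session`.
#' @param names channel names, in the requested output order.
#' @return session restricted to `names`; annotations untouched.
#' @export
select_channels <- function(session, names = c("C3", "C4", "Pz")) {
  have <- rownames(session$signal)
  missing <- setdiff(names, have)
  if (length(missing))
    stop(sprintf("channel(s) not present: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  session$signal <- session$signal[names, , drop = FALSE]
  session
}

#' Extract the centered portion of an interval
#'
#' Returns the middle `keep_s` seconds of a channels-x-samples matrix, the
#' convention used to discard onset/offset transients of each song. The
#' centering offset is `floor((L - keep) / 2)` samples.
#'
#' @param interval_signal channels x samples matrix.
#' @param fs sampling frequency in Hz.
#' @param keep_s seconds to keep (default 20).
#' @return channels x `keep_s * fs` matrix.
#' @export
extract_mid_window <- function(interval_signal, fs, keep_s = 20) {
  keep <- round(keep_s * fs)
  L <- ncol(interval_signal)
  if (L < keep)
    stop(sprintf("interval of %d samples shorter than requested %d", L, keep),
         call. = FALSE)
  off <- (L - keep) %/% 2L
  interval_signal[, (off + 1L):(off + keep), drop = FALSE]
}

#' Stack same-class segments along time
#'
#' @param segments list of channels x samples matrices (equal channel count).
#' @param label emotion label carried by the stack.
#' @param participant_id integer id.
#' @param provenance single tag or per-segment tags in `{"real","gan"}`.
#' @return `stacked_signal`: `signal`, `label`, `participant_id` and a
#'   `provenance` data.frame of half-open `[start, end)` ranges partitioning
#'   the stacked samples.
#' @export
stack_class <- function(segments, label, participant_id = 0L,
                        provenance = "real") {
  nch <- unique(vapply(segments, nrow, integer(1)))
  if (length(nch) != 1L)
    stop("segments disagree on channel count", call. = FALSE)
  lens <- vapply(segments, ncol, integer(1))
  if (length(provenance) == 1L) provenance <- rep(provenance, length(segments))
  stopifnot(length(provenance) == length(segments))
  ends <- cumsum(lens)
  prov <- data.frame(start = c(0L, ends[-length(ends)]), end = ends,
                     tag = provenance, stringsAsFactors = FALSE)
  # merge adjacent ranges with equal tags
  keep <- c(TRUE, prov$tag[-1] != prov$tag[-nrow(prov)])
  grp <- cumsum(keep)
  prov <- data.frame(start = tapply(prov$start, grp, min),
                     end = tapply(prov$end, grp, max),
                     tag = tapply(prov$tag, grp, `[`, 1L),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(signal = do.call(cbind, segments), label = label,
                 participant_id = as.integer(participant_id),
                 provenance = prov),
            class = "stacked_signal")
}

emotion_levels <- c("negative", "neutral", "positive")

new_window_set <- function(windows, labels, participant_ids, split = NULL,
                           provenance = NULL) {
  n <- dim(windows)[1]
  split <- split %||% rep("unassigned", n)
  provenance <- provenance %||% rep("real", n)
  structure(list(windows = windows,
                 labels = factor(labels, levels = emotion_levels),
                 participant_ids = as.integer(participant_ids),
                 split = factor(split, levels = c("train", "val", "test",
                                                  "unassigned")),
                 provenance = provenance),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d x %d; labels: %s; splits: %s\n",
              dim(x$windows)[1], dim(x$windows)[2], dim(x$windows)[3],
              paste(sprintf("%s=%d", levels(x$labels), tabulate(x$labels, 3)),
                    collapse = " "),
              paste(sprintf("%s=%d", levels(x$split), tabulate(x$split, 4)),
                    collapse = " ")))
  invisible(x)
}

#' Cut a stacked signal into fixed-size windows
#'
#' Non-overlapping by default (`stride = size`), so no sample is reused; a
#' signal shorter than `size` yields an empty set. Window `i` starts at
#' sample `(i-1) * stride`.
#'
#' @param stacked a `stacked_signal`.
#' @param size window length in samples (default 125).
#' @param stride hop in samples (default 125).
#' @return a `window_set` with tensor `[n_windows x channels x size]`.
#' @export
window_signal <- function(stacked, size = 125L, stride = 125L) {
  stopifnot(size > 0, stride > 0)
  sig <- stacked$signal
  n <- ncol(sig)
  nch <- nrow(sig)
  nw <- if (n >= size) (n - size) %/% stride + 1L else 0L
  windows <- array(0, dim = c(nw, nch, size))
  prov <- character(nw)
  if (nw > 0) {
    gan_ranges <- stacked$provenance[stacked$provenance$tag == "gan", , drop = FALSE]
    for (i in seq_len(nw)) {
      s0 <- (i - 1L) * stride          # 0-based start
      windows[i, , ] <- sig[, (s0 + 1L):(s0 + size), drop = FALSE]
      overlaps_gan <- nrow(gan_ranges) > 0 &&
        any(gan_ranges$start < s0 + size & gan_ranges$end > s0)
      prov[i] <- if (overlaps_gan) "gan" else "real"
    }
  }
  new_window_set(windows,
                 labels = rep(stacked$label, nw),
                 participant_ids = rep(stacked$participant_id, nw),
                 provenance = prov)
}

#' Concatenate window sets
#' @param ... `window_set` objects.
#' @return a single `window_set`.
#' @export
bind_window_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "window_set"))
    sets <- sets[[1]]
  sets <- Filter(function(s) dim(s$windows)[1] > 0, sets)
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]$windows)[-1]
  n <- sum(vapply(sets, function(s) dim(s$windows)[1], integer(1)))
  windows <- array(0, dim = c(n, d))
  at <- 0L
  for (s in sets) {
    k <- dim(s$windows)[1]
    if (k > 0) windows[(at + 1L):(at + k), , ] <- s$windows
    at <- at + k
  }
  new_window_set(windows,
                 labels = unlist(lapply(sets, function(s) as.character(s$labels))),
                 participant_ids = unlist(lapply(sets, function(s) s$participant_ids)),
                 split = unlist(lapply(sets, function(s) as.character(s$split))),
                 provenance = unlist(lapply(sets, function(s) s$provenance)))
}

#' Subset a window set
#' @param ws a `window_set`; @param idx indices or logical mask.
#' @return the restricted `window_set`.
#' @export
subset_windows <- function(ws, idx) {
  new_window_set(ws$windows[idx, , , drop = FALSE],
                 labels = as.character(ws$labels)[idx],
                 participant_ids = ws$participant_ids[idx],
                 split = as.character(ws$split)[idx],
                 provenance = ws$provenance[idx])
}

#' Sample-budget bookkeeping
#'
#' Reproduces, purely from configuration arithmetic, every sample and set
#' count of the preprocessing chain: per-class stacked real samples, the
#' post-augmentation target, windows per participant, totals, and the
#' train/val/test partition.
#'
#' @param protocol a [protocol_config()].
#' @param keep_s seconds kept per song (default 20).
#' @param window_size,window_stride windowing parameters (default 125/125).
#' @param n_sets_per_participant windows per participant per class after
#'   augmentation (default 1000); fixes the per-class augmentation target at
#'   `n_sets_per_participant * window_size` samples.
#' @param ratios train/val/test fractions (default 0.7/0.2/0.1).
#' @param n_classes classification arity (default 3).
#' @return a `budget_report` list of counts.
#' @export
compute_budget <- function(protocol, keep_s = 20, window_size = 125L,
                           window_stride = 125L,
                           n_sets_per_participant = 1000L,
                           ratios = c(0.7, 0.2, 0.1), n_classes = 3L) {
  fs <- protocol$fs
  nv <- protocol$n_songs_per_valence
  stacked_real <- nv * keep_s * fs                       # per valence class
  stacked_neutral <- nv * protocol$silence_duration_s * fs
  zero <- nv == 0
  target_samples <- if (zero) 0 else as.numeric(n_sets_per_participant) * window_size
  # whole GAN sets of the real-stack size needed to reach (at least) target
  gan_sets_valence <- if (zero) 0 else ceiling(max(0, target_samples - stacked_real) / stacked_real)
  gan_sets_neutral <- if (zero) 0 else ceiling(max(0, target_samples - stacked_neutral) / stacked_neutral)
  n_windows_pp <- if (target_samples >= window_size)
    (target_samples - window_size) %/% window_stride + 1 else 0
  n_sets_per_class <- protocol$n_participants * n_windows_pp
  n_sets_total <- n_classes * n_sets_per_class
  n_val <- round(ratios[2] * n_windows_pp)
  n_test <- round(ratios[3] * n_windows_pp)
  n_train <- n_windows_pp - n_val - n_test
  structure(list(
    stacked_real_samples = c(positive = stacked_real, negative = stacked_real,
                             neutral = stacked_neutral),
    gan_sets = c(valence = gan_sets_valence, neutral = gan_sets_neutral),
    target_samples_after_gan = target_samples,
    n_windows_per_participant = n_windows_pp,
    n_sets_per_class = n_sets_per_class,
    n_sets_total = n_sets_total,
    n_train = n_train * protocol$n_participants * n_classes,
    n_val = n_val * protocol$n_participants * n_classes,
    n_test = n_test * protocol$n_participants * n_classes),
    class = "budget_report")
}

#' @export
print.budget_report <- function(x, ...) {
  cat("<budget_report>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = "/")))
  invisible(x)
}

#' Per-class segment extraction from a session
#'
#' Applies the per-class slicing rules: for each valence class, the centered
#' `keep_s` seconds of every song of that valence; for the neutral class,
#' the full silences following the first `n_songs_per_valence` songs (the
#' retention rule that makes the neutral sample count half a valence
#' class's, matching the downstream bookkeeping).
#'
#' @param session an `emotion_session` (already channel-selected).
#' @param keep_s seconds kept per song (default 20).
#' @param n_neutral number of silences retained (default: number of songs
#'   per valence).
#' @return named list of segment lists: `positive`, `negative`, `neutral`.
#' @export
session_class_segments <- function(session, keep_s = 20, n_neutral = NULL) {
  ann <- session$annotations
  sig <- session$signal
  grab <- function(row) sig[, (row$start + 1L):row$end, drop = FALSE]
  out <- list(positive = list(), negative = list(), neutral = list())
  n_sil <- 0L
  n_neutral <- n_neutral %||% (sum(ann$label %in% c("positive", "negative")) %/% 2L)
  for (i in seq_len(nrow(ann))) {
    row <- ann[i, ]
    if (row$label %in% c("positive", "negative")) {
      seg <- extract_mid_window(grab(row), session$fs, keep_s)
      out[[row$label]] <- c(out[[row$label]], list(seg))
    } else if (n_sil < n_neutral) {
      n_sil <- n_sil + 1L
      out$neutral <- c(out$neutral, list(grab(row)))
    }
  }
  out
}

#' Assign stratified train/val/test splits
#'
#' Splits are drawn independently inside every (participant, class) stratum:
#' `round(ratio * n)` windows go to validation and test, the remainder to
#' train, assigned through a seeded permutation. Windows synthesized by the
#' GAN (provenance `"gan"`) are never placed in validation or test: any such
#' assignment is swapped with a real window from the train pool of the same
#' stratum, keeping all counts unchanged.
#'
#' @param ws a `window_set`.
#' @param ratios train/val/test fractions summing to 1.
#' @param seed RNG seed for the permutation.
#' @return the `window_set` with `split` filled in.
#' @export
make_splits <- function(ws, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-9)
    stop_config("split ratios must be positive and sum to 1")
  split <- as.character(ws$split)
  strata <- interaction(ws$participant_ids, ws$labels, drop = TRUE)
  for (st in levels(strata)) {
    idx <- which(strata == st)
    n <- length(idx)
    n_val <- round(ratios[2] * n)
    n_test <- round(ratios[3] * n)
    n_train <- n - n_val - n_test
    perm <- with_seed(derive_seed(seed, match(st, levels(strata))),
                      sample.int(n))
    ord <- idx[perm]
    lab <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
    # keep GAN windows out of val/test
    is_gan <- ws$provenance[ord] == "gan"
    bad <- which(is_gan & lab != "train")
    pool <- which(!is_gan & lab == "train")
    if (length(bad) > length(pool))
      stop_config("stratum %s: too few real windows to fill val/test", st)
    for (j in seq_along(bad)) {
      k <- pool[j]
      tmp <- lab[k]; lab[k] <- lab[bad[j]]; lab[bad[j]] <- tmp
    }
    split[ord] <- lab
  }
  ws$split <- factor(split, levels = levels(ws$split))
  ws
}
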