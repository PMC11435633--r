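test_that("select_channels subsets, reorders, and names missing channels", {
  sig <- matrix(rnorm(21 * 100), 21,
                dimnames = list(c(paste0("E", 1:18), "C3", "C4", "Pz"), NULL))
  s <- structure(list(signal = sig, fs = 500,
                      annotations = data.frame(), participant_id = 0L),
                 class = "emotion_session")
  out <- select_channels(s, c("C3", "C4", "Pz"))
  expect_equal(rownames(out$signal), c("C3", "C4", "Pz"))
  expect_equal(dim(out$signal), c(3L, 100L))
  expect_identical(select_channels(out, c("C3", "C4", "Pz"))$signal, out$signal)
  expect_error(select_channels(s, c("C3", "XX")), "XX")
})

test_that("extract_mid_window centers with floor((L - keep)/2) offset", {
  sig <- matrix(rep(seq_len(30000), each = 3), 3, byrow = FALSE)
  sig <- matrix(seq_len(3 * 30000), 3)
  out <- extract_mid_window(sig, fs = 500, keep_s = 20)
  expect_equal(dim(out), c(3L, 10000L))
  # 60 s at 500 Hz: keep samples [10000, 20000) of the interval
  expect_identical(out, sig[, 10001:20000])
  # exact-length interval is the identity
  expect_identical(extract_mid_window(sig[, 1:10000], 500, 20), sig[, 1:10000])
  # odd leftover: L = 30001, offset floor(20001/2) = 10000
  sig1 <- matrix(seq_len(3 * 30001), 3)
  out1 <- extract_mid_window(sig1, 500, 20)
  expect_identical(out1, sig1[, 10001:20000])
  expect_error(extract_mid_window(sig[, 1:100], 500, 20), "shorter")
})

test_that("extract_mid_window matches an enumerate-and-check centering oracle", {
  for (L in c(50, 51, 52, 75, 101)) {
    sig <- matrix(seq_len(L), 1)
    out <- extract_mid_window(sig, fs = 1, keep_s = 50)
    off <- (L - 50) %/% 2
    expect_identical(drop(out), (off + 1):(off + 50))
  }
})

test_that("stack_class concatenates along time and tracks provenance", {
  segs <- replicate(5, matrix(rnorm(3 * 10000), 3), simplify = FALSE)
  st <- stack_class(segs, "positive", 0L)
  expect_equal(ncol(st$signal), 50000L)
  expect_equal(st$provenance$tag, "real")
  expect_equal(st$provenance$end, 50000)
  one <- stack_class(segs[1], "neutral")
  expect_identical(one$signal, segs[[1]])
  sil <- replicate(5, matrix(rnorm(3 * 5000), 3), simplify = FALSE)
  expect_equal(ncol(stack_class(sil, "neutral")$signal), 25000L)
  expect_error(stack_class(list(matrix(0, 3, 5), matrix(0, 2, 5)), "x"),
               "channel count")
  mixed <- stack_class(list(segs[[1]], segs[[2]]), "positive",
                       provenance = c("real", "gan"))
  expect_equal(mixed$provenance$tag, c("real", "gan"))
  expect_equal(mixed$provenance$start, c(0, 10000))
})

test_that("windowing yields floor((n - size)/stride) + 1 contiguous slices", {
  st <- stack_class(list(matrix(rnorm(3 * 125000), 3)), "positive", 0L)
  ws <- window_signal(st, 125L, 125L)
  expect_equal(dim(ws$windows), c(1000L, 3L, 125L))
  one <- window_signal(stack_class(list(matrix(rnorm(3 * 125), 3)), "neutral"))
  expect_equal(dim(one$windows)[1], 1L)
  expect_equal(array(one$windows[1, , ], c(3, 125)), one$windows[1, , ])
  two <- window_signal(stack_class(list(matrix(seq_len(3 * 300), 3)), "negative"),
                       125L, 125L)
  expect_equal(dim(two$windows)[1], 2L)
  expect_equal(two$windows[2, , ],
               matrix(seq_len(3 * 300), 3)[, 126:250], ignore_attr = TRUE)
  empty <- window_signal(stack_class(list(matrix(0, 3, 100)), "neutral"), 125L)
  expect_equal(dim(empty$windows)[1], 0L)
})

test_that("windowing equals the naive slide-and-count oracle on random shapes", {
  set.seed(20)
  for (r in 1:40) {
    n <- sample(1:400, 1)
    size <- sample(1:80, 1)
    stride <- sample(1:80, 1)
    sig <- matrix(rnorm(2 * n), 2)
    st <- structure(list(signal = sig, label = "positive", participant_id = 0L,
                         provenance = data.frame(start = 0, end = n, tag = "real")),
                    class = "stacked_signal")
    ws <- window_signal(st, size, stride)
    oracle <- naive_windows(sig, size, stride)
    expect_equal(dim(ws$windows)[1], length(oracle))
    if (length(oracle))
      for (i in seq_along(oracle))
        expect_equal(array(ws$windows[i, , ], dim(oracle[[i]])), oracle[[i]],
                     ignore_attr = TRUE)
  }
})

test_that("budget bookkeeping reproduces every printed default count", {
  b <- compute_budget(protocol_config())
  expect_equal(unname(b$stacked_real_samples["positive"]), 50000)
  expect_equal(unname(b$stacked_real_samples["negative"]), 50000)
  expect_equal(unname(b$stacked_real_samples["neutral"]), 25000)
  expect_equal(unname(b$gan_sets["valence"]), 2)
  expect_equal(unname(b$gan_sets["neutral"]), 4)
  expect_equal(b$target_samples_after_gan, 125000)
  expect_equal(b$n_windows_per_participant, 1000)
  expect_equal(b$n_sets_per_class, 20000)
  expect_equal(b$n_sets_total, 60000)
  expect_equal(b$n_train, 42000)
  expect_equal(b$n_val, 12000)
  expect_equal(b$n_test, 6000)
})

test_that("budget of an empty protocol is all zero", {
  pr <- protocol_config()
  pr$n_songs_per_valence <- 0L
  b <- compute_budget(pr)
  expect_equal(unname(b$stacked_real_samples), c(0, 0, 0))
  expect_equal(b$n_sets_total, 0)
  expect_equal(b$n_train + b$n_val + b$n_test, 0)
})

test_that("splits are stratified, conserved, seeded, and exhaustive", {
  ws <- random_window_set(n = 3000, seed = 21,
                          labels = rep(c("negative", "neutral", "positive"),
                                       each = 1000),
                          participants = rep(rep(0:1, each = 500), 3))
  s1 <- make_splits(ws, seed = 7)
  expect_false(any(s1$split == "unassigned"))
  tab <- table(s1$split)
  expect_equal(unname(tab[c("train", "val", "test")]), c(2100L, 600L, 300L),
               ignore_attr = TRUE)
  # per-stratum deviation below one window
  for (p in 0:1) for (cl in levels(ws$labels)) {
    sel <- s1$participant_ids == p & s1$labels == cl
    expect_equal(sum(s1$split[sel] == "val"), 100)
    expect_equal(sum(s1$split[sel] == "test"), 50)
  }
  s2 <- make_splits(ws, seed = 7)
  expect_identical(as.character(s1$split), as.character(s2$split))
  s3 <- make_splits(ws, seed = 8)
  expect_false(identical(as.character(s1$split), as.character(s3$split)))
  expect_equal(table(s3$split), table(s1$split))
  # 10-window stratum splits 7/2/1
  small <- random_window_set(n = 10, labels = rep("positive", 10), seed = 3)
  sm <- make_splits(small, seed = 1)
  expect_equal(unname(table(sm$split)[c("train", "val", "test")]),
               c(7L, 2L, 1L), ignore_attr = TRUE)
  expect_error(make_splits(ws, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split counts are conserved across 100 seeds", {
  ws <- random_window_set(n = 90, seed = 22,
                          labels = rep(c("negative", "neutral", "positive"), 30))
  for (seed in 1:100) {
    s <- make_splits(ws, seed = seed)
    expect_equal(sum(table(s$split)), 90L)
    expect_equal(unname(table(s$split)["train"]), 63L, ignore_attr = TRUE)
  }
})

test_that("GAN-tagged windows never land in val or test", {
  ws <- random_window_set(n = 100, labels = rep("positive", 100), seed = 23)
  ws$provenance <- rep(c("real", "gan"), each = 50)
  s <- make_splits(ws, seed = 2)
  expect_true(all(s$split[s$provenance == "gan"] == "train"))
  expect_equal(sum(s$split == "val"), 20L)
  expect_equal(sum(s$split == "test"), 10L)
})

test_that("per-class segment slicing keeps half the silences for neutral", {
  pr <- protocol_config(n_songs_per_valence = 5, song_duration_s = 60,
                        silence_duration_s = 10, fs = 100)
  s <- generate_session(pr, class_spectrum_spec(seed = 9L, n_components = 2L), 0L)
  segs <- session_class_segments(s, keep_s = 20)
  expect_length(segs$positive, 5L)
  expect_length(segs$negative, 5L)
  expect_length(segs$neutral, 5L)
  expect_equal(sum(vapply(segs$neutral, ncol, integer(1))), 5 * 10 * 100)
  expect_equal(sum(vapply(segs$positive, ncol, integer(1))), 5 * 20 * 100)
})
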