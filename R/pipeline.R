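# End-to-end orchestration: simulate -> preprocess -> augment -> graph ->
# train -> evaluate, driven by one (optionally YAML-sourced) configuration.

#' Full pipeline configuration
#'
#' Bundles the stage configurations with the run-level choices: the
#' correlation threshold `tau`, the classification `mode`, per-participant
#' window budget and the master seed. Any component can be overridden.
#'
#' @param protocol a [protocol_config()].
#' @param spectra a [class_spectrum_spec()].
#' @param gan a [gan_config()].
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param tau correlation threshold for graph sparsification (default 0.3).
#' @param mode `"3-class"` or `"2-class"` (drops neutral windows).
#' @param keep_s seconds kept from each song (default 20).
#' @param window_size,window_stride windowing parameters.
#' @param n_sets_per_participant post-augmentation windows per participant
#'   per class (default 1000).
#' @param ratios train/val/test fractions.
#' @param use_gan augment with the GAN (disable for quick runs).
#' @param seed master seed; stage seeds are derived from it.
#' @return a `run_config`.
#' @export
run_config <- function(protocol = protocol_config(),
                       spectra = class_spectrum_spec(),
                       gan = gan_config(),
                       model = model_config(),
                       train = train_config(),
                       tau = 0.3, mode = c("3-class", "2-class"),
                       keep_s = 20, window_size = 125L, window_stride = 125L,
                       n_sets_per_participant = 1000L,
                       ratios = c(0.7, 0.2, 0.1),
                       use_gan = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(protocol = protocol, spectra = spectra, gan = gan,
                 model = model, train = train, tau = tau, mode = mode,
                 keep_s = keep_s, window_size = as.integer(window_size),
                 window_stride = as.integer(window_stride),
                 n_sets_per_participant = as.integer(n_sets_per_participant),
                 ratios = ratios, use_gan = isTRUE(use_gan),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; nested maps mirror
#' each stage constructor's arguments. Missing keys fall back to defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$protocol)) args$protocol <- do.call(protocol_config, y$protocol)
  if (!is.null(y$gan)) args$gan <- do.call(gan_config, y$gan)
  if (!is.null(y$model)) args$model <- do.call(model_config, y$model)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$spectra)) args$spectra <- do.call(class_spectrum_spec, y$spectra)
  for (k in c("tau", "mode", "keep_s", "window_size", "window_stride",
              "n_sets_per_participant", "ratios", "use_gan", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Build the labelled real-window set of a cohort
#'
#' Simulates (or accepts) a cohort, slices every session into per-class
#' segments, stacks, windows, and assigns stratified splits.
#'
#' @param cfg a [run_config()].
#' @param cohort optional pre-generated session list.
#' @return a `window_set`.
#' @export
preprocess_cohort <- function(cfg, cohort = NULL) {
  cohort <- cohort %||% generate_cohort(cfg$protocol, cfg$spectra)
  sets <- list()
  for (sess in cohort) {
    sess <- select_channels(sess, cfg$protocol$channels)
    segs <- session_class_segments(sess, keep_s = cfg$keep_s)
    for (cl in names(segs)) {
      if (length(segs[[cl]]) == 0) next
      st <- stack_class(segs[[cl]], cl, sess$participant_id)
      sets[[length(sets) + 1L]] <- window_signal(st, cfg$window_size,
                                                 cfg$window_stride)
    }
  }
  ws <- bind_window_sets(sets)
  make_splits(ws, cfg$ratios, seed = derive_seed(cfg$seed, 41L))
}

#' Augment a window set with GAN-synthesized windows
#'
#' For every class, trains a GAN on that class's training-split windows and
#' synthesizes additional training windows per participant until each
#' (participant, class) stratum holds `n_target` windows.
#'
#' @param ws a `window_set` with splits.
#' @param cfg a [run_config()].
#' @param n_target windows per participant per class after augmentation.
#' @return list: augmented `window_set`, trained `gans` per class.
#' @export
augment_windows <- function(ws, cfg, n_target = cfg$n_sets_per_participant) {
  parts <- sort(unique(ws$participant_ids))
  gans <- list()
  extra <- list()
  for (cl in levels(droplevels(ws$labels))) {
    tr_idx <- which(ws$labels == cl & ws$split == "train")
    if (length(tr_idx) == 0) next
    gcfg <- cfg$gan
    gcfg$seed <- derive_seed(cfg$seed, 43L, match(cl, emotion_levels))
    pair <- train_gan(subset_windows(ws, tr_idx), gcfg)
    gans[[cl]] <- pair
    for (p in parts) {
      n_have <- sum(ws$labels == cl & ws$participant_ids == p)
      n_need <- n_target - n_have
      if (n_need <= 0) next
      sig <- synthesize(pair, n_need * cfg$window_size,
                        seed = derive_seed(cfg$seed, 47L, p,
                                           match(cl, emotion_levels)))
      st <- stack_class(list(sig), cl, p, provenance = "gan")
      w <- window_signal(st, cfg$window_size, cfg$window_stride)
      w$split <- factor(rep("train", length(w$split)), levels = levels(w$split))
      extra[[length(extra) + 1L]] <- w
    }
  }
  ws_aug <- if (length(extra)) bind_window_sets(c(list(ws), extra)) else ws
  list(windows = ws_aug, gans = gans)
}

#' Run the full pipeline
#'
#' Executes every stage and persists artifacts under `out_dir`: the budget
#' report, the connectivity graph, learning curves, test metrics, ROC
#' points, and a manifest with checksums. Deterministic for a fixed
#' configuration seed.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created).
#' @param budget_only stop after writing the budget report.
#' @param verbose print stage progress.
#' @return invisibly, a list with the budget, window set, graph, fit,
#'   metrics report and output paths.
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("dfcgn_run_"),
                         budget_only = FALSE, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  budget <- compute_budget(cfg$protocol, keep_s = cfg$keep_s,
                           window_size = cfg$window_size,
                           window_stride = cfg$window_stride,
                           n_sets_per_participant = cfg$n_sets_per_participant,
                           ratios = cfg$ratios)
  jsonlite::write_json(unclass(budget), file.path(out_dir, "budget.json"),
                       auto_unbox = TRUE, digits = NA)
  if (budget_only) {
    write_manifest(out_dir)
    return(invisible(list(budget = budget, out_dir = out_dir)))
  }
  say("simulate: %d participants", cfg$protocol$n_participants)
  ws <- preprocess_cohort(cfg)
  if (cfg$mode == "2-class")
    ws <- subset_windows(ws, ws$labels != "neutral")
  gans <- NULL
  if (cfg$use_gan) {
    say("augment: GAN per class")
    aug <- augment_windows(ws, cfg)
    ws <- aug$windows
    gans <- aug$gans
  }
  say("graph: correlation over pooled train windows")
  g <- build_channel_graph(pooled_signal(
    subset_windows(ws, ws$split == "train")), tau = cfg$tau)
  write_graph_json(g, file.path(out_dir, "graph.json"))
  mcfg <- cfg$model
  mcfg$n_classes <- if (cfg$mode == "2-class") 2L else 3L
  model <- build_model(mcfg, g, seed = derive_seed(cfg$seed, 53L))
  say("train: %d epochs", cfg$train$epochs)
  tcfg <- cfg$train
  tcfg$seed <- derive_seed(cfg$seed, 59L)
  fit <- train_dfcgn(model, ws, tcfg, verbose = verbose)
  utils::write.csv(fit$history, file.path(out_dir, "learning_curves.csv"),
                   row.names = FALSE)
  te <- which(ws$split == "test")
  scores <- predict(fit, subset_windows(ws, te))
  report <- compute_metrics(droplevels(ws$labels[te]), scores,
                            levels = class_levels_for(mcfg$n_classes))
  write_metrics_json(report, file.path(out_dir, "metrics.json"))
  roc_df <- do.call(rbind, lapply(names(report$roc), function(cl)
    cbind(class = cl, report$roc[[cl]])))
  if (!is.null(roc_df))
    utils::write.csv(roc_df, file.path(out_dir, "roc.csv"), row.names = FALSE)
  write_manifest(out_dir)
  say("done: accuracy %.3f", report$accuracy)
  invisible(list(budget = budget, windows = ws, graph = g, gans = gans,
                 fit = fit, metrics = report, out_dir = out_dir))
}

write_manifest <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  jsonlite::write_json(
    list(files = data.frame(file = files, md5 = unname(sums))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
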