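#' Default end-to-end pipeline configuration
#'
#' One nested list drives the whole experiment; every stochastic stage
#' receives a seed derived deterministically from the global seed and the
#' stage name. The defaults here are intentionally small so a desk-scale
#' smoke run finishes in minutes; scale up `simulate` and the epoch counts
#' for real experiments.
#'
#' @param seed global seed.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(n_train = 20, n_heldout = 10, af_fraction = 0.5,
                    duration_s = 30, fs = 100),
    preprocess = list(qc_threshold = 0.96, hr_floor = 30,
                      segment_seconds = 30, slice_seconds = 15,
                      stride_seconds = 1),
    gan = list(epochs = 2, batch_size = 1, lambda_rec = 100, adv_loss = "bce",
               depth = 3, base_filters = 8, kernel = 9,
               disc_layers = 3, disc_filters = 8),
    embed = list(perplexity = 15, iters = 150, grid_n = 60, max_per_pop = 200),
    classifier = list(epochs = 2, batch = 32, schemes = c("D2", "D4"),
                      n_boot = 200)
  )
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  need <- c("seed", "simulate", "preprocess", "gan", "embed", "classifier")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) stop("config is missing blocks: ", paste(miss, collapse = ", "))
  p <- cfg$preprocess
  if (!is.numeric(p$qc_threshold) || p$qc_threshold <= 0 || p$qc_threshold > 1)
    stop("preprocess$qc_threshold must lie in (0, 1]")
  if (p$hr_floor < 0) stop("preprocess$hr_floor must be non-negative")
  if (p$slice_seconds > p$segment_seconds)
    stop("preprocess$slice_seconds must not exceed segment_seconds")
  s <- cfg$simulate
  if (s$af_fraction < 0 || s$af_fraction > 1)
    stop("simulate$af_fraction must lie in [0, 1]")
  if (s$n_train < 2 || s$n_heldout < 2)
    stop("simulate cohorts need at least 2 records each")
  if (cfg$gan$epochs < 1 || cfg$classifier$epochs < 1)
    stop("epoch counts must be >= 1")
  invisible(TRUE)
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults block-by-block.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config(seed = user$seed %||% 1L)
  for (blk in intersect(names(user), names(cfg))) {
    if (is.list(cfg[[blk]])) {
      for (k in names(user[[blk]])) cfg[[blk]][[k]] <- user[[blk]][[k]]
    } else cfg[[blk]] <- user[[blk]]
  }
  validate_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_log <- function(stage, seed, msg) {
  message(sprintf("[%s seed=%d] %s", stage, seed, msg))
}

#' Run the full pipeline: simulate, screen, train, generate, evaluate
#'
#' Stages, in dependency order: simulate paired cohorts; quality-screen and
#' segment them; train the translation GAN on the training cohort's pairs;
#' generate PPG from the held-out AF ECGs; score morphology (PRD, Pearson
#' correlation) and rhythm agreement of the generated PPG; embed real
#' against generated AF slices and compute the Degree of Overlap; and train
#' the AF classifier under the configured dataset-composition schemes.
#' Every artifact is written under `out_dir` and listed in the returned
#' manifest with its MD5 checksum; rerunning with the same configuration
#' reproduces identical checksums.
#'
#' @param config configuration list from [default_config()] /
#'   [read_config()], or a YAML file path.
#' @param out_dir output directory.
#' @return list with `manifest` (file, md5), `qc`, `metrics`, `overlap_do`,
#'   `classifier_table`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("run")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  fs <- config$simulate$fs

  sim_seed <- derive_seed(seed, "simulate")
  pipeline_log("simulate", sim_seed, sprintf("%d train + %d held-out records",
                                             config$simulate$n_train,
                                             config$simulate$n_heldout))
  train_cohort <- make_cohort(config$simulate$n_train, config$simulate$af_fraction,
                              config$simulate$duration_s, seed = sim_seed, fs = fs,
                              id_prefix = "TR")
  held_cohort <- make_cohort(config$simulate$n_heldout, config$simulate$af_fraction,
                             config$simulate$duration_s,
                             seed = derive_seed(seed, "simulate-heldout"), fs = fs,
                             id_prefix = "HO")

  pp_seed <- derive_seed(seed, "preprocess")
  qc <- lapply(train_cohort, qc_screen, threshold = config$preprocess$qc_threshold,
               hr_floor = config$preprocess$hr_floor)
  keep <- vapply(qc, `[[`, logical(1), "passed")
  pipeline_log("preprocess", pp_seed, sprintf("%d/%d records passed QC",
                                              sum(keep), length(keep)))
  if (!any(keep)) stop("no records passed the QC screen")
  train_cohort <- train_cohort[keep]
  seg_of <- function(cohort, rhythm, origin = "real") {
    stores <- lapply(cohort, segment_annotated, rhythm = rhythm,
                     seconds = config$preprocess$segment_seconds, origin = origin)
    stores <- stores[vapply(stores, n_segments, numeric(1)) > 0]
    if (length(stores) == 0) NULL else do.call(bind_stores, stores)
  }
  pairs <- bind_stores(seg_of(train_cohort, "AF"), seg_of(train_cohort, "SR"))
  qc_df <- data.frame(subject = vapply(seq_along(qc), function(i)
                        sprintf("S%03d", i), character(1)),
                      passed = vapply(qc, `[[`, logical(1), "passed"),
                      interval_correlation = vapply(qc, `[[`, numeric(1),
                                                    "interval_correlation"),
                      mean_hr = vapply(qc, `[[`, numeric(1), "mean_hr"))
  write.csv(qc_df, file.path(out_dir, "qc_report.csv"), row.names = FALSE)

  gan_seed <- derive_seed(seed, "train-gan")
  pipeline_log("train-gan", gan_seed, sprintf("%d pairs, %d epochs",
                                              n_segments(pairs), config$gan$epochs))
  g <- config$gan
  model <- gan_train(pairs,
                     train_config(epochs = g$epochs, batch_size = g$batch_size,
                                  lambda_rec = g$lambda_rec, adv_loss = g$adv_loss,
                                  seed = gan_seed),
                     generator_spec(depth = g$depth, base_filters = g$base_filters,
                                    kernel = g$kernel,
                                    input_len = 2^g$depth *
                                      ceiling(ncol(pairs$segments) / 2^g$depth)),
                     discriminator_spec(n_layers = g$disc_layers,
                                        base_filters = g$disc_filters,
                                        kernel = g$kernel))
  save_translator(model, file.path(out_dir, "translator.rds"))
  write.csv(model$history, file.path(out_dir, "gan_history.csv"), row.names = FALSE)

  gen_seed <- derive_seed(seed, "generate")
  held_af <- seg_of(held_cohort, "AF")
  if (is.null(held_af)) stop("held-out cohort contains no AF segments")
  pipeline_log("generate", gen_seed, sprintf("%d held-out AF segments",
                                             n_segments(held_af)))
  gen_mat <- generate_ppg(model, held_af$ecg)
  gen_af <- segment_store(gen_mat, held_af$labels, "generated",
                          paste0(held_af$parent_id, "_gen"),
                          fs = fs, segment_seconds = held_af$segment_seconds)

  metrics <- segment_metrics(held_af, gen_af)
  report <- summarize_metrics(metrics)
  jsonlite::write_json(unclass(report), file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  emb_seed <- derive_seed(seed, "embed")
  e <- config$embed
  real_slices <- slice_segments(held_af, config$preprocess$slice_seconds,
                                config$preprocess$stride_seconds)
  gen_slices <- slice_segments(gen_af, config$preprocess$slice_seconds,
                               config$preprocess$stride_seconds)
  pipeline_log("embed", emb_seed, sprintf("%d real vs %d generated slices",
                                          n_segments(real_slices),
                                          n_segments(gen_slices)))
  ov <- population_overlap(real_slices, gen_slices, perplexity = e$perplexity,
                           iters = e$iters, seed = emb_seed, grid_n = e$grid_n,
                           max_per_pop = e$max_per_pop)
  jsonlite::write_json(list(degree_of_overlap = ov$do),
                       file.path(out_dir, "overlap.json"),
                       auto_unbox = TRUE, digits = NA)

  clf_seed <- derive_seed(seed, "train-clf")
  cl <- config$classifier
  held_sr <- seg_of(held_cohort, "SR")
  train_sr <- seg_of(train_cohort, "SR")
  train_af <- seg_of(train_cohort, "AF")
  pools <- list(generated_af = gen_slices,
                real_af = slice_segments(train_af, config$preprocess$slice_seconds,
                                         config$preprocess$stride_seconds),
                real_sr = slice_segments(train_sr, config$preprocess$slice_seconds,
                                         config$preprocess$stride_seconds))
  clf_table <- NULL
  if (!is.null(held_sr)) {
    test_store <- bind_stores(
      subset_store(real_slices, real_slices$parent_id %in%
                     with_seed(derive_seed(seed, "test-split"),
                               sample(unique(real_slices$parent_id),
                                      ceiling(length(unique(real_slices$parent_id)) / 2)))),
      slice_segments(held_sr, config$preprocess$slice_seconds,
                     config$preprocess$stride_seconds))
    # drop test-set parents (and their generated twins) from the pools
    test_parents <- unique(test_store$parent_id)
    pools$generated_af <- subset_store(pools$generated_af,
                                       !sub("_gen$", "", pools$generated_af$parent_id)
                                       %in% test_parents)
    pipeline_log("train-clf", clf_seed, paste(cl$schemes, collapse = ", "))
    spec <- classifier_spec(input_len = round(fs * config$preprocess$slice_seconds))
    vr <- run_validation_experiment(pools, test_store, schemes = cl$schemes,
                                    spec = spec, epochs = cl$epochs,
                                    batch = cl$batch, seed = clf_seed,
                                    n_boot = cl$n_boot)
    clf_table <- vr$table
    write.csv(clf_table, file.path(out_dir, "classifier_table.csv"),
              row.names = FALSE)
  }

  files <- list.files(out_dir, full.names = TRUE, recursive = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  list(manifest = manifest, qc = qc_df, metrics = report, overlap_do = ov$do,
       classifier_table = clf_table)
}
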