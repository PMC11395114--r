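#' Pipeline configuration
#'
#' Assembles the per-stage parameters of the end-to-end run into one
#' serializable object. Defaults are desk-scale: a small synthetic
#' cohort, threshold segmentation and a reduced WormCNN, so a full run
#' finishes in minutes on one CPU. Every field can be overridden.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for artifacts.
#' @param synth List: `n_worms`, `canvas` (rows, cols), `accel`.
#' @param preprocess List: `kernel`.
#' @param segment List: `method` ("threshold" or "unet"), `t`, `kernel`;
#'   for "unet" additionally `depth`, `base_channels`, `epochs`,
#'   `train_n`.
#' @param skeleton List: `interval`, `prune`.
#' @param straighten List: `half_width`, `mode`, `out_shape`.
#' @param cnn List: `input_shape`, `stem_filters`, `n_residual_blocks`,
#'   `epochs`, `batch_size`, `learning_rate`.
#' @param hai List: `fraction` (survival fraction for the elderly
#'   threshold).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("wormrun"),
                            synth = list(), preprocess = list(),
                            segment = list(), skeleton = list(),
                            straighten = list(), cnn = list(),
                            hai = list()) {
  merge_defaults <- function(user, def) utils::modifyList(def, user)
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    synth = merge_defaults(synth, list(n_worms = 20L, canvas = c(192L, 192L),
                                       accel = 1, aging = list())),
    preprocess = merge_defaults(preprocess, list(kernel = 3L)),
    segment = merge_defaults(segment, list(method = "threshold", t = 128L,
                                           kernel = 3L, depth = 2L,
                                           base_channels = 8L, epochs = 12L,
                                           train_n = 16L)),
    skeleton = merge_defaults(skeleton, list(interval = 10L, prune = 5L)),
    straighten = merge_defaults(straighten,
                                list(half_width = 15L, mode = "local",
                                     out_shape = c(600L, 30L))),
    cnn = merge_defaults(cnn, list(input_shape = c(150L, 16L),
                                   stem_filters = 8L,
                                   n_residual_blocks = 2L, epochs = 6L,
                                   batch_size = 16L, learning_rate = 1e-3)),
    hai = merge_defaults(hai, list(fraction = 0.2))
  ), class = "pipeline_config")
}

#' Read and write pipeline configurations
#'
#' JSON (de)serialization of a [pipeline_config()]; the round trip is
#' lossless.
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, c(list(seed = x$seed, out_dir = x$out_dir),
                                    x[setdiff(names(x),
                                              c("seed", "out_dir"))]))
  cfg
}

# Segment one denoised image with the classical path: inverted threshold
# -> morphological clean -> hole fill. The input should be denoised but
# NOT histogram-equalized: equalization remaps intensities to quantiles,
# so a fixed mid-grey cutoff would select a fixed image fraction instead
# of the dark worm.
segment_threshold <- function(image, t = 128L, kernel = 3L) {
  fill_holes(morphological_clean(threshold_binarize(image, t), kernel))
}

#' Straighten every image of a synthetic cohort
#'
#' Convenience batch runner for the per-image chain: render, median
#' denoise, threshold segmentation (or ground-truth mask), skeletonize,
#' straighten. Images whose skeleton cannot be ordered (e.g. self-
#' overlapping worms) are dropped.
#'
#' @param cohort A [generate_cohort()] result.
#' @param rows Manifest rows to process (default all).
#' @param use_truth_mask Use the rendered ground-truth mask instead of
#'   threshold segmentation (faster; isolates the straightening step).
#' @param kernel Median/morphology kernel.
#' @param t Threshold for [threshold_binarize()].
#' @param half_width,mode,out_shape Passed to [straighten_worm()].
#' @param equalize Sample strip intensities from the equalized image
#'   (default) rather than the denoised one.
#' @return List with `worms` (straightened worms), `rows` (manifest row
#'   indices actually used).
#' @export
straighten_cohort <- function(cohort, rows = seq_len(nrow(cohort$manifest)),
                              use_truth_mask = FALSE, kernel = 3L, t = 128L,
                              half_width = 15L, mode = "local",
                              out_shape = c(600L, 30L), equalize = TRUE) {
  man <- cohort$manifest
  worms <- list()
  used <- integer(0)
  for (i in rows) {
    res <- tryCatch({
      s <- cohort_sample(cohort, i)
      den <- median_denoise(s$image, kernel)
      src <- if (equalize) to_8bit_grayscale(equalize_histogram(den)) else den
      mask <- if (use_truth_mask) s$mask else
        segment_threshold(den, t, kernel)
      suppressWarnings(straighten_worm(
        src, mask, half_width = half_width, mode = mode,
        out_shape = out_shape, worm_id = man$worm_id[i],
        age_days = man$age_days[i], source_day = man$day[i]))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      worms[[length(worms) + 1L]] <- res
      used <- c(used, i)
    }
  }
  list(worms = worms, rows = used)
}

#' Run the full imaging-to-aging pipeline
#'
#' Executes synthesis, preprocessing, segmentation (threshold path or a
#' U-Net trained on the cohort's ground-truth masks), skeletonization,
#' straightening, WormCNN training for both elderly classification and
#' age regression, evaluation (confusion metrics, ROC/AUC, predicted-age
#' correlation) and the Healthy Aging Index report. All artifacts are
#' written under `config$out_dir`; reruns with the same config and seed
#' reproduce them.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress.
#' @return Invisibly, a list with the cohort, elderly threshold, trained
#'   models, predictions, `metrics`, `roc`, `age_r`, the HAI report and
#'   artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name) say("[%s] %+6.1fs %s", format(Sys.time(), "%H:%M:%S"),
                              as.numeric(difftime(Sys.time(), t0, units = "secs")),
                              name)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(config$out_dir, "config.json"))

  stage("synth: generating cohort")
  law <- do.call(aging_law, c(config$synth$aging,
                              list(accel = config$synth$accel)))
  cohort <- generate_cohort(config$synth$n_worms, seed = config$seed,
                            canvas_shape = config$synth$canvas,
                            aging = law)
  man <- write_cohort(cohort, config$out_dir)

  seg_model <- NULL
  if (config$segment$method == "unet") {
    stage("segment: training U-Net on ground-truth masks")
    n_train <- min(config$segment$train_n, nrow(man))
    idx <- with_seed(config$seed + 11L,
                     sample(nrow(man), n_train))
    imgs <- list(); msks <- list()
    for (k in seq_along(idx)) {
      s <- cohort_sample(cohort, idx[k])
      imgs[[k]] <- pixels_of(preprocess_image(s$image,
                                              config$preprocess$kernel))
      msks[[k]] <- s$mask
    }
    rm(s)
    ucfg <- unet_config(depth = config$segment$depth,
                        base_channels = config$segment$base_channels,
                        epochs = config$segment$epochs,
                        seed = config$seed + 12L)
    seg_model <- train_unet(build_unet(ucfg), imgs, msks)
  }

  stage("preprocess/segment/skeleton/straighten: per-image chain")
  dir.create(file.path(config$out_dir, "strips"), showWarnings = FALSE)
  strips <- vector("list", nrow(man))
  ok <- logical(nrow(man))
  man$strip_path <- NA_character_
  for (i in seq_len(nrow(man))) {
    res <- tryCatch({
      s <- cohort_sample(cohort, i)
      den <- median_denoise(s$image, config$preprocess$kernel)
      pre <- to_8bit_grayscale(equalize_histogram(den))
      mask <- if (is.null(seg_model)) {
        segment_threshold(den, config$segment$t, config$segment$kernel)
      } else {
        fill_holes(morphological_clean(predict_mask(seg_model, pixels_of(pre)),
                                       config$segment$kernel))
      }
      suppressWarnings(straighten_worm(
        pre, mask, half_width = config$straighten$half_width,
        mode = config$straighten$mode, interval = config$skeleton$interval,
        prune = config$skeleton$prune,
        out_shape = config$straighten$out_shape,
        worm_id = man$worm_id[i], age_days = man$age_days[i],
        source_day = man$day[i]))
    }, error = function(e) NULL)
    if (!is.null(res)) {
      strips[[i]] <- res
      ok[i] <- TRUE
      man$strip_path[i] <- file.path("strips",
                                     sprintf("%s_d%02d.png", man$worm_id[i],
                                             man$day[i]))
      write_well_image(res$pixels, file.path(config$out_dir,
                                             man$strip_path[i]))
    }
  }
  if (!any(ok)) stop("pipeline stage 'straighten': no image could be processed")
  if (mean(ok) < 1)
    say("  straightened %d/%d images (%d failed and were dropped)",
        sum(ok), length(ok), sum(!ok))
  write_manifest(man, file.path(config$out_dir, "manifest.csv"))

  stage("aging: survival curve and elderly threshold")
  curve <- survival_curve(cohort$survival)
  threshold <- elderly_age_threshold(curve, config$hai$fraction)
  used <- which(ok)
  ages <- man$age_days[used]
  labels <- as.integer(label_elderly(ages, threshold))

  base_cnn <- function(task, seed_off) {
    wormcnn_config(input_shape = config$cnn$input_shape,
                   stem_filters = config$cnn$stem_filters,
                   n_residual_blocks = config$cnn$n_residual_blocks,
                   task = task, epochs = config$cnn$epochs,
                   learning_rate = config$cnn$learning_rate,
                   batch_size = config$cnn$batch_size,
                   seed = config$seed + seed_off)
  }
  worms_used <- strips[used]

  cls_model <- NULL; metrics <- NULL; roc <- NULL
  if (length(unique(labels)) == 2L) {
    stage("wormcnn: training elderly classifier")
    cls_model <- train_wormcnn(build_wormcnn(base_cnn("classification", 21L)),
                               worms_used, labels)
    cls_pred <- predict(cls_model, worms_used)
    metrics <- compute_metrics(confusion_from_scores(
      cls_pred$elderly_probability, labels))
    roc <- roc_auc(cls_pred$elderly_probability, labels)
  } else {
    say("  skipping classifier: only one class present at threshold %d",
        threshold)
  }

  stage("wormcnn: training age regressor")
  reg_model <- train_wormcnn(build_wormcnn(base_cnn("regression", 22L)),
                             worms_used, ages)
  reg_pred <- predict(reg_model, worms_used)
  age_r <- pearson_r(reg_pred$predicted_age_days, ages)

  stage("hai: report")
  hai <- hai_report(
    data.frame(worm_id = man$worm_id[used],
               predicted_age_days = reg_pred$predicted_age_days),
    data.frame(worm_id = man$worm_id[used], age_days = ages),
    threshold)
  write.csv(hai, file.path(config$out_dir, "hai.csv"), row.names = FALSE)

  summary_json <- list(
    n_worms = nrow(cohort$survival),
    n_images = nrow(man),
    n_straightened = sum(ok),
    elderly_threshold_day = threshold,
    classification = if (!is.null(metrics))
      as.list(metrics_percent(metrics)) else NULL,
    auc = if (!is.null(roc)) roc$auc else NULL,
    age_pearson_r = age_r,
    mean_hai_deviation = mean(hai$deviation))
  jsonlite::write_json(summary_json, file.path(config$out_dir,
                                               "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done")
  invisible(list(cohort = cohort, manifest = man, threshold = threshold,
                 unet = seg_model, classifier = cls_model,
                 regressor = reg_model, metrics = metrics, roc = roc,
                 age_r = age_r, hai = hai, out_dir = config$out_dir))
}
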