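# End-to-end experiment runner: build (or load) a dataset, draw stratified
# splits, train the CNN on images and the GA-SVM cascade on extracted
# features for each split, and evaluate both on the held-out test
# partition.

#' Experiment configuration
#'
#' `paper_mode_config()` mirrors the reference protocol (256 x 256 images,
#' ten splits of 31/45/45 per partition, batch 121 / 50 epochs / lr 0.001,
#' GA 100 x 100); `smoke_config()` is the reduced-budget variant used for
#' continuous testing (64 x 64 images, 2 splits, 5 epochs, GA population 20
#' for 10 generations, well-separated phenotypes).
#'
#' @param data_source `"synthetic"` or `"manifest"`.
#' @param synthetic a [synthetic_config()] (when `data_source` is
#'   `"synthetic"`).
#' @param manifest_path manifest CSV path (when `data_source` is
#'   `"manifest"`).
#' @param n_splits,split_seeds,class_counts split protocol parameters (see
#'   [make_splits()]).
#' @param spec a [network_spec()].
#' @param policy an [augmentation_policy()].
#' @param cnn a [train_config()].
#' @param ga a [ga_config()].
#' @param methods subset of `c("convnet", "svm_ga")` to run.
#' @param features a [feature_options()].
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(data_source = c("synthetic", "manifest"),
                              synthetic = synthetic_config(),
                              manifest_path = NULL,
                              n_splits = 10,
                              split_seeds = seq_len(n_splits),
                              class_counts = c(lymphocyte = 31, pre_T = 45,
                                               pre_B = 45),
                              spec = network_spec(),
                              policy = augmentation_policy(),
                              cnn = train_config(),
                              ga = ga_config(),
                              methods = c("convnet", "svm_ga"),
                              features = feature_options()) {
  data_source <- match.arg(data_source)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(length(split_seeds) == n_splits)
  structure(
    list(data_source = data_source, synthetic = synthetic,
         manifest_path = manifest_path, n_splits = as.integer(n_splits),
         split_seeds = as.integer(split_seeds), class_counts = class_counts,
         spec = spec, policy = policy, cnn = cnn, ga = ga, methods = methods,
         features = features),
    class = "experiment_config"
  )
}

#' @rdname experiment_config
#' @export
paper_mode_config <- function() {
  experiment_config(
    data_source = "synthetic",
    synthetic = synthetic_config(
      n_per_class = c(lymphocyte = 93, pre_T = 135, pre_B = 135),
      image_size = 256, seed = 1
    ),
    n_splits = 10, class_counts = c(lymphocyte = 31, pre_T = 45, pre_B = 45),
    spec = network_spec(input_size = 256),
    policy = augmentation_policy(copies_per_image = 20),
    cnn = train_config(batch_size = 121, epochs = 50, learning_rate = 0.001),
    ga = ga_config(population_size = 100, generations = 100)
  )
}

#' @rdname experiment_config
#' @param seed master seed for the smoke experiment.
#' @export
smoke_config <- function(seed = 1) {
  experiment_config(
    data_source = "synthetic",
    synthetic = synthetic_config(
      n_per_class = c(lymphocyte = 30, pre_T = 36, pre_B = 36),
      image_size = 64, seed = seed,
      per_class_params = default_phenotypes("separated")
    ),
    n_splits = 2, split_seeds = seed + c(0L, 1L),
    class_counts = c(lymphocyte = 10, pre_T = 12, pre_B = 12),
    spec = network_spec(input_size = 64),
    policy = augmentation_policy(copies_per_image = 4),
    cnn = train_config(batch_size = 8, epochs = 5, learning_rate = 0.002,
                       seed = seed),
    ga = ga_config(population_size = 20, generations = 10, seed = seed)
  )
}

experiment_samples <- function(cfg) {
  if (cfg$data_source == "synthetic") {
    generate_dataset(cfg$synthetic)
  } else {
    read_dataset(cfg$manifest_path)
  }
}

#' Run the full experiment
#'
#' For each split: trains the CNN on the split's training images (validated
#' on the validation partition) and the GA-SVM cascade on the features
#' extracted from the same partitions, then evaluates both on the test
#' partition. A failing stage aborts that split with a logged diagnostic;
#' remaining splits proceed.
#'
#' @param cfg an [experiment_config()].
#' @param verbose print per-stage progress.
#' @return an `experiment_report`: `per_split` (list of per-method
#'   [run_metrics()] and confusion matrices), `aggregates` (per-method
#'   [aggregate_metrics()] of accuracy), and `provenance` (seeds, config
#'   hash, package version) — enough to replay the run exactly.
#' @export
run_experiment <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  samples <- experiment_samples(cfg)
  splits <- make_splits(samples, cfg$n_splits, cfg$split_seeds,
                        cfg$class_counts)
  needs_features <- "svm_ga" %in% cfg$methods
  per_split <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    res <- tryCatch({
      out <- list()
      test_truth <- vapply(sp$test, `[[`, "", "label")
      if ("convnet" %in% cfg$methods) {
        say("split %d: training CNN", k)
        cnn_cfg <- cfg$cnn
        cnn_cfg$seed <- derive_seed(cfg$cnn$seed, k)
        model <- train_convnet(sp$train, sp$validation, cfg$spec, cfg$policy,
                               cnn_cfg)
        pred <- predict_convnet(model, sp$test)$labels
        cm <- confusion(test_truth, pred)
        out$convnet <- list(metrics = run_metrics(cm), confusion = cm,
                            training_log = model$training_log)
      }
      if (needs_features) {
        say("split %d: extracting features / GA-SVM", k)
        ftr <- extract_features(sp$train, cfg$features)
        fva <- extract_features(sp$validation, cfg$features)
        fte <- extract_features(sp$test, cfg$features)
        ga_cfg <- cfg$ga
        ga_cfg$seed <- derive_seed(cfg$ga$seed, 1000L + k)
        cascade <- train_cascade(ftr, fva, ga_cfg)
        pred <- predict_cascade(cascade, fte)
        cm <- confusion(test_truth, pred)
        out$svm_ga <- list(
          metrics = run_metrics(cm), confusion = cm,
          params = lapply(cascade[c("stage1", "stage2")], function(s) {
            list(C = s$params$C, gamma = s$params$gamma,
                 n_selected = sum(s$params$mask))
          })
        )
      }
      out
    }, error = function(e) {
      warning(sprintf("split %d aborted: %s", k, conditionMessage(e)))
      NULL
    })
    per_split[[k]] <- res
  }
  ok <- !vapply(per_split, is.null, TRUE)
  aggregates <- lapply(stats::setNames(cfg$methods, cfg$methods), function(m) {
    acc <- vapply(per_split[ok], function(s) s[[m]]$metrics$accuracy, 0)
    if (length(acc) >= 2) aggregate_metrics(acc) else list(mean = mean(acc))
  })
  structure(
    list(per_split = per_split, aggregates = aggregates,
         provenance = list(
           split_seeds = cfg$split_seeds,
           data_seed = if (cfg$data_source == "synthetic") cfg$synthetic$seed else NA,
           cnn_seed = cfg$cnn$seed, ga_seed = cfg$ga$seed,
           methods = cfg$methods,
           package_version = as.character(utils::packageVersion("blastclass")),
           elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
         )),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  for (m in names(x$aggregates)) {
    a <- x$aggregates[[m]]
    if (inherits(a, "aggregate_metrics")) {
      cat(sprintf("  %s accuracy: %.2f ± %.2f over %d splits\n",
                  m, a$mean_2dp, a$sd_2dp, a$n_runs))
    } else {
      cat(sprintf("  %s accuracy: %.2f\n", m, a$mean))
    }
  }
  invisible(x)
}
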