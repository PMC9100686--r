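run_config_schema <- list(
  connectome = c("strategy", "k", "q", "weight"),
  gcn = c("layerWidths", "headWidth", "dropout"),
  cnn = c("convChannels", "kernelSize", "poolSize", "fcWidths", "dropout",
          "zscore"),
  loss = c("lambda", "kernel"),
  train = c("variant", "epochs", "batchSize", "learningRate", "weightDecay",
            "lfWeight", "seed"),
  eval = c("repeats", "testFraction", "stratify"))

#' Read and validate a run configuration
#'
#' The run configuration is a YAML file with nested sections
#' `connectome`, `gcn`, `cnn`, `loss`, `train` and `eval`; every key is
#' optional (defaults are those of [trainConfig()], [gcnBranchConfig()],
#' [cnnBranchConfig()], [prepareCohort()] and [repeatedHoldout()]), and
#' unknown sections or keys are rejected before any computation.
#'
#' @param path YAML file, or a list already parsed.
#' @return list of class `run_config` with complete, validated settings.
#' @export
readRunConfig <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(run_config_schema))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config section '%s'", unknown[1]))
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), run_config_schema[[sec]])
    if (length(bad) > 0L)
      stop(sprintf("unknown key '%s' in config section '%s'", bad[1], sec))
  }
  g <- function(sec, key, default) raw[[sec]][[key]] %||% default
  cfg <- list(
    connectome = list(strategy = g("connectome", "strategy", "knn"),
                      k = g("connectome", "k", 10L),
                      q = g("connectome", "q", 0.2),
                      weight = g("connectome", "weight", "absolute")),
    gcn = gcnBranchConfig(
      layerWidths = g("gcn", "layerWidths", c(64L, 64L)),
      headWidth = g("gcn", "headWidth", 64L),
      dropout = g("gcn", "dropout", 0)),
    cnn = cnnBranchConfig(
      convChannels = g("cnn", "convChannels", c(16L, 32L, 64L, 128L)),
      kernelSize = g("cnn", "kernelSize", 3L),
      poolSize = g("cnn", "poolSize", 2L),
      fcWidths = g("cnn", "fcWidths", c(128L, 64L)),
      dropout = g("cnn", "dropout", 0.5),
      zscore = g("cnn", "zscore", TRUE)),
    loss = list(lambda = g("loss", "lambda", 0.01),
                kernel = g("loss", "kernel", "linear")),
    train = list(variant = g("train", "variant", "multimodal"),
                 epochs = g("train", "epochs", 100L),
                 batchSize = g("train", "batchSize", 16L),
                 learningRate = g("train", "learningRate", 1e-4),
                 weightDecay = g("train", "weightDecay", 0.0015),
                 lfWeight = g("train", "lfWeight", 0.5),
                 seed = g("train", "seed", 1L)),
    eval = list(repeats = g("eval", "repeats", 10L),
                testFraction = g("eval", "testFraction", 0.2),
                stratify = g("eval", "stratify", TRUE)))
  class(cfg) <- "run_config"
  cfg
}

train_config_from_run <- function(cfg, seed = NULL) {
  trainConfig(variant = cfg$train$variant,
              epochs = cfg$train$epochs,
              batchSize = cfg$train$batchSize,
              learningRate = cfg$train$learningRate,
              weightDecay = cfg$train$weightDecay,
              lambda = cfg$loss$lambda,
              mmdKernel = cfg$loss$kernel,
              lfWeight = cfg$train$lfWeight,
              seed = seed %||% cfg$train$seed,
              gcn = cfg$gcn, cnn = cfg$cnn)
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2, compress = FALSE)
  unname(substr(tools::md5sum(f), 1, 10))
}

#' Run the full pipeline on a cohort
#'
#' Composes the stages: manifest loading, connectivity/graph
#' construction, repeated-holdout training and evaluation under the run
#' configuration, and report writing. Outputs (named with a hash of the
#' configuration, so a changed configuration never silently overwrites
#' an older run's files) are: per-repeat metrics TSV, summary TSV,
#' concatenated training-history TSV, a checkpoint of the last repeat's
#' model (RDS, with the configuration embedded), and a plain-text log
#' recording configuration hash, seed and package versions.
#'
#' @param configPath run-configuration YAML (see [readRunConfig()]), or
#'   a `run_config` list.
#' @param manifestPath cohort manifest TSV (see [readCohortManifest()]).
#' @param outDir output directory.
#' @param quiet suppress progress messages (default FALSE).
#' @return Invisibly, a list with the evaluation object and the output
#'   file paths.
#' @export
runPipeline <- function(configPath, manifestPath, outDir,
                        quiet = FALSE) {
  cfg <- if (inherits(configPath, "run_config")) configPath else
    readRunConfig(configPath)
  say <- function(...) if (!quiet) message(sprintf(...))
  hash <- config_hash(cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tag <- function(name) file.path(outDir, sprintf("%s_%s", hash, name))

  say("[%s] loading cohort manifest %s", hash, manifestPath)
  cohort <- readCohortManifest(manifestPath)
  say("[%s] preparing %d subjects (graph strategy: %s)", hash,
      length(cohort), cfg$connectome$strategy)
  prep <- prepareCohort(cohort, strategy = cfg$connectome$strategy,
                        k = cfg$connectome$k, q = cfg$connectome$q,
                        weight = cfg$connectome$weight,
                        zscore = cfg$cnn$zscore)

  histories <- list()
  lastModel <- NULL
  trainFun <- function(trainCohort, seed) {
    tc <- train_config_from_run(cfg, seed = seed)
    model <- trainModel(trainCohort, tc)
    if (nrow(model$history) > 0) {
      h <- model$history
      h$repeat_ <- length(histories) + 1L
      histories[[length(histories) + 1L]] <<- h
    }
    lastModel <<- model
    model
  }
  say("[%s] repeated holdout: %d repeats, test fraction %.2f", hash,
      cfg$eval$repeats, cfg$eval$testFraction)
  ev <- repeatedHoldout(prep, trainFun, nRepeats = cfg$eval$repeats,
                        testFraction = cfg$eval$testFraction,
                        baseSeed = cfg$train$seed,
                        stratify = cfg$eval$stratify)

  paths <- list(perRepeat = tag("metrics_per_repeat.tsv"),
                summary = tag("metrics_summary.tsv"),
                history = tag("training_history.tsv"),
                checkpoint = tag("checkpoint.rds"),
                probs = tag("test_probabilities.tsv"),
                log = tag("run.log"))
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wt(ev$perRepeat, paths$perRepeat)
  wt(ev$summary, paths$summary)
  if (length(histories) > 0) wt(do.call(rbind, histories), paths$history)
  wt(ev$testProbs, paths$probs)
  saveRDS(list(model = lastModel, config = cfg, hash = hash),
          paths$checkpoint)
  writeLines(c(
    sprintf("config_hash: %s", hash),
    sprintf("seed: %d", cfg$train$seed),
    sprintf("variant: %s", cfg$train$variant),
    sprintf("date: %s", format(Sys.time())),
    sprintf("neurofuse: %s",
            as.character(utils::packageVersion("neurofuse"))),
    sprintf("R: %s", R.version.string)), paths$log)
  say("[%s] done; summary written to %s", hash, paths$summary)
  invisible(list(eval = ev, paths = paths, hash = hash))
}
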