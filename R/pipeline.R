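# Reproducible command runner: every subcommand of the command-line
# interface maps onto one package function, takes a seed, writes its
# artifacts under an output directory, and records a manifest (inputs,
# parameters, seed, output checksums). Manifests contain no timestamps,
# so identical (config, seed) runs produce identical manifests; log
# lines carry module, timestamp and seed.

pipeline_log <- function(module, seed, fmt, ...) {
  message(sprintf("[%s] %s seed=%s %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), module, seed,
                  sprintf(fmt, ...)))
}

file_checksums <- function(paths) {
  paths <- unname(unlist(paths))
  # directories contribute the checksums of the files inside them
  expanded <- unlist(lapply(paths, function(p) {
    if (dir.exists(p)) list.files(p, full.names = TRUE, recursive = TRUE)
    else p
  }))
  sums <- tools::md5sum(expanded)
  stats::setNames(as.list(unname(sums)), basename(expanded))
}

#' Run one pipeline command
#'
#' Executes a pipeline stage described by a config list and writes its
#' artifacts plus a `manifest_<command>.json` under `out_dir`. Supported
#' commands: `simulate`, `ewas`, `preselect`, `train-cage`,
#' `predict-cage`, `train-bage`, `predict-bage`, `evaluate`. Input paths
#' are checked before any computation; outputs are deterministic given
#' (config, seed).
#'
#' @param config a named list with `command`, `out_dir`, `seed`, and the
#'   command's parameters (see the CLI script in `inst/cli/` for the
#'   flag-level interface).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$command)) stopf("config$command is required")
  cmd <- config$command
  out_dir <- config$out_dir %||% "."
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  handlers <- list(
    "simulate" = cmd_simulate, "ewas" = cmd_ewas,
    "preselect" = cmd_preselect,
    "train-cage" = cmd_train_cage, "predict-cage" = cmd_predict_cage,
    "train-bage" = cmd_train_bage, "predict-bage" = cmd_predict_bage,
    "evaluate" = cmd_evaluate
  )
  if (!cmd %in% names(handlers)) {
    stopf("unknown command '%s' (known: %s)", cmd,
          paste(names(handlers), collapse = ", "))
  }
  inputs <- unlist(config[grep("_path$|^paths", names(config))])
  if (is.null(inputs)) inputs <- character(0)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L) {
    stopf("input path(s) do not exist: %s", paste(missing_in, collapse = ", "))
  }
  pipeline_log(cmd, seed, "starting (out_dir=%s)", out_dir)
  outputs <- handlers[[cmd]](config, out_dir, seed)
  # parameters carry values only; input files appear as basename+checksum,
  # so manifests are location-independent and identical runs compare equal
  param_keys <- setdiff(names(config),
                        c("command", "out_dir", "seed",
                          grep("_path$|^paths", names(config), value = TRUE)))
  manifest <- list(
    command = cmd, seed = seed,
    parameters = config[param_keys],
    inputs = if (length(inputs)) file_checksums(inputs) else list(),
    outputs = file_checksums(outputs),
    package = as.character(utils::packageVersion("methclocks"))
  )
  manifest_path <- file.path(out_dir, sprintf("manifest_%s.json",
                                              gsub("-", "_", cmd)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  pipeline_log(cmd, seed, "done (%d artifact(s))", length(outputs))
  invisible(manifest)
}

cmd_simulate <- function(config, out_dir, seed) {
  args <- config$sim %||% list()
  args$seed <- seed
  cfg <- do.call(sim_config, args)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, out_dir)
}

read_cohort_dir <- function(dir) {
  list(meth = read_methylation(file.path(dir, "methylation.tsv"), "beta"),
       pheno = read_phenotypes(file.path(dir, "phenotypes.tsv")))
}

cmd_ewas <- function(config, out_dir, seed) {
  model <- config$model %||% "linear"
  meth <- read_methylation(config$meth_path, "beta")
  pheno <- read_phenotypes(config$pheno_path)
  covs <- config$covariates
  M <- suppressWarnings(beta_to_m(meth))
  tab <- switch(model,
                linear = linear_age_ewas(M, pheno, covs),
                quadratic = nested_f_test(linear_age_ewas(M, pheno, covs),
                                          quadratic_age_ewas(M, pheno, covs)),
                cox = cox_mortality_ewas(M, pheno, covs),
                stopf("unknown EWAS model '%s'", model))
  out <- file.path(out_dir, sprintf("ewas_%s.tsv", model))
  write_ewas(tab, out)
  out
}

cmd_preselect <- function(config, out_dir, seed) {
  lin <- read_ewas(config$linear_path, "linear")
  quad <- read_ewas(config$quadratic_path, "quadratic")
  feats <- preselect_features(lin, quad,
                              config$n_linear %||% 10000L,
                              config$n_quadratic %||% 300L)
  out <- file.path(out_dir, "features.tsv")
  utils::write.table(feats, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

read_feature_spec <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("feature_spec", "data.frame"))
}

cmd_train_cage <- function(config, out_dir, seed) {
  cohorts <- lapply(config$paths_cohorts, read_cohort_dir)
  feats <- read_feature_spec(config$features_path)
  models <- train_cage(cohorts, feats, alpha = config$alpha %||% 0.5,
                       k_folds = config$k_folds %||% 25L, seed = seed)
  p1 <- file.path(out_dir, "cage_model_age.tsv")
  p2 <- file.path(out_dir, "cage_model_logage.tsv")
  write_clock_model(models$model_age, p1)
  write_clock_model(models$model_logage, p2)
  c(p1, p2)
}

cmd_predict_cage <- function(config, out_dir, seed) {
  meth <- read_methylation(config$meth_path, "beta")
  m_age <- read_clock_model(config$model_age_path)
  m_log <- read_clock_model(config$model_logage_path)
  pred <- predict_cage(meth, m_age, m_log)
  out <- file.path(out_dir, "cage_predictions.tsv")
  utils::write.table(pred, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

read_bage_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stopf("feature table lacks sample_id")
  df
}

cmd_train_bage <- function(config, out_dir, seed) {
  df <- read_bage_features(config$features_path)
  feat_cols <- setdiff(names(df), c("sample_id", "tte", "event", "batch"))
  X <- as.matrix(df[, feat_cols, drop = FALSE])
  rownames(X) <- df$sample_id
  model <- train_bage(X, df$tte, df$event,
                      alpha = config$alpha %||% 0.5,
                      k_folds = config$k_folds %||% 20L,
                      group_labels = df$batch, seed = seed)
  out <- file.path(out_dir, "bage_model.tsv")
  write_bage_model(model, out)
  out
}

cmd_predict_bage <- function(config, out_dir, seed) {
  df <- read_bage_features(config$features_path)
  model <- read_bage_model(config$model_path)
  X <- as.matrix(df[, setdiff(names(df), c("sample_id", "tte", "event",
                                           "batch")), drop = FALSE])
  rownames(X) <- df$sample_id
  bage <- compute_bage(X, model)
  out_tab <- data.frame(sample_id = df$sample_id, bage = bage)
  if ("age" %in% names(df)) {
    out_tab$bage_accel <- compute_age_accel(bage, df$age)
  }
  out <- file.path(out_dir, "bage_predictions.tsv")
  utils::write.table(out_tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

cmd_evaluate <- function(config, out_dir, seed) {
  pred <- utils::read.table(config$pred_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  pheno <- read_phenotypes(config$pheno_path)
  ix <- match(pred$sample_id, pheno$sample_id)
  if (anyNA(ix)) stopf("prediction sample ids missing from phenotype table")
  task <- config$task %||% "cage"
  out <- file.path(out_dir, sprintf("evaluation_%s.json", task))
  if (task == "cage") {
    m <- regression_metrics(pred$cage, pheno$age[ix])
    jsonlite::write_json(unclass(m), out, auto_unbox = TRUE, digits = NA)
  } else if (task == "bage") {
    assoc <- cox_association(pred$bage_accel %||% pred$bage,
                             pheno$tte[ix], pheno$event[ix],
                             age = pheno$age[ix], sex = pheno$sex[ix])
    keep <- c("hr_per_sd", "ci95", "p", "loghr", "se_loghr", "n", "n_events")
    jsonlite::write_json(unclass(assoc)[keep], out, auto_unbox = TRUE,
                         digits = NA)
  } else stopf("unknown evaluation task '%s'", task)
  out
}
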