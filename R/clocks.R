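# Clock orchestration: chronological-age (cAge) clocks on age and
# log(age), the hybrid prediction rule, EpiScore projection, the
# mortality-trained biological-age (bAge) clock, and age-acceleration
# residuals.

#' Build the clock feature matrix from a beta-value methylation matrix
#'
#' Linear features are the beta values themselves; squared features are
#' the squared beta values (column `<cpg>_sq`). Missing model CpGs are a
#' hard error — silent zero-fill would shift predictions invisibly.
#'
#' @param matrix beta-scale methylation matrix.
#' @param features a `feature_spec` from [preselect_features()], or any
#'   data.frame with `cpg` and `transform` columns.
#' @return numeric matrix, one column per feature.
#' @export
build_feature_matrix <- function(matrix, features) {
  if (meth_scale(matrix) != "beta") {
    stopf("clock features are defined on the beta-value scale")
  }
  miss <- setdiff(unique(features$cpg), colnames(matrix))
  if (length(miss) > 0L) {
    stopf("missing model CpG(s) in methylation matrix: %s%s",
          paste(utils::head(miss, 10L), collapse = ", "),
          if (length(miss) > 10L) sprintf(" (+%d more)", length(miss) - 10L) else "")
  }
  cols <- matrix[, features$cpg, drop = FALSE]
  sq <- features$transform == "squared"
  cols[, sq] <- cols[, sq, drop = FALSE]^2
  colnames(cols) <- ifelse(sq, paste0(features$cpg, "_sq"), features$cpg)
  cols
}

pool_cohorts <- function(cohorts) {
  meths <- lapply(cohorts, `[[`, "meth")
  phenos <- lapply(cohorts, `[[`, "pheno")
  if (length(meths) > 1L) meths <- intersect_cpgs(meths)
  meth <- do.call(rbind, meths)
  attr(meth, "meth_scale") <- meth_scale(meths[[1L]])
  pheno <- do.call(rbind, lapply(phenos, function(p) {
    p[, Reduce(intersect, lapply(phenos, names)), drop = FALSE]
  }))
  rownames(pheno) <- NULL
  if (anyDuplicated(pheno$sample_id)) stopf("duplicate sample ids across cohorts")
  list(meth = as_methylation(meth, meth_scale(meths[[1L]])), pheno = pheno)
}

#' Train chronological-age clocks
#'
#' Pools the cohorts (restricted to their common CpGs), builds the
#' pre-selected beta-value features, and fits two elastic-net models on
#' the pooled samples: one with age as outcome and one with log(age).
#' Cross-validation folds are grouped (by batch when available) and the
#' shrinkage parameter minimizes the mean cross-validated squared error.
#'
#' @param cohorts list of cohorts, each a list with `meth` (beta scale)
#'   and `pheno` (with `age`; `batch` used for fold grouping when present).
#' @param features a `feature_spec` from [preselect_features()].
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param k_folds number of CV folds (default 25).
#' @param seed fold-assignment seed.
#' @param group_by phenotype column defining fold groups (default
#'   `"batch"` when present; `NULL` for ungrouped folds).
#' @param nlambda,lambda_min_ratio lambda-grid shape, see [fit_elastic_net()].
#' @return a list with `model_age` and `model_logage`, both of class
#'   `clock_model`.
#' @export
train_cage <- function(cohorts, features, alpha = 0.5, k_folds = 25L,
                       seed = 1L, group_by = "batch",
                       nlambda = 100L, lambda_min_ratio = 0.001) {
  if (!is.null(cohorts$meth)) cohorts <- list(cohorts)  # single cohort given
  pooled <- pool_cohorts(cohorts)
  age <- pooled$pheno$age
  if (any(age <= 0)) stopf("all ages must be > 0 (log(age) outcome)")
  if (stats::sd(age) == 0) stopf("outcome age has zero variance")
  Xf <- build_feature_matrix(pooled$meth, features)
  groups <- if (!is.null(group_by) && group_by %in% names(pooled$pheno)) {
    paste(pooled$pheno$cohort %||% "", pooled$pheno[[group_by]])
  } else NULL
  folds <- make_folds(pooled$pheno$sample_id, k_folds, groups, seed = seed)
  fit_age <- fit_elastic_net(Xf, age, alpha = alpha, folds = folds,
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio)
  fit_log <- fit_elastic_net(Xf, log(age), alpha = alpha, folds = folds,
                             nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio)
  meta <- list(alpha = alpha, k_folds = k_folds, seed = seed,
               cohorts = paste(unique(pooled$pheno$cohort), collapse = ","),
               n_train = nrow(Xf))
  list(model_age = as_clock_model(fit_age, features, "identity", "cage",
                                  meta),
       model_logage = as_clock_model(fit_log, features, "log", "cage_log",
                                     meta))
}

as_clock_model <- function(path, features, outcome_transform, name, meta) {
  cf <- coef(path)
  b <- cf[-1L]
  nz <- which(b != 0)
  w <- data.frame(feature = names(b)[nz],
                  cpg = features$cpg[match(names(b)[nz], features$feature)],
                  transform = features$transform[match(names(b)[nz],
                                                       features$feature)],
                  weight = unname(b[nz]),
                  stringsAsFactors = FALSE)
  structure(list(name = name, intercept = unname(cf[1L]), weights = w,
                 outcome_transform = outcome_transform,
                 metadata = c(meta, list(
                   lambda_selected = path$lambda_selected,
                   n_features_offered = length(b),
                   n_features_selected = nrow(w),
                   sex_coding = "female=1,male=0"))),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("Clock model '%s' (outcome: %s): intercept %.4g, %d nonzero weights\n",
              x$name,
              if (x$outcome_transform == "log") "log(age), predictions exponentiated"
              else "age (years)",
              x$intercept, nrow(x$weights)))
  if (!is.null(x$metadata$lambda_selected)) {
    cat(sprintf("  alpha = %s, lambda = %.6g, trained on n = %s\n",
                x$metadata$alpha, x$metadata$lambda_selected,
                x$metadata$n_train %||% "?"))
  }
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) {
  stats::setNames(c(object$intercept, object$weights$weight),
                  c("(Intercept)", object$weights$feature))
}

clock_linear_predictor <- function(matrix, model) {
  feats <- model$weights[, c("cpg", "transform")]
  feats$feature <- model$weights$feature
  X <- build_feature_matrix(matrix, feats)
  as.numeric(model$intercept + X %*% model$weights$weight)
}

#' Predict chronological age with the hybrid log(age) rule
#'
#' Computes the age-model prediction for every sample; whenever that
#' prediction is 20 years or younger (inclusive), it is replaced by the
#' exponentiated prediction of the log(age) model, and the branch taken
#' is recorded.
#'
#' @param matrix beta-scale methylation matrix containing every model CpG.
#' @param model_age,model_logage `clock_model`s from [train_cage()].
#' @param threshold hybrid switch point in years (default 20, inclusive).
#' @return data.frame with `sample_id`, `cage` (predicted years) and
#'   `branch` (`"age"` or `"log"`).
#' @export
predict_cage <- function(matrix, model_age, model_logage, threshold = 20) {
  stopifnot(inherits(model_age, "clock_model"),
            inherits(model_logage, "clock_model"))
  if (model_logage$outcome_transform != "log") {
    stopf("model_logage must have the log outcome transform")
  }
  pred <- clock_linear_predictor(matrix, model_age)
  use_log <- pred <= threshold
  if (any(use_log)) {
    lp_log <- clock_linear_predictor(matrix, model_logage)
    pred[use_log] <- exp(lp_log[use_log])
  }
  data.frame(sample_id = rownames(matrix), cage = pred,
             branch = ifelse(use_log, "log", "age"),
             stringsAsFactors = FALSE)
}

#' Project protein EpiScores onto a methylation matrix
#'
#' Each protein score is `intercept + sum(weight * beta)` over its model
#' CpGs — a plain linear projection with no scaling at this stage.
#'
#' @param matrix beta-scale methylation matrix.
#' @param panel list of `episcore_model`s (see
#'   [simulate_episcore_panel()] or [read_episcore_model()]).
#' @return samples x proteins numeric matrix of scores.
#' @export
project_episcores <- function(matrix, panel) {
  if (meth_scale(matrix) != "beta") stopf("EpiScores are defined on beta values")
  if (inherits(panel, "episcore_model")) panel <- list(panel)
  need <- unique(unlist(lapply(panel, function(m) names(m$weights))))
  miss <- setdiff(need, colnames(matrix))
  if (length(miss) > 0L) {
    stopf("missing EpiScore CpG(s): %s", paste(miss, collapse = ", "))
  }
  scores <- vapply(panel, function(m) {
    m$intercept + as.numeric(matrix[, names(m$weights), drop = FALSE] %*%
                               m$weights)
  }, numeric(nrow(matrix)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = nrow(matrix))
  colnames(scores) <- vapply(panel, `[[`, character(1L), "name")
  rownames(scores) <- rownames(matrix)
  scores
}

#' Train the biological-age (mortality) clock
#'
#' Z-scores every feature within the training dataset (the clock's
#' standardization contract), then fits a Cox elastic net of time to
#' all-cause mortality with grouped cross-validation, selecting the
#' shrinkage parameter that maximizes the mean held-out Harrell's C.
#' Features with nonzero weight at the selected lambda are retained.
#'
#' @param features_table data.frame or matrix of raw features
#'   (conventionally chronological age, sex, a smoking score and protein
#'   EpiScores), one row per sample.
#' @param tte,event survival outcome.
#' @param alpha elastic-net mixing parameter (default 0.5).
#' @param k_folds number of CV folds (default 20).
#' @param group_labels optional fold-grouping labels (e.g. batch).
#' @param seed fold seed.
#' @param nlambda,lambda_min_ratio lambda grid shape.
#' @return an object of class `bage_model` with the selected features,
#'   their Cox weights on the z-scored scale, and the standardization
#'   contract.
#' @export
train_bage <- function(features_table, tte, event, alpha = 0.5,
                       k_folds = 20L, group_labels = NULL, seed = 1L,
                       nlambda = 100L, lambda_min_ratio = 0.001) {
  X <- as.matrix(features_table)
  if (is.null(colnames(X))) stopf("features_table needs column names")
  Xz <- scale(X)   # z-score within the training dataset (n-1 sd)
  if (any(!is.finite(Xz))) stopf("zero-variance feature(s) cannot be z-scored")
  folds <- make_folds(rownames(X) %||% as.character(seq_len(nrow(X))),
                      k_folds, group_labels, seed = seed)
  path <- fit_cox_elastic_net(Xz, tte, event, alpha = alpha, folds = folds,
                              nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)
  b <- coef(path)[-1L]
  nz <- which(b != 0)
  if (length(nz) == 0L) {
    warnf("selected lambda retains no features (null bAge model)")
  }
  structure(list(
    features = colnames(X)[nz],
    weights = stats::setNames(unname(b[nz]), colnames(X)[nz]),
    standardization = "zscore_within_dataset",
    output_contract = "linear predictor z-scored within dataset",
    metadata = list(alpha = alpha, k_folds = k_folds, seed = seed,
                    lambda_selected = path$lambda_selected,
                    cv_cindex = if (!is.null(path$cv)) {
                      path$cv$mean[which.max(path$cv$mean)]
                    } else NA_real_,
                    n_train = nrow(X), n_events = sum(event),
                    sex_coding = "female=1,male=0"),
    path = path
  ), class = "bage_model")
}

#' @export
print.bage_model <- function(x, ...) {
  cat(sprintf("bAge model: %d selected features (alpha = %g, lambda = %.5g, CV C = %.3f)\n",
              length(x$features), x$metadata$alpha,
              x$metadata$lambda_selected, x$metadata$cv_cindex))
  if (length(x$features) > 0L) {
    print(round(x$weights, 5))
  }
  invisible(x)
}

#' @export
coef.bage_model <- function(object, ...) object$weights

#' Compute bAge scores
#'
#' Applies the bAge standardization contract: each model feature is
#' z-scored within the scoring dataset, combined with the Cox weights,
#' and the resulting linear predictor is itself z-scored within the
#' dataset (mean 0, SD 1). bAge is therefore a cohort-relative measure.
#'
#' @param features_table raw feature table containing every model feature.
#' @param model a `bage_model`.
#' @return named numeric vector of z-scaled bAge values.
#' @export
compute_bage <- function(features_table, model) {
  stopifnot(inherits(model, "bage_model"))
  X <- as.matrix(features_table)
  miss <- setdiff(model$features, colnames(X))
  if (length(miss) > 0L) {
    stopf("missing bAge feature(s): %s", paste(miss, collapse = ", "))
  }
  Xz <- scale(X[, model$features, drop = FALSE])
  if (any(!is.finite(Xz))) stopf("zero-variance feature(s) in scoring dataset")
  lp <- as.numeric(Xz %*% model$weights)
  if (stats::sd(lp) == 0) stopf("bAge linear predictor has zero variance")
  out <- as.numeric(scale(lp))
  names(out) <- rownames(X)
  out
}

#' Age-acceleration residuals
#'
#' Residuals of the clock prediction regressed on chronological age by
#' simple least squares; by construction orthogonal to age and to the
#' constant. Positive values indicate an epigenetic profile "older" than
#' calendar age.
#'
#' @param predictions clock output (e.g. bAge), one value per sample.
#' @param age chronological age in years.
#' @return numeric vector of residuals.
#' @export
compute_age_accel <- function(predictions, age) {
  n <- length(predictions)
  if (length(age) != n) stopf("length mismatch")
  if (n < 3L) stopf("need at least 3 samples")
  if (stats::sd(age) == 0) stopf("age is constant; residuals undefined")
  fit <- stats::lm.fit(cbind(1, age), predictions)
  stats::setNames(as.numeric(fit$residuals), names(predictions))
}

#' Serialize and load clock models
#'
#' Clock, EpiScore and bAge models are written as weight tables
#' ([write_weight_table()]) with a metadata header block (model type,
#' outcome transform, scaling contract, training parameters).
#'
#' @param model a `clock_model`, `episcore_model` or `bage_model`.
#' @param path file path.
#' @return readers return the reconstructed model object.
#' @export
write_clock_model <- function(model, path) {
  stopifnot(inherits(model, "clock_model"))
  meta <- c(list(model_type = "clock", name = model$name,
                 outcome_transform = model$outcome_transform),
            model$metadata[c("alpha", "lambda_selected", "sex_coding")])
  write_weight_table(model$weights, model$intercept, path,
                     meta = meta[!vapply(meta, is.null, logical(1L))])
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  wt <- read_weight_table(path)
  w <- wt$weights
  w$cpg <- sub("_sq$", "", w$feature)
  structure(list(name = wt$meta$name %||% "clock",
                 intercept = wt$intercept,
                 weights = w[, c("feature", "cpg", "transform", "weight")],
                 outcome_transform = wt$meta$outcome_transform %||% "identity",
                 metadata = wt$meta),
            class = "clock_model")
}

#' @rdname write_clock_model
#' @export
write_episcore_model <- function(model, path) {
  stopifnot(inherits(model, "episcore_model"))
  w <- data.frame(feature = names(model$weights), transform = "linear",
                  weight = unname(model$weights), stringsAsFactors = FALSE)
  write_weight_table(w, model$intercept, path,
                     meta = list(model_type = "episcore", name = model$name,
                                 scale = "beta"))
}

#' @rdname write_clock_model
#' @export
read_episcore_model <- function(path) {
  wt <- read_weight_table(path)
  structure(list(name = wt$meta$name %||% "episcore",
                 intercept = wt$intercept,
                 weights = stats::setNames(wt$weights$weight,
                                           wt$weights$feature)),
            class = "episcore_model")
}

#' @rdname write_clock_model
#' @export
write_bage_model <- function(model, path) {
  stopifnot(inherits(model, "bage_model"))
  w <- data.frame(feature = model$features, transform = "linear",
                  weight = unname(model$weights), stringsAsFactors = FALSE)
  write_weight_table(w, 0, path,
                     meta = list(model_type = "bage",
                                 standardization = model$standardization,
                                 output_contract = model$output_contract,
                                 alpha = model$metadata$alpha,
                                 lambda_selected = model$metadata$lambda_selected,
                                 sex_coding = "female=1,male=0"))
}

#' @rdname write_clock_model
#' @export
read_bage_model <- function(path) {
  wt <- read_weight_table(path)
  structure(list(features = wt$weights$feature,
                 weights = stats::setNames(wt$weights$weight,
                                           wt$weights$feature),
                 standardization = wt$meta$standardization %||%
                   "zscore_within_dataset",
                 output_contract = wt$meta$output_contract %||%
                   "linear predictor z-scored within dataset",
                 metadata = wt$meta),
            class = "bage_model")
}
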