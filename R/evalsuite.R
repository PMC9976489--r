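# Performance metrics, survival-association testing, fixed-effects
# meta-analysis, proportional-hazards diagnostics and the
# leave-one-cohort-out harness.

#' Regression accuracy metrics for age prediction
#'
#' Pearson correlation, root mean square error, and MAE. Note that MAE
#' here is the MEDIAN absolute error — the convention of the
#' epigenetic-clock literature — not the mean; the mean absolute error
#' is additionally reported as `mean_abs_error`.
#'
#' @param pred,truth equal-length finite numeric vectors (n >= 3).
#' @return a list of class `regression_metrics`: `r`, `rmse`, `mae`
#'   (median absolute error), `mean_abs_error`, `n`.
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stopf("pred and truth lengths differ")
  if (length(pred) < 3L) stopf("need at least 3 observations")
  if (any(!is.finite(pred)) || any(!is.finite(truth))) {
    stopf("non-finite values in pred/truth")
  }
  err <- pred - truth
  r <- if (stats::sd(pred) == 0 || stats::sd(truth) == 0) NA_real_
       else stats::cor(pred, truth)
  structure(list(r = r, rmse = sqrt(mean(err^2)),
                 mae = stats::median(abs(err)),
                 mean_abs_error = mean(abs(err)),
                 n = length(pred)),
            class = "regression_metrics")
}

#' @export
print.regression_metrics <- function(x, ...) {
  cat(sprintf("n = %d: r = %.3f, RMSE = %.3f, MAE (median) = %.3f, mean |err| = %.3f\n",
              x$n, x$r, x$rmse, x$mae, x$mean_abs_error))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of concordant pairs among comparable pairs. A pair is
#' comparable when the strictly earlier time is an event (pairs with
#' tied times are not comparable); it is concordant when the
#' earlier-failing sample has the higher risk score, and score ties
#' count one half.
#'
#' @param score risk score (higher = earlier expected failure).
#' @param tte,event survival outcome.
#' @return concordance in \[0, 1\].
#' @export
harrells_c <- function(score, tte, event) {
  n <- length(score)
  if (length(tte) != n || length(event) != n) stopf("length mismatch")
  conc <- 0; comp <- 0
  ev <- which(event == 1)
  if (length(ev) == 0L) stopf("no comparable pairs (no events)")
  for (i in ev) {
    later <- tte > tte[i]
    m <- sum(later)
    if (m == 0L) next
    comp <- comp + m
    conc <- conc + sum(score[i] > score[later]) +
      0.5 * sum(score[i] == score[later])
  }
  if (comp == 0) stopf("no comparable pairs")
  conc / comp
}

#' Association between an age-acceleration measure and mortality
#'
#' Fits a Cox proportional-hazards model of time to all-cause mortality
#' on the z-scored acceleration measure, adjusting for chronological age
#' and sex, and reports the hazard ratio per standard deviation with a
#' Wald confidence interval.
#'
#' @param accel acceleration measure (z-scored internally, so the HR is
#'   per SD and scale-invariant).
#' @param tte,event survival outcome.
#' @param age,sex adjustment covariates (optional but conventional).
#' @param conf_level confidence level (default 0.95).
#' @return a list of class `survival_association`: `hr_per_sd`, `ci95`,
#'   `p`, `loghr`, `se_loghr`, `n`, `n_events`, `covariates`, `flag`.
#' @export
cox_association <- function(accel, tte, event, age = NULL, sex = NULL,
                            conf_level = 0.95) {
  if (stats::sd(accel) == 0) stopf("acceleration measure has zero variance")
  X <- cbind(accel_z = as.numeric(scale(accel)))
  covs <- character(0)
  if (!is.null(age)) { X <- cbind(X, age = age); covs <- c(covs, "age") }
  if (!is.null(sex)) { X <- cbind(X, sex = sex); covs <- c(covs, "sex") }
  fit <- cox_fit(X, tte, event)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  b <- fit$coef[1L]; se <- fit$se[1L]
  structure(list(hr_per_sd = exp(b),
                 ci95 = exp(c(b - zq * se, b + zq * se)),
                 p = fit$p_value[1L],
                 loghr = unname(b), se_loghr = unname(se),
                 n = fit$n, n_events = fit$n_events,
                 covariates = covs,
                 flag = if (fit$converged) NA_character_ else fit$flag,
                 fit = fit),
            class = "survival_association")
}

#' @export
print.survival_association <- function(x, ...) {
  cat(sprintf("HR per SD = %.3f [%.3f, %.3f], p = %s (n = %d, events = %d%s)\n",
              x$hr_per_sd, x$ci95[1L], x$ci95[2L], format.pval(x$p),
              x$n, x$n_events,
              if (length(x$covariates)) paste0("; adjusted for ",
                                               paste(x$covariates, collapse = ", "))
              else ""))
  invisible(x)
}

#' Fixed-effects (inverse-variance) meta-analysis of log hazard ratios
#'
#' Pools per-study log-HR estimates with weights 1/se^2: pooled log-HR =
#' sum(w*theta)/sum(w), pooled SE = sqrt(1/sum(w)).
#'
#' @param per_study a list of `survival_association` objects, or a
#'   data.frame with columns `loghr` and `se` (optionally `study`).
#' @param conf_level confidence level for the pooled interval.
#' @return a list of class `meta_result` with pooled log-HR, SE, HR with
#'   CI, p, and the per-study input table.
#' @export
fixed_effects_meta <- function(per_study, conf_level = 0.95) {
  if (is.data.frame(per_study)) {
    tab <- data.frame(study = per_study$study %||%
                        sprintf("study%d", seq_len(nrow(per_study))),
                      loghr = per_study$loghr, se = per_study$se)
  } else {
    tab <- data.frame(
      study = names(per_study) %||% sprintf("study%d", seq_along(per_study)),
      loghr = vapply(per_study, function(s) s$loghr, numeric(1L)),
      se = vapply(per_study, function(s) s$se_loghr, numeric(1L))
    )
  }
  if (nrow(tab) < 1L) stopf("need at least one study")
  if (any(!is.finite(tab$se)) || any(tab$se <= 0)) {
    stopf("every study needs a finite positive SE")
  }
  w <- 1 / tab$se^2
  theta <- sum(w * tab$loghr) / sum(w)
  se <- sqrt(1 / sum(w))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(loghr = theta, se = se,
                 hr = exp(theta),
                 ci = exp(c(theta - zq * se, theta + zq * se)),
                 p = 2 * stats::pnorm(-abs(theta / se)),
                 per_study = tab),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Fixed-effects meta-analysis of %d studies: HR = %.3f [%.3f, %.3f], p = %s\n",
              nrow(x$per_study), x$hr, x$ci[1L], x$ci[2L], format.pval(x$p)))
  invisible(x)
}

# Kaplan-Meier curve evaluated just before each observation's time:
# returns g(t) = 1 - S(t-) for the conventional KM time transform.
km_transform <- function(tte, event) {
  ut <- sort(unique(tte))
  n_risk <- vapply(ut, function(t) sum(tte >= t), numeric(1L))
  n_ev <- vapply(ut, function(t) sum(tte == t & event == 1), numeric(1L))
  surv <- cumprod(1 - n_ev / n_risk)
  idx <- findInterval(tte, ut, left.open = TRUE)
  1 - c(1, surv)[idx + 1L]
}

#' Test of the proportional-hazards assumption (scaled Schoenfeld residuals)
#'
#' Score test for a time-varying coefficient `beta_j(t) = beta_j +
#' theta_j * g(t)` in a fitted Cox model, per covariate and globally. The
#' per-event Schoenfeld residuals are combined with the centred
#' transformed times through the information matrix of the
#' time-expanded model, the standard formulation of the
#' Grambsch-Therneau diagnostic. The default time transform is the
#' Kaplan-Meier transform `g(t) = 1 - S_KM(t-)`.
#'
#' @param fit a converged [cox_fit()].
#' @param transform `"km"`, `"identity"` or `"rank"`.
#' @return a list of class `schoenfeld_test` with a per-variable table
#'   (chisq, df, p), the global test, the residuals and the transform.
#' @export
schoenfeld_test <- function(fit, transform = c("km", "identity", "rank")) {
  stopifnot(inherits(fit, "cox_fit"))
  transform <- match.arg(transform)
  if (fit$n_events < 3) stopf("need at least 3 events")
  prep <- cox_prep(fit$tte, fit$event)
  si <- cox_score_info(fit$X, fit$eta, prep)
  p <- ncol(fit$X)

  g_all <- switch(transform,
                  km = km_transform(fit$tte, fit$event),
                  identity = fit$tte,
                  rank = rank(fit$tte))
  g_all <- g_all - mean(g_all[fit$event == 1])

  # per distinct event time: risk-set covariance V_g and residual sums
  x_s <- fit$X[prep$ord, , drop = FALSE]
  eta_s <- fit$eta[prep$ord]
  ew <- exp(eta_s)
  wx <- ew * x_s
  S0 <- cumsum(ew)[prep$grp_end]
  xbar <- si$xbar
  egrp <- prep$event_grp
  A <- B <- C <- matrix(0, p, p)
  u <- numeric(p)
  g_s <- g_all[prep$ord]
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- cumsum(wx[, j] * x_s[, k])[prep$grp_end]
      Vjk <- S2jk / S0 - xbar[, j] * xbar[, k]
      a <- sum(prep$d_grp[egrp] * Vjk[egrp])
      A[j, k] <- A[k, j] <- a
    }
  }
  ev_pos <- which(prep$d_s > 0)
  g_ev <- g_s[ev_pos]
  res <- x_s[ev_pos, , drop = FALSE] - xbar[prep$grp[ev_pos], , drop = FALSE]
  u <- as.numeric(crossprod(res, g_ev))
  # g-weighted information blocks (per event individual, Breslow)
  g_grp_sum <- tapply(g_ev, prep$grp[ev_pos], sum)
  g2_grp_sum <- tapply(g_ev^2, prep$grp[ev_pos], sum)
  gi <- as.integer(names(g_grp_sum))
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- cumsum(wx[, j] * x_s[, k])[prep$grp_end]
      Vjk <- S2jk / S0 - xbar[, j] * xbar[, k]
      b <- sum(as.numeric(g_grp_sum) * Vjk[gi])
      cc <- sum(as.numeric(g2_grp_sum) * Vjk[gi])
      B[j, k] <- B[k, j] <- b
      C[j, k] <- C[k, j] <- cc
    }
  }

  test_stat <- function(cols) {
    M <- rbind(cbind(A, B[, cols, drop = FALSE]),
               cbind(t(B[, cols, drop = FALSE]),
                     C[cols, cols, drop = FALSE]))
    uu <- c(rep(0, p), u[cols])
    drop(uu %*% solve(M, uu))
  }
  per_var <- vapply(seq_len(p), function(j) test_stat(j), numeric(1L))
  global <- test_stat(seq_len(p))
  tab <- data.frame(
    variable = colnames(fit$X),
    chisq = per_var, df = 1,
    p = stats::pchisq(per_var, 1, lower.tail = FALSE)
  )
  structure(list(table = tab,
                 global = list(chisq = global, df = p,
                               p = stats::pchisq(global, p, lower.tail = FALSE)),
                 residuals = res, time = prep$t_s[ev_pos],
                 transform = transform),
            class = "schoenfeld_test")
}

#' @export
print.schoenfeld_test <- function(x, ...) {
  cat(sprintf("Proportional-hazards score test (%s time transform)\n", x$transform))
  print(x$table, digits = 4, row.names = FALSE)
  cat(sprintf("GLOBAL: chisq = %.4g, df = %d, p = %s\n",
              x$global$chisq, x$global$df, format.pval(x$global$p)))
  invisible(x)
}

#' Leave-one-cohort-out evaluation harness
#'
#' For each held-out cohort (optionally excluding an anchor cohort that
#' always stays in training), trains a model on all remaining cohorts
#' and evaluates it on the held-out one. The provenance log records, for
#' every round, the training cohorts and the held-out cohort; combined
#' metrics are computed over the concatenation of all held-out
#' predictions.
#'
#' @param cohorts named list of cohorts; each element is a list with at
#'   least `meth` and `pheno` (the shape [simulate_cohort()] returns).
#' @param train_fn function(list_of_cohorts) -> model.
#' @param predict_fn function(model, cohort) -> numeric predictions,
#'   aligned with `cohort$pheno$age`.
#' @param anchor optional cohort name always kept in training and never
#'   held out.
#' @return a list of class `loco_result`: per-cohort
#'   [regression_metrics()], combined metrics, predictions, and the
#'   provenance log.
#' @export
loco_harness <- function(cohorts, train_fn, predict_fn, anchor = NULL) {
  if (length(cohorts) < 2L) stopf("need at least 2 cohorts")
  if (is.null(names(cohorts))) names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  test_set <- setdiff(names(cohorts), anchor)
  if (length(test_set) == 0L) stopf("no cohorts left to hold out")
  provenance <- list()
  per_cohort <- list()
  all_pred <- all_truth <- numeric(0)
  for (nm in test_set) {
    train_names <- setdiff(names(cohorts), nm)
    model <- tryCatch(train_fn(cohorts[train_names]),
                      error = function(e) {
                        stopf("training failed in LOCO round '%s': %s", nm,
                              conditionMessage(e))
                      })
    pred <- predict_fn(model, cohorts[[nm]])
    truth <- cohorts[[nm]]$pheno$age
    per_cohort[[nm]] <- regression_metrics(pred, truth)
    provenance[[nm]] <- list(held_out = nm, trained_on = train_names)
    all_pred <- c(all_pred, pred); all_truth <- c(all_truth, truth)
  }
  structure(list(per_cohort = per_cohort,
                 combined = regression_metrics(all_pred, all_truth),
                 predictions = data.frame(
                   cohort = rep(test_set, vapply(per_cohort, `[[`, 0L, "n")),
                   pred = all_pred, age = all_truth),
                 provenance = provenance,
                 anchor = anchor),
            class = "loco_result")
}

#' @export
print.loco_result <- function(x, ...) {
  cat(sprintf("Leave-one-cohort-out over %d held-out cohorts%s\n",
              length(x$per_cohort),
              if (!is.null(x$anchor)) sprintf(" (anchor: %s)", x$anchor) else ""))
  for (nm in names(x$per_cohort)) {
    m <- x$per_cohort[[nm]]
    cat(sprintf("  %-12s r = %.3f  RMSE = %.3f  MAE = %.3f  (n = %d)\n",
                nm, m$r, m$rmse, m$mae, m$n))
  }
  cat("combined: "); print(x$combined)
  invisible(x)
}

#' Forest-plot-ready association table
#'
#' Flattens per-study survival associations (plus an optional pooled
#' row) into a table of study, HR and CI bounds.
#'
#' @param per_study named list of `survival_association`s.
#' @param meta optional `meta_result` appended as a `pooled` row.
#' @return a data.frame with columns study, hr, low, high, p.
#' @export
forest_table <- function(per_study, meta = NULL) {
  tab <- data.frame(
    study = names(per_study) %||% sprintf("study%d", seq_along(per_study)),
    hr = vapply(per_study, function(s) s$hr_per_sd, numeric(1L)),
    low = vapply(per_study, function(s) s$ci95[1L], numeric(1L)),
    high = vapply(per_study, function(s) s$ci95[2L], numeric(1L)),
    p = vapply(per_study, function(s) s$p, numeric(1L))
  )
  if (!is.null(meta)) {
    tab <- rbind(tab, data.frame(study = "pooled", hr = meta$hr,
                                 low = meta$ci[1L], high = meta$ci[2L],
                                 p = meta$p))
  }
  rownames(tab) <- NULL
  tab
}
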