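# Cox proportional-hazards machinery (Breslow tie handling) used by the
# per-CpG mortality EWAS, the survival-association evaluator and the
# penalized Cox solver's outer loop.

# Precompute the time ordering and tie-group bookkeeping for (tte, event).
# Samples are sorted by decreasing time so that the risk set at any time
# is a prefix and risk-set sums become cumulative sums.
cox_prep <- function(tte, event) {
  n <- length(tte)
  if (length(event) != n) stopf("tte and event lengths differ")
  if (any(!is.finite(tte)) || any(tte < 0)) stopf("tte must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stopf("event must be 0/1")
  if (sum(event) == 0L) stopf("no events in the data")
  ord <- order(tte, decreasing = TRUE)
  t_s <- tte[ord]; d_s <- as.numeric(event[ord])
  r <- rle(t_s)
  grp <- rep(seq_along(r$lengths), r$lengths)     # tie group per position
  grp_end <- cumsum(r$lengths)                    # last index of each group
  d_grp <- as.numeric(tapply(d_s, grp, sum))      # events per distinct time
  list(ord = ord, t_s = t_s, d_s = d_s, grp = grp, grp_end = grp_end,
       d_grp = d_grp, event_grp = which(d_grp > 0), n = n)
}

# Breslow partial log-likelihood, per-sample score residual g and
# diagonal Hessian weights w at linear predictor eta (original sample
# order). Used by the IRLS outer loop of the penalized Cox solver.
cox_deriv <- function(eta, prep) {
  eta_s <- eta[prep$ord]
  ew <- exp(eta_s)
  S0g <- cumsum(ew)[prep$grp_end]                     # risk-set sums per group
  inc_a <- prep$d_grp / S0g                           # per-group d/S0
  inc_b <- prep$d_grp / S0g^2
  # A_i = sum over event times <= t_i (groups at or after i's group)
  A_g <- rev(cumsum(rev(inc_a)))
  B_g <- rev(cumsum(rev(inc_b)))
  A <- A_g[prep$grp]; B <- B_g[prep$grp]
  g_s <- prep$d_s - ew * A
  w_s <- ew * A - ew^2 * B
  ll <- sum(eta_s * prep$d_s) - sum(prep$d_grp * log(S0g))
  g <- numeric(prep$n); w <- numeric(prep$n)
  g[prep$ord] <- g_s; w[prep$ord] <- w_s
  list(loglik = ll, g = g, w = w)
}

# Full score vector and observed information at eta for design X
# (original order). Returns risk-set means as a by-product (needed for
# Schoenfeld residuals).
cox_score_info <- function(X, eta, prep) {
  p <- ncol(X)
  x_s <- X[prep$ord, , drop = FALSE]
  eta_s <- eta[prep$ord]
  ew <- exp(eta_s)
  S0 <- cumsum(ew)[prep$grp_end]
  S1 <- apply(ew * x_s, 2L, cumsum)[prep$grp_end, , drop = FALSE]
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  xbar <- S1 / S0                                     # risk-set mean per group
  U <- numeric(p)
  info <- matrix(0, p, p)
  wx <- ew * x_s
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- cumsum(wx[, j] * x_s[, k])[prep$grp_end]
      v <- sum(prep$d_grp * (S2jk / S0 - xbar[, j] * xbar[, k]))
      info[j, k] <- v; info[k, j] <- v
    }
  }
  ev_rows <- which(prep$d_s > 0)
  U <- colSums(x_s[ev_rows, , drop = FALSE]) -
    colSums(prep$d_grp * xbar)
  ll <- sum(eta_s * prep$d_s) - sum(prep$d_grp * log(S0))
  list(U = U, info = info, loglik = ll, xbar = xbar, S0 = S0)
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the Breslow partial likelihood over the columns of `X` by
#' Newton-Raphson with step-halving whenever a step would decrease the
#' likelihood. Convergence is declared when the largest absolute score
#' component falls below `tol`; monotone-likelihood divergence (a
#' coefficient running away) is flagged after the iteration cap rather
#' than raised.
#'
#' @param X numeric design matrix (no intercept; it is absorbed into the
#'   baseline hazard).
#' @param tte time to event or censoring (years, > 0).
#' @param event 0/1 event indicator; at least one event required.
#' @param max_iter,tol Newton iteration cap and score tolerance.
#' @return an object of class `cox_fit` with coefficients, the inverse
#'   information (`var`), standard errors, Wald z/p, log-likelihoods and
#'   convergence flags. The design and outcome are retained for
#'   downstream diagnostics.
#' @export
cox_fit <- function(X, tte, event, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (any(!is.finite(X))) stopf("non-finite values in the Cox design matrix")
  prep <- cox_prep(tte, event)
  p <- ncol(X)
  beta <- numeric(p)
  si <- cox_score_info(X, as.numeric(X %*% beta), prep)
  ll0 <- si$loglik
  converged <- FALSE; flag <- NA_character_; iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (max(abs(si$U)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(si$info, si$U), error = function(e) NULL)
    if (is.null(delta)) { flag <- "singular_information"; break }
    step <- 1
    for (h in 1:20) {
      cand <- beta + step * delta
      si_new <- cox_score_info(X, as.numeric(X %*% cand), prep)
      if (is.finite(si_new$loglik) && si_new$loglik >= si$loglik - 1e-12) break
      step <- step / 2
    }
    if (!is.finite(si_new$loglik) || si_new$loglik < si$loglik - 1e-12) {
      flag <- "step_halving_failed"; break
    }
    beta <- cand; si <- si_new
    if (max(abs(beta)) > 25) { flag <- "monotone_likelihood"; break }
  }
  if (!converged && is.na(flag)) flag <- "iteration_cap"
  var <- tryCatch(solve(si$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(var), 0))
  z <- beta / se
  structure(list(
    coef = stats::setNames(beta, colnames(X)),
    var = var, se = stats::setNames(se, colnames(X)),
    z = z, p_value = 2 * stats::pnorm(-abs(z)),
    loglik = si$loglik, loglik_null = ll0,
    iter = iter, converged = converged, flag = flag,
    n = prep$n, n_events = sum(prep$d_s),
    X = X, tte = tte, event = event,
    eta = as.numeric(X %*% beta)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (Breslow ties): n = %d, events = %d, %s after %d iterations\n",
              x$n, x$n_events,
              if (x$converged) "converged" else paste0("NOT converged (", x$flag, ")"),
              x$iter))
  tab <- data.frame(coef = x$coef, `HR` = exp(x$coef), se = x$se,
                    z = x$z, p = format.pval(x$p_value), check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coef

#' @export
vcov.cox_fit <- function(object, ...) object$var

#' @export
logLik.cox_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coef), class = "logLik")
}

#' Unscaled Schoenfeld residuals
#'
#' One row per event (in increasing time order); each residual is the
#' event sample's covariate vector minus the risk-set mean at the event
#' time. At the partial-likelihood optimum the rows sum to the score
#' vector, i.e. to zero per covariate.
#'
#' @param fit a [cox_fit()].
#' @return list with `residuals` (events x covariates matrix) and
#'   `time` (event times).
#' @export
schoenfeld_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  prep <- cox_prep(fit$tte, fit$event)
  si <- cox_score_info(fit$X, fit$eta, prep)
  x_s <- fit$X[prep$ord, , drop = FALSE]
  ev_pos <- which(prep$d_s > 0)
  res <- x_s[ev_pos, , drop = FALSE] -
    si$xbar[prep$grp[ev_pos], , drop = FALSE]
  times <- prep$t_s[ev_pos]
  o <- order(times)
  list(residuals = res[o, , drop = FALSE], time = times[o])
}
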