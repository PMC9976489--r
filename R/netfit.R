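# Penalized model fitting: Gaussian and Cox elastic nets by cyclic
# coordinate descent (inner loop in C++), pathwise with warm starts,
# grouped cross-validation for shrinkage selection.

#' Grouped cross-validation folds
#'
#' Assigns samples to k folds such that all samples sharing a grouping
#' label (e.g. a technical batch) land in the same fold. Groups are
#' shuffled with the seed, then assigned largest-first to the currently
#' smallest fold, so fold sizes differ by at most the largest group size.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param k number of folds.
#' @param group_labels one label per sample; `NULL` treats every sample
#'   as its own group (plain k-fold).
#' @param seed integer seed for the shuffle.
#' @return an integer vector of fold indices in 1..k, named by sample id,
#'   with the grouping stored in `attr(, "groups")`.
#' @export
make_folds <- function(sample_ids, k, group_labels = NULL, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  n <- length(sample_ids)
  if (is.null(group_labels)) group_labels <- as.character(seq_len(n))
  if (length(group_labels) != n) stopf("group_labels length != sample_ids length")
  groups <- unique(group_labels)
  if (length(groups) < k) {
    stopf("only %d distinct groups for %d folds", length(groups), k)
  }
  sizes <- table(group_labels)[groups]
  with_seed(child_seed(seed, "folds"), {
    perm <- sample(seq_along(groups))
    groups <- groups[perm]; sizes <- as.integer(sizes[perm])
    ord <- order(sizes, decreasing = TRUE)   # big groups first, ties by shuffle
    fold_of_group <- integer(length(groups))
    fold_fill <- integer(k)
    for (g in ord) {
      f <- which.min(fold_fill)
      fold_of_group[g] <- f
      fold_fill[f] <- fold_fill[f] + sizes[g]
    }
  })
  folds <- fold_of_group[match(group_labels, groups)]
  names(folds) <- sample_ids
  attr(folds, "groups") <- group_labels
  folds
}

std_n <- function(X) {
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2L, mu, "-")^2))   # n-denominator sd
  Xs <- sweep(X, 2L, mu, "-")
  ok <- sds > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2L, sds[ok], "/")
  list(X = Xs, mu = mu, sds = sds, ok = ok)
}

default_lambda_grid <- function(lambda_max, nlambda, min_ratio) {
  exp(seq(log(lambda_max), log(lambda_max * min_ratio), length.out = nlambda))
}

# Exact active-set refinement of a Gaussian elastic-net solution. On the
# active set with fixed signs the problem is a smooth ridge system,
# (G_AA + l2 I) b_A = c_A - l1 * sign_A, solved directly; coordinates
# whose solution flips sign are dropped. This polishes the coordinate-
# descent iterate to machine-precision KKT even on near-collinear
# designs (e.g. a beta value and its square), where plain cyclic descent
# crawls along almost-flat directions. Falls back to the input if the
# refined point does not improve the penalized objective.
enet_refine <- function(G, c0, yy_n, b, alpha, lambda,
                        max_ref = 30L, kkt_tol = 1e-10) {
  p <- length(b)
  l1 <- lambda * alpha; l2 <- lambda * (1 - alpha)
  obj <- function(bb) {
    as.numeric(yy_n / 2 - crossprod(bb, c0) + crossprod(bb, G %*% bb) / 2 +
                 lambda * (alpha * sum(abs(bb)) +
                             (1 - alpha) / 2 * sum(bb^2)))
  }
  best <- b; best_obj <- obj(b)
  for (it in seq_len(max_ref)) {
    grad <- c0 - as.numeric(G %*% b)
    kkt <- ifelse(b == 0, pmax(abs(grad) - l1, 0),
                  abs(grad - l2 * b - l1 * sign(b)))
    if (max(kkt) < kkt_tol) break
    A <- which(b != 0 | abs(grad) > l1 + 1e-12)
    if (length(A) == 0L) break
    s <- ifelse(b[A] != 0, sign(b[A]), sign(grad[A]))
    repeat {
      bA <- tryCatch(
        solve(G[A, A, drop = FALSE] + diag(l2, length(A)), c0[A] - l1 * s),
        error = function(e) NULL)
      if (is.null(bA)) return(best)
      bad <- (sign(bA) != s) & (bA != 0)
      if (!any(bad)) break
      A <- A[!bad]; s <- s[!bad]
      if (length(A) == 0L) { bA <- numeric(0); break }
    }
    b <- numeric(p)
    if (length(A) > 0L) b[A] <- bA
    ob <- obj(b)
    if (ob < best_obj - 1e-15) { best <- b; best_obj <- ob } else break
  }
  best
}

# Pathwise Gaussian solve on the standardized scale: C++ coordinate
# descent with warm starts, then exact active-set refinement per lambda
# (skipped for very wide designs where the Gram matrix would not fit).
gauss_enet_path <- function(Xs, yc, alpha, lambda, tol, maxit,
                            refine = ncol(Xs) <= 3000L) {
  n <- nrow(Xs); p <- ncol(Xs)
  w1 <- rep(1, n)
  # with the exact finisher, descent sweeps only need to track the
  # active set between neighbouring lambdas
  sweeps <- if (refine) min(maxit, 20L) else maxit
  if (refine) {
    G <- crossprod(Xs) / n
    c0 <- as.numeric(crossprod(Xs, yc)) / n
    yy_n <- sum(yc^2) / n
  }
  b <- numeric(p)
  B <- matrix(0, p, length(lambda))
  for (l in seq_along(lambda)) {
    sol <- .cd_enet_wls(Xs, yc, w1, alpha, lambda[l], b, tol,
                        as.integer(sweeps))
    b <- sol$beta
    if (refine) b <- enet_refine(G, c0, yy_n, b, alpha, lambda[l])
    B[, l] <- b
  }
  B
}

#' Fit a Gaussian elastic-net path
#'
#' Minimizes `(1/2n) * sum((y - b0 - X b)^2) + lambda * (alpha*||b||_1 +
#' (1-alpha)/2 * ||b||_2^2)` by pathwise cyclic coordinate descent with
#' soft-thresholding, warm starts down a descending lambda grid, and
#' active-set convergence. Features are standardized internally
#' (n-denominator SDs, the coordinate-descent convention); returned
#' coefficients are on the original feature scale with the intercept
#' adjusted. When folds are supplied, the shrinkage parameter is chosen
#' as the grid point minimizing the mean cross-validated squared error
#' (minimum rule).
#'
#' @param X numeric feature matrix (samples x features, named columns).
#' @param y numeric outcome.
#' @param alpha L1/L2 mixing parameter in \[0, 1\] (default 0.5).
#' @param lambda optional descending grid; by default 100 log-spaced
#'   points from the smallest lambda that zeroes every coefficient down
#'   to 0.001 of it.
#' @param folds optional fold assignment from [make_folds()] for CV.
#' @param nlambda,lambda_min_ratio default grid shape.
#' @param tol,maxit coordinate-descent convergence control (maximum
#'   absolute coefficient change on the standardized scale).
#' @return an object of class `enet_path`.
#' @export
fit_elastic_net <- function(X, y, alpha = 0.5, lambda = NULL, folds = NULL,
                            nlambda = 100L, lambda_min_ratio = 0.001,
                            tol = 1e-7, maxit = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (any(!is.finite(X))) stopf("non-finite values in X")
  if (any(!is.finite(y))) stopf("non-finite values in y")
  if (nrow(X) != length(y)) stopf("nrow(X) != length(y)")
  n <- nrow(X); p <- ncol(X)
  if (stats::sd(y) == 0) stopf("outcome has zero variance")
  alpha <- check_number(alpha, "alpha", 0, 1)

  std <- std_n(X)
  yc <- y - mean(y)
  a_eff <- max(alpha, 0.001)
  lambda_max <- max(abs(crossprod(std$X, yc))) / (n * a_eff) *
    (1 + 1e-9)
  if (is.null(lambda)) {
    lambda <- default_lambda_grid(lambda_max, nlambda, lambda_min_ratio)
  } else {
    if (any(lambda <= 0) || any(diff(lambda) >= 0)) {
      stopf("lambda grid must be strictly descending and positive")
    }
  }
  beta_std <- gauss_enet_path(std$X, yc, alpha, lambda, tol, maxit)
  beta <- beta_std / ifelse(std$sds > 0, std$sds, 1)
  beta[std$sds == 0, ] <- 0
  a0 <- mean(y) - as.numeric(crossprod(beta, std$mu))
  dimnames(beta) <- list(colnames(X), NULL)

  cv <- NULL; lambda_selected <- NA_real_
  if (!is.null(folds)) {
    ks <- sort(unique(folds))
    fold_mse <- matrix(NA_real_, length(ks), length(lambda))
    for (fi in seq_along(ks)) {
      tr <- folds != ks[fi]; te <- !tr
      std_t <- std_n(X[tr, , drop = FALSE])
      yc_t <- y[tr] - mean(y[tr])
      bs_t <- gauss_enet_path(std_t$X, yc_t, alpha, lambda, tol, maxit)
      b_t <- bs_t / ifelse(std_t$sds > 0, std_t$sds, 1)
      b_t[std_t$sds == 0, ] <- 0
      a0_t <- mean(y[tr]) - as.numeric(crossprod(b_t, std_t$mu))
      pred <- sweep(X[te, , drop = FALSE] %*% b_t, 2L, a0_t, "+")
      fold_mse[fi, ] <- colMeans((pred - y[te])^2)
    }
    cvm <- colMeans(fold_mse)
    cvse <- apply(fold_mse, 2L, stats::sd) / sqrt(length(ks))
    cv <- data.frame(lambda = lambda, mean = cvm, se = cvse)
    lambda_selected <- lambda[which.min(cvm)]
  }

  structure(list(
    family = "gaussian", alpha = alpha, lambda = lambda,
    beta = beta, a0 = a0, df = colSums(beta != 0),
    beta_std = beta_std, x_center = std$mu, x_scale = std$sds,
    y_mean = mean(y),
    cv = cv, lambda_selected = lambda_selected,
    feature_names = colnames(X), n = n
  ), class = "enet_path")
}

#' Karush-Kuhn-Tucker optimality check for an elastic-net solution
#'
#' On the internal standardized scale, every solution must satisfy
#' `|x_j' r / n - lambda*(1-alpha)*b_j| <= lambda*alpha` at `b_j = 0` and
#' equality with sign at `b_j != 0`. Returns the largest violation across
#' features (0 means the certificate holds exactly).
#'
#' @param path an `enet_path` (Gaussian family).
#' @param X,y the training data the path was fitted on.
#' @param lambda which grid point to certify (default: every one).
#' @return maximum KKT violation (a non-negative number).
#' @export
kkt_violation <- function(path, X, y, lambda = NULL) {
  stopifnot(inherits(path, "enet_path"), path$family == "gaussian")
  X <- as.matrix(X)
  std <- list(X = sweep(sweep(X, 2L, path$x_center, "-"), 2L,
                        ifelse(path$x_scale > 0, path$x_scale, 1), "/"))
  yc <- y - path$y_mean
  idx <- if (is.null(lambda)) seq_along(path$lambda)
         else vapply(lambda, function(l) which.min(abs(path$lambda - l)),
                     integer(1L))
  n <- nrow(X)
  worst <- 0
  for (l in idx) {
    b <- path$beta_std[, l]
    r <- yc - std$X %*% b
    grad <- as.numeric(crossprod(std$X, r)) / n
    lam <- path$lambda[l]
    lhs <- grad - lam * (1 - path$alpha) * b
    viol <- ifelse(b == 0, pmax(abs(lhs) - lam * path$alpha, 0),
                   abs(lhs - lam * path$alpha * sign(b)))
    worst <- max(worst, viol)
  }
  worst
}

# Penalized Cox objective: -(1/n) * Breslow log partial likelihood +
# elastic-net penalty, on the standardized scale.
cox_pen_obj <- function(beta, Xs, prep, alpha, lambda) {
  eta <- as.numeric(Xs %*% beta)
  d <- cox_deriv(eta, prep)
  -d$loglik / nrow(Xs) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# IRLS + coordinate descent solve of the penalized Cox problem at one
# lambda, warm-started; returns the standardized-scale coefficients.
cox_enet_solve <- function(Xs, prep, alpha, lambda, beta, tol = 1e-7,
                           outer_tol = 1e-6, outer_max = 30L,
                           maxit = 100000L) {
  n <- nrow(Xs)
  obj <- cox_pen_obj(beta, Xs, prep, alpha, lambda)
  flag <- NA_character_
  for (it in seq_len(outer_max)) {
    eta <- as.numeric(Xs %*% beta)
    d <- cox_deriv(eta, prep)
    w <- pmax(d$w, 1e-5)
    z <- eta + d$g / w
    sol <- .cd_enet_wls(Xs, z, w, alpha, lambda, beta, tol, as.integer(maxit))
    beta_new <- sol$beta
    obj_new <- cox_pen_obj(beta_new, Xs, prep, alpha, lambda)
    # step-halve towards the previous iterate on objective increase
    h <- 0
    while (obj_new > obj + 1e-12 && h < 12) {
      beta_new <- (beta_new + beta) / 2
      obj_new <- cox_pen_obj(beta_new, Xs, prep, alpha, lambda)
      h <- h + 1
    }
    if (obj_new > obj + 1e-12) { flag <- "no_descent"; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new; obj <- obj_new
    if (delta < outer_tol) break
    if (it == outer_max) flag <- "outer_cap"
  }
  list(beta = beta, obj = obj, flag = flag)
}

#' Fit a Cox elastic-net path
#'
#' Minimizes `-(1/n) * Breslow log partial likelihood + lambda *
#' (alpha*||b||_1 + (1-alpha)/2*||b||_2^2)` by an outer
#' iteratively-reweighted quadratic approximation to the partial
#' likelihood with an inner coordinate descent, pathwise with warm
#' starts. There is no intercept (it is absorbed by the baseline
#' hazard). When folds are supplied, the selected lambda maximizes the
#' mean held-out Harrell's C across folds.
#'
#' @inheritParams fit_elastic_net
#' @param tte,event survival outcome (times > 0, 0/1 indicator).
#' @return an `enet_path` with `family = "cox"`; coefficients on the
#'   original feature scale.
#' @export
fit_cox_elastic_net <- function(X, tte, event, alpha = 0.5, lambda = NULL,
                                folds = NULL, nlambda = 100L,
                                lambda_min_ratio = 0.001,
                                tol = 1e-7, maxit = 100000L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  if (any(!is.finite(X))) stopf("non-finite values in X")
  n <- nrow(X)
  alpha <- check_number(alpha, "alpha", 0, 1)
  prep <- cox_prep(tte, event)
  std <- std_n(X)
  a_eff <- max(alpha, 0.001)
  g0 <- cox_deriv(rep(0, n), prep)$g
  lambda_max <- max(abs(crossprod(std$X, g0))) / (n * a_eff) *
    (1 + 1e-9)
  if (is.null(lambda)) {
    lambda <- default_lambda_grid(lambda_max, nlambda, lambda_min_ratio)
  } else if (any(lambda <= 0) || any(diff(lambda) >= 0)) {
    stopf("lambda grid must be strictly descending and positive")
  }

  fit_path <- function(Xs, prep_, lam_grid) {
    p <- ncol(Xs)
    beta <- numeric(p)
    B <- matrix(0, p, length(lam_grid))
    flags <- character(length(lam_grid))
    for (l in seq_along(lam_grid)) {
      sol <- cox_enet_solve(Xs, prep_, alpha, lam_grid[l], beta, tol = tol,
                            maxit = maxit)
      beta <- sol$beta
      B[, l] <- beta
      flags[l] <- sol$flag %||% NA_character_
    }
    list(B = B, flags = flags)
  }

  full <- fit_path(std$X, prep, lambda)
  beta <- full$B / ifelse(std$sds > 0, std$sds, 1)
  beta[std$sds == 0, ] <- 0
  dimnames(beta) <- list(colnames(X), NULL)

  cv <- NULL; lambda_selected <- NA_real_
  if (!is.null(folds)) {
    ks <- sort(unique(folds))
    fold_c <- matrix(NA_real_, length(ks), length(lambda))
    for (fi in seq_along(ks)) {
      tr <- folds != ks[fi]; te <- !tr
      if (sum(event[tr]) == 0) stopf("fold %s has zero training events", ks[fi])
      std_t <- std_n(X[tr, , drop = FALSE])
      prep_t <- cox_prep(tte[tr], event[tr])
      ft <- fit_path(std_t$X, prep_t, lambda)
      b_t <- ft$B / ifelse(std_t$sds > 0, std_t$sds, 1)
      b_t[std_t$sds == 0, ] <- 0
      lp_te <- X[te, , drop = FALSE] %*% b_t
      fold_c[fi, ] <- apply(lp_te, 2L, function(s) {
        harrells_c(s, tte[te], event[te])
      })
    }
    cvm <- colMeans(fold_c)
    cvse <- apply(fold_c, 2L, stats::sd) / sqrt(length(ks))
    cv <- data.frame(lambda = lambda, mean = cvm, se = cvse)
    # maximum rule; ties resolved towards the sparser (larger) lambda
    lambda_selected <- lambda[which.max(cvm)]
  }

  structure(list(
    family = "cox", alpha = alpha, lambda = lambda,
    beta = beta, a0 = rep(0, length(lambda)), df = colSums(beta != 0),
    beta_std = full$B, x_center = std$mu, x_scale = std$sds,
    flags = full$flags,
    cv = cv, lambda_selected = lambda_selected,
    feature_names = colnames(X), n = n, n_events = sum(event)
  ), class = "enet_path")
}

#' @export
print.enet_path <- function(x, ...) {
  cat(sprintf("Elastic-net path (%s, alpha = %g): %d features, %d lambdas (%.4g .. %.4g)\n",
              x$family, x$alpha, length(x$feature_names), length(x$lambda),
              max(x$lambda), min(x$lambda)))
  if (!is.null(x$cv)) {
    crit <- if (x$family == "cox") "mean CV Harrell's C" else "mean CV MSE"
    i <- which.min(abs(x$lambda - x$lambda_selected))
    cat(sprintf("  selected lambda = %.6g (%s = %.4g, %d nonzero)\n",
                x$lambda_selected, crit, x$cv$mean[i], x$df[i]))
  }
  invisible(x)
}

#' @export
coef.enet_path <- function(object, s = c("selected", "min"), lambda = NULL, ...) {
  if (is.null(lambda)) {
    s <- match.arg(s)
    lambda <- if (s == "min") min(object$lambda) else object$lambda_selected
    if (is.na(lambda)) stopf("no CV-selected lambda; pass `lambda=`")
  }
  i <- which.min(abs(object$lambda - lambda))
  b <- object$beta[, i]
  c(`(Intercept)` = if (object$family == "gaussian") object$a0[i] else 0,
    b)
}

#' @export
predict.enet_path <- function(object, newx, lambda = NULL, ...) {
  cf <- coef(object, lambda = lambda, ...)
  newx <- as.matrix(newx)
  miss <- setdiff(object$feature_names, colnames(newx))
  if (length(miss) > 0L) {
    stopf("missing feature column(s): %s", paste(miss, collapse = ", "))
  }
  as.numeric(cf[1L] + newx[, object$feature_names, drop = FALSE] %*% cf[-1L])
}

#' EWAS-ranked feature pre-selection
#'
#' Builds the feature list for clock training: the `n_linear` CpGs with
#' the smallest linear-EWAS p-values enter as linear beta-value features,
#' and the `n_quadratic` CpGs with the smallest quadratic-term p-values
#' enter as squared beta-value features; any squared CpG not already in
#' the linear set also contributes its linear form. Ties in p are broken
#' by lexicographic CpG id, so the output ordering is deterministic.
#'
#' @param linear_ewas,quadratic_ewas `ewas_table`s with `p_linear` and
#'   `p_quadratic` columns respectively.
#' @param n_linear,n_quadratic subset sizes (>= 0); requests exceeding
#'   the table size warn and truncate.
#' @return a data.frame of class `feature_spec` with columns `feature`
#'   (unique name, `<cpg>` or `<cpg>_sq`), `cpg`, `transform`
#'   (`linear`/`squared`).
#' @export
preselect_features <- function(linear_ewas, quadratic_ewas,
                               n_linear = 10000L, n_quadratic = 300L) {
  n_linear <- check_count(n_linear, "n_linear", min = 0L)
  n_quadratic <- check_count(n_quadratic, "n_quadratic", min = 0L)
  top_k <- function(tab, p_col, k, what) {
    ok <- !is.na(tab[[p_col]])
    tab <- tab[ok, , drop = FALSE]
    if (k > nrow(tab)) {
      warnf("requested %d %s features but only %d available; truncating",
            k, what, nrow(tab))
      k <- nrow(tab)
    }
    tab[order(tab[[p_col]], tab$cpg)[seq_len(k)], "cpg"]
  }
  lin <- if (n_linear > 0L) top_k(linear_ewas, "p_linear", n_linear, "linear")
         else character(0)
  quad <- if (n_quadratic > 0L) {
    top_k(quadratic_ewas, "p_quadratic", n_quadratic, "quadratic")
  } else character(0)
  extra_lin <- setdiff(quad, lin)
  out <- data.frame(
    cpg = c(lin, quad, extra_lin),
    transform = c(rep("linear", length(lin)), rep("squared", length(quad)),
                  rep("linear", length(extra_lin))),
    stringsAsFactors = FALSE
  )
  out$feature <- ifelse(out$transform == "squared", paste0(out$cpg, "_sq"),
                        out$cpg)
  rownames(out) <- NULL
  structure(out[, c("feature", "cpg", "transform")],
            class = c("feature_spec", "data.frame"))
}
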