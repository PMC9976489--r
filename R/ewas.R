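# Epigenome-wide association engines. The age models follow the
# "age as outcome" orientation: centred age is regressed on the
# standardized CpG M-value (and its standardized square), adjusting for
# covariates. Covariates are projected out once via a QR-based
# annihilator (Frisch-Waugh-Lovell), so the per-CpG work is a cheap
# univariate (or bivariate) regression with the correct residual
# degrees of freedom.

# Build the covariate design (with intercept) and return the orthonormal
# basis Q of its column space plus the residual degrees of freedom
# bookkeeping.
ewas_design <- function(pheno, covariates, pcs = NULL) {
  n <- nrow(pheno)
  Z <- covariate_matrix(pheno, covariates)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    if (nrow(pcs) != n) stopf("PC score rows do not match samples")
    Z <- cbind(Z, pcs)
  }
  D <- cbind(`(Intercept)` = rep(1, n), Z)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    stopf("covariate design is rank deficient (rank %d < %d columns)",
          qrD$rank, ncol(D))
  }
  Q <- qr.Q(qrD)
  list(Q = Q, q = ncol(D), n = n)
}

residualize <- function(x, Q) x - Q %*% crossprod(Q, x)

# Standardize matrix columns with the sample (n-1) sd; columns with zero
# variance come back as NA-filled and are flagged by the caller.
standardize_or_na <- function(X) {
  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  ok <- is.finite(sds) & sds > 0
  Z <- sweep(X, 2L, mu, "-")
  Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, sds[ok], "/")
  Z[, !ok] <- NA_real_
  list(Z = Z, ok = ok)
}

#' Principal components of the methylome
#'
#' Computes sample-level scores of the top-k principal components of the
#' standardized M-value matrix, conventionally included as covariates to
#' absorb unmeasured confounders. To bound memory at scale, only the
#' `max_cpgs` most variable CpGs enter the decomposition.
#'
#' @param matrix methylation matrix on the M-value scale (use
#'   [beta_to_m()] first if needed).
#' @param k number of components; must be < min(n_samples, n_cpgs).
#' @param max_cpgs cap on the number of most-variable CpGs used.
#' @return an n x k matrix of scores (left singular vectors scaled by the
#'   singular values), columns `PC1..PCk`, with attribute `"var_explained"`.
#' @export
compute_dnam_pcs <- function(matrix, k, max_cpgs = 20000L) {
  n <- nrow(matrix); p <- ncol(matrix)
  k <- check_count(k, "k")
  if (k >= min(n, p)) {
    stopf("k = %d must be < min(n_samples, n_cpgs) = %d", k, min(n, p))
  }
  if (p > max_cpgs) {
    v <- apply(matrix, 2L, stats::var)
    matrix <- matrix[, order(v, decreasing = TRUE)[seq_len(max_cpgs)],
                     drop = FALSE]
    p <- max_cpgs
  }
  std <- standardize_or_na(matrix)
  X <- std$Z[, std$ok, drop = FALSE]
  # eigen-decompose the smaller Gram matrix
  if (nrow(X) <= ncol(X)) {
    G <- tcrossprod(X)
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    scores <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(d2), k)
  } else {
    G <- crossprod(X)
    eg <- eigen(G, symmetric = TRUE)
    d2 <- pmax(eg$values[seq_len(k)], 0)
    V <- eg$vectors[, seq_len(k), drop = FALSE]
    scores <- X %*% V
  }
  colnames(scores) <- sprintf("PC%d", seq_len(k))
  rownames(scores) <- rownames(matrix)
  tot <- sum(apply(X, 2L, stats::var)) * (nrow(X) - 1L)
  attr(scores, "var_explained") <- d2 / tot
  scores
}

#' Linear age EWAS
#'
#' For every CpG, fits ordinary least squares of mean-centred age on the
#' standardized CpG M-value plus covariates, and reports the CpG
#' coefficient, its standard error and the two-sided p-value from the t
#' distribution with the model's residual degrees of freedom. CpGs whose
#' standardized column is degenerate (zero variance or collinear with
#' the covariates) get an NA row with a flag instead of aborting the scan.
#'
#' @param matrix methylation matrix on the M-value scale.
#' @param pheno phenotype table with an `age` column, rows aligned with
#'   the matrix.
#' @param covariates character vector of phenotype columns to adjust for
#'   (factors are dummy-coded); `NULL` for an intercept-only adjustment.
#' @param pcs optional matrix of DNAm PC scores appended to the covariates.
#' @return a data.frame of class `ewas_table` with columns `cpg`,
#'   `beta_linear`, `se_linear`, `p_linear`, `n_used`, `flag`, plus `rss`
#'   and `df` used by [nested_f_test()].
#' @export
linear_age_ewas <- function(matrix, pheno, covariates = NULL, pcs = NULL) {
  check_aligned(matrix, pheno)
  if (!"age" %in% names(pheno)) stopf("phenotype table lacks 'age'")
  des <- ewas_design(pheno, covariates, pcs)
  n <- des$n
  if (n <= des$q + 1L) stopf("n = %d too small for %d parameters", n, des$q + 1L)
  y <- residualize(pheno$age - mean(pheno$age), des$Q)
  std <- standardize_or_na(matrix)
  Xr <- residualize(ifelse(is.na(std$Z), 0, std$Z), des$Q)
  sxx <- colSums(Xr^2)
  ok <- std$ok & sxx > 1e-10
  df <- n - des$q - 1L
  sxy <- as.numeric(crossprod(Xr, y))
  b <- ifelse(ok, sxy / sxx, NA_real_)
  rss <- sum(y^2) - ifelse(ok, b^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tstat <- b / se
  out <- data.frame(
    cpg = colnames(matrix),
    beta_linear = b,
    se_linear = ifelse(ok, se, NA_real_),
    p_linear = ifelse(ok, 2 * stats::pt(-abs(tstat), df), NA_real_),
    n_used = n,
    flag = ifelse(ok, NA_character_, "degenerate"),
    rss = ifelse(ok, rss, NA_real_),
    df = df,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ewas_table", "data.frame"),
            model = "linear", n = n, q = des$q,
            sample_ids = rownames(matrix))
}

#' Quadratic age EWAS
#'
#' Joint fit of mean-centred age on the standardized CpG M-value and its
#' standardized square (the M-value is squared first, then scaled), plus
#' covariates. Reports both coefficients with standard errors and
#' p-values.
#'
#' @inheritParams linear_age_ewas
#' @return an `ewas_table` with `beta_linear/se_linear/p_linear` for the
#'   linear term, `beta_quadratic/se_quadratic/p_quadratic` for the
#'   squared term, and `rss`/`df` for the joint model.
#' @export
quadratic_age_ewas <- function(matrix, pheno, covariates = NULL, pcs = NULL) {
  check_aligned(matrix, pheno)
  if (!"age" %in% names(pheno)) stopf("phenotype table lacks 'age'")
  des <- ewas_design(pheno, covariates, pcs)
  n <- des$n
  if (n <= des$q + 2L) stopf("n = %d too small for %d parameters", n, des$q + 2L)
  y <- residualize(pheno$age - mean(pheno$age), des$Q)
  std1 <- standardize_or_na(matrix)
  std2 <- standardize_or_na(matrix^2)
  X1 <- residualize(ifelse(is.na(std1$Z), 0, std1$Z), des$Q)
  X2 <- residualize(ifelse(is.na(std2$Z), 0, std2$Z), des$Q)
  s11 <- colSums(X1^2); s22 <- colSums(X2^2); s12 <- colSums(X1 * X2)
  s1y <- as.numeric(crossprod(X1, y)); s2y <- as.numeric(crossprod(X2, y))
  det <- s11 * s22 - s12^2
  # guard: collinearity of CpG and CpG^2 after residualization
  ok <- std1$ok & std2$ok & s11 > 1e-10 & s22 > 1e-10 &
    det > 1e-8 * pmax(s11 * s22, 1e-300)
  b1 <- ifelse(ok, (s22 * s1y - s12 * s2y) / det, NA_real_)
  b2 <- ifelse(ok, (s11 * s2y - s12 * s1y) / det, NA_real_)
  df <- n - des$q - 2L
  rss <- sum(y^2) - ifelse(ok, b1 * s1y + b2 * s2y, 0)
  sigma2 <- rss / df
  se1 <- sqrt(sigma2 * s22 / det)
  se2 <- sqrt(sigma2 * s11 / det)
  t1 <- b1 / se1; t2 <- b2 / se2
  out <- data.frame(
    cpg = colnames(matrix),
    beta_linear = b1, se_linear = ifelse(ok, se1, NA_real_),
    p_linear = ifelse(ok, 2 * stats::pt(-abs(t1), df), NA_real_),
    beta_quadratic = b2, se_quadratic = ifelse(ok, se2, NA_real_),
    p_quadratic = ifelse(ok, 2 * stats::pt(-abs(t2), df), NA_real_),
    n_used = n,
    flag = ifelse(ok, NA_character_, "degenerate"),
    rss = ifelse(ok, rss, NA_real_),
    df = df,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("ewas_table", "data.frame"),
            model = "quadratic", n = n, q = des$q,
            sample_ids = rownames(matrix))
}

#' Nested F-test of the quadratic against the linear age model
#'
#' Per CpG, compares the model with the linear M-value term only against
#' the one adding the squared term, on identical samples and covariates:
#' F = ((RSS1 - RSS2) / 1) / (RSS2 / df2), p from F(1, df2).
#'
#' @param fit_linear,fit_quadratic `ewas_table`s from [linear_age_ewas()]
#'   and [quadratic_age_ewas()] on the same data.
#' @return the quadratic table augmented with `f_stat` and `p_f`.
#' @export
nested_f_test <- function(fit_linear, fit_quadratic) {
  stopifnot(inherits(fit_linear, "ewas_table"),
            inherits(fit_quadratic, "ewas_table"))
  if (!identical(attr(fit_linear, "sample_ids"),
                 attr(fit_quadratic, "sample_ids"))) {
    stopf("nested models were fitted on different sample sets")
  }
  if (attr(fit_linear, "q") != attr(fit_quadratic, "q")) {
    stopf("nested models use different covariates")
  }
  ix <- match(fit_quadratic$cpg, fit_linear$cpg)
  if (anyNA(ix)) stopf("CpG sets of the two fits differ")
  rss1 <- fit_linear$rss[ix]
  rss2 <- fit_quadratic$rss
  df2 <- fit_quadratic$df
  f <- pmax((rss1 - rss2), 0) / (rss2 / df2)
  out <- fit_quadratic
  out$f_stat <- f
  out$p_f <- stats::pf(f, 1, df2, lower.tail = FALSE)
  out
}

#' Per-CpG Cox mortality EWAS
#'
#' For each CpG, maximizes the Breslow partial likelihood of time to
#' all-cause mortality over the standardized CpG plus covariates
#' (Newton-Raphson with step-halving; see [cox_fit()]), and reports the
#' hazard ratio per standard deviation of the CpG, the standard error of
#' the log hazard ratio, and the Wald p-value. Degenerate CpGs (zero
#' variance) are reported with HR 1 and p 1, flagged; non-converged fits
#' are flagged but keep their last iterate.
#'
#' @inheritParams linear_age_ewas
#' @param pheno phenotype table with `tte` (> 0) and `event` columns.
#' @return an `ewas_table` with columns `cpg`, `hr`, `se_loghr`, `p_cox`,
#'   `n_used`, `flag`.
#' @export
cox_mortality_ewas <- function(matrix, pheno, covariates = NULL, pcs = NULL) {
  check_aligned(matrix, pheno)
  if (!all(c("tte", "event") %in% names(pheno))) {
    stopf("phenotype table lacks 'tte'/'event'")
  }
  if (any(pheno$tte <= 0)) stopf("all tte must be > 0")
  if (sum(pheno$event) < 1) stopf("no events in the data")
  Z <- covariate_matrix(pheno, covariates)
  if (!is.null(pcs)) Z <- cbind(Z, as.matrix(pcs))
  std <- standardize_or_na(matrix)
  p <- ncol(matrix); n <- nrow(matrix)
  hr <- se <- pv <- rep(NA_real_, p)
  flag <- rep(NA_character_, p)
  for (j in seq_len(p)) {
    if (!std$ok[j]) {
      hr[j] <- 1; pv[j] <- 1; flag[j] <- "degenerate"
      next
    }
    X <- cbind(cpg = std$Z[, j], Z)
    fit <- cox_fit(X, pheno$tte, pheno$event)
    hr[j] <- exp(fit$coef[1L])
    se[j] <- fit$se[1L]
    pv[j] <- fit$p_value[1L]
    if (!fit$converged) flag[j] <- fit$flag
  }
  out <- data.frame(cpg = colnames(matrix), hr = hr, se_loghr = se,
                    p_cox = pv, n_used = n, flag = flag,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ewas_table", "data.frame"),
            model = "cox", n = n, sample_ids = rownames(matrix))
}

#' Filter an EWAS table at epigenome-wide significance
#'
#' Retains rows with p below the threshold (default 3.6e-8, the
#' EPIC-array epigenome-wide significance level), sorted by ascending p.
#'
#' @param ewas an `ewas_table`.
#' @param threshold significance threshold (exclusive).
#' @param p_col which p-value column to use; by default the table's
#'   primary one (`p_linear`, `p_quadratic` or `p_cox` by model).
#' @return the filtered, sorted `ewas_table`.
#' @export
apply_significance <- function(ewas, threshold = 3.6e-8, p_col = NULL) {
  stopifnot(inherits(ewas, "ewas_table"))
  if (is.null(p_col)) {
    p_col <- switch(attr(ewas, "model") %||% "linear",
                    linear = "p_linear", quadratic = "p_quadratic",
                    cox = "p_cox")
  }
  if (!p_col %in% names(ewas)) stopf("column '%s' not in EWAS table", p_col)
  p <- ewas[[p_col]]
  keep <- which(!is.na(p) & p < threshold)
  out <- ewas[keep[order(p[keep], ewas$cpg[keep])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialize an EWAS table
#'
#' @param ewas an `ewas_table`.
#' @param path output path (tab-delimited).
#' @export
write_ewas <- function(ewas, path) {
  utils::write.table(ewas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ewas
#' @param model the model the table came from (`linear`, `quadratic`,
#'   `cox`); recorded so [apply_significance()] picks the right column.
#' @export
read_ewas <- function(path, model = c("linear", "quadratic", "cox")) {
  model <- match.arg(model)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("ewas_table", "data.frame"), model = model)
}

check_aligned <- function(matrix, pheno) {
  validate_phenotypes(pheno)
  if (nrow(matrix) != nrow(pheno)) {
    stopf("methylation matrix has %d samples but phenotype table %d rows",
          nrow(matrix), nrow(pheno))
  }
  if (!identical(rownames(matrix), as.character(pheno$sample_id))) {
    stopf("sample ids of methylation matrix and phenotype table do not align")
  }
  invisible(TRUE)
}
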