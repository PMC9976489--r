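covs_std <- c("sex", "batch", "pack_years")

test_that("linear EWAS matches the normal-equations oracle", {
  set.seed(10)
  n <- 200
  age <- runif(n, 20, 90)
  mv <- 0.4 + 0.015 * age + rnorm(n, 0, 0.3)
  m <- matrix(mv, ncol = 1, dimnames = list(sprintf("s%d", 1:n), "cgX"))
  attr(m, "meth_scale") <- "mvalue"
  ph <- data.frame(sample_id = sprintf("s%d", 1:n), age = age)
  tab <- linear_age_ewas(m, ph)

  # oracle: (X'X)^-1 X'y with textbook standard errors
  X <- cbind(1, as.numeric(scale(mv)))
  y <- age - mean(age)
  bhat <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% bhat
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 * diag(solve(crossprod(X))))
  expect_lt(abs(tab$beta_linear - bhat[2]), 1e-8)
  expect_lt(abs(tab$se_linear - se[2]), 1e-8)
  p_oracle <- 2 * pt(-abs(bhat[2] / se[2]), n - 2)
  expect_lt(abs(tab$p_linear - p_oracle), 1e-8)
  expect_equal(tab$n_used, n)
})

test_that("a CpG collinear with a covariate is flagged, not fatal", {
  co <- simulate_cohort(sim_config(n_samples = 80, n_cpgs = 5, seed = 2))
  m <- suppressWarnings(beta_to_m(co$meth))
  ph <- co$pheno
  ph$dup <- m[, 3]           # covariate duplicating CpG 3 exactly
  tab <- linear_age_ewas(m, ph, covariates = c("sex", "dup"))
  expect_identical(tab$flag[3], "degenerate")
  expect_true(is.na(tab$p_linear[3]))
  expect_true(all(is.na(tab$flag[-3])))
  expect_true(all(is.finite(tab$p_linear[-3])))
})

test_that("null CpGs reject at close to the nominal 5% level", {
  co <- simulate_cohort(sim_config(n_samples = 500, n_cpgs = 1000, seed = 4,
                                   fraction_linear = 0, fraction_quadratic = 0,
                                   fraction_logage = 0, fraction_smoking = 0))
  m <- suppressWarnings(beta_to_m(co$meth))
  tab <- linear_age_ewas(m, co$pheno, covariates = covs_std)
  expect_gt(mean(tab$p_linear < 0.05), 0.03)
  expect_lt(mean(tab$p_linear < 0.05), 0.07)
})

test_that("quadratic EWAS detects a curved age trajectory and flags constants", {
  set.seed(6)
  n <- 2000
  age <- runif(n, 18, 99)
  shape <- (age - 18)^2          # generator's quadratic trajectory shape
  noise_sd <- 0.1
  # effect scaled to 2 x the linear-class signal convention
  b <- 2 * 0.02 * sd(age) / sd(shape)
  m <- cbind(cgQ = 0.2 + b * shape + rnorm(n, 0, noise_sd),
             cgConst = rep(1.5, n))
  rownames(m) <- sprintf("s%d", 1:n)
  attr(m, "meth_scale") <- "mvalue"
  ph <- data.frame(sample_id = rownames(m), age = age)
  tab <- quadratic_age_ewas(m, ph)
  expect_lt(tab$p_quadratic[1], 3.6e-8)
  expect_identical(tab$flag[2], "degenerate")
})

test_that("the quadratic term is calibrated under a purely linear signal", {
  set.seed(7)
  n <- 400; reps <- 300
  pq <- replicate(reps, {
    age <- runif(n, 18, 99)
    m <- matrix(0.5 + 0.01 * age + rnorm(n, 0, 0.2), ncol = 1,
                dimnames = list(sprintf("s%d", 1:n), "cg1"))
    attr(m, "meth_scale") <- "mvalue"
    ph <- data.frame(sample_id = rownames(m), age = age)
    quadratic_age_ewas(m, ph)$p_quadratic
  })
  expect_gt(mean(pq < 0.05), 0.01)
  expect_lt(mean(pq < 0.05), 0.10)
})

test_that("nested F equals hand-computed RSS arithmetic and t^2", {
  set.seed(8)
  n <- 20
  age <- runif(n, 20, 80)
  m <- matrix(0.3 + 0.01 * age + 1e-4 * age^2 + rnorm(n, 0, 0.2), ncol = 1,
              dimnames = list(sprintf("s%d", 1:n), "cg1"))
  attr(m, "meth_scale") <- "mvalue"
  ph <- data.frame(sample_id = rownames(m), age = age)
  fl <- linear_age_ewas(m, ph)
  fq <- quadratic_age_ewas(m, ph)
  ft <- nested_f_test(fl, fq)

  y <- age - mean(age)
  x1 <- as.numeric(scale(m[, 1])); x2 <- as.numeric(scale(m[, 1]^2))
  rss1 <- sum(resid(lm(y ~ x1))^2)
  rss2 <- sum(resid(lm(y ~ x1 + x2))^2)
  f_hand <- (rss1 - rss2) / (rss2 / (n - 3))
  expect_lt(abs(ft$f_stat - f_hand), 1e-10)
  expect_equal(ft$p_f, pf(f_hand, 1, n - 3, lower.tail = FALSE))

  # linear t^2 equals the nested F against the covariate-only model
  t2 <- (fl$beta_linear / fl$se_linear)^2
  rss0 <- sum(y^2)
  f_cov <- (rss0 - fl$rss) / (fl$rss / fl$df)
  expect_lt(abs(t2 - f_cov), 1e-8)

  # F is invariant to rescaling the outcome
  ph2 <- ph; ph2$age <- ph$age * 3.7
  ft2 <- nested_f_test(linear_age_ewas(m, ph2), quadratic_age_ewas(m, ph2))
  expect_equal(ft2$f_stat, ft$f_stat, tolerance = 1e-10)

  # mismatched samples are refused
  fq_sub <- quadratic_age_ewas(m[-1, , drop = FALSE], ph[-1, ])
  expect_error(nested_f_test(fl, fq_sub), "different sample sets")
})

test_that("per-CpG Cox EWAS matches survival::coxph and flags constants", {
  skip_if_not_installed("survival")
  co <- simulate_cohort(sim_config(n_samples = 150, n_cpgs = 8, seed = 12,
                                   survival = list(episcore_log_hrs = c(A = 0.6))))
  m <- suppressWarnings(beta_to_m(co$meth))
  m[, 4] <- 2                          # constant CpG
  attr(m, "meth_scale") <- "mvalue"
  tab <- cox_mortality_ewas(m, co$pheno, covariates = c("sex"))
  expect_identical(tab$flag[4], "degenerate")
  expect_equal(tab$hr[4], 1); expect_equal(tab$p_cox[4], 1)
  for (j in c(1, 2, 7)) {
    or <- survival::coxph(survival::Surv(co$pheno$tte, co$pheno$event) ~
                            scale(m[, j]) + co$pheno$sex, ties = "breslow")
    expect_lt(abs(log(tab$hr[j]) - coef(or)[1]), 1e-6)
    expect_lt(abs(tab$se_loghr[j] - sqrt(diag(vcov(or)))[1]), 1e-6)
  }
})

test_that("Cox log-HR matches a grid-search partial-likelihood oracle", {
  sv <- tiny_surv(n = 20, b = 0.9, seed = 13)
  expect_equal(anyDuplicated(sv$tte[sv$event == 1]), 0L)
  fit <- cox_fit(cbind(x = sv$x, z = sv$z), sv$tte, sv$event)
  oracle <- grid_cox_oracle(cbind(sv$x, sv$z), sv$tte, sv$event)
  expect_lt(max(abs(fit$coef - oracle)), 1e-3)
})

test_that("null-CpG Cox EWAS is calibrated at the 5% level", {
  co <- simulate_cohort(sim_config(
    n_samples = 400, n_cpgs = 500, seed = 14,
    fraction_linear = 0, fraction_quadratic = 0, fraction_logage = 0,
    fraction_smoking = 0,
    survival = list(log_hr_age = 0, baseline_scale = 38,
                    admin_censor_years = 15)))
  expect_gt(mean(co$pheno$event), 0.2)   # roughly 30% events
  m <- suppressWarnings(beta_to_m(co$meth))
  tab <- cox_mortality_ewas(m, co$pheno)
  frac <- mean(tab$p_cox < 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("EWAS results are invariant to CpG column order", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_cpgs = 12, seed = 15))
  m <- suppressWarnings(beta_to_m(co$meth))
  perm <- sample(ncol(m))
  mp <- m[, perm]; attr(mp, "meth_scale") <- "mvalue"
  t1 <- linear_age_ewas(m, co$pheno, covariates = covs_std)
  t2 <- linear_age_ewas(mp, co$pheno, covariates = covs_std)
  expect_equal(t2[match(t1$cpg, t2$cpg), "p_linear"], t1$p_linear,
               tolerance = 1e-12)
})

test_that("significance filtering sorts ascending and respects thresholds", {
  tab <- structure(data.frame(cpg = c("a", "b", "c"),
                              p_linear = c(1e-10, 1e-7, 1e-9)),
                   class = c("ewas_table", "data.frame"), model = "linear")
  out <- apply_significance(tab)
  expect_identical(out$cpg, c("a", "c"))
  expect_identical(apply_significance(tab, threshold = 1)$cpg,
                   c("a", "c", "b"))
  tab$p_linear <- rep(0.5, 3)
  expect_identical(nrow(apply_significance(tab)), 0L)
})

test_that("DNAm principal components match a dense SVD oracle", {
  set.seed(16)
  # rank-1 structure: PC1 carries all the variance
  u <- rnorm(30); v <- rnorm(40)
  m1 <- outer(u, v)
  dimnames(m1) <- list(sprintf("s%d", 1:30), sprintf("cg%d", 1:40))
  # columns must have positive variance after standardization: rank-1
  # matrices standardize to rank 1 with sign structure
  sc <- compute_dnam_pcs(m1, 1)
  expect_gt(attr(sc, "var_explained")[1], 0.999)

  m <- matrix(rnorm(20 * 50), 20, 50,
              dimnames = list(sprintf("s%d", 1:20), sprintf("cg%d", 1:50)))
  sc2 <- compute_dnam_pcs(m, 2)
  Z <- scale(m)
  sv <- svd(Z)
  oracle <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  for (k in 1:2) {
    expect_lt(min(max(abs(sc2[, k] - oracle[, k])),
                  max(abs(sc2[, k] + oracle[, k]))), 1e-8)
  }
  expect_lt(abs(sum(sc2[, 1] * sc2[, 2])), 1e-8)
  ve <- attr(sc2, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_error(compute_dnam_pcs(m, 20), "must be <")
})
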