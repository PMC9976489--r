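rand_problem <- function(n = 60, p = 15, k = 4, seed = 1, snr = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
  b <- c(rnorm(k, 0, snr), rep(0, p - k))
  list(X = X, y = drop(X %*% b) + rnorm(n), b = b)
}

test_that("grouped folds are balanced and keep groups intact", {
  f <- make_folds(sprintf("s%d", 1:10), 5, seed = 1)
  expect_identical(sort(as.integer(table(f))), rep(2L, 5))
  expect_identical(sort(unique(f)), 1:5)

  g <- c(rep("big", 50), sprintf("g%d", 1:50))
  f2 <- make_folds(sprintf("s%d", 1:100), 5, g, seed = 2)
  expect_identical(length(unique(f2[g == "big"])), 1L)
  expect_lte(diff(range(table(f2))), 50)

  expect_error(make_folds(sprintf("s%d", 1:9), 5, rep(c("a", "b", "c"), 3)),
               "3 distinct groups")
  expect_identical(make_folds(sprintf("s%d", 1:10), 5, seed = 7),
                   make_folds(sprintf("s%d", 1:10), 5, seed = 7))
})

test_that("the largest default lambda zeroes every coefficient", {
  pr <- rand_problem(seed = 2)
  fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5)
  expect_identical(fit$df[[1]], 0)
  # just below lambda_max at least one coefficient enters
  expect_gt(max(fit$df), 0)
  expect_error(fit_elastic_net(pr$X, pr$y, lambda = c(0.1, 0.2)),
               "descending")
  yy <- pr$y; yy[1] <- NA
  expect_error(fit_elastic_net(pr$X, yy), "non-finite")
})

test_that("objective matches a proximal subgradient oracle at fixed lambda", {
  pr <- rand_problem(n = 50, p = 10, seed = 3)
  lam <- 0.2
  fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5, lambda = c(1, lam))
  ours <- enet_objective(fit, pr$X, pr$y, lam)
  oracle <- enet_prox_oracle(pr$X, pr$y, alpha = 0.5, lambda = lam)
  expect_lt(abs(ours - oracle), 1e-6)
  expect_lte(ours, oracle + 1e-10)   # never worse than the oracle
})

test_that("KKT conditions certify every returned solution", {
  for (s in 1:3) {
    pr <- rand_problem(n = 40 + 10 * s, p = 12, seed = s)
    fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5)
    expect_lt(kkt_violation(fit, pr$X, pr$y), 1e-6)
  }
  # near-collinear design: a beta value and its square
  set.seed(9)
  bcol <- runif(80, 0.2, 0.9)
  Xc <- cbind(a = bcol, a_sq = bcol^2, b = rnorm(80))
  yc <- 2 * bcol + rnorm(80, 0, 0.1)
  fitc <- fit_elastic_net(Xc, yc, alpha = 0.5)
  expect_lt(kkt_violation(fitc, Xc, yc), 1e-6)
})

test_that("the ridge limit reproduces the closed-form solution", {
  pr <- rand_problem(n = 70, p = 8, seed = 4)
  lams <- c(0.6, 0.05)
  fit <- fit_elastic_net(pr$X, pr$y, alpha = 0, lambda = lams)
  n <- nrow(pr$X)
  mu <- colMeans(pr$X)
  sds <- sqrt(colMeans(sweep(pr$X, 2, mu, "-")^2))
  Xs <- sweep(sweep(pr$X, 2, mu, "-"), 2, sds, "/")
  yc <- pr$y - mean(pr$y)
  for (i in seq_along(lams)) {
    closed <- solve(crossprod(Xs) / n + lams[i] * diag(8),
                    crossprod(Xs, yc) / n)
    expect_lt(max(abs(closed - fit$beta_std[, i])), 1e-6)
  }
})

test_that("support size grows as lambda shrinks, with rare exceptions", {
  viol <- 0; total <- 0
  for (s in 1:10) {
    pr <- rand_problem(n = 50, p = 20, k = 6, seed = 100 + s)
    fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5, nlambda = 40)
    d <- diff(fit$df)
    viol <- viol + sum(d < 0); total <- total + length(d)
  }
  expect_gte(1 - viol / total, 0.95)
})

test_that("permuting feature columns permutes coefficients identically", {
  pr <- rand_problem(seed = 5)
  fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5)
  perm <- sample(ncol(pr$X))
  fit2 <- fit_elastic_net(pr$X[, perm], pr$y, alpha = 0.5,
                          lambda = fit$lambda)
  expect_equal(fit2$beta[match(rownames(fit$beta), rownames(fit2$beta)), ],
               fit$beta, tolerance = 1e-6)
})

test_that("CV selects a lambda that recovers a sparse signal", {
  pr <- rand_problem(n = 150, p = 30, k = 5, seed = 6, snr = 2)
  folds <- make_folds(seq_len(150), 5, seed = 1)
  fit <- fit_elastic_net(pr$X, pr$y, alpha = 0.5, folds = folds)
  expect_false(is.na(fit$lambda_selected))
  expect_equal(nrow(fit$cv), length(fit$lambda))
  cf <- coef(fit)[-1]
  expect_true(all(abs(cf[1:5]) > 0))
  pred <- predict(fit, pr$X)
  expect_gt(cor(pred, pr$y), 0.9)
})

test_that("Cox elastic net matches glmnet along the path", {
  skip_if_not_installed("glmnet")
  set.seed(7)
  n <- 90; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
  sv <- tiny_surv(n = n, b = 0, seed = 8)
  tte <- rexp(n, exp(0.8 * X[, 1] - 0.5 * X[, 2]))
  cens <- quantile(tte, 0.7)
  ev <- as.integer(tte <= cens); tte <- pmin(tte, cens)
  fit <- fit_cox_elastic_net(X, tte, ev, alpha = 0.5, nlambda = 40)
  g <- glmnet::glmnet(X, survival::Surv(tte, ev), family = "cox",
                      alpha = 0.5, lambda = fit$lambda, standardize = TRUE,
                      thresh = 1e-14)
  for (k in c(5, 15, 25, 40)) {
    expect_lt(max(abs(as.matrix(g$beta)[, k] - fit$beta[, k])), 1e-5)
  }
  expect_identical(fit$df[[1]], 0)
})

test_that("the ridge-only Cox solution matches a penalized Newton oracle", {
  skip_if_not_installed("survival")
  sv <- tiny_surv(n = 30, b = 0.7, seed = 9)
  X <- cbind(x = sv$x, z = sv$z)
  lam <- 0.05
  fit <- fit_cox_elastic_net(X, sv$tte, sv$event, alpha = 0,
                             lambda = c(1, lam))
  # oracle: survival::coxph with a ridge penalty theta/2 * sum(b^2) on the
  # standardized design equals our -(1/n)*ll + (lam/2)*||b||^2 objective
  # with theta = n * lam
  n <- length(sv$tte)
  mu <- colMeans(X); sds <- sqrt(colMeans(sweep(X, 2, mu, "-")^2))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  or <- survival::coxph(
    survival::Surv(sv$tte, sv$event) ~
      survival::ridge(Xs[, 1], Xs[, 2], theta = n * lam, scale = FALSE),
    ties = "breslow")
  prep <- methclocks:::cox_prep(sv$tte, sv$event)
  obj <- function(b) methclocks:::cox_pen_obj(b, Xs, prep, 0, lam)
  expect_lt(abs(obj(fit$beta_std[, 2]) - obj(unname(coef(or)))), 1e-5)
})

test_that("a null Cox model scores exactly 0.5 concordance", {
  sv <- tiny_surv(n = 100, b = 0.5, seed = 10)
  expect_equal(harrells_c(rep(0, 100), sv$tte, sv$event), 0.5)
})

test_that("the truly hazardous feature is selected at lambda_selected", {
  n_hit <- 0; n_sims <- 20
  for (s in seq_len(n_sims)) {
    set.seed(400 + s)
    n <- 1000; p <- 8
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%d", 1:p)))
    t_raw <- rexp(n, 0.05 * exp(0.7 * X[, 3]))
    cens <- quantile(t_raw, 0.3)   # ~30% events
    tte <- pmin(t_raw, cens); ev <- as.integer(t_raw <= cens)
    folds <- make_folds(seq_len(n), 5, seed = s)
    fit <- fit_cox_elastic_net(X, tte, ev, alpha = 0.5, folds = folds,
                               nlambda = 30)
    cf <- coef(fit)[-1]
    if (cf["f3"] != 0) n_hit <- n_hit + 1
  }
  expect_gte(n_hit / n_sims, 0.95)
})

test_that("fold construction errors surface for event-free training folds", {
  sv <- tiny_surv(n = 40, seed = 11)
  ev <- rep(0L, 40); ev[1] <- 1L   # the single event isolated in one fold
  folds <- rep(1:4, each = 10)
  names(folds) <- sprintf("s%d", 1:40)
  expect_error(
    fit_cox_elastic_net(matrix(rnorm(80), 40, 2), sv$tte, ev,
                        folds = folds, nlambda = 5),
    "zero training events")
})

test_that("pre-selection ranks, deduplicates and breaks ties by CpG id", {
  lin <- structure(data.frame(cpg = sprintf("cg%02d", 1:10),
                              p_linear = c(0.5, 1e-9, 1e-3, 1e-9, 0.2,
                                           1e-6, 0.9, 0.04, 1e-8, 0.7)),
                   class = c("ewas_table", "data.frame"), model = "linear")
  quad <- structure(data.frame(cpg = sprintf("cg%02d", 1:10),
                               p_quadratic = c(1e-4, 0.3, 1e-10, 0.6, 1e-7,
                                               0.2, 0.1, 0.5, 0.8, 0.9)),
                    class = c("ewas_table", "data.frame"), model = "quadratic")
  fs <- preselect_features(lin, quad, 3, 2)
  # ties at 1e-9 broken lexicographically: cg02 before cg04
  expect_identical(fs$cpg[fs$transform == "linear" &
                            fs$cpg %in% c("cg02", "cg04", "cg09")][1:2],
                   c("cg02", "cg04"))
  expect_identical(fs$cpg[fs$transform == "squared"], c("cg03", "cg05"))
  # squared CpGs absent from the linear set gain a linear form, once
  expect_identical(sum(fs$cpg == "cg03"), 2L)
  expect_identical(sum(fs$feature == "cg03"), 1L)
  expect_identical(sum(fs$feature == "cg03_sq"), 1L)
  expect_identical(anyDuplicated(fs$feature), 0L)

  # a quadratic CpG already in the linear set is not duplicated
  quad2 <- quad; quad2$p_quadratic[2] <- 1e-12
  fs2 <- preselect_features(lin, quad2, 3, 1)
  expect_identical(sum(fs2$cpg == "cg02"), 2L)  # one linear + one squared
  expect_identical(nrow(fs2), 4L)

  expect_warning(preselect_features(lin, quad, 50, 2), "truncating")
})
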