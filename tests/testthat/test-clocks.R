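# Hand-built clock models used for the prediction-rule mechanics.
toy_clock <- function(weights, intercept, transform = "identity",
                      name = "toy") {
  w <- data.frame(feature = names(weights),
                  cpg = sub("_sq$", "", names(weights)),
                  transform = ifelse(grepl("_sq$", names(weights)),
                                     "squared", "linear"),
                  weight = unname(weights), stringsAsFactors = FALSE)
  structure(list(name = name, intercept = intercept, weights = w,
                 outcome_transform = transform, metadata = list()),
            class = "clock_model")
}

test_that("EpiScore projection is the stated dot product", {
  m <- matrix(c(0.2, 0.4, 0.1), nrow = 1,
              dimnames = list("s1", c("cg1", "cg2", "cg3")))
  m <- as_methylation(m, "beta")
  mod <- structure(list(name = "p1", intercept = 0.3,
                        weights = c(cg1 = 0.5, cg2 = -1, cg3 = 2)),
                   class = "episcore_model")
  # 0.5*0.2 - 1*0.4 + 2*0.1 + 0.3
  expect_equal(as.numeric(project_episcores(m, list(mod))), 0.2)

  ident <- structure(list(name = "id", intercept = 0, weights = c(cg2 = 1)),
                     class = "episcore_model")
  expect_equal(as.numeric(project_episcores(m, list(ident))), 0.4)

  missing <- structure(list(name = "x", intercept = 0, weights = c(cg9 = 1)),
                       class = "episcore_model")
  expect_error(project_episcores(m, list(missing)), "cg9")
})

test_that("hybrid prediction branches at 20 years inclusive", {
  m <- matrix(c(0.5, 0.2, 0.40), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), "cg1"))
  m <- as_methylation(m, "beta")
  # age model: 94.6 * beta -> predictions 47.3, 18.92, 37.84
  age_model <- toy_clock(c(cg1 = 94.6), 0)
  log_model <- toy_clock(c(cg1 = 2), 2.3, transform = "log")
  out <- predict_cage(m, age_model, log_model)
  expect_equal(out$cage[1], 47.3)
  expect_identical(out$branch[1], "age")
  expect_equal(out$cage[2], exp(2.3 + 2 * 0.2))
  expect_identical(out$branch[2], "log")
  expect_identical(out$branch[3], "age")

  # an age-model output of exactly 20.0 takes the log branch
  m20 <- as_methylation(matrix(20 / 94.6, 1, 1,
                               dimnames = list("s1", "cg1")), "beta")
  out20 <- predict_cage(m20, age_model, log_model)
  expect_identical(out20$branch, "log")

  # squared features are squared beta values
  sq_model <- toy_clock(c(cg1_sq = 100), 10)
  outsq <- predict_cage(m, sq_model, log_model)
  expect_equal(outsq$cage[1], 10 + 100 * 0.25)

  m_other <- as_methylation(matrix(0.5, 1, 1,
                                   dimnames = list("s1", "cgZ")), "beta")
  expect_error(predict_cage(m_other, age_model, log_model), "cg1")
  expect_error(predict_cage(m, age_model, age_model), "log outcome")
})

test_that("prediction ignores CpG order and extra CpGs", {
  co <- simulate_cohort(sim_config(n_samples = 30, n_cpgs = 20, seed = 6))
  model <- toy_clock(c(cg0000003 = 40, cg0000011_sq = 25, cg0000007 = -12), 30)
  logm <- toy_clock(c(cg0000003 = 1), 3, transform = "log")
  base <- predict_cage(co$meth, model, logm)
  perm <- co$meth[, sample(ncol(co$meth))]
  attr(perm, "meth_scale") <- "beta"
  expect_equal(predict_cage(perm, model, logm)$cage, base$cage)
  sub <- co$meth[, c("cg0000003", "cg0000011", "cg0000007")]
  attr(sub, "meth_scale") <- "beta"
  expect_equal(predict_cage(sub, model, logm)$cage, base$cage)
})

test_that("cAge training is deterministic and validates its inputs", {
  cohs <- list(
    a = simulate_cohort(sim_config(n_samples = 120, n_cpgs = 300, seed = 1,
                                   population_seed = 5, n_batches = 6,
                                   cohort_name = "a")),
    b = simulate_cohort(sim_config(n_samples = 120, n_cpgs = 300, seed = 2,
                                   population_seed = 5, n_batches = 6,
                                   cohort_name = "b")))
  feats <- data.frame(feature = c("cg0000001", "cg0000002", "cg0000002_sq"),
                      cpg = c("cg0000001", "cg0000002", "cg0000002"),
                      transform = c("linear", "linear", "squared"))
  m1 <- train_cage(cohs, feats, k_folds = 5, seed = 3, nlambda = 25)
  m2 <- train_cage(cohs, feats, k_folds = 5, seed = 3, nlambda = 25)
  expect_identical(m1$model_age$weights, m2$model_age$weights)
  expect_identical(m1$model_logage$weights, m2$model_logage$weights)
  expect_identical(m1$model_logage$outcome_transform, "log")

  bad <- cohs
  bad$a$pheno$age[1] <- -4
  expect_error(train_cage(bad, feats, k_folds = 5), "> 0")
  const <- cohs
  const$a$pheno$age <- 50
  const$b$pheno$age <- 50
  expect_error(train_cage(const, feats, k_folds = 5), "zero variance")
})

test_that("a trained clock recovers a noiseless sparse linear truth", {
  mk <- function(seed, name) simulate_cohort(
    sim_config(n_samples = 250, n_cpgs = 120, seed = seed,
               population_seed = 8, fraction_linear = 0.25,
               fraction_quadratic = 0, fraction_logage = 0,
               fraction_smoking = 0, noise_sd = 0, batch_sd = 0,
               cell_effect_sd = 0, n_batches = 8, cohort_name = name))
  cohs <- list(a = mk(1, "a"), b = mk(2, "b"))
  truth <- cohs$a$truth$cpgs
  cpgs <- truth$cpg[truth$class == "linear"]
  feats <- data.frame(feature = cpgs, cpg = cpgs, transform = "linear")
  models <- train_cage(cohs, feats, k_folds = 5, seed = 1, nlambda = 50)
  test <- mk(3, "c")
  pred <- predict_cage(test$meth, models$model_age, models$model_logage)
  expect_gt(cor(pred$cage, test$pheno$age), 0.999)
})

test_that("training MAE tracks an independent penalized-regression oracle", {
  skip_if_not_installed("glmnet")
  mk <- function(seed, name) simulate_cohort(
    sim_config(n_samples = 400, n_cpgs = 500, seed = seed,
               population_seed = 12, fraction_linear = 0.2,
               fraction_quadratic = 0, fraction_logage = 0,
               n_batches = 8, cohort_name = name))
  cohs <- list(a = mk(21, "a"), b = mk(22, "b"))
  truth <- cohs$a$truth$cpgs
  cpgs <- truth$cpg[truth$class == "linear"]
  feats <- data.frame(feature = cpgs, cpg = cpgs, transform = "linear")
  models <- train_cage(cohs, feats, k_folds = 5, seed = 2, nlambda = 50)
  pooled_meth <- rbind(cohs$a$meth, cohs$b$meth)
  attr(pooled_meth, "meth_scale") <- "beta"
  age <- c(cohs$a$pheno$age, cohs$b$pheno$age)
  pred <- predict_cage(pooled_meth, models$model_age, models$model_logage)
  mae_ours <- median(abs(pred$cage - age))
  expect_lt(mae_ours, 3)

  X <- pooled_meth[, cpgs]
  g <- glmnet::cv.glmnet(X, age, alpha = 0.5, nfolds = 5)
  mae_oracle <- median(abs(predict(g, X, s = "lambda.min") - age))
  expect_lt(abs(mae_ours - mae_oracle), 0.1)
})

test_that("bAge training finds hazard-driving proteins and age", {
  set.seed(33)
  n <- 800; k <- 10
  scores <- matrix(rnorm(n * k), n, k,
                   dimnames = list(NULL, sprintf("protein%02d", 1:k)))
  age <- runif(n, 30, 90)
  sexv <- rbinom(n, 1, 0.5)
  lp <- 0.06 * (age - 60) + 0.5 * scores[, 2] + 0.5 * scores[, 5]
  t_raw <- 120 * (-log(runif(n)) / exp(lp))^(1 / 1.1)
  tte <- pmin(t_raw, 15); ev <- as.integer(t_raw <= 15)
  feats <- cbind(age = age, sex = sexv, scores)
  rownames(feats) <- sprintf("s%d", 1:n)
  model <- train_bage(feats, tte, ev, k_folds = 5, seed = 1, nlambda = 40)
  expect_true(all(c("age", "protein02", "protein05") %in% model$features))
  bage <- compute_bage(feats, model)
  expect_lt(abs(mean(bage)), 1e-10)
  expect_equal(sd(bage), 1, tolerance = 1e-10)
  expect_gt(harrells_c(bage, tte, ev), 0.6)

  expect_error(train_bage(feats, tte, rep(0L, n)), "no events")
})

test_that("bAge scoring follows the z-scoring contract exactly", {
  model <- structure(list(features = c("a", "b"),
                          weights = c(a = 0.8, b = -0.4),
                          standardization = "zscore_within_dataset",
                          output_contract = "z", metadata = list()),
                     class = "bage_model")
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 4, 0))
  za <- (X[, "a"] - mean(X[, "a"])) / sd(X[, "a"])
  zb <- (X[, "b"] - mean(X[, "b"])) / sd(X[, "b"])
  lp <- 0.8 * za - 0.4 * zb
  expect_equal(unname(compute_bage(X, model)),
               as.numeric(scale(lp)), tolerance = 1e-12)
  # z-scoring absorbs any feature rescaling
  expect_equal(compute_bage(2 * X, model), compute_bage(X, model),
               tolerance = 1e-12)
  expect_error(compute_bage(X[, 1, drop = FALSE], model), "missing")
  Xc <- X; Xc[, "b"] <- 1
  expect_error(compute_bage(Xc, model), "zero-variance")
})

test_that("age-acceleration residuals are exactly the OLS residuals", {
  age <- c(60, 70, 80)
  pred <- c(1, 0, 2)
  res <- compute_age_accel(pred, age)
  expect_equal(unname(res), c(0.5, -1, 0.5), tolerance = 1e-12)
  expect_lt(abs(sum(res * age)), 1e-8)
  expect_lt(abs(sum(res)), 1e-8)

  expect_equal(unname(compute_age_accel(2 + 0.5 * age, age)), rep(0, 3),
               tolerance = 1e-12)
  set.seed(4)
  a2 <- runif(50, 20, 90)
  r2 <- compute_age_accel(rnorm(50), a2)
  expect_lt(abs(cor(r2, a2)), 1e-8)
  expect_error(compute_age_accel(pred, rep(50, 3)), "constant")
})

test_that("clock, EpiScore and bAge models survive serialization", {
  co <- simulate_cohort(sim_config(n_samples = 25, n_cpgs = 30, seed = 14))
  model <- toy_clock(c(cg0000004 = 31.2345678901, cg0000009_sq = -7.5e-3), 42.1)
  logm <- toy_clock(c(cg0000004 = 0.8), 3.1, transform = "log")
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_clock_model(model, p1); write_clock_model(logm, p2)
  m1 <- read_clock_model(p1); m2 <- read_clock_model(p2)
  expect_identical(m2$outcome_transform, "log")
  before <- predict_cage(co$meth, model, logm)
  after <- predict_cage(co$meth, m1, m2)
  expect_equal(after$cage, before$cage, tolerance = 1e-12)

  panel <- simulate_episcore_panel(sim_config(n_samples = 25, n_cpgs = 30,
                                              seed = 14), 2)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_episcore_model(panel[[1]], p3)
  back <- read_episcore_model(p3)
  expect_equal(project_episcores(co$meth, list(back)),
               project_episcores(co$meth, list(panel[[1]])),
               tolerance = 1e-12, ignore_attr = TRUE)

  bmodel <- structure(list(features = c("age", "p1"),
                           weights = c(age = 0.77, p1 = -0.1),
                           standardization = "zscore_within_dataset",
                           output_contract = "z",
                           metadata = list(alpha = 0.5, lambda_selected = 0.01)),
                      class = "bage_model")
  p4 <- withr::local_tempfile(fileext = ".tsv")
  write_bage_model(bmodel, p4)
  bback <- read_bage_model(p4)
  Xf <- cbind(age = runif(10, 40, 80), p1 = rnorm(10))
  expect_equal(compute_bage(Xf, bback), compute_bage(Xf, bmodel),
               tolerance = 1e-12)
})
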