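#' Configuration for synthetic methylation cohorts
#'
#' Bundles and validates every knob of the generator. Defaults describe a
#' blood-methylation cohort of adults recruited across the full adult age
#' span (uniform ages on 18-99 years), with the bulk of CpGs null and
#' small fractions carrying linear, quadratic (curvature anchored
#' at the young edge of the age range, so trajectories stay monotone) or
#' log(age)-shaped trajectories on the M-value scale, plus
#' smoking-associated CpGs driven by pack years. Batch offsets and
#' white-blood-cell composition loadings add age-independent structure.
#' Survival follows a Weibull-baseline Cox model whose linear predictor
#' combines centred age and z-scored protein EpiScore signals, with
#' administrative censoring.
#'
#' @param n_samples,n_cpgs cohort dimensions.
#' @param seed integer seed; all randomness in a simulation derives from it.
#' @param age_range ages are uniform on this interval (years).
#' @param fraction_linear,fraction_quadratic,fraction_logage,fraction_smoking
#'   proportions of CpGs in each trajectory class (must sum to <= 1; the
#'   remainder are null CpGs).
#' @param effect_size_sd scale of per-CpG age slopes on the M-value scale
#'   (per year, for the linear class; other classes are scaled to match
#'   the same signal standard deviation).
#' @param noise_sd residual M-value noise standard deviation.
#' @param n_batches,batch_sd number of technical batches and the SD of the
#'   per-CpG, per-batch M-value offsets.
#' @param n_cell_types number of cell-proportion columns (default 6,
#'   mirroring standard blood reference panels).
#' @param cell_effect_sd SD of cell-composition loadings; loadings hit a
#'   random 20 percent of CpGs.
#' @param cohort_name label written into the phenotype table.
#' @param population_seed seed governing the shared biology — CpG class
#'   assignment, trajectory coefficients, cell loadings and the EpiScore
#'   panel. Cohorts of one multi-cohort study share a `population_seed`
#'   (so a clock trained on some cohorts transfers to the others) while
#'   differing in `seed`, which governs cohort-level sampling (ages,
#'   noise, batches, survival). Defaults to `seed`.
#' @param effect_shift_sd SD of per-CpG perturbations added to the
#'   population trajectory coefficients for this cohort (drawn under
#'   `seed`); nonzero values emulate a cohort whose age-effect map is
#'   shifted, e.g. a different tissue. Default 0.
#' @param survival list with `baseline_shape` and `baseline_scale`
#'   (Weibull), `log_hr_age` (per year, age centred at the midpoint of
#'   `age_range`), `episcore_log_hrs` (named vector, per-SD log hazard
#'   ratios of protein EpiScore signals) and `admin_censor_years`.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 500L, n_cpgs = 2000L, seed = 1L,
                       age_range = c(18, 99),
                       fraction_linear = 0.05, fraction_quadratic = 0.01,
                       fraction_logage = 0.01, fraction_smoking = 0.01,
                       effect_size_sd = 0.02, noise_sd = 0.1,
                       n_batches = 20L, batch_sd = 0.05,
                       n_cell_types = 6L, cell_effect_sd = 0.3,
                       cohort_name = "cohort1",
                       population_seed = NULL,
                       effect_shift_sd = 0,
                       survival = list()) {
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples", min = 2L),
    n_cpgs = check_count(n_cpgs, "n_cpgs", min = 1L),
    seed = check_count(seed, "seed", min = -2147483647),
    age_range = age_range,
    fraction_linear = check_number(fraction_linear, "fraction_linear", 0, 1),
    fraction_quadratic = check_number(fraction_quadratic, "fraction_quadratic", 0, 1),
    fraction_logage = check_number(fraction_logage, "fraction_logage", 0, 1),
    fraction_smoking = check_number(fraction_smoking, "fraction_smoking", 0, 1),
    effect_size_sd = check_number(effect_size_sd, "effect_size_sd", 0),
    noise_sd = check_number(noise_sd, "noise_sd", 0),
    n_batches = check_count(n_batches, "n_batches", min = 1L),
    batch_sd = check_number(batch_sd, "batch_sd", 0),
    n_cell_types = check_count(n_cell_types, "n_cell_types", min = 1L),
    cell_effect_sd = check_number(cell_effect_sd, "cell_effect_sd", 0),
    cohort_name = as.character(cohort_name),
    population_seed = check_count(population_seed %||% seed,
                                  "population_seed", min = -2147483647),
    effect_shift_sd = check_number(effect_shift_sd, "effect_shift_sd", 0),
    rng = "Mersenne-Twister"
  )
  if (!is.numeric(age_range) || length(age_range) != 2L ||
      any(age_range <= 0) || age_range[1L] >= age_range[2L]) {
    stopf("'age_range' must be positive years [min, max] with min < max")
  }
  frac_sum <- cfg$fraction_linear + cfg$fraction_quadratic +
    cfg$fraction_logage + cfg$fraction_smoking
  if (frac_sum > 1) {
    stopf("'fraction_*' values sum to %.3f > 1", frac_sum)
  }
  surv_default <- list(baseline_shape = 1.1, baseline_scale = 160,
                       log_hr_age = 0.09, episcore_log_hrs = numeric(0),
                       admin_censor_years = 15)
  unknown <- setdiff(names(survival), names(surv_default))
  if (length(unknown) > 0L) {
    stopf("unknown survival field(s): %s", paste(unknown, collapse = ", "))
  }
  surv <- utils::modifyList(surv_default, survival)
  check_number(surv$baseline_shape, "survival$baseline_shape", min = 1e-8)
  check_number(surv$baseline_scale, "survival$baseline_scale", min = 1e-8)
  check_number(surv$log_hr_age, "survival$log_hr_age")
  check_number(surv$admin_censor_years, "survival$admin_censor_years", min = 1e-8)
  if (length(surv$episcore_log_hrs) > 0L &&
      is.null(names(surv$episcore_log_hrs))) {
    names(surv$episcore_log_hrs) <-
      sprintf("protein%03d", seq_along(surv$episcore_log_hrs))
  }
  cfg$survival <- surv
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d samples x %d CpGs (seed %d)\n",
              x$n_samples, x$n_cpgs, x$seed))
  cat(sprintf("  ages U[%g, %g]; CpG classes: %.1f%% linear, %.1f%% quadratic, %.1f%% log(age), %.1f%% smoking\n",
              x$age_range[1L], x$age_range[2L], 100 * x$fraction_linear,
              100 * x$fraction_quadratic, 100 * x$fraction_logage,
              100 * x$fraction_smoking))
  cat(sprintf("  effect SD %g, noise SD %g, %d batches (SD %g), %d cell types\n",
              x$effect_size_sd, x$noise_sd, x$n_batches, x$batch_sd,
              x$n_cell_types))
  cat(sprintf("  survival: Weibull(shape %g, scale %g), log-HR age %g/yr, %d EpiScore drivers, censor %g y\n",
              x$survival$baseline_shape, x$survival$baseline_scale,
              x$survival$log_hr_age, length(x$survival$episcore_log_hrs),
              x$survival$admin_censor_years))
  invisible(x)
}

# Deterministic CpG / sample labels.
cpg_ids <- function(p) sprintf("cg%07d", seq_len(p))
sample_ids_for <- function(cfg) sprintf("%s_s%05d", cfg$cohort_name, seq_len(cfg$n_samples))

# Panel generation shared by simulate_cohort() (for hazard drivers) and
# simulate_episcore_panel(): proteins are drawn sequentially from a
# dedicated RNG stream, so the first k proteins are identical however
# many are requested.
episcore_panel_raw <- function(cfg, n_proteins, names = NULL) {
  p <- cfg$n_cpgs
  ids <- cpg_ids(p)
  with_seed(child_seed(cfg$population_seed, "episcore_panel"), {
    lapply(seq_len(n_proteins), function(k) {
      n_w <- sample(5:min(25L, p), 1L)
      idx <- sort(sample.int(p, n_w))
      w <- stats::rnorm(n_w, 0, 1.5)
      if (all(w == 0)) w[1L] <- 1
      nm <- if (!is.null(names) && k <= length(names)) names[k]
            else sprintf("protein%03d", k)
      structure(list(name = nm,
                     intercept = stats::rnorm(1L, 0, 0.1),
                     weights = stats::setNames(w, ids[idx])),
                class = "episcore_model")
    })
  })
}

#' Simulate a protein EpiScore panel
#'
#' Generates stand-in EpiScore weight sets: each protein is a sparse
#' linear combination of beta values over a random CpG subset, mimicking
#' published methylation-based protein surrogates whose true weights are
#' external. With the same config (seed), the panel is identical across
#' calls, and its first proteins coincide with the hazard-driving
#' proteins used by [simulate_cohort()].
#'
#' @param config a [sim_config()].
#' @param n_proteins number of proteins (>= 1).
#' @return a list of `episcore_model` objects (name, intercept, named
#'   weight vector on the beta-value scale).
#' @export
simulate_episcore_panel <- function(config, n_proteins) {
  stopifnot(inherits(config, "sim_config"))
  n_proteins <- check_count(n_proteins, "n_proteins", min = 1L)
  episcore_panel_raw(config, n_proteins,
                     names = names(config$survival$episcore_log_hrs))
}

#' @export
print.episcore_model <- function(x, ...) {
  cat(sprintf("EpiScore '%s': %d CpG weights, intercept %.4g\n",
              x$name, length(x$weights), x$intercept))
  invisible(x)
}

#' Simulate a synthetic methylation cohort
#'
#' Generates, on the M-value scale, per-CpG trajectories by class
#' (null / linear / quadratic / log(age) / smoking), adds batch offsets,
#' cell-composition loadings and Gaussian noise, and converts to beta
#' values through the inverse-logistic map (clipped to (0.001, 0.999)).
#' Per-class coefficients are scaled so each class contributes signal of
#' comparable magnitude: a CpG's trajectory SD over the cohort equals
#' |N(0, effect_size_sd)| * sd(age). Survival times are drawn from a
#' Weibull-baseline Cox model whose linear predictor is
#' `log_hr_age * (age - mid(age_range)) + sum(episcore_log_hrs * z(score))`,
#' where each score is the protein's EpiScore projection of the realized
#' beta matrix; times are administratively censored.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_cohort` with elements `meth` (beta-value
#'   methylation matrix), `pheno` (phenotype data.frame) and `truth`
#'   (per-CpG class labels and generative coefficients, the EpiScore
#'   panel driving the hazard, and the per-sample true hazard linear
#'   predictor).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_samples; p <- cfg$n_cpgs
  ids <- cpg_ids(p); sids <- sample_ids_for(cfg)
  mid_age <- mean(cfg$age_range)

  hr_panel <- if (length(cfg$survival$episcore_log_hrs) > 0L) {
    episcore_panel_raw(cfg, length(cfg$survival$episcore_log_hrs),
                       names = names(cfg$survival$episcore_log_hrs))
  } else list()

  # ---- population layer: the shared biology ------------------------------
  # CpG classes, trajectory coefficients and cell loadings depend only on
  # population_seed (and the deterministic age-range geometry), so cohorts
  # drawn with different cohort seeds share one methylome-age map.
  k_cell <- cfg$n_cell_types
  age_grid <- seq(cfg$age_range[1L], cfg$age_range[2L], length.out = 2001L)
  sd_age_pop <- stats::sd(age_grid)
  min_age <- cfg$age_range[1L]
  sd_quad_pop <- stats::sd((age_grid - min_age)^2)
  sd_log_pop <- stats::sd(log(age_grid))
  smk_probs <- c(current = 0.18, `quit<1y` = 0.03, `quit>1y` = 0.25,
                 never = 0.50, unknown = 0.04)
  py_shape <- 2; py_rate <- 0.12
  p_smoker <- sum(smk_probs[c("current", "quit<1y", "quit>1y")])
  py_m <- py_shape / py_rate; py_v <- py_shape / py_rate^2
  sd_py_pop <- sqrt(p_smoker * (py_v + py_m^2) - (p_smoker * py_m)^2)

  pop <- with_seed(child_seed(cfg$population_seed, "cpg_map"), {
    n_lin <- round(cfg$fraction_linear * p)
    n_quad <- round(cfg$fraction_quadratic * p)
    n_log <- round(cfg$fraction_logage * p)
    n_smk <- round(cfg$fraction_smoking * p)
    cls <- rep("null", p)
    idx <- sample.int(p)  # random placement of signal CpGs
    cls[idx[seq_len(n_lin)]] <- "linear"
    cls[idx[n_lin + seq_len(n_quad)]] <- "quadratic"
    cls[idx[n_lin + n_quad + seq_len(n_log)]] <- "logage"
    cls[idx[n_lin + n_quad + n_log + seq_len(n_smk)]] <- "smoking"

    a0 <- stats::runif(p, -2.5, 2.5)             # baseline M-values
    target_sd <- abs(stats::rnorm(p, 0, cfg$effect_size_sd)) * sd_age_pop
    sgn <- sample(c(-1, 1), p, replace = TRUE)
    b_lin <- b_quad <- b_log <- b_smk <- numeric(p)
    b_lin[cls == "linear"] <- (sgn * target_sd / sd_age_pop)[cls == "linear"]
    b_quad[cls == "quadratic"] <- (sgn * target_sd / sd_quad_pop)[cls == "quadratic"]
    b_log[cls == "logage"] <- (sgn * target_sd / sd_log_pop)[cls == "logage"]
    b_smk[cls == "smoking"] <- (sgn * target_sd / sd_py_pop)[cls == "smoking"]

    cell_cpgs <- integer(0); cell_load <- NULL
    if (cfg$cell_effect_sd > 0 && p >= 5L) {
      cell_cpgs <- sort(sample.int(p, max(1L, round(0.2 * p))))
      cell_load <- matrix(stats::rnorm(k_cell * length(cell_cpgs), 0,
                                       cfg$cell_effect_sd), nrow = k_cell)
    }
    list(cls = cls, a0 = a0, b_lin = b_lin, b_quad = b_quad,
         b_log = b_log, b_smk = b_smk, cell_cpgs = cell_cpgs,
         cell_load = cell_load)
  })

  # ---- cohort layer: sampling, technical structure, survival -------------
  with_seed(cfg$seed, {
    age <- stats::runif(n, cfg$age_range[1L], cfg$age_range[2L])
    sex <- stats::rbinom(n, 1L, 0.5)  # female = 1, male = 0
    batch <- sprintf("batch%02d", sample.int(cfg$n_batches, n, replace = TRUE))

    smoking <- sample(names(smk_probs), n, replace = TRUE, prob = smk_probs)
    pack_years <- numeric(n)
    smoker <- smoking %in% c("current", "quit<1y", "quit>1y")
    pack_years[smoker] <- stats::rgamma(sum(smoker), shape = py_shape,
                                        rate = py_rate)

    # cell proportions: Dirichlet over n_cell_types + an implicit remainder
    dir_alpha <- c(seq(1.5, 5.5, length.out = k_cell), 30)
    raw <- matrix(stats::rgamma(n * (k_cell + 1L),
                                shape = rep(dir_alpha, each = n)), nrow = n)
    cells <- raw[, seq_len(k_cell), drop = FALSE] / rowSums(raw)
    colnames(cells) <- sprintf("cell%d", seq_len(k_cell))

    cls <- pop$cls
    b_lin <- pop$b_lin; b_quad <- pop$b_quad
    b_log <- pop$b_log; b_smk <- pop$b_smk
    if (cfg$effect_shift_sd > 0) {
      nz <- which(cls != "null")
      shift <- stats::rnorm(length(nz), 0, cfg$effect_shift_sd)
      b_lin[nz] <- b_lin[nz] + shift * (cls[nz] == "linear")
      b_quad[nz] <- b_quad[nz] +
        shift * (cls[nz] == "quadratic") / sd_quad_pop * sd_age_pop
      b_log[nz] <- b_log[nz] +
        shift * (cls[nz] == "logage") / sd_log_pop * sd_age_pop
      b_smk[nz] <- b_smk[nz] +
        shift * (cls[nz] == "smoking") / sd_py_pop * sd_age_pop
    }

    M <- matrix(pop$a0, nrow = n, ncol = p, byrow = TRUE)
    is_lin <- cls == "linear"
    if (any(is_lin)) M[, is_lin] <- M[, is_lin] + outer(age, b_lin[is_lin])
    is_quad <- cls == "quadratic"
    if (any(is_quad)) {
      M[, is_quad] <- M[, is_quad] + outer((age - min_age)^2, b_quad[is_quad])
    }
    is_log <- cls == "logage"
    if (any(is_log)) M[, is_log] <- M[, is_log] + outer(log(age), b_log[is_log])
    is_smk <- cls == "smoking"
    if (any(is_smk)) M[, is_smk] <- M[, is_smk] + outer(pack_years, b_smk[is_smk])

    # batch offsets are technical and cohort-specific (all CpGs)
    if (cfg$batch_sd > 0) {
      boff <- matrix(stats::rnorm(cfg$n_batches * p, 0, cfg$batch_sd),
                     nrow = cfg$n_batches)
      bi <- as.integer(factor(batch, levels = sprintf("batch%02d",
                                                      seq_len(cfg$n_batches))))
      M <- M + boff[bi, , drop = FALSE]
    }
    cell_cpgs <- pop$cell_cpgs
    if (length(cell_cpgs) > 0L) {
      cells_c <- sweep(cells, 2L, colMeans(cells), "-")
      M[, cell_cpgs] <- M[, cell_cpgs] + cells_c %*% pop$cell_load
    }
    if (cfg$noise_sd > 0) M <- M + matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)

    beta <- 1 / (1 + 2^(-M))
    beta <- pmin(pmax(beta, 0.001), 0.999)
    dimnames(beta) <- list(sids, ids)
    meth <- as_methylation(beta, "beta")

    # survival driven by centred age + z-scored EpiScore projections
    lp <- cfg$survival$log_hr_age * (age - mid_age)
    score_mat <- NULL
    if (length(hr_panel) > 0L) {
      score_mat <- vapply(hr_panel, function(mod) {
        mod$intercept + as.numeric(beta[, names(mod$weights), drop = FALSE] %*%
                                     mod$weights)
      }, numeric(n))
      colnames(score_mat) <- vapply(hr_panel, `[[`, character(1L), "name")
      z <- scale(score_mat)
      lp <- lp + as.numeric(z %*% cfg$survival$episcore_log_hrs)
    }
    u <- stats::runif(n)
    t_event <- cfg$survival$baseline_scale *
      (-log(u) / exp(lp))^(1 / cfg$survival$baseline_shape)
    cens <- cfg$survival$admin_censor_years
    tte <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)

    pheno <- data.frame(sample_id = sids, age = age, sex = sex,
                        cohort = cfg$cohort_name, batch = batch,
                        set = "set1", smoking_status = smoking,
                        pack_years = pack_years, cells,
                        tte = tte, event = event,
                        stringsAsFactors = FALSE)

    truth <- list(
      cpgs = data.frame(cpg = ids, class = cls, intercept = pop$a0,
                        b_linear = b_lin + ifelse(is_quad, -2 * b_quad * min_age, 0),
                        b_quadratic = b_quad, b_logage = b_log,
                        b_smoking = b_smk, stringsAsFactors = FALSE),
      quad_offset = min_age^2,   # quadratic class: M = a + c*(age-min)^2
      cell_cpgs = ids[cell_cpgs],
      panel = hr_panel,
      true_scores = score_mat,
      hazard_lp = stats::setNames(lp, sids),
      age = stats::setNames(age, sids)
    )
    structure(list(meth = meth, pheno = pheno, truth = truth,
                   config = cfg), class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  tab <- table(x$truth$cpgs$class)
  cat(sprintf("Synthetic cohort '%s': %d samples x %d CpGs; events %d/%d\n",
              x$config$cohort_name, nrow(x$meth), ncol(x$meth),
              sum(x$pheno$event), nrow(x$pheno)))
  cat("  CpG classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the methylation matrix and phenotype sheet in the package's
#' delimited formats plus the per-CpG truth record as a sidecar table.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(meth = file.path(dir, "methylation.tsv"),
             pheno = file.path(dir, "phenotypes.tsv"),
             truth = file.path(dir, "truth_cpgs.tsv"))
  write_methylation(cohort$meth, paths[["meth"]])
  write_phenotypes(cohort$pheno, paths[["pheno"]])
  utils::write.table(cohort$truth$cpgs, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
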