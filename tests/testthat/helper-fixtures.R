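# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

tiny_meth <- function(n = 3, p = 4, seed = 42, scale = "beta") {
  set.seed(seed)
  m <- matrix(runif(n * p, 0.05, 0.95), n, p,
              dimnames = list(sprintf("s%d", seq_len(n)),
                              sprintf("cg%03d", seq_len(p))))
  as_methylation(m, scale)
}

tiny_pheno <- function(n = 3, seed = 42) {
  set.seed(seed)
  data.frame(sample_id = sprintf("s%d", seq_len(n)),
             age = runif(n, 20, 80), sex = rbinom(n, 1, 0.5),
             cohort = "c1", batch = "b1",
             stringsAsFactors = FALSE)
}

# A small survival dataset with a known signal in x.
tiny_surv <- function(n = 60, b = 0.8, seed = 3, censor_q = 0.7) {
  set.seed(seed)
  x <- rnorm(n)
  z <- rbinom(n, 1, 0.5)
  t_raw <- rexp(n, rate = exp(b * x + 0.3 * z))
  cens <- stats::quantile(t_raw, censor_q)
  list(x = x, z = z, tte = pmin(t_raw, cens) + 1e-9,
       event = as.integer(t_raw <= cens))
}

# Brute-force pairwise concordance oracle (double loop, the definition).
concordance_oracle <- function(score, tte, event) {
  n <- length(score); conc <- 0; comp <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (tte[i] < tte[j] && event[i] == 1) {
      comp <- comp + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Coarse-to-fine grid maximization of the Breslow partial likelihood:
# an independent oracle for Cox point estimates (final step size 1e-4).
grid_cox_oracle <- function(X, tte, event, lower = -3, upper = 3) {
  X <- as.matrix(X)
  p <- ncol(X)
  breslow_ll <- function(beta) {
    eta <- as.numeric(X %*% beta)
    ord <- order(tte, decreasing = TRUE)
    t_s <- tte[ord]; d_s <- event[ord]; e_s <- exp(eta[ord])
    r <- rle(t_s); grp <- rep(seq_along(r$lengths), r$lengths)
    S0 <- cumsum(e_s)[cumsum(r$lengths)]
    d_grp <- tapply(d_s, grp, sum)
    sum(eta[ord] * d_s) - sum(d_grp * log(S0))
  }
  centre <- rep(0, p); width <- (upper - lower) / 2
  for (step in c(0.1, 0.01, 1e-3, 1e-4)) {
    grids <- lapply(seq_len(p), function(j) {
      seq(centre[j] - width, centre[j] + width, by = step)
    })
    pts <- as.matrix(expand.grid(grids))
    ll <- apply(pts, 1L, breslow_ll)
    centre <- pts[which.max(ll), ]
    width <- 2 * step
  }
  centre
}

# Proximal (sub)gradient descent oracle for the Gaussian elastic-net
# objective, run from several random starts to a tight tolerance.
enet_prox_oracle <- function(X, y, alpha, lambda, n_starts = 5,
                             tol = 1e-10, max_iter = 200000L, seed = 99) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu, "-")^2))
  Xs <- sweep(sweep(X, 2, mu, "-"), 2, sds, "/")
  yc <- y - mean(y)
  L <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  obj <- function(b) {
    mean((yc - Xs %*% b)^2) / 2 +
      lambda * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
  }
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  best <- Inf
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    b <- rnorm(p, 0, 0.5)
    o_prev <- obj(b)
    for (it in seq_len(max_iter)) {
      grad <- -as.numeric(crossprod(Xs, yc - Xs %*% b)) / n +
        lambda * (1 - alpha) * b
      b <- soft(b - grad / L, lambda * alpha / L)
      if (it %% 100 == 0) {
        o <- obj(b)
        if (o_prev - o < tol) break
        o_prev <- o
      }
    }
    best <- min(best, obj(b))
  }
  best
}

# Penalized Gaussian elastic-net objective of a fitted path at one
# lambda, on the internal standardized scale.
enet_objective <- function(path, X, y, lambda) {
  i <- which.min(abs(path$lambda - lambda))
  b <- path$beta_std[, i]
  sds <- ifelse(path$x_scale > 0, path$x_scale, 1)
  Xs <- sweep(sweep(X, 2, path$x_center, "-"), 2, sds, "/")
  yc <- y - path$y_mean
  mean((yc - Xs %*% b)^2) / 2 +
    path$lambda[i] * (path$alpha * sum(abs(b)) +
                        (1 - path$alpha) / 2 * sum(b^2))
}
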