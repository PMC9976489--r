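# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "methclocks_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. Mersenne-Twister is pinned so that identical
# seeds reproduce byte-identical draws across platforms.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stopf("seed must be a single integer, got %s", deparse(seed))
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive a child seed from a base seed and a stream label, staying inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stopf("'%s' must be an integer >= %d (got %s)", name, min, deparse(x))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stopf("'%s' must be a number in [%s, %s] (got %s)", name,
          format(min), format(max), deparse(x))
  }
  as.numeric(x)
}

# Dummy-code a phenotype data.frame into a numeric covariate matrix
# (no intercept column). Factors/characters are expanded against their
# first level; numeric columns pass through.
covariate_matrix <- function(pheno, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(pheno), ncol = 0L))
  }
  missing_cols <- setdiff(covariates, names(pheno))
  if (length(missing_cols) > 0L) {
    stopf("covariates not found in phenotype table: %s",
          paste(missing_cols, collapse = ", "))
  }
  df <- pheno[covariates]
  for (nm in names(df)) {
    if (is.character(df[[nm]]) || is.logical(df[[nm]])) df[[nm]] <- factor(df[[nm]])
  }
  mm <- stats::model.matrix(~ ., data = df)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  # drop constant columns (e.g. single-level factors after subsetting)
  keep <- apply(mm, 2L, function(col) stats::sd(col) > 0)
  mm[, keep, drop = FALSE]
}
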