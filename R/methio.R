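#' Read and write methylation matrices
#'
#' A methylation matrix is stored as a plain numeric matrix with sample
#' identifiers as row names and CpG identifiers as column names, plus a
#' `"meth_scale"` attribute recording whether values are beta proportions
#' in \[0, 1\] or M-values (log2 beta/(1-beta)). On disk it is a delimited
#' text file: one header row of CpG ids and one leading column of sample
#' ids (samples as rows).
#'
#' @param path path to a delimited text file (tab by default, comma
#'   accepted; inferred from the header line).
#' @param scale either `"beta"` or `"mvalue"`; beta matrices are validated
#'   to lie in \[0, 1\].
#' @return `read_methylation()` returns the matrix; `write_methylation()`
#'   returns `path` invisibly.
#' @examples
#' m <- matrix(runif(6), 2, 3, dimnames = list(c("s1", "s2"), c("cg1", "cg2", "cg3")))
#' m <- as_methylation(m, "beta")
#' f <- tempfile(fileext = ".tsv")
#' write_methylation(m, f)
#' all.equal(read_methylation(f), m)
#' @export
read_methylation <- function(path, scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    stopf("empty methylation file: %s", path, class = "methclocks_format_error")
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stopf("methylation file has no CpG columns: %s", path,
                           class = "methclocks_format_error")
  sample_ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  bad_num <- !vapply(vals, is.numeric, logical(1L))
  if (any(bad_num)) {
    stopf("non-numeric methylation values in column(s): %s",
          paste(names(vals)[bad_num], collapse = ", "),
          class = "methclocks_format_error")
  }
  m <- as.matrix(vals)
  rownames(m) <- sample_ids
  as_methylation(m, scale)
}

#' @param matrix a methylation matrix as returned by [as_methylation()].
#' @param sep field separator for writing (default tab).
#' @rdname read_methylation
#' @export
write_methylation <- function(matrix, path, sep = "\t") {
  m <- as_methylation(matrix, meth_scale(matrix))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param x a numeric matrix with sample row names and CpG column names.
#' @rdname read_methylation
#' @export
as_methylation <- function(x, scale = c("beta", "mvalue")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) stopf("methylation data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stopf("methylation matrix needs sample row names and CpG column names")
  }
  if (anyDuplicated(rownames(x))) {
    stopf("duplicate sample ids: %s",
          paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "),
          class = "methclocks_format_error")
  }
  if (anyDuplicated(colnames(x))) {
    stopf("duplicate CpG ids: %s",
          paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "),
          class = "methclocks_format_error")
  }
  if (scale == "beta") {
    bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      cells <- apply(utils::head(bad, 5L), 1L, function(ij) {
        sprintf("[%s, %s] = %g", rownames(x)[ij[1L]], colnames(x)[ij[2L]],
                x[ij[1L], ij[2L]])
      })
      stopf("beta values outside [0, 1] at %d cell(s), e.g. %s",
            nrow(bad), paste(cells, collapse = "; "),
            class = "methclocks_validation_error")
    }
  }
  attr(x, "meth_scale") <- scale
  x
}

#' @rdname read_methylation
#' @export
meth_scale <- function(matrix) {
  s <- attr(matrix, "meth_scale")
  if (is.null(s)) "beta" else s
}

#' Convert between beta values and M-values
#'
#' M = log2(beta / (1 - beta)); the inverse is beta = 2^M / (1 + 2^M).
#' Beta values at or beyond the open interval (0, 1) are clipped to
#' \[1e-3, 1 - 1e-3\] with a warning before the transform, so M-values
#' stay finite.
#'
#' @param beta numeric vector or matrix of methylation proportions.
#' @param m numeric vector or matrix of M-values.
#' @param clip clipping bound applied to beta values before the log
#'   transform (default 1e-3).
#' @return the transformed object, same shape as the input. Matrix inputs
#'   keep dimnames and get their `"meth_scale"` attribute switched.
#' @export
beta_to_m <- function(beta, clip = 1e-3) {
  n_out <- sum(beta <= 0 | beta >= 1, na.rm = TRUE)
  if (n_out > 0L) {
    warnf("%d beta value(s) at or outside (0, 1); clipped to [%g, %g]",
          n_out, clip, 1 - clip)
  }
  b <- pmin(pmax(beta, clip), 1 - clip)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) attr(out, "meth_scale") <- "mvalue"
  out
}

#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  out <- 1 / (1 + 2^(-m))
  if (is.matrix(m)) attr(out, "meth_scale") <- "beta"
  out
}

#' Mean-impute missing methylation values per CpG and per cohort
#'
#' Each missing entry is replaced by the arithmetic mean of the
#' non-missing values for that CpG within the sample's cohort; observed
#' entries are never touched.
#'
#' @param matrix a methylation matrix (any scale).
#' @param cohort character or factor of cohort labels, one per sample row.
#' @return the matrix with no missing values.
#' @export
impute_mean_per_cpg <- function(matrix, cohort) {
  if (length(cohort) != nrow(matrix)) {
    stopf("cohort labels (%d) do not match sample rows (%d)",
          length(cohort), nrow(matrix))
  }
  if (!anyNA(matrix)) return(matrix)
  out <- matrix
  for (co in unique(cohort)) {
    rows <- which(cohort == co)
    block <- out[rows, , drop = FALSE]
    na_cols <- which(colSums(is.na(block)) > 0L)
    for (j in na_cols) {
      obs <- block[, j][!is.na(block[, j])]
      if (length(obs) == 0L) {
        stopf("cannot impute CpG '%s' in cohort '%s': all values missing",
              colnames(matrix)[j], co, class = "methclocks_imputation_error")
      }
      miss <- is.na(block[, j])
      out[rows[miss], j] <- mean(obs)
    }
  }
  out
}

#' Restrict matrices to their common CpGs
#'
#' Mirrors the harmonisation step applied before pooling cohorts measured
#' on different arrays: every matrix is cut down to the sorted
#' intersection of CpG ids; sample rows are untouched.
#'
#' @param matrices a list of methylation matrices.
#' @return a list of matrices over the identical, sorted CpG set.
#' @export
intersect_cpgs <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L) {
    stopf("intersect_cpgs() needs a list of >= 2 matrices")
  }
  common <- Reduce(intersect, lapply(matrices, colnames))
  if (length(common) == 0L) stopf("no CpGs shared across all matrices")
  common <- sort(common)
  lapply(matrices, function(m) {
    out <- m[, common, drop = FALSE]
    attr(out, "meth_scale") <- meth_scale(m)
    out
  })
}

#' Standardize columns to mean zero, unit variance
#'
#' Uses the sample (n - 1 denominator) standard deviation, so z-scores
#' are bit-reproducible against `scale()`. Returns the centred/scaled
#' matrix together with the moments needed to invert the transform.
#'
#' @param x numeric matrix.
#' @return list with `values` (standardized matrix), `means`, `sds`.
#' @export
standardize_columns <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  zero <- which(sds <= 0 | !is.finite(sds))
  if (length(zero) > 0L) {
    stopf("zero-variance column(s): %s",
          paste(colnames(x)[zero] %||% zero, collapse = ", "))
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sds, "/")
  list(values = z, means = mu, sds = sds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read and write phenotype tables
#'
#' A phenotype table is a data.frame with one row per sample. The column
#' `sample_id` is mandatory; the conventional columns are `age` (years),
#' `sex` (female = 1, male = 0), `cohort`, `batch`, `set`,
#' `smoking_status` (current / quit<1y / quit>1y / never / unknown;
#' "unknown" is a level of its own, not a missing value), `pack_years`,
#' cell proportions `cell1..cell6`, and the survival pair `tte` (years)
#' and `event` (0/1). `tte` and `event` must be missing together.
#'
#' @param path delimited text file with a header of column names.
#' @param pheno a phenotype data.frame.
#' @param sep field separator for writing.
#' @return `read_phenotypes()` returns a validated data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_phenotypes(df)
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(pheno, path, sep = "\t") {
  validate_phenotypes(pheno)
  utils::write.table(pheno, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(pheno) {
  if (!is.data.frame(pheno)) stopf("phenotypes must be a data.frame")
  if (!"sample_id" %in% names(pheno)) stopf("phenotype table lacks a 'sample_id' column")
  if (anyDuplicated(pheno$sample_id)) {
    stopf("duplicate sample ids in phenotype table",
          class = "methclocks_format_error")
  }
  if ("age" %in% names(pheno) && any(pheno$age <= 0, na.rm = TRUE)) {
    stopf("ages must be positive (years)")
  }
  if (xor("tte" %in% names(pheno), "event" %in% names(pheno))) {
    stopf("'tte' and 'event' must be provided together")
  }
  if (all(c("tte", "event") %in% names(pheno))) {
    if (any(xor(is.na(pheno$tte), is.na(pheno$event)))) {
      stopf("'tte' and 'event' must be missing together")
    }
    if (any(pheno$tte < 0, na.rm = TRUE)) stopf("'tte' must be >= 0")
    if (!all(pheno$event %in% c(0, 1, NA))) stopf("'event' must be 0/1")
  }
  pheno
}

#' Read and write model weight tables
#'
#' The interchange format for clock and EpiScore coefficients: three
#' delimited columns `feature`, `transform` (`linear` or `squared`) and
#' `weight`, with the intercept stored as one `(Intercept)` row. Header
#' comment lines of the form `# key: value` carry model metadata (name,
#' outcome transform, scaling contract).
#'
#' @param path delimited text file.
#' @param weights data.frame with columns `feature`, `transform`, `weight`.
#' @param intercept model intercept (real).
#' @param meta named list of scalar metadata written as `# key: value`.
#' @return `read_weight_table()` returns a list with `weights`,
#'   `intercept`, `meta`.
#' @export
read_weight_table <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    pos <- regexpr(":", kv, fixed = TRUE)
    if (pos > 0L) {
      key <- trimws(substr(kv, 1L, pos - 1L))
      meta[[key]] <- trimws(substr(kv, pos + 1L, nchar(kv)))
    }
  }
  body <- lines[!grepl("^#", lines)]
  sep <- if (grepl("\t", body[1L], fixed = TRUE)) "\t" else ","
  df <- utils::read.table(text = body, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("feature", "transform", "weight") %in% names(df))) {
    stopf("weight table needs columns feature, transform, weight",
          class = "methclocks_format_error")
  }
  if (!all(is.finite(df$weight))) stopf("non-finite weights in %s", path)
  int_row <- df$feature == "(Intercept)"
  intercept <- if (any(int_row)) sum(df$weight[int_row]) else 0
  w <- df[!int_row, , drop = FALSE]
  if (anyDuplicated(paste(w$feature, w$transform))) {
    stopf("duplicate feature rows in weight table",
          class = "methclocks_format_error")
  }
  list(weights = w[, c("feature", "transform", "weight")],
       intercept = intercept, meta = meta)
}

#' @rdname read_weight_table
#' @export
write_weight_table <- function(weights, intercept, path, meta = list(),
                               sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]], digits = 17)), con)
  }
  df <- rbind(data.frame(feature = "(Intercept)", transform = "linear",
                         weight = intercept, stringsAsFactors = FALSE),
              weights[, c("feature", "transform", "weight")])
  utils::write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
                     con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
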