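#' Assemble a subject-level dataset for misclassification modelling
#'
#' Validates and packages subject-level records for the two-level Poisson
#' outcome model with a potentially misclassified binary exposure. Each row of
#' `df` is one subject; subjects are grouped into clusters (e.g. geographic
#' units) that receive random intercepts in both the outcome and exposure
#' models.
#'
#' Cluster labels may be arbitrary (character, factor, or non-contiguous
#' integers); they are re-indexed internally to `1..N` and the original labels
#' are kept in `cluster_labels`.
#'
#' @param df A data frame with one row per subject.
#' @param y Name of the nonnegative integer count outcome column.
#' @param cluster Name of the cluster identifier column.
#' @param r Name of the positive offset column (exposure time/size), or `NULL`
#'   for a constant offset of 1.
#' @param z_outcome Character vector of error-free covariate columns entering
#'   the outcome (Poisson) model. May be empty and may coincide with
#'   `z_exposure`.
#' @param z_exposure Character vector of covariate columns entering the
#'   exposure (logistic) model.
#' @param x1 Name of the first fallible binary exposure assessment column.
#' @param x2 Name of the second fallible assessment column, or `NULL` when only
#'   one assessment was made.
#' @param x_true Name of the true-exposure column, or `NULL`. Only simulated
#'   data carry this; it is never used in fitting, only for evaluation.
#'
#' @return An object of class `mc_data`: a list with elements `y`, `r`,
#'   `cluster` (re-indexed to `1..N`), `cluster_labels`, `Zy`, `Zx` (covariate
#'   matrices, possibly zero-column), `x1`, `x2`, `x_true`, `n`, `N`.
#' @examples
#' d <- simulate_misclass_data(sim_design(N = 4, n_per_cluster = 25), seed = 1)
#' d
#' @export
mc_data <- function(df, y = "y", cluster = "cluster", r = NULL,
                    z_outcome = character(), z_exposure = character(),
                    x1 = "x1", x2 = NULL, x_true = NULL) {
  if (!is.data.frame(df)) mc_stop("`df` must be a data frame", "miscount_data_error")
  need <- c(y, cluster, r, z_outcome, z_exposure, x1, x2, x_true)
  miss <- setdiff(unique(need), names(df))
  if (length(miss))
    mc_stop(sprintf("column(s) not found in data: %s", paste(miss, collapse = ", ")),
            "miscount_data_error")

  pull_num <- function(col) {
    v <- df[[col]]
    if (anyNA(v)) mc_stop(sprintf("missing values in column '%s'", col), "miscount_data_error")
    as.numeric(v)
  }
  pull_bin <- function(col) {
    v <- pull_num(col)
    if (!all(v %in% c(0, 1)))
      mc_stop(sprintf("column '%s' must be binary 0/1", col), "miscount_data_error")
    as.integer(v)
  }

  yv <- pull_num(y)
  if (any(yv < 0) || any(yv != floor(yv)))
    mc_stop(sprintf("outcome '%s' must contain nonnegative integers", y), "miscount_data_error")
  rv <- if (is.null(r)) rep(1, nrow(df)) else pull_num(r)
  if (any(rv <= 0)) mc_stop(sprintf("offset '%s' must be strictly positive", r), "miscount_data_error")

  clraw <- df[[cluster]]
  if (anyNA(clraw)) mc_stop(sprintf("missing values in column '%s'", cluster), "miscount_data_error")
  clf <- factor(clraw, levels = unique(clraw))
  cl <- as.integer(clf)

  as_z <- function(cols) {
    m <- if (length(cols)) as.matrix(vapply(cols, pull_num, numeric(nrow(df))))
         else matrix(0, nrow(df), 0L)
    if (nrow(df) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, cols))
    colnames(m) <- cols
    m
  }

  out <- list(
    y = yv, r = rv, cluster = cl, cluster_labels = levels(clf),
    Zy = as_z(z_outcome), Zx = as_z(z_exposure),
    x1 = pull_bin(x1),
    x2 = if (is.null(x2)) NULL else pull_bin(x2),
    x_true = if (is.null(x_true)) NULL else pull_bin(x_true),
    n = nrow(df), N = nlevels(clf)
  )
  class(out) <- "mc_data"
  out
}

#' Read a delimited text file into an `mc_data` object
#'
#' Thin wrapper around [utils::read.csv()] followed by [mc_data()]. Missing
#' values in any required column are an error, never silently dropped.
#'
#' @param path Path to a CSV file with a header row.
#' @param ... Column-name mapping passed to [mc_data()].
#' @return An `mc_data` object.
#' @export
read_mc_data <- function(path, ...) {
  if (!file.exists(path)) mc_stop(sprintf("file not found: %s", path), "miscount_io_error")
  mc_data(read.csv(path), ...)
}

#' Write an `mc_data` object back to CSV
#'
#' Columns are written under the canonical names `y`, `r`, `cluster`,
#' `z1..zq`, `x1` (and `x2`, `x_true` when present). Covariate columns are the
#' union of the outcome- and exposure-model sets.
#'
#' @param data An `mc_data` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mc_data <- function(data, path) {
  stopifnot(inherits(data, "mc_data"))
  df <- as.data.frame(data)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.mc_data <- function(x, ...) {
  zs <- cbind(x$Zy, x$Zx[, setdiff(colnames(x$Zx), colnames(x$Zy)), drop = FALSE])
  df <- data.frame(y = x$y, r = x$r,
                   cluster = x$cluster_labels[x$cluster],
                   stringsAsFactors = FALSE)
  if (ncol(zs)) df <- cbind(df, as.data.frame(zs))
  df$x1 <- x$x1
  if (!is.null(x$x2)) df$x2 <- x$x2
  if (!is.null(x$x_true)) df$x_true <- x$x_true
  df
}

#' @export
print.mc_data <- function(x, ...) {
  cat(sprintf("<mc_data> %d subjects in %d clusters\n", x$n, x$N))
  cat(sprintf("  outcome covariates: %s\n",
              if (ncol(x$Zy)) paste(colnames(x$Zy), collapse = ", ") else "(none)"))
  cat(sprintf("  exposure covariates: %s\n",
              if (ncol(x$Zx)) paste(colnames(x$Zx), collapse = ", ") else "(none)"))
  cat(sprintf("  assessments: x1%s%s\n",
              if (!is.null(x$x2)) ", x2" else "",
              if (!is.null(x$x_true)) " (+ x_true, simulated)" else ""))
  invisible(x)
}
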