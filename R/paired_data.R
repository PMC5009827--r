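#' Paired sample-aligned data matrices
#'
#' Container for the two views of a canonical correlation problem: an n x p
#' matrix X and an n x q matrix Y observed on the same n samples, in the same
#' row order. Entries must be finite; missing values are rejected
#' (complete-case analysis is assumed upstream).
#'
#' @param X,Y numeric matrices with equal row counts.
#' @param sample_ids sample labels (defaults to rownames of X, else s1..sn).
#' @param x_features,y_features feature labels (default colnames, else
#'   x1..xp / y1..yq).
#' @param standardized logical flag; set by [standardize()].
#' @return an object of class `paired_data`.
#' @export
paired_data <- function(X, Y, sample_ids = NULL,
                        x_features = NULL, y_features = NULL,
                        standardized = FALSE) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  if (nrow(X) != nrow(Y)) {
    stop(sprintf("X has %d rows but Y has %d: samples must be aligned",
                 nrow(X), nrow(Y)))
  }
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must contain only finite values (no NA/NaN/Inf)")
  }
  n <- nrow(X)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(X)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs")
  if (is.null(x_features)) {
    x_features <- colnames(X)
    if (is.null(x_features)) x_features <- paste0("x", seq_len(ncol(X)))
  }
  if (is.null(y_features)) {
    y_features <- colnames(Y)
    if (is.null(y_features)) y_features <- paste0("y", seq_len(ncol(Y)))
  }
  dimnames(X) <- list(sample_ids, x_features)
  dimnames(Y) <- list(sample_ids, y_features)
  structure(list(X = X, Y = Y, sample_ids = as.character(sample_ids),
                 x_features = as.character(x_features),
                 y_features = as.character(y_features),
                 standardized = isTRUE(standardized)),
            class = "paired_data")
}

#' @export
print.paired_data <- function(x, ...) {
  cat(sprintf("paired_data: n = %d samples, p = %d (X), q = %d (Y)%s\n",
              nrow(x$X), ncol(x$X), ncol(x$Y),
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Column standardization statistics
#'
#' Computes per-column centers (means) and scales (Euclidean norms of the
#' centered columns) used to standardize a matrix so that every column has
#' mean zero and unit l2 norm. The unit-norm convention makes the diagonal
#' of the sample cross-product the identity, which the grouping-effect bound
#' assumes.
#'
#' @param M numeric matrix.
#' @return list with `center` and `scale` vectors.
#' @export
column_stats <- function(M) {
  ctr <- colMeans(M)
  sc <- sqrt(colSums(sweep(M, 2L, ctr, "-")^2))
  zero <- which(sc <= .Machine$double.eps * nrow(M))
  if (length(zero)) {
    nm <- colnames(M)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop(sprintf("zero-variance column(s): %s", paste(nm, collapse = ", ")))
  }
  list(center = ctr, scale = sc)
}

apply_column_stats <- function(M, stats) {
  sweep(sweep(M, 2L, stats$center, "-"), 2L, stats$scale, "/")
}

#' Standardize paired data
#'
#' Mean-centers every column of X and Y, then rescales it to unit l2 norm.
#' Idempotent up to round-off. Optionally, statistics computed on a training
#' set can be applied to held-out data via `stats`, which is how
#' cross-validation avoids information leakage.
#'
#' @param data a [paired_data()] object.
#' @param stats optional list with elements `x` and `y`, each a
#'   [column_stats()] result from training data, to apply instead of
#'   computing fresh statistics.
#' @return a standardized `paired_data` (flag set only when `stats` is NULL,
#'   since applying foreign statistics does not center the columns exactly).
#' @export
standardize <- function(data, stats = NULL) {
  stopifnot(inherits(data, "paired_data"))
  if (is.null(stats)) {
    sx <- column_stats(data$X)
    sy <- column_stats(data$Y)
    out <- paired_data(apply_column_stats(data$X, sx),
                       apply_column_stats(data$Y, sy),
                       sample_ids = data$sample_ids,
                       x_features = data$x_features,
                       y_features = data$y_features,
                       standardized = TRUE)
    attr(out, "stats") <- list(x = sx, y = sy)
  } else {
    out <- paired_data(apply_column_stats(data$X, stats$x),
                       apply_column_stats(data$Y, stats$y),
                       sample_ids = data$sample_ids,
                       x_features = data$x_features,
                       y_features = data$y_features,
                       standardized = FALSE)
    attr(out, "stats") <- stats
  }
  out
}
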