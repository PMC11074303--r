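# PCA feature extraction: per-pixel spectra are projected onto the leading
# eigenvectors of the band covariance, X ~ Z %*% t(W) + mean. The first
# component carries most of the tissue contrast and feeds both the
# classifier and the cancer-vs-noncancer t-test.

#' Fit a PCA model
#'
#' Eigendecomposition of the unbiased (1/(n-1)) sample covariance of the
#' centered data. Retains either a fixed number of components `k` or the
#' smallest `k` whose eigenvalues sum to at least `variance_fraction` of the
#' total. Loadings are column-orthonormal; each column's sign is fixed so
#' its largest-magnitude entry is positive, making fits deterministic.
#'
#' @param X numeric matrix, n >= 2 rows (pixels) by m columns (bands).
#' @param k number of components to retain (1..m). Give exactly one of `k`
#'   and `variance_fraction`; with neither, `variance_fraction = 0.95`.
#' @param variance_fraction minimum fraction of total variance to retain,
#'   in (0, 1].
#' @return Object of class `thz_pca`: `mean` (length m), `loadings`
#'   (m x k, orthonormal columns), `eigenvalues` (all m, nonincreasing),
#'   `k`.
#' @export
pca_fit <- function(X, k = NULL, variance_fraction = NULL) {
  X <- .as_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("insufficient-data error: PCA needs at least 2 rows")
  if (!is.null(k) && !is.null(variance_fraction))
    stop("give exactly one of 'k' and 'variance_fraction'")
  if (is.null(k) && is.null(variance_fraction)) variance_fraction <- 0.95
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  S <- crossprod(Xc) / (n - 1)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)          # clip tiny negative round-off
  vecs <- eg$vectors
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(m)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  if (is.null(k)) {
    if (variance_fraction <= 0 || variance_fraction > 1)
      stop("'variance_fraction' must be in (0, 1]")
    total <- sum(vals)
    if (variance_fraction == 1) {
      k <- sum(vals > total * 1e-12)  # rank of the covariance
    } else {
      k <- which(cumsum(vals) >= variance_fraction * total)[1]
    }
    k <- max(1L, as.integer(k))
  } else {
    if (k < 1 || k > m) stop("value error: 'k' must be in 1..", m)
    k <- as.integer(k)
  }
  structure(list(mean = mu, loadings = vecs[, seq_len(k), drop = FALSE],
                 eigenvalues = vals, k = k, m = m),
            class = "thz_pca")
}

#' @export
print.thz_pca <- function(x, ...) {
  expl <- sum(x$eigenvalues[seq_len(x$k)]) / sum(x$eigenvalues)
  cat(sprintf("PCA: %d of %d components retained (%.1f%% of variance)\n",
              x$k, x$m, 100 * expl))
  invisible(x)
}

#' Project data onto the retained components
#'
#' @param model a `thz_pca` fit.
#' @param X matrix with the fit's number of columns.
#' @return n x k score matrix `Z = (X - mean) %*% loadings`.
#' @export
pca_transform <- function(model, X) {
  stopifnot(inherits(model, "thz_pca"))
  X <- .as_matrix(X)
  if (ncol(X) != model$m)
    stop("dimension error: expected ", model$m, " columns, got ", ncol(X))
  sweep(X, 2L, model$mean, "-") %*% model$loadings
}

#' Map scores back to band space
#'
#' @param model a `thz_pca` fit.
#' @param Z n x k score matrix.
#' @return Reconstruction `Z %*% t(loadings) + mean`. Over the training
#'   data, the mean squared reconstruction error equals the sum of the
#'   discarded eigenvalues (up to the n-1 vs n variance convention).
#' @export
pca_reconstruct <- function(model, Z) {
  stopifnot(inherits(model, "thz_pca"))
  Z <- .as_matrix(Z, "Z")
  if (ncol(Z) != model$k)
    stop("dimension error: expected ", model$k, " columns, got ", ncol(Z))
  sweep(Z %*% t(model$loadings), 2L, model$mean, "+")
}

#' Serialize a PCA model to JSON
#'
#' @param model a `thz_pca` fit.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
pca_write_json <- function(model, path) {
  stopifnot(inherits(model, "thz_pca"))
  jsonlite::write_json(
    list(mean = model$mean, loadings = as.vector(model$loadings),
         eigenvalues = model$eigenvalues, k = model$k, m = model$m),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a PCA model from JSON
#'
#' @param path file written by [pca_write_json()].
#' @return A `thz_pca` object.
#' @export
pca_read_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  structure(list(mean = as.numeric(o$mean),
                 loadings = matrix(as.numeric(o$loadings),
                                   nrow = o$m, ncol = o$k),
                 eigenvalues = as.numeric(o$eigenvalues),
                 k = as.integer(o$k), m = as.integer(o$m)),
            class = "thz_pca")
}
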