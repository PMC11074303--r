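# Spectral preprocessing: sampling guard, min-max normalization, FIR
# low-pass filtering of pixel spectra.

#' Nyquist sampling check
#'
#' A sampled THz waveform is alias-free only if the sampling interval does
#' not exceed half the reciprocal of the highest frequency component:
#' `sample_interval <= 1 / (2 * max_frequency)`.
#'
#' @param sample_interval sampling interval (time units), > 0.
#' @param max_frequency highest frequency component (1/time), > 0.
#' @return `TRUE` if the condition holds, `FALSE` otherwise.
#' @export
check_nyquist <- function(sample_interval, max_frequency) {
  .stopifnot_scalar_num(sample_interval, "sample_interval", positive = TRUE)
  .stopifnot_scalar_num(max_frequency, "max_frequency", positive = TRUE)
  sample_interval <= 1 / (2 * max_frequency)
}

#' Construct a sampled signal
#'
#' @param values numeric vector of intensities `x[n]`, finite.
#' @param sample_interval positive sampling interval `T_s`.
#' @return An object of class `sampled_signal`.
#' @export
sampled_signal <- function(values, sample_interval = 1) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("'values' must be finite numeric")
  .stopifnot_scalar_num(sample_interval, "sample_interval", positive = TRUE)
  structure(list(values = as.numeric(values),
                 sample_interval = sample_interval),
            class = "sampled_signal")
}

#' Decimate a sampled signal
#'
#' Keeps every `factor`-th sample starting at index 0 and scales the
#' sampling interval accordingly. No anti-alias pre-filter is applied; use
#' [check_nyquist()] on the decimated interval.
#'
#' @param signal a [sampled_signal()].
#' @param factor positive integer decimation factor.
#' @return The decimated `sampled_signal`.
#' @export
resample_signal <- function(signal, factor) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("'factor' must be a positive integer")
  keep <- seq(1L, length(signal$values), by = as.integer(factor))
  sampled_signal(signal$values[keep], signal$sample_interval * factor)
}

#' Fit and apply per-feature min-max normalization
#'
#' Rescales every feature column to \[0, 1\] via
#' `(x - min(x)) / (max(x) - min(x))`. Constant columns make the transform
#' undefined and are rejected. Fit the parameters on the training split
#' only and re-apply them to held-out data with [minmax_apply()] to avoid
#' leakage.
#'
#' @param X numeric matrix (rows = pixels, columns = features).
#' @return List with `X_normalized` and `params` (class
#'   `minmax_params`: `per_feature_min`, `per_feature_max`).
#' @export
minmax_fit_apply <- function(X) {
  X <- .as_matrix(X)
  if (nrow(X) < 1L) stop("need at least one row")
  if (any(!is.finite(X))) stop("'X' must be finite")
  lo <- apply(X, 2L, min)
  hi <- apply(X, 2L, max)
  degen <- which(hi == lo)
  if (length(degen))
    stop("degenerate-feature error: constant column(s) ",
         paste(if (is.null(colnames(X))) degen else colnames(X)[degen],
               collapse = ", "),
         " have max = min; min-max normalization is undefined there")
  params <- structure(list(per_feature_min = lo, per_feature_max = hi),
                      class = "minmax_params")
  list(X_normalized = minmax_apply(params, X), params = params)
}

#' Apply fitted min-max parameters
#'
#' @param params a `minmax_params` object from [minmax_fit_apply()].
#' @param X matrix with the same number of columns as the fit.
#' @return The normalized matrix. Values outside the training range map
#'   outside \[0, 1\]; that is intentional for held-out data.
#' @export
minmax_apply <- function(params, X) {
  stopifnot(inherits(params, "minmax_params"))
  X <- .as_matrix(X)
  if (ncol(X) != length(params$per_feature_min))
    stop("dimension error: expected ", length(params$per_feature_min),
         " columns, got ", ncol(X))
  sweep(sweep(X, 2L, params$per_feature_min, "-"), 2L,
        params$per_feature_max - params$per_feature_min, "/")
}

#' Invert min-max normalization
#'
#' @param params a `minmax_params` object.
#' @param X_normalized normalized matrix.
#' @return The matrix on the original scale:
#'   `x_norm * (max - min) + min`.
#' @export
minmax_invert <- function(params, X_normalized) {
  stopifnot(inherits(params, "minmax_params"))
  X_normalized <- .as_matrix(X_normalized, "X_normalized")
  if (ncol(X_normalized) != length(params$per_feature_min))
    stop("dimension error: expected ", length(params$per_feature_min),
         " columns, got ", ncol(X_normalized))
  sweep(sweep(X_normalized, 2L,
              params$per_feature_max - params$per_feature_min, "*"),
        2L, params$per_feature_min, "+")
}

#' FIR filter kernel
#'
#' @param taps numeric vector of impulse-response coefficients.
#' @param normalize rescale taps to sum to 1 (a unity-DC-gain smoother)?
#' @return An object of class `filter_kernel`.
#' @export
filter_kernel <- function(taps, normalize = FALSE) {
  if (!is.numeric(taps) || length(taps) < 1L || any(!is.finite(taps)))
    stop("'taps' must be a non-empty finite numeric vector")
  taps <- as.numeric(taps)
  if (normalize) taps <- taps / sum(taps)
  structure(list(taps = taps,
                 normalized = isTRUE(all.equal(sum(taps), 1))),
            class = "filter_kernel")
}

#' Default low-pass kernel
#'
#' The 3-tap binomial smoother `[0.25, 0.5, 0.25]`, a mild low-pass with
#' unity DC gain. Spectra of adjacent THz bands are strongly correlated, so
#' a short symmetric smoother removes band-to-band acquisition noise
#' without displacing spectral features.
#'
#' @return A `filter_kernel`.
#' @export
binomial_kernel <- function() filter_kernel(c(0.25, 0.5, 0.25))

#' Low-pass filter pixel spectra
#'
#' Convolves every row of `X` with the kernel taps — the discrete analogue
#' of the continuous convolution `y(t) = (x * h)(t)` — returning output of
#' the same length ("same" mode). Boundaries use edge replication (nearest
#' padding), which avoids artificial dips at the spectrum ends; the
#' convention is fixed for reproducibility. The output sample `y[i]` is
#' `sum_j taps[j] * x[i + j - 1 - floor(L/2)]` (1-based, L = kernel
#' length), so a symmetric kernel is centered on each sample.
#'
#' @param X numeric matrix, one spectrum per row.
#' @param kernel a [filter_kernel()]; must not be longer than the spectrum.
#' @return Filtered matrix, same dimensions as `X`.
#' @export
lowpass <- function(X, kernel = binomial_kernel()) {
  X <- .as_matrix(X)
  stopifnot(inherits(kernel, "filter_kernel"))
  taps <- kernel$taps
  L <- length(taps)
  m <- ncol(X)
  if (L > m)
    stop("kernel error: kernel length ", L, " exceeds spectrum length ", m)
  off <- floor(L / 2)
  # edge-replicated column indices for each tap position
  Y <- matrix(0, nrow(X), m)
  for (j in seq_len(L)) {
    cols <- pmin(pmax(seq_len(m) + (j - 1L) - off, 1L), m)
    Y <- Y + taps[j] * X[, cols, drop = FALSE]
  }
  dimnames(Y) <- dimnames(X)
  Y
}
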