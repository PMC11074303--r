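# Synthetic THz-like hyperspectral phantoms.
#
# Real THz cubes of excised breast-conserving-surgery specimens are not
# publicly deposited, so every downstream stage is exercised on labeled
# phantoms: spatially contiguous fat/muscle/cancer regions on a background,
# class-conditional Gaussian spectra, and an additive-shift corruption
# process standing in for the systematic fresh-vs-FFPE spectral difference.

#' Phantom configuration
#'
#' Describes a synthetic hyperspectral cube: image size, number of spectral
#' bands, the region layout, and the class-conditional spectral model. Each
#' tissue class has an isotropic Gaussian spectrum in band space; class mean
#' vectors are collinear along a fixed spectral direction so the classes are
#' ordered on the latent scale (fat < muscle < cancer), mirroring the
#' increasing water content that drives THz reflectance contrast.
#'
#' @param height,width image dimensions in pixels.
#' @param n_bands number of spectral bands.
#' @param regions list of region descriptors. Each is a list with `label`
#'   (one of `tissue_classes()`) and either `shape = "rect"` with 0-based
#'   inclusive `row0, col0, row1, col1`, or `shape = "disc"` with
#'   `center_row, center_col, radius`. Regions must be disjoint.
#' @param separation Euclidean distance between adjacent class mean spectra,
#'   in units of the noise standard deviation. Default 5: classes are well
#'   separated, as the mouse-tumor imaging literature reports for
#'   fresh-tissue THz contrast.
#' @param class_sd per-class isotropic noise standard deviation (recycled to
#'   length 3, order fat/muscle/cancer). Arbitrary reflectance units.
#' @param background_sd noise SD of background pixels.
#' @param class_means optional 3 x n_bands matrix of class mean spectra
#'   (rows fat, muscle, cancer) overriding the collinear default.
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   the configuration.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(height = 64L, width = 64L, n_bands = 16L,
                           regions = default_region_layout(height, width),
                           separation = 5, class_sd = 1, background_sd = 1,
                           class_means = NULL, seed = 1L) {
  if (height < 1 || width < 1 || n_bands < 1)
    stop("config error: height, width and n_bands must all be >= 1")
  .stopifnot_scalar_num(separation, "separation")
  class_sd <- rep_len(as.numeric(class_sd), 3L)
  if (any(class_sd <= 0) || background_sd <= 0)
    stop("config error: noise standard deviations must be > 0")
  if (is.null(class_means)) {
    # smooth baseline spectrum plus a collinear per-class offset whose
    # Euclidean norm between adjacent classes equals separation * mean(sd)
    base <- sin(seq(0, pi, length.out = n_bands))
    step <- separation * mean(class_sd) / sqrt(n_bands)
    class_means <- t(vapply(1:3, function(lv) base + lv * step,
                            numeric(n_bands)))
  } else {
    class_means <- .as_matrix(class_means, "class_means")
    if (!all(dim(class_means) == c(3L, n_bands)))
      stop("config error: class_means must be 3 x n_bands")
  }
  rownames(class_means) <- tissue_classes()
  cfg <- structure(list(
    height = as.integer(height), width = as.integer(width),
    n_bands = as.integer(n_bands), regions = regions,
    separation = separation, class_sd = class_sd,
    background_sd = background_sd, class_means = class_means,
    background_mean = sin(seq(0, pi, length.out = n_bands)),
    seed = as.integer(seed)
  ), class = "phantom_config")
  .validate_regions(cfg)
  cfg
}

#' Default three-region layout
#'
#' A fat rectangle, a muscle rectangle and a cancer disc on a background,
#' scaled to the image size. Regions are disjoint by construction.
#'
#' @param height,width image dimensions in pixels.
#' @return A list of region descriptors for [phantom_config()].
#' @export
default_region_layout <- function(height, width) {
  h <- as.integer(height); w <- as.integer(width)
  list(
    list(shape = "rect", label = "fat",
         row0 = 0L, col0 = 0L,
         row1 = max(0L, h %/% 3L - 1L), col1 = max(0L, w %/% 2L - 1L)),
    list(shape = "rect", label = "muscle",
         row0 = 0L, col0 = min(w - 1L, w %/% 2L + w %/% 8L),
         row1 = max(0L, h %/% 3L - 1L), col1 = w - 1L),
    list(shape = "disc", label = "cancer",
         center_row = h %/% 2L + h %/% 4L, center_col = w %/% 2L,
         radius = max(1, min(h, w) %/% 5))
  )
}

# pixel membership per region; errors on overlap or unknown labels
.region_mask <- function(region, height, width) {
  rows <- matrix(0:(height - 1L), height, width)
  cols <- matrix(0:(width - 1L), height, width, byrow = TRUE)
  if (identical(region$shape, "rect")) {
    with(region, rows >= row0 & rows <= row1 & cols >= col0 & cols <= col1)
  } else if (identical(region$shape, "disc")) {
    with(region, (rows - center_row)^2 + (cols - center_col)^2 <= radius^2)
  } else stop("config error: unknown region shape: ", region$shape)
}

.validate_regions <- function(cfg) {
  cover <- matrix(0L, cfg$height, cfg$width)
  for (reg in cfg$regions) {
    if (!reg$label %in% tissue_classes())
      stop("config error: region label must be one of ",
           paste(tissue_classes(), collapse = ", "))
    cover <- cover + .region_mask(reg, cfg$height, cfg$width)
  }
  if (any(cover > 1L)) stop("layout error: regions overlap")
  invisible(cfg)
}

.label_map <- function(cfg) {
  labels <- matrix(0L, cfg$height, cfg$width)
  for (reg in cfg$regions)
    labels[.region_mask(reg, cfg$height, cfg$width)] <- .label_to_code(reg$label)
  labels
}

#' Generate a labeled hyperspectral phantom
#'
#' Samples an H x W x B reflectance cube where every pixel's spectrum is an
#' independent isotropic Gaussian around its class mean. Deterministic given
#' the configuration seed.
#'
#' @param config a [phantom_config()].
#' @return An object of class `thz_phantom`: list with `cube`
#'   (H x W x B array, axis order row, col, band), `labels` (H x W integer
#'   map, 0 = background, 1 = fat, 2 = muscle, 3 = cancer),
#'   `corruption_mask` (H x W logical, all `FALSE` here), and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  labels <- .label_map(config)
  h <- config$height; w <- config$width; b <- config$n_bands
  set.seed(config$seed)
  cube <- array(0, dim = c(h, w, b))
  noise <- array(stats::rnorm(h * w * b), dim = c(h, w, b))
  sds <- c(config$background_sd, config$class_sd)  # indexed by code + 1
  means <- rbind(config$background_mean, config$class_means)
  for (band in seq_len(b)) {
    mu <- means[labels + 1L, band]
    sd <- sds[labels + 1L]
    cube[, , band] <- matrix(mu + sd * noise[, , band][seq_along(labels)],
                             h, w)
  }
  structure(list(cube = cube, labels = labels,
                 corruption_mask = matrix(FALSE, h, w), config = config),
            class = "thz_phantom")
}

#' @export
print.thz_phantom <- function(x, ...) {
  d <- dim(x$cube)
  counts <- table(factor(.code_to_label(as.vector(x$labels)),
                         levels = c("background", tissue_classes())))
  cat(sprintf("THz phantom: %d x %d pixels, %d bands\n", d[1], d[2], d[3]))
  cat("  pixels per class:",
      paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  cat(sprintf("  corrupted pixels: %d\n", sum(x$corruption_mask)))
  invisible(x)
}

#' Apply FFPE-style spectral corruption to training pixels
#'
#' Adds a fixed spectral offset to a random subset of labeled pixels,
#' emulating the systematic difference between freshly excised tissue and
#' its dehydrated FFPE counterpart that degrades training-data quality.
#' Exactly `round(fraction * n_labeled)` not-yet-corrupted labeled pixels
#' are flagged; the label map itself is unchanged.
#'
#' @param phantom a `thz_phantom`.
#' @param fraction proportion of labeled pixels to corrupt, in \[0, 1\].
#' @param shift length-`n_bands` additive spectral offset. Default: a
#'   constant shift of 5 noise SDs spread evenly across bands.
#' @param seed integer seed for the pixel subset draw.
#' @return The phantom with shifted spectra and an updated
#'   `corruption_mask`.
#' @export
corrupt_labels <- function(phantom, fraction, shift = NULL, seed = 1L) {
  stopifnot(inherits(phantom, "thz_phantom"))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]")
  b <- dim(phantom$cube)[3]
  if (is.null(shift))
    shift <- rep(5 * mean(phantom$config$class_sd) / sqrt(b), b)
  if (length(shift) != b)
    stop("dimension error: 'shift' must have length n_bands = ", b)
  labeled <- which(phantom$labels > 0L & !phantom$corruption_mask)
  n_target <- round(fraction * sum(phantom$labels > 0L))
  if (n_target == 0L) return(phantom)
  if (n_target > length(labeled))
    stop("requested corruption exceeds available uncorrupted labeled pixels")
  set.seed(seed)
  picked <- sort(sample(labeled, n_target))
  h <- dim(phantom$cube)[1]; w <- dim(phantom$cube)[2]
  for (band in seq_len(b)) {
    plane <- phantom$cube[, , band]
    plane[picked] <- plane[picked] + shift[band]
    phantom$cube[, , band] <- plane
  }
  phantom$corruption_mask[picked] <- TRUE
  phantom
}

#' Flatten a phantom into a per-pixel feature table
#'
#' One row per pixel in row-major order over (row, col); features are the
#' band intensities. Coordinates are 0-based.
#'
#' @param phantom a `thz_phantom`.
#' @param include_background keep background pixels (label code 0)?
#' @return A data.frame with columns `row`, `col`, `label`, `label_code`,
#'   `corrupted`, and `band_1` ... `band_B`.
#' @export
to_pixel_table <- function(phantom, include_background = FALSE) {
  stopifnot(inherits(phantom, "thz_phantom"))
  d <- dim(phantom$cube)
  h <- d[1]; w <- d[2]; b <- d[3]
  # row-major: row varies slowest
  idx <- cbind(row = rep(seq_len(h), each = w), col = rep(seq_len(w), h))
  lin <- idx[, "row"] + (idx[, "col"] - 1L) * h
  X <- matrix(0, nrow(idx), b,
              dimnames = list(NULL, paste0("band_", seq_len(b))))
  for (band in seq_len(b)) X[, band] <- phantom$cube[, , band][lin]
  out <- data.frame(row = idx[, "row"] - 1L, col = idx[, "col"] - 1L,
                    label_code = as.vector(phantom$labels)[lin],
                    corrupted = as.vector(phantom$corruption_mask)[lin])
  out$label <- .code_to_label(out$label_code)
  out <- cbind(out[c("row", "col", "label", "label_code", "corrupted")],
               as.data.frame(X))
  if (!include_background) {
    out <- out[out$label_code > 0L, , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out) == 0L)
      warning("no labeled pixels: returning an empty pixel table")
  }
  out
}

#' Band-intensity feature matrix of a pixel table
#'
#' @param table a pixel table from [to_pixel_table()].
#' @return Numeric matrix of the `band_*` columns.
#' @export
pixel_features <- function(table) {
  as.matrix(table[, grep("^band_", names(table)), drop = FALSE])
}
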