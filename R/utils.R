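# Internal helpers shared across modules.

#' Tissue class labels in their fixed ordinal order
#'
#' The latent-scale ordering used throughout the package: fat < muscle <
#' cancer, matching the increasing water content (and hence THz reflectance)
#' of the three tissue types. Background pixels carry the code 0 and are not
#' part of the ordinal scale.
#'
#' @return Character vector `c("fat", "muscle", "cancer")`.
#' @export
tissue_classes <- function() c("fat", "muscle", "cancer")

# integer codes used on disk and in label maps: 0 = background
.label_codes <- c(background = 0L, fat = 1L, muscle = 2L, cancer = 3L)

.code_to_label <- function(code) {
  lab <- names(.label_codes)[match(code, .label_codes)]
  if (anyNA(lab)) stop("label codes outside {0,1,2,3}: ",
                       paste(unique(code[is.na(lab)]), collapse = ", "))
  lab
}

.label_to_code <- function(label) {
  code <- .label_codes[match(label, names(.label_codes))]
  if (anyNA(code)) stop("unknown tissue label: ",
                        paste(unique(label[is.na(code)]), collapse = ", "))
  unname(code)
}

# ordered factor over the ordinal classes (background excluded)
.as_ordinal <- function(labels) {
  bad <- setdiff(unique(as.character(labels)), tissue_classes())
  if (length(bad)) stop("labels outside the ordinal class set: ",
                        paste(bad, collapse = ", "))
  factor(as.character(labels), levels = tissue_classes(), ordered = TRUE)
}

.stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

.as_matrix <- function(X, name = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", name))
  X
}

# deterministic per-stage seed derived from a global seed; keeps values
# well inside 32-bit integer range
derive_seed <- function(global_seed, stage) {
  stopifnot(is.numeric(global_seed), length(global_seed) == 1L)
  stages <- c(phantom = 1L, corrupt = 2L, split = 3L, preprocess = 4L,
              pca = 5L, reliability = 6L, train = 7L, evaluate = 8L)
  k <- if (is.character(stage)) stages[[stage]] else as.integer(stage)
  as.integer((as.integer(global_seed) %% 2000000L) * 1000L + k)
}
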