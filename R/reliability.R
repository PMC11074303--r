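# EM-based reliability selection of training pixels.
#
# FFPE reference samples dehydrate, so a fraction of nominally labeled
# training pixels carry systematically shifted spectra. Per tissue class, a
# two-component isotropic Gaussian mixture in PCA space separates the
# majority "reliable" population from the shifted one; a pixel's
# reliability score is the posterior responsibility of the reliable
# component, and only pixels whose score exceeds a threshold enter
# training.

# log density of an isotropic Gaussian, rows of Z
.iso_logdens <- function(Z, mu, var) {
  k <- ncol(Z)
  d2 <- rowSums(sweep(Z, 2L, mu, "-")^2)
  -0.5 * (k * log(2 * pi * var) + d2 / var)
}

# EM for one class; deterministic initialization
.em_one_class <- function(Z, max_iter, tol) {
  n <- nrow(Z); k <- ncol(Z)
  med <- apply(Z, 2L, stats::median)
  d2 <- rowSums(sweep(Z, 2L, med, "-")^2)
  mu1 <- med                       # reliable: class median
  mu2 <- Z[which.max(d2), ]        # unreliable: farthest point
  v_tot <- sum(apply(Z, 2L, stats::var)) / k
  v_floor <- max(1e-6 * v_tot, 1e-12)
  v1 <- v2 <- max(v_tot, v_floor)
  pi1 <- 0.8
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    l1 <- log(pi1) + .iso_logdens(Z, mu1, v1)
    l2 <- log(1 - pi1) + .iso_logdens(Z, mu2, v2)
    mx <- pmax(l1, l2)
    ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
    ll_trace <- c(ll_trace, ll)
    r1 <- 1 / (1 + exp(l2 - l1))
    # M-step
    w1 <- sum(r1); w2 <- n - w1
    if (w1 < 1e-10 || w2 < 1e-10) break
    mu1 <- colSums(Z * r1) / w1
    mu2 <- colSums(Z * (1 - r1)) / w2
    v1 <- max(sum(r1 * rowSums(sweep(Z, 2L, mu1, "-")^2)) / (k * w1), v_floor)
    v2 <- max(sum((1 - r1) * rowSums(sweep(Z, 2L, mu2, "-")^2)) / (k * w2),
              v_floor)
    pi1 <- min(max(w1 / n, 1e-6), 1 - 1e-6)
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1e-12))
      break
    ll_old <- ll
  }
  # the heavier component is designated reliable
  if (pi1 < 0.5) {
    tmp <- mu1; mu1 <- mu2; mu2 <- tmp
    tv <- v1; v1 <- v2; v2 <- tv
    pi1 <- 1 - pi1
  }
  list(mean_reliable = mu1, mean_unreliable = mu2,
       var_reliable = v1, var_unreliable = v2,
       pi_reliable = pi1, loglik_trace = ll_trace)
}

#' Fit per-class reliability mixtures by EM
#'
#' For each tissue class, fits a two-component isotropic Gaussian mixture
#' to that class's feature rows; the component with the larger mixing
#' weight is designated "reliable". Initialization is deterministic (the
#' reliable component starts at the class median, the unreliable one at the
#' point farthest from it, mixing weight 0.8), so fits are reproducible
#' without randomness; `seed` is accepted for interface symmetry.
#'
#' @param Z n x k feature matrix (typically PCA scores).
#' @param labels per-row class labels from `tissue_classes()`.
#' @param max_iter maximum EM iterations per class.
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed unused (deterministic initialization); kept so stage seeds
#'   thread uniformly through the pipeline.
#' @param threshold default reliability threshold tau stored with the
#'   model, in \[0, 1\].
#' @return Object of class `reliability_model`: per-class mixtures, their
#'   log-likelihood traces, and `threshold`.
#' @export
em_fit <- function(Z, labels, max_iter = 200L, tol = 1e-8, seed = NULL,
                   threshold = 0.8) {
  Z <- .as_matrix(Z, "Z")
  labels <- as.character(labels)
  if (length(labels) != nrow(Z))
    stop("dimension error: 'labels' must have one entry per row of Z")
  .as_ordinal(labels)  # validates the label set
  classes <- intersect(tissue_classes(), unique(labels))
  fits <- list()
  for (cl in classes) {
    idx <- which(labels == cl)
    if (length(idx) < 4L)
      stop("insufficient-class-data error: class '", cl, "' has ",
           length(idx), " rows; EM needs at least 4")
    fits[[cl]] <- .em_one_class(Z[idx, , drop = FALSE], max_iter, tol)
  }
  structure(list(fits = fits, k = ncol(Z), threshold = threshold),
            class = "reliability_model")
}

#' @export
print.reliability_model <- function(x, ...) {
  cat("EM reliability model (2-component isotropic mixtures per class)\n")
  for (cl in names(x$fits))
    cat(sprintf("  %-7s pi_reliable = %.3f, %d EM iterations\n",
                cl, x$fits[[cl]]$pi_reliable,
                length(x$fits[[cl]]$loglik_trace)))
  cat(sprintf("  default threshold tau = %.2f\n", x$threshold))
  invisible(x)
}

#' Per-pixel reliability scores
#'
#' The posterior responsibility of the pixel's class-specific reliable
#' component at the pixel's features; always in \[0, 1\], and the two
#' component responsibilities sum to one.
#'
#' @param model a `reliability_model`.
#' @param Z feature matrix with the fit's dimension.
#' @param labels per-row class labels.
#' @return Numeric vector of scores in \[0, 1\].
#' @export
reliability_scores <- function(model, Z, labels) {
  stopifnot(inherits(model, "reliability_model"))
  Z <- .as_matrix(Z, "Z")
  if (ncol(Z) != model$k)
    stop("dimension error: expected ", model$k, " feature columns")
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), names(model$fits))
  if (length(unknown))
    stop("label error: no fitted mixture for class(es) ",
         paste(unknown, collapse = ", "))
  scores <- numeric(nrow(Z))
  for (cl in names(model$fits)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    f <- model$fits[[cl]]
    Zi <- Z[idx, , drop = FALSE]
    l1 <- log(f$pi_reliable) + .iso_logdens(Zi, f$mean_reliable,
                                            f$var_reliable)
    l2 <- log(1 - f$pi_reliable) + .iso_logdens(Zi, f$mean_unreliable,
                                                f$var_unreliable)
    scores[idx] <- 1 / (1 + exp(l2 - l1))
  }
  scores
}

#' Threshold reliability scores
#'
#' Retains rows whose score strictly exceeds `tau`. A class losing all its
#' rows is a warning (recorded in the summary), not an error; the caller
#' decides whether training can proceed.
#'
#' @param scores vector from [reliability_scores()].
#' @param tau threshold in \[0, 1\].
#' @param labels optional per-row labels for the per-class summary.
#' @return List with `index` (retained row indices) and `summary`
#'   (data.frame: class, n_before, n_after, tau).
#' @export
select_reliable <- function(scores, tau = 0.8, labels = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("'tau' must be in [0, 1]")
  keep <- which(scores > tau)
  if (is.null(labels)) labels <- rep("all", length(scores))
  labels <- as.character(labels)
  classes <- unique(labels)
  summary <- data.frame(
    class = classes,
    n_before = vapply(classes, function(cl) sum(labels == cl), integer(1)),
    n_after = vapply(classes, function(cl) sum(labels[keep] == cl),
                     integer(1)),
    tau = tau, row.names = NULL)
  empty <- summary$class[summary$n_after == 0L & summary$n_before > 0L]
  if (length(empty))
    warning("no rows retained for class(es): ",
            paste(empty, collapse = ", "))
  list(index = keep, summary = summary)
}
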