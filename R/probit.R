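# Bayesian ordinal probit regression over the ordered tissue classes
# fat < muscle < cancer. A latent Gaussian score beta'z + e (e ~ N(0,1),
# scale fixed for identification) is cut into ordered intervals by
# cutpoints gamma_1 < gamma_2; class probabilities are differences of
# normal CDFs. The model deliberately has few free parameters:
# d + (C - 1) for d features and C classes.

#' Ordinal probit parameters
#'
#' @param beta length-d weight vector.
#' @param cutpoints strictly increasing vector of length C - 1.
#' @param classes ordered class labels, lowest latent class first.
#' @return Object of class `probit_params`.
#' @export
probit_params <- function(beta, cutpoints, classes = tissue_classes()) {
  beta <- as.numeric(beta)
  cutpoints <- as.numeric(cutpoints)
  if (any(!is.finite(beta)) || any(!is.finite(cutpoints)))
    stop("parameter error: parameters must be finite")
  if (length(cutpoints) != length(classes) - 1L)
    stop("parameter error: need ", length(classes) - 1L, " cutpoints for ",
         length(classes), " classes")
  if (length(cutpoints) > 1L && any(diff(cutpoints) <= 0))
    stop("parameter error: cutpoints must be strictly increasing")
  structure(list(beta = beta, cutpoints = cutpoints, classes = classes),
            class = "probit_params")
}

.get_params <- function(params) {
  if (inherits(params, "ordinal_probit"))
    probit_params(params$beta, params$cutpoints, params$classes)
  else if (inherits(params, "probit_params")) params
  else stop("expected 'probit_params' or a fitted 'ordinal_probit'")
}

# y as integer codes 1..C against the parameter class order
.y_index <- function(y, classes) {
  yi <- match(as.character(y), classes)
  if (anyNA(yi))
    stop("label error: labels outside the model's class set: ",
         paste(unique(as.character(y)[is.na(yi)]), collapse = ", "))
  yi
}

#' Class probabilities under an ordinal probit model
#'
#' `P(class c | z) = pnorm(gamma_c - beta'z) - pnorm(gamma_{c-1} - beta'z)`
#' with `gamma_0 = -Inf` and `gamma_C = +Inf`; rows sum to one.
#'
#' @param params `probit_params` or a fitted `ordinal_probit`.
#' @param Z feature matrix (or a single feature vector) with d columns.
#' @return n x C matrix of class probabilities, columns named by class.
#' @export
class_probs <- function(params, Z) {
  p <- .get_params(params)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  Z <- .as_matrix(Z, "Z")
  if (ncol(Z) != length(p$beta))
    stop("dimension error: expected ", length(p$beta), " feature columns")
  eta <- drop(Z %*% p$beta)
  cuts <- c(-Inf, p$cutpoints, Inf)
  C <- length(p$classes)
  out <- vapply(seq_len(C), function(cc)
    stats::pnorm(cuts[cc + 1L] - eta) - stats::pnorm(cuts[cc] - eta),
    numeric(length(eta)))
  out <- matrix(out, ncol = C, dimnames = list(NULL, p$classes))
  out
}

#' Negative log-likelihood and its gradient
#'
#' `NLL = -sum(log P(y_i | z_i))`. Per-observation probabilities are
#' floored at 1e-300 (with a warning) under extreme linear predictors. The
#' gradient is over the stacked parameter vector `c(beta, cutpoints)`.
#'
#' @param params `probit_params` or fitted `ordinal_probit`.
#' @param Z n x d feature matrix.
#' @param y per-row labels from the model's class set.
#' @return List with `nll` (scalar) and `grad` (length d + C - 1).
#' @export
nll_grad <- function(params, Z, y) {
  p <- .get_params(params)
  Z <- .as_matrix(Z, "Z")
  yi <- .y_index(y, p$classes)
  if (length(yi) != nrow(Z))
    stop("dimension error: 'y' must have one label per row of Z")
  d <- length(p$beta); C <- length(p$classes)
  eta <- drop(Z %*% p$beta)
  cuts <- c(-Inf, p$cutpoints, Inf)
  a <- cuts[yi + 1L] - eta   # upper bound argument
  b <- cuts[yi] - eta        # lower bound argument
  prob <- stats::pnorm(a) - stats::pnorm(b)
  if (any(prob < 1e-300)) {
    warning("likelihood floored at 1e-300 for ", sum(prob < 1e-300),
            " observation(s); linear predictor is extreme")
    prob <- pmax(prob, 1e-300)
  }
  nll <- -sum(log(prob))
  phi_a <- stats::dnorm(a)   # dnorm(+-Inf) = 0, as required
  phi_b <- stats::dnorm(b)
  g_eta <- (phi_a - phi_b) / prob
  grad_beta <- drop(crossprod(Z, g_eta))
  grad_cuts <- numeric(C - 1L)
  for (j in seq_len(C - 1L)) {
    grad_cuts[j] <- -sum(phi_a[yi == j] / prob[yi == j]) +
      sum(phi_b[yi == j + 1L] / prob[yi == j + 1L])
  }
  list(nll = nll, grad = c(grad_beta, grad_cuts))
}

# penalized objective used by MAP fitting: NLL + beta'beta / (2 prior_sd^2)
.map_objective <- function(params, Z, y, prior_sd) {
  ng <- nll_grad(params, Z, y)
  pen <- sum(params$beta^2) / (2 * prior_sd^2)
  gpen <- c(params$beta / prior_sd^2, numeric(length(params$cutpoints)))
  list(loss = ng$nll + pen, grad = ng$grad + gpen)
}

#' MAP fit by centralized gradient descent
#'
#' Plain gradient descent on the penalized negative log-likelihood
#' (independent normal(0, prior_sd^2) prior on beta, flat on the ordered
#' cutpoints), stopping when the relative loss change drops below `tol`.
#' Cutpoint ordering is enforced after every step (minimum gap 1e-8).
#' This is the same optimizer the split-learning server runs; fitting
#' centrally is the reference path.
#'
#' @param Z n x d feature matrix.
#' @param y per-row labels; at least two distinct classes required.
#' @param learning_rate step size alpha; default `1/n`, matching the
#'   n-scaling of the summed-likelihood Hessian.
#' @param max_iter,tol iteration cap and relative-change tolerance.
#' @param seed unused (deterministic initialization from zeros); accepted
#'   for uniform stage seeding.
#' @param prior_sd prior standard deviation on beta.
#' @param classes ordered class labels.
#' @return List with `params` (`probit_params`) and `loss_trace`.
#' @export
fit_map_centralized <- function(Z, y, learning_rate = NULL,
                                max_iter = 2000L, tol = 1e-8, seed = NULL,
                                prior_sd = 10, classes = tissue_classes()) {
  Z <- .as_matrix(Z, "Z")
  yi <- .y_index(y, classes)
  if (length(unique(yi)) < 2L)
    stop("need at least 2 distinct classes to fit")
  n <- nrow(Z); d <- ncol(Z); C <- length(classes)
  if (is.null(learning_rate)) learning_rate <- 1 / n
  .stopifnot_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  par <- probit_params(numeric(d),
                       seq(-0.5, 0.5, length.out = C - 1L), classes)
  trace <- numeric(0)
  loss_old <- Inf
  for (it in seq_len(max_iter)) {
    ob <- .map_objective(par, Z, y, prior_sd)
    trace <- c(trace, ob$loss)
    if (!is.finite(ob$loss) || ob$loss > 1e10)
      stop("divergence error: loss exceeded 1e10 at iteration ", it,
           "; try a smaller learning rate alpha")
    if (is.finite(loss_old) &&
        abs(loss_old - ob$loss) < tol * (abs(loss_old) + 1e-12)) break
    loss_old <- ob$loss
    theta <- c(par$beta, par$cutpoints) - learning_rate * ob$grad
    cuts <- theta[(d + 1L):(d + C - 1L)]
    if (C > 2L) for (j in 2:(C - 1L))            # keep ordering
      cuts[j] <- max(cuts[j], cuts[j - 1L] + 1e-8)
    par <- probit_params(theta[seq_len(d)], cuts, classes)
  }
  list(params = par, loss_trace = trace)
}

#' Gibbs sampler for the ordinal probit posterior
#'
#' Albert–Chib latent-variable augmentation: truncated-normal latents given
#' the observed class, a conjugate normal update for beta under the
#' normal(0, prior_sd^2) prior, and uniform conditional draws for each
#' cutpoint on the interval pinned by the neighbouring classes' latents.
#' Every retained draw satisfies the cutpoint ordering by construction.
#'
#' @param Z n x d feature matrix.
#' @param y per-row labels; every class must be present.
#' @param n_draws total Gibbs iterations (must exceed `burn_in`).
#' @param burn_in discarded initial iterations.
#' @param seed integer RNG seed.
#' @param prior_sd prior standard deviation on beta.
#' @param classes ordered class labels.
#' @return Object of class `probit_draws`: `draws`
#'   ((n_draws - burn_in) x (d + C - 1) matrix, columns `beta_*`,
#'   `gamma_*`), `burn_in`, `seed`, `classes`.
#' @export
gibbs_fit <- function(Z, y, n_draws = 1500L, burn_in = 500L, seed = 1L,
                      prior_sd = 10, classes = tissue_classes()) {
  Z <- .as_matrix(Z, "Z")
  yi <- .y_index(y, classes)
  C <- length(classes); d <- ncol(Z); n <- nrow(Z)
  if (n_draws <= burn_in)
    stop("value error: 'n_draws' must exceed 'burn_in'")
  if (length(unique(yi)) < C)
    stop("Gibbs cutpoint updates need every class present in 'y'")
  set.seed(seed)
  V <- solve(crossprod(Z) + diag(1 / prior_sd^2, d))
  RV <- chol(V)
  beta <- numeric(d)
  cuts <- stats::qnorm(cumsum(tabulate(yi, C) / n))[seq_len(C - 1L)]
  cuts <- pmin(pmax(cuts, -4), 4)
  if (any(diff(cuts) <= 0)) cuts <- seq(-0.5, 0.5, length.out = C - 1L)
  keep <- n_draws - burn_in
  draws <- matrix(NA_real_, keep,  d + C - 1L,
                  dimnames = list(NULL, c(paste0("beta_", seq_len(d)),
                                          paste0("gamma_", seq_len(C - 1L)))))
  for (s in seq_len(n_draws)) {
    eta <- drop(Z %*% beta)
    all_cuts <- c(-Inf, cuts, Inf)
    plo <- stats::pnorm(all_cuts[yi] - eta)
    phi <- stats::pnorm(all_cuts[yi + 1L] - eta)
    # guard: keep the truncation interval numerically non-empty
    phi <- pmax(phi, plo + 1e-12)
    u <- eta + stats::qnorm(plo + stats::runif(n) * (phi - plo))
    u <- pmin(pmax(u, eta - 8), eta + 8)
    m <- drop(V %*% crossprod(Z, u))
    beta <- m + drop(t(RV) %*% stats::rnorm(d))
    for (j in seq_len(C - 1L)) {
      lo <- max(u[yi == j], if (j > 1L) cuts[j - 1L] else -Inf)
      hi <- min(u[yi == j + 1L], if (j < C - 1L) cuts[j + 1L] else Inf)
      if (!is.finite(lo)) lo <- hi - 1
      if (!is.finite(hi)) hi <- lo + 1
      if (hi <= lo) hi <- lo + 1e-10
      cuts[j] <- stats::runif(1L, lo, hi)
    }
    if (s > burn_in) draws[s - burn_in, ] <- c(beta, cuts)
  }
  structure(list(draws = draws, burn_in = as.integer(burn_in),
                 seed = as.integer(seed), classes = classes),
            class = "probit_draws")
}

#' @export
print.probit_draws <- function(x, ...) {
  cat(sprintf("ordinal probit posterior: %d retained draws (burn-in %d)\n",
              nrow(x$draws), x$burn_in))
  print(round(colMeans(x$draws), 4))
  invisible(x)
}

#' Fit an ordinal probit tissue classifier
#'
#' The package's central model. `method = "map"` runs gradient descent on
#' the penalized likelihood (the optimizer the split-learning server
#' uses); `method = "gibbs"` draws from the full posterior and reports the
#' posterior mean. Either way the returned object supports `print`,
#' `summary`, `coef`, `predict`, `simulate` and `residuals`.
#'
#' @param Z n x d feature matrix (typically PCA scores).
#' @param y per-row labels from `classes`.
#' @param method `"map"` or `"gibbs"`.
#' @param classes ordered class labels, lowest latent class first.
#' @param ... passed on to [fit_map_centralized()] or [gibbs_fit()].
#' @return Object of class `ordinal_probit` with elements `beta`,
#'   `cutpoints`, `classes`, `method`, `n`, `d`, plus `loss_trace` (map) or
#'   `draws` (gibbs).
#' @export
ordinal_probit <- function(Z, y, method = c("map", "gibbs"),
                           classes = tissue_classes(), ...) {
  method <- match.arg(method)
  Z <- .as_matrix(Z, "Z")
  fit <- if (method == "map") {
    m <- fit_map_centralized(Z, y, classes = classes, ...)
    list(beta = m$params$beta, cutpoints = m$params$cutpoints,
         loss_trace = m$loss_trace)
  } else {
    dr <- gibbs_fit(Z, y, classes = classes, ...)
    post <- colMeans(dr$draws)
    d <- ncol(Z)
    list(beta = unname(post[seq_len(d)]),
         cutpoints = unname(post[-seq_len(d)]), draws = dr)
  }
  structure(c(fit, list(classes = classes, method = method,
                        n = nrow(Z), d = ncol(Z),
                        call = match.call())),
            class = "ordinal_probit")
}

#' @export
print.ordinal_probit <- function(x, ...) {
  cat(sprintf("Ordinal probit classifier (%s), classes %s\n", x$method,
              paste(x$classes, collapse = " < ")))
  cat(sprintf("  %d free parameters (d = %d features + %d cutpoints)\n",
              x$d + length(x$cutpoints), x$d, length(x$cutpoints)))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.ordinal_probit <- function(object, ...) {
  stats::setNames(c(object$beta, object$cutpoints),
                  c(paste0("beta_", seq_len(object$d)),
                    paste0("gamma_", seq_along(object$cutpoints))))
}

#' @export
summary.ordinal_probit <- function(object, ...) {
  out <- list(coefficients = coef(object), method = object$method,
              n = object$n, d = object$d, classes = object$classes)
  if (object$method == "gibbs")
    out$posterior_sd <- apply(object$draws$draws, 2L, stats::sd)
  if (object$method == "map")
    out$final_loss <- utils::tail(object$loss_trace, 1L)
  class(out) <- "summary.ordinal_probit"
  out
}

#' @export
print.summary.ordinal_probit <- function(x, ...) {
  cat(sprintf("Ordinal probit (%s) on n = %d, d = %d\n", x$method, x$n,
              x$d))
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$posterior_sd)) tab$posterior_sd <- x$posterior_sd
  print(round(tab, 4))
  if (!is.null(x$final_loss))
    cat(sprintf("final penalized NLL: %.4f\n", x$final_loss))
  invisible(x)
}

#' Predict tissue classes or probabilities
#'
#' @param object fitted `ordinal_probit`.
#' @param newdata feature matrix.
#' @param type `"probs"` for the n x C probability matrix, `"class"` for
#'   the highest-probability label.
#' @param ... unused.
#' @return Probability matrix or character vector of labels.
#' @export
predict.ordinal_probit <- function(object, newdata,
                                   type = c("probs", "class"), ...) {
  type <- match.arg(type)
  P <- class_probs(object, newdata)
  if (type == "probs") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Simulate class labels from the fitted model
#'
#' @param object fitted `ordinal_probit`.
#' @param nsim number of simulated label vectors.
#' @param seed integer seed.
#' @param newdata feature matrix to simulate at.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated labels.
#' @export
simulate.ordinal_probit <- function(object, nsim = 1, seed = NULL,
                                    newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  P <- class_probs(object, newdata)
  out <- replicate(nsim, {
    u <- stats::runif(nrow(P))
    cum <- t(apply(P, 1L, cumsum))
    object$classes[rowSums(u > cum) + 1L]
  }, simplify = FALSE)
  stats::setNames(as.data.frame(out, stringsAsFactors = FALSE),
                  paste0("sim_", seq_len(nsim)))
}

#' Deviance residuals
#'
#' Per-observation contribution `sqrt(-2 log P(y_i | z_i))`, signed
#' negative when the observed class sits below the predicted one on the
#' ordinal scale.
#'
#' @param object fitted `ordinal_probit`.
#' @param newdata feature matrix.
#' @param y observed labels.
#' @param ... unused.
#' @return Numeric vector of signed deviance residuals.
#' @export
residuals.ordinal_probit <- function(object, newdata, y, ...) {
  P <- class_probs(object, newdata)
  yi <- .y_index(y, object$classes)
  p_obs <- P[cbind(seq_len(nrow(P)), yi)]
  pred <- max.col(P, ties.method = "first")
  sign_r <- ifelse(yi < pred, -1, 1)
  sign_r * sqrt(pmax(-2 * log(pmax(p_obs, 1e-300)), 0))
}

#' Plot a fitted ordinal probit model
#'
#' For a MAP fit, the loss trace over gradient-descent iterations; for a
#' Gibbs fit, parameter trace plots.
#'
#' @param x fitted `ordinal_probit`.
#' @param ... passed to the underlying plot call.
#' @export
plot.ordinal_probit <- function(x, ...) {
  if (x$method == "map") {
    plot(seq_along(x$loss_trace), x$loss_trace, type = "l",
         xlab = "iteration", ylab = "penalized NLL",
         main = "MAP optimization trace", ...)
  } else {
    graphics::matplot(x$draws$draws, type = "l", lty = 1,
                      xlab = "draw", ylab = "parameter value",
                      main = "Gibbs traces", ...)
    graphics::legend("topright", colnames(x$draws$draws),
                     col = seq_len(ncol(x$draws$draws)), lty = 1,
                     cex = 0.7)
  }
  invisible(x)
}

#' Serialize probit parameters to JSON
#'
#' @param params `probit_params` or fitted `ordinal_probit`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
probit_write_json <- function(params, path) {
  p <- .get_params(params)
  jsonlite::write_json(list(beta = p$beta, cutpoints = p$cutpoints,
                            classes = p$classes),
                       path, digits = I(17))
  invisible(path)
}

#' Read probit parameters from JSON
#'
#' @param path file written by [probit_write_json()].
#' @return A `probit_params` object.
#' @export
probit_read_json <- function(path) {
  o <- jsonlite::fromJSON(path)
  probit_params(o$beta, o$cutpoints, o$classes)
}
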