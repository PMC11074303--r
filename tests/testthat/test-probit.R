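test_that("class probabilities telescope to one and match closed forms", {
  set.seed(2)
  p <- probit_params(c(0.8, -1.2), c(-0.3, 0.9))
  Z <- matrix(rnorm(40), 20, 2)
  P <- class_probs(p, Z)
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-12)

  # beta = 0: probabilities are pure CDF differences, independent of z
  p0 <- probit_params(c(0, 0), c(-1, 1))
  P0 <- class_probs(p0, matrix(rnorm(10), 5, 2))
  expect_equal(unname(P0),
               matrix(rep(c(pnorm(-1), pnorm(1) - pnorm(-1),
                            1 - pnorm(1)), each = 5), 5))

  # extreme linear predictor pushes all mass to the top class
  Pinf <- class_probs(probit_params(10, c(-1, 1)), matrix(100, 1, 1))
  expect_equal(unname(Pinf[1, "cancer"]), 1, tolerance = 1e-12)

  expect_error(probit_params(1, c(1, -1)), "strictly increasing")
})

test_that("probabilities agree with numeric integration of the latent normal", {
  p <- probit_params(c(1.1, -0.4), c(-0.6, 0.7))
  set.seed(6)
  Z <- matrix(rnorm(10), 5, 2)
  P <- class_probs(p, Z)
  cuts <- c(-Inf, p$cutpoints, Inf)
  for (i in 1:5) {
    eta <- sum(Z[i, ] * p$beta)
    for (cc in 1:3) {
      ref <- stats::integrate(function(u) dnorm(u, mean = eta),
                              cuts[cc], cuts[cc + 1],
                              rel.tol = 1e-12)$value
      expect_equal(unname(P[i, cc]), ref, tolerance = 1e-8)
    }
  }
})

test_that("the NLL is additive and its gradient matches finite differences", {
  p <- probit_params(c(0, 0), c(0, 1))
  # single observation with P(y) = 0.5: muscle spans (0, 1)... compute one
  # with probability exactly 0.5 via symmetric cutpoints
  p_half <- probit_params(0, c(0, 100))
  ng <- nll_grad(p_half, matrix(0, 1, 1), "muscle")
  expect_equal(ng$nll, log(2), tolerance = 1e-10)

  set.seed(10)
  d <- gen_ordinal(20, c(1.5, -0.7, 0.3), c(-0.5, 0.8), seed = 10)
  par <- probit_params(c(0.4, -0.2, 0.1), c(-0.4, 0.6))
  ng <- nll_grad(par, d$Z, d$y)
  f <- function(theta) nll_grad(probit_params(theta[1:3], theta[4:5]),
                                d$Z, d$y)$nll
  ref <- fd_grad(f, c(par$beta, par$cutpoints))
  expect_equal(ng$grad, ref, tolerance = 1e-5 * max(1, max(abs(ref))))

  # duplicating the data doubles both the loss and the gradient
  ng2 <- nll_grad(par, rbind(d$Z, d$Z), c(d$y, d$y))
  expect_equal(ng2$nll, 2 * ng$nll)
  expect_equal(ng2$grad, 2 * ng$grad)
})

test_that("MAP gradient descent recovers the generating parameters", {
  d <- gen_ordinal(2000, c(1.5, -0.7), c(-0.5, 0.8), seed = 11)
  fit <- fit_map_centralized(d$Z, d$y, max_iter = 3000, tol = 1e-12)
  expect_true(all(abs(fit$params$beta - c(1.5, -0.7)) < 0.15))
  expect_true(all(abs(fit$params$cutpoints - c(-0.5, 0.8)) < 0.15))
  expect_lte(tail(fit$loss_trace, 1), fit$loss_trace[1])

  # independent cross-check: the ordinal probit MLE from MASS::polr
  skip_if_not_installed("MASS")
  y_ord <- factor(d$y, levels = tissue_classes(), ordered = TRUE)
  ref <- MASS::polr(y_ord ~ d$Z, method = "probit")
  expect_equal(unname(fit$params$beta), unname(coef(ref)),
               tolerance = 1e-2)
  expect_equal(unname(fit$params$cutpoints), unname(ref$zeta),
               tolerance = 1e-2)
})

test_that("cutpoint ordering survives separable data and bad settings fail fast", {
  # perfectly separable 1-D data
  Z <- matrix(c(rep(-3, 20), rep(0, 20), rep(3, 20)), ncol = 1)
  y <- rep(tissue_classes(), each = 20)
  fit <- fit_map_centralized(Z, y, max_iter = 500, tol = 1e-10)
  expect_lt(fit$params$cutpoints[1], fit$params$cutpoints[2])

  expect_error(fit_map_centralized(Z, rep("fat", 60)), "2 distinct")
  suppressWarnings(expect_error(
    fit_map_centralized(matrix(rnorm(40), 20, 2),
                        gen_ordinal(20, 1:2, c(-0.5, 0.8), 1)$y,
                        learning_rate = 50, max_iter = 200),
    "divergence|floored"))
})

test_that("the Gibbs sampler is seeded, ordered, and concentrates near truth", {
  d <- gen_ordinal(600, c(1.5, -0.7), c(-0.5, 0.8), seed = 12)
  g1 <- gibbs_fit(d$Z, d$y, n_draws = 400, burn_in = 150, seed = 3)
  g2 <- gibbs_fit(d$Z, d$y, n_draws = 400, burn_in = 150, seed = 3)
  expect_identical(g1$draws, g2$draws)
  expect_true(all(g1$draws[, "gamma_1"] < g1$draws[, "gamma_2"]))
  post <- colMeans(g1$draws)
  expect_true(all(abs(post[1:2] - c(1.5, -0.7)) < 0.25))
  expect_error(gibbs_fit(d$Z, d$y, n_draws = 100, burn_in = 100),
               "value error")
})

test_that("the MAP sits in high posterior density relative to the Gibbs mean", {
  d <- gen_ordinal(800, c(1.5, -0.7), c(-0.5, 0.8), seed = 14)
  m <- fit_map_centralized(d$Z, d$y, max_iter = 3000, tol = 1e-12)
  g <- gibbs_fit(d$Z, d$y, n_draws = 500, burn_in = 200, seed = 4)
  post <- colMeans(g$draws)
  obj <- function(par) {
    ng <- nll_grad(par, d$Z, d$y)
    ng$nll + sum(par$beta^2) / (2 * 100)
  }
  expect_lte(obj(m$params),
             obj(probit_params(post[1:2], post[3:4])) + 1e-6)
})

test_that("the model keeps its small parameter count", {
  d <- gen_ordinal(120, c(0.5, -0.5, 0.2), c(-0.5, 0.5), seed = 15)
  fit <- ordinal_probit(d$Z, d$y, method = "map")
  expect_length(coef(fit), 3 + 2)          # d + (C - 1) free parameters
})

test_that("the ordinal_probit object behaves like a classic model fit", {
  d <- gen_ordinal(500, c(1.2, -0.6), c(-0.5, 0.8), seed = 16)
  fit <- ordinal_probit(d$Z, d$y, method = "map")
  expect_s3_class(fit, "ordinal_probit")
  expect_output(print(fit), "Ordinal probit")
  expect_output(print(summary(fit)), "final penalized NLL")

  P <- predict(fit, d$Z, type = "probs")
  cls <- predict(fit, d$Z, type = "class")
  expect_equal(dim(P), c(500L, 3L))
  expect_true(all(cls %in% tissue_classes()))
  expect_gt(mean(cls == d$y), 0.6)

  sims <- simulate(fit, nsim = 2, seed = 1, newdata = d$Z)
  expect_equal(dim(sims), c(500L, 2L))
  expect_true(all(unlist(sims) %in% tissue_classes()))

  r <- residuals(fit, d$Z, d$y)
  expect_length(r, 500L)
  expect_true(all(is.finite(r)))

  gfit <- ordinal_probit(d$Z, d$y, method = "gibbs", n_draws = 300,
                         burn_in = 100, seed = 2)
  s <- summary(gfit)
  expect_true(all(s$posterior_sd > 0))
  expect_true(all(abs(coef(gfit) - coef(fit)) < 0.2))

  path <- withr::local_tempfile(fileext = ".json")
  probit_write_json(fit, path)
  back <- probit_read_json(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$cutpoints, fit$cutpoints)
})
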