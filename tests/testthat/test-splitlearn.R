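# shared small task for the split-learning suite
split_task <- function(n = 120, m = 6, seed = 99) {
  set.seed(seed)
  X <- matrix(rnorm(n * m), n)
  latent <- drop(X %*% c(1, -1, 0.5, rep(0, m - 4), 0.2)) + rnorm(n)
  list(X = X, y = tissue_classes()[findInterval(latent, c(-0.5, 0.8)) + 1L])
}

test_that("the client forward pass is the documented affine map", {
  cl_id <- client_model(diag(3), activation = "identity")
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(client_forward(cl_id, X), X)

  cl_zero <- client_model(matrix(0, 2, 3))
  expect_equal(client_forward(cl_zero, X), matrix(0, 5, 2))

  # linear in X under identity activation with zero bias
  W <- matrix(rnorm(6), 2, 3)
  cl <- client_model(W)
  expect_equal(client_forward(cl, 3 * X), 3 * client_forward(cl, X))
  expect_error(client_forward(cl, X[, 1:2]), "dimension error")
})

test_that("server gradients match finite differences through the composed loss", {
  task <- split_task(30)
  server <- probit_params(c(0.5, -0.3, 0.2), c(-0.4, 0.6))
  Xt <- task$X[, 1:3]
  st <- server_step(server, Xt, task$y)

  expect_equal(st$loss, nll_grad(server, Xt, task$y)$nll)

  # representation gradient vs central finite differences
  f <- function(Xt_flat) {
    nll_grad(server, matrix(Xt_flat, nrow(Xt)), task$y)$nll
  }
  ref <- fd_grad(f, as.vector(Xt))
  expect_equal(as.vector(st$grad_Xt), ref, tolerance = 1e-5)

  st2 <- server_step(server, rbind(Xt, Xt), c(task$y, task$y))
  expect_equal(st2$loss, 2 * st$loss)
  expect_equal(st2$grad_theta_s, 2 * st$grad_theta_s)
})

test_that("one split round equals one joint gradient-descent step", {
  task <- split_task(50)
  client <- client_model(matrix(rnorm(18, sd = 0.1), 3, 6))
  server <- probit_params(c(0.2, -0.1, 0.3), c(-0.5, 0.5))
  alpha <- 0.01

  # alpha = 0 leaves both halves untouched
  r0 <- split_round(client, server, task$X, task$y, 0)
  expect_equal(r0$client$weights, client$weights)
  expect_equal(r0$server$beta, server$beta)

  r <- split_round(client, server, task$X, task$y, alpha)
  # hand-composed oracle step
  Xt <- client_forward(client, task$X)
  ng <- nll_grad(server, Xt, task$y)
  expect_equal(r$record$loss, ng$nll)
  st <- server_step(server, Xt, task$y)
  expect_equal(r$server$beta, server$beta - alpha * ng$grad[1:3])
  expect_equal(r$client$weights,
               client$weights - alpha * crossprod(st$grad_Xt, task$X))
  expect_equal(r$client$bias,
               client$bias - alpha * colSums(st$grad_Xt))
})

test_that("single-client split training reproduces joint gradient descent", {
  task <- split_task(200)
  alpha <- 1 / 200; rounds <- 60; seed <- 5
  fit <- train_split(task$X, task$y,
                     split_config(learning_rate = alpha,
                                  max_rounds = rounds, tol = 0,
                                  seed = seed, d_out = 3))
  ref <- joint_gd(task$X, task$y, alpha, rounds, seed, d_out = 3)
  expect_equal(fit$n_rounds, rounds)
  expect_equal(fit$session$round_log$loss, ref$losses, tolerance = 1e-9)
  expect_equal(fit$client$weights, ref$W, tolerance = 1e-9)
  expect_equal(fit$server$beta, ref$beta, tolerance = 1e-9)
  expect_equal(fit$server$cutpoints, ref$cuts, tolerance = 1e-9)
})

test_that("training converges, stops on tolerance, and validates partitions", {
  task <- split_task(100)
  # an enormous tolerance stops after exactly one round
  one <- train_split(task$X, task$y,
                     split_config(max_rounds = 50, tol = 1e6, seed = 1))
  expect_equal(one$n_rounds, 1L)
  expect_true(one$converged)

  fit <- train_split(task$X, task$y,
                     split_config(max_rounds = 400, tol = 1e-8, seed = 1))
  losses <- fit$session$round_log$full_loss
  losses <- losses[!is.na(losses)]
  expect_true(all(is.finite(losses)))
  expect_lt(tail(losses, 1), losses[1])

  expect_error(
    train_split(task$X, task$y,
                split_config(mode = "round_robin", n_clients = 2,
                             client_partition = list(1:50, integer(0)))),
    "empty client partition")
  expect_error(
    train_split(task$X, task$y,
                split_config(mode = "round_robin", n_clients = 2,
                             client_partition = list(1:50, 40:100))),
    "disjointly")
})

test_that("round-robin training with IID halves tracks the single client", {
  task <- split_task(300, seed = 42)
  cfg1 <- split_config(max_rounds = 300, tol = 1e-9, seed = 7)
  fit1 <- train_split(task$X, task$y, cfg1)
  cfg2 <- split_config(max_rounds = 300, tol = 1e-9, seed = 7,
                       mode = "round_robin", n_clients = 2)
  fit2 <- train_split(task$X, task$y, cfg2)
  l1 <- tail(stats::na.omit(fit1$session$round_log$full_loss), 1)
  l2 <- tail(stats::na.omit(fit2$session$round_log$full_loss), 1)
  expect_lt(abs(l2 - l1) / l1, 0.05)
})

test_that("the transcript carries only permitted payload kinds", {
  task <- split_task(60)
  fit <- train_split(task$X, task$y,
                     split_config(max_rounds = 20, tol = 0, seed = 2))
  kinds <- unlist(lapply(fit$session$transcript, function(e)
    vapply(e$payloads, `[[`, character(1), "kind")))
  expect_true(all(kinds %in% c("representation", "labels",
                               "representation_gradient", "loss")))
})

test_that("the privacy audit passes honest runs and catches leaked rows", {
  task <- split_task(60)
  fit <- train_split(task$X, task$y,
                     split_config(max_rounds = 15, tol = 0, seed = 2,
                                  d_out = 3, activation = "tanh"))
  rep_ok <- audit_transcript(fit, task$X)
  expect_true(rep_ok$pass)
  expect_equal(rep_ok$n_rounds, 15L)

  # a deliberately mis-wired session that ships X itself
  bad <- fit$session
  bad$transcript[[3]]$payloads[[1]]$payload <- task$X
  expect_error(audit_transcript(bad, task$X),
               "privacy-violation error.*round 3")
})

test_that("split fits expose model methods and serialize their session", {
  task <- split_task(80)
  fit <- train_split(task$X, task$y,
                     split_config(max_rounds = 150, tol = 1e-8, seed = 3))
  expect_output(print(fit), "Split-learning fit")
  co <- coef(fit)
  expect_equal(dim(co$client_weights), c(3L, 6L))
  P <- predict(fit, task$X, type = "probs")
  expect_equal(rowSums(P), rep(1, 80), tolerance = 1e-9)
  expect_gt(mean(predict(fit, task$X, type = "class") == task$y), 0.5)

  path <- withr::local_tempfile(fileext = ".jsonl")
  session_write_jsonl(fit, path)
  lines <- readLines(path)
  expect_gt(length(lines), fit$n_rounds)
  expect_silent(lapply(lines, jsonlite::fromJSON))
})
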