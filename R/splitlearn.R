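# Client/server split learning.
#
# The client holds the raw pixel features and a small feature map
# F_c(X; theta_c) (one linear layer, optionally tanh); the server holds the
# ordinal probit head F_s(.; theta_s). Training exchanges only
# representations ("smashed data"), labels, representation gradients and
# scalar losses — never raw feature rows — and every payload is recorded in
# an auditable transcript. Both halves are updated from the same round's
# loss: theta_s <- theta_s - alpha * grad_theta_s, then
# theta_c <- theta_c - alpha * (chain-rule pullback of the representation
# gradient). For a single client at full batch this is algebraically
# identical to joint gradient descent on the composed model.

#' Client-side feature model
#'
#' @param weights d_out x m weight matrix.
#' @param bias length-d_out bias vector.
#' @param activation `"identity"` or `"tanh"`.
#' @return Object of class `client_model`.
#' @export
client_model <- function(weights, bias = numeric(nrow(weights)),
                         activation = c("identity", "tanh")) {
  activation <- match.arg(activation)
  weights <- .as_matrix(weights, "weights")
  if (any(!is.finite(weights)) || any(!is.finite(bias)))
    stop("client parameters must be finite")
  if (length(bias) != nrow(weights))
    stop("dimension error: bias length must equal nrow(weights)")
  structure(list(weights = weights, bias = as.numeric(bias),
                 activation = activation),
            class = "client_model")
}

# seeded initialization: entries ~ normal(0, 0.01 variance), zero bias
.init_client <- function(m, d_out, activation, seed) {
  set.seed(seed)
  client_model(matrix(stats::rnorm(d_out * m, sd = 0.1), d_out, m),
               numeric(d_out), activation)
}

#' Client forward pass
#'
#' `X_t = activation(X %*% t(weights) + bias)` — the representation
#' ("smashed data") the client sends to the server.
#'
#' @param client a `client_model`.
#' @param X n x m raw feature matrix.
#' @return n x d_out representation matrix.
#' @export
client_forward <- function(client, X) {
  stopifnot(inherits(client, "client_model"))
  X <- .as_matrix(X)
  if (ncol(X) != ncol(client$weights))
    stop("dimension error: expected ", ncol(client$weights), " columns")
  A <- sweep(X %*% t(client$weights), 2L, client$bias, "+")
  if (client$activation == "tanh") tanh(A) else A
}

#' Server-side step: predictions, loss and both gradients
#'
#' The server evaluates the probit head on the received representations,
#' computes the negative log-likelihood loss, its gradient with respect to
#' the head parameters, and the gradient with respect to the
#' representations — the payload returned to the client.
#'
#' @param server `probit_params` (the head theta_s).
#' @param Xt n x d_out representation matrix.
#' @param y per-row labels.
#' @return List: `probs` (n x C), `loss` (scalar NLL), `grad_theta_s`
#'   (length d_out + C - 1), `grad_Xt` (n x d_out).
#' @export
server_step <- function(server, Xt, y) {
  p <- .get_params(server)
  Xt <- .as_matrix(Xt, "Xt")
  ng <- nll_grad(p, Xt, y)
  # dL/deta_i pulled back through eta_i = beta' x_i^t
  yi <- .y_index(y, p$classes)
  eta <- drop(Xt %*% p$beta)
  cuts <- c(-Inf, p$cutpoints, Inf)
  prob <- pmax(stats::pnorm(cuts[yi + 1L] - eta) -
                 stats::pnorm(cuts[yi] - eta), 1e-300)
  g_eta <- (stats::dnorm(cuts[yi + 1L] - eta) -
              stats::dnorm(cuts[yi] - eta)) / prob
  grad_Xt <- outer(g_eta, p$beta)
  list(probs = class_probs(p, Xt), loss = ng$nll, grad_theta_s = ng$grad,
       grad_Xt = grad_Xt)
}

# gradient-descent update of the probit head with ordering enforcement
.update_server <- function(server, grad, alpha) {
  d <- length(server$beta); C <- length(server$classes)
  theta <- c(server$beta, server$cutpoints) - alpha * grad
  cuts <- theta[(d + 1L):(d + C - 1L)]
  if (C > 2L) for (j in 2:(C - 1L))
    cuts[j] <- max(cuts[j], cuts[j - 1L] + 1e-8)
  probit_params(theta[seq_len(d)], cuts, server$classes)
}

#' One split-learning communication round
#'
#' Client forward pass, server step, then parameter updates — server first,
#' client second, both from the same round's gradients (matching a single
#' joint gradient-descent step on the composed model).
#'
#' @param client a `client_model`.
#' @param server `probit_params`.
#' @param X n x m raw features (client side).
#' @param y labels.
#' @param alpha learning rate, > 0.
#' @return List: updated `client`, `server`, and `record` (loss and
#'   gradient norms for the round log).
#' @export
split_round <- function(client, server, X, y, alpha) {
  .stopifnot_scalar_num(alpha, "alpha")
  if (alpha < 0) stop("'alpha' must be >= 0")
  X <- .as_matrix(X)
  Xt <- client_forward(client, X)
  st <- server_step(server, Xt, y)
  if (any(!is.finite(st$grad_theta_s)) || any(!is.finite(st$grad_Xt)))
    stop("numeric error: non-finite gradients in split round")
  server2 <- .update_server(.get_params(server), st$grad_theta_s, alpha)
  dA <- if (client$activation == "tanh") st$grad_Xt * (1 - Xt^2) else st$grad_Xt
  gW <- crossprod(dA, X)            # d_out x m
  gb <- colSums(dA)
  client2 <- client_model(client$weights - alpha * gW,
                          client$bias - alpha * gb, client$activation)
  list(client = client2, server = server2,
       record = list(loss = st$loss,
                     grad_norm_theta_s = sqrt(sum(st$grad_theta_s^2)),
                     grad_norm_Xt = sqrt(sum(st$grad_Xt^2))),
       payloads = list(
         list(kind = "representation", payload = Xt),
         list(kind = "labels", payload = as.character(y)),
         list(kind = "representation_gradient", payload = st$grad_Xt),
         list(kind = "loss", payload = st$loss)))
}

#' Split-training configuration
#'
#' @param learning_rate step size alpha; default `1/n` is filled in by
#'   [train_split()] when `NULL`.
#' @param max_rounds maximum communication rounds.
#' @param tol relative change in full-data loss declaring convergence.
#' @param seed integer seed for client initialization and partitioning.
#' @param d_out client representation width.
#' @param activation client activation.
#' @param mode `"single"` or `"round_robin"` (multi-client).
#' @param n_clients number of clients in round-robin mode.
#' @param client_partition optional list of disjoint row-index vectors
#'   covering all rows, one per client; default is a seeded IID split.
#' @return Object of class `split_config`.
#' @export
split_config <- function(learning_rate = NULL, max_rounds = 500L,
                         tol = 1e-6, seed = 1L, d_out = 3L,
                         activation = c("identity", "tanh"),
                         mode = c("single", "round_robin"),
                         n_clients = 2L, client_partition = NULL) {
  activation <- match.arg(activation)
  mode <- match.arg(mode)
  if (!is.null(learning_rate))
    .stopifnot_scalar_num(learning_rate, "learning_rate", positive = TRUE)
  .stopifnot_scalar_num(tol, "tol")
  if (tol < 0) stop("'tol' must be >= 0 (0 disables early stopping)")
  structure(list(learning_rate = learning_rate,
                 max_rounds = as.integer(max_rounds), tol = tol,
                 seed = as.integer(seed), d_out = as.integer(d_out),
                 activation = activation, mode = mode,
                 n_clients = as.integer(n_clients),
                 client_partition = client_partition),
            class = "split_config")
}

#' Train the split client/server model
#'
#' Iterates communication rounds until the relative change in the
#' full-data loss drops below `tol` or `max_rounds` is reached. In
#' round-robin mode, clients are processed in a fixed order within each
#' round; each receives the current client weights (weight hand-off) and
#' runs one round on its own partition.
#'
#' @param X n x m raw feature matrix.
#' @param y per-row labels.
#' @param config a [split_config()].
#' @param classes ordered class labels.
#' @param validation optional list with elements `X` and `y`; when given,
#'   per-round training/validation loss and accuracy are added to the
#'   round log (the learning-curve protocol).
#' @return Object of class `split_fit`: `client` (`client_model`),
#'   `server` (`probit_params`), `session` (round log data.frame +
#'   transcript), `converged`, `n_rounds`.
#' @export
train_split <- function(X, y, config = split_config(),
                        classes = tissue_classes(), validation = NULL) {
  stopifnot(inherits(config, "split_config"))
  X <- .as_matrix(X)
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) stop("need at least 2 rows to train")
  .y_index(y, classes)
  alpha <- if (is.null(config$learning_rate)) 1 / n else config$learning_rate
  client <- .init_client(m, config$d_out, config$activation, config$seed)
  server <- probit_params(numeric(config$d_out),
                          seq(-0.5, 0.5,
                              length.out = length(classes) - 1L),
                          classes)
  parts <- if (config$mode == "single") list(seq_len(n)) else {
    if (!is.null(config$client_partition)) config$client_partition
    else {
      set.seed(config$seed + 1L)
      idx <- sample.int(n)
      split(idx, rep(seq_len(config$n_clients), length.out = n))
    }
  }
  if (any(vapply(parts, length, integer(1)) == 0L))
    stop("config error: empty client partition")
  if (length(unique(unlist(parts))) != n || length(unlist(parts)) != n)
    stop("config error: client partition must cover all rows disjointly")

  full_loss <- function() nll_grad(server, client_forward(client, X), y)$nll
  loss_prev <- full_loss()
  round_log <- list(); transcript <- list()
  converged <- FALSE; r <- 0L
  while (r < config$max_rounds) {
    r <- r + 1L
    for (ci in seq_along(parts)) {
      rows <- parts[[ci]]
      rr <- split_round(client, server, X[rows, , drop = FALSE], y[rows],
                        alpha)
      client <- rr$client; server <- rr$server
      round_log[[length(round_log) + 1L]] <-
        data.frame(round = r, client = ci, loss = rr$record$loss,
                   grad_norm_theta_s = rr$record$grad_norm_theta_s,
                   grad_norm_Xt = rr$record$grad_norm_Xt,
                   full_loss = NA_real_, train_acc = NA_real_,
                   val_loss = NA_real_, val_acc = NA_real_)
      transcript[[length(transcript) + 1L]] <-
        c(list(round = r, client = ci), list(payloads = rr$payloads))
    }
    loss_now <- full_loss()
    round_log[[length(round_log)]]$full_loss <- loss_now
    if (!is.null(validation)) {
      pred_tr <- classes[max.col(class_probs(server,
                                             client_forward(client, X)),
                                 ties.method = "first")]
      Xt_val <- client_forward(client, validation$X)
      pred_val <- classes[max.col(class_probs(server, Xt_val),
                                  ties.method = "first")]
      last <- length(round_log)
      round_log[[last]]$train_acc <- mean(pred_tr == as.character(y))
      round_log[[last]]$val_loss <- nll_grad(server, Xt_val,
                                             validation$y)$nll
      round_log[[last]]$val_acc <-
        mean(pred_val == as.character(validation$y))
    }
    if (!is.finite(loss_now) || loss_now > 1e10)
      stop("numeric error: loss diverged at round ", r,
           "; try a smaller learning rate")
    if (abs(loss_prev - loss_now) < config$tol * (abs(loss_prev) + 1e-12)) {
      converged <- TRUE
      break
    }
    loss_prev <- loss_now
  }
  structure(list(client = client, server = server,
                 session = list(round_log = do.call(rbind, round_log),
                                transcript = transcript, config = config,
                                alpha = alpha, classes = classes),
                 converged = converged, n_rounds = r),
            class = "split_fit")
}

#' @export
print.split_fit <- function(x, ...) {
  cat(sprintf(
    "Split-learning fit: %d round(s), %s, %s\n", x$n_rounds,
    if (x$session$config$mode == "single") "1 client"
    else paste0(length(unique(x$session$round_log$client)), " clients"),
    if (x$converged) "converged" else "round limit reached"))
  cat(sprintf("  final full-data NLL: %.4f\n",
              utils::tail(stats::na.omit(x$session$round_log$full_loss), 1L)))
  cat("  server head:\n")
  print(round(c(x$server$beta, x$server$cutpoints), 4))
  invisible(x)
}

#' @export
coef.split_fit <- function(object, ...) {
  list(client_weights = object$client$weights,
       client_bias = object$client$bias,
       beta = object$server$beta, cutpoints = object$server$cutpoints)
}

#' @export
predict.split_fit <- function(object, newdata,
                              type = c("probs", "class"), ...) {
  type <- match.arg(type)
  Xt <- client_forward(object$client, newdata)
  P <- class_probs(object$server, Xt)
  if (type == "probs") return(P)
  object$server$classes[max.col(P, ties.method = "first")]
}

#' @export
plot.split_fit <- function(x, ...) {
  lg <- x$session$round_log
  loss <- stats::aggregate(loss ~ round, lg, mean)
  plot(loss$round, loss$loss, type = "l", xlab = "communication round",
       ylab = "NLL", main = "Split-training loss", ...)
  invisible(x)
}

# exact-match row keys for the privacy audit
.row_keys <- function(M) apply(M, 1L, function(r)
  paste(sprintf("%.17g", r), collapse = ","))

#' Audit a split-training transcript for raw-data leakage
#'
#' Verifies that no payload that crossed the client/server boundary equals
#' — or contains as a contiguous column block — any raw feature row of
#' `X_raw`. Payloads narrower than the raw feature dimension cannot contain
#' a full row and pass dimensionally.
#'
#' @param session the `session` element of a `split_fit` (or the fit).
#' @param X_raw the raw feature matrix the client trained on.
#' @return List: `pass` (TRUE), `n_rounds`, `payload_summary` (data.frame
#'   of payload kinds, counts and byte totals). Raises a
#'   privacy-violation error naming the round otherwise.
#' @export
audit_transcript <- function(session, X_raw) {
  if (inherits(session, "split_fit")) session <- session$session
  X_raw <- .as_matrix(X_raw, "X_raw")
  m <- ncol(X_raw)
  raw_keys <- .row_keys(X_raw)
  kinds <- character(0); bytes <- numeric(0)
  for (entry in session$transcript) {
    for (pl in entry$payloads) {
      kinds <- c(kinds, pl$kind)
      bytes <- c(bytes, as.numeric(utils::object.size(pl$payload)))
      P <- pl$payload
      if (!is.matrix(P) || ncol(P) < m) next
      for (start in 1:(ncol(P) - m + 1L)) {
        keys <- .row_keys(P[, start:(start + m - 1L), drop = FALSE])
        if (any(keys %in% raw_keys))
          stop("privacy-violation error: transcript payload of kind '",
               pl$kind, "' at round ", entry$round,
               " contains a raw feature row")
      }
    }
  }
  rounds <- vapply(session$transcript, function(e) e$round, numeric(1))
  list(pass = TRUE, n_rounds = length(unique(rounds)),
       payload_summary = stats::aggregate(
         bytes ~ kind, data.frame(kind = kinds, bytes = bytes),
         FUN = function(b) c(n = length(b), total_bytes = sum(b))))
}

#' Write a session's round log and transcript summary as JSON lines
#'
#' One JSON object per line: round records first, then one summary line
#' per transcript payload (kind and dimensions; payload contents stay in
#' memory).
#'
#' @param session the `session` element of a `split_fit` (or the fit).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
session_write_jsonl <- function(session, path) {
  if (inherits(session, "split_fit")) session <- session$session
  con <- file(path, "w")
  on.exit(close(con))
  lg <- session$round_log
  for (i in seq_len(nrow(lg)))
    writeLines(jsonlite::toJSON(as.list(lg[i, ]), auto_unbox = TRUE,
                                digits = I(17), na = "null"), con)
  for (entry in session$transcript)
    for (pl in entry$payloads)
      writeLines(jsonlite::toJSON(
        list(round = entry$round, client = entry$client, kind = pl$kind,
             dims = if (is.matrix(pl$payload)) dim(pl$payload)
                    else length(pl$payload)),
        auto_unbox = TRUE), con)
  invisible(path)
}
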