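# End-to-end orchestration: phantom generation -> preprocessing -> PCA ->
# EM reliability selection -> split training -> evaluation, with every
# intermediate artifact written to a run directory and checksummed in a
# manifest. All stage seeds derive deterministically from one global seed
# so reruns reproduce identical outputs.

#' Pipeline configuration
#'
#' Bundles per-stage options. Every stage's seed is derived from the
#' global `seed` by a fixed counter scheme, so stages rerun in isolation
#' reproduce their in-pipeline behaviour.
#'
#' @param seed global integer seed.
#' @param phantom list of arguments for [phantom_config()] (seed is filled
#'   in from the global seed).
#' @param corruption_fraction fraction of labeled pixels given the
#'   FFPE-style spectral shift before training.
#' @param corruption_shift optional length-n_bands shift vector; default as
#'   in [corrupt_labels()].
#' @param train_fraction fraction of labeled pixels used for training
#'   (stratified by class); the rest form the validation set.
#' @param kernel_taps low-pass FIR taps applied to every spectrum.
#' @param pca_k retained PCA components (`NULL` to use
#'   `pca_variance_fraction`).
#' @param pca_variance_fraction retained-variance alternative to `pca_k`.
#' @param tau reliability threshold for training-pixel selection.
#' @param em_max_iter,em_tol EM controls.
#' @param train list of arguments for [split_config()].
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 7L, phantom = list(),
                            corruption_fraction = 0.1,
                            corruption_shift = NULL,
                            train_fraction = 0.5,
                            kernel_taps = c(0.25, 0.5, 0.25),
                            pca_k = 3L, pca_variance_fraction = NULL,
                            tau = 0.8, em_max_iter = 200L, em_tol = 1e-8,
                            train = list()) {
  structure(list(seed = as.integer(seed), phantom = phantom,
                 corruption_fraction = corruption_fraction,
                 corruption_shift = corruption_shift,
                 train_fraction = train_fraction,
                 kernel_taps = as.numeric(kernel_taps),
                 pca_k = if (is.null(pca_k)) NULL else as.integer(pca_k),
                 pca_variance_fraction = pca_variance_fraction,
                 tau = tau, em_max_iter = as.integer(em_max_iter),
                 em_tol = em_tol, train = train),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file.
#' @return `path` invisibly / the restored `pipeline_config`.
#' @export
pipeline_config_write <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config_write
#' @export
pipeline_config_read <- function(path) {
  o <- yaml::read_yaml(path)
  do.call(pipeline_config, o)
}

# stratified train/validation split of a pixel table
.split_pixels <- function(table, train_fraction, seed) {
  set.seed(seed)
  train_idx <- integer(0)
  for (cl in unique(table$label)) {
    rows <- which(table$label == cl)
    n_tr <- max(1L, round(train_fraction * length(rows)))
    train_idx <- c(train_idx, sample(rows, n_tr))
  }
  list(train = sort(train_idx),
       val = setdiff(seq_len(nrow(table)), train_idx))
}

#' Run the full pipeline
#'
#' Executes generate -> corrupt -> preprocess -> PCA -> EM reliability
#' selection -> split training -> evaluation, writing every intermediate
#' artifact (cube, pixel tables, fitted models, session log, report,
#' learning curves) plus a checksum manifest to `out_dir`. Rerunning with
#' the same configuration reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created if missing); `NULL` keeps
#'   everything in memory.
#' @return Invisibly, a list: `report` (metrics, per-region AUCs and
#'   thresholds, t-test on PC1, learning-curve summary, privacy audit),
#'   `fit` (`split_fit`), `pca`, `reliability`, `phantom`, `tables`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "phantom"
  res <- tryCatch({
    ph_args <- config$phantom
    ph_args$seed <- derive_seed(config$seed, "phantom")
    phantom <- generate_phantom(do.call(phantom_config, ph_args))
    if (config$corruption_fraction > 0)
      phantom <- corrupt_labels(phantom, config$corruption_fraction,
                                shift = config$corruption_shift,
                                seed = derive_seed(config$seed, "corrupt"))
    tab <- to_pixel_table(phantom, include_background = FALSE)
    if (nrow(tab) == 0L) stop("phantom has no labeled pixels")

    stage <- "preprocess"
    parts <- .split_pixels(tab, config$train_fraction,
                           derive_seed(config$seed, "split"))
    kernel <- filter_kernel(config$kernel_taps)
    X_all <- lowpass(pixel_features(tab), kernel)
    X_tr_raw <- X_all[parts$train, , drop = FALSE]
    X_val_raw <- X_all[parts$val, , drop = FALSE]
    norm <- minmax_fit_apply(X_tr_raw)
    X_tr <- norm$X_normalized
    X_val <- minmax_apply(norm$params, X_val_raw)
    y_tr <- tab$label[parts$train]
    y_val <- tab$label[parts$val]

    stage <- "pca"
    pca <- pca_fit(X_tr, k = config$pca_k,
                   variance_fraction = config$pca_variance_fraction)
    Z_tr <- pca_transform(pca, X_tr)
    Z_val <- pca_transform(pca, X_val)

    stage <- "reliability"
    rel <- em_fit(Z_tr, y_tr, max_iter = config$em_max_iter,
                  tol = config$em_tol, threshold = config$tau)
    scores <- reliability_scores(rel, Z_tr, y_tr)
    sel <- select_reliable(scores, config$tau, y_tr)

    stage <- "train"
    if (length(sel$index) == 0L)
      stop("empty-training-set error: the reliability stage retained no ",
           "pixels at tau = ", config$tau)
    if (length(unique(y_tr[sel$index])) < 2L)
      stop("empty-training-set error: the reliability stage left fewer ",
           "than 2 classes at tau = ", config$tau)
    tr_args <- config$train
    tr_args$seed <- derive_seed(config$seed, "train")
    fit <- train_split(Z_tr[sel$index, , drop = FALSE], y_tr[sel$index],
                       do.call(split_config, tr_args),
                       validation = list(X = Z_val, y = y_val))

    stage <- "evaluate"
    probs <- predict(fit, Z_val, type = "probs")
    pred <- predict(fit, Z_val, type = "class")
    report_cls <- classification_report(y_val, pred)
    region_auc <- list(); region_thr <- list()
    for (cl in tissue_classes()) {
      pos <- y_val == cl
      if (any(pos) && any(!pos)) {
        region_auc[[cl]] <- auc(probs[, cl], pos)
        region_thr[[cl]] <- best_threshold(probs[, cl], pos)
      }
    }
    pc1 <- Z_val[, 1L]
    ttest <- two_sample_ttest(pc1[y_val == "cancer"],
                              pc1[y_val != "cancer"])
    lg <- fit$session$round_log
    lg_epoch <- lg[!is.na(lg$full_loss),
                   c("round", "full_loss", "train_acc", "val_loss",
                     "val_acc")]
    names(lg_epoch)[1:2] <- c("epoch", "train_loss")
    curves <- learning_curves(lg_epoch)
    audit <- audit_transcript(fit$session, X_tr_raw)
    report <- list(
      seed = config$seed,
      n_train = length(sel$index), n_val = length(y_val),
      reliability_summary = sel$summary,
      metrics = report_cls$metrics,
      micro_accuracy = report_cls$micro_accuracy,
      region_auc = lapply(region_auc, identity),
      region_threshold = region_thr,
      ttest_pc1 = unclass(ttest),
      best_val_acc_epoch = curves$best_val_acc_epoch,
      plateau = curves$plateau,
      n_rounds = fit$n_rounds, converged = fit$converged,
      privacy_audit = list(pass = audit$pass,
                           n_rounds = audit$n_rounds))
    list(report = report, fit = fit, pca = pca, reliability = rel,
         phantom = phantom, tables = list(pixels = tab, split = parts),
         curves = curves, norm = norm$params)
  }, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(out_dir)) .write_run_dir(res, config, out_dir)
  invisible(res)
}

# persist all artifacts plus a checksum manifest
.write_run_dir <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cube(res$phantom, file.path(out_dir, "phantom.json"))
  utils::write.csv(res$tables$pixels, file.path(out_dir, "pixels.csv"),
                   row.names = FALSE)
  pca_write_json(res$pca, file.path(out_dir, "pca.json"))
  probit_write_json(res$fit$server, file.path(out_dir, "server.json"))
  jsonlite::write_json(
    list(weights = as.vector(res$fit$client$weights),
         d_out = nrow(res$fit$client$weights),
         m = ncol(res$fit$client$weights),
         bias = res$fit$client$bias,
         activation = res$fit$client$activation),
    file.path(out_dir, "client.json"), digits = I(17), auto_unbox = TRUE)
  session_write_jsonl(res$fit$session, file.path(out_dir, "session.jsonl"))
  utils::write.csv(res$curves$table, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       digits = I(17), auto_unbox = TRUE,
                       dataframe = "rows", force = TRUE)
  pipeline_config_write(config, file.path(out_dir, "config.yaml"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  jsonlite::write_json(
    list(files = data.frame(file = files, md5 = unname(sums))),
    file.path(out_dir, "manifest.json"), dataframe = "rows")
  invisible(out_dir)
}

#' Write a phantom cube to the package's JSON cube format
#'
#' Plain-text layout mirroring the logical HDF5 structure: the reflectance
#' cube (row, col, band axis order), the label map (codes 0 = background,
#' 1 = fat, 2 = muscle, 3 = cancer), the corruption mask, and the seed and
#' serialized configuration as attributes. Numeric values carry 17
#' significant digits, so a write/read round trip is lossless.
#'
#' @param phantom a `thz_phantom`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_cube <- function(phantom, path) {
  stopifnot(inherits(phantom, "thz_phantom"))
  jsonlite::write_json(list(
    format = "splitthz-cube-json-v1",
    seed = phantom$config$seed,
    config_json = as.character(jsonlite::serializeJSON(phantom$config,
                                                       digits = 17)),
    dims = dim(phantom$cube),
    cube = as.vector(phantom$cube),
    labels = as.vector(phantom$labels),
    corruption = as.integer(phantom$corruption_mask)),
    path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a phantom cube from the JSON cube format
#'
#' @param path file written by [write_cube()].
#' @return A `thz_phantom`.
#' @export
read_cube <- function(path) {
  o <- jsonlite::fromJSON(path)
  missing <- setdiff(c("cube", "labels", "corruption", "dims"), names(o))
  if (length(missing))
    stop("format error: missing dataset(s): ",
         paste0("/", missing, collapse = ", "))
  dims <- as.integer(o$dims)
  labels <- as.integer(o$labels)
  if (any(!labels %in% 0:3))
    stop("validation error: label codes outside {0,1,2,3}")
  cfg <- if (!is.null(o$config_json))
    jsonlite::unserializeJSON(o$config_json) else NULL
  structure(list(
    cube = array(as.numeric(o$cube), dim = dims),
    labels = matrix(labels, dims[1], dims[2]),
    corruption_mask = matrix(as.logical(o$corruption), dims[1], dims[2]),
    config = cfg),
    class = "thz_phantom")
}

#' Export a label map as CSV
#'
#' One row per pixel in row-major order: `row`, `col` (0-based) and
#' `label_code`.
#'
#' @param phantom a `thz_phantom`.
#' @param path CSV file to write.
#' @return `path`, invisibly.
#' @export
write_label_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "thz_phantom"))
  h <- nrow(phantom$labels); w <- ncol(phantom$labels)
  df <- data.frame(row = rep(0:(h - 1L), each = w),
                   col = rep(0:(w - 1L), h))
  df$label_code <- phantom$labels[cbind(df$row + 1L, df$col + 1L)]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
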