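#' Seed every stochastic component
#'
#' Sets R's RNG (which drives balancing, the synthetic generator when a spec
#' carries no seed, and default seed selection) and records the value as the
#' package-level default seed, from which weight initialization, mini-batch
#' shuffling and dropout streams are derived deterministically.
#'
#' @param seed Integer seed.
#' @return `seed`, invisibly.
#' @export
set_global_seed <- function(seed) {
  seed <- as.integer(seed)
  set.seed(seed)
  options(ssmfn.seed = seed)
  invisible(seed)
}

default_seed <- function() {
  getOption("ssmfn.seed", 1L)
}

#' Train a model on labeled peptide windows
#'
#' Minimizes two-class cross-entropy with Adam (learning rate from the
#' config, 0.001 by default) over shuffled mini-batches for up to `epochs`
#' epochs. When a validation set is supplied, the six evaluation metrics are
#' logged each epoch and the weights with the best validation MCC are kept
#' alongside the final-epoch weights (ties resolve to the earliest epoch);
#' MCC drives selection because it is the most informative single
#' confusion-matrix summary under class imbalance. Identical
#' (data, config, seed) triples reproduce identical loss histories,
#' selection epochs and weights.
#'
#' @param data Training windows: data frame with `window` and `label`.
#' @param validation Optional validation windows (same columns), disjoint
#'   from `data` by residue string.
#' @param variant Architecture, see [build_model()].
#' @param config A [model_config()].
#' @param seed Integer seed (weights, shuffling, dropout). Defaults to the
#'   value recorded by [set_global_seed()], else 1.
#' @param epochs Overrides `config$epochs` when given.
#' @param verbose Print per-epoch progress.
#' @return An object of class `ssmfn_fit`: the selected weights (`params`),
#'   both checkpoints (`final_params`, `best_params`), `best_epoch`,
#'   `checkpoint_used` (`"best_mcc"` or `"final"`), the per-epoch `history`
#'   tibble (epoch, loss, and validation metrics when available), the
#'   `variant`, `config`, `alphabet` and `seed`.
#' @export
fit_model <- function(data, validation = NULL, variant = "ssmfn_merged",
                      config = model_config(), seed = NULL,
                      epochs = NULL, verbose = FALSE) {
  config <- as_config(config)
  variant <- normalize_variant(variant)
  seed <- as.integer(seed %||% default_seed())
  epochs <- as.integer(epochs %||% config$epochs)
  stopifnot(is.data.frame(data), all(c("window", "label") %in% names(data)))
  if (nrow(data) == 0) {
    rlang::abort("empty training set", class = "ssmfn_training_error")
  }
  batch <- encode_windows(data)
  has_val <- !is.null(validation) && nrow(validation) > 0
  val_batch <- NULL
  if (has_val) {
    overlap <- intersect(data$window, validation$window)
    if (length(overlap) > 0) {
      rlang::abort(paste0("validation set shares ", length(overlap),
                          " window(s) with the training set"),
                   class = "ssmfn_training_error")
    }
    val_batch <- encode_windows(validation)
  }

  history <- vector("list", epochs)
  cb <- function(epoch, loss, val_probs) {
    row <- tibble::tibble(epoch = as.integer(epoch), loss = loss)
    crit <- NULL
    if (has_val) {
      pred <- as.integer(val_probs >= 0.5)
      rep <- metric_report(val_batch$labels, pred, val_probs)
      row <- dplyr::bind_cols(row, rep[c("acc", "f1", "sens", "spec", "mcc",
                                         "auc")])
      crit <- rep$mcc
    }
    history[[epoch]] <<- row
    if (verbose) {
      msg <- sprintf("epoch %d  loss %.4f", epoch, loss)
      if (has_val) msg <- sprintf("%s  val mcc %.4f", msg, row$mcc)
      message(msg)
    }
    crit
  }

  init <- cpp_init(variant, unclass(config), seed)
  run <- cpp_train(init, variant, unclass(config), batch$indices,
                   batch$labels,
                   if (has_val) val_batch$indices else NULL,
                   epochs, config$batch_size, config$learning_rate,
                   seed, cb)
  history <- dplyr::bind_rows(history)
  checkpoint_used <- if (has_val) "best_mcc" else "final"
  structure(
    list(
      variant = variant,
      config = config,
      alphabet = residue_alphabet(),
      params = if (has_val) run$best else run$final,
      best_params = run$best,
      final_params = run$final,
      best_epoch = as.integer(run$best_epoch),
      checkpoint_used = checkpoint_used,
      history = history,
      seed = seed,
      epochs_run = epochs
    ),
    class = "ssmfn_fit"
  )
}

#' @export
print.ssmfn_fit <- function(x, ...) {
  cat("<ssmfn_fit> variant:", x$variant, " epochs:", x$epochs_run,
      " checkpoint:", x$checkpoint_used,
      if (x$checkpoint_used == "best_mcc") paste0("(epoch ", x$best_epoch, ")"),
      "\n final loss:", signif(utils::tail(x$history$loss, 1), 4), "\n")
  invisible(x)
}

#' Predict methylation for peptide windows
#'
#' Eval-mode inference: per-window positive-class probability (exponential
#' normalization of the two head scores) and the hard label, 1 iff that
#' probability is at least 0.5 (equivalently, the positive score is not
#' below the negative score). Input order is preserved and each window is
#' scored independently.
#'
#' @param object An `ssmfn_fit` (or loaded checkpoint).
#' @param newdata Data frame with a `window` column, or character vector.
#' @param ... Unused.
#' @return A tibble: `window`, `prob_methylated`, `pred_label`.
#' @export
predict.ssmfn_fit <- function(object, newdata, ...) {
  if (is.character(newdata)) newdata <- tibble::tibble(window = newdata)
  scores <- forward(object, newdata, mode = "eval")
  probs <- softmax_rows(scores)[, 2L]
  tibble::tibble(
    window = newdata$window,
    prob_methylated = as.numeric(probs),
    pred_label = as.integer(probs >= 0.5)
  )
}

#' Evaluate a fitted model on a labeled dataset
#'
#' Runs [predict.ssmfn_fit()], forms the confusion counts from the hard
#' labels, and computes the six-metric row (AUC from the continuous
#' probabilities, not the hard labels). Deterministic given fixed weights.
#'
#' @param fit An `ssmfn_fit`.
#' @param data Data frame with `window` and `label`.
#' @param f1_variant `"standard"` or `"threat"` (the TP/(TP+FP+FN) form).
#' @return One-row tibble: `model`, then the [metric_report()] columns.
#' @export
evaluate_model <- function(fit, data, f1_variant = c("standard", "threat")) {
  f1_variant <- match.arg(f1_variant)
  stopifnot(is.data.frame(data), all(c("window", "label") %in% names(data)))
  pred <- predict(fit, data)
  rep <- metric_report(data$label, pred$pred_label, pred$prob_methylated,
                       f1_variant)
  dplyr::bind_cols(tibble::tibble(model = fit$variant), rep)
}

#' Save a fitted model as a self-describing text checkpoint
#'
#' The checkpoint is JSON holding the variant tag, the full configuration,
#' the alphabet ordering and every weight matrix (plus batch-norm running
#' statistics) at full precision, so save -> load -> predict reproduces
#' predictions bit-for-bit in eval mode.
#'
#' @param fit An `ssmfn_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "ssmfn_fit") || inherits(fit, "ssmfn_model"))
  payload <- list(
    format = "ssmfn_checkpoint_v1",
    variant = fit$variant,
    config = unclass(as_config(fit$config)),
    alphabet = fit$alphabet %||% residue_alphabet(),
    best_epoch = fit$best_epoch %||% NA_integer_,
    checkpoint_used = fit$checkpoint_used %||% "final",
    seed = fit$seed %||% NA_integer_,
    params = lapply(model_params(fit), function(m) {
      list(dim = dim(m), values = as.numeric(m))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return An `ssmfn_fit` carrying the stored weights (no training history).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("checkpoint not found: ", path),
                 class = "ssmfn_io_error")
  }
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "ssmfn_checkpoint_v1")) {
    rlang::abort("not an ssmfn checkpoint", class = "ssmfn_io_error")
  }
  if (!identical(as.character(payload$alphabet), residue_alphabet())) {
    rlang::abort("checkpoint alphabet does not match this package's alphabet",
                 class = "ssmfn_io_error")
  }
  params <- lapply(payload$params, function(p) {
    matrix(as.numeric(p$values), nrow = p$dim[1], ncol = p$dim[2])
  })
  cfg <- payload$config
  cfg$conv_kernel <- as.integer(unlist(cfg$conv_kernel))
  structure(
    list(
      variant = payload$variant,
      config = do.call(model_config, cfg),
      alphabet = as.character(payload$alphabet),
      params = params,
      best_params = params,
      final_params = params,
      best_epoch = payload$best_epoch,
      checkpoint_used = payload$checkpoint_used,
      history = tibble::tibble(),
      seed = payload$seed,
      epochs_run = NA_integer_
    ),
    class = "ssmfn_fit"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#'
#' @param x An `ssmfn_fit`.
#' @param ... Unused.
#' @return The history tibble: `epoch`, `loss`, and — when a validation set
#'   was supplied — `acc`, `f1`, `sens`, `spec`, `mcc`, `auc`.
#' @export
tidy.ssmfn_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x An `ssmfn_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `variant`, `parameters`, `epochs_run`,
#'   `best_epoch`, `checkpoint_used`, `final_loss`, `seed`.
#' @export
glance.ssmfn_fit <- function(x, ...) {
  tibble::tibble(
    variant = x$variant,
    parameters = count_parameters(x),
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    checkpoint_used = x$checkpoint_used,
    final_loss = if (nrow(x$history) > 0) utils::tail(x$history$loss, 1)
                 else NA_real_,
    seed = x$seed
  )
}
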