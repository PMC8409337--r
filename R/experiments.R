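#' Plan a training/evaluation experiment
#'
#' Describes one experiment: which training regime (train on the natural
#' imbalanced split, or on its balanced undersampled version), which model
#' variants, which evaluation sets, and which seeds. Evaluation sets follow
#' the three-way design used throughout the result tables: the imbalanced
#' validation split as-is, its balanced version, and the test split.
#'
#' @param training_regime `"balanced"` or `"imbalanced"`.
#' @param model_variants Subset of `"ssmfn_merged"`, `"ssmfn_cnn_only"`,
#'   `"ssmfn_lstm_only"`, `"smlp"`.
#' @param evaluation_sets Subset of `"imbalanced_validation"`,
#'   `"balanced_validation"`, `"test"`.
#' @param seeds Integer vector of seeds; one full train/evaluate cycle runs
#'   per (variant, seed).
#' @param config A [model_config()].
#' @param epochs Optional override of `config$epochs`.
#' @return A list of class `experiment_plan`.
#' @export
experiment_plan <- function(training_regime = c("balanced", "imbalanced"),
                            model_variants = c("ssmfn_merged",
                                               "ssmfn_cnn_only",
                                               "ssmfn_lstm_only"),
                            evaluation_sets = c("imbalanced_validation",
                                                "balanced_validation",
                                                "test"),
                            seeds = c(1L, 2L, 3L),
                            config = model_config(),
                            epochs = NULL) {
  training_regime <- match.arg(training_regime)
  model_variants <- vapply(model_variants, normalize_variant, character(1),
                           USE.NAMES = FALSE)
  evaluation_sets <- match.arg(evaluation_sets, several.ok = TRUE)
  stopifnot(length(model_variants) >= 1, length(evaluation_sets) >= 1,
            length(seeds) >= 1)
  structure(
    list(training_regime = training_regime,
         model_variants = model_variants,
         evaluation_sets = evaluation_sets,
         seeds = as.integer(seeds),
         config = as_config(config),
         epochs = epochs),
    class = "experiment_plan"
  )
}

resolve_data <- function(data) {
  if (is.character(data) && length(data) == 1) data <- read_manifest(data)
  stopifnot(is.data.frame(data),
            all(c("window", "label", "split") %in% names(data)))
  missing <- setdiff(c("train", "validation", "test"), unique(data$split))
  if (length(missing) > 0) {
    rlang::abort(paste0("data is missing split(s): ", toString(missing)),
                 class = "ssmfn_manifest_error")
  }
  data
}

data_digest <- function(data) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(data$window, data$label, data$split, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a planned experiment
#'
#' For every (variant, seed) cell: trains under the plan's regime — the
#' balanced regime undersamples the training split (seeded by the cell seed)
#' and monitors the balanced validation split; the imbalanced regime trains
#' and monitors on the natural splits — then evaluates the fit on every
#' requested evaluation set. A failing cell is recorded with its diagnostic
#' and does not abort the other cells. (manifest, plan, seed) fully
#' determine every reported number.
#'
#' @param data A data frame covering the train/validation/test splits
#'   (columns `window`, `label`, `split`), or a path to a YAML manifest for
#'   [read_manifest()].
#' @param plan An [experiment_plan()].
#' @param f1_variant F1 convention recorded in the reports.
#' @param verbose Print progress.
#' @return An `ssmfn_result`: list with the metric `rows` tibble
#'   (variant x evaluation set x seed) and a `provenance` record (config,
#'   seeds, regime, data digest, timestamp).
#' @export
run_experiment <- function(data, plan = experiment_plan(),
                           f1_variant = c("standard", "threat"),
                           verbose = FALSE) {
  f1_variant <- match.arg(f1_variant)
  data <- resolve_data(data)
  digest <- data_digest(data)
  train_nat <- data[data$split == "train", ]
  val_nat <- data[data$split == "validation", ]
  test_set <- data[data$split == "test", ]

  rows <- list()
  for (seed in plan$seeds) {
    if (plan$training_regime == "balanced") {
      train_set <- suppressMessages(balance_dataset(train_nat, seed))
      monitor <- suppressMessages(balance_dataset(val_nat, seed))
    } else {
      train_set <- train_nat
      monitor <- val_nat
    }
    eval_sets <- list(
      imbalanced_validation = val_nat,
      balanced_validation = suppressMessages(balance_dataset(val_nat, seed)),
      test = test_set
    )[plan$evaluation_sets]
    for (variant in plan$model_variants) {
      cell <- tryCatch({
        if (verbose) message("training ", variant, " (seed ", seed, ")")
        fit <- fit_model(train_set, validation = monitor, variant = variant,
                         config = plan$config, seed = seed,
                         epochs = plan$epochs)
        purrr::imap_dfr(eval_sets, function(d, nm) {
          dplyr::bind_cols(
            tibble::tibble(evaluation_set = nm, seed = seed,
                           status = "ok", message = NA_character_),
            evaluate_model(fit, d, f1_variant)
          )
        })
      }, error = function(e) {
        tibble::tibble(evaluation_set = plan$evaluation_sets, seed = seed,
                       status = "failed", message = conditionMessage(e),
                       model = variant)
      })
      rows[[length(rows) + 1]] <- cell
    }
  }
  rows <- dplyr::bind_rows(rows)
  rows <- dplyr::relocate(rows, "model", "evaluation_set", "seed")
  structure(
    list(
      rows = rows,
      provenance = list(
        training_regime = plan$training_regime,
        config = unclass(plan$config),
        epochs = plan$epochs %||% plan$config$epochs,
        seeds = plan$seeds,
        f1_variant = f1_variant,
        data_digest = digest,
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
      )
    ),
    class = "ssmfn_result"
  )
}

#' Branch-wise ablation study
#'
#' Convenience wrapper fixing the model set to the CNN-only, LSTM-only and
#' merged variants, so the contribution of each branch can be read off one
#' table per evaluation set.
#'
#' @inheritParams run_experiment
#' @param training_regime,seeds,config,epochs Passed to [experiment_plan()].
#' @return An `ssmfn_result`, see [run_experiment()].
#' @export
run_ablation <- function(data, training_regime = "balanced",
                         seeds = c(1L, 2L, 3L), config = model_config(),
                         epochs = NULL, verbose = FALSE) {
  plan <- experiment_plan(
    training_regime = training_regime,
    model_variants = c("ssmfn_cnn_only", "ssmfn_lstm_only", "ssmfn_merged"),
    seeds = seeds, config = config, epochs = epochs
  )
  run_experiment(data, plan, verbose = verbose)
}

#' @export
print.ssmfn_result <- function(x, ...) {
  cat("<ssmfn_result> ", nrow(x$rows), " rows (",
      sum(x$rows$status == "ok"), " ok); regime: ",
      x$provenance$training_regime, "\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' Metric rows of an experiment result
#' @param x An `ssmfn_result`.
#' @param ... Unused.
#' @return The `rows` tibble.
#' @export
tidy.ssmfn_result <- function(x, ...) x$rows

#' Per-cell aggregate of an experiment result
#'
#' @param x An `ssmfn_result`.
#' @param ... Unused.
#' @return One row per (model, evaluation set): mean and standard deviation
#'   of each metric over seeds, plus the seed count.
#' @export
glance.ssmfn_result <- function(x, ...) {
  ok <- x$rows[x$rows$status == "ok", ]
  ok |>
    dplyr::group_by(.data$model, .data$evaluation_set) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c("acc", "f1", "sens", "spec", "mcc", "auc")),
                    list(mean = ~mean(.x), sd = ~stats::sd(.x))),
      n_seeds = dplyr::n(),
      .groups = "drop"
    )
}

#' Render an experiment result
#'
#' `"table"` style mirrors the result-table layout: one block per
#' evaluation set, columns Acc/F1/Sens/Spec/MCC/AUC rounded to 4 decimals,
#' with the best value per column marked by `*` (ties all marked); rows are
#' seed-averaged. `"machine"` style is a full-precision, losslessly
#' re-parseable JSON string including provenance.
#'
#' @param result An `ssmfn_result`.
#' @param style `"table"` or `"machine"`.
#' @return A character vector of table lines, or a JSON string.
#' @export
render_report <- function(result, style = c("table", "machine")) {
  style <- match.arg(style)
  stopifnot(inherits(result, "ssmfn_result"))
  if (nrow(result$rows) == 0) {
    rlang::abort("empty result", class = "ssmfn_report_error")
  }
  if (style == "machine") {
    return(jsonlite::toJSON(
      list(rows = result$rows, provenance = result$provenance),
      auto_unbox = TRUE, digits = NA, na = "null"
    ))
  }
  metrics <- c("acc", "f1", "sens", "spec", "mcc", "auc")
  agg <- glance(result)
  lines <- character()
  for (es in unique(agg$evaluation_set)) {
    blk <- agg[agg$evaluation_set == es, ]
    vals <- as.matrix(blk[paste0(metrics, "_mean")])
    marked <- matrix("", nrow(vals), ncol(vals))
    for (j in seq_len(ncol(vals))) {
      col <- round(vals[, j], 4)
      best <- max(col, na.rm = TRUE)
      marked[, j] <- paste0(sprintf("%.4f", col),
                            ifelse(!is.na(col) & col == best, "*", ""))
    }
    lines <- c(lines,
               paste0("== ", es, " =="),
               paste(c(sprintf("%-18s", "Model"),
                       sprintf("%8s", c("Acc", "F1", "Sens", "Spec",
                                        "MCC", "AUC"))), collapse = " "))
    for (i in seq_len(nrow(blk))) {
      lines <- c(lines, paste(c(sprintf("%-18s", blk$model[i]),
                                sprintf("%8s", marked[i, ])), collapse = " "))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Parse a machine-style report back into a result
#'
#' @param json JSON string from `render_report(style = "machine")`.
#' @return An `ssmfn_result` with the same rows and provenance.
#' @export
parse_report <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(rows = tibble::as_tibble(x$rows), provenance = x$provenance),
            class = "ssmfn_result")
}
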