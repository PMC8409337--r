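model_variants <- c("ssmfn_merged", "ssmfn_cnn_only", "ssmfn_lstm_only", "smlp")

#' Build a predictor model
#'
#' Constructs one of the four architectures with freshly initialized weights:
#'
#' * `"ssmfn_merged"` — shared embedding split into an LSTM branch (2 layers
#'   x 64 units, dropout after each layer) and a CNN branch (4 blocks x 64
#'   channels of 3x3 convolution + 2D batch norm + ReLU + dropout, identity
#'   residual connections between the equal-channel blocks), each branch
#'   reduced to a 32-unit latent vector, fused by element-wise summation,
#'   then a 2-unit head.
#' * `"ssmfn_cnn_only"`, `"ssmfn_lstm_only"` — the single-branch ablation
#'   variants (same embedding, the surviving branch's latent feeds the head
#'   directly).
#' * `"smlp"` — the baseline: embedding, flattened to 21 x 19 = 399
#'   features, a 399-unit ReLU layer, and a 2-unit head.
#'
#' @param config A [model_config()]; defaults are the published settings.
#' @param variant One of `"ssmfn_merged"`, `"ssmfn_cnn_only"`,
#'   `"ssmfn_lstm_only"`, `"smlp"`. The shorthand `"merged"`, `"cnn_only"`,
#'   `"lstm_only"` is also accepted.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ssmfn_model`: list with `variant`, `config`,
#'   `params` (named weight matrices) and `alphabet`.
#' @export
build_model <- function(config = model_config(),
                        variant = "ssmfn_merged",
                        seed = 1L) {
  config <- as_config(config)
  variant <- normalize_variant(variant)
  params <- cpp_init(variant, unclass(config), as.integer(seed))
  structure(
    list(variant = variant, config = config, params = params,
         alphabet = residue_alphabet()),
    class = "ssmfn_model"
  )
}

normalize_variant <- function(variant) {
  v <- match.arg(variant, c(model_variants, "merged", "cnn_only", "lstm_only"))
  if (v %in% c("merged", "cnn_only", "lstm_only")) v <- paste0("ssmfn_", v)
  v
}

#' @export
print.ssmfn_model <- function(x, ...) {
  cat("<ssmfn_model> variant:", x$variant,
      " parameters:", count_parameters(x), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalar weights (batch-norm running statistics,
#' which are tracked but not optimized, are excluded). A pure function of
#' the configuration and variant: rebuilding with the same config gives the
#' same count.
#'
#' @param model An `ssmfn_model` or `ssmfn_fit`.
#' @return Integer count.
#' @examples
#' \donttest{
#' count_parameters(build_model(variant = "smlp"))  # 160841
#' }
#' @export
count_parameters <- function(model) {
  params <- model_params(model)
  keep <- !grepl("_rmean$|_rvar$", names(params))
  sum(vapply(params[keep], length, integer(1)))
}

model_params <- function(model) {
  if (inherits(model, "ssmfn_fit")) return(model$params)
  if (inherits(model, "ssmfn_model")) return(model$params)
  rlang::abort("expected an ssmfn_model or ssmfn_fit")
}

model_meta <- function(model) {
  list(variant = model$variant, config = as_config(model$config),
       alphabet = model$alphabet %||% residue_alphabet())
}

#' Forward pass: class scores for encoded windows
#'
#' Runs the network on a batch. In `"eval"` mode dropout is disabled and
#' batch normalization uses its running statistics, so the output is a
#' deterministic function of (weights, input). In `"train"` mode dropout
#' masks and batch statistics are active; a fixed `dropout_seed` makes it
#' reproducible.
#'
#' @param model An `ssmfn_model` or `ssmfn_fit`.
#' @param data Data frame with a `window` column (or an `encoded_batch`).
#' @param mode `"eval"` (default) or `"train"`.
#' @param dropout_seed Seed for the train-mode dropout masks.
#' @return Numeric matrix (n x 2) of raw class scores; normalize with
#'   exponential (softmax) weights for probabilities.
#' @export
forward <- function(model, data, mode = c("eval", "train"), dropout_seed = 1L) {
  mode <- match.arg(mode)
  meta <- model_meta(model)
  batch <- if (inherits(data, "encoded_batch")) data else encode_windows(data)
  cpp_forward(model_params(model), meta$variant, unclass(meta$config),
              batch$indices, mode == "train", as.integer(dropout_seed))
}

#' Branch latent representations (eval mode)
#'
#' @inheritParams forward
#' @return List with `scores` (n x 2), `latent_cnn`, `latent_lstm` and
#'   `fused` (each n x 32 under defaults; a missing branch contributes the
#'   zero vector).
#' @export
forward_latent <- function(model, data) {
  meta <- model_meta(model)
  batch <- if (inherits(data, "encoded_batch")) data else encode_windows(data)
  cpp_forward_latent(model_params(model), meta$variant,
                     unclass(meta$config), batch$indices)
}

#' Fuse two latent vectors by element-wise summation
#'
#' The fusion operation at the junction of the two branches: commutative,
#' length-preserving element-wise addition.
#'
#' @param a,b Numeric vectors (or matrices) of equal dimension.
#' @return `a + b`.
#' @examples
#' fuse(c(1, 2), c(3, 4))
#' @export
fuse <- function(a, b) {
  if (length(a) != length(b)) {
    rlang::abort("latent representations must have equal length to fuse",
                 class = "ssmfn_fusion_error")
  }
  a + b
}

softmax_rows <- function(scores) {
  m <- apply(scores, 1L, max)
  e <- exp(scores - m)
  e / rowSums(e)
}
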