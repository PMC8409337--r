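#' Model and optimization configuration
#'
#' Collects every architecture and training hyperparameter. The defaults are
#' the published settings of the fusion network: a 21-symbol embedding of
#' dimension 21 over 19-residue windows (flattened size 21 x 19 = 399), an
#' LSTM branch of 2 layers x 64 units with dropout 0.5, a CNN branch of 4
#' convolution blocks x 64 channels (3x3 kernels, batch-normalized, dropout
#' 0.5, identity residual connections between the equal-channel blocks), a
#' 32-unit latent layer per branch, a 2-unit output head, and Adam at
#' learning rate 0.001 for 500 epochs. Batch size (not part of the published
#' settings) defaults to 64.
#'
#' @param vocab_size Number of residue symbols (21).
#' @param window_length Window length in residues (19).
#' @param embedding_dim Embedding dimension (21, equal to `vocab_size`).
#' @param lstm_hidden Hidden units per LSTM layer (64).
#' @param lstm_layers Number of stacked LSTM layers (2).
#' @param dropout_rate Drop probability for every dropout layer (0.5).
#' @param cnn_channels Channels per convolution block (64).
#' @param cnn_blocks Number of convolution blocks (4).
#' @param conv_kernel Integer pair, convolution kernel height x width (3, 3).
#' @param latent_dim Units in each branch's latent layer (32).
#' @param output_dim Output neurons (2).
#' @param learning_rate Adam learning rate (0.001).
#' @param epochs Maximum training epochs (500).
#' @param optimizer_name Optimizer label; only `"Adam"` is implemented.
#' @param batch_size Mini-batch size (64).
#' @return A validated list of class `model_config`.
#' @examples
#' cfg <- model_config(epochs = 30)
#' cfg$lstm_hidden
#' @export
model_config <- function(vocab_size = 21L,
                         window_length = 19L,
                         embedding_dim = 21L,
                         lstm_hidden = 64L,
                         lstm_layers = 2L,
                         dropout_rate = 0.5,
                         cnn_channels = 64L,
                         cnn_blocks = 4L,
                         conv_kernel = c(3L, 3L),
                         latent_dim = 32L,
                         output_dim = 2L,
                         learning_rate = 0.001,
                         epochs = 500L,
                         optimizer_name = "Adam",
                         batch_size = 64L) {
  cfg <- list(
    vocab_size = as.integer(vocab_size),
    window_length = as.integer(window_length),
    embedding_dim = as.integer(embedding_dim),
    lstm_hidden = as.integer(lstm_hidden),
    lstm_layers = as.integer(lstm_layers),
    dropout_rate = as.numeric(dropout_rate),
    cnn_channels = as.integer(cnn_channels),
    cnn_blocks = as.integer(cnn_blocks),
    conv_kernel = as.integer(conv_kernel),
    latent_dim = as.integer(latent_dim),
    output_dim = as.integer(output_dim),
    learning_rate = as.numeric(learning_rate),
    epochs = as.integer(epochs),
    optimizer_name = as.character(optimizer_name),
    batch_size = as.integer(batch_size)
  )
  validate_config(cfg)
  structure(cfg, class = "model_config")
}

validate_config <- function(cfg) {
  counts <- c("vocab_size", "window_length", "embedding_dim", "lstm_hidden",
              "lstm_layers", "cnn_channels", "cnn_blocks", "latent_dim",
              "output_dim", "epochs", "batch_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 1) {
      rlang::abort(paste0("config field '", f, "' must be a positive count"),
                   class = "ssmfn_config_error")
    }
  }
  if (length(cfg$conv_kernel) != 2 || any(cfg$conv_kernel < 1) ||
      any(cfg$conv_kernel %% 2 == 0)) {
    rlang::abort("conv_kernel must be two odd positive integers",
                 class = "ssmfn_config_error")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    rlang::abort("dropout_rate must be in [0, 1)", class = "ssmfn_config_error")
  }
  if (cfg$learning_rate <= 0) {
    rlang::abort("learning_rate must be positive", class = "ssmfn_config_error")
  }
  if (cfg$optimizer_name != "Adam") {
    rlang::abort("only the Adam optimizer is implemented",
                 class = "ssmfn_config_error")
  }
  invisible(cfg)
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %s\n", nm, paste(x[[nm]], collapse = " x ")))
  }
  invisible(x)
}

as_config <- function(config) {
  if (is.null(config)) return(model_config())
  if (inherits(config, "model_config")) return(config)
  do.call(model_config, config)
}
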