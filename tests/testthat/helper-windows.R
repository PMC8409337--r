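# deterministic random valid windows for tests
random_windows <- function(n, seed = 1) {
  withr::with_seed(seed, {
    replicate(n, {
      left <- paste(sample(ssmfn:::standard_residues(), 9, replace = TRUE),
                    collapse = "")
      right <- paste(sample(ssmfn:::standard_residues(), 9, replace = TRUE),
                     collapse = "")
      paste0(left, "R", right)
    })
  })
}

random_labeled <- function(n_pos, n_neg, seed = 1) {
  tibble::tibble(
    window = random_windows(n_pos + n_neg, seed),
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
}

# a tiny, strongly separable toy set: positives have A-rich flanks,
# negatives G-rich, with one distinguishing residue per window
separable_toy <- function() {
  mut <- function(w, i, ch) { substr(w, i, i) <- ch; w }
  pos <- paste0(strrep("A", 9), "R", strrep("A", 9))
  neg <- paste0(strrep("G", 9), "R", strrep("G", 9))
  tibble::tibble(
    window = c(mut(pos, 1, "C"), mut(pos, 2, "D"), mut(pos, 3, "E"),
               mut(pos, 4, "F"), mut(neg, 1, "C"), mut(neg, 2, "D"),
               mut(neg, 3, "E"), mut(neg, 4, "F")),
    label = rep(c(1L, 0L), each = 4)
  )
}

# a small configuration for fast training in unit tests (architecture
# shrunk, same structure)
tiny_config <- function(...) {
  model_config(lstm_hidden = 8, cnn_channels = 8, cnn_blocks = 2,
               latent_dim = 8, batch_size = 16, ...)
}
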