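#' The 21-symbol residue alphabet
#'
#' The encoder vocabulary: the 20 standard amino-acid one-letter codes in
#' alphabetical order, followed by `"X"` for unknown or nonstandard residues
#' (selenocysteine, pyrrolysine, ambiguity codes such as `B`/`Z`/`J`, and any
#' other character found in input files map to `"X"` at read time). The
#' ordering is fixed so that integer encodings — and therefore checkpoints —
#' are portable across sessions.
#'
#' @return A character vector of 21 single-letter residue codes. Symbol `i`
#'   encodes as integer `i - 1`, so codes run from 0 (`"A"`) to 20 (`"X"`).
#' @examples
#' residue_alphabet()
#' @export
residue_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

# standard residues only (no X); the synthetic generator draws from these
standard_residues <- function() residue_alphabet()[1:20]

#' Integer codes for residue symbols
#'
#' Maps single-letter residue codes to their 0-based position in
#' [residue_alphabet()].
#'
#' @param symbols Character vector of single-letter residue codes.
#' @return Integer vector of codes in `[0, 20]`.
#' @examples
#' residue_index(c("A", "R", "X"))
#' @export
residue_index <- function(symbols) {
  idx <- match(symbols, residue_alphabet())
  if (anyNA(idx)) {
    bad <- unique(symbols[is.na(idx)])
    rlang::abort(
      paste0("symbol(s) not in the residue alphabet: ", toString(bad)),
      class = "ssmfn_encoding_error"
    )
  }
  idx - 1L
}

#' Encode peptide windows as an integer matrix
#'
#' Turns validated 19-mer windows into the integer batch consumed by the
#' embedding layer: one row per window, one column per position, entries in
#' `[0, 20]` per [residue_alphabet()]. Decoding the matrix reproduces the
#' input strings exactly.
#'
#' @param data A data frame with a `window` character column and, optionally,
#'   a binary `label` column, e.g. from [read_windows()] or
#'   [generate_windows()]. A bare character vector is also accepted.
#' @return An object of class `encoded_batch`: a list with `indices`
#'   (integer matrix, n x 19) and `labels` (integer vector or `NULL`).
#' @examples
#' w <- paste0(strrep("A", 9), "R", strrep("G", 9))
#' encode_windows(tibble::tibble(window = w, label = 1L))
#' @export
encode_windows <- function(data) {
  if (is.character(data)) data <- tibble::tibble(window = data)
  stopifnot(is.data.frame(data), "window" %in% names(data))
  windows <- data$window
  bad <- which(!vapply(windows, window_is_valid, logical(1)))
  if (length(bad) > 0) {
    rlang::abort(
      paste0("invalid window(s) at row(s): ", toString(utils::head(bad, 10))),
      class = "ssmfn_validation_error"
    )
  }
  n <- length(windows)
  chars <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
                  nrow = n, byrow = TRUE)
  indices <- matrix(residue_index(as.vector(chars)), nrow = n)
  labels <- if ("label" %in% names(data)) as.integer(data$label) else NULL
  structure(list(indices = indices, labels = labels), class = "encoded_batch")
}

#' Decode an integer batch back to residue strings
#'
#' @param batch An `encoded_batch` from [encode_windows()], or a bare integer
#'   matrix with entries in `[0, 20]`.
#' @return Character vector of windows.
#' @export
decode_windows <- function(batch) {
  indices <- if (inherits(batch, "encoded_batch")) batch$indices else batch
  stopifnot(is.matrix(indices))
  if (any(indices < 0L | indices > 20L)) {
    rlang::abort("indices out of range [0, 20]", class = "ssmfn_encoding_error")
  }
  letters21 <- residue_alphabet()
  apply(indices, 1L, function(row) paste(letters21[row + 1L], collapse = ""))
}

#' @export
print.encoded_batch <- function(x, ...) {
  cat("<encoded_batch> ", nrow(x$indices), " windows x ", ncol(x$indices),
      " positions", if (!is.null(x$labels)) paste0(", ", sum(x$labels == 1L),
      " positive / ", sum(x$labels == 0L), " negative"), "\n", sep = "")
  invisible(x)
}
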