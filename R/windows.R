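#' @importFrom rlang .data
NULL

window_length_required <- 19L
center_position <- 10L  # 1-based; the candidate methylation site

window_is_valid <- function(residues) {
  nchar(residues) == window_length_required &&
    substr(residues, center_position, center_position) == "R" &&
    all(strsplit(residues, "", fixed = TRUE)[[1]] %in% residue_alphabet())
}

#' Validate peptide windows
#'
#' Checks every window against the three invariants of the data model:
#' length exactly 19, arginine (`R`) at the center (position 10), and every
#' residue a member of [residue_alphabet()]. Verdict-returning: callers decide
#' whether a violation is an error.
#'
#' @param data A data frame with a `window` column, or a character vector.
#' @return A tibble with columns `window`, `valid` (logical) and `violations`
#'   (comma-separated names of the violated invariants, `""` when valid).
#' @examples
#' validate_windows(c(paste0(strrep("A", 9), "R", strrep("A", 9)), "TOOSHORT"))
#' @export
validate_windows <- function(data) {
  if (is.character(data)) data <- tibble::tibble(window = data)
  stopifnot(is.data.frame(data), "window" %in% names(data))
  violations <- vapply(data$window, function(w) {
    v <- character()
    if (nchar(w) != window_length_required) {
      v <- c(v, "wrong_length")
    } else if (substr(w, center_position, center_position) != "R") {
      # center check only meaningful at the right length
      v <- c(v, "center_not_arginine")
    }
    if (nchar(w) == window_length_required &&
        !all(strsplit(w, "", fixed = TRUE)[[1]] %in% residue_alphabet())) {
      v <- c(v, "residue_outside_alphabet")
    }
    paste(v, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  tibble::tibble(window = data$window, valid = violations == "",
                 violations = violations)
}

# uppercase and map any character outside the alphabet to 'X';
# returns list(windows, n_mapped)
sanitize_windows <- function(windows) {
  windows <- toupper(windows)
  chars <- strsplit(windows, "", fixed = TRUE)
  n_mapped <- 0L
  windows <- vapply(chars, function(cc) {
    out <- !(cc %in% residue_alphabet())
    if (any(out)) {
      n_mapped <<- n_mapped + sum(out)
      cc[out] <- "X"
    }
    paste(cc, collapse = "")
  }, character(1))
  list(windows = windows, n_mapped = n_mapped)
}

#' Read labeled peptide windows from a file
#'
#' Reads 19-mer windows from either a plain-text file (one window per line,
#' blank lines ignored — the layout used for per-class window files) or a
#' FASTA file (one record per window; the description line is kept as
#' `source_id`). Input is uppercased; characters outside the alphabet map to
#' `"X"` with a warning. Windows failing the length or center-arginine check
#' are a hard error naming the offending line/record.
#'
#' @param path File to read.
#' @param format `"plain"` or `"fasta"`.
#' @param label Binary label (0 or 1) attached to every window in the file.
#' @return A tibble with columns `window`, `label`, `source_id`, in input
#'   order.
#' @export
read_windows <- function(path, format = c("plain", "fasta"), label) {
  format <- match.arg(format)
  stopifnot(length(label) == 1, label %in% c(0, 1))
  if (!file.exists(path)) {
    rlang::abort(paste0("cannot read file: ", path), class = "ssmfn_io_error")
  }
  if (format == "plain") {
    lines <- readLines(path, warn = FALSE)
    keep <- nzchar(trimws(lines))
    windows <- trimws(lines[keep])
    ids <- paste0(basename(path), ":", which(keep))
    unit <- "line"
  } else {
    seqs <- Biostrings::readAAStringSet(path)
    windows <- unname(as.character(seqs))
    ids <- names(seqs)
    unit <- "record"
  }
  s <- sanitize_windows(windows)
  if (s$n_mapped > 0) {
    rlang::warn(paste0(s$n_mapped, " residue(s) outside the alphabet mapped to 'X' in ",
                       basename(path)))
  }
  verdict <- validate_windows(s$windows)
  if (any(!verdict$valid)) {
    bad <- which(!verdict$valid)
    rlang::abort(
      paste0("invalid window(s) in ", basename(path), " at ", unit, "(s) ",
             toString(utils::head(bad, 10)), ": ",
             toString(unique(verdict$violations[bad]))),
      class = "ssmfn_validation_error"
    )
  }
  tibble::tibble(window = s$windows, label = as.integer(label),
                 source_id = as.character(ids))
}

#' Write peptide windows to a file
#'
#' Inverse of [read_windows()]: `"plain"` writes one window per line,
#' `"fasta"` one record per window (using `source_id` as the header when
#' present). Round-trips are the identity on windows and order.
#'
#' @param data Data frame with a `window` column (and optionally `source_id`).
#' @param path Output file.
#' @param format `"plain"` or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_windows <- function(data, path, format = c("plain", "fasta")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(data), "window" %in% names(data))
  if (format == "plain") {
    writeLines(data$window, path)
  } else {
    ids <- if ("source_id" %in% names(data) && !anyNA(data$source_id)) {
      data$source_id
    } else {
      paste0("window_", seq_len(nrow(data)))
    }
    writeLines(paste0(">", ids, "\n", data$window), path)
  }
  invisible(path)
}

#' Assemble a labeled dataset from per-class files
#'
#' Concatenates one or more positive-class files and one or more
#' negative-class files (positives first, each class in file order) into a
#' single labeled dataset, mirroring the one-positive-file /
#' several-negative-files layout window collections are distributed in.
#' A window appearing with both labels is a contradiction and an error.
#'
#' @param positive_files,negative_files Character vectors of file paths.
#' @param split Split tag: `"train"`, `"validation"` or `"test"`.
#' @param format `"plain"` or `"fasta"`, applied to all files.
#' @return A tibble with columns `window`, `label`, `source_id`, `split`.
#'   The attribute `balanced` records whether class counts are equal (also
#'   recomputable with [is_balanced()]).
#' @export
assemble_dataset <- function(positive_files, negative_files,
                             split = c("train", "validation", "test"),
                             format = c("plain", "fasta")) {
  split <- match.arg(split)
  format <- match.arg(format)
  stopifnot(length(positive_files) >= 1, length(negative_files) >= 1)
  pos <- purrr::map(positive_files, read_windows, format = format, label = 1L)
  neg <- purrr::map(negative_files, read_windows, format = format, label = 0L)
  out <- dplyr::bind_rows(c(pos, neg))
  both <- intersect(out$window[out$label == 1L], out$window[out$label == 0L])
  if (length(both) > 0) {
    rlang::abort(
      paste0("window(s) labeled both positive and negative: ",
             toString(utils::head(both, 5))),
      class = "ssmfn_contradiction_error"
    )
  }
  out$split <- split
  attr(out, "balanced") <- sum(out$label == 1L) == sum(out$label == 0L)
  out
}

#' Is a dataset class-balanced?
#'
#' @param data Data frame with a binary `label` column.
#' @return `TRUE` iff positive and negative counts are equal.
#' @export
is_balanced <- function(data) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  sum(data$label == 1L) == sum(data$label == 0L)
}

#' Per-split class counts and imbalance ratios
#'
#' @param data Data frame with a `label` column and optionally a `split`
#'   column.
#' @return A tibble with one row per split: `n_positive`, `n_negative`,
#'   `ratio` (negative:positive) and `balanced`.
#' @export
dataset_counts <- function(data) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  if (!"split" %in% names(data)) data$split <- "all"
  data |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(
      n_positive = sum(.data$label == 1L),
      n_negative = sum(.data$label == 0L),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio = ifelse(.data$n_positive > 0, .data$n_negative / .data$n_positive, NA_real_),
      balanced = .data$n_positive == .data$n_negative
    )
}

#' Balance a dataset by seeded undersampling
#'
#' Downsamples the majority class uniformly at random, without replacement,
#' to the minority count; the minority class is kept whole and row order
#' within each class is preserved. This is how a 1,038/5,190 training split
#' becomes the 1,038/1,038 balanced split. The same seed always selects the
#' same subset.
#'
#' @param data Data frame with `window` and binary `label` columns.
#' @param seed Integer seed controlling the selection.
#' @return A tibble of the same columns with equal class counts and
#'   attribute `balanced = TRUE`.
#' @export
balance_dataset <- function(data, seed) {
  stopifnot(is.data.frame(data), all(c("window", "label") %in% names(data)))
  n_pos <- sum(data$label == 1L)
  n_neg <- sum(data$label == 0L)
  if (n_pos == n_neg) {
    rlang::inform("dataset already balanced; returning input unchanged")
    attr(data, "balanced") <- TRUE
    return(data)
  }
  minority <- if (n_pos < n_neg) 1L else 0L
  n_min <- min(n_pos, n_neg)
  maj_rows <- which(data$label != minority)
  keep_maj <- withr::with_seed(
    as.integer(seed),
    sort(sample(maj_rows, n_min, replace = FALSE))
  )
  out <- data[sort(c(which(data$label == minority), keep_maj)), , drop = FALSE]
  out <- tibble::as_tibble(out)
  attr(out, "balanced") <- TRUE
  out
}

#' Load every split listed in a dataset manifest
#'
#' A manifest is a YAML file with one stanza per split naming the positive
#' and negative window files (paths relative to the manifest), so a
#' six-file layout loads in one call:
#'
#' ```yaml
#' format: plain
#' train:
#'   positive: [pos_train.txt]
#'   negative: [neg_train_1.txt, neg_train_2.txt]
#' validation:
#'   positive: [pos_val.txt]
#'   negative: [neg_val.txt]
#' test:
#'   positive: [pos_test.txt]
#'   negative: [neg_test.txt]
#' ```
#'
#' @param path Manifest file.
#' @return A single tibble with a `split` column covering every stanza.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("manifest not found: ", path), class = "ssmfn_io_error")
  }
  m <- yaml::read_yaml(path)
  fmt <- m$format %||% "plain"
  base <- dirname(normalizePath(path))
  splits <- intersect(c("train", "validation", "test"), names(m))
  if (length(splits) == 0) {
    rlang::abort("manifest lists no train/validation/test stanza",
                 class = "ssmfn_io_error")
  }
  dplyr::bind_rows(lapply(splits, function(s) {
    assemble_dataset(
      positive_files = file.path(base, unlist(m[[s]]$positive)),
      negative_files = file.path(base, unlist(m[[s]]$negative)),
      split = s, format = fmt
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
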