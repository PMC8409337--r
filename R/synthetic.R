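#' Specification for a planted-motif synthetic benchmark
#'
#' Describes a synthetic window population that emulates the structure of a
#' real methylation-site dataset — 19-mers with a fixed center arginine,
#' disjoint positive/negative sets, a configurable negative:positive ratio,
#' and train/validation/test splits — with a tunable, position-specific
#' class signal. At each signal position, with probability `signal_strength`,
#' the background draw is replaced by a class-specific preferred residue (a
#' fixed, distinct residue per class per position, derived deterministically
#' from the seed). At `signal_strength = 0` both classes are drawn from the
#' identical background distribution, so no classifier can beat chance.
#'
#' The defaults mirror the natural (imbalanced) training profile of curated
#' methylation data: a 5:1 negative:positive ratio at the published split
#' sizes, with a strong four-position motif flanking the center.
#'
#' @param n_positive,n_negative Class totals across all splits.
#' @param signal_positions 0-based window positions carrying class signal;
#'   the center (position 9) is excluded by definition since it is `R` for
#'   both classes.
#' @param signal_strength Replacement probability in `[0, 1]`.
#' @param signal_scheme `"two_sided"` (default): each class has its own
#'   preferred residue at every signal position. `"positive_only"`: only
#'   positive windows carry planted signal and negatives are pure background
#'   draws — the structure of real methylation data, where unmethylated
#'   arginines are simply motif-free. One-sided signal makes false negatives
#'   (positives whose motif positions went unplanted) structurally more
#'   common than false positives (backgrounds mimicking the motif by
#'   chance).
#' @param positive_signal_fraction Penetrance in `[0, 1]` (default 1): the
#'   fraction of positive windows that carry planted signal at all. Real
#'   methylation positives are heterogeneous — some sites have no local
#'   motif — and a fraction below 1 reproduces that: the motif-free
#'   positives are indistinguishable from background, capping attainable
#'   sensitivity while specificity stays high.
#' @param background_frequencies Optional named numeric vector of sampling
#'   weights over the 20 standard residues; uniform when `NULL`.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @param split_fractions Positive train/validation/test fractions summing
#'   to 1.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_positive = 1038L,
                           n_negative = 5190L,
                           signal_positions = c(7L, 8L, 10L, 11L),
                           signal_strength = 0.9,
                           signal_scheme = c("two_sided", "positive_only"),
                           positive_signal_fraction = 1,
                           background_frequencies = NULL,
                           seed = 1L,
                           split_fractions = c(train = 0.70,
                                               validation = 0.15,
                                               test = 0.15)) {
  spec <- list(
    n_positive = as.integer(n_positive),
    n_negative = as.integer(n_negative),
    signal_positions = as.integer(signal_positions),
    signal_strength = as.numeric(signal_strength),
    signal_scheme = match.arg(signal_scheme),
    positive_signal_fraction = as.numeric(positive_signal_fraction),
    background_frequencies = background_frequencies,
    seed = as.integer(seed),
    split_fractions = split_fractions
  )
  problems <- character()
  if (spec$n_positive < 1 || spec$n_negative < 1) {
    problems <- c(problems, "n_positive and n_negative must be positive")
  }
  if (9L %in% spec$signal_positions) {
    problems <- c(problems, "signal_positions may not include the center (9)")
  }
  if (any(spec$signal_positions < 0L | spec$signal_positions > 18L)) {
    problems <- c(problems, "signal_positions must lie in [0, 18]")
  }
  if (spec$signal_strength < 0 || spec$signal_strength > 1) {
    problems <- c(problems, "signal_strength must be in [0, 1]")
  }
  if (spec$positive_signal_fraction < 0 || spec$positive_signal_fraction > 1) {
    problems <- c(problems, "positive_signal_fraction must be in [0, 1]")
  }
  if (length(spec$split_fractions) != 3 || any(spec$split_fractions <= 0) ||
      abs(sum(spec$split_fractions) - 1) > 1e-8) {
    problems <- c(problems, "split_fractions must be 3 positive values summing to 1")
  }
  if (!is.null(spec$background_frequencies)) {
    bf <- spec$background_frequencies
    if (is.null(names(bf)) || !all(names(bf) %in% standard_residues()) ||
        any(bf < 0) || sum(bf) <= 0) {
      problems <- c(problems,
                    "background_frequencies must be non-negative weights named by standard residues")
    }
  }
  if (length(problems) > 0) {
    rlang::abort(paste0("invalid synthetic_spec: ",
                        paste(problems, collapse = "; ")),
                 class = "ssmfn_spec_error")
  }
  names(spec$split_fractions) <- c("train", "validation", "test")
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec> ", x$n_positive, " positive / ", x$n_negative,
      " negative; signal ", x$signal_strength, " at position(s) ",
      toString(x$signal_positions), "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# class-specific preferred residues at each signal position, drawn
# deterministically from the spec seed; distinct per class per position
signal_residues <- function(spec) {
  withr::with_seed(spec$seed, {
    t(vapply(spec$signal_positions,
             function(p) sample(standard_residues(), 2L),
             character(2)))
  })  # matrix: rows = signal positions, col 1 = positive, col 2 = negative
}

# sample n background windows (center fixed to R) as an n x 19 character matrix
sample_background <- function(n, spec) {
  residues <- standard_residues()
  prob <- NULL
  if (!is.null(spec$background_frequencies)) {
    prob <- spec$background_frequencies[residues]
    prob[is.na(prob)] <- 0
    prob <- prob / sum(prob)
  }
  m <- matrix(sample(residues, n * 19L, replace = TRUE, prob = prob),
              nrow = n, ncol = 19L)
  m[, 10L] <- "R"
  m
}

#' Plant position-specific class signal into background windows
#'
#' At each signal position of each window, with probability
#' `spec$signal_strength`, replaces the background residue with the
#' class-specific preferred residue for that position. Consumes the current
#' R random stream (callers seed it; [generate_windows()] does so from
#' `spec$seed`).
#'
#' @param windows Character vector of valid 19-mer windows (background draws).
#' @param class_label 0 or 1; selects which class's preferred residues are
#'   planted.
#' @param spec A [synthetic_spec()].
#' @return Character vector of windows with signal planted.
#' @export
plant_signal <- function(windows, class_label, spec) {
  stopifnot(inherits(spec, "synthetic_spec"), class_label %in% c(0, 1))
  if (spec$signal_strength == 0 || length(spec$signal_positions) == 0 ||
      (spec$signal_scheme == "positive_only" && class_label == 0)) {
    return(windows)
  }
  prefer <- signal_residues(spec)[, if (class_label == 1) 1L else 2L]
  n <- length(windows)
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  # incomplete penetrance: motif-free positives stay pure background
  carrier <- if (class_label == 1 && spec$positive_signal_fraction < 1) {
    stats::runif(n) < spec$positive_signal_fraction
  } else {
    rep(TRUE, n)
  }
  for (k in seq_along(spec$signal_positions)) {
    col <- spec$signal_positions[k] + 1L
    hit <- carrier & (stats::runif(n) < spec$signal_strength)
    m[hit, col] <- prefer[k]
  }
  apply(m, 1L, paste, collapse = "")
}

# largest-remainder apportionment of n into the three split fractions
split_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Generate a labeled synthetic window dataset
#'
#' Draws `n_positive + n_negative` valid 19-mer windows (center `R`, standard
#' residues only) with class signal planted per the spec, splits each class
#' across train/validation/test by largest-remainder apportionment of the
#' split fractions, and guarantees all windows are distinct (collisions are
#' re-drawn), so splits and classes are disjoint by construction. The same
#' seed always yields byte-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `window`, `label`, `source_id`, `split`.
#' @examples
#' d <- generate_windows(synthetic_spec(n_positive = 20, n_negative = 40, seed = 7))
#' dataset_counts(d)
#' @export
generate_windows <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    draw_class <- function(n, label) {
      w <- sample_background(n, spec)
      w <- apply(w, 1L, paste, collapse = "")
      plant_signal(w, label, spec)
    }
    pos <- draw_class(spec$n_positive, 1L)
    neg <- draw_class(spec$n_negative, 0L)
    all_w <- c(pos, neg)
    labs <- rep(c(1L, 0L), c(spec$n_positive, spec$n_negative))
    # re-draw collisions until all windows are pairwise distinct
    for (i in 1:100) {
      dup <- which(duplicated(all_w))
      if (length(dup) == 0) break
      all_w[dup] <- plant_signal(
        apply(sample_background(length(dup), spec), 1L, paste, collapse = ""),
        1L, spec
      )
      # redraw negatives with negative-class signal
      dn <- dup[labs[dup] == 0L]
      if (length(dn) > 0) {
        all_w[dn] <- plant_signal(
          apply(sample_background(length(dn), spec), 1L, paste, collapse = ""),
          0L, spec
        )
      }
    }
    split_of <- function(n) {
      counts <- split_counts(n, spec$split_fractions)
      rep(names(counts), counts)
    }
    tibble::tibble(
      window = all_w,
      label = labs,
      source_id = paste0("synthetic_", ifelse(labs == 1L, "pos", "neg"), "_",
                         c(seq_len(spec$n_positive), seq_len(spec$n_negative))),
      split = c(split_of(spec$n_positive), split_of(spec$n_negative))
    )
  })
}

#' Negative:positive ratio per split of a spec
#'
#' Reports the class counts and negative:positive ratio each split of the
#' spec will contain, e.g. the natural 5:1 training profile
#' (5,190 / 1,038 = 5.0) or a balanced 1:1 profile.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with `split`, `n_positive`, `n_negative`, `ratio`.
#' @export
imbalance_profile <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$n_positive == 0) {
    rlang::abort("ratio undefined with zero positives", class = "ssmfn_spec_error")
  }
  pos <- split_counts(spec$n_positive, spec$split_fractions)
  neg <- split_counts(spec$n_negative, spec$split_fractions)
  tibble::tibble(
    split = names(pos),
    n_positive = as.integer(pos),
    n_negative = as.integer(neg),
    ratio = as.numeric(neg) / as.numeric(pos)
  )
}

#' Write a dataset in the six-file plain-text layout
#'
#' Writes one positive and `n_negative_files` negative training files plus
#' one positive/negative file each for validation and test, together with a
#' YAML manifest consumable by [read_manifest()] — the distribution layout
#' of curated window collections.
#'
#' @param data Tibble with `window`, `label`, `split` columns covering the
#'   three splits.
#' @param dir Output directory (created if needed).
#' @param n_negative_files Number of files the training negatives are split
#'   across (round-robin), default 5.
#' @return Path of the written manifest, invisibly.
#' @export
write_supplementary_layout <- function(data, dir, n_negative_files = 5L) {
  stopifnot(all(c("window", "label", "split") %in% names(data)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sel <- function(s, l) data$window[data$split == s & data$label == l]
  manifest <- list(format = "plain")
  put <- function(windows, file) {
    writeLines(windows, file.path(dir, file))
    file
  }
  neg_train <- sel("train", 0L)
  grp <- rep_len(seq_len(n_negative_files), length(neg_train))
  manifest$train <- list(
    positive = list(put(sel("train", 1L), "train_positive.txt")),
    negative = lapply(seq_len(n_negative_files), function(i) {
      put(neg_train[grp == i], sprintf("train_negative_%d.txt", i))
    })
  )
  manifest$validation <- list(
    positive = list(put(sel("validation", 1L), "validation_positive.txt")),
    negative = list(put(sel("validation", 0L), "validation_negative.txt"))
  )
  manifest$test <- list(
    positive = list(put(sel("test", 1L), "test_positive.txt")),
    negative = list(put(sel("test", 0L), "test_negative.txt"))
  )
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
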