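test_that("the residue alphabet is 21 distinct uppercase letters with X last", {
  ab <- residue_alphabet()
  expect_length(ab, 21)
  expect_false(any(duplicated(ab)))
  expect_true(all(ab == toupper(ab)))
  expect_identical(ab[21], "X")
  expect_setequal(ab[1:20],
                  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                    "K", "M", "F", "P", "S", "T", "W", "Y", "V"))
  expect_identical(residue_index(ab), 0:20)
})

test_that("window validation enforces length, center arginine and alphabet", {
  good <- paste0("VESAAAAVT", "R", "LHAAAAHMN")  # 19-mer, R at position 10
  v <- validate_windows(c(good,
                          substr(good, 1, 18),
                          sub("^(.{9})R", "\\1K", good),
                          sub("A", "1", good)))
  expect_true(v$valid[1])
  expect_match(v$violations[2], "wrong_length")
  expect_match(v$violations[3], "center_not_arginine")
  expect_match(v$violations[4], "residue_outside_alphabet")
})

test_that("plain and FASTA round-trips are the identity on windows and order", {
  d <- random_labeled(5, 0, seed = 3)
  for (fmt in c("plain", "fasta")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_windows(d, path, format = fmt)
    back <- read_windows(path, format = fmt, label = 1L)
    expect_identical(back$window, d$window)
  }
})

test_that("reading uppercases input and maps unknown residues to X with a warning", {
  path <- withr::local_tempfile()
  w <- random_windows(2, seed = 4)
  writeLines(c(tolower(w[1]), sub("^.", "B", w[2])), path)
  expect_warning(out <- read_windows(path, "plain", label = 0L),
                 "mapped to 'X'")
  expect_identical(out$window[1], w[1])
  expect_identical(substr(out$window[2], 1, 1), "X")
})

test_that("invalid windows in a file are rejected naming the position", {
  path <- withr::local_tempfile()
  writeLines(c(random_windows(1, seed = 5), "SHRT"), path)
  suppressWarnings(
    expect_error(read_windows(path, "plain", label = 1L),
                 class = "ssmfn_validation_error")
  )
})

test_that("assemble_dataset concatenates per-class files and flags balance", {
  dir <- withr::local_tempdir()
  pos <- random_windows(6, seed = 10)
  negs <- random_windows(12, seed = 11)
  writeLines(pos, file.path(dir, "pos.txt"))
  writeLines(negs[1:6], file.path(dir, "neg1.txt"))
  writeLines(negs[7:12], file.path(dir, "neg2.txt"))
  d <- assemble_dataset(file.path(dir, "pos.txt"),
                        file.path(dir, c("neg1.txt", "neg2.txt")),
                        split = "train")
  expect_equal(nrow(d), 18)
  expect_identical(d$window[1:6], pos)         # positives first, file order
  expect_identical(d$window[7:18], negs)
  expect_false(attr(d, "balanced"))
  expect_false(is_balanced(d))

  b <- assemble_dataset(file.path(dir, "pos.txt"), file.path(dir, "neg1.txt"),
                        split = "test")
  expect_true(attr(b, "balanced"))
})

test_that("a window labeled both positive and negative is a contradiction", {
  dir <- withr::local_tempdir()
  w <- random_windows(3, seed = 12)
  writeLines(w, file.path(dir, "pos.txt"))
  writeLines(w[2], file.path(dir, "neg.txt"))
  expect_error(
    assemble_dataset(file.path(dir, "pos.txt"), file.path(dir, "neg.txt"),
                     split = "train"),
    class = "ssmfn_contradiction_error"
  )
})

test_that("balancing undersamples the majority to the minority count", {
  d <- random_labeled(40, 200, seed = 20)
  b <- balance_dataset(d, seed = 1)
  expect_equal(sum(b$label == 1L), 40)
  expect_equal(sum(b$label == 0L), 40)
  expect_true(is_balanced(b))
  # minority class preserved exactly as a set, majority a subset
  expect_setequal(b$window[b$label == 1L], d$window[d$label == 1L])
  expect_true(all(b$window[b$label == 0L] %in% d$window[d$label == 0L]))
  expect_false(any(duplicated(b$window)))
})

test_that("balancing is deterministic in the seed and a no-op when balanced", {
  d <- random_labeled(30, 90, seed = 21)
  expect_identical(balance_dataset(d, seed = 7), balance_dataset(d, seed = 7))
  expect_false(identical(balance_dataset(d, seed = 7)$window,
                         balance_dataset(d, seed = 8)$window))
  eq <- random_labeled(10, 10, seed = 22)
  expect_message(out <- balance_dataset(eq, seed = 1), "already balanced")
  expect_identical(out$window, eq$window)
})

test_that("encoding is shape (n x 19), range [0, 20], and round-trips", {
  d <- random_labeled(7, 3, seed = 30)
  enc <- encode_windows(d)
  expect_identical(dim(enc$indices), c(10L, 19L))
  expect_true(all(enc$indices >= 0 & enc$indices <= 20))
  expect_identical(decode_windows(enc), d$window)
  expect_identical(enc$labels, d$label)
  expect_error(encode_windows(tibble::tibble(window = strrep("A", 19))),
               class = "ssmfn_validation_error")
})

test_that("a manifest loads the full six-file layout with per-split counts", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_positive = 30, n_negative = 60, seed = 33,
                         signal_strength = 0)
  d <- generate_windows(spec)
  manifest <- write_supplementary_layout(d, dir)
  back <- read_manifest(manifest)
  expect_setequal(unique(back$split), c("train", "validation", "test"))
  counts <- dataset_counts(back)
  expect_identical(counts[order(counts$split), c("n_positive", "n_negative")],
                   dataset_counts(d)[order(dataset_counts(d)$split),
                                     c("n_positive", "n_negative")])
  expect_setequal(back$window, d$window)
})
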