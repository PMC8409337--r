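test_that("generated windows all pass validation with center arginine", {
  spec <- synthetic_spec(n_positive = 60, n_negative = 120, seed = 70)
  d <- generate_windows(spec)
  expect_equal(nrow(d), 180)
  expect_true(all(validate_windows(d)$valid))
  expect_true(all(substr(d$window, 10, 10) == "R"))
  # no X generated by default; all windows distinct; splits complete
  expect_false(any(grepl("X", d$window, fixed = TRUE)))
  expect_false(any(duplicated(d$window)))
  expect_setequal(unique(d$split), c("train", "validation", "test"))
})

test_that("generation is byte-identical for the same seed", {
  spec <- synthetic_spec(n_positive = 40, n_negative = 40, seed = 42)
  expect_identical(generate_windows(spec), generate_windows(spec))
  spec2 <- synthetic_spec(n_positive = 40, n_negative = 40, seed = 43)
  expect_false(identical(generate_windows(spec)$window,
                         generate_windows(spec2)$window))
})

test_that("invalid specs are rejected with the violated fields listed", {
  expect_error(synthetic_spec(signal_positions = c(9L)), "center")
  expect_error(synthetic_spec(signal_strength = 1.5), "signal_strength")
  expect_error(synthetic_spec(split_fractions = c(0.5, 0.5, 0.5)),
               "split_fractions")
  expect_error(synthetic_spec(n_positive = 0), "positive")
  expect_error(synthetic_spec(background_frequencies = c(Z = 1)),
               "background_frequencies")
})

test_that("imbalance ratios reproduce the natural 5:1 profile and scale", {
  spec <- synthetic_spec(n_positive = 1038, n_negative = 5190, seed = 1)
  prof <- imbalance_profile(spec)
  expect_equal(sum(prof$n_positive), 1038)
  expect_equal(sum(prof$n_negative), 5190)
  expect_equal(sum(prof$n_negative) / sum(prof$n_positive), 5.0)
  balanced <- imbalance_profile(synthetic_spec(n_positive = 200,
                                               n_negative = 200, seed = 1))
  expect_true(all(balanced$ratio == 1))
  # ratio homogeneous under scaling both counts
  x3 <- imbalance_profile(synthetic_spec(n_positive = 3 * 1038,
                                         n_negative = 3 * 5190, seed = 1))
  expect_equal(sum(x3$n_negative) / sum(x3$n_positive), 5.0)
})

test_that("plant_signal limits: strength 1 is deterministic, strength 0 a no-op", {
  spec1 <- synthetic_spec(n_positive = 10, n_negative = 10, seed = 5,
                          signal_strength = 1)
  prefer <- ssmfn:::signal_residues(spec1)
  w <- random_windows(20, seed = 71)
  planted <- withr::with_seed(1, plant_signal(w, 1L, spec1))
  for (k in seq_along(spec1$signal_positions)) {
    pos <- spec1$signal_positions[k] + 1L
    expect_true(all(substr(planted, pos, pos) == prefer[k, 1]))
  }
  spec0 <- synthetic_spec(n_positive = 10, n_negative = 10, seed = 5,
                          signal_strength = 0)
  expect_identical(withr::with_seed(1, plant_signal(w, 1L, spec0)), w)
})

test_that("empirical replacement frequency matches the configured strength", {
  strength <- 0.3
  spec <- synthetic_spec(n_positive = 10, n_negative = 10, seed = 8,
                         signal_positions = 0L, signal_strength = strength)
  prefer <- ssmfn:::signal_residues(spec)[1, 1]
  n <- 10000
  base <- strrep("A", 9)
  w <- rep(paste0(base, "R", base), n)   # position 0 carries 'A' initially
  planted <- withr::with_seed(2, plant_signal(w, 1L, spec))
  hits <- mean(substr(planted, 1, 1) == prefer)
  # the preferred residue can coincide with the background 'A'
  expected <- if (prefer == "A") 1 else strength
  se <- sqrt(strength * (1 - strength) / n)
  expect_lt(abs(hits - expected), 3 * se + 1e-9)
})

test_that("one-sided signal and incomplete penetrance behave as documented", {
  base <- strrep("A", 9)
  w <- rep(paste0(base, "R", base), 4000)
  sp <- synthetic_spec(n_positive = 10, n_negative = 10, seed = 15,
                       signal_positions = 0L, signal_strength = 1,
                       signal_scheme = "positive_only",
                       positive_signal_fraction = 0.5)
  # negatives are never modified under the one-sided scheme
  expect_identical(withr::with_seed(3, plant_signal(w, 0L, sp)), w)
  # positives carry the (deterministic) signal in about half the windows
  prefer <- ssmfn:::signal_residues(sp)[1, 1]
  planted <- withr::with_seed(3, plant_signal(w, 1L, sp))
  frac <- mean(substr(planted, 1, 1) == prefer)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / length(w)))
  expect_error(synthetic_spec(positive_signal_fraction = 1.2),
               "positive_signal_fraction")
})

test_that("class-preferred residues are distinct per class and seed-stable", {
  spec <- synthetic_spec(n_positive = 5, n_negative = 5, seed = 12)
  r1 <- ssmfn:::signal_residues(spec)
  r2 <- ssmfn:::signal_residues(spec)
  expect_identical(r1, r2)
  expect_true(all(r1[, 1] != r1[, 2]))
})

test_that("the written six-file layout loads back with identical content", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_positive = 50, n_negative = 250, seed = 77)
  d <- generate_windows(spec)
  manifest <- write_supplementary_layout(d, dir)
  expect_length(yaml::read_yaml(manifest)$train$negative, 5)
  back <- read_manifest(manifest)
  for (s in c("train", "validation", "test")) {
    expect_setequal(back$window[back$split == s & back$label == 1],
                    d$window[d$split == s & d$label == 1])
    expect_setequal(back$window[back$split == s & back$label == 0],
                    d$window[d$split == s & d$label == 0])
  }
})

test_that("largest-remainder split counts are exact and exhaustive", {
  counts <- ssmfn:::split_counts(101L, c(train = 0.7, validation = 0.15,
                                         test = 0.15))
  expect_equal(sum(counts), 101L)
  expect_true(all(counts >= 15L))
  even <- ssmfn:::split_counts(100L, c(train = 0.7, validation = 0.15,
                                       test = 0.15))
  expect_identical(as.integer(even), c(70L, 15L, 15L))
})
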