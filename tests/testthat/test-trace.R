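# Color-trace construction, frame-rate thinning, and offline alignment.

test_that("build_trace is zero for a constant video and matches a brute-force Delta E", {
  colors <- matrix(rep(c(100, 50, 25), each = 10), ncol = 3)
  tr <- build_trace(frames_from_colors(colors, fps = 2))
  expect_true(all(tr$delta_e == 0))
  expect_equal(nrow(tr), 10)

  # two-frame video: trace is (0, d) with d the Lab distance
  two <- frames_from_colors(rbind(c(10, 10, 10), c(200, 30, 90)), fps = 1)
  tr2 <- build_trace(two)
  d <- delta_e_1976(rgb_to_lab(c(10, 10, 10)), rgb_to_lab(c(200, 30, 90)))
  expect_equal(tr2$delta_e, c(0, d))

  # exponential transition: per-frame brute-force evaluation
  t <- seq(0, 60, by = 2)
  f <- 1 - exp(-0.08 * t)
  colors <- cbind(20 + f * 200, 240 - f * 180, 60 + f * 10)
  tr3 <- build_trace(frames_from_colors(colors, fps = 0.5))
  brute <- vapply(seq_along(t), function(i) {
    l1 <- as.numeric(rgb_to_lab(colors[1, ]))
    li <- as.numeric(rgb_to_lab(colors[i, ]))
    sqrt(sum((li - l1)^2))
  }, numeric(1))
  expect_equal(tr3$delta_e, brute, tolerance = 1e-12)

  expect_error(build_trace(frames_from_colors(colors[1, , drop = FALSE])), "at least 2")
})

test_that("the reference sample maps to Delta E 0 and is user-overridable", {
  colors <- cbind(seq(0, 200, length.out = 21), 50, 80)
  frames <- frames_from_colors(colors, fps = 1)
  tr <- build_trace(frames, reference_index = 5L)
  expect_equal(reference_index(tr), 5L)
  expect_equal(tr$delta_e[6], 0)
  expect_true(all(tr$delta_e >= 0))
  expect_error(build_trace(frames, reference_index = 21L), "reference_index")
})

test_that("delta_e is invariant to a constant time offset", {
  colors <- cbind(seq(10, 240, length.out = 15), 120, 60)
  f1 <- frames_from_colors(colors, fps = 1)
  shifted <- frame_seq(lapply(f1, function(fr) new_frame(fr$pixels, fr$t + 500, fr$index)))
  expect_equal(build_trace(f1)$delta_e, build_trace(shifted)$delta_e)
})

test_that("resample_trace keeps every k-th sample and re-anchors the reference", {
  colors <- cbind(seq(0, 240, length.out = 100), 100, 100)
  tr <- build_trace(frames_from_colors(colors, fps = 10))
  expect_equal(resample_trace(tr, 1), tr, ignore_attr = TRUE)
  thin <- resample_trace(tr, 10)
  expect_equal(nrow(thin), 10)
  expect_equal(thin$frame_index, seq(0, 90, by = 10))
  expect_equal(thin$delta_e[1], 0)

  # reference not retained -> first retained sample becomes the anchor
  tr5 <- build_trace(frames_from_colors(colors, fps = 10), reference_index = 5L)
  thin5 <- resample_trace(tr5, 10)
  expect_equal(thin5$delta_e[1], 0)

  expect_error(resample_trace(tr, 0), "positive")
})

test_that("thinning removes transients shorter than the retained spacing", {
  colors <- matrix(rep(c(100, 100, 100), each = 100), ncol = 3)
  colors[53:54, ] <- matrix(rep(c(250, 20, 20), each = 2), ncol = 3)  # 2-sample spike
  tr <- build_trace(frames_from_colors(colors, fps = 10))
  expect_gt(max(tr$delta_e), 50)
  thin <- resample_trace(tr, 10)   # keeps 0, 10, ..., 90: spike at 52-53 missed
  expect_equal(max(thin$delta_e), 0)
})

test_that("thinning shifts a smooth plateau estimate by at most one retained spacing", {
  t <- seq(0, 300, by = 0.5)
  de <- 50 * (1 - exp(-0.05 * t))
  tr <- synthetic_de_trace(t, de)
  full <- detect_plateau(tr, window = 4, eps = 0.05, min_excursion = 5)
  thin <- synthetic_de_trace(t[seq(1, length(t), by = 4)], de[seq(1, length(t), by = 4)])
  thinned <- detect_plateau(thin, window = 4, eps = 0.05, min_excursion = 5)
  expect_lt(abs(thinned - full), 4 * 0.5 + 2 * 4 * 2)  # one retained spacing + rate-window blur
})

test_that("align_offline pairs by nearest time with ties to the earlier sample", {
  colors <- cbind(seq(0, 200, length.out = 11), 50, 50)
  tr <- build_trace(frames_from_colors(colors, fps = 1))   # t = 0..10 s

  exact <- align_offline(tr, tibble::tibble(t = c(0, 5, 10), value = 1:3))
  expect_equal(exact$t_trace, c(0, 5, 10))
  expect_equal(exact$delta_e, tr$delta_e[c(1, 6, 11)])

  near <- align_offline(tr, tibble::tibble(t = 3.4, value = 1))
  expect_equal(near$t_trace, 3)
  tie <- align_offline(tr, tibble::tibble(t = 3.5, value = 1))
  expect_equal(tie$t_trace, 3)                              # tie -> earlier

  expect_warning(
    out <- align_offline(tr, tibble::tibble(t = c(5, 99), value = 1:2)),
    "dropped")
  expect_equal(nrow(out), 1)
})

test_that("a monotone conversion correlates linearly with its own delta_e pairing", {
  t <- seq(0, 200, by = 1)
  conv <- 1 - exp(-0.03 * t)
  de <- 60 * conv
  tr <- synthetic_de_trace(t, de)
  off <- tibble::tibble(t = seq(5, 195, by = 10), value = 1 - exp(-0.03 * seq(5, 195, by = 10)))
  paired <- align_offline(tr, off)
  r2 <- stats::cor(paired$delta_e, paired$value)^2
  expect_gt(r2, 0.95)
})

test_that("traces export to tidy CSV with the documented schema", {
  colors <- cbind(seq(0, 100, length.out = 5), 50, 50)
  tr <- build_trace(frames_from_colors(colors, fps = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("frame_index", "t_seconds", "roi", "R", "G", "B",
                 "H", "S", "V", "L", "a", "b", "delta_e", "rgb_sum"))
  expect_equal(back$delta_e, signif(tr$delta_e, 6))
})

test_that("pixel_delta_e_trace distinguishes rearrangement from mean-color change", {
  # left/right halves swap: mean color constant, pixels change
  px1 <- array(0, dim = c(4, 4, 3)); px1[, 1:2, ] <- 200
  px2 <- array(0, dim = c(4, 4, 3)); px2[, 3:4, ] <- 200
  frames <- frame_seq(list(new_frame(px1, 0, 0L), new_frame(px2, 1, 1L)))
  mean_tr <- build_trace(frames)
  expect_equal(mean_tr$delta_e[2], 0, tolerance = 1e-9)
  px_tr <- pixel_delta_e_trace(frames)
  expect_gt(px_tr$mean_delta_e[2], 50)
  expect_equal(px_tr$mean_delta_e[1], 0)
})
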