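# Binarization, the Contact interfacial count, and GLCM texture features.

test_that("binarize applies the inclusive RGB window per pixel", {
  inr <- uniform_frame(c(100, 100, 100), 3, 3)
  expect_true(all(binarize(inr, c(50, 50, 50), c(150, 150, 150))))
  expect_false(any(binarize(inr, c(0, 0, 0), c(99, 255, 255))))

  set.seed(31)
  fr <- new_frame(array(runif(6 * 7 * 3, 0, 255), dim = c(6, 7, 3)), t = 0)
  lo <- c(40, 60, 20); hi <- c(200, 220, 180)
  mask <- binarize(fr, lo, hi)
  for (i in 1:6) for (j in 1:7) {
    px <- fr$pixels[i, j, ]
    expect_equal(mask[i, j], all(px >= lo & px <= hi))
  }
  expect_error(binarize(fr, c(10, 10, 10), c(5, 255, 255)), "<=")
})

test_that("contact counts differing 4-neighbor pairs and vanishes on uniform masks", {
  expect_equal(contact(matrix(TRUE, 5, 5)), 0)
  expect_equal(contact(matrix(FALSE, 5, 5)), 0)
  expect_equal(contact(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)), 4)
  for (n in c(3, 6, 9)) {
    half <- cbind(matrix(FALSE, n, n / 3 * 2), matrix(TRUE, n, n - n / 3 * 2))
    expect_equal(contact(half), n)
  }
})

test_that("contact equals the brute-force count on random masks and is complement-invariant", {
  set.seed(37)
  for (i in 1:200) {
    m <- random_mask(16, 16)
    expect_identical(contact(m), brute_contact(m))
    expect_identical(contact(!m), contact(m))
  }
})

test_that("normalized contact divides by the number of adjacent pairs", {
  m <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  cn <- contact(m, normalize = TRUE)
  expect_equal(unname(cn["contact"]), 4)
  expect_equal(unname(cn["contact_norm"]), 1)   # all 4 pairs differ
})

test_that("quantize_gray bins luma into equal-width levels", {
  expect_true(all(quantize_gray(uniform_frame(c(0, 0, 0), 3, 3), 5) == 0))
  expect_true(all(quantize_gray(uniform_frame(c(255, 255, 255), 3, 3), 5) == 4))
  g <- seq(0, 255, length.out = 256)
  px <- array(rep(g, 3), dim = c(1, 256, 3))
  lev <- quantize_gray(new_frame(px, t = 0), 2)
  expect_true(all(lev[1, 1:128] == 0))         # below the 127.5 edge
  expect_true(all(lev[1, 129:256] == 1))
  expect_error(quantize_gray(uniform_frame(c(1, 1, 1)), 1), ">= 2")
})

test_that("compute_glcm matches hand enumeration on canonical patterns", {
  uni <- matrix(2L, 4, 4)
  g <- compute_glcm(uni, levels = 4, offset = c(0, 1))
  expect_equal(sum(g$probabilities > 0), 1)
  expect_equal(g$probabilities[3, 3], 1)

  checker <- outer(0:3, 0:3, function(i, j) (i + j) %% 2)
  gc <- compute_glcm(checker, levels = 2, offset = c(0, 1), symmetric = TRUE)
  expect_equal(gc$probabilities[1, 2], 0.5)
  expect_equal(gc$probabilities[2, 1], 0.5)
  expect_equal(gc$probabilities[1, 1] + gc$probabilities[2, 2], 0)

  expect_error(compute_glcm(matrix(c(0.5, 1, 1, 0), 2), 2, c(0, 1)), "quantize")
  expect_error(compute_glcm(checker, 2, c(0, 0)), "nonzero")
})

test_that("GLCM counts equal a brute-force double loop for the standard offsets", {
  set.seed(43)
  for (rep in 1:50) {
    G <- sample(4:8, 1)
    H <- sample(4:8, 1); W <- sample(4:8, 1)
    img <- matrix(sample(0:(G - 1), H * W, replace = TRUE), H, W)
    for (off in list(c(0, 1), c(1, 0), c(1, 1))) {
      for (sym in c(TRUE, FALSE)) {
        got <- compute_glcm(img, G, off, symmetric = sym)
        expect_true(all(got$counts == brute_glcm_counts(img, G, off, sym)))
        expect_equal(sum(got$counts),
                     sum(brute_glcm_counts(img, G, off, FALSE)) * (1 + sym))
        expect_equal(sum(got$probabilities), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("glcm_features match closed forms on degenerate and checkerboard inputs", {
  f_uni <- glcm_features(compute_glcm(matrix(0L, 5, 5), 4, c(1, 1)))
  expect_equal(unlist(f_uni), c(asm = 1, entropy = 0, homogeneity = 1))

  # uniform white and uniform black give identical feature triples
  f_white <- glcm_features(compute_glcm(quantize_gray(uniform_frame(c(255, 255, 255), 6, 6), 16), 16, c(1, 1)))
  f_black <- glcm_features(compute_glcm(quantize_gray(uniform_frame(c(0, 0, 0), 6, 6), 16), 16, c(1, 1)))
  expect_equal(f_white, f_black)
  expect_equal(unlist(f_white), c(asm = 1, entropy = 0, homogeneity = 1))

  checker <- outer(0:5, 0:5, function(i, j) (i + j) %% 2)
  f_ck <- glcm_features(compute_glcm(checker, 2, c(0, 1)))
  expect_equal(f_ck$asm, 0.5)
  expect_equal(f_ck$entropy, 1)         # two equal cells -> 1 bit
  expect_equal(f_ck$homogeneity, 0.5)   # all mass at |i - j| = 1
})

test_that("features are invariant under gray-level reversal and respect their bounds", {
  set.seed(47)
  for (rep in 1:20) {
    G <- 6
    img <- matrix(sample(0:(G - 1), 49, replace = TRUE), 7, 7)
    f1 <- glcm_features(compute_glcm(img, G, c(1, 1)))
    f2 <- glcm_features(compute_glcm(G - 1L - img, G, c(1, 1)))
    expect_equal(f1, f2)
    expect_true(f1$asm > 0 && f1$asm <= 1)
    expect_true(f1$homogeneity > 0 && f1$homogeneity <= 1)
    expect_lte(f1$entropy, 2 * log2(G))
  }
})

test_that("the inverse-difference-moment homogeneity option down-weights distant pairs more", {
  checker <- outer(0:5, 0:5, function(i, j) 3L * ((i + j) %% 2))
  g <- compute_glcm(checker, 4, c(0, 1))
  h_id <- glcm_features(g, form = "inverse_difference")$homogeneity
  h_idm <- glcm_features(g, form = "idm")$homogeneity
  expect_equal(h_id, 1 / (1 + 3))
  expect_equal(h_idm, 1 / (1 + 9))
})

test_that("texture_trace is flat zero for a constant-color video", {
  frames <- frames_from_colors(matrix(rep(c(80, 90, 100), each = 6), ncol = 3), fps = 1, H = 6, W = 6)
  tt <- texture_trace(frames, rgb_lo = c(0, 0, 0), rgb_hi = c(255, 255, 255), levels = 8)
  expect_true(all(tt$contact == 0))
  expect_true(all(tt$entropy == 0))
  expect_true(all(tt$asm == 1))
})
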