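# Synthetic video generators: determinism, kinetic ground truth, and the
# physical invariants of the mixing simulation.

test_that("gen_reaction starts at color_start and saturates at color_end", {
  sp <- reaction_spec(c(10, 200, 30), c(220, 40, 180), k = 0.5,
                      duration = 60, fps = 1, noise_sigma = 0,
                      width = 4, height = 4, seed = 1)
  g <- gen_reaction(sp)
  first <- spatial_mean(g$frames[[1]], roi_full(c(4, 4)))
  expect_equal(unname(first), c(10, 200, 30), tolerance = 1e-9)
  last <- spatial_mean(g$frames[[length(g$frames)]], roi_full(c(4, 4)))
  expect_equal(unname(last), c(220, 40, 180), tolerance = 0.1)  # k t = 30
})

test_that("generators are bit-reproducible for a fixed spec and seed", {
  sp <- reaction_spec(c(0, 0, 0), c(255, 255, 255), k = 0.1, duration = 10,
                      fps = 2, noise_sigma = 3, width = 6, height = 6, seed = 42)
  g1 <- gen_reaction(sp); g2 <- gen_reaction(sp)
  expect_identical(lapply(g1$frames, `[[`, "pixels"),
                   lapply(g2$frames, `[[`, "pixels"))
  g3 <- gen_reaction(reaction_spec(c(0, 0, 0), c(255, 255, 255), k = 0.1,
                                   duration = 10, fps = 2, noise_sigma = 3,
                                   width = 6, height = 6, seed = 43))
  expect_false(identical(g1$frames[[2]]$pixels, g3$frames[[2]]$pixels))
})

test_that("generator seeds never leak into the caller's RNG stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_reaction(reaction_spec(
    c(0, 0, 0), c(255, 0, 0), k = 1, duration = 2, fps = 1,
    noise_sigma = 2, width = 3, height = 3, seed = 7)))
  expect_identical(runif(3), before)
})

test_that("the pipeline Delta E of a noiseless fixture matches the analytic curve", {
  sp <- reaction_spec(c(90, 30, 140), c(240, 235, 90), k = 0.05,
                      duration = 200, fps = 1, noise_sigma = 0, seed = 2)
  g <- gen_reaction(sp)
  tr <- build_trace(g$frames)
  expect_equal(tr$delta_e, g$truth$curve$delta_e, tolerance = 1e-6)
  expect_equal(g$truth$curve$delta_e,
               g$truth$delta_e_endpoints * g$truth$curve$conversion,
               tolerance = 1e-9)
})

test_that("fitting a noiseless fixture recovers the specified k to 1e-6 relative", {
  for (model in c("first_order", "second_order")) {
    sp <- reaction_spec(c(90, 30, 140), c(240, 235, 90), model = model,
                        k = 0.05, duration = 300, fps = 2, noise_sigma = 0, seed = 3)
    tr <- build_trace(gen_reaction(sp)$frames)
    fit <- fit_rate(tr, model)
    expect_lt(abs(fit$k - 0.05) / 0.05, 1e-6)
  }
})

test_that("the rgb blend option follows the literal channel-wise path", {
  sp <- reaction_spec(c(90, 30, 140), c(240, 235, 90), k = 0.05, duration = 100,
                      fps = 0.5, noise_sigma = 0, blend = "rgb", seed = 4)
  g <- gen_reaction(sp)
  f <- g$truth$curve$conversion
  expected_rgb <- outer(f, c(240, 235, 90) - c(90, 30, 140)) +
    matrix(c(90, 30, 140), length(f), 3, byrow = TRUE)
  got <- t(vapply(g$frames, function(fr) spatial_mean(fr, roi_full(c(32, 32))), numeric(3)))
  expect_equal(unname(got), expected_rgb, tolerance = 1e-9)
})

test_that("pure diffusion contracts concentration variance monotonically", {
  sp <- mixing_spec(grid = c(32, 32), swirl = 0, diffusion = 0.1, steps = 40,
                    blob_center = c(15, 10), blob_radius = 5, seed = 1)
  gm <- gen_mixing(sp)
  v <- vapply(gm$concentration, function(m) stats::var(as.vector(m)), numeric(1))
  expect_true(all(diff(v) < 0))
})

test_that("the mixing stencil conserves total dye mass to 1e-6 over 100 steps", {
  sp <- mixing_spec(grid = c(40, 40), swirl = 0.4, diffusion = 0.1, steps = 101,
                    blob_center = c(20, 13), blob_radius = 6, seed = 1)
  gm <- gen_mixing(sp)
  tot0 <- sum(gm$concentration[[1]])
  expect_lt(abs(sum(gm$concentration[[101]]) - tot0), 1e-6)
  # every step, not just the last
  tots <- vapply(gm$concentration, sum, numeric(1))
  expect_lt(max(abs(tots - tot0)), 1e-6)
})

test_that("long mixing runs approach homogeneity and Contact decays to zero", {
  sp <- mixing_spec(grid = c(32, 32), swirl = 0.4, diffusion = 0.15, steps = 220,
                    blob_center = c(15, 10), blob_radius = 5, seed = 1)
  gm <- gen_mixing(sp)
  final <- gm$concentration[[220]]
  expect_lt(max(abs(final - mean(final))), 0.02)
  thr <- mixing_threshold(sp)
  last <- binarize(gm$frames[[220]], thr$lo, thr$hi)
  expect_equal(contact(last), 0L)
})

test_that("mixing spec validation enforces the stability bound and blob containment", {
  expect_error(mixing_spec(diffusion = 0.3), "stability")
  expect_error(mixing_spec(grid = c(20, 20), blob_center = c(2, 2), blob_radius = 5),
               "inside the grid")
})

test_that("identical wells give identical traces; k-ordering sets plateau ordering", {
  sp_same <- plate_spec(rows = 1, cols = 3, k = 0.05, duration = 100, fps = 1,
                        noise_sigma = 0, seed = 6)
  gp <- gen_plate(sp_same)
  trs <- build_traces(gp$frames, gp$rois)
  des <- split(trs$delta_e, trs$roi)
  expect_equal(des[["A1"]], des[["A2"]])
  expect_equal(des[["A2"]], des[["A3"]])

  # 10-fold k spread: faster wells plateau earlier
  ks <- c(0.01, 0.0316, 0.1)
  sp_var <- plate_spec(rows = 1, cols = 3, k = ks, duration = 600, fps = 1,
                       noise_sigma = 0, seed = 6)
  gv <- gen_plate(sp_var)
  tv <- build_traces(gv$frames, gv$rois)
  plateaus <- vapply(split(as.data.frame(tv), tv$roi), function(tr) {
    detect_plateau(tr, window = 5, eps = 0.05, min_excursion = 5)
  }, numeric(1))
  expect_true(all(diff(plateaus[order(ks)]) < 0))
})

test_that("per-well k recovery stays accurate under sigma = 2 channel noise", {
  ks <- rep(c(0.02, 0.05, 0.08), 2)
  sp <- plate_spec(rows = 2, cols = 3, k = ks, duration = 300, fps = 1,
                   noise_sigma = 2, seed = 11)
  gp <- gen_plate(sp)
  trs <- build_traces(gp$frames, gp$rois)
  fits <- kinetic_summary(trs)
  err <- abs(fits$k[match(gp$truth$well, fits$roi)] - gp$truth$k) / gp$truth$k
  expect_lt(median(err), 0.05)
})
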