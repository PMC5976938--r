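test_that("flat slab rasterizes to the expected column thickness", {
  spec <- phantom_spec(width_mm = 15, thickness_mm = 3, curvature_per_m = 0,
                       pixel_spacing_mm = 0.1, snr = Inf)
  s <- make_geometry(spec)
  counts <- colSums(s$mask)
  expect_true(all(abs(counts - 30) <= 1))
  expect_equal(ncol(s$mask), 150)
})

test_that("curved surface sagitta matches the circular-arc formula", {
  spec <- phantom_spec(width_mm = 15, thickness_mm = 2.5,
                       curvature_per_m = 4.4, pixel_spacing_mm = 0.1,
                       snr = Inf)
  s <- make_geometry(spec)
  dev_px <- max(s$surface_curve$y) - min(s$surface_curve$y)
  # exact circle: sagitta between the outermost and innermost column
  # centers (even column count, so the innermost sits at +/- dx/2)
  R <- 1000 / 4.4
  x <- abs((seq_len(150) - 75.5) * 0.1)
  sag <- function(xx) R - sqrt(R^2 - xx^2)
  expect_equal(dev_px * 0.1, sag(max(x)) - sag(min(x)), tolerance = 1e-9)
  # small-sagitta approximation (width^2 * kappa / 8 ~ 0.12 mm)
  expect_equal(dev_px * 0.1, 15^2 * 4.4e-3 / 8, tolerance = 0.02)
})

test_that("mask equals a brute-force point-in-region rasterization", {
  s <- make_geometry(small_spec())
  ys <- s$surface_curve$y
  yb <- s$bone_curve$y
  for (j in seq_len(ncol(s$mask))) {
    for (i in seq_len(nrow(s$mask))) {
      inside <- (i - 1) >= ys[j] && (i - 1) <= yb[j]
      expect_identical(s$mask[i, j], inside)
    }
  }
  # single connected component: every masked column is a contiguous run
  for (j in which(colSums(s$mask) > 0)) {
    rows <- which(s$mask[, j])
    expect_equal(rows, seq(min(rows), max(rows)))
  }
})

test_that("ground-truth relaxation maps are strictly monotone in fluid fraction", {
  spec <- small_spec()
  s <- make_geometry(spec)
  model <- composition_model()
  gt <- make_ground_truth(s, model, spec)
  z <- gt$depth$z
  msk <- s$mask
  ff <- composition_at(z[msk], model)$ff
  ord <- order(ff)
  for (m in list(gt$t1_map, gt$t1rho_map, gt$t2star_map)) {
    expect_true(all(diff(m[msk][ord]) >= 0))
    expect_gt(stats::cor(ff, m[msk]), 0.999)
  }
  # superficial-zone pixels stay inside the physiologic T1 band
  sz <- msk & !is.na(z) & z < 0.15
  expect_true(all(gt$t1_map[sz] >= 550 & gt$t1_map[sz] <= 750))
})

test_that("a constant-composition model yields spatially constant maps", {
  tg <- data.frame(zone = c("SZ", "TZ", "DZ"), ff = c(70, 70, 70),
                   co = c(10, 10, 10), pg = c(20, 20, 20))
  model <- calibrate_default_profiles(tg, ff_surface = 0.70,
                                      co_surface = 0.10)
  spec <- small_spec()
  s <- make_geometry(spec)
  gt <- make_ground_truth(s, model, spec)
  for (m in list(gt$t1_map, gt$t1rho_map, gt$t2star_map)) {
    vals <- m[s$mask]
    expect_lt(diff(range(vals)), 1e-9)
  }
})

test_that("noiseless stacks follow the theoretical signal equations", {
  tg <- data.frame(zone = c("SZ", "TZ", "DZ"), ff = c(70, 70, 70),
                   co = c(10, 10, 10), pg = c(20, 20, 20))
  model <- calibrate_default_profiles(tg, ff_surface = 0.70,
                                      co_surface = 0.10)
  spec <- small_spec(snr = Inf)
  s <- make_geometry(spec)
  gt <- make_ground_truth(s, model, spec)
  msk <- s$mask
  tau2 <- gt$t2star_map[msk][1]
  pr <- default_protocols()
  st <- simulate_stack(gt, pr$T2STAR, spec)
  px <- which(msk, arr.ind = TRUE)[1, ]
  expect_equal(st$signal[px[1], px[2], ],
               1000 * exp(-pr$T2STAR$times / tau2), tolerance = 1e-12)
  # inversion recovery nulls at TI = T1 ln 2 when TR >> T1
  t1 <- gt$t1_map[msk][1]
  null_proto <- acquisition_protocol("T1", c(100, t1 * log(2), 3 * t1),
                                     tr_ms = 50 * t1)
  stn <- simulate_stack(gt, null_proto, spec)
  expect_lt(stn$signal[px[1], px[2], 2], 1e-6 * 1000)
})

test_that("infinite SNR is exactly noiseless and seeds are reproducible", {
  spec1 <- small_spec(snr = Inf, seed = 1)
  spec2 <- small_spec(snr = Inf, seed = 99)
  s <- make_geometry(spec1)
  gt <- make_ground_truth(s, composition_model(), spec1)
  pr <- default_protocols()$T1RHO
  expect_identical(simulate_stack(gt, pr, spec1)$signal,
                   simulate_stack(gt, pr, spec2)$signal)
  # at finite SNR, identical seeds give identical stacks, new seeds differ
  na <- small_spec(snr = 50, seed = 7)
  nb <- small_spec(snr = 50, seed = 8)
  expect_identical(simulate_stack(gt, pr, na)$signal,
                   simulate_stack(gt, pr, na)$signal)
  expect_false(identical(simulate_stack(gt, pr, na)$signal,
                         simulate_stack(gt, pr, nb)$signal))
})

test_that("Rician realizations converge to the noiseless signal at high SNR", {
  s <- 1000
  sigma <- s / 50
  set.seed(42)
  draws <- sqrt((s + rnorm(1e4, 0, sigma))^2 + rnorm(1e4, 0, sigma)^2)
  expect_lt(abs(mean(draws) - s) / s, 0.01)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(width_mm = -1), "positive")
  expect_error(phantom_spec(snr = 0), "snr")
  expect_error(phantom_spec(curvature_per_m = -2), "curvature")
  expect_error(make_geometry(phantom_spec(thickness_mm = 0.05,
                                          pixel_spacing_mm = 0.1)),
               "not representable")
})
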