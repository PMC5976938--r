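test_that("echo-time filter keeps exactly the sub-cutoff echoes", {
  pr <- default_protocols()$T2STAR
  f <- filter_echoes(pr)
  expect_equal(length(f$times), 9)              # 3.9 + n*6.9, n = 0..8
  expect_equal(max(f$times), 59.1)
  expect_true(all(f$times < 60))
  # strict inequality at the cutoff
  f60 <- filter_echoes(acquisition_protocol("T2STAR", c(10, 30, 50, 60, 90)),
                       max_te_ms = 60)
  expect_equal(f60$times, c(10, 30, 50))
})

test_that("echo-time filter edge cases error or pass through", {
  pr <- default_protocols()$T2STAR
  short <- acquisition_protocol("T2STAR", c(4, 11, 18, 25))
  expect_identical(filter_echoes(short)$times, short$times)
  expect_error(filter_echoes(pr, max_te_ms = 4), "insufficient|fewer")
  expect_error(filter_echoes(default_protocols()$T1RHO), "T2STAR")
})

test_that("acquisition protocols validate their timing invariants", {
  expect_error(acquisition_protocol("T2STAR", c(10, 10, 20)), "increasing")
  expect_error(acquisition_protocol("T2STAR", c(-5, 10)), "non-negative")
  expect_error(acquisition_protocol("T1", c(150, 300, 500)), "tr_ms")
  expect_error(acquisition_protocol("T1", c(150, 300, 5000), tr_ms = 3000),
               "tr_ms")
})

test_that("mono-exponential fit recovers noiseless parameters exactly", {
  te <- filter_echoes(default_protocols()$T2STAR)$times
  for (tau in c(15, 30, 40)) {
    f <- fit_monoexp(1000 * exp(-te / tau), te)
    expect_true(f$converged)
    expect_equal(f$relax_ms, tau, tolerance = 1e-5)
    expect_equal(f$amplitude, 1000, tolerance = 1e-4)
    expect_equal(f$r2_adj, 1, tolerance = 1e-9)
  }
  # with a noise floor
  ff <- fit_monoexp(800 * exp(-te / 25) + 50, te, fit_floor = TRUE)
  expect_equal(ff$relax_ms, 25, tolerance = 1e-4)
  expect_equal(ff$noise_floor, 50, tolerance = 1e-2)
})

test_that("degenerate signals are flagged, not thrown", {
  te <- c(5, 10, 20, 40)
  f <- fit_monoexp(rep(100, 4), te)
  expect_false(f$converged)
  expect_error(fit_monoexp(c(1, NA, 3, 4), te), "non-finite")
  expect_error(fit_monoexp(c(1, 2, 3), c(5, 10)), "length")
})

test_that("fits are equivariant under signal and time rescaling", {
  te <- filter_echoes(default_protocols()$T2STAR)$times
  set.seed(11)
  y <- 1000 * exp(-te / 28) + rnorm(length(te), 0, 15)
  y <- abs(y)
  f1 <- fit_monoexp(y, te)
  fk <- fit_monoexp(5 * y, te)
  expect_equal(fk$relax_ms, f1$relax_ms, tolerance = 1e-6)
  expect_equal(fk$amplitude, 5 * f1$amplitude, tolerance = 1e-6)
  expect_equal(fk$r2_adj, f1$r2_adj, tolerance = 1e-9)
  ft <- fit_monoexp(y, 3 * te)
  expect_equal(ft$relax_ms, 3 * f1$relax_ms, tolerance = 1e-6)
})

test_that("magnitude inversion recovery resolves the polarity fold", {
  ti <- default_protocols()$T1$times
  f <- fit_ir(abs(1000 * (1 - 2 * exp(-ti / 700) + exp(-3000 / 700))),
              ti, 3000)
  expect_true(f$converged)
  expect_equal(f$relax_ms, 700, tolerance = 1e-3)
  expect_equal(f$amplitude, 1000, tolerance = 1e-2)
  # noiseless sweep across the physiologic T1 range
  for (t1 in seq(550, 750, by = 25)) {
    sig <- abs(1000 * (1 - 2 * exp(-ti / t1) + exp(-3000 / t1)))
    fs <- fit_ir(sig, ti, 3000)
    expect_lt(abs(fs$relax_ms - t1) / t1, 0.005)
  }
})

test_that("adjusted R-squared matches a hand-computed oracle", {
  y <- c(3, 1, 4, 1, 5)
  fitted <- c(2.8, 1.3, 3.5, 1.2, 4.6)
  # by hand: SSE = 0.58, SST = 12.8, R2 = 0.9546875,
  # adj = 1 - (1 - R2) * 4 / 2 = 0.909375
  expect_equal(adjusted_r2(y - fitted, y, 2), 0.909375, tolerance = 1e-12)
  expect_equal(adjusted_r2(rep(0, 5), y, 2), 1)
  expect_lte(adjusted_r2(y - mean(y), y, 2), 0)
  expect_warning(r <- adjusted_r2(rep(0, 5), rep(7, 5), 2), "variance")
  expect_true(is.na(r))
  expect_error(adjusted_r2(y - fitted, y, 4), "observations")
})

test_that("time-constant estimates stay accurate and nearly unbiased under noise", {
  te <- filter_echoes(default_protocols()$T2STAR)$times
  tau <- 30; A <- 1000; sigma <- A / 50
  set.seed(21)
  est <- replicate(200, {
    y <- sqrt((A * exp(-te / tau) + rnorm(9, 0, sigma))^2 +
                rnorm(9, 0, sigma)^2)
    fit_monoexp(y, te)$relax_ms
  })
  expect_lt(abs(mean(est) - tau) / tau, 0.02)       # bias < 2 %
  expect_lt(median(abs(est - tau) / tau), 0.05)     # median error < 5 %
})

test_that("fit_map achieves noiseless closure and flags pure noise", {
  spec <- small_spec(snr = Inf)
  s <- make_geometry(spec)
  gt <- make_ground_truth(s, composition_model(), spec)
  protos <- default_protocols()
  truth <- list(T1 = gt$t1_map, T1RHO = gt$t1rho_map, T2STAR = gt$t2star_map)
  for (kind in names(protos)) {
    st <- simulate_stack(gt, protos[[kind]], spec)
    proto <- if (kind == "T2STAR") filter_echoes(protos[[kind]]) else
      protos[[kind]]
    pm <- fit_map(st, proto)
    expect_equal(sum(pm$qc_pass), sum(s$mask))
    rel <- abs(pm$relax_ms[s$mask] - truth[[kind]][s$mask]) /
      truth[[kind]][s$mask]
    expect_lt(max(rel), 1e-3)
  }
  # pure Rician noise: nearly all pixels must fail QC
  set.seed(5)
  d <- dim(s$mask)
  noise <- array(sqrt(rnorm(prod(d) * 9, 0, 20)^2 +
                        rnorm(prod(d) * 9, 0, 20)^2),
                 c(d, 9))
  pmn <- fit_map(noise, filter_echoes(protos$T2STAR), mask = s$mask)
  expect_gte(mean(!pmn$qc_pass[s$mask]), 0.95)
})

test_that("fit_map validates stack/protocol agreement", {
  spec <- small_spec(snr = Inf)
  s <- make_geometry(spec)
  gt <- make_ground_truth(s, composition_model(), spec)
  st <- simulate_stack(gt, default_protocols()$T1RHO, spec)
  expect_error(fit_map(st, default_protocols()$T1), "disagree")
})
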