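test_that("Spearman correlation handles monotone and reversed data", {
  x <- c(1, 3, 4, 7, 9, 12, 15, 20)
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, rev(x))$rho, -1)
  expect_error(spearman(1:2, 1:2), "at least 3")
  expect_error(spearman(1:5, c(1, 2, NA, 4, 5)), "non-finite")
  expect_warning(r <- spearman(1:5, rep(2, 5)), "rank variance")
  expect_true(is.na(r$rho))
})

test_that("tied data matches the brute-force midrank Pearson oracle", {
  x8 <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y8 <- c(2, 1, 3, 3, 5, 4, 6, 6)
  expect_equal(spearman(x8, y8)$rho, oracle_spearman_rho(x8, y8),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman(x, y)$rho, oracle_spearman_rho(x, y),
                 tolerance = 1e-12)
    # independent cross-check against the reference implementation
    expect_equal(spearman(x, y)$rho,
                 unname(stats::cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-values are correct for small samples", {
  # perfect monotone n = 5: only identity and reversal reach |rho| = 1,
  # so the exact two-sided p is 2/5! = 1/60
  r <- spearman(1:5, c(2, 4, 6, 8, 10))
  expect_equal(r$p, 2 / 120, tolerance = 1e-12)
  # exact and approximate p agree in order of magnitude on untied data
  ra <- spearman(1:7, c(2, 1, 4, 3, 6, 5, 7), p_method = "exact")
  expect_true(ra$p > 0 && ra$p < 1)
})

test_that("correlation table has the 3 x 4 x 2 layout and rank invariance", {
  s <- make_geometry(small_spec())
  d <- compute_depth(s)
  mm <- evaluate_on_grid(d)
  rg <- assign_regions(s$mask, 0.2, cr_width_mm = 3)
  # a fake parameter map whose values ARE the fluid fraction
  fake_map <- function(vals) {
    structure(list(relax_ms = vals, qc_pass = s$mask, mask = s$mask,
                   r2_adj = (s$mask) * 1, kind = "T1", qc_threshold = 0.95),
              class = "parameter_map")
  }
  qm <- list(T1 = fake_map(mm$ff))
  tab <- correlation_table(qm, mm, rg)
  expect_equal(nrow(tab), 8)  # 1 qmap x 4 model params x 2 regions
  self <- tab[tab$model_param == "FF", ]
  expect_equal(self$rho_s, rep(1, 2), tolerance = 1e-12)
  expect_true(all(self$stars == "***"))
  # invariance under a strictly monotone transform of the map
  qm2 <- list(T1 = fake_map(exp(3 * mm$ff)))
  tab2 <- correlation_table(qm2, mm, rg)
  expect_equal(tab2$rho_s, tab$rho_s, tolerance = 1e-12)
  # full layout with three sequences
  qm3 <- list(T1 = fake_map(mm$ff), T1RHO = fake_map(mm$ff),
              T2STAR = fake_map(mm$ff))
  expect_equal(nrow(correlation_table(qm3, mm, rg)), 24)
})

test_that("exponential curve fits recover generating parameters", {
  set.seed(9)
  phi <- runif(80, 0.3, 0.9)
  q <- 100 * exp(2 * phi) + 500
  f <- fit_exponential(phi, q)
  expect_true(f$converged)
  expect_lt(abs(f$a - 100) / 100, 0.01)
  expect_lt(abs(f$b - 2) / 2, 0.01)
  expect_lt(abs(f$c - 500) / 500, 0.01)
  expect_gt(f$r2, 0.999)
  # negative rate branch
  qn <- 80 * exp(-3 * phi) + 20
  fn <- fit_exponential(phi, qn)
  expect_lt(abs(fn$b + 3) / 3, 0.01)
  # degenerate constant response
  fd <- fit_exponential(phi, rep(5, 80))
  expect_true(fd$degenerate)
  # nesting: never worse than the best constant model
  set.seed(10)
  qr <- rnorm(80)
  expect_gte(fit_exponential(phi, qr)$r2, 0)
})

test_that("sinusoidal curve fits recover generating parameters", {
  theta <- seq(0, 90, length.out = 60)
  q <- 50 * sin(theta * pi / 180) + 600   # frequency 1 per radian
  f <- fit_sinusoidal(theta, q)
  expect_true(f$converged)
  expect_lt(abs(f$a - 50) / 50, 0.01)
  expect_lt(abs(f$b - 1), 0.01)
  expect_lt(abs(f$c - 600) / 600, 0.01)
  fd <- fit_sinusoidal(theta, rep(3, 60))
  expect_true(fd$degenerate)
})

test_that("group comparisons control the null and detect shifts", {
  set.seed(13)
  null_p <- replicate(100, {
    compare_groups(rnorm(100), rep(c("A", "B"), each = 50))$p_value
  })
  expect_gte(mean(null_p > 0.05), 0.90)
  shifted <- compare_groups(c(rnorm(50), rnorm(50) + 5),
                            rep(c("A", "B"), each = 50))
  expect_lt(shifted$p_value, 0.001)
  expect_equal(shifted$design, "regions")
})

test_that("zonal comparison flags the deep zone via Dunn's post hoc", {
  set.seed(17)
  vals <- c(rnorm(60, 10), rnorm(60, 10), rnorm(60, 6))
  g <- rep(c("SZ", "TZ", "DZ"), each = 60)
  cmp <- compare_groups(vals, g)
  expect_equal(cmp$design, "zones")
  expect_lt(cmp$p_value, 0.05)
  ph <- cmp$posthoc
  expect_false(is.null(ph))
  dz_rows <- grepl("DZ", ph$comparison)
  expect_true(all(ph$p_adj[dz_rows] < 0.05))
  expect_true(all(ph$p_adj[!dz_rows] > 0.05))
  # no post hoc when the omnibus test is null
  set.seed(18)
  cmp0 <- compare_groups(rnorm(180), g)
  if (cmp0$p_value >= 0.05) expect_null(cmp0$posthoc)
  expect_error(compare_groups(1:5, c("A", "A", "A", "A", "B")),
               "at least 2 observations")
})

test_that("zonal summaries report mean, SD and counts per cell", {
  s <- make_geometry(small_spec())
  d <- compute_depth(s)
  zn <- assign_zones(d)
  rg <- assign_regions(s$mask, 0.2, cr_width_mm = 3)
  const <- matrix(NA_real_, nrow(s$mask), ncol(s$mask))
  const[s$mask] <- 7
  tab <- zonal_summary(const, zn, rg)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$mean == 7))
  expect_true(all(tab$sd == 0))
  expect_equal(sum(tab$n), sum(s$mask))
})
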