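# Region-wise statistics: pixel-wise Spearman correlation of qMRI maps
# with modelled composition maps, best-fit curve families, and
# non-parametric group comparisons.

# all permutations of 1..n as an n! x n matrix (exact Spearman null)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation
#'
#' Tie-corrected Spearman coefficient computed as the Pearson correlation
#' of midranks (moment form, authored here rather than delegated). The
#' two-sided p-value is obtained by exact enumeration of the permutation
#' null for n <= 7 (`p_method = "auto"`) and by the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 degrees of freedom otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @param p_method `"auto"`, `"exact"` or `"approx"`.
#' @return List with `rho`, `p`, `n`. Zero rank variance in either
#'   variable yields `rho = NA` with a warning.
#' @export
spearman <- function(x, y, p_method = c("auto", "exact", "approx")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  vx <- sum(dx^2)
  vy <- sum(dy^2)
  if (vx == 0 || vy == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- sum(dx * dy) / sqrt(vx * vy)
  exact <- p_method == "exact" || (p_method == "auto" && n <= 7)
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    perms <- .permutations(n)
    ryp <- matrix(ry[perms], nrow(perms), n)
    dyp <- ryp - mean(ry)
    rhop <- (dyp %*% dx) / sqrt(vx * vy)
    p <- mean(abs(rhop) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
  }
  list(rho = rho, p = p, n = n)
}

.stars <- function(p) {
  ifelse(p <= 0.001, "***",
         ifelse(p <= 0.01, "**",
                ifelse(p <= 0.05, "*", "ns")))
}

#' Region-wise correlation table of qMRI versus modelled parameters
#'
#' Pixel-wise Spearman correlation of every qMRI parameter map against
#' every modelled tissue parameter (FF, CO, PG, CFO), evaluated separately
#' for the central and peripheral regions. QC-failed pixels are excluded.
#' Significance stars follow the three-tier scheme
#' 0.01 < p <= 0.05 (*), 0.001 < p <= 0.01 (**), p <= 0.001 (***).
#'
#' @param qmaps named list of `parameter_map` objects (e.g. `T1`, `T1RHO`,
#'   `T2STAR`).
#' @param mmaps a `modelled_maps` object.
#' @param regions a `region_labels` object.
#' @return data.frame with one row per (qMRI parameter, model parameter,
#'   region): `rho_s`, `p_value`, `n_pixels`, `stars` - 24 rows for the
#'   standard 3 x 4 x 2 layout.
#' @export
correlation_table <- function(qmaps, mmaps, regions) {
  stopifnot(inherits(mmaps, "modelled_maps"),
            inherits(regions, "region_labels"))
  layers <- list(FF = mmaps$ff, CO = mmaps$co, PG = mmaps$pg,
                 CFO = mmaps$cfo)
  rows <- list()
  for (region in c("CR", "PR")) {
    for (qn in names(qmaps)) {
      pm <- qmaps[[qn]]
      stopifnot(inherits(pm, "parameter_map"))
      for (mn in names(layers)) {
        sel <- pm$qc_pass & regions$labels == region &
          !is.na(layers[[mn]])
        sel[is.na(sel)] <- FALSE
        if (sum(sel) < 3) {
          stop("region ", region, " has fewer than 3 usable pixels for ",
               qn, " vs ", mn)
        }
        sp <- spearman(pm$relax_ms[sel], layers[[mn]][sel],
                       p_method = "approx")
        rows[[length(rows) + 1]] <- data.frame(
          qmri = qn, model_param = mn, region = region,
          rho_s = sp$rho, p_value = sp$p, n_pixels = sp$n,
          stars = .stars(sp$p), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

.curve_fit <- function(family, a, b, c, r2, n, converged, degenerate = FALSE) {
  structure(list(family = family, a = a, b = b, c = c, r2 = r2, n = n,
                 converged = converged, degenerate = degenerate),
            class = "curve_fit")
}

# profiled SSE over the nonlinear rate/frequency b: a and c are linear
.curve_profile <- function(b, reg_fun, q, full = FALSE) {
  x <- reg_fun(b)
  if (any(!is.finite(x))) return(if (full) NULL else Inf)
  X <- cbind(x, 1)
  cf <- tryCatch(solve(crossprod(X), crossprod(X, q)),
                 error = function(e) NULL)
  # singular basis (constant regressor): limit is the mean-only fit
  if (is.null(cf)) {
    if (full) return(list(a = 0, c = mean(q), res = q - mean(q)))
    return(sum((q - mean(q))^2))
  }
  r <- q - X %*% cf
  if (full) return(list(a = cf[1], c = cf[2], res = as.numeric(r)))
  sum(r * r)
}

.fit_curve_family <- function(b_grid, reg_fun, q, family, n) {
  sse <- vapply(b_grid, .curve_profile, numeric(1), reg_fun = reg_fun, q = q)
  if (all(!is.finite(sse))) {
    return(.curve_fit(family, NA, NA, mean(q), NA, n, FALSE, TRUE))
  }
  sse[!is.finite(sse)] <- Inf
  is_min <- vapply(seq_along(sse), function(i) {
    l <- if (i > 1) sse[i - 1] else Inf
    r <- if (i < length(sse)) sse[i + 1] else Inf
    sse[i] <= l && sse[i] <= r
  }, logical(1))
  cand <- utils::head(intersect(order(sse), which(is_min)), 6)
  best_b <- b_grid[which.min(sse)]
  best_obj <- min(sse)
  for (i in cand) {
    lo <- b_grid[max(i - 1, 1)]
    hi <- b_grid[min(i + 1, length(b_grid))]
    o <- tryCatch(stats::optimize(.curve_profile, c(lo, hi), reg_fun = reg_fun,
                                  q = q, tol = 1e-9),
                  error = function(e) NULL)
    if (!is.null(o) && o$objective < best_obj) {
      best_b <- o$minimum
      best_obj <- o$objective
    }
  }
  sol <- .curve_profile(best_b, reg_fun, q, full = TRUE)
  sst <- sum((q - mean(q))^2)
  r2 <- 1 - sum(sol$res^2) / sst
  .curve_fit(family, sol$a, best_b, sol$c, r2, n,
             converged = all(is.finite(c(sol$a, best_b, sol$c))))
}

#' Fit an exponential trend to a volume-fraction / qMRI scatter
#'
#' Least-squares fit of `a exp(b phi) + c` with multi-start over the sign
#' and magnitude of the rate b (a and c profiled out in closed form).
#'
#' @param phi volume fractions (predictor).
#' @param q qMRI parameter values (response), same length, n >= 4.
#' @return A `curve_fit` with fields `a`, `b`, `c`, `r2`, `n`; a constant
#'   response is flagged `degenerate`.
#' @export
fit_exponential <- function(phi, q) {
  n <- length(q)
  stopifnot(length(phi) == n)
  if (n < 4) stop("need at least 4 points")
  if (any(!is.finite(phi)) || any(!is.finite(q))) stop("non-finite values")
  if (sd(q) == 0 || sd(phi) == 0) {
    return(.curve_fit("exponential", 0, 0, mean(q), NA_real_, n, FALSE,
                      degenerate = TRUE))
  }
  s <- diff(range(phi))
  bmax <- min(30 / s, 500 / max(abs(phi)))
  mags <- exp(seq(log(1e-3 / s), log(bmax), length.out = 30))
  b_grid <- sort(c(-rev(mags), mags))
  .fit_curve_family(b_grid, function(b) exp(b * phi), q, "exponential", n)
}

#' Fit a sinusoidal trend to a fiber-angle / qMRI scatter
#'
#' Least-squares fit of `a sin(b theta) + c`, with the angle converted to
#' radians internally, so the reported frequency b is per radian.
#' Multi-start over b (the profiled objective is multimodal in the
#' frequency).
#'
#' @param theta_deg fiber orientation angles, degrees.
#' @param q qMRI parameter values, same length, n >= 4.
#' @return A `curve_fit`.
#' @export
fit_sinusoidal <- function(theta_deg, q) {
  n <- length(q)
  stopifnot(length(theta_deg) == n)
  if (n < 4) stop("need at least 4 points")
  if (any(!is.finite(theta_deg)) || any(!is.finite(q))) {
    stop("non-finite values")
  }
  th <- theta_deg * pi / 180
  if (sd(q) == 0 || sd(th) == 0) {
    return(.curve_fit("sinusoidal", 0, 0, mean(q), NA_real_, n, FALSE,
                      degenerate = TRUE))
  }
  s <- diff(range(th))
  b_grid <- exp(seq(log(0.05 / s), log(40 / s), length.out = 60))
  .fit_curve_family(b_grid, function(b) sin(b * th), q, "sinusoidal", n)
}

# Dunn's post hoc test on pooled ranks with tie correction
.dunn_test <- function(values, groups, p_adjust = "bonferroni") {
  g <- droplevels(as.factor(groups))
  r <- rank(values)
  N <- length(values)
  rbar <- tapply(r, g, mean)
  ni <- table(g)
  tie <- table(values)
  tie_term <- sum(tie^3 - tie)
  s2 <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  prs <- utils::combn(levels(g), 2)
  z <- apply(prs, 2, function(pr) {
    (rbar[pr[1]] - rbar[pr[2]]) /
      sqrt(s2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(comparison = paste(prs[1, ], "vs", prs[2, ]),
             z = as.numeric(z),
             p_unadj = as.numeric(p),
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Non-parametric group comparison
#'
#' Two groups (regional design) are compared with the Mann-Whitney U test;
#' three or more groups (zonal design) with the Kruskal-Wallis test
#' followed, when the omnibus test is significant at `alpha`, by Dunn's
#' post hoc test with multiplicity adjustment (Bonferroni by default).
#'
#' @param values numeric sample values.
#' @param groups group labels, same length; every group needs n >= 2.
#' @param p_adjust `"bonferroni"`, `"holm"` or `"none"` for the post hoc
#'   p-values.
#' @param alpha omnibus significance level gating the post hoc test.
#' @return Object of class `group_comparison`: `design`, `statistic`,
#'   `p_value`, and `posthoc` (data.frame or NULL).
#' @export
compare_groups <- function(values, groups,
                           p_adjust = c("bonferroni", "holm", "none"),
                           alpha = 0.05) {
  p_adjust <- match.arg(p_adjust)
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  if (nlevels(g) == 2) {
    w <- stats::wilcox.test(values ~ g, exact = FALSE)
    out <- list(design = "regions", statistic = unname(w$statistic),
                p_value = w$p.value, posthoc = NULL)
  } else {
    k <- stats::kruskal.test(values, g)
    ph <- if (k$p.value < alpha) .dunn_test(values, g, p_adjust) else NULL
    out <- list(design = "zones", statistic = unname(k$statistic),
                p_value = k$p.value, posthoc = ph)
  }
  structure(out, class = "group_comparison")
}

#' Zonal and regional summary of a map
#'
#' Mean, standard deviation and pixel count of a per-pixel map for every
#' zone x region cell (3 zones x 2 regions). Empty cells are reported as
#' missing.
#'
#' @param map numeric matrix (NA outside the mask), a `parameter_map`
#'   (its `relax_ms` restricted to QC-passing pixels is summarized), or a
#'   single layer of `modelled_maps`.
#' @param zones a `zone_labels` object.
#' @param regions a `region_labels` object.
#' @return data.frame with columns `zone`, `region`, `n`, `mean`, `sd`.
#' @export
zonal_summary <- function(map, zones, regions) {
  stopifnot(inherits(zones, "zone_labels"), inherits(regions, "region_labels"))
  if (inherits(map, "parameter_map")) {
    m <- map$relax_ms
    m[!map$qc_pass] <- NA_real_
  } else {
    m <- map
  }
  rows <- list()
  for (zn in c("SZ", "TZ", "DZ")) {
    for (rg in c("CR", "PR")) {
      sel <- !is.na(m) & zones$labels == zn & regions$labels == rg
      sel[is.na(sel)] <- FALSE
      v <- m[sel]
      rows[[length(rows) + 1]] <- data.frame(
        zone = zn, region = rg, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
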