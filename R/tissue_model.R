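# Depth-dependent cartilage composition and fiber-orientation model.
#
# Cartilage is treated as a fluid-filled solid matrix of collagen (CO)
# fibers and proteoglycan (PG) aggregates; at every normalized depth z the
# volume fractions satisfy phi_fluid + phi_CO + phi_PG = 1 and the solid
# fraction is phi_s = 1 - phi_fluid. The fluid fraction decreases with
# depth while collagen and proteoglycan contents increase.

#' Default zonal composition targets
#'
#' Zonal mean volume fractions (percent) of fluid (FF), collagen (CO) and
#' proteoglycan (PG) used to calibrate the default depth profiles, one row
#' per zone (superficial SZ, transitional TZ, deep DZ).
#'
#' Note the TZ row sums to 99%: the three reported means are rounded and
#' cannot all hold exactly under the conservation constraint. The
#' calibration redistributes such per-zone closure residuals evenly across
#' the three constituents (a 1% residual moves each target by 1/3 of a
#' percentage point).
#'
#' @return A data.frame with columns `zone`, `ff`, `co`, `pg` (percent).
#' @export
default_zonal_targets <- function() {
  data.frame(
    zone = c("SZ", "TZ", "DZ"),
    ff = c(78, 70, 51),
    co = c(8, 9, 20),
    pg = c(14, 20, 29),
    stringsAsFactors = FALSE
  )
}

# mean of a piecewise-linear function with knots (kz, v) over [a, b]
.pwl_mean <- function(kz, v, a, b) {
  stopifnot(b > a, a >= kz[1] - 1e-12, b <= kz[length(kz)] + 1e-12)
  xs <- sort(unique(c(a, b, kz[kz > a & kz < b])))
  f <- stats::approx(kz, v, xout = xs)$y
  # trapezoid rule is exact for piecewise-linear integrands on knot cells
  area <- sum(diff(xs) * (utils::head(f, -1) + f[-1]) / 2)
  area / (b - a)
}

#' Calibrate the default depth-dependent composition profiles
#'
#' Builds continuous, monotone piecewise-linear volume-fraction profiles
#' phi_fluid(z), phi_CO(z) with knots at z = 0, the two zone boundaries and
#' z = 1, such that the uniform-depth zonal means reproduce the supplied
#' targets; phi_PG is the conservation remainder 1 - FF - CO, so the sum
#' constraint holds at machine precision by construction.
#'
#' Given the surface anchor values, each interior knot is determined
#' recursively from the zone-mean equations (the mean of a linear segment is
#' the midpoint of its endpoint values). Targets whose per-zone sum deviates
#' from 100% are first closed by spreading the residual evenly over the
#' three constituents.
#'
#' @param targets data.frame as [default_zonal_targets()]: zonal means of
#'   `ff`, `co`, `pg`, in percent or as fractions.
#' @param ff_surface fluid fraction at the articular surface (z = 0);
#'   default 0.82, a typical surface hydration for healthy cartilage.
#' @param co_surface collagen fraction at the surface; default 0.075.
#' @param boundaries zone boundaries on normalized depth, default
#'   `c(0.15, 0.65)`.
#' @return An object of class `composition_model`: knot depths `knots_z`,
#'   knot values `ff`, `co`, `pg` (fractions), the balanced `targets`
#'   (fractions) and a `source` tag.
#' @export
calibrate_default_profiles <- function(targets = default_zonal_targets(),
                                       ff_surface = 0.82,
                                       co_surface = 0.075,
                                       boundaries = c(0.15, 0.65)) {
  stopifnot(is.data.frame(targets), nrow(targets) == 3,
            all(c("ff", "co", "pg") %in% names(targets)))
  if (length(boundaries) != 2 || boundaries[1] <= 0 ||
      boundaries[2] >= 1 || boundaries[1] >= boundaries[2]) {
    stop("zone boundaries must be strictly increasing within (0, 1)")
  }
  tg <- targets[, c("ff", "co", "pg")]
  if (max(tg) > 1.5) tg <- tg / 100  # percent -> fraction
  # close each zone to sum 1, residual split evenly
  res <- 1 - rowSums(tg)
  tg <- tg + res / 3

  knz <- c(0, boundaries, 1)
  knot_values <- function(m, v0) {
    v <- numeric(4)
    v[1] <- v0
    for (i in 1:3) v[i + 1] <- 2 * m[i] - v[i]
    v
  }
  ffv <- knot_values(tg$ff, ff_surface)
  cov <- knot_values(tg$co, co_surface)
  pgv <- 1 - ffv - cov

  ok <- all(diff(ffv) <= 1e-12) && all(diff(cov) >= -1e-12) &&
    all(diff(pgv) >= -1e-12) &&
    all(c(ffv, cov, pgv) >= -1e-12) && all(c(ffv, cov, pgv) <= 1 + 1e-12)
  if (!ok) {
    stop("infeasible zonal targets: calibrated profiles violate ",
         "monotonicity or the [0, 1] volume-fraction range")
  }
  structure(
    list(knots_z = knz, ff = ffv, co = cov, pg = pgv,
         targets = tg, boundaries = boundaries,
         source = if (identical(targets, default_zonal_targets()) &&
                      ff_surface == 0.82 && co_surface == 0.075)
           "default-calibrated" else "user"),
    class = "composition_model"
  )
}

#' Default composition model
#'
#' Shorthand for [calibrate_default_profiles()] with all defaults.
#' @return A `composition_model`.
#' @export
composition_model <- function() calibrate_default_profiles()

#' @export
print.composition_model <- function(x, ...) {
  cat("<composition_model> (", x$source, ")\n", sep = "")
  cat("  knots z:", format(x$knots_z), "\n")
  cat("  FF:", format(round(x$ff, 4)), "\n")
  cat("  CO:", format(round(x$co, 4)), "\n")
  cat("  PG:", format(round(x$pg, 4)), "\n")
  invisible(x)
}

#' Evaluate composition at normalized depth
#'
#' Linear interpolation of the calibrated volume-fraction profiles. The
#' proteoglycan fraction is computed as the conservation remainder
#' `1 - ff - co`, and the solid fraction as `1 - ff`.
#'
#' @param z numeric vector of normalized depths in `[0, 1]`.
#' @param model a `composition_model`.
#' @return data.frame with columns `ff`, `co`, `pg`, `phi_s` (fractions).
#' @export
composition_at <- function(z, model = composition_model()) {
  stopifnot(inherits(model, "composition_model"))
  if (any(!is.finite(z)) || any(z < -1e-12) || any(z > 1 + 1e-12)) {
    stop("normalized depth z must be finite and within [0, 1]")
  }
  z <- pmin(pmax(z, 0), 1)
  ff <- stats::approx(model$knots_z, model$ff, xout = z)$y
  co <- stats::approx(model$knots_z, model$co, xout = z)$y
  data.frame(ff = ff, co = co, pg = 1 - ff - co, phi_s = 1 - ff)
}

#' Fiber architecture of the Benninghoff arcade
#'
#' Mean collagen fiber orientation angle, measured from the local cartilage
#' surface normal: 90 degrees (surface-parallel fibers) throughout the
#' superficial zone, 0 degrees (normal-aligned) throughout the deep zone,
#' and a linear ramp across the transitional zone.
#'
#' @param boundaries zone boundaries on normalized depth.
#' @param n_families number of discrete fiber families about the mean
#'   direction (default 8).
#' @param spread_deg total angular spread of the family fan, degrees.
#' @return An object of class `fiber_model`.
#' @export
fiber_model <- function(boundaries = c(0.15, 0.65), n_families = 8,
                        spread_deg = 90) {
  stopifnot(length(boundaries) == 2, boundaries[1] > 0,
            boundaries[2] < 1, boundaries[1] < boundaries[2],
            n_families >= 1, spread_deg >= 0, spread_deg < 180)
  structure(list(boundaries = boundaries, n_families = as.integer(n_families),
                 spread_deg = spread_deg),
            class = "fiber_model")
}

#' Mean fiber orientation angle at normalized depth
#'
#' @param z numeric vector of normalized depths in `[0, 1]`.
#' @param fiber a `fiber_model`.
#' @return Angles in degrees from the local surface normal.
#' @export
fiber_angle_at <- function(z, fiber = fiber_model()) {
  if (any(!is.finite(z)) || any(z < -1e-12) || any(z > 1 + 1e-12)) {
    stop("normalized depth z must be finite and within [0, 1]")
  }
  z <- pmin(pmax(z, 0), 1)
  b1 <- fiber$boundaries[1]
  b2 <- fiber$boundaries[2]
  ifelse(z < b1, 90, ifelse(z >= b2, 0, 90 * (b2 - z) / (b2 - b1)))
}

#' Discrete fiber family directions
#'
#' Constructs `n` unit vectors fanned equiangularly about the mean fiber
#' direction given by `theta_deg` (angle from the local surface normal).
#' Offsets are symmetric, so the circular mean of the family angles equals
#' `theta_deg`. Vectors are expressed in the local (tangent, normal) frame:
#' the first component is along the surface tangent, the second along the
#' inward normal.
#'
#' @param theta_deg mean fiber angle from the surface normal, degrees.
#' @param n number of families.
#' @param spread_deg total angular spread of the fan, degrees.
#' @return An `n x 2` matrix of unit vectors with attribute `angles_deg`.
#' @export
fiber_families <- function(theta_deg, n = 8, spread_deg = 90) {
  stopifnot(n >= 1, spread_deg >= 0, spread_deg < 180)
  offsets <- if (n == 1) 0 else seq(-spread_deg / 2, spread_deg / 2,
                                    length.out = n)
  ang <- theta_deg + offsets
  rad <- ang * pi / 180
  v <- cbind(tangent = sin(rad), normal = cos(rad))
  attr(v, "angles_deg") <- ang
  v
}

#' Analytic zonal means of the composition and fiber model
#'
#' Exact (integral) uniform-depth zonal means of FF, CO, PG (percent) and
#' the fiber angle (degrees) for each zone; used to verify calibration.
#'
#' @param model a `composition_model`.
#' @param fiber a `fiber_model`.
#' @return data.frame with one row per zone.
#' @export
model_zonal_means <- function(model = composition_model(),
                              fiber = fiber_model()) {
  b <- model$boundaries
  lims <- rbind(SZ = c(0, b[1]), TZ = c(b[1], b[2]), DZ = c(b[2], 1))
  rows <- lapply(rownames(lims), function(zn) {
    a <- lims[zn, 1]; bb <- lims[zn, 2]
    ff <- .pwl_mean(model$knots_z, model$ff, a, bb)
    co <- .pwl_mean(model$knots_z, model$co, a, bb)
    # fiber ramp is piecewise linear with the same knots
    cfo <- .pwl_mean(c(0, fiber$boundaries, 1), c(90, 90, 0, 0), a, bb)
    data.frame(zone = zn, ff = 100 * ff, co = 100 * co,
               pg = 100 * (1 - ff - co), cfo = cfo,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate the tissue model on an image grid
#'
#' Associates every masked pixel with the local modelled composition and
#' fiber orientation via its normalized depth, mirroring the element-wise
#' association of the discretized imaging plane with depth-dependent tissue
#' properties.
#'
#' @param depth a `depth_field` (see [compute_depth()]).
#' @param model a `composition_model`.
#' @param fiber a `fiber_model`.
#' @param elements optional `element_grid` from [discretize()]; when given,
#'   an element-level table of pooled means is attached.
#' @return An object of class `modelled_maps`: matrices `ff`, `co`, `pg`
#'   (fractions), `cfo` (degrees), the `mask`, and optionally
#'   `element_table`.
#' @export
evaluate_on_grid <- function(depth, model = composition_model(),
                             fiber = fiber_model(), elements = NULL) {
  stopifnot(inherits(depth, "depth_field"))
  msk <- depth$mask
  zv <- depth$z[msk]
  comp <- composition_at(zv, model)
  blank <- function() matrix(NA_real_, nrow(msk), ncol(msk))
  ff <- blank(); co <- blank(); pg <- blank(); cfo <- blank()
  ff[msk] <- comp$ff
  co[msk] <- comp$co
  pg[msk] <- comp$pg
  cfo[msk] <- fiber_angle_at(zv, fiber)
  out <- list(ff = ff, co = co, pg = pg, cfo = cfo, mask = msk)
  if (!is.null(elements)) {
    stopifnot(inherits(elements, "element_grid"))
    et <- elements$table
    eid <- factor(elements$element_id[msk], levels = et$element)
    pool <- function(m) as.numeric(tapply(m[msk], eid, mean))
    et$ff <- pool(ff)
    et$co <- pool(co)
    et$pg <- pool(pg)
    et$cfo <- pool(cfo)
    out$element_table <- et
  }
  structure(out, class = "modelled_maps")
}
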