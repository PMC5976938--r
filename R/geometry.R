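# Normalized cartilage depth and ROI labelling.
#
# Coordinates: row-major 2-D grid, 0-based indices, pixel centers. Row
# index increases from the articular surface towards bone; column index
# runs along the sample width. Physical units enter only through
# pixel_spacing_mm.

# minimum Euclidean distance from points (px, py) to a polyline given as a
# data.frame(x, y); exact point-to-segment projection, vectorized over
# points with a loop over segments
.dist_to_polyline <- function(px, py, curve) {
  cx <- curve$x
  cy <- curve$y
  d2 <- rep(Inf, length(px))
  for (j in seq_len(length(cx) - 1)) {
    ax <- cx[j];  ay <- cy[j]
    bx <- cx[j + 1]; by <- cy[j + 1]
    vx <- bx - ax; vy <- by - ay
    vv <- vx * vx + vy * vy
    t <- if (vv > 0) ((px - ax) * vx + (py - ay) * vy) / vv else 0
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (ax + t * vx)
    dy <- py - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

#' Normalized cartilage depth field
#'
#' Computes the normalized depth z in `[0, 1]` for every masked pixel:
#' z = d_surf / (d_surf + d_bone), where d_surf and d_bone are the
#' Euclidean distances to the articular-surface and osteochondral-junction
#' curves. This definition is rotation invariant and reduces to the usual
#' linear depth coordinate on a flat slab. A column-wise alternative
#' (`method = "column"`) measures depth along image columns instead, for
#' flat-slab work.
#'
#' @param sample a `phantom_sample`, or any list with elements `mask`
#'   (logical matrix), `surface_curve` and `bone_curve` (data.frames with
#'   columns `x`, `y` in 0-based pixel coordinates).
#' @param method `"distance"` (default) or `"column"`.
#' @return Object of class `depth_field`: matrix `z` (NA outside the mask),
#'   the `mask`, and the distances `d_surf`, `d_bone` (distance method).
#' @export
compute_depth <- function(sample, method = c("distance", "column")) {
  method <- match.arg(method)
  msk <- sample$mask
  stopifnot(is.matrix(msk), is.logical(msk))
  idx <- which(msk, arr.ind = TRUE)
  py <- idx[, 1] - 1  # 0-based row
  px <- idx[, 2] - 1  # 0-based col
  z <- matrix(NA_real_, nrow(msk), ncol(msk))
  out <- list(mask = msk)
  if (method == "distance") {
    ds <- .dist_to_polyline(px, py, sample$surface_curve)
    db <- .dist_to_polyline(px, py, sample$bone_curve)
    tot <- ds + db
    if (any(tot == 0)) {
      stop("degenerate geometry: pixel equidistant (0) from both curves")
    }
    z[msk] <- ds / tot
    dsm <- matrix(NA_real_, nrow(msk), ncol(msk)); dsm[msk] <- ds
    dbm <- matrix(NA_real_, nrow(msk), ncol(msk)); dbm[msk] <- db
    out$d_surf <- dsm
    out$d_bone <- dbm
  } else {
    ys <- stats::approx(sample$surface_curve$x, sample$surface_curve$y,
                        xout = px, rule = 2)$y
    yb <- stats::approx(sample$bone_curve$x, sample$bone_curve$y,
                        xout = px, rule = 2)$y
    th <- yb - ys
    if (any(th <= 0)) stop("degenerate geometry: non-positive local thickness")
    z[msk] <- pmin(pmax((py - ys) / th, 0), 1)
  }
  out$z <- z
  structure(out, class = "depth_field")
}

#' Assign cartilage zones from normalized depth
#'
#' Labels every masked pixel as superficial (SZ), transitional (TZ) or deep
#' zone (DZ) using half-open depth intervals `[0, b1)`, `[b1, b2)`,
#' `[b2, 1]`; ties at a boundary go to the deeper zone.
#'
#' @param depth a `depth_field`, or a numeric vector/matrix of depths.
#' @param boundaries two strictly increasing values in (0, 1); default
#'   `c(0.15, 0.65)` (SZ 0-15%, TZ 15-65%, DZ 65-100% of sample depth).
#' @return Object of class `zone_labels` with a character matrix (or
#'   vector) `labels` and the `boundaries`.
#' @export
assign_zones <- function(depth, boundaries = c(0.15, 0.65)) {
  if (length(boundaries) != 2 || !all(is.finite(boundaries)) ||
      boundaries[1] <= 0 || boundaries[2] >= 1 ||
      boundaries[1] >= boundaries[2]) {
    stop("zone boundaries must be strictly increasing within (0, 1)")
  }
  z <- if (inherits(depth, "depth_field")) depth$z else depth
  lab <- ifelse(z < boundaries[1], "SZ",
                ifelse(z < boundaries[2], "TZ", "DZ"))
  structure(list(labels = lab, boundaries = boundaries),
            class = "zone_labels")
}

#' Assign central and peripheral regions
#'
#' The central region (CR) is a contiguous band of columns of the stated
#' physical width centered on the mask centroid column; the peripheral
#' region (PR) is the remainder of the mask on both sides.
#'
#' @param mask logical matrix.
#' @param pixel_spacing_mm isotropic pixel size, mm.
#' @param cr_width_mm width of the central band, mm (default 6).
#' @return Object of class `region_labels` with a character matrix
#'   `labels` (`"CR"`/`"PR"`, NA outside mask) and the CR column range.
#' @export
assign_regions <- function(mask, pixel_spacing_mm, cr_width_mm = 6.0) {
  stopifnot(is.matrix(mask), is.logical(mask), pixel_spacing_mm > 0,
            cr_width_mm > 0)
  cols <- which(colSums(mask) > 0)
  width_mm <- length(cols) * pixel_spacing_mm
  if (cr_width_mm > width_mm + 1e-9) {
    stop("central region (", cr_width_mm, " mm) wider than sample (",
         width_mm, " mm)")
  }
  n_cr <- round(cr_width_mm / pixel_spacing_mm)
  centroid <- mean(which(mask, arr.ind = TRUE)[, 2])  # 1-based col centroid
  start <- round(centroid - n_cr / 2 + 0.5)
  cr_cols <- seq(start, length.out = n_cr)
  lab <- matrix(NA_character_, nrow(mask), ncol(mask))
  lab[mask] <- "PR"
  in_cr <- mask & (col(mask) %in% cr_cols)
  lab[in_cr] <- "CR"
  if (!any(lab[mask] == "PR")) {
    warning("central region covers the whole sample; peripheral region empty")
  }
  structure(list(labels = lab, cr_cols = range(cr_cols),
                 cr_width_mm = cr_width_mm),
            class = "region_labels")
}

#' Discretize the mask into rectangular elements
#'
#' Tiles the mask bounding box with square elements of `element_px` pixels
#' a side (rectangular at the boundary), keeping elements that contain at
#' least one masked pixel. Mirrors the rectangular-element discretization
#' of the mid-sagittal imaging plane used to attach depth-dependent tissue
#' properties.
#'
#' @param mask logical matrix.
#' @param depth a `depth_field` on the same grid.
#' @param element_px element edge length in pixels (>= 1).
#' @return Object of class `element_grid`: integer matrix `element_id`
#'   (NA outside mask) and a data.frame `table` with per-element pixel
#'   count and mean depth.
#' @export
discretize <- function(mask, depth, element_px) {
  stopifnot(is.matrix(mask), is.logical(mask), element_px >= 1)
  element_px <- as.integer(element_px)
  idx <- which(mask, arr.ind = TRUE)
  r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
  er <- (idx[, 1] - r0) %/% element_px
  ec <- (idx[, 2] - c0) %/% element_px
  key <- er * (max(ec) + 1L) + ec
  uk <- sort(unique(key))
  eid_pix <- match(key, uk)
  eid <- matrix(NA_integer_, nrow(mask), ncol(mask))
  eid[mask] <- eid_pix
  zv <- depth$z[mask]
  tab <- data.frame(
    element = seq_along(uk),
    row0 = (uk %/% (max(ec) + 1L)) * element_px + r0 - 1L,  # 0-based
    col0 = (uk %% (max(ec) + 1L)) * element_px + c0 - 1L,
    n_pixels = as.integer(table(factor(eid_pix, levels = seq_along(uk)))),
    mean_z = as.numeric(tapply(zv, factor(eid_pix, levels = seq_along(uk)),
                               mean))
  )
  structure(list(element_id = eid, table = tab, element_px = element_px),
            class = "element_grid")
}
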