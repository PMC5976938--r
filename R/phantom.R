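# Synthetic osteochondral phantom.
#
# A convex cartilage cross-section (circular-arc surface, condylar-scale
# curvature, mm-scale thickness) with ground-truth relaxation maps linked
# monotonically to the modelled composition, and simulated magnitude qMRI
# signal stacks under Rician noise. Stands in for raw MRI data so every
# downstream stage is verifiable against a known truth.

#' Default composition-to-relaxation link parameters
#'
#' Synthetic, strictly monotone links mapping the local fluid fraction to
#' relaxation times. Ranges span the physiologic magnitudes of healthy
#' cartilage at 3 T (T1 roughly 550-750 ms, T1rho 40-90 ms, T2* 15-40 ms);
#' relaxation times increase with fluid fraction (hence decrease with
#' collagen/proteoglycan content). These links are test scaffolding, not a
#' biological claim.
#'
#' @param amplitude signal amplitude A at full magnetization.
#' @param noise_floor additive noise floor B of the magnitude signal.
#' @return Named list of link ranges and signal constants.
#' @export
default_link_params <- function(amplitude = 1000, noise_floor = 0) {
  list(t1 = c(550, 750), t1rho = c(40, 90), t2star = c(15, 40),
       amplitude = amplitude, noise_floor = noise_floor)
}

#' Phantom specification
#'
#' @param width_mm sample width (default 15 mm, matching a ca. 1.5 cm
#'   osteochondral block).
#' @param thickness_mm cartilage thickness (default 2.5 mm).
#' @param curvature_per_m surface curvature in 1/m; default 4.4, the mean
#'   curvature of the femoral condyle. 0 gives a flat slab.
#' @param pixel_spacing_mm isotropic pixel size (default 0.1 mm).
#' @param snr signal-to-noise ratio at full amplitude (sigma =
#'   amplitude / snr); `Inf` disables noise.
#' @param seed RNG seed; all stochastic phantom output is reproducible
#'   from it.
#' @param link_params see [default_link_params()].
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(width_mm = 15, thickness_mm = 2.5,
                         curvature_per_m = 4.4, pixel_spacing_mm = 0.1,
                         snr = 50, seed = 1L,
                         link_params = default_link_params()) {
  if (!all(c(width_mm, thickness_mm, pixel_spacing_mm) > 0)) {
    stop("invalid spec: lengths must be positive")
  }
  if (!(snr > 0)) stop("invalid spec: snr must be positive")
  if (curvature_per_m < 0) stop("invalid spec: curvature must be >= 0")
  structure(list(width_mm = width_mm, thickness_mm = thickness_mm,
                 curvature_per_m = curvature_per_m,
                 pixel_spacing_mm = pixel_spacing_mm,
                 snr = snr, seed = as.integer(seed),
                 link_params = link_params),
            class = "phantom_spec")
}

#' Generate the phantom geometry
#'
#' The articular surface is a convex-upward circular arc with the requested
#' curvature; the osteochondral junction is the surface offset by the
#' cartilage thickness. The binary mask contains all pixel centers between
#' the two curves. Curves are returned as ordered polylines in 0-based
#' pixel coordinates (`x` = column, `y` = row; rows increase with depth).
#'
#' @param spec a `phantom_spec`.
#' @return Object of class `phantom_sample`: `mask`, `surface_curve`,
#'   `bone_curve`, `pixel_spacing_mm`.
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dx <- spec$pixel_spacing_mm
  nc <- round(spec$width_mm / dx)
  if (nc < 3 || spec$thickness_mm / dx < 2) {
    stop("invalid spec: width or thickness not representable at pixel ",
         "spacing ", dx, " mm")
  }
  x_mm <- (seq_len(nc) - (nc + 1) / 2) * dx  # column centers, mm from center
  kappa <- spec$curvature_per_m / 1000       # 1/mm
  if (kappa > 0) {
    R <- 1 / kappa
    if (R <= max(abs(x_mm))) {
      stop("invalid spec: curvature too strong for the sample width")
    }
    sag <- R - sqrt(R^2 - x_mm^2)            # 0 at center, max at edges
  } else {
    sag <- rep(0, nc)
  }
  margin <- 2
  y_surf <- margin + sag / dx                # fractional rows, 0-based
  y_bone <- y_surf + spec$thickness_mm / dx
  nr <- ceiling(max(y_bone)) + 3
  rows <- 0:(nr - 1)
  mask <- outer(rows, y_surf, ">=") & outer(rows, y_bone, "<=")
  structure(list(mask = mask,
                 surface_curve = data.frame(x = 0:(nc - 1), y = y_surf),
                 bone_curve = data.frame(x = 0:(nc - 1), y = y_bone),
                 pixel_spacing_mm = dx),
            class = "phantom_sample")
}

#' Ground-truth relaxation maps from modelled composition
#'
#' Each relaxation map is a strictly monotone increasing affine function of
#' the local fluid fraction, rescaled so that the composition model's full
#' fluid-fraction range spans the link range of each parameter. Because the
#' fluid fraction decreases with depth while collagen and proteoglycan
#' increase, relaxation times decrease towards bone, mirroring the sign
#' structure expected of the real tissue.
#'
#' @param sample a `phantom_sample`.
#' @param model a `composition_model`.
#' @param spec the `phantom_spec` (provides link parameters).
#' @return Object of class `ground_truth`: matrices `t1_map`, `t1rho_map`,
#'   `t2star_map` (ms, NA outside mask), `amplitude_map`, scalar
#'   `noise_floor`.
#' @export
make_ground_truth <- function(sample, model = composition_model(), spec) {
  stopifnot(inherits(sample, "phantom_sample"), inherits(spec, "phantom_spec"))
  depth <- compute_depth(sample)
  msk <- sample$mask
  ffv <- composition_at(depth$z[msk], model)$ff
  ffr <- range(model$ff)
  scale01 <- if (diff(ffr) > 0) (ffv - ffr[1]) / diff(ffr) else rep(0.5, length(ffv))
  lp <- spec$link_params
  link <- function(rng) rng[1] + diff(rng) * scale01
  blank <- matrix(NA_real_, nrow(msk), ncol(msk))
  t1 <- blank; t1rho <- blank; t2star <- blank; amp <- blank
  t1[msk] <- link(lp$t1)
  t1rho[msk] <- link(lp$t1rho)
  t2star[msk] <- link(lp$t2star)
  amp[msk] <- lp$amplitude
  structure(list(t1_map = t1, t1rho_map = t1rho, t2star_map = t2star,
                 amplitude_map = amp, noise_floor = lp$noise_floor,
                 depth = depth),
            class = "ground_truth")
}

# magnitude-MRI noise: sqrt((s + n1)^2 + n2^2), n ~ N(0, sigma)
.rician <- function(s, sigma) {
  n <- length(s)
  sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Simulate a qMRI signal stack
#'
#' Computes the noiseless theoretical magnitude signal per pixel and
#' acquisition point and applies Rician noise with sigma = A_max / snr.
#' Signal models: mono-exponential decay over echo time (T2*) or spin-lock
#' duration (T1rho), amplitude times `exp(-t/tau)` plus the noise floor;
#' magnitude inversion recovery for T1,
#' `|A (1 - 2 exp(-TI/T1) + exp(-TR/T1))|`.
#' Background (unmasked) pixels carry pure noise.
#'
#' @param gt a `ground_truth`.
#' @param protocol an `acquisition_protocol`.
#' @param spec the `phantom_spec` (snr and seed). The per-sequence noise
#'   stream is derived deterministically from `spec$seed` and the sequence
#'   kind.
#' @return Object of class `signal_stack`: array `signal`
#'   (rows x cols x acquisition points), `kind`, `times`, `tr_ms`, `mask`.
#' @export
simulate_stack <- function(gt, protocol, spec) {
  stopifnot(inherits(gt, "ground_truth"),
            inherits(protocol, "acquisition_protocol"),
            inherits(spec, "phantom_spec"))
  kind <- protocol$kind
  relax <- switch(kind,
                  T1 = gt$t1_map,
                  T1RHO = gt$t1rho_map,
                  T2STAR = gt$t2star_map,
                  stop("unknown sequence kind: ", kind))
  msk <- !is.na(relax)
  nr <- nrow(relax); ncl <- ncol(relax)
  times <- protocol$times
  S <- array(0, c(nr, ncl, length(times)))
  A <- gt$amplitude_map[msk]
  tau <- relax[msk]
  for (k in seq_along(times)) {
    sk <- matrix(0, nr, ncl)
    if (kind == "T1") {
      m <- abs(1 - 2 * exp(-times[k] / tau) + exp(-protocol$tr_ms / tau))
      sk[msk] <- A * m
    } else {
      sk[msk] <- A * exp(-times[k] / tau) + gt$noise_floor
    }
    S[, , k] <- sk
  }
  if (is.finite(spec$snr)) {
    sigma <- max(A) / spec$snr
    off <- c(T1 = 101L, T1RHO = 202L, T2STAR = 303L)[[kind]]
    set.seed((abs(spec$seed) * 1009L + off) %% .Machine$integer.max)
    S <- array(.rician(as.vector(S), sigma), dim(S))
  }
  structure(list(signal = S, kind = kind, times = times,
                 tr_ms = protocol$tr_ms, mask = msk),
            class = "signal_stack")
}
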