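# Pixel-wise qMRI signal-model fitting.
#
# Three magnitude signal models are fitted per pixel in a least-squares
# sense:
#   T2*   : S(TE)  = A exp(-TE / T2*)        [+ B]
#   T1rho : S(TSL) = A exp(-TSL / T1rho)     [+ B]
#   T1    : S(TI)  = | A (1 - 2 exp(-TI/T1) + exp(-TR/T1)) |
# A is the signal amplitude and B the noise floor. The fits use variable
# projection: for a fixed time constant the remaining parameters are
# linear and solved in closed form, leaving a one-dimensional profiled sum
# of squares that is minimized over a log-spaced grid with local Brent
# refinement (robust on the magnitude-inversion-recovery polarity fold,
# where the objective is non-smooth).

#' Acquisition protocol
#'
#' Timing parameters of one quantitative MRI series.
#'
#' @param kind one of `"T1"` (inversion recovery, times = inversion times
#'   TI), `"T1RHO"` (spin-lock, times = spin-lock durations), `"T2STAR"`
#'   (multi-gradient echo, times = echo times TE). All times in ms.
#' @param times strictly increasing, non-negative times (ms).
#' @param tr_ms repetition time (ms); required for `"T1"` and must exceed
#'   the longest inversion time.
#' @return Object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(kind = c("T1", "T1RHO", "T2STAR"),
                                 times, tr_ms = NULL) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) < 2 || any(!is.finite(times)) || any(times < 0) ||
      any(diff(times) <= 0)) {
    stop("times must be finite, non-negative and strictly increasing")
  }
  if (kind == "T1") {
    if (is.null(tr_ms) || !(tr_ms > max(times))) {
      stop("T1 inversion recovery requires tr_ms > max(TI)")
    }
  }
  structure(list(kind = kind, times = times,
                 tr_ms = if (kind == "T1") as.numeric(tr_ms) else NULL),
            class = "acquisition_protocol")
}

#' Default acquisition protocols
#'
#' The three mapping sequences with their standard timing series:
#' inversion times 150/300/500/800/1000/1300/1500 ms at TR 3000 ms (T1),
#' spin-lock durations 0/10/20/30/40 ms (T1rho), and echo times
#' 3.9 + n x 6.9 ms for n = 0..14 (T2*).
#'
#' @return Named list of `acquisition_protocol` objects.
#' @export
default_protocols <- function() {
  list(
    T1 = acquisition_protocol("T1",
                              c(150, 300, 500, 800, 1000, 1300, 1500),
                              tr_ms = 3000),
    T1RHO = acquisition_protocol("T1RHO", c(0, 10, 20, 30, 40)),
    T2STAR = acquisition_protocol("T2STAR", 3.9 + (0:14) * 6.9)
  )
}

#' Restrict a T2* protocol to short echoes
#'
#' Only echo times strictly below the cutoff are retained for T2* mapping
#' (long echoes are noise-floor dominated). The returned protocol carries
#' the retained indices as attribute `keep_idx`, which [fit_map()] uses to
#' subset a full-length signal stack.
#'
#' @param protocol a `T2STAR` `acquisition_protocol`.
#' @param max_te_ms echo-time cutoff, ms (default 60; strict inequality).
#' @return The filtered `acquisition_protocol`.
#' @export
filter_echoes <- function(protocol, max_te_ms = 60) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  if (protocol$kind != "T2STAR") {
    stop("echo filtering applies to T2STAR protocols only")
  }
  keep <- which(protocol$times < max_te_ms)
  if (length(keep) < 3) {
    stop("insufficient data: fewer than 3 echo times below ", max_te_ms,
         " ms")
  }
  out <- acquisition_protocol("T2STAR", protocol$times[keep])
  attr(out, "keep_idx") <- keep
  out
}

#' Adjusted coefficient of determination
#'
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - p - 1)` with
#' `R2 = 1 - SSE / SST`.
#'
#' @param residuals fit residuals.
#' @param signal observed signal values.
#' @param n_params number of fitted parameters p.
#' @return Scalar adjusted R-squared; `NA` (with a warning) when the signal
#'   has zero variance.
#' @export
adjusted_r2 <- function(residuals, signal, n_params) {
  n <- length(signal)
  stopifnot(length(residuals) == n)
  if (n <= n_params + 1) {
    stop("need more observations than parameters + 1")
  }
  sst <- sum((signal - mean(signal))^2)
  if (sst <= 0) {
    warning("zero total variance: adjusted R-squared undefined")
    return(NA_real_)
  }
  r2 <- 1 - sum(residuals^2) / sst
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

.pixel_fit <- function(relax = NA_real_, amplitude = NA_real_,
                       noise_floor = 0, r2_adj = NA_real_,
                       converged = FALSE, n = NA_integer_, kind = NA) {
  structure(list(relax_ms = relax, amplitude = amplitude,
                 noise_floor = noise_floor, r2_adj = r2_adj,
                 converged = converged, n = n, kind = kind),
            class = "pixel_fit")
}

# profiled SSE of the mono-exponential model at log-tau; returns the SSE,
# or the full linear solution when `full = TRUE`
.monoexp_profile <- function(ltau, y, t, fit_floor, full = FALSE) {
  e <- exp(-t / exp(ltau))
  if (fit_floor) {
    X <- cbind(e, 1)
    cf <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
    # singular basis (constant e): limit is the mean-only fit
    if (is.null(cf)) {
      if (full) return(list(a = 0, b = mean(y), res = y - mean(y)))
      return(sum((y - mean(y))^2))
    }
    r <- y - X %*% cf
    if (full) return(list(a = cf[1], b = cf[2], res = as.numeric(r)))
  } else {
    ee <- sum(e * e)
    # basis underflowed to zero (tau at the short end): amplitude drops out
    if (ee <= 0) {
      if (full) return(list(a = 0, b = 0, res = y))
      return(sum(y * y))
    }
    a <- sum(y * e) / ee
    r <- y - a * e
    if (full) return(list(a = a, b = 0, res = r))
  }
  sum(r * r)
}

# magnitude inversion-recovery model shape (unit amplitude)
.ir_shape <- function(ti, tr, t1) {
  abs(1 - 2 * exp(-ti / t1) + exp(-tr / t1))
}

.ir_profile <- function(lt1, y, ti, tr, full = FALSE) {
  m <- .ir_shape(ti, tr, exp(lt1))
  mm <- sum(m * m)
  if (mm <= 1e-300) {
    if (full) return(list(a = 0, res = y))
    return(sum(y * y))
  }
  a <- max(0, sum(y * m) / mm)
  r <- y - a * m
  if (full) return(list(a = a, res = r))
  sum(r * r)
}

# minimize a 1-D profiled SSE: evaluate on a log-spaced grid, refine every
# local minimum (up to `max_refine`) by Brent search in its bracket
.profile_minimize <- function(sse, lo, hi, n_grid = 60, max_refine = 4,
                              tol = 1e-7) {
  lg <- seq(log(lo), log(hi), length.out = n_grid)
  vals <- vapply(lg, sse, numeric(1))
  if (all(!is.finite(vals))) return(NULL)
  vals[!is.finite(vals)] <- Inf
  is_min <- vapply(seq_along(vals), function(i) {
    l <- if (i > 1) vals[i - 1] else Inf
    r <- if (i < length(vals)) vals[i + 1] else Inf
    vals[i] <= l && vals[i] <= r
  }, logical(1))
  cand <- order(vals)[order(vals) %in% which(is_min)]
  cand <- utils::head(cand, max_refine)
  best <- list(minimum = lg[which.min(vals)], objective = min(vals))
  for (i in cand) {
    a <- lg[max(i - 1, 1)]
    b <- lg[min(i + 1, length(lg))]
    o <- tryCatch(stats::optimize(sse, c(a, b), tol = tol),
                  error = function(e) NULL)
    if (!is.null(o) && o$objective < best$objective) best <- o
  }
  best
}

#' Fit a mono-exponential decay to one pixel
#'
#' Least-squares fit of `A exp(-t/tau) + B` (B fixed at 0 unless
#' `fit_floor`). The time constant is profiled (A, B solved in closed form
#' per candidate tau) and minimized over a log-spaced grid with Brent
#' refinement. tau is capped at 10x the longest acquisition time; hitting
#' the cap, or a degenerate (constant) signal, is reported as
#' `converged = FALSE` rather than an error.
#'
#' @param signal observed magnitude signal.
#' @param times acquisition times (ms), same length.
#' @param fit_floor also fit the additive noise floor B (needs >= 4
#'   points).
#' @return A `pixel_fit`: `relax_ms`, `amplitude`, `noise_floor`,
#'   `r2_adj`, `converged`.
#' @export
fit_monoexp <- function(signal, times, fit_floor = FALSE) {
  if (any(!is.finite(signal))) stop("non-finite signal values")
  n <- length(signal)
  stopifnot(length(times) == n)
  if (n < 3 + fit_floor) {
    stop("need at least ", 3 + fit_floor, " acquisition points")
  }
  n_par <- 2L + fit_floor
  if (sd(signal) == 0) {
    return(.pixel_fit(amplitude = signal[1], n = n, kind = "monoexp"))
  }
  tpos <- times[times > 0]
  cap <- 10 * max(times)
  lo <- min(tpos) / 20
  best <- .profile_minimize(function(lt) .monoexp_profile(lt, signal, times,
                                                          fit_floor),
                            lo, cap)
  if (is.null(best)) return(.pixel_fit(n = n, kind = "monoexp"))
  tau <- exp(best$minimum)
  sol <- .monoexp_profile(best$minimum, signal, times, fit_floor,
                          full = TRUE)
  r2a <- adjusted_r2(sol$res, signal, n_par)
  conv <- is.finite(tau) && tau < 0.999 * cap && is.finite(sol$a)
  .pixel_fit(relax = tau, amplitude = sol$a, noise_floor = sol$b,
             r2_adj = r2a, converged = conv, n = n, kind = "monoexp")
}

#' Fit magnitude inversion recovery to one pixel
#'
#' Least-squares fit of `|A (1 - 2 exp(-TI/T1) + exp(-TR/T1))|` to a
#' magnitude-reconstructed inversion-recovery series. Clinical magnitude
#' reconstruction destroys the sign of the recovery curve, which folds the
#' objective at the null point; the profiled T1 objective is therefore
#' minimized with multi-start refinement over a log-spaced grid so the fit
#' escapes the polarity fold.
#'
#' @param signal observed magnitude signal.
#' @param ti inversion times (ms).
#' @param tr_ms repetition time (ms).
#' @return A `pixel_fit` (noise floor fixed at 0 for this model).
#' @export
fit_ir <- function(signal, ti, tr_ms) {
  if (any(!is.finite(signal))) stop("non-finite signal values")
  n <- length(signal)
  stopifnot(length(ti) == n, tr_ms > max(ti))
  if (n < 4) stop("need at least 4 inversion times")
  if (sd(signal) == 0) {
    return(.pixel_fit(amplitude = signal[1], n = n, kind = "ir"))
  }
  cap <- 10 * max(ti)
  lo <- min(ti[ti > 0]) / 10
  best <- .profile_minimize(function(lt) .ir_profile(lt, signal, ti, tr_ms),
                            lo, cap, n_grid = 80, max_refine = 6)
  if (is.null(best)) return(.pixel_fit(n = n, kind = "ir"))
  t1 <- exp(best$minimum)
  sol <- .ir_profile(best$minimum, signal, ti, tr_ms, full = TRUE)
  r2a <- adjusted_r2(sol$res, signal, 2L)
  conv <- is.finite(t1) && t1 < 0.999 * cap && sol$a > 0
  .pixel_fit(relax = t1, amplitude = sol$a, noise_floor = 0,
             r2_adj = r2a, converged = conv, n = n, kind = "ir")
}

#' Fit a whole signal stack into a parameter map
#'
#' Dispatches every masked pixel of a simulated or measured stack to the
#' fitter matching the sequence kind, then applies quality control: pixels
#' whose adjusted R-squared falls below `qc` (default 0.95), or whose fit
#' did not converge, are flagged and excluded from downstream statistics.
#'
#' @param stack a `signal_stack`, or a 3-D array
#'   (rows x cols x acquisition points).
#' @param protocol an `acquisition_protocol`; defaults to the protocol
#'   embedded in the stack. A protocol produced by [filter_echoes()]
#'   subsets the stack's acquisition dimension via its retained indices.
#' @param mask logical matrix of pixels to fit; defaults to the stack's
#'   mask.
#' @param qc adjusted R-squared quality-control threshold.
#' @param fit_floor fit the noise floor B in mono-exponential models.
#' @return Object of class `parameter_map`: matrices `relax_ms`,
#'   `amplitude`, `noise_floor`, `r2_adj`, logical `converged` and
#'   `qc_pass`, plus `kind`, `qc_threshold`, `mask`.
#' @export
fit_map <- function(stack, protocol = NULL, mask = NULL, qc = 0.95,
                    fit_floor = FALSE) {
  if (inherits(stack, "signal_stack")) {
    S <- stack$signal
    if (is.null(mask)) mask <- stack$mask
    if (is.null(protocol)) {
      protocol <- acquisition_protocol(stack$kind, stack$times,
                                       tr_ms = stack$tr_ms)
    }
  } else {
    S <- stack
    if (is.null(protocol) || is.null(mask)) {
      stop("array input requires both protocol and mask")
    }
  }
  keep <- attr(protocol, "keep_idx")
  if (!is.null(keep) && dim(S)[3] != length(protocol$times)) {
    S <- S[, , keep, drop = FALSE]
  }
  if (dim(S)[3] != length(protocol$times)) {
    stop("stack and protocol lengths disagree (", dim(S)[3], " vs ",
         length(protocol$times), ")")
  }
  nr <- dim(S)[1]; ncl <- dim(S)[2]
  blank <- function(mode = NA_real_) matrix(mode, nr, ncl)
  relax <- blank(); amp <- blank(); floor_ <- blank(); r2 <- blank()
  conv <- matrix(FALSE, nr, ncl)
  idx <- which(mask)
  arr <- matrix(S, nr * ncl, dim(S)[3])  # pixel-major view
  for (i in idx) {
    y <- arr[i, ]
    f <- if (protocol$kind == "T1") {
      fit_ir(y, protocol$times, protocol$tr_ms)
    } else {
      fit_monoexp(y, protocol$times, fit_floor = fit_floor)
    }
    relax[i] <- f$relax_ms
    amp[i] <- f$amplitude
    floor_[i] <- f$noise_floor
    r2[i] <- f$r2_adj
    conv[i] <- f$converged
  }
  qc_pass <- conv & !is.na(r2) & r2 >= qc
  structure(list(relax_ms = relax, amplitude = amp, noise_floor = floor_,
                 r2_adj = r2, converged = conv, qc_pass = qc_pass,
                 kind = protocol$kind, qc_threshold = qc, mask = mask),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  n <- sum(x$mask)
  cat("<parameter_map> ", x$kind, ": ", n, " pixels, ",
      round(100 * sum(x$qc_pass) / n, 1), "% pass QC (adj. R2 >= ",
      x$qc_threshold, ")\n", sep = "")
  invisible(x)
}
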