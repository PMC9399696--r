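# hrm_core: raw melt curves -> derivative melt peaks, normalized curves on an
# analysis window, and difference curves against an automatically selected
# reference. These are the standard HRM constructions: fluorescence is
# rescaled between fitted pre-melt (~1) and post-melt (~0) baselines, and
# each well is compared to a "typical" curve by pointwise subtraction.

#' HRM processing parameters
#'
#' @param pre_window,post_window `(low, high)` temperature pairs (C) framing
#'   the pre-melt and post-melt baseline fit regions. Defaults 78-82 and
#'   90-94 bracket amplicons melting at 84-85.5 C; wide windows keep the
#'   extrapolated baselines stable across the analysis window.
#' @param sg_window,sg_order Savitzky-Golay smoothing window (points, odd)
#'   and polynomial order used before differentiation.
#' @param peak_prominence_frac Peak prominence floor as a fraction of the
#'   largest derivative value (per plate when processed together).
#' @param min_peak_separation Minimum separation (C) between reported peaks.
#' @param amplitude_floor Minimum relative fluorescence drop from pre- to
#'   post-melt region for a well to count as amplified.
#' @param max_cycles Cq values at or beyond this count as non-amplified.
#' @return A list of class `hrm_params`.
#' @export
hrm_params <- function(pre_window = c(78, 82), post_window = c(90, 94),
                       sg_window = 3L, sg_order = 2L,
                       peak_prominence_frac = 0.05,
                       min_peak_separation = 1.0,
                       amplitude_floor = 0.1,
                       max_cycles = 45L) {
  stopifnot(
    length(pre_window) == 2L, length(post_window) == 2L,
    pre_window[1] < pre_window[2], post_window[1] < post_window[2],
    pre_window[2] < post_window[1],
    sg_window %% 2L == 1L, sg_order < sg_window
  )
  structure(as.list(environment()), class = "hrm_params")
}

#' Negative first derivative of a melt curve
#'
#' `-dF/dT` by central differences after light Savitzky-Golay smoothing
#' (local polynomial fit). Melt transitions appear as peaks.
#'
#' @param curve A [melt_curve()].
#' @param sg_window,sg_order Smoothing window (odd number of points) and
#'   polynomial order.
#' @return A list of class `melt_derivative` with `well_id`, `temperature`
#'   and `dfdt` (same length as the input grid).
#' @export
negative_derivative <- function(curve, sg_window = 3L, sg_order = 2L) {
  stopifnot(inherits(curve, "melt_curve"))
  n <- length(curve$temperature)
  if (n < sg_window) {
    abort("curve shorter than the smoothing support", "meltsex_value_error")
  }
  y <- signal::sgolayfilt(curve$rfu, p = sg_order, n = sg_window)
  h <- curve$temperature[2L] - curve$temperature[1L]
  d <- numeric(n)
  d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * h)
  d[1L] <- (y[2L] - y[1L]) / h
  d[n] <- (y[n] - y[n - 1L]) / h
  structure(
    list(well_id = curve$well_id, temperature = curve$temperature, dfdt = -d),
    class = "melt_derivative"
  )
}

# Topographic prominence of the local maximum at index i: height above the
# higher of the two bounding valleys, each valley taken between the peak and
# the nearest strictly higher point (or the trace end) on that side.
peak_prominence_at <- function(y, i) {
  h <- y[i]
  lmin <- h
  j <- i - 1L
  while (j >= 1L && y[j] <= h) {
    if (y[j] < lmin) lmin <- y[j]
    j <- j - 1L
  }
  rmin <- h
  j <- i + 1L
  while (j <= length(y) && y[j] <= h) {
    if (y[j] < rmin) rmin <- y[j]
    j <- j + 1L
  }
  h - max(lmin, rmin)
}

#' Estimate melting temperatures from a derivative trace
#'
#' Local maxima of `-dF/dT` exceeding a prominence floor and separated by at
#' least `min_separation` are reported as melt peaks; each is refined by a
#' quadratic fit through its three nearest grid points. An empty peak list
#' signals a flat or non-amplified well.
#'
#' The prominence floor combines two guards: `min_prominence` (by default
#' `prominence_frac` times this trace's maximum; pass the plate-wide value
#' when processing many wells together) and `noise_mult` robust noise
#' standard deviations of the derivative, estimated from the median absolute
#' successive difference of the trace. The second guard suppresses noise
#' bumps riding the flat pre- and post-melt regions and leaves flat
#' (non-amplified) wells with an empty peak list.
#'
#' @param deriv A `melt_derivative` from [negative_derivative()].
#' @param min_prominence Absolute prominence floor; defaults to
#'   `prominence_frac` times this trace's maximum.
#' @param min_separation Minimum peak separation (C).
#' @param prominence_frac Fraction used for the default floor.
#' @param noise_mult Multiplier of the robust derivative noise s.d. added
#'   to the floor.
#' @return A list of class `melt_peaks` with `well_id` and `peaks`, a data
#'   frame of `(tm, prominence)` sorted by temperature.
#' @export
estimate_tms <- function(deriv, min_prominence = NULL, min_separation = 1.0,
                         prominence_frac = 0.05, noise_mult = 5) {
  stopifnot(inherits(deriv, "melt_derivative"))
  y <- deriv$dfdt
  temp <- deriv$temperature
  n <- length(y)
  if (is.null(min_prominence)) {
    min_prominence <- prominence_frac * max(y, 0)
  }
  # successive differences of the derivative have noise s.d. sigma/h for
  # point noise sigma; the derivative itself sigma/(h*sqrt(2))
  noise_sd <- stats::mad(diff(y)) / sqrt(2)
  min_prominence <- max(min_prominence, noise_mult * noise_sd)
  empty <- data.frame(tm = numeric(0), prominence = numeric(0))
  result <- function(peaks) {
    structure(list(well_id = deriv$well_id, peaks = peaks),
              class = "melt_peaks")
  }
  if (max(y) <= 0 || min_prominence <= 0) return(result(empty))

  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] & y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(result(empty))
  prom <- vapply(cand, function(i) peak_prominence_at(y, i), numeric(1))
  keep <- prom >= min_prominence & prom > 1e-12
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0L) return(result(empty))

  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (k in ord) {
    if (all(abs(temp[cand[k]] - temp[cand[chosen]]) >= min_separation)) {
      chosen <- c(chosen, k)
    }
  }
  cand <- cand[chosen]
  prom <- prom[chosen]

  h <- temp[2L] - temp[1L]
  tm <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
    if (denom >= 0) return(temp[i])
    off <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
    temp[i] + max(min(off, 0.5), -0.5) * h
  }, numeric(1))

  ordt <- order(tm)
  result(data.frame(tm = tm[ordt], prominence = prom[ordt]))
}

#' Normalize a melt curve between pre- and post-melt baselines
#'
#' Fits a straight line to the points inside `pre_window` (upper baseline
#' `U(T)`) and inside `post_window` (lower baseline `L(T)`), then rescales
#' `value(T) = (F(T) - L(T)) / (U(T) - L(T))`, clipped to `[0, 1]`, over the
#' analysis window `[pre_window[2], post_window[1]]`.
#'
#' @param curve A [melt_curve()] (or an already-normalized curve, whose
#'   `values` are then treated as the fluorescence trace).
#' @param pre_window,post_window `(low, high)` C pairs, each spanning >= 3
#'   grid points, pre below post, both inside the curve's grid.
#' @return A list of class `normalized_curve` with `well_id`, `temperature`
#'   (analysis-window grid), `values` in `[0, 1]`, `pre_window`,
#'   `post_window`.
#' @export
normalize_curve <- function(curve, pre_window = c(78, 82),
                            post_window = c(90, 94)) {
  temp <- curve$temperature
  f <- if (!is.null(curve$rfu)) curve$rfu else curve$values
  if (is.null(f)) abort("curve has neither rfu nor values",
                        "meltsex_value_error")
  stopifnot(pre_window[1] < pre_window[2], post_window[1] < post_window[2])
  if (pre_window[2] >= post_window[1]) {
    abort("pre_window must lie below post_window", "meltsex_value_error")
  }
  pre_idx <- which(temp >= pre_window[1] & temp <= pre_window[2])
  post_idx <- which(temp >= post_window[1] & temp <= post_window[2])
  if (length(pre_idx) < 3L || length(post_idx) < 3L) {
    abort("each baseline window must span >= 3 grid points",
          "meltsex_value_error")
  }
  # baselines are fitted on a lightly smoothed trace (the fitted lines are
  # extrapolated across the analysis window, so fit noise tilts the whole
  # normalized curve); the normalized values themselves use the raw trace
  fsm <- if (length(f) >= 5L) signal::sgolayfilt(f, p = 2, n = 5) else f
  fit_line <- function(idx) {
    stats::lm.fit(cbind(1, temp[idx]), fsm[idx])$coefficients
  }
  u <- fit_line(pre_idx)
  l <- fit_line(post_idx)
  win <- which(temp >= pre_window[2] & temp <= post_window[1])
  tw <- temp[win]
  U <- u[1L] + u[2L] * tw
  L <- l[1L] + l[2L] * tw
  denom <- U - L
  if (any(denom <= 0)) {
    abort(sprintf(
      "well '%s': degenerate baselines (upper <= lower inside the analysis window); flat or non-amplified well",
      curve$well_id %||% "?"
    ), "meltsex_degenerate_baseline")
  }
  vals <- pmin(pmax((f[win] - L) / denom, 0), 1)
  structure(
    list(well_id = curve$well_id, temperature = tw, values = vals,
         pre_window = pre_window, post_window = post_window),
    class = "normalized_curve"
  )
}

#' Select the reference ("typical") curve
#'
#' Returns the medoid of the QC-passing normalized curves: the well whose
#' summed max-abs shape distance to all other passing wells is smallest.
#' Ties are broken by lexicographic well id. With a sex-mixed plate the
#' majority shape (typically the male group) wins the medoid.
#'
#' @param normalized Named list of [normalize_curve()] outputs.
#' @param qc_pass Optional character vector of passing well ids (default:
#'   all).
#' @return The reference well id.
#' @export
select_reference <- function(normalized, qc_pass = NULL) {
  ids <- sort(names(normalized))
  if (!is.null(qc_pass)) ids <- ids[ids %in% qc_pass]
  if (length(ids) == 0L) {
    abort("no QC-passing curves to select a reference from",
          "meltsex_value_error")
  }
  if (length(ids) == 1L) return(ids)
  V <- do.call(rbind, lapply(normalized[ids], function(x) x$values))
  D <- as.matrix(stats::dist(V, method = "maximum"))
  ids[which.min(rowSums(D))]
}

#' Difference curve against a reference
#'
#' Pointwise subtraction `curve - reference` on a shared analysis window.
#' Females against a male reference show a pronounced negative excursion
#' near the XIST transition; males are comparatively flat.
#'
#' @param normalized,reference [normalize_curve()] outputs on identical
#'   grids.
#' @return A list of class `difference_curve` with `well_id`,
#'   `reference_well_id`, `temperature`, `values` in `[-1, 1]`.
#' @export
difference_curve <- function(normalized, reference) {
  if (length(normalized$temperature) != length(reference$temperature) ||
      any(abs(normalized$temperature - reference$temperature) > 1e-9)) {
    abort("difference_curve requires identical analysis grids",
          "meltsex_value_error")
  }
  structure(
    list(well_id = normalized$well_id,
         reference_well_id = reference$well_id,
         temperature = normalized$temperature,
         values = normalized$values - reference$values),
    class = "difference_curve"
  )
}
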