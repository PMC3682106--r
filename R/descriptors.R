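#' Compression-modulus profile of an isotherm
#'
#' Computes the in-plane compression modulus Cs-1 = -A (dpi/dA) along a
#' compression run. The derivative dpi/dA is taken from a local
#' least-squares polynomial (degree 3) fitted in a sliding window, which
#' tames the +-0.1 mN/m sensor noise that makes raw finite differences
#' unusable. The profile is reported up to the first collapse; the full
#' arrays are retained internally for collapse detection.
#'
#' @param iso an `isotherm`.
#' @param smoothing_window odd number of points in the local fit (>= 5,
#'   default 11).
#' @return An object of class `compression_profile` with fields `pressure`,
#'   `area`, `cs_inv` (pre-collapse branch), `cs_inv_max`, `pressure_at_max`,
#'   and full-curve fields used by [detect_collapses()].
#' @export
compression_modulus <- function(iso, smoothing_window = 11L) {
  stopifnot(inherits(iso, "isotherm"))
  smoothing_window <- as.integer(smoothing_window)
  if (smoothing_window < 5L) stop("smoothing window must be >= 5 points", call. = FALSE)
  if (length(iso$area) < smoothing_window) {
    stop("too few points for the smoothing window", call. = FALSE)
  }
  area <- iso$area; pressure <- iso$pressure # acquisition order: decreasing area
  fit <- .local_poly(area, pressure, window = smoothing_window, degree = 3L)
  dpda <- fit$deriv
  cs_full <- -area * dpda
  idx <- .collapse_indices(fit$smooth, area, dpda)
  cut <- if (length(idx)) idx[1L] - 1L else length(area)
  branch <- seq_len(cut)
  # for the maximum, skip the sub-lift-off tail (pi ~ 0, modulus undefined)
  # and the points whose fit window straddles the lift-off kink, where the
  # polynomial derivative overshoots
  half <- (smoothing_window - 1L) %/% 2L
  i_lift <- which(fit$smooth >= 0.5)[1L]
  eligible <- branch[branch >= i_lift + half + 2L]
  if (!length(eligible)) eligible <- branch[fit$smooth[branch] >= 0.5]
  if (!length(eligible)) eligible <- branch
  imax <- eligible[which.max(cs_full[eligible])]
  structure(list(
    pressure = pressure[branch],
    area = area[branch],
    cs_inv = cs_full[branch],
    cs_inv_max = cs_full[imax],
    pressure_at_max = pressure[imax],
    pressure_full = pressure,
    pressure_smooth = fit$smooth,
    area_full = area,
    cs_inv_full = cs_full,
    dpda_full = dpda,
    collapse_cut = cut,
    smoothing_window = smoothing_window
  ), class = "compression_profile")
}

#' @export
print.compression_profile <- function(x, ...) {
  cat(sprintf("<compression_profile> Cs-1 max %.1f mN/m at pi = %.2f mN/m (%d branch points)\n",
              x$cs_inv_max, x$pressure_at_max, length(x$cs_inv)))
  invisible(x)
}

# Collapse onsets on a compression run. A collapse is the first point
# (above `min_pressure`, on the rising branch) where |dpi/dA| drops below
# `slope_fraction` of its running maximum, or where the pressure falls on
# further compression. After an onset, the search resumes once the slope
# re-steepens above 3x the post-collapse plateau slope and the pressure
# exceeds the previous collapse pressure (secondary collapse of the other
# component). Returns onset indices in acquisition order.
.collapse_indices <- function(pressure, area, dpda,
                              slope_fraction = 0.1, min_pressure = 5,
                              drop_tol = 0.75, run = 3L) {
  n <- length(pressure)
  absd <- abs(dpda)
  events <- integer(0)
  runmax <- 0
  maxp <- -Inf
  plateau_slope <- NA_real_
  resteep <- 0L
  hit <- 0L
  state <- "search"
  for (i in seq_len(n)) {
    p <- pressure[i]; s <- absd[i]
    if (state == "search") {
      flat <- p > min_pressure && runmax > 0 &&
        (s < slope_fraction * runmax || p < maxp - drop_tol)
      if (flat) {
        # require the condition to persist: a single-point dip can be
        # smoothing ringing or noise at a transition-plateau corner
        hit <- hit + 1L
      } else {
        hit <- 0L
        runmax <- max(runmax, s)
        maxp <- max(maxp, p)
      }
      if (hit >= run) {
        onset <- i - run + 1L
        # confirm: over the following stretch the film must stay flat
        # (median slope below threshold) or keep losing pressure -- a
        # noisy LE-LC transition plateau passes 3-point runs but not this
        hi <- min(n, onset + 15L)
        med_slope <- stats::median(absd[onset:hi])
        med_drop <- stats::median(maxp - pressure[onset:hi])
        # a secondary event must sit clearly above the previous collapse
        above_prev <- !length(events) ||
          pressure[onset] > pressure[events[length(events)]] + 1
        if (above_prev &&
            (med_slope < slope_fraction * runmax || med_drop > drop_tol)) {
          events <- c(events, onset)
          lo <- min(n, onset + 5L)
          plateau_slope <- stats::median(absd[lo:min(n, onset + 20L)])
          state <- "post"
          resteep <- 0L
        }
        hit <- 0L
      }
    } else {
      hot <- s > 3 * max(plateau_slope, 1e-6) && p > pressure[events[length(events)]]
      resteep <- if (hot) resteep + 1L else 0L
      if (resteep >= 3L) { # require a sustained re-steepening, not smoothing tails
        state <- "search"
        runmax <- s
        maxp <- p
      }
    }
  }
  events
}

#' Detect collapse events
#'
#' Finds the monolayer collapse onset(s) along an isotherm from the
#' smoothed slope profile: the point where |dpi/dA| falls below a fraction
#' of its running maximum, or where pressure decreases on compression.
#' Mixed films of immiscible components can show a second, higher-pressure
#' collapse once the slope re-steepens after the first; such events are
#' reported as `secondary`. An empty result is valid (compression stopped
#' before collapse, or the second collapse lies beyond the barrier range).
#'
#' @param iso an `isotherm`.
#' @param profile its [compression_modulus()] profile.
#' @param slope_fraction collapse threshold as a fraction of the running
#'   maximum slope (default 0.1).
#' @param min_pressure ignore the low-pressure region below this value
#'   (mN/m, default 5), where LE-LC transition plateaus live.
#' @return data.frame with columns `pressure`, `area`, `kind`
#'   ("primary"/"secondary"); zero rows if no collapse is found.
#' @export
detect_collapses <- function(iso, profile, slope_fraction = 0.1, min_pressure = 5) {
  stopifnot(inherits(profile, "compression_profile"))
  idx <- .collapse_indices(profile$pressure_smooth, profile$area_full,
                           profile$dpda_full,
                           slope_fraction = slope_fraction,
                           min_pressure = min_pressure)
  if (!length(idx)) {
    return(data.frame(pressure = numeric(0), area = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  }
  data.frame(pressure = profile$pressure_full[idx],
             area = profile$area_full[idx],
             kind = c("primary", rep("secondary", length(idx) - 1L)),
             stringsAsFactors = FALSE)
}

#' Lift-off area of a compression run
#'
#' The lift-off is the largest area at which the surface pressure first
#' rises measurably above zero. Detection requires `run_length` consecutive
#' points at or above `threshold` (so single-point noise spikes cannot
#' define lift-off); the crossing is then back-extrapolated to pi = 0 along
#' a local linear fit of the early rising branch.
#'
#' @param iso an `isotherm`.
#' @param threshold detection threshold in mN/m (default 0.5, above the
#'   sensor-noise floor).
#' @param run_length number of consecutive qualifying points (default 3).
#' @return lift-off area in Angstrom^2/molecule.
#' @export
lift_off <- function(iso, threshold = 0.5, run_length = 3L) {
  stopifnot(inherits(iso, "isotherm"), threshold > 0)
  i0 <- .lift_off_index(iso$pressure, threshold, as.integer(run_length))
  if (is.na(i0)) {
    stop(sprintf("lift-off detection: pressure never sustains >= %.2f mN/m for %d points",
                 threshold, run_length), call. = FALSE)
  }
  a_cross <- iso$area[i0]
  # local back-extrapolation to pi = 0 over the early rising branch; the
  # window is kept short so branch curvature does not bias the intercept
  upper <- max(3 * threshold, 1.5)
  sel <- which(seq_along(iso$area) >= i0 & iso$pressure <= upper)
  sel <- sel[seq_len(min(length(sel), 30L))]
  if (length(sel) >= 3L) {
    cf <- stats::coef(stats::lm(iso$pressure[sel] ~ iso$area[sel]))
    slope <- cf[[2L]]
    if (is.finite(slope) && slope < -1e-6) {
      a0 <- -cf[[1L]] / slope
      if (a0 > a_cross && a0 - a_cross < 5) return(as.numeric(a0))
    }
  }
  as.numeric(a_cross)
}

#' Extrapolated area A0 of the condensed branch
#'
#' Fits a least-squares line to the steepest (most condensed) part of the
#' isotherm -- all pre-collapse points whose compression modulus is at
#' least `fraction` of its maximum -- and evaluates it at pi = 0. This is
#' the conventional "steepest linear segment" extrapolation.
#'
#' @param iso an `isotherm`.
#' @param profile its [compression_modulus()] profile.
#' @param fraction modulus fraction defining the fit region (default 0.85).
#' @return area intercept at pi = 0 (Angstrom^2/molecule).
#' @export
extrapolated_area <- function(iso, profile, fraction = 0.85) {
  stopifnot(inherits(profile, "compression_profile"),
            fraction > 0, fraction < 1)
  sel <- which(profile$cs_inv >= fraction * profile$cs_inv_max &
                 profile$pressure >= 0.25)
  if (length(sel) < 5L) {
    stop("extrapolated area: fewer than 5 points qualify for the fit; lower `fraction`",
         call. = FALSE)
  }
  cf <- stats::coef(stats::lm(profile$area[sel] ~ profile$pressure[sel]))
  as.numeric(cf[[1L]])
}

#' Classify monolayer phase state from the compression modulus
#'
#' Applies the conventional Davies-Rideal magnitude bands to the maximum
#' compression modulus: < 12.5 mN/m gaseous; 12.5-50 liquid-expanded;
#' 50-100 liquid; 100-250 liquid-condensed; > 250 solid.
#'
#' @param profile a `compression_profile`, or a bare Cs-1 max value (mN/m).
#' @return one of "gaseous", "liquid-expanded", "liquid",
#'   "liquid-condensed", "solid".
#' @export
classify_phase <- function(profile) {
  cs <- if (inherits(profile, "compression_profile")) profile$cs_inv_max else as.numeric(profile)
  stopifnot(is.finite(cs), cs > 0)
  if (cs < 12.5) "gaseous"
  else if (cs < 50) "liquid-expanded"
  else if (cs < 100) "liquid"
  else if (cs <= 250) "liquid-condensed"
  else "solid"
}

#' Detect an LE-LC transition plateau
#'
#' A first-order liquid-expanded/liquid-condensed transition shows as a
#' near-horizontal plateau below the collapse, i.e. a local minimum of the
#' compression modulus (below 30 mN/m) flanked by maxima on both sides.
#'
#' @param iso an `isotherm`.
#' @param profile its [compression_modulus()] profile.
#' @return `NULL` if no transition is present; otherwise a list with
#'   `pressure` (mN/m at the modulus minimum) and `a_start`, `a_end`
#'   (areas bounding the plateau, Angstrom^2/molecule).
#' @export
detect_transition_plateau <- function(iso, profile) {
  stopifnot(inherits(profile, "compression_profile"))
  sel <- which(profile$pressure >= 0.75) # skip the sub-lift-off region
  if (length(sel) < 9L) return(NULL)
  cs <- stats::runmed(profile$cs_inv[sel], 5)
  n <- length(cs)
  best <- NULL
  for (i in 2:(n - 1L)) {
    if (cs[i] >= 30) next
    if (!(cs[i] <= cs[i - 1L] && cs[i] <= cs[i + 1L])) next
    left_max <- max(cs[1:i]); right_max <- max(cs[i:n])
    if (left_max < cs[i] + 10 || right_max < cs[i] + 10) next
    if (is.null(best) || cs[i] < best$val) best <- list(i = i, val = cs[i])
  }
  if (is.null(best)) return(NULL)
  i <- best$i
  thr <- 30
  li <- rev(which(cs[1:i] >= thr)); li <- if (length(li)) li[1L] else 1L
  ri <- which(cs[i:n] >= thr); ri <- if (length(ri)) i + ri[1L] - 1L else n
  list(pressure = profile$pressure[sel[i]],
       a_start = profile$area[sel[li]],
       a_end = profile$area[sel[ri]])
}

#' Full descriptor set of an isotherm
#'
#' Convenience wrapper extracting all per-isotherm characteristics:
#' lift-off area, extrapolated area A0, collapse events, maximum
#' compression modulus, phase class and (if present) the LE-LC transition
#' plateau.
#'
#' @param iso an `isotherm`.
#' @param smoothing_window,lift_off_threshold,slope_fraction,a0_fraction
#'   tuning forwarded to the individual extractors.
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(iso, smoothing_window = 11L, lift_off_threshold = 0.5,
                           slope_fraction = 0.1, a0_fraction = 0.85) {
  profile <- compression_modulus(iso, smoothing_window = smoothing_window)
  collapses <- detect_collapses(iso, profile, slope_fraction = slope_fraction)
  a0 <- tryCatch(extrapolated_area(iso, profile, fraction = a0_fraction),
                 error = function(e) NA_real_)
  lo <- tryCatch(lift_off(iso, threshold = lift_off_threshold),
                 error = function(e) NA_real_)
  structure(list(
    label = iso$label,
    components = iso$components,
    mole_fractions = iso$mole_fractions,
    lift_off_area = lo,
    a0_extrapolated = a0,
    collapses = collapses,
    cs_inv_max = profile$cs_inv_max,
    phase_class = classify_phase(profile),
    transition_plateau = detect_transition_plateau(iso, profile),
    profile = profile
  ), class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  pc <- if (nrow(x$collapses)) {
    paste(sprintf("%.1f mN/m (%s, A = %.1f)", x$collapses$pressure,
                  x$collapses$kind, x$collapses$area), collapse = "; ")
  } else "none detected"
  cat(sprintf(paste0("<descriptor_set> %s\n  lift-off %.1f A2 | A0 %.1f A2 | ",
                     "Cs-1 max %.1f mN/m (%s)\n  collapse: %s\n"),
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$lift_off_area, x$a0_extrapolated, x$cs_inv_max, x$phase_class, pc))
  if (!is.null(x$transition_plateau)) {
    cat(sprintf("  LE-LC transition at %.2f mN/m (A %.1f-%.1f A2)\n",
                x$transition_plateau$pressure, x$transition_plateau$a_start,
                x$transition_plateau$a_end))
  }
  invisible(x)
}
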