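#' Construct a pi-A isotherm
#'
#' An isotherm is a single compression run of a Langmuir monolayer: paired
#' mean-molecular-area (A, in Angstrom^2 per molecule) and surface-pressure
#' (pi, in mN/m) readings, with film composition and temperature metadata.
#' Points are stored in acquisition order, i.e. by decreasing area.
#'
#' @param area numeric vector of mean molecular areas (Angstrom^2/molecule).
#' @param pressure numeric vector of surface pressures (mN/m), same length.
#' @param components character vector of component names (length >= 1).
#' @param mole_fractions numeric vector of mole fractions, one per component,
#'   summing to 1.
#' @param temperature subphase temperature in degrees C.
#' @param label free-text label.
#' @return An object of class `isotherm`.
#' @examples
#' iso <- isotherm(seq(90, 40, length.out = 100),
#'                 seq(0, 30, length.out = 100),
#'                 components = "DPPC")
#' print(iso)
#' @export
isotherm <- function(area, pressure, components = "unknown",
                     mole_fractions = rep(1 / length(components), length(components)),
                     temperature = 20, label = "") {
  ord <- order(area, decreasing = TRUE)
  x <- structure(
    list(area = as.numeric(area)[ord], pressure = as.numeric(pressure)[ord],
         components = as.character(components),
         mole_fractions = as.numeric(mole_fractions),
         temperature = as.numeric(temperature), label = as.character(label)),
    class = "isotherm")
  validate_isotherm(x, original_area = as.numeric(area))
  x
}

#' Validate an isotherm against its invariants
#'
#' Checks array lengths, positivity of areas, the sensor-noise pressure
#' floor (-0.5 mN/m), that the film actually develops pressure
#' (max pi > 1 mN/m), that mole fractions form a distribution, and that
#' areas are non-increasing in acquisition order within a 0.5 Angstrom^2
#' noise tolerance.
#'
#' @param x an `isotherm`.
#' @param original_area optionally, areas in the order they were supplied
#'   (used to check acquisition order before internal sorting).
#' @return `x`, invisibly; stops with a validation error naming the violated
#'   invariant otherwise.
#' @export
validate_isotherm <- function(x, original_area = NULL) {
  fail <- function(msg) stop("isotherm validation: ", msg, call. = FALSE)
  if (length(x$area) != length(x$pressure)) fail("area and pressure lengths differ")
  if (length(x$area) < 10L) fail("fewer than 10 points")
  if (any(!is.finite(x$area)) || any(!is.finite(x$pressure))) fail("non-finite values")
  if (any(x$area <= 0)) fail("all areas > 0")
  if (any(x$pressure < -0.5)) fail("pressures >= -0.5 mN/m")
  if (max(x$pressure) <= 1) fail("max pressure > 1 mN/m")
  if (length(x$mole_fractions) != length(x$components)) {
    fail("one mole fraction per component required")
  }
  if (any(x$mole_fractions < 0) || any(x$mole_fractions > 1)) {
    fail("mole fractions in [0, 1]")
  }
  if (abs(sum(x$mole_fractions) - 1) > 1e-9) fail("mole fractions sum to 1")
  a <- if (is.null(original_area)) x$area else original_area
  if (any(diff(a) > 0.5)) fail("area non-increasing in acquisition order (tolerance 0.5 A2)")
  invisible(x)
}

#' @export
print.isotherm <- function(x, ...) {
  comp <- paste(sprintf("%s (%.3g)", x$components, x$mole_fractions), collapse = ", ")
  cat(sprintf("<isotherm> %s\n  %d points, A %.1f-%.1f A2, pi %.2f-%.2f mN/m, %g degC\n  components: %s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$area), min(x$area), max(x$area),
              min(x$pressure), max(x$pressure), x$temperature, comp))
  invisible(x)
}

#' Surface-pressure grid for excess-area integration
#'
#' A strictly increasing pressure grid starting at exactly 0 mN/m, the lower
#' limit of the excess free-enthalpy integral.
#'
#' @param pi_max top of the grid (mN/m, > 0).
#' @param step grid spacing (mN/m); default 0.25.
#' @return An object of class `pressure_grid` with a `values` field.
#' @export
pressure_grid <- function(pi_max, step = 0.25) {
  stopifnot(is.numeric(pi_max), length(pi_max) == 1L, pi_max > 0, step > 0)
  v <- seq(0, pi_max, by = step)
  if (v[length(v)] < pi_max - 1e-12) v <- c(v, pi_max)
  if (any(diff(v) <= 0) || v[1L] != 0) stop("pressure grid must be strictly increasing from 0", call. = FALSE)
  structure(list(values = v), class = "pressure_grid")
}

# --- CSV dialect -----------------------------------------------------------
# Numeric table: comma-separated, UTF-8, header exactly `area_A2,pressure_mN_m`.
# Metadata travels in a sidecar of the same stem with extension `.meta`,
# key: value lines (components, mole_fractions, temperature_C, label), so the
# numeric table stays readable by any tool.

.sidecar_path <- function(path) paste0(sub("\\.[^.]*$", "", path), ".meta")

#' Write an isotherm to CSV plus a metadata sidecar
#'
#' @param iso an `isotherm`.
#' @param path output CSV path; the sidecar is written next to it with a
#'   `.meta` extension unless `sidecar` is given.
#' @param sidecar optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(iso, path, sidecar = .sidecar_path(path)) {
  validate_isotherm(iso)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines("area_A2,pressure_mN_m", con)
  writeLines(sprintf("%.10g,%.10g", iso$area, iso$pressure), con)
  meta <- c(
    sprintf("components: %s", paste(iso$components, collapse = ",")),
    sprintf("mole_fractions: %s", paste(sprintf("%.12g", iso$mole_fractions), collapse = ",")),
    sprintf("temperature_C: %.10g", iso$temperature),
    sprintf("label: %s", iso$label))
  writeLines(meta, sidecar, useBytes = FALSE)
  invisible(path)
}

#' Read an isotherm from CSV (with optional metadata sidecar)
#'
#' Rows are sorted by decreasing area; rows with exactly duplicated areas are
#' averaged (compression troughs emit them), and the result is validated.
#'
#' @param path CSV file with header `area_A2,pressure_mN_m`.
#' @param metadata optional sidecar path; defaults to the same stem with a
#'   `.meta` extension. A missing sidecar yields neutral metadata.
#' @return A validated `isotherm`.
#' @export
read_isotherm <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse error in ", path, ": no data rows", call. = FALSE)
  header <- trimws(strsplit(lines[1L], ",")[[1L]])
  if (length(header) < 2L || header[1L] != "area_A2" || header[2L] != "pressure_mN_m") {
    stop("parse error in ", path, " line 1: expected header 'area_A2,pressure_mN_m'",
         call. = FALSE)
  }
  n <- length(lines) - 1L
  area <- numeric(n); pressure <- numeric(n)
  for (i in seq_len(n)) {
    parts <- strsplit(lines[i + 1L], ",")[[1L]]
    if (length(parts) < 2L) {
      stop("parse error in ", path, " line ", i + 1L, ": expected two fields", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(parts[1:2]))
    if (any(is.na(vals))) {
      stop("parse error in ", path, " line ", i + 1L, ": malformed numeric field", call. = FALSE)
    }
    area[i] <- vals[1L]; pressure[i] <- vals[2L]
  }
  # average duplicated areas, then sort by decreasing area
  if (anyDuplicated(area)) {
    pressure <- tapply(pressure, area, mean)
    area <- as.numeric(names(pressure))
    pressure <- as.numeric(pressure)
  }
  ord <- order(area, decreasing = TRUE)
  area <- area[ord]; pressure <- pressure[ord]

  meta_path <- if (is.null(metadata)) .sidecar_path(path) else metadata
  components <- "unknown"; fractions <- 1; temperature <- 20; label <- ""
  if (file.exists(meta_path)) {
    ml <- readLines(meta_path, encoding = "UTF-8")
    kv <- function(key) {
      hit <- grep(paste0("^", key, ":"), ml, value = TRUE)
      if (!length(hit)) return(NULL)
      trimws(sub(paste0("^", key, ":"), "", hit[1L]))
    }
    if (!is.null(kv("components"))) components <- trimws(strsplit(kv("components"), ",")[[1L]])
    if (!is.null(kv("mole_fractions"))) fractions <- as.numeric(strsplit(kv("mole_fractions"), ",")[[1L]])
    if (!is.null(kv("temperature_C"))) temperature <- as.numeric(kv("temperature_C"))
    if (!is.null(kv("label"))) label <- kv("label")
  }
  isotherm(area, pressure, components = components, mole_fractions = fractions,
           temperature = temperature, label = label)
}

# First index (acquisition order) of a `run_length`-long run with
# pressure >= threshold; NA when the film never develops pressure.
.lift_off_index <- function(pressure, threshold, run_length) {
  ok <- pressure >= threshold
  if (run_length > 1L) {
    run <- stats::filter(as.numeric(ok), rep(1, run_length), sides = 1)
    idx <- which(run == run_length)
    if (!length(idx)) return(NA_integer_)
    idx[1L] - run_length + 1L
  } else {
    idx <- which(ok)
    if (!length(idx)) return(NA_integer_) else idx[1L]
  }
}

#' Resample an isotherm onto a pressure grid
#'
#' Returns A(pi) on the grid by monotone piecewise-linear interpolation on
#' the pre-collapse branch. The branch is taken as the running-maximum
#' ("record") points of pressure from lift-off onwards, which is robust to
#' sensor noise; A(0) is defined as the lift-off area so integrals over
#' pressure can start at exactly 0. Kinked isotherms (plateaus, collapses)
#' are interpolated linearly on purpose: splines overshoot at kinks.
#'
#' @param iso an `isotherm`.
#' @param grid a `pressure_grid`. The caller must keep the grid below the
#'   first collapse pressure; a grid point above the maximum pre-collapse
#'   pressure raises a range error reporting the usable maximum.
#' @return numeric vector of areas (Angstrom^2/molecule), non-increasing in pi.
#' @export
resample_to_grid <- function(iso, grid) {
  stopifnot(inherits(iso, "isotherm"), inherits(grid, "pressure_grid"))
  a_lift <- lift_off(iso)
  i0 <- .lift_off_index(iso$pressure, threshold = 0.5, run_length = 3L)
  p <- iso$pressure[i0:length(iso$pressure)]
  a <- iso$area[i0:length(iso$area)]
  rec <- p > cummax(c(-Inf, p[-length(p)])) # strict records -> strictly increasing pi
  p <- p[rec]; a <- a[rec]
  usable_max <- max(p)
  want <- grid$values
  if (max(want) > usable_max + 1e-9) {
    stop(sprintf("pressure grid exceeds usable range: requested %.3f mN/m, usable pi_max = %.3f mN/m",
                 max(want), usable_max), call. = FALSE)
  }
  xs <- c(0, p); ys <- c(max(a_lift, a[1L]), a)
  out <- stats::approx(xs, ys, xout = want, method = "linear", ties = "ordered")$y
  cummin_out <- cummin(out)
  cummin_out
}
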