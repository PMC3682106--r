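#' Construct a composition series
#'
#' Holds the isotherms of one mixed system over a mole-fraction grid,
#' together with the pure-component reference isotherms -- the unit of
#' analysis for excess-area and excess-free-enthalpy work.
#'
#' @param system_name free-text name.
#' @param components character vector of 2 or 3 component names.
#' @param pure_isotherms named list of `isotherm`s, one per component.
#' @param mixed_isotherms list of `isotherm`s over the composition grid
#'   (their `components` must be a subset of `components`).
#' @param fixed_pair,fixed_ratio optionally, two host components whose mole
#'   ratio must be constant (within 1e-6) across the mixed films -- the
#'   pseudo-binary ternary design.
#' @return An object of class `composition_series`.
#' @export
composition_series <- function(system_name, components, pure_isotherms,
                               mixed_isotherms, fixed_pair = NULL,
                               fixed_ratio = NULL) {
  fail <- function(msg) stop("composition series: ", msg, call. = FALSE)
  components <- as.character(components)
  if (!length(components) %in% c(2L, 3L)) fail("2 or 3 components supported")
  if (!setequal(names(pure_isotherms), components)) {
    fail("pure_isotherms must be named after the components")
  }
  for (iso in mixed_isotherms) {
    if (!all(iso$components %in% components)) {
      fail("mixed isotherm components must be a subset of the series components")
    }
  }
  if (!is.null(fixed_pair)) {
    if (is.null(fixed_ratio)) fail("fixed_ratio required with fixed_pair")
    for (iso in mixed_isotherms) {
      i1 <- match(fixed_pair[1L], iso$components)
      i2 <- match(fixed_pair[2L], iso$components)
      if (is.na(i1) || is.na(i2)) next
      x1 <- iso$mole_fractions[i1]; x2 <- iso$mole_fractions[i2]
      if (x2 > 0 && abs(x1 / x2 - fixed_ratio) > 1e-6) {
        fail("host-component mole ratio varies across the series")
      }
    }
  }
  structure(list(system_name = system_name, components = components,
                 pure_isotherms = pure_isotherms[components],
                 mixed_isotherms = mixed_isotherms,
                 fixed_pair = fixed_pair, fixed_ratio = fixed_ratio),
            class = "composition_series")
}

#' @export
print.composition_series <- function(x, ...) {
  cat(sprintf("<composition_series> %s: %s; %d mixed films\n", x$system_name,
              paste(x$components, collapse = "/"), length(x$mixed_isotherms)))
  invisible(x)
}

# fractions of `iso` aligned to the series component order (0 for absent)
.aligned_fractions <- function(iso, components) {
  x <- numeric(length(components))
  idx <- match(iso$components, components)
  x[idx] <- iso$mole_fractions
  x
}

#' Ideal mean molecular area of a mixed film
#'
#' The mole-fraction-weighted average of the pure-component mean molecular
#' areas at one surface pressure: `A_id = sum_i X_i A_i`; for a binary film
#' this is `A1 X1 + A2 (1 - X1)`.
#'
#' @param pure_areas areas of the pure components at a common pressure
#'   (Angstrom^2/molecule).
#' @param fractions mole fractions, same length, summing to 1.
#' @return ideal area in Angstrom^2/molecule.
#' @export
ideal_area <- function(pure_areas, fractions) {
  if (length(pure_areas) != length(fractions)) {
    stop("ideal_area: one area per mole fraction required", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("ideal_area: fractions must sum to 1", call. = FALSE)
  }
  sum(fractions * pure_areas)
}

# locate the mixed isotherm matching a composition vector
.find_mixed <- function(series, composition) {
  for (j in seq_along(series$mixed_isotherms)) {
    x <- .aligned_fractions(series$mixed_isotherms[[j]], series$components)
    if (max(abs(x - composition)) < 1e-6) return(j)
  }
  stop("no mixed isotherm at composition (",
       paste(signif(composition, 4), collapse = ", "), ") in the series",
       call. = FALSE)
}

.resample_named <- function(iso, grid, who) {
  tryCatch(resample_to_grid(iso, grid),
           error = function(e) {
             stop(sprintf("%s: %s", who, conditionMessage(e)), call. = FALSE)
           })
}

#' Excess-area and excess-free-enthalpy profile of one mixed film
#'
#' Resamples the mixed film and the pure components onto a common pressure
#' grid, forms the excess area `A_exc(pi) = A_mix(pi) - sum_i X_i A_i(pi)`,
#' and integrates it by the trapezoidal rule from 0 to each grid point:
#' `dG_exc(pi) = N_A * integral_0^pi A_exc dpi'`, converted with the exact
#' factor 6.02214076 J/mol per (Angstrom^2 mN/m). Integration starts at
#' pi = 0 with A(0) taken as the lift-off area of each film.
#'
#' @param series a `composition_series`.
#' @param composition mole-fraction vector aligned to `series$components`,
#'   identifying one mixed film.
#' @param pi_max top of the integration range (mN/m); must stay below the
#'   usable (pre-collapse) range of every involved isotherm.
#' @param grid_step pressure grid spacing (mN/m, default 0.25).
#' @return An object of class `excess_profile` with fields `composition`,
#'   `grid`, `a_mixed`, `a_ideal`, `a_excess` and `dg_excess` (J/mol,
#'   cumulative in pi).
#' @export
excess_gibbs <- function(series, composition, pi_max, grid_step = 0.25) {
  stopifnot(inherits(series, "composition_series"))
  composition <- as.numeric(composition)
  if (length(composition) != length(series$components)) {
    stop("composition must align with the series components", call. = FALSE)
  }
  j <- .find_mixed(series, composition)
  grid <- pressure_grid(pi_max, step = grid_step)
  a_mixed <- .resample_named(series$mixed_isotherms[[j]], grid,
                             who = "mixed isotherm")
  a_ideal <- numeric(length(grid$values))
  for (i in seq_along(series$components)) {
    if (composition[i] == 0) next
    ai <- .resample_named(series$pure_isotherms[[i]], grid,
                          who = paste("pure component", series$components[i]))
    a_ideal <- a_ideal + composition[i] * ai
  }
  a_excess <- a_mixed - a_ideal
  dg <- .ANG2_MNM_TO_J_PER_MOL *
    as.numeric(pracma::cumtrapz(grid$values, a_excess))
  structure(list(composition = composition, grid = grid,
                 a_mixed = a_mixed, a_ideal = a_ideal,
                 a_excess = a_excess, dg_excess = dg),
            class = "excess_profile")
}

#' @export
print.excess_profile <- function(x, ...) {
  pm <- max(x$grid$values)
  cat(sprintf("<excess_profile> X = (%s): dG_exc(%g mN/m) = %.1f J/mol\n",
              paste(signif(x$composition, 4), collapse = ", "), pm,
              x$dg_excess[length(x$dg_excess)]))
  invisible(x)
}

#' Mean-area deviation across a composition series
#'
#' At one fixed surface pressure, tabulates the observed mean molecular
#' area `A12`, the ideal area `A12_id` and the excess area `A_exc` for
#' every mixed film -- the mean-area-versus-composition diagnostic plot of
#' mixed-film work.
#'
#' @param series a `composition_series`.
#' @param pi surface pressure (mN/m), below every film's usable range.
#' @param grid_step resampling step (mN/m).
#' @return data.frame with one `x_<component>` column per component plus
#'   `a12`, `a12_id`, `a_exc`.
#' @export
excess_area_curve <- function(series, pi, grid_step = 0.25) {
  stopifnot(inherits(series, "composition_series"))
  rows <- lapply(series$mixed_isotherms, function(iso) {
    x <- .aligned_fractions(iso, series$components)
    out <- as.list(stats::setNames(x, paste0("x_", series$components)))
    prof <- tryCatch(excess_gibbs(series, x, pi_max = pi, grid_step = grid_step),
                     error = function(e) NULL) # film collapses below pi
    if (is.null(prof)) {
      out$a12 <- NA_real_; out$a12_id <- NA_real_; out$a_exc <- NA_real_
    } else {
      nlast <- length(prof$grid$values)
      out$a12 <- prof$a_mixed[nlast]
      out$a12_id <- prof$a_ideal[nlast]
      out$a_exc <- prof$a_excess[nlast]
    }
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Excess free enthalpy versus composition at fixed pressure
#'
#' Evaluates dG_exc at one surface pressure for every film of the series.
#' The default pressure, 30 mN/m, is the monolayer-bilayer correspondence
#' convention. For ternary pseudo-binary series the default ideal reference
#' is the three-component weighted sum of pure areas; setting
#' `reference = "pseudo_binary"` instead references the binary host film
#' (the guest-free member of the series) plus the pure guest.
#'
#' @param series a `composition_series`.
#' @param pi analysis pressure (mN/m, default 30).
#' @param grid_step resampling step (mN/m).
#' @param reference `"pure"` (default) or `"pseudo_binary"`.
#' @param guest for `"pseudo_binary"`: name of the guest component;
#'   defaults to the last series component.
#' @return data.frame with `x_<component>` columns and `dg_exc` (J/mol).
#' @export
dg_vs_composition <- function(series, pi = 30, grid_step = 0.25,
                              reference = c("pure", "pseudo_binary"),
                              guest = NULL) {
  stopifnot(inherits(series, "composition_series"))
  reference <- match.arg(reference)
  comps <- series$components
  if (reference == "pure") {
    rows <- lapply(series$mixed_isotherms, function(iso) {
      x <- .aligned_fractions(iso, comps)
      prof <- tryCatch(excess_gibbs(series, x, pi_max = pi, grid_step = grid_step),
                       error = function(e) NULL) # film collapses below pi
      out <- as.list(stats::setNames(x, paste0("x_", comps)))
      out$dg_exc <- if (is.null(prof)) NA_real_ else prof$dg_excess[length(prof$dg_excess)]
      as.data.frame(out)
    })
    return(do.call(rbind, rows))
  }
  # pseudo-binary: treat the guest-free host film as one pseudo-component
  if (is.null(guest)) guest <- comps[length(comps)]
  gi <- match(guest, comps)
  if (is.na(gi)) stop("guest component not in the series", call. = FALSE)
  host_j <- NULL
  for (j in seq_along(series$mixed_isotherms)) {
    x <- .aligned_fractions(series$mixed_isotherms[[j]], comps)
    if (x[gi] == 0) host_j <- j
  }
  if (is.null(host_j)) {
    stop("pseudo-binary reference needs the guest-free host film in the series",
         call. = FALSE)
  }
  grid <- pressure_grid(pi, step = grid_step)
  a_host <- .resample_named(series$mixed_isotherms[[host_j]], grid, "host film")
  a_guest <- .resample_named(series$pure_isotherms[[gi]], grid,
                             paste("pure component", guest))
  rows <- lapply(series$mixed_isotherms, function(iso) {
    x <- .aligned_fractions(iso, comps)
    a_mix <- .resample_named(iso, grid, "mixed isotherm")
    a_exc <- a_mix - (x[gi] * a_guest + (1 - x[gi]) * a_host)
    dg <- .ANG2_MNM_TO_J_PER_MOL *
      as.numeric(pracma::cumtrapz(grid$values, a_exc))
    out <- as.list(stats::setNames(x, paste0("x_", comps)))
    out$dg_exc <- dg[length(dg)]
    as.data.frame(out)
  })
  do.call(rbind, rows)
}

#' Fit the interaction strength of a synthetic-style excess-area term
#'
#' Given an excess profile whose excess area follows
#' `A_exc(pi) = -beta * P * (1 + pi/pi_ref)` (the generator's interaction
#' model), recovers beta by least squares through the origin.
#'
#' @param profile an `excess_profile`.
#' @param pair_product product `P` of the interacting pair's mole fractions.
#' @param pi_ref reference pressure of the model (mN/m).
#' @return the fitted beta (Angstrom^2).
#' @export
fit_interaction_beta <- function(profile, pair_product, pi_ref = 30) {
  stopifnot(inherits(profile, "excess_profile"), pair_product > 0)
  z <- 1 + profile$grid$values / pi_ref
  cf <- sum(z * profile$a_excess) / sum(z * z)
  -cf / pair_product
}

#' Collapse-pressure miscibility assessment of a composition series
#'
#' Applies the two-dimensional phase rule: components that mix in a
#' monolayer show a collapse pressure that varies with film composition,
#' while immiscible films collapse independently at the pure-component
#' pressures (possibly as two separate collapses in one isotherm). Each
#' interior composition is classified:
#' \itemize{
#'   \item \emph{immiscible} -- at least two collapses, each matching a
#'     distinct pure component's collapse pressure within `tolerance`; or a
#'     single collapse pinned (together with a neighbouring composition or
#'     pure endpoint) at one pure component's collapse pressure.
#'   \item \emph{miscible} -- a single collapse away from both pure values,
#'     or varying monotonically along the composition grid.
#'   \item \emph{partial} -- anything in between.
#' }
#'
#' @param series a `composition_series`.
#' @param descriptors optional precomputed descriptors: a list with `pure`
#'   (named list of [descriptor_set()]s for the pure components) and
#'   `mixed` (list parallel to the mixed isotherms). Computed on the fly
#'   when `NULL`; an explicit list missing pure components is an error.
#' @param tolerance collapse-pressure matching tolerance (mN/m, default
#'   1.5, reflecting typical isotherm reproducibility).
#' @param guest component whose mole fraction orders the composition grid;
#'   defaults to the last series component.
#' @return An object of class `miscibility_report`: a data.frame with
#'   `x_guest`, `collapses`, `classification` and `rationale`.
#' @export
assess_miscibility <- function(series, descriptors = NULL, tolerance = 1.5,
                               guest = NULL) {
  stopifnot(inherits(series, "composition_series"))
  comps <- series$components
  if (is.null(guest)) guest <- comps[length(comps)]
  gi <- match(guest, comps)
  if (is.null(descriptors)) {
    descriptors <- list(
      pure = lapply(series$pure_isotherms, descriptor_set),
      mixed = lapply(series$mixed_isotherms, descriptor_set))
  }
  if (!all(comps %in% names(descriptors$pure))) {
    stop("assess_miscibility: descriptors for all pure components required",
         call. = FALSE)
  }
  pure_pc <- vapply(descriptors$pure[comps], function(d) {
    if (nrow(d$collapses)) d$collapses$pressure[1L] else NA_real_
  }, numeric(1))

  xg <- vapply(series$mixed_isotherms, function(iso) {
    .aligned_fractions(iso, comps)[gi]
  }, numeric(1))
  interior <- which(xg > 0 & xg < 1)
  ord <- interior[order(xg[interior])]
  pc1 <- vapply(descriptors$mixed, function(d) {
    if (nrow(d$collapses)) d$collapses$pressure[1L] else NA_real_
  }, numeric(1))

  # which pure component (if any) each film's first collapse matches
  match_of <- function(p) {
    if (!is.finite(p)) return(NA_integer_)
    d <- abs(pure_pc - p)
    i <- which.min(d)
    if (length(i) && is.finite(d[i]) && d[i] <= tolerance) i else NA_integer_
  }
  m1 <- vapply(pc1, match_of, integer(1))

  # strict monotone variation across the ordered interior run: every step
  # clearly moves (a flat pinned tail is exactly what the phase rule calls
  # immiscible, so weak monotonicity does not count), total span > tolerance
  run_pc <- pc1[ord]
  step_min <- tolerance / 10
  monotone <- length(run_pc) >= 2L && all(is.finite(run_pc)) &&
    (all(diff(run_pc) > step_min) || all(diff(run_pc) < -step_min)) &&
    (max(run_pc) - min(run_pc)) > tolerance

  rows <- lapply(seq_along(ord), function(kk) {
    j <- ord[kk]
    d <- descriptors$mixed[[j]]
    colls <- d$collapses$pressure
    cls <- "partial"; why <- ""
    if (length(colls) >= 2L && !is.na(m1[j])) {
      # two collapses: the first at a pure component's collapse pressure
      # (that component is ejected), the second from the remaining,
      # enriched film at elevated pressure -- the phase-rule signature of
      # an immiscible mixed monolayer
      cls <- "immiscible"
      why <- sprintf("two independent collapses (%s mN/m); first at the pure %s pressure",
                     paste(sprintf("%.1f", colls), collapse = ", "),
                     comps[m1[j]])
    } else if (length(colls) >= 1L && !is.na(m1[j])) {
      # pinned at a pure value? look at interior neighbours on the grid
      neigh <- c(if (kk > 1L) pc1[ord[kk - 1L]],
                 if (kk < length(ord)) pc1[ord[kk + 1L]])
      neigh <- neigh[is.finite(neigh)]
      pinned <- any(abs(neigh - pure_pc[m1[j]]) <= tolerance)
      if (pinned && !monotone) {
        cls <- "immiscible"
        why <- sprintf("collapse pressure constant at the pure %s value (%.1f mN/m)",
                       comps[m1[j]], pure_pc[m1[j]])
      } else if (monotone) {
        cls <- "miscible"
        why <- "collapse pressure varies monotonically with composition"
      } else {
        cls <- "partial"
        why <- "single collapse near one pure-component value, neighbours vary"
      }
    } else if (length(colls) >= 1L) {
      cls <- "miscible"
      why <- sprintf("collapse at %.1f mN/m, away from both pure-component values",
                     colls[1L])
    } else {
      cls <- "partial"
      why <- "no collapse found within the compressed range"
    }
    data.frame(x_guest = xg[j], collapses = paste(sprintf("%.2f", colls), collapse = ";"),
               classification = cls, rationale = why, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "guest") <- guest
  attr(out, "pure_collapses") <- pure_pc
  attr(out, "tolerance") <- tolerance
  class(out) <- c("miscibility_report", class(out))
  out
}

#' @export
print.miscibility_report <- function(x, ...) {
  cat(sprintf("Miscibility report (guest: %s; tolerance %.2g mN/m)\n",
              attr(x, "guest"), attr(x, "tolerance")))
  pc <- attr(x, "pure_collapses")
  cat("Pure collapse pressures:",
      paste(sprintf("%s %.1f", names(pc), pc), collapse = ", "), "mN/m\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  X = %-5.3g  [%s]  pi_coll = %s  -- %s\n", x$x_guest[i],
                x$classification[i], x$collapses[i], x$rationale[i]))
  }
  invisible(x)
}
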