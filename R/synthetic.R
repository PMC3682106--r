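# Synthetic pi-A isotherms with closed-form ground truth.
#
# The pre-collapse branch follows
#     A(pi) = a_coll + (a_lift - a_coll) * ((pi_coll - pi)/pi_coll)^gamma
# so A(0) = a_lift and A(pi_coll) = a_coll exactly, and every analysis
# stage can be checked against the closed form. An optional LE-LC
# transition plateau of given width is inserted at pi_t (with a small
# 1.5 mN/m pressure rise across it -- real transition plateaus are not
# horizontal, and a perfectly flat one would be indistinguishable from a
# collapse under the phase-rule slope criterion). Post-collapse segments
# (terminal plateau or pressure decline, optional secondary collapse)
# emulate the curve families seen in mixed films.

.PLATEAU_HALF_RISE <- 0.75 # mN/m; pressure rises 2*this across a transition plateau

#' Specify a synthetic isotherm
#'
#' @param a_lift lift-off area, A(0), in Angstrom^2/molecule.
#' @param a_coll area at collapse onset (Angstrom^2/molecule), < `a_lift`.
#' @param pi_coll collapse pressure (mN/m, > 0).
#' @param gamma shape exponent of the pre-collapse branch (> 0); 1 gives a
#'   straight line, larger values a film that stiffens on compression. The
#'   compression modulus at the lift-off end is
#'   `a_lift * pi_coll / (gamma * (a_lift - a_coll))`, which is how fixture
#'   Cs-1 targets are set.
#' @param plateau optional LE-LC transition: `list(pi_t = , width = )` with
#'   `pi_t` in mN/m (< `pi_coll`) and `width` in Angstrom^2.
#' @param post_collapse `"plateau"` (pressure holds, creeping up slightly)
#'   or `"decline"` (pressure falls on further compression).
#' @param second_collapse optional pressure (mN/m, > `pi_coll`) of a
#'   secondary collapse after the primary plateau.
#' @param noise_sd_pi Gaussian pressure noise SD (mN/m); requires `seed`.
#' @param n_points number of sampled points (decreasing area).
#' @param seed RNG seed; mandatory whenever `noise_sd_pi > 0` so fixtures
#'   are reproducible.
#' @param components,mole_fractions,temperature,label isotherm metadata.
#' @return An object of class `isotherm_spec`.
#' @export
isotherm_spec <- function(a_lift, a_coll, pi_coll, gamma = 1,
                          plateau = NULL,
                          post_collapse = c("plateau", "decline"),
                          second_collapse = NULL,
                          noise_sd_pi = 0, n_points = 400L, seed = NULL,
                          components = "X", mole_fractions = 1,
                          temperature = 20, label = "") {
  post_collapse <- match.arg(post_collapse)
  fail <- function(msg) stop("isotherm spec: ", msg, call. = FALSE)
  if (!(a_lift > a_coll && a_coll > 0)) fail("need a_lift > a_coll > 0")
  if (pi_coll <= 0) fail("pi_coll must be > 0")
  if (gamma <= 0) fail("gamma must be > 0")
  if (!is.null(plateau)) {
    if (!is.list(plateau) || is.null(plateau$pi_t) || is.null(plateau$width)) {
      fail("plateau must be list(pi_t=, width=)")
    }
    if (plateau$pi_t >= pi_coll) fail("plateau pi_t must lie below pi_coll")
    if (plateau$width <= 0 || plateau$width >= a_lift - a_coll) {
      fail("plateau width must be in (0, a_lift - a_coll)")
    }
  }
  if (!is.null(second_collapse)) {
    second_collapse <- as.numeric(second_collapse)
    if (second_collapse <= pi_coll) fail("second collapse must exceed pi_coll")
  }
  if (noise_sd_pi < 0) fail("noise_sd_pi must be >= 0")
  if (noise_sd_pi > 0 && is.null(seed)) fail("noisy generation requires a seed")
  structure(list(a_lift = a_lift, a_coll = a_coll, pi_coll = pi_coll,
                 gamma = gamma, plateau = plateau,
                 post_collapse = post_collapse,
                 second_collapse = second_collapse,
                 noise_sd_pi = noise_sd_pi, n_points = as.integer(n_points),
                 seed = seed, components = components,
                 mole_fractions = mole_fractions,
                 temperature = temperature, label = label),
            class = "isotherm_spec")
}

# internal lift-off of the base (plateau-free) branch
.base_lift <- function(spec) {
  if (is.null(spec$plateau)) spec$a_lift else spec$a_lift - spec$plateau$width
}

#' Closed-form pre-collapse branch A(pi) of a synthetic isotherm
#'
#' The exact generating curve, exposed as the oracle for interpolation,
#' resampling and excess-area tests. Defined on pi in `[0, pi_coll]`.
#'
#' @param spec an `isotherm_spec`.
#' @return a vectorised function pi -> area (Angstrom^2/molecule).
#' @export
isotherm_truth <- function(spec) {
  stopifnot(inherits(spec, "isotherm_spec"))
  al <- .base_lift(spec); ac <- spec$a_coll; pc <- spec$pi_coll; g <- spec$gamma
  base <- function(p) ac + (al - ac) * pmax((pc - p) / pc, 0)^g
  if (is.null(spec$plateau)) return(function(p) base(p))
  pt <- spec$plateau$pi_t; w <- spec$plateau$width; h <- .PLATEAU_HALF_RISE
  p_lo <- pt - h; p_hi <- pt + h
  a_top <- base(p_lo) + w # expanded side of the plateau
  a_bot <- base(p_hi)
  function(p) {
    out <- numeric(length(p))
    lo <- p <= p_lo; hi <- p >= p_hi; mid <- !lo & !hi
    out[lo] <- base(p[lo]) + w
    out[hi] <- base(p[hi])
    out[mid] <- a_top + (a_bot - a_top) * (p[mid] - p_lo) / (p_hi - p_lo)
    out
  }
}

# inverse of the truth curve: pi(A) on the pre-collapse branch
.truth_inverse <- function(spec) {
  al <- .base_lift(spec); ac <- spec$a_coll; pc <- spec$pi_coll; g <- spec$gamma
  inv_base <- function(a) pc * (1 - pmin(pmax((a - ac) / (al - ac), 0), 1)^(1 / g))
  if (is.null(spec$plateau)) return(inv_base)
  pt <- spec$plateau$pi_t; w <- spec$plateau$width; h <- .PLATEAU_HALF_RISE
  p_lo <- pt - h; p_hi <- pt + h
  base <- function(p) ac + (al - ac) * pmax((pc - p) / pc, 0)^g
  a_top <- base(p_lo) + w
  a_bot <- base(p_hi)
  function(a) {
    out <- numeric(length(a))
    top <- a >= a_top; bot <- a <= a_bot; mid <- !top & !bot
    out[top] <- inv_base(a[top] - w)
    out[bot] <- inv_base(a[bot])
    out[mid] <- p_lo + (p_hi - p_lo) * (a_top - a[mid]) / (a_top - a_bot)
    out
  }
}

# post-collapse segment: piecewise pi(A) for areas below a_coll, in a list of
# (area-span, slope-per-A2) pieces walked toward smaller areas.
.post_collapse_curve <- function(spec) {
  pieces <- list()
  if (spec$post_collapse == "plateau") {
    slope1 <- 0.02  # slight pressure creep along the collapse plateau
  } else {
    slope1 <- -0.15 # pressure decline: film fails and sheds material
  }
  if (is.null(spec$second_collapse)) {
    pieces[[1L]] <- list(span = 0.25 * spec$a_coll, slope = slope1)
  } else {
    rise_span <- 4
    rise_slope <- (spec$second_collapse - (spec$pi_coll + slope1 * 0.15 * spec$a_coll)) / rise_span
    pieces[[1L]] <- list(span = 0.15 * spec$a_coll, slope = slope1)
    pieces[[2L]] <- list(span = rise_span, slope = rise_slope)
    pieces[[3L]] <- list(span = 0.10 * spec$a_coll, slope = 0.02)
  }
  pieces
}

#' Generate a synthetic isotherm
#'
#' Samples the closed-form curve of an [isotherm_spec()] at `n_points`
#' decreasing areas (including a zero-pressure stretch above lift-off and
#' any post-collapse segments) and adds seeded Gaussian pressure noise.
#'
#' @param spec an `isotherm_spec`.
#' @return a validated `isotherm`.
#' @export
generate_isotherm <- function(spec) {
  stopifnot(inherits(spec, "isotherm_spec"))
  inv <- .truth_inverse(spec)
  a_start <- 1.12 * spec$a_lift
  pieces <- .post_collapse_curve(spec)
  post_span <- sum(vapply(pieces, function(p) p$span, numeric(1)))
  a_end <- max(spec$a_coll - post_span, 0.2 * spec$a_coll)
  areas <- seq(a_start, a_end, length.out = spec$n_points)
  p <- numeric(length(areas))
  pre <- areas >= spec$a_coll
  p[areas > spec$a_lift] <- 0
  mid <- pre & areas <= spec$a_lift
  p[mid] <- inv(areas[mid])
  # post-collapse walk
  post_idx <- which(!pre)
  if (length(post_idx)) {
    a_post <- areas[post_idx]
    pr <- numeric(length(a_post))
    p0 <- spec$pi_coll; a0 <- spec$a_coll
    for (piece in pieces) {
      seg <- a_post <= a0 & a_post > a0 - piece$span
      pr[seg] <- p0 + piece$slope * (a0 - a_post[seg])
      p0 <- p0 + piece$slope * piece$span
      a0 <- a0 - piece$span
    }
    pr[a_post <= a0] <- p0 # anything past the last piece holds
    p[post_idx] <- pr
  }
  if (spec$noise_sd_pi > 0) {
    p <- p + .with_seed(spec$seed, stats::rnorm(length(p), sd = spec$noise_sd_pi))
    p <- pmax(p, -0.49)
  }
  isotherm(areas, p, components = spec$components,
           mole_fractions = spec$mole_fractions,
           temperature = spec$temperature, label = spec$label)
}

#' Ground-truth descriptors of a synthetic isotherm
#'
#' Computes, from the closed form and its analytic derivative (no smoothing,
#' no sampling), the descriptor values the analysis stage should recover:
#' lift-off area, collapse pressure/area, the compression-modulus profile
#' and its maximum, and the extrapolated area A0 obtained by the same
#' fit-region definition as [extrapolated_area()] (points with Cs-1 at
#' least `a0_fraction` of the maximum). The modulus is evaluated on
#' `[0, 0.99 * pi_coll]`: for gamma > 1 the closed-form modulus diverges at
#' the collapse point itself, which no finite-resolution measurement sees.
#'
#' @param spec an `isotherm_spec`.
#' @param a0_fraction fit-region fraction, as in [extrapolated_area()].
#' @return list with `lift_off`, `pi_coll`, `a_coll`, `cs_inv_max`,
#'   `pressure_at_max`, `a0`, and the analytic profile (`pressure`, `area`,
#'   `cs_inv`).
#' @export
truth_descriptors <- function(spec, a0_fraction = 0.85) {
  stopifnot(inherits(spec, "isotherm_spec"))
  al <- .base_lift(spec); ac <- spec$a_coll; pc <- spec$pi_coll; g <- spec$gamma
  p <- seq(0, 0.99 * pc, length.out = 2000L)
  truth <- isotherm_truth(spec)
  a <- truth(p)
  u <- (pc - p) / pc
  dadp <- -(g * (al - ac) / pc) * u^(g - 1)
  if (!is.null(spec$plateau)) {
    pt <- spec$plateau$pi_t; h <- .PLATEAU_HALF_RISE; w <- spec$plateau$width
    base <- function(pp) ac + (al - ac) * ((pc - pp) / pc)^g
    mid <- p > pt - h & p < pt + h
    dadp[mid] <- (base(pt + h) - (base(pt - h) + w)) / (2 * h)
  }
  cs <- a / abs(dadp) # Cs-1 = -A dpi/dA = A / |dA/dpi|
  imax <- which.max(cs)
  sel <- which(cs >= a0_fraction * cs[imax])
  a0 <- as.numeric(stats::coef(stats::lm(a[sel] ~ p[sel]))[[1L]])
  list(lift_off = spec$a_lift, pi_coll = pc, a_coll = ac,
       cs_inv_max = cs[imax], pressure_at_max = p[imax], a0 = a0,
       pressure = p, area = a, cs_inv = cs)
}

#' Specify a synthetic composition series
#'
#' Builds the ground truth for mixing analyses: the mixed film at mole
#' fractions X has
#'   `A_mix(pi) = sum_i X_i A_i(pi) - beta * prod(X[pair]) * (1 + pi/pi_ref)`
#' so `beta = 0` gives exactly ideal mixing, `beta > 0` an area condensation
#' (attraction, negative excess area) and `beta < 0` expansion (repulsion).
#' The analytic excess free enthalpy at pressure pi* is
#'   `dG_exc = -6.02214076 * beta * prod(X[pair]) * (pi* + pi*^2/(2 pi_ref))`
#' J/mol, exposed via [mixture_dg_oracle()].
#'
#' @param components named list of `isotherm_spec`s (2 or 3 components).
#' @param fractions list of mole-fraction vectors (each summing to 1,
#'   ordered as `components`); pure endpoints (X_i = 1) are allowed.
#' @param beta interaction strength in Angstrom^2 (sign as above).
#' @param pi_ref reference pressure of the interaction term (mN/m).
#' @param pair indices (or names) of the interacting component pair.
#' @param mixed_pi_coll optional vector of collapse pressures for the mixed
#'   films (one per fractions entry); default is the X-weighted average of
#'   the component collapse pressures (miscible-like behaviour).
#' @param second_collapse optional vector (NA where absent) of secondary
#'   collapse pressures for the mixed films, emulating immiscible films
#'   that shed one component first.
#' @param noise_sd_pi,seed,n_points sampling controls as in
#'   [isotherm_spec()]; mixture members derive per-member seeds from `seed`.
#' @param system_name label for the series.
#' @param fixed_pair,fixed_ratio optionally name two host components whose
#'   mole-fraction ratio is constant across the series (ternary
#'   pseudo-binary designs); checked on construction.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, fractions, beta = 0, pi_ref = 30,
                         pair = c(1L, 2L), mixed_pi_coll = NULL,
                         second_collapse = NULL,
                         noise_sd_pi = 0, seed = NULL, n_points = 400L,
                         system_name = "synthetic mixture",
                         fixed_pair = NULL, fixed_ratio = NULL) {
  fail <- function(msg) stop("mixture spec: ", msg, call. = FALSE)
  if (is.null(names(components)) || any(!nzchar(names(components)))) {
    fail("components must be a named list of isotherm_spec")
  }
  if (!all(vapply(components, inherits, logical(1), "isotherm_spec"))) {
    fail("components must be isotherm_spec objects")
  }
  k <- length(components)
  if (!k %in% c(2L, 3L)) fail("2 or 3 components supported")
  fractions <- lapply(fractions, as.numeric)
  for (x in fractions) {
    if (length(x) != k) fail("each fractions entry needs one value per component")
    if (abs(sum(x) - 1) > 1e-9) fail("fractions must sum to 1")
    if (any(x < 0 | x > 1)) fail("fractions must lie in [0, 1]")
  }
  if (is.character(pair)) pair <- match(pair, names(components))
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyNA(pair) || any(pair < 1L | pair > k)) {
    fail("pair must index two components")
  }
  if (pi_ref <= 0) fail("pi_ref must be > 0")
  if (!is.null(mixed_pi_coll) && length(mixed_pi_coll) != length(fractions)) {
    fail("mixed_pi_coll needs one value per fractions entry")
  }
  if (!is.null(second_collapse) && length(second_collapse) != length(fractions)) {
    fail("second_collapse needs one value (or NA) per fractions entry")
  }
  if (noise_sd_pi > 0 && is.null(seed)) fail("noisy generation requires a seed")
  if (!is.null(fixed_pair)) {
    idx <- match(fixed_pair, names(components))
    if (anyNA(idx)) fail("fixed_pair names not among components")
    r <- vapply(fractions, function(x) {
      if (x[idx[2L]] == 0) NA_real_ else x[idx[1L]] / x[idx[2L]]
    }, numeric(1))
    r <- r[is.finite(r)]
    if (length(r) && !is.null(fixed_ratio) && any(abs(r - fixed_ratio) > 1e-6)) {
      fail("host-component ratio is not constant at fixed_ratio")
    }
  }
  structure(list(components = components, fractions = fractions, beta = beta,
                 pi_ref = pi_ref, pair = pair, mixed_pi_coll = mixed_pi_coll,
                 second_collapse = second_collapse, noise_sd_pi = noise_sd_pi,
                 seed = seed, n_points = as.integer(n_points),
                 system_name = system_name, fixed_pair = fixed_pair,
                 fixed_ratio = fixed_ratio),
            class = "mixture_spec")
}

#' Analytic excess free enthalpy of a synthetic mixture
#'
#' Closed-form antiderivative of the generator's excess-area term,
#' `-N_A * beta * P * integral(1 + pi/pi_ref) dpi`, in J/mol.
#'
#' @param beta interaction strength (Angstrom^2).
#' @param pair_product product of the interacting pair's mole fractions.
#' @param pi surface pressure(s) at which to evaluate (mN/m).
#' @param pi_ref reference pressure (mN/m).
#' @return excess free enthalpy in J/mol (vectorised over `pi`).
#' @export
mixture_dg_oracle <- function(beta, pair_product, pi, pi_ref = 30) {
  -.ANG2_MNM_TO_J_PER_MOL * beta * pair_product * (pi + pi^2 / (2 * pi_ref))
}

#' Generate a synthetic composition series
#'
#' Produces a [composition_series()]: the pure components (unchanged, from
#' their own specs) and one mixed isotherm per fractions entry, built from
#' the mixing rule documented in [mixture_spec()]. Component curves are
#' clamped at their own collapse areas beyond their collapse pressures;
#' excess-area analyses must in any case stay below the lowest pure
#' collapse, which [excess_gibbs()] enforces.
#'
#' @param spec a `mixture_spec`.
#' @return a `composition_series`.
#' @export
generate_mixture_series <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  nm <- names(spec$components)
  k <- length(nm)
  truths <- lapply(spec$components, isotherm_truth)
  pi_colls <- vapply(spec$components, function(s) s$pi_coll, numeric(1))
  pures <- vector("list", k); names(pures) <- nm
  for (i in seq_len(k)) {
    s <- spec$components[[i]]
    s$label <- if (nzchar(s$label)) s$label else nm[i]
    s$components <- nm[i]; s$mole_fractions <- 1
    if (spec$noise_sd_pi > 0) {
      s$noise_sd_pi <- spec$noise_sd_pi
      s$seed <- spec$seed + i
    }
    s$n_points <- spec$n_points
    pures[[i]] <- generate_isotherm(s)
  }
  mixed <- vector("list", length(spec$fractions))
  for (j in seq_along(spec$fractions)) {
    X <- spec$fractions[[j]]
    if (any(X == 1)) { # pure endpoint: return the pure member unchanged
      mixed[[j]] <- pures[[which(X == 1)]]
      next
    }
    # default mixed collapse: X-weighted average, capped at the lowest
    # collapse among the present components (a film cannot outlive the
    # closed-form range of a component it still contains)
    pc_j <- if (!is.null(spec$mixed_pi_coll)) spec$mixed_pi_coll[j] else
      min(sum(X * pi_colls), min(pi_colls[X > 0]))
    pair_prod <- prod(X[spec$pair])
    a_of_pi <- function(p) {
      acc <- 0
      for (i in seq_len(k)) {
        if (X[i] > 0) acc <- acc + X[i] * truths[[i]](pmin(p, pi_colls[i]))
      }
      acc - spec$beta * pair_prod * (1 + p / spec$pi_ref)
    }
    n_pre <- spec$n_points
    p_pre <- seq(0, pc_j, length.out = n_pre)
    a_pre <- a_of_pi(p_pre)
    if (any(a_pre <= 0)) stop("mixture spec: beta too large, mixed area <= 0", call. = FALSE)
    a0 <- a_pre[1L]
    n_flat <- max(10L, n_pre %/% 10L)
    a_flat <- seq(1.12 * a0, a0, length.out = n_flat + 1L)[seq_len(n_flat)]
    p_flat <- rep(0, n_flat)
    # post-collapse tail via the single-isotherm machinery
    a_coll_j <- a_pre[n_pre]
    sc <- if (!is.null(spec$second_collapse) && is.finite(spec$second_collapse[j])) {
      spec$second_collapse[j]
    } else NULL
    tail_spec <- isotherm_spec(a_lift = a0, a_coll = a_coll_j, pi_coll = pc_j,
                               second_collapse = sc)
    pieces <- .post_collapse_curve(tail_spec)
    post_span <- sum(vapply(pieces, function(p) p$span, numeric(1)))
    n_post <- max(20L, n_pre %/% 3L)
    a_post <- seq(a_coll_j, max(a_coll_j - post_span, 0.2 * a_coll_j),
                  length.out = n_post + 1L)[-1L]
    p_post <- numeric(length(a_post))
    p0 <- pc_j; aa <- a_coll_j
    for (piece in pieces) {
      seg <- a_post <= aa & a_post > aa - piece$span
      p_post[seg] <- p0 + piece$slope * (aa - a_post[seg])
      p0 <- p0 + piece$slope * piece$span
      aa <- aa - piece$span
    }
    p_post[a_post <= aa] <- p0
    areas <- c(a_flat, a_pre, a_post) # a_pre is already in decreasing-area order
    press <- c(p_flat, p_pre, p_post)
    # de-duplicate any touching segment ends
    keep <- !duplicated(round(areas, 9))
    areas <- areas[keep]; press <- press[keep]
    if (spec$noise_sd_pi > 0) {
      press <- press + .with_seed(spec$seed + 100 + j,
                                  stats::rnorm(length(press), sd = spec$noise_sd_pi))
      press <- pmax(press, -0.49)
    }
    mixed[[j]] <- isotherm(areas, press, components = nm, mole_fractions = X,
                           temperature = spec$components[[1L]]$temperature,
                           label = sprintf("%s X=(%s)", spec$system_name,
                                           paste(signif(X, 4), collapse = ",")))
  }
  composition_series(system_name = spec$system_name, components = nm,
                     pure_isotherms = pures, mixed_isotherms = mixed,
                     fixed_pair = spec$fixed_pair, fixed_ratio = spec$fixed_ratio)
}

#' Bundled fixture specifications
#'
#' Named isotherm specifications emulating the monolayer families the
#' analyses target: three alkylphosphocholines (hexadecyl-, octadecyl- and
#' erucylphosphocholine analogues: `hepc_like`, `ocpc_like`, `erpc_like`),
#' `dppc_like` (LE-LC transition plateau at 5 mN/m, collapse at 63),
#' `popc_like` (liquid-expanded, collapse at 50) and `chol_like`
#' (condensed, collapse at 44, Cs-1 near 1000 mN/m). The APC parameters
#' (lift-off, collapse pressure and area) follow the characteristic values
#' of the corresponding experimental films; each gamma is set from the
#' target maximum compression modulus via
#' `gamma = a_lift * pi_coll / (Cs1_max * (a_lift - a_coll))`.
#'
#' Also included are the two model-membrane host compositions:
#' `normal_membrane` (cholesterol:DPPC mole ratio 0.67, a normal leucocyte
#' membrane model) and `tumor_membrane` (cholesterol:POPC ratio 0.25, a
#' leukemic cell membrane model), as host names plus ratio; see
#' [membrane_series()] for turning them into ternary series.
#'
#' @return named list of `isotherm_spec` objects and membrane preset lists.
#' @export
fixture_library <- function() {
  list(
    hepc_like = isotherm_spec(98, 32, 31, gamma = 98 * 31 / (41 * 66),
                              label = "HePC-like", components = "HePC_like"),
    ocpc_like = isotherm_spec(70, 28, 38, gamma = 70 * 38 / (63 * 42),
                              label = "OcPC-like", components = "OcPC_like"),
    erpc_like = isotherm_spec(93, 40, 44, gamma = 93 * 44 / (78 * 53),
                              label = "ErPC-like", components = "ErPC_like"),
    dppc_like = isotherm_spec(98, 38, 63, gamma = 4,
                              plateau = list(pi_t = 5, width = 18),
                              label = "DPPC-like", components = "DPPC_like"),
    popc_like = isotherm_spec(100, 46, 50, gamma = 1,
                              label = "POPC-like", components = "POPC_like"),
    chol_like = isotherm_spec(41, 39.2, 44, gamma = 1,
                              label = "cholesterol-like", components = "chol_like"),
    normal_membrane = list(hosts = c("chol_like", "dppc_like"), host_ratio = 0.67),
    tumor_membrane = list(hosts = c("chol_like", "popc_like"), host_ratio = 0.25)
  )
}

#' Ternary model-membrane series with an added guest amphiphile
#'
#' Builds a pseudo-binary composition series: a two-component host film
#' (cholesterol-like plus a phosphatidylcholine-like component at fixed
#' mole ratio) doped with a guest (drug-like) component at the given mole
#' fractions, keeping the host ratio constant -- the standard design for
#' probing drug incorporation into model membranes. The guest interacts
#' with the cholesterol-like host component through the series `beta`.
#'
#' @param membrane `"normal"` (cholesterol:DPPC 0.67) or `"tumor"`
#'   (cholesterol:POPC 0.25).
#' @param guest_spec `isotherm_spec` of the guest component.
#' @param guest_name component name for the guest.
#' @param x_guest guest mole fractions (0 and 1 give the host film and the
#'   pure guest).
#' @param beta,pi_ref interaction term, see [mixture_spec()]; `beta > 0`
#'   condenses the film (negative excess area and enthalpy).
#' @param noise_sd_pi,seed,n_points sampling controls.
#' @return a `mixture_spec` (pass to [generate_mixture_series()]).
#' @export
membrane_series <- function(membrane = c("normal", "tumor"),
                            guest_spec, guest_name = "APC_like",
                            x_guest = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
                            beta = 0, pi_ref = 30,
                            noise_sd_pi = 0, seed = NULL, n_points = 400L) {
  membrane <- match.arg(membrane)
  lib <- fixture_library()
  preset <- lib[[paste0(membrane, "_membrane")]]
  r <- preset$host_ratio
  x_chol_host <- r / (1 + r) # cholesterol share of the host film
  comps <- c(lib[preset$hosts], stats::setNames(list(guest_spec), guest_name))
  fractions <- lapply(x_guest, function(xg) {
    c((1 - xg) * x_chol_host, (1 - xg) * (1 - x_chol_host), xg)
  })
  mixture_spec(components = comps, fractions = fractions, beta = beta,
               pi_ref = pi_ref, pair = c(guest_name, preset$hosts[1L]),
               noise_sd_pi = noise_sd_pi, seed = seed, n_points = n_points,
               system_name = sprintf("%s membrane + %s", membrane, guest_name),
               fixed_pair = preset$hosts, fixed_ratio = r)
}
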