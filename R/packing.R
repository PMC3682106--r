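# Israelachvili critical packing parameter geometry.
#
# The dimensionless packing parameter s = V / (a * l_c) relates the
# hydrocarbon-chain volume V, the headgroup area a and the critical chain
# length l_c of an amphiphile to the aggregate shape it prefers: s < 1/3
# cone, 1/3..1 truncated cone, s ~ 1 cylinder, s > 1 inverted truncated
# cone. V and l_c follow the Tanford group-increment formulas
#   V   = 27.4 + 26.9 * n_c   [A^3]   (CH3 + n_c * CH2 volumes)
#   l_c = 1.5 + 1.265 * n_c   [A]     (CH3 radius + n_c C-C bond lengths)
# with n_c the number of chain carbons counted as methylene increments.

#' Hydrocarbon chain volume from carbon count
#'
#' `V = 27.4 + 26.9 n_c` in cubic Angstrom: the terminal CH3 volume plus
#' `n_c` methylene increments.
#'
#' @param n_c integer carbon count (>= 1); vectorised.
#' @return chain volume(s) in Angstrom^3.
#' @export
chain_volume <- function(n_c) {
  .check_nc(n_c)
  27.4 + 26.9 * n_c
}

#' Critical hydrocarbon chain length from carbon count
#'
#' `l_c = 1.5 + 1.265 n_c` in Angstrom: the CH3 radius plus `n_c` C-C bond
#' lengths.
#'
#' @param n_c integer carbon count (>= 1); vectorised.
#' @return chain length(s) in Angstrom.
#' @export
chain_length <- function(n_c) {
  .check_nc(n_c)
  1.5 + 1.265 * n_c
}

.check_nc <- function(n_c) {
  if (any(!is.finite(n_c)) || any(n_c < 1) || any(abs(n_c - round(n_c)) > 1e-9)) {
    stop("n_c must be a positive integer carbon count", call. = FALSE)
  }
}

#' Critical packing parameter
#'
#' `s = V / (a * l_c)`, dimensionless.
#'
#' @param V chain volume (Angstrom^3, > 0).
#' @param a headgroup area (Angstrom^2, > 0).
#' @param l_c critical chain length (Angstrom, > 0).
#' @return the packing parameter (vectorised).
#' @export
packing_parameter <- function(V, a, l_c) {
  if (any(V <= 0) || any(a <= 0) || any(l_c <= 0)) {
    stop("packing_parameter: all inputs must be > 0", call. = FALSE)
  }
  V / (a * l_c)
}

#' Molecular shape class from the packing parameter
#'
#' Standard Israelachvili banding: cone below 1/3, truncated cone between
#' 1/3 and 1, cylinder within `cylinder_tol` of 1, inverted truncated cone
#' above. Values within `boundary_tol` of the cone limit 1/3 classify as
#' truncated cone: the group-increment inputs carry about 1% uncertainty,
#' so a packing parameter indistinguishable from the cone limit is
#' assigned the less singular class.
#'
#' @param s packing parameter(s), > 0.
#' @param cylinder_tol half-width of the cylinder band around 1 (default 0.05).
#' @param boundary_tol tolerance at the cone/truncated-cone limit (default 0.005).
#' @return character vector: "cone", "truncated_cone", "cylinder" or
#'   "inverted_truncated_cone".
#' @export
classify_shape <- function(s, cylinder_tol = 0.05, boundary_tol = 0.005) {
  if (any(!is.finite(s)) || any(s <= 0)) stop("s must be > 0", call. = FALSE)
  vapply(s, function(si) {
    if (si >= 1 - cylinder_tol && si <= 1 + cylinder_tol) "cylinder"
    else if (si < 1 / 3 - boundary_tol) "cone"
    else if (si < 1) "truncated_cone"
    else "inverted_truncated_cone"
  }, character(1))
}

#' Geometric complementarity of two amphiphile shapes
#'
#' A qualitative packing heuristic: cones and truncated cones pack
#' favourably against inverted truncated cones (opposite tapers fill each
#' other's voids), cylinders only against cylinders; molecules of the same
#' tapered class, or a cone against a truncated cone, do not complement.
#' This mirrors the geometric argument for why single-chain cone-shaped
#' amphiphiles condense with sterols but separate from double-chain
#' phosphatidylcholines; it is not a thermodynamic prediction.
#'
#' @param g1,g2 `molecule_geometry` objects or shape-class strings.
#' @return `"complementary"` or `"non-complementary"`.
#' @export
complementarity <- function(g1, g2) {
  shp <- function(g) {
    if (inherits(g, "molecule_geometry")) g$shape
    else match.arg(g, c("cone", "truncated_cone", "cylinder",
                        "inverted_truncated_cone"))
  }
  s1 <- shp(g1); s2 <- shp(g2)
  tapered <- c("cone", "truncated_cone")
  ok <- (s1 %in% tapered && s2 == "inverted_truncated_cone") ||
    (s2 %in% tapered && s1 == "inverted_truncated_cone") ||
    (s1 == "cylinder" && s2 == "cylinder")
  if (ok) "complementary" else "non-complementary"
}

#' Molecular geometry record
#'
#' Assembles headgroup area, chain length, chain volume, packing parameter
#' and shape class for one amphiphile. `l_c` and `V` are derived from
#' `n_c` via [chain_length()] and [chain_volume()] unless given
#' explicitly; explicit values take precedence (multi-chain lipids and
#' unsaturated chains are not covered by the single-chain increment
#' formulas and must supply measured or literature values). Note the
#' methylene-increment convention: an n-alkyl chain of N carbons
#' contributes N-1 methylene increments past the terminal methyl, so
#' `n_c = N - 1` reproduces the conventional saturated-chain values (e.g.
#' `n_c = 15` for a hexadecyl chain).
#'
#' @param name component name.
#' @param a headgroup area (Angstrom^2).
#' @param n_c optional methylene-increment count per chain.
#' @param chains number of chains (used only to scale a derived `V`).
#' @param l_c,V explicit overrides (Angstrom, Angstrom^3).
#' @return An object of class `molecule_geometry` with fields `name`, `a`,
#'   `n_c`, `chains`, `l_c`, `V`, `s`, `shape`.
#' @export
molecule_geometry <- function(name, a, n_c = NULL, chains = 1L,
                              l_c = NULL, V = NULL) {
  if (is.null(n_c) && (is.null(l_c) || is.null(V))) {
    stop("molecule_geometry: give n_c, or both l_c and V", call. = FALSE)
  }
  if (is.null(l_c)) l_c <- chain_length(n_c)
  if (is.null(V)) V <- chains * chain_volume(n_c)
  if (a <= 0 || l_c <= 0 || V <= 0) {
    stop("molecule_geometry: a, l_c and V must be > 0", call. = FALSE)
  }
  s <- packing_parameter(V, a, l_c)
  structure(list(name = name, a = a, n_c = n_c, chains = as.integer(chains),
                 l_c = l_c, V = V, s = s, shape = classify_shape(s)),
            class = "molecule_geometry")
}

#' @export
print.molecule_geometry <- function(x, ...) {
  cat(sprintf("<molecule_geometry> %s: a = %g A2, l_c = %g A, V = %g A3, s = %.3f (%s)\n",
              x$name, x$a, x$l_c, x$V, x$s, x$shape))
  invisible(x)
}

#' Reference packing-parameter table for common membrane amphiphiles
#'
#' Bundled geometry values for cholesterol, DPPC, POPC and the three
#' alkylphosphocholine antitumor lipids (hexadecyl-, octadecyl- and
#' erucylphosphocholine). Headgroup areas are the literature values
#' 71.7 Angstrom^2 (phosphocholine) and 19 Angstrom^2 (cholesterol);
#' chain parameters for the saturated single-chain compounds come from
#' the group-increment formulas (HePC `n_c = 15`, OcPC `n_c = 17`), while
#' cholesterol, the double-chain phosphatidylcholines and the
#' mono-unsaturated ErPC carry explicit literature values (the increment
#' formulas do not model rings, double chains or cis double bonds). The
#' packing parameter and shape class are recomputed from a, l_c and V.
#'
#' @return data.frame with columns `name`, `a`, `l_c`, `V`, `s`, `shape`.
#' @export
packing_reference <- function() {
  tab <- data.frame(
    name = c("cholesterol", "DPPC", "POPC", "HePC", "OcPC", "ErPC"),
    a = c(19, 71.7, 71.7, 71.7, 71.7, 71.7),
    l_c = c(17.250, 20.475, 20.475, chain_length(15), chain_length(17), 24.400),
    V = c(400, 847, 910, chain_volume(15), chain_volume(17), 582.9),
    stringsAsFactors = FALSE)
  tab$s <- packing_parameter(tab$V, tab$a, tab$l_c)
  tab$shape <- classify_shape(tab$s)
  tab
}
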