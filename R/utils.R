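# Internal helpers shared across modules.

# Unit factor for Eq.-style excess-enthalpy integrals:
# 1 Angstrom^2 * 1 mN/m = 1e-23 J per molecule; times Avogadro's number
# gives J/mol.  Exact by definition of the units.
.ANG2_MNM_TO_J_PER_MOL <- 6.02214076

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Local least-squares polynomial smoothing and first derivative on a
# (possibly unevenly spaced) abscissa.  For each point a window of
# `window` points centred on it (clipped at the ends) is fitted with a
# polynomial of degree `degree`; the fitted value and its first
# derivative at the point are returned.  This is the uneven-spacing
# generalisation of Savitzky-Golay filtering.
.local_poly <- function(x, y, window = 11L, degree = 3L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (window %% 2L == 0L) stop("smoothing window must be odd", call. = FALSE)
  if (window < degree + 2L) stop("smoothing window too small for degree", call. = FALSE)
  if (n < window) stop("too few points for the smoothing window", call. = FALSE)
  half <- (window - 1L) %/% 2L
  smooth <- numeric(n)
  deriv <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    if (hi - lo + 1L < window) { # keep full window at the edges
      if (lo == 1L) hi <- window else lo <- n - window + 1L
    }
    xc <- x[lo:hi] - x[i]
    X <- outer(xc, 0:degree, `^`)
    cf <- tryCatch(qr.coef(qr(X), y[lo:hi]), error = function(e) rep(NA_real_, degree + 1L))
    cf[is.na(cf)] <- 0
    smooth[i] <- cf[1L]
    deriv[i] <- cf[2L]
  }
  list(smooth = smooth, deriv = deriv)
}

# 32-bit FNV-1a hash of a character scalar, as hex.  Used to stamp output
# tables with a configuration fingerprint without external dependencies.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply by the FNV prime, split to stay in double range
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}
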