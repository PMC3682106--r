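# Shared fixtures, built in code at test time.

fixtures <- fixture_library()

# isotherm following an exact closed form pi(A), zero-pressure tail included
linear_isotherm <- function(a0 = 80, slope = 1, a_from = a0 * 1.15, a_to = 40,
                            n = 400, label = "linear") {
  area <- seq(a_from, a_to, length.out = n)
  pressure <- pmax(slope * (a0 - area), 0)
  isotherm(area, pressure, components = "L", label = label)
}

# binary series from two fixture specs with the generator's interaction term
binary_series <- function(beta, fractions = list(c(0.5, 0.5)),
                          comp = list(a = fixtures$hepc_like, b = fixtures$erpc_like),
                          ...) {
  generate_mixture_series(mixture_spec(components = comp, fractions = fractions,
                                       beta = beta, pi_ref = 30, ...))
}

# hand-built series with exactly linear films and a constant excess area,
# for unit-factor and rectangle-integral checks
rectangle_series <- function(a_exc = -10) {
  f <- function(a0, slope) {
    area <- seq(a0 * 1.15, a0 - 50 / slope, length.out = 500)
    isotherm(area, pmax(slope * (a0 - area), 0), components = "x")
  }
  p1 <- f(80, 1)    # A1(pi) = 80 - pi
  p2 <- f(60, 2)    # A2(pi) = 60 - pi/2
  p1$components <- "c1"; p2$components <- "c2"
  amix <- function(p) 0.5 * (80 - p) + 0.5 * (60 - p / 2) + a_exc
  pmix <- seq(0, 45, length.out = 500)
  armix <- amix(pmix)
  mix <- isotherm(c(seq(armix[1] * 1.15, armix[1], length.out = 50)[-50], rev(armix)),
                  c(rep(0, 49), rev(pmix)),
                  components = c("c1", "c2"), mole_fractions = c(0.5, 0.5))
  composition_series("rectangle", c("c1", "c2"),
                     pure_isotherms = list(c1 = p1, c2 = p2),
                     mixed_isotherms = list(mix))
}

# collapse-pressure fixtures for the phase-rule classifier
pinned_series <- function() {
  fr <- lapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(x) c(1 - x, x))
  generate_mixture_series(mixture_spec(
    components = list(chol = fixtures$chol_like, ocpc = fixtures$ocpc_like),
    fractions = fr, beta = 10, pi_ref = 30,
    mixed_pi_coll = c(43, 41.5, 40, 38, 38),
    second_collapse = c(NA, NA, NA, 53, NA)))
}

varying_series <- function() {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  generate_mixture_series(mixture_spec(
    components = list(chol = fixtures$chol_like, hepc = fixtures$hepc_like),
    fractions = lapply(x, function(xi) c(1 - xi, xi)),
    beta = 10, pi_ref = 30, mixed_pi_coll = 44 + (31 - 44) * x))
}
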