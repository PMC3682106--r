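test_that("ideal area is the mole-fraction-weighted average", {
  expect_equal(ideal_area(c(40, 60), c(0.5, 0.5)), 50)
  expect_equal(ideal_area(c(40, 60), c(1, 0)), 40)
  # ternary hand check: 0.27*38 + 0.405*52 + 0.325*90
  expect_equal(ideal_area(c(38, 52, 90), c(0.27, 0.405, 0.325)), 60.57)
  expect_error(ideal_area(c(40, 60), c(0.5, 0.4, 0.1)), "one area per")
  expect_error(ideal_area(c(40, 60), c(0.6, 0.5)), "sum to 1")
})

test_that("an ideal mixture has zero excess enthalpy everywhere", {
  ser <- binary_series(beta = 0)
  prof <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30)
  expect_lt(max(abs(prof$dg_excess)), 1)
  expect_equal(prof$dg_excess[1], 0)
  expect_equal(prof$a_excess, prof$a_mixed - prof$a_ideal)
})

test_that("the unit factor is exact on a rectangle integrand", {
  # constant A_exc = -10 A2 up to 30 mN/m: dG = -10 * 30 * 6.02214076
  ser <- rectangle_series(a_exc = -10)
  prof <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30, grid_step = 0.25)
  expect_equal(max(abs(prof$a_excess - (-10))), 0, tolerance = 1e-6)
  expect_equal(prof$dg_excess[length(prof$dg_excess)], -10 * 30 * 6.02214076,
               tolerance = 1e-7)
})

test_that("trapezoid integration matches the interaction oracle", {
  ser <- binary_series(beta = 20)
  prof <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30, grid_step = 0.25)
  got <- prof$dg_excess[length(prof$dg_excess)]
  want <- mixture_dg_oracle(20, 0.25, 30, pi_ref = 30) # -1354.98 J/mol
  expect_equal(want, -6.02214076 * 5 * 45) # frozen closed form
  expect_lt(abs(got - want) / abs(want), 0.001)
  # convergence: halving the grid step moves the result by < 0.05 %
  fine <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30, grid_step = 0.125)
  expect_lt(abs(fine$dg_excess[length(fine$dg_excess)] - got) / abs(got), 5e-4)
})

test_that("excess quantities are invariant to component order", {
  comp_ab <- list(a = fixtures$hepc_like, b = fixtures$erpc_like)
  comp_ba <- list(b = fixtures$erpc_like, a = fixtures$hepc_like)
  s1 <- binary_series(beta = 20, fractions = list(c(0.3, 0.7)), comp = comp_ab)
  s2 <- binary_series(beta = 20, fractions = list(c(0.7, 0.3)), comp = comp_ba)
  p1 <- excess_gibbs(s1, c(0.3, 0.7), pi_max = 25)
  p2 <- excess_gibbs(s2, c(0.7, 0.3), pi_max = 25)
  expect_equal(p1$a_excess, p2$a_excess, tolerance = 1e-8)
  expect_equal(p1$dg_excess, p2$dg_excess, tolerance = 1e-8)
})

test_that("the interaction strength is recoverable from the excess profile", {
  ser <- binary_series(beta = 20, fractions = list(c(0.5, 0.5)))
  prof <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30)
  expect_equal(fit_interaction_beta(prof, 0.25, pi_ref = 30), 20,
               tolerance = 0.05 * 20)
})

test_that("excess-area curves show the sign and extremum of the interaction", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  fr <- lapply(x, function(xi) c(1 - xi, xi))
  ideal <- binary_series(beta = 0, fractions = fr)
  tab0 <- excess_area_curve(ideal, pi = 20)
  expect_lt(max(abs(tab0$a_exc)), 0.05)

  attr_ser <- binary_series(beta = 20, fractions = fr)
  tab <- excess_area_curve(attr_ser, pi = 20)
  expect_true(all(tab$a_exc < 0))
  expect_equal(which.min(tab$a_exc), 3L) # symmetric term: minimum at X = 0.5

  rep_ser <- binary_series(beta = -20, fractions = fr)
  expect_true(all(excess_area_curve(rep_ser, pi = 20)$a_exc > 0))
})

test_that("dG-versus-composition reproduces generator patterns", {
  x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  fr <- lapply(x, function(xi) c(1 - xi, xi))
  flat <- dg_vs_composition(binary_series(beta = 0, fractions = fr), pi = 30)
  expect_lt(max(abs(flat$dg_exc)), 1)
  dg <- dg_vs_composition(binary_series(beta = 20, fractions = fr), pi = 30)
  expect_true(all(dg$dg_exc < 0))
  expect_equal(which.min(dg$dg_exc), 3L) # strongest interaction at 1:1
  # analytic value at each composition
  for (i in seq_along(x)) {
    expect_equal(dg$dg_exc[i], mixture_dg_oracle(20, x[i] * (1 - x[i]), 30),
                 tolerance = abs(mixture_dg_oracle(20, x[i] * (1 - x[i]), 30)) * 0.001)
  }
})

test_that("ternary membrane series contrast: attractive vs repulsive guest", {
  tum <- generate_mixture_series(membrane_series("tumor", fixtures$hepc_like,
                                                 beta = 15, n_points = 300L))
  nor <- generate_mixture_series(membrane_series("normal", fixtures$hepc_like,
                                                 beta = -15, n_points = 300L))
  dg_t <- dg_vs_composition(tum, pi = 30)
  dg_n <- dg_vs_composition(nor, pi = 30)
  interior_t <- dg_t$x_APC_like > 0 & dg_t$x_APC_like < 1
  interior_n <- dg_n$x_APC_like > 0 & dg_n$x_APC_like < 1
  expect_true(all(dg_t$dg_exc[interior_t] < 0))
  expect_true(all(dg_n$dg_exc[interior_n] > 0))
  # host mole-fraction ratio is fixed across the series (r/(1+r) cholesterol)
  expect_equal(tum$fixed_ratio, 0.25)
  x0 <- tum$mixed_isotherms[[1]]$mole_fractions
  expect_equal(x0[1] / x0[2], 0.25, tolerance = 1e-9)
})

test_that("pseudo-binary reference is available for ternary series", {
  tum <- generate_mixture_series(membrane_series("tumor", fixtures$hepc_like,
                                                 beta = 15, n_points = 300L))
  dg_pb <- dg_vs_composition(tum, pi = 30, reference = "pseudo_binary",
                             guest = "APC_like")
  expect_true(all(is.finite(dg_pb$dg_exc)))
  # both references agree at the endpoints (X = 0 and X = 1)
  expect_equal(dg_pb$dg_exc[dg_pb$x_APC_like == 0], 0, tolerance = 1)
  expect_equal(abs(dg_pb$dg_exc[dg_pb$x_APC_like == 1]), 0, tolerance = 1)
})

test_that("the phase-rule miscibility classifier matches construction", {
  rep1 <- assess_miscibility(pinned_series(), guest = "ocpc")
  expect_identical(rep1$classification[rep1$x_guest >= 0.7],
                   c("immiscible", "immiscible"))
  expect_true(all(rep1$classification[rep1$x_guest <= 0.5] != "immiscible"))
  # the X = 0.7 flag comes from the double collapse
  expect_match(rep1$rationale[rep1$x_guest == 0.7], "two independent collapses")

  rep2 <- assess_miscibility(varying_series(), guest = "hepc")
  expect_true(all(rep2$classification == "miscible"))

  # explicit descriptors missing a pure component is an argument error
  ser <- varying_series()
  expect_error(assess_miscibility(ser, descriptors = list(
    pure = list(), mixed = lapply(ser$mixed_isotherms, descriptor_set))),
    "pure components")
})

test_that("requesting pressures beyond the usable range names the culprit", {
  ser <- binary_series(beta = 0) # HePC-like pure collapses at 31 mN/m
  expect_error(excess_gibbs(ser, c(0.5, 0.5), pi_max = 40),
               "(mixed isotherm|pure component).*usable pi_max")
})
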