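test_that("compression modulus recovers closed-form moduli", {
  # linear EOS pi = 100 - A: dpi/dA = -1, so Cs-1 = A
  area <- seq(95, 40, length.out = 500)
  iso <- isotherm(area, 100 - area, components = "L")
  prof <- compression_modulus(iso)
  i50 <- which.min(abs(prof$area - 50))
  expect_equal(prof$cs_inv[i50], 50, tolerance = 0.01)

  # hyperbolic EOS pi = 2000/(A - 20) - 30: Cs-1 = A * 2000/(A - 20)^2
  area <- seq(2000 / 30 + 20, 45, length.out = 600)
  iso2 <- isotherm(area, 2000 / (area - 20) - 30, components = "H")
  prof2 <- compression_modulus(iso2)
  for (a_at in c(75, 70, 65, 60, 55)) {
    i <- which.min(abs(prof2$area - a_at))
    analytic <- prof2$area[i] * 2000 / (prof2$area[i] - 20)^2
    expect_equal(prof2$cs_inv[i], analytic, tolerance = 0.02)
  }
  i60 <- which.min(abs(prof2$area - 60))
  expect_equal(prof2$cs_inv[i60], 75, tolerance = 75 * 0.02)

  expect_error(compression_modulus(iso, smoothing_window = 3), ">= 5")
  expect_error(compression_modulus(isotherm(seq(90, 82, length.out = 10),
                                            c(rep(0, 5), 1:5), components = "s"),
                                   smoothing_window = 11), "too few points")
})

test_that("lift-off detection finds the generator value and guards noise", {
  iso <- generate_isotherm(fixtures$hepc_like)
  expect_equal(lift_off(iso), 98, tolerance = 1)
  # pressure never sustained above threshold
  a <- seq(90, 50, length.out = 30)
  p <- c(rep(0, 29), 5)
  expect_error(lift_off(isotherm(a, p, components = "x")), "never sustains")
  # 20 noisy seeds stay within reproducibility tolerance
  spec <- fixtures$ocpc_like
  spec$noise_sd_pi <- 0.05
  devs <- vapply(1:20, function(s) {
    spec$seed <- s
    lift_off(generate_isotherm(spec)) - 70
  }, numeric(1))
  expect_true(all(abs(devs) < 2))
})

test_that("extrapolated area recovers a linear steep branch exactly", {
  # A = 75 - 0.8 pi over the whole branch
  area <- seq(75, 35, length.out = 500)
  iso <- isotherm(area, (75 - area) / 0.8, components = "x")
  prof <- compression_modulus(iso)
  expect_equal(extrapolated_area(iso, prof), 75, tolerance = 0.2)
  # an over-tight fit region leaves too few points on a film that
  # stiffens steadily toward collapse
  stiff <- generate_isotherm(fixtures$dppc_like)
  expect_error(extrapolated_area(stiff, compression_modulus(stiff),
                                 fraction = 0.99), "fewer than 5")
})

test_that("collapse detection finds onsets, plateaus and double collapses", {
  # rise to 35 mN/m then terminal plateau
  one <- descriptor_set(generate_isotherm(isotherm_spec(80, 40, 35, gamma = 1)))
  expect_equal(nrow(one$collapses), 1L)
  expect_equal(one$collapses$pressure[1], 35, tolerance = 1)

  # immiscible-style fixture: primary 38, secondary 53
  ms <- mixture_spec(components = list(chol = fixtures$chol_like,
                                       ocpc = fixtures$ocpc_like),
                     fractions = list(c(0.3, 0.7)), beta = 10,
                     mixed_pi_coll = 38, second_collapse = 53)
  two <- descriptor_set(generate_mixture_series(ms)$mixed_isotherms[[1]])
  expect_equal(two$collapses$kind, c("primary", "secondary"))
  expect_equal(two$collapses$pressure[1], 38, tolerance = 1)
  expect_equal(two$collapses$pressure[2], 53, tolerance = 1.5)

  # monotone rise truncated before collapse: no event
  iso <- generate_isotherm(fixtures$erpc_like)
  keep <- iso$pressure < 35 & iso$area >= isotherm_truth(fixtures$erpc_like)(35)
  trunc <- isotherm(iso$area[keep], iso$pressure[keep], components = "t")
  expect_equal(nrow(descriptor_set(trunc)$collapses), 0L)

  # pressure decline after collapse is also an onset signature
  dec <- descriptor_set(generate_isotherm(
    isotherm_spec(80, 40, 35, gamma = 1, post_collapse = "decline")))
  expect_equal(dec$collapses$pressure[1], 35, tolerance = 1)
})

test_that("phase classification follows the conventional modulus bands", {
  expect_identical(classify_phase(41), "liquid-expanded")
  expect_identical(classify_phase(78), "liquid")
  expect_identical(classify_phase(1000), "solid")
  expect_identical(classify_phase(5), "gaseous")
  expect_identical(classify_phase(150), "liquid-condensed")
  # pure function of the modulus: same value in, same class out, total on R+
  for (cs in c(0.1, 12.49, 12.5, 49.9, 50, 99.9, 100, 250, 250.1, 1e4)) {
    expect_identical(classify_phase(cs), classify_phase(cs))
    expect_true(classify_phase(cs) %in%
                  c("gaseous", "liquid-expanded", "liquid",
                    "liquid-condensed", "solid"))
  }
})

test_that("LE-LC transition plateaus are found only where they exist", {
  dppc <- generate_isotherm(fixtures$dppc_like)
  tp <- descriptor_set(dppc)$transition_plateau
  expect_false(is.null(tp))
  expect_equal(tp$pressure, 5, tolerance = 1)
  expect_gt(tp$a_start, tp$a_end)

  popc <- generate_isotherm(fixtures$popc_like)
  expect_null(descriptor_set(popc)$transition_plateau)

  # a flat segment beyond the collapse must not register as a transition
  post <- generate_isotherm(isotherm_spec(80, 40, 35, gamma = 1))
  expect_null(descriptor_set(post)$transition_plateau)
})

test_that("descriptors recover generator ground truth on noise-free fixtures", {
  for (nm in c("hepc_like", "ocpc_like", "erpc_like", "popc_like", "chol_like")) {
    spec <- fixtures[[nm]]
    d <- descriptor_set(generate_isotherm(spec))
    tr <- truth_descriptors(spec)
    expect_equal(d$lift_off_area, tr$lift_off, tolerance = 1,
                 label = paste(nm, "lift-off"))
    expect_equal(d$a0_extrapolated, tr$a0, tolerance = 2,
                 label = paste(nm, "A0"))
    expect_gt(nrow(d$collapses), 0)
    expect_equal(d$collapses$pressure[1], tr$pi_coll, tolerance = 1,
                 label = paste(nm, "collapse pressure"))
    expect_lt(abs(d$cs_inv_max - tr$cs_inv_max) / tr$cs_inv_max, 0.05)
  }
})
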