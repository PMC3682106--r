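test_that("spec invariants are enforced at construction", {
  expect_error(isotherm_spec(40, 50, 30), "a_lift > a_coll")
  expect_error(isotherm_spec(80, 40, -1), "pi_coll")
  expect_error(isotherm_spec(80, 40, 30, gamma = 0), "gamma")
  expect_error(isotherm_spec(80, 40, 30, plateau = list(pi_t = 35, width = 5)),
               "below pi_coll")
  expect_error(isotherm_spec(80, 40, 30, second_collapse = 25), "exceed pi_coll")
  expect_error(isotherm_spec(80, 40, 30, noise_sd_pi = 0.1), "requires a seed")
})

test_that("the sampled curve matches the closed form exactly when noise-free", {
  spec <- isotherm_spec(98, 32, 31, gamma = 1)
  iso <- generate_isotherm(spec)
  truth <- isotherm_truth(spec)
  # linear case: midpoint identity
  expect_equal(truth(31 / 2), (98 + 32) / 2)
  pre <- iso$pressure > 0 & iso$area >= 32
  expect_equal(truth(iso$pressure[pre]), iso$area[pre], tolerance = 1e-9)
  # curved case too
  spec2 <- fixtures$dppc_like
  iso2 <- generate_isotherm(spec2)
  pre2 <- iso2$pressure > 0 & iso2$pressure < 62.9 & iso2$area >= 38
  expect_equal(isotherm_truth(spec2)(iso2$pressure[pre2]), iso2$area[pre2],
               tolerance = 1e-9)
})

test_that("seeded noise is reproducible, unseeded runs differ by seed", {
  spec <- isotherm_spec(98, 32, 31, gamma = 1, noise_sd_pi = 0.05, seed = 11)
  a <- generate_isotherm(spec)
  b <- generate_isotherm(spec)
  expect_identical(a$pressure, b$pressure)
  spec$seed <- 12
  expect_false(identical(a$pressure, generate_isotherm(spec)$pressure))
  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_isotherm(spec)); after <- runif(1)
  expect_identical(before, after)
})

test_that("generator output satisfies every isotherm invariant", {
  for (nm in c("hepc_like", "ocpc_like", "erpc_like", "dppc_like",
               "popc_like", "chol_like")) {
    expect_silent(validate_isotherm(generate_isotherm(fixtures[[nm]])))
  }
  noisy <- fixtures$popc_like
  noisy$noise_sd_pi <- 0.05; noisy$seed <- 3
  expect_silent(validate_isotherm(generate_isotherm(noisy)))
})

test_that("mixture generation honours the interaction oracle", {
  ser0 <- binary_series(beta = 0)
  p0 <- excess_gibbs(ser0, c(0.5, 0.5), pi_max = 30)
  expect_lt(max(abs(p0$dg_excess)), 1)
  ser <- binary_series(beta = 20)
  p <- excess_gibbs(ser, c(0.5, 0.5), pi_max = 30)
  want <- mixture_dg_oracle(20, 0.25, p$grid$values, pi_ref = 30)
  scale <- pmax(abs(want), 10)
  expect_lt(max(abs(p$dg_excess - want) / scale), 0.001)
  # repulsive sign flip
  prep <- excess_gibbs(binary_series(beta = -20), c(0.5, 0.5), pi_max = 30)
  expect_true(all(prep$a_excess > 0))
  # an absurd interaction that drives the area negative is rejected
  expect_error(binary_series(beta = 500), "beta too large")
})

test_that("fixture library encodes the documented study conditions", {
  expect_equal(fixtures$erpc_like$pi_coll, 44)
  expect_equal(fixtures$dppc_like$plateau$pi_t, 5)
  expect_equal(fixtures$dppc_like$pi_coll, 63)
  expect_equal(fixtures$popc_like$pi_coll, 50)
  expect_equal(fixtures$chol_like$pi_coll, 44)
  expect_equal(fixtures$hepc_like$a_lift, 98)
  expect_equal(fixtures$ocpc_like$a_lift, 70)
  # membrane presets: cholesterol share of the host film is r/(1+r)
  expect_equal(fixtures$normal_membrane$host_ratio, 0.67)
  expect_equal(fixtures$tumor_membrane$host_ratio, 0.25)
  expect_equal(0.67 / 1.67, 0.4012, tolerance = 1e-4)
  ms <- membrane_series("normal", fixtures$hepc_like, beta = 0, n_points = 300L)
  x0 <- ms$fractions[[1]] # X_guest = 0: the bare host film
  expect_equal(x0[1], 0.67 / 1.67, tolerance = 1e-9)
})

test_that("compression moduli of fixtures land in the intended bands", {
  # gamma encodes the target maximum modulus a_lift*pi_coll/(gamma*(a_lift-a_coll))
  tr <- truth_descriptors(fixtures$ocpc_like)
  expect_equal(tr$cs_inv_max, 63, tolerance = 63 * 0.01)
  expect_equal(truth_descriptors(fixtures$hepc_like)$cs_inv_max, 41,
               tolerance = 41 * 0.01)
  expect_equal(truth_descriptors(fixtures$erpc_like)$cs_inv_max, 78,
               tolerance = 78 * 0.01)
  expect_gt(truth_descriptors(fixtures$chol_like)$cs_inv_max, 900)
})
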