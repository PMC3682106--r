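test_that("write -> read round trip preserves points and metadata", {
  iso <- generate_isotherm(fixtures$erpc_like)
  iso$components <- c("ErPC_like"); iso$mole_fractions <- 1
  iso$label <- "round trip"
  d <- withr::local_tempdir()
  write_isotherm(iso, file.path(d, "iso.csv"))
  back <- read_isotherm(file.path(d, "iso.csv"))
  expect_equal(back$area, iso$area, tolerance = 1e-6)
  expect_equal(back$pressure, iso$pressure, tolerance = 1e-6)
  expect_identical(back$components, iso$components)
  expect_identical(back$label, iso$label)
  expect_equal(back$mole_fractions, iso$mole_fractions)
  expect_equal(back$temperature, iso$temperature)
})

test_that("duplicated area rows are averaged on read", {
  d <- withr::local_tempdir()
  f <- file.path(d, "dup.csv")
  area <- seq(90, 45, length.out = 30)
  pressure <- pmax(80 - area, 0)
  lines <- c("area_A2,pressure_mN_m", sprintf("%.6f,%.6f", area, pressure),
             sprintf("%.6f,%.6f", area[12], pressure[12] + 1)) # duplicate of row 12
  writeLines(lines, f)
  iso <- read_isotherm(f)
  expect_length(iso$area, 30L) # 31 rows collapse to 30
  i <- which.min(abs(iso$area - area[12]))
  expect_equal(iso$pressure[i], pressure[12] + 0.5, tolerance = 1e-5)
})

test_that("parse and validation errors are specific", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.csv")
  writeLines(c("area_A2,pressure_mN_m", "90,0.1", "85,oops", "80,5"), f)
  expect_error(read_isotherm(f), "line 3")
  f2 <- file.path(d, "flat.csv")
  writeLines(c("area_A2,pressure_mN_m",
               sprintf("%.2f,0", seq(90, 50, length.out = 20))), f2)
  expect_error(read_isotherm(f2), "max pressure > 1")
  expect_error(read_isotherm(file.path(d, "missing.csv")), "no such file")
  writeLines(c("foo,bar", "90,0"), file.path(d, "hdr.csv"))
  expect_error(read_isotherm(file.path(d, "hdr.csv")), "header")
})

test_that("isotherm invariants are enforced", {
  a <- seq(90, 50, length.out = 20); p <- pmax(80 - a, 0)
  expect_error(isotherm(a[1:5], p[1:5]), "10 points")
  expect_error(isotherm(-a, p), "areas > 0")
  expect_error(isotherm(a, p - 10), "-0.5")
  expect_error(isotherm(a, p, components = c("x", "y"),
                        mole_fractions = c(0.6, 0.5)), "sum to 1")
  # non-monotone acquisition beyond the 0.5 A2 noise tolerance
  a2 <- a; a2[10] <- a2[10] + 5
  expect_error(isotherm(rev(a2), rev(p)), "non-increasing")
})

test_that("resampling a linear isotherm is the identity", {
  iso <- linear_isotherm(a0 = 80, slope = 1)
  g <- pressure_grid(20, step = 10)
  expect_equal(g$values, c(0, 10, 20))
  expect_equal(resample_to_grid(iso, g), c(80, 70, 60), tolerance = 1e-6)
})

test_that("grid points beyond the usable range raise a range error", {
  iso <- generate_isotherm(fixtures$erpc_like) # collapses at 44 mN/m
  expect_error(resample_to_grid(iso, pressure_grid(60)), "usable pi_max")
  expect_error(pressure_grid(-5), "pi_max > 0")
})

test_that("resampling matches the generator closed form", {
  for (nm in c("hepc_like", "erpc_like", "popc_like")) {
    spec <- fixtures[[nm]]
    iso <- generate_isotherm(spec)
    g <- pressure_grid(spec$pi_coll - 2, step = 0.25)
    err <- max(abs(resample_to_grid(iso, g) - isotherm_truth(spec)(g$values)))
    expect_lt(err, 0.1)
  }
  # kinked curve: LE-LC plateau
  spd <- fixtures$dppc_like; spd$n_points <- 500L
  g <- pressure_grid(60, step = 0.25)
  err <- max(abs(resample_to_grid(generate_isotherm(spd), g) -
                   isotherm_truth(spd)(g$values)))
  expect_lt(err, 0.1)
})

test_that("noisy resampling stays within reproducibility tolerance", {
  spec <- fixtures$hepc_like
  spec$noise_sd_pi <- 0.05
  for (s in 1:5) {
    spec$seed <- s
    a15 <- resample_to_grid(generate_isotherm(spec), pressure_grid(15, 0.25))
    expect_lt(abs(a15[length(a15)] - isotherm_truth(spec)(15)), 2)
  }
})
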