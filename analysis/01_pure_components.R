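#!/usr/bin/env Rscript
# Pure-component characterisation: generate the six bundled monolayer
# fixtures with realistic sensor noise, extract their isotherm descriptors
# (lift-off, A0, collapse, compression modulus, phase state, LE-LC
# transition), and tabulate the molecular packing geometry.

library(monofilm)

dir.create("results", showWarnings = FALSE)
lib <- fixture_library()
fix_names <- c("hepc_like", "ocpc_like", "erpc_like",
               "dppc_like", "popc_like", "chol_like")

rows <- lapply(seq_along(fix_names), function(i) {
  spec <- lib[[fix_names[i]]]
  spec$noise_sd_pi <- 0.05 # Wilhelmy-plate sensor accuracy scale
  spec$seed <- 100 + i
  d <- descriptor_set(generate_isotherm(spec), smoothing_window = 21L)
  tr <- truth_descriptors(spec)
  data.frame(
    fixture = fix_names[i],
    lift_off_A2 = round(d$lift_off_area, 2),
    a0_A2 = round(d$a0_extrapolated, 2),
    pi_coll_mN_m = round(if (nrow(d$collapses)) d$collapses$pressure[1] else NA, 2),
    a_coll_A2 = round(if (nrow(d$collapses)) d$collapses$area[1] else NA, 2),
    cs_inv_max_mN_m = round(d$cs_inv_max, 1),
    phase = d$phase_class,
    plateau_pi_mN_m = round(if (is.null(d$transition_plateau)) NA
                            else d$transition_plateau$pressure, 2),
    truth_lift_off = spec$a_lift,
    truth_pi_coll = spec$pi_coll,
    truth_cs_inv_max = round(tr$cs_inv_max, 1))
})
desc <- do.call(rbind, rows)
write.csv(desc, "results/pure_descriptors.csv", row.names = FALSE)

cat("Pure-component descriptors (measured on noisy synthetic films vs truth):\n\n")
print(desc[, c("fixture", "lift_off_A2", "pi_coll_mN_m", "cs_inv_max_mN_m",
               "phase", "plateau_pi_mN_m")], row.names = FALSE)
cat("\nFindings: the three drug-like films are liquid-type (Cs-1 max 40-80",
    "mN/m),\nstability (collapse pressure) grows with chain length; the",
    "sterol film is\nsolid-type (Cs-1 ~ 1000 mN/m); only the DPPC-like film",
    "shows an LE-LC\ntransition plateau, near 5 mN/m.\n\n")

pack <- packing_reference()
pack$s <- round(pack$s, 4)
write.csv(pack, "results/packing_parameters.csv", row.names = FALSE)
cat("Molecular packing parameters (s = V / (a l_c)):\n\n")
print(pack, row.names = FALSE)
cat("\nFindings: the single-chain drugs are cones (s ~ 0.29-0.33), the",
    "\nphosphatidylcholines truncated cones, cholesterol an inverted truncated",
    "\ncone (s = 1.22): drug/sterol pairs are geometrically complementary,\n",
    "drug/phosphatidylcholine pairs are not:\n")
cat("  HePC + cholesterol:",
    complementarity(molecule_geometry("HePC", 71.7, n_c = 15),
                    molecule_geometry("chol", 19, l_c = 17.25, V = 400)), "\n")
cat("  HePC + DPPC:      ",
    complementarity("cone", "truncated_cone"), "\n")
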