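#!/usr/bin/env Rscript
# Binary mixed films: mean-area deviations, excess free enthalpy of mixing
# and phase-rule miscibility for a drug/sterol system (attractive) and a
# drug/phosphatidylcholine system (repulsive), over the standard
# mole-fraction grid and analysis pressures.

library(monofilm)

dir.create("results", showWarnings = FALSE)
lib <- fixture_library()
x <- c(0.1, 0.3, 0.5, 0.7, 0.9)
fr <- lapply(x, function(xi) c(1 - xi, xi))
pressures <- c(5, 10, 20, 30)

# drug/sterol: attractive, beta sized to the ~2.5 kJ/mol interaction scale
chol_hepc <- generate_mixture_series(mixture_spec(
  components = list(chol = lib$chol_like, hepc = lib$hepc_like),
  fractions = fr, beta = 37, pi_ref = 30,
  mixed_pi_coll = 44 + (31 - 44) * x, # miscible-like: collapse varies with X
  noise_sd_pi = 0.05, seed = 201, system_name = "sterol + C16 drug"))

# drug/DPPC: repulsive, collapse pinned at the drug value for X >= 0.7
dppc_hepc <- generate_mixture_series(mixture_spec(
  components = list(dppc = lib$dppc_like, hepc = lib$hepc_like),
  fractions = fr, beta = -12, pi_ref = 30,
  mixed_pi_coll = c(50, 45, 38, 31, 31),
  second_collapse = c(NA, NA, NA, 58, NA),
  noise_sd_pi = 0.05, seed = 202, system_name = "DPPC-like + C16 drug"))

for (ser in list(chol_hepc, dppc_hepc)) {
  slug <- gsub("[^A-Za-z0-9]+", "_", ser$system_name)
  dgs <- list()
  for (p in pressures) {
    tab <- dg_vs_composition(ser, pi = p, grid_step = 0.25)
    tab$pi_mN_m <- p
    dgs[[as.character(p)]] <- tab
  }
  dg_all <- do.call(rbind, dgs)
  write.csv(dg_all, sprintf("results/dg_vs_x_%s.csv", slug), row.names = FALSE)
  a30 <- excess_area_curve(ser, pi = 30)
  write.csv(a30, sprintf("results/area_vs_x_pi30_%s.csv", slug), row.names = FALSE)
  cat(sprintf("\n%s, dG_exc (J/mol) at 30 mN/m:\n", ser$system_name))
  print(dgs[["30"]][, !(names(dgs[["30"]]) == "pi_mN_m")], row.names = FALSE)
}

cat("\nFindings: the sterol system shows negative excess areas and excess\n",
    "free enthalpies (attraction) with the extremum at the 1:1 composition,\n",
    "growing with surface pressure; the DPPC system shows positive\n",
    "deviations (repulsion, tendency to demix).\n\n", sep = "")

misc1 <- assess_miscibility(chol_hepc, guest = "hepc")
misc2 <- assess_miscibility(dppc_hepc, guest = "hepc")
sink("results/miscibility_binary.txt")
cat("== sterol + C16 drug ==\n"); print(misc1)
cat("\n== DPPC-like + C16 drug ==\n"); print(misc2)
sink()
print(misc1)
print(misc2)
cat("\nFindings: collapse pressure varying with composition marks the sterol\n",
    "system miscible; the pinned collapse (plus a double collapse at X = 0.7)\n",
    "marks drug-rich DPPC films immiscible.\n", sep = "")
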