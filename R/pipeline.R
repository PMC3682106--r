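# Reporting pipeline: ties isotherm I/O, descriptors, miscibility and
# mixing thermodynamics into one reproducible run over a composition
# series, writing the tabular analogues of the standard mixed-monolayer
# figure panels (descriptor table, collapse-vs-composition, mean-area and
# excess-enthalpy curves at several pressures, miscibility report).

#' Write a composition series to disk (CSVs + sidecars + manifest)
#'
#' @param series a `composition_series`.
#' @param dir output directory (created if missing).
#' @return path of the written `manifest.yaml`, invisibly.
#' @export
write_composition_series <- function(series, dir) {
  stopifnot(inherits(series, "composition_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  slug <- function(s) gsub("[^A-Za-z0-9_]+", "_", s)
  pure_files <- character(0)
  for (nm in series$components) {
    f <- sprintf("pure_%s.csv", slug(nm))
    write_isotherm(series$pure_isotherms[[nm]], file.path(dir, f))
    pure_files <- c(pure_files, f)
  }
  mixed_files <- character(0)
  for (j in seq_along(series$mixed_isotherms)) {
    f <- sprintf("mixed_%02d.csv", j)
    write_isotherm(series$mixed_isotherms[[j]], file.path(dir, f))
    mixed_files <- c(mixed_files, f)
  }
  man <- list(system_name = series$system_name,
              components = as.list(series$components),
              pure = as.list(pure_files),
              mixed = as.list(mixed_files))
  if (!is.null(series$fixed_pair)) {
    man$fixed_ratio <- list(pair = as.list(series$fixed_pair),
                            value = series$fixed_ratio)
  }
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}

#' Read a composition series from a manifest
#'
#' The manifest is a YAML file listing pure and mixed isotherm CSVs
#' (relative to its own directory); per-file composition metadata comes
#' from the `.meta` sidecars.
#'
#' @param path path to `manifest.yaml`.
#' @return a `composition_series`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("no such manifest: ", path, call. = FALSE)
  man <- yaml::read_yaml(path)
  need <- c("system_name", "components", "pure", "mixed")
  missing <- setdiff(need, names(man))
  if (length(missing)) {
    stop("manifest is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!length(man$mixed)) stop("manifest lists no mixed isotherms", call. = FALSE)
  base <- dirname(path)
  pures <- lapply(unlist(man$pure), function(f) read_isotherm(file.path(base, f)))
  names(pures) <- vapply(pures, function(iso) iso$components[1L], character(1))
  mixed <- lapply(unlist(man$mixed), function(f) read_isotherm(file.path(base, f)))
  fixed_pair <- NULL; fixed_ratio <- NULL
  if (!is.null(man$fixed_ratio)) {
    fixed_pair <- unlist(man$fixed_ratio$pair)
    fixed_ratio <- man$fixed_ratio$value
  }
  composition_series(system_name = man$system_name,
                     components = unlist(man$components),
                     pure_isotherms = pures, mixed_isotherms = mixed,
                     fixed_pair = fixed_pair, fixed_ratio = fixed_ratio)
}

#' Pipeline run configuration
#'
#' @param manifest a `composition_series` or a path to a `manifest.yaml`.
#' @param out_dir output directory for the result tables.
#' @param pressures analysis pressures in mN/m (default 5, 10, 20, 30, 35;
#'   30 mN/m is the headline monolayer-bilayer correspondence pressure).
#' @param smoothing_window,lift_off_threshold,slope_fraction,a0_fraction
#'   descriptor tuning, forwarded to [descriptor_set()].
#' @param miscibility_tolerance collapse-matching tolerance (mN/m).
#' @param grid_step integration grid step (mN/m).
#' @return An object of class `run_config`.
#' @export
run_config <- function(manifest, out_dir, pressures = c(5, 10, 20, 30, 35),
                       smoothing_window = 11L, lift_off_threshold = 0.5,
                       slope_fraction = 0.1, a0_fraction = 0.85,
                       miscibility_tolerance = 1.5, grid_step = 0.25) {
  pressures <- sort(as.numeric(pressures))
  if (any(pressures <= 0)) stop("analysis pressures must be positive", call. = FALSE)
  structure(list(manifest = manifest, out_dir = out_dir, pressures = pressures,
                 smoothing_window = smoothing_window,
                 lift_off_threshold = lift_off_threshold,
                 slope_fraction = slope_fraction, a0_fraction = a0_fraction,
                 miscibility_tolerance = miscibility_tolerance,
                 grid_step = grid_step),
            class = "run_config")
}

.config_hash <- function(config) {
  cfg <- config
  cfg$manifest <- if (is.character(cfg$manifest)) cfg$manifest else "<in-memory series>"
  .fnv1a(paste(deparse(cfg[order(names(cfg))]), collapse = ""))
}

.write_table <- function(df, path, hash, pressures) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s; analysis pressures (mN/m): %s",
                     hash, paste(pressures, collapse = ", ")), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE), con, row.names = FALSE,
                   quote = FALSE)
}

#' Run the full analysis pipeline over a composition series
#'
#' Extracts descriptors for every film, tabulates collapse pressure versus
#' composition, computes mean-area and excess-free-enthalpy curves at each
#' analysis pressure, and writes a miscibility report. All numeric tables
#' carry the configuration hash in a header comment; re-running with the
#' same configuration is byte-identical. On a stage failure a `FAILED`
#' marker naming the stage is left in the output directory and the error
#' is re-raised.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the computed tables (`descriptors`,
#'   `collapse_vs_x`, `area_vs_x` and `dg_vs_x` keyed by pressure,
#'   `miscibility`) and the output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  stage <- "load"
  on_fail <- function(e) {
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    series <- if (inherits(config$manifest, "composition_series")) {
      config$manifest
    } else {
      read_manifest(config$manifest)
    }
    comps <- series$components
    guest <- comps[length(comps)]

    stage <- "descriptors"
    all_iso <- c(series$pure_isotherms, series$mixed_isotherms)
    all_desc <- lapply(all_iso, descriptor_set,
                       smoothing_window = config$smoothing_window,
                       lift_off_threshold = config$lift_off_threshold,
                       slope_fraction = config$slope_fraction,
                       a0_fraction = config$a0_fraction)
    desc_tab <- do.call(rbind, lapply(all_desc, function(d) {
      x <- .aligned_fractions(list(components = d$components,
                                   mole_fractions = d$mole_fractions), comps)
      cbind(data.frame(label = d$label, stringsAsFactors = FALSE),
            as.data.frame(as.list(stats::setNames(x, paste0("x_", comps)))),
            data.frame(lift_off_A2 = d$lift_off_area,
                       a0_A2 = d$a0_extrapolated,
                       pi_coll_mN_m = if (nrow(d$collapses)) d$collapses$pressure[1L] else NA_real_,
                       a_coll_A2 = if (nrow(d$collapses)) d$collapses$area[1L] else NA_real_,
                       pi_coll2_mN_m = if (nrow(d$collapses) > 1L) d$collapses$pressure[2L] else NA_real_,
                       cs_inv_max_mN_m = d$cs_inv_max,
                       phase = d$phase_class,
                       plateau_pi_mN_m = if (is.null(d$transition_plateau)) NA_real_ else d$transition_plateau$pressure,
                       stringsAsFactors = FALSE))
    }))
    .write_table(desc_tab, file.path(config$out_dir, "descriptors.csv"),
                 hash, config$pressures)

    stage <- "collapse_vs_composition"
    nmix <- length(series$mixed_isotherms)
    mix_desc <- all_desc[length(series$pure_isotherms) + seq_len(nmix)]
    coll_tab <- desc_tab[length(series$pure_isotherms) + seq_len(nmix),
                         c(paste0("x_", comps), "pi_coll_mN_m", "pi_coll2_mN_m")]
    .write_table(coll_tab, file.path(config$out_dir, "collapse_vs_x.csv"),
                 hash, config$pressures)

    stage <- "excess_area"
    area_tabs <- list(); dg_tabs <- list()
    for (p in config$pressures) {
      at <- excess_area_curve(series, pi = p, grid_step = config$grid_step)
      dt <- dg_vs_composition(series, pi = p, grid_step = config$grid_step)
      area_tabs[[as.character(p)]] <- at
      dg_tabs[[as.character(p)]] <- dt
      .write_table(at, file.path(config$out_dir, sprintf("area_vs_x_pi%g.csv", p)),
                   hash, config$pressures)
      .write_table(dt, file.path(config$out_dir, sprintf("dg_vs_x_pi%g.csv", p)),
                   hash, config$pressures)
    }

    stage <- "miscibility"
    misc <- assess_miscibility(
      series,
      descriptors = list(pure = all_desc[seq_along(series$pure_isotherms)],
                         mixed = mix_desc),
      tolerance = config$miscibility_tolerance, guest = guest)
    misc_path <- file.path(config$out_dir, "miscibility.txt")
    con <- file(misc_path, "wt"); sink(con)
    print(misc)
    sink(); close(con)

    stage <- "log"
    log <- list(package = "monofilm",
                version = as.character(utils::packageVersion("monofilm")),
                config_hash = hash,
                pressures = config$pressures,
                system = series$system_name,
                n_pure = length(series$pure_isotherms),
                n_mixed = nmix)
    writeLines(yaml::as.yaml(log), file.path(config$out_dir, "run_log.yaml"))

    invisible(list(descriptors = desc_tab, collapse_vs_x = coll_tab,
                   area_vs_x = area_tabs, dg_vs_x = dg_tabs,
                   miscibility = misc, out_dir = config$out_dir,
                   config_hash = hash))
  }, error = on_fail)
}
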