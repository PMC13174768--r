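#' Preset simulation studies
#'
#' `run_preset()` re-runs the simulation studies at configurable scale:
#' homogeneous-cube characterization, the 1 cm interaction budget, the
#' 20 cm material-efficiency comparison, the clinical-scale insert
#' cylinders, and idealized end-to-end imaging chains (phantom, transport,
#' ring detection, list-mode reconstruction).
#'
#' @name pptsim-presets
NULL

.ppt_preset_names <- c("water_cube_10", "budget_cube_1", "material_cubes_20",
                       "six_insert", "four_rod", "nu4_small",
                       "clinical_ppt_imaging")

# production-map peak-to-valley between adjacent rods (four_rod layout)
.ppt_rod_p2v <- function(events, rod_radius_mm = 4, offset_mm = 50) {
  ang_pk <- seq(0, 270, by = 90) * pi / 180
  ang_vl <- seq(45, 315, by = 90) * pi / 180
  dens <- function(cx, cy, r) {
    sum(((events$x - cx)^2 + (events$y - cy)^2) <= r^2 &
          abs(events$z) <= 19) / (pi * r^2)
  }
  pk <- mapply(function(a) dens(offset_mm * cos(a), offset_mm * sin(a),
                                rod_radius_mm), ang_pk)
  vl <- mapply(function(a) dens(offset_mm * cos(a), offset_mm * sin(a), 5),
               ang_vl)
  min(pk) / max(mean(vl), .Machine$double.eps)
}

#' 2D event density map
#'
#' @param events A data frame with `x`, `y`, `z` columns (mm).
#' @param plane `"xz"`, `"xy"` or `"yz"`.
#' @param bin_mm Bin width in mm.
#' @return A tibble with the two plane coordinates and `counts`.
#' @export
event_map <- function(events, plane = c("xz", "xy", "yz"), bin_mm = 2) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  u <- events[[ax[1]]]; v <- events[[ax[2]]]
  bu <- bin_mm * floor(u / bin_mm) + bin_mm / 2
  bv <- bin_mm * floor(v / bin_mm) + bin_mm / 2
  out <- dplyr::count(tibble::tibble(u = bu, v = bv), .data$u, .data$v,
                      name = "counts")
  names(out)[1:2] <- ax
  out
}

#' Run a preset study
#'
#' @param name One of `r paste0('\x60', .ppt_preset_names, '\x60', collapse = ", ")`.
#' @param n_primaries Primaries per run (efficiency presets run several
#'   materials at this size each).
#' @param seed Integer seed recorded in all outputs.
#' @param out_dir Optional output directory; when given, the event log(s),
#'   list-mode files, images and a machine-readable `summary.json` are
#'   written there.
#' @param ... Overrides passed to [ppt_config()].
#' @return A bundle (list) with the run configuration, event log(s), and a
#'   `summary` list of the preset's statistics; imaging presets add the
#'   coincidence list and reconstructed `ppt_image3d`.
#' @export
run_preset <- function(name, n_primaries = 1e6, seed = 1, out_dir = NULL,
                       ...) {
  if (!name %in% .ppt_preset_names) {
    stop("unknown preset '", name, "'; available: ",
         paste(.ppt_preset_names, collapse = ", "), call. = FALSE)
  }
  run_config <- list(preset = name, n_primaries = n_primaries, seed = seed,
                     package_version = as.character(utils::packageVersion("pptsim")),
                     overrides = list(...))
  bundle <- switch(name,
    water_cube_10 = .ppt_preset_water_cube(n_primaries, seed, ...),
    budget_cube_1 = .ppt_preset_budget(n_primaries, seed, ...),
    material_cubes_20 = .ppt_preset_materials(n_primaries, seed, ...),
    six_insert = .ppt_preset_cylinder("six_insert", n_primaries, seed, ...),
    four_rod = .ppt_preset_cylinder("four_rod", n_primaries, seed, ...),
    nu4_small = .ppt_preset_imaging("nu4_small", n_primaries, seed, ...),
    clinical_ppt_imaging = .ppt_preset_imaging("four_rod", n_primaries,
                                               seed, tof = TRUE, ...))
  bundle$run_config <- run_config
  if (!is.null(out_dir)) .ppt_write_bundle(bundle, out_dir)
  bundle
}

.ppt_preset_water_cube <- function(n, seed, ...) {
  grid <- build_cube(100, "water", "point")
  cfg <- ppt_config(track_annihilation_photons = FALSE, ...)
  log <- run_simulation(grid, n, cfg, seed)
  ps <- positron_stats(log)
  prof_p <- slice_profile(log$pairs, "x")
  prof_a <- slice_profile(log$annihilations, "x")
  fit_p <- fit_profile(prof_p)
  fit_a <- fit_profile(prof_a)
  list(grid = grid, log = log,
       summary = list(
         interaction_fractions = interaction_fractions(log),
         positron = ps,
         fwhm_production_mm = fit_p$fwhm,
         fwhm_annihilation_mm = fit_a$fwhm,
         fit_production = glance(fit_p), fit_annihilation = glance(fit_a)),
       fits = list(production = fit_p, annihilation = fit_a))
}

.ppt_preset_budget <- function(n, seed, ...) {
  grid <- build_cube(10, "water", "point")
  cfg <- ppt_config(track_secondaries = FALSE,
                    track_annihilation_photons = FALSE, ...)
  log <- run_simulation(grid, n, cfg, seed)
  list(grid = grid, log = log,
       summary = list(
         interaction_fractions = interaction_fractions(log),
         oracle = interaction_fractions_oracle("water", cfg$energy_mev, 1)))
}

.ppt_preset_materials <- function(n, seed, ...) {
  mats <- c("water", "adipose", "lung", "bone")
  logs <- list()
  for (i in seq_along(mats)) {
    grid <- build_cube(200, mats[i], "point", voxel_mm = 2)
    cfg <- ppt_config(track_annihilation_photons = FALSE, ...)
    logs[[mats[i]]] <- run_simulation(grid, n, cfg, seed + i - 1)
  }
  eff <- efficiency_table(logs)
  ratio <- function(a, b) {
    eff$production_efficiency[eff$material == a] /
      eff$production_efficiency[eff$material == b]
  }
  list(logs = logs,
       summary = list(efficiency = eff,
                      bone_over_water = ratio("bone", "water"),
                      bone_over_lung = ratio("bone", "lung")))
}

.ppt_preset_cylinder <- function(preset, n, seed, ...) {
  grid <- build_cylinder_phantom(preset)
  cfg <- ppt_config(track_annihilation_photons = FALSE, ...)
  log <- run_simulation(grid, n, cfg, seed)
  smry <- list(
    interaction_fractions = interaction_fractions(log),
    production_map_xz = event_map(log$pairs, "xz"),
    annihilation_map_xz = event_map(log$annihilations, "xz"))
  if (preset == "four_rod") {
    smry$rod_peak_to_valley <- .ppt_rod_p2v(log$pairs)
  }
  list(grid = grid, log = log, summary = smry)
}

.ppt_preset_imaging <- function(phantom, n, seed, tof = FALSE, ...) {
  grid <- build_cylinder_phantom(phantom)
  cfg <- ppt_config(track_annihilation_photons = TRUE, ...)
  log <- run_simulation(grid, n, cfg, seed)
  ring <- detector_ring(if (tof) "clinical" else "preclinical")
  hits <- detect_singles(log$photons, ring)
  coin <- sort_coincidences(hits, ring)
  geom <- image_geometry(grid$shape, grid$voxel_mm)
  img <- if (nrow(coin)) {
    if (tof) {
      postfilter(mlem_reconstruct(coin, geom, n_iter = 4, n_subsets = 5,
                                  tof = TRUE,
                                  tof_fwhm_ps = ring$timing_fwhm_ps), 9)
    } else {
      mlem_reconstruct(coin, geom, n_iter = 40, n_subsets = 1)
    }
  } else NULL
  list(grid = grid, log = log, ring = ring, coincidences = coin,
       image = img,
       summary = list(
         cascade = list(n_primaries = log$n_primaries,
                        n_pairs = nrow(log$pairs),
                        n_annihilations = nrow(log$annihilations),
                        n_escaping_photons = nrow(log$photons),
                        n_singles = nrow(hits),
                        n_coincidences = nrow(coin))))
}

.ppt_write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  smry <- .ppt_summarize_for_json(bundle$summary)
  smry$run_config <- bundle$run_config
  jsonlite::write_json(smry, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(bundle$log)) {
    write_eventlog(bundle$log, file.path(out_dir, "events.csv.gz"))
  }
  if (!is.null(bundle$logs)) {
    for (nm in names(bundle$logs)) {
      write_eventlog(bundle$logs[[nm]],
                     file.path(out_dir, paste0("events_", nm, ".csv.gz")))
    }
  }
  if (!is.null(bundle$coincidences) && nrow(bundle$coincidences)) {
    write_listmode(bundle$coincidences, bundle$ring,
                   file.path(out_dir, "listmode.tsv"))
  }
  if (!is.null(bundle$image) &&
      requireNamespace("RNifti", quietly = TRUE)) {
    write_image_nifti(bundle$image, file.path(out_dir, "image.nii.gz"))
  }
  invisible(out_dir)
}

.ppt_summarize_for_json <- function(x) {
  if (inherits(x, "ppt_profile_fit")) x <- as.list(glance(x))
  if (inherits(x, "data.frame")) return(x)
  if (is.list(x)) return(lapply(x, .ppt_summarize_for_json))
  x
}
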