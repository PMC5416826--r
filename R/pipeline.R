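# Reproducible pipeline driver: strict configuration, per-stage derived
# seeds, file artifacts and a run manifest.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = "fbalm_run",
    stages = c("simulate", "localize", "render"),
    verbose = TRUE,
    simulate = list(
      structure = list(nucleus_center = c(6400, 6400),
                       nucleus_semiaxes = c(5000, 4000),
                       n_clusters = 60, n_sites = 20000,
                       diameter_range_nm = c(100, 400),
                       backbone_fraction = 0.3, backbone_sd_nm = 25),
      acquisition = list(pixel_size_nm = 100, psf_sigma_nm = 130,
                         n_frames = 1000, mean_events_per_frame = 8,
                         mean_on_frames = 3, photons_per_frame_mean = 1000,
                         background_photons_per_pixel = 10,
                         read_noise_sd = 2, camera_offset = 100,
                         camera_gain = 1, fov_px = c(128, 128))),
    localize = list(threshold_k = 3, roi_halfwidth = 3, bg_radius = 5,
                    smooth_sigma_px = 1.3, filter_fraction = 0.3,
                    merge = TRUE, merge_radius_nm = NULL),
    render = list(mode = "histogram", pixel_nm = 5),
    frc = list(split = "odd_even", render_pixel_nm = 10,
               threshold = 1 / 7, fit_order = 8),
    density = list(bin_nm = 60),
    foci = list(n_foci = 2000, contraction = 0.8434,
                voxel_nm = c(80, 80, 250), k = 4)
  )
}

#' Validate and complete a pipeline configuration
#'
#' Unknown keys anywhere in the configuration are rejected; every
#' defaulted parameter is filled in so the saved copy of the resolved
#' configuration documents the complete run.
#'
#' @param config named list (possibly nested) of overrides, or a path
#'   to a YAML file of the same shape.
#' @return the resolved configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_pipeline_config()
  out <- merge_config(def, config[setdiff(names(config),
                                          c("simulate", "localize",
                                            "render", "frc", "density",
                                            "foci"))])
  for (blk in c("localize", "render", "frc", "density", "foci"))
    out[[blk]] <- merge_config(def[[blk]], config[[blk]], blk)
  sim <- config$simulate
  out$simulate$structure <- merge_config(def$simulate$structure,
                                         sim$structure,
                                         "simulate$structure")
  out$simulate$acquisition <- merge_config(def$simulate$acquisition,
                                           sim$acquisition,
                                           "simulate$acquisition")
  if (!is.null(sim)) {
    unknown <- setdiff(names(sim), c("structure", "acquisition"))
    if (length(unknown) > 0L)
      stop_param("unknown key(s) in simulate: %s",
                 paste(unknown, collapse = ", "))
  }
  bad <- setdiff(out$stages,
                 c("simulate", "localize", "render", "frc", "density",
                   "foci"))
  if (length(bad) > 0L)
    stop_param("unknown stage(s): %s", paste(bad, collapse = ", "))
  class(out) <- "pipeline_config"
  out
}

# Per-stage seeds derived deterministically from the global seed (kept
# below 2^31).
derive_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, localize = 0L, render = 0L, frc = 307L,
            density = 0L, foci = 409L)
  (as.integer(seed) * 7919L + offs[[stage]]) %% 2147483647L
}

#' Run the fBALM pipeline end to end
#'
#' Executes the requested stages in order (simulate, localize, render,
#' frc, density, foci), writing every artifact under `output_dir`
#' together with the resolved configuration and a manifest listing
#' inputs, outputs, per-stage seeds and record counts. All randomness
#' derives from the single global seed, so rerunning a saved
#' configuration reproduces every output bit-exactly.
#'
#' @param config a [pipeline_config()] (or anything accepted by it).
#' @return the manifest, invisibly (list; also written as
#'   `manifest.yaml`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(unclass(config))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(cfg$output_dir, ...)
  yaml::write_yaml(unclass(cfg), out("config_resolved.yaml"))
  manifest <- list(config = "config_resolved.yaml", seed = cfg$seed,
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    log_stage(cfg$verbose, "stage %s done", stage)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      yaml::write_yaml(manifest, out("manifest.yaml"))
      stop_param("stage '%s' failed: %s (partial outputs kept in %s)",
                 stage, conditionMessage(e), cfg$output_dir)
    })
  }

  tab <- NULL
  movie <- NULL
  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    sseed <- derive_seed(cfg$seed, "simulate")
    gt <- generate_chromatin_structure(
      do.call(chromatin_params, cfg$simulate$structure), seed = sseed)
    sim <- simulate_movie(gt, do.call(acquisition_params,
                                      cfg$simulate$acquisition),
                          seed = sseed + 1L)
    movie <<- sim$movie
    utils::write.csv(cbind(site = seq_len(nrow(gt$site_positions)),
                           gt$site_positions),
                     out("ground_truth_sites.csv"), row.names = FALSE)
    ev <- sim$events
    ev$photons_per_frame <- NULL
    utils::write.csv(ev, out("emission_records.csv"), row.names = FALSE)
    write_movie(sim$movie, out("movie.tif"))
    note("simulate", seed = sseed,
         outputs = c("movie.tif", "ground_truth_sites.csv",
                     "emission_records.csv"),
         n_sites = nrow(gt$site_positions), n_events = nrow(sim$events))
  })
  if ("localize" %in% cfg$stages) run_stage("localize", function() {
    if (is.null(movie)) movie <<- read_movie(out("movie.tif"))
    tab <<- localize_movie(movie, do.call(localize_config, cfg$localize),
                           verbose = cfg$verbose)
    write_localizations(tab, out("localizations.csv"))
    note("localize", inputs = "movie.tif", outputs = "localizations.csv",
         n_localizations = nrow(tab))
  })
  get_table <- function() {
    if (is.null(tab))
      tab <<- read_localizations(out("localizations.csv"),
                                 pixel_size_nm =
                                   cfg$simulate$acquisition$pixel_size_nm)
    tab
  }
  if ("render" %in% cfg$stages) run_stage("render", function() {
    tb <- get_table()
    img <- if (cfg$render$mode == "voronoi")
      render_voronoi(tb, pixel_nm = cfg$render$pixel_nm)
    else render_histogram(tb, bin_nm = cfg$render$pixel_nm)
    write_rendered(img, out("reconstruction.tif"))
    note("render", inputs = "localizations.csv",
         outputs = "reconstruction.tif", mode = cfg$render$mode,
         sum = sum(img$values))
  })
  if ("frc" %in% cfg$stages) run_stage("frc", function() {
    tb <- get_table()
    fseed <- derive_seed(cfg$seed, "frc")
    r <- frc_resolution(tb, render_pixel_nm = cfg$frc$render_pixel_nm,
                        split = cfg$frc$split,
                        threshold = cfg$frc$threshold,
                        fit_order = cfg$frc$fit_order, seed = fseed)
    write_frc_curve(r$curve, out("frc_curve.csv"))
    yaml::write_yaml(list(resolution_nm = r$resolution$resolution_nm,
                          method = r$resolution$method,
                          threshold = r$resolution$threshold),
                     out("frc_resolution.yaml"))
    note("frc", seed = fseed, inputs = "localizations.csv",
         outputs = c("frc_curve.csv", "frc_resolution.yaml"),
         resolution_nm = r$resolution$resolution_nm)
  })
  if ("density" %in% cfg$stages) run_stage("density", function() {
    tb <- get_table()
    st <- density_stats(bin_counts(tb, bin_nm = cfg$density$bin_nm))
    yaml::write_yaml(list(median_per_square = st$median_per_square,
                          mean_per_square = st$mean_per_square,
                          normalized_median = st$normalized_median,
                          skewness = st$skewness,
                          n_squares = st$n_squares),
                     out("density_stats.yaml"))
    utils::write.csv(st$cumulative, out("density_cumulative.csv"),
                     row.names = FALSE)
    note("density", inputs = "localizations.csv",
         outputs = c("density_stats.yaml", "density_cumulative.csv"),
         skewness = st$skewness)
  })
  if ("foci" %in% cfg$stages) run_stage("foci", function() {
    fseed <- derive_seed(cfg$seed, "foci")
    before <- generate_foci_3d(cfg$foci$n_foci, seed = fseed)
    after <- apply_isotropic_contraction(before, cfg$foci$contraction)
    write_foci(before, out("foci_before.csv"))
    write_foci(after, out("foci_after.csv"))
    ch <- compare_before_after(before, after)
    yaml::write_yaml(list(delta_mean_nn_nm = ch$delta_mean_nn_nm,
                          volume_change_pct = ch$volume_change_pct,
                          n_before = ch$n_before, n_after = ch$n_after),
                     out("foci_change.yaml"))
    note("foci", seed = fseed,
         outputs = c("foci_before.csv", "foci_after.csv",
                     "foci_change.yaml"),
         volume_change_pct = ch$volume_change_pct)
  })
  yaml::write_yaml(manifest, out("manifest.yaml"))
  invisible(manifest)
}
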