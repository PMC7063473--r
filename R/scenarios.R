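#' Packaged end-to-end scenarios
#'
#' Seeded scenario configurations reproducing the package's reference
#' simulation setups: `cord-activation-mouse`, `cord-activation-macaque`,
#' `cord-activation-human` (cord phantoms illuminated by a 105-um NA-0.22 fiber
#' at the dorsal midline, 10 mW at 473 nm, perfused-tissue absorption) and
#' `wm-block-extent-ratio` (homogeneous white-matter block probed
#' perpendicular to the fibers, for the along-fiber elongation of the
#' activation contour).
#'
#' @return `list_scenarios()`: character vector of packaged scenario names.
#' @export
list_scenarios <- function() {
  dir <- system.file("extdata", "scenarios", package = "spinelight",
                     mustWork = TRUE)
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

#' @rdname list_scenarios
#' @param name packaged scenario name.
#' @return `scenario_path()`: path to the packaged scenario file.
#' @export
scenario_path <- function(name) {
  p <- system.file("extdata", "scenarios", paste0(name, ".json"),
                   package = "spinelight")
  if (p == "")
    stop("unknown scenario '", name, "'; packaged scenarios: ",
         paste(list_scenarios(), collapse = ", "))
  p
}

.scenario_required <- list(
  phantom = NULL, tissues = c("preset"), source = c("power", "wavelength"),
  run = c("n_photons", "seed"), analysis = c("threshold"))

#' Read, validate and write scenario configurations
#'
#' A scenario is a nested JSON document with blocks `phantom` (species
#' preset or block geometry), `tissues` (preset name, blood content,
#' wavelength), `source`, `run` and `analysis`. `read_scenario()` accepts a
#' packaged scenario name or a file path and validates the schema;
#' parse - emit - parse is the identity.
#'
#' @param x packaged scenario name or path to a JSON file.
#' @return a `scenario_config` list.
#' @export
read_scenario <- function(x) {
  path <- if (file.exists(x)) x else scenario_path(x)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_scenario(cfg)
}

#' @rdname read_scenario
#' @param cfg a scenario list.
#' @export
validate_scenario <- function(cfg) {
  missing_blocks <- setdiff(names(.scenario_required), names(cfg))
  bad <- character()
  if (length(missing_blocks))
    bad <- c(bad, paste0("missing block: ", missing_blocks))
  for (blk in intersect(names(.scenario_required), names(cfg))) {
    need <- setdiff(.scenario_required[[blk]], names(cfg[[blk]]))
    if (length(need)) bad <- c(bad, paste0(blk, ": missing ", need))
  }
  if (!is.null(cfg$run$n_photons) && cfg$run$n_photons < 1)
    bad <- c(bad, "run: n_photons must be >= 1")
  if (!is.null(cfg$analysis$threshold) && cfg$analysis$threshold <= 0)
    bad <- c(bad, "analysis: threshold must be positive")
  if (!is.null(cfg$phantom$preset) &&
      !cfg$phantom$preset %in% c("mouse", "macaque", "human"))
    bad <- c(bad, paste0("phantom: unknown preset '", cfg$phantom$preset, "'"))
  if (is.null(cfg$phantom$preset) && is.null(cfg$phantom$block))
    bad <- c(bad, "phantom: needs either a species preset or a block")
  if (length(bad))
    stop("invalid scenario configuration:\n  ", paste(bad, collapse = "\n  "))
  structure(cfg, class = "scenario_config")
}

#' @rdname read_scenario
#' @param path output file.
#' @export
write_scenario <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.scenario_volume <- function(cfg) {
  ph <- cfg$phantom
  if (!is.null(ph$preset)) {
    preset <- species_preset(ph$preset)
    if (!is.null(ph$pitch_mm)) preset$pitch <- ph$pitch_mm
    z_extent <- if (is.null(ph$z_extent_mm)) 4 else ph$z_extent_mm
    cord_phantom(preset, z_extent_mm = z_extent)
  } else {
    b <- ph$block
    spec <- voxel_spec(round(b$size_mm[1] / b$pitch_mm),
                       round(b$size_mm[2] / b$pitch_mm),
                       round(b$size_mm[3] / b$pitch_mm), b$pitch_mm)
    homogeneous_block(spec, label = 1L,
                      name = if (is.null(b$tissue)) "white_matter" else b$tissue)
  }
}

.scenario_source <- function(cfg, volume) {
  sc <- cfg$source
  s <- volume$spec
  pos <- sc$position
  if (is.null(pos) || identical(pos, "dorsal_midline")) {
    x0 <- s$nx * s$dx / 2
    z0 <- s$nz * s$dz / 2
    surf <- dorsal_surface(volume)
    iy <- surf[round(s$nx / 2), round(s$nz / 2)]
    pos <- c(x0, if (is.na(iy)) 0 else iy, z0)
  }
  source_spec(tip_position = as.numeric(pos),
              beam_axis = if (is.null(sc$beam_axis)) c(0, 1, 0)
              else as.numeric(sc$beam_axis),
              core_diameter = if (is.null(sc$core_diameter_mm)) 0.105
              else sc$core_diameter_mm,
              numerical_aperture = if (is.null(sc$na)) 0.22 else sc$na,
              power = sc$power, wavelength = sc$wavelength)
}

#' Run a packaged or user scenario end-to-end
#'
#' Builds the phantom, derives the property table at the simulation
#' wavelength, places the fiber, runs the transport engine, and computes
#' activation metrics.
#'
#' @param scenario a `scenario_config`, packaged scenario name, or path.
#' @param n_photons,seed optional overrides of the scenario's run block
#'   (e.g. for quick desk-scale replicates).
#' @return list with `config`, `volume`, `props`, `source`, `result`
#'   (a `fluence_result`) and `metrics` (an [activation_metrics()]).
#' @export
run_scenario <- function(scenario, n_photons = NULL, seed = NULL) {
  cfg <- if (inherits(scenario, "scenario_config")) scenario
  else read_scenario(scenario)
  if (!is.null(n_photons)) cfg$run$n_photons <- n_photons
  if (!is.null(seed)) cfg$run$seed <- seed
  volume <- .scenario_volume(cfg)
  ts <- cfg$tissues
  tissues <- tissue_preset(
    ts$preset,
    blood_volume_fraction = if (is.null(ts$blood_volume_fraction)) 0.028
    else ts$blood_volume_fraction,
    oxygen_saturation = if (is.null(ts$oxygen_saturation)) 0.62
    else ts$oxygen_saturation,
    mua_baseline = if (is.null(ts$mua_baseline)) 0.05 else ts$mua_baseline,
    g = if (is.null(ts$g)) 0.9 else ts$g,
    b = if (is.null(ts$b)) 1.6 else ts$b)
  props <- build_property_table(tissues, cfg$source$wavelength)
  source <- .scenario_source(cfg, volume)
  config <- run_config(
    n_photons = cfg$run$n_photons, seed = cfg$run$seed,
    combination_mode = if (is.null(cfg$run$combination_mode)) "quadratic"
    else cfg$run$combination_mode)
  result <- run_mc(volume, props, source, config)
  metrics <- activation_metrics(result, volume, source,
                                power = cfg$source$power,
                                threshold = cfg$analysis$threshold)
  list(config = cfg, volume = volume, props = props, source = source,
       result = result, metrics = metrics)
}
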