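# Configuration loading, result serialisation and the named fixture
# scenarios that make every other module testable without external data.

#' Load a phantom description from a YAML config
#'
#' The config mirrors the published phantom description: a material table
#' (coefficients in cm^-1, as printed), a layer list (surface first, the
#' terminal layer semi-infinite), an artery, and the domain. Unknown keys,
#' missing materials and non-positive thicknesses are rejected with the
#' offending key named. All coefficients are converted to mm^-1 on load.
#'
#' @param path path to a YAML file. See
#'   \code{system.file("extdata", "phantom_default.yaml", package = "pulseoxmc")}
#'   for the published configuration.
#' @return A [phantom_model()].
#' @export
load_phantom_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("materials", "layers", "artery", "domain", "separation_mm", "g")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$materials) || is.null(cfg$layers))
    stop("config must define `materials` and `layers`")
  g_default <- if (!is.null(cfg$g)) cfg$g else phantom_constants()$g

  mats <- lapply(cfg$materials, function(m) {
    bad <- setdiff(names(m), c("mu_a_per_cm", "mu_s_prime_per_cm", "g", "n"))
    if (length(bad)) stop("unknown material key(s): ",
                          paste(bad, collapse = ", "),
                          " (coefficients must carry their unit in the key)")
    if (is.null(m$mu_a_per_cm) || is.null(m$mu_s_prime_per_cm))
      stop("material needs `mu_a_per_cm` and `mu_s_prime_per_cm`")
    optical_properties(mu_a = m$mu_a_per_cm / 10,
                       mu_s_prime = m$mu_s_prime_per_cm / 10,
                       g = if (!is.null(m$g)) m$g else g_default,
                       n = if (!is.null(m$n)) m$n else 1)
  })

  nm <- vapply(cfg$layers, function(l) l$name, character(1))
  th <- vapply(cfg$layers, function(l) {
    t <- if (is.null(l$thickness_mm)) Inf else l$thickness_mm
    if (!is.infinite(t) && t <= 0)
      stop("layer `", l$name, "` has non-positive thickness_mm")
    t
  }, numeric(1))
  layers <- layer_stack(nm, th)

  art <- NULL
  if (!is.null(cfg$artery)) {
    a <- cfg$artery
    bad <- setdiff(names(a), c("depth_mm", "diameter_mm", "offset_mm", "material"))
    if (length(bad)) stop("unknown artery key(s): ", paste(bad, collapse = ", "))
    art <- artery(a$depth_mm, a$diameter_mm,
                  offset_mm = if (!is.null(a$offset_mm)) a$offset_mm else 0,
                  material = if (!is.null(a$material)) a$material else "blood")
  }

  dom <- if (!is.null(cfg$domain)) cfg$domain else list()
  phantom_model(
    layers, art, mats,
    lateral_mm = if (!is.null(dom$lateral_mm)) dom$lateral_mm else 30,
    depth_mm_max = if (!is.null(dom$depth_mm)) dom$depth_mm else 60,
    voxel_mm = if (!is.null(dom$voxel_mm)) dom$voxel_mm
      else phantom_constants()$voxel_mm,
    separation_mm = if (!is.null(cfg$separation_mm)) cfg$separation_mm
      else phantom_constants()$separation_mm)
}

# plain-list view of a phantom, for JSON echo and manifests
phantom_to_list <- function(phantom) {
  list(
    materials = lapply(phantom$materials, function(m)
      list(mu_a_per_mm = m$mu_a, mu_s_per_mm = m$mu_s,
           mu_s_prime_per_mm = m$mu_s_prime, g = m$g, n = m$n)),
    layers = Map(function(id, th) list(name = id, thickness_mm = th),
                 phantom$layers$materials, phantom$layers$thickness_mm),
    artery = if (is.null(phantom$artery)) NULL else unclass(phantom$artery),
    domain = list(lateral_mm = phantom$lateral_mm,
                  depth_mm = phantom$depth_mm_max,
                  voxel_mm = phantom$voxel_mm),
    separation_mm = phantom$separation_mm)
}

#' Echo a fully resolved phantom as JSON
#'
#' @param phantom a [phantom_model()].
#' @return A JSON string (all units mm and mm^-1).
#' @export
echo_config <- function(phantom) {
  jsonlite::toJSON(phantom_to_list(phantom), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' Build a named fixture scenario
#'
#' Deterministic, self-contained configurations used throughout the test
#' suite and available to users as worked examples:
#' \describe{
#'   \item{beer_lambert_slab}{a purely absorbing slab (mu_s = 0) of unit
#'     optical depth; the weight crossing the bottom face has the closed
#'     form exp(-mu_a d), carried in \code{$reference}.}
#'   \item{conservative_halfspace}{a scattering, non-absorbing half-space
#'     with matched boundary; all injected weight is eventually re-emitted.}
#'   \item{invisible_artery}{the published phantom with the artery lumen
#'     given its host layer's properties; the pulsation pipeline must
#'     return an amplitude of zero within Monte Carlo error.}
#'   \item{paper_default}{the published phantom, source and detector at a
#'     chosen artery depth.}
#' }
#'
#' @param scenario scenario name.
#' @param depth artery depth for the artery-bearing scenarios, mm.
#' @param mu_a,thickness_mm absorption and thickness of the Beer-Lambert
#'   slab (defaults give optical depth 1).
#' @param n_photons,seed transport defaults carried in the fixture.
#' @return List with \code{phantom}, \code{source}, \code{detector},
#'   \code{options} and a scenario-specific \code{reference} list.
#' @examples
#' fx <- make_fixture("beer_lambert_slab")
#' fx$reference$transmittance  # exp(-1)
#' @export
make_fixture <- function(scenario = c("beer_lambert_slab",
                                      "conservative_halfspace",
                                      "invisible_artery", "paper_default"),
                         depth = 3.7, mu_a = 0.1, thickness_mm = 10,
                         n_photons = 1e5, seed = 1) {
  scenario <- match.arg(scenario)
  opts <- transport_options(n_photons = n_photons, seed = seed)
  src <- source_spec(); det <- detector_spec()
  if (scenario == "beer_lambert_slab") {
    ph <- phantom_model(
      layer_stack("absorber", Inf), artery = NULL,
      materials = list(absorber = optical_properties(mu_a = mu_a, mu_s = 0,
                                                     g = 0)),
      depth_mm_max = thickness_mm)
    ref <- list(transmittance = exp(-mu_a * thickness_mm),
                tally = "escaped_bottom / injected")
  } else if (scenario == "conservative_halfspace") {
    ph <- phantom_model(
      layer_stack("scatterer", Inf), artery = NULL,
      materials = list(scatterer = optical_properties(mu_a = 0, mu_s = 20,
                                                      g = 0.9)),
      lateral_mm = 500, depth_mm_max = 1000)
    ref <- list(reemitted_fraction = 1,
                tally = "(detected + escaped - escaped_bottom) / injected")
  } else if (scenario == "invisible_artery") {
    ph <- build_default_phantom(depth)
    host <- single_layer_host(ph, depth, ph$artery$diameter_mm / 2)
    ph$materials$blood <- ph$materials[[host]]
    ref <- list(amplitude_ppm = 0)
  } else {
    ph <- build_default_phantom(depth)
    ref <- list(diameters_mm = phantom_constants()$diameter_sweep_mm,
                dilation = phantom_constants()$pulsation_intensity)
  }
  list(phantom = ph, source = src, detector = det, options = opts,
       reference = ref, scenario = scenario)
}

#' Manifest of a simulation result
#'
#' Everything needed to reproduce a detection result bit-exactly: the
#' resolved phantom, source, detector, options (including the seed) and
#' the package version.
#'
#' @param result an [run_simulation()] result.
#' @return A manifest list.
#' @seealso [rerun_from_manifest()]
#' @export
result_manifest <- function(result) {
  stopifnot(inherits(result, "mc_detection"))
  list(package = "pulseoxmc",
       version = as.character(utils::packageVersion("pulseoxmc")),
       phantom = phantom_to_list(result$phantom),
       source = unclass(result$source),
       detector = unclass(result$detector),
       options = unclass(result$options))
}

#' Re-run a simulation from its manifest
#'
#' Reconstructs the phantom and options embedded in a manifest (or in a
#' result file written by [write_result()]) and repeats the simulation;
#' with the stored seed the tallies reproduce bit-exactly.
#'
#' @param manifest a manifest list, or the path to a result JSON file.
#' @return An \code{mc_detection} result.
#' @export
rerun_from_manifest <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)$manifest
  pl <- manifest$phantom
  mats <- lapply(pl$materials, function(m)
    optical_properties(mu_a = m$mu_a_per_mm, mu_s = m$mu_s_per_mm,
                       g = m$g, n = m$n))
  nm <- vapply(pl$layers, function(l) l$name, character(1))
  th <- vapply(pl$layers, function(l) {
    t <- l$thickness_mm
    if (is.null(t) || is.character(t)) Inf else as.numeric(t)
  }, numeric(1))
  art <- if (is.null(pl$artery) || length(pl$artery) == 0) NULL else
    artery(pl$artery$depth_mm, pl$artery$diameter_mm,
           pl$artery$offset_mm, pl$artery$material)
  ph <- phantom_model(layer_stack(nm, th), art, mats,
                      lateral_mm = pl$domain$lateral_mm,
                      depth_mm_max = pl$domain$depth_mm,
                      voxel_mm = pl$domain$voxel_mm,
                      separation_mm = pl$separation_mm)
  s <- manifest$source
  src <- source_spec(s$x, s$y, s$type, s$half_angle_deg, s$flux_W)
  d <- manifest$detector
  det <- detector_spec(d$cx, d$cy, d$area_mm2, d$shape)
  o <- manifest$options
  opts <- transport_options(o$n_photons, o$seed, o$packet_offset,
                            o$w_threshold, o$p_survival, o$boundary,
                            o$n_tissue, o$geometry, o$record, o$max_steps)
  run_simulation(ph, src, det, opts)
}

#' Write a detection result (with its manifest) to JSON
#'
#' @param result an [run_simulation()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_result <- function(result, path) {
  stopifnot(inherits(result, "mc_detection"))
  payload <- list(
    tallies = list(
      injected = result$injected, detected = result$detected,
      absorbed = result$absorbed, escaped = result$escaped,
      escaped_bottom = result$escaped_bottom,
      n_detected = result$n_detected,
      detected_fraction = result$detected_fraction,
      detected_fraction_se = result$detected_fraction_se,
      detected_ppm = result$detected_ppm),
    manifest = result_manifest(result))
  # I(17) significant digits: doubles survive the round trip bit-exactly,
  # which rerun_from_manifest relies on
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a depth profile as CSV
#'
#' Columns: depth_mm, amplitude_ppm, amplitude_se_ppm, slope, intercept,
#' r2, n_photons, seed.
#'
#' @param profile a [depth_profile()] result.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  utils::write.csv(profile$table, path, row.names = FALSE)
  invisible(path)
}
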