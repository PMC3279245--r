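#' Photon source specification
#'
#' The default source is a pencil beam injected vertically at the surface,
#' matching the simulation the package reproduces. A cone source samples
#' directions uniformly in solid angle within a half-angle around the
#' vertical, approximating the divergence of the real LED (half angle
#' 55 degrees, 1.8 mW radiant flux).
#'
#' @param x,y position on the surface, mm. The source sits at the origin;
#'   the detector centre at \code{(separation, 0)}.
#' @param type \code{"pencil"} (default) or \code{"cone"}.
#' @param half_angle_deg cone half-angle in degrees (cone type only).
#' @param flux_W nominal radiant flux in W; metadata used by the
#'   calibration arithmetic, not by transport.
#' @return An object of class \code{"source_spec"}.
#' @export
source_spec <- function(x = 0, y = 0, type = c("pencil", "cone"),
                        half_angle_deg = 55,
                        flux_W = phantom_constants()$source_flux_W) {
  type <- match.arg(type)
  if (type == "cone")
    stopifnot(half_angle_deg > 0, half_angle_deg <= 90)
  structure(list(x = x, y = y, type = type,
                 half_angle_deg = half_angle_deg, flux_W = flux_W),
            class = "source_spec")
}

#' Detector specification
#'
#' The default detector mirrors the published geometry: a 7.5 mm^2 active
#' area (as a square of side sqrt(7.5) mm, edges aligned with the
#' source-detector axis) centred 11 mm from the source, accepting every
#' exit angle. A disc of equal area is available.
#'
#' @param cx,cy centre on the surface, mm.
#' @param area_mm2 active area, mm^2.
#' @param shape \code{"square"} or \code{"disc"}.
#' @return An object of class \code{"detector_spec"}.
#' @export
detector_spec <- function(cx = phantom_constants()$separation_mm, cy = 0,
                          area_mm2 = phantom_constants()$detector_area_mm2,
                          shape = c("square", "disc")) {
  shape <- match.arg(shape)
  stopifnot(area_mm2 > 0)
  half <- if (shape == "square") sqrt(area_mm2) / 2 else sqrt(area_mm2 / pi)
  structure(list(cx = cx, cy = cy, area_mm2 = area_mm2, shape = shape,
                 half = half),
            class = "detector_spec")
}

#' Transport options
#'
#' @param n_photons number of photon packets to inject.
#' @param seed integer seed; together with the per-packet substream scheme
#'   it makes runs bit-reproducible and batch-partition invariant.
#' @param packet_offset index of the first packet (for batched runs that
#'   must reproduce a larger run's substreams).
#' @param w_threshold Russian-roulette weight threshold.
#' @param p_survival Russian-roulette survival probability.
#' @param boundary \code{"matched"} (refractive index 1 everywhere, the
#'   default) or \code{"fresnel"} (tissue index \code{n_tissue}, specular
#'   entry loss and internal Fresnel reflection at the free surface).
#' @param n_tissue tissue refractive index for the Fresnel model.
#' @param geometry \code{"implicit"} (analytic surfaces) or
#'   \code{"voxelized"} (0.05 mm grid, voxel-by-voxel traversal).
#' @param record \code{"none"}, \code{"artery"} (per detected packet,
#'   geometric path length and collision count inside the artery lumen,
#'   needed by [perturbed_detection()]), or \code{"cylinders"} (the same
#'   for a grid of candidate cylinders; used by the perturbation sweep).
#' @param max_steps safety cap on interactions per packet.
#' @return An object of class \code{"transport_options"}.
#' @export
transport_options <- function(n_photons = 1e5, seed = 1, packet_offset = 0,
                              w_threshold = 1e-4, p_survival = 0.1,
                              boundary = c("matched", "fresnel"),
                              n_tissue = 1.4,
                              geometry = c("implicit", "voxelized"),
                              record = c("none", "artery", "cylinders"),
                              max_steps = 1e6) {
  boundary <- match.arg(boundary)
  geometry <- match.arg(geometry)
  record <- match.arg(record)
  stopifnot(n_photons >= 1, w_threshold > 0, w_threshold < 1,
            p_survival > 0, p_survival < 1)
  structure(list(n_photons = n_photons, seed = seed,
                 packet_offset = packet_offset,
                 w_threshold = w_threshold, p_survival = p_survival,
                 boundary = boundary, n_tissue = n_tissue,
                 geometry = geometry, record = record,
                 max_steps = max_steps),
            class = "transport_options")
}

# ---- elementary transport samplers --------------------------------------
# These mirror the kernel's arithmetic and give the testable primitives.

#' Sample an exponential free path
#'
#' \code{s = -log(u) / mu_t}, the free-flight distance between
#' interactions in a medium of total attenuation \code{mu_t}.
#'
#' @param mu_t total attenuation coefficient mu_a + mu_s, mm^-1.
#' @param u uniform random deviate(s) in (0, 1).
#' @return Path length(s) in mm; \code{Inf} when \code{mu_t} is 0 (a void:
#'   straight flight to the next boundary).
#' @examples
#' sample_free_path(2, exp(-1))  # 0.5 mm
#' @export
sample_free_path <- function(mu_t, u) {
  stopifnot(mu_t >= 0, all(u > 0), all(u < 1))
  if (mu_t == 0) return(rep(Inf, length(u)))
  -log(u) / mu_t
}

#' Sample a Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of the Henyey-Greenstein phase function. For
#' g = 0 it reduces to an isotropic \code{2u - 1}.
#'
#' @param g anisotropy factor in (-1, 1).
#' @param u uniform random deviate(s) in (0, 1].
#' @return Deflection cosine(s) in [-1, 1]; the first moment equals g.
#' @examples
#' sample_hg_cosine(0.95, 1)  # 1, the forward limit
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(g > -1, g < 1)
  if (g == 0) return(2 * u - 1)
  f <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - f^2) / (2 * g)))
}

#' Albedo weighting at a collision
#'
#' Multiplies the packet weight by the single-scattering albedo
#' \code{mu_s / (mu_a + mu_s)}; the difference is the absorbed weight.
#'
#' @param weight current packet weight(s) in (0, 1].
#' @param mu_a,mu_s absorption and scattering coefficients, mm^-1.
#' @return Updated weight(s).
#' @examples
#' update_weight(1, 0.015, 36)  # skull albedo
#' @export
update_weight <- function(weight, mu_a, mu_s) {
  stopifnot(mu_a + mu_s > 0)
  weight * mu_s / (mu_a + mu_s)
}

#' Russian roulette
#'
#' Unbiased termination of low-weight packets: a packet below the
#' threshold survives with probability \code{p_survival} at weight
#' \code{weight / p_survival} and is otherwise terminated, so the expected
#' returned weight equals the input weight.
#'
#' @param weight packet weight.
#' @param threshold weight below which roulette is played.
#' @param p_survival survival probability in (0, 1).
#' @param u uniform random deviate in (0, 1).
#' @return The (possibly boosted) weight, or 0 for a terminated packet.
#' @export
roulette <- function(weight, threshold, p_survival, u) {
  stopifnot(p_survival > 0, p_survival < 1)
  if (weight >= threshold) return(weight)
  if (u < p_survival) weight / p_survival else 0
}

# ---- full simulation ----------------------------------------------------

#' Run a photon-packet transport simulation
#'
#' Propagates weighted photon packets from the source through the phantom
#' and tallies the weight exiting through the detector aperture. Packets
#' step between sampled collision sites, truncated at material boundaries
#' (layer planes and the artery cylinder in implicit mode; voxel faces in
#' voxelized mode); each collision applies albedo weighting and a
#' Henyey-Greenstein deflection; low weights are terminated by Russian
#' roulette with exact bookkeeping, so injected weight always equals
#' detected + absorbed + escaped to floating-point rounding.
#'
#' @param phantom a [phantom_model()].
#' @param source a [source_spec()].
#' @param detector a [detector_spec()].
#' @param options a [transport_options()].
#' @param record_cylinders optional list with elements \code{axes_z}
#'   (depths of candidate artery axes, mm) and \code{radii} (mm), used with
#'   \code{record = "cylinders"}; per detected packet, the geometric path
#'   length and collision count inside every candidate cylinder are
#'   recorded. Implies the artery is disabled (host material everywhere) so
#'   that the recorded paths are diameter-independent.
#' @return An object of class \code{"mc_detection"}: injected, detected,
#'   absorbed and escaped weights, the detected fraction with its standard
#'   error, packet counts, and (when recording) per-detected-packet
#'   records \code{records$w}, \code{records$l}, \code{records$k},
#'   \code{records$exit_x/_y}, \code{records$packet}.
#' @examples
#' ph <- build_default_phantom(3.7)
#' res <- run_simulation(ph, options = transport_options(n_photons = 2e4, seed = 7))
#' res$detected_fraction
#' @export
run_simulation <- function(phantom,
                           source = source_spec(),
                           detector = detector_spec(),
                           options = transport_options(),
                           record_cylinders = NULL) {
  stopifnot(inherits(phantom, "phantom_model"),
            inherits(source, "source_spec"),
            inherits(detector, "detector_spec"),
            inherits(options, "transport_options"))
  sep <- sqrt((detector$cx - source$x)^2 + (detector$cy - source$y)^2)
  if (sep <= 0) stop("detector must not coincide with the source")
  if (sep < detector$half)
    warning("detector aperture overlaps the source")

  rec_mode <- switch(options$record, none = 0L, artery = 1L, cylinders = 2L)
  artery_on <- !is.null(phantom$artery) && rec_mode != 2L
  if (rec_mode == 1L && is.null(phantom$artery))
    stop("record = 'artery' requires a phantom with an artery")
  if (rec_mode == 2L && is.null(record_cylinders))
    stop("record = 'cylinders' requires `record_cylinders`")

  mats <- phantom$materials
  lay_ids <- phantom$layers$materials
  gvals <- vapply(mats, `[[`, numeric(1), "g")
  if (length(unique(round(gvals, 12))) > 1)
    stop("the transport kernel assumes one anisotropy factor for all materials")
  art <- phantom$artery
  blood <- if (artery_on) mats[[art$material]] else NULL
  cx <- phantom$separation_mm / 2

  geom <- list(
    zb = as.numeric(phantom$layers$boundaries_mm),
    mua = vapply(lay_ids, function(id) mats[[id]]$mu_a, numeric(1)),
    mus = vapply(lay_ids, function(id) mats[[id]]$mu_s, numeric(1)),
    g = gvals[[1]],
    artery_on = artery_on,
    artery_ax = if (is.null(art)) 0 else artery_axis_x(phantom),
    artery_az = if (is.null(art)) 0 else art$depth_mm,
    artery_r = if (is.null(art)) 0 else art$diameter_mm / 2,
    artery_mua = if (artery_on) blood$mu_a else 0,
    artery_mus = if (artery_on) blood$mu_s else 0,
    xlo = cx - phantom$lateral_mm, xhi = cx + phantom$lateral_mm,
    ylo = -phantom$lateral_mm, yhi = phantom$lateral_mm,
    zmax = phantom$depth_mm_max,
    voxel_mode = options$geometry == "voxelized",
    voxel_mm = phantom$voxel_mm)

  src <- list(x = source$x, y = source$y,
              type = if (source$type == "pencil") 0L else 1L,
              half_angle = source$half_angle_deg * pi / 180)
  det <- list(cx = detector$cx, cy = detector$cy,
              shape = if (detector$shape == "square") 0L else 1L,
              half = detector$half)
  opt <- list(n_photons = as.double(options$n_photons),
              seed = as.double(options$seed),
              packet_offset = as.double(options$packet_offset),
              w_threshold = options$w_threshold,
              p_survival = options$p_survival,
              boundary = if (options$boundary == "matched") 0L else 1L,
              n_tissue = options$n_tissue,
              max_steps = as.double(options$max_steps))
  rec <- list(mode = rec_mode)
  if (rec_mode == 2L) {
    rec$axes_z <- as.numeric(record_cylinders$axes_z)
    rec$radii <- as.numeric(record_cylinders$radii)
    rec$axes_x <- if (!is.null(record_cylinders$axes_x))
      record_cylinders$axes_x else cx
  }

  raw <- mc_transport_cpp(geom, src, det, opt, rec)

  n <- raw$injected
  f <- raw$detected / n
  # packetwise variance of the detected contribution (0 for undetected)
  se <- sqrt(max(0, (raw$det_sumw2 - n * f^2) / (n * (n - 1))))
  res <- structure(list(
    injected = n,
    detected = raw$detected,
    absorbed = raw$absorbed,
    escaped = raw$escaped,
    escaped_bottom = raw$escaped_bottom,
    n_detected = raw$n_detected,
    n_lost = raw$n_lost,
    detected_fraction = f,
    detected_fraction_se = se,
    detected_ppm = f * 1e6,
    phantom = phantom, source = source, detector = detector,
    options = options),
    class = "mc_detection")
  if (rec_mode > 0) {
    res$records <- list(w = raw$rec_w, exit_x = raw$rec_x, exit_y = raw$rec_y,
                        packet = raw$rec_packet,
                        l = raw$rec_l, k = raw$rec_k)
    if (rec_mode == 2L) {
      res$records$axes_z <- rec$axes_z
      res$records$radii <- rec$radii
    } else {
      res$records$axes_z <- art$depth_mm
      res$records$radii <- art$diameter_mm / 2
    }
  }
  res
}

#' @export
print.mc_detection <- function(x, ...) {
  cat(sprintf("Monte Carlo detection: %s packets, seed %s\n",
              format(x$injected, big.mark = ","), x$options$seed))
  cat(sprintf("  detected fraction %.4g (%.4g ppm), s.e. %.3g ppm, %d packets\n",
              x$detected_fraction, x$detected_ppm,
              x$detected_fraction_se * 1e6, as.integer(x$n_detected)))
  cat(sprintf("  absorbed %.4g, escaped %.4g, conservation residual %.2g\n",
              x$absorbed / x$injected, x$escaped / x$injected,
              (x$injected - x$detected - x$absorbed - x$escaped) / x$injected))
  invisible(x)
}

#' @export
summary.mc_detection <- function(object, ...) {
  out <- data.frame(
    injected = object$injected,
    detected_fraction = object$detected_fraction,
    detected_ppm = object$detected_ppm,
    se_ppm = object$detected_fraction_se * 1e6,
    n_detected = object$n_detected,
    absorbed_fraction = object$absorbed / object$injected,
    escaped_fraction = object$escaped / object$injected)
  class(out) <- c("summary.mc_detection", "data.frame")
  out
}
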