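#' Ordered stack of tissue layers
#'
#' Layers are listed from the irradiated surface downwards; the last layer
#' is semi-infinite (thickness \code{Inf}). The coordinate convention is
#' z = 0 at the surface, z increasing with depth, all lengths in mm.
#'
#' @param materials character vector of material ids, surface first.
#' @param thickness_mm numeric vector of thicknesses in mm; the last entry
#'   must be \code{Inf} (or omitted, in which case it is appended).
#' @return An object of class \code{"layer_stack"} with the material ids,
#'   thicknesses and cumulative boundary depths.
#' @examples
#' layer_stack(c("skin", "skull", "brain"), c(1.5, 5, Inf))
#' @export
layer_stack <- function(materials, thickness_mm) {
  if (length(thickness_mm) == length(materials) - 1)
    thickness_mm <- c(thickness_mm, Inf)
  stopifnot(length(materials) == length(thickness_mm),
            length(materials) >= 1,
            all(thickness_mm > 0))
  if (!is.infinite(thickness_mm[length(thickness_mm)]))
    stop("the terminal layer must be semi-infinite (thickness Inf)")
  if (any(is.infinite(thickness_mm[-length(thickness_mm)])))
    stop("only the terminal layer may be semi-infinite")
  boundaries <- cumsum(thickness_mm[-length(thickness_mm)])
  if (is.unsorted(boundaries, strictly = TRUE) && length(boundaries) > 1)
    stop("cumulative layer boundaries must be strictly increasing")
  structure(list(materials = as.character(materials),
                 thickness_mm = thickness_mm,
                 boundaries_mm = boundaries),
            class = "layer_stack")
}

#' Cylindrical artery embedded in the phantom
#'
#' The artery is a cylinder of blood-like liquid whose axis lies parallel
#' to the surface. Depth is measured from the surface to the cylinder
#' axis. By default the axis runs along y, i.e. perpendicular to the
#' source-detector line (which runs along x), crossing beneath its
#' midpoint; \code{offset_mm} shifts the axis along x.
#'
#' @param depth_mm depth of the cylinder axis below the surface, mm.
#' @param diameter_mm inner diameter, mm.
#' @param offset_mm lateral shift of the axis along x relative to the
#'   source-detector midpoint, mm.
#' @param material lumen material id.
#' @return An object of class \code{"artery"}.
#' @examples
#' artery(3.7, 0.4)
#' @export
artery <- function(depth_mm, diameter_mm, offset_mm = 0, material = "blood") {
  stopifnot(is.numeric(depth_mm), depth_mm > 0,
            is.numeric(diameter_mm), diameter_mm > 0)
  if (depth_mm - diameter_mm / 2 < 0)
    stop(sprintf(
      "artery protrudes above the surface: radius %.3g mm > depth %.3g mm",
      diameter_mm / 2, depth_mm))
  structure(list(depth_mm = depth_mm, diameter_mm = diameter_mm,
                 offset_mm = offset_mm, material = material),
            class = "artery")
}

#' Layered head phantom with an embedded pulsatile artery
#'
#' Combines a layer stack, one artery and a material table into a
#' queryable model of the phantom. Geometry can be interrogated
#' analytically (implicit mode, the default) or on a cubic voxel grid
#' that mirrors the published 0.05 mm discretisation.
#'
#' @param layers a [layer_stack()].
#' @param artery an [artery()] or \code{NULL} for a plain slab.
#' @param materials named list of [optical_properties()], one entry per
#'   material id referenced by the layers and artery.
#' @param lateral_mm lateral half-extent of the simulation domain in x and
#'   y around the source-detector midpoint, mm.
#' @param depth_mm_max depth of the domain floor, mm.
#' @param voxel_mm voxel edge for voxelized queries, mm.
#' @param separation_mm source-detector separation, mm (fixes the domain
#'   centre and the default artery axis position).
#' @return An object of class \code{"phantom_model"}.
#' @seealso [build_default_phantom()] for the published configuration.
#' @export
phantom_model <- function(layers, artery, materials,
                          lateral_mm = 30, depth_mm_max = 60,
                          voxel_mm = 0.05, separation_mm = 11) {
  stopifnot(inherits(layers, "layer_stack"),
            is.null(artery) || inherits(artery, "artery"),
            voxel_mm > 0, lateral_mm > 0, depth_mm_max > 0)
  referenced <- unique(c(layers$materials,
                         if (!is.null(artery)) artery$material))
  missing <- setdiff(referenced, names(materials))
  if (length(missing))
    stop("materials missing from the table: ", paste(missing, collapse = ", "))
  if (2 * lateral_mm < 4 * separation_mm)
    stop("lateral extent must be at least 4x the source-detector separation")
  structure(list(layers = layers, artery = artery, materials = materials,
                 lateral_mm = lateral_mm, depth_mm_max = depth_mm_max,
                 voxel_mm = voxel_mm, separation_mm = separation_mm),
            class = "phantom_model")
}

#' @export
print.phantom_model <- function(x, ...) {
  cat("Layered head phantom\n")
  n <- length(x$layers$materials)
  for (i in seq_len(n)) {
    th <- x$layers$thickness_mm[i]
    m <- x$materials[[x$layers$materials[i]]]
    cat(sprintf("  %-6s %s  mu_a %.3g /mm, mu_s' %.3g /mm, g %.3g\n",
                x$layers$materials[i],
                if (is.infinite(th)) "semi-inf" else sprintf("%5.1f mm", th),
                m$mu_a, m$mu_s_prime, m$g))
  }
  if (!is.null(x$artery)) {
    m <- x$materials[[x$artery$material]]
    cat(sprintf(
      "  artery: %s, axis depth %.2f mm, diameter %.3f mm (mu_a %.3g /mm, mu_s' %.3g /mm)\n",
      x$artery$material, x$artery$depth_mm, x$artery$diameter_mm,
      m$mu_a, m$mu_s_prime))
  }
  cat(sprintf("  domain %.0f x %.0f x %.0f mm, voxel %.2f mm, separation %.1f mm\n",
              2 * x$lateral_mm, 2 * x$lateral_mm, x$depth_mm_max,
              x$voxel_mm, x$separation_mm))
  invisible(x)
}

#' Build the published three-layer head phantom
#'
#' Constructs the skin / skull / brain phantom with the published optical
#' properties at 910 nm, converted to mm^-1: skin mu_a 0.037, mu_s' 1.6;
#' skull 0.015, 1.8; brain 0.04, 2.1; blood 1.1, 1.9; anisotropy 0.95 for
#' every material. Skin is 1.5 mm, skull 5.0 mm, brain semi-infinite. The
#' artery axis runs perpendicular to the 11 mm source-detector line,
#' beneath its midpoint.
#'
#' @param artery_depth depth of the artery axis below the surface, mm.
#' @param artery_diameter inner diameter of the artery, mm; the relaxed
#'   state is 0.4 mm.
#' @param n refractive index assigned to every material (consulted only by
#'   the mismatched-Fresnel boundary model).
#' @return A [phantom_model()].
#' @examples
#' ph <- build_default_phantom(3.7, 0.4)
#' ph$materials$skull$mu_s  # 36 /mm
#' @export
build_default_phantom <- function(artery_depth,
                                  artery_diameter = phantom_constants()$artery_diameter_mm,
                                  n = 1) {
  stopifnot(artery_depth > 0, artery_diameter > 0, artery_diameter <= 1)
  k <- phantom_constants()
  mats <- lapply(names(k$mu_a_per_cm), function(id)
    optical_properties(mu_a = k$mu_a_per_cm[[id]] / 10,
                       mu_s_prime = k$mu_s_prime_per_cm[[id]] / 10,
                       g = k$g, n = n))
  names(mats) <- names(k$mu_a_per_cm)
  phantom_model(
    layers = layer_stack(c("skin", "skull", "brain"),
                         c(k$layer_thickness_mm[["skin"]],
                           k$layer_thickness_mm[["skull"]], Inf)),
    artery = artery(artery_depth, artery_diameter),
    materials = mats,
    voxel_mm = k$voxel_mm,
    separation_mm = k$separation_mm)
}

# x-coordinate of the artery axis: source at x = 0, detector at
# x = separation, axis beneath the midpoint plus any configured offset
artery_axis_x <- function(phantom) {
  phantom$separation_mm / 2 +
    if (is.null(phantom$artery)) 0 else phantom$artery$offset_mm
}

#' Material at a 3-D position
#'
#' Maps positions to material ids: "blood" wherever the perpendicular
#' distance to the artery axis is at most the artery radius, otherwise the
#' layer containing the depth coordinate. In voxelized mode the query
#' point is snapped to the centre of its 0.05 mm voxel first, so the two
#' modes can disagree only within one voxel of a material boundary.
#'
#' @param phantom a [phantom_model()].
#' @param x,y,z coordinates in mm (vectors of equal length are recycled
#'   against each other); z is depth below the surface.
#' @param mode \code{"implicit"} (analytic, default) or \code{"voxelized"}.
#' @return Character vector of material ids; \code{NA} for positions
#'   outside the simulation domain (an escape, not a material).
#' @examples
#' ph <- build_default_phantom(3.7)
#' material_at(ph, 0, 0, 0.5)            # "skin"
#' material_at(ph, 5.5, 0, 3.7)          # "blood" (on the axis)
#' material_at(ph, 0, 0, 7)              # "brain"
#' @export
material_at <- function(phantom, x, y, z, mode = c("implicit", "voxelized")) {
  mode <- match.arg(mode)
  n <- max(length(x), length(y), length(z))
  x <- rep_len(x, n); y <- rep_len(y, n); z <- rep_len(z, n)
  if (mode == "voxelized") {
    h <- phantom$voxel_mm
    x <- (floor(x / h) + 0.5) * h
    y <- (floor(y / h) + 0.5) * h
    z <- (floor(z / h) + 0.5) * h
  }
  cx <- phantom$separation_mm / 2
  out_of_domain <- z < 0 | z > phantom$depth_mm_max |
    abs(x - cx) > phantom$lateral_mm | abs(y) > phantom$lateral_mm
  idx <- findInterval(z, phantom$layers$boundaries_mm) + 1L
  mat <- phantom$layers$materials[pmin(idx, length(phantom$layers$materials))]
  if (!is.null(phantom$artery)) {
    ax <- artery_axis_x(phantom)
    r <- phantom$artery$diameter_mm / 2
    inside <- (x - ax)^2 + (z - phantom$artery$depth_mm)^2 <= r^2
    mat[inside] <- phantom$artery$material
  }
  mat[out_of_domain] <- NA_character_
  mat
}

#' Change the artery diameter
#'
#' Returns a phantom identical to the input except for the artery
#' diameter; the dilated lumen displaces the surrounding layer material.
#' Used to realise the diameter sweep (0.30-0.50 mm in 0.05 mm steps) and
#' the 4\% dilated state.
#'
#' @param phantom a [phantom_model()] with an artery.
#' @param diameter_mm new inner diameter, mm, in (0, 1].
#' @return The modified [phantom_model()].
#' @examples
#' ph <- build_default_phantom(3.7, 0.4)
#' dilated <- set_artery_diameter(ph, 0.4 * 1.04)
#' @export
set_artery_diameter <- function(phantom, diameter_mm) {
  stopifnot(inherits(phantom, "phantom_model"), !is.null(phantom$artery),
            diameter_mm > 0, diameter_mm <= 1)
  phantom$artery <- artery(phantom$artery$depth_mm, diameter_mm,
                           phantom$artery$offset_mm, phantom$artery$material)
  phantom
}

# layer containing a depth (id), used by the perturbation machinery
layer_material_at_depth <- function(phantom, z) {
  idx <- findInterval(z, phantom$layers$boundaries_mm) + 1L
  phantom$layers$materials[min(idx, length(phantom$layers$materials))]
}

# check that a cylinder (axis depth az, radius r) lies within one layer;
# returns the host material id or NULL
single_layer_host <- function(phantom, az, r) {
  zb <- c(0, phantom$layers$boundaries_mm, Inf)
  top <- az - r; bot <- az + r
  for (i in seq_along(phantom$layers$materials)) {
    if (top >= zb[i] && bot <= zb[i + 1]) return(phantom$layers$materials[i])
  }
  NULL
}
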