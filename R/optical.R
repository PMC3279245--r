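#' Optical properties of a single material
#'
#' Bundles the absorption coefficient, scattering coefficient, scattering
#' anisotropy and refractive index of one material. Either the full
#' scattering coefficient \code{mu_s} or the reduced coefficient
#' \code{mu_s_prime} = mu_s * (1 - g) may be given; the other is derived.
#'
#' @param mu_a absorption coefficient, mm^-1 (>= 0).
#' @param mu_s scattering coefficient, mm^-1 (>= 0); give this or
#'   \code{mu_s_prime}.
#' @param g scattering anisotropy (mean cosine of the deflection angle),
#'   in (-1, 1).
#' @param mu_s_prime reduced scattering coefficient, mm^-1.
#' @param n refractive index (>= 1). Only consulted by the
#'   mismatched-Fresnel boundary model.
#' @return An object of class \code{"optical_properties"}: a list with
#'   fields \code{mu_a}, \code{mu_s}, \code{mu_s_prime}, \code{g}, \code{n},
#'   all in mm^-1 where dimensional.
#' @examples
#' skull <- optical_properties(mu_a = 0.015, mu_s_prime = 1.8, g = 0.95)
#' skull$mu_s  # 36 mm^-1
#' @export
optical_properties <- function(mu_a, mu_s = NULL, g = 0.95, mu_s_prime = NULL,
                               n = 1) {
  if (is.null(mu_s) && is.null(mu_s_prime))
    stop("give either `mu_s` or `mu_s_prime`")
  if (!is.null(mu_s) && !is.null(mu_s_prime) &&
      abs(mu_s * (1 - g) - mu_s_prime) > 1e-10 * max(1, mu_s_prime))
    stop("`mu_s` and `mu_s_prime` are inconsistent with g")
  if (is.null(mu_s)) mu_s <- mu_s_prime / (1 - g)
  if (is.null(mu_s_prime)) mu_s_prime <- mu_s * (1 - g)
  stopifnot(is.numeric(mu_a), length(mu_a) == 1, mu_a >= 0,
            is.numeric(mu_s), length(mu_s) == 1, mu_s >= 0,
            is.numeric(g), length(g) == 1, g > -1, g < 1,
            is.numeric(n), length(n) == 1, n >= 1)
  structure(list(mu_a = mu_a, mu_s = mu_s, mu_s_prime = mu_s_prime,
                 g = g, n = n),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf(
    "optical properties: mu_a %.4g /mm, mu_s %.4g /mm (mu_s' %.4g /mm), g %.3g, n %.3g\n",
    x$mu_a, x$mu_s, x$mu_s_prime, x$g, x$n))
  invisible(x)
}
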