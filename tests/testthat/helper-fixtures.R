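# shared helpers: small phantoms and hand-built sweep objects

tiny_options <- function(n = 2e4, seed = 1, ...) {
  transport_options(n_photons = n, seed = seed, ...)
}

# a diameter_sweep object with prescribed fractions (no simulation)
fake_sweep <- function(diameters, fractions, se = 0, depth = 3.7) {
  structure(list(
    table = data.frame(diameter_mm = diameters, fraction = fractions,
                       se = rep_len(se, length(diameters))),
    depth_mm = depth, method = "direct", n_photons = NA_real_,
    injected = NA_real_, seed = NA_integer_, common_seed = TRUE,
    contrib = NULL),
    class = "diameter_sweep")
}
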