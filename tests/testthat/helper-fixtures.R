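# Shared fixtures, all built in code.

flat_bands <- function(nrow, ncol, values) {
  b <- lapply(values[oli_band_names()], function(v) matrix(v, nrow, ncol))
  names(b) <- oli_band_names()
  b
}

# scene where every band equals `value` everywhere
constant_scene <- function(nrow = 6, ncol = 6, value = 0.2) {
  uniform_scene(nrow, ncol, setNames(rep(value, 9), oli_band_names()))
}

# scene built from explicit per-band matrices (named list), others constant
scene_with <- function(nrow, ncol, override, fill = 0.2, mask = NULL) {
  b <- flat_bands(nrow, ncol, setNames(rep(fill, 9), oli_band_names()))
  for (nm in names(override)) b[[nm]] <- override[[nm]]
  tundra_scene(b, mask = mask)
}

# scene whose pixels carry the signature of a given spectral class
signature_scene <- function(class_grid, noise_sd = 0, seed = 1) {
  mos <- structure(list(spectral = class_grid,
                        labels = matrix(1L, nrow(class_grid), ncol(class_grid)),
                        pixel_size = 30, origin = c(-155, 70.5)),
                   class = "landform_mosaic")
  render_scene(mos, noise_sd = noise_sd, seed = seed)
}

signature_row <- function(class) {
  sig <- default_signatures()
  unlist(sig[sig$class == class, oli_band_names()])
}

# brute-force Theil-Sen oracle: explicit double loop, explicit median
oracle_theil_sen <- function(t, y, ref_year = 2014) {
  sl <- c()
  n <- length(t)
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (t[j] != t[i]) sl <- c(sl, (y[j] - y[i]) / (t[j] - t[i]))
  slope <- median(sl)
  list(slope = slope, intercept = median(y - slope * (t - ref_year)))
}

# a 64x64 mosaic with a water mix small enough for the grid
small_mosaic <- function(seed) {
  generate_landform_mosaic(
    shape = c(64, 64),
    weights = c(lake_small = 1, pond = 1, river = 1, CLC = 1, nDTLB = 1,
                LC = 2, FC = 1, RC = 1, HC = 2, DS = 1, SB = 1, SD = 1),
    seed = seed)
}

default_mosaic <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_landform_mosaic(seed = 42)
    cache
  }
})
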