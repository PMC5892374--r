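#' Multiband reflectance scene
#'
#' A scene holds the nine Landsat 8 OLI reflectance bands on a common 30 m
#' grid: coastal/aerosol, blue, green, red, NIR, SWIR1, SWIR2, panchromatic
#' and cirrus. Reflectances are unitless in \[0, 1.5\] (tolerating slight
#' over-correction); invalid pixels are carried in a logical mask and
#' propagate to every derived index.
#'
#' @param bands named list of nine numeric matrices (names as in
#'   [oli_band_names()]) sharing one shape.
#' @param mask logical matrix, `TRUE` where pixels are valid. Defaults to all
#'   valid.
#' @param pixel_size pixel edge length in metres.
#' @param origin numeric `c(lon, lat)` of the upper-left pixel center, used
#'   when deriving site coordinates.
#' @return An object of class `tundra_scene`.
#' @export
tundra_scene <- function(bands, mask = NULL, pixel_size = 30,
                         origin = c(-155, 70.5)) {
  nms <- oli_band_names()
  if (!all(nms %in% names(bands)))
    stop("scene must provide all nine OLI bands: ",
         paste(setdiff(nms, names(bands)), collapse = ", "))
  bands <- bands[nms]
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1) stop("all band grids must share one shape")
  rng <- range(unlist(lapply(bands, range, na.rm = TRUE)))
  if (rng[1] < 0 || rng[2] > 1.5)
    stop("reflectance values must lie in [0, 1.5]")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(bands[[1]]), ncol(bands[[1]]))
  if (!identical(dim(mask), dim(bands[[1]])))
    stop("mask shape must match band shape")
  structure(list(bands = bands, mask = mask, pixel_size = pixel_size,
                 origin = origin),
            class = "tundra_scene")
}

#' @rdname tundra_scene
#' @export
oli_band_names <- function() {
  c("coastal", "blue", "green", "red", "nir", "swir1", "swir2",
    "pan", "cirrus")
}

#' @export
print.tundra_scene <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat(sprintf("tundra_scene: %d x %d pixels, 9 bands, %g m pixels, %d valid\n",
              d[1], d[2], x$pixel_size, sum(x$mask)))
  invisible(x)
}

normalized_difference <- function(a, b, mask) {
  denom <- a + b
  out <- (a - b) / denom
  out[!mask | denom == 0] <- NA_real_
  out
}

#' Spectral indices
#'
#' Pixel-local band arithmetic used by the landform classifier:
#' * `ndvi`: (NIR - Red) / (NIR + Red), vegetation productivity.
#' * `ndwi`: (Green - NIR) / (Green + NIR), high over open water.
#' * `bluemax`: Blue / MaxDiff where MaxDiff is the per-pixel range (maximum
#'   minus minimum) over all nine bands; a bright-substrate (sand/gravel)
#'   discriminator.
#' * `albedo`: weighted sum of band reflectances; the default coefficients
#'   are Liang's broadband shortwave albedo over blue/red/NIR/SWIR1/SWIR2
#'   (0.356, 0.130, 0.373, 0.085, 0.072 with constant -0.0018).
#'
#' Division by zero and input nodata yield `NA` (never infinities), so
#' thresholding stays well defined.
#'
#' @param scene a [tundra_scene()].
#' @return numeric matrix of index values; `NA` marks nodata.
#' @export
#' @examples
#' sc <- uniform_scene(4, 4, c(coastal = .1, blue = .1, green = .1, red = .1,
#'   nir = .5, swir1 = .1, swir2 = .1, pan = .1, cirrus = .1))
#' ndvi(sc)[1, 1]  # (0.5 - 0.1) / 0.6
ndvi <- function(scene) {
  normalized_difference(scene$bands$nir, scene$bands$red, scene$mask)
}

#' @rdname ndvi
#' @export
ndwi <- function(scene) {
  normalized_difference(scene$bands$green, scene$bands$nir, scene$mask)
}

#' @rdname ndvi
#' @export
bluemax <- function(scene) {
  arr <- simplify2array(scene$bands)
  hi <- apply(arr, c(1, 2), max)
  lo <- apply(arr, c(1, 2), min)
  maxdiff <- hi - lo
  out <- scene$bands$blue / maxdiff
  out[!scene$mask | maxdiff == 0] <- NA_real_
  out
}

#' @rdname ndvi
#' @param coefficients named numeric vector of per-band weights (any subset
#'   of the nine band names); an optional `"(intercept)"` entry is added as a
#'   constant.
#' @export
albedo <- function(scene, coefficients = albedo_coefficients()) {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("albedo coefficients must be a named vector")
  bad <- setdiff(names(coefficients), c(oli_band_names(), "(intercept)"))
  if (length(bad)) stop("unknown band(s) in albedo coefficients: ",
                        paste(bad, collapse = ", "))
  out <- matrix(0, nrow(scene$mask), ncol(scene$mask))
  for (nm in names(coefficients)) {
    if (nm == "(intercept)") out <- out + coefficients[[nm]]
    else out <- out + coefficients[[nm]] * scene$bands[[nm]]
  }
  out[!scene$mask] <- NA_real_
  out
}

#' @rdname ndvi
#' @export
albedo_coefficients <- function() {
  c(blue = 0.356, red = 0.130, nir = 0.373, swir1 = 0.085, swir2 = 0.072,
    "(intercept)" = -0.0018)
}

#' @rdname tundra_scene
#' @param nrow,ncol grid shape.
#' @param values named vector of one reflectance per band.
#' @export
uniform_scene <- function(nrow, ncol, values, pixel_size = 30) {
  bands <- lapply(values[oli_band_names()],
                  function(v) matrix(v, nrow, ncol))
  names(bands) <- oli_band_names()
  tundra_scene(bands, pixel_size = pixel_size)
}
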