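#' Read and write single-band rasters as ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values,
#' top row first. Georeferencing survives a round-trip exactly; `NA` maps to
#' the nodata value.
#'
#' @param mat numeric or integer matrix (row 1 = top of the raster).
#' @param path output path (conventionally `.asc`).
#' @param cellsize pixel size in the grid's units.
#' @param xll,yll lower-left corner coordinates.
#' @param nodata nodata sentinel written for `NA`.
#' @return `read_ascii_grid` returns a matrix with attributes `cellsize`,
#'   `xll`, `yll`; `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(mat, path, cellsize = 30, xll = 0, yll = 0,
                             nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(mat)),
               paste("nrows", nrow(mat)),
               paste("xllcorner", format(xll, scientific = FALSE)),
               paste("yllcorner", format(yll, scientific = FALSE)),
               paste("cellsize", format(cellsize, scientific = FALSE)),
               paste("NODATA_value", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  attr(m, "cellsize") <- vals[["cellsize"]]
  attr(m, "xll") <- vals[["xllcorner"]]
  attr(m, "yll") <- vals[["yllcorner"]]
  m
}

#' Scene, landform-map and trend-raster file interfaces
#'
#' A scene is stored as one ASCII grid per band (`<prefix>_<band>.asc`)
#' plus a `<prefix>_mask.asc` validity grid. A landform map is a single
#' integer-coded grid accompanied by `<prefix>_attributes.csv` (landform,
#' area km^2, soil-moisture-regime rank), `<prefix>_legend.csv` (code to
#' class-name map) and `<prefix>_palette.csv`. A trend raster is written as
#' four grids in the published band order (slope, intercept, upper then
#' lower 95% CI) plus a valid-count grid.
#'
#' @param scene a [tundra_scene()].
#' @param prefix path prefix for the file set.
#' @return readers return the reconstructed object; writers return the file
#'   paths invisibly.
#' @export
write_scene <- function(scene, prefix) {
  paths <- character()
  for (b in oli_band_names()) {
    p <- paste0(prefix, "_", b, ".asc")
    write_ascii_grid(scene$bands[[b]], p, cellsize = scene$pixel_size)
    paths <- c(paths, p)
  }
  p <- paste0(prefix, "_mask.asc")
  write_ascii_grid(scene$mask * 1L, p, cellsize = scene$pixel_size)
  invisible(c(paths, p))
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  bands <- list()
  cellsize <- NULL
  for (b in oli_band_names()) {
    m <- read_ascii_grid(paste0(prefix, "_", b, ".asc"))
    cs <- attr(m, "cellsize")
    if (!is.null(cellsize) && cs != cellsize)
      stop("bands disagree on cellsize")
    if (length(bands) && !identical(dim(m), dim(bands[[1]])))
      stop("bands disagree on shape")
    cellsize <- cs
    attributes(m) <- list(dim = dim(m))
    bands[[b]] <- m
  }
  maskp <- paste0(prefix, "_mask.asc")
  mask <- if (file.exists(maskp)) {
    mm <- read_ascii_grid(maskp)
    matrix(!is.na(mm) & mm != 0, nrow(mm), ncol(mm))
  } else NULL
  tundra_scene(bands, mask = mask, pixel_size = cellsize)
}

#' @rdname write_scene
#' @param map a `landform_map` from [classify_scene()].
#' @export
write_landform_map <- function(map, prefix) {
  p <- paste0(prefix, "_landform.asc")
  write_ascii_grid(map$labels, p, cellsize = map$pixel_size)
  utils::write.csv(landform_attribute_table(map),
                   paste0(prefix, "_attributes.csv"), row.names = FALSE)
  utils::write.csv(map$legend[, c("code", "landform", "description",
                                  "smr_rank")],
                   paste0(prefix, "_legend.csv"), row.names = FALSE)
  utils::write.csv(landform_palette(), paste0(prefix, "_palette.csv"),
                   row.names = FALSE)
  invisible(paste0(prefix, c("_landform.asc", "_attributes.csv",
                             "_legend.csv", "_palette.csv")))
}

#' @rdname write_scene
#' @export
read_landform_map <- function(prefix) {
  m <- read_ascii_grid(paste0(prefix, "_landform.asc"))
  cellsize <- attr(m, "cellsize")
  attributes(m) <- list(dim = dim(m))
  storage.mode(m) <- "integer"
  structure(list(labels = m, legend = landform_legend(),
                 pixel_size = cellsize),
            class = "landform_map")
}

#' @rdname write_scene
#' @param trend a `trend_raster` from [trend_map()].
#' @export
write_trend_raster <- function(trend, prefix) {
  layers <- c("slope", "intercept", "ci_upper", "ci_lower", "n_valid")
  for (l in layers)
    write_ascii_grid(trend[[l]], paste0(prefix, "_", l, ".asc"))
  invisible(paste0(prefix, "_", layers, ".asc"))
}

#' @rdname write_scene
#' @export
read_trend_raster <- function(prefix) {
  layers <- c("slope", "intercept", "ci_upper", "ci_lower", "n_valid")
  out <- list()
  for (l in layers) {
    m <- read_ascii_grid(paste0(prefix, "_", l, ".asc"))
    attributes(m) <- list(dim = dim(m))
    out[[l]] <- m
  }
  structure(c(out, list(units = "NDVI/yr")), class = "trend_raster")
}

#' Read a reference-site table
#'
#' CSV with at least `ecological_landscape` (stratum), `landform`,
#' `latitude` and `longitude` columns. Duplicate sites (same coordinates)
#' are removed with a warning; nonfinite coordinates are an error.
#'
#' @param path CSV path.
#' @return data frame of reference sites.
#' @export
read_reference_csv <- function(path) {
  if (!file.exists(path)) stop("reference CSV not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ecological_landscape", "landform", "latitude", "longitude")
  if (!all(need %in% names(df)))
    stop("reference CSV must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$latitude)) || any(!is.finite(df$longitude)))
    stop("nonfinite coordinates in reference CSV")
  dup <- duplicated(df[, c("latitude", "longitude")])
  if (any(dup)) {
    warning(sum(dup), " duplicate site(s) removed")
    df <- df[!dup, , drop = FALSE]
  }
  df
}
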