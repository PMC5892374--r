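#' Classification threshold configuration
#'
#' The rule hierarchy is driven entirely by named numeric thresholds. The
#' published description of the classifier deliberately replaces numeric
#' values with qualitative ranges (low ... high) because reflectance
#' statistics vary between scenes, so every threshold here carries its
#' qualitative tag for provenance and the numeric default is calibrated
#' against the packaged synthetic signature table (see
#' [default_signatures()]).
#'
#' Comparison conventions: "min"-style thresholds are inclusive (value >=
#' threshold fires the rule), "max"-style thresholds likewise (value <=
#' threshold fires). An object exactly at `wet_dry_ndwi` is wet.
#'
#' @param ... named numeric overrides of individual threshold values,
#'   e.g. `threshold_config(wet_dry_ndwi = -0.4)`.
#' @return A data frame of class `threshold_config` with columns `name`,
#'   `value`, `tag` (qualitative label) and `applies_to` (index or object
#'   property the threshold is compared against).
#' @export
#' @examples
#' cfg <- threshold_config()
#' threshold_value(cfg, "wet_dry_ndwi")
threshold_config <- function(...) {
  df <- data.frame(
    name = c("wet_dry_ndwi",
             "clc_ndvi_min", "clc_ndvi_max",
             "ndtlb_ndvi_min", "ndtlb_edge_area_max",
             "openwater_blue",
             "river_ndvi_max", "river_roundness_max",
             "ice_swir2_min",
             "lake_edge_area_max",
             "fc_ndwi_min",
             "rc_ndvi_low", "rc_ndvi_high",
             "sandgravel_bluemax_min", "sb_ndvi_min",
             "ds_albedo_min"),
    value = c(-0.52,
              0.00, 0.38,
              0.67, 1.20,
              0.060,
              0.00, 0.25,
              0.17,
              0.80,
              -0.655,
              0.37, 0.50,
              0.52, 0.30,
              0.25),
    tag = c("moderate",
            "low", "low",
            "high", "moderate",
            "low-moderate",
            "high", "low",
            "high",
            "low",
            "moderate-high",
            "low-moderate", "low-moderate",
            "high", "moderate-high",
            "high"),
    applies_to = c("ndwi",
                   "ndvi", "ndvi",
                   "ndvi", "edge_area",
                   "blue",
                   "ndvi", "roundness",
                   "swir2",
                   "edge_area",
                   "ndwi",
                   "ndvi", "ndvi",
                   "bluemax", "ndvi",
                   "albedo"),
    stringsAsFactors = FALSE
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), df$name)
    if (length(bad)) stop("unknown threshold name(s): ", paste(bad, collapse = ", "))
    df$value[match(names(overrides), df$name)] <- unlist(overrides)
  }
  class(df) <- c("threshold_config", "data.frame")
  df
}

#' @rdname threshold_config
#' @param config a `threshold_config`.
#' @param name threshold name.
#' @export
threshold_value <- function(config, name) {
  i <- match(name, config$name)
  if (anyNA(i)) stop("threshold not found in config: ",
                     paste(name[is.na(i)], collapse = ", "))
  config$value[i]
}

#' Read/write a threshold configuration as structured text
#'
#' Plain CSV with columns `name,value,tag,applies_to`.
#'
#' @param config a `threshold_config`.
#' @param path file path.
#' @return `read_threshold_config` returns a `threshold_config`;
#'   `write_threshold_config` returns `path` invisibly.
#' @export
write_threshold_config <- function(config, path) {
  utils::write.csv(as.data.frame(config), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_config
#' @export
read_threshold_config <- function(path) {
  if (!file.exists(path)) stop("threshold config file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "value", "tag", "applies_to")
  if (!all(need %in% names(df)))
    stop("threshold config must have columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  class(df) <- c("threshold_config", "data.frame")
  df
}

#' Water-body size taxonomy
#'
#' Water bodies are decomposed by area into coastal saline water
#' (> 100,000 ha), large lakes (<= 100,000, > 90 ha), medium lakes
#' (<= 90, > 20 ha), small lakes (<= 20, > 1 ha) and ponds (<= 1 ha).
#' The 100,000 ha bound on CS exists to keep very large inland lakes
#' (Teshekpuk Lake, ~83,000 ha) classified as lakes.
#'
#' @param cs_min_ha,large_min_ha,medium_min_ha,small_min_ha lower (exclusive)
#'   area bounds in hectares of CS, large, medium and small lakes; anything
#'   at or below `small_min_ha` is a pond.
#' @return a named numeric vector of class `water_taxonomy`.
#' @export
water_taxonomy <- function(cs_min_ha = 100000, large_min_ha = 90,
                           medium_min_ha = 20, small_min_ha = 1) {
  if (!(cs_min_ha > large_min_ha && large_min_ha > medium_min_ha &&
        medium_min_ha > small_min_ha && small_min_ha > 0))
    stop("taxonomy bounds must be strictly decreasing and positive")
  structure(c(cs = cs_min_ha, large = large_min_ha,
              medium = medium_min_ha, small = small_min_ha),
            class = "water_taxonomy")
}
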