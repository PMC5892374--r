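#' Split image objects into wet and dry tundra
#'
#' The first branch of the rule hierarchy: an object is wet tundra iff its
#' mean NDWI is greater than or equal to the `wet_dry_ndwi` threshold
#' (objects exactly at the threshold are wet). The split is exhaustive and
#' exclusive.
#'
#' @param objects a `tundra_objects` map with statistics computed.
#' @param config a [threshold_config()].
#' @return list with integer id vectors `wet` and `dry`.
#' @export
split_wet_dry <- function(objects, config = threshold_config()) {
  st <- objects$stats
  if (is.null(st$ndwi) || anyNA(st$ndwi))
    stop("object NDWI statistics missing; run compute_object_stats() first")
  thr <- threshold_value(config, "wet_dry_ndwi")
  list(wet = st$id[st$ndwi >= thr], dry = st$id[st$ndwi < thr])
}

#' Classify a water body by area
#'
#' Monotone step function over the water-size taxonomy: coastal saline water
#' (> 100,000 ha), large lakes (<= 100,000, > 90 ha), medium lakes
#' (<= 90, > 20 ha), small lakes (<= 20, > 1 ha), ponds (<= 1 ha).
#'
#' @param area_ha water-body area in hectares (> 0); vectorized.
#' @param taxonomy a [water_taxonomy()].
#' @return character vector of landform labels.
#' @export
#' @examples
#' classify_water_body(c(0.9, 20, 83000))  # pond, lake_small, lake_large
classify_water_body <- function(area_ha, taxonomy = water_taxonomy()) {
  if (any(!is.finite(area_ha)) || any(area_ha <= 0))
    stop("water-body area must be positive")
  ifelse(area_ha > taxonomy[["cs"]], "CS",
    ifelse(area_ha > taxonomy[["large"]], "lake_large",
      ifelse(area_ha > taxonomy[["medium"]], "lake_medium",
        ifelse(area_ha > taxonomy[["small"]], "lake_small", "pond"))))
}

water_labels <- c("CS", "lake_large", "lake_medium", "lake_small",
                  "river", "pond")
lake_labels <- c("lake_large", "lake_medium", "lake_small")

neighbours_of <- function(adjacency, id) {
  c(adjacency[adjacency[, 1] == id, 2], adjacency[adjacency[, 2] == id, 1])
}

#' Classify wet tundra objects
#'
#' Applies the wet-tundra rule sequence, in order: (1) coalescent low-center
#' polygons (CLC) by a low (but vegetated) NDVI band; (2) nonpatterned
#' drained thaw-lake basins (nDTLB) by high NDVI and moderate edge-to-area
#' ratio; (2b) open water by a low-moderate blue threshold, fused into
#' spatially distinct water bodies by five spectral-difference merge passes;
#' rivers peeled off water bodies by low roundness and low NDVI, remaining
#' bodies sized by the water taxonomy with a low edge-to-area guard that
#' demotes intricate "lakes" (interconnected pond complexes) back to ponds;
#' (2c) ice/snow by a high SWIR2 threshold, folded into the lake class when
#' lying on a lake, kept as `ice` otherwise; (3) every remaining wet object
#' becomes low-center polygons (LC), the dominant wet landform.
#'
#' @param objects a `tundra_objects` map.
#' @param ids integer ids of the wet objects.
#' @param scene the underlying [tundra_scene()] (water-body merging
#'   recomputes object geometry).
#' @param config a [threshold_config()].
#' @param taxonomy a [water_taxonomy()].
#' @return list with the updated `objects` map and `landform`, a character
#'   vector named by object id (covers all current objects; non-wet ids keep
#'   `NA`).
#' @export
classify_wet <- function(objects, ids, scene, config = threshold_config(),
                         taxonomy = water_taxonomy()) {
  st <- objects$stats
  lab <- stats::setNames(rep(NA_character_, nrow(st)), st$id)
  is_wet <- st$id %in% ids

  clc <- is_wet &
    st$ndvi >= threshold_value(config, "clc_ndvi_min") &
    st$ndvi <= threshold_value(config, "clc_ndvi_max")
  lab[as.character(st$id[clc])] <- "CLC"

  ndtlb <- is_wet & is.na(lab[as.character(st$id)]) &
    st$ndvi >= threshold_value(config, "ndtlb_ndvi_min") &
    st$edge_area <= threshold_value(config, "ndtlb_edge_area_max")
  lab[as.character(st$id[ndtlb])] <- "nDTLB"

  water_ids <- st$id[is_wet & is.na(lab[as.character(st$id)]) &
                       st$blue <= threshold_value(config, "openwater_blue")]
  if (length(water_ids)) {
    objects <- spectral_difference_merge(
      objects, scene,
      threshold = attr(config, "spectral_threshold") %||% 0.02,
      iterations = 5, subset = water_ids)
    st2 <- objects$stats
    # ids of merged representatives (merge keeps the smallest member id)
    water_ids <- intersect(water_ids, st2$id)
    lab2 <- stats::setNames(rep(NA_character_, nrow(st2)), st2$id)
    keep <- intersect(names(lab)[!is.na(lab)], as.character(st2$id))
    lab2[keep] <- lab[keep]
    lab <- lab2
    st <- st2
    w <- st[st$id %in% water_ids, ]
    is_river <- w$roundness <= threshold_value(config, "river_roundness_max") &
      w$ndvi <= threshold_value(config, "river_ndvi_max")
    size <- classify_water_body(w$area_ha, taxonomy)
    guard <- size %in% lake_labels &
      w$edge_area > threshold_value(config, "lake_edge_area_max")
    size[guard] <- "pond"
    size[is_river] <- "river"
    lab[as.character(w$id)] <- size
  }

  st <- objects$stats
  ice <- st$id %in% ids & is.na(lab[as.character(st$id)]) &
    st$swir2 >= threshold_value(config, "ice_swir2_min")
  for (id in st$id[ice]) {
    nb <- setdiff(neighbours_of(objects$adjacency, id), st$id[ice])
    nb_lab <- lab[as.character(nb)]
    on_lake <- length(nb_lab) > 0 && all(nb_lab %in% c(lake_labels, "CS"), na.rm = FALSE) &&
      !anyNA(nb_lab)
    lab[as.character(id)] <- if (on_lake) names(sort(table(nb_lab),
                                                     decreasing = TRUE))[1]
                             else "ice"
  }

  residual <- st$id %in% ids & is.na(lab[as.character(st$id)]) &
    !(st$id %in% st$id[ice])
  lab[as.character(st$id[residual])] <- "LC"
  # merged-away wet ids no longer exist; all surviving wet ids are labeled
  list(objects = objects, landform = lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify dry tundra objects
#'
#' Applies the dry-tundra rule sequence, in order: flat-center polygons (FC)
#' by the highest NDWI among dry objects (slightly wetter surfaces); riparian
#' corridors (RC) by a low-moderate NDVI band plus adjacency to a river
#' object; sand/gravel by a high BlueMax threshold, split into sandy barrens
#' (SB, lightly vegetated, moderate-high NDVI) versus sand dunes (SD, drier);
#' drained slopes (DS) by a high albedo threshold; every remaining dry object
#' becomes high-center polygons (HC), the dominant dry landform.
#'
#' @param objects a `tundra_objects` map.
#' @param ids integer ids of the dry objects.
#' @param landform named character vector of labels so far (needed for river
#'   adjacency); as returned by [classify_wet()].
#' @param config a [threshold_config()].
#' @return updated named label vector.
#' @export
classify_dry <- function(objects, ids, landform,
                         config = threshold_config()) {
  st <- objects$stats
  lab <- landform
  remaining <- function() st$id %in% ids & is.na(lab[as.character(st$id)])

  fc <- remaining() & st$ndwi >= threshold_value(config, "fc_ndwi_min")
  lab[as.character(st$id[fc])] <- "FC"

  river_ids <- as.integer(names(lab)[!is.na(lab) & lab == "river"])
  rc <- remaining() &
    st$ndvi >= threshold_value(config, "rc_ndvi_low") &
    st$ndvi <= threshold_value(config, "rc_ndvi_high")
  if (any(rc)) {
    touches_river <- vapply(st$id, function(id)
      any(neighbours_of(objects$adjacency, id) %in% river_ids), logical(1))
    rc <- rc & touches_river
  }
  lab[as.character(st$id[rc])] <- "RC"

  sand <- remaining() &
    st$bluemax >= threshold_value(config, "sandgravel_bluemax_min")
  sb <- sand & st$ndvi >= threshold_value(config, "sb_ndvi_min")
  lab[as.character(st$id[sb])] <- "SB"
  lab[as.character(st$id[sand & !sb])] <- "SD"

  ds <- remaining() & st$albedo >= threshold_value(config, "ds_albedo_min")
  lab[as.character(st$id[ds])] <- "DS"

  lab[as.character(st$id[remaining()])] <- "HC"
  lab
}

#' Rectify known confusions by landform proximity
#'
#' One deterministic rectification pass over the object labels: (1) lake
#' rule - ponds and CLC adjacent to a lake are relabeled nDTLB (aquatic-wet
#' landforms hugging lake perimeters are young drained-basin surfaces);
#' (2) river rule - remaining ponds and CLC adjacent to a river are relabeled
#' SB. Objects adjacent to both a lake and a river are resolved by the lake
#' rule (documented precedence); there is no fixpoint iteration.
#'
#' @param landform named character label vector (names = object ids).
#' @param objects the `tundra_objects` map supplying adjacency.
#' @param buffer optional adjacency buffer in pixels (0 = objects must share
#'   a border edge); provided for sensitivity tests.
#' @return the rectified label vector.
#' @export
apply_proximity_rules <- function(landform, objects, buffer = 0) {
  adj <- objects$adjacency
  if (buffer > 0) adj <- buffered_adjacency(objects$labels, buffer)
  lab <- landform
  ids <- as.integer(names(lab))
  lake_ids <- ids[!is.na(lab) & lab %in% lake_labels]
  river_ids <- ids[!is.na(lab) & lab == "river"]
  target <- ids[!is.na(lab) & lab %in% c("pond", "CLC")]
  for (id in target) {
    nb <- neighbours_of(adj, id)
    if (any(nb %in% lake_ids)) {
      lab[as.character(id)] <- "nDTLB"
    } else if (any(nb %in% river_ids)) {
      lab[as.character(id)] <- "SB"
    }
  }
  lab
}

buffered_adjacency <- function(labels, buffer) {
  nr <- nrow(labels); nc <- ncol(labels)
  pairs <- matrix(integer(), 0, 2)
  for (dr in -buffer:buffer) {
    for (dc in -buffer:buffer) {
      if (dr == 0 && dc == 0) next
      r1 <- max(1, 1 - dr):min(nr, nr - dr)
      c1 <- max(1, 1 - dc):min(nc, nc - dc)
      a <- labels[r1, c1, drop = FALSE]
      b <- labels[r1 + dr, c1 + dc, drop = FALSE]
      keep <- !is.na(a) & !is.na(b) & a != b
      if (any(keep))
        pairs <- rbind(pairs, cbind(a[keep], b[keep]))
    }
  }
  if (!nrow(pairs)) return(matrix(integer(), 0, 2))
  unique(cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2])))
}

#' Classify a scene into the landform legend
#'
#' Orchestrates the full pipeline: spectral indices, region-merging
#' segmentation, the wet/dry NDWI split, the wet and dry rule hierarchies,
#' the proximity rectification pass, rasterization of object labels to the
#' 30 m grid, and finally any manual-override polygons (e.g. urban areas,
#' which are never assigned automatically).
#'
#' @param scene a [tundra_scene()].
#' @param config a [threshold_config()].
#' @param params a [segmentation_params()].
#' @param taxonomy a [water_taxonomy()].
#' @param overrides optional data frame of rectangles to stamp last, with
#'   columns `row_min`, `row_max`, `col_min`, `col_max`, `landform`.
#' @param proximity apply the proximity rectification pass (default `TRUE`;
#'   disabling it reproduces the documented pond/CLC-near-lake confusion).
#' @param buffer adjacency buffer in pixels for the proximity pass.
#' @return A `landform_map`: list with `labels` (integer code matrix, `NA`
#'   outside the valid area), `legend`, `objects`, `object_landform` and
#'   `pixel_size`.
#' @export
classify_scene <- function(scene, config = threshold_config(),
                           params = segmentation_params(),
                           taxonomy = water_taxonomy(),
                           overrides = NULL, proximity = TRUE, buffer = 0) {
  attr(config, "spectral_threshold") <- params$spectral_threshold
  om <- segment(scene, params)
  wd <- split_wet_dry(om, config)
  wet_res <- classify_wet(om, wd$wet, scene, config, taxonomy)
  om <- wet_res$objects
  landform <- classify_dry(om, wd$dry, wet_res$landform, config)
  if (proximity) landform <- apply_proximity_rules(landform, om, buffer)

  codes <- landform_code(unname(landform))
  code_of <- stats::setNames(codes, names(landform))
  labels <- om$labels
  labels[] <- code_of[as.character(om$labels)]
  storage.mode(labels) <- "integer"

  if (!is.null(overrides)) {
    for (k in seq_len(nrow(overrides))) {
      labels[overrides$row_min[k]:overrides$row_max[k],
             overrides$col_min[k]:overrides$col_max[k]] <-
        landform_code(overrides$landform[k])
    }
    labels[!scene$mask] <- NA_integer_
  }

  structure(list(labels = labels, legend = landform_legend(),
                 objects = om, object_landform = landform,
                 pixel_size = scene$pixel_size),
            class = "landform_map")
}

#' @export
print.landform_map <- function(x, ...) {
  tab <- table(landform_name(x$labels))
  cat("landform_map:", sum(!is.na(x$labels)), "classified pixels\n")
  print(tab)
  invisible(x)
}

#' Landform map attribute table
#'
#' Per-class area summary of a landform map: landform, area (km^2) and soil
#' moisture regime rank (1 = wettest), matching the attribute table shipped
#' with published landform rasters.
#'
#' @param map a `landform_map` from [classify_scene()].
#' @return data frame with columns `landform`, `area_km2`, `smr_rank`.
#' @export
landform_attribute_table <- function(map) {
  leg <- landform_legend()
  counts <- table(factor(as.vector(map$labels), levels = leg$code))
  px_km2 <- map$pixel_size^2 / 1e6
  out <- data.frame(landform = leg$landform,
                    area_km2 = as.vector(counts) * px_km2,
                    smr_rank = leg$smr_rank)
  out[out$area_km2 > 0, , drop = FALSE]
}
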