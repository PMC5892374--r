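#' Segmentation parameters
#'
#' Knobs of the bottom-up region-merging segmentation. A merge of two
#' neighbouring objects is allowed while the weighted increase in
#' heterogeneity stays below `scale`; the spectral variance term is weighted
#' `1 - shape`, the shape term mixes compactness (`compactness`) and
#' smoothness (`1 - compactness`). `spectral_threshold` and
#' `merge_iterations` drive the spectral-difference merge pass used to fuse
#' neighbouring open-water objects.
#'
#' @param scale maximum allowed heterogeneity increase per merge (> 0).
#' @param shape shape weight in \[0, 1\] (0 = purely spectral).
#' @param compactness compactness weight in \[0, 1\].
#' @param spectral_threshold mean-spectra Euclidean distance below which
#'   adjacent objects are fused by [spectral_difference_merge()].
#' @param merge_iterations number of spectral-difference passes.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(scale = 0.5, shape = 0, compactness = 0.5,
                                spectral_threshold = 0.02,
                                merge_iterations = 5) {
  if (scale <= 0) stop("scale must be > 0")
  if (shape < 0 || shape > 1) stop("shape weight must be in [0, 1]")
  if (compactness < 0 || compactness > 1)
    stop("compactness weight must be in [0, 1]")
  structure(list(scale = scale, shape = shape, compactness = compactness,
                 spectral_threshold = spectral_threshold,
                 merge_iterations = merge_iterations),
            class = "segmentation_params")
}

#' Segment a scene into image objects
#'
#' Aggregates neighbouring pixels with similar spectra into image objects by
#' bottom-up pairwise region merging (an open substitute for commercial
#' multiresolution segmentation, keeping the scale/shape/compactness
#' semantics). Objects are 4-connected; merging is deterministic (scan by
#' ascending object id, merge only mutual best fits, ties to the lowest id).
#'
#' @param scene a [tundra_scene()].
#' @param params a [segmentation_params()].
#' @return A `tundra_objects` map: list with `labels` (integer matrix of
#'   object ids, `NA` outside the valid area), `stats` (per-object data frame
#'   from [compute_object_stats()]), `adjacency` (two-column matrix of
#'   adjacent id pairs) and `pixel_size`.
#' @export
#' @examples
#' sc <- uniform_scene(8, 8, setNames(rep(0.2, 9), oli_band_names()))
#' nrow(segment(sc, segmentation_params())$stats)  # 1 object
segment <- function(scene, params = segmentation_params()) {
  if (!any(scene$mask)) stop("scene has no valid pixels")
  labels <- cpp_segment(scene$bands, scene$mask, params$scale,
                        params$shape, params$compactness)
  object_map(labels, scene)
}

object_map <- function(labels, scene) {
  st <- compute_stats_df(labels, scene)
  structure(list(labels = labels, stats = st$stats, adjacency = st$adjacency,
                 pixel_size = scene$pixel_size),
            class = "tundra_objects")
}

#' @export
print.tundra_objects <- function(x, ...) {
  cat(sprintf("tundra_objects: %d objects over %d valid pixels (%g m pixels)\n",
              nrow(x$stats), sum(!is.na(x$labels)), x$pixel_size))
  invisible(x)
}

exposed_edges <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad_shift <- function(dr, dc) {
    out <- matrix(NA_integer_, nr, nc)
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- labels[rs[ok_r], cs[ok_c]]
    out
  }
  exp_count <- matrix(0L, nr, nc)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- pad_shift(d[1], d[2])
    exp_count <- exp_count + (is.na(nb) | nb != labels)
  }
  exp_count[is.na(labels)] <- 0L
  exp_count
}

adjacency_pairs <- function(labels) {
  pairs <- rbind(
    cbind(as.vector(labels[-nrow(labels), ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -ncol(labels)]), as.vector(labels[, -1]))
  )
  pairs <- pairs[!is.na(pairs[, 1]) & !is.na(pairs[, 2]) &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (!nrow(pairs)) return(matrix(integer(), 0, 2))
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  unique(pairs)
}

compute_stats_df <- function(labels, scene) {
  ids_vec <- as.vector(labels)
  ok <- !is.na(ids_vec)
  f <- factor(ids_vec[ok])
  ids <- as.integer(levels(f))
  n <- as.vector(table(f))
  ps <- scene$pixel_size
  mean_by <- function(grid) {
    as.vector(rowsum(as.vector(grid)[ok], f, na.rm = TRUE)) /
      as.vector(rowsum(as.numeric(!is.na(as.vector(grid)[ok])), f))
  }
  st <- data.frame(id = ids, n = n)
  for (b in oli_band_names()) st[[b]] <- mean_by(scene$bands[[b]])
  st$ndvi <- mean_by(ndvi(scene))
  st$ndwi <- mean_by(ndwi(scene))
  st$bluemax <- mean_by(bluemax(scene))
  st$albedo <- mean_by(albedo(scene))
  edges <- exposed_edges(labels)
  edge_counts <- as.vector(rowsum(as.vector(edges)[ok], f))
  st$perimeter_m <- edge_counts * ps
  st$area_ha <- n * ps^2 / 1e4
  st$edge_area <- edge_counts / n
  st$roundness <- 4 * pi * (n * ps^2) / (st$perimeter_m^2)
  list(stats = st, adjacency = adjacency_pairs(labels))
}

#' Recompute object statistics from a label grid
#'
#' Fills the per-object statistics the classification rules consume: mean
#' reflectance per band, mean NDVI/NDWI/BlueMax/albedo, area (ha, pixel
#' count x 0.09 ha at 30 m), perimeter (exposed pixel edges x pixel size),
#' edge-to-area ratio (exposed edge count / pixel count, dimensionless and
#' therefore resolution-explicit) and roundness (4 pi area / perimeter^2).
#'
#' @param objects a `tundra_objects` map (or an integer label matrix).
#' @param scene the [tundra_scene()] the objects partition.
#' @return a `tundra_objects` map with `stats` and `adjacency` recomputed.
#' @export
compute_object_stats <- function(objects, scene) {
  labels <- if (inherits(objects, "tundra_objects")) objects$labels else objects
  if (!identical(dim(labels), dim(scene$mask)))
    stop("object labels and scene shapes differ")
  object_map(labels, scene)
}

#' Merge adjacent objects with similar mean spectra
#'
#' Each pass fuses adjacent object pairs whose 9-band mean-reflectance
#' Euclidean distance is strictly below `threshold`, then recomputes object
#' statistics; the pass is repeated `iterations` times (or until no merge
#' occurs). Looped five times over open-water objects this isolates each
#' spatially distinct water body.
#'
#' @param objects a `tundra_objects` map.
#' @param scene the underlying [tundra_scene()].
#' @param threshold spectral distance below which neighbours merge.
#' @param iterations number of passes (>= 1).
#' @param subset optional integer ids; only objects in the subset are merged
#'   with each other.
#' @return the merged `tundra_objects` map.
#' @export
spectral_difference_merge <- function(objects, scene, threshold,
                                      iterations = 5, subset = NULL) {
  if (iterations < 1) stop("iterations must be >= 1")
  labels <- objects$labels
  bands <- oli_band_names()
  for (pass in seq_len(iterations)) {
    st <- objects$stats
    adj <- objects$adjacency
    if (!is.null(subset))
      adj <- adj[adj[, 1] %in% subset & adj[, 2] %in% subset, , drop = FALSE]
    if (!nrow(adj)) break
    m <- as.matrix(st[, bands])
    rownames(m) <- st$id
    d <- sqrt(rowSums((m[as.character(adj[, 1]), , drop = FALSE] -
                         m[as.character(adj[, 2]), , drop = FALSE])^2))
    fuse <- adj[d < threshold, , drop = FALSE]
    if (!nrow(fuse)) break
    # union-find over this pass's similar pairs
    parent <- stats::setNames(st$id, st$id)
    find <- function(i) {
      while (parent[[as.character(i)]] != i) i <- parent[[as.character(i)]]
      i
    }
    for (k in seq_len(nrow(fuse))) {
      a <- find(fuse[k, 1]); b <- find(fuse[k, 2])
      if (a != b) parent[[as.character(max(a, b))]] <- min(a, b)
    }
    root <- vapply(st$id, find, numeric(1))
    map <- stats::setNames(root, st$id)
    labels[] <- unname(map[as.character(labels)])
    storage.mode(labels) <- "integer"
    objects <- object_map(labels, scene)
  }
  objects
}
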