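#' The tundra landform legend
#'
#' Fifteen geomorphic landform classes are mapped, qualitatively ranked from
#' wet to dry: coastal saline water (CS), large/medium/small lakes, rivers,
#' ponds, coalescent low-center polygons (CLC), nonpatterned drained
#' thaw-lake basins (nDTLB), low-center polygons (LC), sandy barrens (SB),
#' flat-center polygons (FC), riparian corridors (RC), high-center polygons
#' (HC), drained slopes (DS) and sand dunes (SD). Two auxiliary classes can
#' occur: `ice` (ice/snow found away from lakes; ice on lakes is folded into
#' the lake class) and `urban`, which is only ever assigned through a manual
#' override layer.
#'
#' @param final_only if `TRUE`, return only the fifteen core map classes
#'   (excluding `ice` and `urban`).
#' @return A data frame with columns `code` (integer raster code), `landform`
#'   (short label), `description`, and `smr_rank` (soil-moisture regime rank,
#'   1 = wettest).
#' @export
#' @examples
#' landform_legend()
landform_legend <- function(final_only = FALSE) {
  df <- data.frame(
    code = 1:17,
    landform = c("CS", "lake_large", "lake_medium", "lake_small", "river",
                 "pond", "CLC", "nDTLB", "LC", "SB", "FC", "RC", "HC",
                 "DS", "SD", "ice", "urban"),
    description = c(
      "Coastal saline water", "Large lake (<=100,000, >90 ha)",
      "Medium lake (<=90, >20 ha)", "Small lake (<=20, >1 ha)", "River",
      "Pond (<=1 ha)", "Coalescent low-center polygons",
      "Nonpatterned drained thaw-lake basin", "Low-center polygons",
      "Sandy barrens", "Flat-center polygons", "Riparian corridor",
      "High-center polygons", "Drained slope", "Sand dunes",
      "Ice/snow", "Urban"),
    smr_rank = 1:17,
    stringsAsFactors = FALSE
  )
  if (final_only) df[df$landform %in% landform_classes(), , drop = FALSE] else df
}

#' @rdname landform_legend
#' @export
landform_classes <- function() {
  c("CS", "lake_large", "lake_medium", "lake_small", "river", "pond",
    "CLC", "nDTLB", "LC", "SB", "FC", "RC", "HC", "DS", "SD")
}

landform_code <- function(landform) {
  leg <- landform_legend()
  code <- leg$code[match(landform, leg$landform)]
  if (anyNA(code)) stop("unknown landform label: ",
                        paste(landform[is.na(code)], collapse = ", "))
  code
}

landform_name <- function(code) {
  leg <- landform_legend()
  leg$landform[match(code, leg$code)]
}

#' Default color palette for landform maps
#'
#' One hex color per legend class, ordered wet to dry, mirroring the role of
#' the color palette file distributed with published landform maps.
#'
#' @return data frame with columns `code`, `landform`, `color`.
#' @export
landform_palette <- function() {
  leg <- landform_legend()
  leg$color <- c("#08306b", "#2166ac", "#4393c3", "#92c5de", "#35978f",
                 "#80cdc1", "#c7eae5", "#a1d99b", "#41ab5d", "#fee391",
                 "#78c679", "#8c510a", "#addd8e", "#d8b365", "#f6e8c3",
                 "#f7fbff", "#636363")
  leg[, c("code", "landform", "color")]
}
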