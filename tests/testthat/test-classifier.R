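test_that("water-size taxonomy follows the printed inequalities at its boundaries", {
  expect_equal(classify_water_body(c(0.5, 0.9, 1)), rep("pond", 3))
  expect_equal(classify_water_body(1.0001), "lake_small")
  expect_equal(classify_water_body(20), "lake_small")
  expect_equal(classify_water_body(20.0001), "lake_medium")
  expect_equal(classify_water_body(90), "lake_medium")
  expect_equal(classify_water_body(90.0001), "lake_large")
  expect_equal(classify_water_body(83000), "lake_large")  # Teshekpuk-sized
  expect_equal(classify_water_body(100000), "lake_large")
  expect_equal(classify_water_body(100001), "CS")
  expect_error(classify_water_body(0), "positive")
  expect_error(classify_water_body(-3), "positive")
})

test_that("taxonomy is a monotone step function of area", {
  areas <- sort(10^runif(200, -2, 6))
  rank_of <- c(pond = 1, lake_small = 2, lake_medium = 3, lake_large = 4,
               CS = 5)
  ranks <- rank_of[classify_water_body(areas)]
  expect_true(all(diff(ranks) >= 0))
})

test_that("the NDWI split is exhaustive, exclusive, and wet at the threshold", {
  m <- default_mosaic()
  sc <- render_scene(m, noise_sd = 0, seed = 1)
  om <- segment(sc)
  wd <- split_wet_dry(om)
  expect_setequal(c(wd$wet, wd$dry), om$stats$id)
  expect_length(intersect(wd$wet, wd$dry), 0)
  # an object exactly at the threshold is wet (>= convention)
  thr <- threshold_value(threshold_config(), "wet_dry_ndwi")
  g <- 0.3 * (1 + thr) / (1 - thr)  # green/nir solving ndwi == thr
  sc2 <- scene_with(4, 4, list(green = matrix(g, 4, 4),
                               nir = matrix(0.3, 4, 4)))
  om2 <- segment(sc2)
  wd2 <- split_wet_dry(om2)
  expect_length(wd2$wet, 1)
  expect_length(wd2$dry, 0)
})

test_that("an all-water scene maps to a single water class", {
  grid <- matrix("water", 40, 40)
  sc <- signature_scene(grid)
  map <- classify_scene(sc)
  nm <- unique(tundramorph:::landform_name(map$labels))
  expect_length(nm, 1)
  expect_equal(nm, "lake_large")  # 1600 px = 144 ha
})

test_that("elongated water is river, an equal-area compact blob is a lake", {
  grid <- matrix("HC", 64, 64)
  grid[31:32, ] <- "water"            # 128 px corridor
  sc <- signature_scene(grid)
  map <- classify_scene(sc)
  expect_equal(unique(tundramorph:::landform_name(map$labels[31:32, ])),
               "river")
  grid2 <- matrix("HC", 64, 64)
  grid2[26:37, 26:37] <- "water"      # ~144 px compact blob, 12.96 ha
  map2 <- classify_scene(signature_scene(grid2))
  expect_equal(unique(tundramorph:::landform_name(map2$labels[26:37, 26:37])),
               "lake_small")
})

test_that("ice on a lake is folded into the lake; ice on land stays ice", {
  grid <- matrix("HC", 64, 64)
  grid[10:35, 10:35] <- "water"
  grid[20:22, 20:22] <- "ice"         # floe strictly inside the lake
  grid[50:52, 50:52] <- "ice"         # patch on land
  map <- classify_scene(signature_scene(grid))
  ln <- tundramorph:::landform_name
  expect_true(all(ln(map$labels[20:22, 20:22]) %in%
                    c("lake_large", "lake_medium", "lake_small")))
  expect_equal(unique(ln(map$labels[50:52, 50:52])), "ice")
})

test_that("residual rules catch everything: unmatched wet is LC, unmatched dry is HC", {
  grid <- matrix("LC", 32, 32); grid[, 17:32] <- "HC"
  map <- classify_scene(signature_scene(grid))
  ln <- tundramorph:::landform_name
  expect_equal(unique(ln(map$labels[, 1:16])), "LC")
  expect_equal(unique(ln(map$labels[, 17:32])), "HC")
})

test_that("riparian corridor requires river adjacency; otherwise it falls to HC", {
  grid <- matrix("HC", 64, 64)
  grid[31:32, ] <- "water"
  grid[28:30, ] <- "RC"               # touches the river
  grid[5:8, 5:20] <- "RC"             # far from the river
  map <- classify_scene(signature_scene(grid))
  ln <- tundramorph:::landform_name
  expect_equal(unique(ln(map$labels[28:30, ])), "RC")
  expect_equal(unique(ln(map$labels[5:8, 5:20])), "HC")
})

test_that("sand and gravel splits into SB (vegetated) and SD (dry); DS needs high albedo", {
  grid <- matrix("HC", 32, 96)
  grid[, 1:24] <- "SB"; grid[, 25:48] <- "SD"; grid[, 49:72] <- "DS"
  map <- classify_scene(signature_scene(grid))
  ln <- tundramorph:::landform_name
  expect_equal(unique(ln(map$labels[, 1:24])), "SB")
  expect_equal(unique(ln(map$labels[, 25:48])), "SD")
  expect_equal(unique(ln(map$labels[, 49:72])), "DS")
  expect_equal(unique(ln(map$labels[, 73:96])), "HC")
})

test_that("proximity pass: pond/CLC by a lake become nDTLB, by a river become SB, else unchanged", {
  ln <- tundramorph:::landform_name
  grid <- matrix("LC", 80, 80)
  grid[10:21, 10:21] <- "water"       # 144 px = 12.96 ha small lake
  grid[22:23, 14:17] <- "pond"        # pond hugging the lake (8 px)
  grid[60:61, 60:63] <- "pond"        # pond far away
  grid[71:72, ] <- "water"            # river corridor
  grid[66:70, 30:39] <- "CLC"         # CLC touching the river
  grid[40:44, 40:49] <- "CLC"         # CLC touching nothing
  map <- classify_scene(signature_scene(grid))
  expect_equal(unique(ln(map$labels[22:23, 14:17])), "nDTLB")
  expect_equal(unique(ln(map$labels[60:61, 60:63])), "pond")
  expect_equal(unique(ln(map$labels[66:70, 30:39])), "SB")
  expect_equal(unique(ln(map$labels[40:44, 40:49])), "CLC")
  # disabling the pass reproduces the documented confusions
  map0 <- classify_scene(signature_scene(grid), proximity = FALSE)
  expect_equal(unique(ln(map0$labels[22:23, 14:17])), "pond")
  expect_equal(unique(ln(map0$labels[66:70, 30:39])), "CLC")
})

test_that("objects adjacent to both a lake and a river resolve by the lake rule", {
  ln <- tundramorph:::landform_name
  grid <- matrix("LC", 80, 80)
  grid[20:31, 10:21] <- "water"       # lake
  grid[33:34, 1:80] <- "water"        # river below it
  grid[32, 12:19] <- "pond"           # single-row pond touching both
  map <- classify_scene(signature_scene(grid))
  expect_equal(unique(ln(map$labels[32, 12:19])), "nDTLB")
})

test_that("classification is total, conserves area, and uses only legend classes", {
  for (seed in c(3, 14)) {
    m <- generate_landform_mosaic(seed = seed)
    sc <- render_scene(m, seed = seed)
    map <- classify_scene(sc)
    expect_false(anyNA(map$labels[sc$mask]))
    expect_true(all(tundramorph:::landform_name(map$labels[sc$mask]) %in%
                      landform_classes()))
    att <- landform_attribute_table(map)
    expect_equal(sum(att$area_km2), sum(sc$mask) * 900 / 1e6)
  }
})

test_that("classification is deterministic for identical inputs", {
  m <- default_mosaic()
  sc <- render_scene(m, seed = 8)
  expect_identical(classify_scene(sc)$labels, classify_scene(sc)$labels)
})

test_that("manual override polygons are stamped last (urban over SD)", {
  grid <- matrix("SD", 64, 64)
  ov <- data.frame(row_min = 1, row_max = 10, col_min = 1, col_max = 10,
                   landform = "urban")
  map <- classify_scene(signature_scene(grid), overrides = ov)
  ln <- tundramorph:::landform_name
  expect_equal(unique(ln(map$labels[1:10, 1:10])), "urban")
  expect_equal(unique(ln(map$labels[11:64, ])), "SD")
})
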