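test_that("mosaic generation is reproducible and validates its inputs", {
  m1 <- small_mosaic(seed = 7)
  m2 <- small_mosaic(seed = 7)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$spectral, m2$spectral)
  expect_error(generate_landform_mosaic(shape = c(32, 32)), "64")
  expect_error(generate_landform_mosaic(weights = c(HC = -1)), "nonnegative")
  expect_error(generate_landform_mosaic(weights = c(bog = 1)), "unknown")
})

test_that("a degenerate lake-only mix yields one connected lake plus background", {
  m <- generate_landform_mosaic(shape = c(100, 100),
                                weights = c(lake_medium = 1), seed = 3)
  ln <- tundramorph:::landform_name
  expect_setequal(unique(ln(m$labels)), c("lake_medium", "HC"))
  water <- matrix(ifelse(ln(m$labels) == "lake_medium", 1L, NA_integer_),
                  100, 100)
  comp <- tundramorph:::cpp_components(water)
  expect_equal(max(comp, na.rm = TRUE), 1)  # single connected component
})

test_that("a requested 12-pixel water body has area 1.08 ha and is a small lake", {
  m <- generate_landform_mosaic(shape = c(64, 64),
                                weights = c(lake_small = 1),
                                water_px = c(lake_small = 12), seed = 5)
  ln <- tundramorph:::landform_name
  npx <- sum(ln(m$labels) == "lake_small")
  expect_equal(npx, 12)
  expect_equal(npx * 0.09, 1.08)
  expect_equal(classify_water_body(npx * 0.09), "lake_small")
})

test_that("coastal saline water cannot be embedded in a desk-scale grid", {
  expect_error(generate_landform_mosaic(shape = c(64, 64),
                                        weights = c(CS = 1)),
               "too small")
})

test_that("every requested landform appears, and adjacency facts are recorded", {
  m <- default_mosaic()
  present <- unique(tundramorph:::landform_name(m$labels))
  for (cl in c("lake_large", "lake_medium", "lake_small", "pond", "river",
               "nDTLB", "LC", "SB", "FC", "RC", "HC", "DS", "SD"))
    expect_true(cl %in% present, label = paste(cl, "present"))
  expect_true(any(m$adjacency_facts$touches == "lake"))
  expect_true(any(m$adjacency_facts$touches == "river"))
})

test_that("mosaic geometry honours the statistics the classifier tests", {
  m <- default_mosaic()
  ln <- tundramorph:::landform_name
  # each truth water body's pixel count matches its size class
  still <- ln(m$labels) %in% c("lake_large", "lake_medium", "lake_small",
                               "pond")
  comp <- tundramorph:::cpp_components(
    matrix(ifelse(still, m$labels, NA_integer_), nrow(m$labels)))
  for (k in unique(comp[!is.na(comp)])) {
    px <- sum(comp == k, na.rm = TRUE)
    cls <- unique(ln(m$labels[!is.na(comp) & comp == k]))
    expect_equal(classify_water_body(px * 0.09), cls)
  }
  # the river corridor is elongated: roundness far below the river threshold
  riv <- ln(m$labels) == "river"
  npx <- sum(riv)
  edges <- sum(tundramorph:::exposed_edges(
    matrix(ifelse(riv, 1L, NA_integer_), nrow(m$labels))))
  roundness <- 4 * pi * npx / edges^2
  expect_lt(roundness, threshold_value(threshold_config(),
                                       "river_roundness_max"))
})

test_that("rendering with zero noise reproduces signature means exactly", {
  m <- small_mosaic(seed = 2)
  sc <- render_scene(m, noise_sd = 0, seed = 1)
  sig <- default_signatures()
  cls <- spectral_class_of(as.vector(m$spectral))
  for (class in c("water", "HC", "nDTLB")) {
    px <- which(cls == class)
    if (!length(px)) next
    for (b in c("blue", "nir", "swir2"))
      expect_equal(unique(sc$bands[[b]][px]),
                   sig[[b]][sig$class == class], tolerance = 1e-12)
  }
})

test_that("noisy rendering hits signature means within 3 sd / sqrt(n)", {
  m <- generate_landform_mosaic(shape = c(96, 96), seed = 2)
  sc <- render_scene(m, noise_sd = 0.005, seed = 9)
  sig <- default_signatures()
  cls <- spectral_class_of(as.vector(m$spectral))
  for (class in c("HC", "nDTLB")) {
    px <- which(cls == class)
    tol <- 3 * 0.005 / sqrt(length(px))
    for (b in c("red", "nir"))
      expect_lt(abs(mean(sc$bands[[b]][px]) - sig[[b]][sig$class == class]),
                tol)
  }
})

test_that("rendering fails loudly when a class has no signature", {
  m <- small_mosaic(seed = 2)
  sig <- default_signatures()
  expect_error(render_scene(m, signatures = sig[sig$class != "HC", ]), "HC")
})

test_that("rendered index orderings match every pairwise contrast the rules use", {
  grid <- matrix(rep(c("water", "pond", "ice", "CLC", "nDTLB", "LC", "FC",
                       "RC", "HC", "DS", "SB", "SD"), each = 96), 24, 48)
  sc <- signature_scene(grid, noise_sd = 0.005, seed = 3)
  idx <- list(ndvi = ndvi(sc), ndwi = ndwi(sc), bluemax = bluemax(sc),
              albedo = albedo(sc), blue = sc$bands$blue,
              swir2 = sc$bands$swir2)
  cm <- function(ix, class) mean(idx[[ix]][grid == class])
  wet <- c("water", "pond", "ice", "CLC", "nDTLB", "LC")
  dry <- c("FC", "RC", "HC", "DS", "SB", "SD")
  for (w in wet) for (d in dry)
    expect_gt(cm("ndwi", w), cm("ndwi", d))         # wet/dry split
  expect_gt(cm("ndwi", "FC"),
            max(sapply(setdiff(dry, "FC"), function(x) cm("ndwi", x))))
  expect_gt(cm("ndvi", "nDTLB"), max(sapply(setdiff(wet, "nDTLB"),
                                            function(x) cm("ndvi", x))))
  expect_lt(cm("ndvi", "CLC"),
            min(cm("ndvi", "nDTLB"), cm("ndvi", "LC")))  # CLC low among wet veg
  for (x in setdiff(c(wet, dry), c("water", "pond")))
    expect_gt(cm("blue", x), cm("blue", "water"))    # open water darkest blue
  expect_gt(cm("swir2", "ice"), max(sapply(setdiff(wet, "ice"),
                                           function(x) cm("swir2", x))))
  expect_gt(min(cm("bluemax", "SB"), cm("bluemax", "SD")),
            max(sapply(setdiff(dry, c("SB", "SD")),
                       function(x) cm("bluemax", x))))
  expect_gt(cm("ndvi", "SB"), cm("ndvi", "SD"))
  expect_gt(cm("albedo", "DS"), max(cm("albedo", "HC"), cm("albedo", "FC"),
                                    cm("albedo", "RC")))
})

test_that("time stacks are reproducible, seasonal, and correctly masked", {
  s1 <- generate_ndvi_timestack(0.005, 0.4, shape = c(4, 4), seed = 3)
  s2 <- generate_ndvi_timestack(0.005, 0.4, shape = c(4, 4), seed = 3)
  expect_identical(s1$ndvi, s2$ndvi)
  expect_identical(s1$dates, s2$dates)
  md <- format(s1$dates, "%m-%d")
  expect_true(all(md >= "07-01" & md <= "08-30"))
  expect_true(all(diff(as.numeric(s1$dates)) >= 0))
  # sensors respect availability eras
  yr <- as.integer(format(s1$dates, "%Y"))
  expect_true(all(yr[s1$sensors == "TM"] %in% 2005:2011))
  expect_true(all(yr[s1$sensors == "OLI"] %in% 2013:2014))
  expect_error(generate_ndvi_timestack(0, 0.4, shape = c(2, 2),
                                       obs_per_year = 0), "obs_per_year")
  expect_error(generate_ndvi_timestack(0, 0.4, shape = c(2, 2),
                                       mask_fraction = 1), "mask_fraction")
})

test_that("masking at fraction 0.3 of ~60 observations leaves ~42 valid on average", {
  st <- generate_ndvi_timestack(0, 0.4, shape = c(30, 30), years = 2000:2014,
                                obs_per_year = 4, mask_fraction = 0.3,
                                seed = 6)
  counts <- apply(st$valid, c(1, 2), sum)
  expect_equal(mean(counts), 42, tolerance = 0.03)
  # an all-masked pixel reports zero valid count, not an error
  st$valid[1, 1, ] <- FALSE
  tr <- trend_map(st, min_obs = 10)
  expect_equal(tr$n_valid[1, 1], 0)
  expect_true(is.na(tr$slope[1, 1]))
})

test_that("noise-free stacks carry exactly the configured linear signal", {
  sl <- matrix(seq(-0.01, 0.01, length.out = 9), 3, 3)
  st <- generate_ndvi_timestack(sl, 0.35, noise_sd = 0, mask_fraction = 0,
                                seed = 4)
  # least-squares slope equals the true slope to numerical precision
  for (p in c(1, 5, 9)) {
    rc <- arrayInd(p, c(3, 3))
    fit <- lm(st$ndvi[rc[1], rc[2], ] ~ st$dec_years)
    expect_equal(unname(coef(fit)[2]), sl[p], tolerance = 1e-10)
  }
})

test_that("reference-site sampling is exact, unique, reproducible, and guarded", {
  m <- default_mosaic()
  sites <- generate_reference_sites(m, counts = c(`Arctic Peaty Lowland` = 700,
                                                  `Arctic Sandy Lowland` = 300),
                                    seed = 10)
  expect_equal(nrow(sites), 1000)
  expect_equal(as.vector(table(sites$ecological_landscape)), c(700, 300))
  expect_false(any(duplicated(sites[, c("row", "col")])))
  expect_equal(sites$landform,
               tundramorph:::landform_name(m$labels[cbind(sites$row, sites$col)]))
  sites2 <- generate_reference_sites(m, counts = c(`Arctic Peaty Lowland` = 700,
                                                   `Arctic Sandy Lowland` = 300),
                                     seed = 10)
  expect_identical(sites, sites2)
  empty <- generate_reference_sites(m, counts = c(`Arctic Peaty Lowland` = 0))
  expect_equal(nrow(empty), 0)
  expect_error(generate_reference_sites(m, counts = c(`Arctic Peaty Lowland` = 1e6)),
               "requested")
})
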