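#' Per-class spectral signature table
#'
#' Mean reflectance for the nine OLI bands per spectral class, plus a default
#' per-band noise standard deviation, used by [render_scene()]. Values are
#' synthetic stand-ins (no quantitative per-landform spectra are published)
#' chosen so that every qualitative ordering the classifier relies on holds
#' with a wide margin on the decisive index: water NDWI above all land
#' classes, nDTLB NDVI high, CLC NDVI low among wet classes, DS albedo high,
#' sand classes (SB/SD) BlueMax high, SD NDVI below SB NDVI, ice SWIR2 high.
#' Ponds carry their own shallow-water signature, spectrally separated from
#' lake/river water by more than the default spectral-difference merge
#' threshold so that a pond touching a lake remains a distinct object.
#'
#' @return data frame with `class`, one column per band, and `sd`.
#' @export
default_signatures <- function() {
  sig <- rbind(
    water = c(0.030, 0.030, 0.120, 0.050, 0.020, 0.010, 0.010, 0.060, 0.010),
    pond  = c(0.040, 0.040, 0.130, 0.060, 0.040, 0.020, 0.015, 0.070, 0.010),
    ice   = c(0.420, 0.450, 0.480, 0.440, 0.400, 0.260, 0.220, 0.440, 0.040),
    CLC   = c(0.060, 0.090, 0.110, 0.090, 0.130, 0.050, 0.030, 0.100, 0.010),
    nDTLB = c(0.060, 0.090, 0.150, 0.050, 0.380, 0.100, 0.050, 0.180, 0.010),
    LC    = c(0.060, 0.090, 0.110, 0.080, 0.250, 0.090, 0.050, 0.140, 0.010),
    FC    = c(0.060, 0.090, 0.075, 0.070, 0.290, 0.140, 0.080, 0.150, 0.010),
    RC    = c(0.060, 0.090, 0.045, 0.110, 0.280, 0.160, 0.090, 0.160, 0.010),
    HC    = c(0.060, 0.090, 0.050, 0.080, 0.300, 0.200, 0.120, 0.150, 0.010),
    DS    = c(0.180, 0.200, 0.080, 0.280, 0.500, 0.300, 0.200, 0.280, 0.030),
    SB    = c(0.240, 0.260, 0.060, 0.100, 0.460, 0.300, 0.220, 0.260, 0.020),
    SD    = c(0.300, 0.340, 0.070, 0.360, 0.520, 0.300, 0.240, 0.320, 0.040),
    urban = c(0.300, 0.340, 0.070, 0.360, 0.520, 0.300, 0.240, 0.320, 0.040)
  )
  colnames(sig) <- oli_band_names()
  data.frame(class = rownames(sig), sig, sd = 0.005, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Map landform labels to spectral signature classes
#'
#' Coastal saline water, the three lake classes and rivers share the `water`
#' signature; ponds, ice and the terrestrial landforms have their own;
#' urban shares the sand-dune signature (the reason urban is only ever
#' assigned manually).
#'
#' @param landform character vector of landform labels.
#' @return character vector of signature class names.
#' @export
spectral_class_of <- function(landform) {
  out <- landform
  out[landform %in% c("CS", "lake_large", "lake_medium", "lake_small",
                      "river")] <- "water"
  out
}

local_seed <- function(seed) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    f <- function() assign(".Random.seed", old, envir = globalenv())
  } else {
    f <- function() suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  f
}

dilate <- function(mask, radius) {
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(radius)) {
    nb <- out
    nb[-1, ] <- nb[-1, ] | out[-nr, ]
    nb[-nr, ] <- nb[-nr, ] | out[-1, ]
    nb[, -1] <- nb[, -1] | out[, -nc]
    nb[, -nc] <- nb[, -nc] | out[, -1]
    out <- nb
  }
  out
}

# Grow a 4-connected blob of `npx` pixels from `start` within `allowed`,
# biased towards compact growth. Returns a logical mask or NULL on failure.
grow_blob <- function(allowed, start, npx) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  blob <- matrix(FALSE, nr, nc)
  if (!allowed[start[1], start[2]]) return(NULL)
  blob[start[1], start[2]] <- TRUE
  count <- 1L
  while (count < npx) {
    fr <- which(dilate(blob, 1) & !blob & allowed, arr.ind = TRUE)
    if (!nrow(fr)) return(NULL)
    # weight frontier cells by squared count of blob neighbours -> compact
    wts <- apply(fr, 1, function(rc) {
      r <- rc[1]; c <- rc[2]
      nb <- sum(blob[max(1, r - 1), c], blob[min(nr, r + 1), c],
                blob[r, max(1, c - 1)], blob[r, min(nc, c + 1)])
      nb^2
    })
    pick <- fr[sample.int(nrow(fr), 1, prob = wts), ]
    blob[pick[1], pick[2]] <- TRUE
    count <- count + 1L
  }
  blob
}

#' Generate a labeled landform mosaic
#'
#' Builds a synthetic polygonal-tundra landscape on a 30 m grid:
#' terrestrial landform fields as a Voronoi-textured mosaic, rivers as
#' random-walk corridors (guaranteeing low roundness) flanked by riparian
#' corridor margins, lakes and ponds as compact grown blobs with pixel
#' counts matching their size class, plus deliberate proximity fixtures
#' (a pond and a CLC patch touching a lake, a CLC patch touching the river)
#' that exercise the rectification rules. Only the statistics the classifier
#' tests (area, roundness, adjacency, spectra) are realistic, not the visual
#' geometry.
#'
#' The returned `labels` grid is the ground truth a correct classification
#' should reproduce: pond/CLC surfaces touching a lake are recorded as nDTLB
#' and CLC/pond surfaces touching a river as SB (the lake rule taking
#' precedence), while the `spectral` grid keeps the signature class each
#' pixel is rendered with, so disabling the rectification pass reproduces
#' the documented confusions.
#'
#' @param shape integer `c(rows, cols)`, at least 64 x 64.
#' @param weights named nonnegative weights over landform classes. Water
#'   classes get `max(1, round(weight))` instances each; terrestrial classes
#'   share Voronoi cells proportionally to weight. `RC` requires `river`.
#' @param seed integer RNG seed; output is reproducible bit-for-bit.
#' @param water_px named pixel counts per water-body instance (defaults:
#'   lake_large 1334, lake_medium 500, lake_small 89, pond 7).
#' @param n_cells number of Voronoi cells for the terrestrial background.
#' @param origin upper-left pixel-center `c(lon, lat)`.
#' @return A `landform_mosaic`: list with `labels` (truth codes), `spectral`
#'   (signature-class names matrix), `pixel_size`, `origin`, and
#'   `adjacency_facts` (data frame recording which pond/CLC fixtures touch
#'   lakes/rivers).
#' @export
generate_landform_mosaic <- function(shape = c(128, 128),
                                     weights = default_mosaic_weights(),
                                     seed = 1,
                                     water_px = c(lake_large = 1334,
                                                  lake_medium = 500,
                                                  lake_small = 89,
                                                  pond = 7),
                                     n_cells = NULL,
                                     origin = c(-155, 70.5)) {
  if (length(shape) != 2 || any(shape < 64))
    stop("shape must be at least 64 x 64")
  if (any(weights < 0)) stop("class weights must be nonnegative")
  bad <- setdiff(names(weights), landform_legend()$landform)
  if (length(bad)) stop("unknown landform(s) in weights: ",
                        paste(bad, collapse = ", "))
  restore <- local_seed(seed)
  on.exit(restore())
  nr <- shape[1]; nc <- shape[2]

  water_classes <- c("CS", "lake_large", "lake_medium", "lake_small", "pond")
  sizes <- c(CS = 1.12e6, lake_large = 1334, lake_medium = 500,
             lake_small = 89, pond = 7)
  sizes[names(water_px)] <- water_px
  req_water <- intersect(names(weights)[weights > 0], water_classes)
  if (length(req_water)) {
    biggest <- max(sizes[req_water])
    if (biggest > 0.25 * nr * nc)
      stop(sprintf(paste0("grid %d x %d too small to embed requested water ",
                          "body of %d pixels"), nr, nc, round(biggest)))
  }

  field_classes <- c("CLC", "nDTLB", "LC", "SB", "FC", "HC", "DS", "SD")
  fw <- weights[intersect(names(weights)[weights > 0], field_classes)]
  if (!length(fw)) fw <- c(HC = 1)
  if (is.null(n_cells)) n_cells <- max(length(fw), round(nr * nc / 900))

  # Voronoi-textured terrestrial background
  sr <- sample.int(nr, n_cells, replace = TRUE)
  sc <- sample.int(nc, n_cells, replace = TRUE)
  cell_class <- c(names(fw),
                  sample(names(fw), max(0, n_cells - length(fw)),
                         replace = TRUE, prob = fw))[seq_len(n_cells)]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc)
  nearest <- matrix(1L, nr, nc)
  for (k in seq_len(n_cells)) {
    d <- (rows - sr[k])^2 + (cols - sc[k])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    nearest[upd] <- k
  }
  spectral <- matrix(cell_class[nearest], nr, nc)

  facts <- data.frame(feature = character(), spectral = character(),
                      truth = character(), touches = character(),
                      stringsAsFactors = FALSE)
  water_mask <- matrix(FALSE, nr, nc)
  river_mask <- matrix(FALSE, nr, nc)

  # river: random-walk corridor, 2 px wide, left to right
  if (isTRUE(weights["river"] > 0)) {
    r <- sample(seq(round(nr * 0.55), nr - 6), 1)
    for (cc in seq_len(nc)) {
      river_mask[r:(r + 1), cc] <- TRUE
      r <- min(max(r + sample(c(-1, 0, 1), 1), 3), nr - 4)
    }
    spectral[river_mask] <- "river"
    water_mask <- water_mask | river_mask
    if (isTRUE(weights["RC"] > 0)) {
      ring <- dilate(river_mask, 2) & !river_mask
      spectral[ring] <- "RC"
    }
  }

  place_blob <- function(class, npx, must_touch = NULL) {
    forbidden <- dilate(water_mask, 3)
    allowed <- !forbidden &
      !(spectral %in% c("river", "RC")) # keep corridor intact
    dim(allowed) <- dim(spectral)
    if (!is.null(must_touch)) {
      seedable <- dilate(must_touch, 1) & !must_touch & !water_mask
      allowed <- (!dilate(water_mask & !must_touch, 3)) & !water_mask
      dim(allowed) <- dim(spectral)
    } else {
      seedable <- allowed & rows > 3 & rows < nr - 3 & cols > 3 & cols < nc - 3
    }
    for (try in 1:50) {
      cand <- which(seedable, arr.ind = TRUE)
      if (!nrow(cand)) return(NULL)
      start <- cand[sample.int(nrow(cand), 1), ]
      blob <- grow_blob(allowed, start, npx)
      if (!is.null(blob)) return(blob)
    }
    NULL
  }

  lakes <- list()
  for (cl in intersect(req_water, c("CS", "lake_large", "lake_medium",
                                    "lake_small"))) {
    for (i in seq_len(max(1, round(weights[cl])))) {
      blob <- place_blob(cl, sizes[cl])
      if (is.null(blob)) stop("could not place water body of class ", cl)
      spectral[blob] <- "water"
      water_mask <- water_mask | blob
      lakes[[length(lakes) + 1]] <- blob
    }
  }

  if ("pond" %in% req_water) {
    for (i in seq_len(max(1, round(weights["pond"])))) {
      blob <- place_blob("pond", sizes["pond"])
      if (is.null(blob)) stop("could not place pond")
      spectral[blob] <- "pond"
      water_mask <- water_mask | blob
      facts <- rbind(facts, data.frame(feature = "pond", spectral = "pond",
                                       truth = "pond", touches = "none"))
    }
    if (length(lakes)) { # proximity fixture: pond hugging the first lake
      blob <- place_blob("pond", sizes["pond"], must_touch = lakes[[1]])
      if (!is.null(blob)) {
        spectral[blob] <- "pond"
        water_mask <- water_mask | blob
        facts <- rbind(facts, data.frame(feature = "pond_near_lake",
                                         spectral = "pond", truth = "nDTLB",
                                         touches = "lake"))
      }
    }
  }

  if (isTRUE(weights["CLC"] > 0)) {
    if (length(lakes)) {
      blob <- place_blob("CLC", 40, must_touch = lakes[[length(lakes)]])
      if (!is.null(blob)) {
        spectral[blob] <- "CLC"
        facts <- rbind(facts, data.frame(feature = "clc_near_lake",
                                         spectral = "CLC", truth = "nDTLB",
                                         touches = "lake"))
      }
    }
    if (any(river_mask)) {
      blob <- place_blob("CLC", 40, must_touch = river_mask)
      if (!is.null(blob)) {
        spectral[blob] <- "CLC"
        facts <- rbind(facts, data.frame(feature = "clc_near_river",
                                         spectral = "CLC", truth = "SB",
                                         touches = "river"))
      }
    }
  }

  if (isTRUE(weights["ice"] > 0)) {
    if (length(lakes)) { # ice floe strictly inside the first (largest) lake
      inner <- lakes[[1]] & !(dilate(!lakes[[1]], 2))
      cand <- which(inner, arr.ind = TRUE)
      if (nrow(cand)) {
        start <- cand[sample.int(nrow(cand), 1), ]
        blob <- grow_blob(inner, start, min(9, sum(inner)))
        if (!is.null(blob)) spectral[blob] <- "ice"
      }
    }
    blob <- place_blob("ice", 12)
    if (!is.null(blob)) spectral[blob] <- "ice"
  }

  labels <- truth_from_spectral(spectral, water_mask, river_mask,
                                pixel_size = 30)
  structure(list(labels = labels, spectral = spectral, pixel_size = 30,
                 origin = origin, adjacency_facts = facts),
            class = "landform_mosaic")
}

#' @rdname generate_landform_mosaic
#' @export
default_mosaic_weights <- function() {
  c(lake_large = 1, lake_medium = 1, lake_small = 1, pond = 2, river = 1,
    CLC = 1, nDTLB = 1.5, LC = 3, SB = 1, FC = 1.5, RC = 1, HC = 3,
    DS = 1, SD = 1)
}

# Derive ground-truth legend codes from the spectral-class grid: water bodies
# take their taxonomy class (rivers stay rivers), pond/CLC surfaces touching
# a lake become nDTLB, remaining pond/CLC touching a river become SB, ice
# surrounded by one lake takes that lake's class.
truth_from_spectral <- function(spectral, water_mask, river_mask, pixel_size) {
  nr <- nrow(spectral); nc <- ncol(spectral)
  truth <- matrix(NA_character_, nr, nc)
  truth[] <- spectral
  still_water <- water_mask & !river_mask & spectral == "water"
  comp <- cpp_components(matrix(ifelse(still_water, 1L, NA_integer_), nr, nc))
  for (k in unique(comp[!is.na(comp)])) {
    m <- comp == k & !is.na(comp)
    truth[m] <- classify_water_body(sum(m) * pixel_size^2 / 1e4)
  }
  lake_mask <- matrix(truth %in% lake_labels, nr, nc)
  adjust <- function(cls, near, newlab) {
    m <- spectral == cls & truth == cls
    comp <- cpp_components(matrix(ifelse(m, 1L, NA_integer_), nr, nc))
    for (k in unique(comp[!is.na(comp)])) {
      blob <- comp == k & !is.na(comp)
      if (any(dilate(blob, 1) & !blob & near)) truth[blob] <<- newlab
    }
  }
  adjust("pond", lake_mask, "nDTLB")
  adjust("CLC", lake_mask, "nDTLB")
  adjust("pond", river_mask, "SB")
  adjust("CLC", river_mask, "SB")
  ice_m <- spectral == "ice"
  if (any(ice_m)) {
    comp <- cpp_components(matrix(ifelse(ice_m, 1L, NA_integer_), nr, nc))
    for (k in unique(comp[!is.na(comp)])) {
      blob <- comp == k & !is.na(comp)
      ring <- dilate(blob, 1) & !blob
      nb <- unique(truth[ring])
      if (length(nb) && all(nb %in% lake_labels)) truth[blob] <- nb[1]
    }
  }
  codes <- matrix(landform_code(as.vector(truth)), nr, nc)
  codes
}

#' @export
print.landform_mosaic <- function(x, ...) {
  cat("landform_mosaic:", nrow(x$labels), "x", ncol(x$labels), "pixels\n")
  print(table(landform_name(x$labels)))
  invisible(x)
}

#' Render a mosaic to a multispectral scene
#'
#' Draws each pixel's nine band reflectances from the signature of its
#' spectral class plus independent Gaussian noise, clamped to \[0, 1.5\].
#'
#' @param mosaic a `landform_mosaic`.
#' @param signatures signature table as from [default_signatures()].
#' @param noise_sd per-band noise standard deviation; overrides the table's
#'   `sd` column if not `NULL`. Use 0 for noise-free rendering.
#' @param seed RNG seed.
#' @return a [tundra_scene()].
#' @export
render_scene <- function(mosaic, signatures = default_signatures(),
                         noise_sd = NULL, seed = 1) {
  restore <- local_seed(seed)
  on.exit(restore())
  spectral <- matrix(spectral_class_of(as.vector(mosaic$spectral)),
                     nrow(mosaic$spectral), ncol(mosaic$spectral))
  classes <- unique(as.vector(spectral))
  missing <- setdiff(classes, signatures$class)
  if (length(missing))
    stop("no spectral signature for class(es): ",
         paste(missing, collapse = ", "))
  nr <- nrow(spectral); nc <- ncol(spectral)
  idx <- match(as.vector(spectral), signatures$class)
  sds <- if (is.null(noise_sd)) signatures$sd[idx] else noise_sd
  bands <- list()
  for (b in oli_band_names()) {
    mu <- signatures[[b]][idx]
    v <- mu + if (all(sds == 0)) 0 else stats::rnorm(nr * nc, 0, sds)
    bands[[b]] <- matrix(pmin(pmax(v, 0), 1.5), nr, nc)
  }
  tundra_scene(bands, pixel_size = mosaic$pixel_size, origin = mosaic$origin)
}

sensor_availability <- function() {
  list(`ETM+` = c(1999, 2014), TM = c(2005, 2011), OLI = c(2013, 2014))
}

#' Simulate an NDVI time stack with known linear trends
#'
#' Per pixel, NDVI observations follow
#' `gain(sensor) * (intercept + slope * (t - ref_year)) + offset(sensor) +
#' noise`; acquisition dates are drawn inside the July 1 - August 30 peak
#' growing season of each year, sensors are tagged by their availability era
#' (ETM+ 1999-2014, TM 2005-2011, OLI 2013-2014), and a fraction of
#' observations is masked invalid (emulating cloud/shadow screening).
#' Offsets and gains act directly on NDVI, matching how inter-sensor bias is
#' diagnosed.
#'
#' @param slope true slope grid (NDVI/yr) or a scalar.
#' @param intercept true intercept grid at `ref_year` or a scalar.
#' @param shape grid shape when `slope`/`intercept` are scalars.
#' @param years integer years of acquisition.
#' @param obs_per_year observations drawn per year (>= 1).
#' @param noise_sd observation noise standard deviation.
#' @param sensor_offsets,sensor_gains named additive offsets / multiplicative
#'   gains per sensor tag.
#' @param mask_fraction probability in \[0, 1) that an observation is masked.
#' @param ref_year reference year of the intercept.
#' @param seed RNG seed.
#' @return An `ndvi_stack`: list with `dates` (Date), `dec_years`, `sensors`,
#'   `ndvi` (rows x cols x time array), `valid` (same shape, logical) and
#'   `ref_year`.
#' @export
generate_ndvi_timestack <- function(slope, intercept, shape = NULL,
                                    years = 1999:2014, obs_per_year = 4,
                                    noise_sd = 0.02,
                                    sensor_offsets = c(`ETM+` = 0, TM = 0,
                                                       OLI = 0),
                                    sensor_gains = c(`ETM+` = 1, TM = 1,
                                                     OLI = 1),
                                    mask_fraction = 0.2, ref_year = 2014,
                                    seed = 1) {
  if (obs_per_year < 1) stop("obs_per_year must be >= 1")
  if (mask_fraction < 0 || mask_fraction >= 1)
    stop("mask_fraction must be in [0, 1)")
  if (is.null(dim(slope))) {
    if (is.null(shape)) stop("shape required for scalar slope/intercept")
    slope <- matrix(slope, shape[1], shape[2])
  }
  if (is.null(dim(intercept)))
    intercept <- matrix(intercept, nrow(slope), ncol(slope))
  restore <- local_seed(seed)
  on.exit(restore())
  nr <- nrow(slope); nc <- ncol(slope)

  avail <- sensor_availability()
  dates <- as.Date(character()); sensors <- character()
  for (y in years) {
    day <- sort(sample.int(61, obs_per_year, replace = TRUE)) - 1
    d <- as.Date(sprintf("%d-07-01", y)) + day
    ok <- names(avail)[vapply(avail, function(a) y >= a[1] && y <= a[2],
                              logical(1))]
    s <- sample(ok, obs_per_year, replace = TRUE)
    dates <- c(dates, d); sensors <- c(sensors, s)
  }
  dec <- decimal_year(dates)
  nt <- length(dates)
  ndvi_arr <- array(NA_real_, c(nr, nc, nt))
  valid <- array(FALSE, c(nr, nc, nt))
  for (k in seq_len(nt)) {
    base <- intercept + slope * (dec[k] - ref_year)
    g <- sensor_gains[[sensors[k]]]
    o <- sensor_offsets[[sensors[k]]]
    noise <- if (noise_sd > 0) matrix(stats::rnorm(nr * nc, 0, noise_sd),
                                      nr, nc) else 0
    ndvi_arr[, , k] <- g * base + o + noise
    valid[, , k] <- matrix(stats::runif(nr * nc) >= mask_fraction, nr, nc)
  }
  structure(list(dates = dates, dec_years = dec, sensors = sensors,
                 ndvi = ndvi_arr, valid = valid, ref_year = ref_year),
            class = "ndvi_stack")
}

decimal_year <- function(dates) {
  y <- as.integer(format(dates, "%Y"))
  yd <- as.integer(format(dates, "%j"))
  ndays <- ifelse(y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0), 366, 365)
  y + (yd - 1) / ndays
}

#' @export
print.ndvi_stack <- function(x, ...) {
  d <- dim(x$ndvi)
  cat(sprintf("ndvi_stack: %d x %d pixels, %d observations (%s to %s)\n",
              d[1], d[2], d[3], min(x$dates), max(x$dates)))
  cat("sensors:", paste(sprintf("%s=%d", names(table(x$sensors)),
                                table(x$sensors)), collapse = " "), "\n")
  invisible(x)
}

#' Stratified random reference sites from a mosaic
#'
#' Uniform without-replacement sampling of pixel sites within each stratum
#' of a strata grid, labeled with the mosaic's true landform. Mirrors the
#' stratified design used to validate regional landform maps (e.g. 700 and
#' 300 sites over two ecological landscapes).
#'
#' @param mosaic a `landform_mosaic` (or any object with `labels`,
#'   `pixel_size`, `origin`).
#' @param strata character or integer matrix of stratum membership; default
#'   splits the grid into a west "Arctic Peaty Lowland" and an east "Arctic
#'   Sandy Lowland" half.
#' @param counts named integer vector: sites per stratum.
#' @param seed RNG seed.
#' @return data frame with columns `ecological_landscape`, `landform`,
#'   `latitude`, `longitude`, `row`, `col`.
#' @export
generate_reference_sites <- function(mosaic, strata = NULL,
                                     counts = c(`Arctic Peaty Lowland` = 700,
                                                `Arctic Sandy Lowland` = 300),
                                     seed = 1) {
  labels <- mosaic$labels
  if (is.null(strata)) {
    strata <- matrix(rep(c("Arctic Peaty Lowland", "Arctic Sandy Lowland"),
                         times = c(ceiling(ncol(labels) / 2),
                                   floor(ncol(labels) / 2)))[col(labels)],
                     nrow(labels), ncol(labels))
  }
  restore <- local_seed(seed)
  on.exit(restore())
  out <- list()
  for (s in names(counts)) {
    k <- counts[[s]]
    if (k == 0) next
    cand <- which(strata == s & !is.na(labels))
    if (length(cand) < k)
      stop(sprintf("stratum '%s' has %d pixels, %d requested",
                   s, length(cand), k))
    pick <- sample(cand, k)
    rc <- arrayInd(pick, dim(labels))
    out[[s]] <- data.frame(
      ecological_landscape = s,
      landform = landform_name(labels[pick]),
      latitude = mosaic$origin[2] -
        (rc[, 1] - 1) * mosaic$pixel_size / 110540,
      longitude = mosaic$origin[1] +
        (rc[, 2] - 1) * mosaic$pixel_size /
        (111320 * cos(mosaic$origin[2] * pi / 180)),
      row = rc[, 1], col = rc[, 2],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(ecological_landscape = character(),
                      landform = character(), latitude = numeric(),
                      longitude = numeric(), row = integer(),
                      col = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
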