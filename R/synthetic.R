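#' Synthetic study configuration
#'
#' Parameters of the synthetic landscape, fleet and emission ground truth
#' used to exercise the whole framework offline.  The defaults define the
#' package's reference study conditions: a 48 x 48 cell landscape (500 m
#' cells), a 60-dam fleet, a 38-year weekly hydrology record, and a
#' linear (identity-link) ground-truth emission law with known
#' coefficients so every downstream estimate has a recoverable target.
#'
#' @param seed Root seed; all randomness derives from it.
#' @param grid_size Landscape edge length in cells (>= 16).
#' @param cellsize Cell edge length in metres.
#' @param n_dams Number of dams to place.
#' @param years Length of the hydrology record in years.
#' @param river_threshold Flow accumulation (cells) defining river cells.
#' @param min_spacing Minimum Chebyshev spacing between dams (cells).
#' @param seasonal_amplitude Relative amplitude of the seasonal flow cycle.
#' @param flow_noise_sd Relative sd of weekly flow noise.
#' @param truth_noise_sd Additive sd (gCO2e/m2/yr) of the emission truth.
#' @param efficiency Turbine efficiency for the hydropower formula.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, grid_size = 48L, cellsize = 500,
                         n_dams = 60L, years = 38L, river_threshold = 20L,
                         min_spacing = 2L, seasonal_amplitude = 0.4,
                         flow_noise_sd = 0.15, truth_noise_sd = 40,
                         efficiency = 0.9) {
  if (grid_size < 16L) abort("grid_size must be >= 16", "resghg_bad_argument")
  structure(as.list(environment()), class = "synth_config")
}

# ---- landscape --------------------------------------------------------------

# Priority-flood depression filling from a single outlet cell: guarantees
# that every cell has a monotone descending path to the outlet, i.e. the
# D8 network has exactly one outlet.
priority_flood <- function(z, outlet) {
  nr <- nrow(z); nc <- ncol(z)
  n <- nr * nc
  filled <- rep(NA_real_, n)
  inheap <- logical(n)
  h_idx <- integer(n); h_key <- numeric(n); h_n <- 0L
  push <- function(i, key) {
    h_n <<- h_n + 1L
    h_idx[h_n] <<- i; h_key[h_n] <<- key
    k <- h_n
    while (k > 1L) {
      p <- k %/% 2L
      if (h_key[p] <= h_key[k]) break
      tmp <- h_idx[p]; h_idx[p] <<- h_idx[k]; h_idx[k] <<- tmp
      tmpk <- h_key[p]; h_key[p] <<- h_key[k]; h_key[k] <<- tmpk
      k <- p
    }
  }
  pop <- function() {
    top <- h_idx[1L]
    h_idx[1L] <<- h_idx[h_n]; h_key[1L] <<- h_key[h_n]
    h_n <<- h_n - 1L
    k <- 1L
    repeat {
      l <- 2L * k; r <- l + 1L
      s <- k
      if (l <= h_n && h_key[l] < h_key[s]) s <- l
      if (r <= h_n && h_key[r] < h_key[s]) s <- r
      if (s == k) break
      tmp <- h_idx[s]; h_idx[s] <<- h_idx[k]; h_idx[k] <<- tmp
      tmpk <- h_key[s]; h_key[s] <<- h_key[k]; h_key[k] <<- tmpk
      k <- s
    }
    top
  }
  o <- (outlet[2] - 1L) * nr + outlet[1]
  push(o, z[o]); inheap[o] <- TRUE
  eps <- 1e-3
  while (h_n > 0L) {
    i <- pop()
    r <- ((i - 1L) %% nr) + 1L
    c <- ((i - 1L) %/% nr) + 1L
    if (is.na(filled[i])) filled[i] <- z[i]
    for (k in 1:8) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      j <- (cc - 1L) * nr + rr
      if (inheap[j]) next
      inheap[j] <- TRUE
      filled[j] <- max(z[j], filled[i] + eps)
      push(j, filled[j])
    }
  }
  matrix(filled, nr, nc)
}

#' Generate a synthetic landscape
#'
#' Builds a smoothed random-field elevation model (Gaussian hills over a
#' plane tilted towards a single boundary outlet), hydrologically
#' conditioned by priority-flood filling so the drainage network has one
#' outlet; derives temperature (fixed lapse rate, so it decreases with
#' elevation), runoff (increasing with elevation, higher on the moist
#' half), evapotranspiration, population density (concentrated in the warm
#' lowland), a categorical land-cover grid whose forest probability grows
#' away from the warm lowland, and a climate-zone grid combining elevation
#' terciles with the dry/moist halves into the six zone labels.
#'
#' Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_landscape` with [grid_raster()]s `dem`,
#'   `temperature`, `runoff`, `evapotranspiration`, `population_density`,
#'   `landcover`, `zone_code`; plus `class_map`, `zone_levels` and the
#'   outlet cell.
#' @export
synth_landscape <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$grid_size
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  outlet <- c(n, n %/% 2L)
  dist_out <- sqrt((rows - outlet[1])^2 + (cols - outlet[2])^2)
  z <- 400 * dist_out / max(dist_out)
  for (b in seq_len(6L)) {
    cr <- stats::runif(1, 1, n); cc <- stats::runif(1, 1, n)
    h <- stats::runif(1, 150, 500); s <- stats::runif(1, n / 10, n / 4)
    z <- z + h * exp(-((rows - cr)^2 + (cols - cc)^2) / (2 * s^2))
  }
  z <- z + matrix(stats::rnorm(n * n, 0, 4), n, n)
  z <- z - min(z)
  z[outlet[1], outlet[2]] <- 0
  z <- priority_flood(z, outlet)

  moist <- cols > n / 2
  temperature <- 30 - 0.022 * z + matrix(stats::rnorm(n * n, 0, 0.2), n, n)
  runoff <- pmax(350 + 0.8 * z + 300 * moist +
                   matrix(stats::rnorm(n * n, 0, 25), n, n), 0)
  evapo <- pmax(150 + 16 * temperature +
                  matrix(stats::rnorm(n * n, 0, 15), n, n), 0)
  popden <- pmax(180 * exp(-z / 250) +
                   matrix(stats::rnorm(n * n, 0, 5), n, n), 0)

  q <- stats::quantile(z, c(1 / 3, 2 / 3))
  band <- 1L + (z > q[1]) + (z > q[2])      # 1 low, 2 mid, 3 high
  zone_levels <- climate_zones()
  # (band, moist) -> zone label index; warm/dry lowland vs cold uplands
  zone_lut <- matrix(c(5L, 4L,    # low:  Warm temperate dry | Tropical wet moist
                       3L, 6L,    # mid:  Tropical dry montane | Warm temperate moist
                       1L, 2L),   # high: Cool temperate moist dry | Polar ...
                     nrow = 3L, byrow = TRUE)
  zone_code <- matrix(zone_lut[cbind(as.vector(band),
                                     as.vector(moist) + 1L)], n, n)

  class_map <- c(forest = 1L, cropland = 2L, shrub = 3L, other = 4L,
                 water = 5L)
  p_forest <- pmin(0.85, pmax(0.05, 0.12 + 0.0007 * z + 0.18 * moist))
  p_crop <- pmin(0.7, 0.55 * exp(-z / 250))
  p_shrub <- pmin(0.3, pmax(0, 0.22 - 0.3 * p_crop))
  lc <- matrix(NA_integer_, n, n)
  u <- matrix(stats::runif(n * n), n, n)
  lc[] <- 4L
  lc[u < p_forest + p_crop + p_shrub] <- 3L
  lc[u < p_forest + p_crop] <- 2L
  lc[u < p_forest] <- 1L
  water <- matrix(stats::runif(n * n), n, n) < 0.01
  lc[water] <- 5L

  g <- function(m) grid_raster(m, cellsize = cfg$cellsize)
  structure(list(dem = g(z), temperature = g(temperature),
                 runoff = g(runoff), evapotranspiration = g(evapo),
                 population_density = g(popden),
                 landcover = g(lc), zone_code = g(zone_code),
                 class_map = class_map, zone_levels = zone_levels,
                 outlet = outlet),
            class = "synth_landscape")
}

# ---- fleet ------------------------------------------------------------------

#' Generate a synthetic dam fleet on a landscape
#'
#' Routes the landscape with D8, places dams on river cells (highest
#' accumulation first, subject to a minimum spacing), delineates each
#' dam's catchment and flooded reservoir, computes zonal reservoir and
#' catchment parameters, and derives the dam-as-edge tree network from the
#' drainage paths between dams.  Reservoir types echo the geography:
#' irrigation in the warm dry lowland, hydroelectric upstream, every
#' sixth dam run-of-river.
#'
#' @param cfg A [synth_config()].
#' @param landscape A [synth_landscape()].
#' @return A list of class `synth_fleet`: `reservoirs`, `catchments`
#'   (validated record tables), `sites` (dam cells and heights), `network`
#'   (a [to_tree()] result), `d8`, `accumulation`.
#' @export
synth_fleet <- function(cfg, landscape) {
  set.seed(cfg$seed + 1L)
  d8 <- flow_directions(landscape$dem)
  acc <- flow_accumulation(d8)
  riv <- which(acc >= cfg$river_threshold, arr.ind = TRUE)
  if (!nrow(riv)) abort("no river cells at this threshold", "resghg_no_river")
  ord <- order(-acc[riv])
  chosen <- matrix(integer(0), 0, 2)
  for (i in ord) {
    cell <- riv[i, , drop = FALSE]
    if (nrow(chosen)) {
      cheb <- pmax(abs(chosen[, 1] - cell[1]), abs(chosen[, 2] - cell[2]))
      if (min(cheb) < cfg$min_spacing) next
    }
    chosen <- rbind(chosen, cell)
    if (nrow(chosen) == cfg$n_dams) break
  }
  if (nrow(chosen) < cfg$n_dams) {
    abort(sprintf("river network supports only %d of %d requested dams",
                  nrow(chosen), cfg$n_dams), "resghg_too_many_dams")
  }

  n_dams <- cfg$n_dams
  ids <- sprintf("dam%02d", seq_len(n_dams))
  heights <- stats::runif(n_dams, 25, 70)
  zl <- landscape$zone_levels
  zone_at <- zl[landscape$zone_code$z[chosen]]
  # types: warm-dry lowland -> irrigation; every 6th -> RoR; largest
  # accumulations -> hydroelectric; remainder multipurpose
  types <- character(n_dams)
  types[zone_at == "Warm temperate dry"] <- "irrigation"
  types[seq_len(n_dams) %% 6L == 0L] <- "ror"
  rest <- which(types == "")
  hy <- rest[acc[chosen][rest] >= stats::median(acc[chosen][rest])]
  types[hy] <- "hydroelectric"
  types[types == ""] <- "multipurpose"

  ds <- downstream_index(d8)
  nr <- nrow(d8)
  cell_idx <- (chosen[, 2] - 1L) * nr + chosen[, 1]
  dam_at <- integer(max(ds, na.rm = TRUE) + nr)
  dam_at[cell_idx] <- seq_len(n_dams)

  res_rows <- list(); cat_rows <- list(); down_dam <- integer(n_dams)
  climate <- list(air_temperature = landscape$temperature,
                  runoff = landscape$runoff,
                  evapotranspiration = landscape$evapotranspiration,
                  population_density = landscape$population_density)
  for (i in seq_len(n_dams)) {
    site <- as.integer(chosen[i, ])
    cat_mask <- local_catchment(d8, site)
    if (types[i] == "ror") {
      res_mask <- matrix(FALSE, nrow(d8), ncol(d8))
      res_mask[site[1], site[2]] <- TRUE   # token cell for zonal statistics
      fsl <- landscape$dem$z[site[1], site[2]]
    } else {
      res_mask <- flood_reservoir(landscape$dem, d8, site,
                                  dam_height = heights[i], buffer_height = 2)
      fsl <- attr(res_mask, "fsl")
    }
    zp <- zonal_parameters(res_mask, cat_mask, landscape$dem, fsl,
                           landscape$landcover, landscape$class_map,
                           climate = climate)
    rp <- zp$reservoir; cp <- zp$catchment
    is_ror <- types[i] == "ror"
    outflow_m3yr <- cp[["runoff"]] * 1e-3 * cp[["area"]] * 1e6
    res_rows[[i]] <- data.frame(
      id = ids[i], res_type = types[i], zone = zone_at[i],
      area = if (is_ror) 0 else rp[["area"]],
      mean_depth = if (is_ror) 0 else rp[["mean_depth"]],
      volume = if (is_ror) 0 else rp[["volume"]],
      residence_time = if (is_ror || outflow_m3yr <= 0) 0
                       else rp[["volume"]] * 1e6 / outflow_m3yr,
      frac_forest = if (is_ror) 0 else rp[["frac_forest"]],
      frac_cropland = if (is_ror) 0 else rp[["frac_cropland"]],
      frac_shrub = if (is_ror) 0 else rp[["frac_shrub"]],
      frac_other = if (is_ror) 0 else rp[["frac_other"]],
      generation = NA_real_, catchment_id = ids[i],
      stringsAsFactors = FALSE)
    cat_rows[[i]] <- data.frame(
      id = ids[i], area = cp[["area"]], runoff = cp[["runoff"]],
      evapotranspiration = cp[["evapotranspiration"]],
      air_temperature = cp[["air_temperature"]],
      mean_slope = cp[["mean_slope"]],
      population_density = cp[["population_density"]],
      frac_forest = cp[["frac_forest"]], frac_cropland = cp[["frac_cropland"]],
      frac_shrub = cp[["frac_shrub"]], frac_other = cp[["frac_other"]],
      stringsAsFactors = FALSE)
    # walk downstream to the first dam below, if any
    j <- ds[cell_idx[i]]
    down_dam[i] <- 0L
    while (!is.na(j) && j > 0L) {
      if (j <= length(dam_at) && dam_at[j] > 0L) { down_dam[i] <- dam_at[j]; break }
      j <- ds[j]
    }
  }

  nodes <- data.frame(
    id = c("outlet", ids, paste0("r_", ids)),
    type = c("outlet", rep("dam", n_dams), rep("river", n_dams)),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    from = c(ifelse(down_dam > 0L, paste0("r_", ids[pmax(down_dam, 1L)]),
                    "outlet"), ids),
    to = c(ids, paste0("r_", ids)), stringsAsFactors = FALSE)

  structure(list(
    reservoirs = validate_reservoirs(do.call(rbind, res_rows)),
    catchments = validate_catchments(do.call(rbind, cat_rows)),
    sites = data.frame(id = ids, row = chosen[, 1], col = chosen[, 2],
                       dam_height = heights, type = types,
                       down_dam = ifelse(down_dam > 0L, ids[pmax(down_dam, 1L)],
                                         NA_character_),
                       stringsAsFactors = FALSE),
    network = to_tree(nodes, edges),
    d8 = d8, accumulation = acc),
    class = "synth_fleet")
}

# ---- emission ground truth --------------------------------------------------

# per-zone level shifts injected into the truth law (gCO2e/m2/yr)
SYNTH_ZONE_OFFSETS <- c(
  "Cool temperate moist dry" = 20,
  "Polar moist boreal dry moist" = 0,
  "Tropical dry montane" = 180,
  "Tropical wet moist" = 120,
  "Warm temperate dry" = 250,
  "Warm temperate moist" = 60)

#' Synthetic emission ground truth
#'
#' Attaches a known linear emission law to a fleet: CH4 pathways decrease
#' with mean depth and increase with air temperature and catchment area;
#' diffusive CO2 increases with the impounded forest fraction and air
#' temperature; a per-zone level shift (recorded in the manifest) gives
#' emission-factor calibration a recoverable target.  Pathway fluxes are
#' the law's predictions plus Gaussian noise (sd
#' `cfg$truth_noise_sd`), truncated at zero.  The law is returned as an
#' [empirical_model_config()], so with zero noise the model reproduces the
#' generated fluxes exactly.
#'
#' @param cfg A [synth_config()].
#' @param fleet A [synth_fleet()] (or a list with `reservoirs` and
#'   `catchments` tables).
#' @return A list of class `synth_truth`: `fluxes` (per-reservoir pathway
#'   fluxes), `config` (the generating [empirical_model_config()]),
#'   `reservoirs` (records extended with the numeric `zone_offset`
#'   feature), `manifest` (all generating parameters).
#' @export
synth_emission_truth <- function(cfg, fleet) {
  res <- as.data.frame(fleet$reservoirs)
  cat <- as.data.frame(fleet$catchments)
  res$zone_offset <- unname(SYNTH_ZONE_OFFSETS[res$zone])

  paths <- list(
    co2_diffusive = list(
      features = c("frac_forest", "cat.air_temperature", "zone_offset"),
      coef = c(900, 12, 0.3), intercept = 120, link = "identity"),
    ch4_diffusive = list(
      features = c("mean_depth", "cat.air_temperature", "cat.area",
                   "zone_offset"),
      coef = c(-9, 8, 0.02, 1), intercept = 180, link = "identity"),
    ch4_ebullition = list(
      features = c("mean_depth", "cat.air_temperature", "zone_offset"),
      coef = c(-12, 10, 1), intercept = 200, link = "identity"),
    ch4_degassing = list(
      features = c("mean_depth", "cat.air_temperature", "cat.area",
                   "zone_offset"),
      coef = c(-4, 4, 0.03, 0.5), intercept = 80, link = "identity"))
  config <- empirical_model_config(paths, gwp_ch4 = 1, uas_fraction = 0.05)

  set.seed(cfg$seed + 2L)
  pw <- emission_pathways()
  flx <- matrix(NA_real_, nrow(res), length(pw),
                dimnames = list(res$id, pw))
  for (i in seq_len(nrow(res))) {
    prof <- suppressWarnings(
      predict_empirical_profile(res[i, ], cat[match(res$catchment_id[i],
                                                    cat$id), ], config))
    flx[i, ] <- prof$fluxes
  }
  if (cfg$truth_noise_sd > 0) {
    flx <- pmax(flx + matrix(stats::rnorm(length(flx), 0,
                                          cfg$truth_noise_sd),
                             nrow(flx)), 0)
  }
  fluxes <- data.frame(id = res$id, zone = res$zone,
                       res_type = res$res_type, flx,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(fluxes = fluxes, config = config, reservoirs = res,
                 manifest = list(zone_offsets = SYNTH_ZONE_OFFSETS,
                                 pathways = paths,
                                 noise_sd = cfg$truth_noise_sd,
                                 seed = cfg$seed)),
            class = "synth_truth")
}

#' Direct calibration-sample generator
#'
#' Draws per-reservoir pathway fluxes as injected zone means plus Gaussian
#' noise, without the raster pipeline: the minimal data-generating process
#' under which zone-indicator regression provably targets the injected
#' means.  Used for calibration-recovery and bootstrap-coverage studies.
#'
#' @param n Number of reservoirs.
#' @param zone_means Matrix of injected means (rows = zones via rownames,
#'   columns = the four pathways).  Defaults to three zones with
#'   magnitudes typical of a warm-climate fleet.
#' @param sd Noise standard deviation (gCO2e/m2/yr).
#' @param seed Integer seed.
#' @param p_irrigation Proportion of irrigation reservoirs.
#' @return A calibration sample table (see [fit_zone_efs()]) with
#'   attribute `zone_means`.
#' @export
synth_calibration_samples <- function(n = 300L, zone_means = NULL, sd = 80,
                                      seed = 1L, p_irrigation = 0.4) {
  if (is.null(zone_means)) {
    zone_means <- matrix(c(860, 390, 500, 1340,
                           610, 285, 305, 1065,
                           430, 145, 105, 500),
                         nrow = 3L, byrow = TRUE,
                         dimnames = list(c("Tropical dry montane",
                                           "Tropical wet moist",
                                           "Warm temperate dry"),
                                         emission_pathways()))
  }
  set.seed(as.integer(seed))
  zones <- sample(rownames(zone_means), n, replace = TRUE)
  types <- sample(c("irrigation", "hydroelectric", "multipurpose"), n,
                  replace = TRUE,
                  prob = c(p_irrigation, (1 - p_irrigation) / 2,
                           (1 - p_irrigation) / 2))
  flx <- zone_means[zones, , drop = FALSE] +
    matrix(stats::rnorm(n * ncol(zone_means), 0, sd), n)
  flx <- pmax(flx, 0)
  out <- data.frame(id = sprintf("res%04d", seq_len(n)), zone = zones,
                    res_type = types, flx, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[4:7] <- emission_pathways()
  attr(out, "zone_means") <- zone_means
  out
}

#' Direct feature-table generator for surrogate studies
#'
#' Draws reservoir/catchment feature vectors from realistic marginals and
#' computes net areal CO2 and CH4 targets from a smooth known law (CH4
#' decreasing in mean depth, CO2 increasing in impounded forest fraction,
#' both increasing in temperature) plus Gaussian noise.  Bypasses the
#' raster pipeline so large training sets are cheap.
#'
#' @param n Number of reservoirs.
#' @param seed Integer seed.
#' @param noise_sd Additive noise sd (gCO2e/m2/yr).
#' @return A list: `x` (feature matrix), `y_co2`, `y_ch4`, `truth`
#'   (the coefficient lists).
#' @export
synth_surrogate_data <- function(n = 500L, seed = 1L, noise_sd = 30) {
  set.seed(as.integer(seed))
  x <- cbind(
    mean_depth = stats::runif(n, 2, 30),
    air_temperature = stats::runif(n, 10, 30),
    frac_forest = stats::runif(n, 0, 0.9),
    catchment_area = exp(stats::rnorm(n, 5, 0.8)),
    runoff = stats::runif(n, 300, 1500),
    volume = NA_real_)
  x[, "volume"] <- x[, "mean_depth"]^1.5 * exp(stats::rnorm(n, 2, 0.4))
  truth <- list(
    co2 = list(intercept = 120, coef = c(frac_forest = 900,
                                         air_temperature = 12,
                                         runoff = -0.08)),
    ch4 = list(intercept = 450, coef = c(mean_depth = -18,
                                         air_temperature = 10,
                                         catchment_area = 0.35)))
  lin <- function(tr) {
    tr$intercept + as.numeric(x[, names(tr$coef), drop = FALSE] %*% tr$coef)
  }
  y_co2 <- lin(truth$co2) + stats::rnorm(n, 0, noise_sd)
  y_ch4 <- lin(truth$ch4) + stats::rnorm(n, 0, noise_sd)
  list(x = x, y_co2 = y_co2, y_ch4 = y_ch4, truth = truth)
}

# ---- hydrology and generation ----------------------------------------------

#' Hydropower energy of one timestep
#'
#' The hydropower formula `P = rho g eta Q H`, integrated over a timestep.
#'
#' @param q_m3s Flow in m3/s.
#' @param head_m Hydraulic head in m.
#' @param efficiency Turbine efficiency.
#' @param hours Timestep length in hours (168 for weekly).
#' @return Energy in GWh per timestep.
#' @export
hydropower_energy <- function(q_m3s, head_m, efficiency = 0.9, hours = 168) {
  1000 * 9.81 * efficiency * q_m3s * head_m * hours * 3600 / 3.6e12
}

#' Generate weekly energy series for a fleet
#'
#' Weekly flows follow a seasonal sinusoid with multiplicative noise around
#' the catchment water yield; heads derive from a power-law volume-depth
#' bathymetry (head proportional to mean depth for reservoir assets, a
#' small fixed head for run-of-river).  Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @param fleet A [synth_fleet()].
#' @return A list of class `synth_generation`: `series` (weeks x assets
#'   matrix, GWh/week), `annual` (named GWh/yr means), `weeks`.
#' @export
synth_generation <- function(cfg, fleet) {
  set.seed(cfg$seed + 3L)
  res <- as.data.frame(fleet$reservoirs)
  cat <- as.data.frame(fleet$catchments)
  wpy <- 365.25 / 7
  weeks <- round(cfg$years * wpy)
  t <- seq_len(weeks)
  seas <- 1 + cfg$seasonal_amplitude * sin(2 * pi * t / wpy)
  series <- matrix(0, weeks, nrow(res), dimnames = list(NULL, res$id))
  for (i in seq_len(nrow(res))) {
    ci <- match(res$catchment_id[i], cat$id)
    q_base <- cat$runoff[ci] * 1e-3 * cat$area[ci] * 1e6 / (365.25 * 86400)
    q <- pmax(0, q_base * seas * (1 + stats::rnorm(weeks, 0,
                                                   cfg$flow_noise_sd)))
    head <- if (res$res_type[i] == "ror") 5 else 1.5 * res$mean_depth[i]
    series[, i] <- hydropower_energy(q, head, cfg$efficiency)
  }
  annual <- colMeans(series) * wpy
  structure(list(series = series, annual = annual, weeks = weeks),
            class = "synth_generation")
}
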