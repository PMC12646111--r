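#' D8 flow directions
#'
#' Steepest-descent D8 routing: each cell drains to the neighbour with the
#' greatest distance-weighted drop.  Ties and flats are resolved by the
#' deterministic neighbour order N, NE, E, SE, S, SW, W, NW (first neighbour
#' with the maximal positive drop wins).  Cells with no lower neighbour are
#' outlets/pits (code 0); nodata cells are `NA`.
#'
#' @param dem A [grid_raster()] of elevations (m).
#' @return An integer matrix of direction codes 0-8 (class `d8_grid`), with
#'   the DEM dimensions.
#' @export
flow_directions <- function(dem) {
  stopifnot(inherits(dem, "grid_raster"))
  z <- dem$z
  if (all(is.na(z))) abort("all cells are nodata", "resghg_all_masked")
  nr <- nrow(z); nc <- ncol(z)
  d8 <- matrix(NA_integer_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (is.na(z[r, c])) next
      best <- 0L; best_slope <- 0
      for (k in 1:8) {
        rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc || is.na(z[rr, cc])) next
        slope <- (z[r, c] - z[rr, cc]) / D8_DIST[k]
        if (slope > best_slope + 1e-12) {
          best <- k; best_slope <- slope
        }
      }
      d8[r, c] <- best
    }
  }
  class(d8) <- c("d8_grid", class(d8))
  d8
}

# Linear index (column-major) of the downstream cell for every cell;
# 0 = outlet/pit, NA = nodata.
downstream_index <- function(d8) {
  nr <- nrow(d8); nc <- ncol(d8)
  idx <- seq_len(nr * nc)
  r <- ((idx - 1L) %% nr) + 1L
  c <- ((idx - 1L) %/% nr) + 1L
  code <- as.integer(d8)
  ds <- integer(nr * nc)
  ds[is.na(code)] <- NA_integer_
  pos <- which(!is.na(code) & code > 0L)
  rr <- r[pos] + D8_DR[code[pos]]
  cc <- c[pos] + D8_DC[code[pos]]
  ds[pos] <- (cc - 1L) * nr + rr
  ds
}

#' D8 flow accumulation
#'
#' Number of cells draining through each cell, including the cell itself.
#' Computed by topological (Kahn) traversal of the D8 graph.
#'
#' @param d8 A D8 direction grid from [flow_directions()].
#' @return An integer matrix of upstream cell counts (`NA` for nodata).
#' @export
flow_accumulation <- function(d8) {
  nr <- nrow(d8); nc <- ncol(d8)
  ds <- downstream_index(d8)
  n <- nr * nc
  acc <- rep(1L, n)
  acc[is.na(ds)] <- NA_integer_
  indeg <- integer(n)
  tgt <- ds[!is.na(ds) & ds > 0L]
  if (length(tgt)) {
    tab <- tabulate(tgt, nbins = n)
    indeg <- tab
  }
  queue <- which(!is.na(ds) & indeg == 0L)
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    d <- ds[i]
    if (!is.na(d) && d > 0L) {
      acc[d] <- acc[d] + acc[i]
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  matrix(acc, nr, nc)
}

#' Snap a dam site to the river network
#'
#' River cells are cells whose flow accumulation meets a threshold.  The
#' site is moved to the river cell with the smallest Euclidean distance;
#' ties are broken by higher accumulation, then row-major order.
#'
#' @param site Integer vector `c(row, col)`.
#' @param accumulation Matrix from [flow_accumulation()].
#' @param threshold Minimum accumulation (cells) defining the river network.
#' @return Integer `c(row, col)` of the snapped cell.
#' @export
snap_dam <- function(site, accumulation, threshold) {
  riv <- which(!is.na(accumulation) & accumulation >= threshold,
               arr.ind = TRUE)
  if (nrow(riv) == 0L) {
    abort("no river cells at this accumulation threshold", "resghg_no_river")
  }
  d2 <- (riv[, 1] - site[1])^2 + (riv[, 2] - site[2])^2
  acc <- accumulation[riv]
  # row-major order key for the final deterministic tie-break
  rowmajor <- (riv[, 1] - 1) * ncol(accumulation) + riv[, 2]
  o <- order(d2, -acc, rowmajor)
  as.integer(riv[o[1], ])
}

#' Local catchment of a point
#'
#' All cells whose D8 flow path reaches the point (including the point):
#' a reverse breadth-first traversal of the D8 drainage graph.
#'
#' @param d8 A D8 direction grid.
#' @param point Integer `c(row, col)`.
#' @return A logical matrix mask.
#' @export
local_catchment <- function(d8, point) {
  nr <- nrow(d8); nc <- ncol(d8)
  ds <- downstream_index(d8)
  target <- (point[2] - 1L) * nr + point[1]
  # children lists: cells draining directly into each cell
  valid <- which(!is.na(ds) & ds > 0L)
  kids <- split(valid, ds[valid])
  seen <- logical(nr * nc)
  seen[target] <- TRUE
  frontier <- target
  while (length(frontier)) {
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  matrix(seen, nr, nc)
}

# 4-connected component of `candidates` containing (or touching) the seed.
connected_component4 <- function(candidates, seed, include_adjacent = FALSE) {
  nr <- nrow(candidates); nc <- ncol(candidates)
  idx <- function(r, c) (c - 1L) * nr + r
  cand <- as.logical(candidates)
  seen <- logical(nr * nc)
  start <- idx(seed[1], seed[2])
  frontier <- integer(0)
  if (cand[start]) {
    frontier <- start
  } else if (include_adjacent) {
    for (k in c(1L, 3L, 5L, 7L)) {  # N, E, S, W
      rr <- seed[1] + D8_DR[k]; cc <- seed[2] + D8_DC[k]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && cand[idx(rr, cc)]) {
        frontier <- c(frontier, idx(rr, cc))
      }
    }
  }
  seen[frontier] <- TRUE
  while (length(frontier)) {
    r <- ((frontier - 1L) %% nr) + 1L
    c <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (k in c(1L, 3L, 5L, 7L)) {
      rr <- r + D8_DR[k]; cc <- c + D8_DC[k]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      cand_i <- idx(pmin(pmax(rr, 1L), nr), pmin(pmax(cc, 1L), nc))
      keep <- ok & cand[cand_i] & !seen[cand_i]
      nxt <- c(nxt, cand_i[keep])
    }
    nxt <- unique(nxt)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  matrix(seen, nr, nc)
}

#' Flood a planned reservoir to full supply level
#'
#' The full supply level (FSL) defaults to the elevation at the dam base
#' plus the dam height minus the buffer (freeboard) height.  The reservoir
#' mask is the set of cells at or below the FSL that are 4-connected to the
#' dam cell and lie inside the dam's catchment (so nothing downstream of
#' the dam floods).  Flooding is monotone in FSL.
#'
#' @param dem A [grid_raster()] of elevations.
#' @param d8 Matching D8 direction grid.
#' @param site Snapped dam cell, `c(row, col)`.
#' @param fsl Full supply level (masl); overrides the height rule if given.
#' @param dam_height,buffer_height Dam and freeboard heights (m), used when
#'   `fsl` is absent (`dam_height > buffer_height >= 0`).
#' @return A logical reservoir mask with attribute `fsl`.  An FSL below the
#'   base elevation yields an empty mask and a `resghg_empty_reservoir`
#'   warning.
#' @export
flood_reservoir <- function(dem, d8, site, fsl = NULL, dam_height = NULL,
                            buffer_height = 0) {
  z <- dem$z
  base <- z[site[1], site[2]]
  if (is.null(fsl)) {
    stopifnot_number(dam_height, "dam_height", min = 0)
    stopifnot_number(buffer_height, "buffer_height", min = 0, max = dam_height)
    fsl <- base + dam_height - buffer_height
  }
  if (fsl < base) {
    warn(sprintf("FSL %.2f below dam-base elevation %.2f: empty reservoir",
                 fsl, base), "resghg_empty_reservoir")
    mask <- matrix(FALSE, nrow(z), ncol(z))
    attr(mask, "fsl") <- fsl
    return(mask)
  }
  catch <- local_catchment(d8, site)
  cand <- !is.na(z) & z <= fsl & catch
  mask <- connected_component4(cand, site)
  attr(mask, "fsl") <- fsl
  mask
}

#' Extract an existing reservoir from a land-cover grid
#'
#' Existing water bodies are delineated from land cover, not from the DEM
#' (global DEMs flatten standing water): the 4-connected component of
#' water-class cells containing the dam cell (or touching it on an edge),
#' intersected with the dam's catchment so only the upstream water body is
#' kept.
#'
#' @param landcover A [grid_raster()] of integer land-cover codes.
#' @param d8 Matching D8 direction grid.
#' @param site Snapped dam cell, `c(row, col)`.
#' @param water_class Land-cover code of the water class.
#' @return A logical reservoir mask.
#' @section Errors: `resghg_no_water_at_dam` when no water cell touches the
#'   dam.
#' @export
existing_reservoir <- function(landcover, d8, site, water_class) {
  water <- !is.na(landcover$z) & landcover$z == water_class
  comp <- connected_component4(water, site, include_adjacent = TRUE)
  if (!any(comp)) {
    abort("no water-class cell at or adjacent to the dam site",
          "resghg_no_water_at_dam")
  }
  comp & local_catchment(d8, site)
}

#' Zonal reservoir and catchment parameters
#'
#' Computes the per-site feature vectors from delineation masks and
#' co-registered rasters with naive zonal statistics: area from cell
#' counts, land-cover fractions as class shares inside the mask, means for
#' temperature/runoff/slope, mean depth and volume from `FSL - elevation`
#' over the reservoir mask.  The catchment statistics exclude the
#' reservoir cells (catchment-minus-reservoir) when
#' `exclude_reservoir = TRUE`.
#'
#' @param res_mask,cat_mask Logical masks from the delineation steps.
#' @param dem Elevation [grid_raster()] (cellsize taken from here).
#' @param fsl Full supply level used for depth/volume.
#' @param landcover Land-cover [grid_raster()] with integer codes.
#' @param class_map Named integer vector mapping `forest`, `cropland`,
#'   `shrub`, `other` (and optionally `water`) to land-cover codes.
#' @param climate Named list of numeric rasters averaged over the
#'   catchment: `temperature`, `runoff`, `evapotranspiration`,
#'   `population_density` (any subset).
#' @param exclude_reservoir Exclude reservoir cells from catchment stats.
#' @return A list with elements `reservoir` and `catchment`: named numeric
#'   parameter vectors.
#' @export
zonal_parameters <- function(res_mask, cat_mask, dem, fsl, landcover,
                             class_map, climate = list(),
                             exclude_reservoir = TRUE) {
  if (!any(res_mask)) abort("empty reservoir mask", "resghg_empty_mask")
  if (!any(cat_mask)) abort("empty catchment mask", "resghg_empty_mask")
  cs <- dem$cellsize
  cell_km2 <- cs^2 / 1e6
  z <- dem$z
  depth <- fsl - z[res_mask]
  depth[depth < 0] <- 0
  lc <- landcover$z
  cmask <- cat_mask
  if (exclude_reservoir) cmask <- cat_mask & !res_mask
  if (!any(cmask)) cmask <- cat_mask

  frac_of <- function(mask) {
    cells <- lc[mask]
    out <- vapply(c("forest", "cropland", "shrub"), function(cl) {
      if (cl %in% names(class_map)) mean(cells == class_map[[cl]]) else 0
    }, numeric(1))
    c(out, other = 1 - sum(out))
  }

  res_frac <- frac_of(res_mask)
  cat_frac <- frac_of(cmask)

  slope <- mean_slope_pct(dem, cmask)

  reservoir <- c(
    area = sum(res_mask) * cell_km2,
    mean_depth = mean(depth),
    volume = sum(depth) * cs^2 / 1e6,      # Mm3
    frac_forest = unname(res_frac["forest"]),
    frac_cropland = unname(res_frac["cropland"]),
    frac_shrub = unname(res_frac["shrub"]),
    frac_other = unname(res_frac["other"]),
    fsl = fsl
  )
  catchment <- c(
    area = sum(cat_mask) * cell_km2,
    mean_slope = slope,
    frac_forest = unname(cat_frac["forest"]),
    frac_cropland = unname(cat_frac["cropland"]),
    frac_shrub = unname(cat_frac["shrub"]),
    frac_other = unname(cat_frac["other"])
  )
  for (nm in names(climate)) {
    catchment[[nm]] <- mean(climate[[nm]]$z[cmask], na.rm = TRUE)
  }
  list(reservoir = reservoir, catchment = catchment)
}

# Mean absolute slope (%) from central differences inside a mask.
mean_slope_pct <- function(dem, mask) {
  z <- dem$z; cs <- dem$cellsize
  nr <- nrow(z); nc <- ncol(z)
  zx <- matrix(0, nr, nc); zy <- matrix(0, nr, nc)
  if (nc >= 3) zx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * cs)
  if (nr >= 3) zy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * cs)
  s <- sqrt(zx^2 + zy^2) * 100
  mean(s[mask], na.rm = TRUE)
}
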