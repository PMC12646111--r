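test_that("a monotone ramp drains west with cumulative accumulation", {
  z <- matrix(rep(1:6, each = 4), nrow = 4)   # increases eastwards
  d8 <- flow_directions(grid_raster(z))
  expect_true(all(d8[, 2:6] == 7L))           # all interior cells point W
  expect_true(all(d8[, 1] == 0L))             # west edge cells are outlets
  acc <- flow_accumulation(d8)
  for (r in 1:4) expect_equal(acc[r, ], rev(1:6))
})

test_that("a single-cell grid accumulates itself", {
  d8 <- flow_directions(grid_raster(matrix(5)))
  expect_equal(as.integer(d8), 0L)
  expect_equal(as.integer(flow_accumulation(d8)), 1L)
  expect_error(flow_directions(grid_raster(matrix(NA_real_))),
               class = "resghg_all_masked")
})

test_that("flow accumulation matches the path-walking oracle", {
  for (seed in 1:25) {
    nr <- sample(8:20, 1); nc <- sample(8:20, 1)
    dem <- random_dem(nr, nc, seed)
    d8 <- flow_directions(dem)
    expect_equal(flow_accumulation(d8), oracle_accumulation(d8),
                 info = sprintf("seed %d", seed))
  }
})

test_that("dam snapping picks the nearest river cell with documented ties", {
  acc <- matrix(1L, 5, 5)
  acc[3, 2] <- 50L; acc[3, 4] <- 80L
  # already on a river cell: stays put
  expect_equal(snap_dam(c(3, 2), acc, threshold = 10), c(3L, 2L))
  # equidistant cells: the higher accumulation wins
  expect_equal(snap_dam(c(3, 3), acc, threshold = 10), c(3L, 4L))
  # exhaustive check: no river cell is closer than the returned one
  set.seed(4)
  for (i in 1:20) {
    acc2 <- matrix(sample(1:100, 100, TRUE), 10, 10)
    site <- c(sample(10, 1), sample(10, 1))
    s <- snap_dam(site, acc2, threshold = 60)
    riv <- which(acc2 >= 60, arr.ind = TRUE)
    d_res <- sum((s - site)^2)
    expect_true(all(d_res <= (riv[, 1] - site[1])^2 + (riv[, 2] - site[2])^2))
  }
  expect_error(snap_dam(c(1, 1), matrix(1, 3, 3), threshold = 10),
               class = "resghg_no_river")
})

test_that("local catchments equal the reverse-traversal oracle", {
  z <- matrix(rep(1:6, each = 4), nrow = 4)
  d8 <- flow_directions(grid_raster(z))
  # outlet of one ramp row drains that entire row
  expect_equal(sum(local_catchment(d8, c(2, 1))), 6)
  for (seed in 26:45) {
    dem <- random_dem(12, 12, seed)
    d8 <- flow_directions(dem)
    pt <- c(sample(12, 1), sample(12, 1))
    expect_equal(local_catchment(d8, pt), oracle_catchment(d8, pt),
                 info = sprintf("seed %d", seed))
  }
  # headwater cell: singleton catchment
  dem <- random_dem(10, 10, 99)
  d8 <- flow_directions(dem)
  acc <- flow_accumulation(d8)
  hw <- which(acc == 1L, arr.ind = TRUE)[1, ]
  expect_equal(sum(local_catchment(d8, as.integer(hw))), 1)
})

test_that("flooding fills the valley up to the supply level, upstream only", {
  # flat valley floor at 100 bounded by ridges at 200
  z <- matrix(200, 7, 7); z[4, ] <- 100 + 0.01 * (7:1)
  dem <- grid_raster(z)
  d8 <- flow_directions(dem)
  site <- c(4L, 7L)                            # valley outlet on the east
  mask <- flood_reservoir(dem, d8, site, fsl = 101)
  expect_true(all(mask[4, ]))
  expect_equal(sum(mask), 7)
  # FSL below the base: empty mask with a warning
  expect_warning(m0 <- flood_reservoir(dem, d8, site, fsl = 50),
                 class = "resghg_empty_reservoir")
  expect_equal(sum(m0), 0)
})

test_that("flooding is monotone in the supply level and stays in-catchment", {
  for (seed in 46:60) {
    dem <- random_dem(15, 15, seed)
    d8 <- flow_directions(dem)
    acc <- flow_accumulation(d8)
    site <- as.integer(which(acc == max(acc), arr.ind = TRUE)[1, ])
    base <- dem$z[site[1], site[2]]
    catch <- local_catchment(d8, site)
    prev <- NULL
    for (fsl in base + c(2, 5, 10)) {
      mask <- flood_reservoir(dem, d8, site, fsl = fsl)
      expect_true(all(!mask | catch))   # reservoir stays inside the catchment
      # oracle: 4-connected flood fill over eligible cells
      expect_equal(mask, oracle_flood_fill(dem$z <= fsl & catch, site),
                   ignore_attr = TRUE)
      if (!is.null(prev)) expect_true(all(prev <= mask))
      prev <- mask
    }
  }
})

test_that("existing reservoirs come from the upstream water component", {
  z <- matrix(rep(6:1, each = 5), nrow = 5)    # drains east
  dem <- grid_raster(z)
  d8 <- flow_directions(dem)
  lc <- matrix(1L, 5, 6)
  lc[3, 2:3] <- 5L                             # upstream blob (west = high)
  lc[3, 5:6] <- 5L                             # disjoint blob downstream
  site <- c(3L, 4L)                            # adjacent to the upstream blob
  mask <- existing_reservoir(grid_raster(lc), d8, site, water_class = 5L)
  expect_true(mask[3, 2] && mask[3, 3])
  expect_equal(sum(mask), 2)                   # downstream blob excluded
  expect_error(existing_reservoir(grid_raster(matrix(1L, 5, 6)), d8, site,
                                  water_class = 5L),
               class = "resghg_no_water_at_dam")
})

test_that("zonal statistics match naive per-cell loops", {
  set.seed(77)
  for (i in 1:10) {
    dem <- random_dem(12, 12, 200 + i)
    lc <- grid_raster(matrix(sample(1:4, 144, TRUE), 12, 12))
    tmp <- grid_raster(matrix(runif(144, 5, 30), 12, 12))
    d8 <- flow_directions(dem)
    acc <- flow_accumulation(d8)
    site <- as.integer(which(acc == max(acc), arr.ind = TRUE)[1, ])
    cat_mask <- local_catchment(d8, site)
    fsl <- dem$z[site[1], site[2]] + 8
    res_mask <- flood_reservoir(dem, d8, site, fsl = fsl)
    if (sum(res_mask) < 1 || sum(cat_mask & !res_mask) < 1) next
    zp <- zonal_parameters(res_mask, cat_mask, dem, fsl, lc,
                           c(forest = 1L, cropland = 2L, shrub = 3L,
                             other = 4L),
                           climate = list(air_temperature = tmp))
    cells <- which(res_mask)
    expect_equal(zp$reservoir[["area"]], length(cells) * 1 / 1e6)
    depths <- pmax(fsl - dem$z[cells], 0)
    expect_equal(zp$reservoir[["mean_depth"]], mean(depths))
    expect_equal(zp$reservoir[["volume"]], sum(depths) * 1 / 1e6)
    expect_equal(zp$reservoir[["frac_forest"]], mean(lc$z[cells] == 1L))
    cmask <- cat_mask & !res_mask
    expect_equal(zp$catchment[["air_temperature"]], mean(tmp$z[cmask]))
    expect_equal(sum(zp$reservoir[c("frac_forest", "frac_cropland",
                                    "frac_shrub", "frac_other")]), 1)
  }
  expect_error(zonal_parameters(matrix(FALSE, 2, 2), matrix(TRUE, 2, 2),
                                random_dem(2, 2, 1), 10,
                                grid_raster(matrix(1L, 2, 2)),
                                c(forest = 1L)),
               class = "resghg_empty_mask")
})

test_that("10 cells of a 100 m grid cover a tenth of a square kilometre", {
  z <- matrix(0, 5, 5)
  dem <- grid_raster(z + col(z), cellsize = 100)
  d8 <- flow_directions(dem)
  mask <- matrix(FALSE, 5, 5); mask[1:2, 1:5] <- TRUE
  zp <- zonal_parameters(mask, matrix(TRUE, 5, 5), dem, fsl = 10,
                         grid_raster(matrix(1L, 5, 5)), c(forest = 1L))
  expect_equal(zp$reservoir[["area"]], 10 * 100^2 / 1e6)
})

test_that("ascii grids round-trip and reject malformed headers", {
  g <- grid_raster(matrix(c(1.5, 2, NA, 4, 5, 6), 2, 3), cellsize = 30,
                   xll = 100, yll = 200)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  back <- read_ascii_grid(path)
  expect_equal(back$z, g$z)
  expect_equal(back$cellsize, 30)
  expect_equal(back$xll, 100)
  bad <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "1 2"), bad)
  expect_error(read_ascii_grid(bad), class = "resghg_schema_error")
})

test_that("resampling coarsens and refines by integer factors", {
  g <- grid_raster(matrix(1:16, 4, 4), cellsize = 10)
  co <- resample_grid(g, 2, "coarsen")
  expect_equal(dim(co$z), c(2L, 2L))
  expect_equal(co$cellsize, 20)
  re <- resample_grid(co, 2, "refine")
  expect_equal(dim(re$z), c(4L, 4L))
  expect_equal(re$cellsize, 10)
  expect_equal(re$z[1, 1], co$z[1, 1])
})
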