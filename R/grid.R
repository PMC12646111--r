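#' Gridded rasters
#'
#' A minimal single-band raster: a numeric matrix (row 1 = northernmost
#' row), a square cell size in metres and a lower-left corner.  `NA` cells
#' are nodata.  Grid coordinates throughout the package are (row, col),
#' 1-based, cell-centre registered.
#'
#' @param z Numeric matrix of cell values.
#' @param cellsize Cell edge length in metres.
#' @param xll,yll Coordinates of the lower-left corner.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(z, cellsize = 1, xll = 0, yll = 0) {
  if (!is.matrix(z)) abort("z must be a matrix", "resghg_bad_argument")
  stopifnot_number(cellsize, "cellsize", min = .Machine$double.xmin)
  structure(list(z = z, cellsize = cellsize, xll = xll, yll = yll),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("grid_raster: %d x %d cells, cellsize %g m, %d nodata\n",
              nrow(x$z), ncol(x$z), x$cellsize, sum(is.na(x$z))))
  invisible(x)
}

#' Read / write ESRI ASCII grids
#'
#' Single-band ESRI ASCII grid (`.asc`) files: a six-line header
#' (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`) followed by rows north to south.
#'
#' @param path File path.
#' @param x A [grid_raster()].
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `read_ascii_grid()` returns a [grid_raster()];
#'   `write_ascii_grid()` returns `path` invisibly.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    kv <- strsplit(squish(lines[i]), " ")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    abort(sprintf("%s: malformed ASCII grid header (missing %s)", path,
                  paste(miss, collapse = ", ")), "resghg_schema_error")
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    abort(sprintf("%s: expected %d cells, found %d", path,
                  hdr$ncols * hdr$nrows, length(vals)), "resghg_schema_error")
  }
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) z[z == hdr$nodata_value] <- NA_real_
  grid_raster(z, cellsize = hdr$cellsize, xll = hdr$xllcorner,
              yll = hdr$yllcorner)
}

#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(x, path, nodata = -9999) {
  stopifnot(inherits(x, "grid_raster"))
  z <- x$z
  z[is.na(z)] <- nodata
  hdr <- c(sprintf("ncols %d", ncol(z)),
           sprintf("nrows %d", nrow(z)),
           sprintf("xllcorner %.10g", x$xll),
           sprintf("yllcorner %.10g", x$yll),
           sprintf("cellsize %.10g", x$cellsize),
           sprintf("NODATA_value %g", nodata))
  body <- apply(z, 1L, function(r) paste(format(r, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a grid by an integer factor
#'
#' Nearest-neighbour coarsening (block top-left sample) or refinement
#' (block replication), emulating resolution mixing between coarse
#' catchment-scale and fine reservoir-scale analyses.
#'
#' @param x A [grid_raster()].
#' @param factor Positive integer factor.
#' @param mode `"coarsen"` or `"refine"`.
#' @return A resampled [grid_raster()].
#' @export
resample_grid <- function(x, factor, mode = c("coarsen", "refine")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "grid_raster"))
  f <- as.integer(factor)
  if (f < 1L) abort("factor must be >= 1", "resghg_bad_argument")
  z <- x$z
  if (mode == "coarsen") {
    ri <- seq(1L, nrow(z), by = f); ci <- seq(1L, ncol(z), by = f)
    grid_raster(z[ri, ci, drop = FALSE], cellsize = x$cellsize * f,
                xll = x$xll, yll = x$yll)
  } else {
    grid_raster(z[rep(seq_len(nrow(z)), each = f),
                  rep(seq_len(ncol(z)), each = f), drop = FALSE],
                cellsize = x$cellsize / f, xll = x$xll, yll = x$yll)
  }
}

# D8 neighbour offsets in the deterministic tie-break order N, NE, E, SE,
# S, SW, W, NW.  Code 0 marks an outlet/pit (no downslope neighbour).
D8_DR <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
D8_DC <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DIST <- sqrt(D8_DR^2 + D8_DC^2)
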