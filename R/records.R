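#' Reservoir and catchment records
#'
#' Per-site feature tables driving every emission prediction.  A reservoir
#' record describes the impounded water body (morphometry, impounded
#' land-cover fractions, climate zone, optional annual generation); a
#' catchment record describes the drainage area feeding it.
#'
#' Land-cover fraction columns are `frac_forest`, `frac_cropland`,
#' `frac_shrub`, `frac_other`; each lies in \[0, 1\] and the four sum to 1.
#' Run-of-river (`ror`) assets have `area = 0` and no impounded land.
#'
#' @param df A data frame with one row per site.
#' @return The validated data frame (invisibly the same object), with a
#'   class tag `reservoir_records` / `catchment_records`.
#' @name records
NULL

FRACTION_COLS <- c("frac_forest", "frac_cropland", "frac_shrub", "frac_other")

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s table: missing column(s): %s", what,
                  paste(miss, collapse = ", ")), "resghg_schema_error")
  }
}

row_fail <- function(what, rows, msg) {
  abort(sprintf("%s table, row(s) %s: %s", what,
                paste(utils::head(rows, 5L), collapse = ", "), msg),
        "resghg_schema_error", rows = rows)
}

check_fractions <- function(df, what, tol = 1e-9) {
  fr <- as.matrix(df[FRACTION_COLS])
  bad <- which(apply(fr, 1L, function(v) any(!is.finite(v)) ||
                       any(v < -tol) || any(v > 1 + tol)))
  if (length(bad)) row_fail(what, bad, "land-cover fractions must lie in [0, 1]")
  s <- rowSums(fr)
  bad <- which(abs(s - 1) > 1e-9)
  if (length(bad)) row_fail(what, bad, "land-cover fractions must sum to 1")
}

#' @rdname records
#' @export
validate_reservoirs <- function(df) {
  what <- "reservoir"
  check_columns(df, c("id", "res_type", "zone", "area", "mean_depth",
                      "volume", "residence_time", FRACTION_COLS,
                      "catchment_id"), what)
  if (anyDuplicated(df$id)) {
    row_fail(what, which(duplicated(df$id)), "duplicated reservoir id")
  }
  bad <- which(!(df$res_type %in% reservoir_types()))
  if (length(bad)) row_fail(what, bad, "unknown res_type")
  zl <- squish(as.character(df$zone))
  bad <- which(!(zl %in% climate_zones()))
  if (length(bad)) row_fail(what, bad, "unknown climate-zone label")
  df$zone <- zl
  ror <- df$res_type == "ror"
  bad <- which(!ror & !(is.finite(df$area) & df$area > 0))
  if (length(bad)) row_fail(what, bad, "area must be > 0 for non-RoR records")
  bad <- which(ror & df$area != 0)
  if (length(bad)) row_fail(what, bad, "RoR records must have area = 0")
  bad <- which(!ror & !(is.finite(df$mean_depth) & df$mean_depth > 0))
  if (length(bad)) row_fail(what, bad, "mean_depth must be > 0 for non-RoR records")
  check_fractions(df[!ror, , drop = FALSE], what)
  class(df) <- unique(c("reservoir_records", class(df)))
  df
}

#' @rdname records
#' @export
validate_catchments <- function(df) {
  what <- "catchment"
  check_columns(df, c("id", "area", "runoff", "evapotranspiration",
                      "air_temperature", "mean_slope", "population_density",
                      FRACTION_COLS), what)
  if (anyDuplicated(df$id)) {
    row_fail(what, which(duplicated(df$id)), "duplicated catchment id")
  }
  bad <- which(!(is.finite(df$area) & df$area > 0))
  if (length(bad)) row_fail(what, bad, "area must be > 0")
  bad <- which(!(is.finite(df$runoff) & df$runoff >= 0))
  if (length(bad)) row_fail(what, bad, "runoff must be >= 0")
  bad <- which(!(is.finite(df$evapotranspiration) & df$evapotranspiration >= 0))
  if (length(bad)) row_fail(what, bad, "evapotranspiration must be >= 0")
  check_fractions(df, what)
  class(df) <- unique(c("catchment_records", class(df)))
  df
}

#' Read reservoir / catchment tables from CSV
#'
#' Strict schema validation: unknown zone labels, broken fractions or
#' non-positive areas are reported with the offending row numbers.
#'
#' @param path CSV file path.
#' @return A validated record table.
#' @export
read_reservoirs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("generation" %in% names(df)) df$generation <- as.numeric(df$generation)
  validate_reservoirs(df)
}

#' @rdname read_reservoirs
#' @export
read_catchments <- function(path) {
  validate_catchments(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_reservoirs
#' @param df A record table.
#' @export
write_records <- function(df, path) {
  utils::write.csv(as.data.frame(df), path, row.names = FALSE, na = "")
  invisible(path)
}
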