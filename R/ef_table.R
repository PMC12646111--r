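#' Emission-factor tables
#'
#' An `ef_table` stores one areal flux (gCO2e/m2/yr) per (climate zone,
#' emission pathway) cell, optionally with a margin of error (half the width
#' of a bootstrap 95% confidence interval) and a per-cell sample count `n`.
#' Cells may be absent: a missing (zone, pathway) combination means no
#' emission factor is available for that stratum.
#'
#' @param zone,pathway,flux Parallel vectors defining the cells.
#' @param margin Optional margin of error per cell (gCO2e/m2/yr).
#' @param n Optional count of reservoirs contributing to a fitted cell.
#' @param provenance Either `"global"` (published global factors) or
#'   `"fitted"` (recalibrated from model output).
#' @return A data frame of class `ef_table` with columns `zone`, `pathway`,
#'   `flux`, `margin`, `n` and attribute `provenance`.
#' @export
ef_table <- function(zone, pathway, flux, margin = NULL, n = NULL,
                     provenance = c("global", "fitted")) {
  provenance <- match.arg(provenance)
  zone <- canonical_zone(zone)
  pathway <- canonical_pathway(pathway)
  flux <- as.numeric(flux)
  if (length(zone) != length(pathway) || length(zone) != length(flux)) {
    abort("zone, pathway and flux must have equal length", "resghg_bad_argument")
  }
  if (any(!is.finite(flux)) || any(flux < 0)) {
    abort("all emission-factor fluxes must be finite and >= 0",
          "resghg_bad_argument")
  }
  if (is.null(margin)) margin <- rep(NA_real_, length(flux))
  margin <- as.numeric(margin)
  if (any(!is.na(margin) & margin < 0)) {
    abort("margins must be >= 0", "resghg_bad_argument")
  }
  if (is.null(n)) n <- rep(NA_integer_, length(flux))
  key <- paste(zone, pathway, sep = "\r")
  if (anyDuplicated(key)) {
    abort("duplicated (zone, pathway) cells in emission-factor table",
          "resghg_bad_argument")
  }
  out <- data.frame(zone = zone, pathway = pathway, flux = flux,
                    margin = margin, n = as.integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("ef_table", "data.frame")
  out
}

#' Look up an areal emission factor
#'
#' Returns the stored flux for one (zone, pathway) cell, unchanged.
#'
#' @param table An [ef_table()].
#' @param zone A climate-zone label (see [climate_zones()]).
#' @param pathway An emission pathway name (see [emission_pathways()]).
#' @return The areal flux in gCO2e/m2/yr.
#' @section Errors: `resghg_missing_ef` when the cell is absent;
#'   `resghg_unknown_zone` for labels outside the six-zone set.
#' @export
lookup_ef <- function(table, zone, pathway) {
  stopifnot(inherits(table, "ef_table"))
  zone <- canonical_zone(zone)
  pathway <- canonical_pathway(pathway)
  i <- which(table$zone == zone & table$pathway == pathway)
  if (length(i) == 0L) {
    abort(sprintf("no emission factor for zone '%s', pathway '%s'",
                  zone, pathway),
          "resghg_missing_ef", zone = zone, pathway = pathway)
  }
  table$flux[i]
}

#' Load the shipped Tier 1 emission-factor table
#'
#' The package ships the published climate-zone emission factors together
#' with the country-recalibrated variants (all reservoir types, and
#' hydroelectric-plus-multipurpose only), in gCO2e/m2/yr.  Absent cells in
#' the fitted variants reflect climate zones without reservoirs in the
#' underlying fleet.
#'
#' @param source One of `"global"`, `"myanmar_all"`, `"myanmar_hp"`.
#' @return An [ef_table()].
#' @export
load_ef_table <- function(source = c("global", "myanmar_all", "myanmar_hp")) {
  source <- match.arg(source)
  path <- system.file("extdata", "tier1_emission_factors.csv",
                      package = "resghg", mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw <- raw[raw$source == source, , drop = FALSE]
  ef_table(raw$zone, raw$pathway, raw$flux, margin = raw$margin,
           provenance = if (source == "global") "global" else "fitted")
}

#' Read / write emission-factor tables as CSV
#'
#' The on-disk schema is `zone,pathway,flux,margin,provenance`; absent cells
#' are simply absent rows, empty `margin` fields become `NA`.
#'
#' @param path File path.
#' @param table An [ef_table()].
#' @return `read_ef_table()` returns an [ef_table()]; `write_ef_table()`
#'   returns `path` invisibly.
#' @export
read_ef_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("zone", "pathway", "flux")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(miss, collapse = ", ")), "resghg_schema_error")
  }
  prov <- if ("provenance" %in% names(raw) && any(raw$provenance == "fitted")) {
    "fitted"
  } else {
    "global"
  }
  margin <- if ("margin" %in% names(raw)) raw$margin else NULL
  n <- if ("n" %in% names(raw)) raw$n else NULL
  ef_table(raw$zone, raw$pathway, raw$flux, margin = margin, n = n,
           provenance = prov)
}

#' @rdname read_ef_table
#' @export
write_ef_table <- function(table, path) {
  stopifnot(inherits(table, "ef_table"))
  out <- as.data.frame(table)
  out$provenance <- attr(table, "provenance")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.ef_table <- function(x, ...) {
  cat(sprintf("Tier 1 emission-factor table (%s), %d cells, gCO2e/m2/yr\n",
              attr(x, "provenance"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
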