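#' Climate zones and emission pathways
#'
#' Tier 1 emission factors are stratified by climatic zone: a single areal
#' flux per (zone, pathway) cell is applied to every reservoir in that zone.
#' The six zone labels form a closed set; comparisons are exact string
#' matches after canonical whitespace normalisation.
#'
#' @return `climate_zones()` returns the six zone labels;
#'   `emission_pathways()` the four pathway names.
#' @export
climate_zones <- function() {
  c("Cool temperate moist dry",
    "Polar moist boreal dry moist",
    "Tropical dry montane",
    "Tropical wet moist",
    "Warm temperate dry",
    "Warm temperate moist")
}

#' @rdname climate_zones
#' @export
emission_pathways <- function() {
  c("co2_diffusive", "ch4_diffusive", "ch4_ebullition", "ch4_degassing")
}

#' Reservoir use types
#' @return Character vector of the recognised reservoir types.
#' @export
reservoir_types <- function() {
  c("hydroelectric", "multipurpose", "irrigation", "ror")
}

# Collapse runs of whitespace and trim, so that labels read from files with
# stray spacing still match the closed zone set exactly.
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

#' Canonicalise a climate-zone label
#'
#' @param label Character vector of zone labels.
#' @return The canonical labels.  Labels outside the closed six-element set
#'   raise an error of class `resghg_unknown_zone`.
#' @export
canonical_zone <- function(label) {
  lab <- squish(as.character(label))
  bad <- !(lab %in% climate_zones())
  if (any(bad)) {
    abort(sprintf("unknown climate zone label(s): %s",
                  paste(unique(lab[bad]), collapse = ", ")),
          "resghg_unknown_zone")
  }
  lab
}

canonical_pathway <- function(pathway) {
  pw <- squish(as.character(pathway))
  bad <- !(pw %in% emission_pathways())
  if (any(bad)) {
    abort(sprintf("unknown emission pathway(s): %s",
                  paste(unique(pw[bad]), collapse = ", ")),
          "resghg_unknown_pathway")
  }
  pw
}
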