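#' Gross emission profiles
#'
#' A gross emission profile holds one areal flux per emission pathway
#' (gCO2e/m2/yr), their sum (`total_areal`) and the corresponding annual
#' mass (`total_mass`, tCO2e/yr).  The unit identity is exact:
#' g/m2/yr x 1e6 m2/km2 = 1e6 g/km2/yr = 1 t/km2/yr, so
#' `total_mass = total_areal * area_km2`.
#'
#' @param fluxes Named numeric vector over the four pathways
#'   (see [emission_pathways()]); all values >= 0.
#' @param area_km2 Reservoir surface area in km2.
#' @return An object of class `gross_profile`.
#' @export
gross_profile <- function(fluxes, area_km2) {
  pw <- emission_pathways()
  if (!all(pw %in% names(fluxes))) {
    abort("fluxes must be named over all four emission pathways",
          "resghg_bad_argument")
  }
  fluxes <- as.numeric(fluxes[pw])
  names(fluxes) <- pw
  if (any(!is.finite(fluxes))) {
    abort("non-finite pathway flux", "resghg_nonfinite_flux")
  }
  if (any(fluxes < 0)) {
    abort("gross pathway fluxes must be >= 0", "resghg_bad_argument")
  }
  total_areal <- sum(fluxes)
  structure(list(fluxes = fluxes,
                 total_areal = total_areal,
                 area_km2 = area_km2,
                 total_mass = total_areal * area_km2),
            class = "gross_profile")
}

#' @export
print.gross_profile <- function(x, ...) {
  cat("Gross emission profile (gCO2e/m2/yr):\n")
  print(round(x$fluxes, 3))
  cat(sprintf("total areal %.3f gCO2e/m2/yr over %.4f km2 -> %.3f tCO2e/yr\n",
              x$total_areal, x$area_km2, x$total_mass))
  invisible(x)
}

#' Tier 1 gross emission profile for one reservoir
#'
#' Looks up the four pathway fluxes for the reservoir's climate zone in an
#' emission-factor table.  CH4 degassing requires a deep outlet drawing
#' gas-rich hypolimnetic water; irrigation reservoirs usually lack one, so
#' the degassing pathway can be zeroed for them via
#' `include_degassing_for_irrigation = FALSE`.
#'
#' @param res A single reservoir record (one-row data frame or list).
#' @param table An [ef_table()].
#' @param include_degassing_for_irrigation Keep the degassing flux for
#'   irrigation reservoirs (default `TRUE`, the inclusive accounting).
#' @return A [gross_profile()].
#' @section Errors: propagates `resghg_missing_ef`; raises
#'   `resghg_zero_area` for non-RoR records with area <= 0.
#' @export
tier1_gross_profile <- function(res, table,
                                include_degassing_for_irrigation = TRUE) {
  stopifnot_flag(include_degassing_for_irrigation,
                 "include_degassing_for_irrigation")
  res <- as.list(res)
  if (!identical(res$res_type, "ror") &&
      (!is.finite(res$area) || res$area <= 0)) {
    abort(sprintf("reservoir '%s': non-RoR record with area <= 0", res$id),
          "resghg_zero_area")
  }
  fl <- vapply(emission_pathways(),
               function(p) lookup_ef(table, res$zone, p), numeric(1))
  if (identical(res$res_type, "irrigation") &&
      !include_degassing_for_irrigation) {
    fl["ch4_degassing"] <- 0
  }
  gross_profile(fl, res$area)
}

#' Empirical pathway-model configuration
#'
#' The empirical model predicts each pathway's areal flux from reservoir and
#' catchment features through a linear predictor and a link:
#' `flux = linkinv(intercept + sum(coef_i * feature_i))`.  Regression
#' coefficients are user-supplied configuration, not package constants.
#' CH4 pathway outputs are multiplied by `gwp_ch4` to express them in
#' gCO2e/m2/yr; there is deliberately no silent default for `gwp_ch4`.
#'
#' @param pathways Named list over the four pathways; each element a list
#'   with `features` (character), `coef` (numeric, same length),
#'   `intercept` and `link` (`"identity"` or `"log10"`).
#' @param gwp_ch4 CO2-equivalence factor applied to the CH4 pathways (use 1
#'   when the coefficients already produce CO2e).
#' @param uas_fraction Fraction of gross emissions attributed to unrelated
#'   anthropogenic sources in the catchment (nutrients, organic loading),
#'   removed when converting to net anthropogenic emissions.
#' @return An object of class `empirical_model_config`.
#' @export
empirical_model_config <- function(pathways, gwp_ch4, uas_fraction = 0) {
  stopifnot_number(gwp_ch4, "gwp_ch4", min = .Machine$double.xmin)
  stopifnot_number(uas_fraction, "uas_fraction", min = 0, max = 1)
  pw <- emission_pathways()
  if (!all(pw %in% names(pathways))) {
    abort("pathways must contain a spec for each of the four pathways",
          "resghg_bad_argument")
  }
  for (p in pw) {
    s <- pathways[[p]]
    if (length(s$features) != length(s$coef)) {
      abort(sprintf("pathway '%s': features and coef differ in length", p),
            "resghg_bad_argument")
    }
    if (!s$link %in% c("identity", "log10")) {
      abort(sprintf("pathway '%s': link must be 'identity' or 'log10'", p),
            "resghg_bad_argument")
    }
  }
  structure(list(pathways = pathways[pw], gwp_ch4 = gwp_ch4,
                 uas_fraction = uas_fraction),
            class = "empirical_model_config")
}

# Resolve feature names against a reservoir and a catchment record.  Bare
# names are searched in the reservoir record first, then the catchment;
# explicit "res." / "cat." prefixes disambiguate shared names such as area.
resolve_features <- function(features, res, cat) {
  res <- as.list(res); cat <- as.list(cat)
  vapply(features, function(f) {
    if (startsWith(f, "res.")) {
      v <- res[[substring(f, 5L)]]
    } else if (startsWith(f, "cat.")) {
      v <- cat[[substring(f, 5L)]]
    } else if (!is.null(res[[f]])) {
      v <- res[[f]]
    } else {
      v <- cat[[f]]
    }
    if (is.null(v) || !is.numeric(v) || !is.finite(as.numeric(v))) {
      abort(sprintf("feature '%s' not resolvable to a finite numeric field", f),
            "resghg_missing_feature")
    }
    as.numeric(v)
  }, numeric(1))
}

#' Predict a gross emission profile with the empirical pathway model
#'
#' @param res,cat A single reservoir and its catchment record.
#' @param cfg An [empirical_model_config()].
#' @return A [gross_profile()].  Negative identity-link predictions are
#'   clamped to 0 with a warning of class `resghg_clamped_flux` (gross
#'   fluxes are non-negative by definition).
#' @section Errors: `resghg_missing_feature`; `resghg_nonfinite_flux` when a
#'   log10 link overflows.
#' @export
predict_empirical_profile <- function(res, cat, cfg) {
  stopifnot(inherits(cfg, "empirical_model_config"))
  fl <- vapply(emission_pathways(), function(p) {
    s <- cfg$pathways[[p]]
    eta <- s$intercept +
      if (length(s$features)) sum(s$coef * resolve_features(s$features, res, cat)) else 0
    v <- if (s$link == "log10") 10^eta else eta
    if (!is.finite(v)) {
      abort(sprintf("pathway '%s': non-finite flux (linear predictor %g)",
                    p, eta), "resghg_nonfinite_flux")
    }
    if (s$link == "identity" && v < 0) {
      warn(sprintf("pathway '%s': negative identity-link prediction %.4g clamped to 0",
                   p, v), "resghg_clamped_flux")
      v <- 0
    }
    v
  }, numeric(1))
  ch4 <- c("ch4_diffusive", "ch4_ebullition", "ch4_degassing")
  fl[ch4] <- fl[ch4] * cfg$gwp_ch4
  gross_profile(fl, as.list(res)$area)
}

#' Pre-impoundment landscape flux
#'
#' Areal GHG balance of the landscape before flooding, as the land-cover
#' weighted mean of per-class fluxes.  Intact sinks (e.g. forests on
#' mineral soils) carry negative fluxes, so the result may be negative.
#'
#' @param res A reservoir record with land-cover fraction columns.
#' @param table Named numeric vector of per-class areal fluxes
#'   (gCO2e/m2/yr), names `forest`, `cropland`, `shrub`, `other`.
#' @return Weighted-mean areal flux in gCO2e/m2/yr.
#' @export
pre_impoundment_flux <- function(res, table) {
  res <- as.list(res)
  classes <- sub("^frac_", "", FRACTION_COLS)
  fr <- vapply(FRACTION_COLS, function(cn) as.numeric(res[[cn]]), numeric(1))
  names(fr) <- classes
  used <- classes[fr > 0]
  miss <- setdiff(used, names(table))
  if (length(miss)) {
    abort(sprintf("no pre-impoundment flux for land-cover class(es): %s",
                  paste(miss, collapse = ", ")), "resghg_missing_class_flux")
  }
  sum(fr[used] * as.numeric(table[used]))
}

#' Net anthropogenic flux from gross pathway fluxes
#'
#' The linear net-emission relation
#' `F_net = (net_co2 * F_co2 + net_ch4 * F_ch4) * (1 + r_downstream)`,
#' where `net_co2` and `net_ch4` are the anthropogenic proportions of the
#' gross CO2 and CH4 fluxes and `r_downstream` the ratio of downstream to
#' reservoir-surface emissions.  The relation is scale-invariant, so it can
#' be applied in any consistent flux unit (canonically gCO2e/m2/yr here;
#' see [flux_per_day()] for reporting in per-day units).
#'
#' @param f_co2,f_ch4 Gross areal CO2 and CH4 fluxes (vectorised).
#' @param params A [net_conversion_params()].
#' @return Net areal flux in the input unit.
#' @export
net_from_gross <- function(f_co2, f_ch4, params) {
  stopifnot(inherits(params, "net_conversion_params"))
  if (any(!is.finite(f_co2)) || any(!is.finite(f_ch4))) {
    abort("gross fluxes must be finite", "resghg_bad_argument")
  }
  (params$net_co2 * f_co2 + params$net_ch4 * f_ch4) * (1 + params$r_downstream)
}

#' Net-conversion parameters
#'
#' @param net_co2,net_ch4 Anthropogenic proportions, each in \[-1, 1\].
#' @param r_downstream Ratio of downstream to surface emissions, >= 0.
#' @param calibrated Whether the values come from a fit against model output
#'   (`FALSE` marks them "uncalibrated" placeholders).
#' @return An object of class `net_conversion_params`.
#' @export
net_conversion_params <- function(net_co2, net_ch4, r_downstream,
                                  calibrated = FALSE) {
  stopifnot_number(net_co2, "net_co2", -1, 1)
  stopifnot_number(net_ch4, "net_ch4", -1, 1)
  stopifnot_number(r_downstream, "r_downstream", 0)
  structure(list(net_co2 = net_co2, net_ch4 = net_ch4,
                 r_downstream = r_downstream, calibrated = calibrated),
            class = "net_conversion_params")
}

#' Aggregate a gross profile into per-gas fluxes
#'
#' `F_co2` is the diffusive CO2 flux; `F_ch4` sums the CH4 pathways, by
#' default all three (surface diffusion, ebullition, downstream degassing),
#' optionally surface-only.
#'
#' @param profile A [gross_profile()].
#' @param ch4_include_degassing Include the degassing pathway in `F_ch4`.
#' @return Named numeric `c(f_co2, f_ch4)`.
#' @export
per_gas_fluxes <- function(profile, ch4_include_degassing = TRUE) {
  fl <- profile$fluxes
  ch4 <- fl["ch4_diffusive"] + fl["ch4_ebullition"] +
    if (ch4_include_degassing) fl["ch4_degassing"] else 0
  c(f_co2 = unname(fl["co2_diffusive"]), f_ch4 = unname(ch4))
}

#' Net anthropogenic emissions for one reservoir
#'
#' Combines the empirical gross profile with the unrelated-anthropogenic-
#' sources share and the pre-impoundment landscape flux:
#' `net_areal = gross_total * (1 - uas_fraction) * lifetime_multiplier -
#' displaced_areal - pre_impoundment_areal`.  Lifetime integration and
#' displaced aquatic emissions are neutral multipliers by default (1 and 0):
#' the model treats fluxes as lifetime-representative annual rates.
#'
#' @param res,cat Reservoir and catchment records (single site).
#' @param cfg An [empirical_model_config()].
#' @param pre_table Per-class pre-impoundment fluxes, see
#'   [pre_impoundment_flux()].
#' @param lifetime_multiplier,displaced_areal Neutral-by-default adjustments
#'   for lifetime integration and displaced emissions.
#' @return A list of class `net_emission_result` with the gross profile,
#'   `pre_impoundment_areal`, `net_areal` (gCO2e/m2/yr, may be negative) and
#'   `net_mass` (tCO2e/yr).
#' @export
net_anthropogenic <- function(res, cat, cfg, pre_table,
                              lifetime_multiplier = 1, displaced_areal = 0) {
  gross <- predict_empirical_profile(res, cat, cfg)
  pre <- pre_impoundment_flux(res, pre_table)
  net_areal <- gross$total_areal * (1 - cfg$uas_fraction) *
    lifetime_multiplier - displaced_areal - pre
  structure(list(gross = gross,
                 pre_impoundment_areal = pre,
                 net_areal = net_areal,
                 net_mass = net_areal * gross$area_km2),
            class = "net_emission_result")
}

#' @export
print.net_emission_result <- function(x, ...) {
  cat(sprintf("Net anthropogenic emissions: %.3f gCO2e/m2/yr (%.3f tCO2e/yr)\n",
              x$net_areal, x$net_mass))
  cat(sprintf("  gross %.3f, pre-impoundment %.3f gCO2e/m2/yr\n",
              x$gross$total_areal, x$pre_impoundment_areal))
  invisible(x)
}

#' Emission intensity of a generating asset
#'
#' Emissions per unit of generated electricity.  The unit identity is
#' direct: tCO2e/yr over GWh/yr equals g/kWh.  Run-of-river hydropower
#' carries a constant biogenic intensity (default 3 gCO2e/kWh) regardless of
#' mass, having no impounded surface; the lifecycle variant adds a constant
#' increment (default 19 gCO2e/kWh) for infrastructure and supply-chain
#' emissions.
#'
#' @param total_mass Annual emissions, tCO2e/yr.
#' @param generation Annual generation, GWh/yr (> 0).
#' @param res_type Reservoir type; `"ror"` triggers the constant intensity.
#' @param lifecycle Add the lifecycle increment.
#' @param ror_intensity,lifecycle_increment The two constants, gCO2e/kWh.
#' @return Emission intensity in gCO2e/kWh.
#' @export
emission_intensity <- function(total_mass, generation,
                               res_type = "hydroelectric",
                               lifecycle = FALSE,
                               ror_intensity = 3, lifecycle_increment = 19) {
  stopifnot_flag(lifecycle, "lifecycle")
  if (identical(res_type, "ror")) {
    ei <- ror_intensity
  } else {
    if (!is.finite(generation) || generation <= 0) {
      abort("generation must be > 0", "resghg_zero_generation")
    }
    ei <- total_mass / generation
  }
  ei + if (lifecycle) lifecycle_increment else 0
}

#' Flux unit conversion
#'
#' Converts areal fluxes between per-year and per-day bases using the mean
#' Julian year (365.25 d).
#'
#' @param x Flux values.
#' @return Converted fluxes.
#' @export
flux_per_day <- function(x) x / 365.25

#' @rdname flux_per_day
#' @export
flux_per_year <- function(x) x * 365.25
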