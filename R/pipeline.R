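#' Default pre-impoundment landscape fluxes
#'
#' Per land-cover class areal fluxes (gCO2e/m2/yr) used to subtract the
#' landscape's pre-flooding GHG balance.  Forests and shrubland on mineral
#' soils are net carbon sinks (negative), cropland a modest source.
#'
#' @return Named numeric vector.
#' @export
default_pre_impoundment <- function() {
  c(forest = -50, cropland = 15, shrub = -5, other = 0)
}

#' Uncalibrated net-conversion defaults
#'
#' Placeholder proportions for converting Tier 1 gross fluxes to net
#' anthropogenic emissions; marked uncalibrated.  Use
#' [calibrate_net_params()] to fit them against model output.
#'
#' @return A [net_conversion_params()] with `calibrated = FALSE`.
#' @export
default_net_params <- function() {
  net_conversion_params(0.5, 0.85, 0.15, calibrated = FALSE)
}

#' Per-fleet emission accounting under both methods
#'
#' For every reservoir, assembles the model-based gross profile (the
#' pathway fluxes supplied, e.g. the synthetic ground truth or an
#' empirical-model prediction) and the Tier 1 profile from an
#' emission-factor table, then converts both to net anthropogenic
#' emissions: the model path via the unrelated-anthropogenic-sources share
#' and the pre-impoundment flux, the Tier 1 path via the linear
#' net-conversion relation.
#'
#' @param fluxes Per-reservoir pathway flux table (columns `id` plus the
#'   four pathways), gCO2e/m2/yr.
#' @param reservoirs,catchments Validated record tables.
#' @param table An [ef_table()] for the Tier 1 path.
#' @param net_params A [net_conversion_params()].
#' @param pre_table Per-class pre-impoundment fluxes.
#' @param uas_fraction Unrelated-anthropogenic-sources share of gross.
#' @param include_degassing_for_irrigation Tier 1 degassing toggle.
#' @return Data frame with per-reservoir gross and net areal fluxes and
#'   masses under both methods.
#' @export
fleet_emissions <- function(fluxes, reservoirs, catchments, table,
                            net_params = default_net_params(),
                            pre_table = default_pre_impoundment(),
                            uas_fraction = 0.05,
                            include_degassing_for_irrigation = TRUE) {
  res <- as.data.frame(reservoirs)
  pw <- emission_pathways()
  out <- lapply(seq_len(nrow(res)), function(i) {
    r <- res[i, ]
    fx <- as.numeric(fluxes[match(r$id, fluxes$id), pw])
    names(fx) <- pw
    gm <- gross_profile(fx, r$area)
    pre <- if (r$res_type == "ror") 0 else pre_impoundment_flux(r, pre_table)
    net_model_areal <- gm$total_areal * (1 - uas_fraction) - pre
    ge <- tier1_gross_profile(r, table, include_degassing_for_irrigation)
    gas <- per_gas_fluxes(ge)
    net_ef_areal <- net_from_gross(gas["f_co2"], gas["f_ch4"], net_params)
    data.frame(id = r$id, res_type = r$res_type, zone = r$zone,
               area = r$area,
               gross_model_areal = gm$total_areal,
               gross_model_mass = gm$total_mass,
               net_model_areal = net_model_areal,
               net_model_mass = net_model_areal * r$area,
               gross_ef_areal = ge$total_areal,
               gross_ef_mass = ge$total_mass,
               net_ef_areal = unname(net_ef_areal),
               net_ef_mass = unname(net_ef_areal) * r$area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble planner asset metrics for a synthetic fleet
#'
#' Combines the generation series, the emission accounting and the
#' impounded land areas into the planner's asset table.  Run-of-river
#' assets carry emissions implied by the constant biogenic emission
#' intensity (so a pure-RoR portfolio reports exactly that intensity) and
#' zero land loss.  Existing infrastructure (for the built scenario) is
#' the non-hydroelectric storage fleet: irrigation and multipurpose
#' reservoirs.
#'
#' @param fleet A [synth_fleet()].
#' @param emissions A [fleet_emissions()] table.
#' @param gen A [synth_generation()].
#' @param ror_intensity Biogenic emission intensity of RoR assets, g/kWh.
#' @return An [asset_metrics()] table (extra column `land_loss`).
#' @export
build_asset_metrics <- function(fleet, emissions, gen, ror_intensity = 3) {
  res <- as.data.frame(fleet$reservoirs)
  wpy <- 365.25 / 7
  energy <- gen$annual[res$id]
  firm <- vapply(res$id, function(id)
    firm_power(gen$series[, id], annualize = wpy), numeric(1))
  em <- emissions[match(res$id, emissions$id), ]
  is_ror <- res$res_type == "ror"
  # g/kWh x GWh/yr = t/yr: intensity-implied mass for run-of-river
  em_model <- ifelse(is_ror, ror_intensity * energy, pmax(em$net_model_mass, 0))
  em_ef <- ifelse(is_ror, ror_intensity * energy, pmax(em$net_ef_mass, 0))
  df <- data.frame(
    id = res$id,
    type = ifelse(is_ror, "ror", "reservoir"),
    energy = unname(energy), firm = unname(firm),
    emissions_model = em_model, emissions_ef = em_ef,
    cropland_loss = ifelse(is_ror, 0, res$frac_cropland * res$area),
    forest_loss = ifelse(is_ror, 0, res$frac_forest * res$area),
    existing = res$res_type %in% c("irrigation", "multipurpose"),
    stringsAsFactors = FALSE)
  df$land_loss <- df$cropland_loss + df$forest_loss
  asset_metrics(df)
}

#' Surrogate feature matrix for a fleet
#'
#' Binds the reservoir morphometry, impounded land cover and catchment
#' descriptors into the numeric feature matrix used for surrogate
#' training and explanation.
#'
#' @param reservoirs,catchments Validated record tables.
#' @return Numeric matrix, one row per reservoir (rownames = ids).
#' @export
fleet_feature_matrix <- function(reservoirs, catchments) {
  res <- as.data.frame(reservoirs)
  cat <- as.data.frame(catchments)[match(res$catchment_id,
                                         catchments$id), ]
  feats <- cbind(
    mean_depth = res$mean_depth, volume = res$volume, area = res$area,
    residence_time = res$residence_time, frac_forest = res$frac_forest,
    frac_cropland = res$frac_cropland,
    catchment_area = cat$area, runoff = cat$runoff,
    evapotranspiration = cat$evapotranspiration,
    air_temperature = cat$air_temperature, mean_slope = cat$mean_slope,
    population_density = cat$population_density)
  rownames(feats) <- res$id
  feats
}

#' Run the synthetic end-to-end study
#'
#' The full two-step pipeline on synthetic data: generate a landscape,
#' delineate a dam fleet, attach the ground-truth emission law, account
#' emissions under both the model and the Tier 1 method, recalibrate
#' zone emission factors and net-conversion parameters against the model
#' output, train surrogate models with attributions and importances, and
#' approximate the Pareto frontier of dam portfolios under both the built
#' and not-built scenarios.
#'
#' The planning step traces the canonical energy-versus-emissions
#' trade-off (total hydropower maximised, total model emissions
#' minimised), with land losses and firm power reported along the
#' frontier; the full five-objective specification of
#' [default_objectives()] remains available, best suited to smaller
#' networks because the state space of the dynamic program grows quickly
#' with the number of objectives.
#'
#' @param cfg A [synth_config()].
#' @param epsilon Planner precision (normalised units).
#' @param n_boot Bootstrap resamples for emission-factor margins.
#' @param surrogate_trials Random-search budget for the surrogates.
#' @return A list with every intermediate product (landscape, fleet,
#'   truth, emissions, calibration, surrogates, frontiers, report tables).
#' @export
run_pipeline <- function(cfg = synth_config(), epsilon = 0.05,
                         n_boot = 1000L, surrogate_trials = 8L) {
  landscape <- synth_landscape(cfg)
  fleet <- synth_fleet(cfg, landscape)
  truth <- synth_emission_truth(cfg, fleet)
  ef_global <- load_ef_table("global")
  emis <- fleet_emissions(truth$fluxes, fleet$reservoirs, fleet$catchments,
                          ef_global, uas_fraction = truth$config$uas_fraction)

  fitted <- bootstrap_margins(truth$fluxes, n_boot = n_boot,
                              seed = cfg$seed + 10L)
  gas <- t(vapply(seq_len(nrow(emis)), function(i) {
    r <- as.data.frame(fleet$reservoirs)[i, ]
    per_gas_fluxes(tier1_gross_profile(r, ef_global))
  }, numeric(2)))
  keep <- as.data.frame(fleet$reservoirs)$res_type != "ror"
  net_cal <- calibrate_net_params(gas[keep, 1], gas[keep, 2],
                                  emis$net_model_areal[keep],
                                  r_grid = seq(0, 0.5, by = 0.05))

  res <- truth$reservoirs
  feats <- fleet_feature_matrix(fleet$reservoirs, fleet$catchments)
  pre <- vapply(seq_len(nrow(res)), function(i)
    if (res$res_type[i] == "ror") 0
    else pre_impoundment_flux(res[i, ], default_pre_impoundment()),
    numeric(1))
  u <- truth$config$uas_fraction
  y_co2 <- truth$fluxes$co2_diffusive * (1 - u) - pre
  y_ch4 <- (truth$fluxes$ch4_diffusive + truth$fluxes$ch4_ebullition +
              truth$fluxes$ch4_degassing) * (1 - u)
  scfg <- surrogate_config(n_trials = surrogate_trials, seed = cfg$seed)
  sur_co2 <- train_surrogate(feats, y_co2, scfg)
  sur_ch4 <- train_surrogate(feats, y_ch4, scfg)
  imp_co2 <- permutation_importance(sur_co2, feats, y_co2, seed = cfg$seed)
  imp_ch4 <- permutation_importance(sur_ch4, feats, y_ch4, seed = cfg$seed)
  attr_ch4 <- t(vapply(seq_len(nrow(feats)), function(i) {
    bd <- breakdown(sur_ch4, feats[i, ], feats)
    bd$contributions[colnames(feats)]
  }, numeric(ncol(feats))))
  emb <- attribution_embedding(attr_ch4, k = 2L, seed = cfg$seed)

  gen <- synth_generation(cfg, fleet)
  assets <- build_asset_metrics(fleet, emis, gen)
  objectives <- list(
    objective_spec("hydropower", "energy", "max", "sum"),
    objective_spec("ghg emissions", "emissions_model", "min", "sum"))
  frontier_nb <- epsilon_pareto(fleet$network, assets, objectives,
                                epsilon = epsilon, scenario = "not_built")
  frontier_b <- epsilon_pareto(fleet$network, assets, objectives,
                               epsilon = epsilon, scenario = "built")

  list(cfg = cfg, landscape = landscape, fleet = fleet, truth = truth,
       emissions = emis, ef_fitted = fitted, net_calibrated = net_cal,
       surrogates = list(co2 = sur_co2, ch4 = sur_ch4),
       importances = list(co2 = imp_co2, ch4 = imp_ch4),
       embedding = emb, generation = gen, assets = assets,
       objectives = objectives,
       frontiers = list(not_built = frontier_nb, built = frontier_b),
       report = list(not_built = frontier_report(frontier_nb, assets),
                     built = frontier_report(frontier_b, assets)))
}
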