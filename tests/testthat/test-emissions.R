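res_record <- function(zone = "Warm temperate dry", type = "hydroelectric",
                       area = 1, depth = 10, forest = 0.5, crop = 0.2,
                       shrub = 0.2, other = 0.1) {
  data.frame(id = "r1", res_type = type, zone = zone, area = area,
             mean_depth = depth, volume = area * depth, residence_time = 0.5,
             frac_forest = forest, frac_cropland = crop, frac_shrub = shrub,
             frac_other = other, generation = 10, catchment_id = "c1",
             stringsAsFactors = FALSE)
}

cat_record <- function(area = 100, temp = 22) {
  data.frame(id = "c1", area = area, runoff = 800, evapotranspiration = 500,
             air_temperature = temp, mean_slope = 4, population_density = 50,
             frac_forest = 0.4, frac_cropland = 0.3, frac_shrub = 0.2,
             frac_other = 0.1, stringsAsFactors = FALSE)
}

test_that("tier1 profiles are zone lookups with exact mass accounting", {
  tab <- load_ef_table("global")
  r <- res_record(zone = "Polar moist boreal dry moist")
  p <- tier1_gross_profile(r, tab)
  expect_equal(unname(p$fluxes["ch4_diffusive"]), 69.52)
  expect_equal(p$total_areal, sum(p$fluxes))
  # unit identity: g/m2/yr over 1 km2 is exactly t/yr
  expect_identical(p$total_mass, p$total_areal * r$area)
  r2 <- res_record(area = 3.7)
  p2 <- tier1_gross_profile(r2, tab)
  expect_identical(p2$total_mass, p2$total_areal * 3.7)
})

test_that("degassing exclusion applies to irrigation reservoirs only", {
  tab <- load_ef_table("global")
  irr <- res_record(type = "irrigation")
  hyd <- res_record(type = "hydroelectric")
  p_off <- tier1_gross_profile(irr, tab,
                               include_degassing_for_irrigation = FALSE)
  p_on <- tier1_gross_profile(irr, tab)
  expect_identical(unname(p_off$fluxes["ch4_degassing"]), 0)
  expect_lte(p_off$total_areal, p_on$total_areal)
  h_off <- tier1_gross_profile(hyd, tab,
                               include_degassing_for_irrigation = FALSE)
  h_on <- tier1_gross_profile(hyd, tab)
  expect_identical(h_off$fluxes, h_on$fluxes)
})

test_that("tier1 totals are monotone in the table cells", {
  tab <- load_ef_table("global")
  r <- res_record()
  base <- tier1_gross_profile(r, tab)$total_areal
  for (p in emission_pathways()) {
    tab2 <- tab
    i <- which(tab2$zone == r$zone & tab2$pathway == p)
    tab2$flux[i] <- tab2$flux[i] + 100
    expect_gt(tier1_gross_profile(r, tab2)$total_areal, base)
  }
  expect_error(tier1_gross_profile(res_record(area = 0), tab),
               class = "resghg_zero_area")
})

test_that("empirical model evaluates the linear predictor through the link", {
  mk_cfg <- function(link, intercepts) {
    empirical_model_config(
      stats::setNames(lapply(intercepts, function(b)
        list(features = character(0), coef = numeric(0), intercept = b,
             link = link)), emission_pathways()),
      gwp_ch4 = 1)
  }
  r <- res_record(); ct <- cat_record()
  p <- predict_empirical_profile(r, ct, mk_cfg("identity", c(5, 7, 11, 13)))
  expect_equal(unname(p$fluxes), c(5, 7, 11, 13))
  p10 <- predict_empirical_profile(r, ct, mk_cfg("log10", c(2, 2, 2, 2)))
  expect_equal(unname(p10$fluxes), rep(100, 4))

  # independent evaluation of a full linear predictor
  cfg <- empirical_model_config(list(
    co2_diffusive = list(features = c("frac_forest", "cat.air_temperature"),
                         coef = c(900, 12), intercept = 120,
                         link = "identity"),
    ch4_diffusive = list(features = c("mean_depth", "cat.area"),
                         coef = c(-9, 0.02), intercept = 300,
                         link = "identity"),
    ch4_ebullition = list(features = "mean_depth", coef = -12,
                          intercept = 400, link = "identity"),
    ch4_degassing = list(features = character(0), coef = numeric(0),
                         intercept = 50, link = "identity")),
    gwp_ch4 = 2)
  p <- predict_empirical_profile(r, ct, cfg)
  hand <- c(120 + 900 * 0.5 + 12 * 22,
            2 * (300 - 9 * 10 + 0.02 * 100),
            2 * (400 - 12 * 10),
            2 * 50)
  expect_equal(unname(p$fluxes), hand)
  expect_error(predict_empirical_profile(
    r, ct, empirical_model_config(list(
      co2_diffusive = list(features = "no_such_field", coef = 1,
                           intercept = 0, link = "identity"),
      ch4_diffusive = list(features = character(0), coef = numeric(0),
                           intercept = 0, link = "identity"),
      ch4_ebullition = list(features = character(0), coef = numeric(0),
                            intercept = 0, link = "identity"),
      ch4_degassing = list(features = character(0), coef = numeric(0),
                           intercept = 0, link = "identity")), gwp_ch4 = 1)),
    class = "resghg_missing_feature")
})

test_that("negative identity-link predictions clamp to zero with a warning", {
  cfg <- empirical_model_config(list(
    co2_diffusive = list(features = character(0), coef = numeric(0),
                         intercept = -10, link = "identity"),
    ch4_diffusive = list(features = character(0), coef = numeric(0),
                         intercept = 1, link = "identity"),
    ch4_ebullition = list(features = character(0), coef = numeric(0),
                          intercept = 1, link = "identity"),
    ch4_degassing = list(features = character(0), coef = numeric(0),
                         intercept = 1, link = "identity")), gwp_ch4 = 1)
  expect_warning(p <- predict_empirical_profile(res_record(), cat_record(),
                                                cfg),
                 class = "resghg_clamped_flux")
  expect_identical(unname(p$fluxes["co2_diffusive"]), 0)
})

test_that("pre-impoundment flux is the land-cover weighted mean", {
  tab <- c(forest = -50, cropland = 20, shrub = 0, other = 0)
  r <- res_record(forest = 1, crop = 0, shrub = 0, other = 0)
  expect_equal(pre_impoundment_flux(r, tab), -50)
  r2 <- res_record(forest = 0.5, crop = 0.5, shrub = 0, other = 0)
  expect_equal(pre_impoundment_flux(r2, c(forest = -40, cropland = 20)), -10)
  set.seed(42)
  for (i in 1:100) {
    fr <- runif(4); fr <- fr / sum(fr)
    fx <- rnorm(4, 0, 50)
    r3 <- res_record(forest = fr[1], crop = fr[2], shrub = fr[3],
                     other = fr[4])
    tab3 <- c(forest = fx[1], cropland = fx[2], shrub = fx[3], other = fx[4])
    expect_equal(pre_impoundment_flux(r3, tab3), sum(fr * fx))
  }
  expect_error(pre_impoundment_flux(res_record(forest = 1, crop = 0,
                                               shrub = 0, other = 0),
                                    c(cropland = 5)),
               class = "resghg_missing_class_flux")
})

test_that("net conversion follows the linear relation exactly", {
  id <- net_conversion_params(1, 1, 0)
  expect_equal(net_from_gross(123.4, 56.7, id), 123.4 + 56.7)
  expect_equal(net_from_gross(0, 0, net_conversion_params(0.3, 0.9, 2)), 0)
  # value computed by hand: (0.5*100 + 0.8*200) * 1.25 = 262.5
  expect_equal(net_from_gross(100, 200, net_conversion_params(0.5, 0.8, 0.25)),
               262.5)
})

test_that("net anthropogenic accounting combines gross, uas and landscape", {
  r <- res_record(); ct <- cat_record()
  pre <- c(forest = -50, cropland = 15, shrub = -5, other = 0)
  base_paths <- stats::setNames(lapply(c(100, 200, 300, 50), function(b)
    list(features = character(0), coef = numeric(0), intercept = b,
         link = "identity")), emission_pathways())
  cfg0 <- empirical_model_config(base_paths, gwp_ch4 = 1, uas_fraction = 0)
  out0 <- net_anthropogenic(r, ct, cfg0,
                            c(forest = 0, cropland = 0, shrub = 0, other = 0))
  expect_equal(out0$net_areal, out0$gross$total_areal)
  cfg1 <- empirical_model_config(base_paths, gwp_ch4 = 1, uas_fraction = 1)
  out1 <- net_anthropogenic(r, ct, cfg1, pre)
  expect_equal(out1$net_areal, -out1$pre_impoundment_areal)
  set.seed(11)
  for (i in 1:50) {
    u <- runif(1)
    cfg <- empirical_model_config(base_paths, gwp_ch4 = 1, uas_fraction = u)
    out <- net_anthropogenic(r, ct, cfg, pre)
    expect_equal(out$net_areal,
                 out$gross$total_areal * (1 - u) - out$pre_impoundment_areal)
    expect_equal(out$net_mass, out$net_areal * r$area)
  }
})

test_that("emission intensity handles mass, RoR constants and lifecycle", {
  expect_equal(emission_intensity(1000, 1), 1000)
  expect_equal(emission_intensity(5000, 20), 250)
  expect_equal(emission_intensity(1e6, 10, res_type = "ror"), 3)
  expect_equal(emission_intensity(0, 1, res_type = "ror", lifecycle = TRUE),
               3 + 19)
  expect_equal(emission_intensity(1000, 2, lifecycle = TRUE), 500 + 19)
  expect_error(emission_intensity(100, 0), class = "resghg_zero_generation")
})

test_that("per-day and per-year flux conversions invert each other", {
  x <- c(0, 1, 365.25, 1000)
  expect_equal(flux_per_year(flux_per_day(x)), x)
  expect_equal(flux_per_day(365.25), 1)
})
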