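test_that("age-stratified BEF method matches hand arithmetic on one record", {
  inv <- single_arbor("P_yunnanensis", "middle_aged", volume = 1000)
  st <- carbon_variable_bef(inv, by = NULL)
  expect_equal(st$carbon_tC, 1000 * 0.483 * 1.837 * (1 + 0.143) * 0.511)
  # zero volume gives zero carbon
  expect_equal(carbon_variable_bef(single_arbor("Quercus_sp", "mature", 0),
                                   by = NULL)$carbon_tC, 0)
})

test_that("arbor records without an age group are rejected by name", {
  bad <- tibble::as_tibble(mini_inventory())
  bad$age_group[1] <- "not_applicable"
  # bypass constructor validation to exercise the estimator's own guard
  inv <- structure(bad, class = class(mini_inventory()))
  expect_error(carbon_variable_bef(inv), "r1")
})

test_that("pooled BEF method reproduces published per-species stocks", {
  reg <- default_registry()
  cases <- list(
    list("P_yunnanensis", 1251790.89, 588618.02),
    list("Quercus_sp", 76041.34, 47029.75),
    list("C_funebris", 462.35, 236.16))
  for (cs in cases) {
    inv <- single_arbor(cs[[1]], "middle_aged", volume = cs[[2]])
    st <- carbon_bef(inv, reg, by = NULL)
    expect_equal(round_half_up(st$carbon_tC, 2), cs[[3]], label = cs[[1]])
  }
})

test_that("volume conversion is composition-independent at 0.475 tC/m3", {
  inv <- mini_inventory() # mixed species and ages; arbor volume 1700
  st <- carbon_volume_conversion(inv, by = NULL)
  expect_equal(st$carbon_tC, 1700 * 0.475)
  one <- carbon_volume_conversion(single_arbor("E_robusta", "young", 1),
                                  by = NULL)
  expect_equal(one$carbon_tC, 0.475)
  # published total volume reproduces the published total stock
  big <- single_arbor("P_yunnanensis", "young", volume = 1417181.20)
  expect_equal(round_half_up(carbon_volume_conversion(big, by = NULL)$carbon_tC, 2),
               673161.07)
})

test_that("linear biomass-volume method handles both application levels", {
  reg <- default_registry()
  # species aggregate: intercept once per species
  inv <- single_arbor("P_yunnanensis", "middle_aged", volume = 1251790.89)
  st <- carbon_continuous_bcf(inv, reg, application_level = "species_aggregate")
  expect_equal(st$carbon_tC, (0.5101 * 1251790.89 + 1.0451) * 0.511)
  expect_false(st$intercept_only)
  # zero volume with one record: carbon = b x CF, flagged intercept-only
  z <- carbon_continuous_bcf(single_arbor("Quercus_sp", "mature", 0), reg,
                             application_level = "species_aggregate")
  expect_equal(z$carbon_tC, 8.5473 * 0.500)
  expect_true(z$intercept_only)
  # two records of one species: aggregate vs per-record differ by b x CF
  two <- as_inventory(tibble::tibble(
    record_id = c("a", "b"), compartment_id = "c",
    vegetation_type = "arbor", species = "P_armandii",
    age_group = "young", area_hm2 = 1, volume_m3 = 10,
    zone = "core"))
  agg <- carbon_continuous_bcf(two, reg, application_level = "species_aggregate")
  per <- carbon_continuous_bcf(two, reg, application_level = "per_record")
  expect_equal(per$carbon_tC - agg$carbon_tC, 18.7435 * 0.523)
  # application level must be explicit
  expect_error(carbon_continuous_bcf(two, reg), "explicitly")
})

test_that("area-based method reproduces published economic and shrub stocks", {
  inv <- mini_inventory()
  targets <- tibble::tibble(vegetation_type = c("economic", "shrub"),
                            area_hm2 = c(376.33, 56.37), volume_m3 = NA)
  cal <- calibrate_inventory(inv, targets)
  st <- carbon_area_based(cal)
  eco <- st$carbon_tC[st$vegetation_type == "economic"]
  shr <- st$carbon_tC[st$vegetation_type == "shrub"]
  expect_equal(round_half_up(eco, 2), 4191.94)
  expect_equal(round_half_up(shr, 2), 523.52)
  # zero area contributes zero
  empty <- as_inventory(tibble::as_tibble(mini_inventory())[0, ])
  expect_equal(nrow(carbon_area_based(empty)), 0)
})

test_that("methods are homogeneous of degree one in volume", {
  inv <- generate_inventory(generator_config(n_subcompartments = 200L), seed = 11)
  scaled <- tibble::as_tibble(inv)
  scaled$volume_m3 <- scaled$volume_m3 * 3
  inv3 <- as_inventory(scaled)
  for (f in list(carbon_variable_bef, carbon_bef, carbon_volume_conversion)) {
    expect_equal(f(inv3, by = NULL)$carbon_tC,
                 3 * f(inv, by = NULL)$carbon_tC)
  }
})

test_that("per-species stocks are additive to the method total", {
  inv <- generate_inventory(generator_config(n_subcompartments = 200L), seed = 5)
  for (f in list(carbon_variable_bef, carbon_bef, carbon_volume_conversion)) {
    expect_equal(sum(f(inv, by = "species")$carbon_tC),
                 f(inv, by = NULL)$carbon_tC, tolerance = 1e-12)
  }
  st <- carbon_continuous_bcf(inv, application_level = "per_record",
                              by = c("species", "zone"))
  expect_equal(sum(st$carbon_tC),
               carbon_continuous_bcf(inv, application_level = "per_record",
                                     by = NULL)$carbon_tC,
               tolerance = 1e-12)
})

test_that("pooled method equals age-stratified method when age rows equal the pooled row", {
  reg <- default_registry()
  sp <- reg$species_params
  pooled <- sp[sp$stratum == "total", ]
  flat <- sp
  for (i in seq_len(nrow(flat))) {
    j <- which(pooled$species == flat$species[i])
    flat$BEF[i] <- pooled$BEF[j]
    flat$R[i] <- pooled$R[j]
  }
  reg_flat <- load_registry_overrides(reg, species_params = flat)
  inv <- generate_inventory(generator_config(n_subcompartments = 150L), seed = 2)
  expect_equal(carbon_variable_bef(inv, reg_flat, by = "species"),
               dplyr::mutate(carbon_bef(inv, reg_flat, by = "species"),
                             method = "variable_bef"))
})

test_that("carbon and densities are non-negative and mutually consistent", {
  inv <- generate_inventory(generator_config(n_subcompartments = 200L), seed = 9)
  st <- carbon_variable_bef(inv, by = c("species", "age_group"))
  expect_true(all(st$carbon_tC >= 0))
  st2 <- carbon_density(st)
  expect_equal(st2$density_tC_per_hm2 * st2$area_hm2, st2$carbon_tC,
               tolerance = 1e-9)
  bad <- st
  bad$area_hm2[1] <- 0
  expect_error(carbon_density(bad), "zero area")
})

test_that("whole-vegetation stocks combine arbor and area-based layers", {
  inv <- mini_inventory()
  veg <- vegetation_stocks(inv, arbor_method = "bef")
  expect_setequal(veg$vegetation_type, c("arbor", "economic", "shrub"))
  expect_equal(sum(veg$carbon_tC),
               carbon_bef(inv, by = NULL)$carbon_tC +
                 sum(carbon_area_based(inv)$carbon_tC))
  tot <- stock_total(veg)
  expect_equal(tot$area_hm2, sum(veg$area_hm2))
})
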