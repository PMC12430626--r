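test_that("generation is deterministic under a fixed seed", {
  cfg <- generator_config(n_subcompartments = 200L)
  a <- generate_inventory(cfg, seed = 99)
  b <- generate_inventory(cfg, seed = 99)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- generate_inventory(cfg, seed = 100)
  expect_false(identical(a$volume_m3, c$volume_m3))
})

test_that("generated tables are schema-valid with the configured structure", {
  cfg <- generator_config(n_subcompartments = 500L)
  inv <- generate_inventory(cfg, seed = 4)
  expect_equal(nrow(inv), 500)
  expect_equal(nrow(inventory_problems(inv)), 0)
  s <- summarize_inventory(inv, "vegetation_type")
  expect_setequal(s$vegetation_type,
                  c("arbor", "economic", "shrub", "non_stocked"))
  # area-only types carry zero volume
  expect_equal(s$volume_m3[s$vegetation_type != "arbor"], rep(0, 3))
  # every (species, age) cell is populated, so calibration is feasible
  cells <- summarize_inventory(inv, c("species", "age_group"))
  arbor_cells <- cells[cells$species %in% inventory_levels()$arbor_species, ]
  expect_equal(nrow(arbor_cells), 28)
})

test_that("sampled species shares track the configured simplex", {
  shares <- c(P_yunnanensis = 0.9, Quercus_sp = 0.1, E_robusta = 0,
              P_armandii = 0, A_cremastogyne = 0, K_fortunei = 0,
              C_funebris = 0)
  cfg <- generator_config(n_subcompartments = 10000L,
                          species_area_shares = shares)
  inv <- generate_inventory(cfg, seed = 8)
  tab <- tibble::as_tibble(inv)
  arbor <- tab[tab$vegetation_type == "arbor", ]
  n_free <- nrow(arbor) - 28 # minus the guaranteed coverage block
  p_hat <- (sum(arbor$species == "P_yunnanensis") - 4) / n_free
  se <- sqrt(0.9 * 0.1 / n_free)
  expect_lt(abs(p_hat - 0.9), 3 * se)
})

test_that("infeasible simplexes and scales are config errors", {
  expect_error(generator_config(zone_shares = c(core = 0.7, buffer = 0.7,
                                                experimental = 0.1)),
               "simplex")
  expect_error(generator_config(species_area_shares = c(P_yunnanensis = 1)),
               "named over")
  expect_error(generator_config(volume_density_cv = -1), "positive")
  expect_error(generator_config(n_subcompartments = 30L), "Too few")
})

test_that("calibration hits targeted marginals exactly and preserves structure", {
  inv <- generate_inventory(generator_config(n_subcompartments = 300L), seed = 6)
  targets <- tibble::tibble(
    vegetation_type = c("arbor", "economic"),
    species = c("P_yunnanensis", NA),
    age_group = NA_character_,
    area_hm2 = c(5000, 376.33),
    volume_m3 = c(800000, NA))
  cal <- calibrate_inventory(inv, targets)
  s <- summarize_inventory(cal, c("vegetation_type", "species"))
  py <- s[!is.na(s$species) & s$species == "P_yunnanensis", ]
  expect_equal(py$area_hm2, 5000, tolerance = 1e-9)
  expect_equal(py$volume_m3, 800000, tolerance = 1e-9)
  eco <- s[s$vegetation_type == "economic", ]
  expect_equal(eco$area_hm2, 376.33, tolerance = 1e-9)
  # within-group relative structure is preserved (common scale factor)
  before <- tibble::as_tibble(inv)
  after <- tibble::as_tibble(cal)
  sel <- before$species == "P_yunnanensis"
  ratios <- after$volume_m3[sel] / before$volume_m3[sel]
  expect_lt(diff(range(ratios)), 1e-12)
  # untargeted groups are untouched
  other <- before$species == "Quercus_sp"
  expect_identical(after$volume_m3[other], before$volume_m3[other])
})

test_that("calibration to current totals is the identity", {
  inv <- generate_inventory(generator_config(n_subcompartments = 100L), seed = 12)
  s <- summarize_inventory(inv, "vegetation_type")
  t_arbor <- s[s$vegetation_type == "arbor", ]
  cal <- calibrate_inventory(inv, tibble::tibble(
    vegetation_type = "arbor", area_hm2 = t_arbor$area_hm2,
    volume_m3 = t_arbor$volume_m3))
  expect_equal(tibble::as_tibble(cal), tibble::as_tibble(inv),
               tolerance = 1e-12)
})

test_that("empty targeted groups raise calibration errors", {
  inv <- mini_inventory() # has no K_fortunei records
  expect_error(calibrate_inventory(inv, tibble::tibble(
    vegetation_type = "arbor", species = "K_fortunei", age_group = NA,
    area_hm2 = 10, volume_m3 = NA)), "matches no records")
})

test_that("the calibrated fixture reproduces the published marginal totals", {
  inv <- zixi_fixture()
  s <- summarize_inventory(inv, "vegetation_type")
  expect_equal(s$area_hm2[s$vegetation_type == "economic"], 376.33,
               tolerance = 1e-9)
  expect_equal(s$area_hm2[s$vegetation_type == "shrub"], 56.37,
               tolerance = 1e-9)
  expect_equal(s$area_hm2[s$vegetation_type == "arbor"], 14447.58,
               tolerance = 1e-9)
  expect_equal(s$volume_m3[s$vegetation_type == "arbor"], 1417181.20,
               tolerance = 1e-9)
  sp <- summarize_inventory(inv, "species")
  expect_equal(sp$volume_m3[sp$species == "P_yunnanensis"], 1251790.89,
               tolerance = 1e-9)
  expect_equal(sp$area_hm2[sp$species == "P_yunnanensis"], 12789.08,
               tolerance = 1e-9)
  expect_equal(sp$volume_m3[sp$species == "Quercus_sp"], 76041.34,
               tolerance = 1e-9)
  expect_equal(sp$volume_m3[sp$species == "C_funebris"], 462.35,
               tolerance = 1e-9)
})

test_that("the fixture regenerates identically from its source config", {
  a <- zixi_fixture()
  b <- zixi_fixture()
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("fixture pooled-BEF stocks match the published per-species values", {
  inv <- zixi_fixture()
  st <- carbon_bef(inv, by = "species")
  expect_equal(round_half_up(st$carbon_tC[st$species == "P_yunnanensis"], 2),
               588618.02)
  expect_equal(round_half_up(st$carbon_tC[st$species == "Quercus_sp"], 2),
               47029.75)
  expect_equal(round_half_up(st$carbon_tC[st$species == "C_funebris"], 2),
               236.16)
})
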