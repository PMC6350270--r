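test_that("simulated explant counts recover configured densities", {
  # identity effect: group mean density converges to the baseline
  cfg <- scenario_config(
    seed = 11,
    drug_effects = drug_effect("null", 1, 1, 0),
    n_explants_per_group = 10000,
    baseline_ki67_density = 100, baseline_tunel_density = 100,
    explant_area_mean = 1, explant_area_cv = 0
  )
  rec <- simulate_explants(cfg)
  ki <- rec[rec$marker == "Ki67" & rec$group == "vehicle", ]
  dens <- ki$positive_count / ki$tumor_area_mm2
  se <- sd(dens) / sqrt(length(dens))
  expect_lt(abs(mean(dens) - 100), 3 * se)

  # halved proliferation: Monte-Carlo mean count ~ 50 over 1e4 draws
  cfg2 <- scenario_config(
    seed = 12, drug_effects = drug_effect("half", 0.5, 1, 0),
    n_explants_per_group = 10000,
    baseline_ki67_density = 100, explant_area_mean = 1, explant_area_cv = 0
  )
  rec2 <- simulate_explants(cfg2)
  counts <- rec2$positive_count[rec2$marker == "Ki67" & rec2$group == "half"]
  se2 <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se2)
})

test_that("explant simulation honors overdispersion and validates config", {
  cfg_nb <- scenario_config(
    seed = 5, drug_effects = drug_effect("d", 1, 1, 0),
    n_explants_per_group = 5000, count_dispersion = 0.5,
    baseline_ki67_density = 100, explant_area_mean = 1, explant_area_cv = 0
  )
  counts <- with(simulate_explants(cfg_nb),
                 positive_count[marker == "Ki67" & group == "vehicle"])
  # NB variance mu + dispersion * mu^2 = 100 + 0.5 * 100^2 >> Poisson
  expect_gt(var(counts), 2000)
  expect_lt(abs(mean(counts) - 100), 3 * sd(counts) / sqrt(length(counts)))

  expect_error(scenario_config(seed = 1, drug_effects = drug_effect("d", 1, 1, 0),
                               baseline_ki67_density = 0),
               "baseline_ki67_density")
  expect_error(scenario_config(seed = 1, drug_effects = drug_effect("d", 1, 1, 0),
                               measurement_days = c(3, 1, 7)),
               "strictly increasing")
  expect_error(drug_effect("d", -1, 1, 0), "prolif_multiplier")
  expect_error(drug_effect("d", 1, 1, 1.5), "growth_inhibition")
})

test_that("simulation is deterministic given the scenario seed", {
  eff <- sample_drug_effects(3, seed = 2)
  cfg <- scenario_config(seed = 42, drug_effects = eff)
  expect_identical(simulate_explants(cfg), simulate_explants(cfg))
  expect_identical(simulate_growth(cfg), simulate_growth(cfg))
  expect_identical(sample_drug_effects(3, seed = 2), eff)

  cfg2 <- scenario_config(seed = 43, drug_effects = eff)
  expect_false(identical(simulate_explants(cfg), simulate_explants(cfg2)))
})

test_that("noise-free growth follows the exponential model exactly", {
  # closed form: V(14) = 100 * exp(0.1 * 14) with inhibition 0
  cfg <- scenario_config(
    seed = 1, drug_effects = drug_effect("d", 1, 1, 0),
    baseline_growth_rate = 0.1, initial_volume = 100,
    initial_volume_cv = 0, caliper_cv = 0,
    measurement_days = c(0, 7, 14)
  )
  vol <- caliper_volumes(simulate_growth(cfg))
  v14 <- vol$volume_mm3[vol$group == "vehicle" & vol$day == 14]
  expect_equal(v14, rep(100 * exp(1.4), length(v14)), tolerance = 1e-9)

  # full inhibition freezes the series at V0
  cfg_stop <- scenario_config(
    seed = 1, drug_effects = drug_effect("halt", 1, 1, 1),
    initial_volume = 100, initial_volume_cv = 0, caliper_cv = 0
  )
  vol2 <- caliper_volumes(simulate_growth(cfg_stop))
  halted <- vol2$volume_mm3[vol2$group == "halt"]
  expect_equal(halted, rep(100, length(halted)), tolerance = 1e-9)
})

test_that("stronger inhibition yields smaller volumes at every day", {
  mk <- function(g) scenario_config(
    seed = 7, drug_effects = drug_effect("d", 1, 1, g),
    initial_volume_cv = 0, caliper_cv = 0
  )
  v_half <- caliper_volumes(simulate_growth(mk(0.5)))
  v_none <- caliper_volumes(simulate_growth(mk(0)))
  half <- v_half[v_half$group == "d", ]
  none <- v_none[v_none$group == "d", ]
  expect_true(all(half$volume_mm3 <= none$volume_mm3))
  expect_true(all(half$volume_mm3[half$day > 0] <
                    none$volume_mm3[none$day > 0]))
})

test_that("aspect ratio decomposition preserves the caliper volume", {
  cfg <- scenario_config(
    seed = 3, drug_effects = drug_effect("d", 1, 1, 0.3),
    aspect_ratio = 1.6, initial_volume_cv = 0, caliper_cv = 0
  )
  gr <- simulate_growth(cfg)
  expect_true(all(gr$d1_mm > gr$d2_mm))  # L != W exercises the min/max rule
  vol <- tumor_volume(gr$d1_mm, gr$d2_mm)
  expected <- 100 * exp(0.08 * ifelse(gr$group == "d", 0.7, 1) * gr$day)
  expect_equal(vol, expected, tolerance = 1e-9)
})

test_that("rendered tiles expose exact ground truth", {
  # empty case
  blank <- render_ihc_tile(0, tile_side_mm = 0.2, pixel_size_um = 2, seed = 1)
  expect_identical(blank$true_count, 0L)
  expect_true(all(blank$image < 0.5))

  # enumerated debug placement
  fixed <- render_ihc_tile(0, tile_side_mm = 0.1, pixel_size_um = 2,
                           centers = rbind(c(10, 10), c(25, 25), c(40, 12)))
  expect_identical(fixed$true_count, 3L)

  # Poisson mean: density 50 on a 1 mm^2 tile, 200 seeds
  counts <- vapply(1:200, function(s) {
    render_ihc_tile(50, tile_side_mm = 1, pixel_size_um = 4,
                    nucleus_radius_um = 10, seed = s)$true_count
  }, integer(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 50), 3 * se)
})
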