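# small, fast configurations used throughout this file
small_cfg <- function(...) {
  args <- list(grid = list(nx = 20L, ny = 20L, nz = 40L, h = 1),
               duration_d = 6, dt_d = 0.5, seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}

test_that("transpiration demand is linear in fraction and biomass", {
  plant <- list(biomass = 0.5)
  expect_equal(transpiration_demand(plant, 0), 0)
  expect_equal(transpiration_demand(plant, 1, 100), 50)
  expect_equal(transpiration_demand(plant, 0.5, 100),
               transpiration_demand(plant, 1, 100) / 2)
  expect_error(transpiration_demand(plant, 1.5), "f_T")
})

test_that("a hairless axis inside one voxel reaches exactly that voxel", {
  g <- soil_grid(10, 10, 10, h = 2)
  seg <- list(x0 = 0.3, y0 = 0.2, z0 = 2.5, x1 = 0.3, y1 = 0.2, z1 = 3.4,
              radius_cm = 0.02, length_cm = 0.9)
  rv <- reachable_voxels(seg, 0, g)
  expect_equal(nrow(rv), 1L)
  expect_equal(rv$k, 2L)  # z in (2, 4)
  expect_equal(rv$weight, 0.9, tolerance = 1e-12)
})

test_that("reach grows monotonically with hair length and weights sum to length", {
  g <- soil_grid(30, 30, 30, h = 0.2)  # fine grid so reach spans voxels
  set.seed(4)
  for (case in 1:10) {
    p0 <- c(runif(2, -1, 1), runif(1, 1, 3))
    d <- runif(3, -0.4, 0.4)
    seg <- list(x0 = p0[1], y0 = p0[2], z0 = p0[3],
                x1 = p0[1] + d[1], y1 = p0[2] + d[2], z1 = p0[3] + d[3],
                radius_cm = 0.02, length_cm = sqrt(sum(d^2)))
    rv_short <- reachable_voxels(seg, 0.1, g)
    rv_long <- reachable_voxels(seg, 1, g)
    expect_true(all(rv_short$index %in% rv_long$index))
    expect_equal(sum(rv_short$weight), seg$length_cm, tolerance = 1e-9)
    expect_equal(sum(rv_long$weight), seg$length_cm, tolerance = 1e-9)
    # dense-sampling oracle: much finer spacing, same totals
    rv_dense <- reachable_voxels(seg, 1, g, spacing = 0.002)
    expect_equal(sum(rv_dense$weight), seg$length_cm, tolerance = 1e-9)
    agg <- merge(as.data.frame(rv_long)[, c("index", "weight")],
                 as.data.frame(rv_dense)[, c("index", "weight")],
                 by = "index", all = TRUE)
    agg[is.na(agg)] <- 0
    expect_lt(max(abs(agg$weight.x - agg$weight.y)), 0.05 * seg$length_cm)
  }
})

test_that("one-segment uptake equals the scalar hand calculation", {
  p <- architecture_params(
    elongation_rate = c(primary = 2, seminal = 0, lateral = 0),
    seminal_count = 0L, branching_interval_cm = 0,
    insertion_angle_deg = c(primary = 0, seminal = 0, lateral = 0),
    gravitropism_deg_per_cm = c(primary = 0, seminal = 0, lateral = 0),
    max_root_hair_length_mm = 0, root_hair_growth_rate_mm_d = 0,
    dt_max_d = 1)
  state <- grow(root_system_init(p, 1), p, 1)  # one 2 cm vertical segment
  expect_equal(nrow(state$segments), 1L)

  g <- soil_grid(4, 4, 4, h = 5)
  C0 <- 0.8
  g$C$nitrate[] <- C0
  g$initial_total["nitrate"] <- soil_total_n(g)
  cfg <- scenario_config(rhl_mm = 0, rhd_per_cm = 0,
                         grid = list(nx = 4L, ny = 4L, nz = 4L, h = 5),
                         kinetics = list(I_max = 0.05, K_m = 0.1), seed = 1)
  plant <- rhizoN:::new_plant_state(cfg$shoot)
  plant$biomass <- 0.4
  dt <- 0.25
  up <- uptake_step(state, g, plant, cfg, p, dt)

  A <- 2 * pi * 0.025 * 2
  demand <- 0.05 * C0 / (0.1 + C0) * A * dt
  delta <- sqrt(4 * g$D_e[["nitrate"]] * dt / g$b[["nitrate"]])
  n_acc <- C0 * g$b[["nitrate"]] * pi * (0.025 + delta)^2 * 2
  expect_gt(n_acc, demand)  # ample-N regime: the shell cap is slack
  E <- 1 * 100 * 0.4
  hand <- demand + E * C0 * dt
  expect_equal(up$plant$cum_uptake, hand, tolerance = 1e-10)
  expect_equal(up$plant$uptake_diffusive, demand, tolerance = 1e-10)
  expect_equal(up$plant$uptake_massflow, E * C0 * dt, tolerance = 1e-10)
  # soil lost exactly what the plant gained
  expect_equal(soil_total_n(g) - soil_total_n(up$grid), hand,
               tolerance = 1e-8)

  # zero concentration: zero uptake
  gz <- g; gz$C$nitrate[] <- 0
  upz <- uptake_step(state, gz, plant, cfg, p, dt)
  expect_equal(upz$plant$cum_uptake, 0)

  # saturation limit: K_m -> 0 with ample N gives I_max * A * dt
  cfg_s <- scenario_config(rhl_mm = 0, rhd_per_cm = 0,
                           grid = list(nx = 4L, ny = 4L, nz = 4L, h = 5),
                           kinetics = list(I_max = 0.05, K_m = 1e-12),
                           transpiration = 0, seed = 1)
  ups <- uptake_step(state, g, plant, cfg_s, p, dt)
  expect_equal(ups$plant$cum_uptake, 0.05 * A * dt, tolerance = 1e-6)
})

test_that("zero N supply yields zero uptake and the N-limited biomass floor", {
  res <- run_simulation(small_cfg(n_kg_ha = 0))
  expect_equal(res$final[["uptake_umol"]], 0)
  floor_b <- res$config$shoot$B0 +
    res$config$shoot$seed_reserve_umol / res$config$shoot$n_demand_umol_g
  expect_equal(res$final[["biomass_g"]], floor_b, tolerance = 1e-10)
})

test_that("a zero-duration run echoes the initial state", {
  res <- run_simulation(small_cfg(duration_d = 0))
  expect_equal(nrow(res$series), 1L)
  expect_equal(res$final[["uptake_umol"]], 0)
  expect_equal(res$final[["biomass_g"]], res$config$shoot$B0)
})

test_that("cumulative uptake survives an independent conservation audit", {
  res <- run_simulation(small_cfg(seed = 21))
  # audit: N that left the soil equals N credited to the plant
  soil_loss <- res$grid$initial_total[["nitrate"]] -
    soil_total_n(res$grid, "nitrate")
  expect_equal(soil_loss, res$final[["uptake_umol"]],
               tolerance = 1e-8 * res$grid$initial_total[["nitrate"]])
  expect_lt(res$conservation_residual, 1e-8)
  # the split ledgers add up exactly
  expect_equal(res$final[["uptake_umol"]],
               res$final[["uptake_diffusive_umol"]] +
                 res$final[["uptake_massflow_umol"]], tolerance = 1e-12)
  # series is monotone in time
  expect_true(all(diff(res$series$uptake_umol) >= 0))
  expect_true(all(diff(res$series$biomass_g) >= 0))
})

test_that("the mass-flow ledger is identically zero without transpiration", {
  res <- run_simulation(small_cfg(transpiration = 0, seed = 3))
  expect_identical(res$final[["uptake_massflow_umol"]], 0)
  expect_gt(res$final[["uptake_diffusive_umol"]], 0)
})

test_that("simulations are deterministic given the scenario seed", {
  r1 <- run_simulation(small_cfg(duration_d = 3, seed = 17))
  r2 <- run_simulation(small_cfg(duration_d = 3, seed = 17))
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final, r2$final)
})

test_that("a depletion zone forms around roots under pure diffusion", {
  cfg <- small_cfg(transpiration = 0, seed = 5,
                   soil = list(D_e = c(nitrate = 0.01)))
  res <- run_simulation(cfg)
  seg <- res$state$segments
  lh <- rhizoN:::segment_hair_length(seg, architecture_params(
    max_root_hair_length_mm = cfg$rhl_mm,
    root_hair_growth_rate_mm_d = cfg$rhl_mm / 2), res$state$time)
  m <- rhizoN:::map_segments_to_voxels(seg, seg[, "radius"] + lh / 10,
                                       res$grid, 0.1)
  root_vox <- unique(m$vox)
  C <- res$grid$C$nitrate
  expect_lt(mean(C[root_vox]), mean(C))
})

test_that("sweeps enumerate the factorial design and stay tidy", {
  base <- scenario_config(grid = list(nx = 10L, ny = 10L, nz = 20L, h = 2),
                          duration_d = 3, dt_d = 0.5)
  one <- run_sweep(0.5, 500, 104, 1, base = base)
  expect_equal(nrow(one), 1L)
  expect_s3_class(one, "sweep_table")

  four <- run_sweep(c(0, 1), c(100, 1000), 104, 1, base = base)
  expect_equal(nrow(four), 4L)
  expect_equal(nrow(unique(four[, c("rhl_mm", "rhd_per_cm")])), 4L)
  expect_named(four, c("rhl_mm", "rhd_per_cm", "n_kg_ha",
                       "transpiration_pct", "replicate", "seed",
                       "uptake_umol", "uptake_massflow_umol",
                       "uptake_diffusive_umol", "root_length_cm",
                       "area_cm2", "area_hairs_cm2",
                       "conservation_residual"))
  expect_true(all(four$conservation_residual < 1e-8))

  csv <- tempfile(fileext = ".csv")
  write_sweep_csv(four, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$uptake_umol, four$uptake_umol, tolerance = 1e-12)
  unlink(csv)
})

test_that("interrupted sweeps resume from the cell cache", {
  base <- scenario_config(grid = list(nx = 10L, ny = 10L, nz = 20L, h = 2),
                          duration_d = 2, dt_d = 0.5)
  cache <- tempfile("sweepcache")
  t1 <- run_sweep(c(0, 1), 500, 104, 1, base = base, cache_dir = cache)
  t2 <- run_sweep(c(0, 1), 500, 104, 1, base = base, cache_dir = cache)
  expect_identical(t1$uptake_umol, t2$uptake_umol)
  expect_equal(length(list.files(cache)), 2L)
  unlink(cache, recursive = TRUE)
})

test_that("scenario validation warns outside the calibrated phene range", {
  expect_warning(scenario_config(rhl_mm = 2), "calibrated")
  expect_warning(scenario_config(rhd_per_cm = 50), "calibrated")
  expect_error(scenario_config(transpiration = 2), "0, 1")
  expect_error(scenario_config(n_kg_ha = -5), ">= 0")
  expect_silent(scenario_config())
})
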