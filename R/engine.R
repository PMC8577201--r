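#' Scenario configuration for one simulated plant
#'
#' Bundles everything one in-silico plant needs: the root hair phenes
#' (maximum hair length and hair density), soil N supply as a field-style
#' application rate, the transpiration fraction dialling mass flow, grid
#' geometry, Michaelis-Menten uptake kinetics, the water-use coefficient
#' and the scenario seed. Hair lengths outside the 0-1 mm range or
#' densities outside 100-1000 per cm are outside the calibrated phenotype
#' range and trigger a warning (not an error).
#'
#' @param rhl_mm Maximum root hair length (mm).
#' @param rhd_per_cm Root hair density (hairs per cm of axis).
#' @param n_kg_ha N application rate (kg N ha^-1), all as nitrate.
#' @param transpiration Transpiration fraction `f_T` in \[0, 1\] (1 = 100
#'   percent of potential water use).
#' @param duration_d Simulated duration (days), default 15.
#' @param dt_d Engine time step (days), default 0.25.
#' @param grid List `nx, ny, nz, h` (voxel counts and edge, cm). The
#'   default is a 20 x 20 x 40 cm closed box at 5 mm resolution.
#' @param kinetics List `I_max` (umol cm^-2 d^-1) and `K_m` (umol cm^-3
#'   soil solution).
#' @param water_use_cm3_g_d Water-use coefficient `W`: potential
#'   transpiration per g shoot biomass per day (default 100 cm^3 g^-1 d^-1).
#' @param shoot List of shoot-growth parameters: `B0` initial biomass (g),
#'   `r` logistic rate (d^-1), `K` logistic ceiling (g), `n_demand_umol_g`
#'   structural N demand per g new biomass, `seed_reserve_umol` seed N
#'   reserve.
#' @param soil List of soil overrides (`b`, `D_e`, `theta`; named per
#'   species).
#' @param arch Named list of additional [architecture_params()] overrides.
#' @param sample_spacing_cm Axial spacing of root sample points used to
#'   map segments onto voxels.
#' @param seed Integer scenario seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(rhl_mm = 0.5, rhd_per_cm = 500, n_kg_ha = 104,
                            transpiration = 1.0, duration_d = 15,
                            dt_d = 0.25,
                            grid = list(nx = 40L, ny = 40L, nz = 80L, h = 0.5),
                            kinetics = list(I_max = 2, K_m = 0.05),
                            water_use_cm3_g_d = 100,
                            shoot = list(B0 = 0.05, r = 0.35, K = 5,
                                         n_demand_umol_g = 1500,
                                         seed_reserve_umol = 400),
                            soil = list(),
                            arch = list(),
                            sample_spacing_cm = 0.1,
                            seed = 1L) {
  if (rhl_mm < 0 || rhd_per_cm < 0) {
    stop("Hair length and density must be >= 0.", call. = FALSE)
  }
  if (rhl_mm > 1 || (rhd_per_cm > 0 && (rhd_per_cm < 100 || rhd_per_cm > 1000))) {
    warning("Root hair phenotype outside the calibrated range (0-1 mm, 100-1000 per cm).",
            call. = FALSE)
  }
  if (transpiration < 0 || transpiration > 1) {
    stop("`transpiration` must lie in [0, 1].", call. = FALSE)
  }
  if (duration_d < 0) stop("`duration_d` must be >= 0.", call. = FALSE)
  if (dt_d <= 0) stop("`dt_d` must be > 0.", call. = FALSE)
  if (kinetics$K_m <= 0) stop("`K_m` must be > 0.", call. = FALSE)
  if (n_kg_ha < 0) stop("`n_kg_ha` must be >= 0.", call. = FALSE)
  structure(
    list(rhl_mm = rhl_mm, rhd_per_cm = rhd_per_cm, n_kg_ha = n_kg_ha,
         transpiration = transpiration, duration_d = duration_d, dt_d = dt_d,
         grid = grid, kinetics = kinetics,
         water_use_cm3_g_d = water_use_cm3_g_d, shoot = shoot, soil = soil,
         arch = arch, sample_spacing_cm = sample_spacing_cm,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> RHL %g mm, RHD %g /cm, N %g kg/ha, transpiration %g%%, %g d (seed %d)\n",
    x$rhl_mm, x$rhd_per_cm, x$n_kg_ha, 100 * x$transpiration, x$duration_d,
    x$seed))
  invisible(x)
}

#' Daily transpiration demand of the shoot
#'
#' `f_T x W x shoot biomass`: the potential water use of the shoot (W cm^3
#' of water per g biomass per day) scaled by the transpiration fraction.
#' This is the dial that controls convective (mass-flow) N delivery to the
#' root surfaces.
#'
#' @param plant A `plant_state` (or any list with `$biomass` in g).
#' @param f_T Transpiration fraction in \[0, 1\].
#' @param W Water-use coefficient (cm^3 g^-1 d^-1).
#' @return Water demand in cm^3 d^-1.
#' @export
transpiration_demand <- function(plant, f_T, W = 100) {
  stopifnot(f_T >= 0, f_T <= 1, W >= 0)
  f_T * W * plant$biomass
}

new_plant_state <- function(shoot) {
  structure(
    list(biomass = shoot$B0, cum_uptake = 0, uptake_diffusive = 0,
         uptake_massflow = 0,
         n_content = shoot$seed_reserve_umol, time = 0),
    class = "plant_state")
}

# --- segment -> voxel mapping ------------------------------------------------

# Sample points along every segment (matrix rows) at roughly `spacing` cm;
# returns parallel vectors: segment row index, voxel linear index and
# weight (cm of axis), after splitting each point's weight equally over the
# voxels whose centers lie within `reach` of it (the containing voxel is
# always included, so hairless roots map to the voxels holding the axis).
map_segments_to_voxels <- function(seg, reach, grid, spacing) {
  n_seg <- nrow(seg)
  if (n_seg == 0L) {
    return(list(seg = integer(0), vox = integer(0), w = numeric(0),
                dropped = 0))
  }
  len <- seg[, "length"]
  npts <- pmax(1L, ceiling(len / spacing))
  seg_idx <- rep.int(seq_len(n_seg), npts)
  frac <- (sequence(npts) - 0.5) / rep.int(npts, npts)
  px <- seg[seg_idx, "x0"] + (seg[seg_idx, "x1"] - seg[seg_idx, "x0"]) * frac
  py <- seg[seg_idx, "y0"] + (seg[seg_idx, "y1"] - seg[seg_idx, "y0"]) * frac
  pz <- seg[seg_idx, "z0"] + (seg[seg_idx, "z1"] - seg[seg_idx, "z0"]) * frac
  w <- rep.int(len / npts, npts)

  h <- grid$h
  nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
  # domain: x, y centered on the seed, z downward from the surface
  ix <- floor(px / h + nx / 2) + 1
  iy <- floor(py / h + ny / 2) + 1
  iz <- floor(pz / h) + 1
  iz[pz == 0] <- 1L  # seed sits exactly on the surface
  inside <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & iz >= 1 & iz <= nz
  dropped <- sum(w[!inside])
  if (!any(inside)) {
    return(list(seg = integer(0), vox = integer(0), w = numeric(0),
                dropped = dropped))
  }
  seg_idx <- seg_idx[inside]; w <- w[inside]
  px <- px[inside]; py <- py[inside]; pz <- pz[inside]
  ix <- ix[inside]; iy <- iy[inside]; iz <- iz[inside]

  reach_pt <- reach[seg_idx]
  smax <- max(1L, ceiling(max(reach_pt) / h))
  # candidate voxels per point: containing voxel plus in-reach neighbours
  cx0 <- (ix - 0.5 - nx / 2) * h
  cy0 <- (iy - 0.5 - ny / 2) * h
  cz0 <- (iz - 0.5) * h
  cand_seg <- list(); cand_vox <- list(); cand_pt <- list()
  npt <- length(px)
  pt_id <- seq_len(npt)
  k <- 0L
  for (di in -smax:smax) for (dj in -smax:smax) for (dk in -smax:smax) {
    if (di == 0L && dj == 0L && dk == 0L) {
      sel <- pt_id
      jx <- ix; jy <- iy; jz <- iz
    } else {
      d2 <- (cx0 + di * h - px)^2 + (cy0 + dj * h - py)^2 +
        (cz0 + dk * h - pz)^2
      ok <- d2 <= reach_pt^2
      jx <- ix + di; jy <- iy + dj; jz <- iz + dk
      ok <- ok & jx >= 1 & jx <= nx & jy >= 1 & jy <= ny & jz >= 1 & jz <= nz
      if (!any(ok)) next
      sel <- pt_id[ok]
      jx <- jx[ok]; jy <- jy[ok]; jz <- jz[ok]
    }
    k <- k + 1L
    cand_pt[[k]] <- sel
    cand_vox[[k]] <- jx + (jy - 1) * nx + (jz - 1) * nx * ny
  }
  pt_all <- unlist(cand_pt, use.names = FALSE)
  vox_all <- unlist(cand_vox, use.names = FALSE)
  n_cand <- tabulate(pt_all, nbins = npt)
  w_all <- (w / n_cand)[pt_all]
  list(seg = seg_idx[pt_all], vox = as.integer(vox_all), w = w_all,
       dropped = dropped)
}

#' Voxels reachable by one root segment
#'
#' Returns the soil voxels a segment can draw N from: those whose centers
#' lie within `radius + hair length` of points along the axis, each voxel
#' weighted by the axis length it serves (weights sum to the segment
#' length). A hairless segment reaches only the voxel(s) containing the
#' axis.
#'
#' @param segment A single-row segment table (see [root_segments()]) or a
#'   named list with `x0..z1`, `radius_cm`, `length_cm`.
#' @param hair_length_mm Current hair length on the segment (mm).
#' @param grid A `soil_grid`.
#' @param spacing Axial sampling distance (cm).
#' @return Tibble with voxel indices `i, j, k`, linear `index`, and
#'   `weight` (cm).
#' @export
reachable_voxels <- function(segment, hair_length_mm, grid, spacing = 0.02) {
  stopifnot(inherits(grid, "soil_grid"), hair_length_mm >= 0)
  seg <- matrix(c(segment$x0, segment$y0, segment$z0,
                  segment$x1, segment$y1, segment$z1,
                  segment$radius_cm, segment$length_cm),
                nrow = 1,
                dimnames = list(NULL, c("x0", "y0", "z0", "x1", "y1", "z1",
                                        "radius", "length")))
  reach <- segment$radius_cm + hair_length_mm / 10
  m <- map_segments_to_voxels(seg, reach, grid, spacing)
  if (length(m$vox) == 0L) {
    return(tibble::tibble(i = integer(0), j = integer(0), k = integer(0),
                          index = integer(0), weight = numeric(0)))
  }
  agg <- rowsum(m$w, m$vox, reorder = TRUE)
  vox <- as.integer(rownames(agg))
  nx <- grid$nx; ny <- grid$ny
  k <- (vox - 1L) %/% (nx * ny) + 1L
  j <- ((vox - 1L) %% (nx * ny)) %/% nx + 1L
  i <- (vox - 1L) %% nx + 1L
  tibble::tibble(i = i, j = j, k = k, index = vox,
                 weight = unname(agg[, 1L]))
}

# --- uptake ------------------------------------------------------------------

#' One uptake step: Michaelis-Menten influx plus mass flow
#'
#' For every segment, active (diffusive-pathway) uptake follows
#' Michaelis-Menten kinetics on the reach-weighted mean concentration,
#' applied to the full absorptive area (root cylinder plus hairs) and
#' capped by the N accessible within the segment's depletion shell (the
#' cylinder of radius `root radius + hair length + sqrt(4 D_e dt / b)`,
#' i.e. how far hairs plus one step of diffusive resupply can reach below
#' voxel resolution). Mass-flow delivery is the segment's share of the
#' transpiration stream times the local concentration. Withdrawals from
#' shared voxels are rationed proportionally, which is where hair-hair and
#' root-root competition emerges. Concentrations never go negative; plant
#' ledgers split uptake into its diffusive and mass-flow components
#' exactly.
#'
#' @param state A `root_system`.
#' @param grid A `soil_grid`.
#' @param plant A `plant_state`.
#' @param config A `scenario_config`.
#' @param params The `architecture_params` in force.
#' @param dt Time step (days).
#' @param species Soil species tapped (default nitrate).
#' @return List `(grid, plant)` after the step.
#' @export
uptake_step <- function(state, grid, plant, config, params, dt,
                        species = "nitrate") {
  stopifnot(dt > 0)
  seg <- state$segments
  if (nrow(seg) == 0L) return(list(grid = grid, plant = plant))
  lh_mm <- segment_hair_length(seg, params, state$time)
  lh_cm <- lh_mm / 10
  reach <- seg[, "radius"] + lh_cm
  m <- map_segments_to_voxels(seg, reach, grid, config$sample_spacing_cm)
  if (length(m$vox) == 0L) return(list(grid = grid, plant = plant))

  nvox <- grid$nx * grid$ny * grid$nz
  key <- (m$seg - 1) * as.double(nvox) + m$vox
  agg <- rowsum(cbind(m$w, m$w * grid$C[[species]][m$vox]), key,
                reorder = FALSE)
  keys <- as.double(rownames(agg))
  sv_seg <- as.integer((keys - 1) %/% nvox + 1)
  sv_vox <- as.integer(keys - (sv_seg - 1) * as.double(nvox))
  sumW <- rowsum(agg[, 1L], sv_seg, reorder = FALSE)
  sumWC <- rowsum(agg[, 2L], sv_seg, reorder = FALSE)
  seg_ids <- as.integer(rownames(sumW))
  cbar <- numeric(nrow(seg))
  cbar[seg_ids] <- ifelse(sumW[, 1L] > 0, sumWC[, 1L] / sumW[, 1L], 0)

  L <- seg[, "length"]
  area <- 2 * pi * seg[, "radius"] * L +
    params$root_hair_density_per_cm * L * 2 * pi * params$hair_radius_cm * lh_cm
  I_max <- config$kinetics$I_max
  K_m <- config$kinetics$K_m
  demand <- I_max * cbar / (K_m + cbar) * area * dt

  # sub-voxel depletion cap: N accessible inside the hair + resupply shell
  delta <- sqrt(4 * grid$D_e[[species]] * dt / grid$b[[species]])
  v_shell <- pi * (seg[, "radius"] + lh_cm + delta)^2 * L
  n_acc <- cbar * grid$b[[species]] * v_shell
  diffusive <- pmin(demand, n_acc)

  E <- transpiration_demand(plant, config$transpiration,
                            config$water_use_cm3_g_d)
  a_tot <- sum(area)
  w_seg <- if (a_tot > 0) E * area / a_tot else rep(0, length(area))
  massflow <- w_seg * cbar * dt

  request <- diffusive + massflow
  # distribute each segment's request over its voxels, concentration-weighted
  denom <- numeric(nrow(seg))
  denom[seg_ids] <- sumWC[, 1L]
  wc <- agg[, 2L]
  req_entry <- ifelse(denom[sv_seg] > 0,
                      request[sv_seg] * wc / denom[sv_seg], 0)
  res <- withdraw_many(grid, sv_vox, req_entry, species)
  grid <- res$grid
  got <- rowsum(res$taken, sv_seg, reorder = FALSE)[, 1L]
  actual <- numeric(nrow(seg))
  actual[seg_ids] <- got
  frac_mf <- ifelse(request > 0, massflow / request, 0)

  plant$uptake_massflow <- plant$uptake_massflow + sum(actual * frac_mf)
  plant$uptake_diffusive <- plant$uptake_diffusive + sum(actual * (1 - frac_mf))
  plant$cum_uptake <- plant$uptake_massflow + plant$uptake_diffusive
  plant$n_content <- config$shoot$seed_reserve_umol + plant$cum_uptake
  list(grid = grid, plant = plant)
}

logistic_biomass <- function(t, shoot) {
  shoot$K * shoot$B0 * exp(shoot$r * t) /
    (shoot$K + shoot$B0 * (exp(shoot$r * t) - 1))
}

#' Run one scenario
#'
#' The daily loop couples the modules: grow the architecture (hairs ride
#' the same clock), diffuse soil N (subcycled to the explicit-scheme
#' stability bound), take up N, and update shoot biomass as the minimum of
#' the potential logistic trajectory and the N-limited trajectory
#' `B0 + plant N / structural demand`. Deterministic given the scenario
#' seed; the result carries the conservation residual of the full run.
#'
#' @param config A `scenario_config`.
#' @return A `simulation_result`: list with `series` (one row per day:
#'   time, biomass, cumulative/diffusive/mass-flow uptake, plant N, root
#'   length, areas), `final` (named summary), `config`, and
#'   `conservation_residual`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  g_h <- if (config$rhl_mm > 0) config$rhl_mm / 2 else 0
  arch_args <- c(
    list(max_root_hair_length_mm = config$rhl_mm,
         root_hair_density_per_cm = config$rhd_per_cm,
         root_hair_growth_rate_mm_d = g_h),
    config$arch)
  params <- do.call(architecture_params, arch_args)

  soil_args <- list(nx = config$grid$nx, ny = config$grid$ny,
                    nz = config$grid$nz, h = config$grid$h,
                    species = "nitrate")
  for (nm in intersect(names(config$soil), c("b", "D_e", "theta"))) {
    soil_args[[nm]] <- config$soil[[nm]]
  }
  if (!is.null(soil_args$b) && is.null(names(soil_args$b))) {
    names(soil_args$b) <- "nitrate"
  }
  if (!is.null(soil_args$D_e) && is.null(names(soil_args$D_e))) {
    names(soil_args$D_e) <- "nitrate"
  }
  grid <- do.call(soil_grid, soil_args)
  grid <- init_from_application_rate(config$n_kg_ha, grid, "nitrate")

  state <- root_system_init(params, config$seed)
  plant <- new_plant_state(config$shoot)

  record <- function(state, plant) {
    tibble::tibble(
      time_d = state$time,
      biomass_g = plant$biomass,
      uptake_umol = plant$cum_uptake,
      uptake_diffusive_umol = plant$uptake_diffusive,
      uptake_massflow_umol = plant$uptake_massflow,
      plant_n_umol = plant$n_content,
      root_length_cm = total_root_length(state),
      area_cm2 = absorptive_surface_area(state, params, FALSE),
      area_hairs_cm2 = absorptive_surface_area(state, params, TRUE))
  }

  rows <- list(record(state, plant))
  if (config$duration_d > 0) {
    n_steps <- ceiling(config$duration_d / config$dt_d - 1e-9)
    dt <- config$duration_d / n_steps
    stable <- diffusion_stable_dt(grid, "nitrate")
    n_sub <- max(1L, ceiling(dt / stable + 1e-12))
    next_record <- 1
    for (s in seq_len(n_steps)) {
      state <- grow(state, params, dt)
      for (i in seq_len(n_sub)) grid <- diffuse(grid, dt / n_sub, "nitrate")
      up <- uptake_step(state, grid, plant, config, params, dt)
      grid <- up$grid
      plant <- up$plant
      plant$biomass <- min(logistic_biomass(state$time, config$shoot),
                           config$shoot$B0 +
                             plant$n_content / config$shoot$n_demand_umol_g)
      plant$time <- state$time
      if (state$time >= next_record - 1e-9) {
        rows[[length(rows) + 1L]] <- record(state, plant)
        next_record <- next_record + 1
      }
    }
  }
  series <- dplyr::bind_rows(rows)
  residual <- conservation_residual(grid, "nitrate")
  last <- series[nrow(series), ]
  structure(
    list(series = series,
         final = c(uptake_umol = last$uptake_umol,
                   uptake_diffusive_umol = last$uptake_diffusive_umol,
                   uptake_massflow_umol = last$uptake_massflow_umol,
                   biomass_g = last$biomass_g,
                   root_length_cm = last$root_length_cm,
                   area_cm2 = last$area_cm2,
                   area_hairs_cm2 = last$area_hairs_cm2),
         config = config,
         conservation_residual = residual,
         state = state, grid = grid, plant = plant),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %g d: uptake %.1f umol (%.1f diffusive + %.1f mass flow), biomass %.2f g\n",
    x$config$duration_d, x$final["uptake_umol"],
    x$final["uptake_diffusive_umol"], x$final["uptake_massflow_umol"],
    x$final["biomass_g"]))
  cat(sprintf("  root length %.1f cm, area %.1f (bare) / %.1f (hairs) cm2, conservation residual %.2g\n",
              x$final["root_length_cm"], x$final["area_cm2"],
              x$final["area_hairs_cm2"], x$conservation_residual))
  invisible(x)
}

#' Run a factorial sweep over root hair and supply factors
#'
#' Full Cartesian product of hair length x hair density x N rate x
#' transpiration fraction (the reference design is 7 x 3 x 3 x 4 = 252
#' scenarios), each cell with its own derived seed. Failed cells are
#' recorded and skipped, not fatal. When `cache_dir` is given, finished
#' cells are cached by configuration hash so an interrupted sweep resumes.
#'
#' @param rhl_levels Hair lengths (mm), e.g. `c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1)`.
#' @param rhd_levels Hair densities (per cm), e.g. `c(100, 500, 1000)`.
#' @param n_levels N application rates (kg ha^-1), e.g. `c(62.4, 104, 145.6)`.
#' @param transpiration_levels Transpiration fractions, e.g.
#'   `c(0.25, 0.5, 0.75, 1)`.
#' @param base A `scenario_config` supplying everything else.
#' @param replicates Replicates per cell (default 1; the engine is
#'   deterministic per seed, so replicates differ only through the seed).
#' @param seed Master seed; each cell gets an independent derived seed.
#' @param common_seed Use the master seed itself for every cell instead of
#'   derived per-cell seeds. With a common seed the root architecture is
#'   identical across hair-phene levels (hair length and density do not
#'   touch axis geometry), which isolates the hair effect for
#'   monotonicity audits.
#' @param cache_dir Optional directory for resumable cell caching.
#' @param quiet Suppress per-cell progress messages?
#' @return A `sweep_table` tibble with one row per cell x replicate and
#'   columns `rhl_mm, rhd_per_cm, n_kg_ha, transpiration_pct, replicate,
#'   seed, uptake_umol, uptake_massflow_umol, uptake_diffusive_umol,
#'   root_length_cm, area_cm2, area_hairs_cm2, conservation_residual`.
#'   Failures are collected in the `failures` attribute.
#' @export
run_sweep <- function(rhl_levels = c(0, 0.1, 0.3, 0.5, 0.7, 0.9, 1),
                      rhd_levels = c(100, 500, 1000),
                      n_levels = c(62.4, 104, 145.6),
                      transpiration_levels = c(0.25, 0.5, 0.75, 1),
                      base = scenario_config(),
                      replicates = 1L,
                      seed = base$seed,
                      common_seed = FALSE,
                      cache_dir = NULL,
                      quiet = TRUE) {
  stopifnot(length(rhl_levels) > 0, length(rhd_levels) > 0,
            length(n_levels) > 0, length(transpiration_levels) > 0,
            replicates >= 1L)
  design <- expand.grid(replicate = seq_len(replicates),
                        rhl_mm = rhl_levels, rhd_per_cm = rhd_levels,
                        n_kg_ha = n_levels,
                        transpiration = transpiration_levels,
                        KEEP.OUT.ATTRS = FALSE)
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  failures <- list()
  rows <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    cell <- design[r, ]
    cell_seed <- if (common_seed) as.integer(seed) else
      as.integer((as.double(seed) * 7919 + r * 104729) %% 2147483647)
    cfg <- scenario_config(
      rhl_mm = cell$rhl_mm, rhd_per_cm = cell$rhd_per_cm,
      n_kg_ha = cell$n_kg_ha, transpiration = cell$transpiration,
      duration_d = base$duration_d, dt_d = base$dt_d, grid = base$grid,
      kinetics = base$kinetics, water_use_cm3_g_d = base$water_use_cm3_g_d,
      shoot = base$shoot, soil = base$soil, arch = base$arch,
      sample_spacing_cm = base$sample_spacing_cm, seed = cell_seed)
    cache_file <- if (!is.null(cache_dir)) {
      file.path(cache_dir, paste0(config_hash(cfg), ".rds"))
    }
    row <- NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      row <- readRDS(cache_file)
    } else {
      t0 <- Sys.time()
      res <- tryCatch(run_simulation(cfg), error = function(e) e)
      if (inherits(res, "error")) {
        failures[[length(failures) + 1L]] <-
          list(cell = cell, message = conditionMessage(res))
        if (!quiet) message(sprintf("cell %d FAILED: %s", r,
                                    conditionMessage(res)))
      } else {
        row <- tibble::tibble(
          rhl_mm = cell$rhl_mm, rhd_per_cm = cell$rhd_per_cm,
          n_kg_ha = cell$n_kg_ha,
          transpiration_pct = 100 * cell$transpiration,
          replicate = cell$replicate, seed = cell_seed,
          uptake_umol = res$final[["uptake_umol"]],
          uptake_massflow_umol = res$final[["uptake_massflow_umol"]],
          uptake_diffusive_umol = res$final[["uptake_diffusive_umol"]],
          root_length_cm = res$final[["root_length_cm"]],
          area_cm2 = res$final[["area_cm2"]],
          area_hairs_cm2 = res$final[["area_hairs_cm2"]],
          conservation_residual = res$conservation_residual)
        if (!is.null(cache_file)) saveRDS(row, cache_file)
        if (!quiet) {
          message(sprintf("cell %d/%d done in %.1f s", r, nrow(design),
                          as.numeric(Sys.time() - t0, units = "secs")))
        }
      }
    }
    rows[[r]] <- row
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- failures
  class(out) <- c("sweep_table", class(out))
  out
}

#' Stable hash of a configuration (key order independent)
#'
#' @param config Any list-like configuration.
#' @return A short hex string.
#' @export
config_hash <- function(config) {
  canonical <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  rlang::hash(canonical(unclass(config)))
}

#' Write a sweep table to the canonical CSV layout
#'
#' @param sweep A `sweep_table`.
#' @param path Output CSV path.
#' @export
write_sweep_csv <- function(sweep, path) {
  cols <- c("rhl_mm", "rhd_per_cm", "n_kg_ha", "transpiration_pct",
            "replicate", "seed", "uptake_umol", "uptake_massflow_umol",
            "uptake_diffusive_umol", "root_length_cm", "area_cm2",
            "area_hairs_cm2", "conservation_residual")
  utils::write.csv(as.data.frame(sweep)[, cols], path, row.names = FALSE)
  invisible(path)
}
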