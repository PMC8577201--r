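#' Create a voxelized soil nitrogen grid
#'
#' The soil is a closed box of `nx x ny x nz` cubic voxels of edge `h` cm,
#' z increasing downward from the surface. Each mineral N species (nitrate,
#' ammonium) carries a solution concentration field `C` in umol per cm^3 of
#' soil volume, a constant buffer capacity `b` (ratio of total to dissolved
#' N; sorbed N is always in local equilibrium with solution), and an
#' effective diffusion coefficient `D_e` in cm^2 d^-1. All faces are
#' zero-flux, so total N changes only through logged withdrawals (root
#' uptake) and the conservation ledger is exactly auditable.
#'
#' Defaults reflect the species contrast that makes ammonium
#' diffusion-limited relative to nitrate: ammonium is strongly sorbed
#' (large `b`) and diffuses slowly, nitrate is mobile.
#'
#' @param nx,ny,nz Voxel counts along x, y, z.
#' @param h Voxel edge length (cm).
#' @param species Character vector of species names to carry.
#' @param b Named buffer capacities (>= 1), one per species.
#' @param D_e Named effective diffusivities (cm^2 d^-1), one per species.
#' @param theta Volumetric water content (0 < theta < 1).
#' @return A `soil_grid` object.
#' @export
soil_grid <- function(nx, ny, nz, h,
                      species = c("nitrate", "ammonium"),
                      b = c(nitrate = 2, ammonium = 10),
                      D_e = c(nitrate = 0.05, ammonium = 0.005),
                      theta = 0.3) {
  stopifnot(nx >= 1L, ny >= 1L, nz >= 1L, h > 0, theta > 0, theta < 1)
  if (!all(species %in% names(b)) || !all(species %in% names(D_e))) {
    stop("`b` and `D_e` must be named for every species.", call. = FALSE)
  }
  if (any(b[species] < 1)) stop("Buffer capacity must be >= 1.", call. = FALSE)
  if (any(D_e[species] < 0)) stop("D_e must be >= 0.", call. = FALSE)
  fields <- lapply(species, function(s) array(0, dim = c(nx, ny, nz)))
  names(fields) <- species
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         h = h, species = species, C = fields,
         b = b[species], D_e = D_e[species], theta = theta,
         withdrawn = stats::setNames(numeric(length(species)), species),
         initial_total = stats::setNames(numeric(length(species)), species)),
    class = "soil_grid"
  )
}

#' @export
print.soil_grid <- function(x, ...) {
  cat(sprintf("<soil_grid> %d x %d x %d voxels, h = %g cm (%g x %g x %g cm)\n",
              x$nx, x$ny, x$nz, x$h, x$nx * x$h, x$ny * x$h, x$nz * x$h))
  for (s in x$species) {
    cat(sprintf("  %-9s total %.4g umol (b = %g, D_e = %g cm2/d), withdrawn %.4g umol\n",
                s, soil_total_n(x, s), x$b[[s]], x$D_e[[s]], x$withdrawn[[s]]))
  }
  invisible(x)
}

#' Total N held in the grid for one species
#'
#' Counts dissolved plus sorbed N: `sum(C) * b * h^3` (umol).
#'
#' @param grid A `soil_grid`.
#' @param species Species name.
#' @export
soil_total_n <- function(grid, species = "nitrate") {
  stopifnot(inherits(grid, "soil_grid"), species %in% grid$species)
  sum(grid$C[[species]]) * grid$b[[species]] * grid$h^3
}

#' Initialize a grid from a field-style N application rate
#'
#' Converts an areal application rate in kg N per hectare into voxel
#' concentrations: 1 kg ha^-1 = 1e-8 kg cm^-2 = 0.01 mg cm^-2 of ground
#' area, i.e. `rate * 10 / 14.007` umol N cm^-2. The areal amount is
#' distributed over the soil column either uniformly or with an
#' exponentially decaying depth profile; the voxel totals sum exactly to
#' `rate x ground area`.
#'
#' @param rate Application rate (kg N ha^-1), >= 0.
#' @param grid A `soil_grid` (or arguments for one via `...` is not
#'   supported; build the grid first).
#' @param species Which species receives the N (default nitrate).
#' @param profile `"uniform"` or `"exponential"`.
#' @param z_scale Decay length (cm) of the exponential profile.
#' @return The grid with the species field loaded and its conservation
#'   ledger reset.
#' @examples
#' g <- soil_grid(4, 4, 8, h = 5)
#' g <- init_from_application_rate(104, g)
#' soil_total_n(g)  # 104 kg/ha over a 20 x 20 cm box -> 2.97e4 umol
#' @export
init_from_application_rate <- function(rate, grid, species = "nitrate",
                                       profile = c("uniform", "exponential"),
                                       z_scale = 15) {
  stopifnot(inherits(grid, "soil_grid"), species %in% grid$species)
  profile <- match.arg(profile)
  if (rate < 0) stop("Application rate must be >= 0.", call. = FALSE)
  if (grid$nz < 1L) stop("Zero-depth domain.", call. = FALSE)
  umol_per_cm2 <- rate * 1e-8 * 1e9 / 14.007   # kg/ha -> ug/cm2 -> umol/cm2
  # column weights over nz layers, summing to 1 exactly
  w <- switch(profile,
    uniform = rep(1 / grid$nz, grid$nz),
    exponential = {
      zc <- (seq_len(grid$nz) - 0.5) * grid$h
      raw <- exp(-zc / z_scale)
      raw / sum(raw)
    })
  # total (dissolved + sorbed) concentration per voxel, then solution C
  layer_total_conc <- umol_per_cm2 * w / grid$h      # umol per cm3 soil
  C <- array(0, dim = c(grid$nx, grid$ny, grid$nz))
  for (k in seq_len(grid$nz)) {
    C[, , k] <- layer_total_conc[k] / grid$b[[species]]
  }
  grid$C[[species]] <- C
  grid$withdrawn[[species]] <- 0
  grid$initial_total[[species]] <- soil_total_n(grid, species)
  grid
}

# explicit-scheme stability bound for one diffusion step (days)
diffusion_stable_dt <- function(grid, species) {
  if (grid$D_e[[species]] <= 0) return(Inf)
  grid$b[[species]] * grid$h^2 / (6 * grid$D_e[[species]])
}

#' One explicit buffered-diffusion step
#'
#' Advances `b dC/dt = D_e lap(C)` by one explicit 6-neighbour
#' finite-difference step with zero-flux boundaries, in flux form so total
#' N is conserved to rounding. The step refuses `dt` beyond the stability
#' bound `b h^2 / (6 D_e)`; the simulation engine subcycles instead.
#'
#' @param grid A `soil_grid`.
#' @param dt Time step (days).
#' @param species Species to diffuse; default all carried species.
#' @return The updated grid.
#' @export
diffuse <- function(grid, dt, species = grid$species) {
  stopifnot(inherits(grid, "soil_grid"), dt > 0)
  for (s in species) {
    if (grid$D_e[[s]] <= 0) next
    bound <- diffusion_stable_dt(grid, s)
    if (dt > bound * (1 + 1e-12)) {
      stop(sprintf(
        "dt = %g d exceeds the stability bound %g d for species '%s'; subcycle the call.",
        dt, bound, s), call. = FALSE)
    }
    alpha <- grid$D_e[[s]] * dt / (grid$b[[s]] * grid$h^2)
    C <- grid$C[[s]]
    nx <- grid$nx; ny <- grid$ny; nz <- grid$nz
    if (nx > 1L) {
      f <- alpha * (C[-1L, , , drop = FALSE] - C[-nx, , , drop = FALSE])
      C[-nx, , ] <- C[-nx, , , drop = FALSE] + f
      C[-1L, , ] <- C[-1L, , , drop = FALSE] - f
    }
    if (ny > 1L) {
      f <- alpha * (C[, -1L, , drop = FALSE] - C[, -ny, , drop = FALSE])
      C[, -ny, ] <- C[, -ny, , drop = FALSE] + f
      C[, -1L, ] <- C[, -1L, , drop = FALSE] - f
    }
    if (nz > 1L) {
      f <- alpha * (C[, , -1L, drop = FALSE] - C[, , -nz, drop = FALSE])
      C[, , -nz] <- C[, , -nz, drop = FALSE] + f
      C[, , -1L] <- C[, , -1L, drop = FALSE] - f
    }
    grid$C[[s]] <- C
  }
  grid
}

#' Withdraw N from one voxel
#'
#' Removes up to `amount` umol from a voxel, counting the sorbed fraction
#' (available N per voxel is `C * b * h^3`); the concentration never goes
#' negative and the withdrawal ledger records what was actually taken.
#'
#' @param grid A `soil_grid`.
#' @param voxel Integer vector `c(i, j, k)` (1-based).
#' @param amount Requested withdrawal (umol), >= 0.
#' @param species Species name.
#' @return A list `(grid, withdrawn)`.
#' @export
withdraw <- function(grid, voxel, amount, species = "nitrate") {
  stopifnot(inherits(grid, "soil_grid"), species %in% grid$species)
  if (amount < 0) stop("Withdrawal amount must be >= 0.", call. = FALSE)
  if (length(voxel) != 3L || any(voxel < 1L) ||
      voxel[1L] > grid$nx || voxel[2L] > grid$ny || voxel[3L] > grid$nz) {
    stop("Invalid voxel index.", call. = FALSE)
  }
  vol_factor <- grid$b[[species]] * grid$h^3
  avail <- grid$C[[species]][voxel[1L], voxel[2L], voxel[3L]] * vol_factor
  take <- min(amount, avail)
  grid$C[[species]][voxel[1L], voxel[2L], voxel[3L]] <-
    (avail - take) / vol_factor
  grid$withdrawn[[species]] <- grid$withdrawn[[species]] + take
  list(grid = grid, withdrawn = take)
}

# Vectorized withdrawal used by the uptake engine: `idx` are linear voxel
# indices (possibly repeated), `amounts` the per-entry requests. Requests
# that oversubscribe a voxel are rationed proportionally, which is how
# neighbouring root segments (and dense hairy segments sharing a voxel)
# compete for the same N pool.
withdraw_many <- function(grid, idx, amounts, species = "nitrate") {
  vol_factor <- grid$b[[species]] * grid$h^3
  C <- grid$C[[species]]
  per_voxel <- rowsum(amounts, idx, reorder = FALSE)
  ux <- as.integer(rownames(per_voxel))
  avail <- C[ux] * vol_factor
  scale <- ifelse(per_voxel[, 1L] > avail & per_voxel[, 1L] > 0,
                  avail / per_voxel[, 1L], 1)
  scale_per_entry <- scale[match(idx, ux)]
  taken <- amounts * scale_per_entry
  removed <- rowsum(taken, idx, reorder = FALSE)[, 1L]
  C[ux] <- pmax(0, (avail - removed) / vol_factor)
  grid$C[[species]] <- C
  grid$withdrawn[[species]] <- grid$withdrawn[[species]] + sum(taken)
  list(grid = grid, taken = taken)
}

#' Conservation residual of a grid
#'
#' Relative imbalance `|initial - (current + withdrawn)| / max(initial, eps)`
#' for one species; exact bookkeeping keeps this at rounding level.
#'
#' @inheritParams soil_total_n
#' @export
conservation_residual <- function(grid, species = "nitrate") {
  stopifnot(inherits(grid, "soil_grid"))
  init <- grid$initial_total[[species]]
  if (init == 0) return(0)
  abs(init - soil_total_n(grid, species) - grid$withdrawn[[species]]) / init
}

#' Export a grid snapshot as a tidy table
#'
#' One row per voxel and species: indices, layer depth, and solution
#' concentration. Suitable for CSV export; pair with [soil_grid_header()]
#' for the geometry metadata.
#'
#' @inheritParams soil_total_n
#' @param species Species to include (default all).
#' @return A tibble with columns `i, j, k, z_cm, species, C`.
#' @export
soil_grid_snapshot <- function(grid, species = grid$species) {
  stopifnot(inherits(grid, "soil_grid"))
  out <- lapply(species, function(s) {
    idx <- expand.grid(i = seq_len(grid$nx), j = seq_len(grid$ny),
                       k = seq_len(grid$nz))
    tibble::tibble(i = idx$i, j = idx$j, k = idx$k,
                   z_cm = (idx$k - 0.5) * grid$h,
                   species = s, C = as.vector(grid$C[[s]]))
  })
  dplyr::bind_rows(out)
}

#' Grid geometry header as a JSON-ready list
#'
#' @inheritParams soil_total_n
#' @export
soil_grid_header <- function(grid) {
  stopifnot(inherits(grid, "soil_grid"))
  list(dims = c(grid$nx, grid$ny, grid$nz), h_cm = grid$h,
       species = grid$species, b = as.list(grid$b),
       D_e_cm2_d = as.list(grid$D_e), theta = grid$theta)
}
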