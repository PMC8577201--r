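#' Architecture parameters for a maize seedling root system
#'
#' Builds the parameter set describing a simplified maize seedling root
#' system: a vertical primary axis, a whorl of seminal axes, and
#' first-order laterals, plus the root-hair phenes (length ceiling,
#' elongation rate, density, radius, hair-free zone behind the tip).
#' Defaults come from the packaged `maize_seedling.yaml` profile, a
#' plausible seedling parameterization; every value can be overridden.
#'
#' Classes are `primary`, `seminal`, `lateral`; per-class fields are named
#' vectors in that order. Lengths are cm internally; only hair lengths are
#' expressed in mm, mirroring how root hair data are reported.
#'
#' @param ... Named overrides of the defaults, e.g.
#'   `max_root_hair_length_mm = 1`, `root_hair_density_per_cm = 1000`,
#'   `elongation_rate = c(primary = 2, seminal = 1.5, lateral = 0.5)`.
#' @return An `architecture_params` list.
#' @examples
#' p <- architecture_params(max_root_hair_length_mm = 1)
#' p$root_hair_density_per_cm
#' @export
architecture_params <- function(...) {
  defaults <- maize_seedling_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop(sprintf("Unknown parameter(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  for (nm in names(over)) {
    if (is.numeric(defaults[[nm]]) && length(defaults[[nm]]) > 1L &&
        !is.null(names(defaults[[nm]]))) {
      v <- defaults[[nm]]
      o <- over[[nm]]
      if (is.null(names(o)) && length(o) == length(v)) names(o) <- names(v)
      v[names(o)] <- o
      defaults[[nm]] <- v
    } else {
      defaults[[nm]] <- over[[nm]]
    }
  }
  validate_architecture_params(defaults)
}

maize_seedling_defaults <- function() {
  path <- system.file("extdata", "maize_seedling.yaml", package = "rhizoN")
  raw <- yaml::read_yaml(path)
  per_class <- function(x) unlist(x)[c("primary", "seminal", "lateral")]
  list(
    elongation_rate = per_class(raw$elongation_rate_cm_d),
    seminal_count = as.integer(raw$seminal_count),
    branching_interval_cm = raw$branching_interval_cm,
    lateral_delay_d = raw$lateral_delay_d,
    insertion_angle_deg = per_class(raw$insertion_angle_deg),
    gravitropism_deg_per_cm = per_class(raw$gravitropism_deg_per_cm),
    radius_cm = per_class(raw$radius_cm),
    max_root_hair_length_mm = raw$max_root_hair_length_mm,
    root_hair_growth_rate_mm_d = raw$root_hair_growth_rate_mm_d,
    hair_free_tip_zone_cm = raw$hair_free_tip_zone_cm,
    root_hair_density_per_cm = raw$root_hair_density_per_cm,
    hair_radius_cm = raw$hair_radius_cm,
    dt_max_d = raw$dt_max_d
  )
}

validate_architecture_params <- function(p) {
  nonneg <- c("elongation_rate", "branching_interval_cm", "lateral_delay_d",
              "gravitropism_deg_per_cm", "radius_cm",
              "max_root_hair_length_mm", "root_hair_growth_rate_mm_d",
              "hair_free_tip_zone_cm", "root_hair_density_per_cm",
              "hair_radius_cm")
  for (nm in nonneg) {
    if (any(p[[nm]] < 0)) {
      stop(sprintf("Parameter '%s' must be >= 0.", nm), call. = FALSE)
    }
  }
  if (p$seminal_count < 0) stop("seminal_count must be >= 0.", call. = FALSE)
  if (p$max_root_hair_length_mm > 0 && p$root_hair_growth_rate_mm_d <= 0) {
    stop("A positive max root hair length requires a positive hair growth rate.",
         call. = FALSE)
  }
  if (p$dt_max_d <= 0) stop("dt_max_d must be > 0.", call. = FALSE)
  structure(p, class = "architecture_params")
}

CLASS_LEVELS <- c("primary", "seminal", "lateral")

# deterministic per-branch jitter in [0, 1): a small integer hash so the
# architecture is byte-identical for a given seed regardless of how grow()
# calls are partitioned in time
hash01 <- function(seed, a, b) {
  x <- (as.double(seed) * 2654435761 + a * 40503 + b * 69069) %% 2147483647
  x <- (x * 16807) %% 2147483647
  x / 2147483647
}

#' Initialize a root system at germination
#'
#' Creates the seed-position state: a vertical primary axis and
#' `seminal_count` seminal axes fanned at the seminal insertion angle with
#' deterministic, seed-derived azimuths. The coordinate origin is the seed;
#' z increases downward (cm).
#'
#' @param params An `architecture_params`.
#' @param seed Integer scenario seed controlling azimuthal jitter.
#' @return A `root_system` state at time 0.
#' @export
root_system_init <- function(params, seed = 1L) {
  stopifnot(inherits(params, "architecture_params"))
  n_sem <- params$seminal_count
  n_axes <- 1L + n_sem
  axes <- data.frame(
    axis_id = seq_len(n_axes),
    class = c(1L, rep(2L, n_sem)),
    x = 0, y = 0, z = 0,
    hx = 0, hy = 0, hz = 1,
    emerged = 0,
    length = 0,
    since_branch = 0,
    branch_count = 0L,
    parent_axis = NA_integer_,
    last_seg = NA_integer_
  )
  if (n_sem > 0L) {
    for (i in seq_len(n_sem)) {
      az <- 2 * pi * ((i - 1) / n_sem + hash01(seed, 0, i))
      th <- params$insertion_angle_deg[["seminal"]] * pi / 180
      axes[i + 1L, c("hx", "hy", "hz")] <-
        c(sin(th) * cos(az), sin(th) * sin(az), cos(th))
    }
  }
  th0 <- params$insertion_angle_deg[["primary"]] * pi / 180
  az0 <- 2 * pi * hash01(seed, 0, 0)
  axes[1L, c("hx", "hy", "hz")] <-
    c(sin(th0) * cos(az0), sin(th0) * sin(az0), cos(th0))
  structure(
    list(segments = empty_segment_matrix(), axes = axes, time = 0,
         seed = as.integer(seed), next_axis = n_axes + 1L,
         next_seg = 1L, pending = list()),
    class = "root_system"
  )
}

SEG_COLS <- c("id", "parent", "axis", "class", "x0", "y0", "z0",
              "x1", "y1", "z1", "radius", "t_created", "length")

empty_segment_matrix <- function() {
  m <- matrix(numeric(0), ncol = length(SEG_COLS))
  colnames(m) <- SEG_COLS
  m
}

#' @export
print.root_system <- function(x, ...) {
  cat(sprintf("<root_system> t = %g d, %d axes, %d segments, total length %.1f cm\n",
              x$time, nrow(x$axes), nrow(x$segments), total_root_length(x)))
  invisible(x)
}

#' Total root length (cm) of a root system state
#'
#' @param state A `root_system`.
#' @export
total_root_length <- function(state) {
  stopifnot(inherits(state, "root_system"))
  if (nrow(state$segments) == 0L) return(0)
  sum(state$segments[, "length"])
}

# rotate a unit heading toward vertical (0,0,1) by `ang` radians
bend_to_vertical <- function(h, ang) {
  cosang <- max(-1, min(1, h[3L]))
  cur <- acos(cosang)
  if (cur < 1e-12 || ang <= 0) return(h)
  new_ang <- max(0, cur - ang)
  # component of h orthogonal to vertical
  horiz <- c(h[1L], h[2L], 0)
  nh <- sqrt(sum(horiz^2))
  if (nh < 1e-12) return(c(0, 0, 1))
  horiz <- horiz / nh
  c(sin(new_ang) * horiz[1L], sin(new_ang) * horiz[2L], cos(new_ang))
}

#' Grow a root system forward in time
#'
#' Elongates every emerged axis tip along its heading, bending toward the
#' vertical according to the class gravitropism strength; emits lateral
#' primordia behind primary/seminal tips at the branching interval, which
#' emerge after the lateral delay with a deterministic seed-derived
#' azimuth. Calls are internally subdivided into steps of at most
#' `params$dt_max_d` so that `grow(grow(s, d), d)` and `grow(s, 2 d)`
#' agree whenever `d` is a multiple of the internal step.
#'
#' @param state A `root_system`.
#' @param params An `architecture_params`.
#' @param dt Time increment in days, > 0.
#' @return The advanced state.
#' @export
grow <- function(state, params, dt) {
  stopifnot(inherits(state, "root_system"),
            inherits(params, "architecture_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number of days.", call. = FALSE)
  }
  n_chunks <- max(1L, ceiling(dt / params$dt_max_d - 1e-9))
  chunk <- dt / n_chunks
  for (i in seq_len(n_chunks)) {
    state <- grow_chunk(state, params, chunk)
  }
  state
}

grow_chunk <- function(state, params, dt) {
  t0 <- state$time
  t1 <- t0 + dt
  axes <- state$axes
  new_rows <- vector("list", nrow(axes) + length(state$pending))
  nr <- 0L

  # promote pending lateral primordia emerging before the end of this
  # chunk; elongation below starts them at their exact emergence time
  still_pending <- list()
  for (p in state$pending) {
    if (p$emerge < t1 - 1e-12) {
      axes <- rbind(axes, data.frame(
        axis_id = state$next_axis, class = 3L,
        x = p$x, y = p$y, z = p$z, hx = p$hx, hy = p$hy, hz = p$hz,
        emerged = p$emerge, length = 0, since_branch = 0, branch_count = 0L,
        parent_axis = p$parent_axis, last_seg = p$parent_seg))
      state$next_axis <- state$next_axis + 1L
    } else {
      still_pending[[length(still_pending) + 1L]] <- p
    }
  }
  state$pending <- still_pending

  for (a in seq_len(nrow(axes))) {
    emerged <- axes$emerged[a]
    if (emerged >= t1 - 1e-12) next
    cls <- CLASS_LEVELS[axes$class[a]]
    rate <- params$elongation_rate[[cls]]
    # an axis that has not elongated yet starts at its exact emergence
    # time (possibly inside an earlier chunk), so no growth is lost
    start <- if (axes$length[a] == 0) emerged else max(t0, emerged)
    dl <- rate * (t1 - start)
    if (dl <= 0) next
    h <- c(axes$hx[a], axes$hy[a], axes$hz[a])
    gamma <- params$gravitropism_deg_per_cm[[cls]] * pi / 180
    h <- bend_to_vertical(h, gamma * dl)
    base <- c(axes$x[a], axes$y[a], axes$z[a])
    tip <- base + h * dl
    seg_id <- state$next_seg
    state$next_seg <- state$next_seg + 1L
    nr <- nr + 1L
    new_rows[[nr]] <- c(seg_id, axes$last_seg[a] %||% NA_real_,
                        axes$axis_id[a], axes$class[a],
                        base, tip, params$radius_cm[[cls]], start, dl)

    # lateral primordia on primary/seminal axes
    if (axes$class[a] %in% c(1L, 2L) && params$branching_interval_cm > 0 &&
        params$elongation_rate[["lateral"]] > 0) {
      acc <- axes$since_branch[a] + dl
      while (acc >= params$branching_interval_cm - 1e-12) {
        acc <- acc - params$branching_interval_cm
        # branch point: distance back from the new tip
        bp <- tip - h * acc
        t_pass <- t1 - acc / rate
        bidx <- axes$branch_count[a] + 1L
        axes$branch_count[a] <- bidx
        az <- 2 * pi * hash01(state$seed, axes$axis_id[a], bidx)
        th <- params$insertion_angle_deg[["lateral"]] * pi / 180
        state$pending[[length(state$pending) + 1L]] <- list(
          x = bp[1L], y = bp[2L], z = bp[3L],
          hx = sin(th) * cos(az), hy = sin(th) * sin(az), hz = cos(th),
          emerge = t_pass + params$lateral_delay_d,
          parent_axis = axes$axis_id[a], parent_seg = seg_id)
      }
      axes$since_branch[a] <- acc
    }

    axes$x[a] <- tip[1L]; axes$y[a] <- tip[2L]; axes$z[a] <- tip[3L]
    axes$hx[a] <- h[1L]; axes$hy[a] <- h[2L]; axes$hz[a] <- h[3L]
    axes$length[a] <- axes$length[a] + dl
    axes$last_seg[a] <- seg_id
  }

  if (nr > 0L) {
    add <- do.call(rbind, new_rows[seq_len(nr)])
    colnames(add) <- SEG_COLS
    state$segments <- rbind(state$segments, add)
  }
  state$axes <- axes
  state$time <- t1
  state
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Root hair length at a position along an axis
#'
#' Hairs are absent in the hair-free zone behind the tip; behind it they
#' elongate at the hair growth rate from the moment the tissue left the
#' zone, saturating at the maximum hair length. Time since leaving the
#' zone is inferred from the distance and the class elongation rate, and
#' can never exceed the segment age.
#'
#' @param distance_from_tip Distance behind the axis tip (cm), >= 0.
#' @param segment_age Age of the segment (days), >= 0.
#' @param params An `architecture_params`.
#' @param class Axis class (`"primary"`, `"seminal"` or `"lateral"`).
#' @return Hair length in mm.
#' @export
hair_length_at <- function(distance_from_tip, segment_age, params,
                           class = "primary") {
  stopifnot(inherits(params, "architecture_params"),
            all(distance_from_tip >= 0), all(segment_age >= 0),
            class %in% CLASS_LEVELS)
  lmax <- params$max_root_hair_length_mm
  if (lmax == 0) return(rep(0, length(distance_from_tip)))
  rate <- params$elongation_rate[[class]]
  zone <- params$hair_free_tip_zone_cm
  t_out <- if (rate > 0) (distance_from_tip - zone) / rate else
    ifelse(distance_from_tip > zone, segment_age, 0)
  t_out <- pmin(pmax(t_out, 0), segment_age)
  ifelse(distance_from_tip <= zone, 0,
         pmin(lmax, params$root_hair_growth_rate_mm_d * t_out))
}

# per-segment current hair length (mm) at state time `t`: age-based form of
# hair_length_at() used throughout the engine (a segment laid down at
# t_created sits `zone/rate` days inside the hair-free zone)
segment_hair_length <- function(segments, params, t) {
  if (nrow(segments) == 0L) return(numeric(0))
  lmax <- params$max_root_hair_length_mm
  if (lmax == 0) return(rep(0, nrow(segments)))
  cls <- CLASS_LEVELS[segments[, "class"]]
  rate <- params$elongation_rate[cls]
  zone_delay <- ifelse(rate > 0, params$hair_free_tip_zone_cm / rate, 0)
  age <- t - segments[, "t_created"]
  t_out <- pmax(0, age - zone_delay)
  pmin(lmax, params$root_hair_growth_rate_mm_d * t_out)
}

#' Absorptive root surface area
#'
#' Without hairs: the sum of cylinder areas `2 pi r L` over all segments.
#' With hairs: adds, per segment, `density x length x 2 pi r_hair x l_hair`
#' where `l_hair` is the segment's current hair length (mm converted to
#' cm). Root hairs are treated statistically (density times mean length),
#' never as individual geometric objects.
#'
#' @param state A `root_system`.
#' @param params An `architecture_params`.
#' @param include_hairs Add the root-hair lateral area?
#' @return Area in cm^2.
#' @export
absorptive_surface_area <- function(state, params, include_hairs = TRUE) {
  stopifnot(inherits(state, "root_system"),
            inherits(params, "architecture_params"))
  seg <- state$segments
  if (nrow(seg) == 0L) return(0)
  bare <- sum(2 * pi * seg[, "radius"] * seg[, "length"])
  if (!include_hairs) return(bare)
  lh_cm <- segment_hair_length(seg, params, state$time) / 10
  hairs <- sum(params$root_hair_density_per_cm * seg[, "length"] *
                 2 * pi * params$hair_radius_cm * lh_cm)
  bare + hairs
}

#' Segment table of a root system
#'
#' @param state A `root_system`.
#' @return A tibble with one row per segment: `segment_id`, `parent_id`,
#'   `class`, base and tip coordinates, `radius_cm`, `t_created_d`,
#'   `length_cm`.
#' @export
root_segments <- function(state) {
  stopifnot(inherits(state, "root_system"))
  seg <- state$segments
  tibble::tibble(
    segment_id = as.integer(seg[, "id"]),
    parent_id = as.integer(seg[, "parent"]),
    class = CLASS_LEVELS[seg[, "class"]],
    x0 = seg[, "x0"], y0 = seg[, "y0"], z0 = seg[, "z0"],
    x1 = seg[, "x1"], y1 = seg[, "y1"], z1 = seg[, "z1"],
    radius_cm = seg[, "radius"],
    t_created_d = seg[, "t_created"],
    length_cm = seg[, "length"]
  )
}

#' Write a root system to CSV (+ optional JSON summary)
#'
#' @param state A `root_system`.
#' @param params An `architecture_params` (for the area summary).
#' @param csv Path for the tidy segment CSV.
#' @param json Optional path for a summary JSON (total length, area with
#'   and without hairs).
#' @return Invisibly, the segment tibble.
#' @export
write_root_system <- function(state, params, csv, json = NULL) {
  tbl <- root_segments(state)
  utils::write.csv(tbl, csv, row.names = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(
      list(time_d = state$time,
           n_segments = nrow(tbl),
           total_length_cm = total_root_length(state),
           area_cm2 = absorptive_surface_area(state, params, FALSE),
           area_with_hairs_cm2 = absorptive_surface_area(state, params, TRUE)),
      json, auto_unbox = TRUE, digits = NA)
  }
  invisible(tbl)
}
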