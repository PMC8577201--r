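lone_primary <- function(rate = 2) {
  architecture_params(
    elongation_rate = c(primary = rate, seminal = 0, lateral = 0),
    seminal_count = 0L,
    branching_interval_cm = 0,
    insertion_angle_deg = c(primary = 0, seminal = 0, lateral = 0),
    gravitropism_deg_per_cm = c(primary = 0, seminal = 0, lateral = 0))
}

test_that("a lone primary axis elongates at rate x time, perfectly vertical", {
  p <- lone_primary(rate = 2)
  s <- grow(root_system_init(p, 1), p, 15)
  expect_equal(total_root_length(s), 30, tolerance = 1e-10)
  seg <- root_segments(s)
  expect_true(all(abs(seg$x0) < 1e-12 & abs(seg$x1) < 1e-12))
  expect_true(all(abs(seg$y0) < 1e-12 & abs(seg$y1) < 1e-12))
  expect_equal(max(seg$z1), 30, tolerance = 1e-10)
})

test_that("total length matches the brute-force elongation ledger oracle", {
  p <- architecture_params()
  s <- grow(root_system_init(p, 3), p, 15)
  expect_equal(total_root_length(s), root_length_oracle(p, 15),
               tolerance = 1e-8)
  # and at an intermediate, non-integer time
  p2 <- architecture_params(seminal_count = 2L)
  s2 <- grow(root_system_init(p2, 9), p2, 7.5)
  expect_equal(total_root_length(s2), root_length_oracle(p2, 7.5),
               tolerance = 1e-8)
})

test_that("segment geometry is self-consistent and stays below the surface", {
  p <- architecture_params()
  s <- grow(root_system_init(p, 11), p, 10)
  seg <- root_segments(s)
  eu <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2 + (seg$z1 - seg$z0)^2)
  expect_equal(eu, seg$length_cm, tolerance = 1e-10)
  expect_true(all(seg$length_cm > 0))
  expect_true(all(seg$z0 >= -1e-12 & seg$z1 >= -1e-12))
  expect_true(all(seg$t_created_d >= 0 & seg$t_created_d <= 10))
  # forest rooted at the seed: every parent id exists or is NA
  expect_true(all(is.na(seg$parent_id) |
                    seg$parent_id %in% seg$segment_id))
})

test_that("growth is additive over dt-splitting and reproducible by seed", {
  p <- architecture_params()
  a <- grow(grow(root_system_init(p, 5), p, 2), p, 2)
  b <- grow(root_system_init(p, 5), p, 4)
  expect_identical(a$segments, b$segments)

  c1 <- grow(root_system_init(p, 5), p, 6)
  c2 <- grow(root_system_init(p, 5), p, 6)
  expect_identical(c1$segments, c2$segments)

  d <- grow(root_system_init(p, 6), p, 6)
  expect_false(identical(c1$segments, d$segments))

  # length is non-decreasing in time
  lens <- sapply(1:5, function(t) {
    total_root_length(grow(root_system_init(p, 5), p, t))
  })
  expect_true(all(diff(lens) > 0))
})

test_that("hair length follows the tip-zone ramp and saturates", {
  p <- architecture_params(max_root_hair_length_mm = 1,
                           root_hair_growth_rate_mm_d = 0.5)
  # inside the hair-free zone
  expect_equal(hair_length_at(0.2, 5, p), 0)
  # one day past the zone: rate 2 cm/d, zone 0.5 cm -> distance 2.5 cm
  expect_equal(hair_length_at(2.5, 10, p), 0.5)
  # far behind the tip on an old segment: saturation at l_max
  p_fast <- architecture_params(max_root_hair_length_mm = 1,
                                root_hair_growth_rate_mm_d = 100)
  expect_equal(hair_length_at(5, 10, p_fast), 1)
  # hairless phenotype
  p0 <- architecture_params(max_root_hair_length_mm = 0,
                            root_hair_growth_rate_mm_d = 0)
  expect_equal(hair_length_at(5, 10, p0), 0)
  # monotone in age, bounded by l_max
  ages <- seq(0, 10, by = 0.5)
  lens <- sapply(ages, function(a) hair_length_at(3, a, p))
  expect_true(all(diff(lens) >= 0))
  expect_true(all(lens <= 1 + 1e-12))
})

test_that("absorptive surface area matches the cylinder formula and oracle", {
  # one 10 cm segment of radius 0.05: bare area 2 pi r L
  p <- lone_primary(rate = 10)
  p <- architecture_params(
    elongation_rate = c(primary = 10, seminal = 0, lateral = 0),
    seminal_count = 0L, branching_interval_cm = 0,
    insertion_angle_deg = c(primary = 0, seminal = 0, lateral = 0),
    gravitropism_deg_per_cm = c(primary = 0, seminal = 0, lateral = 0),
    radius_cm = c(primary = 0.05, seminal = 0.02, lateral = 0.01))
  s <- grow(root_system_init(p, 1), p, 1)
  expect_equal(absorptive_surface_area(s, p, FALSE), 2 * pi * 0.05 * 10,
               tolerance = 1e-10)

  # hairless phenotype: both flags identical
  p0 <- architecture_params(max_root_hair_length_mm = 0,
                            root_hair_growth_rate_mm_d = 0)
  s0 <- grow(root_system_init(p0, 2), p0, 8)
  expect_equal(absorptive_surface_area(s0, p0, TRUE),
               absorptive_surface_area(s0, p0, FALSE))

  # full system with hairs: independent per-segment summation oracle
  ph <- architecture_params(max_root_hair_length_mm = 1,
                            root_hair_growth_rate_mm_d = 0.5)
  sh <- grow(root_system_init(ph, 4), ph, 10)
  seg <- root_segments(sh)
  zone_delay <- ph$hair_free_tip_zone_cm /
    ph$elongation_rate[seg$class]
  lh_mm <- pmin(1, 0.5 * pmax(0, (10 - seg$t_created_d) - zone_delay))
  oracle <- sum(2 * pi * seg$radius_cm * seg$length_cm) +
    sum(ph$root_hair_density_per_cm * seg$length_cm *
          2 * pi * ph$hair_radius_cm * lh_mm / 10)
  expect_equal(absorptive_surface_area(sh, ph, TRUE), oracle,
               tolerance = 1e-8)
  expect_gt(absorptive_surface_area(sh, ph, TRUE),
            absorptive_surface_area(sh, ph, FALSE))
})

test_that("parameter validation enforces the physical invariants", {
  expect_error(architecture_params(seminal_count = -1L), ">= 0")
  expect_error(architecture_params(root_hair_density_per_cm = -5), ">= 0")
  expect_error(architecture_params(max_root_hair_length_mm = 1,
                                   root_hair_growth_rate_mm_d = 0),
               "growth rate")
  p <- architecture_params()
  expect_error(grow(root_system_init(p, 1), p, -1), "positive")
})

test_that("root system export round-trips through CSV", {
  p <- architecture_params()
  s <- grow(root_system_init(p, 8), p, 5)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_root_system(s, p, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(root_segments(s)))
  expect_equal(back$length_cm, root_segments(s)$length_cm, tolerance = 1e-10)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$total_length_cm, total_root_length(s), tolerance = 1e-10)
  unlink(c(csv, js))
})
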