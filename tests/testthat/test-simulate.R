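test_that("cell patterns hit their target area and are reproducible", {
  # roughness 0 is a circle
  circ <- make_cell_pattern(c(35, 35), 692, roughness = 0, seed = 1)
  expect_lt(abs(attr(circ, "area_um2") - 692) / 692, 0.01)
  r <- sqrt((circ$x - 17500)^2 + (circ$y - 17500)^2)
  expect_lt(diff(range(r)) / mean(r), 1e-6)

  # reference geometry: 692 um^2 in a 35 x 35 um^2 frame
  poly <- make_cell_pattern(c(35, 35), 692, roughness = 0.1, seed = 2)
  expect_gte(attr(poly, "area_um2"), 657)
  expect_lte(attr(poly, "area_um2"), 727)

  poly2 <- make_cell_pattern(c(35, 35), 692, roughness = 0.1, seed = 2)
  expect_identical(poly$x, poly2$x)

  expect_error(make_cell_pattern(c(10, 10), 120, seed = 1), "frame")
})

test_that("equilibrium bound-complex density solves the mass balance", {
  expect_equal(equilibrium_pair_fraction(80, 80, 0), 0)
  # quadratic x^2 - 260 x + 6400 = 0, smaller root (260 - sqrt(42000))/2
  expect_equal(equilibrium_pair_fraction(80, 80, 0.01),
               (260 - sqrt(42000)) / 2 / 100 * 100, tolerance = 1e-12)
  expect_equal(round(equilibrium_pair_fraction(80, 80, 0.01), 2), 27.53)
  # saturation limit
  expect_lt(abs(equilibrium_pair_fraction(80, 80, 1e6) - 80) / 80, 1e-3)
  # mass-balance residual property across a parameter sweep
  for (ka in c(1e-3, 0.05, 1, 20)) {
    for (ab in list(c(50, 50), c(10, 120), c(200, 35))) {
      x <- equilibrium_pair_fraction(ab[1], ab[2], ka)
      expect_gte(x, 0)
      expect_lte(x, min(ab) + 1e-9)
      expect_lt(abs(ka * (ab[1] - x) * (ab[2] - x) - x), 1e-6 * max(1, x))
    }
  }
})

test_that("molecule placement respects counts, containment and determinism", {
  sim <- local_sim(area_um2 = 50, density = 120, log_ka = -3, seed = 7)
  a <- sim$total_density / 2
  x <- equilibrium_pair_fraction(a, a, 10^sim$input_log_ka)
  expect_equal(sim$n_pairs, round(x * sim$pattern_area_um2))

  # density bookkeeping: molecule count ~ density * area
  expect_lt(abs(nrow(sim$molecules) / sim$pattern_area_um2 - sim$total_density),
            1 / sim$pattern_area_um2 + 1e-9)

  # species balance and pair structure
  expect_equal(sum(sim$molecules$species == "A"),
               sum(sim$molecules$species == "B"))
  tab <- table(sim$molecules$pair_id)
  expect_true(all(tab == 2))

  # all true positions inside the polygon
  expect_true(all(smlmeq:::points_in_polygon(sim$molecules$x_true,
                                             sim$molecules$y_true,
                                             sim$pattern)))

  sim2 <- place_molecules(sim$pattern, 120, -3, seed = 8)
  sim3 <- place_molecules(sim$pattern, 120, -3, seed = 8)
  expect_identical(sim2$molecules, sim3$molecules)
})

test_that("noise-free coincident pairs are recovered exactly by matching", {
  sim <- local_sim(area_um2 = 10, density = 100, log_ka = 0,
                   loc_sigma_nm = 0, seed = 3)
  mol <- sim$molecules
  a <- mol[mol$species == "A", c("x", "y")]
  b <- mol[mol$species == "B", c("x", "y")]
  expect_equal(match_pairs(a, b, 1)$n_pairs, sim$n_pairs)
  # bound partners coincide exactly at zero separation and zero noise
  bound <- mol[!is.na(mol$pair_id), ]
  pos_a <- bound[bound$species == "A", ][order(bound$pair_id[bound$species == "A"]), ]
  pos_b <- bound[bound$species == "B", ][order(bound$pair_id[bound$species == "B"]), ]
  expect_equal(pos_a$x, pos_b$x)
})

test_that("homo-mode placement solves the dimer mass balance", {
  sim <- local_sim(area_um2 = 25, density = 200, log_ka = -1.5, mode = "homo",
                   seed = 5)
  expect_true(all(sim$molecules$species == "A"))
  rho <- sim$total_density
  ka <- 10^sim$input_log_ka
  x <- sim$n_pairs / sim$pattern_area_um2
  m <- (nrow(sim$molecules) - 2 * sim$n_pairs) / sim$pattern_area_um2
  # Ka * [A]^2 = [A2] up to the rounding of counts
  expect_lt(abs(ka * m^2 - x) / x, 0.05)
  expect_equal(2 * sim$n_pairs + sum(is.na(sim$molecules$pair_id)),
               nrow(sim$molecules))
})

test_that("CSR placements reproduce the Poisson mean-NND closed form", {
  # log Ka -> -inf: effectively no pairs; mean first NND = 0.5 / sqrt(rho)
  sim <- local_sim(area_um2 = 40, density = 300, log_ka = -8,
                   loc_sigma_nm = 0, seed = 9, roughness = 0)
  expect_lte(sim$n_pairs, 2)
  got <- mean_nnd(sim$molecules[, c("x", "y")])
  expected <- 0.5 / sqrt(sim$total_density) * 1000
  expect_lt(abs(got - expected) / expected, 0.03)
})

test_that("blink traces have the qPAINT dark-time structure", {
  m1 <- data.frame(x = 0, y = 0, count_weight = 1L)
  m2 <- data.frame(x = 0, y = 0, count_weight = 2L)
  b1 <- emit_blink_traces(m1, 0.3, 20, 0.1, 60000, 0, seed = 11)
  b2 <- emit_blink_traces(m2, 0.3, 20, 0.1, 60000, 0, seed = 12)
  d1 <- dark_times(b1$locs$frame, 1, 0.1)
  d2 <- dark_times(b2$locs$frame, 1, 0.1)
  expect_gte(length(d1), 200)
  expect_gte(length(d2), 200)
  # two docking sites halve the mean dark time
  expect_lt(abs(mean(d2) / mean(d1) - 0.5), 0.05)

  # zero noise: all localizations of a molecule coincide
  expect_equal(length(unique(b1$locs$x)), 1L)

  # every molecule with bursts appears in both outputs
  expect_setequal(unique(b1$locs$molecule_id), unique(b1$traces$molecule_id))

  # short acquisitions warn about unreliable dark-time statistics
  expect_warning(emit_blink_traces(m1, 0.3, 20, 0.1, 100, 0, seed = 1),
                 "dark-time")

  # determinism
  b3 <- emit_blink_traces(m2, 0.3, 20, 0.1, 60000, 0, seed = 12)
  expect_identical(b2$locs, b3$locs)
})
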