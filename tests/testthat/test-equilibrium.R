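test_that("NND distributions match the brute-force oracle", {
  expect_equal(nnd_distribution(data.frame(x = c(0, 20), y = c(0, 0))),
               c(20, 20))
  expect_equal(nnd_distribution(data.frame(x = 0, y = 0),
                                data.frame(x = 40, y = 0)), 40)
  withr::with_seed(51, {
    a <- data.frame(x = runif(500, 0, 5000), y = runif(500, 0, 5000))
    b <- data.frame(x = runif(300, 0, 5000), y = runif(300, 0, 5000))
  })
  expect_equal(nnd_distribution(a), brute_nnd(a), tolerance = 1e-12)
  expect_equal(nnd_distribution(a, b), brute_nnd(a, b), tolerance = 1e-12)
})

test_that("CSR references stay inside the mask and are reproducible", {
  sim <- local_sim(area_um2 = 25, seed = 52)
  pts <- sim$molecules
  mask <- ksdensity_pattern(pts[, c("x", "y", "species")],
                            frame_nm = sim_frame(sim))
  a <- pts[pts$species == "A", c("x", "y")]
  b <- pts[pts$species == "B", c("x", "y")]
  ref <- csr_reference(a, b, mask, scenario = "both_csr", seed = 5)
  expect_equal(sum(ref$species == "A"), nrow(a))
  expect_equal(sum(ref$species == "B"), nrow(b))
  idx <- smlmeq:::grid_index(smlmeq:::make_grid(
    c(mask$origin[1], mask$origin[1] + nrow(mask$occupancy) * mask$pixel_nm,
      mask$origin[2], mask$origin[2] + ncol(mask$occupancy) * mask$pixel_nm),
    mask$pixel_nm), ref$x, ref$y)
  expect_true(all(mask$occupancy[idx]))

  ref2 <- csr_reference(a, b, mask, scenario = "both_csr", seed = 5)
  expect_identical(ref, ref2)

  # a_csr keeps B fixed
  ref3 <- csr_reference(a, b, mask, scenario = "a_csr", seed = 6)
  expect_equal(ref3$x[ref3$species == "B"], b$x)
})

test_that("greedy matching is deterministic, exclusive and near-optimal", {
  # chain a--b--a with spacings 10 and 12 nm: only the 10 nm pair forms
  a <- data.frame(x = c(0, 22), y = 0)
  b <- data.frame(x = 10, y = 0)
  m <- match_pairs(a, b, 25)
  expect_equal(m$n_pairs, 1L)
  expect_equal(m$pairs$i, 1L)
  expect_equal(m$free_a, 2L)
  expect_equal(m$n_free_b, 0L)

  # trivial: one close pair
  expect_equal(match_pairs(data.frame(x = 0, y = 0),
                           data.frame(x = 10, y = 0), 25)$n_pairs, 1L)

  # greedy vs the exhaustive maximum matching on small sets: never more,
  # never below the greedy guarantee of half the optimum, and within 1 in
  # almost all random configurations
  within_one <- 0L
  for (s in 1:10) {
    withr::with_seed(100 + s, {
      na <- sample(3:6, 1); nb <- sample(3:6, 1)
      a <- data.frame(x = runif(na, 0, 60), y = runif(na, 0, 60))
      b <- data.frame(x = runif(nb, 0, 60), y = runif(nb, 0, 60))
    })
    m <- match_pairs(a, b, 30)
    cand <- smlmeq:::candidate_pairs(as.matrix(a), as.matrix(b), 30)
    opt <- brute_max_matching(cand, max(nrow(a), nrow(b)))
    expect_lte(m$n_pairs, opt)
    expect_gte(2L * m$n_pairs, opt)
    if (m$n_pairs >= opt - 1L) within_one <- within_one + 1L
  }
  expect_gte(within_one, 8L)

  # mass conservation, hetero and homo
  withr::with_seed(53, {
    a <- data.frame(x = runif(200, 0, 2000), y = runif(200, 0, 2000))
    b <- data.frame(x = runif(150, 0, 2000), y = runif(150, 0, 2000))
  })
  mh <- match_pairs(a, b, 60)
  expect_equal(2 * mh$n_pairs + mh$n_free_a + mh$n_free_b, 350L)
  mm <- match_pairs(a, NULL, 60)
  expect_equal(2 * mm$n_pairs + mm$n_free_a, 200L)
})

test_that("Ka arithmetic and the noise-free closed loop are exact", {
  r <- compute_ka(50, 100, 100, 100)
  expect_equal(r$ka_um2, 0.5)
  expect_equal(r$log_k, log10(0.5))
  expect_warning(z <- compute_ka(0, 100, 100, 100), "No pairs")
  expect_equal(z$ka_um2, 0)
  expect_true(is.na(z$log_k))
  expect_error(compute_ka(5, 0, 10, 100), "free")

  # closed loop: exact positions, true area -> input log Ka within 0.05
  sim <- local_sim(area_um2 = 50, density = 160, log_ka = -2,
                   loc_sigma_nm = 0, seed = 54)
  mol <- sim$molecules
  m <- match_pairs(mol[mol$species == "A", c("x", "y")],
                   mol[mol$species == "B", c("x", "y")], 1)
  res <- compute_ka(m, area_um2 = sim$pattern_area_um2)
  expect_lt(abs(res$log_k - sim$input_log_ka), 0.05)
})

test_that("molar Kd uses the TIRF observation volume", {
  kd <- compute_kd_molar(1, 1, 1, 1, tirf_depth_nm = 100)
  # one molecule in 1 um^2 x 100 nm = 1e-16 L -> 1.66e-8 M
  expect_equal(kd$c_free_ligand_molar, 1.6605e-8, tolerance = 1e-4)
  kd2 <- compute_kd_molar(1, 1, 1, 1, tirf_depth_nm = 200)
  expect_equal(kd2$kd_molar, kd$kd_molar / 2)
  expect_error(compute_kd_molar(0, 1, 1, 1), "undefined")
  expect_error(compute_kd_molar(1, 1, 1, 1, tirf_depth_nm = 80), "100, 250")

  # closed loop: Kd from matched counts equals Kd from ground-truth counts
  sim <- local_sim(area_um2 = 50, density = 160, log_ka = -1.5,
                   loc_sigma_nm = 0, seed = 55)
  mol <- sim$molecules
  m <- match_pairs(mol[mol$species == "A", c("x", "y")],
                   mol[mol$species == "B", c("x", "y")], 1)
  got <- compute_kd_molar(m, area_um2 = sim$pattern_area_um2)
  n_free_true <- sum(is.na(mol$pair_id) & mol$species == "A")
  truth <- compute_kd_molar(sim$n_pairs, n_free_true, n_free_true,
                            sim$pattern_area_um2)
  expect_lt(abs(got$log_k - truth$log_k), 0.1)
})

test_that("threshold scan flags association against its CSR reference", {
  # associated data with 15 nm pair separation: delta peaks near 15-25 nm
  sim <- local_sim(area_um2 = 25, density = 160, log_ka = -1.5,
                   pair_separation_nm = 15, loc_sigma_nm = 3, seed = 56)
  pts <- sim$molecules
  mask <- ksdensity_pattern(pts[, c("x", "y", "species")],
                            frame_nm = sim_frame(sim))
  scan <- threshold_scan(pts[pts$species == "A", c("x", "y")],
                         pts[pts$species == "B", c("x", "y")],
                         mask, thresholds = seq(10, 60, 5), n_csr = 8,
                         seed = 57)
  expect_true(all(scan$delta[scan$threshold_nm <= 30] > 0))
  best <- attr(scan, "best_threshold_nm")
  expect_gte(best, 10)
  expect_lte(best, 30)
  # beyond the pair-distance scale the association signal decays: by 60 nm
  # the contrast has lost at least a third of its peak value
  expect_lt(scan$delta[scan$threshold_nm == 60], max(scan$delta) * 2 / 3)
})

test_that("infinite-dilution extrapolation is exact on a line", {
  series <- tibble::tibble(density = c(0.1, 0.2, 0.3),
                           log_k = c(-1.5, -1.4, -1.3))
  fit <- suppressWarnings(extrapolate_to_infinite_dilution(series))
  expect_equal(fit$log_k_limit, -1.6, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(glance(fit)$log_k_limit, -1.6, tolerance = 1e-12)
  expect_equal(suppressWarnings(tidy(fit))$estimate[1], -1.6, tolerance = 1e-12)
  expect_error(extrapolate_to_infinite_dilution(series[1, ]), "2 points")
  expect_error(
    extrapolate_to_infinite_dilution(
      tibble::tibble(density = c(0.1, 0.1), log_k = c(-1, -2))),
    "distinct")

  # OLS recovery on noisy synthetic series: intercept within 2 SE most times
  hits <- 0L
  for (s in 1:40) {
    withr::with_seed(200 + s, {
      x <- seq(50, 200, length.out = 8)
      y <- -1.6 + 0.004 * x + rnorm(8, 0, 0.05)
    })
    f <- extrapolate_to_infinite_dilution(tibble::tibble(density = x, log_k = y))
    if (abs(f$log_k_limit + 1.6) <= 2 * f$se) hits <- hits + 1L
  }
  expect_gte(hits, 33L)  # ~95 % coverage
})

test_that("cluster size distributions and stepwise constants are consistent", {
  far <- data.frame(x = c(0, 1000, 2000), y = 0)
  cm <- cluster_molecules(far, linkage_nm = 50)
  expect_equal(cm$sizes, tibble::tibble(j = 1L, n_j = 3L))

  chain <- data.frame(x = c(0, 10, 20, 30), y = 0)
  cc <- cluster_molecules(chain, linkage_nm = 15)
  expect_equal(cc$sizes, tibble::tibble(j = 4L, n_j = 1L))

  # arithmetic of the stepwise formula
  sw <- stepwise_constants(tibble::tibble(j = 1:2, n_j = c(100L, 20L)),
                           area_um2 = 50)
  expect_equal(sw$ka_j_um2, 0.1)

  # a missing size is skipped with a log message
  expect_message(
    sw2 <- stepwise_constants(tibble::tibble(j = c(1L, 3L), n_j = c(10L, 5L)),
                              area_um2 = 10, j_max = 3),
    "skipped")

  # geometric distribution n_j = n1 (q n1 / A)^(j-1) gives constant Ka_j = q
  # (q n1 / A = 1/2 keeps every count an exact integer)
  q <- 0.1; n1 <- 400L; A <- 80
  sizes <- tibble::tibble(j = 1:5, n_j = as.integer(n1 * 0.5^(0:4)))
  swg <- stepwise_constants(sizes, area_um2 = A)
  expect_equal(swg$ka_j_um2, rep(q, 4), tolerance = 1e-12)
})

test_that("cluster occupancy reproduces hand counts and beats its CSR null", {
  # one 3-cluster with 2 of its sites bound
  rec <- data.frame(x = c(0, 20, 40), y = 0)
  lig <- data.frame(x = c(1, 21, 500), y = 0)
  cl <- cluster_molecules(rec, linkage_nm = 30)
  occ <- occupancy_analysis(cl, lig, proximity_nm = 10)
  expect_equal(occ$by_size$j, 3L)
  expect_equal(occ$by_size$p_bound, 2 / 3)

  # saturation: every site bound
  lig_full <- data.frame(x = c(0, 20, 40), y = 1)
  occf <- occupancy_analysis(cl, lig_full, proximity_nm = 10)
  expect_equal(occf$by_size$p_bound, 1)

  # associated simulation: actual p_bound above the ligand-CSR reference
  sim <- local_sim(area_um2 = 25, density = 200, log_ka = -1, seed = 59)
  pts <- sim$molecules
  mask <- ksdensity_pattern(pts[, c("x", "y", "species")],
                            frame_nm = sim_frame(sim))
  clr <- cluster_molecules(pts[pts$species == "A", c("x", "y")],
                           linkage_nm = 30)
  oc <- occupancy_analysis(clr, pts[pts$species == "B", c("x", "y")],
                           proximity_nm = 25, randomization = "ligand_csr",
                           mask = mask, n_random = 5, seed = 60)
  with_data <- oc$by_size[oc$by_size$n_clusters >= 20 &
                          !is.na(oc$by_size$p_bound_csr), ]
  expect_gt(nrow(with_data), 1)
  expect_true(all(with_data$p_bound > with_data$p_bound_csr))
})

test_that("the log K scale converts to Gibbs energy as printed", {
  # the printed value, 743 J/mol, to within the rounding unit
  expect_lt(abs(energy_equivalent(0.3) - 743), 1)
  expect_equal(energy_equivalent(0.3, 298.15), 0.3 * 8.31446 * 298.15)
})
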