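test_that("mean first NND matches closed forms", {
  expect_equal(mean_nnd(data.frame(x = c(0, 30), y = c(0, 0))), 30)
  sq <- data.frame(x = c(0, 1000, 0, 1000), y = c(0, 0, 1000, 1000))
  expect_equal(mean_nnd(sq), 1000)
  expect_error(mean_nnd(data.frame(x = 1, y = 1)), "2 points")

  # CSR at 160 um^-2: Poisson closed form 0.5/sqrt(rho) = 39.5 nm
  withr::with_seed(21, {
    n <- 1e4
    side <- sqrt(n / 160) * 1000
    pts <- data.frame(x = runif(n, 0, side), y = runif(n, 0, side))
    expect_lt(abs(mean_nnd(pts) - 39.53) / 39.53, 0.03)
  })

  # species-aware NND ignores the other channel's coincident partner
  two <- data.frame(x = c(0, 1, 1000, 1001), y = 0,
                    species = c("A", "B", "A", "B"))
  expect_lt(mean_nnd(two), 2)
  expect_equal(mean_nnd(two, by_species = TRUE), 1000)
})

test_that("Delaunay pattern area is exact on closed-form geometries", {
  # single triangle below the acceptance threshold
  tri <- data.frame(x = c(0, 100, 0), y = c(0, 0, 100))
  mask <- delaunay_pattern(tri, f_d = 3)
  expect_equal(mask$area_um2, 5000 * 1e-6)
  expect_true(all(mask$in_pattern))

  # n x n grid of spacing s: mu = s, all triangles s^2/2 accepted,
  # total area (n-1)^2 s^2
  g <- expand.grid(x = (0:9) * 100, y = (0:9) * 100)
  gm <- delaunay_pattern(g, f_d = 3)
  expect_equal(gm$mu_nnd_nm, 100)
  expect_equal(gm$area_um2 * 1e6, 81 * 1e4, tolerance = 1e-9)

  # a far outlier joins no accepted triangle: the sliver triangles tying it
  # to the dense region have area ~ 0.5 * spacing * distance, far above the
  # (3 mu)^2 acceptance cut
  blob <- expand.grid(x = (0:14) * 20, y = (0:14) * 20)
  pts <- rbind(blob, data.frame(x = 3000, y = 3000))
  m2 <- delaunay_pattern(pts, f_d = 3)
  expect_false(m2$in_pattern[226])
  expect_true(all(m2$in_pattern[1:225]))

  expect_error(delaunay_pattern(data.frame(x = 1:5, y = 2 * (1:5))),
               "[Dd]egenerate")
})

test_that("accepting every triangle recovers the convex hull area", {
  withr::with_seed(8, {
    pts <- data.frame(x = runif(400, 0, 2000), y = runif(400, 0, 2000))
  })
  mask <- delaunay_pattern(pts, f_d = 1e6, rasterize = FALSE)
  hull <- pts[chull(pts$x, pts$y), ]
  expect_equal(mask$area_um2 * 1e6, smlmeq:::polygon_area(cbind(hull$x, hull$y)),
               tolerance = 1e-9)
})

test_that("Voronoi pattern matches grid geometry and the deldir oracle", {
  g <- expand.grid(x = (0:9) * 100, y = (0:9) * 100)
  gm <- voronoi_pattern(g, f_v = 3)
  # interior cells are s^2 squares; boundary cells are unbounded -> rejected
  expect_equal(sum(gm$in_pattern), 64)
  expect_equal(gm$area_um2 * 1e6, 64 * 1e4, tolerance = 1e-6)

  # independent oracle: deldir tile polygons (shoelace area per bounded cell)
  skip_if_not_installed("deldir")
  withr::with_seed(13, {
    pts <- data.frame(x = runif(300, 0, 2000), y = runif(300, 0, 2000))
  })
  cells <- smlmeq:::voronoi_cell_areas(
    as.matrix(pts), smlmeq:::triangulate_points(as.matrix(pts))$tri)
  # unbounded cells are exactly those of convex-hull sites
  hull <- sort(chull(pts$x, pts$y))
  expect_identical(which(is.na(cells)), hull)
  tl <- deldir::tile.list(deldir::deldir(pts$x, pts$y,
                                         rw = c(-1e4, 1e4 + 2000, -1e4, 1e4 + 2000)))
  for (i in seq_along(tl)) {
    if (any(tl[[i]]$bp)) next  # clipped by the oracle's window
    oracle_area <- smlmeq:::polygon_area(cbind(tl[[i]]$x, tl[[i]]$y))
    expect_equal(cells[i], oracle_area, tolerance = 1e-6)
  }

  # a sparse point amid a dense blob has an oversized cell -> rejected
  withr::with_seed(14, {
    blob <- data.frame(x = rnorm(200, 0, 50), y = rnorm(200, 0, 50))
  })
  pts2 <- rbind(blob, data.frame(x = 600, y = 0))
  m <- voronoi_pattern(pts2, f_v = 3)
  expect_false(m$in_pattern[201])
})

test_that("tessellation areas are translation and rotation invariant", {
  withr::with_seed(15, {
    pts <- data.frame(x = runif(300, 0, 1500), y = runif(300, 0, 1500))
  })
  shift <- data.frame(x = pts$x + 1e5, y = pts$y - 7e4)
  th <- pi / 7
  rot <- data.frame(x = cos(th) * pts$x - sin(th) * pts$y,
                    y = sin(th) * pts$x + cos(th) * pts$y)
  for (fn in list(function(p) delaunay_pattern(p, 3, rasterize = FALSE),
                  function(p) voronoi_pattern(p, 3, rasterize = FALSE))) {
    a0 <- fn(pts)$area_um2
    expect_equal(fn(shift)$area_um2, a0, tolerance = 1e-9)
    expect_equal(fn(rot)$area_um2, a0, tolerance = 1e-6)
  }
  # ks-density: invariant up to one raster pixel
  k0 <- ksdensity_pattern(pts)
  k1 <- ksdensity_pattern(shift)
  px_area <- (k0$pixel_nm)^2 * 1e-6
  expect_lt(abs(k1$area_um2 - k0$area_um2), 60 * px_area)
})

test_that("ks-density threshold behaves as c times the single-kernel peak", {
  # one isolated molecule is rejected for c > 1
  one <- ksdensity_pattern(data.frame(x = 0, y = 0), f_k = 1,
                           th_constant = 1.5, mu_nnd_nm = 40)
  expect_equal(one$area_um2, 0)
  expect_false(any(one$in_pattern))

  # two coincident molecules double the peak -> accepted at c = 1.5
  two <- ksdensity_pattern(data.frame(x = c(0, 0), y = c(0, 0)), f_k = 1,
                           th_constant = 1.5, mu_nnd_nm = 40)
  expect_gt(two$area_um2, 0)
  expect_true(all(two$in_pattern))

  # monotone: larger threshold constant, smaller area
  withr::with_seed(16, {
    pts <- data.frame(x = rnorm(500, 0, 300), y = rnorm(500, 0, 300))
  })
  a15 <- ksdensity_pattern(pts, th_constant = 1.5)$area_um2
  a25 <- ksdensity_pattern(pts, th_constant = 2.5)$area_um2
  expect_lte(a25, a15)

  # undersampled kernel is refused
  expect_error(ksdensity_pattern(pts, pixel_nm = 500), "undersamples")
})

test_that("area grows with the expansion factor for all methods", {
  sim <- local_sim(area_um2 = 25, seed = 31)
  pts <- sim$molecules[, c("x", "y", "species")]
  for (est in list(function(f) delaunay_pattern(pts, f, rasterize = FALSE)$area_um2,
                   function(f) voronoi_pattern(pts, f, rasterize = FALSE)$area_um2,
                   function(f) ksdensity_pattern(pts, f)$area_um2)) {
    areas <- vapply(c(0.5, 1, 2, 3), est, numeric(1))
    expect_true(all(diff(areas) >= -1e-9))
  }
})

test_that("pattern scoring computes the pixel confusion matrix", {
  g <- smlmeq:::make_grid(c(0, 100, 0, 100), 10)
  occ <- matrix(FALSE, 10, 10)
  occ[1:5, ] <- TRUE
  mask <- smlmeq:::new_pattern_mask(g, occ, 0.5, "delaunay", list(f_d = 3),
                                    10, logical(0))
  # identical truth -> F1 = 1
  expect_equal(score_pattern(mask, occ)$f1, 1)
  # disjoint -> F1 = 0
  other <- matrix(FALSE, 10, 10); other[6:10, ] <- TRUE
  expect_equal(score_pattern(mask, other)$f1, 0)
  # recovered covers half the truth, no FP -> F1 = 2/3
  half <- occ; half[1:10, ] <- TRUE
  sc <- score_pattern(mask, half)
  expect_equal(sc$f1, 2 / 3)
  expect_equal(sc$tp + sc$fp + sc$fn + sc$tn, 100)
})

test_that("expansion-factor optimization maximizes F1 with conservative ties", {
  sim <- local_sim(area_um2 = 25, seed = 33)
  pts <- sim$molecules[, c("x", "y", "species")]
  fr <- sim_frame(sim)

  # single-element grid returns that element
  one <- optimize_expansion_factor(pts, "delaunay", sim$pattern, 3,
                                   frame_nm = fr)
  expect_equal(one$best_factor, 3)

  # exact tie (two factors large enough to accept everything) -> smaller wins
  tie <- optimize_expansion_factor(pts, "delaunay", sim$pattern, c(200, 100),
                                   frame_nm = fr)
  expect_equal(tie$best_factor, 100)
  expect_equal(tie$scores$f1[1], tie$scores$f1[2])

  # the reference factors sit at (or within 0.01 of) the optimum
  od <- optimize_expansion_factor(pts, "delaunay", sim$pattern, c(1, 2, 3, 4),
                                  frame_nm = fr)
  expect_lt(max(od$scores$f1) - od$scores$f1[od$scores$factor == 3], 0.01)
  ov <- optimize_expansion_factor(pts, "voronoi", sim$pattern, c(1, 2, 3, 4),
                                  frame_nm = fr)
  expect_lt(max(ov$scores$f1) - ov$scores$f1[ov$scores$factor == 3], 0.01)
})
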