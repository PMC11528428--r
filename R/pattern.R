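#' Mean first nearest-neighbour distance
#'
#' The mean, over all points, of the distance to the nearest distinct point.
#' This is the unit scale for all three occupied-area estimators.  With
#' `by_species = TRUE` and a `species` column present, each point's nearest
#' neighbour is searched within its own species (its own imaging channel)
#' and the distances of all points are pooled into one mean; this keeps the
#' scale anchored to the inter-molecular spacing rather than to the
#' intra-pair distance when many molecules are bound.
#'
#' For a homogeneous Poisson process of intensity rho the expectation is
#' `0.5 / sqrt(rho)`.
#'
#' @param points Data frame or matrix with `x`, `y` (nm); optionally a
#'   `species` column.
#' @param by_species Search neighbours within species (default `FALSE`,
#'   i.e. the pooled definition).
#' @return Mean first NND in nm.
#' @export
#' @examples
#' mean_nnd(data.frame(x = c(0, 30), y = c(0, 0)))  # 30
mean_nnd <- function(points, by_species = FALSE) {
  xy <- as_xy(points)
  if (nrow(xy) < 2L) abort("mean_nnd() needs at least 2 points.")
  if (by_species && is.data.frame(points) && "species" %in% names(points)) {
    sp <- as.character(points$species)
    d <- unlist(lapply(split(seq_len(nrow(xy)), sp), function(idx) {
      if (length(idx) < 2L) return(numeric())
      FNN::get.knn(xy[idx, , drop = FALSE], k = 1L)$nn.dist[, 1L]
    }), use.names = FALSE)
    if (length(d) == 0L) abort("No species has 2 or more points.")
    return(mean(d))
  }
  mean(FNN::get.knn(xy, k = 1L)$nn.dist[, 1L])
}

# Species-aware scale used by the estimators; falls back to the pooled NND.
pattern_mu_nnd <- function(points) {
  has_sp <- is.data.frame(points) && "species" %in% names(points) &&
    length(unique(points$species)) > 1L
  mean_nnd(points, by_species = has_sp)
}

# ---- raster grid -----------------------------------------------------------

# frame_nm: c(xmin, xmax, ymin, ymax).  Pixel (i, j) covers
# [x0+(i-1)*px, x0+i*px) x [y0+(j-1)*px, y0+j*px); centres at x0+(i-0.5)*px.
make_grid <- function(frame_nm, pixel_nm) {
  nx <- max(1L, ceiling((frame_nm[2L] - frame_nm[1L]) / pixel_nm))
  ny <- max(1L, ceiling((frame_nm[4L] - frame_nm[3L]) / pixel_nm))
  list(x0 = frame_nm[1L], y0 = frame_nm[3L], nx = nx, ny = ny,
       pixel_nm = pixel_nm)
}

default_frame <- function(xy, pad_nm) {
  c(min(xy[, 1L]) - pad_nm, max(xy[, 1L]) + pad_nm,
    min(xy[, 2L]) - pad_nm, max(xy[, 2L]) + pad_nm)
}

grid_index <- function(grid, x, y) {
  ix <- pmin(pmax(floor((x - grid$x0) / grid$pixel_nm) + 1L, 1L), grid$nx)
  iy <- pmin(pmax(floor((y - grid$y0) / grid$pixel_nm) + 1L, 1L), grid$ny)
  cbind(ix, iy)
}

# Default raster pixel: a quarter of the NND scale, floored so the grid stays
# below ~2500 pixels per axis on large frames.
default_pixel <- function(mu_nnd, frame_nm, sigma = NULL) {
  p <- if (is.null(sigma)) mu_nnd / 4 else min(mu_nnd / 4, sigma / 3)
  extent <- max(frame_nm[2L] - frame_nm[1L], frame_nm[4L] - frame_nm[3L])
  max(p, extent / 2500)
}

new_pattern_mask <- function(grid, occupancy, area_um2, method, params,
                             mu_nnd_nm, in_pattern) {
  structure(list(origin = c(grid$x0, grid$y0),
                 pixel_nm = grid$pixel_nm,
                 occupancy = occupancy,
                 area_um2 = area_um2,
                 method = method,
                 params = params,
                 mu_nnd_nm = mu_nnd_nm,
                 in_pattern = in_pattern),
            class = "pattern_mask")
}

#' @export
print.pattern_mask <- function(x, ...) {
  cat(sprintf("<pattern_mask> %s: %.2f um^2 (mu_NND = %.1f nm, %d x %d px @ %.1f nm)\n",
              x$method, x$area_um2, x$mu_nnd_nm,
              nrow(x$occupancy), ncol(x$occupancy), x$pixel_nm))
  cat(sprintf("  params: %s; %d / %d points in pattern\n",
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
              sum(x$in_pattern), length(x$in_pattern)))
  invisible(x)
}

# Rasterize a set of triangles (vertex coordinate vectors) onto a grid.
# Fully vectorized: candidate pixels are enumerated per triangle bounding box
# with sequence(), then tested with barycentric sign checks.
rasterize_triangles <- function(grid, ax, ay, bx, by, cx, cy) {
  occ <- matrix(FALSE, grid$nx, grid$ny)
  if (length(ax) == 0L) return(occ)
  px <- grid$pixel_nm
  ix0 <- pmax(floor((pmin(ax, bx, cx) - grid$x0) / px) + 1L, 1L)
  ix1 <- pmin(floor((pmax(ax, bx, cx) - grid$x0) / px) + 1L, grid$nx)
  iy0 <- pmax(floor((pmin(ay, by, cy) - grid$y0) / px) + 1L, 1L)
  iy1 <- pmin(floor((pmax(ay, by, cy) - grid$y0) / px) + 1L, grid$ny)
  keep <- ix1 >= ix0 & iy1 >= iy0
  if (!any(keep)) return(occ)
  ax <- ax[keep]; ay <- ay[keep]; bx <- bx[keep]; by <- by[keep]
  cx <- cx[keep]; cy <- cy[keep]
  ix0 <- ix0[keep]; ix1 <- ix1[keep]; iy0 <- iy0[keep]; iy1 <- iy1[keep]

  ly <- iy1 - iy0 + 1L
  tri_of_row <- rep.int(seq_along(ly), ly)          # (triangle, raster row)
  row_iy <- sequence(ly, from = iy0)
  lx <- (ix1 - ix0 + 1L)[tri_of_row]
  row_id <- rep.int(seq_along(tri_of_row), lx)      # expand rows to pixels
  pix_ix <- sequence(lx, from = ix0[tri_of_row])
  pix_iy <- row_iy[row_id]
  tri <- tri_of_row[row_id]

  qx <- grid$x0 + (pix_ix - 0.5) * px
  qy <- grid$y0 + (pix_iy - 0.5) * px
  d1 <- (bx[tri] - ax[tri]) * (qy - ay[tri]) - (by[tri] - ay[tri]) * (qx - ax[tri])
  d2 <- (cx[tri] - bx[tri]) * (qy - by[tri]) - (cy[tri] - by[tri]) * (qx - bx[tri])
  d3 <- (ax[tri] - cx[tri]) * (qy - cy[tri]) - (ay[tri] - cy[tri]) * (qx - cx[tri])
  eps <- .Machine$double.eps * 1e3 * px^2
  inside <- (d1 >= -eps & d2 >= -eps & d3 >= -eps) |
            (d1 <= eps & d2 <= eps & d3 <= eps)
  occ[cbind(pix_ix[inside], pix_iy[inside])] <- TRUE
  occ
}

# Rasterize a polygon (even-odd rule) onto a grid; returns a logical matrix.
rasterize_polygon <- function(grid, poly) {
  poly <- as_xy(poly, "polygon")
  occ <- matrix(FALSE, grid$nx, grid$ny)
  px <- grid$pixel_nm
  ix0 <- pmax(floor((min(poly[, 1L]) - grid$x0) / px) + 1L, 1L)
  ix1 <- pmin(floor((max(poly[, 1L]) - grid$x0) / px) + 1L, grid$nx)
  iy0 <- pmax(floor((min(poly[, 2L]) - grid$y0) / px) + 1L, 1L)
  iy1 <- pmin(floor((max(poly[, 2L]) - grid$y0) / px) + 1L, grid$ny)
  if (ix1 < ix0 || iy1 < iy0) return(occ)
  xs <- grid$x0 + (ix0:ix1 - 0.5) * px
  ys <- grid$y0 + (iy0:iy1 - 0.5) * px
  qx <- rep(xs, times = length(ys))
  qy <- rep(ys, each = length(xs))
  inside <- points_in_polygon(qx, qy, poly)
  occ[ix0:ix1, iy0:iy1] <- matrix(inside, length(xs), length(ys))
  occ
}

# Shared triangulation helper: unique coordinates + Delaunay triangle indices.
triangulate_points <- function(xy) {
  key <- paste(xy[, 1L], xy[, 2L], sep = "\r")
  uidx <- which(!duplicated(key))
  map <- match(key, key[uidx])
  ux <- xy[uidx, , drop = FALSE]
  if (nrow(ux) < 3L || is_collinear(ux)) {
    abort("Degenerate geometry: points are collinear or too few for tessellation.")
  }
  tr <- tryCatch(interp::tri.mesh(ux[, 1L], ux[, 2L]),
                 error = function(e) abort(paste0("Delaunay triangulation failed: ",
                                                  conditionMessage(e))))
  list(tri = interp::triangles(tr), ux = ux, map = map)
}

#' Occupied area by Delaunay tessellation
#'
#' Triangulates the molecular coordinates and keeps every triangle whose
#' area is at most `(f_d * mu_NND)^2`; the occupied pattern is the union of
#' accepted triangles.  The reported `area_um2` is the exact sum of accepted
#' triangle areas; the raster is a rendering used for scoring and display.
#' A point belongs to the pattern iff it is a vertex of at least one
#' accepted triangle.
#'
#' @param points Data frame or matrix with `x`, `y` in nm (optional
#'   `species` column, used for the NND scale).
#' @param f_d Expansion factor (default 3).
#' @param pixel_nm Raster pixel size; default `mu_NND / 4` (floored so the
#'   grid stays tractable on large frames).
#' @param frame_nm Raster frame `c(xmin, xmax, ymin, ymax)` in nm; defaults
#'   to the data bounding box padded by one NND scale.
#' @param mu_nnd_nm Override for the NND scale (computed from the data when
#'   `NULL`).
#' @param rasterize Set `FALSE` to skip the raster (area and membership only).
#' @return A `pattern_mask` object.
#' @export
delaunay_pattern <- function(points, f_d = 3, pixel_nm = NULL,
                             frame_nm = NULL, mu_nnd_nm = NULL,
                             rasterize = TRUE) {
  xy <- as_xy(points)
  if (nrow(xy) < 3L) abort("Delaunay pattern needs at least 3 points.")
  if (f_d <= 0) abort("`f_d` must be positive.")
  mu <- mu_nnd_nm %||% pattern_mu_nnd(points)
  tp <- triangulate_points(xy)
  nd <- tp$tri[, 1:3, drop = FALSE]
  ux <- tp$ux
  ax <- ux[nd[, 1L], 1L]; ay <- ux[nd[, 1L], 2L]
  bx <- ux[nd[, 2L], 1L]; by <- ux[nd[, 2L], 2L]
  cx <- ux[nd[, 3L], 1L]; cy <- ux[nd[, 3L], 2L]
  tri_area <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  accept <- tri_area <= (f_d * mu)^2
  area_um2 <- sum(tri_area[accept]) * 1e-6

  member_u <- logical(nrow(ux))
  member_u[unique(as.vector(nd[accept, , drop = FALSE]))] <- TRUE
  in_pattern <- member_u[tp$map]

  frame_nm <- frame_nm %||% default_frame(xy, mu)
  pixel_nm <- pixel_nm %||% default_pixel(mu, frame_nm)
  grid <- make_grid(frame_nm, pixel_nm)
  occ <- if (rasterize) {
    rasterize_triangles(grid, ax[accept], ay[accept], bx[accept], by[accept],
                        cx[accept], cy[accept])
  } else {
    matrix(FALSE, grid$nx, grid$ny)
  }
  new_pattern_mask(grid, occ, area_um2, "delaunay", list(f_d = f_d), mu,
                   in_pattern)
}

# Voronoi cell areas from the Delaunay triangulation.  Each bounded cell is
# the union of wedges (site, c1, c2) where c1, c2 are circumcenters of the
# two triangles adjacent to a Delaunay edge incident to the site.  Sites on
# the convex hull have unbounded cells (area NA).
voronoi_cell_areas <- function(ux, tri) {
  nd <- tri[, 1:3, drop = FALSE]
  nb <- tri[, 4:6, drop = FALSE]
  n <- nrow(ux)
  x <- ux[, 1L]; y <- ux[, 2L]
  ax <- x[nd[, 1L]]; ay <- y[nd[, 1L]]
  bx <- x[nd[, 2L]]; by <- y[nd[, 2L]]
  cx <- x[nd[, 3L]]; cy <- y[nd[, 3L]]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  ccx <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
          (cx^2 + cy^2) * (ay - by)) / d
  ccy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
          (cx^2 + cy^2) * (bx - ax)) / d

  unbounded <- rep(FALSE, n)
  e_i <- integer(); e_t <- integer(); e_nb <- integer()
  tseq <- seq_len(nrow(nd))
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    i <- nd[, others[1L]]; j <- nd[, others[2L]]
    nbk <- nb[, k]
    hull <- nbk == 0L
    unbounded[c(i[hull], j[hull])] <- TRUE
    keep <- !hull & nbk > tseq   # each interior edge once
    e_i <- c(e_i, i[keep], j[keep])
    e_t <- c(e_t, tseq[keep], tseq[keep])
    e_nb <- c(e_nb, nbk[keep], nbk[keep])
  }
  w <- abs((ccx[e_t] - x[e_i]) * (ccy[e_nb] - y[e_i]) -
           (ccx[e_nb] - x[e_i]) * (ccy[e_t] - y[e_i])) / 2
  area <- rep(NA_real_, n)
  s <- rowsum(w, e_i)
  area[as.integer(rownames(s))] <- s[, 1L]
  area[unbounded] <- NA_real_
  area
}

#' Occupied area by Voronoi tessellation
#'
#' Computes the Voronoi diagram of the molecular coordinates and keeps every
#' bounded cell whose area is at most `(f_v * mu_NND)^2`; unbounded cells
#' (sites on the convex hull) are always rejected, so the estimator never
#' credits area outside the data's support.  `area_um2` is the exact sum of
#' accepted cell areas.  A point belongs to the pattern iff its own cell is
#' accepted.  The raster assigns each pixel to the cell of its nearest site.
#'
#' @inheritParams delaunay_pattern
#' @param f_v Expansion factor (default 3).
#' @return A `pattern_mask` object.
#' @export
voronoi_pattern <- function(points, f_v = 3, pixel_nm = NULL,
                            frame_nm = NULL, mu_nnd_nm = NULL,
                            rasterize = TRUE) {
  xy <- as_xy(points)
  if (nrow(xy) < 4L) abort("Voronoi pattern needs at least 4 points.")
  if (f_v <= 0) abort("`f_v` must be positive.")
  mu <- mu_nnd_nm %||% pattern_mu_nnd(points)
  tp <- triangulate_points(xy)
  cell_area <- voronoi_cell_areas(tp$ux, tp$tri)
  accept <- !is.na(cell_area) & cell_area <= (f_v * mu)^2
  area_um2 <- sum(cell_area[accept]) * 1e-6
  in_pattern <- accept[tp$map]

  frame_nm <- frame_nm %||% default_frame(xy, mu)
  pixel_nm <- pixel_nm %||% default_pixel(mu, frame_nm)
  grid <- make_grid(frame_nm, pixel_nm)
  occ <- matrix(FALSE, grid$nx, grid$ny)
  if (rasterize && any(accept)) {
    qx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$pixel_nm
    qy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$pixel_nm
    q <- cbind(rep(qx, times = grid$ny), rep(qy, each = grid$nx))
    nn <- FNN::get.knnx(tp$ux, q, k = 1L)$nn.index[, 1L]
    occ[] <- accept[nn]
  }
  new_pattern_mask(grid, occ, area_um2, "voronoi", list(f_v = f_v), mu,
                   in_pattern)
}

#' Occupied area by thresholded kernel surface density (ks-density)
#'
#' Evaluates a Gaussian kernel density surface with
#' `sigma_x = sigma_y = f_k * mu_NND` on a raster (each of the `N_T` kernels
#' carries mass `1/N_T`, so the surface integrates to 1 over the plane) and
#' keeps pixels whose density is at least
#' `TH = th_constant / (2 * pi * sigma_x * sigma_y * N_T)`, i.e.
#' `th_constant` times the peak height of a single kernel.  With
#' `th_constant > 1` an isolated molecule is rejected, which is what makes
#' the estimator exclude void and isolated areas without user-defined
#' absolute thresholds.
#'
#' Kernels are truncated at 4 sigma (relative error < 3e-4) and the surface
#' is computed by FFT convolution of the binned counts.
#'
#' @inheritParams delaunay_pattern
#' @param f_k Gaussian dispersion factor (default 1).
#' @param th_constant Threshold constant c in `TH = c/(2 pi sigma^2 N_T)`
#'   (default 1.5).
#' @param pixel_nm Raster pixel size; must be at most `sigma / 2`, default
#'   `min(mu_NND / 4, sigma / 3)`.
#' @return A `pattern_mask` object.
#' @export
ksdensity_pattern <- function(points, f_k = 1, th_constant = 1.5,
                              pixel_nm = NULL, frame_nm = NULL,
                              mu_nnd_nm = NULL) {
  xy <- as_xy(points)
  if (nrow(xy) < 1L) abort("ks-density pattern needs at least 1 point.")
  if (f_k <= 0 || th_constant <= 0) abort("`f_k` and `th_constant` must be positive.")
  mu <- mu_nnd_nm %||% (if (nrow(xy) >= 2L) pattern_mu_nnd(points) else
    abort("`mu_nnd_nm` must be given for a single point."))
  sigma <- f_k * mu
  frame_nm <- frame_nm %||% default_frame(xy, 4 * sigma)
  pixel_nm <- pixel_nm %||% default_pixel(mu, frame_nm, sigma = sigma)
  if (pixel_nm > sigma / 2) {
    abort(sprintf(
      "Raster pixel (%.1f nm) undersamples the kernel: need pixel_nm <= sigma/2 = %.1f nm.",
      pixel_nm, sigma / 2))
  }
  grid <- make_grid(frame_nm, pixel_nm)
  n_t <- nrow(xy)

  idx <- grid_index(grid, xy[, 1L], xy[, 2L])
  counts <- matrix(0, grid$nx, grid$ny)
  lin <- tabulate(idx[, 1L] + (idx[, 2L] - 1L) * grid$nx, nbins = grid$nx * grid$ny)
  counts[] <- lin

  m <- ceiling(4 * sigma / pixel_nm)
  dx <- (-m:m) * pixel_nm
  k1 <- dnorm(dx, 0, sigma)
  kernel <- outer(k1, k1)           # continuous density per nm^2
  dens <- conv2_fft(counts, kernel) / n_t
  th <- th_constant / (2 * pi * sigma^2 * n_t)
  occ <- dens >= th
  area_um2 <- sum(occ) * pixel_nm^2 * 1e-6
  in_pattern <- occ[idx]

  new_pattern_mask(grid, occ, area_um2, "ksdensity",
                   list(f_k = f_k, th_constant = th_constant), mu, in_pattern)
}

#' Score a recovered pattern against a ground-truth polygon
#'
#' Rasterizes the true polygon on the mask's grid and classifies each pixel
#' as TP (occupied in both), FP (recovered only), FN (truth only) or TN
#' (neither); F1 = 2 TP / (2 TP + FP + FN).
#'
#' @param recovered A `pattern_mask`.
#' @param truth A ground-truth polygon (vertex tibble/matrix, nm) or a
#'   logical matrix already on the same grid.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`, `f1`.
#' @export
score_pattern <- function(recovered, truth) {
  if (!inherits(recovered, "pattern_mask")) abort("`recovered` must be a pattern_mask.")
  grid <- list(x0 = recovered$origin[1L], y0 = recovered$origin[2L],
               nx = nrow(recovered$occupancy), ny = ncol(recovered$occupancy),
               pixel_nm = recovered$pixel_nm)
  tr <- if (is.matrix(truth) && is.logical(truth)) truth else rasterize_polygon(grid, truth)
  if (!all(dim(tr) == dim(recovered$occupancy))) {
    abort("Truth raster does not match the mask's grid.")
  }
  rec <- recovered$occupancy
  tp <- sum(rec & tr); fp <- sum(rec & !tr)
  fn <- sum(!rec & tr); tn <- sum(!rec & !tr)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  tibble(tp = tp, fp = fp, fn = fn, tn = tn, f1 = f1)
}

#' Optimize an expansion factor against ground truth
#'
#' Runs one area estimator over a grid of candidate expansion factors and
#' returns the factor maximizing the pixel-wise F1 score against the true
#' polygon; ties are broken toward the smaller (more conservative) factor.
#'
#' @param points Molecular coordinates (nm).
#' @param method `"delaunay"`, `"voronoi"` or `"ksdensity"`.
#' @param truth_polygon Ground-truth polygon (nm).
#' @param factor_grid Numeric vector of candidate factors.
#' @param ... Passed to the estimator (e.g. `th_constant`, `pixel_nm`,
#'   `frame_nm`).
#' @return List with `best_factor` and `scores` (tibble of factor, F1 and
#'   area).
#' @export
optimize_expansion_factor <- function(points,
                                      method = c("delaunay", "voronoi", "ksdensity"),
                                      truth_polygon, factor_grid, ...) {
  method <- match.arg(method)
  if (length(factor_grid) < 1L) abort("`factor_grid` must be non-empty.")
  est <- switch(method,
                delaunay = function(f, ...) delaunay_pattern(points, f_d = f, ...),
                voronoi = function(f, ...) voronoi_pattern(points, f_v = f, ...),
                ksdensity = function(f, ...) ksdensity_pattern(points, f_k = f, ...))
  scores <- purrr::map_dfr(factor_grid, function(f) {
    mask <- est(f, ...)
    sc <- score_pattern(mask, truth_polygon)
    tibble(factor = f, f1 = sc$f1, area_um2 = mask$area_um2)
  })
  best <- scores$factor[order(-scores$f1, scores$factor)][1L]
  list(best_factor = best, scores = scores)
}
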