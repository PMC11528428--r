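#' First nearest-neighbour distance distribution
#'
#' Homo mode (one point set): per-point distance to the nearest distinct
#' point of the same set.  Hetero mode (two sets): per-`points_a` distance
#' to the nearest point of `points_b`.
#'
#' @param points_a Coordinates (nm).
#' @param points_b Optional second species' coordinates (nm).
#' @return Numeric vector of distances (nm).
#' @export
nnd_distribution <- function(points_a, points_b = NULL) {
  a <- as_xy(points_a, "points_a")
  if (is.null(points_b)) {
    if (nrow(a) < 2L) abort("Homo-mode NND needs at least 2 points.")
    return(FNN::get.knn(a, k = 1L)$nn.dist[, 1L])
  }
  b <- as_xy(points_b, "points_b")
  if (nrow(a) < 1L || nrow(b) < 1L) abort("Both point sets must be non-empty.")
  FNN::get.knnx(b, a, k = 1L)$nn.dist[, 1L]
}

#' CSR reference distribution inside a pattern mask
#'
#' Draws a complete-spatial-randomness (CSR) reference at the experimentally
#' measured counts: the randomized species' molecules are placed uniformly
#' inside the occupied pixels of `mask`, while the other species (scenarios
#' `a_csr` / `b_csr`) keeps its experimental positions.
#'
#' @param points_a Species-A coordinates (nm).
#' @param points_b Optional species-B coordinates (hetero analyses).
#' @param mask A `pattern_mask` with positive area.
#' @param scenario Which species to randomize: `"both_csr"`, `"a_csr"`
#'   (A randomized, B experimental) or `"b_csr"`.
#' @param seed Integer seed.
#' @return A molecule-map tibble (`x`, `y`, `species`).
#' @export
csr_reference <- function(points_a, points_b = NULL, mask,
                          scenario = c("both_csr", "a_csr", "b_csr"),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  if (!inherits(mask, "pattern_mask")) abort("`mask` must be a pattern_mask.")
  occ_idx <- which(mask$occupancy)
  if (length(occ_idx) == 0L) abort("`mask` has no occupied pixels.")
  a <- as_xy(points_a, "points_a")
  b <- if (!is.null(points_b)) as_xy(points_b, "points_b")
  n_px <- length(occ_idx)
  dens <- (nrow(a) + if (is.null(b)) 0L else nrow(b)) /
    (n_px * mask$pixel_nm^2 * 1e-6)
  if (dens > 1e4) warn("CSR density above 1e4 um^-2; mask may be too small.")

  draw <- function(n) {
    pick <- occ_idx[sample.int(n_px, n, replace = TRUE)]
    ix <- (pick - 1L) %% nrow(mask$occupancy) + 1L
    iy <- (pick - 1L) %/% nrow(mask$occupancy) + 1L
    cbind(x = mask$origin[1L] + (ix - 1L + runif(n)) * mask$pixel_nm,
          y = mask$origin[2L] + (iy - 1L + runif(n)) * mask$pixel_nm)
  }

  with_seed(seed, {
    out_a <- if (scenario %in% c("both_csr", "a_csr")) draw(nrow(a)) else a
    out_b <- if (is.null(b)) NULL else if (scenario %in% c("both_csr", "b_csr")) draw(nrow(b)) else b
    res <- tibble(x = out_a[, 1L], y = out_a[, 2L], species = "A")
    if (!is.null(out_b)) {
      res <- dplyr::bind_rows(res, tibble(x = out_b[, 1L], y = out_b[, 2L],
                                          species = "B"))
    }
    res
  })
}

# All candidate pairs within `radius`, either cross-set (hetero) or within
# one set (homo, i < j).  Uses kd-tree kNN with an adaptively grown k.
candidate_pairs <- function(a, b = NULL, radius) {
  if (is.null(b)) {
    n <- nrow(a)
    if (n < 2L) return(tibble(i = integer(), j = integer(), dist = numeric()))
    k <- min(n - 1L, 8L)
    repeat {
      nn <- FNN::get.knn(a, k = k)
      # complete iff every point's k-th neighbour already lies beyond radius
      if (k == n - 1L || min(nn$nn.dist[, k]) > radius) break
      k <- min(n - 1L, k * 2L)
    }
    i <- rep(seq_len(n), k)
    j <- as.vector(nn$nn.index)
    d <- as.vector(nn$nn.dist)
    keep <- d <= radius & i < j
    # each unordered pair appears at least once with i < j among the two
    # directed kNN lists as long as k reached past the radius for both ends
    out <- tibble(i = i[keep], j = j[keep], dist = d[keep])
    dplyr::distinct(out, .data$i, .data$j, .keep_all = TRUE)
  } else {
    na <- nrow(a); nb <- nrow(b)
    if (na == 0L || nb == 0L) return(tibble(i = integer(), j = integer(), dist = numeric()))
    k <- min(nb, 8L)
    repeat {
      nn <- FNN::get.knnx(b, a, k = k)
      if (k == nb || min(nn$nn.dist[, k]) > radius) break
      k <- min(nb, k * 2L)
    }
    i <- rep(seq_len(na), k)
    j <- as.vector(nn$nn.index)
    d <- as.vector(nn$nn.dist)
    keep <- d <= radius
    tibble(i = i[keep], j = j[keep], dist = d[keep])
  }
}

#' Match molecules into pairs under a proximity criterion
#'
#' Candidate pairs are all cross-set (hetero) or distinct within-set (homo)
#' pairs at distance `<= proximity_nm`.  Pairs are accepted greedily in
#' ascending distance order with 1:1 exclusivity (each molecule joins at
#' most one pair); ties are broken by lowest index, so the result is
#' deterministic given the input order.  Unmatched molecules are free.
#'
#' @param points_a Coordinates of species A (nm).
#' @param points_b Optional coordinates of species B; omit for
#'   homo-association.
#' @param proximity_nm Proximity criterion (nm, > 0).
#' @return List with `pairs` (tibble `i`, `j`, `dist`; for homo mode both
#'   index into `points_a`), `free_a`, `free_b` (integer indices),
#'   `n_pairs`, `n_free_a`, `n_free_b`.
#' @export
match_pairs <- function(points_a, points_b = NULL, proximity_nm) {
  if (proximity_nm <= 0) abort("`proximity_nm` must be positive.")
  a <- as_xy(points_a, "points_a")
  b <- if (!is.null(points_b)) as_xy(points_b, "points_b")
  cand <- candidate_pairs(a, b, proximity_nm)
  homo <- is.null(b)
  ord <- order(cand$dist, cand$i, cand$j)
  ci <- cand$i[ord]; cj <- cand$j[ord]; cd <- cand$dist[ord]

  used_a <- logical(nrow(a))
  used_b <- if (homo) used_a else logical(nrow(b))
  keep <- logical(length(ci))
  if (homo) {
    for (k in seq_along(ci)) {
      if (!used_a[ci[k]] && !used_a[cj[k]]) {
        used_a[ci[k]] <- TRUE; used_a[cj[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    free_a <- which(!used_a); free_b <- integer()
  } else {
    for (k in seq_along(ci)) {
      if (!used_a[ci[k]] && !used_b[cj[k]]) {
        used_a[ci[k]] <- TRUE; used_b[cj[k]] <- TRUE
        keep[k] <- TRUE
      }
    }
    free_a <- which(!used_a); free_b <- which(!used_b)
  }
  pairs <- tibble(i = ci[keep], j = cj[keep], dist = cd[keep])
  list(pairs = pairs, free_a = free_a, free_b = free_b,
       n_pairs = nrow(pairs), n_free_a = length(free_a),
       n_free_b = if (homo) length(free_a) else length(free_b))
}

new_equilibrium_result <- function(...) {
  structure(tibble(...), class = c("equilibrium_result", class(tibble())))
}

#' Two-dimensional association constant
#'
#' For a 1:1 association with Ka = \[AB\]/(\[A\]\[B\]) on an area scale,
#' `Ka = n_pairs * A / (n_free_a * n_free_b)` in um^2.  For homo-association
#' (dimerization) both free factors are the same species' free monomer
#' count: `Ka = n_pairs * A / n_free^2`.
#'
#' @param pairs Number of bound pairs, or the list returned by
#'   [match_pairs()] (in which case the free counts are taken from it).
#' @param n_free_a,n_free_b Free-molecule counts (`n_free_b` defaults to
#'   `n_free_a`, the homo convention).
#' @param area_um2 Occupied area (um^2).
#' @param mode `"hetero"` or `"homo"` (annotation only).
#' @return A one-row `equilibrium_result` tibble with counts, `ka_um2` and
#'   `log_ka` (`NA` with a warning when no pairs were found).
#' @export
#' @examples
#' compute_ka(50, 100, 100, 100)  # Ka = 0.5 um^2
compute_ka <- function(pairs, n_free_a = NULL, n_free_b = NULL, area_um2,
                       mode = c("hetero", "homo")) {
  mode <- match.arg(mode)
  if (is.list(pairs) && !is.null(pairs$n_pairs)) {
    n_free_a <- n_free_a %||% pairs$n_free_a
    n_free_b <- n_free_b %||% pairs$n_free_b
    pairs <- pairs$n_pairs
  }
  n_free_b <- n_free_b %||% n_free_a
  if (area_um2 <= 0) abort("`area_um2` must be positive.")
  if (n_free_a <= 0 || n_free_b <= 0) {
    abort("Association constant undefined: no free molecules.")
  }
  ka <- pairs * area_um2 / (n_free_a * n_free_b)
  if (pairs == 0) warn("No pairs found: Ka = 0, log Ka undefined.")
  new_equilibrium_result(
    n_pairs = as.integer(pairs), n_free_a = as.integer(n_free_a),
    n_free_b = as.integer(n_free_b), area_um2 = area_um2,
    ka_um2 = ka, log_k = ifelse(ka > 0, log10(ka), NA_real_),
    scale = "um2", mode = mode)
}

#' Molar dissociation constant through the TIRF observation volume
#'
#' For a membrane receptor R binding a cytosolic ligand L
#' (R + L <-> RL), the free-ligand concentration is obtained by
#' converting the occupied area to a volume via the TIRF evanescent-field
#' depth: `c_L = n_free_ligand / (area_um2 * depth_um * 1e-15 L * N_A)`,
#' and `Kd = c_L * n_free_receptor / n_pairs` (molar).
#'
#' @param pairs Number of bound complexes (> 0), or a [match_pairs()] result
#'   (ligand = species B).
#' @param n_free_receptor,n_free_ligand Free counts.
#' @param area_um2 Occupied area (um^2).
#' @param tirf_depth_nm TIRF depth (nm), in `[100, 250]`.
#' @return One-row `equilibrium_result` tibble with `kd_molar` and `log_k`.
#' @export
compute_kd_molar <- function(pairs, n_free_receptor = NULL,
                             n_free_ligand = NULL, area_um2,
                             tirf_depth_nm = 100) {
  if (is.list(pairs) && !is.null(pairs$n_pairs)) {
    n_free_receptor <- n_free_receptor %||% pairs$n_free_a
    n_free_ligand <- n_free_ligand %||% pairs$n_free_b
    pairs <- pairs$n_pairs
  }
  if (tirf_depth_nm < 100 || tirf_depth_nm > 250) {
    abort("`tirf_depth_nm` must lie in [100, 250] nm.")
  }
  if (pairs <= 0) abort("Dissociation constant undefined: no bound complexes.")
  if (area_um2 <= 0) abort("`area_um2` must be positive.")
  volume_l <- area_um2 * (tirf_depth_nm * 1e-3) * 1e-15
  c_ligand <- n_free_ligand / (volume_l * .N_AVOGADRO)
  kd <- c_ligand * n_free_receptor / pairs
  new_equilibrium_result(
    n_pairs = as.integer(pairs), n_free_a = as.integer(n_free_receptor),
    n_free_b = as.integer(n_free_ligand), area_um2 = area_um2,
    kd_molar = kd, log_k = log10(kd), scale = "molar",
    mode = "hetero_dissociation", tirf_depth_nm = tirf_depth_nm,
    c_free_ligand_molar = c_ligand)
}

#' Proximity-threshold scan against CSR references
#'
#' Computes the apparent log Ka of the experimental distribution and of CSR
#' references (mean over `n_csr` seeded realizations inside `mask`) at each
#' proximity threshold, and their difference
#' `delta = log_k_exp - log_k_csr`.  The threshold maximizing delta is the
#' data-driven proximity criterion.
#'
#' @param points_a,points_b Experimental coordinates (nm); `points_b = NULL`
#'   for homo-association.
#' @param mask `pattern_mask` providing both the CSR support and the area.
#' @param thresholds Ascending proximity thresholds (nm).
#' @param scenario CSR scenario passed to [csr_reference()].
#' @param n_csr Number of CSR realizations per threshold (default 20).
#' @param seed Integer seed.
#' @return A tibble (class `smlmeq_scan`) with one row per threshold:
#'   `threshold_nm`, `log_k_exp`, `log_k_csr`, `log_k_csr_sd`, `delta`;
#'   attribute `best_threshold_nm` holds the argmax of delta.
#' @export
threshold_scan <- function(points_a, points_b = NULL, mask, thresholds,
                           scenario = c("both_csr", "a_csr", "b_csr"),
                           n_csr = 20L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted ascending.")
  a <- as_xy(points_a, "points_a")
  b <- if (!is.null(points_b)) as_xy(points_b, "points_b")
  homo <- is.null(b)
  area <- mask$area_um2
  mode <- if (homo) "homo" else "hetero"

  log_ka_at <- function(pa, pb, r) {
    m <- match_pairs(pa, pb, r)
    if (m$n_pairs == 0L || m$n_free_a == 0L || m$n_free_b == 0L) return(NA_real_)
    log10(m$n_pairs * area / (m$n_free_a * m$n_free_b))
  }

  refs <- purrr::map(seq_len(n_csr), function(r) {
    ref <- csr_reference(a, b, mask, scenario = scenario, seed = seed + r)
    list(a = as_xy(ref[ref$species == "A", ], "csr"),
         b = if (homo) NULL else as_xy(ref[ref$species == "B", ], "csr"))
  })

  rows <- purrr::map_dfr(thresholds, function(r) {
    lk_exp <- log_ka_at(a, b, r)
    lk_csr <- vapply(refs, function(ref) log_ka_at(ref$a, ref$b, r), numeric(1))
    tibble(threshold_nm = r,
           log_k_exp = lk_exp,
           log_k_csr = mean(lk_csr, na.rm = TRUE),
           log_k_csr_sd = sd(lk_csr, na.rm = TRUE),
           delta = lk_exp - mean(lk_csr, na.rm = TRUE))
  })
  best <- rows$threshold_nm[which.max(rows$delta)]
  structure(rows, best_threshold_nm = best,
            class = c("smlmeq_scan", class(rows)))
}

#' Extrapolate log K to infinite dilution
#'
#' Incomplete labeling makes the apparent constant depend on total molecular
#' density; the corrected value is the intercept of an ordinary
#' least-squares fit of log K against density (or free-ligand
#' concentration), i.e. the extrapolation to infinite dilution.
#'
#' @param series Data frame with the abscissa in the first column (density
#'   or concentration) and `log_k` in the second (or columns named
#'   `density` / `concentration` and `log_k`).
#' @param weights Optional OLS weights.
#' @return A list of class `dilution_fit`: `log_k_limit`, `se`, `slope`,
#'   `n`, and the underlying `lm` fit.
#' @export
extrapolate_to_infinite_dilution <- function(series, weights = NULL) {
  if (!is.data.frame(series) || nrow(series) < 2L) {
    abort("Extrapolation needs at least 2 points.")
  }
  xcol <- intersect(c("density", "concentration"), names(series))
  x <- if (length(xcol) > 0L) series[[xcol[1L]]] else series[[1L]]
  y <- if ("log_k" %in% names(series)) series[["log_k"]] else series[[2L]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L) abort("Extrapolation needs at least 2 distinct abscissae.")
  fit <- if (is.null(weights)) lm(y ~ x) else lm(y ~ x, weights = weights[ok])
  sm <- summary(fit)$coefficients
  structure(list(log_k_limit = unname(coef(fit)[1L]),
                 se = sm[1L, 2L],
                 slope = unname(coef(fit)[2L]),
                 n = length(x),
                 fit = fit),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("Infinite-dilution extrapolation (n = %d): log K_limit = %.3f +/- %.3f (slope %.3g)\n",
              x$n, x$log_k_limit, x$se, x$slope))
  invisible(x)
}

#' Single-linkage clustering of molecules
#'
#' Groups molecules into clusters by single-linkage connectivity at
#' distance `<= linkage_nm` (connected components of the distance graph,
#' computed exactly through the Delaunay triangulation, which contains the
#' Euclidean minimum spanning tree) and tabulates the cluster size
#' distribution.
#'
#' @param points Molecular coordinates (nm).
#' @param linkage_nm Linkage distance (nm, > 0).
#' @return A list of class `smlmeq_clusters`: `assignments` (input tibble
#'   plus `cluster`), `sizes` (tibble `j`, `n_j`), `linkage_nm`.
#' @export
cluster_molecules <- function(points, linkage_nm) {
  if (linkage_nm <= 0) abort("`linkage_nm` must be positive.")
  xy <- as_xy(points)
  comp <- if (nrow(xy) == 1L) 1L else single_linkage_components(xy, linkage_nm)
  sizes_tab <- table(table(comp))
  sizes <- tibble(j = as.integer(names(sizes_tab)),
                  n_j = as.integer(sizes_tab))
  assignments <- as_tibble(as.data.frame(xy))
  assignments$cluster <- as.integer(comp)
  structure(list(assignments = assignments, sizes = sizes,
                 linkage_nm = linkage_nm),
            class = "smlmeq_clusters")
}

#' @export
print.smlmeq_clusters <- function(x, ...) {
  cat(sprintf("%d molecules in %d clusters (linkage %.0f nm); size range %d-%d\n",
              nrow(x$assignments), max(x$assignments$cluster), x$linkage_nm,
              min(x$sizes$j), max(x$sizes$j)))
  invisible(x)
}

#' Stepwise cluster association constants
#'
#' For cluster growth one monomer at a time, the association constant of
#' the step forming a j-mer from a (j-1)-mer and a monomer is
#' `Ka_j = N_j * A / (N_{j-1} * N_1)` (um^2), with `N_j` the number of
#' clusters of j members and `A` the occupied area.  Steps with
#' `N_{j-1} = 0` are skipped.
#'
#' When `reference_curve = TRUE` a column `log_ka_ref` is added with a
#' 1/j-shaped reference anchored at j = 2 — the qualitative expectation for
#' size-independent association with dissociation rate growing linearly in
#' cluster size.  It is a heuristic overlay for comparison, not a fitted
#' model.
#'
#' @param clusters An `smlmeq_clusters` object or a tibble with columns
#'   `j`, `n_j`.
#' @param area_um2 Occupied area (um^2).
#' @param j_max Largest cluster size to report (default: largest observed).
#' @param reference_curve Add the 1/j reference overlay column.
#' @return Tibble with `j`, `n_j`, `ka_j_um2`, `log_ka_j` (and optionally
#'   `log_ka_ref`) for j >= 2.
#' @export
#' @examples
#' stepwise_constants(tibble::tibble(j = 1:2, n_j = c(100, 20)), area_um2 = 50)
stepwise_constants <- function(clusters, area_um2, j_max = NULL,
                               reference_curve = FALSE) {
  sizes <- if (inherits(clusters, "smlmeq_clusters")) clusters$sizes else as_tibble(clusters)
  if (!all(c("j", "n_j") %in% names(sizes))) {
    abort("`clusters` must provide columns `j` and `n_j`.")
  }
  if (area_um2 <= 0) abort("`area_um2` must be positive.")
  j_max <- j_max %||% max(sizes$j)
  n_of <- function(j) {
    hit <- sizes$n_j[sizes$j == j]
    if (length(hit) == 0L) 0L else hit
  }
  n1 <- n_of(1L)
  if (n1 == 0L) abort("No monomers (N_1 = 0): stepwise constants undefined.")
  out <- purrr::map_dfr(2:j_max, function(j) {
    nj <- n_of(j); njm1 <- n_of(j - 1L)
    if (njm1 == 0L || nj == 0L) {
      inform(sprintf("Step j = %d skipped (N_%d = %d, N_%d = %d).",
                     j, j - 1L, njm1, j, nj))
      return(NULL)
    }
    ka <- nj * area_um2 / (njm1 * n1)
    tibble(j = j, n_j = nj, ka_j_um2 = ka, log_ka_j = log10(ka))
  })
  if (reference_curve && nrow(out) > 0L) {
    # anchored at the first reported step; shape ~ 1/j
    out$log_ka_ref <- out$log_ka_j[1L] + log10(out$j[1L] / out$j)
  }
  out
}

#' Langmuir-type occupancy of receptor clusters by a ligand
#'
#' Assigns each ligand molecule to at most one receptor site (greedy
#' nearest-available matching within `proximity_nm`, via [match_pairs()]),
#' then tabulates, per receptor-cluster size j, the mean fraction of
#' occupied sites `p_bound_j = mean(s / j)`.  With
#' `randomization = "ligand_csr"`, a randomized reference repeats the
#' analysis with ligand positions redrawn under CSR inside `mask` (mean
#' over `n_random` realizations).
#'
#' A linear fit of `1 / p_bound_j` against j is reported (slope,
#' intercept).  Converting the slope into a molar Kd requires the
#' free-ligand concentration and is model-dependent; the conversion scale
#' is left to the user (`kd_scale = c_free_ligand`, reported as
#' `kd_slope_scaled = slope * kd_scale` when supplied).
#'
#' @param receptor_clusters `smlmeq_clusters` for the receptor species.
#' @param ligand_points Ligand coordinates (nm).
#' @param proximity_nm Site-occupancy proximity criterion (nm).
#' @param randomization `"none"` or `"ligand_csr"`.
#' @param mask `pattern_mask` (required for `ligand_csr`).
#' @param n_random CSR realizations for the reference (default 10).
#' @param kd_scale Optional free-ligand concentration used to scale the
#'   slope (model-dependent; see Details).
#' @param seed Integer seed.
#' @return A list of class `smlmeq_occupancy`: `by_size` (tibble `j`,
#'   `n_clusters`, `mean_bound`, `p_bound`, and `p_bound_csr` when
#'   randomized), `fit` (one-row tibble with slope and intercept of
#'   `1/p_bound` vs j), `proximity_nm`.
#' @export
occupancy_analysis <- function(receptor_clusters, ligand_points, proximity_nm,
                               randomization = c("none", "ligand_csr"),
                               mask = NULL, n_random = 10L, kd_scale = NULL,
                               seed = 1L) {
  randomization <- match.arg(randomization)
  if (!inherits(receptor_clusters, "smlmeq_clusters")) {
    abort("`receptor_clusters` must come from cluster_molecules().")
  }
  rec <- receptor_clusters$assignments
  lig <- as_xy(ligand_points, "ligand_points")

  occupancy_by_size <- function(lig_xy) {
    m <- match_pairs(rec[, c("x", "y")], lig_xy, proximity_nm)
    bound <- logical(nrow(rec))
    bound[m$pairs$i] <- TRUE
    dplyr::summarise(
      dplyr::group_by(tibble(cluster = rec$cluster, bound = bound), .data$cluster),
      j = dplyr::n(), s = sum(.data$bound), .groups = "drop")
  }

  obs <- occupancy_by_size(lig)
  by_size <- dplyr::summarise(dplyr::group_by(obs, .data$j),
                              n_clusters = dplyr::n(),
                              mean_bound = mean(.data$s),
                              p_bound = mean(.data$s / .data$j),
                              .groups = "drop")

  if (randomization == "ligand_csr") {
    if (is.null(mask)) abort("`mask` is required for ligand_csr randomization.")
    ref <- purrr::map_dfr(seq_len(n_random), function(r) {
      lig_csr <- csr_reference(lig, NULL, mask, scenario = "both_csr",
                               seed = seed + r)
      o <- occupancy_by_size(as_xy(lig_csr, "csr"))
      dplyr::summarise(dplyr::group_by(o, .data$j),
                       p_bound = mean(.data$s / .data$j), .groups = "drop")
    })
    ref <- dplyr::summarise(dplyr::group_by(ref, .data$j),
                            p_bound_csr = mean(.data$p_bound), .groups = "drop")
    by_size <- dplyr::left_join(by_size, ref, by = "j")
  }

  fit_rows <- by_size[by_size$p_bound > 0, , drop = FALSE]
  fit <- if (nrow(fit_rows) >= 2L && length(unique(fit_rows$j)) >= 2L) {
    f <- lm(I(1 / p_bound) ~ j, data = fit_rows)
    tibble(slope = unname(coef(f)[2L]), intercept = unname(coef(f)[1L]),
           kd_slope_scaled = if (is.null(kd_scale)) NA_real_ else
             unname(coef(f)[2L]) * kd_scale)
  } else {
    tibble(slope = NA_real_, intercept = NA_real_, kd_slope_scaled = NA_real_)
  }
  structure(list(by_size = by_size, fit = fit, proximity_nm = proximity_nm),
            class = "smlmeq_occupancy")
}

#' @export
print.smlmeq_occupancy <- function(x, ...) {
  cat(sprintf("Cluster occupancy at %.0f nm proximity (%d sizes):\n",
              x$proximity_nm, nrow(x$by_size)))
  print(x$by_size)
  cat(sprintf("1/p_bound vs j: slope %.3g, intercept %.3g\n",
              x$fit$slope, x$fit$intercept))
  invisible(x)
}

#' Free-energy equivalent of a log K difference
#'
#' Converts a difference on the -dG/RT = log10 K scale into an energy
#' (J/mol): `delta * R * T`.  At T = 298.15 K a difference of 0.3 amounts
#' to about 743 J/mol.
#'
#' @param delta Difference on the log10 K scale.
#' @param temperature_k Temperature (K).
#' @return Energy difference in J/mol.
#' @export
energy_equivalent <- function(delta, temperature_k = 298.15) {
  delta * .R_GAS * temperature_k
}
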