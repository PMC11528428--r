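#' Recover log Ka from a simulated field
#'
#' Runs the estimation pipeline on one simulated field: estimate the
#' occupied area from the observed molecular coordinates (both species
#' pooled), keep the molecules inside the recovered pattern, match pairs at
#' the proximity criterion and compute the association constant with the
#' estimated area.
#'
#' @param sim An `smlmeq_sim` from [place_molecules()].
#' @param method Area estimator: `"delaunay"`, `"voronoi"` or
#'   `"ksdensity"`.
#' @param factor Expansion factor (defaults: 3, 3 and 1 respectively).
#' @param th_constant ks-density threshold constant.
#' @param proximity_nm Pair proximity criterion (nm); 15 nm suits the
#'   simulation's localization noise.
#' @param pixel_nm Raster pixel override.
#' @param score Also compute the pixel-wise F1 of the recovered pattern
#'   against the true polygon.
#' @return One-row tibble: method, factor, `mu_nnd_nm`, `area_um2`, `f1`,
#'   counts, `log_ka`, `deviation` (recovered - input).
#' @export
recover_log_ka <- function(sim,
                           method = c("ksdensity", "delaunay", "voronoi"),
                           factor = NULL, th_constant = 1.5,
                           proximity_nm = 15, pixel_nm = NULL,
                           score = TRUE) {
  method <- match.arg(method)
  if (!inherits(sim, "smlmeq_sim")) abort("`sim` must come from place_molecules().")
  factor <- factor %||% switch(method, delaunay = 3, voronoi = 3, ksdensity = 1)
  pts <- sim$molecules[, c("x", "y", "species")]
  frame <- frame_of(sim)
  mask <- switch(method,
    delaunay = delaunay_pattern(pts, f_d = factor, pixel_nm = pixel_nm,
                                frame_nm = frame),
    voronoi = voronoi_pattern(pts, f_v = factor, pixel_nm = pixel_nm,
                              frame_nm = frame),
    ksdensity = ksdensity_pattern(pts, f_k = factor, th_constant = th_constant,
                                  pixel_nm = pixel_nm, frame_nm = frame))
  f1 <- if (score) score_pattern(mask, sim$pattern)$f1 else NA_real_

  keep <- mask$in_pattern
  if (sim$mode == "hetero") {
    a <- pts[keep & pts$species == "A", c("x", "y")]
    b <- pts[keep & pts$species == "B", c("x", "y")]
    m <- match_pairs(a, b, proximity_nm)
    res <- compute_ka(m, area_um2 = mask$area_um2, mode = "hetero")
  } else {
    a <- pts[keep, c("x", "y")]
    m <- match_pairs(a, NULL, proximity_nm)
    res <- compute_ka(m, area_um2 = mask$area_um2, mode = "homo")
  }
  tibble(method = method, factor = factor,
         mu_nnd_nm = mask$mu_nnd_nm, area_um2 = mask$area_um2, f1 = f1,
         n_in_pattern = sum(keep), n_pairs = res$n_pairs,
         n_free_a = res$n_free_a, n_free_b = res$n_free_b,
         log_ka = res$log_k,
         deviation = res$log_k - sim$input_log_ka)
}

frame_of <- function(sim) {
  fr <- attr(sim$pattern, "frame_um")
  if (is.null(fr)) return(NULL)
  c(0, fr[1L] * 1000, 0, fr[2L] * 1000)
}

#' Validation grid: density x affinity recovery study
#'
#' Simulates two-species equilibrium fields over a grid of total densities
#' and affinities inside cell-shaped patterns, recovers the pattern with
#' each area method, matches pairs at the proximity criterion and reports
#' the deviation of the recovered log Ka from the input together with the
#' pattern-recovery F1 — the end-to-end accuracy study of the method.
#'
#' @param densities Total molecular densities (um^-2).
#' @param log_kas Input log10 Ka values (um^2 scale).
#' @param methods Area estimators to run.
#' @param replicates Simulation replicates per cell (default 3).
#' @param seed Integer seed; every cell/replicate derives its own.
#' @param pattern_area_um2 Simulated pattern area (um^2).
#' @param roughness Cell-outline roughness.
#' @param proximity_nm Proximity criterion (nm).
#' @param loc_sigma_nm Simulated localization noise (nm).
#' @param factors Named list of expansion factors
#'   (`delaunay`, `voronoi`, `ksdensity`).
#' @param th_constant ks-density threshold constant.
#' @param pixel_nm Raster pixel override for scoring.
#' @return Tibble (class `smlmeq_grid`) with one row per
#'   (density, log Ka, replicate, method): `f1`, `area_um2`,
#'   `recovered_log_ka`, `deviation`, `cell_seed`, `failed`.
#' @export
run_validation_grid <- function(densities = c(120, 160, 280, 400),
                                log_kas = c(-3, -2, -1, 0),
                                methods = c("delaunay", "voronoi", "ksdensity"),
                                replicates = 3L,
                                seed = 1L,
                                pattern_area_um2 = 100,
                                roughness = 0.1,
                                proximity_nm = 15,
                                loc_sigma_nm = 3,
                                factors = list(delaunay = 3, voronoi = 3,
                                               ksdensity = 1),
                                th_constant = 1.5,
                                pixel_nm = NULL) {
  if (length(methods) == 0L) abort("`methods` must be non-empty.")
  if (length(densities) == 0L || length(log_kas) == 0L) {
    abort("`densities` and `log_kas` must be non-empty.")
  }
  methods <- match.arg(methods, c("delaunay", "voronoi", "ksdensity"),
                       several.ok = TRUE)
  # pattern sized relative to the frame as in the reference geometry
  frame_side <- sqrt(pattern_area_um2 / 0.565)
  cells <- tidyr::expand_grid(density = densities, log_ka = log_kas,
                              replicate = seq_len(replicates))
  rows <- purrr::pmap_dfr(cells, function(density, log_ka, replicate) {
    cell_seed <- (seed * 7919L +
                  match(density, densities) * 1009L +
                  match(log_ka, log_kas) * 101L + replicate) %% 2147483647L
    sim <- tryCatch({
      poly <- make_cell_pattern(c(frame_side, frame_side), pattern_area_um2,
                                roughness = roughness, seed = cell_seed)
      place_molecules(poly, density, log_ka, mode = "hetero",
                      loc_sigma_nm = loc_sigma_nm, seed = cell_seed + 1L)
    }, error = function(e) e)
    purrr::map_dfr(methods, function(mth) {
      base <- tibble(density = density, log_ka = log_ka,
                     replicate = replicate, method = mth,
                     cell_seed = cell_seed)
      if (inherits(sim, "error")) {
        return(dplyr::mutate(base, f1 = NA_real_, area_um2 = NA_real_,
                             recovered_log_ka = NA_real_,
                             deviation = NA_real_, failed = TRUE,
                             message = conditionMessage(sim)))
      }
      out <- tryCatch(
        recover_log_ka(sim, method = mth, factor = factors[[mth]],
                       th_constant = th_constant,
                       proximity_nm = proximity_nm, pixel_nm = pixel_nm),
        error = function(e) e)
      if (inherits(out, "error")) {
        dplyr::mutate(base, f1 = NA_real_, area_um2 = NA_real_,
                      recovered_log_ka = NA_real_, deviation = NA_real_,
                      failed = TRUE, message = conditionMessage(out))
      } else {
        dplyr::mutate(base, f1 = out$f1, area_um2 = out$area_um2,
                      recovered_log_ka = out$log_ka,
                      deviation = out$deviation, failed = FALSE,
                      message = NA_character_)
      }
    })
  })
  structure(rows, seed = seed, class = c("smlmeq_grid", class(rows)))
}

#' Summarize a validation grid per cell
#'
#' Mean and worst-case absolute deviation and minimum F1 per
#' (density, log Ka, method) cell.
#'
#' @param grid Result of [run_validation_grid()].
#' @return Tibble with `mean_deviation`, `worst_abs_deviation`, `min_f1`
#'   per cell.
#' @export
summarize_validation_grid <- function(grid) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(grid), .data$density, .data$log_ka, .data$method),
    mean_deviation = mean(.data$deviation, na.rm = TRUE),
    worst_abs_deviation = max(abs(.data$deviation), na.rm = TRUE),
    min_f1 = min(.data$f1, na.rm = TRUE),
    n_failed = sum(.data$failed),
    .groups = "drop")
}
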