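#' Generate a cell-shaped simulation pattern
#'
#' Builds a simply connected polygon mimicking a cell outline: a circle whose
#' radius is perturbed by low-order Fourier harmonics with random phases, then
#' rescaled so the enclosed area matches `target_area_um2`.  `roughness`
#' controls the total relative amplitude of the perturbation (0 gives a
#' circle).
#'
#' @param frame_size_um Numeric pair, frame width and height (um).
#' @param target_area_um2 Target polygon area (um^2); must be smaller than
#'   the frame area.
#' @param roughness Relative boundary perturbation amplitude in `[0, 1]`.
#' @param seed Integer seed (phases and harmonic amplitudes are random).
#' @param n_vertices Number of boundary vertices.
#' @param harmonics Integer vector of Fourier orders used for the
#'   perturbation.
#' @return A tibble of polygon vertices `x`, `y` in nm (closed implicitly),
#'   with attributes `area_um2` (exact shoelace area) and `frame_um`.
#' @export
#' @examples
#' poly <- make_cell_pattern(c(35, 35), 692, roughness = 0.1, seed = 1)
#' attr(poly, "area_um2")
make_cell_pattern <- function(frame_size_um, target_area_um2,
                              roughness = 0.1, seed = 1L,
                              n_vertices = 256L, harmonics = 2:6) {
  stopifnot(length(frame_size_um) == 2L, all(frame_size_um > 0))
  if (target_area_um2 >= prod(frame_size_um)) {
    abort("`target_area_um2` must be smaller than the frame area.")
  }
  if (roughness < 0 || roughness > 1) abort("`roughness` must be in [0, 1].")

  with_seed(seed, {
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
    amp <- if (roughness > 0) {
      u <- runif(length(harmonics), 0.3, 1) / harmonics
      roughness * u / sum(u)
    } else {
      rep(0, length(harmonics))
    }
    phase <- runif(length(harmonics), 0, 2 * pi)
    r <- rep(1, n_vertices)
    for (k in seq_along(harmonics)) {
      r <- r + amp[k] * cos(harmonics[k] * theta + phase[k])
    }
    # rescale so the polygon area matches the target exactly
    area0 <- polygon_area(cbind(r * cos(theta), r * sin(theta)))
    scale_um <- sqrt(target_area_um2 / area0)
    r <- r * scale_um
    max_r <- min(frame_size_um) / 2
    if (max(r) > max_r) {
      # damp the perturbation until the outline fits inside the frame
      r0 <- mean(r)
      r <- r0 + (r - r0) * (max_r - r0) / (max(r) - r0) * 0.98
      area1 <- polygon_area(cbind(r * cos(theta), r * sin(theta)))
      r <- r * sqrt(target_area_um2 / area1)
      if (max(r) > max_r) {
        abort("Target area does not fit inside the frame at this roughness.")
      }
    }
    cx <- frame_size_um[1L] / 2
    cy <- frame_size_um[2L] / 2
    poly <- tibble(x = (cx + r * cos(theta)) * 1000,
                   y = (cy + r * sin(theta)) * 1000)
    structure(poly,
              area_um2 = polygon_area(cbind(poly$x, poly$y)) * 1e-6,
              frame_um = frame_size_um,
              class = c("smlmeq_polygon", class(poly)))
  })
}

#' Bound-complex density at equilibrium
#'
#' For the 1:1 association A + B <-> AB with Ka = \[AB\]/(\[A\]\[B\]) on an
#' area scale, returns the bound-complex areal density `x` solving the mass
#' balance `ka * (a - x) * (b - x) = x`, i.e. the root of
#' `ka*x^2 - (ka*(a+b)+1)*x + ka*a*b = 0` lying in `[0, min(a, b)]`.
#'
#' @param a_total,b_total Total areal densities of each species (um^-2).
#' @param ka Association constant on the um^2 scale (>= 0).
#' @return Bound complex density (um^-2).
#' @export
#' @examples
#' equilibrium_pair_fraction(80, 80, 0.01)  # 27.53 um^-2
equilibrium_pair_fraction <- function(a_total, b_total, ka) {
  stopifnot(a_total >= 0, b_total >= 0, ka >= 0)
  if (ka == 0 || a_total == 0 || b_total == 0) return(0)
  b <- ka * (a_total + b_total) + 1
  disc <- b^2 - 4 * ka^2 * a_total * b_total
  # smaller quadratic root, computed in the numerically stable form
  x <- 2 * ka * a_total * b_total / (b + sqrt(pmax(disc, 0)))
  min(x, a_total, b_total)
}

# Uniform points inside a polygon by rejection sampling in its bounding box.
runif_in_polygon <- function(n, poly) {
  if (n == 0L) return(cbind(x = numeric(), y = numeric()))
  bb <- apply(as_xy(poly, "polygon"), 2L, range)
  out <- matrix(NA_real_, n, 2L)
  filled <- 0L
  while (filled < n) {
    m <- max(2L * (n - filled), 64L)
    px <- runif(m, bb[1L, 1L], bb[2L, 1L])
    py <- runif(m, bb[1L, 2L], bb[2L, 2L])
    ok <- points_in_polygon(px, py, poly)
    take <- min(sum(ok), n - filled)
    if (take > 0L) {
      idx <- which(ok)[seq_len(take)]
      out[filled + seq_len(take), ] <- cbind(px[idx], py[idx])
      filled <- filled + take
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Place two interacting species at equilibrium inside a pattern
#'
#' Simulates ground-truth molecular positions of species at a total areal
#' density and affinity inside a cell-shaped polygon, then perturbs each
#' position with isotropic Gaussian localization noise to produce the
#' observed coordinates.  In `hetero` mode the two species A and B are
#' present in equal amounts and pair as A + B <-> AB; in `homo` mode a
#' single species dimerizes (2A <-> A2, Ka = \[A2\]/\[A\]^2, solved through
#' the same quadratic with `a = b = rho/2` and `4*ka`).
#'
#' The number of bound pairs is `round(x * area)` with `x` from
#' [equilibrium_pair_fraction()].  Bound partners are placed at distance
#' `pair_separation_nm` with uniform random orientation; all true positions
#' lie inside the polygon (rejection sampling), while noisy observed
#' positions may fall slightly outside it.
#'
#' @param pattern Polygon from [make_cell_pattern()] (or any tibble of
#'   vertices in nm with an `area_um2` attribute).
#' @param total_density Total molecular density, both species pooled
#'   (um^-2); must be <= 1e4.
#' @param log_ka log10 of the association constant on the um^2 scale.
#' @param mode `"hetero"` (A + B) or `"homo"` (single species).
#' @param pair_separation_nm True physical distance between bound partners.
#' @param loc_sigma_nm Localization noise s.d. per coordinate (nm).
#' @param seed Integer seed.
#' @return A list of class `smlmeq_sim`: `molecules` (tibble with observed
#'   `x`, `y`, true `x_true`, `y_true`, `species`, `pair_id`), `pattern`,
#'   `pattern_area_um2`, `input_log_ka`, `total_density`, `mode`, `seed`.
#' @export
place_molecules <- function(pattern, total_density, log_ka,
                            mode = c("hetero", "homo"),
                            pair_separation_nm = 0,
                            loc_sigma_nm = 3,
                            seed = 1L) {
  mode <- match.arg(mode)
  area <- attr(pattern, "area_um2") %||% (polygon_area(as_xy(pattern, "pattern")) * 1e-6)
  if (is.null(area) || area <= 0) abort("`pattern` must enclose a positive area.")
  if (total_density > 1e4) abort("total_density above the supported regime (1e4 um^-2).")
  ka <- 10^log_ka

  with_seed(seed, {
    if (mode == "hetero") {
      a <- total_density / 2
      x <- equilibrium_pair_fraction(a, a, ka)
      n_a <- round(a * area)
      n_b <- n_a
      n_pairs <- round(x * area)
      n_pairs <- min(n_pairs, n_a, n_b)
      species_free <- c(rep("A", n_a - n_pairs), rep("B", n_b - n_pairs))
      pair_species <- c("A", "B")
    } else {
      x <- equilibrium_pair_fraction(total_density / 2, total_density / 2, 4 * ka)
      n_tot <- round(total_density * area)
      n_pairs <- min(round(x * area), n_tot %/% 2L)
      species_free <- rep("A", n_tot - 2L * n_pairs)
      pair_species <- c("A", "A")
    }

    anchors <- runif_in_polygon(n_pairs, pattern)
    partners <- matrix(NA_real_, n_pairs, 2L)
    if (n_pairs > 0L) {
      todo <- seq_len(n_pairs)
      while (length(todo) > 0L) {
        ang <- runif(length(todo), 0, 2 * pi)
        px <- anchors[todo, 1L] + pair_separation_nm * cos(ang)
        py <- anchors[todo, 2L] + pair_separation_nm * sin(ang)
        ok <- if (pair_separation_nm > 0) points_in_polygon(px, py, pattern) else rep(TRUE, length(todo))
        partners[todo[ok], ] <- cbind(px[ok], py[ok])
        bad <- todo[!ok]
        # re-draw both anchor and orientation for rejected partners
        if (length(bad) > 0L) anchors[bad, ] <- runif_in_polygon(length(bad), pattern)
        todo <- bad
      }
    }
    free_xy <- runif_in_polygon(length(species_free), pattern)

    mol <- tibble(
      x_true = c(anchors[, 1L], partners[, 1L], free_xy[, 1L]),
      y_true = c(anchors[, 2L], partners[, 2L], free_xy[, 2L]),
      species = c(rep(pair_species[1L], n_pairs), rep(pair_species[2L], n_pairs),
                  species_free),
      pair_id = c(seq_len(n_pairs), seq_len(n_pairs),
                  rep(NA_integer_, length(species_free)))
    )
    mol$x <- mol$x_true + rnorm(nrow(mol), 0, loc_sigma_nm)
    mol$y <- mol$y_true + rnorm(nrow(mol), 0, loc_sigma_nm)
    mol <- mol[, c("x", "y", "x_true", "y_true", "species", "pair_id")]

    structure(list(molecules = mol,
                   pattern = pattern,
                   pattern_area_um2 = area,
                   input_log_ka = log_ka,
                   total_density = total_density,
                   mode = mode,
                   n_pairs = n_pairs,
                   seed = seed),
              class = "smlmeq_sim")
  })
}

#' @export
print.smlmeq_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated %s field: %d molecules (%d bound pairs) in %.1f um^2\n",
    x$mode, nrow(x$molecules), x$n_pairs, x$pattern_area_um2))
  cat(sprintf("  total density %.0f um^-2, input log Ka = %.2f, seed %d\n",
              x$total_density, x$input_log_ka, x$seed))
  invisible(x)
}

#' Emit DNA-PAINT blinking traces for a molecule map
#'
#' Generates per-molecule ON/OFF time traces from a two-state renewal
#' process -- exponential OFF dwells with mean `tau_off_s / n_sites`
#' (superposition of `n_sites` independent docking sites, taken from
#' `count_weight`) alternating with exponential ON dwells of mean
#' `tau_on_s` -- discretized to camera frames (a frame is ON if any part of
#' an ON dwell overlaps it).  Each ON frame yields one localization at the
#' molecule position plus isotropic Gaussian noise.
#'
#' @param molecules Molecule map tibble (`x`, `y` in nm; optional
#'   `count_weight` = docking-site multiplicity).
#' @param tau_on_s,tau_off_s Mean ON and single-site mean OFF dwell (s).
#' @param frame_interval_s Frame interval (s).
#' @param frame_count Number of frames.
#' @param locs_per_on_frame_sigma_nm Localization noise s.d. (nm).
#' @param seed Integer seed.
#' @return A list: `locs` (localization tibble `x`, `y`, `frame`,
#'   `molecule_id`) and `traces` (tibble of ON bursts `molecule_id`,
#'   `start_frame`, `end_frame` half-open, plus `n_sites`).
#' @export
emit_blink_traces <- function(molecules, tau_on_s, tau_off_s,
                              frame_interval_s, frame_count,
                              locs_per_on_frame_sigma_nm = 5,
                              seed = 1L) {
  stopifnot(tau_on_s > 0, tau_off_s > 0, frame_count >= 1)
  molecules <- as_molecule_map(molecules)
  t_total <- frame_count * frame_interval_s
  if (t_total < 10 * tau_off_s) {
    warn("Acquisition shorter than 10 * tau_off: dark-time statistics unreliable.")
  }

  with_seed(seed, {
    res <- purrr::map(seq_len(nrow(molecules)), function(i) {
      n_sites <- molecules$count_weight[i]
      mean_off <- tau_off_s / n_sites
      n_guess <- max(16L, ceiling(2 * t_total / (mean_off + tau_on_s)) + 8L)
      repeat {
        offs <- rexp(n_guess, 1 / mean_off)
        ons <- rexp(n_guess, 1 / tau_on_s)
        ends <- cumsum(offs + ons)
        if (ends[n_guess] > t_total) break
        n_guess <- n_guess * 2L
      }
      on_start <- ends - ons
      keep <- on_start < t_total
      on_start <- on_start[keep]
      on_end <- pmin(ends[keep], t_total)
      if (length(on_start) == 0L) return(NULL)
      f0 <- pmax(floor(on_start / frame_interval_s), 0)
      f1 <- pmin(floor((on_end - 1e-12) / frame_interval_s), frame_count - 1L)
      ok <- f1 >= f0
      list(bursts = tibble(molecule_id = i,
                           start_frame = as.integer(f0[ok]),
                           end_frame = as.integer(f1[ok]) + 1L,
                           n_sites = n_sites),
           frames = unique(unlist(purrr::map2(f0[ok], f1[ok], seq))))
    })
    res <- purrr::compact(res)
    if (length(res) == 0L) {
      return(list(locs = tibble(x = numeric(), y = numeric(),
                                frame = integer(), molecule_id = integer()),
                  traces = tibble(molecule_id = integer(),
                                  start_frame = integer(),
                                  end_frame = integer(), n_sites = integer())))
    }
    traces <- dplyr::bind_rows(purrr::map(res, "bursts"))
    locs <- purrr::map_dfr(res, function(r) {
      id <- r$bursts$molecule_id[1L]
      tibble(molecule_id = id, frame = as.integer(sort(r$frames)))
    })
    locs$x <- molecules$x[locs$molecule_id] +
      rnorm(nrow(locs), 0, locs_per_on_frame_sigma_nm)
    locs$y <- molecules$y[locs$molecule_id] +
      rnorm(nrow(locs), 0, locs_per_on_frame_sigma_nm)
    list(locs = locs[, c("x", "y", "frame", "molecule_id")], traces = traces)
  })
}
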