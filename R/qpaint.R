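#' Group localizations into single-molecule clusters
#'
#' Density-connected grouping: localizations within `radius_nm` of each
#' other are linked (single-linkage connectivity), and groups with fewer
#' than `min_locs` localizations are discarded as noise (`cluster = NA`).
#'
#' @param table Localization tibble (`x`, `y` in nm, `frame`).
#' @param radius_nm Linking radius (nm, > 0).  A sensible default is about
#'   3x the median localization precision.
#' @param min_locs Minimum localizations per retained cluster.
#' @return The input tibble with an integer `cluster` column (`NA` for
#'   noise); retained clusters are renumbered 1..K.
#' @export
cluster_localizations <- function(table, radius_nm, min_locs = 10L) {
  if (radius_nm <= 0) abort("`radius_nm` must be positive.")
  if (!is.data.frame(table) || nrow(table) == 0L) abort("`table` must be non-empty.")
  xy <- as_xy(table)
  comp <- if (nrow(xy) == 1L) 1L else single_linkage_components(xy, radius_nm)
  counts <- tabulate(comp)
  keep <- counts[comp] >= min_locs
  out <- as_tibble(table)
  cl <- rep(NA_integer_, nrow(out))
  cl[keep] <- as.integer(factor(comp[keep]))
  out$cluster <- cl
  out
}

#' Dark times of a localization cluster
#'
#' Merges localization frames into ON bursts (consecutive frames with gaps
#' of at most `link_gap` frames belong to one burst) and returns the dark
#' times between consecutive bursts: `(gap in frames) * frame_interval_s`,
#' where the gap counts the empty frames strictly between two bursts.
#'
#' @param frames Integer frame indices of one cluster's localizations.
#' @param link_gap Maximum frame gap merged into a burst (default 1).
#' @param frame_interval_s Frame interval (s).
#' @return Numeric vector of dark times (s); empty when the cluster has a
#'   single burst.
#' @export
#' @examples
#' dark_times(c(0, 1, 2, 50, 120), link_gap = 1, frame_interval_s = 0.1)
dark_times <- function(frames, link_gap = 1L, frame_interval_s = 0.1) {
  if (length(frames) < 2L) abort("Need at least 2 localizations.")
  f <- sort(unique(as.integer(frames)))
  gap <- diff(f)
  brk <- which(gap > link_gap)
  if (length(brk) == 0L) return(numeric())
  burst_end <- f[brk]
  burst_start <- f[brk + 1L]
  (burst_start - burst_end - 1L) * frame_interval_s
}

#' qPAINT index
#'
#' The qPAINT index (QPI) of a localization cluster is the inverse of its
#' mean dark time, `1 / mean(tau_off)`.  With `n` independent docking
#' sites the mean dark time shrinks by `1/n`, so the QPI of a cluster is
#' (up to sampling error) an integer multiple of the single-site QPI.
#'
#' @param dark_times_s Positive dark times (s), at least one.
#' @return QPI in 1/s.
#' @export
qpi <- function(dark_times_s) {
  if (length(dark_times_s) == 0L) {
    abort("QPI undefined: no dark times (single-burst cluster).")
  }
  1 / mean(dark_times_s)
}

#' Fit the QPI histogram with Gaussians at integer multiples of a unit QPI
#'
#' Bins the QPI values (Freedman-Diaconis widths) and least-squares fits
#' the histogram to `sum_k A_k * Normal(k * q1, sigma_k)`, `k = 1..K`, with
#' the unit QPI `q1` shared across components so the peak means are exact
#' integer multiples by construction.  Initialization takes `q1` from the
#' histogram's first mode.
#'
#' @param qpis Numeric QPI values (1/s), at least 20.
#' @param K Number of Gaussian components (default 2).
#' @return A `qpi_fit` object: `unit_qpi_s_inv`, `peak_means`,
#'   `peak_sigmas`, `peak_weights` (normalized to 1), `K`, `histogram`
#'   (tibble of bin mids and densities) and the `nls` fit.
#' @export
fit_qpi_mixture <- function(qpis, K = 2L) {
  qpis <- qpis[is.finite(qpis)]
  if (length(qpis) < 20L) abort("Need at least 20 QPI values to fit.")
  if (K < 1L) abort("`K` must be >= 1.")
  bw <- 2 * stats::IQR(qpis) / length(qpis)^(1 / 3)
  if (bw <= 0) bw <- diff(range(qpis)) / 30
  if (bw <= 0) {
    # all values identical: unit QPI is that value, width at resolution floor
    return(new_qpi_fit(unit = qpis[1L], sigmas = rep(1e-6, K),
                       amps = c(length(qpis), rep(0, K - 1L)), K = K,
                       histogram = tibble(mid = qpis[1L], density = 1),
                       fit = NULL))
  }
  breaks <- seq(0, max(qpis) + bw, by = bw)
  h <- graphics::hist(qpis, breaks = breaks, plot = FALSE)
  dat <- tibble(mid = h$mids, density = h$density)

  # initialize the unit QPI from the histogram's FIRST mode: the lowest-QPI
  # local maximum of substantial height (higher multiples sit at k * q1)
  dens <- h$density
  is_peak <- dens >= c(-Inf, head(dens, -1L)) & dens >= c(tail(dens, -1L), -Inf)
  prominent <- which(is_peak & dens >= 0.25 * max(dens))
  q1_0 <- h$mids[prominent[1L]]
  # parameter vector: q1, then (a_k, s_k) per component; q1 is kept near the
  # first mode so the solution cannot slide to the q1/2 relabelling
  start <- c(q1_0, as.vector(rbind(max(h$density) * q1_0 / seq_len(K),
                                   rep(q1_0 / 5, K))))
  lower <- c(q1_0 * 0.6, rep(c(0, q1_0 / 50), K))
  upper <- c(q1_0 * 1.6, rep(c(Inf, q1_0 * 2), K))
  model <- function(par, x) {
    q1 <- par[1L]
    out <- 0
    for (k in seq_len(K)) {
      out <- out + par[2L * k] * dnorm(x, k * q1, par[2L * k + 1L])
    }
    out
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(par) dat$density - model(par, dat$mid),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      abort(sprintf(
        "QPI mixture fit failed to converge (initial q1 = %.4g): %s",
        q1_0, conditionMessage(e)))
    })
  if (fit$info == 0L || fit$info == 5L) {
    abort(sprintf(
      "QPI mixture fit failed to converge (initial q1 = %.4g): %s",
      q1_0, fit$message))
  }
  par <- fit$par
  # component weights = fitted mass with data support (a spike squeezed in
  # between histogram bins carries no evidence and gets weight ~ 0)
  masses <- vapply(seq_len(K), function(k) {
    sum(par[2L * k] * dnorm(dat$mid, k * par[1L], par[2L * k + 1L])) * bw
  }, numeric(1))
  new_qpi_fit(unit = par[1L],
              sigmas = par[2L * seq_len(K) + 1L],
              amps = masses,
              K = K, histogram = dat, fit = fit)
}

new_qpi_fit <- function(unit, sigmas, amps, K, histogram, fit) {
  w <- if (sum(amps) > 0) amps / sum(amps) else rep(0, K)
  structure(list(unit_qpi_s_inv = unit,
                 peak_means = unit * seq_len(K),
                 peak_sigmas = sigmas,
                 peak_weights = w,
                 K = K,
                 histogram = histogram,
                 fit = fit),
            class = "qpi_fit")
}

#' @export
print.qpi_fit <- function(x, ...) {
  cat(sprintf("qPAINT index fit: unit QPI = %.4g 1/s, %d components\n",
              x$unit_qpi_s_inv, x$K))
  cat(sprintf("  weights: %s\n", paste(round(x$peak_weights, 3), collapse = ", ")))
  invisible(x)
}

# Deterministic 2-means split of a point cloud: centers initialized at the
# two extremes of the principal axis, fixed number of Lloyd iterations.
split_two_means <- function(xy, iters = 25L) {
  ctr <- colMeans(xy)
  cen <- sweep(xy, 2L, ctr)
  sv <- svd(cen, nu = 0L, nv = 1L)
  proj <- cen %*% sv$v[, 1L]
  c1 <- xy[which.min(proj), ]
  c2 <- xy[which.max(proj), ]
  lab <- rep(1L, nrow(xy))
  for (it in seq_len(iters)) {
    d1 <- (xy[, 1L] - c1[1L])^2 + (xy[, 2L] - c1[2L])^2
    d2 <- (xy[, 1L] - c2[1L])^2 + (xy[, 2L] - c2[2L])^2
    new_lab <- ifelse(d1 <= d2, 1L, 2L)
    if (all(new_lab == lab) && it > 1L) break
    lab <- new_lab
    if (any(lab == 1L)) c1 <- colMeans(xy[lab == 1L, , drop = FALSE])
    if (any(lab == 2L)) c2 <- colMeans(xy[lab == 2L, , drop = FALSE])
  }
  lab
}

# Split one cluster's localizations into `count` sub-positions by repeated
# 2-means splitting of the widest subcluster.
subdivide_cluster <- function(xy, count) {
  groups <- list(xy)
  while (length(groups) < count) {
    spread <- vapply(groups, function(g) {
      if (nrow(g) < 2L) return(-1)
      sum(apply(g, 2L, stats::var))
    }, numeric(1))
    widest <- which.max(spread)
    g <- groups[[widest]]
    if (nrow(g) < 2L) break  # cannot split further
    lab <- split_two_means(g)
    if (length(unique(lab)) < 2L) break
    groups[[widest]] <- g[lab == 1L, , drop = FALSE]
    groups[[length(groups) + 1L]] <- g[lab == 2L, , drop = FALSE]
  }
  t(vapply(groups, colMeans, numeric(2)))
}

#' qPAINT records for clustered localizations
#'
#' Per retained cluster: number of localizations, dark times, QPI and
#' centroid.  Clusters with no measurable dark time (a single burst) get
#' `qpi = NA` and are excluded from histogram fitting.
#'
#' @param table Clustered localization tibble from
#'   [cluster_localizations()] (columns `x`, `y`, `frame`, `cluster`).
#' @param link_gap Burst-linking gap in frames.
#' @param frame_interval_s Frame interval (s).
#' @return Tibble with one row per cluster: `cluster`, `n_locs`,
#'   `n_dark_times`, `qpi_s_inv`, `centroid_x`, `centroid_y`.
#' @export
qpi_records <- function(table, link_gap = 1L, frame_interval_s = 0.1) {
  if (!"cluster" %in% names(table)) {
    abort("`table` must carry a `cluster` column (see cluster_localizations()).")
  }
  tab <- table[!is.na(table$cluster), , drop = FALSE]
  purrr::map_dfr(split(as_tibble(tab), tab$cluster), function(g) {
    dt <- if (nrow(g) < 2L) numeric() else
      dark_times(g$frame, link_gap, frame_interval_s)
    tibble(cluster = g$cluster[1L],
           n_locs = nrow(g),
           n_dark_times = length(dt),
           qpi_s_inv = if (length(dt) == 0L) NA_real_ else 1 / mean(dt),
           centroid_x = mean(g$x),
           centroid_y = mean(g$y))
  })
}

#' Convert qPAINT records into a counted molecule map
#'
#' Each cluster is assigned `max(1, round(qpi / unit_qpi))` molecules and
#' its localization cloud is split into that many sub-positions by
#' deterministic repeated 2-means splitting (always splitting the widest
#' subcluster); the molecule map gains one point of `count_weight = 1` per
#' sub-position.
#'
#' @param records Tibble from [qpi_records()].
#' @param fit A `qpi_fit` (or a single numeric unit QPI).
#' @param table The clustered localization tibble the records came from.
#' @return Molecule-map tibble (`x`, `y`, `species`, `count_weight`,
#'   `source_cluster`).
#' @export
assign_counts <- function(records, fit, table) {
  unit <- if (inherits(fit, "qpi_fit")) fit$unit_qpi_s_inv else as.numeric(fit)
  if (!is.finite(unit) || unit <= 0) abort("Unit QPI must be positive.")
  species <- if ("species" %in% names(table)) table$species[1L] else "A"
  purrr::map_dfr(seq_len(nrow(records)), function(r) {
    cl <- records$cluster[r]
    q <- records$qpi_s_inv[r]
    count <- if (is.finite(q)) max(1L, round(q / unit)) else 1L
    xy <- as_xy(table[!is.na(table$cluster) & table$cluster == cl, , drop = FALSE])
    pos <- if (count == 1L) {
      matrix(colMeans(xy), 1L, 2L)
    } else {
      subdivide_cluster(xy, count)
    }
    tibble(x = pos[, 1L], y = pos[, 2L], species = species,
           count_weight = 1L, source_cluster = as.integer(cl))
  })
}

#' qPAINT molecular counting, end to end
#'
#' Convenience wrapper chaining [cluster_localizations()], [qpi_records()],
#' [fit_qpi_mixture()] and [assign_counts()] into a counted molecule map.
#'
#' @param table Localization tibble (`x`, `y`, `frame`).
#' @param radius_nm Clustering radius (nm).
#' @param min_locs Minimum localizations per cluster.
#' @param link_gap Burst-linking gap (frames).
#' @param frame_interval_s Frame interval (s).
#' @param K Mixture components for the QPI histogram fit.
#' @return List: `molecules` (molecule map), `records`, `fit`.
#' @export
qpaint_molecules <- function(table, radius_nm, min_locs = 10L, link_gap = 1L,
                             frame_interval_s = 0.1, K = 2L) {
  clustered <- cluster_localizations(table, radius_nm, min_locs)
  records <- qpi_records(clustered, link_gap, frame_interval_s)
  fit <- fit_qpi_mixture(records$qpi_s_inv[is.finite(records$qpi_s_inv)], K = K)
  molecules <- assign_counts(records, fit, clustered)
  list(molecules = molecules, records = records, fit = fit)
}
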