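# Shared fixtures: all synthetic, generated in code.

# A small reference simulation: cell-shaped pattern with both species at
# equilibrium.  Cached per options to keep the suite fast.
local_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(area_um2 = 25, density = 160, log_ka = -2, loc_sigma_nm = 3,
           pair_separation_nm = 0, seed = 42, roughness = 0.1,
           mode = "hetero") {
    key <- paste(area_um2, density, log_ka, loc_sigma_nm, pair_separation_nm,
                 seed, roughness, mode, sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    side <- sqrt(area_um2 / 0.565)
    poly <- make_cell_pattern(c(side, side), area_um2, roughness = roughness,
                              seed = seed)
    sim <- place_molecules(poly, density, log_ka, mode = mode,
                           pair_separation_nm = pair_separation_nm,
                           loc_sigma_nm = loc_sigma_nm, seed = seed + 1L)
    cache[[key]] <- sim
    sim
  }
})

sim_frame <- function(sim) {
  fr <- attr(sim$pattern, "frame_um")
  c(0, fr[1] * 1000, 0, fr[2] * 1000)
}

# Brute-force O(n^2) nearest-neighbour distances.
brute_nnd <- function(a, b = NULL) {
  a <- as.matrix(a)
  if (is.null(b)) {
    d <- as.matrix(dist(a))
    diag(d) <- Inf
    unname(apply(d, 1, min))
  } else {
    b <- as.matrix(b)
    unname(apply(a, 1, function(p) min(sqrt((b[, 1] - p[1])^2 + (b[, 2] - p[2])^2))))
  }
}

# Brute-force single-linkage components via pairwise distances + igraph.
brute_components <- function(xy, r) {
  n <- nrow(xy)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  d <- as.matrix(dist(xy))
  idx <- which(d <= r & upper.tri(d), arr.ind = TRUE)
  if (nrow(idx) > 0) g <- igraph::add_edges(g, t(idx))
  igraph::components(g)$membership
}

# Two labelings define the same partition?
same_partition <- function(a, b) {
  all(tapply(b, a, function(v) length(unique(v))) == 1) &&
    all(tapply(a, b, function(v) length(unique(v))) == 1)
}

# Exhaustive maximum matching size on a small candidate-pair list.
brute_max_matching <- function(pairs, n) {
  best <- 0L
  recurse <- function(k, used, size) {
    if (k > nrow(pairs)) {
      best <<- max(best, size)
      return(invisible())
    }
    # prune: even taking all remaining pairs cannot beat best
    if (size + (nrow(pairs) - k + 1L) <= best) return(invisible())
    recurse(k + 1L, used, size)
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used[i] && !used[j + n]) {
      used[i] <- TRUE; used[j + n] <- TRUE
      recurse(k + 1L, used, size + 1L)
    }
  }
  recurse(1L, logical(2L * n), 0L)
  best
}
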