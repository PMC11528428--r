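# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Extract an n x 2 coordinate matrix (nm) from a tibble/data frame/matrix.
as_xy <- function(points, arg = "points") {
  if (is.matrix(points)) {
    if (ncol(points) < 2L) abort(sprintf("`%s` must have two coordinate columns.", arg))
    xy <- points[, 1:2, drop = FALSE]
  } else if (is.data.frame(points)) {
    cols <- intersect(c("x", "y"), names(points))
    if (length(cols) < 2L) {
      abort(sprintf("`%s` must contain columns `x` and `y` (nm).", arg))
    }
    xy <- cbind(points[["x"]], points[["y"]])
  } else {
    abort(sprintf("`%s` must be a data frame or matrix of coordinates.", arg))
  }
  storage.mode(xy) <- "double"
  if (anyNA(xy) || any(!is.finite(xy))) {
    abort(sprintf("`%s` contains missing or non-finite coordinates.", arg))
  }
  colnames(xy) <- c("x", "y")
  xy
}

# Shoelace (signed) polygon area; vertices as two-column matrix, open or closed.
polygon_area <- function(xy) {
  xy <- as_xy(xy, "polygon")
  n <- nrow(xy)
  if (n >= 2L && all(xy[1L, ] == xy[n, ])) {
    xy <- xy[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Vectorized even-odd (crossing-number) point-in-polygon test.
# px, py: query coordinates; poly: two-column vertex matrix (open or closed).
points_in_polygon <- function(px, py, poly) {
  poly <- as_xy(poly, "polygon")
  n <- nrow(poly)
  if (all(poly[1L, ] == poly[n, ])) {
    poly <- poly[-n, , drop = FALSE]
    n <- n - 1L
  }
  inside <- logical(length(px))
  xj <- poly[n, 1L]; yj <- poly[n, 2L]
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    xj <- xi; yj <- yi
  }
  inside
}

# 2D linear convolution of a count matrix with a small kernel via FFT,
# zero-padded so there is no wrap-around. Returns a matrix of dim(m).
conv2_fft <- function(m, kernel) {
  km <- nrow(kernel); kn <- ncol(kernel)
  stopifnot(km %% 2L == 1L, kn %% 2L == 1L)
  n1 <- stats::nextn(nrow(m) + km - 1L, factors = c(2, 3, 5))
  n2 <- stats::nextn(ncol(m) + kn - 1L, factors = c(2, 3, 5))
  pm <- matrix(0, n1, n2)
  pm[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  pk <- matrix(0, n1, n2)
  pk[seq_len(km), seq_len(kn)] <- kernel
  out <- Re(stats::fft(stats::fft(pm) * stats::fft(pk), inverse = TRUE)) / (n1 * n2)
  # centre of the kernel maps to offset (km-1)/2, (kn-1)/2
  r0 <- (km - 1L) / 2L
  c0 <- (kn - 1L) / 2L
  out[r0 + seq_len(nrow(m)), c0 + seq_len(ncol(m)), drop = FALSE]
}

is_collinear <- function(xy, tol = 1e-9) {
  if (nrow(xy) < 3L) return(TRUE)
  v <- sweep(xy, 2L, xy[1L, ])
  cr <- v[, 1L] * v[2L, 2L] - v[, 2L] * v[2L, 1L]
  span <- max(abs(v))
  all(abs(cr) <= tol * max(span^2, 1))
}

# Single-linkage connected components at distance <= linkage, exact, by
# grid bucketing: with cell side linkage/sqrt(2) all points sharing a cell
# are mutually within linkage (star edges suffice), and two cells can only
# link if they lie within two cells of each other, in which case the cells'
# components merge iff the minimum cross-set distance is <= linkage.
single_linkage_components <- function(xy, linkage) {
  n <- nrow(xy)
  if (n == 0L) return(integer())
  if (n == 1L) return(1L)
  s <- linkage / sqrt(2)
  cx <- floor(xy[, 1L] / s)
  cy <- floor(xy[, 2L] / s)
  cx <- cx - min(cx); cy <- cy - min(cy)
  ncx <- max(cx) + 1
  key <- cx + cy * ncx
  ord <- order(key)
  ukey <- unique(key[ord])
  cell_of <- match(key, ukey)                  # point -> occupied-cell index
  first_in_cell <- ord[!duplicated(key[ord])]  # representative point per cell

  # star edges inside each cell
  e_i <- first_in_cell[cell_of]
  e_j <- seq_len(n)
  star <- e_i != e_j
  edges_i <- e_i[star]; edges_j <- e_j[star]

  # candidate neighbouring cell pairs (half-plane of offsets to avoid doubles)
  offs <- cbind(dx = c(1L, 2L, -2L, -1L, 0L, 1L, 2L, -2L, -1L, 0L, 1L, 2L),
                dy = c(0L, 0L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L))
  idx_by_cell <- split(seq_len(n), cell_of)
  sizes <- lengths(idx_by_cell)
  for (o in seq_len(nrow(offs))) {
    nb_key <- ukey + offs[o, 1L] + offs[o, 2L] * ncx
    nb_cell <- match(nb_key, ukey)
    hit <- which(!is.na(nb_cell))
    if (length(hit) == 0L) next
    a_cell <- hit; b_cell <- nb_cell[hit]
    work <- sizes[a_cell] * sizes[b_cell]
    small <- work <= 4096
    # small cell pairs: expand to point pairs and test vectorized
    if (any(small)) {
      ac <- a_cell[small]; bc <- b_cell[small]
      la <- sizes[ac]; lb <- sizes[bc]
      pair_id <- rep.int(seq_along(ac), la * lb)
      a_rep <- unlist(lapply(seq_along(ac), function(q) {
        rep(idx_by_cell[[ac[q]]], each = lb[q])
      }), use.names = FALSE)
      bi <- unlist(lapply(seq_along(ac), function(q) {
        rep(idx_by_cell[[bc[q]]], times = la[q])
      }), use.names = FALSE)
      d2 <- (xy[a_rep, 1L] - xy[bi, 1L])^2 + (xy[a_rep, 2L] - xy[bi, 2L])^2
      ok <- d2 <= linkage^2
      if (any(ok)) {
        # one linking edge per cell pair is enough for connectivity
        lnk <- !duplicated(pair_id[ok])
        edges_i <- c(edges_i, a_rep[ok][lnk])
        edges_j <- c(edges_j, bi[ok][lnk])
      }
    }
    # large cell pairs: nearest-neighbour shortcut
    if (any(!small)) {
      for (q in which(!small)) {
        ia <- idx_by_cell[[a_cell[q]]]
        ib <- idx_by_cell[[b_cell[q]]]
        nn <- FNN::get.knnx(xy[ib, , drop = FALSE], xy[ia, , drop = FALSE], k = 1L)
        w <- which.min(nn$nn.dist[, 1L])
        if (nn$nn.dist[w, 1L] <= linkage) {
          edges_i <- c(edges_i, ia[w])
          edges_j <- c(edges_j, ib[nn$nn.index[w, 1L]])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges_i) > 0L) g <- igraph::add_edges(g, rbind(edges_i, edges_j))
  as.integer(igraph::components(g)$membership)
}
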