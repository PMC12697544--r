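# In-plane geometry primitives shared by the measurement modules.
# All masks are logical nx x ny matrices in the canonical frame
# (x medial->lateral, y inferior->superior). Connectivity is 8-connected
# throughout: the contiguity rules are defined with voxels "connected by
# either corners or edges".

mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  colnames(w) <- c("x", "y")
  w
}

# 8-connected component labeling. Returns an integer matrix (0 = background).
label_components_8 <- function(mask) {
  out <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) {
    return(out)
  }
  nr <- nrow(mask)
  id <- match(seq_len(nr * ncol(mask)), idx) # pixel -> node id (NA off mask)
  # Undirected edges to 4 of the 8 neighbours (the other 4 are mirrored).
  offs <- c(1L, nr, nr + 1L, nr - 1L) # +x, +y, +x+y, -x+y (column-major: +1 row)
  edges <- integer(0)
  x <- ((idx - 1L) %% nr) + 1L
  for (k in seq_along(offs)) {
    nb <- idx + offs[k]
    ok <- nb >= 1L & nb <= length(mask)
    # guard row wrap-around for offsets touching +/- 1 row
    if (offs[k] %in% c(1L, nr + 1L)) ok <- ok & (x < nr)
    if (offs[k] == nr - 1L) ok <- ok & (x > 1L)
    ok <- ok & !is.na(id[pmax(nb, 1L)])
    if (any(ok)) {
      edges <- c(edges, rbind(id[idx[ok]], id[nb[ok]]))
    }
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp)
  out
}

largest_component_size <- function(mask) {
  lab <- label_components_8(mask)
  if (!any(lab > 0L)) {
    return(0L)
  }
  max(tabulate(lab))
}

# 8-neighbourhood boundary pixels of a pixel set (matrix of x,y), as indices
# into an (nr, nc) grid; out-of-image neighbours are reported as NA.
neighbourhood_8 <- function(coords, nr, nc) {
  dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  x <- rep(coords[, 1], each = 8L) + dx
  y <- rep(coords[, 2], each = 8L) + dy
  inside <- x >= 1L & x <= nr & y >= 1L & y <= nc
  list(x = x, y = y, inside = inside)
}

# Zhang-Suen thinning of a binary mask to a 1-pixel-wide 8-connected skeleton.
skeletonize <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask)
  nr <- nrow(img)
  nc <- ncol(img)
  sh <- function(m, dx, dy) {
    out <- matrix(0L, nr, nc)
    xs <- max(1, 1 + dx):min(nr, nr + dx)
    ys <- max(1, 1 + dy):min(nc, nc + dy)
    out[xs, ys] <- m[xs - dx, ys - dy]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise starting north (here: +y is "north")
      p2 <- sh(img, 0, 1)
      p3 <- sh(img, 1, 1)
      p4 <- sh(img, 1, 0)
      p5 <- sh(img, 1, -1)
      p6 <- sh(img, 0, -1)
      p7 <- sh(img, -1, -1)
      p8 <- sh(img, -1, 0)
      p9 <- sh(img, -1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- img == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L
}

# Graph over skeleton pixels; 8-neighbour edges weighted by step length
# (dx for axial steps, dx * sqrt(2) for diagonal steps).
skeleton_graph <- function(skel, dx = 1) {
  coords <- mask_coords(skel)
  n <- nrow(coords)
  if (n == 0L) {
    return(list(graph = igraph::make_empty_graph(0, directed = FALSE), coords = coords))
  }
  key <- coords[, 1] + (coords[, 2] - 1L) * nrow(skel)
  id <- integer(length(skel))
  id[key] <- seq_len(n)
  from <- integer(0)
  to <- integer(0)
  wts <- numeric(0)
  steps <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in steps) {
    nx <- coords[, 1] + s[1]
    ny <- coords[, 2] + s[2]
    ok <- nx >= 1L & nx <= nrow(skel) & ny >= 1L & ny <= ncol(skel)
    nbkey <- nx + (ny - 1L) * nrow(skel)
    ok[ok] <- skel[nbkey[ok]]
    if (any(ok)) {
      from <- c(from, seq_len(n)[ok])
      to <- c(to, id[nbkey[ok]])
      wts <- c(wts, rep(if (all(s != 0L) && sum(abs(s)) == 2L) dx * sqrt(2) else dx, sum(ok)))
    }
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::E(g)$weight <- wts
  list(graph = g, coords = coords)
}

# Remove skeleton spurs: branches from an endpoint to the nearest junction
# that are shorter than `min_len` pixels.
prune_spurs <- function(skel, min_len = 3L) {
  repeat {
    sg <- skeleton_graph(skel)
    if (igraph::vcount(sg$graph) == 0L) {
      return(skel)
    }
    deg <- igraph::degree(sg$graph)
    endpoints <- which(deg == 1L)
    removed_any <- FALSE
    for (e in endpoints) {
      path <- e
      cur <- e
      prev <- -1L
      while (length(path) < min_len) {
        nbs <- setdiff(as.integer(igraph::neighbors(sg$graph, cur)), prev)
        if (length(nbs) != 1L) break
        if (deg[nbs] > 2L) { # reached a junction: this is a spur
          skel[sg$coords[path, , drop = FALSE]] <- FALSE
          removed_any <- TRUE
          break
        }
        prev <- cur
        cur <- nbs
        path <- c(path, cur)
      }
    }
    if (!removed_any) {
      return(skel)
    }
  }
}

# Smoothed polyline length: moving-average the pixel-chain coordinates
# (window `w`, ends kept) then sum Euclidean segment lengths. For straight
# chains this equals the raw chain length; for digitized curves it removes
# the systematic overestimate of the axial/diagonal chain metric.
smoothed_path_length <- function(xy, dx = 1, w = 7L) {
  n <- nrow(xy)
  if (n < 2L) {
    return(0)
  }
  sm <- smooth_polyline(xy, w)
  sum(sqrt(rowSums((sm[-1, , drop = FALSE] - sm[-n, , drop = FALSE])^2))) * dx
}

# Extend a pixel-chain path beyond its first/last point along the local
# end tangent, staying inside `mask`; returns the exit-adjacent point or
# NULL. Compensates the end erosion of morphological thinning.
tangent_extension <- function(xy, mask, from_start = TRUE, lookback = 4L) {
  n <- nrow(xy)
  if (n < 2L) {
    return(NULL)
  }
  if (from_start) {
    p0 <- xy[1, ]
    pk <- xy[min(1L + lookback, n), ]
  } else {
    p0 <- xy[n, ]
    pk <- xy[max(1L, n - lookback), ]
  }
  dir <- p0 - pk
  len <- sqrt(sum(dir^2))
  if (len == 0) {
    return(NULL)
  }
  dir <- dir / len
  t_last <- NULL
  step <- 0.25
  for (t in seq(step, 2 * max(dim(mask)), by = step)) {
    p <- p0 + t * dir
    xi <- round(p[1])
    yi <- round(p[2])
    if (xi < 1 || xi > nrow(mask) || yi < 1 || yi > ncol(mask) || !mask[xi, yi]) break
    t_last <- t
  }
  if (is.null(t_last)) {
    return(NULL)
  }
  t_end <- t_last - step / 2 # stop halfway into the boundary pixel shell
  # ~1-voxel-spaced intermediate points so downstream per-point region
  # assignment stays dense along the extension
  ts <- unique(c(seq(1, t_end, by = 1), t_end))
  ts <- ts[ts > 0]
  if (length(ts) == 0L) {
    return(NULL)
  }
  out <- cbind(p0[1] + ts * dir[1], p0[2] + ts * dir[2])
  if (from_start) out[rev(seq_len(nrow(out))), , drop = FALSE] else out
}

smooth_polyline <- function(xy, w = 7L) {
  n <- nrow(xy)
  if (n <= 2L || w <= 1L) {
    return(xy)
  }
  half <- w %/% 2L
  sm <- xy
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    sm[i, ] <- colMeans(xy[lo:hi, , drop = FALSE])
  }
  sm[1, ] <- xy[1, ]
  sm[n, ] <- xy[n, ]
  sm
}

# Local maxima of a profile with a prominence criterion. Plateaus count as
# a single peak at their centre. Returns integer positions.
find_peaks <- function(y, prominence = 0) {
  n <- length(y)
  if (n == 0L) {
    return(integer(0))
  }
  # candidate peaks: strictly higher than nearest differing neighbours
  cand <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left_ok <- i == 1L || y[i - 1L] < y[i]
    right_ok <- j == n || y[j + 1L] < y[i]
    if (left_ok && right_ok) cand <- c(cand, as.integer(round((i + j) / 2)))
    i <- j + 1L
  }
  if (length(cand) == 0L) {
    return(integer(0))
  }
  keep <- vapply(cand, function(p) peak_prominence(y, p, cand) >= prominence, logical(1))
  cand[keep]
}

peak_prominence <- function(y, p, peaks) {
  h <- y[p]
  # walk left until a higher point; key saddle is the minimum passed
  left_min <- h
  i <- p
  while (i > 1L) {
    i <- i - 1L
    if (y[i] > h) break
    left_min <- min(left_min, y[i])
  }
  if (i == 1L && y[1L] <= h) left_min <- min(left_min, y[1L])
  higher_left <- any(y[seq_len(p - 1L)] > h)
  right_min <- h
  i <- p
  while (i < length(y)) {
    i <- i + 1L
    if (y[i] > h) break
    right_min <- min(right_min, y[i])
  }
  higher_right <- any(y[seq(p, length(y))] > h)
  saddle <- if (higher_left && higher_right) {
    max(left_min, right_min)
  } else if (higher_left) {
    left_min
  } else if (higher_right) {
    right_min
  } else {
    min(left_min, right_min) # global maximum: prominence vs lowest base
  }
  h - saddle
}

# For each query point, squared distance to the nearest point of `ref`
# (both k x 2 matrices); returns list(dist2, index into ref).
nearest_point <- function(query, ref) {
  if (nrow(ref) == 0L) {
    return(list(dist2 = rep(Inf, nrow(query)), index = rep(NA_integer_, nrow(query))))
  }
  d2 <- outer(query[, 1], ref[, 1], "-")^2 + outer(query[, 2], ref[, 2], "-")^2
  idx <- max.col(-d2, ties.method = "first")
  list(dist2 = d2[cbind(seq_len(nrow(query)), idx)], index = idx)
}
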