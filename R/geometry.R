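# Planar polyline geometry: signed areas, brute-force self-intersection and
# decomposition of a self-intersecting closed curve into simple lobes.

# Signed shoelace area of a polygon given in order (closure implicit).
# Positive for counter-clockwise orientation.
shoelace_signed <- function(x, y) {
  xn <- c(x[-1], x[1])
  yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# All pairwise intersections between non-adjacent segments of the closed
# polyline through (x, y) (closure segment appended). O(n^2) by design;
# robust and fast enough at the 500-1500 vertex scale used here.
# Returns a data.frame: seg1, t1, seg2, t2, x, y  (t = parameter along segment).
poly_self_intersections <- function(x, y) {
  n <- length(x)
  x1 <- x
  y1 <- y
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  rx <- x2 - x1
  ry <- y2 - y1
  eps <- 1e-14 * max(abs(c(rx, ry)), 1e-300)^2
  out <- vector("list", 0L)
  for (j in seq_len(n - 2L)) {
    ks <- (j + 2L):n
    if (j == 1L) ks <- ks[ks != n]  # closure segment is adjacent to segment 1
    qpx <- x1[ks] - x1[j]
    qpy <- y1[ks] - y1[j]
    denom <- rx[j] * ry[ks] - ry[j] * rx[ks]
    tnum <- qpx * ry[ks] - qpy * rx[ks]
    unum <- qpx * ry[j] - qpy * rx[j]
    ok <- abs(denom) > eps
    t <- ifelse(ok, tnum / denom, NA_real_)
    u <- ifelse(ok, unum / denom, NA_real_)
    tol <- 1e-12
    hit <- ok & t >= -tol & t <= 1 + tol & u >= -tol & u <= 1 + tol
    if (any(hit)) {
      kk <- ks[hit]
      th <- pmin(pmax(t[hit], 0), 1)
      uh <- pmin(pmax(u[hit], 0), 1)
      out[[length(out) + 1L]] <- data.frame(
        seg1 = j, t1 = th, seg2 = kk, t2 = uh,
        x = x1[j] + th * rx[j], y = y1[j] + th * ry[j])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seg1 = integer(), t1 = numeric(), seg2 = integer(),
                      t2 = numeric(), x = numeric(), y = numeric()))
  }
  do.call(rbind, out)
}

# Greedy single-linkage clustering of 2-D points with a per-axis radius.
# Returns an integer cluster label per point.
cluster_points <- function(px, py, rx, ry) {
  m <- length(px)
  lab <- integer(m)
  cx <- numeric(0)
  cy <- numeric(0)
  for (k in seq_len(m)) {
    if (length(cx)) {
      d <- which(abs(px[k] - cx) <= rx & abs(py[k] - cy) <= ry)
    } else d <- integer(0)
    if (length(d)) {
      lab[k] <- d[1]
    } else {
      cx <- c(cx, px[k])
      cy <- c(cy, py[k])
      lab[k] <- length(cx)
    }
  }
  lab
}

# Total unsigned area enclosed by a (possibly self-intersecting) closed
# polyline: intersections are inserted as explicit vertices, the augmented
# cycle is decomposed into simple loops with a stack, and the absolute
# shoelace areas of the loops are summed.
decompose_loop_area <- function(x, y) {
  ints <- poly_self_intersections(x, y)
  if (nrow(ints) == 0L) return(abs(shoelace_signed(x, y)))

  scale_x <- max(diff(range(x)), 1e-300)
  scale_y <- max(diff(range(y)), 1e-300)
  lab <- cluster_points(ints$x / scale_x, ints$y / scale_y, 1e-9, 1e-9)

  n <- length(x)
  # Build the augmented vertex cycle: each segment's start vertex followed by
  # its intersection points ordered by parameter. Vertices get id 0 (never
  # matched); intersection points carry their cluster id.
  ids <- list()
  xs <- list()
  ys <- list()
  ev1 <- split(seq_len(nrow(ints)), ints$seg1)
  ev2 <- split(seq_len(nrow(ints)), ints$seg2)
  for (k in seq_len(n)) {
    ids[[length(ids) + 1L]] <- 0L
    xs[[length(xs) + 1L]] <- x[k]
    ys[[length(ys) + 1L]] <- y[k]
    r1 <- ev1[[as.character(k)]]
    r2 <- ev2[[as.character(k)]]
    if (length(r1) || length(r2)) {
      tt <- c(ints$t1[r1], ints$t2[r2])
      rr <- c(r1, r2)
      o <- order(tt)
      for (m in o) {
        ids[[length(ids) + 1L]] <- lab[rr[m]]
        xs[[length(xs) + 1L]] <- ints$x[rr[m]]
        ys[[length(ys) + 1L]] <- ints$y[rr[m]]
      }
    }
  }
  ids <- unlist(ids)
  xs <- unlist(xs)
  ys <- unlist(ys)

  # Stack traversal: on re-encountering an open intersection id, the slice
  # since its first occurrence is a simple loop.
  area <- 0
  path_id <- integer(0)
  path_x <- numeric(0)
  path_y <- numeric(0)
  open_pos <- new.env(parent = emptyenv())
  for (k in seq_along(ids)) {
    id <- ids[k]
    key <- as.character(id)
    if (id > 0L && !is.null(open_pos[[key]])) {
      p0 <- open_pos[[key]]
      sel <- p0:length(path_x)
      area <- area + abs(shoelace_signed(c(path_x[sel], xs[k]),
                                         c(path_y[sel], ys[k])))
      # drop loop interior; keep the junction vertex at p0
      if (p0 < length(path_x)) {
        drop <- (p0 + 1L):length(path_x)
        for (d in drop) {
          dk <- as.character(path_id[d])
          if (path_id[d] > 0L && !is.null(open_pos[[dk]]) &&
              open_pos[[dk]] >= p0 + 1L) rm(list = dk, envir = open_pos)
        }
        path_id <- path_id[-drop]
        path_x <- path_x[-drop]
        path_y <- path_y[-drop]
      }
    } else {
      path_id <- c(path_id, id)
      path_x <- c(path_x, xs[k])
      path_y <- c(path_y, ys[k])
      if (id > 0L) open_pos[[key]] <- length(path_x)
    }
  }
  area + abs(shoelace_signed(path_x, path_y))
}
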