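# Planar geometry primitives for polygon handling.
#
# Polygons are lists of rings; each ring is an n x 2 coordinate matrix
# (not necessarily closed -- closure is implicit). The first ring is the
# shell, later rings are holes. Point-in-polygon uses the even-odd rule,
# which makes shells/holes work without orientation bookkeeping.

ring_close <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, , drop = FALSE])
  ring
}

ring_open <- function(ring) {
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

# signed shoelace area of one ring (counter-clockwise positive)
ring_signed_area <- function(ring) {
  ring <- ring_open(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Even-odd area of a polygon given as a list of rings: a ring nested in an
# even number of other rings adds its area, in an odd number subtracts
# (holes). Handles multi-shell ring lists (e.g. repaired bow-ties or
# multipolygon parts flattened into one list).
polygon_area <- function(poly) {
  k <- length(poly)
  if (k == 0) return(0)
  areas <- vapply(poly, function(r) abs(ring_signed_area(r)), numeric(1))
  if (k == 1) return(areas)
  depth <- integer(k)
  for (i in seq_len(k)) {
    p <- ring_open(poly[[i]])[1, ]
    for (j in seq_len(k)) {
      if (i != j && points_in_ring(p[1], p[2], poly[[j]])) depth[i] <- depth[i] + 1L
    }
  }
  sum(areas * ifelse(depth %% 2 == 0, 1, -1))
}

polygon_bbox <- function(poly) {
  xy <- do.call(rbind, poly)
  c(xmin = min(xy[, 1]), ymin = min(xy[, 2]), xmax = max(xy[, 1]), ymax = max(xy[, 2]))
}

# Even-odd point-in-polygon, vectorised over points. Points exactly on an
# edge are treated as inside (the half-open crossing rule makes on-edge
# results orientation dependent; the 15 m dilation test downstream makes
# the distinction immaterial because boundary points are at distance 0).
points_in_ring <- function(px, py, ring) {
  ring <- ring_open(ring)
  n <- nrow(ring)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygon <- function(px, py, poly) {
  inside <- logical(length(px))
  for (ring in poly) inside <- xor(inside, points_in_ring(px, py, ring))
  inside
}

# squared distance from points to one segment, vectorised over points
dist2_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

# distance from points to the polygon boundary (all rings)
dist_to_polygon_boundary <- function(px, py, poly) {
  d2 <- rep(Inf, length(px))
  for (ring in poly) {
    ring <- ring_close(ring)
    for (i in seq_len(nrow(ring) - 1)) {
      d2 <- pmin(d2, dist2_point_segment(px, py, ring[i, 1], ring[i, 2],
                                         ring[i + 1, 1], ring[i + 1, 2]))
    }
  }
  sqrt(d2)
}

# TRUE for points within `buffer` metres of the polygon (interior included)
points_near_polygon <- function(px, py, poly, buffer) {
  inside <- points_in_polygon(px, py, poly)
  if (buffer <= 0) return(inside)
  out <- !inside
  if (any(out)) inside[out] <- dist_to_polygon_boundary(px[out], py[out], poly) <= buffer
  inside
}

# --- ring validity & repair ------------------------------------------------

# proper crossing of segments p1-p2 and p3-p4; returns the intersection
# point or NULL. Touching at endpoints is not a crossing.
segment_crossing <- function(p1, p2, p3, p4, eps = 1e-12) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < eps) return(NULL)
  t <- ((p3[1] - p1[1]) * d2[2] - (p3[2] - p1[2]) * d2[1]) / denom
  u <- ((p3[1] - p1[1]) * d1[2] - (p3[2] - p1[2]) * d1[1]) / denom
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * d1
}

# self-intersection points of a ring (proper crossings between
# non-adjacent edges)
ring_self_intersections <- function(ring) {
  ring <- ring_open(ring)
  n <- nrow(ring)
  if (n < 4) return(list())
  hits <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1) next
      if (i == 1 && j == n) next  # adjacent through closure
      p <- segment_crossing(ring[i, ], ring[i %% n + 1, ],
                            ring[j, ], ring[j %% n + 1, ])
      if (!is.null(p)) hits[[length(hits) + 1]] <- list(i = i, j = j, p = p)
    }
  }
  hits
}

# Repair a self-intersecting ring by splitting it at its crossing points
# and keeping every resulting simple loop (the even-odd reading of the
# ring, matching a zero-width-buffer / make-valid repair for transversal
# crossings such as bow-ties). Returns a list of simple rings.
repair_ring <- function(ring, tol = 1e-9) {
  ring <- ring_open(ring)
  hits <- ring_self_intersections(ring)
  if (length(hits) == 0) return(list(ring))

  n <- nrow(ring)
  # insert crossing points into the edge sequence
  extras <- vector("list", n)
  for (h in hits) {
    for (edge in c(h$i, h$j)) {
      a <- ring[edge, ]
      t <- sqrt(sum((h$p - a)^2))
      extras[[edge]] <- rbind(extras[[edge]], c(h$p, t))
    }
  }
  pts <- list()
  for (i in seq_len(n)) {
    pts[[length(pts) + 1]] <- ring[i, ]
    ex <- extras[[i]]
    if (!is.null(ex)) {
      ex <- ex[order(ex[, 3]), , drop = FALSE]
      for (k in seq_len(nrow(ex))) pts[[length(pts) + 1]] <- ex[k, 1:2]
    }
  }
  seqm <- do.call(rbind, pts)

  # walk the sequence; when a point repeats, the enclosed stretch is a loop
  loops <- list()
  path <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(seqm))) {
    p <- seqm[i, ]
    if (nrow(path) > 0) {
      same <- which(abs(path[, 1] - p[1]) < tol & abs(path[, 2] - p[2]) < tol)
      if (length(same) > 0) {
        k <- same[1]
        loop <- path[k:nrow(path), , drop = FALSE]
        if (nrow(loop) >= 3 && abs(ring_signed_area(loop)) > tol)
          loops[[length(loops) + 1]] <- loop
        path <- path[seq_len(k), , drop = FALSE]
        next
      }
    }
    path <- rbind(path, p)
  }
  if (nrow(path) >= 3 && abs(ring_signed_area(path)) > tol)
    loops[[length(loops) + 1]] <- path
  if (length(loops) == 0) list(ring) else loops
}

# Repair a polygon (list of rings): every self-intersecting ring is split
# into its simple loops; the result is a flat ring list interpreted under
# the even-odd rule, which matches a zero-width-buffer / make-valid repair
# for transversal crossings such as bow-ties.
repair_polygon <- function(poly) {
  out <- list()
  for (ring in poly) out <- c(out, repair_ring(ring))
  out
}

polygon_is_valid <- function(poly) {
  all(vapply(poly, function(r) length(ring_self_intersections(r)) == 0, logical(1)))
}
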