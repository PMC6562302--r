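## Planar geometry primitives for home-range estimation. All polygons are
## stored as n x 2 coordinate matrices in counterclockwise order, coordinates
## in meters. Isopleths are unions of convex hulls; union areas are computed
## exactly by a vertical slab decomposition (split the x axis at every vertex
## and edge crossing, where the union's cross-section length is linear in x,
## and integrate by the midpoint rule, which is exact for linear functions).

## Convex hull as a CCW matrix; may return 1 or 2 rows for degenerate input.
convex_hull <- function(points) {
  points <- as.matrix(points)
  pts <- unique(points)
  if (nrow(pts) <= 2) return(pts)
  idx <- chull(pts[, 1], pts[, 2])
  hull <- pts[rev(idx), , drop = FALSE]  # chull is clockwise; reverse to CCW
  if (nrow(hull) < 3) return(hull)
  hull
}

## Shoelace area; 0 for degenerate polygons.
polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

## Boundary-inclusive point-in-convex-polygon test, vectorized over points.
## Handles degenerate polygons (single points and segments).
point_in_convex <- function(px, py, poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n == 1) {
    return(abs(px - poly[1, 1]) <= tol & abs(py - poly[1, 2]) <= tol)
  }
  if (n == 2) {
    ax <- poly[1, 1]; ay <- poly[1, 2]; bx <- poly[2, 1]; by <- poly[2, 2]
    len2 <- (bx - ax)^2 + (by - ay)^2
    if (len2 == 0) return(abs(px - ax) <= tol & abs(py - ay) <= tol)
    len <- sqrt(len2)
    cross <- (bx - ax) * (py - ay) - (by - ay) * (px - ax)
    t <- ((px - ax) * (bx - ax) + (py - ay) * (by - ay)) / len2
    dist_tol <- tol * max(1, len)
    return(abs(cross) / len <= dist_tol & t >= -tol & t <= 1 + tol)
  }
  inside <- rep(TRUE, length(px))
  scale <- max(abs(poly)) + 1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    inside <- inside & (cr >= -tol * scale)
    if (!any(inside)) break
  }
  inside
}

## Sutherland-Hodgman clip of a convex subject polygon by a convex CCW clip
## polygon; returns a CCW matrix (possibly with < 3 rows when the
## intersection is empty or degenerate).
clip_convex <- function(subject, clip) {
  if (nrow(subject) < 3 || nrow(clip) < 3) return(subject[0, , drop = FALSE])
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    n <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])
    keep <- side >= 0
    res <- matrix(0, 0, 2)
    for (k in seq_len(n)) {
      k2 <- if (k == n) 1L else k + 1L
      if (keep[k]) res <- rbind(res, inp[k, ])
      if (xor(keep[k], keep[k2])) {
        t <- side[k] / (side[k] - side[k2])
        res <- rbind(res, inp[k, ] + t * (inp[k2, ] - inp[k, ]))
      }
    }
    out <- res
  }
  out
}

## Separating-axis overlap test for convex polygons (touching counts as
## overlapping). Degenerate polygons are supported by adding edge-direction
## axes.
convex_overlap <- function(A, B, tol = 1e-9) {
  axes_of <- function(P) {
    n <- nrow(P)
    if (n == 1) return(matrix(0, 0, 2))
    idx2 <- c(seq_len(n)[-1], 1)
    ex <- P[idx2, 1] - P[, 1]
    ey <- P[idx2, 2] - P[, 2]
    ax <- cbind(-ey, ex)
    if (n == 2) ax <- rbind(ax, cbind(ex, ey))
    len <- sqrt(rowSums(ax^2))
    ax <- ax[len > 0, , drop = FALSE] / len[len > 0]
    ax
  }
  axes <- rbind(axes_of(A), axes_of(B))
  if (nrow(axes) == 0) {
    return(sqrt(sum((A[1, ] - B[1, ])^2)) <= tol)
  }
  scale <- max(abs(rbind(A, B))) + 1
  for (i in seq_len(nrow(axes))) {
    pa <- A %*% axes[i, ]
    pb <- B %*% axes[i, ]
    if (max(pa) < min(pb) - tol * scale || max(pb) < min(pa) - tol * scale)
      return(FALSE)
  }
  TRUE
}

## Exact area of the union of convex polygons via slab decomposition.
union_area <- function(polys) {
  polys <- Filter(function(p) polygon_area(p) > 0, polys)
  if (!length(polys)) return(0)
  if (length(polys) == 1) return(polygon_area(polys[[1]]))
  edges <- do.call(rbind, lapply(seq_along(polys), function(i) {
    P <- polys[[i]]
    n <- nrow(P)
    idx2 <- c(seq_len(n)[-1], 1)
    cbind(P[, 1], P[, 2], P[idx2, 1], P[idx2, 2], i)
  }))
  xs <- c(edges[, 1], edges[, 3])
  ne <- nrow(edges)
  xlo <- pmin(edges[, 1], edges[, 3])
  xhi <- pmax(edges[, 1], edges[, 3])
  # candidate crossing pairs of edges from different polygons
  cand <- which(outer(xlo, xhi, "<=") & outer(xhi, xlo, ">=") &
                  outer(edges[, 5], edges[, 5], "!="), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (nrow(cand)) {
    p1 <- edges[cand[, 1], , drop = FALSE]
    p2 <- edges[cand[, 2], , drop = FALSE]
    rx <- p1[, 3] - p1[, 1]; ry <- p1[, 4] - p1[, 2]
    sx <- p2[, 3] - p2[, 1]; sy <- p2[, 4] - p2[, 2]
    denom <- rx * sy - ry * sx
    qpx <- p2[, 1] - p1[, 1]; qpy <- p2[, 2] - p1[, 2]
    t <- (qpx * sy - qpy * sx) / denom
    u <- (qpx * ry - qpy * rx) / denom
    ok <- is.finite(t) & is.finite(u) & t >= 0 & t <= 1 & u >= 0 & u <= 1
    xs <- c(xs, p1[ok, 1] + t[ok] * rx[ok])
  }
  xs <- sort(unique(xs))
  scale <- max(abs(xs)) + 1
  widths <- diff(xs)
  keep <- widths > 1e-12 * scale
  if (!any(keep)) return(0)
  mids <- (xs[-1] + xs[-length(xs)])[keep] / 2
  widths <- widths[keep]
  M <- length(mids)
  # per-polygon y-interval at each slab midpoint
  entries_mid <- integer(0)
  entries_lo <- numeric(0)
  entries_hi <- numeric(0)
  for (i in seq_along(polys)) {
    P <- polys[[i]]
    n <- nrow(P)
    idx2 <- c(seq_len(n)[-1], 1)
    x1 <- P[, 1]; y1 <- P[, 2]; x2 <- P[idx2, 1]; y2 <- P[idx2, 2]
    pxlo <- min(x1); pxhi <- max(x1)
    rel <- which(mids > pxlo & mids < pxhi)
    if (!length(rel)) next
    xm <- mids[rel]
    ylo <- rep(Inf, length(rel))
    yhi <- rep(-Inf, length(rel))
    for (e in seq_len(n)) {
      lo <- min(x1[e], x2[e]); hi <- max(x1[e], x2[e])
      crosses <- xm > lo & xm < hi
      if (!any(crosses)) next
      yv <- y1[e] + (xm[crosses] - x1[e]) * (y2[e] - y1[e]) / (x2[e] - x1[e])
      ylo[crosses] <- pmin(ylo[crosses], yv)
      yhi[crosses] <- pmax(yhi[crosses], yv)
    }
    valid <- is.finite(ylo) & yhi > ylo
    entries_mid <- c(entries_mid, rel[valid])
    entries_lo <- c(entries_lo, ylo[valid])
    entries_hi <- c(entries_hi, yhi[valid])
  }
  if (!length(entries_mid)) return(0)
  ord <- order(entries_mid, entries_lo)
  g <- entries_mid[ord]
  lo <- entries_lo[ord]
  hi <- entries_hi[ord]
  # union length of intervals within each midpoint group
  coverage <- numeric(M)
  runmax <- -Inf
  prev_g <- -1L
  for (k in seq_along(g)) {
    if (g[k] != prev_g) {
      runmax <- -Inf
      prev_g <- g[k]
    }
    start <- max(lo[k], runmax)
    if (hi[k] > start) coverage[g[k]] <- coverage[g[k]] + hi[k] - start
    runmax <- max(runmax, hi[k])
  }
  sum(widths * coverage)
}

## Area of the intersection of two unions of convex polygons.
union_intersection_area <- function(polysA, polysB) {
  polysA <- Filter(function(p) polygon_area(p) > 0, polysA)
  polysB <- Filter(function(p) polygon_area(p) > 0, polysB)
  if (!length(polysA) || !length(polysB)) return(0)
  pieces <- list()
  bbox <- function(p) c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  bbA <- lapply(polysA, bbox)
  bbB <- lapply(polysB, bbox)
  for (i in seq_along(polysA)) {
    for (j in seq_along(polysB)) {
      a <- bbA[[i]]; b <- bbB[[j]]
      if (a[2] < b[1] || b[2] < a[1] || a[4] < b[3] || b[4] < a[3]) next
      piece <- clip_convex(polysA[[i]], polysB[[j]])
      if (nrow(piece) >= 3 && polygon_area(piece) > 0)
        pieces[[length(pieces) + 1]] <- piece
    }
  }
  union_area(pieces)
}

## Connected components of a set of convex polygons (touching at a point
## counts as connected). Returns component label per polygon.
polygon_components <- function(polys) {
  n <- length(polys)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  bbox <- function(p) c(min(p[, 1]), max(p[, 1]), min(p[, 2]), max(p[, 2]))
  bb <- lapply(polys, bbox)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- bb[[i]]; b <- bb[[j]]
      if (a[2] < b[1] || b[2] < a[1] || a[4] < b[3] || b[4] < a[3]) next
      ri <- find(i); rj <- find(j)
      if (ri == rj) next
      if (convex_overlap(polys[[i]], polys[[j]])) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}
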