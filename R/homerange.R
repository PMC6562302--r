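#' Percent minimum convex polygon home range
#'
#' Peels the points farthest from the arithmetic centroid until `percent`% of
#' points remain (ties kept in input order), then returns their convex hull.
#' The 95% MCP measures overall space use; the 50% MCP the core area.
#'
#' @param points two-column matrix or data frame of coordinates (m), or a
#'   track-like object.
#' @param percent percentage of points to retain, in `(0, 100]`.
#' @param animal_id identifier carried into the estimate.
#' @param coverage_days temporal coverage of the data (days), used for
#'   overlap-based deduplication.
#' @return a `homerange` object: method `"MCP"`, requested and achieved
#'   levels, the hull as a single polygon, `area_km2`, `n_points`.
#' @export
mcp <- function(points, percent = 95, animal_id = "unknown",
                coverage_days = NA_real_) {
  pts <- points_matrix(points)
  if (percent <= 0 || percent > 100) stop("percent must lie in (0, 100]")
  n <- nrow(pts)
  n_keep <- ceiling(n * percent / 100)
  ctr <- colMeans(pts)
  d <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  keep <- order(d, seq_len(n))[seq_len(n_keep)]
  kept <- pts[sort(keep), , drop = FALSE]
  if (nrow(unique(kept)) < 5)
    stop("need at least 5 distinct points after peeling")
  hull <- convex_hull(kept)
  area <- polygon_area(hull)
  if (area <= 0) stop("degenerate hull: peeled points are collinear")
  new_homerange(animal_id, "MCP", percent / 100, n_keep / n, list(hull),
                area, n, coverage_days, components = 1L)
}

#' Maximum pairwise distance of a point set
#'
#' The diameter of the location set, used as the adaptive sphere-of-influence
#' parameter `a` of the a-LoCoH estimator. Exact: computed over convex hull
#' vertices for large sets, all pairs otherwise.
#'
#' @param points two-column matrix/data frame or track-like object (>= 2
#'   points).
#' @return maximum Euclidean distance (m).
#' @export
max_pairwise_distance <- function(points) {
  pts <- points_matrix(points)
  if (nrow(pts) < 2) stop("need at least 2 points")
  if (nrow(pts) > 2000) {
    hull <- convex_hull(pts)
    if (nrow(hull) >= 2) pts <- hull
  }
  max(dist(pts))
}

#' Adaptive local convex hull (a-LoCoH) home range
#'
#' For every location (root), builds the convex hull of the root and the
#' maximal prefix of its distance-sorted neighbors whose cumulative distance
#' to the root does not exceed `a`. Hulls are sorted by the number of
#' locations they enclose (ascending, ties by area) and unioned cumulatively;
#' each requested isopleth is the cumulative union whose enclosed-point
#' fraction is nearest the target. The default targets give the 95% home
#' range and 50% core area.
#'
#' @param points two-column matrix/data frame or track-like object (>= 5
#'   points).
#' @param a sphere-of-influence radius (m); defaults to
#'   [max_pairwise_distance()] of the points (the adaptive rule).
#' @param isopleth_targets fractions of points the isopleths should enclose.
#' @param animal_id,coverage_days metadata carried into the estimates.
#' @return list of `homerange` objects, one per target, each with the hull
#'   union as `polygons`, exact union `area_km2`, achieved fraction, and the
#'   number of noncontiguous components.
#' @export
alocoh <- function(points, a = NULL, isopleth_targets = c(0.5, 0.95),
                   animal_id = "unknown", coverage_days = NA_real_) {
  pts <- points_matrix(points)
  n <- nrow(pts)
  if (n < 5) stop("need at least 5 points")
  if (is.null(a)) a <- max_pairwise_distance(pts)
  if (a <= 0) stop("a must be positive")
  hulls <- vector("list", n)
  areas <- numeric(n)
  enclosed <- integer(n)
  for (i in seq_len(n)) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    ord <- order(d, seq_len(n))
    ord <- ord[ord != i]
    cum <- cumsum(d[ord])
    m <- sum(cum <= a)
    members <- c(i, ord[seq_len(m)])
    hull <- convex_hull(pts[members, , drop = FALSE])
    hulls[[i]] <- hull
    areas[i] <- polygon_area(hull)
    enclosed[i] <- sum(point_in_convex(pts[, 1], pts[, 2], hull))
  }
  if (all(areas <= 0))
    stop("all local hulls are degenerate; increase a or supply more points")
  ord <- order(enclosed, areas, seq_len(n))
  hulls <- hulls[ord]
  inside <- rep(FALSE, n)
  frac <- numeric(n)
  for (j in seq_len(n)) {
    h <- hulls[[j]]
    todo <- which(!inside)
    if (length(todo))
      inside[todo] <- point_in_convex(pts[todo, 1], pts[todo, 2], h)
    frac[j] <- sum(inside) / n
  }
  lapply(isopleth_targets, function(target) {
    j_star <- which.min(abs(frac - target))
    polys <- hulls[seq_len(j_star)]
    area <- union_area(polys)
    if (area <= 0)
      stop("degenerate isopleth at target ", target,
           ": union of local hulls has zero area")
    solid <- Filter(function(p) polygon_area(p) > 0, polys)
    comp <- length(unique(polygon_components(solid)))
    new_homerange(animal_id, "aLoCoH", target, frac[j_star], polys,
                  area, n, coverage_days, components = comp)
  })
}

new_homerange <- function(animal_id, method, level, achieved, polygons,
                          area_m2, n_points, coverage_days, components) {
  structure(list(animal_id = animal_id, method = method, level = level,
                 achieved = achieved, polygons = polygons,
                 area_km2 = area_m2 * 1e-6, n_points = n_points,
                 coverage_days = coverage_days, components = components),
            class = "homerange")
}

#' @export
print.homerange <- function(x, ...) {
  cat(x$method, " home range (", x$animal_id, "): level ", x$level,
      " (achieved ", round(x$achieved, 3), "), area ",
      format(x$area_km2, digits = 4), " km2, ", x$components,
      " component(s)\n", sep = "")
  invisible(x)
}

#' Home-range complexity index
#'
#' `(MCP - LoCoH) / MCP` on areas at the same isopleth level. The index is 0
#' when the two estimates coincide (no complexity) and approaches 1 as the
#' useable space (LoCoH) fragments within the overall extent (MCP). A
#' negative raw value is clamped to 0 with a warning.
#'
#' @param mcp_area MCP isopleth area (> 0), or a `homerange`.
#' @param locoh_area LoCoH isopleth area, or a `homerange`.
#' @return complexity index in `[0, 1)`.
#' @export
complexity_index <- function(mcp_area, locoh_area) {
  if (inherits(mcp_area, "homerange")) mcp_area <- mcp_area$area_km2
  if (inherits(locoh_area, "homerange")) locoh_area <- locoh_area$area_km2
  if (mcp_area <= 0) stop("MCP area must be positive")
  C <- (mcp_area - locoh_area) / mcp_area
  if (C < 0) {
    warning("LoCoH area exceeds MCP area; clamping complexity to 0")
    C <- 0
  }
  C
}

#' Number of noncontiguous polygons in an isopleth
#'
#' Connected components of the polygon union; polygons touching at a single
#' point count as connected.
#'
#' @param polygons a `homerange` or list of convex polygon matrices.
#' @return integer component count.
#' @export
count_components <- function(polygons) {
  if (inherits(polygons, "homerange")) polygons <- polygons$polygons
  solid <- Filter(function(p) polygon_area(p) > 0, polygons)
  if (!length(solid)) return(0L)
  length(unique(polygon_components(solid)))
}

#' Spatial overlap fraction of two home ranges
#'
#' Intersection area divided by the smaller of the two areas, i.e. the
#' fraction of the smaller animal's space contained in the overlap. Both
#' estimates must be at the same isopleth level.
#'
#' @param hr_i,hr_j `homerange` objects.
#' @return overlap fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(hr_i, hr_j) {
  stopifnot(inherits(hr_i, "homerange"), inherits(hr_j, "homerange"))
  if (abs(hr_i$level - hr_j$level) > 1e-9)
    stop("home ranges must be at the same isopleth level")
  inter_m2 <- union_intersection_area(hr_i$polygons, hr_j$polygons)
  inter_m2 * 1e-6 / min(hr_i$area_km2, hr_j$area_km2)
}

#' Deduplicate home ranges of the same social group
#'
#' Home ranges overlapping by more than 90% of the smaller range's space
#' indicate members of one social group; of each such pair, the estimate
#' with the greater temporal coverage is retained. Pairs are resolved
#' greedily in descending overlap order, and a pair is skipped when one
#' member was already dropped, so both members of a pair are never dropped
#' together.
#'
#' @param estimates list of `homerange` objects with `coverage_days` set.
#' @param threshold overlap fraction above which a pair is deduplicated.
#' @return list with `retained` (the kept estimates), `dropped_idx`, and
#'   `overlaps` (data frame of all pairwise fractions).
#' @export
dedup_homeranges <- function(estimates, threshold = 0.90) {
  n <- length(estimates)
  if (n < 2) return(list(retained = estimates, dropped_idx = integer(0),
                         overlaps = data.frame()))
  pairs <- t(combn(n, 2))
  frac <- apply(pairs, 1, function(ij)
    overlap_fraction(estimates[[ij[1]]], estimates[[ij[2]]]))
  ov <- data.frame(i = pairs[, 1], j = pairs[, 2], fraction = frac)
  dropped <- logical(n)
  for (r in order(-ov$fraction)) {
    if (ov$fraction[r] <= threshold) break
    i <- ov$i[r]; j <- ov$j[r]
    if (dropped[i] || dropped[j]) next
    ci <- estimates[[i]]$coverage_days
    cj <- estimates[[j]]$coverage_days
    drop <- if (isTRUE(cj < ci)) j else if (isTRUE(ci < cj)) i else max(i, j)
    dropped[drop] <- TRUE
  }
  list(retained = estimates[!dropped], dropped_idx = which(dropped),
       overlaps = ov)
}

#' Classify a home range along the urbanization gradient
#'
#' Averages the imperviousness of raster cells whose centers fall inside the
#' home-range polygons and assigns the landscape class: natural fragment
#' (< 20%), suburban (20-50%, boundaries inclusive), or highly urbanized
#' (> 50%).
#'
#' @param polygon a `homerange` or list of convex polygon matrices.
#' @param raster an `imperv_raster`.
#' @return list with `class` and `mean_imperviousness`.
#' @export
classify_landscape <- function(polygon, raster) {
  polys <- if (inherits(polygon, "homerange")) polygon$polygons else polygon
  stopifnot(inherits(raster, "imperv_raster"))
  cells <- raster_cells(raster)
  inside <- rep(FALSE, nrow(cells))
  for (p in polys) {
    todo <- which(!inside)
    if (!length(todo)) break
    inside[todo] <- point_in_convex(cells$x[todo], cells$y[todo], p)
  }
  if (!any(inside)) stop("no raster cell centers fall inside the polygon")
  m <- mean(cells$value[inside])
  cls <- if (m < 20) "natural_fragment" else if (m <= 50) "suburban" else
    "highly_urbanized"
  list(class = cls, mean_imperviousness = m)
}

#' Export home ranges as GeoJSON
#'
#' Writes a FeatureCollection of MultiPolygons (planar coordinates in
#' meters) with the estimate metadata as feature properties.
#'
#' @param estimates a `homerange` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homeranges_geojson <- function(estimates, path) {
  if (inherits(estimates, "homerange")) estimates <- list(estimates)
  features <- lapply(estimates, function(hr) {
    rings <- lapply(Filter(function(p) polygon_area(p) > 0, hr$polygons),
                    function(p) {
                      ring <- rbind(p, p[1, , drop = FALSE])
                      list(lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ])))
                    })
    list(type = "Feature",
         geometry = list(type = "MultiPolygon", coordinates = rings),
         properties = list(animal_id = hr$animal_id, method = hr$method,
                           level = hr$level, achieved = hr$achieved,
                           area_km2 = hr$area_km2,
                           components = hr$components))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## Internal: coerce coordinates to a 2-column matrix.
points_matrix <- function(points) {
  if (inherits(points, "sim_track") ||
      (is.data.frame(points) && all(c("x", "y") %in% names(points)))) {
    fixes <- as_track_df(points)
    return(cbind(fixes$x, fixes$y))
  }
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2)
  unname(pts)
}
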