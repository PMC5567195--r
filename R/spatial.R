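#' Habitat patch polygon
#'
#' A planar polygon (meters) bounding the habitat patch whose edge defines
#' "edge of the habitat" in the plot-placement analysis. Coordinates must be
#' projected planar coordinates; geographic (lon/lat) input must be
#' projected upstream.
#'
#' @param exterior numeric matrix (or two-column data frame) of >= 3
#'   vertices of the outer ring; an explicitly closed ring (first vertex
#'   repeated last) is accepted.
#' @param holes optional list of interior rings in the same format.
#' @return an object of class `habitat_polygon`.
#' @examples
#' sq <- habitat_polygon(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' distance_to_edge(c(50, 50), sq)  # 50
#' @export
habitat_polygon <- function(exterior, holes = list()) {
  exterior <- check_ring(exterior, "exterior")
  holes <- lapply(seq_along(holes), function(i) {
    check_ring(holes[[i]], paste0("hole ", i))
  })
  structure(list(parts = list(list(exterior = exterior, holes = holes))),
            class = "habitat_polygon")
}

# validate one ring: >= 3 vertices, non-zero area, no self-intersection;
# returned open (closing vertex stripped)
check_ring <- function(ring, what) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2 || anyNA(ring)) {
    stop(what, " must be a numeric n x 2 matrix without NAs", call. = FALSE)
  }
  n <- nrow(ring)
  if (n >= 4 && all(ring[1, ] == ring[n, ])) {
    ring <- ring[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stop(what, " needs at least 3 distinct vertices", call. = FALSE)
  if (abs(ring_area(ring)) <= 0) {
    stop(what, " has zero area (degenerate ring)", call. = FALSE)
  }
  if (ring_self_intersects(ring)) {
    stop(what, " is self-intersecting", call. = FALSE)
  }
  dimnames(ring) <- NULL
  ring
}

# signed shoelace area of an open ring
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# proper-crossing test for non-adjacent segment pairs (O(n^2); patch rings
# are small)
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closure
      if (segments_cross(a[i, ], b[i, ], a[j, ], b[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                         (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

# min distance from point to the segments of an open ring
ring_distance <- function(point, ring) {
  n <- nrow(ring)
  a <- ring
  b <- ring[c(2:n, 1), , drop = FALSE]
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  len2 <- dx^2 + dy^2
  t <- ((point[1] - a[, 1]) * dx + (point[2] - a[, 2]) * dy) / len2
  t[len2 == 0] <- 0
  t <- pmin(pmax(t, 0), 1)
  px <- a[, 1] + t * dx; py <- a[, 2] + t * dy
  sqrt(min((point[1] - px)^2 + (point[2] - py)^2))
}

# even-odd ray casting; boundary handled by the caller via ring_distance
point_in_ring <- function(point, ring) {
  x <- point[1]; y <- point[2]
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# index of the polygon part containing the point (boundary counts as
# inside), or 0
containing_part <- function(point, polygon, eps = 1e-9) {
  for (k in seq_along(polygon$parts)) {
    part <- polygon$parts[[k]]
    rings <- c(list(part$exterior), part$holes)
    on_boundary <- any(vapply(rings, function(r) {
      ring_distance(point, r) <= eps
    }, logical(1)))
    if (on_boundary) return(k)
    if (point_in_ring(point, part$exterior) &&
        !any(vapply(part$holes, function(h) point_in_ring(point, h),
                    logical(1)))) {
      return(k)
    }
  }
  0L
}

#' Is a point inside the habitat patch?
#'
#' Boundary points count as inside (plots laid along paths on the patch
#' boundary are not excluded).
#'
#' @param point numeric vector `c(x, y)` in meters.
#' @param polygon a [habitat_polygon()].
#' @return logical.
#' @export
point_in_polygon <- function(point, polygon) {
  stopifnot(inherits(polygon, "habitat_polygon"), length(point) == 2)
  containing_part(as.numeric(point), polygon) > 0L
}

#' Distance from a plot location to the habitat edge
#'
#' Minimum Euclidean distance from a point inside the habitat patch to the
#' patch boundary (outer ring or any hole). Boundary points return 0;
#' points outside the patch are an error, since sample plots must lie in
#' the habitat.
#'
#' @param point numeric vector `c(x, y)` in meters.
#' @param polygon a [habitat_polygon()].
#' @return distance in meters (>= 0).
#' @export
distance_to_edge <- function(point, polygon) {
  stopifnot(inherits(polygon, "habitat_polygon"), length(point) == 2)
  point <- as.numeric(point)
  k <- containing_part(point, polygon)
  if (k == 0L) {
    stop("point (", point[1], ", ", point[2],
         ") lies outside the habitat patch", call. = FALSE)
  }
  part <- polygon$parts[[k]]
  rings <- c(list(part$exterior), part$holes)
  min(vapply(rings, function(r) ring_distance(point, r), numeric(1)))
}

#' Read a habitat polygon from GeoJSON
#'
#' Accepts a `Polygon` or `MultiPolygon` geometry (optionally wrapped in a
#' `Feature` or as the first feature of a `FeatureCollection`), with planar
#' coordinates in meters.
#'
#' @param path path to a GeoJSON file.
#' @return a [habitat_polygon()].
#' @export
read_polygon_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  if (identical(g$type, "FeatureCollection")) {
    if (length(g$features) == 0) stop("empty FeatureCollection", call. = FALSE)
    g <- g$features[[1]]
  }
  if (identical(g$type, "Feature")) g <- g$geometry
  ring_from_json <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) {
      c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))
    }))
  }
  part_from_json <- function(poly_coords) {
    rings <- lapply(poly_coords, ring_from_json)
    list(exterior = check_ring(rings[[1]], "exterior"),
         holes = lapply(rings[-1], check_ring, what = "hole"))
  }
  if (identical(g$type, "Polygon")) {
    parts <- list(part_from_json(g$coordinates))
  } else if (identical(g$type, "MultiPolygon")) {
    parts <- lapply(g$coordinates, part_from_json)
  } else {
    stop("unsupported GeoJSON geometry type: ", g$type, call. = FALSE)
  }
  structure(list(parts = parts), class = "habitat_polygon")
}

#' Write a habitat polygon to GeoJSON
#'
#' @param polygon a [habitat_polygon()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_polygon_geojson <- function(polygon, path) {
  stopifnot(inherits(polygon, "habitat_polygon"))
  ring_to_json <- function(ring) {
    ring <- rbind(ring, ring[1, ])  # GeoJSON rings are closed
    lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ]))
  }
  part_to_json <- function(part) {
    c(list(ring_to_json(part$exterior)), lapply(part$holes, ring_to_json))
  }
  if (length(polygon$parts) == 1) {
    geom <- list(type = "Polygon",
                 coordinates = part_to_json(polygon$parts[[1]]))
  } else {
    geom <- list(type = "MultiPolygon",
                 coordinates = lapply(polygon$parts, part_to_json))
  }
  jsonlite::write_json(geom, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Permutation comparison of edge distances between observer groups
#'
#' Tests whether expert and non-expert plots differ in their mean distance
#' to the habitat-patch edge, by permuting the observer-status labels over
#' plots. The observed statistic is the difference of group means (expert
#' minus non-expert); the p-value uses the add-one estimator
#' `(#\{permuted >= observed\} + 1) / (n_permutations + 1)` and is
#' two-sided (on the absolute difference) by default.
#'
#' @param dataset a [survey_dataset()] with both observer groups.
#' @param polygon the patch [habitat_polygon()]; all plot locations must
#'   lie inside it.
#' @param n_permutations number of label permutations (default 5000).
#' @param seed integer RNG seed (mandatory; recorded in the result).
#' @param alternative `"two.sided"` (default) or `"greater"` (experts
#'   farther from the edge than non-experts).
#' @return an object of class `edge_comparison`: list with
#'   `mean_dist_expert`, `mean_dist_nonexpert`, `observed_diff`, `p_value`,
#'   `n_permutations`, `seed`, `alternative`, `distances` (named vector).
#' @export
compare_edge_distance <- function(dataset, polygon, n_permutations = 5000,
                                  seed, alternative = c("two.sided",
                                                        "greater")) {
  stopifnot(inherits(dataset, "survey_dataset"))
  alternative <- match.arg(alternative)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  st <- observer_statuses(dataset)
  if (sum(st == "expert") < 2 || sum(st == "non_expert") < 2) {
    stop("need at least 2 plots per observer group", call. = FALSE)
  }
  d <- vapply(dataset$plots, function(p) {
    distance_to_edge(c(p$x, p$y), polygon)
  }, numeric(1))
  names(d) <- plot_ids(dataset)

  is_exp <- st == "expert"
  stat <- function(flag) mean(d[flag]) - mean(d[!flag])
  observed <- stat(is_exp)

  if (length(unique(d)) == 1) {
    warning("all edge distances identical; p-value set to 1", call. = FALSE)
    p <- 1
    observed <- 0
  } else {
    set.seed(as.integer(seed))
    n <- length(d)
    perm_stat <- vapply(seq_len(n_permutations), function(i) {
      stat(seq_len(n) %in% sample.int(n, sum(is_exp)))
    }, numeric(1))
    p <- if (alternative == "two.sided") {
      (sum(abs(perm_stat) >= abs(observed) - 1e-12) + 1) /
        (n_permutations + 1)
    } else {
      (sum(perm_stat >= observed - 1e-12) + 1) / (n_permutations + 1)
    }
  }
  structure(
    list(mean_dist_expert = mean(d[is_exp]),
         mean_dist_nonexpert = mean(d[!is_exp]),
         observed_diff = observed,
         p_value = p,
         n_permutations = n_permutations,
         seed = as.integer(seed),
         alternative = alternative,
         distances = d),
    class = "edge_comparison"
  )
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat("Edge-distance comparison (permutation test,",
      x$n_permutations, "permutations)\n")
  cat(sprintf("  mean distance to edge: experts %.2f m, non-experts %.2f m\n",
              x$mean_dist_expert, x$mean_dist_nonexpert))
  cat(sprintf("  observed difference: %.2f m (%s), p = %.4g\n",
              x$observed_diff, x$alternative, x$p_value))
  invisible(x)
}
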