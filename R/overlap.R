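#' Percent of suitable habitat intersected by moderate-to-high risk
#'
#' @param habitat binary \code{grid_raster} (non-zero = suitable) on
#'   the risk map's grid.
#' @param riskmap a \code{risk_map}.
#' @return percentage in [0, 100].
#' @export
habitat_overlap <- function(habitat, riskmap) {
  stopifnot(same_grid(habitat$grid, riskmap$raster$grid))
  suit <- !is.na(habitat$values) & habitat$values != 0
  cls <- riskmap$raster$values
  use <- suit & !is.na(cls)
  if (!any(use)) stop("zero suitable cells")
  100 * mean(cls[use] >= 1)
}

shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Adaptive local convex hull (a-LoCoH) home range
#'
#' For each location, a local hull is the convex hull of the point and
#' its nearest neighbours, added in distance order while the cumulative
#' neighbour distance stays within the adaptive parameter \code{a}
#' (default: the maximum pairwise distance among the animal's
#' locations).  Hulls are sorted by ascending area and unioned until
#' the requested fraction of locations is covered (duplicated
#' coordinates count with their multiplicity); the union is the
#' isopleth home range.
#'
#' @param locations a \code{point_set} of one animal's locations.
#' @param isopleth coverage fraction (default 0.95).
#' @param a optional cumulative-distance parameter (m).
#' @param min_locations minimum locations required (default 26, i.e.
#'   more than 25).
#' @param id animal identifier carried to the output.
#' @return object of class \code{home_range}: \code{hulls} (list of
#'   vertex matrices), \code{members} (location indices per hull),
#'   \code{n_locations}, \code{a}, \code{isopleth}, \code{coverage}.
#' @export
alocoh_homerange <- function(locations, isopleth = 0.95, a = NULL,
                             min_locations = 26, id = NULL) {
  n <- nrow(locations)
  if (n < min_locations)
    stop("insufficient locations (", n, " < ", min_locations, ")")
  P <- cbind(locations$x, locations$y)
  D <- as.matrix(stats::dist(P))
  if (max(D) == 0) stop("degenerate geometry: all locations identical")
  if (is.null(a)) a <- max(D)
  hulls <- vector("list", n)
  members <- vector("list", n)
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ])             # self first (distance 0)
    cum <- cumsum(D[i, ord])
    take <- ord[cum <= a]
    pts <- unique(P[take, , drop = FALSE])
    hull <- if (nrow(pts) >= 3) pts[grDevices::chull(pts), , drop = FALSE]
            else pts
    hulls[[i]] <- hull
    members[[i]] <- take
    areas[i] <- shoelace_area(hull)
  }
  ord <- order(areas)
  covered <- logical(n)
  chosen <- integer(0)
  for (h in ord) {
    chosen <- c(chosen, h)
    covered[members[[h]]] <- TRUE
    hull <- hulls[[h]]
    if (nrow(hull) >= 3) {
      inside <- sp::point.in.polygon(P[, 1], P[, 2],
                                     hull[, 1], hull[, 2]) > 0
      covered <- covered | inside
    }
    if (mean(covered) >= isopleth) break
  }
  structure(list(id = if (is.null(id)) locations$id[1] else id,
                 hulls = hulls[chosen], members = members[chosen],
                 n_locations = n, a = a, isopleth = isopleth,
                 coverage = mean(covered), locations = locations),
            class = "home_range")
}

#' @export
print.home_range <- function(x, ...) {
  cat(sprintf("<home_range> %s: %d hulls from %d locations (a = %.0f m), %.0f%% isopleth covering %.1f%%\n",
              x$id, length(x$hulls), x$n_locations, x$a,
              100 * x$isopleth, 100 * x$coverage))
  invisible(x)
}

#' Does a home range contain the given points?
#' @param hr a \code{home_range}.
#' @param x,y point coordinates.
#' @return logical vector.
#' @export
hr_contains <- function(hr, x, y) {
  inside <- rep(FALSE, length(x))
  for (hull in hr$hulls) {
    if (nrow(hull) < 3) next
    inside <- inside |
      sp::point.in.polygon(x, y, hull[, 1], hull[, 2]) > 0
  }
  inside
}

#' Planar area of a home range (km2)
#'
#' Measured by rasterizing the hull union at a fine resolution
#' (cell-center rule), consistent with all other raster statistics.
#'
#' @param hr a \code{home_range}.
#' @param cell rasterization cell size (m); default scales to about
#'   300 cells across the range.
#' @return area in km2.
#' @export
hr_area <- function(hr, cell = NULL) {
  allv <- do.call(rbind, hr$hulls)
  if (is.null(cell))
    cell <- max(diff(range(allv[, 1])), diff(range(allv[, 2]))) / 300
  xs <- seq(min(allv[, 1]) + cell / 2, max(allv[, 1]), by = cell)
  ys <- seq(min(allv[, 2]) + cell / 2, max(allv[, 2]), by = cell)
  px <- rep(xs, times = length(ys)); py <- rep(ys, each = length(xs))
  sum(hr_contains(hr, px, py)) * cell^2 / 1e6
}

#' Overlap of home ranges with moderate-to-high risk
#'
#' Each range is rasterized on the risk map's grid (cell-center rule);
#' its overlap is the percent of non-nodata cells in class moderate or
#' high.  Ranges with no on-grid cells are excluded with a warning.
#'
#' @param homeranges list of \code{home_range}s.
#' @param riskmap a \code{risk_map}.
#' @return list of class \code{overlap_report}: \code{per_range}
#'   (data.frame id, n_cells, percent_overlap), \code{mean}, \code{sd}
#'   (population), \code{min}, \code{max}, \code{percent_with_overlap},
#'   \code{n}.
#' @export
homerange_overlap <- function(homeranges, riskmap) {
  if (!length(homeranges)) stop("at least one home range required")
  g <- riskmap$raster$grid
  cc <- cell_centers(g)
  xs <- rep(cc$x, each = g$n_rows)
  ys <- rep(cc$y, times = g$n_cols)
  cls <- as.vector(riskmap$raster$values)
  rows <- list()
  for (hr in homeranges) {
    inside <- hr_contains(hr, xs, ys)
    k <- cls[inside]
    k <- k[!is.na(k)]
    if (!length(k)) {
      warning("home range with no on-grid cells excluded: ", hr$id)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = hr$id, n_cells = length(k),
      percent_overlap = 100 * mean(k >= 1), stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no home range overlaps the grid")
  per <- do.call(rbind, rows)
  p <- per$percent_overlap
  structure(list(per_range = per, mean = mean(p),
                 sd = sqrt(mean((p - mean(p))^2)),
                 min = min(p), max = max(p),
                 percent_with_overlap = 100 * mean(p > 0),
                 n = nrow(per)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> n = %d ranges: mean %.1f%% +/- %.1f SD (range %.1f-%.1f%%); %.0f%% with any overlap\n",
              x$n, x$mean, x$sd, x$min, x$max, x$percent_with_overlap))
  invisible(x)
}

#' Write home ranges to GeoJSON (one MultiPolygon per animal)
#' @param homeranges list of \code{home_range}s.
#' @param path output path.
#' @export
write_homeranges <- function(homeranges, path) {
  feats <- lapply(homeranges, function(hr) {
    polys <- lapply(hr$hulls[vapply(hr$hulls, nrow, 1L) >= 3],
                    function(h) {
                      ring <- rbind(h, h[1, ])
                      list(lapply(seq_len(nrow(ring)), function(i) ring[i, ]))
                    })
    list(type = "Feature",
         properties = list(id = hr$id, n_locations = hr$n_locations,
                           a = hr$a, isopleth = hr$isopleth),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
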