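#' Construct a set of polylines (e.g. stream reaches)
#'
#' @param coords list of 2-column matrices (x, y metres), one per reach.
#' @param id unique reach identifiers.
#' @param name reach names (several reaches may share one stream name).
#' @param unit summary-unit (e.g. subwatershed) label per reach.
#' @return object of class \code{line_set}: list of features, each with
#'   \code{id}, \code{name}, \code{unit}, \code{xy}.
#' @export
line_set <- function(coords, id = NULL, name = NULL, unit = NULL) {
  n <- length(coords)
  if (!n) stop("empty line set")
  if (is.null(id)) id <- seq_len(n)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("reach ids must be unique")
  name <- if (is.null(name)) id else as.character(name)
  if (is.null(unit)) unit <- rep("unit1", n)
  unit <- as.character(unit)
  feats <- lapply(seq_len(n), function(i) {
    xy <- coords[[i]]
    stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 2,
              all(is.finite(xy)))
    list(id = id[i], name = name[i], unit = unit[i], xy = xy)
  })
  structure(feats, class = "line_set")
}

#' @export
print.line_set <- function(x, ...) {
  cat(sprintf("<line_set> %d reaches, total length %.2f km\n",
              length(x), sum(line_lengths(x)) / 1000))
  invisible(x)
}

#' Per-reach polyline lengths in metres
#' @param lines a \code{line_set}.
#' @return numeric vector.
#' @export
line_lengths <- function(lines) {
  vapply(lines, function(f) {
    d <- diff(f$xy)
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
}

#' Construct a set of polygons
#'
#' @param coords list of 2-column vertex matrices (rings need not be
#'   explicitly closed).
#' @param id unique polygon identifiers.
#' @return object of class \code{poly_set}.
#' @export
poly_set <- function(coords, id = NULL) {
  n <- length(coords)
  if (!n) stop("empty polygon set")
  if (is.null(id)) id <- seq_len(n)
  if (anyDuplicated(id)) stop("polygon ids must be unique")
  feats <- lapply(seq_len(n), function(i) {
    xy <- coords[[i]]
    stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3,
              all(is.finite(xy)))
    list(id = id[i], xy = xy)
  })
  structure(feats, class = "poly_set")
}

# ---- GeoJSON --------------------------------------------------------------

#' Write points, lines or polygons to GeoJSON
#' @param x a \code{point_set}, \code{line_set} or \code{poly_set}.
#' @param path output path.
#' @export
write_geojson <- function(x, path) {
  feat <- function(geom, props) list(type = "Feature", properties = props,
                                     geometry = geom)
  if (inherits(x, "point_set")) {
    feats <- lapply(seq_len(nrow(x)), function(i)
      feat(list(type = "Point", coordinates = c(x$x[i], x$y[i])),
           list(id = x$id[i])))
  } else if (inherits(x, "line_set")) {
    feats <- lapply(x, function(f)
      feat(list(type = "LineString",
                coordinates = lapply(seq_len(nrow(f$xy)),
                                     function(i) f$xy[i, ])),
           list(id = f$id, name = f$name, unit = f$unit)))
  } else if (inherits(x, "poly_set")) {
    feats <- lapply(x, function(f) {
      ring <- f$xy
      if (!all(ring[1, ] == ring[nrow(ring), ]))
        ring <- rbind(ring, ring[1, ])
      feat(list(type = "Polygon",
                coordinates = list(lapply(seq_len(nrow(ring)),
                                          function(i) ring[i, ]))),
           list(id = f$id))
    })
  } else stop("unsupported geometry object")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON file of LineString or Polygon features
#' @param path input path.
#' @return a \code{line_set} or \code{poly_set} depending on content.
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats) || !length(feats)) stop("no features in ", path)
  types <- vapply(feats, function(f) f$geometry$type, character(1))
  getmat <- function(cc) do.call(rbind, lapply(cc, function(p)
    as.numeric(unlist(p)[1:2])))
  prop <- function(f, k, d) {
    v <- f$properties[[k]]; if (is.null(v)) d else v
  }
  if (all(types == "LineString")) {
    line_set(lapply(feats, function(f) getmat(f$geometry$coordinates)),
             id = vapply(seq_along(feats), function(i)
               as.character(prop(feats[[i]], "id", i)), character(1)),
             name = vapply(seq_along(feats), function(i)
               as.character(prop(feats[[i]], "name", i)), character(1)),
             unit = vapply(seq_along(feats), function(i)
               as.character(prop(feats[[i]], "unit", "unit1")), character(1)))
  } else if (all(types == "Polygon")) {
    poly_set(lapply(feats, function(f) getmat(f$geometry$coordinates[[1]])),
             id = vapply(seq_along(feats), function(i)
               as.character(prop(feats[[i]], "id", i)), character(1)))
  } else stop("unsupported or mixed geometry types in ", path)
}

# ---- rasterization --------------------------------------------------------

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx * vx + vy * vy
  t <- if (l2 == 0) 0 else pmin(pmax(((px - ax) * vx + (py - ay) * vy) / l2, 0), 1)
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Rasterize lines or polygons onto a grid
#'
#' A cell is foreground when its center is covered by a polygon
#' (boundary inclusive) or lies within \code{cell_size / 2} of a line.
#'
#' @param features a \code{line_set} or \code{poly_set}.
#' @param grid target \code{grid_spec}.
#' @return binary (0/1) \code{grid_raster}.
#' @export
rasterize_features <- function(features, grid) {
  cc <- cell_centers(grid)
  fg <- matrix(FALSE, grid$n_rows, grid$n_cols)
  cs <- grid$cell_size
  if (inherits(features, "poly_set")) {
    xs <- rep(cc$x, each = grid$n_rows)
    ys <- rep(cc$y, times = grid$n_cols)
    for (f in features) {
      inside <- sp::point.in.polygon(xs, ys, f$xy[, 1], f$xy[, 2]) > 0
      fg <- fg | matrix(inside, grid$n_rows, grid$n_cols)
    }
  } else if (inherits(features, "line_set")) {
    half <- cs / 2
    for (f in features) {
      xy <- f$xy
      for (s in seq_len(nrow(xy) - 1L)) {
        a <- xy[s, ]; b <- xy[s + 1L, ]
        # candidate cells: bounding box of the segment expanded by half a cell
        cset <- which(cc$x >= min(a[1], b[1]) - half - 1e-9 &
                        cc$x <= max(a[1], b[1]) + half + 1e-9)
        rset <- which(cc$y >= min(a[2], b[2]) - half - 1e-9 &
                        cc$y <= max(a[2], b[2]) + half + 1e-9)
        if (!length(cset) || !length(rset)) next
        px <- rep(cc$x[cset], each = length(rset))
        py <- rep(cc$y[rset], times = length(cset))
        d <- dist_point_segment(px, py, a[1], a[2], b[1], b[2])
        hit <- matrix(d <= half + 1e-9, length(rset), length(cset))
        fg[rset, cset] <- fg[rset, cset] | hit
      }
    }
  } else stop("features must be a line_set or poly_set")
  if (!any(fg)) stop("rasterization produced no foreground cells")
  grid_raster(matrix(as.numeric(fg), grid$n_rows, grid$n_cols), grid)
}

#' Euclidean distance to the nearest foreground cell
#'
#' Each cell receives the planar distance in metres from its center to
#' the nearest foreground cell center; foreground cells get 0.  Vector
#' features are rasterized first (see \code{\link{rasterize_features}}).
#'
#' @param features binary \code{grid_raster} (non-zero = foreground) or a
#'   \code{line_set} / \code{poly_set}.
#' @param grid target \code{grid_spec} (required for vector input;
#'   ignored for raster input).
#' @return \code{grid_raster} of distances in metres.
#' @export
distance_transform <- function(features, grid = NULL) {
  if (!inherits(features, "grid_raster")) {
    if (is.null(grid)) stop("grid required for vector features")
    features <- rasterize_features(features, grid)
  }
  g <- features$grid
  fg <- !is.na(features$values) & features$values != 0
  if (!any(fg)) stop("empty foreground")
  # distmap(): per non-zero pixel, distance to nearest zero pixel
  d <- EBImage::distmap(matrix(as.numeric(!fg), g$n_rows, g$n_cols))
  grid_raster(as.matrix(d) * g$cell_size, g)
}
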