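#' Define the common analysis grid
#'
#' All rasters in an analysis share one regular grid in a projected
#' (planar, metre-unit) coordinate reference system.  Cells are addressed
#' by (row, col) with row 1 at the top (north); values sit at cell
#' centers; a point belongs to the cell whose half-open interval
#' \code{[x0, x0 + cell)} x \code{[y0, y0 + cell)} contains it.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size cell edge length in metres (> 0); default 90, the
#'   analysis resolution of the pipeline.
#' @param origin_x,origin_y coordinates of the lower-left corner, metres.
#' @param crs identifier of the projected CRS; informational only, but
#'   all inputs must share it.
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 90,
                      origin_x = 0, origin_y = 0, crs = "local-metres") {
  stopifnot(cell_size > 0, n_rows >= 1, n_cols >= 1)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = cell_size,
                 origin_x = origin_x, origin_y = origin_y, crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells @ %g m, origin (%g, %g), crs %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

same_grid <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "cell_size",
                                "origin_x", "origin_y")],
                   unclass(b)[c("n_rows", "n_cols", "cell_size",
                                "origin_x", "origin_y")]))
}

#' Construct a raster on a grid
#'
#' A \code{grid_raster} is a numeric matrix of per-cell values on a
#' \code{\link{grid_spec}}; \code{NA} marks nodata and is excluded from
#' all statistics.  Row 1 of the matrix is the northernmost row.
#'
#' @param values numeric matrix with \code{n_rows} x \code{n_cols}, or a
#'   single number to fill the grid.
#' @param grid a \code{grid_spec}.
#' @return an object of class \code{grid_raster}.
#' @export
grid_raster <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  if (length(values) == 1L)
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid), class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<grid_raster> %d x %d @ %g m; %d nodata cells",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("; range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
plot.grid_raster <- function(x, main = "", ...) {
  cc <- cell_centers(x$grid)
  z <- t(x$values[x$grid$n_rows:1, , drop = FALSE])  # [col, south-to-north row]
  graphics::image(cc$x, sort(cc$y), z, xlab = "x (m)", ylab = "y (m)",
                  main = main, useRaster = TRUE, asp = 1, ...)
  invisible(x)
}

#' Cell-center coordinates of a grid
#'
#' @param grid a \code{grid_spec}.
#' @return list with \code{x} (length \code{n_cols}, west to east) and
#'   \code{y} (length \code{n_rows}, north to south, matching row order).
#' @export
cell_centers <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size,
       y = grid$origin_y + (grid$n_rows - seq_len(grid$n_rows) + 0.5) *
         grid$cell_size)
}

#' Map point coordinates to grid cells
#'
#' @param x,y point coordinates in metres.
#' @param grid a \code{grid_spec}.
#' @return data.frame with \code{row}, \code{col} (NA when the point falls
#'   outside the grid) and logical \code{inside}.
#' @export
point_cells <- function(x, y, grid) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1L
  row <- grid$n_rows - floor((y - grid$origin_y) / grid$cell_size)
  inside <- !is.na(col) & !is.na(row) &
    col >= 1L & col <= grid$n_cols & row >= 1L & row <= grid$n_rows
  col[!inside] <- NA_integer_; row[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Read raster values at point locations
#'
#' @param raster a \code{grid_raster}.
#' @param x,y point coordinates in metres.
#' @return numeric vector; NA for off-grid points and nodata cells.
#' @export
raster_values_at <- function(raster, x, y) {
  pc <- point_cells(x, y, raster$grid)
  out <- rep(NA_real_, length(x))
  ok <- pc$inside
  out[ok] <- raster$values[cbind(pc$row[ok], pc$col[ok])]
  out
}

# ---- point sets -----------------------------------------------------------

#' Construct a set of projected points
#'
#' @param x,y coordinates in metres (finite).
#' @param id unique point identifiers (default sequential).
#' @param year,group optional per-point metadata.
#' @return data.frame of class \code{point_set}.
#' @export
point_set <- function(x, y, id = NULL, year = NULL, group = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  if (is.null(id)) id <- seq_along(x)
  if (anyDuplicated(id)) stop("point ids must be unique")
  df <- data.frame(x = as.numeric(x), y = as.numeric(y), id = id,
                   stringsAsFactors = FALSE)
  if (!is.null(year)) df$year <- year
  if (!is.null(group)) df$group <- group
  class(df) <- c("point_set", "data.frame")
  df
}

#' Read points from CSV or GeoJSON
#'
#' CSV files must have \code{x}, \code{y} columns in metres (optionally
#' \code{id}, \code{year}); GeoJSON files must contain Point features.
#' Points outside the grid bounding box are excluded with a message.
#'
#' @param path file path (.csv or .geojson/.json).
#' @param grid a \code{grid_spec} used to bound the points.
#' @return a \code{point_set}.
#' @export
load_points <- function(path, grid) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    feats <- gj$features
    if (is.null(feats) || !length(feats)) stop("no parseable coordinates in ", path)
    xy <- t(vapply(feats, function(f) unlist(f$geometry$coordinates)[1:2],
                   numeric(2)))
    ids <- vapply(seq_along(feats), function(i) {
      p <- feats[[i]]$properties
      if (!is.null(p$id)) as.character(p$id) else as.character(i)
    }, character(1))
    pts <- point_set(xy[, 1], xy[, 2], id = ids)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df) || !all(c("x", "y") %in% names(df)))
      stop("no parseable coordinates in ", path)
    pts <- point_set(df$x, df$y,
                     id = if ("id" %in% names(df)) df$id else NULL,
                     year = if ("year" %in% names(df)) df$year else NULL)
  }
  inb <- point_cells(pts$x, pts$y, grid)$inside
  if (any(!inb))
    message(sum(!inb), " point(s) outside grid bounds excluded")
  out <- pts[inb, , drop = FALSE]
  if (!nrow(out)) stop("no points fall inside the grid")
  class(out) <- c("point_set", "data.frame")
  out
}

#' Write points to CSV
#' @param points a \code{point_set}.
#' @param path output .csv path.
#' @export
write_points <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}

# ---- ESRI ASCII grid I/O --------------------------------------------------

#' Read a raster from an ESRI ASCII grid (.asc) file
#'
#' @param path input path.
#' @param crs CRS identifier to record on the grid.
#' @return a \code{grid_raster}.
#' @export
read_ascii_grid <- function(path, crs = "local-metres") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid_raster(m, grid_spec(hdr$nrows, hdr$ncols, hdr$cellsize,
                           hdr$xllcorner, hdr$yllcorner, crs))
}

#' Write a raster to an ESRI ASCII grid (.asc) file
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the raster bit-exactly.
#'
#' @param raster a \code{grid_raster}.
#' @param path output path.
#' @export
write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  v <- raster$values
  v[is.na(v)] <- -9999
  hdr <- c(sprintf("NCOLS %d", g$n_cols),
           sprintf("NROWS %d", g$n_rows),
           sprintf("XLLCORNER %.17g", g$origin_x),
           sprintf("YLLCORNER %.17g", g$origin_y),
           sprintf("CELLSIZE %.17g", g$cell_size),
           "NODATA_VALUE -9999")
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---- alignment / stacks ---------------------------------------------------

#' Resample a raster onto a target grid
#'
#' Bilinear interpolation (for continuous layers) or nearest-neighbour
#' sampling at the target cell centers.  A raster already on the target
#' grid is returned value-identical.
#'
#' @param raster source \code{grid_raster}.
#' @param grid target \code{grid_spec}.
#' @param method "bilinear" or "nearest".
#' @return a \code{grid_raster} on \code{grid}.
#' @export
align_raster <- function(raster, grid, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (same_grid(raster$grid, grid)) return(grid_raster(raster$values, grid))
  sg <- raster$grid
  tc <- cell_centers(grid)
  # overlap check on bounding boxes
  if (grid$origin_x >= sg$origin_x + sg$n_cols * sg$cell_size ||
      sg$origin_x >= grid$origin_x + grid$n_cols * grid$cell_size ||
      grid$origin_y >= sg$origin_y + sg$n_rows * sg$cell_size ||
      sg$origin_y >= grid$origin_y + grid$n_rows * grid$cell_size)
    stop("source raster does not overlap the target grid")
  xs <- rep(tc$x, each = grid$n_rows)
  ys <- rep(tc$y, times = grid$n_cols)
  if (method == "nearest") {
    vals <- raster_values_at(raster, xs, ys)
  } else {
    # fractional source index of each target center (1-based, at centers)
    fc <- (xs - sg$origin_x) / sg$cell_size + 0.5
    fr <- sg$n_rows - (ys - sg$origin_y) / sg$cell_size + 0.5
    c0 <- pmin(pmax(floor(fc), 1L), sg$n_cols); c1 <- pmin(c0 + 1L, sg$n_cols)
    r0 <- pmin(pmax(floor(fr), 1L), sg$n_rows); r1 <- pmin(r0 + 1L, sg$n_rows)
    wc <- pmin(pmax(fc - c0, 0), 1); wr <- pmin(pmax(fr - r0, 0), 1)
    V <- raster$values
    v00 <- V[cbind(r0, c0)]; v01 <- V[cbind(r0, c1)]
    v10 <- V[cbind(r1, c0)]; v11 <- V[cbind(r1, c1)]
    vals <- (1 - wr) * ((1 - wc) * v00 + wc * v01) +
      wr * ((1 - wc) * v10 + wc * v11)
    off <- fc < 0.5 | fc > sg$n_cols + 0.5 | fr < 0.5 | fr > sg$n_rows + 0.5
    vals[off] <- NA_real_
  }
  grid_raster(matrix(vals, grid$n_rows, grid$n_cols), grid)
}

#' Build a predictor stack from raster files
#'
#' Reads single-band ASCII-grid rasters and aligns each to the common
#' analysis grid (bilinear).  Nodata propagates.
#'
#' @param paths named character vector of .asc paths; names become layer
#'   names (defaults to file base names).
#' @param grid target \code{grid_spec}.
#' @return a \code{predictor_stack}: named list of \code{grid_raster}s
#'   sharing \code{grid}.
#' @export
load_stack <- function(paths, grid) {
  nm <- names(paths)
  if (is.null(nm)) nm <- sub("\\.asc$", "", basename(paths))
  if (anyDuplicated(nm)) stop("layer names must be unique")
  layers <- lapply(paths, function(p) align_raster(read_ascii_grid(p), grid))
  names(layers) <- nm
  predictor_stack(layers)
}

#' Assemble rasters into a predictor stack
#' @param layers named list of \code{grid_raster}s on one shared grid.
#' @return object of class \code{predictor_stack}.
#' @export
predictor_stack <- function(layers) {
  stopifnot(length(layers) >= 1, !is.null(names(layers)),
            !anyDuplicated(names(layers)))
  g <- layers[[1]]$grid
  ok <- vapply(layers, function(l) same_grid(l$grid, g), logical(1))
  if (!all(ok)) stop("all layers must share the same grid")
  structure(layers, grid = g, class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<predictor_stack> %d layers on %d x %d grid @ %g m\n",
              length(x), g$n_rows, g$n_cols, g$cell_size))
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.predictor_stack` <- function(x, i) {
  predictor_stack(unclass(x)[i])
}

stack_grid <- function(stack) attr(stack, "grid")
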