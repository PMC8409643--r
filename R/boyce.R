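#' Continuous Boyce curve of a suitability surface
#'
#' Slides overlapping windows of width \code{window_width} across
#' [0, 1]; per window, P is the fraction of evaluation presences whose
#' suitability falls in the window and E the fraction of non-nodata
#' cells there.  Windows with E = 0 are dropped.  The Boyce index is
#' the Spearman rank correlation of P/E with the window midpoint: a
#' surface that ranks presences correctly gives an index near 1.
#'
#' @param suitability \code{grid_raster} with values in [0, 1].
#' @param eval_presences a \code{point_set} (values are read off the
#'   raster) or a numeric vector of presence suitabilities.
#' @param window_width window width in suitability units (default 0.1).
#' @param n_windows number of windows (default 101).
#' @return list of class \code{boyce_curve}: \code{curve} (data.frame
#'   with mid, P, E, PE), \code{index}, \code{window_width}.
#' @export
boyce_curve <- function(suitability, eval_presences, window_width = 0.1,
                        n_windows = 101) {
  cells <- suitability$values[!is.na(suitability$values)]
  if (!length(cells) || diff(range(cells)) == 0)
    stop("suitability surface is constant; Boyce curve undefined")
  scores <- if (is.numeric(eval_presences)) eval_presences else
    raster_values_at(suitability, eval_presences$x, eval_presences$y)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 10)
    stop("at least 10 evaluation presences required")
  lo <- seq(0, 1 - window_width, length.out = n_windows)
  hi <- lo + window_width
  P <- E <- numeric(n_windows)
  for (i in seq_len(n_windows)) {
    P[i] <- mean(scores >= lo[i] & scores <= hi[i])
    E[i] <- mean(cells >= lo[i] & cells <= hi[i])
  }
  keep <- E > 0
  if (!any(keep)) stop("all windows empty")
  curve <- data.frame(mid = (lo + hi)[keep] / 2, P = P[keep], E = E[keep],
                      PE = P[keep] / E[keep])
  index <- stats::cor(curve$PE, curve$mid, method = "spearman")
  structure(list(curve = curve, index = index,
                 window_width = window_width), class = "boyce_curve")
}

#' @export
print.boyce_curve <- function(x, ...) {
  cat(sprintf("<boyce_curve> %d windows (width %g); Boyce index %.3f\n",
              nrow(x$curve), x$window_width, x$index))
  invisible(x)
}

#' @export
plot.boyce_curve <- function(x, ...) {
  graphics::plot(x$curve$mid, x$curve$PE, type = "b", pch = 16, cex = 0.6,
                 xlab = "suitability (window midpoint)",
                 ylab = "P/E ratio", ...)
  graphics::abline(h = c(1, 2), lty = 2, col = "grey50")
  invisible(x)
}

# Lowest midpoint from which the P/E curve stays at or above `level`
# (the last upcrossing, guarding against noisy curves).  NA when the
# curve never settles above the level.
pe_threshold <- function(curve, level) {
  below <- which(curve$PE < level)
  if (!length(below)) return(curve$mid[1])
  last_below <- max(below)
  if (last_below == nrow(curve)) return(NA_real_)
  curve$mid[last_below + 1]
}

#' Classify a suitability surface into low / moderate / high risk
#'
#' Default thresholds from the Boyce curve: the low/moderate cut is the
#' lowest suitability where P/E first reaches and stays at or above 1
#' (presences found at least as often as availability predicts), the
#' moderate/high cut where it stays at or above 2.  Cells are labelled
#' 0 = low on [0, t1), 1 = moderate on [t1, t2), 2 = high on [t2, 1].
#'
#' @param suitability \code{grid_raster} (logistic output).
#' @param curve a \code{boyce_curve} (may be NULL when \code{overrides}
#'   is given).
#' @param overrides optional list with \code{t_low_mod},
#'   \code{t_mod_high} overriding the curve-derived thresholds.
#' @param pe_levels P/E levels defining the two cuts (default 1 and 2).
#' @return object of class \code{risk_map}: \code{raster} (cell classes
#'   0/1/2), \code{thresholds}, \code{boyce_index}.
#' @export
classify_risk <- function(suitability, curve = NULL, overrides = NULL,
                          pe_levels = c(1, 2)) {
  if (!is.null(overrides)) {
    t1 <- overrides$t_low_mod; t2 <- overrides$t_mod_high
  } else {
    if (is.null(curve)) stop("either a Boyce curve or overrides required")
    t1 <- pe_threshold(curve$curve, pe_levels[1])
    t2 <- pe_threshold(curve$curve, pe_levels[2])
    if (is.na(t1)) {
      warning("P/E never settles above ", pe_levels[1],
              "; emitting an all-low map")
      t1 <- t2 <- Inf
    } else if (is.na(t2)) {
      warning("P/E never settles above ", pe_levels[2],
              "; no high class emitted")
      t2 <- Inf
    } else if (t1 == t2) {
      # P/E jumps past both levels in the same window: the moderate
      # band starts there and high begins at the next window
      nxt <- curve$curve$mid[curve$curve$mid > t1]
      t2 <- if (length(nxt)) min(nxt) else Inf
    } else if (t1 > t2) {
      stop("degenerate thresholds (t1 > t2); supply overrides")
    }
  }
  v <- suitability$values
  cls <- ifelse(v < t1, 0, ifelse(v < t2, 1, 2))
  structure(list(raster = grid_raster(cls, suitability$grid),
                 thresholds = c(t_low_mod = t1, t_mod_high = t2),
                 boyce_index = if (!is.null(curve)) curve$index else NA_real_),
            class = "risk_map")
}

#' @export
print.risk_map <- function(x, ...) {
  a <- class_areas(x)
  cat(sprintf("<risk_map> thresholds (%.3g, %.3g); Boyce index %.3f\n",
              x$thresholds[1], x$thresholds[2], x$boyce_index))
  print(a)
  invisible(x)
}

#' @export
plot.risk_map <- function(x, ...) {
  plot(x$raster, col = c("#e8f0e0", "#f7c873", "#c23b22"),
       main = "risk class (low / moderate / high)", ...)
  invisible(x)
}

#' Percentage shares of class areas
#' @param areas_km2 numeric vector of per-class areas (any unit).
#' @return percentages summing to 100.
#' @export
class_shares <- function(areas_km2) {
  stopifnot(all(areas_km2 >= 0), sum(areas_km2) > 0)
  100 * areas_km2 / sum(areas_km2)
}

#' Per-class areas and extent shares of a risk map
#'
#' Area = cell count x cell_size^2 / 1e6 (planar CRS); percentages are
#' over the non-nodata extent and sum to 100.
#'
#' @param riskmap a \code{risk_map}.
#' @return data.frame with \code{class}, \code{cells}, \code{area_km2},
#'   \code{percent}.
#' @export
class_areas <- function(riskmap) {
  v <- riskmap$raster$values
  if (all(is.na(v))) stop("empty risk map")
  cs <- riskmap$raster$grid$cell_size
  cnt <- vapply(0:2, function(k) sum(v == k, na.rm = TRUE), numeric(1))
  data.frame(class = c("low", "moderate", "high"), cells = cnt,
             area_km2 = cnt * cs^2 / 1e6,
             percent = class_shares(cnt),
             stringsAsFactors = FALSE)
}

#' Proportion of each summary unit in moderate-to-high risk
#'
#' @param riskmap a \code{risk_map}.
#' @param units a \code{poly_set} of summary-unit polygons (e.g.
#'   subwatersheds).
#' @return data.frame with \code{unit}, \code{n_cells},
#'   \code{prop_mod_high} (NA, flagged, for units with no overlapping
#'   cells).
#' @export
summarize_units <- function(riskmap, units) {
  g <- riskmap$raster$grid
  cc <- cell_centers(g)
  xs <- rep(cc$x, each = g$n_rows)
  ys <- rep(cc$y, times = g$n_cols)
  cls <- as.vector(riskmap$raster$values)
  out <- lapply(units, function(f) {
    inside <- sp::point.in.polygon(xs, ys, f$xy[, 1], f$xy[, 2]) > 0
    k <- cls[inside]
    k <- k[!is.na(k)]
    data.frame(unit = f$id, n_cells = length(k),
               prop_mod_high = if (length(k)) mean(k >= 1) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (any(res$n_cells == 0))
    warning("unit(s) with no overlapping cells: ",
            paste(res$unit[res$n_cells == 0], collapse = ", "))
  res
}

#' Write a risk map as ASCII grid plus JSON metadata
#' @param riskmap a \code{risk_map}.
#' @param path_prefix output prefix; writes \code{<prefix>.asc} and
#'   \code{<prefix>.json}.
#' @export
write_risk_map <- function(riskmap, path_prefix) {
  write_ascii_grid(riskmap$raster, paste0(path_prefix, ".asc"))
  jsonlite::write_json(list(thresholds = as.list(riskmap$thresholds),
                            boyce_index = riskmap$boyce_index,
                            classes = list(low = 0, moderate = 1, high = 2)),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path_prefix)
}
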