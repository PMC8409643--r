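#' Select stream reaches for ground-truth surveys
#'
#' Emulates the survey design: repeatedly draw a random reach, add
#' every reach sharing its name within the same summary unit, and
#' accumulate stream length until at least \code{target_fraction} of
#' the total network length is selected.
#'
#' @param network a \code{line_set} of stream reaches with names and
#'   unit labels.
#' @param target_fraction fraction of total stream km to select
#'   (default 0.01).
#' @param seed integer seed.
#' @return list of class \code{survey_plan}: \code{reach_ids},
#'   \code{selected_km}, \code{total_km}, \code{target_fraction}.
#' @export
select_survey_streams <- function(network, target_fraction = 0.01,
                                  seed = 1L) {
  if (!length(network)) stop("empty stream network")
  lens <- line_lengths(network) / 1000
  total <- sum(lens)
  ids <- vapply(network, `[[`, character(1), "id")
  nms <- vapply(network, function(f) as.character(f$name), character(1))
  uns <- vapply(network, function(f) as.character(f$unit), character(1))
  set.seed(seed)
  selected <- logical(length(network))
  if (target_fraction > 0) {
    while (sum(lens[selected]) < target_fraction * total &&
           !all(selected)) {
      pool <- which(!selected)
      pick <- pool[sample.int(length(pool), 1)]
      grp <- nms == nms[pick] & uns == uns[pick]
      selected <- selected | grp
    }
  }
  structure(list(reach_ids = ids[selected],
                 reach_km = lens[selected],
                 selected_km = sum(lens[selected]), total_km = total,
                 target_fraction = target_fraction),
            class = "survey_plan")
}

#' @export
print.survey_plan <- function(x, ...) {
  cat(sprintf("<survey_plan> %d reaches, %.2f of %.2f km (target %.1f%%)\n",
              length(x$reach_ids), x$selected_km, x$total_km,
              100 * x$target_fraction))
  invisible(x)
}

# Exact apportionment of one segment's length across the risk classes
# of the cells it traverses.  Returns named length (m) per class label
# "0","1","2" plus "nodata".
segment_class_lengths <- function(a, b, riskmap) {
  g <- riskmap$raster$grid
  cs <- g$cell_size
  len <- sqrt(sum((b - a)^2))
  if (len == 0) return(c("0" = 0, "1" = 0, "2" = 0, nodata = 0))
  # crossing parameters with vertical and horizontal grid lines
  tx <- ty <- numeric(0)
  kr <- function(lo, hi, o) {
    from <- ceiling((lo - o) / cs); to <- floor((hi - o) / cs)
    if (from > to) numeric(0) else seq(from, to)
  }
  if (b[1] != a[1]) {
    ks <- kr(min(a[1], b[1]), max(a[1], b[1]), g$origin_x)
    tx <- ((g$origin_x + ks * cs) - a[1]) / (b[1] - a[1])
  }
  if (b[2] != a[2]) {
    ks <- kr(min(a[2], b[2]), max(a[2], b[2]), g$origin_y)
    ty <- ((g$origin_y + ks * cs) - a[2]) / (b[2] - a[2])
  }
  ts <- sort(unique(c(0, 1, tx[tx > 0 & tx < 1], ty[ty > 0 & ty < 1])))
  out <- c("0" = 0, "1" = 0, "2" = 0, nodata = 0)
  for (i in seq_len(length(ts) - 1L)) {
    tm <- (ts[i] + ts[i + 1]) / 2
    p <- a + tm * (b - a)
    k <- raster_values_at(riskmap$raster, p[1], p[2])
    lab <- if (is.na(k)) "nodata" else as.character(k)
    out[lab] <- out[lab] + (ts[i + 1] - ts[i]) * len
  }
  out
}

#' Tabulate a survey outcome on the risk map
#'
#' Apportions each surveyed reach's length across the risk classes of
#' the cells it traverses (exact line/cell intersection lengths) and
#' labels each discovered plot with the class of its cell.
#'
#' @param plots a \code{point_set} of discovered cultivation plots.
#' @param reaches a \code{line_set} of the surveyed reaches.
#' @param riskmap a \code{risk_map}.
#' @return list of class \code{survey_outcome}: \code{km_by_class}
#'   (low/moderate/high, km), \code{plot_classes}, \code{observed}
#'   (counts per class).
#' @export
classify_survey <- function(plots, reaches, riskmap) {
  km <- c("0" = 0, "1" = 0, "2" = 0, nodata = 0)
  for (f in reaches) {
    xy <- f$xy
    for (s in seq_len(nrow(xy) - 1L))
      km <- km + segment_class_lengths(xy[s, ], xy[s + 1L, ], riskmap)
  }
  cls <- raster_values_at(riskmap$raster, plots$x, plots$y)
  if (any(is.na(cls))) stop("plot off the risk-map grid or on nodata")
  labels <- c("low", "moderate", "high")
  observed <- vapply(0:2, function(k) sum(cls == k), numeric(1))
  names(observed) <- labels
  structure(list(km_by_class = stats::setNames(km[1:3] / 1000, labels),
                 plot_classes = stats::setNames(labels[cls + 1], plots$id),
                 observed = observed),
            class = "survey_outcome")
}

#' Observed-vs-expected chi-square for a survey outcome
#'
#' Expected plot counts per class equal the class's share of surveyed
#' stream kilometres times the total plots discovered; classes with no
#' surveyed length are excluded from the test (and must have zero
#' observations).
#'
#' @param outcome a \code{survey_outcome}, or a list with
#'   \code{observed} and \code{km_by_class}.
#' @return list of class \code{chisq_result}: \code{observed},
#'   \code{expected}, \code{statistic}, \code{df}, \code{p_value}.
#' @export
chisq_survey <- function(outcome) {
  obs <- outcome$observed
  km <- outcome$km_by_class
  N <- sum(obs)
  if (N < 1) stop("zero plots discovered")
  if (any(obs > 0 & km <= 0))
    stop("class with observed plots but zero surveyed km")
  use <- km > 0
  expected <- km[use] / sum(km[use]) * N
  statistic <- sum((obs[use] - expected)^2 / expected)
  df <- sum(use) - 1L
  structure(list(observed = obs[use], expected = expected,
                 statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE)),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> X-squared = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  tab <- rbind(observed = x$observed, expected = round(x$expected, 2))
  print(tab)
  invisible(x)
}

#' Percentage of points per risk class
#'
#' Off-grid or nodata points are excluded with a message; rounded
#' integer percentages (reporting style) sit beside the raw fractions.
#'
#' @param points a \code{point_set}.
#' @param riskmap a \code{risk_map}.
#' @return data.frame with \code{class}, \code{count}, \code{percent},
#'   \code{percent_rounded}.
#' @export
class_percentages <- function(points, riskmap) {
  cls <- raster_values_at(riskmap$raster, points$x, points$y)
  if (all(is.na(cls))) stop("no points on the risk-map grid")
  if (any(is.na(cls)))
    message(sum(is.na(cls)), " point(s) off-grid or on nodata excluded")
  cls <- cls[!is.na(cls)]
  cnt <- vapply(0:2, function(k) sum(cls == k), numeric(1))
  data.frame(class = c("low", "moderate", "high"), count = cnt,
             percent = 100 * cnt / sum(cnt),
             percent_rounded = round(100 * cnt / sum(cnt)),
             stringsAsFactors = FALSE)
}

#' Distance from points to the nearest cell of a target risk class
#'
#' Planar distance to the nearest target-class cell center; points
#' inside a target cell get 0.
#'
#' @param points a \code{point_set}.
#' @param riskmap a \code{risk_map}.
#' @param target_class "high", "moderate" or "low" (or 0/1/2).
#' @return list with \code{distances} (m, per point), \code{mean},
#'   \code{min}, \code{max}.
#' @export
distance_to_class <- function(points, riskmap, target_class = "high") {
  if (is.character(target_class))
    target_class <- match(target_class, c("low", "moderate", "high")) - 1L
  g <- riskmap$raster$grid
  idx <- which(riskmap$raster$values == target_class)
  if (!length(idx)) stop("no cells of the target class")
  rc <- arrayInd(idx, dim(riskmap$raster$values))
  cc <- cell_centers(g)
  tx <- cc$x[rc[, 2]]; ty <- cc$y[rc[, 1]]
  inside <- raster_values_at(riskmap$raster, points$x, points$y) ==
    target_class
  d <- vapply(seq_len(nrow(points)), function(i) {
    if (isTRUE(inside[i])) return(0)
    sqrt(min((tx - points$x[i])^2 + (ty - points$y[i])^2))
  }, numeric(1))
  list(distances = d, mean = mean(d), min = min(d), max = max(d))
}
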