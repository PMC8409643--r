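#' Spatially thin occurrence points
#'
#' Enforces a minimum nearest-neighbour distance (default 2000 m,
#' boundary inclusive: a pair exactly at the threshold is kept) by
#' iteratively removing the most crowded point -- the one with the most
#' neighbours closer than the threshold -- with ties broken by a seeded
#' random draw.  The result is maximal: no removed point can be
#' re-added without violating the constraint.
#'
#' @param points a \code{point_set}.
#' @param thin_distance minimum pairwise distance (m).
#' @param seed integer seed for tie-breaking.
#' @return list of class \code{thin_result}: \code{kept},
#'   \code{removed} (both \code{point_set}s) and
#'   \code{min_pairwise_distance}.
#' @export
thin_occurrences <- function(points, thin_distance = 2000, seed = 1L) {
  n <- nrow(points)
  if (n < 1) stop("at least one point required")
  set.seed(seed)
  keep <- rep(TRUE, n)
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(points$x, points$y)))
    diag(d) <- Inf
    close <- d < thin_distance   # strictly closer = violation
    repeat {
      counts <- rowSums(close[keep, keep, drop = FALSE])
      if (!any(counts > 0)) break
      worst <- which(counts == max(counts))
      drop_local <- if (length(worst) > 1) sample(worst, 1) else worst
      keep[which(keep)[drop_local]] <- FALSE
    }
    # re-add removed points freed up by later removals (maximality)
    out_idx <- which(!keep)
    if (length(out_idx) > 1) out_idx <- sample(out_idx)
    for (i in out_idx)
      if (!any(close[i, keep])) keep[i] <- TRUE
    # exchange pass: swapping one kept point for two conflicting
    # removed ones grows the kept set; repeat until no swap helps
    repeat {
      improved <- FALSE
      kept_idx <- which(keep)
      if (length(kept_idx) > 1) kept_idx <- sample(kept_idx)
      for (k in kept_idx) {
        keep_k <- keep; keep_k[k] <- FALSE
        cand <- setdiff(which(!keep), k)
        if (length(cand) > 1) cand <- sample(cand)
        added <- integer(0)
        for (i in cand) {
          against <- c(which(keep_k), added)
          if (!any(close[i, against])) added <- c(added, i)
        }
        if (length(added) >= 2) {
          keep <- keep_k; keep[added] <- TRUE
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
  }
  kept <- points[keep, , drop = FALSE]
  removed <- points[!keep, , drop = FALSE]
  class(kept) <- class(removed) <- c("point_set", "data.frame")
  mind <- if (nrow(kept) > 1)
    min(stats::dist(cbind(kept$x, kept$y))) else Inf
  structure(list(kept = kept, removed = removed,
                 min_pairwise_distance = mind,
                 thin_distance = thin_distance),
            class = "thin_result")
}

#' @export
print.thin_result <- function(x, ...) {
  cat(sprintf("<thin_result> kept %d of %d points (min distance %.1f m >= %g m)\n",
              nrow(x$kept), nrow(x$kept) + nrow(x$removed),
              x$min_pairwise_distance, x$thin_distance))
  invisible(x)
}

#' Sample random background (availability) points
#'
#' Points are uniform over eligible (non-nodata, non-zero) cells of the
#' extent mask, cells drawn with replacement and jittered uniformly
#' within the cell.
#'
#' @param mask binary \code{grid_raster}; non-zero cells are eligible.
#' @param n number of points (default 10,000).
#' @param seed integer seed.
#' @return a \code{point_set}.
#' @export
sample_background <- function(mask, n = 10000, seed = 1L) {
  g <- mask$grid
  eligible <- which(!is.na(mask$values) & mask$values != 0)
  if (!length(eligible)) stop("empty background mask")
  set.seed(seed)
  cells <- eligible[sample.int(length(eligible), n, replace = TRUE)]
  rc <- arrayInd(cells, dim(mask$values))
  cs <- g$cell_size
  x <- g$origin_x + (rc[, 2] - 1) * cs + stats::runif(n) * cs
  y <- g$origin_y + (g$n_rows - rc[, 1]) * cs + stats::runif(n) * cs
  point_set(x, y, id = paste0("bg", seq_len(n)))
}

#' Focal (moving-window) statistic of a raster
#'
#' The window at each cell contains every cell whose center lies within
#' \code{radius} of the focal center.  Nodata cells are excluded from
#' the window; windows are truncated at edges (no padding); the output
#' is nodata only where the window is empty.
#'
#' @param raster a \code{grid_raster}.
#' @param radius window radius in metres (default 450).
#' @param stat "mean" or "std" (population standard deviation).
#' @return a \code{grid_raster}.
#' @export
focal_stat <- function(raster, radius = 450, stat = c("mean", "std")) {
  stat <- match.arg(stat)
  g <- raster$grid
  if (radius < g$cell_size / 2) stop("radius must be at least half a cell")
  if (all(is.na(raster$values))) stop("all-nodata input")
  rc <- floor(radius / g$cell_size)
  offs <- expand.grid(di = -rc:rc, dj = -rc:rc)
  offs <- offs[(offs$di^2 + offs$dj^2) * g$cell_size^2 <= radius^2 + 1e-9, ]
  v <- raster$values
  ok <- !is.na(v)
  v0 <- ifelse(ok, v, 0)
  nr <- g$n_rows; nc <- g$n_cols
  s <- s2 <- cnt <- matrix(0, nr, nc)
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    r_dst <- max(1, 1 - di):min(nr, nr - di)
    c_dst <- max(1, 1 - dj):min(nc, nc - dj)
    r_src <- r_dst + di; c_src <- c_dst + dj
    s[r_dst, c_dst] <- s[r_dst, c_dst] + v0[r_src, c_src]
    if (stat == "std")
      s2[r_dst, c_dst] <- s2[r_dst, c_dst] + v0[r_src, c_src]^2
    cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + ok[r_src, c_src]
  }
  out <- if (stat == "mean") s / cnt else {
    m <- s / cnt
    sqrt(pmax(s2 / cnt - m^2, 0))
  }
  out[cnt == 0] <- NA_real_
  grid_raster(out, g)
}

#' Apply a focal mean to every layer of a stack
#' @param stack a \code{predictor_stack}.
#' @param radius window radius (m).
#' @return a smoothed \code{predictor_stack}.
#' @export
focal_smooth_stack <- function(stack, radius = 450) {
  out <- lapply(stack, focal_stat, radius = radius, stat = "mean")
  names(out) <- names(stack)
  predictor_stack(out)
}

#' Extract predictor values at points
#'
#' One row per point; rows hitting nodata in any layer (or falling off
#' the grid) are dropped with a message.
#'
#' @param stack a \code{predictor_stack}.
#' @param points a \code{point_set}.
#' @return data.frame with \code{id}, \code{x}, \code{y} and one column
#'   per layer.
#' @export
extract_values <- function(stack, points) {
  vals <- lapply(stack, raster_values_at, x = points$x, y = points$y)
  df <- data.frame(id = points$id, x = points$x, y = points$y,
                   stringsAsFactors = FALSE)
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  bad <- !stats::complete.cases(df[names(stack)])
  if (any(bad)) message(sum(bad), " point(s) dropped (nodata or off-grid)")
  out <- df[!bad, , drop = FALSE]
  if (!nrow(out)) stop("no points survive extraction")
  out
}

#' Assemble the presence/background sample table
#'
#' @param stack a \code{predictor_stack}.
#' @param presences,background \code{point_set}s.
#' @return data.frame of class \code{sample_table} with a 0/1
#'   \code{presence} column followed by predictor columns; the predictor
#'   names are recorded in attribute \code{"variables"}.
#' @export
build_samples <- function(stack, presences, background) {
  p <- extract_values(stack, presences)
  b <- extract_values(stack, background)
  p$presence <- 1L; b$presence <- 0L
  out <- rbind(p, b)
  attr(out, "variables") <- names(stack)
  class(out) <- c("sample_table", "data.frame")
  out
}

sample_variables <- function(samples) {
  v <- attr(samples, "variables")
  if (is.null(v))
    v <- setdiff(names(samples), c("id", "x", "y", "presence", "fold",
                                   "group", "year"))
  v
}

#' Assign cross-validation folds to presences
#'
#' Random partition into \code{k} folds with sizes differing by at most
#' one; each fold serves once as the held-out test split.
#'
#' @param n number of presences, or a \code{sample_table} (its presence
#'   rows are counted).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold labels in \code{1..k}.
#' @export
make_cv_folds <- function(n, k = 10, seed = 1L) {
  if (is.data.frame(n)) n <- sum(n$presence == 1)
  if (n < k) stop("fewer presences (", n, ") than folds (", k, ")")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}
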