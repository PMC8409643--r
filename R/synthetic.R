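#' Configuration for a synthetic landscape
#'
#' The default preset is a desk-scale analogue of the study system: a
#' 200 x 200 grid at 90 m (18 x 18 km), band-shaped true selection for
#' mid elevations and moderate slopes, biased presence sampling that
#' mimics law-enforcement search concentrated near previously found
#' sites, streams carrying planted cultivation plots, a binary habitat
#' layer, and clustered telemetry.
#'
#' @param grid analysis \code{grid_spec}; default 200 x 200 at 90 m.
#' @param seed integer seed; the same seed reproduces every output
#'   bit-identically.
#' @param corr_length spatial correlation length (m) of the smooth
#'   random fields; must be at least one cell.
#' @param n_presences presence points to sample (default 500).
#' @param n_streams,n_roads numbers of stream / road polylines.
#' @param n_plots cultivation plots planted along streams.
#' @param n_animals,locs_per_animal,telemetry_dispersion telemetry
#'   geometry: animals, locations each, and isotropic spread (m).
#' @param bias_strength strength (>= 0) of the detection-bias field
#'   mixed multiplicatively into presence sampling; 0 disables bias.
#' @return list of class \code{landscape_config}.
#' @export
landscape_config <- function(grid = grid_spec(200, 200, 90),
                             seed = 1L, corr_length = 1200,
                             n_presences = 500, n_streams = 12,
                             n_roads = 6, n_plots = 40,
                             n_animals = 12, locs_per_animal = 40,
                             telemetry_dispersion = 1000,
                             bias_strength = 8) {
  stopifnot(inherits(grid, "grid_spec"),
            corr_length >= grid$cell_size,
            n_presences >= 1, n_streams >= 0, n_roads >= 1,
            n_plots >= 0, n_animals >= 1, locs_per_animal >= 1,
            telemetry_dispersion > 0, bias_strength >= 0)
  structure(list(grid = grid, seed = as.integer(seed),
                 corr_length = corr_length, n_presences = n_presences,
                 n_streams = n_streams, n_roads = n_roads,
                 n_plots = n_plots, n_animals = n_animals,
                 locs_per_animal = locs_per_animal,
                 telemetry_dispersion = telemetry_dispersion,
                 bias_strength = bias_strength),
            class = "landscape_config")
}

# Smooth unit-variance Gaussian random field by FFT convolution of white
# noise with a Gaussian kernel (periodic boundaries).  Uses the current
# RNG state.
gaussian_field <- function(grid, corr_length) {
  nr <- grid$n_rows; nc <- grid$n_cols
  sd_cells <- corr_length / grid$cell_size
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-0.5 * (outer(di^2, dj^2, "+")) / sd_cells^2)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

# Gaussian smoothing of an arbitrary matrix (same kernel, normalized to
# preserve the mean); used for the detection-bias density.
smooth_matrix <- function(m, grid, corr_length) {
  nr <- grid$n_rows; nc <- grid$n_cols
  sd_cells <- corr_length / grid$cell_size
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-0.5 * (outer(di^2, dj^2, "+")) / sd_cells^2)
  k <- k / sum(k)
  Re(stats::fft(stats::fft(m) * stats::fft(k), inverse = TRUE)) / (nr * nc)
}

# Random monotone (west-to-east) lattice path along cell centers.
monotone_path <- function(grid) {
  cc <- cell_centers(grid)
  r <- sample.int(grid$n_rows, 1)
  rows <- integer(grid$n_cols)
  rows[1] <- r
  for (j in 2:grid$n_cols) {
    r <- r + sample(c(-1L, 0L, 1L), 1)
    r <- min(max(r, 1L), grid$n_rows)
    rows[j] <- r
  }
  cbind(x = cc$x, y = cc$y[rows])
}

gen_paths <- function(grid, n, prefix, n_names = NULL) {
  if (n == 0) stop("zero paths requested")
  coords <- lapply(seq_len(n), function(i) monotone_path(grid))
  # several reaches may share a stream name; unit = y-quartile of start
  if (is.null(n_names)) n_names <- max(1L, ceiling(n * 0.7))
  nms <- paste0(prefix, "_", sample.int(n_names, n, replace = TRUE))
  y0 <- vapply(coords, function(m) m[1, 2], numeric(1))
  yq <- cut(y0, breaks = stats::quantile(c(grid$origin_y,
            grid$origin_y + grid$n_rows * grid$cell_size), 0:4 / 4),
            include.lowest = TRUE, labels = paste0("huc", 1:4))
  line_set(coords, id = paste0(prefix, seq_len(n)), name = nms,
           unit = as.character(yq))
}

#' Generate a synthetic predictor stack
#'
#' Layers emulate the candidate-variable roles of the real analysis:
#' smooth correlated random fields for elevation, canopy cover, stand
#' age, transformed aspect and precipitation (the latter deliberately
#' collinear with elevation so that correlation grouping has work to
#' do), percent slope derived from elevation by central finite
#' differences, and distance-to-feature layers (roads, water, private
#' land, recent disturbance) computed by exact Euclidean distance
#' transform of generated masks and polylines.
#'
#' @param config a \code{landscape_config}.
#' @return a \code{predictor_stack}; the generated stream network is
#'   attached as attribute \code{"streams"}.
#' @export
gen_predictors <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  g <- config$grid
  set.seed(config$seed)
  cl <- config$corr_length

  z_elev <- gaussian_field(g, cl * 1.5)
  elevation <- pmax(1200 + 500 * z_elev, 0)

  # percent slope from elevation (central differences, one-sided edges)
  nr <- g$n_rows; nc <- g$n_cols; cs <- g$cell_size
  denx <- matrix(2 * cs, nr, nc); denx[, c(1, nc)] <- cs
  deny <- matrix(2 * cs, nr, nc); deny[c(1, nr), ] <- cs
  gx <- (elevation[, c(2:nc, nc)] - elevation[, c(1, 1:(nc - 1))]) / denx
  gy <- (elevation[c(1, 1:(nr - 1)), ] - elevation[c(2:nr, nr), ]) / deny
  slope <- 100 * sqrt(gx^2 + gy^2)

  canopy <- pmin(pmax(50 + 25 * gaussian_field(g, cl), 0), 100)
  stand_age <- pmin(pmax(100 + 50 * gaussian_field(g, cl), 5), 300)
  aspect_tr <- pmin(pmax(gaussian_field(g, cl * 0.5), -2), 2) / 2
  precip <- pmin(pmax(185 + 57.5 * (0.8 * z_elev +
                                      0.6 * gaussian_field(g, cl)), 70), 300)

  streams <- gen_paths(g, max(config$n_streams, 1L), "stream")
  roads <- gen_paths(g, config$n_roads, "road")
  zp <- gaussian_field(g, cl)
  private <- zp > stats::quantile(zp, 0.85)
  zd <- gaussian_field(g, cl * 0.7)
  disturbed <- zd > stats::quantile(zd, 0.90)

  dist_water <- distance_transform(streams, g)
  dist_road <- distance_transform(roads, g)
  dist_private <- distance_transform(grid_raster(private * 1, g))
  dist_disturbance <- distance_transform(grid_raster(disturbed * 1, g))

  stack <- predictor_stack(list(
    elevation = grid_raster(elevation, g),
    slope = grid_raster(slope, g),
    canopy_cover = grid_raster(canopy, g),
    stand_age = grid_raster(stand_age, g),
    aspect_transformed = grid_raster(aspect_tr, g),
    precipitation = grid_raster(precip, g),
    dist_water = dist_water,
    dist_road = dist_road,
    dist_private = dist_private,
    dist_disturbance = dist_disturbance))
  attr(stack, "streams") <- streams
  attr(stack, "roads") <- roads
  stack
}

#' Define a true selection model for synthetic landscapes
#'
#' Each term maps one predictor through a response shape -- a band
#' (Gaussian bump equal to 0.5 at \code{center +/- halfwidth}), a
#' proximity decay \code{exp(-x / scale)}, or a scaled linear ramp --
#' and contributes \code{weight} times that response to a logit.
#'
#' @param terms list of term lists: \code{list(var=, type=
#'   c("band","prox","linear"), weight=, center=, halfwidth=, scale=,
#'   x0=)} with the parameters their type needs.
#' @param intercept logit intercept.
#' @param bias_strength default detection-bias strength carried with
#'   the model.
#' @return list of class \code{true_model}.
#' @export
true_model <- function(terms, intercept = 0, bias_strength = 1) {
  for (tm in terms)
    stopifnot(!is.null(tm$var), tm$type %in% c("band", "prox", "linear"),
              is.numeric(tm$weight))
  structure(list(terms = terms, intercept = intercept,
                 bias_strength = bias_strength), class = "true_model")
}

#' The default band-shaped true model
#'
#' Mid-elevation band (800--1600 m, i.e. center 1200 m, halfwidth
#' 400 m), moderate-slope band (30--60\%), proximity to water, and a
#' mild canopy preference.  Band weights and intercept are strong, so
#' suitability is high only where both bands coincide and near zero
#' elsewhere -- most of the landscape is low-likelihood, as in real
#' cultivation-risk geographies -- and discovery bias is on by
#' default, emulating search effort clustered near known sites.
#' @return a \code{true_model}.
#' @export
default_true_model <- function() {
  true_model(list(
    list(var = "elevation", type = "band", center = 1200, halfwidth = 400,
         weight = 20),
    list(var = "slope", type = "band", center = 45, halfwidth = 15,
         weight = 18),
    list(var = "dist_water", type = "prox", scale = 300, weight = 2),
    list(var = "canopy_cover", type = "linear", x0 = 50, scale = 50,
         weight = 1)),
    intercept = -30, bias_strength = 8)
}

term_response <- function(x, tm) {
  switch(tm$type,
         band = exp(-0.5 * ((x - tm$center) /
                              (tm$halfwidth / sqrt(2 * log(2))))^2),
         prox = exp(-x / tm$scale),
         linear = (x - tm$x0) / tm$scale)
}

#' Evaluate true suitability over a predictor stack
#'
#' Cellwise inverse-logit of the weighted sum of the model's response
#' terms; values in [0, 1].
#'
#' @param stack a \code{predictor_stack}.
#' @param model a \code{true_model}.
#' @return \code{grid_raster} of suitabilities.
#' @export
define_true_suitability <- function(stack, model) {
  g <- stack_grid(stack)
  lin <- matrix(model$intercept, g$n_rows, g$n_cols)
  for (tm in model$terms) {
    if (is.null(stack[[tm$var]]))
      stop("true model variable not in stack: ", tm$var)
    lin <- lin + tm$weight * term_response(stack[[tm$var]]$values, tm)
  }
  grid_raster(stats::plogis(lin), g)
}

#' Sample presence points proportional to suitability
#'
#' Cells are drawn without replacement with probability proportional to
#' suitability times the optional bias raster; each point is jittered
#' uniformly within its cell.
#'
#' @param suitability \code{grid_raster} in [0, 1].
#' @param n number of presences.
#' @param bias optional \code{grid_raster} of multiplicative sampling
#'   weights (e.g. detection bias).
#' @param seed integer seed.
#' @return a \code{point_set}.
#' @export
sample_presences <- function(suitability, n, bias = NULL, seed = 1L) {
  g <- suitability$grid
  w <- suitability$values
  if (!is.null(bias)) {
    stopifnot(same_grid(bias$grid, g))
    w <- w * bias$values
  }
  w[is.na(w)] <- 0
  eligible <- which(w > 0)
  if (length(eligible) < n)
    stop("n exceeds the number of cells with positive sampling weight")
  set.seed(seed)
  cells <- sample(eligible, n, replace = FALSE, prob = w[eligible])
  rc <- arrayInd(cells, dim(w))
  cs <- g$cell_size
  x <- g$origin_x + (rc[, 2] - 1) * cs + stats::runif(n) * cs
  y <- g$origin_y + (g$n_rows - rc[, 1]) * cs + stats::runif(n) * cs
  point_set(x, y, id = paste0("p", seq_len(n)))
}

#' Detection-bias field from previously found sites
#'
#' Emulates search effort concentrated at and near previously found
#' cultivation sites: a seed set of discoveries is drawn proportional
#' to suitability, smoothed into a density, normalized to mean one, and
#' mixed as \code{1 + strength * density}.
#'
#' @param suitability \code{grid_raster}.
#' @param strength bias strength (>= 0); 0 gives a flat field of ones.
#' @param seed integer seed.
#' @param n_seeds number of seed discoveries.
#' @param smooth_length smoothing correlation length (m).
#' @return \code{grid_raster} of sampling-weight multipliers.
#' @export
gen_detection_bias <- function(suitability, strength = 1, seed = 1L,
                               n_seeds = 50, smooth_length = 1500) {
  g <- suitability$grid
  if (strength == 0) return(grid_raster(1, g))
  pts <- sample_presences(suitability, n_seeds, seed = seed)
  cnt <- matrix(0, g$n_rows, g$n_cols)
  pc <- point_cells(pts$x, pts$y, g)
  for (i in seq_len(nrow(pc)))
    cnt[pc$row[i], pc$col[i]] <- cnt[pc$row[i], pc$col[i]] + 1
  dens <- smooth_matrix(cnt, g, smooth_length)
  dens <- pmax(dens, 0)
  dens <- dens / mean(dens)
  grid_raster(1 + strength * dens, g)
}

#' Plant cultivation plots along a stream network
#'
#' Plots are placed by rejection sampling: a random position along a
#' random reach (chosen proportional to length), offset by at most
#' 300 m, accepted with probability proportional to the suitability of
#' the receiving cell.  Each plot is labelled with the suitability
#' tercile of its cell ("low", "mid", "high").
#'
#' @param config a \code{landscape_config}.
#' @param suitability \code{grid_raster}.
#' @param seed integer seed.
#' @param streams optional existing \code{line_set}; generated when NULL.
#' @return list with \code{streams} (a \code{line_set}) and \code{plots}
#'   (a \code{point_set} with tercile labels in \code{group}).
#' @export
gen_streams_and_plots <- function(config, suitability, seed = 1L,
                                  streams = NULL) {
  if (config$n_streams == 0 && is.null(streams))
    stop("zero streams requested")
  g <- suitability$grid
  set.seed(seed)
  if (is.null(streams)) streams <- gen_paths(g, config$n_streams, "stream")
  n <- config$n_plots
  if (n == 0)
    return(list(streams = streams,
                plots = point_set(numeric(0), numeric(0), id = character(0))))
  lens <- line_lengths(streams)
  smax <- max(suitability$values, na.rm = TRUE)
  terc <- stats::quantile(suitability$values, c(1 / 3, 2 / 3), na.rm = TRUE)
  xs <- ys <- numeric(n); lab <- character(n)
  got <- 0L; tries <- 0L
  while (got < n && tries < 100000L) {
    tries <- tries + 1L
    f <- streams[[sample.int(length(streams), 1, prob = lens)]]
    seg <- sample.int(nrow(f$xy) - 1L, 1)
    t <- stats::runif(1)
    base <- f$xy[seg, ] + t * (f$xy[seg + 1L, ] - f$xy[seg, ])
    ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 300)
    p <- base + rad * c(cos(ang), sin(ang))
    s <- raster_values_at(suitability, p[1], p[2])
    if (is.na(s) || stats::runif(1) > s / smax) next
    got <- got + 1L
    xs[got] <- p[1]; ys[got] <- p[2]
    lab[got] <- if (s <= terc[1]) "low" else if (s <= terc[2]) "mid" else "high"
  }
  if (got < n) stop("could not place requested plots near streams")
  list(streams = streams,
       plots = point_set(xs, ys, id = paste0("plot", seq_len(n)),
                         group = lab))
}

#' Derive a binary habitat layer from the stack
#'
#' @param stack a \code{predictor_stack}.
#' @param rule function taking a data.frame of per-cell layer values and
#'   returning a logical vector (TRUE = suitable).
#' @return binary \code{grid_raster} (1 = suitable habitat).
#' @export
gen_habitat <- function(stack, rule) {
  g <- stack_grid(stack)
  df <- as.data.frame(lapply(stack, function(l) as.vector(l$values)))
  suit <- rule(df)
  stopifnot(is.logical(suit), length(suit) == g$n_rows * g$n_cols)
  suit[is.na(suit)] <- FALSE
  if (!any(suit)) stop("habitat rule selects zero cells")
  message(sprintf("habitat: %.1f%% of cells suitable",
                  100 * mean(suit)))
  grid_raster(matrix(as.numeric(suit), g$n_rows, g$n_cols), g)
}

#' Generate clustered telemetry for several animals
#'
#' Each animal gets a uniformly placed center and locations from an
#' isotropic bivariate normal (sd = \code{dispersion}) truncated to the
#' grid.
#'
#' @param n_animals,locs_per_animal counts.
#' @param dispersion isotropic location spread (m).
#' @param grid a \code{grid_spec}.
#' @param seed integer seed.
#' @return named list of \code{point_set}s, one per animal.
#' @export
gen_telemetry <- function(n_animals, locs_per_animal, dispersion, grid,
                          seed = 1L) {
  stopifnot(locs_per_animal >= 1)
  set.seed(seed)
  xmin <- grid$origin_x; xmax <- grid$origin_x + grid$n_cols * grid$cell_size
  ymin <- grid$origin_y; ymax <- grid$origin_y + grid$n_rows * grid$cell_size
  out <- lapply(seq_len(n_animals), function(a) {
    cx <- stats::runif(1, xmin + dispersion, xmax - dispersion)
    cy <- stats::runif(1, ymin + dispersion, ymax - dispersion)
    xs <- ys <- numeric(locs_per_animal)
    for (i in seq_len(locs_per_animal)) {
      repeat {
        x <- stats::rnorm(1, cx, dispersion)
        y <- stats::rnorm(1, cy, dispersion)
        if (x >= xmin && x < xmax && y >= ymin && y < ymax) break
      }
      xs[i] <- x; ys[i] <- y
    }
    point_set(xs, ys, id = paste0("a", a, "_", seq_len(locs_per_animal)))
  })
  names(out) <- paste0("animal", seq_len(n_animals))
  out
}

#' Generate a complete synthetic study system
#'
#' Runs every generator with seeds derived from \code{config$seed}:
#' predictors, true suitability, detection bias, presences, streams with
#' planted plots, a habitat layer (elevation between its 40th and 80th
#' percentiles, emulating a forest species whose range overlaps the
#' cultivation band), and telemetry.
#'
#' @param config a \code{landscape_config}.
#' @param model a \code{true_model}; default \code{default_true_model()}.
#' @return list of class \code{synthetic_truth} with elements
#'   \code{stack}, \code{suitability}, \code{model}, \code{bias},
#'   \code{presences}, \code{streams}, \code{plots}, \code{habitat},
#'   \code{telemetry}, \code{config}.
#' @export
synthetic_landscape <- function(config = landscape_config(),
                                model = default_true_model()) {
  stack <- gen_predictors(config)
  suit <- define_true_suitability(stack, model)
  bias <- gen_detection_bias(suit, strength = config$bias_strength,
                             seed = config$seed + 101L)
  presences <- sample_presences(suit, config$n_presences, bias = bias,
                                seed = config$seed + 202L)
  sp <- gen_streams_and_plots(config, suit, seed = config$seed + 303L,
                              streams = attr(stack, "streams"))
  habitat <- suppressMessages(gen_habitat(stack, function(df) {
    q <- stats::quantile(df$elevation, c(0.4, 0.8), na.rm = TRUE)
    df$elevation >= q[1] & df$elevation <= q[2]
  }))
  telemetry <- gen_telemetry(config$n_animals, config$locs_per_animal,
                             config$telemetry_dispersion, config$grid,
                             seed = config$seed + 404L)
  structure(list(stack = stack, suitability = suit, model = model,
                 bias = bias, presences = presences,
                 streams = sp$streams, plots = sp$plots,
                 habitat = habitat, telemetry = telemetry,
                 config = config),
            class = "synthetic_truth")
}

#' Write a synthetic study system to disk
#'
#' Rasters as ESRI ASCII grids, vectors as GeoJSON, points as CSV, plus
#' a JSON manifest recording the seed and file roles.
#'
#' @param truth a \code{synthetic_truth}.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(truth$stack))
    write_ascii_grid(truth$stack[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_ascii_grid(truth$suitability, file.path(dir, "true_suitability.asc"))
  write_ascii_grid(truth$habitat, file.path(dir, "habitat.asc"))
  write_points(truth$presences, file.path(dir, "presences.csv"))
  write_points(truth$plots, file.path(dir, "plots.csv"))
  write_geojson(truth$streams, file.path(dir, "streams.geojson"))
  for (nm in names(truth$telemetry))
    write_points(truth$telemetry[[nm]],
                 file.path(dir, paste0("telemetry_", nm, ".csv")))
  manifest <- list(seed = truth$config$seed,
                   grid = unclass(truth$config$grid),
                   layers = names(truth$stack),
                   n_presences = nrow(truth$presences),
                   n_plots = nrow(truth$plots),
                   n_streams = length(truth$streams),
                   animals = names(truth$telemetry))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
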