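#' Pipeline tunables with their standard defaults
#'
#' Bundles every tunable of the risk-mapping pipeline.  Defaults follow
#' the published analysis protocol: 2000 m minimum nearest-neighbour
#' thinning, 10,000 background points, 450 m focal window, 10-fold
#' cross-validation, optimizer cap of 500 iterations, regularization
#' multipliers {0.5, 1, 1.5, 2, 3, 5}, feature modes {auto, lqp, hinge},
#' |r| > 0.7 correlation grouping, 95\% home-range isopleths, and a
#' minimum of 26 telemetry locations per animal.
#'
#' @param thin_distance minimum nearest-neighbour distance (m).
#' @param n_background number of background (availability) points.
#' @param focal_radius focal-window radius (m) for predictor smoothing.
#' @param cv_folds number of cross-validation folds.
#' @param max_iterations optimizer iteration cap per model fit.
#' @param reg_multipliers regularization multipliers to tune over.
#' @param feature_modes feature modes to tune over.
#' @param correlation_threshold |Pearson r| above which variables group.
#' @param isopleth home-range isopleth fraction.
#' @param min_locations minimum locations per animal for a home range.
#' @param n_hinge_knots hinge knots per variable.
#' @param tol optimizer convergence tolerance (max projected gradient).
#' @param seed integer seed recorded in all outputs.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(thin_distance = 2000, n_background = 10000,
                       focal_radius = 450, cv_folds = 10,
                       max_iterations = 500,
                       reg_multipliers = c(0.5, 1, 1.5, 2, 3, 5),
                       feature_modes = c("auto", "lqp", "hinge"),
                       correlation_threshold = 0.7,
                       isopleth = 0.95, min_locations = 26,
                       n_hinge_knots = 50, tol = 1e-5, seed = 1L) {
  stopifnot(thin_distance >= 0, n_background >= 1, focal_radius > 0,
            cv_folds >= 2, max_iterations >= 1,
            all(reg_multipliers > 0),
            all(feature_modes %in% c("auto", "lqp", "hinge")),
            correlation_threshold > 0, correlation_threshold < 1,
            isopleth > 0, isopleth <= 1, min_locations >= 1,
            n_hinge_knots >= 2)
  structure(list(thin_distance = thin_distance,
                 n_background = n_background,
                 focal_radius = focal_radius, cv_folds = cv_folds,
                 max_iterations = max_iterations,
                 reg_multipliers = reg_multipliers,
                 feature_modes = feature_modes,
                 correlation_threshold = correlation_threshold,
                 isopleth = isopleth, min_locations = min_locations,
                 n_hinge_knots = n_hinge_knots, tol = tol,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write a resolved configuration beside run outputs
#' @param config a \code{run_config}.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a configuration file, filling unstated tunables with defaults
#' @param path YAML path.
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
}
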