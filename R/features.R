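#' Describe a feature expansion
#'
#' The three tested feature sets: \code{"lqp"} (linear + quadratic +
#' product), \code{"hinge"} (forward and reverse hinges only), and
#' \code{"auto"} (all of the above).
#'
#' @param mode one of "auto", "lqp", "hinge".
#' @param variables character vector of predictor names.
#' @param n_hinge_knots hinge knots per variable (default 50).
#' @return list of class \code{feature_spec}.
#' @export
feature_spec <- function(mode = c("auto", "lqp", "hinge"), variables,
                         n_hinge_knots = 50) {
  mode <- match.arg(mode)
  stopifnot(length(variables) >= 1, n_hinge_knots >= 2)
  structure(list(mode = mode, variables = variables,
                 n_hinge_knots = n_hinge_knots), class = "feature_spec")
}

#' Build a featurizer from training samples
#'
#' Records per-variable scaling bounds (min, max over all training
#' rows) and hinge knots (evenly spaced quantiles of the background
#' rows).  Constant variables are excluded with a warning.
#'
#' @param samples a \code{sample_table} (needs a \code{presence} column
#'   to identify background rows; otherwise all rows supply knots).
#' @param spec a \code{feature_spec}.
#' @return list of class \code{featurizer} with \code{bounds},
#'   \code{knots}, \code{meta} (one row per feature) and \code{spec}.
#' @export
make_featurizer <- function(samples, spec) {
  vars <- spec$variables
  missing <- setdiff(vars, names(samples))
  if (length(missing)) stop("variables not in samples: ",
                            paste(missing, collapse = ", "))
  bg <- if ("presence" %in% names(samples))
    samples[samples$presence == 0, , drop = FALSE] else samples
  if (!nrow(bg)) bg <- samples
  bounds <- list(); knots <- list()
  for (v in vars) {
    x <- samples[[v]]
    rng <- range(x, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("constant variable excluded from features: ", v)
      next
    }
    bounds[[v]] <- rng
    if (spec$mode %in% c("auto", "hinge")) {
      pr <- seq_len(spec$n_hinge_knots) / (spec$n_hinge_knots + 1)
      k <- unique(as.numeric(stats::quantile(bg[[v]], pr, na.rm = TRUE,
                                             names = FALSE)))
      knots[[v]] <- k[k > rng[1] & k < rng[2]]
    }
  }
  vars <- names(bounds)
  if (!length(vars)) stop("no usable (non-constant) variables")
  meta <- list()
  add <- function(name, type, var1, var2 = NA_character_, knot = NA_real_)
    meta[[length(meta) + 1L]] <<- data.frame(
      name = name, type = type, var1 = var1, var2 = var2, knot = knot,
      stringsAsFactors = FALSE)
  if (spec$mode %in% c("auto", "lqp")) {
    for (v in vars) {
      add(v, "linear", v)
      add(paste0(v, "^2"), "quadratic", v)
    }
    if (length(vars) > 1)
      for (i in seq_len(length(vars) - 1))
        for (j in (i + 1):length(vars))
          add(paste0(vars[i], "*", vars[j]), "product", vars[i], vars[j])
  }
  if (spec$mode %in% c("auto", "hinge")) {
    for (v in vars) {
      for (k in knots[[v]]) {
        add(sprintf("hf(%s,%.6g)", v, k), "hinge_fwd", v, knot = k)
        add(sprintf("hr(%s,%.6g)", v, k), "hinge_rev", v, knot = k)
      }
    }
  }
  structure(list(bounds = bounds, knots = knots,
                 meta = do.call(rbind, meta),
                 spec = feature_spec(spec$mode, vars, spec$n_hinge_knots)),
            class = "featurizer")
}

#' Compute the feature matrix for a set of samples
#'
#' Variables are clamped into the training bounds (projection-time
#' clamping), scaled to [0, 1], then expanded; every feature lies in
#' [0, 1].
#'
#' @param ftz a \code{featurizer}.
#' @param samples data.frame holding the featurizer's variables.
#' @return numeric matrix, one column per feature.
#' @export
featurize <- function(ftz, samples) {
  vars <- ftz$spec$variables
  missing <- setdiff(vars, names(samples))
  if (length(missing)) stop("feature mismatch; missing: ",
                            paste(missing, collapse = ", "))
  xs <- list()
  for (v in vars) {
    b <- ftz$bounds[[v]]
    xs[[v]] <- (pmin(pmax(samples[[v]], b[1]), b[2]) - b[1]) / (b[2] - b[1])
  }
  m <- ftz$meta
  F <- matrix(0, nrow(samples), nrow(m),
              dimnames = list(NULL, m$name))
  for (f in seq_len(nrow(m))) {
    v <- m$var1[f]
    F[, f] <- switch(m$type[f],
      linear = xs[[v]],
      quadratic = xs[[v]]^2,
      product = xs[[v]] * xs[[m$var2[f]]],
      hinge_fwd = {
        b <- ftz$bounds[[v]]
        ks <- (m$knot[f] - b[1]) / (b[2] - b[1])
        pmax(0, (xs[[v]] - ks) / (1 - ks))
      },
      hinge_rev = {
        b <- ftz$bounds[[v]]
        ks <- (m$knot[f] - b[1]) / (b[2] - b[1])
        pmax(0, (ks - xs[[v]]) / ks)
      })
  }
  F
}

#' Expand samples into a feature matrix
#'
#' Convenience wrapper: builds the featurizer from \code{samples} and
#' returns the expanded matrix together with it.
#'
#' @param samples a \code{sample_table}.
#' @param spec a \code{feature_spec}.
#' @return list of class \code{feature_matrix}: \code{F} (samples x
#'   features), \code{meta}, \code{featurizer}, and \code{presence}
#'   flags when present in \code{samples}.
#' @export
expand_features <- function(samples, spec) {
  ftz <- make_featurizer(samples, spec)
  structure(list(F = featurize(ftz, samples), meta = ftz$meta,
                 featurizer = ftz,
                 presence = samples$presence), class = "feature_matrix")
}

# Published default regularization schedule c(class, m): piecewise-linear
# interpolation in the number of presences m.  Hinge features use a
# constant 0.5.
reg_schedule <- function(type, m) {
  if (type %in% c("hinge_fwd", "hinge_rev")) return(0.5)
  pts_m <- c(0, 10, 30, 100)
  pts_c <- c(1, 1, 0.2, 0.05)
  stats::approx(pts_m, pts_c, xout = min(m, 100), rule = 2)$y
}

#' Default per-feature L1 penalties
#'
#' \code{beta_j = r * c(class, m) * s_j / sqrt(m)} with \code{m} the
#' number of presences, \code{s_j} the feature standard deviation over
#' the presence rows (floored at 1e-3 to keep the problem bounded), and
#' \code{c} the published per-class default schedule.
#'
#' @param meta feature metadata (from a \code{featurizer}).
#' @param Fp presence feature matrix.
#' @param r regularization multiplier.
#' @return numeric vector of penalties.
#' @export
default_betas <- function(meta, Fp, r = 1) {
  m <- nrow(Fp)
  s <- apply(Fp, 2, stats::sd)
  s[!is.finite(s) | s < 1e-3] <- 1e-3
  cls <- vapply(meta$type, reg_schedule, numeric(1), m = m)
  r * cls * s / sqrt(m)
}
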