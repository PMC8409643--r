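#' Fit a presence-background maximum-entropy model
#'
#' \code{maxent()} is the package's central fitting function.  The model
#' is the Gibbs distribution over background locations
#' \eqn{q(x) \propto \exp(\lambda \cdot f(x))} whose feature
#' expectations match the presence means to within per-feature L1
#' penalties: the fit maximizes
#' \deqn{\bar f_{pres} \cdot \lambda - \log \frac{1}{N}\sum_{bg}
#'   e^{\lambda \cdot f} - \sum_j \beta_j |\lambda_j|}
#' by an accelerated proximal-gradient (FISTA) solve with backtracking;
#' convergence is declared when the maximum projected gradient falls
#' below \code{tol}.
#'
#' @param samples a \code{sample_table} with a 0/1 \code{presence}
#'   column and predictor columns.
#' @param variables predictors to use (default: all recorded on the
#'   table).
#' @param mode feature mode: "auto", "lqp" or "hinge".
#' @param r regularization multiplier (default 1).
#' @param betas optional explicit per-feature penalties overriding the
#'   default schedule.
#' @param max_iter optimizer iteration cap (default 500).
#' @param tol convergence tolerance on the projected gradient.
#' @param n_hinge_knots hinge knots per variable.
#' @return an object of class \code{maxent}; see
#'   \code{\link{predict.maxent}}, \code{\link{summary.maxent}}.
#' @export
maxent <- function(samples, variables = NULL,
                   mode = c("auto", "lqp", "hinge"), r = 1, betas = NULL,
                   max_iter = 500, tol = 1e-5, n_hinge_knots = 50) {
  mode <- match.arg(mode)
  stopifnot("presence" %in% names(samples))
  if (is.null(variables)) variables <- sample_variables(samples)
  spec <- feature_spec(mode, variables, n_hinge_knots)
  ftz <- make_featurizer(samples, spec)
  F <- featurize(ftz, samples)
  # presence samples are added to the fitting background (the cited
  # tool's default); otherwise a feature positive at a presence but
  # zero on every background point has no finite optimum
  fit <- fit_maxent(
    structure(list(F = F[samples$presence == 1, , drop = FALSE],
                   meta = ftz$meta, featurizer = ftz),
              class = "feature_matrix"),
    structure(list(F = F[c(which(samples$presence == 0),
                           which(samples$presence == 1)), ,
                         drop = FALSE],
                   meta = ftz$meta, featurizer = ftz),
              class = "feature_matrix"),
    r = r, betas = betas, max_iter = max_iter, tol = tol)
  fit$call <- match.call()
  vars <- fit$featurizer$spec$variables
  fit$var_means <- colMeans(samples[samples$presence == 0, vars,
                                    drop = FALSE])
  fit
}

#' Fit the maximum-entropy model from feature matrices
#'
#' Lower-level interface taking pre-built presence and background
#' feature matrices (which must share one featurizer).
#'
#' @param presence_fm,background_fm \code{feature_matrix} objects.
#' @param r regularization multiplier.
#' @param betas optional explicit per-feature penalties.
#' @param max_iter,tol optimizer controls.
#' @param init optional warm-start weight vector (e.g. from a fit of
#'   the same feature space on overlapping data).
#' @return an object of class \code{maxent} with elements including
#'   \code{lambdas}, \code{betas}, \code{log_Z} (log normalizer over the
#'   training background), \code{entropy} (of the fitted background
#'   distribution, nats), \code{featurizer}, convergence info, and the
#'   per-variable optimizer-path gains used for percent contribution.
#' @export
fit_maxent <- function(presence_fm, background_fm, r = 1, betas = NULL,
                       max_iter = 500, tol = 1e-5, init = NULL) {
  Fp <- presence_fm$F; Fb <- background_fm$F
  if (nrow(Fp) < 2) stop("at least 2 presences required")
  if (nrow(Fb) < 10) stop("at least 10 background samples required")
  if (!identical(colnames(Fp), colnames(Fb)))
    stop("presence and background feature matrices do not match")
  meta <- presence_fm$meta
  if (is.null(betas)) betas <- default_betas(meta, Fp, r)
  stopifnot(length(betas) == ncol(Fp))

  J <- ncol(Fp); nb <- nrow(Fb)
  mp <- colMeans(Fp)
  res <- fista_l1(Fb, mp, betas, max_iter = max_iter, tol = tol,
                  init = init)
  l <- res$l; gains <- res$gains
  converged <- res$converged; it <- res$iterations
  if (!converged)
    warning("maxent fit did not reach tolerance in ", max_iter,
            " iterations (max projected gradient ",
            format(res$pg_max, digits = 3), "); returning best iterate")

  s <- drop(Fb %*% l)
  mx <- max(s)
  log_Z <- mx + log(sum(exp(s - mx)))
  q <- exp(s - log_Z)
  H <- -sum(ifelse(q > 0, q * log(q), 0))

  obj_out <- structure(list(
    lambdas = stats::setNames(l, colnames(Fp)),
    betas = stats::setNames(betas, colnames(Fp)),
    meta = meta, featurizer = presence_fm$featurizer,
    r = r, mode = presence_fm$featurizer$spec$mode,
    log_Z = log_Z, entropy = H,
    n_presence = nrow(Fp), n_background = nb,
    presence_means = mp, bg_expectations = drop(crossprod(Fb, q)),
    converged = converged, iterations = it,
    gains = stats::setNames(gains, colnames(Fp))), class = "maxent")
  # training scores kept for thresholds/AUC without re-featurizing
  obj_out$train_presence_logistic <- maxent_transform(
    drop(Fp %*% l), obj_out, "logistic")
  obj_out$train_background_logistic <- maxent_transform(s, obj_out, "logistic")
  obj_out$train_auc <- compute_auc(obj_out$train_presence_logistic,
                                   obj_out$train_background_logistic)
  obj_out
}

maxent_transform <- function(link, model, type) {
  raw <- exp(link - model$log_Z)
  switch(type,
         link = link,
         raw = raw,
         logistic = {
           eHq <- exp(model$entropy) * raw
           eHq / (1 + eHq)
         })
}

#' Predict from a fitted maximum-entropy model
#'
#' Projection features are clamped into the training bounds.  "raw" is
#' the Gibbs density normalized to sum to one over the training
#' background; "logistic" is the fixed-prevalence transform
#' \eqn{e^H q / (1 + e^H q)} of raw output \eqn{q}, in (0, 1).
#'
#' @param object a \code{maxent} model.
#' @param newdata a data.frame of predictor columns or a
#'   \code{predictor_stack}.
#' @param type "logistic" (default), "raw" or "link".
#' @param ... unused.
#' @return numeric vector, or a \code{grid_raster} when \code{newdata}
#'   is a stack.
#' @export
predict.maxent <- function(object, newdata,
                           type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "predictor_stack")) {
    g <- stack_grid(newdata)
    df <- as.data.frame(lapply(newdata, function(l) as.vector(l$values)))
    ok <- stats::complete.cases(df[object$featurizer$spec$variables])
    out <- rep(NA_real_, nrow(df))
    if (any(ok))
      out[ok] <- predict.maxent(object, df[ok, , drop = FALSE], type = type)
    return(grid_raster(matrix(out, g$n_rows, g$n_cols), g))
  }
  F <- featurize(object$featurizer, newdata)
  maxent_transform(drop(F %*% object$lambdas), object, type)
}

#' @export
coef.maxent <- function(object, ...) object$lambdas

#' @export
print.maxent <- function(x, ...) {
  cat(sprintf("<maxent> %s features, r = %g: %d/%d nonzero weights\n",
              x$mode, x$r, sum(x$lambdas != 0), length(x$lambdas)))
  cat(sprintf("  n = %d presences / %d background; entropy %.3f nats; training AUC %.3f\n",
              x$n_presence, x$n_background, x$entropy, x$train_auc))
  if (!x$converged) cat("  (not converged)\n")
  invisible(x)
}

#' @export
summary.maxent <- function(object, ...) {
  nz <- object$lambdas[object$lambdas != 0]
  top <- utils::head(nz[order(-abs(nz))], 10)
  ans <- list(mode = object$mode, r = object$r,
              n_features = length(object$lambdas),
              n_nonzero = length(nz),
              entropy = object$entropy, train_auc = object$train_auc,
              converged = object$converged,
              iterations = object$iterations, top = top)
  class(ans) <- "summary.maxent"
  ans
}

#' @export
print.summary.maxent <- function(x, ...) {
  cat(sprintf("Maximum-entropy model (%s features, r = %g)\n", x$mode, x$r))
  cat(sprintf("  %d of %d feature weights nonzero; entropy %.3f; training AUC %.3f\n",
              x$n_nonzero, x$n_features, x$entropy, x$train_auc))
  cat(sprintf("  optimizer: %d iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  cat("  largest weights:\n")
  for (i in seq_along(x$top))
    cat(sprintf("    %-28s %+.4f\n", names(x$top)[i], x$top[i]))
  invisible(x)
}

#' Marginal response curves of a fitted model
#'
#' For each plotted variable, the logistic prediction along an even grid
#' over its training bounds with the other variables held at their
#' training-background means.
#'
#' @param x a \code{maxent} model.
#' @param variables which variables to plot (default all).
#' @param n_points grid resolution.
#' @param ... passed to \code{plot}.
#' @export
plot.maxent <- function(x, variables = NULL, n_points = 100, ...) {
  vars <- x$featurizer$spec$variables
  if (is.null(variables)) variables <- vars
  means <- x$var_means
  if (is.null(means))
    means <- vapply(x$featurizer$bounds, mean, numeric(1))
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(variables)))
  on.exit(graphics::par(op))
  for (v in variables) {
    b <- x$featurizer$bounds[[v]]
    grid <- seq(b[1], b[2], length.out = n_points)
    nd <- as.data.frame(lapply(means[vars], rep, n_points))
    names(nd) <- vars
    nd[[v]] <- grid
    graphics::plot(grid, predict(x, nd), type = "l", xlab = v,
                   ylab = "logistic output", ylim = c(0, 1), ...)
  }
  invisible(x)
}

#' Simulate presence locations from a fitted model
#'
#' Draws cells over a predictor stack with probability proportional to
#' the model's raw output, jittered within cells.
#'
#' @param object a \code{maxent} model.
#' @param nsim number of points.
#' @param seed integer seed.
#' @param stack a \code{predictor_stack} to project onto.
#' @param ... unused.
#' @return a \code{point_set}.
#' @export
simulate.maxent <- function(object, nsim = 1, seed = 1L, stack, ...) {
  raw <- predict(object, stack, type = "raw")
  sample_presences(raw, nsim, seed = seed)
}

#' Area under the ROC curve for presence vs background scores
#'
#' Probability that a random presence outscores a random background
#' point, ties counted one half (Mann-Whitney form, computed from
#' ranks).
#'
#' @param presence_scores,background_scores numeric score vectors.
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(presence_scores, background_scores) {
  np <- length(presence_scores); nb <- length(background_scores)
  if (!np || !nb) stop("empty score set")
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Ten-percent training omission rate on held-out presences
#'
#' Threshold at the 10th percentile of training presence scores; the
#' rate is the fraction of test presences scoring strictly below it.
#'
#' @param train_presence_scores,test_presence_scores score vectors
#'   (logistic scale).
#' @param level percentile level (default 0.10).
#' @return omission rate in [0, 1].
#' @export
omission_rate <- function(train_presence_scores, test_presence_scores,
                          level = 0.10) {
  if (length(train_presence_scores) < 10)
    stop("at least 10 training presences required")
  if (!length(test_presence_scores)) stop("empty test set")
  thr <- stats::quantile(train_presence_scores, level, names = FALSE)
  mean(test_presence_scores < thr)
}

#' Serialize a fitted model to JSON
#'
#' Stores feature metadata, training bounds and knots, weights,
#' normalizer, entropy and regularization settings; the file round
#' trips through \code{\link{read_maxent}}.
#'
#' @param model a \code{maxent} model.
#' @param path output .json path.
#' @export
write_maxent <- function(model, path) {
  ftz <- model$featurizer
  out <- list(mode = model$mode, r = model$r,
              variables = ftz$spec$variables,
              n_hinge_knots = ftz$spec$n_hinge_knots,
              bounds = ftz$bounds, knots = ftz$knots,
              meta = ftz$meta,
              lambdas = as.list(model$lambdas),
              betas = as.list(model$betas),
              log_Z = model$log_Z, entropy = model$entropy,
              n_presence = model$n_presence,
              n_background = model$n_background,
              var_means = as.list(model$var_means),
              converged = model$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by \code{write_maxent}
#' @param path .json path.
#' @return a \code{maxent} model usable with \code{predict}.
#' @export
read_maxent <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  ftz <- structure(list(
    bounds = lapply(j$bounds, as.numeric),
    knots = lapply(j$knots, as.numeric),
    meta = as.data.frame(j$meta, stringsAsFactors = FALSE),
    spec = feature_spec(j$mode, j$variables, j$n_hinge_knots)),
    class = "featurizer")
  structure(list(lambdas = unlist(j$lambdas), betas = unlist(j$betas),
                 meta = ftz$meta, featurizer = ftz, r = j$r,
                 mode = j$mode, log_Z = j$log_Z, entropy = j$entropy,
                 n_presence = j$n_presence, n_background = j$n_background,
                 var_means = unlist(j$var_means), converged = j$converged,
                 gains = NULL, train_auc = NA_real_),
            class = "maxent")
}
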