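#' Cross-validated evaluation of one model setting
#'
#' Runs the k-fold design for a fixed variable set / mode / multiplier,
#' collecting per-fold test AUC, the pooled held-out logistic scores
#' (used downstream for the Boyce analysis) and the mean 10\% omission
#' rate.
#'
#' @param samples a \code{sample_table}.
#' @param folds presence fold labels.
#' @param variables,mode,r model settings.
#' @param config a \code{run_config}.
#' @return list with \code{fold_aucs}, \code{mean_test_auc},
#'   \code{held_out_scores}, \code{mean_omission_10}.
#' @export
cv_evaluate <- function(samples, folds, variables, mode = "auto", r = 1,
                        config = run_config()) {
  cv <- cv_core(samples, folds, variables, mode, r, config)
  cv[c("fold_aucs", "mean_test_auc", "held_out_scores",
       "mean_omission_10")]
}

#' Run the full risk-mapping pipeline
#'
#' Thins the occurrences (2000 m rule), samples background over the
#' stack's valid extent, smooths every predictor with a 450 m focal
#' mean, extracts the sample table, assigns cross-validation folds,
#' groups collinear variables and picks univariate-AUC winners, prunes
#' by stepwise jackknife, tunes feature mode x regularization
#' multiplier by AICc, refits the winning settings, cross-validates
#' them, and classifies the logistic surface into low/moderate/high
#' risk via the Boyce curve of the pooled held-out predictions.
#'
#' @param stack a \code{predictor_stack} (raw, unsmoothed layers).
#' @param presences a \code{point_set} of occurrence localities.
#' @param config a \code{run_config}; its \code{seed} drives every
#'   random step.
#' @return object of class \code{grow_risk_fit}.
#' @export
grow_risk_pipeline <- function(stack, presences, config = run_config()) {
  g <- stack_grid(stack)
  seed <- config$seed

  thin <- thin_occurrences(presences, config$thin_distance, seed = seed)

  valid <- Reduce(`&`, lapply(stack, function(l) !is.na(l$values)))
  mask <- grid_raster(valid * 1, g)
  background <- sample_background(mask, config$n_background,
                                  seed = seed + 1L)

  smoothed <- focal_smooth_stack(stack, config$focal_radius)
  samples <- build_samples(smoothed, thin$kept, background)
  folds <- make_cv_folds(samples, k = config$cv_folds, seed = seed + 2L)

  groups <- group_correlated(samples, config$correlation_threshold)
  selection <- univariate_select(groups, samples, folds, config)
  jackknife <- stepwise_jackknife(selection$selected, samples, folds,
                                  config)
  tuning <- tune_hyperparameters(samples, smoothed, jackknife$retained,
                                 config)

  final <- maxent(samples, variables = jackknife$retained,
                  mode = tuning$winner$mode, r = tuning$winner$r,
                  max_iter = config$max_iterations, tol = config$tol,
                  n_hinge_knots = config$n_hinge_knots)
  cv <- cv_evaluate(samples, folds, jackknife$retained,
                    mode = tuning$winner$mode, r = tuning$winner$r,
                    config = config)

  surface <- predict(final, smoothed, type = "logistic")
  boyce <- boyce_curve(surface, cv$held_out_scores)
  riskmap <- classify_risk(surface, boyce)
  importance <- variable_importance(final, samples, seed = seed + 3L)

  structure(list(thin = thin, background = background,
                 samples = samples, folds = folds, groups = groups,
                 selection = selection, jackknife = jackknife,
                 tuning = tuning, model = final, cv = cv,
                 surface = surface, boyce = boyce, riskmap = riskmap,
                 importance = importance, config = config),
            class = "grow_risk_fit")
}

#' @export
print.grow_risk_fit <- function(x, ...) {
  cat("Trespass-cultivation risk model\n")
  cat(sprintf("  occurrences: %d thinned to %d (>= %g m apart)\n",
              nrow(x$thin$kept) + nrow(x$thin$removed), nrow(x$thin$kept),
              x$config$thin_distance))
  cat(sprintf("  variables: %d candidates -> %d after grouping -> %d retained\n",
              length(unlist(x$groups)), length(x$selection$selected),
              length(x$jackknife$retained)))
  cat(sprintf("  winner: %s features, r = %g (AICc %.1f)\n",
              x$tuning$winner$mode, x$tuning$winner$r, x$tuning$winner$AICc))
  cat(sprintf("  mean %d-fold test AUC %.3f; mean 10%% omission %.3f; Boyce index %.3f\n",
              x$config$cv_folds, x$cv$mean_test_auc, x$cv$mean_omission_10,
              x$boyce$index))
  cat(sprintf("  risk thresholds: %.3f / %.3f\n",
              x$riskmap$thresholds[1], x$riskmap$thresholds[2]))
  invisible(x)
}

#' @export
summary.grow_risk_fit <- function(object, ...) {
  print(object)
  cat("\nretained variables:", paste(object$jackknife$retained,
                                     collapse = ", "), "\n")
  cat("\nvariable importance:\n")
  print(object$importance, row.names = FALSE, digits = 3)
  cat("\nclass areas:\n")
  print(class_areas(object$riskmap), row.names = FALSE, digits = 4)
  invisible(object)
}
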