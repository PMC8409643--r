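#' Mean cross-validated test AUC for a variable set
#'
#' For each fold, fits the model on the background plus out-of-fold
#' presences and scores the held-out presences against the training
#' background (the standard presence-background CV design).
#'
#' @param samples a \code{sample_table}.
#' @param folds fold labels for the presence rows (in table order).
#' @param variables predictors to use.
#' @param mode,r feature mode and regularization multiplier.
#' @param config a \code{run_config} (optimizer controls).
#' @return mean test AUC over folds; per-fold AUCs in attribute
#'   \code{"folds"}.
#' @export
cv_mean_auc <- function(samples, folds, variables, mode = "auto", r = 1,
                        config = run_config()) {
  cv <- cv_core(samples, folds, variables, mode, r, config)
  structure(cv$mean_test_auc, folds = cv$fold_aucs)
}

# Shared cross-validation engine.  Features are defined once from the
# full sample table (hinge knots from the background, which every fold
# shares); fold fits differ only in which presence rows enter the
# likelihood, and each is warm-started from the all-presence fit.
cv_core <- function(samples, folds, variables, mode = "auto", r = 1,
                    config = run_config()) {
  pres_idx <- which(samples$presence == 1)
  bg_idx <- which(samples$presence == 0)
  stopifnot(length(folds) == length(pres_idx))
  spec <- feature_spec(mode, variables, config$n_hinge_knots)
  ftz <- make_featurizer(samples, spec)
  F <- featurize(ftz, samples)
  mkfm <- function(rows) structure(
    list(F = F[rows, , drop = FALSE], meta = ftz$meta, featurizer = ftz),
    class = "feature_matrix")
  # training presences join the fitting background (the cited tool's
  # default; keeps every feature's optimum finite)
  full <- fit_maxent(mkfm(pres_idx), mkfm(c(bg_idx, pres_idx)), r = r,
                     max_iter = config$max_iterations, tol = config$tol)
  ids <- sort(unique(folds))
  aucs <- omis <- rep(NA_real_, length(ids))
  held <- rep(NA_real_, length(pres_idx))
  for (i in seq_along(ids)) {
    f <- ids[i]
    tr_pres <- pres_idx[folds != f]
    m <- fit_maxent(mkfm(tr_pres), mkfm(c(bg_idx, tr_pres)), r = r,
                    max_iter = config$max_iterations, tol = config$tol,
                    init = full$lambdas)
    link <- drop(F[pres_idx[folds == f], , drop = FALSE] %*% m$lambdas)
    sc <- maxent_transform(link, m, "logistic")
    bg_sc <- maxent_transform(drop(F[bg_idx, , drop = FALSE] %*%
                                     m$lambdas), m, "logistic")
    held[folds == f] <- sc
    aucs[i] <- compute_auc(sc, bg_sc)
    if (length(tr_pres) >= 10)
      omis[i] <- omission_rate(m$train_presence_logistic, sc)
  }
  list(fold_aucs = stats::setNames(aucs, ids), mean_test_auc = mean(aucs),
       held_out_scores = held, mean_omission_10 = mean(omis),
       full_fit = full)
}

#' Group collinear variables
#'
#' Pearson correlations over the pooled presence + background rows;
#' groups are the connected components of the graph with an edge
#' wherever |r| strictly exceeds the threshold.  Constant variables are
#' assigned singleton groups with a warning.
#'
#' @param samples a \code{sample_table}.
#' @param threshold correlation threshold (default 0.7).
#' @param variables candidate variables (default all on the table).
#' @return list of character vectors (the groups).
#' @export
group_correlated <- function(samples, threshold = 0.7, variables = NULL) {
  if (nrow(samples) < 2) stop("at least 2 samples required")
  if (is.null(variables)) variables <- sample_variables(samples)
  X <- as.matrix(samples[variables])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("constant variable(s) assigned singleton groups: ",
            paste(variables[sds == 0], collapse = ", "))
  suppressWarnings(R <- stats::cor(X, use = "pairwise.complete.obs"))
  adj <- abs(R) > threshold
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  # connected components by breadth-first search
  seen <- rep(FALSE, length(variables))
  groups <- list()
  for (s in seq_along(variables)) {
    if (seen[s]) next
    comp <- s; queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      comp <- c(comp, nb); queue <- c(queue, nb)
    }
    groups[[length(groups) + 1L]] <- variables[sort(comp)]
  }
  groups
}

#' Pick one variable per correlated group by univariate CV AUC
#'
#' Singleton groups pass through.  For each multi-member group, a
#' default-settings univariate model is cross-validated per member; the
#' member with the highest mean test AUC wins, ties broken
#' lexicographically.
#'
#' @param groups list of character vectors from
#'   \code{\link{group_correlated}}.
#' @param samples a \code{sample_table}.
#' @param folds presence fold labels.
#' @param config a \code{run_config}.
#' @return list with \code{selected} (character vector) and
#'   \code{auc_table} (per-variable mean test AUC where fitted).
#' @export
univariate_select <- function(groups, samples, folds,
                              config = run_config()) {
  selected <- character(0)
  tab <- list()
  for (gr in groups) {
    if (length(gr) == 1) {
      selected <- c(selected, gr)
      next
    }
    aucs <- vapply(gr, function(v)
      as.numeric(cv_mean_auc(samples, folds, v, mode = "auto", r = 1,
                             config = config)), numeric(1))
    tab[[length(tab) + 1L]] <- data.frame(variable = gr, mean_test_auc = aucs,
                                          stringsAsFactors = FALSE)
    ord <- order(-aucs, gr)      # ties -> lexicographically first
    selected <- c(selected, gr[ord[1]])
  }
  list(selected = selected,
       auc_table = if (length(tab)) do.call(rbind, tab) else
         data.frame(variable = character(0), mean_test_auc = numeric(0)))
}

#' Stepwise jackknife variable reduction
#'
#' Repeatedly refits the model leaving out each remaining variable and
#' removes the one whose omission yields the highest mean test AUC;
#' stops when every removal would strictly lower the AUC or one
#' variable remains.  The retained set is the best-AUC state visited
#' (including the full set).
#'
#' @param variables starting variable set.
#' @param samples a \code{sample_table}.
#' @param folds presence fold labels (held fixed across refits so AUC
#'   differences reflect variables, not fold noise).
#' @param config a \code{run_config}.
#' @return list of class \code{selection_trace}: \code{trace}
#'   (data.frame of removed variable and AUC after removal),
#'   \code{retained}, \code{retained_auc}, \code{full_auc}.
#' @export
stepwise_jackknife <- function(variables, samples, folds,
                               config = run_config()) {
  current <- variables
  cur_auc <- as.numeric(cv_mean_auc(samples, folds, current,
                                    config = config))
  full_auc <- cur_auc
  best_set <- current; best_auc <- cur_auc
  trace <- data.frame(removed = character(0), mean_test_auc = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(current) > 1) {
    cand_auc <- vapply(current, function(v)
      as.numeric(cv_mean_auc(samples, folds, setdiff(current, v),
                             config = config)), numeric(1))
    ord <- order(-cand_auc, current)
    v_star <- current[ord[1]]
    a_star <- cand_auc[ord[1]]
    if (a_star < cur_auc) break
    current <- setdiff(current, v_star)
    cur_auc <- a_star
    trace <- rbind(trace, data.frame(removed = v_star,
                                     mean_test_auc = a_star,
                                     stringsAsFactors = FALSE))
    if (a_star >= best_auc) { best_auc <- a_star; best_set <- current }
  }
  structure(list(trace = trace, retained = best_set,
                 retained_auc = best_auc, full_auc = full_auc),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat(sprintf("<selection_trace> full-set AUC %.4f; retained %d variable(s) (AUC %.4f)\n",
              x$full_auc, length(x$retained), x$retained_auc))
  if (nrow(x$trace)) {
    cat("  removal order:\n")
    for (i in seq_len(nrow(x$trace)))
      cat(sprintf("    -%s  -> %.4f\n", x$trace$removed[i],
                  x$trace$mean_test_auc[i]))
  }
  invisible(x)
}

#' Small-sample-corrected AIC from its components
#'
#' \code{AICc = 2K - 2LL + 2K(K + 1)/(n - K - 1)}; undefined (NA) when
#' \code{K >= n - 1}.
#'
#' @param K number of nonzero feature weights.
#' @param LL log-likelihood of the presences under the
#'   grid-standardized raw output.
#' @param n number of presences.
#' @return AICc value, or NA when undefined.
#' @export
aicc_value <- function(K, LL, n) {
  if (K >= n - 1) return(NA_real_)
  2 * K - 2 * LL + 2 * K * (K + 1) / (n - K - 1)
}

#' AICc of a fitted model over a projection grid
#'
#' The raw output is standardized to sum to one over the non-nodata
#' cells of the projection stack; the log-likelihood sums the log
#' standardized value at each presence cell; K counts nonzero feature
#' weights.
#'
#' @param model a \code{maxent} model.
#' @param presences a \code{point_set} (or data.frame with x, y) of the
#'   presences used to fit.
#' @param stack the projection \code{predictor_stack}.
#' @return list with \code{K}, \code{LL}, \code{AICc}, \code{valid}.
#' @export
compute_aicc <- function(model, presences, stack) {
  raw <- predict(model, stack, type = "raw")
  tot <- sum(raw$values, na.rm = TRUE)
  p_at <- raster_values_at(raw, presences$x, presences$y) / tot
  if (any(is.na(p_at)))
    stop("presence outside the projection grid or on nodata")
  n <- nrow(presences)
  K <- sum(model$lambdas != 0)
  LL <- sum(log(p_at))
  aicc <- aicc_value(K, LL, n)
  list(K = K, LL = LL, AICc = aicc, valid = !is.na(aicc))
}

#' Tune feature mode and regularization multiplier by AICc
#'
#' Fits every mode x multiplier combination on the full training data
#' (18 with the default grids) and scores each by AICc over the
#' projection stack.  The winner has minimum AICc among valid rows;
#' exact ties go to the larger multiplier, then the simpler mode
#' (lqp < hinge < auto).
#'
#' @param samples a \code{sample_table} restricted to the selected
#'   variables (plus presence/x/y columns).
#' @param stack projection \code{predictor_stack}.
#' @param variables variables to fit.
#' @param config a \code{run_config} (modes, multipliers, optimizer).
#' @return list of class \code{tuning_result}: \code{table} and
#'   \code{winner} (list with mode, r).
#' @export
tune_hyperparameters <- function(samples, stack, variables,
                                 config = run_config()) {
  presences <- samples[samples$presence == 1, c("x", "y"), drop = FALSE]
  rows <- list()
  for (mode in config$feature_modes) {
    for (r in config$reg_multipliers) {
      m <- maxent(samples, variables = variables, mode = mode, r = r,
                  max_iter = config$max_iterations, tol = config$tol,
                  n_hinge_knots = config$n_hinge_knots)
      a <- compute_aicc(m, presences, stack)
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, r = r, K = a$K, LL = a$LL, AICc = a$AICc,
        valid = a$valid, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  val <- tab[tab$valid, , drop = FALSE]
  if (!nrow(val)) stop("all mode x multiplier combinations invalid")
  mode_rank <- c(lqp = 1, hinge = 2, auto = 3)
  ord <- order(val$AICc, -val$r, mode_rank[val$mode])
  win <- val[ord[1], ]
  structure(list(table = tab,
                 winner = list(mode = win$mode, r = win$r,
                               AICc = win$AICc, K = win$K)),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d combinations; winner: %s features, r = %g (AICc %.2f, K = %d)\n",
              nrow(x$table), x$winner$mode, x$winner$r, x$winner$AICc,
              x$winner$K))
  invisible(x)
}

#' Percent contribution and permutation importance of each variable
#'
#' Percent contribution allocates the optimizer's per-iteration
#' objective gains to the source variable of the responsible features
#' (product features credit both parents equally), normalized to sum
#' to 100; it is path-dependent and approximate, but seed-stable.
#' Permutation importance is the drop in training AUC after permuting
#' each variable's values across the pooled presence + background rows
#' (one seeded permutation), floored at zero and normalized to 100.
#'
#' @param model a fitted \code{maxent} model.
#' @param samples the training \code{sample_table}.
#' @param seed integer seed for the permutations.
#' @return data.frame with \code{variable}, \code{percent_contribution},
#'   \code{permutation_importance}; each column sums to 100 (when any
#'   signal exists).
#' @export
variable_importance <- function(model, samples, seed = 1L) {
  if (is.null(model$gains)) stop("model carries no optimizer path")
  vars <- model$featurizer$spec$variables
  contrib <- stats::setNames(numeric(length(vars)), vars)
  m <- model$meta
  for (j in seq_along(model$gains)) {
    g <- model$gains[j]
    if (m$type[j] == "product") {
      contrib[m$var1[j]] <- contrib[m$var1[j]] + g / 2
      contrib[m$var2[j]] <- contrib[m$var2[j]] + g / 2
    } else {
      contrib[m$var1[j]] <- contrib[m$var1[j]] + g
    }
  }
  if (sum(contrib) > 0) contrib <- 100 * contrib / sum(contrib)

  pres <- samples$presence == 1
  base_scores <- predict(model, samples, type = "link")
  base_auc <- compute_auc(base_scores[pres], base_scores[!pres])
  set.seed(seed)
  drops <- vapply(vars, function(v) {
    perm <- samples
    perm[[v]] <- perm[[v]][sample.int(nrow(perm))]
    sc <- predict(model, perm, type = "link")
    base_auc - compute_auc(sc[pres], sc[!pres])
  }, numeric(1))
  drops <- pmax(drops, 0)
  if (sum(drops) > 0) drops <- 100 * drops / sum(drops)
  data.frame(variable = vars,
             percent_contribution = as.numeric(contrib),
             permutation_importance = as.numeric(drops),
             stringsAsFactors = FALSE)
}

#' Univariate response curve of one predictor
#'
#' Fits a default-settings model on the single variable and evaluates
#' the logistic output on an even grid spanning the training bounds
#' (clamped beyond them).
#'
#' @param samples a \code{sample_table}.
#' @param variable variable name.
#' @param config a \code{run_config}.
#' @param n_points curve resolution (default 100).
#' @param mode,r settings of the univariate fit (defaults: auto, 1).
#' @return data.frame of class \code{response_curve} with columns
#'   \code{x} and \code{logistic}.
#' @export
response_curve <- function(samples, variable, config = run_config(),
                           n_points = 100, mode = "auto", r = 1) {
  m <- maxent(samples, variables = variable, mode = mode, r = r,
              max_iter = config$max_iterations, tol = config$tol,
              n_hinge_knots = config$n_hinge_knots)
  b <- m$featurizer$bounds[[variable]]
  x <- seq(b[1], b[2], length.out = n_points)
  nd <- stats::setNames(data.frame(x), variable)
  out <- data.frame(x = x, logistic = predict(m, nd))
  attr(out, "variable") <- variable
  class(out) <- c("response_curve", "data.frame")
  out
}

#' @export
plot.response_curve <- function(x, ...) {
  graphics::plot(x$x, x$logistic, type = "l",
                 xlab = attr(x, "variable"), ylab = "logistic output",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Compare the pooled-extent model with per-region models
#'
#' Fits the default-settings model with cross-validation on the whole
#' extent and on each labelled region; regions with fewer presences
#' than folds are skipped with a warning.
#'
#' @param samples a \code{sample_table} whose presence rows carry a
#'   \code{group} (region) column.
#' @param variables variables to fit.
#' @param config a \code{run_config}.
#' @return data.frame with \code{region}, \code{n_presence},
#'   \code{mean_test_auc} (whole extent first).
#' @export
compare_extent_models <- function(samples, variables,
                                  config = run_config()) {
  pres <- samples[samples$presence == 1, , drop = FALSE]
  if (is.null(pres$group)) stop("presence rows must carry a region label")
  bg <- samples[samples$presence == 0, , drop = FALSE]
  regions <- unique(pres$group)
  run_one <- function(sub, label) {
    if (sum(sub$presence == 1) < config$cv_folds) {
      warning("region skipped (fewer presences than folds): ", label)
      return(NULL)
    }
    folds <- make_cv_folds(sub, k = config$cv_folds, seed = config$seed)
    data.frame(region = label, n_presence = sum(sub$presence == 1),
               mean_test_auc = as.numeric(
                 cv_mean_auc(sub, folds, variables, config = config)),
               stringsAsFactors = FALSE)
  }
  out <- list(run_one(rbind(pres, bg), "whole_extent"))
  for (rg in regions)
    out <- c(out, list(run_one(rbind(pres[pres$group == rg, , drop = FALSE],
                                     bg), rg)))
  do.call(rbind, out)
}
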