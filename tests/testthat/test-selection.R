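test_that("correlation grouping equals brute-force transitive closure", {
  set.seed(41)
  n <- 300
  base <- rnorm(n)
  pres <- data.frame(a = base[1:30])
  # a ~ b strongly, c independent, d constant
  df <- data.frame(a = base, b = base + rnorm(n, 0, 0.1), c = rnorm(n),
                   d = 1)
  samples <- mini_samples(df[1:30, ], df[31:n, ])
  expect_warning(gr <- group_correlated(samples, 0.7,
                                        c("a", "b", "c", "d")),
                 "constant")
  expect_true(any(vapply(gr, function(g) setequal(g, c("a", "b")),
                         TRUE)))
  expect_true(list("c") %in% lapply(gr, as.list) ||
                any(vapply(gr, identical, TRUE, y = "c")))
  # duplicated column forms one group of two
  s2 <- mini_samples(data.frame(u = rnorm(20), v = 0),
                     data.frame(u = rnorm(50), v = 0))
  s2$v <- s2$u
  gr2 <- group_correlated(s2, 0.7, c("u", "v"))
  expect_equal(sort(lengths(gr2), decreasing = TRUE)[1], 2)
  # |r| exactly at the threshold is NOT an edge (strict inequality)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)  # r = 0.8; rescale to hit 0.7
  # construct exact r = 0.7 via rotation instead: use threshold = |r|
  s3 <- mini_samples(data.frame(p = x[1:2], q = y[1:2]),
                     data.frame(p = x[3:4], q = y[3:4]))
  r_pq <- abs(cor(s3$p, s3$q))
  gr3 <- group_correlated(s3, threshold = r_pq, c("p", "q"))
  expect_equal(lengths(gr3), c(1, 1))
  # brute-force transitive closure oracle on random correlation structures
  set.seed(43)
  for (rep in 1:5) {
    k <- sample(4:8, 1)
    X <- matrix(rnorm(120 * k), 120, k)
    # duplicate-ish columns force edges
    for (j in sample(k, 2)) X[, j] <- X[, 1] + rnorm(120, 0, 0.05)
    colnames(X) <- letters[1:k]
    sm <- mini_samples(as.data.frame(X[1:20, , drop = FALSE]),
                       as.data.frame(X[21:120, , drop = FALSE]))
    gr <- group_correlated(sm, 0.7, letters[1:k])
    # oracle: warshall closure of the |r| > 0.7 adjacency
    A <- abs(cor(X)) > 0.7; diag(A) <- TRUE
    for (m in 1:k) A <- A | (A[, m] %o% A[m, ])
    oracle <- unique(apply(A, 1, function(row) paste(sort(colnames(X)[row]),
                                                     collapse = ",")))
    got <- sort(vapply(gr, function(g) paste(sort(g), collapse = ","),
                       ""))
    expect_setequal(got, sort(oracle))
  }
})

test_that("univariate selection passes singletons and picks the signal variable", {
  set.seed(47)
  # presences concentrated at high u; v is pure noise but correlated set
  u <- rnorm(400)
  pres_u <- rnorm(40, 2)
  samples <- mini_samples(data.frame(u = pres_u, v = rnorm(40)),
                          data.frame(u = u, v = rnorm(400)))
  folds <- make_cv_folds(40, 10, seed = 3)
  out <- univariate_select(list(c("u", "v")), samples, folds,
                           run_config(n_hinge_knots = 8))
  expect_equal(out$selected, "u")
  out1 <- univariate_select(list("v"), samples, folds, run_config())
  expect_equal(out1$selected, "v")
  expect_equal(nrow(out1$auc_table), 0)
})

test_that("jackknife removes a pure-noise variable and stops correctly", {
  set.seed(53)
  samples <- mini_samples(
    data.frame(sig = rnorm(40, 2), noise = runif(40)),
    data.frame(sig = rnorm(400), noise = runif(400)))
  folds <- make_cv_folds(40, 10, seed = 5)
  tr <- stepwise_jackknife(c("sig", "noise"), samples, folds,
                           run_config(n_hinge_knots = 8))
  expect_true("sig" %in% tr$retained)
  expect_gte(tr$retained_auc, tr$full_auc - 1e-12)
  # single variable: empty trace, variable retained
  tr1 <- stepwise_jackknife("sig", samples, folds, run_config())
  expect_equal(tr1$retained, "sig")
  expect_equal(nrow(tr1$trace), 0)
})

test_that("AICc follows the hand formula and flags the undefined case", {
  expect_equal(aicc_value(K = 3, LL = -10, n = 20), 27.5)
  expect_true(is.na(aicc_value(K = 19, LL = -10, n = 20)))
  # grid-standardized raw sums to one and yields a finite AICc
  truth <- small_truth()
  th <- thin_occurrences(truth$presences, 1000, seed = 2)
  g <- truth$suitability$grid
  bg <- sample_background(grid_raster(matrix(1, g$n_rows, g$n_cols), g),
                          400, seed = 3)
  sm <- focal_smooth_stack(truth$stack, 450)
  samples <- build_samples(sm, th$kept, bg)
  m <- maxent(samples, variables = c("elevation", "slope"), mode = "lqp")
  raw <- predict(m, sm, type = "raw")
  std <- raw$values / sum(raw$values, na.rm = TRUE)
  expect_equal(sum(std, na.rm = TRUE), 1, tolerance = 1e-9)
  a <- compute_aicc(m, samples[samples$presence == 1, ], sm)
  expect_true(a$valid)
  expect_equal(a$AICc, aicc_value(a$K, a$LL, sum(samples$presence)))
})

test_that("the tuning table covers all combinations with the documented tie-breaks", {
  truth <- small_truth()
  th <- thin_occurrences(truth$presences, 1000, seed = 2)
  g <- truth$suitability$grid
  bg <- sample_background(grid_raster(matrix(1, g$n_rows, g$n_cols), g),
                          400, seed = 3)
  sm <- focal_smooth_stack(truth$stack, 450)
  samples <- build_samples(sm, th$kept, bg)
  cfg <- run_config(n_hinge_knots = 8)
  tr <- suppressWarnings(tune_hyperparameters(samples, sm,
    c("elevation", "slope"), cfg))
  expect_equal(nrow(tr$table), 18)
  expect_equal(tr$winner$AICc, min(tr$table$AICc[tr$table$valid]))
  # K decreases (weakly) along the multiplier path within a mode
  for (md in c("lqp", "hinge", "auto")) {
    sub <- tr$table[tr$table$mode == md, ]
    sub <- sub[order(sub$r), ]
    expect_true(all(diff(sub$K) <= 0))
  }
})

test_that("importance is 100 for a single variable and favours the signal", {
  set.seed(59)
  samples <- mini_samples(
    data.frame(sig = rnorm(40, 2), noise = runif(40)),
    data.frame(sig = rnorm(400), noise = runif(400)))
  m1 <- maxent(samples, variables = "sig", mode = "lqp")
  imp1 <- variable_importance(m1, samples)
  expect_equal(imp1$percent_contribution, 100)
  expect_equal(imp1$permutation_importance, 100)
  m2 <- maxent(samples, variables = c("sig", "noise"), mode = "lqp")
  imp2 <- variable_importance(m2, samples, seed = 2)
  expect_equal(sum(imp2$percent_contribution), 100, tolerance = 0.1)
  expect_equal(sum(imp2$permutation_importance), 100, tolerance = 0.1)
  expect_gt(imp2$permutation_importance[imp2$variable == "sig"],
            imp2$permutation_importance[imp2$variable == "noise"])
})

test_that("response curves have the requested length and clamp outside bounds", {
  set.seed(61)
  samples <- mini_samples(data.frame(v = rnorm(30, 1)),
                          data.frame(v = rnorm(300)))
  rc <- response_curve(samples, "v", n_points = 77)
  expect_equal(nrow(rc), 77)
  expect_true(all(rc$logistic > 0 & rc$logistic < 1))
  # a linear-only univariate model yields a monotone curve
  fmspec <- feature_spec("lqp", "v")
  ftz <- make_featurizer(samples, fmspec)
  keep <- ftz$meta$type == "linear"
  sub <- function(rows) structure(list(
    F = featurize(ftz, samples[rows, ])[, keep, drop = FALSE],
    meta = ftz$meta[keep, ], featurizer = ftz), class = "feature_matrix")
  m <- fit_maxent(sub(samples$presence == 1), sub(samples$presence == 0))
  xs <- seq(min(samples$v), max(samples$v), length.out = 50)
  sc <- growrisk:::maxent_transform(
    featurize(m$featurizer, data.frame(v = xs))[, keep, drop = FALSE] %*%
      m$lambdas, m, "logistic")
  expect_true(all(diff(sc) >= -1e-12) || all(diff(sc) <= 1e-12))
})

test_that("extent comparison reports pooled plus per-region rows and skips small regions", {
  set.seed(67)
  pres <- data.frame(v = rnorm(30, 1.5))
  bg <- data.frame(v = rnorm(200))
  samples <- mini_samples(pres, bg)
  samples$group <- NA_character_
  samples$group[samples$presence == 1] <- rep(c("north", "south"),
                                              c(27, 3))
  cfg <- run_config(cv_folds = 5, n_hinge_knots = 8, seed = 2)
  expect_warning(tab <- compare_extent_models(samples, "v", cfg),
                 "skipped")
  expect_equal(tab$region, c("whole_extent", "north"))
  expect_equal(tab$n_presence, c(30, 27))
})
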