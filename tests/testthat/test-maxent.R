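test_that("feature expansion produces scaled linear, quadratic and hinge features", {
  pres <- data.frame(v = c(0.5, 0.7))
  bg <- data.frame(v = seq(0, 1, length.out = 50))
  samples <- mini_samples(pres, bg)
  fm <- expand_features(samples, feature_spec("lqp", "v"))
  i <- which(samples$v == 0.5)[1]
  expect_equal(unname(fm$F[i, "v"]), 0.5)
  expect_equal(unname(fm$F[i, "v^2"]), 0.25)
  expect_true(all(fm$F >= 0 & fm$F <= 1))
  # forward hinge value by hand: knot 0.4, max 1 -> (0.7-0.4)/0.6
  ftz <- structure(list(bounds = list(v = c(0, 1)), knots = list(v = 0.4),
                        meta = data.frame(name = "h", type = "hinge_fwd",
                                          var1 = "v", var2 = NA,
                                          knot = 0.4),
                        spec = feature_spec("hinge", "v")),
                   class = "featurizer")
  expect_equal(unname(featurize(ftz, data.frame(v = 0.7))[1, 1]), 0.5)
  # constant variable excluded with a warning
  s2 <- mini_samples(data.frame(v = c(1, 1), w = c(0, 2)),
                     data.frame(v = rep(1, 20), w = runif(20)))
  expect_warning(fm2 <- expand_features(s2, feature_spec("lqp", c("v", "w"))),
                 "constant")
  expect_false(any(grepl("^v", colnames(fm2$F))))
})

test_that("one-feature fit matches the grid-search oracle (lambda = ln 9 at beta 0.1)", {
  fms <- binary_feature_fm()
  m <- fit_maxent(fms$presence, fms$background, betas = 0.1, tol = 1e-9,
                  max_iter = 2000)
  # independent oracle: dense grid search of the penalized objective
  obj <- function(l) -l + log(mean(exp(fms$background$F %*% l))) + 0.1 * abs(l)
  grid <- seq(0, 5, by = 1e-4)
  l_star <- grid[which.min(vapply(grid, obj, numeric(1)))]
  expect_equal(unname(m$lambdas), l_star, tolerance = 1e-3)
  expect_equal(unname(m$lambdas), log(9), tolerance = 1e-5)
})

test_that("total shrinkage drives all weights to zero and the model to uniform", {
  fms <- binary_feature_fm()
  m <- fit_maxent(fms$presence, fms$background, betas = 1e6)
  expect_true(all(m$lambdas == 0))
  raw <- growrisk:::maxent_transform(
    drop(fms$background$F %*% m$lambdas), m, "raw")
  expect_same_values(raw, 1 / 100, tol = 1e-12)
  logi <- growrisk:::maxent_transform(
    drop(fms$background$F %*% m$lambdas), m, "logistic")
  expect_same_values(logi, 0.5, tol = 1e-12)
})

test_that("every fit satisfies raw normalization and the KKT box constraint", {
  set.seed(13)
  for (rep in 1:4) {
    n <- 40
    pres <- data.frame(u = rnorm(n, 1), v = runif(n))
    bg <- data.frame(u = rnorm(200), v = runif(200))
    samples <- mini_samples(pres, bg)
    mode <- c("lqp", "auto", "hinge", "lqp")[rep]
    m <- maxent(samples, mode = mode, r = c(0.5, 1, 2, 5)[rep],
                n_hinge_knots = 10, max_iter = 20000)
    expect_true(m$converged)
    # raw normalization over the fitting background (which includes the
    # presence samples, as in the classic tool)
    F <- featurize(m$featurizer,
                   samples[order(samples$presence), ])
    raw <- growrisk:::maxent_transform(drop(F %*% m$lambdas), m, "raw")
    expect_equal(sum(raw), 1, tolerance = 1e-9)
    # KKT: |E_q[f_j] - mean_presence f_j| <= beta_j for all features
    expect_true(all(abs(m$bg_expectations - m$presence_means) <=
                      m$betas + 2e-5))
    expect_gte(m$entropy, 0)
  }
})

test_that("objective is maximized: fitted solution beats random probes", {
  set.seed(17)
  pres <- data.frame(u = rnorm(30, 1))
  bg <- data.frame(u = rnorm(150))
  samples <- mini_samples(pres, bg)
  m <- maxent(samples, mode = "lqp", max_iter = 20000)
  # the fitting background includes the presence samples
  Fb <- featurize(m$featurizer, samples[order(samples$presence), ])
  Fp <- featurize(m$featurizer, samples[samples$presence == 1, ])
  pen_obj <- function(l)
    mean(Fp %*% l) - log(mean(exp(Fb %*% l))) - sum(m$betas * abs(l))
  at_fit <- pen_obj(m$lambdas)
  for (k in 1:50)
    expect_gte(at_fit, pen_obj(m$lambdas + rnorm(length(m$lambdas), 0, 0.3)))
})

test_that("parameter recovery: linear-feature Gibbs truth is recovered within the beta box", {
  # truth: q(x) propto exp(l1*f1 + l2*f2) over a discrete background
  set.seed(23)
  l_true <- c(2, -1)
  for (m_pres in c(100, 500)) {
    bgX <- cbind(f1 = runif(2000), f2 = runif(2000))
    wts <- exp(bgX %*% l_true)
    pres_idx <- sample(nrow(bgX), m_pres, replace = TRUE,
                       prob = wts / sum(wts))
    samples <- mini_samples(as.data.frame(bgX[pres_idx, ]),
                            as.data.frame(bgX))
    fm <- expand_features(samples, feature_spec("lqp", c("f1", "f2")))
    keep <- fm$meta$type == "linear"
    sub <- function(rows) structure(
      list(F = fm$F[rows, keep, drop = FALSE], meta = fm$meta[keep, ],
           featurizer = fm$featurizer), class = "feature_matrix")
    fit <- fit_maxent(sub(samples$presence == 1), sub(samples$presence == 0))
    # features were scaled to [0,1] from data bounds; rescale weights back
    b <- fm$featurizer$bounds
    l_hat <- unname(fit$lambdas / c(diff(b$f1), diff(b$f2)))
    # sampling noise plus the L1 bias bound: tolerance grows with beta
    tol <- 0.5 + 10 * max(fit$betas)
    expect_lt(max(abs(l_hat - l_true)), tol)
  }
})

test_that("AUC equals the brute-force pairwise count, ties at one half", {
  expect_equal(compute_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_equal(compute_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(compute_auc(rep(1, 5), rep(1, 7)), 0.5)
  set.seed(29)
  for (rep in 1:10) {
    p <- sample(0:10, sample(3:50, 1), replace = TRUE)
    b <- sample(0:10, sample(3:50, 1), replace = TRUE)
    brute <- mean(outer(p, b, function(a, d) (a > d) + 0.5 * (a == d)))
    expect_equal(compute_auc(p, b), brute)
  }
})

test_that("omission thresholds behave at the 10th percentile", {
  tr <- seq(0.01, 1, length.out = 50)
  expect_equal(omission_rate(tr, tr), 0.10)          # n divisible by 10
  expect_equal(omission_rate(tr, rep(1, 5)), 0)
  expect_equal(omission_rate(tr, rep(0, 5)), 1)
  expect_error(omission_rate(tr[1:5], tr), "at least 10")
})

test_that("prediction clamps beyond training bounds and stacks round trip", {
  set.seed(37)
  pres <- data.frame(v = runif(30, 0.4, 0.9))
  bg <- data.frame(v = runif(100))
  samples <- mini_samples(pres, bg)
  m <- maxent(samples, mode = "lqp")
  hi <- predict(m, data.frame(v = c(1, 5, 100)))
  expect_true(all(hi == hi[1]))                       # clamped flat
  # model JSON round trip preserves predictions
  path <- tempfile(fileext = ".json")
  write_maxent(m, path)
  m2 <- read_maxent(path)
  nd <- data.frame(v = seq(0, 1, 0.05))
  expect_equal(predict(m2, nd), predict(m, nd), tolerance = 1e-12)
})

test_that("simulate draws points concentrated where the model is high", {
  truth <- small_truth()
  sm <- focal_smooth_stack(truth$stack, 450)
  th <- thin_occurrences(truth$presences, 1000, seed = 2)
  bg <- sample_background(truth$habitat$grid |> (\(g)
    grid_raster(matrix(1, g$n_rows, g$n_cols), g))(), 500, seed = 3)
  samples <- build_samples(sm, th$kept, bg)
  m <- maxent(samples, variables = c("elevation", "slope"), mode = "lqp")
  pts <- simulate(m, nsim = 200, seed = 4, stack = sm)
  expect_equal(nrow(pts), 200)
  sc <- predict(m, sm)
  expect_gt(mean(raster_values_at(sc, pts$x, pts$y)),
            mean(sc$values, na.rm = TRUE))
})
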