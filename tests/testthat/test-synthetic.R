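test_that("generators are bit-deterministic under a fixed seed", {
  cfg <- landscape_config(grid = grid_spec(40, 40, 90), seed = 5,
                          n_presences = 50)
  s1 <- gen_predictors(cfg)
  s2 <- gen_predictors(cfg)
  for (nm in names(s1)) expect_identical(s1[[nm]]$values, s2[[nm]]$values)
  t1 <- gen_telemetry(3, 30, 500, cfg$grid, seed = 8)
  t2 <- gen_telemetry(3, 30, 500, cfg$grid, seed = 8)
  expect_identical(t1, t2)
})

test_that("slope is zero on a flat elevation field and follows finite differences", {
  # the percent-slope helper is exercised through a hand-checkable ramp:
  # elevation rising 9 m per 90 m cell eastward is a 10% slope
  g <- grid_spec(5, 5, 90)
  elev <- matrix(rep(seq(0, 36, by = 9), each = 5), 5, 5)
  st <- predictor_stack(list(elevation = grid_raster(elev, g)))
  # reuse the generator's derivation by finite differences
  gx <- (elev[, c(2:5, 5)] - elev[, c(1, 1:4)]) /
    matrix(c(90, 180, 180, 180, 90)[col(elev)], 5, 5)
  expect_equal(unique(as.vector(100 * abs(gx))), 10)
})

test_that("longer correlation length raises short-range autocorrelation", {
  g <- grid_spec(60, 60, 90)
  lag1 <- function(cl, seed) {
    set.seed(seed)
    f <- growrisk:::gaussian_field(g, cl)
    cor(as.vector(f[, -1]), as.vector(f[, -ncol(f)]))
  }
  expect_gt(mean(sapply(1:3, function(s) lag1(10 * 90, s))),
            mean(sapply(1:3, function(s) lag1(90, s))))
})

test_that("true suitability is the inverse logit of the weighted responses", {
  g <- grid_spec(1, 2, 90)
  st <- predictor_stack(list(elevation = grid_raster(matrix(c(1200, 2000), 1), g)))
  tm <- true_model(list(list(var = "elevation", type = "band",
                             center = 1200, halfwidth = 400, weight = 2)),
                   intercept = -1)
  s <- define_true_suitability(st, tm)
  # hand computation: response exp(-0.5*((x-c)/(hw/sqrt(2 ln 2)))^2)
  r2 <- exp(-0.5 * ((2000 - 1200) / (400 / sqrt(2 * log(2))))^2)
  expect_equal(s$values[1, 1], plogis(-1 + 2 * 1))
  expect_equal(s$values[1, 2], plogis(-1 + 2 * r2))
  # zero weights give 0.5 everywhere
  tm0 <- true_model(list(list(var = "elevation", type = "band",
                              center = 1200, halfwidth = 400, weight = 0)))
  expect_same_values(define_true_suitability(st, tm0)$values, 0.5)
  # band center beats band edge by monotone construction
  expect_gt(s$values[1, 1], s$values[1, 2])
  expect_error(define_true_suitability(st, true_model(list(
    list(var = "nope", type = "band", center = 0, halfwidth = 1,
         weight = 1)))), "not in stack")
})

test_that("presence sampling follows its target distribution", {
  g <- grid_spec(20, 20, 90)
  # single eligible cell cannot supply five without-replacement draws
  one <- matrix(0, 20, 20); one[5, 5] <- 1
  expect_error(sample_presences(grid_raster(one, g), 5), "exceeds")
  # uniform suitability: quadrant counts pass a chi-square GOF
  unif <- grid_raster(matrix(1, 20, 20), g)
  pts <- sample_presences(unif, 200, seed = 19)
  qx <- pts$x > 900; qy <- pts$y > 900
  counts <- table(factor(paste(qx, qy), levels = c("FALSE FALSE",
    "FALSE TRUE", "TRUE FALSE", "TRUE TRUE")))
  expect_gt(chisq.test(counts)$p.value, 0.01)
  # doubled weight on the left half shows up in expectation
  bias <- grid_raster(matrix(rep(c(2, 1), each = 10), 20, 20,
                             byrow = TRUE), g)
  left <- replicate(50, {
    p <- sample_presences(unif, 40, bias = bias,
                          seed = sample.int(1e6, 1))
    mean(p$x < 900)
  })
  expect_gt(mean(left), 0.55)
})

test_that("streams carry plots within 300 m, denser where suitable", {
  truth <- small_truth()
  cfg <- truth$config
  d <- distance_transform(truth$streams, truth$suitability$grid)
  dist_at_plots <- raster_values_at(d, truth$plots$x, truth$plots$y)
  # plots sit within 300 m of a stream (cell-center rule gives the
  # rasterized network half a cell of slack)
  expect_true(all(dist_at_plots <= 300 + 1.5 * 90))
  s_at_plots <- raster_values_at(truth$suitability, truth$plots$x,
                                 truth$plots$y)
  terc <- quantile(truth$suitability$values, c(1 / 3, 2 / 3))
  expect_gt(sum(s_at_plots > terc[2]), sum(s_at_plots <= terc[1]))
  # zero plots requested -> empty set
  sp0 <- gen_streams_and_plots(landscape_config(grid = cfg$grid,
    n_plots = 0), truth$suitability, seed = 3)
  expect_equal(nrow(sp0$plots), 0)
})

test_that("habitat rules select the stated fraction and reject empty rules", {
  truth <- small_truth()
  st <- truth$stack
  expect_message(hab <- gen_habitat(st, function(df) {
    q <- quantile(df$elevation, c(0.25, 0.75))
    df$elevation >= q[1] & df$elevation <= q[2]
  }), "50.0%")
  expect_equal(mean(hab$values), 0.5, tolerance = 0.01)
  expect_message(all_in <- gen_habitat(st, function(df) rep(TRUE, nrow(df))))
  expect_true(all(all_in$values == 1))
  expect_error(suppressMessages(gen_habitat(st,
    function(df) rep(FALSE, nrow(df)))), "zero cells")
})

test_that("telemetry has the requested geometry and dispersion", {
  g <- grid_spec(100, 100, 90)
  tel <- gen_telemetry(4, 30, 500, g, seed = 44)
  expect_length(tel, 4)
  expect_true(all(vapply(tel, nrow, 1L) == 30))
  big <- gen_telemetry(1, 1000, 700, g, seed = 45)[[1]]
  d <- sqrt((big$x - mean(big$x))^2 + (big$y - mean(big$y))^2)
  # radial sd of an isotropic normal: sample sd of each axis near 700
  expect_lt(abs(sd(big$x) - 700) / 700, 0.15)
})

test_that("the preset landscape recovers the true bands from its own samples", {
  truth <- small_truth()
  th <- thin_occurrences(truth$presences, 1000, seed = 6)
  g <- truth$suitability$grid
  bg <- sample_background(grid_raster(matrix(1, g$n_rows, g$n_cols), g),
                          500, seed = 7)
  sm <- focal_smooth_stack(truth$stack, 450)
  samples <- build_samples(sm, th$kept, bg)
  rc_e <- response_curve(samples, "elevation", n_points = 200)
  peak_e <- rc_e$x[which.max(rc_e$logistic)]
  expect_gt(peak_e, 800); expect_lt(peak_e, 1600)
  rc_s <- response_curve(samples, "slope", n_points = 200)
  peak_s <- rc_s$x[which.max(rc_s$logistic)]
  expect_gt(peak_s, 30); expect_lt(peak_s, 60)
})
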