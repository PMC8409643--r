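test_that("survey stream selection accumulates same-named reaches to the target", {
  mk_reach <- function(x0, y0, len = 1000)
    cbind(c(x0, x0 + len), c(y0, y0))
  net <- line_set(lapply(1:10, function(i) mk_reach(0, i * 100)),
                  id = paste0("r", 1:10),
                  name = paste0("s", rep(1:10, 1)),
                  unit = rep("u1", 10))
  plan <- select_survey_streams(net, target_fraction = 0.25, seed = 2)
  expect_gte(length(plan$reach_ids), 3)
  expect_gte(plan$selected_km, 0.25 * plan$total_km)
  # same-named reaches in a unit come as a bundle
  net2 <- line_set(list(mk_reach(0, 0), mk_reach(0, 100), mk_reach(0, 200)),
                   id = c("a", "b", "c"), name = c("n1", "n1", "n2"),
                   unit = c("u1", "u1", "u1"))
  plan2 <- select_survey_streams(net2, target_fraction = 0.5, seed = 1)
  if ("a" %in% plan2$reach_ids) expect_true("b" %in% plan2$reach_ids)
  # single reach network; zero target
  one <- line_set(list(mk_reach(0, 0)))
  expect_equal(select_survey_streams(one, 0.01)$selected_km,
               select_survey_streams(one, 0.01)$total_km)
  expect_length(select_survey_streams(net, 0)$reach_ids, 0)
})

test_that("reach kilometres are apportioned exactly across traversed classes", {
  cls <- matrix(0, 4, 4); cls[, 3:4] <- 2   # east half high, 90 m cells
  rm <- manual_riskmap(cls)
  # reach crossing the class boundary at x = 180 symmetric: 50/50 split
  reach <- line_set(list(cbind(c(90, 270), c(200, 200))))
  plots <- point_set(c(100, 250), c(200, 200))
  out <- classify_survey(plots, reach, rm)
  expect_equal(unname(out$km_by_class["low"]), 0.09)
  expect_equal(unname(out$km_by_class["high"]), 0.09)
  expect_equal(unname(out$plot_classes), c("low", "high"))
  # reach entirely in high
  r2 <- line_set(list(cbind(c(200, 340), c(100, 300))))
  out2 <- classify_survey(point_set(200, 100), r2, rm)
  expect_equal(unname(out2$km_by_class["high"]),
               sqrt(140^2 + 200^2) / 1000)
  expect_equal(sum(out2$km_by_class[c("low", "moderate")]), 0)
  # off-grid plot errors
  expect_error(classify_survey(point_set(1e5, 1e5), reach, rm), "off")
})

test_that("chi-square matches the hand oracle and conserves totals", {
  out <- list(observed = c(low = 9, moderate = 3, high = 2),
              km_by_class = c(low = 10, moderate = 10, high = 80))
  # spec orientation: km (10,10,80) with observed (9,3,2)
  res <- chisq_survey(out)
  expect_equal(sum(res$expected), sum(res$observed), tolerance = 1e-9)
  expect_equal(unname(res$expected), c(1.4, 1.4, 11.2))
  expect_equal(res$statistic, (9 - 1.4)^2 / 1.4 + (3 - 1.4)^2 / 1.4 +
                 (2 - 11.2)^2 / 11.2, tolerance = 1e-12)
  expect_equal(res$statistic, 50.64, tolerance = 0.005)
  expect_equal(res$df, 2)
  # cross-check p-value with the stats implementation
  ref <- suppressWarnings(chisq.test(c(9, 3, 2), p = c(0.1, 0.1, 0.8)))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  # proportional observations give statistic zero
  prop <- list(observed = c(low = 1, moderate = 1, high = 8),
               km_by_class = c(low = 10, moderate = 10, high = 80))
  expect_equal(chisq_survey(prop)$statistic, 0)
  expect_error(chisq_survey(list(observed = c(low = 0, moderate = 0,
                                              high = 0),
                                 km_by_class = c(low = 1, moderate = 1,
                                                 high = 1))), "zero plots")
  expect_error(chisq_survey(list(observed = c(low = 1, moderate = 0,
                                              high = 0),
                                 km_by_class = c(low = 0, moderate = 1,
                                                 high = 1))), "zero surveyed")
})

test_that("class percentages reproduce integer reporting", {
  cls <- matrix(rep(0:2, times = c(4, 4, 4)), 3, 4)
  g <- grid_spec(3, 4, 90)
  rm <- manual_riskmap(cls, g)
  cc <- cell_centers(g)
  # place counts (34, 26, 32) into low/moderate/high cells
  pick <- function(k, n) {
    idx <- which(rm$raster$values == k, arr.ind = TRUE)
    i <- idx[rep(seq_len(nrow(idx)), length.out = n), , drop = FALSE]
    cbind(cc$x[i[, 2]], cc$y[i[, 1]]) + runif(2 * n, -20, 20)
  }
  xy <- rbind(pick(0, 32), pick(1, 26), pick(2, 34))
  pts <- point_set(xy[, 1], xy[, 2])
  tab <- class_percentages(pts, rm)
  expect_equal(tab$count, c(32, 26, 34))
  expect_equal(tab$percent_rounded, c(35, 28, 37))
  # all in one class
  p1 <- point_set(rep(cc$x[1], 3), rep(cc$y[1], 3) + c(0, 1, 2))
  t1 <- class_percentages(p1, rm)
  expect_equal(t1$percent[t1$class == "low"], 100)
})

test_that("distances to the nearest high cell follow grid geometry", {
  cls <- matrix(0, 5, 5); cls[3, 3] <- 2
  rm <- manual_riskmap(cls)
  cc <- cell_centers(rm$raster$grid)
  inside <- point_set(cc$x[3], cc$y[3])
  d0 <- distance_to_class(inside, rm)
  expect_equal(d0$distances, 0)
  neigh <- point_set(cc$x[4], cc$y[3])
  expect_equal(distance_to_class(neigh, rm)$distances, 90)
  expect_error(distance_to_class(neigh, manual_riskmap(matrix(0, 2, 2))),
               "target class")
})

test_that("plots planted proportional to suitability concentrate in surveyed mod-high", {
  truth <- small_truth()
  suit <- truth$suitability
  rm <- classify_risk(suit, overrides = list(
    t_low_mod = unname(quantile(suit$values, 0.70)),
    t_mod_high = unname(quantile(suit$values, 0.90))))
  wins <- 0L
  for (rep in 1:20) {
    sp <- gen_streams_and_plots(truth$config, suit, seed = 100 + rep,
                                streams = truth$streams)
    out <- classify_survey(sp$plots, sp$streams, rm)
    km_share <- sum(out$km_by_class[c("moderate", "high")]) /
      sum(out$km_by_class)
    plot_share <- mean(out$plot_classes %in% c("moderate", "high"))
    wins <- wins + (plot_share > km_share)
  }
  expect_gte(wins, 15)
})
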