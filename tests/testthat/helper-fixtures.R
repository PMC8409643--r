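# Shared fixtures: everything is generated in code at test time.

# small grid with origin at (0, 0)
mini_grid <- function(nr = 10, nc = 10, cs = 90) grid_spec(nr, nc, cs)

# deterministic raster with an arbitrary smooth-ish pattern
mini_raster <- function(nr = 10, nc = 10, cs = 90) {
  g <- mini_grid(nr, nc, cs)
  v <- outer(seq_len(nr), seq_len(nc), function(i, j) sin(i / 2) + cos(j / 3))
  grid_raster(v, g)
}

# tiny presence/background sample table from explicit predictor values
mini_samples <- function(pres, bg) {
  stopifnot(is.data.frame(pres), is.data.frame(bg),
            identical(names(pres), names(bg)))
  out <- rbind(cbind(pres, presence = 1L), cbind(bg, presence = 0L))
  out$x <- seq_len(nrow(out)); out$y <- seq_len(nrow(out))
  out$id <- paste0("s", seq_len(nrow(out)))
  attr(out, "variables") <- setdiff(names(pres), c("x", "y", "id"))
  class(out) <- c("sample_table", "data.frame")
  out
}

# one-feature feature_matrix pair for analytic solver checks
binary_feature_fm <- function(np = 20, nb = 100) {
  meta <- data.frame(name = "f", type = "linear", var1 = "v",
                     var2 = NA_character_, knot = NA_real_,
                     stringsAsFactors = FALSE)
  ftz <- structure(list(bounds = list(v = c(0, 1)), knots = list(),
                        meta = meta, spec = feature_spec("lqp", "v")),
                   class = "featurizer")
  mk <- function(F) structure(list(F = F, meta = meta, featurizer = ftz),
                              class = "feature_matrix")
  list(presence = mk(matrix(1, np, 1, dimnames = list(NULL, "f"))),
       background = mk(matrix(rep(c(0, 1), each = nb / 2), nb, 1,
                              dimnames = list(NULL, "f"))))
}

# small synthetic study system reused across tests (cached per session)
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synthetic_landscape(landscape_config(
        grid = grid_spec(80, 80, 90), seed = 7, n_presences = 200,
        n_streams = 6, n_plots = 15, n_animals = 3,
        locs_per_animal = 30, telemetry_dispersion = 600))
    cache
  }
})

# a plain risk map built by hand from a class matrix
manual_riskmap <- function(cls, g = NULL, t1 = 0.3, t2 = 0.6) {
  if (is.null(g)) g <- grid_spec(nrow(cls), ncol(cls), 90)
  structure(list(raster = grid_raster(cls, g),
                 thresholds = c(t_low_mod = t1, t_mod_high = t2),
                 boyce_index = NA_real_),
            class = "risk_map")
}

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b), na.rm = TRUE) <= tol)
}
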