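small_stack <- function(seed = 2, nr = 12, nc = 20) {
  set.seed(seed)
  base <- matrix(rep(seq(0, 100, length.out = nc), each = nr), nr, nc)
  list(
    grad  = raster_grid(base + matrix(stats::rnorm(nr * nc, 0, 5), nr, nc),
                        0, 40, 0.1),
    noise = raster_grid(matrix(stats::rnorm(nr * nc, 10, 3), nr, nc),
                        0, 40, 0.1))
}

test_that("grid thinning keeps one point per occupied cell, seeded", {
  tmpl <- raster_grid(matrix(0, 10, 10), 0, 40, 0.1)
  pts <- data.frame(lon = c(0.1, 0.11, 0.12, 0.13, 0.14, 0.7),
                    lat = c(40.1, 40.11, 40.12, 40.13, 40.14, 40.7))
  th <- grid_thin(pts, cell = 0.5, tmpl, seed = 3)
  expect_equal(nrow(th), 2)   # two occupied 0.5-degree cells
  th2 <- grid_thin(pts, cell = 0.5, tmpl, seed = 3)
  expect_identical(th, th2)
  # retained count equals occupied cells for random input
  set.seed(8)
  pts2 <- data.frame(lon = stats::runif(200), lat = 40 + stats::runif(200))
  occ_cells <- length(unique(paste(floor(pts2$lon / 0.5),
                                   floor((pts2$lat - 40) / 0.5))))
  expect_equal(nrow(grid_thin(pts2, 0.5, tmpl, seed = 1)), occ_cells)
  expect_warning(grid_thin(pts2[0, ], 0.5, tmpl), "no occurrence")
})

test_that("uncorrelated-subset selection matches exhaustive enumeration", {
  set.seed(14)
  for (rep in 1:4) {
    k <- 8
    n <- 300
    base <- matrix(stats::rnorm(n * 3), n, 3)
    mix <- matrix(stats::runif(k * 3, -1, 1), 3, k)
    vals <- base %*% mix + 0.4 * matrix(stats::rnorm(n * k), n, k)
    stack <- lapply(seq_len(k), function(j)
      raster_grid(matrix(vals[, j], 15, 20), 0, 40, 0.1))
    names(stack) <- paste0("v", seq_len(k))
    sel <- select_uncorrelated(stack, n_sample = n, r_max = 0.8, seed = 1)
    r <- stats::cor(vals)
    expect_equal(length(sel), oracle_max_subset_size(r, 0.8))
    sub <- abs(r[match(sel, names(stack)), match(sel, names(stack))])
    diag(sub) <- 0
    expect_true(all(sub < 0.8))
  }
})

test_that("selection edge cases: identical layers, constant layers", {
  nr <- 10; nc <- 10
  set.seed(4)
  a <- matrix(stats::rnorm(100), nr, nc)
  stack <- list(a = raster_grid(a, 0, 0, 1),
                b = raster_grid(a, 0, 0, 1),          # identical twin
                c = raster_grid(matrix(stats::rnorm(100), nr, nc), 0, 0, 1),
                k = raster_grid(matrix(1, nr, nc), 0, 0, 1))  # constant
  expect_warning(sel <- select_uncorrelated(stack, n_sample = 100, seed = 1),
                 "constant")
  expect_equal(length(sel), 2)
  expect_false(all(c("a", "b") %in% sel))
})

test_that("feature construction counts, boundaries and shift invariance", {
  set.seed(6)
  vals <- cbind(x = stats::runif(50), y = stats::runif(50))
  spec <- build_features(vals, "HQP", n_knots = 5)
  # 2*(2*5) hinge + 2 quadratic + 1 product + 2 linear = 25
  expect_equal(nrow(spec$table), 25)
  fm <- feature_matrix(spec, vals)
  expect_true(all(fm >= 0 & fm <= 1))
  # value exactly at a knot: both hinge orientations vanish there;
  # the reverse hinge reaches 1 at the variable's minimum
  specx <- build_features(cbind(x = c(0, 1)), "H", n_knots = 1)  # knot 0.5
  hin <- specx$table$class == "hinge"
  fwd <- which(hin & specx$table$orientation == "forward")
  rev_ <- which(hin & specx$table$orientation == "reverse")
  fmx <- feature_matrix(specx, cbind(x = c(0.5, 0, 1)))
  expect_equal(unname(fmx[1, c(fwd, rev_)]), c(0, 0))
  expect_equal(unname(fmx[2, rev_]), 1)
  expect_equal(unname(fmx[3, fwd]), 1)
  # shifting a raw variable leaves the (min-max scaled) features unchanged
  spec2 <- build_features(vals + 100, "HQP", n_knots = 5)
  expect_equal(feature_matrix(spec2, vals + 100), fm)
  expect_warning(build_features(cbind(x = rep(1, 5), y = 1:5), "H", 3),
                 "zero-range")
})

test_that("null maxent model: gain 0, logistic 0.5, raw sums to 1", {
  set.seed(9)
  vals <- cbind(x = stats::runif(40))
  spec <- build_features(vals, "H", n_knots = 3)
  fb <- feature_matrix(spec, vals)
  # presences identical to background mean pattern + huge penalty
  fp <- fb[1:5, , drop = FALSE]
  m <- fit_maxent(fp, fb, spec, beta = c(hinge = 1e6, linear = 1e6),
                  tol = 1e-8)
  expect_equal(unname(m$lambda), rep(0, length(m$lambda)))
  expect_equal(m$gain, 0)
  expect_equal(logistic_from_eta(m, rep(0, 40)), rep(0.5, 40))
  raw <- exp(m$eta_bg - m$log_zsum)
  expect_equal(sum(raw), 1, tolerance = 1e-9)
})

test_that("1-D binary feature matches the closed-form mean constraint", {
  # single binary feature splitting the background in half; with beta=0
  # the fitted lambda solves  p1 = mean presence feature, where
  # p1 = e^l / (e^l + 1) over the two background halves
  f <- c(rep(1, 50), rep(0, 50))
  spec <- list(class_set = "H", n_knots = 0, vars = "b", categorical = "b",
               min = c(b = 0), max = c(b = 1),
               table = data.frame(var = "b", class = "categorical",
                                  knot = NA, orientation = NA,
                                  feature = "f1"))
  class(spec) <- "chequer_features"
  fb <- matrix(f, ncol = 1, dimnames = list(NULL, "f1"))
  fp <- matrix(c(1, 1, 1, 1, 0), ncol = 1, dimnames = list(NULL, "f1"))
  m <- fit_maxent(fp, fb, spec, beta = c(categorical = 0), tol = 1e-10)
  lam <- unname(m$lambda)
  expect_equal(exp(lam) / (exp(lam) + 1), 0.8, tolerance = 1e-6)
  expect_gt(m$gain, 0)
  # logistic output is higher where the feature is 1
  L <- logistic_from_eta(m, c(lam, 0))
  expect_gt(L[1], L[2])
  # raw distribution sums to 1 after the fit
  expect_equal(sum(exp(m$eta_bg - m$log_zsum)), 1, tolerance = 1e-9)
})

test_that("max-SSS threshold matches the exhaustive scan oracle", {
  # separable scores: lowest threshold between the groups
  expect_equal(maxsss_threshold(c(0.9, 0.8), c(0.2, 0.1)), 0.8)
  # degenerate: all scores equal
  expect_equal(maxsss_threshold(c(0.4, 0.4), c(0.4, 0.4)), 0.4)
  # the documented 3v3 example, via the oracle
  p <- c(0.8, 0.7, 0.3); b <- c(0.6, 0.2, 0.1)
  expect_equal(maxsss_threshold(p, b), oracle_maxsss(p, b))
  set.seed(12)
  for (rep in 1:10) {
    p <- round(stats::runif(6), 2)
    b <- round(stats::runif(8), 2)
    expect_equal(maxsss_threshold(p, b), oracle_maxsss(p, b))
  }
})

test_that("AUC closed forms and permutation behaviour", {
  expect_equal(auc_score(c(0.9, 0.8, 0.7, 0.6), c(0.5, 0.4, 0.3, 0.2)), 1)
  expect_equal(auc_score(c(1, 1), c(1, 1)), 0.5)   # full ties
  set.seed(10)
  scores <- stats::runif(2000)
  expect_equal(auc_score(scores[1:1000], scores[1001:2000]), 0.5,
               tolerance = 0.05)
})

test_that("alpha hull: convex limit, disjoint clusters, presence cells", {
  tmpl <- raster_grid(matrix(0, 20, 20), 0, 0, 0.1)
  sq <- data.frame(lon = c(0.3, 1.7, 1.7, 0.3), lat = c(0.3, 0.3, 1.7, 1.7))
  hull <- alpha_hull_layer(sq, alpha = 100, tmpl)
  expect_equal(hull$values[chequer:::raster_cell_index(tmpl, 1, 1)], 1)
  expect_true(all(hull$values %in% c(0, 1)))
  # the cell of every presence point is 1
  expect_true(all(hull$values[chequer:::raster_cell_index(tmpl, sq$lon,
                                                          sq$lat)] == 1))
  # two distant clusters with small alpha: corridor stays 0
  cl <- rbind(data.frame(lon = c(0.15, 0.45, 0.3), lat = c(0.15, 0.15, 0.45)),
              data.frame(lon = c(1.55, 1.85, 1.7), lat = c(1.55, 1.55, 1.85)))
  h2 <- alpha_hull_layer(cl, alpha = 0.5, tmpl)
  expect_equal(h2$values[chequer:::raster_cell_index(tmpl, 1, 1)], 0)
  expect_equal(h2$values[chequer:::raster_cell_index(tmpl, 0.25, 0.25)], 1)
  expect_warning(alpha_hull_layer(sq[1:2, ], 1, tmpl), "fewer than 3")
})

test_that("maxent separates a planted gradient and stays monotone in eta", {
  stack <- small_stack()
  set.seed(5)
  sv <- stack_values(stack)
  # presences where the gradient is high
  p <- stats::plogis((sv$values[, "grad"] - 60) / 10)
  pres <- sv$cells[stats::runif(nrow(sv$cells)) < p * 0.5, ]
  fit <- fit_sdm(pres, stack, class_set = "H", n_knots = 10, seed = 1)
  expect_gt(fit$auc_train, 0.7)
  expect_gt(fit$model$gain, 0)
  # monotonicity of the logistic in eta
  eta <- seq(-3, 3, length.out = 11)
  L <- chequer:::logistic_from_eta(fit$model, eta)
  expect_true(all(diff(L) > 0))
  # prediction raster exists, lies in [0,1] and is non-degenerate
  pr <- predict_logistic(fit$model, stack)
  expect_true(all(pr$values >= 0 & pr$values <= 1))
  expect_gt(max(pr$values) - min(pr$values), 0.1)
  # importance: gradient dominates noise in both views
  imp <- variable_importance(fit)
  expect_equal(sum(imp$contribution), 100, tolerance = 1e-6)
  expect_gt(imp$contribution["grad"], 50)
  expect_gt(imp$jackknife["grad"], imp$jackknife["noise"])
})

test_that("replicated subsampling returns seeded, sane AUCs", {
  stack <- small_stack()
  set.seed(5)
  sv <- stack_values(stack)
  p <- stats::plogis((sv$values[, "grad"] - 60) / 10)
  pres <- sv$cells[stats::runif(nrow(sv$cells)) < p * 0.4, ]
  r1 <- replicate_runs(pres, stack, n_rep = 3, seed = 7, class_set = "H",
                       n_knots = 8)
  r2 <- replicate_runs(pres, stack, n_rep = 3, seed = 7, class_set = "H",
                       n_knots = 8)
  expect_equal(r1$auc, r2$auc)
  expect_true(all(r1$auc > 0.5 & r1$auc <= 1))
})

test_that("H and HQP logistic maps agree on the 1-D threshold world", {
  w <- default_world()
  occ <- simulate_presences(w)
  tmpl <- w$rasters$precip_driest
  occB <- grid_thin(occ$B, 0.5, tmpl, seed = 1)
  oneD <- w$rasters["precip_driest"]
  fitH <- fit_sdm(occB, oneD, class_set = "H", n_knots = 15, seed = 1)
  fitQ <- fit_sdm(occB, oneD, class_set = "HQP", n_knots = 15, seed = 1)
  LH <- predict_logistic(fitH$model, oneD)
  LQ <- predict_logistic(fitQ$model, oneD)
  expect_lt(mean(abs(LH$values - LQ$values), na.rm = TRUE), 0.05)
})

test_that("single-variable response recovers the planted threshold", {
  # pure 1-D threshold world: presences follow the climatic logistic
  # alone (no island masking), wet-adapted species
  w <- default_world()
  occ <- simulate_presences(w, mask_units = FALSE)
  tmpl <- w$rasters$precip_driest
  occA <- grid_thin(occ$A, 0.5, tmpl, seed = 1)
  fit <- fit_sdm(occA, w$rasters["precip_driest"], class_set = "H",
                 n_knots = 15, seed = 1)
  v <- seq(min(fit$background_values), max(fit$background_values),
           length.out = 400)
  L <- predict_maxent(fit$model, cbind(precip_driest = v))
  half <- min(L) + 0.5 * (max(L) - min(L))
  crossing <- v[which(L >= half)[1]]
  # one raster cell spans clim_slope * cellsize = 1 mm of the gradient
  expect_lt(abs(crossing - w$truth$threshold),
            w$cfg$clim_slope * w$cfg$cellsize)
  # and the suitability map is higher above the threshold than below
  pr <- predict_logistic(fit$model, w$rasters["precip_driest"])
  above <- pr$values[w$rasters$precip_driest$values > w$truth$threshold]
  below <- pr$values[w$rasters$precip_driest$values <= w$truth$threshold]
  expect_gt(mean(above, na.rm = TRUE), mean(below, na.rm = TRUE))
})
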