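# Ecological niche modeling around the maxent core: occurrence
# thinning, maximum-uncorrelated variable selection, AUC / threshold /
# importance evaluation, the alpha-hull biotic layer, and the
# cryptic-peer model.

#' Extract aligned values from a raster stack
#'
#' @param stack Named list of \code{chequer_raster} layers on identical
#'   grids.
#' @return List: \code{values} (cells x layers matrix over cells valid
#'   in every layer), \code{cells} (data.frame row, col, lon, lat).
#' @export
stack_values <- function(stack) {
  stopifnot(length(stack) >= 1)
  t0 <- stack[[1]]
  for (r in stack) {
    if (r$nrows != t0$nrows || r$ncols != t0$ncols ||
        abs(r$cellsize - t0$cellsize) > 1e-12)
      stop("raster stack layers are not on the same grid")
  }
  valid <- Reduce(`&`, lapply(stack, function(r) !is.na(r$values)))
  idx <- which(valid, arr.ind = TRUE)
  cc <- raster_cell_centers(t0)
  vals <- vapply(stack, function(r) r$values[idx], numeric(nrow(idx)))
  vals <- matrix(vals, nrow = nrow(idx),
                 dimnames = list(NULL, names(stack)))
  list(values = vals,
       cells = data.frame(row = idx[, 1], col = idx[, 2],
                          lon = cc$lon[idx[, 2]], lat = cc$lat[idx[, 1]]))
}

#' Thin occurrence points on a grid
#'
#' Overlays a grid of \code{cell} degrees anchored at the template
#' origin and keeps exactly one uniformly random point per occupied
#' cell (seeded), removing clustered records due to unbalanced sampling.
#'
#' @param points data.frame with lon, lat.
#' @param cell Thinning cell size in degrees (default 0.5).
#' @param template A \code{chequer_raster} providing the grid origin.
#' @param seed Integer seed.
#' @param report Optional \code{chequer_report}.
#' @return Thinned data.frame (same columns).
#' @export
grid_thin <- function(points, cell = 0.5, template, seed = 1,
                      report = NULL) {
  stopifnot(cell > 0)
  if (nrow(points) == 0) {
    warning("no occurrence points to thin")
    return(points)
  }
  gx <- floor((points$lon - template$xll) / cell)
  gy <- floor((points$lat - template$yll) / cell)
  key <- paste(gx, gy)
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(points)), key), function(ii) {
    if (length(ii) == 1) ii else ii[sample.int(length(ii), 1)]
  }), use.names = FALSE)
  keep <- sort(keep)
  report_log(report, "grid_thin", n_input = nrow(points),
             n_retained = length(keep), cell_deg = cell)
  points[keep, , drop = FALSE]
}

# Bron-Kerbosch (with pivot) enumeration of all maximal cliques of an
# undirected graph given as a logical adjacency matrix.
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return()
    }
    pivot_pool <- c(P, X)
    u <- pivot_pool[which.max(vapply(pivot_pool, function(v)
      sum(adj[v, P]), numeric(1)))]
    for (v in P[!adj[u, P]]) {
      bk(c(R, v), P[adj[v, P]], X[adj[v, X]])
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

#' Select the maximum uncorrelated variable subset
#'
#' Samples \code{n_sample} cell locations valid in all layers (seeded),
#' computes pairwise Pearson correlations, and returns the
#' maximum-cardinality subset of variables with all pairwise
#' |r| < \code{r_max}, found exactly by clique search on the
#' compatibility graph. Ties are broken by preferring variables with
#' lower mean absolute correlation, then input order. Constant layers
#' are excluded with a warning.
#'
#' @param stack Named list of \code{chequer_raster} layers.
#' @param n_sample Number of sampled cells (default 10000; capped at the
#'   number of valid cells).
#' @param r_max Pearson threshold (default 0.8).
#' @param seed Integer seed.
#' @param report Optional \code{chequer_report}.
#' @return Character vector of selected layer names (input order).
#' @export
select_uncorrelated <- function(stack, n_sample = 10000, r_max = 0.8,
                                seed = 1, report = NULL) {
  sv <- stack_values(stack)
  n <- nrow(sv$values)
  if (n < 2) stop("fewer than 2 valid cells in the stack")
  set.seed(seed)
  take <- if (n_sample < n) sample.int(n, n_sample) else seq_len(n)
  vals <- sv$values[take, , drop = FALSE]
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant layer(s): ",
            paste(colnames(vals)[sds == 0], collapse = ", "))
    vals <- vals[, sds > 0, drop = FALSE]
  }
  vars <- colnames(vals)
  k <- length(vars)
  if (k == 0) stop("no variable with non-zero variance")
  if (k == 1) return(vars)
  r <- stats::cor(vals)
  adj <- abs(r) < r_max
  diag(adj) <- FALSE
  cl <- maximal_cliques(adj)
  sizes <- lengths(cl)
  cl <- cl[sizes == max(sizes)]
  mac <- rowMeans(abs(r) - diag(1, k))  # mean |r| to the other variables
  score <- vapply(cl, function(s) sum(mac[s]), numeric(1))
  cl <- cl[score <= min(score) + 1e-12]
  keyed <- vapply(cl, function(s) paste(sprintf("%03d", s), collapse = ","),
                  character(1))
  best <- cl[[order(keyed)[1]]]
  sel <- vars[best]
  report_log(report, "select_uncorrelated", n_layers = length(stack),
             n_sample = length(take), r_max = r_max, selected = sel)
  sel
}

#' Area under the ROC curve for presence vs background scores
#'
#' Mann--Whitney rank statistic; ties count 0.5.
#'
#' @param pres_scores,bg_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(pres_scores, bg_scores) {
  m <- length(pres_scores); n <- length(bg_scores)
  stopifnot(m > 0, n > 0)
  r <- rank(c(pres_scores, bg_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Maximum training sensitivity-plus-specificity threshold
#'
#' Scans the sorted unique logistic scores; sensitivity is the fraction
#' of presences scoring >= t, specificity the fraction of background
#' scoring < t. Among ties the lowest threshold is returned.
#'
#' @param pres_scores,bg_scores Numeric logistic scores.
#' @return The selected threshold.
#' @export
maxsss_threshold <- function(pres_scores, bg_scores) {
  cand <- sort(unique(c(pres_scores, bg_scores)))
  ss <- vapply(cand, function(t)
    mean(pres_scores >= t) + mean(bg_scores < t), numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1]]
}

#' Fit a maxent model from occurrences and a raster stack
#'
#' Convenience wrapper: extracts presence/background variable values,
#' builds the feature spec on their union, and fits.
#'
#' @param occ data.frame with lon, lat (already thinned).
#' @param stack Named list of layers (the model variables).
#' @param class_set \code{"H"} or \code{"HQP"}.
#' @param n_knots Hinge knots per orientation.
#' @param categorical Names of 0/1 layers.
#' @param bg_max Background cap; if the stack has more valid cells, a
#'   seeded subsample of this size is used (default 10000).
#' @param seed Seed for the background subsample.
#' @param ... Passed to \code{\link{fit_maxent}} (beta, tol, max_iter).
#' @return List of class \code{chequer_sdm}: model, presence/background
#'   values, logistic scores, AUC (training), max-SSS threshold.
#' @export
fit_sdm <- function(occ, stack, class_set = "H", n_knots = 30,
                    categorical = character(0), bg_max = 10000, seed = 1,
                    ...) {
  sv <- stack_values(stack)
  if (nrow(sv$values) > bg_max) {
    set.seed(seed)
    take <- sample.int(nrow(sv$values), bg_max)
    sv$values <- sv$values[take, , drop = FALSE]
    sv$cells <- sv$cells[take, , drop = FALSE]
  }
  tmpl <- stack[[1]]
  rc <- raster_cell_index(tmpl, occ$lon, occ$lat)
  if (any(is.na(rc[, 1]))) stop("occurrence point outside the stack extent")
  pres_vals <- vapply(stack, function(r) r$values[rc], numeric(nrow(rc)))
  pres_vals <- matrix(pres_vals, nrow = nrow(rc),
                      dimnames = list(NULL, names(stack)))
  if (any(!is.finite(pres_vals)))
    stop("occurrence point on a nodata cell")
  spec <- build_features(rbind(sv$values, pres_vals), class_set, n_knots,
                         categorical)
  fp <- feature_matrix(spec, pres_vals)
  fb <- feature_matrix(spec, sv$values)
  model <- fit_maxent(fp, fb, spec, ...)
  pres_scores <- predict_maxent(model, pres_vals)
  bg_scores <- logistic_from_eta(model, model$eta_bg)
  structure(list(model = model, presence_values = pres_vals,
                 background_values = sv$values, background_cells = sv$cells,
                 pres_scores = pres_scores, bg_scores = bg_scores,
                 auc_train = auc_score(pres_scores, bg_scores),
                 threshold = maxsss_threshold(pres_scores, bg_scores)),
            class = "chequer_sdm")
}

#' Replicated subsample evaluation
#'
#' Splits the presences into train/test \code{n_rep} times (seeded),
#' refits on the training fraction and scores AUC on the test fraction
#' against the background.
#'
#' @param occ Thinned occurrence data.frame (lon, lat).
#' @param stack Model layers.
#' @param n_rep Number of replicates (default 100).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed.
#' @param ... Passed to \code{\link{fit_sdm}}.
#' @return List: mean_auc, auc (per replicate), sd_auc.
#' @export
replicate_runs <- function(occ, stack, n_rep = 100, train_frac = 0.75,
                           seed = 1, ...) {
  stopifnot(n_rep >= 1, train_frac > 0, train_frac < 1)
  n <- nrow(occ)
  aucs <- numeric(n_rep)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_rep)
  for (rep in seq_len(n_rep)) {
    set.seed(seeds[rep])
    tr <- sample.int(n, max(1, round(train_frac * n)))
    te <- setdiff(seq_len(n), tr)
    if (!length(te)) stop("empty test set after split")
    fit <- fit_sdm(occ[tr, , drop = FALSE], stack, ...)
    test_vals <- vapply(stack, function(r)
      r$values[raster_cell_index(r, occ$lon[te], occ$lat[te])],
      numeric(length(te)))
    test_vals <- matrix(test_vals, nrow = length(te),
                        dimnames = list(NULL, names(stack)))
    aucs[rep] <- auc_score(predict_maxent(fit$model, test_vals),
                           fit$bg_scores)
  }
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), auc = aucs)
}

#' Percent contribution and jackknife variable importance
#'
#' Percent contribution is the model's per-variable cumulative gain
#' trace normalized to sum 100. The jackknife table reports the
#' training gain of a model fitted on each variable alone (same
#' presences, background and settings).
#'
#' @param sdm A \code{chequer_sdm} from \code{\link{fit_sdm}}.
#' @param beta,tol,max_iter Fit settings for the single-variable refits
#'   (defaults as in \code{\link{fit_maxent}}).
#' @return List: \code{contribution} (named percents),
#'   \code{jackknife} (named single-variable training gains).
#' @export
variable_importance <- function(sdm, beta = BETA_DEFAULTS, tol = 1e-6,
                                max_iter = 200) {
  trace <- sdm$model$gain_trace
  total <- sum(trace)
  contribution <- if (total > 0) 100 * trace / total else
    stats::setNames(rep(NA_real_, length(trace)), names(trace))
  vars <- sdm$model$spec$vars
  jack <- stats::setNames(numeric(length(vars)), vars)
  for (v in vars) {
    spec1 <- build_features(rbind(sdm$background_values[, v, drop = FALSE],
                                  sdm$presence_values[, v, drop = FALSE]),
                            class_set = sdm$model$spec$class_set,
                            n_knots = sdm$model$spec$n_knots,
                            categorical = intersect(v, sdm$model$spec$categorical))
    fp <- feature_matrix(spec1, sdm$presence_values[, v, drop = FALSE])
    fb <- feature_matrix(spec1, sdm$background_values[, v, drop = FALSE])
    jack[v] <- fit_maxent(fp, fb, spec1, beta = beta, tol = tol,
                          max_iter = max_iter)$gain
  }
  list(contribution = contribution, jackknife = jack)
}

#' Rasterized alpha-hull occupancy layer
#'
#' The alpha shape is the union of Delaunay triangles whose circumcircle
#' radius is at most \code{alpha} (degrees). A cell is 1 if its center
#' lies inside the shape or within half a cell of a presence point,
#' else 0; nodata cells of the template stay NA.
#'
#' @param points data.frame with lon, lat (>= 3 for a hull; fewer
#'   degrade to point-buffer cells with a warning).
#' @param alpha Circumradius bound in degrees (default 10).
#' @param template A \code{chequer_raster}.
#' @return A binary \code{chequer_raster}.
#' @export
alpha_hull_layer <- function(points, alpha = 10, template) {
  stopifnot(alpha > 0)
  cc <- raster_cell_centers(template)
  vals <- matrix(0, template$nrows, template$ncols)
  vals[is.na(template$values)] <- NA
  tris <- NULL
  if (nrow(points) >= 3) {
    tri <- tryCatch(delaunay_triangles(points$lon, points$lat),
                    error = function(e) NULL)
    if (!is.null(tri)) {
      keep <- logical(nrow(tri))
      for (t in seq_len(nrow(tri))) {
        ccirc <- circumcircle(c(points$lon[tri[t, 1]], points$lat[tri[t, 1]]),
                              c(points$lon[tri[t, 2]], points$lat[tri[t, 2]]),
                              c(points$lon[tri[t, 3]], points$lat[tri[t, 3]]))
        keep[t] <- !is.null(ccirc) && sqrt(ccirc$r2) <= alpha
      }
      tris <- tri[keep, , drop = FALSE]
    }
  } else {
    warning("fewer than 3 points; alpha hull degenerates to point buffers")
  }
  half <- template$cellsize / 2
  for (row in seq_len(template$nrows)) {
    for (col in seq_len(template$ncols)) {
      if (is.na(vals[row, col])) next
      x <- cc$lon[col]; y <- cc$lat[row]
      inside <- FALSE
      if (!is.null(tris) && nrow(tris)) {
        for (t in seq_len(nrow(tris))) {
          if (point_in_triangle(x, y,
                                c(points$lon[tris[t, 1]], points$lat[tris[t, 1]]),
                                c(points$lon[tris[t, 2]], points$lat[tris[t, 2]]),
                                c(points$lon[tris[t, 3]], points$lat[tris[t, 3]]))) {
            inside <- TRUE; break
          }
        }
      }
      if (!inside &&
          any(abs(points$lon - x) <= half & abs(points$lat - y) <= half))
        inside <- TRUE
      vals[row, col] <- as.numeric(inside)
    }
  }
  # invariant: the cell holding each presence point is 1
  rc <- raster_cell_index(template, points$lon, points$lat)
  ok <- !is.na(rc[, 1])
  vals[rc[ok, , drop = FALSE]] <- 1
  raster_grid(vals, template$xll, template$yll, template$cellsize,
              template$nodata)
}

#' Cryptic-peer biotic model
#'
#' Refits a species' model with the peer cryptic species' alpha-hull
#' occupancy layer as an additional categorical variable, dropping the
#' least important climatic variable (lowest percent contribution in the
#' climatic model) so both model series use the same number of
#' variables.
#'
#' @param occ Thinned focal-species occurrences (lon, lat).
#' @param climate Named list of the climatic layers used by the climatic
#'   model.
#' @param peer_hull Binary \code{chequer_raster} from
#'   \code{\link{alpha_hull_layer}} of the peer species.
#' @param contribution Named percent contributions of the climatic
#'   model (used to pick the variable to drop; ties by input order).
#' @param hull_name Name for the hull layer (default "peer_hull").
#' @param ... Passed to \code{\link{fit_sdm}}.
#' @return List: \code{sdm} (the refit), \code{dropped} (variable
#'   removed), \code{importance} (variable_importance of the refit),
#'   \code{hull_rank} (contribution rank of the hull layer, 1 = top).
#' @export
biotic_model <- function(occ, climate, peer_hull, contribution,
                         hull_name = "peer_hull", ...) {
  clim_contrib <- contribution[names(climate)]
  drop <- names(climate)[which.min(clim_contrib)]
  layers <- climate[setdiff(names(climate), drop)]
  layers[[hull_name]] <- peer_hull
  sdm <- fit_sdm(occ, layers, categorical = hull_name, ...)
  imp <- variable_importance(sdm)
  ranks <- rank(-imp$contribution, ties.method = "min")
  list(sdm = sdm, dropped = drop, importance = imp,
       hull_rank = unname(ranks[hull_name]))
}
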