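# Residual genetic-divergence landscape: site-level mean p-distances,
# Delaunay graph over collection sites, competing distance-decay
# regressions with R-squared selection, edge-midpoint residuals, and
# inverse-distance-weighted interpolation to a raster.

#' Collapse specimens into collection sites
#'
#' Specimens within \code{tol} great-circle degrees of each other (single
#' linkage) share a site. Site coordinates are the member centroid; the
#' between-site distance is the arithmetic mean of all cross-site
#' specimen-pair p-distances; the diagonal is the mean within-site
#' pairwise distance (0 for singletons).
#'
#' @param dm Specimen p-distance matrix (dimnames = specimen ids).
#' @param loc Locality table containing every specimen in \code{dm}.
#' @param tol Linkage tolerance in great-circle degrees (default 0:
#'   exact coordinate match).
#' @return A list of class \code{chequer_sites}: \code{sites} (data.frame
#'   site_id, lat, lon, n) , \code{members} (list of specimen ids) and
#'   \code{d} (site distance matrix).
#' @export
collapse_to_sites <- function(dm, loc, tol = 0) {
  ids <- rownames(dm)
  miss <- setdiff(ids, loc$specimen_id)
  if (length(miss)) stop("no coordinates for: ", paste(miss, collapse = ", "))
  loc <- loc[match(ids, loc$specimen_id), ]
  n <- length(ids)
  # single-linkage clustering on great-circle separation
  if (n == 1) {
    grp <- 1L
  } else {
    geo <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      geo[i, (i + 1):n] <- central_angle_deg(loc$lon[i], loc$lat[i],
                                             loc$lon[(i + 1):n],
                                             loc$lat[(i + 1):n])
    }
    geo <- geo + t(geo)
    if (all(geo[upper.tri(geo)] > tol)) {
      grp <- seq_len(n)
    } else {
      hc <- stats::hclust(stats::as.dist(geo), method = "single")
      grp <- stats::cutree(hc, h = tol + 1e-12)
    }
  }
  k <- max(grp)
  sites <- data.frame(site_id = paste0("S", seq_len(k)),
                      lat = NA_real_, lon = NA_real_, n = NA_integer_,
                      stringsAsFactors = FALSE)
  members <- vector("list", k)
  for (g in seq_len(k)) {
    sel <- grp == g
    sites$lat[g] <- mean(loc$lat[sel])
    sites$lon[g] <- mean(loc$lon[sel])
    sites$n[g] <- sum(sel)
    members[[g]] <- ids[sel]
  }
  sd_ <- matrix(0, k, k, dimnames = list(sites$site_id, sites$site_id))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      ia <- which(grp == a); ib <- which(grp == b)
      if (a == b) {
        sd_[a, b] <- if (length(ia) > 1)
          mean(dm[ia, ia][upper.tri(dm[ia, ia])]) else 0
      } else {
        sd_[a, b] <- mean(dm[ia, ib, drop = FALSE])
      }
    }
  }
  structure(list(sites = sites, members = members, d = sd_),
            class = "chequer_sites")
}

#' Delaunay edges between collection sites
#'
#' Planar Delaunay triangulation on (lon, lat); returns the unique
#' undirected edges.
#'
#' @param sites A \code{chequer_sites}.
#' @return Two-column integer matrix of site indices (i < j).
#' @export
delaunay_edges <- function(sites) {
  s <- sites$sites
  if (nrow(s) < 3)
    stop("need >= 3 sites for a triangulation; use direct pairwise mode")
  tri <- tryCatch(delaunay_triangles(s$lon, s$lat), error = function(e)
    stop("triangulation failed (collinear sites?): ", conditionMessage(e)))
  triangles_to_edges(tri)
}

# Fit one decay family to (g, d) pairs; returns list(family, par, pred fn,
# r_squared, converged).
fit_one_decay <- function(family, g, d) {
  sst <- sum((d - mean(d))^2)
  r2 <- function(pred) if (sst > 0) 1 - sum((d - pred)^2) / sst else NA_real_
  if (family == "linear") {
    fit <- stats::lm(d ~ g)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    list(family = family, a = a, b = b,
         predict = function(gg) a + b * gg,
         r_squared = r2(stats::fitted(fit)), converged = TRUE)
  } else if (family == "log_linear") {
    if (any(g <= 0)) return(list(family = family, a = NA, b = NA,
                                 predict = NULL, r_squared = -Inf,
                                 converged = FALSE))
    lg <- log(g)
    fit <- stats::lm(d ~ lg)
    a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
    list(family = family, a = a, b = b,
         predict = function(gg) a + b * log(gg),
         r_squared = r2(stats::fitted(fit)), converged = TRUE)
  } else { # asymptotic d = a * (1 - exp(-b * g)), a, b >= 0
    starts <- list(c(a = max(d), b = 1 / mean(g)),
                   c(a = max(d), b = 1 / max(g)))
    best <- NULL
    for (st in starts) {
      fit <- tryCatch(
        stats::nls(d ~ a * (1 - exp(-b * g)), start = as.list(st),
                   algorithm = "port", lower = c(a = 0, b = 0),
                   control = stats::nls.control(warnOnly = FALSE)),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit)) {
        rr <- r2(stats::fitted(fit))
        if (is.null(best) || rr > best$r_squared) {
          a <- unname(stats::coef(fit)["a"]); b <- unname(stats::coef(fit)["b"])
          best <- list(family = family, a = a, b = b,
                       predict = local({aa <- a; bb <- b
                         function(gg) aa * (1 - exp(-bb * gg))}),
                       r_squared = rr, converged = TRUE)
        }
      }
    }
    if (is.null(best))
      best <- list(family = family, a = NA, b = NA, predict = NULL,
                   r_squared = -Inf, converged = FALSE)
    best
  }
}

#' Fit competing distance-decay regressions and select by R-squared
#'
#' Fits d = a + b g (linear), d = a + b ln g (log-linear) and
#' d = a (1 - exp(-b g)) (asymptotic, non-negative parameters,
#' multi-start) by least squares, and selects the converged fit with the
#' highest R-squared. Geographic distances are great-circle km.
#'
#' @param gen Numeric vector of genetic distances (p-distance).
#' @param geo Numeric vector of geographic distances (km), same length.
#' @param report Optional \code{chequer_report}.
#' @return List of class \code{chequer_decay}: \code{best} (selected fit)
#'   and \code{fits} (all three).
#' @export
fit_decay_models <- function(gen, geo, report = NULL) {
  stopifnot(length(gen) == length(geo))
  if (length(gen) < 3) stop("need >= 3 (genetic, geographic) pairs")
  fits <- lapply(c("linear", "log_linear", "asymptotic"),
                 fit_one_decay, g = geo, d = gen)
  names(fits) <- vapply(fits, `[[`, character(1), "family")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) stop("no decay regression converged")
  r2s <- vapply(fits, `[[`, numeric(1), "r_squared")
  r2s[!conv] <- -Inf
  best <- fits[[which.max(r2s)]]
  report_log(report, "fit_decay_models",
             n_pairs = length(gen), selected = best$family,
             r_squared = r2s[conv], converged = names(fits)[conv])
  structure(list(best = best, fits = fits), class = "chequer_decay")
}

#' Edge-midpoint residuals of the selected decay model
#'
#' For each Delaunay edge, residual = observed between-site p-distance
#' minus the decay-model prediction at the edge's great-circle length;
#' the residual is attributed to the arithmetic midpoint of the segment.
#'
#' @param decay A \code{chequer_decay} (or a single fit with a
#'   \code{predict} element).
#' @param sites A \code{chequer_sites}.
#' @param edges Two-column site-index matrix from
#'   \code{\link{delaunay_edges}}.
#' @return data.frame: mid_lon, mid_lat, residual, observed, predicted,
#'   gdist_km, site_i, site_j.
#' @export
edge_residuals <- function(decay, sites, edges) {
  fit <- if (inherits(decay, "chequer_decay")) decay$best else decay
  if (!fit$converged) stop("selected decay fit did not converge")
  s <- sites$sites
  i <- edges[, 1]; j <- edges[, 2]
  g <- haversine_km(s$lon[i], s$lat[i], s$lon[j], s$lat[j])
  obs <- sites$d[cbind(i, j)]
  pred <- fit$predict(g)
  data.frame(mid_lon = (s$lon[i] + s$lon[j]) / 2,
             mid_lat = (s$lat[i] + s$lat[j]) / 2,
             residual = obs - pred, observed = obs, predicted = pred,
             gdist_km = g, site_i = i, site_j = j)
}

#' Inverse-distance-weighted interpolation of residual points
#'
#' Cell value = sum(w_k v_k) / sum(w_k), w_k = planar distance from the
#' cell center to point k raised to \code{-power}; a cell center
#' coinciding with a data point (distance < 1e-9 deg) takes that point's
#' value exactly. No search-radius cutoff. Output is a convex
#' combination of the inputs, hence bounded by their range.
#'
#' @param points data.frame with mid_lon, mid_lat, residual (as from
#'   \code{\link{edge_residuals}}).
#' @param template A \code{chequer_raster} defining the output grid;
#'   NA (nodata) cells stay NA.
#' @param power IDW exponent (> 0, default 2).
#' @return A \code{chequer_raster} of interpolated residuals.
#' @export
idw_interpolate <- function(points, template, power = 2) {
  stopifnot(power > 0)
  if (nrow(points) == 0) stop("empty residual point set")
  cc <- raster_cell_centers(template)
  out <- template$values
  px <- points$mid_lon; py <- points$mid_lat; pv <- points$residual
  for (row in seq_len(template$nrows)) {
    y <- cc$lat[row]
    mask <- !is.na(template$values[row, ])
    if (!any(mask)) next
    xs <- cc$lon[mask]
    vals <- numeric(length(xs))
    for (ci in seq_along(xs)) {
      d2 <- (px - xs[ci])^2 + (py - y)^2
      hit <- which(d2 < 1e-18)
      if (length(hit)) {
        vals[ci] <- pv[hit[1]]
      } else {
        w <- d2^(-power / 2)
        vals[ci] <- sum(w * pv) / sum(w)
      }
    }
    out[row, mask] <- vals
  }
  raster_grid(out, template$xll, template$yll, template$cellsize,
              template$nodata)
}

#' Full genetic-landscape pipeline
#'
#' Collapses specimens to sites, triangulates, fits the decay models on
#' the Delaunay-edge pairs (default) or on all site pairs, computes
#' edge-midpoint residuals and interpolates them onto the template grid.
#'
#' @param dm Specimen p-distance matrix.
#' @param loc Locality table.
#' @param template Output \code{chequer_raster} template.
#' @param tol Site-collapse tolerance, great-circle degrees.
#' @param power IDW exponent.
#' @param fit_on \code{"edges"} (default) or \code{"all_pairs"}.
#' @param report Optional \code{chequer_report}.
#' @return List: sites, edges, decay, residuals, raster.
#' @export
genetic_landscape <- function(dm, loc, template, tol = 0, power = 2,
                              fit_on = c("edges", "all_pairs"),
                              report = NULL) {
  fit_on <- match.arg(fit_on)
  sites <- collapse_to_sites(dm, loc, tol)
  edges <- delaunay_edges(sites)
  s <- sites$sites
  if (fit_on == "edges") {
    i <- edges[, 1]; j <- edges[, 2]
  } else {
    pr <- which(upper.tri(sites$d), arr.ind = TRUE)
    i <- pr[, 1]; j <- pr[, 2]
  }
  g <- haversine_km(s$lon[i], s$lat[i], s$lon[j], s$lat[j])
  decay <- fit_decay_models(sites$d[cbind(i, j)], g, report)
  resid <- edge_residuals(decay, sites, edges)
  ras <- idw_interpolate(resid, template, power)
  report_log(report, "genetic_landscape", n_specimens = nrow(dm),
             n_sites = nrow(s), n_edges = nrow(edges), tol_deg = tol,
             idw_power = power, fit_on = fit_on)
  list(sites = sites, edges = edges, decay = decay, residuals = resid,
       raster = ras)
}
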