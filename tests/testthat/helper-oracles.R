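# Independent oracles used by the unit and acceptance tests. Each is a
# deliberately naive implementation (enumeration / closed form) kept
# separate from the package's algorithms.

# Brute-force Delaunay edges: a triangle belongs to the triangulation
# iff no other point lies strictly inside its circumcircle.
oracle_delaunay_edges <- function(x, y) {
  n <- length(x)
  edges <- matrix(integer(0), 0, 2)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    cc <- chequer:::circumcircle(c(x[i], y[i]), c(x[j], y[j]), c(x[k], y[k]))
    if (is.null(cc)) next
    others <- setdiff(seq_len(n), c(i, j, k))
    d2 <- (x[others] - cc$center[1])^2 + (y[others] - cc$center[2])^2
    if (all(d2 > cc$r2 * (1 - 1e-12))) {
      edges <- rbind(edges, c(i, j), c(j, k), c(i, k))
    }
  }
  unique(edges[order(edges[, 1], edges[, 2]), , drop = FALSE])
}

# Least-squares fit of a 4-taxon quartet topology; returns SSE.
# Topology given as list(pair1, pair2) of index pairs.
quartet_sse <- function(d, split) {
  a <- split[[1]][1]; b <- split[[1]][2]
  c_ <- split[[2]][1]; dd <- split[[2]][2]
  # design matrix for the 5 branch lengths (a, b, c, d, internal)
  rows <- list(c(a, b), c(a, c_), c(a, dd), c(b, c_), c(b, dd), c(c_, dd))
  X <- matrix(0, 6, 5)
  yv <- numeric(6)
  for (r in seq_along(rows)) {
    i <- rows[[r]][1]; j <- rows[[r]][2]
    for (t in 1:4) X[r, t] <- as.numeric(t %in% c(i, j))
    same_side <- (all(c(i, j) %in% c(a, b))) || (all(c(i, j) %in% c(c_, dd)))
    X[r, 5] <- as.numeric(!same_side)
    yv[r] <- d[i, j]
  }
  fit <- stats::lm.fit(X, yv)
  sum(fit$residuals^2)
}

# Best quartet topology by least squares over the 3 possible splits.
oracle_quartet <- function(d) {
  splits <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
                 list(c(1, 4), c(2, 3)))
  sse <- vapply(splits, quartet_sse, numeric(1), d = d)
  splits[[which.min(sse)]]
}

# All edges present in at least one minimum spanning tree, by explicit
# enumeration of spanning trees (n <= 7 nodes).
oracle_msn_edges <- function(d) {
  n <- nrow(d)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(pairs)
  combs <- utils::combn(ne, n - 1)
  best_w <- Inf
  keep <- list()
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    comp <- chequer:::components_from_edges(n, pairs[sel, 1], pairs[sel, 2])
    if (max(comp) != 1) next
    w <- sum(d[pairs[sel, , drop = FALSE]])
    if (w < best_w - 1e-9) { best_w <- w; keep <- list(sel) }
    else if (abs(w - best_w) <= 1e-9) keep[[length(keep) + 1]] <- sel
  }
  idx <- sort(unique(unlist(keep)))
  out <- pairs[idx, , drop = FALSE]
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

# Minimum spanning forest weight and edge count by enumeration over
# edge subsets (small graphs only).
oracle_min_events <- function(units, edges_df) {
  n <- length(units)
  idx <- stats::setNames(seq_len(n), units)
  i <- idx[edges_df$unit_u]; j <- idx[edges_df$unit_v]
  full_comp <- chequer:::components_from_edges(n, i, j)
  n_events <- n - max(full_comp)
  # minimal total length achieving that connectivity
  ne <- nrow(edges_df)
  best <- Inf
  if (n_events == 0) return(list(count = 0, total_km = 0))
  for (k in n_events:ne) {
    combs <- utils::combn(ne, k)
    for (ci in seq_len(ncol(combs))) {
      sel <- combs[, ci]
      comp <- chequer:::components_from_edges(n, i[sel], j[sel])
      if (max(comp) == max(full_comp)) {
        best <- min(best, sum(edges_df$km[sel]))
      }
    }
    if (is.finite(best)) break   # k = n_events suffices for a forest
  }
  list(count = n_events, total_km = best)
}

# Exhaustive maximum subset with all pairwise |r| < r_max.
oracle_max_subset_size <- function(r, r_max) {
  k <- nrow(r)
  best <- 0
  for (mask in 0:(2^k - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    if (length(sel) <= best) next
    ok <- TRUE
    if (length(sel) > 1) {
      sub <- abs(r[sel, sel])
      diag(sub) <- 0
      ok <- all(sub < r_max)
    }
    if (ok) best <- length(sel)
  }
  best
}

# Exhaustive max-SSS scan (same >=/< convention as the contract).
oracle_maxsss <- function(pres, bg) {
  cand <- sort(unique(c(pres, bg)))
  ss <- vapply(cand, function(t) mean(pres >= t) + mean(bg < t), numeric(1))
  cand[which(ss >= max(ss) - 1e-12)[1]]
}

# Shared default synthetic world (seed fixed across the suite).
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_world(default_world_config(seed = 1))
    cache
  }
})

full_template <- function(world) {
  cfg <- world$cfg
  raster_grid(matrix(0, cfg$nrows, cfg$ncols), cfg$lon0, cfg$lat0,
              cfg$cellsize)
}

# tiny handmade alignment builders
aln_of <- function(...) {
  seqs <- c(...)
  alignment(paste0("s", seq_along(seqs)), seqs)
}
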