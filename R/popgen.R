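# Pairwise p-distances, neighbour-joining identification trees and
# species assignment for cryptic taxa.

# Encode an alignment as an n x L integer matrix; A,C,G,T -> 1..4,
# gaps / N / IUPAC ambiguities -> NA (treated as missing for distances).
encode_alignment <- function(aln) {
  stopifnot(inherits(aln, "chequer_alignment"))
  m <- matrix(NA_integer_, length(aln$ids), aln$length,
              dimnames = list(aln$ids, NULL))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(aln$seqs)) {
    ch <- strsplit(aln$seqs[i], "")[[1]]
    m[i, ] <- unname(code[ch])
  }
  m
}

#' Pairwise p-distance matrix
#'
#' p-distance between two sequences is the proportion of compared sites
#' that differ. Sites holding a gap, N or IUPAC ambiguity code in either
#' sequence of a pair are excluded from that pair (pairwise deletion);
#' under complete deletion any site missing in any sequence is excluded
#' for all pairs.
#'
#' @param aln A \code{chequer_alignment} with at least 2 records.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}.
#' @return Symmetric numeric matrix of p-distances in [0, 1], with
#'   specimen ids as dimnames.
#' @export
p_distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- encode_alignment(aln)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  if (deletion == "complete") {
    keep <- colSums(is.na(m)) == 0
    if (!any(keep)) stop("no site free of missing data under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  ok <- !is.na(m)
  valid <- ok %*% t(ok)                       # compared sites per pair
  same <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    ib <- (m == b) & ok
    same <- same + ib %*% t(ib)
  }
  if (any(valid[upper.tri(valid)] == 0)) {
    idx <- which(valid == 0 & upper.tri(valid), arr.ind = TRUE)[1, ]
    stop("no comparable sites between '", rownames(m)[idx[1]], "' and '",
         rownames(m)[idx[2]], "'")
  }
  d <- (valid - same) / valid
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbour-joining tree
#'
#' Saitou--Nei agglomeration on the Q criterion. Ties on Q are broken by
#' the lowest-index pair in the current node ordering (insertion order),
#' so the result is deterministic. Negative branch lengths are clamped
#' to zero.
#'
#' @param d Symmetric distance matrix with >= 3 taxa (dimnames = taxa).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix not symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  active <- seq_len(n)            # node ids of current rows/cols
  next_node <- n + 1L
  edges <- matrix(integer(0), 0, 2)
  elen <- numeric(0)
  D <- d

  while (length(active) > 3) {
    r <- length(active)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    # lowest-index pair among ties (row-major scan, i < j)
    best <- NULL
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        if (Q[i, j] <= qmin + 1e-12) { best <- c(i, j); break }
      }
      if (!is.null(best)) break
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    edges <- rbind(edges, c(next_node, active[i]), c(next_node, active[j]))
    elen <- c(elen, max(0, li), max(0, lj))
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    active <- c(active[keep], next_node)
    next_node <- next_node + 1L
  }

  # final trifurcation by the three-point formulas
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  center <- next_node
  edges <- rbind(edges, c(center, a), c(center, b), c(center, c3))
  elen <- c(elen, max(0, la), max(0, lb), max(0, lc))

  # renumber internals so the trifurcating center is n+1 (ape convention)
  internals <- sort(unique(edges[edges > n]))
  remap <- integer(max(internals))
  remap[center] <- n + 1L
  others <- setdiff(internals, center)
  if (length(others)) remap[others] <- n + 1L + seq_along(others)
  e2 <- edges
  e2[e2 > n] <- remap[e2[e2 > n]]
  tr <- structure(list(edge = e2, edge.length = elen,
                       tip.label = labels, Nnode = length(internals)),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Resamples alignment sites with replacement, rebuilds the NJ tree per
#' pseudo-replicate, and annotates each internal branch of the
#' point-estimate tree with the percentage of replicates containing the
#' same bipartition (floor-rounded integer percent, stored in
#' \code{node.label}).
#'
#' @param aln A \code{chequer_alignment}.
#' @param n_reps Number of pseudo-replicates (default 100).
#' @param seed Integer seed; same seed, same supports.
#' @param deletion Deletion mode passed to \code{\link{p_distance_matrix}}.
#' @return An \code{ape::phylo} with integer percent supports in
#'   \code{node.label}.
#' @export
bootstrap_supports <- function(aln, n_reps = 100, seed = 1,
                               deletion = "pairwise") {
  stopifnot(n_reps >= 1)
  point <- nj_tree(p_distance_matrix(aln, deletion))
  m_ids <- aln$ids
  set.seed(seed)
  L <- aln$length
  chars <- do.call(rbind, strsplit(aln$seqs, ""))
  boots <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- alignment(m_ids, apply(chars[, cols, drop = FALSE], 1, paste,
                                  collapse = ""))
    boots[[rep]] <- nj_tree(p_distance_matrix(res, deletion))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- n_reps   # trivial partitions present in all
  point$node.label <- as.character(floor(100 * counts / n_reps))
  point
}

#' Assign specimens to species from their tree position
#'
#' References must form monophyletic groups relative to each other: the
#' smallest clade spanning one species' references may not contain
#' another species' reference (queries may interleave freely). The tree
#' is midpoint-rooted for clade extraction; each non-reference leaf
#' receives the species of the smallest clade that contains it together
#' with at least one reference, provided all references in that clade
#' belong to one species; otherwise the leaf is reported as
#' \code{"unassigned"}.
#'
#' @param tree An \code{ape::phylo} whose tips include all references.
#' @param references Named character vector: specimen_id -> species.
#' @return Named character vector over all tips (species or "unassigned").
#' @export
assign_species <- function(tree, references) {
  stopifnot(inherits(tree, "phylo"))
  refs <- references[names(references) %in% tree$tip.label]
  if (!length(refs)) stop("no reference specimen found among tree tips")
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  desc0 <- phangorn::Descendants(rooted, type = "tips")
  species <- unique(refs)
  for (sp in species) {
    tips <- names(refs)[refs == sp]
    if (length(tips) > 1) {
      mrca <- ape::getMRCA(rooted, tips)
      clade <- rooted$tip.label[desc0[[mrca]]]
      foreign <- intersect(clade, names(refs)[refs != sp])
      if (length(foreign)) {
        stop("reference species '", sp, "' is not monophyletic; ",
             "conflicting leaves: ",
             paste(sort(c(tips, foreign)), collapse = ", "))
      }
    }
  }
  anc_list <- phangorn::Ancestors(rooted, seq_len(ntip), "all")
  desc <- phangorn::Descendants(rooted, type = "tips")
  ref_idx <- match(names(refs), rooted$tip.label)
  out <- stats::setNames(rep(NA_character_, ntip), rooted$tip.label)
  out[names(refs)] <- unname(refs)
  for (tip in seq_len(ntip)) {
    if (!is.na(out[tip])) next
    assigned <- "unassigned"
    for (node in anc_list[[tip]]) {
      in_clade <- intersect(desc[[node]], ref_idx)
      if (length(in_clade)) {
        sp <- unique(refs[match(in_clade, ref_idx)])
        if (length(sp) == 1) assigned <- sp
        break
      }
    }
    out[tip] <- assigned
  }
  out
}

#' Write a distance matrix as square CSV
#'
#' @param d Symmetric matrix with dimnames.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_distance_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}
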