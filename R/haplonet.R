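# Haplotype collapsing and parsimony-limited minimum-spanning-network
# construction. The statistical-parsimony connection probability is
# replaced by an explicit mutational-step limit (default 11 steps for a
# ~658 bp barcode, the conventional 95% parsimony limit), which
# reproduces adjacency and component structure for shallow intraspecific
# networks.

#' Collapse unambiguous sequences into haplotypes
#'
#' Sequences containing gaps, N or IUPAC ambiguity codes are excluded
#' (and logged); identical remaining sequences are merged into one
#' haplotype. Land-unit occurrences come from the locality table.
#'
#' @param aln A \code{chequer_alignment}.
#' @param loc Locality table with a \code{land_unit} column (may be NA).
#' @param report Optional \code{chequer_report}.
#' @return data.frame of class \code{chequer_haplotypes}: hap_id,
#'   sequence, frequency, members (list), units (list).
#' @export
collapse_haplotypes <- function(aln, loc = NULL, report = NULL) {
  clean <- grepl("^[ACGT]+$", aln$seqs)
  excluded <- aln$ids[!clean]
  if (!any(clean)) stop("all sequences contain ambiguities/gaps; nothing to collapse")
  ids <- aln$ids[clean]
  seqs <- aln$seqs[clean]
  groups <- split(ids, factor(seqs, levels = unique(seqs)))
  hap <- data.frame(hap_id = paste0("H", seq_along(groups)),
                    sequence = names(groups),
                    frequency = lengths(groups),
                    stringsAsFactors = FALSE, row.names = NULL)
  hap$members <- unname(groups)
  hap$units <- lapply(groups, function(mm) {
    if (is.null(loc)) return(character(0))
    u <- loc$land_unit[match(mm, loc$specimen_id)]
    sort(unique(u[!is.na(u)]))
  })
  report_log(report, "collapse_haplotypes", n_input = length(aln$ids),
             n_excluded = length(excluded), excluded = excluded,
             n_haplotypes = nrow(hap))
  class(hap) <- c("chequer_haplotypes", "data.frame")
  hap
}

# Hamming distance matrix between haplotype sequences (equal length,
# unambiguous).
hamming_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Build a parsimony-limited minimum spanning network
#'
#' Edge weights are exact Hamming distances in mutational steps. The
#' network keeps every edge that occurs in at least one minimum spanning
#' tree (Kruskal with ties retained: an edge of weight w is kept iff its
#' endpoints are in different components of the graph of all
#' strictly-lighter kept edges), which also retains the tie loops that
#' statistical-parsimony software reports as ambiguous connections.
#' Edges longer than \code{connection_limit} steps are then removed, so
#' the final graph may be disconnected.
#'
#' @param haps A \code{chequer_haplotypes}.
#' @param connection_limit Maximum steps admitted (default 11).
#' @param report Optional \code{chequer_report}.
#' @return List of class \code{chequer_network}: \code{haplotypes},
#'   \code{edges} (data.frame hap_i, hap_j, steps), \code{component}
#'   (integer per haplotype), \code{connection_limit}.
#' @export
build_network <- function(haps, connection_limit = 11, report = NULL) {
  n <- nrow(haps)
  if (n == 0) stop("no haplotypes")
  edges <- data.frame(hap_i = integer(0), hap_j = integer(0),
                      steps = integer(0))
  if (n > 1) {
    d <- hamming_matrix(haps$sequence)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    w <- d[pairs]
    ord <- order(w, pairs[, 1], pairs[, 2])
    pairs <- pairs[ord, , drop = FALSE]
    w <- w[ord]
    # union-find over edges with weight strictly below the current group
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    keep <- logical(length(w))
    k <- 1
    while (k <= length(w)) {
      grp <- which(w == w[k])            # all edges of this weight
      for (e in grp) {
        keep[e] <- find(pairs[e, 1]) != find(pairs[e, 2])
      }
      for (e in grp) {                   # union after deciding the group
        ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
        if (ra != rb) parent[ra] <- rb
      }
      k <- max(grp) + 1
    }
    sel <- keep & (w <= connection_limit)
    edges <- data.frame(hap_i = pairs[sel, 1], hap_j = pairs[sel, 2],
                        steps = w[sel])
  }
  comp <- components_from_edges(n, edges$hap_i, edges$hap_j)
  report_log(report, "build_network", n_haplotypes = n,
             connection_limit = connection_limit, n_edges = nrow(edges),
             n_components = max(comp))
  structure(list(haplotypes = haps, edges = edges, component = comp,
                 connection_limit = connection_limit),
            class = "chequer_network")
}

# connected components from an undirected edge list over 1..n
components_from_edges <- function(n, i, j) {
  parent <- seq_len(n)
  i <- as.integer(i); j <- as.integer(j)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_along(i)) {
    ra <- find(i[e]); rb <- find(j[e])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

# degree of each haplotype node in the network
network_degrees <- function(net) {
  n <- nrow(net$haplotypes)
  tabulate(c(net$edges$hap_i, net$edges$hap_j), nbins = n)
}

#' Write a haplotype network as edge-list + haplotype-table CSVs
#'
#' @param net A \code{chequer_network}.
#' @param edge_path,hap_path Output CSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_network_csv <- function(net, edge_path, hap_path) {
  h <- net$haplotypes
  e <- net$edges
  utils::write.csv(data.frame(hap_i = h$hap_id[e$hap_i],
                              hap_j = h$hap_id[e$hap_j],
                              steps = e$steps),
                   edge_path, row.names = FALSE)
  utils::write.csv(data.frame(hap_id = h$hap_id, frequency = h$frequency,
                              members = vapply(h$members, paste,
                                               character(1), collapse = ";"),
                              units = vapply(h$units, paste,
                                             character(1), collapse = ";")),
                   hap_path, row.names = FALSE)
  invisible(list(edges = edge_path, haplotypes = hap_path))
}
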