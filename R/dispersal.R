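# Minimum over-sea dispersal-event inference: isobath merges, evidence
# graphs over land units per haplotype-network component, MST-based
# event minimization, the conservative ambiguity exclusion rule, and
# dispersal-length summaries.

#' Apply isobath merges to locality land units
#'
#' Units connected to another land mass at the reference isobath are
#' absorbed into it (transitively), so crossings inside a merged pair
#' are never scored as dispersal.
#'
#' @param loc Locality table with a \code{land_unit} column.
#' @param sg A \code{chequer_straits}.
#' @return List of class \code{chequer_landunits}: \code{mapping}
#'   (named character: original -> effective), \code{loc} (re-labeled
#'   table), \code{units} (effective unit names), \code{sg}.
#' @export
apply_isobath_merges <- function(loc, sg) {
  stopifnot(inherits(sg, "chequer_straits"))
  unknown <- setdiff(unique(stats::na.omit(loc$land_unit)), sg$units)
  if (length(unknown))
    stop("locality land_unit(s) not in strait graph: ",
         paste(unknown, collapse = ", "))
  mapping <- stats::setNames(sg$units, sg$units)
  if (nrow(sg$merges)) {
    step <- stats::setNames(sg$merges$absorbed_into, sg$merges$unit)
    for (u in sg$units) {
      cur <- u
      seen <- character(0)
      while (cur %in% names(step)) {
        if (cur %in% seen) stop("cyclic merge chain at unit ", cur)
        seen <- c(seen, cur)
        cur <- unname(step[cur])
      }
      mapping[u] <- cur
    }
  }
  loc2 <- loc
  ok <- !is.na(loc2$land_unit)
  loc2$land_unit[ok] <- unname(mapping[loc2$land_unit[ok]])
  structure(list(mapping = mapping, loc = loc2,
                 units = sort(unique(unname(mapping))), sg = sg),
            class = "chequer_landunits")
}

# Strait distance between two effective units: minimum over the original
# units absorbed into each side.
effective_distance <- function(lus, u, v) {
  a <- names(lus$mapping)[lus$mapping == u]
  b <- names(lus$mapping)[lus$mapping == v]
  min(lus$sg$km[a, b, drop = FALSE])
}

#' Build per-component dispersal evidence graphs
#'
#' For each connected component of the haplotype network, a graph over
#' the effective land units its haplotypes occupy. An edge (u, v)
#' carries evidence \code{shared_haplotype} when some haplotype occurs in
#' both units, or \code{linked_haplotypes} when two network-adjacent
#' haplotypes occur in u and v respectively. Edge weight is the strait
#' distance; unit pairs without a configured strait get the great-circle
#' distance between the units' locality centroids and are flagged.
#'
#' @param net A \code{chequer_network} (haplotype units must already be
#'   effective units, i.e. the alignment's localities were passed through
#'   \code{\link{apply_isobath_merges}} before haplotype collapsing, or
#'   re-labeled here via \code{lus$mapping}).
#' @param lus A \code{chequer_landunits}.
#' @param report Optional \code{chequer_report}.
#' @return List of data.frames (one per network component) with columns
#'   unit_u, unit_v, km, evidence, witnesses, flagged_no_strait.
#' @export
evidence_graph <- function(net, lus, report = NULL) {
  haps <- net$haplotypes
  # re-label haplotype units to effective units
  units_eff <- lapply(haps$units, function(u)
    sort(unique(unname(lus$mapping[u]))))
  comps <- sort(unique(net$component))
  out <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    hs <- which(net$component == comps[ci])
    acc <- list()
    add_edge <- function(u, v, evidence, witness) {
      if (u == v) return()
      key <- paste(sort(c(u, v)), collapse = "|")
      cur <- acc[[key]]
      if (is.null(cur)) {
        cur <- list(u = sort(c(u, v))[1], v = sort(c(u, v))[2],
                    evidence = evidence, witnesses = witness)
      } else {
        cur$evidence <- unique(c(cur$evidence, evidence))
        cur$witnesses <- unique(c(cur$witnesses, witness))
      }
      acc[[key]] <<- cur
    }
    for (h in hs) {
      uu <- units_eff[[h]]
      if (length(uu) > 1) {
        for (a in seq_len(length(uu) - 1)) for (b in (a + 1):length(uu))
          add_edge(uu[a], uu[b], "shared_haplotype", haps$hap_id[h])
      }
    }
    ce <- net$edges[net$component[net$edges$hap_i] == comps[ci], ,
                    drop = FALSE]
    for (e in seq_len(nrow(ce))) {
      ui <- units_eff[[ce$hap_i[e]]]
      uj <- units_eff[[ce$hap_j[e]]]
      for (a in ui) for (b in uj) {
        if (a != b)
          add_edge(a, b, "linked_haplotypes",
                   paste(haps$hap_id[ce$hap_i[e]], haps$hap_id[ce$hap_j[e]],
                         sep = "+"))
      }
    }
    if (length(acc)) {
      df <- do.call(rbind, lapply(acc, function(x)
        data.frame(unit_u = x$u, unit_v = x$v,
                   evidence = paste(sort(x$evidence), collapse = ";"),
                   witnesses = paste(sort(x$witnesses), collapse = ";"),
                   stringsAsFactors = FALSE)))
      rownames(df) <- NULL
      df$km <- mapply(function(u, v) effective_distance(lus, u, v),
                      df$unit_u, df$unit_v)
      df$flagged_no_strait <- !is.finite(df$km)
      if (any(df$flagged_no_strait)) {
        cen <- unit_centroids(lus)
        for (r in which(df$flagged_no_strait)) {
          df$km[r] <- haversine_km(cen[df$unit_u[r], "lon"],
                                   cen[df$unit_u[r], "lat"],
                                   cen[df$unit_v[r], "lon"],
                                   cen[df$unit_v[r], "lat"])
          warning("no configured strait between ", df$unit_u[r], " and ",
                  df$unit_v[r], "; using great-circle centroid distance")
        }
      }
      df <- df[order(df$unit_u, df$unit_v), ]
      rownames(df) <- NULL
      out[[ci]] <- df
    } else {
      out[[ci]] <- data.frame(unit_u = character(0), unit_v = character(0),
                              evidence = character(0),
                              witnesses = character(0), km = numeric(0),
                              flagged_no_strait = logical(0))
    }
  }
  report_log(report, "evidence_graph", n_components = length(comps),
             n_edges = sum(vapply(out, nrow, integer(1))))
  out
}

# centroid of each effective unit's localities (fallback distance only)
unit_centroids <- function(lus) {
  loc <- lus$loc[!is.na(lus$loc$land_unit), ]
  agg <- stats::aggregate(cbind(lon, lat) ~ land_unit, data = loc, FUN = mean)
  m <- as.matrix(agg[, c("lon", "lat")])
  rownames(m) <- agg$land_unit
  m
}

#' Minimize over-sea dispersal events
#'
#' Per evidence-graph component, the retained events are the edges of a
#' minimum spanning tree under strait-length weights (ties broken by
#' shorter length, then lexicographic unit names): the smallest set of
#' crossings explaining the observed occupancy, regardless of ancestor
#' placement. Disconnected evidence graphs contribute one tree per
#' connected part and are flagged.
#'
#' @param evidence List of evidence data.frames from
#'   \code{\link{evidence_graph}}.
#' @param report Optional \code{chequer_report}.
#' @return data.frame of events: event_id, unit_u, unit_v, km, evidence,
#'   witnesses, component, status (all "retained" here), reason.
#' @export
minimize_events <- function(evidence, report = NULL) {
  rows <- list()
  eid <- 0L
  for (ci in seq_along(evidence)) {
    df <- evidence[[ci]]
    if (nrow(df) == 0) next
    units <- sort(unique(c(df$unit_u, df$unit_v)))
    idx <- stats::setNames(seq_along(units), units)
    ord <- order(df$km, df$unit_u, df$unit_v)
    parent <- seq_along(units)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in ord) {
      ra <- find(idx[[df$unit_u[e]]]); rb <- find(idx[[df$unit_v[e]]])
      if (ra != rb) {
        parent[ra] <- rb
        eid <- eid + 1L
        rows[[length(rows) + 1L]] <-
          data.frame(event_id = paste0("E", eid),
                     unit_u = df$unit_u[e], unit_v = df$unit_v[e],
                     km = df$km[e], evidence = df$evidence[e],
                     witnesses = df$witnesses[e], component = ci,
                     status = "retained", reason = "",
                     stringsAsFactors = FALSE)
      }
    }
  }
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), unit_u = character(0),
               unit_v = character(0), km = numeric(0),
               evidence = character(0), witnesses = character(0),
               component = integer(0), status = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  report_log(report, "minimize_events", n_events = nrow(ev))
  ev
}

#' Flag ambiguous long-distance events
#'
#' An event is auto-excluded as ambiguous when both (a) an alternative
#' path between its two units exists through intermediate occupied units
#' whose longest single crossing is strictly shorter than the event's
#' crossing, and (b) a witnessing haplotype is an interior node of the
#' network (degree >= 2), i.e. plausibly ancestral, so extinction or
#' non-detection of it on the intermediate units explains the pattern
#' more conservatively. Explicit per-event overrides win and are logged.
#'
#' @param events Events from \code{\link{minimize_events}}.
#' @param net The \code{chequer_network}.
#' @param lus The \code{chequer_landunits}.
#' @param overrides Optional data.frame (event_id, action in
#'   \{retain, exclude\}, note).
#' @param report Optional \code{chequer_report}.
#' @return Events with updated \code{status} and \code{reason}.
#' @export
flag_ambiguous <- function(events, net, lus, overrides = NULL,
                           report = NULL) {
  if (nrow(events) == 0) return(events)
  deg <- network_degrees(net)
  hap_ids <- net$haplotypes$hap_id
  occ_units <- sort(unique(unlist(lapply(net$haplotypes$units, function(u)
    unname(lus$mapping[u])))))
  for (r in seq_len(nrow(events))) {
    u <- events$unit_u[r]; v <- events$unit_v[r]
    alt <- best_alternative_path(lus, occ_units, u, v, exclude_direct = TRUE)
    wit <- unique(unlist(strsplit(strsplit(events$witnesses[r], ";")[[1]],
                                  "\\+")))
    interior <- any(deg[match(wit, hap_ids)] >= 2, na.rm = TRUE)
    if (is.finite(alt) && alt < events$km[r] && interior) {
      events$status[r] <- "excluded_ambiguous"
      events$reason[r] <- sprintf(
        "alternative path with max crossing %.1f km < %.1f km; interior witness",
        alt, events$km[r])
    }
  }
  if (!is.null(overrides) && nrow(overrides)) {
    bad <- setdiff(overrides$event_id, events$event_id)
    if (length(bad)) stop("override references unknown event id(s): ",
                          paste(bad, collapse = ", "))
    for (r in seq_len(nrow(overrides))) {
      i <- match(overrides$event_id[r], events$event_id)
      act <- overrides$action[r]
      events$status[i] <- if (act == "exclude") "excluded_ambiguous" else "retained"
      note <- if ("note" %in% names(overrides)) overrides$note[r] else ""
      events$reason[i] <- paste0("override: ", act,
                                 if (nzchar(note)) paste0(" (", note, ")") else "")
    }
  }
  report_log(report, "flag_ambiguous",
             n_excluded = sum(events$status == "excluded_ambiguous"),
             excluded = events$event_id[events$status == "excluded_ambiguous"])
  events
}

# Minimax alternative path: over paths u -> v through occupied units
# (optionally forbidding the direct edge), minimize the longest single
# crossing; returns that bottleneck length (Inf if no path).
best_alternative_path <- function(lus, occ_units, u, v,
                                  exclude_direct = FALSE) {
  n <- length(occ_units)
  idx <- stats::setNames(seq_len(n), occ_units)
  W <- matrix(Inf, n, n)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    W[a, b] <- W[b, a] <- effective_distance(lus, occ_units[a], occ_units[b])
  }
  if (exclude_direct) W[idx[[u]], idx[[v]]] <- W[idx[[v]], idx[[u]]] <- Inf
  # minimax shortest path (Floyd-Warshall on the bottleneck semiring)
  for (k in seq_len(n)) for (a in seq_len(n)) for (b in seq_len(n)) {
    W[a, b] <- min(W[a, b], max(W[a, k], W[k, b]))
  }
  W[idx[[u]], idx[[v]]]
}

#' Summarize dispersal lengths against reference strait widths
#'
#' @param events Scored events (after \code{\link{flag_ambiguous}}).
#' @param bins Histogram bin edges in km (default 0 to just past the
#'   longest retained event in 25 km steps).
#' @param reference_straits Optional named numeric vector of strait
#'   widths (km) to compare against the inferred dispersal capability.
#' @param report Optional \code{chequer_report}.
#' @return List of class \code{chequer_dispersal_summary}: counts,
#'   histogram (data.frame), reference comparison table.
#' @export
summarize_lengths <- function(events, bins = NULL,
                              reference_straits = NULL, report = NULL) {
  retained <- events[events$status == "retained", , drop = FALSE]
  excluded <- events[events$status != "retained", , drop = FALSE]
  if (nrow(retained)) {
    if (is.null(bins))
      bins <- seq(0, 25 * ceiling(max(retained$km) / 25 + 1e-9), by = 25)
    h <- graphics::hist(retained$km, breaks = bins, plot = FALSE)
    histo <- data.frame(from_km = h$breaks[-length(h$breaks)],
                        to_km = h$breaks[-1], count = h$counts)
    capability_km <- max(retained$km)
  } else {
    histo <- data.frame(from_km = numeric(0), to_km = numeric(0),
                        count = integer(0))
    capability_km <- NA_real_
  }
  refs <- NULL
  if (!is.null(reference_straits)) {
    refs <- data.frame(strait = names(reference_straits),
                       width_km = unname(reference_straits),
                       within_capability =
                         if (is.na(capability_km)) NA else
                           unname(reference_straits) <= capability_km)
  }
  report_log(report, "summarize_lengths", retained = nrow(retained),
             excluded = nrow(excluded), capability_km = capability_km)
  structure(list(retained = nrow(retained), excluded = nrow(excluded),
                 histogram = histo, capability_km = capability_km,
                 references = refs),
            class = "chequer_dispersal_summary")
}

#' Full dispersal pipeline
#'
#' Merges land units at the isobath, builds evidence graphs from a
#' haplotype network, minimizes crossings, applies the conservative
#' ambiguity rule and summarizes the dispersal-length spectrum.
#'
#' @param net A \code{chequer_network}.
#' @param loc Locality table with land units.
#' @param sg A \code{chequer_straits}.
#' @param overrides Optional override data.frame (see
#'   \code{\link{flag_ambiguous}}).
#' @param reference_straits Optional named widths (km).
#' @param report Optional \code{chequer_report}.
#' @return List: landunits, evidence, events, summary.
#' @export
infer_dispersal <- function(net, loc, sg, overrides = NULL,
                            reference_straits = NULL, report = NULL) {
  lus <- apply_isobath_merges(loc, sg)
  ev <- evidence_graph(net, lus, report)
  events <- minimize_events(ev, report)
  events <- flag_ambiguous(events, net, lus, overrides, report)
  summ <- summarize_lengths(events, reference_straits = reference_straits,
                            report = report)
  list(landunits = lus, evidence = ev, events = events, summary = summ)
}
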