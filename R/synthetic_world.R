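# Synthetic archipelago generator with known truth: two mainlands and
# four islands on a 0.1-degree grid, a west-east precipitation gradient
# with a shared climatic threshold splitting two deeply divergent
# cryptic species, planted over-sea colonizations of known number and
# length, star-like haplotype clouds, and presence points drawn from
# logistic suitability. Every quantity the pipeline infers is recorded
# in the truth object.

#' Default synthetic-world configuration
#'
#' The default world mimics the study system coarsely: a dry-adapted
#' western species (B) on the western mainland and two islands, a
#' wet-adapted eastern species (A) on the eastern mainland and two
#' islands, strait widths \{3, 5, 12, 90, 140\} km contrasting short
#' unobserved crossings (the 5 km contact strait) with long observed
#' ones, one islet merged into the western mainland at the reference
#' isobath, and a precipitation-of-driest-quarter gradient of 10 mm per
#' degree with the species threshold at 62 mm.
#'
#' @param seed Root seed; the world, haplotype and presence stages use
#'   substreams seed, seed+1, seed+2.
#' @return A configuration list.
#' @export
default_world_config <- function(seed = 1) {
  units <- data.frame(
    name    = c("MainlandW", "Islet0", "Island1", "Island2", "Island3",
                "Island4", "MainlandE"),
    lon_min = c(0.2, 3.0, 3.4, 4.4, 5.2, 6.2, 7.2),
    lon_max = c(2.8, 3.4, 4.2, 5.2, 6.0, 6.8, 9.8),
    lat_min = c(41.2, 43.8, 43.0, 43.0, 41.8, 42.2, 41.2),
    lat_max = c(44.8, 44.4, 43.8, 43.8, 42.6, 42.8, 44.8),
    stringsAsFactors = FALSE)
  straits <- data.frame(
    from = c("MainlandW", "MainlandW", "Island1", "Island2", "Island3",
             "Island4"),
    to   = c("Islet0", "Island1", "Island2", "Island3", "Island4",
             "MainlandE"),
    km   = c(0, 12, 3, 5, 90, 140),
    stringsAsFactors = FALSE)
  list(
    seed = seed,
    lon0 = 0, lat0 = 41, ncols = 100, nrows = 40, cellsize = 0.1,
    units = units,
    merges = data.frame(unit = "Islet0", absorbed_into = "MainlandW",
                        stringsAsFactors = FALSE),
    straits = straits,
    # climate: signal = 10 mm/deg lon + 10, sd-4 noise; decoy correlated
    # with the signal at r > 0.9 (and mildly with the noise layer, as
    # real bioclim decoys are); independent temperature-like noise layer
    clim_intercept = 10, clim_slope = 10, clim_noise_sd = 4,
    threshold = 62, softening = 12,
    species = list(
      A = list(units = c("MainlandE", "Island4", "Island3"),
               colonizations = data.frame(
                 from = c("MainlandE", "Island4"),
                 to = c("Island4", "Island3"), stringsAsFactors = FALSE),
               direction = +1),
      B = list(units = c("MainlandW", "Islet0", "Island1", "Island2"),
               colonizations = data.frame(
                 from = c("MainlandW", "MainlandW", "Island1"),
                 to = c("Islet0", "Island1", "Island2"),
                 stringsAsFactors = FALSE),
               direction = -1)),
    seq_length = 658, interspecies_diff = 30,
    colonization_rate = 2, satellite_prob = 0.25,
    n_localities = 2, n_specimens = 3, n_ambiguous = 1,
    prevalence = 0.5
  )
}

# unit name of each raster cell (character matrix, NA = sea)
cell_units <- function(cfg) {
  lon <- cfg$lon0 + (seq_len(cfg$ncols) - 0.5) * cfg$cellsize
  lat <- cfg$lat0 + (cfg$nrows - seq_len(cfg$nrows) + 0.5) * cfg$cellsize
  u <- matrix(NA_character_, cfg$nrows, cfg$ncols)
  for (k in seq_len(nrow(cfg$units))) {
    r <- cfg$units[k, ]
    rows <- which(lat > r$lat_min & lat < r$lat_max)
    cols <- which(lon > r$lon_min & lon < r$lon_max)
    if (any(!is.na(u[rows, cols])))
      stop("overlapping land-unit polygons at ", r$name)
    u[rows, cols] <- r$name
  }
  u
}

#' Generate the synthetic world: climate rasters, straits, unit map
#'
#' The climate stack holds the signal variable (precipitation of the
#' driest quarter, a longitude gradient plus noise), a decoy correlated
#' with it at |r| > 0.9, and an independent noise layer, exercising
#' variable selection and importance attribution downstream.
#'
#' @param cfg Configuration from \code{\link{default_world_config}}.
#' @return List of class \code{chequer_world}: cfg, rasters (named
#'   list), straits, unit_map (character matrix), truth.
#' @export
generate_world <- function(cfg = default_world_config()) {
  umap <- cell_units(cfg)
  land <- !is.na(umap)
  if (!any(land)) stop("no land cells in configuration")
  set.seed(cfg$seed)
  lon <- cfg$lon0 + (seq_len(cfg$ncols) - 0.5) * cfg$cellsize
  base <- matrix(rep(cfg$clim_intercept + cfg$clim_slope * lon,
                     each = cfg$nrows), cfg$nrows, cfg$ncols)
  n_land <- sum(land)
  signal <- matrix(NA_real_, cfg$nrows, cfg$ncols)
  signal[land] <- base[land] + stats::rnorm(n_land, 0, cfg$clim_noise_sd)
  sig_z <- (signal[land] - mean(signal[land])) / stats::sd(signal[land])
  noise <- matrix(NA_real_, cfg$nrows, cfg$ncols)
  noise[land] <- 15 + 5 * stats::rnorm(n_land)
  noi_z <- (noise[land] - mean(noise[land])) / stats::sd(noise[land])
  decoy <- matrix(NA_real_, cfg$nrows, cfg$ncols)
  decoy[land] <- 40 + 20 * (0.95 * sig_z + 0.2 * noi_z +
                              0.1 * stats::rnorm(n_land))
  mk <- function(m) raster_grid(m, cfg$lon0, cfg$lat0, cfg$cellsize)
  rng <- range(signal[land])
  if (cfg$threshold <= rng[1] || cfg$threshold >= rng[2])
    stop("species threshold outside the generated climate range")
  sg <- strait_graph(cfg$units$name, cfg$merges, cfg$straits)
  structure(list(
    cfg = cfg,
    rasters = list(precip_driest = mk(signal), precip_decoy = mk(decoy),
                   temp_noise = mk(noise)),
    straits = sg, unit_map = umap,
    truth = list(signal_var = "precip_driest", decoy_var = "precip_decoy",
                 noise_var = "temp_noise", threshold = cfg$threshold,
                 uncorrelated_subset = c("precip_driest", "temp_noise"),
                 contact_units = c("Island2", "Island3"),
                 contact_strait_km = 5)),
    class = "chequer_world")
}

# mutate k distinct sites of a sequence, each to a different base
mutate_sites <- function(seq_chars, k) {
  if (k == 0) return(seq_chars)
  k <- min(k, length(seq_chars))
  sites <- sample.int(length(seq_chars), k)
  for (s in sites) {
    seq_chars[s] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[s]), 1)
  }
  seq_chars
}

#' Simulate haplotype evolution with planted colonizations
#'
#' Each species starts from an ancestral sequence on its mainland; each
#' planted colonization copies the source unit's founder and applies
#' Poisson-distributed substitutions at distinct sites; specimens are
#' unit founders with low-probability single-site satellite mutations
#' (star-like clouds). The two species differ at a fixed number of
#' planted sites (deep cryptic divergence). A configurable number of
#' specimens per species receives an N to exercise ambiguity exclusion.
#'
#' @param world A \code{chequer_world}.
#' @return List: \code{aln} (\code{chequer_alignment}), \code{loc}
#'   (locality table with true species labels and land units),
#'   \code{truth} (per-species colonization table with realized
#'   mutational steps, expected event counts and lengths).
#' @export
simulate_haplotypes <- function(world) {
  cfg <- world$cfg
  set.seed(cfg$seed + 1L)
  L <- cfg$seq_length
  anc <- list()
  anc$A <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  anc$B <- mutate_sites(anc$A, cfg$interspecies_diff)

  umap <- world$unit_map
  cc_lon <- cfg$lon0 + (seq_len(cfg$ncols) - 0.5) * cfg$cellsize
  cc_lat <- cfg$lat0 + (cfg$nrows - seq_len(cfg$nrows) + 0.5) * cfg$cellsize

  ids <- character(0); seqs <- character(0)
  loc <- list()
  truth_col <- list()
  for (sp in names(cfg$species)) {
    spc <- cfg$species[[sp]]
    founders <- list()
    founders[[spc$units[1]]] <- anc[[sp]]
    cols <- spc$colonizations
    cols$steps <- NA_integer_
    cols$km <- NA_real_
    for (k in seq_len(nrow(cols))) {
      src <- founders[[cols$from[k]]]
      if (is.null(src)) stop("colonization from unoccupied unit ",
                             cols$from[k])
      steps <- stats::rpois(1, cfg$colonization_rate)
      founders[[cols$to[k]]] <- mutate_sites(src, steps)
      cols$steps[k] <- steps
      cols$km[k] <- world$straits$km[cols$from[k], cols$to[k]]
    }
    truth_col[[sp]] <- cols
    for (u in spc$units) {
      cells <- which(umap == u, arr.ind = TRUE)
      take <- cells[sample.int(nrow(cells), cfg$n_localities), ,
                    drop = FALSE]
      for (li in seq_len(nrow(take))) {
        lname <- paste0(sp, "_", u, "_L", li)
        for (si in seq_len(cfg$n_specimens)) {
          sid <- paste0(lname, "_", si)
          s <- founders[[u]]
          if (stats::runif(1) < cfg$satellite_prob) s <- mutate_sites(s, 1)
          ids <- c(ids, sid)
          seqs <- c(seqs, paste(s, collapse = ""))
          loc[[length(loc) + 1L]] <- data.frame(
            specimen_id = sid, species = sp,
            lat = cc_lat[take[li, 1]], lon = cc_lon[take[li, 2]],
            locality = lname, land_unit = u, stringsAsFactors = FALSE)
        }
      }
    }
    # plant ambiguous bases on n_ambiguous specimens of this species
    sp_idx <- grep(paste0("^", sp, "_"), ids)
    amb <- sample(sp_idx, min(cfg$n_ambiguous, length(sp_idx)))
    for (i in amb) {
      ch <- strsplit(seqs[i], "")[[1]]
      ch[sample.int(L, 1)] <- "N"
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  loc <- do.call(rbind, loc)
  # planted event counts: colonizations between distinct effective units
  eff <- stats::setNames(cfg$units$name, cfg$units$name)
  if (nrow(cfg$merges)) eff[cfg$merges$unit] <- cfg$merges$absorbed_into
  truth <- list(colonizations = truth_col,
                planted_events = vapply(truth_col, function(tc)
                  sum(eff[tc$from] != eff[tc$to]), integer(1)),
                planted_lengths = lapply(truth_col, function(tc)
                  tc$km[eff[tc$from] != eff[tc$to]]),
                species = stats::setNames(loc$species, loc$specimen_id))
  list(aln = alignment(ids, seqs), loc = validate_locality_table(loc),
       truth = truth)
}

#' Simulate presence points from logistic suitability
#'
#' Species A occupies cells with climate above the threshold, species B
#' below, with logistic edge-softening; each species occurs only inside
#' its occupied land units (mutual exclusion on islands). Each candidate
#' cell enters independently with probability
#' prevalence * plogis(direction * (climate - t) / softening).
#'
#' @param world A \code{chequer_world}.
#' @param mask_units If TRUE (default), each species is restricted to
#'   its occupied land units (mutual exclusion on islands); if FALSE,
#'   presences follow the climatic logistic over all land, giving the
#'   pure 1-D threshold world used for response-recovery checks.
#' @return List per species of data.frame (lon, lat), plus
#'   \code{truth} (suitable-cell counts and inclusion probabilities).
#' @export
simulate_presences <- function(world, mask_units = TRUE) {
  cfg <- world$cfg
  set.seed(cfg$seed + 2L)
  clim <- world$rasters$precip_driest
  cc <- raster_cell_centers(clim)
  out <- list()
  truth <- list()
  for (sp in names(cfg$species)) {
    spc <- cfg$species[[sp]]
    in_units <- if (mask_units) world$unit_map %in% spc$units else
      !is.na(world$unit_map)
    cand <- which(in_units & !is.na(clim$values), arr.ind = TRUE)
    v <- clim$values[cand]
    p <- stats::plogis(spc$direction * (v - cfg$threshold) / cfg$softening)
    if (!any(p > 0.5)) stop("species ", sp, " has no suitable cell")
    inc <- stats::runif(length(p)) < p * cfg$prevalence
    if (!any(inc)) stop("no presence sampled for species ", sp)
    out[[sp]] <- data.frame(lon = cc$lon[cand[inc, 2]],
                            lat = cc$lat[cand[inc, 1]])
    truth[[sp]] <- list(n_candidate = length(p), expected = sum(p) *
                          cfg$prevalence, n_sampled = sum(inc))
  }
  c(out, list(truth = truth))
}

#' Write a simulated world to disk in the package's external formats
#'
#' Emits the alignment (FASTA), locality table and occurrences (CSV),
#' strait configuration (CSV), climate stack (ESRI ASCII grids) and the
#' truth record (JSON).
#'
#' @param world A \code{chequer_world}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
emit_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_haplotypes(world)
  occ <- simulate_presences(world)
  cfg <- world$cfg
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             loc = file.path(dir, "localities.csv"),
             straits = file.path(dir, "straits.csv"),
             truth = file.path(dir, "truth.json"))
  write_fasta(sim$aln, paths["fasta"])
  utils::write.csv(sim$loc, paths["loc"], row.names = FALSE)
  scsv <- rbind(
    data.frame(type = "unit", from = cfg$units$name, to = "", km = NA),
    data.frame(type = "merge", from = cfg$merges$unit,
               to = cfg$merges$absorbed_into, km = NA),
    data.frame(type = "distance", from = cfg$straits$from,
               to = cfg$straits$to, km = cfg$straits$km))
  utils::write.csv(scsv, paths["straits"], row.names = FALSE, na = "")
  for (nm in names(world$rasters)) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_raster(world$rasters[[nm]], p)
    paths[nm] <- p
  }
  for (sp in setdiff(names(occ), "truth")) {
    p <- file.path(dir, paste0("occurrences_", sp, ".csv"))
    utils::write.csv(occ[[sp]], p, row.names = FALSE)
    paths[paste0("occ_", sp)] <- p
  }
  jsonlite::write_json(
    list(planted_events = as.list(sim$truth$planted_events),
         planted_lengths = sim$truth$planted_lengths,
         threshold = world$truth$threshold,
         signal_var = world$truth$signal_var,
         uncorrelated_subset = world$truth$uncorrelated_subset,
         contact_units = world$truth$contact_units),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
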