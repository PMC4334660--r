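# Readers/writers for the external formats, plus the run-report logger.
# Downstream modules consume only the in-memory types built here; no
# other module touches files directly.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
VALID_BASES <- c("A", "C", "G", "T", "N", "-", IUPAC_AMBIG)

#' Construct an alignment of equal-length nucleotide sequences
#'
#' @param ids Character vector of unique specimen ids.
#' @param seqs Character vector of upper-case nucleotide strings, all the
#'   same length.
#' @return An object of class \code{chequer_alignment} with elements
#'   \code{ids}, \code{seqs} and \code{length} (number of sites).
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) {
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  lens <- nchar(seqs)
  if (length(seqs) == 0) stop("empty alignment")
  if (any(lens != lens[1])) {
    bad <- ids[which(lens != lens[1])[1]]
    stop("sequence length mismatch at record '", bad, "' (",
         lens[which(lens != lens[1])[1]], " vs ", lens[1], " sites)")
  }
  letters_used <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  unknown <- setdiff(letters_used, VALID_BASES)
  if (length(unknown)) {
    stop("invalid characters in alignment: ", paste(unknown, collapse = ", "))
  }
  structure(list(ids = ids, seqs = seqs, length = lens[1]),
            class = "chequer_alignment")
}

#' @export
print.chequer_alignment <- function(x, ...) {
  cat("Alignment:", length(x$ids), "sequences x", x$length, "sites\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Ids are the first whitespace-delimited token of each header; sequences
#' are upper-cased. All records must have the same length.
#'
#' @param path Path to a FASTA file.
#' @return A \code{chequer_alignment}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                   error = function(e) NULL)
  if (is.null(recs) || length(recs) == 0)
    stop("FASTA format error: no records in ", path)
  ids <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1)
  seqs <- vapply(as.character(recs), function(s)
    paste(toupper(s), collapse = ""), character(1))
  alignment(ids, unname(seqs))
}

#' Write an alignment to FASTA
#'
#' @param aln A \code{chequer_alignment}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "chequer_alignment"))
  lines <- character(2L * length(aln$ids))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$ids)
  lines[c(FALSE, TRUE)] <- aln$seqs
  writeLines(lines, path)
  invisible(path)
}

#' Read a specimen locality table
#'
#' Comma-separated, UTF-8, mandatory header with at least columns
#' \code{specimen_id, species, lat, lon, locality}; an optional
#' \code{land_unit} column names the land unit of each locality.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with validated coordinates and unique ids.
#' @export
read_locality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  validate_locality_table(df)
}

#' Validate a locality table held in a data.frame
#'
#' @param df A data.frame shaped like the locality CSV.
#' @return The validated data.frame (land_unit column added as NA if absent).
#' @export
validate_locality_table <- function(df) {
  need <- c("specimen_id", "species", "lat", "lon", "locality")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("locality table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"land_unit" %in% names(df)) df$land_unit <- NA_character_
  df$specimen_id <- as.character(df$specimen_id)
  if (anyDuplicated(df$specimen_id)) {
    stop("duplicate specimen_id: ",
         paste(unique(df$specimen_id[duplicated(df$specimen_id)]), collapse = ", "))
  }
  if (any(!is.finite(df$lat)) || any(df$lat < -90 | df$lat > 90))
    stop("latitude out of [-90, 90]")
  if (any(!is.finite(df$lon)) || any(df$lon < -180 | df$lon > 180))
    stop("longitude out of [-180, 180]")
  df
}

#' Build a strait graph
#'
#' Land units joined by sea straits at a reference isobath. Pairs without
#' a listed strait have infinite distance (no direct crossing); merged
#' units (islands inside the same isobath contour as a mainland) have
#' distance 0 and are absorbed during dispersal scoring.
#'
#' @param units Character vector of land-unit names.
#' @param merges Two-column data.frame or matrix (unit, absorbed_into).
#' @param distances Data.frame with columns \code{from, to, km}.
#' @return An object of class \code{chequer_straits} with \code{units},
#'   \code{merges}, and a symmetric \code{km} matrix (Inf = no strait).
#' @export
strait_graph <- function(units, merges = NULL, distances = NULL) {
  units <- as.character(units)
  if (anyDuplicated(units)) stop("duplicate unit names")
  n <- length(units)
  km <- matrix(Inf, n, n, dimnames = list(units, units))
  diag(km) <- 0
  if (!is.null(merges) && nrow(merges) > 0) {
    merges <- as.data.frame(merges, stringsAsFactors = FALSE)
    names(merges)[1:2] <- c("unit", "absorbed_into")
    bad <- setdiff(unlist(merges[, 1:2]), units)
    if (length(bad)) stop("merge references unknown unit(s): ",
                          paste(bad, collapse = ", "))
    for (r in seq_len(nrow(merges))) {
      km[merges$unit[r], merges$absorbed_into[r]] <- 0
      km[merges$absorbed_into[r], merges$unit[r]] <- 0
    }
  } else {
    merges <- data.frame(unit = character(0), absorbed_into = character(0),
                         stringsAsFactors = FALSE)
  }
  if (!is.null(distances) && nrow(distances) > 0) {
    for (r in seq_len(nrow(distances))) {
      a <- as.character(distances$from[r]); b <- as.character(distances$to[r])
      d <- as.numeric(distances$km[r])
      if (!(a %in% units) || !(b %in% units))
        stop("distance entry references unknown unit: ", a, "-", b)
      if (!is.finite(d) || d < 0) stop("invalid strait distance ", d,
                                       " for ", a, "-", b)
      if (is.finite(km[a, b]) && km[a, b] != d && !(a == b))
        stop("conflicting distance entries for ", a, "-", b,
             ": ", km[a, b], " vs ", d)
      km[a, b] <- d; km[b, a] <- d
    }
  }
  structure(list(units = units, merges = merges, km = km),
            class = "chequer_straits")
}

#' Read a strait/land-unit configuration CSV
#'
#' One row per declaration; columns \code{type, from, to, km} with
#' \code{type} in \{unit, merge, distance\}. \code{unit} rows name a land
#' unit (\code{from}); \code{merge} rows absorb \code{from} into \code{to};
#' \code{distance} rows give the sea-crossing width in km between
#' \code{from} and \code{to} at the reference isobath.
#'
#' @param path Path to the configuration CSV.
#' @return A \code{chequer_straits}.
#' @export
read_strait_config <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("type", "from", "to", "km")
  if (!all(need %in% names(df)))
    stop("strait config must have columns: ", paste(need, collapse = ", "))
  units <- df$from[df$type == "unit"]
  merges <- df[df$type == "merge", c("from", "to")]
  names(merges) <- c("unit", "absorbed_into")
  dist <- df[df$type == "distance", c("from", "to", "km")]
  strait_graph(units, merges, dist)
}

#' Construct a raster grid
#'
#' Lower-left corner origin; row 1 of \code{values} is the northernmost
#' row (standard ESRI ASCII layout). Coordinates are WGS84 decimal degrees.
#'
#' @param values Numeric matrix (nrows x ncols); NA marks nodata.
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell size in decimal degrees (> 0).
#' @param nodata Sentinel written for NA cells (default -9999).
#' @return An object of class \code{chequer_raster}.
#' @export
raster_grid <- function(values, xll, yll, cellsize, nodata = -9999) {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || cellsize <= 0) stop("cellsize must be > 0")
  structure(list(values = values, nrows = nrow(values), ncols = ncol(values),
                 xll = xll, yll = yll, cellsize = cellsize, nodata = nodata),
            class = "chequer_raster")
}

#' @export
print.chequer_raster <- function(x, ...) {
  cat(sprintf("Raster: %d x %d cells of %g deg, origin (%g, %g)\n",
              x$nrows, x$ncols, x$cellsize, x$xll, x$yll))
  invisible(x)
}

# Cell-center coordinates. Row 1 is the northernmost row.
raster_cell_centers <- function(r) {
  lon <- r$xll + (seq_len(r$ncols) - 0.5) * r$cellsize
  lat <- r$yll + (r$nrows - seq_len(r$nrows) + 0.5) * r$cellsize
  list(lon = lon, lat = lat)
}

# Row/col of the cell containing (lon, lat); NA if outside the extent.
raster_cell_index <- function(r, lon, lat) {
  col <- floor((lon - r$xll) / r$cellsize) + 1
  row <- r$nrows - floor((lat - r$yll) / r$cellsize)
  bad <- col < 1 | col > r$ncols | row < 1 | row > r$nrows
  col[bad] <- NA; row[bad] <- NA
  cbind(row = row, col = col)
}

#' Read an ESRI ASCII grid
#'
#' Header keys \code{ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value} (case-insensitive), then nrows x ncols values, row 1 =
#' northernmost.
#'
#' @param path Path to the .asc file.
#' @return A \code{chequer_raster}; nodata cells are NA.
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("ASCII grid header incomplete in ", path)
  nodata <- if ("nodata_value" %in% names(hdr)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ", nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Values are written with enough precision that write-then-read
#' reproduces them to at least 6 decimal places.
#'
#' @param r A \code{chequer_raster}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(r, path) {
  stopifnot(inherits(r, "chequer_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", r$ncols),
    paste("nrows", r$nrows),
    paste("xllcorner", format(r$xll, digits = 12)),
    paste("yllcorner", format(r$yll, digits = 12)),
    paste("cellsize", format(r$cellsize, digits = 12)),
    paste("NODATA_value", format(r$nodata, digits = 12))
  ), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  for (row in seq_len(r$nrows)) {
    writeLines(paste(formatC(m[row, ], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

# ---- run report -----------------------------------------------------------

#' Create a run report collector
#'
#' Every pipeline stage records its input counts, exclusions and selected
#' parameters here, so that the decisions the results hinge on are
#' auditable. The report is a mutable environment written out as JSON.
#'
#' @return An object of class \code{chequer_report}.
#' @export
run_report <- function() {
  e <- new.env(parent = emptyenv())
  e$entries <- list()
  structure(e, class = "chequer_report")
}

#' Record an entry in a run report
#'
#' @param report A \code{chequer_report} (or NULL, in which case this is
#'   a no-op so stages can run without a collector).
#' @param stage Name of the pipeline stage.
#' @param ... Named values to record.
#' @return The report, invisibly.
#' @export
report_log <- function(report, stage, ...) {
  if (is.null(report)) return(invisible(NULL))
  stopifnot(inherits(report, "chequer_report"))
  entry <- list(...)
  report$entries[[length(report$entries) + 1L]] <-
    c(list(stage = stage), entry)
  invisible(report)
}

#' Write a run report to JSON
#'
#' @param report A \code{chequer_report}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "chequer_report"))
  jsonlite::write_json(report$entries, path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
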