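#' @include AllClasses.R
NULL

#' Construct an OccurrenceSet
#'
#' @param longitude,latitude numeric vectors (degrees, WGS84)
#' @param allele character vector of allele labels
#' @param provenance free-text note on origin
#' @return an \linkS4class{OccurrenceSet}
#' @export
occurrenceSet <- function(longitude, latitude, allele, provenance = "") {
  rec <- data.frame(longitude = as.numeric(longitude),
                    latitude = as.numeric(latitude),
                    allele = as.character(allele),
                    stringsAsFactors = FALSE)
  new("OccurrenceSet", records = rec, provenance = provenance)
}

#' Read occurrences from headered delimited text
#'
#' Expects columns \code{longitude}, \code{latitude}, \code{allele}
#' (comma- or tab-delimited, autodetected from the header line).
#'
#' @param path file path
#' @param provenance provenance note (default: the path)
#' @export
readOccurrences <- function(path, provenance = path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("longitude", "latitude", "allele")
  if (!all(need %in% names(df)))
    stop("occurrence table must have columns: ",
         paste(need, collapse = ", "))
  occurrenceSet(df$longitude, df$latitude, df$allele, provenance)
}

#' Write occurrences as headered CSV
#'
#' @param occ an OccurrenceSet
#' @param path output path
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ@records[c("longitude", "latitude", "allele")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Great-circle distance matrix (haversine, Earth radius 6371 km)
#' @noRd
haversineKm <- function(lon, lat) {
  n <- length(lon)
  m <- matrix(0, n, n)
  if (n < 2L) return(m)
  pts <- cbind(lon, lat)
  for (i in seq_len(n - 1L)) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[(i + 1L):n, , drop = FALSE],
                                  r = 6371000) / 1000
    m[i, (i + 1L):n] <- d
    m[(i + 1L):n, i] <- d
  }
  m
}

#' Spatially thin occurrences to a minimum pairwise distance
#'
#' Greedy, input-order thinning applied independently per allele: a record
#' is kept iff its great-circle distance (haversine, Earth radius 6371 km)
#' to every already-kept record of the same allele is at least
#' \code{minDistanceKm} (inclusive: exactly the threshold is kept). A site
#' shared by both alleles is thinned once per allele, so dual-type sites
#' survive as two records.
#'
#' @param occ an OccurrenceSet
#' @param minDistanceKm minimum pairwise distance (km); 0 returns the
#'   input unchanged
#' @return thinned OccurrenceSet (same record order)
#' @export
thinOccurrences <- function(occ, minDistanceKm) {
  stopifnot(minDistanceKm >= 0)
  rec <- occ@records
  if (nrow(rec) == 0L || minDistanceKm == 0) return(occ)
  keep <- logical(nrow(rec))
  for (al in unique(rec$allele)) {
    idx <- which(rec$allele == al)
    kept <- integer()
    for (i in idx) {
      if (length(kept) == 0L) { keep[i] <- TRUE; kept <- i; next }
      d <- geosphere::distHaversine(
        cbind(rec$longitude[i], rec$latitude[i]),
        cbind(rec$longitude[kept], rec$latitude[kept]),
        r = 6371000) / 1000
      # inclusive threshold, with a micron of slack for haversine rounding
      if (all(d >= minDistanceKm - 1e-9)) {
        keep[i] <- TRUE; kept <- c(kept, i)
      }
    }
  }
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("OccurrenceSet", records = out,
      provenance = sprintf("%s; thinned to >= %g km",
                           occ@provenance, minDistanceKm))
}
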