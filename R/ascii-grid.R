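#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, NODATA_value) followed by nrows rows of
#' ncols whitespace-separated values, row 1 = north. Centre registration is
#' converted to corner registration internally.
#'
#' @param path file path
#' @return list with \code{values} (numeric matrix, NoData as NA),
#'   \code{xll}, \code{yll}, \code{cellsize}, \code{nodata}
#' @export
readAsciiGrid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1]) &&
        !is.na(suppressWarnings(as.numeric(tok[2])))) {
      hdr[[tolower(tok[1])]] <- as.numeric(tok[2]); i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header keys): ", path)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  cs <- hdr$cellsize
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - cs / 2
  else stop("missing xllcorner/xllcenter in ", path)
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - cs / 2
  else stop("missing yllcorner/yllcenter in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- paste(lines[(i + 1L):length(lines)], collapse = " ")
  vals <- as.numeric(strsplit(trimws(body), "\\s+")[[1]])
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s",
                 nr * nc, length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m, xll = xll, yll = yll, cellsize = cs, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values numeric matrix, row 1 = north; NA written as the NoData
#'   sentinel
#' @param path output path
#' @param xll,yll lower-left corner (degrees)
#' @param cellsize cell edge (degrees)
#' @param nodata NoData sentinel (default -9999)
#' @param digits significant digits for values; the default 17 round-trips
#'   doubles exactly
#' @export
writeAsciiGrid <- function(values, path, xll, yll, cellsize,
                           nodata = -9999, digits = 17) {
  stopifnot(is.matrix(values))
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    paste("xllcorner", format(xll, digits = 15)),
    paste("yllcorner", format(yll, digits = 15)),
    paste("cellsize", format(cellsize, digits = 15)),
    paste("NODATA_value", format(nodata))
  ), con)
  writeLines(apply(v, 1L, function(r)
    paste(sprintf("%.*g", digits, r), collapse = " ")), con)
  invisible(path)
}
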