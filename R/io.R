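#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster format (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value` header
#' followed by rows of numbers, northernmost row first).
#'
#' @param path Path to a `.asc` file.
#' @return A list with `values` (numeric matrix, `n_rows x n_cols`, row 1 =
#'   southernmost grid row so that `values[r, c]` matches the package's
#'   south-west-origin cell indexing), `xllcorner`, `yllcorner`, `cellsize`
#'   and `nodata`.
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  repeat {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(tok[2])
      i <- i + 1L
    } else {
      break
    }
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[k]])) stop("missing ESRI ASCII header field: ", k)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    stop("ESRI ASCII body has ", length(vals), " values, expected ", nc * nr)
  }
  # file rows run north -> south; store south row first
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE]
  nodata <- hdr$nodata_value
  if (!is.null(nodata)) m[m == nodata] <- NA_real_
  list(values = m, xllcorner = hdr$xllcorner, yllcorner = hdr$yllcorner,
       cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param values Numeric matrix, `n_rows x n_cols`, row 1 = southernmost row.
#' @param path Output path.
#' @param xllcorner,yllcorner Coordinates of the south-west corner.
#' @param cellsize Cell edge length (same units as the corner coordinates).
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(values, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1, nodata = -9999) {
  stopifnot(is.matrix(values))
  nr <- nrow(values)
  nc <- ncol(values)
  m <- values[nr:1, , drop = FALSE]
  m[is.na(m)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(xllcorner, scientific = FALSE)),
    paste("yllcorner", format(yllcorner, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)
  ), con)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
  invisible(path)
}
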