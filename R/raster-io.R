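#' Reclassify a categorical land-cover raster into a binary landscape
#'
#' Cells whose class code is in `focus_codes` become focus (`+1`); every
#' other cell, including nodata, becomes background (`-1`). Mapping nodata to
#' background (with a warning) is the package's policy: the two-state model
#' has no third category.
#'
#' @param raster An integer matrix of land-cover class codes (must be
#'   square).
#' @param focus_codes Non-empty vector of integer class codes to treat as
#'   the focus category.
#' @param nodata_code Optional code marking missing cells.
#' @return A [landscape] with the same dimensions.
#' @examples
#' codes <- matrix(c(42, 41, 42, 11), 2, 2)
#' reclassify(codes, focus_codes = 42)
#' @export
reclassify <- function(raster, focus_codes, nodata_code = NULL) {
  if (!is.matrix(raster)) stop("`raster` must be a matrix of class codes", call. = FALSE)
  if (nrow(raster) != ncol(raster)) {
    stop("raster must be square (got ", nrow(raster), " x ", ncol(raster), ")",
         call. = FALSE)
  }
  if (length(focus_codes) < 1) stop("`focus_codes` must be non-empty", call. = FALSE)
  if (!is.null(nodata_code)) {
    if (nodata_code %in% focus_codes) {
      stop("`nodata_code` may not be a focus code", call. = FALSE)
    }
    n_missing <- sum(raster == nodata_code)
    if (n_missing > 0) {
      warning(n_missing, " nodata cell(s) mapped to background", call. = FALSE)
    }
  }
  out <- matrix(-1L, nrow(raster), ncol(raster))
  out[raster %in% focus_codes] <- 1L
  landscape(out)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    asc = "ascii_grid", txt = "ascii_grid",
    tif = "geotiff", tiff = "geotiff",
    png = "png_preview",
    stop("cannot guess raster format from extension '.", ext, "'", call. = FALSE)
  )
}

read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-+0-9.eE]+\\s*$", lines[i])) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(tok[1])]] <- as.numeric(tok[2])
    i <- i + 1
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows)) {
    stop("not an Esri ASCII grid: missing ncols/nrows header in ", path, call. = FALSE)
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         hdr$ncols * hdr$nrows, call. = FALSE)
  }
  # row-major body, row 1 = top
  m <- matrix(as.integer(vals), nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  attr(m, "nodata_code") <- if (!is.null(hdr$nodata_value)) as.integer(hdr$nodata_value) else NULL
  m
}

write_ascii_grid <- function(values, path, nodata = -9999L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    "xllcorner 0",
    "yllcorner 0",
    "cellsize 1",
    paste("NODATA_value", nodata)
  ), con)
  utils::write.table(values, con, row.names = FALSE, col.names = FALSE)
}

#' Read a landscape from a raster file
#'
#' Supported formats: Esri ASCII grid (`.asc`/`.txt`) and single-band TIFF
#' (`.tif`/`.tiff`; class codes must fit in 0..255). If `focus_codes` is
#' given, the decoded grid is passed through [reclassify()]; otherwise the
#' file must already be binary, either `{0, 1}` (0 is recoded to background)
#' or `{-1, +1}`.
#'
#' @param path File to read.
#' @param format `"ascii_grid"`, `"geotiff"`, or `"auto"` (guess from the
#'   extension).
#' @param focus_codes Optional class codes defining the focus category.
#' @param nodata_code Optional nodata code forwarded to [reclassify()].
#' @return A [landscape].
#' @export
read_landscape <- function(path, format = c("auto", "ascii_grid", "geotiff"),
                           focus_codes = NULL, nodata_code = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  m <- switch(format,
    ascii_grid = {
      g <- read_ascii_grid(path)
      if (is.null(nodata_code)) nodata_code <- attr(g, "nodata_code")
      attr(g, "nodata_code") <- NULL
      g
    },
    geotiff = {
      v <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(v)) == 3) v <- v[, , 1]
      matrix(as.integer(v), nrow(v), ncol(v))
    },
    stop("unsupported read format: ", format, call. = FALSE)
  )
  if (!is.null(focus_codes)) {
    return(reclassify(m, focus_codes, nodata_code = nodata_code))
  }
  vals <- unique(as.vector(m))
  if (all(vals %in% c(0L, 1L)) || all(vals %in% c(-1L, 1L))) {
    return(as_landscape(m))
  }
  stop("raster is not binary; pass `focus_codes` to reclassify it", call. = FALSE)
}

#' Write a landscape to a raster file
#'
#' Binary rasters are written with the GIS-friendly `{0, 1}` encoding
#' (background 0, focus 1); the in-memory `{-1, +1}` encoding is restored on
#' read. `png_preview` writes a colour image with focus cells green and
#' background cells yellow.
#'
#' @param x A [landscape].
#' @param path Output file.
#' @param format `"ascii_grid"`, `"geotiff"`, `"png_preview"`, or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(x, path,
                            format = c("auto", "ascii_grid", "geotiff", "png_preview")) {
  x <- as_landscape(x)
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  zero_one <- matrix(as.integer(x == 1L), nrow(x), ncol(x))
  switch(format,
    ascii_grid = write_ascii_grid(zero_one, path),
    geotiff = tiff::writeTIFF(zero_one / 255, path, bits.per.sample = 8),
    png_preview = {
      img <- array(0, dim = c(nrow(x), ncol(x), 3))
      focus <- x == 1L
      for (ch in 1:3) {
        col_focus <- c(0.10, 0.59, 0.25)[ch]
        col_back <- c(0.95, 0.89, 0.26)[ch]
        img[, , ch] <- ifelse(focus, col_focus, col_back)
      }
      png::writePNG(img, path)
    },
    stop("unsupported write format: ", format, call. = FALSE)
  )
  invisible(path)
}
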