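# Raster and report I/O. Images are h x w x 3 arrays in [0, 1];
# PNG via the png package, TIFF via tiff when available.

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    return(tiff::readTIFF(path))
  }
  stop("unsupported raster format: .", ext, call. = FALSE)
}

#' Read an RGB image
#'
#' Reads a PNG or TIFF file into an `h x w x 3` numeric array in
#' `[0, 1]`. Grayscale images are replicated across channels; an alpha
#' channel is dropped.
#'
#' @param path file path.
#' @return Numeric array `h x w x 3`.
#' @export
read_image <- function(path) {
  x <- read_raster(path)
  if (length(dim(x)) == 2) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] < 3) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3))
  x
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image numeric array `h x w x 3` in `[0, 1]`.
#' @param path output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

# JSON report helpers: one-row tibbles <-> JSON objects.
write_report_json <- function(report, path, meta = NULL) {
  x <- as.list(report)
  if (!is.null(meta)) x$metadata <- meta
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a long-format results table
#'
#' Reads a CSV with the columns `image_id, method, metric, value` (the
#' package's interchange format between measurement and agreement
#' analysis) and validates the schema, naming any missing column.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_results_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("image_id", "method", "metric", "value")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("results CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) df$value <- numeric(0)
  if (!is.numeric(df$value))
    stop("results CSV column 'value' must be numeric", call. = FALSE)
  df
}
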