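#' Construct a FLIM stack from a 3-D photon-count array
#'
#' A FLIM stack is a `rows x cols x n_bins` array of photon counts: pixel
#' `(i, j)` holds the arrival-time histogram of the photons detected at image
#' row `i` (row 1 is the top of the image) and column `j`. Counts must be
#' non-negative and finite; real-valued (non-integer) counts are accepted so
#' that noiseless expected-value histograms from the synthetic generator can
#' flow through the same code paths at machine precision.
#'
#' @param counts Non-negative numeric array `rows x cols x n_bins`
#'   (`n_bins >= 2`).
#' @param source_path Text identifier recorded in provenance, typically the
#'   file the stack was read from.
#' @return An object of class `flim_stack`.
#' @export
flim_stack <- function(counts, source_path = "<in-memory>") {
  if (!is.array(counts) || length(dim(counts)) != 3L)
    stop("counts must be a 3-D array (rows x cols x n_bins)")
  d <- dim(counts)
  if (d[1] < 1L || d[2] < 1L)
    stop("stack must have at least one row and one column")
  if (d[3] < 2L)
    stop("fewer than 2 temporal bins")
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts must be finite and non-missing")
  if (any(counts < 0))
    stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, source_path = source_path),
            class = "flim_stack")
}

#' Read a time-domain FLIM stack from a multi-page TIFF
#'
#' Each page of the TIFF is one temporal bin; page order is temporal order.
#' Integer sample formats are read verbatim; floating-point pages are
#' accepted if every value is non-negative and integral to within 1e-6
#' (some exporters store counts as float).
#'
#' @param path Path to a multi-page grayscale TIFF.
#' @return A [flim_stack()].
#' @export
read_flim_stack <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("fewer than 2 temporal bins in ", path)
  for (k in seq_along(pages)) {
    pg <- pages[[k]]
    if (!is.matrix(pg))
      stop(sprintf("page %d of %s is not single-channel grayscale", k, path))
    if (!identical(dim(pg), dim(pages[[1L]])))
      stop(sprintf("page %d of %s has dimensions %dx%d, expected %dx%d",
                   k, path, nrow(pg), ncol(pg),
                   nrow(pages[[1L]]), ncol(pages[[1L]])))
    if (any(pg < 0))
      stop(sprintf("negative values on page %d of %s", k, path))
    if (is.double(pg) && any(abs(pg - round(pg)) > 1e-6))
      stop(sprintf("non-integral photon counts on page %d of %s", k, path))
  }
  counts <- array(unlist(pages, use.names = FALSE),
                  dim = c(dim(pages[[1L]]), length(pages)))
  flim_stack(counts, source_path = path)
}

#' Write a FLIM stack as a multi-page 16-bit TIFF
#'
#' Inverse of [read_flim_stack()] for integer-valued stacks with per-bin
#' counts below 2^16; used to materialise synthetic fixtures in the same
#' dialect the reader consumes.
#'
#' @param stack A [flim_stack()]. Counts are rounded to integers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_flim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "flim_stack"))
  counts <- round(stack$counts)
  if (any(counts > 65535))
    stop("per-bin counts exceed the 16-bit range of the stack writer")
  pages <- lapply(seq_len(dim(counts)[3]),
                  function(k) counts[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' @export
print.flim_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("FLIM stack %d x %d pixels, %d temporal bins (%s)\n",
              d[1], d[2], d[3], x$source_path))
  cat(sprintf("  total photons: %.4g, mean per pixel: %.4g\n",
              sum(x$counts), sum(x$counts) / (d[1] * d[2])))
  invisible(x)
}

#' @export
dim.flim_stack <- function(x) dim(x$counts)
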