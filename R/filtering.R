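#' Pixel mask with provenance
#'
#' A boolean include grid plus the ordered list of criteria that produced
#' it. Masks combine by conjunction: a pixel survives only if it passes
#' every recorded criterion.
#'
#' @param include Logical matrix.
#' @param provenance List of records, each `list(criterion, lo, hi)`.
#' @return Object of class `flim_mask`.
#' @export
flim_mask <- function(include, provenance = list()) {
  stopifnot(is.matrix(include), is.logical(include))
  include[is.na(include)] <- FALSE
  structure(list(include = include, provenance = provenance),
            class = "flim_mask")
}

#' @export
print.flim_mask <- function(x, ...) {
  cat(sprintf("Mask %d x %d: %d of %d pixels included\n",
              nrow(x$include), ncol(x$include),
              sum(x$include), length(x$include)))
  for (p in x$provenance)
    cat(sprintf("  - %s in [%g, %g]\n", p$criterion, p$lo, p$hi))
  invisible(x)
}

#' Intensity threshold mask
#'
#' Keeps pixels whose total photon count lies in `[min_counts, max_counts]`
#' (both bounds inclusive). Dim pixels are the main source of noise-driven
#' out-of-range phasors, so a minimum-count threshold is the first filter
#' applied in practice.
#'
#' @param field A `phasor_field`.
#' @param min_counts Lower bound (>= 0).
#' @param max_counts Optional upper bound (> `min_counts`).
#' @return A [flim_mask()].
#' @export
intensity_mask <- function(field, min_counts, max_counts = Inf) {
  stopifnot(inherits(field, "phasor_field"))
  if (min_counts < 0) stop("min_counts must be non-negative")
  if (max_counts <= min_counts) stop("max_counts must exceed min_counts")
  flim_mask(field$intensity >= min_counts & field$intensity <= max_counts,
            list(list(criterion = "intensity", lo = min_counts,
                      hi = max_counts)))
}

#' Threshold mask on an arbitrary contrast map
#'
#' Keeps defined pixels whose map value lies in `[lo, hi]` (inclusive, so
#' widening the range never removes a pixel). Used for lifetime and
#' distance-based masking.
#'
#' @param map Numeric matrix (NaN = undefined).
#' @param lo,hi Bounds, `lo <= hi`.
#' @param criterion Label recorded in provenance.
#' @return A [flim_mask()].
#' @export
contrast_mask <- function(map, lo, hi, criterion = "contrast") {
  stopifnot(is.matrix(map))
  if (lo > hi) stop("inverted bounds: lo must not exceed hi")
  flim_mask(!is.na(map) & map >= lo & map <= hi,
            list(list(criterion = criterion, lo = lo, hi = hi)))
}

#' Combine two masks by conjunction
#'
#' @param a,b [flim_mask()]s of identical dimensions.
#' @return A [flim_mask()] including pixels present in both, with
#'   concatenated provenance.
#' @export
combine_masks <- function(a, b) {
  stopifnot(inherits(a, "flim_mask"), inherits(b, "flim_mask"))
  if (!identical(dim(a$include), dim(b$include)))
    stop("mask dimensions differ")
  flim_mask(a$include & b$include, c(a$provenance, b$provenance))
}

# NaN-aware 3x3 median with symmetric edge padding. Undefined neighbours are
# dropped from the window; an undefined centre pixel stays undefined.
median3x3 <- function(x) {
  r <- nrow(x); cc <- ncol(x)
  xp <- x[c(1L, seq_len(r), r), c(1L, seq_len(cc), cc), drop = FALSE]
  neigh <- matrix(NA_real_, r * cc, 9L)
  k <- 1L
  for (dj in 0:2) for (di in 0:2) {
    neigh[, k] <- xp[di + seq_len(r), dj + seq_len(cc)]
    k <- k + 1L
  }
  out <- apply(neigh, 1L, stats::median, na.rm = TRUE)
  out[is.na(out)] <- NaN
  out[is.na(as.vector(x))] <- NaN
  matrix(out, r, cc)
}

#' Reversible 3x3 median filter on the phasor coordinates
#'
#' Applies a 3x3 sliding-window median to the `g` and `s` grids `passes`
#' times. The filter shrinks the scatter of the phasor cloud without touching
#' the intensity image, and it is reversible: the pristine coordinates are
#' retained and restored by [revert_filters()]. Edges are handled by
#' symmetric padding; undefined (NaN) neighbours are excluded from each
#' window and undefined pixels stay undefined.
#'
#' @param field A `phasor_field` with at least one defined pixel.
#' @param passes Number of filter passes (>= 1).
#' @return The filtered `phasor_field`.
#' @export
median_filter_phasor <- function(field, passes = 1L) {
  stopifnot(inherits(field, "phasor_field"))
  passes <- as.integer(passes)
  if (is.na(passes) || passes < 1L) stop("passes must be >= 1")
  if (!any(defined_pixels(field))) stop("field has no defined pixels")
  g <- field$g; s <- field$s
  for (i in seq_len(passes)) {
    g <- median3x3(g)
    s <- median3x3(s)
  }
  field$g <- g
  field$s <- s
  field$median_passes <- field$median_passes + passes
  field$provenance <- c(field$provenance,
                        sprintf("3x3 median filter: %d pass(es) (total %d)",
                                passes, field$median_passes))
  field
}

#' Undo all median filtering
#'
#' Restores the pristine (unfiltered) `g` and `s` grids retained when the
#' field was created, making the median filter reversible. A no-op on an
#' unfiltered field.
#'
#' @param field A `phasor_field`.
#' @return The field with pristine coordinates and zero recorded passes.
#' @export
revert_filters <- function(field) {
  stopifnot(inherits(field, "phasor_field"))
  if (field$median_passes > 0L)
    field$provenance <- c(field$provenance,
                          sprintf("median filter reverted (%d pass(es) undone)",
                                  field$median_passes))
  field$g <- field$unfiltered_g
  field$s <- field$unfiltered_s
  field$median_passes <- 0L
  field
}
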