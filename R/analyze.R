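#' Run the full phasor analysis pipeline on one stack
#'
#' Transform, calibrate, filter, map: the non-interactive equivalent of the
#' standard workflow. Steps, in order: phasor transform at the configured
#' harmonic; calibration; optional reversible median filtering of g/s;
#' phase/modulation lifetime maps; optional distance-from-species and
#' two-component fraction maps; mask construction from the intensity and
#' contrast thresholds; ROI statistics over the mask.
#'
#' @param input A [flim_stack()] or a path to a multi-page TIFF.
#' @param params An [acquisition_params()] object.
#' @param calibration A `phasor_calibration` (its harmonic must match).
#' @param min_intensity,max_intensity Intensity threshold bounds.
#' @param median_passes Number of 3x3 median passes on g/s (0 = none).
#' @param species_b Optional [species_location()]: reference point for the
#'   distance map (and fraction denominator endpoint).
#' @param species_a Optional second species; with `species_b` present a
#'   fraction map `f_A = d_B / |AB|` is computed.
#' @param taup_range,taum_range,distance_range Optional `c(lo, hi)` contrast
#'   thresholds added to the mask.
#' @param clip_fraction Clamp fractions into [0, 1]?
#' @return Object of class `flim_result` holding the maps (`g_map`, `s_map`,
#'   `intensity_map`, `taup_map`, `taum_map`, `distance_map`,
#'   `fraction_map`), the `mask`, the calibrated `field`, `params`,
#'   `calibration`, `provenance` and `summary` statistics.
#' @export
flim_analyze <- function(input, params, calibration,
                         min_intensity = 0, max_intensity = Inf,
                         median_passes = 0L,
                         species_b = NULL, species_a = NULL,
                         taup_range = NULL, taum_range = NULL,
                         distance_range = NULL, clip_fraction = FALSE) {
  stack <- if (inherits(input, "flim_stack")) input else read_flim_stack(input)
  stopifnot(inherits(params, "acquisition_params"),
            inherits(calibration, "phasor_calibration"))

  field <- phasor_transform(stack, params)
  field <- apply_calibration(field, calibration)
  if (median_passes > 0L)
    field <- median_filter_phasor(field, median_passes)

  ltm <- lifetime_maps(field)
  dmap <- if (!is.null(species_b)) distance_map(field, species_b)
  fmap <- if (!is.null(species_b) && !is.null(species_a))
    fraction_map(field, species_a, species_b, clip = clip_fraction)

  mask <- intensity_mask(field, min_intensity, max_intensity)
  if (!any(mask$include))
    stop(sprintf("no pixels left after intensity threshold [%g, %g]",
                 min_intensity, max_intensity))
  add_range <- function(mask, map, range, label) {
    if (is.null(range)) return(mask)
    if (is.null(map)) stop(label, " threshold given but no ", label, " map")
    mask <- combine_masks(mask, contrast_mask(map, range[1], range[2], label))
    if (!any(mask$include))
      stop(sprintf("no pixels left after %s threshold [%g, %g]",
                   label, range[1], range[2]))
    mask
  }
  mask <- add_range(mask, ltm$taup_ns, taup_range, "TauP")
  mask <- add_range(mask, ltm$taum_ns, taum_range, "TauM")
  mask <- add_range(mask, if (is.null(dmap)) NULL else dmap$d,
                    distance_range, "distance")

  result <- structure(list(
    source = stack$source_path,
    params = params, calibration = calibration, field = field,
    g_map = field$g, s_map = field$s, intensity_map = field$intensity,
    taup_map = ltm$taup_ns, taum_map = ltm$taum_ns,
    distance_map = if (is.null(dmap)) NULL else dmap$d,
    fraction_map = if (is.null(fmap)) NULL else fmap$f_a,
    species_a = species_a, species_b = species_b,
    mask = mask, provenance = field$provenance),
    class = "flim_result")
  result$summary <- roi_statistics(result)
  result
}

#' @export
print.flim_result <- function(x, ...) {
  cat(sprintf("FLIM analysis of %s (%d x %d pixels)\n", x$source,
              nrow(x$g_map), ncol(x$g_map)))
  print(x$summary)
  invisible(x)
}

#' @export
summary.flim_result <- function(object, ...) object$summary

#' Batch-process several stacks with one shared parameter set
#'
#' Each input is analysed with identical settings; per-file failures are
#' caught, logged and reported, and processing continues. When `out_dir`
#' is given, each result is exported with [write_result()] and a combined
#' one-row-per-file summary CSV is written.
#'
#' @param inputs Character vector of stack paths (or list of
#'   [flim_stack()]s).
#' @param params,calibration,... Passed to [flim_analyze()].
#' @param out_dir Optional output directory.
#' @return Object of class `flim_batch`: list with `results` (named list of
#'   `flim_result`s), `summary` (data frame, one row per successful file),
#'   and `failures` (named character vector of error messages).
#' @export
flim_batch <- function(inputs, params, calibration, ..., out_dir = NULL) {
  if (length(inputs) == 0L) stop("empty input list")
  names(inputs) <- vapply(seq_along(inputs), function(i) {
    x <- if (is.list(inputs)) inputs[[i]] else inputs[i]
    if (inherits(x, "flim_stack")) x$source_path else as.character(x)
  }, character(1))

  results <- list()
  failures <- character()
  rows <- list()
  for (nm in names(inputs)) {
    input <- if (is.list(inputs)) inputs[[nm]] else nm
    res <- tryCatch(flim_analyze(input, params, calibration, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[nm] <- conditionMessage(res)
      message("batch: failed on ", nm, ": ", conditionMessage(res))
      next
    }
    results[[nm]] <- res
    st <- res$summary
    rows[[nm]] <- data.frame(file = nm, n_pixels = st$n_pixels,
                             mean_g = st$mean_g, mean_s = st$mean_s,
                             mean_taup_ns = st$mean_taup_ns,
                             mean_taum_ns = st$mean_taum_ns,
                             mean_distance = if (is.finite(st$mean_distance))
                               st$mean_distance else NA_real_)
    if (!is.null(out_dir))
      write_result(res, out_dir,
                   stem = tools::file_path_sans_ext(basename(nm)))
  }
  summary_df <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame()
  if (!is.null(out_dir) && length(rows))
    utils::write.csv(summary_df, file.path(out_dir, "batch_summary.csv"),
                     row.names = FALSE, na = "")
  structure(list(results = results, summary = summary_df,
                 failures = failures),
            class = "flim_batch")
}

#' @export
print.flim_batch <- function(x, ...) {
  cat(sprintf("Batch analysis: %d succeeded, %d failed\n",
              length(x$results), length(x$failures)))
  if (nrow(x$summary)) print(x$summary, row.names = FALSE)
  for (nm in names(x$failures))
    cat(sprintf("  FAILED %s: %s\n", nm, x$failures[nm]))
  invisible(x)
}
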