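#' Write a numeric matrix as a 32-bit float single-page TIFF
#'
#' Uncompressed little-endian IEEE-float TIFF (SampleFormat 3), the dialect
#' ImageJ-style tools read back verbatim; undefined pixels are stored as
#' NaN. Written by hand because the general-purpose TIFF writers available
#' to R quantise samples to [0, 1] integers.
#'
#' @param x Numeric matrix (row 1 = top image row).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  h <- nrow(x); w <- ncol(x)
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  u32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  # header: II, magic 42, first IFD at offset 8
  writeBin(charToRaw("II"), con)
  u16(42); u32(8)
  n_tags <- 10L
  data_offset <- 8L + 2L + n_tags * 12L + 4L
  tag <- function(id, type, count, value) {
    u16(id); u16(type); u32(count); u32(value)
  }
  u16(n_tags)
  tag(256L, 4L, 1L, w)              # ImageWidth
  tag(257L, 4L, 1L, h)              # ImageLength
  tag(258L, 3L, 1L, 32L)            # BitsPerSample
  tag(259L, 3L, 1L, 1L)             # Compression: none
  tag(262L, 3L, 1L, 1L)             # Photometric: BlackIsZero
  tag(273L, 4L, 1L, data_offset)    # StripOffsets
  tag(277L, 3L, 1L, 1L)             # SamplesPerPixel
  tag(278L, 4L, 1L, h)              # RowsPerStrip
  tag(279L, 4L, 1L, 4L * w * h)     # StripByteCounts
  tag(339L, 3L, 1L, 3L)             # SampleFormat: IEEE float
  u32(0)                            # no further IFD
  # raster data, row-major from the top row
  v <- as.numeric(t(x))
  v[is.na(v)] <- NaN
  writeBin(v, con, size = 4, endian = "little")
  invisible(path)
}

#' Read a single-page float TIFF written by [write_float_tiff()]
#'
#' @param path TIFF path.
#' @return Numeric matrix with NaN where undefined.
#' @export
read_float_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) != 2L)
    stop("expected a single-channel float TIFF: ", path)
  x
}

#' Export an analysis result to a directory
#'
#' Writes one 32-bit float single-page TIFF per available map (g, s,
#' intensity, TauP, TauM, and distance when present) with masked-out pixels
#' stored as NaN, one CSV row of mask-averaged summary statistics, and a
#' plain-text provenance log of the applied filters and thresholds.
#'
#' @param result A [flim_analyze()] result (`flim_result`).
#' @param out_dir Output directory (created if needed).
#' @param stem File-name stem; defaults to the input stack's base name.
#' @return Character vector of written paths, invisibly.
#' @export
write_result <- function(result, out_dir, stem = NULL) {
  stopifnot(inherits(result, "flim_result"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  if (is.null(stem))
    stem <- tools::file_path_sans_ext(basename(result$source))

  maps <- list(g = result$g_map, s = result$s_map,
               intensity = result$intensity_map,
               taup = result$taup_map, taum = result$taum_map,
               distance = result$distance_map)
  written <- character()
  for (nm in names(maps)) {
    if (is.null(maps[[nm]])) next
    m <- maps[[nm]]
    m[!result$mask$include] <- NaN
    p <- file.path(out_dir, sprintf("%s_%s.tif", stem, nm))
    write_float_tiff(m, p)
    written <- c(written, p)
  }

  stats <- roi_statistics(result)
  csv_path <- file.path(out_dir, sprintf("%s_summary.csv", stem))
  df <- data.frame(file = result$source, n_pixels = stats$n_pixels,
                   mean_g = stats$mean_g, mean_s = stats$mean_s,
                   mean_taup_ns = stats$mean_taup_ns,
                   mean_taum_ns = stats$mean_taum_ns,
                   mean_distance = if (is.finite(stats$mean_distance))
                     stats$mean_distance else NA_real_)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  written <- c(written, csv_path)

  log_path <- file.path(out_dir, sprintf("%s_provenance.txt", stem))
  writeLines(c(result$provenance,
               vapply(result$mask$provenance, function(p)
                 sprintf("mask: %s in [%g, %g]", p$criterion, p$lo, p$hi),
                 character(1))),
             log_path)
  written <- c(written, log_path)
  invisible(written)
}

run_config_keys <- c("rep_rate_mhz", "n_bins", "bin_width_ns", "harmonic",
                     "calibration", "filters", "species", "output_dir",
                     "input")

#' Load and validate a run configuration (JSON or YAML)
#'
#' A configuration names the acquisition parameters, the calibration (a
#' reference stack path plus its known lifetime, or an explicit phase
#' offset and modulation factor - never both), filters, species
#' definitions, inputs and output directory. Missing optional entries get
#' explicit defaults: harmonic 1, no median passes, no thresholds. Unknown
#' top-level keys warn but do not fail.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` document.
#' @return Object of class `run_config`: a validated list with
#'   `params` ([acquisition_params()]), `calibration`, `filters`,
#'   `species`, `output_dir` and `input`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("config must be a mapping/object")

  unknown <- setdiff(names(cfg), run_config_keys)
  if (length(unknown))
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(c("rep_rate_mhz", "n_bins", "bin_width_ns"), names(cfg))
  if (length(missing))
    stop("missing mandatory config keys: ", paste(missing, collapse = ", "))

  params <- acquisition_params(cfg$rep_rate_mhz, cfg$n_bins,
                               cfg$bin_width_ns,
                               harmonic = cfg$harmonic %||% 1L)

  calib <- cfg$calibration
  if (!is.null(calib)) {
    has_ref <- !is.null(calib$reference)
    has_explicit <- !is.null(calib$phase_offset_rad) ||
      !is.null(calib$modulation_factor)
    if (has_ref && has_explicit)
      stop("calibration over-specified: give a reference stack or explicit corrections, not both")
    if (has_ref && is.null(calib$reference_lifetime_ns))
      stop("calibration reference needs reference_lifetime_ns")
    if (has_explicit &&
        (is.null(calib$phase_offset_rad) || is.null(calib$modulation_factor)))
      stop("explicit calibration needs both phase_offset_rad and modulation_factor")
  }

  filters <- cfg$filters %||% list()
  filters$min_intensity <- filters$min_intensity %||% 0
  filters$max_intensity <- filters$max_intensity %||% Inf
  filters$median_passes <- filters$median_passes %||% 0L

  species <- cfg$species
  if (is.data.frame(species))  # JSON readers simplify a list of mappings
    species <- lapply(seq_len(nrow(species)), function(i)
      as.list(species[i, , drop = FALSE]))

  structure(list(params = params, calibration = calib, filters = filters,
                 species = species, output_dir = cfg$output_dir,
                 input = cfg$input),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
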