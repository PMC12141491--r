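#' Read a two-column spectrum CSV
#'
#' Expects a header and at least two columns; the first two are taken as
#' wavelength (nm) and intensity (counts).
#'
#' @param path File path.
#' @param meta Metadata list attached to the spectrum.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, meta = list()) {
  df <- read.csv(path)
  if (ncol(df) < 2L) stop("expected at least two columns")
  emission_spectrum(df[[1L]], df[[2L]], meta = meta)
}

#' Read a spectrometer text export
#'
#' Tab-separated dialect with `#`-prefixed header lines followed by
#' `wavelength<TAB>counts` rows.
#'
#' @param path File path.
#' @param meta Metadata list attached to the spectrum.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_txt <- function(path, meta = list()) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed row in ", path)
  wl <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  ct <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (any(is.na(wl)) || any(is.na(ct))) stop("non-numeric data row in ", path)
  emission_spectrum(wl, ct, meta = meta)
}

#' Write a spectrum to a two-column CSV
#' @param s An [emission_spectrum()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(inherits(s, "emission_spectrum"))
  write.csv(data.frame(wavelength_nm = s$wavelength_nm,
                       intensity = s$intensity),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a PAM trace CSV
#'
#' Columns `time_s, fluorescence, is_pulse, ppfd, light_label`.
#'
#' @param path File path.
#' @param meta Metadata list.
#' @return A [fluorescence_trace()].
#' @export
read_trace_csv <- function(path, meta = list()) {
  df <- read.csv(path)
  need <- c("time_s", "fluorescence", "is_pulse", "ppfd", "light_label")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns: ", paste(need, collapse = ", "))
  fluorescence_trace(df$time_s, df$fluorescence,
                     as.logical(df$is_pulse), df$ppfd, df$light_label,
                     meta = meta)
}

#' Read a minimal fluorometer export
#'
#' Semicolon-separated dialect: device header lines (anything before the
#' first line whose first field is numeric) are skipped; data rows are
#' `time;fluorescence;pulse(0/1);ppfd;label`.
#'
#' @param path File path.
#' @param meta Metadata list.
#' @return A [fluorescence_trace()].
#' @export
read_trace_fluorometer <- function(path, meta = list()) {
  lines <- readLines(path)
  first_field <- vapply(strsplit(lines, ";", fixed = TRUE), function(p)
    if (length(p)) trimws(p[[1L]]) else "", character(1))
  is_data <- suppressWarnings(!is.na(as.numeric(first_field)))
  start <- which(is_data)
  if (!length(start)) stop("no numeric data rows in ", path)
  rows <- strsplit(lines[is_data], ";", fixed = TRUE)
  if (any(lengths(rows) < 5L)) stop("malformed data row in ", path)
  get <- function(i) trimws(vapply(rows, `[[`, character(1), i))
  fluorescence_trace(as.numeric(get(1L)), as.numeric(get(2L)),
                     as.numeric(get(3L)) != 0, as.numeric(get(4L)),
                     get(5L), meta = meta)
}

#' Read a grayscale micrograph TIFF
#'
#' Single-plane 8/16-bit grayscale; multi-channel images are reduced to the
#' first channel with a warning. Intensities come back on a 0-1 scale.
#'
#' @param path File path.
#' @return A numeric intensity matrix.
#' @export
read_micrograph_tiff <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) {
    warning("multi-channel TIFF; using the first channel")
    x <- x[, , 1L]
  }
  x
}

#' Write a grayscale image (and optional label mask) as TIFF
#'
#' The intensity image is written as 16-bit grayscale; a label mask is
#' written with labels scaled into the 16-bit range (divide by 65535 and
#' multiply back to recover integer labels).
#'
#' @param img Numeric matrix on a 0-1 scale.
#' @param path Output path for the intensity image.
#' @param mask Optional integer label matrix.
#' @param mask_path Output path for the mask (required with `mask`).
#' @return `path`, invisibly.
#' @export
write_scene_tiff <- function(img, path, mask = NULL, mask_path = NULL) {
  tiff::writeTIFF(pmin(pmax(img, 0), 1), path, bits.per.sample = 16L)
  if (!is.null(mask)) {
    if (is.null(mask_path)) stop("mask_path required when writing a mask")
    tiff::writeTIFF(mask / 65535, mask_path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Write a per-pulse parameter table
#' @param params A `photo_params` data frame from [trace_timecourse()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_photo_params_csv <- function(params, path) {
  write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format group table
#'
#' Columns `group`, `replicate`, `value`; returns the named list of numeric
#' vectors that [gated_compare()] consumes.
#'
#' @param path File path.
#' @return Named list of numeric vectors.
#' @export
read_group_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("group", "value") %in% names(df)))
    stop("group CSV needs 'group' and 'value' columns")
  split(as.numeric(df$value), df$group)
}
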