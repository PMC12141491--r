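#' Dilution series of one biological replicate
#'
#' Concentrated powder samples re-absorb their own fluorescence, distorting
#' the spectral shape (most visibly in the 710-730 nm region), so each
#' biological replicate is measured at several dilutions (e.g. 100/50/25%
#' sample in optically neutral quartz powder). This container groups the
#' spectra of one replicate for QC.
#'
#' @param spectra List of [emission_spectrum()] objects (raw or processed),
#'   each with `meta$dilution_percent` set and sharing the same
#'   `meta$sample_id`.
#' @return An object of class `dilution_series`.
#' @export
dilution_series <- function(spectra) {
  if (!length(spectra)) stop("empty dilution series")
  ok <- vapply(spectra, inherits, logical(1), "emission_spectrum")
  if (!all(ok)) stop("all elements must be emission spectra")
  dil <- vapply(spectra, function(s) {
    d <- s$meta$dilution_percent
    if (is.null(d)) stop("every spectrum needs meta$dilution_percent")
    as.numeric(d)
  }, numeric(1))
  ids <- vapply(spectra, function(s)
    as.character(s$meta$sample_id %||% NA_character_), character(1))
  if (length(unique(ids)) > 1L)
    stop("dilution series mixes sample ids: ", paste(unique(ids), collapse = ", "))
  if (anyDuplicated(dil)) stop("duplicated dilution levels")
  o <- order(dil, decreasing = TRUE)
  structure(
    list(spectra = spectra[o], dilution_percent = dil[o],
         sample_id = ids[1L], selected = NULL, flags = character(),
         agreement = NULL),
    class = "dilution_series"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the working dilution of a series
#'
#' Walks the series from the most concentrated to the most dilute sample and
#' selects the most concentrated dilution whose normalized PSI statistic
#' agrees with the next more dilute one within a relative tolerance --- the
#' rationale being that once further dilution no longer changes the spectral
#' shape, self-absorption is negligible and the less noisy (more
#' concentrated) member of the agreeing pair is preferred. If no adjacent
#' pair agrees, the most dilute sample whose raw PSII-window signal still
#' exceeds a noise floor is selected and a `self_absorption` warning flag is
#' set. A single-spectrum series is returned selected with an `unverified`
#' flag.
#'
#' @param d A [dilution_series()]. Raw spectra are processed through
#'   [process_spectrum()] automatically.
#' @param tol_rel Relative tolerance for PSI-statistic agreement between
#'   adjacent dilutions (default 0.05).
#' @param noise_floor Minimum raw PSII-window peak height (counts) for the
#'   fallback selection (default 0).
#' @param ... Passed to [process_spectrum()] for unprocessed members.
#' @return The series with `$selected` (dilution percent), `$selected_index`,
#'   `$psi_values`, `$agreement` (relative differences between adjacent
#'   dilutions) and `$flags` filled in.
#' @export
qc_select_dilution <- function(d, tol_rel = 0.05, noise_floor = 0, ...) {
  stopifnot(inherits(d, "dilution_series"))
  proc <- lapply(d$spectra, function(s) {
    if (inherits(s, "processed_spectrum")) s else process_spectrum(s, ...)
  })
  psi <- vapply(proc, function(p) psi_statistic(p)$value, numeric(1))
  raw_psii <- vapply(proc, function(p) p$psii_peak$raw_height, numeric(1))
  n <- length(proc)
  d$psi_values <- psi
  d$processed <- proc
  if (n == 1L) {
    d$selected_index <- 1L
    d$selected <- d$dilution_percent[1L]
    d$flags <- c(d$flags, "unverified")
    return(d)
  }
  rel <- abs(psi[-n] - psi[-1L]) / abs(psi[-1L])
  d$agreement <- rel
  hit <- which(rel <= tol_rel)
  if (length(hit)) {
    d$selected_index <- hit[1L]
  } else {
    above <- which(raw_psii > noise_floor)
    if (!length(above))
      stop("no dilution exceeds the PSII noise floor")
    d$selected_index <- max(above)   # most dilute above the floor
    d$flags <- c(d$flags, "self_absorption")
  }
  d$selected <- d$dilution_percent[d$selected_index]
  d
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> sample %s: %s%%\n", x$sample_id,
              paste(x$dilution_percent, collapse = "/")))
  if (!is.null(x$selected))
    cat(sprintf("  selected: %g%%%s\n", x$selected,
                if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Compare normalized PSI fluorescence between two light treatments
#'
#' Tests whether two treatment groups (one PSI statistic per biological
#' replicate) differ, via the gated decision tree of [gated_compare()].
#'
#' @param groupA,groupB Numeric vectors of per-replicate PSI statistics,
#'   length >= 2 each.
#' @param alpha Significance level (default 0.05).
#' @param names Character length-2 group labels.
#' @return A `group_comparison` (see [gated_compare()]) with `$effect` set to
#'   the difference of group means (A - B).
#' @export
compare_states <- function(groupA, groupB, alpha = 0.05,
                           names = c("A", "B")) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 replicates")
  g <- stats::setNames(list(as.numeric(groupA), as.numeric(groupB)), names)
  res <- gated_compare(g, alpha = alpha)
  res$effect <- mean(groupA) - mean(groupB)
  res
}
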