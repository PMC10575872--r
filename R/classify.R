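# Composite-specific SWIR threshold classification. Water absorbs strongly
# in the short-wave infrared, so inundated pixels sit low on the SWIR
# scale; a threshold placed between the wet and dry reference medians
# separates the two, and recomputing it per composite absorbs interannual
# radiometric drift.

#' Compute the composite-specific SWIR threshold
#'
#' The threshold interpolates between the median SWIR reflectance of the
#' permanent wet reference pixels and that of the permanent dry reference
#' pixels:
#'
#'   `threshold = swir_wet + coefficient * (swir_dry - swir_wet)`
#'
#' with the standard coefficient 0.3, i.e. three tenths of the way from
#' wet towards dry. Medians are taken over reference pixels that are valid
#' (non-nodata) in this composite. When `swir_dry <= swir_wet` the record
#' is flagged degenerate: the wet/dry contrast has collapsed and
#' classification would be meaningless.
#'
#' @param composite an [build_annual_composite()] result.
#' @param refs a [derive_reference_regions()] result (or any list with
#'   logical `wet_mask` / `dry_mask` matrices).
#' @param coefficient interpolation coefficient, default 0.3.
#' @return An object of class `threshold_record`: `year`, `swir_wet`,
#'   `swir_dry`, `swir_threshold`, `coefficient`, `degenerate`.
#' @export
compute_swir_threshold <- function(composite, refs, coefficient = 0.3) {
  valid <- !is.na(composite$swir)
  wet_px <- composite$swir[refs$wet_mask & valid]
  dry_px <- composite$swir[refs$dry_mask & valid]
  if (length(wet_px) == 0)
    stop("no valid wet reference pixels in composite for year ", composite$year)
  if (length(dry_px) == 0)
    stop("no valid dry reference pixels in composite for year ", composite$year)
  swir_wet <- median(wet_px)
  swir_dry <- median(dry_px)
  structure(list(year = composite$year, swir_wet = swir_wet,
                 swir_dry = swir_dry,
                 swir_threshold = swir_wet + coefficient * (swir_dry - swir_wet),
                 coefficient = coefficient,
                 degenerate = swir_dry <= swir_wet),
            class = "threshold_record")
}

#' Classify a composite into a binary inundation map
#'
#' Pixels with SWIR reflectance strictly below the threshold are labelled
#' inundated (1); pixels at or above it are labelled dry (0) -- equality
#' goes to dry as the conservative reading. Nodata propagates. Degenerate
#' thresholds refuse to classify unless overridden, since a collapsed
#' wet/dry contrast would silently invert the map's meaning.
#'
#' @param composite an [build_annual_composite()] result.
#' @param thr a [compute_swir_threshold()] record.
#' @param allow_degenerate classify anyway when `thr$degenerate` is TRUE.
#' @return An object of class `inundation_map`: `year`, `labels` (integer
#'   matrix over 0/1/NA), `threshold_used`.
#' @export
classify_inundation <- function(composite, thr, allow_degenerate = FALSE) {
  if (thr$degenerate && !allow_degenerate)
    stop("degenerate threshold for year ", thr$year,
         " (swir_dry <= swir_wet); refusing to classify")
  labels <- matrix(NA_integer_, nrow(composite$swir), ncol(composite$swir))
  ok <- !is.na(composite$swir)
  labels[ok] <- ifelse(composite$swir[ok] < thr$swir_threshold, 1L, 0L)
  structure(list(year = composite$year, labels = labels, threshold_used = thr),
            class = "inundation_map")
}

#' Aggregate inundation maps into an inundation-frequency map
#'
#' Per pixel, the percentage of years with a valid label in which the
#' pixel was classified inundated: 100 means flooded in every available
#' time step, 0 permanently dry. Denominators are per-pixel available-year
#' counts, so nodata years at a pixel do not distort its percentage.
#'
#' @param maps non-empty list of [classify_inundation()] maps sharing
#'   geometry.
#' @return An object of class `frequency_map`: `percent` matrix (0-100,
#'   NA where no year has a valid label) and `n_years_available` matrix.
#' @export
inundation_frequency <- function(maps) {
  if (length(maps) == 0) stop("no inundation maps supplied")
  d <- dim(maps[[1]]$labels)
  wet <- matrix(0L, d[1], d[2])
  avail <- matrix(0L, d[1], d[2])
  for (m in maps) {
    if (!all(dim(m$labels) == d)) stop("frequency: maps have mismatched geometry")
    ok <- !is.na(m$labels)
    avail <- avail + ok
    wet <- wet + (ok & m$labels == 1L)
  }
  percent <- matrix(NA_real_, d[1], d[2])
  nz <- avail > 0
  percent[nz] <- 100 * wet[nz] / avail[nz]
  structure(list(percent = percent, n_years_available = avail),
            class = "frequency_map")
}
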