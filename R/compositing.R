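# From dated, cloud-contaminated scenes to one quality-controlled annual
# median SWIR composite per year: mask QA-flagged pixels, gap-fill them
# from temporally adjacent scenes, take the per-pixel seasonal median, and
# drop composites that fail quality control.

#' Construct a scene
#'
#' A scene is one dated observation of the site: a SWIR reflectance grid
#' (possibly absent), a QA grid (0 clear, 1 cloud, 2 cloud shadow), and a
#' per-pixel validity mask. All grids share dimensions.
#'
#' @param swir numeric matrix of reflectance in `[0, 1]`, or `NULL` when
#'   the scene lacks the SWIR band.
#' @param qa integer matrix of QA categories (0 clear / 1 cloud / 2 shadow).
#' @param date scene acquisition date (`Date` or coercible).
#' @param scene_id identifier string.
#' @param valid optional logical matrix; defaults to all-TRUE where a SWIR
#'   grid exists (QA flags are applied by [apply_cloud_mask()]), all-FALSE
#'   otherwise.
#' @return An object of class `scene`.
#' @export
scene <- function(swir, qa, date, scene_id, valid = NULL) {
  if (!is.null(swir)) stopifnot(all(dim(swir) == dim(qa)))
  if (is.null(valid)) {
    valid <- if (is.null(swir)) matrix(FALSE, nrow(qa), ncol(qa))
             else !is.na(swir)
  }
  stopifnot(all(dim(valid) == dim(qa)))
  structure(list(swir = swir, qa = qa, valid = valid,
                 date = as.Date(date), scene_id = as.character(scene_id)),
            class = "scene")
}

#' Mask cloud and cloud-shadow pixels of a scene
#'
#' Marks every pixel whose QA category is cloud or cloud shadow as invalid;
#' reflectance values are left in place but excluded from all later
#' medians. Idempotent.
#'
#' @param scene a [scene()].
#' @return The scene with its validity mask updated.
#' @export
apply_cloud_mask <- function(scene) {
  if (is.null(scene$qa)) stop("scene has no QA grid; cannot cloud-mask")
  scene$valid <- scene$valid & (scene$qa == 0L)
  scene
}

#' Fill masked pixels from temporally adjacent scenes
#'
#' Each invalid pixel is replaced by the median of that pixel's valid
#' values over archive scenes dated within `window_days` of the scene's
#' own date (the scene itself excluded). Pixels with an empty candidate
#' pool stay invalid; valid pixels are never modified, so gap-filling on a
#' fully valid scene is the identity.
#'
#' @param scene a [scene()]; returned unchanged if it has no SWIR grid.
#' @param archive list of scenes sharing the scene's grid geometry.
#' @param window_days candidate pool half-width in days; the default 366
#'   reads "a year before or after" inclusively.
#' @return The scene with fillable pixels filled and marked valid.
#' @export
gap_fill <- function(scene, archive, window_days = 366) {
  if (is.null(scene$swir)) return(scene)
  fillable <- which(!scene$valid)
  if (length(fillable) == 0) return(scene)
  pool <- Filter(function(s) {
    !is.null(s$swir) && s$scene_id != scene$scene_id &&
      abs(as.numeric(s$date - scene$date)) <= window_days
  }, archive)
  if (length(pool) == 0) return(scene)
  for (s in pool) {
    if (!all(dim(s$swir) == dim(scene$swir)))
      stop("gap_fill: archive scene ", s$scene_id, " has mismatched geometry")
  }
  stack <- vapply(pool, function(s) {
    v <- s$swir[fillable]
    v[!s$valid[fillable]] <- NA_real_
    v
  }, numeric(length(fillable)))
  fill <- stack_median(matrix(stack, nrow = length(fillable)))
  ok <- !is.na(fill)
  scene$swir[fillable[ok]] <- fill[ok]
  scene$valid[fillable[ok]] <- TRUE
  scene
}

#' Build the annual median SWIR composite for one year
#'
#' Selects the scenes dated inside the season window of `year` and takes
#' the per-pixel median of their valid SWIR values (even counts: mean of
#' the two middle values). Pixels with no valid observation in any scene
#' are nodata. If no in-window scene carries a SWIR band the composite is
#' returned with `has_swir = FALSE`.
#'
#' @param scenes list of [scene()] objects (any years; filtered by date).
#' @param year composite year.
#' @param season_window `c("mm-dd", "mm-dd")` inclusive season bounds.
#' @return An object of class `annual_composite`: `year`, `swir` matrix
#'   (NA = nodata), `masked_fraction`, `n_scenes`, `has_swir`.
#' @export
build_annual_composite <- function(scenes, year,
                                   season_window = c("06-01", "09-30")) {
  start <- as.Date(paste0(year, "-", season_window[1]))
  end <- as.Date(paste0(year, "-", season_window[2]))
  sel <- Filter(function(s) s$date >= start && s$date <= end, scenes)
  withband <- Filter(function(s) !is.null(s$swir), sel)
  dims <- NULL
  for (s in sel) { dims <- dim(s$qa); break }
  if (length(withband) == 0) {
    if (is.null(dims)) dims <- c(0L, 0L)
    return(structure(list(year = as.integer(year),
                          swir = matrix(NA_real_, dims[1], dims[2]),
                          masked_fraction = 1, n_scenes = 0L, has_swir = FALSE),
                     class = "annual_composite"))
  }
  d <- dim(withband[[1]]$swir)
  stack <- vapply(withband, function(s) {
    if (!all(dim(s$swir) == d)) stop("composite: scenes have mismatched geometry")
    v <- as.numeric(s$swir)
    v[!s$valid] <- NA_real_
    v
  }, numeric(prod(d)))
  med <- stack_median(matrix(stack, nrow = prod(d)))
  swir <- matrix(med, d[1], d[2])
  structure(list(year = as.integer(year), swir = swir,
                 masked_fraction = mean(is.na(swir)),
                 n_scenes = length(withband), has_swir = TRUE),
            class = "annual_composite")
}

#' Quality-filter a set of annual composites
#'
#' Drops composites lacking a SWIR band and composites whose residual
#' masked fraction exceeds `max_masked_fraction`. The default 0 keeps only
#' composites devoid of masking altogether; it is strict, so it is
#' configurable for cloudy archives.
#'
#' @param composites list of [build_annual_composite()] results.
#' @param max_masked_fraction maximum tolerated nodata fraction (strict
#'   `>` comparison drops offenders).
#' @return list with `kept` (composites ordered by year) and `report`
#'   (data frame: year, reason, masked_fraction, n_scenes; one row per
#'   rejection).
#' @export
filter_composites <- function(composites, max_masked_fraction = 0) {
  keep <- logical(length(composites))
  rows <- list()
  for (i in seq_along(composites)) {
    cm <- composites[[i]]
    if (!cm$has_swir) {
      rows[[length(rows) + 1]] <- data.frame(
        year = cm$year, reason = "missing SWIR band",
        masked_fraction = cm$masked_fraction, n_scenes = cm$n_scenes)
    } else if (cm$masked_fraction > max_masked_fraction) {
      rows[[length(rows) + 1]] <- data.frame(
        year = cm$year, reason = "masked fraction above threshold",
        masked_fraction = cm$masked_fraction, n_scenes = cm$n_scenes)
    } else keep[i] <- TRUE
  }
  kept <- composites[keep]
  kept <- kept[order(vapply(kept, function(c) as.numeric(c$year), numeric(1)))]
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(year = integer(), reason = character(),
                            masked_fraction = numeric(), n_scenes = integer())
  list(kept = kept, report = report)
}
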