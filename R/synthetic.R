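# Synthetic Landsat-like site generator. A circular water body with a
# configurable interannual area trend stands in for a real wetland: wet
# pixels draw SWIR reflectance from a low distribution, dry pixels from a
# high one, cloud/shadow patches contaminate the QA band, and some scenes
# lack the SWIR band entirely -- the data regime the compositing and
# classification stages are built to survive.

#' Configuration for a synthetic wetland site
#'
#' Bundles and validates every knob of the synthetic scene generator. The
#' defaults emulate a mid-size monsoon-fed wetland observed at 30 m
#' resolution over 1991-2020 with four usable scenes per June-September
#' season.
#'
#' @param grid_rows,grid_cols grid size in pixels.
#' @param pixel_size pixel edge length in metres (Landsat SWIR: 30).
#' @param years integer vector of years covered (inclusive).
#' @param water_center `(row, col)` of the water body centre in pixels;
#'   defaults to the grid centre.
#' @param base_radius water-body radius in metres in the first year.
#' @param area_trend_slope fractional change in true wet area per year
#'   relative to the first year (e.g. -0.02 loses 2% of the initial area
#'   each year).
#' @param interannual_noise_sd coefficient of variation of multiplicative
#'   lognormal area noise (0 = deterministic trend).
#' @param scenes_per_season number of scenes rendered per season.
#' @param season_window character length-2 `c("mm-dd", "mm-dd")` start and
#'   end of the compositing season, default June 1 - September 30.
#' @param mu_wet,sd_wet,mu_dry,sd_dry SWIR reflectance distributions
#'   (dimensionless, 0-1 scale) for wet and dry pixels. Water absorbs
#'   strongly in SWIR, so `mu_wet < mu_dry` is required.
#' @param cloud_fraction expected fraction of pixels flagged cloud/shadow
#'   per scene, in `[0, 1)`.
#' @param missing_band_prob probability that a scene carries no SWIR band.
#' @param label_noise_rate probability that a validation reference label is
#'   flipped (emulates photo-interpretation error), in `[0, 0.5)`.
#' @param seed integer seed; every generator operation is a pure function
#'   of (config, seed).
#' @return An object of class `site_truth_config`.
#' @export
site_truth_config <- function(grid_rows = 100, grid_cols = 100,
                              pixel_size = 30,
                              years = 1991:2020,
                              water_center = NULL,
                              base_radius = 900,
                              area_trend_slope = 0,
                              interannual_noise_sd = 0,
                              scenes_per_season = 4,
                              season_window = c("06-01", "09-30"),
                              mu_wet = 0.05, sd_wet = 0.02,
                              mu_dry = 0.25, sd_dry = 0.03,
                              cloud_fraction = 0,
                              missing_band_prob = 0,
                              label_noise_rate = 0,
                              seed = 1L) {
  if (is.null(water_center)) water_center <- c((grid_rows + 1) / 2, (grid_cols + 1) / 2)
  cfg <- list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
              pixel_size = pixel_size, years = as.integer(sort(years)),
              water_center = as.numeric(water_center), base_radius = base_radius,
              area_trend_slope = area_trend_slope,
              interannual_noise_sd = interannual_noise_sd,
              scenes_per_season = as.integer(scenes_per_season),
              season_window = season_window,
              mu_wet = mu_wet, sd_wet = sd_wet, mu_dry = mu_dry, sd_dry = sd_dry,
              cloud_fraction = cloud_fraction,
              missing_band_prob = missing_band_prob,
              label_noise_rate = label_noise_rate, seed = as.integer(seed))
  class(cfg) <- "site_truth_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (!(cfg$mu_wet < cfg$mu_dry))
    stop("invalid config: mu_wet must be < mu_dry (SWIR of water is lower than of dry land)")
  if (cfg$cloud_fraction < 0 || cfg$cloud_fraction >= 1)
    stop("invalid config: cloud_fraction must be in [0, 1)")
  if (cfg$missing_band_prob < 0 || cfg$missing_band_prob > 1)
    stop("invalid config: missing_band_prob must be in [0, 1]")
  if (cfg$label_noise_rate < 0 || cfg$label_noise_rate >= 0.5)
    stop("invalid config: label_noise_rate must be in [0, 0.5)")
  if (cfg$pixel_size <= 0) stop("invalid config: pixel_size must be > 0")
  if (cfg$scenes_per_season < 1) stop("invalid config: scenes_per_season must be >= 1")
  if (cfg$grid_rows < 1 || cfg$grid_cols < 1) stop("invalid config: empty grid")
  if (cfg$base_radius <= 0) stop("invalid config: base_radius must be > 0")
  if (length(cfg$years) < 1) stop("invalid config: no years")
  if (any(cfg$sd_wet < 0, cfg$sd_dry < 0)) stop("invalid config: negative reflectance sd")
  invisible(cfg)
}

#' Generate the true inundation history of a synthetic site
#'
#' The true wet extent in year `y` is a disc whose area follows
#' `A_y = A_0 * (1 + area_trend_slope * (y - y_first))`, perturbed by
#' multiplicative lognormal noise with unit mean and coefficient of
#' variation `interannual_noise_sd`, clipped to the grid area. The recorded
#' "true" area is the discretized one: wet-pixel count times pixel area.
#'
#' @param config a [site_truth_config()].
#' @return An object of class `synthetic_truth`: list with `masks` (named
#'   list of logical matrices, one per year), `true_area_km2` (named
#'   numeric), and `config`.
#' @export
generate_truth <- function(config) {
  validate_config(config)
  yrs <- config$years
  a0 <- pi * config$base_radius^2                       # m^2
  grid_area <- config$grid_rows * config$grid_cols * config$pixel_size^2
  mult <- rep(1, length(yrs))
  if (config$interannual_noise_sd > 0) {
    sdlog <- sqrt(log(1 + config$interannual_noise_sd^2))
    mult <- with_seed(derive_seed(config$seed, "area-noise"),
                      exp(rnorm(length(yrs), -sdlog^2 / 2, sdlog)))
  }
  masks <- vector("list", length(yrs))
  areas <- numeric(length(yrs))
  for (i in seq_along(yrs)) {
    a <- a0 * (1 + config$area_trend_slope * (yrs[i] - yrs[1])) * mult[i]
    a <- min(max(a, 0), grid_area)
    r_px <- sqrt(a / pi) / config$pixel_size
    m <- disc_mask(config$grid_rows, config$grid_cols, config$water_center, r_px)
    masks[[i]] <- m
    areas[i] <- sum(m) * (config$pixel_size^2 / 1e6)    # km^2 = count x pixel area
  }
  names(masks) <- names(areas) <- as.character(yrs)
  structure(list(masks = masks, true_area_km2 = areas, config = config),
            class = "synthetic_truth")
}

season_dates <- function(year, season_window, n) {
  start <- as.Date(paste0(year, "-", season_window[1]))
  end <- as.Date(paste0(year, "-", season_window[2]))
  if (n == 1) return(start + round(as.numeric(end - start) / 2))
  start + round(seq(0, as.numeric(end - start), length.out = n))
}

# Grow square cloud/shadow patches from random anchors until the target
# flagged fraction is reached; the last patch is trimmed so the flagged
# count lands exactly on the target. Patches alternate cloud (1)/shadow (2).
place_cloud_patches <- function(nr, nc, cloud_fraction) {
  qa <- matrix(0L, nr, nc)
  target <- round(cloud_fraction * nr * nc)
  kind <- 1L
  flagged <- 0L
  while (flagged < target) {
    h <- sample(2:6, 1)                                # patch half-width, px
    r <- sample.int(nr, 1); c <- sample.int(nc, 1)
    rows <- max(1, r - h):min(nr, r + h)
    cols <- max(1, c - h):min(nc, c + h)
    cells <- as.vector(outer(rows, cols, function(i, j) i + (j - 1L) * nr))
    cells <- cells[qa[cells] == 0L]
    cells <- cells[seq_len(min(length(cells), target - flagged))]
    qa[cells] <- kind
    flagged <- flagged + length(cells)
    kind <- if (kind == 1L) 2L else 1L
  }
  qa
}

#' Render the scene stack for one year of a synthetic site
#'
#' Produces `scenes_per_season` dated scenes spread uniformly over the
#' season window. Each pixel draws SWIR reflectance from
#' `Normal(mu_wet, sd_wet)` if wet in the truth, else
#' `Normal(mu_dry, sd_dry)`, truncated to `[0, 1]`. Contiguous square
#' cloud/shadow patches flag about `cloud_fraction` of the QA band, and
#' with probability `missing_band_prob` a scene carries no SWIR grid at
#' all (as in early Landsat 5 archives).
#'
#' Scenes are rendered "raw": the QA flags are present but not yet applied
#' to the validity mask -- that is [apply_cloud_mask()]'s job.
#'
#' @param truth a [generate_truth()] result.
#' @param year year to render; must lie in the truth's range.
#' @return list of `scene` objects (see [scene()]).
#' @export
render_scene_set <- function(truth, year) {
  cfg <- truth$config
  key <- as.character(year)
  if (!key %in% names(truth$masks)) stop("year ", year, " outside the truth's range")
  wet <- truth$masks[[key]]
  nr <- cfg$grid_rows; nc <- cfg$grid_cols
  dates <- season_dates(year, cfg$season_window, cfg$scenes_per_season)
  mu <- matrix(cfg$mu_dry, nr, nc); mu[wet] <- cfg$mu_wet
  sd <- matrix(cfg$sd_dry, nr, nc); sd[wet] <- cfg$sd_wet
  with_seed(derive_seed(cfg$seed, "scenes", year), {
    lapply(seq_len(cfg$scenes_per_season), function(s) {
      swir <- matrix(pmin(pmax(rnorm(nr * nc, mu, sd), 0), 1), nr, nc)
      if (runif(1) < cfg$missing_band_prob) swir <- NULL
      qa <- if (cfg$cloud_fraction > 0) place_cloud_patches(nr, nc, cfg$cloud_fraction)
            else matrix(0L, nr, nc)
      scene(swir = swir, qa = qa, date = dates[s],
            scene_id = sprintf("site-%d-%s-%d", year, format(dates[s]), s))
    })
  })
}

#' Derive permanent wet/dry reference regions from a synthetic truth
#'
#' Automates the manual digitization step of reference-region selection:
#' the permanent wet region is the intersection of all yearly wet masks,
#' the permanent dry region the intersection of all yearly dry masks, each
#' morphologically eroded by `erosion_margin` pixels to stay clear of the
#' fluctuating shoreline.
#'
#' @param truth a [generate_truth()] result.
#' @param erosion_margin non-negative integer erosion depth in pixels.
#' @return An object of class `reference_regions`: list with logical
#'   `wet_mask` and `dry_mask` (always disjoint).
#' @export
derive_reference_regions <- function(truth, erosion_margin = 0) {
  stopifnot(erosion_margin >= 0)
  wet <- erode_mask(Reduce(`&`, truth$masks), erosion_margin)
  dry <- erode_mask(Reduce(`&`, lapply(truth$masks, `!`)), erosion_margin)
  if (!any(wet)) stop("site unusable: permanent wet reference region is empty after erosion")
  if (!any(dry)) stop("site unusable: permanent dry reference region is empty after erosion")
  structure(list(wet_mask = wet, dry_mask = dry), class = "reference_regions")
}

#' Reference labels at validation points, with photo-interpretation noise
#'
#' Looks up the true wet/dry state at each point for one year and flips
#' each label independently with probability `label_noise_rate`, emulating
#' the error of a human interpreting historical imagery.
#'
#' @param truth a [generate_truth()] result.
#' @param points data frame with integer `row`, `col` columns.
#' @param year year whose truth mask to read.
#' @param label_noise_rate flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return integer vector of labels (1 wet, 0 dry), one per point.
#' @export
reference_labels_at_points <- function(truth, points, year,
                                       label_noise_rate = truth$config$label_noise_rate,
                                       seed = truth$config$seed) {
  cfg <- truth$config
  key <- as.character(year)
  if (!key %in% names(truth$masks)) stop("year ", year, " outside the truth's range")
  if (any(points$row < 1 | points$row > cfg$grid_rows |
          points$col < 1 | points$col > cfg$grid_cols))
    stop("validation point outside the site grid")
  if (label_noise_rate < 0 || label_noise_rate >= 0.5)
    stop("label_noise_rate must be in [0, 0.5)")
  labels <- as.integer(truth$masks[[key]][cbind(points$row, points$col)])
  if (label_noise_rate > 0) {
    flip <- with_seed(derive_seed(seed, "labels", year),
                      runif(length(labels)) < label_noise_rate)
    labels[flip] <- 1L - labels[flip]
  }
  labels
}
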