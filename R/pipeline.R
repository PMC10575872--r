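# Per-site and batch orchestration: scenes -> cloud mask -> gap-fill ->
# annual composites -> quality filter -> per-composite threshold ->
# inundation maps -> frequency map -> area series -> Mann-Kendall ->
# summary -> validation, with every intermediate writable to disk.

#' Run the full inundation analysis for one synthetic site
#'
#' Executes every stage of the pipeline on a synthetic site defined by a
#' [site_truth_config()]. Any stage failure aborts with the stage name in
#' the error message. With `out_dir` set, all intermediates (thresholds,
#' maps, frequency, areas, trend, validation points, error matrix, report)
#' are written as plain-text files.
#'
#' @param config a [site_truth_config()].
#' @param site_id identifier used in tables and file names.
#' @param out_dir optional directory for file outputs.
#' @param use_gap_fill apply [gap_fill()] before compositing (default TRUE;
#'   FALSE for ablation).
#' @param max_masked_fraction composite quality threshold, see
#'   [filter_composites()].
#' @param coefficient threshold interpolation coefficient, see
#'   [compute_swir_threshold()].
#' @param erosion_margin reference-region erosion depth in pixels.
#' @param n_validation_years,n_points_per_year validation sampling design
#'   (defaults 5 and 50, i.e. 250 points per site).
#' @return An object of class `site_report`: list with `site_id`,
#'   `config`, `truth`, `filter_report`, `thresholds`, `maps`,
#'   `frequency`, `area_series`, `mk`, `summary`, `points`,
#'   `error_matrix`, and `meta` (config hash, seed, timestamp, paths).
#' @export
run_site <- function(config, site_id = "site", out_dir = NULL,
                     use_gap_fill = TRUE, max_masked_fraction = 0,
                     coefficient = 0.3, erosion_margin = 1,
                     n_validation_years = 5, n_points_per_year = 50) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  truth <- stage("simulate", generate_truth(config))
  yrs <- config$years

  scenes_by_year <- stage("render", lapply(yrs, function(y) render_scene_set(truth, y)))
  names(scenes_by_year) <- as.character(yrs)

  scenes_by_year <- stage("cloud-mask",
    lapply(scenes_by_year, function(sc) lapply(sc, apply_cloud_mask)))

  if (use_gap_fill) {
    scenes_by_year <- stage("gap-fill", {
      filled <- scenes_by_year
      for (i in seq_along(yrs)) {
        neigh <- unlist(scenes_by_year[as.character(
          intersect(yrs, (yrs[i] - 1):(yrs[i] + 1)))], recursive = FALSE)
        filled[[i]] <- lapply(scenes_by_year[[i]], gap_fill, archive = neigh)
      }
      filled
    })
  }

  composites <- stage("composite",
    lapply(yrs, function(y) build_annual_composite(
      scenes_by_year[[as.character(y)]], y, config$season_window)))

  filt <- stage("filter", filter_composites(composites, max_masked_fraction))
  if (length(filt$kept) == 0)
    stop("stage filter: zero usable composites after quality filtering", call. = FALSE)

  refs <- stage("reference-regions", derive_reference_regions(truth, erosion_margin))

  thresholds <- stage("threshold",
    lapply(filt$kept, compute_swir_threshold, refs = refs, coefficient = coefficient))

  maps <- stage("classify", mapply(classify_inundation, filt$kept, thresholds,
                                   SIMPLIFY = FALSE))

  freq <- stage("frequency", inundation_frequency(maps))

  series <- stage("area-series",
    inundated_area_series(maps, pixel_area = config$pixel_size^2 / 1e6,
                          site_id = site_id))

  mk <- stage("trend", mann_kendall(series$areas))
  summ <- stage("summary", site_summary(series))

  points <- stage("validate", {
    pts <- sample_validation_points(maps, n_years = n_validation_years,
                                    n_points_per_year = n_points_per_year,
                                    seed = config$seed, site_id = site_id)
    pts <- extract_predicted_labels(maps, pts)
    for (y in unique(pts$year)) {
      sel <- pts$year == y
      pts$reference[sel] <- reference_labels_at_points(
        truth, pts[sel, ], y, config$label_noise_rate, config$seed)
    }
    pts
  })
  errmat <- stage("validate", build_error_matrix(points))

  meta <- list(config_hash = config_hash(config), seed = config$seed,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               n_composites_kept = length(filt$kept),
               n_composites_rejected = nrow(filt$report), paths = list())
  report <- structure(list(site_id = site_id, config = config, truth = truth,
                           filter_report = filt$report, thresholds = thresholds,
                           maps = maps, frequency = freq, area_series = series,
                           mk = mk, summary = summ, points = points,
                           error_matrix = errmat, meta = meta),
                      class = "site_report")
  if (!is.null(out_dir)) report <- write_site_outputs(report, out_dir)
  report
}

#' Run a batch of sites and tally their trends
#'
#' Runs [run_site()] independently per config; a failing site is logged
#' and excluded, not fatal, unless every site fails. Site order does not
#' affect any per-site result (each site is seeded from its own config).
#'
#' @param configs named list of [site_truth_config()] objects; names are
#'   the site ids.
#' @param ... passed on to [run_site()].
#' @return An object of class `batch_summary`: `trend_tally` (counts over
#'   the five trend classes, summing to the number of successful sites),
#'   `mean_overall_accuracy`, `sites` (one-row-per-site data frame),
#'   `reports`, `failures` (named character of error messages).
#' @export
run_batch <- function(configs, ...) {
  if (length(configs) == 0) stop("empty batch")
  ids <- names(configs)
  if (is.null(ids)) ids <- paste0("site", seq_along(configs))
  reports <- list(); failures <- character()
  for (i in seq_along(configs)) {
    res <- tryCatch(run_site(configs[[i]], site_id = ids[i], ...),
                    error = function(e) e)
    if (inherits(res, "error")) failures[ids[i]] <- conditionMessage(res)
    else reports[[ids[i]]] <- res
  }
  if (length(reports) == 0)
    stop("all sites failed; first error: ", failures[1])
  tally <- table(factor(vapply(reports, function(r) r$mk$trend_class, character(1)),
                        levels = TREND_CLASSES))
  sites <- do.call(rbind, lapply(reports, site_report_row))
  rownames(sites) <- NULL
  structure(list(trend_tally = tally,
                 mean_overall_accuracy =
                   mean(vapply(reports, function(r) r$error_matrix$overall_accuracy,
                               numeric(1))),
                 sites = sites, reports = reports, failures = failures),
            class = "batch_summary")
}

site_report_row <- function(r) {
  data.frame(site_id = r$site_id, n = r$area_series$n,
             S = r$mk$S, varS = r$mk$varS, Zc = r$mk$Zc, p = r$mk$p,
             r1 = r$mk$r1, trend_class = r$mk$trend_class,
             mean_area_km2 = r$summary$mean,
             max_min_ratio = r$summary$max_min_ratio,
             overall_accuracy = r$error_matrix$overall_accuracy)
}

#' @export
print.site_report <- function(x, ...) {
  cat("Inundation analysis for", x$site_id, "\n")
  cat("  composites kept:", x$meta$n_composites_kept,
      " rejected:", x$meta$n_composites_rejected, "\n")
  cat(sprintf("  area: mean %.3f km2, range %.3f-%.3f (min %d, max %d)\n",
              x$summary$mean, x$summary$min, x$summary$max,
              x$summary$year_of_min, x$summary$year_of_max))
  cat(sprintf("  Mann-Kendall: S = %d, Zc = %.3f, p = %.4g -> %s\n",
              x$mk$S, x$mk$Zc, x$mk$p, x$mk$trend_class))
  cat(sprintf("  validation: %d points, overall accuracy %.1f%%\n",
              nrow(x$points), x$error_matrix$overall_accuracy))
  invisible(x)
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("Mann-Kendall: n = %d, S = %d, var(S) = %.2f, Zc = %.4f, p = %.4g\n",
              x$n, x$S, x$varS, x$Zc, x$p))
  cat(sprintf("  lag-1 autocorrelation r1 = %.3f%s; trend class: %s\n",
              x$r1, if (x$r1_flag) " (flagged)" else "", x$trend_class))
  invisible(x)
}

#' @export
print.error_matrix <- function(x, ...) {
  cat("Error matrix (rows predicted, columns reference):\n")
  print(x$counts)
  cat(sprintf("overall accuracy %.1f%%; producer's dry %.1f%% wet %.1f%%; user's dry %.1f%% wet %.1f%%\n",
              x$overall_accuracy, x$producers_accuracy["dry"],
              x$producers_accuracy["wet"], x$users_accuracy["dry"],
              x$users_accuracy["wet"]))
  invisible(x)
}

#' @export
print.batch_summary <- function(x, ...) {
  cat("Batch of", nrow(x$sites), "sites",
      if (length(x$failures)) paste0("(", length(x$failures), " failed)") else "", "\n")
  print(x$trend_tally)
  cat(sprintf("mean overall accuracy %.1f%%\n", x$mean_overall_accuracy))
  invisible(x)
}
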