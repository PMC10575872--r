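# Plain-text file interfaces: ESRI ASCII grids for rasters, CSV for
# tables, GeoJSON for reference regions and points, JSON for reports, and
# a flat key=value format for site configs.

#' Write a grid as an ESRI ASCII raster
#'
#' Row 1 of the matrix is the top (northernmost) raster row, matching the
#' ASCII-grid convention. Logical grids are written as 0/1.
#'
#' @param m numeric or logical matrix; NA becomes `nodata_value`.
#' @param path output file.
#' @param cellsize pixel size in the coordinate units (metres).
#' @param xllcorner,yllcorner lower-left corner coordinates.
#' @param nodata_value sentinel written for NA.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, path, cellsize = 30, xllcorner = 0,
                             yllcorner = 0, nodata_value = -9999) {
  if (is.logical(m)) m <- m * 1L
  m[is.na(m)] <- nodata_value
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(m)), paste("nrows", nrow(m)),
               paste("xllcorner", xllcorner), paste("yllcorner", yllcorner),
               paste("cellsize", cellsize), paste("NODATA_value", nodata_value)),
             con)
  write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster into a matrix
#'
#' @param path file written by [write_ascii_grid()] or any conforming tool.
#' @return numeric matrix with NA at nodata; `cellsize`, `xllcorner`,
#'   `yllcorner` attached as attributes.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "cellsize") <- hdr$cellsize
  attr(m, "xllcorner") <- hdr$xllcorner
  attr(m, "yllcorner") <- hdr$yllcorner
  m
}

#' Export a binary mask as GeoJSON pixel polygons
#'
#' Writes every TRUE pixel as a square polygon in a FeatureCollection,
#' using a local metre-based coordinate frame with the grid's lower-left
#' corner at the origin.
#'
#' @param mask logical matrix (row 1 = top row).
#' @param path output file.
#' @param cellsize pixel edge length.
#' @return `path`, invisibly.
#' @export
write_mask_geojson <- function(mask, path, cellsize = 30) {
  nr <- nrow(mask)
  idx <- which(mask, arr.ind = TRUE)
  feats <- lapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    x0 <- (c - 1) * cellsize; y0 <- (nr - r) * cellsize
    ring <- list(c(x0, y0), c(x0 + cellsize, y0),
                 c(x0 + cellsize, y0 + cellsize), c(x0, y0 + cellsize),
                 c(x0, y0))
    list(type = "Feature",
         properties = list(row = unname(r), col = unname(c)),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a threshold-record series as CSV
#'
#' @param thresholds list of [compute_swir_threshold()] records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_threshold_csv <- function(thresholds, path) {
  df <- do.call(rbind, lapply(thresholds, function(t)
    data.frame(year = t$year, swir_wet = t$swir_wet, swir_dry = t$swir_dry,
               swir_threshold = t$swir_threshold, degenerate = t$degenerate)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write validation points as CSV
#'
#' @param points a [sample_validation_points()] data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(points, path) {
  write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Write an error matrix with its accuracies as CSV
#'
#' Layout: the 2x2 counts (rows predicted, columns reference) followed by
#' the accuracy rows, all labelled.
#'
#' @param em an [build_error_matrix()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_error_matrix_csv <- function(em, path) {
  df <- data.frame(
    quantity = c("count_pred_dry_ref_dry", "count_pred_dry_ref_wet",
                 "count_pred_wet_ref_dry", "count_pred_wet_ref_wet",
                 "n_total", "overall_accuracy_pct",
                 "producers_accuracy_dry_pct", "producers_accuracy_wet_pct",
                 "users_accuracy_dry_pct", "users_accuracy_wet_pct"),
    value = c(em$counts[1, 1], em$counts[1, 2], em$counts[2, 1], em$counts[2, 2],
              em$n_total, em$overall_accuracy,
              em$producers_accuracy["dry"], em$producers_accuracy["wet"],
              em$users_accuracy["dry"], em$users_accuracy["wet"]))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a site config to a flat key=value text file
#'
#' @param config a [site_truth_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_config <- function(config, path) {
  writeLines(config_lines(config), path)
  invisible(path)
}

config_lines <- function(config) {
  vapply(names(unclass(config)), function(k)
    paste0(k, "=", paste(config[[k]], collapse = ",")), character(1))
}

#' Read a site config from a flat key=value text file
#'
#' @param path file written by [write_site_config()].
#' @return A [site_truth_config()].
#' @export
read_site_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(site_truth_config, vals)
}

# Stable hash of a config for provenance metadata.
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(config_lines(config), f)
  unname(tools::md5sum(f))
}

#' Serialize a site report to JSON
#'
#' Writes the scalar/tabular parts of a [run_site()] report (filter
#' report, thresholds, area series, trend result, summary, error matrix,
#' metadata); grids live in their own raster files.
#'
#' @param report a `site_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_site_report_json <- function(report, path) {
  x <- list(
    site_id = report$site_id,
    config = unclass(report$config),
    filter_report = report$filter_report,
    thresholds = lapply(report$thresholds, unclass),
    area_series = report$area_series[c("site_id", "years", "areas",
                                       "n_nodata", "pixel_area", "n")],
    mk = unclass(report$mk),
    summary = unclass(report$summary),
    error_matrix = list(counts = report$error_matrix$counts,
                        n_total = report$error_matrix$n_total,
                        overall_accuracy = report$error_matrix$overall_accuracy,
                        producers_accuracy = as.list(report$error_matrix$producers_accuracy),
                        users_accuracy = as.list(report$error_matrix$users_accuracy)),
    meta = report$meta)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(path)
}

# Write every file-based intermediate of a site run; returns the report
# with meta$paths filled.
write_site_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ps <- report$config$pixel_size
  p <- list()
  p$config <- write_site_config(report$config, file.path(out_dir, "config.txt"))
  p$thresholds <- write_threshold_csv(report$thresholds,
                                      file.path(out_dir, "thresholds.csv"))
  p$filter_report <- file.path(out_dir, "filter_report.csv")
  write.csv(report$filter_report, p$filter_report, row.names = FALSE)
  p$frequency <- write_ascii_grid(report$frequency$percent,
                                  file.path(out_dir, "frequency_pct.asc"),
                                  cellsize = ps)
  p$area_series <- file.path(out_dir, "area_series.csv")
  write.csv(data.frame(site_id = report$area_series$site_id,
                       year = report$area_series$years,
                       area_km2 = report$area_series$areas,
                       n_nodata = report$area_series$n_nodata),
            p$area_series, row.names = FALSE)
  p$trend <- file.path(out_dir, "trend.csv")
  write.csv(site_report_row(report), p$trend, row.names = FALSE)
  p$points <- write_points_csv(report$points, file.path(out_dir, "points.csv"))
  p$error_matrix <- write_error_matrix_csv(report$error_matrix,
                                           file.path(out_dir, "error_matrix.csv"))
  for (m in report$maps)
    write_ascii_grid(m$labels, file.path(out_dir,
                     sprintf("inundation_%d.asc", m$year)), cellsize = ps)
  p$maps_dir <- out_dir
  report$meta$paths <- p
  p$report <- file.path(out_dir, "report.json")
  report$meta$paths <- p
  write_site_report_json(report, p$report)
  report
}
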