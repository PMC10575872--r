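# Image-based accuracy assessment: seeded random validation points (by
# default 50 points in each of 5 randomly chosen years, 250 per site),
# predicted labels read off the inundation maps, reference labels from
# photo-interpretation (or the synthetic truth), and the 2x2 error matrix
# with overall, producer's and user's accuracies.

#' Draw seeded random validation points over inundation maps
#'
#' Chooses `n_years` of the available years uniformly without replacement,
#' then per chosen year draws `n_points_per_year` positions independently
#' and uniformly over the map's valid (non-nodata) pixels, so every point
#' carries a usable predicted label. Fully reproducible from the seed.
#'
#' @param maps list of [classify_inundation()] maps, one per available year.
#' @param n_years number of years to validate (default 5).
#' @param n_points_per_year points per chosen year (default 50).
#' @param seed integer seed.
#' @param site_id identifier carried into the points table.
#' @return data frame: `site_id`, `year`, `row`, `col`, `predicted`,
#'   `reference` (the last two NA until filled).
#' @export
sample_validation_points <- function(maps, n_years = 5, n_points_per_year = 50,
                                     seed = 1L, site_id = "site") {
  years <- vapply(maps, function(m) as.numeric(m$year), numeric(1))
  if (length(years) < n_years)
    stop("only ", length(years), " available years; cannot validate ", n_years)
  with_seed(derive_seed(seed, "validation"), {
    chosen <- sort(sample(years, n_years))
    out <- lapply(chosen, function(y) {
      m <- maps[[which(years == y)]]
      ok <- which(!is.na(m$labels))
      if (length(ok) == 0) stop("year ", y, ": map has no valid pixels to sample")
      pick <- ok[sample.int(length(ok), n_points_per_year, replace = TRUE)]
      data.frame(site_id = site_id, year = y,
                 row = row(m$labels)[pick], col = col(m$labels)[pick],
                 predicted = NA_integer_, reference = NA_integer_)
    })
    do.call(rbind, out)
  })
}

#' Fill predicted labels from the inundation maps
#'
#' @param maps list of [classify_inundation()] maps covering every year in
#'   `points`.
#' @param points a [sample_validation_points()] data frame.
#' @return `points` with `predicted` filled from the map labels.
#' @export
extract_predicted_labels <- function(maps, points) {
  years <- vapply(maps, function(m) as.numeric(m$year), numeric(1))
  for (y in unique(points$year)) {
    i <- which(years == y)
    if (length(i) == 0) stop("no inundation map for year ", y)
    sel <- points$year == y
    points$predicted[sel] <- maps[[i]]$labels[cbind(points$row[sel], points$col[sel])]
  }
  if (anyNA(points$predicted)) stop("validation point fell on a nodata pixel")
  points
}

#' Build the 2x2 error matrix and its accuracies
#'
#' Rows are the predicted class (dry, wet), columns the reference class.
#' Overall accuracy is the diagonal sum over the total count; producer's
#' accuracy divides each diagonal entry by its reference-column total
#' (complement of omission error); user's accuracy divides it by its
#' predicted-row total (complement of commission error). All are reported
#' as percentages; a class absent from the reference has no defined
#' producer's accuracy and is reported NA, not 0.
#'
#' @param points data frame with binary `predicted` and `reference`
#'   columns, no missing values.
#' @return An object of class `error_matrix`: `counts` (2x2), `n_total`,
#'   `overall_accuracy`, `producers_accuracy` (named: dry, wet),
#'   `users_accuracy` (named: dry, wet).
#' @export
build_error_matrix <- function(points) {
  if (nrow(points) < 1) stop("no validation points")
  if (anyNA(points$predicted) || anyNA(points$reference))
    stop("every validation point needs both predicted and reference labels")
  stopifnot(all(points$predicted %in% 0:1), all(points$reference %in% 0:1))
  counts <- matrix(0L, 2, 2, dimnames = list(predicted = c("dry", "wet"),
                                             reference = c("dry", "wet")))
  for (i in seq_len(nrow(points)))
    counts[points$predicted[i] + 1L, points$reference[i] + 1L] <-
      counts[points$predicted[i] + 1L, points$reference[i] + 1L] + 1L
  error_matrix_from_counts(counts)
}

#' Accuracies from an existing 2x2 count matrix
#'
#' @param counts 2x2 integer matrix, rows = predicted (dry, wet),
#'   columns = reference (dry, wet).
#' @return An `error_matrix` object; see [build_error_matrix()].
#' @export
error_matrix_from_counts <- function(counts) {
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  n <- sum(counts)
  if (n < 1) stop("empty error matrix")
  dimnames(counts) <- list(predicted = c("dry", "wet"), reference = c("dry", "wet"))
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  pa <- ifelse(col_tot > 0, 100 * diag(counts) / col_tot, NA_real_)
  ua <- ifelse(row_tot > 0, 100 * diag(counts) / row_tot, NA_real_)
  names(pa) <- names(ua) <- c("dry", "wet")
  structure(list(counts = counts, n_total = n,
                 overall_accuracy = 100 * sum(diag(counts)) / n,
                 producers_accuracy = pa, users_accuracy = ua),
            class = "error_matrix")
}
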