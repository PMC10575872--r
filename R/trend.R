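# Yearly inundated-area series and their monotonic-trend statistics: the
# nonparametric Mann-Kendall test with tie-corrected variance and
# continuity correction, a lag-1 autocorrelation screen, boxplot-style
# site summaries, and trend-by-covariate cross-tabulation.

#' Yearly inundated-area series from inundation maps
#'
#' Area in year y is the count of pixels labelled inundated times the
#' pixel area; 30 m pixels give `pixel_area = 0.0009` km2. Nodata pixels
#' contribute nothing; their count per year is recorded alongside.
#'
#' @param maps non-empty list of [classify_inundation()] maps.
#' @param pixel_area area of one pixel in km2 (default 0.0009, i.e. 30 m).
#' @param site_id identifier carried into downstream tables.
#' @return An object of class `area_series`: `site_id`, `years`, `areas`
#'   (km2), `n_nodata` (pixels per year), `pixel_area`, `n`.
#' @export
inundated_area_series <- function(maps, pixel_area = 0.0009, site_id = "site") {
  if (length(maps) == 0) stop("no inundation maps supplied")
  stopifnot(pixel_area > 0)
  years <- as.integer(vapply(maps, function(m) as.numeric(m$year), numeric(1)))
  o <- order(years)
  maps <- maps[o]; years <- years[o]
  areas <- vapply(maps, function(m) sum(m$labels == 1L, na.rm = TRUE) * pixel_area,
                  numeric(1))
  n_nodata <- vapply(maps, function(m) sum(is.na(m$labels)), numeric(1))
  structure(list(site_id = site_id, years = years, areas = unname(areas),
                 n_nodata = unname(n_nodata), pixel_area = pixel_area,
                 n = length(years)),
            class = "area_series")
}

#' Mann-Kendall monotonic trend test
#'
#' Computes the Kendall sum `S = sum_{i<j} sign(x_j - x_i)`, its
#' tie-corrected variance
#' `varS = [n(n-1)(2n+5) - sum_p t_p(t_p-1)(2t_p+5)] / 18`
#' over tie groups of size `t_p`, and the continuity-corrected standard
#' score `Zc = (S - sign(S)) / sqrt(varS)` (0 when S = 0), with a
#' two-sided normal p-value. A trend is called significant when
#' `|Zc| > 1.96` (p < 0.05); the sign of Zc splits the remaining classes:
#'
#' * `significantly_increasing`: Zc >  1.96
#' * `increasing`:               0 < Zc <= 1.96
#' * `no_trend`:                 Zc = 0
#' * `decreasing`:               -1.96 <= Zc < 0
#' * `significantly_decreasing`: Zc < -1.96
#'
#' The lag-1 autocorrelation of the series is computed as a screen and
#' annotates the result; it does not alter the test. Optional pre-whitening
#' (`prewhiten = TRUE`) removes an AR(1) component `x_t - r1 * x_(t-1)`
#' before testing, for series where the screen flags serial dependence.
#'
#' @param values numeric series in time order, length >= 3 (lengths < 8
#'   trigger a small-sample warning: the normal approximation weakens).
#' @param prewhiten remove the estimated AR(1) component first.
#' @return An object of class `mk_result`: `S`, `varS`, `Zc`, `p`, `n`,
#'   `r1`, `r1_flag`, `trend_class`, `prewhitened`.
#' @export
mann_kendall <- function(values, prewhiten = FALSE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("Mann-Kendall test needs at least 3 values")
  if (anyNA(x)) stop("Mann-Kendall test does not accept missing values")
  if (n < 8) warning("n < 8: Mann-Kendall normal approximation is weak for small samples")
  ac <- lag1_autocorr(x)
  if (prewhiten && ac$r1_flag && !ac$degenerate) {
    x <- x[-1] - ac$r1 * x[-n]
    n <- length(x)
  }
  S <- sum(sign(outer(x, x, "-"))[lower.tri(matrix(0, n, n))])
  ties <- table(x)
  t_p <- as.numeric(ties[ties > 1])
  varS <- (n * (n - 1) * (2 * n + 5) - sum(t_p * (t_p - 1) * (2 * t_p + 5))) / 18
  Zc <- if (S > 0) (S - 1) / sqrt(varS)
        else if (S < 0) (S + 1) / sqrt(varS)
        else 0
  if (varS == 0) Zc <- 0                               # all values tied
  p <- 2 * pnorm(-abs(Zc))
  trend_class <- if (Zc > 1.96) "significantly_increasing"
                 else if (Zc > 0) "increasing"
                 else if (Zc == 0) "no_trend"
                 else if (Zc >= -1.96) "decreasing"
                 else "significantly_decreasing"
  structure(list(S = S, varS = varS, Zc = Zc, p = p, n = n,
                 r1 = ac$r1, r1_flag = ac$r1_flag,
                 trend_class = trend_class, prewhitened = isTRUE(prewhiten)),
            class = "mk_result")
}

#' Lag-1 autocorrelation screen
#'
#' Sample lag-1 autocorrelation of the mean-centred series,
#' `r1 = sum((x_t - m)(x_(t+1) - m)) / sum((x_t - m)^2)`, flagged when
#' `|r1| > 1.96 / sqrt(n)` (the approximate 5% white-noise bound). A
#' zero-variance series has no defined autocorrelation; it is reported as
#' 0 with a degenerate flag.
#'
#' @param values numeric series in time order, length >= 3.
#' @return list with `r1`, `r1_flag`, `degenerate`, `n`.
#' @export
lag1_autocorr <- function(values) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 3) stop("lag-1 autocorrelation needs at least 3 values")
  m <- mean(x)
  v <- sum((x - m)^2)
  if (v == 0)
    return(list(r1 = 0, r1_flag = FALSE, degenerate = TRUE, n = n))
  r1 <- sum((x[-n] - m) * (x[-1] - m)) / v
  list(r1 = r1, r1_flag = abs(r1) > 1.96 / sqrt(n), degenerate = FALSE, n = n)
}

#' Boxplot-style summary of an area series
#'
#' Minimum, first quartile, mean, third quartile, maximum (quartiles by
#' linear interpolation between order statistics), the years of minimum
#' and maximum extent (earliest year wins ties), and the max/min extent
#' ratio -- undefined (NA, flagged) when the minimum is zero rather than
#' infinite.
#'
#' @param series an [inundated_area_series()] result.
#' @return An object of class `site_summary`.
#' @export
site_summary <- function(series) {
  x <- series$areas
  stopifnot(length(x) >= 1)
  q <- unname(quantile(x, c(0.25, 0.75), type = 7))
  i_min <- which.min(x); i_max <- which.max(x)       # which.* take the earliest tie
  ratio_defined <- min(x) > 0
  structure(list(site_id = series$site_id,
                 min = min(x), q1 = q[1], mean = mean(x), q3 = q[2], max = max(x),
                 year_of_min = series$years[i_min],
                 year_of_max = series$years[i_max],
                 max_min_ratio = if (ratio_defined) max(x) / min(x) else NA_real_,
                 ratio_defined = ratio_defined),
            class = "site_summary")
}

TREND_CLASSES <- c("significantly_decreasing", "decreasing", "no_trend",
                   "increasing", "significantly_increasing")

#' Cross-tabulate trend classes against a binned covariate
#'
#' Counts sites per (trend class, covariate bin) with half-open bins
#' `[lo, hi)` -- a value on an interior edge joins the upper bin. Values
#' outside every bin fall into an explicit `outside` column rather than
#' being dropped.
#'
#' @param site_table data frame with columns `site_id`, `trend_class`,
#'   `covariate`.
#' @param bin_edges strictly increasing numeric bin boundaries.
#' @return integer matrix (rows: the five trend classes; columns: bins
#'   plus `outside`) with `row_margin` and `col_margin` attributes.
#' @export
covariate_crosstab <- function(site_table, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  k <- length(bin_edges) - 1
  labels <- paste0("[", bin_edges[-length(bin_edges)], ",", bin_edges[-1], ")")
  idx <- findInterval(site_table$covariate, bin_edges)
  idx[site_table$covariate >= bin_edges[length(bin_edges)]] <- 0L  # overflow high
  cls <- factor(site_table$trend_class, levels = TREND_CLASSES)
  if (anyNA(cls)) stop("unknown trend_class in site_table")
  counts <- matrix(0L, length(TREND_CLASSES), k + 1,
                   dimnames = list(TREND_CLASSES, c(labels, "outside")))
  for (i in seq_along(idx)) {
    col <- if (idx[i] >= 1 && idx[i] <= k) idx[i] else k + 1L
    counts[as.integer(cls[i]), col] <- counts[as.integer(cls[i]), col] + 1L
  }
  attr(counts, "row_margin") <- rowSums(counts)
  attr(counts, "col_margin") <- colSums(counts)
  counts
}
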