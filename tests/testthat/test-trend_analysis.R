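mkmap <- function(labels, year) structure(
  list(year = year, labels = labels, threshold_used = NULL),
  class = "inundation_map")

test_that("area series converts inundated pixel counts at 30 m to km2", {
  empty <- mkmap(matrix(0L, 3, 3), 2000)
  expect_equal(inundated_area_series(list(empty))$areas, 0)

  lab <- matrix(0L, 40, 40)
  lab[seq_len(1234)] <- 1L
  s <- inundated_area_series(list(mkmap(lab, 2001)))
  expect_equal(s$areas, 1.1106)         # 1234 x 0.0009 km2

  lab[3, 3] <- NA_integer_
  s2 <- inundated_area_series(list(mkmap(lab, 2001)))
  expect_equal(s2$n_nodata, 1)

  # years are ordered regardless of input order
  s3 <- inundated_area_series(list(mkmap(lab, 2005), mkmap(lab, 2001)))
  expect_equal(s3$years, c(2001L, 2005L))
  expect_error(inundated_area_series(list()), "no inundation maps")
})

test_that("Mann-Kendall reproduces hand-enumerated statistics", {
  r <- suppressWarnings(mann_kendall(1:5))
  expect_identical(r$S, 10)
  expect_equal(r$varS, 50 / 3)
  expect_equal(r$Zc, 9 / sqrt(50 / 3))
  expect_equal(r$trend_class, "significantly_increasing")
  expect_equal(r$p, 2 * pnorm(-9 / sqrt(50 / 3)))

  const <- suppressWarnings(mann_kendall(rep(4, 6)))
  expect_identical(const$S, 0)
  expect_identical(const$Zc, 0)
  expect_equal(const$trend_class, "no_trend")

  fwd <- suppressWarnings(mann_kendall(c(3, 1, 4, 1, 5)))
  rev <- suppressWarnings(mann_kendall(rev(c(3, 1, 4, 1, 5))))
  expect_identical(rev$S, -fwd$S)
  expect_equal(rev$Zc, -fwd$Zc)

  expect_error(mann_kendall(c(1, 2)), "at least 3")
  expect_warning(mann_kendall(1:5), "small samples")
})

test_that("S, varS and Zc match the brute-force oracle on random tied series", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:40, 1)
    x <- if (rep %% 2) rnorm(n) else round(rnorm(n), sample(0:1, 1))
    r <- suppressWarnings(mann_kendall(x))
    o <- mk_oracle(x)
    expect_identical(r$S, o$S)
    expect_identical(r$varS, o$varS)
    expect_equal(r$Zc, o$Zc, tolerance = 1e-12)
    # continuity correction sends |S| <= 1 to Zc = 0; otherwise signs agree
    expect_true(r$Zc == 0 || sign(r$Zc) == sign(r$S))
  }
})

test_that("the trend verdict is invariant to rescaling the areas", {
  set.seed(7)
  x <- cumsum(rnorm(25)) + 50
  a <- mann_kendall(x)
  b <- mann_kendall(1000 * x)
  expect_identical(a[c("S", "varS", "Zc", "p", "trend_class")],
                   b[c("S", "varS", "Zc", "p", "trend_class")])
})

test_that("lag-1 autocorrelation estimates AR(1) structure and flags it", {
  set.seed(13)
  # AR(1) with coefficient 0.8: estimate lands near 0.8 and is flagged
  n <- 1000
  x <- numeric(n); x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- 0.8 * x[t - 1] + rnorm(1)
  ac <- lag1_autocorr(x)
  expect_lt(abs(ac$r1 - 0.8), 0.05)
  expect_true(ac$r1_flag)

  # white noise: |r1| below 0.08 in at least 95% of replicates
  inside <- vapply(1:100, function(i) abs(lag1_autocorr(rnorm(1000))$r1) < 0.08,
                   logical(1))
  expect_gte(mean(inside), 0.95)

  z <- lag1_autocorr(rep(2, 10))
  expect_true(z$degenerate)
  expect_identical(z$r1, 0)
  expect_false(z$r1_flag)
})

test_that("pre-whitening engages only when the screen flags dependence", {
  set.seed(19)
  n <- 60
  x <- numeric(n); x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- 0.9 * x[t - 1] + rnorm(1)
  pw <- mann_kendall(x, prewhiten = TRUE)
  expect_true(pw$prewhitened)
  expect_equal(pw$n, n - 1)             # one observation consumed by the AR(1) filter
  iid <- mann_kendall(rnorm(n), prewhiten = TRUE)
  expect_equal(iid$n, n)                # screen not flagged: series untouched
})

test_that("site summaries use interpolated quartiles and flag zero minima", {
  series <- function(areas, years = seq_along(areas) + 2000)
    structure(list(site_id = "s", years = years, areas = areas,
                   n_nodata = rep(0, length(areas)), pixel_area = 9e-4,
                   n = length(areas)), class = "area_series")

  s1 <- site_summary(series(c(2, 2, 2)))
  expect_equal(unlist(s1[c("min", "q1", "mean", "q3", "max", "max_min_ratio")]),
               c(min = 2, q1 = 2, mean = 2, q3 = 2, max = 2, max_min_ratio = 1))

  s2 <- site_summary(series(c(1, 2, 3, 4, 5)))
  expect_equal(s2$q1, 2); expect_equal(s2$q3, 4)
  expect_equal(s2$mean, 3); expect_equal(s2$max_min_ratio, 5)
  expect_equal(s2$year_of_min, 2001); expect_equal(s2$year_of_max, 2005)

  s3 <- site_summary(series(c(3, 0, 5)))
  expect_true(is.na(s3$max_min_ratio))
  expect_false(s3$ratio_defined)

  # ties go to the earliest year
  s4 <- site_summary(series(c(5, 1, 1, 5)))
  expect_equal(s4$year_of_min, 2002)
  expect_equal(s4$year_of_max, 2001)
})

test_that("trend-by-covariate crosstab uses half-open bins with an overflow column", {
  tab <- data.frame(site_id = "a", trend_class = "increasing", covariate = 120)
  ct <- covariate_crosstab(tab, c(0, 100, 200))
  expect_equal(sum(ct), 1)
  expect_equal(ct["increasing", "[100,200)"], 1L)
  expect_equal(attr(ct, "row_margin")[["increasing"]], 1L)

  many <- data.frame(site_id = letters[1:4],
                     trend_class = c("no_trend", "decreasing",
                                     "significantly_increasing", "increasing"),
                     covariate = c(100, 100, 250, -5))
  ct2 <- covariate_crosstab(many, c(0, 100, 200))
  # value exactly on the interior edge joins the upper bin
  expect_equal(ct2["no_trend", "[100,200)"], 1L)
  expect_equal(ct2["decreasing", "[100,200)"], 1L)
  # values outside all bins land in the overflow column, high or low
  expect_equal(ct2["significantly_increasing", "outside"], 1L)
  expect_equal(ct2["increasing", "outside"], 1L)
  expect_equal(sum(attr(ct2, "col_margin")), 4L)

  expect_error(covariate_crosstab(tab, c(1, 1, 2)), "strictly increasing")
  expect_error(covariate_crosstab(data.frame(site_id = "x", trend_class = "up",
                                             covariate = 1), c(0, 1)),
               "trend_class")
})
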