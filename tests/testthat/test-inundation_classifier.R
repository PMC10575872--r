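comp_from <- function(swir, year = 2000) structure(
  list(year = year, swir = swir, masked_fraction = mean(is.na(swir)),
       n_scenes = 1L, has_swir = TRUE), class = "annual_composite")

refs_from <- function(wet, dry) structure(list(wet_mask = wet, dry_mask = dry),
                                          class = "reference_regions")

test_that("the SWIR threshold interpolates 3/10 of the wet-dry contrast", {
  swir <- matrix(c(0, 0, 1, 1), 2, 2)
  refs <- refs_from(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                    matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  thr <- compute_swir_threshold(comp_from(swir), refs)
  expect_identical(thr$swir_threshold, 0.3)
  expect_identical(thr$swir_wet, 0)
  expect_identical(thr$swir_dry, 1)
  expect_false(thr$degenerate)

  swir2 <- matrix(c(0.05, 0.05, 0.25, 0.25), 2, 2)
  thr2 <- compute_swir_threshold(comp_from(swir2), refs)
  expect_equal(thr2$swir_threshold, 0.11)
  expect_true(thr2$swir_wet < thr2$swir_threshold &&
              thr2$swir_threshold < thr2$swir_dry)

  # zero wet-dry span: threshold collapses and is flagged degenerate
  thr3 <- compute_swir_threshold(comp_from(matrix(0.2, 2, 2)), refs)
  expect_equal(thr3$swir_threshold, 0.2)
  expect_true(thr3$degenerate)

  # the coefficient is configurable
  expect_equal(compute_swir_threshold(comp_from(swir), refs,
                                      coefficient = 0.5)$swir_threshold, 0.5)
})

test_that("medians ignore nodata reference pixels and empty references error", {
  swir <- matrix(c(0.05, NA, 0.9, 0.25), 2, 2)
  refs <- refs_from(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2),
                    matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2))
  thr <- compute_swir_threshold(comp_from(swir), refs)
  expect_equal(thr$swir_wet, 0.05)      # the NA wet pixel is excluded
  expect_equal(thr$swir_dry, 0.25)

  all_na <- comp_from(matrix(NA_real_, 2, 2))
  expect_error(compute_swir_threshold(all_na, refs), "wet reference")
  dry_gone <- refs_from(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2))
  expect_error(compute_swir_threshold(comp_from(swir), dry_gone), "dry reference")
})

test_that("classification thresholds strictly below, ties to dry, nodata kept", {
  thr <- structure(list(year = 2000, swir_wet = 0.05, swir_dry = 0.25,
                        swir_threshold = 0.11, coefficient = 0.3,
                        degenerate = FALSE), class = "threshold_record")
  swir <- matrix(c(0.05, 0.11, 0.1099, NA), 2, 2)
  m <- classify_inundation(comp_from(swir), thr)
  expect_identical(m$labels, matrix(c(1L, 0L, 1L, NA), 2, 2))

  all_wet <- classify_inundation(comp_from(matrix(0.05, 3, 3)), thr)
  expect_true(all(all_wet$labels == 1L))

  thr$degenerate <- TRUE
  expect_error(classify_inundation(comp_from(swir), thr), "degenerate")
  over <- classify_inundation(comp_from(swir), thr, allow_degenerate = TRUE)
  expect_identical(over$labels[1, 1], 1L)
})

test_that("a noise-free synthetic composite classifies to the truth exactly", {
  cfg <- quiet_config()
  tr <- generate_truth(cfg)
  scs <- lapply(render_scene_set(tr, 2005), apply_cloud_mask)
  cm <- build_annual_composite(scs, 2005)
  refs <- derive_reference_regions(tr, 1)
  thr <- compute_swir_threshold(cm, refs)
  m <- classify_inundation(cm, thr)
  expect_identical(m$labels == 1L, tr$masks[["2005"]])
})

test_that("classifier agrees with an exhaustive per-pixel oracle on small grids", {
  set.seed(41)
  for (rep in 1:20) {
    nr <- sample(3:10, 1); nc <- sample(3:10, 1)
    swir <- matrix(runif(nr * nc), nr, nc)
    swir[sample(nr * nc, round(0.1 * nr * nc))] <- NA
    wet <- matrix(FALSE, nr, nc); dry <- matrix(FALSE, nr, nc)
    wet[sample(which(!is.na(swir)), 3)] <- TRUE
    dry[sample(setdiff(which(!is.na(swir)), which(wet)), 3)] <- TRUE
    cm <- comp_from(swir)
    thr <- compute_swir_threshold(cm, refs_from(wet, dry))
    got <- classify_inundation(cm, thr, allow_degenerate = TRUE)$labels
    expect_identical(got, classify_oracle(swir, wet, dry))
  }
})

test_that("classification is invariant under affine reflectance maps", {
  set.seed(43)
  for (rep in 1:20) {
    swir <- matrix(runif(64, 0, 0.5), 8, 8)
    wet <- matrix(FALSE, 8, 8); dry <- matrix(FALSE, 8, 8)
    wet[sample(64, 4)] <- TRUE
    dry[sample(which(!wet), 4)] <- TRUE
    refs <- refs_from(wet, dry)
    a <- runif(1, 0.2, 3); b <- runif(1, -0.1, 0.4)
    base <- classify_inundation(comp_from(swir),
              compute_swir_threshold(comp_from(swir), refs),
              allow_degenerate = TRUE)
    mapped <- classify_inundation(comp_from(a * swir + b),
                compute_swir_threshold(comp_from(a * swir + b), refs),
                allow_degenerate = TRUE)
    expect_identical(base$labels, mapped$labels)
  }
})

test_that("raising a pixel's reflectance never flips it from dry to wet", {
  set.seed(47)
  swir <- matrix(runif(100, 0, 0.4), 10, 10)
  wet <- matrix(FALSE, 10, 10); dry <- matrix(FALSE, 10, 10)
  wet[order(swir)[1:5]] <- TRUE
  dry[order(swir, decreasing = TRUE)[1:5]] <- TRUE
  refs <- refs_from(wet, dry)
  thr <- compute_swir_threshold(comp_from(swir), refs)
  base <- classify_inundation(comp_from(swir), thr)$labels
  px <- sample(setdiff(which(!wet & !dry), which(is.na(swir))), 10)
  for (p in px) {
    bumped <- swir
    bumped[p] <- bumped[p] + runif(1, 0, 0.5)
    thr_b <- compute_swir_threshold(comp_from(bumped), refs)
    lab <- classify_inundation(comp_from(bumped), thr_b)$labels
    expect_false(base[p] == 0L && lab[p] == 1L)
  }
})

test_that("frequency is the percent of available years inundated, per pixel", {
  mkmap <- function(labels, year) structure(
    list(year = year, labels = labels, threshold_used = NULL),
    class = "inundation_map")
  # pixel [1,1]: wet 3 of 10 valid years; pixel [2,1]: nodata in 4 years,
  # wet in 3 of the 6 valid ones; pixel [1,2] always wet; [2,2] never
  maps <- lapply(1:10, function(i) {
    lab <- matrix(0L, 2, 2)
    lab[1, 1] <- if (i <= 3) 1L else 0L
    lab[2, 1] <- if (i <= 4) NA_integer_ else if (i <= 7) 1L else 0L
    lab[1, 2] <- 1L
    mkmap(lab, 2000 + i)
  })
  fr <- inundation_frequency(maps)
  expect_equal(fr$percent, matrix(c(30, 50, 100, 0), 2, 2))
  expect_equal(fr$n_years_available, matrix(c(10L, 6L, 10L, 10L), 2, 2))

  # a pixel with no valid label in any year is nodata with denominator 0
  allna <- lapply(maps, function(m) { m$labels[2, 2] <- NA_integer_; m })
  fr2 <- inundation_frequency(allna)
  expect_true(is.na(fr2$percent[2, 2]))
  expect_equal(fr2$n_years_available[2, 2], 0L)

  small <- mkmap(matrix(0L, 3, 3), 2050)
  expect_error(inundation_frequency(c(maps, list(small))), "geometry")
  expect_error(inundation_frequency(list()), "no inundation maps")
})
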