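# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, stats::median per pixel) so they share
# no code path with the implementation they check.

# Mann-Kendall by explicit pair enumeration and tie counting.
mk_oracle <- function(x) {
  n <- length(x)
  S <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) S <- S + sign(x[j] - x[i])
  tie_sizes <- c()
  for (v in unique(x)) {
    cnt <- sum(x == v)
    if (cnt > 1) tie_sizes <- c(tie_sizes, cnt)
  }
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(tie_sizes * (tie_sizes - 1) * (2 * tie_sizes + 5))) / 18
  Zc <- if (varS == 0) 0
        else if (S > 0) (S - 1) / sqrt(varS)
        else if (S < 0) (S + 1) / sqrt(varS)
        else 0
  list(S = S, varS = varS, Zc = Zc)
}

# Count pixels whose centres fall inside a disc, by exhaustive loop.
disc_pixel_count <- function(nr, nc, center, radius_px) {
  count <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if ((r - center[1])^2 + (c - center[2])^2 <= radius_px^2) count <- count + 1
  }
  count
}

# Per-pixel threshold reclassification, written independently of
# classify_inundation: medians via stats::median, explicit double loop.
classify_oracle <- function(swir, wet_mask, dry_mask, coefficient = 0.3) {
  wet_med <- median(swir[wet_mask & !is.na(swir)])
  dry_med <- median(swir[dry_mask & !is.na(swir)])
  thr <- wet_med + coefficient * (dry_med - wet_med)
  out <- matrix(NA_integer_, nrow(swir), ncol(swir))
  for (r in seq_len(nrow(swir))) for (c in seq_len(ncol(swir))) {
    v <- swir[r, c]
    if (!is.na(v)) out[r, c] <- if (v < thr) 1L else 0L
  }
  out
}

# A clear-sky scene with a constant-valued grid, for compositing contracts.
flat_scene <- function(value, date, nr = 5, nc = 5, id = paste0("s", value, date)) {
  scene(swir = matrix(value, nr, nc), qa = matrix(0L, nr, nc),
        date = date, scene_id = id)
}

# Small noise-free site config used across end-to-end tests.
quiet_config <- function(...) {
  defaults <- list(grid_rows = 40, grid_cols = 40, base_radius = 300,
                   years = 2001:2015, sd_wet = 0, sd_dry = 0,
                   interannual_noise_sd = 0, cloud_fraction = 0,
                   missing_band_prob = 0, label_noise_rate = 0, seed = 7)
  args <- utils::modifyList(defaults, list(...))
  do.call(site_truth_config, args)
}
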