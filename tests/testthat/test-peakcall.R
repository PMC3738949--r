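# track-pair builder from explicit normalized vectors (bypasses read I/O)
tracks_from_values <- function(values, bin_size = 100L, smooth = FALSE) {
  g <- genome_table(names(values), lengths(values) * bin_size)
  raw <- values
  tr <- tracks_from_raw(raw, g, bin_size = bin_size,
                        fragment_length = bin_size, smoothing_width = bin_size,
                        smooth = smooth)
  # overwrite normalization: use the values as-is so tests control intensity
  for (ch in g$chrom) {
    tr$chroms[[ch]]$normalized <- values[[ch]]
    tr$chroms[[ch]]$smoothed <- values[[ch]]
  }
  tr$chrom_stats$mean_depth <- vapply(values, mean, 0)
  tr
}

test_that("a strongly enriched window passes all five thresholds", {
  set.seed(41)
  base <- pmax(rnorm(400, 1, 0.1), 0.01)
  chip <- base
  chip[181:220] <- chip[181:220] * 10      # 10x enrichment, max >> 6
  ctrl <- pmax(rnorm(400, 1, 0.1), 0.01)
  pr <- peak_params()
  win <- window_scan(tracks_from_values(list(c1 = chip)),
                     tracks_from_values(list(c1 = ctrl)), pr)
  covering <- win[win$start_bin >= 185 & win$start_bin <= 190, ]
  expect_true(all(covering$significant))
  pc <- call_peaks(tracks_from_values(list(c1 = chip)),
                   tracks_from_values(list(c1 = ctrl)), pr)
  expect_equal(nrow(pc$peaks), 1L)
  expect_gte(pc$peaks$max_intensity, pr$intensity_thresh)
  # summit sits inside the enriched stretch
  expect_gte(pc$peaks$summit, 180 * 100)
  expect_lte(pc$peaks$summit, 220 * 100)
})

test_that("all-zero ChIP windows and identical tracks yield nothing", {
  zeros <- list(c1 = numeric(200))
  ctrl <- list(c1 = rep(1, 200))
  pc <- call_peaks(tracks_from_values(zeros), tracks_from_values(ctrl))
  expect_equal(nrow(pc$peaks), 0L)
  same <- list(c1 = pmax(rnorm(300, 2, 0.5), 0))
  pc2 <- call_peaks(tracks_from_values(same), tracks_from_values(same))
  expect_equal(nrow(pc2$peaks), 0L)    # fold = 1 can never exceed 3
  pc3 <- call_peaks(tracks_from_values(same), tracks_from_values(same))
  expect_identical(pc2$peaks, pc3$peaks)  # swap antisymmetry on identity
})

test_that("high-control repetitive windows are rejected by threshold (iv)", {
  set.seed(42)
  chip <- pmax(rnorm(2000, 1, 0.1), 0.01)
  ctrl <- pmax(rnorm(2000, 1, 0.1), 0.01)
  chip[181:220] <- 100   # passes (i)-(iii) and (v) on its own...
  ctrl[181:220] <- 25    # ...but control is ~17x its chromosome depth
  pc <- call_peaks(tracks_from_values(list(c1 = chip)),
                   tracks_from_values(list(c1 = ctrl)))
  expect_equal(nrow(pc$peaks), 0L)
  expect_gt(pc$rejections[["control_repeat"]], 0)
})

test_that("contiguous significant windows merge; gaps split peaks", {
  w <- 30L
  sig <- data.frame(
    chrom = "c1",
    start_bin = c(0L, 1L, 2L, 60L),
    pvalue = c(1e-6, 1e-8, 1e-5, 1e-6),
    fold = c(4, 6, 5, 4), chip_max = 8, control_mean = 1,
    pass_p = TRUE, pass_fold = TRUE, pass_depth = TRUE,
    pass_repeat = TRUE, pass_intensity = TRUE, significant = TRUE)
  chip <- tracks_from_values(list(c1 = rep(1, 200)))
  pk <- merge_windows(sig, chip, peak_params(window_bins = w))
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$start, c(0, 60) * 100)
  expect_equal(pk$end, c(32, 90) * 100)     # union [0,32), single [60,90)
  expect_equal(pk$pvalue, c(1e-8, 1e-6))
  expect_equal(pk$fold_enrichment, c(6, 4))
  expect_true(all((pk$end - pk$start) %% 100 == 0))
})

test_that("empirical FDR is swapped-peaks over ChIP peaks with guards", {
  set.seed(43)
  chip <- pmax(rnorm(600, 1, 0.1), 0.01)
  chip[101:140] <- chip[101:140] * 12
  ctrl <- pmax(rnorm(600, 1, 0.1), 0.01)
  tc <- tracks_from_values(list(c1 = chip))
  tu <- tracks_from_values(list(c1 = ctrl))
  expect_warning(r <- empirical_fdr(tc, tu), "100")   # < 100 peaks warning
  expect_equal(r$fdr, r$n_control_peaks / r$n_chip_peaks)
  expect_equal(r$fdr, 0)
  # no ChIP peaks -> NA with warning
  expect_warning(r0 <- empirical_fdr(tu, tu), "undefined")
  expect_true(is.na(r0$fdr))
})

test_that("the intensity sweep is consistent and monotone in peak counts", {
  set.seed(44)
  chip <- pmax(rnorm(1000, 1, 0.1), 0.01)
  for (s in c(101, 301, 501, 701)) chip[s:(s + 39)] <- chip[s:(s + 39)] * 10
  ctrl <- pmax(rnorm(1000, 1, 0.1), 0.01)
  tc <- tracks_from_values(list(c1 = chip))
  tu <- tracks_from_values(list(c1 = ctrl))
  tab <- fdr_threshold_sweep(tc, tu, thresholds = c(6, 8, 16))
  expect_equal(nrow(tab), 3L)
  expect_true(all(diff(tab$n_chip_peaks) <= 0))
  one <- fdr_threshold_sweep(tc, tu, thresholds = 6)
  ref <- suppressWarnings(empirical_fdr(tc, tu))
  expect_equal(one$n_chip_peaks, ref$n_chip_peaks)
  expect_equal(one$fdr, ref$fdr)
  expect_equal(nrow(fdr_threshold_sweep(tc, tu, thresholds = numeric(0))), 0L)
  expect_error(fdr_threshold_sweep(tc, tu, thresholds = c(8, 6)), "ascending")
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(peak_params(window_bins = 1), "window_bins")
  expect_error(peak_params(fold_thresh = -1), "positive")
  g <- genome_table("c1", 1000)
  t10 <- tracks_from_raw(list(c1 = rep(1, 100)), g, bin_size = 10)
  t20 <- tracks_from_raw(list(c1 = rep(1, 50)), g, bin_size = 20)
  expect_error(window_scan(t10, t20), "bin-size mismatch")
})
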