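setup_tracks <- function() {
  set.seed(71)
  g <- genome_table("chr9", 2e5)
  raw_c <- rpois(2e4, 15); raw_u <- rpois(2e4, 15)
  raw_c[5001:5100] <- raw_c[5001:5100] * 10
  chip <- tracks_from_raw(list(chr9 = as.numeric(raw_c)), g)
  ctrl <- tracks_from_raw(list(chr9 = as.numeric(raw_u)), g)
  list(g = g, chip = chip, ctrl = ctrl)
}

test_that("region models carry one panel per track with the field colors", {
  s <- setup_tracks()
  pk <- data.frame(chrom = "chr9", start = 50000, end = 51000,
                   stringsAsFactors = FALSE)
  m <- region_plot_model(s$chip, s$ctrl, list("chr9", 40000, 60000),
                         peaks = pk)
  expect_s3_class(m, "track_plot_model")
  expect_equal(vapply(m$panels, `[[`, "", "kind"),
               c("chip", "control", "ratio"))
  chip_bars <- m$panels[[1]]$bars
  # red bins are exactly the peak interval intersected with the region
  red <- chip_bars[chip_bars$color == "red", ]
  expect_equal(min(red$start), 50000)
  expect_equal(max(red$end), 51000)
  expect_true(all(red$start >= 50000 & red$end <= 51000))
  # control panel never turns red
  expect_false(any(m$panels[[2]]$bars$color == "red"))
  expect_true(all(m$panels[[2]]$bars$color == "steelblue"))
  # no peaks -> no red anywhere
  m0 <- region_plot_model(s$chip, s$ctrl, list("chr9", 40000, 60000))
  expect_false(any(vapply(m0$panels, function(p)
    any(p$bars$color == "red"), TRUE)))
})

test_that("region models are deterministic and validate their inputs", {
  s <- setup_tracks()
  m1 <- region_plot_model(s$chip, s$ctrl, list("chr9", 0, 10000))
  m2 <- region_plot_model(s$chip, s$ctrl, list("chr9", 0, 10000))
  expect_identical(m1, m2)
  expect_error(region_plot_model(s$chip, s$ctrl, list("chrX", 0, 100)),
               "chromosome")
  expect_error(region_plot_model(s$chip, s$ctrl, list("chr9", 5e5, 6e5)),
               "bounds")
  expect_error(region_plot_model(s$chip, s$ctrl, list("chr9", 0, 100),
                                 tracks = character(0)), "track")
})

test_that("figures are written in pdf and png", {
  s <- setup_tracks()
  fp <- tempfile(fileext = ".pdf")
  render_region(s$chip, s$ctrl, list("chr9", 0, 2e5), fp)
  expect_true(file.exists(fp) && file.size(fp) > 0)
  gp <- tempfile(fileext = ".png")
  render_region(s$chip, s$ctrl, list("chr9", 40000, 60000), gp)
  expect_true(file.exists(gp) && file.size(gp) > 0)
  expect_error(render_region(s$chip, s$ctrl, list("chr9", 0, 100),
                             tempfile(fileext = ".svg")), "format")
  wp <- tempfile(fileext = ".pdf")
  render_chromosome(s$chip, s$ctrl, wp)
  expect_true(file.exists(wp) && file.size(wp) > 0)
})

test_that("macro rebinning colors bars red strictly above the ratio cut", {
  g <- genome_table("c1", 1e6)
  raw_c <- rep(10, 1e5); raw_u <- rep(10, 1e5)
  chip <- tracks_from_raw(list(c1 = raw_c), g)
  ctrl <- tracks_from_raw(list(c1 = raw_u), g)
  m <- chromosome_plot_model(chip, ctrl, "c1", macro_bin = 1e5)
  b <- m$panels[[1]]$bars
  expect_equal(nrow(b), 10L)
  expect_true(all(b$color == "black"))   # ratio exactly 1: strict >
  # double ChIP in one macro bin -> exactly one red bar
  raw_c2 <- raw_c; raw_c2[30001:40000] <- 20
  chip2 <- tracks_from_raw(list(c1 = raw_c2), g)
  m2 <- chromosome_plot_model(chip2, ctrl, "c1", macro_bin = 1e5)
  expect_equal(sum(m2$panels[[1]]$bars$color == "red"), 1L)
  expect_equal(which(m2$panels[[1]]$bars$color == "red"), 4L)
  # assembly gap (no reads in either sample) -> bar at 0
  raw_c3 <- raw_c; raw_u3 <- raw_u
  raw_c3[50001:60000] <- 0; raw_u3[50001:60000] <- 0
  m3 <- chromosome_plot_model(tracks_from_raw(list(c1 = raw_c3), g),
                              tracks_from_raw(list(c1 = raw_u3), g), "c1",
                              macro_bin = 1e5)
  expect_equal(m3$panels[[1]]$bars$height[6], 0)
  expect_error(chromosome_plot_model(chip, ctrl, "c1", macro_bin = 1),
               "macro bin")
})

test_that("gene annotation parses BED12 and refFlat into exon models", {
  bed12 <- paste(c("chr9", 1000, 9000, "geneA", 0, "+", 1000, 9000, "0",
                   3, "500,400,300,", "0,3000,7700,"), collapse = "\t")
  pb <- tempfile(); writeLines(bed12, pb)
  gb <- read_genes(pb, "bed12")
  expect_equal(gb$exon_starts[[1]], c(1000, 4000, 8700))
  expect_equal(gb$exon_ends[[1]], c(1500, 4400, 9000))
  rf <- paste(c("GENEA", "NM_1", "chr9", "+", 1000, 9000, 1000, 9000, 3,
                "1000,4000,8700,", "1500,4400,9000,"), collapse = "\t")
  pr <- tempfile(); writeLines(rf, pr)
  gr <- read_genes(pr, "refflat")
  expect_equal(gr$exon_starts[[1]], c(1000, 4000, 8700))
  expect_equal(gr$start, 1000)
  # genes flow into the region model and are clipped to the region
  s <- setup_tracks()
  m <- region_plot_model(s$chip, s$ctrl, list("chr9", 0, 20000),
                         genes = gb)
  expect_equal(nrow(m$genes), 1L)
})

test_that("GC windows count G/C among non-N bases", {
  skip_if_not_installed("Biostrings")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", paste0(strrep("G", 4), strrep("A", 4), "GCAT",
                             strrep("N", 4))), fa)
  g <- genome_table("c1", 16)
  gc <- gc_track(fa, g, window = 4)
  expect_equal(gc$c1, c(1, 0, 0.5, NA))
  expect_error(gc_track(fa, genome_table("c2", 16), window = 4), "lacks")
})
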