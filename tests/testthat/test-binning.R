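g1 <- genome_table("chr1", 1000)

one_read <- function(pos5, strand = "+", n_k = 1L, reflen = 36L,
                     chrom = "chr1") {
  data.table::data.table(chrom = chrom, pos5 = pos5, strand = strand,
                         n_k = n_k, read_id = "r1", reflen = reflen,
                         score = NA_real_)
}

test_that("a plus-strand read covers fragment_length/bin_size bins", {
  r <- bin_reads(one_read(0), g1, bin_size = 10, fragment_length = 150)
  expect_equal(r$chr1[1:15], rep(1, 15))
  expect_equal(sum(r$chr1), 15)
})

test_that("multi-mapped weight 1/n_k spreads over the same bins", {
  r <- bin_reads(one_read(0, n_k = 4L), g1, 10, 150)
  expect_equal(r$chr1[1:15], rep(0.25, 15))
})

test_that("minus-strand fragments extend leftward and clip at 0", {
  # 5' end at coordinate 20 (pos5 11, reflen 10): fragment [0, 21)
  r <- bin_reads(one_read(11, strand = "-", reflen = 10L), g1, 10, 150)
  expect_equal(r$chr1[1:3], rep(1, 3))
  expect_equal(sum(r$chr1), 3)
})

test_that("fragments are never shrunk below the aligned read length", {
  r <- bin_reads(one_read(0, reflen = 80L), g1, 10, fragment_length = 50)
  expect_equal(sum(r$chr1 > 0), 8)   # 80 bp, not 50
})

test_that("binning matches the naive per-base overlap oracle exactly", {
  set.seed(101)
  for (rep in 1:20) {
    g <- genome_table(c("cA", "cB"), sample(500:2000, 2))
    aln <- random_alignments(g, sample(20:80, 1), read_length = 25L)
    bs <- sample(c(5L, 10L, 25L), 1)
    fl <- sample(c(40L, 100L, 150L), 1)
    got <- bin_reads(aln, g, bs, fl)
    want <- oracle_bin_reads(aln, g, bs, fl)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("per-base weight mass equals clipped fragment lengths / n_k", {
  set.seed(7)
  g <- genome_table("cA", 2000)
  aln <- random_alignments(g, 50, read_length = 25L)
  bs <- 1L   # per-base accounting
  got <- bin_reads(aln, g, bs, 100L)
  flen <- pmax(100L, aln$reflen)
  fs <- ifelse(aln$strand == "+", aln$pos5, aln$pos5 + aln$reflen - flen)
  fe <- fs + flen
  clipped <- pmin(fe, 2000) - pmax(fs, 0)
  expect_equal(sum(got$cA), sum(clipped / aln$n_k), tolerance = 1e-9)
})

test_that("normalization reproduces the modified-RPKM formula", {
  expect_equal(normalize_track(5, 1e6, 1e8), 5)
  expect_equal(normalize_track(5, 2e6, 1e8), 2.5)
  expect_equal(normalize_track(0, 1e6, 1e8), 0)
  expect_equal(normalize_track(c(2, 4), 5e5, 25e6), c(1, 2))
  expect_warning(out <- normalize_track(c(1, 2), 0, 1e8), "N_i")
  expect_equal(out, c(1, 2))
})

test_that("doubling every read leaves normalized tracks unchanged", {
  set.seed(21)
  g <- toy_genome()
  aln <- random_alignments(g, 400)
  doubled <- data.table::rbindlist(list(aln, aln))
  doubled$read_id <- sprintf("d%05d", seq_len(nrow(doubled)))
  tr1 <- parse2wig(aln, g, Tb = 1000L)      # cap high: no duplicate removal
  tr2 <- parse2wig(doubled, g, Tb = 1000L)
  for (ch in g$chrom)
    expect_equal(tr1$chroms[[ch]]$normalized, tr2$chroms[[ch]]$normalized,
                 tolerance = 1e-9)
})

test_that("smoothing is a mass-preserving centered moving average", {
  expect_equal(smooth_track(rep(2.5, 100), 500, 10), rep(2.5, 100))
  x <- numeric(201); x[101] <- 1
  s <- smooth_track(x, 510, 10)             # w = 51
  expect_equal(s[101 + (-25:25)], rep(1 / 51, 51))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_equal(smooth_track(x, 10, 10), x)  # width == bin -> identity
  # edge windows truncate instead of zero-padding
  y <- c(1, numeric(50))
  expect_equal(smooth_track(y, 50, 10)[1], 1 / 3)
  expect_error(smooth_track(x, 5, 10), "smoothing_width")
})

test_that("library accounting adds up and flags bad libraries", {
  lines <- sam_lines(sprintf("r%02d", 1:10), c(rep(0L, 7), rep(4L, 3)),
                     "chr1", c(1L, 1L, 1L, 1L, 1L, 101L, 201L, 1L, 1L, 1L),
                     "20M")
  g <- genome_table("chr1", 10000)
  tr <- parse2wig(write_sam_file(lines), g, Tb = 1L)
  s <- tr$stats
  expect_equal(s$total_reads, 10L)
  expect_equal(s$mapped_unique + s$mapped_multi + s$unmapped, s$total_reads)
  expect_equal(s$unmapped, 3L)
  expect_equal(s$remaining, s$selected_records - s$filtered_pcr)
  # 5 duplicates at one 5' end, cap 1 -> 4 filtered of 7 mapped (> 40%)
  rep_lines <- library_report(tr)
  expect_true(any(grepl("over-amplified", rep_lines)))
  # mapping ratio 70%
  expect_true(any(grepl("70.0%", rep_lines)))
})
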