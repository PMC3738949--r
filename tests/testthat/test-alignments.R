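g <- genome_table("chr1", 10000)

test_that("SAM parsing follows the 1-based / strand conventions", {
  path <- write_sam_file(c(
    sam_lines("r1", 0L, "chr1", 11L, "50M"),
    sam_lines("r2", 16L, "chr1", 101L, "50M"),
    sam_lines("r3", 4L, "*", 0L, "*")        # unmapped: skipped
  ))
  aln <- read_alignments(path, "sam", g)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$pos5, c(10, 100))
  expect_equal(aln$strand, c("+", "-"))
  # reverse-strand 5' end = pos5 + aligned length - 1
  expect_equal(chipscan:::five_prime_end(aln), c(10, 149))
  expect_equal(attr(aln, "n_unmapped"), 1L)
})

test_that("CIGAR reference length counts M/D/N/=/X only", {
  expect_equal(chipscan:::cigar_reflen("50M"), 50L)
  expect_equal(chipscan:::cigar_reflen("10M5I10M"), 20L)
  expect_equal(chipscan:::cigar_reflen("10M5D10M"), 25L)
  expect_equal(chipscan:::cigar_reflen("5S30M2N3X"), 35L)
  expect_error(chipscan:::cigar_reflen("xyz"), "CIGAR")
})

test_that("multiplicity comes from NH when present, else QNAME counting", {
  with_nh <- write_sam_file(
    sam_lines("r1", 0L, "chr1", 1L, "20M", "NH:i:7"))
  expect_equal(read_alignments(with_nh, "sam", g)$n_k, 7L)

  shared <- write_sam_file(c(
    sam_lines("m1", 0L, "chr1", 1L, "20M"),
    sam_lines("m1", 0L, "chr1", 501L, "20M"),
    sam_lines("m1", 0L, "chr1", 901L, "20M"),
    sam_lines("u1", 0L, "chr1", 201L, "20M")
  ))
  aln <- read_alignments(shared, "sam", g)
  expect_equal(aln$n_k, c(3L, 3L, 3L, 1L))
})

test_that("alignments on unknown chromosomes error or skip as configured", {
  path <- write_sam_file(c(
    sam_lines("r1", 0L, "chr1", 1L, "20M"),
    sam_lines("r2", 0L, "chrUn", 1L, "20M")))
  expect_error(read_alignments(path, "sam", g), "chrUn")
  expect_warning(aln <- read_alignments(path, "sam", g, "skip"), "chrUn")
  expect_equal(nrow(aln), 1L)
})

test_that("the three parsers agree on simulator-paired fixtures", {
  gg <- genome_table(c("c1", "c2"), c(20000, 10000))
  cfg <- sim_config(genome = gg, n_reads_chip = 500, n_reads_control = 500,
                    peaks = plant_peaks(gg, 2, 400, 8),
                    pseudo_sites = plant_peaks(gg, 1, 400, 4, phase = 0.2),
                    repeat_families = list(
                      list(chrom = "c1", starts = c(15000, 17000),
                           unit_length = 1000)),
                    duplication_rate = 0.05, seed = 42)
  sim <- simulate_reads(cfg, outdir = tempfile())
  sam <- read_alignments(sim$files[["chip_sam"]], "sam", gg)
  bowtie <- read_alignments(sim$files[["chip_bowtie"]], "bowtie", gg)
  bedp <- tempfile(fileext = ".bed")
  write_sim_bed(sim$chip, bedp)
  bed <- read_alignments(bedp, "bed", gg)
  key <- function(a) paste(a$read_id, a$chrom, a$pos5, a$strand)
  expect_setequal(key(sam), key(bowtie))
  expect_setequal(key(sam), key(bed))
  # NH round-trips through SAM and the bowtie "other alignments" column
  expect_identical(sort(sam$n_k), sort(bowtie$n_k))
  expect_gt(max(sam$n_k), 1L)
})

test_that("mapping-mode selection implements -m1/-mM/-k1 semantics", {
  aln <- data.table::data.table(
    chrom = "chr1",
    pos5 = c(0, 100, 200, 300, 400),
    strand = "+",
    n_k = c(1L, 12L, 12L, 3L, 3L),
    read_id = c("a", "b", "b", "c", "c"),
    reflen = 20L, score = c(NA, NA, NA, 10, 30))
  expect_equal(select_alignments(aln, "unique")$read_id, "a")
  # n_k = 12 exceeds M = 10: every locus of that read is dropped
  m <- select_alignments(aln, "multi", M = 10L)
  expect_false(any(m$read_id == "b"))
  expect_equal(nrow(m), 3L)
  b <- select_alignments(aln, "best")
  expect_equal(nrow(b), 3L)             # one locus per read
  expect_true(all(b$n_k == 1L))         # weight reset to 1
  expect_equal(b$pos5[b$read_id == "c"], 400)  # highest score wins
  expect_equal(b$pos5[b$read_id == "b"], 100)  # tie -> leftmost
  expect_error(select_alignments(aln, "multi", M = 0L), "M")
})
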