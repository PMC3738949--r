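# Independent brute-force oracles and small fixture builders used across the
# suite. These deliberately avoid the package's own algorithms: the Wilcoxon
# oracle enumerates rank partitions with combn(), the binning oracle does
# naive interval-overlap double loops.

# exact one-sided rank-sum p by enumerating every size-n1 rank partition
oracle_wilcoxon_greater <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  parts <- utils::combn(length(r), n1)
  sums <- colSums(matrix(r[parts], nrow = n1))
  mean(sums >= W - 1e-9)
}

# naive per-fragment/per-bin overlap count: weight of every fragment
# overlapping >= 1 bp of the bin
oracle_bin_reads <- function(aln, genome, bin_size, fragment_length) {
  out <- lapply(seq_len(nrow(genome)), function(ci) {
    L <- genome$length[ci]
    nb <- as.integer(ceiling(L / bin_size))
    vals <- numeric(nb)
    rows <- which(aln$chrom == genome$chrom[ci])
    for (k in rows) {
      flen <- max(fragment_length, aln$reflen[k])
      if (aln$strand[k] == "+") {
        s <- aln$pos5[k]; e <- s + flen
      } else {
        e5 <- aln$pos5[k] + aln$reflen[k] - 1
        s <- e5 - flen + 1; e <- e5 + 1
      }
      s <- max(s, 0); e <- min(e, L)
      if (e <= s) next
      for (b in seq_len(nb)) {
        b0 <- (b - 1) * bin_size; b1 <- min(b0 + bin_size, L)
        if (s < b1 && e > b0) vals[b] <- vals[b] + 1 / aln$n_k[k]
      }
    }
    vals
  })
  names(out) <- genome$chrom
  out
}

# random alignment table on a toy genome
random_alignments <- function(genome, n, read_length = 20L, max_nk = 4L) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  L <- genome$length[ci]
  pos5 <- floor(runif(n) * (L - read_length))
  data.table::data.table(
    chrom = genome$chrom[ci],
    pos5 = pos5,
    strand = sample(c("+", "-"), n, replace = TRUE),
    n_k = sample.int(max_nk, n, replace = TRUE),
    read_id = sprintf("r%05d", seq_len(n)),
    reflen = read_length,
    score = NA_real_)
}

# minimal SAM text from explicit fields
sam_lines <- function(qname, flag, rname, pos1, cigar, tags = NULL) {
  base <- sprintf("%s\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  qname, flag, rname, pos1, cigar)
  if (!is.null(tags)) base <- paste(base, tags, sep = "\t")
  base
}

write_sam_file <- function(lines, genome = NULL) {
  path <- tempfile(fileext = ".sam")
  hdr <- if (!is.null(genome))
    sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$length)
  writeLines(c(hdr, lines), path)
  path
}

# pileup builder: c reads at one strand-specific 5' end
pileup_alignments <- function(c, chrom = "chr1", pos5 = 100, strand = "+",
                              reflen = 20L, id_prefix = "p") {
  data.table::data.table(
    chrom = chrom, pos5 = pos5, strand = strand, n_k = 1L,
    read_id = sprintf("%s%03d", id_prefix, seq_len(c)),
    reflen = reflen, score = NA_real_)
}

toy_genome <- function() genome_table(c("chrA", "chrB"), c(5000, 3000))

# fraction of truth intervals overlapped (>= 1 bp) by a called peak
sensitivity_vs_truth <- function(peaks, truth) {
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    any(peaks$chrom == truth$chrom[i] &
          peaks$start < truth$end[i] & peaks$end > truth$start[i])
  }, TRUE)
  mean(hit)
}

# do all intervals in `sub` lie within the union of intervals in `sup`?
intervals_subset_of <- function(sub, sup) {
  if (nrow(sub) == 0L) return(TRUE)
  all(vapply(seq_len(nrow(sub)), function(i) {
    cover <- sup[sup$chrom == sub$chrom[i] &
                   sup$start <= sub$start[i] & sup$end >= sub$end[i], ]
    nrow(cover) > 0L
  }, TRUE))
}
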