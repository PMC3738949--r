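#' Bin extended read fragments into fixed-width bins
#'
#' Each alignment is extended from its strand-specific 5' end to the expected
#' sonication fragment length (3'-ward: rightward on `+`, leftward on `-`),
#' clipped to the chromosome, and its weight `1/n_k` is added to every bin
#' the fragment overlaps. Fragments are never shrunk below the aligned read
#' length. Alignments must already be mode-selected and duplicate-filtered.
#'
#' @param aln Alignment table.
#' @param genome A [genome_table].
#' @param bin_size Bin width in bp (default 10).
#' @param fragment_length Expected fragment length in bp (default 150).
#' @return Named list (per chromosome, genome order) of numeric vectors of
#'   raw bin values `r_x`; vector length is `ceiling(L_i / bin_size)`.
#' @export
bin_reads <- function(aln, genome, bin_size = 10L, fragment_length = 150L) {
  if (bin_size < 1L || fragment_length < 1L)
    stop("bin_size and fragment_length must be >= 1")
  stopifnot_genome(genome)
  tracks <- lapply(seq_len(nrow(genome)), function(i) {
    numeric(n_bins(genome$length[i], bin_size))
  })
  names(tracks) <- genome$chrom
  if (nrow(aln) == 0L) return(tracks)

  flen <- pmax(fragment_length, aln$reflen)
  fstart <- ifelse(aln$strand == "+", aln$pos5,
                   aln$pos5 + aln$reflen - flen)
  fend <- fstart + flen
  w <- 1 / aln$n_k

  idx <- split(seq_len(nrow(aln)), factor(aln$chrom, levels = genome$chrom))
  for (i in seq_len(nrow(genome))) {
    rows <- idx[[i]]
    if (!length(rows)) next
    L <- genome$length[i]
    s <- pmax(fstart[rows], 0)
    e <- pmin(fend[rows], L)
    ok <- e > s
    s <- s[ok]; e <- e[ok]; wi <- w[rows][ok]
    nb <- length(tracks[[i]])
    b0 <- floor(s / bin_size)           # first overlapped bin
    b1 <- floor((e - 1) / bin_size)     # last overlapped bin
    # difference-array accumulation: O(reads + bins)
    acc <- numeric(nb + 1L)
    grp <- c(as.integer(b0) + 1L, pmin(as.integer(b1) + 2L, nb + 1L))
    add <- rowsum(c(wi, -wi), grp)
    acc[as.integer(rownames(add))] <- add[, 1L]
    tracks[[i]] <- cumsum(acc)[seq_len(nb)]
  }
  tracks
}

#' Depth-normalize a binned track
#'
#' Modified RPKM scaling of raw bin counts: reads per 10^6 mapped reads per
#' 100 Mb of chromosome, `R_x = 1e6 * (r_x / N_i) * (L_i / 1e8)`, with `N_i`
#' the (weighted) read count mapped to chromosome `i` and `L_i` its length.
#' Normalization is per chromosome.
#'
#' @param raw Numeric vector of raw bin values `r_x`.
#' @param N_i Weighted read count on the chromosome.
#' @param L_i Chromosome length (bp).
#' @return Numeric vector of normalized values `R_x`.
#' @export
normalize_track <- function(raw, N_i, L_i) {
  if (N_i <= 0) {
    warning("no mapped reads on chromosome (N_i = 0); returning raw values")
    return(raw)
  }
  1e6 * (raw / N_i) * (L_i / 1e8)
}

#' Smooth a binned track with a centered moving average
#'
#' Averages each bin over a window of `round(smoothing_width / bin_size)`
#' bins, forced odd so the window is centered; windows are truncated at the
#' chromosome ends (the edge bins average over fewer bins). A smoothing width
#' equal to the bin size is the identity.
#'
#' @param x Numeric vector of (normalized) bin values.
#' @param smoothing_width Smoothing width in bp (default 500).
#' @param bin_size Bin width in bp (default 10).
#' @return Smoothed numeric vector, same length.
#' @export
smooth_track <- function(x, smoothing_width = 500L, bin_size = 10L) {
  if (smoothing_width < bin_size)
    stop("smoothing_width must be >= bin_size")
  w <- round(smoothing_width / bin_size)
  if (w %% 2 == 0) w <- w + 1L
  if (w <= 1L || length(x) <= 1L) return(x)
  h <- (w - 1L) %/% 2L
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Convert mapped reads into normalized, smoothed binned coverage tracks
#'
#' The preprocessing half of the pipeline: parse a mapped-read file, apply
#' the mapping-mode filter, cap PCR duplicates at [compute_Tb()]'s `T_b`,
#' bin fragment-extended reads with `1/n_k` weighting, normalize each
#' chromosome to reads per 10^6 per 100 Mb, and smooth. Library quality
#' counters are collected along the way (see [library_report()]).
#'
#' @param input Path to a mapped-read file, or an alignment table from
#'   [read_alignments()].
#' @param genome A [genome_table].
#' @param format Input format when `input` is a path: `"sam"`, `"bowtie"`,
#'   `"bed"`.
#' @param bin_size,fragment_length,smoothing_width Track parameters in bp
#'   (defaults 10, 150, 500).
#' @param mode,M Mapping mode and multiplicity cap, see
#'   [select_alignments()] (defaults `"multi"`, 10).
#' @param Tb PCR-duplicate cap; `NULL` (default) computes it from the data.
#' @param smooth Set `FALSE` to skip smoothing (the smoothed track then
#'   equals the normalized one).
#' @param on_missing_chrom Passed to [read_alignments()].
#' @return A `coverage_tracks` object: list with `genome`, the parameters,
#'   `chroms` (per-chromosome lists with `raw`, `normalized`, `smoothed`
#'   vectors), `chrom_stats` (per-chromosome `N_i`, `L_i`, `mean_depth`) and
#'   `stats` (library counters).
#' @export
parse2wig <- function(input, genome, format = c("sam", "bowtie", "bed"),
                      bin_size = 10L, fragment_length = 150L,
                      smoothing_width = 500L,
                      mode = c("multi", "unique", "best"), M = 10L,
                      Tb = NULL, smooth = TRUE,
                      on_missing_chrom = c("error", "skip")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  stopifnot_genome(genome)
  if (is.character(input)) {
    aln <- read_alignments(input, format, genome, on_missing_chrom)
  } else {
    aln <- data.table::as.data.table(input)
  }
  n_unmapped <- attr(aln, "n_unmapped") %||% 0L
  reads <- unique(aln[, list(read_id, n_k)])
  mapped_unique <- sum(reads$n_k == 1L)
  mapped_multi <- sum(reads$n_k > 1L)

  sel <- select_alignments(aln, mode, M, genome)
  n_plus <- sum(sel$strand == "+")
  n_minus <- nrow(sel) - n_plus
  L <- genome_length(genome)
  if (is.null(Tb)) Tb <- compute_Tb(n_plus, n_minus, L)
  flt <- filter_pcr_bias(sel, Tb)
  kept <- flt$alignments

  raw <- bin_reads(kept, genome, bin_size, fragment_length)
  wN <- tapply(1 / kept$n_k, factor(kept$chrom, levels = genome$chrom), sum)
  wN[is.na(wN)] <- 0
  chroms <- vector("list", nrow(genome))
  names(chroms) <- genome$chrom
  for (i in seq_len(nrow(genome))) {
    nrm <- if (wN[i] > 0) normalize_track(raw[[i]], wN[i], genome$length[i])
           else raw[[i]]
    smo <- if (smooth) smooth_track(nrm, smoothing_width, bin_size) else nrm
    chroms[[i]] <- list(raw = raw[[i]], normalized = nrm, smoothed = smo)
  }
  chrom_stats <- data.frame(
    chrom = genome$chrom,
    N_i = as.numeric(wN),
    L_i = genome$length,
    mean_depth = vapply(chroms, function(ch) mean(ch$smoothed), 0),
    stringsAsFactors = FALSE
  )
  stats <- list(
    total_reads = mapped_unique + mapped_multi + n_unmapped,
    mapped_unique = mapped_unique,
    mapped_multi = mapped_multi,
    unmapped = n_unmapped,
    selected_records = nrow(sel),
    filtered_pcr = flt$n_filtered,
    filtered_pcr_weight = flt$weight_filtered,
    remaining = nrow(kept),
    n_plus = n_plus, n_minus = n_minus,
    E_plus = n_plus / L, E_minus = n_minus / L,
    Tb = Tb
  )
  structure(list(genome = genome, bin_size = as.integer(bin_size),
                 fragment_length = as.integer(fragment_length),
                 smoothing_width = as.integer(smoothing_width),
                 mode = mode, M = as.integer(M),
                 chroms = chroms, chrom_stats = chrom_stats, stats = stats),
            class = "coverage_tracks")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coverage_tracks <- function(x, ...) {
  s <- x$stats
  cat("Binned coverage tracks (", nrow(x$genome), " chromosome(s), bin ",
      x$bin_size, " bp, fragment ", x$fragment_length, " bp, smoothing ",
      x$smoothing_width, " bp, mode '", x$mode, "')\n", sep = "")
  cat("  reads: ", s$total_reads, " total; ", s$mapped_unique, " unique, ",
      s$mapped_multi, " multi-mapped, ", s$unmapped, " unmapped\n", sep = "")
  cat("  PCR filter: T_b = ", s$Tb, "; ", s$filtered_pcr,
      " alignment(s) removed, ", s$remaining, " kept\n", sep = "")
  invisible(x)
}

#' @export
summary.coverage_tracks <- function(object, ...) {
  cat(library_report(object), sep = "\n")
  invisible(object$stats)
}

#' Library quality report
#'
#' Summarizes the read-accounting counters of a track set: totals, mapping
#' ratio, PCR-bias fraction, per-strand expectations and the duplicate cap.
#' A mapping ratio below 50% and a PCR-bias fraction above 40% (a sign of
#' template over-amplification) are flagged as warnings; a PCR-bias fraction
#' under 20% is typical of a healthy library.
#'
#' @param x A `coverage_tracks` object (or its `stats` list).
#' @param file Optional path; when given the report is also written as a
#'   two-column TSV of counter name and value.
#' @return Character vector of report lines, invisibly when printed via
#'   [summary.coverage_tracks()].
#' @export
library_report <- function(x, file = NULL) {
  s <- if (inherits(x, "coverage_tracks")) x$stats else x
  pct <- function(a, b) if (b > 0) sprintf("%.1f%%", 100 * a / b) else "NA"
  mapped <- s$mapped_unique + s$mapped_multi
  lines <- c(
    sprintf("total reads\t%d", s$total_reads),
    sprintf("mapped (unique)\t%d\t%s", s$mapped_unique, pct(s$mapped_unique, s$total_reads)),
    sprintf("mapped (multi)\t%d\t%s", s$mapped_multi, pct(s$mapped_multi, s$total_reads)),
    sprintf("unmapped\t%d\t%s", s$unmapped, pct(s$unmapped, s$total_reads)),
    sprintf("mapping ratio\t%s", pct(mapped, s$total_reads)),
    sprintf("alignments after mode selection\t%d", s$selected_records),
    sprintf("PCR duplicate cap T_b\t%d", s$Tb),
    sprintf("filtered as PCR bias\t%d\t%s", s$filtered_pcr,
            pct(s$filtered_pcr, s$selected_records)),
    sprintf("remaining alignments\t%d", s$remaining)
  )
  if (s$total_reads > 0 && mapped / s$total_reads < 0.5)
    lines <- c(lines, "WARNING: mapping ratio < 50%")
  if (s$selected_records > 0 && s$filtered_pcr / s$selected_records > 0.4)
    lines <- c(lines,
      "WARNING: PCR bias > 40% of mapped reads; the library may be over-amplified")
  if (!is.null(file)) writeLines(lines, file)
  lines
}
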