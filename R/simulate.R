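#' Simulation configuration
#'
#' Describes a synthetic ChIP-seq experiment with known ground truth. The
#' defaults define the validation conditions used throughout the package: a
#' 10-Mb genome (2 chromosomes of 5 Mb), one million 36-bp single-end reads
#' per sample, 150-bp fragments, 20 planted sharp binding sites at 10-fold
#' enrichment, 5 pseudobinding sites (input-enriched loci present in both
#' samples, as at active promoters), two multi-mapping repeat families and a
#' 2% PCR duplication rate.
#'
#' @param genome A [genome_table] (default 2 x 5 Mb).
#' @param n_reads_chip,n_reads_control Background read counts per sample
#'   (enrichment reads are added on top; default 1e6 each).
#' @param read_length Read length in bp (default 36).
#' @param fragment_length Sonication fragment length in bp (default 150).
#' @param peaks data.frame of planted ChIP peaks with columns `chrom`,
#'   `center`, `width`, `fold` (> 1), `shape` (`"sharp"` or `"broad"`);
#'   `NULL` plants 20 sharp 1-kb fold-10 peaks evenly over the genome.
#' @param pseudo_sites data.frame like `peaks` for loci enriched in *both*
#'   samples; `NULL` plants 5 sharp 1-kb fold-5 sites.
#' @param repeat_families List of repeat families, each a list with `chrom`,
#'   `starts` (copy start coordinates) and `unit_length`; reads from any
#'   copy are emitted at the homologous position of every copy with
#'   `n_k` = number of copies. `NULL` plants a 3-copy and a 5-copy family of
#'   2-kb units.
#' @param duplication_rate Fraction of fragments re-emitted at an identical
#'   5' end (PCR duplicates; default 0.02).
#' @param seed RNG seed; the same seed reproduces byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = genome_table(c("chrS1", "chrS2"), c(5e6, 5e6)),
                       n_reads_chip = 1e6, n_reads_control = 1e6,
                       read_length = 36L, fragment_length = 150L,
                       peaks = NULL, pseudo_sites = NULL,
                       repeat_families = NULL,
                       duplication_rate = 0.02, seed = 1L) {
  stopifnot_genome(genome)
  if (is.null(peaks))
    peaks <- plant_peaks(genome, n = 20L, width = 1000, fold = 10,
                         shape = "sharp", phase = 0.5)
  if (is.null(pseudo_sites))
    pseudo_sites <- plant_peaks(genome, n = 5L, width = 1000, fold = 5,
                                shape = "sharp", phase = 0.13)
  if (is.null(repeat_families))
    repeat_families <- list(
      list(chrom = genome$chrom[1L],
           starts = genome$length[1L] - c(1.3e5, 1.1e5, 0.9e5),
           unit_length = 2000),
      list(chrom = genome$chrom[min(2L, nrow(genome))],
           starts = genome$length[min(2L, nrow(genome))] -
             c(5e5, 4.7e5, 4.4e5, 4.1e5, 3.8e5), unit_length = 2000)
    )
  check_sites <- function(df, what) {
    i <- match(df$chrom, genome$chrom)
    if (anyNA(i)) stop(what, " on unknown chromosome")
    if (any(df$center - df$width / 2 < 0 |
            df$center + df$width / 2 > genome$length[i]))
      stop(what, " extend outside chromosome bounds")
    if (any(df$fold <= 1)) stop(what, " must have fold > 1")
  }
  check_sites(peaks, "planted peaks")
  if (nrow(pseudo_sites)) check_sites(pseudo_sites, "pseudobinding sites")
  structure(list(genome = genome, n_reads_chip = n_reads_chip,
                 n_reads_control = n_reads_control,
                 read_length = as.integer(read_length),
                 fragment_length = as.integer(fragment_length),
                 peaks = peaks, pseudo_sites = pseudo_sites,
                 repeat_families = repeat_families,
                 duplication_rate = duplication_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Evenly spaced planted sites
#'
#' Helper building a data.frame of planted sites spread evenly over the
#' genome (round-robin across chromosomes, centers on a regular grid).
#'
#' @param genome A [genome_table].
#' @param n Number of sites.
#' @param width Site width (bp).
#' @param fold Enrichment fold (> 1).
#' @param shape `"sharp"` (point source) or `"broad"` (uniform domain).
#' @param phase Grid phase in (0, 1); different phases give disjoint grids.
#' @return data.frame with columns `chrom`, `center`, `width`, `fold`,
#'   `shape`.
#' @export
plant_peaks <- function(genome, n, width, fold, shape = "sharp", phase = 0.5) {
  nc <- nrow(genome)
  chrom_idx <- rep(seq_len(nc), length.out = n)
  per <- tabulate(chrom_idx, nbins = nc)
  out <- lapply(seq_len(nc), function(i) {
    k <- per[i]
    if (k == 0L) return(NULL)
    centers <- round(genome$length[i] * (seq_len(k) - 1 + phase) / k)
    data.frame(chrom = genome$chrom[i], center = centers, width = width,
               fold = fold, shape = shape, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# draw fragment start coordinates for one enrichment site
site_fragments <- function(site, n_extra, flen, L) {
  if (n_extra <= 0L) return(numeric(0))
  if (site$shape == "sharp") {
    centers <- site$center + runif(n_extra, -flen / 2, flen / 2)
    f0 <- round(centers - flen / 2)
  } else {
    lo <- site$center - site$width / 2
    f0 <- floor(lo + runif(n_extra) * (site$width - flen))
  }
  pmin(pmax(f0, 0), L - flen)
}

# one sample's fragments: background + enrichment sites, then duplicates,
# then repeat-family multi-mapping expansion
simulate_sample <- function(cfg, n_reads, sites, id_prefix) {
  genome <- cfg$genome
  flen <- cfg$fragment_length
  L_tot <- genome_length(genome)
  # background uniform over the genome
  chrom_i <- sample.int(nrow(genome), n_reads, replace = TRUE,
                        prob = genome$length / L_tot)
  f0 <- floor(runif(n_reads) * (genome$length[chrom_i] - flen + 1))
  # planted enrichment
  for (k in seq_len(nrow(sites))) {
    s <- sites[k, ]
    ci <- match(s$chrom, genome$chrom)
    n_extra <- round((s$fold - 1) * n_reads * s$width / L_tot)
    fs <- site_fragments(s, n_extra, flen, genome$length[ci])
    chrom_i <- c(chrom_i, rep(ci, length(fs)))
    f0 <- c(f0, fs)
  }
  strand <- sample(c("+", "-"), length(f0), replace = TRUE)
  # PCR duplicates: re-emit existing fragments at identical 5' ends
  n_dup <- round(cfg$duplication_rate * length(f0))
  if (n_dup > 0L) {
    di <- sample.int(length(f0), n_dup, replace = TRUE)
    chrom_i <- c(chrom_i, chrom_i[di])
    f0 <- c(f0, f0[di])
    strand <- c(strand, strand[di])
  }
  read_id <- sprintf("%s%07d", id_prefix, seq_along(f0))
  n_k <- rep(1L, length(f0))
  # repeat families: homologous loci, one record per copy, shared read id
  rec <- data.table::data.table(chrom_i = chrom_i, f0 = f0, strand = strand,
                                read_id = read_id, n_k = n_k)
  extra <- list()
  for (fam in cfg$repeat_families) {
    ci <- match(fam$chrom, genome$chrom)
    nc <- length(fam$starts)
    if (nc < 2L) next
    span <- fam$unit_length - flen
    for (j in seq_len(nc)) {
      inside <- which(rec$chrom_i == ci & rec$f0 >= fam$starts[j] &
                      rec$f0 <= fam$starts[j] + span & rec$n_k == 1L)
      if (!length(inside)) next
      rec$n_k[inside] <- nc
      off <- rec$f0[inside] - fam$starts[j]
      others <- setdiff(seq_len(nc), j)
      for (o in others) {
        extra[[length(extra) + 1L]] <- data.table::data.table(
          chrom_i = ci, f0 = fam$starts[o] + off,
          strand = rec$strand[inside], read_id = rec$read_id[inside],
          n_k = nc)
      }
    }
  }
  if (length(extra)) rec <- data.table::rbindlist(c(list(rec), extra))
  # fragments -> aligned reads at the fragment 5' end
  rl <- cfg$read_length
  pos5 <- ifelse(rec$strand == "+", rec$f0, rec$f0 + flen - rl)
  data.table::data.table(
    chrom = genome$chrom[rec$chrom_i],
    pos5 = pmin(pmax(pos5, 0), genome$length[rec$chrom_i] - rl),
    strand = rec$strand, n_k = rec$n_k, read_id = rec$read_id,
    reflen = rl, score = NA_real_)
}

#' Simulate a ChIP-seq experiment with known ground truth
#'
#' Generates paired ChIP and control read sets under a [sim_config()]:
#' background fragments uniform over the genome, planted-peak fragments at
#' rates giving the configured fold enrichment (point-source with
#' fragment-scale jitter for sharp sites, uniform over the domain for broad
#' ones), pseudobinding-site fragments in both samples, PCR duplicates
#' re-emitting existing fragments, and repeat-family reads emitted at every
#' homologous copy with `n_k` set accordingly. Fully reproducible from the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param outdir Optional directory; when given, writes `chip.sam`,
#'   `control.sam`, Bowtie-format twins `chip.bowtie` / `control.bowtie`,
#'   and the ground truth `truth.bed` (BED6, fold in the score column).
#' @return List with `chip` and `control` alignment tables (the in-memory
#'   form of [read_alignments()]), `truth` (planted intervals), and `files`
#'   (written paths, when `outdir` was given).
#' @export
simulate_reads <- function(cfg, outdir = NULL) {
  if (!inherits(cfg, "sim_config")) stop("cfg must come from sim_config()")
  set.seed(cfg$seed)
  chip_sites <- rbind(cfg$peaks, cfg$pseudo_sites)
  chip <- simulate_sample(cfg, cfg$n_reads_chip, chip_sites, "chip")
  control <- simulate_sample(cfg, cfg$n_reads_control, cfg$pseudo_sites, "ctrl")
  truth <- data.frame(
    chrom = cfg$peaks$chrom,
    start = round(cfg$peaks$center - cfg$peaks$width / 2),
    end = round(cfg$peaks$center + cfg$peaks$width / 2),
    name = sprintf("site%03d", seq_len(nrow(cfg$peaks))),
    score = cfg$peaks$fold,
    strand = rep(".", nrow(cfg$peaks)),
    stringsAsFactors = FALSE
  )
  files <- NULL
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    files <- c(
      chip_sam = write_sim_sam(chip, cfg$genome,
                               file.path(outdir, "chip.sam")),
      control_sam = write_sim_sam(control, cfg$genome,
                                  file.path(outdir, "control.sam")),
      chip_bowtie = write_sim_bowtie(chip, file.path(outdir, "chip.bowtie")),
      control_bowtie = write_sim_bowtie(control,
                                        file.path(outdir, "control.bowtie")),
      truth_bed = {
        p <- file.path(outdir, "truth.bed")
        utils::write.table(truth, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
        p
      }
    )
  }
  list(chip = chip, control = control, truth = truth, files = files)
}

#' Write simulated alignments as headered SAM
#' @param aln Alignment table from [simulate_reads()].
#' @param genome A [genome_table] (for `@SQ` header lines).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(aln, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", genome$chrom, genome$length))
  flag <- ifelse(aln$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNH:i:%d",
                  aln$read_id, flag, aln$chrom, as.integer(aln$pos5) + 1L,
                  as.integer(aln$reflen), aln$n_k)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated alignments in Bowtie default text format
#' @inheritParams write_sim_sam
#' @return `path`, invisibly.
#' @export
write_sim_bowtie <- function(aln, path) {
  rl <- aln$reflen
  seqs <- strrep("A", rl)
  quals <- strrep("I", rl)
  body <- sprintf("%s\t%s\t%s\t%d\t%s\t%s\t%d\t",
                  aln$read_id, aln$strand, aln$chrom, as.integer(aln$pos5),
                  seqs, quals, aln$n_k - 1L)
  writeLines(body, path)
  invisible(path)
}

#' Write simulated alignments as BED6
#' @inheritParams write_sim_sam
#' @return `path`, invisibly.
#' @export
write_sim_bed <- function(aln, path) {
  body <- sprintf("%s\t%d\t%d\t%s\t0\t%s", aln$chrom, as.integer(aln$pos5),
                  as.integer(aln$pos5 + aln$reflen), aln$read_id, aln$strand)
  writeLines(body, path)
  invisible(path)
}

#' Build coverage tracks from raw per-chromosome bin vectors
#'
#' Wraps already-binned raw values into a `coverage_tracks` object,
#' normalizing with the modified-RPKM formula (`N_i` approximated as the
#' raw mass divided by the bins-per-fragment factor) and smoothing. Used for
#' track-level simulations and macro-rebinned views.
#'
#' @param raw Named list (per chromosome) of raw bin vectors.
#' @param genome A [genome_table].
#' @param bin_size,fragment_length,smoothing_width Track parameters (bp).
#' @param smooth Smooth after normalizing (default TRUE).
#' @return A `coverage_tracks` object.
#' @export
tracks_from_raw <- function(raw, genome, bin_size = 10L,
                            fragment_length = 150L, smoothing_width = 500L,
                            smooth = TRUE) {
  stopifnot_genome(genome)
  bins_per_frag <- max(1, fragment_length / bin_size)
  chroms <- vector("list", nrow(genome))
  names(chroms) <- genome$chrom
  N <- numeric(nrow(genome))
  for (i in seq_len(nrow(genome))) {
    r <- raw[[genome$chrom[i]]]
    N[i] <- sum(r) / bins_per_frag
    nrm <- if (N[i] > 0) normalize_track(r, N[i], genome$length[i]) else r
    smo <- if (smooth) smooth_track(nrm, smoothing_width, bin_size) else nrm
    chroms[[i]] <- list(raw = r, normalized = nrm, smoothed = smo)
  }
  structure(list(genome = genome, bin_size = as.integer(bin_size),
                 fragment_length = as.integer(fragment_length),
                 smoothing_width = as.integer(smoothing_width),
                 mode = "raw", M = NA_integer_, chroms = chroms,
                 chrom_stats = data.frame(
                   chrom = genome$chrom, N_i = N, L_i = genome$length,
                   mean_depth = vapply(chroms, function(ch) mean(ch$smoothed), 0),
                   stringsAsFactors = FALSE),
                 stats = list(total_reads = round(sum(N)),
                              mapped_unique = round(sum(N)), mapped_multi = 0L,
                              unmapped = 0L, selected_records = round(sum(N)),
                              filtered_pcr = 0L, filtered_pcr_weight = 0,
                              remaining = round(sum(N)), n_plus = NA, n_minus = NA,
                              E_plus = NA, E_minus = NA, Tb = 1L)),
            class = "coverage_tracks")
}

#' Paired null tracks from a shared Poisson background
#'
#' Draws two independent track sets whose raw bin values come from the same
#' Poisson background (no enrichment anywhere) — the null model for
#' type-I-error checks of the peak caller.
#'
#' @param genome A [genome_table].
#' @param depth Mean raw value per bin (default 15, matching ~15x fragment
#'   coverage at the default settings).
#' @param bin_size,fragment_length,smoothing_width Track parameters (bp).
#' @param seed RNG seed.
#' @return List with `chip` and `control` `coverage_tracks`.
#' @export
simulate_null_tracks <- function(genome, depth = 15, bin_size = 10L,
                                 fragment_length = 150L,
                                 smoothing_width = 500L, seed = 1L) {
  set.seed(seed)
  draw <- function() {
    raw <- lapply(seq_len(nrow(genome)), function(i)
      as.numeric(rpois(n_bins(genome$length[i], bin_size), depth)))
    names(raw) <- genome$chrom
    tracks_from_raw(raw, genome, bin_size, fragment_length, smoothing_width)
  }
  list(chip = draw(), control = draw())
}
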