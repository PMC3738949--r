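#' Read gene annotations (BED12 or refFlat)
#'
#' Parses gene models for figure annotation. BED12 columns 11/12 give exon
#' block sizes/starts; refFlat carries explicit exon start/end lists.
#'
#' @param path Annotation file.
#' @param format `"bed12"` or `"refflat"`.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `strand` and
#'   list columns `exon_starts`, `exon_ends` (0-based half-open).
#' @export
read_genes <- function(path, format = c("bed12", "refflat")) {
  format <- match.arg(format)
  dt <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  split_ints <- function(s) lapply(strsplit(s, ","), function(x)
    as.numeric(x[nzchar(x)]))
  if (format == "bed12") {
    if (ncol(dt) < 12L) stop("BED12 needs 12 columns")
    sizes <- split_ints(as.character(dt[[11L]]))
    offs <- split_ints(as.character(dt[[12L]]))
    exon_starts <- Map(function(s, o) s + o, dt[[2L]], offs)
    exon_ends <- Map(`+`, exon_starts, sizes)
    out <- data.frame(chrom = dt[[1L]], start = dt[[2L]], end = dt[[3L]],
                      name = dt[[4L]], strand = dt[[6L]],
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(dt) < 11L) stop("refFlat needs 11 columns")
    exon_starts <- split_ints(as.character(dt[[10L]]))
    exon_ends <- split_ints(as.character(dt[[11L]]))
    out <- data.frame(chrom = dt[[3L]], start = dt[[5L]], end = dt[[6L]],
                      name = dt[[1L]], strand = dt[[4L]],
                      stringsAsFactors = FALSE)
  }
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  out
}

track_colors <- c(chip = "forestgreen", control = "steelblue",
                  ratio = "darkorange", peak = "red")

#' Figure data model for a region plot
#'
#' Builds the backend-independent description of a read-distribution figure:
#' per-panel bar lists (position, height, color) for the requested tracks
#' over a genomic region, with bins inside peaks recolored red on the ChIP
#' and ratio panels. Rendering ([render_region()]) only draws this model, so
#' tests can assert figure content without rasterization.
#'
#' @param chip,control `coverage_tracks` objects (control optional when only
#'   the ChIP track is plotted).
#' @param region `c(chrom, start, end)` — chromosome name and 0-based
#'   half-open coordinates.
#' @param peaks Optional `peak_calls` object or peaks data.frame; member
#'   bins are drawn red.
#' @param genes Optional [read_genes()] data.frame.
#' @param tracks Character subset of `c("chip", "control", "ratio")` in
#'   display order.
#' @param scale_ratio Y-axis cap for the ratio panel (default 5).
#' @param value Track vector to display (default `"smoothed"`).
#' @return A `track_plot_model` list with `region`, `bin_size`, `panels`
#'   (each with `label`, `kind`, `ymax` and a `bars` data.frame of `start`,
#'   `end`, `height`, `color`) and `genes`.
#' @export
region_plot_model <- function(chip, control = NULL, region, peaks = NULL,
                              genes = NULL,
                              tracks = c("chip", "control", "ratio"),
                              scale_ratio = 5, value = "smoothed") {
  chrom <- as.character(region[[1L]])
  from <- as.numeric(region[[2L]]); to <- as.numeric(region[[3L]])
  if (!(chrom %in% chip$genome$chrom)) stop("unknown chromosome: ", chrom)
  L <- chip$genome$length[match(chrom, chip$genome$chrom)]
  if (from >= to || from < 0 || to > L)
    stop("region outside chromosome bounds")
  if (!length(tracks)) stop("at least one track is required")
  bs <- chip$bin_size
  b0 <- floor(from / bs); b1 <- ceiling(to / bs) - 1L
  bins <- b0:b1
  starts <- bins * bs
  ends <- pmin(starts + bs, L)
  slice <- function(tr) tr$chroms[[chrom]][[value]][bins + 1L]
  pk <- if (inherits(peaks, "peak_calls")) peaks$peaks else peaks
  in_peak <- rep(FALSE, length(bins))
  if (!is.null(pk) && nrow(pk)) {
    pk <- pk[pk$chrom == chrom, , drop = FALSE]
    for (r in seq_len(nrow(pk)))
      in_peak <- in_peak | (starts < pk$end[r] & ends > pk$start[r])
  }
  panels <- list()
  for (kind in tracks) {
    if (kind %in% c("control", "ratio") && is.null(control))
      stop("control tracks requested but no control given")
    h <- switch(kind,
      chip = slice(chip),
      control = slice(control),
      ratio = {
        cv <- slice(chip); uv <- slice(control)
        r <- ifelse(uv > 0, cv / uv, ifelse(cv > 0, scale_ratio, 0))
        pmin(r, scale_ratio)
      })
    col <- rep(track_colors[[kind]], length(h))
    if (kind %in% c("chip", "ratio")) col[in_peak] <- track_colors[["peak"]]
    panels[[length(panels) + 1L]] <- list(
      label = kind, kind = kind,
      ymax = if (kind == "ratio") scale_ratio else max(h, 1e-9),
      bars = data.frame(start = starts, end = ends, height = h, color = col,
                        stringsAsFactors = FALSE))
  }
  g <- NULL
  if (!is.null(genes)) {
    g <- genes[genes$chrom == chrom & genes$start < to & genes$end > from, ,
               drop = FALSE]
  }
  structure(list(region = list(chrom = chrom, start = from, end = to),
                 bin_size = bs, panels = panels, genes = g),
            class = "track_plot_model")
}

draw_model_page <- function(model, from, to) {
  np <- length(model$panels)
  has_genes <- !is.null(model$genes) && nrow(model$genes) > 0
  graphics::par(mfrow = c(np + has_genes, 1L),
                mar = c(2.2, 4, 1.2, 1), mgp = c(2.2, 0.6, 0))
  for (p in model$panels) {
    b <- p$bars
    keep <- b$start < to & b$end > from
    b <- b[keep, , drop = FALSE]
    graphics::plot(NA, xlim = c(from, to), ylim = c(0, p$ymax * 1.05),
                   xlab = "", ylab = p$label, xaxs = "i", yaxs = "i")
    if (nrow(b))
      graphics::rect(b$start, 0, b$end, b$height, col = b$color,
                     border = NA)
    if (p$kind == "ratio")
      graphics::abline(h = 1, lty = 3, col = "grey40")
  }
  if (has_genes) {
    g <- model$genes
    graphics::plot(NA, xlim = c(from, to), ylim = c(0, nrow(g) + 1),
                   xlab = model$region$chrom, ylab = "genes", axes = FALSE)
    graphics::axis(1)
    for (i in seq_len(nrow(g))) {
      y <- i
      graphics::segments(g$start[i], y, g$end[i], y, lwd = 1)  # intron line
      es <- g$exon_starts[[i]]; ee <- g$exon_ends[[i]]
      graphics::rect(es, y - 0.25, ee, y + 0.25, col = "black")  # exons
      graphics::text(g$start[i], y + 0.45, g$name[i], adj = 0, cex = 0.7)
    }
  }
}

open_device <- function(file, width = 10, height = 7) {
  ext <- tolower(tools::file_ext(file))
  switch(ext,
    pdf = grDevices::pdf(file, width = width, height = height,
                         onefile = TRUE),
    png = grDevices::png(file, width = width * 100, height = height * 100,
                         res = 100),
    stop("unsupported figure format: .", ext, " (use .pdf or .png)"))
  ext
}

#' Render a region read-distribution figure
#'
#' Draws bar graphs of the ChIP (green), control (blue) and ChIP/control
#' ratio (orange) tracks over a region, bins inside called peaks in red, and
#' gene models underneath (thick boxes = exons, thin line = introns).
#' Output format follows the file extension (`.pdf` multi-page — one page
#' per `page_bp` of region — or `.png`, first page only).
#'
#' @inheritParams region_plot_model
#' @param file Output figure path (`.pdf` or `.png`).
#' @param page_bp Region span per pdf page (default 1 Mb).
#' @param ... Passed to [region_plot_model()].
#' @return Invisibly, the `track_plot_model` drawn.
#' @export
render_region <- function(chip, control = NULL, region, file, peaks = NULL,
                          genes = NULL, page_bp = 1e6, ...) {
  model <- region_plot_model(chip, control, region, peaks, genes, ...)
  ext <- open_device(file)
  on.exit(grDevices::dev.off())
  from <- model$region$start; to <- model$region$end
  pages <- if (ext == "pdf") ceiling((to - from) / page_bp) else 1L
  for (pg in seq_len(pages)) {
    p0 <- from + (pg - 1) * page_bp
    p1 <- min(from + pg * page_bp, to)
    draw_model_page(model, p0, p1)
  }
  invisible(model)
}

#' Figure data model for a chromosome-wide enrichment view
#'
#' Rebins the raw tracks to a macro bin (sum of raw values, then the usual
#' per-chromosome renormalization) and computes the ChIP/control enrichment
#' ratio per macro bin. Bars with ratio strictly above `scale_ratio`
#' (default 1) are red, others black; macro bins with no reads in either
#' sample (assembly gaps) get height 0.
#'
#' @param chip,control `coverage_tracks` objects.
#' @param chrom Chromosome name.
#' @param macro_bin Macro bin width in bp (default 100 kb); must be a
#'   multiple of (and at least) the native bin size.
#' @param scale_ratio Red/black threshold on the ratio (default 1).
#' @return A `track_plot_model` with a single `ratio` panel.
#' @export
chromosome_plot_model <- function(chip, control, chrom, macro_bin = 1e5,
                                  scale_ratio = 1) {
  bs <- chip$bin_size
  if (macro_bin < bs) stop("macro bin must be >= native bin size")
  fac <- as.integer(round(macro_bin / bs))
  i <- match(chrom, chip$genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  L <- chip$genome$length[i]
  rebin <- function(tr) {
    r <- tr$chroms[[chrom]]$raw
    grp <- (seq_along(r) - 1L) %/% fac
    raw_m <- as.numeric(rowsum(r, grp))
    N_i <- tr$chrom_stats$N_i[i]
    if (N_i > 0) normalize_track(raw_m, N_i, L) else raw_m
  }
  cm <- rebin(chip); um <- rebin(control)
  ratio <- ifelse(cm + um == 0, 0, ifelse(um > 0, cm / um, Inf))
  nb <- length(cm)
  starts <- (seq_len(nb) - 1) * macro_bin
  ends <- pmin(starts + macro_bin, L)
  col <- ifelse(ratio > scale_ratio, track_colors[["peak"]], "black")
  height <- pmin(ratio, scale_ratio * 4)
  structure(list(region = list(chrom = chrom, start = 0, end = L),
                 bin_size = macro_bin,
                 panels = list(list(label = paste0(chrom, " ChIP/control"),
                                    kind = "ratio",
                                    ymax = max(height, scale_ratio * 1.5),
                                    bars = data.frame(start = starts,
                                                      end = ends,
                                                      height = height,
                                                      color = col,
                                                      stringsAsFactors = FALSE))),
                 genes = NULL),
            class = "track_plot_model")
}

#' Render chromosome-wide macro views
#'
#' One panel per chromosome of the whole-genome enrichment profile at a
#' macro bin (default 100 kb), red bars where ChIP/control exceeds
#' `scale_ratio`.
#'
#' @inheritParams chromosome_plot_model
#' @param file Output figure path (`.pdf` or `.png`).
#' @param chroms Chromosomes to draw (default: all in genome order).
#' @return Invisibly, the list of `track_plot_model`s drawn.
#' @export
render_chromosome <- function(chip, control, file, chroms = NULL,
                              macro_bin = 1e5, scale_ratio = 1) {
  if (is.null(chroms)) chroms <- chip$genome$chrom
  models <- lapply(chroms, function(ch)
    chromosome_plot_model(chip, control, ch, macro_bin, scale_ratio))
  ext <- open_device(file, width = 10, height = 3 * length(models))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(models), 1L), mar = c(2.2, 4, 1.2, 1))
  for (m in models) {
    p <- m$panels[[1L]]
    b <- p$bars
    graphics::plot(NA, xlim = c(0, m$region$end), ylim = c(0, p$ymax),
                   xlab = "", ylab = p$label, xaxs = "i", yaxs = "i")
    graphics::rect(b$start, 0, b$end, b$height, col = b$color, border = NA)
    graphics::abline(h = scale_ratio, lty = 3, col = "grey40")
  }
  invisible(models)
}

#' @export
plot.coverage_tracks <- function(x, control = NULL, region = NULL,
                                 file = NULL, ...) {
  if (is.null(region)) {
    region <- list(x$genome$chrom[1L], 0,
                   min(x$genome$length[1L], 1e6))
  }
  tracks <- if (is.null(control)) "chip" else c("chip", "control", "ratio")
  if (is.null(file)) {
    model <- region_plot_model(x, control, region, tracks = tracks, ...)
    draw_model_page(model, model$region$start, model$region$end)
    return(invisible(model))
  }
  render_region(x, control, region, file, tracks = tracks, ...)
}

#' GC-content track from a genome FASTA
#'
#' Fraction of G/C among non-N bases per fixed window; all-N windows
#' (assembly gaps) are `NA`. Requires the Biostrings package.
#'
#' @param fasta Path to the genome FASTA.
#' @param genome A [genome_table]; sequence names must cover its
#'   chromosomes.
#' @param window Window width in bp (default 500 kb).
#' @return Named list (per chromosome) of GC-fraction vectors.
#' @export
gc_track <- function(fasta, genome, window = 5e5) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("gc_track() requires the Biostrings package")
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  missing <- setdiff(genome$chrom, names(seqs))
  if (length(missing))
    stop("FASTA lacks chromosome(s): ", paste(missing, collapse = ", "))
  out <- lapply(seq_len(nrow(genome)), function(i) {
    s <- seqs[[genome$chrom[i]]]
    L <- length(s)
    if (L != genome$length[i])
      stop("FASTA/genome-table length mismatch for ", genome$chrom[i])
    starts <- seq.int(1L, L, by = window)
    ends <- pmin(starts + window - 1L, L)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("G", "C", "A", "T"))
    gc <- freq[, "G"] + freq[, "C"]
    acgt <- rowSums(freq)
    ifelse(acgt > 0, gc / acgt, NA_real_)
  })
  names(out) <- genome$chrom
  out
}
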