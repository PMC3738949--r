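#' Write binned tracks as wiggle-family files
#'
#' Writes one track file per chromosome. Dialects:
#' \describe{
#'   \item{`wiggle`}{UCSC fixedStep text, `start=1`, `step` = `span` = bin
#'     size, values to 4 decimal places (browser-uploadable).}
#'   \item{`bedgraph`}{4-column bedGraph, 0-based half-open bins, last bin
#'     clipped to the chromosome end.}
#'   \item{`binary`}{A compact fixed-width dialect of this package: the magic
#'     string `"CSWIG1"`, then three little-endian int32 (bin size, value
#'     count, chromosome-name length), the chromosome name, then the values
#'     as little-endian float64. Round-trips bit-exactly.}
#'   \item{`compressed`}{gzip of the `wiggle` text dialect.}
#' }
#'
#' @param tracks A `coverage_tracks` object from [parse2wig()].
#' @param dir Output directory (created if needed).
#' @param dialect Output dialect, see above.
#' @param value Which vector to write: `"smoothed"` (default),
#'   `"normalized"` or `"raw"`.
#' @param prefix Filename prefix (default `"track"`).
#' @return Invisibly, the named vector of written file paths (per
#'   chromosome).
#' @export
write_wig <- function(tracks, dir,
                      dialect = c("wiggle", "bedgraph", "binary", "compressed"),
                      value = c("smoothed", "normalized", "raw"),
                      prefix = "track") {
  dialect <- match.arg(dialect)
  value <- match.arg(value)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- switch(dialect, wiggle = ".wig", bedgraph = ".bedGraph",
                binary = ".bwig", compressed = ".wig.gz")
  bs <- tracks$bin_size
  paths <- character(nrow(tracks$genome))
  names(paths) <- tracks$genome$chrom
  for (i in seq_len(nrow(tracks$genome))) {
    chrom <- tracks$genome$chrom[i]
    v <- tracks$chroms[[i]][[value]]
    if (anyNA(v) || any(!is.finite(v)))
      stop("track for ", chrom, " contains NA/NaN/Inf; refusing to write")
    path <- file.path(dir, paste0(prefix, "_", chrom, ext))
    switch(dialect,
      wiggle = writeLines(wiggle_lines(chrom, v, bs), path),
      compressed = {
        con <- gzfile(path, "wb")
        writeLines(wiggle_lines(chrom, v, bs), con)
        close(con)
      },
      bedgraph = {
        L <- tracks$genome$length[i]
        starts <- (seq_along(v) - 1L) * bs
        ends <- pmin(starts + bs, L)
        writeLines(sprintf("%s\t%d\t%d\t%.4f", chrom, starts, ends, v), path)
      },
      binary = {
        con <- file(path, "wb")
        writeChar("CSWIG1", con, nchars = 6L, eos = NULL)
        writeBin(as.integer(c(bs, length(v), nchar(chrom))), con,
                 size = 4L, endian = "little")
        writeChar(chrom, con, nchars = nchar(chrom), eos = NULL)
        writeBin(as.double(v), con, size = 8L, endian = "little")
        close(con)
      })
    paths[i] <- path
  }
  invisible(paths)
}

wiggle_lines <- function(chrom, v, bs) {
  c(sprintf("fixedStep chrom=%s start=1 step=%d span=%d", chrom, bs, bs),
    sprintf("%.4f", v))
}

#' Read a wiggle-family track file
#'
#' Reads one per-chromosome track file written by [write_wig()]; the dialect
#' is inferred from the extension (`.wig`, `.wig.gz`, `.bedGraph`, `.bwig`).
#'
#' @param path File path.
#' @return List with `chrom`, `bin_size` and `values`.
#' @export
read_wig <- function(path) {
  if (grepl("\\.bwig$", path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 6L, useBytes = TRUE)
    if (!identical(magic, "CSWIG1")) stop("not a CSWIG1 binary track: ", path)
    hdr <- readBin(con, "integer", 3L, size = 4L, endian = "little")
    chrom <- readChar(con, hdr[3L], useBytes = TRUE)
    vals <- readBin(con, "double", hdr[2L], size = 8L, endian = "little")
    return(list(chrom = chrom, bin_size = hdr[1L], values = vals))
  }
  if (grepl("\\.bedGraph$", path, ignore.case = TRUE)) {
    dt <- data.table::fread(path, header = FALSE, sep = "\t")
    return(list(chrom = as.character(dt[[1L]][1L]),
                bin_size = as.integer(dt[[3L]][1L] - dt[[2L]][1L]),
                values = as.numeric(dt[[4L]])))
  }
  lines <- readLines(path)   # file() decompresses .gz transparently
  hdr <- lines[1L]
  if (!startsWith(hdr, "fixedStep"))
    stop("expected a fixedStep wiggle header in ", path)
  field <- function(key) sub(paste0(".*", key, "="), "",
                             regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr)))
  list(chrom = sub("chrom=", "", field("chrom")),
       bin_size = as.integer(sub("step=", "", field("step"))),
       values = as.numeric(lines[-1L]))
}

#' Write a peak list as a BED-compatible TSV
#'
#' Tab-delimited peak table whose first three columns are chrom/start/end,
#' with a `#`-prefixed header line, so the file doubles as a BED file.
#' Peaks must be non-overlapping (merging happens upstream) and sorted by
#' (chromosome order, start).
#'
#' @param peaks A `peak_calls` object or its `peaks` data.frame.
#' @param path Output file.
#' @param sort Set `TRUE` to sort unsorted input instead of erroring.
#' @return Invisibly, `path`.
#' @export
write_peaks <- function(peaks, path, sort = FALSE) {
  pk <- if (inherits(peaks, "peak_calls")) peaks$peaks else peaks
  chrom_rank <- match(pk$chrom, unique(pk$chrom))
  ord <- order(chrom_rank, pk$start)
  if (!identical(ord, seq_len(nrow(pk)))) {
    if (!sort) stop("peaks are not sorted by (chromosome, start); ",
                    "pass sort = TRUE to sort on write")
    pk <- pk[ord, , drop = FALSE]
  }
  for (chr in unique(pk$chrom)) {
    p <- pk[pk$chrom == chr, , drop = FALSE]
    if (nrow(p) > 1L && any(p$start[-1L] < p$end[-nrow(p)]))
      stop("overlapping peaks on ", chr, "; merge before writing")
  }
  hdr <- paste0("#", paste(colnames(pk), collapse = "\t"))
  con <- file(path, "w")
  writeLines(hdr, con)
  if (nrow(pk))
    utils::write.table(pk, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(path)
}

#' Read a peak TSV written by [write_peaks()]
#' @param path File path.
#' @return data.frame of peaks.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1L]), "\t")[[1L]]
  if (length(lines) == 1L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    return(out)
  }
  dt <- utils::read.table(path, sep = "\t", comment.char = "#",
                          col.names = cols, stringsAsFactors = FALSE)
  dt
}
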