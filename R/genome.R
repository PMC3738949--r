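#' Construct a genome table
#'
#' A genome table is the ordered list of chromosome names and lengths that
#' fixes the coordinate frame for every downstream computation; its row order
#' defines output ordering everywhere.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer-ish vector of chromosome lengths in base pairs
#'   (strictly positive).
#' @return A `genome_table`: a data.frame with columns `chrom` and `length`.
#' @export
genome_table <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal length")
  if (anyDuplicated(chrom))
    stop("duplicate chromosome name: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_table", "data.frame"))
}

#' Read a genome table file
#'
#' Parses a two-column tab-delimited file of chromosome name and length,
#' preserving file order.
#'
#' @param path Path to a tab-delimited file with columns name, length.
#' @return A [genome_table].
#' @export
read_genome_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty genome table: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad))
    stop("genome table line ", bad[1L], " does not have two tab-separated fields")
  chrom <- vapply(parts, `[[`, "", 1L)
  lenstr <- vapply(parts, `[[`, "", 2L)
  len <- suppressWarnings(as.numeric(lenstr))
  if (anyNA(len)) {
    i <- which(is.na(len))[1L]
    stop("genome table line ", i, ": length '", lenstr[i], "' is not an integer")
  }
  genome_table(chrom, len)
}

#' @export
print.genome_table <- function(x, ...) {
  cat("Genome table:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Total genome length
#' @param genome A [genome_table].
#' @return Sum of chromosome lengths (bp).
#' @export
genome_length <- function(genome) sum(genome$length)

# number of bins on one chromosome
n_bins <- function(chrom_length, bin_size) as.integer(ceiling(chrom_length / bin_size))

stopifnot_genome <- function(genome) {
  if (!inherits(genome, "genome_table"))
    stop("expected a genome_table (see read_genome_table())")
  invisible(genome)
}
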