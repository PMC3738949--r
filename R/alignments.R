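#' Read mapped-read alignments
#'
#' Parses a mapped-read file into one record per mapped locus. Supported
#' formats: `"sam"` (text SAM, header optional — chromosome lengths come from
#' the genome table), `"bowtie"` (Bowtie default text output) and `"bed"`
#' (6-column BED). All coordinates are converted to the internal 0-based
#' half-open convention at this boundary; SAM/Bowtie records flagged unmapped
#' are dropped.
#'
#' The mapping multiplicity `n_k` (number of loci a read maps to, giving each
#' locus weight `1/n_k`) is taken from the SAM `NH` tag when present, from the
#' Bowtie "other alignments" column (+1), and otherwise by counting loci that
#' share a read id across the whole file; reads seen at a single locus get
#' `n_k = 1`.
#'
#' @param path Input file.
#' @param format One of `"sam"`, `"bowtie"`, `"bed"`.
#' @param genome A [genome_table]; every alignment must lie on one of its
#'   chromosomes.
#' @param on_missing_chrom `"error"` (default) to fail on an alignment whose
#'   chromosome is absent from the genome table, `"skip"` to drop such
#'   records with a warning.
#' @return A `data.table` with columns `chrom`, `pos5` (0-based leftmost
#'   aligned base), `strand` (`"+"`/`"-"`), `n_k`, `read_id`, `reflen`
#'   (reference bases consumed) and `score` (alignment score, `NA` when the
#'   format carries none).
#' @export
read_alignments <- function(path, format = c("sam", "bowtie", "bed"),
                            genome, on_missing_chrom = c("error", "skip")) {
  format <- match.arg(format)
  on_missing_chrom <- match.arg(on_missing_chrom)
  stopifnot_genome(genome)
  aln <- switch(format,
    sam = parse_sam(path),
    bowtie = parse_bowtie(path),
    bed = parse_bed_alignments(path)
  )
  # fall back to counting loci per read id when no explicit multiplicity
  n_unmapped <- attr(aln, "n_unmapped")
  if (all(is.na(aln$n_k))) aln[, n_k := .N, by = "read_id"]
  aln$n_k[is.na(aln$n_k)] <- 1L
  out <- validate_alignments(aln, genome, on_missing_chrom)
  data.table::setattr(out, "n_unmapped", if (is.null(n_unmapped)) 0L else n_unmapped)
  out
}

validate_alignments <- function(aln, genome, on_missing_chrom = "error") {
  known <- match(aln$chrom, genome$chrom)
  if (anyNA(known)) {
    missing <- unique(aln$chrom[is.na(known)])
    if (on_missing_chrom == "error")
      stop("alignment(s) on chromosome(s) absent from the genome table: ",
           paste(missing, collapse = ", "))
    warning("skipping ", sum(is.na(known)), " alignment(s) on unknown chromosome(s): ",
            paste(missing, collapse = ", "))
    aln <- aln[!is.na(known)]
    known <- known[!is.na(known)]
  }
  over <- aln$pos5 + aln$reflen > genome$length[known]
  if (any(over))
    stop(sum(over), " alignment(s) extend past the chromosome end (first: ",
         aln$chrom[which(over)[1L]], ":", aln$pos5[which(over)[1L]], ")")
  if (any(aln$n_k < 1L)) stop("n_k must be >= 1")
  aln[]
}

# reference bases consumed by a CIGAR string (M/D/N/=/X ops); vectorized over
# the unique CIGARs so million-read files do not pay per-record regex cost
cigar_reflen <- function(cigar) {
  u <- unique(cigar)
  ulen <- vapply(u, function(cg) {
    if (cg == "*") return(NA_integer_)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1L]]
    if (!length(ops) || nchar(paste(ops, collapse = "")) != nchar(cg))
      stop("malformed CIGAR: ", cg)
    kind <- substring(ops, nchar(ops))
    n <- as.integer(substring(ops, 1L, nchar(ops) - 1L))
    sum(n[kind %in% c("M", "D", "N", "=", "X")])
  }, 0L)
  unname(ulen[match(cigar, u)])
}

# pull an integer SAM tag (e.g. "NH", "AS") out of the optional columns
extract_sam_tag <- function(dt, tagcols, tag) {
  out <- rep(NA_integer_, nrow(dt))
  pat <- paste0("^", tag, ":i:")
  for (cl in tagcols) {
    v <- as.character(dt[[cl]])
    hit <- !is.na(v) & startsWith(v, paste0(tag, ":i:"))
    if (any(hit)) out[hit] <- as.integer(sub(pat, "", v[hit]))
  }
  out
}

parse_sam <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          quote = "", colClasses = list(character = 1L))
  dt <- dt[!startsWith(dt[[1L]], "@")]
  if (nrow(dt) == 0L) stop("no alignment records in ", path)
  flag <- as.integer(dt[[2L]])
  mapped <- bitwAnd(flag, 4L) == 0L
  n_unmapped <- sum(!mapped)
  dt <- dt[mapped]
  flag <- flag[mapped]
  reflen <- cigar_reflen(as.character(dt[[6L]]))
  reflen[is.na(reflen)] <- 1L
  tagcols <- seq.int(12L, ncol(dt))
  out <- data.table::data.table(
    chrom = as.character(dt[[3L]]),
    pos5 = as.numeric(dt[[4L]]) - 1,          # SAM POS is 1-based
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    n_k = if (ncol(dt) >= 12L) extract_sam_tag(dt, tagcols, "NH") else NA_integer_,
    read_id = as.character(dt[[1L]]),
    reflen = reflen,
    score = if (ncol(dt) >= 12L) as.numeric(extract_sam_tag(dt, tagcols, "AS"))
            else NA_real_
  )
  data.table::setattr(out, "n_unmapped", n_unmapped)
  out
}

parse_bowtie <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, fill = TRUE,
                          quote = "", colClasses = list(character = c(1L, 2L, 3L, 5L)))
  if (ncol(dt) < 7L) stop("not Bowtie default output (need >= 7 columns): ", path)
  data.table::data.table(
    chrom = as.character(dt[[3L]]),
    pos5 = as.numeric(dt[[4L]]),              # bowtie offsets are 0-based
    strand = as.character(dt[[2L]]),
    n_k = as.integer(dt[[7L]]) + 1L,          # column 7 = number of *other* loci
    read_id = as.character(dt[[1L]]),
    reflen = nchar(as.character(dt[[5L]])),
    score = NA_real_
  )
}

parse_bed_alignments <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "")
  if (ncol(dt) < 6L) stop("alignment BED must have 6 columns: ", path)
  data.table::data.table(
    chrom = as.character(dt[[1L]]),
    pos5 = as.numeric(dt[[2L]]),
    strand = as.character(dt[[6L]]),
    n_k = NA_integer_,                        # resolved by read-id counting
    read_id = as.character(dt[[4L]]),
    reflen = as.numeric(dt[[3L]]) - as.numeric(dt[[2L]]),
    score = NA_real_
  )
}

# strand-specific 5' end of each alignment (rightmost aligned base for "-")
five_prime_end <- function(aln) {
  ifelse(aln$strand == "+", aln$pos5, aln$pos5 + aln$reflen - 1)
}

#' Select alignments by mapping mode
#'
#' Mapping-mode filters mirroring the `-m1` / `-m10` / `-k1` conventions:
#' `"unique"` keeps only uniquely mapped reads (`n_k == 1`);
#' `"multi"` keeps all loci of reads mapped to at most `M` loci, each locus
#' carrying weight `1/n_k`; `"best"` keeps exactly one locus per read (the
#' highest alignment score, ties broken by genome chromosome order then
#' leftmost position) and resets its weight to 1.
#'
#' @param aln Alignment table from [read_alignments()].
#' @param mode `"unique"`, `"multi"` or `"best"`.
#' @param M Multiplicity cap for `"multi"` (default 10).
#' @param genome Optional [genome_table] supplying chromosome order for
#'   `"best"` tie-breaking; file order of appearance is used otherwise.
#' @return Filtered alignment table.
#' @export
select_alignments <- function(aln, mode = c("unique", "multi", "best"),
                              M = 10L, genome = NULL) {
  mode <- match.arg(mode)
  if (mode == "multi" && M < 1L) stop("M must be >= 1")
  if (mode == "unique") return(aln[aln$n_k == 1L])
  if (mode == "multi") return(aln[aln$n_k <= M])
  # best: one locus per read id
  chrom_rank <- if (!is.null(genome)) match(aln$chrom, genome$chrom)
                else match(aln$chrom, unique(aln$chrom))
  score <- ifelse(is.na(aln$score), 0, aln$score)
  ord <- order(aln$read_id, -score, chrom_rank, aln$pos5)
  best <- ord[!duplicated(aln$read_id[ord])]
  out <- aln[sort(best)]
  out$n_k <- 1L
  out
}

#' PCR-duplicate count cap
#'
#' The duplicate-count cap `T_b` above which reads sharing a strand-specific
#' 5' end are treated as PCR over-amplification: the larger of 1 and ten
#' times the per-base expected read count `E(s) = N^s / L`, where `N^s` is
#' the read count on strand `s` and `L` the genome length; the strand with
#' the higher expectation governs and the product is rounded up.
#'
#' @param n_plus,n_minus Mapped read counts on the + and - strands.
#' @param L Genome length in bp (sum of the genome-table lengths).
#' @return Integer cap `T_b >= 1`.
#' @export
compute_Tb <- function(n_plus, n_minus, L) {
  if (L <= 0) stop("genome length must be positive")
  e10 <- max(n_plus, n_minus) / L * 10
  max(1L, as.integer(ceiling(e10)))
}

#' Filter PCR-duplicate alignments
#'
#' Groups alignments by (chromosome, strand-specific 5' end, strand) and
#' keeps at most `Tb` per group in first-seen order; the excess is counted as
#' PCR bias. Opposite-strand reads at the same coordinate are independent
#' groups and never collapsed. The operation is idempotent.
#'
#' @param aln Alignment table.
#' @param Tb Duplicate cap from [compute_Tb()] (`>= 1`).
#' @return List with `alignments` (kept records), `n_filtered` (records
#'   removed) and `weight_filtered` (removed weight, in `1/n_k` read units).
#' @export
filter_pcr_bias <- function(aln, Tb) {
  if (Tb < 1L) stop("Tb must be >= 1")
  if (nrow(aln) == 0L)
    return(list(alignments = aln, n_filtered = 0L, weight_filtered = 0))
  key <- data.table::data.table(chrom = aln$chrom, fp = five_prime_end(aln),
                                strand = aln$strand)
  keep <- key[, occ := seq_len(.N), by = c("chrom", "fp", "strand")][["occ"]] <= Tb
  list(alignments = aln[keep],
       n_filtered = sum(!keep),
       weight_filtered = sum(1 / aln$n_k[!keep]))
}
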