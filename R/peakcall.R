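#' Peak-calling parameters
#'
#' The five significance thresholds and scan settings of the sliding-window
#' peak caller. A window of contiguous bins is significant only when all five
#' hold simultaneously (strict inequalities):
#' \enumerate{
#'   \item one-sided Wilcoxon rank-sum p (ChIP greater than control)
#'     `< p_thresh`;
#'   \item fold enrichment (ChIP window sum / control window sum)
#'     `> fold_thresh`;
#'   \item maximum ChIP bin intensity / ChIP chromosome mean depth
#'     `> chip_depth_ratio_thresh`;
#'   \item control window mean / control chromosome mean depth
#'     `< control_repeat_thresh` (rejects highly repetitive regions);
#'   \item maximum ChIP bin intensity `> intensity_thresh`.
#' }
#'
#' @param window_bins Window length in bins (default 30).
#' @param p_thresh Threshold (i), default 1e-4.
#' @param fold_thresh Threshold (ii), default 3.0.
#' @param chip_depth_ratio_thresh Threshold (iii), default 3.0.
#' @param control_repeat_thresh Threshold (iv), default 10.0.
#' @param intensity_thresh Threshold (v), default 6.0, in normalized units.
#' @param step_bins Scan stride in bins (default 1).
#' @param control_floor Zero-control guard: the control window sum in the
#'   fold ratio is floored at `control mean depth * window_bins *
#'   control_floor` (default 0.1) so depleted-control windows stay callable
#'   without division by zero.
#' @param use_smoothed Apply the thresholds to the smoothed track (default)
#'   or, when `FALSE`, to the unsmoothed normalized track.
#' @return A `peak_params` list.
#' @export
peak_params <- function(window_bins = 30L,
                        p_thresh = 1e-4,
                        fold_thresh = 3.0,
                        chip_depth_ratio_thresh = 3.0,
                        control_repeat_thresh = 10.0,
                        intensity_thresh = 6.0,
                        step_bins = 1L,
                        control_floor = 0.1,
                        use_smoothed = TRUE) {
  p <- list(window_bins = as.integer(window_bins), p_thresh = p_thresh,
            fold_thresh = fold_thresh,
            chip_depth_ratio_thresh = chip_depth_ratio_thresh,
            control_repeat_thresh = control_repeat_thresh,
            intensity_thresh = intensity_thresh,
            step_bins = as.integer(step_bins),
            control_floor = control_floor,
            use_smoothed = isTRUE(use_smoothed))
  if (p$window_bins < 2L) stop("window_bins must be >= 2")
  if (p$step_bins < 1L) stop("step_bins must be >= 1")
  num <- c(p$p_thresh, p$fold_thresh, p$chip_depth_ratio_thresh,
           p$control_repeat_thresh, p$intensity_thresh)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be positive")
  structure(p, class = "peak_params")
}

track_vectors <- function(tracks, use_smoothed) {
  lapply(tracks$chroms, function(ch)
    if (use_smoothed) ch$smoothed else ch$normalized)
}

#' Sliding-window scan of a ChIP/control track pair
#'
#' Slides a window of `window_bins` contiguous bins along every chromosome
#' (stride `step_bins`) and evaluates the five threshold quantities of
#' [peak_params()] for each window position.
#'
#' @param chip,control `coverage_tracks` objects on the same genome and bin
#'   size.
#' @param params A [peak_params()] list.
#' @return A data.frame with one row per window: `chrom`, `start_bin`,
#'   `pvalue`, `fold`, `chip_max`, `control_mean`, the five per-threshold
#'   logicals `pass_p` .. `pass_intensity`, and `significant`.
#' @export
window_scan <- function(chip, control, params = peak_params()) {
  if (!inherits(chip, "coverage_tracks") || !inherits(control, "coverage_tracks"))
    stop("chip and control must be coverage_tracks objects")
  if (chip$bin_size != control$bin_size)
    stop("bin-size mismatch between ChIP (", chip$bin_size,
         ") and control (", control$bin_size, ")")
  if (!identical(chip$genome$chrom, control$genome$chrom))
    stop("chromosome mismatch between ChIP and control tracks")
  w <- params$window_bins
  step <- params$step_bins
  vc_all <- track_vectors(chip, params$use_smoothed)
  vu_all <- track_vectors(control, params$use_smoothed)
  res <- vector("list", nrow(chip$genome))
  for (i in seq_len(nrow(chip$genome))) {
    vc <- vc_all[[i]]; vu <- vu_all[[i]]
    if (length(vc) < w) next
    mean_chip <- mean(vc)
    mean_ctrl <- mean(vu)
    if (w >= 10L) {
      m <- cpp_window_scan(vc, vu, w, step)
    } else {
      starts0 <- seq.int(0L, length(vc) - w, by = step)
      m <- t(vapply(starts0, function(s) {
        xs <- vc[(s + 1):(s + w)]; ys <- vu[(s + 1):(s + w)]
        c(sum(xs), sum(ys), max(xs), wilcoxon_greater(xs, ys))
      }, numeric(4)))
    }
    if (nrow(m) == 0L) next
    start_bin <- seq.int(0L, by = step, length.out = nrow(m))
    chip_sum <- m[, 1L]; ctrl_sum <- m[, 2L]
    chip_max <- m[, 3L]; pval <- m[, 4L]
    floorv <- mean_ctrl * w * params$control_floor
    denom <- pmax(ctrl_sum, floorv)
    fold <- ifelse(denom > 0, chip_sum / denom,
                   ifelse(chip_sum > 0, Inf, 0))
    control_mean <- ctrl_sum / w
    pass_p <- pval < params$p_thresh
    pass_fold <- fold > params$fold_thresh
    pass_depth <- mean_chip > 0 & chip_max / max(mean_chip, .Machine$double.xmin) >
      params$chip_depth_ratio_thresh
    rep_ratio <- if (mean_ctrl > 0) control_mean / mean_ctrl else rep(0, length(control_mean))
    pass_repeat <- rep_ratio < params$control_repeat_thresh
    pass_intensity <- chip_max > params$intensity_thresh
    res[[i]] <- data.frame(
      chrom = chip$genome$chrom[i], start_bin = start_bin,
      pvalue = pval, fold = fold, chip_max = chip_max,
      control_mean = control_mean,
      pass_p = pass_p, pass_fold = pass_fold, pass_depth = pass_depth,
      pass_repeat = pass_repeat, pass_intensity = pass_intensity,
      significant = pass_p & pass_fold & pass_depth & pass_repeat &
        pass_intensity,
      stringsAsFactors = FALSE
    )
  }
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res))
    return(data.frame(chrom = character(), start_bin = integer(),
                      pvalue = numeric(), fold = numeric(),
                      chip_max = numeric(), control_mean = numeric(),
                      pass_p = logical(), pass_fold = logical(),
                      pass_depth = logical(), pass_repeat = logical(),
                      pass_intensity = logical(), significant = logical()))
  do.call(rbind, res)
}

#' Merge significant windows into peaks
#'
#' Overlapping or abutting significant windows on one chromosome are merged
#' into a single peak spanning their union. Peak statistics: p-value is the
#' minimum and fold enrichment the maximum over member windows; the peak
#' maximum intensity and its summit come from the ChIP track bins inside the
#' merged interval (leftmost bin on ties).
#'
#' @param windows Window table from [window_scan()] (only rows with
#'   `significant == TRUE` are used), sorted by (chromosome, start).
#' @param chip The ChIP `coverage_tracks` (for summit/max lookup).
#' @param params The [peak_params()] used for the scan.
#' @return data.frame of peaks: `chrom`, `start`, `end` (bp, 0-based
#'   half-open, clipped to the chromosome), `name`, `pvalue`,
#'   `fold_enrichment`, `max_intensity`, `summit` (bp of the summit bin
#'   start).
#' @export
merge_windows <- function(windows, chip, params = peak_params()) {
  sig <- windows[windows$significant, , drop = FALSE]
  bs <- chip$bin_size
  w <- params$window_bins
  vecs <- track_vectors(chip, params$use_smoothed)
  out <- list()
  for (chr in chip$genome$chrom) {
    sw <- sig[sig$chrom == chr, , drop = FALSE]
    if (nrow(sw) == 0L) next
    sw <- sw[order(sw$start_bin), , drop = FALSE]
    sbin <- sw$start_bin
    ebin <- sbin + w
    # merge overlapping-or-abutting [sbin, ebin) intervals
    grp <- cumsum(c(1L, as.integer(sbin[-1L] > cummax(ebin[-length(ebin)]))))
    v <- vecs[[chr]]
    L <- chip$genome$length[match(chr, chip$genome$chrom)]
    for (g in unique(grp)) {
      rows <- which(grp == g)
      b0 <- min(sbin[rows]); b1 <- max(ebin[rows])
      seg <- v[(b0 + 1):min(b1, length(v))]
      imax <- which.max(seg)
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr,
        start = b0 * bs,
        end = min(b1 * bs, L),
        pvalue = min(sw$pvalue[rows]),
        fold_enrichment = max(sw$fold[rows]),
        max_intensity = max(seg),
        summit = (b0 + imax - 1L) * bs,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), pvalue = numeric(),
                      fold_enrichment = numeric(), max_intensity = numeric(),
                      summit = numeric(), stringsAsFactors = FALSE))
  pk <- do.call(rbind, out)
  pk <- pk[order(match(pk$chrom, chip$genome$chrom), pk$start), , drop = FALSE]
  pk <- data.frame(pk[, c("chrom", "start", "end")],
                   name = sprintf("peak%05d", seq_len(nrow(pk))),
                   pk[, c("pvalue", "fold_enrichment", "max_intensity", "summit")],
                   stringsAsFactors = FALSE)
  rownames(pk) <- NULL
  pk
}

#' Call peaks on a ChIP/control track pair
#'
#' Runs the sliding-window scan, applies the five thresholds, merges
#' contiguous significant windows, and reports per-threshold diagnostics
#' (how many windows each threshold alone rejected).
#'
#' @param chip,control `coverage_tracks` objects on the same genome/bin size;
#'   both must be normalized (as produced by [parse2wig()]).
#' @param params A [peak_params()] list.
#' @return A `peak_calls` object: list with `peaks` (data.frame as in
#'   [merge_windows()]), `rejections` (named counts of windows failing each
#'   threshold, plus totals) and `params`.
#' @export
call_peaks <- function(chip, control, params = peak_params()) {
  win <- window_scan(chip, control, params)
  peaks <- merge_windows(win, chip, params)
  rejections <- c(
    n_windows = nrow(win),
    p = sum(!win$pass_p),
    fold = sum(!win$pass_fold),
    chip_depth_ratio = sum(!win$pass_depth),
    control_repeat = sum(!win$pass_repeat),
    intensity = sum(!win$pass_intensity),
    n_significant = sum(win$significant)
  )
  structure(list(peaks = peaks, rejections = rejections, params = params,
                 genome = chip$genome, bin_size = chip$bin_size),
            class = "peak_calls")
}

#' @export
print.peak_calls <- function(x, ...) {
  cat("Peak calls:", nrow(x$peaks), "peak(s) from",
      x$rejections[["n_windows"]], "windows (",
      x$rejections[["n_significant"]], "significant )\n")
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10L))
  if (nrow(x$peaks) > 10L) cat("...", nrow(x$peaks) - 10L, "more\n")
  invisible(x)
}

#' @export
summary.peak_calls <- function(object, ...) {
  r <- object$rejections
  cat("windows scanned:        ", r[["n_windows"]], "\n")
  cat("rejected by threshold (windows failing each predicate):\n")
  for (nm in c("p", "fold", "chip_depth_ratio", "control_repeat", "intensity"))
    cat(sprintf("  %-18s %d\n", nm, r[[nm]]))
  cat("significant windows:    ", r[["n_significant"]], "\n")
  cat("merged peaks:           ", nrow(object$peaks), "\n")
  invisible(r)
}

#' Empirical FDR by ChIP/control sample swap
#'
#' Calls peaks twice with identical parameters — once as given and once with
#' the ChIP and control samples swapped — and returns the ratio (number of
#' swapped-sample peaks) / (number of ChIP peaks). The estimate is `NA` with
#' a warning when no ChIP peaks are called, and a warning is emitted when
#' fewer than 100 ChIP peaks are available, where the ratio becomes
#' unstable.
#'
#' @param chip,control `coverage_tracks` objects.
#' @param params A [peak_params()] list.
#' @return List with `fdr`, `n_chip_peaks`, `n_control_peaks`, and the two
#'   `peak_calls` objects (`chip_calls`, `swapped_calls`).
#' @export
empirical_fdr <- function(chip, control, params = peak_params()) {
  fwd <- call_peaks(chip, control, params)
  rev <- call_peaks(control, chip, params)
  n_chip <- nrow(fwd$peaks)
  n_ctrl <- nrow(rev$peaks)
  if (n_chip == 0L) {
    warning("no ChIP peaks called; empirical FDR is undefined")
    fdr <- NA_real_
  } else {
    if (n_chip < 100L)
      warning("only ", n_chip,
              " ChIP peaks; empirical FDR is unreliable below ~100 peaks")
    fdr <- n_ctrl / n_chip
  }
  list(fdr = fdr, n_chip_peaks = n_chip, n_control_peaks = n_ctrl,
       chip_calls = fwd, swapped_calls = rev)
}

#' Peak-count / FDR sweep over the intensity threshold
#'
#' Re-runs [empirical_fdr()] with each value of `thresholds` substituted for
#' the maximum-intensity threshold (v), tabulating how peak counts and the
#' swap FDR respond as the peak-intensity cutoff is made more stringent.
#'
#' @param chip,control `coverage_tracks` objects.
#' @param params Base [peak_params()]; all other thresholds are held fixed.
#' @param thresholds Ascending numeric vector of intensity thresholds.
#' @return data.frame with columns `intensity_thresh`, `n_chip_peaks`,
#'   `n_control_peaks`, `fdr`.
#' @export
fdr_threshold_sweep <- function(chip, control, params = peak_params(),
                                thresholds = c(6, 8, 16)) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  if (!length(thresholds))
    return(data.frame(intensity_thresh = numeric(), n_chip_peaks = integer(),
                      n_control_peaks = integer(), fdr = numeric()))
  rows <- lapply(thresholds, function(th) {
    p <- params
    p$intensity_thresh <- th
    r <- suppressWarnings(empirical_fdr(chip, control, p))
    data.frame(intensity_thresh = th, n_chip_peaks = r$n_chip_peaks,
               n_control_peaks = r$n_control_peaks, fdr = r$fdr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
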