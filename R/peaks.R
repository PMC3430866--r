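## Peak-processing stage: repeat-mask filtering, binding-density matrices
## around summits, sequencing-depth saturation curves, and the partition of
## peaks into the early-shared ("2,3,4") and late-only ("4 only") classes.

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(start = peaks$start + 1L,
                                          end = peaks$end))
}

mask_granges <- function(mask) {
  GenomicRanges::reduce(
    GenomicRanges::GRanges(mask$chrom,
                           IRanges::IRanges(start = mask$start + 1L,
                                            end = mask$end)))
}

#' Fraction of each peak covered by a repeat mask
#' @param peaks Peak table.
#' @param repeat_mask Data frame with `chrom`, `start`, `end` (0-based
#'   half-open); overlap is computed on the merged mask.
#' @return Numeric vector of masked-base fractions, one per peak.
#' @export
repeat_overlap_fraction <- function(peaks, repeat_mask) {
  if (nrow(peaks) == 0L) return(numeric(0))
  if (is.null(repeat_mask) || nrow(repeat_mask) == 0L)
    return(rep(0, nrow(peaks)))
  gr <- peaks_granges(peaks)
  mk <- mask_granges(repeat_mask)
  ov <- GenomicRanges::findOverlaps(gr, mk)
  frac <- rep(0, nrow(peaks))
  if (length(ov) > 0) {
    inter <- IRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                 mk[S4Vectors::subjectHits(ov)])
    w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
    frac[as.integer(names(w))] <- as.numeric(w) /
      (peaks$end - peaks$start)[as.integer(names(w))]
  }
  frac
}

#' Filter peaks lying in repeat regions
#'
#' A peak is excluded iff the fraction of its bases covered by the merged
#' repeat mask exceeds `repeat_fraction` (default 0.6: a 100 bp peak with
#' 61 masked bases is excluded, with 60 it is retained).
#'
#' @param peaks Peak table.
#' @param repeat_mask Repeat-mask intervals (`chrom`, `start`, `end`).
#' @param cfg A [pipeline_config()].
#' @return List with `retained` (peak table) and `excluded` (data frame of
#'   `peak_id` and `masked_fraction` for the dropped peaks).
#' @export
filter_repeat_peaks <- function(peaks, repeat_mask, cfg = pipeline_config()) {
  frac <- repeat_overlap_fraction(peaks, repeat_mask)
  drop <- frac > cfg$repeat_fraction
  list(retained = peaks[!drop, , drop = FALSE],
       excluded = data.frame(peak_id = peaks$peak_id[drop],
                             masked_fraction = frac[drop],
                             stringsAsFactors = FALSE))
}

#' Binding-density matrix around peak summits
#'
#' For each peak, mean coverage per bin over
#' `[summit - halfwindow, summit + halfwindow)`; regions absent from the
#' track read as zero. Rows are ordered by descending population-4 height
#' so the strongest-binding block is visible at the top of a rendered
#' heatmap.
#'
#' @param peaks Peak table.
#' @param coverage Coverage track (`chrom`, `start`, `end`, `value`),
#'   0-based half-open, non-overlapping.
#' @param cfg A [pipeline_config()]; supplies the half-window (default
#'   5 kb).
#' @param bin_bp Bin width; must divide the full window.
#' @return Matrix (peaks x bins) with peak ids as rownames, plus a
#'   `bin_bp` attribute.
#' @export
density_matrix <- function(peaks, coverage, cfg = pipeline_config(),
                           bin_bp = 100L) {
  hw <- cfg$heatmap_halfwindow_bp
  if ((2L * hw) %% bin_bp != 0L)
    stop("bin_bp must divide the window (2 x halfwindow)")
  nb <- (2L * hw) %/% bin_bp
  ord <- order(-peaks$h4)
  peaks <- peaks[ord, , drop = FALSE]
  m <- matrix(0, nrow(peaks), nb,
              dimnames = list(peaks$peak_id, NULL))
  cov_by_chrom <- split(coverage, coverage$chrom)
  for (i in seq_len(nrow(peaks))) {
    cv <- cov_by_chrom[[peaks$chrom[i]]]
    if (is.null(cv) || nrow(cv) == 0L) next
    win_start <- peaks$summit[i] - hw
    for (b in seq_len(nb)) {
      bs <- win_start + (b - 1L) * bin_bp
      be <- bs + bin_bp
      ov <- cv[cv$start < be & cv$end > bs, , drop = FALSE]
      if (nrow(ov) == 0L) next
      w <- pmin(ov$end, be) - pmax(ov$start, bs)
      m[i, b] <- sum(w * ov$value) / bin_bp
    }
  }
  attr(m, "bin_bp") <- bin_bp
  m
}

#' Sequencing-depth saturation curve by binomial thinning
#'
#' Emulates subsampling the library to a fraction of its depth: each
#' peak's read count is binomially thinned at each depth (`n_reps` times)
#' and the mean fraction of peaks whose thinned count still reaches
#' `threshold` is reported with its Monte-Carlo standard error.
#'
#' @param per_peak_counts Non-negative integer vector of per-peak read
#'   counts.
#' @param depths Depth fractions in (0, 1].
#' @param n_reps Thinning replicates per depth.
#' @param threshold Minimum thinned count for a peak to be recovered.
#' @param seed Integer seed.
#' @return Data frame with `depth`, `recovered_fraction`, `se`.
#' @export
saturation_curve <- function(per_peak_counts, depths = seq(0.1, 1, by = 0.1),
                             n_reps = 20L, threshold = 10L, seed = 1L) {
  stopifnot(all(depths > 0), all(depths <= 1),
            all(per_peak_counts >= 0),
            all(per_peak_counts == round(per_peak_counts)))
  set.seed(stage_seed(seed, "saturation"))
  n <- length(per_peak_counts)
  out <- lapply(depths, function(f) {
    fr <- vapply(seq_len(n_reps), function(r) {
      thinned <- stats::rbinom(n, per_peak_counts, f)
      mean(thinned >= threshold)
    }, numeric(1))
    data.frame(depth = f, recovered_fraction = mean(fr),
               se = stats::sd(fr) / sqrt(n_reps))
  })
  do.call(rbind, out)
}

#' Partition peaks into early-shared and late-only classes
#'
#' Peaks called in population 2 or 3 (regardless of population 4) form the
#' `"2,3,4"` partition; peaks called exclusively in population 4 form
#' `"4 only"`. The two partitions are disjoint and cover all peaks. The
#' pairwise Pearson correlations of peak heights are reported per
#' partition and overall.
#'
#' @param peaks Peak table with `called2`, `called3`, `called4` flags; a
#'   peak with no called population violates the peak invariant and is an
#'   error.
#' @return List with `partition` (data frame `peak_id`, `partition`) and
#'   `height_correlations` (data frame with the three pairwise
#'   correlations for each of `"2,3,4"`, `"4 only"` and `"all"`).
#' @export
partition_peaks <- function(peaks) {
  if (nrow(peaks) == 0L)
    stop("no peaks to partition")
  none <- !(peaks$called2 | peaks$called3 | peaks$called4)
  if (any(none))
    stop("peak with no called population: ", peaks$peak_id[none][1])
  lab <- ifelse(peaks$called2 | peaks$called3, "2,3,4", "4 only")
  hc <- function(idx) {
    if (sum(idx) < 3L) return(c(r23 = NA_real_, r24 = NA_real_, r34 = NA_real_))
    ## constant heights have no defined correlation; report NA quietly
    cc <- function(x, y) if (stats::sd(x) == 0 || stats::sd(y) == 0)
      NA_real_ else stats::cor(x, y)
    c(r23 = cc(peaks$h2[idx], peaks$h3[idx]),
      r24 = cc(peaks$h2[idx], peaks$h4[idx]),
      r34 = cc(peaks$h3[idx], peaks$h4[idx]))
  }
  cors <- rbind("2,3,4" = hc(lab == "2,3,4"),
                "4 only" = hc(lab == "4 only"),
                all = hc(rep(TRUE, nrow(peaks))))
  list(partition = data.frame(peak_id = peaks$peak_id, partition = lab,
                              stringsAsFactors = FALSE),
       height_correlations = as.data.frame(cors))
}
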