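## Association of ChIP peaks and signal with replication origins: peak
## filtering, peak-to-origin distances, the cumulative distance x intensity
## grid, an analytic placement p-value, and mark-level vs efficiency
## scaling.

#' Filter peaks by fold-enrichment
#'
#' Keeps peaks with fold-enrichment strictly greater than `min_fold`
#' (default 5, the standard enrichment-over-background cutoff). Input order
#' is preserved.
#'
#' @param peaks a `peak_set`.
#' @param min_fold strict lower bound on fold-enrichment.
#' @return the filtered `peak_set`.
#' @export
filter_peaks <- function(peaks, min_fold = 5) {
  out <- peaks[peaks$fold > min_fold, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(peaks)
  out
}

## origin 5 kb windows per chromosome, sorted: list of (start, end) matrices
.origin_windows <- function(origins, halfwidth) {
  lapply(split(origins$midpoint, origins$chrom), function(m) {
    m <- sort(m)
    cbind(start = m - halfwidth, end = m + halfwidth)
  })
}

#' Peak-to-origin distances
#'
#' Each origin is represented as a 5 kb window centered on its midpoint
#' (`origin_halfwidth` each side). A peak overlapping a window has distance
#' 0; otherwise the distance is the gap to the nearest window edge on the
#' same chromosome. Peaks on origin-free chromosomes get `NA`.
#'
#' @param peaks a `peak_set`.
#' @param origins an `origin_map`.
#' @param origin_halfwidth half-width of the origin window (default 2500).
#' @return numeric vector of distances in bp, one per peak.
#' @export
peak_origin_distances <- function(peaks, origins, origin_halfwidth = 2500) {
  wins <- .origin_windows(origins, origin_halfwidth)
  d <- rep(NA_real_, nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    w <- wins[[cn]]
    sel <- which(peaks$chrom == cn)
    if (is.null(w)) next
    ps <- peaks$start[sel]; pe <- peaks$end[sel]
    ## candidate windows: the one at/left of the peak start and the next one
    i <- findInterval(ps, w[, "start"])
    gap_to <- function(j) {
      ok <- j >= 1 & j <= nrow(w)
      g <- rep(Inf, length(j))
      jj <- which(ok)
      g[jj] <- pmax(w[j[jj], "start"] - pe[jj], ps[jj] - w[j[jj], "end"], 0)
      g
    }
    d[sel] <- pmin(gap_to(i), gap_to(i + 1L))
  }
  d
}

#' Cumulative distance x intensity association grid
#'
#' Counts, for each intensity bin and each distance threshold, the peaks
#' whose origin distance is at or below the threshold (cumulative along the
#' distance axis). Also reports, per distance threshold, the fraction of
#' origins above an efficiency cutoff that have a peak within that
#' distance.
#'
#' @param peaks a (filtered) `peak_set`.
#' @param origins an `origin_map` with efficiencies.
#' @param distance_grid distance thresholds in bp.
#' @param intensity_breaks fold-enrichment bin edges (extended to cover the
#'   observed range).
#' @param origin_halfwidth origin window half-width in bp.
#' @param efficiency_cutoff cutoff for the "efficient origins" summary
#'   (default 0.3).
#' @return list with `counts` (intensity bins x thresholds, cumulative),
#'   `distance_grid`, `intensity_breaks`, `peak_distance`,
#'   `frac_efficient_origins_with_peak`, `marginal` (peaks per intensity
#'   bin).
#' @export
association_grid <- function(peaks, origins,
                             distance_grid = c(0, 500, 1000, 2000, 5000,
                                               10000, 20000),
                             intensity_breaks = NULL,
                             origin_halfwidth = 2500,
                             efficiency_cutoff = 0.3) {
  d <- peak_origin_distances(peaks, origins, origin_halfwidth)
  if (is.null(intensity_breaks))
    intensity_breaks <- pretty(peaks$fold, n = 8)
  intensity_breaks <- unique(sort(c(intensity_breaks,
                                    min(peaks$fold, na.rm = TRUE),
                                    max(peaks$fold, na.rm = TRUE))))
  ib <- cut(peaks$fold, intensity_breaks, include.lowest = TRUE)
  counts <- vapply(distance_grid, function(th)
    as.numeric(table(ib[!is.na(d) & d <= th])), numeric(nlevels(ib)))
  counts <- matrix(counts, nrow = nlevels(ib),
                   dimnames = list(levels(ib), paste0("<=", distance_grid)))
  ## origin-side summary: efficient origins with a peak within each threshold
  od <- .origin_peak_distance(origins, peaks, origin_halfwidth)
  effsel <- !is.na(origins$efficiency) & origins$efficiency > efficiency_cutoff
  frac <- if (any(effsel))
    vapply(distance_grid, function(th)
      mean(od[effsel] <= th, na.rm = TRUE), 0)
  else rep(NA_real_, length(distance_grid))
  list(counts = counts, distance_grid = distance_grid,
       intensity_breaks = intensity_breaks, peak_distance = d,
       frac_efficient_origins_with_peak = setNames(frac,
                                                   paste0("<=", distance_grid)),
       marginal = as.numeric(table(ib)))
}

## distance from each origin window to the nearest peak
.origin_peak_distance <- function(origins, peaks, halfwidth) {
  out <- rep(NA_real_, nrow(origins))
  for (cn in unique(origins$chrom)) {
    sel <- which(origins$chrom == cn)
    pk <- peaks[peaks$chrom == cn, , drop = FALSE]
    if (!nrow(pk)) next
    pk <- pk[order(pk$start), , drop = FALSE]
    cme <- cummax(pk$end)              # rightmost end among peaks 1..i
    ws <- origins$midpoint[sel] - halfwidth
    we <- origins$midpoint[sel] + halfwidth
    i <- findInterval(we, pk$start)    # peaks starting at/left of window end
    dl <- ifelse(i >= 1L, pmax(0, ws - cme[pmax(i, 1L)]), Inf)
    dr <- ifelse(i < nrow(pk), pmax(0, pk$start[pmin(i + 1L, nrow(pk))] - we),
                 Inf)
    out[sel] <- pmin(dl, dr)
  }
  out
}

#' Analytic peak-placement p-value
#'
#' Probability that a uniformly placed interval of the peak's length, on the
#' peak's chromosome, lands at a distance to its nearest origin window less
#' than or equal to the observed distance. Origin windows are the 5 kb
#' intervals centered on midpoints. Computed exactly as the measure of
#' admissible placements divided by all placements (a simplified analytic
#' form of interval-association testing under a uniform-placement null).
#'
#' @param peak one-row `peak_set` (or list with `chrom`, `start`, `end`).
#' @param origins an `origin_map`.
#' @param chrom_length length of the peak's chromosome in bp.
#' @param origin_halfwidth origin window half-width.
#' @return p-value in `[0, 1]`.
#' @export
peak_association_pvalue <- function(peak, origins, chrom_length,
                                    origin_halfwidth = 2500) {
  L <- peak$end - peak$start
  if (L <= 0 || L > chrom_length) stopf("invalid peak length")
  w <- .origin_windows(origins, origin_halfwidth)[[peak$chrom]]
  if (is.null(w)) return(NA_real_)
  pk <- data.frame(chrom = peak$chrom, start = peak$start, end = peak$end,
                   stringsAsFactors = FALSE)
  dobs <- peak_origin_distances(pk, origins, origin_halfwidth)
  ## admissible placement starts s in [0, G-L]: gap(s) <= dobs
  ## gap <= d  <=>  s >= win_start - L - d  and  s <= win_end + d
  lo <- pmax(0, w[, "start"] - L - dobs)
  hi <- pmin(chrom_length - L, w[, "end"] + dobs)
  keep <- hi >= lo
  if (!any(keep)) return(0)
  iv <- cbind(lo[keep], hi[keep])
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (r in seq_len(nrow(iv))[-1]) {
    if (iv[r, 1] <= cur_hi) cur_hi <- max(cur_hi, iv[r, 2])
    else { tot <- tot + (cur_hi - cur_lo + 1); cur_lo <- iv[r, 1]; cur_hi <- iv[r, 2] }
  }
  tot <- tot + (cur_hi - cur_lo + 1)
  min(1, tot / (chrom_length - L + 1))
}

#' ChIP signal level versus origin efficiency
#'
#' Per origin, the mean signal over midpoint +/- `flank` is computed from a
#' bedGraph-style signal table; origins are then grouped into efficiency
#' bins (deciles by default) and the Spearman correlation over the unbinned
#' (efficiency, signal) pairs is reported (Pearson available via `method`).
#'
#' @param signal data.frame (`chrom`, `start`, `end`, `value`) as from
#'   [read_bedgraph()].
#' @param origins an `origin_map` with efficiencies.
#' @param flank half-window around the midpoint (default 2500 bp).
#' @param efficiency_bins number of equal-count efficiency bins (default 10).
#' @param method correlation method, `"spearman"` (default) or `"pearson"`.
#' @param chrom_sizes optional named lengths used to clip windows at
#'   chromosome ends (defaults to the last signal record's end).
#' @return list with `per_origin` (efficiency, mean_signal), `bin_means`
#'   (bin, mean, se, n), `correlation`, `method`.
#' @export
signal_vs_efficiency <- function(signal, origins, flank = 2500,
                                 efficiency_bins = 10,
                                 method = c("spearman", "pearson"),
                                 chrom_sizes = NULL) {
  method <- match.arg(method)
  ms <- rep(NA_real_, nrow(origins))
  for (cn in unique(origins$chrom)) {
    sg <- signal[signal$chrom == cn, , drop = FALSE]
    sel <- which(origins$chrom == cn)
    if (!nrow(sg)) next
    sg <- sg[order(sg$start), , drop = FALSE]
    clen <- if (!is.null(chrom_sizes)) chrom_sizes[[cn]] else max(sg$end)
    for (i in sel) {
      a <- max(0, origins$midpoint[i] - flank)
      b <- min(clen, origins$midpoint[i] + flank)
      j <- which(sg$end > a & sg$start < b)
      if (!length(j)) { ms[i] <- 0; next }
      ov <- pmin(sg$end[j], b) - pmax(sg$start[j], a)
      ms[i] <- sum(sg$value[j] * ov) / (b - a)
    }
  }
  ok <- !is.na(ms) & !is.na(origins$efficiency)
  eff <- origins$efficiency[ok]; sig <- ms[ok]
  qs <- quantile(eff, probs = seq(0, 1, length.out = efficiency_bins + 1))
  bins <- cut(eff, unique(qs), include.lowest = TRUE)
  bm <- data.frame(
    bin = levels(bins),
    mean = as.numeric(tapply(sig, bins, mean)),
    se = as.numeric(tapply(sig, bins, function(v) sd(v) / sqrt(length(v)))),
    n = as.numeric(table(bins)))
  r <- suppressWarnings(cor(eff, sig, method = method))
  list(per_origin = data.frame(efficiency = origins$efficiency,
                               mean_signal = ms),
       bin_means = bm, correlation = r, method = method)
}
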