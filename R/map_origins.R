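#' Map replication origins from Okazaki fragment data
#'
#' The package's main fitting function. Takes stranded fragments (or a
#' pre-binned stranded track), runs the full calling pipeline — 100 bp
#' binning, 1.5 kb rolling-median smoothing, strand-fraction normalization,
#' the 12 kb two-window transition metric, peak calling, and per-origin
#' annotation of efficiency (max normalized strand fraction within 20 kb)
#' and transition zone (distance between flanking Watson/Crick maxima
#' within 25 kb) — and returns a classed `origin_map`.
#'
#' @param x a `fragment_set` (see [read_fragments_bed()],
#'   [simulate_fragments()]) or an already-binned `stranded_track`.
#' @param chrom_sizes named vector of chromosome lengths (required for a
#'   `fragment_set`).
#' @param bin_size bin width in bp.
#' @param smooth_window rolling-median window in bp.
#' @param oem_window transition-metric flank width in bp.
#' @param threshold minimum metric value for a call.
#' @param min_separation call merge distance in bp.
#' @param efficiency_radius efficiency search radius in bp.
#' @param tz_radius transition-zone search radius in bp.
#' @param efficiency_mode `"amplitude"` (default), `"max_strand_aware"` or `"max_blind"`; see
#'   [annotate_efficiency()].
#' @return an `origin_map` data.frame with one row per origin (`chrom`,
#'   `midpoint`, `score`, `efficiency`, `watson_max_pos`, `crick_max_pos`,
#'   `transition_zone`, `tz_flagged`), with the normalized track and the
#'   parameters attached as attributes.
#' @examples
#' m <- simulate_genome_model(1, 1e6, 10, "fixed", 0.8, seed = 2)
#' fr <- simulate_fragments(m, n_cells = 200, fragments_per_cell = 400, seed = 3)
#' om <- map_origins(fr, m$chromosomes)
#' summary(om)
#' @export
map_origins <- function(x, chrom_sizes = NULL, bin_size = 100,
                        smooth_window = 1500, oem_window = 12000,
                        threshold = 0.1, min_separation = 12000,
                        efficiency_radius = 20000, tz_radius = 25000,
                        efficiency_mode = "amplitude") {
  if (inherits(x, "fragment_set")) {
    if (is.null(chrom_sizes)) stopf("`chrom_sizes` required for fragments")
    track <- bin_fragments(x, chrom_sizes, bin_size)
  } else if (inherits(x, "stranded_track")) {
    track <- x
  } else stopf("`x` must be a fragment_set or stranded_track")
  track <- smooth_track(track, smooth_window)
  track <- normalize_track(track)
  metric <- origin_transition_metric(track, oem_window)
  om <- call_origins(metric, threshold, min_separation)
  om <- annotate_efficiency(om, track, efficiency_radius,
                            mode = efficiency_mode)
  om <- annotate_transition_zone(om, track, tz_radius)
  attr(om, "track") <- track
  attr(om, "params") <- list(bin_size = bin_size,
                             smooth_window = smooth_window,
                             oem_window = oem_window, threshold = threshold,
                             min_separation = min_separation,
                             efficiency_radius = efficiency_radius,
                             tz_radius = tz_radius,
                             efficiency_mode = efficiency_mode)
  class(om) <- c("origin_map", "data.frame")
  om
}

#' @export
print.origin_map <- function(x, ...) {
  cat(sprintf("<origin_map> %d origins on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  if (nrow(x) && !is.null(x$efficiency))
    cat(sprintf("  median efficiency %.2f\n",
                median(x$efficiency, na.rm = TRUE)))
  if (nrow(x)) {
    ss <- spacing_stats(x)
    if (!is.na(ss$median_spacing))
      cat(sprintf("  median spacing %.1f kb; %.0f%% within 100 kb of a neighbor\n",
                  ss$median_spacing / 1000, 100 * ss$frac_within))
  }
  invisible(x)
}

#' @export
summary.origin_map <- function(object, ...) {
  ss <- spacing_stats(object)
  out <- list(
    n_origins = nrow(object),
    n_chromosomes = length(unique(object$chrom)),
    median_spacing_bp = ss$median_spacing,
    frac_within_100kb = ss$frac_within,
    efficiency_quartiles =
      if (!is.null(object$efficiency))
        quantile(object$efficiency, c(0.25, 0.5, 0.75), na.rm = TRUE)
      else NULL,
    median_transition_zone_bp =
      if (!is.null(object$transition_zone))
        median(object$transition_zone, na.rm = TRUE) else NULL,
    params = attr(object, "params"))
  class(out) <- "summary.origin_map"
  out
}

#' @export
print.summary.origin_map <- function(x, ...) {
  cat(sprintf("Origin map: %d origins on %d chromosome(s)\n",
              x$n_origins, x$n_chromosomes))
  if (!is.na(x$median_spacing_bp %||% NA))
    cat(sprintf("  median spacing     %.1f kb\n", x$median_spacing_bp / 1000))
  if (!is.na(x$frac_within_100kb %||% NA))
    cat(sprintf("  within 100 kb      %.1f%%\n", 100 * x$frac_within_100kb))
  if (!is.null(x$efficiency_quartiles))
    cat(sprintf("  efficiency (IQR)   %.2f [%.2f-%.2f]\n",
                x$efficiency_quartiles[2], x$efficiency_quartiles[1],
                x$efficiency_quartiles[3]))
  if (!is.null(x$median_transition_zone_bp))
    cat(sprintf("  median transition zone %.1f kb\n",
                x$median_transition_zone_bp / 1000))
  invisible(x)
}

#' Plot the replication fork directionality profile around origin calls
#'
#' Draws the normalized Watson fraction for one chromosome region with the
#' called origin midpoints marked.
#'
#' @param x an `origin_map` produced by [map_origins()] (needs the attached
#'   track).
#' @param chrom chromosome to plot (default: first).
#' @param xlim region in bp (default: whole chromosome).
#' @param ... passed to [graphics::plot()].
#' @export
plot.origin_map <- function(x, chrom = NULL, xlim = NULL, ...) {
  track <- attr(x, "track")
  if (is.null(track)) stopf("origin_map carries no track; refit with map_origins()")
  chrom <- chrom %||% names(track$fW)[1]
  fw <- track$fW[[chrom]]
  pos <- (seq_along(fw) - 0.5) * track$bin_size
  if (is.null(xlim)) xlim <- range(pos)
  plot(pos, fw, type = "l", col = "firebrick", xlim = xlim, ylim = c(0, 1),
       xlab = sprintf("%s position (bp)", chrom),
       ylab = "Watson fraction", ...)
  abline(h = 0.5, lty = 3, col = "grey50")
  mids <- x$midpoint[x$chrom == chrom]
  points(mids, rep(0.02, length(mids)), pch = 17, col = "black")
  invisible(x)
}
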