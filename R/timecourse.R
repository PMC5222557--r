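## Embryonic transcriptome coupling: per-gene normalization over the time
## course, maternal/zygotic partitioning, origin-relative abundance heatmap
## through the 50 time points, and a scalar proximal/distal coupling
## statistic.

#' Normalize an expression time course
#'
#' Each gene's row is divided by its row sum so the 50 time points sum to
#' 1. All-zero rows are labeled `unexpressed` and left untouched.
#'
#' @param tc an `expression_timecourse` (or a bare gene x time matrix).
#' @return the normalized `expression_timecourse` with a `$status` vector
#'   (`"expressed"`/`"unexpressed"`).
#' @export
normalize_timecourse <- function(tc) {
  if (is.matrix(tc))
    tc <- structure(list(expr = tc,
                         genes = data.frame(gene_id = rownames(tc) %||%
                                              as.character(seq_len(nrow(tc)))),
                         normalized = FALSE),
                    class = "expression_timecourse")
  rs <- rowSums(tc$expr)
  expressed <- rs > 0
  tc$expr[expressed, ] <- tc$expr[expressed, , drop = FALSE] / rs[expressed]
  tc$status <- ifelse(expressed, "expressed", "unexpressed")
  tc$normalized <- TRUE
  tc
}

## expression mass in the best 5-point window vs the first-5 window
.first_window_dominant <- function(profile, early_window = 5) {
  n <- length(profile)
  win <- vapply(seq_len(n - early_window + 1L), function(s)
    sum(profile[s:(s + early_window - 1L)]), 0)
  which.max(win) == 1L
}

#' Partition genes into maternal and zygotic classes
#'
#' Normalized profiles are clustered with k-means whose initial centers are
#' the mean profiles of argmax-time quantile groups — a deterministic,
#' input-order-invariant initialization; a cluster is
#' maternal when its centroid holds more expression mass in the first
#' `early_window` time points than in any other window of that length.
#' Members of maternal clusters are labeled `maternal`, all other expressed
#' genes `zygotic`, all-zero genes `unexpressed`. `rule = "argmax"` applies
#' the deterministic per-gene rule instead (maternal iff the profile's
#' argmax time point is within the early window), for reproducibility
#' audits.
#'
#' @param tc a normalized `expression_timecourse`.
#' @param k_clusters number of k-means clusters (>= 2; default 6).
#' @param early_window number of leading time points defining "maternal"
#'   (default 5).
#' @param rule `"cluster"` (default) or `"argmax"`.
#' @param seed RNG seed for k-means.
#' @return the time course with `$genes$label` filled in.
#' @export
classify_maternal <- function(tc, k_clusters = 6, early_window = 5,
                              rule = c("cluster", "argmax"), seed = 1) {
  rule <- match.arg(rule)
  if (!isTRUE(tc$normalized)) tc <- normalize_timecourse(tc)
  if (rule == "cluster" && k_clusters < 2) stopf("`k_clusters` must be >= 2")
  expressed <- tc$status == "expressed"
  lab <- rep("unexpressed", nrow(tc$expr))
  x <- tc$expr[expressed, , drop = FALSE]
  if (rule == "argmax") {
    maternal <- apply(x, 1, which.max) <= early_window
  } else {
    ## deterministic initialization: centers are mean profiles of argmax-time
    ## quantile groups, so the result does not depend on gene input order
    am <- apply(x, 1, which.max)
    qs <- unique(quantile(am, probs = seq(0, 1, length.out = k_clusters + 1)))
    grp <- if (length(qs) > 1) cut(am, qs, include.lowest = TRUE)
           else factor(rep("all", length(am)))
    centers <- do.call(rbind, lapply(levels(grp), function(g)
      colMeans(x[grp == g, , drop = FALSE])))
    centers <- unique(centers)
    if (nrow(centers) < 2L) {
      maternal <- rep(.first_window_dominant(centers[1, ], early_window),
                      nrow(x))
    } else {
      km <- with_seed(seed, kmeans(x, centers = centers, iter.max = 50))
      mat_cluster <- apply(km$centers, 1, .first_window_dominant,
                           early_window = early_window)
      maternal <- mat_cluster[km$cluster]
    }
  }
  lab[expressed] <- ifelse(maternal, "maternal", "zygotic")
  tc$genes$label <- lab
  tc
}

#' Origin-relative transcript abundance heatmap
#'
#' Origins are ranked by efficiency and the top `top_n` retained. For every
#' time point and signed-distance bin within +/- `flank` of a retained
#' origin midpoint, the normalized expression of (by default zygotic) genes
#' whose anchor falls in that bin is summed. A gene inside the flank of
#' several origins contributes to each (set `dedupe = TRUE` to count only
#' the nearest origin).
#'
#' @param tc a normalized, labeled `expression_timecourse`
#'   (see [classify_maternal()]).
#' @param origins an `origin_map` with efficiencies.
#' @param top_n origins to keep (clipped with a warning if larger than the
#'   map).
#' @param flank half-window around origin midpoints (default 25 kb).
#' @param bin signed-distance bin width in bp (default 2.5 kb).
#' @param zygotic_only drop maternal transcripts (default TRUE).
#' @param dedupe if TRUE each gene counts only toward its nearest origin.
#' @param anchor gene anchor (see [orientation_bias()]).
#' @return a `coupling_heatmap`: list with `matrix` (time points x distance
#'   bins), `bin_mid`, `top_n`, `flank`.
#' @export
coupling_heatmap <- function(tc, origins, top_n = 1000, flank = 25000,
                             bin = 2500, zygotic_only = TRUE,
                             dedupe = FALSE, anchor = "midpoint") {
  if (!isTRUE(tc$normalized)) stopf("time course must be normalized first")
  if (is.null(tc$genes$label) && zygotic_only)
    stopf("genes are unlabeled; run classify_maternal()")
  if (top_n > nrow(origins)) {
    warning(sprintf("top_n = %d exceeds %d available origins; clipped",
                    top_n, nrow(origins)))
    top_n <- nrow(origins)
  }
  keep_o <- order(-origins$efficiency)[seq_len(top_n)]
  om <- origins[keep_o, , drop = FALSE]
  g <- tc$genes
  use <- tc$status == "expressed"
  if (zygotic_only) use <- use & g$label == "zygotic"
  edges <- seq(-flank, flank, by = bin)
  nb <- length(edges) - 1L
  ntp <- ncol(tc$expr)
  hm <- matrix(0, nrow = ntp, ncol = nb,
               dimnames = list(colnames(tc$expr),
                               paste0("d", (edges[-length(edges)] + edges[-1]) / 2)))
  pos <- .gene_anchor(g, anchor)
  for (cn in unique(om$chrom)) {
    op <- sort(om$midpoint[om$chrom == cn])
    gi <- which(use & g$chrom == cn)
    if (!length(gi) || !length(op)) next
    for (i in gi) {
      d_all <- pos[i] - op
      hit <- which(abs(d_all) <= flank)
      if (!length(hit)) next
      if (dedupe) hit <- hit[which.min(abs(d_all[hit]))]
      for (h in hit) {
        b <- findInterval(d_all[h], edges, rightmost.closed = TRUE)
        b <- min(max(b, 1L), nb)
        hm[, b] <- hm[, b] + tc$expr[i, ]
      }
    }
  }
  structure(list(matrix = hm,
                 bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
                 top_n = top_n, flank = flank, bin = bin,
                 zygotic_only = zygotic_only),
            class = "coupling_heatmap")
}

#' @export
print.coupling_heatmap <- function(x, ...) {
  cat(sprintf("<coupling_heatmap> %d time points x %d distance bins (top %d origins, +/-%g kb)\n",
              nrow(x$matrix), ncol(x$matrix), x$top_n, x$flank / 1000))
  invisible(x)
}

#' Proximal/distal coupling statistic per time point
#'
#' For each time point, `log2((mean proximal abundance + pc) /
#' (mean distal abundance + pc))` where proximal bins lie within
#' `proximal` bp of the origin midpoint and distal bins between
#' `distal[1]` and `distal[2]` bp away (either side). The pseudo-count
#' `pc` guards empty bins and defaults to 1e-6 of the heatmap's total
#' mass (or 1e-12 if the heatmap is empty). A uniform heatmap gives 0
#' everywhere; positive values mean transcription concentrates at
#' origins.
#'
#' @param hm a `coupling_heatmap`.
#' @param proximal half-width of the proximal zone in bp (default 5000).
#' @param distal c(lo, hi) unsigned distance range of the distal zone
#'   (default 15-25 kb).
#' @param pseudo_count optional override of `pc`.
#' @return numeric vector, one value per time point.
#' @export
coupling_statistic <- function(hm, proximal = 5000, distal = c(15000, 25000),
                               pseudo_count = NULL) {
  stopifnot(inherits(hm, "coupling_heatmap"))
  pc <- pseudo_count %||% max(1e-12, 1e-6 * sum(hm$matrix))
  prox <- abs(hm$bin_mid) <= proximal
  dist <- abs(hm$bin_mid) >= distal[1] & abs(hm$bin_mid) <= distal[2]
  if (!any(prox) || !any(dist)) stopf("zones select no bins; widen them")
  log2((rowMeans(hm$matrix[, prox, drop = FALSE]) + pc) /
         (rowMeans(hm$matrix[, dist, drop = FALSE]) + pc))
}
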