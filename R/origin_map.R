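## Origin calling from a stranded track: median smoothing, strand-fraction
## normalization, the two-window transition (OEM-style) metric, peak
## calling, and per-origin annotation (efficiency, transition zone).

## Centered rolling median with truncated windows at the edges; `mask`ed
## bins are excluded as contributors. Fast path uses runmed and patches the
## edge bins and any bin whose window touches a masked bin.
rolling_median_masked <- function(x, halfwin, mask = NULL) {
  n <- length(x)
  brute <- function(i) {
    j <- max(1L, i - halfwin):min(n, i + halfwin)
    if (!is.null(mask)) j <- j[!mask[j]]
    if (!length(j)) return(NA_real_)
    median(x[j])
  }
  k <- 2L * halfwin + 1L
  if (k >= n) return(vapply(seq_len(n), brute, 0))
  out <- as.numeric(runmed(x, k, endrule = "keep"))
  redo <- c(seq_len(halfwin), seq(n - halfwin + 1L, n))
  if (!is.null(mask) && any(mask)) {
    near <- unique(unlist(lapply(which(mask), function(i)
      max(1L, i - halfwin):min(n, i + halfwin))))
    redo <- unique(c(redo, near))
  }
  out[redo] <- vapply(redo, brute, 0)
  out
}

#' Median-smooth a stranded track
#'
#' Each strand's bin counts are replaced by a centered rolling median over
#' `window` bp (default 1.5 kb). The window is coerced up to an odd multiple
#' of the bin size if needed (with a message); edge bins use the truncated
#' window, and zero-coverage (masked) bins do not contribute to their
#' neighbors' medians.
#'
#' @param track a `stranded_track` from [bin_fragments()].
#' @param window smoothing window in bp (>= bin size).
#' @return the smoothed `stranded_track`.
#' @export
smooth_track <- function(track, window = 1500) {
  stopifnot(inherits(track, "stranded_track"))
  if (window < track$bin_size) stopf("`window` must be >= bin size")
  k <- round(window / track$bin_size)
  if (k %% 2L == 0L) {
    k <- k + 1L
    message(sprintf("smoothing window coerced up to %d bp (odd multiple of bin size)",
                    k * track$bin_size))
  }
  h <- (k - 1L) %/% 2L
  track$rawW <- track$W
  track$rawC <- track$C
  for (cn in names(track$W)) {
    mask <- track_mask(track, cn)
    w <- rolling_median_masked(as.numeric(track$W[[cn]]), h, mask)
    c_ <- rolling_median_masked(as.numeric(track$C[[cn]]), h, mask)
    track$W[[cn]] <- w
    track$C[[cn]] <- c_
  }
  track$smoothed <- TRUE
  track
}

#' Normalize a stranded track to per-bin strand fractions
#'
#' Per bin, `fW = W / (W + C)` and `fC = C / (W + C)`. Bins with zero total
#' coverage are masked (NA), not treated as `fW = 0`, to avoid fake strand
#' signal in gaps.
#'
#' @param track a (typically smoothed) `stranded_track`.
#' @return the track with `$fW`/`$fC` filled in.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "stranded_track"))
  track$fW <- lapply(names(track$W), function(cn) {
    tot <- track$W[[cn]] + track$C[[cn]]
    ifelse(tot > 0, track$W[[cn]] / tot, NA_real_)
  })
  names(track$fW) <- names(track$W)
  track$fC <- lapply(names(track$fW), function(cn)
    ifelse(is.na(track$fW[[cn]]), NA_real_, 1 - track$fW[[cn]]))
  names(track$fC) <- names(track$W)
  track
}

#' Origin transition metric (OEM-style)
#'
#' For each bin b, `M(b) = F_W(left) - F_W(right)` where `F_W` is the
#' aggregate Watson fraction `sum(W) / (sum(W) + sum(C))` of the smoothed
#' counts over the `window` bp immediately left (respectively right) of b
#' (the bin itself excluded). M peaks at Watson-to-Crick transitions, i.e.
#' replication origins, and lies in `[-1, 1]`. Bins where either flanking
#' window is empty or has zero total counts are NA; windows are truncated
#' at chromosome ends.
#'
#' @param track a normalized `stranded_track` (smoothed counts present).
#' @param window flank width in bp (default 12 kb).
#' @return an `oem_metric`: per-chromosome numeric vectors plus bin size.
#' @export
origin_transition_metric <- function(track, window = 12000) {
  stopifnot(inherits(track, "stranded_track"))
  k <- round(window / track$bin_size)
  if (k < 2L) stopf("`window` must span at least 2 bins")
  M <- lapply(names(track$W), function(cn) {
    w <- as.numeric(track$W[[cn]]); c_ <- as.numeric(track$C[[cn]])
    n <- length(w)
    csW <- c(0, cumsum(w)); csC <- c(0, cumsum(c_))
    b <- seq_len(n)
    la <- pmax(1L, b - k); lb <- b - 1L          # left window bins
    ra <- b + 1L; rb <- pmin(n, b + k)           # right window bins
    sumW_l <- csW[lb + 1L] - csW[la]; sumC_l <- csC[lb + 1L] - csC[la]
    sumW_r <- csW[rb + 1L] - csW[ra]; sumC_r <- csC[rb + 1L] - csC[ra]
    lt <- sumW_l + sumC_l; rt <- sumW_r + sumC_r
    out <- ifelse(lb >= la & rb >= ra & lt > 0 & rt > 0,
                  sumW_l / pmax(lt, 1e-300) - sumW_r / pmax(rt, 1e-300),
                  NA_real_)
    out[lb < la | rb < ra] <- NA_real_
    out
  })
  structure(list(M = setNames(M, names(track$W)), bin_size = track$bin_size,
                 chrom_sizes = track$chrom_sizes, window = window),
            class = "oem_metric")
}

## leftmost indices of strict local maxima (plateaus count once, at their
## leftmost bin); NA treated as -Inf
.local_maxima <- function(m) {
  v <- ifelse(is.na(m), -Inf, m)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  prev <- c(-Inf, r$values[-length(r$values)])
  nxt <- c(r$values[-1L], -Inf)
  starts[r$values > prev & r$values > nxt & is.finite(r$values)]
}

#' Call origins from the transition metric
#'
#' Origins are local maxima of M above `threshold`. Maxima closer than
#' `min_separation` are merged keeping the larger (score ties keep the
#' leftmost); the call midpoint is the bin center of the surviving maximum.
#' Deterministic.
#'
#' @param metric an `oem_metric`.
#' @param threshold minimum M value for a call.
#' @param min_separation merge distance in bp.
#' @return an `origin_map` data.frame (`chrom`, `midpoint`, `score`).
#' @export
call_origins <- function(metric, threshold = 0.1, min_separation = 12000) {
  stopifnot(inherits(metric, "oem_metric"))
  calls <- lapply(names(metric$M), function(cn) {
    m <- metric$M[[cn]]
    idx <- .local_maxima(m)
    idx <- idx[m[idx] > threshold]
    if (!length(idx))
      return(data.frame(chrom = character(), midpoint = numeric(),
                        score = numeric()))
    pos <- (idx - 1) * metric$bin_size + metric$bin_size / 2
    sc <- m[idx]
    ## greedy merge: best score first, leftmost on ties
    o <- order(-sc, pos)
    keep_pos <- numeric(0); keep_sc <- numeric(0)
    for (i in o) {
      if (all(abs(keep_pos - pos[i]) >= min_separation)) {
        keep_pos <- c(keep_pos, pos[i]); keep_sc <- c(keep_sc, sc[i])
      }
    }
    o2 <- order(keep_pos)
    data.frame(chrom = cn, midpoint = keep_pos[o2], score = keep_sc[o2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  structure(out, class = c("origin_map", "data.frame"),
            params = list(threshold = threshold,
                          min_separation = min_separation,
                          oem_window = metric$window,
                          bin_size = metric$bin_size),
            chrom_sizes = metric$chrom_sizes)
}

## Aggregate Watson fraction per bin: running sums of the (raw, pre-
## smoothing) counts over +/- h bins. Counter-acts the 0/1 saturation of
## single sparse bins when locating and measuring strand-fraction maxima.
.agg_fw <- function(track, cn, h) {
  w <- as.numeric((track$rawW %||% track$W)[[cn]])
  c_ <- as.numeric((track$rawC %||% track$C)[[cn]])
  n <- length(w)
  csW <- c(0, cumsum(w)); csC <- c(0, cumsum(c_))
  b <- seq_len(n); a <- pmax(1L, b - h); z <- pmin(n, b + h)
  sw <- csW[z + 1L] - csW[a]; sc <- csC[z + 1L] - csC[a]
  ifelse(sw + sc > 0, sw / (sw + sc), NA_real_)
}

## max and argmax of v over bin range a..b, ties broken toward `toward`
## (bin index); returns c(max, argmax_bin) or NA if all-NA
.window_max <- function(v, a, b, toward) {
  a <- max(1L, a); b <- min(length(v), b)
  if (a > b) return(c(NA_real_, NA_real_))
  vv <- v[a:b]
  if (all(is.na(vv))) return(c(NA_real_, NA_real_))
  mx <- max(vv, na.rm = TRUE)
  cand <- a:b
  cand <- cand[!is.na(vv) & vv == mx]
  c(mx, cand[which.min(abs(cand - toward))])
}

#' Annotate origin efficiency
#'
#' Origin efficiency is reported on the normalized-reads scale (0-1; a
#' strand-balanced track gives exactly 0.5). Three estimators are
#' available:
#'
#' * `"amplitude"` (default): half the Watson-to-Crick transition
#'   amplitude at the origin, shifted onto the 0-1 scale —
#'   `(F_W(left flank) + F_C(right flank)) / 2`, where `F` are aggregate
#'   strand fractions of the raw binned counts over `amplitude_window` bp
#'   immediately left/right of the midpoint. The expectation of this
#'   quantity is the probability the origin fires in a cycle (conditional
#'   on its chromosome replicating), and it is robust to closely spaced
#'   neighboring origins.
#' * `"max_strand_aware"`: maximum normalized strand fraction within
#'   `radius` of the midpoint, searching `fW` left of the midpoint and
#'   `fC` right of it. This is the classical definition; with origins
#'   spaced comparably to `radius` the window max reflects the strongest
#'   origin in the neighborhood rather than the annotated one, and with
#'   sparse counts it saturates at 1.
#' * `"max_blind"`: maximum of both fractions over the whole +/- radius
#'   window.
#'
#' All modes also record `watson_max_pos` / `crick_max_pos`, the argmax
#' positions of the aggregate strand fractions in the strand-appropriate
#' windows (ties resolved toward the midpoint).
#'
#' @param origins an `origin_map`.
#' @param track a normalized `stranded_track`.
#' @param radius search radius in bp for the max modes and the argmaxes.
#' @param mode `"amplitude"` (default), `"max_strand_aware"` or
#'   `"max_blind"`.
#' @param amplitude_window flank width in bp for the amplitude estimator.
#' @param agg_window half-window (bp) of the count aggregation used for
#'   the max modes and argmaxes; defaults to 750 (a 1.5 kb window).
#' @return the `origin_map` with `efficiency`, `watson_max_pos`,
#'   `crick_max_pos` columns.
#' @export
annotate_efficiency <- function(origins, track, radius = 20000,
                                mode = c("amplitude", "max_strand_aware",
                                         "max_blind"),
                                amplitude_window = 4000, agg_window = 750) {
  mode <- match.arg(mode)
  if (is.null(track$fW)) stopf("track is not normalized; call normalize_track()")
  bs <- track$bin_size
  h <- max(1L, round(agg_window / bs))
  eff <- wpos <- cpos <- numeric(nrow(origins))
  fa <- lapply(names(track$W), function(cn) .agg_fw(track, cn, h))
  names(fa) <- names(track$W)
  for (i in seq_len(nrow(origins))) {
    cn <- origins$chrom[i]
    if (!cn %in% names(track$fW)) stopf("origin on unknown chromosome %s", cn)
    mid <- origins$midpoint[i]
    if (mid < 0 || mid > track$chrom_sizes[[cn]])
      stopf("origin midpoint %g outside chromosome %s", mid, cn)
    bmid <- floor(mid / bs) + 1L
    r <- round(radius / bs)
    fw <- fa[[cn]]
    wm <- .window_max(fw, bmid - r, bmid, toward = bmid)
    cm <- .window_max(1 - fw, bmid, bmid + r, toward = bmid)
    wpos[i] <- if (is.na(wm[2])) NA_real_ else (wm[2] - 1) * bs + bs / 2
    cpos[i] <- if (is.na(cm[2])) NA_real_ else (cm[2] - 1) * bs + bs / 2
    eff[i] <- switch(mode,
      amplitude = {
        ka <- max(1L, round(amplitude_window / bs))
        w <- as.numeric((track$rawW %||% track$W)[[cn]])
        c_ <- as.numeric((track$rawC %||% track$C)[[cn]])
        n <- length(w)
        li <- max(1L, bmid - ka):max(1L, bmid - 1L)
        ri <- min(n, bmid + 1L):min(n, bmid + ka)
        lw <- sum(w[li]); lc <- sum(c_[li])
        rw <- sum(w[ri]); rc <- sum(c_[ri])
        if (lw + lc == 0 || rw + rc == 0) NA_real_
        else (lw / (lw + lc) + rc / (rw + rc)) / 2
      },
      max_strand_aware = {
        vals <- c(wm[1], cm[1])
        if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
      },
      max_blind = {
        wb <- .window_max(fw, bmid - r, bmid + r, toward = bmid)
        cb <- .window_max(1 - fw, bmid - r, bmid + r, toward = bmid)
        vals <- c(wb[1], cb[1])
        if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
      })
  }
  origins$efficiency <- eff
  origins$watson_max_pos <- wpos
  origins$crick_max_pos <- cpos
  origins
}

#' Annotate transition-zone width
#'
#' The transition zone (initiation-zone width) is the distance between the
#' normalized Watson maximum left of the midpoint and the normalized Crick
#' maximum right of it, each searched within `search_radius` (default
#' 25 kb). Maxima are located on the aggregate strand fractions (raw
#' counts summed over `agg_window` around each bin) so that single sparse
#' bins do not pin the argmax; ties are resolved toward the midpoint, so a
#' point-source origin yields a near-zero zone. Negative values (possible
#' in noise) are kept but flagged in the `tz_flagged` column.
#'
#' @param origins an `origin_map`.
#' @param track a normalized `stranded_track`.
#' @param search_radius search radius in bp.
#' @param agg_window aggregation half-window in bp (default 750).
#' @return the `origin_map` with `transition_zone` and `tz_flagged` columns.
#' @export
annotate_transition_zone <- function(origins, track, search_radius = 25000,
                                     agg_window = 750) {
  if (is.null(track$fW)) stopf("track is not normalized; call normalize_track()")
  bs <- track$bin_size
  h <- max(1L, round(agg_window / bs))
  fa <- lapply(names(track$W), function(cn) .agg_fw(track, cn, h))
  names(fa) <- names(track$W)
  tz <- numeric(nrow(origins))
  wpos <- cpos <- numeric(nrow(origins))
  for (i in seq_len(nrow(origins))) {
    cn <- origins$chrom[i]
    bmid <- floor(origins$midpoint[i] / bs) + 1L
    r <- round(search_radius / bs)
    wm <- .window_max(fa[[cn]], bmid - r, bmid, toward = bmid)
    cm <- .window_max(1 - fa[[cn]], bmid, bmid + r, toward = bmid)
    wpos[i] <- if (is.na(wm[2])) NA_real_ else (wm[2] - 1) * bs + bs / 2
    cpos[i] <- if (is.na(cm[2])) NA_real_ else (cm[2] - 1) * bs + bs / 2
    tz[i] <- cpos[i] - wpos[i]
  }
  origins$transition_zone <- tz
  origins$tz_flagged <- !is.na(tz) & tz < 0
  ## keep the efficiency-window argmaxes if already present, else record these
  if (is.null(origins$watson_max_pos)) {
    origins$watson_max_pos <- wpos
    origins$crick_max_pos <- cpos
  }
  origins
}

#' Inter-origin spacing statistics
#'
#' Spacings are consecutive midpoint differences within chromosomes. An
#' origin is "within 100 kb of another origin" when its nearest-neighbor
#' distance is <= 100 kb.
#'
#' @param origins an `origin_map` (sorted per chromosome).
#' @param within_bp neighborhood threshold (default 100 kb).
#' @return list with `median_spacing`, `frac_within`, `spacings`,
#'   `nn_distance`. With fewer than 2 origins on every chromosome the
#'   sample is empty and the statistics are NA.
#' @export
spacing_stats <- function(origins, within_bp = 1e5) {
  spac <- numeric(0); nn <- numeric(0)
  for (cn in unique(origins$chrom)) {
    p <- sort(origins$midpoint[origins$chrom == cn])
    if (length(p) < 2L) { nn <- c(nn, NA_real_); next }
    d <- diff(p)
    spac <- c(spac, d)
    nn <- c(nn, pmin(c(Inf, d), c(d, Inf)))
  }
  if (length(spac) == 0L)
    return(list(median_spacing = NA_real_, frac_within = NA_real_,
                spacings = numeric(0), nn_distance = nn))
  list(median_spacing = median(spac),
       frac_within = mean(nn[!is.na(nn)] <= within_bp),
       spacings = spac, nn_distance = nn)
}

#' Compare two origin maps
#'
#' Origins are paired when their 5 kb windows (midpoint +/- `window`/2)
#' overlap, i.e. midpoints within `window` bp; pairing is greedy
#' nearest-first with each origin used once. Returns the Spearman
#' correlation of the paired efficiencies and the percentage of `a`'s
#' origins that found a partner.
#'
#' @param a,b `origin_map`s carrying efficiencies.
#' @param window pairing window in bp (default 5000 = overlapping 5 kb
#'   origin windows).
#' @return list with `spearman_r`, `percent_overlap`, `n_paired`, `pairs`.
#' @export
compare_origin_maps <- function(a, b, window = 5000) {
  pairs <- list()
  for (cn in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == cn); ib <- which(b$chrom == cn)
    if (!length(ia) || !length(ib)) next
    d <- abs(outer(a$midpoint[ia], b$midpoint[ib], "-"))
    cand <- which(d < window, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(d[cand]), , drop = FALSE]
    useda <- logical(length(ia)); usedb <- logical(length(ib))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!useda[i] && !usedb[j]) {
        useda[i] <- usedb[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(ia[i], ib[j])
      }
    }
  }
  if (!length(pairs))
    return(list(spearman_r = NA_real_, percent_overlap = 0, n_paired = 0L,
                pairs = data.frame(a = integer(), b = integer())))
  pm <- do.call(rbind, pairs)
  r <- suppressWarnings(cor(a$efficiency[pm[, 1]], b$efficiency[pm[, 2]],
                            method = "spearman"))
  list(spearman_r = r, percent_overlap = 100 * nrow(pm) / nrow(a),
       n_paired = nrow(pm), pairs = data.frame(a = pm[, 1], b = pm[, 2]))
}

#' Origin-centered stranded signal heatmap
#'
#' For each origin, the smoothed Watson and Crick counts over midpoint +/-
#' `flank` are extracted; each origin-strand row is mean-centered and scaled
#' to unit sum of squares (all-constant rows become zero vectors and are
#' flagged). Rows are ordered by ascending transition zone; origins with a
#' flagged (negative) transition zone or whose window exceeds the
#' chromosome are excluded.
#'
#' @param origins an `origin_map` with `transition_zone`.
#' @param track a smoothed `stranded_track`.
#' @param flank half-window in bp (default 25 kb).
#' @return list with matrices `watson`, `crick` (origins x positions),
#'   `order` (row indices into `origins`), `zero_rows`.
#' @export
origin_strand_heatmap <- function(origins, track, flank = 25000) {
  if (is.null(origins$transition_zone))
    stopf("origins need a transition_zone; run annotate_transition_zone()")
  bs <- track$bin_size
  r <- round(flank / bs)
  flagged <- origins$tz_flagged %||% rep(FALSE, nrow(origins))
  ok <- !flagged & !is.na(origins$transition_zone)
  bmid <- floor(origins$midpoint / bs) + 1L
  nb <- vapply(origins$chrom, function(cn) length(track$W[[cn]]), 1L)
  ok <- ok & (bmid - r >= 1L) & (bmid + r <= nb)
  idx <- which(ok)
  idx <- idx[order(origins$transition_zone[idx])]
  unitize <- function(x) {
    x <- x - mean(x)
    ss <- sqrt(sum(x^2))
    if (ss == 0) x else x / ss
  }
  get_rows <- function(sig) {
    t(vapply(idx, function(i) {
      b <- bmid[i]
      unitize(as.numeric(sig[[origins$chrom[i]]][(b - r):(b + r)]))
    }, numeric(2L * r + 1L)))
  }
  watson <- get_rows(track$W); crick <- get_rows(track$C)
  zero <- rowSums(watson^2) == 0 | rowSums(crick^2) == 0
  list(watson = watson, crick = crick, order = idx, zero_rows = zero)
}

#' Genome duplication time from origin spacing and fork speed
#'
#' Two forks converge on each inter-origin interval, so
#' `t = spacing / (2 * fork_speed)`. With origins every 75 kb and forks at
#' 2.5 kb/min, duplication completes in 15 minutes.
#'
#' @param origin_spacing inter-origin spacing in kb (>= 0).
#' @param fork_speed fork speed in kb/min (> 0).
#' @return time in minutes.
#' @examples
#' replication_time(75, 2.5)  # 15
#' @export
replication_time <- function(origin_spacing, fork_speed) {
  if (any(origin_spacing < 0)) stopf("`origin_spacing` must be >= 0")
  if (any(fork_speed <= 0)) stopf("`fork_speed` must be > 0")
  origin_spacing / (2 * fork_speed)
}
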