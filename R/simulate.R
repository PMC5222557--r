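## Stochastic replication simulator: per-cell origin firing, bidirectional
## forks at uniform speed, lagging-strand fragment emission.

## Draw one firing vector for a chromosome, rejection-resampling until at
## least one origin fires (every chromosome is replicated every cycle).
## The rejection conditions probabilities upward; expected_watson_fraction()
## reproduces exactly this conditioning.
.draw_firing <- function(e) {
  repeat {
    fired <- runif(length(e)) < e
    if (any(fired)) return(fired)
  }
}

#' Simulate origin firing in a single cell
#'
#' Each origin fires independently with its firing probability; chromosomes
#' where no origin fired are redrawn until at least one fires. Fork
#' direction at any position follows from the nearest fired origin: a
#' position left of its nearest fired origin is replicated by the leftward
#' fork (Watson-strand Okazaki fragments), a position right of it by the
#' rightward fork (Crick-strand fragments).
#'
#' @param model a [genome_model()].
#' @param seed RNG seed.
#' @param position_jitter_sd per-cell Gaussian displacement (bp) of each
#'   fired origin's position, emulating broad initiation zones; 0 gives
#'   point-source origins.
#' @return a `cell_replication` object: `$fired` is a named list of sorted
#'   fired-origin positions per chromosome, `$fired_index` the logical
#'   firing vector aligned with `model$origins`.
#' @export
simulate_cell <- function(model, seed = 1, position_jitter_sd = 0) {
  stopifnot(inherits(model, "genome_model"))
  check_positive(position_jitter_sd, "position_jitter_sd", allow_zero = TRUE)
  with_seed(seed, .simulate_cell_impl(model, position_jitter_sd))
}

.simulate_cell_impl <- function(model, position_jitter_sd = 0) {
  fired_idx <- logical(nrow(model$origins))
  fired <- lapply(names(model$chromosomes), function(cn) {
    sel <- model$origins$chrom == cn
    f <- .draw_firing(model$origins$efficiency[sel])
    fired_idx[which(sel)[f]] <<- TRUE
    pos <- model$origins$pos[sel][f]
    if (position_jitter_sd > 0) {
      pos <- sort(pos + round(rnorm(length(pos), 0, position_jitter_sd)))
      pos <- pmin(pmax(pos, 0), model$chromosomes[[cn]] - 1)
    }
    pos
  })
  structure(list(fired = setNames(fired, names(model$chromosomes)),
                 fired_index = fired_idx),
            class = "cell_replication")
}

#' Fork direction at positions given fired origins
#'
#' Direction is `"R"` (rightward fork, Crick fragments) where the nearest
#' fired origin is strictly left, `"L"` (leftward fork, Watson fragments)
#' where it is strictly right. Exact ties are broken uniformly at random
#' per position, matching the half-weight a tie receives in
#' [expected_watson_fraction()].
#'
#' @param fired sorted vector of fired origin positions on one chromosome.
#' @param pos positions to query.
#' @return character vector of `"L"`/`"R"`.
#' @export
fork_direction <- function(fired, pos) {
  if (length(fired) == 0L) stopf("no fired origin on chromosome")
  i <- findInterval(pos, fired)                       # index of origin <= pos
  dl <- ifelse(i >= 1L, pos - fired[pmax(i, 1L)], Inf)
  dr <- ifelse(i < length(fired), fired[pmin(i + 1L, length(fired))] - pos, Inf)
  dir <- ifelse(dl < dr, "R", "L")
  tie <- which(dl == dr & is.finite(dl))
  if (length(tie)) dir[tie] <- ifelse(runif(length(tie)) < 0.5, "L", "R")
  dir
}

.draw_lengths <- function(n, fl) {
  k <- sample.int(3L, n, replace = TRUE, prob = fl$weights)
  len <- round(k * fl$period + rnorm(n, 0, fl$jitter_sd))
  pmin(pmax(len, fl$min), fl$max)
}

#' Simulate a population of Okazaki fragments
#'
#' For each cell an origin-firing configuration is drawn, then
#' `fragments_per_cell` lagging-strand fragments are emitted: the 5' anchor
#' of each fragment is uniform over the genome, the length follows the
#' nucleosome-periodic mixture, and the strand is Watson where the local
#' fork moves leftward, Crick where it moves rightward. Fragments are
#' truncated at chromosome ends (and dropped if truncation leaves < 30 bp);
#' truncation and drop counts are recorded in attributes `n_truncated` and
#' `n_dropped`.
#'
#' @inheritParams simulate_cell
#' @param n_cells number of cells.
#' @param fragments_per_cell fragments emitted per cell.
#' @return a `fragment_set`: data.frame (`chrom`, `start`, `end`, `strand`)
#'   in 0-based half-open coordinates, strand `"+"` = Watson, `"-"` = Crick.
#' @export
simulate_fragments <- function(model, n_cells = 2000, fragments_per_cell = 500,
                               seed = 1, position_jitter_sd = 0) {
  stopifnot(inherits(model, "genome_model"))
  check_positive(n_cells, "n_cells")
  check_positive(fragments_per_cell, "fragments_per_cell")
  chroms <- model$chromosomes
  pchrom <- chroms / sum(chroms)
  with_seed(seed, {
    out <- vector("list", n_cells)
    for (cell in seq_len(n_cells)) {
      cr <- .simulate_cell_impl(model, position_jitter_sd)
      ci <- sample.int(length(chroms), fragments_per_cell,
                       replace = TRUE, prob = pchrom)
      anchor <- floor(runif(fragments_per_cell) * chroms[ci])
      len <- .draw_lengths(fragments_per_cell, model$fragment_length)
      dir <- character(fragments_per_cell)
      for (k in seq_along(chroms)) {
        sel <- ci == k
        if (any(sel)) dir[sel] <- fork_direction(cr$fired[[k]], anchor[sel])
      }
      ## Watson fragment: 5' end at anchor, extends right.
      ## Crick fragment: 5' end at anchor (template 3'->5' leftwards), extends left.
      watson <- dir == "L"
      start <- ifelse(watson, anchor, anchor + 1 - len)
      end <- ifelse(watson, anchor + len, anchor + 1)
      out[[cell]] <- data.frame(chrom = names(chroms)[ci], start = start,
                                end = end, strand = ifelse(watson, "+", "-"),
                                stringsAsFactors = FALSE)
    }
    fr <- do.call(rbind, out)
    clen <- chroms[fr$chrom]
    s <- pmax(fr$start, 0); e <- pmin(fr$end, clen)
    n_trunc <- sum(s != fr$start | e != fr$end)
    keep <- (e - s) >= 30
    fr <- data.frame(chrom = fr$chrom[keep], start = s[keep], end = e[keep],
                     strand = fr$strand[keep], stringsAsFactors = FALSE)
    rownames(fr) <- NULL
    structure(fr, class = c("fragment_set", "data.frame"),
              n_truncated = n_trunc, n_dropped = sum(!keep),
              n_emitted = n_cells * fragments_per_cell)
  })
}

#' Expected Watson-strand fraction at a position
#'
#' Closed-form strand-bias oracle: enumerates every origin-firing
#' combination on the position's chromosome (renormalized to exclude the
#' all-unfired event, mirroring the simulator's rejection rule) and sums the
#' probability that the nearest fired origin lies strictly right of the
#' position; an exact distance tie contributes 1/2.
#'
#' @param model a [genome_model()].
#' @param chrom chromosome name.
#' @param position positions in bp (vectorized).
#' @return expected Watson fraction in `[0,1]` per position.
#' @export
expected_watson_fraction <- function(model, chrom, position) {
  stopifnot(inherits(model, "genome_model"))
  sel <- model$origins$chrom == chrom
  pos <- model$origins$pos[sel]
  e <- model$origins$efficiency[sel]
  n <- length(pos)
  if (n == 0L) stopf("unknown chromosome %s", chrom)
  if (n > 20L) stopf("enumeration limit: %d origins on %s (max 20)", n, chrom)
  total <- numeric(length(position))
  norm <- 0
  for (m in seq_len(2^n - 1L)) {
    fired <- as.logical(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)))
    w <- prod(ifelse(fired, e, 1 - e))
    if (w == 0) next
    norm <- norm + w
    fp <- pos[fired]
    i <- findInterval(position, fp)
    dl <- ifelse(i >= 1L, position - fp[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(fp), fp[pmin(i + 1L, length(fp))] - position, Inf)
    total <- total + w * (as.numeric(dr < dl) + 0.5 * (dr == dl))
  }
  total / norm
}

#' Simulate enhancer-mark ChIP peaks around origins
#'
#' One peak per origin with fold-enrichment
#' `baseline + intensity_slope * firing_probability + N(0, noise_sd)`
#' (floored at 1) and a jittered center, plus uniformly placed low-intensity
#' background peaks. Emulates enhancer marks whose level scales with origin
#' efficiency.
#'
#' @inheritParams simulate_cell
#' @param intensity_slope fold-enrichment gained per unit firing probability.
#' @param background_peak_rate background peaks per Mb (Poisson).
#' @param noise_sd Gaussian noise on fold-enrichment.
#' @param baseline fold-enrichment at firing probability 0.
#' @param center_jitter_sd sd (bp) of the peak-center offset from the origin.
#' @param peak_width peak interval width in bp.
#' @return a `peak_set` data.frame (`chrom`, `start`, `end`, `name`, `fold`,
#'   `summit`); attribute `origin_index` maps each peak to its source origin
#'   row in `model$origins` (NA for background peaks).
#' @export
simulate_chip_peaks <- function(model, intensity_slope = 9,
                                background_peak_rate = 5, noise_sd = 0.5,
                                baseline = 1.5, center_jitter_sd = 500,
                                peak_width = 800, seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  for (nm in c("background_peak_rate", "noise_sd", "center_jitter_sd"))
    check_positive(get(nm), nm, allow_zero = TRUE)
  check_positive(peak_width, "peak_width")
  with_seed(seed, {
    org <- model$origins
    center <- org$pos + round(rnorm(nrow(org), 0, center_jitter_sd))
    fold <- pmax(1, baseline + intensity_slope * org$efficiency +
                   rnorm(nrow(org), 0, noise_sd))
    n_bg <- rpois(length(model$chromosomes),
                  background_peak_rate * model$chromosomes / 1e6)
    bg <- data.frame(
      chrom = rep(names(model$chromosomes), n_bg),
      center = floor(runif(sum(n_bg)) *
                       rep(model$chromosomes, n_bg)),
      fold = runif(sum(n_bg), 1, 4), stringsAsFactors = FALSE)
    pk <- data.frame(
      chrom = c(org$chrom, bg$chrom),
      center = c(center, bg$center),
      fold = c(fold, bg$fold),
      origin_index = c(seq_len(nrow(org)), rep(NA_integer_, nrow(bg))),
      stringsAsFactors = FALSE)
    h <- floor(peak_width / 2)
    pk$start <- pmax(0L, pk$center - h)
    pk$end <- pmin(model$chromosomes[pk$chrom], pk$center + h)
    o <- order(match(pk$chrom, names(model$chromosomes)), pk$start)
    pk <- pk[o, , drop = FALSE]
    out <- data.frame(chrom = pk$chrom, start = pk$start, end = pk$end,
                      name = sprintf("peak_%d", seq_len(nrow(pk))),
                      fold = pk$fold, summit = pk$center - pk$start,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    structure(out, class = c("peak_set", "data.frame"),
              origin_index = pk$origin_index)
  })
}

#' Simulate an embryonic expression time course coupled to origins
#'
#' Generates genes of three classes: maternal transcripts (expression mass
#' in the first five time points, positions uniform), early-zygotic genes
#' (positions within `coupling_window` of an origin, sampled preferentially
#' near high-efficiency origins; expression mass in time points 9-25) and
#' late-zygotic genes (positions >= 15 kb from any origin; mass from time
#' point 40 on). Profiles are unimodal Gaussian bumps with multiplicative
#' log-normal noise. Within the coupling window gene strand is biased toward
#' co-directionality with the predominant local fork direction: genes left
#' of an origin preferentially on the "-" strand (leftward-transcribed),
#' genes right of it on "+".
#'
#' @inheritParams simulate_cell
#' @param n_genes number of genes.
#' @param n_timepoints number of time points (>= 10; default 50).
#' @param coupling_window early-zygotic placement window around origins (bp).
#' @param proportions named vector of class proportions
#'   (`maternal`, `early`, `late`), normalized internally.
#' @param orientation_bias in `[0,1]`: 0 = strand symmetric, 1 = fully
#'   co-directional inside the coupling window.
#' @param noise_sd sd of the log-normal multiplicative expression noise.
#' @return an `expression_timecourse`: list with `$expr` (gene x time matrix,
#'   un-normalized), `$genes` (gene_id, chrom, start, end, strand, class).
#' @export
simulate_timecourse <- function(model, n_genes = 1500, n_timepoints = 50,
                                coupling_window = 25000,
                                proportions = c(maternal = 0.4, early = 0.3,
                                                late = 0.3),
                                orientation_bias = 0.6, noise_sd = 0.3,
                                seed = 1) {
  stopifnot(inherits(model, "genome_model"))
  if (n_timepoints < 10) stopf("`n_timepoints` must be >= 10")
  check_positive(n_genes, "n_genes")
  if (orientation_bias < 0 || orientation_bias > 1)
    stopf("`orientation_bias` must be in [0,1]")
  proportions <- proportions / sum(proportions)
  with_seed(seed, {
    cls <- sample(c("maternal", "early", "late"), n_genes, replace = TRUE,
                  prob = proportions[c("maternal", "early", "late")])
    chroms <- model$chromosomes
    org <- model$origins
    mid <- function(n) {            # uniform genome positions
      ci <- sample.int(length(chroms), n, replace = TRUE,
                       prob = chroms / sum(chroms))
      list(chrom = names(chroms)[ci], pos = floor(runif(n) * chroms[ci]))
    }
    chrom <- character(n_genes); pos <- numeric(n_genes)
    ## maternal: uniform
    i <- which(cls == "maternal")
    u <- mid(length(i)); chrom[i] <- u$chrom; pos[i] <- u$pos
    ## early-zygotic: near origins, weighted by firing probability
    i <- which(cls == "early")
    oi <- sample.int(nrow(org), length(i), replace = TRUE,
                     prob = org$efficiency)
    off <- round(runif(length(i), -coupling_window, coupling_window))
    chrom[i] <- org$chrom[oi]
    pos[i] <- pmin(pmax(org$pos[oi] + off, 0), chroms[org$chrom[oi]] - 1)
    ## late-zygotic: >= 15 kb from every origin (rejection)
    i <- which(cls == "late")
    need <- i
    while (length(need)) {
      u <- mid(length(need))
      d <- .nearest_origin_distance(u$chrom, u$pos, org)
      ok <- d >= 15000
      chrom[need[ok]] <- u$chrom[ok]; pos[need[ok]] <- u$pos[ok]
      need <- need[!ok]
    }
    ## gene extents
    len <- pmin(pmax(round(rlnorm(n_genes, log(2000), 0.5)), 200), 20000)
    start <- pmax(0, round(pos - len / 2))
    end <- pmin(chroms[chrom], start + len)
    ## strand: co-directional bias inside the coupling window
    d <- .nearest_origin_signed(chrom, pos, org)
    strand <- ifelse(runif(n_genes) < 0.5, "+", "-")
    inwin <- abs(d) <= coupling_window
    pref <- ifelse(d < 0, "-", "+")      # left of origin -> leftward-transcribed
    take <- inwin & (runif(n_genes) < 0.5 + orientation_bias / 2)
    strand[take] <- pref[take]
    ## unimodal profiles
    peak <- numeric(n_genes); wid <- numeric(n_genes)
    i <- cls == "maternal"; peak[i] <- sample(1:3, sum(i), TRUE);  wid[i] <- 2
    i <- cls == "early";    peak[i] <- sample(11:22, sum(i), TRUE); wid[i] <- 3
    i <- cls == "late";     peak[i] <- sample(42:48, sum(i), TRUE); wid[i] <- 3
    tp <- seq_len(n_timepoints)
    expr <- t(vapply(seq_len(n_genes), function(g) {
      base <- dnorm(tp, peak[g], wid[g])
      base * exp(rnorm(n_timepoints, 0, noise_sd))
    }, numeric(n_timepoints)))
    dimnames(expr) <- list(sprintf("gene_%04d", seq_len(n_genes)),
                           paste0("t", tp))
    genes <- data.frame(gene_id = rownames(expr), chrom = chrom,
                        start = start, end = end, strand = strand,
                        class = cls, stringsAsFactors = FALSE)
    rownames(genes) <- NULL
    structure(list(expr = expr, genes = genes, normalized = FALSE),
              class = "expression_timecourse")
  })
}

## unsigned distance from positions to nearest origin midpoint
.nearest_origin_distance <- function(chrom, pos, origins) {
  abs(.nearest_origin_signed(chrom, pos, origins))
}

## signed distance: position minus nearest origin midpoint (ties -> left origin)
.nearest_origin_signed <- function(chrom, pos, origins) {
  out <- numeric(length(pos))
  for (cn in unique(chrom)) {
    op <- sort(origins$pos[origins$chrom == cn])
    sel <- chrom == cn
    if (length(op) == 0L) { out[sel] <- Inf; next }
    p <- pos[sel]
    i <- findInterval(p, op)
    dl <- ifelse(i >= 1L, p - op[pmax(i, 1L)], Inf)
    dr <- ifelse(i < length(op), op[pmin(i + 1L, length(op))] - p, Inf)
    out[sel] <- ifelse(dl <= dr, dl, -dr)
  }
  out
}
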