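#' Construct a replication genome model
#'
#' A `genome_model` is the ground truth behind the simulator: a set of
#' chromosomes, per-chromosome replication origins with firing probabilities
#' (the probability an origin initiates replication in a given cell cycle),
#' a uniform fork speed, and a fragment-length model describing the
#' nucleosome-periodic Okazaki fragment size distribution.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param origins data.frame with columns `chrom`, `pos` (bp, 0-based),
#'   `efficiency` (firing probability in `[0,1]`). Positions must be strictly
#'   increasing within each chromosome and every chromosome needs at least
#'   one origin.
#' @param fork_speed replication fork speed in kb/min (must be > 0).
#' @param fragment_length fragment-length model from
#'   [fragment_length_model()].
#' @return an object of class `genome_model`.
#' @seealso [simulate_genome_model()] to draw a random model.
#' @export
genome_model <- function(chromosomes, origins, fork_speed = 2.5,
                         fragment_length = fragment_length_model()) {
  if (is.null(names(chromosomes)) || any(!nzchar(names(chromosomes))))
    stopf("`chromosomes` must be a named vector of lengths")
  if (any(chromosomes <= 0)) stopf("chromosome lengths must be positive")
  check_positive(fork_speed, "fork_speed")
  origins <- as.data.frame(origins)
  need <- c("chrom", "pos", "efficiency")
  if (!all(need %in% names(origins)))
    stopf("`origins` needs columns %s", paste(need, collapse = ", "))
  origins$chrom <- as.character(origins$chrom)
  if (!all(origins$chrom %in% names(chromosomes)))
    stopf("origins reference unknown chromosomes: %s",
          paste(setdiff(origins$chrom, names(chromosomes)), collapse = ", "))
  if (any(origins$efficiency < 0 | origins$efficiency > 1))
    stopf("firing probabilities must lie in [0,1]")
  for (cn in names(chromosomes)) {
    p <- origins$pos[origins$chrom == cn]
    if (length(p) < 1L) stopf("chromosome %s has no origin", cn)
    if (any(diff(p) <= 0)) stopf("origin positions on %s not strictly increasing", cn)
    if (any(p < 0 | p >= chromosomes[[cn]]))
      stopf("origin positions on %s outside [0, length)", cn)
  }
  structure(list(chromosomes = chromosomes,
                 origins = origins[order(match(origins$chrom, names(chromosomes)),
                                         origins$pos), , drop = FALSE],
                 fork_speed = fork_speed,
                 fragment_length = fragment_length),
            class = "genome_model")
}

#' Okazaki fragment length model
#'
#' Okazaki fragment sizes show a periodic ladder at multiples of the
#' nucleosome repeat. Lengths are drawn as `k * period + N(0, jitter_sd)`
#' with `k` sampled from `weights` over `{1, 2, 3}`, then clamped to
#' `[min, max]` and rounded.
#'
#' @param min,max hard bounds in bp.
#' @param period nucleosome repeat length in bp.
#' @param weights mixture weights for 1x, 2x, 3x the period (normalized).
#' @param jitter_sd Gaussian jitter sd in bp.
#' @export
fragment_length_model <- function(min = 100, max = 600, period = 172,
                                  weights = c(0.55, 0.30, 0.15),
                                  jitter_sd = 12) {
  check_positive(min, "min"); check_positive(max, "max")
  check_positive(period, "period"); check_positive(jitter_sd, "jitter_sd",
                                                  allow_zero = TRUE)
  if (min >= max) stopf("fragment length min must be < max")
  if (length(weights) != 3L || any(weights < 0) || sum(weights) == 0)
    stopf("`weights` must be 3 non-negative numbers")
  list(min = min, max = max, period = period,
       weights = weights / sum(weights), jitter_sd = jitter_sd)
}

#' Draw a random genome model
#'
#' Origin positions are sampled uniformly (without replacement, hence
#' strictly increasing after sorting) along each chromosome; firing
#' probabilities are i.i.d. draws from the chosen distribution. The default
#' desk-scale model (2 chromosomes x 5 Mb, 125 origins each, beta(2,2)
#' efficiencies) emulates the ~40 kb mean origin spacing and ~50% median
#' efficiency regime of worm embryo OK-seq maps.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (shared).
#' @param n_origins origins per chromosome (>= 1).
#' @param efficiency one of `"beta"`, `"uniform"`, `"fixed"`.
#' @param eff_params distribution parameters: `c(shape1, shape2)` for beta,
#'   `c(min, max)` for uniform, a single value for fixed.
#' @param fork_speed fork speed in kb/min.
#' @param fragment_length see [fragment_length_model()].
#' @param seed RNG seed; identical seeds give identical models.
#' @return a [genome_model()].
#' @examples
#' m <- simulate_genome_model(1, 1e6, 25, "fixed", 0.5, seed = 7)
#' nrow(m$origins)
#' @export
simulate_genome_model <- function(n_chrom = 2, chrom_length = 5e6,
                                  n_origins = 125,
                                  efficiency = c("beta", "uniform", "fixed"),
                                  eff_params = c(2, 2), fork_speed = 2.5,
                                  fragment_length = fragment_length_model(),
                                  seed = 1) {
  check_positive(n_chrom, "n_chrom"); check_positive(chrom_length, "chrom_length")
  if (!is.numeric(n_origins) || any(n_origins < 1))
    stopf("`n_origins` must be >= 1 per chromosome")
  efficiency <- match.arg(efficiency)
  chroms <- setNames(rep(chrom_length, n_chrom),
                     paste0("chr", seq_len(n_chrom)))
  with_seed(seed, {
    orig <- do.call(rbind, lapply(names(chroms), function(cn) {
      pos <- sort(sample.int(chrom_length - 1L, n_origins))
      e <- switch(efficiency,
        beta    = rbeta(n_origins, eff_params[1], eff_params[2]),
        uniform = runif(n_origins, eff_params[1], eff_params[2]),
        fixed   = rep(eff_params[1], n_origins))
      data.frame(chrom = cn, pos = pos, efficiency = e,
                 stringsAsFactors = FALSE)
    }))
    genome_model(chroms, orig, fork_speed = fork_speed,
                 fragment_length = fragment_length)
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model>\n")
  cat(sprintf("  %d chromosome(s), total %.1f Mb\n",
              length(x$chromosomes), sum(x$chromosomes) / 1e6))
  cat(sprintf("  %d origins (median firing probability %.2f)\n",
              nrow(x$origins), median(x$origins$efficiency)))
  cat(sprintf("  fork speed %.2f kb/min; fragment period %d bp\n",
              x$fork_speed, x$fragment_length$period))
  invisible(x)
}

#' @importFrom stats rbeta
NULL
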