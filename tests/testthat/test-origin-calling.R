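test_that("rolling median smoothing matches a brute-force oracle", {
  set.seed(10)
  x <- as.numeric(rpois(3000, 3))
  x[sample.int(3000, 60)] <- 0          # ensure masked bins exist
  W <- x; C <- as.numeric(rpois(3000, 3))
  tr <- toy_track(W, C)
  sm <- smooth_track(tr, 1500)
  mask <- W + C == 0
  h <- 7
  brute <- function(v, i) {
    j <- max(1, i - h):min(length(v), i + h)
    j <- j[!mask[j]]
    if (!length(j)) NA_real_ else median(v[j])
  }
  idx <- sample.int(3000, 1000)
  expect_equal(sm$W$chr1[idx], vapply(idx, function(i) brute(W, i), 0))
  expect_equal(sm$C$chr1[idx], vapply(idx, function(i) brute(C, i), 0))
})

test_that("smoothing leaves constants alone and removes single-bin spikes", {
  tr <- toy_track(rep(5, 100), rep(5, 100))
  sm <- smooth_track(tr, 1500)
  expect_equal(sm$W$chr1, rep(5, 100))

  spike <- rep(1, 100); spike[50] <- 100
  sm2 <- smooth_track(toy_track(spike, rep(1, 100)), 1500)
  expect_equal(sm2$W$chr1[50], 1)       # median of the 15-bin window

  expect_message(smooth_track(toy_track(rep(1, 50), rep(1, 50)), 1600),
                 "coerced")
  expect_error(smooth_track(toy_track(rep(1, 50), rep(1, 50)), 50), ">=")
})

test_that("normalization yields strand fractions and masks empty bins", {
  tr <- toy_track(c(10, 5, 0), c(0, 5, 0), bin_size = 100)
  nt <- normalize_track(tr)
  expect_equal(nt$fW$chr1, c(1, 0.5, NA))
  expect_equal(nt$fC$chr1, c(0, 0.5, NA))
})

test_that("transition metric matches hand arithmetic and is antisymmetric", {
  ## 10-bin toy track, 2-bin windows: hand-computed two-window quotients
  W <- c(4, 4, 4, 4, 2, 1, 0, 0, 0, 0)
  C <- c(0, 0, 0, 0, 2, 3, 4, 4, 4, 4)
  tr <- normalize_track(toy_track(W, C))
  met <- origin_transition_metric(tr, window = 200)   # 2-bin flanks
  b <- 5                                              # left bins {3,4}, right {6,7}
  hand <- (W[3] + W[4]) / (W[3] + W[4] + C[3] + C[4]) -
    (W[6] + W[7]) / (W[6] + W[7] + C[6] + C[7])
  expect_equal(met$M$chr1[b], hand)

  ## pure Watson left / pure Crick right of b gives M = 1
  W2 <- c(rep(5, 10), rep(0, 10)); C2 <- c(rep(0, 10), rep(5, 10))
  m2 <- origin_transition_metric(normalize_track(toy_track(W2, C2)),
                                 window = 500)
  expect_equal(max(m2$M$chr1, na.rm = TRUE), 1)

  ## swap Watson/Crick labels: metric negates wherever defined
  m2r <- origin_transition_metric(normalize_track(toy_track(C2, W2)),
                                  window = 500)
  expect_equal(m2r$M$chr1, -m2$M$chr1)
  expect_true(all(abs(m2$M$chr1) <= 1, na.rm = TRUE))

  ## strand-balanced noise: metric stays small and centered
  set.seed(3)
  Wn <- as.numeric(rpois(2000, 20)); Cn <- as.numeric(rpois(2000, 20))
  mn <- origin_transition_metric(normalize_track(toy_track(Wn, Cn)),
                                 window = 12000)
  expect_lt(abs(mean(mn$M$chr1, na.rm = TRUE)), 0.02)
  expect_error(origin_transition_metric(tr, window = 100), "2 bins")
})

test_that("peak calling is deterministic with leftmost tie-breaking", {
  ## two equal maxima 5 kb apart -> single call at the leftmost
  M <- rep(NA_real_, 400)
  M[100:300] <- 0
  M[150] <- 0.5; M[200] <- 0.5
  met <- structure(list(M = list(chr1 = M), bin_size = 100,
                        chrom_sizes = c(chr1 = 40000), window = 12000),
                   class = "oem_metric")
  calls <- call_origins(met, threshold = 0.1, min_separation = 12000)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$midpoint, (150 - 1) * 100 + 50)

  ## all-masked metric: no calls, no error
  met0 <- structure(list(M = list(chr1 = rep(NA_real_, 100)), bin_size = 100,
                         chrom_sizes = c(chr1 = 10000), window = 12000),
                    class = "oem_metric")
  expect_equal(nrow(call_origins(met0)), 0L)
})

test_that("a single clean origin is recovered within 2 kb with efficiency 1", {
  m <- genome_model(c(chr1 = 1e6),
                    data.frame(chrom = "chr1", pos = 5e5, efficiency = 1))
  fr <- simulate_fragments(m, n_cells = 300, fragments_per_cell = 300, seed = 8)
  om <- suppressMessages(map_origins(fr, m$chromosomes))
  expect_equal(nrow(om), 1L)
  expect_lt(abs(om$midpoint - 5e5), 2000)
  expect_gt(om$efficiency, 0.95)
  ## sharp origin: a few bins, bounded by the 1.5 kb argmax aggregation
  expect_lte(om$transition_zone, 2500)
  expect_false(om$tz_flagged)
})

test_that("strand-balanced tracks give efficiency exactly 0.5", {
  tr <- normalize_track(toy_track(rep(8, 500), rep(8, 500)))
  om <- structure(data.frame(chrom = "chr1",
                             midpoint = c(10050, 25050, 40050),
                             score = 0.1, stringsAsFactors = FALSE),
                  class = c("origin_map", "data.frame"))
  for (mode in c("amplitude", "max_strand_aware", "max_blind")) {
    ann <- annotate_efficiency(om, tr, mode = mode)
    expect_equal(ann$efficiency, rep(0.5, 3), info = mode)
  }
})

test_that("transition zone grows with initiation-zone width", {
  org <- data.frame(chrom = "chr1", pos = seq(5e4, 9.5e5, by = 1e5),
                    efficiency = 0.9)
  m <- genome_model(c(chr1 = 1e6), org)
  tz <- vapply(c(0, 8000), function(j) {
    fr <- simulate_fragments(m, n_cells = 800, fragments_per_cell = 300,
                             seed = 5, position_jitter_sd = j)
    om <- suppressMessages(map_origins(fr, m$chromosomes))
    mean(om$transition_zone, na.rm = TRUE)
  }, 0)
  expect_lt(tz[1], tz[2])
})

test_that("spacing statistics match brute force and handle degenerate maps", {
  om <- structure(data.frame(chrom = "chr1", midpoint = c(0, 4e4, 8e4)),
                  class = c("origin_map", "data.frame"))
  ss <- spacing_stats(om)
  expect_equal(ss$median_spacing, 4e4)
  expect_equal(ss$frac_within, 1)

  single <- structure(data.frame(chrom = "chr1", midpoint = 1e4),
                      class = c("origin_map", "data.frame"))
  ss1 <- spacing_stats(single)
  expect_true(is.na(ss1$median_spacing))
  expect_equal(length(ss1$spacings), 0L)

  set.seed(11)
  pos <- sort(sample.int(1e7, 1000))
  omr <- structure(data.frame(chrom = "chr1", midpoint = pos),
                   class = c("origin_map", "data.frame"))
  expect_equal(spacing_stats(omr)$median_spacing,
               median(diff(sort(pos))))   # brute-force sorted differences
})

test_that("origin map comparison is reflexive and rank-antisymmetric", {
  sim <- default_sim()
  om <- sim$origins
  self <- compare_origin_maps(om, om)
  expect_equal(self$spearman_r, 1.0)
  expect_equal(self$percent_overlap, 100)

  rev <- om
  rev$efficiency <- max(om$efficiency, na.rm = TRUE) +
    min(om$efficiency, na.rm = TRUE) - om$efficiency   # reverse ranks
  expect_equal(compare_origin_maps(om, rev)$spearman_r, -1.0)
})

test_that("two same-model runs give concordant origin maps", {
  sim <- default_sim()
  fr2 <- simulate_fragments(sim$model, seed = 77)
  om2 <- suppressMessages(map_origins(fr2, sim$model$chromosomes))
  cmp <- compare_origin_maps(sim$origins, om2)
  expect_gte(cmp$spearman_r, 0.8)
  expect_gte(cmp$percent_overlap, 90)
})

test_that("origin-centered heatmap rows are unit-normalized and ordered", {
  sim <- default_sim()
  om <- sim$origins
  hm <- origin_strand_heatmap(om, attr(om, "track"))
  expect_true(all(abs(rowMeans(hm$watson)) < 1e-9))
  ss <- rowSums(hm$watson^2)
  expect_true(all(abs(ss[!hm$zero_rows] - 1) < 1e-9))
  expect_true(all(diff(om$transition_zone[hm$order]) >= 0))

  ## constant row degenerates to the zero vector, flagged not errored
  trc <- smooth_track(toy_track(rep(3, 600), rep(3, 600)), 1500)
  omc <- structure(data.frame(chrom = "chr1", midpoint = 30050, score = 0.1,
                              transition_zone = 0, tz_flagged = FALSE),
                   class = c("origin_map", "data.frame"))
  hmc <- origin_strand_heatmap(omc, trc)
  expect_true(all(hmc$watson == 0))
  expect_true(hmc$zero_rows[1])
})

test_that("duplication time follows the two-fork closed form", {
  expect_identical(replication_time(75, 2.5), 15)
  expect_identical(replication_time(0, 2.5), 0)
  expect_identical(replication_time(40, 2.5), 8)
  expect_error(replication_time(40, 0), "> 0")
  expect_error(replication_time(-1, 2.5), ">= 0")
})
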