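test_that("peak filtering is strictly greater-than and order-preserving", {
  pk <- structure(data.frame(chrom = "chr1", start = c(0, 100, 200),
                             end = c(50, 150, 250), name = c("a", "b", "c"),
                             fold = c(4.9, 5.0, 5.1), summit = NA_integer_,
                             stringsAsFactors = FALSE),
                  class = c("peak_set", "data.frame"))
  out <- filter_peaks(pk, 5)
  expect_equal(out$name, "c")
  expect_equal(nrow(filter_peaks(pk[0, ], 5)), 0L)

  set.seed(4)
  folds <- runif(1000, 0, 10)
  pk2 <- structure(data.frame(chrom = "chr1", start = seq_len(1000) * 10,
                              end = seq_len(1000) * 10 + 5, name = "x",
                              fold = folds, summit = NA_integer_,
                              stringsAsFactors = FALSE),
                   class = c("peak_set", "data.frame"))
  expect_equal(nrow(filter_peaks(pk2, 5)), sum(folds > 5))
  expect_equal(filter_peaks(pk2, 5)$fold, folds[folds > 5])  # order kept
})

test_that("peak-to-origin distances use the 5 kb origin window", {
  om <- structure(data.frame(chrom = "chr1", midpoint = 10000),
                  class = c("origin_map", "data.frame"))
  pk <- function(s, e, cn = "chr1")
    data.frame(chrom = cn, start = s, end = e)
  expect_equal(peak_origin_distances(pk(9000, 9100), om), 0)    # inside
  expect_equal(peak_origin_distances(pk(10000, 10100), om), 0)  # overlap
  expect_equal(peak_origin_distances(pk(13500, 13600), om), 1000)
  expect_equal(peak_origin_distances(pk(5000, 6000), om), 1500)
  expect_true(is.na(peak_origin_distances(pk(100, 200, "chr2"), om)))
})

test_that("peak distances agree with a GenomicRanges oracle", {
  skip_if_not_installed("GenomicRanges")
  set.seed(7)
  om <- structure(data.frame(chrom = "chr1",
                             midpoint = sort(sample(5000:995000, 40))),
                  class = c("origin_map", "data.frame"))
  st <- sort(sample(0:999000, 300))
  pk <- data.frame(chrom = "chr1", start = st,
                   end = st + sample(100:900, 300, replace = TRUE))
  d <- peak_origin_distances(pk, om)
  gr_p <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(pk$start + 1, pk$end))
  gr_o <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(om$midpoint - 2500 + 1,
                                                  om$midpoint + 2500))
  hits <- GenomicRanges::distanceToNearest(gr_p, gr_o)
  expect_equal(d, as.numeric(S4Vectors::mcols(hits)$distance))
})

test_that("association grid is cumulative and conserves the peak count", {
  sim <- default_sim()
  pk <- filter_peaks(simulate_chip_peaks(sim$model, seed = 3), 5)
  g <- association_grid(pk, sim$origins)
  expect_true(all(apply(g$counts, 1, function(r) all(diff(r) >= 0))))
  expect_equal(sum(g$marginal), nrow(pk))
  expect_equal(unname(g$counts[, ncol(g$counts)]),
               g$marginal - as.numeric(
                 table(cut(pk$fold, g$intensity_breaks,
                           include.lowest = TRUE)[
                             is.na(g$peak_distance) |
                               g$peak_distance > max(g$distance_grid)])))
  ## high-intensity peaks sit closer to origins than low-intensity ones
  hi <- pk$fold > median(pk$fold)
  expect_lt(wilcox.test(g$peak_distance[hi], g$peak_distance[!hi],
                        alternative = "less")$p.value, 0.01)
  ## most efficient origins carry a nearby peak
  expect_gt(g$frac_efficient_origins_with_peak[["<=1000"]], 0.5)
})

test_that("placement p-value matches closed form and Monte Carlo", {
  ## origins tiling the chromosome: any placement scores p = 1
  om_t <- structure(data.frame(chrom = "chr1",
                               midpoint = seq(2500, 97500, by = 5000)),
                    class = c("origin_map", "data.frame"))
  expect_equal(peak_association_pvalue(
    list(chrom = "chr1", start = 100, end = 200), om_t, 1e5), 1)

  ## single 5 kb window on 1 Mb, near-point peak at d = 0: coverage ratio
  om_1 <- structure(data.frame(chrom = "chr1", midpoint = 5e5),
                    class = c("origin_map", "data.frame"))
  p0 <- peak_association_pvalue(list(chrom = "chr1", start = 499000,
                                     end = 499001), om_1, 1e6)
  expect_equal(p0, 5002 / 1e6, tolerance = 1e-3)

  ## Monte-Carlo placement oracle on random fixtures
  set.seed(21)
  om_r <- structure(data.frame(chrom = "chr1",
                               midpoint = sort(sample(10000:490000, 8))),
                    class = c("origin_map", "data.frame"))
  G <- 5e5; B <- 10000
  for (trial in 1:3) {
    L <- sample(200:2000, 1)
    s <- sample(0:(G - L), 1)
    p <- peak_association_pvalue(list(chrom = "chr1", start = s, end = s + L),
                                 om_r, G)
    dobs <- peak_origin_distances(data.frame(chrom = "chr1", start = s,
                                             end = s + L), om_r)
    ss <- sample(0:(G - L), B, replace = TRUE)
    dmc <- peak_origin_distances(data.frame(chrom = "chr1", start = ss,
                                            end = ss + L), om_r)
    phat <- mean(dmc <= dobs)
    expect_lt(abs(p - phat), 3 * sqrt(p * (1 - p) / B) + 1e-9)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("signal level scales with origin efficiency", {
  sim <- default_sim()
  om <- sim$origins
  ## manufacture a signal proportional to efficiency around each origin
  set.seed(9)
  sig <- data.frame(chrom = om$chrom,
                    start = pmax(0, om$midpoint - 2500),
                    end = om$midpoint + 2500,
                    value = om$efficiency + rnorm(nrow(om), 0, 0.02))
  sv <- signal_vs_efficiency(sig, om)
  expect_gte(sv$correlation, 0.9)
  ## reversing the efficiency ranking negates the correlation
  om_r <- om
  om_r$efficiency <- max(om$efficiency) + min(om$efficiency) - om$efficiency
  sv_r <- signal_vs_efficiency(sig, om_r)
  expect_equal(sv_r$correlation, -sv$correlation, tolerance = 1e-6)
  ## constant signal (one genome-wide record per chromosome)
  cs <- sim$model$chromosomes
  sig_c <- data.frame(chrom = names(cs), start = 0, end = as.numeric(cs),
                      value = 1)
  sv_c <- signal_vs_efficiency(sig_c, om)
  expect_true(is.na(sv_c$correlation) || abs(sv_c$correlation) < 0.05)
  expect_equal(length(unique(round(sv_c$bin_means$mean, 9))), 1L)
})
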