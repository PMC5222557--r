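test_that("genome model generation respects the requested distribution and seed", {
  m <- simulate_genome_model(1, 1e6, 25, "fixed", 0.5, seed = 7)
  expect_equal(nrow(m$origins), 25)
  expect_true(all(m$origins$efficiency == 0.5))
  expect_true(all(diff(m$origins$pos) > 0))

  m1 <- simulate_genome_model(2, 5e6, 125, "beta", c(2, 2), seed = 1)
  m2 <- simulate_genome_model(2, 5e6, 125, "beta", c(2, 2), seed = 1)
  expect_identical(m1, m2)

  mb <- simulate_genome_model(1, 1e6, 25, "beta", c(2, 2), seed = 1)
  expect_lt(abs(median(mb$origins$efficiency) - 0.5), 0.1)  # beta(2,2) median
})

test_that("genome model validation rejects bad inputs", {
  expect_error(simulate_genome_model(0, 1e6, 10), "positive")
  expect_error(simulate_genome_model(1, -5, 10), "positive")
  expect_error(genome_model(c(chr1 = 1e6),
                            data.frame(chrom = "chr1", pos = 100,
                                       efficiency = 1.2)), "\\[0,1\\]")
  expect_error(genome_model(c(chr1 = 1e6),
                            data.frame(chrom = "chr1", pos = c(10, 10),
                                       efficiency = c(0.5, 0.5))),
               "strictly increasing")
  expect_error(genome_model(c(chr1 = 1e6, chr2 = 1e6),
                            data.frame(chrom = "chr1", pos = 10,
                                       efficiency = 0.5)), "no origin")
})

test_that("per-cell firing matches the rejection-conditioned probabilities", {
  ## single always-on origin: fires every cell, directions split at it
  m1 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, efficiency = 1))
  cell <- simulate_cell(m1, seed = 3)
  expect_equal(cell$fired$chr1, 5e5)
  expect_equal(fork_direction(cell$fired$chr1, c(1e5, 4e5)), c("L", "L"))
  expect_equal(fork_direction(cell$fired$chr1, c(6e5, 9e5)), c("R", "R"))

  ## two always-on origins: directions flip at their midpoint
  m2 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = c(25e4, 75e4),
                                efficiency = c(1, 1)))
  f <- simulate_cell(m2, seed = 1)$fired$chr1
  expect_equal(fork_direction(f, c(49e4)), "R")   # nearer the left origin
  expect_equal(fork_direction(f, c(51e4)), "L")   # nearer the right origin

  ## enumeration oracle: e = (0.8, 0.4), conditioned on >= 1 firing
  m3 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = c(25e4, 75e4),
                                efficiency = c(0.8, 0.4)))
  norm <- 1 - 0.2 * 0.6                       # P(at least one fires)
  pA <- 0.8 / norm; pB <- 0.4 / norm          # conditioned marginals
  n <- 10000
  fired <- vapply(seq_len(n), function(s)
    simulate_cell(m3, seed = s)$fired_index, logical(2))
  fA <- mean(fired[1, ]); fB <- mean(fired[2, ])
  expect_lt(abs(fA - pA), 3 * sqrt(pA * (1 - pA) / n))
  expect_lt(abs(fB - pB), 3 * sqrt(pB * (1 - pB) / n))
})

test_that("expected Watson fraction enumeration matches hand-computed values", {
  m1 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, efficiency = 1))
  expect_equal(expected_watson_fraction(m1, "chr1", 1e5), 1.0)
  expect_equal(expected_watson_fraction(m1, "chr1", 9e5), 0.0)

  m2 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = c(25e4, 75e4),
                                efficiency = c(1, 1)))
  expect_equal(expected_watson_fraction(m2, "chr1", 5e5), 0.5)  # exact tie

  ## hand enumeration for e = (0.8, 0.4) at a point nearer the left origin:
  ## Watson only when the left origin is unfired and the right one fired.
  m3 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = c(25e4, 75e4),
                                efficiency = c(0.8, 0.4)))
  expect_equal(expected_watson_fraction(m3, "chr1", 4e5),
               (0.2 * 0.4) / (1 - 0.2 * 0.6))

  big <- genome_model(c(chr1 = 1e7),
                      data.frame(chrom = "chr1",
                                 pos = seq(1e5, 2.2e6, by = 1e5),
                                 efficiency = 0.5))
  expect_error(expected_watson_fraction(big, "chr1", 5e5), "enumeration limit")
})

test_that("simulated fragments obey the strand logic and count conservation", {
  m1 <- genome_model(c(chr1 = 1e6),
                     data.frame(chrom = "chr1", pos = 5e5, efficiency = 1))
  fr <- simulate_fragments(m1, n_cells = 50, fragments_per_cell = 200, seed = 4)
  anchor <- ifelse(fr$strand == "+", fr$start, fr$end - 1)
  expect_true(all(fr$strand[anchor < 5e5] == "+"))
  expect_true(all(fr$strand[anchor > 5e5] == "-"))
  expect_equal(nrow(fr) + attr(fr, "n_dropped"), attr(fr, "n_emitted"))
  expect_true(all(fr$end - fr$start >= 30 & fr$end - fr$start <= 600))
  expect_true(all(fr$start >= 0 & fr$end <= 1e6))

  fr2 <- simulate_fragments(m1, n_cells = 50, fragments_per_cell = 200, seed = 4)
  expect_identical(fr, fr2)   # seed determinism, byte-identical
})

test_that("fragment lengths show the nucleosome-periodic ladder", {
  m <- genome_model(c(chr1 = 1e6),
                    data.frame(chrom = "chr1", pos = 5e5, efficiency = 1))
  fr <- simulate_fragments(m, n_cells = 100, fragments_per_cell = 500, seed = 6)
  len <- fr$end - fr$start
  h <- tabulate(len, nbins = 600)[100:600]
  ac <- stats::acf(h, lag.max = 250, plot = FALSE)$acf[-1]
  period_hat <- which.max(ac[100:250]) + 99   # search away from lag 0
  expect_lt(abs(period_hat - m$fragment_length$period), 2 * 12)  # +/- jitter
})

test_that("empirical Watson fraction converges to the enumeration oracle", {
  m <- simulate_genome_model(1, 1e6, 8, "beta", c(2, 2), seed = 42)
  fr <- simulate_fragments(m, n_cells = 400, fragments_per_cell = 500, seed = 43)
  anchor <- ifelse(fr$strand == "+", fr$start, fr$end - 1)
  win <- 10000
  bins <- floor(anchor / win)
  probes <- (sort(unique(bins)) + 0.5) * win
  emp <- vapply(sort(unique(bins)), function(b)
    mean(fr$strand[bins == b] == "+"), 0)
  n_per <- as.numeric(table(bins))
  ## expected fraction = oracle averaged over the window (it varies inside);
  ## fragments from one cell share a firing configuration, so the effective
  ## sample size per window is the number of cells, not the fragment count
  offs <- (c(1, 3, 5, 7, 9) / 10 - 0.5) * win
  expt <- vapply(probes, function(p)
    mean(expected_watson_fraction(m, "chr1", p + offs)), 0)
  sd3 <- 3 * sqrt(pmax(expt * (1 - expt), 1e-4) / 400)
  expect_true(mean(abs(emp - expt) <= sd3) >= 0.95)
})

test_that("chip peak simulation scales intensity with firing probability", {
  m <- simulate_genome_model(1, 2e6, 20, "beta", c(2, 2), seed = 9)
  p0 <- simulate_chip_peaks(m, intensity_slope = 0, noise_sd = 0,
                            background_peak_rate = 0, seed = 1)
  expect_equal(length(unique(p0$fold)), 1L)    # flat map, identical folds

  p1 <- simulate_chip_peaks(m, noise_sd = 0, background_peak_rate = 0,
                            center_jitter_sd = 0, seed = 1)
  oi <- attr(p1, "origin_index")
  expect_equal(order(p1$fold), order(m$origins$efficiency[oi]))

  p2 <- simulate_chip_peaks(m, seed = 2)
  oi2 <- attr(p2, "origin_index")
  keep <- !is.na(oi2)
  r <- cor(p2$fold[keep], m$origins$efficiency[oi2[keep]], method = "spearman")
  expect_gte(r, 0.8)
  expect_error(simulate_chip_peaks(m, background_peak_rate = -1), "positive")
})

test_that("simulated time course places classes in their windows", {
  m <- simulate_genome_model(1, 2e6, 20, "beta", c(2, 2), seed = 9)
  tc <- simulate_timecourse(m, n_genes = 300,
                            proportions = c(maternal = 1, early = 0, late = 0),
                            seed = 3)
  expect_true(all(apply(tc$expr, 1, which.max) <= 5))

  tc2 <- simulate_timecourse(m, n_genes = 600, orientation_bias = 0, seed = 4)
  ob <- orientation_bias(
    structure(tc2$genes, class = c("gene_table", "data.frame")),
    truth_map(m))
  expect_lt(abs(mean(ob$log2_ratio, na.rm = TRUE)), 0.25)  # symmetric null

  tc3 <- simulate_timecourse(m, n_genes = 500, seed = 5)
  late <- tc3$genes$class == "late"
  d <- abs(okseqr:::.nearest_origin_signed(tc3$genes$chrom[late],
                                           (tc3$genes$start[late] +
                                              tc3$genes$end[late]) / 2,
                                           m$origins))
  expect_true(all(d >= 15000 - 10000))  # midpoint anchor vs placement point
  expect_error(simulate_timecourse(m, n_timepoints = 5), ">= 10")
})
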