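## Shared fixtures, memoized so the desk-scale default simulation (2 x 5 Mb,
## 125 origins/chromosome, beta(2,2) efficiencies, 2000 cells x 500
## fragments) is generated once per test run.

.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$default)) {
    m <- simulate_genome_model(seed = 1)
    fr <- simulate_fragments(m, seed = 2)
    om <- suppressMessages(map_origins(fr, m$chromosomes))
    .fixture_env$default <- list(model = m, fragments = fr, origins = om)
  }
  .fixture_env$default
}

## ground-truth origins dressed as an origin_map (for pairing/comparison)
truth_map <- function(model) {
  structure(data.frame(chrom = model$origins$chrom,
                       midpoint = model$origins$pos,
                       efficiency = model$origins$efficiency,
                       stringsAsFactors = FALSE),
            class = c("origin_map", "data.frame"))
}

## hand-built single-chromosome track from bin-count vectors
toy_track <- function(W, C, bin_size = 100, chrom = "chr1") {
  okseqr:::new_stranded_track(
    setNames(list(as.numeric(W)), chrom),
    setNames(list(as.numeric(C)), chrom),
    setNames(length(W) * bin_size, chrom), bin_size)
}

## nearest-neighbor distance among ground-truth origins
truth_nn <- function(model) {
  vapply(seq_len(nrow(model$origins)), function(i) {
    p <- model$origins$pos[model$origins$chrom == model$origins$chrom[i]]
    d <- abs(p - model$origins$pos[i])
    min(d[d > 0])
  }, 0)
}
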