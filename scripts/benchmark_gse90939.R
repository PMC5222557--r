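#!/usr/bin/env Rscript
## Genome-scale benchmark on real Okazaki-fragment sequencing data.
##
## The headline genome-wide numbers (>2000 origins, ~40 kb median spacing,
## 96% of origins within 100 kb of a neighbor, ~50% median efficiency, and
## ~75% of >30%-efficiency origins within 1 kb of an H3K27ac peak) require
## the deposited worm embryo OK-seq data (GEO accession GSE90939, mapped to
## WS220) together with modENCODE H3K27ac peak calls. Those datasets are
## not shipped with the package; this script reproduces the numbers once
## you have them locally:
##
##   1. Align the Okazaki fragment reads to WS220 (Bowtie2 --local,
##      filter MAPQ >= 30) and export strand-separated fragment intervals
##      as BED6, or 100 bp-binned stranded coverage as a bedGraph pair.
##   2. Call H3K27ac peaks (MACS2, default parameters) and keep the
##      narrowPeak output; fold enrichment must be in column 7.
##   3. Run:
##      Rscript scripts/benchmark_gse90939.R \
##        --fragments okseq_ws220.bed --chrom-sizes ws220.chrom.sizes \
##        --peaks H3K27ac_peaks.narrowPeak --out results/benchmark
##      (use --watson/--crick bedGraphs instead of --fragments if starting
##      from pre-binned coverage)

suppressPackageStartupMessages(library(okseqr))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = "results/benchmark")
i <- 1L
while (i <= length(args)) {
  key <- sub("^--", "", args[i]); key <- gsub("-", "_", key)
  opt[[key]] <- args[i + 1L]; i <- i + 2L
}
stopifnot(!is.null(opt$chrom_sizes))

inputs <- opt[intersect(names(opt),
                        c("fragments", "watson", "crick", "chrom_sizes",
                          "peaks"))]
res <- run_pipeline(run_config(), opt$out,
                    stages = c("call", if (!is.null(opt$peaks)) "assoc"),
                    inputs = inputs)

om <- res$origins
ss <- spacing_stats(om)
cat(sprintf("origins called:                  %d\n", nrow(om)))
cat(sprintf("median spacing:                  %.1f kb\n",
            ss$median_spacing / 1000))
cat(sprintf("origins within 100 kb:           %.1f%%\n",
            100 * ss$frac_within))
cat(sprintf("median efficiency:               %.1f%%\n",
            100 * median(om$efficiency, na.rm = TRUE)))
if (!is.null(res$assoc))
  cat(sprintf("efficient origins w/ peak <=1kb: %.1f%%\n",
              100 * res$assoc$frac_efficient_origins_with_peak[["<=1000"]]))
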