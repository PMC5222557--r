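## End-to-end pipeline driver with config validation, provenance sidecars
## and per-stage record-count logging.

#' Build a validated pipeline configuration
#'
#' Collects every tunable the pipeline stages expose, with the standard
#' defaults (100 bp bins, 1.5 kb smoothing, 12 kb metric window, 20 kb
#' efficiency radius, 25 kb transition-zone radius, 2.5 kb origin windows,
#' 5-fold peak filter, 25 kb flank, top 1000 origins). Window-type lengths
#' must be positive multiples of the bin size. The config is serialized
#' verbatim into every output's JSON sidecar.
#'
#' @param ... overrides of the defaults listed above.
#' @return a validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(bin_size = 100, smooth_window = 1500, oem_window = 12000,
              threshold = 0.1, min_separation = 12000,
              efficiency_radius = 20000, tz_radius = 25000,
              origin_halfwidth = 2500, min_fold = 5, flank = 25000,
              top_n = 1000, k_clusters = 6, seed = 1,
              n_cells = 2000, fragments_per_cell = 500,
              n_chrom = 2, chrom_length = 5e6, n_origins = 125,
              efficiency = "beta", eff_params = c(2, 2))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  check_positive(cfg$bin_size, "bin_size")
  for (f in c("smooth_window", "oem_window", "min_separation",
              "efficiency_radius", "tz_radius", "flank"))
    if (cfg[[f]] < cfg$bin_size || cfg[[f]] %% cfg$bin_size != 0)
      stopf("`%s` must be a positive multiple of bin_size", f)
  for (f in c("origin_halfwidth", "top_n", "k_clusters", "n_cells",
              "fragments_per_cell", "n_chrom", "chrom_length", "n_origins"))
    check_positive(cfg[[f]], f)
  structure(cfg, class = "run_config")
}

## deterministic 32-bit polynomial hash of the JSON-serialized config,
## for provenance sidecars
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

.log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[okseqr] ", fmt), ...))
}

#' Run the full pipeline
#'
#' Executes, as requested by `stages`: simulate (fragments + truth from the
#' config's genome model) or load (fragments BED / bedGraph pair +
#' chrom.sizes) -> bin/smooth/normalize/call/annotate -> optional
#' association, gene-context and time-course analyses. All artifacts are
#' written under `out_dir` together with a JSON sidecar carrying the full
#' config, its hash, the package version and per-stage record counts. Any
#' stage error aborts with the stage name.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param stages character subset of
#'   `c("simulate", "call", "assoc", "genes", "timecourse")`.
#' @param inputs optional named list of input paths for non-simulated runs:
#'   `fragments` (BED6) or `watson`/`crick` (bedGraph pair), `chrom_sizes`,
#'   `peaks`, `genes`, `expression`.
#' @param quiet suppress stage logs.
#' @return invisibly, a list of in-memory results
#'   (`model`, `origins`, `assoc`, `orientation`, `heatmap`, ...).
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("simulate", "call"),
                         inputs = list(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  counts <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  model <- NULL; fragments <- NULL; chrom_sizes <- NULL
  peaks <- NULL; tc <- NULL

  if ("simulate" %in% stages) {
    run_stage("simulate", {
      model <- simulate_genome_model(config$n_chrom, config$chrom_length,
                                     config$n_origins, config$efficiency,
                                     config$eff_params, seed = config$seed)
      fragments <- simulate_fragments(model, config$n_cells,
                                      config$fragments_per_cell,
                                      seed = config$seed + 1)
      chrom_sizes <- model$chromosomes
      peaks <- simulate_chip_peaks(model, seed = config$seed + 2)
      tc <- simulate_timecourse(model, seed = config$seed + 3)
      write_genome_model(model, file.path(out_dir, "truth_origins.tsv"),
                         file.path(out_dir, "chrom.sizes"))
      write_fragments_bed(fragments, file.path(out_dir, "fragments.bed"))
      write_peaks(peaks, file.path(out_dir, "peaks.narrowPeak"))
      write_matrix(tc, file.path(out_dir, "timecourse.tsv"))
      counts$fragments <- nrow(fragments)
      .log_stage(quiet, "simulate: %d fragments, %d origins (truth)",
                 nrow(fragments), nrow(model$origins))
      res$model <- model
    })
  } else {
    run_stage("load", {
      chrom_sizes <- read_chrom_sizes(inputs$chrom_sizes)
      if (!is.null(inputs$fragments))
        fragments <- read_fragments_bed(inputs$fragments)
      if (!is.null(inputs$peaks)) peaks <- read_peaks(inputs$peaks)
      if (!is.null(inputs$expression)) tc <- read_matrix(inputs$expression)
    })
  }

  origins <- NULL
  if ("call" %in% stages) {
    run_stage("call", {
      x <- if (!is.null(fragments)) {
        counts$fragments <- nrow(fragments)
        bin_fragments(fragments, chrom_sizes, config$bin_size)
      } else if (!is.null(inputs$watson)) {
        track_from_bedgraphs(inputs$watson, inputs$crick, chrom_sizes,
                             config$bin_size)
      } else stopf("no fragments or bedGraph pair available")
      origins <- map_origins(x, bin_size = config$bin_size,
                             smooth_window = config$smooth_window,
                             oem_window = config$oem_window,
                             threshold = config$threshold,
                             min_separation = config$min_separation,
                             efficiency_radius = config$efficiency_radius,
                             tz_radius = config$tz_radius)
      write_origins_bed(origins, file.path(out_dir, "origins.bed"),
                        halfwidth = config$origin_halfwidth)
      ss <- spacing_stats(origins)
      write.table(data.frame(stat = c("n_origins", "median_spacing_bp",
                                      "frac_within_100kb",
                                      "median_efficiency"),
                             value = c(nrow(origins), ss$median_spacing,
                                       ss$frac_within,
                                       median(origins$efficiency,
                                              na.rm = TRUE))),
                  file.path(out_dir, "spacing_stats.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      counts$origins <- nrow(origins)
      .log_stage(quiet, "call: %d origins (median spacing %.1f kb)",
                 nrow(origins), (ss$median_spacing %||% NA) / 1000)
      res$origins <- origins
    })
  }

  if ("assoc" %in% stages) {
    run_stage("assoc", {
      if (is.null(peaks)) stopf("no peaks available")
      if (is.null(origins)) stopf("assoc requires the call stage")
      pk <- filter_peaks(peaks, config$min_fold)
      grid <- association_grid(pk, origins,
                               origin_halfwidth = config$origin_halfwidth)
      write.table(cbind(intensity_bin = rownames(grid$counts), grid$counts),
                  file.path(out_dir, "association_grid.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      counts$peaks_filtered <- nrow(pk)
      .log_stage(quiet, "assoc: %d/%d peaks pass >%g-fold filter",
                 nrow(pk), nrow(peaks), config$min_fold)
      res$assoc <- grid
    })
  }

  if ("genes" %in% stages) {
    run_stage("genes", {
      gt <- if (!is.null(inputs$genes)) read_genes(inputs$genes)
      else if (!is.null(tc))
        structure(tc$genes[, c("gene_id", "chrom", "start", "end", "strand")],
                  class = c("gene_table", "data.frame"))
      else stopf("no gene table available")
      if (is.null(origins)) stopf("genes requires the call stage")
      ob <- orientation_bias(gt, origins, flank = config$flank)
      write.table(ob, file.path(out_dir, "orientation_bias.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$genes <- nrow(gt)
      .log_stage(quiet, "genes: %d genes profiled", nrow(gt))
      res$orientation <- ob
    })
  }

  if ("timecourse" %in% stages) {
    run_stage("timecourse", {
      if (is.null(tc)) stopf("no expression time course available")
      if (is.null(origins)) stopf("timecourse requires the call stage")
      tc <- normalize_timecourse(tc)
      tc <- classify_maternal(tc, config$k_clusters, seed = config$seed + 4)
      hm <- coupling_heatmap(tc, origins, top_n = config$top_n,
                             flank = config$flank)
      cs <- coupling_statistic(hm)
      write.table(cbind(timepoint = rownames(hm$matrix), hm$matrix),
                  file.path(out_dir, "coupling_heatmap.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(data.frame(timepoint = seq_along(cs), log2_prox_dist = cs),
                  file.path(out_dir, "coupling_statistic.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(tc$genes, file.path(out_dir, "gene_labels.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      counts$zygotic <- sum(tc$genes$label == "zygotic")
      .log_stage(quiet, "timecourse: %d maternal / %d zygotic genes",
                 sum(tc$genes$label == "maternal"), counts$zygotic)
      res$timecourse <- tc
      res$heatmap <- hm
      res$coupling <- cs
    })
  }

  sidecar <- list(tool = "okseqr",
                  version = as.character(utils::packageVersion("okseqr")),
                  config = unclass(config), config_hash = config_hash(config),
                  stages = stages, record_counts = counts,
                  fragment_anchor = "5prime")
  jsonlite::write_json(sidecar, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
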