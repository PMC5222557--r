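## Genomic format IO (BED6, narrowPeak, bedGraph, chrom.sizes, expression
## TSV) and fragment binning into stranded tracks. All internal coordinates
## are 0-based half-open, matching BED/bedGraph conventions. Reads are
## gzip-transparent (gzfile also handles plain text).

.read_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  con <- gzfile(path, "rt"); on.exit(close(con))
  readLines(con)
}

.split_fields <- function(lines, path, min_fields) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  short <- which(vapply(fields, length, 1L) < min_fields)
  if (length(short))
    stopf("%s line %d: expected >= %d tab-separated fields, got %d",
          path, lineno[short[1]], min_fields, length(fields[[short[1]]]))
  list(fields = fields, lineno = lineno)
}

.check_coords <- function(start, end, path, lineno) {
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stopf("%s line %d: non-numeric start/end", path, lineno[bad[1]])
  bad <- which(start >= end)
  if (length(bad))
    stopf("%s line %d: start (%d) must be < end (%d)",
          path, lineno[bad[1]], start[bad[1]], end[bad[1]])
  if (any(start < 0)) stopf("%s: negative start coordinate", path)
}

#' Read a chrom.sizes file
#' @param path two-column TSV (chromosome name, length in bp).
#' @return named numeric vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  p <- .split_fields(.read_lines(path), path, 2L)
  nm <- vapply(p$fields, `[[`, "", 1L)
  len <- as.numeric(vapply(p$fields, `[[`, "", 2L))
  if (any(is.na(len) | len <= 0)) stopf("%s: non-positive chromosome length", path)
  setNames(len, nm)
}

#' Read stranded Okazaki fragments from BED6
#'
#' Strand is essential for OK-seq: `"."` (and anything outside `+`/`-`)
#' is rejected with the offending line number.
#'
#' @param path BED6 file (gzip allowed).
#' @return a `fragment_set` data.frame (`chrom`, `start`, `end`, `strand`).
#' @export
read_fragments_bed <- function(path) {
  p <- .split_fields(.read_lines(path), path, 6L)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- as.integer(vapply(p$fields, `[[`, "", 2L))
  end <- as.integer(vapply(p$fields, `[[`, "", 3L))
  strand <- vapply(p$fields, `[[`, "", 6L)
  .check_coords(start, end, path, p$lineno)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stopf("%s line %d: fragment strand must be '+' or '-', got '%s'",
          path, p$lineno[bad[1]], strand[bad[1]])
  structure(data.frame(chrom = chrom, start = start, end = end,
                       strand = strand, stringsAsFactors = FALSE),
            class = c("fragment_set", "data.frame"))
}

#' Write fragments as BED6
#' @param fragments a `fragment_set`.
#' @param path output path.
#' @export
write_fragments_bed <- function(fragments, path) {
  df <- data.frame(fragments$chrom, fragments$start, fragments$end,
                   sprintf("frag_%d", seq_len(nrow(fragments))), 0L,
                   fragments$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ChIP peaks (narrowPeak or BED5+fold)
#'
#' ENCODE narrowPeak (10 columns; fold-enrichment in `signalValue`, summit
#' offset in column 10) or a 7-column BED variant with fold-enrichment in
#' column 7. No fold filtering happens at parse time; see
#' [filter_peaks()].
#'
#' @param path peak file.
#' @return a `peak_set` data.frame (`chrom`, `start`, `end`, `name`, `fold`,
#'   `summit`).
#' @export
read_peaks <- function(path) {
  p <- .split_fields(.read_lines(path), path, 7L)
  nf <- vapply(p$fields, length, 1L)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- as.integer(vapply(p$fields, `[[`, "", 2L))
  end <- as.integer(vapply(p$fields, `[[`, "", 3L))
  name <- vapply(p$fields, `[[`, "", 4L)
  fold <- as.numeric(vapply(p$fields, `[[`, "", 7L))
  summit <- ifelse(nf >= 10L,
                   as.integer(vapply(p$fields, function(f)
                     if (length(f) >= 10L) f[[10L]] else NA_character_, "")),
                   NA_integer_)
  .check_coords(start, end, path, p$lineno)
  bad <- which(is.na(fold) | fold < 0)
  if (length(bad))
    stopf("%s line %d: fold enrichment must be a non-negative number",
          path, p$lineno[bad[1]])
  structure(data.frame(chrom = chrom, start = start, end = end, name = name,
                       fold = fold, summit = summit, stringsAsFactors = FALSE),
            class = c("peak_set", "data.frame"))
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks a `peak_set`.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name, 0L, ".",
                   peaks$fold, -1, -1,
                   ifelse(is.na(peaks$summit), -1L, peaks$summit))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table from BED6
#' @param path BED6 file; column 4 is the gene id.
#' @return a `gene_table` data.frame
#'   (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_genes <- function(path) {
  p <- .split_fields(.read_lines(path), path, 6L)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- as.integer(vapply(p$fields, `[[`, "", 2L))
  end <- as.integer(vapply(p$fields, `[[`, "", 3L))
  id <- vapply(p$fields, `[[`, "", 4L)
  strand <- vapply(p$fields, `[[`, "", 6L)
  .check_coords(start, end, path, p$lineno)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stopf("%s line %d: gene strand must be '+' or '-', got '%s'",
          path, p$lineno[bad[1]], strand[bad[1]])
  structure(data.frame(gene_id = id, chrom = chrom, start = start, end = end,
                       strand = strand, stringsAsFactors = FALSE),
            class = c("gene_table", "data.frame"))
}

#' Write a gene table as BED6
#' @param genes a `gene_table`.
#' @param path output path.
#' @export
write_genes <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                   genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene x time-point expression matrix
#'
#' TSV with header; columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' optionally `class`, then the time points `t1..tN`.
#'
#' @param path TSV file.
#' @return an `expression_timecourse` (un-normalized).
#' @export
read_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta_cols <- intersect(c("gene_id", "chrom", "start", "end", "strand",
                           "class"), names(df))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(need %in% meta_cols))
    stopf("%s: missing required columns %s", path,
          paste(setdiff(need, meta_cols), collapse = ", "))
  tp_cols <- grep("^t[0-9]+$", names(df), value = TRUE)
  if (length(tp_cols) < 1L) stopf("%s: no time-point columns t1..tN", path)
  tp_cols <- tp_cols[order(as.integer(sub("^t", "", tp_cols)))]
  expr <- as.matrix(df[, tp_cols, drop = FALSE])
  if (!is.numeric(expr)) stopf("%s: non-numeric expression values", path)
  rownames(expr) <- df$gene_id
  genes <- df[, meta_cols, drop = FALSE]
  if (is.null(genes$class)) genes$class <- NA_character_
  structure(list(expr = expr, genes = genes, normalized = FALSE),
            class = "expression_timecourse")
}

#' Write an expression time course as TSV
#' @param tc an `expression_timecourse`.
#' @param path output path.
#' @export
write_matrix <- function(tc, path) {
  df <- cbind(tc$genes[, intersect(c("gene_id", "chrom", "start", "end",
                                     "strand", "class"), names(tc$genes))],
              as.data.frame(tc$expr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bin stranded fragments into a 100 bp stranded track
#'
#' Each fragment increments exactly one bin on its strand's counter: the
#' bin containing its 5' end (Watson fragments: `start`; Crick fragments:
#' `end - 1`). The 5' end marks the initiation point of each Okazaki
#' fragment, which is the convention for OK-seq strand profiles; this
#' choice is recorded in the track metadata.
#'
#' @param fragments a `fragment_set`.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp (default 100).
#' @return a `stranded_track`: per-chromosome Watson/Crick bin counts.
#' @export
bin_fragments <- function(fragments, chrom_sizes, bin_size = 100) {
  check_positive(bin_size, "bin_size")
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown))
    stopf("fragments on unknown chromosome(s): %s",
          paste(unknown, collapse = ", "))
  nb <- ceiling(chrom_sizes / bin_size)
  anchor <- ifelse(fragments$strand == "+", fragments$start,
                   fragments$end - 1)
  bin <- floor(anchor / bin_size) + 1L
  W <- C <- setNames(lapply(nb, function(n) integer(n)), names(chrom_sizes))
  for (cn in names(chrom_sizes)) {
    sel <- fragments$chrom == cn
    w <- sel & fragments$strand == "+"
    c_ <- sel & fragments$strand == "-"
    W[[cn]] <- tabulate(bin[w], nbins = nb[[cn]])
    C[[cn]] <- tabulate(bin[c_], nbins = nb[[cn]])
  }
  new_stranded_track(W, C, chrom_sizes, bin_size,
                     anchor = "5prime")
}

new_stranded_track <- function(W, C, chrom_sizes, bin_size,
                               anchor = "5prime", smoothed = FALSE) {
  structure(list(W = W, C = C, chrom_sizes = chrom_sizes,
                 bin_size = bin_size, anchor = anchor, smoothed = smoothed,
                 fW = NULL, fC = NULL),
            class = "stranded_track")
}

#' @export
print.stranded_track <- function(x, ...) {
  tot <- sum(vapply(x$W, sum, 0)) + sum(vapply(x$C, sum, 0))
  cat(sprintf("<stranded_track> %d chromosome(s), bin %d bp, %s counts%s%s\n",
              length(x$W), x$bin_size, format(tot, big.mark = ","),
              if (x$smoothed) ", smoothed" else "",
              if (!is.null(x$fW)) ", normalized" else ""))
  invisible(x)
}

## zero-coverage mask for one chromosome (raw counts)
track_mask <- function(track, chrom) {
  track$W[[chrom]] + track$C[[chrom]] == 0
}

#' Write a per-bin signal as bedGraph
#'
#' One record per run of constant value; NA bins are omitted.
#'
#' @param track a `stranded_track`.
#' @param path output path.
#' @param strand `"W"` or `"C"`: write that strand's counts;
#'   `"fW"` writes the normalized Watson fraction.
#' @export
write_bedgraph <- function(track, path, strand = c("W", "C", "fW", "fC")) {
  strand <- match.arg(strand)
  sig <- switch(strand, W = track$W, C = track$C, fW = track$fW, fC = track$fC)
  if (is.null(sig)) stopf("track has no %s signal (normalize first?)", strand)
  con <- file(path, "wt"); on.exit(close(con))
  for (cn in names(sig)) {
    v <- sig[[cn]]
    r <- rle(ifelse(is.na(v), NA_real_, v))
    endbin <- cumsum(r$lengths)
    startbin <- endbin - r$lengths
    keep <- !is.na(r$values)
    if (!any(keep)) next
    start <- startbin[keep] * track$bin_size
    end <- pmin(endbin[keep] * track$bin_size, track$chrom_sizes[[cn]])
    write.table(data.frame(cn, start, end, r$values[keep]), con, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph file
#' @param path bedGraph (gzip allowed).
#' @return data.frame (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  p <- .split_fields(.read_lines(path), path, 4L)
  chrom <- vapply(p$fields, `[[`, "", 1L)
  start <- as.numeric(vapply(p$fields, `[[`, "", 2L))
  end <- as.numeric(vapply(p$fields, `[[`, "", 3L))
  value <- as.numeric(vapply(p$fields, `[[`, "", 4L))
  .check_coords(start, end, path, p$lineno)
  if (anyNA(value)) stopf("%s: non-numeric bedGraph value", path)
  data.frame(chrom = chrom, start = start, end = end, value = value,
             stringsAsFactors = FALSE)
}

#' Build a stranded track from a Watson/Crick bedGraph pair
#'
#' For pre-binned coverage: each bedGraph record's value is assigned to all
#' bins it spans (values are per-bin counts, not re-scaled).
#'
#' @param watson_path,crick_path bedGraph files for the two strands.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param bin_size bin width in bp.
#' @return a `stranded_track`.
#' @export
track_from_bedgraphs <- function(watson_path, crick_path, chrom_sizes,
                                 bin_size = 100) {
  fill <- function(bg) {
    nb <- ceiling(chrom_sizes / bin_size)
    out <- setNames(lapply(nb, function(n) numeric(n)), names(chrom_sizes))
    unknown <- setdiff(unique(bg$chrom), names(chrom_sizes))
    if (length(unknown))
      stopf("bedGraph records on unknown chromosome(s): %s",
            paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(bg))) {
      b0 <- floor(bg$start[i] / bin_size) + 1L
      b1 <- ceiling(bg$end[i] / bin_size)
      out[[bg$chrom[i]]][b0:b1] <- bg$value[i]
    }
    out
  }
  new_stranded_track(fill(read_bedgraph(watson_path)),
                     fill(read_bedgraph(crick_path)),
                     chrom_sizes, bin_size)
}

#' Write origin calls as BED
#'
#' Each origin becomes a 5 kb interval centered on the midpoint (the
#' standard origin-window convention for downstream peak association), with
#' columns chrom, midpoint-2500, midpoint+2500, id, round(1000 x efficiency),
#' ".", efficiency, transition_zone_bp.
#'
#' @param origins an `origin_map` (or data.frame with `chrom`, `midpoint`,
#'   `efficiency`, `transition_zone`).
#' @param path output path.
#' @param halfwidth half-width of the written interval (default 2500 bp).
#' @export
write_origins_bed <- function(origins, path, halfwidth = 2500) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste0("#chrom\tstart\tend\tid\tscore\tstrand\t",
                    "efficiency\ttransition_zone"), con)
  if (nrow(origins) == 0L) return(invisible(path))
  eff <- origins$efficiency %||% rep(NA_real_, nrow(origins))
  tz <- origins$transition_zone %||% rep(NA_real_, nrow(origins))
  df <- data.frame(origins$chrom,
                   pmax(0, round(origins$midpoint - halfwidth)),
                   round(origins$midpoint + halfwidth),
                   sprintf("origin_%d", seq_len(nrow(origins))),
                   ifelse(is.na(eff), 0L, round(1000 * eff)), ".",
                   eff, tz)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read origin calls written by [write_origins_bed()]
#' @param path origins BED file.
#' @return an `origin_map` data.frame.
#' @export
read_origins_bed <- function(path) {
  lines <- .read_lines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(structure(data.frame(chrom = character(), midpoint = numeric(),
                                score = numeric(), efficiency = numeric(),
                                transition_zone = numeric()),
                     class = c("origin_map", "data.frame")))
  f <- strsplit(lines, "\t", fixed = TRUE)
  structure(data.frame(
    chrom = vapply(f, `[[`, "", 1L),
    midpoint = (as.numeric(vapply(f, `[[`, "", 2L)) +
                  as.numeric(vapply(f, `[[`, "", 3L))) / 2,
    score = NA_real_,
    efficiency = as.numeric(vapply(f, `[[`, "", 7L)),
    transition_zone = as.numeric(vapply(f, `[[`, "", 8L)),
    stringsAsFactors = FALSE), class = c("origin_map", "data.frame"))
}

#' Write a genome model's ground truth to disk
#'
#' TSV sidecar (chrom, pos, firing_probability) plus a chrom.sizes file.
#'
#' @param model a `genome_model`.
#' @param origins_path,sizes_path output paths.
#' @export
write_genome_model <- function(model, origins_path, sizes_path) {
  write.table(data.frame(chrom = model$origins$chrom, pos = model$origins$pos,
                         firing_probability = model$origins$efficiency),
              origins_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(names(model$chromosomes),
                         as.integer(model$chromosomes)),
              sizes_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(origins_path)
}
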