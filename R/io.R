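## File-format front doors. BED-family formats go through rtracklayer (which
## owns the 0-based conversion); BEDPE, sparse contact-matrix TSV and count
## tables are plain tables read/written here.

#' Read a peak set from BED or narrowPeak
#'
#' BED6 (or fewer columns) is read with `rtracklayer`; files ending in
#' `.narrowPeak` get the standard 4 extra columns (signalValue, pValue,
#' qValue, peak). Gzipped input is transparent. Peaks are returned sorted by
#' (chrom, start) with exact duplicate intervals removed; absent scores
#' default to 1.
#'
#' @param path BED/narrowPeak file, optionally gzipped.
#' @return `GRanges` sorted by position, with a `score` column.
#' @export
read_peaks_bed <- function(path) {
  if (grepl("\\.narrowPeak(\\.gz)?$", path)) {
    extra <- c(signalValue = "numeric", pValue = "numeric",
               qValue = "numeric", peak = "integer")
    gr <- rtracklayer::import(path, format = "BED", extraCols = extra)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
  }
  as_peak_set(gr)
}

#' Canonicalise a peak set
#'
#' Sorts by (chrom, start), drops exact duplicate spans and fills missing
#' scores with 1 (the default unit signal).
#'
#' @param gr a `GRanges`.
#' @return sorted, deduplicated `GRanges` with a `score` column.
#' @export
as_peak_set <- function(gr) {
  stopifnot(is(gr, "GRanges"))
  if (is.null(mcols(gr)$score) || all(is.na(mcols(gr)$score)))
    mcols(gr)$score <- 1
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  key <- paste(seqnames(gr), start(gr), end(gr))
  gr[!duplicated(key)]
}

#' Write a peak set as BED6
#'
#' @param peaks `GRanges`.
#' @param path output file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = if (!is.null(mcols(peaks)$name)) mcols(peaks)$name
                          else paste0("peak_", seq_along(peaks)),
                   score = if (!is.null(mcols(peaks)$score))
                             mcols(peaks)$score else 1,
                   strand = ifelse(as.character(strand(peaks)) == "*", ".",
                                   as.character(strand(peaks))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track into fixed-width bins
#'
#' Interval values are distributed over the bins they cover proportionally to
#' the overlap, i.e. each bin holds the coverage-weighted sum of track values
#' divided by the bin width (uncovered stretches count as 0 signal).
#'
#' @param path bedGraph file, optionally gzipped.
#' @param binsize bin width in bp (default 1000).
#' @return a binned-track `data.frame` (see [binned_track()]).
#' @export
read_bedgraph_track <- function(path, binsize = 1000L) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  s0 <- start(gr) - 1L; e0 <- end(gr); val <- mcols(gr)$score
  chrom <- as.character(seqnames(gr))
  first <- s0 %/% binsize; last <- (e0 - 1L) %/% binsize
  n <- last - first + 1L
  bins <- unlist(lapply(seq_along(s0),
                        function(i) seq.int(first[i], last[i])))
  idx <- rep(seq_along(s0), n)
  bs <- pmax(bins * binsize, s0[idx])
  be <- pmin((bins + 1L) * binsize, e0[idx])
  contrib <- val[idx] * (be - bs) / binsize
  agg <- stats::aggregate(contrib,
                          by = list(chrom = chrom[idx], bin = bins),
                          FUN = sum)
  binned_track(agg$chrom, agg$bin, agg$x, binsize)
}

#' Construct a binned signal track
#'
#' A binned track is a `data.frame` with columns `chrom`, `bin` (0-based bin
#' index) and `value`, plus a `binsize` attribute; bins absent from the table
#' carry value 0.
#'
#' @param chrom,bin,value equal-length vectors.
#' @param binsize bin width in bp.
#' @return `data.frame` with attribute `binsize`.
#' @export
binned_track <- function(chrom, bin, value, binsize) {
  stopifnot(binsize > 0, all(is.finite(value)))
  df <- data.frame(chrom = as.character(chrom), bin = as.integer(bin),
                   value = as.numeric(value))
  df <- df[order(df$chrom, df$bin), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "binsize") <- as.integer(binsize)
  df
}

#' Read / write chromatin loops in BEDPE
#'
#' 10-column BEDPE (chrom1, start1, end1, chrom2, start2, end2, name, score,
#' strand1, strand2) with an optional 11th raw-count column. Only
#' intra-chromosomal loops are accepted; anchors must have width equal to
#' `resolution` and anchor1 must start before anchor2.
#'
#' @param path BEDPE file, optionally gzipped.
#' @param resolution anchor width in bp (default 5000).
#' @return a loop `data.frame` (columns `chrom`, `start1`, `end1`, `start2`,
#'   `end2`, `name`, `count`; 0-based half-open anchors) with attribute
#'   `resolution`.
#' @export
read_loops_bedpe <- function(path, resolution = 5000L) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 6) stop("BEDPE needs at least 6 columns")
  loops <- data.frame(chrom = df[[1]], start1 = df[[2]], end1 = df[[3]],
                      start2 = df[[5]], end2 = df[[6]],
                      name = if (ncol(df) >= 7) df[[7]]
                             else paste0("loop_", seq_len(nrow(df))),
                      count = if (ncol(df) >= 11) df[[11]] else NA_real_)
  if (!all(df[[4]] == df[[1]])) stop("only intra-chromosomal loops supported")
  validate_loops(loops, resolution)
}

#' @rdname read_loops_bedpe
#' @param loops a loop `data.frame`.
#' @export
validate_loops <- function(loops, resolution = attr(loops, "resolution")) {
  need <- c("chrom", "start1", "end1", "start2", "end2")
  if (!all(need %in% names(loops))) stop("loops need columns: ",
                                         paste(need, collapse = ", "))
  if (is.null(resolution)) stop("loop resolution not set")
  if (any(loops$end1 - loops$start1 != resolution) ||
      any(loops$end2 - loops$start2 != resolution))
    stop("anchor widths must equal the resolution (", resolution, " bp)")
  if (any(loops$start1 >= loops$start2))
    stop("anchor1 must be upstream of anchor2")
  if (is.null(loops$name)) loops$name <- paste0("loop_", seq_len(nrow(loops)))
  if (is.null(loops$count)) loops$count <- NA_real_
  rownames(loops) <- NULL
  attr(loops, "resolution") <- as.integer(resolution)
  loops
}

#' @rdname read_loops_bedpe
#' @export
write_loops_bedpe <- function(loops, path) {
  loops <- validate_loops(loops)
  df <- data.frame(loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2,
                   loops$name, 0, ".", ".",
                   ifelse(is.na(loops$count), ".",
                          as.character(loops$count)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' One anchor of each loop as a GRanges
#'
#' @param loops loop `data.frame`.
#' @param which `1` or `2` for the upstream/downstream anchor.
#' @return `GRanges` of anchors, in loop order.
#' @export
loop_anchors <- function(loops, which = 1L) {
  stopifnot(which %in% c(1L, 2L))
  if (nrow(loops) == 0L) return(GRanges())
  if (which == 1L) granges0(loops$chrom, loops$start1, loops$end1)
  else granges0(loops$chrom, loops$start2, loops$end2)
}

#' Read / write a gene-by-sample count matrix
#'
#' TSV with a header of sample names and gene ids in the first column.
#'
#' @param path TSV file, optionally gzipped.
#' @return integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_counts
#' @param counts matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an external differential-expression table
#'
#' Accepts tables produced by an external DE tool so the target-classification
#' chain can run on published outputs: TSV with columns `gene_id`, `log2fc`,
#' and `p_adj` (a `p` column is optional).
#'
#' @param path TSV file.
#' @param lfc_threshold,alpha thresholds used to call the `direction` column;
#'   set `alpha = NULL` to threshold on fold change only.
#' @return a DE `data.frame` as produced by [differential_expression()].
#' @export
read_de_table <- function(path, lfc_threshold = 0.5, alpha = 0.05) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "p_adj")
  if (!all(need %in% names(df))) stop("DE table needs columns: ",
                                      paste(need, collapse = ", "))
  if (is.null(df$p)) df$p <- df$p_adj
  pass <- if (is.null(alpha)) rep(TRUE, nrow(df)) else df$p_adj < alpha
  df$direction <- ifelse(pass & df$log2fc > lfc_threshold, "up",
                  ifelse(pass & df$log2fc < -lfc_threshold, "down", "ns"))
  df[c("gene_id", "log2fc", "p", "p_adj", "direction")]
}
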