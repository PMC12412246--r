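#' Compare two peak sets (Venn-style sharing)
#'
#' A peak of one set is *shared* iff it overlaps at least one peak of the
#' other set by `min_bp` or more. Because overlaps are many-to-many the
#' shared counts are reported from each side separately, together with the
#' size of the merged union of both sets.
#'
#' @param a,b `GRanges` peak sets.
#' @param min_bp minimum overlap (default 1).
#' @return list with `shared_a`, `shared_b`, `unique_a`, `unique_b`,
#'   `n_a`, `n_b`, `n_union_merged`.
#' @export
compare_peak_sets <- function(a, b, min_bp = 1L) {
  sl <- union(seqlevels(a), seqlevels(b))
  seqlevels(a) <- sl
  seqlevels(b) <- sl
  sa <- countOverlaps(a, b, minoverlap = min_bp, ignore.strand = TRUE) > 0
  sb <- countOverlaps(b, a, minoverlap = min_bp, ignore.strand = TRUE) > 0
  list(shared_a = sum(sa), shared_b = sum(sb),
       unique_a = sum(!sa), unique_b = sum(!sb),
       n_a = length(a), n_b = length(b),
       n_union_merged = length(reduce(c(granges(a), granges(b)))))
}

#' @importFrom GenomicRanges granges
NULL

#' Pearson correlation between two binned signal tracks
#'
#' Computed over the union of bins touched by either track (a bin absent from
#' one track contributes 0 there), optionally restricted to bins overlapping
#' a region set. At least 3 bins are required.
#'
#' @param a,b binned tracks (see [binned_track()]) with equal `binsize`.
#' @param regions optional `GRanges`; only bins overlapping these regions are
#'   used.
#' @return Pearson r.
#' @export
signal_correlation <- function(a, b, regions = NULL) {
  bs <- attr(a, "binsize")
  if (is.null(bs) || !identical(bs, attr(b, "binsize")))
    stop("tracks must carry the same binsize")
  key_a <- paste(a$chrom, a$bin); key_b <- paste(b$chrom, b$bin)
  keys <- union(key_a, key_b)
  va <- a$value[match(keys, key_a)]; va[is.na(va)] <- 0
  vb <- b$value[match(keys, key_b)]; vb[is.na(vb)] <- 0
  if (!is.null(regions)) {
    parts <- strsplit(keys, " ", fixed = TRUE)
    chrom <- vapply(parts, `[`, "", 1L)
    bin <- as.integer(vapply(parts, `[`, "", 2L))
    gr <- granges0(chrom, bin * bs, (bin + 1L) * bs)
    keep <- overlapsAny(gr, regions, ignore.strand = TRUE)
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 3L) stop("need at least 3 bins to correlate")
  stats::cor(va, vb)
}

#' Genomic feature distribution of a peak set
#'
#' Applies [annotate_peaks()] to every peak and tabulates category fractions
#' (they sum to 1).
#'
#' @inheritParams annotate_peaks
#' @return named numeric vector of fractions over all feature categories.
#' @export
genomic_distribution <- function(peaks, genes, promoter_up = 2000L,
                                 promoter_down = 2000L,
                                 downstream_bp = 3000L) {
  if (length(peaks) == 0L) stop("empty peak set")
  ann <- annotate_peaks(peaks, genes, promoter_up, promoter_down,
                        downstream_bp)
  tab <- table(ann) / length(peaks)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Fraction of G4 peaks co-bound by each transcription factor
#'
#' For each TF set, the fraction of G4 peaks overlapped by at least one TF
#' peak (by `min_bp` or more). Fractions are independent across TFs and need
#' not sum to 1.
#'
#' @param g4 `GRanges` of G4 peaks.
#' @param tf_sets named list of `GRanges`.
#' @param min_bp minimum overlap (default 1).
#' @return named numeric vector, one fraction per TF.
#' @export
tf_overlap_fractions <- function(g4, tf_sets, min_bp = 1L) {
  if (length(tf_sets) == 0L) stop("need at least one TF set")
  vapply(tf_sets, function(tf) {
    if (length(tf) == 0L || length(g4) == 0L) return(0)
    mean(countOverlaps(g4, tf, minoverlap = min_bp,
                       ignore.strand = TRUE) > 0)
  }, 0)
}
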