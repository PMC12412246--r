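#' @import methods
#' @importFrom GenomicRanges GRanges findOverlaps countOverlaps reduce seqnames
#'   start end width strand pintersect
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits DataFrame
#' @importFrom GenomeInfoDb seqlevels seqlevels<- seqlengths
NULL

## All in-memory intervals are GRanges (1-based, closed); every file-facing
## reader/writer converts from/to the 0-based half-open BED convention.

#' Build a GRanges from 0-based half-open coordinates
#'
#' Convenience constructor used throughout the package (and its tests) so that
#' coordinates can be written down in the BED convention the input files use.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 integer vectors, 0-based half-open (`end0 > start0 >= 0`).
#' @param strand strand codes (`+`, `-` or `.`/`*`); `.` is mapped to `*`.
#' @param score optional numeric signal, stored in `mcols()$score`.
#' @param name optional interval names.
#' @return a `GRanges`.
#' @export
granges0 <- function(chrom, start0, end0, strand = "*", score = NULL, name = NULL) {
  start0 <- as.numeric(start0); end0 <- as.numeric(end0)
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be non-empty")
  if (any(start0 < 0) || any(end0 <= start0))
    stop("invalid interval: require end > start >= 0 (0-based half-open)")
  strand <- ifelse(strand == ".", "*", strand)
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = strand)
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

#' Pairwise interval overlap with a minimum-width requirement
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @param min_bp minimum overlap in bp for a `TRUE` verdict (default 1).
#' @return logical vector; symmetric in `a` and `b`.
#' @export
overlaps <- function(a, b, min_bp = 1L) {
  stopifnot(is(a, "GRanges"), is(b, "GRanges"), min_bp >= 1)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have equal length")
  }
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= min_bp
}

#' Read or validate a gene-model table
#'
#' Gene models are a plain table with columns `gene_id`, `chrom`, `strand`
#' (`+`/`-`), `tss`, `start`, `end` (all coordinates 0-based; `start`/`end`
#' half-open gene body) and optionally `exon_starts`/`exon_ends`
#' (comma-separated 0-based block coordinates, BED12-style). The TSS must equal
#' `start` on the plus strand and `end - 1` on the minus strand.
#'
#' @param path TSV file (optionally gzipped) with a header row.
#' @return a validated `data.frame` of gene models.
#' @export
read_gene_models <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  validate_gene_models(df)
}

#' @rdname read_gene_models
#' @param genes a gene-model `data.frame` to validate.
#' @export
validate_gene_models <- function(genes) {
  need <- c("gene_id", "chrom", "strand", "tss", "start", "end")
  if (!all(need %in% names(genes)))
    stop("gene models need columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (any(genes$end <= genes$start)) stop("gene body must have end > start")
  plus <- genes$strand == "+"
  if (any(genes$tss[plus] != genes$start[plus]) ||
      any(genes$tss[!plus] != genes$end[!plus] - 1))
    stop("tss must be span start (+) or span end - 1 (-)")
  genes
}

#' @rdname read_gene_models
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Strand-aware promoter windows around the TSS
#'
#' The window contains the TSS base plus `upstream` bases 5' of it and
#' `downstream - 1` bases 3' of it, in gene orientation, so that plus- and
#' minus-strand windows of mirror-image genes are mirror images. In 0-based
#' half-open coordinates this is `[tss - upstream, tss + downstream)` on the
#' plus strand and `[tss - downstream + 1, tss + upstream + 1)` on the minus
#' strand. Windows are clipped at position 0.
#'
#' @param genes gene-model `data.frame` (see [read_gene_models()]).
#' @param upstream,downstream non-negative window extents in bp
#'   (default 2000/2000, the -2 kb..+2 kb display convention around the TSS).
#' @return a `GRanges` with one window per gene (`mcols()$gene_id`).
#' @export
promoter_windows <- function(genes, upstream = 2000L, downstream = 2000L) {
  genes <- validate_gene_models(genes)
  if (upstream < 0 || downstream < 0) stop("window extents must be >= 0")
  if (upstream + downstream <= 0) stop("promoter window has non-positive width")
  plus <- genes$strand == "+"
  s0 <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  e0 <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  s0 <- pmax(s0, 0)
  granges0(genes$chrom, s0, e0, strand = genes$strand, name = genes$gene_id)
}

.exon_granges <- function(genes) {
  if (!all(c("exon_starts", "exon_ends") %in% names(genes)))
    return(granges0(genes$chrom, genes$start, genes$end, name = genes$gene_id))
  es <- strsplit(as.character(genes$exon_starts), ",")
  ee <- strsplit(as.character(genes$exon_ends), ",")
  n <- lengths(es)
  granges0(rep(genes$chrom, n), as.numeric(unlist(es)), as.numeric(unlist(ee)),
           name = rep(genes$gene_id, n))
}

#' Feature-category annotation of peaks by midpoint
#'
#' Assigns each peak the single highest-priority feature category whose region
#' contains the peak midpoint: Promoter > Exon > Intron > Downstream >
#' DistalIntergenic ("Downstream" = up to `downstream_bp` past the gene 3'
#' end). Ties between genes at the same priority are broken by the smallest
#' midpoint-to-TSS distance, then lexicographic `gene_id`. A `FivePrimeUTR`
#' level is reserved in the factor but never assigned (transcript models carry
#' no UTR resolution).
#'
#' @param peaks `GRanges` of peaks.
#' @param genes gene-model `data.frame`; an empty table maps every peak to
#'   `DistalIntergenic`.
#' @param promoter_up,promoter_down promoter window extents (bp).
#' @param downstream_bp extent of the downstream category past the 3' end.
#' @return factor of categories, one per peak, with levels
#'   `Promoter, FivePrimeUTR, Exon, Intron, Downstream, DistalIntergenic`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_up = 2000L,
                           promoter_down = 2000L, downstream_bp = 3000L) {
  lev <- c("Promoter", "FivePrimeUTR", "Exon", "Intron", "Downstream",
           "DistalIntergenic")
  if (length(peaks) == 0L) return(factor(character(), levels = lev))
  ## midpoint of the 0-based half-open span, as a width-1 range
  mid0 <- floor((start(peaks) - 1 + end(peaks)) / 2)
  mids <- GRanges(seqnames(peaks), IRanges(mid0 + 1, mid0 + 1))
  if (is.null(genes) || nrow(genes) == 0L)
    return(factor(rep("DistalIntergenic", length(peaks)), levels = lev))
  genes <- validate_gene_models(genes)
  prom <- promoter_windows(genes, promoter_up, promoter_down)
  body <- granges0(genes$chrom, genes$start, genes$end, name = genes$gene_id)
  exon <- .exon_granges(genes)
  plus <- genes$strand == "+"
  ds0 <- ifelse(plus, genes$end, pmax(genes$start - downstream_bp, 0))
  de0 <- ifelse(plus, genes$end + downstream_bp, genes$start)
  keep <- de0 > ds0
  down <- granges0(genes$chrom[keep], ds0[keep], de0[keep],
                   name = genes$gene_id[keep])
  cat_regions <- list(Promoter = prom, Exon = exon, Intron = body,
                      Downstream = down)
  prio <- rep(NA_integer_, length(peaks))
  gene_of <- rep(NA_character_, length(peaks))
  tss_by_gene <- stats::setNames(genes$tss, genes$gene_id)
  for (k in seq_along(cat_regions)) {
    hits <- findOverlaps(mids, cat_regions[[k]], ignore.strand = TRUE)
    if (length(hits) == 0L) next
    qh <- queryHits(hits); sh <- subjectHits(hits)
    gid <- mcols(cat_regions[[k]])$name[sh]
    d <- abs(mid0[qh] - tss_by_gene[gid])
    ord <- order(qh, d, gid)
    qh <- qh[ord]; gid <- gid[ord]
    first <- !duplicated(qh)
    sel <- qh[first]
    new <- is.na(prio[sel])
    prio[sel[new]] <- k
    gene_of[sel[new]] <- gid[first][new]
  }
  labs <- c("Promoter", "Exon", "Intron", "Downstream")[prio]
  labs[is.na(labs)] <- "DistalIntergenic"
  out <- factor(labs, levels = lev)
  names(out) <- names(peaks)
  attr(out, "gene_id") <- gene_of
  out
}
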