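#' Median-of-ratios library size factors
#'
#' Per-sample size factors computed as the median across genes of the ratio
#' between the sample's count and the gene's geometric mean, using only genes
#' with no zero count.
#'
#' @param counts gene-by-sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
size_factors_mor <- function(counts) {
  use <- rowSums(counts == 0) == 0
  if (!any(use)) stop("no gene is expressed in every sample")
  lg <- rowMeans(log(counts[use, , drop = FALSE]))
  apply(counts[use, , drop = FALSE], 2,
        function(x) exp(stats::median(log(x) - lg)))
}

#' Differential expression between two groups (stand-in test)
#'
#' A documented stand-in for a dedicated count-based DE tool, not a
#' re-implementation of one: counts are normalised with median-of-ratios size
#' factors, log2(CPM + 1) values are tested per gene between the two groups,
#' and p-values are Benjamini-Hochberg adjusted. With
#' `method = "moderated"` (the default) the test is a moderated t-statistic
#' with an intensity-dependent variance prior fitted across genes
#' (limma-trend), which keeps the test calibrated and powered at the small
#' replicate numbers (2-3 per group) this package targets; `method = "welch"`
#' is a plain per-gene Welch t-test. Log2 fold changes are computed from the
#' normalised group means. A gene is called `up` if `log2fc > lfc_threshold`
#' and `p_adj < alpha` (mirrored for `down`); with `p_filter = FALSE` only
#' the fold-change threshold is applied.
#'
#' @param counts non-negative integer gene-by-sample matrix with rownames.
#' @param groups factor/character of length `ncol(counts)` with exactly two
#'   levels and at least two samples per level; the second level is the
#'   numerator of the fold change.
#' @param lfc_threshold absolute log2 fold-change threshold (default 0.5).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param method `"moderated"` (limma-trend) or `"welch"`.
#' @param p_filter if `FALSE`, call DEGs on fold change alone.
#' @return `data.frame` with columns `gene_id`, `log2fc`, `p`, `p_adj`,
#'   `direction` (`up`/`down`/`ns`).
#' @export
differential_expression <- function(counts, groups, lfc_threshold = 0.5,
                                    alpha = 0.05,
                                    method = c("moderated", "welch"),
                                    p_filter = TRUE) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  ## reference level = first factor level (or first appearance)
  groups <- if (is.factor(groups)) droplevels(groups)
            else factor(groups, levels = unique(groups))
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 samples")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  sf <- size_factors_mor(counts)
  q <- sweep(counts, 2, sf, "/")
  cpm <- sweep(q, 2, colSums(q), "/") * 1e6
  y <- log2(cpm + 1)
  g1 <- groups == levels(groups)[1]
  g2 <- groups == levels(groups)[2]
  if (method == "welch") {
    m1 <- rowMeans(y[, g1, drop = FALSE])
    m2 <- rowMeans(y[, g2, drop = FALSE])
    v1 <- apply(y[, g1, drop = FALSE], 1, stats::var)
    v2 <- apply(y[, g2, drop = FALSE], 1, stats::var)
    n1 <- sum(g1); n2 <- sum(g2)
    se2 <- v1 / n1 + v2 / n2
    tt <- (m2 - m1) / sqrt(se2)
    dfree <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), dfree)
    p[!is.finite(p)] <- 1
  } else {
    design <- cbind(intercept = 1, diff = as.numeric(g2))
    use <- rowSums(counts) > 0   # degenerate genes would distort the prior
    fit <- limma::eBayes(limma::lmFit(y[use, , drop = FALSE], design),
                         trend = TRUE)
    p <- rep(1, nrow(y))
    p[use] <- fit$p.value[, "diff"]
  }
  lfc <- log2((rowMeans(q[, g2, drop = FALSE]) + 0.5) /
                (rowMeans(q[, g1, drop = FALSE]) + 0.5))
  allzero <- rowSums(counts) == 0
  p[allzero] <- 1
  lfc[allzero] <- 0
  p_adj <- stats::p.adjust(p, "BH")
  pass <- if (p_filter) p_adj < alpha else rep(TRUE, length(p))
  direction <- ifelse(pass & lfc > lfc_threshold, "up",
               ifelse(pass & lfc < -lfc_threshold, "down", "ns"))
  direction[allzero] <- "ns"
  data.frame(gene_id = rownames(counts), log2fc = lfc, p = p, p_adj = p_adj,
             direction = direction, row.names = NULL)
}

#' Genes gaining a promoter G4 peak between two stages
#'
#' A gene shows promoter G4 *gain* if its promoter window overlaps at least
#' one stage-2 peak and no stage-1 peak.
#'
#' @param peaks_stage1,peaks_stage2 `GRanges` peak sets for the two stages.
#' @param genes gene-model `data.frame`.
#' @param promoter_up,promoter_down promoter window extents (bp).
#' @param min_bp minimum overlap (default 1).
#' @return character vector of gene ids.
#' @export
promoter_g4_gain <- function(peaks_stage1, peaks_stage2, genes,
                             promoter_up = 2000L, promoter_down = 2000L,
                             min_bp = 1L) {
  prom <- promoter_windows(genes, promoter_up, promoter_down)
  in2 <- countOverlaps(prom, peaks_stage2, minoverlap = min_bp,
                       ignore.strand = TRUE) > 0
  in1 <- countOverlaps(prom, peaks_stage1, minoverlap = min_bp,
                       ignore.strand = TRUE) > 0
  genes$gene_id[in2 & !in1]
}

#' Classify promoter-G4 genes by stage differential expression
#'
#' `G4_up` = genes with promoter G4 gain that are significantly upregulated
#' between the stages; `G4_down` = gain genes significantly downregulated.
#'
#' @param g4_gain_gene_ids character vector from [promoter_g4_gain()].
#' @param de_stage DE table for stage 2 vs stage 1
#'   (see [differential_expression()]).
#' @return list with `g4_up` and `g4_down` gene-id vectors.
#' @export
classify_promoter_g4_genes <- function(g4_gain_gene_ids, de_stage) {
  list(g4_up = sort(intersect(g4_gain_gene_ids,
                              de_stage$gene_id[de_stage$direction == "up"])),
       g4_down = sort(intersect(g4_gain_gene_ids,
                                de_stage$gene_id[de_stage$direction == "down"])))
}

#' Call bona fide G4 targets from the ligand-perturbation contrast
#'
#' `G4_activated` = G4-up genes downregulated by the G4-stabilising ligand;
#' `G4_repressed` = G4-down genes upregulated by it. By construction
#' `G4_activated` is a subset of the G4-up set and `G4_repressed` of the
#' G4-down set.
#'
#' @param g4_up,g4_down gene-id vectors from [classify_promoter_g4_genes()].
#' @param de_pds DE table for ligand vs vehicle.
#' @return list with `g4_activated` and `g4_repressed` gene-id vectors.
#' @export
call_bona_fide_targets <- function(g4_up, g4_down, de_pds) {
  list(g4_activated = sort(intersect(g4_up,
                             de_pds$gene_id[de_pds$direction == "down"])),
       g4_repressed = sort(intersect(g4_down,
                             de_pds$gene_id[de_pds$direction == "up"])))
}

#' Per-gene target-class labels from the full classification chain
#'
#' Combines [classify_promoter_g4_genes()] and [call_bona_fide_targets()]
#' into a single label per gene: bona fide labels (`G4_activated`,
#' `G4_repressed`) take precedence over the stage labels (`G4_up`,
#' `G4_down`); all other genes are `none`.
#'
#' @param gene_ids all gene ids to label.
#' @param g4_up,g4_down,g4_activated,g4_repressed gene-id vectors.
#' @return `data.frame` with `gene_id` and `label`.
#' @export
target_class_table <- function(gene_ids, g4_up, g4_down, g4_activated,
                               g4_repressed) {
  lab <- rep("none", length(gene_ids))
  lab[gene_ids %in% g4_up] <- "G4_up"
  lab[gene_ids %in% g4_down] <- "G4_down"
  lab[gene_ids %in% g4_activated] <- "G4_activated"
  lab[gene_ids %in% g4_repressed] <- "G4_repressed"
  data.frame(gene_id = gene_ids,
             label = factor(lab, levels = c("G4_up", "G4_down",
                                            "G4_activated", "G4_repressed",
                                            "none")))
}
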