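#' Classify loops by G4 occupancy of their anchors
#'
#' `dual_G4` if both anchors overlap at least one G4 peak (by `min_bp`),
#' `single_G4` if exactly one does, `no_G4` otherwise. The three counts
#' partition the loop set; classification is invariant to swapping the
#' anchors.
#'
#' @param loops loop `data.frame` (see [read_loops_bedpe()]).
#' @param g4 `GRanges` of G4 peaks.
#' @param min_bp minimum anchor-peak overlap (default 1).
#' @return list with `class` (factor per loop, levels `dual_G4`,
#'   `single_G4`, `no_G4`) and `counts`.
#' @export
classify_loop_anchors <- function(loops, g4, min_bp = 1L) {
  lev <- c("dual_G4", "single_G4", "no_G4")
  a1 <- countOverlaps(loop_anchors(loops, 1L), g4, minoverlap = min_bp,
                      ignore.strand = TRUE) > 0
  a2 <- countOverlaps(loop_anchors(loops, 2L), g4, minoverlap = min_bp,
                      ignore.strand = TRUE) > 0
  cls <- factor(lev[3L - (a1 + a2)], levels = lev)
  list(class = cls, counts = table(cls))
}

#' Promoter/enhancer typing of loop anchors
#'
#' Each anchor is labelled `P` if it overlaps a promoter element (P wins ties
#' with E), `E` if it overlaps an enhancer only, and unlabelled otherwise;
#' the loop type is the unordered pair: `P-P`, `E-P`, `E-E` or `other`.
#' Promoter and enhancer sets are expected to be disjoint (enhancers are
#' typically acetylation peaks outside promoter windows).
#'
#' @param loops loop `data.frame`.
#' @param promoters,enhancers `GRanges` element sets.
#' @param min_bp minimum overlap (default 1).
#' @return factor per loop with levels `P-P`, `E-P`, `E-E`, `other`.
#' @export
loop_ep_type <- function(loops, promoters, enhancers, min_bp = 1L) {
  lab <- function(anchors) {
    p <- countOverlaps(anchors, promoters, minoverlap = min_bp,
                       ignore.strand = TRUE) > 0
    e <- countOverlaps(anchors, enhancers, minoverlap = min_bp,
                       ignore.strand = TRUE) > 0
    ifelse(p, "P", ifelse(e, "E", "N"))
  }
  l1 <- lab(loop_anchors(loops, 1L)); l2 <- lab(loop_anchors(loops, 2L))
  pair <- paste(pmin(l1, l2), pmax(l1, l2), sep = "")
  type <- ifelse(pair == "PP", "P-P",
          ifelse(pair == "EP", "E-P",
          ifelse(pair == "EE", "E-E", "other")))
  factor(type, levels = c("P-P", "E-P", "E-E", "other"))
}

#' Stratify gene expression by the G4 loop class of the promoter
#'
#' A gene belongs to a loop class if its promoter window overlaps an anchor
#' of a loop of that class; genes appearing in several classes are assigned
#' the highest (dual_G4 > single_G4 > no_G4). Returns per-class gene sets,
#' expression medians and pairwise Wilcoxon rank-sum p-values.
#'
#' @param loops loop `data.frame`.
#' @param classes loop classes (factor/character parallel to `loops`).
#' @param genes gene-model `data.frame`.
#' @param expression named numeric vector of per-gene expression values
#'   (names = `gene_id`); must be finite.
#' @param promoter_up,promoter_down promoter window extents (bp).
#' @param min_bp minimum promoter-anchor overlap (default 1).
#' @return list with `assignment` (`data.frame` of gene_id, class), `n`,
#'   `medians`, `pairwise` rank-sum table.
#' @export
stratify_expression_by_loop_class <- function(loops, classes, genes,
                                              expression,
                                              promoter_up = 2000L,
                                              promoter_down = 2000L,
                                              min_bp = 1L) {
  stopifnot(all(is.finite(expression)))
  lev <- c("dual_G4", "single_G4", "no_G4")
  classes <- as.character(classes)
  prom <- promoter_windows(genes, promoter_up, promoter_down)
  best <- rep(NA_integer_, nrow(genes))
  for (k in seq_along(lev)) {
    sel <- which(classes == lev[k])
    if (!length(sel)) next
    anc <- c(loop_anchors(loops[sel, , drop = FALSE], 1L),
             loop_anchors(loops[sel, , drop = FALSE], 2L))
    hit <- countOverlaps(prom, anc, minoverlap = min_bp,
                         ignore.strand = TRUE) > 0
    best[hit & is.na(best)] <- k
  }
  assigned <- !is.na(best)
  assignment <- data.frame(gene_id = genes$gene_id[assigned],
                           class = factor(lev[best[assigned]], levels = lev))
  expr <- expression[assignment$gene_id]
  med <- tapply(expr, assignment$class, stats::median)
  pairs <- t(utils::combn(lev, 2))
  pv <- apply(pairs, 1, function(p) {
    x <- expr[assignment$class == p[1]]; y <- expr[assignment$class == p[2]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    stats::wilcox.test(x, y)$p.value
  })
  list(assignment = assignment, n = table(assignment$class), medians = med,
       pairwise = data.frame(class_a = pairs[, 1], class_b = pairs[, 2],
                             p = pv))
}
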