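#' Binned contact matrix (sparse, symmetric)
#'
#' Stores per-chromosome upper-triangle pixels (`bin1 <= bin2`, 0-based bin
#' indices) of a symmetric binned contact map. Duplicate pixels are summed;
#' pixels given with `bin1 > bin2` are mirrored into the upper triangle.
#'
#' @param pixels `data.frame` with columns `chrom`, `bin1`, `bin2`, `count`.
#' @param binsize bin width in bp.
#' @param sizes named integer vector of chromosome sizes in bp.
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(pixels, binsize, sizes) {
  stopifnot(all(c("chrom", "bin1", "bin2", "count") %in% names(pixels)),
            binsize > 0, !is.null(names(sizes)))
  if (any(pixels$count < 0)) stop("counts must be >= 0")
  if (!all(pixels$chrom %in% names(sizes)))
    stop("pixel chromosome absent from sizes")
  i <- pmin(pixels$bin1, pixels$bin2)
  j <- pmax(pixels$bin1, pixels$bin2)
  nb <- ceiling(sizes / binsize)
  if (any(j >= nb[pixels$chrom])) stop("bin index outside chromosome")
  key <- paste(pixels$chrom, i, j)
  first <- which(!duplicated(key))
  idx <- match(key, key[first])
  cnt <- rowsum(as.numeric(pixels$count), idx)[, 1]
  px <- data.frame(chrom = as.character(pixels$chrom[first]),
                   bin1 = as.integer(i[first]), bin2 = as.integer(j[first]),
                   count = as.numeric(cnt))
  px <- px[px$count > 0, , drop = FALSE]
  px <- px[order(px$chrom, px$bin1, px$bin2), , drop = FALSE]
  rownames(px) <- NULL
  structure(list(binsize = as.integer(binsize),
                 sizes = stats::setNames(as.numeric(sizes), names(sizes)),
                 pixels = px),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("contact_matrix:", length(x$sizes), "chromosome(s),",
      x$binsize, "bp bins,", nrow(x$pixels), "non-zero pixels, total",
      format(sum(x$pixels$count), big.mark = ","), "counts\n")
  invisible(x)
}

#' Total counts in a contact matrix
#' @param cm a `contact_matrix`.
#' @export
total_counts <- function(cm) sum(cm$pixels$count)

#' Read / write a sparse contact matrix
#'
#' Upper-triangle TSV with columns `chrom`, `bin1`, `bin2`, `count` and a
#' sidecar chromosome-sizes file (`chrom<TAB>size`).
#'
#' @param path matrix TSV, optionally gzipped.
#' @param sizes_path chromosome-sizes TSV.
#' @param binsize bin width in bp.
#' @return a `contact_matrix`.
#' @export
read_contact_matrix <- function(path, sizes_path, binsize) {
  px <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sz <- utils::read.table(sizes_path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  contact_matrix(px, binsize, stats::setNames(sz[[2]], sz[[1]]))
}

#' @rdname read_contact_matrix
#' @param cm a `contact_matrix`.
#' @export
write_contact_matrix <- function(cm, path, sizes_path = NULL) {
  utils::write.table(cm$pixels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sizes_path))
    utils::write.table(data.frame(names(cm$sizes), cm$sizes), sizes_path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  invisible(path)
}

.n_bins <- function(cm) ceiling(cm$sizes / cm$binsize)

#' Distance-expected model and observed/expected normalisation
#'
#' The expected count at bin distance `d` is the mean raw count over *all*
#' bin pairs at that distance on the chromosome (zero pixels included):
#' `expected(d) = sum(counts at d) / (nbins - d)`. O/E values are
#' `count / expected(distance)`; a pixel at a distance with zero expected is
#' undefined (masked as `NA` on lookup).
#'
#' @param cm a `contact_matrix` with at least one non-zero pixel.
#' @return object of class `oe_matrix`: the matrix plus per-chromosome
#'   expected-by-distance tables and an `oe` column on the pixels.
#' @export
observed_expected <- function(cm) {
  if (nrow(cm$pixels) == 0L) stop("empty contact matrix")
  nb <- .n_bins(cm)
  px <- cm$pixels
  d <- px$bin2 - px$bin1
  expected <- lapply(names(cm$sizes), function(ch) {
    sel <- px$chrom == ch
    tot <- rowsum(px$count[sel], d[sel])
    dd <- as.integer(rownames(tot))
    data.frame(distance = dd, expected = tot[, 1] / (nb[ch] - dd))
  })
  names(expected) <- names(cm$sizes)
  px$oe <- px$count / .expected_at(expected, px$chrom, d)
  structure(list(cm = cm, expected = expected, pixels = px),
            class = "oe_matrix")
}

.expected_at <- function(expected, chrom, d) {
  chrom <- rep_len(as.character(chrom), length(d))
  out <- numeric(length(d))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    e <- expected[[ch]]
    m <- match(d[sel], e$distance)
    out[sel] <- ifelse(is.na(m), 0, e$expected[m])
  }
  out
}

#' O/E value at arbitrary pixels (symmetric lookup)
#'
#' @param oe an `oe_matrix`.
#' @param chrom,bin1,bin2 pixel coordinates (order-free: `O/E(i,j) =
#'   O/E(j,i)`).
#' @return numeric vector; 0 where the raw count is zero but the distance has
#'   a positive expected value, `NA` where the expected value is zero.
#' @export
oe_at <- function(oe, chrom, bin1, bin2) {
  i <- pmin(bin1, bin2); j <- pmax(bin1, bin2)
  key <- paste(chrom, i, j)
  cnt <- oe$pixels$count[match(key, paste(oe$pixels$chrom, oe$pixels$bin1,
                                          oe$pixels$bin2))]
  cnt[is.na(cnt)] <- 0
  exp_d <- .expected_at(oe$expected, chrom, j - i)
  ifelse(exp_d > 0, cnt / exp_d, NA_real_)
}

.loop_bins <- function(loops, binsize) {
  mid1 <- floor((loops$start1 + loops$end1) / 2)
  mid2 <- floor((loops$start2 + loops$end2) / 2)
  data.frame(chrom = loops$chrom,
             bin1 = mid1 %/% binsize, bin2 = mid2 %/% binsize)
}

#' Loop interaction frequency (O/E at the loop pixel)
#'
#' The loop pixel is the bin pair containing the two anchor midpoints. Loops
#' whose pixel is masked (zero expected at that distance) are excluded with a
#' message.
#'
#' @param loops loop `data.frame` (see [read_loops_bedpe()]).
#' @param oe an `oe_matrix` (or a `contact_matrix`, normalised on the fly).
#' @return numeric vector of O/E values, `NA` for excluded loops.
#' @export
interaction_frequency <- function(loops, oe) {
  if (is(oe, "contact_matrix")) oe <- observed_expected(oe)
  lb <- .loop_bins(loops, oe$cm$binsize)
  v <- oe_at(oe, lb$chrom, lb$bin1, lb$bin2)
  if (anyNA(v))
    message(sum(is.na(v)), " loop(s) at masked pixels excluded")
  v
}

#' Interaction frequency compared across loop classes
#'
#' Per-class medians of loop-pixel O/E plus two-sided Wilcoxon rank-sum
#' p-values for every class pair.
#'
#' @param loops loop `data.frame`.
#' @param classes factor/character of loop classes, parallel to `loops` rows.
#' @param oe an `oe_matrix` or `contact_matrix`.
#' @return list with `frequency` (per loop), `medians`, `n`, and `pairwise`
#'   (`data.frame` of class pairs and rank-sum p-values).
#' @export
loop_class_interaction <- function(loops, classes, oe) {
  classes <- as.character(classes)
  freq <- interaction_frequency(loops, oe)
  ok <- !is.na(freq)
  med <- tapply(freq[ok], classes[ok], stats::median)
  nn <- table(classes[ok])
  cls <- sort(unique(classes))
  pairs <- t(utils::combn(cls, 2))
  pv <- apply(pairs, 1, function(p) {
    x <- freq[ok & classes == p[1]]; y <- freq[ok & classes == p[2]]
    if (length(x) < 2 || length(y) < 2) return(NA_real_)
    stats::wilcox.test(x, y)$p.value
  })
  list(frequency = freq, medians = med, n = nn,
       pairwise = data.frame(class_a = pairs[, 1], class_b = pairs[, 2],
                             p = pv))
}

#' Aggregate peak analysis (APA) over a loop set
#'
#' For each eligible loop the `(2*half_window+1)^2` O/E submatrix centred on
#' the loop pixel is extracted; submatrices are averaged element-wise and the
#' APA score is the centre pixel of the aggregate divided by the mean of its
#' `corner x corner` lower-left block (the short-distance background).
#' Loops closer than `2*half_window` bins to the diagonal, or whose window
#' leaves the chromosome, are excluded.
#'
#' @param loops loop `data.frame`.
#' @param cm a `contact_matrix` (or a precomputed `oe_matrix`).
#' @param half_window window half-width in bins (default 5, i.e. 11x11).
#' @param corner corner block size in bins (default 3).
#' @return list with `score`, `aggregate` (the mean O/E window),
#'   `n_loops` used.
#' @export
apa <- function(loops, cm, half_window = 5L, corner = 3L) {
  oe <- if (is(cm, "oe_matrix")) cm else observed_expected(cm)
  bs <- oe$cm$binsize
  nb <- .n_bins(oe$cm)
  lb <- .loop_bins(loops, bs)
  w <- 2L * half_window + 1L
  eligible <- (lb$bin2 - lb$bin1) > 2L * half_window &
    lb$bin1 - half_window >= 0 & lb$bin2 + half_window < nb[lb$chrom]
  if (!any(eligible)) stop("no loops eligible for APA at this window size")
  lb <- lb[eligible, , drop = FALSE]
  offs <- seq.int(-half_window, half_window)
  acc <- matrix(0, w, w); cnt <- matrix(0, w, w)
  for (r in seq_len(nrow(lb))) {
    ii <- lb$bin1[r] + offs
    jj <- lb$bin2[r] + offs
    sub <- matrix(oe_at(oe, lb$chrom[r],
                        rep(ii, times = w), rep(jj, each = w)), w, w)
    ok <- !is.na(sub)
    acc[ok] <- acc[ok] + sub[ok]
    cnt <- cnt + ok
  }
  agg <- acc / cnt
  centre <- agg[half_window + 1L, half_window + 1L]
  bg <- mean(agg[(w - corner + 1L):w, 1:corner])
  list(score = centre / bg, aggregate = agg, n_loops = nrow(lb))
}

#' Distance-stratified differential interactions between two conditions
#'
#' A documented stand-in for joint-normalisation differential tools:
#' counts are depth-scaled to a common library size and bin pairs with mean
#' raw count below `A_min` (the "A" filter) are dropped. Per-pixel log2
#' ratios `M = log2((b + eps) / (a + eps))` are centred and scaled within
#' distance strata (median/MAD; one stratum per bin distance up to 100 bins,
#' then log-spaced) and reported as `z` for effect-size inspection.
#' Significance comes from an exact conditional test: given the pixel total
#' `a + b`, the condition-B count is binomial with success probability equal
#' to B's share of the total library under the null of equal underlying
#' intensity, which keeps the test calibrated at the low counts the `A_min`
#' filter admits (a normal approximation to the standardised log-ratio is
#' visibly anti-conservative there). Two-sided p-values are
#' Benjamini-Hochberg adjusted. Equivalence with any external tool is not
#' claimed.
#'
#' @param a,b `contact_matrix` objects on the same bin grid (condition A is
#'   the reference; `direction = "up"` means higher in `b`).
#' @param A_min minimum mean raw count (default 15).
#' @param alpha adjusted-p cutoff for a significant call (default 0.1).
#' @param restrict_to optional `GRanges`; keep only bin pairs where at least
#'   one bin overlaps these regions (applied before testing).
#' @param epsilon pseudocount in the log ratio (default 1).
#' @return `data.frame` with one row per tested bin pair: `chrom`, `bin1`,
#'   `bin2`, `distance`, `count_a`, `count_b`, `M`, `z`, `p`, `p_adj`,
#'   `significant`, `direction`.
#' @export
differential_interactions <- function(a, b, A_min = 15, alpha = 0.1,
                                      restrict_to = NULL, epsilon = 1) {
  if (!identical(a$binsize, b$binsize) ||
      !identical(a$sizes[order(names(a$sizes))],
                 b$sizes[order(names(b$sizes))]))
    stop("contact matrices must share binsize and chromosome sizes")
  key_a <- paste(a$pixels$chrom, a$pixels$bin1, a$pixels$bin2)
  key_b <- paste(b$pixels$chrom, b$pixels$bin1, b$pixels$bin2)
  keys <- union(key_a, key_b)
  ca <- a$pixels$count[match(keys, key_a)]; ca[is.na(ca)] <- 0
  cb <- b$pixels$count[match(keys, key_b)]; cb[is.na(cb)] <- 0
  parts <- strsplit(keys, " ", fixed = TRUE)
  df <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                   bin1 = as.integer(vapply(parts, `[`, "", 2L)),
                   bin2 = as.integer(vapply(parts, `[`, "", 3L)),
                   count_a = ca, count_b = cb)
  df$distance <- df$bin2 - df$bin1
  df <- df[(df$count_a + df$count_b) / 2 >= A_min, , drop = FALSE]
  if (!is.null(restrict_to)) {
    bs <- a$binsize
    g1 <- granges0(df$chrom, df$bin1 * bs, (df$bin1 + 1) * bs)
    g2 <- granges0(df$chrom, df$bin2 * bs, (df$bin2 + 1) * bs)
    keep <- overlapsAny(g1, restrict_to, ignore.strand = TRUE) |
      overlapsAny(g2, restrict_to, ignore.strand = TRUE)
    df <- df[keep, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    df$M <- df$z <- df$p <- df$p_adj <- numeric(0)
    df$significant <- logical(0); df$direction <- character(0)
    return(df)
  }
  ## depth scaling to the geometric-mean library size
  ta <- total_counts(a); tb <- total_counts(b)
  s <- sqrt(ta * tb)
  sa <- df$count_a * s / ta
  sb <- df$count_b * s / tb
  df$M <- log2((sb + epsilon) / (sa + epsilon))
  strat <- ifelse(df$distance <= 100, df$distance,
                  101 + floor(8 * log2(pmax(df$distance, 101) / 100)))
  med <- stats::ave(df$M, strat, FUN = stats::median)
  madv <- stats::ave(df$M, strat, FUN = function(x) stats::mad(x))
  nstrat <- stats::ave(df$M, strat, FUN = length)
  df$z <- ifelse(madv > 0 & nstrat >= 5, (df$M - med) / madv, 0)
  ## exact conditional (mid-p) test on the raw pixel counts; mid-p offsets
  ## the discreteness conservatism of the plain exact test
  ntot <- df$count_a + df$count_b
  pi0 <- tb / (ta + tb)
  x <- df$count_b
  p_lo <- stats::pbinom(x, ntot, pi0) - 0.5 * stats::dbinom(x, ntot, pi0)
  p_hi <- 1 - stats::pbinom(x - 1, ntot, pi0) -
    0.5 * stats::dbinom(x, ntot, pi0)
  df$p <- pmin(2 * pmin(p_lo, p_hi), 1)
  df$p[ntot == 0] <- 1
  df$p_adj <- stats::p.adjust(df$p, "BH")
  df$significant <- df$p_adj < alpha
  df$direction <- ifelse(df$M > 0, "up", ifelse(df$M < 0, "down", "none"))
  rownames(df) <- NULL
  df
}
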