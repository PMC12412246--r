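make_genes <- function(n = 20, chrom_size = 2e5, seed = 1) {
  set.seed(seed)
  spacing <- chrom_size %/% n
  tss <- spacing %/% 2 + spacing * (0:(n - 1))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body <- 4000
  start <- ifelse(strand == "+", tss, tss - body + 1)
  end <- start + body
  data.frame(gene_id = sprintf("g%03d", 1:n), chrom = "chrT",
             strand = strand, tss = tss, start = start, end = end,
             exon_starts = paste(start, end - 400, sep = ","),
             exon_ends = paste(start + 400, end, sep = ","))
}

test_that("interval constructor and overlap predicate behave at boundaries", {
  a <- granges0("chr1", 100, 200)
  expect_true(overlaps(a, granges0("chr1", 150, 300), min_bp = 1))
  ## half-open adjacency is not overlap
  expect_false(overlaps(a, granges0("chr1", 200, 300), min_bp = 1))
  expect_false(overlaps(a, granges0("chr2", 100, 200), min_bp = 1))
  expect_true(overlaps(a, granges0("chr1", 150, 300), min_bp = 50))
  expect_false(overlaps(a, granges0("chr1", 150, 300), min_bp = 51))
  expect_error(granges0("chr1", 200, 200), "end > start")
  expect_error(granges0("chr1", -1, 10), "end > start|>= 0")
})

test_that("overlap verdicts match the per-base oracle and are symmetric", {
  set.seed(99)
  for (i in 1:1000) {
    c1 <- sample(c("c1", "c2"), 1); c2 <- sample(c("c1", "c2"), 1)
    s1 <- sample(0:500, 1); e1 <- s1 + sample(1:100, 1)
    s2 <- sample(0:500, 1); e2 <- s2 + sample(1:100, 1)
    mb <- sample(1:30, 1)
    got <- overlaps(granges0(c1, s1, e1), granges0(c2, s2, e2), mb)
    rev <- overlaps(granges0(c2, s2, e2), granges0(c1, s1, e1), mb)
    expect_identical(got, rev)
    expect_identical(unname(got), oracle_overlap0(c1, s1, e1, c2, s2, e2, mb))
  }
})

test_that("promoter windows are strand-aware, clipped and mirror-symmetric", {
  g <- data.frame(gene_id = c("p", "m", "edge"), chrom = "chrT",
                  strand = c("+", "-", "+"),
                  tss = c(10000, 10000, 500),
                  start = c(10000, 6001, 500), end = c(14000, 10001, 4500))
  pw <- promoter_windows(g, 2000, 2000)
  expect_equal(start(pw[1]) - 1, 8000); expect_equal(end(pw[1]), 12000)
  expect_equal(start(pw[2]) - 1, 8001); expect_equal(end(pw[2]), 12001)
  expect_equal(start(pw[3]) - 1, 0)  # clipped at the chromosome start
  ## per-base enumeration oracle on random gene/window combinations
  set.seed(5)
  for (i in 1:200) {
    tss <- sample(3000:50000, 1); strand <- sample(c("+", "-"), 1)
    up <- sample(0:3000, 1); down <- sample(1:3000, 1)
    gg <- data.frame(gene_id = "x", chrom = "c", strand = strand, tss = tss,
                     start = if (strand == "+") tss else tss - 1000 + 1,
                     end = if (strand == "+") tss + 1000 else tss + 1)
    w <- promoter_windows(gg, up, down)
    want <- oracle_promoter0(tss, strand, up, down)
    expect_equal(c(start(w) - 1, end(w)), want)
  }
  ## mirror-image genes give mirror-image windows
  L <- 20000
  gp <- data.frame(gene_id = "f", chrom = "c", strand = "+", tss = 4000,
                   start = 4000, end = 6000)
  gm <- data.frame(gene_id = "r", chrom = "c", strand = "-",
                   tss = L - 1 - 4000, start = L - 6000, end = L - 4000)
  wp <- promoter_windows(gp, 1500, 800)
  wm <- promoter_windows(gm, 1500, 800)
  expect_equal(c(start(wm) - 1, end(wm)),
               c(L - end(wp), L - (start(wp) - 1)))
})

test_that("midpoint annotation follows the priority order", {
  genes <- make_genes()
  ## a peak whose midpoint is in one gene's promoter wins over any intron
  g2 <- genes[1:2, ]
  g2$strand <- c("+", "+")
  g2$tss <- c(10000, 9000); g2$start <- g2$tss; g2$end <- g2$tss + 4000
  g2$exon_starts <- paste(g2$start, g2$end - 400, sep = ",")
  g2$exon_ends <- paste(g2$start + 400, g2$end, sep = ",")
  ## midpoint 9500: inside promoter of gene1 (8000..12000) and intron of gene2
  pk <- granges0("chrT", 9400, 9600)
  expect_equal(as.character(annotate_peaks(pk, g2)), "Promoter")
  ## no genes at all
  expect_equal(as.character(annotate_peaks(pk, genes[0, ])),
               "DistalIntergenic")
  ## category fractions always sum to one
  set.seed(3)
  pk <- granges0("chrT", s <- sample(0:190000, 300), s + 300)
  expect_equal(sum(genomic_distribution(pk, genes)), 1.0)
})

test_that("annotation agrees with the brute-force priority oracle", {
  genes <- make_genes(n = 20, seed = 2)
  set.seed(17)
  s <- sample(0:195000, 500)
  pk <- granges0("chrT", s, s + sample(50:500, 500, replace = TRUE))
  got <- as.character(annotate_peaks(pk, genes))
  mid0 <- floor((s + (end(pk) - 0)) / 2)
  mid0 <- floor(((start(pk) - 1) + end(pk)) / 2)
  want <- vapply(mid0, oracle_annotate0, "", genes = genes)
  expect_identical(got, want)
})

test_that("gene-model IO round-trips and validates", {
  genes <- make_genes(5)
  f <- tempfile()
  write_gene_models(genes, f)
  back <- read_gene_models(f)
  expect_equal(back$tss, genes$tss)
  bad <- genes; bad$tss[1] <- bad$tss[1] + 1
  expect_error(validate_gene_models(bad), "tss")
})
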