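make_loops <- function(b1, b2, chrom = "chrT", res = 5000) {
  validate_loops(data.frame(chrom = chrom,
                            start1 = b1 * res, end1 = (b1 + 1) * res,
                            start2 = b2 * res, end2 = (b2 + 1) * res),
                 res)
}

uniform_cm <- function(nb = 60, c = 8, binsize = 5000, chrom = "chrT") {
  g <- expand.grid(bin1 = 0:(nb - 1), bin2 = 0:(nb - 1))
  g <- g[g$bin1 < g$bin2, ]
  contact_matrix(data.frame(chrom = chrom, g, count = c), binsize,
                 stats::setNames(nb * binsize, chrom))
}

test_that("anchor-G4 classification partitions the loop set and ignores anchor order", {
  set.seed(21)
  res <- 5000
  b1 <- sample(0:50, 60, replace = TRUE)
  b2 <- b1 + sample(12:40, 60, replace = TRUE)
  loops <- make_loops(b1, b2)
  s <- sample(0:300000, 40)
  g4 <- as_peak_set(granges0("chrT", s, s + 300))
  got <- classify_loop_anchors(loops, g4)
  expect_equal(sum(got$counts), nrow(loops))
  ## brute-force verdict per loop
  wantv <- vapply(seq_len(nrow(loops)), function(i) {
    hit <- function(s0, e0) any(vapply(seq_along(g4), function(j) {
      oracle_overlap0("chrT", s0, e0, "chrT", start(g4[j]) - 1, end(g4[j]))
    }, TRUE))
    n <- hit(loops$start1[i], loops$end1[i]) + hit(loops$start2[i],
                                                   loops$end2[i])
    c("no_G4", "single_G4", "dual_G4")[n + 1]
  }, "")
  expect_equal(as.character(got$class), wantv)
  ## swapping the anchors leaves the class unchanged
  swapped <- loops
  swapped[c("start1", "end1", "start2", "end2")] <-
    loops[c("start2", "end2", "start1", "end1")]
  ## (re-validate via direct overlap counting: validate_loops enforces order)
  a1 <- countOverlaps(loop_anchors(loops, 1), g4) > 0
  a2 <- countOverlaps(loop_anchors(loops, 2), g4) > 0
  expect_equal(3 - (a1 + a2), 3 - (a2 + a1))
})

test_that("promoter/enhancer loop typing resolves the anchor-label pair", {
  loops <- make_loops(c(2, 2, 2, 2), c(14, 15, 16, 17))
  prom <- granges0("chrT", c(11000, 71000), c(13000, 73000))   # bins 2, 14
  enh <- granges0("chrT", c(76000, 82000), c(76500, 82500))    # bins 15, 16
  ty <- loop_ep_type(loops, prom, enh)
  expect_equal(as.character(ty), c("P-P", "E-P", "E-P", "other"))
  ## P wins a tie with E on the same anchor
  both <- loop_ep_type(loops[2, ], prom,
                       c(enh, granges0("chrT", 11000, 13000)))
  expect_equal(as.character(both), "E-P")
  ## unlabelled anchors
  expect_equal(as.character(loop_ep_type(loops[4, ], prom[0], enh[0])),
               "other")
})

test_that("observed/expected matches per-distance means and is symmetric", {
  cm <- uniform_cm(nb = 40, c = 5)
  oe <- observed_expected(cm)
  expect_true(all(abs(oe$pixels$oe - 1) < 1e-12))
  ## single nonzero pixel at distance d among (nb - d) pairs
  nb <- 30
  cm1 <- contact_matrix(data.frame(chrom = "c", bin1 = 4, bin2 = 10,
                                   count = 7),
                        5000, c(c = nb * 5000))
  oe1 <- observed_expected(cm1)
  expect_equal(oe1$pixels$oe, nb - 6)
  expect_equal(oe_at(oe1, "c", 10, 4), oe_at(oe1, "c", 4, 10))
  expect_equal(oe_at(oe1, "c", 0, 6), 0)          # zero pixel, same distance
  expect_true(is.na(oe_at(oe1, "c", 0, 5)))       # distance never observed
  ## random matrix vs brute-force per-distance means
  set.seed(9)
  nb <- 200
  g <- data.frame(bin1 = sample(0:(nb - 2), 500, replace = TRUE))
  g$bin2 <- pmin(g$bin1 + sample(1:30, 500, replace = TRUE), nb - 1)
  g$count <- rpois(500, 10)
  cmr <- contact_matrix(data.frame(chrom = "c", g), 5000, c(c = nb * 5000))
  oer <- observed_expected(cmr)
  d <- cmr$pixels$bin2 - cmr$pixels$bin1
  for (dd in unique(d)) {
    want <- sum(cmr$pixels$count[d == dd]) / (nb - dd)
    got <- oer$expected$c$expected[oer$expected$c$distance == dd]
    expect_equal(got, want)
  }
  expect_error(observed_expected(contact_matrix(
    data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
               count = numeric()), 5000, c(c = 1e5))), "empty")
})

test_that("loop frequency is 1 on a uniform matrix and ranks planted classes", {
  cm <- uniform_cm(nb = 60, c = 8)
  loops <- make_loops(c(3, 10), c(20, 40))
  expect_equal(interaction_frequency(loops, cm), c(1, 1))
  ## planted class multipliers recovered in O/E medians and rank-sum order
  set.seed(33)
  cfg <- synth_config(seed = 33)
  genes <- synth_gene_table(cfg)
  loops <- synth_loops(cfg, genes)
  pix <- data.frame(bin1 = loops$start1 %/% 5000,
                    bin2 = loops$start2 %/% 5000,
                    multiplier = loops$multiplier)
  mat <- synth_contact_matrix(cfg, enrich = pix)
  res <- loop_class_interaction(loops, loops$class, mat$cm)
  expect_gt(res$medians["dual_G4"], res$medians["single_G4"])
  expect_gt(res$medians["single_G4"], res$medians["no_G4"])
  p_dn <- res$pairwise$p[res$pairwise$class_a == "dual_G4" &
                           res$pairwise$class_b == "no_G4"]
  expect_lt(p_dn, 0.01)
})

test_that("APA equals the hand-computed ratio and is scale invariant", {
  ## uniform matrix -> exactly 1
  cm <- uniform_cm(nb = 60, c = 4)
  loops <- make_loops(10, 40)
  expect_equal(apa(loops, cm)$score, 1.0)
  ## hand-built 11x11 window: centre pixel enriched 5x over flat background
  nb <- 60
  g <- expand.grid(bin1 = 0:(nb - 1), bin2 = 0:(nb - 1))
  g <- g[g$bin1 < g$bin2, ]
  g$count <- 10
  g$count[g$bin1 == 20 & g$bin2 == 45] <- 50
  cm2 <- contact_matrix(data.frame(chrom = "chrT", g), 5000,
                        c(chrT = nb * 5000))
  oe2 <- observed_expected(cm2)
  res <- apa(make_loops(20, 45), cm2)
  w <- 11
  sub <- matrix(oe_at(oe2, "chrT", rep(20 + (-5:5), times = w),
                      rep(45 + (-5:5), each = w)), w, w)
  expect_equal(res$score, sub[6, 6] / mean(sub[9:11, 1:3]))
  ## global scaling of raw counts cancels in O/E
  g3 <- g; g3$count <- g3$count * 17
  cm3 <- contact_matrix(data.frame(chrom = "chrT", g3), 5000,
                        c(chrT = nb * 5000))
  expect_equal(apa(make_loops(20, 45), cm3)$score, res$score)
  ## loops too close to the diagonal are refused
  expect_error(apa(make_loops(10, 18), cm), "no loops eligible")
})

test_that("expression stratification assigns genes to the highest loop class", {
  res <- 5000
  genes <- data.frame(gene_id = c("gd", "gs", "gn", "gx"), chrom = "chrT",
                      strand = "+",
                      tss = c(105000, 205000, 305000, 405000),
                      start = c(105000, 205000, 305000, 405000),
                      end = c(109000, 209000, 309000, 409000))
  ## loops anchored at the genes' TSS bins (21, 41, 61) + far partners
  loops <- make_loops(c(21, 21, 41, 61), c(90, 110, 90, 110))
  classes <- c("dual_G4", "single_G4", "single_G4", "no_G4")
  expr <- c(gd = 8, gs = 6, gn = 5, gx = 4)
  st <- stratify_expression_by_loop_class(loops, classes, genes, expr)
  got <- stats::setNames(as.character(st$assignment$class),
                         st$assignment$gene_id)
  ## gd sits at a dual and a single anchor -> dual wins
  expect_equal(unname(got["gd"]), "dual_G4")
  expect_equal(unname(got["gs"]), "single_G4")
  expect_equal(unname(got["gn"]), "no_G4")
  expect_false("gx" %in% names(got))
  ## no loops at all -> nothing assigned
  st0 <- stratify_expression_by_loop_class(loops[0, ], character(0), genes,
                                           expr)
  expect_equal(nrow(st0$assignment), 0)
  ## planted expression shift recovers ordering with rank-sum support
  set.seed(44)
  cfg <- synth_config(seed = 44)
  b <- generate_bundle(cfg)
  cls <- classify_loop_anchors(b$loops, b$peaks$ASC)$class
  st2 <- stratify_expression_by_loop_class(b$loops, cls, b$genes,
                                           b$expression)
  expect_gt(st2$medians["dual_G4"], st2$medians["no_G4"])
  p <- st2$pairwise$p[st2$pairwise$class_a == "dual_G4" &
                        st2$pairwise$class_b == "no_G4"]
  expect_lt(p, 0.01)
})

test_that("BEDPE and matrix IO round-trip", {
  loops <- make_loops(c(2, 5), c(20, 30))
  f <- tempfile(fileext = ".bedpe")
  write_loops_bedpe(loops, f)
  back <- read_loops_bedpe(f, resolution = 5000)
  expect_equal(back$start1, loops$start1)
  expect_equal(back$start2, loops$start2)
  expect_error(make_loops(10, 10), "upstream")
  cm <- uniform_cm(nb = 10, c = 3)
  fm <- tempfile(); fs <- tempfile()
  write_contact_matrix(cm, fm, fs)
  back2 <- read_contact_matrix(fm, fs, 5000)
  expect_equal(back2$pixels, cm$pixels)
  expect_equal(total_counts(back2), total_counts(cm))
})
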