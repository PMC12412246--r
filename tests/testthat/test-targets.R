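toy_de <- function(ids, dirs) {
  data.frame(gene_id = ids, log2fc = ifelse(dirs == "up", 2,
                                            ifelse(dirs == "down", -2, 0)),
             p = 0.001, p_adj = ifelse(dirs == "ns", 0.9, 0.001),
             direction = dirs)
}

test_that("promoter-G4 gain is stage-2-only promoter occupancy", {
  genes <- data.frame(gene_id = c("a", "b", "c"), chrom = "chrT",
                      strand = "+", tss = c(10000, 30000, 50000),
                      start = c(10000, 30000, 50000),
                      end = c(14000, 34000, 54000))
  pk <- function(at) as_peak_set(granges0("chrT", at - 150, at + 150))
  stage2 <- pk(c(10000, 30000))          # promoters of a and b
  stage1 <- pk(30000)                    # b already occupied
  expect_equal(promoter_g4_gain(stage1, stage2, genes), "a")
  ## identical stages gain nothing; empty stage 1 gains all stage-2 hits
  expect_equal(length(promoter_g4_gain(stage2, stage2, genes)), 0L)
  expect_equal(promoter_g4_gain(stage2[0], stage2, genes), c("a", "b"))
})

test_that("promoter-G4 gain equals brute-force evaluation on random fixtures", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 15
    genes <- data.frame(gene_id = sprintf("g%02d", 1:n), chrom = "chrT",
                        strand = sample(c("+", "-"), n, TRUE),
                        tss = seq(10000, by = 12000, length.out = n))
    genes$start <- ifelse(genes$strand == "+", genes$tss, genes$tss - 3999)
    genes$end <- genes$start + 4000
    s1 <- sample(0:180000, 20); s2 <- sample(0:180000, 20)
    p1 <- as_peak_set(granges0("chrT", s1, s1 + 300))
    p2 <- as_peak_set(granges0("chrT", s2, s2 + 300))
    got <- promoter_g4_gain(p1, p2, genes)
    want <- vapply(seq_len(n), function(i) {
      pw <- oracle_promoter0(genes$tss[i], genes$strand[i], 2000, 2000)
      hit <- function(pk) any(vapply(seq_along(pk), function(j) {
        oracle_overlap0("chrT", pw[1], pw[2], "chrT",
                        start(pk[j]) - 1, end(pk[j]))
      }, TRUE))
      hit(p2) && !hit(p1)
    }, TRUE)
    expect_setequal(got, genes$gene_id[want])
  }
})

test_that("G4-up/down classification is exact set intersection", {
  de <- toy_de(letters[1:10], c("up", "up", "up", "up", "down", "down",
                                "down", "ns", "ns", "ns"))
  cls <- classify_promoter_g4_genes(letters[1:10], de)
  expect_equal(cls$g4_up, c("a", "b", "c", "d"))
  expect_equal(cls$g4_down, c("e", "f", "g"))
  empty <- classify_promoter_g4_genes(character(0), de)
  expect_equal(length(empty$g4_up) + length(empty$g4_down), 0L)
  ## random fixtures vs literal set algebra, order-invariant
  set.seed(9)
  for (rep in 1:20) {
    ids <- sprintf("x%03d", 1:50)
    dirs <- sample(c("up", "down", "ns"), 50, TRUE)
    gain <- sample(ids, 20)
    de <- toy_de(ids, dirs)
    cls <- classify_promoter_g4_genes(gain, de)
    expect_setequal(cls$g4_up, intersect(gain, ids[dirs == "up"]))
    expect_setequal(cls$g4_down, intersect(gain, ids[dirs == "down"]))
    shuf <- classify_promoter_g4_genes(sample(gain), de[sample(50), ])
    expect_identical(shuf, cls)
  }
})

test_that("bona fide targets are the ligand-reversed subsets", {
  pds <- toy_de(c("b", "c", "d", "f"), c("down", "down", "down", "up"))
  res <- call_bona_fide_targets(c("a", "b", "c"), c("e", "f"), pds)
  expect_equal(res$g4_activated, c("b", "c"))
  expect_equal(res$g4_repressed, "f")
  ## all-ns perturbation yields empty sets
  ns <- toy_de(c("a", "b"), c("ns", "ns"))
  res0 <- call_bona_fide_targets(c("a", "b"), c("x"), ns)
  expect_equal(length(res0$g4_activated) + length(res0$g4_repressed), 0L)
})

test_that("subset invariants hold across random classification chains", {
  set.seed(77)
  for (rep in 1:20) {
    ids <- sprintf("g%03d", 1:100)
    gain <- sample(ids, 40)
    de1 <- toy_de(ids, sample(c("up", "down", "ns"), 100, TRUE))
    de2 <- toy_de(ids, sample(c("up", "down", "ns"), 100, TRUE))
    cls <- classify_promoter_g4_genes(gain, de1)
    bf <- call_bona_fide_targets(cls$g4_up, cls$g4_down, de2)
    expect_true(all(bf$g4_activated %in% cls$g4_up))
    expect_true(all(bf$g4_repressed %in% cls$g4_down))
    expect_true(all(cls$g4_up %in% gain))
    tab <- target_class_table(ids, cls$g4_up, cls$g4_down,
                              bf$g4_activated, bf$g4_repressed)
    expect_equal(nrow(tab), 100)
    expect_equal(sum(tab$label == "G4_activated"),
                 length(bf$g4_activated))
  }
})

test_that("the full chain recovers planted bona fide targets on the bundle", {
  ## ~50 planted activated targets: promoter-gain genes x up-fraction x
  ## ligand-reversal fraction
  cfg <- synth_config(seed = 101, n_genes = 800L, chrom_size = 8e6,
                      pool_sizes = c(dual = 180L, single_pos = 140L,
                                     single_neg = 140L, no = 180L),
                      n_gain_free = 40L, n_shared = 32L, n_fisc_only = 24L,
                      pds_reversal_frac = 0.25)
  b <- generate_bundle(cfg)
  gain <- promoter_g4_gain(b$peaks$FISC, b$peaks$ASC, b$genes)
  de1 <- differential_expression(b$counts$counts_stage,
                                 b$counts$groups_stage)
  de2 <- differential_expression(b$counts$counts_pds, b$counts$groups_pds)
  cls <- classify_promoter_g4_genes(gain, de1)
  bf <- call_bona_fide_targets(cls$g4_up, cls$g4_down, de2)
  truth <- b$truth$genes
  planted_act <- truth$gene_id[truth$bona_fide == "activated"]
  planted_rep <- truth$gene_id[truth$bona_fide == "repressed"]
  expect_gt(length(planted_act), 40)
  ## planted targets recovered at high rate; false bona fide calls require a
  ## false positive in both independent contrasts, so at most a stray one or
  ## two among hundreds of candidates
  expect_gte(mean(planted_act %in% bf$g4_activated), 0.9)
  expect_true(all(bf$g4_activated %in% planted_act))
  expect_lte(sum(!(bf$g4_repressed %in% planted_rep)), 2)
  ## external DE tables drive the same chain through the reader
  f <- tempfile()
  utils::write.table(de1[c("gene_id", "log2fc", "p", "p_adj")], f,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cls2 <- classify_promoter_g4_genes(gain, read_de_table(f))
  expect_identical(cls2, cls)
})
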