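test_that("minimal canonical motifs are found on both strands", {
  h <- scan_pqs("GGGAGGGAGGGAGGG")
  expect_equal(length(h), 1L)
  expect_equal(as.character(strand(h)), "+")
  expect_equal(mcols(h)$subtype, "canonical")
  expect_equal(mcols(h)$tract_lengths, "3,3,3,3")
  expect_equal(mcols(h)$loop_lengths, "1,1,1")
  expect_equal(c(start(h) - 1L, end(h)), c(0L, 15L))

  h2 <- scan_pqs("CCCACCCACCCACCC")
  expect_equal(as.character(strand(h2)), "-")
  expect_equal(mcols(h2)$subtype, "canonical")
  expect_equal(mcols(h2)$sequence, "GGGTGGGTGGGTGGG")
  expect_equal(c(start(h2) - 1L, end(h2)), c(0L, 15L))
})

test_that("subtype classification respects the family boundaries", {
  expect_equal(classify_subtype(c(3, 3, 3, 3), c(7, 1, 1)), "canonical")
  expect_equal(classify_subtype(c(3, 3, 3, 3), c(8, 1, 1)), "long_loop")
  expect_equal(classify_subtype(c(2, 2, 2, 2), c(12, 3, 3)), "two_quartet")
  expect_equal(classify_subtype(c(3, 4, 3, 3), c(2, 1, 1), bulge_len = 3),
               "bulge")
  expect_error(classify_subtype(c(3, 3, 3), c(1, 1)), "at least 4")
  expect_error(classify_subtype(c(3, 3, 3, 3), c(1, 1)), "loops")
  expect_error(classify_subtype(c(1, 3, 3, 3), c(1, 1, 1)), "no G4 subtype")
  expect_error(classify_subtype(c(2, 2, 2, 2), c(13, 1, 1)), "no G4 subtype")
})

test_that("scanner output matches the exhaustive enumerator on random sequences", {
  set.seed(2024)
  for (i in 1:60) {
    s <- random_dna(300, gc_boost = i %% 2 == 0)
    o <- oracle_scan(s)
    h <- scanner_hits_df(scan_pqs(s))
    expect_equal(unname(as.matrix(h[c("start0", "end0")])),
                 unname(as.matrix(o[c("start0", "end0")])))
    expect_equal(h$subtype, o$subtype)
    expect_equal(h$strand, o$strand)
  }
})

test_that("N breaks runs and loops and never matches", {
  ## an N inside a loop splits the chain: no 4-tract match remains
  expect_equal(length(scan_pqs("GGGAGGGANGGGAGGG")), 0L)
  ## the match restarts after the N-carrying loop
  h <- scan_pqs("GGNGAGGGAGGGAGGGAGG")
  expect_equal(length(h), 1L)
  expect_equal(start(h) - 1L, 5L)
  expect_equal(mcols(h)$subtype, "two_quartet")
  expect_error(scan_pqs("GGGAXGGG"), "A, C, G, T, N")
  ## oracle agreement with embedded N
  set.seed(7)
  for (i in 1:10) {
    s <- random_dna(300, gc_boost = TRUE)
    pos <- sample(300, 5)
    substr(s, pos[1], pos[1]) <- "N"
    o <- oracle_scan(s)
    h <- scanner_hits_df(scan_pqs(s))
    expect_equal(h$subtype, o$subtype)
    expect_equal(unname(as.matrix(h[c("start0", "end0")])),
                 unname(as.matrix(o[c("start0", "end0")])))
  }
})

test_that("reverse-complement scanning mirrors the hit set", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_dna(250, gc_boost = TRUE)
    n <- nchar(s)
    h <- scanner_hits_df(scan_pqs(s))
    hr <- scanner_hits_df(scan_pqs(oracle_revcomp(s)))
    mirrored <- data.frame(start0 = n - hr$end0, end0 = n - hr$start0,
                           subtype = hr$subtype,
                           strand = ifelse(hr$strand == "+", "-", "+"))
    mirrored <- mirrored[order(mirrored$start0, mirrored$strand,
                               mirrored$end0), ]
    expect_equal(unname(as.matrix(h[c("start0", "end0")])),
                 unname(as.matrix(mirrored[c("start0", "end0")])))
    expect_equal(h$subtype, mirrored$subtype)
    expect_equal(h$strand, mirrored$strand)
  }
})

test_that("canonical hits are contained in the extended pattern via precedence", {
  ## a canonical match embedded in a long-loop context keeps its canonical
  ## label; the surrounding long-loop chain is suppressed by precedence
  s <- paste0("GGGAGGGAGGGAGGG", strrep("A", 9), "GGG")
  h <- scan_pqs(s)
  expect_equal(mcols(h)$subtype, "canonical")
  expect_equal(end(h), 15L)
  ## relaxing the canonical loop bound to the extended bound makes the two
  ## families coincide: every canonical hit is still matched
  cfg_wide <- pattern_config(loop_max_canonical = 12)
  set.seed(5)
  for (i in 1:10) {
    s <- random_dna(300, gc_boost = TRUE)
    canon <- scan_pqs(s)
    canon <- canon[mcols(canon)$subtype == "canonical"]
    wide <- scan_pqs(s, config = cfg_wide)
    if (length(canon))
      expect_true(all(countOverlaps(canon, wide) > 0))
  }
})

test_that("scanner BED output is byte-identical across runs", {
  set.seed(31)
  s <- random_dna(2000, gc_boost = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_pqs_bed(scan_pqs(s, "chrT"), f1)
  write_pqs_bed(scan_pqs(s, "chrT"), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_gt(length(readLines(f1)), 0L)
})

test_that("peak-PQS overlap flags planted peaks and rejects bad input", {
  genome <- c(chrP = paste0(strrep("A", 100), "GGGTGGGTGGGTGGG",
                            strrep("A", 185),
                            strrep("T", 300)))
  peaks <- granges0(rep("chrP", 2), c(50, 300), c(350, 600))
  res <- peak_pqs_overlap(peaks, genome)
  expect_equal(res$positive, c(TRUE, FALSE))
  expect_equal(res$fraction, 0.5)
  expect_error(peak_pqs_overlap(granges0("chrP", 500, 700), genome),
               "outside chromosome bounds")
  expect_error(peak_pqs_overlap(granges0("chrX", 0, 10), genome),
               "absent from genome")
})
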