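## Independent brute-force oracles. These re-derive expected results from the
## structural definitions by exhaustive enumeration, sharing no code with the
## package implementations they check.

oracle_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

## maximal G-runs by rle over the character vector
.o_runs <- function(s) {
  ch <- strsplit(s, "")[[1]]
  r <- rle(ch == "G")
  e <- cumsum(r$lengths)
  b <- e - r$lengths           # 0-based starts
  data.frame(start0 = b[r$values], end0 = e[r$values],
             len = r$lengths[r$values])
}

.o_nfree <- function(s, from0, to0) {     # [from0, to0) contains no N
  to0 <= from0 || !grepl("N", substr(s, from0 + 1, to0), fixed = TRUE)
}

## all (not just maximal) simple-family matches: >=4 eligible runs, every
## consecutive-eligible gap in 1..L and N-free
.o_family_pairs <- function(s, runs, k, L) {
  E <- which(runs$len >= k)
  out <- list()
  if (length(E) < 4) return(out)
  for (ai in seq_along(E)) {
    for (bi in seq_along(E)) {
      if (bi - ai + 1 < 4) next
      sel <- E[ai:bi]
      gaps <- runs$start0[sel[-1]] - runs$end0[sel[-length(sel)]]
      if (any(gaps < 1) || any(gaps > L)) next
      okN <- all(mapply(function(f, t) .o_nfree(s, f, t),
                        runs$end0[sel[-length(sel)]], runs$start0[sel[-1]]))
      if (!okN) next
      out[[length(out) + 1]] <- list(start0 = runs$start0[sel[1]],
                                     end0 = runs$end0[sel[length(sel)]],
                                     max_gap = max(gaps))
    }
  }
  out
}

## all bulge-family matches: plain runs >=3 G chained with gaps 1..7 around
## exactly one interrupted tract (two adjacent runs, gap 1..bulge_max,
## total G >= 3)
.o_bulge_all <- function(s, runs, cfg) {
  n <- nrow(runs)
  plain <- which(runs$len >= cfg$min_tract_canonical)
  out <- list()
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    g <- runs$start0[i + 1] - runs$end0[i]
    if (g < 1 || g > cfg$bulge_max || !.o_nfree(s, runs$end0[i],
                                                runs$start0[i + 1])) next
    if (runs$len[i] + runs$len[i + 1] < cfg$min_tract_canonical) next
    ## walk left over consecutive plain runs
    lefts <- c()
    prev_end <- runs$start0[i]
    cands <- rev(plain[plain < i])
    for (p in cands) {
      gp <- prev_end - runs$end0[p]
      if (gp < 1 || gp > cfg$loop_max_canonical ||
          !.o_nfree(s, runs$end0[p], prev_end)) break
      lefts <- c(lefts, p)
      prev_end <- runs$start0[p]
    }
    rights <- c()
    prev_start <- runs$end0[i + 1]
    for (p in plain[plain > i + 1]) {
      gp <- runs$start0[p] - prev_start
      if (gp < 1 || gp > cfg$loop_max_canonical ||
          !.o_nfree(s, prev_start, runs$start0[p])) break
      rights <- c(rights, p)
      prev_start <- runs$end0[p]
    }
    ## every (l, r) extent is a structural match
    for (l in 0:length(lefts)) {
      for (r in 0:length(rights)) {
        if (l + 1 + r < cfg$min_tracts) next
        st <- if (l > 0) runs$start0[lefts[l]] else runs$start0[i]
        en <- if (r > 0) runs$end0[rights[r]] else runs$end0[i + 1]
        out[[length(out) + 1]] <- list(start0 = st, end0 = en)
      }
    }
  }
  out
}

.o_drop_contained <- function(ms) {
  if (length(ms) < 2) return(ms)
  st <- vapply(ms, `[[`, 0, "start0"); en <- vapply(ms, `[[`, 0, "end0")
  keep <- vapply(seq_along(ms), function(i) {
    !any(st <= st[i] & en >= en[i] & (st < st[i] | en > en[i]))
  }, TRUE)
  ms[keep]
}

## leftmost-longest non-overlapping resolution within one family
.o_greedy <- function(ms) {
  if (length(ms) < 2) return(ms)
  st <- vapply(ms, `[[`, 0, "start0"); en <- vapply(ms, `[[`, 0, "end0")
  keep <- list(); last_end <- -1
  for (j in order(st, -en)) {
    if (st[j] >= last_end) {
      keep[[length(keep) + 1]] <- ms[[j]]
      last_end <- en[j]
    }
  }
  keep
}

## precedence merge: canonical > long_loop > bulge > two_quartet, leftmost-
## longest within a family, non-overlapping overall
.o_merge <- function(fams) {
  acc <- data.frame(start0 = numeric(0), end0 = numeric(0),
                    subtype = character(0))
  for (sub in c("canonical", "long_loop", "bulge", "two_quartet")) {
    ms <- fams[[sub]]
    if (!length(ms)) next
    st <- vapply(ms, `[[`, 0, "start0"); en <- vapply(ms, `[[`, 0, "end0")
    for (j in order(st, -en)) {
      if (nrow(acc) && any(st[j] < acc$end0 & en[j] > acc$start0)) next
      acc <- rbind(acc, data.frame(start0 = st[j], end0 = en[j],
                                   subtype = sub))
    }
  }
  acc
}

oracle_scan_strand <- function(s, cfg) {
  runs <- .o_runs(s)
  canon <- .o_drop_contained(.o_family_pairs(s, runs,
                                             cfg$min_tract_canonical,
                                             cfg$loop_max_canonical))
  ext <- .o_family_pairs(s, runs, cfg$min_tract_canonical,
                         cfg$loop_max_extended)
  ll <- .o_drop_contained(ext)
  ll <- Filter(function(m) m$max_gap > cfg$loop_max_canonical, ll)
  bul <- .o_drop_contained(.o_bulge_all(s, runs, cfg))
  tq <- .o_drop_contained(.o_family_pairs(s, runs,
                                          cfg$min_tract_two_quartet,
                                          cfg$loop_max_extended))
  .o_merge(list(canonical = .o_greedy(canon), long_loop = .o_greedy(ll),
                bulge = .o_greedy(bul), two_quartet = .o_greedy(tq)))
}

## full oracle: both strands, minus-strand coordinates mapped back
oracle_scan <- function(s, cfg = pattern_config()) {
  s <- toupper(s)
  n <- nchar(s)
  p <- oracle_scan_strand(s, cfg)
  p$strand <- if (nrow(p)) "+" else character(0)
  m <- oracle_scan_strand(oracle_revcomp(s), cfg)
  if (nrow(m)) {
    m <- data.frame(start0 = n - m$end0, end0 = n - m$start0,
                    subtype = m$subtype, strand = "-")
  } else m$strand <- character(0)
  out <- rbind(p, m)
  out[order(out$start0, out$strand, out$end0), , drop = FALSE]
}

## scanner output in the same comparable form
scanner_hits_df <- function(gr) {
  df <- data.frame(start0 = GenomicRanges::start(gr) - 1,
                   end0 = GenomicRanges::end(gr),
                   subtype = S4Vectors::mcols(gr)$subtype,
                   strand = as.character(GenomicRanges::strand(gr)))
  df[order(df$start0, df$strand, df$end0), , drop = FALSE]
}

## random test sequences: a mix of uniform and G-enriched composition so all
## four subtype families actually occur
random_dna <- function(n, gc_boost = FALSE) {
  probs <- if (gc_boost) c(A = .2, C = .2, G = .4, T = .2)
           else c(A = .25, C = .25, G = .25, T = .25)
  paste(sample(names(probs), n, replace = TRUE, prob = probs),
        collapse = "")
}

## per-base brute-force interval overlap
oracle_overlap0 <- function(c1, s1, e1, c2, s2, e2, min_bp = 1) {
  if (c1 != c2) return(FALSE)
  length(intersect(seq.int(s1, e1 - 1), seq.int(s2, e2 - 1))) >= min_bp
}

## per-base promoter window: positions within `up` bases 5' and `down - 1`
## bases 3' of the TSS in gene orientation (clipped at 0)
oracle_promoter0 <- function(tss, strand, up, down) {
  o <- -(up):(down - 1)
  pos <- if (strand == "+") tss + o else tss - o
  pos <- pos[pos >= 0]
  c(min(pos), max(pos) + 1)
}

## brute-force midpoint annotation with explicit priority walk
oracle_annotate0 <- function(mid0, genes, up = 2000, down = 2000,
                             ds_bp = 3000) {
  if (is.null(genes) || nrow(genes) == 0) return("DistalIntergenic")
  hits <- data.frame(prio = integer(0), dist = numeric(0),
                     gene = character(0))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    within0 <- function(s0, e0) mid0 >= s0 && mid0 < e0
    pw <- oracle_promoter0(g$tss, g$strand, up, down)
    cats <- c()
    if (within0(pw[1], pw[2])) cats <- c(cats, 1)
    es <- as.numeric(strsplit(as.character(g$exon_starts), ",")[[1]])
    ee <- as.numeric(strsplit(as.character(g$exon_ends), ",")[[1]])
    if (any(mapply(within0, es, ee))) cats <- c(cats, 2)
    if (within0(g$start, g$end)) cats <- c(cats, 3)
    dsr <- if (g$strand == "+") c(g$end, g$end + ds_bp)
           else c(max(g$start - ds_bp, 0), g$start)
    if (within0(dsr[1], dsr[2])) cats <- c(cats, 4)
    if (length(cats))
      hits <- rbind(hits, data.frame(prio = min(cats),
                                     dist = abs(mid0 - g$tss),
                                     gene = g$gene_id))
  }
  if (nrow(hits) == 0) return("DistalIntergenic")
  best <- hits[order(hits$prio, hits$dist, hits$gene), ][1, ]
  c("Promoter", "Exon", "Intron", "Downstream")[best$prio]
}

## quick NB count simulator for DE calibration tests (independent of synth)
sim_nb_counts <- function(n_genes, n_per_group, mu, dispersion, lfc = 0,
                          n_de = 0) {
  eff <- rep(0, n_genes)
  if (n_de > 0) eff[seq_len(n_de)] <- lfc
  m1 <- matrix(rep(mu, n_per_group), n_genes)
  m2 <- matrix(rep(mu * 2^eff, n_per_group), n_genes)
  cnt <- cbind(matrix(rnbinom(n_genes * n_per_group, mu = m1,
                              size = 1 / dispersion), n_genes),
               matrix(rnbinom(n_genes * n_per_group, mu = m2,
                              size = 1 / dispersion), n_genes))
  rownames(cnt) <- paste0("g", seq_len(n_genes))
  colnames(cnt) <- c(paste0("a", seq_len(n_per_group)),
                     paste0("b", seq_len(n_per_group)))
  cnt
}
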