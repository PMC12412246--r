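#' Pattern configuration for the PQS scanner
#'
#' A putative quadruplex-forming sequence (PQS) consists of at least
#' `min_tracts` G-runs separated by loops. Four structural families are
#' scanned: canonical (G-runs >= `min_tract_canonical`, loops 1..
#' `loop_max_canonical`), long-loop (same runs, at least one loop in
#' `loop_max_canonical + 1` .. `loop_max_extended`), bulged (canonical-style
#' but exactly one G-tract carries a single 1..`bulge_max` nt non-G
#' insertion), and two-quartet (G-runs >= `min_tract_two_quartet`, loops up
#' to `loop_max_extended`).
#'
#' @param min_tract_canonical minimum G-run length for three-tetrad families
#'   (default 3).
#' @param min_tract_two_quartet minimum G-run length for the two-quartet
#'   family (default 2).
#' @param loop_max_canonical maximum canonical loop length (default 7).
#' @param loop_max_extended maximum loop length for long-loop and two-quartet
#'   families (default 12).
#' @param bulge_max maximum length of the single non-G insertion in a bulged
#'   tract (default 7).
#' @param min_tracts minimum number of G-tracts in a hit (default 4).
#' @return a named list of class `pqs_config`.
#' @export
pattern_config <- function(min_tract_canonical = 3L, min_tract_two_quartet = 2L,
                           loop_max_canonical = 7L, loop_max_extended = 12L,
                           bulge_max = 7L, min_tracts = 4L) {
  cfg <- list(min_tract_canonical = as.integer(min_tract_canonical),
              min_tract_two_quartet = as.integer(min_tract_two_quartet),
              loop_max_canonical = as.integer(loop_max_canonical),
              loop_max_extended = as.integer(loop_max_extended),
              bulge_max = as.integer(bulge_max),
              min_tracts = as.integer(min_tracts))
  if (any(unlist(cfg) <= 0)) stop("all pattern parameters must be positive")
  if (cfg$loop_max_extended < cfg$loop_max_canonical)
    stop("loop_max_extended must be >= loop_max_canonical")
  class(cfg) <- "pqs_config"
  cfg
}

.pqs_subtypes <- c("canonical", "long_loop", "bulge", "two_quartet")

.revcomp <- function(s) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

## Maximal G-runs of a strand sequence: data.frame(start0, end0, len),
## 0-based half-open, plus cumulative N counts for loop validation.
.strand_index <- function(s) {
  m <- gregexpr("G+", s, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    runs <- data.frame(start0 = integer(), end0 = integer(), len = integer())
  } else {
    st <- as.integer(m) - 1L
    ln <- attr(m, "match.length")
    runs <- data.frame(start0 = st, end0 = st + ln, len = ln)
  }
  isN <- as.integer(strsplit(s, "", fixed = TRUE)[[1]] == "N")
  list(runs = runs, cumN = c(0L, cumsum(isN)))
}

.gap_has_n <- function(idx, from0, to0) {
  idx$cumN[to0 + 1L] - idx$cumN[from0 + 1L] > 0L
}

## Maximal chains of eligible runs (len >= k) with inter-run gaps in 1..L and
## no N in gaps; returns matches with >= min_tracts tracts.
.family_chains <- function(idx, k, L, min_tracts) {
  runs <- idx$runs
  keep <- which(runs$len >= k)
  if (length(keep) < min_tracts) return(list())
  rs <- runs$start0[keep]; re <- runs$end0[keep]; rl <- runs$len[keep]
  m <- length(keep)
  gap <- rs[-1] - re[-m]
  gapN <- idx$cumN[rs[-1] + 1L] - idx$cumN[re[-m] + 1L] > 0L
  ok <- gap >= 1L & gap <= L & !gapN
  seg <- cumsum(c(TRUE, !ok))
  out <- list()
  for (g in split(seq_len(m), seg)) {
    if (length(g) < min_tracts) next
    out[[length(out) + 1L]] <- list(
      start0 = rs[g[1]], end0 = re[g[length(g)]],
      tracts = rl[g], loops = gap[g[-length(g)]],
      bulge_len = NA_integer_, bulge_tract = NA_integer_)
  }
  out
}

## Bulge-family matches: chains of plain runs (len >= 3) plus exactly one
## bulged unit (two consecutive maximal runs separated by a 1..bulge_max
## non-G, N-free gap, with >= min_tract_canonical G in total), loops 1..
## loop_max_canonical. Candidates are resolved leftmost-longest.
.bulge_chains <- function(idx, cfg) {
  runs <- idx$runs
  n <- nrow(runs)
  if (n < 2L) return(list())
  k <- cfg$min_tract_canonical
  L <- cfg$loop_max_canonical
  plain <- which(runs$len >= k)
  ## candidate bulged units
  gap <- runs$start0[-1] - runs$end0[-n]
  gapN <- idx$cumN[runs$start0[-1] + 1L] - idx$cumN[runs$end0[-n] + 1L] > 0L
  cand <- which(gap >= 1L & gap <= cfg$bulge_max & !gapN &
                  runs$len[-n] + runs$len[-1] >= k)
  if (length(cand) == 0L || length(plain) + 1L < cfg$min_tracts) return(list())
  ## segment the plain runs exactly as the canonical family would
  if (length(plain) > 1L) {
    pgap <- runs$start0[plain[-1]] - runs$end0[plain[-length(plain)]]
    pN <- idx$cumN[runs$start0[plain[-1]] + 1L] -
      idx$cumN[runs$end0[plain[-length(plain)]] + 1L] > 0L
    pok <- pgap >= 1L & pgap <= L & !pN
  } else pok <- logical(0)
  pseg <- cumsum(c(TRUE, !pok))
  ppos <- seq_along(plain) - match(pseg, pseg)       # position in segment - 1
  plen <- stats::ave(ppos, pseg, FUN = length)       # segment length
  ## vectorised flank chaining over all candidates
  li <- findInterval(cand - 0.5, plain)              # last plain run < i
  nleft <- integer(length(cand))
  hasl <- li >= 1L
  if (any(hasl)) {
    lp <- plain[li[hasl]]
    g <- runs$start0[cand[hasl]] - runs$end0[lp]
    okN <- idx$cumN[runs$start0[cand[hasl]] + 1L] -
      idx$cumN[runs$end0[lp] + 1L] == 0L
    ok <- g >= 1L & g <= L & okN
    nleft[hasl][ok] <- ppos[li[hasl]][ok] + 1L
  }
  ri <- findInterval(cand + 1.5, plain) + 1L         # first plain run > i+1
  nright <- integer(length(cand))
  hasr <- ri <= length(plain)
  if (any(hasr)) {
    rp <- plain[ri[hasr]]
    g <- runs$start0[rp] - runs$end0[cand[hasr] + 1L]
    okN <- idx$cumN[runs$start0[rp] + 1L] -
      idx$cumN[runs$end0[cand[hasr] + 1L] + 1L] == 0L
    ok <- g >= 1L & g <= L & okN
    nright[hasr][ok] <- (plen[ri[hasr]] - ppos[ri[hasr]])[ok]
  }
  keep <- nleft + 1L + nright >= cfg$min_tracts
  if (!any(keep)) return(list())
  matches <- Map(function(i, nl, nr) list(i = i, nleft = nl, nright = nr),
                 cand[keep], nleft[keep], nright[keep])
  ## materialise matches with tract/loop metadata
  built <- lapply(matches, function(mm) {
    i <- mm$i
    li <- which(plain < i); ri <- which(plain > i + 1L)
    lsel <- if (mm$nleft) plain[li[(length(li) - mm$nleft + 1L):length(li)]]
            else integer()
    rsel <- if (mm$nright) plain[ri[seq_len(mm$nright)]] else integer()
    units_start <- c(runs$start0[lsel], runs$start0[i], runs$start0[rsel])
    units_end <- c(runs$end0[lsel], runs$end0[i + 1L], runs$end0[rsel])
    tracts <- c(runs$len[lsel], runs$len[i] + runs$len[i + 1L],
                runs$len[rsel])
    loops <- units_start[-1] - units_end[-length(units_end)]
    list(start0 = units_start[1], end0 = units_end[length(units_end)],
         tracts = tracts, loops = loops,
         bulge_len = runs$start0[i + 1L] - runs$end0[i],
         bulge_tract = mm$nleft + 1L)
  })
  ## leftmost-longest, non-overlapping within the family
  st <- vapply(built, `[[`, 0, "start0")
  en <- vapply(built, `[[`, 0, "end0")
  ord <- order(st, -en)
  out <- list(); last_end <- -1L
  for (j in ord) {
    if (st[j] >= last_end) {
      out[[length(out) + 1L]] <- built[[j]]
      last_end <- en[j]
    }
  }
  out
}

## Precedence merge across families on one strand: canonical > long_loop >
## bulge > two_quartet; within a family left to right; a match is kept iff it
## overlaps no already-kept match.
.merge_families <- function(fam) {
  kept <- list()
  ivs <- matrix(numeric(0), ncol = 2)
  for (sub in .pqs_subtypes) {
    for (mm in fam[[sub]]) {
      if (nrow(ivs) == 0 ||
          all(mm$end0 <= ivs[, 1] | mm$start0 >= ivs[, 2])) {
        mm$subtype <- sub
        kept[[length(kept) + 1L]] <- mm
        ivs <- rbind(ivs, c(mm$start0, mm$end0))
      }
    }
  }
  kept[order(vapply(kept, `[[`, 0, "start0"))]
}

.scan_strand <- function(s, cfg) {
  idx <- .strand_index(s)
  ext <- .family_chains(idx, cfg$min_tract_canonical, cfg$loop_max_extended,
                        cfg$min_tracts)
  fam <- list(
    canonical = .family_chains(idx, cfg$min_tract_canonical,
                               cfg$loop_max_canonical, cfg$min_tracts),
    long_loop = Filter(function(m) max(m$loops) > cfg$loop_max_canonical, ext),
    bulge = .bulge_chains(idx, cfg),
    two_quartet = .family_chains(idx, cfg$min_tract_two_quartet,
                                 cfg$loop_max_extended, cfg$min_tracts))
  .merge_families(fam)
}

#' Scan a DNA sequence for putative quadruplex-forming sequences
#'
#' Both strands are scanned: the given sequence directly, and its reverse
#' complement with hit coordinates mapped back to the plus strand and reported
#' on strand `-`. G-tracts are maximal runs of G; loops are the stretches
#' between consecutive qualifying tracts (they may contain shorter G-runs but
#' never N). Hits are maximal and non-overlapping within a strand; where
#' structural families overlap, the highest-precedence subtype wins
#' (canonical > long_loop > bulge > two_quartet).
#'
#' @param sequence DNA string over `A,C,G,T,N` (case-insensitive) or a
#'   `Biostrings::DNAString`.
#' @param chrom chromosome name for the output coordinates.
#' @param offset 0-based offset of `sequence` on `chrom` (default 0).
#' @param config a [pattern_config()].
#' @return `GRanges` with metadata columns `subtype`, `sequence` (in the
#'   G4-forming orientation), `tract_lengths`, `loop_lengths` (comma-joined),
#'   `n_tracts`, `bulge_len`.
#' @export
scan_pqs <- function(sequence, chrom = "seq", offset = 0L,
                     config = pattern_config()) {
  s <- toupper(as.character(sequence))
  if (grepl("[^ACGTN]", s)) stop("sequence may only contain A, C, G, T, N")
  n <- nchar(s)
  plus <- .scan_strand(s, config)
  rc <- .revcomp(s)
  minus <- .scan_strand(rc, config)
  rows <- list()
  for (mm in plus)
    rows[[length(rows) + 1L]] <- c(mm, list(strand = "+",
      g_start0 = mm$start0, g_end0 = mm$end0,
      seq = substr(s, mm$start0 + 1L, mm$end0)))
  for (mm in minus)
    rows[[length(rows) + 1L]] <- c(mm, list(strand = "-",
      g_start0 = n - mm$end0, g_end0 = n - mm$start0,
      seq = substr(rc, mm$start0 + 1L, mm$end0)))
  if (length(rows) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(subtype = character(), sequence = character(),
                           tract_lengths = character(),
                           loop_lengths = character(),
                           n_tracts = integer(), bulge_len = integer())
    return(gr)
  }
  st <- vapply(rows, `[[`, 0, "g_start0")
  en <- vapply(rows, `[[`, 0, "g_end0")
  gr <- granges0(chrom, st + offset, en + offset,
                 strand = vapply(rows, `[[`, "", "strand"))
  mcols(gr) <- DataFrame(
    subtype = vapply(rows, `[[`, "", "subtype"),
    sequence = vapply(rows, `[[`, "", "seq"),
    tract_lengths = vapply(rows, function(r) paste(r$tracts, collapse = ","), ""),
    loop_lengths = vapply(rows, function(r) paste(r$loops, collapse = ","), ""),
    n_tracts = vapply(rows, function(r) length(r$tracts), 0L),
    bulge_len = vapply(rows, function(r) as.integer(r$bulge_len), 0L))
  gr[order(start(gr), as.character(strand(gr)))]
}

#' Classify a G4 structure into its subtype
#'
#' Precedence: canonical > long_loop > bulge > two_quartet. Canonical: all
#' tracts >= 3 G, all loops <= 7, no bulge. Long-loop: all tracts >= 3 G,
#' maximum loop 8..12. Bulge: exactly one interrupted tract (total G >= 3),
#' remaining tracts >= 3 G, loops <= 7. Two-quartet: >= 4 tracts of >= 2 G
#' (tracts of exactly 2 allowed), loops <= 12.
#'
#' @param tract_lengths integer vector of G-tract lengths (>= 4 tracts).
#' @param loop_lengths integer vector of loop lengths
#'   (`length(tract_lengths) - 1`).
#' @param bulge_len length of the single non-G insertion, or `NA`/`NULL` for
#'   an uninterrupted structure.
#' @param config a [pattern_config()].
#' @return one of `"canonical"`, `"long_loop"`, `"bulge"`, `"two_quartet"`.
#' @export
classify_subtype <- function(tract_lengths, loop_lengths, bulge_len = NA,
                             config = pattern_config()) {
  if (length(tract_lengths) < config$min_tracts)
    stop("need at least ", config$min_tracts, " tracts")
  if (length(loop_lengths) != length(tract_lengths) - 1L)
    stop("need exactly length(tract_lengths) - 1 loops")
  if (is.null(bulge_len)) bulge_len <- NA
  has_bulge <- !is.na(bulge_len)
  k3 <- config$min_tract_canonical
  if (!has_bulge && all(tract_lengths >= k3)) {
    if (all(loop_lengths <= config$loop_max_canonical)) return("canonical")
    if (all(loop_lengths <= config$loop_max_extended)) return("long_loop")
  }
  if (has_bulge && bulge_len >= 1 && bulge_len <= config$bulge_max &&
      all(tract_lengths >= k3) &&  # interrupted tract carries total G >= 3
      all(loop_lengths <= config$loop_max_canonical))
    return("bulge")
  if (!has_bulge && all(tract_lengths >= config$min_tract_two_quartet) &&
      all(loop_lengths <= config$loop_max_extended))
    return("two_quartet")
  stop("structure matches no G4 subtype")
}

#' Flag peaks that overlap a predicted PQS
#'
#' A peak is PQS-positive iff at least one PQS hit on either strand overlaps
#' it by >= 1 bp. Whole chromosomes are scanned once, then hits are
#' intersected with the peaks.
#'
#' @param peaks `GRanges` of peaks; every chromosome must be present in the
#'   genome and peaks must lie within chromosome bounds.
#' @param genome a named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a FASTA file path.
#' @param config a [pattern_config()].
#' @return list with `positive` (logical per peak), `fraction`
#'   (positives / total) and `hits` (the scanned PQS `GRanges`).
#' @export
peak_pqs_overlap <- function(peaks, genome, config = pattern_config()) {
  seqs <- .as_genome_seqs(genome)
  chroms <- unique(as.character(seqnames(peaks)))
  missing <- setdiff(chroms, names(seqs))
  if (length(missing)) stop("chromosome(s) absent from genome: ",
                            paste(missing, collapse = ", "))
  lens <- nchar(seqs)
  bad <- which(end(peaks) > lens[as.character(seqnames(peaks))] |
                 start(peaks) < 1)
  if (length(bad)) stop("peak outside chromosome bounds: ",
                        paste0(seqnames(peaks)[bad], ":",
                               start(peaks)[bad] - 1, "-", end(peaks)[bad],
                               collapse = ", "))
  hits <- lapply(chroms, function(ch) scan_pqs(seqs[[ch]], ch, 0L, config))
  hits <- do.call(c, hits)
  pos <- countOverlaps(peaks, hits, ignore.strand = TRUE) > 0
  list(positive = pos,
       fraction = if (length(peaks)) mean(pos) else NaN,
       hits = hits)
}

.as_genome_seqs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    ss <- Biostrings::readDNAStringSet(genome)
    names(ss) <- sub("\\s.*$", "", names(ss))
    genome <- ss
  }
  if (is(genome, "DNAStringSet"))
    return(stats::setNames(as.character(genome), names(genome)))
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("genome must be a FASTA path, DNAStringSet or named character vector")
}

#' Write PQS hits as BED6+
#'
#' Columns 7-9 carry subtype, tract lengths and loop lengths; output is
#' deterministic (byte-identical for identical input).
#'
#' @param hits `GRanges` from [scan_pqs()].
#' @param path output path.
#' @export
write_pqs_bed <- function(hits, path) {
  df <- data.frame(chrom = as.character(seqnames(hits)),
                   start = start(hits) - 1L, end = end(hits),
                   name = paste0("pqs_", seq_along(hits)),
                   score = mcols(hits)$n_tracts,
                   strand = as.character(strand(hits)),
                   subtype = mcols(hits)$subtype,
                   tracts = mcols(hits)$tract_lengths,
                   loops = mcols(hits)$loop_lengths)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
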