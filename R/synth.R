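#' Configuration for the synthetic-data generator
#'
#' The generator emulates the statistical structure of the sequencing-derived
#' inputs the analysis consumes: a random genome with planted PQS motifs under
#' designated G4 peaks, per-stage peak sets with promoter gains, TF peak sets
#' with planned co-binding fractions, promoter/enhancer elements, a loop set
#' with G4-anchor classes, distance-decay contact matrices with
#' class-dependent loop enrichment and planted differential pixels, and
#' negative-binomial count matrices with planted differential genes linked to
#' promoter-G4 status.
#'
#' Genes are placed on a uniform TSS grid (one gene per
#' `chrom_size / n_genes` bp, jittered when slack allows, at least
#' `min_gene_spacing` apart) so that each gene owns exactly two contact-map
#' bins; loop anchors are drawn from disjoint per-class gene pools, which
#' makes every truth-table entry exact by construction.
#'
#' @param seed integer RNG seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @param chrom,chrom_size chromosome name and length (default one 2-Mb
#'   chromosome).
#' @param binsize contact-map bin width (default 5000).
#' @param n_genes number of genes (default 200).
#' @param gene_body,exon_width gene-body span and terminal-exon width (bp).
#' @param min_gene_spacing minimum TSS spacing (default 10 kb).
#' @param promoter_up,promoter_down promoter window extents (bp).
#' @param peak_width,tf_peak_width G4 / TF peak widths (bp).
#' @param pqs_plant_rate fraction of G4 peak loci given a planted PQS
#'   (default 0.8; the remainder are G4-depleted so their truth is negative).
#' @param pqs_subtype_mix named fractions over planted subtypes.
#' @param pqs_minus_frac fraction of plants on the minus strand.
#' @param pool_sizes genes per loop-anchor pool (`dual`, `single_pos`,
#'   `single_neg`, `no`).
#' @param n_gain_free,n_shared,n_fisc_only free-pool genes given an
#'   activated-stage-only promoter peak, a peak in both stages, or a
#'   quiescent-stage-only peak.
#' @param n_noise_peaks,n_fisc_noise non-promoter peaks per stage.
#' @param tf_fractions planned TF co-binding fractions of activated-stage G4
#'   peaks (defaults 0.49/0.22/0.15 for MAX/YY1/CTCF-like factors).
#' @param n_tf_extra TF-only peaks per factor.
#' @param ep_probs per-gene element designation probabilities
#'   (`P`, `E`, `none`).
#' @param loops_per_class loops per G4 class (default 200).
#' @param class_multipliers loop-pixel contact enrichment per class
#'   (default 3/2/1 for dual/single/no).
#' @param min_sep_bins,max_sep_bins anchor separation range in bins.
#' @param depth expected total contact count per matrix (default 1e6).
#' @param decay_exponent distance-decay exponent (default 1).
#' @param n_diff_down,n_diff_up differential pixels planted in condition B.
#' @param diff_effect multiplier applied to down pixels (default 0.5, i.e.
#'   two-fold decrease; up pixels get its reciprocal).
#' @param diff_min_expected minimum baseline expected count of a planted
#'   differential pixel (default 60; keeps planted effects detectable under
#'   Poisson noise at the default depth).
#' @param nb_dispersion,base_meanlog,base_sdlog negative-binomial dispersion
#'   and log-normal baseline-mean parameters for counts.
#' @param de_effect planted |log2 fold change| between stages (default 2.5).
#' @param gain_up_frac,gain_down_frac fractions of promoter-gain genes
#'   planted up-/down-regulated on activation.
#' @param background_de_frac fraction of non-gain genes planted differential.
#' @param pds_reversal_frac fraction of gain-and-regulated genes whose effect
#'   the G4 ligand reverses (the planted bona fide targets).
#' @param pds_effect planted |log2 fold change| of the ligand reversal.
#' @param n_samples replicates per group (default 3).
#' @param expr_base_mean,expr_base_sd,expr_shift baseline and per-loop-class
#'   shift of the per-gene expression values used for loop-class
#'   stratification (log2 scale).
#' @return a named list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         chrom = "chrS", chrom_size = 2e6,
                         binsize = 5000L,
                         n_genes = 200L, gene_body = 4000L, exon_width = 400L,
                         min_gene_spacing = 10000L,
                         promoter_up = 2000L, promoter_down = 2000L,
                         peak_width = 300L, tf_peak_width = 200L,
                         pqs_plant_rate = 0.8,
                         pqs_subtype_mix = c(canonical = 0.4,
                                             two_quartet = 0.25,
                                             bulge = 0.2, long_loop = 0.15),
                         pqs_minus_frac = 0.5,
                         pool_sizes = c(dual = 50L, single_pos = 35L,
                                        single_neg = 35L, no = 50L),
                         n_gain_free = 10L, n_shared = 8L, n_fisc_only = 6L,
                         n_noise_peaks = 20L, n_fisc_noise = 5L,
                         tf_fractions = c(MAX = 0.49, YY1 = 0.22,
                                          CTCF = 0.15),
                         n_tf_extra = 10L,
                         ep_probs = c(P = 0.45, E = 0.35, none = 0.20),
                         loops_per_class = 200L,
                         class_multipliers = c(dual_G4 = 3, single_G4 = 2,
                                               no_G4 = 1),
                         min_sep_bins = 11L, max_sep_bins = 100L,
                         depth = 1e6, decay_exponent = 1,
                         n_diff_down = 100L, n_diff_up = 25L,
                         diff_effect = 0.5, diff_min_expected = 60,
                         nb_dispersion = 0.1,
                         base_meanlog = log(150), base_sdlog = 1,
                         de_effect = 2.5, gain_up_frac = 0.55,
                         gain_down_frac = 0.25, background_de_frac = 0.10,
                         pds_reversal_frac = 0.2, pds_effect = 2.5,
                         n_samples = 3L,
                         expr_base_mean = 5, expr_base_sd = 1,
                         expr_shift = c(dual_G4 = 1, single_G4 = 0.5,
                                        no_G4 = 0)) {
  cfg <- as.list(environment())
  stopifnot(cfg$pqs_plant_rate >= 0, cfg$pqs_plant_rate <= 1,
            abs(sum(cfg$pqs_subtype_mix) - 1) < 1e-9,
            all(cfg$class_multipliers >= 1),
            cfg$class_multipliers["dual_G4"] >=
              cfg$class_multipliers["single_G4"],
            cfg$class_multipliers["single_G4"] >=
              cfg$class_multipliers["no_G4"],
            cfg$diff_effect > 0, cfg$depth > 0)
  class(cfg) <- "synth_config"
  cfg
}

## ---- sequence builders -----------------------------------------------------

## sample `n` bases containing no GG or CC dinucleotide (so no PQS on either
## strand can arise or extend here)
.depleted_seq <- function(n) {
  if (n <= 0) return("")
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (n > 1) {
    bad <- which(x[-1] == x[-n] & x[-1] %in% c("G", "C")) + 1L
    if (length(bad)) x[bad] <- sample(c("A", "T"), length(bad),
                                      replace = TRUE)
  }
  paste(x, collapse = "")
}

## loop filler: no G (would extend a tract) and no CC (whose reverse
## complement is a G-run that could seed a spurious opposite-strand match)
.loop_seq <- function(len) {
  x <- sample(c("A", "C", "T"), len, replace = TRUE)
  if (len > 1) {
    bad <- which(x[-1] == "C" & x[-len] == "C") + 1L
    if (length(bad)) x[bad] <- sample(c("A", "T"), length(bad),
                                      replace = TRUE)
  }
  paste(x, collapse = "")
}

## minimal PQS motif of a given structural subtype
.pqs_motif <- function(subtype) {
  if (subtype == "canonical") {
    loops <- sample(1:7, 3, replace = TRUE)
    paste0("GGG", .loop_seq(loops[1]), "GGG", .loop_seq(loops[2]),
           "GGG", .loop_seq(loops[3]), "GGG")
  } else if (subtype == "long_loop") {
    loops <- sample(1:7, 3, replace = TRUE)
    loops[sample(3, 1)] <- sample(8:12, 1)
    paste0("GGG", .loop_seq(loops[1]), "GGG", .loop_seq(loops[2]),
           "GGG", .loop_seq(loops[3]), "GGG")
  } else if (subtype == "bulge") {
    loops <- sample(1:7, 3, replace = TRUE)
    blen <- sample(1:7, 1)
    split2 <- sample(1:2, 1)  # 2+1 or 1+2 G around the insertion
    bulged <- paste0(strrep("G", split2), .loop_seq(blen),
                     strrep("G", 3L - split2))
    tracts <- c(rep("GGG", 3), bulged)[sample(4)]
    paste0(tracts[1], .loop_seq(loops[1]), tracts[2], .loop_seq(loops[2]),
           tracts[3], .loop_seq(loops[3]), tracts[4])
  } else if (subtype == "two_quartet") {
    loops <- sample(1:12, 3, replace = TRUE)
    paste0("GG", .loop_seq(loops[1]), "GG", .loop_seq(loops[2]),
           "GG", .loop_seq(loops[3]), "GG")
  } else stop("unknown subtype: ", subtype)
}

## a peak-width region: A/T edge flanks, GG/CC-free filler, and optionally a
## planted motif at the centre
.peak_region_seq <- function(width, motif = NULL, minus = FALSE,
                             edge = 13L) {
  at <- function(n) paste(sample(c("A", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(motif)) {
    return(paste0(at(edge), .depleted_seq(width - 2L * edge), at(edge)))
  }
  if (minus) motif <- .revcomp(motif)
  ml <- nchar(motif)
  ## layout: [AT edge][filler][AT spacer][motif][AT spacer][filler][AT edge]
  ## the spacers insulate the motif from single G/C in the filler
  room <- width - 4L * edge - ml
  if (room < 0L) stop("peak too narrow for planted motif")
  dl <- room %/% 2L
  paste0(at(edge), .depleted_seq(dl), at(edge), motif, at(edge),
         .depleted_seq(room - dl), at(edge))
}

## all intra-chromosomal bin pairs at distance >= 1, upper triangle
.pixel_grid <- function(nb) {
  dd <- rep.int(seq_len(nb - 1L), (nb - 1L):1L)
  b1 <- sequence((nb - 1L):1L) - 1L
  data.frame(bin1 = b1, bin2 = b1 + dd, distance = dd)
}

## ---- component generators (consume the current RNG stream) -----------------

#' Synthetic gene table with anchor pools and element designations
#'
#' @param cfg a [synth_config()].
#' @return gene-model `data.frame` with extra columns `pool` (anchor pool or
#'   free-pool role), `ep_role` (`P`/`E`/`none`) and `tss_bin`.
#' @keywords internal
synth_gene_table <- function(cfg) {
  spacing <- floor(cfg$chrom_size / cfg$n_genes)
  if (spacing < cfg$min_gene_spacing)
    stop("too many genes for genome: spacing ", spacing, " < ",
         cfg$min_gene_spacing, " bp")
  slack <- (spacing - cfg$min_gene_spacing) %/% 2L
  tss <- floor(spacing / 2) + spacing * (seq_len(cfg$n_genes) - 1L)
  if (slack > 0) tss <- tss + sample(seq(-slack, slack),
                                     cfg$n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  start <- ifelse(strand == "+", tss, tss - cfg$gene_body + 1L)
  end <- start + cfg$gene_body
  ex1s <- start; ex1e <- start + cfg$exon_width
  ex2s <- end - cfg$exon_width; ex2e <- end
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = cfg$chrom, strand = strand, tss = tss, start = start, end = end,
    exon_starts = paste(ex1s, ex2s, sep = ","),
    exon_ends = paste(ex1e, ex2e, sep = ","))
  ## anchor pools + free-pool roles
  ps <- cfg$pool_sizes
  n_free <- cfg$n_genes - sum(ps)
  if (n_free < cfg$n_gain_free + cfg$n_shared + cfg$n_fisc_only)
    stop("pool sizes leave too few free genes")
  roles <- c(rep(names(ps), ps),
             rep("gain_free", cfg$n_gain_free), rep("shared", cfg$n_shared),
             rep("fisc_only", cfg$n_fisc_only),
             rep("plain", n_free - cfg$n_gain_free - cfg$n_shared -
                   cfg$n_fisc_only))
  genes$pool <- sample(roles)
  genes$ep_role <- sample(names(cfg$ep_probs), cfg$n_genes, replace = TRUE,
                          prob = cfg$ep_probs)
  genes$tss_bin <- genes$tss %/% cfg$binsize
  validate_gene_models(genes)
}

#' Synthetic loop set over the gene anchor pools
#'
#' @param cfg a [synth_config()].
#' @param genes table from [synth_gene_table()].
#' @return loop `data.frame` with truth columns `class`, `ep_type`,
#'   `multiplier`.
#' @keywords internal
synth_loops <- function(cfg, genes) {
  bin_of <- stats::setNames(genes$tss_bin, genes$gene_id)
  pools <- split(genes$gene_id, genes$pool)
  draw <- function(pool_a, pool_b, n) {
    out <- matrix(character(0), ncol = 2)
    used <- character(0)
    tries <- 0L
    while (nrow(out) < n) {
      tries <- tries + 1L
      if (tries > 5000L * n)
        stop("cannot place ", n, " loops with the given pools/separation")
      ga <- sample(pool_a, 1L); gb <- sample(pool_b, 1L)
      if (ga == gb) next
      sep <- abs(bin_of[ga] - bin_of[gb])
      if (sep < cfg$min_sep_bins || sep > cfg$max_sep_bins) next
      pair <- if (bin_of[ga] < bin_of[gb]) c(ga, gb) else c(gb, ga)
      key <- paste(pair, collapse = "|")
      if (key %in% used) next
      used <- c(used, key)
      out <- rbind(out, pair)
    }
    out
  }
  n <- cfg$loops_per_class
  dual <- draw(pools$dual, pools$dual, n)
  single <- draw(pools$single_pos, pools$single_neg, n)
  noG4 <- draw(pools$no, pools$no, n)
  g1 <- c(dual[, 1], single[, 1], noG4[, 1])
  g2 <- c(dual[, 2], single[, 2], noG4[, 2])
  cls <- rep(c("dual_G4", "single_G4", "no_G4"), each = n)
  b1 <- bin_of[g1]; b2 <- bin_of[g2]
  role <- stats::setNames(genes$ep_role, genes$gene_id)
  pair_lab <- function(a, b) {
    lab <- function(r) ifelse(r == "P", "P", ifelse(r == "E", "E", "N"))
    la <- lab(role[a]); lb <- lab(role[b])
    key <- paste0(pmin(la, lb), pmax(la, lb))
    ifelse(key == "PP", "P-P", ifelse(key == "EP", "E-P",
      ifelse(key == "EE", "E-E", "other")))
  }
  loops <- data.frame(
    chrom = cfg$chrom,
    start1 = b1 * cfg$binsize, end1 = (b1 + 1) * cfg$binsize,
    start2 = b2 * cfg$binsize, end2 = (b2 + 1) * cfg$binsize,
    name = sprintf("loop_%04d", seq_along(g1)),
    count = NA_real_,
    class = cls, ep_type = pair_lab(g1, g2),
    gene1 = g1, gene2 = g2,
    multiplier = unname(cfg$class_multipliers[cls]))
  validate_loops(loops, cfg$binsize)
}

#' Synthetic distance-decay contact matrix
#'
#' Poisson counts with expectation `depth`-scaled `d^-exponent` decay,
#' multiplied at enriched pixels.
#'
#' @param cfg a [synth_config()].
#' @param enrich optional `data.frame` with `bin1`, `bin2`, `multiplier`.
#' @param depth expected total count (default `cfg$depth`).
#' @return list with `cm` (a [contact_matrix()]) and `lambda` (the expected
#'   counts, parallel to the enumerated pixels `data.frame` `grid`).
#' @keywords internal
synth_contact_matrix <- function(cfg, enrich = NULL, depth = cfg$depth) {
  nb <- as.integer(ceiling(cfg$chrom_size / cfg$binsize))
  grid <- .pixel_grid(nb)
  base <- grid$distance^(-cfg$decay_exponent)
  C <- depth / sum(base)
  lambda <- C * base
  if (!is.null(enrich) && nrow(enrich)) {
    key <- paste(grid$bin1, grid$bin2)
    m <- match(paste(pmin(enrich$bin1, enrich$bin2),
                     pmax(enrich$bin1, enrich$bin2)), key)
    if (anyNA(m)) stop("enriched pixel outside the bin grid")
    lambda[m] <- lambda[m] * enrich$multiplier
  }
  counts <- stats::rpois(nrow(grid), lambda)
  cm <- contact_matrix(
    data.frame(chrom = cfg$chrom, bin1 = grid$bin1, bin2 = grid$bin2,
               count = counts),
    cfg$binsize, stats::setNames(cfg$chrom_size, cfg$chrom))
  list(cm = cm, lambda = lambda, grid = grid)
}

#' Synthetic contact-matrix pair with planted differential pixels
#'
#' Condition A carries the loop-class enrichment; condition B shares the same
#' expectation except at planted pixels (`diff_effect` fold down, reciprocal
#' up), drawn among non-loop pixels with baseline expectation at least
#' `diff_min_expected`.
#'
#' @param cfg a [synth_config()].
#' @param loop_pixels optional `data.frame` with `bin1`, `bin2`,
#'   `multiplier` (the loop enrichment, shared by both conditions).
#' @return list with `cm_a`, `cm_b` and `diff_truth` (`data.frame` of planted
#'   pixels and directions).
#' @keywords internal
synth_contact_pair <- function(cfg, loop_pixels = NULL) {
  nb <- as.integer(ceiling(cfg$chrom_size / cfg$binsize))
  grid <- .pixel_grid(nb)
  base <- grid$distance^(-cfg$decay_exponent)
  C <- cfg$depth / sum(base)
  lambda <- C * base
  key <- paste(grid$bin1, grid$bin2)
  is_loop <- rep(FALSE, nrow(grid))
  if (!is.null(loop_pixels) && nrow(loop_pixels)) {
    m <- match(paste(pmin(loop_pixels$bin1, loop_pixels$bin2),
                     pmax(loop_pixels$bin1, loop_pixels$bin2)), key)
    lambda[m] <- lambda[m] * loop_pixels$multiplier
    is_loop[m] <- TRUE
  }
  eligible <- which(!is_loop & lambda >= cfg$diff_min_expected)
  n_diff <- cfg$n_diff_down + cfg$n_diff_up
  if (length(eligible) < n_diff)
    stop("not enough well-covered pixels for the planted differentials")
  sel <- sample(eligible, n_diff)
  down <- sel[seq_len(cfg$n_diff_down)]
  up <- setdiff(sel, down)
  lambda_b <- lambda
  lambda_b[down] <- lambda[down] * cfg$diff_effect
  lambda_b[up] <- lambda[up] / cfg$diff_effect
  mk <- function(lam) contact_matrix(
    data.frame(chrom = cfg$chrom, bin1 = grid$bin1, bin2 = grid$bin2,
               count = stats::rpois(nrow(grid), lam)),
    cfg$binsize, stats::setNames(cfg$chrom_size, cfg$chrom))
  diff_truth <- data.frame(
    chrom = cfg$chrom,
    bin1 = grid$bin1[c(down, up)], bin2 = grid$bin2[c(down, up)],
    direction = rep(c("down", "up"), c(length(down), length(up))))
  list(cm_a = mk(lambda), cm_b = mk(lambda_b), diff_truth = diff_truth)
}

#' Synthetic count matrices for the two expression contrasts
#'
#' Stage contrast (quiescent vs activated) with planted effects on
#' promoter-gain genes plus background differentials, and a ligand contrast
#' (vehicle vs ligand, both on the activated baseline) reversing a fraction
#' of the planted gain effects — the planted bona fide targets.
#'
#' @param cfg a [synth_config()].
#' @param gene_ids all gene ids.
#' @param gain_ids ids with planted promoter-G4 gain.
#' @return list with `counts_stage`, `groups_stage`, `counts_pds`,
#'   `groups_pds`, and `truth` (`data.frame` with `gene_id`, `stage_de`,
#'   `pds_de`, `bona_fide`).
#' @keywords internal
synth_count_contrasts <- function(cfg, gene_ids, gain_ids) {
  n <- length(gene_ids)
  mu <- stats::rlnorm(n, cfg$base_meanlog, cfg$base_sdlog)
  stage_de <- rep("ns", n)
  gain <- gene_ids %in% gain_ids
  r <- stats::runif(n)
  stage_de[gain & r < cfg$gain_up_frac] <- "up"
  stage_de[gain & r >= cfg$gain_up_frac &
             r < cfg$gain_up_frac + cfg$gain_down_frac] <- "down"
  rb <- stats::runif(n)
  stage_de[!gain & rb < cfg$background_de_frac / 2] <- "up"
  stage_de[!gain & rb >= cfg$background_de_frac / 2 &
             rb < cfg$background_de_frac] <- "down"
  eff <- ifelse(stage_de == "up", cfg$de_effect,
                ifelse(stage_de == "down", -cfg$de_effect, 0))
  mu_act <- mu * 2^eff
  rev_draw <- stats::runif(n) < cfg$pds_reversal_frac
  bona <- rep("none", n)
  bona[gain & stage_de == "up" & rev_draw] <- "activated"
  bona[gain & stage_de == "down" & rev_draw] <- "repressed"
  pds_de <- ifelse(bona == "activated", "down",
                   ifelse(bona == "repressed", "up", "ns"))
  mu_pds <- mu_act * 2^(ifelse(pds_de == "down", -cfg$pds_effect,
                               ifelse(pds_de == "up", cfg$pds_effect, 0)))
  k <- cfg$n_samples
  nb_mat <- function(m) matrix(stats::rnbinom(n * k, mu = rep(m, k),
                                              size = 1 / cfg$nb_dispersion),
                               nrow = n)
  counts_stage <- cbind(nb_mat(mu), nb_mat(mu_act))
  colnames(counts_stage) <- c(paste0("FISC_", 1:k), paste0("ASC_", 1:k))
  counts_pds <- cbind(nb_mat(mu_act), nb_mat(mu_pds))
  colnames(counts_pds) <- c(paste0("DMSO_", 1:k), paste0("PDS_", 1:k))
  rownames(counts_stage) <- rownames(counts_pds) <- gene_ids
  list(counts_stage = counts_stage,
       groups_stage = factor(rep(c("FISC", "ASC"), each = k),
                             levels = c("FISC", "ASC")),
       counts_pds = counts_pds,
       groups_pds = factor(rep(c("DMSO", "PDS"), each = k),
                           levels = c("DMSO", "PDS")),
       truth = data.frame(gene_id = gene_ids, stage_de = stage_de,
                          pds_de = pds_de, bona_fide = bona,
                          base_mean = mu))
}

#' Generate the full synthetic input bundle
#'
#' Deterministic given the configuration (including its seed). See
#' [synth_config()] for what is emulated. Use [write_bundle()] to materialise
#' the bundle as the plain-text files the readers consume and
#' [check_bundle()] to verify the truth table against the emitted data.
#'
#' @param cfg a [synth_config()].
#' @return a list of class `synth_bundle` with elements `genome`
#'   (named character), `genes`, `peaks` (list of `GRanges` per stage),
#'   `tf_peaks`, `elements` (`promoters`/`enhancers`), `loops`, `matrices`
#'   (`ctrl`/`treat`), `counts`, `expression`, and `truth`.
#' @export
generate_bundle <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  genes <- synth_gene_table(cfg)
  w <- cfg$peak_width
  ## ---- peak plan: promoter peaks by pool role, noise peaks in gap slots ----
  asc_roles <- c("dual", "single_pos", "gain_free", "shared")
  fisc_roles <- c("shared", "fisc_only")
  prom_peak <- function(sel) data.frame(
    gene = genes$gene_id[sel],
    start = genes$tss[sel] - w %/% 2L, kind = "promoter")
  asc_df <- prom_peak(genes$pool %in% asc_roles)
  fisc_df <- prom_peak(genes$pool %in% fisc_roles)
  gap_slots <- seq_len(cfg$n_genes - 1L)  # slot k: after gene k
  need <- cfg$n_noise_peaks + cfg$n_fisc_noise
  if (length(gap_slots) < need) stop("not enough gap slots for noise peaks")
  slots <- sample(gap_slots, need)
  spacing <- floor(cfg$chrom_size / cfg$n_genes)
  noise_start <- function(k) floor(spacing / 2) + spacing * (k - 1L) + 7200L
  asc_noise <- data.frame(gene = NA_character_,
                          start = noise_start(slots[seq_len(cfg$n_noise_peaks)]),
                          kind = "noise")
  fisc_noise <- data.frame(gene = NA_character_,
                           start = noise_start(slots[cfg$n_noise_peaks +
                                                       seq_len(cfg$n_fisc_noise)]),
                           kind = "noise")
  asc_df <- rbind(asc_df, asc_noise)
  fisc_df <- rbind(fisc_df, fisc_noise)
  ## unique peak loci across stages (shared promoters coincide)
  loci <- unique(rbind(asc_df, fisc_df)[c("start", "kind")])
  loci <- loci[order(loci$start), , drop = FALSE]
  n_loci <- nrow(loci)
  n_plant <- round(cfg$pqs_plant_rate * n_loci)
  planted <- rep(FALSE, n_loci)
  planted[sample(n_loci, n_plant)] <- TRUE
  subtype <- rep(NA_character_, n_loci)
  subtype[planted] <- sample(names(cfg$pqs_subtype_mix), n_plant,
                             replace = TRUE, prob = cfg$pqs_subtype_mix)
  minus <- stats::runif(n_loci) < cfg$pqs_minus_frac
  ## ---- genome ----
  base_seq <- paste(sample(c("A", "C", "G", "T"), cfg$chrom_size,
                           replace = TRUE), collapse = "")
  pieces <- character(0)
  cursor <- 0L
  region <- character(n_loci)
  for (r in seq_len(n_loci)) {
    motif <- if (planted[r]) .pqs_motif(subtype[r]) else NULL
    region[r] <- .peak_region_seq(w, motif, minus[r])
    pieces <- c(pieces, substr(base_seq, cursor + 1L, loci$start[r]),
                region[r])
    cursor <- loci$start[r] + w
  }
  pieces <- c(pieces, substr(base_seq, cursor + 1L, cfg$chrom_size))
  genome <- stats::setNames(paste(pieces, collapse = ""), cfg$chrom)
  ## ---- peak GRanges per stage ----
  locus_key <- paste(loci$start)
  mk_peaks <- function(df, stage) {
    gr <- granges0(cfg$chrom, df$start, df$start + w,
                   name = sprintf("%s_peak_%03d", stage, seq_len(nrow(df))))
    mcols(gr)$score <- 1
    as_peak_set(gr)
  }
  asc <- mk_peaks(asc_df, "ASC"); fisc <- mk_peaks(fisc_df, "FISC")
  peak_truth <- data.frame(
    start = loci$start, end = loci$start + w, kind = loci$kind,
    planted_pqs = planted, subtype = ifelse(planted, subtype, "none"),
    pqs_strand = ifelse(planted, ifelse(minus, "-", "+"), "."),
    in_asc = locus_key %in% paste(asc_df$start),
    in_fisc = locus_key %in% paste(fisc_df$start))
  ## ---- TF peaks ----
  tf_peaks <- list(); tf_truth <- list()
  n_asc <- length(asc)
  free_slots <- setdiff(gap_slots, slots)
  for (tf in names(cfg$tf_fractions)) {
    n_tf <- round(cfg$tf_fractions[[tf]] * n_asc)
    sel <- sample(n_asc, n_tf)
    centre <- (start(asc[sel]) - 1L + end(asc[sel])) %/% 2L
    extra_slots <- sample(free_slots, min(cfg$n_tf_extra,
                                          length(free_slots)))
    extra <- noise_start(extra_slots) + 600L  # clear of any G4 peak
    s0 <- c(centre - cfg$tf_peak_width %/% 2L, extra)
    tf_peaks[[tf]] <- as_peak_set(granges0(cfg$chrom, s0,
                                           s0 + cfg$tf_peak_width))
    tf_truth[[tf]] <- list(fraction = n_tf / n_asc, n_overlapping = n_tf)
  }
  ## ---- elements ----
  pw <- promoter_windows(genes, cfg$promoter_up, cfg$promoter_down)
  promoters <- pw[genes$ep_role == "P"]
  enh_sel <- genes$ep_role == "E"
  enhancers <- granges0(cfg$chrom, genes$tss[enh_sel] + 2500L,
                        genes$tss[enh_sel] + 3000L,
                        name = genes$gene_id[enh_sel])
  ## ---- loops + matrices ----
  loops <- synth_loops(cfg, genes)
  loop_pixels <- data.frame(bin1 = loops$start1 %/% cfg$binsize,
                            bin2 = loops$start2 %/% cfg$binsize,
                            multiplier = loops$multiplier)
  mats <- synth_contact_pair(cfg, loop_pixels)
  ## ---- counts + expression ----
  gain_ids <- genes$gene_id[genes$pool %in% c("dual", "single_pos",
                                              "gain_free")]
  counts <- synth_count_contrasts(cfg, genes$gene_id, gain_ids)
  loop_class_of_gene <- rep("none", cfg$n_genes)
  loop_class_of_gene[genes$pool == "dual"] <- "dual_G4"
  loop_class_of_gene[genes$pool %in% c("single_pos", "single_neg")] <-
    "single_G4"
  loop_class_of_gene[genes$pool == "no"] <- "no_G4"
  shift <- ifelse(loop_class_of_gene == "none", 0,
                  cfg$expr_shift[loop_class_of_gene])
  expression <- stats::setNames(
    stats::rnorm(cfg$n_genes, cfg$expr_base_mean, cfg$expr_base_sd) + shift,
    genes$gene_id)
  ## anchored genes only get the class; the pool IS the class by construction
  gene_truth <- data.frame(
    gene_id = genes$gene_id, pool = genes$pool, ep_role = genes$ep_role,
    loop_class = loop_class_of_gene,
    promoter_g4_gain = genes$gene_id %in% gain_ids,
    stage_de = counts$truth$stage_de, pds_de = counts$truth$pds_de,
    bona_fide = counts$truth$bona_fide, expr_shift = unname(shift))
  ## a pool gene is only truly anchored if some loop uses it
  anchored <- unique(c(loops$gene1, loops$gene2))
  gene_truth$loop_class[!(gene_truth$gene_id %in% anchored)] <- "none"
  structure(list(
    config = cfg, genome = genome, genes = genes,
    peaks = list(FISC = fisc, ASC = asc), tf_peaks = tf_peaks,
    elements = list(promoters = promoters, enhancers = enhancers),
    loops = loops, matrices = list(ctrl = mats$cm_a, treat = mats$cm_b),
    counts = counts, expression = expression,
    truth = list(genes = gene_truth, peaks = peak_truth,
                 loops = loops[c("name", "class", "ep_type", "multiplier")],
                 diff_pixels = mats$diff_truth, tf = tf_truth)),
    class = "synth_bundle")
}

#' Write a synthetic bundle to disk
#'
#' Emits the plain-text files the package readers consume: genome FASTA,
#' gene-model TSV, per-stage and TF peak BEDs, element BEDs, loop BEDPE,
#' contact-matrix TSVs with a chromosome-sizes sidecar, count TSVs, an
#' expression TSV and the truth table as JSON.
#'
#' @param bundle from [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(bundle$genome), p("genome.fa"))
  write_gene_models(bundle$genes, p("genes.tsv"))
  for (st in names(bundle$peaks))
    write_peaks_bed(bundle$peaks[[st]], p(paste0("peaks_", st, ".bed")))
  for (tf in names(bundle$tf_peaks))
    write_peaks_bed(bundle$tf_peaks[[tf]], p(paste0("tf_", tf, ".bed")))
  write_peaks_bed(bundle$elements$promoters, p("promoters.bed"))
  write_peaks_bed(bundle$elements$enhancers, p("enhancers.bed"))
  write_loops_bedpe(bundle$loops, p("loops.bedpe"))
  write_contact_matrix(bundle$matrices$ctrl, p("matrix_ctrl.tsv"),
                       p("chrom_sizes.tsv"))
  write_contact_matrix(bundle$matrices$treat, p("matrix_treat.tsv"))
  write_counts(bundle$counts$counts_stage, p("counts_stage.tsv"))
  write_counts(bundle$counts$counts_pds, p("counts_pds.tsv"))
  utils::write.table(
    data.frame(gene_id = names(bundle$expression),
               expression = bundle$expression),
    p("expression.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$params <- unclass(bundle$config)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Verify a bundle's truth table against its emitted data
#'
#' Independent consistency checks: planted PQS peaks must contain a scanned
#' hit of the planted subtype and strand (and unplanted peaks none), loop
#' classes and E-P types recomputed from the emitted peaks/elements must
#' equal the truth, promoter-G4 gain recomputed from the two stage peak sets
#' must equal the truth, and the matrices/counts must be dimensioned and
#' depth-scaled as configured.
#'
#' @param bundle from [generate_bundle()].
#' @return `TRUE` invisibly; stops at the first inconsistency.
#' @export
check_bundle <- function(bundle) {
  cfg <- bundle$config
  tr <- bundle$truth$peaks
  for (r in seq_len(nrow(tr))) {
    seqr <- substr(bundle$genome[[cfg$chrom]], tr$start[r] + 1L, tr$end[r])
    hits <- scan_pqs(seqr, cfg$chrom, tr$start[r])
    if (tr$planted_pqs[r]) {
      if (length(hits) != 1L ||
          mcols(hits)$subtype != tr$subtype[r] ||
          as.character(strand(hits)) != tr$pqs_strand[r])
        stop("peak at ", tr$start[r], ": planted ", tr$subtype[r],
             " not recovered")
    } else if (length(hits) != 0L) {
      stop("peak at ", tr$start[r], ": unplanted locus contains a PQS")
    }
  }
  cls <- classify_loop_anchors(bundle$loops, bundle$peaks$ASC)$class
  if (!all(as.character(cls) == bundle$truth$loops$class))
    stop("loop classes disagree with truth")
  ep <- loop_ep_type(bundle$loops, bundle$elements$promoters,
                     bundle$elements$enhancers)
  if (!all(as.character(ep) == bundle$truth$loops$ep_type))
    stop("loop E-P types disagree with truth")
  gain <- promoter_g4_gain(bundle$peaks$FISC, bundle$peaks$ASC,
                           bundle$genes, cfg$promoter_up, cfg$promoter_down)
  want <- sort(bundle$truth$genes$gene_id[bundle$truth$genes$promoter_g4_gain])
  if (!identical(sort(gain), want))
    stop("promoter-G4 gain set disagrees with truth")
  for (m in bundle$matrices)
    if (abs(total_counts(m) / cfg$depth - 1) > 0.05)
      stop("matrix depth far from configured value")
  stopifnot(nrow(bundle$counts$counts_stage) == cfg$n_genes,
            length(bundle$expression) == cfg$n_genes)
  invisible(TRUE)
}
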