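#!/usr/bin/env Rscript
## Step 2 — PQS scanning and the G4 peak landscape.
##
## Scans the genome for putative quadruplex-forming sequences on both
## strands, types each hit (canonical / long-loop / bulge / two-quartet),
## measures peak-PQS overlap, stage-to-stage peak sharing, the genomic
## feature distribution of the peaks and TF co-binding fractions.

suppressPackageStartupMessages(library(quadloop))

bdir <- "results/bundle"
genome <- file.path(bdir, "genome.fa")
genes <- read_gene_models(file.path(bdir, "genes.tsv"))
fisc <- read_peaks_bed(file.path(bdir, "peaks_FISC.bed"))
asc <- read_peaks_bed(file.path(bdir, "peaks_ASC.bed"))

ov <- peak_pqs_overlap(asc, genome)
write_pqs_bed(ov$hits, "results/pqs_hits.bed")
cat(sprintf("ASC peaks overlapping a PQS: %.1f%% (%d/%d)\n",
            100 * ov$fraction, sum(ov$positive), length(asc)))

in_peaks <- ov$hits[GenomicRanges::countOverlaps(ov$hits, asc) > 0]
subt <- table(S4Vectors::mcols(in_peaks)$subtype)
cat("subtypes of peak-resident PQS:\n")
print(round(100 * subt / sum(subt), 1))

cmp <- compare_peak_sets(fisc, asc)
cat(sprintf("peak sharing FISC vs ASC: %d/%d and %d/%d shared (union %d)\n",
            cmp$shared_a, cmp$n_a, cmp$shared_b, cmp$n_b,
            cmp$n_union_merged))

dist <- genomic_distribution(asc, genes)
write.table(data.frame(category = names(dist), fraction = dist),
            "results/peak_distribution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("genomic distribution of ASC peaks (%):\n")
print(round(100 * dist, 1))

tf_files <- list.files(bdir, pattern = "^tf_.*\\.bed$", full.names = TRUE)
tfs <- lapply(tf_files, read_peaks_bed)
names(tfs) <- sub("^tf_(.*)\\.bed$", "\\1", basename(tf_files))
fr <- tf_overlap_fractions(asc, tfs)
write.table(data.frame(tf = names(fr), fraction = fr),
            "results/tf_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("TF co-binding fractions of G4 peaks (%):\n")
print(round(100 * fr, 1))
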