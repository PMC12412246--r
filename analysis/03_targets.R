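#!/usr/bin/env Rscript
## Step 3 — promoter-G4 target-gene classification chain.
##
## Promoter G4 gain (activated-stage-only promoter peaks) is intersected with
## stage differential expression to define G4-up / G4-down genes, then with
## the G4-ligand perturbation contrast to call the bona fide G4-activated and
## G4-repressed targets. Recovery is reported against the generator truth.

suppressPackageStartupMessages(library(quadloop))

bdir <- "results/bundle"
genes <- read_gene_models(file.path(bdir, "genes.tsv"))
fisc <- read_peaks_bed(file.path(bdir, "peaks_FISC.bed"))
asc <- read_peaks_bed(file.path(bdir, "peaks_ASC.bed"))
cnt_stage <- read_counts(file.path(bdir, "counts_stage.tsv"))
cnt_pds <- read_counts(file.path(bdir, "counts_pds.tsv"))

gain <- promoter_g4_gain(fisc, asc, genes)
cat(sprintf("genes with promoter G4 gain on activation: %d/%d\n",
            length(gain), nrow(genes)))

grp <- function(m) factor(sub("_\\d+$", "", colnames(m)),
                          levels = unique(sub("_\\d+$", "", colnames(m))))
de_stage <- differential_expression(cnt_stage, grp(cnt_stage))
de_pds <- differential_expression(cnt_pds, grp(cnt_pds))

cls <- classify_promoter_g4_genes(gain, de_stage)
bf <- call_bona_fide_targets(cls$g4_up, cls$g4_down, de_pds)
cat(sprintf("G4-up genes: %d; G4-down genes: %d\n",
            length(cls$g4_up), length(cls$g4_down)))
cat(sprintf("bona fide G4-activated: %d; G4-repressed: %d\n",
            length(bf$g4_activated), length(bf$g4_repressed)))

tab <- target_class_table(genes$gene_id, cls$g4_up, cls$g4_down,
                          bf$g4_activated, bf$g4_repressed)
write.table(tab, "results/target_classes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- jsonlite::read_json(file.path(bdir, "truth.json"),
                             simplifyVector = TRUE)$genes
planted <- truth$gene_id[truth$bona_fide == "activated"]
if (length(planted))
  cat(sprintf("planted activated targets recovered: %.0f%% (%d/%d)\n",
              100 * mean(planted %in% bf$g4_activated),
              sum(planted %in% bf$g4_activated), length(planted)))
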