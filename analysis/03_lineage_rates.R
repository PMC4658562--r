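#!/usr/bin/env Rscript
# Stage 3: lineage evolutionary rates.
#
# Fits the free-ratio codon model to every gene in the bundle, removes
# dN/dS > 4 outliers and dS > 1 saturated genes on the zokor/rat pair,
# compares the two lineages' dN/dS distributions by rank-sum test, and runs
# the GO-category acceleration (binomial) test on concatenated categories.

Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
suppressPackageStartupMessages(library(burrowevol))

input <- "results/data"
dir.create("results/rates", recursive = TRUE, showWarnings = FALSE)
tree <- prepare_tree(file.path(input, "tree.nwk"))
files <- sort(list.files(file.path(input, "alignments"), full.names = TRUE))
alns <- lapply(files, read_codon_fasta)
names(alns) <- sub("\\.fasta$", "", basename(files))

recs <- lapply(names(alns), function(g) fit_free_ratio(alns[[g]], tree, gene = g))
tab <- do.call(rbind, lapply(recs, function(r)
  cbind(gene = r$gene, r$branches, kappa = r$kappa)))
write.table(tab, "results/rates/free_ratio.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pair <- c("zokor", "rat")
kept <- filter_rate_outliers(recs, pair, omega_max = 4)
cat(sprintf("dN/dS > 4 filter: %d -> %d genes (removed: %s)\n", length(recs),
            length(kept), paste(attr(kept, "removed")$gene, collapse = ", ")))
sat <- saturation_filter(kept, pair, ds_max = 1)
cat(sprintf("dS > 1 saturation filter: %d -> %d genes (removed: %s)\n",
            length(kept), length(sat$records),
            paste(attr(sat$records, "removed")$gene, collapse = ", ")))
write.table(sat$diagnostic, "results/rates/saturation_diagnostic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cmp <- compare_lineage_rates(sat$records, "zokor", "rat")
cat(sprintf("Lineage dN/dS: zokor mean %.4f vs rat mean %.4f (rank-sum p = %.3g)\n",
            cmp$meanA, cmp$meanB, cmp$p_value))

ann <- read.table(file.path(input, "annotations.tsv"), header = TRUE, sep = "\t")
kept_genes <- vapply(sat$records, function(r) as.character(r$gene), character(1))
cats <- go_category_rates(alns[kept_genes], ann, tree, lineages = pair,
                          min_genes = 3) # demo bundle scale
if (length(cats)) {
  totals <- burrowevol:::genome_nonsyn_totals(sat$records, alns, pair)
  tests <- do.call(rbind, lapply(cats, function(cr)
    cbind(term = cr$term, n_genes = cr$n_genes,
          accelerated_category_test(cr, totals))))
  write.table(tests, "results/rates/go_acceleration.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  acc <- tests[tests$p_accelerated < 0.05, ]
  cat(sprintf("GO acceleration: %d categories tested, %d directional signals at p < 0.05\n",
              length(cats), nrow(acc)))
} else cat("GO acceleration: no category exceeded the size threshold\n")
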