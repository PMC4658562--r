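#!/usr/bin/env Rscript
# Stage 4: positive selection on the zokor lineage.
#
# Branch-site model A on every gene with zokor as foreground: LRT p-values,
# BH q-values, the PSG list at p < 0.05, BEB site posteriors for the PSGs,
# and tissue-specificity of PSG expression at the 1.5 / 3 / 4.5 fold ladder.

Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
suppressPackageStartupMessages(library(burrowevol))

input <- "results/data"
dir.create("results/selection", recursive = TRUE, showWarnings = FALSE)
tree <- prepare_tree(file.path(input, "tree.nwk"))
files <- sort(list.files(file.path(input, "alignments"), full.names = TRUE))
alns <- lapply(files, read_codon_fasta)
names(alns) <- sub("\\.fasta$", "", basename(files))

tests <- lapply(names(alns), function(g)
  branch_site_test(alns[[g]], tree, foreground = "zokor", gene = g))
p <- vapply(tests, `[[`, numeric(1), "p_value")
tab <- data.frame(gene = names(alns),
                  statistic = vapply(tests, `[[`, numeric(1), "statistic"),
                  p_value = p, q_value = benjamini_hochberg(p),
                  omega2 = vapply(tests, function(x) x$params_alt$omega2,
                                  numeric(1)))
tab$psg <- tab$p_value < 0.05
write.table(tab, "results/selection/branch_site.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json(file.path(input, "truth.json"))
planted <- names(Filter(function(g) g$role == "psg", truth$genes))
cat(sprintf("Branch-site screen: %d/%d genes at p < 0.05 (planted selected: %s)\n",
            sum(tab$psg), nrow(tab), paste(planted, collapse = ", ")))

psg <- tab$gene[tab$psg]
for (g in psg) {
  i <- match(g, names(alns))
  beb <- beb_site_posteriors(tests[[i]]$params_alt, alns[[g]], tree)
  n_hi <- sum(beb$pp_class2 > 0.9)
  cat(sprintf("  %s: omega2 = %.2f, %d sites with BEB posterior > 0.9\n",
              g, tab$omega2[i], n_hi))
  write.table(beb, sprintf("results/selection/beb_%s.tsv", g), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

expr_df <- read.table(file.path(input, "expression.tsv"), header = TRUE,
                      sep = "\t", check.names = FALSE)
expr <- as.matrix(expr_df[, -1]); rownames(expr) <- expr_df$gene
if (length(psg)) {
  prof <- tissue_specificity_profile(expr, intersect(psg, rownames(expr)))
  write.table(prof, "results/selection/psg_tissue_profile.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  top <- prof[prof$fold == 1.5 & prof$n_genes > 0, ]
  if (nrow(top))
    cat("Tissue-specific highest expression of PSGs (1.5-fold):",
        paste(sprintf("%s %d", top$tissue, top$n_genes), collapse = ", "), "\n")
}
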