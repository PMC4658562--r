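#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Writes a complete input bundle for the six-taxon rodent study design:
# per-gene codon alignments (with planted positively selected, rate-outlier
# and saturated genes), per-gene protein alignments with planted parallel
# substitutions on the zokor / naked mole-rat pair, and the GO, expression
# and PPI fixtures. Truth metadata lands beside the data.

Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
suppressPackageStartupMessages(library(burrowevol))

out <- "results/data"
truth <- write_study_bundle(out, n_genes = 12, n_codons = 150, seed = 42)

cat("Synthetic bundle written to", out, "\n")
cat(sprintf("  genes: %d (planted PSG %d, dN/dS outlier %d, saturated %d)\n",
            truth$n_genes, truth$n_psg_planted, truth$n_outlier_planted,
            truth$n_saturated_planted))
cat(sprintf("  genes with planted parallel sites: %d\n",
            sum(truth$n_parallel_planted > 0)))
cat(sprintf("  planted enriched GO terms: %s; planted hub: %s\n",
            paste(truth$fixtures$enriched_terms, collapse = ", "),
            truth$fixtures$hub))
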