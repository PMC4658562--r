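#!/usr/bin/env Rscript
# Stage 5: parallel / convergent evolution on the zokor and naked mole-rat
# branches.
#
# Marginal ancestral reconstruction of every protein alignment, substitution
# calls at the strict PP > 0.9 rule, classification on the focal branch
# pair, and binning of parallel evolved genes by their change counts.

Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")
suppressPackageStartupMessages(library(burrowevol))

input <- "results/data"
dir.create("results/convergence", recursive = TRUE, showWarnings = FALSE)
tree <- prepare_tree(file.path(input, "tree.nwk"))
pair <- c("zokor", "naked_mole_rat")
files <- sort(list.files(file.path(input, "proteins"), full.names = TRUE))

cls <- lapply(files, function(f) {
  x <- Biostrings::readAAStringSet(f)
  asr <- marginal_ancestral_reconstruction(setNames(as.character(x), names(x)),
                                           tree)
  ev <- call_branch_substitutions(asr, pp_min = 0.9)
  classify_pairwise_changes(ev, pair, tree)
})
names(cls) <- sub("\\.fasta$", "", basename(files))

tab <- do.call(rbind, lapply(names(cls), function(g) {
  cl <- cls[[g]]
  if (!nrow(cl)) return(NULL)
  cbind(gene = g, cl)
}))
if (!is.null(tab))
  write.table(tab, "results/convergence/pair_classification.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)

bins <- summarize_parallel_genes(cls)
conv <- sum(vapply(cls, function(cl) sum(cl$class == "convergent"), numeric(1)))
truth <- jsonlite::read_json(file.path(input, "truth.json"))
planted <- unlist(truth$n_parallel_planted)
cat(sprintf("Parallel evolved genes: %d (planted: %d); convergent sites: %d\n",
            bins$n_parallel_genes, sum(planted > 0), conv))
cat(sprintf("  bins by parallel-change count: 1 change %d, 2 changes %d, >2 changes %d\n",
            bins$bin_sizes[["1"]], bins$bin_sizes[["2"]], bins$bin_sizes[[">2"]]))
jsonlite::write_json(list(bin_sizes = as.list(bins$bin_sizes),
                          genes = bins$bins),
                     "results/convergence/peg_summary.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
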