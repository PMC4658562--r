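# Synthetic study bundle: every input the pipeline consumes, written to a
# directory as plain-text files with the generating truth alongside.

#' Write a complete synthetic input bundle
#'
#' Generates per-gene codon alignments on the study phylogeny (per-gene
#' dN/dS scaled around the lineage defaults, with a planted fraction of
#' positively selected genes, dN/dS outliers and saturated genes), per-gene
#' protein alignments with planted parallel substitutions on the focal pair,
#' and the annotation / expression / PPI fixtures. All files are plain text:
#' FASTA alignments, Newick tree, TSV tables and a JSON truth file.
#'
#' @param dir Output directory (created).
#' @param n_genes Number of genes.
#' @param n_codons Codon columns per gene.
#' @param seed Integer seed.
#' @param frac_psg Fraction of genes simulated under the branch-site
#'   alternative (omega2 = 4 on 30 percent of sites) on the foreground.
#' @param n_outlier,n_saturated Genes planted with focal dN/dS > 4 and with
#'   focal dS > 1 respectively.
#' @param n_protein_sites Sites per protein alignment.
#' @param tree Study tree (default [study_tree()]).
#' @param foreground Foreground branch id (default "zokor").
#' @param focal_pair Convergence branch pair (default zokor / naked mole-rat).
#' @return Invisibly, the truth list (also written to `truth.json`).
#' @export
write_study_bundle <- function(dir, n_genes = 12L, n_codons = 150L, seed = 1L,
                               frac_psg = 0.2, n_outlier = 1L,
                               n_saturated = 1L, n_protein_sites = 120L,
                               tree = study_tree(), foreground = "zokor",
                               focal_pair = c("zokor", "naked_mole_rat")) {
  dir.create(file.path(dir, "alignments"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "proteins"), showWarnings = FALSE)
  fx <- generate_annotation_fixtures(n_genes, n_terms = 12L, n_tissues = 5L,
                                     seed = seed + 1L)
  genes <- rownames(fx$expression)
  om0 <- study_branch_omega()
  st <- tree_struct(tree)
  n_psg <- round(frac_psg * n_genes)
  roles <- rep("background", n_genes)
  roles[seq_len(n_psg)] <- "psg"
  if (n_outlier > 0) roles[n_psg + seq_len(n_outlier)] <- "outlier"
  if (n_saturated > 0) roles[n_psg + n_outlier + seq_len(n_saturated)] <- "saturated"
  truth_genes <- list()
  n_parallel <- integer(n_genes)
  with_seed(seed + 2L, {
    gene_scale <- exp(stats::rnorm(n_genes, 0, 0.35))
    par_draw <- sample(c(0L, 1L, 2L, 3L), n_genes, replace = TRUE,
                       prob = c(0.6, 0.25, 0.1, 0.05))
  })
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    gseed <- seed * 1000L + i
    role <- roles[i]
    gtree <- tree
    om <- pmin(om0 * gene_scale[i], 0.9)
    if (role == "outlier") om[foreground] <- 6
    if (role == "saturated") {
      ed <- branch_edge_index(st, foreground)
      # inflate the focal branch length so dS exceeds 1
      gtree <- tree
      eidx <- which(branch_ids(gtree) == foreground)
      gtree$edge.length[eidx] <- 1.6
      om[foreground] <- 0.1
    }
    if (role == "psg") {
      sim <- simulate_branch_site_alignment(gtree, foreground, p0 = 0.6,
                                            p1 = 0.1, omega0 = 0.08,
                                            omega2 = 4, kappa = 2,
                                            n_codons = n_codons, seed = gseed)
    } else {
      sim <- simulate_codon_alignment(gtree, kappa = 2, per_branch_omega = om,
                                      n_codons = n_codons, seed = gseed)
    }
    write_codon_fasta(sim$alignment, file.path(dir, "alignments",
                                               paste0(g, ".fasta")))
    n_parallel[i] <- par_draw[i]
    prot <- simulate_protein_with_parallel_sites(
      tree, focal_pair, n_sites = n_protein_sites,
      n_parallel = n_parallel[i], seed = gseed + 500000L)
    Biostrings::writeXStringSet(Biostrings::AAStringSet(prot$alignment),
                                file.path(dir, "proteins", paste0(g, ".fasta")))
    truth_genes[[g]] <- list(role = role, n_parallel = n_parallel[i])
  }
  ape::write.tree(tree, file.path(dir, "tree.nwk"))
  utils::write.table(fx$annotations, file.path(dir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene = rownames(fx$expression), fx$expression,
                     check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fx$network, file.path(dir, "ppi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(seed = seed, n_genes = n_genes, n_codons = n_codons,
                foreground = foreground, focal_pair = focal_pair,
                genes = truth_genes,
                n_psg_planted = sum(roles == "psg"),
                n_outlier_planted = sum(roles == "outlier"),
                n_saturated_planted = sum(roles == "saturated"),
                n_parallel_planted = setNames(n_parallel, genes),
                fixtures = fx$truth)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(truth)
}
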