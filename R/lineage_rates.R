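# Genome-scale rate filtering and comparison: dN/dS outlier and dS
# saturation filters, lineage mean-rate comparison, and the GO-category
# acceleration (binomial) test on concatenated category alignments.

# Extract one branch statistic across a list of gene_evolution_records.
branch_stat <- function(records, branch, stat) {
  vapply(records, function(r) {
    i <- match(branch, r$branches$branch)
    if (is.na(i)) NA_real_ else r$branches[[stat]][i]
  }, numeric(1))
}

record_genes <- function(records)
  vapply(records, function(r) as.character(r$gene), character(1))

#' Remove dN/dS outlier genes
#'
#' Drops genes whose dN/dS exceeds `omega_max` on either focal branch
#' (strictly greater; `omega = omega_max` is kept). Genes with undefined
#' omega on a focal branch are kept.
#'
#' @param records List of `gene_evolution_record`s.
#' @param focal_branches Character vector of (typically two) branch ids.
#' @param omega_max Threshold (default 4).
#' @return Filtered list; removed genes and reasons in `attr(,"removed")`.
#' @export
filter_rate_outliers <- function(records, focal_branches, omega_max = 4) {
  bad <- rep(FALSE, length(records))
  why <- character(length(records))
  for (b in focal_branches) {
    om <- branch_stat(records, b, "omega")
    hit <- !is.na(om) & om > omega_max
    why[hit & !bad] <- sprintf("omega %.4g > %g on %s", om[hit & !bad],
                               omega_max, b)
    bad <- bad | hit
  }
  out <- records[!bad]
  attr(out, "removed") <- data.frame(gene = record_genes(records)[bad],
                                     reason = why[bad],
                                     stringsAsFactors = FALSE)
  out
}

#' Remove saturated genes and emit the saturation diagnostic
#'
#' Drops genes with dS strictly greater than `ds_max` on either focal branch
#' (dS equal to the threshold is kept) and returns, alongside, the (dS,
#' ts/tv) diagnostic table used to inspect saturation visually.
#'
#' @inheritParams filter_rate_outliers
#' @param ds_max dS threshold (default 1).
#' @return List with `records` (filtered) and `diagnostic` (data.frame gene,
#'   branch, dS, ts_tv); removed genes in `attr(records, "removed")`.
#' @export
saturation_filter <- function(records, focal_branches, ds_max = 1) {
  diag_list <- lapply(focal_branches, function(b) {
    data.frame(gene = record_genes(records), branch = b,
               dS = branch_stat(records, b, "dS"),
               ts_tv = branch_stat(records, b, "ts_tv"),
               stringsAsFactors = FALSE)
  })
  diagnostic <- do.call(rbind, diag_list)
  bad <- rep(FALSE, length(records))
  why <- character(length(records))
  for (b in focal_branches) {
    ds <- branch_stat(records, b, "dS")
    hit <- !is.na(ds) & ds > ds_max
    why[hit & !bad] <- sprintf("dS %.4g > %g on %s", ds[hit & !bad], ds_max, b)
    bad <- bad | hit
  }
  out <- records[!bad]
  attr(out, "removed") <- data.frame(gene = record_genes(records)[bad],
                                     reason = why[bad],
                                     stringsAsFactors = FALSE)
  list(records = out, diagnostic = diagnostic)
}

#' Compare mean dN/dS between two lineages
#'
#' Means are taken over genes with a defined dN/dS on the respective branch;
#' the two sets are compared with an unpaired two-sided Wilcoxon rank-sum
#' test (exact enumeration when both samples have at most `exact_max`
#' observations and no ties; normal approximation with continuity and tie
#' correction otherwise).
#'
#' @param records List of `gene_evolution_record`s.
#' @param lineageA,lineageB Branch ids.
#' @param exact_max Largest per-group size for the exact test (default 12).
#' @param paired Use a paired signed-rank test on genes with both values
#'   defined (default FALSE, matching a rank-sum comparison).
#' @return List with `meanA`, `meanB`, `statistic`, `p_value`, `nA`, `nB`.
#' @export
compare_lineage_rates <- function(records, lineageA, lineageB,
                                  exact_max = 12L, paired = FALSE) {
  a <- branch_stat(records, lineageA, "omega")
  b <- branch_stat(records, lineageB, "omega")
  if (paired) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 genes with defined omega per lineage")
  exact <- !paired && length(a) <= exact_max && length(b) <= exact_max &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, paired = paired, exact = exact, correct = TRUE))
  list(meanA = mean(a), meanB = mean(b),
       statistic = unname(wt$statistic), p_value = wt$p.value,
       nA = length(a), nB = length(b))
}

#' Per-GO-category concatenated rate estimates
#'
#' For every GO term annotated to strictly more than `min_genes` of the
#' supplied genes, concatenates the member alignments into a category
#' supergene, fits the free-ratio model, and records per-lineage dN/dS and
#' expected substitution counts (flow proportion x branch length x length in
#' codons).
#'
#' @param alignments_by_gene Named list of `codon_alignment`s.
#' @param annotations data.frame with columns `gene`, `term`.
#' @param tree Prepared `phylo`.
#' @param lineages Branch ids to report (default: all).
#' @param min_genes Strict lower bound on category size (default 20).
#' @return List of `category_rate_record`s: term, n_genes, genes, and a
#'   per-lineage data.frame (branch, omega, exp_nonsyn, exp_syn).
#' @export
go_category_rates <- function(alignments_by_gene, annotations, tree,
                              lineages = NULL, min_genes = 20L) {
  tree <- prepare_tree(tree)
  lineages <- lineages %||% branch_ids(tree)
  ann <- annotations[annotations$gene %in% names(alignments_by_gene), ]
  terms <- split(ann$gene, ann$term)
  terms <- terms[vapply(terms, function(g) length(unique(g)) > min_genes,
                        logical(1))]
  lapply(names(terms), function(tm) {
    genes <- unique(terms[[tm]])
    super <- concatenate_alignments(alignments_by_gene[genes])
    rec <- fit_free_ratio(super, tree, gene = tm)
    idx <- match(lineages, rec$branches$branch)
    n_codons <- super$n_codons
    per <- data.frame(
      branch = lineages,
      omega = rec$branches$omega[idx],
      exp_nonsyn = expected_counts(rec, lineages, n_codons, "nonsyn"),
      exp_syn = expected_counts(rec, lineages, n_codons, "syn"),
      stringsAsFactors = FALSE)
    structure(list(term = tm, n_genes = length(genes), genes = genes,
                   lineage = per, lnL = rec$lnL, kappa = rec$kappa),
              class = "category_rate_record")
  })
}

# Expected substitution counts on given branches of a fitted record.
expected_counts <- function(record, branches, n_codons, kind = c("nonsyn", "syn")) {
  kind <- match.arg(kind)
  vapply(branches, function(b) {
    i <- match(b, record$branches$branch)
    if (is.na(i) || record$degenerate) return(0)
    fl <- substitution_flows(record$kappa, max(record$branches$omega[i], 0,
                                               na.rm = TRUE),
                             record$codon_freqs)
    p <- if (kind == "nonsyn") fl$p_nonsyn else fl$p_syn
    record$branches$t[i] * p * n_codons
  }, numeric(1))
}

#' Binomial test for accelerated category evolution
#'
#' With `a` expected nonsynonymous substitutions in the category on lineage
#' A, `b` on lineage B, and `p0` the genome-wide lineage-A share of
#' nonsynonymous substitutions, tests "accelerated on A" with the one-sided
#' binomial tail P(X >= a | n = a + b, p0) and symmetrically for B. Counts
#' are rounded to the nearest integer before testing.
#'
#' @param category A `category_rate_record` (or list with `lineage` table).
#' @param genome_totals Named numeric: genome-wide expected nonsynonymous
#'   counts for the two lineages (names = branch ids).
#' @return data.frame with one row per direction: lineage, a, b, p0,
#'   p_accelerated.
#' @export
accelerated_category_test <- function(category, genome_totals) {
  if (length(genome_totals) != 2L || is.null(names(genome_totals)))
    stop("genome_totals must be a named length-2 vector")
  if (any(genome_totals <= 0)) stop("genome totals must be positive")
  lins <- names(genome_totals)
  counts <- setNames(vapply(lins, function(b) {
    i <- match(b, category$lineage$branch)
    if (is.na(i)) stop("category record lacks lineage ", b)
    category$lineage$exp_nonsyn[i]
  }, numeric(1)), lins)
  a <- round(counts[1]); b <- round(counts[2])
  n <- a + b
  p0 <- genome_totals[1] / sum(genome_totals)
  pA <- if (n == 0) 1 else stats::pbinom(a - 1, n, p0, lower.tail = FALSE)
  pB <- if (n == 0) 1 else stats::pbinom(b - 1, n, 1 - p0, lower.tail = FALSE)
  data.frame(lineage = lins, a = c(a, b), b = c(b, a),
             p0 = c(p0, 1 - p0), p_accelerated = c(pA, pB),
             rounded_from = unname(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
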