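# Candidate-gene interpretation: hypergeometric GO over-representation,
# tissue-specificity classification, and PPI sub-network extraction.

#' Hypergeometric GO enrichment
#'
#' One-sided (upper-tail) hypergeometric test of each term with at least one
#' candidate member, against the supplied background universe, with
#' Benjamini-Hochberg q-values across the tested terms. Results are ordered
#' by ascending p with a deterministic term-id tie-break.
#'
#' @param candidates Character vector of candidate genes (must be a subset
#'   of `background`).
#' @param background Character vector: the annotated gene universe.
#' @param annotations data.frame with columns `gene`, `term`.
#' @return data.frame: term, k (candidates with term), K (background with
#'   term), n (candidate set size), N (background size), p_value, q_value.
#' @export
hypergeometric_enrichment <- function(candidates, background, annotations) {
  candidates <- unique(candidates)
  background <- unique(background)
  extra <- setdiff(candidates, background)
  if (length(extra))
    stop("candidate gene(s) not in background: ",
         paste(utils::head(extra, 5), collapse = ", "))
  ann <- unique(annotations[annotations$gene %in% background,
                            c("gene", "term")])
  N <- length(background)
  n <- length(candidates)
  K_all <- table(ann$term)
  in_cand <- ann$gene %in% candidates
  k_all <- table(factor(ann$term[in_cand], levels = names(K_all)))
  tested <- names(K_all)[k_all >= 1]
  if (!length(tested))
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0)))
  k <- as.integer(k_all[tested])
  K <- as.integer(K_all[tested])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = tested, k = k, K = K, n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), ]
  out$q_value <- benjamini_hochberg(out$p_value)
  rownames(out) <- NULL
  attr(out, "untested_terms") <- setdiff(names(K_all), tested)
  out
}

#' Tissue-specific highest expression classification
#'
#' A gene is assigned to tissue T iff its log2(FPKM + 1) in T is strictly
#' greater than `fold` times the log2(FPKM + 1) of every other tissue; at
#' most one tissue can qualify per gene.
#'
#' @param table Gene x tissue matrix of FPKM values (>= 0), with rownames.
#' @param genes Genes to classify (must all be rows of `table`).
#' @param fold Fold threshold on the log2(FPKM + 1) scale (> 1).
#' @return Named character vector gene -> tissue, `NA` for unassigned genes.
#' @export
tissue_specific_highest_expression <- function(table, genes, fold) {
  if (fold <= 1) stop("fold must be > 1")
  if (any(table < 0)) stop("FPKM values must be >= 0")
  if (is.null(colnames(table)) || ncol(table) < 2L)
    stop("expression table needs named tissue columns (>= 2)")
  missing <- setdiff(genes, rownames(table))
  if (length(missing))
    stop("gene(s) absent from expression table: ",
         paste(utils::head(missing, 5), collapse = ", "))
  lx <- log2(table[genes, , drop = FALSE] + 1)
  tissues <- colnames(lx)
  out <- setNames(rep(NA_character_, length(genes)), genes)
  for (g in seq_along(genes)) {
    v <- lx[g, ]
    for (ti in seq_along(tissues)) {
      if (all(v[ti] > fold * v[-ti])) {
        out[g] <- tissues[ti]
        break
      }
    }
  }
  out
}

#' Tissue-specificity profile over a ladder of fold thresholds
#'
#' @inheritParams tissue_specific_highest_expression
#' @param folds Fold thresholds (default `c(1.5, 3, 4.5)`).
#' @return data.frame: fold, tissue, n_genes, percent (of the input set).
#' @export
tissue_specificity_profile <- function(table, genes, folds = c(1.5, 3, 4.5)) {
  res <- lapply(folds, function(f) {
    a <- tissue_specific_highest_expression(table, genes, f)
    tab <- table(factor(a, levels = colnames(table)))
    data.frame(fold = f, tissue = names(tab), n_genes = as.integer(tab),
               percent = 100 * as.integer(tab) / length(genes),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

ppi_graph <- function(edges) {
  if (!all(c("from", "to") %in% names(edges)))
    stop("edge list must have columns from, to")
  e <- edges[edges$from != edges$to, c("from", "to")]
  key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
  e <- e[!duplicated(key), ]
  igraph::graph_from_data_frame(e, directed = FALSE)
}

#' Extract seed-anchored PPI sub-networks
#'
#' Builds the graph induced by the seed genes plus their direct interactors,
#' takes connected components, and retains components with at least
#' `min_nodes` nodes (strictly more than `min_nodes - 1`; the default keeps
#' components of 6+ nodes and filters those with <= 5).
#'
#' @param seeds Character vector of seed genes.
#' @param edges Undirected edge list (data.frame `from`, `to`); self-loops
#'   and duplicate edges are ignored.
#' @param min_nodes Minimum component size retained (default 6).
#' @return List with `subnetworks` (list of data.frames with `nodes`
#'   (node, degree, is_seed) and `edges`), and `summary` (mapped_seeds,
#'   total_seeds, percent_mapped, total_nodes, total_edges, n_subnetworks).
#' @export
extract_subnetworks <- function(seeds, edges, min_nodes = 6L) {
  seeds <- unique(seeds)
  g <- ppi_graph(edges)
  present <- intersect(seeds, igraph::V(g)$name)
  nb <- if (length(present))
    unique(unlist(lapply(igraph::ego(g, order = 1, nodes = present),
                         function(v) names(v)))) else character(0)
  keep <- union(present, nb)
  sub <- igraph::induced_subgraph(g, keep)
  comp <- igraph::components(sub)
  retained <- which(comp$csize >= min_nodes)
  subnetworks <- lapply(retained, function(ci) {
    nodes <- names(comp$membership)[comp$membership == ci]
    gg <- igraph::induced_subgraph(sub, nodes)
    deg <- igraph::degree(gg)
    el <- igraph::as_data_frame(gg, what = "edges")
    list(nodes = data.frame(node = names(deg), degree = as.integer(deg),
                            is_seed = names(deg) %in% seeds,
                            stringsAsFactors = FALSE),
         edges = el)
  })
  all_nodes <- unlist(lapply(subnetworks, function(s) s$nodes$node))
  total_edges <- sum(vapply(subnetworks, function(s) nrow(s$edges), integer(1)))
  mapped <- sum(seeds %in% all_nodes)
  list(subnetworks = subnetworks,
       summary = list(mapped_seeds = mapped, total_seeds = length(seeds),
                      percent_mapped = if (length(seeds)) 100 * mapped / length(seeds) else 0,
                      total_nodes = length(all_nodes),
                      total_edges = total_edges,
                      n_subnetworks = length(subnetworks)))
}

#' High-degree nodes of retained sub-networks
#'
#' @param subnets Result of [extract_subnetworks()].
#' @param min_degree Degree threshold; nodes with degree strictly greater
#'   are reported (default 100).
#' @param seed_labels Optional named character vector gene -> label (e.g.
#'   "PSG", "PEG", "both") used to annotate hits.
#' @return data.frame: node, degree, label (NA when unlabelled), sorted by
#'   decreasing degree.
#' @export
high_degree_nodes <- function(subnets, min_degree = 100L, seed_labels = NULL) {
  nodes <- do.call(rbind, lapply(subnets$subnetworks, function(s) s$nodes))
  if (is.null(nodes) || !nrow(nodes))
    return(data.frame(node = character(0), degree = integer(0),
                      label = character(0)))
  hits <- nodes[nodes$degree > min_degree, , drop = FALSE]
  hits$label <- if (nrow(hits) == 0L) character(0)
  else if (is.null(seed_labels)) rep(NA_character_, nrow(hits))
  else unname(seed_labels[hits$node])
  hits <- hits[order(-hits$degree, hits$node), c("node", "degree", "label")]
  rownames(hits) <- NULL
  hits
}

#' Label genes by candidate-class membership
#'
#' @param psg,peg Character vectors of positively selected and parallel
#'   evolved genes.
#' @return Named character vector with values "PSG", "PEG" or "both".
#' @export
candidate_labels <- function(psg, peg) {
  all <- union(psg, peg)
  setNames(ifelse(all %in% psg & all %in% peg, "both",
                  ifelse(all %in% psg, "PSG", "PEG")), all)
}
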