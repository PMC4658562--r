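# Annotation, expression and interaction-network fixtures with planted
# structure (enriched terms, tissue-specific genes, high-degree hubs).

#' Generate annotation, expression and PPI fixtures
#'
#' Produces the three interpretation-layer inputs with known ground truth:
#' a gene -> GO-term table (with two planted enriched terms covering a
#' designated candidate set), a gene x tissue FPKM matrix (with planted
#' tissue-specific genes), and a simple undirected PPI edge list (with a
#' planted hub of 120 edges when enough genes are available).
#'
#' @param n_genes Number of genes (`gene0001`, ...).
#' @param n_terms Number of GO-like terms (`T0001`, ...); 0 gives an empty
#'   annotation table.
#' @param n_tissues Number of tissues (defaults to the five-tissue panel
#'   brain/liver/kidney/muscle/retina when `n_tissues = 5`).
#' @param seed Integer seed.
#' @return List with `annotations` (data.frame gene, term), `expression`
#'   (matrix genes x tissues of FPKM), `network` (data.frame from, to) and
#'   `truth` (planted candidate set, enriched terms, tissue-specific genes,
#'   hub gene).
#' @export
generate_annotation_fixtures <- function(n_genes, n_terms, n_tissues, seed) {
  if (n_genes <= 0) stop("n_genes must be positive")
  genes <- sprintf("gene%04d", seq_len(n_genes))
  tissues <- if (n_tissues == 5L) {
    c("brain", "liver", "kidney", "muscle", "retina")
  } else sprintf("tissue%02d", seq_len(n_tissues))
  terms <- if (n_terms > 0) sprintf("T%04d", seq_len(n_terms)) else character(0)
  with_seed(seed, {
    # candidate set: first 10% of genes (at least 5, at most 50)
    n_cand <- min(50L, max(5L, round(n_genes * 0.1)))
    candidates <- genes[seq_len(min(n_cand, n_genes))]
    ann <- NULL
    enriched <- character(0)
    if (n_terms > 0) {
      k <- stats::rpois(n_genes, 2)
      g <- rep(genes, k)
      t <- if (length(g)) sample(terms, length(g), replace = TRUE) else character(0)
      ann <- unique(data.frame(gene = g, term = t, stringsAsFactors = FALSE))
      # planted enriched terms: cover the whole candidate set plus ~5% of the
      # background
      enriched <- terms[seq_len(min(2L, n_terms))]
      for (tm in enriched) {
        avail <- setdiff(genes, candidates)
        bg_extra <- if (length(avail))
          sample(avail, min(length(avail), max(1L, round(0.05 * n_genes))))
        else character(0)
        add <- data.frame(gene = c(candidates, bg_extra), term = tm,
                          stringsAsFactors = FALSE)
        ann <- unique(rbind(ann[ann$term != tm, ], add))
      }
      ann <- ann[order(ann$gene, ann$term), ]
      rownames(ann) <- NULL
    } else {
      ann <- data.frame(gene = character(0), term = character(0))
    }
    # expression
    expr <- matrix(stats::rlnorm(n_genes * length(tissues), meanlog = 2, sdlog = 1),
                   nrow = n_genes, dimnames = list(genes, tissues))
    n_spec <- min(10L, n_genes)
    spec_genes <- sample(genes, n_spec)
    spec_tissue <- sample(tissues, n_spec, replace = TRUE)
    for (i in seq_len(n_spec))
      expr[spec_genes[i], spec_tissue[i]] <-
        max(expr[spec_genes[i], ]) * 60 + 100
    # network: random simple graph plus a planted hub with 120 edges
    m <- min(4L * n_genes, n_genes * (n_genes - 1) / 2)
    a <- sample(genes, m, replace = TRUE)
    b <- sample(genes, m, replace = TRUE)
    edges <- data.frame(from = pmin(a, b), to = pmax(a, b),
                        stringsAsFactors = FALSE)
    edges <- unique(edges[edges$from != edges$to, ])
    hub <- NA_character_
    if (n_genes > 121L) {
      hub <- genes[n_genes] # deterministic choice
      partners <- sample(setdiff(genes, hub), 120L)
      hub_edges <- data.frame(from = pmin(hub, partners),
                              to = pmax(hub, partners),
                              stringsAsFactors = FALSE)
      edges <- edges[!(edges$from == hub | edges$to == hub), ]
      edges <- unique(rbind(edges, hub_edges))
    }
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
    list(annotations = ann, expression = expr, network = edges,
         truth = list(candidates = candidates, enriched_terms = enriched,
                      tissue_specific = setNames(spec_tissue, spec_genes),
                      hub = hub, seed = seed))
  })
}
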