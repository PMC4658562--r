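test_that("hypergeometric enrichment matches exact combinatorics", {
  # N=20, K=5, n=5, k=5 -> 1 / C(20,5)
  bg <- paste0("g", 1:20)
  ann <- data.frame(gene = bg[1:5], term = "T1")
  res <- hypergeometric_enrichment(bg[1:5], bg, ann)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # exhaustive oracle on random small instances (N <= 30)
  withr::with_seed(81, {
    for (i in 1:10) {
      N <- sample(10:30, 1)
      bgx <- paste0("x", seq_len(N))
      K <- sample.int(N, 1)
      n <- sample.int(N, 1)
      annx <- data.frame(gene = sample(bgx, K), term = "T")
      cand <- sample(bgx, n)
      k <- sum(cand %in% annx$gene)
      if (k == 0) next
      got <- hypergeometric_enrichment(cand, bgx, annx)
      oracle <- sum(vapply(k:min(K, n), function(j)
        choose(K, j) * choose(N - K, n - j), numeric(1))) / choose(N, n)
      expect_equal(got$p_value, oracle, tolerance = 1e-10)
    }
  })
})

test_that("enrichment edge rules: full candidates, untested terms, bad input", {
  bg <- paste0("g", 1:10)
  ann <- data.frame(gene = bg, term = "T1")
  res <- hypergeometric_enrichment(bg, bg, ann)
  expect_equal(res$p_value, 1)
  ann2 <- rbind(ann, data.frame(gene = bg[6:10], term = "T2"))
  res2 <- hypergeometric_enrichment(bg[1:3], bg, ann2)
  expect_false("T2" %in% res2$term)           # k = 0: not tested
  expect_true("T2" %in% attr(res2, "untested_terms"))
  expect_error(hypergeometric_enrichment(c(bg[1], "zz"), bg, ann), "zz")
})

test_that("tissue-specificity follows the printed log2 fold rule", {
  tiss <- c("brain", "liver", "kidney", "muscle", "retina")
  m <- rbind(hi = 2^c(6, 1, 1, 1, 1) - 1,   # log2(fpkm+1) = (6,1,1,1,1)
             zero = rep(0, 5),
             close = 2^c(4, 3, 1, 1, 1) - 1) # (4,3,1,1,1)
  colnames(m) <- tiss
  expect_equal(unname(tissue_specific_highest_expression(m, "hi", 3)), "brain")
  expect_true(is.na(tissue_specific_highest_expression(m, "zero", 1.5)))
  expect_true(is.na(tissue_specific_highest_expression(m, "close", 1.5)))
  expect_error(tissue_specific_highest_expression(m, "nope", 2), "nope")
  expect_error(tissue_specific_highest_expression(m, "hi", 1), "fold")
})

test_that("tissue assignments are monotone in the fold threshold", {
  withr::with_seed(82, {
    m <- matrix(stats::rlnorm(200 * 5, 2, 1.5), 200,
                dimnames = list(paste0("g", 1:200),
                                c("brain", "liver", "kidney", "muscle", "retina")))
  })
  genes <- rownames(m)
  prev <- NULL
  for (f in c(1.5, 3, 4.5)) {
    a <- tissue_specific_highest_expression(m, genes, f)
    assigned <- names(a)[!is.na(a)]
    expect_lte(length(assigned), length(genes))
    if (!is.null(prev)) expect_true(all(assigned %in% prev))
    prev <- assigned
  }
  prof <- tissue_specificity_profile(m, genes)
  expect_equal(sort(unique(prof$fold)), c(1.5, 3, 4.5))
  expect_true(all(prof$percent >= 0 & prof$percent <= 100))
})

test_that("sub-network extraction applies the component-size rule exactly", {
  # seed neighbourhoods: a 6-node star (retained), a 5-node star (dropped)
  # and an isolated seed (dropped)
  e6 <- data.frame(from = "a0", to = paste0("a", 1:5))
  e5 <- data.frame(from = "b0", to = paste0("b", 1:4))
  edges <- rbind(e6, e5)
  seeds <- c("a0", "b0", "iso")
  sub <- extract_subnetworks(seeds, edges, min_nodes = 6)
  expect_equal(sub$summary$n_subnetworks, 1L)
  expect_equal(sub$summary$total_nodes, 6L)
  expect_equal(sub$summary$total_edges, 5L)
  expect_equal(sub$summary$mapped_seeds, 1L)
  # duplicate rows and reversed edges do not change totals
  edges2 <- rbind(edges, data.frame(from = edges$to, to = edges$from), edges[1, ])
  sub2 <- extract_subnetworks(seeds, edges2[sample(nrow(edges2)), ], min_nodes = 6)
  expect_equal(sub2$summary$total_nodes, sub$summary$total_nodes)
  expect_equal(sub2$summary$total_edges, sub$summary$total_edges)
})

test_that("high-degree reporting uses a strict threshold and candidate labels", {
  hub <- data.frame(from = "h", to = paste0("n", 1:101))
  spoke <- data.frame(from = "m", to = paste0("q", 1:100))
  sub_hub <- extract_subnetworks("h", hub, min_nodes = 6)
  sub_spoke <- extract_subnetworks("m", spoke, min_nodes = 6)
  labels <- candidate_labels(psg = c("h", "x"), peg = c("h", "y"))
  hd <- high_degree_nodes(sub_hub, 100, labels)
  expect_equal(hd$node, "h")
  expect_equal(hd$degree, 101L)
  expect_equal(hd$label, "both")
  expect_equal(nrow(high_degree_nodes(sub_spoke, 100)), 0L) # degree 100 excluded
  expect_equal(unname(labels[c("x", "y")]), c("PSG", "PEG"))
})
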