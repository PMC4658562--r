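test_that("zero branch lengths give identical leaves and an empty event log", {
  tr <- prepare_tree("((a:0,b:0)ab:0,c:0)r;")
  sim <- simulate_codon_alignment(tr, kappa = 2, per_branch_omega = 0.5,
                                  n_codons = 50, seed = 1)
  m <- sim$alignment$codons
  expect_true(all(m[1, ] == m[2, ]) && all(m[1, ] == m[3, ]))
  expect_equal(nrow(sim$truth$event_log), 0L)
})

test_that("omega = 0 simulations contain only synonymous events", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, kappa = 2, per_branch_omega = 0,
                                  n_codons = 500, seed = 2)
  expect_gt(nrow(sim$truth$event_log), 0L)
  expect_true(all(sim$truth$event_log$synonymous))
})

test_that("identical seeds reproduce simulations exactly; seeds differ otherwise", {
  tr <- study_tree()
  s1 <- simulate_codon_alignment(tr, 2, 0.2, n_codons = 40, seed = 9)
  s2 <- simulate_codon_alignment(tr, 2, 0.2, n_codons = 40, seed = 9)
  s3 <- simulate_codon_alignment(tr, 2, 0.2, n_codons = 40, seed = 10)
  expect_identical(s1$alignment$codons, s2$alignment$codons)
  expect_identical(s1$truth$event_log, s2$truth$event_log)
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
})

test_that("replaying the event log reproduces every leaf sequence", {
  tr <- study_tree()
  for (seed in c(3, 4)) {
    sim <- simulate_codon_alignment(tr, 2, 0.3, n_codons = 80, seed = seed)
    rp <- replay_event_log(sim$truth)
    expect_identical(rp[sim$alignment$taxa, ], sim$alignment$codons)
  }
  bs <- simulate_branch_site_alignment(tr, "zokor", p0 = 0.6, p1 = 0.2,
                                       omega0 = 0.1, omega2 = 4, kappa = 2,
                                       n_codons = 60, seed = 5)
  rp <- replay_event_log(bs$truth)
  expect_identical(rp[bs$alignment$taxa, ], bs$alignment$codons)
})

test_that("simulated ts/tv event ratio matches the rate-matrix expectation", {
  # single effective branch: expectation computed from substitution flows
  tr <- prepare_tree("(a:0.5,b:0.0)r;")
  sim <- simulate_codon_alignment(tr, kappa = 2, per_branch_omega = 1,
                                  n_codons = 8000, seed = 6)
  ev <- sim$truth$event_log
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  pos <- mapply(function(f, t) which(strsplit(f, "")[[1]] != strsplit(t, "")[[1]]),
                ev$from_codon, ev$to_codon)
  fr <- substr(ev$from_codon, pos, pos)
  to <- substr(ev$to_codon, pos, pos)
  is_ts <- purine[fr] == purine[to]
  fl <- burrowevol:::substitution_flows(2, 1, uniform_codon_freqs())
  expected <- fl$p_ts / fl$p_tv
  observed <- sum(is_ts) / sum(!is_ts)
  expect_equal(observed, expected, tolerance = 0.08)
})

test_that("branch-site simulation honours its class structure", {
  tr <- study_tree()
  # degenerate proportions: p0 = 1 leaves no class-2 sites
  s <- simulate_branch_site_alignment(tr, "zokor", p0 = 1, p1 = 0,
                                      omega0 = 0.2, omega2 = 9, kappa = 2,
                                      n_codons = 100, seed = 7)
  expect_true(all(s$truth$site_classes == "0"))
  # class-2 sites accumulate more foreground nonsynonymous events
  s2 <- simulate_branch_site_alignment(tr, "zokor", p0 = 0.65, p1 = 0.05,
                                       omega0 = 0.1, omega2 = 5, kappa = 2,
                                       n_codons = 300, seed = 8)
  ev <- s2$truth$event_log
  cls <- s2$truth$site_classes
  fg_nonsyn <- ev[ev$branch == "zokor" & !ev$synonymous, ]
  per_class <- table(factor(cls[fg_nonsyn$site], levels = c("0", "1", "2a", "2b")))
  n_class <- table(factor(cls, levels = c("0", "1", "2a", "2b")))
  rate2 <- sum(per_class[c("2a", "2b")]) / sum(n_class[c("2a", "2b")])
  rate0 <- per_class[["0"]] / n_class[["0"]]
  expect_gt(rate2, rate0)
  # foreground absent from tree is rejected
  expect_error(simulate_branch_site_alignment(tr, "pika", 0.5, 0.3, 0.2, 2,
                                              2, 10, 1), "pika")
})

test_that("degenerate branch-site model collapses to the neutral single-class model", {
  tr <- study_tree()
  s <- simulate_branch_site_alignment(tr, "zokor", p0 = 0.4, p1 = 0.4,
                                      omega0 = 1, omega2 = 1, kappa = 2,
                                      n_codons = 50, seed = 11)
  ll_bs <- log_likelihood(s$alignment, tr,
                          list(kappa = 2, p0 = 0.4, p1 = 0.4, omega0 = 1,
                               omega2 = 1, foreground = "zokor"))
  ll_one <- log_likelihood(s$alignment, tr, list(kappa = 2, omega = 1))
  expect_equal(ll_bs, ll_one, tolerance = 1e-10)
})

test_that("planted parallel sites are exact and exclusive", {
  tr <- study_tree()
  pair <- c("zokor", "naked_mole_rat")
  p0 <- simulate_protein_with_parallel_sites(tr, pair, n_sites = 120,
                                             n_parallel = 0, seed = 12)
  cl0 <- pair_oracle(p0$truth, pair)
  expect_equal(sum(cl0$class == "parallel"), 0L)
  p5 <- simulate_protein_with_parallel_sites(tr, pair, n_sites = 200,
                                             n_parallel = 5, seed = 13)
  cl5 <- pair_oracle(p5$truth, pair)
  expect_equal(sum(cl5$class == "parallel"), 5L)
  expect_setequal(cl5$site[cl5$class == "parallel"], p5$truth$parallel_sites)
  # planted Glu -> Asp replacement classifies as parallel downstream
  pe <- simulate_protein_with_parallel_sites(tr, pair, n_sites = 30,
                                             n_parallel = 1, seed = 14,
                                             planted_change = c("E", "D"))
  ev <- events_from_truth(pe$truth, pair)
  cls <- classify_pairwise_changes(ev, pair, tr)
  hit <- cls[cls$site == pe$truth$parallel_sites[1], ]
  expect_equal(hit$class, "parallel")
  expect_equal(hit$from_a, "E")
  expect_equal(hit$to_a, "D")
  expect_error(simulate_protein_with_parallel_sites(tr, pair, 10, 11, 1),
               "exceed")
  expect_error(simulate_protein_with_parallel_sites(tr, c("zokor", "murid"),
                                                    10, 1, 1), "ancestral")
})

test_that("fixture generator plants verifiable structure", {
  fx <- generate_annotation_fixtures(150, n_terms = 10, n_tissues = 5, seed = 21)
  expect_true(all(fx$expression >= 0))
  expect_true(all(fx$network$from != fx$network$to))
  key <- paste(pmin(fx$network$from, fx$network$to),
               pmax(fx$network$from, fx$network$to))
  expect_equal(anyDuplicated(key), 0L)
  # planted hub reaches the high-degree summary at the printed threshold
  sub <- extract_subnetworks(c(fx$truth$candidates, fx$truth$hub), fx$network)
  hubs <- high_degree_nodes(sub, 100)
  expect_true(fx$truth$hub %in% hubs$node)
  expect_equal(hubs$degree[hubs$node == fx$truth$hub], 120L)
  # planted enriched term is recovered far below 1e-6
  bg <- rownames(fx$expression)
  enr <- hypergeometric_enrichment(fx$truth$candidates, bg, fx$annotations)
  expect_lt(enr$p_value[enr$term == fx$truth$enriched_terms[1]], 1e-6)
  # no terms -> empty annotation and no tested terms downstream
  fx0 <- generate_annotation_fixtures(30, n_terms = 0, n_tissues = 3, seed = 22)
  expect_equal(nrow(fx0$annotations), 0L)
  enr0 <- hypergeometric_enrichment(rownames(fx0$expression)[1:5],
                                    rownames(fx0$expression), fx0$annotations)
  expect_equal(nrow(enr0), 0L)
  # determinism
  fx2 <- generate_annotation_fixtures(150, n_terms = 10, n_tissues = 5, seed = 21)
  expect_identical(fx$annotations, fx2$annotations)
  expect_identical(fx$network, fx2$network)
  expect_identical(fx$expression, fx2$expression)
})
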