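pairz <- c("zokor", "naked_mole_rat")

test_that("unanimous leaves reconstruct with near-certain posteriors", {
  tr <- study_tree()
  aln <- setNames(rep(strrep("K", 10), 6), tr$tip.label)
  asr <- marginal_ancestral_reconstruction(aln, tr)
  expect_true(all(asr$best_state == "K"))
  expect_true(all(asr$pp > 0.99))
})

test_that("marginal posteriors match the Bayes closed form on a star tree", {
  star <- ape::read.tree(text = "(a:0.2,b:0.3,c:0.4)r;")
  aln <- c(a = "KA", b = "KA", c = "RA")
  asr <- marginal_ancestral_reconstruction(aln, star, reestimate_lengths = FALSE)
  Q <- aa_rate_matrix()
  pi <- attr(Q, "pi")
  Pa <- transition_probabilities(Q, 0.2)
  Pb <- transition_probabilities(Q, 0.3)
  Pc <- transition_probabilities(Q, 0.4)
  for (s in 1:2) {
    obs <- c(substr(aln[1], s, s), substr(aln[2], s, s), substr(aln[3], s, s))
    post <- pi * Pa[, obs[1]] * Pb[, obs[2]] * Pc[, obs[3]]
    post <- post / sum(post)
    expect_equal(asr$posterior[["r"]][, s], post, tolerance = 1e-10)
  }
  sums <- colSums(asr$posterior[["r"]])
  expect_true(all(abs(sums - 1) < 1e-8))
})

test_that("the amino-acid pruning likelihood matches an independent implementation", {
  skip_if_not_installed("phangorn")
  tr <- study_tree()
  sim <- simulate_protein_with_parallel_sites(tr, pairz, 60, 2, seed = 91)
  aln <- sim$alignment
  st <- burrowevol:::tree_struct(tr)
  codes <- burrowevol:::aa_codes(aln)[tr$tip.label, ]
  pat <- burrowevol:::aa_pattern_data(codes)
  Q <- aa_rate_matrix()
  P <- burrowevol:::aa_pcube(Q, st$t)
  ll_mine <- burrowevol:::cpp_prune_loglik(pat$tipdata, pat$counts, st$edge,
                                           P, rep(1 / 20, 20))$loglik
  m <- t(vapply(strsplit(aln, ""), identity, character(nchar(aln[1]))))
  rownames(m) <- names(aln)
  fit <- phangorn::pml(tr, phangorn::phyDat(m, type = "AA"))
  expect_equal(ll_mine, fit$logLik, tolerance = 1e-6)
})

test_that("substitution calls apply the strict posterior cutoff at both ends", {
  tr <- study_tree()
  st <- burrowevol:::tree_struct(tr)
  internal <- st$labels[(st$ntip + 1):max(st$edge)]
  nsite <- 3
  best <- matrix("A", length(internal), nsite, dimnames = list(internal, NULL))
  pp <- matrix(1, length(internal), nsite, dimnames = list(internal, NULL))
  tips <- matrix("A", st$ntip, nsite, dimnames = list(tr$tip.label, NULL))
  # zokor differs at all three sites; parent ("murid") pp varies
  tips["zokor", ] <- "S"
  pp["murid", 1] <- 0.90   # exactly at the cutoff: suppressed
  pp["murid", 2] <- 0.91   # above: emitted
  pp["murid", 3] <- 0.9000001
  post <- structure(list(best_state = best, pp = pp, tip_states = tips,
                         tree = tr), class = "ancestral_posterior")
  ev <- call_branch_substitutions(post, pp_min = 0.9)
  zk <- ev[ev$branch == "zokor", ]
  expect_setequal(zk$site, c(2L, 3L))
  # raising the cutoff is monotone: never more events
  for (cut in c(0, 0.5, 0.95, 0.99)) {
    n_low <- nrow(call_branch_substitutions(post, pp_min = cut))
    n_high <- nrow(call_branch_substitutions(post, pp_min = min(cut + 0.04, 1)))
    expect_gte(n_low, n_high)
  }
})

test_that("pairwise classification follows the ancestral-state definitions", {
  mk <- function(fa, ta, fb, tb) {
    data.frame(branch = rep(pairz, c(1, 1)), site = 1L,
               from_aa = c(fa, fb), to_aa = c(ta, tb),
               stringsAsFactors = FALSE)
  }
  expect_equal(classify_pairwise_changes(mk("E", "D", "E", "D"), pairz)$class,
               "parallel")
  expect_equal(classify_pairwise_changes(mk("K", "D", "E", "D"), pairz)$class,
               "convergent")
  expect_equal(classify_pairwise_changes(mk("E", "D", "E", "V"), pairz)$class,
               "divergent")
  one <- data.frame(branch = "zokor", site = 1L, from_aa = "E", to_aa = "D")
  expect_equal(classify_pairwise_changes(one, pairz)$class, "none")
  # focal order does not matter
  tr <- study_tree()
  sim <- simulate_protein_with_parallel_sites(tr, pairz, 150, 3, seed = 71)
  ev <- events_from_truth(sim$truth)
  c1 <- classify_pairwise_changes(ev, pairz, tr)
  c2 <- classify_pairwise_changes(ev, rev(pairz), tr)
  expect_equal(sum(c1$class == "parallel"), sum(c2$class == "parallel"))
  expect_equal(sum(c1$class == "convergent"), sum(c2$class == "convergent"))
  expect_error(classify_pairwise_changes(ev, c("zokor", "murid"), tr),
               "ancestral")
})

test_that("classification from true states equals the site-comparison oracle", {
  tr <- study_tree()
  for (seed in 72:74) {
    sim <- simulate_protein_with_parallel_sites(tr, pairz, 100,
                                                n_parallel = seed - 71,
                                                seed = seed)
    ev <- events_from_truth(sim$truth, pairz)
    got <- classify_pairwise_changes(ev, pairz, tr)
    want <- pair_oracle(sim$truth, pairz)
    got_sub <- got[got$class != "none", c("site", "class")]
    want_sub <- want[want$class != "none", c("site", "class")]
    rownames(got_sub) <- rownames(want_sub) <- NULL
    expect_equal(got_sub, want_sub)
  }
})

test_that("ancestral reconstruction recovers planted focal events with high recall", {
  tr <- study_tree()
  sim <- simulate_protein_with_parallel_sites(tr, pairz, 200, 8, seed = 75)
  asr <- marginal_ancestral_reconstruction(sim$alignment, tr)
  ev <- call_branch_substitutions(asr, pp_min = 0.9)
  cls <- classify_pairwise_changes(ev, pairz, tr)
  found <- cls$site[cls$class == "parallel"]
  recall <- mean(sim$truth$parallel_sites %in% found)
  expect_gte(recall, 0.9)
})

test_that("parallel-gene binning matches hand counts", {
  mk_cl <- function(n_par) {
    if (n_par == 0) return(data.frame(site = integer(0), class = character(0)))
    data.frame(site = seq_len(n_par), class = "parallel")
  }
  cls <- lapply(c(g1 = 1, g2 = 1, g3 = 2, g4 = 3, g5 = 5, g6 = 0), mk_cl)
  s <- summarize_parallel_genes(cls)
  expect_equal(unname(s$bin_sizes), c(2L, 1L, 2L))
  expect_setequal(s$bins[["1"]], c("g1", "g2"))
  expect_setequal(s$bins[[">2"]], c("g4", "g5"))
  expect_equal(s$n_parallel_genes, 5L)
  empty <- summarize_parallel_genes(lapply(1:3, function(i) mk_cl(0)))
  expect_equal(unname(empty$bin_sizes), c(0L, 0L, 0L))
})
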