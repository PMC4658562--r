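# Fast fitting checks; the heavier parameter-recovery and calibration
# studies live in test-acceptance.R.

test_that("free-ratio estimates are invariant under taxon relabelling", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, 2, 0.3, n_codons = 120, seed = 51)
  rec <- fit_free_ratio(sim$alignment, tr)
  # relabel: swap two tip names consistently in tree and alignment
  tr2 <- tr
  map <- c(zokor = "zz", rat = "rr")
  tr2$tip.label[match(names(map), tr2$tip.label)] <- map
  m <- sim$alignment$codons
  rownames(m)[match(names(map), rownames(m))] <- map
  rec2 <- fit_free_ratio(codon_alignment(m), prepare_tree(tr2))
  expect_equal(rec$kappa, rec2$kappa, tolerance = 1e-6)
  o1 <- setNames(rec$branches$omega, rec$branches$branch)
  o2 <- setNames(rec2$branches$omega, rec2$branches$branch)
  expect_equal(unname(o1["zokor"]), unname(o2["zz"]), tolerance = 1e-6)
  expect_equal(unname(o1["rat"]), unname(o2["rr"]), tolerance = 1e-6)
})

test_that("free-ratio flags genes without variation instead of fitting them", {
  tr <- study_tree()
  m <- matrix("GCT", 6, 10, dimnames = list(tr$tip.label, NULL))
  rec <- fit_free_ratio(codon_alignment(m), tr)
  expect_true(rec$degenerate)
  expect_true(all(is.na(rec$branches$omega)))
  expect_true(all(!rec$branches$omega_defined))
})

test_that("free-ratio fits are bit-for-bit reproducible", {
  tr <- study_tree()
  sim <- simulate_codon_alignment(tr, 2, 0.3, n_codons = 90, seed = 52)
  r1 <- fit_free_ratio(sim$alignment, tr)
  r2 <- fit_free_ratio(sim$alignment, tr)
  expect_identical(r1$branches, r2$branches)
  expect_identical(r1$lnL, r2$lnL)
})

test_that("branch-site null is nested in the alternative and both are reproducible", {
  tr <- study_tree()
  sim <- simulate_branch_site_alignment(tr, "zokor", 0.7, 0.2, 0.15, 1, 2,
                                        150, seed = 53)
  t1 <- branch_site_test(sim$alignment, tr, foreground = "zokor")
  t2 <- branch_site_test(sim$alignment, tr, foreground = "zokor")
  expect_gte(t1$lnL_alt, t1$lnL_null - 1e-4)
  expect_gte(t1$statistic, 0)
  expect_identical(t1$lnL_alt, t2$lnL_alt)
  expect_identical(t1$p_value, t2$p_value)
  expect_error(fit_branch_site(sim$alignment, tr, foreground = "no_such"),
               "no_such")
})

test_that("a PAML-style foreground mark on the tree is honoured", {
  tr <- prepare_tree("(((kangaroo_rat:0.5,(rat:0.4,zokor:0.25)m:0.15)my:0.1,(guinea_pig:0.45,naked_mole_rat:0.38)h:0.2)ro:0.12,human:0.7)r;")
  marked <- ape::read.tree(text = "(((kangaroo_rat:0.5,(rat:0.4,zokor#1:0.25)m:0.15)my:0.1,(guinea_pig:0.45,naked_mole_rat:0.38)h:0.2)ro:0.12,human:0.7)r;")
  pt <- prepare_tree(marked)
  expect_equal(attr(pt, "foreground"), "zokor")
})

test_that("LRT statistic and p-values match the chi-square(1) closed form", {
  expect_equal(branch_site_lrt(-100, -100)$statistic, 0)
  expect_equal(branch_site_lrt(-100, -100)$p_value, 1)
  # chi-square(1) = squared standard normal: p = 2 * (1 - Phi(sqrt(x)))
  lrt1 <- branch_site_lrt(-100, -100 + 3.841 / 2)
  expect_equal(lrt1$statistic, 3.841, tolerance = 1e-12)
  expect_equal(lrt1$p_value, 2 * stats::pnorm(sqrt(3.841), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(lrt1$p_value, 0.05, tolerance = 1e-3)
  lrt2 <- branch_site_lrt(-100, -100 + 6.635 / 2)
  expect_equal(lrt2$p_value, 0.01, tolerance = 1e-3)
  expect_equal(branch_site_lrt(-100, -99, mixture = TRUE)$p_value,
               stats::pchisq(2, 1, lower.tail = FALSE) / 2)
  expect_error(branch_site_lrt(-100, -101), "nested")
})

test_that("Benjamini-Hochberg matches the hand-computed step-up values", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(benjamini_hochberg(0.123), 0.123)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  # order preservation and independent closed form
  p <- c(0.30, 0.01, 0.04, 0.80)
  q_manual <- {
    o <- order(p)
    r <- p[o] * length(p) / seq_along(p)
    r <- rev(cummin(rev(r)))
    out <- numeric(length(p))
    out[o] <- pmin(r, 1)
    out
  }
  expect_equal(benjamini_hochberg(p), q_manual, tolerance = 1e-12)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BEB posteriors are probabilities and rank planted selected sites higher", {
  tr <- study_tree()
  sim <- simulate_branch_site_alignment(tr, "zokor", 0.6, 0.1, 0.1, 5, 2,
                                        200, seed = 54)
  alt <- fit_branch_site(sim$alignment, tr, "zokor", fix_omega2 = FALSE)
  beb <- beb_site_posteriors(alt$params, sim$alignment, tr)
  expect_equal(nrow(beb), 200L)
  expect_true(all(beb$pp_class2 >= 0 & beb$pp_class2 <= 1))
  cls <- sim$truth$site_classes
  expect_gt(mean(beb$pp_class2[cls %in% c("2a", "2b")]),
            mean(beb$pp_class2[cls == "0"]))
})
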