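pair <- c("zokor", "rat")

test_that("dN/dS outlier filter applies the strict printed boundary", {
  recs <- list(fake_record("g1", c(zokor = 4.0, rat = 0.1)),
               fake_record("g2", c(zokor = 4.01, rat = 0.1)),
               fake_record("g3", c(zokor = 0.1, rat = 5)),
               fake_record("g4", c(zokor = NA, rat = 0.2)))
  kept <- filter_rate_outliers(recs, pair, omega_max = 4)
  expect_setequal(burrowevol:::record_genes(kept), c("g1", "g4"))
  expect_setequal(attr(kept, "removed")$gene, c("g2", "g3"))
})

test_that("a planted toy set of 10 records with 3 outliers keeps 7", {
  om <- c(rep(0.2, 7), 6, 8, 4.5)
  recs <- lapply(seq_along(om), function(i)
    fake_record(paste0("g", i), c(zokor = om[i], rat = 0.2)))
  kept <- filter_rate_outliers(recs, pair)
  expect_length(kept, 7L)
})

test_that("saturation filter keeps dS = 1 and drops dS > 1, with diagnostics", {
  recs <- list(fake_record("g1", c(zokor = 0.2, rat = 0.2),
                           dS = c(zokor = 1.0, rat = 0.5)),
               fake_record("g2", c(zokor = 0.2, rat = 0.2),
                           dS = c(zokor = 1.2, rat = 0.5)))
  out <- saturation_filter(recs, pair, ds_max = 1)
  expect_equal(burrowevol:::record_genes(out$records), "g1")
  expect_equal(nrow(out$diagnostic), 4L) # 2 genes x 2 lineages
  expect_true(all(c("dS", "ts_tv") %in% names(out$diagnostic)))
})

test_that("outlier and saturation filters commute", {
  withr::with_seed(61, {
    recs <- lapply(1:40, function(i)
      fake_record(paste0("g", i),
                  c(zokor = stats::rlnorm(1, -1.5, 1.2),
                    rat = stats::rlnorm(1, -1.5, 1.2)),
                  dS = c(zokor = stats::rlnorm(1, -0.5, 0.6),
                         rat = stats::rlnorm(1, -0.5, 0.6))))
  })
  a <- saturation_filter(filter_rate_outliers(recs, pair), pair)$records
  b <- filter_rate_outliers(saturation_filter(recs, pair)$records, pair)
  expect_identical(burrowevol:::record_genes(a),
                   burrowevol:::record_genes(b))
})

test_that("lineage comparison reproduces the exact small-sample rank-sum p", {
  recs <- mapply(function(i, oz, or) fake_record(paste0("g", i),
                                                 c(zokor = oz, rat = or)),
                 1:3, c(1, 2, 3), c(4, 5, 6), SIMPLIFY = FALSE)
  cmp <- compare_lineage_rates(recs, "zokor", "rat")
  # exact two-sided enumeration over choose(6,3) = 20 orderings
  expect_equal(cmp$p_value, 0.1, tolerance = 1e-12)
  expect_equal(cmp$meanA, 2)
  expect_equal(cmp$meanB, 5)
  # identical vectors (with jitter to break ties deterministically) -> p ~ 1
  same <- lapply(1:6, function(i)
    fake_record(paste0("s", i), c(zokor = 0.1 + i / 100, rat = 0.1 + i / 100)))
  expect_gt(compare_lineage_rates(same, "zokor", "rat")$p_value, 0.9)
  expect_error(compare_lineage_rates(recs[1], "zokor", "rat"), "at least 2")
})

test_that("lineage comparison detects a genuine stochastic rate difference", {
  withr::with_seed(62, {
    recs <- lapply(1:300, function(i)
      fake_record(paste0("g", i),
                  c(zokor = stats::rlnorm(1, log(0.09), 0.5),
                    rat = stats::rlnorm(1, log(0.136), 0.5))))
  })
  cmp <- compare_lineage_rates(recs, "zokor", "rat")
  expect_lt(cmp$meanA, cmp$meanB)
  expect_lt(cmp$p_value, 0.05)
})

test_that("GO category rates respect the strict >20-gene rule and concatenation identity", {
  tr <- study_tree()
  g <- simulate_codon_alignment(tr, 2, 0.25, n_codons = 12, seed = 63)$alignment
  alns <- lapply(1:21, function(i) g)
  names(alns) <- paste0("g", 1:21)
  ann21 <- data.frame(gene = paste0("g", 1:21), term = "T21")
  ann20 <- data.frame(gene = paste0("g", 1:20), term = "T20")
  cats <- go_category_rates(alns, rbind(ann21, ann20), tr,
                            lineages = pair, min_genes = 20)
  expect_equal(vapply(cats, `[[`, character(1), "term"), "T21")
  expect_equal(cats[[1]]$n_genes, 21L)
  # concatenating copies of one gene recovers that gene's omega
  single <- fit_free_ratio(g, tr, gene = "g1")
  conc <- cats[[1]]$lineage
  oz_single <- single$branches$omega[single$branches$branch == "zokor"]
  oz_cat <- conc$omega[conc$branch == "zokor"]
  expect_equal(oz_cat, oz_single, tolerance = 0.05)
})

test_that("binomial acceleration test matches the closed-form tail", {
  cat_rec <- list(lineage = data.frame(branch = pair,
                                       omega = c(0.3, 0.1),
                                       exp_nonsyn = c(30, 10),
                                       exp_syn = c(40, 40)))
  res <- accelerated_category_test(cat_rec, c(zokor = 500, rat = 500))
  closed <- sum(vapply(30:40, function(k) choose(40, k) * 0.5^40, numeric(1)))
  expect_equal(res$p_accelerated[res$lineage == "zokor"], closed,
               tolerance = 1e-12)
  expect_equal(closed, 1.1e-3, tolerance = 0.05)
  # counts proportional to the genome share are null-centred
  cat_null <- list(lineage = data.frame(branch = pair,
                                        omega = c(0.2, 0.2),
                                        exp_nonsyn = c(20, 20),
                                        exp_syn = c(30, 30)))
  res0 <- accelerated_category_test(cat_null, c(zokor = 100, rat = 100))
  expect_true(all(res0$p_accelerated >= 0.5))
  zero <- list(lineage = data.frame(branch = pair, omega = c(0, 0),
                                    exp_nonsyn = c(0, 0), exp_syn = c(0, 0)))
  expect_true(all(accelerated_category_test(zero, c(zokor = 1, rat = 1))$p_accelerated == 1))
})

test_that("category test p-values are conservative under a null simulation", {
  withr::with_seed(64, {
    ps <- replicate(200, {
      n <- stats::rpois(1, 30) + 5
      a <- stats::rbinom(1, n, 0.5)
      rec <- list(lineage = data.frame(branch = pair, omega = c(0.2, 0.2),
                                       exp_nonsyn = c(a, n - a),
                                       exp_syn = c(1, 1)))
      min(accelerated_category_test(rec, c(zokor = 300, rat = 300))$p_accelerated)
    })
  })
  # two-sided-by-minimum at alpha/2 each: rejection rate should not exceed
  # the nominal level by much under the null
  expect_lte(mean(ps < 0.025), 0.05 + 0.03)
})
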