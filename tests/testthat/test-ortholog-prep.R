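test_that("longest-ORF prediction matches examples and the brute-force scan", {
  expect_equal(as.character(find_longest_orf("ATGAAATAA", min_nt = 9)),
               "ATGAAATAA")
  # longest ORF of 119 nt cannot exist in-frame; a 117-nt ORF fails at 120
  orf117 <- paste0("ATG", strrep("GCT", 37), "TAA") # 39 codons = 117 nt
  expect_null(find_longest_orf(orf117, min_nt = 120))
  expect_equal(as.character(find_longest_orf(orf117, min_nt = 117)), orf117)
  # reverse-strand ORFs are found
  fwd <- paste0("ATG", strrep("GAA", 10), "TGA")
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(as.character(find_longest_orf(rev, min_nt = 36)), fwd)
  # random sequences agree with the exhaustive six-frame oracle
  withr::with_seed(31, {
    for (i in 1:5) {
      x <- paste0(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
      got <- find_longest_orf(x, min_nt = 60)
      want <- orf_oracle(x, min_nt = 60)
      expect_identical(if (is.null(got)) NULL else as.character(got), want)
    }
  })
  expect_error(find_longest_orf("ATGXXX"), "alphabet")
})

test_that("best reciprocal hits honour mutual-best and e-value rules", {
  ab <- data.frame(query = "a", subject = "b", evalue = 1e-10,
                   bitscore = 50, length = 100)
  ba <- data.frame(query = "b", subject = "a", evalue = 1e-10,
                   bitscore = 50, length = 100)
  expect_equal(best_reciprocal_hits(ab, ba),
               data.frame(a = "a", b = "b"), ignore_attr = TRUE)
  # one direction above the cutoff excludes the pair
  ba$evalue <- 1e-3
  expect_equal(nrow(best_reciprocal_hits(ab, ba)), 0L)
  # malformed rows are rejected with the row number
  bad <- ab
  bad$evalue <- -1
  expect_error(best_reciprocal_hits(bad, ba), "row 1")
})

test_that("BRH equals exhaustive enumeration and is symmetric", {
  ht <- random_hit_tables(50, seed = 33)
  got <- best_reciprocal_hits(ht$ab, ht$ba)
  want <- brh_oracle(ht$ab, ht$ba)
  expect_equal(got$a, want$a)
  expect_equal(got$b, want$b)
  expect_equal(anyDuplicated(got$a), 0L)
  expect_equal(anyDuplicated(got$b), 0L)
  swapped <- best_reciprocal_hits(ht$ba, ht$ab)
  expect_setequal(paste(got$a, got$b), paste(swapped$b, swapped$a))
})

test_that("codon block trimming follows the gap, run and block rules", {
  taxa <- c("a", "b", "c", "d")
  cons <- function(codon) setNames(rep(codon, 4), taxa)
  # fully conserved alignment returned unchanged
  m <- do.call(cbind, lapply(rep("GCT", 8), cons))
  rownames(m) <- taxa
  aln <- codon_alignment(m)
  expect_equal(trim_codon_blocks(aln)$codons, aln$codons)
  # a gap codon removes its column
  m2 <- m
  m2["a", 4] <- "---"
  t2 <- trim_codon_blocks(codon_alignment(m2))
  expect_false(4L %in% attr(t2, "kept_columns"))
  # a conserved block of 5 codons flanked by removed columns is dropped
  gap_col <- c("---", "GGG", "CCC", "AAA")
  m3 <- cbind(do.call(cbind, lapply(rep("GCT", 5), cons)), gap_col,
              do.call(cbind, lapply(rep("TGG", 6), cons)))
  rownames(m3) <- taxa
  t3 <- trim_codon_blocks(codon_alignment(m3))
  expect_equal(attr(t3, "kept_columns"), 7:12)
  expect_equal(t3$n_codons, 6L)
})

test_that("trimming is idempotent on random gapped alignments", {
  tab <- burrowevol:::codon_tables()
  withr::with_seed(34, {
    for (i in 1:5) {
      m <- matrix(sample(c(tab$codons, "---"), 5 * 40, replace = TRUE,
                         prob = c(rep(0.9 / 61, 61), 0.1)),
                  nrow = 5, dimnames = list(letters[1:5], NULL))
      # seed some conservation
      for (j in seq_len(40)) if (stats::runif(1) < 0.6) m[, j] <- sample(tab$codons, 1)
      a1 <- trim_codon_blocks(codon_alignment(m))
      a2 <- trim_codon_blocks(a1)
      expect_identical(a1$codons, a2$codons)
      expect_true(all(a1$codons != "---"))
    }
  })
})

test_that("post-trim length filter applies the printed nucleotide bound", {
  nine <- codon_alignment(rbind(a = c("ATG", "GCT", "GCA"),
                                b = c("ATG", "GCT", "GCA")))
  expect_false(filter_alignment_length(nine, 10))   # 9 nt < 10
  twelve <- codon_alignment(rbind(a = rep("GCT", 4), b = rep("GCT", 4)))
  expect_true(filter_alignment_length(twelve, 10))  # 12 nt
  empty <- codon_alignment(matrix(character(0), nrow = 2, ncol = 0,
                                  dimnames = list(c("a", "b"), NULL)))
  expect_false(filter_alignment_length(empty, 10))
})

test_that("fourfold-degenerate extraction matches the codon table", {
  # glycine family: third positions extracted
  gly <- codon_alignment(rbind(a = c("GGT"), b = c("GGC"), c = c("GGA")))
  f <- extract_fourfold_sites(gly)
  expect_equal(unname(f), c("T", "C", "A"), ignore_attr = TRUE)
  # phenylalanine (2-fold) not extracted
  phe <- codon_alignment(rbind(a = "TTT", b = "TTC", c = "TTT"))
  expect_equal(unname(extract_fourfold_sites(phe)), rep("", 3),
               ignore_attr = TRUE)
  # 100-codon random alignment equals the brute-force per-column check
  aln <- random_codon_alignment(c("a", "b", "c", "d"), 100, seed = 35)
  got <- attr(extract_fourfold_sites(aln), "columns")
  gc <- Biostrings::GENETIC_CODE
  want <- which(vapply(seq_len(100), function(j) {
    col <- aln$codons[, j]
    pre <- substr(col, 1, 2)
    if (length(unique(pre)) != 1L) return(FALSE)
    fam <- gc[paste0(pre[1], c("A", "C", "G", "T"))]
    all(fam != "*") && length(unique(fam)) == 1L
  }, logical(1)))
  expect_equal(got, want)
  expect_lte(length(got), aln$n_codons)
})

test_that("supergene concatenation preserves boundaries and rejects gaps in taxa", {
  a1 <- random_codon_alignment(c("a", "b", "c"), 10, seed = 36)
  a2 <- random_codon_alignment(c("a", "b", "c"), 10, seed = 37)
  super <- concatenate_alignments(list(g1 = a1, g2 = a2))
  expect_equal(super$n_codons, 20L)
  b <- attr(super, "boundaries")
  expect_identical(super$codons[, b$start[1]:b$end[1]], a1$codons)
  expect_identical(super$codons[, b$start[2]:b$end[2]], a2$codons)
  expect_equal(concatenate_alignments(list(), taxa = c("a", "b"))$n_codons, 0L)
  a3 <- random_codon_alignment(c("a", "b"), 5, seed = 38)
  expect_error(concatenate_alignments(list(a1, a3)), "lacks taxa")
})
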