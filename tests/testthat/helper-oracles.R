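# Shared fixtures and independent oracles used across the suite. Oracles are
# deliberately written as brute-force computations (enumeration, closed
# forms) that never touch the code paths they check.

# one BLAS thread: the linear algebra here is far below the threading
# break-even and oversubscription slows the optimisers down
Sys.setenv(OPENBLAS_NUM_THREADS = "1", OMP_NUM_THREADS = "1")

toy_tree3 <- function() {
  prepare_tree("((a:0.10,b:0.20)ab:0.15,c:0.30)r;")
}

toy_tree4 <- function() {
  prepare_tree("(((a:0.05,b:0.12)ab:0.08,c:0.22)abc:0.06,d:0.30)r;")
}

# random gap-free codon alignment over the sense codons
random_codon_alignment <- function(taxa, n_codons, seed) {
  tab <- burrowevol:::codon_tables()
  withr::with_seed(seed, {
    mat <- matrix(sample(tab$codons, length(taxa) * n_codons, replace = TRUE),
                  nrow = length(taxa), dimnames = list(taxa, NULL))
  })
  codon_alignment(mat)
}

# Brute-force pruning oracle: enumerates every assignment of codon states to
# the internal nodes and sums pi(root) * prod(edge transition terms), with
# transition matrices from an independent matrix exponential (Matrix::expm).
# Missing (gap) tips contribute a factor of 1 (sum over a stochastic row).
# Feasible for 3-4 tips (61^2 .. 61^3 assignments, vectorised over tuples).
enumeration_loglik <- function(aln, tree, kappa, omega, codon_freqs) {
  tree <- prepare_tree(tree)
  st <- burrowevol:::tree_struct(tree)
  Q <- build_codon_rate_matrix(kappa, omega, codon_freqs)
  pi <- unname(attr(Q, "pi"))
  P <- lapply(seq_len(nrow(st$edge)), function(e)
    as.matrix(Matrix::expm(matrix(Q, 61, 61) * st$t[e])))
  codes <- burrowevol:::alignment_codes(aln)[tree$tip.label, , drop = FALSE]
  ntip <- st$ntip
  nnode <- max(st$edge)
  internal <- (ntip + 1L):nnode
  grid <- as.matrix(expand.grid(rep(list(1:61), length(internal))))
  node_col <- function(v) grid[, match(v, internal)]
  # internal-only factor: root prior times internal-internal edges
  base <- pi[node_col(st$root)]
  for (e in seq_len(nrow(st$edge))) {
    ch <- st$edge[e, 2]
    if (ch > ntip)
      base <- base * P[[e]][cbind(node_col(st$edge[e, 1]), node_col(ch))]
  }
  total <- 0
  for (s in seq_len(ncol(codes))) {
    f <- base
    for (e in seq_len(nrow(st$edge))) {
      ch <- st$edge[e, 2]
      if (ch <= ntip) {
        obs <- codes[ch, s]
        if (!is.na(obs)) f <- f * P[[e]][node_col(st$edge[e, 1]), obs]
      }
    }
    total <- total + log(sum(f))
  }
  unname(total)
}

# Brute-force six-frame ORF scan with the same conventions as the package:
# ATG..stop inclusive, min length, frame order then 5'-most.
orf_oracle <- function(x, min_nt = 120L) {
  x <- toupper(x)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 1:6) {
    s <- if (frame <= 3) x else rc
    off <- (frame - 1L) %% 3L
    n <- (nchar(s) - off) %/% 3L
    if (n < 2) next
    cds <- substring(s, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
    for (st in seq_len(n)) {
      if (cds[st] != "ATG") next
      for (en in st:n) {
        if (cds[en] %in% stops) {
          len <- (en - st + 1L) * 3L
          if (len >= min_nt && (is.null(best) || len > attr(best, "len")))
            best <- structure(paste0(cds[st:en], collapse = ""), len = len)
          break
        }
      }
    }
  }
  if (is.null(best)) NULL else as.character(best)
}

# Exhaustive reciprocal-best enumeration oracle for BRH.
brh_oracle <- function(ab, ba, e_cutoff = 1e-5) {
  best <- function(h, q) {
    h <- h[h$query == q & h$evalue <= e_cutoff, ]
    if (!nrow(h)) return(NA_character_)
    h <- h[order(h$evalue, -h$bitscore, -h$length, h$subject), ]
    h$subject[1]
  }
  out <- NULL
  for (q in unique(ab$query)) {
    b <- best(ab, q)
    if (is.na(b)) next
    if (identical(best(ba, b), q)) out <- rbind(out, data.frame(a = q, b = b))
  }
  if (is.null(out)) data.frame(a = character(0), b = character(0)) else
    out[order(out$a), , drop = FALSE]
}

random_hit_tables <- function(n_genes, seed) {
  withr::with_seed(seed, {
    mk <- function(qs, ss) {
      n <- 4L * n_genes
      data.frame(query = sample(qs, n, replace = TRUE),
                 subject = sample(ss, n, replace = TRUE),
                 evalue = 10^(-sample.int(12, n, replace = TRUE)),
                 bitscore = round(stats::runif(n, 30, 300), 1),
                 length = sample.int(500, n, replace = TRUE),
                 stringsAsFactors = FALSE)
    }
    list(ab = mk(paste0("A", seq_len(n_genes)), paste0("B", seq_len(n_genes))),
         ba = mk(paste0("B", seq_len(n_genes)), paste0("A", seq_len(n_genes))))
  })
}

# Site-by-site comparison oracle for parallel / convergent classification
# from true node states (matrix nodes x sites, labelled rows).
pair_oracle <- function(truth, focal_pair) {
  st <- burrowevol:::tree_struct(truth$tree)
  rownames(truth$node_states) <- truth$node_labels
  out <- NULL
  e1 <- st$edge[burrowevol:::branch_edge_index(st, focal_pair[1]), ]
  e2 <- st$edge[burrowevol:::branch_edge_index(st, focal_pair[2]), ]
  for (s in seq_len(ncol(truth$node_states))) {
    a_anc <- truth$node_states[e1[1], s]; a_der <- truth$node_states[e1[2], s]
    b_anc <- truth$node_states[e2[1], s]; b_der <- truth$node_states[e2[2], s]
    a_has <- a_anc != a_der; b_has <- b_anc != b_der
    if (!a_has && !b_has) next
    cls <- if (!a_has || !b_has) "none"
    else if (a_anc == b_anc && a_der == b_der) "parallel"
    else if (a_anc != b_anc && a_der == b_der) "convergent"
    else "divergent"
    out <- rbind(out, data.frame(site = s, class = cls))
  }
  if (is.null(out)) data.frame(site = integer(0), class = character(0)) else out
}

# True-state event table (net change per focal branch and site) fed to the
# classifier when "injecting true ancestral states".
events_from_truth <- function(truth, branches = NULL) {
  st <- burrowevol:::tree_struct(truth$tree)
  branches <- branches %||% st$branch
  out <- NULL
  for (b in branches) {
    e <- st$edge[burrowevol:::branch_edge_index(st, b), ]
    anc <- truth$node_states[e[1], ]
    der <- truth$node_states[e[2], ]
    idx <- which(anc != der)
    if (length(idx))
      out <- rbind(out, data.frame(branch = b, site = idx,
                                   from_aa = anc[idx], to_aa = der[idx],
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out))
    data.frame(branch = character(0), site = integer(0),
               from_aa = character(0), to_aa = character(0))
  else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal synthetic gene_evolution_record for filter tests
fake_record <- function(gene, omega, dS = NULL, ts_tv = NULL) {
  br <- data.frame(branch = names(omega), t = 0.1,
                   dN = 0.01, dS = if (is.null(dS)) 0.1 else unname(dS),
                   omega = unname(omega),
                   ts_tv = if (is.null(ts_tv)) 1.5 else unname(ts_tv),
                   omega_defined = !is.na(omega),
                   stringsAsFactors = FALSE)
  structure(list(gene = gene, branches = br, kappa = 2, lnL = -100,
                 converged = TRUE, degenerate = FALSE,
                 codon_freqs = uniform_codon_freqs(), flags = character(0)),
            class = "gene_evolution_record")
}
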