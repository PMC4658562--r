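# Likelihood interface: pattern compression and the exported log_likelihood()
# over codon alignments, for single-class (per-branch omega) and branch-site
# mixture parameterisations.

# Compress alignment columns into unique site patterns. Rows of the code
# matrix must be ordered to match the tip numbering of the tree.
compress_patterns <- function(codes) {
  key <- apply(codes, 2L, paste0, collapse = ",")
  first <- !duplicated(key)
  pat <- codes[, first, drop = FALSE]
  counts <- as.numeric(table(factor(key, levels = key[first])))
  pat[is.na(pat)] <- 0L
  storage.mode(pat) <- "integer"
  list(tipdata = pat, counts = counts,
       site_pattern = match(key, key[first]))
}

# Align alignment rows with tree tips and compress.
pattern_data <- function(aln, tree) {
  if (!setequal(aln$taxa, tree$tip.label))
    stop("alignment taxa and tree tips differ: ",
         paste(symdiff_chr(aln$taxa, tree$tip.label), collapse = ", "))
  codes <- alignment_codes(aln)[tree$tip.label, , drop = FALSE]
  compress_patterns(codes)
}

symdiff_chr <- function(a, b) c(setdiff(a, b), setdiff(b, a))

# Class proportions of branch-site model A from (p0, p1).
branch_site_weights <- function(p0, p1) {
  p2 <- 1 - p0 - p1
  if (p2 < 0 && p2 > -1e-9) p2 <- 0
  stopifnot(p0 >= 0, p1 >= 0, p2 >= -1e-12)
  denom <- p0 + p1
  if (denom <= 0) stop("p0 + p1 must be positive")
  c(p0 = p0, p1 = p1, p2a = p2 * p0 / denom, p2b = p2 * p1 / denom)
}

# Per-edge omega matrix (nedge x nclass) of branch-site model A.
branch_site_omega_edge <- function(st, foreground, omega0, omega2) {
  fg <- branch_edge_index(st, foreground)
  nedge <- nrow(st$edge)
  om <- cbind(class0 = rep(omega0, nedge), class1 = rep(1, nedge),
              class2a = rep(omega0, nedge), class2b = rep(1, nedge))
  om[fg, c("class2a", "class2b")] <- omega2
  om
}

# Closed-form mean-rate constants of the unscaled GY94 generator: with
# q_ij = pi_j * kappa^[ts] * omega^[nonsyn], the expected rate is
# A + kappa*B + omega*C + kappa*omega*D where A..D are frequency-weighted
# counts of the four single-nucleotide change types.
rate_constants <- function(pi) {
  type <- codon_tables()$type
  pp <- outer(unname(pi), unname(pi))
  c(A = sum(pp[type == 2L]), B = sum(pp[type == 1L]),
    C = sum(pp[type == 4L]), D = sum(pp[type == 3L]))
}

codon_mean_rate <- function(kappa, omega, rc) {
  rc[["A"]] + kappa * rc[["B"]] + omega * rc[["C"]] + kappa * omega * rc[["D"]]
}

# Low-level evaluator shared by log_likelihood() and the optimisers.
# pat: output of pattern_data(); tmat are *effective* times per edge/class
# (branch lengths already divided by the relevant mean rate).
codon_loglik_eval <- function(pat, st, tmat, omega_edge, weights, kappa, pi,
                              per_pattern = FALSE) {
  type <- codon_tables()$type
  cpp_codon_loglik(pat$tipdata, pat$counts, st$edge, as.matrix(tmat),
                   as.matrix(omega_edge), weights, kappa, unname(pi), type,
                   per_pattern)
}

# Effective-time matrix under the class-mixture scaling convention: each
# edge's branch length is expected substitutions per codon averaged over the
# site classes present on it.
mixture_tmat <- function(tvec, omega_edge, weights, kappa, rc) {
  omega_edge <- as.matrix(omega_edge)
  rates <- matrix(codon_mean_rate(kappa, as.vector(omega_edge), rc),
                  nrow = nrow(omega_edge))
  s <- as.vector(rates %*% weights)
  s[s <= 0] <- 1
  matrix(tvec / s, nrow = length(tvec), ncol = ncol(omega_edge))
}

#' Log-likelihood of a codon alignment under a codon model
#'
#' Felsenstein pruning over the 61 sense codons. Gapped or ambiguous codons
#' are treated as missing data. Two parameterisations are supported: a
#' single-class model with one dN/dS value per branch (`params$omega` a named
#' map, or a single number applied to all branches), and branch-site model A
#' (`params` with `p0`, `p1`, `omega0`, `omega2`, `foreground`), whose site
#' likelihood is the mixture over the four site classes.
#'
#' @param aln A `codon_alignment`.
#' @param tree A prepared `phylo` tree whose tips match the alignment taxa;
#'   branch lengths are expected substitutions per codon.
#' @param params A list: either `list(kappa=, omega=, codon_freqs=)` with
#'   `omega` a single value or named per-branch vector, or
#'   `list(kappa=, p0=, p1=, omega0=, omega2=, foreground=, codon_freqs=)`.
#' @return The log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(aln, tree, params) {
  tree <- prepare_tree(tree)
  st <- tree_struct(tree)
  pat <- pattern_data(aln, tree)
  pi <- check_codon_freqs(params$codon_freqs %||% uniform_codon_freqs())
  kappa <- params$kappa %||% 2
  rc <- rate_constants(pi)
  if (!is.null(params$p0)) {
    fg <- params$foreground %||% attr(tree, "foreground")
    if (is.null(fg)) stop("branch-site parameters require a foreground branch")
    w <- branch_site_weights(params$p0, params$p1)
    om <- branch_site_omega_edge(st, fg, params$omega0, params$omega2)
    res <- codon_loglik_eval(pat, st, mixture_tmat(st$t, om, w, kappa, rc),
                             om, w, kappa, pi)
  } else {
    omega <- params$omega
    if (is.null(omega)) stop("params must contain omega or branch-site fields")
    if (length(omega) == 1L && is.null(names(omega))) {
      ov <- rep(unname(omega), nrow(st$edge))
    } else {
      idx <- branch_edge_index(st, names(omega))
      ov <- rep(NA_real_, nrow(st$edge))
      ov[idx] <- unname(omega)
      if (anyNA(ov)) stop("omega map must cover every branch; missing: ",
                          paste(st$branch[is.na(ov)], collapse = ", "))
    }
    om <- matrix(ov, ncol = 1)
    res <- codon_loglik_eval(pat, st, mixture_tmat(st$t, om, 1, kappa, rc),
                             om, 1, kappa, pi)
  }
  res$loglik
}

`%||%` <- function(a, b) if (is.null(a)) b else a
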