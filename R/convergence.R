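# Marginal amino-acid ancestral reconstruction and detection of parallel /
# convergent substitutions on a focal branch pair.

aa_codes <- function(alignment) {
  aas <- amino_acids()
  if (is.null(names(alignment))) stop("protein alignment must be named")
  len <- unique(nchar(alignment))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  codes <- matrix(match(mat, aas), nrow = nrow(mat), dimnames = dimnames(mat))
  codes
}

aa_pattern_data <- function(codes) {
  codes[is.na(codes)] <- 0L
  storage.mode(codes) <- "integer"
  key <- apply(codes, 2L, paste0, collapse = ",")
  first <- !duplicated(key)
  list(tipdata = codes[, first, drop = FALSE],
       counts = as.numeric(table(factor(key, levels = key[first]))),
       site_pattern = match(key, key[first]))
}

aa_pcube <- function(Q, tvec) {
  pi <- attr(Q, "pi")
  e <- reversible_eigen(Q, pi)
  P <- array(0, c(20, 20, length(tvec)))
  for (i in seq_along(tvec)) {
    M <- e$left %*% (exp(e$values * tvec[i]) * e$right)
    M[M < 0] <- 0
    P[, , i] <- M / rowSums(M)
  }
  P
}

# ML branch lengths under a fixed amino-acid model.
aa_optim_lengths <- function(pat, st, Q) {
  pi <- attr(Q, "pi")
  nedge <- nrow(st$edge)
  fn <- function(logt) {
    -cpp_prune_loglik(pat$tipdata, pat$counts, st$edge,
                      aa_pcube(Q, exp(logt)), unname(pi))$loglik
  }
  t0 <- log(pmin(pmax(st$t, 5e-3), 3))
  fit <- stats::optim(t0, fn, method = "L-BFGS-B",
                      lower = log(1e-6), upper = log(10),
                      control = list(maxit = 200L, factr = 1e9))
  exp(fit$par)
}

#' Marginal ancestral reconstruction of a protein alignment
#'
#' Computes, at every internal node and site, the marginal posterior
#' distribution over the 20 residues conditional on all tip data, under a
#' reversible amino-acid model given by an exchangeability matrix and residue
#' frequencies. Branch lengths are re-estimated by maximum likelihood under
#' the same model before reconstruction (disable with
#' `reestimate_lengths = FALSE`). Gap positions contribute a flat partial
#' from that tip.
#'
#' @param aln Named character vector of aligned protein sequences.
#' @param tree Prepared `phylo` with matching tips.
#' @param exchangeability,freqs Passed to [aa_rate_matrix()]; default is the
#'   uniform process.
#' @param reestimate_lengths Re-fit branch lengths by ML (default TRUE).
#' @return An `ancestral_posterior`: list with `posterior` (named list of
#'   20 x n_sites matrices per internal node), `best_state` and `pp`
#'   (matrices internal-nodes x sites), `tip_states` (character matrix),
#'   `tree`, `branch_lengths`.
#' @export
marginal_ancestral_reconstruction <- function(aln, tree, exchangeability = NULL,
                                              freqs = rep(1 / 20, 20),
                                              reestimate_lengths = TRUE) {
  tree <- prepare_tree(tree, allow_multifurcation = TRUE)
  if (!setequal(names(aln), tree$tip.label))
    stop("alignment taxa and tree tips differ")
  st <- tree_struct(tree)
  codes <- aa_codes(aln)[tree$tip.label, , drop = FALSE]
  aas <- amino_acids()
  Q <- aa_rate_matrix(exchangeability, freqs)
  pi <- attr(Q, "pi")
  pat <- aa_pattern_data(codes)
  tvec <- if (reestimate_lengths) aa_optim_lengths(pat, st, Q) else st$t
  nsite <- ncol(codes)
  nnode <- max(st$edge)
  ntip <- st$ntip
  P <- aa_pcube(Q, tvec)
  # up (postorder) partials, unscaled is fine at these sizes in log-safe data
  L <- vector("list", nnode)
  msg <- vector("list", nrow(st$edge))
  tipL <- function(i) {
    M <- matrix(0, 20, nsite)
    idx <- codes[i, ]
    ok <- !is.na(idx) & idx > 0
    M[cbind(idx[ok], which(ok))] <- 1
    M[, !ok] <- 1
    M
  }
  scal <- rep(0, nsite)
  for (e in seq_len(nrow(st$edge))) {
    p <- st$edge[e, 1]; ch <- st$edge[e, 2]
    Lc <- if (ch <= ntip) tipL(ch) else L[[ch]]
    msg[[e]] <- P[, , e] %*% Lc
    L[[p]] <- if (is.null(L[[p]])) msg[[e]] else {
      M <- L[[p]] * msg[[e]]
      mx <- apply(M, 2L, max)
      mx[mx <= 0] <- 1
      scal <- scal + log(mx)
      sweep(M, 2L, mx, "/")
    }
  }
  # down pass
  U <- vector("list", nnode)
  U[[st$root]] <- matrix(pi, 20, nsite)
  for (e in rev(seq_len(nrow(st$edge)))) {
    p <- st$edge[e, 1]; ch <- st$edge[e, 2]
    if (ch <= ntip) next
    sib <- setdiff(which(st$edge[, 1] == p), e)
    W <- U[[p]]
    for (s2 in sib) W <- W * msg[[s2]]
    Uc <- t(P[, , e]) %*% W
    mx <- apply(Uc, 2L, max)
    mx[mx <= 0] <- 1
    U[[ch]] <- sweep(Uc, 2L, mx, "/")
  }
  internal <- (ntip + 1L):nnode
  posterior <- list()
  best <- pp <- matrix(NA_real_, length(internal), nsite,
                       dimnames = list(st$labels[internal], NULL))
  beststate <- matrix(NA_character_, length(internal), nsite,
                      dimnames = list(st$labels[internal], NULL))
  for (v in internal) {
    M <- U[[v]] * L[[v]]
    M <- sweep(M, 2L, colSums(M), "/")
    rownames(M) <- aas
    lbl <- st$labels[v]
    posterior[[lbl]] <- M
    bi <- apply(M, 2L, which.max)
    beststate[lbl, ] <- aas[bi]
    pp[lbl, ] <- M[cbind(bi, seq_len(nsite))]
  }
  tip_states <- matrix(ifelse(is.na(codes), "-", aas[codes]),
                       nrow = ntip, dimnames = list(tree$tip.label, NULL))
  structure(list(posterior = posterior, best_state = beststate, pp = pp,
                 tip_states = tip_states, tree = tree,
                 branch_lengths = setNames(tvec, st$branch)),
            class = "ancestral_posterior")
}

#' Call per-branch amino-acid substitutions
#'
#' Emits a substitution event for every (branch, site) whose best-supported
#' states at the two branch ends differ, requiring every reconstructed
#' (internal) endpoint to have posterior probability strictly greater than
#' `pp_min`; observed leaf states always pass (pp = 1). Sites where the leaf
#' end is a gap are skipped.
#'
#' @param posterior An `ancestral_posterior`.
#' @param pp_min Posterior-probability cutoff (default 0.9; events at exactly
#'   `pp_min` are suppressed).
#' @param mode `"both"` applies the cutoff to both ends of internal-internal
#'   branches; `"ancestral"` only to the parent end.
#' @return data.frame: branch, site, from_aa, to_aa, from_pp, to_pp.
#' @export
call_branch_substitutions <- function(posterior, pp_min = 0.9,
                                      mode = c("both", "ancestral")) {
  mode <- match.arg(mode)
  st <- tree_struct(posterior$tree)
  ntip <- st$ntip
  out <- list()
  for (e in seq_len(nrow(st$edge))) {
    p <- st$edge[e, 1]; ch <- st$edge[e, 2]
    plab <- st$labels[p]
    from <- posterior$best_state[plab, ]
    from_pp <- posterior$pp[plab, ]
    if (ch <= ntip) {
      to <- posterior$tip_states[st$labels[ch], ]
      to_pp <- rep(1, length(to))
      to_internal <- FALSE
    } else {
      clab <- st$labels[ch]
      to <- posterior$best_state[clab, ]
      to_pp <- posterior$pp[clab, ]
      to_internal <- TRUE
    }
    keep <- from != to & to != "-" & from_pp > pp_min
    if (to_internal && mode == "both") keep <- keep & to_pp > pp_min
    idx <- which(keep)
    if (length(idx))
      out[[length(out) + 1L]] <- data.frame(
        branch = st$branch[e], site = idx, from_aa = from[idx],
        to_aa = to[idx], from_pp = from_pp[idx], to_pp = to_pp[idx],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(branch = character(0), site = integer(0),
                      from_aa = character(0), to_aa = character(0),
                      from_pp = numeric(0), to_pp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$site, res$branch), ]
}

#' Classify substitutions on a focal branch pair
#'
#' Per site carrying substitution events on both focal branches: "parallel"
#' when both branches share ancestral and derived residues, "convergent"
#' when the ancestral residues differ but the derived residues match,
#' "divergent" when the derived residues differ. Sites with an event on only
#' one focal branch are classified "none".
#'
#' @param events Event table from [call_branch_substitutions()] (or a
#'   simulation event log with columns branch, site, from_aa, to_aa).
#' @param focal_pair Two distinct branch ids.
#' @param tree Optional tree used to reject an ancestor-descendant pair.
#' @return data.frame: site, class, from_a, to_a, from_b, to_b.
#' @export
classify_pairwise_changes <- function(events, focal_pair, tree = NULL) {
  if (length(focal_pair) != 2L || focal_pair[1] == focal_pair[2])
    stop("focal_pair must name two distinct branches")
  if (!is.null(tree) && branches_nested(prepare_tree(tree), focal_pair[1],
                                        focal_pair[2]))
    stop("focal branches must not be ancestral to one another")
  ea <- events[events$branch == focal_pair[1], , drop = FALSE]
  eb <- events[events$branch == focal_pair[2], , drop = FALSE]
  sites <- sort(unique(c(ea$site, eb$site)))
  if (!length(sites))
    return(data.frame(site = integer(0), class = character(0),
                      from_a = character(0), to_a = character(0),
                      from_b = character(0), to_b = character(0)))
  res <- lapply(sites, function(s) {
    ra <- ea[ea$site == s, , drop = FALSE]
    rb <- eb[eb$site == s, , drop = FALSE]
    fa <- if (nrow(ra)) ra$from_aa[1] else NA_character_
    ta <- if (nrow(ra)) ra$to_aa[nrow(ra)] else NA_character_
    fb <- if (nrow(rb)) rb$from_aa[1] else NA_character_
    tb <- if (nrow(rb)) rb$to_aa[nrow(rb)] else NA_character_
    # multi-jump paths reduce to their net ancestral -> derived change
    a_has <- nrow(ra) > 0 && !identical(fa, ta)
    b_has <- nrow(rb) > 0 && !identical(fb, tb)
    cls <- if (!a_has || !b_has) "none"
    else if (fa == fb && ta == tb) "parallel"
    else if (fa != fb && ta == tb) "convergent"
    else "divergent"
    data.frame(site = s, class = cls, from_a = fa, to_a = ta,
               from_b = fb, to_b = tb, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Bin genes by their parallel-substitution counts
#'
#' @param classifications_by_gene Named list of classification tables from
#'   [classify_pairwise_changes()].
#' @return List with `counts` (named vector of parallel-site counts for genes
#'   with at least one parallel site), `bins` (gene lists for 1, 2 and >2
#'   parallel changes) and `bin_sizes`.
#' @export
summarize_parallel_genes <- function(classifications_by_gene) {
  counts <- vapply(classifications_by_gene,
                   function(cl) sum(cl$class == "parallel"), numeric(1))
  counts <- counts[counts > 0]
  bins <- list(`1` = names(counts)[counts == 1],
               `2` = names(counts)[counts == 2],
               `>2` = names(counts)[counts > 2])
  list(counts = counts, bins = bins,
       bin_sizes = vapply(bins, length, integer(1)),
       n_parallel_genes = length(counts))
}
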