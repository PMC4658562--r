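# Synthetic-data generators. All substitution simulation uses exact CTMC
# sampling along each branch (exponential waiting times from the rate matrix),
# so every realised substitution is recorded in an event log that downstream
# tests can use as ground truth.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L) stop("seed must be an integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  force(expr)
}

# Exact CTMC path for one site on one branch.
# Q must be a (scaled) rate matrix; returns final state and event list.
sim_ctmc_site <- function(state, Q, t) {
  events_from <- integer(0); events_to <- integer(0)
  elapsed <- 0
  repeat {
    rate <- -Q[state, state]
    if (rate <= 0) break
    elapsed <- elapsed + stats::rexp(1L, rate)
    if (elapsed > t) break
    p <- Q[state, ]
    p[state] <- 0
    nxt <- sample.int(length(p), 1L, prob = p)
    events_from <- c(events_from, state)
    events_to <- c(events_to, nxt)
    state <- nxt
  }
  list(state = state, from = events_from, to = events_to)
}

# Evolve a full sequence along a tree in preorder. Qs is a function(edge_row,
# site) -> rate matrix (already scaled). Returns node-state matrix and event
# log (branch, site, from, to, in realised order).
sim_along_tree <- function(st, root_states, Qfun) {
  nnode <- max(st$edge)
  nsite <- length(root_states)
  states <- matrix(NA_integer_, nnode, nsite)
  states[st$root, ] <- root_states
  ord <- rev(seq_len(nrow(st$edge))) # reverse postorder = preorder
  ev_branch <- character(0); ev_site <- integer(0)
  ev_from <- integer(0); ev_to <- integer(0)
  for (e in ord) {
    parent <- st$edge[e, 1]; child <- st$edge[e, 2]
    t_e <- st$t[e]
    for (s in seq_len(nsite)) {
      res <- sim_ctmc_site(states[parent, s], Qfun(e, s), t_e)
      states[child, s] <- res$state
      k <- length(res$from)
      if (k) {
        ev_branch <- c(ev_branch, rep(st$branch[e], k))
        ev_site <- c(ev_site, rep(s, k))
        ev_from <- c(ev_from, res$from)
        ev_to <- c(ev_to, res$to)
      }
    }
  }
  list(states = states,
       events = data.frame(branch = ev_branch, site = ev_site,
                           from = ev_from, to = ev_to,
                           stringsAsFactors = FALSE))
}

resolve_branch_omega <- function(st, per_branch_omega) {
  if (length(per_branch_omega) == 1L && is.null(names(per_branch_omega)))
    return(setNames(rep(unname(per_branch_omega), nrow(st$edge)), st$branch))
  idx <- branch_edge_index(st, names(per_branch_omega))
  ov <- setNames(rep(NA_real_, nrow(st$edge)), st$branch)
  ov[idx] <- unname(per_branch_omega)
  if (anyNA(ov)) stop("per_branch_omega must cover every branch; missing: ",
                      paste(names(ov)[is.na(ov)], collapse = ", "))
  ov
}

#' Simulate a codon alignment with per-branch dN/dS
#'
#' Evolves `n_codons` sites from the stationary distribution down the tree
#' under a codon model with one dN/dS value per branch, by exact CTMC
#' sampling. Every substitution is recorded in the returned event log.
#'
#' @param tree Prepared rooted binary `phylo` tree; branch lengths in expected
#'   substitutions per codon.
#' @param kappa Transition/transversion rate ratio.
#' @param per_branch_omega Single dN/dS or a named branch -> dN/dS map.
#' @param codon_freqs 61-vector of sense-codon frequencies (stops rejected).
#' @param n_codons Number of codon sites.
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @return List with `alignment` (a `codon_alignment`) and `truth`, a
#'   `simulation_truth` list carrying `per_branch_omega`, `kappa`,
#'   `site_classes` (NULL here), `event_log` (branch, site, from_codon,
#'   to_codon), `node_states`, `root_seq` and `seed`.
#' @export
simulate_codon_alignment <- function(tree, kappa, per_branch_omega,
                                     codon_freqs = uniform_codon_freqs(),
                                     n_codons, seed) {
  tree <- prepare_tree(tree)
  if (!is.numeric(n_codons) || n_codons < 1) stop("n_codons must be positive")
  pi <- check_codon_freqs(codon_freqs)
  st <- tree_struct(tree)
  ov <- resolve_branch_omega(st, per_branch_omega)
  Qs <- lapply(unique(ov), function(w) build_codon_rate_matrix(kappa, w, pi))
  names(Qs) <- as.character(unique(ov))
  with_seed(seed, {
    root <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    sim <- sim_along_tree(st, root, function(e, s) Qs[[as.character(ov[e])]])
  })
  finish_codon_sim(sim, st, tree, ov, kappa, NULL, seed)
}

finish_codon_sim <- function(sim, st, tree, ov, kappa, site_classes, seed) {
  tab <- codon_tables()
  tips <- sim$states[seq_len(st$ntip), , drop = FALSE]
  mat <- matrix(tab$codons[tips], nrow = nrow(tips),
                dimnames = list(st$labels[seq_len(st$ntip)], NULL))
  ev <- sim$events
  ev$from_codon <- tab$codons[ev$from]
  ev$to_codon <- tab$codons[ev$to]
  ev$synonymous <- tab$aa[ev$from] == tab$aa[ev$to]
  ev <- ev[, c("branch", "site", "from_codon", "to_codon", "synonymous")]
  truth <- structure(list(per_branch_omega = ov, kappa = kappa,
                          site_classes = site_classes, event_log = ev,
                          node_states = sim$states,
                          node_labels = st$labels,
                          root_seq = tab$codons[sim$states[st$root, ]],
                          tree = tree, seed = seed),
                     class = "simulation_truth")
  list(alignment = codon_alignment(mat), truth = truth)
}

#' Simulate a codon alignment under branch-site model A
#'
#' Sites fall into classes 0 (dN/dS `omega0` everywhere), 1 (neutral
#' everywhere), 2a and 2b (`omega2` on the foreground branch, `omega0` or 1
#' elsewhere), with proportions `(p0, p1, (1-p0-p1)*p0/(p0+p1),
#' (1-p0-p1)*p1/(p0+p1))`. Branch lengths are expected substitutions per codon
#' under the class mixture.
#'
#' @inheritParams simulate_codon_alignment
#' @param foreground Branch id of the foreground lineage.
#' @param p0,p1 Class-0 and class-1 proportions (`p0 + p1 <= 1`).
#' @param omega0 Purifying dN/dS in (0, 1).
#' @param omega2 Foreground dN/dS for class-2 sites (>= 1).
#' @return As [simulate_codon_alignment()]; `truth$site_classes` holds the
#'   per-site class labels ("0", "1", "2a", "2b").
#' @export
simulate_branch_site_alignment <- function(tree, foreground, p0, p1, omega0,
                                           omega2, kappa, n_codons, seed,
                                           codon_freqs = uniform_codon_freqs()) {
  tree <- prepare_tree(tree)
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12)
    stop("need p0 >= 0, p1 >= 0, p0 + p1 <= 1")
  st <- tree_struct(tree)
  fg_edge <- branch_edge_index(st, foreground) # errors if absent
  pi <- check_codon_freqs(codon_freqs)
  w <- branch_site_weights(p0, p1)
  om_edge <- branch_site_omega_edge(st, foreground, omega0, omega2)
  # per-edge mixture mean rate: scale every class Q on an edge consistently
  rate_of <- function(om) attr(build_codon_rate_matrix(kappa, om, pi), "rate")
  rates <- vapply(sort(unique(as.vector(om_edge))), rate_of, numeric(1))
  names(rates) <- as.character(sort(unique(as.vector(om_edge))))
  Qraw <- lapply(names(rates), function(o)
    build_codon_rate_matrix(kappa, as.numeric(o), pi) * rate_of(as.numeric(o)))
  names(Qraw) <- names(rates)
  Qscaled <- lapply(seq_len(nrow(st$edge)), function(e) {
    s_e <- sum(w * rates[as.character(om_edge[e, ])])
    lapply(seq_along(w), function(cl) Qraw[[as.character(om_edge[e, cl])]] / s_e)
  })
  with_seed(seed, {
    classes <- sample(names(w), n_codons, replace = TRUE, prob = w)
    root <- sample.int(61L, n_codons, replace = TRUE, prob = pi)
    cls_idx <- match(classes, names(w))
    sim <- sim_along_tree(st, root, function(e, s) Qscaled[[e]][[cls_idx[s]]])
  })
  ov <- setNames(rep(NA_real_, nrow(st$edge)), st$branch)
  out <- finish_codon_sim(sim, st, tree, ov, kappa,
                          c("0", "1", "2a", "2b")[cls_idx], seed)
  out$truth$branch_site <- list(foreground = foreground, p0 = p0, p1 = p1,
                                omega0 = omega0, omega2 = omega2)
  out
}

# --- amino-acid simulation ------------------------------------------------

amino_acids <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Amino-acid rate matrix from exchangeabilities and frequencies
#'
#' Default is the uniform (Poisson-type) process: equal exchangeabilities and
#' frequencies. Any symmetric 20x20 exchangeability matrix and frequency
#' vector can be supplied. Scaled to one expected substitution per unit time.
#'
#' @param exchangeability Symmetric 20x20 non-negative matrix (diagonal
#'   ignored), or NULL for uniform.
#' @param freqs 20-vector of residue frequencies summing to 1.
#' @return 20x20 rate matrix with `attr(,"pi")`.
#' @export
aa_rate_matrix <- function(exchangeability = NULL, freqs = rep(1 / 20, 20)) {
  aas <- amino_acids()
  if (is.null(exchangeability))
    exchangeability <- matrix(1, 20, 20)
  if (!isTRUE(all.equal(exchangeability, t(exchangeability), tolerance = 1e-8)))
    stop("exchangeability matrix must be symmetric")
  if (length(freqs) != 20L || any(freqs < 0) || abs(sum(freqs) - 1) > 1e-6)
    stop("freqs must be a 20-vector summing to 1")
  Q <- exchangeability * rep(freqs, each = 20)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(freqs * diag(Q))
  Q <- Q / rate
  dimnames(Q) <- list(aas, aas)
  attr(Q, "pi") <- setNames(freqs, aas)
  Q
}

#' Simulate a protein alignment with planted parallel substitutions
#'
#' Background sites evolve under an amino-acid substitution process on the
#' tree; exactly `n_parallel` planted sites carry the same ancestral->derived
#' replacement on both focal branches (and are invariant elsewhere).
#' Background sites that by chance produce an identical replacement on both
#' focal branches are resimulated, so the planted count is exact.
#'
#' @param tree Prepared `phylo` tree; branch lengths in substitutions/site.
#' @param focal_pair Character vector of two distinct branch ids, neither
#'   ancestral to the other.
#' @param n_sites Total number of alignment sites.
#' @param n_parallel Number of planted parallel sites (`<= n_sites`).
#' @param seed Integer seed.
#' @param exchangeability,freqs Passed to [aa_rate_matrix()].
#' @param planted_change Optional length-2 residue vector `c(from, to)` used
#'   for every planted site (default: drawn at random per site).
#' @return List with `alignment` (named character vector of aligned protein
#'   sequences), and `truth` carrying `node_states` (true residues at every
#'   node), `event_log` (branch, site, from_aa, to_aa), `parallel_sites`,
#'   `node_labels`, `tree` and `seed`.
#' @export
simulate_protein_with_parallel_sites <- function(tree, focal_pair, n_sites,
                                                 n_parallel, seed,
                                                 exchangeability = NULL,
                                                 freqs = rep(1 / 20, 20),
                                                 planted_change = NULL) {
  tree <- prepare_tree(tree)
  if (length(focal_pair) != 2L || focal_pair[1] == focal_pair[2])
    stop("focal_pair must name two distinct branches")
  if (n_parallel > n_sites) stop("n_parallel cannot exceed n_sites")
  if (branches_nested(tree, focal_pair[1], focal_pair[2]))
    stop("focal branches must not be ancestral to one another")
  st <- tree_struct(tree)
  fidx <- branch_edge_index(st, focal_pair)
  Q <- aa_rate_matrix(exchangeability, freqs)
  pi <- attr(Q, "pi")
  aas <- amino_acids()
  nnode <- max(st$edge)

  with_seed(seed, {
    n_bg <- n_sites - n_parallel
    # background: resimulate sites whose focal endpoint states form an
    # identical replacement on both focal branches
    states <- matrix(NA_integer_, nnode, n_sites)
    ev_list <- list()
    if (n_bg > 0) {
      done <- 0L
      while (done < n_bg) {
        root <- sample.int(20L, 1L, prob = pi)
        sim <- sim_along_tree(within_one_site(st), root, function(e, s) Q)
        sm <- sim$states[, 1L]
        a_anc <- sm[st$edge[fidx[1], 1]]; a_der <- sm[st$edge[fidx[1], 2]]
        b_anc <- sm[st$edge[fidx[2], 1]]; b_der <- sm[st$edge[fidx[2], 2]]
        if (a_anc != a_der && b_anc != b_der &&
            a_anc == b_anc && a_der == b_der) next # accidental parallel
        done <- done + 1L
        states[, done] <- sm
        if (nrow(sim$events)) {
          sim$events$site <- done
          ev_list[[length(ev_list) + 1L]] <- sim$events
        }
      }
    }
    # planted parallel sites: invariant everywhere except one identical
    # replacement on each focal branch
    par_sites <- if (n_parallel > 0) n_bg + seq_len(n_parallel) else integer(0)
    for (s in par_sites) {
      if (is.null(planted_change)) {
        fr <- sample.int(20L, 1L)
        to <- sample(setdiff(seq_len(20L), fr), 1L)
      } else {
        fr <- match(planted_change[1], aas)
        to <- match(planted_change[2], aas)
        if (anyNA(c(fr, to)) || fr == to) stop("invalid planted_change")
      }
      states[, s] <- fr
      for (k in 1:2) {
        # derived side of the focal branch: the child node and everything
        # below it carries the derived residue
        below <- descendant_nodes(st, st$edge[fidx[k], 2])
        states[below, s] <- to
        ev_list[[length(ev_list) + 1L]] <- data.frame(
          branch = st$branch[fidx[k]], site = s, from = fr, to = to,
          stringsAsFactors = FALSE)
      }
    }
  })

  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(branch = character(0), site = integer(0),
               from = integer(0), to = integer(0))
  events$from_aa <- aas[events$from]
  events$to_aa <- aas[events$to]
  events <- events[, c("branch", "site", "from_aa", "to_aa")]
  tips <- states[seq_len(st$ntip), , drop = FALSE]
  alignment <- setNames(apply(tips, 1L, function(r) paste0(aas[r], collapse = "")),
                        st$labels[seq_len(st$ntip)])
  truth <- structure(list(node_states = matrix(aas[states], nrow = nnode),
                          node_labels = st$labels,
                          event_log = events,
                          parallel_sites = if (n_parallel > 0)
                            (n_sites - n_parallel) + seq_len(n_parallel)
                          else integer(0),
                          focal_pair = focal_pair, tree = tree, seed = seed),
                     class = "simulation_truth")
  list(alignment = alignment, truth = truth)
}

# single-site view of a tree struct (same edges, used by per-site simulation)
within_one_site <- function(st) st

# child node plus all nodes below it
descendant_nodes <- function(st, node) {
  out <- node
  repeat {
    kids <- st$edge[st$edge[, 1] %in% out, 2]
    new <- setdiff(kids, out)
    if (!length(new)) break
    out <- c(out, new)
  }
  out
}

#' Replay a simulation event log from the root sequence
#'
#' Applies the logged substitutions branch by branch from the root states and
#' returns the implied tip sequences; used to check event-log consistency.
#'
#' @param truth A `simulation_truth` from a codon simulation.
#' @return Character matrix of codons (tips x sites).
#' @export
replay_event_log <- function(truth) {
  st <- tree_struct(truth$tree)
  tab <- codon_tables()
  root <- match(truth$root_seq, tab$codons)
  nnode <- max(st$edge)
  states <- matrix(NA_integer_, nnode, length(root))
  states[st$root, ] <- root
  ev <- truth$event_log
  for (e in rev(seq_len(nrow(st$edge)))) {
    parent <- st$edge[e, 1]; child <- st$edge[e, 2]
    seqs <- states[parent, ]
    rows <- which(ev$branch == st$branch[e])
    for (r in rows) {
      s <- ev$site[r]
      fr <- match(ev$from_codon[r], tab$codons)
      if (seqs[s] != fr) stop("event log inconsistent at branch ",
                              st$branch[e], " site ", s)
      seqs[s] <- match(ev$to_codon[r], tab$codons)
    }
    states[child, ] <- seqs
  }
  tips <- states[seq_len(st$ntip), , drop = FALSE]
  matrix(tab$codons[tips], nrow = nrow(tips),
         dimnames = list(st$labels[seq_len(st$ntip)], NULL))
}
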