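# Maximum-likelihood codon model fits: single-ratio (internal), per-branch
# free-ratio with dN/dS decomposition, branch-site model A with LRT and
# Bayes empirical Bayes site posteriors.
#
# All fits use bounded quasi-Newton optimisation (L-BFGS-B) on log/logit
# transformed parameters with deterministic starting points, so repeated
# fits of the same data are bit-for-bit reproducible. Gradients are forward
# finite differences sharing the base evaluation, which roughly halves the
# evaluation count relative to central differencing.

.t_bounds <- log(c(1e-6, 20))
.kappa_bounds <- log(c(0.05, 50))
.omega_bounds <- log(c(1e-4, 50))

optim_nll <- function(par, fn, lower, upper, maxit = 300L, factr = 1e9) {
  memo <- new.env(parent = emptyenv())
  f <- function(p) {
    v <- fn(p)
    memo$par <- p
    memo$val <- v
    v
  }
  gr <- function(p) {
    f0 <- if (!is.null(memo$par) && identical(memo$par, p)) memo$val else fn(p)
    vapply(seq_along(p), function(i) {
      h <- 1e-5 * max(1, abs(p[i]))
      ph <- p
      if (p[i] + h > upper[i]) h <- -h # step inward at the bound
      ph[i] <- p[i] + h
      (fn(ph) - f0) / h
    }, numeric(1))
  }
  stats::optim(par, f, gr, method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = maxit, factr = factr))
}

# Does the alignment carry any variation at all?
alignment_invariant <- function(pat) {
  all(apply(pat$tipdata, 2L, function(col) {
    v <- col[col > 0L]
    length(unique(v)) <= 1L
  }))
}

# Single-class evaluator with per-branch omega and per-branch own-rate
# scaling (branch length = expected substitutions per codon on that branch
# under its own omega).
single_class_nll <- function(pat, st, tvec, omegas, kappa, pi, rc) {
  teff <- tvec / codon_mean_rate(kappa, omegas, rc)
  -codon_loglik_eval(pat, st, matrix(teff, ncol = 1),
                     matrix(omegas, ncol = 1), 1, kappa, pi)$loglik
}

# --- single-ratio (M0-style) fit: kappa, one omega, branch lengths --------
fit_single_ratio <- function(pat, st, pi, omega_starts = c(0.1, 1, 2),
                             t_init = NULL, kappa_init = 2, maxit = 200L,
                             factr = 1e9) {
  nedge <- nrow(st$edge)
  rc <- rate_constants(pi)
  t0 <- pmin(pmax(t_init %||% st$t, 2e-3), 5)
  fn <- function(par) {
    single_class_nll(pat, st, exp(par[seq_len(nedge)]),
                     rep(exp(par[nedge + 2L]), nedge),
                     exp(par[nedge + 1L]), pi, rc)
  }
  lower <- c(rep(.t_bounds[1], nedge), .kappa_bounds[1], .omega_bounds[1])
  upper <- c(rep(.t_bounds[2], nedge), .kappa_bounds[2], .omega_bounds[2])
  best <- NULL
  for (w0 in omega_starts) {
    par0 <- c(log(t0), log(kappa_init), log(w0))
    fit <- optim_nll(par0, fn, lower, upper, maxit = maxit, factr = factr)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(t = setNames(exp(best$par[seq_len(nedge)]), st$branch),
       kappa = exp(best$par[nedge + 1L]),
       omega = exp(best$par[nedge + 2L]),
       lnL = -best$value,
       convergence = best$convergence == 0L)
}

#' Fit the free-ratio codon model to one gene
#'
#' Maximum-likelihood estimation of kappa, branch lengths and an independent
#' dN/dS per branch, followed by a decomposition of each branch length into
#' dN and dS through the expected synonymous/nonsynonymous substitution flows
#' of the fitted rate matrix, and a transition/transversion substitution
#' count ratio from the same flows. The fit starts from a single-ratio fit
#' (itself started from three deterministic omega values).
#'
#' @param aln A `codon_alignment` with at least 2 codon columns.
#' @param tree Prepared `phylo` with tips matching the alignment.
#' @param gene Optional gene id stored in the record.
#' @param codon_freqs `"F3x4"` (default), `"F1x4"`, `"uniform"`, or a
#'   61-vector.
#' @return A `gene_evolution_record`: list with `gene`, `branches` (data.frame
#'   branch, t, dN, dS, omega, ts_tv, omega_defined), `kappa`, `lnL`,
#'   `converged`, `flags` (character vector of filter annotations, empty
#'   here). When the alignment has no variation, all branch lengths collapse
#'   and every omega is flagged undefined.
#' @export
fit_free_ratio <- function(aln, tree, gene = NA_character_,
                           codon_freqs = "F3x4") {
  tree <- prepare_tree(tree)
  st <- tree_struct(tree)
  pat <- pattern_data(aln, tree)
  pi <- resolve_freqs(codon_freqs, aln)
  rc <- rate_constants(pi)
  nedge <- nrow(st$edge)
  if (alignment_invariant(pat)) {
    br <- data.frame(branch = st$branch, t = 0, dN = 0, dS = 0,
                     omega = NA_real_, ts_tv = NA_real_,
                     omega_defined = FALSE, stringsAsFactors = FALSE)
    ll <- -single_class_nll(pat, st, rep(0, nedge), rep(1, nedge), 2, pi, rc)
    return(structure(list(gene = gene, branches = br, kappa = NA_real_,
                          lnL = ll, converged = TRUE, degenerate = TRUE,
                          codon_freqs = pi, flags = character(0)),
                     class = "gene_evolution_record"))
  }
  m0 <- fit_single_ratio(pat, st, pi)
  fn <- function(par) {
    single_class_nll(pat, st, exp(par[seq_len(nedge)]),
                     exp(par[nedge + 1L + seq_len(nedge)]),
                     exp(par[nedge + 1L]), pi, rc)
  }
  par0 <- c(log(pmax(m0$t, 1e-5)), log(m0$kappa),
            rep(log(max(m0$omega, 1e-3)), nedge))
  lower <- c(rep(.t_bounds[1], nedge), .kappa_bounds[1], rep(.omega_bounds[1], nedge))
  upper <- c(rep(.t_bounds[2], nedge), .kappa_bounds[2], rep(.omega_bounds[2], nedge))
  fit <- optim_nll(par0, fn, lower, upper, maxit = 500L)
  tv <- setNames(exp(fit$par[seq_len(nedge)]), st$branch)
  kap <- exp(fit$par[nedge + 1L])
  om <- setNames(exp(fit$par[nedge + 1L + seq_len(nedge)]), st$branch)
  br <- branch_decomposition(tv, om, kap, pi)
  structure(list(gene = gene, branches = br, kappa = kap, lnL = -fit$value,
                 converged = fit$convergence == 0L, degenerate = FALSE,
                 codon_freqs = pi, flags = character(0)),
            class = "gene_evolution_record")
}

resolve_freqs <- function(codon_freqs, aln) {
  if (is.character(codon_freqs) && length(codon_freqs) == 1L)
    empirical_codon_freqs(aln, codon_freqs)
  else check_codon_freqs(codon_freqs)
}

# dN/dS and ts/tv decomposition of fitted branch parameters from expected
# substitution flows. A branch with (numerically) zero length has dS = 0 and
# an undefined omega.
branch_decomposition <- function(t, omega, kappa, pi, t_tol = 1e-5) {
  n <- length(t)
  dN <- dS <- tstv <- numeric(n)
  defined <- t > t_tol
  for (i in seq_len(n)) {
    fl <- substitution_flows(kappa, omega[i], pi)
    # synonymous (nonsynonymous) sites per codon are 3x the neutral flow
    # fraction, so dS = t * p_syn / (3 * rho_S1) is per synonymous site
    dS[i] <- t[i] * fl$p_syn / (3 * fl$neutral_syn_fraction)
    dN[i] <- t[i] * fl$p_nonsyn / (3 * (1 - fl$neutral_syn_fraction))
    tstv[i] <- if (fl$p_tv > 0) fl$p_ts / fl$p_tv else NA_real_
  }
  data.frame(branch = names(t), t = unname(t), dN = dN, dS = dS,
             omega = ifelse(defined, unname(omega), NA_real_),
             ts_tv = ifelse(defined, tstv, NA_real_),
             omega_defined = defined, stringsAsFactors = FALSE)
}

#' @export
print.gene_evolution_record <- function(x, ...) {
  cat(sprintf("gene_evolution_record %s: lnL = %.3f, kappa = %.3f\n",
              x$gene, x$lnL, x$kappa))
  print(x$branches)
  invisible(x)
}

# --- branch-site model A --------------------------------------------------

bs_transform <- function(par, fix_omega2) {
  # par: a, b (class logits), logit omega0, log kappa, log t_fg,
  #      [log(omega2 - 1)]
  ea <- exp(par[1]); eb <- exp(par[2])
  denom <- 1 + ea + eb
  p0 <- ea / denom; p1 <- eb / denom
  omega0 <- 1 / (1 + exp(-par[3]))
  kappa <- exp(par[4])
  t_fg <- exp(par[5])
  omega2 <- if (fix_omega2) 1 else 1 + exp(par[6])
  list(p0 = p0, p1 = p1, omega0 = omega0, kappa = kappa, t_fg = t_fg,
       omega2 = omega2)
}

bs_inverse <- function(p0, p1, omega0, kappa, t_fg, omega2 = NULL) {
  p2 <- max(1 - p0 - p1, 1e-6)
  c(log(p0 / p2), log(p1 / p2), log(omega0 / (1 - omega0)), log(kappa),
    log(max(t_fg, 1e-7)),
    if (!is.null(omega2)) log(max(omega2 - 1, 1e-6)))
}

# Memoised per-class pattern log-likelihoods. With background effective
# times fixed, a class is fully determined by (kappa, background omega,
# foreground omega, foreground time), so moving the class proportions (which
# the optimiser also does) never forces a pruning pass.
bs_class_engine <- function(pat, st, fg_idx, teff_bg, pi) {
  memo <- new.env(parent = emptyenv())
  nedge <- nrow(st$edge)
  function(kappa, om_bg, om_fg, t_fg) {
    key <- paste(format(c(kappa, om_bg, om_fg, t_fg), digits = 17),
                 collapse = "|")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    ov <- rep(om_bg, nedge)
    ov[fg_idx] <- om_fg
    tv <- teff_bg
    tv[fg_idx] <- t_fg
    ll <- codon_loglik_eval(pat, st, matrix(tv, ncol = 1),
                            matrix(ov, ncol = 1), 1, kappa,
                            pi)$pattern_loglik
    memo[[key]] <- ll
    ll
  }
}

bs_mix_nll <- function(classll, weights, counts) {
  M <- do.call(rbind, classll)
  mx <- apply(M, 2L, max)
  mix <- mx + log(as.vector(weights %*% exp(sweep(M, 2L, mx))))
  -sum(counts * mix)
}

#' Fit branch-site model A
#'
#' Fits the branch-site positive-selection model: four site classes with
#' purifying (`omega0`), neutral, and foreground-selected (`omega2`) dN/dS,
#' where `omega2` applies only on the designated foreground branch. Under the
#' null `omega2` is fixed at 1; under the alternative it is estimated with
#' `omega2 >= 1`. Branch lengths are estimated once under a single-ratio
#' model; background branches are then held at their fitted values (on a
#' mutational time scale) while kappa, the mixture parameters and the
#' foreground branch's effective time are optimised. Keeping the foreground
#' time free in both the null and the alternative fit makes the two models
#' exactly nested, so the LRT retains one degree of freedom.
#'
#' @param aln A `codon_alignment`.
#' @param tree Prepared `phylo`; tips must match the alignment.
#' @param foreground Branch id of the foreground branch (defaults to a `#1`
#'   mark on the tree).
#' @param fix_omega2 TRUE fits the null model (omega2 = 1).
#' @param codon_freqs As in [fit_free_ratio()].
#' @param m0 Optional precomputed single-ratio fit (used to share the branch
#'   length estimation between the null and alternative fits).
#' @return List with `params` (p0, p1, p2a, p2b, omega0, omega2, kappa,
#'   foreground, branch_lengths, codon_freqs), `lnL`, `converged` and the
#'   `m0` prefit.
#' @export
fit_branch_site <- function(aln, tree, foreground = NULL, fix_omega2 = FALSE,
                            codon_freqs = "F3x4", m0 = NULL) {
  tree <- prepare_tree(tree)
  foreground <- foreground %||% attr(tree, "foreground")
  if (is.null(foreground)) stop("no foreground branch given or marked on tree")
  st <- tree_struct(tree)
  fg_idx <- branch_edge_index(st, foreground) # reject absent foreground
  pat <- pattern_data(aln, tree)
  pi <- resolve_freqs(codon_freqs, aln)
  rc <- rate_constants(pi)
  if (is.null(m0)) m0 <- fit_single_ratio(pat, st, pi, omega_starts = 0.5,
                                          maxit = 150L, factr = 1e10)
  tv <- unname(m0$t[st$branch])
  # background branches: effective (mutational) times fixed from the
  # single-ratio fit; the foreground effective time stays a free parameter
  # in both the null and alternative fits, so the two models remain nested
  teff_bg <- tv / codon_mean_rate(m0$kappa, m0$omega, rc)
  t_fg0 <- max(teff_bg[fg_idx], 1e-6)
  w0_ref <- min(max(m0$omega, 0.01), 0.9)
  engine <- bs_class_engine(pat, st, fg_idx, teff_bg, pi)
  fn <- function(par) {
    th <- bs_transform(par, fix_omega2)
    w <- branch_site_weights(th$p0, th$p1)
    cls <- list(engine(th$kappa, th$omega0, th$omega0, th$t_fg),
                engine(th$kappa, 1, 1, th$t_fg),
                engine(th$kappa, th$omega0, th$omega2, th$t_fg),
                engine(th$kappa, 1, th$omega2, th$t_fg))
    bs_mix_nll(cls, w, pat$counts)
  }
  starts <- list(c(p0 = 0.75, p1 = 0.15, omega0 = w0_ref))
  omega2_starts <- if (fix_omega2) NULL else c(2, 8)
  lower <- c(-12, -12, -12, .kappa_bounds[1], log(1e-7),
             if (!fix_omega2) log(1e-4))
  upper <- c(12, 12, 12, .kappa_bounds[2], log(10),
             if (!fix_omega2) log(60))
  best <- NULL
  for (s in starts) {
    w2set <- if (fix_omega2) NA else omega2_starts
    for (w2 in w2set) {
      par0 <- bs_inverse(s[["p0"]], s[["p1"]], s[["omega0"]], m0$kappa,
                         t_fg0, if (!fix_omega2) w2)
      fit <- try(optim_nll(par0, fn, lower, upper, maxit = 250L),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best)) stop("branch-site optimisation failed on all starts")
  th <- bs_transform(best$par, fix_omega2)
  w <- branch_site_weights(th$p0, th$p1)
  teff <- teff_bg
  teff[fg_idx] <- th$t_fg
  params <- list(p0 = th$p0, p1 = th$p1, p2a = unname(w["p2a"]),
                 p2b = unname(w["p2b"]), omega0 = th$omega0,
                 omega2 = th$omega2, kappa = th$kappa,
                 foreground = foreground,
                 branch_lengths = setNames(tv, st$branch),
                 effective_times = setNames(teff, st$branch),
                 codon_freqs = pi)
  list(params = params, lnL = -best$value,
       converged = best$convergence == 0L, m0 = m0)
}

#' Likelihood-ratio test for the branch-site model
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the null (omega2 = 1) and
#'   alternative fits.
#' @param mixture Use the 50:50 mixture of chi-square(0) and chi-square(1)
#'   reference instead of plain chi-square(1) (default FALSE).
#' @param tol Allowed numerical deficit of `lnL_alt` below `lnL_null`.
#' @return List with `statistic` (2 * (lnL_alt - lnL_null), clamped at 0)
#'   and `p_value`.
#' @export
branch_site_lrt <- function(lnL_null, lnL_alt, mixture = FALSE, tol = 1e-2) {
  if (lnL_alt < lnL_null - tol)
    stop("lnL_alt is below lnL_null beyond tolerance: models not nested?")
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture) p <- if (stat == 0) 1 else p / 2
  list(statistic = stat, p_value = p)
}

#' Run the branch-site test on one gene
#'
#' Convenience wrapper: one shared single-ratio prefit, the null and
#' alternative branch-site fits, the LRT, and (optionally) BEB site
#' posteriors under the alternative.
#'
#' @inheritParams fit_branch_site
#' @param beb Compute BEB site posteriors (default FALSE).
#' @param gene Optional gene id.
#' @return A `selection_test_result`: list with `gene`, `lnL_null`,
#'   `lnL_alt`, `statistic`, `p_value`, `params_alt`, `params_null`,
#'   `converged` and optionally `beb_sites` (data.frame site, pp_class2).
#' @export
branch_site_test <- function(aln, tree, foreground = NULL, beb = FALSE,
                             codon_freqs = "F3x4", gene = NA_character_) {
  tree <- prepare_tree(tree)
  null <- fit_branch_site(aln, tree, foreground, fix_omega2 = TRUE,
                          codon_freqs = codon_freqs)
  alt <- fit_branch_site(aln, tree, foreground, fix_omega2 = FALSE,
                         codon_freqs = codon_freqs, m0 = null$m0)
  if (alt$lnL < null$lnL) alt$lnL <- null$lnL # nested up to optimiser noise
  lrt <- branch_site_lrt(null$lnL, alt$lnL)
  out <- list(gene = gene, lnL_null = null$lnL, lnL_alt = alt$lnL,
              statistic = lrt$statistic, p_value = lrt$p_value,
              params_alt = alt$params, params_null = null$params,
              converged = null$converged && alt$converged)
  if (beb) out$beb_sites <- beb_site_posteriors(alt$params, aln, tree)
  structure(out, class = "selection_test_result")
}

#' @export
print.selection_test_result <- function(x, ...) {
  cat(sprintf("branch-site test %s: LRT = %.3f, p = %.4g (omega2 = %.3f)\n",
              x$gene, x$statistic, x$p_value, x$params_alt$omega2))
  invisible(x)
}

# BEB prior grid: uniform over (p0, p1) on a 10 x 10 lattice restricted to
# the simplex, omega0 on 10 points in (0,1), omega2 on 10 points in (1, 11).
beb_grid <- function(d = 10L) {
  g <- (2 * seq_len(d) - 1) / (2 * d)
  pp <- expand.grid(p0 = g, p1 = g)
  pp <- pp[pp$p0 + pp$p1 <= 1, ]
  list(p = pp, omega0 = g, omega2 = 1 + 10 * g)
}

#' Bayes empirical Bayes site posteriors for the branch-site model
#'
#' Per-site posterior probability that the site belongs to the positively
#' selected classes (2a or 2b), integrating over a uniform discrete prior
#' grid on (p0, p1, omega0, omega2) with kappa and branch lengths fixed at
#' their maximum-likelihood estimates.
#'
#' @param alt_params `params` element of an alternative [fit_branch_site()].
#' @param aln,tree The fitted alignment and tree.
#' @return data.frame with `site` and `pp_class2` (posterior in `[0, 1]`).
#' @export
beb_site_posteriors <- function(alt_params, aln, tree) {
  tree <- prepare_tree(tree)
  st <- tree_struct(tree)
  pat <- pattern_data(aln, tree)
  pi <- alt_params$codon_freqs %||% uniform_codon_freqs()
  teff <- if (!is.null(alt_params$effective_times))
    unname(alt_params$effective_times[st$branch])
  else {
    rc <- rate_constants(pi)
    w <- branch_site_weights(alt_params$p0, alt_params$p1)
    om <- branch_site_omega_edge(st, alt_params$foreground,
                                 alt_params$omega0, alt_params$omega2)
    mixture_tmat(unname(alt_params$branch_lengths[st$branch]), om, w,
                 alt_params$kappa, rc)[, 1]
  }
  grid <- beb_grid()
  npat <- ncol(pat$tipdata)
  npp <- nrow(grid$p)
  wmat <- t(apply(grid$p, 1L, function(r) branch_site_weights(r[1], r[2])))
  ng <- length(grid$omega0) * length(grid$omega2)
  log_mix <- matrix(0, npp * ng, npat)   # per grid point: site log-mixture
  post2_num <- matrix(0, npp * ng, npat) # class-2 share of the mixture
  tmat <- matrix(teff, nrow = length(teff), ncol = 4)
  row <- 0L
  for (w0 in grid$omega0) {
    for (w2 in grid$omega2) {
      om <- branch_site_omega_edge(st, alt_params$foreground, w0, w2)
      cl <- codon_loglik_eval(pat, st, tmat, om, rep(0.25, 4),
                              alt_params$kappa, pi,
                              per_pattern = TRUE)$class_loglik
      mx <- apply(cl, 2L, max)
      el <- exp(sweep(cl, 2L, mx)) # 4 x npat, scaled
      for (g in seq_len(npp)) {
        row <- row + 1L
        mixt <- as.vector(wmat[g, ] %*% el)
        log_mix[row, ] <- log(mixt) + mx
        post2_num[row, ] <- as.vector(wmat[g, 3:4] %*% el[3:4, , drop = FALSE]) / mixt
      }
    }
  }
  lp <- as.vector(log_mix %*% pat$counts)
  lp <- lp - max(lp)
  wgrid <- exp(lp) / sum(exp(lp))
  pp_pat <- as.vector(t(post2_num) %*% wgrid)
  data.frame(site = seq_along(pat$site_pattern),
             pp_class2 = pp_pat[pat$site_pattern])
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the input.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
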