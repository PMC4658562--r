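# GY94-style codon rate matrices and transition probabilities.

check_codon_freqs <- function(codon_freqs) {
  tab <- codon_tables()
  if (length(codon_freqs) != 61L)
    stop("codon_freqs must have length 61 (sense codons only)")
  if (!is.null(names(codon_freqs))) {
    if (any(!names(codon_freqs) %in% tab$codons))
      stop("codon_freqs contains stop or invalid codons: ",
           paste(setdiff(names(codon_freqs), tab$codons), collapse = ", "))
    codon_freqs <- codon_freqs[tab$codons]
  } else names(codon_freqs) <- tab$codons
  if (any(codon_freqs < 0) || abs(sum(codon_freqs) - 1) > 1e-6)
    stop("codon_freqs must be non-negative and sum to 1")
  codon_freqs / sum(codon_freqs)
}

#' Uniform sense-codon frequencies
#' @return Named 61-vector, each 1/61.
#' @export
uniform_codon_freqs <- function() {
  tab <- codon_tables()
  setNames(rep(1 / 61, 61), tab$codons)
}

#' Build a codon substitution rate matrix
#'
#' Constructs the 61x61 instantaneous rate matrix of the standard codon model:
#' single-nucleotide changes only, target-codon frequency `pi_j`, a factor
#' `kappa` for transitions and `omega` for nonsynonymous changes. The matrix is
#' scaled so the expected number of substitutions per codon per unit time is 1
#' at the given parameters (so branch lengths are substitutions per codon).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0, finite).
#' @param codon_freqs 61-vector of sense-codon frequencies summing to 1;
#'   names, if present, must be sense codons (stop codons are rejected).
#' @return 61x61 rate matrix with rows summing to zero; the stationary
#'   frequencies are attached as `attr(,"pi")` and the unscaled mean rate as
#'   `attr(,"rate")`.
#' @export
build_codon_rate_matrix <- function(kappa, omega, codon_freqs = uniform_codon_freqs()) {
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be a positive real")
  if (!is.finite(omega) || omega < 0) stop("omega must be finite and >= 0")
  pi <- check_codon_freqs(codon_freqs)
  type <- codon_tables()$type
  fac <- c(1, kappa, 1, kappa * omega, omega) # index by type+1
  Q <- matrix(fac[type + 1L], 61, 61) * (type > 0L)
  Q <- Q * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  if (rate > 0) Q <- Q / rate
  dimnames(Q) <- dimnames(type)
  attr(Q, "pi") <- pi
  attr(Q, "rate") <- rate
  Q
}

# Symmetric eigendecomposition of a reversible rate matrix.
# Returns A, lambda with P(t) = A %*% (exp(lambda*t) * t(A_inv_rows))...
# concretely P(t) = D^{ -1/2 } V exp(L t) V' D^{ 1/2 }.
reversible_eigen <- function(Q, pi) {
  d <- sqrt(pi)
  S <- Q * outer(d, 1 / d)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(values = e$values,
       left = e$vectors / d,        # D^{-1/2} V    (61 x 61)
       right = t(e$vectors * d))    # V' D^{1/2}
}

#' Transition probability matrix of a codon model
#'
#' Matrix exponential `expm(Q t)` computed through the symmetric
#' eigendecomposition available for reversible rate matrices.
#'
#' @param Q Rate matrix from [build_codon_rate_matrix()] (or any reversible
#'   rate matrix with stationary frequencies in `attr(,"pi")`).
#' @param t Elapsed time (expected substitutions per site), >= 0.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t) {
  if (!is.finite(t) || t < 0) stop("t must be >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must carry stationary frequencies in attr(,'pi')")
  e <- reversible_eigen(Q, pi)
  P <- e$left %*% (exp(e$values * t) * e$right)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Empirical codon frequencies from an alignment (F3x4 / F1x4 / uniform)
#'
#' @param aln A `codon_alignment`.
#' @param method `"F3x4"` (positional nucleotide frequencies), `"F1x4"`, or
#'   `"uniform"`.
#' @return Named 61-vector summing to 1. A small floor keeps every sense codon
#'   strictly positive.
#' @export
empirical_codon_freqs <- function(aln, method = c("F3x4", "F1x4", "uniform")) {
  method <- match.arg(method)
  tab <- codon_tables()
  if (method == "uniform") return(uniform_codon_freqs())
  codons <- as.vector(aln$codons)
  codons <- codons[codons %in% tab$codons]
  if (!length(codons)) return(uniform_codon_freqs())
  cm <- do.call(rbind, strsplit(codons, ""))
  nt <- c("A", "C", "G", "T")
  if (method == "F3x4") {
    fr <- vapply(1:3, function(p) {
      tabp <- table(factor(cm[, p], levels = nt))
      as.numeric(tabp) / sum(tabp)
    }, numeric(4))
    rownames(fr) <- nt
    pi <- vapply(tab$codons, function(cd) {
      s <- strsplit(cd, "")[[1]]
      fr[s[1], 1] * fr[s[2], 2] * fr[s[3], 3]
    }, numeric(1))
  } else {
    tab1 <- table(factor(as.vector(cm), levels = nt))
    fr <- as.numeric(tab1) / sum(tab1)
    names(fr) <- nt
    pi <- vapply(tab$codons, function(cd) {
      s <- strsplit(cd, "")[[1]]
      fr[s[1]] * fr[s[2]] * fr[s[3]]
    }, numeric(1))
  }
  pi <- pmax(pi, 1e-8)
  pi / sum(pi)
}

# Expected substitution flows of a fitted branch: given kappa, omega, pi,
# returns proportions of the (unit-scaled) rate that are synonymous /
# nonsynonymous and transition / transversion, plus the neutral (omega = 1)
# synonymous site fraction used for dN/dS denominators.
substitution_flows <- function(kappa, omega, pi) {
  type <- codon_tables()$type
  Q <- build_codon_rate_matrix(kappa, omega, pi)
  flow <- Q * pi            # pi_i q_ij
  syn <- sum(flow[type == 1L | type == 2L])
  nonsyn <- sum(flow[type == 3L | type == 4L])
  ts <- sum(flow[type == 1L | type == 3L])
  tv <- sum(flow[type == 2L | type == 4L])
  Q1 <- build_codon_rate_matrix(kappa, 1, pi)
  flow1 <- Q1 * pi
  syn1 <- sum(flow1[type == 1L | type == 2L])
  list(p_syn = syn, p_nonsyn = nonsyn, p_ts = ts, p_tv = tv,
       neutral_syn_fraction = syn1)
}
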