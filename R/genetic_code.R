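# Genetic-code tables shared by the simulator and the likelihood machinery.
# All codon-indexed structures use the 61 sense codons of the standard code,
# ordered alphabetically (AAA, AAC, ..., TTT minus the three stops).

.codon_env <- new.env(parent = emptyenv())

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 sense codons in alphabetical order.
#' @export
sense_codons <- function() {
  codon_tables()$codons
}

# Build (once) the codon bookkeeping tables:
#  - codons: the 61 sense codons
#  - aa: amino acid encoded by each sense codon
#  - type: 61x61 integer matrix classifying single-nucleotide changes
#      0 = identical or multi-nucleotide change
#      1 = synonymous transition,    2 = synonymous transversion
#      3 = nonsynonymous transition, 4 = nonsynonymous transversion
#  - fourfold_prefix: dinucleotide prefixes whose third position is free
codon_tables <- function() {
  if (!is.null(.codon_env$tables)) return(.codon_env$tables)
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc)[gc != "*"])
  stopifnot(length(codons) == 61L)
  aa <- unname(gc[codons])
  n <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  type <- matrix(0L, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      diff <- which(cmat[i, ] != cmat[j, ])
      if (length(diff) != 1L) next
      ts <- purine[cmat[i, diff]] == purine[cmat[j, diff]]
      syn <- aa[i] == aa[j]
      type[i, j] <- if (syn) (if (ts) 1L else 2L) else (if (ts) 3L else 4L)
    }
  }
  prefixes <- unique(substr(names(gc), 1, 2))
  fourfold <- prefixes[vapply(prefixes, function(p) {
    fam <- gc[paste0(p, c("A", "C", "G", "T"))]
    all(fam != "*") && length(unique(fam)) == 1L
  }, logical(1))]
  .codon_env$tables <- list(codons = codons, aa = aa, type = type,
                            fourfold_prefix = fourfold)
  .codon_env$tables
}

#' Translate a vector of codons to amino acids
#'
#' Codons containing gaps or ambiguity codes translate to `"-"` / `"X"`.
#'
#' @param codons Character vector of 3-letter codon strings.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"
  out
}

codon_index <- function(codons) {
  tab <- codon_tables()
  match(codons, tab$codons)
}

# --- codon alignment container -------------------------------------------

#' Construct a codon alignment
#'
#' A light container for in-frame, gapped coding alignments: sequences are
#' stored as a taxa x codon-columns character matrix over the 61 sense codons
#' plus the gap codon `"---"`. Codons containing `N` or partial gaps are kept
#' verbatim but treated as missing data by the likelihood machinery.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (equal length, length divisible by 3), or a character matrix of codons
#'   (taxa in rows) with rownames.
#' @return An object of class `codon_alignment` with elements `taxa`,
#'   `codons` (character matrix) and `n_codons`.
#' @export
codon_alignment <- function(sequences) {
  if (is.matrix(sequences)) {
    mat <- sequences
    if (is.null(rownames(mat))) stop("codon matrix must have rownames (taxa)")
  } else {
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
      stop("sequences must be named by taxon")
    len <- unique(nchar(sequences))
    if (length(len) != 1L) stop("aligned sequences must have equal length")
    if (len %% 3L != 0L) stop("alignment length must be divisible by 3")
    nc <- len %/% 3L
    mat <- t(vapply(sequences, function(s)
      substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc)), character(nc)))
    if (nc == 1L) mat <- matrix(mat, ncol = 1L, dimnames = list(names(sequences), NULL))
    rownames(mat) <- names(sequences)
  }
  mat <- toupper(mat)
  aa <- translate_codons(as.vector(mat))
  if (any(aa == "*")) {
    bad <- which(matrix(aa, nrow = nrow(mat)) == "*", arr.ind = TRUE)
    stop(sprintf("internal stop codon at taxon '%s', codon column %d",
                 rownames(mat)[bad[1, 1]], bad[1, 2]))
  }
  structure(list(taxa = rownames(mat), codons = mat, n_codons = ncol(mat)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d taxa, %d codon columns\n",
              length(x$taxa), x$n_codons))
  invisible(x)
}

# Flatten a codon_alignment back to nucleotide strings.
alignment_sequences <- function(aln) {
  out <- apply(aln$codons, 1L, paste0, collapse = "")
  if (aln$n_codons == 0L) out <- setNames(rep("", length(aln$taxa)), aln$taxa)
  out
}

#' Read / write codon alignments as FASTA
#'
#' @param path FASTA file path.
#' @return `read_codon_fasta()` returns a `codon_alignment`.
#' @export
read_codon_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  codon_alignment(setNames(as.character(x), names(x)))
}

#' @rdname read_codon_fasta
#' @param aln A `codon_alignment`.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- alignment_sequences(aln)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(seqs), filepath = path)
  invisible(path)
}

# Integer-coded alignment: taxa x columns, values 1..61 or NA for anything
# that is not a sense codon (gap, N, partial gap). Used by the likelihood.
alignment_codes <- function(aln) {
  idx <- codon_index(as.vector(aln$codons))
  matrix(idx, nrow = nrow(aln$codons), dimnames = dimnames(aln$codons))
}
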