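# Ortholog preparation: ORF prediction, best-reciprocal-hit pairing,
# codon-aware block trimming, post-trim length filtering, fourfold-degenerate
# site extraction and supergene concatenation.

#' Find the longest open reading frame of a transcript
#'
#' Scans all six frames (three forward, three on the reverse complement) for
#' start-to-stop open reading frames (ATG .. stop, stop included in the
#' length) and returns the longest with length >= `min_nt`. Ties are broken
#' deterministically: lowest frame index (forward frames 1-3, then reverse
#' 4-6), then the 5'-most start within the frame.
#'
#' @param transcript A nucleotide string (A, C, G, T, N).
#' @param min_nt Minimum ORF length in nucleotides including the stop codon
#'   (default 120).
#' @return The ORF sequence (coding strand, including the stop codon), with
#'   attributes `frame` and `start`, or `NULL` when no qualifying ORF exists.
#' @export
find_longest_orf <- function(transcript, min_nt = 120L) {
  if (!is.character(transcript) || length(transcript) != 1L || !nzchar(transcript))
    stop("transcript must be a single non-empty string")
  transcript <- toupper(transcript)
  if (grepl("[^ACGTN]", transcript)) stop("alphabet restricted to A,C,G,T,N")
  if (min_nt %% 3L != 0L) stop("min_nt must be divisible by 3")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(transcript)))
  stops <- c("TAA", "TAG", "TGA")
  best <- NULL
  for (frame in 1:6) {
    s <- if (frame <= 3) transcript else rc
    off <- (frame - 1L) %% 3L
    n <- (nchar(s) - off) %/% 3L
    if (n < 2L) next
    codons <- substring(s, off + 3L * seq_len(n) - 2L, off + 3L * seq_len(n))
    starts <- which(codons == "ATG")
    stop_pos <- which(codons %in% stops)
    for (st in starts) {
      nxt <- stop_pos[stop_pos > st]
      if (!length(nxt)) next
      len <- (nxt[1] - st + 1L) * 3L
      if (len < min_nt) next
      if (is.null(best) || len > attr(best, "len")) {
        orf <- paste0(codons[st:nxt[1]], collapse = "")
        best <- structure(orf, len = len, frame = frame,
                          start = off + 3L * (st - 1L) + 1L)
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(as.character(best), frame = attr(best, "frame"),
            start = attr(best, "start"))
}

#' Best reciprocal hits between two similarity tables
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s best hit in `ab` and `a` is
#' `b`'s best hit in `ba`, with both supporting e-values <= `e_cutoff`.
#' Best hits are resolved deterministically: lowest e-value, then highest bit
#' score, then longest alignment, then lexicographic subject id.
#'
#' @param ab,ba Hit tables (data.frames with columns `query`, `subject`,
#'   `evalue`, `bitscore`, `length`), one search direction each.
#' @param e_cutoff E-value cutoff (default 1e-5).
#' @return data.frame with columns `a`, `b`; each id appears at most once.
#' @export
best_reciprocal_hits <- function(ab, ba, e_cutoff = 1e-5) {
  ab <- validate_hit_table(ab, "ab")
  ba <- validate_hit_table(ba, "ba")
  best_of <- function(h) {
    h <- h[h$evalue <= e_cutoff, , drop = FALSE]
    if (!nrow(h)) return(setNames(character(0), character(0)))
    o <- order(h$query, h$evalue, -h$bitscore, -h$length, h$subject)
    h <- h[o, ]
    h <- h[!duplicated(h$query), ]
    setNames(h$subject, h$query)
  }
  fwd <- best_of(ab)
  rev <- best_of(ba)
  a <- names(fwd)
  keep <- !is.na(rev[fwd[a]]) & rev[fwd[a]] == a
  keep[is.na(keep)] <- FALSE
  out <- data.frame(a = a[keep], b = unname(fwd[a[keep]]),
                    stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

validate_hit_table <- function(h, label) {
  need <- c("query", "subject", "evalue", "bitscore", "length")
  if (!is.data.frame(h) || !all(need %in% names(h)))
    stop(sprintf("hit table '%s' must have columns %s", label,
                 paste(need, collapse = ", ")))
  bad <- which(!is.finite(h$evalue) | h$evalue < 0 |
                 !nzchar(h$query) | !nzchar(h$subject))
  if (length(bad))
    stop(sprintf("hit table '%s': malformed row %d", label, bad[1]))
  h
}

#' Read a 12-column tabular similarity file
#'
#' BLAST `-outfmt 6` layout: qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore.
#'
#' @param path TSV file path.
#' @return Hit-table data.frame (`query`, `subject`, `evalue`, `bitscore`,
#'   `length`).
#' @export
read_hit_table <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(x) < 12L) stop("expected 12 tab-separated columns: ", path)
  data.frame(query = as.character(x[[1]]), subject = as.character(x[[2]]),
             evalue = as.numeric(x[[11]]), bitscore = as.numeric(x[[12]]),
             length = as.integer(x[[4]]), stringsAsFactors = FALSE)
}

# --- codon-aware block trimming ------------------------------------------

# Column conservation: TRUE when the most frequent codon is shared by at
# least half of the taxa. Columns containing a gap codon are handled
# separately by the gap rule.
codon_column_conserved <- function(col) {
  tabu <- table(col)
  max(tabu) >= length(col) / 2
}

#' Trim a codon alignment into conserved blocks
#'
#' A simplified codon-mode block filter in the spirit of alignment-cleaning
#' tools: codon columns containing a gap are removed (unless
#' `allow_gap_columns`), runs of more than `max_contig_nonconserved`
#' consecutive non-conserved columns are removed, and surviving runs of
#' consecutive retained columns shorter than `min_block_codons` are dropped.
#' The rules are applied to a fixpoint, which makes the operation idempotent.
#'
#' @param aln A `codon_alignment`.
#' @param min_block_codons Minimum retained block length in codons (default 6).
#' @param max_contig_nonconserved Longest run of non-conserved codon columns
#'   allowed inside a block (default 1).
#' @param allow_gap_columns Keep columns containing gap codons (default FALSE).
#' @return The trimmed `codon_alignment`; retained original column indices in
#'   `attr(,"kept_columns")`.
#' @export
trim_codon_blocks <- function(aln, min_block_codons = 6L,
                              max_contig_nonconserved = 1L,
                              allow_gap_columns = FALSE) {
  if (!inherits(aln, "codon_alignment")) stop("aln must be a codon_alignment")
  mat <- aln$codons
  nc <- ncol(mat)
  if (nc == 0L) return(aln)
  has_gap <- apply(mat, 2L, function(col) any(col == "---" | grepl("-", col)))
  conserved <- vapply(seq_len(nc), function(j)
    !has_gap[j] && codon_column_conserved(mat[, j]), logical(1))
  keep <- rep(TRUE, nc)
  if (!allow_gap_columns) keep[has_gap] <- FALSE
  repeat {
    prev <- keep
    # remove over-long runs of non-conserved retained columns
    idx <- which(keep)
    if (length(idx)) {
      r <- rle(conserved[idx])
      pos <- cumsum(c(1L, r$lengths))
      for (k in seq_along(r$lengths)) {
        if (!r$values[k] && r$lengths[k] > max_contig_nonconserved)
          keep[idx[pos[k]:(pos[k + 1L] - 1L)]] <- FALSE
      }
    }
    # drop retained blocks shorter than the minimum
    idx <- which(keep)
    if (length(idx)) {
      brk <- c(0L, which(diff(idx) > 1L), length(idx))
      for (k in seq_len(length(brk) - 1L)) {
        block <- idx[(brk[k] + 1L):brk[k + 1L]]
        if (length(block) < min_block_codons) keep[block] <- FALSE
      }
    }
    if (identical(keep, prev)) break
  }
  out <- codon_alignment(mat[, keep, drop = FALSE])
  attr(out, "kept_columns") <- which(keep)
  out
}

#' Post-trim alignment length filter
#'
#' @param aln A `codon_alignment` (after trimming).
#' @param min_nt Minimum alignment length in nucleotides (default 10);
#'   strictly shorter alignments are dropped. The default is deliberately not
#'   a codon multiple; it is applied literally in nucleotides.
#' @return TRUE (keep) or FALSE (drop).
#' @export
filter_alignment_length <- function(aln, min_nt = 10L) {
  3L * aln$n_codons >= min_nt
}

#' Extract fourfold-degenerate third-position sites
#'
#' Returns the third codon positions of gap-free codon columns in which every
#' taxon shares the same first two nucleotides and that dinucleotide prefix
#' determines a fourfold-degenerate amino acid under the standard code.
#'
#' @param aln A `codon_alignment`.
#' @return Named character vector of concatenated third-position nucleotides
#'   (one string per taxon); selected codon columns in `attr(,"columns")`.
#' @export
extract_fourfold_sites <- function(aln) {
  tab <- codon_tables()
  mat <- aln$codons
  pick <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    if (any(grepl("-", col)) || any(!col %in% tab$codons)) return(FALSE)
    pre <- substr(col, 1L, 2L)
    length(unique(pre)) == 1L && pre[1] %in% tab$fourfold_prefix
  }, logical(1))
  cols <- which(pick)
  third <- substr(mat[, cols, drop = FALSE], 3L, 3L)
  third <- matrix(third, nrow = nrow(mat))
  out <- setNames(apply(third, 1L, paste0, collapse = ""), aln$taxa)
  if (!length(cols)) out <- setNames(rep("", length(aln$taxa)), aln$taxa)
  attr(out, "columns") <- cols
  out
}

#' Concatenate codon alignments into a supergene
#'
#' @param alns List of `codon_alignment`s over the same taxon set.
#' @param taxa Ordered taxon vector for the output (default: taxa of the
#'   first alignment).
#' @return A `codon_alignment` whose length is the sum of the input lengths;
#'   `attr(,"boundaries")` is a data.frame (gene, start, end) of codon-column
#'   spans (1-based, inclusive) allowing exact slicing back into the inputs.
#' @export
concatenate_alignments <- function(alns, taxa = NULL) {
  if (!length(alns)) {
    taxa <- taxa %||% character(0)
    out <- codon_alignment(matrix(character(0), nrow = length(taxa), ncol = 0,
                                  dimnames = list(taxa, NULL)))
    attr(out, "boundaries") <- data.frame(gene = character(0),
                                          start = integer(0), end = integer(0))
    return(out)
  }
  taxa <- taxa %||% alns[[1]]$taxa
  for (i in seq_along(alns)) {
    missing <- setdiff(taxa, alns[[i]]$taxa)
    if (length(missing))
      stop(sprintf("alignment %s lacks taxa: %s",
                   names(alns)[i] %||% i, paste(missing, collapse = ", ")))
  }
  mats <- lapply(alns, function(a) a$codons[taxa, , drop = FALSE])
  lens <- vapply(mats, ncol, integer(1))
  out <- codon_alignment(do.call(cbind, mats))
  ends <- cumsum(lens)
  attr(out, "boundaries") <- data.frame(
    gene = names(alns) %||% as.character(seq_along(alns)),
    start = c(1L, utils::head(ends, -1L) + 1L), end = ends,
    stringsAsFactors = FALSE)
  out
}
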