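# Tree handling. Trees are ape "phylo" objects, rooted and binary. A branch is
# identified by the node at its child end: tip branches by the tip label,
# internal branches by the internal node label (assigned "N<k>" when absent).

#' Prepare a phylogeny for model fitting
#'
#' Checks that the tree is rooted and binary, assigns labels to unlabelled
#' internal nodes, and parses a PAML-style foreground mark (a `#1` suffix on a
#' tip or node label), which is stored in `attr(tree, "foreground")`.
#'
#' @param tree An `ape::phylo` object or a Newick string / file path.
#' @param allow_multifurcation Accept polytomies (used by ancestral
#'   reconstruction; substitution models and simulation require binary
#'   trees).
#' @return A `phylo` object with complete node labels.
#' @export
prepare_tree <- function(tree, allow_multifurcation = FALSE) {
  if (is.character(tree)) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  }
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object or Newick")
  if (!allow_multifurcation) {
    # a basal polytomy reads as unrooted in the ape convention; under a
    # reversible model a multifurcating "root" node is an acceptable root
    if (!ape::is.rooted(tree)) stop("tree must be rooted")
    if (!ape::is.binary(tree)) stop("tree must be binary")
  }
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (is.null(tree$node.label)) tree$node.label <- rep("", tree$Nnode)
  blank <- !nzchar(tree$node.label)
  tree$node.label[blank] <- paste0("N", which(blank))
  fg <- NULL
  strip <- function(x) sub("\\s*#\\s*1$", "", x)
  marked_tip <- grepl("#\\s*1$", tree$tip.label)
  marked_node <- grepl("#\\s*1$", tree$node.label)
  if (any(marked_tip) || any(marked_node)) {
    tree$tip.label <- strip(tree$tip.label)
    tree$node.label <- strip(tree$node.label)
    fg <- c(tree$tip.label[marked_tip], tree$node.label[marked_node])[1]
  }
  attr(tree, "foreground") <- fg
  tree
}

node_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' Branch identifiers of a tree
#'
#' @param tree A prepared `phylo` tree.
#' @return Character vector, one id per edge (ordered as `tree$edge`), naming
#'   each branch by its child node.
#' @export
branch_ids <- function(tree) {
  node_labels(tree)[tree$edge[, 2]]
}

# Postorder edge table used by likelihood and simulation code.
# Returns list(edge = matrix parent/child (postorder), t = lengths,
#              branch = ids, root = root node index, ntip = #tips)
tree_struct <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ids <- node_labels(tr)[tr$edge[, 2]]
  list(edge = tr$edge, t = tr$edge.length, branch = ids,
       root = length(tr$tip.label) + 1L, ntip = length(tr$tip.label),
       labels = node_labels(tr))
}

# Map branch id -> edge row (in tree_struct order); errors on unknown ids.
branch_edge_index <- function(st, ids) {
  idx <- match(ids, st$branch)
  if (anyNA(idx)) stop("unknown branch id(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  idx
}

# TRUE if branch `a` lies on the root-ward path of branch `b` or vice versa.
branches_nested <- function(tree, a, b) {
  st <- tree_struct(tree)
  child_of <- function(id) st$edge[branch_edge_index(st, id), 2]
  ancestors <- function(node) {
    out <- integer(0)
    repeat {
      row <- which(st$edge[, 2] == node)
      if (!length(row)) break
      node <- st$edge[row, 1]
      out <- c(out, node)
    }
    out
  }
  na <- child_of(a); nb <- child_of(b)
  (na %in% ancestors(nb)) || (nb %in% ancestors(na))
}

#' The default six-taxon study phylogeny
#'
#' A rooted tree of the six species used throughout the synthetic analyses
#' (zokor, rat, kangaroo rat, guinea pig, naked mole-rat, human), with branch
#' lengths in expected substitutions per codon. The zokor and naked mole-rat
#' terminal branches are the usual foreground / focal-pair choices.
#'
#' @return A prepared `phylo` object.
#' @export
study_tree <- function() {
  nw <- paste0("(((kangaroo_rat:0.55,(rat:0.40,zokor:0.25)murid:0.15)",
               "myomorpha:0.10,(guinea_pig:0.45,naked_mole_rat:0.38)",
               "hystricomorpha:0.20)rodentia:0.12,human:0.75)root;")
  prepare_tree(nw)
}

#' Default per-branch dN/dS values for the study phylogeny
#'
#' Terminal-branch values follow the contrast the pipeline is designed to
#' detect: strong purifying selection on the zokor branch (0.09) and a higher
#' rat value (0.136), with intermediate values elsewhere.
#'
#' @return Named numeric vector keyed by branch id.
#' @export
study_branch_omega <- function() {
  tr <- study_tree()
  om <- setNames(rep(0.12, nrow(tr$edge)), branch_ids(tr))
  om["zokor"] <- 0.09
  om["rat"] <- 0.136
  om["naked_mole_rat"] <- 0.11
  om["human"] <- 0.10
  om
}
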