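#' Parse a Newick tree
#'
#' Thin wrapper around [ape::read.tree()] adding the error reporting the
#' pipeline needs: unbalanced parentheses are reported with the offending
#' character position, and duplicate leaf labels are an error rather than a
#' silent oddity.  Trees are treated as rooted throughout the package.
#'
#' @param text Newick string (terminating `;` optional), or `NULL`.
#' @param file path to a Newick file, used when `text` is `NULL`.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  in_q <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_q <- !in_q
    if (in_q) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at position ", i)
    }
  }
  if (depth != 0L) stop("unbalanced '(': ", depth, " unclosed at end of input")
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  tr
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] object.
#' @param file optional output path.
#' @param digits precision for branch lengths.
#' @return the Newick string, invisibly when writing to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

clade_key <- function(labels) paste(sort(labels), collapse = "\r")

#' Non-trivial clades of a rooted tree
#'
#' Every internal node other than the root defines a clade: the set of
#' leaves it subtends.  Clades (not unrooted splits) are the unit of all
#' consensus, support, and constraint logic in this package, matching how
#' clade supports are reported on rooted consensus trees.
#'
#' @param tree an [ape::phylo] object (may be multifurcating).
#' @return list of character vectors of tip labels, one per non-trivial
#'   clade (size between 2 and `ntips - 1`).
#' @export
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  desc <- descendant_tips(tree)
  nodes <- setdiff(unique(tree$edge[, 2L]), seq_len(ntip))
  out <- lapply(nodes, function(v) tree$tip.label[desc[[v]]])
  out <- out[vapply(out, length, 1L) >= 2L & vapply(out, length, 1L) < ntip]
  out
}

# tip indices under every node, indexed by node id
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  desc <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  edge <- tree$edge[postorder_edges(tree), , drop = FALSE]
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; c <- edge[r, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

# row order of tree$edge such that each child's subtree precedes its edge
postorder_edges <- function(tree) {
  ape::reorder.phylo(tree, "postorder", index.only = TRUE)
}

check_same_leaves <- function(trees) {
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    cur <- sort(trees[[i]]$tip.label)
    if (!identical(ref, cur)) {
      d <- c(setdiff(ref, cur), setdiff(cur, ref))
      stop("trees have mismatched leaf sets; symmetric difference: ",
           paste(d, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Clade frequencies across a set of rooted trees
#'
#' @param trees list of [ape::phylo] objects on an identical leaf set.
#' @return data frame with columns `clade` (list of tip-label vectors) and
#'   `freq` (fraction of trees containing each clade).
#' @export
clade_frequencies <- function(trees) {
  check_same_leaves(trees)
  counts <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (tr in trees) {
    for (cl in tree_clades(tr)) {
      k <- clade_key(cl)
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
      store[[k]] <- cl
    }
  }
  keys <- ls(counts)
  data.frame(
    clade = I(lapply(keys, function(k) store[[k]])),
    freq = vapply(keys, function(k) counts[[k]], 1L) / length(trees),
    row.names = NULL
  )
}

# Build a rooted (possibly multifurcating) tree from a compatible clade set.
# `labels`, if given, annotates each clade's node.
tree_from_clades <- function(clades, tips, labels = NULL) {
  nest <- function(tipset, idx) {
    sizes <- vapply(clades[idx], length, 1L)
    idx <- idx[order(-sizes)]
    children <- list(); used <- character()
    for (i in idx) {
      cl <- clades[[i]]
      if (length(intersect(cl, used))) next     # inside an earlier maximal clade
      inner <- idx[vapply(idx, function(j)
        j != i && all(clades[[j]] %in% cl), TRUE)]
      lab <- if (is.null(labels)) "" else labels[i]
      children <- c(children, paste0(nest(cl, inner), lab))
      used <- c(used, cl)
    }
    loose <- setdiff(tipset, used)
    parts <- c(unlist(children), quote_label(loose))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  root_idx <- seq_along(clades)
  txt <- paste0(nest(tips, root_idx), ";")
  parse_newick(txt)
}

quote_label <- function(x) {
  needs <- grepl("[ ,():;]", x)
  x[needs] <- paste0("'", x[needs], "'")
  x
}

#' Strict consensus of rooted trees
#'
#' Returns the tree containing exactly the clades present in every input
#' tree.  All inputs must share one leaf set; a mismatch is an error that
#' lists the symmetric difference.
#'
#' @param trees a non-empty list of [ape::phylo] objects.
#' @return an [ape::phylo] object (multifurcating where inputs disagree).
#' @export
strict_consensus <- function(trees) {
  stopifnot(length(trees) >= 1L)
  cf <- clade_frequencies(trees)
  keep <- cf$freq >= 1
  tree_from_clades(cf$clade[keep], sort(trees[[1L]]$tip.label))
}

#' Majority-rule consensus of rooted trees
#'
#' Contains exactly the clades whose frequency strictly exceeds
#' `threshold` (so at the default 0.5 a clade in exactly half the trees is
#' excluded).  Frequencies are attached as node labels.
#'
#' @param trees a non-empty list of [ape::phylo] objects.
#' @param threshold clade-frequency cutoff in `[0.5, 1)`; strict inequality.
#' @return an [ape::phylo] with clade frequencies as `node.label`.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1L, threshold >= 0.5, threshold < 1)
  cf <- clade_frequencies(trees)
  keep <- cf$freq > threshold
  tree_from_clades(cf$clade[keep], sort(trees[[1L]]$tip.label),
                   labels = format(cf$freq, digits = 4L)[keep])
}

#' Restrict two trees to their shared taxa
#'
#' Both trees are pruned to the leaves present in both, with resulting
#' degree-2 nodes suppressed (branch lengths summed), the preprocessing
#' required before stratigraphic congruence values of different studies'
#' topologies can be compared.
#'
#' @param tree_a,tree_b [ape::phylo] objects.
#' @return list with elements `tree_a`, `tree_b`, `shared` (the common
#'   leaf labels).  Fewer than 3 shared leaves is an error.
#' @export
prune_to_common_taxa <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 3L)
    stop("only ", length(shared), " shared taxa; need at least 3")
  list(tree_a = ape::keep.tip(tree_a, shared),
       tree_b = ape::keep.tip(tree_b, shared),
       shared = sort(shared))
}

#' Does a rooted tree contain a clade?
#'
#' @param tree an [ape::phylo] object.
#' @param taxa tip labels of the putative clade.
#' @return logical.
#' @export
has_clade <- function(tree, taxa) {
  key <- clade_key(taxa)
  any(vapply(tree_clades(tree), clade_key, "") == key)
}
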