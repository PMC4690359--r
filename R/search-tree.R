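# Unrooted binary trees for tree search, held as plain 2-column integer
# edge matrices.  Tips are 1..ntip (indexing matrix rows / tipcost slabs);
# internal node ids are arbitrary and may be non-contiguous after moves.
# The compiled scorer accepts these matrices directly.

etree_adj <- function(E, maxid = max(E)) {
  adj <- vector("list", maxid)
  for (r in seq_len(nrow(E))) {
    a <- E[r, 1L]; b <- E[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# nodes reachable from `from` when edge row `skip` is removed
etree_component <- function(E, from, skip) {
  adjE <- vector("list", max(E))
  for (r in seq_len(nrow(E))) {
    if (r == skip) next
    a <- E[r, 1L]; b <- E[r, 2L]
    adjE[[a]] <- c(adjE[[a]], b)
    adjE[[b]] <- c(adjE[[b]], a)
  }
  seen <- logical(max(E))
  stack <- from
  seen[from] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    for (u in adjE[[v]]) if (!seen[u]) { seen[u] <- TRUE; stack <- c(stack, u) }
  }
  which(seen)
}

# the single unrooted topology on the first three tips of `order`
etree_init <- function(order, internal_id) {
  cbind(rep(internal_id, 3L), order[1:3], deparse.level = 0L)
}

# subdivide edge row `r` with node `mid` and hang `leaf` from it
etree_insert <- function(E, r, mid, leaf) {
  a <- E[r, 1L]; b <- E[r, 2L]
  rbind(E[-r, , drop = FALSE],
        c(a, mid), c(mid, b), c(mid, leaf), deparse.level = 0L)
}

# Rooted-clade keys of an unrooted tree relative to a reference tip, one
# per internal edge; the tree fingerprint is their sorted concatenation.
etree_splits <- function(E, ntip, ref = 1L) {
  adj <- etree_adj(E)
  maxid <- length(adj)
  parent <- integer(maxid)
  order <- integer(0L)
  stack <- ref
  parent[ref] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
  }
  below <- vector("list", maxid)
  for (v in rev(order)) {
    if (v <= ntip) below[[v]] <- v
    for (u in adj[[v]]) if (u != parent[v]) below[[v]] <- c(below[[v]], below[[u]])
  }
  keys <- character(0L)
  for (v in order) {
    if (v <= ntip || v == ref) next
    tips <- sort(below[[v]])
    if (length(tips) >= 2L && length(tips) <= ntip - 2L)
      keys <- c(keys, paste(tips, collapse = ","))
  }
  sort(keys)
}

etree_fingerprint <- function(E, ntip) {
  paste(etree_splits(E, ntip), collapse = ";")
}

# Does the unrooted tree, rooted at tip `og`, contain `clade` (tip ids)?
# During stepwise addition `og` may not be placed yet; any placed tip
# outside the clade serves as the reference, and a clade spanning every
# placed tip is vacuously present.
etree_has_clade <- function(E, ntip, clade, og) {
  present <- sort(unique(c(E)))
  present <- present[present <= ntip]
  if (!og %in% present) {
    alt <- setdiff(present, clade)
    if (!length(alt)) return(TRUE)
    og <- alt[1L]
  }
  key <- paste(sort(clade), collapse = ",")
  # splits relative to og: a clade is a component not containing og
  adj <- etree_adj(E)
  parent <- integer(length(adj))
  order <- integer(0L)
  stack <- og; parent[og] <- -1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order <- c(order, v)
    for (u in adj[[v]]) if (u != parent[v]) { parent[u] <- v; stack <- c(stack, u) }
  }
  below <- vector("list", length(adj))
  for (v in rev(order)) {
    if (v <= ntip) below[[v]] <- v
    for (u in adj[[v]]) if (u != parent[v]) below[[v]] <- c(below[[v]], below[[u]])
  }
  for (v in order) {
    if (v == og) next
    if (paste(sort(below[[v]]), collapse = ",") == key) return(TRUE)
  }
  FALSE
}

# Root an unrooted edge matrix on the branch of tip `og` and return a
# rooted binary ape::phylo with the package's taxon labels.
etree_to_phylo <- function(E, ntip, labels, og = 1L) {
  adj <- etree_adj(E)
  u <- adj[[og]][1L]
  part <- function(v, p) {
    if (v <= ntip) return(quote_label(labels[v]))
    kids <- setdiff(adj[[v]], p)
    paste0("(", paste(vapply(kids, function(w) part(w, v), ""),
                      collapse = ","), ")")
  }
  txt <- paste0("(", quote_label(labels[og]), ",", part(u, og), ");")
  parse_newick(txt)
}

# inverse of etree_to_phylo: unroot a binary rooted phylo into an edge
# matrix whose tip ids follow `taxa` (the matrix row order)
phylo_to_etree <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  map <- match(tree$tip.label, taxa)
  if (anyNA(map)) stop("tree has tips outside the matrix: ",
                       paste(tree$tip.label[is.na(map)], collapse = ", "))
  idmap <- c(map, length(taxa) + seq_len(tree$Nnode))
  E <- cbind(idmap[tree$edge[, 1L]], idmap[tree$edge[, 2L]])
  root <- idmap[ntip + 1L]
  kids <- E[E[, 1L] == root, 2L]
  if (length(kids) == 2L) {   # suppress the rooting node
    E <- E[E[, 1L] != root, , drop = FALSE]
    E <- rbind(E, kids)
  }
  unname(E)
}

# Enumerate TBR neighbours of an unrooted binary tree, calling
# `visit(Enew)` for each candidate.  Covers the full neighbourhood:
# bisect every branch, reconnect every pair of branches of the two
# fragments (with rerooting of the clipped fragment); leaf bisections
# give the SPR subset.  The identity reconnection is skipped.
tbr_apply <- function(E, ntip, visit) {
  m <- nrow(E)
  adj <- etree_adj(E)
  for (e in seq_len(m)) {
    u <- E[e, 1L]; v <- E[e, 2L]
    compA <- etree_component(E, u, e)
    inA <- logical(length(adj)); inA[compA] <- TRUE
    rowsA <- which(inA[E[, 1L]] & inA[E[, 2L]])
    rowsB <- setdiff(seq_len(m)[-e], rowsA)
    frag <- function(node, rows) {
      # returns list(edges = matrix, merged_row = row index recreating
      # the original attachment, or NA when node is a leaf fragment)
      if (!length(rows)) return(list(edges = NULL, merged = NA_integer_))
      Ef <- E[rows, , drop = FALSE]
      nb <- setdiff(adj[[node]], c(u, v))
      if (length(nb) == 2L) {   # suppress the degree-2 stump
        keep <- !(Ef[, 1L] == node | Ef[, 2L] == node)
        Ef <- rbind(Ef[keep, , drop = FALSE], nb)
        merged <- nrow(Ef)
      } else merged <- NA_integer_
      list(edges = Ef, merged = merged)
    }
    A <- frag(u, rowsA)
    B <- frag(v, rowsB)
    optA <- if (is.null(A$edges)) 0L else seq_len(nrow(A$edges))
    optB <- if (is.null(B$edges)) 0L else seq_len(nrow(B$edges))
    idA <- if (is.na(A$merged)) 0L else A$merged
    idB <- if (is.na(B$merged)) 0L else B$merged
    for (ra in optA) {
      for (rb in optB) {
        if (ra == idA && rb == idB) next   # identity reconnection
        partA <- if (ra == 0L) NULL else {
          r <- A$edges[ra, ]
          rbind(A$edges[-ra, , drop = FALSE], c(r[1L], u), c(u, r[2L]))
        }
        partB <- if (rb == 0L) NULL else {
          r <- B$edges[rb, ]
          rbind(B$edges[-rb, , drop = FALSE], c(r[1L], v), c(v, r[2L]))
        }
        if (ra == 0L && rb == 0L) next   # both fragments single leaves: n = 2
        Enew <- rbind(partA, partB, c(u, v), deparse.level = 0L)
        visit(Enew)
      }
    }
  }
  invisible(NULL)
}

# Enumerate every unrooted binary topology on `ntip` tips by recursive
# leaf insertion, calling visit(E) per tree.  (2n-5)!! trees; guarded by
# callers to small n.
all_topologies_apply <- function(ntip, visit) {
  stopifnot(ntip >= 3L)
  recur <- function(E, t, next_id) {
    if (t > ntip) { visit(E); return(invisible(NULL)) }
    for (r in seq_len(nrow(E))) {
      recur(etree_insert(E, r, next_id, t), t + 1L, next_id + 1L)
    }
  }
  recur(etree_init(1:3, ntip + 1L), 4L, ntip + 2L)
}
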