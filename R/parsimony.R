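INF_COST <- 1e7
K_STATES <- 10L  # common state space; unobserved states are inert under unit cost

# k x nchar x ntip cost array from a morph_matrix (0 = allowed, INF = not).
# Missing and inapplicable cells are all-zero columns ("any state").
tipcost_array <- function(x, tip_order = x$taxa, k = K_STATES) {
  cells <- x$cells[tip_order, , drop = FALSE]
  nc <- ncol(cells)
  arr <- array(0, dim = c(k, nc, length(tip_order)))
  bits <- bitwShiftL(1L, 0:(k - 1L))
  for (t in seq_along(tip_order)) {
    m <- cells[t, ]
    obs <- m > 0L
    if (any(obs)) {
      allow <- outer(bits, m[obs], function(b, mm) bitwAnd(mm, b) != 0L)
      block <- matrix(0, k, sum(obs))
      block[!allow] <- INF_COST
      arr[, obs, t] <- block
    }
  }
  arr
}

# cost array for a single 0-based state vector (e.g. the area character)
tipcost_single <- function(states, tip_order = names(states), k) {
  arr <- array(INF_COST, dim = c(k, 1L, length(tip_order)))
  st <- states[tip_order]
  for (t in seq_along(tip_order)) arr[st[t] + 1L, 1L, t] <- 0
  arr
}

# Score a tree given as an edge matrix over node ids with tips 1..ntip.
score_edges <- function(edges, ntip, tipcost, nchar, weights = NULL,
                        per_char = FALSE, k = dim(tipcost)[1L]) {
  if (is.null(weights)) weights <- rep(1, nchar)
  C_parsimony_score(edges, ntip, as.numeric(tipcost), k, nchar, weights,
                    per_char)
}

# Map a phylo's tips onto matrix rows so edge node ids 1..ntip index tipcost.
phylo_score_edges <- function(tree, x) {
  absent <- setdiff(tree$tip.label, x$taxa)
  if (length(absent))
    stop("tree leaves without a matrix row: ", paste(absent, collapse = ", "))
  tree$edge
}

#' Parsimony length and ensemble indices of a tree
#'
#' Computes the minimum number of unordered state changes each character
#' requires on `tree` (Fitch counting, generalised to polytomies via
#' uniform-cost dynamic programming), together with the ensemble
#' consistency index (CI = sum of per-character minima / length), retention
#' index (RI), and rescaled consistency index (RCI = CI x RI).  Missing and
#' inapplicable cells never add steps.  Because parsimony-uninformative
#' characters add equal amounts to the numerators and denominators of some
#' published index variants, the indices are reported both over all
#' characters and over informative characters only.
#'
#' @param tree a rooted [ape::phylo]; may be multifurcating.  Tip labels
#'   must appear in `x`.
#' @param x a [morph_matrix()].
#' @param weights optional per-character multiplicities (used by the
#'   bootstrap); default all 1.
#' @return object of class `parsimony_score`: list with `total_length`,
#'   `per_char_length`, `min_steps`, `max_steps`, `ci`, `ri`, `rci`, and
#'   `*_informative` variants.
#' @export
fitch_length <- function(tree, x, weights = NULL) {
  tc <- tipcost_array(x, tip_order = tree$tip.label)
  nc <- n_char(x)
  if (is.null(weights)) weights <- rep(1, nc)
  edges <- phylo_score_edges(tree, x)
  sc <- score_edges(edges, length(tree$tip.label), tc, nc, weights,
                    per_char = TRUE)
  b <- char_bounds(x, tips = tree$tip.label)
  len <- sc$per_char
  idx <- function(sub) {
    smin <- sum(weights[sub] * b$min_steps[sub])
    smax <- sum(weights[sub] * b$max_steps[sub])
    slen <- sum(weights[sub] * len[sub])
    ci <- if (slen > 0) smin / slen else NA_real_
    ri <- if (smax > smin) (smax - slen) / (smax - smin) else NA_real_
    list(ci = ci, ri = ri, rci = ci * ri)
  }
  all_i <- idx(seq_len(nc))
  inf <- which(b$min_steps < b$max_steps)
  inf_i <- idx(inf)
  structure(list(
    total_length = sc$total,
    per_char_length = len,
    min_steps = b$min_steps,
    max_steps = b$max_steps,
    ci = all_i$ci, ri = all_i$ri, rci = all_i$rci,
    ci_informative = inf_i$ci, ri_informative = inf_i$ri,
    rci_informative = inf_i$rci,
    n_informative = length(inf)
  ), class = "parsimony_score")
}

#' @export
print.parsimony_score <- function(x, ...) {
  cat("Parsimony score\n")
  cat("  length:", x$total_length, "\n")
  cat(sprintf("  CI = %.2f  RI = %.2f  RCI = %.2f  (all %d characters)\n",
              x$ci, x$ri, x$rci, length(x$per_char_length)))
  cat(sprintf("  CI = %.2f  RI = %.2f  RCI = %.2f  (%d informative only)\n",
              x$ci_informative, x$ri_informative, x$rci_informative,
              x$n_informative))
  invisible(x)
}

#' Per-character minimum and maximum step counts
#'
#' `min_steps` is the smallest length the character can require on any
#' tree: the number of states it is forced to exhibit minus one.  States
#' fixed by monomorphic cells all count; a polymorphic cell adds a state
#' only if none of its members is otherwise present (it is free to side
#' with an existing state).  `max_steps` is the length on the star tree:
#' the number of scorable cells minus the largest count attainable by any
#' single state, again with polymorphic cells free to join the majority.
#' These are the ingredients of the CI and RI denominators.
#'
#' @param x a [morph_matrix()].
#' @param tips optional subset of taxa to restrict to.
#' @return list with integer vectors `min_steps`, `max_steps`.
#' @export
char_bounds <- function(x, tips = x$taxa) {
  cells <- x$cells[tips, , drop = FALSE]
  nc <- ncol(cells)
  bits <- bitwShiftL(1L, 0:(K_STATES - 1L))
  min_s <- integer(nc)
  max_s <- integer(nc)
  for (j in seq_len(nc)) {
    m <- cells[, j]
    m <- m[m > 0L]
    if (!length(m)) next
    counts <- vapply(bits, function(b) sum(bitwAnd(m, b) != 0L), 1L)
    fixed <- Reduce(bitwOr, m[bitwAnd(m, m - 1L) == 0L], accumulate = FALSE) %||% 0L
    poly <- m[bitwAnd(m, m - 1L) != 0L]
    extra <- as.integer(length(poly) > 0L && any(bitwAnd(poly, fixed) == 0L))
    nreq <- sum(bitwAnd(fixed, bits) != 0L) + extra
    min_s[j] <- max(nreq - 1L, 0L)
    max_s[j] <- length(m) - max(counts)
  }
  list(min_steps = min_s, max_steps = max_s)
}

# --- most-parsimonious-reconstruction machinery (R-side dynamic program) ---

colmin <- function(w) do.call(pmin, lapply(seq_len(nrow(w)), function(i) w[i, ]))

# Down/up pass over a rooted (possibly multifurcating) phylo.
# tipcost: k x nchar x ntip (tips ordered as tree$tip.label).
# Returns per-node downpass costs, uppass ("rest of tree") costs, each
# child's contribution to its parent, and per-character optimal lengths.
parsimony_dp <- function(tree, tipcost) {
  k <- dim(tipcost)[1L]; nc <- dim(tipcost)[2L]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- postorder_edges(tree)
  edge <- tree$edge
  down <- vector("list", nnode)
  contrib <- vector("list", nnode)   # indexed by child node
  for (t in seq_len(ntip)) down[[t]] <- matrix(tipcost[, , t], k, nc)
  for (v in (ntip + 1L):nnode) down[[v]] <- matrix(0, k, nc)
  for (r in po) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    w <- down[[ch]]
    mn1 <- rep(colmin(w) + 1, each = k)
    contrib[[ch]] <- pmin(w, mn1)
    down[[p]] <- down[[p]] + contrib[[ch]]
  }
  charlen <- colmin(down[[root]])
  up <- vector("list", nnode)
  up[[root]] <- matrix(0, k, nc)
  for (r in rev(po)) {      # preorder: parents before children
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    w <- up[[p]] + down[[p]] - contrib[[ch]]
    up[[ch]] <- pmin(w, rep(colmin(w) + 1, each = k))
  }
  list(down = down, up = up, contrib = contrib, charlen = charlen,
       k = k, nchar = nc, root = root, ntip = ntip)
}

#' Most-parsimonious-reconstruction state sets
#'
#' For every node and character, the set of states that the node takes in
#' at least one most-parsimonious reconstruction (over the common state
#' space; unobserved states can never appear).  Leaves participate too:
#' observed leaves keep their observed set (narrowed to optimal members
#' when polymorphic), missing leaves get every state consistent with an
#' optimal reconstruction.
#'
#' @param tree rooted [ape::phylo], polytomies allowed.
#' @param x a [morph_matrix()].
#' @return object of class `mpr_sets`: list with `sets` (list indexed
#'   `[[node]][[character]]` of integer state vectors), `charlen`
#'   (per-character optimal length), `tree`.
#' @export
mpr_state_sets <- function(tree, x) {
  tc <- tipcost_array(x, tip_order = tree$tip.label)
  dp <- parsimony_dp(tree, tc)
  nnode <- length(dp$down)
  sets <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    tot <- dp$down[[v]] + dp$up[[v]]
    opt <- abs(sweep(tot, 2L, dp$charlen)) < 0.5
    sets[[v]] <- lapply(seq_len(dp$nchar), function(j) which(opt[, j]) - 1L)
  }
  structure(list(sets = sets, charlen = dp$charlen, tree = tree),
            class = "mpr_sets")
}

# Per internal edge, per character: can the branch carry zero changes in
# some most-parsimonious reconstruction?  Used by the branch-collapse rule
# and by the unambiguous-change report.
branch_zero_possible <- function(tree, dp) {
  edge <- tree$edge
  out <- matrix(NA, nrow(edge), dp$nchar)
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    w <- dp$up[[p]] + (dp$down[[p]] - dp$contrib[[ch]]) + dp$down[[ch]]
    out[r, ] <- abs(colmin(w) - dp$charlen) < 0.5
  }
  out
}

#' Collapse branches whose minimum length is zero
#'
#' Contracts every internal branch that can be assigned zero changes
#' (summed over all characters) in at least one most-parsimonious
#' reconstruction -- the collapse rule under which distinct trees of a
#' search are counted.  Each contracted branch individually supports a
#' zero-change reconstruction; when several such branches are contracted
#' at once the multifurcating tree may rescore longer than its binary
#' source, which is inherent to the rule (different characters may rely
#' on different branches), so length bookkeeping always refers to the
#' binary trees.
#'
#' @param tree rooted binary (or already partially collapsed) [ape::phylo].
#' @param x a [morph_matrix()].
#' @return a rooted, possibly multifurcating [ape::phylo].
#' @export
collapse_min_zero <- function(tree, x) {
  tc <- tipcost_array(x, tip_order = tree$tip.label)
  dp <- parsimony_dp(tree, tc)
  zp <- branch_zero_possible(tree, dp)
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2L] > ntip
  drop <- internal & apply(zp, 1L, all)
  if (!any(drop)) return(tree)
  contract_edges(tree, tree$edge[drop, 2L])
}

# contract the branches above the given internal nodes (merge each into its
# surviving ancestor) and rebuild the tree
contract_edges <- function(tree, drop_nodes) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  repl <- seq_len(nnode)
  for (r in rev(postorder_edges(tree))) {   # parents before children
    ch <- edge[r, 2L]
    if (ch %in% drop_nodes) repl[ch] <- repl[edge[r, 1L]]
  }
  kids <- vector("list", nnode)
  for (v in seq_len(nnode)) {
    if (v == ntip + 1L) next                       # root
    if (v > ntip && repl[v] != v) next             # contracted away
    np <- repl[parent[v]]
    kids[[np]] <- c(kids[[np]], v)
  }
  newick_of <- function(v) {
    if (v <= ntip) return(quote_label(tree$tip.label[v]))
    paste0("(", paste(vapply(kids[[v]], newick_of, ""), collapse = ","), ")")
  }
  parse_newick(paste0(newick_of(ntip + 1L), ";"))
}

#' Unambiguously optimised character changes of a set of equally
#' parsimonious trees
#'
#' A change to derived state `s` of character `c` on the branch subtending
#' a clade is unambiguous when, in every supplied tree that contains the
#' clade, every most-parsimonious reconstruction assigns `s` to the clade's
#' node and not to its parent.  This is the list reported as unambiguous
#' synapomorphies on a consensus topology.
#'
#' @param trees list of rooted [ape::phylo] objects of equal parsimony
#'   length on `x` (unequal lengths are an error).
#' @param x a [morph_matrix()].
#' @return data frame with columns `clade` (list of tip labels),
#'   `character` (1-based), `state`, `label` (`"character:state"` form),
#'   `n_trees` (trees containing the clade).
#' @export
unambiguous_changes <- function(trees, x) {
  stopifnot(length(trees) >= 1L)
  lens <- vapply(trees, function(tr) fitch_length(tr, x)$total_length, 1)
  if (diff(range(lens)) > 0.5)
    stop("trees are not equally parsimonious: lengths ",
         paste(unique(lens), collapse = ", "))
  clade_seen <- new.env(parent = emptyenv())  # cladekey -> n trees containing it
  acc <- new.env(parent = emptyenv())  # cladekey|char -> consistent change record
  for (tr in trees) {
    tc <- tipcost_array(x, tip_order = tr$tip.label)
    dp <- parsimony_dp(tr, tc)
    nnode <- dp$ntip + tr$Nnode
    opt <- lapply(seq_len(nnode), function(v)
      abs(sweep(dp$down[[v]] + dp$up[[v]], 2L, dp$charlen)) < 0.5)
    desc <- descendant_tips(tr)
    edge <- tr$edge
    ntip <- dp$ntip
    for (r in seq_len(nrow(edge))) {
      ch <- edge[r, 2L]
      if (ch <= ntip) next
      tipset <- tr$tip.label[desc[[ch]]]
      if (length(tipset) >= length(tr$tip.label)) next
      key0 <- clade_key(tipset)
      clade_seen[[key0]] <- (clade_seen[[key0]] %||% 0L) + 1L
      p <- edge[r, 1L]
      oc <- opt[[ch]]; op <- opt[[p]]
      single <- colSums(oc) == 1L
      # unambiguous within this tree: child fixed to s, parent never s
      for (j in which(single)) {
        s <- which(oc[, j]) - 1L
        if (op[s + 1L, j]) next
        key <- paste0(key0, "|", j)
        cur <- acc[[key]]
        if (is.null(cur))
          cur <- list(state = s, ok = TRUE, n = 0L, clade = tipset,
                      char = j, key0 = key0)
        cur$n <- cur$n + 1L
        if (cur$state != s) cur$ok <- FALSE
        acc[[key]] <- cur
      }
    }
  }
  rows <- lapply(ls(acc), function(k) acc[[k]])
  # require the change in every tree that contains the clade
  rows <- Filter(function(e) e$ok && e$n == clade_seen[[e$key0]], rows)
  if (!length(rows))
    return(data.frame(clade = I(list()), character = integer(),
                      state = integer(), label = character(),
                      n_trees = integer()))
  data.frame(
    clade = I(lapply(rows, `[[`, "clade")),
    character = vapply(rows, `[[`, 1L, "char"),
    state = vapply(rows, `[[`, 1L, "state"),
    label = vapply(rows, function(e) paste0(e$char, ":", e$state), ""),
    n_trees = vapply(rows, `[[`, 1L, "n"),
    row.names = NULL
  )
}
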