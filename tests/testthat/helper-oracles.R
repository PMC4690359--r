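# Independent brute-force oracles.  These deliberately avoid the package's
# dynamic programs: parsimony quantities come from exhaustive enumeration
# of ancestral assignments, stratigraphic extrema from direct enumeration
# of topologies, Mk quantities from exhaustive sums over ancestral states.

with_seed_public <- function(seed, expr) {
  set.seed(seed)
  expr
}

# random rooted binary tree with tip labels from `taxa`
rand_tree <- function(taxa) {
  ape::rtree(length(taxa), tip.label = sample(taxa))
}

# random morph_matrix: masks over `k` states with missing/inapplicable/
# polymorphic cells sprinkled in
rand_matrix <- function(ntax, nchar, k = 3L, p_special = 0.15) {
  taxa <- paste0("T", seq_len(ntax))
  cells <- matrix(bitwShiftL(1L, sample.int(k, ntax * nchar, TRUE) - 1L),
                  ntax, nchar)
  n_sp <- rbinom(1L, ntax * nchar, p_special)
  if (n_sp > 0L) {
    idx <- sample.int(ntax * nchar, n_sp)
    kind <- sample(c(-1L, -2L, 3L), n_sp, TRUE)
    cells[idx] <- kind
  }
  morph_matrix(cells, taxa)
}

# allowed 0-based states of a cell for a given per-character universe
cell_states <- function(cell, universe) {
  if (cell < 0L) return(universe)
  st <- which(bitwAnd(cell, bitwShiftL(1L, 0:9)) != 0L) - 1L
  st
}

# exhaustive minimum-change count for one character on a rooted tree,
# enumerating every assignment of states to internal nodes and to
# flexible leaves
oracle_char_fit <- function(tree, cells_col, universe, collect_sets = FALSE) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  if (!length(universe))
    return(list(len = 0, sets = replicate(nnode, integer(), simplify = FALSE)))
  choices <- vector("list", nnode)
  for (i in seq_len(ntip)) choices[[i]] <- cell_states(cells_col[i], universe)
  for (v in (ntip + 1L):nnode) choices[[v]] <- universe
  grid_len <- vapply(choices, length, 1L)
  total <- prod(grid_len)
  best <- Inf
  sets <- replicate(nnode, integer(), simplify = FALSE)
  assign_idx <- rep(1L, nnode)
  for (it in seq_len(total)) {
    st <- mapply(function(ch, i) ch[i], choices, assign_idx)
    cost <- sum(st[edge[, 1L]] != st[edge[, 2L]])
    if (cost < best - 0.5) {
      best <- cost
      if (collect_sets) sets <- lapply(st, function(s) s)
    } else if (collect_sets && cost < best + 0.5) {
      sets <- mapply(function(old, s) union(old, s), sets, st,
                     SIMPLIFY = FALSE)
    }
    # odometer increment
    for (v in seq_len(nnode)) {
      assign_idx[v] <- assign_idx[v] + 1L
      if (assign_idx[v] <= grid_len[v]) break
      assign_idx[v] <- 1L
    }
  }
  list(len = best, sets = lapply(sets, function(s) sort(as.integer(s))))
}

oracle_fitch <- function(tree, x) {
  uni <- state_universe(x)
  cells <- x$cells[tree$tip.label, , drop = FALSE]
  lens <- vapply(seq_len(ncol(cells)), function(j)
    oracle_char_fit(tree, cells[, j], uni[[j]])$len, 1)
  list(total = sum(lens), per_char = lens)
}

oracle_mpr <- function(tree, x) {
  uni <- state_universe(x)
  cells <- x$cells[tree$tip.label, , drop = FALSE]
  lapply(seq_len(ncol(cells)), function(j)
    oracle_char_fit(tree, cells[, j], uni[[j]], collect_sets = TRUE)$sets)
}

# per character, per edge: does some optimal assignment give the edge
# equal endpoint states?  And: is the change child = s, parent != s forced
# in every optimal assignment?
oracle_edge_analysis <- function(tree, cells_col, universe) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  m <- nrow(edge)
  if (!length(universe))
    return(list(zero_ok = rep(TRUE, m), forced = vector("list", m)))
  choices <- vector("list", nnode)
  for (i in seq_len(ntip)) choices[[i]] <- cell_states(cells_col[i], universe)
  for (v in (ntip + 1L):nnode) choices[[v]] <- universe
  grid_len <- vapply(choices, length, 1L)
  total <- prod(grid_len)
  best <- Inf
  zero_ok <- rep(FALSE, m)
  child_states <- vector("list", m)  # observed (child, parent-equal?) combos
  parent_states <- vector("list", m)
  assign_idx <- rep(1L, nnode)
  for (it in seq_len(total)) {
    st <- mapply(function(ch, i) ch[i], choices, assign_idx)
    cost <- sum(st[edge[, 1L]] != st[edge[, 2L]])
    if (cost < best - 0.5) {
      best <- cost
      zero_ok <- st[edge[, 1L]] == st[edge[, 2L]]
      child_states <- lapply(seq_len(m), function(r) st[edge[r, 2L]])
      parent_states <- lapply(seq_len(m), function(r) st[edge[r, 1L]])
    } else if (cost < best + 0.5) {
      zero_ok <- zero_ok | (st[edge[, 1L]] == st[edge[, 2L]])
      for (r in seq_len(m)) {
        child_states[[r]] <- union(child_states[[r]], st[edge[r, 2L]])
        parent_states[[r]] <- union(parent_states[[r]], st[edge[r, 1L]])
      }
    }
    for (v in seq_len(nnode)) {
      assign_idx[v] <- assign_idx[v] + 1L
      if (assign_idx[v] <= grid_len[v]) break
      assign_idx[v] <- 1L
    }
  }
  forced <- lapply(seq_len(m), function(r) {
    cs <- child_states[[r]]
    if (length(cs) == 1L && !(cs %in% parent_states[[r]])) cs else integer()
  })
  list(zero_ok = zero_ok, forced = forced, best = best)
}

# all MIG values over every rooted binary topology on the given ages
oracle_all_migs <- function(ages) {
  n <- length(ages)
  recur <- function(a) {
    if (length(a) == 1L) return(0)
    mx <- max(a)
    out <- numeric(0L)
    # splits fixing the first element in part A
    rest <- a[-1L]
    for (mask in 0:(2^(length(rest)) - 1L)) {
      inA <- as.logical(bitwAnd(mask, 2^(seq_along(rest) - 1L)))
      A <- c(a[1L], rest[inA]); B <- rest[!inA]
      if (!length(B)) next
      va <- recur(A); vb <- recur(B)
      add <- (mx - max(A)) + (mx - max(B))
      out <- c(out, outer(va, vb, "+") + add)
    }
    out
  }
  recur(ages)
}

# exhaustive Mk likelihood and node marginals by summing over all
# ancestral state assignments
oracle_mk <- function(tree, states, alpha, k, prior = rep(1 / k, k)) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  len <- tree$edge.length
  internal <- (ntip + 1L):nnode
  P <- lapply(seq_len(nrow(edge)), function(r)
    stratphylo:::mk_pmat(alpha, len[r], k))
  grid <- as.matrix(expand.grid(rep(list(seq_len(k) - 1L), length(internal))))
  total <- 0
  marg <- matrix(0, nnode, k)
  st <- integer(nnode)
  st[seq_len(ntip)] <- states[tree$tip.label]
  for (g in seq_len(nrow(grid))) {
    st[internal] <- grid[g, ]
    pr <- prior[st[ntip + 1L] + 1L]
    for (r in seq_len(nrow(edge)))
      pr <- pr * P[[r]][st[edge[r, 1L]] + 1L, st[edge[r, 2L]] + 1L]
    total <- total + pr
    for (v in seq_len(nnode)) marg[v, st[v] + 1L] <- marg[v, st[v] + 1L] + pr
  }
  list(lik = total, marginals = marg / total)
}
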