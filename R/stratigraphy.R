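ages_vector <- function(ages, taxa, which = c("oldest", "youngest")) {
  which <- match.arg(which)
  if (inherits(ages, "age_table")) {
    validate_taxa(ages, taxa)
    v <- if (which == "oldest") ages$fad_oldest else ages$fad_youngest
    names(v) <- ages$taxon
    v[taxa]
  } else {
    v <- ages[taxa]
    if (anyNA(v)) stop("ages missing for: ",
                       paste(taxa[is.na(v)], collapse = ", "))
    v
  }
}

#' Minimum-age time calibration with ghost lineages
#'
#' Assigns each leaf its first-appearance age (an endpoint of its age
#' interval) and each internal node the maximum of its children's ages --
#' the minimum-age calibration under which every implied gap is as short
#' as the topology allows.  The ghost duration of a branch is the age
#' difference between its two ends: the span of fossil record the
#' topology implies but the rocks have not yielded.
#'
#' @param tree rooted [ape::phylo] (polytomies allowed).
#' @param ages an `age_table` covering the tips, or a named numeric vector
#'   of point ages (Ma).
#' @param which interval endpoint to use: `"oldest"` (default) or
#'   `"youngest"`.
#' @return object of class `calibrated_tree`: list with `tree`, `node_age`
#'   (ages for all node ids), `ghost` (per `tree$edge` row, myr), `which`.
#' @export
calibrate <- function(tree, ages, which = c("oldest", "youngest")) {
  which <- match.arg(which)
  la <- ages_vector(ages, tree$tip.label, which)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  age <- numeric(nnode)
  age[seq_len(ntip)] <- la
  edge <- tree$edge
  for (r in postorder_edges(tree)) {
    p <- edge[r, 1L]
    age[p] <- max(age[p], age[edge[r, 2L]])
  }
  ghost <- age[edge[, 1L]] - age[edge[, 2L]]
  structure(list(tree = tree, node_age = age, ghost = ghost, which = which),
            class = "calibrated_tree")
}

#' @export
print.calibrated_tree <- function(x, ...) {
  cat("Time-calibrated tree:", length(x$tree$tip.label), "tips\n")
  cat(sprintf("  root age %.1f Ma; total implied gap (MIG) %.1f myr\n",
              x$node_age[length(x$tree$tip.label) + 1L], sum(x$ghost)))
  cat(sprintf("  longest single ghost lineage %.1f myr\n", max(x$ghost)))
  invisible(x)
}

#' Minimum implied gap
#'
#' Sum of ghost-lineage durations over all branches of a calibrated tree,
#' in myr: the total span of missing fossil record the topology implies
#' given the first appearances.
#'
#' @param ct a [calibrate()] result.
#' @return numeric scalar (myr).
#' @export
mig <- function(ct) {
  stopifnot(inherits(ct, "calibrated_tree"))
  sum(ct$ghost)
}

dfact <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

#' Extremal implied gaps over all topologies
#'
#' The minimum (`g_min`) and maximum (`g_max`) MIG attainable by any
#' rooted binary topology on leaves with the given first-appearance ages.
#' The closed forms are `g_min = oldest - youngest` (attained by the
#' pectinate tree with taxa nested oldest-first, where every gap
#' telescopes along one path) and `g_max = sum(oldest - age_i)` (attained
#' by a pectinate tree carrying the oldest taxon at its innermost
#' position, so every other taxon hangs from a root-age node).  Both are
#' certified against exhaustive enumeration over all topologies, which is
#' also available directly (`method = "exhaustive"`, up to 8 leaves, via
#' dynamic programming over leaf subsets -- an exact minimisation /
#' maximisation over all (2n-3)!! rooted binary trees).
#'
#' @param ages numeric vector of leaf ages (Ma), length at least 3.
#' @param method `"construction"` (default, any n) or `"exhaustive"`
#'   (n <= 8).
#' @return list with `g_min`, `g_max` (myr).
#' @export
g_bounds <- function(ages, method = c("construction", "exhaustive")) {
  method <- match.arg(method)
  ages <- as.numeric(ages)
  stopifnot(length(ages) >= 2L)
  if (method == "construction") {
    return(list(g_min = max(ages) - min(ages),
                g_max = sum(max(ages) - ages)))
  }
  n <- length(ages)
  if (n > 8L) stop("exhaustive bounds limited to 8 leaves")
  nset <- bitwShiftL(1L, n) - 1L
  fmin <- rep(NA_real_, nset)
  fmax <- rep(NA_real_, nset)
  amax <- rep(NA_real_, nset)
  for (S in seq_len(nset)) {
    members <- which(bitwAnd(S, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    amax[S] <- max(ages[members])
    if (length(members) == 1L) { fmin[S] <- 0; fmax[S] <- 0; next }
    lo <- bitwAnd(S, -S)   # fix lowest bit in A for unordered splits
    best_lo <- Inf; best_hi <- -Inf
    A <- bitwAnd(S - 1L, S)
    while (A > 0L) {
      if (bitwAnd(A, lo) == lo) {
        B <- bitwAnd(S, bitwNot(A))
        if (B > 0L) {
          base_lo <- fmin[A] + fmin[B] +
            (amax[S] - amax[A]) + (amax[S] - amax[B])
          base_hi <- fmax[A] + fmax[B] +
            (amax[S] - amax[A]) + (amax[S] - amax[B])
          if (base_lo < best_lo) best_lo <- base_lo
          if (base_hi > best_hi) best_hi <- base_hi
        }
      }
      A <- bitwAnd(A - 1L, S)
    }
    fmin[S] <- best_lo; fmax[S] <- best_hi
  }
  list(g_min = fmin[nset], g_max = fmax[nset])
}

#' Gap excess ratio and modified Manhattan stratigraphic measure
#'
#' `ger = (g_max - mig) / (g_max - g_min)` scales a tree's implied gap
#' between the best and worst achievable on the same ages (1 = as
#' congruent as any topology can be, 0 = as incongruent).  `msm_star =
#' g_min / mig` is the ratio of the minimal possible gap to the observed
#' one.  Degenerate denominators (all ages equal for GER; zero MIG for
#' MSM*) give `NA`, the explicit "undefined" value.
#'
#' @param ct a [calibrate()] result.
#' @return numeric scalar in `[0, 1]`, or `NA` when undefined.
#' @export
ger <- function(ct) {
  la <- ct$node_age[seq_along(ct$tree$tip.label)]
  b <- g_bounds(la)
  if (b$g_max <= b$g_min) return(NA_real_)
  (b$g_max - mig(ct)) / (b$g_max - b$g_min)
}

#' @rdname ger
#' @export
msm_star <- function(ct) {
  la <- ct$node_age[seq_along(ct$tree$tip.label)]
  m <- mig(ct)
  if (m <= 0) return(NA_real_)
  g_bounds(la)$g_min / m
}

# ---- binary resolutions of polytomies ------------------------------------

as_nested <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- vector("list", ntip + tree$Nnode)
  for (r in seq_len(nrow(tree$edge)))
    kids[[tree$edge[r, 1L]]] <- c(kids[[tree$edge[r, 1L]]], tree$edge[r, 2L])
  build <- function(v) {
    if (v <= ntip) return(tree$tip.label[v])
    lapply(kids[[v]], build)
  }
  build(ntip + 1L)
}

nested_to_newick <- function(x) {
  if (is.character(x)) return(quote_label(x))
  paste0("(", paste(vapply(x, nested_to_newick, ""), collapse = ","), ")")
}

# Binary joins introduced while resolving a polytomy are tagged so the
# insertion recursion treats already-resolved subtree units as atomic.
shape_join <- function(a, b) structure(list(a, b), class = "shape_join")
is_join <- function(x) inherits(x, "shape_join")

# all rooted binary shapes over a list of units, by leaf insertion
binary_shapes <- function(items) {
  insert_all <- function(T, x) {
    out <- list(shape_join(T, x))
    if (is_join(T)) {
      for (l in insert_all(T[[1L]], x)) out <- c(out, list(shape_join(l, T[[2L]])))
      for (r in insert_all(T[[2L]], x)) out <- c(out, list(shape_join(T[[1L]], r)))
    }
    out
  }
  shapes <- list(items[[1L]])
  for (i in seq_along(items)[-1L]) {
    shapes <- unlist(lapply(shapes, insert_all, x = items[[i]]),
                     recursive = FALSE)
  }
  shapes
}

random_shape <- function(items) {
  T <- items[[1L]]
  count_pos <- function(T) if (is_join(T))
    1L + count_pos(T[[1L]]) + count_pos(T[[2L]]) else 1L
  insert_at <- function(T, x, pos) {
    # pos 1 = above T; then recurse left, right
    if (pos == 1L) return(list(new = shape_join(T, x), used = 1L))
    used <- 1L
    if (is_join(T)) {
      l <- insert_at(T[[1L]], x, pos - used)
      if (!is.null(l$new)) return(list(new = shape_join(l$new, T[[2L]]),
                                       used = used + l$used))
      used <- used + l$used
      r <- insert_at(T[[2L]], x, pos - used)
      if (!is.null(r$new)) return(list(new = shape_join(T[[1L]], r$new),
                                       used = used + r$used))
      used <- used + r$used
    }
    list(new = NULL, used = used)
  }
  for (i in seq_along(items)[-1L]) {
    np <- count_pos(T)
    pos <- sample.int(np, 1L)
    T <- insert_at(T, items[[i]], pos)$new
  }
  T
}

#' Count the binary resolutions of a multifurcating tree
#'
#' @param tree rooted [ape::phylo].
#' @return the number of fully binary trees obtainable by resolving every
#'   polytomy, `prod((2 d - 3)!!)` over nodes with `d` children.
#' @export
count_resolutions <- function(tree) {
  tab <- tabulate(tree$edge[, 1L])
  prod(vapply(tab[tab > 0L], function(d) dfact(2 * d - 3), 1))
}

resolve_nested_all <- function(x) {
  if (is.character(x)) return(list(x))
  sub <- lapply(x, resolve_nested_all)   # list per child of alternatives
  grid <- expand.grid(lapply(sub, seq_along))
  out <- list()
  for (g in seq_len(nrow(grid))) {
    units <- lapply(seq_along(sub), function(i) sub[[i]][[grid[g, i]]])
    if (length(units) == 1L) { out <- c(out, units); next }
    out <- c(out, binary_shapes(units))
  }
  # strip the join tag so enclosing levels treat these subtrees as atomic
  lapply(out, unclass)
}

resolve_nested_random <- function(x) {
  if (is.character(x)) return(x)
  units <- lapply(x, resolve_nested_random)
  if (length(units) == 1L) return(units[[1L]])
  unclass(random_shape(units))
}

#' All (or sampled) binary resolutions of a tree
#'
#' @param tree rooted [ape::phylo].
#' @param cap enumerate exhaustively when [count_resolutions()] is at most
#'   this; otherwise draw `n_samples` uniform resolutions (seeded by the
#'   caller's RNG state).
#' @param n_samples number of sampled resolutions beyond the cap.
#' @return list with `trees` (list of binary [ape::phylo]) and `sampled`
#'   (logical).
#' @export
binary_resolutions <- function(tree, cap = 1000L, n_samples = 100L) {
  nres <- count_resolutions(tree)
  nested <- as_nested(tree)
  if (nres <= cap) {
    shapes <- resolve_nested_all(nested)
    trees <- lapply(shapes, function(s)
      parse_newick(paste0(nested_to_newick(s), ";")))
    return(list(trees = trees, sampled = FALSE))
  }
  trees <- lapply(seq_len(n_samples), function(i)
    parse_newick(paste0(nested_to_newick(resolve_nested_random(nested)), ";")))
  list(trees = trees, sampled = TRUE)
}

# one-off metric evaluation (reference path, used in tests)
metric_point <- function(tree, la) {
  make_metric_fn(tree)(la)
}

# precompile the traversal of one binary resolution so that the
# resolution x age-endpoint sweep costs microseconds per point
make_metric_fn <- function(bt) {
  po <- postorder_edges(bt)
  edge <- bt$edge
  ntip <- length(bt$tip.label)
  nnode <- ntip + bt$Nnode
  tips <- bt$tip.label
  function(la) {
    age <- numeric(nnode)
    age[seq_len(ntip)] <- la[tips]
    for (r in po) {
      p <- edge[r, 1L]
      if (age[p] < age[edge[r, 2L]]) age[p] <- age[edge[r, 2L]]
    }
    m <- sum(age[edge[, 1L]] - age[edge[, 2L]])
    ta <- age[seq_len(ntip)]
    amax <- max(ta)
    gmin <- amax - min(ta)
    gmax <- sum(amax - ta)
    g <- if (gmax > gmin) (gmax - m) / (gmax - gmin) else NA_real_
    s <- if (m > 0) gmin / m else NA_real_
    c(mig = m, g_min = gmin, g_max = gmax, ger = g, msm_star = s)
  }
}

#' Stratigraphic congruence metrics under uncertainty
#'
#' Computes MIG, the extremal gaps, GER, and MSM* for a topology whose
#' polytomies and first-appearance ages are uncertain, reporting the full
#' range each metric can take: every binary resolution of every polytomy
#' (exhaustive up to `max_resolutions`, otherwise uniform seeded sampling,
#' flagged) crossed with the endpoints of every taxon's age interval
#' (exhaustive when at most `max_uncertain_exhaustive` taxa have
#' non-degenerate intervals, otherwise seeded coordinate search from
#' random starts, flagged).
#'
#' @param tree rooted [ape::phylo], polytomies allowed.
#' @param ages an `age_table` covering the tips.
#' @param max_resolutions exhaustive-resolution cap.
#' @param n_resolution_samples resolutions drawn beyond the cap.
#' @param max_uncertain_exhaustive endpoint-enumeration cap (number of
#'   uncertain taxa).
#' @param n_restarts coordinate-search restarts per metric bound.
#' @param seed integer seed for any sampling.
#' @return object of class `strat_metrics`: data frame `table` with one
#'   row per metric (`lo`, `hi`), plus `n_resolutions`, `sampled` flags.
#' @export
strat_metrics <- function(tree, ages, max_resolutions = 1000L,
                          n_resolution_samples = 100L,
                          max_uncertain_exhaustive = 12L,
                          n_restarts = 3L, seed = 1L) {
  stopifnot(inherits(ages, "age_table"))
  validate_taxa(ages, tree$tip.label)
  old <- ages_vector(ages, tree$tip.label, "oldest")
  yng <- ages_vector(ages, tree$tip.label, "youngest")
  unc <- which(old - yng > 1e-9)
  with_seed(seed, {
    res <- binary_resolutions(tree, cap = max_resolutions,
                              n_samples = n_resolution_samples)
    metrics <- c("mig", "g_min", "g_max", "ger", "msm_star")
    lo <- stats::setNames(rep(Inf, 5L), metrics)
    hi <- stats::setNames(rep(-Inf, 5L), metrics)
    upd <- function(vals) {
      ok <- !is.na(vals)
      lo[ok] <<- pmin(lo[ok], vals[ok])
      hi[ok] <<- pmax(hi[ok], vals[ok])
    }
    exhaustive_ages <- length(unc) <= max_uncertain_exhaustive
    combos <- if (exhaustive_ages && length(unc)) {
      as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(unc))))
    } else matrix(FALSE, 1L, 0L)
    for (bt in res$trees) {
      fn <- make_metric_fn(bt)
      if (exhaustive_ages) {
        for (g in seq_len(nrow(combos))) {
          la <- old
          if (length(unc)) la[unc[combos[g, ]]] <- yng[unc[combos[g, ]]]
          upd(fn(la))
        }
      } else {
        for (mi in seq_along(metrics)) {
          for (want_max in c(FALSE, TRUE)) {
            for (rs in seq_len(n_restarts)) {
              use_y <- stats::runif(length(unc)) < 0.5
              val <- coord_search(fn, old, yng, unc, use_y, metrics[mi],
                                  want_max)
              v <- rep(NA_real_, 5L); names(v) <- metrics
              v[metrics[mi]] <- val
              upd(v)
            }
          }
        }
      }
    }
    lo[!is.finite(lo)] <- NA_real_
    hi[!is.finite(hi)] <- NA_real_
    structure(list(
      table = data.frame(metric = metrics, lo = unname(lo), hi = unname(hi)),
      n_resolutions = length(res$trees),
      resolutions_sampled = res$sampled,
      ages_exhaustive = exhaustive_ages,
      n_uncertain = length(unc)
    ), class = "strat_metrics")
  })
}

coord_search <- function(fn, old, yng, unc, use_y, metric, want_max,
                         max_pass = 20L) {
  eval_assign <- function(use_y) {
    la <- old
    la[unc[use_y]] <- yng[unc[use_y]]
    fn(la)[[metric]]
  }
  cur <- eval_assign(use_y)
  better <- function(a, b) {
    if (is.na(a)) return(FALSE)
    if (is.na(b)) return(TRUE)
    if (want_max) a > b + 1e-12 else a < b - 1e-12
  }
  for (pass in seq_len(max_pass)) {
    changed <- FALSE
    for (i in seq_along(unc)) {
      alt <- use_y; alt[i] <- !alt[i]
      v <- eval_assign(alt)
      if (better(v, cur)) { use_y <- alt; cur <- v; changed <- TRUE }
    }
    if (!changed) break
  }
  cur
}

#' @export
print.strat_metrics <- function(x, ...) {
  cat("Stratigraphic congruence metrics",
      if (x$resolutions_sampled || !x$ages_exhaustive)
        "(sampling-based bounds)" else "(exhaustive)", "\n")
  cat("  resolutions considered:", x$n_resolutions,
      " uncertain-age taxa:", x$n_uncertain, "\n")
  tab <- x$table
  tab$lo <- round(tab$lo, 3L); tab$hi <- round(tab$hi, 3L)
  print.data.frame(tab, row.names = FALSE)
  invisible(x)
}
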