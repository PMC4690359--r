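#' Search configuration
#'
#' Bundles the knobs of the heuristic parsimony search.  Two named presets
#' ship with the package: `"desk"` (50 random-addition replicates, up to
#' 100 trees held per replicate, 500 overall) for interactive work and
#' tests, and `"paper"` (10,000 replicates, 10,000 trees per replicate)
#' matching the full published protocol.
#'
#' @param replicates number of random-addition + branch-swapping replicates.
#' @param max_trees maximum equal-length trees saved within one replicate.
#' @param hold maximum trees retained overall.
#' @param seed integer seed; every stochastic choice (addition orders,
#'   tie-breaks) derives from it, so equal configs give identical results.
#' @param collapse collapse branches of minimum length zero in the
#'   reported trees ([collapse_min_zero()]).
#' @param constraints list of [constraint()] objects.
#' @param outgroup taxon used to root reported trees; defaults to the
#'   first matrix taxon (the most distant outgroup by convention).
#' @param preset `"desk"` or `"paper"`; overrides `replicates`/`max_trees`/
#'   `hold`.
#' @return object of class `search_config`.
#' @export
search_config <- function(replicates = 50L, max_trees = 100L, hold = 500L,
                          seed = 1L, collapse = TRUE, constraints = list(),
                          outgroup = NULL, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    if (preset == "desk") { replicates <- 50L; max_trees <- 100L; hold <- 500L }
    if (preset == "paper") { replicates <- 10000L; max_trees <- 10000L; hold <- 10000L }
  }
  stopifnot(replicates >= 1L, max_trees >= 1L, hold >= 1L)
  structure(list(replicates = as.integer(replicates),
                 max_trees = as.integer(max_trees),
                 hold = as.integer(hold),
                 seed = as.integer(seed),
                 collapse = isTRUE(collapse),
                 constraints = constraints,
                 outgroup = outgroup),
            class = "search_config")
}

#' Topological constraint
#'
#' @param mode `"enforce"` (the taxa must form a clade) or `"forbid"`
#'   (they must not).
#' @param taxa character vector of at least two taxon labels, fewer than
#'   the whole taxon set; must not include the rooting outgroup.
#' @return object of class `constraint`.
#' @export
constraint <- function(mode = c("enforce", "forbid"), taxa) {
  mode <- match.arg(mode)
  stopifnot(length(taxa) >= 2L)
  structure(list(mode = mode, taxa = as.character(taxa)), class = "constraint")
}

resolve_constraints <- function(constraints, taxa, outgroup) {
  out <- lapply(constraints, function(cn) {
    stopifnot(inherits(cn, "constraint"))
    idx <- match(cn$taxa, taxa)
    if (anyNA(idx))
      stop("constraint names unknown taxa: ",
           paste(cn$taxa[is.na(idx)], collapse = ", "))
    if (length(idx) >= length(taxa))
      stop("constraint clade must be a proper subset of the taxa")
    if (match(outgroup, taxa) %in% idx)
      stop("constraint clade may not contain the outgroup ", outgroup)
    list(mode = cn$mode, tips = sort(idx))
  })
  # pairwise compatibility of enforced clades; forbid vs enforce clash
  enf <- Filter(function(e) e$mode == "enforce", out)
  if (length(enf) > 1L) {
    for (i in seq_along(enf)) for (j in seq_len(i - 1L)) {
      a <- enf[[i]]$tips; b <- enf[[j]]$tips
      ov <- intersect(a, b)
      if (length(ov) && !all(a %in% b) && !all(b %in% a))
        stop("unsatisfiable constraints: enforced clades overlap without nesting")
    }
  }
  for (f in Filter(function(e) e$mode == "forbid", out)) {
    for (e in enf) if (identical(f$tips, e$tips))
      stop("unsatisfiable constraints: the same clade is enforced and forbidden")
  }
  out
}

satisfies_constraints <- function(E, ntip, rcons, og, placed = NULL) {
  for (cn in rcons) {
    tips <- cn$tips
    if (!is.null(placed)) {
      tips <- intersect(tips, placed)
      if (length(tips) < 2L) next
      if (cn$mode == "forbid") next    # forbids are checked on full trees only
    }
    present <- etree_has_clade(E, ntip, tips, og)
    if (cn$mode == "enforce" && !present) return(FALSE)
    if (cn$mode == "forbid" && present && length(tips) == length(cn$tips))
      return(FALSE)
  }
  TRUE
}

#' Random stepwise-addition starting tree
#'
#' Builds a binary tree by adding taxa in random order, each at the
#' placement minimising total parsimony length at that step; ties are
#' broken uniformly at random.  The addition order and tie-breaks are
#' drawn from R's RNG, so seed the stream (or use [heuristic_search()],
#' which does) for reproducibility.
#'
#' @param x a [morph_matrix()] with at least 3 taxa.
#' @param weights optional per-character multiplicities.
#' @param outgroup taxon label used to root the returned tree.
#' @return a rooted binary [ape::phylo].
#' @export
random_addition_tree <- function(x, weights = NULL, outgroup = x$taxa[1L]) {
  tc <- tipcost_array(x)
  nc <- n_char(x)
  og <- match(outgroup, x$taxa)
  E <- addition_etree(x, tc, nc, weights, rcons = list(), og = og)
  etree_to_phylo(E, n_taxa(x), x$taxa, og = og)
}

addition_etree <- function(x, tc, nc, weights, rcons, og) {
  ntip <- n_taxa(x)
  stopifnot(ntip >= 3L)
  ord <- sample.int(ntip)
  E <- etree_init(ord, ntip + 1L)
  next_id <- ntip + 2L
  placed <- ord[1:3]
  for (i in seq_len(ntip)[-(1:3)]) {
    t <- ord[i]
    placed_new <- c(placed, t)
    cand <- vector("list", nrow(E))
    lens <- rep(Inf, nrow(E))
    for (r in seq_len(nrow(E))) {
      Enew <- etree_insert(E, r, next_id, t)
      if (length(rcons) &&
          !satisfies_constraints(Enew, ntip, rcons, og, placed = placed_new))
        next
      cand[[r]] <- Enew
      lens[r] <- score_edges(Enew, ntip, tc, nc, weights)$total
    }
    if (!any(is.finite(lens)))
      stop("constraints leave no feasible insertion for taxon ", x$taxa[t])
    best <- which(lens == min(lens))
    pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
    E <- cand[[pick]]
    next_id <- next_id + 1L
    placed <- placed_new
  }
  E
}

# Hill-climb through the TBR neighbourhood.  Strictly shorter neighbours
# are always accepted (restarting the queue); equal-length distinct trees
# are collected up to `max_trees`.  Terminates when every saved tree has
# had its full neighbourhood examined.
tbr_climb <- function(E0, ntip, tc, nc, weights, max_trees = 100L,
                      rcons = list(), og = 1L) {
  best <- score_edges(E0, ntip, tc, nc, weights)$total
  pool <- list(E0)
  keys <- etree_fingerprint(E0, ntip)
  swapped <- FALSE
  repeat {
    todo <- which(!swapped)
    if (!length(todo)) break
    i <- todo[1L]
    found_shorter <- FALSE
    visit <- function(Enew) {
      if (found_shorter) return(invisible(NULL))
      s <- score_edges(Enew, ntip, tc, nc, weights)$total
      if (s > best - 0.5 && s < best + 0.5) {      # equal length
        if (length(pool) < max_trees) {
          k <- etree_fingerprint(Enew, ntip)
          if (!k %in% keys) {
            if (!length(rcons) ||
                satisfies_constraints(Enew, ntip, rcons, og)) {
              pool[[length(pool) + 1L]] <<- Enew
              keys <<- c(keys, k)
              swapped <<- c(swapped, FALSE)
            }
          }
        }
      } else if (s < best) {
        if (!length(rcons) || satisfies_constraints(Enew, ntip, rcons, og)) {
          best <<- s
          pool <<- list(Enew)
          keys <<- etree_fingerprint(Enew, ntip)
          swapped <<- FALSE
          found_shorter <<- TRUE
        }
      }
      invisible(NULL)
    }
    tbr_apply(pool[[i]], ntip, visit)
    if (!found_shorter) swapped[i] <- TRUE
  }
  list(best = best, trees = pool)
}

finish_search <- function(x, pool, best, per_rep, config, og) {
  ntip <- n_taxa(x)
  binary <- lapply(pool, etree_to_phylo, ntip = ntip, labels = x$taxa, og = og)
  mpts <- binary
  if (config$collapse) mpts <- lapply(mpts, collapse_min_zero, x = x)
  keys <- vapply(mpts, function(tr)
    paste(sort(vapply(tree_clades(tr), clade_key, "")), collapse = ";"), "")
  keep <- !duplicated(keys)
  structure(list(best_length = best,
                 mpts = mpts[keep],
                 mpts_binary = binary[keep],
                 per_replicate = per_rep,
                 seed = config$seed,
                 config = config),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Parsimony search result\n")
  cat("  best length:", x$best_length, "\n")
  cat("  most parsimonious trees (collapsed, distinct):", length(x$mpts), "\n")
  cat("  replicates:", length(x$per_replicate),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Heuristic maximum-parsimony search
#'
#' Runs `replicates` rounds of random stepwise addition followed by
#' tree-bisection-reconnection (TBR) branch swapping, pools the trees,
#' filters to the overall best length, collapses branches of minimum
#' length zero, and removes duplicate topologies.  Fully reproducible
#' from `config$seed`.
#'
#' @param x a [morph_matrix()].
#' @param config a [search_config()].
#' @param weights optional per-character multiplicities (bootstrap use).
#' @return object of class `search_result`: `best_length`, `mpts`
#'   (collapsed distinct trees, rooted on the outgroup), `mpts_binary`,
#'   `per_replicate` best lengths, `seed`, `config`.
#' @export
heuristic_search <- function(x, config = search_config(), weights = NULL) {
  og_label <- config$outgroup %||% x$taxa[1L]
  og <- match(og_label, x$taxa)
  if (is.na(og)) stop("outgroup ", og_label, " not in matrix")
  rcons <- resolve_constraints(config$constraints, x$taxa, og_label)
  tc <- tipcost_array(x)
  nc <- n_char(x)
  ntip <- n_taxa(x)
  with_seed(config$seed, {
    best <- Inf
    pool <- list()
    keys <- character(0L)
    per_rep <- numeric(config$replicates)
    for (rep_i in seq_len(config$replicates)) {
      E0 <- addition_etree(x, tc, nc, weights, rcons, og)
      if (length(rcons) && !satisfies_constraints(E0, ntip, rcons, og))
        E0 <- escape_forbidden(E0, ntip, tc, nc, weights, rcons, og)
      cl <- tbr_climb(E0, ntip, tc, nc, weights, config$max_trees, rcons, og)
      per_rep[rep_i] <- cl$best
      if (cl$best < best - 0.5) {
        best <- cl$best; pool <- list(); keys <- character(0L)
      }
      if (cl$best < best + 0.5) {
        for (E in cl$trees) {
          k <- etree_fingerprint(E, ntip)
          if (!k %in% keys && length(pool) < config$hold) {
            pool[[length(pool) + 1L]] <- E
            keys <- c(keys, k)
          }
        }
      }
    }
    finish_search(x, pool, best, per_rep, config, og)
  })
}

# start tree violates a forbid constraint: move to its best satisfying
# TBR neighbour (repeat if necessary)
escape_forbidden <- function(E, ntip, tc, nc, weights, rcons, og,
                             max_iter = 5L) {
  for (iter in seq_len(max_iter)) {
    if (satisfies_constraints(E, ntip, rcons, og)) return(E)
    bestE <- NULL; bestlen <- Inf
    tbr_apply(E, ntip, function(Enew) {
      if (!satisfies_constraints(Enew, ntip, rcons, og)) return(invisible(NULL))
      s <- score_edges(Enew, ntip, tc, nc, weights)$total
      if (s < bestlen) { bestlen <<- s; bestE <<- Enew }
      invisible(NULL)
    })
    if (is.null(bestE))
      stop("could not satisfy constraints from the starting tree")
    E <- bestE
  }
  if (!satisfies_constraints(E, ntip, rcons, og))
    stop("could not satisfy constraints from the starting tree")
  E
}

#' Constrained heuristic search
#'
#' [heuristic_search()] restricted to trees satisfying every constraint in
#' `config$constraints` -- enforced clades must be present, forbidden
#' clades absent.  Used for alternative-placement experiments (how many
#' extra steps a rival hypothesis costs) and by [bremer_supports()].
#'
#' @inheritParams heuristic_search
#' @return a `search_result`.
#' @export
constrained_search <- function(x, config) {
  if (!length(config$constraints))
    stop("constrained_search called without constraints; use heuristic_search")
  heuristic_search(x, config)
}

#' Bremer (decay) supports of consensus clades
#'
#' For each clade of the strict consensus of `result`, the Bremer support
#' is the best length achievable by a tree lacking the clade minus the
#' best length overall, found by TBR searches started from the
#' most-parsimonious trees pushed off the clade.
#'
#' @param x a [morph_matrix()].
#' @param result a `search_result` from [heuristic_search()].
#' @param config optional [search_config()] governing the forbidden
#'   searches (defaults to the config in `result`).
#' @return data frame with columns `clade` (list of tip labels) and
#'   `bremer`.
#' @export
bremer_supports <- function(x, result, config = result$config) {
  cons <- strict_consensus(result$mpts)
  clades <- tree_clades(cons)
  og_label <- config$outgroup %||% x$taxa[1L]
  og <- match(og_label, x$taxa)
  tc <- tipcost_array(x)
  nc <- n_char(x)
  ntip <- n_taxa(x)
  bremer <- with_seed(child_seed(config$seed, 777L), vapply(clades, function(cl) {
    # clade absent from some saved MPT -> decay 0 by definition
    if (!all(vapply(result$mpts, has_clade, TRUE, taxa = cl))) return(0)
    rcons <- resolve_constraints(list(constraint("forbid", cl)), x$taxa, og_label)
    best <- Inf
    for (tr in result$mpts_binary) {
      E <- phylo_to_etree(tr, x$taxa)
      E <- escape_forbidden(E, ntip, tc, nc, NULL, rcons, og)
      cl2 <- tbr_climb(E, ntip, tc, nc, NULL,
                       max_trees = min(config$max_trees, 20L),
                       rcons = rcons, og = og)
      best <- min(best, cl2$best)
    }
    best - result$best_length
  }, 1))
  data.frame(clade = I(clades), bremer = bremer)
}

#' Bootstrap clade supports
#'
#' Standard nonparametric bootstrap: characters are resampled with
#' replacement to the original count, a reduced heuristic search is run on
#' each pseudoreplicate, and each clade's support is the fraction of
#' pseudoreplicate strict-consensus trees containing it.
#'
#' @param x a [morph_matrix()].
#' @param config a [search_config()]; its seed drives the resampling.
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates.
#' @param inner_replicates random-addition replicates per pseudoreplicate.
#' @return data frame with columns `clade` (list of tip labels) and
#'   `freq` in `[0, 1]`, sorted by decreasing support.
#' @export
bootstrap_supports <- function(x, config = search_config(),
                               n_pseudoreplicates = 100L,
                               inner_replicates = 5L) {
  nc <- n_char(x)
  counts <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (b in seq_len(n_pseudoreplicates)) {
    sd <- child_seed(config$seed, b)
    w <- with_seed(sd, tabulate(sample.int(nc, nc, replace = TRUE), nc))
    cfg <- search_config(replicates = inner_replicates,
                         max_trees = min(config$max_trees, 20L),
                         hold = min(config$hold, 50L),
                         seed = child_seed(sd, 1L),
                         collapse = FALSE,
                         constraints = config$constraints,
                         outgroup = config$outgroup)
    res <- heuristic_search(x, cfg, weights = as.numeric(w))
    cons <- strict_consensus(res$mpts)
    for (cl in tree_clades(cons)) {
      k <- clade_key(cl)
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      store[[k]] <- cl
    }
  }
  keys <- ls(counts)
  out <- data.frame(
    clade = I(lapply(keys, function(k) store[[k]])),
    freq = vapply(keys, function(k) counts[[k]], 1L) / n_pseudoreplicates,
    row.names = NULL
  )
  out[order(-out$freq), , drop = FALSE]
}

#' Exhaustive parsimony search
#'
#' Scores every unrooted binary topology (guarded to 9 or fewer taxa) and
#' returns all optimal trees; the reference oracle for the heuristic
#' machinery and for exact Bremer values on small matrices.
#'
#' @param x a [morph_matrix()] with at most 9 taxa.
#' @param constraints optional list of [constraint()] objects; only
#'   satisfying topologies compete.
#' @param outgroup rooting taxon for the returned trees.
#' @param collapse collapse minimum-length-zero branches in the output.
#' @return a `search_result`.
#' @export
exhaustive_search <- function(x, constraints = list(),
                              outgroup = x$taxa[1L], collapse = TRUE) {
  ntip <- n_taxa(x)
  if (ntip > 9L) stop("exhaustive search is limited to 9 taxa")
  og <- match(outgroup, x$taxa)
  rcons <- resolve_constraints(constraints, x$taxa, outgroup)
  tc <- tipcost_array(x)
  nc <- n_char(x)
  best <- Inf
  pool <- list()
  all_topologies_apply(ntip, function(E) {
    if (length(rcons) && !satisfies_constraints(E, ntip, rcons, og))
      return(invisible(NULL))
    s <- score_edges(E, ntip, tc, nc, NULL)$total
    if (s < best - 0.5) { best <<- s; pool <<- list(E) }
    else if (s < best + 0.5) pool[[length(pool) + 1L]] <<- E
    invisible(NULL)
  })
  if (!is.finite(best)) stop("constraints are unsatisfiable")
  cfg <- search_config(replicates = 1L, collapse = collapse,
                       constraints = constraints, outgroup = outgroup)
  finish_search(x, pool, best, best, cfg, og)
}
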