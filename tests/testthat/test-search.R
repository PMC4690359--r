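# a perfectly hierarchical (compatible) matrix over a pectinate tree:
# character j marks the clade of the first j+1 taxa... here, nested 1s
nested_matrix <- function(ntax) {
  taxa <- paste0("T", seq_len(ntax))
  cells <- matrix(1L, ntax, ntax - 2L)
  for (j in seq_len(ntax - 2L)) cells[seq_len(j + 1L), j] <- 2L
  morph_matrix(cells[, rev(seq_len(ntax - 2L)), drop = FALSE], taxa)
}

test_that("random addition is deterministic under a seed and recovers a
           compatible hierarchy", {
  x <- nested_matrix(8L)
  t1 <- with_seed_public(5L, random_addition_tree(x))
  t2 <- with_seed_public(5L, random_addition_tree(x))
  expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = FALSE))
  # the compatible matrix has a unique perfect tree: length = n characters
  f <- fitch_length(t1, x)
  expect_equal(f$total_length, n_char(x))
  expect_equal(f$ci, 1)
})

test_that("three taxa give the unique topology", {
  x <- rand_matrix(3L, 4L)
  tr <- with_seed_public(1L, random_addition_tree(x))
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(tr$Nnode, 2L)
})

test_that("the TBR neighbourhood of a 4-taxon tree reaches all topologies", {
  E <- rbind(c(5L, 1L), c(5L, 2L), c(6L, 3L), c(6L, 4L), c(5L, 6L))
  seen <- character(0L)
  stratphylo:::tbr_apply(E, 4L, function(Enew) {
    seen <<- union(seen, stratphylo:::etree_fingerprint(Enew, 4L))
    invisible(NULL)
  })
  seen <- union(seen, stratphylo:::etree_fingerprint(E, 4L))
  expect_equal(length(seen), 3L)
})

test_that("heuristic search equals exhaustive search on small matrices", {
  set.seed(601)
  for (i in 1:6) {
    x <- rand_matrix(sample(5:7, 1L), sample(5:8, 1L), k = 3L)
    ex <- exhaustive_search(x)
    hs <- heuristic_search(x, search_config(replicates = 3L, seed = i))
    expect_equal(hs$best_length, ex$best_length)
  }
})

test_that("identical seeds give identical search results", {
  set.seed(602)
  x <- rand_matrix(7L, 10L, k = 3L)
  r1 <- heuristic_search(x, search_config(replicates = 4L, seed = 9L))
  r2 <- heuristic_search(x, search_config(replicates = 4L, seed = 9L))
  expect_equal(r1$best_length, r2$best_length)
  expect_equal(r1$per_replicate, r2$per_replicate)
  expect_equal(vapply(r1$mpts, write_newick, ""),
               vapply(r2$mpts, write_newick, ""))
})

test_that("pooling more replicates never lengthens the best tree", {
  set.seed(603)
  x <- rand_matrix(8L, 8L, k = 3L)
  r1 <- heuristic_search(x, search_config(replicates = 1L, seed = 4L))
  r5 <- heuristic_search(x, search_config(replicates = 5L, seed = 4L))
  expect_lte(r5$best_length, r1$best_length)
})

test_that("collapsing retains branches carrying unambiguous changes", {
  set.seed(604)
  for (i in 1:5) {
    x <- rand_matrix(6L, 8L, k = 2L)
    res <- heuristic_search(x, search_config(replicates = 2L, seed = i))
    for (b in seq_along(res$mpts)) {
      chg <- unambiguous_changes(res$mpts_binary[b], x)
      col <- res$mpts[[b]]
      for (r in seq_len(nrow(chg))) {
        expect_true(has_clade(col, chg$clade[[r]]))
      }
    }
  }
})

test_that("constrained searches match the filtered exhaustive optimum", {
  set.seed(605)
  for (i in 1:4) {
    x <- rand_matrix(6L, 6L, k = 3L)
    cl <- sample(x$taxa[-1L], 3L)
    for (mode in c("enforce", "forbid")) {
      cn <- list(constraint(mode, cl))
      ex <- exhaustive_search(x, constraints = cn)
      cs <- constrained_search(x, search_config(replicates = 3L, seed = i,
                                                constraints = cn))
      expect_equal(cs$best_length, ex$best_length)
      # constraining never shortens the optimum
      expect_gte(cs$best_length, exhaustive_search(x)$best_length)
    }
  }
})

test_that("enforcing a clade already in all MPTs leaves the length unchanged", {
  x <- nested_matrix(7L)
  free <- heuristic_search(x, search_config(replicates = 2L, seed = 3L))
  cl <- tree_clades(strict_consensus(free$mpts))[[1L]]
  cons <- constrained_search(x, search_config(replicates = 2L, seed = 3L,
            constraints = list(constraint("enforce", cl))))
  expect_equal(cons$best_length, free$best_length)
})

test_that("constraint validation rejects impossible requests", {
  x <- rand_matrix(6L, 5L)
  expect_error(resolve_constraints <- constrained_search(x,
    search_config(constraints = list(constraint("enforce", c("T2", "T3")),
                                     constraint("forbid", c("T2", "T3"))))),
    "enforced and forbidden")
  expect_error(constrained_search(x,
    search_config(constraints = list(constraint("enforce", c("T1", "T2"))))),
    "outgroup")
  expect_error(constrained_search(x,
    search_config(constraints = list(constraint("enforce", c("T2", "T3")),
                                     constraint("enforce", c("T3", "T4"))))),
    "overlap without nesting")
})

test_that("Bremer supports equal exhaustive decay indices", {
  set.seed(606)
  for (i in 1:3) {
    x <- rand_matrix(6L, sample(5:8, 1L), k = 3L)
    ex <- exhaustive_search(x)
    hs <- heuristic_search(x, search_config(replicates = 3L, seed = i))
    br <- bremer_supports(x, hs)
    expect_true(all(br$bremer >= 0))
    for (r in seq_len(nrow(br))) {
      forb <- exhaustive_search(x, constraints = list(
        constraint("forbid", br$clade[[r]])))
      expect_equal(br$bremer[r], forb$best_length - ex$best_length)
    }
  }
})

test_that("bootstrap gives full support to a perfectly congruent matrix", {
  base <- nested_matrix(7L)
  # replicate each clade character so that resampling essentially never
  # drops a clade's entire evidence (a singleton character would cap its
  # expected support near 1 - 1/e)
  x <- morph_matrix(base$cells[, rep(seq_len(n_char(base)), each = 8L)],
                    base$taxa)
  bs <- bootstrap_supports(x, search_config(seed = 11L),
                           n_pseudoreplicates = 20L, inner_replicates = 2L)
  true_tree <- heuristic_search(x, search_config(replicates = 1L, seed = 1L))
  for (cl in tree_clades(strict_consensus(true_tree$mpts))) {
    f <- bs$freq[vapply(bs$clade, function(b) setequal(b, cl), TRUE)]
    expect_equal(f, 1)
  }
  expect_true(all(bs$freq >= 0 & bs$freq <= 1))
  # seeded reproducibility
  bs2 <- bootstrap_supports(x, search_config(seed = 11L),
                            n_pseudoreplicates = 20L, inner_replicates = 2L)
  expect_equal(bs, bs2)
})
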