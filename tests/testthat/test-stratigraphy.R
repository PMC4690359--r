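ages_tab <- function(taxa, oldest, youngest = oldest) {
  read_age_table(df = data.frame(taxon = taxa, fad_oldest = oldest,
                                 fad_youngest = youngest))
}

test_that("calibration dates nodes by their oldest descendant", {
  tr <- parse_newick("(A,B);")
  ct <- calibrate(tr, ages_tab(c("A", "B"), c(100, 80)))
  expect_equal(ct$node_age[3L], 100)
  g <- ct$ghost[match(1:2, tr$edge[, 2L])]
  expect_equal(g, c(0, 20))
  # equal ages leave no ghosts
  ct0 <- calibrate(tr, ages_tab(c("A", "B"), c(90, 90)))
  expect_equal(mig(ct0), 0)
  expect_error(calibrate(tr, ages_tab("A", 100)), "lacks taxa: B")
})

test_that("calibration is monotone in leaf ages", {
  set.seed(701)
  tr <- ape::rtree(8L, tip.label = paste0("t", 1:8))
  a <- runif(8L, 10, 100)
  ct <- calibrate(tr, ages_tab(paste0("t", 1:8), a))
  for (i in 1:8) {
    a2 <- a; a2[i] <- a2[i] + 15
    ct2 <- calibrate(tr, ages_tab(paste0("t", 1:8), a2))
    expect_true(all(ct2$node_age >= ct$node_age - 1e-12))
  }
})

test_that("MIG equals the direct sum over branches and the age-ordered
           pectinate tree attains the lower bound", {
  # oldest-first pectinate: every gap telescopes along one path
  tr <- parse_newick("(A,(B,(C,D)));")
  ct <- calibrate(tr, ages_tab(LETTERS[1:4], c(40, 30, 20, 10)))
  expect_equal(mig(ct), 30)             # = oldest - youngest = g_min
  expect_equal(ger(ct), 1)
  expect_equal(msm_star(ct), 1)
  # direct recomputation on random trees
  set.seed(702)
  for (i in 1:10) {
    tr <- ape::rtree(7L, tip.label = paste0("t", 1:7))
    a <- round(runif(7L, 0, 120), 1)
    ct <- calibrate(tr, ages_tab(paste0("t", 1:7), a))
    expect_equal(mig(ct),
                 sum(ct$node_age[tr$edge[, 1L]] - ct$node_age[tr$edge[, 2L]]))
  }
})

test_that("extremal-gap constructions match topology enumeration", {
  set.seed(703)
  for (i in 1:25) {
    n <- sample(3:7, 1L)
    a <- round(runif(n, 0, 100), 1)
    migs <- oracle_all_migs(a)
    b <- g_bounds(a)
    expect_equal(b$g_min, min(migs))
    expect_equal(b$g_max, max(migs))
    bx <- g_bounds(a, method = "exhaustive")
    expect_equal(bx$g_min, min(migs))
    expect_equal(bx$g_max, max(migs))
  }
  expect_equal(g_bounds(c(50, 50, 50)), list(g_min = 0, g_max = 0))
})

test_that("every topology's MIG lies within the bounds", {
  set.seed(704)
  for (i in 1:10) {
    n <- sample(4:8, 1L)
    a <- round(runif(n, 0, 100), 1)
    b <- g_bounds(a)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    m <- mig(calibrate(tr, ages_tab(paste0("t", seq_len(n)), a)))
    expect_gte(m + 1e-9, b$g_min)
    expect_lte(m - 1e-9, b$g_max)
  }
})

test_that("the worst-case construction scores GER 0", {
  # oldest taxon at the innermost position: every other taxon hangs from a
  # root-age node
  tr <- parse_newick("((((A,B),C),D),E);")
  a <- c(A = 90, B = 10, C = 25, D = 40, E = 5)
  ct <- calibrate(tr, ages_tab(names(a), a))
  b <- g_bounds(a)
  expect_equal(mig(ct), b$g_max)
  expect_equal(ger(ct), 0)
})

test_that("GER and MSM* are shift- and scale-invariant; degenerate cases
           are NA", {
  set.seed(705)
  tr <- ape::rtree(6L, tip.label = paste0("t", 1:6))
  a <- runif(6L, 20, 150)
  nm <- paste0("t", 1:6)
  g0 <- ger(calibrate(tr, ages_tab(nm, a)))
  m0 <- msm_star(calibrate(tr, ages_tab(nm, a)))
  expect_equal(ger(calibrate(tr, ages_tab(nm, a + 37))), g0)
  expect_equal(ger(calibrate(tr, ages_tab(nm, a * 3.5))), g0)
  expect_equal(msm_star(calibrate(tr, ages_tab(nm, a * 3.5))), m0)
  ct_flat <- calibrate(tr, ages_tab(nm, rep(80, 6L)))
  expect_true(is.na(ger(ct_flat)))
  expect_true(is.na(msm_star(ct_flat)))
})

test_that("resolution counting and enumeration agree", {
  tri <- parse_newick("((A,B,C),D);")
  expect_equal(count_resolutions(tri), 3)
  res <- binary_resolutions(tri)
  expect_false(res$sampled)
  expect_equal(length(res$trees), 3L)
  keys <- vapply(res$trees, function(t)
    paste(sort(vapply(tree_clades(t), function(cl)
      paste(sort(cl), collapse = "+"), "")), collapse = ";"), "")
  expect_equal(length(unique(keys)), 3L)
  big <- parse_newick("((A,B,C,D,E),(F,G,H,I));")
  expect_equal(count_resolutions(big), 105 * 15)
  res2 <- binary_resolutions(big, cap = 10L, n_samples = 7L)
  expect_true(res2$sampled)
  expect_equal(length(res2$trees), 7L)
})

test_that("point metrics are degenerate intervals for binary trees with
           point ages", {
  set.seed(706)
  tr <- ape::rtree(6L, tip.label = paste0("t", 1:6))
  tab <- ages_tab(paste0("t", 1:6), round(runif(6L, 10, 90), 1))
  sm <- strat_metrics(tr, tab, seed = 1L)
  ct <- calibrate(tr, tab)
  expect_equal(sm$table$lo, sm$table$hi)
  expect_equal(sm$table$lo[sm$table$metric == "mig"], mig(ct))
  expect_equal(sm$table$lo[sm$table$metric == "ger"], ger(ct))
  expect_equal(sm$table$lo[sm$table$metric == "msm_star"], msm_star(ct))
})

test_that("a trichotomy's interval spans exactly its three resolutions", {
  tr <- parse_newick("((A,B,C),(D,E));")
  tab <- ages_tab(LETTERS[1:5], c(80, 45, 30, 55, 20))
  sm <- strat_metrics(tr, tab, seed = 2L)
  vals <- vapply(binary_resolutions(tr)$trees, function(bt)
    mig(calibrate(bt, tab)), 1)
  expect_equal(sm$table$lo[sm$table$metric == "mig"], min(vals))
  expect_equal(sm$table$hi[sm$table$metric == "mig"], max(vals))
})

test_that("widening an age interval never narrows the metric intervals and
           midpoints stay inside", {
  tr <- parse_newick("((A,B),(C,(D,E)));")
  old <- c(80, 45, 30, 55, 20)
  sm1 <- strat_metrics(tr, ages_tab(LETTERS[1:5], old, old - 4), seed = 3L)
  sm2 <- strat_metrics(tr, ages_tab(LETTERS[1:5], old + 6, old - 10), seed = 3L)
  expect_true(all(sm2$table$lo <= sm1$table$lo + 1e-9))
  expect_true(all(sm2$table$hi >= sm1$table$hi - 1e-9))
  mid <- calibrate(tr, ages_tab(LETTERS[1:5], old - 2))
  expect_gte(mig(mid), sm1$table$lo[sm1$table$metric == "mig"] - 1e-9)
  expect_lte(mig(mid), sm1$table$hi[sm1$table$metric == "mig"] + 1e-9)
})
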