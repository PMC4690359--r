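area_tab <- function(taxa, areas) {
  read_area_table(df = data.frame(taxon = taxa, area = areas))
}

test_that("branch-length schemes: unit everywhere; ghost with zeros -> 1", {
  tr <- parse_newick("(A,B);")
  u <- assign_branch_lengths(tr, "unit")
  expect_equal(u$edge.length, c(1, 1))
  tab <- read_age_table(df = data.frame(taxon = c("A", "B"),
                                        fad_oldest = c(100, 80),
                                        fad_youngest = c(100, 80)))
  g <- assign_branch_lengths(tr, "ghost", ages = tab)
  got <- g$edge.length[match(1:2, tr$edge[, 2L])]
  expect_equal(got, c(1, 20))
  expect_error(assign_branch_lengths(tr, "ghost"), "require an age table")
})

test_that("parsimony areas: monomorphic data give certainty everywhere", {
  tr <- ape::rtree(6L, tip.label = paste0("t", 1:6))
  rec <- parsimony_areas(tr, area_tab(paste0("t", 1:6),
                                      rep("South America", 6L)))
  expect_true(all(rec$values[, "South America"] == 1))
})

test_that("a South American outgroup grade fixes a South American root", {
  # two successive outgroup leaves and the basal-most ingroup taxon share
  # the area; the rest of the ingroup is elsewhere
  tr <- parse_newick("(out1,(out2,(basal,((in1,in2),(in3,in4)))));")
  tab <- area_tab(c("out1", "out2", "basal", "in1", "in2", "in3", "in4"),
                  c("South America", "South America", "South America",
                    "Asia", "Asia", "North America", "North America"))
  rec <- parsimony_areas(tr, tab)
  root <- length(tr$tip.label) + 1L
  expect_equal(unname(rec$values[root, "South America"]), 1)
})

test_that("parsimony area vectors equal uniform weights over MPR sets", {
  set.seed(801)
  for (i in 1:8) {
    taxa <- paste0("t", 1:6)
    tr <- rand_tree(taxa)
    st <- sample(0:2, 6L, TRUE)
    tab <- area_tab(taxa, CONTINENTS[st + 1L])
    rec <- parsimony_areas(tr, tab)
    # oracle via single-character matrix over the same states
    x <- morph_matrix(matrix(bitwShiftL(1L, st), ncol = 1L), taxa)
    om <- oracle_mpr(tr, x)[[1L]]
    for (v in seq_along(om)) {
      idx <- om[[v]] + 1L
      expect_equal(sum(rec$values[v, ]), 1)
      expect_equal(unname(rec$values[v, idx]),
                   rep(1 / length(idx), length(idx)))
      expect_true(all(rec$values[v, -idx] == 0))
    }
  }
})

test_that("pruning likelihood equals exhaustive summation to 1e-10", {
  set.seed(802)
  for (i in 1:6) {
    tr <- ape::rtree(5L, tip.label = paste0("t", 1:5))
    st <- stats::setNames(sample(0:3, 5L, TRUE), tr$tip.label)
    attr(st, "levels") <- CONTINENTS[1:4]
    alpha <- runif(1L, 0.05, 1.5)
    o <- oracle_mk(tr, st, alpha, 4L)
    expect_equal(mk_loglik(tr, st, alpha, k = 4L), log(o$lik),
                 tolerance = 1e-10)
  }
})

test_that("likelihood limits behave: saturation and identical-state cherries", {
  tr <- parse_newick("(A:1,B:1);")
  same <- stats::setNames(c(0L, 0L), c("A", "B"))
  diff <- stats::setNames(c(0L, 1L), c("A", "B"))
  attr(same, "levels") <- attr(diff, "levels") <- CONTINENTS
  for (alpha in c(0.01, 0.1, 1, 3)) {
    expect_gt(mk_loglik(tr, same, alpha, k = 6L),
              mk_loglik(tr, diff, alpha, k = 6L))
  }
  # alpha -> infinity: every tip becomes an independent uniform draw
  expect_equal(mk_loglik(tr, diff, 500, k = 6L), 2 * log(1 / 6),
               tolerance = 1e-6)
  flat <- parse_newick("(A:0,B:1);")
  expect_error(mk_loglik(flat, same, 0.5, k = 6L), "positive")
})

test_that("fitted rates scale inversely with branch lengths and beat
           random rates", {
  set.seed(803)
  cfg <- sim_config(n_taxa = 32L, alpha_area = 0.05, seed = 17L)
  tr <- simulate_yule_tree(cfg)
  tr$edge.length <- rep(1, nrow(tr$edge))
  st <- stratphylo:::sim_mk_states(tr, 0.08, 6L)[seq_len(32L)]
  names(st) <- tr$tip.label
  attr(st, "levels") <- CONTINENTS
  fit1 <- fit_mk(tr, st, k = 6L)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  fit2 <- fit_mk(tr2, st, k = 6L)
  expect_equal(fit2$alpha, fit1$alpha / 2, tolerance = 1e-4)
  for (a in exp(runif(10L, log(1e-4), log(5)))) {
    expect_gte(fit1$loglik + 1e-8, mk_loglik(tr, st, a, k = 6L))
  }
  mono <- stats::setNames(rep(0L, 32L), tr$tip.label)
  attr(mono, "levels") <- CONTINENTS
  expect_error(fit_mk(tr, mono, k = 6L), "unidentifiable")
})

test_that("marginal reconstructions equal exhaustive conditionals and sum
           to one", {
  set.seed(804)
  for (i in 1:5) {
    tr <- ape::rtree(5L, tip.label = paste0("t", 1:5))
    st <- stats::setNames(sample(0:5, 5L, TRUE), tr$tip.label)
    while (length(unique(st)) < 2L)
      st <- stats::setNames(sample(0:5, 5L, TRUE), tr$tip.label)
    attr(st, "levels") <- CONTINENTS
    alpha <- runif(1L, 0.05, 1)
    model <- structure(list(alpha = alpha, root_prior = rep(1 / 6, 6L)),
                       class = "mk_fit")
    rec <- marginal_areas(tr, states = st, model = model)
    o <- oracle_mk(tr, st, alpha, 6L)
    expect_equal(max(abs(rec$values - o$marginals)), 0, tolerance = 1e-10)
    expect_equal(unname(rowSums(rec$values)), rep(1, nrow(rec$values)),
                 tolerance = 1e-10)
  }
})

test_that("relabelling areas permutes reconstructions equivariantly and
           child order is irrelevant", {
  set.seed(805)
  tr <- ape::rtree(6L, tip.label = paste0("t", 1:6))
  st <- stats::setNames(c(0L, 1L, 2L, 0L, 1L, 2L), tr$tip.label)
  attr(st, "levels") <- CONTINENTS
  model <- structure(list(alpha = 0.3, root_prior = rep(1 / 6, 6L)),
                     class = "mk_fit")
  rec <- marginal_areas(tr, states = st, model = model)
  perm <- c(3L, 0L, 5L, 1L, 2L, 4L)   # state i -> perm[i+1]
  st2 <- st
  st2[] <- perm[st + 1L]
  attr(st2, "levels") <- CONTINENTS
  rec2 <- marginal_areas(tr, states = st2, model = model)
  expect_equal(unname(rec2$values[, perm + 1L]), unname(rec$values),
               tolerance = 1e-12)
  tr_rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  rec3 <- marginal_areas(tr_rot, states = st, model = model)
  root <- 7L
  expect_equal(rec3$values[root, ], rec$values[root, ], tolerance = 1e-12)
})

test_that("simulated histories are reconstructed above chance at moderate
           rates", {
  set.seed(806)
  acc <- replicate(25L, {
    cfg <- sim_config(n_taxa = 16L, alpha_area = 0.05, seed = sample.int(1e6, 1L))
    tr <- simulate_yule_tree(cfg)
    depth <- max(stratphylo:::node_ages_from_lengths(tr))
    alpha <- 0.3 / depth
    truth <- stratphylo:::sim_mk_states(tr, alpha, 6L)
    st <- truth[1:16]
    names(st) <- tr$tip.label
    attr(st, "levels") <- CONTINENTS
    if (length(unique(st)) < 2L) return(NA_real_)
    model <- structure(list(alpha = alpha, root_prior = rep(1 / 6, 6L)),
                       class = "mk_fit")
    rec <- marginal_areas(tr, states = st, model = model)
    inner <- 17:31
    mean(apply(rec$values[inner, ], 1L, which.max) - 1L == truth[inner])
  })
  expect_gt(mean(acc, na.rm = TRUE), 0.5)
})
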