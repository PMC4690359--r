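test_that("textbook cases score correctly", {
  m <- parse_morph_matrix(text = c("xread", "3 4", "A 000", "B 001",
                                   "C 110", "D 11?", ";"))
  tr <- parse_newick("((A,B),(C,D));")
  f <- fitch_length(tr, m)
  # char 1: single origin of 1 in (C,D); char 2: same; char 3: autapomorphy
  expect_equal(f$per_char_length, c(1, 1, 1))
  expect_equal(f$total_length, 3)
  # constant character adds nothing
  m2 <- parse_morph_matrix(text = c("xread", "1 4", "A 0", "B 0", "C 0",
                                    "D 0", ";"))
  expect_equal(fitch_length(tr, m2)$total_length, 0)
})

test_that("lengths match exhaustive labelling enumeration on random cases", {
  set.seed(501)
  for (i in 1:25) {
    ntax <- sample(4:6, 1L)
    x <- rand_matrix(ntax, sample(3:6, 1L), k = 3L)
    tr <- rand_tree(x$taxa)
    o <- oracle_fitch(tr, x)
    f <- fitch_length(tr, x)
    expect_equal(f$total_length, o$total)
    expect_equal(f$per_char_length, o$per_char)
  }
})

test_that("length is invariant to taxon order and rerooting", {
  set.seed(502)
  x <- rand_matrix(7L, 10L, k = 3L)
  tr <- rand_tree(x$taxa)
  base <- fitch_length(tr, x)$total_length
  for (i in 1:5) {
    tr2 <- ape::root(ape::unroot(tr), outgroup = sample(x$taxa, 1L),
                     resolve.root = TRUE)
    expect_equal(fitch_length(tr2, x)$total_length, base)
  }
})

test_that("resolving a polytomy never lengthens the tree", {
  set.seed(503)
  for (i in 1:5) {
    x <- rand_matrix(7L, 8L, k = 3L)
    poly <- parse_newick(paste0("(", paste(x$taxa[1:4], collapse = ","),
                                ",(", paste(x$taxa[5:7], collapse = ","),
                                "));"))
    lp <- fitch_length(poly, x)$total_length
    lens <- vapply(binary_resolutions(poly, cap = 200L)$trees,
                   function(bt) fitch_length(bt, x)$total_length, 1)
    # the hard polytomy forces shared ancestral states, so every binary
    # resolution scores no longer than it
    expect_true(all(lens <= lp + 1e-9))
  }
})

test_that("two-state binary-tree scores agree with phangorn's Fitch", {
  skip_if_not_installed("phangorn")
  set.seed(504)
  for (i in 1:5) {
    ntax <- 8L
    taxa <- paste0("T", 1:ntax)
    states <- matrix(sample(0:1, ntax * 12L, TRUE), ntax)
    x <- morph_matrix(matrix(bitwShiftL(1L, states), ntax), taxa)
    tr <- rand_tree(taxa)
    pd <- phangorn::phyDat(matrix(as.character(states), ntax,
                                  dimnames = list(taxa, NULL)),
                           type = "USER", levels = c("0", "1"))
    expect_equal(fitch_length(tr, x)$total_length,
                 phangorn::parsimony(tr, pd))
  }
})

test_that("per-character bounds equal star-tree scoring", {
  set.seed(505)
  for (i in 1:10) {
    x <- rand_matrix(sample(5:9, 1L), 8L, k = 3L)
    star <- parse_newick(paste0("(", paste(x$taxa, collapse = ","), ");"))
    b <- char_bounds(x)
    expect_equal(fitch_length(star, x)$per_char_length, as.numeric(b$max_steps))
    # the minimum bound is attained over trees: check against the best
    # length seen across random topologies (never below, often equal)
    lens <- sapply(1:5, function(k) fitch_length(rand_tree(x$taxa), x)$per_char_length)
    expect_true(all(apply(lens, 1L, min) >= b$min_steps - 1e-9))
  }
  # worked example: 5 taxa coded 0,0,0,1,1
  m <- morph_matrix(matrix(bitwShiftL(1L, c(0L, 0L, 0L, 1L, 1L))),
                    paste0("t", 1:5))
  b <- char_bounds(m)
  expect_equal(b$min_steps, 1L)
  expect_equal(b$max_steps, 2L)
})

test_that("ensemble indices obey their identities", {
  set.seed(506)
  for (i in 1:8) {
    x <- rand_matrix(7L, 12L, k = 3L)
    tr <- rand_tree(x$taxa)
    f <- fitch_length(tr, x)
    expect_true(f$ci >= 0 && f$ci <= 1)
    expect_true(f$ri >= 0 && f$ri <= 1)
    expect_equal(f$rci, f$ci * f$ri)
    expect_equal(f$total_length, sum(f$per_char_length))
    expect_true(all(f$per_char_length >= f$min_steps - 1e-9))
    expect_true(all(f$per_char_length <= f$max_steps + 1e-9))
  }
})

test_that("MPR state sets equal brute-force enumeration", {
  set.seed(507)
  for (i in 1:15) {
    ntax <- sample(4:6, 1L)
    x <- rand_matrix(ntax, sample(3:5, 1L), k = 3L)
    tr <- rand_tree(x$taxa)
    mp <- mpr_state_sets(tr, x)
    om <- oracle_mpr(tr, x)
    for (v in seq_along(mp$sets)) {
      for (j in seq_len(n_char(x))) {
        expect_identical(sort(mp$sets[[v]][[j]]), om[[j]][[v]])
      }
    }
  }
})

test_that("MPR trivial cases: symmetric cherry and constant characters", {
  m <- parse_morph_matrix(text = c("xread", "2 2", "A 00", "B 10", ";"))
  tr <- parse_newick("(A,B);")
  mp <- mpr_state_sets(tr, m)
  root <- 3L
  expect_equal(mp$sets[[root]][[1L]], c(0L, 1L))   # equivocal
  expect_equal(mp$sets[[root]][[2L]], 0L)          # constant
})

test_that("collapse decisions match MPR enumeration", {
  set.seed(508)
  for (i in 1:12) {
    ntax <- sample(5:6, 1L)
    x <- rand_matrix(ntax, sample(3:5, 1L), k = 2L)
    tr <- rand_tree(x$taxa)
    uni <- state_universe(x)
    cells <- x$cells[tr$tip.label, , drop = FALSE]
    dp <- stratphylo:::parsimony_dp(tr, stratphylo:::tipcost_array(x, tr$tip.label))
    zp <- stratphylo:::branch_zero_possible(tr, dp)
    for (j in seq_len(n_char(x))) {
      oa <- oracle_edge_analysis(tr, cells[, j], uni[[j]])
      expect_equal(zp[, j], oa$zero_ok)
    }
    # exactly the all-characters-zero internal branches disappear
    col <- collapse_min_zero(tr, x)
    internal <- tr$edge[, 2L] > ntax
    keep <- internal & !apply(zp, 1L, all)
    expect_equal(length(tree_clades(col)), sum(keep))
  }
})

test_that("fully uninformative matrices collapse to the star tree", {
  taxa <- paste0("T", 1:6)
  x <- morph_matrix(matrix(c(rep(1L, 5L), 2L), 6L, 3L), taxa)  # autapomorphies
  tr <- rand_tree(taxa)
  col <- collapse_min_zero(tr, x)
  expect_equal(col$Nnode, 1L)
})

test_that("unambiguous changes match enumeration over all reconstructions", {
  set.seed(509)
  for (i in 1:10) {
    ntax <- sample(4:6, 1L)
    x <- rand_matrix(ntax, sample(3:4, 1L), k = 2L)
    tr <- rand_tree(x$taxa)
    uni <- state_universe(x)
    cells <- x$cells[tr$tip.label, , drop = FALSE]
    got <- unambiguous_changes(list(tr), x)
    desc <- stratphylo:::descendant_tips(tr)
    ntips <- length(tr$tip.label)
    for (j in seq_len(n_char(x))) {
      oa <- oracle_edge_analysis(tr, cells[, j], uni[[j]])
      for (r in seq_len(nrow(tr$edge))) {
        ch <- tr$edge[r, 2L]
        if (ch <= ntips) next
        tipset <- sort(tr$tip.label[desc[[ch]]])
        hit <- got[got$character == j &
                     vapply(got$clade, function(cl)
                       identical(sort(cl), tipset), TRUE), ]
        if (length(oa$forced[[r]])) {
          expect_equal(nrow(hit), 1L)
          expect_equal(hit$state, oa$forced[[r]])
        } else {
          expect_equal(nrow(hit), 0L)
        }
      }
    }
  }
})

test_that("a cherry's symmetric difference yields no unambiguous change", {
  m <- parse_morph_matrix(text = c("xread", "1 4", "A 0", "B 0", "C 1",
                                   "D 1", ";"))
  tr <- parse_newick("((A,B),(C,D));")
  got <- unambiguous_changes(list(tr), m)
  # the 0->1 change could sit on either side of the root: ambiguous
  expect_equal(nrow(got), 0L)
  expect_error(unambiguous_changes(list(tr, parse_newick("((A,C),(B,D));")), m),
               "not equally parsimonious")
})
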