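#' Simulation configuration
#'
#' Defaults mirror the scale and texture of a large basal-ornithischian
#' matrix: 65 taxa scored for 255 unordered characters with up to four
#' states, roughly 30% missing data, occasional {0,1} polymorphisms and
#' inapplicable cells, a pure-birth tree spanning on the order of 170 myr
#' (birth rate 0.025 per lineage per myr), slow character evolution, a
#' six-area geographic character, and stage-level (about +/- 2.5 myr)
#' uncertainty on first-appearance ages.
#'
#' @param n_taxa,n_characters matrix dimensions.
#' @param n_states states per character (2--10).
#' @param alpha_char Mk rate per myr for morphological characters.
#' @param alpha_area Mk rate per myr for the geographic character.
#' @param birth_rate Yule speciation rate per lineage per myr.
#' @param missing_frac,polymorphic_frac,inapplicable_frac cell-degradation
#'   fractions (must sum to at most 1).
#' @param age_noise half-width (myr) of first-appearance age intervals.
#' @param n_areas number of geographic areas.
#' @param seed integer seed; all generator randomness derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 65L, n_characters = 255L, n_states = 4L,
                       alpha_char = 0.002, alpha_area = 0.001,
                       birth_rate = 0.025, missing_frac = 0.30,
                       polymorphic_frac = 0.01, inapplicable_frac = 0.02,
                       age_noise = 2.5, n_areas = 6L, seed = 1L) {
  stopifnot(n_taxa >= 3L, n_characters >= 1L,
            n_states >= 2L, n_states <= MAX_STATES,
            alpha_char > 0, alpha_area > 0, birth_rate > 0,
            missing_frac >= 0, polymorphic_frac >= 0, inapplicable_frac >= 0,
            missing_frac + polymorphic_frac + inapplicable_frac <= 1,
            age_noise >= 0, n_areas >= 2L, n_areas <= length(CONTINENTS))
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_taxa, "taxa,", x$n_characters,
      "characters,", x$n_states, "states, seed", x$seed, "\n")
  invisible(x)
}

# forward pure-birth simulation run until n lineages exist, plus the
# memoryless grace period to the (uncounted) next event
sim_yule <- function(n, b) {
  t_now <- 0
  active_parent <- 0L      # 0 = origin (stem above the first split, dropped)
  active_start <- 0
  ep <- integer(0L); ec <- integer(0L); el <- numeric(0L)
  next_internal <- -1L
  repeat {
    k <- length(active_parent)
    t_now <- t_now + stats::rexp(1L, k * b)
    if (k == n) break
    i <- sample.int(k, 1L)
    w <- next_internal; next_internal <- next_internal - 1L
    if (active_parent[i] != 0L) {
      ep <- c(ep, active_parent[i]); ec <- c(ec, w)
      el <- c(el, t_now - active_start[i])
    }
    active_parent <- c(active_parent[-i], w, w)
    active_start <- c(active_start[-i], t_now, t_now)
  }
  for (i in seq_len(n)) {
    ep <- c(ep, active_parent[i]); ec <- c(ec, i)
    el <- c(el, t_now - active_start[i])
  }
  kids <- split(seq_along(ep), ep)
  nw <- function(v) {
    rows <- kids[[as.character(v)]]
    parts <- vapply(rows, function(r) {
      ch <- ec[r]
      lab <- if (ch > 0L) paste0("t", ch) else nw(ch)
      paste0(lab, ":", format(el[r], digits = 12))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  parse_newick(paste0(nw(-1L), ";"))
}

#' Simulate a Yule (pure-birth) calibrated tree
#'
#' Lineages split independently at `birth_rate` per lineage per myr,
#' starting from one lineage; the process stops when `n_taxa` lineages
#' exist and appends the memoryless grace time to the next (uncounted)
#' split.  Branch lengths are in myr; all tips are contemporaneous, so tip
#' age is 0 Ma and node ages equal their depths.
#'
#' @param config a [sim_config()].
#' @return a rooted binary [ape::phylo] with `edge.length` in myr.
#' @export
simulate_yule_tree <- function(config) {
  with_seed(child_seed(config$seed, 1L),
            sim_yule(config$n_taxa, config$birth_rate))
}

# node ages (Ma) of an ultrametric-from-present tree with edge lengths
node_ages_from_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  depth <- numeric(nnode)   # distance from root
  edge <- tree$edge
  for (r in rev(postorder_edges(tree)))
    depth[edge[r, 2L]] <- depth[edge[r, 1L]] + tree$edge.length[r]
  max(depth) - depth
}

# evolve one Mk character down the tree; returns states for all nodes
sim_mk_states <- function(tree, alpha, k) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  st <- integer(nnode)
  root <- ntip + 1L
  st[root] <- sample.int(k, 1L) - 1L
  edge <- tree$edge
  for (r in rev(postorder_edges(tree))) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    P <- mk_pmat(alpha, tree$edge.length[r], k)
    st[ch] <- sample.int(k, 1L, prob = P[st[p] + 1L, ]) - 1L
  }
  st
}

#' Simulate Mk characters on a tree, with fossil-style degradation
#'
#' Each character evolves independently under the symmetric Mk model along
#' the branches.  Cells are then degraded uniformly at random: a fraction
#' set to missing (`?`), a fraction to inapplicable (`-`), and a fraction
#' replaced by the `{0,1}` polymorphism (`a`), mimicking the symbol
#' repertoire of published matrices.  The undegraded matrix and true node
#' states are returned for recovery scoring.
#'
#' @param tree rooted [ape::phylo] with branch lengths (myr).
#' @param config a [sim_config()].
#' @return list with `matrix` (degraded [morph_matrix()]), `clean_matrix`,
#'   and `true_node_states` (nodes x characters, 0-based).
#' @export
simulate_characters <- function(tree, config) {
  with_seed(child_seed(config$seed, 2L), {
    ntip <- length(tree$tip.label)
    nnode <- ntip + tree$Nnode
    k <- config$n_states
    nc <- config$n_characters
    truth <- matrix(0L, nnode, nc)
    for (j in seq_len(nc)) truth[, j] <- sim_mk_states(tree, config$alpha_char, k)
    cells <- matrix(bitwShiftL(1L, truth[seq_len(ntip), , drop = FALSE]),
                    ntip, nc)
    clean <- morph_matrix(cells, tree$tip.label)
    n_cells <- length(cells)
    n_mis <- round(config$missing_frac * n_cells)
    n_inap <- round(config$inapplicable_frac * n_cells)
    n_poly <- round(config$polymorphic_frac * n_cells)
    pick <- sample.int(n_cells, n_mis + n_inap + n_poly)
    cells[pick[seq_len(n_mis)]] <- MISSING_CELL
    if (n_inap) cells[pick[n_mis + seq_len(n_inap)]] <- INAP_CELL
    if (n_poly) cells[pick[n_mis + n_inap + seq_len(n_poly)]] <- 3L
    list(matrix = morph_matrix(cells, tree$tip.label),
         clean_matrix = clean,
         true_node_states = truth)
  })
}

#' Simulate first-appearance ages
#'
#' Each taxon's true first appearance is drawn uniformly along its
#' subtending branch (somewhere below its parent node), and the reported
#' interval is the truth plus/minus `age_noise`, truncated at 0 Ma.
#'
#' @param tree rooted [ape::phylo] with branch lengths (myr).
#' @param config a [sim_config()].
#' @return an `age_table` with the true ages in `attr(, "true_fad")`.
#' @export
simulate_fads <- function(tree, config) {
  with_seed(child_seed(config$seed, 3L), {
    ntip <- length(tree$tip.label)
    age <- node_ages_from_lengths(tree)
    edge <- tree$edge
    fad <- numeric(ntip)
    for (r in seq_len(nrow(edge))) {
      ch <- edge[r, 2L]
      if (ch > ntip) next
      par_age <- age[edge[r, 1L]]
      fad[ch] <- par_age - stats::runif(1L, 0, tree$edge.length[r])
    }
    tab <- read_age_table(df = data.frame(
      taxon = tree$tip.label,
      fad_oldest = pmax(fad + config$age_noise, 0),
      fad_youngest = pmax(fad - config$age_noise, 0)))
    attr(tab, "true_fad") <- stats::setNames(fad, tree$tip.label)
    tab
  })
}

#' Simulate the geographic character
#'
#' A single state per taxon evolved under the symmetric Mk model at
#' `alpha_area` over `n_areas` continents.
#'
#' @inheritParams simulate_fads
#' @return an `area_table`; true node areas in `attr(, "true_node_area")`.
#' @export
simulate_areas <- function(tree, config) {
  with_seed(child_seed(config$seed, 4L), {
    st <- sim_mk_states(tree, config$alpha_area, config$n_areas)
    levels <- CONTINENTS[seq_len(config$n_areas)]
    ntip <- length(tree$tip.label)
    tab <- read_area_table(df = data.frame(
      taxon = tree$tip.label,
      area = levels[st[seq_len(ntip)] + 1L]), levels = levels)
    attr(tab, "true_node_area") <- st
    tab
  })
}

#' Simulate a complete study dataset
#'
#' Generates, under one seed, everything the pipeline consumes: a Yule
#' tree in Ma, an Mk character matrix with missing/inapplicable/
#' polymorphic degradation, first-appearance age intervals, and a
#' geographic character -- together with every ground truth needed to
#' score recovery.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_output`: list with `tree`, `matrix`,
#'   `clean_matrix`, `true_node_states`, `ages`, `areas`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  tree <- simulate_yule_tree(config)
  chars <- simulate_characters(tree, config)
  ages <- simulate_fads(tree, config)
  areas <- simulate_areas(tree, config)
  structure(list(tree = tree, matrix = chars$matrix,
                 clean_matrix = chars$clean_matrix,
                 true_node_states = chars$true_node_states,
                 ages = ages, areas = areas, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat("Simulated dataset (seed ", x$config$seed, ")\n", sep = "")
  print(x$matrix)
  cat("  tree depth ", round(max(node_ages_from_lengths(x$tree)), 1),
      " myr\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the matrix (TNT), ages (CSV), areas (CSV), true tree (Newick),
#' and a JSON manifest echoing the configuration.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_morph_matrix(sim$matrix, file.path(dir, "matrix.tnt"), "tnt")
  utils::write.csv(as.data.frame(unclass(sim$ages)[c("taxon", "fad_oldest",
                                                     "fad_youngest")]),
                   file.path(dir, "ages.csv"), row.names = FALSE)
  utils::write.csv(data.frame(taxon = sim$areas$taxon, area = sim$areas$area),
                   file.path(dir, "areas.csv"), row.names = FALSE)
  write_newick(sim$tree, file.path(dir, "true_tree.nwk"))
  jsonlite::write_json(unclass(sim$config), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
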