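#' Assign branch lengths for likelihood tracing
#'
#' Two schemes are used for ancestral-area likelihood reconstruction:
#' `"unit"` sets every branch length to 1 (topology-only weighting);
#' `"ghost"` sets each branch to its implied missing fossil record in myr
#' under the minimum-age calibration with oldest first appearances, with
#' exact zeros replaced by 1 so that every branch retains positive length.
#'
#' @param tree rooted [ape::phylo].
#' @param scheme `"unit"` or `"ghost"`.
#' @param ages an `age_table`; required for `scheme = "ghost"`.
#' @return the tree with `edge.length` set.
#' @export
assign_branch_lengths <- function(tree, scheme = c("unit", "ghost"),
                                  ages = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "unit") {
    tree$edge.length <- rep(1, nrow(tree$edge))
    return(tree)
  }
  if (is.null(ages)) stop("ghost-lineage branch lengths require an age table")
  ct <- calibrate(tree, ages, which = "oldest")
  len <- ct$ghost
  len[len <= 0] <- 1
  tree$edge.length <- len
  tree
}

recon_matrix <- function(tree, values, method, levels) {
  colnames(values) <- levels
  ntip <- length(tree$tip.label)
  rownames(values) <- c(tree$tip.label,
                        paste0("node", (ntip + 1L):(ntip + tree$Nnode)))
  structure(list(tree = tree, values = values, method = method,
                 levels = levels),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, digits = 1, ...) {
  ntip <- length(x$tree$tip.label)
  cat("Ancestral-state reconstruction (", x$method, ") over ",
      length(x$levels), " areas\n", sep = "")
  inner <- x$values[-seq_len(ntip), , drop = FALSE]
  best <- colnames(inner)[apply(inner, 1L, which.max)]
  show <- utils::head(data.frame(round(100 * inner, digits),
                                 best = best, check.names = FALSE), 10L)
  print(show)
  if (nrow(inner) > 10L) cat("  ...\n")
  invisible(x)
}

#' Extract one node's support vector
#'
#' @param recon an `ancestral_recon`.
#' @param taxa tip labels; the node reported is their most recent common
#'   ancestor.
#' @param percent return percentages (default) rather than fractions.
#' @return named numeric vector over the areas.
#' @export
node_support <- function(recon, taxa, percent = TRUE) {
  node <- ape::getMRCA(recon$tree, taxa)
  v <- recon$values[node, ]
  if (percent) 100 * v else v
}

#' Parsimony ancestral areas
#'
#' Reconstructs ancestral areas on a fixed (possibly multifurcating)
#' topology under unordered parsimony: each node's support vector puts
#' uniform weight on the states in its most-parsimonious-reconstruction
#' set -- the convention behind equivocal pie-chart nodes.
#'
#' @param tree rooted [ape::phylo].
#' @param areas an `area_table` covering the tips.
#' @return an `ancestral_recon` (method `"PB"`).
#' @export
parsimony_areas <- function(tree, areas) {
  ch <- build_area_character(areas, tree$tip.label)
  levels <- attr(ch, "levels")
  k <- length(levels)
  tc <- tipcost_single(ch, tip_order = tree$tip.label, k = k)
  dp <- parsimony_dp(tree, tc)
  nnode <- length(tree$tip.label) + tree$Nnode
  vals <- matrix(0, nnode, k)
  for (v in seq_len(nnode)) {
    tot <- dp$down[[v]][, 1L] + dp$up[[v]][, 1L]
    opt <- abs(tot - dp$charlen[1L]) < 0.5
    vals[v, opt] <- 1 / sum(opt)
  }
  recon_matrix(tree, vals, "PB", levels)
}

mk_pmat <- function(alpha, t, k) {
  e <- exp(-k * alpha * t)
  off <- (1 - e) / k
  m <- matrix(off, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

# conditional (downpass) likelihoods per node with log scaling factors
mk_down <- function(tree, states, alpha, k) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  L <- matrix(0, nnode, k)
  for (t in seq_len(ntip)) L[t, states[t] + 1L] <- 1
  L[(ntip + 1L):nnode, ] <- 1
  logscale <- numeric(nnode)
  edge <- tree$edge
  len <- tree$edge.length
  for (r in postorder_edges(tree)) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    P <- mk_pmat(alpha, len[r], k)
    contrib <- as.numeric(P %*% L[ch, ])
    L[p, ] <- L[p, ] * contrib
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(L[p, ])
    if (m > 0 && (m < 1e-200 || m > 1e200)) {
      L[p, ] <- L[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  list(L = L, logscale = logscale)
}

#' Mk log-likelihood of a discrete character on a tree
#'
#' Felsenstein pruning over a rooted (possibly multifurcating) tree under
#' the symmetric k-state Markov model with transition probabilities
#' `P(i -> i, t) = 1/k + (k-1)/k exp(-k a t)` and
#' `P(i -> j, t) = 1/k (1 - exp(-k a t))`, summed against the root prior.
#'
#' @param tree rooted [ape::phylo] with strictly positive `edge.length`.
#' @param states named integer vector of 0-based tip states (e.g. from
#'   [build_area_character()]).
#' @param alpha the single rate parameter (> 0).
#' @param k number of states.
#' @param root_prior probability vector over states; default flat.
#' @return log-likelihood (numeric scalar).
#' @export
mk_loglik <- function(tree, states, alpha, k = length(attr(states, "levels")),
                      root_prior = rep(1 / k, k)) {
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("all branch lengths must be positive; see assign_branch_lengths()")
  stopifnot(length(root_prior) == k, abs(sum(root_prior) - 1) < 1e-8)
  st <- states[tree$tip.label]
  d <- mk_down(tree, st, alpha, k)
  root <- length(tree$tip.label) + 1L
  log(sum(root_prior * d$L[root, ])) + d$logscale[root]
}

#' Fit the single-rate Mk model
#'
#' Maximises [mk_loglik()] over the rate by bounded one-dimensional
#' optimisation on a log scale.  The returned object follows the usual
#' fitted-model conventions (`coef`, `logLik`, `print`).
#'
#' @inheritParams mk_loglik
#' @param interval search bracket for the rate.
#' @return object of class `mk_fit`.
#' @export
fit_mk <- function(tree, states, k = length(attr(states, "levels")),
                   root_prior = rep(1 / k, k),
                   interval = c(1e-8, 1e3)) {
  st <- states[tree$tip.label]
  if (length(unique(st)) < 2L)
    stop("all tips share one state; the rate is unidentifiable ",
         "(use parsimony_areas instead)")
  f <- function(la) -mk_loglik(tree, states, exp(la), k, root_prior)
  opt <- stats::optimize(f, interval = log(interval), tol = 1e-10)
  structure(list(alpha = exp(opt$minimum), loglik = -opt$objective,
                 k = k, root_prior = root_prior, tree = tree,
                 states = st),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Symmetric Mk model fit (", x$k, " states)\n", sep = "")
  cat(sprintf("  rate alpha = %.6g per branch-length unit\n", x$alpha))
  cat(sprintf("  log-likelihood = %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) c(alpha = object$alpha)

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$loglik, df = 1L, class = "logLik")
}

#' Marginal likelihood ancestral areas
#'
#' Per-node marginal reconstruction under the symmetric Mk model: the
#' posterior support of state `s` at a node is proportional to the tree
#' likelihood with that node fixed to `s`, computed by the standard
#' inside-outside two-pass.  Vectors are normalised to 1 per node.
#'
#' @param tree rooted [ape::phylo] with positive branch lengths.
#' @param areas an `area_table`, or `NULL` if `states` is given directly.
#' @param model an `mk_fit`, or `NULL` to fit the rate on the spot.
#' @param states optional named 0-based state vector (overrides `areas`).
#' @param method label stored on the result (e.g. `"LEB"`, `"LFR"`).
#' @return an `ancestral_recon` whose rows sum to 1.
#' @export
marginal_areas <- function(tree, areas = NULL, model = NULL, states = NULL,
                           method = "Mk") {
  if (is.null(states)) {
    if (is.null(areas)) stop("provide areas or states")
    states <- build_area_character(areas, tree$tip.label)
  }
  levels <- attr(states, "levels") %||%
    as.character(seq_len(max(states) + 1L) - 1L)
  k <- length(levels)
  if (is.null(model)) model <- fit_mk(tree, states, k = k)
  alpha <- model$alpha
  prior <- model$root_prior
  st <- states[tree$tip.label]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  d <- mk_down(tree, st, alpha, k)
  edge <- tree$edge
  len <- tree$edge.length
  # outside pass: out[v, s] = likelihood of everything outside v's subtree
  # given v in state s (unnormalised, shared scaling dropped)
  out <- matrix(0, nnode, k)
  root <- ntip + 1L
  out[root, ] <- prior
  children <- vector("list", nnode)
  rows <- vector("list", nnode)
  for (r in seq_len(nrow(edge))) {
    children[[edge[r, 1L]]] <- c(children[[edge[r, 1L]]], edge[r, 2L])
    rows[[edge[r, 2L]]] <- r
  }
  for (r in rev(postorder_edges(tree))) {   # parents before children
    p <- edge[r, 1L]; v <- edge[r, 2L]
    sib <- setdiff(children[[p]], v)
    w <- out[p, ]
    for (b in sib) {
      Pb <- mk_pmat(alpha, len[rows[[b]]], k)
      w <- w * as.numeric(Pb %*% d$L[b, ])
    }
    Pv <- mk_pmat(alpha, len[r], k)
    out[v, ] <- as.numeric(t(Pv) %*% w)
    m <- max(out[v, ])
    if (m > 0) out[v, ] <- out[v, ] / m
  }
  vals <- d$L * out
  vals <- vals / rowSums(vals)
  res <- recon_matrix(tree, vals, method, levels)
  res$model <- model
  res
}
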