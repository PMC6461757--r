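# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own traversal code: they work from
# ape's full node-distance matrix / clade extraction primitives.

# RED by explicit path averaging: for each node (root first, by depth),
# red = red(parent) + (dist(parent, node) / mean dist(parent, leaves under
# node)) * (1 - red(parent)).
red_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  D <- ape::dist.nodes(tree)
  depth <- D[root, ]
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  tips_under <- function(nd) {
    if (nd <= ntip) return(nd)
    which(abs(D[nd, seq_len(ntip)] - (depth[seq_len(ntip)] - depth[nd])) <
            1e-9)
  }
  red <- rep(NA_real_, nnode)
  red[root] <- 0
  for (nd in order(depth)) {
    if (nd == root) next
    pa <- parent[nd]
    tips <- tips_under(nd)
    if (nd <= ntip) { red[nd] <- 1; next }
    u <- mean(D[pa, tips])
    red[nd] <- red[pa] + (D[pa, nd] / u) * (1 - red[pa])
  }
  red
}

# Maximal member-only subtrees by brute enumeration over every node.
brute_subclades <- function(tree, members) {
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  tips_under <- function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else ape::extract.clade(tree, nd)$tip.label
  }
  cand <- vapply(seq_len(nnode), function(nd)
    all(tips_under(nd) %in% members), logical(1L))
  parent <- rep(NA_integer_, nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  maximal <- which(cand & (is.na(parent) | !cand[parent]))
  lapply(maximal, tips_under)
}

# Random rooted binary tree with iid exponential branch lengths.
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = TRUE)
    tr$edge.length <- rexp(nrow(tr$edge)) + 1e-6
    tr
  })
}

# Minimal stand-in for an nb_glm_fit, for exercising the BH screen alone.
fake_fit <- function(clade, variable, block_p, coef_p = block_p,
                     estimate = 1) {
  structure(list(clade = clade, variable = variable,
                 coefficients = data.frame(
                   term = c("(Intercept)", ".x"), estimate = c(0, estimate),
                   se = 1, z = 0, p = c(1, coef_p)),
                 wald = list(statistic = 0, df = 1, p = block_p),
                 converged = TRUE),
            class = "nb_glm_fit")
}

# The 11 lineage markers absent from every MAG of the study lineage, as
# listed in the CheckM refinement workflow; used with a 188-marker table.
ABSENT_MARKERS <- c("TIGR00537", "TIGR02237", "TIGR00422", "PF01287.15",
                    "TIGR03677", "PF09249.6", "PF13685.1", "TIGR00162",
                    "PF02649.9", "PF03684.8", "PF01849.13")

marker_table_188 <- function(n_genomes = 20, seed = 11) {
  ids <- c(sprintf("MK%04d", seq_len(188 - length(ABSENT_MARKERS))),
           ABSENT_MARKERS)
  simulate_marker_table(n_genomes, ids, true_completeness = 0.9,
                        true_contamination = 0.02,
                        absent_markers = ABSENT_MARKERS, seed = seed)
}
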