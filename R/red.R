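#' Relative evolutionary divergence (RED) of every node in a rooted tree
#'
#' RED places the root at 0 and every extant leaf at 1, linearly
#' interpolating internal nodes according to lineage-specific rates of
#' evolution: for a node with parent RED `p`, branch length `d` to its
#' parent, and mean path length `u` from the parent to all of the node's
#' descendant leaves,
#' \deqn{red = p + (d / u)(1 - p).}
#' Zero-length internal branches are collapsed to polytomies before the
#' computation (a zero-length internal edge carries no divergence signal and
#' would otherwise create degenerate interpolation); polytomies are handled
#' natively. Zero-length terminal branches are permitted and their leaves are
#' pinned at RED 1.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths and at least
#'   two leaves.
#' @return A `red_annotation`: data frame with one row per node (ape node
#'   numbering of the possibly collapsed tree) and columns `node`, `label`,
#'   `is_leaf`, `red`, and the audit quantities `p`, `d`, `u`. The (collapsed)
#'   tree is attached as attribute `tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1)X:1,C:2)R;")
#' compute_red(tr)
#' @export
compute_red <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted (no root is guessed)")
  if (ape::Ntip(tree) < 2L) stop("tree must have at least 2 leaves")
  if (any(tree$edge.length < 0)) stop("branch lengths must be non-negative")
  # collapse zero-length *internal* edges to polytomies
  internal <- tree$edge[, 2L] > ape::Ntip(tree)
  if (any(internal & tree$edge.length == 0))
    tree <- ape::di2multi(tree, tol = 1e-12)

  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  parent_of <- integer(nnode); parent_of[] <- NA_integer_
  edge_len <- numeric(nnode); edge_len[] <- NA_real_
  parent_of[po$edge[, 2L]] <- po$edge[, 1L]
  edge_len[po$edge[, 2L]] <- po$edge.length

  # postorder: per-node mean distance to its descendant leaves, and leaf count
  nleaf <- integer(nnode); mdist <- numeric(nnode)
  nleaf[seq_len(ntip)] <- 1L
  for (k in seq_len(nrow(po$edge))) {
    ch <- po$edge[k, 2L]; pa <- po$edge[k, 1L]
    # postorder: ch's subtree is complete, so its sum can become a mean now
    if (ch > ntip) mdist[ch] <- mdist[ch] / nleaf[ch]
    nleaf[pa] <- nleaf[pa] + nleaf[ch]
    mdist[pa] <- mdist[pa] + nleaf[ch] * (po$edge.length[k] + mdist[ch])
  }
  mdist[root] <- mdist[root] / nleaf[root]

  # preorder: interpolate RED down from the root
  red <- numeric(nnode); red[] <- NA_real_
  u <- numeric(nnode); u[] <- NA_real_
  red[root] <- 0
  for (k in rev(seq_len(nrow(po$edge)))) {  # reverse postorder = preorder
    ch <- po$edge[k, 2L]; pa <- po$edge[k, 1L]
    d <- po$edge.length[k]
    uu <- d + mdist[ch]
    u[ch] <- uu
    if (ch <= ntip) {
      red[ch] <- 1
    } else if (uu == 0) {
      if (d > 0)
        stop("degenerate node ", ch, ": zero mean parent-to-leaf distance ",
             "with positive branch length")
      red[ch] <- red[pa]
    } else {
      red[ch] <- red[pa] + (d / uu) * (1 - red[pa])
    }
  }

  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else rep(NA_character_, tree$Nnode))
  ann <- data.frame(node = seq_len(nnode), label = labels,
                    is_leaf = seq_len(nnode) <= ntip,
                    red = red,
                    p = red[parent_of],
                    d = edge_len,
                    u = u,
                    stringsAsFactors = FALSE)
  structure(ann, class = c("red_annotation", "data.frame"), tree = tree)
}

#' @export
print.red_annotation <- function(x, ...) {
  cat("RED annotation over", sum(x$is_leaf), "leaves /", nrow(x), "nodes\n")
  print.data.frame(head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more nodes\n")
  invisible(x)
}

# Tip labels descending from a node (node may itself be a tip).
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

# MRCA of a set of tip labels (the tip itself for a singleton).
mrca_node <- function(tree, tips) {
  if (length(tips) == 1L) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}
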