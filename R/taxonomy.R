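RANK_NAMES <- c(d = "domain", p = "phylum", c = "class", o = "order",
                f = "family", g = "genus", s = "species")

#' Parse semicolon-delimited lineage strings into a long genome-rank table
#'
#' Accepts GTDB-style prefixed lineages (`o__Foo;f__Bar;g__Baz`) or plain
#' semicolon-delimited strings, in which case `ranks` names the positions.
#'
#' @param seed_taxonomy Named character vector (names = genome ids, values =
#'   lineage strings) or a two-column data frame (genome id, lineage).
#' @param ranks Rank names assumed for unprefixed lineages, outermost first.
#' @return Data frame with columns `genome`, `rank`, `taxon`.
#' @export
parse_lineages <- function(seed_taxonomy,
                           ranks = c("phylum", "class", "order",
                                     "family", "genus")) {
  if (is.data.frame(seed_taxonomy)) {
    lin <- setNames(as.character(seed_taxonomy[[2L]]),
                    as.character(seed_taxonomy[[1L]]))
  } else lin <- seed_taxonomy
  out <- lapply(names(lin), function(g) {
    parts <- trimws(strsplit(lin[[g]], ";", fixed = TRUE)[[1L]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) return(NULL)
    if (all(grepl("^[dpcofgs]__", parts))) {
      rk <- RANK_NAMES[substr(parts, 1L, 1L)]
      tx <- sub("^[dpcofgs]__", "", parts)
    } else {
      if (length(parts) > length(ranks))
        stop("lineage for ", g, " has more fields than named ranks")
      rk <- ranks[seq_along(parts)]
      tx <- parts
    }
    keep <- nzchar(tx)
    data.frame(genome = g, rank = rk[keep], taxon = tx[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  dup <- unique(res[, c("genome", "rank")])
  if (nrow(dup) != nrow(res))
    stop("conflicting seed lineages: a genome is assigned twice at one rank")
  res
}

#' Fit per-rank RED windows from a seed taxonomy
#'
#' For every named taxon at each rank, the taxon is placed at the RED value
#' of the last common ancestor of its member genomes; the rank's window is
#' the median of those placements, plus/minus `half_width` (default 0.1,
#' the tolerance used for the genus rank), intersected with `[0, 1]`.
#'
#' @param annotation A `red_annotation` from [compute_red()].
#' @param seed_taxonomy See [parse_lineages()].
#' @param half_width Half-width of every rank window.
#' @param ranks Ranks to fit (those with no seed taxa are dropped with a
#'   warning).
#' @return A `rank_windows` data frame with columns `rank`, `median_red`,
#'   `half_width`, `lower`, `upper`, `n_taxa`.
#' @export
fit_rank_windows <- function(annotation, seed_taxonomy, half_width = 0.1,
                             ranks = c("phylum", "class", "order",
                                       "family", "genus")) {
  tree <- attr(annotation, "tree")
  lin <- parse_lineages(seed_taxonomy, ranks = ranks)
  lin <- lin[lin$genome %in% tree$tip.label, , drop = FALSE]
  rows <- lapply(ranks, function(r) {
    sub <- lin[lin$rank == r, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("no seed taxa at rank '", r, "'; window absent")
      return(NULL)
    }
    reds <- vapply(split(sub$genome, sub$taxon), function(tips) {
      annotation$red[mrca_node(tree, tips)]
    }, numeric(1L))
    data.frame(rank = r, median_red = median(reds), half_width = half_width,
               lower = max(0, median(reds) - half_width),
               upper = min(1, median(reds) + half_width),
               n_taxa = length(reds), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  structure(res, class = c("rank_windows", "data.frame"))
}

#' Test a taxon for monophyly and enumerate its maximal member-only subclades
#'
#' A taxon is monophyletic when the last common ancestor of its members
#' contains only members. Otherwise the members decompose uniquely into the
#' minimal set of maximal subtrees whose leaves are all members; these are
#' the clades a polyphyletic taxon is split into.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param members Character vector of member leaf labels (subset of tips).
#' @param taxon Optional taxon name carried through to the report.
#' @return A list with `taxon`, `monophyletic`, `n_subclades`, `subclades`
#'   (list of tip-label vectors in ladder order: descending size, then
#'   alphabetical first leaf), and `subclade_nodes`.
#' @export
detect_polyphyly <- function(tree, members, taxon = NULL) {
  if (length(members) == 0L) stop("member set must be non-empty")
  if (!all(members %in% tree$tip.label))
    stop("members must be a subset of the tree's leaves")
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  is_member_clade <- logical(nnode)
  is_member_clade[seq_len(ntip)] <- tree$tip.label %in% members
  n_child <- integer(nnode); ok_child <- integer(nnode)
  for (k in seq_len(nrow(po$edge))) {
    pa <- po$edge[k, 1L]; ch <- po$edge[k, 2L]
    # postorder: ch's subtree is complete, so finalise internal ch now
    if (ch > ntip)
      is_member_clade[ch] <- n_child[ch] > 0L && ok_child[ch] == n_child[ch]
    n_child[pa] <- n_child[pa] + 1L
    ok_child[pa] <- ok_child[pa] + is_member_clade[ch]
  }
  root <- ntip + 1L
  is_member_clade[root] <- n_child[root] > 0L &&
    ok_child[root] == n_child[root]
  parent_of <- integer(nnode); parent_of[] <- NA_integer_
  parent_of[po$edge[, 2L]] <- po$edge[, 1L]
  maximal <- which(is_member_clade &
                     (is.na(parent_of) | !is_member_clade[parent_of]))
  subclades <- lapply(maximal, function(nd) sort(clade_tips(tree, nd)))
  ord <- order(-lengths(subclades),
               vapply(subclades, `[`, character(1L), 1L))
  list(taxon = taxon,
       monophyletic = length(maximal) == 1L &&
         setequal(clade_tips(tree, mrca_node(tree, members)), members),
       n_subclades = length(maximal),
       subclades = subclades[ord],
       subclade_nodes = maximal[ord])
}

#' Normalise a seed taxonomy into rank-consistent monophyletic taxa
#'
#' Each seed taxon is first decomposed into its maximal member-only subclades
#' (polyphyletic taxa fall apart at this step). Any clade whose RED value
#' falls below the lower edge of its rank window is too deep for the rank and
#' is recursively replaced by its child clades, whose RED values are larger.
#' Clades whose RED lies above the window cannot be repaired by splitting and
#' are flagged unresolved but kept. When a taxon ends up as several clades
#' they are renamed with numeric suffixes (`X1, X2, ...`) in ladder order
#' (descending clade size, then alphabetical first leaf).
#'
#' The output taxa partition the input genomes of every processed taxon, and
#' re-running the normalisation on its own output is a fixed point.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param annotation `red_annotation` for `tree` from [compute_red()].
#' @param seed_taxonomy See [parse_lineages()].
#' @param windows `rank_windows` from [fit_rank_windows()].
#' @param ranks Ranks to normalise (default: every rank with a window).
#' @return A `taxon_assignments` list with `assignments` (data frame: `name`,
#'   `rank`, `node`, `red_value`, `status` in kept/split_child/renamed,
#'   `in_window`, `n_genomes`) and `genome_map` (data frame: `genome`,
#'   `rank`, `taxon`).
#' @export
normalise_taxonomy <- function(tree, annotation, seed_taxonomy, windows,
                               ranks = NULL) {
  lin <- parse_lineages(seed_taxonomy)
  if (is.null(ranks)) ranks <- intersect(unique(lin$rank), windows$rank)
  if (!all(ranks %in% windows$rank))
    stop("no window available for rank(s): ",
         paste(setdiff(ranks, windows$rank), collapse = ", "))
  assign_rows <- list(); map_rows <- list()
  for (r in ranks) {
    win <- windows[windows$rank == r, ]
    sub <- lin[lin$rank == r & lin$genome %in% tree$tip.label, , drop = FALSE]
    for (tx in sort(unique(sub$taxon))) {
      members <- sub$genome[sub$taxon == tx]
      rep0 <- detect_polyphyly(tree, members, taxon = tx)
      # recursively split clades that sit below the rank window
      final_nodes <- integer(0)
      queue <- rep0$subclade_nodes
      while (length(queue)) {
        nd <- queue[[1L]]; queue <- queue[-1L]
        red_nd <- annotation$red[nd]
        if (!annotation$is_leaf[nd] && red_nd < win$lower) {
          kids <- attr(annotation, "tree")$edge[
            attr(annotation, "tree")$edge[, 1L] == nd, 2L]
          queue <- c(queue, as.list(kids))
        } else final_nodes <- c(final_nodes, nd)
      }
      tips_of <- lapply(final_nodes, clade_tips, tree = tree)
      ord <- order(-lengths(tips_of),
                   vapply(lapply(tips_of, sort), `[`, character(1L), 1L))
      final_nodes <- final_nodes[ord]; tips_of <- tips_of[ord]
      split <- length(final_nodes) > 1L
      # strip a trailing numeric suffix check is unnecessary: names are
      # regenerated only when splitting, so reruns are stable
      nm <- if (split) paste0(tx, seq_along(final_nodes)) else tx
      st <- if (split) "split_child" else "kept"
      for (i in seq_along(final_nodes)) {
        nd <- final_nodes[i]
        red_nd <- annotation$red[nd]
        assign_rows[[length(assign_rows) + 1L]] <- data.frame(
          name = nm[i], rank = r, node = nd, red_value = red_nd,
          status = st,
          in_window = red_nd >= win$lower & red_nd <= win$upper,
          n_genomes = length(tips_of[[i]]), stringsAsFactors = FALSE)
        map_rows[[length(map_rows) + 1L]] <- data.frame(
          genome = tips_of[[i]], rank = r, taxon = nm[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(assignments = do.call(rbind, assign_rows),
                 genome_map = do.call(rbind, map_rows)),
            class = "taxon_assignments")
}

#' @export
print.taxon_assignments <- function(x, ...) {
  cat("Taxon assignments:", nrow(x$assignments), "taxa over",
      length(unique(x$genome_map$genome)), "genomes\n")
  print.data.frame(x$assignments, ...)
  invisible(x)
}
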