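test_that("RED endpoints and the hand-worked interpolation example", {
  tr <- ape::read.tree(text = "((A:1,B:1)X:1,C:2)R;")
  ann <- compute_red(tr)
  root <- ape::Ntip(tr) + 1L
  expect_equal(ann$red[root], 0)
  expect_equal(ann$red[ann$is_leaf], rep(1, 3))
  # X: p = 0, d = 1, u = mean(R->A, R->B) = 2, red = 0 + (1/2)(1-0)
  x <- which(ann$label == "X")
  expect_equal(ann$red[x], 0.5)
  expect_equal(ann$p[x], 0)
  expect_equal(ann$d[x], 1)
  expect_equal(ann$u[x], 2)

  two <- compute_red(ape::read.tree(text = "(A:1,B:3)R;"))
  expect_equal(sort(two$red), c(0, 1, 1))
})

test_that("compute_red matches the path-averaging oracle on random trees", {
  for (seed in 1:10) {
    n <- 3L + (seed %% 8L)
    tr <- random_tree(n, seed = seed * 13L)
    ann <- compute_red(tr)
    expect_equal(ann$red, red_oracle(tr), tolerance = 1e-12)
  }
})

test_that("RED is invariant to global branch-length scaling", {
  tr <- random_tree(20, seed = 42)
  sc <- tr
  sc$edge.length <- sc$edge.length * 37.5
  expect_equal(compute_red(tr)$red, compute_red(sc)$red, tolerance = 1e-12)
})

test_that("RED is non-decreasing along every root-to-leaf path", {
  tr <- random_tree(30, seed = 99)
  ann <- compute_red(tr)
  parent <- rep(NA_integer_, nrow(ann))
  tr2 <- attr(ann, "tree")
  parent[tr2$edge[, 2L]] <- tr2$edge[, 1L]
  ok <- !is.na(parent)
  expect_true(all(ann$red[ok] >= ann$red[parent[ok]] - 1e-12))
  expect_true(all(ann$red >= 0 & ann$red <= 1))
})

test_that("degenerate trees are refused or repaired", {
  expect_error(compute_red(ape::rtree(5, rooted = FALSE)), "rooted")
  # zero-length internal branch collapses to a polytomy, not an error
  tr <- ape::read.tree(text = "((A:1,B:1)X:0,C:2)R;")
  ann <- compute_red(tr)
  expect_equal(nrow(ann), 4L)  # 3 tips + single root polytomy
  expect_equal(sort(ann$red), c(0, 1, 1, 1))
  # zero-length terminal branch is permitted, leaf pinned at 1
  tr2 <- ape::read.tree(text = "((A:0,B:1)X:1,C:2)R;")
  expect_equal(compute_red(tr2)$red[1:3], rep(1, 3))
})

test_that("rank windows recover hand-placed and painted medians", {
  # cherries whose MRCAs sit at RED 0.8, 0.9, 0.95 exactly:
  # A: 4/(4+1); W: 7.5/(7.5+7.5) = 0.5; B: 0.5 + (4/5)(0.5); C: 0.5 + (9/10)(0.5)
  tr <- ape::read.tree(text = paste0(
    "((a1:1,a2:1)A:4,((b1:1,b2:1)B:4,(c1:1,c2:1)C:9)W:7.5)R;"))
  ann <- compute_red(tr)
  tax <- setNames(sprintf("g__%s", c("A", "A", "B", "B", "C", "C")),
                  tr$tip.label)
  win <- suppressWarnings(fit_rank_windows(ann, tax, ranks = "genus"))
  expect_equal(win$median_red, 0.9)
  expect_equal(win$lower, 0.8)
  expect_equal(win$upper, 1.0)  # clipped at 1

  # identical placement: window is r +/- 0.1
  tax1 <- setNames(sprintf("g__%s", c("A", "A", "B", "B")), tr$tip.label[1:4])
  win1 <- suppressWarnings(
    fit_rank_windows(compute_red(ape::read.tree(
      text = "((a1:1,a2:1)A:4,(b1:1,b2:1)B:4)R;")),
      setNames(c("g__A", "g__A", "g__B", "g__B"),
               c("a1", "a2", "b1", "b2")), ranks = "genus"))
  expect_equal(win1$median_red, 0.8)
  expect_equal(c(win1$lower, win1$upper), c(0.7, 0.9))

  # painted bands on a simulated tree recover the band centres
  tr2 <- simulate_tree(300, rate_heterogeneity = 1, seed = 31)
  ann2 <- compute_red(tr2)
  tax2 <- magpipe:::paint_taxonomy_by_red(tr2, ann2,
                                          centres = c(family = 0.4,
                                                      genus = 0.7),
                                          tol = 0.02)
  win2 <- fit_rank_windows(ann2, tax2, ranks = c("family", "genus"))
  expect_true(all(win2$n_taxa >= 3))
  expect_lt(abs(win2$median_red[win2$rank == "family"] - 0.4), 0.02)
  expect_lt(abs(win2$median_red[win2$rank == "genus"] - 0.7), 0.02)

  expect_warning(fit_rank_windows(ann, tax, ranks = c("genus", "order")),
                 "order")
})

test_that("polyphyly detection matches brute-force subclade enumeration", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):1)R;")
  mono <- detect_polyphyly(tr, c("A", "B"))
  expect_true(mono$monophyletic)
  expect_equal(mono$n_subclades, 1L)

  # two disjoint cherries separated by non-members
  poly <- detect_polyphyly(tr, c("A", "B", "E", "F"), taxon = "L")
  expect_false(poly$monophyletic)
  expect_equal(poly$n_subclades, 2L)
  expect_equal(poly$subclades, list(c("A", "B"), c("E", "F")))

  expect_error(detect_polyphyly(tr, character(0)), "non-empty")
  expect_error(detect_polyphyly(tr, "Z"), "subset")

  big <- random_tree(50, seed = 7)
  for (seed in 1:15) {
    members <- withr::with_seed(seed, sample(big$tip.label,
                                             sample(2:25, 1)))
    found <- detect_polyphyly(big, members)
    oracle <- brute_subclades(big, members)
    expect_equal(found$n_subclades, length(oracle))
    expect_setequal(vapply(found$subclades, paste, character(1L),
                           collapse = ","),
                    vapply(lapply(oracle, sort), paste, character(1L),
                           collapse = ","))
  }
})

test_that("taxonomy normalisation keeps, splits, partitions, and is idempotent", {
  tr <- ape::read.tree(text = paste0(
    "(((A:1,B:1)ab:1,(C:1,D:1)cd:1)X:0.2,(E:8,F:8)Y:2)R;"))
  ann <- compute_red(tr)
  # genus Y sits inside the window -> kept unchanged
  # genus X is too deep (red below window) -> split into its two children
  redX <- ann$red[which(ann$label == "X")]
  redY <- ann$red[which(ann$label == "Y")]
  win <- data.frame(rank = "genus", median_red = redY, half_width = 0.05,
                    lower = redY - 0.05, upper = redY + 0.05)
  stopifnot(redX < win$lower)
  tax <- setNames(c("g__X", "g__X", "g__X", "g__X", "g__Y", "g__Y"),
                  c("A", "B", "C", "D", "E", "F"))
  res <- normalise_taxonomy(tr, ann, tax, win)
  a <- res$assignments
  expect_equal(a$status[a$name == "Y"], "kept")
  expect_setequal(a$name[a$status == "split_child"], c("X1", "X2"))
  # partition: every genome appears exactly once
  expect_setequal(res$genome_map$genome, tr$tip.label)
  expect_equal(anyDuplicated(res$genome_map$genome), 0L)

  # idempotence: rerunning on the normalised output changes nothing
  tax2 <- setNames(paste0("g__", res$genome_map$taxon), res$genome_map$genome)
  res2 <- normalise_taxonomy(tr, ann, tax2, win)
  expect_equal(sort(res2$assignments$name), sort(a$name))
  expect_true(all(res2$assignments$status == "kept"))
  m1 <- res$genome_map[order(res$genome_map$genome), ]
  m2 <- res2$genome_map[order(res2$genome_map$genome), ]
  expect_equal(m1$taxon, m2$taxon)
})

test_that("split children are suffixed in ladder order on a planted case", {
  # deliberately deep genus with a 3-leaf and a 1-leaf child clade
  tr <- ape::read.tree(text =
    "((((A:1,B:1):1,C:2):1,D:3)X:0.1,(E:5,F:5)Y:1)R;")
  ann <- compute_red(tr)
  redY <- ann$red[which(ann$label == "Y")]
  win <- data.frame(rank = "genus", median_red = redY, half_width = 0.05,
                    lower = redY - 0.05, upper = redY + 0.05)
  tax <- setNames(c(rep("g__X", 4), "g__Y", "g__Y"), c(LETTERS[1:4], "E", "F"))
  res <- normalise_taxonomy(tr, ann, tax, win)
  gm <- res$genome_map
  # larger child clade takes suffix 1
  expect_setequal(gm$genome[gm$taxon == "X1"], c("A", "B", "C"))
  expect_setequal(gm$genome[gm$taxon == "X2"], "D")
})
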