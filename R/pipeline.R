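#' Default pipeline configuration
#'
#' All thresholds default to the values the individual stages document:
#' screening at 20% completeness / 10% contamination, dereplication at 99.5%
#' identity, BH thresholds 0.1 (variable) and 0.05 (coefficient), RED
#' half-width 0.1, spline df 3 to 9, spectral positions 315/318 with
#' alignment filter 30% similarity and termini 113 to 585.
#'
#' @param ... Named overrides of any default.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(min_completeness = 20, max_contamination = 10,
              derep_threshold = 99.5,
              bh_variable_threshold = 0.1, bh_coefficient_threshold = 0.05,
              red_half_width = 0.1, spline_df_range = 3:9,
              pos_tuning = 315, pos_donor = 318,
              min_similarity = 0.30, termini = c(113, 585),
              n_genomes = 40, n_markers = 120, n_samples = 36, n_clades = 8,
              n_pr_seqs = 30)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$min_completeness >= 0, cfg$min_completeness <= 100,
            cfg$max_contamination >= 0, cfg$max_contamination <= 100,
            cfg$derep_threshold > 0, cfg$derep_threshold <= 100,
            cfg$bh_variable_threshold > 0, cfg$bh_variable_threshold < 1,
            cfg$bh_coefficient_threshold > 0,
            cfg$bh_coefficient_threshold < 1,
            cfg$red_half_width > 0, all(cfg$spline_df_range >= 1))
  cfg
}

#' Validate a bundle of pipeline inputs
#'
#' Report-only structural checks: tree rootedness and branch lengths, marker
#' table rectangularity and non-negativity, alignment width equality, and
#' metadata coverage of the count samples. Inputs are never mutated.
#'
#' @param tree Optional [ape::phylo].
#' @param marker_table Optional genome x marker matrix.
#' @param alignment Optional [Biostrings::AAStringSet] (or list of strings).
#' @param dataset Optional `abundance_dataset` (counts + metadata).
#' @return Data frame with columns `check`, `ok`, `detail`; zero rows of
#'   `ok = FALSE` means a valid bundle.
#' @export
validate_inputs <- function(tree = NULL, marker_table = NULL,
                            alignment = NULL, dataset = NULL) {
  rows <- list()
  add <- function(check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(check = check, ok = ok,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }
  if (!is.null(tree)) {
    add("tree_rooted", ape::is.rooted(tree),
        if (ape::is.rooted(tree)) "" else
          "tree is unrooted; RED requires a rooted tree or an explicit outgroup")
    add("tree_branch_lengths", !is.null(tree$edge.length) &&
          all(tree$edge.length >= 0), "")
    add("tree_unique_leaves", !anyDuplicated(tree$tip.label), "")
  }
  if (!is.null(marker_table)) {
    ok <- is.matrix(marker_table) && is.numeric(marker_table) &&
      all(marker_table >= 0)
    add("marker_table_rectangular_nonnegative", ok, "")
  }
  if (!is.null(alignment)) {
    w <- if (inherits(alignment, "XStringSet")) Biostrings::width(alignment)
    else nchar(unlist(alignment))
    ok <- length(unique(w)) == 1L
    bad <- if (!ok) {
      nm <- if (inherits(alignment, "XStringSet")) names(alignment)
      else names(unlist(alignment))
      paste("ragged width at:", paste(nm[w != w[1L]], collapse = ","))
    } else ""
    add("alignment_equal_widths", ok, bad)
  }
  if (!is.null(dataset)) {
    ok <- all(colnames(dataset$counts) %in% dataset$metadata$sample)
    add("metadata_covers_samples", ok,
        if (ok) "" else "count samples missing from metadata")
  }
  do.call(rbind, rows)
}

# Simulated pairwise identity matrix with planted >threshold clusters.
simulate_identity_matrix <- function(genome_ids, n_clusters = NULL,
                                     threshold = 99.5, seed = NULL) {
  n <- length(genome_ids)
  if (is.null(n_clusters)) n_clusters <- max(2L, n %/% 3L)
  draw <- function() {
    grp <- sort(rep_len(seq_len(n_clusters), n))
    m <- matrix(runif(n * n, 75, 95), n, n)
    m[outer(grp, grp, `==`)] <- runif(sum(outer(grp, grp, `==`)),
                                      threshold, 100)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 100
    dimnames(m) <- list(genome_ids, genome_ids)
    attr(m, "clusters") <- setNames(grp, genome_ids)
    m
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Paint a seed taxonomy onto a tree at fixed RED bands: a taxon at a rank is
# an internal clade whose RED lies within centre +/- tol, clades taken
# deepest-first so taxa at one rank are leaf-disjoint. Tips not covered by
# any band clade stay unassigned at that rank.
paint_taxonomy_by_red <- function(tree, annotation,
                                  centres = c(family = 0.4, genus = 0.7),
                                  tol = 0.15) {
  ntip <- ape::Ntip(tree)
  groups <- lapply(names(centres), function(rk) {
    ctr <- centres[[rk]]
    cand <- which(!annotation$is_leaf &
                    abs(annotation$red - ctr) <= tol)
    cand <- cand[order(annotation$red[cand])]  # deepest (maximal) first
    lab <- setNames(rep(NA_character_, ntip), tree$tip.label)
    i <- 0L
    for (nd in cand) {
      tips <- clade_tips(tree, nd)
      if (all(is.na(lab[tips]))) {
        i <- i + 1L
        lab[tips] <- sprintf("%s%02d", toupper(substr(rk, 1L, 1L)), i)
      }
    }
    lab
  })
  names(groups) <- names(centres)
  vapply(tree$tip.label, function(tp) {
    tx <- vapply(groups, `[[`, character(1L), tp)
    ok <- !is.na(tx)
    paste(sprintf("%s__%s", substr(names(centres)[ok], 1L, 1L), tx[ok]),
          collapse = ";")
  }, character(1L))
}

#' Run the full pipeline on simulated inputs
#'
#' One-command demonstration: simulates a genome tree, marker table, MAG
#' manifest, identity matrix, proteorhodopsin alignment and abundance
#' dataset with a fixed seed, then runs marker refinement, quality
#' estimation, screening, MIMAG classification, type-material selection,
#' dereplication, RED annotation, rank windows, taxonomy normalisation,
#' spectral and donor classification, library scaling, per-clade NB GLMs
#' with the BH screen, and an NB GAM on a seasonal series. All tables are
#' written as TSV (plus the tree as newick and a JSON run manifest) under
#' `out_dir`; outputs are byte-identical for a fixed config and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every simulation.
#' @param config A [pipeline_config()] list.
#' @return Invisibly, a list of all in-memory stage results.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  # stage simulations get distinct sub-seeds derived from the master seed
  subseed <- function(k) (seed * 101L + k) %% .Machine$integer.max

  tree <- simulate_tree(config$n_genomes, rate_heterogeneity = 0.8,
                        seed = subseed(1L))
  ann <- compute_red(tree)
  seed_tax <- paint_taxonomy_by_red(tree, ann)
  windows <- fit_rank_windows(ann, seed_tax,
                              half_width = config$red_half_width,
                              ranks = c("family", "genus"))
  taxa <- normalise_taxonomy(tree, ann, seed_tax, windows)

  comp <- withr::with_seed(subseed(2L), runif(config$n_genomes, 0.3, 1))
  cont <- withr::with_seed(subseed(3L), runif(config$n_genomes, 0, 0.12))
  sim_mk <- simulate_marker_table(config$n_genomes,
                                  sprintf("MK%04d", seq_len(config$n_markers)),
                                  comp, cont, seed = subseed(4L))
  markers <- refine_marker_set(sim_mk$table)
  qual <- estimate_quality(sim_mk$table, markers)
  recs <- withr::with_seed(subseed(5L), mag_records(
    genome = qual$genome, completeness = qual$completeness,
    contamination = qual$contamination,
    n_contigs = sample(20:250, config$n_genomes, replace = TRUE),
    n_ambiguous_bases = sample(0:30, config$n_genomes, replace = TRUE),
    len_16s = sample(c(0, 900, 1250, 1500), config$n_genomes, replace = TRUE),
    len_23s = sample(c(0, 1500, 1950, 2900), config$n_genomes, replace = TRUE),
    len_5s = sample(c(0, 105, 120), config$n_genomes, replace = TRUE),
    n_trnas = sample(10:22, config$n_genomes, replace = TRUE),
    family = {
      lin <- parse_lineages(seed_tax)
      fam <- lin$taxon[lin$rank == "family"][
        match(qual$genome, lin$genome[lin$rank == "family"])]
      ifelse(is.na(fam), "unplaced", fam)
    }))
  screened <- screen_mags(recs, config$min_completeness,
                          config$max_contamination)
  hq <- mimag_high_quality(recs)
  type_material <- tryCatch(
    suppressWarnings(select_type_material(recs)), error = function(e) NULL)
  idm <- simulate_identity_matrix(recs$genome,
                                  threshold = config$derep_threshold,
                                  seed = subseed(6L))
  derep <- dereplicate(idm, recs, threshold = config$derep_threshold)

  sim_pr <- simulate_pr_alignment(
    config$n_pr_seqs,
    rep(c("SP", "DP"), length.out = config$n_pr_seqs),
    seed = subseed(7L))
  filt <- filter_alignment(sim_pr$alignment,
                           min_similarity = config$min_similarity,
                           start_col = config$termini[1L],
                           end_col = config$termini[2L])
  spectral <- classify_spectral(filt, pos_tuning = config$pos_tuning)
  donor <- classify_donor(filt, pos_donor = config$pos_donor)
  depths <- withr::with_seed(subseed(8L), ifelse(
    sim_pr$truth$label == "SP", runif(config$n_pr_seqs, 0, 50),
    runif(config$n_pr_seqs, 50, 200)))
  depth_bins <- class_by_depth(spectral, setNames(depths, spectral$id))

  ds <- simulate_counts(config$n_samples, config$n_clades,
                        coefficients = seq(-0.6, 0.6,
                                           length.out = config$n_clades),
                        dispersion_alpha = 0.4, seed = subseed(9L))
  ds$size_factors <- scale_by_library_size(ds$counts)$size_factors
  fits <- lapply(rownames(ds$counts), function(cl)
    fit_nb_glm(ds, cl, "covariate"))
  screen <- significance_screen(fits, config$bh_variable_threshold,
                                config$bh_coefficient_threshold)
  seas <- simulate_counts(15, 1, coefficients = 0, dispersion_alpha = 0.2,
                          covariates = rep(0, 15), seasonal_amplitude = 1,
                          time = 1:15, library_sizes = rep(1, 15),
                          seed = subseed(10L))
  gam <- fit_nb_gam(seas$counts[1L, ], time = 1:15,
                    df_range = config$spline_df_range)

  # ---- write the bundle ----
  p <- function(f) file.path(out_dir, f)
  ape::write.tree(tree, p("tree.nwk"))
  write_tsv_matrix(as.data.frame(ann), p("red.tsv"), id_name = "row")
  write.table(taxa$assignments, p("taxa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(taxa$genome_map, p("genome_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(screened, p("screen.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(hq, p("mimag.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(type_material))
    write.table(type_material, p("type_material.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(derep$clusters, p("dereplication.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(merge(spectral, donor, by = "id"), p("spectral_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(depth_bins, p("spectral_by_depth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(screen$variables, p("glm_screen.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(time = gam$time, fitted = gam$fitted,
                         lower = gam$lower, upper = gam$upper),
              p("gam_smooth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(package = "magpipe",
                   version = as.character(utils::packageVersion("magpipe")),
                   seed = seed,
                   config = config[order(names(config))],
                   outputs = sort(list.files(out_dir, pattern = "\\.(tsv|nwk)$")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(tree = tree, annotation = ann, windows = windows,
                 taxa = taxa, quality = qual, screened = screened,
                 mimag = hq, type_material = type_material, derep = derep,
                 spectral = spectral, donor = donor,
                 depth_bins = depth_bins, glm_fits = fits,
                 glm_screen = screen, gam = gam))
}
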