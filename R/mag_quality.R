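#' Refine a lineage marker set by dropping globally absent markers
#'
#' Markers with zero copies in every genome of the lineage carry no signal
#' for that lineage and deflate completeness estimates; they are removed from
#' the working set.
#'
#' @param table Genome x marker copy-count matrix (non-negative integers).
#' @param full_set Marker ids to refine (defaults to the table's columns).
#' @return Character vector of retained marker ids (subset of `full_set`).
#'   Warns and returns `character(0)` if every marker is globally absent.
#' @export
refine_marker_set <- function(table, full_set = colnames(table)) {
  if (is.null(full_set) || length(full_set) == 0L)
    stop("full_set must be non-empty")
  if (nrow(table) == 0L) stop("marker table must cover at least one genome")
  present <- colnames(table)[colSums(table > 0) > 0]
  kept <- full_set[full_set %in% present]
  if (length(kept) == 0L) warning("all markers are globally absent")
  kept
}

#' Marker-based completeness and contamination estimates
#'
#' Single-marker approximation to CheckM-style estimates:
#' completeness is the percentage of markers present at least once, and
#' contamination the percentage of surplus copies,
#' `100 * sum(max(copy - 1, 0)) / n_markers`.
#'
#' @param table Genome x marker copy-count matrix.
#' @param markers Marker ids to use (typically from [refine_marker_set()]).
#' @return Data frame with columns `genome`, `completeness`, `contamination`
#'   (percent).
#' @export
estimate_quality <- function(table, markers = colnames(table)) {
  if (length(markers) == 0L) stop("marker list must be non-empty")
  if (!all(markers %in% colnames(table)))
    stop("markers must be columns of the table")
  sub <- table[, markers, drop = FALSE]
  data.frame(genome = rownames(sub),
             completeness = 100 * rowSums(sub > 0) / length(markers),
             contamination = 100 * rowSums(pmax(sub - 1, 0)) / length(markers),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Screen MAGs on completeness and contamination thresholds
#'
#' A genome is kept iff `completeness >= min_completeness` and
#' `contamination <= max_contamination` (the boundary is on the keep side,
#' matching exclusion rules phrased as "< 20%" completeness and "> 10%"
#' contamination). Defaults are the permissive lineage-wide screen; the
#' stricter site screen used for fresh assemblies is obtained with
#' `min_completeness = 50, max_contamination = 1`.
#'
#' @param records Data frame with columns `genome`, `completeness`,
#'   `contamination` (a [mag_records()] manifest works).
#' @param min_completeness,max_contamination Percent thresholds in `[0, 100]`.
#' @return The input with logical `passed_screen` and a `reasons` string
#'   naming each failed rule (empty when kept).
#' @export
screen_mags <- function(records, min_completeness = 20,
                        max_contamination = 10) {
  stopifnot(min_completeness >= 0, min_completeness <= 100,
            max_contamination >= 0, max_contamination <= 100)
  fail_comp <- records$completeness < min_completeness
  fail_cont <- records$contamination > max_contamination
  records$passed_screen <- !(fail_comp | fail_cont)
  records$reasons <- trimws(paste(ifelse(fail_comp, "completeness", ""),
                                  ifelse(fail_cont, "contamination", "")))
  records
}

#' Construct a MAG manifest
#'
#' Convenience constructor validating the per-genome quality and assembly
#' attributes used by the screening, MIMAG, and type-material rules.
#'
#' @param genome Genome ids.
#' @param completeness,contamination Percent estimates.
#' @param n_contigs,n_ambiguous_bases Assembly counts.
#' @param len_16s,len_23s,len_5s rRNA gene lengths in bp (0 = absent).
#' @param n_trnas Number of distinct tRNAs.
#' @param family Family-level taxon label.
#' @return Data frame manifest (one row per genome).
#' @export
mag_records <- function(genome, completeness, contamination,
                        n_contigs = NA_integer_,
                        n_ambiguous_bases = NA_integer_,
                        len_16s = 0, len_23s = 0, len_5s = 0,
                        n_trnas = 0, family = NA_character_) {
  stopifnot(all(completeness >= 0 & completeness <= 100),
            all(contamination >= 0))
  data.frame(genome = genome, completeness = completeness,
             contamination = contamination, n_contigs = n_contigs,
             n_ambiguous_bases = n_ambiguous_bases, len_16s = len_16s,
             len_23s = len_23s, len_5s = len_5s, n_trnas = n_trnas,
             family = family, stringsAsFactors = FALSE)
}

#' MIMAG high-quality draft classification
#'
#' High quality requires completeness strictly above 90%, contamination
#' strictly below 5%, near full-length rRNA genes (16S >= 1200 bp,
#' 23S >= 1900 bp, 5S >= 100 bp) and at least 18 tRNAs. Missing rRNA entries
#' count as length 0 and fail the corresponding rule.
#'
#' @param records MAG manifest (see [mag_records()]).
#' @return The input with logical `is_mimag_hq` and a `reasons` string of
#'   failed rules among completeness/contamination/16S/23S/5S/tRNA.
#' @export
mimag_high_quality <- function(records) {
  z <- function(x) ifelse(is.na(x), 0, x)
  rules <- cbind(completeness = records$completeness > 90,
                 contamination = records$contamination < 5,
                 `16S` = z(records$len_16s) >= 1200,
                 `23S` = z(records$len_23s) >= 1900,
                 `5S` = z(records$len_5s) >= 100,
                 tRNA = z(records$n_trnas) >= 18)
  records$is_mimag_hq <- rowSums(rules) == ncol(rules)
  records$reasons <- apply(rules, 1L, function(r)
    paste(colnames(rules)[!r], collapse = ","))
  records
}

#' Quality score for ranking MAGs
#'
#' `completeness - 4 * contamination`, the score used to rank candidate
#' type-material genomes (no rounding before ranking).
#'
#' @param records MAG manifest, or numeric completeness if `contamination`
#'   is given separately.
#' @param contamination Optional numeric vector.
#' @return Numeric scores.
#' @export
quality_score <- function(records, contamination = NULL) {
  if (is.numeric(records)) return(records - 4 * contamination)
  records$completeness - 4 * records$contamination
}

#' Select per-family type material
#'
#' Candidates must pass [mimag_high_quality()], have at most 100 contigs and
#' fewer than 10 ambiguous bases; within each family the candidate with the
#' highest [quality_score()] wins (ties broken lexicographically by genome
#' id). Families with no candidate are reported with a warning and omitted.
#'
#' @param records MAG manifest with `family` labels.
#' @return Data frame of chosen genomes, one row per family with a winner.
#' @export
select_type_material <- function(records) {
  if (any(is.na(records$family))) stop("family labels must be present")
  hq <- mimag_high_quality(records)
  cand <- records[hq$is_mimag_hq &
                    records$n_contigs <= 100 &
                    records$n_ambiguous_bases < 10, , drop = FALSE]
  out <- lapply(sort(unique(records$family)), function(fam) {
    sub <- cand[cand$family == fam, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("family '", fam, "' has no type-material candidate")
      return(NULL)
    }
    sc <- quality_score(sub)
    sub <- sub[order(-sc, sub$genome), , drop = FALSE]
    cbind(sub[1L, , drop = FALSE], quality_score = max(sc))
  })
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}

#' Dereplicate genomes at an identity threshold
#'
#' Greedy clustering on a pairwise percent-identity matrix: genomes are
#' visited in order of descending quality score (ties by id); each unassigned
#' genome becomes a cluster representative and absorbs every unassigned
#' genome with identity at or above the threshold. Representatives are
#' therefore pairwise below the threshold and every absorbed genome sits at
#' or above the threshold to its representative.
#'
#' @param identity_matrix Symmetric percent-identity matrix, diagonal 100,
#'   dimnames = genome ids.
#' @param records MAG manifest supplying quality scores (rows matched by
#'   `genome`).
#' @param threshold Percent identity above which genomes are redundant
#'   (default 99.5).
#' @return A list with `representatives` (character), and `clusters`
#'   (data frame `genome`, `representative`).
#' @export
dereplicate <- function(identity_matrix, records, threshold = 99.5) {
  if (!isSymmetric(unname(identity_matrix)))
    stop("identity matrix must be symmetric")
  ids <- rownames(identity_matrix)
  if (!all(abs(diag(identity_matrix) - 100) < 1e-8))
    stop("identity matrix diagonal must be 100")
  sc <- quality_score(records)[match(ids, records$genome)]
  ord <- ids[order(-sc, ids)]
  rep_of <- setNames(rep(NA_character_, length(ids)), ids)
  for (g in ord) {
    if (!is.na(rep_of[[g]])) next
    rep_of[[g]] <- g
    hits <- ids[identity_matrix[g, ] >= threshold & is.na(rep_of)]
    rep_of[hits] <- g
  }
  list(representatives = unique(unname(rep_of[ord])),
       clusters = data.frame(genome = ids, representative = unname(rep_of[ids]),
                             stringsAsFactors = FALSE))
}

#' Per-genus trait prevalence
#'
#' Proportion of the MAGs in each genus that carry each trait.
#'
#' @param trait_table Genome x trait logical/0-1 matrix (rownames = genomes).
#' @param taxonomy Named character vector genome -> genus covering all rows.
#' @return Genus x trait matrix of proportions in `[0, 1]`.
#' @export
trait_prevalence <- function(trait_table, taxonomy) {
  g <- taxonomy[rownames(trait_table)]
  if (any(is.na(g))) stop("every genome must be assigned a genus")
  carriers <- rowsum((trait_table > 0) + 0, group = g)
  sweep(carriers, 1L, as.vector(table(g)[rownames(carriers)]), `/`)
}
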