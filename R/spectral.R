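# Character matrix view of an alignment; stops on ragged widths.
aln_matrix <- function(aln) {
  if (length(aln) == 0L) stop("alignment is empty")
  w <- Biostrings::width(aln)
  if (length(unique(w)) != 1L)
    stop("alignment is ragged: sequences differ in width")
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Filter a protein alignment by termini and per-column conservation
#'
#' Columns outside `[start_col, end_col]` are removed, as are columns whose
#' modal non-gap residue accounts for less than `min_similarity` of the
#' non-gap entries in that column (all-gap columns always fail). Original
#' column coordinates remain addressable through the retained index map, so
#' positions named on the unfiltered alignment (e.g. the tuning residue at
#' column 315) can still be queried after filtering.
#'
#' @param aln A [Biostrings::AAStringSet] of equal-width sequences, or the
#'   `alignment` element of [simulate_pr_alignment()] output.
#' @param min_similarity Minimum modal non-gap residue frequency in `[0, 1]`
#'   (default 0.30).
#' @param start_col,end_col 1-based termini of the retained region
#'   (defaults 113 and 585, capped at the alignment width).
#' @return A `filtered_alignment`: list with `alignment` (the filtered
#'   [Biostrings::AAStringSet]) and `col_map` (original column index of each
#'   retained column).
#' @export
filter_alignment <- function(aln, min_similarity = 0.30,
                             start_col = 113, end_col = 585) {
  m <- aln_matrix(aln)
  w <- ncol(m)
  end_col <- min(end_col, w)
  if (start_col < 1 || start_col > end_col)
    stop("need 1 <= start_col <= end_col <= alignment width")
  cols <- start_col:end_col
  keep <- vapply(cols, function(j) {
    res <- m[, j]
    res <- res[res != "-"]
    length(res) > 0L && max(table(res)) / length(res) >= min_similarity
  }, logical(1L))
  kept <- cols[keep]
  out <- Biostrings::AAStringSet(apply(m[, kept, drop = FALSE], 1L,
                                       paste, collapse = ""))
  names(out) <- rownames(m)
  structure(list(alignment = out, col_map = kept),
            class = "filtered_alignment")
}

# Residue at an *original* alignment column; "-" when the column was
# filtered out or the position holds a gap.
residue_at <- function(aln, id, pos) {
  if (inherits(aln, "filtered_alignment")) {
    j <- match(pos, aln$col_map)
    if (is.na(j)) return("-")
    aln <- aln$alignment
  } else {
    if (is.list(aln) && !is.null(aln$alignment)) aln <- aln$alignment
    j <- pos
  }
  if (!(id %in% names(aln))) stop("sequence id '", id, "' absent")
  if (j > Biostrings::width(aln)[match(id, names(aln))])
    stop("position ", pos, " beyond alignment width")
  substr(as.character(aln[[id]]), j, j)
}

seq_ids <- function(aln) {
  if (inherits(aln, "filtered_alignment")) names(aln$alignment)
  else if (is.list(aln) && !is.null(aln$alignment)) names(aln$alignment)
  else names(aln)
}

#' Spectral-tuning classification of proteorhodopsin sequences
#'
#' The residue at the spectral-tuning alignment column (default 315, 1-based
#' on the unfiltered alignment) determines the predicted absorption maximum:
#' nonpolar methionine (M) tunes the pigment to green light with maximal
#' absorption at 525 nm (shallow-photic class `green_SP`), polar glutamine
#' (Q) to blue light at 490 nm (deep-photic class `blue_DP`). Any other
#' residue, ambiguity code X, or a gap yields `unknown` with no wavelength;
#' the classification is total over the alignment alphabet.
#'
#' @param aln Alignment (raw, simulated, or [filter_alignment()] output).
#' @param ids Sequence ids to classify (default all).
#' @param pos_tuning Tuning column in original coordinates (default 315).
#' @return Data frame with `id`, `residue_315`, `spectral_class`
#'   (`green_SP`/`blue_DP`/`unknown`), `absorption_max_nm` (525, 490, or NA).
#' @export
classify_spectral <- function(aln, ids = seq_ids(aln), pos_tuning = 315) {
  res <- vapply(ids, residue_at, character(1L), aln = aln, pos = pos_tuning)
  cls <- ifelse(res == "M", "green_SP",
                ifelse(res == "Q", "blue_DP", "unknown"))
  data.frame(id = ids, residue_315 = unname(res),
             spectral_class = unname(cls),
             absorption_max_nm = unname(ifelse(cls == "green_SP", 525,
                                        ifelse(cls == "blue_DP", 490, NA_real_))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proton-donor classification of proteorhodopsin sequences
#'
#' The residue at the proton-donor column (default 318) separates
#' light-driven proton pumps from photosensors: glutamic acid (E) and lysine
#' (K) are the conserved donors of the blue (DP) and green (SP) pump clades
#' respectively, while phenylalanine (F) or serine (S) at this position marks
#' rhodopsins used as photosensors. Anything else is `unknown`.
#'
#' @inheritParams classify_spectral
#' @param pos_donor Donor column in original coordinates (default 318).
#' @return Data frame with `id`, `residue_318`, `donor_class` in
#'   `proton_pump_E`/`proton_pump_K`/`photosensor`/`unknown`.
#' @export
classify_donor <- function(aln, ids = seq_ids(aln), pos_donor = 318) {
  res <- vapply(ids, residue_at, character(1L), aln = aln, pos = pos_donor)
  cls <- ifelse(res == "E", "proton_pump_E",
                ifelse(res == "K", "proton_pump_K",
                       ifelse(res %in% c("F", "S"), "photosensor", "unknown")))
  data.frame(id = ids, residue_318 = unname(res), donor_class = unname(cls),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spectral class composition by depth bin
#'
#' Tabulates the fraction of green-, blue-, and unknown-tuned sequences per
#' depth bin; within each bin the three fractions sum to 1.
#'
#' @param calls Output of [classify_spectral()].
#' @param depths Per-sequence sampling depth in metres (named by id, or in
#'   `calls` order).
#' @param bin_edges Increasing depth bin edges covering all depths; bins are
#'   left-closed (`[e_i, e_{i+1})`, last bin closed).
#' @return Data frame with `bin`, `n`, `green_SP`, `blue_DP`, `unknown`.
#' @export
class_by_depth <- function(calls, depths,
                           bin_edges = c(0, 50, 200, Inf)) {
  d <- if (!is.null(names(depths))) depths[calls$id] else depths
  if (length(d) != nrow(calls) || any(is.na(d)))
    stop("every call needs a depth")
  if (any(d < min(bin_edges) | d > max(bin_edges)))
    stop("depth outside the bin range")
  bin <- cut(d, breaks = bin_edges, right = FALSE, include.lowest = TRUE)
  classes <- c("green_SP", "blue_DP", "unknown")
  out <- lapply(levels(bin), function(b) {
    cl <- calls$spectral_class[bin == b]
    n <- length(cl)
    fr <- if (n) as.vector(table(factor(cl, classes)) / n) else rep(NA_real_, 3)
    data.frame(bin = b, n = n, green_SP = fr[1], blue_DP = fr[2],
               unknown = fr[3], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
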