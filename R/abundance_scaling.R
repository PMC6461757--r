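#' Median-of-ratios library size factors
#'
#' For each sample the size factor is the median, over clades with non-zero
#' counts in every sample, of the ratio of the clade's count to the clade's
#' geometric mean across samples. Clades with any zero count are excluded
#' from the median (their geometric mean is zero); an optional pseudo-count
#' rescues datasets where no clade is complete.
#'
#' @param counts Clade x sample count matrix (>= 2 samples).
#' @param pseudo_count Added to every count before computing factors
#'   (default 0).
#' @return A list with `size_factors` (per sample) and `scaled`
#'   (`counts / size_factor`, original counts, not pseudo-counted).
#' @export
scale_by_library_size <- function(counts, pseudo_count = 0) {
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(rowSums(counts) == 0))
    stop("every clade must be non-zero in at least one sample")
  k <- counts + pseudo_count
  complete <- rowSums(k == 0) == 0L
  if (!any(complete))
    stop("no clade is non-zero in all samples; rerun with a pseudo_count ",
         "(e.g. pseudo_count = 1)")
  loggeo <- rowMeans(log(k[complete, , drop = FALSE]))
  ratios <- log(k[complete, , drop = FALSE]) - loggeo
  sf <- exp(apply(ratios, 2L, median))
  names(sf) <- colnames(counts)
  list(size_factors = sf, scaled = sweep(counts, 2L, sf, `/`))
}

#' Exclude sparse samples by mapped-read share
#'
#' A sample is dropped when its share of the total mapped reads falls below
#' `min_fraction` of the uniform per-sample share `1 / n_samples`; with the
#' default 0.05 a sample must hold at least 5% of its "fair share" of the
#' data to be retained.
#'
#' @param counts Clade x sample count matrix.
#' @param min_fraction Fraction of the uniform share required, in `(0, 1)`.
#' @return List with `kept` and `dropped` sample names and the per-sample
#'   `share` vector.
#' @export
exclude_sparse_samples <- function(counts, min_fraction = 0.05) {
  if (min_fraction <= 0 || min_fraction >= 1)
    stop("min_fraction must lie in (0, 1)")
  share <- colSums(counts) / sum(counts)
  cutoff <- min_fraction / ncol(counts)
  kept <- colnames(counts)[share >= cutoff]
  if (length(kept) == 0L) stop("all samples fall below the sparsity cutoff")
  list(kept = kept, dropped = setdiff(colnames(counts), kept), share = share)
}

#' Normalise a gene's abundance by single-copy ribosomal genes
#'
#' Ratio of the gene count to the mean of five single-copy ribosomal protein
#' gene counts (S4, S15, S24e, S27ae, L21), giving a per-genome-equivalent
#' abundance that is invariant to sequencing depth.
#'
#' @param gene_counts Numeric vector of gene counts (one per sample).
#' @param ribosomal_counts Matrix with one row per sample and five columns
#'   (or a vector of five counts for a single sample).
#' @return Numeric ratios; `NA` with a warning where all five ribosomal
#'   counts are zero.
#' @export
normalize_by_single_copy <- function(gene_counts, ribosomal_counts) {
  if (is.null(dim(ribosomal_counts)))
    ribosomal_counts <- matrix(ribosomal_counts, nrow = 1L)
  if (ncol(ribosomal_counts) != 5L)
    stop("expected counts for five single-copy ribosomal genes")
  denom <- rowMeans(ribosomal_counts)
  if (any(denom == 0)) {
    warning("all ribosomal counts zero for ",
            sum(denom == 0), " sample(s); ratio undefined")
    denom[denom == 0] <- NA_real_
  }
  gene_counts / denom
}
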