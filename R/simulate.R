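#' Simulate a rooted genome tree with rate heterogeneity
#'
#' Builds a rooted binary tree by uniform random joins: starting from
#' `n_leaves` singleton subtrees, two subtrees are picked uniformly at random
#' and joined until a single rooted tree remains. Each branch length is an
#' exponential(1) draw multiplied by a gamma-distributed rate factor with
#' shape `rate_heterogeneity` and mean 1, so smaller shapes give stronger
#' lineage-specific rate variation. This is the substrate used to exercise
#' relative evolutionary divergence (RED), whose whole point is robustness to
#' such rate variation.
#'
#' @param n_leaves Number of leaves (genomes); at least 2.
#' @param rate_heterogeneity Positive gamma shape for per-branch rate
#'   multipliers; 1 gives moderate variation, small values strong variation.
#' @param seed Optional integer seed; fixed seed gives a bit-identical tree.
#' @return A rooted [ape::phylo] object with `n_leaves` tips labelled
#'   `g001, g002, ...` and strictly positive branch lengths.
#' @examples
#' tr <- simulate_tree(10, rate_heterogeneity = 0.5, seed = 1)
#' ape::is.rooted(tr)
#' @export
simulate_tree <- function(n_leaves, rate_heterogeneity = 1, seed = NULL) {
  if (!is.numeric(n_leaves) || length(n_leaves) != 1L || n_leaves < 2)
    stop("n_leaves must be a single integer >= 2")
  if (!is.numeric(rate_heterogeneity) || rate_heterogeneity <= 0)
    stop("rate_heterogeneity must be a positive real")
  n_leaves <- as.integer(n_leaves)
  build <- function() {
    frags <- sprintf("g%03d", seq_len(n_leaves))
    while (length(frags) > 1L) {
      idx <- sample.int(length(frags), 2L)
      bl <- rexp(2L) * rgamma(2L, shape = rate_heterogeneity,
                              rate = rate_heterogeneity)
      bl <- pmax(bl, 1e-9)  # branch lengths strictly positive
      joined <- sprintf("(%s:%.10f,%s:%.10f)",
                        frags[idx[1L]], bl[1L], frags[idx[2L]], bl[2L])
      frags <- c(frags[-idx], joined)
    }
    ape::read.tree(text = paste0(frags, ";"))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Simulate a genome-by-marker copy-count table
#'
#' Emulates a CheckM-style lineage marker table. For each genome, every
#' marker is natively present with probability `true_completeness`; a present
#' marker gains an extra (contaminant) copy with probability
#' `true_contamination / true_completeness`, so that the expected fraction of
#' duplicated markers equals `true_contamination` and both the completeness
#' and the contamination estimators of [estimate_quality()] are unbiased.
#' Markers listed in `absent_markers` are zeroed in every genome, emulating
#' markers genuinely missing from an entire lineage.
#'
#' @param n_genomes Number of genomes (rows).
#' @param marker_ids Character vector of unique marker identifiers (columns).
#' @param true_completeness Per-genome fraction in `[0, 1]` (recycled).
#' @param true_contamination Per-genome non-negative fraction (recycled).
#' @param absent_markers Markers forced to zero copies in all genomes.
#' @param seed Optional integer seed.
#' @return A list with `table` (integer matrix, genomes x markers) and
#'   `truth` (data frame of the per-genome generating parameters).
#' @export
simulate_marker_table <- function(n_genomes, marker_ids,
                                  true_completeness = 1,
                                  true_contamination = 0,
                                  absent_markers = character(),
                                  seed = NULL) {
  if (length(marker_ids) == 0L) stop("marker_ids must be non-empty")
  if (anyDuplicated(marker_ids)) stop("marker_ids must be unique")
  comp <- rep_len(true_completeness, n_genomes)
  cont <- rep_len(true_contamination, n_genomes)
  if (any(comp < 0 | comp > 1)) stop("true_completeness must lie in [0, 1]")
  if (any(cont < 0)) stop("true_contamination must be non-negative")
  if (!all(absent_markers %in% marker_ids))
    stop("absent_markers must be a subset of marker_ids")
  m <- length(marker_ids)
  draw <- function() {
    p_dup <- ifelse(comp > 0, pmin(1, cont / comp), 0)
    present <- matrix(rbinom(n_genomes * m, 1L, rep(comp, m)),
                      nrow = n_genomes)
    extra <- matrix(rbinom(n_genomes * m, 1L, rep(p_dup, m)),
                    nrow = n_genomes) * present
    tab <- present + extra
    dimnames(tab) <- list(sprintf("mag%03d", seq_len(n_genomes)), marker_ids)
    tab[, marker_ids %in% absent_markers] <- 0L
    tab
  }
  tab <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(table = tab,
       truth = data.frame(genome = rownames(tab),
                          true_completeness = comp,
                          true_contamination = cont))
}

#' Simulate a clade-by-sample abundance dataset with known effects
#'
#' Counts are negative-binomial with mean
#' `library_size * exp(intercept + effect + seasonal)` and variance
#' `mu + alpha * mu^2` (the dispersion parameterisation optimised by the
#' model-fitting functions). The per-clade `coefficients` act on a single
#' covariate, which may be numeric (slope per clade) or a factor
#' (treatment-coded effects per non-reference level, rows = clades). The
#' seasonal term is `seasonal_amplitude * sin(2 * pi * time / 12)`, an annual
#' cycle over a monthly `time` covariate.
#'
#' @param n_samples,n_clades Dimensions of the count matrix.
#' @param coefficients Numeric vector (length `n_clades`) for a numeric
#'   covariate, or matrix `n_clades x (nlevels - 1)` for a factor covariate.
#' @param dispersion_alpha Positive NB dispersion alpha (`Var = mu + alpha mu^2`).
#'   Values below 1e-10 are treated as the Poisson limit.
#' @param covariates Per-sample covariate (numeric vector or factor); default
#'   standard-normal draws.
#' @param seasonal_amplitude Non-negative amplitude of the annual sinusoid.
#' @param time Per-sample time in months (required if `seasonal_amplitude > 0`;
#'   defaults to `1:n_samples`).
#' @param library_sizes Per-sample multipliers; default log-normal around 1.
#' @param intercept Log-scale baseline mean (default `log(50)`).
#' @param seed Optional integer seed.
#' @return An `abundance_dataset`: list with `counts` (clades x samples),
#'   `metadata` (data frame with the covariate and `time`), `library_sizes`,
#'   and `truth` (generating parameters, including the per-sample true mean
#'   matrix `mu`).
#' @export
simulate_counts <- function(n_samples, n_clades, coefficients = 0,
                            dispersion_alpha = 0.5, covariates = NULL,
                            seasonal_amplitude = 0, time = NULL,
                            library_sizes = NULL, intercept = log(50),
                            seed = NULL) {
  if (dispersion_alpha <= 0) stop("dispersion_alpha must be > 0")
  if (seasonal_amplitude < 0) stop("seasonal_amplitude must be non-negative")
  draw <- function() {
    x <- if (is.null(covariates)) rnorm(n_samples) else covariates
    if (length(x) != n_samples) stop("covariates must have length n_samples")
    tm <- if (is.null(time)) seq_len(n_samples) else time
    lib <- if (is.null(library_sizes)) exp(rnorm(n_samples, 0, 0.3)) else library_sizes
    if (is.factor(x) || is.character(x)) {
      x <- factor(x)
      B <- coefficients
      if (is.null(dim(B))) B <- matrix(B, nrow = n_clades, ncol = nlevels(x) - 1L)
      if (nrow(B) != n_clades || ncol(B) != nlevels(x) - 1L)
        stop("coefficients must be n_clades x (nlevels - 1) for a factor covariate")
      mm <- model.matrix(~x)[, -1L, drop = FALSE]
      eff <- B %*% t(mm)
    } else {
      beta <- rep_len(coefficients, n_clades)
      eff <- outer(beta, x)
      B <- beta
    }
    seas <- seasonal_amplitude * sin(2 * pi * tm / 12)
    eta <- intercept + eff + matrix(seas, n_clades, n_samples, byrow = TRUE)
    mu <- sweep(exp(eta), 2L, lib, `*`)
    cnt <- if (dispersion_alpha < 1e-10) {
      rpois(length(mu), lambda = mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / dispersion_alpha)
    }
    counts <- matrix(cnt, n_clades, n_samples,
                     dimnames = list(sprintf("clade%03d", seq_len(n_clades)),
                                     sprintf("s%03d", seq_len(n_samples))))
    meta <- data.frame(sample = colnames(counts), covariate = x, time = tm,
                       stringsAsFactors = FALSE)
    structure(list(counts = counts, metadata = meta, library_sizes = lib,
                   truth = list(coefficients = B, intercept = intercept,
                                dispersion_alpha = dispersion_alpha,
                                seasonal_amplitude = seasonal_amplitude,
                                mu = mu)),
              class = "abundance_dataset")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Amino-acid alphabet used by the alignment simulator (20 standard residues).
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a proteorhodopsin protein alignment with known tuning classes
#'
#' Generates a fixed-width protein alignment in which the spectral-tuning
#' column (default 315) carries methionine (M) for shallow-photic (`SP`,
#' green-absorbing) sequences and glutamine (Q) for deep-photic (`DP`,
#' blue-absorbing) sequences, and the proton-donor column (default 318)
#' carries lysine (K) for `SP` and glutamic acid (E) for `DP`. All other
#' columns are uniform random residues. Gaps can be injected at chosen
#' (sequence, column) positions to create degenerate cases.
#'
#' @param n_seqs Number of sequences.
#' @param class_labels Per-sequence label, `"SP"` or `"DP"` (recycled).
#' @param seed Optional integer seed.
#' @param width Alignment width in columns (must cover the indexed columns).
#' @param pos_tuning,pos_donor 1-based alignment columns of the tuning and
#'   donor residues.
#' @param gaps Optional data frame with columns `seq` (index or id) and `col`;
#'   each entry replaces that residue with `-`.
#' @return A list with `alignment` (a named [Biostrings::AAStringSet]) and
#'   `truth` (data frame of the planted class labels).
#' @export
simulate_pr_alignment <- function(n_seqs, class_labels = "SP", seed = NULL,
                                  width = 660, pos_tuning = 315,
                                  pos_donor = 318, gaps = NULL) {
  labs <- rep_len(as.character(class_labels), n_seqs)
  if (!all(labs %in% c("SP", "DP")))
    stop("class_labels must be 'SP' or 'DP'")
  if (width < max(pos_tuning, pos_donor))
    stop("width must cover pos_tuning and pos_donor")
  draw <- function() {
    m <- matrix(sample(AA20, n_seqs * width, replace = TRUE),
                nrow = n_seqs, ncol = width)
    m[, pos_tuning] <- ifelse(labs == "SP", "M", "Q")
    m[, pos_donor]  <- ifelse(labs == "SP", "K", "E")
    m
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  ids <- sprintf("pr%03d", seq_len(n_seqs))
  if (!is.null(gaps)) {
    for (k in seq_len(nrow(gaps))) {
      i <- gaps$seq[k]
      if (is.character(i)) i <- match(i, ids)
      m[i, gaps$col[k]] <- "-"
    }
  }
  aln <- Biostrings::AAStringSet(apply(m, 1L, paste, collapse = ""))
  names(aln) <- ids
  list(alignment = aln, truth = data.frame(id = ids, label = labs))
}
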