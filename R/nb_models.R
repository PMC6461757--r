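# NB log-likelihood at dispersion alpha (Var = mu + alpha * mu^2).
nb_loglik <- function(y, mu, alpha) {
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
}

# Fit a fixed-alpha NB log-link GLM and return its AIC (2k - 2 loglik,
# alpha counted as one parameter). Returns Inf on failure.
nb_fit_alpha <- function(formula, data, offset, alpha) {
  data$.off <- offset
  fit <- tryCatch(
    suppressWarnings(glm(formula, data = data, offset = .off,
                         family = MASS::negative.binomial(theta = 1 / alpha,
                                                          link = "log"))),
    error = function(e) NULL)
  if (is.null(fit)) return(list(aic = Inf, fit = NULL))
  ll <- nb_loglik(data$.y, fitted(fit), alpha)
  list(aic = 2 * (length(coef(fit)) + 1) - 2 * ll, fit = fit, loglik = ll)
}

# Bounded 1-D AIC minimisation over log(alpha).
nb_optimise_alpha <- function(formula, data, offset,
                              alpha_bounds = c(1e-6, 1e3), alpha_tol = 1e-3) {
  obj <- function(la) nb_fit_alpha(formula, data, offset, exp(la))$aic
  opt <- optimize(obj, interval = log(alpha_bounds), tol = alpha_tol)
  alpha <- exp(opt$minimum)
  res <- nb_fit_alpha(formula, data, offset, alpha)
  if (!is.finite(res$aic)) stop("NB fit failed across the alpha range")
  c(res, list(alpha = alpha))
}

# Resolve size factors for an abundance dataset (stored or recomputed).
dataset_size_factors <- function(dataset) {
  if (!is.null(dataset$size_factors)) return(dataset$size_factors)
  scale_by_library_size(dataset$counts)$size_factors
}

#' Negative-binomial GLM of one clade's abundance on one variable
#'
#' Fits a log-link NB regression of a clade's counts on a single metadata
#' variable, with `log(size factor)` offsets carrying the median-of-ratios
#' library scaling. Rows with missing values of the variable are dropped
#' before fitting. The NB dispersion `alpha` (`Var = mu + alpha * mu^2`) is
#' chosen by bounded 1-D minimisation of the fit's AIC on the log-alpha
#' scale. Categorical variables use treatment coding against a reference
#' level or sum-to-zero (deviation) coding with an omitted level; see
#' [select_reference_level()] for choosing that level by AIC. Wald tests are
#' returned per coefficient and as a block chi-square test for the whole
#' variable.
#'
#' @param dataset An `abundance_dataset` (list with `counts`, `metadata`,
#'   optional `size_factors`).
#' @param clade Row name or index into `counts`.
#' @param variable Column of `metadata`.
#' @param coding `"treatment"` or `"sum"` (categorical variables only).
#' @param reference Reference (treatment) or omitted (sum) level; default
#'   first sorted level.
#' @param alpha_bounds,alpha_tol Search interval for alpha and tolerance of
#'   the log-alpha optimisation.
#' @return An `nb_glm_fit`: list with `clade`, `variable`, `coding`,
#'   `reference`, `coefficients` (term, estimate, se, z, p), `alpha`, `aic`,
#'   `loglik`, `wald` (block statistic, df, p), `converged`, `n`.
#' @export
fit_nb_glm <- function(dataset, clade, variable, coding = c("treatment", "sum"),
                       reference = NULL, alpha_bounds = c(1e-6, 1e3),
                       alpha_tol = 1e-3) {
  coding <- match.arg(coding)
  y <- dataset$counts[clade, ]
  x <- dataset$metadata[[variable]]
  if (is.null(x)) stop("variable '", variable, "' absent from metadata")
  sf <- dataset_size_factors(dataset)
  ok <- !is.na(x)
  y <- as.numeric(y[ok]); x <- x[ok]; off <- log(sf[ok])
  if (length(unique(x)) < 2L)
    stop("variable '", variable, "' is constant after dropping missing rows")
  if (is.character(x)) x <- factor(x)
  contrast <- NULL
  if (is.factor(x)) {
    x <- droplevels(x)
    lv <- sort(levels(x))
    if (is.null(reference)) reference <- lv[1L]
    if (!reference %in% lv) stop("reference level not observed")
    if (coding == "treatment") {
      x <- factor(x, levels = c(reference, setdiff(lv, reference)))
      contrast <- "contr.treatment"
    } else {
      x <- factor(x, levels = c(setdiff(lv, reference), reference))
      contrast <- "contr.sum"
    }
  } else reference <- NULL
  data <- data.frame(.y = y, .x = x)
  if (!is.null(contrast)) contrasts(data$.x) <- contrast
  res <- nb_optimise_alpha(.y ~ .x, data, off, alpha_bounds, alpha_tol)
  fit <- res$fit
  smry <- summary(fit, dispersion = 1)  # NB variance is fully specified
  sm <- smry$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                      se = sm[, 2L], z = sm[, 3L], p = sm[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  nonint <- which(coefs$term != "(Intercept)")
  b <- coef(fit)[nonint]
  V <- smry$cov.scaled[nonint, nonint, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  structure(list(clade = clade, variable = variable, coding = coding,
                 reference = reference, coefficients = coefs,
                 alpha = res$alpha, aic = res$aic, loglik = res$loglik,
                 wald = list(statistic = W, df = length(b),
                             p = pchisq(W, length(b), lower.tail = FALSE)),
                 converged = fit$converged, n = length(y)),
            class = "nb_glm_fit")
}

#' @export
print.nb_glm_fit <- function(x, ...) {
  cat(sprintf("NB GLM: clade %s ~ %s (%s coding%s)\n", x$clade, x$variable,
              x$coding,
              if (is.null(x$reference)) "" else paste0(", ref ", x$reference)))
  cat(sprintf("  alpha = %.4g, AIC = %.2f, block Wald p = %.3g, n = %d\n",
              x$alpha, x$aic, x$wald$p, x$n))
  print.data.frame(x$coefficients, digits = 4, ...)
  invisible(x)
}

#' Choose the reference / omitted level of a categorical variable by AIC
#'
#' Fits one NB GLM per candidate level (as the treatment reference or the
#' sum-coding omitted level) and returns the level whose model minimises the
#' AIC; ties go to the first level in sorted order. Candidates whose fit
#' fails are skipped with a warning.
#'
#' @inheritParams fit_nb_glm
#' @return List with `reference`, `fit` (the winning `nb_glm_fit`), and
#'   `aic_table` (level, aic).
#' @export
select_reference_level <- function(dataset, clade, variable,
                                   coding = c("treatment", "sum"), ...) {
  coding <- match.arg(coding)
  x <- dataset$metadata[[variable]]
  if (!(is.factor(x) || is.character(x)))
    stop("reference-level selection needs a categorical variable")
  lv <- sort(unique(as.character(x[!is.na(x)])))
  if (length(lv) < 2L) stop("variable has fewer than 2 observed levels")
  fits <- lapply(lv, function(l) {
    tryCatch(fit_nb_glm(dataset, clade, variable, coding, reference = l, ...),
             error = function(e) {
               warning("candidate level '", l, "' skipped: ",
                       conditionMessage(e))
               NULL
             })
  })
  aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$aic, numeric(1L))
  if (all(is.infinite(aics))) stop("every candidate reference fit failed")
  best <- which.min(aics)  # first minimum = first sorted level on ties
  list(reference = lv[best], fit = fits[[best]],
       aic_table = data.frame(level = lv, aic = aics,
                              stringsAsFactors = FALSE))
}

#' Benjamini-Hochberg screen over clade-variable NB fits
#'
#' Variable-level (block Wald) p values are BH-adjusted across clades,
#' either within each variable (default) or over all fits at once; variables
#' with adjusted p at or below `variable_threshold` are kept. Within kept
#' fits, per-coefficient p values are BH-adjusted over the same family scope
#' and coefficients at or below `coefficient_threshold` are reported with
#' the sign of their estimate (positive association = `+`, negative = `-`).
#'
#' @param fits List of `nb_glm_fit` objects.
#' @param variable_threshold FDR threshold for a variable (default 0.1).
#' @param coefficient_threshold FDR threshold for a coefficient (default 0.05).
#' @param family BH family: `"variable"` (adjust across clades within each
#'   variable) or `"global"`.
#' @return List with `variables` (clade, variable, p, p_adj, significant) and
#'   `coefficients` (significant coefficients of kept variables, with sign).
#' @export
significance_screen <- function(fits, variable_threshold = 0.1,
                                coefficient_threshold = 0.05,
                                family = c("variable", "global")) {
  family <- match.arg(family)
  if (length(fits) == 0L) stop("empty fit list")
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(fits) == 0L) stop("no converged fits to screen")
  vt <- data.frame(clade = vapply(fits, `[[`, character(1L), "clade"),
                   variable = vapply(fits, `[[`, character(1L), "variable"),
                   p = vapply(fits, function(f) f$wald$p, numeric(1L)),
                   stringsAsFactors = FALSE)
  grp <- if (family == "variable") vt$variable else rep("all", nrow(vt))
  vt$p_adj <- ave(vt$p, grp, FUN = function(p) p.adjust(p, "BH"))
  vt$significant <- vt$p_adj <= variable_threshold
  kept <- which(vt$significant)
  coefs <- do.call(rbind, lapply(kept, function(i) {
    cc <- fits[[i]]$coefficients
    cc <- cc[cc$term != "(Intercept)", , drop = FALSE]
    if (nrow(cc) == 0L) return(NULL)
    cbind(clade = vt$clade[i], variable = vt$variable[i], cc,
          stringsAsFactors = FALSE)
  }))
  if (!is.null(coefs) && nrow(coefs)) {
    cg <- if (family == "variable") coefs$variable else rep("all", nrow(coefs))
    coefs$p_adj <- ave(coefs$p, cg, FUN = function(p) p.adjust(p, "BH"))
    coefs <- coefs[coefs$p_adj <= coefficient_threshold, , drop = FALSE]
    coefs$sign <- ifelse(coefs$estimate > 0, "+", "-")
    rownames(coefs) <- NULL
  }
  list(variables = vt, coefficients = coefs)
}

#' Negative-binomial GAM: cubic-spline smooth of a count time series
#'
#' Fits a log-link NB regression of counts on a cubic B-spline basis of
#' time. The spline degrees of freedom (3 to 9 by default) and the NB
#' dispersion alpha are chosen jointly by minimising the AIC: alpha is
#' optimised within each candidate df, and the df with the smallest AIC
#' wins. A pointwise Wald confidence band is computed on the linear
#' predictor and transformed through the log link.
#'
#' @param y Count vector (a clade's time series), at least 10 points.
#' @param time Numeric time covariate (e.g. months).
#' @param df_range Candidate spline degrees of freedom (default `3:9`;
#'   truncated with a warning when the series is too short for the larger
#'   values).
#' @param size_factors Optional per-point library size factors (offsets).
#' @param level Confidence level of the pointwise band (default 0.95).
#' @inheritParams fit_nb_glm
#' @return An `nb_gam_fit`: list with `spline_df`, `alpha`, `aic`,
#'   `aic_table`, `time`, `fitted` (mean scale), `lower`, `upper`,
#'   `converged`.
#' @export
fit_nb_gam <- function(y, time, df_range = 3:9, size_factors = NULL,
                       level = 0.95, alpha_bounds = c(1e-6, 1e3),
                       alpha_tol = 1e-3) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 time points")
  if (length(time) != n) stop("time must match y in length")
  max_df <- n - 2L
  if (any(df_range > max_df)) {
    warning("series too short for df > ", max_df, "; range truncated")
    df_range <- df_range[df_range <= max_df]
  }
  off <- if (is.null(size_factors)) rep(0, n) else log(size_factors)
  cands <- lapply(df_range, function(df) {
    B <- splines::bs(time, df = df, degree = 3L)
    data <- data.frame(.y = as.numeric(y), B = I(B))
    res <- tryCatch(nb_optimise_alpha(.y ~ B, data, off, alpha_bounds,
                                      alpha_tol),
                    error = function(e) list(aic = Inf))
    c(res, list(df = df, B = B))
  })
  aics <- vapply(cands, `[[`, numeric(1L), "aic")
  if (all(is.infinite(aics))) stop("no spline fit converged")
  best <- cands[[which.min(aics)]]
  fit <- best$fit
  X <- model.matrix(fit)
  eta <- drop(X %*% coef(fit)) + off
  V <- summary(fit, dispersion = 1)$cov.scaled
  se_eta <- sqrt(rowSums((X %*% V) * X))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(spline_df = best$df, alpha = best$alpha, aic = best$aic,
                 aic_table = data.frame(df = df_range, aic = aics),
                 time = time, fitted = exp(eta),
                 lower = exp(eta - z * se_eta),
                 upper = exp(eta + z * se_eta),
                 converged = fit$converged),
            class = "nb_gam_fit")
}

#' @export
print.nb_gam_fit <- function(x, ...) {
  cat(sprintf("NB GAM: cubic spline df = %d, alpha = %.4g, AIC = %.2f\n",
              x$spline_df, x$alpha, x$aic))
  invisible(x)
}

#' Flag groups whose confidence interval excludes the grand mean
#'
#' The baseline is the mean of the group means (grand mean); a group differs
#' from baseline when its Wald confidence interval excludes it. The flags
#' are invariant under relabelling of the groups.
#'
#' @param group_stats Data frame with columns `group`, `mean`, `se`.
#' @param level Confidence level (default 0.95).
#' @return The input with `lower`, `upper`, `baseline`, and logical
#'   `differs`.
#' @export
baseline_contrast <- function(group_stats, level = 0.95) {
  if (nrow(group_stats) < 2L) stop("need at least 2 groups")
  z <- qnorm(1 - (1 - level) / 2)
  grand <- mean(group_stats$mean)
  group_stats$lower <- group_stats$mean - z * group_stats$se
  group_stats$upper <- group_stats$mean + z * group_stats$se
  group_stats$baseline <- grand
  group_stats$differs <- grand < group_stats$lower |
    grand > group_stats$upper
  group_stats
}
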