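toy_counts <- function() {
  m <- rbind(c(2, 4, 8), c(3, 6, 12), c(4, 8, 16), c(5, 10, 20))
  dimnames(m) <- list(sprintf("c%d", 1:4), sprintf("s%d", 1:3))
  m
}

test_that("median-of-ratios size factors match hand computation", {
  sf <- scale_by_library_size(toy_counts())$size_factors
  # geometric means per clade: 4, 6, 8, 10 -> all ratios 0.5, 1, 2
  expect_equal(unname(sf), c(0.5, 1, 2))

  same <- matrix(5, 3, 4, dimnames = list(NULL, sprintf("s%d", 1:4)))
  expect_equal(unname(scale_by_library_size(same)$size_factors),
               rep(1, 4))

  # multiplying one sample by c multiplies its factor by c relative to the
  # other samples, and leaves scaled counts unchanged, both up to the single
  # global c^(1/n) shift of the geometric-mean pseudo-reference
  m <- toy_counts()
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  r1 <- scale_by_library_size(m); r2 <- scale_by_library_size(m2)
  expect_equal(unname(r2$size_factors / r1$size_factors),
               c(1, 3, 1) * 3^(-1 / 3))
  expect_equal(r2$scaled, r1$scaled * 3^(1 / 3))

  sparse <- rbind(c(0, 3, 4), c(5, 0, 6), c(7, 8, 0))
  expect_error(scale_by_library_size(sparse), "pseudo_count")
  expect_no_error(scale_by_library_size(sparse, pseudo_count = 1))
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  m <- simulate_counts(12, 30, coefficients = 0.3, dispersion_alpha = 0.3,
                       seed = 10)$counts
  m <- m[rowSums(m == 0) == 0, ]
  expect_equal(unname(scale_by_library_size(m)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("sparse-sample exclusion applies the fair-share rule", {
  eq <- matrix(10, 5, 20, dimnames = list(NULL, sprintf("s%02d", 1:20)))
  expect_length(exclude_sparse_samples(eq)$dropped, 0L)

  z <- eq; z[, 3] <- 0
  expect_equal(exclude_sparse_samples(z)$dropped, "s03")

  # 6 of 20 samples planted below 5% of the uniform share
  m <- matrix(100, 4, 20, dimnames = list(NULL, sprintf("s%02d", 1:20)))
  m[, 1:6] <- 0.2  # share ~0.1% of fair share
  expect_length(exclude_sparse_samples(m, 0.05)$dropped, 6L)
  expect_error(exclude_sparse_samples(m, 1.5), "min_fraction")
})

test_that("intercept-only data recovers log(c) and dropped-missing rules hold", {
  n <- 40
  ds <- list(counts = matrix(7, 1, n, dimnames = list("k", NULL)),
             metadata = data.frame(x = rnorm(n)),
             size_factors = rep(1, n))
  f <- fit_nb_glm(ds, "k", "x")
  expect_equal(f$coefficients$estimate[1], log(7), tolerance = 1e-4)
  expect_equal(f$coefficients$estimate[2], 0, tolerance = 1e-4)

  ds$metadata$x <- c(rep(NA, 20), rep(1, 20))
  expect_error(fit_nb_glm(ds, "k", "x"), "constant")
  expect_error(fit_nb_glm(ds, "k", "nope"), "absent")
})

test_that("NB dispersion lands at a local AIC minimum", {
  ds <- simulate_counts(300, 1, coefficients = 0.5, dispersion_alpha = 0.5,
                        library_sizes = rep(1, 300), seed = 11)
  ds$size_factors <- rep(1, 300)
  f <- fit_nb_glm(ds, "clade001", "covariate")
  d <- data.frame(.y = as.numeric(ds$counts[1, ]),
                  .x = ds$metadata$covariate)
  off <- rep(0, 300)
  aic_at <- function(a) magpipe:::nb_fit_alpha(.y ~ .x, d, off, a)$aic
  expect_lte(f$aic, aic_at(f$alpha * 2))
  expect_lte(f$aic, aic_at(f$alpha / 2))
  expect_gt(f$alpha, 0)
  expect_lt(abs(f$alpha - 0.5), 0.25)
})

test_that("reference-level choice minimises AIC over every candidate", {
  x <- factor(rep(c("low", "mid", "high"), length.out = 90))
  ds <- simulate_counts(90, 1, coefficients = matrix(c(0.8, -0.4), 1),
                        dispersion_alpha = 0.3, covariates = x,
                        library_sizes = rep(1, 90), seed = 12)
  ds$size_factors <- rep(1, 90)
  sel <- select_reference_level(ds, "clade001", "covariate")
  expect_true(all(is.finite(sel$aic_table$aic)))
  expect_equal(nrow(sel$aic_table), 3L)
  # exhaustive oracle: winner's AIC <= every alternative
  expect_true(all(sel$fit$aic <= sel$aic_table$aic + 1e-9))
  # deterministic across reruns
  sel2 <- select_reference_level(ds, "clade001", "covariate")
  expect_identical(sel$reference, sel2$reference)

  # sum-to-zero coding also fits every omitted-level candidate
  sel3 <- select_reference_level(ds, "clade001", "covariate", coding = "sum")
  expect_true(all(is.finite(sel3$aic_table$aic)))
})

test_that("BH screen matches the hand-worked step-up example", {
  fits <- mapply(fake_fit, sprintf("c%d", 1:5), "temp",
                 c(0.01, 0.02, 0.03, 0.04, 0.2),
                 SIMPLIFY = FALSE)
  # sorted p(i) <= (i/5) * 0.05 holds for the first four
  res <- significance_screen(fits, variable_threshold = 0.05)
  expect_equal(sum(res$variables$significant), 4L)

  none <- significance_screen(mapply(fake_fit, sprintf("c%d", 1:4), "t",
                                     1, SIMPLIFY = FALSE))
  expect_equal(sum(none$variables$significant), 0L)

  one <- significance_screen(list(fake_fit("c1", "t", 0.04)),
                             variable_threshold = 0.05)
  expect_equal(sum(one$variables$significant), 1L)  # BH(m = 1) = raw p
  expect_error(significance_screen(list()), "empty")
})

test_that("significant coefficients carry the sign of the association", {
  fits <- list(fake_fit("up", "temp", 1e-4, 1e-4, estimate = 2),
               fake_fit("down", "temp", 1e-4, 1e-4, estimate = -2))
  res <- significance_screen(fits)
  expect_equal(res$coefficients$sign[res$coefficients$clade == "up"], "+")
  expect_equal(res$coefficients$sign[res$coefficients$clade == "down"], "-")
})

test_that("NB GAM: constant series gives a flat smooth with honest band", {
  y <- rep(20, 15)
  g <- fit_nb_gam(y, 1:15)
  expect_lt(diff(range(g$fitted)), 1e-3)
  expect_true(all(g$lower <= 20 & g$upper >= 20))
  expect_true(g$spline_df >= 3 && g$spline_df <= 9)

  expect_warning(fit_nb_gam(rep(c(3, 9), 5), 1:10), "truncated")
  expect_error(fit_nb_gam(rep(5, 8), 1:8), "at least 10")
})

test_that("baseline contrast flags only genuinely shifted groups", {
  same <- data.frame(group = c("a", "b", "c"), mean = 5, se = 0.5)
  expect_false(any(baseline_contrast(same)$differs))

  shifted <- data.frame(group = c("a", "b", "c", "d"),
                        mean = c(5, 5, 5, 5 + 5 * 0.5), se = 0.5)
  bc <- baseline_contrast(shifted)
  expect_true(bc$differs[bc$group == "d"])
  expect_false(any(bc$differs[bc$group != "d"]))

  # invariant under relabelling
  relab <- shifted[c(4, 1, 3, 2), ]
  expect_equal(sum(baseline_contrast(relab)$differs), sum(bc$differs))
  expect_error(baseline_contrast(same[1, ]), "2 groups")
})

test_that("single-copy ribosomal normalisation is a plain mean ratio", {
  expect_equal(normalize_by_single_copy(10, c(4, 5, 6, 5, 5)), 2.0)
  expect_equal(normalize_by_single_copy(5, rep(5, 5)), 1.0)
  expect_equal(normalize_by_single_copy(20, 2 * c(4, 5, 6, 5, 5)),
               normalize_by_single_copy(10, c(4, 5, 6, 5, 5)))
  expect_warning(r <- normalize_by_single_copy(3, rep(0, 5)), "zero")
  expect_true(is.na(r))
  expect_error(normalize_by_single_copy(3, 1:4), "five")
})
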