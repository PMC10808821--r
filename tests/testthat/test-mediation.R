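test_that("path coefficients match the normal-equations oracle on a toy", {
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8),
                  m = c(2, 1, 4, 3, 6, 5, 8, 7),
                  y = c(1, 3, 2, 5, 4, 7, 6, 9))
  fit <- fit_mediation(d, "x", "m", "y", boot = 0)
  Xa <- cbind(1, d$x)
  Xb <- cbind(1, d$x, d$m)
  a <- ols_brute(Xa, d$m)[2]
  cb <- ols_brute(Xb, d$y)
  expect_equal(fit$a_path, a, tolerance = 1e-12)
  expect_equal(fit$c_direct, cb[2], tolerance = 1e-12)
  expect_equal(fit$b_path, cb[3], tolerance = 1e-12)
  expect_equal(fit$indirect, fit$a_path * fit$b_path)
  expect_equal(fit$total, fit$indirect + fit$c_direct)
})

test_that("indirect plus direct equals the total-model exposure coefficient", {
  # product-of-coefficients and difference-of-coefficients estimators
  # coincide in linear models with a shared covariate set
  for (s in 1:6) {
    sc <- toy_synthetic(seed = s, n = 120)
    d <- sc$cohort
    d$amed_total <- compute_amed_scores(d, d$sex)$total
    d$med <- sc$taxa[d$sample_id, "Family05"]
    covs <- default_covariates("sat")
    fit <- fit_mediation(d, "amed_total", "med", "sat", covs, boot = 0)
    total_model <- fit_adjusted_model(d, "amed_total", "sat", covs)
    expect_equal(fit$total, total_model$beta, tolerance = 1e-8)
  }
})

test_that("a null exposure-mediator path yields a near-zero proportion", {
  props <- vapply(1:10, function(s) {
    sc <- toy_synthetic(seed = s, n = 400, diet_effect_a = 0)
    d <- sc$cohort
    d$amed_total <- compute_amed_scores(d, d$sex)$total
    d$med <- sc$taxa[d$sample_id, "Family05"]
    fit_mediation(d, "amed_total", "med", "sat",
                  default_covariates("sat"), boot = 0)$proportion_mediated
  }, numeric(1))
  expect_lt(abs(mean(props)), 3)
})

test_that("near-zero totals are flagged undefined, not infinite", {
  set.seed(41)
  d <- data.frame(x = rnorm(50), m = rnorm(50))
  d$y <- rnorm(50)
  fit <- fit_mediation(d, "x", "m", "y", boot = 0, total_tol = 10)
  expect_true(fit$undefined)
  expect_true(is.na(fit$proportion_mediated))

  d$m2 <- d$m
  d$m2[] <- 1
  expect_error(fit_mediation(d, "x", "m2", "y", boot = 0),
               class = "amediate_validation_error")
})

test_that("bootstrap CIs are seed-deterministic and cover the truth", {
  sc <- toy_synthetic(seed = 11, n = 300)
  d <- sc$cohort
  d$amed_total <- compute_amed_scores(d, d$sex)$total
  d$med <- sc$taxa[d$sample_id, "Family05"]
  covs <- default_covariates("sat")
  f1 <- fit_mediation(d, "amed_total", "med", "sat", covs, boot = 200, seed = 99)
  f2 <- fit_mediation(d, "amed_total", "med", "sat", covs, boot = 200, seed = 99)
  expect_identical(f1$prop_ci, f2$prop_ci)
  expect_true(f1$prop_ci[1] < f1$proportion_mediated)
  expect_true(f1$prop_ci[2] > f1$proportion_mediated)

  # reduced-scale coverage check: truth is 20% by construction
  covered <- vapply(1:20, function(s) {
    sc <- toy_synthetic(seed = s, n = 300)
    d <- sc$cohort
    d$amed_total <- compute_amed_scores(d, d$sex)$total
    d$med <- sc$taxa[d$sample_id, "Family05"]
    ci <- fit_mediation(d, "amed_total", "med", "sat", covs,
                        boot = 200, seed = s)$prop_ci
    ci[1] <= 20 && 20 <= ci[2]
  }, logical(1))
  expect_gte(sum(covered), 16)  # ~95% nominal, binomial slack at 20 reps
})

test_that("PCA combination reproduces its closed forms and the eigen oracle", {
  n <- 80
  set.seed(43)
  base <- runif(n)
  # two perfectly correlated taxa: rank-1 correlation
  taxa <- cbind(a = 2 + base, b = 5 + 3 * base)
  rownames(taxa) <- paste0("s", 1:n)
  pc <- combine_mediators_pca(taxa, c("a", "b"))
  expect_equal(pc$variance_explained, 1, tolerance = 1e-10)
  expect_equal(abs(unname(pc$loadings)), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(sum(pc$loadings^2), 1)

  # two uncorrelated taxa: identity correlation, half the variance each
  u <- scale(rnorm(n))[, 1]
  v <- scale(residuals(lm(rnorm(n) ~ u)))[, 1]
  taxa2 <- cbind(a = 10 + u, b = 10 + v)
  rownames(taxa2) <- paste0("s", 1:n)
  pc2 <- combine_mediators_pca(taxa2, c("a", "b"))
  expect_equal(pc2$variance_explained, 0.5, tolerance = 1e-8)

  # five random taxa vs a dense eigendecomposition
  taxa5 <- matrix(rexp(5 * n), n, 5, dimnames = list(paste0("s", 1:n), letters[1:5]))
  taxa5 <- taxa5 / rowSums(taxa5) * 100
  pc5 <- combine_mediators_pca(taxa5, letters[1:5])
  eg <- eigen(cor(taxa5), symmetric = TRUE)
  expect_equal(pc5$variance_explained, eg$values[1] / sum(eg$values))
  expect_equal(abs(unname(pc5$loadings)), abs(eg$vectors[, 1]), tolerance = 1e-8)
  expect_gt(pc5$loadings[which.max(abs(pc5$loadings))], 0)

  expect_error(combine_mediators_pca(taxa5, "a"), class = "amediate_validation_error")
})

test_that("a redundant-copy PCA mediator does at least as well as one copy", {
  # noise-free limit: two exact affine copies of the true mediator
  sc <- toy_synthetic(seed = 13, n = 300)
  d <- sc$cohort
  d$amed_total <- compute_amed_scores(d, d$sex)$total
  med <- sc$taxa[d$sample_id, "Family05"]
  taxa <- cbind(c1 = med, c2 = 1 + 2 * med)
  rownames(taxa) <- d$sample_id
  covs <- default_covariates("sat")
  d$m_single <- med
  p_single <- fit_mediation(d, "amed_total", "m_single", "sat", covs,
                            boot = 0)$proportion_mediated
  pc <- combine_mediators_pca(taxa / max(taxa) , c("c1", "c2"))
  d$m_pca <- pc$component_scores
  p_pca <- fit_mediation(d, "amed_total", "m_pca", "sat", covs,
                         boot = 0)$proportion_mediated
  expect_gte(p_pca + 1e-8, p_single)
})

test_that("the mediation report preserves signed proportions and layout", {
  sc <- toy_synthetic(seed = 15, n = 200)
  d <- sc$cohort
  d$amed_total <- compute_amed_scores(d, d$sex)$total
  d$med <- sc$taxa[d$sample_id, "Family05"]
  r1 <- fit_mediation(d, "amed_total", "med", "sat",
                      default_covariates("sat"), boot = 50, seed = 1)
  r2 <- r1
  r2$proportion_mediated <- -8.7
  r2$outside_range <- TRUE
  rep_ <- mediation_report(list(r1, r2))
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$proportion_mediated_pct[2], -8.7)  # sign passed through
  expect_true(rep_$outside_range[2])
  expect_true(all(c("b_path", "b_ci_low", "b_ci_high", "b_p", "n") %in% names(rep_)))
  expect_error(mediation_report(list()), class = "amediate_validation_error")
})
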