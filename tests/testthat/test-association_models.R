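test_that("CRP preparation imputes below-LOD values as LOD/sqrt(2) then logs", {
  expect_equal(prepare_crp(0.5, lod = 0.9), log(0.9 / sqrt(2)))
  expect_equal(prepare_crp(0.9, lod = 0.9), log(0.9))  # boundary not imputed
  expect_equal(prepare_crp(c(0.5, 2.6), lod = 0.9),
               c(log(0.9 / sqrt(2)), log(2.6)))
  expect_error(prepare_crp(c(1, -0.1)), class = "amediate_validation_error")
})

test_that("percent change back-transform is exact and monotone", {
  expect_equal(unname(percent_change(0)["estimate"]), 0)
  expect_equal(unname(percent_change(log(0.8))["estimate"]), -20)
  expect_equal(unname(percent_change(0.25)["estimate"]), 100 * (exp(1)^0.25 - 1))
  pc <- percent_change(0.1, -0.2, 0.4)
  expect_true(pc["ci_low"] < pc["estimate"] && pc["estimate"] < pc["ci_high"])
})

test_that("a two-group model with no covariates returns the mean difference", {
  d <- data.frame(g = factor(c(0, 0, 0, 1, 1, 1)),
                  y = c(1, 2, 3, 7, 8, 9))
  fit <- fit_adjusted_model(d, "g", "y")
  expect_equal(fit$beta, mean(d$y[4:6]) - mean(d$y[1:3]))
  expect_equal(fit$adjusted_means$estimate, c(2, 8))
  # matches the normal-equations solve
  X <- cbind(1, as.numeric(d$g))
  expect_equal(fit$beta, ols_brute(X, d$y)[2])
})

test_that("model fits equal normal-equations solutions on random designs", {
  set.seed(31)
  for (i in 1:20) {
    n <- 40
    d <- data.frame(y = rnorm(n), x = rnorm(n), w1 = rnorm(n),
                    w2 = factor(sample(c("a", "b", "c"), n, TRUE)))
    fit <- fit_adjusted_model(d, "x", "y", c("w1", "w2"))
    X <- model.matrix(~ x + w1 + w2, d)
    expect_equal(fit$beta, ols_brute(X, d$y)[["x"]], tolerance = 1e-8)
  }
})

test_that("tertile-size-weighted adjusted means recover the raw mean", {
  sc <- toy_synthetic(seed = 2, n = 150)
  d <- sc$cohort
  d$tert <- assign_sex_specific_tertiles(
    compute_amed_scores(d, d$sex)$total, d$sex)
  fit <- fit_adjusted_model(d, "tert", "sat")  # exposure is the only predictor
  m <- fit$adjusted_means
  expect_equal(sum(m$estimate * m$n) / sum(m$n), mean(d$sat), tolerance = 1e-10)
  expect_true(all(m$ci_low < m$estimate & m$estimate < m$ci_high))
})

test_that("geometric means are exponentiated adjusted log-means", {
  sc <- toy_synthetic(seed = 3, n = 150)
  d <- sc$cohort
  d$logcrp <- prepare_crp(d$crp)
  d$tert <- assign_sex_specific_tertiles(
    compute_amed_scores(d, d$sex)$total, d$sex)
  fit <- fit_adjusted_model(d, "tert", "logcrp", log_outcome = TRUE)
  expect_equal(fit$adjusted_means$geometric_mean,
               exp(fit$adjusted_means$estimate))
  expect_equal(unname(fit$percent_change["estimate"]),
               100 * (exp(fit$beta) - 1))
  # log-scale contrast back-transforms to the geometric-mean ratio (two-group)
  d$half <- factor(as.integer(d$logcrp > median(d$logcrp)))
  f2 <- fit_adjusted_model(d, "half", "logcrp", log_outcome = TRUE)
  gm <- tapply(d$logcrp, d$half, mean)
  expect_equal(unname(f2$percent_change["estimate"]),
               100 * (exp(gm[["1"]]) / exp(gm[["0"]]) - 1), tolerance = 1e-8)
})

test_that("BH q-values equal brute force and are screened at q < 0.25", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_brute(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_brute(rep(1, 6)), rep(1, 6))
  expect_equal(bh_brute(0.2), 0.2)
  set.seed(33)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    expect_equal(p.adjust(p, "BH"), bh_brute(p))
  }
})

test_that("taxa screen models each taxon with BH control across taxa only", {
  sc <- toy_synthetic(seed = 5, n = 250, diet_effect_a = 1.2)
  d <- sc$cohort
  scores <- compute_amed_scores(d, d$sex)
  d$tert_num <- as.numeric(assign_sex_specific_tertiles(scores$total, d$sex))
  res <- screen_taxa(sc$taxa, d, "tert_num")
  expect_equal(nrow(res), ncol(sc$taxa))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_true(res$significant[res$taxon == "Family05"])

  # zero-variance taxon dropped with a warning
  taxa2 <- sc$taxa
  taxa2[, "Family36"] <- 0
  expect_warning(res2 <- screen_taxa(taxa2, d, "tert_num"), "zero-variance")
  expect_false("Family36" %in% res2$taxon)
})

test_that("mediator candidates need both diet and outcome significance", {
  diet <- data.frame(taxon = c("A", "B", "C"), q_value = c(0.1, 0.1, 0.9))
  outc <- data.frame(taxon = c("A", "B", "C"), p_value = c(0.01, 0.5, 0.01))
  expect_equal(select_mediator_candidates(diet, outc), "A")
  expect_equal(select_mediator_candidates(
    data.frame(taxon = "A", q_value = 0.9),
    data.frame(taxon = "A", p_value = 0.9)), character(0))
})

test_that("incomplete rows are dropped per model with a note", {
  d <- data.frame(y = c(rnorm(19), NA), x = rnorm(20), w = rnorm(20))
  expect_message(fit <- fit_adjusted_model(d, "x", "y", "w"), "dropping 1")
  expect_equal(fit$n, 19)
  # rank deficiency is named
  d$w2 <- d$w
  expect_error(suppressMessages(fit_adjusted_model(d, "x", "y", c("w", "w2"))),
               "w2", class = "amediate_validation_error")
})
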