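## Covariate-adjusted linear ("ANCOVA") models for every exposure-outcome
## pair in the design: aMed tertiles, component binaries, and taxa abundances
## against SAT, VAT, log-CRP, diversity, and taxa — with the log-scale
## back-transform and Benjamini-Hochberg control for the taxa screens.

#' Default covariate set per outcome family
#'
#' All models adjust for sex/menopausal status (3 levels), age, smoking
#' status, physical activity (MET/wk), supplement, hormone-therapy and
#' corticosteroid use, and energy intake. Adiposity outcomes (SAT, VAT) add
#' height (m); CRP adds BMI (kg/m2); taxa and diversity outcomes use the base
#' set only.
#'
#' @param outcome One of `"sat"`, `"vat"`, `"crp"`, `"taxa"`, `"diversity"`.
#' @return Character vector of covariate column names.
#' @export
default_covariates <- function(outcome = c("sat", "vat", "crp", "taxa", "diversity")) {
  outcome <- match.arg(outcome)
  base <- c("sex3", "age", "smoking", "activity", "supplements",
            "hormone_therapy", "corticosteroids", "energy")
  switch(outcome,
         sat = , vat = c(base, "height"),
         crp = c(base, "bmi"),
         base)
}

#' Prepare CRP for modelling
#'
#' Values strictly below the assay limit of detection are imputed as
#' LOD / sqrt(2); the vector is then natural-log transformed (CRP is
#' right-skewed and summarized as geometric means).
#'
#' @param values CRP concentrations, mg/L (nonnegative).
#' @param lod Limit of detection, mg/L (default 0.9).
#' @return Log-scale CRP vector; `NA`s pass through.
#' @export
prepare_crp <- function(values, lod = 0.9) {
  if (lod <= 0) abort_validation("lod must be positive")
  if (any(values < 0, na.rm = TRUE))
    abort_validation("CRP values must be nonnegative")
  below <- !is.na(values) & values < lod
  values[below] <- lod / sqrt(2)
  log(values)
}

#' Back-transform a log-scale coefficient to percent change
#'
#' Applies \eqn{100 (e^x - 1)} to an estimate and its confidence bounds; the
#' map is monotone so bound order is preserved.
#'
#' @param beta Log-scale estimate.
#' @param ci_low,ci_high Optional confidence bounds.
#' @return Named numeric vector `estimate` (plus `ci_low`, `ci_high` when
#'   supplied), in percent.
#' @export
percent_change <- function(beta, ci_low = NULL, ci_high = NULL) {
  f <- function(x) 100 * (exp(x) - 1)
  out <- c(estimate = f(beta))
  if (!is.null(ci_low)) out <- c(out, ci_low = f(ci_low))
  if (!is.null(ci_high)) out <- c(out, ci_high = f(ci_high))
  out
}

## internal: coerce model columns, drop incomplete rows with a note
model_frame <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    abort_validation(paste0("model column(s) absent: ", paste(missing, collapse = ", ")))
  mf <- data[, cols, drop = FALSE]
  ok <- complete.cases(mf)
  if (any(!ok))
    message(sprintf("dropping %d of %d rows with missing model data", sum(!ok), nrow(mf)))
  mf[ok, , drop = FALSE]
}

## internal: covariates constant in the analysis sample carry no information
## and would make the design singular (e.g. an all-zero rare-medication flag
## in a small subsample); drop them with a note.
drop_constant_covariates <- function(mf, covariates) {
  keep <- vapply(covariates, function(cv) length(unique(mf[[cv]])) > 1L, logical(1))
  if (any(!keep))
    message("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "))
  covariates[keep]
}

## internal: adjusted (marginal) means per exposure level — the fitted value
## averaged over the observed covariate distribution with the exposure set to
## each level, i.e. covariates held at their means/observed proportions.
adjusted_level_means <- function(fit, exposure, levels_, df_resid) {
  mm <- model.matrix(fit)
  beta <- coef(fit)
  V <- vcov(fit)
  out <- lapply(levels_, function(lv) {
    cols_exp <- which(startsWith(colnames(mm), exposure))
    x <- colMeans(mm)
    ## rebuild exposure dummies for this level from the factor contrasts
    x[cols_exp] <- 0
    this <- paste0(exposure, lv)
    if (this %in% colnames(mm)) x[this] <- 1
    est <- sum(x * beta)
    se <- sqrt(drop(t(x) %*% V %*% x))
    tcrit <- qt(0.975, df_resid)
    c(estimate = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se)
  })
  do.call(rbind, out)
}

#' Fit a covariate-adjusted exposure-outcome model
#'
#' OLS ("ANCOVA") of `outcome` on `exposure` plus covariates. For an ordered
#' categorical exposure (tertiles) two fits are made: a categorical fit
#' giving covariate-adjusted means per level (evaluated at the covariate
#' means / observed category proportions) and a numeric-coded fit (1/2/3)
#' giving the linear trend coefficient and P-trend. Binary and continuous
#' exposures use a single fit. When `log_outcome = TRUE` the trend estimate
#' is additionally reported as percent change \eqn{100(e^\beta - 1)} and the
#' adjusted means are exponentiated to geometric means.
#'
#' @param data Data frame holding all model columns.
#' @param exposure Exposure column name. Factors/characters are treated as
#'   ordered categories; numeric as continuous; 0/1 numeric as binary.
#' @param outcome Outcome column name (already log-transformed if applicable).
#' @param covariates Character vector of covariate column names.
#' @param log_outcome Is the outcome on the natural-log scale?
#' @return List of class `adjusted_association`: `exposure`, `outcome`, `n`,
#'   `adjusted_means` (per-level data frame or `NULL`), `beta`, `ci_low`,
#'   `ci_high`, `p_value`, and `percent_change` (log outcomes only).
#' @export
fit_adjusted_model <- function(data, exposure, outcome, covariates = character(),
                               log_outcome = FALSE) {
  mf <- model_frame(data, c(outcome, exposure, covariates))
  covariates <- drop_constant_covariates(mf, covariates)
  ex <- mf[[exposure]]
  categorical <- is.factor(ex) || is.character(ex)
  if (categorical) {
    mf[[exposure]] <- droplevels(factor(ex))
    if (nlevels(mf[[exposure]]) < 2L)
      abort_validation("exposure has fewer than 2 observed levels")
  }
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  form <- as.formula(paste(outcome, "~", rhs))
  fit_num <- NULL
  if (categorical) {
    fit_cat <- lm(form, data = mf)
    mf$.exposure_num <- as.numeric(mf[[exposure]])
    form_num <- as.formula(paste(outcome, "~",
                                 paste(c(".exposure_num", covariates), collapse = " + ")))
    fit_num <- lm(form_num, data = mf)
    trend_term <- ".exposure_num"
  } else {
    fit_cat <- NULL
    fit_num <- lm(form, data = mf)
    trend_term <- exposure
  }
  if (any(is.na(coef(fit_num)))) {
    bad <- names(coef(fit_num))[is.na(coef(fit_num))]
    abort_validation(paste0("rank-deficient design; collinear term(s): ",
                            paste(bad, collapse = ", ")))
  }
  sm <- summary(fit_num)$coefficients
  est <- sm[trend_term, "Estimate"]
  se <- sm[trend_term, "Std. Error"]
  p <- sm[trend_term, "Pr(>|t|)"]
  tcrit <- qt(0.975, fit_num$df.residual)
  means <- NULL
  if (categorical) {
    lv <- levels(mf[[exposure]])
    counts <- table(mf[[exposure]])
    if (any(counts == 0L))
      abort_validation("an exposure level has zero observations")
    m <- adjusted_level_means(fit_cat, exposure, lv, fit_cat$df.residual)
    means <- data.frame(level = lv, n = as.integer(counts), m,
                        row.names = NULL, check.names = FALSE)
    if (log_outcome) {
      means$geometric_mean <- exp(means$estimate)
      means$gm_ci_low <- exp(means$ci_low)
      means$gm_ci_high <- exp(means$ci_high)
    }
  }
  res <- list(exposure = exposure, outcome = outcome, n = nrow(mf),
              adjusted_means = means,
              beta = est, ci_low = est - tcrit * se, ci_high = est + tcrit * se,
              p_value = p, log_outcome = log_outcome)
  if (log_outcome)
    res$percent_change <- percent_change(res$beta, res$ci_low, res$ci_high)
  structure(res, class = "adjusted_association")
}

#' @export
print.adjusted_association <- function(x, ...) {
  cat(sprintf("Adjusted association: %s -> %s (n = %d)\n",
              x$exposure, x$outcome, x$n))
  cat(sprintf("  beta = %.4g (95%% CI %.4g, %.4g), p = %.3g\n",
              x$beta, x$ci_low, x$ci_high, x$p_value))
  if (!is.null(x$percent_change))
    cat(sprintf("  percent change = %.2f%% (%.2f%%, %.2f%%)\n",
                x$percent_change[1], x$percent_change[2], x$percent_change[3]))
  if (!is.null(x$adjusted_means)) {
    cat("  adjusted means:\n")
    print(x$adjusted_means, digits = 4)
  }
  invisible(x)
}

#' Screen taxa abundances against a diet exposure
#'
#' Fits one covariate-adjusted model per (core-filtered) taxon with the taxon
#' abundance as outcome and the diet exposure (numeric tertile, component
#' binary, or continuous score) as predictor, then applies Benjamini-Hochberg
#' FDR control across the taxa family of tests. Significance is flagged at
#' `q_threshold` (default 0.25).
#'
#' @param taxa Samples x taxa abundance matrix, rows aligned with `data`.
#' @param data Data frame with the exposure and covariates.
#' @param exposure Exposure column name in `data`.
#' @param covariates Covariate column names (base set, no height/BMI).
#' @param q_threshold BH significance cutoff.
#' @return Data frame: `taxon`, `beta`, `ci_low`, `ci_high`, `p_value`,
#'   `q_value`, `significant`, `n`. Zero-variance taxa are dropped with a
#'   warning.
#' @export
screen_taxa <- function(taxa, data, exposure,
                        covariates = default_covariates("taxa"),
                        q_threshold = 0.25) {
  taxa <- check_taxa_matrix(taxa)
  if (nrow(taxa) != nrow(data))
    abort_validation("taxa rows must align with data rows")
  keep <- apply(taxa, 2, function(v) var(v, na.rm = TRUE) > 0)
  if (any(!keep))
    warning(sprintf("dropping %d zero-variance taxa from the screen", sum(!keep)))
  taxa <- taxa[, keep, drop = FALSE]
  rows <- lapply(colnames(taxa), function(tx) {
    d <- data
    d$.taxon <- taxa[, tx]
    fit <- fit_adjusted_model(d, exposure, ".taxon", covariates)
    data.frame(taxon = tx, beta = fit$beta, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p_value = fit$p_value, n = fit$n)
  })
  out <- do.call(rbind, rows)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < q_threshold
  out[, c("taxon", "beta", "ci_low", "ci_high", "p_value", "q_value",
          "significant", "n")]
}

#' Associate taxa abundances with an outcome
#'
#' One covariate-adjusted model per taxon with the outcome as dependent
#' variable and the taxon abundance as continuous predictor (the
#' taxon-to-outcome direction used for mediator candidacy and the b-path
#' reporting). Uses the outcome's covariate set (with height or BMI).
#'
#' @inheritParams screen_taxa
#' @param outcome Outcome column name in `data` (log-CRP already transformed).
#' @return Data frame: `taxon`, `beta`, `ci_low`, `ci_high`, `p_value`, `n`.
#' @export
screen_taxa_outcome <- function(taxa, data, outcome,
                                covariates = default_covariates("sat")) {
  taxa <- check_taxa_matrix(taxa)
  if (nrow(taxa) != nrow(data))
    abort_validation("taxa rows must align with data rows")
  rows <- lapply(colnames(taxa), function(tx) {
    d <- data
    d$.taxon <- taxa[, tx]
    fit <- fit_adjusted_model(d, ".taxon", outcome, covariates)
    data.frame(taxon = tx, beta = fit$beta, ci_low = fit$ci_low,
               ci_high = fit$ci_high, p_value = fit$p_value, n = fit$n)
  })
  do.call(rbind, rows)
}

#' Select mediator candidate taxa
#'
#' A taxon is a mediation candidate for a given outcome when it passes the
#' diet screen (BH q below `q_threshold`) and its association with that
#' outcome has p below `p_threshold`.
#'
#' @param diet_screen Output of [screen_taxa()] for the diet exposure.
#' @param outcome_screen Output of [screen_taxa_outcome()] for one outcome.
#' @param q_threshold BH cutoff on the diet screen (default 0.25).
#' @param p_threshold p cutoff on the outcome association (default 0.05).
#' @return Character vector of candidate taxa (possibly empty).
#' @export
select_mediator_candidates <- function(diet_screen, outcome_screen,
                                       q_threshold = 0.25, p_threshold = 0.05) {
  diet_ok <- diet_screen$taxon[diet_screen$q_value < q_threshold]
  out_ok <- outcome_screen$taxon[outcome_screen$p_value < p_threshold]
  intersect(diet_ok, out_ok)
}
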