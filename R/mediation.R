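## Linear structural-equation mediation: how much of a diet-outcome
## association runs through a microbial mediator. Two OLS path regressions
## with a common covariate set:
##
##   mediator ~ exposure + covariates            (a-path)
##   outcome  ~ exposure + mediator + covariates (b-path and direct c')
##
## indirect = a*b, total = a*b + c', proportion mediated = indirect/total.
## In this linear, interaction-free model the product-of-coefficients and
## difference-of-coefficients estimators coincide, so `total` equals the
## exposure coefficient from outcome ~ exposure + covariates.

## internal: OLS fit on a model matrix returning coefficients, and optionally
## their standard errors (plain normal-theory, used for the b-path CI/p).
ols_paths <- function(X, y, want_se = FALSE) {
  fit <- lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    abort_validation("rank-deficient design in path regression")
  out <- list(coef = fit$coefficients)
  if (want_se) {
    df <- length(y) - ncol(X)
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    out$se <- sqrt(diag(XtXinv) * sigma2)
    out$df <- df
  }
  out
}

## internal: numeric model matrix (intercept, exposure[, mediator], covariate
## dummies) shared by the path fits and the bootstrap.
path_model_matrix <- function(data, covariates) {
  if (length(covariates) == 0L)
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  form <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  model.matrix(form, data = data)
}

#' Fit a linear mediation model for one (exposure, mediator, outcome) triple
#'
#' Decomposes the covariate-adjusted association between a diet exposure
#' (e.g., the continuous aMed total) and an outcome (SAT, VAT, or log-CRP)
#' into the part transmitted through a microbial mediator (indirect, a*b) and
#' the direct remainder (c'). The proportion mediated is the signed ratio
#' indirect/total in percent; values outside \[0, 100\] (inconsistent
#' mediation / suppression) are reported as-is with `outside_range = TRUE`.
#' A percentile bootstrap over participants gives the proportion's CI.
#'
#' @param data Data frame with exposure, mediator, outcome and covariates.
#' @param exposure,mediator,outcome Column names; all numeric.
#' @param covariates Covariate column names, identical in both path fits.
#' @param boot Bootstrap replicates for the proportion CI (0 disables).
#' @param seed Integer seed for the bootstrap resampling.
#' @param total_tol If `|total|` falls below this, the proportion is reported
#'   as `NA` with `undefined = TRUE` rather than a near-infinite ratio.
#' @return List of class `mediation_result`: `a_path`, `b_path`, `c_direct`,
#'   `indirect`, `total`, `proportion_mediated` (percent), `prop_ci`
#'   (percentile 95% CI), `b_se`, `b_ci`, `b_p` (the mediator-to-outcome
#'   association), `n`, and flags.
#' @export
fit_mediation <- function(data, exposure, mediator, outcome,
                          covariates = character(), boot = 1000, seed = NULL,
                          total_tol = 1e-8) {
  mf <- model_frame(data, unique(c(exposure, mediator, outcome, covariates)))
  covariates <- drop_constant_covariates(mf, covariates)
  m <- mf[[mediator]]
  if (var(m) <= 0) abort_validation("mediator has zero variance")
  W <- path_model_matrix(mf, covariates)
  x <- mf[[exposure]]
  y <- mf[[outcome]]
  Xa <- cbind(W, exposure = x)
  Xb <- cbind(W, exposure = x, mediator = m)

  paths <- function(ix) {
    fa <- lm.fit(Xa[ix, , drop = FALSE], m[ix])$coefficients
    fb <- lm.fit(Xb[ix, , drop = FALSE], y[ix])$coefficients
    a <- fa[["exposure"]]; b <- fb[["mediator"]]; cd <- fb[["exposure"]]
    c(a = a, b = b, c_direct = cd, indirect = a * b, total = a * b + cd)
  }
  est <- paths(seq_along(y))
  fb_se <- ols_paths(Xb, y, want_se = TRUE)
  b_i <- which(colnames(Xb) == "mediator")
  b_se <- fb_se$se[b_i]
  tcrit <- qt(0.975, fb_se$df)
  b_ci <- est[["b"]] + c(-1, 1) * tcrit * b_se
  b_p <- 2 * pt(abs(est[["b"]] / b_se), fb_se$df, lower.tail = FALSE)

  undefined <- abs(est[["total"]]) < total_tol
  prop <- if (undefined) NA_real_ else 100 * est[["indirect"]] / est[["total"]]

  prop_ci <- c(NA_real_, NA_real_)
  boot_dropped <- 0L
  if (boot > 0 && !undefined) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
      set.seed(seed)
    }
    n <- length(y)
    draws <- vapply(seq_len(boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      p <- paths(ix)
      if (abs(p[["total"]]) < total_tol) NA_real_
      else 100 * p[["indirect"]] / p[["total"]]
    }, numeric(1))
    boot_dropped <- sum(is.na(draws))
    draws <- draws[!is.na(draws)]
    if (length(draws) >= 10)
      prop_ci <- unname(quantile(draws, c(0.025, 0.975), type = 7))
  }

  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 a_path = unname(est[["a"]]), b_path = unname(est[["b"]]),
                 c_direct = unname(est[["c_direct"]]),
                 indirect = unname(est[["indirect"]]),
                 total = unname(est[["total"]]),
                 proportion_mediated = prop, prop_ci = prop_ci,
                 b_se = unname(b_se), b_ci = b_ci, b_p = unname(b_p),
                 n = length(y), boot = boot, boot_dropped = boot_dropped,
                 undefined = undefined,
                 outside_range = isTRUE(!is.na(prop) && (prop < 0 || prop > 100))),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d)\n",
              x$exposure, x$mediator, x$outcome, x$n))
  cat(sprintf("  a = %.4g, b = %.4g, c' = %.4g\n", x$a_path, x$b_path, x$c_direct))
  cat(sprintf("  indirect = %.4g, total = %.4g\n", x$indirect, x$total))
  if (x$undefined) {
    cat("  proportion mediated: undefined (|total| below tolerance)\n")
  } else {
    cat(sprintf("  proportion mediated = %.1f%%", x$proportion_mediated))
    if (all(is.finite(x$prop_ci)))
      cat(sprintf(" (95%% bootstrap CI %.1f%%, %.1f%%)", x$prop_ci[1], x$prop_ci[2]))
    cat("\n")
    if (x$outside_range)
      cat("  note: proportion outside [0, 100]% (inconsistent mediation)\n")
  }
  invisible(x)
}

#' Combine candidate mediators into one component by PCA
#'
#' Standardizes the candidate taxa columns, takes the first eigenvector of
#' their correlation matrix as loadings (sign fixed so the largest-magnitude
#' loading is positive), and returns per-sample scores summarizing the joint
#' microbial signal, with the fraction of variance the component explains.
#'
#' @param taxa Samples x taxa abundance matrix.
#' @param candidates Character vector of at least two column names.
#' @return List of class `combined_mediator`: `component_scores`,
#'   `variance_explained`, `loadings` (unit norm), `candidates`.
#' @export
combine_mediators_pca <- function(taxa, candidates) {
  taxa <- check_taxa_matrix(taxa)
  if (length(candidates) < 2L)
    abort_validation("need >= 2 candidate taxa to combine; use single-taxon mediation")
  missing <- setdiff(candidates, colnames(taxa))
  if (length(missing))
    abort_validation(paste0("candidate taxa absent from table: ",
                            paste(missing, collapse = ", ")))
  X <- taxa[, candidates, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) abort_validation("candidate taxa must have nonzero variance")
  Z <- scale(X)
  eg <- eigen(cor(X), symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  structure(list(component_scores = drop(Z %*% v),
                 variance_explained = eg$values[1] / sum(eg$values),
                 loadings = setNames(v, candidates),
                 candidates = candidates),
            class = "combined_mediator")
}

#' Tabulate mediation results
#'
#' One row per (exposure, outcome, mediator) with the mediator-to-outcome
#' b-path estimate, CI and p, and the signed proportion mediated in percent
#' (`NA` when the total association is below tolerance; `outside_range`
#' flags inconsistent mediation rather than truncating).
#'
#' @param results List of `mediation_result` objects.
#' @return Data frame report.
#' @export
mediation_report <- function(results) {
  if (length(results) == 0L) abort_validation("no mediation results to report")
  rows <- lapply(results, function(r) {
    data.frame(exposure = r$exposure, outcome = r$outcome, mediator = r$mediator,
               b_path = r$b_path, b_ci_low = r$b_ci[1], b_ci_high = r$b_ci[2],
               b_p = r$b_p,
               proportion_mediated_pct = r$proportion_mediated,
               prop_ci_low = r$prop_ci[1], prop_ci_high = r$prop_ci[2],
               outside_range = r$outside_range, n = r$n)
  })
  do.call(rbind, rows)
}
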