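## Synthetic cohorts with the statistical structure the analysis assumes:
## covariates, nine-component dietary intakes driven by a latent diet-quality
## factor, compositional taxa abundances partly driven by the computed aMed
## score, and outcomes generated by a linear mediation model with known
## ground-truth proportion mediated.
##
## Generative mediation structure (per mediator taxon j, standardized scales):
##   X  = standardized aMed total, recomputed from the generated intakes
##   Mj = a_j * X + N(0, noise_sd_mediator)
##   Y* = c * X + sum_j b_j * Mj + covariate effects + N(0, noise_sd_outcome)
## and each outcome (SAT, VAT, log-CRP) is an affine map of its own Y* draw.
## The mediator taxon's relative abundance is an affine function of Mj
## (base_share * (1 + k * Mj), k = 0.25, floored at 5% of base), with the
## remaining taxa drawn logistic-normally and rescaled to close the
## composition at 100. Proportion mediated is invariant to affine maps of
## exposure, mediator and outcome, so the truth for taxon j is
##   a_j * b_j / (c + sum_k a_k * b_k)
## which reduces to a*b/(a*b + c) for a single mediator.

## Table-like intake targets (mean, sd, loading on the latent diet factor):
## favorable components load positively, red meat negatively, alcohol and
## energy not at all (the alcohol point is a nonmonotone window).
intake_targets <- function() {
  data.frame(
    component = c("vegetables", "legumes", "fruit", "nuts", "wholegrains",
                  "fish", "mufa_sfa_ratio", "red_meat", "alcohol", "energy"),
    mean = c(201, 3.2, 229, 4.4, 22.7, 30.1, 0.89, 107, 15.8, 2295),
    sd   = c(93.2, 3.4, 150, 5.9, 20.1, 22.9, 0.11, 68.6, 19.6, 679),
    loading = c(0.45, 0.45, 0.45, 0.45, 0.45, 0.45, 0.45, -0.45, 0, 0))
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_participants Cohort size (>= 30).
#' @param seed Integer seed; the same config + seed reproduces the cohort
#'   byte-for-byte.
#' @param n_taxa Number of family-level taxa (default 36).
#' @param frac_female Proportion female.
#' @param frac_postmenopausal Proportion postmenopausal among females.
#' @param mediator_taxa Names (`"FamilyXX"`) or indices of true mediator taxa.
#' @param diet_effect_a Exposure-to-mediator slope(s), recycled over
#'   mediators (standardized exposure scale).
#' @param mediator_effect_b Mediator-to-outcome slope(s), recycled.
#' @param direct_effect_c Direct exposure-to-outcome slope.
#' @param noise_sd_mediator,noise_sd_outcome Residual SDs of the mediator and
#'   outcome equations.
#' @param crp_lod CRP limit of detection in mg/L (default 0.9).
#' @param energy_outlier_frac Fraction of participants given implausible
#'   energy intakes (<800 or >6000 kcal/d).
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_participants = 620, seed = 1L, n_taxa = 36,
                             frac_female = 0.41, frac_postmenopausal = 0.72,
                             mediator_taxa = "Family05",
                             diet_effect_a = 0.5, mediator_effect_b = 0.4,
                             direct_effect_c = 0.8,
                             noise_sd_mediator = 1, noise_sd_outcome = 1,
                             crp_lod = 0.9, energy_outlier_frac = 0.01) {
  if (!is.numeric(n_participants) || n_participants < 30)
    abort_validation("n_participants must be >= 30", "amediate_config_error")
  if (!is.numeric(n_taxa) || n_taxa < 1)
    abort_validation("n_taxa must be a positive count", "amediate_config_error")
  for (p in c(frac_female = frac_female, frac_postmenopausal = frac_postmenopausal,
              energy_outlier_frac = energy_outlier_frac)) {
    if (p < 0 || p > 1)
      abort_validation("proportion parameters must lie in [0, 1]",
                       "amediate_config_error")
  }
  if (length(mediator_taxa) < 1)
    abort_validation("at least one mediator taxon must be flagged",
                     "amediate_config_error")
  if (noise_sd_mediator <= 0 || noise_sd_outcome <= 0)
    abort_validation("noise SDs must be positive", "amediate_config_error")
  if (crp_lod <= 0)
    abort_validation("crp_lod must be positive", "amediate_config_error")
  taxa_names <- sprintf("Family%02d", seq_len(n_taxa))
  if (is.numeric(mediator_taxa)) mediator_taxa <- taxa_names[mediator_taxa]
  if (any(!mediator_taxa %in% taxa_names))
    abort_validation("mediator_taxa must name taxa within n_taxa",
                     "amediate_config_error")
  structure(list(n_participants = as.integer(n_participants),
                 seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 frac_female = frac_female,
                 frac_postmenopausal = frac_postmenopausal,
                 mediator_taxa = mediator_taxa,
                 diet_effect_a = rep_len(diet_effect_a, length(mediator_taxa)),
                 mediator_effect_b = rep_len(mediator_effect_b, length(mediator_taxa)),
                 direct_effect_c = direct_effect_c,
                 noise_sd_mediator = noise_sd_mediator,
                 noise_sd_outcome = noise_sd_outcome,
                 crp_lod = crp_lod,
                 energy_outlier_frac = energy_outlier_frac,
                 taxa_names = taxa_names,
                 mediator_signal_scale = 0.25),
            class = "generator_config")
}

## run expr under a temporary seed, restoring any pre-existing RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
          else assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

## lognormal parameters matching a target mean and sd
lnorm_pars <- function(m, s) {
  sig2 <- log(1 + (s / m)^2)
  c(mu = log(m) - sig2 / 2, sigma = sqrt(sig2))
}

#' Generate a synthetic cohort with known mediation structure
#'
#' See the package vignette for the generative model. The exposure entering
#' the mediation structure is the aMed score recomputed from the generated
#' intakes (standardized), so the cohort's ground truth refers to the same
#' derived score the analysis pipeline uses.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_cohort`: `cohort` (one row per
#'   participant: covariates, intakes, outcomes), `taxa` (samples x taxa
#'   percent-scale matrix, rows sum to 100), `truth` (per mediator x outcome:
#'   a, b, c and the ground-truth proportion mediated), and `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "generator_config"))
    abort_validation("config must come from generator_config()",
                     "amediate_config_error")
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_participants
  id <- sprintf("S%04d", seq_len(n))

  ## --- covariates ---------------------------------------------------------
  female <- runif(n) < config$frac_female
  post <- female & (runif(n) < config$frac_postmenopausal)
  sex <- ifelse(female, "female", "male")
  sex3 <- ifelse(!female, "male",
                 ifelse(post, "postmenopausal_female", "premenopausal_female"))
  age <- runif(n, 25, 83)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE,
                    prob = c(0.50, 0.38, 0.12))
  ap <- lnorm_pars(105, 64)
  activity <- rlnorm(n, ap["mu"], ap["sigma"])
  supplements <- as.integer(runif(n) < 0.40)
  hormone_therapy <- as.integer(female & runif(n) < 0.08)
  corticosteroids <- as.integer(runif(n) < 0.02)
  height <- ifelse(female, rnorm(n, 1.65, 0.065), rnorm(n, 1.78, 0.070))
  bmi <- pmax(rnorm(n, 27.2, 4.4), 16)

  ## --- intakes from a latent diet-quality factor --------------------------
  z <- rnorm(n)
  tg <- intake_targets()
  intakes <- data.frame(sample_id = id)
  for (i in seq_len(nrow(tg))) {
    pr <- lnorm_pars(tg$mean[i], tg$sd[i])
    rho <- tg$loading[i]
    lg <- pr["mu"] + pr["sigma"] * (rho * z + sqrt(1 - rho^2) * rnorm(n))
    intakes[[tg$component[i]]] <- exp(unname(lg))
  }
  n_out <- round(config$energy_outlier_frac * n)
  if (n_out > 0) {
    who <- sample.int(n, n_out)
    lo <- seq_len(n_out) %% 2 == 0
    intakes$energy[who[lo]] <- runif(sum(lo), 300, 799)
    intakes$energy[who[!lo]] <- runif(sum(!lo), 6001, 8000)
  }

  ## --- exposure: the recomputed aMed score, standardized ------------------
  score <- compute_amed_scores(intakes, sex)
  x_std <- if (sd(score$total) > 0) as.numeric(scale(score$total))
           else numeric(n)

  ## --- mediators and taxa composition -------------------------------------
  med_names <- config$mediator_taxa
  a <- config$diet_effect_a
  b <- config$mediator_effect_b
  k <- config$mediator_signal_scale
  M <- vapply(seq_along(med_names), function(j)
    a[j] * x_std + rnorm(n, 0, config$noise_sd_mediator), numeric(n))
  colnames(M) <- med_names

  base_share <- exp(-0.18 * (seq_len(config$n_taxa) - 1))
  base_share <- 100 * base_share / sum(base_share)
  names(base_share) <- config$taxa_names
  med_idx <- match(med_names, config$taxa_names)
  taxa <- matrix(0, n, config$n_taxa,
                 dimnames = list(id, config$taxa_names))
  ## mediator shares: affine in the structural mediator, floored at 5% of base
  for (j in seq_along(med_idx))
    taxa[, med_idx[j]] <- base_share[med_idx[j]] * pmax(1 + k * M[, j], 0.05)
  ## remaining taxa: logistic-normal, rescaled to close the composition
  rest <- setdiff(seq_len(config$n_taxa), med_idx)
  w <- sweep(matrix(exp(rnorm(n * length(rest), 0, 0.6)), n, length(rest)),
             2, base_share[rest], `*`)
  taxa[, rest] <- w * (100 - rowSums(taxa[, med_idx, drop = FALSE])) / rowSums(w)
  stopifnot(all(abs(rowSums(taxa) - 100) < 1e-9))

  ## --- outcomes ------------------------------------------------------------
  cvec <- config$direct_effect_c
  age_std <- (age - 54) / 16.7
  structural <- cvec * x_std + drop(M %*% b)
  lat <- function() structural + 0.25 * as.numeric(!female) + 0.20 * age_std +
    rnorm(n, 0, config$noise_sd_outcome)
  sat <- pmax(6.9 + 2.0 * lat(), 0.1)
  vat <- pmax(4.1 + 1.2 * lat(), 0.1)
  crp <- exp(0.7 + 0.5 * lat())

  cohort <- data.frame(sample_id = id, sex = sex, sex3 = sex3, age = age,
                       smoking = smoking, activity = activity,
                       supplements = supplements,
                       hormone_therapy = hormone_therapy,
                       corticosteroids = corticosteroids,
                       height = height, bmi = bmi,
                       intakes[, -1, drop = FALSE],
                       sat = sat, vat = vat, crp = crp,
                       stringsAsFactors = FALSE)

  total_assoc <- cvec + sum(a * b)
  truth <- expand.grid(taxon = med_names, outcome = c("sat", "vat", "crp"),
                       stringsAsFactors = FALSE)
  truth$a <- a[match(truth$taxon, med_names)]
  truth$b <- b[match(truth$taxon, med_names)]
  truth$c_direct <- cvec
  truth$proportion_mediated <- if (abs(total_assoc) > 1e-12)
    100 * truth$a * truth$b / total_assoc else NA_real_

  structure(list(cohort = cohort, taxa = taxa, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d taxa, %d true mediator(s)\n",
              nrow(x$cohort), ncol(x$taxa), length(x$config$mediator_taxa)))
  cat("Ground-truth proportion mediated (%):\n")
  print(unique(x$truth[, c("taxon", "proportion_mediated")]), row.names = FALSE)
  invisible(x)
}

#' Write a synthetic cohort to delimited files
#'
#' Emits `covariates.csv` (covariates + outcomes), `intakes.csv`, `taxa.csv`
#' and `truth.csv` into `directory`, in the dialect [read_cohort()] and
#' [run_pipeline()] consume: UTF-8, header row, `sample_id` key column,
#' missing values as empty fields.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if needed).
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, directory, delimiter = ",") {
  if (!inherits(cohort, "synthetic_cohort"))
    abort_validation("cohort must be a synthetic_cohort")
  if (ncol(cohort$taxa) == 0L)
    abort_validation("cohort has an empty taxa set")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cov_cols <- c("sample_id", "sex", "sex3", "age", "smoking", "activity",
                "supplements", "hormone_therapy", "corticosteroids",
                "height", "bmi", "sat", "vat", "crp")
  intake_cols <- c("sample_id", amed_components(), "energy")
  taxa_df <- data.frame(sample_id = rownames(cohort$taxa),
                        cohort$taxa, check.names = FALSE)
  paths <- c(covariates = file.path(directory, "covariates.csv"),
             intakes = file.path(directory, "intakes.csv"),
             taxa = file.path(directory, "taxa.csv"),
             truth = file.path(directory, "truth.csv"))
  wr <- function(df, path) utils::write.table(
    df, path, sep = delimiter, row.names = FALSE, quote = TRUE, na = "")
  wr(cohort$cohort[, cov_cols], paths["covariates"])
  wr(cohort$cohort[, intake_cols], paths["intakes"])
  wr(taxa_df, paths["taxa"])
  wr(cohort$truth, paths["truth"])
  invisible(paths)
}

#' Read a cohort from delimited files
#'
#' Counterpart of [write_cohort()]; also accepts externally prepared tables
#' in the same layout (`truth.csv` optional).
#'
#' @param directory Directory holding `covariates.csv`, `intakes.csv`,
#'   `taxa.csv`.
#' @param delimiter Field delimiter.
#' @return List with `cohort` (covariates + intakes + outcomes merged by
#'   `sample_id`), `taxa` matrix, and `truth` (or `NULL`).
#' @export
read_cohort <- function(directory, delimiter = ",") {
  rd <- function(name) {
    path <- file.path(directory, name)
    if (!file.exists(path)) abort_validation(paste0("missing input file: ", path))
    utils::read.table(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  covs <- rd("covariates.csv")
  intakes <- rd("intakes.csv")
  cohort <- merge(covs, intakes, by = "sample_id", sort = FALSE)
  taxa_df <- rd("taxa.csv")
  taxa <- as.matrix(taxa_df[, setdiff(names(taxa_df), "sample_id"), drop = FALSE])
  rownames(taxa) <- taxa_df$sample_id
  truth_path <- file.path(directory, "truth.csv")
  truth <- if (file.exists(truth_path))
    utils::read.table(truth_path, sep = delimiter, header = TRUE,
                      stringsAsFactors = FALSE) else NULL
  list(cohort = cohort, taxa = taxa, truth = truth)
}
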