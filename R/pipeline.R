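## End-to-end orchestration: from the three input tables (or a synthetic
## cohort) through scoring, covariate-adjusted models, the taxa screen, and
## the mediation decomposition, to a set of delimited reports.

#' Pipeline configuration
#'
#' All analysis thresholds in one serializable list; every default is the
#' value the analysis design prescribes, and every one can be moved for
#' sensitivity runs.
#'
#' @param energy_bounds Plausible energy window, kcal/d (records outside are
#'   excluded).
#' @param alcohol_window Closed moderate-alcohol window, g/d.
#' @param crp_lod CRP limit of detection, mg/L.
#' @param core_threshold_abundance,core_threshold_fraction,core_rule Core
#'   microbiota filter parameters (see [filter_core_microbiota()]).
#' @param q_threshold BH significance cutoff for taxa screens.
#' @param p_threshold Two-sided significance cutoff elsewhere.
#' @param boot Bootstrap replicates for mediation CIs.
#' @param seed Integer seed (bootstrap resampling).
#' @param mediation_components aMed components (e.g. `"alcohol"`) whose
#'   binary exposures also get screen + mediation stages, in addition to the
#'   total score.
#' @param delimiter Report field delimiter.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(energy_bounds = c(800, 6000),
                            alcohol_window = c(5, 25),
                            crp_lod = 0.9,
                            core_threshold_abundance = 0.01,
                            core_threshold_fraction = 0.10,
                            core_rule = "drop_low_prevalence",
                            q_threshold = 0.25, p_threshold = 0.05,
                            boot = 1000, seed = 1L,
                            mediation_components = character(),
                            delimiter = ",") {
  structure(list(energy_bounds = energy_bounds, alcohol_window = alcohol_window,
                 crp_lod = crp_lod,
                 core_threshold_abundance = core_threshold_abundance,
                 core_threshold_fraction = core_threshold_fraction,
                 core_rule = core_rule,
                 q_threshold = q_threshold, p_threshold = p_threshold,
                 boot = boot, seed = as.integer(seed),
                 mediation_components = mediation_components,
                 delimiter = delimiter),
            class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Checks column presence, types, sample-ID agreement across tables, and
#' abundance nonnegativity/closure, returning a machine-readable report.
#'
#' @param cohort Data frame of covariates + intakes + outcomes (as returned
#'   by [read_cohort()]).
#' @param taxa Samples x taxa abundance matrix.
#' @return List with `ok` (logical) and `issues` (character vector).
#' @export
validate_inputs <- function(cohort, taxa) {
  issues <- character()
  need <- c("sample_id", "sex", "sex3", "age", "smoking", "activity",
            "supplements", "hormone_therapy", "corticosteroids",
            "height", "bmi", amed_components(), "energy")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    issues <- c(issues, paste0("cohort table missing column(s): ",
                               paste(miss, collapse = ", ")))
  if (!any(c("sat", "vat", "crp") %in% names(cohort)))
    issues <- c(issues, "cohort table has no outcome column (sat, vat, crp)")
  if ("sample_id" %in% names(cohort) && anyDuplicated(cohort$sample_id))
    issues <- c(issues, "duplicated sample_id in cohort table")
  if (is.null(rownames(taxa))) {
    issues <- c(issues, "taxa matrix lacks sample_id rownames")
  } else if ("sample_id" %in% names(cohort)) {
    extra <- setdiff(rownames(taxa), cohort$sample_id)
    if (length(extra))
      issues <- c(issues, paste0(length(extra), " taxa sample(s) absent from cohort"))
  }
  if (!is.numeric(taxa)) {
    issues <- c(issues, "taxa matrix must be numeric")
  } else {
    if (any(taxa < 0, na.rm = TRUE)) {
      bad <- which(taxa < 0, arr.ind = TRUE)[1, ]
      issues <- c(issues, sprintf("negative abundance at sample %s, taxon %s",
                                  rownames(taxa)[bad[1]], colnames(taxa)[bad[2]]))
    }
    if (any(rowSums(taxa) > 100 + 1e-6, na.rm = TRUE))
      issues <- c(issues, "taxa row sums exceed 100%")
  }
  num_cols <- intersect(c("age", "activity", "height", "bmi", "energy",
                          amed_components()), names(cohort))
  for (col in num_cols)
    if (!is.numeric(cohort[[col]]))
      issues <- c(issues, paste0("cohort column '", col, "' must be numeric"))
  list(ok = length(issues) == 0L, issues = issues)
}

## one outcome family: energy exclusion, scoring and tertiles on the
## subsample where the outcome is observed, then models + screens + mediation
analyze_family <- function(cohort, taxa, outcome, config) {
  log_outcome <- outcome == "crp"
  sub <- cohort[!is.na(cohort[[outcome]]), , drop = FALSE]
  spl <- exclude_implausible_energy(sub, config$energy_bounds[1],
                                    config$energy_bounds[2])
  d <- spl$kept
  n_excluded <- nrow(spl$excluded)
  taxa_sub <- taxa[d$sample_id, , drop = FALSE]

  scores <- compute_amed_scores(d, d$sex, alcohol_window = config$alcohol_window)
  d$amed_total <- scores$total
  d$amed_tertile <- assign_sex_specific_tertiles(scores$total, d$sex)
  d$.outcome <- if (log_outcome) prepare_crp(d[[outcome]], config$crp_lod)
                else d[[outcome]]
  covs <- default_covariates(outcome)

  ## Table-2 shape: outcome by aMed tertile
  tertile_model <- fit_adjusted_model(d, "amed_tertile", ".outcome", covs,
                                      log_outcome = log_outcome)
  tertile_model$outcome <- outcome

  ## Figure-1 shape: outcome by component binaries
  comp_rows <- lapply(amed_components(), function(cp) {
    d$.comp <- factor(component_binary_exposure(d, d$sex, cp,
                                                alcohol_window = config$alcohol_window),
                      levels = c(0, 1))
    fit <- fit_adjusted_model(d, ".comp", ".outcome", covs,
                              log_outcome = log_outcome)
    data.frame(component = cp, outcome = outcome, beta = fit$beta,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               p_value = fit$p_value,
               pct_change = if (log_outcome) fit$percent_change[["estimate"]] else NA_real_,
               n = fit$n)
  })
  components <- do.call(rbind, comp_rows)

  ## core filter + diversity + ordination + diet screen (Table-3 shape)
  core <- filter_core_microbiota(taxa_sub, config$core_threshold_abundance,
                                 config$core_threshold_fraction,
                                 rule = config$core_rule)
  d$.shannon <- shannon_index(taxa_sub)
  diversity_model <- fit_adjusted_model(d, "amed_tertile", ".shannon",
                                        default_covariates("diversity"))
  ord <- suppressWarnings(pcoa_ordination(bray_curtis_matrix(taxa_sub), 3))
  d$.tertile_num <- as.numeric(d$amed_tertile)
  diet_screen <- screen_taxa(core$abundance, d, ".tertile_num",
                             q_threshold = config$q_threshold)
  diet_screen$exposure <- "amed_tertile"

  ## taxon -> outcome associations and mediator candidates
  outcome_screen <- screen_taxa_outcome(core$abundance, d, ".outcome", covs)
  candidates <- select_mediator_candidates(diet_screen, outcome_screen,
                                           config$q_threshold, config$p_threshold)

  ## mediation: continuous aMed total as exposure, per candidate + PCA
  run_mediation <- function(exposure_col, cand, label) {
    res <- list()
    for (tx in cand) {
      d$.med <- taxa_sub[, tx]
      r <- fit_mediation(d, exposure_col, ".med", ".outcome", covs,
                         boot = config$boot, seed = config$seed)
      r$mediator <- tx; r$exposure <- label; r$outcome <- outcome
      res[[tx]] <- r
    }
    if (length(cand) >= 2) {
      pc <- combine_mediators_pca(taxa_sub, cand)
      d$.med <- pc$component_scores
      r <- fit_mediation(d, exposure_col, ".med", ".outcome", covs,
                         boot = config$boot, seed = config$seed)
      r$mediator <- paste0(label, " PCA1"); r$exposure <- label
      r$outcome <- outcome
      r$variance_explained <- pc$variance_explained
      res[["PCA1"]] <- r
    }
    res
  }
  mediation <- run_mediation("amed_total", candidates, "amed_score")

  ## optional component-exposure mediation (e.g. moderate alcohol)
  for (cp in config$mediation_components) {
    d$.comp_num <- component_binary_exposure(d, d$sex, cp,
                                             alcohol_window = config$alcohol_window)
    comp_screen <- screen_taxa(core$abundance, d, ".comp_num",
                               q_threshold = config$q_threshold)
    cand_cp <- select_mediator_candidates(comp_screen, outcome_screen,
                                          config$q_threshold, config$p_threshold)
    mediation <- c(mediation, run_mediation(".comp_num", cand_cp, cp))
  }

  list(outcome = outcome, n = nrow(d), n_excluded_energy = n_excluded,
       n_missing_outcome = nrow(cohort) - nrow(sub),
       scores = data.frame(sample_id = d$sample_id, total = d$amed_total,
                           tertile = as.character(d$amed_tertile)),
       tertile_model = tertile_model, components = components,
       core = core, shannon = d$.shannon, ordination = ord,
       diversity_model = diversity_model,
       diet_screen = diet_screen, outcome_screen = outcome_screen,
       candidates = candidates, mediation = mediation)
}

#' Run the full diet-microbiome-adiposity analysis
#'
#' Executes, per outcome family (adiposity: SAT and VAT; inflammation: CRP),
#' on the subsample with that outcome observed: energy exclusion, aMed
#' scoring and sex-specific tertiles, CRP LOD handling and log transform,
#' tertile and component models, core-microbiota filtering, Shannon/PCoA
#' summaries, the BH-controlled diet-taxa screen, mediator-candidate
#' selection, and single-taxon plus PCA-combined mediation. Reports are
#' written as delimited files and are a pure function of (inputs, config).
#'
#' @param cohort Data frame of covariates + intakes + outcomes, or a
#'   `synthetic_cohort` (its taxa table is then taken from the object).
#' @param taxa Samples x taxa matrix (ignored for a `synthetic_cohort`).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for reports; `NULL` skips writing.
#' @return List of class `pipeline_result` with one element per outcome plus
#'   `metadata`; invisibly writes the report files when `out_dir` is given.
#' @export
run_pipeline <- function(cohort, taxa = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(cohort, "synthetic_cohort")) {
    taxa <- cohort$taxa
    cohort <- cohort$cohort
  }
  val <- validate_inputs(cohort, taxa)
  if (!val$ok)
    abort_validation(paste0("invalid inputs:\n  ",
                            paste(val$issues, collapse = "\n  ")))
  outcomes <- intersect(c("sat", "vat", "crp"), names(cohort))
  outcomes <- outcomes[vapply(outcomes, function(o) any(!is.na(cohort[[o]])),
                              logical(1))]
  if (length(outcomes) == 0L) abort_validation("no non-missing outcomes to analyze")

  results <- list()
  for (oc in outcomes) {
    t0 <- proc.time()[["elapsed"]]
    results[[oc]] <- analyze_family(cohort, taxa, oc, config)
    message(sprintf("stage %s: n = %d (%.1fs)", oc, results[[oc]]$n,
                    proc.time()[["elapsed"]] - t0))
  }

  metadata <- list(
    config = unclass(config),
    n_input = nrow(cohort),
    counts = lapply(results, function(r)
      list(analyzed = r$n, excluded_energy = r$n_excluded_energy,
           missing_outcome = r$n_missing_outcome)))

  out <- structure(list(results = results, metadata = metadata),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_reports(out, out_dir, config$delimiter)
  out
}

## flatten per-outcome results into the delimited report set
write_reports <- function(x, out_dir, delimiter = ",") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = delimiter, row.names = FALSE,
    quote = TRUE, na = "")
  res <- x$results

  tert <- do.call(rbind, lapply(res, function(r) {
    m <- r$tertile_model$adjusted_means
    for (col in c("geometric_mean", "gm_ci_low", "gm_ci_high"))
      if (is.null(m[[col]])) m[[col]] <- NA_real_
    data.frame(outcome = r$outcome, m,
               beta = r$tertile_model$beta, p_trend = r$tertile_model$p_value,
               check.names = FALSE)
  }))
  wr(tert, "amed_tertile_models.csv")
  wr(do.call(rbind, lapply(res, `[[`, "components")), "component_models.csv")
  wr(do.call(rbind, lapply(res, function(r) {
    cbind(outcome = r$outcome, r$diet_screen)
  })), "taxa_diet_screen.csv")
  wr(do.call(rbind, lapply(res, function(r) {
    cbind(outcome = r$outcome, r$outcome_screen)
  })), "taxa_outcome_models.csv")
  wr(do.call(rbind, lapply(res, function(r) {
    data.frame(outcome = r$outcome, sample_id = r$scores$sample_id,
               shannon = r$shannon,
               r$ordination$coordinates[r$scores$sample_id, , drop = FALSE],
               check.names = FALSE)
  })), "diversity_ordination.csv")
  med <- lapply(res, function(r) if (length(r$mediation))
    mediation_report(r$mediation) else NULL)
  med <- do.call(rbind, med[!vapply(med, is.null, logical(1))])
  if (!is.null(med)) wr(med, "mediation_report.csv")
  wr(do.call(rbind, lapply(res, function(r) {
    if (length(r$candidates) == 0L)
      return(NULL)
    data.frame(outcome = r$outcome, taxon = r$candidates)
  })), "mediator_candidates.csv")
  wr(do.call(rbind, lapply(res, function(r) cbind(outcome = r$outcome, r$scores))),
     "amed_scores.csv")
  jsonlite::write_json(x$metadata, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("amediate pipeline result\n")
  for (r in x$results) {
    cat(sprintf("\n== outcome %s (n = %d, %d excluded for energy) ==\n",
                r$outcome, r$n, r$n_excluded_energy))
    cat(sprintf("  aMed tertile trend: beta = %.3f, p = %.3g\n",
                r$tertile_model$beta, r$tertile_model$p_value))
    cat(sprintf("  taxa passing diet screen (q < %.2g): %d; mediator candidates: %s\n",
                0.25, sum(r$diet_screen$significant),
                if (length(r$candidates)) paste(r$candidates, collapse = ", ")
                else "none"))
    for (m in r$mediation)
      cat(sprintf("  mediation via %s: %.1f%% of the total association\n",
                  m$mediator, m$proportion_mediated))
  }
  invisible(x)
}
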