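## Alternate Mediterranean Diet (aMed) scoring.
##
## Nine components: vegetables, legumes, fruit, nuts, whole grains, fish and
## the monounsaturated:saturated fat ratio each score one point when intake
## lies strictly above the sex-specific cohort median; red and processed meat
## scores one point when intake lies strictly below the median; alcohol scores
## one point inside a fixed moderate window (5-25 g/d, both ends included).
## Totals range 0-9, higher = greater adherence.

#' Names of the nine aMed score components
#'
#' @return Character vector of the nine component names in canonical order.
#'   All but `red_meat` (reverse-scored) and `alcohol` (window-scored) award a
#'   point for intake above the sex-specific median.
#' @export
amed_components <- function() {
  c("vegetables", "legumes", "fruit", "nuts", "wholegrains",
    "fish", "mufa_sfa_ratio", "red_meat", "alcohol")
}

## components scored against a sex-specific median (all but alcohol)
median_components <- function() setdiff(amed_components(), "alcohol")

check_intakes <- function(intakes) {
  needed <- c("sample_id", amed_components(), "energy")
  missing <- setdiff(needed, names(intakes))
  if (length(missing))
    abort_validation(paste0("intake table is missing column(s): ",
                            paste(missing, collapse = ", ")))
  num <- c(amed_components(), "energy")
  for (col in num) {
    v <- intakes[[col]]
    if (!is.numeric(v))
      abort_validation(paste0("intake column '", col, "' must be numeric"))
    if (any(v < 0, na.rm = TRUE))
      abort_validation(paste0("intake column '", col, "' has negative values"))
  }
  if (any(intakes$energy <= 0, na.rm = TRUE))
    abort_validation("energy intakes must be positive")
  invisible(intakes)
}

#' Exclude participants with implausible energy intakes
#'
#' Removes records whose reported energy intake is below 800 kcal/d or above
#' 6000 kcal/d; the bounds themselves survive (the exclusion is strict).
#'
#' @param intakes Data frame with at least `sample_id` and `energy` (kcal/d).
#' @param lower,upper Plausibility bounds in kcal/d.
#' @return List with elements `kept` and `excluded`, both data frames in the
#'   original row order; `kept` plus `excluded` partition the input.
#' @export
exclude_implausible_energy <- function(intakes, lower = 800, upper = 6000) {
  if (!is.data.frame(intakes) || nrow(intakes) == 0L)
    abort_validation("intake table must be a non-empty data frame")
  if (!"energy" %in% names(intakes))
    abort_validation("intake table is missing column(s): energy")
  keep <- intakes$energy >= lower & intakes$energy <= upper
  keep[is.na(keep)] <- FALSE
  list(kept = intakes[keep, , drop = FALSE],
       excluded = intakes[!keep, , drop = FALSE])
}

#' Sex-specific component medians
#'
#' Within-stratum medians of the eight median-scored aMed components
#' (alcohol is scored against a fixed window, not a median). Apply the energy
#' exclusion before calling; the medians define the analysis-sample cutpoints.
#'
#' @param intakes Intake data frame (see [amed_components()] for columns).
#' @param sex Per-row stratum labels (typically `"male"` / `"female"`).
#' @return A data frame with one row per component and one column per stratum.
#' @export
compute_sex_specific_medians <- function(intakes, sex) {
  check_intakes(intakes)
  sex <- as.character(sex)
  if (length(sex) != nrow(intakes))
    abort_validation("sex labels must match the intake rows")
  strata <- sort(unique(sex))
  if (any(is.na(sex)) || length(strata) < 1L)
    abort_validation("sex labels must be non-missing")
  comps <- median_components()
  out <- vapply(strata, function(s) {
    rows <- sex == s
    if (!any(rows)) abort_validation(paste0("sex stratum '", s, "' is empty"))
    vapply(comps, function(cp) median(intakes[[cp]][rows]), numeric(1))
  }, numeric(length(comps)))
  out <- as.data.frame(out)
  rownames(out) <- comps
  out
}

#' Score a single aMed component
#'
#' @param component One of [amed_components()].
#' @param intake Intake value(s) in g/d (dimensionless for `mufa_sfa_ratio`).
#' @param median Sex-specific median for the participant's stratum; ignored
#'   for `alcohol`.
#' @param alcohol_window Closed moderate-intake window in g/d.
#' @return Integer 0/1 point(s), vectorized over `intake`.
#' @export
score_component <- function(component, intake, median = NULL,
                            alcohol_window = c(5, 25)) {
  if (!component %in% amed_components())
    abort_validation(paste0("unknown aMed component: ", component))
  if (component == "alcohol") {
    return(as.integer(intake >= alcohol_window[1] & intake <= alcohol_window[2]))
  }
  if (is.null(median))
    abort_validation(paste0("component '", component, "' needs a median"))
  if (component == "red_meat") as.integer(intake < median)
  else as.integer(intake > median)
}

#' Compute aMed scores for a cohort
#'
#' Scores each of the nine components against sex-specific medians computed
#' on the supplied (already energy-filtered) sample, and sums them to the
#' 0-9 total.
#'
#' @param intakes Intake data frame (post energy exclusion).
#' @param sex Per-row stratum labels.
#' @param medians Optional precomputed medians from
#'   [compute_sex_specific_medians()]; recomputed from `intakes` when `NULL`.
#' @param alcohol_window Closed moderate alcohol window in g/d.
#' @return Data frame: `sample_id`, one 0/1 column per component, and `total`.
#' @export
compute_amed_scores <- function(intakes, sex, medians = NULL,
                                alcohol_window = c(5, 25)) {
  check_intakes(intakes)
  sex <- as.character(sex)
  if (is.null(medians)) medians <- compute_sex_specific_medians(intakes, sex)
  pts <- data.frame(sample_id = intakes$sample_id)
  for (cp in amed_components()) {
    if (cp == "alcohol") {
      pts[[cp]] <- score_component(cp, intakes[[cp]],
                                   alcohol_window = alcohol_window)
    } else {
      med <- as.numeric(medians[cp, sex])
      pts[[cp]] <- score_component(cp, intakes[[cp]], med)
    }
  }
  pts$total <- rowSums(pts[, amed_components()])
  stopifnot(all(pts$total >= 0 & pts$total <= 9))
  pts
}

#' Assign sex-specific tertiles of the aMed score
#'
#' Within each sex stratum, participants are ranked by total score and cut at
#' the empirical 1/3 and 2/3 quantile positions; scores tied at a boundary all
#' receive the lower tertile label, so tertile sizes are unequal exactly when
#' the tie structure forces it.
#'
#' @param total Numeric vector of aMed totals.
#' @param sex Per-participant stratum labels.
#' @return Factor with levels `T1 < T2 < T3` (a degenerate stratum can leave
#'   upper levels empty).
#' @export
assign_sex_specific_tertiles <- function(total, sex) {
  sex <- as.character(sex)
  if (length(total) != length(sex))
    abort_validation("total and sex must have equal length")
  out <- character(length(total))
  for (s in unique(sex)) {
    rows <- which(sex == s)
    n <- length(rows)
    if (n < 3L)
      abort_validation(paste0("sex stratum '", s, "' has fewer than 3 participants"))
    srt <- sort(total[rows])
    cut1 <- srt[ceiling(n / 3)]
    cut2 <- srt[ceiling(2 * n / 3)]
    lab <- ifelse(total[rows] <= cut1, "T1",
                  ifelse(total[rows] <= cut2, "T2", "T3"))
    out[rows] <- lab
  }
  factor(out, levels = c("T1", "T2", "T3"))
}

#' Binary above/below-median exposure for one component
#'
#' The per-component contrast used for the component-level analyses: above vs
#' below the sex-specific median for favorable components, below vs above for
#' red and processed meat, and inside vs outside the moderate window for
#' alcohol. Identical to the component's score points.
#'
#' @inheritParams compute_amed_scores
#' @param component One of [amed_components()].
#' @return Integer 0/1 exposure per participant.
#' @export
component_binary_exposure <- function(intakes, sex, component, medians = NULL,
                                      alcohol_window = c(5, 25)) {
  check_intakes(intakes)
  sex <- as.character(sex)
  if (component == "alcohol")
    return(score_component("alcohol", intakes$alcohol,
                           alcohol_window = alcohol_window))
  if (is.null(medians)) medians <- compute_sex_specific_medians(intakes, sex)
  med <- as.numeric(medians[component, sex])
  score_component(component, intakes[[component]], med)
}
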