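#' Assemble a full pipeline report
#'
#' Runs the complete analysis on an assessment table: scores both
#' timepoints, summarizes the gain, fits the change-score factor model
#' (parallel-analysis retention, ML extraction, varimax, fit panel) and the
#' spline dose-response (with the 4-vs-0 and 7-vs-4 module contrasts and
#' the tail-flatness check), and tests demographic independence.
#'
#' @param assessments long assessment data frame (both timepoints).
#' @param battery a `bhi_battery`.
#' @param seed seed for the parallel-analysis reference.
#' @param m forced factor count (`NULL`: retain by parallel analysis).
#' @param reps parallel-analysis replicates.
#' @param spline_df dose-response spline df.
#' @return A `bhi_report` list: `gain`, `factors`, `dose`, `demographics`,
#'   `meta` (resolved settings and package version).
#' @export
bhi_report <- function(assessments, battery, seed, m = NULL, reps = 500,
                       spline_df = 3) {
  if (missing(seed)) stop("bhi_report() requires an explicit seed")
  scores <- score_assessments(assessments, battery)
  deltas <- delta_table(assessments, battery, scores)
  gain <- gain_summary(deltas)
  sol <- factor_solution(deltas[, paste0("d_", battery$id)],
                         m = m, reps = reps, seed = seed)
  out_dose <- NULL
  if ("modules_completed" %in% names(deltas)) {
    fit <- fit_dose_response(deltas, df = spline_df)
    out_dose <- list(
      fit = fit,
      curve = predict_dose(fit, seq(fit$dose_range[1], fit$dose_range[2],
                                    length.out = 50)),
      contrast_4_0 = dose_contrast(fit, 4, 0),
      contrast_7_4 = dose_contrast(fit, 7, 4),
      flatness = flatness_beyond(fit))
  }
  demo <- NULL
  if (any(c("age", "gender", "education") %in% names(deltas)))
    demo <- demographic_independence(deltas)
  meta <- list(package_version = as.character(utils::packageVersion("bhindex")),
               seed = seed, reps = reps, spline_df = spline_df,
               m = sol$m, n_completers = nrow(deltas),
               weights = stats::setNames(battery$weight, battery$id))
  structure(list(scores = scores, deltas = deltas, gain = gain,
                 factors = sol, dose = out_dose, demographics = demo,
                 meta = meta),
            class = "bhi_report")
}

#' @export
print.bhi_report <- function(x, ...) {
  g <- x$gain
  cat("<bhi_report>\n")
  cat(sprintf("  completers: %d; mean gain %.2f points (sd %.2f), d = %.2f [%.2f, %.2f]\n",
              g$n, g$mean, g$sd, g$d, g$d_ci[1], g$d_ci[2]))
  cat(sprintf("  %.0f%% with >= %g-point gain\n", 100 * g$prop_at_least,
              g$threshold))
  cat("  factors: "); print(x$factors)
  if (!is.null(x$dose)) {
    cat(sprintf("  dose contrasts: 4 vs 0 = %.2f, 7 vs 4 = %.2f; tail %s\n",
                x$dose$contrast_4_0$estimate, x$dose$contrast_7_4$estimate,
                if (x$dose$flatness$flat) "flat" else "not flat"))
  }
  invisible(x)
}

#' Serialize a report to JSON
#'
#' Machine-readable summary: gain statistics, eigenvalue table, fit panel,
#' normalized loadings, dose contrasts and demographic tests, with the
#' resolved configuration embedded for reproducibility.
#'
#' @param report a `bhi_report`.
#' @param path optional output file.
#' @return The JSON text, invisibly.
#' @export
report_json <- function(report, path = NULL) {
  sol <- report$factors
  payload <- list(
    meta = report$meta,
    gain = report$gain,
    factor_model = list(
      retained = sol$parallel$retained, m = sol$m,
      eigenvalues = sol$parallel$eigenvalues,
      reference_eigenvalues = sol$parallel$reference,
      adjusted_eigenvalues = sol$parallel$adjusted,
      fit = sol$fit,
      normalized_loadings = as.data.frame(sol$normalized),
      salient_mass = sol$salient_mass,
      cumulative_variance = sol$variance$cumulative_variance,
      proportion_explained = sol$variance$proportion_explained),
    dose_response = if (!is.null(report$dose)) list(
      knots = report$dose$fit$knots,
      contrast_4_0 = report$dose$contrast_4_0,
      contrast_7_4 = report$dose$contrast_7_4,
      flatness = report$dose$flatness) else NULL,
    demographics = report$demographics)
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = 8,
                          pretty = TRUE, null = "null")
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}
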