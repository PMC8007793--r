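#' Clinician-consensus measure weights
#'
#' Half of the total index weight goes to the cognition domain; daily life
#' and social interaction carry relatively higher weight than well-being
#' because they represent long-term function. Within a domain the weight is
#' split equally among its measures. The non-cognitive split is a package
#' default (the consensus scheme fixed only the cognitive share) and can be
#' overridden.
#'
#' @param battery a `bhi_battery`.
#' @param domain_weights named vector of domain totals summing to 1.
#' @return Named vector of per-measure weights summing to 1.
#' @export
consensus_weights <- function(battery,
                              domain_weights = c(cognition = 0.50,
                                                 daily_life = 0.20,
                                                 social_interaction = 0.20,
                                                 well_being = 0.10)) {
  stopifnot(inherits(battery, "bhi_battery"))
  if (abs(sum(domain_weights) - 1) > 1e-9)
    stop("domain weights must sum to 1")
  counts <- table(battery$domain)
  w <- domain_weights[battery$domain] / as.numeric(counts[battery$domain])
  names(w) <- battery$id
  w
}

#' Score one assessment record
#'
#' Converts each raw measure score to a percentile via its reference
#' distribution (reversing reverse-scored measures), then combines
#' percentiles as the weighted average \eqn{\sum_i w_i P_i} with
#' \eqn{\sum_i w_i = 1}. Domain component scores use the within-domain
#' weights renormalized to 1. Missing measures have their weight
#' renormalized over the available set; a fully missing domain is an error
#' because the index is defined as a four-component composite.
#'
#' @param record named numeric vector (or one-row data frame) of raw scores
#'   keyed by measure id; `NA` marks a missing measure.
#' @param battery a `bhi_battery` with weights.
#' @return A `bhi_result` list: `percentiles`, `components` (one per
#'   domain), `overall`, `weights`.
#' @export
compute_index <- function(record, battery) {
  validate_battery(battery)
  if (is.data.frame(record)) record <- unlist(record[1, , drop = TRUE])
  x <- as.numeric(record[battery$id])
  P <- rep(NA_real_, nrow(battery))
  ok <- !is.na(x)
  for (i in which(ok))
    P[i] <- percentile(battery$reference[[i]], x[i], battery$direction[i])
  names(P) <- battery$id
  for (d in bhi_domains()) {
    in_d <- battery$domain == d
    if (!any(ok & in_d))
      stop("no non-missing measure in domain '", d, "'")
  }
  w <- battery$weight
  wn <- ifelse(ok, w, 0)
  wn <- wn / sum(wn)
  overall <- sum(wn * P, na.rm = TRUE)
  components <- vapply(bhi_domains(), function(d) {
    in_d <- battery$domain == d & ok
    wd <- w[in_d] / sum(w[in_d])
    sum(wd * P[in_d])
  }, 0)
  structure(list(percentiles = P, components = components,
                 overall = overall, weights = wn),
            class = "bhi_result")
}

#' @export
print.bhi_result <- function(x, ...) {
  cat("<bhi_result> overall =", round(x$overall, 2), "\n")
  print(round(x$components, 2))
  invisible(x)
}

#' Score a cohort of assessment records
#'
#' Vectorized scoring of a long-format assessment table (one row per
#' participant x timepoint, one column per measure id).
#'
#' @param assessments data frame with columns `participant_id`, `timepoint`
#'   (1 or 2) and one column per battery measure id.
#' @param battery a `bhi_battery`.
#' @return Data frame of `participant_id`, `timepoint`, one percentile
#'   column per measure (prefixed `p_`), the four domain component scores
#'   and `overall`.
#' @export
score_assessments <- function(assessments, battery) {
  validate_battery(battery)
  missing_cols <- setdiff(battery$id, names(assessments))
  if (length(missing_cols))
    stop("assessment table lacks measure columns: ",
         paste(missing_cols, collapse = ", "))
  if (!all(assessments$timepoint %in% c(1, 2)))
    stop("timepoint must be 1 or 2")
  key <- paste(assessments$participant_id, assessments$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (participant, timepoint) records")
  n <- nrow(assessments)
  P <- matrix(NA_real_, n, nrow(battery),
              dimnames = list(NULL, battery$id))
  for (i in seq_len(nrow(battery))) {
    xi <- as.numeric(assessments[[battery$id[i]]])
    ok <- !is.na(xi)
    P[ok, i] <- percentile(battery$reference[[i]], xi[ok],
                           battery$direction[i])
  }
  w <- battery$weight
  ok <- !is.na(P)
  wn <- ok * rep(w, each = n)
  wn <- wn / rowSums(wn)
  overall <- rowSums(wn * P, na.rm = TRUE)
  comp <- sapply(bhi_domains(), function(d) {
    in_d <- battery$domain == d
    wd <- ok[, in_d, drop = FALSE] * rep(w[in_d], each = n)
    if (any(rowSums(wd) == 0))
      stop("no non-missing measure in domain '", d, "'")
    rowSums((wd / rowSums(wd)) * P[, in_d, drop = FALSE], na.rm = TRUE)
  })
  out <- data.frame(participant_id = assessments$participant_id,
                    timepoint = assessments$timepoint)
  colnames(P) <- paste0("p_", colnames(P))
  cbind(out, P, comp, overall = overall)
}

#' Index change between two scored timepoints
#'
#' @param result_t1,result_t2 `bhi_result` objects for the same participant
#'   (or numeric overall scores).
#' @param participant_id optional pair of ids checked for equality.
#' @return Change in index points, time 2 minus time 1.
#' @export
delta_index <- function(result_t1, result_t2, participant_id = NULL) {
  if (!is.null(participant_id) && length(participant_id) == 2 &&
      participant_id[1] != participant_id[2])
    stop("results belong to different participants")
  o1 <- if (inherits(result_t1, "bhi_result")) result_t1$overall else result_t1
  o2 <- if (inherits(result_t2, "bhi_result")) result_t2$overall else result_t2
  o2 - o1
}

#' Per-participant change table
#'
#' Joins the two timepoints of a scored cohort into one row per completer:
#' sign-adjusted raw change per measure (so that positive change always
#' means improvement), the index change, and any carried covariates
#' (`modules_completed`, `age`, `gender`, `education`).
#'
#' @param assessments the raw assessment table (both timepoints).
#' @param battery a `bhi_battery`.
#' @param scores optional precomputed output of [score_assessments()].
#' @return Data frame with one row per participant present at both
#'   timepoints: `participant_id`, `d_<measure>` columns, `dbhi`, covariates.
#' @export
delta_table <- function(assessments, battery, scores = NULL) {
  if (is.null(scores)) scores <- score_assessments(assessments, battery)
  t1 <- assessments[assessments$timepoint == 1, , drop = FALSE]
  t2 <- assessments[assessments$timepoint == 2, , drop = FALSE]
  common <- intersect(t1$participant_id, t2$participant_id)
  t1 <- t1[match(common, t1$participant_id), , drop = FALSE]
  t2 <- t2[match(common, t2$participant_id), , drop = FALSE]
  sgn <- ifelse(battery$direction == "lower_better", -1, 1)
  d <- sapply(seq_len(nrow(battery)), function(i) {
    sgn[i] * (as.numeric(t2[[battery$id[i]]]) -
              as.numeric(t1[[battery$id[i]]]))
  })
  colnames(d) <- paste0("d_", battery$id)
  s1 <- scores[scores$timepoint == 1, ]
  s2 <- scores[scores$timepoint == 2, ]
  dbhi <- s2$overall[match(common, s2$participant_id)] -
    s1$overall[match(common, s1$participant_id)]
  out <- data.frame(participant_id = common)
  out <- cbind(out, d, dbhi = dbhi)
  for (cv in c("modules_completed", "age", "gender", "education"))
    if (cv %in% names(t1)) out[[cv]] <- t1[[cv]]
  out
}

#' Gain summary for a cohort's index changes
#'
#' Mean change, its one-sample t test, Cohen's d = mean/sd with a
#' noncentral-t confidence interval, and the proportion of participants
#' with at least a threshold gain (default 5 index points).
#'
#' @param deltas numeric vector of index changes, or a [delta_table()]
#'   data frame (its `dbhi` column is used).
#' @param threshold gain threshold in index points.
#' @param conf_level confidence level for the d interval.
#' @return List: `n`, `mean`, `sd`, `t`, `p`, `d`, `d_ci`,
#'   `prop_at_least`.
#' @export
gain_summary <- function(deltas, threshold = 5, conf_level = 0.95) {
  x <- if (is.data.frame(deltas)) deltas$dbhi else deltas
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("gain summary requires at least 2 observations")
  m <- mean(x); s <- stats::sd(x)
  tt <- stats::t.test(x)
  d <- m / s
  ci <- .d_ci_noncentral(d, n, conf_level)
  list(n = n, mean = m, sd = s,
       t = unname(tt$statistic), p = tt$p.value,
       d = d, d_ci = ci,
       prop_at_least = mean(x >= threshold), threshold = threshold)
}

# CI for Cohen's d of a one-sample change by inverting the noncentral-t
# distribution of t = d * sqrt(n).
.d_ci_noncentral <- function(d, n, conf_level = 0.95) {
  t_obs <- d * sqrt(n)
  df <- n - 1
  alpha <- 1 - conf_level
  # pt() with large ncp warns about final-digit precision; irrelevant here
  f <- function(ncp, target)
    suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - target
  lim <- abs(t_obs) + 10 * sqrt(1 + t_obs^2 / (2 * df)) + 10
  lo <- tryCatch(stats::uniroot(f, c(-lim, lim), target = 1 - alpha / 2,
                                tol = 1e-8)$root, error = function(e) NA_real_)
  hi <- tryCatch(stats::uniroot(f, c(-lim, lim), target = alpha / 2,
                                tol = 1e-8)$root, error = function(e) NA_real_)
  c(lower = lo / sqrt(n), upper = hi / sqrt(n))
}
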