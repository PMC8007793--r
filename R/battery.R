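#' The four brain-health domains
#'
#' The battery spans exactly four domains: cognition, well-being, social
#' interaction and daily life.
#' @return Character vector of the four domain labels.
#' @export
bhi_domains <- function() {
  c("cognition", "well_being", "social_interaction", "daily_life")
}

# Nominal raw-score scales for the default battery. The pipeline consumes
# instrument totals, so each measure only needs a family and two moments;
# values are plausible published ranges for the named instruments, not
# normative constants.
.default_measure_table <- function() {
  df <- read.csv(text = "
id,name,domain,direction,family,m1,m2
strategic_attention_t2,Strategic attention (trial 2),cognition,higher_better,gaussian,28,9
strategic_attention_t3,Strategic attention (trial 3),cognition,higher_better,gaussian,32,9
innovation,Innovation,cognition,higher_better,gaussian,24,7
high_level_interpretation,High-level interpretation,cognition,higher_better,gaussian,15,4
abstraction,Abstraction,cognition,higher_better,gaussian,18,5
summary_of_text,Summary of text,cognition,higher_better,gaussian,21,6
memory,Memory,cognition,higher_better,gaussian,33,8
happiness,Happiness,well_being,higher_better,gaussian,4.3,0.7
depression,Depression,well_being,lower_better,gamma,4.0,3.8
anxiety,Anxiety,well_being,lower_better,gamma,3.5,3.3
stress,Stress,well_being,lower_better,gamma,6.5,4.5
resilience,Resilience,well_being,higher_better,gaussian,75,12
satisfaction,Satisfaction,well_being,higher_better,gaussian,83,14
meaningful_activities,Meaningful activities,daily_life,higher_better,gaussian,38,6
sleep,Sleep,daily_life,lower_better,negative_binomial,5,9
metabolic_equivalents,Metabolic equivalents,daily_life,higher_better,bootstrap_met,NA,NA
outlook,Outlook,daily_life,higher_better,gaussian,70,12
social_support,Social support,social_interaction,higher_better,gaussian,28,5
compassion,Compassion,social_interaction,higher_better,gaussian,100,15
social_engagement,Social engagement,social_interaction,higher_better,gaussian,50,10
", stringsAsFactors = FALSE, strip.white = TRUE)
  df
}

.build_ref <- function(family, m1, m2, id, empirical_n, seed) {
  switch(family,
    gaussian = ref_gaussian(m1, m2),
    gamma = ref_gamma(m1, m2),
    negative_binomial = ref_negative_binomial(m1, m2),
    bootstrap_met = bootstrap_met_cdf(seed = seed),
    empirical = {
      # cognition references are empirical samples; fabricate a reference
      # population from the nominal Gaussian scale, deterministically
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      ref_empirical(stats::rnorm(empirical_n, m1, m2))
    },
    stop("unknown reference family: ", family))
}

#' The default 20-measure assessment battery
#'
#' Seven cognition measures, six well-being, four daily-life and three
#' social-interaction measures, with depression, anxiety, stress and sleep
#' reverse-scored (lower raw scores are better). Cognition measures carry
#' empirical reference samples (fabricated deterministically from nominal
#' scales, standing in for a large normative sample); questionnaire totals
#' use moment-matched Gaussian or gamma references; the sleep index uses a
#' negative-binomial reference; metabolic equivalents use a bootstrap
#' reference built from the sufficient statistics of the fitness
#' questionnaire inputs. Weights default to the clinician-consensus scheme
#' (see [consensus_weights()]).
#'
#' @param empirical_n size of each fabricated empirical reference sample.
#' @param seed seed for the fabricated empirical and bootstrap references.
#' @param domain_weights named domain weight vector passed to
#'   [consensus_weights()].
#' @return A `bhi_battery`: a data frame with one row per measure (columns
#'   `id`, `name`, `domain`, `direction`, `weight`) and a list column
#'   `reference` of [bhi_ref] objects.
#' @export
default_battery <- function(empirical_n = 1000, seed = 20260101,
                            domain_weights = NULL) {
  tab <- .default_measure_table()
  refs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    fam <- tab$family[i]
    if (tab$domain[i] == "cognition") fam <- "empirical"
    refs[[i]] <- .build_ref(fam, tab$m1[i], tab$m2[i], tab$id[i],
                            empirical_n, seed + i)
  }
  bat <- tab[, c("id", "name", "domain", "direction")]
  bat$reference <- refs
  bat$family <- ifelse(tab$domain == "cognition", "empirical", tab$family)
  bat <- new_battery(bat)
  w <- if (is.null(domain_weights)) consensus_weights(bat)
       else consensus_weights(bat, domain_weights)
  bat$weight <- as.numeric(w[bat$id])
  validate_battery(bat)
}

new_battery <- function(df) {
  class(df) <- c("bhi_battery", "data.frame")
  df
}

validate_battery <- function(bat) {
  stopifnot(inherits(bat, "bhi_battery"))
  if (anyDuplicated(bat$id))
    stop("duplicate measure id: ",
         paste(unique(bat$id[duplicated(bat$id)]), collapse = ", "))
  if (!all(bat$domain %in% bhi_domains()))
    stop("unknown domain label")
  if (!all(bat$direction %in% c("higher_better", "lower_better")))
    stop("direction must be higher_better or lower_better")
  if (!is.null(bat$weight)) {
    if (any(bat$weight < 0)) stop("negative measure weight")
    if (abs(sum(bat$weight) - 1) > 1e-12)
      stop("measure weights must sum to 1")
  }
  bat
}

#' @export
print.bhi_battery <- function(x, ...) {
  cat("<bhi_battery> ", nrow(x), " measures\n", sep = "")
  tab <- table(factor(x$domain, levels = bhi_domains()))
  cat("  domains: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$weight)) {
    dw <- tapply(x$weight, x$domain, sum)
    cat("  domain weights: ",
        paste(names(dw), signif(dw, 3), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

.serialize_ref <- function(ref) {
  out <- list(method = ref$method)
  if (ref$method == "empirical") {
    out$sample <- ref$params$sample
  } else {
    out$params <- ref$params[names(ref$params) %in%
                               c("mean", "sd", "var", "shape", "rate",
                                 "size", "prob")]
  }
  out
}

.deserialize_ref <- function(spec) {
  m <- spec$method
  if (is.null(m)) stop("reference spec missing method")
  switch(m,
    empirical = ref_empirical(unlist(spec$sample)),
    gaussian = ref_gaussian(spec$params$mean, spec$params$sd),
    gamma = ref_gamma(spec$params$mean, spec$params$sd),
    negative_binomial = ref_negative_binomial(spec$params$mean,
                                              spec$params$var),
    stop("unknown reference method in config: ", m))
}

#' Save a battery configuration to JSON
#'
#' The configuration records, per measure: id, display name, domain,
#' direction, weight, and the full reference specification (including
#' empirical reference samples), so that `load_battery(save_battery(b))`
#' round-trips exactly.
#'
#' @param battery a `bhi_battery`.
#' @param path file path; if `NULL` the JSON text is returned invisibly.
#' @return The JSON text, invisibly.
#' @export
save_battery <- function(battery, path = NULL) {
  validate_battery(battery)
  measures <- lapply(seq_len(nrow(battery)), function(i) {
    list(id = battery$id[i], name = battery$name[i],
         domain = battery$domain[i], direction = battery$direction[i],
         family = if (is.null(battery$family)) battery$reference[[i]]$method
                  else battery$family[i],
         weight = battery$weight[i],
         reference = .serialize_ref(battery$reference[[i]]))
  })
  txt <- jsonlite::toJSON(list(measures = measures), auto_unbox = TRUE,
                          digits = NA, pretty = TRUE)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

#' Load a battery configuration from JSON
#'
#' @param config JSON text or a path to a JSON file, as written by
#'   [save_battery()]. Measures must supply `id`, `domain`, `direction` and a
#'   `reference` spec; if any weight is omitted, all weights default to the
#'   clinician-consensus scheme. Supplied weights are normalized to sum to 1.
#' @return A `bhi_battery`.
#' @export
load_battery <- function(config) {
  doc <- jsonlite::fromJSON(config, simplifyVector = FALSE)
  if (is.null(doc$measures)) stop("battery config has no 'measures' entry")
  rows <- lapply(doc$measures, function(m) {
    for (f in c("id", "domain", "direction", "reference"))
      if (is.null(m[[f]])) stop("measure config missing field: ", f)
    m
  })
  bat <- data.frame(
    id = vapply(rows, function(m) m$id, ""),
    name = vapply(rows, function(m) if (is.null(m$name)) m$id else m$name, ""),
    domain = vapply(rows, function(m) m$domain, ""),
    direction = vapply(rows, function(m) m$direction, ""),
    stringsAsFactors = FALSE)
  bat$reference <- lapply(rows, function(m) .deserialize_ref(m$reference))
  bat$family <- vapply(seq_along(rows), function(i) {
    if (is.null(rows[[i]]$family)) bat$reference[[i]]$method
    else rows[[i]]$family
  }, "")
  bat <- new_battery(bat)
  w <- vapply(rows, function(m) {
    if (is.null(m$weight)) NA_real_ else as.numeric(m$weight)
  }, 0)
  if (anyNA(w)) {
    bat$weight <- as.numeric(consensus_weights(bat)[bat$id])
  } else {
    if (any(w < 0) || sum(w) <= 0)
      stop("battery weights must be nonnegative with positive sum")
    bat$weight <- w / sum(w)
  }
  validate_battery(bat)
}
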