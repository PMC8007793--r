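#' Reference normalized loading pattern for the three change constructs
#'
#' The 20 x 3 normalized loading matrix describing the latent structure of
#' 3-month change scores observed in the pilot cohort: a social/mental-
#' fortitude construct, a mood construct (negative loadings on the
#' sign-adjusted depression, anxiety and stress changes), and a cognition
#' construct with contributions from sleep, outlook and compassion. Each
#' column has unit Euclidean norm up to printing precision. This matrix is
#' the default latent structure of the synthetic-cohort generator and the
#' reference pattern for recovery tests.
#'
#' @return Numeric 20 x 3 matrix, rows named by measure id, columns
#'   `F1`-`F3`.
#' @export
default_loadings <- function() {
  ids <- .default_measure_table()$id
  L <- matrix(c(
     0.046, -0.100,  0.139,
     0.009, -0.128,  0.322,
    -0.036,  0.017,  0.344,
     0.037, -0.086,  0.209,
     0.083, -0.061, -0.176,
    -0.060, -0.007,  0.178,
    -0.044, -0.043,  0.605,
     0.240,  0.245,  0.186,
    -0.086, -0.463,  0.036,
    -0.021, -0.506,  0.099,
     0.024, -0.568, -0.040,
     0.368,  0.156,  0.119,
     0.392,  0.157,  0.030,
     0.385, -0.036, -0.017,
    -0.054, -0.151, -0.200,
     0.166, -0.102,  0.149,
     0.134,  0.017,  0.205,
     0.390, -0.145, -0.103,
     0.274, -0.057,  0.317,
     0.451,  0.009, -0.094),
    ncol = 3, byrow = TRUE,
    dimnames = list(ids, c("F1", "F2", "F3")))
  L
}

#' Reference cumulative-variance row for the three change constructs
#'
#' Cumulative shares of total variance explained by the three constructs in
#' the pilot factor solution; [proportion_explained()] converts it to
#' per-factor proportions.
#' @return Numeric vector of length 3.
#' @export
default_cumulative_variance <- function() c(0.144, 0.229, 0.275)
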