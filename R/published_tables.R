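# Accessors for the published reference tables shipped with the package.
# All cells are stored verbatim, including known internal inconsistencies
# between tables; each accessor documents its table of origin so tests
# can assert against the published numbers without retyping them.

#' Published group summary statistics
#'
#' The study's descriptive table: per-parameter mean and SD for the obese
#' (n = 100) and normal (n = 100) groups, the printed percent-difference
#' column and significance p-values. These means/SDs are also the default
#' sampling targets of [cohort_spec()].
#'
#' Note two known quirks, stored verbatim: the printed percent differences
#' for `bf_pct`, `tbw_kg` and `mm_kg` do not match the symmetric
#' percent-difference formula that reproduces the other six rows (they
#' appear to be typographical), and the obese `bf_pct` mean here (31.309)
#' differs from the prototype-device mean in
#' [published_validation_table()] (30.309).
#'
#' @return Data frame with columns `parameter`, `obese_mean`, `obese_sd`,
#'   `normal_mean`, `normal_sd`, `pct_diff_printed`, `p_value`.
#' @export
published_group_summary <- function() {
  read.csv(pbc_extdata("published_group_summary.csv"),
           stringsAsFactors = FALSE)
}

#' Published device-validation table
#'
#' Group-level prototype (PBCA) vs reference (TBCA) means, SDs, standard
#' errors, p-values, and the printed per-row accuracies for the seven
#' validated parameters in both groups.
#'
#' @return Data frame with one row per (parameter, group).
#' @export
published_validation_table <- function() {
  read.csv(pbc_extdata("published_validation.csv"),
           stringsAsFactors = FALSE)
}

#' Published validation means as a paired-measurement table
#'
#' The validation table reduced to the paired layout consumed by
#' [mean_accuracy()], [mean_avg_error()] and [agreement_report()]:
#' `device_a` is the prototype mean, `device_b` the reference mean.
#'
#' @return Data frame with columns `parameter`, `group`, `device_a`,
#'   `device_b`.
#' @export
published_validation_pairs <- function() {
  v <- published_validation_table()
  data.frame(
    parameter = v$parameter,
    group = v$group,
    device_a = v$pbca_mean,
    device_b = v$tbca_mean,
    stringsAsFactors = FALSE
  )
}

#' Published correlation matrix (obese group)
#'
#' The Pearson correlation matrix published for the obese group (n = 100)
#' across the seven measured parameters, mirrored to a full symmetric
#' matrix with unit diagonal. Available as an optional correlation target
#' for the Gaussian-copula mode of [generate_cohort()].
#'
#' @return A 7 x 7 named numeric matrix.
#' @export
published_correlation_matrix <- function() {
  df <- read.csv(pbc_extdata("published_correlation.csv"),
                 stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$parameter
  m
}

#' Published reliability table (stored verbatim)
#'
#' The inter-rater reliability table for both devices: percent mean
#' difference with CI, p-values, SEM, mean difference, the published
#' "relative reliability" column, and inter-rater reliability with CI.
#' The relative-reliability and percent-mean-difference columns have no
#' stated formula (several values exceed any correlation bound); they are
#' carried verbatim and never recomputed by this package.
#'
#' @return Data frame with one row per (variable, device).
#' @export
published_reliability_table <- function() {
  read.csv(pbc_extdata("published_reliability.csv"),
           stringsAsFactors = FALSE)
}
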