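# Synthetic study cohorts: seeded truncated-normal sampling around the
# published per-group means/SDs, algebraic inversion of the estimation
# chain back to raw sensor frames, and a virtual device pair for
# exercising the agreement statistics. No external data are required
# anywhere in the pipeline.

# Composition parameters measured by both devices, in table order.
pbc_parameters <- function() {
  c("weight_kg", "bmi", "bf_pct", "ffm_kg", "tbw_kg", "mm_kg", "bm_kg")
}

# Truncated-normal draws via the inverse-CDF; `lo` may be a vector of
# subject-specific lower bounds. sd = 0 degenerates to the mean.
pbc_rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd < 0) pbc_stop("negative SD", class = "pedibca_spec_error")
  lo <- rep_len(lo, n)
  hi <- rep_len(hi, n)
  if (sd == 0) {
    if (any(lo > mean) || any(hi < mean)) {
      pbc_stop("truncation bounds exclude the (zero-SD) mean",
               class = "pedibca_spec_error")
    }
    return(rep(mean, n))
  }
  if (any(lo > mean + 4 * sd) || any(hi < mean - 4 * sd)) {
    pbc_stop("infeasible truncation: bounds exclude mean +/- 4 SD",
             class = "pedibca_spec_error")
  }
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Specification of a synthetic study cohort
#'
#' Defines the two study groups to simulate. The default per-group,
#' per-parameter means and SDs are the published descriptive statistics
#' ([published_group_summary()]): obese and normal groups of 100 children
#' each with a 50/50 sex split. Default truncation keeps weight, height
#' and the composition masses positive and body fat within (0, 60)%.
#'
#' @param n_obese,n_normal Group sizes (>= 1).
#' @param parameters Data frame in the layout of
#'   [published_group_summary()] giving the sampling mean/SD per
#'   parameter and group.
#' @param sex_split Proportion of boys per group (default 0.5).
#' @param bounds Named list of `c(lower, upper)` truncation bounds per
#'   parameter; unlisted parameters are unbounded.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   through it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_obese = 100, n_normal = 100,
                        parameters = published_group_summary(),
                        sex_split = 0.5,
                        bounds = NULL,
                        seed = 1L) {
  if (n_obese < 1L || n_normal < 1L) {
    pbc_stop("group sizes must be >= 1", class = "pedibca_spec_error")
  }
  need <- c("parameter", "obese_mean", "obese_sd", "normal_mean",
            "normal_sd")
  if (!all(need %in% names(parameters))) {
    pbc_schema_error("parameter table lacks mean/SD columns")
  }
  if (any(parameters$obese_sd < 0) || any(parameters$normal_sd < 0)) {
    pbc_stop("all SDs must be >= 0", class = "pedibca_spec_error")
  }
  default_bounds <- list(
    age_years = c(0, Inf), weight_kg = c(0, Inf), height_cm = c(0, Inf),
    bmi = c(0, Inf), bf_pct = c(0, 60), ffm_kg = c(0, Inf),
    tbw_kg = c(0, Inf), mm_kg = c(0, Inf), bm_kg = c(0, Inf)
  )
  bounds <- modifyList(default_bounds, bounds %||% list())
  structure(
    list(
      n_obese = as.integer(n_obese),
      n_normal = as.integer(n_normal),
      parameters = parameters,
      sex_split = sex_split,
      bounds = bounds,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a synthetic study cohort
#'
#' Draws a subject-level cohort for the two study groups using seeded
#' truncated-normal sampling around the specification's per-group
#' means/SDs.
#'
#' Two modes are offered because three of the nine parameters are
#' deterministic functions of the others in the device's forward chain
#' (BMI from weight and height; body fat from BMI, age and sex; bone
#' mass from weight, height and muscle mass), so no raw sensor frame can
#' realize independently sampled values for them:
#' \describe{
#'   \item{`"pipeline"` (default)}{samples the free quantities (age, sex,
#'     height, weight, fat-free mass, total body water, muscle mass) and
#'     derives BMI, body fat and bone mass through the estimation
#'     equations. Every subject is exactly realizable by a sensor frame,
#'     so the cohort round-trips through [invert_to_sensors()] and
#'     [estimate_all()].}
#'   \item{`"table"`}{samples all nine parameters independently from
#'     their published marginals, emulating the published summary table
#'     without cross-parameter consistency.}
#' }
#'
#' In `"table"` mode an optional correlation matrix (for example
#' [published_correlation_matrix()]) can be supplied; parameters named in
#' it are then drawn through a Gaussian copula targeting that
#' correlation. This is an extension for stress testing, not a claim
#' about the study population.
#'
#' Parameters are otherwise sampled independently; subject-specific lower
#' bounds keep fat-free and muscle mass inside the sensor-invertible
#' domain.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"pipeline"` or `"table"` (see Details).
#' @param correlation Optional correlation matrix for `"table"` mode.
#' @return Data frame with one row per subject: `subject_id`,
#'   `group_label`, `age_years`, `sex_code`, `height_cm` and the seven
#'   composition parameters.
#' @export
generate_cohort <- function(spec, mode = c("pipeline", "table"),
                            correlation = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(correlation) && mode != "table") {
    pbc_contract_error(
      "a correlation target is only meaningful in mode = \"table\""
    )
  }
  pars <- spec$parameters
  row_of <- function(p) pars[pars$parameter == p, , drop = FALSE]
  withr::with_seed(spec$seed, {
    groups <- list(
      obese = spec$n_obese,
      normal = spec$n_normal
    )
    out <- lapply(names(groups), function(g) {
      n <- groups[[g]]
      mean_col <- paste0(g, "_mean")
      sd_col <- paste0(g, "_sd")
      draw <- function(p, lo = NULL) {
        r <- row_of(p)
        if (nrow(r) != 1L) {
          pbc_schema_error(sprintf("no sampling row for parameter '%s'", p))
        }
        b <- spec$bounds[[p]] %||% c(-Inf, Inf)
        lo_eff <- if (is.null(lo)) b[1L] else pmax(b[1L], lo)
        pbc_rtruncnorm(n, r[[mean_col]], r[[sd_col]], lo_eff, b[2L])
      }
      n_boys <- round(n * spec$sex_split)
      sex <- sample(rep(c(1L, 0L), c(n_boys, n - n_boys)))
      age <- draw("age_years")
      height <- draw("height_cm")
      weight <- draw("weight_kg")
      # keep fat-free mass and muscle mass inside the invertible domain
      # (positive implied impedance/resistance)
      eps <- 1e-6
      ffm_v <- draw("ffm_kg", lo = 0.151 * weight + 1.613 + eps)
      mm_v <- draw("mm_kg", lo = sex + 3.825 + 5.102 - 0.071 * age + eps)
      tbw_v <- draw("tbw_kg")

      if (mode == "pipeline") {
        bmi_v <- bmi(weight, height / 100)
        bf_v <- bf_percent(bmi_v, age, sex)
        bm_v <- suppressWarnings(bm(weight, height, mm_v))
      } else {
        if (is.null(correlation)) {
          bmi_v <- draw("bmi")
          bf_v <- draw("bf_pct")
          bm_v <- draw("bm_kg")
        } else {
          cop <- pbc_copula_draw(n, correlation, pars, mean_col, sd_col,
                                 spec$bounds)
          # copula draws replace the marginal draws for named parameters
          for (p in colnames(cop)) {
            switch(p,
              weight_kg = weight <- cop[, p],
              ffm_kg = ffm_v <- cop[, p],
              tbw_kg = tbw_v <- cop[, p],
              mm_kg = mm_v <- cop[, p],
              bmi = NULL, bf_pct = NULL, bm_kg = NULL
            )
          }
          bmi_v <- if ("bmi" %in% colnames(cop)) cop[, "bmi"] else draw("bmi")
          bf_v <- if ("bf_pct" %in% colnames(cop)) cop[, "bf_pct"]
                  else draw("bf_pct")
          bm_v <- if ("bm_kg" %in% colnames(cop)) cop[, "bm_kg"]
                  else draw("bm_kg")
        }
      }
      data.frame(
        group_label = g, age_years = age, sex_code = sex,
        height_cm = height, weight_kg = weight, bmi = bmi_v,
        bf_pct = bf_v, ffm_kg = ffm_v, tbw_kg = tbw_v, mm_kg = mm_v,
        bm_kg = bm_v, stringsAsFactors = FALSE
      )
    })
    cohort <- do.call(rbind, out)
    cohort <- cbind(
      subject_id = sprintf("S%04d", seq_len(nrow(cohort))),
      cohort, stringsAsFactors = FALSE
    )
    attr(cohort, "mode") <- mode
    cohort
  })
}

# Gaussian-copula draw for the parameters named in `correlation`.
# The matrix is symmetrized and eigen-clipped to the nearest PSD
# correlation before factoring.
pbc_copula_draw <- function(n, correlation, pars, mean_col, sd_col,
                            bounds) {
  stopifnot(is.matrix(correlation),
            !is.null(rownames(correlation)),
            identical(rownames(correlation), colnames(correlation)))
  r <- (correlation + t(correlation)) / 2
  eg <- eigen(r, symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  root <- eg$vectors %*% diag(sqrt(vals), length(vals))
  z <- matrix(rnorm(n * ncol(r)), n) %*% t(root)
  u <- pnorm(z)
  out <- matrix(NA_real_, n, ncol(r), dimnames = list(NULL, colnames(r)))
  for (j in seq_len(ncol(r))) {
    p <- colnames(r)[j]
    row <- pars[pars$parameter == p, , drop = FALSE]
    if (nrow(row) != 1L) {
      pbc_schema_error(sprintf("no sampling row for parameter '%s'", p))
    }
    b <- bounds[[p]] %||% c(-Inf, Inf)
    m <- row[[mean_col]]
    s <- row[[sd_col]]
    if (s == 0) {
      out[, j] <- m
    } else {
      p_lo <- pnorm(b[1L], m, s)
      p_hi <- pnorm(b[2L], m, s)
      out[, j] <- qnorm(p_lo + u[, j] * (p_hi - p_lo), m, s)
    }
  }
  out
}

#' Invert a body composition to a raw sensor frame
#'
#' Solves the estimation chain backwards: ADC counts from weight via the
#' load-cell calibration, impedance from the fat-free-mass relation
#' (`Z = 0.742 H^2 / (FFM - 0.151 W - 1.613)`), resistance from the
#' muscle-mass relation, optical current from the total-body-water
#' relation, and the photosensor voltage from the optical current given a
#' configured initial voltage. Running [estimate_all()] on the resulting
#' frame reproduces the sensor-driven fields (weight, fat-free mass,
#' total body water, muscle mass) exactly; BMI, body fat and bone mass
#' follow deterministically from the profile, weight and muscle mass.
#'
#' @param composition A [body_composition()] object or named list with at
#'   least `weight_kg`, `ffm_kg`, `tbw_kg`, `mm_kg`.
#' @param profile A [subject_profile()].
#' @param calib A [fit_load_cell_calibration()].
#' @param v0_volts Initial photosensor voltage used for the optical
#'   inversion (default 0.5 V).
#' @param responsivity Photosensor responsivity (default 0.42).
#' @param i_load_a,frequency_hz Excitation settings recorded in the frame.
#' @param log_base Log base of the total-body-water equation.
#' @return A named list (sensor frame) with `subject_id`, `adc_counts`,
#'   `v0_volts`, `v_volts`, `z_ohm`, `resistance_ohm`, `i_load_a`,
#'   `frequency_hz`.
#' @export
invert_to_sensors <- function(composition, profile, calib,
                              v0_volts = 0.5, responsivity = 0.42,
                              i_load_a = 0.25e-3, frequency_hz = 50000,
                              log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(profile, "subject_profile"),
            inherits(calib, "load_cell_calibration"))
  comp <- as.list(composition)
  for (f in c("weight_kg", "ffm_kg", "tbw_kg", "mm_kg")) {
    if (is.null(comp[[f]]) || !is.finite(comp[[f]])) {
      pbc_stop(sprintf("composition lacks finite field '%s'", f),
               class = "pedibca_inversion_error")
    }
  }
  w <- comp$weight_kg
  h <- profile$height_cm
  if (w < 0) {
    pbc_stop("weight must be non-negative for the load-cell inversion",
             class = "pedibca_inversion_error")
  }
  adc <- (w + calib$offset_c) / calib$slope_m

  ffm_denom <- comp$ffm_kg - 0.151 * w - 1.613
  if (ffm_denom <= 0) {
    pbc_stop(
      "fat-free-mass relation not invertible: FFM must exceed 0.151*W + 1.613",
      class = "pedibca_inversion_error"
    )
  }
  z <- 0.742 * h^2 / ffm_denom

  mm_denom <- comp$mm_kg - profile$sex_code - 3.825 +
    0.071 * profile$age_years - 5.102
  if (mm_denom <= 0) {
    pbc_stop(
      "muscle-mass relation not invertible: resistance would be non-positive",
      class = "pedibca_inversion_error"
    )
  }
  res <- 0.401 * h^2 / mm_denom

  # total-body-water relation solved for the optical current
  x <- (comp$tbw_kg - 0.698 * profile$age_years - 0.414 * h +
          0.491 * w - 14.61) / 2.638
  oc <- if (log_base == "log10") 10^(-x) else exp(-x)
  v <- oc / responsivity

  list(
    subject_id = profile$subject_id,
    adc_counts = adc,
    v0_volts = v0_volts,
    v_volts = v,
    z_ohm = z,
    resistance_ohm = res,
    i_load_a = i_load_a,
    frequency_hz = frequency_hz
  )
}

#' Invert a whole cohort to sensor frames
#'
#' Applies [invert_to_sensors()] row-wise to a cohort generated by
#' [generate_cohort()].
#'
#' @param cohort Cohort data frame.
#' @param calib A [fit_load_cell_calibration()].
#' @param ... Passed to [invert_to_sensors()].
#' @return Data frame of sensor frames, one row per subject.
#' @export
invert_cohort <- function(cohort, calib, ...) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    s <- cohort[i, ]
    prof <- subject_profile(s$subject_id, s$age_years, s$sex_code,
                            s$height_cm, s$group_label)
    as.data.frame(invert_to_sensors(s, prof, calib, ...),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Specification of a virtual device pair
#'
#' Measurement-error model for two virtual devices measuring the same
#' cohort: independent zero-mean Gaussian error per device and parameter.
#'
#' @param error_sd_a,error_sd_b Error SDs for devices A and B: a single
#'   number applied to every parameter, or a named vector keyed by
#'   parameter (`weight_kg`, `bmi`, `bf_pct`, `ffm_kg`, `tbw_kg`,
#'   `mm_kg`, `bm_kg`).
#' @param seed Integer seed.
#' @return An object of class `device_pair_spec`.
#' @export
device_pair_spec <- function(error_sd_a = 0, error_sd_b = 0, seed = 1L) {
  expand <- function(sd) {
    pars <- pbc_parameters()
    if (length(sd) == 1L && is.null(names(sd))) {
      sd <- setNames(rep(sd, length(pars)), pars)
    }
    if (!all(names(sd) %in% pars)) {
      pbc_stop("error SDs keyed by unknown parameter",
               class = "pedibca_spec_error")
    }
    full <- setNames(rep(0, length(pars)), pars)
    full[names(sd)] <- sd
    if (any(full < 0)) {
      pbc_stop("error SDs must be >= 0", class = "pedibca_spec_error")
    }
    full
  }
  structure(
    list(
      error_sd_a = expand(error_sd_a),
      error_sd_b = expand(error_sd_b),
      seed = as.integer(seed)
    ),
    class = "device_pair_spec"
  )
}

#' Simulate paired measurements from two virtual devices
#'
#' Adds independent seeded Gaussian measurement error per device and
#' parameter to each subject's true composition, producing the
#' subject-level paired table consumed by [agreement_report()].
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param pair_spec A [device_pair_spec()].
#' @return Long data frame with columns `subject_id`, `group`,
#'   `parameter`, `device_a`, `device_b`.
#' @export
simulate_device_pair <- function(cohort, pair_spec) {
  stopifnot(inherits(pair_spec, "device_pair_spec"))
  pars <- pbc_parameters()
  withr::with_seed(pair_spec$seed, {
    rows <- lapply(pars, function(p) {
      truth <- cohort[[p]]
      n <- length(truth)
      data.frame(
        subject_id = cohort$subject_id,
        group = cohort$group_label,
        parameter = p,
        device_a = truth + rnorm(n, 0, pair_spec$error_sd_a[[p]]),
        device_b = truth + rnorm(n, 0, pair_spec$error_sd_b[[p]]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Collapse subject-level device pairs to group means
#'
#' Aggregates a [simulate_device_pair()] table to the per-(parameter,
#' group) mean level consumed by [mean_accuracy()] and
#' [mean_avg_error()].
#'
#' @param pairs Subject-level paired table.
#' @return Data frame with columns `parameter`, `group`, `device_a`,
#'   `device_b`.
#' @export
group_mean_pairs <- function(pairs) {
  agg <- aggregate(cbind(device_a, device_b) ~ parameter + group,
                   data = pairs, FUN = mean)
  agg[order(agg$parameter, agg$group), , drop = FALSE]
}
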