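# Estimation chain: from weight/height/age/sex and sensor-derived
# quantities to the six body-composition parameters, plus the CDC
# weight-status classification on a supplied BMI-for-age percentile.
#
# Symbols used in the device equations: W weight (kg), H height (cm,
# except BMI which takes metres), R age (years), S sex code (0 girl,
# 1 boy), Z impedance (ohm), OC optical current (A).

#' Subject demographic profile
#'
#' @param subject_id Opaque identifier string.
#' @param age_years Age in years, positive.
#' @param sex_code 0 for girls, 1 for boys.
#' @param height_cm Standing height in cm, positive.
#' @param group_label One of `"underweight"`, `"healthy"`, `"overweight"`,
#'   `"obese"`, `"normal"` or `"unknown"`. (`"normal"` is the study's
#'   shorthand for the healthy-weight group.)
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, age_years, sex_code, height_cm,
                            group_label = "unknown") {
  if (!sex_code %in% c(0, 1)) {
    pbc_domain_error("'sex_code' must be 0 (girl) or 1 (boy)")
  }
  pbc_check_numeric(age_years, "age_years", positive = TRUE)
  pbc_check_numeric(height_cm, "height_cm", positive = TRUE)
  allowed <- c("underweight", "healthy", "overweight", "obese", "normal",
               "unknown")
  if (!group_label %in% allowed) {
    pbc_domain_error(sprintf(
      "'group_label' must be one of: %s", paste(allowed, collapse = ", ")
    ))
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      age_years = age_years,
      sex_code = as.integer(sex_code),
      height_cm = height_cm,
      group_label = group_label
    ),
    class = "subject_profile"
  )
}

#' Body mass index
#'
#' `BMI = W / H^2` with weight in kg and height in metres. This is the
#' only equation in the chain that takes height in metres; everything
#' downstream uses centimetres.
#'
#' @param weight_kg Weight in kg, non-negative.
#' @param height_m Height in metres, positive.
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  pbc_check_numeric(weight_kg, "weight_kg", nonnegative = TRUE)
  pbc_check_numeric(height_m, "height_m", positive = TRUE)
  weight_kg / height_m^2
}

#' Body-fat percentage from BMI, age and sex
#'
#' The device's pediatric equation `BF% = 1.15*BMI - 0.7*R - 3.6*S + 1.4`
#' (R age in years, S sex code). Evaluated exactly as published; the
#' result is not clipped to \[0, 100\].
#'
#' @param bmi BMI in kg/m^2, non-negative.
#' @param age_years Age in years.
#' @param sex_code 0 for girls, 1 for boys.
#' @return Body-fat percentage.
#' @export
bf_percent <- function(bmi, age_years, sex_code) {
  pbc_check_numeric(bmi, "bmi", nonnegative = TRUE)
  pbc_check_numeric(age_years, "age_years")
  if (any(!sex_code %in% c(0, 1))) {
    pbc_domain_error("'sex_code' must be 0 (girl) or 1 (boy)")
  }
  1.15 * bmi - 0.7 * age_years - 3.6 * sex_code + 1.4
}

#' Fat-free mass from the impedance index
#'
#' `FFM = 0.742 * H^2 / Z + 0.151 * W + 1.613` with H in cm and Z in ohm.
#' `H^2/Z` is the classic bioimpedance "impedance index" predictor.
#'
#' @param height_cm Height in cm.
#' @param impedance_ohm Impedance magnitude in ohm, positive.
#' @param weight_kg Weight in kg.
#' @return Fat-free mass in kg.
#' @export
ffm <- function(height_cm, impedance_ohm, weight_kg) {
  pbc_check_numeric(height_cm, "height_cm", nonnegative = TRUE)
  pbc_check_numeric(impedance_ohm, "impedance_ohm", positive = TRUE)
  pbc_check_numeric(weight_kg, "weight_kg", nonnegative = TRUE)
  0.742 * height_cm^2 / impedance_ohm + 0.151 * weight_kg + 1.613
}

#' Muscle mass from the resistance index, sex and age
#'
#' `MM = 0.401 * H^2 / Res + S + 3.825 - 0.071 * R + 5.102` with H in cm,
#' Res in ohm, S the sex code and R age in years.
#'
#' @param height_cm Height in cm.
#' @param resistance_ohm Resistance in ohm, positive.
#' @param sex_code 0 for girls, 1 for boys.
#' @param age_years Age in years.
#' @return Muscle mass in kg.
#' @export
mm <- function(height_cm, resistance_ohm, sex_code, age_years) {
  pbc_check_numeric(height_cm, "height_cm", nonnegative = TRUE)
  pbc_check_numeric(resistance_ohm, "resistance_ohm", positive = TRUE)
  if (any(!sex_code %in% c(0, 1))) {
    pbc_domain_error("'sex_code' must be 0 (girl) or 1 (boy)")
  }
  pbc_check_numeric(age_years, "age_years")
  height_cm^2 / resistance_ohm * 0.401 + sex_code + 3.825 -
    0.071 * age_years + 5.102
}

#' Total body water from age, height, weight and optical current
#'
#' `TBW = 0.698*R + 0.414*H - 0.491*W + 2.638*log10(1/OC) + 14.61` with H
#' in cm and OC the photosensor optical current in A. The logarithm
#' defaults to base 10, consistent with the optical-density definition; a
#' natural-log variant is available for sensitivity analysis.
#'
#' @param age_years Age in years.
#' @param height_cm Height in cm.
#' @param weight_kg Weight in kg.
#' @param optical_current_a Optical current in A, positive.
#' @param log_base `"log10"` (default) or `"ln"`.
#' @return Total body water in kg.
#' @export
tbw <- function(age_years, height_cm, weight_kg, optical_current_a,
                log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  pbc_check_numeric(age_years, "age_years")
  pbc_check_numeric(height_cm, "height_cm", nonnegative = TRUE)
  pbc_check_numeric(weight_kg, "weight_kg", nonnegative = TRUE)
  pbc_check_numeric(optical_current_a, "optical_current_a", positive = TRUE)
  lg <- if (log_base == "log10") log10 else log
  0.698 * age_years + 0.414 * height_cm - 0.491 * weight_kg +
    2.638 * lg(1 / optical_current_a) + 14.61
}

#' Bone mass from weight, height and muscle mass
#'
#' `BM = 0.328*W + 0.339*H - 29.533 - MM` with H in cm. The published
#' equation can produce negative values for small children; these are
#' emitted with a soft warning rather than rejected.
#'
#' @param weight_kg Weight in kg.
#' @param height_cm Height in cm.
#' @param mm_kg Muscle mass in kg.
#' @return Bone mass in kg.
#' @export
bm <- function(weight_kg, height_cm, mm_kg) {
  pbc_check_numeric(weight_kg, "weight_kg")
  pbc_check_numeric(height_cm, "height_cm")
  pbc_check_numeric(mm_kg, "mm_kg")
  out <- 0.328 * weight_kg + 0.339 * height_cm - 29.533 - mm_kg
  if (any(out < 0)) {
    pbc_warn(sprintf("bone mass estimate is negative (min %.3f kg)",
                     min(out)))
  }
  out
}

#' Body-composition result container
#'
#' Bundles the six estimated parameters plus weight for one subject and
#' applies soft-range checks: a body-fat percentage outside \[0, 100\]
#' warns but is kept (the published equations can produce such values and
#' the package reproduces them as printed).
#'
#' @param weight_kg,bmi,bf_pct,ffm_kg,tbw_kg,mm_kg,bm_kg Parameter values;
#'   all must be finite and weight positive.
#' @return An object of class `body_composition`.
#' @export
body_composition <- function(weight_kg, bmi, bf_pct, ffm_kg, tbw_kg,
                             mm_kg, bm_kg) {
  vals <- c(weight_kg = weight_kg, bmi = bmi, bf_pct = bf_pct,
            ffm_kg = ffm_kg, tbw_kg = tbw_kg, mm_kg = mm_kg,
            bm_kg = bm_kg)
  if (any(!is.finite(vals))) {
    pbc_domain_error("all body-composition fields must be finite")
  }
  if (weight_kg <= 0) {
    pbc_domain_error("'weight_kg' must be positive")
  }
  if (bf_pct < 0 || bf_pct > 100) {
    pbc_warn(sprintf("body-fat percentage %.2f outside [0, 100]", bf_pct))
  }
  structure(as.list(vals), class = "body_composition")
}

#' @export
print.body_composition <- function(x, ...) {
  cat("Body composition estimate\n")
  lab <- c(weight_kg = "Weight (kg)", bmi = "BMI (kg/m2)",
           bf_pct = "Body fat (%)", ffm_kg = "Fat-free mass (kg)",
           tbw_kg = "Total body water (kg)", mm_kg = "Muscle mass (kg)",
           bm_kg = "Bone mass (kg)")
  for (f in names(lab)) {
    cat(sprintf("  %-22s %8.3f\n", lab[[f]], x[[f]]))
  }
  invisible(x)
}

#' CDC weight-status category from a BMI-for-age percentile
#'
#' Maps a supplied BMI-for-age percentile to the CDC category: below the
#' 5th percentile underweight, 5th up to (not including) the 85th healthy,
#' 85th up to the 95th overweight, 95th and above obese. The percentile is
#' an input; this package does not compute percentiles from growth
#' references.
#'
#' @param bmi_for_age_percentile Percentile in \[0, 100\]; vectorized.
#' @return Character vector of categories.
#' @examples
#' classify_weight_status(c(4.9, 50, 85, 96))
#' @export
classify_weight_status <- function(bmi_for_age_percentile) {
  p <- bmi_for_age_percentile
  pbc_check_numeric(p, "bmi_for_age_percentile")
  if (any(p < 0) || any(p > 100)) {
    pbc_domain_error("percentile must lie in [0, 100]")
  }
  out <- character(length(p))
  out[p < 5] <- "underweight"
  out[p >= 5 & p < 85] <- "healthy"
  out[p >= 85 & p < 95] <- "overweight"
  out[p >= 95] <- "obese"
  out
}

# Run one estimation stage, relabelling any error with the stage name so
# failures in a chained run identify the equation that could not be
# evaluated.
pbc_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    pbc_stop(
      sprintf("stage '%s': %s", stage, conditionMessage(e)),
      class = c("pedibca_stage_error",
                if (inherits(e, "pedibca_schema_error"))
                  "pedibca_schema_error" else "pedibca_domain_error"),
      stage = stage
    )
  })
}

#' Full estimation chain for one subject
#'
#' Chains the sensor conversions and parameter equations: ADC counts to
#' weight (or a directly supplied weight), then BMI, body fat, fat-free
#' mass (from impedance), muscle mass (from resistance, falling back to
#' the impedance magnitude when no separate resistance is supplied — the
#' device measures a single bipolar 50-kHz signal), total body water
#' (from the optical current, derived from the photosensor voltage when
#' not supplied directly) and bone mass. Height is converted to metres
#' for BMI only. Errors are relabelled with the failing stage.
#'
#' @param profile A [subject_profile()].
#' @param frame A named list or one-row data frame of raw sensor readings;
#'   recognized fields: `weight_kg` or `adc_counts` (needs `calib`),
#'   `z_ohm`, `resistance_ohm`, `optical_current_a` or `v_volts` (with
#'   optional `responsivity`).
#' @param calib Optional [fit_load_cell_calibration()], required when the
#'   frame carries `adc_counts` instead of `weight_kg`.
#' @param log_base Log base for the total-body-water equation.
#' @return A [body_composition()] object.
#' @export
estimate_all <- function(profile, frame, calib = NULL,
                         log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  stopifnot(inherits(profile, "subject_profile"))
  if (is.data.frame(frame)) frame <- as.list(frame)

  field <- function(name) {
    v <- frame[[name]]
    if (is.null(v) || length(v) != 1L || is.na(v)) NULL else v
  }

  w <- pbc_stage("weight", {
    if (!is.null(field("weight_kg"))) {
      pbc_check_numeric(field("weight_kg"), "weight_kg", positive = TRUE)
      field("weight_kg")
    } else if (!is.null(field("adc_counts"))) {
      if (is.null(calib)) {
        pbc_schema_error("frame supplies 'adc_counts' but no calibration given")
      }
      adc_to_weight(field("adc_counts"), calib)
    } else {
      pbc_schema_error("frame supplies neither 'weight_kg' nor 'adc_counts'")
    }
  })

  bmi_v <- pbc_stage("bmi", bmi(w, profile$height_cm / 100))
  bf_v <- pbc_stage(
    "bf_percent",
    bf_percent(bmi_v, profile$age_years, profile$sex_code)
  )

  ffm_v <- pbc_stage("ffm", {
    z <- field("z_ohm")
    if (is.null(z)) {
      pbc_schema_error("no impedance available: frame lacks 'z_ohm'")
    }
    ffm(profile$height_cm, z, w)
  })

  mm_v <- pbc_stage("mm", {
    res <- field("resistance_ohm") %||% field("z_ohm")
    mm(profile$height_cm, res, profile$sex_code, profile$age_years)
  })

  tbw_v <- pbc_stage("tbw", {
    oc <- field("optical_current_a")
    if (is.null(oc)) {
      v <- field("v_volts")
      if (is.null(v)) {
        pbc_schema_error(
          "no optical current: frame lacks both 'optical_current_a' and 'v_volts'"
        )
      }
      oc <- optical_current(v, field("responsivity") %||% 0.42)
    }
    tbw(profile$age_years, profile$height_cm, w, oc, log_base = log_base)
  })

  bm_v <- pbc_stage("bm", bm(w, profile$height_cm, mm_v))

  body_composition(
    weight_kg = w, bmi = bmi_v, bf_pct = bf_v, ffm_kg = ffm_v,
    tbw_kg = tbw_v, mm_kg = mm_v, bm_kg = bm_v
  )
}

#' Run the estimation chain over a subjects + frames table
#'
#' Joins subject records to sensor frames on `subject_id` and applies
#' [estimate_all()] per subject. Per-subject stage errors are collected,
#' not fatal: the run continues and returns both successful compositions
#' and an error table.
#'
#' @param subjects Data frame with columns `subject_id`, `age_years`,
#'   `sex_code`, `height_cm`, and optionally `group_label`.
#' @param frames Data frame of sensor frames keyed by `subject_id`.
#' @param calib Optional load-cell calibration.
#' @param log_base Log base for the total-body-water equation.
#' @return A list with `composition` (data frame, one row per successful
#'   subject) and `errors` (data frame with `subject_id`, `stage`,
#'   `message`).
#' @export
estimate_table <- function(subjects, frames, calib = NULL,
                           log_base = c("log10", "ln")) {
  log_base <- match.arg(log_base)
  need <- c("subject_id", "age_years", "sex_code", "height_cm")
  missing_cols <- setdiff(need, names(subjects))
  if (nrow(subjects) == 0L) {
    pbc_schema_error("empty subjects table")
  }
  if (length(missing_cols) > 0L) {
    pbc_schema_error(sprintf(
      "subjects table lacks required columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (!"subject_id" %in% names(frames)) {
    pbc_schema_error("frames table lacks 'subject_id'")
  }

  rows <- vector("list", nrow(subjects))
  errs <- list()
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    fr <- frames[frames$subject_id == s$subject_id, , drop = FALSE]
    res <- tryCatch({
      if (nrow(fr) != 1L) {
        pbc_schema_error(sprintf(
          "expected exactly one sensor frame for subject '%s', found %d",
          s$subject_id, nrow(fr)
        ))
      }
      prof <- subject_profile(
        s$subject_id, s$age_years, s$sex_code, s$height_cm,
        if ("group_label" %in% names(s)) s$group_label else "unknown"
      )
      comp <- suppressWarnings(
        estimate_all(prof, fr, calib = calib, log_base = log_base)
      )
      data.frame(
        subject_id = prof$subject_id,
        group_label = prof$group_label,
        weight_kg = comp$weight_kg, bmi = comp$bmi, bf_pct = comp$bf_pct,
        ffm_kg = comp$ffm_kg, tbw_kg = comp$tbw_kg, mm_kg = comp$mm_kg,
        bm_kg = comp$bm_kg,
        stringsAsFactors = FALSE
      )
    }, pedibca_error = function(e) {
      errs[[length(errs) + 1L]] <<- data.frame(
        subject_id = as.character(s$subject_id),
        stage = if (!is.null(e$stage)) e$stage else "input",
        message = conditionMessage(e),
        stringsAsFactors = FALSE
      )
      NULL
    })
    rows[[i]] <- res
  }
  ok <- rows[!vapply(rows, is.null, logical(1))]
  empty_comp <- data.frame(
    subject_id = character(), group_label = character(),
    weight_kg = numeric(), bmi = numeric(), bf_pct = numeric(),
    ffm_kg = numeric(), tbw_kg = numeric(), mm_kg = numeric(),
    bm_kg = numeric(), stringsAsFactors = FALSE
  )
  list(
    composition = if (length(ok)) do.call(rbind, ok) else empty_comp,
    errors = if (length(errs)) do.call(rbind, errs) else
      data.frame(subject_id = character(), stage = character(),
                 message = character(), stringsAsFactors = FALSE)
  )
}
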