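# Device-validation metrics: per-row accuracy, cohort-level mean accuracy
# and mean average error, symmetric percent difference between groups,
# Bland-Altman limits of agreement, intraclass correlation (two-way
# random effects) with F-based confidence intervals, and the standard
# error of measurement derived from the ICC.

#' Per-measurement accuracy of a device against a reference
#'
#' `accuracy = (1 - |p - t| / t) * 100`, the device-validation accuracy
#' of a prototype value `p` against a reference value `t`. Full precision
#' is returned; round to 2 decimals for reporting.
#'
#' @param p_value Prototype-device value(s).
#' @param t_value Reference-device value(s); must be positive.
#' @return Accuracy in percent (at most 100; can be negative for gross
#'   disagreement).
#' @examples
#' accuracy(43.501, 42.746)  # 98.23 to 2 dp
#' @export
accuracy <- function(p_value, t_value) {
  pbc_check_numeric(p_value, "p_value")
  pbc_check_numeric(t_value, "t_value")
  if (any(t_value == 0)) {
    pbc_domain_error("reference value must be nonzero")
  }
  if (any(t_value < 0)) {
    pbc_domain_error("reference value must be positive")
  }
  (1 - abs(p_value - t_value) / t_value) * 100
}

# Validate a paired-measurement table: columns parameter, group,
# device_a, device_b; exactly two groups covering the same parameters.
pbc_check_paired <- function(table) {
  need <- c("parameter", "group", "device_a", "device_b")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0L) {
    pbc_schema_error(sprintf(
      "paired table lacks column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  groups <- unique(table$group)
  if (length(groups) != 2L) {
    pbc_contract_error(sprintf(
      "paired table must contain exactly two groups, found %d",
      length(groups)
    ))
  }
  sets <- lapply(groups, function(g) sort(table$parameter[table$group == g]))
  if (!identical(sets[[1L]], sets[[2L]])) {
    pbc_contract_error(
      "both groups must cover the same parameter set exactly once each"
    )
  }
  if (anyDuplicated(paste(table$parameter, table$group))) {
    pbc_contract_error("duplicate (parameter, group) rows in paired table")
  }
  invisible(table)
}

#' Mean accuracy across parameters and groups
#'
#' `100 - (sum of per-row percent differences) / (2 * n_parameters)`,
#' where each row's percent difference is `100 - accuracy` and the table
#' covers both study groups for every parameter. With the packaged
#' published validation means (7 parameters, two groups) this reproduces
#' the device's overall mean accuracy.
#'
#' @param table Data frame with columns `parameter`, `group`, `device_a`
#'   (prototype) and `device_b` (reference), one row per parameter and
#'   group.
#' @return Mean accuracy in percent (full precision).
#' @seealso [mean_avg_error()], [accuracy()]
#' @export
mean_accuracy <- function(table) {
  pbc_check_paired(table)
  diff_pct <- 100 - accuracy(table$device_a, table$device_b)
  n_par <- length(unique(table$parameter))
  100 - sum(diff_pct) / (2 * n_par)
}

#' Mean average error across parameters and groups
#'
#' `(sum of |reference - prototype|) / (2 * n_parameters)` over both
#' groups. Units are mixed across parameters; the result is reported
#' dimensionless, as is conventional for this summary.
#'
#' @inheritParams mean_accuracy
#' @return Mean average error (full precision).
#' @export
mean_avg_error <- function(table) {
  pbc_check_paired(table)
  n_par <- length(unique(table$parameter))
  sum(abs(table$device_b - table$device_a)) / (2 * n_par)
}

#' Symmetric percent difference between two group means
#'
#' `100 * |a - b| / ((a + b) / 2)`: the absolute difference relative to
#' the mean of the two values, symmetric in its arguments.
#'
#' @param a,b Group means; `a + b` must be nonzero.
#' @return Percent difference.
#' @examples
#' percent_difference(43.501, 29.511)  # 38.322
#' @export
percent_difference <- function(a, b) {
  pbc_check_numeric(a, "a")
  pbc_check_numeric(b, "b")
  if (any(a + b == 0)) {
    pbc_domain_error("a + b must be nonzero")
  }
  abs(a - b) / ((a + b) / 2) * 100
}

#' Bland-Altman analysis of paired measurements
#'
#' Computes the bias (mean difference `a - b`) and the 95% limits of
#' agreement `bias +/- 1.96 * SD` of the differences, with the sample
#' (n-1) standard deviation.
#'
#' @param a,b Paired per-subject measurements from the two devices.
#' @param conf_factor Multiplier for the limits of agreement (1.96 for
#'   the conventional 95% limits).
#' @return An object of class `bland_altman`: list with `bias`,
#'   `loa_low`, `loa_high`, `sd_diff`, `differences`, `means`, `n`.
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(0, 0, 0))
#' ba$bias      # 2
#' ba$loa_high  # 2 + 1.96
#' @export
bland_altman <- function(a, b, conf_factor = 1.96) {
  pbc_check_numeric(a, "a")
  pbc_check_numeric(b, "b")
  if (length(a) != length(b)) {
    pbc_contract_error("'a' and 'b' must have equal length")
  }
  if (length(a) < 2L) {
    pbc_stop("Bland-Altman needs at least 2 pairs",
             class = c("pedibca_insufficient_data", "pedibca_contract_error"))
  }
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(
    list(
      bias = bias,
      loa_low = bias - conf_factor * s,
      loa_high = bias + conf_factor * s,
      sd_diff = s,
      differences = d,
      means = (a + b) / 2,
      n = length(d),
      conf_factor = conf_factor
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman: bias %.4g, limits of agreement [%.4g, %.4g] (n = %d)\n",
    x$bias, x$loa_low, x$loa_high, x$n
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Differences against pairwise means, with horizontal lines at the bias
#' and the limits of agreement.
#'
#' @param x A [bland_altman()] object.
#' @param xlab,ylab,main Plot annotation.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference", main = "Bland-Altman",
                              ...) {
  plot(x$means, x$differences, xlab = xlab, ylab = ylab, main = main, ...)
  abline(h = x$bias, lty = 2)
  abline(h = c(x$loa_low, x$loa_high), lty = 3)
  invisible(x)
}

#' Intraclass correlation coefficient (two-way random effects, single
#' measures)
#'
#' Computes the ICC from the two-way ANOVA mean-squares decomposition of
#' an n-subjects by k-raters matrix. The default form is absolute
#' agreement, ICC(2,1); a consistency form is also available. Confidence
#' intervals use the F-distribution method.
#'
#' With subjects as rows and raters as columns, the mean squares are
#' `MSR` (rows), `MSC` (columns), `MSE` (residual), and
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' \deqn{ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE)}
#'
#' @param ratings Numeric matrix (or data frame) with one row per subject
#'   and one column per rater/device; no missing cells.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return An object of class `icc_estimate`: list with `icc`, `ci_low`,
#'   `ci_high`, `type`, `mean_squares`, `n`, `k`.
#' @export
icc <- function(ratings, type = c("agreement", "consistency"),
                conf_level = 0.95) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  if (anyNA(x)) {
    pbc_contract_error("ratings matrix must have no missing cells")
  }
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2L || k < 2L) {
    pbc_contract_error("need at least 2 subjects and 2 raters")
  }

  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - k * sum((row_means - grand)^2) -
    n * sum((col_means - grand)^2)
  mse <- max(sse, 0) / ((n - 1) * (k - 1))

  alpha <- 1 - conf_level
  if (type == "agreement") {
    denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
    est <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0 || est >= 1) {
      ci <- c(est, est)
    } else {
      a <- (k * est) / (n * (1 - est))
      b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      f_l <- qf(1 - alpha / 2, n - 1, v)
      f_u <- qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - f_l * mse) /
        (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (f_u * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f_u * msr)
      ci <- c(lower, upper)
    }
  } else {
    denom <- msr + (k - 1) * mse
    est <- if (denom == 0) 1 else (msr - mse) / denom
    if (mse == 0) {
      ci <- c(est, est)
    } else {
      fobs <- msr / mse
      f_l <- fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      f_u <- fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((f_l - 1) / (f_l + k - 1), (f_u - 1) / (f_u + k - 1))
    }
  }

  structure(
    list(
      icc = est, ci_low = ci[1L], ci_high = ci[2L],
      type = type, conf_level = conf_level,
      mean_squares = list(msr = msr, msc = msc, mse = mse),
      n = n, k = k
    ),
    class = "icc_estimate"
  )
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat(sprintf(
    "ICC (%s, single measures): %.3f [%.3f, %.3f] (n = %d, k = %d)\n",
    x$type, x$icc, x$ci_low, x$ci_high, x$n, x$k
  ))
  invisible(x)
}

#' Standard error of measurement from an ICC
#'
#' `SEM = sd * sqrt(1 - ICC)`.
#'
#' @param sd Measurement standard deviation (same units as the
#'   measurement), non-negative.
#' @param icc Reliability coefficient in \[0, 1\].
#' @return SEM in the units of `sd`.
#' @export
sem_from_icc <- function(sd, icc) {
  pbc_check_numeric(sd, "sd", nonnegative = TRUE)
  pbc_check_numeric(icc, "icc")
  if (any(icc < 0) || any(icc > 1)) {
    pbc_domain_error("'icc' must lie in [0, 1]")
  }
  sd * sqrt(1 - icc)
}

#' Group summary statistics with percent differences and tests
#'
#' Reproduces the study's descriptive layout: per-parameter group
#' mean +/- SD, symmetric percent difference between the two groups,
#' Welch t-test p-value, and per-group Shapiro-Wilk normality p-values,
#' plus a per-group Pearson correlation matrix across the parameters.
#'
#' @param records Data frame with a group column and numeric parameter
#'   columns.
#' @param parameters Parameter columns to summarize; defaults to all
#'   numeric columns other than identifiers.
#' @param group_col Name of the group column (default `"group_label"`).
#' @return A list with `summary` (one row per parameter) and
#'   `correlations` (named list of per-group correlation matrices).
#' @export
summarize_groups <- function(records, parameters = NULL,
                             group_col = "group_label") {
  if (!group_col %in% names(records)) {
    pbc_schema_error(sprintf("records lack group column '%s'", group_col))
  }
  groups <- sort(unique(records[[group_col]]))
  if (length(groups) != 2L) {
    pbc_contract_error(
      "percent differences require exactly two groups in the records"
    )
  }
  if (is.null(parameters)) {
    num <- vapply(records, is.numeric, logical(1))
    parameters <- setdiff(names(records)[num], c("sex_code"))
  }
  for (g in groups) {
    if (sum(records[[group_col]] == g) < 2L) {
      pbc_contract_error(sprintf("group '%s' has fewer than 2 subjects", g))
    }
  }

  rows <- lapply(parameters, function(p) {
    x1 <- records[[p]][records[[group_col]] == groups[1L]]
    x2 <- records[[p]][records[[group_col]] == groups[2L]]
    shap <- function(x) {
      if (length(x) >= 3L && length(x) <= 5000L && sd(x) > 0) {
        shapiro.test(x)$p.value
      } else {
        NA_real_
      }
    }
    p_t <- if (sd(x1) > 0 || sd(x2) > 0) {
      t.test(x1, x2)$p.value
    } else {
      NA_real_
    }
    data.frame(
      parameter = p,
      mean_1 = mean(x1), sd_1 = sd(x1),
      mean_2 = mean(x2), sd_2 = sd(x2),
      pct_diff = percent_difference(mean(x1), mean(x2)),
      p_value = p_t,
      shapiro_p_1 = shap(x1), shapiro_p_2 = shap(x2),
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  names(summary) <- sub("_1$", paste0("_", groups[1L]), names(summary))
  names(summary) <- sub("_2$", paste0("_", groups[2L]), names(summary))

  correlations <- lapply(setNames(groups, groups), function(g) {
    sub <- records[records[[group_col]] == g, parameters, drop = FALSE]
    cor(as.matrix(sub))
  })

  list(summary = summary, correlations = correlations)
}

#' Full device-agreement report
#'
#' Assembles the validation statistics for a prototype-vs-reference
#' comparison: per-row accuracy and percent difference from a mean-level
#' paired table, the overall mean accuracy and mean average error, and —
#' when subject-level pairs are supplied — per-parameter Bland-Altman
#' limits, ICC with confidence interval, SEM, mean difference and paired
#' t-test p-value.
#'
#' @param mean_table Mean-level paired table (`parameter`, `group`,
#'   `device_a`, `device_b`).
#' @param subject_pairs Optional subject-level long table with columns
#'   `subject_id`, `parameter`, `device_a`, `device_b`.
#' @param icc_type ICC form passed to [icc()].
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(mean_table, subject_pairs = NULL,
                             icc_type = c("agreement", "consistency")) {
  icc_type <- match.arg(icc_type)
  need <- c("parameter", "group", "device_a", "device_b")
  missing_cols <- setdiff(need, names(mean_table))
  if (length(missing_cols) > 0L) {
    pbc_schema_error(sprintf(
      "paired table lacks column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  rows <- mean_table
  rows$accuracy <- accuracy(rows$device_a, rows$device_b)
  rows$accuracy_2dp <- round(rows$accuracy, 2)
  rows$abs_diff <- abs(rows$device_b - rows$device_a)
  # the aggregate metrics need full two-group coverage; per-row accuracy
  # is reported regardless
  aggregates <- tryCatch(
    list(mean_accuracy = mean_accuracy(mean_table),
         mean_avg_error = mean_avg_error(mean_table)),
    pedibca_contract_error = function(e) {
      pbc_warn(sprintf("aggregate metrics skipped: %s", conditionMessage(e)))
      list(mean_accuracy = NA_real_, mean_avg_error = NA_real_)
    }
  )

  per_parameter <- NULL
  if (!is.null(subject_pairs)) {
    need <- c("subject_id", "parameter", "device_a", "device_b")
    missing_cols <- setdiff(need, names(subject_pairs))
    if (length(missing_cols) > 0L) {
      pbc_schema_error(sprintf(
        "subject pairs lack column(s): %s",
        paste(missing_cols, collapse = ", ")
      ))
    }
    per_parameter <- lapply(
      setNames(unique(subject_pairs$parameter),
               unique(subject_pairs$parameter)),
      function(p) {
        sub <- subject_pairs[subject_pairs$parameter == p, ]
        a <- sub$device_a
        b <- sub$device_b
        if (length(a) < 2L) {
          pbc_warn(sprintf(
            "parameter '%s': fewer than 2 pairs; Bland-Altman/ICC skipped", p
          ), class = "pedibca_insufficient_data_warning")
          return(list(parameter = p, n = length(a), bland_altman = NULL,
                      icc = NULL, sem = NA_real_,
                      mean_difference = mean(a - b), paired_p = NA_real_))
        }
        ba <- bland_altman(a, b)
        ic <- icc(cbind(a, b), type = icc_type)
        # SD across all measurements of the parameter, both devices
        s <- sd(c(a, b))
        list(
          parameter = p,
          n = length(a),
          bland_altman = ba,
          icc = ic,
          sem = sem_from_icc(s, max(min(ic$icc, 1), 0)),
          mean_difference = mean(a - b),
          # constant differences make the paired t statistic undefined
          paired_p = tryCatch(t.test(a, b, paired = TRUE)$p.value,
                              error = function(e) NA_real_)
        )
      }
    )
  }

  structure(
    list(
      rows = rows,
      mean_accuracy = aggregates$mean_accuracy,
      mean_avg_error = aggregates$mean_avg_error,
      per_parameter = per_parameter,
      icc_type = icc_type
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Device agreement report\n")
  cat(sprintf("  mean accuracy:      %.2f%%\n", x$mean_accuracy))
  cat(sprintf("  mean average error: %.3f\n", x$mean_avg_error))
  cat("  per-row accuracy (%):\n")
  tab <- x$rows[, c("parameter", "group", "device_a", "device_b",
                    "accuracy_2dp")]
  print(tab, row.names = FALSE)
  if (!is.null(x$per_parameter)) {
    cat("  subject-level agreement:\n")
    for (pp in x$per_parameter) {
      if (is.null(pp$bland_altman)) {
        cat(sprintf("    %-8s (insufficient pairs)\n", pp$parameter))
      } else {
        cat(sprintf(
          "    %-8s bias %7.3f LoA [%7.3f, %7.3f]  ICC %.3f  SEM %.3f\n",
          pp$parameter, pp$bland_altman$bias, pp$bland_altman$loa_low,
          pp$bland_altman$loa_high, pp$icc$icc, pp$sem
        ))
      }
    }
  }
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report An [agreement_report()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  doc <- list(
    mean_accuracy = report$mean_accuracy,
    mean_avg_error = report$mean_avg_error,
    rows = report$rows,
    icc_type = report$icc_type
  )
  if (!is.null(report$per_parameter)) {
    doc$per_parameter <- lapply(report$per_parameter, function(pp) {
      list(
        parameter = pp$parameter,
        n = pp$n,
        bias = pp$bland_altman$bias %||% NA_real_,
        loa_low = pp$bland_altman$loa_low %||% NA_real_,
        loa_high = pp$bland_altman$loa_high %||% NA_real_,
        icc = pp$icc$icc %||% NA_real_,
        icc_ci = c(pp$icc$ci_low %||% NA_real_, pp$icc$ci_high %||% NA_real_),
        sem = pp$sem,
        mean_difference = pp$mean_difference,
        paired_p = pp$paired_p
      )
    })
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
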