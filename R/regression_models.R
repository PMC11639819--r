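# Cross-parameter linear prediction models: the published coefficient
# sets as fixed artifacts, plus ordinary-least-squares refitting of the
# same model forms and stepwise selection on partial-F p-values.

# Cache environment for the packaged model file.
.pbc_cache <- new.env(parent = emptyenv())

pbc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "pedibca")
  if (!nzchar(path)) {
    pbc_stop(sprintf("packaged data file '%s' not found", file),
             class = "pedibca_internal_error")
  }
  path
}

pbc_published_models <- function() {
  if (is.null(.pbc_cache$models)) {
    .pbc_cache$models <- jsonlite::read_json(
      pbc_extdata("published_models.json"), simplifyVector = TRUE
    )
  }
  .pbc_cache$models
}

#' Construct a linear prediction model object
#'
#' Low-level constructor for the `bca_model` class used by both the
#' published coefficient sets and freshly fitted models.
#'
#' @param response Name of the response parameter.
#' @param intercept Intercept, in response units.
#' @param coefficients Named numeric vector, predictor name to coefficient.
#' @param diagnostics Named list of fit diagnostics (`r_squared`,
#'   `multiple_r`, `f_stat`, `sig_f`, ...). `multiple_r` and `r_squared`
#'   are stored verbatim as metadata and are not validated against each
#'   other.
#' @param coef_table Optional data frame with per-term `estimate`, `se`,
#'   `t`, `p` (rows named by term, including `"(Intercept)"`).
#' @param source Provenance string (`"table"`, `"equation"` or
#'   `"fitted"`).
#' @return An object of class `bca_model`.
#' @export
bca_model <- function(response, intercept, coefficients,
                      diagnostics = list(), coef_table = NULL,
                      source = "fitted") {
  known <- c("BMI", "BF", "FFM", "TBW", "MM", "BM", "weight")
  stopifnot(is.numeric(intercept), length(intercept) == 1L)
  if (length(coefficients) > 0L) {
    stopifnot(is.numeric(coefficients), !is.null(names(coefficients)))
  }
  if (response %in% known && length(coefficients) > 0L &&
      !all(names(coefficients) %in% known)) {
    # published parameter space: predictors restricted to the known set
    pbc_domain_error(sprintf(
      "unknown predictor(s): %s",
      paste(setdiff(names(coefficients), known), collapse = ", ")
    ))
  }
  r2 <- diagnostics$r_squared
  if (!is.null(r2) && (r2 < 0 || r2 > 1)) {
    pbc_domain_error("'r_squared' must lie in [0, 1]")
  }
  structure(
    list(
      response = response,
      intercept = intercept,
      coefficients = coefficients,
      diagnostics = diagnostics,
      coef_table = coef_table,
      source = source
    ),
    class = "bca_model"
  )
}

#' Retrieve a published body-composition prediction model
#'
#' Returns one of the six published linear models predicting each
#' body-composition parameter from the other five. The regression table
#' is the canonical source (`source = "table"`). Two coefficients were
#' printed differently in the running-text equations (the BMI coefficient
#' of the body-fat model, and the body-fat coefficient of the
#' fat-free-mass model); those variants are retrievable with
#' `source = "equation"`. The bone-mass model's body-fat coefficient is
#' an explicit zero.
#'
#' @param response One of `"BMI"`, `"BF"`, `"FFM"`, `"TBW"`, `"MM"`,
#'   `"BM"`.
#' @param source `"table"` (canonical, default) or `"equation"` (the
#'   running-text variant where it differs).
#' @return A [bca_model()] object.
#' @examples
#' m <- published_model("BMI")
#' predict(m, list(BF = 0, FFM = 0, TBW = 0, MM = 0, BM = 0))  # intercept
#' @export
published_model <- function(response, source = c("table", "equation")) {
  source <- match.arg(source)
  models <- pbc_published_models()
  if (!response %in% names(models$table4)) {
    pbc_domain_error(sprintf(
      "unknown response '%s'; expected one of: %s",
      response, paste(names(models$table4), collapse = ", ")
    ))
  }
  rec <- NULL
  src <- "table"
  if (source == "equation" && response %in% names(models$equation_text)) {
    rec <- models$equation_text[[response]]
    src <- "equation"
  } else {
    rec <- models$table4[[response]]
  }
  coefs <- unlist(rec$coefficients)
  coef_table <- NULL
  if (!is.null(rec$std_errors)) {
    terms <- c("(Intercept)", names(coefs))
    keys <- c("intercept", names(coefs))
    coef_table <- data.frame(
      estimate = c(rec$intercept, unname(coefs)),
      se = unlist(rec$std_errors)[keys],
      t = unlist(rec$t_stats)[keys],
      p = unlist(rec$p_values)[keys],
      row.names = terms
    )
  }
  bca_model(
    response = rec$response,
    intercept = rec$intercept,
    coefficients = coefs,
    diagnostics = list(
      multiple_r = rec$multiple_r, r_squared = rec$r_squared,
      f_stat = rec$f_stat, sig_f = rec$sig_f
    ),
    coef_table = coef_table,
    source = src
  )
}

#' Predict from a linear model
#'
#' Evaluates `intercept + sum(coefficient * value)`. Every predictor in
#' the model must be supplied; a missing one raises a contract error
#' naming it.
#'
#' @param object A [bca_model()].
#' @param newdata Named list, named numeric vector, or one-row data frame
#'   of predictor values.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.bca_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) newdata <- as.list(newdata)
  if (is.numeric(newdata) && !is.list(newdata)) newdata <- as.list(newdata)
  missing_pred <- setdiff(names(object$coefficients), names(newdata))
  if (length(missing_pred) > 0L) {
    pbc_contract_error(sprintf(
      "missing predictor value(s): %s", paste(missing_pred, collapse = ", ")
    ))
  }
  out <- object$intercept
  for (p in names(object$coefficients)) {
    out <- out + object$coefficients[[p]] * newdata[[p]]
  }
  unname(out)
}

#' @export
print.bca_model <- function(x, ...) {
  cat(sprintf("Linear model for %s (%s)\n", x$response, x$source))
  cat(sprintf("  intercept: %.4g\n", x$intercept))
  if (length(x$coefficients)) {
    for (p in names(x$coefficients)) {
      cat(sprintf("  %-8s %8.4g\n", p, x$coefficients[[p]]))
    }
  } else {
    cat("  (intercept-only)\n")
  }
  d <- x$diagnostics
  if (!is.null(d$r_squared)) {
    cat(sprintf("  R^2 = %.4g", d$r_squared))
    if (!is.null(d$f_stat)) cat(sprintf(", F = %.4g", d$f_stat))
    cat("\n")
  }
  invisible(x)
}

#' Fit a linear model by ordinary least squares
#'
#' Fits `response ~ predictors` with an intercept via [stats::lm()] and
#' packages the result in the same `bca_model` layout as the published
#' models (coefficients plus per-term SE/t/p and R-squared / F
#' diagnostics).
#'
#' @param records Data frame holding the response and predictor columns.
#' @param response Response column name.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @return A [bca_model()] with `source = "fitted"` and the underlying
#'   `lm` fit attached as attribute `"fit"`.
#' @export
fit_linear_model <- function(records, response, predictors) {
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols) > 0L) {
    pbc_schema_error(sprintf(
      "records lack column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  n <- nrow(records)
  p <- length(predictors)
  if (n <= p + 1L) {
    pbc_stop(
      sprintf("underdetermined fit: n = %d with %d predictor(s)", n, p),
      class = c("pedibca_singular_design", "pedibca_domain_error")
    )
  }
  if (p > 0L) {
    const <- predictors[vapply(records[predictors],
                               function(x) length(unique(x)) == 1L,
                               logical(1))]
    if (length(const) > 0L) {
      pbc_stop(
        sprintf("constant predictor column(s): %s",
                paste(const, collapse = ", ")),
        class = c("pedibca_singular_design", "pedibca_domain_error")
      )
    }
  }
  fml <- if (p == 0L) {
    as.formula(sprintf("`%s` ~ 1", response))
  } else {
    as.formula(sprintf("`%s` ~ %s", response,
                       paste(sprintf("`%s`", predictors), collapse = " + ")))
  }
  fit <- lm(fml, data = records)
  if (fit$rank < p + 1L) {
    pbc_stop("rank-deficient design matrix",
             class = c("pedibca_singular_design", "pedibca_domain_error"))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  # strip the backticks lm adds around non-syntactic names
  rownames(ct) <- gsub("`", "", rownames(ct))
  coefs <- setNames(ct[, "Estimate"], rownames(ct))
  coef_table <- data.frame(
    estimate = ct[, "Estimate"], se = ct[, "Std. Error"],
    t = ct[, "t value"], p = ct[, "Pr(>|t|)"],
    row.names = rownames(ct)
  )
  diag <- list(
    r_squared = unname(sm$r.squared),
    multiple_r = sqrt(unname(sm$r.squared)),
    n = n
  )
  if (!is.null(sm$fstatistic)) {
    fs <- sm$fstatistic
    diag$f_stat <- unname(fs[1L])
    diag$sig_f <- unname(pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  }
  out <- bca_model(
    response = response,
    intercept = unname(coefs["(Intercept)"]),
    coefficients = if (p > 0L) coefs[setdiff(names(coefs), "(Intercept)")]
                   else setNames(numeric(0), character(0)),
    diagnostics = diag,
    coef_table = coef_table,
    source = "fitted"
  )
  attr(out, "fit") <- fit
  out
}

#' Stepwise model selection by partial-F p-values
#'
#' Forward selection with backward elimination: at each round the
#' candidate whose partial F test (equivalently, squared t test) has the
#' smallest p-value enters if p < `p_enter`; then any included predictor
#' whose partial F p-value exceeds `p_remove` is dropped (largest p
#' first). Ties are broken by smallest p-value, then alphabetically, so
#' the procedure is deterministic for a given input. Defaults follow the
#' common statistical-package convention (enter 0.05, remove 0.10).
#'
#' @param records Data frame of observations.
#' @param response Response column name.
#' @param candidates Character vector of candidate predictor columns.
#' @param p_enter Entry threshold for the partial-F p-value.
#' @param p_remove Removal threshold; should be >= `p_enter`.
#' @return A [bca_model()] fitted on the selected predictors (possibly
#'   intercept-only).
#' @export
stepwise_fit <- function(records, response, candidates,
                         p_enter = 0.05, p_remove = 0.10) {
  missing_cols <- setdiff(c(response, candidates), names(records))
  if (length(missing_cols) > 0L) {
    pbc_schema_error(sprintf(
      "records lack column(s): %s", paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(records) <= length(candidates) + 1L && length(candidates) > 0L) {
    # conservative: selection paths may visit the full model
    pbc_stop(
      "underdetermined selection: too few rows for the candidate set",
      class = c("pedibca_singular_design", "pedibca_domain_error")
    )
  }

  partial_p <- function(included, term) {
    # p-value of the partial F test for `term` on top of `included`
    fit0 <- lm(pbc_formula(response, included), data = records)
    fit1 <- lm(pbc_formula(response, c(included, term)), data = records)
    an <- anova(fit0, fit1)
    an[["Pr(>F)"]][2L]
  }

  current <- character(0)
  for (iter in seq_len(2L * length(candidates) + 2L)) {
    changed <- FALSE
    # forward step
    remaining <- sort(setdiff(candidates, current))
    if (length(remaining) > 0L) {
      pvals <- vapply(remaining, function(tm) partial_p(current, tm),
                      numeric(1))
      best <- remaining[order(pvals, remaining)][1L]
      if (pvals[[best]] < p_enter) {
        current <- c(current, best)
        changed <- TRUE
      }
    }
    # backward step
    if (length(current) > 0L) {
      pvals <- vapply(current, function(tm) {
        partial_p(setdiff(current, tm), tm)
      }, numeric(1))
      worst <- current[order(-pvals, current)][1L]
      if (pvals[[worst]] > p_remove) {
        current <- setdiff(current, worst)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  fit_linear_model(records, response, sort(current))
}

pbc_formula <- function(response, predictors) {
  if (length(predictors) == 0L) {
    as.formula(sprintf("`%s` ~ 1", response))
  } else {
    as.formula(sprintf("`%s` ~ %s", response,
                       paste(sprintf("`%s`", predictors), collapse = " + ")))
  }
}

#' Serialize a model to JSON
#'
#' Writes the `{response, intercept, coefficients, diagnostics}` document
#' used for model interchange; [model_from_json()] reads it back.
#'
#' @param model A [bca_model()].
#' @param path Output file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
model_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "bca_model"))
  doc <- list(
    response = model$response,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    diagnostics = model$diagnostics,
    source = model$source
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' @rdname model_to_json
#' @param json A JSON string or file path produced by [model_to_json()].
#' @export
model_from_json <- function(json) {
  doc <- jsonlite::read_json(json, simplifyVector = TRUE)
  bca_model(
    response = doc$response,
    intercept = doc$intercept,
    coefficients = unlist(doc$coefficients) %||%
      setNames(numeric(0), character(0)),
    diagnostics = as.list(doc$diagnostics),
    source = doc$source %||% "fitted"
  )
}
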