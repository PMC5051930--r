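#' Fit the logistic outcome model for risk adjustment
#'
#' Fits a maximum-likelihood logistic regression of the binary encounter
#' outcome on the declared baseline covariates. The fitted probabilities
#' feed [risk_adjust()]. Fitting is complete-case: encounters with a missing
#' outcome or a missing covariate value are excluded (and counted in the
#' returned object).
#'
#' Ordinal covariates such as triage acuity are treated as categorical by
#' default, with the most frequent level as the reference; declare them
#' `"numeric"` to impose a linear trend instead. An empty covariate vector
#' fits the intercept-only model, whose fitted probability is the observed
#' positive-outcome rate.
#'
#' @param encounters data.frame of encounter records (see
#'   [read_encounters()]).
#' @param covariates Named character vector mapping covariate column names to
#'   `"categorical"` or `"numeric"`, e.g. `c(acuity = "categorical")`. May be
#'   empty for an intercept-only model.
#' @return An object of class `spor_risk_model`: coefficients, covariate
#'   specification with factor levels (reference first), convergence flag,
#'   log-likelihood, and the number of encounters used/excluded.
#' @export
fit_risk_model <- function(encounters, covariates = c(acuity = "categorical")) {
  stopifnot(is.data.frame(encounters), "outcome" %in% names(encounters))
  if (length(covariates) > 0L) {
    if (is.null(names(covariates)) || any(names(covariates) == "")) {
      stop("covariates must be a named vector, e.g. c(acuity = \"categorical\")")
    }
    bad <- setdiff(names(covariates), names(encounters))
    if (length(bad) > 0L) {
      stop("covariate column(s) not found: ", paste(bad, collapse = ", "))
    }
    if (!all(covariates %in% c("categorical", "numeric"))) {
      stop("covariate types must be \"categorical\" or \"numeric\"")
    }
  }
  cov_names <- names(covariates)

  df <- encounters[!is.na(encounters$outcome), , drop = FALSE]
  if (length(cov_names) > 0L) {
    cc <- stats::complete.cases(df[, cov_names, drop = FALSE])
  } else {
    cc <- rep(TRUE, nrow(df))
  }
  n_excluded <- sum(!cc) + sum(is.na(encounters$outcome))
  df <- df[cc, , drop = FALSE]

  y <- as.integer(df$outcome)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L) {
    stop("need at least two encounters with each outcome value to fit")
  }

  fit_data <- data.frame(.y = y)
  levels_map <- list()
  for (cv in cov_names) {
    if (covariates[[cv]] == "categorical") {
      f <- factor(df[[cv]])
      if (nlevels(f) < 2L) {
        stop("degenerate categorical covariate (single level): ", cv)
      }
      ref <- names(which.max(table(f)))
      f <- stats::relevel(f, ref = ref)
      levels_map[[cv]] <- levels(f)
      fit_data[[cv]] <- f
    } else {
      x <- as.numeric(df[[cv]])
      if (length(unique(x)) < 2L) {
        stop("degenerate numeric covariate (constant): ", cv)
      }
      fit_data[[cv]] <- x
    }
  }

  fml <- if (length(cov_names) > 0L) {
    stats::as.formula(paste(".y ~", paste(cov_names, collapse = " + ")))
  } else {
    stats::as.formula(".y ~ 1")
  }

  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = fit_data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged || sep_warn) {
    cf <- coef(fit)
    worst <- names(cf)[which.max(abs(cf))]
    stop("logistic fit failed (non-convergence or separation); ",
         "largest coefficient: ", worst)
  }

  structure(
    list(
      coefficients = coef(fit),
      std_errors = summary(fit)$coefficients[, "Std. Error"],
      covariates = covariates,
      levels = levels_map,
      converged = fit$converged,
      log_likelihood = as.numeric(stats::logLik(fit)),
      n_fit = nrow(df),
      n_excluded = n_excluded
    ),
    class = "spor_risk_model"
  )
}

#' @export
print.spor_risk_model <- function(x, ...) {
  cat("Logistic risk model (", x$n_fit, " encounters, ",
      x$n_excluded, " excluded)\n", sep = "")
  cat("log-likelihood:", format(x$log_likelihood, digits = 6), "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# clipping guard: keeps every fitted p strictly inside (0,1) so downstream
# risk-adjusted outcomes are strictly positive
.p_clip <- 1e-9

#' Predict positive-outcome probabilities
#'
#' Builds the linear predictor directly from the stored coefficients (so a
#' model reloaded from JSON predicts like the freshly fitted one, to double
#' precision)
#' and clips the result to `[1e-9, 1 - 1e-9]`. Rows with a missing covariate
#' yield `NA`.
#'
#' @param object A `spor_risk_model`.
#' @param newdata data.frame with the model's covariate columns.
#' @param ... Unused.
#' @return Numeric vector of fitted probabilities.
#' @export
predict.spor_risk_model <- function(object, newdata, ...) {
  cf <- object$coefficients
  eta <- rep(unname(cf["(Intercept)"]), nrow(newdata))
  for (cv in names(object$covariates)) {
    if (!cv %in% names(newdata)) stop("newdata lacks covariate column: ", cv)
    if (object$covariates[[cv]] == "categorical") {
      x <- as.character(newdata[[cv]])
      lv <- object$levels[[cv]]
      unseen <- setdiff(unique(x[!is.na(x)]), lv)
      if (length(unseen) > 0L) {
        stop("unseen level(s) for covariate ", cv, ": ",
             paste(unseen, collapse = ", "))
      }
      add <- rep(0, length(x))
      for (l in lv[-1L]) {
        add[!is.na(x) & x == l] <- unname(cf[paste0(cv, l)])
      }
      add[is.na(x)] <- NA_real_
      eta <- eta + add
    } else {
      eta <- eta + unname(cf[cv]) * as.numeric(newdata[[cv]])
    }
  }
  p <- stats::plogis(eta)
  pmin(pmax(p, .p_clip), 1 - .p_clip)
}

#' Risk-adjust a binary outcome
#'
#' Maps a binary outcome `y` and a fitted positive-outcome probability `p`
#' onto `r = (1 + y - p) / 2` in `[0, 1]`. The transform generously rewards
#' unexpectedly good outcomes (`y = 1` with low `p` gives `r` near 1),
#' heavily penalises unexpectedly bad ones (`y = 0` with high `p` gives `r`
#' near 0), and assigns values near 0.5 to expected outcomes. For any fixed
#' `p`, `r(1, p) - r(0, p) = 1/2`.
#'
#' @param y Binary outcome(s), each exactly 0 or 1.
#' @param p Fitted probability(ies) in `[0, 1]`; values of exactly 0 or 1
#'   are accepted with a warning (they arise only from degenerate fits).
#' @return Numeric vector of risk-adjusted outcomes in `[0, 1]`.
#' @export
risk_adjust <- function(y, p) {
  if (!all(y %in% c(0, 1))) stop("y must be 0 or 1")
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p must lie in [0, 1]")
  }
  if (any(p == 0 | p == 1)) {
    warning("degenerate fitted probability (p = 0 or 1) passed to risk_adjust")
  }
  (1 + y - p) / 2
}

#' Compute risk-adjusted outcomes for a set of encounters
#'
#' Applies the fitted model to every encounter with a non-missing outcome
#' and complete covariates.
#'
#' @param model A `spor_risk_model`.
#' @param encounters Encounter data.frame.
#' @return data.frame with columns `encounter_id`, `p` (fitted probability)
#'   and `r` (risk-adjusted outcome).
#' @export
risk_adjusted_outcomes <- function(model, encounters) {
  p <- predict(model, encounters)
  keep <- !is.na(encounters$outcome) & !is.na(p)
  data.frame(
    encounter_id = encounters$encounter_id[keep],
    p = p[keep],
    r = risk_adjust(as.numeric(encounters$outcome[keep]), p[keep]),
    stringsAsFactors = FALSE
  )
}

#' Named risk-adjusted outcome vector
#'
#' Convenience accessor: the `encounter_id -> r` map consumed by
#' [project_collaboration()] and the permutation machinery.
#'
#' @param ra Output of [risk_adjusted_outcomes()].
#' @return Named numeric vector of `r` values keyed by encounter id.
#' @export
outcome_map <- function(ra) {
  setNames(ra$r, ra$encounter_id)
}

#' Persist a risk model as JSON
#'
#' @param model A `spor_risk_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(
    list(
      coefficients = as.list(model$coefficients),
      std_errors = as.list(model$std_errors),
      covariates = as.list(model$covariates),
      levels = model$levels,
      converged = model$converged,
      log_likelihood = model$log_likelihood,
      n_fit = model$n_fit,
      n_excluded = model$n_excluded
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Reload a risk model saved with [write_risk_model()]
#'
#' @param path Path to the JSON document.
#' @return A `spor_risk_model` predicting like the original (coefficients
#'   survive the text round trip to double precision).
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(obj$coefficients),
      std_errors = unlist(obj$std_errors),
      covariates = unlist(obj$covariates),
      levels = obj$levels,
      converged = obj$converged,
      log_likelihood = obj$log_likelihood,
      n_fit = obj$n_fit,
      n_excluded = obj$n_excluded
    ),
    class = "spor_risk_model"
  )
}
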