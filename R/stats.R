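# Regression summaries: how the sampling regime predicts metric
# discrepancy (multiple linear regression) and the binary detection /
# acceptable-assortativity outcomes (logistic regression).

new_regression <- function(terms, r_squared, model_kind, transform, fit,
                           converged = TRUE) {
  structure(list(terms = terms, r_squared = r_squared,
                 model_kind = model_kind, transform = transform,
                 converged = converged, fit = fit),
            class = "netss_regression")
}

#' @export
print.netss_regression <- function(x, ...) {
  cat(sprintf("%s regression (%s)\n",
              if (x$model_kind == "linear") "Linear" else "Logistic",
              x$transform))
  print(x$terms, row.names = FALSE, digits = 4)
  if (!is.na(x$r_squared)) cat(sprintf("R-squared = %.3f\n", x$r_squared))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}

terms_table <- function(coefs) {
  data.frame(term = rownames(coefs),
             coefficient = coefs[, 1],
             std_error = coefs[, 2],
             p_value = coefs[, 4],
             row.names = NULL)
}

#' Linear model of metric discrepancy on the sampling regime
#'
#' Ordinary least squares of a discrepancy measure on the number of
#' individuals, the number of observations per individual, and their
#' interaction.  With `log_transform = TRUE` (used for the community
#' count and density discrepancies) predictors enter as natural logs
#' and the response as `log1p` — discrepancies of exactly zero occur,
#' so the shifted log keeps the transform defined while preserving
#' order.  The clustering-coefficient discrepancy is conventionally
#' fitted untransformed.
#'
#' @param results Results table from [run_experiment()].
#' @param response One of `"delta_n_comm"`, `"delta_density"`,
#'   `"delta_clustering"`.
#' @param log_transform Log-transform response and predictors.
#' @return A `netss_regression` object: coefficient table (estimate,
#'   standard error, p-value), R-squared, and the underlying `lm` fit.
#' @export
fit_discrepancy_model <- function(results,
                                  response = c("delta_n_comm",
                                               "delta_density",
                                               "delta_clustering"),
                                  log_transform = TRUE) {
  response <- match.arg(response)
  if (!response %in% names(results)) {
    stop("response column ", response, " not present", call. = FALSE)
  }
  cc <- stats::complete.cases(results[c(response, "n_individuals", "n_obs")])
  dat <- results[cc, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no complete rows to fit", call. = FALSE)
  if (stats::var(dat$n_individuals) == 0 || stats::var(dat$n_obs) == 0) {
    stop("zero-variance predictor: the regime grid must vary", call. = FALSE)
  }
  if (log_transform) {
    dd <- data.frame(y = log1p(dat[[response]]),
                     n_individuals = log(dat$n_individuals),
                     n_obs = log(dat$n_obs))
    transform <- paste0("log1p(", response, ") ~ log(n_individuals) * log(n_obs)")
  } else {
    dd <- data.frame(y = dat[[response]],
                     n_individuals = dat$n_individuals,
                     n_obs = dat$n_obs)
    transform <- paste0(response, " ~ n_individuals * n_obs")
  }
  fit <- stats::lm(y ~ n_individuals * n_obs, data = dd)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response
  new_regression(terms_table(sm$coefficients), r_squared = r2,
                 model_kind = "linear", transform = transform, fit = fit)
}

#' Logistic model of a binary network outcome on the sampling regime
#'
#' Maximum-likelihood logistic regression of a 0/1 outcome (evidence
#' for community structure, or acceptable community assortativity) on
#' the number of individuals, observations per individual, and their
#' interaction.  Predictors are left on their natural scale.  A
#' single-class response or (quasi-)complete separation is an explicit
#' error, never a silent fit.
#'
#' @param results Results table from [run_experiment()].
#' @param response `"evidence"` or `"acceptable_rcom"`.
#' @return A `netss_regression` object with the coefficient table and
#'   convergence report (`r_squared` is `NA` for logistic models).
#' @export
fit_detection_model <- function(results,
                                response = c("evidence", "acceptable_rcom")) {
  response <- match.arg(response)
  if (!response %in% names(results)) {
    stop("response column ", response, " not present", call. = FALSE)
  }
  y <- results[[response]]
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("single-class response: ", response, " is constantly ", y[1],
         call. = FALSE)
  }
  dd <- data.frame(y = y, n_individuals = results$n_individuals,
                   n_obs = results$n_obs)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ n_individuals * n_obs, family = stats::binomial(), data = dd),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    stop("(quasi-)complete separation: fitted probabilities of 0 or 1; ",
         "the logistic coefficients are not identifiable", call. = FALSE)
  }
  sm <- summary(fit)
  new_regression(terms_table(sm$coefficients), r_squared = NA_real_,
                 model_kind = "logistic",
                 transform = paste0(response, " ~ n_individuals * n_obs"),
                 fit = fit, converged = fit$converged)
}
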