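## timecourse: logistic time courses of Haldane's Rule and of complete
## reproductive isolation, with the divergence time at which the fitted
## probability crosses 50%.

new_timecourse_result <- function(model, n_used, coding) {
  res <- list(model = model, crossing_my = crossing_point(model),
              n_used = n_used, coding = coding)
  class(res) <- "timecourse_result"
  res
}

#' @export
print.timecourse_result <- function(x, ...) {
  cat(sprintf("Logistic time course (n = %d): 50%% crossing at %.4g MY\n",
              x$n_used, x$crossing_my))
  cat("coding:", paste(names(x$coding), "=", x$coding, collapse = ", "),
      "\n")
  print(x$model)
  invisible(x)
}

#' 50%-probability crossing point of a logistic time course
#'
#' For a binomial-logit fit with an intercept and a single slope on
#' divergence time, the divergence at which the fitted probability equals
#' one half is `-intercept / slope`. The crossing point is invariant to
#' which outcome is coded 1 (both coefficients flip sign).
#'
#' @param fit a `model_fit` of family `binomial_logit` with exactly two
#'   coefficients (intercept, slope).
#' @return numeric crossing point in million years.
#' @export
crossing_point <- function(fit) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$family != "binomial_logit") {
    stop("crossing_point requires a binomial_logit fit", call. = FALSE)
  }
  if (length(fit$coefficients) != 2L) {
    stop("crossing_point requires an intercept and one slope",
         call. = FALSE)
  }
  b0 <- fit$coefficients[[1L]]
  b1 <- fit$coefficients[[2L]]
  if (abs(b1) < 1e-12) stop("flat time course: slope is zero", call. = FALSE)
  -b0 / b1
}

timecourse_fit <- function(div, y1, coding, n_min_each = 1L) {
  if (sum(y1 == 1L) < n_min_each || sum(y1 == 0L) < n_min_each) {
    stop("degenerate response: need both outcome classes present",
         call. = FALSE)
  }
  X <- cbind("(Intercept)" = rep(1, length(div)), divergence_my = div)
  fit <- fit_logistic(y1, X, response_name = names(coding)[coding == 1L])
  new_timecourse_result(fit, length(div), coding)
}

#' Time course of Haldane's Rule
#'
#' Restricts the dataset to crosses where some offspring were fertile and
#' fits a logistic regression of the indicator "only males fertile"
#' (birds are ZW, so the heterogametic females fail first) on divergence
#' time. The crossing point is the divergence at which a hybridization has
#' a 50% probability of exhibiting Haldane's Rule.
#'
#' @param ds a `cross_dataset` with at least one `MALE_ONLY` and one
#'   `BOTH_FERTILE` record.
#' @return a `timecourse_result` (model, `crossing_my`, `n_used`, coding).
#' @export
haldane_regression <- function(ds) {
  stopifnot(inherits(ds, "cross_dataset"))
  sub <- ds[ds$outcome != "STERILE", , drop = FALSE]
  if (nrow(sub) < 2L) {
    stop("degenerate response: fewer than 2 fertile-outcome records",
         call. = FALSE)
  }
  y <- as.integer(sub$outcome == "MALE_ONLY")
  timecourse_fit(sub$divergence_my, y,
                 coding = c(BOTH_FERTILE = 0L, MALE_ONLY = 1L))
}

#' Time course of speciation (complete reproductive isolation)
#'
#' Fits a logistic regression of the indicator "all offspring sterile" on
#' divergence time over all records. The crossing point is the divergence
#' at which a cross has a 50% probability of complete postzygotic
#' isolation.
#'
#' @param ds a `cross_dataset` with at least one `STERILE` and one
#'   non-sterile record.
#' @return a `timecourse_result`.
#' @export
speciation_regression <- function(ds) {
  stopifnot(inherits(ds, "cross_dataset"))
  y <- as.integer(ds$outcome == "STERILE")
  timecourse_fit(ds$divergence_my, y,
                 coding = c(FERTILE = 0L, STERILE = 1L))
}
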