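## stats_core: self-contained regression engine. Binomial-logit fits by
## IRLS, Gaussian fits by least squares with the ML variance in the
## likelihood, AIC with k counting the Gaussian variance parameter,
## McFadden's pseudo-R-squared, and bidirectional stepwise AIC selection
## with deterministic tie-breaks.

new_model_fit <- function(response_name, predictor_names, coefficients,
                          loglik, n, k, fitted, residuals, family,
                          se = NULL, sigma2 = NULL) {
  fit <- list(
    response_name = response_name,
    predictor_names = predictor_names,
    coefficients = coefficients,
    loglik = loglik,
    aic = 2 * k - 2 * loglik,
    n = n,
    k = k,
    fitted = fitted,
    residuals = residuals,
    family = family,
    se = se,
    sigma2 = sigma2
  )
  class(fit) <- "model_fit"
  fit
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s fit: %s ~ %s\n", x$family, x$response_name,
              if (length(x$predictor_names)) {
                paste(x$predictor_names, collapse = " + ")
              } else "1"))
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$se)) {
    tab$std_error <- x$se
    tab$z <- x$coefficients / x$se
  }
  print(signif(as.matrix(tab), 4L))
  cat(sprintf("n = %d, k = %d, logLik = %.4f, AIC = %.4f\n",
              x$n, x$k, x$loglik, x$aic))
  invisible(x)
}

check_design <- function(X, n) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))[
      seq_len(ncol(X))]
  }
  if (nrow(X) != n) stop("X and y lengths differ", call. = FALSE)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  X
}

#' Fit a binomial-logit regression by IRLS
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, converged when the largest coefficient change is below `tol` or
#' after `max_iter` iterations. Complete separation is detected as a
#' diverging standardized coefficient and raised as an error.
#'
#' @param y binary response vector (0/1), both classes present.
#' @param X design matrix including the intercept column.
#' @param response_name,predictor_names optional names used in reports.
#' @param tol convergence tolerance on the coefficient change.
#' @param max_iter maximum IRLS iterations.
#' @return a `model_fit` with the binomial log-likelihood, AIC
#'   (`k = ncol(X)`), fitted probabilities, response residuals and
#'   asymptotic standard errors from the observed information.
#' @export
fit_logistic <- function(y, X, response_name = "y",
                         predictor_names = NULL, tol = 1e-8,
                         max_iter = 100L) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  n <- length(y)
  X <- check_design(X, n)
  if (length(unique(y)) < 2L) {
    stop("degenerate response: only one class present", call. = FALSE)
  }
  p_names <- predictor_names %||% colnames(X)
  beta <- numeric(ncol(X))
  xsd <- apply(X, 2L, sd)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    scaled <- abs(beta) * ifelse(xsd > 0, xsd, 1)
    if (any(scaled > 50)) {
      stop("complete separation detected: standardized coefficient for ",
           paste(p_names[scaled > 50], collapse = ", "),
           " is diverging", call. = FALSE)
    }
    if (delta < tol) break
  }
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  loglik <- sum(y * log(p) + (1 - y) * log1p(-p))
  w <- pmax(p * (1 - p), 1e-12)
  se <- sqrt(diag(solve(t(X * w) %*% X)))
  names(beta) <- names(se) <- colnames(X)
  new_model_fit(response_name, p_names, beta, loglik, n, ncol(X),
                fitted = p, residuals = y - p, family = "binomial_logit",
                se = se)
}

#' Fit a Gaussian linear regression
#'
#' Ordinary least squares; the log-likelihood is the Gaussian likelihood at
#' the ML variance estimate (RSS/n), and the parameter count `k` includes
#' the variance parameter so that AIC matches the usual convention for
#' Gaussian GLMs.
#'
#' @param y numeric response.
#' @param X design matrix including the intercept column.
#' @param response_name,predictor_names optional names used in reports.
#' @return a `model_fit` with `k = ncol(X) + 1`, standard errors from the
#'   unbiased residual variance, and `sigma2` the ML variance.
#' @export
fit_gaussian <- function(y, X, response_name = "y",
                         predictor_names = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  X <- check_design(X, n)
  k <- ncol(X) + 1L
  if (n <= k) stop("n must exceed the parameter count", call. = FALSE)
  qr_x <- qr(X)
  beta <- qr.coef(qr_x, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  rss <- sum(res^2)
  sigma2 <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2) + 1)
  df_res <- n - ncol(X)
  s2_unbiased <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qr_x))
  se <- sqrt(diag(xtx_inv) * s2_unbiased)
  names(beta) <- names(se) <- colnames(X)
  new_model_fit(response_name, predictor_names %||% colnames(X), beta,
                loglik, n, k, fitted = fitted, residuals = res,
                family = "gaussian_identity", se = se, sigma2 = sigma2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' McFadden's pseudo-R-squared
#'
#' `1 - logLik(fit) / logLik(null_fit)` where `null_fit` is the
#' intercept-only model of the same family on the same response.
#'
#' @param fit fitted `model_fit`.
#' @param null_fit intercept-only `model_fit` of the same family.
#' @return numeric scalar.
#' @export
mcfadden_r2 <- function(fit, null_fit) {
  stopifnot(inherits(fit, "model_fit"), inherits(null_fit, "model_fit"))
  if (fit$family != null_fit$family) {
    stop("fit and null_fit must share a family", call. = FALSE)
  }
  null_slopes <- if (null_fit$family == "gaussian_identity") {
    null_fit$k - 2L
  } else {
    null_fit$k - 1L
  }
  if (null_slopes != 0L) stop("null_fit must be intercept-only", call. = FALSE)
  if (null_fit$loglik == 0) {
    stop("null log-likelihood is zero; pseudo-R2 undefined", call. = FALSE)
  }
  1 - fit$loglik / null_fit$loglik
}

fit_family <- function(y, X, family, response_name, predictor_names) {
  switch(family,
         binomial_logit = fit_logistic(y, X, response_name, predictor_names),
         gaussian_identity = fit_gaussian(y, X, response_name,
                                          predictor_names),
         stop("unknown family: ", family, call. = FALSE))
}

fit_terms <- function(response, terms, data, family) {
  y <- data[[response]]
  terms <- sort(terms)
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  if (length(terms)) {
    X <- cbind(X, as.matrix(data[terms]))
  }
  tryCatch(
    fit_family(y, X, family, response, c("(Intercept)", terms)),
    error = function(e) {
      stop("fit failed for model {", paste(terms, collapse = ", "),
           "}: ", conditionMessage(e), call. = FALSE)
    })
}

#' Bidirectional stepwise model selection by AIC
#'
#' Starts from the model containing all candidate terms; at each step every
#' single-term drop and add is evaluated and the move with the lowest AIC
#' is taken, stopping at a local minimum. Ties are broken in favour of
#' fewer terms, then by lexicographic term order, so the selected model is
#' invariant to the order in which candidate terms are supplied.
#'
#' @param response name of the response column in `data`.
#' @param full_terms character vector of candidate predictor columns.
#' @param data model frame holding the response and all candidates.
#' @param family `"gaussian_identity"` or `"binomial_logit"`.
#' @return list with `fit` (the selected `model_fit`), `selected_terms`,
#'   and `trace` (a data.frame of the models visited).
#' @export
stepwise_aic <- function(response, full_terms, data,
                         family = c("gaussian_identity", "binomial_logit")) {
  family <- match.arg(family)
  if (length(full_terms) < 1L) stop("need at least one candidate term")
  full_terms <- sort(unique(full_terms))
  current <- full_terms
  current_fit <- fit_terms(response, current, data, family)
  trace <- data.frame(step = 0L, action = "start",
                      terms = paste(current, collapse = "+"),
                      aic = current_fit$aic, stringsAsFactors = FALSE)
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    cand <- list()
    for (tm in current) {
      cand[[paste0("- ", tm)]] <- setdiff(current, tm)
    }
    for (tm in setdiff(full_terms, current)) {
      cand[[paste0("+ ", tm)]] <- sort(c(current, tm))
    }
    if (length(cand) == 0L) break
    aics <- vapply(cand, function(tm) {
      fit_terms(response, tm, data, family)$aic
    }, numeric(1L))
    sizes <- vapply(cand, length, integer(1L))
    labels <- vapply(cand, paste, character(1L), collapse = "+")
    ord <- order(aics, sizes, labels)
    best <- ord[1L]
    if (aics[best] < current_fit$aic - 1e-10) {
      current <- cand[[best]]
      current_fit <- fit_terms(response, current, data, family)
      trace <- rbind(trace, data.frame(
        step = step_i, action = names(cand)[best],
        terms = paste(current, collapse = "+"),
        aic = current_fit$aic, stringsAsFactors = FALSE))
    } else {
      break
    }
  }
  list(fit = current_fit, selected_terms = current, trace = trace)
}
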