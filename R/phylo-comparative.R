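## phylo_comparative: Brownian-motion covariance from an ultrametric tree,
## phylogenetic signal (Pagel's lambda by ML, Blomberg's K with a seeded
## permutation test), and single-predictor PGLS with an F-test.

#' Brownian-motion covariance matrix from a phylogeny
#'
#' Under Brownian motion the trait covariance of two tips is proportional
#' to their shared root-to-MRCA path length; for an ultrametric tree of
#' height H and pairwise divergence T_ij this is H - T_ij / 2, with the
#' diagonal equal to H.
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @param species_subset tips to include, in the requested order; `NULL`
#'   for all tips.
#' @return symmetric positive-semidefinite matrix with species dimnames.
#' @export
bm_covariance <- function(tree, species_subset = NULL) {
  stopifnot(inherits(tree, "phylo"))
  species_subset <- species_subset %||% tree$tip.label
  missing_tips <- setdiff(species_subset, tree$tip.label)
  if (length(missing_tips)) {
    stop("species not in tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  C <- ape::vcv.phylo(tree)
  C[species_subset, species_subset, drop = FALSE]
}

lambda_cov <- function(C, lambda) {
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

## Gaussian log-likelihood of values x under N(mu * 1, sigma2 * V) profiled
## over mu (GLS mean) and sigma2 (ML).
bm_profile_loglik <- function(x, V) {
  n <- length(x)
  ch <- chol(V)
  Vinv_x <- backsolve(ch, forwardsolve(t(ch), x))
  Vinv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Vinv_x) / sum(Vinv_1)
  r <- x - mu
  Vinv_r <- backsolve(ch, forwardsolve(t(ch), r))
  sigma2 <- sum(r * Vinv_r) / n
  logdet <- 2 * sum(log(diag(ch)))
  list(loglik = -0.5 * (n * log(2 * pi * sigma2) + logdet + n),
       mu = mu, sigma2 = sigma2)
}

blomberg_k <- function(x, C) {
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  a_hat <- drop((one %*% Cinv %*% x) / (one %*% Cinv %*% one))
  r <- x - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- drop(r %*% Cinv %*% r) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  (mse0 / mse) / expected
}

#' Phylogenetic signal of a species-level variable
#'
#' `method = "pagel_lambda"`: maximum-likelihood estimate of the branch
#' length transformation lambda scaling the off-diagonal covariance,
#' with a likelihood-ratio test against lambda = 0 (chi-squared, 1 df).
#' `method = "blomberg_K"`: Blomberg's K (observed vs Brownian-expected
#' ratio of mean squared errors), with a p-value from `n_perm` seeded
#' tip-label permutations using the add-one convention.
#'
#' @param values named numeric vector (names are tree tips).
#' @param tree an [ape::phylo] object covering all names.
#' @param method `"pagel_lambda"` or `"blomberg_K"`.
#' @param n_perm permutations for the K test (>= 100).
#' @param seed integer seed for the permutation null.
#' @return list of class `signal_result`: `statistic_name`, `estimate`,
#'   `p_value`, plus method detail (`loglik`, `loglik0` or `n_perm`).
#' @export
phylo_signal <- function(values, tree, method = c("pagel_lambda",
                                                  "blomberg_K"),
                         n_perm = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (is.null(names(values))) stop("values must be named by species")
  if (length(values) < 4L) stop("need at least 4 species", call. = FALSE)
  if (sd(values) == 0) stop("values are constant", call. = FALSE)
  C <- bm_covariance(tree, names(values))
  x <- as.numeric(values)
  if (method == "pagel_lambda") {
    obj <- function(lam) bm_profile_loglik(x, lambda_cov(C, lam))$loglik
    opt <- optimize(obj, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    ## the optimum can sit on a boundary; compare against both endpoints
    cand <- c(opt$maximum, 0, 1)
    ll <- c(opt$objective, obj(0), obj(1))
    est <- cand[which.max(ll)]
    ll_hat <- max(ll)
    ll0 <- obj(0)
    lrt <- max(0, 2 * (ll_hat - ll0))
    res <- list(statistic_name = "pagel_lambda", estimate = est,
                p_value = pchisq(lrt, df = 1L, lower.tail = FALSE),
                loglik = ll_hat, loglik0 = ll0, lrt = lrt)
  } else {
    if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
    obs <- blomberg_k(x, C)
    set.seed(seed)
    null_k <- vapply(seq_len(n_perm), function(i) {
      blomberg_k(sample(x), C)
    }, numeric(1L))
    p <- (1 + sum(null_k >= obs)) / (n_perm + 1)
    res <- list(statistic_name = "blomberg_K", estimate = obs,
                p_value = p, n_perm = n_perm, seed = seed)
  }
  class(res) <- "signal_result"
  res
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g\n", x$statistic_name, x$estimate,
              x$p_value))
  invisible(x)
}

#' Phylogenetic generalized least squares of one variable on another
#'
#' GLS with residual covariance V = C(lambda), where C is the
#' Brownian-motion covariance of the tree pruned to the named species.
#' The slope is tested with an F-test against the intercept-only GLS
#' model, and R-squared is 1 - RSS/TSS in the whitened space.
#'
#' @param y,x named numeric vectors over the same species.
#' @param tree an [ape::phylo] object covering all names.
#' @param lambda_mode `"fixed_1"` (pure Brownian, default), `"fixed_0"`
#'   (star phylogeny; equals OLS on an ultrametric tree) or `"ml"`.
#' @return list of class `pgls_result` with `coefficients`, `F_stat`,
#'   `df1`, `df2`, `r_squared`, `p_value`, `lambda`, `n`.
#' @export
pgls_fit <- function(y, x, tree, lambda_mode = c("fixed_1", "fixed_0",
                                                 "ml")) {
  lambda_mode <- match.arg(lambda_mode)
  if (is.null(names(y)) || is.null(names(x))) {
    stop("y and x must be named by species", call. = FALSE)
  }
  if (!setequal(names(y), names(x))) {
    stop("misaligned names between y and x", call. = FALSE)
  }
  x <- x[names(y)]
  n <- length(y)
  if (n < 4L) stop("need at least 4 species", call. = FALSE)
  C <- bm_covariance(tree, names(y))
  X <- cbind("(Intercept)" = rep(1, n), x = as.numeric(x))

  gls_rss <- function(V, XX, yy) {
    ch <- tryCatch(chol(V), error = function(e) {
      stop("singular phylogenetic covariance", call. = FALSE)
    })
    Xw <- forwardsolve(t(ch), XX)
    yw <- forwardsolve(t(ch), yy)
    beta <- qr.coef(qr(Xw), yw)
    r <- yw - Xw %*% beta
    list(beta = beta, rss = sum(r^2), logdet = 2 * sum(log(diag(ch))))
  }
  loglik_lambda <- function(lam) {
    f <- gls_rss(lambda_cov(C, lam), X, as.numeric(y))
    -0.5 * (n * log(2 * pi * f$rss / n) + f$logdet + n)
  }
  lambda <- switch(lambda_mode,
                   fixed_1 = 1,
                   fixed_0 = 0,
                   ml = {
                     opt <- optimize(loglik_lambda, c(0, 1), maximum = TRUE,
                                     tol = 1e-8)
                     cand <- c(opt$maximum, 0, 1)
                     cand[which.max(c(opt$objective, loglik_lambda(0),
                                      loglik_lambda(1)))]
                   })
  V <- lambda_cov(C, lambda)
  full <- gls_rss(V, X, as.numeric(y))
  null <- gls_rss(V, X[, 1L, drop = FALSE], as.numeric(y))
  df1 <- 1L
  df2 <- n - 2L
  F_stat <- ((null$rss - full$rss) / df1) / (full$rss / df2)
  res <- list(
    coefficients = setNames(drop(full$beta), colnames(X)),
    F_stat = F_stat, df1 = df1, df2 = df2,
    r_squared = 1 - full$rss / null$rss,
    p_value = pf(F_stat, df1, df2, lower.tail = FALSE),
    lambda = lambda, n = n
  )
  class(res) <- "pgls_result"
  res
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf(
    "PGLS (lambda = %.3g, n = %d): slope %.4g, F_%d,%d = %.4g, R2 = %.3g, p = %.4g\n",
    x$lambda, x$n, x$coefficients[[2L]], x$df1, x$df2, x$F_stat,
    x$r_squared, x$p_value))
  invisible(x)
}
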