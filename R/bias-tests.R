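## bias_tests: publication-bias diagnostics. Each species' RI index is
## compared to a permutation null built by averaging randomly drawn
## residuals, and the number of observations per species is regressed on
## its mean residual.

#' Permutation null for per-species RI indices
#'
#' For each species with `n_focal` contributing residuals, draws `n_focal`
#' residuals from the pool without replacement and averages them,
#' repeating `n_perm` times; the two-sided p-value compares `|observed|`
#' to the null with the add-one convention
#' `p = (1 + #{|null| >= |observed|}) / (n_perm + 1)`. The Bonferroni
#' threshold `0.05 / n_species_tested` is reported alongside.
#'
#' @param indices `indices` data.frame from [compute_ri_index()].
#' @param pool numeric vector of all per-cross residuals.
#' @param n_perm number of permutations (>= 100; the study convention is
#'   10,000).
#' @param seed integer seed.
#' @param exclude_focal drop the focal species' own residuals from the
#'   pool before drawing (default keeps them).
#' @param keep_null retain the per-species null means in the result.
#' @return list of class `permutation_test_set`: `tests` (data.frame:
#'   `species`, `n_focal`, `observed_mean`, `p_value`,
#'   `significant_bonferroni`), `alpha_bonferroni`, `n_perm`, `seed`, and
#'   optionally `null_means` (list).
#' @export
permutation_null <- function(indices, pool, n_perm = 10000L, seed = 1L,
                             exclude_focal = FALSE, keep_null = FALSE) {
  if (n_perm < 100L) stop("n_perm must be at least 100", call. = FALSE)
  n_species <- nrow(indices)
  if (max(indices$n_records) > length(pool)) {
    stop("a focal species has more records than the residual pool",
         call. = FALSE)
  }
  set.seed(seed)
  null_store <- if (keep_null) vector("list", n_species) else NULL
  p <- numeric(n_species)
  for (i in seq_len(n_species)) {
    n_focal <- indices$n_records[i]
    this_pool <- pool
    if (exclude_focal) {
      own <- indices$residuals[[i]]
      for (r in own) {
        hit <- match(r, this_pool)
        if (!is.na(hit)) this_pool <- this_pool[-hit]
      }
      if (length(this_pool) < n_focal) {
        stop("pool too small after excluding focal residuals",
             call. = FALSE)
      }
    }
    nulls <- vapply(seq_len(n_perm), function(b) {
      mean(this_pool[sample.int(length(this_pool), n_focal)])
    }, numeric(1L))
    p[i] <- (1 + sum(abs(nulls) >= abs(indices$mean_residual[i]))) /
      (n_perm + 1)
    if (keep_null) null_store[[i]] <- nulls
  }
  alpha <- 0.05 / n_species
  tests <- data.frame(
    species = indices$species,
    n_focal = indices$n_records,
    observed_mean = indices$mean_residual,
    p_value = p,
    significant_bonferroni = p < alpha,
    stringsAsFactors = FALSE
  )
  out <- list(tests = tests, alpha_bonferroni = alpha, n_perm = n_perm,
              seed = seed)
  if (keep_null) out$null_means <- null_store
  class(out) <- "permutation_test_set"
  out
}

#' @export
print.permutation_test_set <- function(x, ...) {
  cat(sprintf(
    "Permutation null (%d draws, seed %d): %d species tested, Bonferroni alpha %.3g\n",
    x$n_perm, x$seed, nrow(x$tests), x$alpha_bonferroni))
  cat(sprintf("  species significant after correction: %d\n",
              sum(x$tests$significant_bonferroni)))
  invisible(x)
}

#' Regression of the RI index on the number of observations
#'
#' If publication bias inflated well-studied species' compatibility, the
#' per-species mean residual should rise with its record count. Fits the
#' Gaussian regression `mean_residual ~ n_records` and reports McFadden's
#' pseudo-R-squared against the intercept-only model and the slope
#' p-value (t-test).
#'
#' @param indices `indices` data.frame from [compute_ri_index()].
#' @return list with `fit`, `r2_mcfadden`, `slope_p`.
#' @export
records_vs_residual <- function(indices) {
  if (nrow(indices) < 4L) stop("need at least 4 species", call. = FALSE)
  X <- cbind("(Intercept)" = rep(1, nrow(indices)),
             n_records = indices$n_records)
  fit <- fit_gaussian(indices$mean_residual, X,
                      response_name = "mean_residual")
  null_fit <- fit_gaussian(indices$mean_residual,
                           X[, 1L, drop = FALSE],
                           response_name = "mean_residual")
  tval <- fit$coefficients[["n_records"]] / fit$se[["n_records"]]
  slope_p <- 2 * pt(abs(tval), df = fit$n - 2L, lower.tail = FALSE)
  list(fit = fit, r2_mcfadden = mcfadden_r2(fit, null_fit),
       slope_p = slope_p)
}
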