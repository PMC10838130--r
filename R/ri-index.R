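## ri_index: species-level reproductive-isolation index. The ordinal score
## of every cross is regressed on divergence time; each cross's residual is
## attributed to both member species, and a species' index is the mean of
## all residuals involving it. Positive values mean the species' crosses
## are on average more hybrid-compatible than divergence alone predicts.

#' Compute per-species reproductive-isolation indices
#'
#' Fits the baseline Gaussian regression of the 1-3 isolation score on
#' divergence time over all records, then averages the residuals of all
#' crosses involving each species.
#'
#' @param ds a `cross_dataset` with at least 3 records and at least 2
#'   distinct divergence values.
#' @return list with `indices` (data.frame: `species`, `n_records`,
#'   `mean_residual`, list-column `residuals`) and `fit` (the baseline
#'   `model_fit`).
#' @export
compute_ri_index <- function(ds) {
  stopifnot(inherits(ds, "cross_dataset"))
  if (nrow(ds) < 3L) stop("need at least 3 records", call. = FALSE)
  if (length(unique(ds$divergence_my)) < 2L) {
    stop("need at least 2 distinct divergence values", call. = FALSE)
  }
  y <- score_cross(ds$outcome)
  X <- cbind("(Intercept)" = rep(1, nrow(ds)),
             divergence_my = ds$divergence_my)
  fit <- fit_gaussian(y, X, response_name = "ri_score")
  res <- fit$residuals
  species <- cross_species(ds)
  per_species <- lapply(species, function(sp) {
    idx <- which(ds$species_a == sp | ds$species_b == sp)
    res[idx]
  })
  indices <- data.frame(
    species = species,
    n_records = vapply(per_species, length, integer(1L)),
    mean_residual = vapply(per_species, mean, numeric(1L)),
    stringsAsFactors = FALSE
  )
  indices$residuals <- I(per_species)
  list(indices = indices, fit = fit)
}
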