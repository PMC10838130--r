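## predictor_analysis: per-pair predictors of the ordinal isolation score
## (habitat mismatch, clutch-size difference, PCA-reduced morphological
## differences) and stepwise-AIC selection of the isolation model.

#' Build per-pair predictor features
#'
#' For every cross with complete trait data for both species, computes the
#' habitat match indicator (1 if the two species share a habitat class),
#' the absolute clutch-size difference, the 11 absolute morphological
#' differences, and the first two principal-component scores of the
#' centred (and, by default, unit-variance scaled) pair-by-trait
#' difference matrix. Pairs lacking complete traits are dropped and
#' reported.
#'
#' @param ds a `cross_dataset`.
#' @param traits trait table as from [read_trait_table()].
#' @param pca_scale scale difference columns to unit variance before PCA
#'   (the 11 variables mix millimetres and grams).
#' @return list with `features` (one row per retained pair: `ri_score`,
#'   `divergence_my`, `habitat_match`, `clutch_diff`, the 11 `diff_*`
#'   columns, `pc1`, `pc2`), `pca` (loadings, explained fractions,
#'   centering/scaling), and `dropped_pairs`.
#' @export
build_pair_features <- function(ds, traits, pca_scale = TRUE) {
  stopifnot(inherits(ds, "cross_dataset"))
  if (!"complete" %in% names(traits)) {
    morph_ok <- rowSums(is.na(as.matrix(traits[MORPH_VARS]))) == 0L
    traits$complete <- morph_ok & !is.na(traits$clutch_size) &
      traits$clutch_size > 0
  }
  rownames(traits) <- traits$species
  have <- function(sp) sp %in% traits$species && traits[sp, "complete"]
  ok <- vapply(seq_len(nrow(ds)), function(i) {
    have(ds$species_a[i]) && have(ds$species_b[i])
  }, logical(1L))
  dropped <- ds[!ok, c("species_a", "species_b"), drop = FALSE]
  if (nrow(dropped)) {
    message("dropping ", nrow(dropped),
            " pair(s) with incomplete trait data")
  }
  sub <- ds[ok, , drop = FALSE]
  if (nrow(sub) < 3L) {
    stop("need at least 3 pairs with complete traits for PCA",
         call. = FALSE)
  }
  ta <- traits[sub$species_a, , drop = FALSE]
  tb <- traits[sub$species_b, , drop = FALSE]
  morph_diff <- abs(as.matrix(ta[MORPH_VARS]) - as.matrix(tb[MORPH_VARS]))
  colnames(morph_diff) <- paste0("diff_", MORPH_VARS)
  habitat_match <- as.integer(tolower(trimws(ta$habitat)) ==
                                tolower(trimws(tb$habitat)))
  clutch_diff <- abs(ta$clutch_size - tb$clutch_size)

  keep <- apply(morph_diff, 2L, function(col) sd(col) > 0)
  if (any(!keep)) {
    warning("dropping zero-variance difference column(s): ",
            paste(colnames(morph_diff)[!keep], collapse = ", "))
  }
  pca <- prcomp(morph_diff[, keep, drop = FALSE], center = TRUE,
                scale. = pca_scale)
  vars <- pca$sdev^2
  scores <- pca$x
  features <- data.frame(
    species_a = sub$species_a, species_b = sub$species_b,
    ri_score = score_cross(sub$outcome),
    divergence_my = sub$divergence_my,
    habitat_match = habitat_match,
    clutch_diff = clutch_diff,
    morph_diff, check.names = FALSE, stringsAsFactors = FALSE
  )
  features$pc1 <- scores[, 1L]
  features$pc2 <- if (ncol(scores) >= 2L) scores[, 2L] else 0
  pca_model <- list(
    loadings = pca$rotation,
    explained_fraction = vars / sum(vars),
    center = pca$center,
    scale = if (isFALSE(pca$scale)) NULL else pca$scale,
    columns = colnames(morph_diff)[keep]
  )
  list(features = features, pca = pca_model, dropped_pairs = dropped)
}

#' Fit and select the reproductive-isolation predictor model
#'
#' Fits the full Gaussian model
#' `ri_score ~ divergence_my + clutch_diff + pc1 + pc2 + habitat_match`,
#' runs bidirectional stepwise AIC selection, and reports the selected
#' fit, its McFadden pseudo-R-squared against the intercept-only model,
#' and the selection trace.
#'
#' @param features feature table from [build_pair_features()].
#' @return list with `fit`, `selected_terms`, `r2_mcfadden`, `null_fit`,
#'   `trace`.
#' @export
fit_predictor_model <- function(features) {
  if (nrow(features) < 10L) {
    stop("need at least 10 pairs to fit the predictor model",
         call. = FALSE)
  }
  terms <- c("divergence_my", "clutch_diff", "pc1", "pc2", "habitat_match")
  ## a candidate with no variation (e.g. every pair sharing a habitat)
  ## carries no information and would make the design singular
  constant <- vapply(terms, function(tm) sd(features[[tm]]) == 0,
                     logical(1L))
  if (any(constant)) {
    message("dropping constant predictor(s): ",
            paste(terms[constant], collapse = ", "))
    terms <- terms[!constant]
  }
  sel <- stepwise_aic("ri_score", terms, features,
                      family = "gaussian_identity")
  null_fit <- fit_terms("ri_score", character(0L), features,
                        "gaussian_identity")
  list(fit = sel$fit, selected_terms = sel$selected_terms,
       r2_mcfadden = mcfadden_r2(sel$fit, null_fit),
       null_fit = null_fit, trace = sel$trace)
}
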