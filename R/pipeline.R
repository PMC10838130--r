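## cli_pipeline: end-to-end orchestration. A single config (real input
## files or a synthetic-data configuration) drives every stage; outputs
## land in a run directory with a manifest recording input checksums and
## the resolved configuration. A rerun with the same config and inputs is
## byte-identical.

#' Run the full hybrid-compatibility analysis pipeline
#'
#' Stages: input loading (or synthetic generation) - dataset summary -
#' Haldane's Rule and speciation time courses - pair features and
#' predictor-model selection - per-species RI index - domestication index
#' (skipped and flagged when no corpus/lexicon is configured) -
#' phylogenetic signal and PGLS of RI index on domestication index
#' (skipped without a tree) - permutation bias diagnostics. Synthetic
#' inputs are first written to disk and read back through the package's
#' own readers, so the file formats are exercised on every run.
#'
#' @param config list with either `synthetic` (a [sim_config()] or `TRUE`)
#'   or input paths `crosses`, `traits`, `tree`, `corpus_dir`, `lexicon`
#'   (the last three optional); plus `out_dir` (required), `seed`
#'   (default 1), `n_perm` (default 1000), `lambda_mode`, `pca_scale`,
#'   `overrides` (named numeric domestication overrides),
#'   `exclude_extreme` (optional integer vector `c(n_top, n_bottom)` for
#'   the trimmed PGLS rerun).
#' @return the manifest list, invisibly; all artifacts are under
#'   `config$out_dir`.
#' @export
run_full_pipeline <- function(config) {
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_perm <- as.integer(config$n_perm %||% 1000L)
  lambda_mode <- config$lambda_mode %||% "fixed_1"
  pca_scale <- config$pca_scale %||% TRUE
  use_synth <- !is.null(config$synthetic) && !isFALSE(config$synthetic)
  if (use_synth && !is.null(config$crosses)) {
    stop("config must name either synthetic or real inputs, not both",
         call. = FALSE)
  }

  inputs <- list()
  if (use_synth) {
    cfg <- if (inherits(config$synthetic, "sim_config")) {
      config$synthetic
    } else {
      sim_config(seed = seed)
    }
    in_dir <- file.path(out_dir, "inputs")
    dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
    tree <- simulate_tree(cfg)
    traits <- simulate_traits(tree, cfg)
    ds <- simulate_crosses(tree, traits, cfg)
    corpus <- simulate_corpus(cross_species(ds), cfg,
                              file.path(in_dir, "corpus"))
    inputs$crosses <- file.path(in_dir, "crosses.csv")
    inputs$traits <- file.path(in_dir, "traits.csv")
    inputs$tree <- file.path(in_dir, "tree.nwk")
    inputs$lexicon <- file.path(in_dir, "lexicon.csv")
    inputs$corpus_dir <- corpus$corpus_dir
    write_cross_table(ds, inputs$crosses)
    write_trait_table(traits, inputs$traits)
    ape::write.tree(tree, inputs$tree)
    write_lexicon(corpus$lexicon, inputs$lexicon)
    write_report(as.list(corpus$true_counts),
                 file.path(in_dir, "true_counts.json"))
  } else {
    if (is.null(config$crosses)) stop("config$crosses is required")
    inputs$crosses <- config$crosses
    inputs$traits <- config$traits
    inputs$tree <- config$tree
    inputs$lexicon <- config$lexicon
    inputs$corpus_dir <- config$corpus_dir
  }

  manifest <- list(config = list(seed = seed, n_perm = n_perm,
                                 lambda_mode = lambda_mode,
                                 pca_scale = pca_scale,
                                 synthetic = use_synth),
                   inputs = list(), outputs = list(), skipped = list())
  add_output <- function(name, path) {
    manifest$outputs[[name]] <<- list(
      path = basename(path), md5 = unname(tools::md5sum(path)))
  }

  ## stage: core_io -------------------------------------------------------
  ds <- read_cross_table(inputs$crosses)
  traits <- if (!is.null(inputs$traits)) read_trait_table(inputs$traits)
  tree <- if (!is.null(inputs$tree)) read_phylogeny(inputs$tree)
  ## inputs under out_dir are recorded relative to it so a rerun into a
  ## different directory stays byte-identical
  out_norm <- normalizePath(out_dir)
  rel_path <- function(p) {
    pn <- normalizePath(p)
    if (startsWith(pn, paste0(out_norm, .Platform$file.sep))) {
      substring(pn, nchar(out_norm) + 2L)
    } else {
      p
    }
  }
  for (nm in c("crosses", "traits", "tree", "lexicon")) {
    if (!is.null(inputs[[nm]])) {
      manifest$inputs[[nm]] <- list(path = rel_path(inputs[[nm]]),
                                    md5 = unname(tools::md5sum(inputs[[nm]])))
    }
  }
  message("loaded ", nrow(ds), " crosses over ",
          length(cross_species(ds)), " species")

  summ <- summarize_dataset(ds)
  write_report(unclass(summ)[c("n_pairs", "n_species", "mean_divergence",
                               "sd_divergence", "min_divergence",
                               "max_divergence", "mean_partner_count")],
               file.path(out_dir, "summary.json"))
  add_output("summary", file.path(out_dir, "summary.json"))

  ## stage: timecourse ----------------------------------------------------
  hald <- haldane_regression(ds)
  spec <- speciation_regression(ds)
  write_report(list(
    haldane = list(crossing_my = hald$crossing_my, n_used = hald$n_used,
                   coefficients = as.list(hald$model$coefficients)),
    speciation = list(crossing_my = spec$crossing_my, n_used = spec$n_used,
                      coefficients = as.list(spec$model$coefficients))),
    file.path(out_dir, "timecourse.json"))
  add_output("timecourse", file.path(out_dir, "timecourse.json"))

  ## stage: predictor_analysis -------------------------------------------
  model <- NULL
  if (!is.null(traits)) {
    feats <- build_pair_features(ds, traits, pca_scale = pca_scale)
    model <- fit_predictor_model(feats$features)
    write_report(feats$features, file.path(out_dir, "features.tsv"),
                 format = "tsv")
    write_report(list(
      selected_terms = model$selected_terms,
      coefficients = as.list(model$fit$coefficients),
      aic = model$fit$aic, r2_mcfadden = model$r2_mcfadden,
      pca_explained = feats$pca$explained_fraction,
      n_dropped_pairs = nrow(feats$dropped_pairs)),
      file.path(out_dir, "predictor_model.json"))
    add_output("features", file.path(out_dir, "features.tsv"))
    add_output("predictor_model", file.path(out_dir, "predictor_model.json"))
  } else {
    manifest$skipped$predictor_analysis <- "no trait table configured"
  }

  ## stage: ri_index ------------------------------------------------------
  ri <- compute_ri_index(ds)
  write_report(ri$indices[c("species", "n_records", "mean_residual")],
               file.path(out_dir, "ri_index.tsv"), format = "tsv")
  add_output("ri_index", file.path(out_dir, "ri_index.tsv"))

  ## stage: domestication_text -------------------------------------------
  dom <- NULL
  if (!is.null(inputs$corpus_dir) && !is.null(inputs$lexicon)) {
    lex <- read_lexicon(inputs$lexicon)
    raw <- count_occurrences(inputs$corpus_dir, lex)
    dom <- scale_index(raw, override = config$overrides)
    write_report(dom, file.path(out_dir, "domestication.tsv"),
                 format = "tsv")
    add_output("domestication", file.path(out_dir, "domestication.tsv"))
  } else {
    manifest$skipped$domestication_text <- "no corpus/lexicon configured"
  }

  ## stage: phylo_comparative --------------------------------------------
  if (!is.null(tree) && !is.null(dom)) {
    common <- Reduce(intersect, list(ri$indices$species, dom$species,
                                     tree$tip.label))
    if (length(common) < length(ri$indices$species)) {
      message("pruning to ", length(common),
              " species present in tree, RI and domestication tables")
    }
    y <- setNames(ri$indices$mean_residual,
                  ri$indices$species)[common]
    x <- setNames(dom$scaled, dom$species)[common]
    base_fit <- fit_gaussian(y, cbind("(Intercept)" = rep(1, length(y)),
                                      dom = as.numeric(x)),
                             response_name = "ri_index")
    sig_lambda <- phylo_signal(setNames(base_fit$residuals, common), tree,
                               method = "pagel_lambda")
    sig_k <- phylo_signal(setNames(base_fit$residuals, common), tree,
                          method = "blomberg_K", n_perm = n_perm,
                          seed = seed + 10L)
    pgls <- pgls_fit(y, x, tree, lambda_mode = lambda_mode)
    pgls_out <- list(
      signal = list(
        pagel_lambda = list(estimate = sig_lambda$estimate,
                            p_value = sig_lambda$p_value),
        blomberg_K = list(estimate = sig_k$estimate,
                          p_value = sig_k$p_value)),
      pgls = unclass(pgls))
    ## trimmed rerun excluding the most and least domesticated species
    if (!is.null(config$exclude_extreme)) {
      keep <- trim_extremes(x, config$exclude_extreme[1L],
                            config$exclude_extreme[2L])
      if (length(keep) >= 4L) {
        pgls_out$pgls_trimmed <- unclass(
          pgls_fit(y[keep], x[keep], tree, lambda_mode = lambda_mode))
      }
    }
    write_report(pgls_out, file.path(out_dir, "pgls.json"))
    add_output("pgls", file.path(out_dir, "pgls.json"))
  } else {
    manifest$skipped$phylo_comparative <-
      "needs both a tree and a domestication index"
  }

  ## stage: bias_tests ----------------------------------------------------
  perm <- permutation_null(ri$indices, ri$fit$residuals, n_perm = n_perm,
                           seed = seed + 20L)
  rvr <- records_vs_residual(ri$indices)
  write_report(perm$tests, file.path(out_dir, "bias_tests.tsv"),
               format = "tsv")
  write_report(list(
    alpha_bonferroni = perm$alpha_bonferroni,
    n_significant = sum(perm$tests$significant_bonferroni),
    min_p = min(perm$tests$p_value),
    records_vs_residual = list(r2_mcfadden = rvr$r2_mcfadden,
                               slope_p = rvr$slope_p)),
    file.path(out_dir, "bias_summary.json"))
  add_output("bias_tests", file.path(out_dir, "bias_tests.tsv"))
  add_output("bias_summary", file.path(out_dir, "bias_summary.json"))

  write_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

## names of the species kept after removing the n_top highest and n_bottom
## lowest values of x (ties at the boundary resolved by name order, so the
## trim is deterministic)
trim_extremes <- function(x, n_top, n_bottom) {
  ord <- order(x, names(x))
  drop <- c(head(ord, n_bottom), head(rev(ord), n_top))
  names(x)[-drop]
}

#' Reproduce the study's headline dataset and time-course numbers
#'
#' Given the deposited cross table (one row per hybridizing species pair
#' with fertility outcome and TimeTree divergence), recomputes the
#' dataset summary and both logistic time courses.
#'
#' @param cross_path path to the deposited cross table (delimited text in
#'   the [read_cross_table()] layout).
#' @return list with `summary`, `haldane`, `speciation`.
#' @export
reproduce_study <- function(cross_path) {
  ds <- read_cross_table(cross_path)
  list(summary = summarize_dataset(ds),
       haldane = haldane_regression(ds),
       speciation = speciation_regression(ds))
}
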