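## synthetic_data: Yule trees, Brownian traits, an ordered-logit cross
## simulator and planted-occurrence text corpora. Every downstream stage
## can be exercised against known ground truth without any download.
##
## Defaults emulate the study conditions: 77 species, 123 crosses, a
## 65-MY-old clade, and an ordered-logit latent scale whose cutpoints put
## the sterile 50% boundary near 19 MY and the male-only boundary near
## 8 MY of divergence.

#' Simulation configuration
#'
#' @param n_species number of tips (>= 4).
#' @param seed integer master seed; each generator stage draws from its own
#'   substream (`seed + stage offset`) so adding a stage does not perturb
#'   earlier stages.
#' @param birth_rate Yule speciation rate (shape only; the tree is rescaled
#'   to `tree_height`).
#' @param tree_height root-to-tip height in MY.
#' @param n_crosses number of species pairs to sample.
#' @param pair_weight_scale e-folding scale (MY) of the divergence decay
#'   in pair sampling weights, `exp(-divergence / scale)`: recorded
#'   hybridizations are overwhelmingly between close relatives, so
#'   sampled pairs concentrate at shallow divergences; `Inf` samples
#'   pairs uniformly.
#' @param beta0 ordered-logit latent intercept.
#' @param beta_t latent slope on divergence time (per MY).
#' @param beta_c latent slope on absolute clutch-size difference (per egg).
#' @param c1,c2 ordered-logit cutpoints, `c1 < c2`: latent values below
#'   `c1` give `BOTH_FERTILE`, in `[c1, c2)` give `MALE_ONLY`, at or above
#'   `c2` give `STERILE`.
#' @param bm_sigma2 Brownian rate per morphological trait (per MY).
#' @param trait_root root state of every morphological trait.
#' @param clutch_sigma2 Brownian rate of log clutch size (per MY).
#' @param clutch_root root clutch size (eggs).
#' @param n_habitats number of habitat categories.
#' @param habitat_rate symmetric Markov switching rate between habitat
#'   categories along branches (per MY).
#' @param domestication_weights optional named non-negative reals steering
#'   how often each species is planted in the corpus; `NULL` draws them.
#' @param corpus_docs number of corpus documents to write.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_species = 77L, seed = 1L, birth_rate = 0.1,
                       tree_height = 65, n_crosses = 123L,
                       pair_weight_scale = 6,
                       beta0 = 0, beta_t = 0.15, beta_c = 0.1,
                       c1 = 1.15, c2 = 2.9,
                       bm_sigma2 = 0.1, trait_root = 10,
                       clutch_sigma2 = 0.005, clutch_root = 8,
                       n_habitats = 3L, habitat_rate = 0.01,
                       domestication_weights = NULL, corpus_docs = 10L) {
  if (n_species < 4L) stop("n_species must be at least 4", call. = FALSE)
  if (!(c1 < c2)) stop("cutpoints must satisfy c1 < c2", call. = FALSE)
  if (birth_rate <= 0 || tree_height <= 0 || bm_sigma2 < 0 ||
      clutch_sigma2 < 0 || habitat_rate < 0) {
    stop("rates must be positive", call. = FALSE)
  }
  if (n_habitats < 1L) stop("n_habitats must be at least 1", call. = FALSE)
  if (corpus_docs < 1L) stop("corpus_docs must be at least 1", call. = FALSE)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

stage_seed <- function(cfg, offset) {
  (as.integer(cfg$seed) + offset) %% .Machine$integer.max
}

#' Simulate an ultrametric pure-birth phylogeny
#'
#' Yule tree with `cfg$n_species` tips, rescaled so the root-to-tip height
#' equals `cfg$tree_height` MY; tips are labelled `sp1..spN`.
#'
#' @param cfg a [sim_config()].
#' @return an ultrametric [ape::phylo] object.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg, 0L))
  tree <- ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0)
  height <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (cfg$tree_height / height)
  tree$tip.label <- paste0("sp", seq_len(cfg$n_species))
  validate_phylogeny(tree)
}

#' Simulate species traits on a phylogeny
#'
#' Each of the 11 morphological variables evolves by Brownian motion
#' (variance `bm_sigma2` per MY) from a common root state; clutch size is
#' Brownian on the log scale and exponentiated; habitat follows a
#' symmetric Markov jump process with `n_habitats` states along branches.
#'
#' @param tree tree from [simulate_tree()].
#' @param cfg a [sim_config()].
#' @return trait data.frame in the [read_trait_table()] layout.
#' @export
simulate_traits <- function(tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tree, "phylo"))
  set.seed(stage_seed(cfg, 1L))
  n <- length(tree$tip.label)
  morph <- vapply(MORPH_VARS, function(v) {
    ape::rTraitCont(tree, model = "BM", sigma = sqrt(cfg$bm_sigma2),
                    root.value = cfg$trait_root)
  }, numeric(n))
  clutch <- exp(ape::rTraitCont(tree, model = "BM",
                                sigma = sqrt(cfg$clutch_sigma2),
                                root.value = log(cfg$clutch_root)))
  habitat <- if (cfg$n_habitats == 1L || cfg$habitat_rate == 0) {
    rep("habitat1", n)
  } else {
    states <- ape::rTraitDisc(tree, model = "ER", k = cfg$n_habitats,
                              rate = cfg$habitat_rate,
                              states = paste0("habitat",
                                              seq_len(cfg$n_habitats)))
    as.character(states)
  }
  traits <- data.frame(species = tree$tip.label, habitat = habitat,
                       morph, clutch_size = unname(clutch),
                       check.names = FALSE, stringsAsFactors = FALSE)
  traits$complete <- TRUE
  rownames(traits) <- NULL
  traits
}

#' Simulate hybridization crosses under an ordered-logit model
#'
#' Samples `cfg$n_crosses` distinct species pairs, computes each pair's
#' divergence time from the tree and latent compatibility
#' `eta = beta0 + beta_t * divergence + beta_c * |clutch difference|`,
#' adds standard logistic noise and thresholds at the cutpoints: below
#' `c1` the cross is `BOTH_FERTILE`, between the cutpoints `MALE_ONLY`,
#' above `c2` `STERILE` - so the probability of the more isolated
#' categories is monotone in divergence.
#'
#' @param tree tree from [simulate_tree()].
#' @param traits trait table covering all tips (for clutch sizes).
#' @param cfg a [sim_config()].
#' @return a [cross_dataset()].
#' @export
simulate_crosses <- function(tree, traits, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  missing_sp <- setdiff(tree$tip.label, traits$species)
  if (length(missing_sp)) {
    stop("traits missing for: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  }
  set.seed(stage_seed(cfg, 2L))
  pairs <- t(combn(tree$tip.label, 2L))
  if (cfg$n_crosses > nrow(pairs)) {
    stop("n_crosses exceeds the number of distinct pairs", call. = FALSE)
  }
  div_mat <- ape::cophenetic.phylo(tree) / 2
  all_div <- div_mat[cbind(pairs[, 1L], pairs[, 2L])]
  w <- if (is.finite(cfg$pair_weight_scale)) {
    exp(-all_div / cfg$pair_weight_scale)
  } else {
    rep(1, nrow(pairs))
  }
  pick <- sample.int(nrow(pairs), cfg$n_crosses, prob = w)
  pairs <- pairs[pick, , drop = FALSE]
  rownames(traits) <- traits$species
  div <- all_div[pick]
  clutch_diff <- abs(traits[pairs[, 1L], "clutch_size"] -
                       traits[pairs[, 2L], "clutch_size"])
  eta <- cfg$beta0 + cfg$beta_t * div + cfg$beta_c * clutch_diff
  z <- eta + rlogis(length(eta))
  outcome <- ifelse(z < cfg$c1, "BOTH_FERTILE",
                    ifelse(z < cfg$c2, "MALE_ONLY", "STERILE"))
  cross_dataset(pairs[, 1L], pairs[, 2L], outcome, div,
                source = "synthetic")
}

#' Closed-form category probabilities of the ordered-logit generator
#'
#' @param eta latent mean (vector).
#' @param c1,c2 cutpoints.
#' @return matrix with columns `BOTH_FERTILE`, `MALE_ONLY`, `STERILE`.
#' @export
ordered_logit_probs <- function(eta, c1, c2) {
  p_both <- plogis(c1 - eta)
  p_sterile <- plogis(eta - c2)
  cbind(BOTH_FERTILE = p_both, MALE_ONLY = 1 - p_both - p_sterile,
        STERILE = p_sterile)
}

#' Simulate a text corpus with planted species-name occurrences
#'
#' Writes `cfg$corpus_docs` plain-text documents to `dir`, planting a
#' known number of occurrences of one name variant per species between
#' filler words. Each species gets a scientific-name variant and a common
#' name; the first two species deliberately share overlapping common
#' names (the second species' name contains the first's as a substring)
#' so longest-match scanning is exercised.
#'
#' @param species character vector of species names.
#' @param cfg a [sim_config()].
#' @param dir output directory for the corpus (created if needed).
#' @return list with `corpus_dir`, `lexicon` (a `name_lexicon`) and
#'   `true_counts` (named integer vector; the planted ground truth).
#' @export
simulate_corpus <- function(species, cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(species) == 0L) stop("empty species list", call. = FALSE)
  set.seed(stage_seed(cfg, 3L))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(species)
  common <- paste0("fowl", seq_len(n))
  if (n >= 2L) {
    common[1L] <- "turkey"
    common[2L] <- "ocellated turkey"
  }
  lex <- name_lexicon(rep(species, 2L),
                      c(tolower(species), common))
  weights <- cfg$domestication_weights %||%
    setNames(rexp(n, rate = 1 / 10), species)
  if (is.null(names(weights))) names(weights) <- species
  true_counts <- setNames(rpois(n, lambda = weights[species]), species)
  filler <- c("the", "aviary", "notes", "on", "breeding", "season",
              "eggs", "plumage", "keeper", "winter")
  docs <- vector("list", cfg$corpus_docs)
  for (d in seq_len(cfg$corpus_docs)) docs[[d]] <- character(0L)
  for (i in seq_len(n)) {
    k <- true_counts[[i]]
    if (k == 0L) next
    ## plant the common-name variant; scientific names stay unplanted so
    ## overlapping-variant bookkeeping has a single ground truth per species
    where <- sample.int(cfg$corpus_docs, k, replace = TRUE)
    for (d in seq_len(cfg$corpus_docs)) {
      reps <- sum(where == d)
      if (reps > 0L) {
        docs[[d]] <- c(docs[[d]], rep(common[i], reps))
      }
    }
  }
  files <- file.path(dir, sprintf("doc%03d.txt", seq_len(cfg$corpus_docs)))
  for (d in seq_len(cfg$corpus_docs)) {
    tokens <- docs[[d]]
    words <- sample(filler, 20L + 3L * length(tokens), replace = TRUE)
    if (length(tokens)) {
      at <- sort(sample.int(length(words), length(tokens)))
      for (j in seq_along(tokens)) {
        words[at[j]] <- paste0(words[at[j]], ". ", tokens[j], ".")
      }
    }
    writeLines(paste(words, collapse = " "), files[d])
  }
  list(corpus_dir = dir, lexicon = lex, true_counts = true_counts)
}
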