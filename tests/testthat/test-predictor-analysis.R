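test_that("pair features are symmetric absolute differences", {
  sp <- c("A a", "B b", "C c", "D d", "E e", "F f")
  traits <- make_traits(sp, clutch = c(12, 4.5, 6, 8, 5, 9),
                        habitat = c("forest", "forest", "shrub",
                                    "shrub", "forest", "wetland"))
  ## make two species trait-identical
  traits[traits$species == "B b", galliso:::MORPH_VARS] <-
    traits[traits$species == "A a", galliso:::MORPH_VARS]
  traits$clutch_size[traits$species == "B b"] <- 12
  ds <- cross_dataset(c("A a", "A a", "C c", "E e"),
                      c("B b", "C c", "D d", "F f"),
                      rep("MALE_ONLY", 4L), c(2, 10, 4, 6))
  built <- build_pair_features(ds, traits)
  f <- built$features
  idab <- f$species_a == "A a" & f$species_b == "B b"
  expect_true(all(as.matrix(
    f[idab, paste0("diff_", galliso:::MORPH_VARS)]) == 0))
  expect_equal(f$clutch_diff[idab], 0)
  expect_equal(f$habitat_match[idab], 1L)
  expect_equal(f$habitat_match[f$species_a == "C c" &
                                 f$species_b == "D d"], 1L)
  expect_equal(f$habitat_match[f$species_a == "E e" &
                                 f$species_b == "F f"], 0L)
  ## clutch sizes 12 and 6 on the A-C pair
  expect_equal(f$clutch_diff[f$species_a == "A a" & f$species_b == "C c"],
               6)

  ## within-pair order invariance
  ds_swapped <- cross_dataset(ds$species_b, ds$species_a, ds$outcome,
                              ds$divergence_my)
  f2 <- build_pair_features(ds_swapped, traits)$features
  expect_equal(f2[names(f)], f[names(f)])
})

test_that("clutch difference is plain arithmetic", {
  sp <- c("A a", "B b", "C c", "D d")
  traits <- make_traits(sp, clutch = c(12, 4.5, 7, 7))
  ds <- cross_dataset(c("A a", "A a", "C c"), c("B b", "C c", "D d"),
                      rep("STERILE", 3L), c(5, 6, 7))
  f <- build_pair_features(ds, traits)$features
  expect_equal(f$clutch_diff[f$species_a == "A a" & f$species_b == "B b"],
               7.5)
})

test_that("PCA of the difference matrix matches an eigendecomposition oracle", {
  set.seed(19)
  sp <- paste0(LETTERS[1:10], " ", letters[1:10])
  traits <- make_traits(sp, seed = 19L)
  ds <- cross_dataset(sp[c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9)],
                      sp[c(2, 3, 4, 5, 6, 7, 8, 9, 10, 10)],
                      rep(c("STERILE", "MALE_ONLY"), 5L),
                      seq(2, 20, by = 2))
  built <- build_pair_features(ds, traits, pca_scale = TRUE)
  D <- as.matrix(built$features[paste0("diff_", galliso:::MORPH_VARS)])
  ## oracle: eigenvalues of the correlation matrix of the differences
  ## (10 pairs give a rank-9 centred matrix, so the trailing eigenvalues
  ## are numerically zero and only the informative ones are compared)
  ev <- eigen(cor(D), symmetric = TRUE)$values
  expect_equal(head(built$pca$explained_fraction, 9L),
               head(ev / sum(ev), 9L), tolerance = 1e-8)
  expect_equal(sum(built$pca$explained_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(built$pca$explained_fraction) < 1e-12))
  ## loadings are orthonormal
  L <- built$pca$loadings
  expect_equal(t(L) %*% L, diag(ncol(L)), tolerance = 1e-8,
               ignore_attr = TRUE)
  ## full reconstruction through the loadings
  scores <- scale(D, center = built$pca$center,
                  scale = built$pca$scale) %*% L
  recon <- scores %*% t(L)
  expect_equal(recon,
               scale(D, center = built$pca$center,
                     scale = built$pca$scale),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a single varying difference column carries all the variance", {
  sp <- paste0("S", 1:5, " x")
  traits <- make_traits(sp)
  traits[galliso:::MORPH_VARS] <- 50
  traits$mass <- c(10, 20, 35, 55, 80)
  ds <- cross_dataset(sp[c(1, 2, 3, 4)], sp[c(2, 3, 4, 5)],
                      rep("STERILE", 4L), c(1, 2, 3, 4))
  expect_warning(built <- build_pair_features(ds, traits),
                 "zero-variance")
  expect_equal(built$pca$explained_fraction[[1L]], 1, tolerance = 1e-12)
  expect_identical(built$pca$columns, "diff_mass")
})

test_that("pairs with incomplete traits are dropped and reported", {
  sp <- paste0("S", 1:6, " x")
  traits <- make_traits(sp)
  traits$mass[6L] <- NA
  traits$complete <- NULL
  ds <- cross_dataset(sp[c(1, 2, 3, 4, 5)], sp[c(2, 3, 4, 5, 6)],
                      rep("MALE_ONLY", 5L), 1:5)
  expect_message(built <- build_pair_features(ds, traits), "dropping 1")
  expect_equal(nrow(built$features), 4L)
  expect_equal(nrow(built$dropped_pairs), 1L)
})

test_that("model selection recovers a divergence-only truth on synthetic data", {
  ## crosses generated with beta_c = 0; the trait-difference predictors
  ## are decoupled from divergence by permuting them across pairs, so the
  ## only true signal is divergence time. AIC retains a null predictor
  ## with probability about 0.16 each, hence the frequency check.
  n_noise_kept <- integer(5L)
  for (s in 1:5) {
    cfg <- sim_config(n_species = 80L, n_crosses = 2000L, beta_c = 0,
                      seed = 23L + s, pair_weight_scale = 20)
    tree <- simulate_tree(cfg)
    traits <- simulate_traits(tree, cfg)
    ds <- simulate_crosses(tree, traits, cfg)
    built <- build_pair_features(ds, traits)
    feats <- built$features
    set.seed(1000L + s)
    noise_terms <- c("clutch_diff", "pc1", "pc2", "habitat_match")
    for (tm in noise_terms) feats[[tm]] <- sample(feats[[tm]])
    model <- fit_predictor_model(feats)
    expect_true("divergence_my" %in% model$selected_terms)
    n_noise_kept[s] <- sum(noise_terms %in% model$selected_terms)
    expect_gt(model$r2_mcfadden, 0)
    expect_equal(model$fit$aic, 2 * model$fit$k - 2 * model$fit$loglik)
  }
  ## expected noise retention about 0.16 * 4 per run
  expect_lte(mean(n_noise_kept), 1.5)
})
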