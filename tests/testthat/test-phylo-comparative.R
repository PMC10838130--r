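test_that("BM covariance matches its closed-form and the path oracle", {
  star <- ape::read.tree(text = "(a:7,b:7,c:7,d:7);")
  C_star <- bm_covariance(star)
  expect_equal(C_star, 7 * diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)

  cherry <- ape::read.tree(text = "((a:2,b:2):8,c:10);")
  C <- bm_covariance(cherry)
  expect_equal(C["a", "b"], 10 - 2)  # height H minus split time t
  expect_equal(C["a", "c"], 0)
  expect_equal(unname(diag(C)), rep(10, 3))

  cfg <- sim_config(n_species = 20L, seed = 37L)
  tree <- simulate_tree(cfg)
  C20 <- bm_covariance(tree)
  oracle <- oracle_shared_path(tree)
  expect_equal(C20[rownames(oracle), colnames(oracle)], oracle,
               tolerance = 1e-8)
  ## requested order is honoured
  sub <- rev(tree$tip.label[1:5])
  expect_identical(rownames(bm_covariance(tree, sub)), sub)
  expect_error(bm_covariance(tree, "nope"), "not in tree")
})

test_that("BM covariance is symmetric positive semidefinite on random trees", {
  for (s in 1:50) {
    cfg <- sim_config(n_species = sample(5:25, 1L), seed = s)
    C <- bm_covariance(simulate_tree(cfg))
    expect_lt(max(abs(C - t(C))), 1e-10)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    expect_true(all(C <= diag(C) + 1e-10))
  }
})

test_that("Blomberg's K matches picante and honours the add-one rule", {
  cfg <- sim_config(n_species = 16L, seed = 41L)
  tree <- simulate_tree(cfg)
  set.seed(1)
  x <- setNames(rnorm(16), tree$tip.label)
  res <- phylo_signal(x, tree, method = "blomberg_K", n_perm = 100L,
                      seed = 2L)
  expect_equal(res$estimate, picante::Kcalc(x[tree$tip.label], tree),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_gte(res$p_value, 1 / 101)
  expect_lte(res$p_value, 1)

  ## perfectly clade-structured values: no permutation reproduces the
  ## clade split, so p sits at the add-one lower bound
  tips_a <- paste0("(", paste0("a", 1:8, ":1", collapse = ","), "):9")
  tips_b <- paste0("(", paste0("b", 1:8, ":1", collapse = ","), "):9")
  two_clade <- ape::read.tree(text = paste0("(", tips_a, ",", tips_b, ");"))
  v <- setNames(c(rep(0, 8), rep(10, 8)) + 0.01 * (1:16),
                two_clade$tip.label)
  res2 <- phylo_signal(v, two_clade, method = "blomberg_K", n_perm = 200L,
                       seed = 3L)
  expect_equal(res2$p_value, 1 / 201)

  expect_error(phylo_signal(x, tree, method = "blomberg_K", n_perm = 50L),
               "at least 100")
  expect_error(phylo_signal(setNames(rep(1, 16), tree$tip.label), tree),
               "constant")
})

test_that("K averages about 1 for traits simulated under BM", {
  cfg <- sim_config(n_species = 30L, seed = 43L)
  tree <- simulate_tree(cfg)
  set.seed(44)
  ks <- vapply(1:60, function(i) {
    x <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    blomberg <- phylo_signal(x, tree, method = "blomberg_K",
                             n_perm = 100L, seed = i)
    blomberg$estimate
  }, numeric(1L))
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.2)
})

test_that("Pagel's lambda separates BM traits from tree-independent ones", {
  cfg <- sim_config(n_species = 40L, seed = 47L)
  tree <- simulate_tree(cfg)

  set.seed(48)
  x_bm <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  res_bm <- phylo_signal(x_bm, tree, method = "pagel_lambda")
  expect_gt(res_bm$estimate, 0.8)
  expect_lt(res_bm$p_value, 0.05)

  ## independent values: lambda near 0, LRT non-significant in >= 90% of
  ## seeds
  hits <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    x <- setNames(rnorm(40), tree$tip.label)
    res <- phylo_signal(x, tree, method = "pagel_lambda")
    res$p_value > 0.05 && res$estimate < 0.5
  }, logical(1L))
  expect_gte(mean(hits), 0.9)
})

test_that("lambda ML agrees with phytools on a fixed dataset", {
  cfg <- sim_config(n_species = 25L, seed = 53L)
  tree <- simulate_tree(cfg)
  set.seed(54)
  x <- ape::rTraitCont(tree, model = "BM", sigma = 1) +
    rnorm(25, sd = 2)
  res <- phylo_signal(x, tree, method = "pagel_lambda")
  ph <- phytools::phylosig(tree, x[tree$tip.label], method = "lambda")
  expect_equal(res$estimate, ph$lambda, tolerance = 1e-3)
  expect_equal(res$loglik, ph$logL, tolerance = 1e-4)
})

test_that("PGLS reduces to OLS under an identity covariance", {
  cfg <- sim_config(n_species = 20L, seed = 59L)
  tree <- simulate_tree(cfg)
  set.seed(60)
  y <- setNames(rnorm(20), tree$tip.label)
  x <- setNames(rnorm(20), tree$tip.label)
  res0 <- pgls_fit(y, x, tree, lambda_mode = "fixed_0")
  ols <- lm(y ~ x)
  expect_equal(unname(res0$coefficients), unname(coef(ols)),
               tolerance = 1e-8)
  f_ols <- summary(ols)$fstatistic
  expect_equal(res0$F_stat, unname(f_ols[1L]), tolerance = 1e-8)
  expect_equal(res0$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("PGLS equals whitened OLS and is scalar- and lambda-continuous", {
  cfg <- sim_config(n_species = 24L, seed = 61L)
  tree <- simulate_tree(cfg)
  set.seed(62)
  y <- setNames(ape::rTraitCont(tree, model = "BM", sigma = 1),
                tree$tip.label)
  x <- setNames(rnorm(24), tree$tip.label)
  res <- pgls_fit(y, x, tree, lambda_mode = "fixed_1")

  ## algebraic oracle: whiten by the inverse Cholesky factor, then OLS
  C <- bm_covariance(tree, names(y))
  W <- solve(t(chol(C)))
  yw <- drop(W %*% y)
  Xw <- W %*% cbind(1, unname(x))
  wfit <- lm(yw ~ Xw - 1)
  expect_equal(unname(res$coefficients), unname(coef(wfit)),
               tolerance = 1e-8)
  rss1 <- sum(residuals(wfit)^2)
  rss0 <- sum(residuals(lm(yw ~ Xw[, 1L] - 1))^2)
  F_oracle <- (rss0 - rss1) / (rss1 / (24 - 2))
  expect_equal(res$F_stat, F_oracle, tolerance = 1e-8)

  ## nlme cross-check of the coefficients under Brownian correlation
  dat <- data.frame(y = as.numeric(y), x = as.numeric(x),
                    sp = names(y))
  gfit <- nlme::gls(y ~ x, data = dat,
                    correlation = ape::corBrownian(1, tree, form = ~sp))
  expect_equal(unname(res$coefficients), unname(coef(gfit)),
               tolerance = 1e-6)

  ## multiplying V by a scalar cannot move the slope: compare against a
  ## tree with rescaled branch lengths
  tree2 <- tree
  tree2$edge.length <- tree2$edge.length * 3.7
  res2 <- pgls_fit(y, x, tree2, lambda_mode = "fixed_1")
  expect_equal(res2$coefficients, res$coefficients, tolerance = 1e-8)
  expect_equal(res2$F_stat, res$F_stat, tolerance = 1e-8)

  ## lambda -> 0 approaches the OLS coefficients along a grid
  ols_beta <- unname(coef(lm(y ~ x)))
  gaps <- vapply(c(0.5, 0.1, 0.01, 0.001), function(lam) {
    V <- bm_covariance(tree, names(y))
    V_l <- V * lam
    diag(V_l) <- diag(V)
    W <- solve(t(chol(V_l)))
    max(abs(unname(coef(lm(drop(W %*% y) ~ W %*% cbind(1, unname(x)) - 1)))
            - ols_beta))
  }, numeric(1L))
  expect_true(all(diff(gaps) < 0))

  ## ml mode lands within [0, 1] and never beats the profile likelihood
  res_ml <- pgls_fit(y, x, tree, lambda_mode = "ml")
  expect_gte(res_ml$lambda, 0)
  expect_lte(res_ml$lambda, 1)
})

test_that("PGLS rejects misaligned or missing species", {
  cfg <- sim_config(n_species = 10L, seed = 67L)
  tree <- simulate_tree(cfg)
  y <- setNames(rnorm(10), tree$tip.label)
  x <- setNames(rnorm(10), c(tree$tip.label[-1], "ghost"))
  expect_error(pgls_fit(y, x, tree), "misaligned")
  x2 <- setNames(rnorm(10), sub("sp1$", "ghost", tree$tip.label))
  y2 <- setNames(rnorm(10), names(x2))
  expect_error(pgls_fit(y2, x2, tree), "not in tree")
})
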