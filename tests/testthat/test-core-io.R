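test_that("cross tables parse, canonicalize pair order and collapse duplicates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "species_a,species_b,outcome,divergence_my,source",
    "Gallus gallus,Phasianus colchicus,male_only,31,ref1",
    "Pavo cristatus,Gallus gallus,sterile,34,ref2",
    "Gallus gallus,Pavo cristatus,Sterile,34,ref3"
  ), path)
  ds <- read_cross_table(path)
  expect_s3_class(ds, "cross_dataset")
  expect_equal(nrow(ds), 2L)  # reversed duplicate collapsed
  expect_lte(length(cross_species(ds)), 6L)
  ## alphabetical order within every pair
  expect_true(all(ds$species_a < ds$species_b))
  expect_setequal(ds$outcome, c("MALE_ONLY", "STERILE"))
})

test_that("cross table validation errors name the problem", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_a,species_b,divergence_my",
               "A a,B b,10"), path)
  expect_error(read_cross_table(path), "outcome")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_a,species_b,outcome,divergence_my",
               "A a,B b,mostly fertile,10"), path2)
  expect_error(read_cross_table(path2), "unknown outcome")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_a,species_b,outcome,divergence_my",
               "A a,B b,sterile,10",
               "B b,A a,both_fertile,10"), path3)
  expect_error(read_cross_table(path3), "conflicting outcome")

  expect_error(cross_dataset("A a", "A a", "sterile", 5), "species_a equals")
  expect_error(cross_dataset("A a", "B b", "sterile", -1), "positive")
})

test_that("species names collapse to Genus species", {
  expect_equal(normalize_species_name("gallus  gallus domesticus"),
               "Gallus gallus")
  expect_equal(normalize_species_name("CROSSOPTILON harmani"),
               "Crossoptilon harmani")
  expect_equal(normalize_species_name("sp12"), "sp12")
})

test_that("fertility outcomes score 1/2/3 from sterile to both fertile", {
  expect_identical(score_cross(c("STERILE", "MALE_ONLY", "BOTH_FERTILE")),
                   c(1L, 2L, 3L))
  expect_error(score_cross("FERTILE-ISH"), "outcome")
})

test_that("dataset summaries match direct arithmetic and brute-force recounts", {
  ds <- cross_dataset(c("A a", "C c"), c("B b", "D d"),
                      c("sterile", "both_fertile"), c(10, 20))
  s <- summarize_dataset(ds)
  expect_equal(s$n_pairs, 2L)
  expect_equal(s$mean_divergence, 15)
  expect_equal(s$n_species, 4L)

  ## brute-force recount on random synthetic datasets
  cfg <- sim_config(n_species = 20L, n_crosses = 40L, seed = 11L)
  tree <- simulate_tree(cfg)
  traits <- simulate_traits(tree, cfg)
  ds2 <- simulate_crosses(tree, traits, cfg)
  s2 <- summarize_dataset(ds2)
  expect_equal(s2$n_pairs, nrow(ds2))
  expect_equal(s2$n_species, length(unique(c(ds2$species_a, ds2$species_b))))
  expect_equal(s2$mean_partner_count,
               mean(table(c(ds2$species_a, ds2$species_b))))
  expect_equal(s2$divergence_interval[["upper"]],
               mean(ds2$divergence_my) + 1.96 * sd(ds2$divergence_my))
  for (cls in unique(ds2$outcome)) {
    sub <- ds2[ds2$outcome == cls, ]
    expect_equal(s2$max_divergence_by_outcome[[cls]]$divergence_my,
                 max(sub$divergence_my))
    expect_equal(s2$min_divergence_by_outcome[[cls]]$divergence_my,
                 min(sub$divergence_my))
  }
  expect_error(summarize_dataset(ds2[0, ]))
})

test_that("summaries are invariant to row order and within-pair order", {
  ds <- graded_crosses()
  perm <- sample(nrow(ds))
  ds2 <- cross_dataset(ds$species_b[perm], ds$species_a[perm],
                       ds$outcome[perm], ds$divergence_my[perm])
  expect_equal(summarize_dataset(ds2)[c("n_pairs", "n_species",
                                        "mean_divergence",
                                        "mean_partner_count")],
               summarize_dataset(ds)[c("n_pairs", "n_species",
                                       "mean_divergence",
                                       "mean_partner_count")])
})

test_that("cross tables round-trip through write and read", {
  ds <- graded_crosses()
  path <- withr::local_tempfile(fileext = ".csv")
  write_cross_table(ds, path)
  back <- read_cross_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ds))
})

test_that("reports serialize deterministically in both formats", {
  s <- summarize_dataset(toy_crosses())
  rec <- unclass(s)[c("n_pairs", "n_species", "mean_divergence",
                      "mean_partner_count")]
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_report(rec, p1)
  write_report(rec, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- jsonlite::read_json(p1, simplifyVector = TRUE)
  expect_equal(back$n_pairs, rec$n_pairs)
  expect_equal(back$mean_divergence, rec$mean_divergence,
               tolerance = 1e-5)

  fit <- fit_gaussian(c(1, 2, 3, 4.5, 6),
                      cbind("(Intercept)" = rep(1, 5),
                            x = c(1, 2, 3, 4, 5)))
  pt <- withr::local_tempfile(fileext = ".tsv")
  write_report(fit, pt, format = "tsv")
  tab <- read.delim(pt)
  expect_equal(nrow(tab), 2L)  # one coefficient per row
  expect_equal(tab$term, c("(Intercept)", "x"))
})

test_that("phylogeny validation enforces ultrametricity and unique labels", {
  expect_silent(validate_phylogeny(balanced_tree()))
  ragged <- ape::read.tree(text = "((a:5,b:3):5,(c:5,d:5):5);")
  expect_error(validate_phylogeny(ragged), "ultrametric")
  dup <- ape::read.tree(text = "((a:5,a:5):5,(c:5,d:5):5);")
  expect_error(validate_phylogeny(dup), "duplicate tip")
})
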