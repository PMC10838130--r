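## Fixtures built in code: tiny cross datasets, trees and trait tables.

toy_crosses <- function() {
  cross_dataset(
    species_a = c("Gallus gallus", "Gallus gallus", "Pavo cristatus",
                  "Meleagris gallopavo", "Numida meleagris",
                  "Phasianus colchicus"),
    species_b = c("Phasianus colchicus", "Pavo cristatus",
                  "Meleagris gallopavo", "Numida meleagris",
                  "Gallus gallus", "Pavo cristatus"),
    outcome = c("MALE_ONLY", "STERILE", "STERILE", "STERILE",
                "STERILE", "MALE_ONLY"),
    divergence_my = c(31, 34, 38, 41, 51, 33)
  )
}

## crosses spanning all outcome classes with overlapping divergence ranges
## (no class is linearly separable from the others in divergence time)
graded_crosses <- function() {
  cross_dataset(
    species_a = paste0("g", 1:12, " a"),
    species_b = paste0("h", 1:12, " b"),
    outcome = rep(c("BOTH_FERTILE", "MALE_ONLY", "STERILE"), each = 4L),
    divergence_my = c(1, 2, 3, 11, 4, 9, 14, 22, 6, 18, 30, 45)
  )
}

balanced_tree <- function() {
  ape::read.tree(text = "((a:5,b:5):5,(c:5,d:5):5);")
}

make_traits <- function(species, clutch = NULL, habitat = NULL,
                        seed = 1L) {
  set.seed(seed)
  n <- length(species)
  morph <- matrix(rnorm(n * length(galliso:::MORPH_VARS), mean = 50,
                        sd = 10),
                  nrow = n,
                  dimnames = list(NULL, galliso:::MORPH_VARS))
  out <- data.frame(species = species,
                    habitat = habitat %||% rep("forest", n),
                    morph,
                    clutch_size = clutch %||% runif(n, 4, 12),
                    check.names = FALSE, stringsAsFactors = FALSE)
  out$complete <- TRUE
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
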