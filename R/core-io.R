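## core_io: domain types, scoring conventions and delimited-text readers for
## cross tables, trait tables, Newick trees and result reports.

#' Normalize a species name to "Genus species"
#'
#' Collapses whitespace, drops subspecies epithets (any token beyond the
#' second) and standardizes capitalization (genus capitalized, epithet lower
#' case), so that records referring to subspecies collapse to the species
#' level.
#'
#' @param x character vector of species names.
#' @return character vector of normalized binomials.
#' @examples
#' normalize_species_name("gallus  gallus domesticus")
#' @export
normalize_species_name <- function(x) {
  x <- trimws(gsub("[_[:space:]]+", " ", as.character(x)))
  vapply(strsplit(x, " ", fixed = TRUE), function(tok) {
    if (length(tok) == 0L || !nzchar(tok[1L])) {
      stop("empty species name", call. = FALSE)
    }
    tok <- tok[seq_len(min(2L, length(tok)))]
    if (length(tok) == 2L) {
      tok[1L] <- paste0(toupper(substr(tok[1L], 1L, 1L)),
                        tolower(substr(tok[1L], 2L, nchar(tok[1L]))))
      tok[2L] <- tolower(tok[2L])
    }
    paste(tok, collapse = " ")
  }, character(1L))
}

#' Default synonym map for fertility outcome labels
#'
#' Maps lower-case outcome spellings found in source tables onto the three
#' canonical categories `STERILE`, `MALE_ONLY` and `BOTH_FERTILE`.
#'
#' @return named character vector; names are lower-case labels, values are
#'   canonical categories.
#' @export
default_outcome_map <- function() {
  c(
    "sterile" = "STERILE",
    "all sterile" = "STERILE",
    "all offspring sterile" = "STERILE",
    "both sexes sterile" = "STERILE",
    "male_only" = "MALE_ONLY",
    "male only" = "MALE_ONLY",
    "males only" = "MALE_ONLY",
    "only males fertile" = "MALE_ONLY",
    "only male offspring fertile" = "MALE_ONLY",
    "both_fertile" = "BOTH_FERTILE",
    "both fertile" = "BOTH_FERTILE",
    "both sexes fertile" = "BOTH_FERTILE",
    "fertile" = "BOTH_FERTILE"
  )
}

normalize_outcome <- function(x, outcome_map = default_outcome_map()) {
  key <- tolower(trimws(gsub("[_[:space:]]+", " ", as.character(x))))
  key2 <- gsub(" ", "_", key)
  out <- ifelse(toupper(key2) %in% OUTCOME_LEVELS, toupper(key2),
                unname(outcome_map[key]))
  miss <- is.na(out)
  if (any(miss)) {
    stop("unknown outcome label(s) in row(s) ",
         paste(which(miss), collapse = ", "), ": ",
         paste(unique(x[miss]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Construct a validated cross dataset
#'
#' A cross dataset holds one row per hybridizing species pair with its F1
#' fertility outcome and divergence time. Pairs are unordered: the two
#' species are stored in alphabetical order and duplicate listings of the
#' same pair are collapsed (conflicting outcomes are an error).
#'
#' @param species_a,species_b character vectors of species names.
#' @param outcome character vector of canonical outcome categories or labels
#'   recognised by `outcome_map`.
#' @param divergence_my positive numeric divergence times, million years.
#' @param source optional character vector of free-text provenance notes.
#' @param outcome_map label synonym map, see [default_outcome_map()].
#' @return a `data.frame` of class `cross_dataset` with columns `species_a`,
#'   `species_b`, `outcome`, `divergence_my`, `source` and an attribute
#'   `species` (sorted unique species names).
#' @export
cross_dataset <- function(species_a, species_b, outcome, divergence_my,
                          source = NA_character_,
                          outcome_map = default_outcome_map()) {
  species_a <- normalize_species_name(species_a)
  species_b <- normalize_species_name(species_b)
  outcome <- normalize_outcome(outcome, outcome_map)
  divergence_my <- as.numeric(divergence_my)
  n <- length(species_a)
  stopifnot(length(species_b) == n, length(outcome) == n,
            length(divergence_my) == n)
  source <- rep_len(as.character(source), n)
  if (any(!is.finite(divergence_my) | divergence_my <= 0)) {
    stop("divergence_my must be positive and finite (rows ",
         paste(which(!is.finite(divergence_my) | divergence_my <= 0),
               collapse = ", "), ")", call. = FALSE)
  }
  if (any(species_a == species_b)) {
    stop("species_a equals species_b in row(s) ",
         paste(which(species_a == species_b), collapse = ", "),
         call. = FALSE)
  }
  ## canonical unordered pair: alphabetical order within the pair
  swap <- species_a > species_b
  tmp <- species_a[swap]
  species_a[swap] <- species_b[swap]
  species_b[swap] <- tmp
  ds <- data.frame(species_a = species_a, species_b = species_b,
                   outcome = outcome, divergence_my = divergence_my,
                   source = source, stringsAsFactors = FALSE)
  key <- paste(ds$species_a, ds$species_b, sep = " x ")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- ds[key == k, ]
      if (length(unique(rows$outcome)) > 1L) {
        stop("duplicate pair ", k, " listed with conflicting outcomes: ",
             paste(unique(rows$outcome), collapse = " vs "), call. = FALSE)
      }
    }
    ds <- ds[!duplicated(key), , drop = FALSE]
    rownames(ds) <- NULL
  }
  ds <- ds[order(ds$species_a, ds$species_b), , drop = FALSE]
  rownames(ds) <- NULL
  attr(ds, "species") <- sort(unique(c(ds$species_a, ds$species_b)))
  class(ds) <- c("cross_dataset", "data.frame")
  ds
}

#' Species involved in a cross dataset
#' @param ds a `cross_dataset`.
#' @return sorted character vector of unique species names.
#' @export
cross_species <- function(ds) {
  sort(unique(c(ds$species_a, ds$species_b)))
}

#' Read a cross table from delimited text
#'
#' Expects a header row naming the columns `species_a`, `species_b`,
#' `outcome` and `divergence_my` (`source` optional); the delimiter (tab or
#' comma) is auto-detected from the header unless given.
#'
#' @param path file path.
#' @param sep field delimiter; `NULL` to auto-detect.
#' @param outcome_map label synonym map, see [default_outcome_map()].
#' @return a validated [cross_dataset()].
#' @export
read_cross_table <- function(path, sep = NULL,
                             outcome_map = default_outcome_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = TRUE)
  needed <- c("species_a", "species_b", "outcome", "divergence_my")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("cross table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  src <- if ("source" %in% names(raw)) raw$source else NA_character_
  cross_dataset(raw$species_a, raw$species_b, raw$outcome,
                raw$divergence_my, src, outcome_map = outcome_map)
}

#' Write a cross dataset as delimited text
#' @param ds a `cross_dataset`.
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_cross_table <- function(ds, path, sep = ",") {
  write.table(as.data.frame(ds), path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Ordinal reproductive-isolation score of a fertility outcome
#'
#' Scores a cross 1 if all offspring were sterile, 2 if only male offspring
#' were fertile (the Haldane's Rule stage in a ZW system), and 3 if
#' offspring of both sexes were fertile.
#'
#' @param outcome character vector of canonical outcome categories.
#' @return integer vector of scores in \{1, 2, 3\}.
#' @export
score_cross <- function(outcome) {
  if (!all(outcome %in% OUTCOME_LEVELS)) {
    stop("outcome must be one of ", paste(OUTCOME_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  match(outcome, OUTCOME_LEVELS)
}

#' Summarize a cross dataset
#'
#' Reports pair and species counts, divergence-time statistics with a
#' dispersion interval (mean plus/minus 1.96 standard deviations),
#' per-species hybridization partner counts, and the most and least
#' diverged record within each outcome class.
#'
#' @param ds a non-empty `cross_dataset`.
#' @return a list of class `cross_summary`.
#' @export
summarize_dataset <- function(ds) {
  if (!inherits(ds, "cross_dataset")) stop("ds must be a cross_dataset")
  if (nrow(ds) == 0L) stop("empty cross dataset", call. = FALSE)
  div <- ds$divergence_my
  partners <- table(c(ds$species_a, ds$species_b))
  extreme <- function(cls, which_fun) {
    sub <- ds[ds$outcome == cls, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    as.list(sub[which_fun(sub$divergence_my), c("species_a", "species_b",
                                                "divergence_my")])
  }
  sdv <- if (length(div) > 1L) sd(div) else 0
  out <- list(
    n_pairs = nrow(ds),
    n_species = length(cross_species(ds)),
    mean_divergence = mean(div),
    sd_divergence = sdv,
    min_divergence = min(div),
    max_divergence = max(div),
    divergence_interval = c(lower = mean(div) - 1.96 * sdv,
                            upper = mean(div) + 1.96 * sdv),
    partner_counts = setNames(as.integer(partners), names(partners)),
    mean_partner_count = mean(as.integer(partners)),
    max_divergence_by_outcome = setNames(
      lapply(OUTCOME_LEVELS, extreme, which_fun = which.max), OUTCOME_LEVELS),
    min_divergence_by_outcome = setNames(
      lapply(OUTCOME_LEVELS, extreme, which_fun = which.min), OUTCOME_LEVELS)
  )
  class(out) <- "cross_summary"
  out
}

#' @export
print.cross_summary <- function(x, ...) {
  cat(sprintf("Cross dataset: %d pairs involving %d species\n",
              x$n_pairs, x$n_species))
  cat(sprintf("Divergence (MY): mean %.3g (interval %.3g to %.3g), range %.3g-%.3g\n",
              x$mean_divergence, x$divergence_interval[["lower"]],
              x$divergence_interval[["upper"]], x$min_divergence,
              x$max_divergence))
  cat(sprintf("Mean hybridization partners per species: %.3g\n",
              x$mean_partner_count))
  for (cls in OUTCOME_LEVELS) {
    rec <- x$max_divergence_by_outcome[[cls]]
    if (!is.null(rec)) {
      cat(sprintf("  most diverged %s: %s x %s at %.4g MY\n", cls,
                  rec$species_a, rec$species_b, rec$divergence_my))
    }
  }
  invisible(x)
}

#' Read a species trait table
#'
#' Delimited text with columns `species`, `habitat`, the 11 morphological
#' measurements (`beak_length_culmen`, `beak_length_nares`, `beak_width`,
#' `beak_depth`, `tarsus_length`, `wing_length`, `kipps_distance`,
#' `secondary1`, `hand_wing_index`, `tail_length`, `mass`) and
#' `clutch_size`. Species with any missing morphology value or non-positive
#' clutch size are flagged `complete = FALSE` rather than dropped.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to auto-detect.
#' @return data.frame with a logical `complete` column appended.
#' @export
read_trait_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  tr <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                   stringsAsFactors = FALSE, comment.char = "")
  needed <- c("species", "habitat", MORPH_VARS, "clutch_size")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols)) {
    stop("trait table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tr$species <- normalize_species_name(tr$species)
  if (anyDuplicated(tr$species)) {
    stop("duplicate species in trait table: ",
         paste(unique(tr$species[duplicated(tr$species)]), collapse = ", "),
         call. = FALSE)
  }
  morph_ok <- rowSums(is.na(as.matrix(tr[MORPH_VARS]))) == 0L
  clutch_ok <- !is.na(tr$clutch_size) & tr$clutch_size > 0
  tr$complete <- morph_ok & clutch_ok
  tr
}

#' Write a species trait table
#' @param traits trait data.frame as returned by [read_trait_table()].
#' @param path file path.
#' @param sep field delimiter.
#' @export
write_trait_table <- function(traits, path, sep = ",") {
  keep <- c("species", "habitat", MORPH_VARS, "clutch_size")
  write.table(traits[keep], path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate an ultrametric phylogeny
#'
#' Wraps [ape::read.tree()] and checks tip-label uniqueness and
#' ultrametricity (all root-to-tip path lengths equal to within
#' `tol * height`).
#'
#' @param path Newick file path.
#' @param tol relative ultrametricity tolerance.
#' @return an [ape::phylo] object with attribute `height`.
#' @export
read_phylogeny <- function(path, tol = 1e-6) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick tree from ", path)
  validate_phylogeny(tree, tol = tol)
}

#' Validate an ultrametric phylogeny object
#' @param tree an [ape::phylo] object with branch lengths.
#' @param tol relative ultrametricity tolerance.
#' @return the tree, invisibly annotated with its height.
#' @export
validate_phylogeny <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  height <- max(depths)
  if (max(depths) - min(depths) > tol * height) {
    stop("tree is not ultrametric: root-to-tip spread ",
         format(max(depths) - min(depths)), " exceeds tolerance",
         call. = FALSE)
  }
  attr(tree, "height") <- height
  tree
}

signif_rapply <- function(x, digits = 6L) {
  if (is.list(x)) {
    lapply(x, signif_rapply, digits = digits)
  } else if (is.double(x)) {
    signif(x, digits)
  } else {
    x
  }
}

#' Write a stage result as TSV or JSON
#'
#' Serialization is deterministic: field order follows the object, floats
#' are written at 6 significant digits, and writing the same object twice
#' produces byte-identical files.
#'
#' @param results a model fit, data.frame or list of (lists of) scalars.
#' @param path output file path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "tsv") {
    df <- if (inherits(results, "model_fit")) {
      data.frame(term = names(results$coefficients),
                 estimate = signif(unname(results$coefficients), 6L),
                 stringsAsFactors = FALSE)
    } else if (is.data.frame(results)) {
      as.data.frame(signif_rapply(as.list(results)),
                    stringsAsFactors = FALSE, check.names = FALSE)
    } else {
      stop("cannot write ", class(results)[1L], " as TSV", call. = FALSE)
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = TRUE, eol = "\n")
  } else {
    x <- results
    if (inherits(x, "model_fit")) x <- unclass(x)
    if (is.data.frame(x)) x <- as.list(x)
    x <- signif_rapply(x)
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                             null = "null", na = "null", pretty = TRUE)
    writeLines(json, path, useBytes = TRUE)
  }
  invisible(path)
}
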