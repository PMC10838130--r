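## domestication_text: corpus-based domestication index. Occurrences of
## species-name variants are counted across a plain-text document
## collection with longest-match overlap resolution (so "ocellated turkey"
## is never also counted as "turkey"), then min-max rescaled to [0, 1].

#' Read a species-name lexicon
#'
#' Delimited text with columns `species` and `variant`. Every variant must
#' map to exactly one species; ambiguous variants are a load-time error.
#' Exact duplicate rows are collapsed with a warning.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to auto-detect.
#' @return data.frame of class `name_lexicon` with columns `species`,
#'   `variant`.
#' @export
read_lexicon <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  lex <- read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "")
  missing_cols <- setdiff(c("species", "variant"), names(lex))
  if (length(missing_cols)) {
    stop("lexicon ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  name_lexicon(lex$species, lex$variant)
}

#' Construct a validated name lexicon
#' @param species character vector of species names.
#' @param variant character vector of name variants (scientific or common).
#' @return data.frame of class `name_lexicon`.
#' @export
name_lexicon <- function(species, variant) {
  lex <- data.frame(species = as.character(species),
                    variant = normalize_scan_text(variant),
                    stringsAsFactors = FALSE)
  if (any(!nzchar(lex$variant))) stop("empty name variant", call. = FALSE)
  lex <- lex[!duplicated(lex[c("species", "variant")]), , drop = FALSE]
  dup <- unique(lex$variant[duplicated(lex$variant)])
  if (length(dup)) {
    stop("ambiguous variant(s) mapping to multiple species: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(lex) <- NULL
  class(lex) <- c("name_lexicon", "data.frame")
  lex
}

#' Write a lexicon as delimited text
#' @param lexicon a `name_lexicon`.
#' @param path file path.
#' @export
write_lexicon <- function(lexicon, path) {
  write.table(as.data.frame(lexicon), path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

## Lower-case the text, rejoin words wrapped across lines with a trailing
## hyphen ("tur-\nkey" -> "turkey"), and collapse inline hyphens and runs
## of whitespace to single spaces, so names hyphenated or wrapped in
## historical OCR text still match their lexicon variant.
normalize_scan_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("-[[:blank:]]*\n[[:blank:]]*", "", x)
  x <- gsub("[-[:space:]]+", " ", x)
  trimws(x)
}

## Longest-match scan of one normalized document. Variants are tried in
## order of token count, then character length (descending), ties broken
## lexicographically; matched spans are consumed so shorter variants never
## recount text claimed by a longer one. Word boundaries are letter /
## non-letter transitions.
scan_document <- function(text, lexicon) {
  counts <- setNames(integer(length(unique(lexicon$species))),
                     unique(lexicon$species))
  ntok <- lengths(strsplit(lexicon$variant, " ", fixed = TRUE))
  ord <- order(-ntok, -nchar(lexicon$variant), lexicon$variant)
  for (i in ord) {
    v <- lexicon$variant[i]
    pat <- paste0("(?<![a-z])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", v),
                  "(?![a-z])")
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    counts[lexicon$species[i]] <- counts[lexicon$species[i]] + length(m)
    ## consume matched spans: overwrite with a non-letter filler
    for (j in seq_along(m)) {
      len <- attr(m, "match.length")[j]
      substr(text, m[j], m[j] + len - 1L) <- strrep("\001", len)
    }
  }
  counts
}

#' Count species-name occurrences in a corpus
#'
#' Scans every `.txt` file in `corpus_dir` for occurrences of all lexicon
#' variants, case-insensitively on word boundaries, resolving overlapping
#' variants longest-first (text consumed by a longer variant is not
#' recounted for a shorter one), and sums counts over documents.
#'
#' @param corpus_dir directory of plain-text documents.
#' @param lexicon a `name_lexicon`.
#' @return named integer vector of raw occurrence counts per species.
#' @export
count_occurrences <- function(corpus_dir, lexicon) {
  stopifnot(inherits(lexicon, "name_lexicon"))
  if (nrow(lexicon) == 0L) stop("empty lexicon", call. = FALSE)
  files <- sort(list.files(corpus_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no readable .txt documents in ", corpus_dir, call. = FALSE)
  }
  counts <- setNames(integer(length(unique(lexicon$species))),
                     unique(lexicon$species))
  for (f in files) {
    text <- tryCatch(
      paste(readLines(f, warn = FALSE), collapse = "\n"),
      error = function(e) stop("cannot read corpus file ", f, ": ",
                               conditionMessage(e), call. = FALSE))
    doc_counts <- scan_document(normalize_scan_text(text), lexicon)
    counts <- counts + doc_counts[names(counts)]
  }
  counts
}

#' Rescale raw occurrence counts to a domestication index
#'
#' Min-max rescales raw counts to [0, 1] (the least-mentioned species maps
#' to 0 and the most-mentioned to 1), or divides by the maximum when
#' `method = "maxdiv"`. Overrides (e.g. forcing the chicken to 1) are
#' applied after scaling and clamped to [0, 1].
#'
#' @param raw_counts named integer vector of per-species counts.
#' @param override optional named numeric vector of post-scaling overrides.
#' @param method `"minmax"` (default) or `"maxdiv"`.
#' @return data.frame with columns `species`, `raw_count`, `scaled`.
#' @export
scale_index <- function(raw_counts, override = NULL,
                        method = c("minmax", "maxdiv")) {
  method <- match.arg(method)
  if (length(raw_counts) < 2L) stop("need at least 2 species", call. = FALSE)
  rng <- range(raw_counts)
  if (rng[1L] == rng[2L]) {
    stop("degenerate scaling: all counts equal", call. = FALSE)
  }
  scaled <- switch(method,
                   minmax = (raw_counts - rng[1L]) / (rng[2L] - rng[1L]),
                   maxdiv = raw_counts / rng[2L])
  if (!is.null(override)) {
    bad <- setdiff(names(override), names(raw_counts))
    if (length(bad)) {
      stop("override names not in the species set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    scaled[names(override)] <- pmin(1, pmax(0, override))
  }
  data.frame(species = names(raw_counts),
             raw_count = as.integer(raw_counts),
             scaled = unname(scaled), stringsAsFactors = FALSE)
}
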