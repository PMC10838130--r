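## Independent oracles used to validate the package's implementations.
## Each is deliberately naive (enumeration, grids, closed forms) and never
## shares code with the path it checks.

## Logistic MLE by nested grid refinement over the coefficient space.
oracle_logistic_grid <- function(y, X, lo = -10, hi = 10, n_grid = 25L,
                                 refinements = 40L) {
  p <- ncol(X)
  stopifnot(p == 2L)
  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta)))
  }
  lo <- rep(lo, p); hi <- rep(hi, p)
  for (r in seq_len(refinements)) {
    g1 <- seq(lo[1L], hi[1L], length.out = n_grid)
    g2 <- seq(lo[2L], hi[2L], length.out = n_grid)
    ll <- outer(g1, g2, Vectorize(function(a, b) loglik(c(a, b))))
    best <- which(ll == max(ll), arr.ind = TRUE)[1L, ]
    step1 <- g1[2L] - g1[1L]; step2 <- g2[2L] - g2[1L]
    ## keep a generous window around the best lattice point so the search
    ## can drift along the intercept/slope likelihood ridge
    lo <- c(g1[best[1L]] - 4 * step1, g2[best[2L]] - 4 * step2)
    hi <- c(g1[best[1L]] + 4 * step1, g2[best[2L]] + 4 * step2)
  }
  c(g1[best[1L]], g2[best[2L]])
}

## Pairwise divergence times by explicit root-to-tip path enumeration.
oracle_divergence_times <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))
  len_to_parent <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  len_to_parent[tree$edge[, 2L]] <- tree$edge.length
  path_to_root <- function(node) {
    path <- node
    while (node != root) {
      node <- parent_of[node]
      path <- c(path, node)
    }
    path
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + len_to_parent[node]
      node <- parent_of[node]
    }
    d
  }
  height <- max(vapply(seq_len(n_tip), depth, numeric(1L)))
  out <- matrix(0, n_tip, n_tip,
                dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n_tip - 1L)) {
    pi <- path_to_root(i)
    for (j in seq(i + 1L, n_tip)) {
      pj <- path_to_root(j)
      mrca <- pi[pi %in% pj][1L]
      out[i, j] <- out[j, i] <- height - depth(mrca)
    }
  }
  out
}

## Shared root-to-MRCA path length per tip pair (BM covariance oracle).
oracle_shared_path <- function(tree) {
  div <- oracle_divergence_times(tree)
  n_tip <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)[seq_len(n_tip)]
  height <- max(depths)
  C <- height - div
  diag(C) <- depths
  C
}

## Exhaustive two-sided permutation p-value for drawing n_focal residuals
## from a pool without replacement (all combinations enumerated).
oracle_perm_p_exact <- function(pool, n_focal, observed) {
  draws <- combn(pool, n_focal)
  means <- colMeans(matrix(draws, nrow = n_focal))
  mean(abs(means) >= abs(observed) - 1e-12)
}

## Brute-force longest-match occurrence counts: enumerate every variant
## occurrence position, then resolve overlaps by (token count, length,
## lexicographic) priority.
oracle_count <- function(text, lexicon) {
  norm <- function(x) {
    x <- tolower(x)
    x <- gsub("-[[:blank:]]*\n[[:blank:]]*", "", x)
    trimws(gsub("[-[:space:]]+", " ", x))
  }
  text <- norm(text)
  hits <- list()
  for (i in seq_len(nrow(lexicon))) {
    v <- norm(lexicon$variant[i])
    pat <- paste0("(?<![a-z])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", v),
                  "(?![a-z])")
    m <- gregexpr(pat, text, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (j in seq_along(m)) {
      hits[[length(hits) + 1L]] <- list(
        species = lexicon$species[i], variant = v,
        start = m[j], end = m[j] + attr(m, "match.length")[j] - 1L,
        ntok = length(strsplit(v, " ", fixed = TRUE)[[1L]]))
    }
  }
  counts <- setNames(integer(length(unique(lexicon$species))),
                     unique(lexicon$species))
  if (!length(hits)) return(counts)
  ord <- order(-vapply(hits, `[[`, integer(1L), "ntok"),
               -vapply(hits, function(h) nchar(h$variant), integer(1L)),
               vapply(hits, `[[`, character(1L), "variant"))
  taken <- rep(FALSE, nchar(text))
  for (h in hits[ord]) {
    span <- seq(h$start, h$end)
    if (!any(taken[span])) {
      counts[h$species] <- counts[h$species] + 1L
      taken[span] <- TRUE
    }
  }
  counts
}
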