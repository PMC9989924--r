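#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields `term`, `description`,
#' then member gene ids. Duplicate members within a set are dropped (with a
#' message); duplicate term ids are an error.
#'
#' @param path Path to the GMT file.
#' @return A `gene_set_collection`: list with `sets` (named list of character
#'   vectors), `descriptions` (named character), `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  descriptions <- character()
  n_dups <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    term <- fields[1]
    if (term %in% names(sets)) stop("duplicate term id in GMT: ", term)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    uniq <- unique(members)
    n_dups <- n_dups + (length(members) - length(uniq))
    if (!length(uniq)) stop("GMT line ", i, " (", term, ") has no members")
    sets[[term]] <- uniq
    descriptions[term] <- fields[2]
  }
  if (n_dups > 0) {
    message("read_gmt: dropped ", n_dups, " duplicate member(s) within sets")
  }
  structure(list(sets = sets, descriptions = descriptions,
                 source = basename(path)),
            class = "gene_set_collection")
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): drawing `n` genes from a
#' background of `N` of which `K` belong to the set, the probability of an
#' overlap at least `k`.
#'
#' @param k Observed overlap.
#' @param K Set size within the background.
#' @param n Query size within the background.
#' @param N Background size.
#' @return The tail probability in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      stop("k, K, n, N must be single nonnegative integers")
    }
  }
  if (K > N || n > N || k > min(K, n)) {
    stop(sprintf("inconsistent counts: k=%d, K=%d, n=%d, N=%d", k, K, n, N))
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' The step-up rule: with p-values sorted ascending, `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  m <- length(p_values)
  if (m == 0) stop("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  ord <- order(p_values)
  q_sorted <- pmin(1, rev(cummin(rev(p_values[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Over-representation test of a query gene list
#'
#' Hypergeometric enrichment of `query` against every set in `collection`,
#' with all sets and the query first intersected with `background` (the genes
#' the upstream screen actually tested). Results with overlap below
#' `min_overlap` are dropped; the rest are BH-adjusted and sorted by ascending
#' p with ties broken by term id.
#'
#' @param query Character vector of gene ids (e.g. a correlated gene set).
#' @param background Character vector: the tested gene universe.
#' @param collection A `gene_set_collection` from [read_gmt()].
#' @param min_overlap Minimum overlap k to report a set (default 2).
#' @return Data frame with columns `term`, `description`, `k`, `K`, `n`, `N`,
#'   `p`, `q`. Note `q` is adjusted across the reported sets.
#' @export
enrich <- function(query, background, collection, min_overlap = 2) {
  stopifnot(inherits(collection, "gene_set_collection"))
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  query <- intersect(query, background)
  if (!length(query)) stop("query is empty after intersecting with background")
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(collection$sets), function(term) {
    members <- intersect(collection$sets[[term]], background)
    K <- length(members)
    k <- length(intersect(members, query))
    if (k < min_overlap) return(NULL)
    data.frame(term = term,
               description = unname(collection$descriptions[term]),
               k = k, K = K, n = n, N = N,
               p = hypergeometric_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), description = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
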