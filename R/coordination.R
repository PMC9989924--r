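#' Pearson correlation of two vectors
#'
#' Plain sample Pearson correlation with the preconditions the rest of the
#' package relies on made explicit: equal length, at least 3 points, neither
#' vector constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 3) stop("need at least 3 points, got ", length(x))
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input vector")
  }
  r <- stats::cor(x, y)
  # guard against |r| creeping past 1 by rounding
  max(-1, min(1, r))
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact small-sample null distribution: under H0 (bivariate
#' normality, rho = 0), `t = r * sqrt((n - 2) / (1 - r^2))` follows a t
#' distribution with `n - 2` degrees of freedom.
#'
#' @param r Correlation, `|r| <= 1`.
#' @param n Number of paired observations, `n >= 3`.
#' @return Two-sided p-value; exactly 0 only when `|r| = 1`.
#' @export
pearson_pvalue <- function(r, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    stop("n must be a single integer >= 3")
  }
  if (any(abs(r) > 1 + 1e-12)) stop("|r| must be <= 1")
  r <- pmax(-1, pmin(1, r))
  p <- ifelse(abs(r) == 1, 0, {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  })
  pmin(p, 1)
}

#' Critical |r| for a given significance level
#'
#' Inverts [pearson_pvalue()]: returns the magnitude of correlation at which
#' the two-sided p-value equals `alpha` for sample size `n`. Monotone
#' decreasing in `n`.
#'
#' @param n Sample size, >= 3.
#' @param alpha Two-sided significance level in (0, 1).
#' @return The threshold `|r|`.
#' @export
critical_r <- function(n, alpha = 0.05) {
  if (!is.numeric(n) || length(n) != 1 || n < 3) {
    stop("n must be a single integer >= 3")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be in (0, 1)")
  }
  tcrit <- stats::qt(alpha / 2, df = n - 2, lower.tail = FALSE)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Whole-transcriptome correlation profile of one gene
#'
#' For a gene g, the vector of Pearson correlations between g's expression and
#' every gene in the matrix (including g itself, whose entry is exactly 1),
#' computed across samples. The matrix must be variance-filtered first.
#'
#' @param matrix A variance-filtered [expression_matrix].
#' @param gene Gene identifier present in the matrix.
#' @return A `correlation_profile`: list with `gene`, `r_values` (named, one
#'   per gene in matrix order), `n_samples`.
#' @export
correlation_profile <- function(matrix, gene) {
  stopifnot(inherits(matrix, "expression_matrix"))
  idx <- match(gene, matrix$gene_ids)
  if (is.na(idx)) stop("gene not found in matrix: ", gene)
  r <- as.vector(stats::cor(matrix$values[idx, ], t(matrix$values)))
  r <- pmax(-1, pmin(1, r))
  r[idx] <- 1
  names(r) <- matrix$gene_ids
  structure(list(gene = gene, r_values = r, n_samples = matrix$n_samples),
            class = "correlation_profile")
}

# Pearson correlation of profile rows a and b of a precomputed gene-gene
# correlation matrix, excluding the columns at positions `excl` (the two
# genes' own entries, which are identically 1 by construction).
profile_cor <- function(cmat, a, b, excl) {
  x <- cmat[a, -excl]
  y <- cmat[b, -excl]
  stats::cor(x, y)
}

#' Coordination between two genes
#'
#' The coordination statistic: the Pearson correlation between the two genes'
#' whole-transcriptome correlation profiles, after removing both genes' own
#' entries (which are fixed at 1 by construction and would inflate the
#' statistic). High coordination means the two genes relate to the rest of the
#' transcriptome in the same way across individuals.
#'
#' @param profile_a,profile_b `correlation_profile` objects computed from the
#'   same matrix (identical gene order).
#' @return A `coordination_result`: list with `gene_a`, `gene_b`,
#'   `coordination_r`, `n_points`, `p_analytic`, and `NULL` placeholders for
#'   the permutation fields (see [permutation_pvalue()]).
#' @export
coordination <- function(profile_a, profile_b) {
  stopifnot(inherits(profile_a, "correlation_profile"),
            inherits(profile_b, "correlation_profile"))
  ids_a <- names(profile_a$r_values)
  ids_b <- names(profile_b$r_values)
  if (length(ids_a) != length(ids_b) || !all(ids_a == ids_b)) {
    stop("profiles come from different matrices (gene order mismatch)")
  }
  excl <- match(c(profile_a$gene, profile_b$gene), ids_a)
  excl <- unique(excl[!is.na(excl)])
  x <- profile_a$r_values[-excl]
  y <- profile_b$r_values[-excl]
  r <- max(-1, min(1, stats::cor(x, y)))
  n_points <- length(x)
  structure(
    list(gene_a = profile_a$gene, gene_b = profile_b$gene,
         coordination_r = r, n_points = n_points,
         p_analytic = pearson_pvalue(r, n_points),
         p_permutation = NULL, n_permutations = NULL, seed = NULL),
    class = "coordination_result")
}

#' @export
print.coordination_result <- function(x, ...) {
  cat(sprintf("coordination(%s, %s): r = %.4f over %d profile points, p = %.3g\n",
              x$gene_a, x$gene_b, x$coordination_r, x$n_points, x$p_analytic))
  if (!is.null(x$p_permutation)) {
    cat(sprintf("  permutation p = %.4g (B = %d, seed = %d)\n",
                x$p_permutation, x$n_permutations, x$seed))
  }
  invisible(x)
}

#' Permutation p-value for a coordination statistic
#'
#' Null model: gene A's expression values are shuffled across samples
#' (severing A's relationship to the transcriptome while preserving all other
#' structure), A's profile is recomputed, and its coordination with gene B's
#' fixed profile re-evaluated. The p-value uses the add-one estimator
#' `(1 + #(|null| >= |observed|)) / (B + 1)`.
#'
#' @param matrix A variance-filtered [expression_matrix].
#' @param gene_a,gene_b Gene identifiers; `gene_a` is the permuted one.
#' @param n_permutations Number of permutations B, >= 99.
#' @param seed Integer seed; the result is reproducible given it.
#' @return A `coordination_result` with `p_permutation`, `n_permutations` and
#'   `seed` filled in.
#' @export
permutation_pvalue <- function(matrix, gene_a, gene_b,
                               n_permutations = 999, seed) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (missing(seed)) stop("seed is mandatory")
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  ia <- match(gene_a, matrix$gene_ids)
  ib <- match(gene_b, matrix$gene_ids)
  if (is.na(ia)) stop("gene not found in matrix: ", gene_a)
  if (is.na(ib)) stop("gene not found in matrix: ", gene_b)
  prof_a <- correlation_profile(matrix, gene_a)
  prof_b <- correlation_profile(matrix, gene_b)
  obs <- coordination(prof_a, prof_b)
  excl <- unique(c(ia, ib))
  tx <- t(matrix$values)
  b_fixed <- prof_b$r_values[-excl]
  set.seed(seed)
  n_extreme <- 0L
  for (i in seq_len(n_permutations)) {
    perm <- sample(matrix$n_samples)
    ra <- as.vector(stats::cor(matrix$values[ia, perm], tx))
    null_r <- stats::cor(ra[-excl], b_fixed)
    if (abs(null_r) >= abs(obs$coordination_r)) n_extreme <- n_extreme + 1L
  }
  obs$p_permutation <- (1 + n_extreme) / (n_permutations + 1)
  obs$n_permutations <- as.integer(n_permutations)
  obs$seed <- as.integer(seed)
  obs
}

#' Scan all genes for coordination with a query panel
#'
#' For every gene outside the panel, computes its coordination with each panel
#' member and aggregates across the panel (mean is the primary score, min is
#' reported alongside). Candidates are ranked by descending mean coordination
#' with dense ranks; ties share a rank and are ordered lexicographically by
#' gene id within the tie.
#'
#' @param matrix A variance-filtered [expression_matrix].
#' @param panel Character vector of panel gene ids, all present in the matrix.
#' @return A `panel_scan_result`: list with `panel`, `candidates` (data.frame
#'   with columns candidate, one `coord_<panel gene>` column per member,
#'   `mean_coordination`, `min_coordination`, `p_analytic` for the mean, and
#'   `rank`), sorted by rank then id.
#' @export
coordination_scan <- function(matrix, panel) {
  stopifnot(inherits(matrix, "expression_matrix"))
  panel <- as.character(panel)
  if (length(panel) < 1) stop("panel must contain at least 1 gene")
  missing_panel <- setdiff(panel, matrix$gene_ids)
  if (length(missing_panel)) {
    stop("panel gene(s) absent from matrix: ",
         paste(missing_panel, collapse = ", "))
  }
  g <- length(matrix$gene_ids)
  cmat <- stats::cor(t(matrix$values))
  cmat <- pmin(pmax(cmat, -1), 1)
  diag(cmat) <- 1
  p_idx <- match(panel, matrix$gene_ids)
  cand_idx <- setdiff(seq_len(g), p_idx)
  per_pair <- array(NA_real_, dim = c(length(cand_idx), length(panel)),
                    dimnames = list(matrix$gene_ids[cand_idx],
                                    paste0("coord_", panel)))
  for (j in seq_along(p_idx)) {
    pj <- p_idx[j]
    for (i in seq_along(cand_idx)) {
      ci <- cand_idx[i]
      per_pair[i, j] <- profile_cor(cmat, ci, pj, unique(c(ci, pj)))
    }
  }
  mean_c <- rowMeans(per_pair)
  min_c <- apply(per_pair, 1, min)
  n_points <- g - 2L  # points per pairwise coordination (both self-entries out)
  df <- data.frame(candidate = rownames(per_pair), per_pair,
                   mean_coordination = mean_c, min_coordination = min_c,
                   p_analytic = pearson_pvalue(mean_c, n_points),
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ord <- order(-df$mean_coordination, df$candidate)
  df <- df[ord, , drop = FALSE]
  # dense rank: equal scores share a rank, next distinct score gets rank + 1
  df$rank <- cumsum(!duplicated(df$mean_coordination))
  rownames(df) <- NULL
  structure(list(panel = panel, candidates = df, n_profile_points = n_points),
            class = "panel_scan_result")
}

#' @export
print.panel_scan_result <- function(x, ...) {
  cat("coordination scan: panel of", length(x$panel), "genes,",
      nrow(x$candidates), "candidates\n")
  print(utils::head(x$candidates[, c("candidate", "mean_coordination",
                                     "min_coordination", "rank")], 5))
  invisible(x)
}

#' Genes significantly correlated with a query gene
#'
#' Selects the genes whose correlation-profile entry against the query passes
#' the two-sided Pearson significance threshold at level `alpha`, optionally
#' restricted to positive correlations, ordered by descending R. The query
#' gene itself is always excluded.
#'
#' @param matrix A variance-filtered [expression_matrix].
#' @param gene Query gene id.
#' @param alpha Significance level for [pearson_pvalue()] (default 0.05).
#' @param direction `"positive"` (R > 0 required, default) or `"both"`.
#' @return Data frame with columns `gene`, `r`, `p`, sorted by descending `r`.
#' @export
correlated_gene_set <- function(matrix, gene, alpha = 0.05,
                                direction = c("positive", "both")) {
  direction <- match.arg(direction)
  prof <- correlation_profile(matrix, gene)
  r <- prof$r_values
  p <- pearson_pvalue(r, prof$n_samples)
  keep <- names(r) != gene & p < alpha
  if (direction == "positive") keep <- keep & r > 0
  out <- data.frame(gene = names(r)[keep], r = unname(r[keep]),
                    p = unname(p[keep]), stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
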