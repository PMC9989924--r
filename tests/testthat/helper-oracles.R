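# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the implementation it checks:
# raw-sums formulas instead of stats::cor, numeric integration instead of
# stats::pt, combinatorial enumeration instead of stats::phyper, literal
# rule application instead of vectorized shortcuts.

# Pearson correlation via the raw-sums formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# full gene-gene correlation matrix from the raw-sums formula
oracle_profile_matrix <- function(values) {
  n <- ncol(values)
  S <- rowSums(values)
  Q <- rowSums(values^2)
  cross <- tcrossprod(values)
  num <- n * cross - outer(S, S)
  den <- sqrt(outer(n * Q - S^2, n * Q - S^2))
  R <- num / den
  diag(R) <- 1
  R
}

# coordination of genes a and b from an oracle profile matrix
oracle_coordination <- function(R, a, b) {
  excl <- unique(c(a, b))
  oracle_pearson(R[a, -excl], R[b, -excl])
}

# two-sided Pearson p-value by numeric integration of the t density
oracle_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- abs(r) * sqrt((n - 2) / (1 - r^2))
  df <- n - 2
  dens <- function(t) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + t^2 / df)^(-(df + 1) / 2)
  }
  min(1, 2 * stats::integrate(dens, tval, Inf, rel.tol = 1e-12)$value)
}

# critical |r| by bisection on the integration oracle
oracle_critical_r <- function(n, alpha) {
  f <- function(r) oracle_pvalue(r, n) - alpha
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-13)$root
}

# hypergeometric upper tail by direct combinatorial enumeration
oracle_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# BH step-up by literal application of the rule
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# interval length by one-by-one enumeration of valid coordinates
oracle_interval_length <- function(a, b) {
  coords <- setdiff(seq(a, b), 0)
  length(coords)
}

# IUPAC-aware Levenshtein by an explicit full DP matrix
oracle_edit_distance <- function(pattern, window) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(gsub("X", "N", pattern)), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  m <- length(p); l <- length(w)
  D <- matrix(0L, m + 1, l + 1)
  D[, 1] <- 0:m
  D[1, ] <- 0:l
  for (i in seq_len(m)) {
    for (j in seq_len(l)) {
      hit <- length(intersect(sets[[p[i]]], sets[[w[j]]])) > 0
      D[i + 1, j + 1] <- min(D[i, j] + !hit, D[i, j + 1] + 1, D[i + 1, j] + 1)
    }
  }
  as.integer(D[m + 1, l + 1])
}

# naive exact degenerate matcher (max_edit = 0 reference)
oracle_naive_match <- function(seq, consensus) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  p <- strsplit(toupper(gsub("X", "N", consensus)), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  m <- length(p)
  starts <- integer()
  for (start in seq_len(length(s) - m + 1)) {
    ok <- TRUE
    for (i in seq_len(m)) {
      if (!length(intersect(sets[[p[i]]], sets[[s[start + i - 1]]]))) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, start)
  }
  starts
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
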