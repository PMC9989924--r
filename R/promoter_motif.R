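# IUPAC nucleotide codes -> the set of bases each one stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

#' Construct a promoter sequence with a declared TSS position
#'
#' Sequences are stored 5'->3' on the sense strand. `tss_offset` is the
#' 1-based string index of the +1 (first transcribed) base; everything before
#' it is upstream. Promoter coordinates follow the no-zero convention:
#' ..., -2, -1, +1, +2, ... with no position 0.
#'
#' @param id Record identifier.
#' @param sequence DNA string over A, C, G, T, N (lowercase accepted).
#' @param tss_offset 1-based index of the +1 position, within the sequence.
#' @return A `promoter_sequence` object.
#' @export
promoter_sequence <- function(id, sequence, tss_offset = nchar(sequence)) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("invalid character '", chars[bad[1]], "' at position ", bad[1],
         " in promoter ", id)
  }
  if (!is.numeric(tss_offset) || length(tss_offset) != 1 ||
      tss_offset != round(tss_offset) ||
      tss_offset < 1 || tss_offset > nchar(sequence)) {
    stop("tss_offset out of range [1, ", nchar(sequence), "] for promoter ", id)
  }
  structure(list(id = id, sequence = sequence,
                 tss_offset = as.integer(tss_offset), strand = "+"),
            class = "promoter_sequence")
}

#' Read promoter sequences from FASTA
#'
#' The TSS position is parsed from a header token of the form `tss=<int>`
#' (1-based index within the record); records without one default to
#' `tss = length`, i.e. the whole record is treated as upstream sequence.
#'
#' @param path FASTA file path.
#' @return A list of [promoter_sequence] objects, named by record id.
#' @export
read_promoters <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (!length(recs)) stop("no FASTA records in ", path)
  out <- lapply(seq_along(recs), function(i) {
    header <- names(recs)[i]
    id <- strsplit(header, "\\s+")[[1]][1]
    seq <- as.character(recs[[i]])
    m <- regmatches(header, regexpr("tss=-?[0-9]+", header))
    tss <- if (length(m)) as.integer(sub("tss=", "", m)) else nchar(seq)
    promoter_sequence(id, seq, tss)
  })
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Length of a closed TSS-relative interval
#'
#' Counts the integer positions from `start` to `end` inclusive under the
#' no-zero convention: coordinates run ..., -2, -1, +1, +2, ... so an interval
#' crossing the TSS contains `(-start) + end` positions, while a same-sign
#' interval contains the usual `end - start + 1`.
#'
#' @param start,end TSS-relative coordinates, `start <= end` in no-zero order,
#'   neither equal to 0.
#' @return Integer number of positions.
#' @export
interval_length <- function(start, end) {
  if (start == 0 || end == 0) {
    stop("no position 0 in TSS-relative convention")
  }
  if (start != round(start) || end != round(end)) {
    stop("coordinates must be integers")
  }
  if (!tss_leq(start, end)) stop("start must not exceed end in no-zero order")
  if (sign(start) == sign(end)) {
    as.integer(end - start + 1)
  } else {
    as.integer(-start + end)
  }
}

# no-zero ordering: is a <= b?
tss_leq <- function(a, b) a <= b

#' Convert a string index to a TSS-relative coordinate
#'
#' The base at `tss_offset` maps to +1; the base immediately upstream maps to
#' -1 (there is no 0). Bijective over the sequence; [from_tss_relative()] is
#' the inverse.
#'
#' @param promoter A [promoter_sequence].
#' @param string_index 1-based position within the sequence.
#' @return TSS-relative coordinate (negative upstream, positive from +1 on).
#' @export
to_tss_relative <- function(promoter, string_index) {
  stopifnot(inherits(promoter, "promoter_sequence"))
  len <- nchar(promoter$sequence)
  if (any(string_index < 1 | string_index > len)) {
    stop("string index out of range [1, ", len, "]")
  }
  ifelse(string_index >= promoter$tss_offset,
         string_index - promoter$tss_offset + 1L,
         string_index - promoter$tss_offset)
}

#' Convert a TSS-relative coordinate back to a string index
#'
#' Inverse of [to_tss_relative()].
#'
#' @param promoter A [promoter_sequence].
#' @param coord TSS-relative coordinate (nonzero).
#' @return 1-based string index.
#' @export
from_tss_relative <- function(promoter, coord) {
  stopifnot(inherits(promoter, "promoter_sequence"))
  if (any(coord == 0)) stop("no position 0 in TSS-relative convention")
  idx <- ifelse(coord > 0, coord + promoter$tss_offset - 1L,
                coord + promoter$tss_offset)
  len <- nchar(promoter$sequence)
  if (any(idx < 1 | idx > len)) stop("coordinate maps outside the sequence")
  as.integer(idx)
}

#' Construct a consensus motif pattern
#'
#' Consensus strings use IUPAC degeneracy codes; the placeholder `x` (any
#' base) is mapped to `N`. Matching is by Levenshtein edit distance where a
#' window base matches a pattern code at zero cost when their base sets
#' intersect; substitutions, insertions and deletions cost 1.
#'
#' @param consensus Consensus string (e.g. `"TGATGxAAx"`).
#' @param max_edit_distance Maximum edit distance for a reported hit, >= 0.
#' @return A `motif_pattern` object.
#' @export
motif_pattern <- function(consensus, max_edit_distance = 0) {
  consensus <- toupper(consensus)
  consensus <- gsub("X", "N", consensus, fixed = TRUE)
  if (!nzchar(consensus)) stop("empty consensus")
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad)) {
    stop("invalid IUPAC code '", chars[bad[1]], "' at position ", bad[1])
  }
  if (max_edit_distance < 0 || max_edit_distance != round(max_edit_distance)) {
    stop("max_edit_distance must be a nonnegative integer")
  }
  structure(list(consensus = consensus,
                 max_edit_distance = as.integer(max_edit_distance)),
            class = "motif_pattern")
}

# zero-cost match between a pattern IUPAC code and a sequence base
# (sequence N is treated as fully degenerate: sets must intersect)
iupac_match <- function(pat_char, seq_char) {
  length(intersect(IUPAC_SETS[[pat_char]], IUPAC_SETS[[seq_char]])) > 0
}

#' IUPAC-aware Levenshtein distance
#'
#' Edit distance between a degenerate consensus and a concrete window:
#' matches through the degeneracy sets cost 0, mismatches and indels cost 1.
#'
#' @param pattern Consensus string (IUPAC codes; `x` mapped to `N`).
#' @param window Sequence window over A, C, G, T, N.
#' @return Integer edit distance.
#' @export
iupac_edit_distance <- function(pattern, window) {
  p <- strsplit(toupper(gsub("X", "N", pattern, fixed = TRUE)), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  m <- length(p); l <- length(w)
  prev <- 0:l
  for (i in seq_len(m)) {
    cur <- numeric(l + 1)
    cur[1] <- i
    for (j in seq_len(l)) {
      cost <- if (iupac_match(p[i], w[j])) 0 else 1
      cur[j + 1] <- min(prev[j] + cost, prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  as.integer(prev[l + 1])
}

#' Scan a promoter for approximate consensus matches
#'
#' Semi-global alignment of the consensus against the promoter: every window
#' whose IUPAC-aware Levenshtein distance is at most the pattern's
#' `max_edit_distance` yields a hit. Hits ending at the same sequence
#' position (one anchor) are collapsed to the minimal-distance, then
#' shortest, then leftmost window; hits at distinct anchors may overlap.
#' Scanning is forward-strand only by default; `both_strands = TRUE` also
#' scans the reverse complement and reports those hits with strand `"-"` in
#' sense-strand coordinates.
#'
#' @param promoter A [promoter_sequence].
#' @param pattern A [motif_pattern].
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return Data frame of hits: `promoter_id`, `start`, `end` (TSS-relative,
#'   closed, no-zero), `matched`, `edit_distance`, `strand`, `consensus`,
#'   ordered by start. Zero rows when nothing matches (including when the
#'   pattern is longer than the sequence plus the edit budget).
#' @export
scan_consensus <- function(promoter, pattern, both_strands = FALSE) {
  stopifnot(inherits(promoter, "promoter_sequence"),
            inherits(pattern, "motif_pattern"))
  hits <- scan_one_strand(promoter$sequence, pattern)
  hits$strand <- rep("+", nrow(hits))
  if (both_strands) {
    rc <- revcomp(promoter$sequence)
    rhits <- scan_one_strand(rc, pattern)
    if (nrow(rhits)) {
      len <- nchar(promoter$sequence)
      s <- len - rhits$end + 1L
      e <- len - rhits$start + 1L
      rhits$start <- s
      rhits$end <- e
      rhits$strand <- "-"
      hits <- rbind(hits, rhits)
    }
  }
  if (!nrow(hits)) {
    return(data.frame(promoter_id = character(), start = integer(),
                      end = integer(), matched = character(),
                      edit_distance = integer(), strand = character(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(
    promoter_id = promoter$id,
    start = to_tss_relative(promoter, hits$start),
    end = to_tss_relative(promoter, hits$end),
    matched = hits$matched,
    edit_distance = hits$edit_distance,
    strand = hits$strand,
    consensus = pattern$consensus,
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# scan one oriented sequence; returns string-index hits
scan_one_strand <- function(seq, pattern) {
  p <- strsplit(pattern$consensus, "", fixed = TRUE)[[1]]
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  m <- length(p); l <- length(s)
  maxe <- pattern$max_edit_distance
  empty <- data.frame(start = integer(), end = integer(),
                      matched = character(), edit_distance = integer(),
                      stringsAsFactors = FALSE)
  if (m > l + maxe) return(empty)
  # semi-global DP: D[i+1, j+1] = cost of aligning pattern[1..i] to a window
  # ending at j with free start
  prev <- rep(0, l + 1)
  for (i in seq_len(m)) {
    cur <- numeric(l + 1)
    cur[1] <- i
    for (j in seq_len(l)) {
      cost <- if (iupac_match(p[i], s[j])) 0 else 1
      cur[j + 1] <- min(prev[j] + cost, prev[j + 1] + 1, cur[j] + 1)
    }
    prev <- cur
  }
  ends <- which(prev[-1] <= maxe)
  if (!length(ends)) return(empty)
  rows <- lapply(ends, function(j) {
    # candidate windows ending at j: lengths within the edit budget of m
    lens <- seq(max(1, m - maxe), min(j, m + maxe))
    win <- vapply(lens, function(len) {
      paste(s[(j - len + 1):j], collapse = "")
    }, character(1))
    d <- vapply(win, function(w) iupac_edit_distance(pattern$consensus, w),
                integer(1))
    ok <- which(d <= maxe)
    if (!length(ok)) return(NULL)
    # minimal distance, then shortest window (start is determined by length
    # at a fixed end, so the leftmost rule never has to break a further tie)
    best <- ok[order(d[ok], lens[ok])][1]
    data.frame(start = j - lens[best] + 1L, end = j,
               matched = unname(win[best]), edit_distance = d[best],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(toupper(seq), "")[[1]]]), collapse = "")
}
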