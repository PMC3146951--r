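# Sequence-set reduction: fragment removal, CD-HIT-style greedy identity
# de-duplication, and BLASTCLUST-style score/length-coverage grouping.
# Alignments are global Needleman-Wunsch with BLOSUM62, gap open 11 /
# extend 1, via Biostrings.

#' Remove short sequence fragments
#'
#' Retains exactly the records of at least `min_len` residues, preserving
#' input order.
#'
#' @param records Record `data.frame`.
#' @param min_len Minimum retained length, residues.
#' @return The filtered record `data.frame`.
#' @export
remove_fragments <- function(records, min_len = 100L) {
  records[nchar(records$sequence) >= min_len, , drop = FALSE]
}

# BLOSUM62 lacks U and O; map them (with any other unknowns) to X.
blosum_safe <- function(s) {
  chartr("UO", "XX", s)
}

align_global <- function(a, b_vec) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(blosum_safe(b_vec)),
    Biostrings::AAString(blosum_safe(a)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
}

alignment_stats <- function(aln) {
  p <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
  q <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
  t(vapply(seq_along(p), function(k) {
    cols <- length(p[[k]])
    both <- p[[k]] != "-" & q[[k]] != "-"
    c(columns = cols,
      identical = sum(both & p[[k]] == q[[k]]),
      aligned_pairs = sum(both))
  }, numeric(3L)))
}

#' Pairwise global identity and normalised score
#'
#' Identity is the number of identical aligned pairs divided by the total
#' alignment columns (gap columns included). The normalised score is half the
#' raw BLOSUM62 score per alignment column, a half-bit approximation of
#' bit score per column (the `-S` score-coverage statistic); the exact
#' Karlin-Altschul scaling is deliberately not reproduced since the statistic
#' is a representative-picking heuristic.
#'
#' @param a,b Amino-acid sequences (single strings).
#' @return List with `identity` (fraction in \[0,1\]), `alignment_length`
#'   (columns), `score_per_column` and `aligned_pairs` (columns with a
#'   residue on both sides).
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  aln <- align_global(a, b)
  st <- alignment_stats(aln)
  list(identity = unname(st[1L, "identical"] / st[1L, "columns"]),
       alignment_length = unname(st[1L, "columns"]),
       score_per_column = unname((Biostrings::score(aln) / 2) /
                                   st[1L, "columns"]),
       aligned_pairs = unname(st[1L, "aligned_pairs"]))
}

#' Greedy identity-threshold de-duplication
#'
#' CD-HIT-style incremental clustering: records are sorted by decreasing
#' length (ties broken lexicographically by id); each record joins the first
#' existing representative with identity strictly greater than the threshold,
#' otherwise it founds a new cluster. Because a record founds a cluster only
#' when no existing representative exceeds the threshold, no two retained
#' representatives exceed it either. A length-ratio prefilter skips
#' alignments that cannot reach the threshold (identity never exceeds
#' shorter/longer length under the gap-inclusive denominator).
#'
#' @param records Record `data.frame` (non-empty).
#' @param identity_threshold Identity above which a record is absorbed.
#' @return List with `records` (representatives, in greedy order),
#'   `assignments` (`data.frame` of `representative_id`, `member_id`,
#'   representatives included as their own members) and `threshold`.
#' @export
dedupe <- function(records, identity_threshold = 0.95) {
  stopifnot(nrow(records) > 0L)
  ord <- order(-nchar(records$sequence), records$id)
  records <- records[ord, , drop = FALSE]
  rep_idx <- integer(0)
  assign_rep <- character(nrow(records))
  for (r in seq_len(nrow(records))) {
    len_r <- nchar(records$sequence[r])
    cand <- rep_idx[pmin(nchar(records$sequence[rep_idx]), len_r) /
                      pmax(nchar(records$sequence[rep_idx]), len_r) >
                      identity_threshold]
    found <- NA_integer_
    if (length(cand)) {
      aln <- align_global(records$sequence[r], records$sequence[cand])
      st <- alignment_stats(aln)
      hit <- which(st[, "identical"] / st[, "columns"] > identity_threshold)
      if (length(hit)) found <- cand[hit[1L]]
    }
    if (is.na(found)) {
      rep_idx <- c(rep_idx, r)
      assign_rep[r] <- records$id[r]
    } else {
      assign_rep[r] <- records$id[found]
    }
  }
  list(records = records[rep_idx, , drop = FALSE],
       assignments = data.frame(representative_id = assign_rep,
                                member_id = records$id,
                                stringsAsFactors = FALSE),
       threshold = identity_threshold)
}

#' Score/length-coverage grouping
#'
#' Single-linkage grouping in which an edge joins two sequences iff the
#' normalised alignment score is at least `score_per_column_min` and the
#' aligned (residue-on-both-sides) columns cover at least
#' `length_coverage_min` of at least one of the two sequences (no requirement
#' on both, matching BLASTCLUST's `-b F`). Every record lands in exactly one
#' group; the group representative is its longest member (ties by id).
#'
#' @param records Record `data.frame`.
#' @param score_per_column_min Minimum half-bit score per alignment column.
#' @param length_coverage_min Minimum covered fraction of the better-covered
#'   sequence.
#' @return `data.frame` with columns `representative_id`, `member_id`.
#' @export
group_by_coverage <- function(records, score_per_column_min = 1.0,
                              length_coverage_min = 0.5) {
  n <- nrow(records)
  if (n == 0L)
    return(data.frame(representative_id = character(0),
                      member_id = character(0), stringsAsFactors = FALSE))
  adj <- matrix(FALSE, n, n)
  for (a in seq_len(n)) {
    if (a == n) break
    bs <- (a + 1L):n
    aln <- align_global(records$sequence[a], records$sequence[bs])
    st <- alignment_stats(aln)
    spc <- (Biostrings::score(aln) / 2) / st[, "columns"]
    cov <- pmax(st[, "aligned_pairs"] / nchar(records$sequence[a]),
                st[, "aligned_pairs"] / nchar(records$sequence[bs]))
    edge <- spc >= score_per_column_min & cov >= length_coverage_min
    adj[a, bs[edge]] <- TRUE
    adj[bs[edge], a] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  rep_of <- vapply(seq_len(max(comp)), function(cl) {
    members <- which(comp == cl)
    members <- members[order(-nchar(records$sequence[members]),
                             records$id[members])]
    records$id[members[1L]]
  }, character(1L))
  data.frame(representative_id = rep_of[comp],
             member_id = records$id,
             stringsAsFactors = FALSE)
}
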