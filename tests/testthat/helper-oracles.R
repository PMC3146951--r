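# Independent oracles used across tests. These deliberately avoid the
# package's pattern engine and window code: matches are found by direct
# character comparison, windows recomputed from the formulas, containment
# checked by interval arithmetic.

# All (start, end) spans of a literal-x(3)-literal motif, by brute force.
brute_5mer <- function(sequence, first, last) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 5L) return(data.frame(start = integer(0), end = integer(0)))
  s <- which(chars[1:(n - 4L)] == first & chars[5:n] == last)
  data.frame(start = s, end = s + 4L)
}

# Fully general brute-force matcher: recursive enumeration over elements.
brute_match <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  recurse <- function(pos, els) {
    if (length(els) == 0L) return(pos - 1L)
    el <- els[[1L]]
    if (el$type == "literal") {
      if (pos > n || chars[pos] != el$residue) return(integer(0))
      return(recurse(pos + 1L, els[-1L]))
    }
    out <- integer(0)
    for (k in el$min:el$max) {
      if (pos + k - 1L > n) break
      out <- c(out, recurse(pos + k, els[-1L]))
    }
    out
  }
  res <- do.call(rbind, lapply(seq_len(n), function(s) {
    e <- sort(unique(recurse(s, pattern$elements)))
    if (length(e)) data.frame(start = s, end = e) else NULL
  }))
  if (is.null(res)) data.frame(start = integer(0), end = integer(0)) else res
}

# Brute-force windowed scan: match everywhere, then keep matches fully
# contained in the appropriate half-window.
brute_scan <- function(sequence, topology, c_flank = 5L, n_flank = 5L) {
  n <- nchar(sequence)
  out <- list()
  for (k in seq_len(nrow(topology))) {
    i <- topology$start[k]; j <- topology$end[k]
    mid <- (i + j) %/% 2L
    cw <- c(max(1L, mid), min(n, j + c_flank))
    nw <- c(max(1L, i - n_flank), min(n, mid))
    s <- brute_5mer(sequence, "S", "H")
    s <- s[s$start >= cw[1L] & s$end <= cw[2L], , drop = FALSE]
    h <- brute_5mer(sequence, "H", "H")
    h <- h[h$start >= nw[1L] & h$end <= nw[2L], , drop = FALSE]
    if (nrow(s))
      out[[length(out) + 1L]] <- data.frame(pattern = "SxxxH", start = s$start,
                                            end = s$end, tm_index = k,
                                            window = "c_half")
    if (nrow(h))
      out[[length(out) + 1L]] <- data.frame(pattern = "HxxxH", start = h$start,
                                            end = h$end, tm_index = k,
                                            window = "n_half")
  }
  if (length(out) == 0L)
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), tm_index = integer(0),
                      window = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$pattern <- as.character(res$pattern)
  res$window <- as.character(res$window)
  res
}

# Direct sliding-window mean with truncated edges, computed naively.
brute_profile <- function(sequence, scale = kyte_doolittle, window = 19L) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  vals <- unname(scale[chars])
  vals[is.na(vals)] <- mean(scale)
  half <- (window - 1L) %/% 2L
  vapply(seq_along(vals), function(p)
    mean(vals[max(1L, p - half):min(length(vals), p + half)]), numeric(1L))
}

# Random protein over the full alphabet (biased towards S and H so motif
# hits actually occur).
random_sequence <- function(n, s_h_boost = 4) {
  alpha <- c(AA_STANDARD, AA_AMBIGUOUS)
  w <- rep(1, length(alpha))
  w[alpha %in% c("S", "H")] <- s_h_boost
  paste(sample(alpha, n, replace = TRUE, prob = w), collapse = "")
}

# Random valid topology for a sequence of length n: segments of >= 15
# residues, sorted, non-overlapping, indices 1..k.
random_topology <- function(n, max_tm = 8L) {
  starts <- integer(0); ends <- integer(0)
  pos <- sample.int(20L, 1L)
  while (pos + 15L <= n && length(starts) < max_tm) {
    len <- sample(15:28, 1L)
    if (pos + len - 1L > n) break
    starts <- c(starts, pos); ends <- c(ends, pos + len - 1L)
    pos <- pos + len + sample.int(40L, 1L)
  }
  data.frame(index = seq_along(starts), start = starts, end = ends)
}

# Shorthand: one-off record.
rec1 <- function(sequence, id = "p1") {
  protein_records(id, sequence)
}
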