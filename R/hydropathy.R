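# Sliding-window hydropathy TM prediction. This is the documented stand-in
# for a dedicated topology predictor: scan results can always be reproduced
# from a user-supplied topology table instead (read_topology_table), so the
# motif scan is decoupled from predictor quality.

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values for the twenty standard amino acids.
#' Positive values are hydrophobic; transmembrane helices average well above
#' the detection threshold, soluble loops below it.
#'
#' @format Named numeric vector of length 20.
#' @export
kyte_doolittle <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)

#' Hydropathy predictor configuration
#'
#' Classical single-helix heuristic defaults: Kyte-Doolittle scale, 19-residue
#' window, window-mean threshold 1.6. Runs closer than `merge_gap` residues
#' are merged first, then runs shorter than `min_tm_len` are discarded
#' (merge-then-filter, which makes the output deterministic in borderline
#' cases).
#'
#' @param scale Named numeric residue -> hydropathy map.
#' @param window Odd window length in residues (>= 5).
#' @param threshold Window-mean value at or above which a position counts as
#'   membrane-like (scale units).
#' @param min_tm_len Minimum length of a reported segment, residues.
#' @param merge_gap Runs separated by fewer than this many sub-threshold
#'   residues are merged before length filtering.
#' @return A list of class `hydropathy_config`.
#' @export
hydropathy_config <- function(scale = kyte_doolittle, window = 19L,
                              threshold = 1.6, min_tm_len = 15L,
                              merge_gap = 3L) {
  window <- as.integer(window)
  if (window < 5L || window %% 2L == 0L)
    stop("window must be odd and >= 5")
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (min_tm_len < 5L) stop("min_tm_len must be >= 5")
  structure(list(scale = scale, window = window, threshold = threshold,
                 min_tm_len = as.integer(min_tm_len),
                 merge_gap = as.integer(merge_gap)),
            class = "hydropathy_config")
}

#' Smoothed per-residue hydropathy profile
#'
#' Value at position p is the mean scale value over the window centred at p;
#' within half a window of either terminus the mean is taken over the
#' truncated window, so short termini can still host segments. Ambiguity
#' letters contribute the mean of the scale.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param config A [hydropathy_config()].
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(sequence, config = hydropathy_config()) {
  n <- nchar(sequence)
  if (n < config$window)
    stop("sequence shorter than the smoothing window (", config$window,
         "); supply an external topology table instead")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  vals <- unname(config$scale[chars])
  vals[is.na(vals)] <- mean(config$scale)
  half <- (config$window - 1L) %/% 2L
  cs <- cumsum(c(0, vals))
  p <- seq_len(n)
  lo <- pmax(1L, p - half)
  hi <- pmin(n, p + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Predict transmembrane segments from hydropathy
#'
#' Maximal runs of positions with smoothed hydropathy at or above the
#' threshold become candidate segments; runs closer than `merge_gap` are
#' merged, runs shorter than `min_tm_len` discarded, and survivors indexed
#' 1..n in sequence order. Sequences shorter than the smoothing window yield
#' an empty topology.
#'
#' @param record A single protein record (one-row `data.frame` or list with
#'   `id` and `sequence`).
#' @param config A [hydropathy_config()].
#' @return Topology `data.frame` with columns `index`, `start`, `end`.
#' @export
predict_tm <- function(record, config = hydropathy_config()) {
  seqstr <- record_sequence(record)
  if (nchar(seqstr) < config$window) return(empty_topology())
  prof <- hydropathy_profile(seqstr, config)
  r <- rle(prof >= config$threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0L) return(empty_topology())
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (k in 2L:nrow(runs)) {
      gap <- runs$start[k] - merged$end[nrow(merged)] - 1L
      if (gap < config$merge_gap) {
        merged$end[nrow(merged)] <- runs$end[k]
      } else {
        merged <- rbind(merged, runs[k, ])
      }
    }
  }
  merged <- merged[merged$end - merged$start + 1L >= config$min_tm_len, ,
                   drop = FALSE]
  if (nrow(merged) == 0L) return(empty_topology())
  out <- data.frame(index = seq_len(nrow(merged)),
                    start = as.integer(merged$start),
                    end = as.integer(merged$end))
  validate_topology(out, nchar(seqstr))
  out
}

#' Predict topologies for a whole record set
#'
#' @param records Record `data.frame`.
#' @param config A [hydropathy_config()].
#' @return Named list of topologies, one per record.
#' @export
predict_tm_all <- function(records, config = hydropathy_config()) {
  out <- lapply(seq_len(nrow(records)),
                function(r) predict_tm(records[r, ], config))
  names(out) <- records$id
  out
}

# Accept a one-row data.frame or a list with $sequence.
record_sequence <- function(record) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record$sequence[[1L]]
  } else record$sequence
}

record_id <- function(record) {
  if (is.data.frame(record)) record$id[[1L]] else record$id
}
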