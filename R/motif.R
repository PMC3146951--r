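# PROSITE-style pattern matching with bounded wildcards, the half-window
# arithmetic of the topology-anchored scan, and the naive whole-sequence
# composite pattern baseline.

#' Construct a motif pattern
#'
#' A pattern is an ordered list of elements: literal residues, which match
#' only the exact standard amino acid, and wildcards `x(min,max)`, which match
#' any run of `min` to `max` residues (including ambiguity letters). At least
#' one element must be a literal.
#'
#' @param name Pattern name (token).
#' @param elements List of elements, each `list(type = "literal", residue =)`
#'   or `list(type = "wildcard", min =, max =)`.
#' @return A list of class `motif_pattern`.
#' @seealso [parse_pattern()] for the PROSITE-like string notation.
#' @export
motif_pattern <- function(name, elements) {
  has_literal <- FALSE
  for (el in elements) {
    if (identical(el$type, "literal")) {
      if (!el$residue %in% AA_STANDARD)
        stop("pattern literal must be a standard residue, got '",
             el$residue, "'")
      has_literal <- TRUE
    } else if (identical(el$type, "wildcard")) {
      if (el$min < 0L || el$min > el$max)
        stop("wildcard bounds must satisfy 0 <= min <= max")
    } else stop("unknown pattern element type")
  }
  if (!has_literal) stop("pattern must contain at least one literal residue")
  structure(list(name = name, elements = elements), class = "motif_pattern")
}

#' Parse a PROSITE-like pattern string
#'
#' Accepts dash-separated notation (`"S-x(3)-H"`, `"S-x(3)-H-x(100,10000)-H-x(3)-H"`)
#' and the compact form where `x` is a single-residue wildcard (`"SxxxH"`).
#'
#' @param text Pattern string.
#' @param name Pattern name; defaults to the string itself.
#' @return A [motif_pattern()].
#' @export
parse_pattern <- function(text, name = text) {
  tokens <- if (grepl("-", text, fixed = TRUE))
    strsplit(text, "-", fixed = TRUE)[[1L]]
  else
    regmatches(text, gregexpr("x\\([0-9]+(,[0-9]+)?\\)|.", text))[[1L]]
  elements <- lapply(tokens, function(tok) {
    tok <- trimws(tok)
    if (tok %in% c("x", "X"))
      return(list(type = "wildcard", min = 1L, max = 1L))
    m <- regmatches(tok, regexec("^[xX]\\(([0-9]+)(,([0-9]+))?\\)$", tok))[[1L]]
    if (length(m)) {
      lo <- as.integer(m[2L])
      hi <- if (nzchar(m[4L])) as.integer(m[4L]) else lo
      return(list(type = "wildcard", min = lo, max = hi))
    }
    if (nchar(tok) == 1L)
      return(list(type = "literal", residue = toupper(tok)))
    stop("cannot parse pattern token '", tok, "'")
  })
  motif_pattern(name, elements)
}

#' The CREST motif patterns
#'
#' `sxxxh` and `hxxxh` are the two histidine-containing patterns used by the
#' topology-anchored scan; `d` is the single conserved aspartate checked in
#' extended mode.
#'
#' @return Named list of [motif_pattern()]s.
#' @export
crest_patterns <- function() {
  list(sxxxh = parse_pattern("S-x(3)-H", "SxxxH"),
       hxxxh = parse_pattern("H-x(3)-H", "HxxxH"),
       d = parse_pattern("D", "D"))
}

#' Scan configuration
#'
#' Houses the constants of the topology-anchored scan and the naive baseline:
#' half-window flanks of 5 residues, minimum transmembrane-index separation of
#' 3, and the 100-10000 residue spacer of the whole-sequence pattern.
#'
#' @param c_half_flank Residues appended C-terminally to the C-half window.
#' @param n_half_flank Residues prepended N-terminally to the N-half window.
#' @param min_tm_separation Minimum `hxxxh_tm - sxxxh_tm` for a passing call.
#' @param naive_spacer_min,naive_spacer_max Bounds on the wildcard spacer of
#'   the naive `SxxxHx(min,max)HxxxH` pattern.
#' @param mode `"core"` (SxxxH + HxxxH only) or `"extended"` (additionally
#'   require a literal D in the N-half window of the segment after the
#'   SxxxH-bearing one).
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(c_half_flank = 5L, n_half_flank = 5L,
                        min_tm_separation = 3L, naive_spacer_min = 100L,
                        naive_spacer_max = 10000L,
                        mode = c("core", "extended")) {
  mode <- match.arg(mode)
  if (c_half_flank < 0L || n_half_flank < 0L)
    stop("flanks must be >= 0")
  if (naive_spacer_min < 0L || naive_spacer_min > naive_spacer_max)
    stop("naive spacer bounds must satisfy 0 <= min <= max")
  if (min_tm_separation < 0L) stop("min_tm_separation must be >= 0")
  structure(list(c_half_flank = as.integer(c_half_flank),
                 n_half_flank = as.integer(n_half_flank),
                 min_tm_separation = as.integer(min_tm_separation),
                 naive_spacer_min = as.integer(naive_spacer_min),
                 naive_spacer_max = as.integer(naive_spacer_max),
                 mode = mode),
            class = "scan_config")
}

#' Enumerate all pattern matches in a sequence
#'
#' Every match span is reported, overlapping matches included; for bounded
#' wildcards every admissible repeat count is enumerated, so one start
#' position may yield several `(start, end)` spans. Literal positions match
#' only the exact standard residue; wildcards match any residue including
#' ambiguity letters.
#'
#' @param sequence Amino-acid sequence (single string).
#' @param pattern A [motif_pattern()].
#' @return `data.frame` with integer columns `start`, `end` (1-based,
#'   inclusive), sorted by `(start, end)`.
#' @export
find_pattern <- function(sequence, pattern) {
  stopifnot(inherits(pattern, "motif_pattern"))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  els <- pattern$elements
  starts <- if (length(els) && identical(els[[1L]]$type, "literal"))
    which(chars == els[[1L]]$residue) else seq_len(n)
  out_s <- integer(0); out_e <- integer(0)
  for (s in starts) {
    set <- s  # candidate positions of the next unmatched residue
    for (el in els) {
      if (el$type == "literal") {
        set <- set[set <= n]
        set <- set[chars[set] == el$residue] + 1L
      } else {
        set <- if (el$min == el$max) set + el$min
               else sort(unique(unlist(lapply(set, function(p)
                 p + el$min:el$max))))
        set <- set[set <= n + 1L]
      }
      if (!length(set)) break
    }
    if (length(set)) {
      out_s <- c(out_s, rep.int(s, length(set)))
      out_e <- c(out_e, set - 1L)
    }
  }
  res <- data.frame(start = as.integer(out_s), end = as.integer(out_e))
  res[order(res$start, res$end), , drop = FALSE]
}

#' Half-window of a transmembrane segment
#'
#' For a segment with start `i` and end `j` (1-based, inclusive), the C-half
#' window is `[floor((i+j)/2), j + c_half_flank]` and the N-half window
#' `[i - n_half_flank, floor((i+j)/2)]`; both are clamped to
#' `[1, sequence_length]`. The midpoint uses integer floor.
#'
#' @param tm One-row topology slice (or list) with `start` and `end`.
#' @param kind `"c_half"` or `"n_half"`.
#' @param config A [scan_config()].
#' @param sequence_length Length of the protein, for clamping.
#' @return Integer vector `c(a, b)`.
#' @export
window_for <- function(tm, kind = c("c_half", "n_half"),
                       config = scan_config(), sequence_length) {
  kind <- match.arg(kind)
  i <- as.integer(tm$start); j <- as.integer(tm$end)
  mid <- (i + j) %/% 2L
  w <- if (kind == "c_half") c(mid, j + config$c_half_flank)
       else c(i - config$n_half_flank, mid)
  c(max(1L, w[1L]), min(as.integer(sequence_length), w[2L]))
}

#' Topology-anchored motif scan
#'
#' For every transmembrane segment, reports SxxxH matches whose full span lies
#' inside the segment's C-half window and HxxxH matches fully inside its
#' N-half window (full containment: a motif overhanging a window boundary
#' does not count). In extended mode, literal D matches in N-half windows are
#' additionally reported for the aspartate check.
#'
#' @param record A single protein record.
#' @param topology Topology `data.frame` for that protein.
#' @param config A [scan_config()].
#' @return `data.frame` of hits with columns `pattern`, `start`, `end`,
#'   `tm_index`, `window`.
#' @export
scan_tm_windows <- function(record, topology, config = scan_config()) {
  seqstr <- record_sequence(record)
  validate_topology(topology, nchar(seqstr))
  pats <- crest_patterns()
  hits <- list()
  emit <- function(pattern, win, tm_index, window_kind) {
    if (win[2L] - win[1L] + 1L < 1L) return(NULL)
    m <- find_pattern(substr(seqstr, win[1L], win[2L]), pattern)
    if (nrow(m) == 0L) return(NULL)
    data.frame(pattern = pattern$name,
               start = m$start + win[1L] - 1L,
               end = m$end + win[1L] - 1L,
               tm_index = as.integer(tm_index),
               window = window_kind,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(topology))) {
    tm <- topology[k, ]
    cw <- window_for(tm, "c_half", config, nchar(seqstr))
    nw <- window_for(tm, "n_half", config, nchar(seqstr))
    hits[[length(hits) + 1L]] <- emit(pats$sxxxh, cw, tm$index, "c_half")
    hits[[length(hits) + 1L]] <- emit(pats$hxxxh, nw, tm$index, "n_half")
    if (config$mode == "extended")
      hits[[length(hits) + 1L]] <- emit(pats$d, nw, tm$index, "n_half")
  }
  hits <- hits[!vapply(hits, is.null, logical(1L))]
  if (length(hits) == 0L)
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), tm_index = integer(0),
                      window = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Naive whole-sequence composite pattern scan
#'
#' Matches `SxxxHx(min,max)HxxxH` anywhere in the sequence: every pair of an
#' SxxxH at position s and an HxxxH at position t with spacer
#' `t - (s + 5)` within the configured bounds. No topology is consulted.
#'
#' @param record A single protein record.
#' @param config A [scan_config()]; only the spacer bounds are used.
#' @return `data.frame` of hits with columns `pattern`, `start`, `end`,
#'   `tm_index` (always 0), `window` (always `"whole_sequence"`).
#' @export
naive_scan <- function(record, config = scan_config()) {
  seqstr <- record_sequence(record)
  pat <- motif_pattern(
    sprintf("SxxxHx(%d,%d)HxxxH", config$naive_spacer_min,
            config$naive_spacer_max),
    c(parse_pattern("S-x(3)-H")$elements,
      list(list(type = "wildcard", min = config$naive_spacer_min,
                max = config$naive_spacer_max)),
      parse_pattern("H-x(3)-H")$elements))
  m <- find_pattern(seqstr, pat)
  data.frame(pattern = rep.int(pat$name, nrow(m)),
             start = m$start, end = m$end,
             tm_index = rep.int(0L, nrow(m)),
             window = rep.int("whole_sequence", nrow(m)),
             stringsAsFactors = FALSE)
}
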