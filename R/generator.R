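# Labelled synthetic membrane proteins: the CREST architecture planted
# (positives) or violated in exactly one named way (decoy classes). The
# generator is the ground-truth source for every downstream stage.

#' Default transmembrane residue composition
#'
#' Leucine/isoleucine/valine-dominated, as in real transmembrane helices;
#' mean Kyte-Doolittle hydropathy about +3.6.
#'
#' @return Named numeric weight vector.
#' @export
crest_tm_alphabet <- function() {
  c(L = 0.30, I = 0.24, V = 0.22, F = 0.10, A = 0.07, M = 0.04, W = 0.03)
}

#' Default loop residue composition
#'
#' A soluble-domain-like composition with a polar bias (mean Kyte-Doolittle
#' hydropathy about -0.36). Histidine and cysteine are deliberately absent so
#' that histidine-containing motifs occur only where planted; label
#' correctness is additionally enforced by rejection sampling, so user
#' alphabets containing any residue remain safe.
#'
#' @return Named numeric weight vector.
#' @export
crest_loop_alphabet <- function() {
  c(S = 0.11, T = 0.08, G = 0.10, P = 0.06, N = 0.05, Q = 0.05, D = 0.06,
    E = 0.06, K = 0.05, R = 0.04, A = 0.11, L = 0.09, V = 0.07, I = 0.05,
    Y = 0.02, F = 0.01)
}

#' Generator specification
#'
#' Defaults emulate the seven-transmembrane CREST core architecture:
#' seven hydrophobic segments of 18-25 residues separated (and flanked) by
#' hydrophilic loops of 10-60 residues. `extra_tm_pairs` optionally inserts
#' additional transmembrane pairs between the motif-bearing segments
#' (emulating SID-1's extra segment pair), shifting the HxxxH-bearing segment
#' to index `7 + 2 * extra_tm_pairs`; off by default.
#'
#' @param n_tm Number of core transmembrane segments (>= 7 for the canonical
#'   CREST layout).
#' @param tm_length_range Integer range of segment lengths, residues.
#' @param loop_length_range Integer range of loop lengths, residues.
#' @param hydrophobic_alphabet Named weight vector for segment residues.
#' @param loop_alphabet Named weight vector for loop residues.
#' @param extra_tm_pairs Extra segment pairs inserted after core segment 3.
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(n_tm = 7L, tm_length_range = c(18L, 25L),
                           loop_length_range = c(10L, 60L),
                           hydrophobic_alphabet = crest_tm_alphabet(),
                           loop_alphabet = crest_loop_alphabet(),
                           extra_tm_pairs = 0L) {
  n_tm <- as.integer(n_tm)
  if (n_tm < 1L) stop("n_tm must be >= 1")
  for (rg in list(tm_length_range, loop_length_range))
    if (length(rg) != 2L || rg[1L] > rg[2L] || rg[1L] < 1L)
      stop("length ranges must be non-empty ascending pairs of positive ",
           "integers")
  for (alpha in list(hydrophobic_alphabet, loop_alphabet)) {
    if (is.null(names(alpha)) || !all(names(alpha) %in% AA_STANDARD))
      stop("alphabets must be named by standard residues")
    if (any(!is.finite(alpha)) || any(alpha <= 0))
      stop("alphabet weights must be positive and finite")
  }
  structure(list(n_tm = n_tm,
                 tm_length_range = as.integer(tm_length_range),
                 loop_length_range = as.integer(loop_length_range),
                 hydrophobic_alphabet = hydrophobic_alphabet,
                 loop_alphabet = loop_alphabet,
                 extra_tm_pairs = as.integer(extra_tm_pairs)),
            class = "generator_spec")
}

decoy_kinds <- function() {
  c("decoy_order", "decoy_separation", "decoy_window", "decoy_no_motif",
    "soluble")
}

sample_residues <- function(n, alphabet) {
  if (n == 0L) return(character(0))
  sample(names(alphabet), n, replace = TRUE, prob = alphabet)
}

sample_range <- function(range, n = 1L) {
  sample(seq.int(range[1L], range[2L]), n, replace = TRUE)
}

# TM/loop skeleton: n segments with planted coordinates, n+1 loops.
build_skeleton <- function(spec) {
  k <- spec$n_tm + 2L * spec$extra_tm_pairs
  tm_len <- sample_range(spec$tm_length_range, k)
  loop_len <- sample_range(spec$loop_length_range, k + 1L)
  start <- integer(k); end <- integer(k)
  pos <- 0L
  for (t in seq_len(k)) {
    pos <- pos + loop_len[t]
    start[t] <- pos + 1L
    end[t] <- pos + tm_len[t]
    pos <- end[t]
  }
  list(topology = data.frame(index = seq_len(k), start = start, end = end),
       tm_len = tm_len, loop_len = loop_len,
       total = pos + loop_len[k + 1L])
}

assemble_chars <- function(skel, spec, tm_alpha = spec$hydrophobic_alphabet,
                           loop_alpha = spec$loop_alphabet) {
  chars <- sample_residues(skel$total, loop_alpha)
  for (t in seq_len(nrow(skel$topology))) {
    idx <- skel$topology$start[t]:skel$topology$end[t]
    chars[idx] <- sample_residues(length(idx), tm_alpha)
  }
  chars
}

# Admissible start range for a 5-residue motif fully inside a segment's
# half-window, flanks included: the scan windows extend 5 residues past the
# segment boundary precisely because boundary motifs may straddle a
# predicted edge, and planted placements cover that same range.
motif_start_range <- function(tm, half = c("c", "n"),
                              flank = 5L) {
  half <- match.arg(half)
  mid <- (tm$start + tm$end) %/% 2L
  if (half == "c") c(mid, tm$end + flank - 4L)
  else c(tm$start - flank, mid - 4L)
}

plant_motif <- function(chars, start, letters) {
  for (k in seq_along(letters))
    if (!is.na(letters[k])) chars[start + k - 1L] <- letters[k]
  chars
}

sxxxh_letters <- c("S", NA, NA, NA, "H")
hxxxh_letters <- c("H", NA, NA, NA, "H")

plant_at <- function(chars, tm, half, letters) {
  rg <- motif_start_range(tm, half)
  rg <- c(max(1L, rg[1L]), min(length(chars) - 4L, rg[2L]))
  if (rg[2L] < rg[1L])
    stop("generation error: transmembrane segment too short to host a ",
         "5-residue motif inside its half-window; widen tm_length_range")
  start <- sample_range(rg)
  list(chars = plant_motif(chars, start, letters), start = start)
}

motif_tm_indices <- function(spec) {
  if (spec$n_tm < 7L)
    stop("canonical CREST layout requires n_tm >= 7")
  list(s = 2L, d = 3L, h = 7L + 2L * spec$extra_tm_pairs)
}

build_labelled <- function(label, spec) {
  if (label == "soluble") {
    skel <- build_skeleton(spec)
    chars <- sample_residues(skel$total, spec$loop_alphabet)
    return(list(sequence = paste(chars, collapse = ""),
                truth = list(topology = empty_topology(),
                             motif_positions = list(), label = label)))
  }
  if (label == "decoy_no_motif") {
    strip <- function(a) a[!names(a) %in% c("S", "H", "D")]
    spec2 <- spec
    spec2$hydrophobic_alphabet <- strip(spec$hydrophobic_alphabet)
    spec2$loop_alphabet <- strip(spec$loop_alphabet)
    skel <- build_skeleton(spec2)
    chars <- assemble_chars(skel, spec2)
    return(list(sequence = paste(chars, collapse = ""),
                truth = list(topology = skel$topology,
                             motif_positions = list(), label = label)))
  }
  skel <- build_skeleton(spec)
  chars <- assemble_chars(skel, spec)
  tms <- motif_tm_indices(spec)
  topo <- skel$topology
  place <- switch(label,
    positive = list(s_tm = tms$s, s_half = "c",
                    h_tm = tms$h, h_half = "n", d_tm = tms$d),
    decoy_order = list(s_tm = tms$h, s_half = "c",
                       h_tm = tms$s, h_half = "n", d_tm = tms$d),
    decoy_separation = list(s_tm = tms$s, s_half = "c",
                            h_tm = tms$s + 2L, h_half = "n", d_tm = tms$d),
    decoy_window = list(s_tm = tms$s, s_half = "n",
                        h_tm = tms$h, h_half = "c", d_tm = tms$d),
    stop("unknown generator label '", label, "'"))
  ps <- plant_at(chars, topo[place$s_tm, ], place$s_half, sxxxh_letters)
  chars <- ps$chars
  ph <- plant_at(chars, topo[place$h_tm, ], place$h_half, hxxxh_letters)
  chars <- ph$chars
  d_rg <- motif_start_range(topo[place$d_tm, ], "n")
  d_rg[2L] <- d_rg[2L] + 4L  # single residue only needs to sit in the window
  d_rg[1L] <- max(1L, d_rg[1L])
  d_pos <- sample_range(d_rg)
  chars <- plant_motif(chars, d_pos, "D")
  list(sequence = paste(chars, collapse = ""),
       truth = list(topology = topo,
                    motif_positions = list(sxxxh = ps$start, d = d_pos,
                                           hxxxh = ph$start),
                    label = label))
}

label_ok <- function(built, label, config = scan_config()) {
  rec <- list(id = "tmp", sequence = built$sequence)
  res <- classify_protein(rec, built$truth$topology, config)
  if (label == "positive") res$positive else !res$positive
}

generate_labelled <- function(label, spec, max_attempts = 1000L) {
  for (k in seq_len(max_attempts)) {
    built <- build_labelled(label, spec)
    if (label_ok(built, label)) return(built)
  }
  stop("generation error: could not realise label '", label, "' in ",
       max_attempts, " attempts")
}

#' Generate one positive synthetic CREST protein
#'
#' Plants SxxxH fully inside the C-half window of transmembrane segment 2
#' (its C-terminal half plus the 5-residue flank, so the motif may straddle
#' the segment boundary), a single D inside the N-half window of segment 3,
#' and HxxxH fully inside the N-half window of segment 7 (shifted when
#' `extra_tm_pairs > 0`).
#' Remaining segment residues come from the hydrophobic alphabet, loops from
#' the loop alphabet, so the planted motifs are guaranteed to satisfy the
#' constellation caller under the planted topology. Uses the current RNG
#' state; seed via [set.seed()] or [generate_dataset()].
#'
#' @param spec A [generator_spec()].
#' @param id Identifier for the returned record.
#' @return List with `record` (one-row `data.frame`) and `truth` (planted
#'   `topology`, `motif_positions`, `label`).
#' @export
generate_positive <- function(spec = generator_spec(), id = "pos_0001") {
  built <- generate_labelled("positive", spec)
  list(record = protein_records(id, built$sequence), truth = built$truth)
}

#' Generate one decoy synthetic protein
#'
#' Each decoy class violates exactly the constraint it is named after:
#' `decoy_order` swaps the motif-bearing segments (HxxxH N-terminal to
#' SxxxH); `decoy_separation` plants the motifs two segments apart;
#' `decoy_window` plants each motif in the wrong half of its segment;
#' `decoy_no_motif` draws from alphabets without S, H or D; `soluble` emits a
#' loop-composition sequence with an empty topology. Rejection sampling
#' (capped at 1000 attempts) guarantees the protein classifies negative under
#' its planted topology.
#'
#' @param kind One of the decoy labels above.
#' @param spec A [generator_spec()].
#' @param id Identifier for the returned record.
#' @return As [generate_positive()].
#' @export
generate_decoy <- function(kind, spec = generator_spec(), id = NULL) {
  if (!kind %in% decoy_kinds()) stop("unknown decoy kind '", kind, "'")
  if (is.null(id)) id <- paste0(kind, "_0001")
  built <- generate_labelled(kind, spec)
  list(record = protein_records(id, built$sequence), truth = built$truth)
}

#' Generate a labelled synthetic dataset
#'
#' `n_per_class` proteins per label (positive plus the five decoy classes),
#' optionally written to disk as FASTA + topology table + truth JSON via the
#' package writers. Identifiers encode the label for auditing only;
#' downstream code never reads labels from ids.
#'
#' @param n_per_class Proteins per label (>= 1).
#' @param spec A [generator_spec()].
#' @param seed Integer seed; the dataset is a pure function of
#'   `(n_per_class, spec, seed)`.
#' @param dir Optional output directory (created if needed); writes
#'   `proteins.fasta`, `topology.tsv`, `truth.json`.
#' @param classes Labels to generate (default all six).
#' @param stamp Optional provenance header lines for the writers.
#' @return List with `records`, `topologies` (named list of planted
#'   topologies), `truth` (`data.frame` of `id`, `label`) and `details`
#'   (full per-protein truth).
#' @export
generate_dataset <- function(n_per_class, spec = generator_spec(),
                             seed = NULL, dir = NULL,
                             classes = c("positive", decoy_kinds()),
                             stamp = NULL) {
  if (n_per_class < 1L) stop("n_per_class must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  ids <- character(0); seqs <- character(0); labels <- character(0)
  topologies <- list(); details <- list()
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      built <- generate_labelled(cl, spec)
      id <- sprintf("%s_%04d", cl, k)
      ids <- c(ids, id); seqs <- c(seqs, built$sequence)
      labels <- c(labels, cl)
      topologies[[id]] <- built$truth$topology
      details[[id]] <- built$truth
    }
  }
  records <- protein_records(ids, seqs, description = labels)
  truth <- data.frame(id = ids, label = labels, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(records, file.path(dir, "proteins.fasta"))
    write_topology_table(topologies, file.path(dir, "topology.tsv"),
                         stamp = stamp)
    jsonlite::write_json(
      lapply(details, function(tr)
        list(label = tr$label, motif_positions = tr$motif_positions,
             topology = tr$topology)),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(records = records, topologies = topologies, truth = truth,
       details = details)
}
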