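# Combine windowed motif hits into CREST-candidate calls under the ordering
# and separation constraints, and evaluate calls against generator truth.

empty_calls <- function() {
  data.frame(protein_id = character(0), sxxxh_tm = integer(0),
             sxxxh_start = integer(0), sxxxh_end = integer(0),
             hxxxh_tm = integer(0), hxxxh_start = integer(0),
             hxxxh_end = integer(0), tm_separation = integer(0),
             passed = logical(0), mode = character(0),
             stringsAsFactors = FALSE)
}

#' Enumerate constellation calls from windowed hits
#'
#' Every pair of a C-half SxxxH hit and an N-half HxxxH hit is reported.
#' A pair passes when SxxxH lies in a lower-indexed transmembrane segment
#' than HxxxH and the (signed) index difference
#' `tm_separation = hxxxh_tm - sxxxh_tm` is at least `min_tm_separation`.
#' In extended mode a passing pair additionally requires at least one literal
#' D hit in the N-half window of the segment directly after the SxxxH-bearing
#' one (the conserved aspartate at the start of the third core segment).
#'
#' @param hits Hit `data.frame` from [scan_tm_windows()] for one protein.
#' @param topology The protein's topology (used to validate hit indices).
#' @param config A [scan_config()].
#' @param protein_id Identifier recorded in the calls.
#' @return Call `data.frame`; one row per (SxxxH, HxxxH) pair.
#' @export
call_constellations <- function(hits, topology, config = scan_config(),
                                protein_id = "") {
  if (nrow(hits) > 0L && !all(hits$tm_index %in% topology$index))
    stop("hit references a transmembrane index absent from the topology")
  s_hits <- hits[hits$pattern == "SxxxH" & hits$window == "c_half", ,
                 drop = FALSE]
  h_hits <- hits[hits$pattern == "HxxxH" & hits$window == "n_half", ,
                 drop = FALSE]
  if (nrow(s_hits) == 0L || nrow(h_hits) == 0L) return(empty_calls())
  d_tms <- unique(hits$tm_index[hits$pattern == "D" & hits$window == "n_half"])
  grid <- expand.grid(s = seq_len(nrow(s_hits)), h = seq_len(nrow(h_hits)))
  sep <- h_hits$tm_index[grid$h] - s_hits$tm_index[grid$s]
  passed <- s_hits$tm_index[grid$s] < h_hits$tm_index[grid$h] &
    sep >= config$min_tm_separation
  if (config$mode == "extended")
    passed <- passed & (s_hits$tm_index[grid$s] + 1L) %in% d_tms
  out <- data.frame(protein_id = rep.int(protein_id, nrow(grid)),
                    sxxxh_tm = s_hits$tm_index[grid$s],
                    sxxxh_start = s_hits$start[grid$s],
                    sxxxh_end = s_hits$end[grid$s],
                    hxxxh_tm = h_hits$tm_index[grid$h],
                    hxxxh_start = h_hits$start[grid$h],
                    hxxxh_end = h_hits$end[grid$h],
                    tm_separation = as.integer(sep),
                    passed = passed,
                    mode = rep.int(config$mode, nrow(grid)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sxxxh_start, out$hxxxh_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one protein as a CREST candidate
#'
#' Runs the topology-anchored scan and the constellation caller; a protein is
#' positive iff at least one passing call exists. A protein with an empty
#' topology is trivially negative (no windows exist).
#'
#' @param record A single protein record.
#' @param topology The protein's topology.
#' @param config A [scan_config()].
#' @return List with `positive` (logical) and `calls` (all enumerated pairs).
#' @export
classify_protein <- function(record, topology, config = scan_config()) {
  hits <- scan_tm_windows(record, topology, config)
  calls <- call_constellations(hits, topology, config,
                               protein_id = record_id(record))
  list(positive = any(calls$passed), calls = calls)
}

#' Classify a record set
#'
#' @param records Record `data.frame`.
#' @param topologies Named list of topologies covering every record id
#'   (missing entries are treated as empty topologies).
#' @param config A [scan_config()].
#' @return List with `predictions` (`data.frame` of `id`, `positive`) and
#'   `calls` (row-bound calls of all proteins).
#' @export
classify_all <- function(records, topologies, config = scan_config()) {
  res <- lapply(seq_len(nrow(records)), function(r) {
    topo <- topologies[[records$id[r]]]
    if (is.null(topo)) topo <- empty_topology()
    classify_protein(records[r, ], topo, config)
  })
  list(predictions = data.frame(id = records$id,
                                positive = vapply(res, `[[`, logical(1L),
                                                  "positive"),
                                stringsAsFactors = FALSE),
       calls = do.call(rbind, c(list(empty_calls()),
                                lapply(res, `[[`, "calls"))))
}

#' Evaluate predictions against generator truth
#'
#' Sensitivity is computed over the positive class; specificity over each
#' decoy class separately and pooled over all non-positive classes.
#'
#' @param truth `data.frame` with columns `id`, `label`.
#' @param predictions `data.frame` with columns `id`, `positive`.
#' @return List of class `crest_eval`: `n`, `confusion` (label x predicted
#'   table), `sensitivity`, `specificity` (named, one per non-positive class
#'   plus `"pooled"`), `per_class` counts.
#' @export
evaluate <- function(truth, predictions) {
  if (nrow(truth) == 0L) stop("empty dataset")
  if (!setequal(truth$id, predictions$id) ||
      nrow(truth) != nrow(predictions))
    stop("truth and predictions must cover identical protein ids")
  m <- merge(truth, predictions, by = "id")
  m <- m[order(m$id), ]
  confusion <- table(label = m$label,
                     predicted = factor(ifelse(m$positive, "positive",
                                               "negative"),
                                        levels = c("positive", "negative")))
  pos <- m$label == "positive"
  sens <- if (any(pos)) mean(m$positive[pos]) else NA_real_
  neg_classes <- sort(unique(m$label[!pos]))
  spec <- vapply(neg_classes,
                 function(cl) mean(!m$positive[m$label == cl]), numeric(1L))
  pooled <- if (any(!pos)) mean(!m$positive[!pos]) else NA_real_
  structure(list(n = nrow(m), confusion = confusion, sensitivity = sens,
                 specificity = c(spec, pooled = pooled),
                 per_class = table(m$label)),
            class = "crest_eval")
}

#' @export
print.crest_eval <- function(x, ...) {
  cat("CREST constellation screen evaluation (n = ", x$n, ")\n\n", sep = "")
  print(x$confusion)
  cat("\nsensitivity (positives):", format(x$sensitivity, digits = 4), "\n")
  cat("specificity:\n")
  for (nm in names(x$specificity))
    cat(sprintf("  %-18s %s\n", nm,
                format(x$specificity[[nm]], digits = 4)))
  invisible(x)
}
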