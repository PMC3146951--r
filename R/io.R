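# File formats. All residue coordinates throughout the package are 1-based and
# inclusive on both ends; every tabular writer states this in its '#' header.

#' Standard and ambiguity amino-acid letters
#'
#' The twenty standard residues, and the ambiguity/nonstandard letters
#' (X, B, Z, U, O, J) that are accepted in input sequences. Ambiguity letters
#' match pattern wildcards but never pattern literals.
#'
#' @format Character vectors.
#' @export
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname AA_STANDARD
#' @export
AA_AMBIGUOUS <- c("X", "B", "Z", "U", "O", "J")

aa_allowed <- function() c(AA_STANDARD, AA_AMBIGUOUS)

#' Assemble a set of protein records
#'
#' @param id Character vector of unique identifiers (no whitespace).
#' @param sequence Character vector of uppercase amino-acid sequences.
#' @param description Optional free-text descriptions (default "").
#' @return A `data.frame` with columns `id`, `description`, `sequence`.
#' @export
protein_records <- function(id, sequence, description = "") {
  rec <- data.frame(id = as.character(id),
                    description = rep_len(as.character(description), length(id)),
                    sequence = toupper(as.character(sequence)),
                    stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

validate_records <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "description", "sequence") %in% names(records)))
  if (anyDuplicated(records$id))
    stop("duplicate protein id(s): ",
         paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  if (any(grepl("\\s", records$id)) || any(records$id == ""))
    stop("protein ids must be non-empty and contain no whitespace")
  if (any(nchar(records$sequence) < 1L))
    stop("empty sequence for id(s): ",
         paste(records$id[nchar(records$sequence) < 1L], collapse = ", "))
  bad <- !grepl(paste0("^[", paste(aa_allowed(), collapse = ""), "]+$"),
                records$sequence)
  if (any(bad))
    stop("illegal characters in sequence for id(s): ",
         paste(records$id[bad], collapse = ", "))
  invisible(records)
}

#' Read a protein FASTA file
#'
#' Multi-line records and CRLF line endings are accepted; sequences are
#' uppercased; terminal or internal `*` stop characters are stripped with a
#' warning. Gap characters (`-`, `.`) and any letter outside the standard and
#' ambiguity alphabets are parse errors naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` of records (columns `id`, `description`, `sequence`).
#' @export
read_fasta <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  keep <- !grepl("^\\s*$", lines) | seq_along(lines) < length(lines)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur <- NULL; cur_seq <- character(0); cur_line <- 0L
  flush <- function() {
    if (is.null(cur)) return()
    s <- toupper(paste(cur_seq, collapse = ""))
    if (grepl("\\*", s)) {
      warning("stop character '*' stripped from sequence of '", cur$id, "'")
      s <- gsub("*", "", s, fixed = TRUE)
    }
    if (nchar(s) == 0L)
      stop("FASTA parse error at line ", cur_line, ": empty sequence for '",
           cur$id, "'")
    ids <<- c(ids, cur$id); descs <<- c(descs, cur$desc); seqs <<- c(seqs, s)
  }
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl("^>", ln)) {
      flush()
      hdr <- sub("^>\\s*", "", ln)
      if (hdr == "")
        stop("FASTA parse error at line ", k, ": empty header")
      id <- sub("\\s.*$", "", hdr)
      desc <- sub("^\\S+\\s*", "", hdr)
      cur <- list(id = id, desc = desc); cur_seq <- character(0); cur_line <- k
    } else if (grepl("^\\s*$", ln)) {
      next
    } else {
      if (is.null(cur))
        stop("FASTA parse error at line ", k, ": sequence before any header")
      if (grepl("[-.]", ln))
        stop("FASTA parse error at line ", k, ": gap character in sequence")
      if (grepl("\\s", trimws(ln)))
        stop("FASTA parse error at line ", k, ": whitespace inside sequence")
      ok <- paste0("^[", paste(aa_allowed(), collapse = ""), "*]+$")
      if (!grepl(ok, toupper(trimws(ln))))
        stop("FASTA parse error at line ", k, ": illegal character in sequence")
      cur_seq <- c(cur_seq, trimws(ln))
    }
  }
  flush()
  if (length(ids) == 0L) stop("FASTA parse error: no records in '", path, "'")
  rec <- data.frame(id = ids, description = descs, sequence = seqs,
                    stringsAsFactors = FALSE)
  validate_records(rec)
  rec
}

#' Write protein records as FASTA
#'
#' @param records Record `data.frame` as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_records(records)
  con <- file(path, open = "wb")  # fixed \n endings keep writers byte-stable
  on.exit(close(con))
  for (r in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[r]))
      paste0(">", records$id[r], " ", records$description[r])
    else paste0(">", records$id[r])
    writeLines(hdr, con)
    s <- records$sequence[r]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Validate a topology (ordered transmembrane segments)
#'
#' @param topology `data.frame` with columns `index`, `start`, `end`.
#' @param sequence_length Optional sequence length to check bounds against.
#' @param min_tm_len Minimum admissible segment length (0 disables the check;
#'   the hydropathy predictor enforces its own minimum).
#' @return The topology, invisibly; errors describe the violated invariant.
#' @export
validate_topology <- function(topology, sequence_length = NULL, min_tm_len = 0L) {
  stopifnot(is.data.frame(topology),
            all(c("index", "start", "end") %in% names(topology)))
  n <- nrow(topology)
  if (n == 0L) return(invisible(topology))
  if (any(topology$start > topology$end))
    stop("topology invalid: segment start > end")
  if (any(topology$start < 1L))
    stop("topology invalid: segment start < 1")
  if (!identical(as.integer(topology$index), seq_len(n)))
    stop("topology invalid: segment indices must be 1..n consecutive")
  if (is.unsorted(topology$start, strictly = TRUE))
    stop("topology invalid: segments must be sorted by start")
  if (n > 1L && any(topology$start[-1L] <= topology$end[-n]))
    stop("topology invalid: overlapping segments")
  if (min_tm_len > 0L && any(topology$end - topology$start + 1L < min_tm_len))
    stop("topology invalid: segment shorter than ", min_tm_len, " residues")
  if (!is.null(sequence_length) && any(topology$end > sequence_length))
    stop("topology invalid: segment end beyond sequence length ",
         sequence_length)
  invisible(topology)
}

empty_topology <- function() {
  data.frame(index = integer(0), start = integer(0), end = integer(0))
}

#' Read a transmembrane topology table
#'
#' Tab-separated columns `protein_id`, `tm_index`, `start`, `end` (an optional
#' fifth orientation column is ignored), 1-based inclusive coordinates, one row
#' per predicted segment. Lines starting with `#` and an optional header line
#' are skipped. The format matches what a Phobius-style predictor's output is
#' usually reduced to; [predict_tm()] writes the same dialect.
#'
#' @param path Path to the table.
#' @return Named list (by protein id) of topology `data.frame`s with columns
#'   `index`, `start`, `end`.
#' @export
read_topology_table <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  rows <- which(!grepl("^#", lines) & !grepl("^\\s*$", lines))
  if (length(rows) == 0L) return(structure(list(), names = character(0)))
  first <- strsplit(lines[rows[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(first) >= 4L && is.na(suppressWarnings(as.integer(first[2L]))))
    rows <- rows[-1L]  # header line
  out <- list()
  for (k in rows) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L)
      stop("topology table error at line ", k, ": expected >= 4 tab-separated ",
           "columns (protein_id, tm_index, start, end)")
    idx <- suppressWarnings(as.integer(f[2L]))
    a <- suppressWarnings(as.integer(f[3L]))
    b <- suppressWarnings(as.integer(f[4L]))
    if (anyNA(c(idx, a, b)))
      stop("topology table error at line ", k, ": non-integer coordinate")
    if (a > b)
      stop("topology table error at line ", k, ": start > end")
    out[[f[1L]]] <- rbind(out[[f[1L]]],
                          data.frame(index = idx, start = a, end = b))
  }
  for (pid in names(out)) {
    topo <- out[[pid]][order(out[[pid]]$start), , drop = FALSE]
    rownames(topo) <- NULL
    res <- tryCatch(validate_topology(topo),
                    error = function(e) stop("topology table error for ",
                                             "protein '", pid, "': ",
                                             conditionMessage(e), call. = FALSE))
    out[[pid]] <- topo
  }
  out
}

#' Write a transmembrane topology table
#'
#' @param topologies Named list of topology `data.frame`s.
#' @param path Output path.
#' @param stamp Optional character vector of `#` provenance header lines
#'   (see [version_stamp()]).
#' @export
write_topology_table <- function(topologies, path, stamp = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(stamp,
               "# coordinates are 1-based, inclusive on both ends",
               "protein_id\ttm_index\tstart\tend"), con)
  for (pid in names(topologies)) {
    topo <- topologies[[pid]]
    if (nrow(topo) == 0L) next
    writeLines(sprintf("%s\t%d\t%d\t%d", pid, topo$index, topo$start, topo$end),
               con)
  }
  invisible(path)
}

#' Write constellation calls
#'
#' Deterministic column order `protein_id, sxxxh_tm, sxxxh_start, hxxxh_tm,
#' hxxxh_start, tm_separation, passed, mode` and stable row order by
#' `(protein_id, sxxxh_start)`; identical input yields byte-identical files.
#'
#' @param calls Call `data.frame` as returned by [call_constellations()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param stamp Optional `#` provenance header lines (TSV only).
#' @export
write_calls <- function(calls, path, format = c("tsv", "json"), stamp = NULL) {
  format <- match.arg(format)
  cols <- c("protein_id", "sxxxh_tm", "sxxxh_start", "hxxxh_tm", "hxxxh_start",
            "tm_separation", "passed", "mode")
  if (nrow(calls) > 0L) {
    calls <- calls[order(calls$protein_id, calls$sxxxh_start,
                         calls$hxxxh_start), cols, drop = FALSE]
  } else {
    calls <- calls[, cols, drop = FALSE]
  }
  if (format == "json") {
    jsonlite::write_json(calls, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(stamp,
               "# coordinates are 1-based, inclusive on both ends",
               paste(cols, collapse = "\t")), con)
  if (nrow(calls) > 0L)
    writeLines(do.call(sprintf,
                       c(list("%s\t%d\t%d\t%d\t%d\t%d\t%s\t%s"),
                         lapply(cols, function(cl) {
                           v <- calls[[cl]]
                           if (is.logical(v)) tolower(as.character(v)) else v
                         }))), con)
  invisible(path)
}
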