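# Orchestration: generate -> (predict TM | load topology) -> filter -> scan
# -> classify -> evaluate as one reproducible run. A single global seed fans
# out to per-stage derived seeds so stages can rerun independently yet
# reproducibly. No output file carries a timestamp: identical resolved
# config + seed gives byte-identical run directories.

crestscan_version <- function() {
  as.character(utils::packageVersion("crestscan"))
}

#' Full run configuration
#'
#' Nested per-stage configuration with complete defaults: a fully-default
#' configuration runs end-to-end on generated data. `topology_source` selects
#' which topology the scan consumes: `"planted"` (generator truth),
#' `"predicted"` (hydropathy predictor) or a path to an external topology
#' table.
#'
#' @param generator A [generator_spec()].
#' @param hydropathy A [hydropathy_config()].
#' @param scan A [scan_config()].
#' @param filter List with `enabled`, `min_len`, `identity`,
#'   `score_per_column`, `length_coverage`.
#' @param n_per_class Generated proteins per label.
#' @param topology_source `"planted"`, `"predicted"`, or a file path.
#' @param seed Integer master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(generator = generator_spec(),
                       hydropathy = hydropathy_config(),
                       scan = scan_config(),
                       filter = list(enabled = TRUE, min_len = 100L,
                                     identity = 0.95, score_per_column = 1.0,
                                     length_coverage = 0.5),
                       n_per_class = 20L,
                       topology_source = "planted",
                       seed = 1L) {
  cfg <- structure(list(generator = generator, hydropathy = hydropathy,
                        scan = scan, filter = filter,
                        n_per_class = as.integer(n_per_class),
                        topology_source = topology_source,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!inherits(config$generator, "generator_spec"))
    stop("config invalid: generator must be a generator_spec")
  if (!inherits(config$hydropathy, "hydropathy_config"))
    stop("config invalid: hydropathy must be a hydropathy_config")
  if (!inherits(config$scan, "scan_config"))
    stop("config invalid: scan must be a scan_config")
  needed <- c("enabled", "min_len", "identity", "score_per_column",
              "length_coverage")
  if (!all(needed %in% names(config$filter)))
    stop("config invalid: filter must name ",
         paste(needed, collapse = ", "))
  if (config$n_per_class < 1L)
    stop("config invalid: n_per_class must be >= 1")
  if (!(config$topology_source %in% c("planted", "predicted")) &&
      !is.character(config$topology_source))
    stop("config invalid: topology_source")
  if (is.na(config$seed)) stop("config invalid: seed must be an integer")
  invisible(config)
}

#' @export
print.run_config <- function(x, ...) {
  cat(config_text(x), sep = "\n")
  invisible(x)
}

# Deterministic flat key-value rendering; also the on-disk snapshot format.
config_text <- function(config) {
  num <- function(v) paste(format(v, digits = 15), collapse = ",")
  alpha <- function(a) paste(sprintf("%s:%s", names(a), format(a, digits = 15)),
                             collapse = ",")
  g <- config$generator; h <- config$hydropathy; s <- config$scan
  c(sprintf("generator.n_tm = %d", g$n_tm),
    sprintf("generator.tm_length_range = %s", num(g$tm_length_range)),
    sprintf("generator.loop_length_range = %s", num(g$loop_length_range)),
    sprintf("generator.hydrophobic_alphabet = %s",
            alpha(g$hydrophobic_alphabet)),
    sprintf("generator.loop_alphabet = %s", alpha(g$loop_alphabet)),
    sprintf("generator.extra_tm_pairs = %d", g$extra_tm_pairs),
    sprintf("hydropathy.scale = %s", alpha(h$scale)),
    sprintf("hydropathy.window = %d", h$window),
    sprintf("hydropathy.threshold = %s", num(h$threshold)),
    sprintf("hydropathy.min_tm_len = %d", h$min_tm_len),
    sprintf("hydropathy.merge_gap = %d", h$merge_gap),
    sprintf("scan.c_half_flank = %d", s$c_half_flank),
    sprintf("scan.n_half_flank = %d", s$n_half_flank),
    sprintf("scan.min_tm_separation = %d", s$min_tm_separation),
    sprintf("scan.naive_spacer_min = %d", s$naive_spacer_min),
    sprintf("scan.naive_spacer_max = %d", s$naive_spacer_max),
    sprintf("scan.mode = %s", s$mode),
    sprintf("filter.enabled = %s", tolower(config$filter$enabled)),
    sprintf("filter.min_len = %d", as.integer(config$filter$min_len)),
    sprintf("filter.identity = %s", num(config$filter$identity)),
    sprintf("filter.score_per_column = %s",
            num(config$filter$score_per_column)),
    sprintf("filter.length_coverage = %s", num(config$filter$length_coverage)),
    sprintf("dataset.n_per_class = %d", config$n_per_class),
    sprintf("topology_source = %s", config$topology_source),
    sprintf("seed = %d", config$seed))
}

#' Read a run configuration file
#'
#' Flat `section.key = value` lines (the same format [run_all()] snapshots);
#' `#` comments and blank lines ignored; unknown keys are errors. Values
#' given in the file override defaults.
#'
#' @param path Path to the configuration file.
#' @return A [run_config()].
#' @export
read_config <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z_.]+)\\s*=\\s*(.*?)\\s*$",
                                  lines))
  bad <- vapply(kv, length, integer(1L)) != 3L
  if (any(bad))
    stop("config parse error at line: ", lines[bad][1L])
  keys <- vapply(kv, `[[`, character(1L), 2L)
  vals <- vapply(kv, `[[`, character(1L), 3L)
  get <- function(key, default) {
    if (!key %in% keys) return(default)
    vals[match(key, keys)]
  }
  ints <- function(v) as.integer(strsplit(v, ",", fixed = TRUE)[[1L]])
  alpha <- function(v) {
    parts <- strsplit(strsplit(v, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[[`, character(1L), 2L)),
                    vapply(parts, `[[`, character(1L), 1L))
  }
  known <- c("generator.n_tm", "generator.tm_length_range",
             "generator.loop_length_range", "generator.hydrophobic_alphabet",
             "generator.loop_alphabet", "generator.extra_tm_pairs",
             "hydropathy.scale", "hydropathy.window", "hydropathy.threshold",
             "hydropathy.min_tm_len", "hydropathy.merge_gap",
             "scan.c_half_flank", "scan.n_half_flank",
             "scan.min_tm_separation", "scan.naive_spacer_min",
             "scan.naive_spacer_max", "scan.mode", "filter.enabled",
             "filter.min_len", "filter.identity", "filter.score_per_column",
             "filter.length_coverage", "dataset.n_per_class",
             "topology_source", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("config validation error: unknown key(s) ",
         paste(unknown, collapse = ", "))
  dg <- generator_spec(); dh <- hydropathy_config(); ds <- scan_config()
  run_config(
    generator = generator_spec(
      n_tm = as.integer(get("generator.n_tm", dg$n_tm)),
      tm_length_range = ints(get("generator.tm_length_range",
                                 paste(dg$tm_length_range, collapse = ","))),
      loop_length_range = ints(get("generator.loop_length_range",
                                   paste(dg$loop_length_range,
                                         collapse = ","))),
      hydrophobic_alphabet = if ("generator.hydrophobic_alphabet" %in% keys)
        alpha(get("generator.hydrophobic_alphabet", ""))
      else dg$hydrophobic_alphabet,
      loop_alphabet = if ("generator.loop_alphabet" %in% keys)
        alpha(get("generator.loop_alphabet", "")) else dg$loop_alphabet,
      extra_tm_pairs = as.integer(get("generator.extra_tm_pairs",
                                      dg$extra_tm_pairs))),
    hydropathy = hydropathy_config(
      scale = if ("hydropathy.scale" %in% keys)
        alpha(get("hydropathy.scale", "")) else dh$scale,
      window = as.integer(get("hydropathy.window", dh$window)),
      threshold = as.numeric(get("hydropathy.threshold", dh$threshold)),
      min_tm_len = as.integer(get("hydropathy.min_tm_len", dh$min_tm_len)),
      merge_gap = as.integer(get("hydropathy.merge_gap", dh$merge_gap))),
    scan = scan_config(
      c_half_flank = as.integer(get("scan.c_half_flank", ds$c_half_flank)),
      n_half_flank = as.integer(get("scan.n_half_flank", ds$n_half_flank)),
      min_tm_separation = as.integer(get("scan.min_tm_separation",
                                         ds$min_tm_separation)),
      naive_spacer_min = as.integer(get("scan.naive_spacer_min",
                                        ds$naive_spacer_min)),
      naive_spacer_max = as.integer(get("scan.naive_spacer_max",
                                        ds$naive_spacer_max)),
      mode = get("scan.mode", ds$mode)),
    filter = list(enabled = tolower(get("filter.enabled", "true")) == "true",
                  min_len = as.integer(get("filter.min_len", 100L)),
                  identity = as.numeric(get("filter.identity", 0.95)),
                  score_per_column = as.numeric(get("filter.score_per_column",
                                                    1.0)),
                  length_coverage = as.numeric(get("filter.length_coverage",
                                                   0.5))),
    n_per_class = as.integer(get("dataset.n_per_class", 20L)),
    topology_source = get("topology_source", "planted"),
    seed = as.integer(get("seed", 1L)))
}

#' Provenance record for output headers
#'
#' Tool version, resolved-configuration hash (md5 of the flat snapshot text)
#' and master seed, formatted as `#` comment lines for embedding in every
#' tabular output. The hash changes iff the resolved configuration changes;
#' nothing time-dependent is included.
#'
#' @param config A [run_config()].
#' @return Character vector of `#` lines.
#' @export
version_stamp <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(config_text(config), tmp)
  hash <- unname(tools::md5sum(tmp))
  c(sprintf("# crestscan %s", crestscan_version()),
    sprintf("# config_hash=%s", hash),
    sprintf("# seed=%d", config$seed))
}

# Stable per-stage seed derived from the master seed and the stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 10000L
  (as.integer(seed) * 10007L + h) %% .Machine$integer.max
}

#' Run the full pipeline
#'
#' generate -> topology (planted / predicted / external) -> filter -> scan ->
#' classify -> evaluate, writing every intermediate plus a resolved-config
#' snapshot and a log into `out_dir`. Identical configuration and seed yield
#' byte-identical directory contents.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `report` (a `crest_eval`), `calls`,
#'   `records`, `topologies` and `paths`.
#' @export
run_all <- function(config = run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- version_stamp(config)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    message("[crestscan] ", msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  writeLines(config_text(config), file.path(out_dir, "config.resolved"))

  say("generate: %d proteins per class (seed %d)", config$n_per_class,
      stage_seed(config$seed, "generate"))
  ds <- stage("generate",
              generate_dataset(config$n_per_class, config$generator,
                               seed = stage_seed(config$seed, "generate"),
                               dir = out_dir, stamp = stamp))

  records <- ds$records
  if (isTRUE(config$filter$enabled)) {
    say("filter: min_len=%d identity=%.2f", config$filter$min_len,
        config$filter$identity)
    records <- stage("filter", {
      kept <- remove_fragments(records, config$filter$min_len)
      dd <- dedupe(kept, config$filter$identity)
      utils::write.table(dd$assignments,
                         file.path(out_dir, "clusters.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      dd$records[order(dd$records$id), , drop = FALSE]
    })
    write_fasta(records, file.path(out_dir, "proteins.filtered.fasta"))
  }

  say("topology: source=%s", config$topology_source)
  topologies <- stage("topology", {
    if (identical(config$topology_source, "planted")) {
      ds$topologies[records$id]
    } else if (identical(config$topology_source, "predicted")) {
      topo <- predict_tm_all(records, config$hydropathy)
      write_topology_table(topo, file.path(out_dir, "topology.predicted.tsv"),
                           stamp = stamp)
      topo
    } else {
      read_topology_table(config$topology_source)
    }
  })

  say("scan + classify: mode=%s", config$scan$mode)
  cls <- stage("classify", classify_all(records, topologies, config$scan))
  write_calls(cls$calls, file.path(out_dir, "calls.tsv"), "tsv", stamp = stamp)

  say("evaluate")
  truth <- ds$truth[ds$truth$id %in% records$id, , drop = FALSE]
  report <- stage("evaluate", evaluate(truth, cls$predictions))

  pos_ids <- cls$predictions$id[cls$predictions$positive]
  groups <- if (length(pos_ids) >= 1L)
    stage("group", group_by_coverage(
      records[records$id %in% pos_ids, , drop = FALSE],
      config$filter$score_per_column, config$filter$length_coverage))
  else data.frame(representative_id = character(0), member_id = character(0))
  utils::write.table(groups, file.path(out_dir, "candidate_groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  jsonlite::write_json(
    list(tool = sprintf("crestscan %s", crestscan_version()),
         seed = config$seed,
         n = report$n,
         sensitivity = report$sensitivity,
         specificity = as.list(report$specificity),
         per_class = as.list(report$per_class),
         n_candidate_groups = length(unique(groups$representative_id))),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  say("done: %s", out_dir)
  invisible(list(report = report, calls = cls$calls, records = records,
                 topologies = topologies,
                 paths = list(out_dir = out_dir,
                              calls = file.path(out_dir, "calls.tsv"),
                              report = file.path(out_dir, "report.json"))))
}
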