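# Orchestration: chunked, optionally parallel runs with deterministic
# output, and the classed linkage result.

#' Partition a table into chunks that keep equal keys together
#'
#' Splits `records` into chunks of roughly `chunk_size` rows such that all
#' rows sharing a key value land in the same chunk (a requirement for
#' per-chunk key joins to lose no candidate). Every row appears in exactly
#' one chunk.
#'
#' @param records data.frame.
#' @param key vector of key values, one per row (or a column name).
#' @param chunk_size target rows per chunk.
#' @return list of data.frames (empty list for empty input).
#' @export
partition_stream <- function(records, key, chunk_size = 10000L) {
  if (nrow(records) == 0L) return(list())
  if (is.character(key) && length(key) == 1L && key %in% names(records))
    key <- records[[key]]
  key <- as.character(key)
  key[is.na(key)] <- ""
  sizes <- table(key)
  keys <- names(sizes)
  # greedy fill in key order: deterministic, each key in exactly one chunk
  chunk_of <- integer(length(keys))
  cur <- 1L
  acc <- 0L
  for (i in seq_along(keys)) {
    if (acc >= chunk_size && acc > 0L) {
      cur <- cur + 1L
      acc <- 0L
    }
    chunk_of[i] <- cur
    acc <- acc + as.integer(sizes[i])
  }
  assign_chunk <- chunk_of[match(key, keys)]
  idx <- split(seq_len(nrow(records)), assign_chunk)
  lapply(idx, function(i) records[i, , drop = FALSE])
}

.auto_workers <- function(workers, n_chunks) {
  if (identical(workers, "auto")) {
    cores <- tryCatch(parallel::detectCores(), error = function(e) 1L)
    if (is.na(cores)) cores <- 1L
    workers <- max(1L, cores - 1L)
  }
  workers <- as.integer(workers)
  if (is.na(workers) || workers < 1L)
    stop("worker_count must be a positive integer or \"auto\"",
         call. = FALSE)
  min(workers, max(1L, n_chunks))
}

#' Link a patient registry against a mortality file
#'
#' The main entry point. Runs the chosen strategy over the two tables and
#' returns a classed result. The `"dld"` strategy cleans both sides,
#' generates candidate pairs by two-pass blocking (birth date; 4+4
#' name-prefix key), computes per-field restricted Damerau-Levenshtein
#' distances, validates each candidate against the thresholds and selects
#' the most pertinent pair per local record. The `"direct"` strategy is the
#' exact-match reference (minimal cleaning, strict equality).
#'
#' The mortality file is processed in chunks whose size bounds the working
#' set; chunks can be scored on parallel workers. Output is sorted, so the
#' retained pair set is identical for any worker count and chunk size.
#'
#' @param local `person_records` data.frame (see [read_person_table()]).
#' @param fnmd `mortality_records` data.frame (see [read_mortality_table()]).
#' @param strategy `"dld"` (default) or `"direct"`.
#' @param thresholds a [dld_thresholds()].
#' @param chunk_size mortality rows per chunk (default 50000).
#' @param workers number of parallel workers, or `"auto"` to use all
#'   available cores minus one (capped at the number of chunks).
#' @param home_country home-country token used for `country_group`.
#' @return object of class `linkage`: a list with `pairs` (data.frame of
#'   retained pairs with distances, `selected`, `ambiguous`, `death_date`),
#'   `summary` (named counts), `strategy`, `thresholds`, `call`. A local
#'   record is classified deceased iff it has at least one selected pair.
#' @export
#' @examples
#' coh <- simulate_cohort(200, seed = 1)
#' fit <- link_records(coh$person, coh$mortality)
#' fit
#' head(matched_ids(fit))
link_records <- function(local, fnmd, strategy = c("dld", "direct"),
                         thresholds = dld_thresholds(),
                         chunk_size = 50000L, workers = 1L,
                         home_country = "france") {
  strategy <- match.arg(strategy)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    stop("chunk_size must be a positive integer", call. = FALSE)
  if (!inherits(thresholds, "dld_thresholds"))
    stop("thresholds must be built with dld_thresholds()", call. = FALSE)

  if (strategy == "direct") {
    res <- .run_direct(local, fnmd)
  } else {
    nw <- .auto_workers(workers, ceiling(nrow(fnmd) / chunk_size))
    chunker <- function(fc) partition_stream(fc, fc$key_date, chunk_size)
    res <- .run_dld(local, fnmd, thresholds, home_country,
                    chunks = chunker, workers = nw)
  }
  structure(list(pairs = res$pairs, summary = res$counts,
                 strategy = strategy, thresholds = thresholds,
                 call = match.call()),
            class = "linkage")
}

#' Local record ids classified as deceased by a linkage
#'
#' @param object a `linkage` object.
#' @return character vector of local ids with at least one selected pair.
#' @export
matched_ids <- function(object) {
  sort(unique(object$pairs$local_id[object$pairs$selected]))
}

#' @export
print.linkage <- function(x, ...) {
  s <- x$summary
  cat("Record linkage (", x$strategy, " strategy)\n", sep = "")
  cat("  local records:    ", s[["n_local"]], "\n", sep = "")
  cat("  mortality records:", s[["n_fnmd"]], "\n")
  if (x$strategy == "dld") {
    cat("  candidate pairs:  ", s[["n_candidates"]],
        " (date pass ", s[["n_candidates_date"]],
        ", name pass ", s[["n_candidates_name"]], ")\n", sep = "")
  }
  cat("  validated pairs:  ", s[["n_validated"]], "\n", sep = "")
  cat("  selected pairs:   ", s[["n_selected"]], "\n", sep = "")
  cat("  locals linked:    ", length(matched_ids(x)), "\n", sep = "")
  invisible(x)
}

#' @export
summary.linkage <- function(object, ...) {
  s <- as.list(object$summary)
  s$n_linked_locals <- length(matched_ids(object))
  s$n_ambiguous <- sum(object$pairs$ambiguous)
  if (object$strategy == "dld") {
    cross <- as.numeric(s$n_local) * as.numeric(s$n_fnmd)
    s$comparison_reduction <- if (s$n_candidates > 0)
      cross / s$n_candidates else Inf
  }
  structure(s, class = "summary.linkage", strategy = object$strategy)
}

#' @export
print.summary.linkage <- function(x, ...) {
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(format(nm, width = 22), format(v, big.mark = ","), "\n")
  }
  invisible(x)
}

#' Assemble a run configuration
#'
#' Mirrors the command-line flags: paths, mappings, strategy, thresholds,
#' chunking and worker settings. [run_linkage()] validates the
#' configuration before touching any file.
#'
#' @param local_path,fnmd_path input file paths.
#' @param out_path output pair-file path.
#' @param local_mapping,fnmd_mapping [column_mapping()] objects.
#' @param strategy `"dld"` or `"direct"`.
#' @param thresholds a [dld_thresholds()].
#' @param chunk_size,workers see [link_records()].
#' @param home_country home-country token.
#' @param seed integer seed (used only by simulation subcommands).
#' @return object of class `run_config`.
#' @export
run_config <- function(local_path, fnmd_path, out_path = NULL,
                       local_mapping = column_mapping(),
                       fnmd_mapping = column_mapping(),
                       strategy = c("dld", "direct"),
                       thresholds = dld_thresholds(),
                       chunk_size = 50000L, workers = 1L,
                       home_country = "france", seed = 1L) {
  strategy <- match.arg(strategy)
  if (!inherits(local_mapping, "column_mapping") ||
      !inherits(fnmd_mapping, "column_mapping"))
    stop("mappings must be column_mapping objects", call. = FALSE)
  if (!inherits(thresholds, "dld_thresholds"))
    stop("thresholds must be built with dld_thresholds()", call. = FALSE)
  chunk_size <- as.integer(chunk_size)
  if (is.na(chunk_size) || chunk_size < 1L)
    stop("chunk_size must be a positive integer", call. = FALSE)
  if (!identical(workers, "auto")) {
    w <- as.integer(workers)
    if (is.na(w) || w < 1L)
      stop("workers must be a positive integer or \"auto\"", call. = FALSE)
  }
  structure(list(local_path = local_path, fnmd_path = fnmd_path,
                 out_path = out_path, local_mapping = local_mapping,
                 fnmd_mapping = fnmd_mapping, strategy = strategy,
                 thresholds = thresholds, chunk_size = chunk_size,
                 workers = workers, home_country = home_country,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run a linkage from a configuration
#'
#' Reads the two registries, runs [link_records()], optionally writes the
#' pair file, and returns the `linkage` object. Configuration errors are
#' raised before any file is read.
#'
#' @param config a [run_config()].
#' @return a `linkage` object (invisibly when a pair file is written).
#' @export
run_linkage <- function(config) {
  if (!inherits(config, "run_config"))
    stop("config must be built with run_config()", call. = FALSE)
  local <- read_person_table(config$local_path, config$local_mapping)
  fnmd <- read_mortality_table(config$fnmd_path, config$fnmd_mapping)
  fit <- link_records(local, fnmd, strategy = config$strategy,
                      thresholds = config$thresholds,
                      chunk_size = config$chunk_size,
                      workers = config$workers,
                      home_country = config$home_country)
  if (!is.null(config$out_path)) {
    write_pairs(fit$pairs, config$out_path)
    return(invisible(fit))
  }
  fit
}
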