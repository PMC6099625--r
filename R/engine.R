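# Execution engine: scatter-gather over an assigned corpus. Rank 0 plans,
# workers initialise each plugin once and process exactly their assigned
# files, outputs and timing logs are gathered afterwards. Files are the unit
# of work because real NER tools pay a large initialisation cost per pass.

.pluginRegistry <- new.env(parent = emptyenv())
assign("order", character(), envir = .pluginRegistry)

#' Plugin registry
#'
#' A process-wide registry of annotator plugins, so runs can refer to
#' plugins by name. Registration order is preserved (and determines output
#' ordering in reports). Registering a second plugin under an existing name
#' is an error; use \code{resetPlugins} first.
#'
#' @param plugin a \code{\link{Plugin}}.
#' @return \code{registerPlugin} invisibly returns the plugin's name;
#'   \code{listPlugins} returns the registered names in registration order;
#'   \code{getPlugin} returns a \code{Plugin}; \code{resetPlugins} clears
#'   the registry.
#' @export
registerPlugin <- function(plugin) {
  stopifnot(is(plugin, "Plugin"))
  nm <- pluginName(plugin)
  if (nm %in% get("order", envir = .pluginRegistry))
    stop("a plugin named ", dQuote(nm, FALSE), " is already registered",
         call. = FALSE)
  assign(nm, plugin, envir = .pluginRegistry)
  assign("order", c(get("order", envir = .pluginRegistry), nm),
         envir = .pluginRegistry)
  invisible(nm)
}

#' @rdname registerPlugin
#' @export
listPlugins <- function() get("order", envir = .pluginRegistry)

#' @rdname registerPlugin
#' @param name a registered plugin name.
#' @export
getPlugin <- function(name) {
  if (!name %in% get("order", envir = .pluginRegistry))
    stop("no plugin named ", dQuote(name, FALSE), " is registered",
         call. = FALSE)
  get(name, envir = .pluginRegistry)
}

#' @rdname registerPlugin
#' @export
resetPlugins <- function() {
  rm(list = ls(envir = .pluginRegistry), envir = .pluginRegistry)
  assign("order", character(), envir = .pluginRegistry)
  invisible(NULL)
}

.resolvePlugins <- function(plugins) {
  if (is(plugins, "Plugin")) plugins <- list(plugins)
  plugins <- lapply(plugins, function(p) {
    if (is.character(p)) getPlugin(p) else p
  })
  nms <- vapply(plugins, pluginName, character(1))
  if (anyDuplicated(nms)) stop("duplicate plugin names", call. = FALSE)
  stats::setNames(plugins, nms)
}

# Process the files of one rank: init each plugin once, then annotate and
# write one merged PubTator output file per input file.
.rankWorker <- function(rank, files, plugins, outDir) {
  perFile <- list(); inits <- list(); fails <- list()
  states <- lapply(plugins, function(p) {
    t0 <- nowSeconds()
    st <- p@init()
    inits[[length(inits) + 1L]] <<- data.frame(
      rank = rank, plugin = pluginName(p), seconds = nowSeconds() - t0,
      stringsAsFactors = FALSE)
    st
  })
  for (f in files) {
    res <- tryCatch({
      docs <- readPubTator(f)
      annotated <- lapply(docs, function(ad) {
        doc <- document(ad)
        per <- lapply(seq_along(plugins), function(j) {
          p <- plugins[[j]]
          key <- paste(f, pluginName(p), sep = "\t")
          t0 <- nowSeconds()
          ann <- p@annotate(doc, states[[j]])
          perFile[[key]] <<- data.frame(
            file_id = f, rank = rank, plugin = pluginName(p),
            seconds = (perFile[[key]]$seconds %||% 0) + (nowSeconds() - t0),
            stringsAsFactors = FALSE)
          ann
        })
        mergeAnnotations(doc, per)
      })
      writePubTator(annotated, file.path(outDir, basename(f)))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      fails[[length(fails) + 1L]] <- data.frame(
        file_id = f, rank = rank, message = res, stringsAsFactors = FALSE)
      # drop partial timings for the failed file
      perFile <- perFile[!startsWith(names(perFile), paste0(f, "\t"))]
    }
  }
  list(perFile = perFile, inits = inits, fails = fails)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run annotator plugins over a corpus in parallel
#'
#' The full pipeline: measure the corpus, compute a static
#' \code{\link{Assignment}} with the chosen strategy, then have each worker
#' rank initialise every plugin exactly once and process exactly its
#' assigned files, writing one merged PubTator output file per input file
#' (same basename, in \code{outDir}). Per-file and per-init timings are
#' gathered into a \code{\link{TimeLog}}.
#'
#' The annotation output is a pure function of the corpus and plugins: it
#' is identical — as a set of (doc id, start, end, type, concept) tuples —
#' across backends, strategies and worker counts; only the timing
#' attribution changes.
#'
#' Backends: \code{"serial"} executes all ranks in-process (rank
#' attribution is still recorded); \code{"local"} forks one OS process per
#' rank via \code{parallel::mclapply}. A message-passing multi-node backend
#' is not provided; the plan-file interface (\code{\link{writePlan}})
#' supports external MPI launchers that implement the same scatter-gather
#' contract.
#'
#' @param paths character vector of PubTator input file paths.
#' @param plugins list of \code{\link{Plugin}} objects or registered plugin
#'   names.
#' @param strategy \code{"short_board"}, \code{"round_robin"} or
#'   \code{"modulo"}.
#' @param nProcs number of worker ranks.
#' @param backend \code{"serial"} or \code{"local"}.
#' @param outDir output directory (created if absent).
#' @param shuffleSeed optional seed for the modulo strategy's shuffle.
#' @param strict logical; when \code{TRUE} any failed file raises an error
#'   after the run report is complete. When \code{FALSE} (default) failures
#'   are isolated: they are recorded in the TimeLog and remaining files are
#'   still processed.
#' @return A \code{\link{TimeLog}}.
#' @export
runEngine <- function(paths, plugins, strategy = "short_board", nProcs = 1L,
                      backend = c("serial", "local", "mpi"),
                      outDir, shuffleSeed = NULL, strict = FALSE) {
  backend <- match.arg(backend)
  if (backend == "mpi")
    stop("the message-passing backend requires an external MPI launcher; ",
         "use backend = 'serial' or 'local' here and writePlan() to drive ",
         "an MPI harness", call. = FALSE)
  nProcs <- as.integer(nProcs)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  plugins <- .resolvePlugins(plugins)
  caps <- vapply(plugins, function(p) p@spec@maxProcsPerNode, integer(1))
  if (any(nProcs > caps))
    warning("nProcs = ", nProcs, " exceeds the per-node cap of plugin(s) ",
            paste(names(caps)[nProcs > caps], collapse = ", "),
            "; ensure the launcher spreads ranks across nodes",
            call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  # measure leniently: a file that cannot be sized is still assigned (at
  # size 0) and its failure is recorded by the worker that draws it
  sizes <- vapply(paths, function(p) {
    tryCatch(sum(vapply(readPubTator(p), function(d)
      nchar(compositeText(d)), numeric(1))),
      error = function(e) 0)
  }, numeric(1))
  corpus <- Corpus(paths, unname(sizes))
  assignment <- assignStrategy(corpus, nProcs, strategy,
                               shuffleSeed = shuffleSeed)
  ranks <- seq_len(nProcs) - 1L
  work <- function(r) .rankWorker(r, groups(assignment)[[r + 1L]],
                                  plugins, outDir)
  results <- if (backend == "serial") lapply(ranks, work)
             else parallel::mclapply(ranks, work, mc.cores = nProcs)
  bad <- vapply(results, function(x) !is.list(x) || is.null(x$inits),
                logical(1))
  if (any(bad))
    stop("worker rank(s) ", paste(ranks[bad], collapse = ", "),
         " crashed: ", paste(unique(unlist(results[bad])), collapse = "; "),
         call. = FALSE)

  bindAll <- function(field, empty) {
    rows <- unlist(lapply(results, `[[`, field), recursive = FALSE,
                   use.names = FALSE)
    if (length(rows)) do.call(rbind, rows) else empty
  }
  log <- TimeLog(
    perFile = bindAll("perFile",
                      data.frame(file_id = character(), rank = integer(),
                                 plugin = character(), seconds = numeric(),
                                 stringsAsFactors = FALSE)),
    perRankInit = bindAll("inits",
                          data.frame(rank = integer(), plugin = character(),
                                     seconds = numeric(),
                                     stringsAsFactors = FALSE)),
    failures = bindAll("fails",
                       data.frame(file_id = character(), rank = integer(),
                                  message = character(),
                                  stringsAsFactors = FALSE)))
  if (strict && nrow(failures(log)))
    stop(nrow(failures(log)), " file(s) failed: ",
         paste(failures(log)$file_id, collapse = ", "), call. = FALSE)
  log
}

#' Summarise a TimeLog into run metrics
#'
#' Each rank's total execution time is its initialisation seconds plus the
#' sum of its per-file seconds; the totals feed \code{\link{lbe}}. Ranks
#' that appear nowhere in the log (no work, no init) are not invented:
#' supply \code{nProcs} to include idle ranks as zero-time workers.
#'
#' @param timelog a \code{\link{TimeLog}}.
#' @param nProcs optional total rank count (to account for idle ranks).
#' @return A list: \code{metrics} (a \code{\link{RunMetrics}}),
#'   \code{perRank} (data.frame rank/seconds) and \code{perPlugin}
#'   (data.frame plugin/seconds, total annotation time per plugin).
#' @export
evaluateTimeLog <- function(timelog, nProcs = NULL) {
  pf <- perFileTimes(timelog)
  pi <- perRankInitTimes(timelog)
  if (!nrow(pf) && !nrow(pi)) stop("empty time log", call. = FALSE)
  ranks <- sort(unique(c(pf$rank, pi$rank)))
  if (!is.null(nProcs)) ranks <- seq_len(as.integer(nProcs)) - 1L
  totals <- vapply(ranks, function(r) {
    sum(pf$seconds[pf$rank == r]) + sum(pi$seconds[pi$rank == r])
  }, numeric(1))
  perPlugin <- stats::aggregate(seconds ~ plugin, data = pf, FUN = sum)
  list(metrics = lbe(totals),
       perRank = data.frame(rank = ranks, seconds = totals),
       perPlugin = perPlugin)
}

#' Serialise a TimeLog
#'
#' Tab-separated records: \code{init} rows (rank, plugin, seconds),
#' \code{file} rows (file id, rank, plugin, seconds) and \code{fail} rows.
#'
#' @param timelog a \code{\link{TimeLog}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeTimeLog <- function(timelog, path) {
  pf <- perFileTimes(timelog); pi <- perRankInitTimes(timelog)
  fl <- failures(timelog)
  lines <- c(
    if (nrow(pi)) paste("init", pi$rank, pi$plugin,
                        sprintf("%.6f", pi$seconds), sep = "\t"),
    if (nrow(pf)) paste("file", pf$file_id, pf$rank, pf$plugin,
                        sprintf("%.6f", pf$seconds), sep = "\t"),
    if (nrow(fl)) paste("fail", fl$file_id, fl$rank, fl$message, sep = "\t"))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' @rdname writeTimeLog
#' @export
readTimeLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, character(1), 1L)
  mk <- function(rows, cols, types) {
    if (!length(rows))
      return(stats::setNames(
        as.data.frame(lapply(types, function(t) vector(t, 0)),
                      stringsAsFactors = FALSE), cols))
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- cols
    for (k in seq_along(cols)) df[[k]] <- as(df[[k]], types[k])
    df
  }
  TimeLog(
    perFile = mk(lapply(parts[kind == "file"], `[`, 2:5),
                 c("file_id", "rank", "plugin", "seconds"),
                 c("character", "integer", "character", "numeric")),
    perRankInit = mk(lapply(parts[kind == "init"], `[`, 2:4),
                     c("rank", "plugin", "seconds"),
                     c("integer", "character", "numeric")),
    failures = mk(lapply(parts[kind == "fail"], `[`, 2:4),
                  c("file_id", "rank", "message"),
                  c("character", "integer", "character")))
}

#' Write a run report
#'
#' Delimited-text summary of an evaluated run: per-rank totals, per-plugin
#' totals, and the MET/AET/LBE line.
#'
#' @param evaluation result of \code{\link{evaluateTimeLog}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeRunReport <- function(evaluation, path) {
  m <- evaluation$metrics
  lines <- c("# per-rank totals (rank\tseconds)",
             paste(evaluation$perRank$rank,
                   sprintf("%.4f", evaluation$perRank$seconds), sep = "\t"),
             "# per-plugin totals (plugin\tseconds)",
             paste(evaluation$perPlugin$plugin,
                   sprintf("%.4f", evaluation$perPlugin$seconds), sep = "\t"),
             "# summary",
             sprintf("MET\t%.4f", maxSeconds(m)),
             sprintf("AET\t%.4f", meanSeconds(m)),
             sprintf("LBE\t%.2f", lbeRatio(m)))
  writeLines(lines, path)
  invisible(path)
}

#' Collect the annotation set of a run's outputs
#'
#' Reads every PubTator file in a directory and returns the flat set of
#' annotation tuples (doc id, start, end, mention, type, concept), sorted.
#' Used to verify that runs with different backends, strategies or worker
#' counts produce identical annotations.
#'
#' @param dir directory of PubTator files.
#' @return A data.frame of annotation tuples, one row per annotation.
#' @export
annotationSet <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  rows <- do.call(rbind, c(list(annotationTable()), lapply(files, function(f) {
    do.call(rbind, c(list(annotationTable()),
                     lapply(readPubTator(f), annotations)))
  })))
  rows <- rows[order(rows$doc_id, rows$start, rows$end, rows$type,
                     rows$concept), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
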