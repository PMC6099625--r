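# Static load-balancing strategies, makespan accounting, the LBE statistic,
# and a brute-force optimal-makespan oracle for small instances.

.resolveCosts <- function(corpus, costs) {
  if (is.null(costs)) return(sizeChars(corpus))
  costs <- costs[fileIds(corpus)]
  if (any(is.na(costs)))
    stop("missing cost for file ",
         dQuote(fileIds(corpus)[which(is.na(costs))[1L]], FALSE),
         call. = FALSE)
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  costs
}

# Descending-cost order with deterministic tie-break on file id.
.costOrder <- function(ids, costs) {
  ord <- order(-costs, ids, method = "radix")
  ids[ord]
}

#' Modulo (random) assignment
#'
#' The file at list position \code{P} (0-based) goes to rank
#' \code{P mod nProcs}. With \code{shuffleSeed} the file list is first
#' shuffled reproducibly, which turns the deterministic deal into a
#' simulation of random distribution — the behaviour of a naive scheduler
#' fed files in arbitrary directory order. File sizes play no role, which
#' is exactly why this strategy degrades on skewed corpora.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param nProcs number of worker ranks, >= 1.
#' @param shuffleSeed optional integer; when given, the file list is
#'   shuffled with this seed before the modulo deal.
#' @return An \code{\link{Assignment}}.
#' @examples
#' co <- Corpus(paste0("f", 0:4), c(7, 5, 4, 3, 2))
#' groups(assignModulo(co, 2))
#' @export
assignModulo <- function(corpus, nProcs, shuffleSeed = NULL) {
  nProcs <- as.integer(nProcs)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  ids <- fileIds(corpus)
  if (!is.null(shuffleSeed))
    ids <- withSeed(shuffleSeed, sample(ids))
  groups <- lapply(seq_len(nProcs) - 1L, function(r) {
    ids[which((seq_along(ids) - 1L) %% nProcs == r)]
  })
  Assignment(nProcs, groups)
}

#' Serpentine round-robin assignment
#'
#' Files are sorted by cost in descending order and dealt to ranks in
#' serpentine passes: pass 0 left-to-right (rank 0, 1, ..., n-1), pass 1
#' right-to-left (n-1, ..., 0), and so on, stopping when files run out.
#' Mixing large files with small ones this way keeps per-rank totals
#' roughly balanced while still assigning (almost) equal file counts.
#'
#' @inheritParams assignModulo
#' @param costs optional named numeric vector of per-file costs (names are
#'   file ids); defaults to the corpus character sizes.
#' @return An \code{\link{Assignment}}.
#' @export
assignRoundRobin <- function(corpus, nProcs, costs = NULL) {
  nProcs <- as.integer(nProcs)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  costs <- .resolveCosts(corpus, costs)
  ids <- .costOrder(fileIds(corpus), unname(costs))
  groups <- rep(list(character()), nProcs)
  for (k in seq_along(ids)) {
    pass <- (k - 1L) %/% nProcs
    pos <- (k - 1L) %% nProcs
    r <- if (pass %% 2L == 0L) pos else nProcs - 1L - pos
    groups[[r + 1L]] <- c(groups[[r + 1L]], ids[k])
  }
  Assignment(nProcs, groups)
}

#' Greedy least-loaded ("Short-Board") assignment
#'
#' The longest-processing-time greedy heuristic: files are sorted by cost
#' in descending order and each file in turn is dispatched to the rank
#' whose current cumulative cost is smallest. The name alludes to the
#' shortest stave of a barrel: the least-loaded worker bounds nothing, so
#' topping it up first keeps the load profile level. Ties on cost are
#' broken by file id (ascending), ties on load by lowest rank, so
#' assignments are fully reproducible.
#'
#' The classic worst-case guarantee for this heuristic applies: its
#' makespan is at most \code{4/3 - 1/(3 nProcs)} times the optimum.
#'
#' @inheritParams assignRoundRobin
#' @return An \code{\link{Assignment}}.
#' @examples
#' co <- Corpus(paste0("f", 0:4), c(7, 5, 4, 3, 2))
#' makespan(assignShortBoard(co, 2), sizeChars(co))  # 11, the optimum
#' @export
assignShortBoard <- function(corpus, nProcs, costs = NULL) {
  nProcs <- as.integer(nProcs)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  costs <- .resolveCosts(corpus, costs)
  ids <- .costOrder(fileIds(corpus), unname(costs))
  loads <- numeric(nProcs)
  groups <- rep(list(character()), nProcs)
  for (id in ids) {
    r <- which.min(loads)  # first minimum = lowest rank
    groups[[r]] <- c(groups[[r]], id)
    loads[r] <- loads[r] + costs[[id]]
  }
  Assignment(nProcs, groups)
}

#' Dispatch on a strategy name
#'
#' Convenience wrapper mapping \code{"modulo"}, \code{"round_robin"} or
#' \code{"short_board"} to the corresponding assignment function.
#'
#' @inheritParams assignRoundRobin
#' @param strategy strategy name.
#' @param shuffleSeed passed to \code{\link{assignModulo}}; ignored by the
#'   size-aware strategies.
#' @return An \code{\link{Assignment}}.
#' @export
assignStrategy <- function(corpus, nProcs,
                           strategy = c("short_board", "round_robin",
                                        "modulo"),
                           costs = NULL, shuffleSeed = NULL) {
  strategy <- match.arg(strategy)
  switch(strategy,
         modulo = assignModulo(corpus, nProcs, shuffleSeed = shuffleSeed),
         round_robin = assignRoundRobin(corpus, nProcs, costs = costs),
         short_board = assignShortBoard(corpus, nProcs, costs = costs))
}

#' Per-rank loads and makespan of an assignment
#'
#' \code{rankLoads} sums the member costs of each rank; \code{makespan} is
#' the maximum — the completion time of the slowest worker, the quantity a
#' static scheduler tries to minimise (the run is not finished until the
#' slowest rank finishes).
#'
#' @param assignment an \code{\link{Assignment}}.
#' @param costs named numeric vector of per-file costs covering every
#'   assigned file.
#' @return \code{rankLoads}: numeric vector of length \code{nProcs};
#'   \code{makespan}: a single number (0 for an empty corpus).
#' @export
rankLoads <- function(assignment, costs) {
  vapply(groups(assignment), function(g) {
    if (!length(g)) return(0)
    cs <- costs[g]
    if (any(is.na(cs)))
      stop("missing cost for file ", dQuote(g[which(is.na(cs))[1L]], FALSE),
           call. = FALSE)
    sum(cs)
  }, numeric(1))
}

#' @rdname rankLoads
#' @export
makespan <- function(assignment, costs) {
  loads <- rankLoads(assignment, costs)
  if (!length(loads)) 0 else max(loads)
}

#' Load-balancing efficiency (LBE)
#'
#' \code{LBE = AET / MET}: the average execution time across workers
#' divided by the maximum. LBE is 1 exactly when all workers finish
#' together (AET = MET) and decreases towards 0 as the load profile skews;
#' it is invariant to a common positive rescaling of all times. Reporting
#' is conventionally rounded to 2 decimals.
#'
#' @param perProcSeconds non-empty numeric vector of per-worker execution
#'   times (seconds, all >= 0, maximum > 0).
#' @return A \code{\link{RunMetrics}} holding the per-process times, MET
#'   (max), AET (mean) and their ratio.
#' @examples
#' lbeRatio(lbe(c(1, 3)))  # 2/3
#' @export
lbe <- function(perProcSeconds) {
  p <- as.numeric(perProcSeconds)
  if (!length(p)) stop("per-process times must be non-empty", call. = FALSE)
  if (any(is.na(p)) || any(p < 0))
    stop("per-process times must be non-negative", call. = FALSE)
  if (max(p) == 0)
    stop("no work executed: maximum per-process time is 0", call. = FALSE)
  new("RunMetrics", perProcSeconds = p, maxSeconds = max(p),
      meanSeconds = mean(p), lbeRatio = mean(p) / max(p))
}

#' Exact optimal makespan by exhaustive search
#'
#' Brute-force oracle for small instances: the exact minimum makespan over
#' all partitions of the given costs into \code{nProcs} groups, found by
#' depth-first enumeration (in descending-cost order) with two prunings:
#' a branch whose partial load already meets the incumbent is cut, and a
#' file is offered to at most one currently-empty rank (empty ranks are
#' interchangeable).
#'
#' Intended as a test oracle for scheduler quality, not a scheduler; the
#' instance caps keep the enumeration trivial.
#'
#' @param costs numeric vector of non-negative costs.
#' @param nProcs number of ranks, at most \code{maxProcs}.
#' @param maxFiles,maxProcs instance caps (defaults 14 files, 4 ranks);
#'   larger instances are refused — use the simulator for those.
#' @return The minimal achievable makespan.
#' @examples
#' optimalMakespan(c(7, 5, 4, 3, 2), 2)  # 11
#' @export
optimalMakespan <- function(costs, nProcs, maxFiles = 14L, maxProcs = 4L) {
  costs <- as.numeric(costs)
  if (any(is.na(costs)) || any(costs < 0))
    stop("costs must be non-negative", call. = FALSE)
  if (length(costs) > maxFiles || nProcs > maxProcs)
    stop("instance exceeds the enumeration cap (", maxFiles, " files, ",
         maxProcs, " ranks); use simulateRun() for larger instances",
         call. = FALSE)
  if (!length(costs)) return(0)
  nProcs <- as.integer(nProcs)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  costs <- sort(costs, decreasing = TRUE)
  best <- sum(costs)  # one rank takes everything
  loads <- numeric(nProcs)
  recurse <- function(i) {
    if (i > length(costs)) {
      best <<- min(best, max(loads))
      return(invisible())
    }
    triedEmpty <- FALSE
    for (r in seq_len(nProcs)) {
      if (loads[r] == 0) {
        if (triedEmpty) next
        triedEmpty <- TRUE
      }
      if (loads[r] + costs[i] >= best) next
      loads[r] <<- loads[r] + costs[i]
      recurse(i + 1L)
      loads[r] <<- loads[r] - costs[i]
    }
  }
  recurse(1L)
  best
}

# ---- plan files ----------------------------------------------------------

#' Read and write assignment plan files
#'
#' A plan is a tab-separated text file with one line per assigned file:
#' rank (0-based), file id, cost. It is the hand-off between planning and
#' execution: \code{\link{runEngine}} and external launchers consume it.
#'
#' @param assignment an \code{\link{Assignment}}.
#' @param costs named numeric vector of per-file costs.
#' @param path plan file path.
#' @return \code{writePlan} invisibly returns \code{path};
#'   \code{readPlan} returns a list with elements \code{assignment} (an
#'   \code{Assignment}) and \code{costs} (named numeric vector).
#' @export
writePlan <- function(assignment, costs, path) {
  rows <- do.call(rbind, lapply(seq_len(nProcs(assignment)), function(r) {
    g <- groups(assignment)[[r]]
    if (!length(g)) return(NULL)
    data.frame(rank = r - 1L, file_id = g, cost = unname(costs[g]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(rank = integer(), file_id = character(),
                       cost = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writePlan
#' @param nProcs optional rank count for \code{readPlan}; defaults to one
#'   more than the highest rank in the file (so trailing empty ranks are
#'   preserved only when given explicitly).
#' @export
readPlan <- function(path, nProcs = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#",
                          col.names = c("rank", "file_id", "cost"),
                          colClasses = c("integer", "character", "numeric"))
  n <- if (is.null(nProcs)) max(df$rank, 0L) + 1L else as.integer(nProcs)
  grp <- lapply(seq_len(n) - 1L, function(r) df$file_id[df$rank == r])
  list(assignment = Assignment(n, grp),
       costs = stats::setNames(df$cost, df$file_id))
}
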