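# Scheduling simulator: pure arithmetic over a workload model, so strategy
# comparisons that would need hours of annotator time run in milliseconds.

#' Simulate a parallel run
#'
#' Computes the chosen strategy's \code{\link{Assignment}} using
#' model-predicted per-file costs, then sets each rank's simulated
#' execution time to \code{initCost} plus the sum of its files' predicted
#' costs. No annotator is invoked. Initialisation is one constant per
#' worker per run (the summed one-time startup of all plugins); because
#' every rank pays it, a large \code{initCost} drives LBE towards 1 while
#' the makespan plateaus — the regime where adding processes stops helping.
#'
#' @param corpus a \code{\link{Corpus}}.
#' @param model a \code{\link{WorkloadModel}}; default
#'   \code{\link{identityModel}()} (cost = character count).
#' @param strategy \code{"short_board"}, \code{"round_robin"} or
#'   \code{"modulo"}.
#' @param nProcs number of simulated worker ranks, >= 1.
#' @param initCost per-worker one-time initialisation seconds, >= 0.
#' @param shuffleSeed optional seed for the modulo strategy's shuffle.
#' @return A \code{\link{RunMetrics}}.
#' @examples
#' co <- Corpus(paste0("f", 0:4), c(7, 5, 4, 3, 2))
#' simulateRun(co, strategy = "short_board", nProcs = 2)  # LBE 10.5/11
#' @export
simulateRun <- function(corpus, model = identityModel(),
                        strategy = c("short_board", "round_robin", "modulo"),
                        nProcs, initCost = 0, shuffleSeed = NULL) {
  strategy <- match.arg(strategy)
  if (nProcs < 1L) stop("nProcs must be >= 1")
  if (initCost < 0) stop("initCost must be >= 0")
  costs <- predictCost(model, corpus)
  assignment <- assignStrategy(corpus, nProcs, strategy, costs = costs,
                               shuffleSeed = shuffleSeed)
  lbe(initCost + rankLoads(assignment, costs))
}

#' Compare strategies across parallel scales
#'
#' Runs \code{\link{simulateRun}} for every combination of strategy and
#' process count, averaging MET, AET and LBE over seeds. Seeds affect only
#' the modulo strategy's shuffle and, when \code{corpus} is a generator
#' function, the corpus draw; the size-aware strategies are deterministic
#' on a fixed corpus.
#'
#' @param corpus a \code{\link{Corpus}}, or a function of one argument
#'   (a seed) returning a \code{Corpus}.
#' @param model a \code{\link{WorkloadModel}}.
#' @param nProcsList integer vector of process counts.
#' @param initCost per-worker initialisation seconds.
#' @param seeds integer vector of seeds to average over.
#' @param strategies strategy names to compare.
#' @return A data.frame with one row per (strategy, n_procs): columns
#'   \code{strategy}, \code{n_procs}, \code{met}, \code{aet}, \code{lbe}
#'   (each averaged over seeds).
#' @export
compareStrategies <- function(corpus, model = identityModel(),
                              nProcsList, initCost = 0, seeds = 1L,
                              strategies = c("modulo", "round_robin",
                                             "short_board")) {
  if (!length(nProcsList)) stop("nProcsList must be non-empty")
  grid <- expand.grid(strategy = strategies, n_procs = nProcsList,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    st <- grid$strategy[k]; np <- grid$n_procs[k]
    runs <- vapply(seeds, function(s) {
      co <- if (is.function(corpus)) corpus(s) else corpus
      m <- simulateRun(co, model, st, np, initCost, shuffleSeed = s)
      c(maxSeconds(m), meanSeconds(m), lbeRatio(m))
    }, numeric(3))
    data.frame(strategy = st, n_procs = np,
               met = mean(runs[1, ]), aet = mean(runs[2, ]),
               lbe = mean(runs[3, ]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a strategy comparison as a panelled text table
#'
#' Three panels — maximum times, average times, efficiencies — with one row
#' per process count and one column per strategy.
#'
#' @param comparison result of \code{\link{compareStrategies}}.
#' @param path output path; omit to return the lines invisibly.
#' @return Invisibly, the character vector of emitted lines.
#' @export
writeComparison <- function(comparison, path = NULL) {
  strategies <- unique(comparison$strategy)
  nps <- sort(unique(comparison$n_procs))
  panel <- function(title, col, digits) {
    header <- paste(c("n_procs", strategies), collapse = "\t")
    body <- vapply(nps, function(np) {
      vals <- vapply(strategies, function(st) {
        v <- comparison[comparison$strategy == st &
                          comparison$n_procs == np, col]
        sprintf(paste0("%.", digits, "f"), v)
      }, character(1))
      paste(c(np, vals), collapse = "\t")
    }, character(1))
    c(paste0("# ", title), header, body, "")
  }
  out <- c(panel("maximum time among all processes (s)", "met", 2),
           panel("average time of all processes (s)", "aet", 2),
           panel("efficiency (average/maximum)", "lbe", 2))
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
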