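# Bundled reference benchmark tables (plain-text fixtures under extdata).

#' Bundled reference benchmark tables
#'
#' Small published benchmark measurements of three document-level NER tools,
#' shipped as plain-text fixtures: \code{referenceSerialTimes} returns the
#' serial processing times by input size (MB) or by article count, used to
#' fit and check the affine workload model; \code{referenceStrategyTimes}
#' returns per-strategy maximum and average execution times on a 16 MB /
#' 175-article corpus at 2–64 processes, used as worked examples for the
#' LBE statistic.
#'
#' @param by \code{"size"} (per-MB table) or \code{"count"} (per-article
#'   table).
#' @return A data.frame. For \code{referenceSerialTimes}: one row per
#'   input (size_mb or n_papers) with per-tool and total seconds. For
#'   \code{referenceStrategyTimes}: columns \code{panel} ("max"/"avg"),
#'   \code{n_procs}, and one column of seconds per strategy.
#' @examples
#' fitTimeModel(with(referenceSerialTimes(),
#'                   data.frame(size = size_mb, seconds = total)),
#'              sizeUnit = "MB")
#' @export
referenceSerialTimes <- function(by = c("size", "count")) {
  by <- match.arg(by)
  path <- system.file("extdata",
                      paste0("serial_times_by_", by, ".tsv"),
                      package = "corpusBalance", mustWork = TRUE)
  first <- if (by == "size") "size_mb" else "n_papers"
  utils::read.table(path, sep = "\t", comment.char = "#",
                    col.names = c(first, "gnormplus", "tmvar", "dnorm",
                                  "total"))
}

#' @rdname referenceSerialTimes
#' @export
referenceStrategyTimes <- function() {
  path <- system.file("extdata", "strategy_times.tsv",
                      package = "corpusBalance", mustWork = TRUE)
  utils::read.table(path, sep = "\t", comment.char = "#",
                    col.names = c("panel", "n_procs", "random",
                                  "round_robin", "short_board"),
                    colClasses = c("character", "integer", "numeric",
                                   "numeric", "numeric"))
}
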